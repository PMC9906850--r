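#' Standardize continuous covariates
#'
#' Centers to mean 0 and scales to sample SD 1, storing the transform so
#' fitted slopes can be mapped back to the raw scale.
#'
#' @param data a `data.frame`.
#' @param cols character vector of numeric columns to standardize.
#' @return `data` with the columns replaced; attribute `standardization` is a
#'   `data.frame(column, center, scale)`.
#' @export
standardize <- function(data, cols) {
  df <- as.data.frame(data)
  assert_that(all(cols %in% names(df)), "columns not found")
  ctr <- numeric(length(cols)); scl <- numeric(length(cols))
  for (k in seq_along(cols)) {
    x <- df[[cols[k]]]
    assert_that(is.numeric(x), paste0(cols[k], " is not numeric"))
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("zero-variance column: ", cols[k], call. = FALSE)
    ctr[k] <- mean(x, na.rm = TRUE); scl[k] <- s
    df[[cols[k]]] <- (x - ctr[k]) / s
  }
  attr(df, "standardization") <- data.frame(column = cols, center = ctr,
                                            scale = scl,
                                            stringsAsFactors = FALSE)
  df
}

#' Pairwise collinearity screen
#'
#' Flags covariate pairs whose absolute Pearson correlation exceeds `r_max`;
#' flagged pairs are excluded from co-occurring in enumerated candidate
#' models.
#'
#' @param data a `data.frame`.
#' @param cols numeric columns to screen.
#' @param r_max flagging threshold.
#' @return list: `r` (correlation matrix), `flagged` (2-column character
#'   matrix of flagged pairs, possibly 0 rows).
#' @export
collinearity_screen <- function(data, cols, r_max = 0.7) {
  assert_that(length(cols) >= 2, "need at least 2 covariates")
  r <- cor(as.data.frame(data)[, cols], use = "pairwise.complete.obs")
  flagged <- which(abs(r) > r_max & upper.tri(r), arr.ind = TRUE)
  pairs <- cbind(cols[flagged[, 1]], cols[flagged[, 2]])
  list(r = r, flagged = pairs)
}

#' Fit one candidate mixed model by maximum likelihood
#'
#' A linear mixed model with the given fixed-effect subset and a random
#' intercept for the grouping factor, fitted by ML (not REML) so that AICc
#' values are comparable across fixed-effect sets. The parameter count `k`
#' includes the residual and random-intercept variances. Fits with a singular
#' random-effect estimate are flagged.
#'
#' @param data model data.
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms (may be empty for the
#'   intercept-only model).
#' @param group random-intercept grouping column.
#' @return list of class `candidate_model`: formula, coefficients and their
#'   SEs, logLik, k, n, singular flag, and the fitted lme4 object.
#' @export
fit_lmm_ml <- function(data, response, fixed = character(0),
                       group = "individual") {
  df <- as.data.frame(data)
  assert_that(length(unique(df[[group]])) >= 2,
              "grouping factor needs >= 2 levels")
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs, "+ (1 |", group, ")"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = df, REML = FALSE)))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  structure(list(formula = paste(response, "~", rhs),
                 fixed = fixed,
                 coef = fe, se = se,
                 loglik = as.numeric(logLik(fit)),
                 k = length(fe) + 2L,
                 n = nrow(df),
                 singular = lme4::isSingular(fit),
                 fit = fit),
            class = "candidate_model")
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik model log-likelihood.
#' @param k parameter count (fixed effects plus estimated variances).
#' @param n sample size; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1)
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

subsets_of <- function(terms) {
  if (!length(terms)) return(list(character(0)))
  unlist(lapply(0:length(terms), function(m)
    combn(terms, m, simplify = FALSE)), recursive = FALSE)
}

violates <- function(set, excluded_pairs) {
  if (is.null(excluded_pairs) || !nrow(excluded_pairs)) return(FALSE)
  any(apply(excluded_pairs, 1, function(pr) all(pr %in% set)))
}

#' Enumerate, fit and AICc-rank candidate mixed models
#'
#' Stage 1 enumerates all subsets of the core predictors (plus any forced-in
#' terms, minus subsets containing a flagged collinear pair). Stage 2, if
#' `stage2` terms are given, augments the stage-1 models within
#' `stage2_delta` of the best with every non-empty subset of the additional
#' terms, then re-ranks the pooled set. Ranking is deterministic: ties break
#' by fewer parameters, then by formula text. Singular fits can be dropped.
#'
#' @param data model data.
#' @param response response column.
#' @param core character vector of stage-1 candidate terms.
#' @param stage2 optional character vector of stage-2 augmentation terms.
#' @param forced terms included in every model.
#' @param excluded_pairs 2-column matrix of terms that may not co-occur
#'   (see [collinearity_screen()]).
#' @param group random-intercept grouping column.
#' @param stage2_delta AICc window defining the stage-1 top set.
#' @param drop_singular drop models with singular random-effect fits.
#' @param max_models refuse enumerations beyond this size unless raised.
#' @return `data.frame` ranked by AICc: formula, k, loglik, AICc, delta,
#'   weight, singular, stage; attribute `models` holds the fitted
#'   `candidate_model` objects in table order.
#' @export
enumerate_and_rank <- function(data, response, core, stage2 = NULL,
                               forced = character(0), excluded_pairs = NULL,
                               group = "individual", stage2_delta = 4.3,
                               drop_singular = FALSE, max_models = 4096) {
  free <- setdiff(core, forced)
  sets <- lapply(subsets_of(free), function(s) c(forced, s))
  sets <- Filter(function(s) !violates(s, excluded_pairs), sets)
  if (length(sets) > max_models)
    stop("enumeration would produce ", length(sets), " models (> ",
         max_models, "); raise max_models to override", call. = FALSE)
  fit_sets <- function(sets, stage) {
    lapply(sets, function(s) {
      m <- fit_lmm_ml(data, response, sort(s), group)  # canonical term order
      m$stage <- stage
      m
    })
  }
  models <- fit_sets(sets, 1L)
  if (!is.null(stage2) && length(stage2)) {
    a1 <- vapply(models, function(m) aicc(m$loglik, m$k, m$n), 0)
    top <- which(a1 - min(a1) <= stage2_delta)
    aug_sets <- list()
    for (i in top) {
      base_set <- models[[i]]$fixed
      for (s2 in subsets_of(stage2)[-1]) {
        cand <- c(base_set, s2)
        if (!violates(cand, excluded_pairs)) aug_sets <- c(aug_sets, list(cand))
      }
    }
    aug_sets <- unique(aug_sets)
    existing <- lapply(models, function(m) sort(m$fixed))
    aug_sets <- Filter(function(s) !list(sort(s)) %in% existing, aug_sets)
    if (length(models) + length(aug_sets) > max_models)
      stop("stage-2 enumeration exceeds ", max_models, " models",
           call. = FALSE)
    models <- c(models, fit_sets(aug_sets, 2L))
  }
  if (drop_singular) {
    keep <- !vapply(models, `[[`, TRUE, "singular")
    assert_that(any(keep), "all candidate models singular")
    models <- models[keep]
  }
  tab <- data.frame(
    formula = vapply(models, `[[`, "", "formula"),
    k = vapply(models, `[[`, 0L, "k"),
    loglik = vapply(models, `[[`, 0, "loglik"),
    stage = vapply(models, `[[`, 0L, "stage"),
    singular = vapply(models, `[[`, TRUE, "singular"),
    stringsAsFactors = FALSE
  )
  tab$AICc <- vapply(seq_len(nrow(tab)), function(i)
    aicc(tab$loglik[i], tab$k[i], models[[i]]$n), 0)
  ord <- order(tab$AICc, tab$k, tab$formula)
  tab <- tab[ord, , drop = FALSE]
  models <- models[ord]
  tab$delta <- tab$AICc - tab$AICc[1]
  w <- exp(-0.5 * tab$delta)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  attr(tab, "models") <- models
  tab
}

#' Full model averaging with unconditional standard errors
#'
#' Averages coefficients over the models within `delta_max` AICc of the best,
#' substituting 0 where a predictor is absent (full averaging, shrinking weak
#' predictors toward 0). The unconditional SE combines within-model variance
#' and among-model spread (Burnham & Anderson):
#' `SE = sum_m w_m sqrt(se_m^2 + (b_m - b_avg)^2)` with weights renormalized
#' over the averaging set.
#'
#' @param ranked output of [enumerate_and_rank()] (with its `models`
#'   attribute).
#' @param delta_max AICc window defining the averaging set.
#' @return `data.frame`: term, estimate, se_unconditional, ci_low, ci_high,
#'   n_models (models in the set containing the term).
#' @export
model_average <- function(ranked, delta_max = 4) {
  models <- attr(ranked, "models")
  assert_that(!is.null(models), "ranked table lost its models attribute")
  inset <- which(ranked$delta <= delta_max)
  assert_that(length(inset) >= 1, "no model within delta_max")
  w <- ranked$weight[inset] / sum(ranked$weight[inset])
  terms_all <- unique(unlist(lapply(models[inset],
                                    function(m) names(m$coef))))
  rows <- lapply(terms_all, function(tm) {
    b <- vapply(models[inset], function(m) {
      if (tm %in% names(m$coef)) unname(m$coef[tm]) else 0
    }, 0)
    s <- vapply(models[inset], function(m) {
      if (tm %in% names(m$coef)) unname(m$se[tm]) else 0
    }, 0)
    est <- sum(w * b)
    se_u <- sum(w * sqrt(s^2 + (b - est)^2))
    data.frame(term = tm, estimate = est, se_unconditional = se_u,
               ci_low = est - 1.96 * se_u, ci_high = est + 1.96 * se_u,
               n_models = sum(vapply(models[inset],
                                     function(m) tm %in% names(m$coef),
                                     TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
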