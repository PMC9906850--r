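#' Build the survival analysis table
#'
#' One record per individual carrying its fate, tracking duration and
#' movement covariates. Individuals that crossed the juvenile-to-adult
#' boundary (first birthday) while tracked contribute two independent
#' records: a juvenile span censored at the transition, then an adult span
#' from the transition to the fate.
#'
#' @param survival `data.frame` with `individual`, `duration_days`, `event`
#'   (1 dead / 0 censored), as from [simulate_survival()] or field records.
#' @param metadata `data.frame` with `individual`, `sex`, `hatch_date`,
#'   `tag_start`.
#' @param summaries per-individual covariates: `individual`,
#'   `mean_max_disp_km` (and optionally others), e.g. aggregated from
#'   [build_index_table()] summaries.
#' @param riiv rIIV table (`individual`, `riiv_km`), e.g. [extract_riiv()].
#' @return `data.frame` of records: record, individual, duration_days, event,
#'   age_group, sex, riiv_km, mean_max_disp_km, track_days. Individuals
#'   without an rIIV estimate are dropped with a message.
#' @export
build_survival_table <- function(survival, metadata, summaries, riiv) {
  sv <- as.data.frame(survival)
  md <- as.data.frame(metadata)
  have_riiv <- sv$individual %in% riiv$individual
  if (any(!have_riiv))
    message(sum(!have_riiv), " individuals dropped: no rIIV estimate")
  sv <- sv[have_riiv, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sv))) {
    ind <- sv$individual[i]
    m <- md[md$individual == ind, ][1, ]
    dur <- sv$duration_days[i]
    ev <- sv$event[i]
    trans_day <- if (!is.na(m$hatch_date))
      as.numeric(as.Date(m$hatch_date) + 365L - as.Date(m$tag_start))
    else -Inf
    covs <- data.frame(
      individual = ind, sex = m$sex,
      riiv_km = riiv$riiv_km[match(ind, riiv$individual)],
      mean_max_disp_km = summaries$mean_max_disp_km[
        match(ind, summaries$individual)],
      stringsAsFactors = FALSE)
    if (trans_day > 0 && trans_day < dur) {
      rows[[length(rows) + 1L]] <- cbind(
        covs, duration_days = trans_day, event = 0L,
        age_group = "juvenile", track_days = trans_day)
      rows[[length(rows) + 1L]] <- cbind(
        covs, duration_days = dur - trans_day, event = ev,
        age_group = "adult", track_days = dur - trans_day)
    } else {
      age <- if (trans_day <= 0) "adult" else "juvenile"
      rows[[length(rows) + 1L]] <- cbind(
        covs, duration_days = dur, event = ev, age_group = age,
        track_days = dur)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[out$duration_days > 0, , drop = FALSE]
  out$record <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Breslow/Efron partial log-likelihood, gradient and information for sorted
# data (increasing time). Ties share an event time.
cox_loglik <- function(beta, Xs, time, status, ties = "breslow") {
  n <- nrow(Xs); p <- ncol(Xs)
  eta <- as.numeric(Xs %*% beta)
  w <- exp(eta)
  # cumulative risk sums from the largest time down
  ord <- n:1
  S0 <- cumsum(w[ord])[ord]                 # sum over risk set {t_j >= t_i}
  S1 <- apply(Xs * w, 2, function(cl) cumsum(cl[ord])[ord])
  S1 <- matrix(S1, n, p)
  # align risk sets at tied times: use the first index of each tied block
  first_of_time <- match(time, time)
  S0 <- S0[first_of_time]
  S1 <- S1[first_of_time, , drop = FALSE]
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  ev_times <- unique(time[status == 1])
  for (t in ev_times) {
    di <- which(time == t & status == 1)
    d <- length(di)
    i0 <- di[1]
    s0 <- S0[i0]; s1 <- S1[i0, ]
    xsum <- colSums(Xs[di, , drop = FALSE])
    etasum <- sum(eta[di])
    # S2 at this risk set (computed lazily)
    rs <- which(time >= t)
    Xr <- Xs[rs, , drop = FALSE] * sqrt(w[rs])
    s2 <- crossprod(Xr)
    if (ties == "efron" && d > 1) {
      wd <- w[di]
      s0d <- sum(wd)
      s1d <- colSums(Xs[di, , drop = FALSE] * wd)
      Xd <- Xs[di, , drop = FALSE] * sqrt(wd)
      s2d <- crossprod(Xd)
      for (k in seq_len(d) - 1) {
        f <- k / d
        a0 <- s0 - f * s0d
        a1 <- s1 - f * s1d
        a2 <- s2 - f * s2d
        ll <- ll - log(a0)
        grad <- grad - a1 / a0
        info <- info + a2 / a0 - tcrossprod(a1) / a0^2
      }
      ll <- ll + etasum
      grad <- grad + xsum
    } else {
      ll <- ll + etasum - d * log(s0)
      grad <- grad + xsum - d * s1 / s0
      info <- info + d * (s2 / s0 - tcrossprod(s1 / s0))
    }
  }
  list(ll = ll, grad = grad, info = info)
}

#' Cox proportional-hazards regression by partial likelihood
#'
#' Newton-Raphson maximization of the partial log-likelihood with
#' step-halving; Breslow handling of tied event times (Efron available via
#' `ties = "efron"`). Convergence requires a relative log-likelihood change
#' below `tol`; standard errors come from the inverse observed information.
#' A monotone likelihood (complete separation) is detected when a coefficient
#' runs away; it is capped and flagged with a warning.
#'
#' @param records survival records (see [build_survival_table()]) with
#'   `duration_days` and `event` columns.
#' @param covariates character vector of covariate columns (factors expand to
#'   treatment contrasts).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param standardize center/scale continuous covariates first.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return object of class `cox_fit`: `coef`, `se`, `loglik` (null, final),
#'   `hr`, `hr_ci`, `n`, `n_events`, `score_max` (max |score| at the
#'   optimum), `ties`, `flags`.
#' @export
fit_cox <- function(records, covariates, ties = c("breslow", "efron"),
                    standardize = FALSE, tol = 1e-9, max_iter = 50) {
  ties <- match.arg(ties)
  df <- as.data.frame(records)
  assert_that(all(c("duration_days", "event") %in% names(df)),
              "records need duration_days and event columns")
  assert_that(sum(df$event) >= 1, "need at least 1 event")
  df <- df[complete.cases(df[, c("duration_days", "event", covariates)]), ,
           drop = FALSE]
  mm <- model.matrix(stats::reformulate(covariates), df)[, -1, drop = FALSE]
  const <- apply(mm, 2, function(cl) var(cl) == 0)
  if (any(const))
    stop("constant covariate: ", paste(colnames(mm)[const], collapse = ", "),
         call. = FALSE)
  if (standardize) mm <- scale(mm)
  o <- order(df$duration_days)
  Xs <- mm[o, , drop = FALSE]
  time <- df$duration_days[o]
  status <- df$event[o]
  p <- ncol(Xs)
  beta <- numeric(p)
  fit0 <- cox_loglik(beta, Xs, time, status, ties)
  ll_null <- fit0$ll
  ll_old <- ll_null
  flags <- character(0)
  cur <- fit0
  for (it in seq_len(max_iter)) {
    step <- solve(cur$info + diag(1e-10, p), cur$grad)
    h <- 1
    repeat {
      beta_new <- beta + h * step
      cand <- cox_loglik(beta_new, Xs, time, status, ties)
      if (is.finite(cand$ll) && cand$ll >= cur$ll - 1e-12) break
      h <- h / 2
      if (h < 1e-8) { cand <- cur; beta_new <- beta; break }
    }
    done <- abs(cand$ll - ll_old) < tol * (abs(ll_old) + tol)
    beta <- beta_new; cur <- cand; ll_old <- cand$ll
    if (done) break
  }
  if (any(abs(beta) > 15)) {
    flags <- c(flags, "monotone_likelihood")
    beta <- pmin(pmax(beta, -15), 15)
    cur <- cox_loglik(beta, Xs, time, status, ties)
    warning("monotone partial likelihood (complete separation); ",
            "coefficient capped at |15|")
  }
  dinv <- diag(solve(cur$info))
  if (any(dinv < 0)) {
    flags <- c(flags, "ill_conditioned_information")
    warning("observed information is ill-conditioned; some SEs unavailable")
  }
  se <- sqrt(pmax(dinv, 0))
  se[dinv < 0] <- NA_real_
  names(beta) <- names(se) <- colnames(Xs)
  structure(list(coef = beta, se = se,
                 loglik = c(null = ll_null, final = cur$ll),
                 hr = exp(beta),
                 hr_ci = cbind(low = exp(beta - 1.96 * se),
                               high = exp(beta + 1.96 * se)),
                 n = nrow(Xs), n_events = sum(status),
                 score_max = max(abs(cur$grad)), ties = ties,
                 flags = flags),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards (", x$ties, " ties): ", x$n, " records, ",
      x$n_events, " events\n", sep = "")
  print(hazard_ratio_table(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Forest-style hazard-ratio table
#'
#' Per covariate: hazard ratio `exp(beta)`, Wald 95% CI and p-value.
#' Categorical covariates are reported against their (dropped) reference
#' level. HR < 1 means higher values of the covariate decrease hazard
#' (protective); HR > 1 means they increase it.
#'
#' @param fit a [fit_cox()] result.
#' @return `data.frame`: covariate, coef, se, hr, ci_low, ci_high, p_wald.
#' @export
hazard_ratio_table <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  z <- fit$coef / fit$se
  data.frame(covariate = names(fit$coef), coef = unname(fit$coef),
             se = unname(fit$se), hr = unname(fit$hr),
             ci_low = unname(fit$hr_ci[, "low"]),
             ci_high = unname(fit$hr_ci[, "high"]),
             p_wald = unname(2 * pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}
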