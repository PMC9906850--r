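#' One-random-intercept linear mixed model by profiled REML
#'
#' Estimates among-individual and residual variance components for a trait by
#' restricted maximum likelihood, profiling the criterion over the variance
#' ratio `gamma = var_among / var_within` (block-diagonal Woodbury identities,
#' 1-D optimization on log-gamma). On balanced designs the estimates coincide
#' with the closed-form one-way ANOVA moment estimators.
#'
#' @param obs `data.frame` of observations.
#' @param value_col,id_col column names of the trait value and the individual.
#' @param covariates optional character vector of fixed covariates to partial
#'   out before partitioning (adjusted repeatability; default none).
#' @return an object of class `variance_components`: `var_among`,
#'   `var_within`, `grand_mean`, `method`, bookkeeping and the fitted fixed
#'   part (for parametric bootstrap). `var_among` is `NA` with
#'   `flag = "all_singletons"` when no individual has 2 observations.
#' @export
fit_lmm_reml <- function(obs, value_col = "value", id_col = "individual",
                         covariates = NULL) {
  df <- as.data.frame(obs)
  assert_that(all(c(value_col, id_col) %in% names(df)),
              "value/id columns not found")
  df <- df[complete.cases(df[, c(value_col, id_col, covariates)]), ,
           drop = FALSE]
  y <- df[[value_col]]
  g <- factor(df[[id_col]])
  assert_that(nlevels(g) >= 2, "need at least 2 individuals")
  n <- length(y)
  n_i <- as.numeric(table(g))
  gi <- as.integer(g)
  X <- if (is.null(covariates)) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  else model.matrix(stats::reformulate(covariates), df)
  p <- ncol(X)

  base <- list(grand_mean = mean(y), method = "REML", n_obs = n,
               n_groups = nlevels(g), groups = levels(g))
  if (all(n_i == 1)) {
    vc <- c(base, list(var_among = NA_real_, var_within = var(y),
                       gamma = NA_real_, flag = "all_singletons",
                       fixed = list(X = X, gi = gi,
                                    beta = qr.coef(qr(X), y))))
    class(vc) <- "variance_components"
    return(vc)
  }
  if (var(y) == 0) {
    vc <- c(base, list(var_among = 0, var_within = 0, gamma = 0, flag = NULL,
                       fixed = list(X = X, gi = gi,
                                    beta = qr.coef(qr(X), y))))
    class(vc) <- "variance_components"
    return(vc)
  }

  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y * y)
  Xg <- rowsum(X, gi)              # n_groups x p, group sums of X
  yg <- as.numeric(rowsum(y, gi))  # group sums of y

  crit <- function(gamma) {
    ci <- gamma / (1 + gamma * n_i)
    A <- XtX - crossprod(Xg * sqrt(ci))
    Xy <- Xty - crossprod(Xg, ci * yg)
    yy <- yty - sum(ci * yg^2)
    bhat <- solve(A, Xy)
    rss <- yy - sum(bhat * Xy)
    if (rss <= 0) return(Inf)
    sum(log1p(gamma * n_i)) + determinant(A, logarithm = TRUE)$modulus +
      (n - p) * log(rss)
  }
  opt <- optimize(function(lg) crit(exp(lg)), c(-30, 15), tol = 1e-12)
  gamma <- exp(opt$minimum)
  if (crit(0) <= opt$objective) gamma <- 0
  ci <- gamma / (1 + gamma * n_i)
  A <- XtX - crossprod(Xg * sqrt(ci))
  Xy <- Xty - crossprod(Xg, ci * yg)
  bhat <- solve(A, Xy)
  rss <- (yty - sum(ci * yg^2)) - sum(bhat * Xy)
  var_within <- as.numeric(rss / (n - p))
  vc <- c(base, list(var_among = gamma * var_within,
                     var_within = var_within, gamma = gamma, flag = NULL,
                     fixed = list(X = X, gi = gi, beta = as.numeric(bhat))))
  class(vc) <- "variance_components"
  vc
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components (%s): among = %.4g, within = %.4g\n",
              x$method, x$var_among, x$var_within))
  invisible(x)
}

#' Repeatability (intraclass correlation)
#'
#' `Rp = var_among / (var_among + var_within)`, the proportion of total
#' variance accounted for by consistent differences among individuals.
#'
#' @param vc a [fit_lmm_reml()] result (or list with `var_among`,
#'   `var_within`).
#' @return Rp in `[0, 1]`; `NA` with attribute `undefined = TRUE` for the
#'   degenerate 0/0 case.
#' @export
repeatability <- function(vc) {
  tot <- vc$var_among + vc$var_within
  if (is.na(tot)) return(NA_real_)
  if (tot == 0) return(structure(NA_real_, undefined = TRUE))
  vc$var_among / tot
}

#' Coefficient of among-individual variation
#'
#' `CVi = sqrt(var_among) / grand_mean`: the among-individual SD standardized
#' by the trait mean.
#'
#' @param vc a [fit_lmm_reml()] result.
#' @return CVi (>= 0).
#' @export
cvi <- function(vc) {
  if (is.null(vc$grand_mean) || !is.finite(vc$grand_mean) ||
      vc$grand_mean <= 0)
    stop("CVi undefined: trait mean must be positive", call. = FALSE)
  sqrt(vc$var_among) / vc$grand_mean
}

#' Parametric bootstrap confidence interval for a repeatability statistic
#'
#' Simulates datasets from the fitted mixed model (normal random intercepts
#' and residuals at the REML estimates), refits, and returns the percentile
#' 95% interval of the statistic. An undefined statistic on a degenerate
#' resample counts as 0.
#'
#' @param obs observations as in [fit_lmm_reml()].
#' @param statistic `"Rp"`, `"CVi"`, or a function of a
#'   `variance_components` object.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @param value_col,id_col,covariates passed to [fit_lmm_reml()].
#' @return `c(lower, upper)`; attributes `point`, `n_fail`.
#' @export
bootstrap_ci <- function(obs, statistic = "Rp", n_boot = 1000, seed = 1L,
                         value_col = "value", id_col = "individual",
                         covariates = NULL) {
  stat_fn <- if (is.function(statistic)) statistic
  else switch(match.arg(statistic, c("Rp", "CVi")),
              Rp = function(vc) {
                r <- repeatability(vc); if (is.na(r)) 0 else r
              },
              CVi = function(vc) cvi(vc))
  fit <- fit_lmm_reml(obs, value_col, id_col, covariates)
  if (!is.null(fit$flag)) stop("cannot bootstrap: ", fit$flag, call. = FALSE)
  X <- fit$fixed$X; gi <- fit$fixed$gi; beta <- fit$fixed$beta
  mu_hat <- as.numeric(X %*% beta)
  sa <- sqrt(max(fit$var_among, 0)); se <- sqrt(max(fit$var_within, 0))
  df_b <- as.data.frame(obs)
  df_b <- df_b[complete.cases(df_b[, c(value_col, id_col, covariates)]), ,
               drop = FALSE]
  set.seed(derive_seed(seed, 11L))
  vals <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    a <- rnorm(fit$n_groups, 0, sa)
    df_b[[value_col]] <- mu_hat + a[gi] + rnorm(fit$n_obs, 0, se)
    vb <- try(fit_lmm_reml(df_b, value_col, id_col, covariates),
              silent = TRUE)
    if (!inherits(vb, "try-error")) vals[b] <- stat_fn(vb)
  }
  ok <- vals[is.finite(vals)]
  n_fail <- n_boot - length(ok)
  if (n_fail > 0.05 * n_boot)
    warning("more than 5% of bootstrap refits failed; interval widened ",
            "to the resample range")
  ci <- if (n_fail > 0.05 * n_boot && length(ok)) range(ok)
  else quantile(ok, c(0.025, 0.975), names = FALSE)
  structure(ci, point = stat_fn(fit), n_fail = n_fail)
}

#' Population repeatability estimate with bootstrap intervals
#'
#' Convenience wrapper combining [fit_lmm_reml()], [repeatability()],
#' [cvi()] and [bootstrap_ci()].
#'
#' @inheritParams bootstrap_ci
#' @return list of class `repeatability_estimate`: Rp, CVi, their 95% CIs,
#'   sample sizes, `n_boot`, `seed`.
#' @export
estimate_repeatability <- function(obs, value_col = "value",
                                   id_col = "individual", covariates = NULL,
                                   n_boot = 1000, seed = 1L) {
  vc <- fit_lmm_reml(obs, value_col, id_col, covariates)
  rp_ci <- bootstrap_ci(obs, "Rp", n_boot, seed, value_col, id_col, covariates)
  cv_ci <- tryCatch(
    bootstrap_ci(obs, "CVi", n_boot, seed, value_col, id_col, covariates),
    error = function(e) c(NA_real_, NA_real_))
  structure(list(Rp = repeatability(vc),
                 Rp_ci = as.numeric(rp_ci),
                 CVi = tryCatch(cvi(vc), error = function(e) NA_real_),
                 CVi_ci = as.numeric(cv_ci),
                 n_individuals = vc$n_groups, n_obs = vc$n_obs,
                 n_boot = n_boot, seed = seed, vc = vc),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("Rp = %.3f [%.3f, %.3f]  CVi = %.3f [%.3f, %.3f]  (%d ind, %d obs)\n",
              x$Rp, x$Rp_ci[1], x$Rp_ci[2], x$CVi, x$CVi_ci[1], x$CVi_ci[2],
              x$n_individuals, x$n_obs))
  invisible(x)
}

#' Across-period consistency of predictability
#'
#' Repeatability of log-rIIV across period-specific DHGLM fits: is an
#' individual that was relatively predictable in one period similarly
#' predictable in the others? Computed on the log scale (rIIV is an SD, a
#' ratio-scale quantity).
#'
#' @param period_riiv output of [riiv_by_period()] (columns individual,
#'   scope, riiv_km).
#' @param n_boot,seed bootstrap settings.
#' @return a `repeatability_estimate` for log-rIIV.
#' @export
riiv_consistency <- function(period_riiv, n_boot = 1000, seed = 1L) {
  df <- as.data.frame(period_riiv)
  assert_that(length(unique(df$scope)) >= 2,
              "need rIIV from at least 2 periods")
  multi <- names(which(table(df$individual) >= 2))
  assert_that(length(multi) >= 2,
              "need at least 2 individuals measured in 2+ periods")
  df$log_riiv <- log(df$riiv_km)
  estimate_repeatability(df, value_col = "log_riiv", id_col = "individual",
                         n_boot = n_boot, seed = seed)
}
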