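#' Specification for the double-hierarchical Gaussian model
#'
#' The model for nightly max-displacement `y_ij` (individual i, night j) is
#' \deqn{y_{ij} = x_{ij}'\beta + u_i + e_{ij}, \quad e_{ij} \sim N(0, \sigma_{ij}^2)}
#' \deqn{\log \sigma_{ij} = w_{ij}'\lambda + v_i}
#' with `(u_i, v_i)` bivariate normal with SDs `tau_u`, `tau_v` and
#' correlation `rho`. `u_i` is the individual's behavioral type (mean-part
#' intercept); `exp(.)` of the dispersion linear predictor plus `v_i` is its
#' residual SD — individuals with large `v_i` are less predictable.
#'
#' Priors are weakly informative: `N(0, 10^2)` on mean fixed effects,
#' `N(0, 5^2)` on dispersion fixed effects, half-normal(2) on `tau_u` and
#' `tau_v`, uniform(-1, 1) on `rho`.
#'
#' @param mean_formula right-hand-side formula for the mean part.
#' @param dispersion_formula right-hand-side formula for the dispersion part.
#' @param response response column name (km).
#' @param log_response model `log(response)` instead (sensitivity mode).
#' @param chains,iter MCMC chains and total iterations per chain (first half
#'   is warmup and discarded).
#' @param min_nights individuals with fewer nights are excluded from the fit.
#' @param seed RNG seed.
#' @return an object of class `dhglm_spec`.
#' @export
dhglm_spec <- function(mean_formula = ~ age_class + sex + period,
                       dispersion_formula = ~ age_class,
                       response = "max_disp_km",
                       log_response = FALSE,
                       chains = 4, iter = 4000,
                       min_nights = 5, seed = 1L) {
  assert_that(chains >= 1 && iter >= 100, "need chains >= 1 and iter >= 100")
  structure(list(mean_formula = mean_formula,
                 dispersion_formula = dispersion_formula,
                 response = response, log_response = log_response,
                 chains = as.integer(chains), iter = as.integer(iter),
                 min_nights = min_nights, seed = as.integer(seed)),
            class = "dhglm_spec")
}

# drop formula terms that are constant in `data` (e.g. single-period subsets)
drop_constant_terms <- function(formula, data) {
  tl <- attr(terms(formula), "term.labels")
  keep <- vapply(tl, function(tm) {
    vars <- all.vars(stats::as.formula(paste("~", tm)))
    all(vars %in% names(data)) &&
      all(vapply(vars, function(v) length(unique(data[[v]])) > 1, TRUE))
  }, TRUE)
  if (all(keep)) return(formula)
  if (!any(keep)) return(~1)
  stats::reformulate(tl[keep])
}

#' Fit the double-hierarchical Gaussian model by MCMC
#'
#' Gibbs updates for the conjugate mean-part blocks (fixed effects and
#' individual intercepts given the current dispersion surface) and adaptive
#' random-walk Metropolis updates for the dispersion fixed effects, the
#' individual dispersion intercepts, and the hyperparameters
#' `(tau_u, tau_v, rho)` (on log / Fisher-z scales). Convergence is assessed
#' by split-R-hat on the hyperparameters; a non-converged fit is returned
#' with `converged = FALSE` and a warning, never silently accepted.
#'
#' @param index_table night-index table with the response, covariate columns
#'   and an `individual` column.
#' @param spec a [dhglm_spec()].
#' @return an object of class `dhglm_fit`: posterior draws, diagnostics,
#'   individual bookkeeping and the spec.
#' @export
fit_dhglm <- function(index_table, spec = dhglm_spec()) {
  stopifnot(inherits(spec, "dhglm_spec"))
  df <- as.data.frame(index_table)
  assert_that(spec$response %in% names(df),
              paste0("response column '", spec$response, "' not found"))
  cnt <- table(df$individual)
  keep_ids <- names(cnt)[cnt >= spec$min_nights]
  assert_that(length(keep_ids) >= 2, "need at least 2 individuals")
  df <- df[df$individual %in% keep_ids, , drop = FALSE]

  mf <- drop_constant_terms(spec$mean_formula, df)
  wf <- drop_constant_terms(spec$dispersion_formula, df)
  X <- model.matrix(mf, df)
  W <- model.matrix(wf, df)
  if (qr(X)$rank < ncol(X)) {
    stop("singular mean design; collinear columns among: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  }
  y <- df[[spec$response]]
  if (spec$log_response) y <- log(y)
  id <- factor(df$individual)
  ind <- levels(id)
  gi <- as.integer(id)
  n_ind <- length(ind)
  n <- length(y)
  p <- ncol(X); q <- ncol(W)
  n_i <- as.numeric(table(gi))
  # per-individual mean dispersion design rows (for back-transformed rIIV)
  Wbar <- apply(W, 2, function(col) tapply(col, gi, mean))
  Wbar <- matrix(Wbar, nrow = n_ind, dimnames = list(ind, colnames(W)))

  warmup <- floor(spec$iter / 2)
  keep_n <- spec$iter - warmup
  run_chain <- function(chain) {
    set.seed(derive_seed(spec$seed, 100L + chain))
    # warm starts from per-individual moments
    ols <- lm.fit(X, y)
    beta <- ols$coefficients
    r0 <- y - X %*% beta
    ubar <- tapply(r0, gi, mean)
    u <- as.numeric(ubar) * 0.8
    sdi <- as.numeric(tapply(r0, gi, sd))
    sdi[!is.finite(sdi) | sdi <= 0] <- sd(r0)
    lam <- c(log(mean(sdi)), rep(0, q - 1))
    v <- as.numeric(log(sdi)) - as.numeric(Wbar %*% lam)
    tau_u <- max(sd(u), 0.05); tau_v <- max(sd(v), 0.05)
    rho <- if (n_ind > 2) max(min(cor(u, v), 0.9), -0.9) else 0
    s_lam <- 0.1; s_v <- 0.3; s_h <- 0.2
    acc <- c(lam = 0, v = 0, h = 0); tries <- 0
    prior_beta_prec <- 1 / 100
    out <- list(beta = matrix(NA_real_, keep_n, p),
                lam = matrix(NA_real_, keep_n, q),
                hyp = matrix(NA_real_, keep_n, 3,
                             dimnames = list(NULL, c("tau_u", "tau_v", "rho"))),
                u = matrix(NA_real_, keep_n, n_ind),
                v = matrix(NA_real_, keep_n, n_ind))
    hyper_lp <- function(lt_u, lt_v, z, u, v) {
      tu <- exp(lt_u); tv <- exp(lt_v); r <- tanh(z)
      sum(log_dbvn(u, v, tu, tv, r)) +
        log_dhalfnorm(tu, 2) + log_dhalfnorm(tv, 2) +
        lt_u + lt_v + log(1 - r^2)
    }
    s_t <- rep(0.5, q); acc_t <- numeric(q)
    s_su <- 0.2; s_sv <- 0.2; acc_s <- numeric(2)
    for (it in seq_len(spec$iter)) {
      g <- as.numeric(W %*% lam)
      log_sig <- g + v[gi]
      wgt <- exp(-2 * log_sig)
      # -- (beta, u) | rest: beta drawn with u marginalized out (Woodbury on
      #    the per-individual compound-symmetry blocks), then u | beta
      #    conjugate. Joint draw by composition avoids the slow ridge between
      #    fixed effects and individual intercepts.
      if (tau_u < 1e-8) { m0 <- rep(0, n_ind); c2 <- 0 }
      else if (tau_v < 1e-8) { m0 <- rep(0, n_ind); c2 <- tau_u^2 }
      else { m0 <- rho * tau_u / tau_v * v; c2 <- tau_u^2 * (1 - rho^2) }
      S0 <- as.numeric(rowsum(wgt, gi))
      Xw <- X * wgt
      ytil <- y - m0[gi]
      XtVX <- crossprod(X, Xw)
      XtVy <- crossprod(X, ytil * wgt)
      if (c2 > 0) {
        f <- c2 / (1 + c2 * S0)
        Xg_w <- rowsum(Xw, gi)                    # n_ind x p
        yg_w <- as.numeric(rowsum(ytil * wgt, gi))
        XtVX <- XtVX - crossprod(Xg_w * sqrt(f))
        XtVy <- XtVy - crossprod(Xg_w, f * yg_w)
      }
      A <- XtVX + diag(prior_beta_prec, p)
      R <- chol(A)
      m <- backsolve(R, backsolve(R, XtVy, transpose = TRUE))
      beta <- as.numeric(m + backsolve(R, rnorm(p)))
      r1 <- y - as.numeric(X %*% beta)
      if (tau_u < 1e-8) {
        u <- rep(0, n_ind)
      } else {
        S1 <- as.numeric(rowsum(r1 * wgt, gi))
        prec <- S0 + 1 / c2
        u <- (S1 + m0 / c2) / prec + rnorm(n_ind) / sqrt(prec)
      }
      resid2 <- (r1 - u[gi])^2
      # -- lambda | rest (random-walk Metropolis)
      ll_lam <- function(l) {
        ls <- as.numeric(W %*% l) + v[gi]
        sum(-ls - 0.5 * resid2 * exp(-2 * ls)) + sum(dnorm(l, 0, 5, log = TRUE))
      }
      lam_p <- lam + s_lam * rnorm(q)
      cur <- ll_lam(lam); prop <- ll_lam(lam_p)
      a_lam <- 0
      if (log(runif(1)) < prop - cur) { lam <- lam_p; a_lam <- 1 }
      # -- v | rest (elementwise random-walk Metropolis)
      g <- as.numeric(W %*% lam)
      a_i <- as.numeric(rowsum(resid2 * exp(-2 * g), gi))
      if (tau_v < 1e-8) {
        v <- rep(0, n_ind); a_v <- 1
      } else {
        if (tau_u < 1e-8) { mv <- rep(0, n_ind); cv2 <- tau_v^2 }
        else { mv <- rho * tau_v / tau_u * u; cv2 <- tau_v^2 * (1 - rho^2) }
        lv <- function(vv) -n_i * vv - 0.5 * a_i * exp(-2 * vv) -
          (vv - mv)^2 / (2 * cv2)
        v_p <- v + s_v * rnorm(n_ind)
        logr <- lv(v_p) - lv(v)
        acc_v <- log(runif(n_ind)) < logr
        v[acc_v] <- v_p[acc_v]
        a_v <- mean(acc_v)
      }
      # -- ridge translation: shift a dispersion fixed effect and compensate
      #    through the v_i (near-invariant likelihood when the covariate is
      #    individual-constant), Metropolis-corrected. Decouples lambda from
      #    the individual dispersion intercepts.
      if (tau_v >= 1e-8) {
        if (tau_u < 1e-8) { mv <- rep(0, n_ind); cv2 <- tau_v^2 }
        else { mv <- rho * tau_v / tau_u * u; cv2 <- tau_v^2 * (1 - rho^2) }
        ll_disp <- function(l, vv) {
          ls <- as.numeric(W %*% l) + vv[gi]
          sum(-ls - 0.5 * resid2 * exp(-2 * ls))
        }
        cur_ll <- ll_disp(lam, v)
        for (j in seq_len(q)) {
          d <- s_t[j] * rnorm(1)
          lam_p <- lam; lam_p[j] <- lam[j] + d
          v_p <- v - d * Wbar[, j]
          lr <- ll_disp(lam_p, v_p) - cur_ll +
            dnorm(lam_p[j], 0, 5, log = TRUE) - dnorm(lam[j], 0, 5, log = TRUE) -
            sum((v_p - mv)^2 - (v - mv)^2) / (2 * cv2)
          if (is.finite(lr) && log(runif(1)) < lr) {
            lam <- lam_p; v <- v_p
            cur_ll <- ll_disp(lam, v)
            acc_t[j] <- acc_t[j] + 1
          }
        }
      }
      # -- (tau_u, tau_v, rho) | u, v (joint random-walk Metropolis)
      a_h <- 0
      if (tau_u >= 1e-8 || tau_v >= 1e-8) {
        cur_t <- c(log(max(tau_u, 1e-12)), log(max(tau_v, 1e-12)), atanh(rho))
        prop_t <- cur_t + s_h * rnorm(3)
        lr <- hyper_lp(prop_t[1], prop_t[2], prop_t[3], u, v) -
          hyper_lp(cur_t[1], cur_t[2], cur_t[3], u, v)
        if (is.finite(lr) && log(runif(1)) < lr) {
          tau_u <- exp(prop_t[1]); tau_v <- exp(prop_t[2])
          rho <- tanh(prop_t[3]); a_h <- 1
        }
      }
      # -- scale interweaving: jointly rescale (u, tau_u) and (v, tau_v) to
      #    traverse the funnel between random effects and their SDs; the
      #    standardized effects are invariant, so the prior ratio collapses
      #    to the half-normal on the SD plus a single Jacobian term
      if (tau_u >= 1e-8) {
        g2 <- as.numeric(W %*% lam)
        wgt2 <- exp(-2 * (g2 + v[gi]))
        S0b <- as.numeric(rowsum(wgt2, gi))
        S1b <- as.numeric(rowsum(r1 * wgt2, gi))
        eps <- s_su * rnorm(1); sc <- exp(eps)
        u_p <- sc * u
        lld <- -0.5 * sum((u_p^2 - u^2) * S0b - 2 * (u_p - u) * S1b)
        lr <- lld + eps + log_dhalfnorm(sc * tau_u, 2) -
          log_dhalfnorm(tau_u, 2)
        if (is.finite(lr) && log(runif(1)) < lr) {
          u <- u_p; tau_u <- sc * tau_u; acc_s[1] <- acc_s[1] + 1
        }
      }
      if (tau_v >= 1e-8) {
        g2 <- as.numeric(W %*% lam)
        resid2b <- (r1 - u[gi])^2
        a_ib <- as.numeric(rowsum(resid2b * exp(-2 * g2), gi))
        eps <- s_sv * rnorm(1); sc <- exp(eps)
        v_p <- sc * v
        lld <- sum(-n_i * (v_p - v) -
                     0.5 * a_ib * (exp(-2 * v_p) - exp(-2 * v)))
        lr <- lld + eps + log_dhalfnorm(sc * tau_v, 2) -
          log_dhalfnorm(tau_v, 2)
        if (is.finite(lr) && log(runif(1)) < lr) {
          v <- v_p; tau_v <- sc * tau_v; acc_s[2] <- acc_s[2] + 1
        }
      }
      # adapt proposal scales during warmup
      acc <- acc + c(a_lam, a_v, a_h); tries <- tries + 1
      if (it <= warmup && it %% 50 == 0) {
        rate <- acc / tries
        s_lam <- s_lam * exp(rate[1] - 0.3)
        s_v <- s_v * exp(rate[2] - 0.44)
        s_h <- s_h * exp(rate[3] - 0.3)
        s_t <- s_t * exp(acc_t / tries - 0.3)
        s_su <- s_su * exp(acc_s[1] / tries - 0.44)
        s_sv <- s_sv * exp(acc_s[2] / tries - 0.44)
        acc[] <- 0; acc_t[] <- 0; acc_s[] <- 0; tries <- 0
      }
      if (it > warmup) {
        k <- it - warmup
        out$beta[k, ] <- beta; out$lam[k, ] <- lam
        out$hyp[k, ] <- c(tau_u, tau_v, rho)
        out$u[k, ] <- u; out$v[k, ] <- v
      }
    }
    out
  }
  chains <- lapply(seq_len(spec$chains), run_chain)

  bind <- function(el) do.call(rbind, lapply(chains, `[[`, el))
  draws <- list(beta = bind("beta"), lam = bind("lam"), hyp = bind("hyp"),
                u = bind("u"), v = bind("v"))
  colnames(draws$beta) <- colnames(X); colnames(draws$lam) <- colnames(W)
  colnames(draws$u) <- ind; colnames(draws$v) <- ind
  chain_of <- rep(seq_len(spec$chains), each = keep_n)

  mat_by_chain <- function(x) matrix(x, nrow = keep_n, ncol = spec$chains)
  diag_pars <- cbind(mu = draws$beta[, 1], lambda0 = draws$lam[, 1],
                     draws$hyp)
  rhat <- apply(diag_pars, 2, function(col) split_rhat(mat_by_chain(col)))
  ess <- apply(diag_pars, 2, function(col) {
    ac <- acf(col, lag.max = min(100, keep_n - 1), plot = FALSE)$acf[-1]
    first_neg <- which(ac < 0)[1]
    k <- if (is.na(first_neg)) length(ac) else max(1, first_neg - 1)
    length(col) / (1 + 2 * sum(ac[seq_len(k)], na.rm = TRUE))
  })
  converged <- all(is.finite(rhat)) && all(rhat < 1.05)
  if (!converged)
    warning("DHGLM did not converge (max split-Rhat = ",
            round(max(rhat, na.rm = TRUE), 3), "); fit flagged")
  structure(list(draws = draws, chain = chain_of, individuals = ind,
                 n_nights = setNames(as.integer(n_i), ind), Wbar = Wbar,
                 mean_terms = colnames(X), disp_terms = colnames(W),
                 rhat = rhat, ess = ess, converged = converged,
                 spec = spec, n_obs = n),
            class = "dhglm_fit")
}

#' @export
print.dhglm_fit <- function(x, ...) {
  cat("DHGLM fit:", length(x$individuals), "individuals,", x$n_obs,
      "nights\n")
  hyp <- colMeans(x$draws$hyp)
  cat(sprintf("  tau_u = %.3f  tau_v = %.3f  rho = %.3f\n",
              hyp[1], hyp[2], hyp[3]))
  cat(sprintf("  max split-Rhat = %.3f  converged = %s\n",
              max(x$rhat, na.rm = TRUE), x$converged))
  invisible(x)
}

#' Extract individual predictability (rIIV) from a DHGLM fit
#'
#' rIIV for individual i is the posterior mean of the back-transformed
#' residual SD `exp(wbar_i' lambda + v_i)` (km), where `wbar_i` averages the
#' individual's dispersion covariates; the 95% credible interval comes from
#' the same draws. Low rIIV = high predictability.
#'
#' @param fit a [fit_dhglm()] result.
#' @param scope label recorded in the output (e.g. `"overall"` or a period).
#' @return `data.frame` sorted by rIIV: individual, scope, riiv_km, ci_low,
#'   ci_high, n_nights.
#' @export
extract_riiv <- function(fit, scope = "overall") {
  stopifnot(inherits(fit, "dhglm_fit"))
  lin <- fit$draws$lam %*% t(fit$Wbar) + fit$draws$v    # draws x individuals
  rv <- exp(lin)
  out <- data.frame(
    individual = fit$individuals,
    scope = scope,
    riiv_km = colMeans(rv),
    ci_low = apply(rv, 2, quantile, 0.025),
    ci_high = apply(rv, 2, quantile, 0.975),
    n_nights = as.integer(fit$n_nights[fit$individuals]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$riiv_km, out$individual), ]
  rownames(out) <- NULL
  out
}

#' Period-specific predictability
#'
#' Refits the DHGLM independently within each period cell (period label plus
#' keyed year) and emits per-individual-period rIIV for the consistency /
#' repeatability stage.
#'
#' @param index_table night-index table (see [fit_dhglm()]).
#' @param spec a [dhglm_spec()].
#' @param min_individuals period cells with fewer individuals are skipped with
#'   a warning.
#' @param by_year if `FALSE`, pool years so cells are P1/P2/P3 labels only.
#' @return stacked `data.frame` of [extract_riiv()] tables, scope =
#'   period cell.
#' @export
riiv_by_period <- function(index_table, spec = dhglm_spec(),
                           min_individuals = 2, by_year = TRUE) {
  df <- as.data.frame(index_table)
  assert_that("period" %in% names(df), "index_table needs a period column")
  cell <- if (by_year && "period_year" %in% names(df))
    paste0(df$period_year, "-", df$period) else df$period
  out <- list()
  for (cl in sort(unique(cell))) {
    sub <- df[cell == cl, , drop = FALSE]
    n_ok <- sum(table(sub$individual) >= spec$min_nights)
    if (n_ok < min_individuals) {
      warning("period ", cl, " skipped: fewer than ", min_individuals,
              " individuals with enough nights")
      next
    }
    fit <- fit_dhglm(sub, spec)
    out[[cl]] <- extract_riiv(fit, scope = cl)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
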