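# shared fixture builders; everything is generated in code at test time

# a minimal fix table at constant position (speeds are zero)
toy_fixes <- function(stds, dt_s = 10, tag = "tagA") {
  data.frame(tag_id = tag,
             time_ms = seq_along(stds) * dt_s * 1000,
             x = 0, y = 0, std = stds,
             stringsAsFactors = FALSE)
}

# a track from explicit coordinates, evenly spaced in time
toy_track <- function(x, y, dt_s = 8, t0_s = 0) {
  data.frame(tag_id = "tagA",
             time_ms = (t0_s + (seq_along(x) - 1) * dt_s) * 1000,
             x = x, y = y, std = 5,
             stringsAsFactors = FALSE)
}

# balanced one-way data with known variance components; `exact = TRUE`
# rescales the realized effects to the target sample variances so the
# calibration is not dominated by Monte-Carlo error in the draw itself
balanced_oneway <- function(n_groups, n_per, var_among, var_within,
                            mean = 0, seed = 1, exact = FALSE) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = n_per)
  a <- rnorm(n_groups, 0, sqrt(var_among))
  e <- rnorm(length(g), 0, sqrt(var_within))
  if (exact) {
    a <- (a - mean(a)) / sd(a) * sqrt(var_among)
    e <- (e - mean(e)) / sd(e) * sqrt(var_within)
  }
  data.frame(individual = g, value = mean + a[g] + e)
}

# nightly-index table drawn directly from the hierarchical model
sim_indices <- function(n_ind = 30, nights = 60, tau_u = 0.5, tau_v = 0.4,
                        rho = 0.3, mu = 2.45, lambda0 = log(0.5),
                        lambda_age = 0, seed = 1, ...) {
  cfg <- sim_config(n_individuals = n_ind, nights_per_individual = nights,
                    tau_u = tau_u, tau_v = tau_v, rho = rho, mu = mu,
                    lambda0 = lambda0, lambda_age = lambda_age,
                    seed = seed, ...)
  coh <- simulate_cohort(cfg)
  list(config = cfg, cohort = coh,
       indices = simulate_night_indices(cfg, coh$truth))
}

# exponential two-group survival records with known log rate ratio
two_group_surv <- function(n, log_rr = 0.7, base_rate = 0.05,
                           cens_rate = 0.01, seed = 1) {
  set.seed(seed)
  grp <- rbinom(n, 1, 0.5)
  tt <- rexp(n, base_rate * exp(log_rr * grp))
  cens <- rexp(n, cens_rate)
  data.frame(duration_days = pmin(tt, cens),
             event = as.integer(tt <= cens), group = grp)
}

# brute-force Cox partial likelihood (Breslow) for oracle comparisons
brute_cox_loglik <- function(beta, time, status, X) {
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (t in unique(time[status == 1])) {
    di <- which(time == t & status == 1)
    rs <- which(time >= t)
    ll <- ll + sum(eta[di]) - length(di) * log(sum(exp(eta[rs])))
  }
  ll
}
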