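test_that("cohort draws honour degenerate and correlated hyperparameters", {
  cfg0 <- sim_config(n_individuals = 12, tau_u = 0, tau_v = 0, seed = 3)
  coh0 <- simulate_cohort(cfg0)
  expect_equal(coh0$truth$u_i, rep(0, 12))
  expect_equal(coh0$truth$v_i, rep(0, 12))
  juv <- coh0$truth$age_at_tagging == "juvenile"
  expect_equal(unique(coh0$truth$riiv_true[!juv]), exp(cfg0$lambda0))

  cfg <- sim_config(n_individuals = 1e4, nights_per_individual = 1,
                    tau_u = 0.5, tau_v = 0.4, rho = 0.3, seed = 5)
  coh <- simulate_cohort(cfg)
  expect_lt(abs(cor(coh$truth$u_i, coh$truth$v_i) - 0.3), 0.02)
  expect_lt(abs(sd(coh$truth$u_i) - 0.5), 0.02)

  expect_error(sim_config(rho = 1.4), "rho")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(n_individuals = 6, nights_per_individual = 10, seed = 9)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a, b)
  na <- simulate_night_indices(cfg, a$truth)
  nb <- simulate_night_indices(cfg, b$truth)
  expect_identical(na, nb)
  sa <- simulate_survival(a$truth, cfg)
  expect_identical(sa, simulate_survival(b$truth, cfg))
})

test_that("nightly draws converge to the generative moments", {
  # noiseless limit: per-individual means pin down mu + u_i
  s <- sim_indices(n_ind = 10, nights = 50, tau_v = 0, lambda0 = log(1e-4),
                   mu = 5, lambda_age = 0, seed = 2,
                   beta_age = 0, beta_sex = 0)
  m_i <- tapply(s$indices$max_disp_km, s$indices$individual, mean)
  sd_i <- tapply(s$indices$max_disp_km, s$indices$individual, sd)
  expect_lt(max(sd_i), 1e-3)
  truth <- s$cohort$truth
  expect_equal(as.numeric(m_i[truth$individual]),
               5 + truth$u_i, tolerance = 1e-3)

  # group-level dispersion preset: juvenile vs adult residual SDs
  s2 <- sim_indices(n_ind = 120, nights = 200, tau_u = 0.3, tau_v = 0,
                    mu = 6, lambda0 = log(1.23),
                    lambda_age = log(2.25 / 1.23), seed = 4,
                    prop_juvenile = 0.5)
  ind2 <- s2$indices
  cls <- tapply(ind2$age_class, ind2$individual, function(z) z[1])
  pure <- names(cls)[vapply(split(ind2$age_class, ind2$individual),
                            function(z) length(unique(z)) == 1, TRUE)]
  sds <- tapply(ind2$max_disp_km, ind2$individual, sd)[pure]
  expect_equal(unname(mean(sds[cls[pure] == "adult"])), 1.23,
               tolerance = 0.05)
  expect_equal(unname(mean(sds[cls[pure] == "juvenile"])), 2.25,
               tolerance = 0.05)

  # variance algebra: between-individual SD of means
  s3 <- sim_indices(n_ind = 100, nights = 100, tau_u = 0.5, tau_v = 0,
                    mu = 6, lambda0 = 0, lambda_age = 0, seed = 6,
                    beta_age = 0, beta_sex = 0)
  m3a <- tapply(s3$indices$max_disp_km, s3$indices$individual, mean)
  expect_lt(abs(sd(m3a) - sqrt(0.5^2 + 1 / 100)), 0.1)
})

test_that("per-individual SD converges to true rIIV and truncation is rare", {
  # dispersion scale kept clear of the truncation floor, where the Gaussian
  # SD identity holds (resampling shrinks the SD of high-sigma individuals)
  s <- sim_indices(n_ind = 5, nights = 1e4, tau_u = 0.3, tau_v = 0.3,
                   mu = 2.45, lambda0 = log(0.5), lambda_age = 0, seed = 8)
  # relative error of empirical SD vs true rIIV below 5% at 10^4 nights
  truth <- s$cohort$truth
  sds <- tapply(s$indices$max_disp_km, s$indices$individual, sd)
  rel <- abs(sds[truth$individual] - truth$riiv_true) / truth$riiv_true
  expect_lt(max(rel), 0.05)
  expect_lt(attr(s$indices, "truncation_frac"), 0.02)
})

test_that("night tracks are built to the target displacement", {
  cfg <- sim_config(noise_sd_m = 0, seed = 1)
  tr <- simulate_night_track(2.6, cfg, nest = c(1000, 2000),
                             night_start_s = 0, seed = 11)
  expect_equal(nrow(tr), 5850)   # 13 h at 8 s
  d <- sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2) / 1000
  step_km <- cfg$speed_m_s * cfg$fix_interval_s / 1000
  expect_lt(max(d) - 2.6, 1e-9)
  expect_gte(max(d), 2.6 - step_km)
  expect_error(simulate_night_track(-1, cfg), "target displacement")

  # planted stop bouts are recovered by the default stop detector
  cfg2 <- sim_config(seed = 2)  # 5 m noise, 300 s bouts, 5 m radius
  tr2 <- simulate_night_track(2.6, cfg2, seed = 12)
  seg <- segment_moves_stops(tr2, 20, 60)
  planted <- tr2$true_mode == "stop"
  expect_gte(mean(seg$labels[planted] == "stop"), 0.9)
})

test_that("artifact injection is reproducible and leaves clean tracks alone", {
  cfg <- sim_config(seed = 1)
  tr <- simulate_night_track(2, cfg, seed = 3)
  cfg0 <- sim_config(artifact_rates = c(std = 0, speed = 0), seed = 1)
  expect_identical(inject_artifacts(tr, cfg0, seed = 4)[, c("x", "y", "std")],
                   tr[, c("x", "y", "std")])

  cfgr <- sim_config(artifact_rates = c(std = 0.01, speed = 0.01), seed = 1)
  a1 <- inject_artifacts(tr, cfgr, seed = 5)
  a2 <- inject_artifacts(tr, cfgr, seed = 5)
  expect_identical(a1, a2)
  set.seed(5)
  expect_equal(sum(a1$artifact_std), rbinom(1, nrow(tr), 0.01))
  expect_gt(min(a1$std[a1$artifact_std]), 50)
})

test_that("survival generator matches its exponential model", {
  cfg <- sim_config(n_individuals = 400, nights_per_individual = 600,
                    censor_day = 600, seed = 7,
                    hazard = list(baseline = 5e-3, gamma_riiv = 0,
                                  gamma_age = 0.7))
  coh <- simulate_cohort(cfg)
  sv <- simulate_survival(coh$truth, cfg)
  expect_gt(attr(sv, "event_fraction"), 0.5)
  # Cox on the age group recovers the planted log rate ratio
  sv$juv <- as.integer(sv$age_at_tagging == "juvenile")
  fit <- fit_cox(sv, "juv")
  expect_lt(abs(fit$coef[["juv"]] - 0.7), 0.15)

  cfg0 <- sim_config(n_individuals = 20, censor_day = 0, seed = 7)
  coh0 <- simulate_cohort(cfg0)
  sv0 <- simulate_survival(coh0$truth, cfg0)
  expect_equal(sum(sv0$event), 0)
  expect_error(
    simulate_survival(coh0$truth,
                      sim_config(hazard = list(baseline = 0, gamma_riiv = 0,
                                               gamma_age = 0))),
    "baseline")
})

test_that("raw CSV export omits truth labels and round-trips via read_fixes", {
  cfg <- sim_config(n_individuals = 2, nights_per_individual = 2,
                    fix_interval_s = 60, seed = 13)
  sim <- simulate_tracking_data(cfg)
  dir <- withr::local_tempdir()
  paths <- write_sim_csvs(sim, dir)
  hdr <- names(data.table::fread(paths["fixes"], nrows = 1))
  expect_setequal(hdr, c("tag_id", "time_utc_ms", "x_m", "y_m", "std_m"))
  fx <- read_fixes(paths["fixes"])
  expect_equal(nrow(fx), nrow(sim$fixes))
  expect_true(all(diff(fx$time_ms[fx$tag_id == fx$tag_id[1]]) > 0))
})
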