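test_that("stop-location thinning keeps evenly spaced perch fixes", {
  # a 1-h stationary stop sampled at 8 s thins to t = 0, 600, ..., 3600
  d <- as.numeric(as.Date("2021-06-10"))
  t_s <- d * 86400 + 17 * 3600 + seq(0, 3600, by = 8) - 2 * 3600
  ds <- data.frame(individual = "a", night_date = as.Date("2021-06-10"),
                   period = "P2", period_year = 2021L,
                   time_ms = t_s * 1000, x = 0, y = 0, std = 5)
  pts <- stop_locations(ds, min_points = 1)
  expect_equal(nrow(pts[[1]]), 7)
  expect_equal(pts[[1]]$time_s - pts[[1]]$time_s[1], seq(0, 3600, by = 600))

  # thinning twice changes nothing (idempotence via the same interval)
  ds2 <- ds[(ds$time_ms / 1000) %in% pts[[1]]$time_s, ]
  pts2 <- stop_locations(ds2, min_points = 1, stop_min_duration = 0)
  expect_equal(pts2[[1]]$time_s, pts[[1]]$time_s)

  # an all-move night contributes nothing
  dm <- ds
  dm$x <- seq(0, by = 64, length.out = nrow(dm))
  expect_length(stop_locations(dm, min_points = 1), 0)
})

test_that("autocorrelation timescale hits the floor for white noise and
           recovers an Ornstein-Uhlenbeck truth", {
  set.seed(2)
  iid <- data.frame(x = rnorm(500, 0, 100), y = rnorm(500, 0, 100),
                    time_s = seq(0, by = 600, length.out = 500))
  expect_equal(fit_position_autocorrelation(iid), 600)

  # OU with tau = 3600 s sampled at 600 s, two independent axes
  sim_ou <- function(n, tau, dt, seed) {
    set.seed(seed)
    phi <- exp(-dt / tau)
    z <- numeric(n)
    for (i in 2:n) z[i] <- phi * z[i - 1] + rnorm(1, 0, sqrt(1 - phi^2))
    z
  }
  ou <- data.frame(x = 400 * sim_ou(3000, 3600, 600, 4),
                   y = 400 * sim_ou(3000, 3600, 600, 5),
                   time_s = seq(0, by = 600, length.out = 3000))
  tau_hat <- fit_position_autocorrelation(ou)
  expect_lt(abs(tau_hat / 3600 - 1), 0.25)

  # time reversal leaves the estimate unchanged
  rev_ou <- ou[nrow(ou):1, ]
  rev_ou$time_s <- sort(max(ou$time_s) - rev_ou$time_s)
  expect_equal(fit_position_autocorrelation(rev_ou), tau_hat,
               tolerance = 1e-9)

  # a non-decaying correlation profile (steady drift) caps at span/4
  nn <- 2000
  drift <- data.frame(x = seq(0, 5e4, length.out = nn) + rnorm(nn, 0, 5),
                      y = seq(0, -3e4, length.out = nn) + rnorm(nn, 0, 5),
                      time_s = seq(0, by = 600, length.out = nn))
  expect_warning(tau_d <- fit_position_autocorrelation(drift),
                 "non-decaying")
  expect_equal(tau_d, diff(range(drift$time_s)) / 4)
})

test_that("kernel home range matches the Gaussian closed form", {
  set.seed(6)
  pts <- data.frame(x = rnorm(5000, 0, 1000), y = rnorm(5000, 0, 1000),
                    time_s = seq(0, by = 600, length.out = 5000))
  hr <- kde_home_range(pts, tau_pos = 600)
  truth <- pi * qchisq(0.95, 2)     # 18.82 km2 at sigma = 1 km
  expect_lt(abs(hr$area_km2 / truth - 1), 0.10)
  expect_equal(unname(hr$center["x"]), mean(pts$x))
  expect_lte(hr$n_eff, hr$n_points)

  # isopleth monotone in level
  hr50 <- kde_home_range(pts, tau_pos = 600, level = 0.50)
  expect_lt(hr50$area_km2, hr$area_km2)

  # translation and rotation invariance within grid discretization
  th <- 0.7
  rot <- data.frame(x = cos(th) * pts$x - sin(th) * pts$y + 5e4,
                    y = sin(th) * pts$x + cos(th) * pts$y - 2e4,
                    time_s = pts$time_s)
  hr_rot <- kde_home_range(rot, tau_pos = 600)
  expect_lt(abs(hr_rot$area_km2 / hr$area_km2 - 1), 0.02)

  # N_eff decreases in tau_pos and the area responds to the wider bandwidth
  hr_slow <- kde_home_range(pts, tau_pos = 6000)
  expect_lt(hr_slow$n_eff, hr$n_eff)
  expect_gt(hr_slow$area_km2, hr$area_km2)

  expect_error(kde_home_range(data.frame(x = rep(1, 50), y = rep(2, 50),
                                         time_s = 1:50), 600),
               "degenerate")
})

test_that("correlated points are handled by the effective sample size", {
  # OU positions: the N_eff-adjusted area stays near the iid-equivalent
  sim_ou <- function(n, tau, dt, seed) {
    set.seed(seed)
    phi <- exp(-dt / tau)
    z <- numeric(n)
    for (i in 2:n) z[i] <- phi * z[i - 1] + rnorm(1, 0, sqrt(1 - phi^2))
    z
  }
  n <- 4320  # 30 days at 10-min sampling
  ou <- data.frame(x = 1000 * sim_ou(n, 3600, 600, 8),
                   y = 1000 * sim_ou(n, 3600, 600, 9),
                   time_s = seq(0, by = 600, length.out = n))
  tau_hat <- fit_position_autocorrelation(ou)
  hr <- kde_home_range(ou, tau_hat)
  truth <- pi * qchisq(0.95, 2)
  expect_lt(abs(hr$area_km2 / truth - 1), 0.20)
})

test_that("density index counts occupied boxes on a closed disk by year", {
  centers <- data.frame(individual = "a", period = "P1", period_year = 2021L,
                        center_x = 0, center_y = 0)
  expect_equal(density_index(centers,
                             data.frame(x = numeric(0), y = numeric(0),
                                        year = integer(0)))$density, 0L)
  occ <- data.frame(
    x = c(100, 1700, 500, -800, 3000, 900),
    y = c(0, 0, 400, 200, 0, -100),
    year = c(2021, 2021, 2021, 2021, 2021, 2020))
  out <- density_index(centers, occ)
  # three strictly inside + one at exactly 1.7 km (closed disk); the distant
  # box and the wrong-year box are excluded
  expect_equal(out$density, 4L)
})
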