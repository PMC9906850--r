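#' Simulation configuration for a synthetic tracking study
#'
#' Builds the configuration object consumed by every `simulate_*()` function.
#' Defaults emulate the statistical structure of a nocturnal central-place
#' forager cohort tracked by a regional reverse-GPS system: individual nightly
#' max-displacement follows a Gaussian with an individual-specific mean
#' (behavioral type, `mu + u_i`) and an individual-specific residual SD
#' (predictability, `sigma_ij = exp(lambda0 + lambda_age * juvenile + v_i)`),
#' with `(u_i, v_i)` bivariate normal across individuals.
#'
#' @param n_individuals number of tracked individuals.
#' @param nights_per_individual tracked nights per individual; scalar or a
#'   vector of length `n_individuals`.
#' @param fix_interval_s localization interval in seconds.
#' @param night_start_hour,night_end_hour local clock hours bounding a tracking
#'   night (closed at start, open at end).
#' @param utc_offset_h fixed offset of local time from UTC, hours.
#' @param start_date first possible tagging date.
#' @param mu population mean nightly max-displacement, km. Covariate effects
#'   are centered in the generator, so `mu` is also (up to truncation) the
#'   cohort-mean displacement.
#' @param beta_age additive effect of juvenile age class on the mean, km
#'   (juvenile-minus-adult contrast, applied centered).
#' @param beta_sex additive effect of male sex on the mean, km (male-minus-
#'   female contrast, applied centered).
#' @param lambda0 population log residual SD (log-km) for the adult reference.
#' @param lambda_age additive effect of juvenile age class on the log residual
#'   SD.
#' @param tau_u among-individual SD of mean intercepts `u_i`, km.
#' @param tau_v among-individual SD of dispersion intercepts `v_i`, log-km.
#' @param rho correlation between `u_i` and `v_i`.
#' @param noise_sd_m isotropic localization noise SD, meters.
#' @param artifact_rates named fractions `c(std = , speed = )` of fixes turned
#'   into accuracy outliers and speed spikes.
#' @param hazard list with `baseline` (events per day), `gamma_riiv` (log
#'   hazard per km of true rIIV) and `gamma_age` (log hazard for juveniles).
#' @param censor_day administrative censoring horizon, days from tagging.
#' @param trunc_floor_km displacement draws below this floor are resampled.
#' @param speed_m_s flight speed used to build trajectories (free parameter,
#'   not an estimate).
#' @param stop_bouts list with `n`, `duration_s`, `radius_m` describing
#'   perching bouts planted along the outbound leg.
#' @param prop_juvenile fraction of individuals tagged as juveniles.
#' @param area_m `c(width, height)` of the planar study area, meters.
#' @param total_dist_factor,total_dist_lsd nightly total distance is
#'   `max_disp * total_dist_factor * exp(rnorm(1, 0, total_dist_lsd))`.
#' @param n_boxes number of nest boxes in the occupancy table.
#' @param seed integer RNG seed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 74,
                       nights_per_individual = 115,
                       fix_interval_s = 8,
                       night_start_hour = 17,
                       night_end_hour = 6,
                       utc_offset_h = 2,
                       start_date = as.Date("2020-02-01"),
                       mu = 2.45,
                       beta_age = 0.5,
                       beta_sex = 0.3,
                       lambda0 = log(1.23),
                       lambda_age = log(2.25 / 1.23),
                       tau_u = 0.887,
                       tau_v = 0.4,
                       rho = 0.3,
                       noise_sd_m = 5,
                       artifact_rates = c(std = 0.005, speed = 0.002),
                       hazard = list(baseline = 1 / 1000,
                                     gamma_riiv = -0.5,
                                     gamma_age = 0.3),
                       censor_day = 570,
                       trunc_floor_km = 0.05,
                       speed_m_s = 8,
                       stop_bouts = list(n = 3, duration_s = 300, radius_m = 5),
                       prop_juvenile = 0.6,
                       area_m = c(20000, 10000),
                       total_dist_factor = 4.82,
                       total_dist_lsd = 0.3,
                       n_boxes = 120,
                       seed = 1L) {
  cfg <- as.list(environment())
  assert_that(is_count(n_individuals), "n_individuals must be a positive integer")
  assert_that(all(nights_per_individual >= 1) &&
                (length(nights_per_individual) %in% c(1L, n_individuals)),
              "nights_per_individual must be scalar or one value per individual")
  assert_that(fix_interval_s > 0, "fix_interval_s must be > 0")
  assert_that(tau_u >= 0 && tau_v >= 0 && noise_sd_m >= 0,
              "all SDs must be >= 0")
  if (abs(rho) > 1) stop("invalid covariance: |rho| > 1", call. = FALSE)
  assert_that(all(artifact_rates >= 0 & artifact_rates <= 1),
              "artifact rates must lie in [0, 1]")
  assert_that(hazard$baseline >= 0, "hazard baseline must be >= 0")
  assert_that(trunc_floor_km > 0, "truncation floor must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

night_window_s <- function(config) {
  ((24 - config$night_start_hour) + config$night_end_hour) * 3600
}

#' Simulate a tracked cohort with known ground truth
#'
#' Draws per-individual behavioral-type intercepts `u_i` and dispersion
#' intercepts `v_i` from the configured bivariate normal, assigns sex, hatch
#' dates (juveniles transition to adult at their first birthday), tagging
#' dates and nest coordinates.
#'
#' @param config a [sim_config()].
#' @return list with `metadata` (one row per individual: ids, sex, hatch and
#'   tagging dates, nest coordinates, nights tracked) and `truth` (the same
#'   rows plus `u_i`, `v_i` and the individual true rIIV in km, evaluated at
#'   the tagging-age class).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_individuals
  uv <- rbvn(n, config$tau_u, config$tau_v, config$rho)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  juv <- runif(n) < config$prop_juvenile
  tag_start <- config$start_date + sample(0:300, n, replace = TRUE)
  hatch <- as.Date(ifelse(juv, tag_start - round(runif(n, 60, 300)),
                          tag_start - round(runif(n, 400, 2000))),
                   origin = "1970-01-01")
  nights <- rep_len(config$nights_per_individual, n)
  meta <- data.frame(
    individual = sprintf("owl%03d", seq_len(n)),
    tag_id = sprintf("tag%04d", 1000L + seq_len(n)),
    sex = sex,
    hatch_date = hatch,
    tag_start = tag_start,
    age_at_tagging = ifelse(juv, "juvenile", "adult"),
    nest_x = runif(n, 0, config$area_m[1]),
    nest_y = runif(n, 0, config$area_m[2]),
    n_nights = as.integer(nights),
    stringsAsFactors = FALSE
  )
  truth <- meta
  truth$u_i <- uv[, 1]
  truth$v_i <- uv[, 2]
  truth$riiv_true <- exp(config$lambda0 + config$lambda_age * juv + truth$v_i)
  list(metadata = meta, truth = truth)
}

#' Simulate per-night true max-displacement draws (fast generative path)
#'
#' Bypasses trajectory construction: nightly max-displacement is drawn directly
#' from the hierarchical model, `d_ij ~ N(mu + beta_age * juv_ij + beta_sex *
#' male_i + u_i, sigma_ij)` with `sigma_ij = exp(lambda0 + lambda_age * juv_ij
#' + v_i)`. Draws below the truncation floor are resampled (not clipped) so the
#' Gaussian bulk is preserved; the resampled fraction is reported.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element of [simulate_cohort()].
#' @return a `data.frame` with one row per individual-night (individual,
#'   night_date, period, age_class, sex, max_disp_km, total_dist_km,
#'   sigma_true); attribute `truncation_frac` gives the fraction of resampled
#'   draws.
#' @export
simulate_night_indices <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  idx <- rep(seq_len(nrow(truth)), truth$n_nights)
  night_date <- truth$tag_start[idx] +
    unlist(lapply(truth$n_nights, seq_len), use.names = FALSE) - 1L
  juv <- as.integer(night_date < truth$hatch_date[idx] + 365L)
  male <- as.integer(truth$sex[idx] == "M")
  # covariate effects are centered so `mu` is the cohort-mean displacement
  mean_ij <- config$mu + config$beta_age * (juv - 0.5) +
    config$beta_sex * (male - 0.5) + truth$u_i[idx]
  sigma_ij <- exp(config$lambda0 + config$lambda_age * juv + truth$v_i[idx])
  d <- rnorm(length(idx), mean_ij, sigma_ij)
  n_trunc <- 0L
  repeat {
    bad <- which(d < config$trunc_floor_km)
    if (!length(bad)) break
    n_trunc <- n_trunc + length(bad)
    d[bad] <- rnorm(length(bad), mean_ij[bad], sigma_ij[bad])
  }
  total <- d * config$total_dist_factor *
    exp(rnorm(length(d), 0, config$total_dist_lsd))
  per <- assign_period(night_date, with_year = TRUE)
  out <- data.frame(
    individual = truth$individual[idx],
    night_date = night_date,
    period = per$period,
    period_year = per$year,
    age_class = ifelse(juv == 1L, "juvenile", "adult"),
    sex = truth$sex[idx],
    max_disp_km = d,
    total_dist_km = total,
    sigma_true = sigma_ij,
    stringsAsFactors = FALSE
  )
  attr(out, "truncation_frac") <- n_trunc / (length(idx) + n_trunc)
  out
}

#' Simulate one night's trajectory
#'
#' Constructs an out-and-back central-place trajectory: a perch at the nest, an
#' outbound flight to a far point at `target_km` from the nest interleaved with
#' perching bouts, a long perch at the far point, a return flight, and a final
#' perch until the night ends. Fixes are laid down every `fix_interval_s`
#' seconds over the whole night window; isotropic Gaussian localization noise
#' is added afterwards. Ground-truth activity mode is kept in the `true_mode`
#' column (never exported to raw CSV by [write_sim_csvs()]).
#'
#' @param target_km true max-displacement for the night (km, > 0).
#' @param config a [sim_config()].
#' @param nest numeric `c(x, y)` of the roost, meters.
#' @param night_start_s epoch seconds (UTC) of the night start.
#' @param tag_id tag identifier recorded on each fix.
#' @param seed optional seed (defaults to leaving the RNG stream untouched).
#' @return a `data.frame` of fixes: tag_id, time_ms, x, y, std, true_mode.
#' @export
simulate_night_track <- function(target_km, config, nest = c(0, 0),
                                 night_start_s = 0, tag_id = "tag0001",
                                 seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(target_km > 0, "target displacement must be > 0")
  if (!is.null(seed)) set.seed(seed)
  dt <- config$fix_interval_s
  win <- night_window_s(config)
  n_fix <- floor(win / dt)
  if (n_fix < 2) stop("night window shorter than 2 steps", call. = FALSE)
  d_m <- target_km * 1000
  v <- config$speed_m_s
  kb <- config$stop_bouts$n
  bout_dur <- config$stop_bouts$duration_s
  bout_rad <- config$stop_bouts$radius_m
  perch0 <- 600
  far_dur <- 600
  needed <- perch0 + d_m / v + kb * bout_dur + far_dur + d_m / v
  if (needed > win) { perch0 <- 0; far_dur <- 0; kb <- 0
    needed <- 2 * d_m / v }
  if (needed > win)
    stop("night window too short for the requested displacement", call. = FALSE)
  theta <- runif(1, 0, 2 * pi)
  far <- nest + d_m * c(cos(theta), sin(theta))

  # phase table: mode, duration, start/end anchors (stops anchor at `from`)
  leg_t <- d_m / v / (kb + 1)
  frac <- seq(0, 1, length.out = kb + 2)
  phases <- list(list("stop", perch0, nest, nest))
  for (i in seq_len(kb + 1)) {
    a <- nest + frac[i] * (far - nest); b <- nest + frac[i + 1] * (far - nest)
    phases <- c(phases, list(list("move", leg_t, a, b)))
    if (i <= kb) phases <- c(phases, list(list("stop", bout_dur, b, b)))
  }
  phases <- c(phases, list(list("stop", far_dur, far, far)))
  phases <- c(phases, list(list("move", d_m / v, far, nest)))
  used <- sum(vapply(phases, function(p) p[[2]], 0))
  phases <- c(phases, list(list("stop", win - used, nest, nest)))

  t_rel <- (seq_len(n_fix) - 1) * dt
  starts <- cumsum(c(0, vapply(phases, function(p) p[[2]], 0)))
  ph <- findInterval(t_rel, starts, rightmost.closed = FALSE)
  ph[ph > length(phases)] <- length(phases)
  x <- numeric(n_fix); y <- numeric(n_fix); mode <- character(n_fix)
  for (k in seq_along(phases)) {
    sel <- which(ph == k)
    if (!length(sel)) next
    p <- phases[[k]]
    mode[sel] <- p[[1]]
    if (p[[1]] == "move") {
      f <- (t_rel[sel] - starts[k]) / p[[2]]
      x[sel] <- p[[3]][1] + f * (p[[4]][1] - p[[3]][1])
      y[sel] <- p[[3]][2] + f * (p[[4]][2] - p[[3]][2])
    } else {
      r <- bout_rad * sqrt(runif(length(sel)))
      a <- runif(length(sel), 0, 2 * pi)
      x[sel] <- p[[3]][1] + r * cos(a)
      y[sel] <- p[[3]][2] + r * sin(a)
      # keep jitter from exceeding the target displacement
      dd <- dist2d(nest[1], nest[2], x[sel], y[sel])
      over <- dd > d_m & dd > 0
      if (any(over)) {
        sc <- d_m / dd[over]
        x[sel][over] <- nest[1] + (x[sel][over] - nest[1]) * sc
        y[sel][over] <- nest[2] + (y[sel][over] - nest[2]) * sc
      }
    }
  }
  # anchor the night's first fix at the roost so displacement-to-first-fix
  # cannot exceed the target through perch jitter
  x[1] <- nest[1]; y[1] <- nest[2]
  if (config$noise_sd_m > 0) {
    x <- x + rnorm(n_fix, 0, config$noise_sd_m)
    y <- y + rnorm(n_fix, 0, config$noise_sd_m)
  }
  data.frame(
    tag_id = tag_id,
    time_ms = (night_start_s + t_rel) * 1000,
    x = x, y = y,
    std = runif(n_fix, 3, 15),
    true_mode = mode,
    stringsAsFactors = FALSE
  )
}

#' Plant localization artifacts in a clean track
#'
#' Marks a binomially drawn subset of fixes as accuracy outliers (STD drawn
#' above 50 m) and another subset as speed spikes (position displaced so the
#' implied incoming speed exceeds 15 m/s). Ground-truth labels are stored in
#' the `artifact_std` / `artifact_speed` columns so downstream filter recovery
#' is measurable.
#'
#' @param track a track `data.frame` as from [simulate_night_track()].
#' @param config a [sim_config()].
#' @param seed optional seed.
#' @return the track with updated `std`, `x`, `y` and logical artifact labels.
#' @export
inject_artifacts <- function(track, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(track)
  track$artifact_std <- FALSE
  track$artifact_speed <- FALSE
  if (n == 0) return(track)
  r <- config$artifact_rates
  n_std <- rbinom(1, n, r[["std"]])
  if (n_std > 0) {
    i <- sample.int(n, n_std)
    track$std[i] <- 50 + rexp(n_std, 1 / 30)
    track$artifact_std[i] <- TRUE
  }
  if (n > 1) {
    n_sp <- rbinom(1, n - 1, r[["speed"]])
    if (n_sp > 0) {
      i <- sample(2:n, n_sp)
      dt_prev <- (track$time_ms[i] - track$time_ms[i - 1]) / 1000
      shift <- 15 * dt_prev * runif(n_sp, 2, 4)
      a <- runif(n_sp, 0, 2 * pi)
      track$x[i] <- track$x[i] + shift * cos(a)
      track$y[i] <- track$y[i] + shift * sin(a)
      track$artifact_speed[i] <- TRUE
    }
  }
  track
}

#' Simulate survival outcomes from true predictability
#'
#' Event times are exponential with rate `baseline * exp(gamma_riiv * rIIV_i +
#' gamma_age * juvenile_i)`, censored administratively at `censor_day` and at
#' the end of tracking.
#'
#' @param truth the `truth` element of [simulate_cohort()].
#' @param config a [sim_config()].
#' @return `data.frame`: individual, duration_days, event (1 dead, 0 censored)
#'   and the hazard covariates; attribute `event_fraction`.
#' @export
simulate_survival <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$hazard$baseline <= 0)
    stop("hazard baseline must be positive", call. = FALSE)
  set.seed(derive_seed(config$seed, 3L))
  juv <- as.integer(truth$age_at_tagging == "juvenile")
  rate <- config$hazard$baseline *
    exp(config$hazard$gamma_riiv * truth$riiv_true +
          config$hazard$gamma_age * juv)
  t_event <- rexp(nrow(truth), rate)
  horizon <- pmin(config$censor_day, truth$n_nights)
  event <- as.integer(t_event <= horizon)
  out <- data.frame(
    individual = truth$individual,
    duration_days = pmin(t_event, horizon),
    event = event,
    riiv_true = truth$riiv_true,
    age_at_tagging = truth$age_at_tagging,
    sex = truth$sex,
    stringsAsFactors = FALSE
  )
  attr(out, "event_fraction") <- mean(event)
  out
}

#' Simulate a nest-box occupancy table
#'
#' @param config a [sim_config()].
#' @param years calendar years covered.
#' @return `data.frame`: box_id, x, y, year (one row per occupied box-year).
#' @export
simulate_occupancy <- function(config, years = 2020:2021) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 4L))
  n <- config$n_boxes
  bx <- runif(n, 0, config$area_m[1])
  by <- runif(n, 0, config$area_m[2])
  occ <- expand.grid(box_id = seq_len(n), year = years)
  occ$x <- bx[occ$box_id]
  occ$y <- by[occ$box_id]
  occ[runif(nrow(occ)) < 0.6, c("box_id", "x", "y", "year")]
}

#' Simulate the full raw tracking dataset (trajectory path)
#'
#' Generates the cohort, nightly displacement targets, full-resolution
#' trajectories and artifact injection for every individual-night. This is the
#' slow, end-to-end input used to exercise the preprocessing and segmentation
#' stages; use [simulate_night_indices()] for purely statistical tests.
#'
#' @param config a [sim_config()].
#' @return list: `fixes` (data.table of raw fixes incl. hidden truth columns),
#'   `nights` (the night-index truth table), `cohort` (metadata + truth),
#'   `occupancy`.
#' @export
simulate_tracking_data <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- simulate_cohort(config)
  nights <- simulate_night_indices(config, cohort$truth)
  occupancy <- simulate_occupancy(config)
  set.seed(derive_seed(config$seed, 5L))
  nseed <- sample.int(2^31 - 2, nrow(nights))
  meta <- cohort$metadata
  rowi <- match(nights$individual, meta$individual)
  start_s <- as.numeric(nights$night_date) * 86400 +
    config$night_start_hour * 3600 - config$utc_offset_h * 3600
  tracks <- vector("list", nrow(nights))
  for (j in seq_len(nrow(nights))) {
    tr <- simulate_night_track(
      target_km = nights$max_disp_km[j], config = config,
      nest = c(meta$nest_x[rowi[j]], meta$nest_y[rowi[j]]),
      night_start_s = start_s[j], tag_id = meta$tag_id[rowi[j]],
      seed = nseed[j])
    tracks[[j]] <- inject_artifacts(tr, config)
  }
  fixes <- data.table::rbindlist(tracks)
  data.table::setorder(fixes, tag_id, time_ms)
  list(fixes = fixes, nights = nights, cohort = cohort,
       occupancy = occupancy)
}

#' Write simulated raw inputs to CSV plus a ground-truth JSON
#'
#' The raw fix CSV carries only the observable columns (tag_id, time_utc_ms,
#' x_m, y_m, std_m); truth labels go to the JSON sidecar.
#'
#' @param sim output of [simulate_tracking_data()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_sim_csvs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- sim$fixes[, c("tag_id", "time_ms", "x", "y", "std")]
  data.table::setnames(fx, c("tag_id", "time_utc_ms", "x_m", "y_m", "std_m"))
  paths <- c(
    fixes = file.path(dir, "fixes.csv"),
    meta = file.path(dir, "metadata.csv"),
    occupancy = file.path(dir, "occupancy.csv"),
    truth = file.path(dir, "truth.json")
  )
  data.table::fwrite(fx, paths["fixes"])
  data.table::fwrite(sim$cohort$metadata, paths["meta"])
  data.table::fwrite(sim$occupancy, paths["occupancy"])
  truth <- list(
    individuals = sim$cohort$truth,
    night_truth = sim$nights,
    artifact_labels = sim$fixes[, c("tag_id", "time_ms", "artifact_std",
                                    "artifact_speed")],
    truncation_frac = attr(sim$nights, "truncation_frac")
  )
  jsonlite::write_json(truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
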