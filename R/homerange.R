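#' Stop-mode locations thinned for home-range estimation
#'
#' Pools the stop-mode fixes of every night in an individual-period cell and
#' thins them to at least `subsample_interval` seconds apart (greedy, per
#' night), mirroring the practice of estimating home range from perch/rest
#' locations at a coarse interval rather than from flight fixes.
#'
#' @param dataset retained fixes with `individual`, `night_date`, `period`,
#'   `period_year` columns.
#' @param subsample_interval minimum spacing, seconds.
#' @param stop_radius,stop_min_duration passed to [segment_moves_stops()].
#' @param min_points cells with fewer thinned points are skipped (logged via
#'   a message), mirroring exclusion of non-converging individuals.
#' @return named list (one element per `individual|period|year` cell) of
#'   `data.frame`s with `time_s`, `x`, `y`.
#' @export
stop_locations <- function(dataset, subsample_interval = 600,
                           stop_radius = 20, stop_min_duration = 60,
                           min_points = 30) {
  df <- as.data.frame(dataset)
  key <- paste(df$individual, df$night_date)
  idx <- split(seq_len(nrow(df)), key)
  stops <- lapply(idx, function(ii) {
    tr <- df[ii, , drop = FALSE]
    tr <- tr[order(tr$time_ms), , drop = FALSE]
    seg <- segment_moves_stops(tr, stop_radius, stop_min_duration)
    tr[seg$labels == "stop", , drop = FALSE]
  })
  sdf <- do.call(rbind, stops)
  if (is.null(sdf) || nrow(sdf) == 0) return(list())
  cell <- paste(sdf$individual, sdf$period, sdf$period_year, sep = "|")
  out <- list()
  for (cl in unique(cell)) {
    sub <- sdf[cell == cl, , drop = FALSE]
    sub <- sub[order(sub$time_ms), , drop = FALSE]
    night_grp <- as.integer(factor(paste(sub$night_date)))
    keep <- thin_times_cpp(sub$time_ms / 1000, night_grp, subsample_interval)
    pts <- data.frame(time_s = sub$time_ms[keep] / 1000,
                      x = sub$x[keep], y = sub$y[keep])
    if (nrow(pts) < min_points) {
      message("cell ", cl, " skipped: only ", nrow(pts),
              " thinned stop points (< ", min_points, ")")
      next
    }
    out[[cl]] <- pts
  }
  out
}

#' Positional autocorrelation timescale
#'
#' Fits an exponential decay `r(k) = exp(-k dt / tau)` to the empirical
#' lagged autocorrelation of each coordinate axis by least squares and
#' averages the axes; `tau` is floored at the (median) sampling interval. A
#' non-decaying correlation profile falls back to a quarter of the time span,
#' with a warning.
#'
#' @param points `data.frame` with `time_s`, `x`, `y`, near-regular spacing.
#' @param max_lag largest lag (in steps) entering the fit.
#' @return `tau_pos` in seconds.
#' @export
fit_position_autocorrelation <- function(points, max_lag = 50) {
  n <- nrow(points)
  assert_that(n >= 30, "need at least 30 timed points")
  dt <- median(diff(points$time_s))
  span <- diff(range(points$time_s))
  K <- max(2L, min(max_lag, floor(n / 4)))
  lag_r <- function(z) {
    z <- z - mean(z)
    v <- sum(z^2)
    vapply(seq_len(K), function(k)
      sum(z[seq_len(n - k)] * z[(k + 1):n]) / v, 0)
  }
  fit_tau <- function(r) {
    # least squares always has a solution: uncorrelated axes push tau to the
    # lower bound (later floored at dt), persistent correlation pushes it up
    sse <- function(tau) sum((r - exp(-seq_len(K) * dt / tau))^2)
    optimize(sse, c(dt / 10, span))$minimum
  }
  tau <- mean(c(fit_tau(lag_r(points$x)), fit_tau(lag_r(points$y))))
  if (tau > span / 4) {
    warning("non-decaying position autocorrelation; tau set to span/4")
    tau <- span / 4
  }
  max(tau, dt)
}

#' Autocorrelation-adjusted kernel home range
#'
#' A simplified autocorrelation-corrected kernel density home range: the
#' kernel reference bandwidth is computed from the effective sample size
#' `N_eff = min(n, 1 + T_span / (2 tau_pos))` rather than the raw point count
#' (serially correlated points carry less information, so the kernel must
#' smooth more), and the area is the smallest set of 512 x 512 grid cells
#' containing `level` probability mass. This replaces full autocorrelated
#' kernel density machinery (variogram model selection, optimal weights) by
#' its core correction; the simplification is recorded in the output.
#'
#' @param points `data.frame` with `x`, `y` (meters) and `time_s`.
#' @param tau_pos autocorrelation timescale, seconds (see
#'   [fit_position_autocorrelation()]).
#' @param level isopleth probability level.
#' @param gridsize grid cells per axis.
#' @return list of class `home_range_estimate`: `area_km2`, `center` (mean of
#'   the points), `n_points`, `n_eff`, `bandwidth_m` (per axis), `tau_pos_s`,
#'   `level`, `grid` parameters, `estimator = "neff-adjusted-kde"`.
#' @export
kde_home_range <- function(points, tau_pos, level = 0.95, gridsize = 512) {
  n <- nrow(points)
  assert_that(n >= 30, "need at least 30 points")
  if (sd(points$x) == 0 || sd(points$y) == 0 ||
      abs(cor(points$x, points$y)) > 0.9999)
    stop("degenerate (collinear or identical) points", call. = FALSE)
  t_span <- diff(range(points$time_s))
  n_eff <- min(n, 1 + t_span / (2 * tau_pos))
  h <- c(sd(points$x), sd(points$y)) * n_eff^(-1 / 6)
  rx <- range(points$x) + c(-3, 3) * h[1]
  ry <- range(points$y) + c(-3, 3) * h[2]
  kd <- KernSmooth::bkde2D(cbind(points$x, points$y), bandwidth = h,
                           gridsize = c(gridsize, gridsize),
                           range.x = list(rx, ry))
  dx <- diff(kd$x1[1:2]); dy <- diff(kd$x2[1:2])
  pmass <- kd$fhat * dx * dy
  pmass <- pmass / sum(pmass)
  ord <- sort(as.numeric(pmass), decreasing = TRUE)
  n_cells <- which(cumsum(ord) >= level)[1]
  structure(list(
    area_km2 = n_cells * dx * dy / 1e6,
    center = c(x = mean(points$x), y = mean(points$y)),
    n_points = n, n_eff = n_eff, bandwidth_m = h, tau_pos_s = tau_pos,
    level = level,
    grid = list(gridsize = gridsize, dx = dx, dy = dy, pad_bandwidths = 3),
    estimator = "neff-adjusted-kde"
  ), class = "home_range_estimate")
}

#' @export
print.home_range_estimate <- function(x, ...) {
  cat(sprintf("Home range (%s, %g%% isopleth): %.2f km2 (n = %d, N_eff = %.0f)\n",
              x$estimator, 100 * x$level, x$area_km2, x$n_points, x$n_eff))
  invisible(x)
}

#' Home ranges for every individual-period cell
#'
#' @param stop_pts output of [stop_locations()].
#' @param level isopleth level.
#' @return `data.frame`: individual, period, period_year, area_km2, center_x,
#'   center_y, n_points, n_eff, tau_pos_s.
#' @export
home_range_table <- function(stop_pts, level = 0.95) {
  rows <- lapply(names(stop_pts), function(cl) {
    pts <- stop_pts[[cl]]
    parts <- strsplit(cl, "|", fixed = TRUE)[[1]]
    tau <- tryCatch(fit_position_autocorrelation(pts),
                    warning = function(w) diff(range(pts$time_s)) / 4)
    hr <- tryCatch(kde_home_range(pts, tau, level), error = function(e) NULL)
    if (is.null(hr)) return(NULL)
    data.frame(individual = parts[1], period = parts[2],
               period_year = as.integer(parts[3]),
               area_km2 = hr$area_km2, center_x = hr$center[1],
               center_y = hr$center[2], n_points = hr$n_points,
               n_eff = hr$n_eff, tau_pos_s = tau,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Occupied nest-box density around home-range centers
#'
#' Counts occupied boxes within a closed disk of `radius_m` of each
#' home-range center, matched to the cell's keyed year. This density index is
#' independent of the tracking effort itself.
#'
#' @param hr_centers `data.frame` with `individual`, `period`, `period_year`,
#'   `center_x`, `center_y`.
#' @param occupancy `data.frame` with `x`, `y`, `year` (one row per occupied
#'   box-year).
#' @param radius_m disk radius, meters (default the median home-range
#'   radius of the study system, 1.7 km).
#' @return `hr_centers` with an integer `density` column.
#' @export
density_index <- function(hr_centers, occupancy, radius_m = 1700) {
  out <- as.data.frame(hr_centers)
  out$density <- vapply(seq_len(nrow(out)), function(i) {
    occ <- occupancy[occupancy$year == out$period_year[i], , drop = FALSE]
    if (!nrow(occ)) return(0L)
    d <- dist2d(out$center_x[i], out$center_y[i], occ$x, occ$y)
    sum(d <= radius_m)
  }, 0L)
  out
}
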