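#' Segment a night into move and stop bouts
#'
#' A stop is a maximal run of consecutive fixes that all lie within
#' `stop_radius` of the run's running centroid and that lasts at least
#' `stop_min_duration` seconds; every other fix belongs to a move segment.
#' The rule is deterministic and tuned so the radius is well above typical
#' localization accuracy and the duration well above the fix interval.
#'
#' @param track a single night's fixes, time-sorted (`time_ms`, `x`, `y`).
#' @param stop_radius stop radius, meters.
#' @param stop_min_duration minimum stop duration, seconds.
#' @return list: `labels` (per-fix `"move"/"stop"`), `segments` (a
#'   `data.frame`: mode, start, end (fix indices), duration_s, centroid_x,
#'   centroid_y, radius_m — radius only for stops).
#' @export
segment_moves_stops <- function(track, stop_radius = 20,
                                stop_min_duration = 60) {
  n <- nrow(track)
  if (n == 0) return(list(labels = character(0),
                          segments = data.frame()))
  lab <- stop_label_cpp(track$x, track$y, track$time_ms / 1000,
                        stop_radius, stop_min_duration)
  labels <- ifelse(lab > 0, "stop", "move")
  # contiguous runs of equal mode become segments (adjacent moves merge)
  r <- rle(labels)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  t_s <- track$time_ms / 1000
  seg <- data.frame(mode = r$values, start = start, end = end)
  seg$duration_s <- t_s[end] - t_s[start]
  seg$centroid_x <- vapply(seq_len(nrow(seg)),
                           function(i) mean(track$x[start[i]:end[i]]), 0)
  seg$centroid_y <- vapply(seq_len(nrow(seg)),
                           function(i) mean(track$y[start[i]:end[i]]), 0)
  seg$radius_m <- vapply(seq_len(nrow(seg)), function(i) {
    if (seg$mode[i] != "stop") return(NA_real_)
    ii <- start[i]:end[i]
    max(dist2d(seg$centroid_x[i], seg$centroid_y[i], track$x[ii], track$y[ii]))
  }, 0)
  list(labels = labels, segments = seg)
}

#' Nightly maximal displacement
#'
#' Beeline distance from the night's first fix (typically the roost) to the
#' most distant fix of the night, in km.
#'
#' @param track a single night's fixes, time-sorted.
#' @return displacement in km (0 for a single fix).
#' @export
max_displacement <- function(track) {
  n <- nrow(track)
  assert_that(n >= 1, "max_displacement needs at least one fix")
  km(max(dist2d(track$x[1], track$y[1], track$x, track$y)))
}

#' Move-only nightly total distance
#'
#' Sum of consecutive-fix step lengths where both endpoints are labeled
#' `move`; steps bridging a move and a stop are excluded, so localization
#' jitter accumulated while perching does not inflate the estimate.
#'
#' @param track a single night's fixes, time-sorted.
#' @param labels per-fix mode labels from [segment_moves_stops()].
#' @return distance in km (0 when there is no move segment).
#' @export
total_distance <- function(track, labels) {
  n <- nrow(track)
  if (n < 2) return(0)
  both_move <- labels[-n] == "move" & labels[-1] == "move"
  if (!any(both_move)) return(0)
  steps <- dist2d(track$x[-n], track$y[-n], track$x[-1], track$y[-1])
  km(sum(steps[both_move]))
}

#' Build the night-index table and individual-period summaries
#'
#' Runs move/stop segmentation on every retained night and computes the two
#' nightly indices (max-displacement, move-only total distance), then
#' aggregates per individual-period.
#'
#' @param dataset retained fixes with `individual`, `night_date`, `period`,
#'   `period_year` columns (output of [apply_inclusion_rules()]).
#' @param stop_radius,stop_min_duration passed to [segment_moves_stops()].
#' @param metadata optional metadata for age-class assignment.
#' @return list: `nights` (one row per individual-night: indices, n_fixes,
#'   n_stop_fixes, period, covariates) and `summary` (per individual-period
#'   means and night counts).
#' @export
build_index_table <- function(dataset, stop_radius = 20,
                              stop_min_duration = 60, metadata = NULL) {
  df <- as.data.frame(dataset)
  if (nrow(df) == 0) {
    empty <- data.frame(individual = character(0), night_date = as.Date(character(0)),
                        period = character(0), max_disp_km = numeric(0),
                        total_dist_km = numeric(0), n_fixes = integer(0),
                        n_stop_fixes = integer(0))
    return(list(nights = empty, summary = data.frame()))
  }
  key <- paste(df$individual, df$night_date)
  idx <- split(seq_len(nrow(df)), key)
  rows <- lapply(idx, function(ii) {
    tr <- df[ii, , drop = FALSE]
    tr <- tr[order(tr$time_ms), , drop = FALSE]
    seg <- segment_moves_stops(tr, stop_radius, stop_min_duration)
    data.frame(
      individual = tr$individual[1],
      night_date = tr$night_date[1],
      period = tr$period[1] %||% NA_character_,
      period_year = tr$period_year[1] %||% NA_integer_,
      max_disp_km = max_displacement(tr),
      total_dist_km = total_distance(tr, seg$labels),
      n_fixes = nrow(tr),
      n_stop_fixes = sum(seg$labels == "stop"),
      stringsAsFactors = FALSE
    )
  })
  nights <- do.call(rbind, rows)
  rownames(nights) <- NULL
  nights <- nights[order(nights$individual, nights$night_date), ]
  if (!is.null(metadata)) {
    nights$age_class <- assign_age_class(nights$individual,
                                         nights$night_date, metadata)
    nights$sex <- metadata$sex[match(nights$individual, metadata$individual)]
  }
  cell <- interaction(nights$individual, nights$period, nights$period_year,
                      drop = TRUE)
  summary <- data.frame(
    individual = tapply(nights$individual, cell, `[`, 1),
    period = tapply(as.character(nights$period), cell, `[`, 1),
    period_year = as.integer(tapply(nights$period_year, cell, `[`, 1)),
    n_nights = as.integer(table(cell)),
    mean_max_disp_km = as.numeric(tapply(nights$max_disp_km, cell, mean)),
    mean_total_dist_km = as.numeric(tapply(nights$total_dist_km, cell, mean)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  list(nights = nights, summary = summary)
}
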