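#' Read a raw fix table from CSV
#'
#' Reads, types, de-duplicates and time-sorts localization fixes. Duplicate
#' `(tag, time)` rows collapse to the first occurrence.
#'
#' @param path CSV file path.
#' @param columns named character vector mapping the internal names `tag_id`,
#'   `time_ms`, `x`, `y`, `std` to the file's column names.
#' @return a `data.table` with columns tag_id (character), time_ms (numeric,
#'   UTC epoch milliseconds), x, y (meters), std (meters).
#' @export
read_fixes <- function(path,
                       columns = c(tag_id = "tag_id", time_ms = "time_utc_ms",
                                   x = "x_m", y = "y_m", std = "std_m")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  missing_cols <- setdiff(unname(columns), names(dt))
  if (length(missing_cols))
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dt <- dt[, unname(columns), with = FALSE]
  data.table::setnames(dt, names(columns))
  dt[, `:=`(tag_id = as.character(tag_id), time_ms = as.numeric(time_ms),
            x = as.numeric(x), y = as.numeric(y), std = as.numeric(std))]
  bad <- which(!is.finite(dt$time_ms))
  if (length(bad)) {
    warning(length(bad), " rows with unparseable time dropped (first at row ",
            bad[1], ")")
    dt <- dt[-bad]
  }
  data.table::setorder(dt, tag_id, time_ms)
  dt <- dt[!duplicated(dt[, c("tag_id", "time_ms")])]
  dt[]
}

#' Quality-filter fixes by accuracy and speed
#'
#' Two sequential filters: (1) drop fixes whose localization accuracy estimate
#' exceeds `std_max`; (2) a forward sweep per tag that drops any fix whose
#' straight-line speed from the last retained fix exceeds `speed_max`
#' (recomputed against the previous retained fix, so spikes cannot shield each
#' other). The output is always a subset of the input and the filter is
#' idempotent.
#'
#' @param fixes a fix table (as from [read_fixes()]), time-sorted per tag.
#' @param std_max accuracy threshold, meters.
#' @param speed_max speed threshold, m/s.
#' @return the retained fixes; attribute `stage_counts` holds the number
#'   removed by each filter.
#' @export
filter_fixes <- function(fixes, std_max = 50, speed_max = 15) {
  fixes <- as.data.frame(fixes)
  n0 <- nrow(fixes)
  keep_std <- !(fixes$std > std_max)
  f1 <- fixes[keep_std, , drop = FALSE]
  if (nrow(f1) > 0) {
    grp <- as.integer(factor(f1$tag_id, levels = unique(f1$tag_id)))
    keep_sp <- speed_filter_cpp(f1$x, f1$y, f1$time_ms / 1000, grp, speed_max)
  } else keep_sp <- logical(0)
  out <- f1[keep_sp, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage_counts") <- c(std = n0 - nrow(f1),
                                 speed = nrow(f1) - nrow(out))
  out
}

local_seconds <- function(time_ms, utc_offset_h) {
  time_ms / 1000 + utc_offset_h * 3600
}

#' Segment fixes into tracking nights
#'
#' A night spans one evening (closed at `start_hour`:00:00 local) to the next
#' morning (open at `end_hour`:00:00 local) and is labeled by the evening's
#' calendar date. Daytime fixes are dropped. Local time is UTC plus a fixed
#' offset; no daylight-saving handling.
#'
#' @param fixes a filtered fix table.
#' @param start_hour,end_hour local clock hours bounding the night.
#' @param utc_offset_h fixed UTC offset in hours.
#' @return the nocturnal fixes with an added `night_date` (Date) column.
#' @export
segment_nights <- function(fixes, start_hour = 17, end_hour = 6,
                           utc_offset_h = 2) {
  fixes <- as.data.frame(fixes)
  loc <- local_seconds(fixes$time_ms, utc_offset_h)
  day <- floor(loc / 86400)
  sec <- loc - day * 86400
  evening <- sec >= start_hour * 3600
  morning <- sec < end_hour * 3600
  keep <- evening | morning
  out <- fixes[keep, , drop = FALSE]
  nd <- day[keep] - ifelse(morning[keep], 1, 0)
  out$night_date <- as.Date(nd, origin = "1970-01-01")
  rownames(out) <- NULL
  out
}

#' Assign seasonal periods to dates
#'
#' Periods follow the annual cycle: P1 = Feb-May (incubating/nesting), P2 =
#' Jun-Sep (rearing/post-breeding), P3 = Oct-Jan (fall-winter). P3 spans a
#' year boundary and is keyed to the year of its October, so a January night
#' joins the preceding autumn.
#'
#' @param dates a Date vector.
#' @param with_year if `TRUE`, return a `data.frame` with the keyed year.
#' @return character vector of `"P1"/"P2"/"P3"`, or a `data.frame(period,
#'   year)` when `with_year = TRUE`.
#' @export
assign_period <- function(dates, with_year = FALSE) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  mon <- lt$mon + 1L
  yr <- lt$year + 1900L
  period <- ifelse(mon >= 2 & mon <= 5, "P1",
                   ifelse(mon >= 6 & mon <= 9, "P2", "P3"))
  if (!with_year) return(period)
  year <- ifelse(period == "P3" & mon == 1L, yr - 1L, yr)
  data.frame(period = period, year = as.integer(year))
}

#' Assign age class at a given date
#'
#' Juvenile before the first-birthday date (hatch + 365 days), adult on and
#' after it. Individuals with no hatch date take the fixed class from
#' metadata; with neither, they are flagged `NA` (excluded from age-dependent
#' models).
#'
#' @param individual individual ids (recycled against `dates`).
#' @param dates Date vector.
#' @param metadata `data.frame` with columns `individual`, `hatch_date` and
#'   optionally `age_at_tagging`.
#' @return character vector `"juvenile"/"adult"` (NA when unknown).
#' @export
assign_age_class <- function(individual, dates, metadata) {
  i <- match(individual, metadata$individual)
  hatch <- metadata$hatch_date[i]
  fixed <- if ("age_at_tagging" %in% names(metadata))
    metadata$age_at_tagging[i] else rep(NA_character_, length(i))
  out <- ifelse(!is.na(hatch),
                ifelse(as.Date(dates) < as.Date(hatch) + 365L,
                       "juvenile", "adult"),
                fixed)
  as.character(out)
}

#' Apply night- and individual-level inclusion rules
#'
#' Order of operations: nights overlapping an individual's exclusion window
#' are dropped first (e.g. incubation spans), then nights without more than
#' `min_fixes` fixes, then individual-period cells with fewer than
#' `min_nights` qualifying nights. The report reconciles every count.
#'
#' @param night_fixes fixes with `individual` and `night_date` columns (see
#'   [segment_nights()]).
#' @param min_fixes a night is kept only if it has strictly more fixes.
#' @param min_nights an individual-period is kept only with at least this many
#'   nights.
#' @param exclusion_windows optional `data.frame(individual, start, end)` of
#'   dates to drop (inclusive).
#' @return list: `dataset` (retained fixes with `period`, `period_year`
#'   columns) and `report` (per-stage counts).
#' @export
apply_inclusion_rules <- function(night_fixes, min_fixes = 1000,
                                  min_nights = 25,
                                  exclusion_windows = NULL) {
  df <- as.data.frame(night_fixes)
  assert_that(all(c("individual", "night_date") %in% names(df)),
              "night_fixes needs individual and night_date columns")
  key <- paste(df$individual, df$night_date)
  n_nights0 <- length(unique(key))

  excl <- rep(FALSE, nrow(df))
  if (!is.null(exclusion_windows) && nrow(exclusion_windows) > 0) {
    for (r in seq_len(nrow(exclusion_windows))) {
      w <- exclusion_windows[r, ]
      excl <- excl | (df$individual == w$individual &
                        df$night_date >= as.Date(w$start) &
                        df$night_date <= as.Date(w$end))
    }
  }
  df1 <- df[!excl, , drop = FALSE]
  key1 <- key[!excl]
  nights_excluded <- n_nights0 - length(unique(key1))

  cnt <- table(key1)
  ok_nights <- names(cnt)[cnt > min_fixes]
  keep1 <- key1 %in% ok_nights
  df2 <- df1[keep1, , drop = FALSE]
  key2 <- key1[keep1]
  nights_small <- length(unique(key1)) - length(ok_nights)

  per <- assign_period(df2$night_date, with_year = TRUE)
  df2$period <- per$period
  df2$period_year <- per$year
  cell <- paste(df2$individual, df2$period, df2$period_year)
  nk <- paste(cell, df2$night_date)
  nights_per_cell <- tapply(df2$night_date, cell,
                            function(d) length(unique(d)))
  ok_cells <- names(nights_per_cell)[nights_per_cell >= min_nights]
  keep2 <- cell %in% ok_cells
  out <- df2[keep2, , drop = FALSE]
  rownames(out) <- NULL
  cells_dropped <- length(nights_per_cell) - length(ok_cells)
  nights_cell_drop <- length(unique(nk)) - length(unique(nk[keep2]))

  report <- list(
    nights_in = n_nights0,
    nights_excluded_window = nights_excluded,
    nights_below_min_fixes = nights_small,
    cells_below_min_nights = cells_dropped,
    nights_dropped_with_cells = nights_cell_drop,
    nights_out = length(unique(paste(out$individual, out$night_date))),
    fixes_in = nrow(df), fixes_out = nrow(out),
    min_fixes = min_fixes, min_nights = min_nights
  )
  list(dataset = out, report = report)
}
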