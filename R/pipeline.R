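#' End-to-end run configuration
#'
#' Bundles every stage parameter (defaults follow the study design: 50 m
#' accuracy cutoff, 15 m/s speed cutoff, 17:00-06:00 nights, >1000 fixes per
#' night, >=25 nights per individual-period, 600 s home-range subsampling,
#' 1.7 km density radius), the simulation settings, stage toggles and a
#' global seed. The configuration is serialized verbatim into every output's
#' metadata so a run is reproducible from its config alone.
#'
#' @param out_dir artifact directory.
#' @param seed global seed (propagated to every stochastic stage).
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param fast_path if `TRUE`, skip trajectory construction and preprocessing
#'   and draw nightly indices directly from the generative model (statistical
#'   testing mode; the home-range stage is then unavailable).
#' @param std_max,speed_max,night_start_hour,night_end_hour,utc_offset_h,
#'   min_fixes,min_nights preprocessing parameters.
#' @param stop_radius,stop_min_duration move/stop segmentation parameters.
#' @param hr_interval_s,hr_level,density_radius_m home-range parameters.
#' @param dhglm_chains,dhglm_iter sampler effort for the pipeline fits.
#' @param riiv_periods also fit period-specific DHGLMs (consistency stage).
#' @param n_boot bootstrap resamples for repeatability intervals.
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "preprocess", "indices", "dhglm", "repeatability",
#'   "homerange", "survival", "models")`.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("predmove_run_"),
                       seed = 1L,
                       sim = sim_config(n_individuals = 20,
                                        nights_per_individual = 40),
                       fast_path = FALSE,
                       std_max = 50, speed_max = 15,
                       night_start_hour = 17, night_end_hour = 6,
                       utc_offset_h = 2,
                       min_fixes = 1000, min_nights = 25,
                       stop_radius = 20, stop_min_duration = 60,
                       hr_interval_s = 600, hr_level = 0.95,
                       density_radius_m = 1700,
                       dhglm_chains = 2, dhglm_iter = 2000,
                       riiv_periods = FALSE, n_boot = 500,
                       stages = c("simulate", "preprocess", "indices",
                                  "dhglm", "repeatability", "homerange",
                                  "survival", "models")) {
  sim$seed <- as.integer(seed)
  cfg <- as.list(environment())
  all_stages <- c("simulate", "preprocess", "indices", "dhglm",
                  "repeatability", "homerange", "survival", "models")
  assert_that(all(stages %in% all_stages), "unknown stage name")
  class(cfg) <- "run_config"
  cfg
}

config_json <- function(config) {
  ser <- config
  ser$sim <- unclass(ser$sim)
  ser$sim$start_date <- as.character(ser$sim$start_date)
  jsonlite::toJSON(unclass(ser), auto_unbox = TRUE, digits = NA,
                   null = "null")
}

need_stage <- function(artifacts, what, consumer) {
  if (is.null(artifacts[[what]]))
    stop("stage '", consumer, "' needs the '", what,
         "' stage output; enable it or provide the artifact", call. = FALSE)
  artifacts[[what]]
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on simulated inputs:
#' simulate -> preprocess -> indices -> dhglm -> repeatability -> homerange
#' -> survival -> models. Every tabular artifact is written as CSV into
#' `config$out_dir` together with a consolidated JSON report linking each
#' output to the config hash, seed and package version. A failed or disabled
#' upstream stage halts its consumers with an error naming the missing
#' dependency.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with every in-memory artifact plus `report`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- config_json(config)
  cfg_path <- file.path(config$out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  meta_stamp <- list(config_hash = cfg_hash, seed = config$seed,
                     package_version =
                       as.character(utils::packageVersion("predmove")))
  art <- list()
  on <- function(s) s %in% config$stages
  save_csv <- function(obj, name) {
    p <- file.path(config$out_dir, paste0(name, ".csv"))
    data.table::fwrite(as.data.frame(obj), p)
    p
  }
  written <- character(0)

  if (on("simulate")) {
    if (config$fast_path) {
      art$cohort <- simulate_cohort(config$sim)
      art$night_truth <- simulate_night_indices(config$sim, art$cohort$truth)
      art$occupancy <- simulate_occupancy(config$sim)
    } else {
      simdat <- simulate_tracking_data(config$sim)
      art$cohort <- simdat$cohort
      art$night_truth <- simdat$nights
      art$occupancy <- simdat$occupancy
      art$raw_fixes <- simdat$fixes
    }
    written["metadata"] <- save_csv(art$cohort$metadata, "metadata")
  }

  if (on("preprocess") && !config$fast_path) {
    raw <- need_stage(art, "raw_fixes", "preprocess")
    filt <- filter_fixes(raw, config$std_max, config$speed_max)
    counts <- attr(filt, "stage_counts")
    nights <- segment_nights(filt, config$night_start_hour,
                             config$night_end_hour, config$utc_offset_h)
    meta <- art$cohort$metadata
    nights$individual <- meta$individual[match(nights$tag_id, meta$tag_id)]
    inc <- apply_inclusion_rules(nights, config$min_fixes, config$min_nights)
    art$dataset <- inc$dataset
    art$qc_report <- c(list(filter_counts = as.list(counts)), inc$report)
  }

  if (on("indices")) {
    if (config$fast_path) {
      ni <- need_stage(art, "night_truth", "indices")
      art$indices <- ni[, c("individual", "night_date", "period",
                            "period_year", "age_class", "sex",
                            "max_disp_km", "total_dist_km")]
      cell <- interaction(ni$individual, ni$period, ni$period_year,
                          drop = TRUE)
      art$summary <- data.frame(
        individual = tapply(ni$individual, cell, `[`, 1),
        period = tapply(ni$period, cell, `[`, 1),
        period_year = as.integer(tapply(ni$period_year, cell, `[`, 1)),
        n_nights = as.integer(table(cell)),
        mean_max_disp_km = as.numeric(tapply(ni$max_disp_km, cell, mean)),
        mean_total_dist_km = as.numeric(tapply(ni$total_dist_km, cell, mean)),
        stringsAsFactors = FALSE)
    } else {
      ds <- need_stage(art, "dataset", "indices")
      it <- build_index_table(ds, config$stop_radius,
                              config$stop_min_duration,
                              metadata = art$cohort$metadata)
      art$indices <- it$nights
      art$summary <- it$summary
    }
    written["indices"] <- save_csv(art$indices, "indices")
    written["summary"] <- save_csv(art$summary, "summary")
  }

  if (on("dhglm")) {
    idx <- need_stage(art, "indices", "dhglm")
    # in small cohorts covariates can be aliased; fall back to simpler mean
    # models rather than refusing the whole run
    fml <- list(~ age_class + sex + period, ~ age_class + period,
                ~ age_class, ~ 1)
    fit <- NULL
    for (mf in fml) {
      spec <- dhglm_spec(mean_formula = mf,
                         chains = config$dhglm_chains,
                         iter = config$dhglm_iter,
                         seed = derive_seed(config$seed, 21L))
      fit <- tryCatch(fit_dhglm(idx, spec),
                      error = function(e) {
                        if (grepl("singular", conditionMessage(e))) NULL
                        else stop(e)
                      })
      if (!is.null(fit)) break
    }
    art$dhglm <- fit
    art$riiv <- extract_riiv(art$dhglm)
    written["riiv"] <- save_csv(art$riiv, "riiv")
    if (config$riiv_periods) {
      art$riiv_period <- riiv_by_period(idx, spec)
      written["riiv_period"] <- save_csv(art$riiv_period, "riiv_period")
    }
  }

  if (on("repeatability")) {
    idx <- need_stage(art, "indices", "repeatability")
    art$repeatability <- estimate_repeatability(
      idx, value_col = "max_disp_km", id_col = "individual",
      n_boot = config$n_boot, seed = derive_seed(config$seed, 22L))
    if (!is.null(art$riiv_period) &&
        length(unique(art$riiv_period$scope)) >= 2) {
      art$riiv_consistency <- tryCatch(
        riiv_consistency(art$riiv_period, n_boot = config$n_boot,
                         seed = derive_seed(config$seed, 23L)),
        error = function(e) NULL)
    }
  }

  if (on("homerange") && !config$fast_path) {
    ds <- need_stage(art, "dataset", "homerange")
    pts <- stop_locations(ds, config$hr_interval_s, config$stop_radius,
                          config$stop_min_duration)
    hr <- home_range_table(pts, config$hr_level)
    if (!is.null(hr) && nrow(hr))
      hr <- density_index(hr, art$occupancy, config$density_radius_m)
    art$home_range <- hr
    if (!is.null(hr)) written["home_range"] <- save_csv(hr, "home_range")
  }

  if (on("survival")) {
    riiv <- need_stage(art, "riiv", "survival")
    truth <- need_stage(art, "cohort", "survival")$truth
    meta <- art$cohort$metadata
    sv <- simulate_survival(truth, config$sim)
    # per-individual covariate summary across cells
    summ <- need_stage(art, "summary", "survival")
    agg <- aggregate(mean_max_disp_km ~ individual, data = summ, FUN = mean)
    art$survival_table <- build_survival_table(sv, meta, agg, riiv)
    written["survival"] <- save_csv(art$survival_table, "survival_table")
    # per-record tracking duration is omitted: under exponential simulation
    # with administrative censoring it equals the outcome time by
    # construction, which makes the partial likelihood monotone
    covs <- c("riiv_km", "mean_max_disp_km", "sex", "age_group")
    covs <- covs[vapply(covs, function(cc)
      length(unique(art$survival_table[[cc]])) > 1, TRUE)]
    if (sum(art$survival_table$event) >= 1 && length(covs)) {
      art$cox <- fit_cox(art$survival_table, covs)
      art$hazard_ratios <- hazard_ratio_table(art$cox)
      written["hazard"] <- save_csv(art$hazard_ratios, "hazard_ratios")
    } else {
      message("survival stage: no events (or no varying covariates); ",
              "Cox fit skipped")
    }
  }

  if (on("models")) {
    idx <- need_stage(art, "summary", "models")
    riiv <- need_stage(art, "riiv", "models")
    md <- idx
    md$riiv_km <- riiv$riiv_km[match(md$individual, riiv$individual)]
    md$age_class <- art$cohort$metadata$age_at_tagging[
      match(md$individual, art$cohort$metadata$individual)]
    md$sex <- art$cohort$metadata$sex[
      match(md$individual, art$cohort$metadata$individual)]
    if (!is.null(art$home_range) && !config$fast_path &&
        nrow(art$home_range)) {
      md <- merge(md, art$home_range,
                  by = c("individual", "period", "period_year"))
      md$log_hr <- log(md$area_km2)
    }
    md <- md[complete.cases(md[, c("riiv_km", "mean_max_disp_km")]), ]
    # a random intercept needs repeated individuals (multi-period cells)
    if (nrow(md) >= 12 && "log_hr" %in% names(md) &&
        max(table(md$individual)) >= 2) {
      cont <- c("mean_max_disp_km", "mean_total_dist_km", "n_nights",
                "riiv_km")
      scr <- collinearity_screen(md, cont)
      mds <- standardize(md, cont)
      core <- c("age_class", "mean_max_disp_km", "riiv_km", "n_nights")
      core <- core[vapply(core, function(cc)
        length(unique(md[[cc]])) > 1, TRUE)]
      art$hr_models <- enumerate_and_rank(
        mds, "log_hr", core,
        stage2 = if ("density" %in% names(mds)) "density" else NULL,
        excluded_pairs = scr$flagged, group = "individual")
      art$hr_avg <- model_average(art$hr_models)
      written["hr_models"] <- save_csv(
        art$hr_models[, setdiff(names(art$hr_models), "models")],
        "hr_models")
      written["hr_avg"] <- save_csv(art$hr_avg, "hr_model_average")
    } else {
      message("models stage: skipped (needs >= 12 home-range cells and ",
              "individuals tracked in more than one period)")
    }
  }

  report <- c(meta_stamp, list(
    stages_run = intersect(config$stages,
                           c("simulate", "preprocess", "indices", "dhglm",
                             "repeatability", "homerange", "survival",
                             "models")),
    fast_path = config$fast_path,
    outputs = as.list(written),
    qc = art$qc_report,
    dhglm_converged = if (!is.null(art$dhglm)) art$dhglm$converged,
    repeatability = if (!is.null(art$repeatability))
      art$repeatability[c("Rp", "Rp_ci", "CVi", "CVi_ci")],
    parameters = list(std_max = config$std_max, speed_max = config$speed_max,
                      night = paste0(config$night_start_hour, ":00-",
                                     config$night_end_hour, ":00"),
                      min_fixes = config$min_fixes,
                      min_nights = config$min_nights,
                      hr_interval_s = config$hr_interval_s,
                      hr_level = config$hr_level,
                      density_radius_m = config$density_radius_m)
  ))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  art$report <- report
  invisible(art)
}
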