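#' Default pipeline configuration
#'
#' One list drives every stage: the bin grid, the affinity smoothing
#' coefficient, the k-selection mode and search range, the cleaning rules
#' (spike cutoff 10 m/s, 3% file-exclusion rule), the generic zone
#' boundaries, the normality-gate level and the master seed.
#'
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    grid = list(v_min = 0, v_max = 10, width = 0.1),
    beta = 0.1,
    k_mode = "auto",
    k_range = c(2L, 10L),
    seed = 20230021L,
    cleaning = list(spike_cutoff = 10, max_removed_fraction = 0.03),
    generic_scheme = list(
      boundaries = c(2.0, 3.5, 5.5, 6.0),
      zone_names = c("standing_walking", "jogging", "cruising",
                     "high_speed_running", "sprinting")
    ),
    alpha_norm = 0.05,
    simulate = list(
      duration_min = c(14, 20),
      male = list(state_means = c(1.2, 3.2, 5.8, 7.8), state_sds = 0.3,
                  dwell_mean_s = 4, a_max = 6, spike_rate = 0.002),
      female = list(state_means = c(1.0, 3.0, 5.0, 7.0), state_sds = 0.3,
                    dwell_mean_s = 4, a_max = 6, spike_rate = 0.002)
    )
  ), class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param path YAML file path.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  cfg <- utils::modifyList(base, cfg)
  cfg$k_range <- as.integer(cfg$k_range)
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname read_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (beta <= 0) vz_validation_error("beta must be positive")
    if (!k_mode %in% c("auto") && !is.numeric(k_mode)) {
      vz_validation_error("k_mode must be \"auto\" or a cluster count")
    }
    if (k_range[1] < 2 || k_range[2] < k_range[1] + 2) {
      vz_validation_error("k_range must satisfy k_min >= 2, k_max >= k_min + 2")
    }
    if (cleaning$max_removed_fraction < 0 || cleaning$max_removed_fraction > 1) {
      vz_validation_error("max_removed_fraction must lie in [0, 1]")
    }
    if (alpha_norm <= 0 || alpha_norm >= 1) {
      vz_validation_error("alpha_norm must lie in (0, 1)")
    }
  })
  invisible(cfg)
}

#' Hash of a configuration
#'
#' Short deterministic digest recorded in outputs so every run is
#' auditable against the configuration that produced it.
#'
#' @param config A `pipeline_config` (or any list).
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config), digits.d = 15)),
             collapse = "\n")
  raw <- utf8ToInt(s)
  h <- 5381
  for (r in raw) h <- (h * 31 + r) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Simulate a synthetic match cohort to disk
#'
#' Writes one seeded trace CSV (plus JSON sidecar) per player-match under
#' `out_dir`, with match durations drawn uniformly from the configured
#' range, and a `manifest.json` listing files and model parameters.
#' Identical configuration and seed give identical manifests and traces.
#'
#' @param config A `pipeline_config`.
#' @param n_players Players in the cohort.
#' @param n_matches Total match files to generate (players are cycled so
#'   the mean matches-per-player is `n_matches / n_players`).
#' @param sex `"male"` or `"female"` (selects the simulation model).
#' @param out_dir Output directory; must be empty unless `force = TRUE`.
#' @param force Overwrite a non-empty directory.
#' @return Character vector of trace file paths, invisibly.
#' @export
simulate_cohort <- function(config, n_players, n_matches, sex, out_dir,
                            force = FALSE) {
  stopifnot(sex %in% c("male", "female"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force) {
    vz_validation_error(sprintf("out_dir %s is not empty (use force = TRUE)", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$simulate[[sex]]
  model <- locomotion_model(
    state_means = p$state_means, state_sds = p$state_sds,
    dwell_mean_s = p$dwell_mean_s, a_max = p$a_max,
    spike_rate = p$spike_rate
  )
  dur_range <- config$simulate$duration_min * 60
  paths <- character(n_matches)
  entries <- vector("list", n_matches)
  for (i in seq_len(n_matches)) {
    seed_i <- derive_seed(config$seed, i + if (sex == "male") 0L else 100000L)
    duration <- withr::with_seed(seed_i, stats::runif(1, dur_range[1], dur_range[2]))
    player <- sprintf("%s_p%02d", sex, ((i - 1L) %% n_players) + 1L)
    match <- sprintf("m%03d", i)
    trace <- simulate_trace(model, duration, seed = derive_seed(seed_i, 1L),
                            player_id = player, match_id = match, sex = sex)
    paths[i] <- file.path(out_dir, sprintf("%s_%s.csv", player, match))
    write_trace(trace, paths[i])
    entries[[i]] <- list(file = basename(paths[i]), player_id = player,
                         match_id = match, sex = sex,
                         duration_s = round(duration, 1), seed = seed_i)
  }
  manifest <- list(
    sex = sex, n_players = n_players, n_matches = n_matches,
    model = p, seed = config$seed, config_hash = config_hash(config),
    files = entries
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Run the full threshold-derivation pipeline on a trace directory
#'
#' Ingest and clean every trace CSV in `trace_dir`, pool the retained
#' files of the requested cohort, select k (elbow) unless fixed in the
#' configuration, cluster each match at that k, and average the per-match
#' boundaries into cohort thresholds.
#'
#' @param config A `pipeline_config`.
#' @param trace_dir Directory of trace CSVs (sidecars supply metadata).
#' @param cohort `"male"`, `"female"` or `"other"`.
#' @return A list: `thresholds` (a `zone_thresholds`), `cleaning` (per-file
#'   summary data frame), `n_retained`.
#' @export
run_derive <- function(config, trace_dir, cohort) {
  paths <- list.files(trace_dir, pattern = "\\.csv$", full.names = TRUE)
  paths <- paths[!grepl("\\.meta\\.json$", paths)]
  if (length(paths) == 0L) vz_validation_error("no trace files found")
  cohort_data <- load_cohort(paths,
                             spike_cutoff = config$cleaning$spike_cutoff,
                             max_removed_fraction = config$cleaning$max_removed_fraction)
  traces <- cohort_data$traces[[cohort]]
  if (length(traces) == 0L) {
    vz_validation_error(sprintf("every %s file was excluded by cleaning", cohort))
  }
  grid <- bin_grid(config$grid$v_min, config$grid$v_max, config$grid$width)
  thresholds <- derive_cohort_thresholds(
    traces, k = config$k_mode, cohort = cohort, grid = grid,
    beta = config$beta, k_range = config$k_range, seed = config$seed
  )
  list(thresholds = thresholds, cleaning = cohort_data$summary,
       n_retained = length(traces))
}

#' Quantify zone profiles for a trace directory
#'
#' @param config A `pipeline_config`.
#' @param trace_dir Directory of trace CSVs.
#' @param scheme A `zone_scheme` (derived or generic).
#' @param cohort Cohort to profile.
#' @return The [cohort_profiles()] result.
#' @export
run_quantify <- function(config, trace_dir, scheme, cohort) {
  paths <- list.files(trace_dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(paths) == 0L) vz_validation_error("no trace files found")
  cohort_data <- load_cohort(paths,
                             spike_cutoff = config$cleaning$spike_cutoff,
                             max_removed_fraction = config$cleaning$max_removed_fraction)
  traces <- cohort_data$traces[[cohort]]
  if (length(traces) == 0L) vz_validation_error("no retained traces for cohort")
  cohort_profiles(traces, scheme)
}

#' Published cohort activity statistics for elite rugby sevens
#'
#' Summary activity statistics (mean, SD, group sizes and printed
#' p-values) for elite international male (55 match files) and female (33
#' match files) rugby sevens cohorts, as reported in the sports-science
#' literature, together with the published four-category velocity
#' thresholds. Used to re-test published between-sex comparisons from
#' summaries alone and as arithmetic-consistency reference points.
#'
#' @return A list of data frames: `activity` (total/relative distance and
#'   max speed), `derived_zones` (distance per derived movement category),
#'   `generic_zones` (distance per legacy zone), and `thresholds` (the
#'   published male/female category boundaries, m/s).
#' @export
sevens_reference_stats <- function() {
  list(
    n = c(male = 55, female = 33),
    activity = data.frame(
      metric = c("total_distance_m", "relative_distance_m_per_min", "max_speed_mps"),
      male_mean = c(1378.63, 70.32, 8.34),
      male_sd = c(407.35, 19.92, 1.03),
      female_mean = c(1345.78, 71.35, 7.40),
      female_sd = c(353.97, 14.81, 0.89),
      p_printed = c(0.692, 0.782, 0.001)
    ),
    derived_zones = data.frame(
      zone = c("low", "moderate", "high", "very_high"),
      male_mean = c(585.40, 484.19, 275.47, 33.57),
      male_sd = c(163.83, 172.74, 146.84, 32.13),
      female_mean = c(512.57, 461.76, 296.02, 75.42),
      female_sd = c(122.84, 195.57, 159.23, 57.13),
      p_printed = c(0.02, 0.59, 0.55, 0.001)
    ),
    generic_zones = data.frame(
      zone = c("standing_walking", "jogging", "cruising",
               "high_speed_running", "sprinting"),
      male_mean = c(572.25, 348.06, 317.38, 45.86, 95.09),
      male_sd = c(157.49, 111.91, 153.32, 29.54, 63.19),
      female_mean = c(533.37, 374.66, 322.86, 41.28, 73.61),
      female_sd = c(123.88, 149.30, 190.33, 22.00, 56.45),
      p_printed = c(0.20, 0.38, 0.89, 0.65, 0.12)
    ),
    thresholds = data.frame(
      cohort = c("male", "female"),
      b1 = c(2.05, 1.87), b2 = c(4.26, 3.74), b3 = c(7.20, 5.97)
    )
  )
}
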