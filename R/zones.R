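#' Movement-category zone scheme
#'
#' A named set of contiguous velocity zones. Zones are half-open
#' `[lower, upper)` with the first zone starting at 0 and the last zone
#' closed above at `v_max` (10 m/s), mirroring the bin convention.
#'
#' @param boundaries Strictly increasing interior boundary velocities
#'   (m/s); the zone count is `length(boundaries) + 1`.
#' @param zone_names Unique zone labels; defaults to `zone1..zoneK`.
#' @param name Scheme name.
#' @return An object of class `zone_scheme`.
#' @export
zone_scheme <- function(boundaries, zone_names = NULL, name = "custom") {
  boundaries <- as.double(boundaries)
  if (length(boundaries) && is.unsorted(boundaries, strictly = TRUE)) {
    vz_validation_error("boundaries must be strictly increasing")
  }
  k <- length(boundaries) + 1L
  if (is.null(zone_names)) zone_names <- paste0("zone", seq_len(k))
  if (length(zone_names) != k || anyDuplicated(zone_names)) {
    vz_validation_error("zone_names must be unique and one longer than boundaries")
  }
  structure(list(name = name, boundaries = boundaries, zone_names = zone_names),
            class = "zone_scheme")
}

#' Generic rugby sevens velocity zones
#'
#' The legacy arbitrary five-zone scheme used in international rugby
#' sevens practice: standing/walking (0-2 m/s), jogging (2-3.5), cruising
#' (3.5-5.5), high-speed running (5.5-6) and sprinting (above 6).
#'
#' @return A `zone_scheme`.
#' @export
generic_zone_scheme <- function() {
  zone_scheme(
    boundaries = c(2.0, 3.5, 5.5, 6.0),
    zone_names = c("standing_walking", "jogging", "cruising",
                   "high_speed_running", "sprinting"),
    name = "generic"
  )
}

#' Zone scheme from derived cohort thresholds
#'
#' @param thresholds A `zone_thresholds` from [derive_cohort_thresholds()].
#' @param zone_names Optional labels; defaults to low/moderate/high/very
#'   high naming for k = 4, `zone1..zoneK` otherwise.
#' @return A `zone_scheme`.
#' @export
zone_scheme_from_thresholds <- function(thresholds, zone_names = NULL) {
  stopifnot(inherits(thresholds, "zone_thresholds"))
  if (is.null(zone_names) && thresholds$k == 4L) {
    zone_names <- c("low", "moderate", "high", "very_high")
  }
  zone_scheme(thresholds$boundaries, zone_names,
              name = paste0("derived_", thresholds$cohort))
}

#' Merge two adjacent zones of a scheme
#'
#' Removes the boundary between `lower_zone` and the zone above it,
#' summing their spans into one zone (used e.g. to combine the generic
#' high-speed-running and sprinting zones into a single top zone).
#'
#' @param scheme A `zone_scheme`.
#' @param lower_zone Name of the lower of the two zones to merge.
#' @param merged_name Name for the combined zone.
#' @return A `zone_scheme` with one fewer zone.
#' @export
merge_zones <- function(scheme, lower_zone, merged_name = NULL) {
  i <- match(lower_zone, scheme$zone_names)
  if (is.na(i) || i >= length(scheme$zone_names)) {
    vz_validation_error("lower_zone must name a zone below the top zone")
  }
  if (is.null(merged_name)) {
    merged_name <- paste(scheme$zone_names[i], scheme$zone_names[i + 1L], sep = "_")
  }
  nm <- scheme$zone_names
  nm[i] <- merged_name
  zone_scheme(scheme$boundaries[-i], nm[-(i + 1L)], name = scheme$name)
}

#' Activity profile of one match trace
#'
#' Per-sample distance is velocity times the sampling period (rectangle
#' rule at 10 Hz); each sample's distance accrues to the zone containing
#' its velocity. Duration is the retained sample count over
#' `sample_hz * 60`, so removed spikes shorten effective duration
#' slightly; relative distance is total distance per minute.
#'
#' @param trace A cleaned [velocity_trace()].
#' @param scheme A `zone_scheme`.
#' @return An object of class `zone_profile`: `match_id`, `player_id`,
#'   `sex`, `distance_per_zone` (named, m), `total_distance_m`,
#'   `relative_distance_m_per_min`, `max_velocity_mps`, `duration_min`.
#' @export
profile_trace <- function(trace, scheme) {
  stopifnot(inherits(trace, "velocity_trace"), inherits(scheme, "zone_scheme"))
  n <- length(trace$velocities)
  if (n == 0L) vz_validation_error("cannot profile an empty trace")
  dt <- 1 / trace$sample_hz
  # half-open zones [lower, upper); findInterval's left.open=FALSE matches
  zone_of <- findInterval(trace$velocities, c(scheme$boundaries))
  dist <- trace$velocities * dt
  per_zone <- vapply(seq_along(scheme$zone_names) - 1L,
                     function(z) sum(dist[zone_of == z]), numeric(1))
  names(per_zone) <- scheme$zone_names
  total <- sum(dist)
  duration_min <- n * dt / 60
  structure(
    list(
      match_id = trace$match_id,
      player_id = trace$player_id,
      sex = trace$sex,
      scheme = scheme$name,
      distance_per_zone = per_zone,
      total_distance_m = total,
      relative_distance_m_per_min = total / duration_min,
      max_velocity_mps = max(trace$velocities),
      duration_min = duration_min
    ),
    class = "zone_profile"
  )
}

#' Cohort zone profiles and summary
#'
#' Profiles every trace and summarises each zone distance and activity
#' metric as mean and sample standard deviation (n-1 denominator) by sex.
#'
#' @param traces List of cleaned [velocity_trace()] objects.
#' @param scheme A `zone_scheme`.
#' @return A list with `profiles` (data frame, one row per match:
#'   identifiers, per-zone distances, totals) and `summary` (data frame of
#'   per-sex mean and SD per metric; SD is `NA` for single-trace groups).
#' @export
cohort_profiles <- function(traces, scheme) {
  if (length(traces) == 0L) vz_validation_error("traces must be non-empty")
  profs <- lapply(traces, profile_trace, scheme = scheme)
  zone_cols <- do.call(rbind, lapply(profs, `[[`, "distance_per_zone"))
  profiles <- data.frame(
    player_id = vapply(profs, `[[`, character(1), "player_id"),
    match_id = vapply(profs, `[[`, character(1), "match_id"),
    sex = vapply(profs, `[[`, character(1), "sex"),
    zone_cols,
    total_distance_m = vapply(profs, `[[`, numeric(1), "total_distance_m"),
    relative_distance_m_per_min = vapply(profs, `[[`, numeric(1),
                                         "relative_distance_m_per_min"),
    max_velocity_mps = vapply(profs, `[[`, numeric(1), "max_velocity_mps"),
    duration_min = vapply(profs, `[[`, numeric(1), "duration_min"),
    row.names = NULL
  )
  metrics <- c(scheme$zone_names, "total_distance_m",
               "relative_distance_m_per_min", "max_velocity_mps", "duration_min")
  summaries <- lapply(split(profiles, profiles$sex), function(g) {
    data.frame(
      sex = g$sex[1L],
      metric = metrics,
      n = nrow(g),
      mean = vapply(metrics, function(m) mean(g[[m]]), numeric(1)),
      sd = vapply(metrics, function(m) if (nrow(g) > 1L) stats::sd(g[[m]]) else NA_real_,
                  numeric(1)),
      row.names = NULL
    )
  })
  list(profiles = profiles, summary = do.call(rbind, c(summaries, make.row.names = FALSE)))
}
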