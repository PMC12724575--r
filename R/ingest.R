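#' Clean a velocity trace
#'
#' Applies the point-level spike rule: every sample with instantaneous
#' velocity strictly greater than `spike_cutoff` (default 10 m/s) is
#' removed together with its time stamp; remaining samples keep their
#' original stamps, so removals leave gaps rather than resampled series.
#' Values exactly equal to the cutoff are kept. The file-level rule then
#' flags the trace as retained only when the removed fraction (relative to
#' the original sample count) does not exceed `max_removed_fraction`.
#'
#' @param trace A [velocity_trace()].
#' @param spike_cutoff Velocity above which a sample is an artefact (m/s).
#' @param max_removed_fraction Largest tolerated removed fraction before
#'   the whole file is excluded (default 0.03).
#' @return A list with elements `trace` (the cleaned [velocity_trace()],
#'   which may contain sampling gaps) and `report` (a `cleaning_report`
#'   with `n_total`, `n_removed`, `removed_fraction`, `retained`).
#' @export
clean_trace <- function(trace, spike_cutoff = 10, max_removed_fraction = 0.03) {
  stopifnot(inherits(trace, "velocity_trace"))
  n_total <- length(trace$velocities)
  if (n_total == 0L) vz_validation_error("cannot clean an empty trace")
  keep <- trace$velocities <= spike_cutoff
  n_removed <- sum(!keep)
  removed_fraction <- n_removed / n_total
  cleaned <- velocity_trace(
    times = trace$times[keep],
    velocities = trace$velocities[keep],
    player_id = trace$player_id, match_id = trace$match_id,
    sex = trace$sex, sample_hz = trace$sample_hz,
    check = FALSE
  )
  report <- structure(
    list(
      player_id = trace$player_id,
      match_id = trace$match_id,
      n_total = n_total,
      n_removed = n_removed,
      removed_fraction = removed_fraction,
      retained = removed_fraction <= max_removed_fraction
    ),
    class = "cleaning_report"
  )
  list(trace = cleaned, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %s/%s: %d/%d removed (%.2f%%) -> %s\n",
    x$player_id, x$match_id, x$n_removed, x$n_total,
    100 * x$removed_fraction, if (x$retained) "retained" else "EXCLUDED"
  ))
  invisible(x)
}

#' Load and clean a cohort of trace files
#'
#' Reads every file, applies [clean_trace()], drops files failing the
#' file-level exclusion rule, and returns retained traces grouped by sex
#' together with a per-file cleaning summary.
#'
#' @param paths Character vector of trace CSV paths.
#' @param spike_cutoff,max_removed_fraction Cleaning parameters, see
#'   [clean_trace()].
#' @return A list with `traces` (named list `male` / `female` / `other` of
#'   cleaned [velocity_trace()] objects) and `summary` (a data frame with
#'   one row per input file: identifiers, sample counts, removed fraction
#'   and retention flag).
#' @export
load_cohort <- function(paths, spike_cutoff = 10, max_removed_fraction = 0.03) {
  if (length(paths) == 0L) vz_validation_error("paths must be non-empty")
  rows <- vector("list", length(paths))
  traces <- list(male = list(), female = list(), other = list())
  for (i in seq_along(paths)) {
    trace <- read_trace(paths[[i]])
    res <- clean_trace(trace, spike_cutoff, max_removed_fraction)
    rep <- res$report
    rows[[i]] <- data.frame(
      file = paths[[i]],
      player_id = rep$player_id,
      match_id = rep$match_id,
      sex = trace$sex,
      n_total = rep$n_total,
      n_removed = rep$n_removed,
      removed_fraction = rep$removed_fraction,
      retained = rep$retained
    )
    if (rep$retained) {
      sex <- if (trace$sex %in% c("male", "female")) trace$sex else "other"
      traces[[sex]] <- c(traces[[sex]], list(res$trace))
    }
  }
  list(traces = traces, summary = do.call(rbind, rows))
}
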