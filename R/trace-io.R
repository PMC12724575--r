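#' Write a velocity trace to disk
#'
#' One comma-separated file per player-match with header
#' `time_s,velocity_mps`, plus a JSON sidecar (`<stem>.meta.json`) holding
#' player, match, sex and sampling-rate metadata.
#'
#' @param trace A [velocity_trace()].
#' @param path Path of the CSV file to write.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "velocity_trace"))
  df <- data.frame(time_s = trace$times, velocity_mps = trace$velocities)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    player_id = trace$player_id, match_id = trace$match_id,
    sex = trace$sex, sample_hz = trace$sample_hz
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", "", path, ignore.case = TRUE) |>
  paste0(".meta.json")

#' Read a velocity trace from disk
#'
#' Accepts any comma-separated file with `time_s` and `velocity_mps`
#' columns (extra columns are ignored). Metadata come from the JSON
#' sidecar when present, otherwise from the arguments.
#'
#' @param path Path to the CSV file.
#' @param player_id,match_id,sex,sample_hz Fallback metadata when no
#'   sidecar file exists.
#' @return A [velocity_trace()].
#' @export
read_trace <- function(path, player_id = NULL, match_id = NULL,
                       sex = "other", sample_hz = 10) {
  if (!file.exists(path)) vz_parse_error(sprintf("trace file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) vz_parse_error(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  required <- c("time_s", "velocity_mps")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    vz_parse_error(sprintf("%s: missing column(s) %s", path,
                           paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) vz_parse_error(sprintf("%s: no data rows", path))
  for (col in required) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      vz_parse_error(sprintf("%s: non-numeric %s at data line %d", path, col, bad[1L]))
    }
  }
  meta_path <- sidecar_path(path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  sample_hz <- meta$sample_hz %||% sample_hz
  steps <- diff(as.numeric(df$time_s))
  if (length(steps) && any(abs(steps - 1 / sample_hz) > 1e-9)) {
    vz_parse_error(sprintf("%s: non-uniform sampling at data line %d", path,
                           which(abs(steps - 1 / sample_hz) > 1e-9)[1L] + 1L))
  }
  velocity_trace(
    times = as.numeric(df$time_s),
    velocities = as.numeric(df$velocity_mps),
    player_id = meta$player_id %||% player_id %||% tools::file_path_sans_ext(basename(path)),
    match_id = meta$match_id %||% match_id %||% "m1",
    sex = meta$sex %||% sex,
    sample_hz = sample_hz
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
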