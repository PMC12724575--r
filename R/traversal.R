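#' Velocity bin grid
#'
#' The discretisation grid for traversal counting: 100 half-open bins of
#' width 0.1 m/s covering 0-10 m/s. Bin `i` (0-based) spans
#' `[i/10, (i+1)/10)`; the top bin is closed at `v_max` so a legal cleaned
#' velocity of exactly 10 m/s still bins.
#'
#' @param v_min,v_max Grid range (m/s).
#' @param width Bin width (m/s).
#' @return An object of class `bin_grid`.
#' @export
bin_grid <- function(v_min = 0, v_max = 10, width = 0.1) {
  n_bins <- (v_max - v_min) / width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    vz_validation_error("(v_max - v_min) must be an exact multiple of width")
  }
  structure(
    list(v_min = v_min, v_max = v_max, width = width, n_bins = as.integer(round(n_bins))),
    class = "bin_grid"
  )
}

#' Map velocities to bin indices
#'
#' @param v Velocities (m/s) within `[v_min, v_max]`.
#' @param grid A [bin_grid()].
#' @return Integer 0-based bin indices, `floor((v - v_min)/width)` with
#'   `v = v_max` mapped into the top bin.
#' @export
bin_index <- function(v, grid = bin_grid()) {
  if (any(v < grid$v_min - 1e-12) || any(v > grid$v_max + 1e-12)) {
    vz_validation_error(sprintf("velocity outside [%g, %g]; run cleaning first",
                                grid$v_min, grid$v_max))
  }
  idx <- as.integer(floor((v - grid$v_min) / grid$width + 1e-9))
  pmin(idx, grid$n_bins - 1L)
}

#' Traversal matrix of a velocity trace
#'
#' A traversal is a change in velocity across two adjacent timepoints.
#' For every pair of consecutive retained samples whose time stamps differ
#' by exactly one sampling period, the count for (bin at t, bin at t+1) is
#' incremented; self-traversals land on the diagonal and carry bin
#' occupancy. Pairs spanning a cleaning gap are not counted — bridging a
#' gap would fabricate a transition that never happened.
#'
#' @param trace A cleaned [velocity_trace()].
#' @param grid A [bin_grid()].
#' @return An object of class `traversal_matrix` with fields `counts`
#'   (`n_bins x n_bins` integer matrix), `grid` and `source`.
#' @export
traversal_matrix <- function(trace, grid = bin_grid()) {
  stopifnot(inherits(trace, "velocity_trace"))
  n <- length(trace$velocities)
  if (n < 2L) vz_validation_error("trace must contain at least two samples")
  dt <- 1 / trace$sample_hz
  contiguous <- abs(diff(trace$times) - dt) <= 1e-9
  bins <- bin_index(trace$velocities, grid)
  from <- bins[-n][contiguous]
  to <- bins[-1L][contiguous]
  counts <- matrix(0L, grid$n_bins, grid$n_bins)
  if (length(from)) {
    # accumulate pair counts via a flat index table
    flat <- from * grid$n_bins + to
    tab <- table(flat)
    counts[as.integer(names(tab)) + 1L] <- as.integer(tab)
    # flat index i*n+j maps to counts[j+1, i+1] in column-major order; transpose
    counts <- t(counts)
  }
  structure(
    list(counts = counts, grid = grid,
         source = paste(trace$player_id, trace$match_id, sep = "/")),
    class = "traversal_matrix"
  )
}

#' Pool traversal matrices
#'
#' Element-wise sum of traversal counts across traces, merging all
#' retained match files of a cohort into one transition dataset.
#'
#' @param matrices A list of [traversal_matrix()] objects on one grid.
#' @return A `traversal_matrix` with `source = "pooled"`.
#' @export
pool_traversals <- function(matrices) {
  if (length(matrices) == 0L) vz_validation_error("matrices must be non-empty")
  grid <- matrices[[1L]]$grid
  for (m in matrices) {
    stopifnot(inherits(m, "traversal_matrix"))
    if (m$grid$n_bins != grid$n_bins || m$grid$width != grid$width ||
        m$grid$v_min != grid$v_min) {
      vz_validation_error("all traversal matrices must share one grid")
    }
  }
  counts <- Reduce(`+`, lapply(matrices, `[[`, "counts"))
  structure(list(counts = counts, grid = grid, source = "pooled"),
            class = "traversal_matrix")
}

#' Beta-smoothed affinity matrix from traversal counts
#'
#' The clustering affinity is the symmetrised traversal matrix, scaled so
#' its largest entry is 1, plus `beta` on the two off-diagonals (the chain
#' adjacency between neighbouring velocity bins). The chain term keeps
#' every bin connected to its velocity neighbours, preventing the grouping
#' of velocity values that share no observed traversals, and guarantees a
#' connected graph with strictly positive degrees. Because of the max
#' normalisation the construction is invariant to uniform scaling of the
#' counts.
#'
#' The returned object also carries the diagonal-inclusive row sums of the
#' source counts as `occupancy`; downstream clustering uses these as bin
#' weights.
#'
#' @param T A [traversal_matrix()].
#' @param beta Smoothing coefficient (> 0), default 0.1.
#' @return An object of class `affinity_matrix` with fields `weights`,
#'   `beta`, `grid`, `occupancy`.
#' @export
affinity_from_traversals <- function(T, beta = 0.1) {
  stopifnot(inherits(T, "traversal_matrix"))
  if (!is_scalar_number(beta) || beta <= 0) {
    vz_validation_error("beta must be a positive number")
  }
  n <- T$grid$n_bins
  S <- (T$counts + t(T$counts)) / 2
  m <- max(S)
  if (m > 0) S <- S / m
  C <- matrix(0, n, n)
  idx <- seq_len(n - 1L)
  C[cbind(idx, idx + 1L)] <- 1
  C[cbind(idx + 1L, idx)] <- 1
  structure(
    list(weights = S + beta * C, beta = beta, grid = T$grid,
         occupancy = rowSums(T$counts)),
    class = "affinity_matrix"
  )
}

#' Write a square matrix with grid metadata as CSV
#'
#' Serialises a traversal or affinity matrix to a comma-separated square
#' table preceded by a `#`-prefixed header line recording the grid
#' parameters (and beta for affinities).
#'
#' @param x A `traversal_matrix` or `affinity_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  if (inherits(x, "traversal_matrix")) {
    header <- sprintf("# traversal v_min=%g v_max=%g width=%g source=%s",
                      x$grid$v_min, x$grid$v_max, x$grid$width, x$source)
    mat <- x$counts
  } else if (inherits(x, "affinity_matrix")) {
    header <- sprintf("# affinity v_min=%g v_max=%g width=%g beta=%g",
                      x$grid$v_min, x$grid$v_max, x$grid$width, x$beta)
    mat <- x$weights
  } else {
    vz_validation_error("x must be a traversal_matrix or affinity_matrix")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(mat, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
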