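#' Spectral clustering of velocity bins
#'
#' Normalised spectral clustering of the 100 velocity bins on the
#' beta-smoothed traversal affinity. The symmetric normalised Laplacian
#' `L = I - D^(-1/2) A D^(-1/2)` is eigendecomposed; the eigenvectors of
#' the k smallest eigenvalues form the embedding, rows are normalised to
#' unit length, and seeded k-means (10 restarts) labels the bins. Clusters
#' are then relabelled 0..k-1 by ascending occupancy-weighted mean bin
#' velocity and, if the labelling is not contiguous along the velocity
#' axis, a deterministic local repair is applied (see Details).
#'
#' The within-cluster sum of squares is computed in velocity space: bin
#' centres weighted by bin occupancy (diagonal-inclusive traversal row
#' sums), with each cluster centre the occupancy-weighted mean velocity of
#' its bins. Empty bins take part in the clustering (they carry beta edges
#' only) but contribute zero weight to WCSS and cluster means.
#'
#' @details Contiguity repair: a single occupancy-weighted mode filter
#' (window of 3 bins) smooths isolated single-bin flips; any remaining
#' fragment — a maximal run whose label also occurs in another run — is
#' merged into the adjacent run with the larger summed affinity across the
#' fragment boundary, smallest-occupancy fragments first. The beta chain
#' term makes fragmentation rare; the repair is deterministic and local.
#'
#' @param A An `affinity_matrix` from [affinity_from_traversals()].
#' @param k Number of clusters, `2 <= k <= 20`.
#' @param seed Integer seed for the k-means restarts.
#' @return An object of class `cluster_solution`: `k`, `labels` (0-based,
#'   length `n_bins`, ordered by ascending velocity), `wcss`
#'   (occupancy-weighted, (m/s)^2), `contiguous`.
#' @export
spectral_cluster <- function(A, k, seed = 20230021) {
  stopifnot(inherits(A, "affinity_matrix"))
  if (!is_scalar_number(k) || k < 2 || k > 20) {
    vz_validation_error("k must lie in [2, 20]")
  }
  k <- as.integer(k)
  n <- A$grid$n_bins
  # cluster the occupied velocity support: bins outside [first, last]
  # occupied bin carry beta edges only and no distance mass, and a long
  # unvisited tail would otherwise be split off as a spurious category —
  # the opposite of what the beta smoothing is for. Interior empty bins
  # still participate through their chain edges; leading/trailing empty
  # bins inherit the end clusters.
  occupied <- which(A$occupancy > 0)
  support <- if (length(occupied)) seq.int(min(occupied), max(occupied)) else seq_len(n)
  m <- length(support)
  if (k > m) vz_cluster_error("k exceeds the number of occupied-component bins")
  W <- A$weights[support, support, drop = FALSE]
  deg <- rowSums(W)
  if (any(deg <= 0)) vz_cluster_error("affinity has a zero-degree bin")
  d_inv_sqrt <- 1 / sqrt(deg)
  L <- diag(m) - (d_inv_sqrt * W) * rep(d_inv_sqrt, each = m)
  L <- (L + t(L)) / 2
  e <- eigen(L, symmetric = TRUE)
  # eigen() returns decreasing eigenvalues: k smallest are the last k columns
  U <- e$vectors[, m:(m - k + 1L), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  nonzero <- norms > 0
  U[nonzero, ] <- U[nonzero, , drop = FALSE] / norms[nonzero]

  km <- withr::with_seed(as.integer(seed), tryCatch(
    stats::kmeans(U, centers = k, nstart = 10, iter.max = 100),
    error = function(e) {
      # identical embedding rows can defeat random centre sampling;
      # fall back to spread deterministic centres over the distinct rows
      uu <- unique(U)
      if (nrow(uu) < k) {
        vz_cluster_error("fewer distinct embedded bins than clusters")
      }
      init <- uu[round(seq(1, nrow(uu), length.out = k)), , drop = FALSE]
      stats::kmeans(U, centers = init, iter.max = 100)
    }
  ))
  labels <- rep(NA_integer_, n)
  labels[support] <- km$cluster
  if (support[1L] > 1L) labels[seq_len(support[1L] - 1L)] <- labels[support[1L]]
  if (support[m] < n) labels[(support[m] + 1L):n] <- labels[support[m]]

  centres <- (seq_len(n) - 0.5) * A$grid$width + A$grid$v_min
  occ <- A$occupancy
  labels <- order_labels_by_velocity(labels, centres, occ, k)
  repaired <- repair_contiguity(labels, occ, A$weights, k)
  labels <- order_labels_by_velocity(repaired, centres, occ, k)
  contiguous <- is_contiguous(labels)

  structure(
    list(
      k = k,
      labels = labels - 1L,
      wcss = weighted_wcss(labels, centres, occ),
      contiguous = contiguous,
      grid = A$grid
    ),
    class = "cluster_solution"
  )
}

# relabel clusters 1..k by ascending occupancy-weighted mean velocity;
# empty-occupancy clusters ordered by unweighted mean bin centre
order_labels_by_velocity <- function(labels, centres, occ, k) {
  means <- vapply(seq_len(k), function(c) {
    in_c <- labels == c
    w <- occ[in_c]
    if (sum(w) > 0) sum(w * centres[in_c]) / sum(w) else mean(centres[in_c])
  }, numeric(1))
  match(labels, order(means))
}

is_contiguous <- function(labels) {
  r <- rle(labels)$values
  length(r) == length(unique(r))
}

weighted_wcss <- function(labels, centres, occ) {
  total <- 0
  for (c in unique(labels)) {
    in_c <- labels == c
    w <- occ[in_c]
    if (sum(w) > 0) {
      mu <- sum(w * centres[in_c]) / sum(w)
      total <- total + sum(w * (centres[in_c] - mu)^2)
    }
  }
  total
}

repair_contiguity <- function(labels, occ, W, k) {
  if (is_contiguous(labels)) return(labels)
  n <- length(labels)
  # one pass of an occupancy-weighted mode filter, window 3
  filt <- labels
  w_occ <- occ + 1e-12  # empty bins still vote, infinitesimally
  for (i in seq_len(n)) {
    win <- max(1L, i - 1L):min(n, i + 1L)
    votes <- tapply(w_occ[win], labels[win], sum)
    filt[i] <- as.integer(names(votes)[which.max(votes)])
  }
  if (length(unique(filt)) == k) labels <- filt
  # merge remaining fragments (runs of a label that occurs in >1 run)
  for (iter in seq_len(n)) {
    if (is_contiguous(labels)) break
    r <- rle(labels)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    dup <- r$values[duplicated(r$values) | duplicated(r$values, fromLast = TRUE)]
    frag_idx <- which(r$values %in% dup)
    run_occ <- vapply(frag_idx, function(j) sum(occ[starts[j]:ends[j]]), numeric(1))
    j <- frag_idx[order(run_occ, frag_idx)][1L]
    bins <- starts[j]:ends[j]
    left_ok <- j > 1L
    right_ok <- j < length(r$values)
    aff_left <- if (left_ok) sum(W[bins, starts[j - 1L]:ends[j - 1L]]) else -Inf
    aff_right <- if (right_ok) sum(W[bins, starts[j + 1L]:ends[j + 1L]]) else -Inf
    labels[bins] <- if (aff_left >= aff_right) r$values[j - 1L] else r$values[j + 1L]
    # renumber in case a label vanished, keeping k labels where possible
    labels <- match(labels, sort(unique(labels)))
  }
  labels
}

#' Elbow-method selection of the number of movement categories
#'
#' Runs [spectral_cluster()] for every k in `[k_min, k_max]` and selects
#' the inflection point of the WCSS-vs-k curve: the interior k maximising
#' the discrete second difference `WCSS(k-1) - 2 WCSS(k) + WCSS(k+1)`,
#' ties broken toward smaller k. A WCSS increase beyond a small tolerance
#' (a k-means local optimum) is reported as a warning, not an error.
#'
#' @param A An `affinity_matrix`.
#' @param k_min,k_max Search range; `k_min >= 2`, `k_max >= k_min + 2` so
#'   at least one interior k exists.
#' @param seed Integer seed passed to each clustering.
#' @return An object of class `elbow_curve`: `k_values`, `wcss_values`,
#'   `k_star`, and `solutions` (the per-k `cluster_solution`s).
#' @export
elbow_select <- function(A, k_min = 2, k_max = 10, seed = 20230021) {
  if (k_min < 2) vz_validation_error("k_min must be at least 2")
  if (k_max < k_min + 2) vz_validation_error("k_max must be at least k_min + 2")
  k_values <- seq.int(k_min, k_max)
  solutions <- lapply(k_values, function(k) spectral_cluster(A, k, seed))
  wcss <- vapply(solutions, `[[`, numeric(1), "wcss")
  if (any(diff(wcss) > 1e-6 * wcss[1L])) {
    warning("WCSS not monotone non-increasing in k (k-means local optimum)",
            call. = FALSE)
  }
  k_star <- select_elbow_k(k_values, wcss)
  structure(
    list(k_values = k_values, wcss_values = wcss, k_star = k_star,
         solutions = solutions),
    class = "elbow_curve"
  )
}

# interior argmax of the discrete second difference, ties toward smaller k
select_elbow_k <- function(k_values, wcss_values) {
  n <- length(k_values)
  if (n < 3L) vz_validation_error("need at least three k values for an elbow")
  interior <- 2:(n - 1L)
  d2 <- wcss_values[interior - 1L] - 2 * wcss_values[interior] + wcss_values[interior + 1L]
  k_values[interior[which.max(d2)]]
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat("<elbow_curve>\n")
  print(data.frame(k = x$k_values, wcss = signif(x$wcss_values, 6)))
  cat("selected k* =", x$k_star, "\n")
  invisible(x)
}

#' Velocity boundaries of a contiguous cluster solution
#'
#' For each pair of adjacent clusters, the boundary is the lower edge of
#' the first bin of the upper cluster (bin index times bin width).
#'
#' @param sol A contiguous `cluster_solution`.
#' @param grid A [bin_grid()] (defaults to the solution's own grid).
#' @return Numeric vector of k-1 strictly increasing boundary velocities
#'   (m/s).
#' @export
extract_boundaries <- function(sol, grid = sol$grid) {
  stopifnot(inherits(sol, "cluster_solution"))
  if (!sol$contiguous) {
    vz_cluster_error("solution is not contiguous; repair must run first")
  }
  changes <- which(diff(sol$labels) != 0L)
  grid$v_min + changes * grid$width
}

#' Derive cohort movement-category thresholds (two-stage procedure)
#'
#' Stage 1: the traversal matrices of all retained match files are pooled
#' and, when `k = "auto"`, the elbow method on the pooled affinity selects
#' the number of categories. Stage 2: each match file is clustered
#' independently at that fixed k and its boundaries extracted; the cohort
#' thresholds are the arithmetic per-rank means of the per-match
#' boundaries (well defined because every match uses the same k),
#' reported to 0.01 m/s with unrounded values kept in the provenance.
#'
#' Matches whose per-file clustering fails (e.g. too few occupied bins)
#' are excluded from the mean and listed in the provenance.
#'
#' @param traces List of cleaned [velocity_trace()] objects, one cohort.
#' @param k `"auto"` (elbow selection) or a fixed integer count.
#' @param cohort Label stored on the result (`"male"`, `"female"`, ...).
#' @param grid A [bin_grid()].
#' @param beta Affinity smoothing coefficient.
#' @param k_range Length-2 integer vector, elbow search range for
#'   `k = "auto"`.
#' @param seed Integer seed for all clustering stages.
#' @return An object of class `zone_thresholds`: `cohort`, `k`,
#'   `boundaries` (rounded, length k-1), `boundaries_raw`, `elbow` (the
#'   stage-1 curve or `NULL`), `per_match` (matrix of per-match
#'   boundaries), `failed_matches`.
#' @export
derive_cohort_thresholds <- function(traces, k = "auto", cohort = "other",
                                     grid = bin_grid(), beta = 0.1,
                                     k_range = c(2L, 10L), seed = 20230021) {
  if (length(traces) < 1L) vz_validation_error("need at least one retained trace")
  mats <- lapply(traces, traversal_matrix, grid = grid)

  elbow <- NULL
  if (identical(k, "auto")) {
    pooled <- pool_traversals(mats)
    elbow <- elbow_select(affinity_from_traversals(pooled, beta),
                          k_min = k_range[1L], k_max = k_range[2L], seed = seed)
    k <- elbow$k_star
  }
  k <- as.integer(k)

  per_match <- vector("list", length(mats))
  sources <- character(length(mats))
  failed <- character()
  for (i in seq_along(mats)) {
    res <- tryCatch(
      {
        sol <- spectral_cluster(affinity_from_traversals(mats[[i]], beta), k, seed)
        b <- extract_boundaries(sol, grid)
        if (length(b) != k - 1L) vz_cluster_error("degenerate solution: fewer than k categories")
        b
      },
      velozone_error = function(e) e
    )
    if (inherits(res, "velozone_error")) {
      failed <- c(failed, sprintf("%s: %s", mats[[i]]$source, conditionMessage(res)))
    } else {
      per_match[[i]] <- res
      sources[i] <- mats[[i]]$source
    }
  }
  ok <- !vapply(per_match, is.null, logical(1))
  if (!any(ok)) {
    vz_cluster_error("per-match clustering failed for every trace")
  }
  tab <- do.call(rbind, per_match[ok])
  rownames(tab) <- make.unique(sources[ok])
  raw <- colMeans(tab)
  structure(
    list(
      cohort = cohort,
      k = k,
      boundaries = round(raw, 2),
      boundaries_raw = raw,
      elbow = elbow,
      per_match = tab,
      failed_matches = failed
    ),
    class = "zone_thresholds"
  )
}

#' @export
print.zone_thresholds <- function(x, ...) {
  cat(sprintf("<zone_thresholds> cohort=%s k=%d\n", x$cohort, x$k))
  lo <- c(0, x$boundaries)
  hi <- c(x$boundaries, NA)
  for (z in seq_len(x$k)) {
    if (z < x$k) {
      cat(sprintf("  zone %d: %.2f-%.2f m/s\n", z, lo[z], hi[z]))
    } else {
      cat(sprintf("  zone %d: > %.2f m/s\n", z, lo[z]))
    }
  }
  cat(sprintf("  (%d match files averaged, %d failed)\n",
              nrow(x$per_match), length(x$failed_matches)))
  invisible(x)
}

#' Write zone thresholds as JSON
#'
#' @param x A `zone_thresholds`.
#' @param path Output path.
#' @param config Optional configuration list; its hash is recorded.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(x, path, config = NULL) {
  stopifnot(inherits(x, "zone_thresholds"))
  doc <- list(
    cohort = x$cohort,
    k = x$k,
    boundaries = x$boundaries,
    boundaries_raw = x$boundaries_raw,
    per_match_boundaries = apply(x$per_match, 1L, identity, simplify = FALSE),
    failed_matches = x$failed_matches,
    config_hash = if (is.null(config)) NA else config_hash(config)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
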