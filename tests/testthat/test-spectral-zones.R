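test_that("two-block affinities split exactly at the minimum normalised cut", {
  Tm <- block_traversal(split = 50, density1 = 5, density2 = 5, seed = 1)
  A <- affinity_from_traversals(Tm)
  sol <- spectral_cluster(A, 2)
  expect_true(sol$contiguous)
  expect_equal(which(diff(sol$labels) != 0), 50L)
  expect_equal(brute_force_ncut_split(A$weights), 50L)
  expect_equal(extract_boundaries(sol), 5.0)
})

test_that("cluster counts outside [2, 20] or above the occupied support are rejected", {
  A <- affinity_from_traversals(block_traversal(50, 5, 5, seed = 2))
  expect_error(spectral_cluster(A, 1), class = "velozone_validation_error")
  expect_error(spectral_cluster(A, 21), class = "velozone_validation_error")
  narrow <- structure(list(counts = {
    m <- matrix(0L, 100, 100); m[10:12, 10:12] <- 5L; m
  }, grid = bin_grid(), source = "n"), class = "traversal_matrix")
  expect_error(spectral_cluster(affinity_from_traversals(narrow), 5),
               class = "velozone_cluster_error")
})

test_that("four uniform blocks yield equal clusters with the analytic weighted WCSS", {
  counts <- matrix(0L, 100, 100)
  for (b in 0:3) {
    idx <- b * 25 + 1:25
    counts[idx, idx] <- 4L
  }
  Tm <- structure(list(counts = counts, grid = bin_grid(), source = "blocks4"),
                  class = "traversal_matrix")
  sol <- spectral_cluster(affinity_from_traversals(Tm), 4)
  expect_true(sol$contiguous)
  expect_equal(rle(sol$labels)$lengths, rep(25L, 4))
  # closed form: equal occupancy w per bin, centres c_i, per-block variance
  centres <- (1:100 - 0.5) / 10
  occ <- rowSums(counts)
  wcss_oracle <- sum(vapply(0:3, function(b) {
    idx <- b * 25 + 1:25
    mu <- sum(occ[idx] * centres[idx]) / sum(occ[idx])
    sum(occ[idx] * (centres[idx] - mu)^2)
  }, numeric(1)))
  expect_equal(sol$wcss, wcss_oracle, tolerance = 1e-9)
})

test_that("the elbow is the interior k maximising the second difference", {
  expect_equal(velozone:::select_elbow_k(2:7, c(100, 40, 12, 10, 9, 8.5)), 3L)
  # strictly linear decline: all interior second differences zero, tie
  # broken toward the smallest interior k
  expect_equal(velozone:::select_elbow_k(2:8, seq(70, 10, by = -10)), 3L)
  expect_error(velozone:::select_elbow_k(2:3, c(2, 1)), class = "velozone_validation_error")
  expect_error(elbow_select(NULL, k_min = 1, k_max = 5), class = "velozone_validation_error")
  expect_error(elbow_select(NULL, k_min = 2, k_max = 3), class = "velozone_validation_error")
})

test_that("boundaries are the lower edges of each upper cluster's first bin", {
  sol <- make_solution(rep(0:2, c(20, 30, 50)))
  expect_equal(extract_boundaries(sol), c(2.0, 5.0))
  expect_equal(extract_boundaries(make_solution(rep(0:1, c(21, 79)))), 2.1)
  expect_equal(extract_boundaries(make_solution(rep(0L, 100))), numeric(0))
  bad <- make_solution(c(rep(0L, 50), 1L, rep(0L, 9), rep(1L, 40)))
  bad$contiguous <- FALSE
  expect_error(extract_boundaries(bad), class = "velozone_cluster_error")
})

test_that("solutions on chain-connected affinities are contiguous at every k", {
  cohort <- recovery_cohorts()[[1]]
  A <- affinity_from_traversals(pool_traversals(lapply(cohort[1:10], traversal_matrix)))
  for (k in 2:8) {
    sol <- spectral_cluster(A, k)
    expect_true(sol$contiguous)
    expect_equal(sort(unique(sol$labels)), 0:(k - 1))
    expect_false(is.unsorted(sol$labels))
  }
})

test_that("WCSS is non-increasing in k, with local-optimum violations flagged", {
  cohort <- recovery_cohorts()[[1]]
  A <- affinity_from_traversals(pool_traversals(lapply(cohort[1:10], traversal_matrix)))
  wcss <- withCallingHandlers(
    elbow_select(A, 2, 10)$wcss_values,
    warning = function(w) {
      expect_match(conditionMessage(w), "WCSS not monotone")
      invokeRestart("muffleWarning")
    }
  )
  increases <- diff(wcss)
  # genuine decreases dominate; any increase is within the k-means
  # local-optimum scale, far below the structural drops
  expect_lt(max(increases), 0.05 * wcss[1])
  expect_lt(wcss[3], 0.2 * wcss[1])  # k=4 captures the four-state structure
})

test_that("boundary positions are stable across clustering seeds", {
  cohort <- recovery_cohorts()[[1]]
  A <- affinity_from_traversals(pool_traversals(lapply(cohort, traversal_matrix)))
  boundaries <- t(vapply(1:10, function(s) {
    extract_boundaries(spectral_cluster(A, 4, seed = s))
  }, numeric(3)))
  spread <- apply(boundaries, 2, function(b) diff(range(b)))
  expect_true(all(spread < 0.1))  # under one bin width
})

test_that("cohort thresholds are the per-match means and survive degenerate cohorts", {
  trace <- recovery_cohorts()[[1]][[1]]
  single <- suppressWarnings(
    derive_cohort_thresholds(list(trace), k = 4, cohort = "other"))
  A <- affinity_from_traversals(traversal_matrix(trace))
  direct <- extract_boundaries(spectral_cluster(A, 4))
  expect_equal(single$boundaries_raw, direct, ignore_attr = TRUE)

  pair <- suppressWarnings(
    derive_cohort_thresholds(list(trace, trace), k = 4, cohort = "other"))
  expect_equal(pair$boundaries_raw, single$boundaries_raw, ignore_attr = TRUE)
  expect_equal(nrow(pair$per_match), 2L)

  expect_true(all(diff(single$boundaries) > 0))
  expect_error(derive_cohort_thresholds(list(), k = 4),
               class = "velozone_validation_error")
})

test_that("matches whose per-file clustering fails are excluded and logged", {
  good <- recovery_cohorts()[[1]][[1]]
  # a nearly-constant trace occupies too few bins to support k = 4
  degenerate <- flat_trace(2.0, 30, match_id = "flat")
  res <- suppressWarnings(
    derive_cohort_thresholds(list(good, degenerate), k = 4, cohort = "other"))
  expect_equal(nrow(res$per_match), 1L)
  expect_length(res$failed_matches, 1L)
  expect_match(res$failed_matches, "flat")
})
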