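#' Multi-state locomotion model for synthetic match traces
#'
#' Defines a semi-Markov locomotor process over a small set of movement
#' states (e.g. standing/walking, jogging, striding, sprinting). The
#' process dwells in a state for a geometrically distributed number of
#' samples, then jumps to another state with probability proportional to
#' the corresponding row of `transition_weights`. Within a state the
#' velocity is pulled toward the state mean with Gaussian noise, subject to
#' an acceleration limit and a hard velocity cap. Optional spike artefacts
#' replace the recorded value with an impossible velocity above the cap,
#' emulating GPS error that downstream cleaning must remove.
#'
#' @param state_means Target velocities per state (m/s), strictly
#'   increasing, all in `[0, v_cap)`.
#' @param state_sds Per-state velocity noise standard deviation (m/s),
#'   recycled to the number of states.
#' @param dwell_mean_s Mean dwell time per state in seconds, recycled.
#' @param transition_weights Square matrix of relative transition
#'   propensities with zero diagonal; rows need not be normalised.
#'   Defaults to uniform off-diagonal weights.
#' @param a_max Maximum absolute acceleration (m/s^2).
#' @param v_cap Hard velocity cap (m/s).
#' @param spike_rate Per-sample probability that the recorded value is
#'   replaced by an artefactual spike in `(v_cap, v_cap + 3]`.
#' @param sample_hz Sampling rate (Hz).
#'
#' @return An object of class `locomotion_model`.
#' @seealso [simulate_trace()], [expected_state_occupancy()],
#'   [default_locomotion_model()]
#' @export
locomotion_model <- function(state_means,
                             state_sds = 0.3,
                             dwell_mean_s = 4,
                             transition_weights = NULL,
                             a_max = 6,
                             v_cap = 10,
                             spike_rate = 0,
                             sample_hz = 10) {
  if (!is.numeric(state_means) || length(state_means) < 1L || anyNA(state_means)) {
    vz_validation_error("state_means must be a non-empty numeric vector")
  }
  n <- length(state_means)
  if (is.unsorted(state_means, strictly = TRUE)) {
    vz_validation_error("state_means must be strictly increasing")
  }
  if (!is_scalar_number(v_cap) || v_cap <= 0) {
    vz_validation_error("v_cap must be a positive number")
  }
  if (any(state_means < 0) || any(state_means >= v_cap)) {
    vz_validation_error("state_means must lie in [0, v_cap)")
  }
  state_sds <- rep_len(as.double(state_sds), n)
  if (any(!is.finite(state_sds)) || any(state_sds < 0)) {
    vz_validation_error("state_sds must be finite and non-negative")
  }
  dwell_mean_s <- rep_len(as.double(dwell_mean_s), n)
  if (any(!is.finite(dwell_mean_s)) || any(dwell_mean_s <= 0)) {
    vz_validation_error("dwell_mean_s must be positive")
  }
  if (is.null(transition_weights)) {
    transition_weights <- matrix(1, n, n) - diag(n)
    if (n == 1L) transition_weights <- matrix(0, 1L, 1L)
  }
  transition_weights <- as.matrix(transition_weights)
  if (!all(dim(transition_weights) == c(n, n))) {
    vz_validation_error("transition_weights must be a square matrix matching state_means")
  }
  if (any(diag(transition_weights) != 0)) {
    vz_validation_error("transition_weights must have a zero diagonal")
  }
  if (any(transition_weights < 0)) {
    vz_validation_error("transition_weights must be non-negative")
  }
  if (n > 1L && any(rowSums(transition_weights) <= 0)) {
    vz_validation_error("every transition_weights row must have positive sum")
  }
  if (!is_scalar_number(a_max) || a_max <= 0) {
    vz_validation_error("a_max must be a positive number")
  }
  if (!is_scalar_number(spike_rate) || spike_rate < 0 || spike_rate >= 1) {
    vz_validation_error("spike_rate must lie in [0, 1)")
  }
  if (!is_scalar_number(sample_hz) || sample_hz <= 0) {
    vz_validation_error("sample_hz must be a positive number")
  }
  structure(
    list(
      state_means = as.double(state_means),
      state_sds = state_sds,
      dwell_mean_s = dwell_mean_s,
      transition_weights = transition_weights,
      a_max = as.double(a_max),
      v_cap = as.double(v_cap),
      spike_rate = as.double(spike_rate),
      sample_hz = as.double(sample_hz)
    ),
    class = "locomotion_model"
  )
}

#' Default cohort locomotion models
#'
#' Four-state models whose state means are calibrated so that simulated
#' match maxima land near the cohort maximum velocities reported for elite
#' rugby sevens (about 8.3 m/s for men, 7.4 m/s for women).
#'
#' @param sex `"male"` or `"female"`.
#' @param spike_rate Per-sample artefact probability (default 0).
#' @return A `locomotion_model`.
#' @export
default_locomotion_model <- function(sex = c("male", "female"), spike_rate = 0) {
  sex <- match.arg(sex)
  means <- switch(sex,
    male = c(1.2, 3.2, 5.8, 7.8),
    female = c(1.0, 3.0, 5.0, 7.0)
  )
  locomotion_model(means, state_sds = 0.3, dwell_mean_s = 4, a_max = 6,
                   spike_rate = spike_rate)
}

#' Construct a velocity trace
#'
#' A velocity trace is one player-match instantaneous-velocity series at a
#' fixed sampling rate, the atomic input of the whole pipeline.
#'
#' @param times Sample times (s), strictly increasing.
#' @param velocities Instantaneous velocities (m/s), finite, non-negative.
#' @param player_id,match_id Identifiers.
#' @param sex `"male"`, `"female"` or `"other"`.
#' @param sample_hz Sampling rate (Hz).
#' @param check If `TRUE` (default) require a constant sampling step of
#'   `1/sample_hz`; cleaned traces with gaps set this to `FALSE`.
#' @return An object of class `velocity_trace`.
#' @export
velocity_trace <- function(times, velocities, player_id = "p1", match_id = "m1",
                           sex = "other", sample_hz = 10, check = TRUE) {
  times <- as.double(times)
  velocities <- as.double(velocities)
  if (length(times) != length(velocities)) {
    vz_validation_error("times and velocities must have equal length")
  }
  if (length(times) == 0L) vz_validation_error("trace must contain at least one sample")
  if (anyNA(velocities) || any(!is.finite(velocities)) || any(velocities < 0)) {
    vz_validation_error("velocities must be finite and non-negative")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    vz_validation_error("times must be strictly increasing")
  }
  if (check && length(times) > 1L) {
    steps <- diff(times)
    if (any(abs(steps - 1 / sample_hz) > 1e-9)) {
      vz_validation_error("times must advance by exactly 1/sample_hz")
    }
  }
  structure(
    list(
      player_id = as.character(player_id),
      match_id = as.character(match_id),
      sex = as.character(sex),
      sample_hz = as.double(sample_hz),
      times = times,
      velocities = velocities
    ),
    class = "velocity_trace"
  )
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf(
    "<velocity_trace> %s/%s (%s): %d samples @ %g Hz, %.1f min, max %.2f m/s\n",
    x$player_id, x$match_id, x$sex, length(x$velocities), x$sample_hz,
    length(x$velocities) / (x$sample_hz * 60), max(x$velocities)
  ))
  invisible(x)
}

#' Stationary state occupancy of a locomotion model
#'
#' Occupancy fractions of the semi-Markov chain: the stationary vector of
#' the embedded jump chain, weighted by the mean dwell time of each state
#' and normalised to sum to one. Serves as the analytic oracle for
#' long-run state frequencies of [simulate_trace()].
#'
#' @param model A [locomotion_model()].
#' @return Numeric vector of occupancy fractions, one per state.
#' @export
expected_state_occupancy <- function(model) {
  stopifnot(inherits(model, "locomotion_model"))
  n <- length(model$state_means)
  if (n == 1L) return(1)
  P <- model$transition_weights / rowSums(model$transition_weights)
  # irreducibility: every state reachable from every other
  reach <- diag(n) + P
  for (i in seq_len(ceiling(log2(n)) + 1L)) reach <- reach %*% reach
  if (any(reach == 0)) {
    vz_validation_error("transition structure is reducible; occupancy undefined")
  }
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  pi_embed <- Re(e$vectors[, i])
  pi_embed <- pi_embed / sum(pi_embed)
  occ <- pi_embed * model$dwell_mean_s
  occ / sum(occ)
}

#' Simulate a 10 Hz velocity trace from a locomotion model
#'
#' The state sequence follows the model's semi-Markov chain: dwell lengths
#' are geometric with mean `dwell_mean_s * sample_hz` samples and the next
#' state is drawn proportionally to the current row of
#' `transition_weights`. The start state is drawn from the stationary
#' occupancy and the start velocity is 0 m/s (kick-off from standing).
#' Each step the velocity is pulled fully toward the state mean plus
#' Gaussian noise, the per-step change is clipped to `a_max / sample_hz`,
#' and the result clamped to `[0, v_cap]`. With probability `spike_rate`
#' the recorded value (not the dynamical state) is replaced by an
#' artefactual spike drawn uniformly in `(v_cap, v_cap + 3]`.
#'
#' @param model A [locomotion_model()].
#' @param duration_s Trace duration in seconds.
#' @param seed Integer seed; identical inputs give identical traces.
#' @param player_id,match_id,sex Metadata carried on the trace.
#' @return A [velocity_trace()].
#' @export
simulate_trace <- function(model, duration_s, seed,
                           player_id = "p1", match_id = "m1", sex = "other") {
  stopifnot(inherits(model, "locomotion_model"))
  if (!is_scalar_number(duration_s) || duration_s <= 0) {
    vz_validation_error("duration_s must be a positive number")
  }
  n_samples <- round(duration_s * model$sample_hz)
  if (n_samples < 1L) vz_validation_error("duration too short for one sample")
  n_states <- length(model$state_means)
  dt <- 1 / model$sample_hz
  dv_max <- model$a_max * dt

  sim <- withr::with_seed(as.integer(seed), {
    occ <- if (n_states > 1L) expected_state_occupancy(model) else 1
    state <- sample.int(n_states, 1L, prob = occ)
    # remaining samples in current dwell (>= 1)
    dwell_left <- 1L + stats::rgeom(1L, 1 / (model$dwell_mean_s[state] * model$sample_hz))
    v <- 0
    out <- numeric(n_samples)
    state_seq <- integer(n_samples)
    noise <- stats::rnorm(n_samples)
    for (t in seq_len(n_samples)) {
      if (dwell_left <= 0L && n_states > 1L) {
        state <- sample.int(n_states, 1L, prob = model$transition_weights[state, ])
        dwell_left <- 1L + stats::rgeom(1L, 1 / (model$dwell_mean_s[state] * model$sample_hz))
      }
      target <- model$state_means[state] + model$state_sds[state] * noise[t]
      dv <- target - v
      if (dv > dv_max) dv <- dv_max else if (dv < -dv_max) dv <- -dv_max
      v <- v + dv
      if (v < 0) v <- 0 else if (v > model$v_cap) v <- model$v_cap
      out[t] <- v
      state_seq[t] <- state
      dwell_left <- dwell_left - 1L
    }
    if (model$spike_rate > 0) {
      hit <- stats::runif(n_samples) < model$spike_rate
      if (any(hit)) {
        out[hit] <- model$v_cap + stats::runif(sum(hit), 0, 3)
      }
    }
    list(out = out, states = state_seq)
  })

  trace <- velocity_trace(
    times = (seq_len(n_samples) - 1L) * dt,
    velocities = sim$out,
    player_id = player_id, match_id = match_id, sex = sex,
    sample_hz = model$sample_hz
  )
  # ground-truth state sequence, for generative-recovery diagnostics
  attr(trace, "states") <- sim$states
  trace
}
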