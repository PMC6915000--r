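# Shared fixtures: curve builders and the independent brute-force SF oracle.

grid_pct <- 0:100

mk_curve <- function(values, joint = "hip_flexext", side = NA_character_,
                     subject_id = NA_character_, group = NA_character_,
                     cycle_index = NA_integer_) {
  normalized_curve(values, joint = joint, side = side,
                   subject_id = subject_id, group = group,
                   cycle_index = cycle_index, n_points = length(values))
}

# Direct loop transcription of the SF definition, independent of the
# vectorised implementation: per-instant difference over the mean of the
# two whole-cycle ranges.
sf_oracle <- function(v1, v2) {
  r1 <- max(v1) - min(v1)
  r2 <- max(v2) - min(v2)
  out <- numeric(length(v1))
  for (k in seq_along(v1)) {
    out[k] <- (v1[k] - v2[k]) / (0.5 * (r1 + r2)) * 100
  }
  out
}

# Random non-degenerate 101-point curve.
rand_curve_values <- function(amp = NULL) {
  if (is.null(amp)) amp <- stats::runif(1, 2, 40)
  base <- stats::rnorm(1, 0, 10)
  base + amp * sin(2 * pi * grid_pct / 100 + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(101, 0, amp / 10)
}

# A cosine-based angle_cycle sampled at `hz` over `dur` seconds.
mk_cycle <- function(f, hz = 120, dur = 1.1, joint = "hip_flexext",
                     side = "right", subject_id = "S01", group = "normal",
                     cycle_index = 1L) {
  tm <- seq(0, dur, by = 1 / hz)
  if (tm[length(tm)] < dur) tm <- c(tm, dur)
  angle_cycle(tm, f(tm), subject_id, group, side, joint, cycle_index)
}
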