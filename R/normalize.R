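# Time normalisation: resample each measured cycle onto the canonical
# 0..100%CT grid with local (windowed) Lagrange interpolating polynomials.

# Evaluate the local Lagrange interpolant through the `order + 1` samples
# nearest each output abscissa. Windows are clamped at the ends of the
# record. When an output abscissa coincides bitwise with a sample time the
# basis collapses to exactly 1/0 and the sample value is reproduced
# bit-identically.
lagrange_local <- function(x, y, xout, order = 3L) {
  n <- length(x)
  k <- order + 1L
  if (n < k)
    stop_gaitsf("gaitsf_insufficient_data",
                "need at least %d samples for order-%d interpolation", k, order)
  left <- findInterval(xout, x, all.inside = TRUE)
  start <- pmin(pmax(left - (k %/% 2L) + 1L, 1L), n - k + 1L)
  out <- numeric(length(xout))
  for (j in seq_along(xout)) {
    idx <- start[j]:(start[j] + k - 1L)
    xi <- x[idx]
    yi <- y[idx]
    xx <- xout[j]
    s <- 0
    for (m in seq_len(k)) {
      L <- 1
      for (q in seq_len(k)) {
        if (q != m) L <- L * (xx - xi[q]) / (xi[m] - xi[q])
      }
      s <- s + yi[m] * L
    }
    out[j] <- s
  }
  out
}

#' Time-normalise one gait cycle to the canonical %CT grid
#'
#' Resamples a measured cycle so that its first sample maps to 0%CT and its
#' last to 100%CT, with values every 1%CT (101 points). Each grid value is
#' the local cubic Lagrange interpolant through the four samples nearest the
#' grid abscissa; a single global polynomial over a whole cycle would suffer
#' Runge oscillation, whereas short windows are stable and exact for local
#' cubics. Grid points that coincide with sample times reproduce the sampled
#' value bit-identically.
#'
#' @param cycle An [angle_cycle()].
#' @param n_points Output grid length; the canonical grid is 101 (1%CT
#'   spacing). Configurable for testing only.
#' @return A [normalized_curve()] with the cycle's metadata carried over.
#' @export
#' @examples
#' tm <- seq(0, 1.1, by = 1 / 120)
#' cyc <- angle_cycle(tm, 25 + 20 * cos(2 * pi * tm / 1.1), "S01", "normal",
#'                    "right", "knee_flexext", 1)
#' curve <- time_normalize(cyc)
#' range(curve$values)
time_normalize <- function(cycle, n_points = 101L) {
  if (!inherits(cycle, "angle_cycle"))
    stop_gaitsf("gaitsf_input_error", "time_normalize expects an angle_cycle")
  t0 <- cycle$time[1]
  t1 <- cycle$time[length(cycle$time)]
  grid <- seq(t0, t1, length.out = n_points)
  vals <- lagrange_local(cycle$time, cycle$angle, grid, order = 3L)
  normalized_curve(vals, joint = cycle$joint, side = cycle$side,
                   subject_id = cycle$subject_id, group = cycle$group,
                   cycle_index = cycle$cycle_index, n_points = n_points)
}

#' Time-normalise every cycle of a set
#'
#' @param set A [subject_set()].
#' @param n_points Grid length, see [time_normalize()].
#' @return A list of [normalized_curve()] objects (class `"normalized_set"`).
#' @export
normalize_set <- function(set, n_points = 101L) {
  if (!inherits(set, "subject_set"))
    stop_gaitsf("gaitsf_input_error", "normalize_set expects a subject_set")
  curves <- lapply(set$cycles, time_normalize, n_points = n_points)
  structure(curves, class = "normalized_set")
}

#' @export
print.normalized_set <- function(x, ...) {
  cat(sprintf("<normalized_set> %d curves on the %d-point grid\n",
              length(x), if (length(x)) x[[1]]$n_points else 0L))
  invisible(x)
}

#' Check that two normalised curves are comparable
#'
#' The symmetry function needs two curves of the same joint on the same
#' grid. Returns `TRUE`/`FALSE` (never an error) with a `reason` attribute
#' explaining a failure.
#'
#' @param first,second [normalized_curve()] objects (anything else is a
#'   diagnostic `FALSE`).
#' @return Logical scalar with attribute `reason` when `FALSE`.
#' @export
validate_pair <- function(first, second) {
  fail <- function(why) structure(FALSE, reason = why)
  if (!inherits(first, "normalized_curve") || !inherits(second, "normalized_curve"))
    return(fail("both inputs must be normalized curves"))
  if (first$n_points != second$n_points)
    return(fail(sprintf("grid length mismatch: %d vs %d",
                        first$n_points, second$n_points)))
  if (first$joint != second$joint)
    return(fail(sprintf("joint mismatch: %s vs %s", first$joint, second$joint)))
  TRUE
}
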