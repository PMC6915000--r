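# The symmetry function SF(t) and its parameterisation.
#
# SF(t) = (x1(t) - x2(t)) / (0.5 * (Range(x1) + Range(x2))) * 100%
#
# where Range(x) is the scalar max - min of the curve over the whole cycle.
# A constant denominator is the only reading under which the classic worked
# examples hold: a constant 1 deg side difference gives SF = 20% when each
# side's range is 5 deg and 2% when it is 50 deg, and two equal-range curves
# with opposite, simultaneous extremes touch +/-200%.

#' Range of motion of a curve
#'
#' The scalar `max - min` over the whole cycle — the denominator ingredient
#' of the symmetry function and the ROM parameter of angle curves.
#'
#' @param curve A [normalized_curve()], an SF curve, or a bare numeric
#'   vector of finite values.
#' @return Numeric scalar in the curve's units (degrees for angle curves).
#' @export
#' @examples
#' curve_range(c(-10.4, 0, 34.6))  # 45.0
curve_range <- function(curve) {
  v <- curve_values(curve)
  max(v) - min(v)
}

curve_values <- function(curve) {
  v <- if (is.numeric(curve)) curve else curve$values
  if (is.null(v) || !is.numeric(v))
    stop_gaitsf("gaitsf_input_error", "not a curve: no numeric values found")
  if (any(!is.finite(v)))
    stop_gaitsf("gaitsf_input_error", "curve values must be finite")
  v
}

#' The time-continuous symmetry function of two curves
#'
#' Computes SF(t) on the common %CT grid: the pointwise difference between
#' the first and second curve as a percentage of the mean of the two curves'
#' ranges of motion. Positive SF means the first curve runs higher (the
#' first side "dominates"); see [canonical_sign_labels()] for the standard
#' orderings. Scores near 0 indicate symmetry; equal-range curves of
#' opposite, simultaneous extremes reach the hypothetical bound of +/-200%.
#'
#' The index is intentionally normalised by the movement's own range, so a
#' fixed angular difference reads large against a small range (1 deg over a
#' 5 deg range is 20%) and small against a large one (1 deg over 50 deg is
#' 2%); curves whose combined range is below `eps` are rejected rather than
#' amplified into meaningless percentages.
#'
#' @param first,second [normalized_curve()] objects on the same grid and
#'   joint (see [validate_pair()]).
#' @param eps Degenerate-range guard in degrees: if
#'   `0.5 * (range(first) + range(second)) < eps` an error of class
#'   `gaitsf_degenerate_range` is raised.
#' @return An object of class `"sf_curve"`: list with `values` (percent, one
#'   per grid point), `pct_ct`, `first_label`, `second_label`, `joint`.
#' @export
#' @examples
#' a <- normalized_curve(2.5 + 2.5 * cos(2 * pi * (0:100) / 100), "pelvis_tilt")
#' b <- normalized_curve(a$values - 1, "pelvis_tilt")
#' unique(round(symmetry_function(a, b)$values, 10))  # constant 20%
symmetry_function <- function(first, second, eps = 1e-6) {
  ok <- validate_pair(first, second)
  if (!isTRUE(ok))
    stop_gaitsf("gaitsf_input_error", "incomparable curves: %s", attr(ok, "reason"))
  denom <- 0.5 * (curve_range(first) + curve_range(second))
  if (denom < eps)
    stop_gaitsf("gaitsf_degenerate_range",
                "mean range of motion %.3g deg is below eps = %.3g deg; SF is unstable for near-constant curves",
                denom, eps)
  structure(
    list(values = (first$values - second$values) / denom * 100,
         pct_ct = first$pct_ct,
         first_label = side_label(first), second_label = side_label(second),
         joint = first$joint, n_points = first$n_points),
    class = "sf_curve"
  )
}

side_label <- function(curve) {
  if (!is.na(curve$side)) as.character(curve$side)
  else if (!is.na(curve$group)) as.character(curve$group)
  else "curve"
}

#' @export
print.sf_curve <- function(x, ...) {
  cat(sprintf("<sf_curve> %s: %s - %s, peaks [%.1f, %.1f] %%\n",
              x$joint, x$first_label, x$second_label,
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.sf_curve <- function(x, ...) {
  data.frame(joint = x$joint, pct_ct = x$pct_ct, sf_percent = x$values,
             stringsAsFactors = FALSE)
}

#' Parameterise a curve: peaks, peak times and range
#'
#' Extracts the highest and lowest value reached by a curve, the %CT at
#' which each occurs (first occurrence on the grid when tied), and the range
#' `rom = peak_max - peak_min`. Applies identically to angle curves
#' (degrees) and SF curves (percent).
#'
#' @param curve A [normalized_curve()], `sf_curve`, or numeric vector
#'   (assumed to span 0--100%CT evenly).
#' @return An object of class `"curve_params"`: list with `peak_min`,
#'   `t_min`, `peak_max`, `t_max`, `rom`.
#' @export
#' @examples
#' p <- parameterize(normalized_curve(10 + 5 * cos(2 * pi * (0:100) / 100),
#'                                    "hip_flexext"))
#' p$rom  # 10
parameterize <- function(curve) {
  v <- curve_values(curve)
  grid <- if (is.numeric(curve)) seq(0, 100, length.out = length(v)) else curve$pct_ct
  i_min <- which.min(v)
  i_max <- which.max(v)
  structure(
    list(peak_min = v[i_min], t_min = grid[i_min],
         peak_max = v[i_max], t_max = grid[i_max],
         rom = v[i_max] - v[i_min]),
    class = "curve_params"
  )
}

#' @export
print.curve_params <- function(x, ...) {
  cat(sprintf("peak_min %.2f @ %.0f%%CT | peak_max %.2f @ %.0f%%CT | ROM %.2f\n",
              x$peak_min, x$t_min, x$peak_max, x$t_max, x$rom))
  invisible(x)
}

#' @export
as.data.frame.curve_params <- function(x, ...) {
  data.frame(peak_min = x$peak_min, t_min = x$t_min, peak_max = x$peak_max,
             t_max = x$t_max, rom = x$rom)
}

#' Classify asymmetry magnitude against the 10% / 15% conventions
#'
#' Symmetry-index magnitudes of 15% or more are conventionally associated
#' with injured gait, while non-injured populations typically stay below
#' 10%; the band between is reported as borderline. The default summary
#' statistic is the larger absolute SF peak (`peak_abs`); `mean_abs` (the
#' mean of |SF(t)| over the cycle, requiring the curve itself) is provided
#' as a smoother alternative.
#'
#' @param x A `curve_params` object from an SF curve (for `peak_abs`), or an
#'   `sf_curve` (either statistic).
#' @param statistic `"peak_abs"` (default) or `"mean_abs"`.
#' @return Character scalar `"symmetric"` (< 10), `"borderline"` (10--15) or
#'   `"asymmetric"` (>= 15), with the statistic's value in attribute
#'   `"value"`.
#' @export
#' @examples
#' classify_asymmetry(parameterize(c(rep(0, 100), 12)))
classify_asymmetry <- function(x, statistic = c("peak_abs", "mean_abs")) {
  statistic <- match.arg(statistic)
  s <- if (statistic == "peak_abs") {
    p <- if (inherits(x, "curve_params")) x else parameterize(x)
    max(abs(p$peak_min), abs(p$peak_max))
  } else {
    if (inherits(x, "curve_params"))
      stop_gaitsf("gaitsf_input_error",
                  "mean_abs needs the SF curve itself, not just its parameters")
    mean(abs(curve_values(x)))
  }
  label <- if (s < 10) "symmetric" else if (s < 15) "borderline" else "asymmetric"
  structure(label, value = s)
}

#' Fit the symmetry-function result for a pair of curves
#'
#' The main entry point for a single bilateral comparison: computes the SF
#' curve, parameterises it, locates the gait phase of each SF peak and
#' classifies the asymmetry magnitude. Returns a classed object with
#' `print`, `summary`, `coef` and `plot` methods.
#'
#' @inheritParams symmetry_function
#' @param statistic Summary statistic for [classify_asymmetry()].
#' @return Object of class `"gait_sf"`: list with `curve` (`sf_curve`),
#'   `params` (`curve_params` of the SF curve, percent), `peak_phases`
#'   (data frame: phase of the SF minimum and maximum), `classification`,
#'   `statistic`, `statistic_value`.
#' @export
#' @examples
#' grid <- (0:100) / 100
#' right <- normalized_curve(12 + 22 * cos(2 * pi * (grid - 0.9)), "hip_flexext",
#'                           side = "right")
#' left <- normalized_curve(12 + 20 * cos(2 * pi * (grid - 0.9)), "hip_flexext",
#'                          side = "left")
#' fit <- gait_sf(right, left)
#' fit
#' coef(fit)
gait_sf <- function(first, second, statistic = c("peak_abs", "mean_abs"),
                    eps = 1e-6) {
  statistic <- match.arg(statistic)
  curve <- symmetry_function(first, second, eps = eps)
  params <- parameterize(curve)
  cls <- classify_asymmetry(if (statistic == "peak_abs") params else curve,
                            statistic = statistic)
  res <- structure(
    list(curve = curve, params = params, peak_phases = NULL,
         classification = as.character(cls),
         statistic = statistic, statistic_value = attr(cls, "value")),
    class = "gait_sf"
  )
  annotate_phases(res)
}

#' Annotate an SF result with the gait phases of its peaks
#'
#' Fills `peak_phases` with the Perry phase containing the %CT of the SF
#' minimum and maximum — the instants of greatest one-sided dominance, used
#' to localise where in the cycle the asymmetry concentrates.
#'
#' @param result A `"gait_sf"` object.
#' @return The result with `peak_phases` set (data frame, rows `min`, `max`).
#' @export
annotate_phases <- function(result) {
  if (!inherits(result, "gait_sf"))
    stop_gaitsf("gaitsf_input_error", "annotate_phases expects a gait_sf result")
  ph <- locate_phase(c(result$params$t_min, result$params$t_max))
  ph$peak <- c("min", "max")
  result$peak_phases <- ph[, c("peak", "pct_ct", "phase", "ic_flag")]
  result
}

#' @export
print.gait_sf <- function(x, ...) {
  cat(sprintf("Symmetry function: %s (%s - %s)\n", x$curve$joint,
              x$curve$first_label, x$curve$second_label))
  cat(sprintf("  SF peaks: %.1f%% at %.0f%%CT (%s), %.1f%% at %.0f%%CT (%s); range %.1f%%\n",
              x$params$peak_min, x$params$t_min, x$peak_phases$phase[1],
              x$params$peak_max, x$params$t_max, x$peak_phases$phase[2],
              x$params$rom))
  cat(sprintf("  %s (%s = %.1f%%)\n", x$classification, x$statistic,
              x$statistic_value))
  invisible(x)
}

#' @export
coef.gait_sf <- function(object, ...) {
  p <- object$params
  c(peak_min = p$peak_min, t_min = p$t_min, peak_max = p$peak_max,
    t_max = p$t_max, rom = p$rom)
}

#' @export
summary.gait_sf <- function(object, ...) {
  out <- list(
    joint = object$curve$joint,
    labels = c(first = object$curve$first_label,
               second = object$curve$second_label),
    params = as.data.frame(object$params),
    peak_phases = object$peak_phases,
    classification = object$classification,
    statistic = object$statistic,
    statistic_value = object$statistic_value,
    mean_abs_sf = mean(abs(object$curve$values))
  )
  class(out) <- "summary.gait_sf"
  out
}

#' @export
print.summary.gait_sf <- function(x, ...) {
  cat(sprintf("Symmetry function for %s (positive = %s dominance)\n",
              x$joint, x$labels[["first"]]))
  print(round(x$params, 2), row.names = FALSE)
  cat("Peak phases:\n")
  print(x$peak_phases, row.names = FALSE)
  cat(sprintf("Mean |SF| over the cycle: %.2f%%\n", x$mean_abs_sf))
  cat(sprintf("Classification (%s = %.1f%%): %s\n", x$statistic,
              x$statistic_value, x$classification))
  invisible(x)
}

#' @export
plot.gait_sf <- function(x, shade_phases = TRUE, ...) {
  v <- x$curve$values
  plot(x$curve$pct_ct, v, type = "n",
       xlab = "gait cycle (%CT)", ylab = "SF (%)",
       main = sprintf("%s: %s - %s", x$curve$joint, x$curve$first_label,
                      x$curve$second_label), ...)
  if (shade_phases) {
    ph <- perry_phases()
    usr <- graphics::par("usr")
    shade <- rep(c(NA, "grey92"), length.out = nrow(ph))
    for (i in seq_len(nrow(ph))) {
      if (!is.na(shade[i]))
        graphics::rect(ph$start_pct[i], usr[3], ph$end_pct[i], usr[4],
                       col = shade[i], border = NA)
      graphics::mtext(ph$phase[i], side = 3, line = 0, cex = 0.6,
                      at = (ph$start_pct[i] + ph$end_pct[i]) / 2)
    }
  }
  graphics::abline(h = 0, col = "grey50")
  graphics::abline(h = c(-10, 10), col = "grey70", lty = 3)
  graphics::lines(x$curve$pct_ct, v, lwd = 2)
  graphics::points(c(x$params$t_min, x$params$t_max),
                   c(x$params$peak_min, x$params$peak_max), pch = 19)
  invisible(x)
}
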