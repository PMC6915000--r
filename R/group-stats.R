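# Ensemble averaging of curves and the cohort statistical protocol:
# Shapiro-Wilk normality screen, then paired (between sides) or Welch
# (between groups) t-tests on curve parameters.

#' Pointwise ensemble mean and SD of curves
#'
#' Averages a collection of curves on a common grid, the construction behind
#' mean +/- SD kinematic bands. A single curve yields itself with `sd = 0`.
#'
#' @param curves List of [normalized_curve()] (or `sf_curve`) objects of the
#'   same joint and grid, or a numeric matrix with one column per curve.
#' @return Object of class `"ensemble_curve"`: `mean`, `sd` (pointwise,
#'   unbiased), `n`, `pct_ct`, `joint`.
#' @export
ensemble <- function(curves) {
  if (is.matrix(curves)) {
    mat <- curves
    joint <- NA_character_
    grid <- seq(0, 100, length.out = nrow(mat))
  } else {
    if (!length(curves))
      stop_gaitsf("gaitsf_input_error", "cannot ensemble an empty curve list")
    joints <- unique(vapply(curves, function(c) c$joint %||% NA_character_, ""))
    lens <- unique(vapply(curves, function(c) length(c$values), 0L))
    if (length(lens) != 1)
      stop_gaitsf("gaitsf_input_error", "curves have differing grid lengths")
    if (length(joints) != 1)
      stop_gaitsf("gaitsf_input_error", "curves mix joints: %s",
                  paste(joints, collapse = ", "))
    mat <- vapply(curves, function(c) c$values, numeric(lens))
    joint <- joints
    grid <- curves[[1]]$pct_ct
  }
  n <- ncol(mat)
  if (is.null(n) || n == 0)
    stop_gaitsf("gaitsf_input_error", "cannot ensemble an empty curve list")
  structure(
    list(mean = rowMeans(mat),
         sd = if (n > 1) apply(mat, 1, stats::sd) else rep(0, nrow(mat)),
         n = n, pct_ct = grid, joint = joint),
    class = "ensemble_curve"
  )
}

#' @export
print.ensemble_curve <- function(x, ...) {
  cat(sprintf("<ensemble_curve> %s: n = %d, mean range %.2f, max SD %.2f\n",
              x$joint, x$n, max(x$mean) - min(x$mean), max(x$sd)))
  invisible(x)
}

#' @export
plot.ensemble_curve <- function(x, band = TRUE, col = "steelblue", ...) {
  lo <- x$mean - x$sd
  hi <- x$mean + x$sd
  plot(x$pct_ct, x$mean, type = "n", ylim = range(lo, hi),
       xlab = "gait cycle (%CT)", ylab = "angle (deg)",
       main = x$joint, ...)
  if (band)
    graphics::polygon(c(x$pct_ct, rev(x$pct_ct)), c(lo, rev(hi)),
                      col = grDevices::adjustcolor(col, 0.3), border = NA)
  graphics::lines(x$pct_ct, x$mean, col = col, lwd = 2)
  invisible(x)
}

# Convert an ensemble mean back to a normalized_curve (for mean-curve SF).
ensemble_mean_curve <- function(e, side = NA_character_, group = NA_character_,
                                subject_id = NA_character_) {
  normalized_curve(e$mean, joint = e$joint, side = side, group = group,
                   subject_id = subject_id, n_points = length(e$mean))
}

#' Compare curve parameters between two samples
#'
#' Runs, per parameter, the cohort protocol: a Shapiro-Wilk normality check
#' on each sample, then a parametric t-test — paired for side comparisons
#' (both sides measured on the same subjects), Welch two-sample for group
#' comparisons. A non-normal sample (Shapiro p < alpha) does not switch the
#' test; it flags the row as `assumption_violated` and emits a warning.
#'
#' @param a,b Data frames (or named lists) of per-subject parameter values
#'   with matching numeric columns, e.g. the output of
#'   [group_param_table()]'s per-subject stage or any subset of
#'   `peak_min`, `t_min`, `peak_max`, `t_max`, `rom`. For `paired = TRUE`
#'   rows must correspond to the same subjects in the same order.
#' @param paired Paired t-test (sides) or Welch two-sample (groups).
#' @param alpha Significance level for both the normality screen and the
#'   t-test flag.
#' @return Data frame with one row per parameter: sample sizes and means,
#'   Shapiro p-values, `statistic`, `df`, `p_value`, `significant`,
#'   `assumption_violated`.
#' @export
#' @examples
#' a <- data.frame(rom = rnorm(12, 45, 1))
#' b <- data.frame(rom = rnorm(12, 35, 1))
#' compare_params(a, b, paired = TRUE)
compare_params <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- as.data.frame(a)
  b <- as.data.frame(b)
  pars <- intersect(names(a), names(b))
  pars <- pars[vapply(pars, function(p) is.numeric(a[[p]]), TRUE)]
  if (!length(pars))
    stop_gaitsf("gaitsf_input_error", "no common numeric parameter columns")
  if (nrow(a) < 3 || nrow(b) < 3)
    stop_gaitsf("gaitsf_insufficient_data",
                "need at least 3 observations per sample (got %d and %d)",
                nrow(a), nrow(b))
  if (paired && nrow(a) != nrow(b))
    stop_gaitsf("gaitsf_input_error", "paired comparison needs equal sample sizes")
  rows <- lapply(pars, function(p) {
    xa <- a[[p]]
    xb <- b[[p]]
    sw_a <- shapiro_p(xa)
    sw_b <- shapiro_p(xb)
    violated <- (!is.na(sw_a) && sw_a < alpha) || (!is.na(sw_b) && sw_b < alpha)
    ht <- safe_t_test(xa, xb, paired = paired)
    data.frame(parameter = p, n_a = length(xa), n_b = length(xb),
               mean_a = mean(xa), mean_b = mean(xb),
               shapiro_p_a = sw_a, shapiro_p_b = sw_b,
               statistic = ht$statistic, df = ht$df, p_value = ht$p,
               significant = ht$p < alpha,
               assumption_violated = violated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$assumption_violated))
    warning(sprintf(
      "parametric assumption violated (Shapiro-Wilk p < %.2g) for: %s; t-test reported regardless",
      alpha, paste(out$parameter[out$assumption_violated], collapse = ", ")))
  out
}

shapiro_p <- function(x) {
  if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0) return(NA_real_)
  stats::shapiro.test(x)$p.value
}

# t.test errors on essentially-constant data; identical samples are a
# legitimate degenerate input (difference 0) and should read as p = 1.
safe_t_test <- function(xa, xb, paired) {
  degenerate <- if (paired) stats::sd(xa - xb) < 1e-12
                else stats::sd(xa) < 1e-12 && stats::sd(xb) < 1e-12 &&
                     abs(mean(xa) - mean(xb)) < 1e-12
  if (degenerate)
    return(list(statistic = 0, df = if (paired) length(xa) - 1 else NA_real_,
                p = 1))
  ht <- stats::t.test(xa, xb, paired = paired, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
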