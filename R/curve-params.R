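# Per-side angle-curve parameterisation and the group-level summary table.

#' Parameterise an angle curve
#'
#' [parameterize()] applied to a joint-angle curve: peak flexion/extension
#' values in degrees, their timing in %GC and the range of motion. Shared
#' implementation with SF-curve parameterisation; this wrapper additionally
#' insists on an angle curve so units stay unambiguous.
#'
#' @param curve A [normalized_curve()].
#' @return A `curve_params` object (degrees / %GC).
#' @export
angle_params <- function(curve) {
  if (!inherits(curve, "normalized_curve"))
    stop_gaitsf("gaitsf_input_error", "angle_params expects a normalized_curve")
  parameterize(curve)
}

params_per_curve <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    cbind(
      data.frame(subject_id = cv$subject_id, group = cv$group, side = cv$side,
                 joint = cv$joint, cycle_index = cv$cycle_index,
                 stringsAsFactors = FALSE),
      as.data.frame(parameterize(cv))
    )
  }))
}

#' Group summary table of curve parameters
#'
#' Builds the classic cohort table: mean and standard deviation of each
#' curve parameter (peak_min, t_min, peak_max, t_max, rom) per
#' (group, side, joint). Aggregation order is fixed: parameters are
#' extracted per cycle, averaged within subject, then summarised across
#' subjects with the unbiased sample SD — so every subject carries equal
#' weight regardless of how many cycles were recorded. A cell with a single
#' subject reports `sd = NA` and is flagged.
#'
#' Peak times are averaged linearly in %GC (no circular statistics), so
#' means of peaks that straddle the 0/100%CT wrap should be read with care.
#'
#' @param set A `normalized_set` (see [normalize_set()]) or [subject_set()]
#'   (normalised on the fly).
#' @return Data frame with one row per (group, side, joint, parameter):
#'   columns `group`, `side`, `joint`, `parameter`, `mean`, `sd`,
#'   `n_subjects`, `single_subject`.
#' @export
group_param_table <- function(set) {
  if (inherits(set, "subject_set")) set <- normalize_set(set)
  if (!inherits(set, "normalized_set"))
    stop_gaitsf("gaitsf_input_error", "group_param_table expects a normalized_set or subject_set")
  per_cycle <- params_per_curve(set)
  pars <- c("peak_min", "t_min", "peak_max", "t_max", "rom")
  # per-cycle -> subject means
  subj <- stats::aggregate(per_cycle[pars],
                           per_cycle[c("subject_id", "group", "side", "joint")],
                           mean)
  # subject means -> group mean +/- SD
  rows <- lapply(split(subj, subj[c("group", "side", "joint")], drop = TRUE),
                 function(d) {
    data.frame(group = d$group[1], side = d$side[1], joint = d$joint[1],
               parameter = pars,
               mean = vapply(pars, function(p) mean(d[[p]]), 0),
               sd = vapply(pars, function(p)
                 if (nrow(d) > 1) stats::sd(d[[p]]) else NA_real_, 0),
               n_subjects = nrow(d),
               single_subject = nrow(d) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$joint, out$group, out$side, match(out$parameter, pars)), ]
}

#' Wide export of a group parameter table
#'
#' Reshapes [group_param_table()] output into the report layout: one row
#' per (joint, parameter), one `mean (sd)` column per (group, side).
#'
#' @param table Output of [group_param_table()].
#' @param digits Rounding for display.
#' @return Data frame in wide layout.
#' @export
param_table_wide <- function(table, digits = 2) {
  table$cell <- sprintf("%.*f ± %.*f", digits, table$mean, digits,
                        ifelse(is.na(table$sd), 0, table$sd))
  table$col <- paste(table$group, table$side, sep = ".")
  wide <- stats::reshape(
    table[, c("joint", "parameter", "col", "cell")],
    idvar = c("joint", "parameter"), timevar = "col", direction = "wide"
  )
  names(wide) <- sub("^cell\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
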