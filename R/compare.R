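# Cohort-level SF comparisons: per-subject SF (then summarised across
# subjects) or SF of group-mean curves, per joint, under the standard sign
# conventions.

subject_side_curves <- function(set) {
  if (inherits(set, "subject_set")) set <- normalize_set(set)
  if (!inherits(set, "normalized_set"))
    stop_gaitsf("gaitsf_input_error", "expected a subject_set or normalized_set")
  meta <- data.frame(
    subject_id = vapply(set, function(c) c$subject_id, ""),
    group = vapply(set, function(c) c$group, ""),
    side = vapply(set, function(c) c$side, ""),
    joint = vapply(set, function(c) c$joint, ""),
    stringsAsFactors = FALSE
  )
  out <- list()
  for (key in unique(paste(meta$subject_id, meta$side, meta$joint, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sel <- which(meta$subject_id == parts[1] & meta$side == parts[2] &
                 meta$joint == parts[3])
    e <- ensemble(set[sel])
    out[[length(out) + 1L]] <- ensemble_mean_curve(
      e, side = parts[2], group = meta$group[sel[1]], subject_id = parts[1])
  }
  structure(out, class = "normalized_set")
}

resolve_side <- function(curves_meta, label) {
  # "right"/"left" and "involved"/"uninvolved" are interchangeable
  # vocabularies; a comparison asks for one label and matches it literally.
  curves_meta$side == label
}

#' Cohort symmetry-function comparison
#'
#' Runs the full SF pipeline for each joint of a cohort under one of the
#' three standard comparison modes (see [canonical_sign_labels()]):
#' `normal_LR` (right minus left within healthy subjects), `uTHR_sides`
#' (uninvolved minus involved within patients) and `uTHR_vs_normal`
#' (normative reference minus involved side, needing a `reference` cohort).
#'
#' Two aggregation modes are provided because cohort-mean SF curves can be
#' built either way: `per_subject` computes one SF per subject from the
#' subject's cycle-mean side curves, then summarises SF parameters across
#' subjects (mean, SD) and ensembles the SF curves; `mean_curve` first
#' ensembles each side's curves across the whole cohort and compares the
#' two mean curves once.
#'
#' @param set A [subject_set()] or `normalized_set` to analyse.
#' @param mode Comparison mode, see above.
#' @param aggregate `"per_subject"` or `"mean_curve"`.
#' @param reference For `uTHR_vs_normal`: the healthy cohort whose
#'   ensemble-mean curve (side `reference_side`) is the norm.
#' @param reference_side Side of the reference cohort used as the norm
#'   (default `"right"`).
#' @param statistic Classification statistic, see [classify_asymmetry()].
#' @return Object of class `"sf_comparison"`: `mode`, `aggregate`,
#'   `labels`, `joints` (per-joint list with `sf` ([gait_sf()] of the mean
#'   comparison), `sf_ensemble` (per-subject mode only) and `per_subject`
#'   parameter rows), plus a stacked `per_subject` data frame and a
#'   `summary` data frame of SF parameters (mean, sd across subjects).
#' @export
#' @examples
#' coh <- preset_cohort("uTHR", n_subjects = 3, seed = 7, n_cycles = 2)
#' cmp <- sf_compare(coh, mode = "uTHR_sides")
#' cmp$summary[cmp$summary$parameter == "rom", ]
sf_compare <- function(set, mode = c("normal_LR", "uTHR_sides", "uTHR_vs_normal"),
                       aggregate = c("per_subject", "mean_curve"),
                       reference = NULL, reference_side = "right",
                       statistic = "peak_abs") {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  labels <- canonical_sign_labels(mode)
  curves <- subject_side_curves(set)
  meta <- data.frame(
    subject_id = vapply(curves, function(c) c$subject_id, ""),
    side = vapply(curves, function(c) c$side, ""),
    joint = vapply(curves, function(c) c$joint, ""),
    stringsAsFactors = FALSE
  )
  ref_curves <- NULL
  if (mode == "uTHR_vs_normal") {
    if (is.null(reference))
      stop_gaitsf("gaitsf_config_error",
                  "mode uTHR_vs_normal needs a healthy `reference` cohort")
    rc <- subject_side_curves(reference)
    rmeta <- data.frame(
      side = vapply(rc, function(c) c$side, ""),
      joint = vapply(rc, function(c) c$joint, ""),
      stringsAsFactors = FALSE
    )
    ref_curves <- lapply(stats::setNames(nm = unique(rmeta$joint)), function(j) {
      sel <- which(rmeta$joint == j & rmeta$side == reference_side)
      if (!length(sel)) return(NULL)
      cv <- ensemble_mean_curve(ensemble(rc[sel]), side = "normal",
                                group = "normal")
      cv
    })
  }
  joints <- sort(unique(meta$joint))
  per_joint <- list()
  per_subject_rows <- list()
  for (j in joints) {
    if (mode == "uTHR_vs_normal") {
      first_of <- function(sel) ref_curves[[j]]
      second_label <- labels[["second"]]
    } else {
      second_label <- labels[["second"]]
    }
    subjects <- unique(meta$subject_id[meta$joint == j])
    fits <- list()
    for (s in subjects) {
      i2 <- which(meta$joint == j & meta$subject_id == s &
                  meta$side == second_label)
      if (mode == "uTHR_vs_normal") {
        if (is.null(ref_curves[[j]]) || !length(i2)) next
        first <- ref_curves[[j]]
      } else {
        i1 <- which(meta$joint == j & meta$subject_id == s &
                    meta$side == labels[["first"]])
        if (!length(i1) || !length(i2)) next
        first <- curves[[i1]]
      }
      fits[[s]] <- gait_sf(first, curves[[i2]], statistic = statistic)
    }
    if (!length(fits)) next
    if (aggregate == "per_subject") {
      ps <- do.call(rbind, lapply(names(fits), function(s) {
        f <- fits[[s]]
        cbind(data.frame(subject_id = s, joint = j,
                         stringsAsFactors = FALSE),
              as.data.frame(f$params),
              data.frame(peak_abs = max(abs(f$params$peak_min),
                                        abs(f$params$peak_max)),
                         classification = f$classification,
                         stringsAsFactors = FALSE))
      }))
      sf_ens <- ensemble(lapply(fits, function(f) f$curve))
      # SF result of the ensemble-mean SF curve, for reporting/plotting
      mean_sf <- structure(
        list(values = sf_ens$mean, pct_ct = sf_ens$pct_ct,
             first_label = labels[["first"]], second_label = second_label,
             joint = j, n_points = length(sf_ens$mean)),
        class = "sf_curve")
      params <- parameterize(mean_sf)
      cls <- classify_asymmetry(params)
      fit <- structure(
        list(curve = mean_sf, params = params, peak_phases = NULL,
             classification = as.character(cls), statistic = "peak_abs",
             statistic_value = attr(cls, "value")),
        class = "gait_sf")
      fit <- annotate_phases(fit)
      per_joint[[j]] <- list(sf = fit, sf_ensemble = sf_ens,
                             per_subject = ps, fits = fits)
      per_subject_rows[[j]] <- ps
    } else {
      if (mode == "uTHR_vs_normal") {
        first <- ref_curves[[j]]
        sel2 <- which(meta$joint == j & meta$side == second_label)
        second <- ensemble_mean_curve(ensemble(curves[sel2]),
                                      side = second_label)
      } else {
        sel1 <- which(meta$joint == j & meta$side == labels[["first"]])
        sel2 <- which(meta$joint == j & meta$side == second_label)
        if (!length(sel1) || !length(sel2)) next
        first <- ensemble_mean_curve(ensemble(curves[sel1]),
                                     side = labels[["first"]])
        second <- ensemble_mean_curve(ensemble(curves[sel2]),
                                      side = second_label)
      }
      per_joint[[j]] <- list(sf = gait_sf(first, second,
                                          statistic = statistic))
    }
  }
  if (!length(per_joint))
    stop_gaitsf("gaitsf_input_error",
                "no comparable side pairs found for mode %s", mode)
  summary_df <- NULL
  if (length(per_subject_rows)) {
    ps_all <- do.call(rbind, per_subject_rows)
    rownames(ps_all) <- NULL
    pars <- c("peak_min", "t_min", "peak_max", "t_max", "rom", "peak_abs")
    summary_df <- do.call(rbind, lapply(split(ps_all, ps_all$joint), function(d)
      data.frame(joint = d$joint[1], parameter = pars,
                 mean = vapply(pars, function(p) mean(d[[p]]), 0),
                 sd = vapply(pars, function(p)
                   if (nrow(d) > 1) stats::sd(d[[p]]) else NA_real_, 0),
                 n_subjects = nrow(d), stringsAsFactors = FALSE)))
    rownames(summary_df) <- NULL
  } else ps_all <- NULL
  structure(
    list(mode = mode, aggregate = aggregate, labels = labels,
         joints = per_joint, per_subject = ps_all, summary = summary_df),
    class = "sf_comparison"
  )
}

#' @export
print.sf_comparison <- function(x, ...) {
  cat(sprintf("<sf_comparison> mode %s (positive = %s dominance), aggregate %s\n",
              x$mode, x$labels[["first"]], x$aggregate))
  for (j in names(x$joints)) {
    f <- x$joints[[j]]$sf
    cat(sprintf("  %-20s SF peaks [%.1f, %.1f]%% -> %s\n", j,
                f$params$peak_min, f$params$peak_max, f$classification))
  }
  invisible(x)
}
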