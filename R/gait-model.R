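# Domain layer: joints, sides, groups, the Perry gait-phase taxonomy and the
# per-cycle / per-curve containers shared by every other module.

#' Recognised joint, side and group labels
#'
#' The package analyses four sagittal-plane angles. Side labels come in two
#' vocabularies: anatomical (`right`/`left`) for healthy cohorts and clinical
#' (`involved`/`uninvolved`) for unilateral patients; they are interchangeable
#' everywhere, with the mapping of involved to left or right recorded in the
#' input metadata, not inferred.
#'
#' @format Character vectors.
#' @name gait_vocabulary
#' @keywords internal
NULL

gait_joints <- c("pelvis_tilt", "hip_flexext", "knee_flexext", "ankle_dorsiplantar")
gait_sides  <- c("right", "left", "involved", "uninvolved")
gait_groups <- c("uTHR", "normal")

#' Perry gait-phase boundaries
#'
#' The eight phases of the gait cycle in percent cycle time (%CT):
#' loading response LR 0--10, midstance MSt 10--30, terminal stance TSt
#' 30--50, terminal double stance TDSt 50--60, initial swing ISw 60--73,
#' midswing MSw 73--87, terminal swing TSw 87--100. Initial contact IC
#' (0--2%CT) overlaps LR and is carried as a flag rather than a ninth
#' disjoint phase. Intervals are half-open `[start, end)` with 100%CT
#' assigned to TSw.
#'
#' @return A data frame with columns `phase`, `start_pct`, `end_pct`.
#' @seealso [locate_phase()]
#' @export
#' @examples
#' perry_phases()
perry_phases <- function() {
  data.frame(
    phase     = c("LR", "MSt", "TSt", "TDSt", "ISw", "MSw", "TSw"),
    start_pct = c(0, 10, 30, 50, 60, 73, 87),
    end_pct   = c(10, 30, 50, 60, 73, 87, 100),
    stringsAsFactors = FALSE
  )
}

#' Locate the gait phase of a cycle-time instant
#'
#' Maps %CT values to the Perry phase containing them. Phases are half-open
#' intervals `[start, end)`; `t = 100` maps to terminal swing. Instants at or
#' below 2%CT additionally carry `ic_flag = TRUE` because initial contact
#' (0--2%CT) overlaps loading response.
#'
#' @param t Numeric vector of cycle-time instants in %CT, each in `[0, 100]`.
#' @return A data frame with one row per instant: `pct_ct`, `phase`,
#'   `start_pct`, `end_pct`, `ic_flag`.
#' @export
#' @examples
#' locate_phase(c(0, 20, 54, 87, 100))
locate_phase <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)))
    stop_gaitsf("gaitsf_input_error", "phase lookup needs finite numeric %%CT values")
  if (any(t < 0 | t > 100))
    stop_gaitsf("gaitsf_range_error", "cycle-time instant outside [0, 100] %%CT")
  ph <- perry_phases()
  idx <- findInterval(t, ph$start_pct)  # [start, end); t = 100 falls in TSw
  data.frame(
    pct_ct    = t,
    phase     = ph$phase[idx],
    start_pct = ph$start_pct[idx],
    end_pct   = ph$end_pct[idx],
    ic_flag   = t <= 2,
    stringsAsFactors = FALSE
  )
}

#' Sign convention labels for a comparison mode
#'
#' The symmetry function is signed: positive SF means the first curve runs
#' higher. Each comparison mode fixes which side is "first":
#' healthy left-right comparisons put `right` first (positive SF = right-side
#' dominance), within-patient comparisons put `uninvolved` first, and
#' patient-versus-norm comparisons put the `normal` reference first.
#'
#' @param comparison_mode One of `"normal_LR"`, `"uTHR_sides"`,
#'   `"uTHR_vs_normal"`.
#' @return Named character vector with elements `first` and `second`.
#' @export
#' @examples
#' canonical_sign_labels("uTHR_sides")
canonical_sign_labels <- function(comparison_mode) {
  switch(comparison_mode,
    normal_LR      = c(first = "right",      second = "left"),
    uTHR_sides     = c(first = "uninvolved", second = "involved"),
    uTHR_vs_normal = c(first = "normal",     second = "involved"),
    stop_gaitsf("gaitsf_config_error",
                "unknown comparison mode '%s'", comparison_mode)
  )
}

#' One side's joint-angle trace over one gait cycle
#'
#' Constructor and validator for the per-cycle container. Times are raw
#' seconds (or already-%CT values for pre-normalised input); the first and
#' last samples define 0 and 100%CT — cycle segmentation is the caller's
#' responsibility.
#'
#' @param time Numeric vector of sample times, strictly increasing, length
#'   >= 4.
#' @param angle Numeric vector of joint angles in degrees, same length,
#'   all finite.
#' @param subject_id Subject identifier (character scalar).
#' @param group `"uTHR"` or `"normal"`.
#' @param side One of `r paste0('"', gait_sides, '"', collapse = ", ")`.
#' @param joint One of `r paste0('"', gait_joints, '"', collapse = ", ")`.
#' @param cycle_index Integer cycle number within the subject/side/joint.
#' @return An object of class `"angle_cycle"`.
#' @export
#' @examples
#' tm <- seq(0, 1.1, by = 1 / 120)
#' angle_cycle(tm, 20 * sin(2 * pi * tm / 1.1), "S01", "normal", "right",
#'             "hip_flexext", 1)
angle_cycle <- function(time, angle, subject_id, group, side, joint,
                        cycle_index = 1L) {
  time <- as.numeric(time)
  angle <- as.numeric(angle)
  if (length(time) != length(angle))
    stop_gaitsf("gaitsf_input_error", "time and angle lengths differ")
  if (length(time) < 4)
    stop_gaitsf("gaitsf_insufficient_data",
                "a cycle needs at least 4 samples, got %d", length(time))
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop_gaitsf("gaitsf_input_error", "sample times must be finite and strictly increasing")
  if (any(!is.finite(angle)))
    stop_gaitsf("gaitsf_input_error", "angles must be finite")
  group <- match.arg(group, gait_groups)
  side  <- match.arg(side, gait_sides)
  joint <- match.arg(joint, gait_joints)
  structure(
    list(time = time, angle = angle,
         subject_id = as.character(subject_id), group = group, side = side,
         joint = joint, cycle_index = as.integer(cycle_index)),
    class = "angle_cycle"
  )
}

#' @export
print.angle_cycle <- function(x, ...) {
  cat(sprintf("<angle_cycle> %s %s %s/%s cycle %d: %d samples over %.3f s\n",
              x$subject_id, x$joint, x$group, x$side, x$cycle_index,
              length(x$time), diff(range(x$time))))
  invisible(x)
}

#' A time-normalised angle curve on the canonical %CT grid
#'
#' Holds the 101 angle values (one per 1%CT from 0 to 100) produced by
#' [time_normalize()], plus the metadata carried over from the source cycle.
#' `n_points` other than 101 is supported for testing only.
#'
#' @param values Numeric vector of angles in degrees, length `n_points`,
#'   all finite.
#' @param joint,side,subject_id,group Metadata carried with the curve.
#' @param cycle_index Integer cycle number (NA for aggregated curves).
#' @param n_points Grid length; the canonical grid has 101 points.
#' @return An object of class `"normalized_curve"`.
#' @export
normalized_curve <- function(values, joint, side = NA_character_,
                             subject_id = NA_character_,
                             group = NA_character_, cycle_index = NA_integer_,
                             n_points = 101L) {
  values <- as.numeric(values)
  if (length(values) != n_points)
    stop_gaitsf("gaitsf_input_error",
                "expected %d grid values, got %d", n_points, length(values))
  if (any(!is.finite(values)))
    stop_gaitsf("gaitsf_input_error", "curve values must be finite")
  joint <- match.arg(joint, gait_joints)
  structure(
    list(values = values,
         pct_ct = seq(0, 100, length.out = n_points),
         joint = joint, side = side, subject_id = subject_id, group = group,
         cycle_index = cycle_index, n_points = as.integer(n_points)),
    class = "normalized_curve"
  )
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("<normalized_curve> %s [%s %s %s]: %d points, range %.2f deg\n",
              x$joint, x$group, x$side,
              x$subject_id, x$n_points, diff(range(x$values))))
  invisible(x)
}

#' @export
as.data.frame.normalized_curve <- function(x, ...) {
  data.frame(subject_id = x$subject_id, group = x$group, side = x$side,
             joint = x$joint, cycle_index = x$cycle_index,
             pct_ct = x$pct_ct, angle_deg = x$values,
             stringsAsFactors = FALSE)
}

#' A collection of measured gait cycles
#'
#' Thin container around a list of [angle_cycle()] objects, as produced by
#' [read_cycles()] or [simulate_subject()]/[preset_cohort()].
#'
#' @param cycles List of `angle_cycle` objects.
#' @return An object of class `"subject_set"`.
#' @export
subject_set <- function(cycles) {
  if (!length(cycles) || !all(vapply(cycles, inherits, TRUE, "angle_cycle")))
    stop_gaitsf("gaitsf_input_error", "subject_set needs a non-empty list of angle_cycle objects")
  structure(list(cycles = cycles), class = "subject_set")
}

set_meta <- function(set) {
  cy <- set$cycles
  data.frame(
    idx = seq_along(cy),
    subject_id = vapply(cy, function(c) c$subject_id, ""),
    group = vapply(cy, function(c) c$group, ""),
    side = vapply(cy, function(c) c$side, ""),
    joint = vapply(cy, function(c) c$joint, ""),
    cycle_index = vapply(cy, function(c) c$cycle_index, 1L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.subject_set <- function(x, ...) {
  m <- set_meta(x)
  cat(sprintf("<subject_set> %d cycles, %d subject(s), joints: %s\n",
              nrow(m), length(unique(m$subject_id)),
              paste(sort(unique(m$joint)), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.subject_set <- function(x, ...) {
  do.call(rbind, lapply(x$cycles, function(c) {
    data.frame(subject_id = c$subject_id, group = c$group, side = c$side,
               joint = c$joint, cycle_index = c$cycle_index,
               time_s = c$time, angle_deg = c$angle, stringsAsFactors = FALSE)
  }))
}
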