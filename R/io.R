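# Long-format CSV input/output and report writing. All files use '.' as
# decimal separator, UTF-8, '\n' line endings; doubles are written with
# round-trip precision (%.17g).

required_id_cols <- c("subject_id", "group", "side", "joint", "cycle_index")

#' Read gait cycles from long-format CSV
#'
#' Expects a header with columns `subject_id`, `group`, `side`, `joint`,
#' `cycle_index` and either `time_s` + `angle_deg` (raw timestamps) or
#' `pct_ct` + `angle_deg` (pre-normalised percent-cycle samples). A
#' `pct_ct` trace that is not exactly the canonical 0--100 integer grid is
#' accepted with a warning and re-normalised downstream.
#'
#' @param path CSV file path.
#' @return A [subject_set()].
#' @export
read_cycles <- function(path) {
  if (!file.exists(path))
    stop_gaitsf("gaitsf_io_error", "input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  have <- names(df)
  missing_id <- setdiff(required_id_cols, have)
  if (length(missing_id))
    stop_gaitsf("gaitsf_schema_error", "missing column(s): %s",
                paste(missing_id, collapse = ", "))
  time_col <- if ("time_s" %in% have) "time_s"
              else if ("pct_ct" %in% have) "pct_ct"
              else stop_gaitsf("gaitsf_schema_error",
                               "need a time_s or pct_ct column")
  if (!"angle_deg" %in% have)
    stop_gaitsf("gaitsf_schema_error", "missing column(s): angle_deg")
  if (!is.numeric(df$angle_deg) || any(!is.finite(df$angle_deg)))
    stop_gaitsf("gaitsf_schema_error",
                "non-numeric or non-finite angle_deg at row(s): %s",
                row_list(which(!is.finite(suppressWarnings(as.numeric(df$angle_deg))))))
  if (!is.numeric(df[[time_col]]))
    stop_gaitsf("gaitsf_schema_error", "non-numeric %s column", time_col)
  key <- paste(df$subject_id, df$side, df$joint, df$cycle_index, df[[time_col]],
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop_gaitsf("gaitsf_schema_error",
                "duplicated (subject, side, joint, cycle, time) key at row(s): %s",
                row_list(dup))
  grp_key <- paste(df$subject_id, df$group, df$side, df$joint, df$cycle_index,
                   sep = "\r")
  cycles <- lapply(split(seq_len(nrow(df)), grp_key), function(sel) {
    d <- df[sel, ]
    d <- d[order(d[[time_col]]), ]
    if (time_col == "pct_ct" &&
        !(nrow(d) == 101 && isTRUE(all.equal(d$pct_ct, 0:100))))
      warning(sprintf(
        "pct_ct trace %s/%s/%s cycle %s is not the canonical 0-100 grid (%d points); re-normalizing",
        d$subject_id[1], d$side[1], d$joint[1], d$cycle_index[1], nrow(d)))
    angle_cycle(d[[time_col]], d$angle_deg, d$subject_id[1], d$group[1],
                d$side[1], d$joint[1], d$cycle_index[1])
  })
  names(cycles) <- NULL
  subject_set(cycles)
}

row_list <- function(rows, max_show = 10) {
  rows <- rows + 1L  # header line
  shown <- paste(utils::head(rows, max_show), collapse = ", ")
  if (length(rows) > max_show) shown <- paste0(shown, ", ...")
  shown
}

# Round-trip-precise CSV writer ('.' decimal, '\n', UTF-8, %.17g doubles).
write_csv_precise <- function(df, path) {
  fmt_col <- function(x) {
    if (is.double(x)) sprintf("%.17g", x)
    else as.character(x)
  }
  cols <- lapply(df, fmt_col)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a subject set to long-format CSV
#'
#' Inverse of [read_cycles()]: numeric fields round-trip to full double
#' precision.
#'
#' @param set A [subject_set()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cycles <- function(set, path) {
  if (!inherits(set, "subject_set"))
    stop_gaitsf("gaitsf_input_error", "write_cycles expects a subject_set")
  write_csv_precise(as.data.frame(set), path)
}

#' Write a comparison report
#'
#' Emits, under `out_dir`: one `sf_<joint>.csv` per joint (grid, SF mean
#' and — in per-subject mode — across-subject SD), `params.csv` (SF
#' parameter summary), `summary.json` (peak SF, its %CT and Perry phase,
#' classification per joint) and optionally one PNG per joint with the SF
#' trace. Refuses to write anything for an empty result.
#'
#' @param results An [sf_compare()] result.
#' @param out_dir Output directory (created if needed).
#' @param plots Write PNG plots?
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(results, out_dir, plots = TRUE) {
  if (!inherits(results, "sf_comparison"))
    stop_gaitsf("gaitsf_input_error", "write_report expects an sf_comparison")
  if (!length(results$joints))
    stop_gaitsf("gaitsf_input_error", "empty result set: nothing to report")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop_gaitsf("gaitsf_io_error", "cannot create output directory %s", out_dir)
  written <- character()
  summary_list <- list()
  for (j in names(results$joints)) {
    item <- results$joints[[j]]
    f <- item$sf
    df <- data.frame(pct_ct = f$curve$pct_ct, sf_percent = f$curve$values)
    if (!is.null(item$sf_ensemble)) df$sf_sd <- item$sf_ensemble$sd
    p <- file.path(out_dir, sprintf("sf_%s.csv", j))
    write_csv_precise(df, p)
    written <- c(written, p)
    summary_list[[j]] <- list(
      first = results$labels[["first"]], second = results$labels[["second"]],
      peak_min = f$params$peak_min, t_min = f$params$t_min,
      phase_min = f$peak_phases$phase[1],
      peak_max = f$params$peak_max, t_max = f$params$t_max,
      phase_max = f$peak_phases$phase[2],
      rom = f$params$rom, classification = f$classification
    )
    if (plots) {
      pp <- file.path(out_dir, sprintf("sf_%s.png", j))
      grDevices::png(pp, width = 900, height = 500, res = 110)
      plot(f)
      grDevices::dev.off()
      written <- c(written, pp)
    }
  }
  params_df <- if (!is.null(results$summary)) results$summary
  else do.call(rbind, lapply(names(results$joints), function(j) {
    cbind(data.frame(joint = j, stringsAsFactors = FALSE),
          as.data.frame(results$joints[[j]]$sf$params))
  }))
  pf <- file.path(out_dir, "params.csv")
  write_csv_precise(params_df, pf)
  jf <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(mode = results$mode, aggregate = results$aggregate,
         joints = summary_list),
    jf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, pf, jf)
  message(sprintf("report: %d joint(s), %d file(s) -> %s",
                  length(results$joints), length(written), out_dir))
  invisible(written)
}
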