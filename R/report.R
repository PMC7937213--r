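#' Run the full MID / PASS analysis pipeline
#'
#' Orchestrates every estimator for every configured instrument on a single
#' cohort: pairwise-deletion pair counts, MID by ROC / MDoC / MC on the
#' pooled follow-ups, both PASS methods under both anchor definitions,
#' anchor-adequacy diagnostics, per-timepoint MID-ROC variants, and an
#' optional subgroup sensitivity analysis (by default surgery = ASD + DA
#' combined vs exercise therapy = ET). Any estimator failure (e.g. an empty
#' anchor group in a subgroup) is recorded in `problems` and leaves a gap;
#' the bundle is still produced. Fully reproducible under `seed`.
#'
#' @param input An `anchored_outcome_table`, a path to a CSV readable by
#'   [load_table()], or a scenario name from [scenario_library()].
#' @param instruments Instrument names to analyse (default: all present).
#' @param timepoints Follow-up months to pool (default: all present).
#' @param subgroups Named list of group-label vectors for sensitivity
#'   analyses, or `NULL` to skip. Default surgery / exercise split.
#' @param n_boot Bootstrap replicates for MDoC / MC / correlation CIs.
#' @param seed Integer seed driving every stochastic step (scenario
#'   generation and bootstraps).
#' @param adequacy_threshold Passed to [validate_anchor()].
#' @param anchor_sign Passed to [validate_anchor()] (`sign` argument).
#' @return A `report_bundle`: list with `pair_counts`, `mid_roc`,
#'   `mid_mdoc_mc`, `pass_table`, `anchor_report`, `mid_roc_by_timepoint`,
#'   `subgroup_mid_roc`, `problems`, `metadata`.
#' @export
run_full_analysis <- function(input, instruments = NULL, timepoints = NULL,
                              subgroups = list(surgery = c("ASD", "DA"),
                                               exercise = "ET"),
                              n_boot = 1000, seed = 1,
                              adequacy_threshold = 0.3,
                              anchor_sign = "aligned") {
  table <- if (inherits(input, "anchored_outcome_table")) {
    input
  } else if (is.character(input) && length(input) == 1L && file.exists(input)) {
    load_table(input)
  } else if (is.character(input) && length(input) == 1L) {
    generate_trial(scenario_library(input, seed = seed))$table
  } else {
    stop("input must be an outcome table, a CSV path, or a scenario name",
         call. = FALSE)
  }
  table <- compute_changes(table)
  if (is.null(instruments)) instruments <- unique(table$instrument)
  if (is.null(timepoints)) timepoints <- sort(unique(table$timepoint))
  pooled <- pool_timepoints(table, timepoints)

  problems <- list()
  note_problem <- function(what, e) {
    problems[[length(problems) + 1L]] <<-
      data.frame(cell = what, message = conditionMessage(e),
                 stringsAsFactors = FALSE)
    NULL
  }
  try_cell <- function(what, expr) {
    tryCatch(expr, error = function(e) note_problem(what, e))
  }

  mid_roc <- list(); mid_mm <- list(); pass_rows <- list()
  anchor_reports <- list(); tp_rows <- list(); sub_rows <- list()

  for (ins in instruments) {
    r <- try_cell(paste0("mid_roc/", ins), estimate_mid_roc(pooled, ins))
    if (!is.null(r)) mid_roc[[ins]] <- r

    for (method in c("MDoC", "MC")) {
      fn <- if (method == "MDoC") estimate_mid_mdoc else estimate_mid_mc
      m <- try_cell(paste0("mid_", tolower(method), "/", ins),
                    fn(pooled, ins, n_boot = n_boot, seed = seed))
      if (!is.null(m)) mid_mm[[paste(ins, method)]] <- m
    }

    for (anc in list(pass_anchor(1), pass_anchor(c(1, 2)))) {
      alab <- paste(anc$satisfied, collapse = "+")
      pr <- try_cell(paste0("pass_roc/", ins, "/", alab),
                     estimate_pass_roc(pooled, ins, anc))
      pp <- try_cell(paste0("pass_pct/", ins, "/", alab),
                     estimate_pass_percentile(pooled, ins, anc))
      pass_rows[[paste(ins, alab)]] <- data.frame(
        instrument = ins, anchor = alab,
        pass_percentile = if (is.null(pp)) NA else pp$pass_threshold,
        pass_roc = if (is.null(pr)) NA else pr$pass_threshold,
        sensitivity = if (is.null(pr)) NA else pr$sensitivity,
        specificity = if (is.null(pr)) NA else pr$specificity,
        auc = if (is.null(pr)) NA else pr$auc_estimate$auc,
        auc_low = if (is.null(pr)) NA else pr$auc_estimate$ci_low,
        auc_high = if (is.null(pr)) NA else pr$auc_estimate$ci_high,
        n_satisfied = if (is.null(pr)) NA else pr$n_satisfied,
        n_rest = if (is.null(pr)) NA else pr$n_rest,
        stringsAsFactors = FALSE)
    }

    a <- try_cell(paste0("anchor/", ins),
                  validate_anchor(pooled, ins, adequacy_threshold,
                                  sign = anchor_sign, n_boot = n_boot,
                                  seed = seed))
    if (!is.null(a)) anchor_reports[[ins]] <- a

    ins_tps <- sort(unique(pooled$timepoint[pooled$instrument == ins]))
    for (tp in ins_tps) {
      rt <- try_cell(paste0("mid_roc/", ins, "/t", tp),
                     estimate_mid_roc(pool_timepoints(pooled, tp), ins))
      if (!is.null(rt)) {
        tp_rows[[paste(ins, tp)]] <- data.frame(
          instrument = ins, timepoint = tp, mid = rt$mid,
          sensitivity = rt$sensitivity, specificity = rt$specificity,
          auc = rt$auc_estimate$auc, auc_low = rt$auc_estimate$ci_low,
          auc_high = rt$auc_estimate$ci_high, stringsAsFactors = FALSE)
      }
    }

    for (sg in names(subgroups)) {
      sub <- pooled[pooled$group %in% subgroups[[sg]], , drop = FALSE]
      rs <- try_cell(paste0("mid_roc/", ins, "/", sg),
                     estimate_mid_roc(sub, ins))
      if (!is.null(rs)) {
        sub_rows[[paste(ins, sg)]] <- data.frame(
          instrument = ins, subgroup = sg, mid = rs$mid,
          sensitivity = rs$sensitivity, specificity = rs$specificity,
          auc = rs$auc_estimate$auc, n_improved = rs$n_improved,
          n_not_improved = rs$n_not_improved, stringsAsFactors = FALSE)
      }
    }
  }

  mid_roc_df <- do.call(rbind, c(lapply(mid_roc, function(r) data.frame(
    instrument = r$instrument, mid = r$mid, sensitivity = r$sensitivity,
    specificity = r$specificity, auc = r$auc_estimate$auc,
    auc_low = r$auc_estimate$ci_low, auc_high = r$auc_estimate$ci_high,
    n_improved = r$n_improved, n_not_improved = r$n_not_improved,
    n_excluded_worse = r$n_excluded_worse, stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
  mid_mm_df <- do.call(rbind, c(lapply(mid_mm, function(m) data.frame(
    instrument = m$instrument, method = m$method, mid = m$mid,
    ci_low = m$ci$ci_low, ci_high = m$ci$ci_high,
    stringsAsFactors = FALSE)), list(make.row.names = FALSE)))

  structure(
    list(pair_counts = pair_counts(table),
         mid_roc = mid_roc_df,
         mid_mdoc_mc = mid_mm_df,
         pass_table = do.call(rbind, c(pass_rows, list(make.row.names = FALSE))),
         anchor_report = anchor_reports,
         mid_roc_by_timepoint = do.call(rbind, c(tp_rows, list(make.row.names = FALSE))),
         subgroup_mid_roc = do.call(rbind, c(sub_rows, list(make.row.names = FALSE))),
         mid_roc_detail = mid_roc,
         problems = if (length(problems)) do.call(rbind, problems) else NULL,
         metadata = list(seed = seed, n_boot = n_boot,
                         timepoints = timepoints, instruments = instruments)),
    class = "report_bundle"
  )
}

#' Write a report bundle to disk
#'
#' Emits one CSV per table (pair counts, MID-ROC, MDoC/MC, PASS, anchor
#' correlations, per-timepoint and subgroup MID), a JSON summary of the
#' whole bundle, and a plain-text summary. Thresholds are written at full
#' precision unless `round_thresholds` is set, in which case a presentation
#' copy rounded to `digits` decimals is used in the text summary.
#'
#' @param bundle A `report_bundle` from [run_full_analysis()].
#' @param dir Output directory (created if needed).
#' @param round_thresholds Round thresholds in the text summary?
#' @param digits Decimals used when rounding.
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir, round_thresholds = FALSE,
                                digits = 0) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE, na = "")
    }
  }
  wr(bundle$pair_counts, "pair_counts")
  wr(bundle$mid_roc, "mid_roc")
  wr(bundle$mid_mdoc_mc, "mid_mdoc_mc")
  wr(bundle$pass_table, "pass")
  wr(bundle$mid_roc_by_timepoint, "mid_roc_by_timepoint")
  wr(bundle$subgroup_mid_roc, "subgroup_mid_roc")
  anchor_df <- do.call(rbind, c(lapply(bundle$anchor_report,
                                       `[[`, "correlations"),
                                list(make.row.names = FALSE)))
  wr(anchor_df, "anchor_correlations")
  wr(bundle$problems, "problems")

  json <- list(metadata = bundle$metadata,
               pair_counts = bundle$pair_counts,
               mid_roc = bundle$mid_roc, mid_mdoc_mc = bundle$mid_mdoc_mc,
               pass = bundle$pass_table, anchor = anchor_df)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows")

  txt <- utils::capture.output(print(bundle, round_thresholds = round_thresholds,
                                     digits = digits))
  writeLines(txt, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.report_bundle <- function(x, round_thresholds = FALSE, digits = 0, ...) {
  fmt <- function(v) {
    if (round_thresholds) formatC(round(v, digits), format = "fg") else signif(v, 4)
  }
  cat("== MID / PASS analysis bundle ==\n")
  cat(sprintf("seed %d, %d bootstrap replicates, timepoints pooled: %s\n\n",
              x$metadata$seed, x$metadata$n_boot,
              paste(x$metadata$timepoints, collapse = ", ")))
  cat("Pair counts (GRC-outcome pairs per timepoint):\n")
  print(x$pair_counts, row.names = FALSE)
  if (!is.null(x$mid_roc)) {
    cat("\nMID, ROC closest-to-corner (pooled):\n")
    d <- x$mid_roc; d$mid <- fmt(d$mid)
    print(d, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$mid_mdoc_mc)) {
    cat("\nMID, MDoC and MC (pooled, bootstrap CI):\n")
    d <- x$mid_mdoc_mc; d$mid <- fmt(d$mid)
    print(d, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$pass_table)) {
    cat("\nPASS (both anchors, percentile and ROC methods):\n")
    d <- x$pass_table
    d$pass_percentile <- fmt(d$pass_percentile); d$pass_roc <- fmt(d$pass_roc)
    print(d, row.names = FALSE, digits = 3)
  }
  for (ins in names(x$anchor_report)) {
    flags <- x$anchor_report[[ins]]$flags
    if (!flags$adequate_change_correlation) {
      cat(sprintf("\nNOTE: anchor inadequate for '%s' (|rho with change| below %.2f); its MID is unreliable.\n",
                  ins, x$anchor_report[[ins]]$adequacy_threshold))
    }
  }
  if (!is.null(x$problems)) {
    cat("\nCells not computed:\n")
    print(x$problems, row.names = FALSE)
  }
  invisible(x)
}
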