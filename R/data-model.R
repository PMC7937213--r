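#' Instrument specification
#'
#' Describes one outcome instrument: its scale bounds, whether improvement
#' means the score goes down (pain VAS) or up (function scores), and whether
#' the score is integer-valued.
#'
#' @param name Identifier used in the `instrument` column of an outcome table.
#' @param scale_min,scale_max Scale bounds in score units; `scale_min` must be
#'   strictly below `scale_max`.
#' @param direction `"decrease_is_better"` (e.g. a 0-100 mm pain VAS) or
#'   `"increase_is_better"` (e.g. Constant-Murley score, Simple Shoulder Test).
#' @param integer_valued Logical; `TRUE` for instruments whose scores are
#'   integers (e.g. a 0-12 item count).
#'
#' @return An object of class `instrument_spec`.
#' @examples
#' instrument_spec("pain_activity", 0, 100, "decrease_is_better")
#' @export
instrument_spec <- function(name, scale_min, scale_max,
                            direction = c("decrease_is_better", "increase_is_better"),
                            integer_valued = FALSE) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(scale_min), is.numeric(scale_max),
            length(scale_min) == 1L, length(scale_max) == 1L,
            is.logical(integer_valued), length(integer_valued) == 1L)
  if (!(scale_min < scale_max)) {
    stop("scale_min must be strictly less than scale_max", call. = FALSE)
  }
  structure(
    list(name = name, scale_min = scale_min, scale_max = scale_max,
         direction = direction, integer_valued = integer_valued),
    class = "instrument_spec"
  )
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> %s [%g, %g], %s%s\n",
              x$name, x$scale_min, x$scale_max, x$direction,
              if (x$integer_valued) ", integer" else ""))
  invisible(x)
}

#' Default shoulder-trial instrument set
#'
#' The four instruments of the shoulder cohort the package targets: pain at
#' rest and pain on arm activity (VAS, 0-100 mm, lower is better), the
#' Constant-Murley score (0-100, higher is better) and the Simple Shoulder
#' Test (0-12 items, higher is better, integer).
#'
#' @return Named list of [instrument_spec()] objects.
#' @export
default_instruments <- function() {
  list(
    pain_rest       = instrument_spec("pain_rest", 0, 100, "decrease_is_better"),
    pain_activity   = instrument_spec("pain_activity", 0, 100, "decrease_is_better"),
    constant_murley = instrument_spec("constant_murley", 0, 100, "increase_is_better"),
    sst             = instrument_spec("sst", 0, 12, "increase_is_better", integer_valued = TRUE)
  )
}

.required_cols <- c("patient_id", "group", "timepoint", "instrument",
                    "baseline", "post", "grc")

#' Construct and validate an anchored outcome table
#'
#' The central data container: a long-format data frame with one row per
#' patient x timepoint x instrument, holding the baseline score, the
#' follow-up (post) score, and the 5-level global-rating-of-change (GRC)
#' anchor (1 = very satisfied / healed ... 5 = worse). Validation enforces
#' the GRC domain, the instrument scale bounds, and uniqueness of
#' (patient_id, timepoint, instrument); offending rows are reported by index.
#'
#' Missing `post` or `grc` values are legal: analyses use pairwise deletion,
#' so each estimator works on the rows where the fields it needs are present.
#'
#' @param records Data frame with columns `patient_id`, `group`, `timepoint`,
#'   `instrument`, `baseline`, `post`, `grc`.
#' @param instruments Named list of [instrument_spec()]; every value in the
#'   `instrument` column must name one of them.
#'
#' @return The validated data frame, classed `anchored_outcome_table`, with
#'   the instrument list stored in the `"instruments"` attribute.
#' @export
as_outcome_table <- function(records, instruments = default_instruments()) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(.required_cols, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(names(instruments))) {
    names(instruments) <- vapply(instruments, `[[`, "", "name")
  }
  for (col in c("baseline", "post", "grc", "timepoint")) {
    if (!is.numeric(records[[col]]) && !all(is.na(records[[col]]))) {
      suppressWarnings(num <- as.numeric(as.character(records[[col]])))
      bad <- which(!is.na(records[[col]]) & is.na(num))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric values in column '%s' at row(s): %s",
                     col, paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
      }
      records[[col]] <- num
    }
  }

  unknown <- !records$instrument %in% names(instruments)
  if (any(unknown)) {
    stop("unknown instrument(s): ",
         paste(unique(records$instrument[unknown]), collapse = ", "),
         " at row(s): ", paste(utils::head(which(unknown), 10L), collapse = ", "),
         call. = FALSE)
  }

  grc_bad <- which(!is.na(records$grc) &
                     (records$grc %% 1 != 0 | records$grc < 1 | records$grc > 5))
  if (length(grc_bad) > 0L) {
    stop("grc outside {1,...,5} at row(s): ",
         paste(utils::head(grc_bad, 10L), collapse = ", "), call. = FALSE)
  }

  for (nm in unique(records$instrument)) {
    spec <- instruments[[nm]]
    sel <- records$instrument == nm
    for (col in c("baseline", "post")) {
      v <- records[[col]]
      bad <- which(sel & !is.na(v) & (v < spec$scale_min | v > spec$scale_max))
      if (length(bad) > 0L) {
        stop(sprintf("%s out of [%g, %g] for instrument '%s' at row(s): %s",
                     col, spec$scale_min, spec$scale_max, nm,
                     paste(utils::head(bad, 10L), collapse = ", ")),
             call. = FALSE)
      }
    }
  }

  key <- paste(records$patient_id, records$timepoint, records$instrument, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate (patient_id, timepoint, instrument) at row(s): ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }

  rownames(records) <- NULL
  structure(records,
            instruments = instruments,
            class = c("anchored_outcome_table", "data.frame"))
}

#' Load an anchored outcome table from a delimited text file
#'
#' Reads a long-format CSV (header row, UTF-8) and validates it with
#' [as_outcome_table()]. Column names differing from the canonical ones are
#' handled through `schema`, a named character vector mapping canonical name
#' to file column name, e.g. `c(patient_id = "id", grc = "anchor")`.
#'
#' @param path Path to a delimited text file.
#' @param schema Optional named character vector; canonical names not listed
#'   are looked up verbatim.
#' @param instruments Named list of [instrument_spec()].
#' @param sep Field separator (default comma).
#'
#' @return An `anchored_outcome_table`.
#' @export
load_table <- function(path, schema = NULL, instruments = default_instruments(),
                       sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  mapping <- stats::setNames(.required_cols, .required_cols)
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), .required_cols)
    if (length(unknown) > 0L) {
      stop("schema maps unknown canonical column(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mapping[names(schema)] <- schema
  }
  absent <- mapping[!mapping %in% names(raw)]
  if (length(absent) > 0L) {
    stop("mapped column(s) not found in file: ",
         paste(sprintf("%s -> %s", names(absent), absent), collapse = ", "),
         call. = FALSE)
  }
  records <- stats::setNames(raw[, mapping, drop = FALSE], names(mapping))
  as_outcome_table(records, instruments = instruments)
}

#' Write an anchored outcome table to CSV
#'
#' @param table An `anchored_outcome_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_outcome_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Add change scores and improvement magnitudes
#'
#' Adds `change = post - baseline` (signed, in score units) and
#' `improvement` (positive = the patient got better): for
#' decrease-is-better instruments `improvement = -change`, otherwise
#' `improvement = change`. Rows with either score missing get missing change.
#' All estimators consume `improvement`, so pain and function instruments
#' share one code path and every reported threshold is a positive magnitude.
#'
#' Idempotent: recomputing on an already-augmented table changes nothing.
#'
#' @param table An `anchored_outcome_table`.
#' @return The table with `change` and `improvement` columns.
#' @export
compute_changes <- function(table) {
  stopifnot(inherits(table, "anchored_outcome_table"))
  instruments <- attr(table, "instruments")
  table$change <- table$post - table$baseline
  dir <- vapply(instruments, `[[`, "", "direction")[table$instrument]
  table$improvement <- ifelse(dir == "decrease_is_better", -table$change, table$change)
  table
}

#' Pool follow-up timepoints
#'
#' Returns the row-concatenation of the selected timepoints. The analysis
#' unit stays the patient x timepoint pair ("GRC-outcome pair"): a patient
#' measured at three follow-ups contributes three rows, with no clustering
#' collapse, matching a pooled primary analysis over all follow-ups.
#'
#' @param table An `anchored_outcome_table`.
#' @param timepoints Numeric vector of follow-up months to keep; each must
#'   occur in the table.
#' @return The filtered `anchored_outcome_table`.
#' @export
pool_timepoints <- function(table, timepoints) {
  stopifnot(inherits(table, "anchored_outcome_table"), length(timepoints) > 0L)
  unknown <- setdiff(timepoints, unique(table$timepoint))
  if (length(unknown) > 0L) {
    stop("timepoint(s) not present in table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- table[table$timepoint %in% timepoints, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Analysis-ready pair counts per instrument and timepoint
#'
#' Counts rows where both the GRC anchor and the scores needed for a change
#' analysis (baseline and post) are present -- the pairwise-deletion sample
#' sizes. Instruments not measured at a timepoint get `NA` in that cell.
#'
#' @param table An `anchored_outcome_table`.
#' @return Data frame with one row per instrument, one column per timepoint,
#'   and a `combined` column summing across timepoints.
#' @export
pair_counts <- function(table) {
  stopifnot(inherits(table, "anchored_outcome_table"))
  tps <- sort(unique(table$timepoint))
  instruments <- names(attr(table, "instruments"))
  instruments <- instruments[instruments %in% unique(table$instrument)]
  complete <- !is.na(table$grc) & !is.na(table$baseline) & !is.na(table$post)
  out <- data.frame(instrument = instruments, stringsAsFactors = FALSE)
  for (tp in tps) {
    cnt <- vapply(instruments, function(ins) {
      sel <- table$instrument == ins & table$timepoint == tp
      if (!any(sel)) NA_integer_ else sum(complete & sel)
    }, integer(1))
    out[[paste0("m", tp)]] <- cnt
  }
  out$combined <- vapply(instruments, function(ins) {
    sum(complete & table$instrument == ins)
  }, integer(1))
  out
}
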