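#' PASS anchor definition
#'
#' The "satisfied" side of the PASS dichotomization: either GRC answer 1
#' only ("very satisfied -- healed completely") or answers 1-2 (adding
#' "satisfied -- much better, only minor activity-related symptoms").
#' Everyone else, worseners included, forms the rest.
#'
#' @param satisfied Integer vector, exactly `1` or `c(1, 2)`.
#' @return An object of class `pass_anchor`.
#' @export
pass_anchor <- function(satisfied = 1) {
  satisfied <- sort(unique(as.integer(satisfied)))
  if (!(identical(satisfied, 1L) || identical(satisfied, c(1L, 2L)))) {
    stop("satisfied set must be exactly {1} or {1, 2}", call. = FALSE)
  }
  structure(list(satisfied = satisfied), class = "pass_anchor")
}

#' @export
print.pass_anchor <- function(x, ...) {
  cat(sprintf("<pass_anchor> satisfied = GRC answer(s) %s\n",
              paste(x$satisfied, collapse = "+")))
  invisible(x)
}

#' Dichotomize the GRC anchor for PASS estimation
#'
#' @param grc Integer vector in `{1,...,5}` (NA propagated).
#' @param anchor A [pass_anchor()], or `1` / `c(1, 2)` for convenience.
#' @return Logical vector, `TRUE` = satisfied. Nobody is excluded.
#' @export
dichotomize_grc_for_pass <- function(grc, anchor = pass_anchor(1)) {
  if (!inherits(anchor, "pass_anchor")) anchor <- pass_anchor(anchor)
  bad <- !is.na(grc) & (grc %% 1 != 0 | grc < 1 | grc > 5)
  if (any(bad)) {
    stop("grc outside {1,...,5} at position(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "), call. = FALSE)
  }
  ifelse(is.na(grc), NA, grc %in% anchor$satisfied)
}

# rows of one instrument with anchor and post score both present
.pass_frame <- function(table, instrument) {
  stopifnot(inherits(table, "anchored_outcome_table"))
  d <- table[table$instrument == instrument &
               !is.na(table$grc) & !is.na(table$post), , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("no complete (grc, post) pairs for instrument '", instrument, "'",
         call. = FALSE)
  }
  d
}

.new_pass_estimate <- function(instrument, spec, anchor, method, threshold, ...) {
  structure(
    c(list(instrument = instrument, anchor = anchor, method = method,
           pass_threshold = threshold,
           well_region = if (spec$direction == "decrease_is_better") "<=" else ">="),
      list(...)),
    class = "pass_estimate"
  )
}

#' PASS by the ROC closest-to-corner method
#'
#' Thresholds the follow-up (post) score -- not the change -- against the
#' satisfied / rest dichotomization. For decrease-is-better instruments a
#' low post score predicts feeling well, so the ROC direction is "lower";
#' for increase-is-better instruments it is "higher". The "well" region is
#' `post <= threshold` or `post >= threshold` accordingly (`well_region`
#' field).
#'
#' @param table An `anchored_outcome_table`.
#' @param instrument Instrument name.
#' @param anchor A [pass_anchor()] (or `1` / `c(1, 2)`).
#' @param level Confidence level for the AUC interval.
#' @return A `pass_estimate` with `pass_threshold`, `sensitivity`,
#'   `specificity`, `auc_estimate`, `n_satisfied`, `n_rest`, `roc`.
#' @export
estimate_pass_roc <- function(table, instrument, anchor = pass_anchor(1),
                              level = 0.95) {
  if (!inherits(anchor, "pass_anchor")) anchor <- pass_anchor(anchor)
  d <- .pass_frame(table, instrument)
  spec <- attr(table, "instruments")[[instrument]]
  satisfied <- dichotomize_grc_for_pass(d$grc, anchor)
  n_sat <- sum(satisfied); n_rest <- sum(!satisfied)
  if (n_sat == 0L) stop("satisfied class is empty", call. = FALSE)
  if (n_rest == 0L) stop("rest class is empty", call. = FALSE)

  dir <- if (spec$direction == "decrease_is_better") "lower" else "higher"
  curve <- build_roc(d$post, satisfied, direction = dir)
  sel <- select_closest_to_corner(curve)
  auc_est <- auc_delong_ci(d$post, satisfied, direction = dir, level = level)
  .new_pass_estimate(instrument, spec, anchor, "ROC", sel$cutoff,
                     sensitivity = sel$sensitivity,
                     specificity = sel$specificity,
                     auc_estimate = auc_est,
                     n_satisfied = n_sat, n_rest = n_rest, roc = curve)
}

#' PASS by the 75th/25th percentile method
#'
#' The threshold is a percentile of the post scores of the satisfied group:
#' the 75th percentile for decrease-is-better instruments (three quarters of
#' satisfied patients report that much symptom or less) and the 25th for
#' increase-is-better instruments. Quantiles use linear interpolation
#' between order statistics.
#'
#' @inheritParams estimate_pass_roc
#' @return A `pass_estimate` with `pass_threshold`, `percentile`,
#'   `n_satisfied`, `n_rest`.
#' @export
estimate_pass_percentile <- function(table, instrument, anchor = pass_anchor(1)) {
  if (!inherits(anchor, "pass_anchor")) anchor <- pass_anchor(anchor)
  d <- .pass_frame(table, instrument)
  spec <- attr(table, "instruments")[[instrument]]
  satisfied <- dichotomize_grc_for_pass(d$grc, anchor)
  if (!any(satisfied)) stop("satisfied class is empty", call. = FALSE)
  p <- if (spec$direction == "decrease_is_better") 0.75 else 0.25
  thr <- stats::quantile(d$post[satisfied], probs = p, type = 7, names = FALSE)
  .new_pass_estimate(instrument, spec, anchor, "percentile", thr,
                     percentile = p,
                     n_satisfied = sum(satisfied), n_rest = sum(!satisfied))
}

#' @export
print.pass_estimate <- function(x, ...) {
  cat(sprintf("<pass_estimate> %s, %s method, anchor GRC %s: well if post %s %.4g",
              x$instrument, x$method, paste(x$anchor$satisfied, collapse = "+"),
              x$well_region, x$pass_threshold))
  if (!is.null(x$auc_estimate)) {
    cat(sprintf("\n  sens %.2f, spec %.2f, AUC %.2f (%.2f to %.2f); %d satisfied, %d rest",
                x$sensitivity, x$specificity, x$auc_estimate$auc,
                x$auc_estimate$ci_low, x$auc_estimate$ci_high,
                x$n_satisfied, x$n_rest))
  }
  cat("\n")
  invisible(x)
}
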