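#' Dichotomize the GRC anchor for MID estimation
#'
#' Responses 1-3 (very satisfied, satisfied, somewhat satisfied) count as
#' improved; response 4 (dissatisfied -- "the same as before treatment") as
#' not improved; response 5 (worse) is excluded, so the resulting MID is a
#' threshold for improvement only.
#'
#' @param grc Integer vector with values in `{1,...,5}` (NA allowed,
#'   propagated).
#' @return Factor with levels `improved`, `not_improved`, `excluded`.
#' @export
dichotomize_grc_for_mid <- function(grc) {
  bad <- !is.na(grc) & (grc %% 1 != 0 | grc < 1 | grc > 5)
  if (any(bad)) {
    stop("grc outside {1,...,5} at position(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_character_, length(grc))
  out[!is.na(grc) & grc <= 3] <- "improved"
  out[!is.na(grc) & grc == 4] <- "not_improved"
  out[!is.na(grc) & grc == 5] <- "excluded"
  factor(out, levels = c("improved", "not_improved", "excluded"))
}

# rows of one instrument with anchor and improvement both present
.mid_frame <- function(table, instrument) {
  stopifnot(inherits(table, "anchored_outcome_table"))
  if (is.null(table$improvement)) table <- compute_changes(table)
  d <- table[table$instrument == instrument &
               !is.na(table$grc) & !is.na(table$improvement), , drop = FALSE]
  if (nrow(d) == 0L) {
    stop("no complete (grc, change) pairs for instrument '", instrument, "'",
         call. = FALSE)
  }
  d
}

.new_mid_estimate <- function(...) structure(list(...), class = "mid_estimate")

#' MID by the ROC closest-to-corner method
#'
#' Builds the ROC of the improvement magnitude against the dichotomized
#' anchor (improved = GRC 1-3 vs not improved = GRC 4; GRC 5 excluded),
#' selects the cutoff closest to the top-left corner, and attaches the
#' DeLong AUC confidence interval. Larger improvement predicts the improved
#' class for every instrument because both pain and function scores are
#' expressed as positive improvement magnitudes.
#'
#' @param table An `anchored_outcome_table` (change scores are computed if
#'   absent).
#' @param instrument Instrument name.
#' @param level Confidence level for the AUC interval.
#' @return A `mid_estimate` with fields `mid`, `sensitivity`, `specificity`,
#'   `auc_estimate`, `n_improved`, `n_not_improved`, `n_excluded_worse`, and
#'   the underlying `roc` curve.
#' @export
estimate_mid_roc <- function(table, instrument, level = 0.95) {
  d <- .mid_frame(table, instrument)
  cls <- dichotomize_grc_for_mid(d$grc)
  n_excl <- sum(cls == "excluded")
  d <- d[cls != "excluded", , drop = FALSE]
  cls <- cls[cls != "excluded"]
  n_imp <- sum(cls == "improved"); n_not <- sum(cls == "not_improved")
  if (n_imp == 0L) stop("improved class is empty", call. = FALSE)
  if (n_not == 0L) stop("not_improved class is empty", call. = FALSE)

  improved <- cls == "improved"
  curve <- build_roc(d$improvement, improved, direction = "higher")
  sel <- select_closest_to_corner(curve)
  auc_est <- auc_delong_ci(d$improvement, improved, direction = "higher",
                           level = level)
  .new_mid_estimate(
    instrument = instrument, method = "ROC", mid = sel$cutoff,
    sensitivity = sel$sensitivity, specificity = sel$specificity,
    auc_estimate = auc_est, ci = NULL,
    n_improved = n_imp, n_not_improved = n_not, n_excluded_worse = n_excl,
    roc = curve
  )
}

#' MID by the mean difference of change (MDoC) method
#'
#' The mean improvement magnitude of the "somewhat satisfied" group (GRC 3)
#' minus that of the "dissatisfied" group (GRC 4), with a percentile
#' bootstrap confidence interval.
#'
#' @inheritParams estimate_mid_roc
#' @inheritParams percentile_ci
#' @return A `mid_estimate` with `mid`, `ci` (a `bootstrap_ci`), and group
#'   counts `n_improved` (GRC 3) and `n_not_improved` (GRC 4).
#' @export
estimate_mid_mdoc <- function(table, instrument, n_boot = 1000, level = 0.95,
                              seed = NULL, unit = c("row", "patient")) {
  unit <- match.arg(unit)
  d <- .mid_frame(table, instrument)
  d <- d[d$grc %in% c(3, 4), , drop = FALSE]
  n3 <- sum(d$grc == 3); n4 <- sum(d$grc == 4)
  if (n3 == 0L) stop("GRC=3 (somewhat satisfied) group is empty", call. = FALSE)
  if (n4 == 0L) stop("GRC=4 (dissatisfied) group is empty", call. = FALSE)
  stat <- function(df) {
    mean(df$improvement[df$grc == 3]) - mean(df$improvement[df$grc == 4])
  }
  ci <- percentile_ci(d, stat, n_boot = n_boot, level = level,
                      seed = seed, unit = unit)
  .new_mid_estimate(
    instrument = instrument, method = "MDoC", mid = ci$estimate, ci = ci,
    sensitivity = NULL, specificity = NULL, auc_estimate = NULL,
    n_improved = n3, n_not_improved = n4, n_excluded_worse = 0L
  )
}

#' MID by the mean change (MC) method
#'
#' The mean improvement magnitude within the "somewhat satisfied" group
#' (GRC 3), with a percentile bootstrap confidence interval.
#'
#' @inheritParams estimate_mid_mdoc
#' @return A `mid_estimate` with `mid`, `ci`, and `n_improved` (GRC 3 count).
#' @export
estimate_mid_mc <- function(table, instrument, n_boot = 1000, level = 0.95,
                            seed = NULL, unit = c("row", "patient")) {
  unit <- match.arg(unit)
  d <- .mid_frame(table, instrument)
  d <- d[d$grc == 3, , drop = FALSE]
  if (nrow(d) == 0L) stop("GRC=3 (somewhat satisfied) group is empty", call. = FALSE)
  ci <- percentile_ci(d, function(df) mean(df$improvement),
                      n_boot = n_boot, level = level, seed = seed, unit = unit)
  .new_mid_estimate(
    instrument = instrument, method = "MC", mid = ci$estimate, ci = ci,
    sensitivity = NULL, specificity = NULL, auc_estimate = NULL,
    n_improved = nrow(d), n_not_improved = NA_integer_, n_excluded_worse = 0L
  )
}

#' @export
print.mid_estimate <- function(x, ...) {
  cat(sprintf("<mid_estimate> %s, %s method: MID = %.4g", x$instrument,
              x$method, x$mid))
  if (!is.null(x$ci)) {
    cat(sprintf(" (%g%% CI %.4g to %.4g)", 100 * x$ci$level,
                x$ci$ci_low, x$ci$ci_high))
  }
  if (!is.null(x$auc_estimate)) {
    cat(sprintf("\n  sens %.2f, spec %.2f, AUC %.2f (%.2f to %.2f); %d improved, %d not improved, %d worse excluded",
                x$sensitivity, x$specificity, x$auc_estimate$auc,
                x$auc_estimate$ci_low, x$auc_estimate$ci_high,
                x$n_improved, x$n_not_improved, x$n_excluded_worse))
  }
  cat("\n")
  invisible(x)
}
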