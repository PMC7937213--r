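#' Percentile bootstrap confidence interval for a table statistic
#'
#' Resamples the data with replacement `n_boot` times, recomputes the
#' statistic on each replicate, and returns the empirical
#' `(1-level)/2` and `1-(1-level)/2` quantiles (linear interpolation between
#' order statistics, the same quantile rule used throughout the package).
#'
#' The resampling unit defaults to the row, i.e. the pooled GRC-outcome
#' pair; `unit = "patient"` resamples whole patients (all their rows move
#' together), a sensitivity option for clustered follow-ups. Replicates on
#' which the statistic is undefined (an anchor group empty in the resample,
#' an error, a non-finite value) are dropped and counted; if more than half
#' are dropped the interval is refused.
#'
#' @param data Data frame passed to `statistic`.
#' @param statistic Function of one data frame returning a single number.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @param unit `"row"` or `"patient"`.
#' @param patient_col Column holding the patient identifier when
#'   `unit = "patient"`.
#'
#' @return An object of class `bootstrap_ci`: list with `estimate`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_dropped`, `level`, `seed`, `unit`.
#' @export
percentile_ci <- function(data, statistic, n_boot = 1000, level = 0.95,
                          seed = NULL, unit = c("row", "patient"),
                          patient_col = "patient_id") {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(data), is.function(statistic), n_boot >= 1)
  estimate <- statistic(data)
  if (length(estimate) != 1L || !is.finite(estimate)) {
    stop("statistic must return a single finite number on the full data",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  nr <- nrow(data)
  if (unit == "patient") {
    ids <- unique(data[[patient_col]])
    rows_by_id <- split(seq_len(nr), match(data[[patient_col]], ids))
  }

  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- if (unit == "row") {
      sample.int(nr, nr, replace = TRUE)
    } else {
      unlist(rows_by_id[sample.int(length(rows_by_id), length(rows_by_id),
                                   replace = TRUE)], use.names = FALSE)
    }
    val <- tryCatch(statistic(data[idx, , drop = FALSE]),
                    error = function(e) NA_real_)
    if (length(val) != 1L || !is.finite(val)) NA_real_ else as.numeric(val)
  }, numeric(1))

  n_dropped <- sum(is.na(reps))
  if (n_dropped > n_boot / 2) {
    stop(sprintf("statistic undefined on %d of %d bootstrap replicates",
                 n_dropped, n_boot), call. = FALSE)
  }
  qs <- stats::quantile(reps[!is.na(reps)],
                        probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 7, names = FALSE)
  structure(
    list(estimate = estimate, ci_low = qs[1L], ci_high = qs[2L],
         n_boot = n_boot, n_dropped = n_dropped, level = level,
         seed = seed, unit = unit),
    class = "bootstrap_ci"
  )
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("<bootstrap_ci> %.4g (%g%% CI %.4g to %.4g), %d replicates (%d dropped), unit = %s\n",
              x$estimate, 100 * x$level, x$ci_low, x$ci_high,
              x$n_boot, x$n_dropped, x$unit))
  invisible(x)
}
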