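#' Build an ROC curve over candidate cutoffs
#'
#' Candidate cutoffs are the midpoints between consecutive distinct observed
#' scores, plus one sentinel below the minimum and one above the maximum, so
#' the curve always runs from (sens 0, spec 1) to (sens 1, spec 0). Placing
#' cutoffs between observations (rather than at them) yields thresholds such
#' as 1.5 on an integer 0-12 scale and makes the `>=` / `>` distinction
#' irrelevant: no score ever equals a cutoff.
#'
#' @param scores Numeric vector of finite scores.
#' @param labels Logical (or 0/1) vector, `TRUE` = positive class.
#' @param direction `"higher"` if larger scores predict the positive class
#'   (improvement magnitudes), `"lower"` if smaller scores do (pain post
#'   scores when "well" means little pain).
#'
#' @return An object of class `roc_curve`: a list with `points` (data frame
#'   of cutoff, sensitivity, specificity), `n_positive`, `n_negative`,
#'   `direction`.
#' @export
build_roc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(scores) == 0L || any(!is.finite(scores))) {
    stop("scores must be finite and nonempty", call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos < 1L || n_neg < 1L) {
    stop("both classes must be present to build an ROC curve", call. = FALSE)
  }

  u <- sort(unique(scores))
  gap <- if (length(u) > 1L) min(diff(u)) else 1
  cutoffs <- c(u[1L] - gap / 2,
               if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2,
               u[length(u)] + gap / 2)

  pts <- vapply(cutoffs, function(ct) {
    called_pos <- if (direction == "higher") scores > ct else scores < ct
    c(sensitivity = sum(called_pos & labels) / n_pos,
      specificity = sum(!called_pos & !labels) / n_neg)
  }, c(sensitivity = 0, specificity = 0))

  structure(
    list(points = data.frame(cutoff = cutoffs,
                             sensitivity = pts["sensitivity", ],
                             specificity = pts["specificity", ],
                             row.names = NULL),
         n_positive = n_pos, n_negative = n_neg, direction = direction),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, %d positive / %d negative, %s scores predict positive\n",
              nrow(x$points), x$n_positive, x$n_negative, x$direction))
  invisible(x)
}

#' Plot an ROC curve
#'
#' @param x A `roc_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  ord <- order(1 - x$points$specificity, x$points$sensitivity)
  graphics::plot(1 - x$points$specificity[ord], x$points$sensitivity[ord],
                 type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Select the cutoff closest to the top-left ROC corner
#'
#' Returns the curve point minimizing the unweighted Euclidean distance
#' `sqrt((1 - sens)^2 + (1 - spec)^2)` to the ideal corner (sensitivity 1,
#' specificity 1). Ties are broken by higher sensitivity, then higher
#' specificity, then smaller cutoff.
#'
#' @param curve A `roc_curve` from [build_roc()].
#' @return An object of class `cutoff_result`: list with `cutoff`,
#'   `sensitivity`, `specificity`, `distance_to_corner`.
#' @export
select_closest_to_corner <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  p <- curve$points
  d <- sqrt((1 - p$sensitivity)^2 + (1 - p$specificity)^2)
  ord <- order(d, -p$sensitivity, -p$specificity, p$cutoff)
  i <- ord[1L]
  structure(
    list(cutoff = p$cutoff[i], sensitivity = p$sensitivity[i],
         specificity = p$specificity[i], distance_to_corner = d[i]),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> cutoff %g (sens %.3f, spec %.3f, distance %.4f)\n",
              x$cutoff, x$sensitivity, x$specificity, x$distance_to_corner))
  invisible(x)
}

.check_two_classes <- function(scores, labels, min_per_class = 1L) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (sum(labels) < min_per_class || sum(!labels) < min_per_class) {
    stop(sprintf("need at least %d observation(s) per class", min_per_class),
         call. = FALSE)
  }
  list(scores = scores, labels = labels)
}

#' Nonparametric area under the ROC curve
#'
#' The Mann-Whitney statistic: the fraction of (positive, negative) pairs in
#' which the positive observation is ranked on the correct side, ties
#' counted 1/2. Computed from mid-ranks in O(n log n).
#'
#' @inheritParams build_roc
#' @return AUC as a fraction in `[0, 1]`.
#' @export
auc <- function(scores, labels, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  d <- .check_two_classes(scores, labels)
  s <- if (direction == "lower") -d$scores else d$scores
  m <- sum(d$labels); n <- sum(!d$labels)
  r <- rank(s)  # average ranks for ties
  (sum(r[d$labels]) - m * (m + 1) / 2) / (m * n)
}

#' AUC with a DeLong confidence interval
#'
#' Estimates the AUC variance with DeLong's structural-components method:
#' each positive observation gets a placement value (the fraction of
#' negatives it beats, ties 1/2) and vice versa; the AUC variance is the sum
#' of the two placement-value sample variances divided by their class sizes.
#' The interval is Wald on the AUC scale, clipped to `[0, 1]`; perfectly
#' separated data give variance 0 and the degenerate interval `[1, 1]`.
#'
#' @inheritParams build_roc
#' @param level Confidence level (default 0.95).
#' @return An object of class `auc_estimate`: list with `auc`, `ci_low`,
#'   `ci_high`, `level`, `variance`, `n_positive`, `n_negative`.
#' @export
auc_delong_ci <- function(scores, labels, direction = c("higher", "lower"),
                          level = 0.95) {
  direction <- match.arg(direction)
  d <- .check_two_classes(scores, labels, min_per_class = 2L)
  s <- if (direction == "lower") -d$scores else d$scores
  x <- s[d$labels]; y <- s[!d$labels]
  m <- length(x); n <- length(y)

  # placement values via pooled mid-ranks (Sun & Xu formulation)
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n          # per-positive
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m  # per-negative
  a <- mean(v10)
  variance <- stats::var(v10) / m + stats::var(v01) / n

  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(variance)
  structure(
    list(auc = a,
         ci_low = max(0, a - half), ci_high = min(1, a + half),
         level = level, variance = variance,
         n_positive = m, n_negative = n),
    class = "auc_estimate"
  )
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("<auc_estimate> AUC %.3f (%g%% CI %.3f to %.3f), %d pos / %d neg\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high,
              x$n_positive, x$n_negative))
  invisible(x)
}
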