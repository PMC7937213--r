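#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, after pairwise deletion of
#' incomplete pairs. With fewer than 3 complete pairs, or a vector whose
#' values are all tied (zero rank variance), the coefficient is undefined
#' and returned as `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Spearman's rho in `[-1, 1]`, or `NA` if undefined.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("rank correlation undefined for an all-tied vector; returning NA")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

# one bootstrapped correlation row; NULL if not computable
.rho_row <- function(d, xcol, label, instrument, timepoint, n_boot, seed) {
  d <- d[!is.na(d[[xcol]]) & !is.na(d$anchor_aligned), , drop = FALSE]
  if (nrow(d) < 3L || length(unique(d[[xcol]])) == 1L ||
      length(unique(d$anchor_aligned)) == 1L) {
    return(data.frame(instrument = instrument, timepoint = timepoint,
                      pair = label, rho = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n = nrow(d),
                      stringsAsFactors = FALSE))
  }
  ci <- percentile_ci(
    d, function(df) suppressWarnings(
      stats::cor(df$anchor_aligned, df[[xcol]], method = "spearman")),
    n_boot = n_boot, seed = seed
  )
  data.frame(instrument = instrument, timepoint = timepoint, pair = label,
             rho = ci$estimate, ci_low = ci$ci_low, ci_high = ci$ci_high,
             n = nrow(d), stringsAsFactors = FALSE)
}

#' Anchor adequacy diagnostics
#'
#' A transition anchor is credible when it correlates with the change in
#' the outcome, ideally more strongly than with the follow-up (post) score
#' alone, and barely with the baseline score. This computes Spearman
#' correlations of the GRC with baseline, post and change scores, per
#' timepoint and pooled, with percentile bootstrap confidence intervals,
#' and derives three flags from the pooled estimates:
#'
#' * `near_zero_baseline`: |rho(GRC, baseline)| below `baseline_threshold`;
#' * `change_exceeds_post`: |rho(GRC, change)| > |rho(GRC, post)| (the
#'   pattern expected when the anchor captures true change rather than the
#'   current state; its absence suggests recall bias);
#' * `adequate_change_correlation`: |rho(GRC, change)| at least
#'   `adequacy_threshold` -- when `FALSE`, anchor-based MIDs for this
#'   instrument should be treated as unreliable.
#'
#' @param table An `anchored_outcome_table`.
#' @param instrument Instrument name.
#' @param adequacy_threshold Minimum |rho| with the change score for the
#'   anchor to count as adequate (default 0.3; "adequate" has no universal
#'   numeric definition, so this is configurable).
#' @param baseline_threshold Maximum |rho| with baseline considered "near
#'   zero" (default 0.1).
#' @param sign `"aligned"` correlates the reversed anchor (6 - GRC, larger =
#'   more satisfied) against improvement-oriented scores, so an informative
#'   anchor gives positive rho for every instrument; `"paper"` correlates
#'   the reversed anchor against raw scores and signed change, reproducing
#'   the sign conventions of published shoulder-trial reports (negative rho
#'   against pain change, positive against function change).
#' @param n_boot,seed Bootstrap settings, see [percentile_ci()].
#' @return An `anchor_validation_report`: list with `correlations` (data
#'   frame: instrument, timepoint -- months or `"pooled"` -- pair, rho, CI,
#'   n) and `flags`.
#' @export
validate_anchor <- function(table, instrument, adequacy_threshold = 0.3,
                            baseline_threshold = 0.1,
                            sign = c("aligned", "paper"),
                            n_boot = 1000, seed = NULL) {
  sign <- match.arg(sign)
  stopifnot(inherits(table, "anchored_outcome_table"))
  if (is.null(table$improvement)) table <- compute_changes(table)
  spec <- attr(table, "instruments")[[instrument]]
  if (is.null(spec)) stop("unknown instrument '", instrument, "'", call. = FALSE)

  d <- table[table$instrument == instrument, , drop = FALSE]
  d$anchor_aligned <- 6 - d$grc  # larger = more satisfied
  decrease <- spec$direction == "decrease_is_better"
  if (sign == "aligned") {
    d$x_baseline <- d$baseline
    d$x_post <- if (decrease) -d$post else d$post
    d$x_change <- d$improvement
  } else {
    d$x_baseline <- d$baseline
    d$x_post <- d$post
    d$x_change <- d$change
  }

  tps <- sort(unique(d$timepoint))
  scopes <- c(as.list(tps), list(tps))
  scope_labels <- c(as.character(tps), "pooled")
  rows <- list()
  for (i in seq_along(scopes)) {
    dd <- d[d$timepoint %in% scopes[[i]], , drop = FALSE]
    for (pair in c("grc_vs_baseline", "grc_vs_post", "grc_vs_change")) {
      xcol <- sub("grc_vs", "x", pair)
      rows[[length(rows) + 1L]] <-
        .rho_row(dd, xcol, pair, instrument, scope_labels[i], n_boot, seed)
    }
  }
  correlations <- do.call(rbind, rows)

  pooled <- correlations[correlations$timepoint == "pooled", ]
  rho_of <- function(pair) pooled$rho[pooled$pair == pair]
  flags <- list(
    near_zero_baseline = isTRUE(abs(rho_of("grc_vs_baseline")) < baseline_threshold),
    change_exceeds_post = isTRUE(abs(rho_of("grc_vs_change")) > abs(rho_of("grc_vs_post"))),
    adequate_change_correlation = isTRUE(abs(rho_of("grc_vs_change")) >= adequacy_threshold)
  )
  structure(
    list(instrument = instrument, correlations = correlations, flags = flags,
         adequacy_threshold = adequacy_threshold,
         baseline_threshold = baseline_threshold, sign = sign),
    class = "anchor_validation_report"
  )
}

#' @export
print.anchor_validation_report <- function(x, ...) {
  cat(sprintf("<anchor_validation_report> %s (sign mode: %s)\n",
              x$instrument, x$sign))
  pooled <- x$correlations[x$correlations$timepoint == "pooled", ]
  for (i in seq_len(nrow(pooled))) {
    cat(sprintf("  %-16s rho %+.2f (%.2f to %.2f), n = %d\n",
                pooled$pair[i], pooled$rho[i], pooled$ci_low[i],
                pooled$ci_high[i], pooled$n[i]))
  }
  cat(sprintf("  adequate (|rho_change| >= %.2f): %s; change > post: %s; baseline ~ 0: %s\n",
              x$adequacy_threshold, x$flags$adequate_change_correlation,
              x$flags$change_exceeds_post, x$flags$near_zero_baseline))
  invisible(x)
}
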