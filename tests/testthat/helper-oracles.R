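# Independent brute-force oracles used to freeze expected values and to
# cross-check the package implementations. Deliberately naive: plain loops,
# no shared code with the package internals.

# AUC by exhaustive pair counting: fraction of (positive, negative) pairs
# ordered correctly, ties 1/2.
oracle_auc <- function(scores, labels, direction = "higher") {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (x in pos) {
    for (y in neg) {
      better <- if (direction == "higher") x > y else x < y
      total <- total + better + 0.5 * (x == y)
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive closest-to-corner search over the same candidate cutoff grid
# (midpoints plus sentinels), with the tie-break order sens > spec > cutoff.
oracle_corner <- function(scores, labels, direction = "higher") {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  gap <- if (length(u) > 1) min(diff(u)) else 1
  cands <- c(u[1] - gap / 2,
             if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
             u[length(u)] + gap / 2)
  best <- NULL
  for (ct in cands) {
    called <- if (direction == "higher") scores > ct else scores < ct
    sens <- sum(called & labels) / sum(labels)
    spec <- sum(!called & !labels) / sum(!labels)
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    cand <- list(cutoff = ct, sens = sens, spec = spec, d = d)
    if (is.null(best) ||
        d < best$d - 1e-12 ||
        (abs(d - best$d) <= 1e-12 &&
           (sens > best$sens + 1e-12 ||
              (abs(sens - best$sens) <= 1e-12 &&
                 (spec > best$spec + 1e-12 ||
                    (abs(spec - best$spec) <= 1e-12 && ct < best$cutoff)))))) {
      best <- cand
    }
  }
  best
}

# Independent end-to-end ROC-MID on a generated cohort: pairwise deletion,
# dichotomization and corner search written from scratch.
oracle_mid_roc <- function(table, instrument) {
  d <- as.data.frame(table)
  d <- d[d$instrument == instrument, ]
  imp <- ifelse(d$instrument %in% c("pain_rest", "pain_activity"),
                d$baseline - d$post, d$post - d$baseline)
  keep <- !is.na(d$grc) & !is.na(imp) & d$grc != 5
  imp <- imp[keep]
  improved <- d$grc[keep] <= 3
  oracle_corner(imp, improved, "higher")$cutoff
}

# Small well-formed cohort table for unit tests.
toy_table <- function() {
  records <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:10), each = 2),
    group = rep(c("ASD", "ET"), each = 10),
    timepoint = rep(c(6, 24), 10),
    instrument = "pain_activity",
    baseline = rep(c(70, 55, 80, 60, 75, 65, 72, 68, 58, 77), each = 2),
    post = c(40, 30, 50, 45, 20, 15, 55, 58, 70, 72,
             30, 25, 60, 50, 35, 28, 52, 40, 45, 38),
    grc = c(1, 1, 2, 2, 1, 1, 3, 3, 4, 5, 2, 1, 4, 3, 2, 2, 3, 2, 3, 3),
    stringsAsFactors = FALSE
  )
  as_outcome_table(records,
                   instruments = default_instruments()["pain_activity"])
}

# Random small score/label set with ties (integer scores) for property tests.
random_roc_case <- function(n_max = 30) {
  m <- sample(2:(n_max / 2), 1)
  n <- sample(2:(n_max / 2), 1)
  scores <- sample(0:12, m + n, replace = TRUE)
  labels <- c(rep(TRUE, m), rep(FALSE, n))
  list(scores = scores, labels = labels,
       direction = sample(c("higher", "lower"), 1))
}
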