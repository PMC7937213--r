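test_that("perfectly separated classes give a perfect operating point", {
  curve <- build_roc(c(25, 30, 5, 10), c(TRUE, TRUE, FALSE, FALSE), "higher")
  expect_true(17.5 %in% curve$points$cutoff)
  pt <- curve$points[curve$points$cutoff == 17.5, ]
  expect_equal(pt$sensitivity, 1)
  expect_equal(pt$specificity, 1)
  sel <- select_closest_to_corner(curve)
  expect_equal(sel$cutoff, 17.5)
  expect_equal(sel$distance_to_corner, 0)
})

test_that("candidate cutoffs are midpoints between distinct observed scores", {
  curve <- build_roc(c(1, 1, 2, 2), c(TRUE, TRUE, FALSE, TRUE), "higher")
  expect_true(1.5 %in% curve$points$cutoff)
  expect_equal(nrow(curve$points), 3L)  # two sentinels + one midpoint
})

test_that("identical scores yield only the two sentinel points with sens + spec = 1", {
  curve <- build_roc(rep(4, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), "higher")
  expect_equal(nrow(curve$points), 2L)
  expect_equal(curve$points$sensitivity + curve$points$specificity, c(1, 1))
})

test_that("single-class labels are a degenerate-input error", {
  expect_error(build_roc(1:4, rep(TRUE, 4), "higher"), "both classes")
  expect_error(auc(1:4, rep(FALSE, 4)), "per class")
})

test_that("corner selection matches hand-computed distances and tie-breaks", {
  curve <- structure(
    list(points = data.frame(cutoff = c(1, 2),
                             sensitivity = c(0.90, 0.60),
                             specificity = c(0.78, 0.95)),
         n_positive = 10, n_negative = 10, direction = "higher"),
    class = "roc_curve")
  sel <- select_closest_to_corner(curve)
  expect_equal(sel$cutoff, 1)
  expect_equal(sel$distance_to_corner, sqrt(0.10^2 + 0.22^2), tolerance = 1e-12)
  # equal distances: the higher-sensitivity point wins
  curve$points <- data.frame(cutoff = c(1, 2),
                             sensitivity = c(0.7, 0.9),
                             specificity = c(0.9, 0.7))
  expect_equal(select_closest_to_corner(curve)$cutoff, 2)
})

test_that("auc equals the hand-counted Mann-Whitney fraction", {
  expect_equal(auc(c(3, 5, 2, 4), c(1, 1, 0, 0), "higher"), 0.75)
  expect_equal(auc(c(25, 30, 5, 10), c(1, 1, 0, 0), "higher"), 1)
})

test_that("auc matches brute-force pair counting and direction reversal flips it", {
  set.seed(42)
  for (rep in 1:50) {
    cs <- random_roc_case()
    a <- auc(cs$scores, cs$labels, cs$direction)
    expect_equal(a, oracle_auc(cs$scores, cs$labels, cs$direction))
    flipped <- if (cs$direction == "higher") "lower" else "higher"
    expect_equal(auc(cs$scores, cs$labels, flipped), 1 - a)
    # location invariance
    expect_equal(auc(cs$scores + 7.3, cs$labels, cs$direction), a)
  }
})

test_that("score translation leaves every operating point unchanged", {
  set.seed(7)
  cs <- random_roc_case()
  c1 <- build_roc(cs$scores, cs$labels, cs$direction)
  c2 <- build_roc(cs$scores + 100, cs$labels, cs$direction)
  expect_equal(c2$points$sensitivity, c1$points$sensitivity)
  expect_equal(c2$points$specificity, c1$points$specificity)
  expect_equal(c2$points$cutoff, c1$points$cutoff + 100)
})

test_that("DeLong variance matches the hand-computed placement values", {
  # positives {3, 5}, negatives {2, 4}: V10 = (0.5, 1), V01 = (1, 0.5),
  # var = 0.125/2 + 0.125/2
  est <- auc_delong_ci(c(3, 5, 2, 4), c(1, 1, 0, 0), "higher")
  expect_equal(est$auc, 0.75)
  expect_equal(est$variance, 0.125)
  expect_equal(est$ci_low, max(0, 0.75 - qnorm(0.975) * sqrt(0.125)))
  expect_equal(est$ci_high, 1)  # clipped
})

test_that("DeLong AUC equals auc() on any input and degenerates for separated data", {
  set.seed(11)
  for (rep in 1:25) {
    cs <- random_roc_case()
    expect_equal(auc_delong_ci(cs$scores, cs$labels, cs$direction)$auc,
                 auc(cs$scores, cs$labels, cs$direction))
  }
  est <- auc_delong_ci(c(10, 9, 1, 2), c(1, 1, 0, 0), "higher")
  expect_equal(est$auc, 1)
  expect_equal(est$variance, 0)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1))
})

test_that("AUC and DeLong CI agree with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- round(rnorm(60, 10, 4), 1)
  labels <- rbinom(60, 1, plogis((scores - 10) / 2))
  if (sum(labels) < 2 || sum(!labels) < 2) skip("degenerate draw")
  ref <- pROC::roc(labels, scores, direction = "<", levels = c(0, 1),
                   quiet = TRUE)
  est <- auc_delong_ci(scores, labels, "higher")
  expect_equal(est$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(est$variance, as.numeric(pROC::var(ref)), tolerance = 1e-12)
  expect_equal(est$ci_low, max(0, ref_ci[1]), tolerance = 1e-9)
  expect_equal(est$ci_high, min(1, ref_ci[3]), tolerance = 1e-9)
})
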