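make_mid_table <- function(improvements, grc) {
  n <- length(improvements)
  rec <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)), group = "ET", timepoint = 6,
    instrument = "pain_activity", baseline = 70,
    post = 70 - improvements, grc = grc)
  compute_changes(as_outcome_table(rec, default_instruments()["pain_activity"]))
}

test_that("GRC dichotomization follows the improved / no-change / worse rule", {
  expect_equal(as.character(dichotomize_grc_for_mid(c(1, 2, 3, 4, 5))),
               c("improved", "improved", "improved", "not_improved", "excluded"))
  expect_true(is.na(dichotomize_grc_for_mid(NA)))
  expect_error(dichotomize_grc_for_mid(c(2, 6)), "position.*2")
})

test_that("a planted noise-free threshold is recovered with AUC 1", {
  set.seed(21)
  imp <- runif(60, 0, 40)
  grc <- ifelse(imp > 20, sample(1:3, 60, replace = TRUE), 4)
  est <- estimate_mid_roc(make_mid_table(imp, grc), "pain_activity")
  expect_equal(est$auc_estimate$auc, 1)
  below <- max(imp[imp <= 20]); above <- min(imp[imp > 20])
  expect_equal(est$mid, (below + above) / 2)
  expect_equal(est$sensitivity, 1)
  expect_equal(est$specificity, 1)
})

test_that("worseners are excluded from ROC and counted; a single class errors", {
  imp <- c(1, 2, 25, 30, -20, -25)
  grc <- c(4, 4, 2, 1, 5, 5)
  est <- estimate_mid_roc(make_mid_table(imp, grc), "pain_activity")
  expect_equal(est$n_excluded_worse, 2L)
  expect_equal(est$n_improved, 2L)
  expect_equal(est$n_not_improved, 2L)
  expect_equal(est$auc_estimate$auc, 1)
  expect_error(estimate_mid_roc(make_mid_table(c(5, 10), c(1, 2)),
                                "pain_activity"),
               "not_improved class is empty")
})

test_that("MDoC and MC match hand arithmetic and carry bootstrap CIs", {
  tab <- make_mid_table(c(10, 20, 0, 10), c(3, 3, 4, 4))
  mdoc <- estimate_mid_mdoc(tab, "pain_activity", n_boot = 100, seed = 1)
  expect_equal(mdoc$mid, 10)
  expect_s3_class(mdoc$ci, "bootstrap_ci")
  mc <- estimate_mid_mc(tab, "pain_activity", n_boot = 100, seed = 1)
  expect_equal(mc$mid, 15)
  single <- estimate_mid_mc(make_mid_table(c(12, 1), c(3, 4)),
                            "pain_activity", n_boot = 50, seed = 1)
  expect_equal(single$mid, 12)
  expect_equal(c(single$ci$ci_low, single$ci$ci_high), c(12, 12))
  expect_error(estimate_mid_mdoc(make_mid_table(c(5, 6), c(3, 3)),
                                 "pain_activity"),
               "GRC=4")
})

test_that("MDoC equals MC minus the dissatisfied group's mean improvement on generated cohorts", {
  for (s in 1:5) {
    tab <- compute_changes(
      generate_trial(scenario_library("fimpact-like", seed = s))$table)
    for (ins in c("pain_activity", "sst")) {
      mdoc <- estimate_mid_mdoc(tab, ins, n_boot = 5, seed = 1)
      mc <- estimate_mid_mc(tab, ins, n_boot = 5, seed = 1)
      d <- tab[tab$instrument == ins & !is.na(tab$grc) & !is.na(tab$improvement), ]
      expect_equal(mdoc$mid, mc$mid - mean(d$improvement[d$grc == 4]),
                   tolerance = 1e-12)
    }
  }
})

test_that("worsener rows do not touch MDoC or MC", {
  tab_with <- make_mid_table(c(10, 20, 0, 10, -30), c(3, 3, 4, 4, 5))
  tab_without <- make_mid_table(c(10, 20, 0, 10), c(3, 3, 4, 4))
  for (fn in list(estimate_mid_mdoc, estimate_mid_mc)) {
    expect_equal(fn(tab_with, "pain_activity", n_boot = 50, seed = 2)$mid,
                 fn(tab_without, "pain_activity", n_boot = 50, seed = 2)$mid)
  }
})

test_that("subgroup estimation is the same code path on filtered rows", {
  g <- generate_trial(scenario_library("fimpact-like", seed = 3))
  tab <- compute_changes(g$table)
  sub <- tab[tab$group %in% c("ASD", "DA"), ]
  est_sub <- estimate_mid_roc(sub, "pain_activity")
  manual <- as_outcome_table(as.data.frame(sub)[, prothresh:::.required_cols],
                             attr(tab, "instruments"))
  expect_equal(estimate_mid_roc(manual, "pain_activity")$mid, est_sub$mid)
  expect_lt(est_sub$n_improved + est_sub$n_not_improved,
            estimate_mid_roc(tab, "pain_activity")$n_improved +
              estimate_mid_roc(tab, "pain_activity")$n_not_improved)
})
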