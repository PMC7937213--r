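make_pass_table <- function(posts, grc, instrument = "pain_activity") {
  n <- length(posts)
  spec <- default_instruments()[[instrument]]
  rec <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)), group = "ET", timepoint = 6,
    instrument = instrument, baseline = (spec$scale_min + spec$scale_max) / 2,
    post = posts, grc = grc)
  as_outcome_table(rec, default_instruments()[instrument])
}

test_that("the anchor definition admits only {1} and {1,2} and dichotomizes accordingly", {
  expect_error(pass_anchor(c(1, 3)), "exactly")
  expect_error(pass_anchor(2), "exactly")
  expect_false(dichotomize_grc_for_pass(2, pass_anchor(1)))
  expect_true(dichotomize_grc_for_pass(2, pass_anchor(c(1, 2))))
  expect_true(dichotomize_grc_for_pass(1, pass_anchor(1)))
  # nobody excluded: worseners fall in the rest class
  expect_false(dichotomize_grc_for_pass(5, pass_anchor(1)))
})

test_that("a planted noise-free post threshold is recovered with AUC 1", {
  set.seed(31)
  posts <- round(runif(80, 0, 60))
  grc <- ifelse(posts <= 9, 1, sample(2:5, 80, replace = TRUE))
  est <- estimate_pass_roc(make_pass_table(posts, grc), "pain_activity",
                           pass_anchor(1))
  expect_equal(est$auc_estimate$auc, 1)
  hi <- max(posts[posts <= 9]); lo <- min(posts[posts > 9])
  expect_equal(est$pass_threshold, (hi + lo) / 2)
  expect_equal(est$well_region, "<=")
})

test_that("mirroring the scale maps one direction onto the other", {
  set.seed(32)
  posts <- round(runif(60, 0, 100))
  grc <- ifelse(posts <= 30, 1, sample(2:5, 60, replace = TRUE))
  pain <- make_pass_table(posts, grc, "pain_activity")
  cs <- make_pass_table(100 - posts, grc, "constant_murley")
  r_pain <- estimate_pass_roc(pain, "pain_activity", 1)
  r_cs <- estimate_pass_roc(cs, "constant_murley", 1)
  expect_equal(r_cs$pass_threshold, 100 - r_pain$pass_threshold)
  expect_equal(r_cs$sensitivity, r_pain$sensitivity)
  expect_equal(r_cs$well_region, ">=")
  p_pain <- estimate_pass_percentile(pain, "pain_activity", 1)
  p_cs <- estimate_pass_percentile(cs, "constant_murley", 1)
  expect_equal(p_cs$pass_threshold, 100 - p_pain$pass_threshold)
  expect_equal(p_cs$percentile, 0.25)
  expect_equal(p_pain$percentile, 0.75)
})

test_that("the percentile rule interpolates between order statistics", {
  est <- estimate_pass_percentile(
    make_pass_table(c(0, 2, 2, 4, 50, 60), c(1, 1, 1, 1, 4, 5)),
    "pain_activity", pass_anchor(1))
  expect_equal(est$pass_threshold, 2.5)  # hand: sorted {0,2,2,4}, h = 3.25
  expect_equal(est$n_satisfied, 4L)
  constant <- estimate_pass_percentile(
    make_pass_table(c(7, 7, 7, 30), c(1, 1, 1, 3)), "pain_activity", 1)
  expect_equal(constant$pass_threshold, 7)
})

test_that("the wider anchor never has fewer satisfied patients and PASS is never stricter", {
  for (s in 1:5) {
    tab <- generate_trial(scenario_library("fimpact-like", seed = s))$table
    for (ins in c("pain_activity", "constant_murley")) {
      e1 <- estimate_pass_roc(tab, ins, pass_anchor(1))
      e12 <- estimate_pass_roc(tab, ins, pass_anchor(c(1, 2)))
      expect_gte(e12$n_satisfied, e1$n_satisfied)
      # wider satisfied set admits more symptoms: threshold moves toward
      # (or stays at) the symptomatic side
      if (e1$well_region == "<=") {
        expect_gte(e12$pass_threshold, e1$pass_threshold)
      } else {
        expect_lte(e12$pass_threshold, e1$pass_threshold)
      }
    }
  }
})

test_that("empty satisfied class is an error", {
  tab <- make_pass_table(c(10, 20, 30), c(3, 4, 5))
  expect_error(estimate_pass_roc(tab, "pain_activity", 1), "satisfied class")
  expect_error(estimate_pass_percentile(tab, "pain_activity", 1), "satisfied class")
})
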