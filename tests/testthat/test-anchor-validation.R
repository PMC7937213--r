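test_that("spearman_rho matches hand-ranked values and handles degenerate input", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(1:10, -(1:10)), -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
  expect_warning(r <- spearman_rho(c(2, 2, 2), 1:3), "all-tied")
  expect_true(is.na(r))
  # pairwise deletion, then invariance to monotone rescaling
  x <- c(1, 2, NA, 4, 5); y <- c(2, 1, 7, 9, NA)
  expect_equal(spearman_rho(x, y), spearman_rho(exp(x), y * 100))
})

test_that("an anchor independent of the outcome gives near-zero correlations and an inadequate flag", {
  set.seed(51)
  n <- 400
  rec <- data.frame(
    patient_id = sprintf("P%03d", 1:n), group = "ET", timepoint = 6,
    instrument = "pain_activity", baseline = round(runif(n, 40, 90)),
    post = round(runif(n, 0, 90)), grc = sample(1:5, n, replace = TRUE))
  tab <- as_outcome_table(rec, default_instruments()["pain_activity"])
  rep <- validate_anchor(tab, "pain_activity", n_boot = 50, seed = 1)
  pooled <- rep$correlations[rep$correlations$timepoint == "pooled", ]
  expect_true(all(abs(pooled$rho) < 0.15))
  expect_false(rep$flags$adequate_change_correlation)
})

test_that("an anchor driven by the change score correlates positively with improvement for both directions", {
  for (s in 1:3) {
    tab <- compute_changes(
      generate_trial(scenario_library("fimpact-like", seed = s))$table)
    for (ins in c("pain_activity", "constant_murley")) {
      rep <- validate_anchor(tab, ins, n_boot = 20, seed = 1)
      pooled <- rep$correlations[rep$correlations$timepoint == "pooled", ]
      expect_gt(pooled$rho[pooled$pair == "grc_vs_change"], 0.3)
      expect_true(rep$flags$adequate_change_correlation)
      expect_equal(sort(unique(rep$correlations$timepoint)),
                   sort(c(unique(as.character(
                     tab$timepoint[tab$instrument == ins])), "pooled")))
    }
  }
})

test_that("paper-sign mode flips the printed sign for pain but not function instruments", {
  tab <- compute_changes(
    generate_trial(scenario_library("fimpact-like", seed = 2))$table)
  ali <- validate_anchor(tab, "pain_activity", n_boot = 10, seed = 1,
                         sign = "aligned")
  pap <- validate_anchor(tab, "pain_activity", n_boot = 10, seed = 1,
                         sign = "paper")
  rho <- function(r, p) {
    d <- r$correlations
    d$rho[d$timepoint == "pooled" & d$pair == p]
  }
  expect_equal(rho(pap, "grc_vs_change"), -rho(ali, "grc_vs_change"))
  expect_equal(rho(pap, "grc_vs_post"), -rho(ali, "grc_vs_post"))
  cs_ali <- validate_anchor(tab, "constant_murley", n_boot = 10, seed = 1)
  cs_pap <- validate_anchor(tab, "constant_murley", n_boot = 10, seed = 1,
                            sign = "paper")
  expect_equal(rho(cs_pap, "grc_vs_change"), rho(cs_ali, "grc_vs_change"))
})

test_that("flags are deterministic functions of the estimates and thresholds", {
  tab <- compute_changes(
    generate_trial(scenario_library("fimpact-like", seed = 4))$table)
  rep <- validate_anchor(tab, "pain_rest", n_boot = 20, seed = 1)
  pooled <- rep$correlations[rep$correlations$timepoint == "pooled", ]
  rho <- function(p) pooled$rho[pooled$pair == p]
  expect_equal(rep$flags$adequate_change_correlation,
               abs(rho("grc_vs_change")) >= rep$adequacy_threshold)
  expect_equal(rep$flags$near_zero_baseline,
               abs(rho("grc_vs_baseline")) < rep$baseline_threshold)
  expect_equal(rep$flags$change_exceeds_post,
               abs(rho("grc_vs_change")) > abs(rho("grc_vs_post")))
  strict <- validate_anchor(tab, "pain_rest", adequacy_threshold = 0.99,
                            n_boot = 20, seed = 1)
  expect_false(strict$flags$adequate_change_correlation)
})
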