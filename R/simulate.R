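#' Per-instrument simulation parameters
#'
#' @param spec An [instrument_spec()].
#' @param baseline_mean,baseline_sd Baseline score distribution (normal,
#'   clipped to the scale). `baseline_sd = 0` fixes every baseline, which
#'   makes the implied post-score ("well") threshold exact -- useful for
#'   planted-threshold recovery checks.
#' @param effect_scale Score units of observed change per unit of latent
#'   improvement: the bridge from the latent scale to the instrument scale.
#' @param noise_sd Measurement noise SD of the observed change, in score
#'   units. Relative to `effect_scale` this sets how well the instrument can
#'   discriminate anchor groups.
#' @param timepoints Follow-up months at which the instrument is measured.
#' @return A `sim_instrument` parameter list.
#' @export
sim_instrument <- function(spec, baseline_mean, baseline_sd, effect_scale,
                           noise_sd, timepoints) {
  stopifnot(inherits(spec, "instrument_spec"),
            baseline_sd >= 0, noise_sd >= 0, effect_scale > 0,
            length(timepoints) >= 1)
  structure(list(spec = spec, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, effect_scale = effect_scale,
                 noise_sd = noise_sd, timepoints = sort(timepoints)),
            class = "sim_instrument")
}

.default_sim_instruments <- function() {
  ins <- default_instruments()
  list(
    pain_rest = sim_instrument(ins$pain_rest, baseline_mean = 40,
                               baseline_sd = 18, effect_scale = 16.25,
                               noise_sd = 38, timepoints = c(6, 12, 24)),
    pain_activity = sim_instrument(ins$pain_activity, baseline_mean = 70,
                                   baseline_sd = 15, effect_scale = 25,
                                   noise_sd = 10, timepoints = c(6, 12, 24)),
    constant_murley = sim_instrument(ins$constant_murley, baseline_mean = 50,
                                     baseline_sd = 12, effect_scale = 12.5,
                                     noise_sd = 7, timepoints = c(6, 24)),
    sst = sim_instrument(ins$sst, baseline_mean = 6, baseline_sd = 2.5,
                         effect_scale = 1.875, noise_sd = 0.8,
                         timepoints = c(6, 24))
  )
}

#' Configuration of a synthetic anchored-trial cohort
#'
#' The generator draws, per patient x timepoint, a latent improvement
#' `L ~ Normal(latent_mean, latent_sd)` (with a within-patient random effect
#' carrying `patient_share` of the variance, so a patient's follow-ups are
#' correlated). Each instrument observes `effect_scale * L` plus
#' measurement noise as its change score, signed by the instrument's
#' improvement direction; post = baseline +/- change, clipped to the scale
#' and (optionally) rounded to integers. The 5-level GRC anchor is an
#' ordinal cut of
#' `U = (1 - w) * L + w * P + anchor noise`,
#' where `P` is the cohort-standardized composite of the oriented post
#' scores mapped back to the latent scale and `w = recall_bias_weight`:
#' `w > 0` makes the anchor reflect the current state rather than true
#' change, the recall-bias failure mode. GRC answer k is assigned when `U`
#' falls between `tau[k]` and `tau[k-1]` (`tau` strictly decreasing; `U >=
#' tau[1]` gives answer 1, `U < tau[4]` gives answer 5 = worse).
#'
#' The implied ground-truth thresholds follow from the cut points: a
#' patient is "improved" (GRC 1-3) exactly when `U >= tau[3]`, so with a
#' noise-free anchor the true improvement threshold on an instrument's
#' scale is `effect_scale * tau[3]`; likewise `effect_scale * tau[1]` is
#' the improvement needed to be "very satisfied".
#'
#' @param n_patients Cohort size (default 193).
#' @param groups Named numeric vector of allocation weights (default
#'   ASD:DA:ET = 1:1:1, the two surgical arms and exercise therapy).
#' @param instruments Named list of [sim_instrument()] parameter sets.
#' @param latent_mean,latent_sd Latent improvement distribution (default
#'   N(2, 1): most of the cohort improves).
#' @param patient_share Fraction of latent variance between patients
#'   (default 0.5).
#' @param baseline_share Fraction of baseline variance carried by a shared
#'   per-patient severity factor (default 0.5, i.e. baseline correlation
#'   ~0.5 across instruments): severe patients are severe on every
#'   measure, signed by each instrument's direction. This is what lets a
#'   recall-biased anchor track every instrument's post score.
#' @param tau Strictly decreasing GRC cut points on the latent scale,
#'   `tau[1] > tau[2] > tau[3] > tau[4]`. The default `c(2.5, 1.9, 0.8,
#'   0.04)` yields roughly 31% answer 1, 11% answers 4-5 and 2-3% worseners.
#' @param anchor_noise_sd SD of the anchor noise; a scalar, or a named
#'   vector by timepoint (e.g. `c("6" = 0.8, "24" = 0.2)`) for anchors
#'   whose reliability changes over follow-up.
#' @param recall_bias_weight Weight `w` in `[0, 1)` on the post-score
#'   composite in the anchor (default 0).
#' @param missing_post_rate Probability a post score is missing, per row.
#' @param missing_grc_rate Probability the GRC is missing, per patient x
#'   timepoint (shared across instruments, as a questionnaire item would be).
#' @param round_scores Round generated scores to integers (mm / points)?
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `trial_sim_config`.
#' @export
trial_sim_config <- function(n_patients = 193,
                             groups = c(ASD = 1, DA = 1, ET = 1),
                             instruments = .default_sim_instruments(),
                             latent_mean = 2, latent_sd = 1,
                             patient_share = 0.5,
                             baseline_share = 0.5,
                             tau = c(2.5, 1.9, 0.8, 0.04),
                             anchor_noise_sd = 0.4,
                             recall_bias_weight = 0,
                             missing_post_rate = 0.07,
                             missing_grc_rate = 0.02,
                             round_scores = TRUE,
                             seed = 1) {
  stopifnot(n_patients >= 1, length(groups) >= 1, !is.null(names(groups)),
            latent_sd >= 0, patient_share >= 0, patient_share <= 1,
            baseline_share >= 0, baseline_share <= 1,
            length(tau) == 4, all(anchor_noise_sd >= 0),
            recall_bias_weight >= 0, recall_bias_weight < 1,
            missing_post_rate >= 0, missing_post_rate < 1,
             missing_grc_rate >= 0, missing_grc_rate < 1)
  if (any(diff(tau) >= 0)) {
    stop("tau must be strictly decreasing (tau[1] > ... > tau[4])",
         call. = FALSE)
  }
  structure(
    list(n_patients = n_patients, groups = groups, instruments = instruments,
         latent_mean = latent_mean, latent_sd = latent_sd,
         patient_share = patient_share, baseline_share = baseline_share,
         tau = tau,
         anchor_noise_sd = anchor_noise_sd,
         recall_bias_weight = recall_bias_weight,
         missing_post_rate = missing_post_rate,
         missing_grc_rate = missing_grc_rate,
         round_scores = round_scores, seed = seed),
    class = "trial_sim_config"
  )
}

.anchor_noise_at <- function(config, tp) {
  s <- config$anchor_noise_sd
  if (length(s) == 1L && is.null(names(s))) return(unname(s))
  if (!as.character(tp) %in% names(s)) {
    stop("anchor_noise_sd has no entry for timepoint ", tp, call. = FALSE)
  }
  unname(s[[as.character(tp)]])
}

.clip_round <- function(x, spec, round_scores) {
  x <- pmin(pmax(x, spec$scale_min), spec$scale_max)
  if (round_scores || spec$integer_valued) x <- round(x)
  x
}

#' Generate a synthetic anchored-trial cohort
#'
#' Draws a full cohort under a [trial_sim_config()] and returns both the
#' analysis table and the generating ground truth, so estimator recovery
#' can be checked against known thresholds.
#'
#' @param config A `trial_sim_config`.
#' @return A list with:
#' * `table`: an `anchored_outcome_table` (long format, one row per
#'   patient x timepoint x instrument, with missingness applied);
#' * `truth`: list with `latent` (data frame of patient, timepoint, latent
#'   improvement `L`, anchor signal `U`, and the pre-missingness GRC),
#'   `thresholds` (per instrument: `true_mid` = improvement needed to be
#'   rated improved, `true_satisfied_improvement`, and `true_pass_post`,
#'   the implied post-score threshold -- exact only when `baseline_sd = 0`,
#'   otherwise `NA`), and the `config`.
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  w <- config$recall_bias_weight

  alloc <- rep(names(config$groups),
               times = diff(round(cumsum(c(0, config$groups)) / sum(config$groups) * n)))
  patient <- sprintf("P%03d", seq_len(n))

  tps <- sort(unique(unlist(lapply(config$instruments, `[[`, "timepoints"))))
  sd_b <- config$latent_sd * sqrt(config$patient_share)
  sd_e <- config$latent_sd * sqrt(1 - config$patient_share)
  b_p <- stats::rnorm(n, 0, sd_b)
  severity <- stats::rnorm(n)  # shared across instruments, signed by direction
  latent <- expand.grid(patient_id = patient, timepoint = tps,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  latent <- latent[order(latent$patient_id, latent$timepoint), , drop = FALSE]
  rownames(latent) <- NULL
  latent$L <- config$latent_mean + b_p[match(latent$patient_id, patient)] +
    stats::rnorm(nrow(latent), 0, sd_e)

  # instrument-level scores
  rows <- list()
  for (nm in names(config$instruments)) {
    par <- config$instruments[[nm]]
    spec <- par$spec
    sgn <- if (spec$direction == "decrease_is_better") 1 else -1
    base_z <- sqrt(config$baseline_share) * sgn * severity +
      sqrt(1 - config$baseline_share) * stats::rnorm(n)
    base <- .clip_round(par$baseline_mean + par$baseline_sd * base_z,
                        spec, config$round_scores)
    for (tp in par$timepoints) {
      L_tp <- latent$L[latent$timepoint == tp]
      delta <- par$effect_scale * L_tp + stats::rnorm(n, 0, par$noise_sd)
      post_raw <- if (spec$direction == "decrease_is_better") base - delta else base + delta
      post <- .clip_round(post_raw, spec, config$round_scores)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient, group = alloc, timepoint = tp,
        instrument = nm, baseline = base, post = post,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)

  # anchor signal: latent improvement, optionally blended with the current
  # state (recall bias), plus noise
  if (w > 0) {
    zsum <- numeric(nrow(latent)); zcnt <- numeric(nrow(latent))
    for (nm in names(config$instruments)) {
      par <- config$instruments[[nm]]
      sel <- tab$instrument == nm
      oriented <- if (par$spec$direction == "decrease_is_better") -tab$post[sel] else tab$post[sel]
      z <- as.numeric(scale(oriented))
      key <- match(paste(tab$patient_id[sel], tab$timepoint[sel]),
                   paste(latent$patient_id, latent$timepoint))
      zsum[key] <- zsum[key] + z
      zcnt[key] <- zcnt[key] + 1
    }
    P <- config$latent_mean + config$latent_sd * zsum / pmax(zcnt, 1)
  } else {
    P <- 0
  }
  noise <- stats::rnorm(nrow(latent)) *
    vapply(latent$timepoint, function(tp) .anchor_noise_at(config, tp), 0)
  latent$U <- (1 - w) * latent$L + w * P + noise
  latent$grc <- 5L - findInterval(latent$U, rev(config$tau))

  tab$grc <- latent$grc[match(paste(tab$patient_id, tab$timepoint),
                              paste(latent$patient_id, latent$timepoint))]

  # missingness: post per row; grc per patient x timepoint
  if (config$missing_post_rate > 0) {
    tab$post[stats::runif(nrow(tab)) < config$missing_post_rate] <- NA
  }
  if (config$missing_grc_rate > 0) {
    drop_pt <- latent[stats::runif(nrow(latent)) < config$missing_grc_rate,
                      c("patient_id", "timepoint")]
    if (nrow(drop_pt) > 0) {
      tab$grc[paste(tab$patient_id, tab$timepoint) %in%
                paste(drop_pt$patient_id, drop_pt$timepoint)] <- NA
    }
  }

  specs <- lapply(config$instruments, `[[`, "spec")
  thresholds <- lapply(config$instruments, function(par) {
    exact_base <- par$baseline_sd == 0
    pass_change <- par$effect_scale * config$tau[1L]
    pass_post <- if (exact_base) {
      raw <- if (par$spec$direction == "decrease_is_better") {
        .clip_round(par$baseline_mean, par$spec, config$round_scores) - pass_change
      } else {
        .clip_round(par$baseline_mean, par$spec, config$round_scores) + pass_change
      }
      pmin(pmax(raw, par$spec$scale_min), par$spec$scale_max)
    } else NA_real_
    list(true_mid = par$effect_scale * config$tau[3L],
         true_satisfied_improvement = pass_change,
         true_pass_post = pass_post)
  })

  list(table = as_outcome_table(tab, instruments = specs),
       truth = list(latent = latent, thresholds = thresholds, config = config))
}

#' Named library of simulation scenarios
#'
#' Ships the study conditions the test-suite and examples run under:
#'
#' * `"fimpact-like"`: the default cohort -- 193 patients, three arms,
#'   pain VAS at 6/12/24 months and CS/SST at 6/24, a moderately noisy
#'   anchor, item-level missingness. Pain at rest is given weak
#'   discrimination (its change is mostly noise) and the other three
#'   instruments good-to-excellent discrimination, reproducing the
#'   qualitative spread seen in shoulder-trial anchor studies.
#' * `"perfect-anchor"`: all noise off, fixed baselines, no rounding or
#'   missingness -- the anchor is a deterministic step function of latent
#'   improvement, so planted thresholds are recovered exactly up to
#'   midpoint resolution (and the implied post-score PASS threshold is
#'   exact).
#' * `"worthless-anchor"`: anchor noise swamps the signal; the GRC carries
#'   no information and every AUC is near 0.5.
#' * `"recall-biased"`: anchor weight 0.7 on the current post state, the
#'   mechanism that makes GRC correlate more with post scores than with
#'   change scores.
#'
#' @param name Optional scenario name; omitted, the full named list of
#'   configs is returned.
#' @param seed Seed stored in the returned config(s).
#' @return A `trial_sim_config`, or a named list of them.
#' @export
scenario_library <- function(name = NULL, seed = 1) {
  perfect_instruments <- lapply(.default_sim_instruments(), function(par) {
    sim_instrument(par$spec, baseline_mean = par$baseline_mean,
                   baseline_sd = 0, effect_scale = par$effect_scale,
                   noise_sd = 0, timepoints = par$timepoints)
  })
  lib <- list(
    "fimpact-like" = trial_sim_config(seed = seed),
    "perfect-anchor" = trial_sim_config(
      instruments = perfect_instruments, anchor_noise_sd = 0,
      missing_post_rate = 0, missing_grc_rate = 0,
      round_scores = FALSE, seed = seed),
    "worthless-anchor" = trial_sim_config(anchor_noise_sd = 10, seed = seed),
    "recall-biased" = trial_sim_config(recall_bias_weight = 0.7, seed = seed)
  )
  if (is.null(name)) return(lib)
  if (!name %in% names(lib)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(lib), collapse = ", "), call. = FALSE)
  }
  lib[[name]]
}
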