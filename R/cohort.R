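# Individual-level synthetic cohorts emulating the diagnostic-accuracy
# survey behind the screening parameters, plus a per-woman microsimulation of
# the full decision tree used as a brute-force oracle for the analytic
# engine. The generator is parameterised by per-woman accuracies
# (sensitivity/specificity, with EPDS accuracy conditional on the Whooley
# result to induce the two-stage dependence); simple random sampling, no
# survey weighting.

#' Cohort generator configuration
#'
#' @param n_women Cohort size (>= 1).
#' @param prevalence Probability of major depressive disorder (gold-standard
#'   diagnosis).
#' @param whooley_sens,whooley_spec Whooley sensitivity and specificity.
#' @param epds_sens_given_wpos,epds_sens_given_wneg EPDS sensitivity among
#'   depressed women, conditional on the Whooley result.
#' @param epds_fpr_given_wpos,epds_fpr_given_wneg EPDS false-positive rate
#'   among non-depressed women, conditional on the Whooley result.
#' @param no_screen_sens,no_screen_spec Accuracy of routine midwife judgement
#'   (used only when simulating the no-screen judgement field).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `antescreen_cohort_config`.
#' @seealso [derive_cohort_config()] for the configuration implied by a model
#'   parameter set.
#' @export
cohort_config <- function(n_women, prevalence,
                          whooley_sens, whooley_spec,
                          epds_sens_given_wpos, epds_fpr_given_wpos,
                          epds_sens_given_wneg, epds_fpr_given_wneg,
                          no_screen_sens = NA_real_, no_screen_spec = NA_real_,
                          seed = NULL) {
  stopifnot(n_women >= 1)
  probs <- c(prevalence = prevalence, whooley_sens = whooley_sens,
             whooley_spec = whooley_spec,
             epds_sens_given_wpos = epds_sens_given_wpos,
             epds_fpr_given_wpos = epds_fpr_given_wpos,
             epds_sens_given_wneg = epds_sens_given_wneg,
             epds_fpr_given_wneg = epds_fpr_given_wneg)
  bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(bad))
    stop("cohort_config(): not a probability: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(n_women = as.integer(n_women), prevalence = prevalence,
                 whooley_sens = whooley_sens, whooley_spec = whooley_spec,
                 epds_sens_given_wpos = epds_sens_given_wpos,
                 epds_fpr_given_wpos = epds_fpr_given_wpos,
                 epds_sens_given_wneg = epds_sens_given_wneg,
                 epds_fpr_given_wneg = epds_fpr_given_wneg,
                 no_screen_sens = no_screen_sens,
                 no_screen_spec = no_screen_spec,
                 seed = seed),
            class = "antescreen_cohort_config")
}

#' Cohort configuration implied by a model parameter set
#'
#' Inverts the strategy-level probability blocks back to per-woman
#' accuracies: prevalence and Whooley sensitivity/specificity from the
#' Whooley block; EPDS accuracy among Whooley-positives from the two-stage
#' block; EPDS accuracy among Whooley-negatives solved so that the marginal
#' EPDS accuracy matches the EPDS block; midwife-judgement accuracy from the
#' no-screen block (whose source survey had a different prevalence -- the
#' conditional accuracies transfer, the marginal positivity rate does not).
#'
#' @param params An `antescreen_params` object.
#' @param n_women Cohort size.
#' @param seed Optional seed stored in the configuration.
#' @return An `antescreen_cohort_config` object.
#' @export
#' @examples
#' cfg <- derive_cohort_config(default_parameters(), n_women = 1000)
#' cfg$prevalence  # ~ 0.101, the survey's weighted prevalence
derive_cohort_config <- function(params, n_women = 10000, seed = NULL) {
  m <- param_means(params)
  w <- m$accuracy$whooley
  joint_pos_dep <- w$p_positive * w$p_tp_given_positive
  joint_neg_dep <- (1 - w$p_positive) * (1 - w$p_tn_given_negative)
  prev <- joint_pos_dep + joint_neg_dep
  sens_w <- joint_pos_dep / prev
  spec_w <- (1 - w$p_positive) * w$p_tn_given_negative / (1 - prev)

  ts <- m$accuracy$whooley_epds
  p_dep_wpos <- ts$p_stage2_positive_given_stage1_positive * ts$p_tp_given_both_positive +
    (1 - ts$p_stage2_positive_given_stage1_positive) *
      (1 - ts$p_tn_given_stage1pos_stage2neg)
  e_sens_wpos <- ts$p_stage2_positive_given_stage1_positive *
    ts$p_tp_given_both_positive / p_dep_wpos
  e_fpr_wpos <- ts$p_stage2_positive_given_stage1_positive *
    (1 - ts$p_tp_given_both_positive) / (1 - p_dep_wpos)

  e <- m$accuracy$epds
  prev_e <- e$p_positive * e$p_tp_given_positive +
    (1 - e$p_positive) * (1 - e$p_tn_given_negative)
  sens_e <- e$p_positive * e$p_tp_given_positive / prev_e
  spec_e <- (1 - e$p_positive) * e$p_tn_given_negative / (1 - prev_e)
  e_sens_wneg <- (sens_e - sens_w * e_sens_wpos) / (1 - sens_w)
  e_fpr_wneg <- ((1 - spec_e) - (1 - spec_w) * e_fpr_wpos) / spec_w

  ns <- m$accuracy$no_screen
  prev_ns <- ns$p_positive * ns$p_tp_given_positive +
    (1 - ns$p_positive) * (1 - ns$p_tn_given_negative)
  sens_ns <- ns$p_positive * ns$p_tp_given_positive / prev_ns
  spec_ns <- (1 - ns$p_positive) * ns$p_tn_given_negative / (1 - prev_ns)

  cohort_config(n_women, prev, sens_w, spec_w,
                e_sens_wpos, e_fpr_wpos, e_sens_wneg, e_fpr_wneg,
                no_screen_sens = sens_ns, no_screen_spec = spec_ns,
                seed = seed)
}

#' Simulate a synthetic accuracy-survey cohort
#'
#' Each woman gets a gold-standard diagnosis at the configured prevalence, a
#' Whooley result from the Whooley accuracy, an EPDS result from the EPDS
#' accuracy conditional on her Whooley result, and (when the configuration
#' carries judgement accuracies) a routine-judgement result.
#'
#' @param config An `antescreen_cohort_config` object.
#' @return Data frame with one row per woman: `id`, `true_depressed`,
#'   `whooley_positive`, `epds_positive`, `no_screen_positive` (NA when no
#'   judgement accuracies were configured).
#' @export
#' @examples
#' cfg <- derive_cohort_config(default_parameters(), n_women = 500, seed = 42)
#' head(simulate_cohort(cfg))
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "antescreen_cohort_config"))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  n <- config$n_women
  dep <- stats::rbinom(n, 1L, config$prevalence) == 1L
  p_wpos <- ifelse(dep, config$whooley_sens, 1 - config$whooley_spec)
  wpos <- stats::rbinom(n, 1L, p_wpos) == 1L
  p_epos <- ifelse(dep,
                   ifelse(wpos, config$epds_sens_given_wpos,
                          config$epds_sens_given_wneg),
                   ifelse(wpos, config$epds_fpr_given_wpos,
                          config$epds_fpr_given_wneg))
  epos <- stats::rbinom(n, 1L, p_epos) == 1L
  if (is.finite(config$no_screen_sens)) {
    p_npos <- ifelse(dep, config$no_screen_sens, 1 - config$no_screen_spec)
    npos <- stats::rbinom(n, 1L, p_npos) == 1L
  } else {
    npos <- rep(NA, n)
  }
  data.frame(id = seq_len(n), true_depressed = dep, whooley_positive = wpos,
             epds_positive = epos, no_screen_positive = npos)
}

#' Per-woman screen result and outcome class for a strategy
#'
#' @keywords internal
classify_outcomes <- function(cohort, strategy) {
  strategy <- match.arg(strategy, strategies())
  positive <- switch(strategy,
    whooley = cohort$whooley_positive,
    epds = cohort$epds_positive,
    whooley_epds = cohort$whooley_positive & cohort$epds_positive,
    no_screen = cohort$no_screen_positive)
  if (anyNA(positive))
    stop("cohort has no simulated '", strategy, "' screen results", call. = FALSE)
  ifelse(positive,
         ifelse(cohort$true_depressed, "tp", "fp"),
         ifelse(cohort$true_depressed, "fn", "tn"))
}

#' Re-estimate a strategy's screening parameters from a cohort
#'
#' Observed proportions with their raw event counts, in the shape of the
#' model's accuracy block for that strategy, ready for beta construction.
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @param strategy One of [strategies()].
#' @return List with `strategy`, `estimates` (named proportions), `events`
#'   (numerators), `n` (denominators), and `class_counts` (tp/fp/tn/fn).
#' @export
estimate_strategy_params <- function(cohort, strategy) {
  strategy <- match.arg(strategy, strategies())
  stopifnot(nrow(cohort) >= 1)
  prop <- function(num, denom, cell) {
    if (sum(denom) == 0)
      stop("cannot estimate '", cell, "' for strategy '", strategy,
           "': empty conditioning cell", call. = FALSE)
    c(p = sum(num & denom) / sum(denom), events = sum(num & denom),
      n = sum(denom))
  }
  dep <- cohort$true_depressed
  all_women <- rep(TRUE, nrow(cohort))
  if (strategy == "whooley_epds") {
    w <- cohort$whooley_positive
    e <- cohort$epds_positive
    est <- rbind(
      p_stage1_positive = prop(w, all_women, "p_stage1_positive"),
      p_stage2_positive_given_stage1_positive =
        prop(e, w, "p_stage2_positive_given_stage1_positive"),
      p_tp_given_both_positive = prop(dep, w & e, "p_tp_given_both_positive"),
      p_tn_given_stage1pos_stage2neg =
        prop(!dep, w & !e, "p_tn_given_stage1pos_stage2neg"),
      p_tn_given_stage1_negative = prop(!dep, !w, "p_tn_given_stage1_negative")
    )
  } else {
    positive <- switch(strategy, whooley = cohort$whooley_positive,
                       epds = cohort$epds_positive,
                       no_screen = cohort$no_screen_positive)
    if (anyNA(positive))
      stop("cohort has no simulated '", strategy, "' screen results",
           call. = FALSE)
    est <- rbind(
      p_positive = prop(positive, all_women, "p_positive"),
      p_tp_given_positive = prop(dep, positive, "p_tp_given_positive"),
      p_tn_given_negative = prop(!dep, !positive, "p_tn_given_negative")
    )
  }
  cls <- classify_outcomes(cohort, strategy)
  list(strategy = strategy,
       estimates = stats::setNames(est[, "p"], rownames(est)),
       events = stats::setNames(est[, "events"], rownames(est)),
       n = stats::setNames(est[, "n"], rownames(est)),
       class_counts = c(tp = sum(cls == "tp"), fp = sum(cls == "fp"),
                        tn = sum(cls == "tn"), fn = sum(cls == "fn")))
}

#' Strategy-level probabilities implied by a cohort configuration
#'
#' The expected values of [estimate_strategy_params()] under the generator:
#' the yardstick for parameter-recovery checks. For the instrument
#' strategies these reproduce the model's accuracy blocks (up to their mutual
#' printing-precision inconsistencies); the no-screen block is reproduced in
#' its conditional accuracies but not its positivity rate, because the
#' generator applies the judgement accuracy at the survey prevalence rather
#' than the no-screen source study's.
#'
#' @param config An `antescreen_cohort_config` object.
#' @param strategy One of [strategies()].
#' @return Named numeric vector of expected proportions.
#' @export
implied_strategy_accuracy <- function(config, strategy) {
  strategy <- match.arg(strategy, strategies())
  prev <- config$prevalence
  single <- function(sens, spec) {
    p_pos <- prev * sens + (1 - prev) * (1 - spec)
    c(p_positive = p_pos,
      p_tp_given_positive = prev * sens / p_pos,
      p_tn_given_negative = (1 - prev) * spec / (1 - p_pos))
  }
  if (strategy == "whooley")
    return(single(config$whooley_sens, config$whooley_spec))
  if (strategy == "no_screen")
    return(single(config$no_screen_sens, config$no_screen_spec))
  # joint cells p(D, W, E)
  sens_e_marg <- config$whooley_sens * config$epds_sens_given_wpos +
    (1 - config$whooley_sens) * config$epds_sens_given_wneg
  fpr_e_marg <- (1 - config$whooley_spec) * config$epds_fpr_given_wpos +
    config$whooley_spec * config$epds_fpr_given_wneg
  if (strategy == "epds")
    return(single(sens_e_marg, 1 - fpr_e_marg))
  dep_wpos <- prev * config$whooley_sens
  nondep_wpos <- (1 - prev) * (1 - config$whooley_spec)
  p_wpos <- dep_wpos + nondep_wpos
  both_dep <- dep_wpos * config$epds_sens_given_wpos
  both_nondep <- nondep_wpos * config$epds_fpr_given_wpos
  p_both <- both_dep + both_nondep
  s1pos_s2neg_dep <- dep_wpos * (1 - config$epds_sens_given_wpos)
  s1pos_s2neg_nondep <- nondep_wpos * (1 - config$epds_fpr_given_wpos)
  c(p_stage1_positive = p_wpos,
    p_stage2_positive_given_stage1_positive = p_both / p_wpos,
    p_tp_given_both_positive = both_dep / p_both,
    p_tn_given_stage1pos_stage2neg =
      s1pos_s2neg_nondep / (s1pos_s2neg_dep + s1pos_s2neg_nondep),
    p_tn_given_stage1_negative =
      (1 - prev) * config$whooley_spec / (1 - p_wpos))
}

#' Microsimulate one screening arm woman by woman
#'
#' Brute-force oracle for [evaluate_arm()]: every woman walks the decision
#' tree with a Bernoulli draw at each chance node (treatment modality,
#' response, spontaneous recovery, later identification), and QALYs and costs
#' are assigned by the same rules as [pathway_values()]. For the three
#' instrument strategies the outcome class comes from the cohort's simulated
#' screen results; the no-screen judgement is not part of the emulated
#' accuracy survey (its source data imply a different prevalence), so that
#' arm's screening node is replayed from the strategy's analytic outcome
#' distribution.
#'
#' @param cohort Data frame from [simulate_cohort()].
#' @param strategy One of [strategies()].
#' @param params An `antescreen_params` object.
#' @return List with `women` (per-woman records: outcome class, pathway
#'   indicators, realised QALY and cost), `mean_qaly`, `mean_cost`,
#'   `se_qaly`, `se_cost` (arm means include the screening cost).
#' @export
microsimulate_arm <- function(cohort, strategy, params) {
  strategy <- match.arg(strategy, strategies())
  n <- nrow(cohort)
  m <- param_means(params)
  if (strategy == "no_screen") {
    dist <- outcome_distribution(strategy, params)
    cls <- sample(c("tp", "fp", "tn", "fn"), n, replace = TRUE,
                  prob = unlist(dist))
  } else {
    cls <- classify_outcomes(cohort, strategy)
  }
  tr <- m$treatment
  q <- m$qalys
  co <- m$costs

  is_tp <- cls == "tp"; is_fp <- cls == "fp"
  is_tn <- cls == "tn"; is_fn <- cls == "fn"

  spont <- rep(NA, n)
  spont[is_fn] <- stats::rbinom(sum(is_fn), 1L, tr$p_spontaneous) == 1L
  later <- rep(NA, n)
  undet <- is_fn & !spont
  later[undet] <- stats::rbinom(sum(undet), 1L, tr$p_later_id) == 1L

  treated <- is_tp | (undet & later %in% TRUE)
  gets_modality <- treated | is_fp
  fsh <- rep(NA, n)
  fsh[gets_modality] <- stats::rbinom(sum(gets_modality), 1L, tr$p_fsh) == 1L
  responded <- rep(NA, n)
  responded[treated] <- stats::rbinom(sum(treated), 1L,
    ifelse(fsh[treated], tr$p_respond_fsh, tr$p_respond_hipt)) == 1L

  q_dn <- q$depressed_to_nondepressed
  q_dd <- q$depressed_to_depressed
  q_nn <- q$nondepressed_to_nondepressed
  modality_cost <- ifelse(fsh, co$c_fsh, co$c_hipt)

  qaly <- numeric(n)
  cost <- numeric(n)
  qaly[treated] <- ifelse(responded[treated], q_dn, q_dd)
  cost[treated] <- modality_cost[treated] +
    ifelse(responded[treated], co$other_care_nondepressed, co$other_care_depressed)
  qaly[is_fp] <- tr$fp_qaly_multiplier * q_nn
  cost[is_fp] <- tr$fp_resource_fraction * modality_cost[is_fp] +
    co$other_care_nondepressed
  qaly[is_tn] <- q_nn
  cost[is_tn] <- co$other_care_nondepressed
  rec <- is_fn & spont %in% TRUE
  qaly[rec] <- q_dn
  cost[rec] <- co$other_care_nondepressed
  missed <- undet & later %in% FALSE
  qaly[missed] <- q_dd
  cost[missed] <- co$other_care_depressed

  screen_cost <- m$costs$screen_cost[[strategy]]
  cost <- cost + screen_cost
  women <- data.frame(id = cohort$id, outcome_class = cls,
                      spontaneously_recovered = spont,
                      later_identified = later,
                      treated = treated,
                      modality_fsh = fsh, responded = responded,
                      qaly = qaly, cost = cost)
  list(women = women,
       mean_qaly = mean(qaly), mean_cost = mean(cost),
       se_qaly = stats::sd(qaly) / sqrt(n),
       se_cost = stats::sd(cost) / sqrt(n))
}
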