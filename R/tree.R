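# Decision-tree evaluation: screening node -> outcome class distribution,
# treatment pathway -> expected QALY and cost per outcome class, arm value =
# class-probability-weighted expectation plus the arm's screening cost.
# All arithmetic is written to be vectorised, so the same code evaluates the
# base case (scalars) and the PSA draw table (vectors).

#' Outcome-class distribution of a single-stage screen
#'
#' Splits a cohort into true positive, false positive, true negative and
#' false negative fractions from the marginal screen-positive probability and
#' the two conditional accuracies. Complements are computed, never supplied,
#' so the four classes always partition the cohort.
#'
#' @param p_positive Probability of a positive screen.
#' @param p_tp_given_positive Probability a positive screen is a true positive.
#' @param p_tn_given_negative Probability a negative screen is a true negative.
#' @return List with components `p_tp`, `p_fp`, `p_tn`, `p_fn` (vectorised
#'   over the inputs), summing to 1.
#' @export
#' @examples
#' outcome_distribution_single(0.0438, 0.6667, 0.8855)  # no-screen base case
outcome_distribution_single <- function(p_positive, p_tp_given_positive,
                                        p_tn_given_negative) {
  check_unit_interval(p_positive = p_positive,
                      p_tp_given_positive = p_tp_given_positive,
                      p_tn_given_negative = p_tn_given_negative)
  list(p_tp = p_positive * p_tp_given_positive,
       p_fp = p_positive * (1 - p_tp_given_positive),
       p_tn = (1 - p_positive) * p_tn_given_negative,
       p_fn = (1 - p_positive) * (1 - p_tn_given_negative))
}

#' Outcome-class distribution of the two-stage (Whooley then EPDS) screen
#'
#' Only women positive on both stages screen positive overall. Stage-one
#' negatives and stage-one-positive/stage-two-negative women are screen
#' negative, each group with its own true-negative probability.
#'
#' @param acc Two-stage accuracy block: a list (of scalars or vectors) with
#'   elements `p_stage1_positive`, `p_stage2_positive_given_stage1_positive`,
#'   `p_tp_given_both_positive`, `p_tn_given_stage1pos_stage2neg`,
#'   `p_tn_given_stage1_negative`.
#' @return List with components `p_tp`, `p_fp`, `p_tn`, `p_fn`, summing to 1.
#' @export
outcome_distribution_two_stage <- function(acc) {
  need <- c("p_stage1_positive", "p_stage2_positive_given_stage1_positive",
            "p_tp_given_both_positive", "p_tn_given_stage1pos_stage2neg",
            "p_tn_given_stage1_negative")
  missing <- setdiff(need, names(acc))
  if (length(missing))
    stop("two-stage accuracy block is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  acc <- lapply(acc[need], leaf_mean)
  do.call(check_unit_interval, acc)
  s1 <- acc$p_stage1_positive
  s2 <- acc$p_stage2_positive_given_stage1_positive
  both_pos <- s1 * s2
  s1pos_s2neg <- s1 * (1 - s2)
  s1neg <- 1 - s1
  list(
    p_tp = both_pos * acc$p_tp_given_both_positive,
    p_fp = both_pos * (1 - acc$p_tp_given_both_positive),
    p_tn = s1pos_s2neg * acc$p_tn_given_stage1pos_stage2neg +
           s1neg * acc$p_tn_given_stage1_negative,
    p_fn = s1pos_s2neg * (1 - acc$p_tn_given_stage1pos_stage2neg) +
           s1neg * (1 - acc$p_tn_given_stage1_negative)
  )
}

#' Outcome-class distribution for any strategy
#'
#' @param strategy One of [strategies()].
#' @param params An `antescreen_params` object.
#' @return List with components `p_tp`, `p_fp`, `p_tn`, `p_fn`.
#' @export
outcome_distribution <- function(strategy, params) {
  strategy <- match.arg(strategy, strategies())
  acc <- params$accuracy[[strategy]]
  if (strategy == "whooley_epds") {
    outcome_distribution_two_stage(acc)
  } else {
    outcome_distribution_single(leaf_mean(acc$p_positive),
                                leaf_mean(acc$p_tp_given_positive),
                                leaf_mean(acc$p_tn_given_negative))
  }
}

#' Expected QALYs and costs conditional on outcome class
#'
#' Walks the treatment pathway shared by all strategies. True positives are
#' treated (facilitated self-help or high-intensity therapy) and respond or
#' not; false positives keep the non-depressed QALY (optionally decremented,
#' sensitivity scenario 4) and consume a fraction of treatment resources
#' before their status is recognised; true negatives stay well; false
#' negatives spontaneously recover, or are identified later and treated like
#' true positives, or remain depressed and untreated. Costs here exclude the
#' screening cost, which is attached per arm.
#'
#' Accepts either an `antescreen_params` object or a plain nested list of
#' numeric leaves (possibly vectors, as in the PSA) with the same shape.
#'
#' @param params Model parameters.
#' @return List with `qaly_tp`, `qaly_fp`, `qaly_tn`, `qaly_fn`, `cost_tp`,
#'   `cost_fp`, `cost_tn`, `cost_fn`, plus the composites `p_respond` and
#'   `treat_cost`.
#' @export
pathway_values <- function(params) {
  m <- if (inherits(params, "antescreen_params")) param_means(params) else params
  tr <- m$treatment
  q <- m$qalys
  co <- m$costs

  p_respond <- tr$p_fsh * tr$p_respond_fsh + (1 - tr$p_fsh) * tr$p_respond_hipt
  treat_cost <- tr$p_fsh * co$c_fsh + (1 - tr$p_fsh) * co$c_hipt

  q_dn <- q$depressed_to_nondepressed
  q_dd <- q$depressed_to_depressed
  q_nn <- q$nondepressed_to_nondepressed

  qaly_tp <- p_respond * q_dn + (1 - p_respond) * q_dd
  qaly_fp <- tr$fp_qaly_multiplier * q_nn
  qaly_tn <- q_nn
  qaly_fn <- tr$p_spontaneous * q_dn +
    (1 - tr$p_spontaneous) *
      (tr$p_later_id * qaly_tp + (1 - tr$p_later_id) * q_dd)

  other_dep <- co$other_care_depressed
  other_nondep <- co$other_care_nondepressed
  cost_tp <- treat_cost + p_respond * other_nondep + (1 - p_respond) * other_dep
  cost_fp <- tr$fp_resource_fraction * treat_cost + other_nondep
  cost_tn <- other_nondep
  cost_fn <- tr$p_spontaneous * other_nondep +
    (1 - tr$p_spontaneous) *
      (tr$p_later_id * cost_tp + (1 - tr$p_later_id) * other_dep)

  list(qaly_tp = qaly_tp, qaly_fp = qaly_fp, qaly_tn = qaly_tn, qaly_fn = qaly_fn,
       cost_tp = cost_tp, cost_fp = cost_fp, cost_tn = cost_tn, cost_fn = cost_fn,
       p_respond = p_respond, treat_cost = treat_cost)
}

#' Expected QALYs and cost per woman for one strategy
#'
#' @param strategy One of [strategies()].
#' @param params An `antescreen_params` object.
#' @return One-row data frame with columns `strategy`, `mean_qaly`,
#'   `mean_cost`.
#' @export
#' @examples
#' evaluate_arm("no_screen", default_parameters())
evaluate_arm <- function(strategy, params) {
  strategy <- match.arg(strategy, strategies())
  dist <- outcome_distribution(strategy, params)
  pv <- pathway_values(params)
  screen_cost <- leaf_mean(params$costs$screen_cost[[strategy]])
  data.frame(
    strategy = strategy,
    mean_qaly = dist$p_tp * pv$qaly_tp + dist$p_fp * pv$qaly_fp +
      dist$p_tn * pv$qaly_tn + dist$p_fn * pv$qaly_fn,
    mean_cost = screen_cost + dist$p_tp * pv$cost_tp + dist$p_fp * pv$cost_fp +
      dist$p_tn * pv$cost_tn + dist$p_fn * pv$cost_fn,
    stringsAsFactors = FALSE
  )
}

#' Evaluate every strategy
#'
#' @param params An `antescreen_params` object.
#' @return Data frame with one row per strategy in the canonical order
#'   (`whooley`, `epds`, `whooley_epds`, `no_screen`) and columns `strategy`,
#'   `mean_qaly`, `mean_cost`.
#' @export
#' @examples
#' evaluate_all(default_parameters())
evaluate_all <- function(params) {
  out <- do.call(rbind, lapply(strategies(), evaluate_arm, params = params))
  rownames(out) <- NULL
  out
}

check_unit_interval <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(NULL)
}
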