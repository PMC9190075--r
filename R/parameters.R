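# Parameter container: a nested list whose leaves are either plain numerics
# (structural constants, never sampled) or small tagged lists carrying the
# point estimate plus what the PSA needs to rebuild the sampling distribution.

#' @keywords internal
prob_param <- function(mean, events = NULL, ci = NULL, sampled = TRUE) {
  stopifnot(is.numeric(mean), length(mean) == 1L, mean >= 0, mean <= 1)
  n_eff <- NULL
  if (!is.null(events)) {
    stopifnot(events > 0, mean > 0)
    n_eff <- events / mean  # total effective observations behind the estimate
  }
  if (!is.null(ci)) stopifnot(length(ci) == 2L, ci[1] <= mean, mean <= ci[2])
  structure(list(mean = mean, n_eff = n_eff, ci = ci,
                 sampled = sampled && !is.null(n_eff)),
            class = "asc_prob")
}

#' @keywords internal
cost_param <- function(mean, se_fraction = 0.30) {
  stopifnot(is.numeric(mean), length(mean) == 1L, mean >= 0, se_fraction > 0)
  structure(list(mean = mean, se_fraction = se_fraction), class = "asc_cost")
}

#' @keywords internal
qaly_param <- function(mean, se_fraction = 0.30) {
  stopifnot(is.numeric(mean), length(mean) == 1L, mean >= 0, mean <= 1)
  structure(list(mean = mean, se_fraction = se_fraction), class = "asc_qaly")
}

is_param_leaf <- function(x) inherits(x, c("asc_prob", "asc_cost", "asc_qaly"))

#' Point estimate of a parameter leaf
#'
#' @param x A parameter leaf or plain numeric.
#' @return The numeric point estimate.
#' @keywords internal
leaf_mean <- function(x) if (is_param_leaf(x)) x$mean else x

#' Default model parameters
#'
#' The complete printed base case: screening-pathway probabilities with the
#' weighted event counts behind them, treatment-pathway probabilities
#' (including the derived response and later-identification probabilities),
#' nine-month QALY trajectories, health-state utilities, and 2015/16 unit
#' costs. Conditional complements (for example the false-positive share of
#' positive screens) are never stored: they are always computed as one minus
#' the first-listed probability, which keeps every branch pair normalised.
#'
#' @return An object of class `antescreen_params`: a validated nested list
#'   with components `accuracy` (per strategy), `treatment`, `costs`,
#'   `utilities`, `qalys` and `horizon_months`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$accuracy$whooley$p_positive$mean
#' p$qalys$nondepressed_to_nondepressed$mean
default_parameters <- function() {
  rr_fsh <- 0.73
  rr_hipt <- 0.48
  ar_no_improvement <- 0.67
  detection_rate_source <- 0.41
  detection_source_months <- 36
  horizon_months <- 9

  params <- list(
    accuracy = list(
      whooley = list(
        p_positive          = prob_param(0.0909, 906,   c(0.085, 0.097)),
        p_tp_given_positive = prob_param(0.4530, 410.4, c(0.420, 0.485)),
        p_tn_given_negative = prob_param(0.9341, 8460,  c(0.929, 0.939))
      ),
      epds = list(
        p_positive          = prob_param(0.1144, 1138,  c(0.108, 0.121)),
        p_tp_given_positive = prob_param(0.5188, 590.6, c(0.490, 0.548)),
        p_tn_given_negative = prob_param(0.9534, 8398,  c(0.949, 0.958))
      ),
      whooley_epds = list(
        p_stage1_positive                      = prob_param(0.0895, 890.2, c(0.084, 0.095)),
        p_stage2_positive_given_stage1_positive = prob_param(0.4114, 366.2, c(0.379, 0.444)),
        p_tp_given_both_positive               = prob_param(0.7500, 8460,  c(0.741, 0.759)),
        p_tn_given_stage1pos_stage2neg         = prob_param(0.7531, 274.6, c(0.708, 0.797)),
        p_tn_given_stage1_negative             = prob_param(0.9341, 394.6, c(0.910, 0.953))
      ),
      no_screen = list(
        p_positive          = prob_param(0.0438, 6,   c(0.016, 0.084)),
        p_tp_given_positive = prob_param(0.6667, 4,   c(0.284, 0.947)),
        p_tn_given_negative = prob_param(0.8855, 116, c(0.826, 0.934))
      )
    ),
    treatment = list(
      p_fsh = prob_param(0.7921, 79.21, c(0.705, 0.864)),
      rr_fsh = rr_fsh,
      rr_hipt = rr_hipt,
      ar_no_improvement = ar_no_improvement,
      p_respond_fsh = prob_param(response_probability(rr_fsh, ar_no_improvement),
                                 51.09, c(0.413, 0.607)),
      p_respond_hipt = prob_param(response_probability(rr_hipt, ar_no_improvement),
                                  67.84, c(0.586, 0.767)),
      p_spontaneous = prob_param(0.33, 33, c(0.242, 0.425)),
      detection_rate_source = detection_rate_source,
      detection_source_months = detection_source_months,
      p_later_id = prob_param(
        later_identification_probability(detection_rate_source,
                                         detection_source_months,
                                         horizon_months),
        10.25, c(0.050, 0.166)),
      fp_resource_fraction = 0.20,
      fp_qaly_multiplier = 1.0
    ),
    costs = list(
      midwife_rate_per_min = 2.65,
      screen_minutes = list(whooley = 1.71, epds = 3.54, no_screen = 3.0),
      screen_cost = list(
        whooley      = cost_param(4.53),
        epds         = cost_param(9.38),
        # derived: weighted two-stage cost (prints as the published 5.37)
        whooley_epds = cost_param(two_stage_screen_cost(4.53, 9.38, 0.0895)),
        no_screen    = cost_param(7.95)
      ),
      c_fsh = cost_param(759),
      c_hipt = cost_param(3114),
      other_care_depressed = cost_param(2005),
      other_care_nondepressed = cost_param(1680)
    ),
    utilities = list(
      ante_depressed    = list(mean = 0.678, se = 0.04),
      ante_nondepressed = list(mean = 0.888, se = 0.01),
      post_depressed    = list(mean = 0.771, se = 0.03),
      post_nondepressed = list(mean = 0.907, se = 0.01)
    ),
    qalys = list(
      depressed_to_nondepressed    = qaly_param(0.6553),
      depressed_to_depressed       = qaly_param(0.5991),
      nondepressed_to_nondepressed = qaly_param(0.7422)
    ),
    horizon_months = horizon_months
  )
  class(params) <- "antescreen_params"
  validate_parameters(params)
  params
}

#' Validate a model parameter set
#'
#' Checks every probability leaf lies in \[0, 1\] (with its CI ordered around
#' the mean and a positive effective count when one is present), every cost is
#' non-negative with a positive dispersion, utilities lie in \[0, 1\] with the
#' depressed state below the non-depressed state in each period, and the QALY
#' trajectories are ordered
#' `depressed_to_depressed <= depressed_to_nondepressed <=
#' nondepressed_to_nondepressed`.
#'
#' @param params An `antescreen_params` object (or plain nested list with the
#'   same shape).
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending parameter.
#' @export
validate_parameters <- function(params) {
  fail <- function(key, msg) {
    stop("invalid parameter '", key, "': ", msg, call. = FALSE)
  }
  walk <- function(x, path) {
    if (is_param_leaf(x)) {
      key <- paste(path, collapse = ".")
      if (inherits(x, "asc_prob")) {
        if (!is.finite(x$mean) || x$mean < 0 || x$mean > 1)
          fail(key, paste0("probability ", x$mean, " outside [0, 1]"))
        if (!is.null(x$ci) && (x$ci[1] > x$mean || x$mean > x$ci[2]))
          fail(key, "confidence interval does not bracket the mean")
        if (!is.null(x$n_eff) && x$n_eff <= 0)
          fail(key, "effective sample size must be > 0")
      } else if (inherits(x, "asc_cost")) {
        if (!is.finite(x$mean) || x$mean < 0) fail(key, "cost must be >= 0")
        if (x$se_fraction <= 0) fail(key, "se fraction must be > 0")
      } else {
        if (!is.finite(x$mean) || x$mean < 0 || x$mean > 1)
          fail(key, paste0("QALY value ", x$mean, " outside [0, 1]"))
      }
    } else if (is.list(x)) {
      for (nm in names(x)) walk(x[[nm]], c(path, nm))
    }
    invisible(NULL)
  }
  walk(unclass(params), character(0))

  u <- params$utilities
  for (nm in names(u)) {
    if (u[[nm]]$mean < 0 || u[[nm]]$mean > 1)
      fail(paste0("utilities.", nm), "utility outside [0, 1]")
  }
  if (u$ante_depressed$mean >= u$ante_nondepressed$mean)
    fail("utilities.ante_depressed", "depressed utility must be below non-depressed")
  if (u$post_depressed$mean >= u$post_nondepressed$mean)
    fail("utilities.post_depressed", "depressed utility must be below non-depressed")

  q <- lapply(params$qalys, leaf_mean)
  if (!(q$depressed_to_depressed <= q$depressed_to_nondepressed &&
        q$depressed_to_nondepressed <= q$nondepressed_to_nondepressed))
    fail("qalys", "trajectories must be ordered dep->dep <= dep->nondep <= nondep->nondep")

  tr <- params$treatment
  if (tr$fp_resource_fraction < 0 || tr$fp_resource_fraction > 1)
    fail("treatment.fp_resource_fraction", "must lie in [0, 1]")
  if (tr$fp_qaly_multiplier < 0 || tr$fp_qaly_multiplier > 1)
    fail("treatment.fp_qaly_multiplier", "must lie in [0, 1]")
  if (params$horizon_months <= 0) fail("horizon_months", "must be > 0")
  invisible(params)
}

#' Point estimates of all parameters as a plain nested list
#'
#' Strips the distribution metadata, leaving numeric leaves only: the form the
#' tree engine consumes.
#'
#' @param params An `antescreen_params` object.
#' @return Nested list of numerics with the same shape as `params`.
#' @export
param_means <- function(params) {
  strip <- function(x) {
    if (is_param_leaf(x)) return(x$mean)
    if (is.list(x) && !is.null(x$mean) && !is.null(x$se) && length(x) == 2L)
      return(x$mean)
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  strip(unclass(params))
}

#' @export
print.antescreen_params <- function(x, ...) {
  m <- param_means(x)
  cat("Antenatal depression screening model parameters\n")
  cat(sprintf("  horizon: %g months\n", m$horizon_months))
  for (s in strategies()) {
    a <- m$accuracy[[s]]
    cat(sprintf("  %-13s %s\n", s,
                paste(sprintf("%s=%.4f", names(a), unlist(a)), collapse = " ")))
  }
  cat(sprintf("  treatment: p_fsh=%.4f respond_fsh=%.4f respond_hipt=%.4f spont=%.2f later_id=%.4f\n",
              m$treatment$p_fsh, m$treatment$p_respond_fsh,
              m$treatment$p_respond_hipt, m$treatment$p_spontaneous,
              m$treatment$p_later_id))
  cat(sprintf("  screen costs: %s\n",
              paste(sprintf("%s=%.2f", names(m$costs$screen_cost),
                            unlist(m$costs$screen_cost)), collapse = " ")))
  cat(sprintf("  QALY trajectories: d->n=%.4f d->d=%.4f n->n=%.4f\n",
              m$qalys$depressed_to_nondepressed, m$qalys$depressed_to_depressed,
              m$qalys$nondepressed_to_nondepressed))
  invisible(x)
}

# ---- configuration files ----------------------------------------------------

# Leaves that are derived from other parameters; recomputed after an overlay
# unless the configuration sets them explicitly.
derived_leaves <- function() {
  c("treatment.p_respond_fsh", "treatment.p_respond_hipt",
    "treatment.p_later_id", "costs.screen_cost.whooley_epds")
}

flatten_keys <- function(x, path = character(0)) {
  if (is_param_leaf(x) || !is.list(x) ||
      (is.list(x) && !is.null(x$mean) && !is.null(x$se))) {
    return(stats::setNames(list(x), paste(path, collapse = ".")))
  }
  out <- list()
  for (nm in names(x)) out <- c(out, flatten_keys(x[[nm]], c(path, nm)))
  out
}

set_leaf_mean <- function(params, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  leaf <- tryCatch(params[[path]], error = function(e) NULL)
  if (is.null(leaf)) stop("unknown configuration key '", key, "'", call. = FALSE)
  if (!is.numeric(value) || length(value) != 1L)
    stop("configuration key '", key, "' must be a single number", call. = FALSE)
  if (is_param_leaf(leaf)) {
    leaf$mean <- value
    leaf$ci <- NULL  # the printed interval no longer applies off the base case
    params[[path]] <- leaf
  } else if (is.list(leaf) && !is.null(leaf$mean)) {
    leaf$mean <- value
    params[[path]] <- leaf
  } else if (is.numeric(leaf)) {
    params[[path]] <- value
  } else {
    stop("configuration key '", key, "' is not a settable parameter", call. = FALSE)
  }
  params
}

rederive_parameters <- function(params, skip = character(0)) {
  tr <- params$treatment
  reset <- function(leaf, mean) {
    if (!isTRUE(all.equal(leaf$mean, mean))) leaf$ci <- NULL
    leaf$mean <- mean
    leaf
  }
  if (!("treatment.p_respond_fsh" %in% skip)) {
    params$treatment$p_respond_fsh <- reset(
      params$treatment$p_respond_fsh,
      response_probability(tr$rr_fsh, tr$ar_no_improvement))
  }
  if (!("treatment.p_respond_hipt" %in% skip)) {
    params$treatment$p_respond_hipt <- reset(
      params$treatment$p_respond_hipt,
      response_probability(tr$rr_hipt, tr$ar_no_improvement))
  }
  if (!("treatment.p_later_id" %in% skip)) {
    params$treatment$p_later_id <- reset(
      params$treatment$p_later_id,
      later_identification_probability(tr$detection_rate_source,
                                       tr$detection_source_months,
                                       params$horizon_months))
  }
  if (!("costs.screen_cost.whooley_epds" %in% skip)) {
    params$costs$screen_cost$whooley_epds$mean <- two_stage_screen_cost(
      params$costs$screen_cost$whooley$mean,
      params$costs$screen_cost$epds$mean,
      params$accuracy$whooley_epds$p_stage1_positive$mean)
  }
  params
}

config_flat_values <- function(config, path = character(0)) {
  out <- list()
  for (nm in names(config)) {
    x <- config[[nm]]
    if (is.list(x)) {
      out <- c(out, config_flat_values(x, c(path, nm)))
    } else {
      out[[paste(c(path, nm), collapse = ".")]] <- x
    }
  }
  out
}

#' Load model parameters from a YAML configuration file
#'
#' The configuration mirrors the parameter tree with one numeric value per
#' key (`treatment: {p_spontaneous: 0}` sets the spontaneous-recovery
#' probability). Values overlay the defaults; any key not present in the
#' default tree is a hard error, as is any value failing validation. Derived
#' parameters (the two response probabilities, the later-identification
#' probability, and the weighted two-stage screening cost) are recomputed from
#' their sources after the overlay unless the file sets them explicitly.
#'
#' @param config_path Path to a YAML file, or `NULL` for pure defaults.
#' @param base Parameter set to overlay onto (default [default_parameters()]).
#' @return A validated `antescreen_params` object.
#' @seealso [dump_default_config()]
#' @export
load_parameters <- function(config_path = NULL, base = default_parameters()) {
  params <- base
  overridden <- character(0)
  if (!is.null(config_path)) {
    if (!file.exists(config_path))
      stop("configuration file not found: ", config_path, call. = FALSE)
    config <- yaml::read_yaml(config_path)
    if (length(config)) {
      vals <- config_flat_values(config)
      known <- names(flatten_keys(unclass(params)))
      for (key in names(vals)) {
        if (!(key %in% known))
          stop("unknown configuration key '", key, "'", call. = FALSE)
        params <- set_leaf_mean(params, key, vals[[key]])
      }
      overridden <- names(vals)
    }
  }
  params <- rederive_parameters(params, skip = intersect(overridden, derived_leaves()))
  class(params) <- "antescreen_params"
  validate_parameters(params)
  params
}

#' Write the full default configuration for editing
#'
#' Produces a YAML file holding every settable parameter at its default value;
#' edit and feed back through [load_parameters()].
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
dump_default_config <- function(path) {
  means <- param_means(default_parameters())
  yaml::write_yaml(means, path)
  invisible(path)
}
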