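# The thirteen one-way sensitivity analyses (1a-7b), each expressed as a
# declarative set of parameter overrides applied to the base case. An
# override value may be a number (re-centres the mean, keeping the
# dispersion rule: effective sample size for betas, 30%-of-mean SE for
# gammas), a list(mean, n_eff) replacing a probability's evidence base, or a
# function of the current parameters (the utility rescalings of 5a/5b).

#' Built-in sensitivity scenarios
#'
#' * 1a -- no-screen detection replaced by GP-detection probabilities
#'   (positive 0.25, true-positive given positive 0.40, true-negative given
#'   negative 0.8667; beta dispersion recovered from the printed intervals),
#'   no-screen cost replaced by a GP contact at GBP 31;
#' * 1b -- as 1a but with the GP contact cost set to GBP 0;
#' * 2a / 2b -- all treated women receive facilitated self-help / all receive
#'   high-intensity psychological therapy;
#' * 3a / 3b -- later identification of false negatives 5% / 20%;
#' * 4 -- 2% quality-of-life decrement for false positives;
#' * 5a / 5b -- depressed-state utilities +15% / -15%, with the two depressed
#'   QALY trajectories rescaled through a 6-months-antenatal +
#'   3-months-postnatal area-under-curve proxy;
#' * 6a / 6b -- false positives consume 10% / 30% of treatment resources;
#' * 7a / 7b -- spontaneous recovery 0% / 50%.
#'
#' @return Named list of scenario objects (id, description, overrides).
#' @export
#' @examples
#' names(builtin_scenarios())
builtin_scenarios <- function() {
  mitchell <- list(
    "accuracy.no_screen.p_positive" =
      list(mean = 0.25, ci = c(0.171, 0.339)),
    "accuracy.no_screen.p_tp_given_positive" =
      list(mean = 0.40, ci = c(0.221, 0.594)),
    "accuracy.no_screen.p_tn_given_negative" =
      list(mean = 0.8667, ci = c(0.782, 0.933))
  )
  scale_depressed_utilities <- function(factor) {
    function(params) {
      u <- params$utilities
      q <- params$qalys
      proxy <- function(ante, post) (6 * ante + 3 * post) / 12
      ratio_dd <- proxy(u$ante_depressed$mean * factor,
                        u$post_depressed$mean * factor) /
        proxy(u$ante_depressed$mean, u$post_depressed$mean)
      # the depressed->non-depressed trajectory mixes depressed (antenatal)
      # and recovered (postnatal) time: only its depressed component moves
      ratio_dn <- proxy(u$ante_depressed$mean * factor,
                        u$post_nondepressed$mean) /
        proxy(u$ante_depressed$mean, u$post_nondepressed$mean)
      list(
        "utilities.ante_depressed" = u$ante_depressed$mean * factor,
        "utilities.post_depressed" = u$post_depressed$mean * factor,
        "qalys.depressed_to_depressed" = q$depressed_to_depressed$mean * ratio_dd,
        "qalys.depressed_to_nondepressed" = q$depressed_to_nondepressed$mean * ratio_dn
      )
    }
  }
  scen <- function(id, description, overrides) {
    structure(list(id = id, description = description, overrides = overrides),
              class = "antescreen_scenario")
  }
  list(
    "1a" = scen("1a", "No-screen detection from GP data; GP contact cost GBP 31",
                c(mitchell, list("costs.screen_cost.no_screen" = 31))),
    "1b" = scen("1b", "As 1a with no-screen contact cost GBP 0",
                c(mitchell, list("costs.screen_cost.no_screen" = 0))),
    "2a" = scen("2a", "All treated women receive facilitated self-help",
                list("treatment.p_fsh" = 1)),
    "2b" = scen("2b", "All treated women receive high-intensity therapy",
                list("treatment.p_fsh" = 0)),
    "3a" = scen("3a", "Later identification of false negatives 5%",
                list("treatment.p_later_id" = 0.05)),
    "3b" = scen("3b", "Later identification of false negatives 20%",
                list("treatment.p_later_id" = 0.20)),
    "4"  = scen("4", "2% quality-of-life reduction for false positives",
                list("treatment.fp_qaly_multiplier" = 0.98)),
    "5a" = scen("5a", "Depressed-state utilities +15%",
                list(transform = scale_depressed_utilities(1.15))),
    "5b" = scen("5b", "Depressed-state utilities -15%",
                list(transform = scale_depressed_utilities(0.85))),
    "6a" = scen("6a", "False positives consume 10% of treatment resources",
                list("treatment.fp_resource_fraction" = 0.10)),
    "6b" = scen("6b", "False positives consume 30% of treatment resources",
                list("treatment.fp_resource_fraction" = 0.30)),
    "7a" = scen("7a", "Spontaneous recovery 0%",
                list("treatment.p_spontaneous" = 0)),
    "7b" = scen("7b", "Spontaneous recovery 50%",
                list("treatment.p_spontaneous" = 0.50))
  )
}

#' @export
print.antescreen_scenario <- function(x, ...) {
  cat(sprintf("Scenario %s: %s\n", x$id, x$description))
  invisible(x)
}

#' Apply a sensitivity scenario to a parameter set
#'
#' Returns a new parameter set; the input is untouched. Overridden
#' probability parameters keep their effective sample size (so their PSA
#' betas re-centre with the same dispersion rule) unless the scenario
#' supplies a new evidence base; overridden costs keep the 30%-of-mean SE
#' rule. Derived parameters not explicitly overridden are recomputed.
#'
#' @param params An `antescreen_params` object.
#' @param scenario A scenario object from [builtin_scenarios()], or a
#'   scenario id string.
#' @return A validated `antescreen_params` object.
#' @export
#' @examples
#' p1a <- apply_scenario(default_parameters(), "1a")
#' p1a$accuracy$no_screen$p_positive$mean
apply_scenario <- function(params, scenario) {
  if (is.character(scenario)) {
    all <- builtin_scenarios()
    if (!(scenario %in% names(all)))
      stop("unknown scenario id '", scenario, "'; valid ids: ",
           paste(names(all), collapse = ", "), call. = FALSE)
    scenario <- all[[scenario]]
  }
  overrides <- scenario$overrides
  if (!is.null(overrides$transform)) {
    computed <- overrides$transform(params)
    overrides <- c(overrides[names(overrides) != "transform"], computed)
  }
  out <- params
  for (key in names(overrides)) {
    value <- overrides[[key]]
    if (is.list(value)) {
      path <- strsplit(key, ".", fixed = TRUE)[[1]]
      leaf <- tryCatch(out[[path]], error = function(e) NULL)
      if (!inherits(leaf, "asc_prob"))
        stop("scenario override '", key, "' targets a non-probability leaf",
             call. = FALSE)
      leaf$mean <- value$mean
      if (!is.null(value$ci)) {
        leaf$ci <- value$ci
        leaf$n_eff <- effective_n_from_ci(value$mean, value$ci[1], value$ci[2])
      } else if (!is.null(value$n_eff)) {
        leaf$n_eff <- value$n_eff
        leaf$ci <- NULL
      }
      out[[path]] <- leaf
    } else {
      out <- set_leaf_mean(out, key, value)
    }
  }
  out <- rederive_parameters(out, skip = intersect(names(overrides),
                                                   derived_leaves()))
  class(out) <- "antescreen_params"
  validate_parameters(out)
  out
}

#' Run the base case and a set of sensitivity scenarios
#'
#' For each scenario (the base case included under id `"base"`): the
#' deterministic arm results, the incremental table against no screening, the
#' dominance frontier, and a CEAC from a PSA. The same seed is used for every
#' scenario's PSA, giving common random numbers across scenarios.
#'
#' @param params Base-case parameters.
#' @param ids Scenario ids to run (default: all thirteen).
#' @param n_iterations PSA iterations per scenario.
#' @param seed Integer seed.
#' @param lambda_grid Willingness-to-pay grid for the CEACs.
#' @return Named list (by scenario id) of lists with elements `scenario`,
#'   `params`, `arms`, `incremental`, `frontier`, `ceac`.
#' @export
run_scenarios <- function(params = default_parameters(),
                          ids = names(builtin_scenarios()),
                          n_iterations = 5000, seed = 1L,
                          lambda_grid = default_lambda_grid()) {
  all <- builtin_scenarios()
  bad <- setdiff(ids, names(all))
  if (length(bad))
    stop("unknown scenario id(s): ", paste(bad, collapse = ", "),
         "; valid ids: ", paste(names(all), collapse = ", "), call. = FALSE)
  run_one <- function(id) {
    sp <- if (id == "base") params else apply_scenario(params, all[[id]])
    arms <- evaluate_all(sp)
    psa <- run_psa(sp, n_iterations = n_iterations, seed = seed,
                   keep_draws = FALSE)
    list(scenario = if (id == "base") {
           structure(list(id = "base", description = "Base case",
                          overrides = list()), class = "antescreen_scenario")
         } else all[[id]],
         params = sp,
         arms = arms,
         incremental = incremental_vs_reference(arms, "no_screen"),
         frontier = dominance_frontier(arms),
         ceac = ceac(psa, lambda_grid))
  }
  out <- lapply(c("base", ids), run_one)
  names(out) <- c("base", ids)
  out
}
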