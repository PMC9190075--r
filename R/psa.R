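# Probabilistic sensitivity analysis. Every uncertain probability is drawn
# from the beta implied by its point estimate and effective event count,
# every cost from a gamma with SE = 30% of the mean, and the QALY
# trajectories from method-of-moments betas on [0, 1]. Draws are shared
# across arms within an iteration (common random numbers), and derived
# quantities -- the weighted two-stage screening cost in particular -- are
# recomputed from the draws. Health-state utilities do not enter the tree
# directly (the printed trajectories do) and are not sampled.

psa_sampling_spec <- function(params) {
  spec <- list()
  add <- function(key, type, mean, aux) {
    spec[[length(spec) + 1L]] <<- list(key = key, type = type, mean = mean, aux = aux)
  }
  for (s in strategies()) {
    for (nm in names(params$accuracy[[s]])) {
      leaf <- params$accuracy[[s]][[nm]]
      add(paste("accuracy", s, nm, sep = "."), "beta_n", leaf$mean, leaf$n_eff)
    }
  }
  for (nm in c("p_fsh", "p_respond_fsh", "p_respond_hipt",
               "p_spontaneous", "p_later_id")) {
    leaf <- params$treatment[[nm]]
    add(paste("treatment", nm, sep = "."), "beta_n", leaf$mean, leaf$n_eff)
  }
  for (nm in c("whooley", "epds", "no_screen")) {
    leaf <- params$costs$screen_cost[[nm]]
    add(paste("costs.screen_cost", nm, sep = "."), "gamma",
        leaf$mean, leaf$se_fraction)
  }
  for (nm in c("c_fsh", "c_hipt", "other_care_depressed",
               "other_care_nondepressed")) {
    leaf <- params$costs[[nm]]
    add(paste("costs", nm, sep = "."), "gamma", leaf$mean, leaf$se_fraction)
  }
  for (nm in names(params$qalys)) {
    leaf <- params$qalys[[nm]]
    add(paste("qalys", nm, sep = "."), "beta_sd", leaf$mean, leaf$se_fraction)
  }
  spec
}

draw_column <- function(item, n) {
  m <- item$mean
  if (item$type == "beta_n") {
    if (is.null(item$aux) || m <= 0 || m >= 1) return(rep(m, n))
    stats::rbeta(n, shape1 = m * item$aux, shape2 = (1 - m) * item$aux)
  } else if (item$type == "gamma") {
    if (m <= 0) return(rep(m, n))
    g <- gamma_from_mean_se(m, item$aux * m)
    stats::rgamma(n, shape = g["shape"], scale = g["scale"])
  } else if (item$type == "beta_sd") {
    if (m <= 0 || m >= 1) return(rep(m, n))
    sh <- tryCatch(beta_from_mean_sd(m, item$aux * m),
                   error = function(e) stop("cannot moment-match a beta for '",
                                            item$key, "': ", conditionMessage(e),
                                            call. = FALSE))
    stats::rbeta(n, shape1 = sh["alpha"], shape2 = sh["beta"])
  } else {
    stop("unknown draw type ", item$type, call. = FALSE)
  }
}

#' Draw a table of sampled parameter values
#'
#' One column per uncertain parameter (dotted key names), one row per
#' Monte-Carlo iteration, sampled in a fixed column order from the current
#' RNG stream.
#'
#' @param params An `antescreen_params` object.
#' @param n Number of iterations.
#' @return Data frame of draws, `n` rows.
#' @export
sample_draw_table <- function(params, n) {
  stopifnot(n >= 1)
  spec <- psa_sampling_spec(params)
  cols <- lapply(spec, draw_column, n = n)
  names(cols) <- vapply(spec, `[[`, "", "key")
  as.data.frame(cols, check.names = FALSE, optional = TRUE)
}

set_means_by_key <- function(means, keys, values) {
  for (i in seq_along(keys)) {
    path <- strsplit(keys[[i]], ".", fixed = TRUE)[[1]]
    means[[path]] <- values[[i]]
  }
  means
}

#' Plain means list with one draw-table row (or all rows) substituted in
#'
#' @keywords internal
means_with_draws <- function(params, draws) {
  m <- param_means(params)
  m <- set_means_by_key(m, names(draws), as.list(draws))
  # derived from the draws, not sampled separately
  m$costs$screen_cost$whooley_epds <- two_stage_screen_cost(
    m$costs$screen_cost$whooley, m$costs$screen_cost$epds,
    m$accuracy$whooley_epds$p_stage1_positive)
  m
}

#' One random draw of the full parameter set
#'
#' Samples every uncertain parameter once from the current RNG stream and
#' returns a parameter object whose point estimates are the draws (structural
#' constants unchanged, complements and the two-stage screening cost
#' recomputed). Use `set.seed()` beforehand for reproducibility.
#'
#' @param params An `antescreen_params` object.
#' @return An `antescreen_params` object holding the draw.
#' @export
#' @examples
#' set.seed(1)
#' draw <- sample_parameters(default_parameters())
#' draw$accuracy$whooley$p_positive$mean
sample_parameters <- function(params) {
  row <- sample_draw_table(params, 1L)
  out <- params
  for (key in names(row)) out <- set_leaf_mean(out, key, row[[key]])
  out$costs$screen_cost$whooley_epds$mean <- two_stage_screen_cost(
    out$costs$screen_cost$whooley$mean, out$costs$screen_cost$epds$mean,
    out$accuracy$whooley_epds$p_stage1_positive$mean)
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws parameter sets and propagates them through the decision tree,
#' producing `n_iterations` simulated (QALY, cost) pairs per arm. The tree
#' algebra is evaluated vectorised over the draw tables; any single row is
#' identical to evaluating [evaluate_arm()] on the corresponding
#' single-draw parameter set.
#'
#' By default each arm's cost-outcome data are simulated from its own
#' independent parameter draws (`common_draws = FALSE`), the structure that
#' reproduces the published model's Monte-Carlo behaviour: with a
#' willingness to pay of zero all four arms are cost-effective with similar
#' probability, and pairwise cost-effectiveness planes scatter roughly
#' equally over the four quadrants. With `common_draws = TRUE` the shared
#' parameters (treatment pathway, QALY trajectories, costs) take one draw
#' per iteration used by every arm; arm differences are then driven almost
#' entirely by the screening-accuracy parameters, which concentrates the
#' scatter and makes the cheapest arm win nearly always at low willingness
#' to pay.
#'
#' @param params An `antescreen_params` object.
#' @param n_iterations Number of Monte-Carlo iterations (default 5000).
#' @param seed Integer seed; the run is bit-reproducible given
#'   (`params`, `n_iterations`, `seed`, `common_draws`).
#' @param keep_draws Keep the parameter draw tables in the result (default
#'   TRUE).
#' @param common_draws Share one draw of the non-accuracy parameters across
#'   arms within an iteration (default FALSE: fully independent arms).
#' @return An object of class `antescreen_psa`: list with `n_iterations`,
#'   `seed`, `arms`, matrices `qaly` and `cost` (iterations x arms), and
#'   optionally `param_draws` (a draw table per arm, or a single table when
#'   `common_draws = TRUE`).
#' @export
#' @examples
#' psa <- run_psa(default_parameters(), n_iterations = 200, seed = 1)
#' colMeans(psa$qaly)
run_psa <- function(params, n_iterations = 5000, seed = 1L, keep_draws = TRUE,
                    common_draws = FALSE) {
  stopifnot(n_iterations >= 1)
  set.seed(as.integer(seed))
  arms <- strategies()
  qaly <- cost <- matrix(NA_real_, nrow = n_iterations, ncol = length(arms),
                         dimnames = list(NULL, arms))
  if (common_draws) {
    draws <- sample_draw_table(params, n_iterations)
    m <- means_with_draws(params, draws)
    for (s in arms) {
      res <- evaluate_arm(s, m)
      qaly[, s] <- res$mean_qaly
      cost[, s] <- res$mean_cost
    }
  } else {
    draws <- lapply(stats::setNames(arms, arms), function(s) {
      d <- sample_draw_table(params, n_iterations)
      res <- evaluate_arm(s, means_with_draws(params, d))
      qaly[, s] <<- res$mean_qaly
      cost[, s] <<- res$mean_cost
      d
    })
  }
  structure(list(n_iterations = n_iterations, seed = as.integer(seed),
                 arms = arms, common_draws = common_draws,
                 qaly = qaly, cost = cost,
                 param_draws = if (keep_draws) draws),
            class = "antescreen_psa")
}

#' @export
print.antescreen_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations, seed %d\n", x$n_iterations, x$seed))
  cat("mean QALYs: ", paste(sprintf("%s=%.4f", x$arms, colMeans(x$qaly)),
                            collapse = " "), "\n", sep = "")
  cat("mean costs: ", paste(sprintf("%s=%.0f", x$arms, colMeans(x$cost)),
                            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Default willingness-to-pay grid
#'
#' GBP 0 to 50,000 per QALY in steps of 1,000: covers the NICE
#' GBP 20,000-30,000 band with room either side.
#'
#' @return Numeric vector of lambda values.
#' @export
default_lambda_grid <- function() seq(0, 50000, by = 1000)

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability that each arm attains
#' the maximal net monetary benefit across the PSA iterations; exact ties
#' split equally among the tied arms, so the probabilities sum to one by
#' construction.
#'
#' @param psa An `antescreen_psa` object.
#' @param lambda_grid Non-empty vector of willingness-to-pay values (>= 0).
#' @return Data frame: `lambda` plus one probability column per arm.
#' @export
#' @examples
#' psa <- run_psa(default_parameters(), n_iterations = 200, seed = 1)
#' head(ceac(psa, c(0, 20000, 30000)))
ceac <- function(psa, lambda_grid = default_lambda_grid()) {
  stopifnot(inherits(psa, "antescreen_psa"), length(lambda_grid) >= 1)
  if (any(lambda_grid < 0)) stop("lambda values must be >= 0", call. = FALSE)
  out <- matrix(NA_real_, nrow = length(lambda_grid), ncol = length(psa$arms),
                dimnames = list(NULL, psa$arms))
  for (i in seq_along(lambda_grid)) {
    nmb <- net_monetary_benefit(psa$qaly, psa$cost, lambda_grid[i])
    best <- nmb == row_maxs(nmb)
    weights <- best / rowSums(best)
    out[i, ] <- colMeans(weights)
  }
  data.frame(lambda = lambda_grid, out, check.names = FALSE)
}

row_maxs <- function(m) do.call(pmax, as.data.frame(m))

#' Incremental cost-effectiveness plane scatter
#'
#' Per-iteration incremental (QALY, cost) pairs of each non-reference arm
#' against the same iteration's reference arm values.
#'
#' @param psa An `antescreen_psa` object.
#' @param reference Strategy id of the reference arm.
#' @return Data frame with columns `iteration`, `strategy`, `delta_qaly`,
#'   `delta_cost`.
#' @export
ce_plane <- function(psa, reference = "no_screen") {
  stopifnot(inherits(psa, "antescreen_psa"))
  if (!(reference %in% psa$arms))
    stop("reference strategy '", reference, "' is not among the arms", call. = FALSE)
  others <- setdiff(psa$arms, reference)
  do.call(rbind, lapply(others, function(s) {
    data.frame(iteration = seq_len(psa$n_iterations), strategy = s,
               delta_qaly = psa$qaly[, s] - psa$qaly[, reference],
               delta_cost = psa$cost[, s] - psa$cost[, reference],
               stringsAsFactors = FALSE)
  }))
}

#' CEAC convergence check over cumulative iteration blocks
#'
#' Recomputes the acceptability probabilities at `block_count` cumulative
#' iteration counts and reports the largest absolute change in any arm's
#' probability between the final two blocks -- small drift indicates the
#' Monte-Carlo sample size is adequate at that willingness to pay.
#'
#' @param psa An `antescreen_psa` object.
#' @param lambda Willingness to pay per QALY.
#' @param block_count Number of cumulative blocks (>= 2).
#' @return List with `drift` (max absolute change between the last two
#'   blocks) and `trace` (blocks x arms probability matrix).
#' @export
convergence_check <- function(psa, lambda = 20000, block_count = 10) {
  stopifnot(inherits(psa, "antescreen_psa"), block_count >= 2)
  ns <- unique(round(seq_len(block_count) * psa$n_iterations / block_count))
  ns <- ns[ns >= 1]
  trace <- t(vapply(ns, function(k) {
    sub <- structure(list(n_iterations = k, seed = psa$seed, arms = psa$arms,
                          qaly = psa$qaly[seq_len(k), , drop = FALSE],
                          cost = psa$cost[seq_len(k), , drop = FALSE]),
                     class = "antescreen_psa")
    unlist(ceac(sub, lambda)[1, psa$arms])
  }, numeric(length(psa$arms))))
  rownames(trace) <- ns
  last <- nrow(trace)
  list(drift = max(abs(trace[last, ] - trace[last - 1, ])), trace = trace)
}
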