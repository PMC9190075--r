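test_that("PSA runs are bit-reproducible under a seed and differ across seeds", {
  a <- run_psa(base_params, n_iterations = 200, seed = 11)
  b <- run_psa(base_params, n_iterations = 200, seed = 11)
  expect_identical(a$qaly, b$qaly)
  expect_identical(a$cost, b$cost)
  expect_identical(a$param_draws, b$param_draws)
  c <- run_psa(base_params, n_iterations = 200, seed = 12)
  expect_false(identical(a$qaly, c$qaly))
  expect_equal(dim(c$qaly), dim(a$qaly))
  one <- run_psa(base_params, n_iterations = 1, seed = 1)
  expect_equal(nrow(one$qaly), 1)
})

test_that("sampled parameters match their target means and respect complements", {
  set.seed(42)
  draws <- sample_draw_table(base_params, 1e5)
  x <- draws[["accuracy.whooley.p_positive"]]
  expect_lt(abs(mean(x) - 0.0909), 3 * sd(x) / sqrt(length(x)))
  y <- draws[["costs.c_fsh"]]
  expect_lt(abs(mean(y) - 759), 3 * sd(y) / sqrt(length(y)))
  expect_equal(sd(y) / mean(y), 0.30, tolerance = 0.02)
  z <- draws[["qalys.nondepressed_to_nondepressed"]]
  expect_lt(abs(mean(z) - 0.7422), 3 * sd(z) / sqrt(length(z)))
  expect_true(all(z >= 0 & z <= 1))

  set.seed(43)
  draw <- sample_parameters(base_params)
  expect_s3_class(draw, "antescreen_params")
  # the two-stage screening cost is recomputed from the drawn components
  expect_equal(draw$costs$screen_cost$whooley_epds$mean,
               two_stage_screen_cost(draw$costs$screen_cost$whooley$mean,
                                     draw$costs$screen_cost$epds$mean,
                                     draw$accuracy$whooley_epds$p_stage1_positive$mean))
  set.seed(43)
  draw2 <- sample_parameters(base_params)
  expect_identical(param_means(draw), param_means(draw2))
})

test_that("forcing all distribution variances to zero recovers the base case", {
  p <- base_params
  walk_tight <- function(x) {
    if (inherits(x, "asc_prob")) {
      if (!is.null(x$n_eff)) x$n_eff <- 1e12
    } else if (inherits(x, c("asc_cost", "asc_qaly"))) {
      x$se_fraction <- 1e-6
    } else if (is.list(x) && is.null(x$mean)) {
      for (nm in names(x)) x[[nm]] <- walk_tight(x[[nm]])
    }
    x
  }
  tight <- walk_tight(p)
  class(tight) <- "antescreen_params"
  psa <- run_psa(tight, n_iterations = 5, seed = 3)
  base <- evaluate_all(base_params)
  for (s in strategies()) {
    expect_equal(unname(psa$qaly[, s]), rep(base$mean_qaly[base$strategy == s], 5),
                 tolerance = 1e-3)
    expect_equal(unname(psa$cost[, s]), rep(base$mean_cost[base$strategy == s], 5),
                 tolerance = 1e-3)
  }
})

test_that("a PSA row equals the tree evaluated on that row's parameter draw", {
  psa <- run_psa(base_params, n_iterations = 8, seed = 21)
  for (s in c("whooley", "whooley_epds", "no_screen")) {
    d <- psa$param_draws[[s]]
    for (i in c(1, 5, 8)) {
      p_i <- base_params
      for (key in names(d)) p_i <- antescreen:::set_leaf_mean(p_i, key, d[i, key])
      p_i$costs$screen_cost$whooley_epds$mean <- two_stage_screen_cost(
        p_i$costs$screen_cost$whooley$mean, p_i$costs$screen_cost$epds$mean,
        p_i$accuracy$whooley_epds$p_stage1_positive$mean)
      r <- evaluate_arm(s, p_i)
      expect_equal(unname(psa$qaly[i, s]), r$mean_qaly, tolerance = 1e-12)
      expect_equal(unname(psa$cost[i, s]), r$mean_cost, tolerance = 1e-12)
    }
  }
  # common-draws variant shares one draw table across arms
  psa_c <- run_psa(base_params, n_iterations = 8, seed = 21, common_draws = TRUE)
  expect_s3_class(psa_c$param_draws, "data.frame")
})

test_that("PSA arm means are mean-preserving around the base case", {
  psa <- run_psa(base_params, n_iterations = 5000, seed = 1, keep_draws = FALSE)
  base <- evaluate_all(base_params)
  for (s in strategies()) {
    se_q <- sd(psa$qaly[, s]) / sqrt(psa$n_iterations)
    se_c <- sd(psa$cost[, s]) / sqrt(psa$n_iterations)
    expect_lt(abs(mean(psa$qaly[, s]) - base$mean_qaly[base$strategy == s]),
              3 * se_q)
    expect_lt(abs(mean(psa$cost[, s]) - base$mean_cost[base$strategy == s]),
              3 * se_c)
  }
})

test_that("CEAC probabilities are a tie-splitting partition of the iterations", {
  psa <- run_psa(base_params, n_iterations = 500, seed = 5, keep_draws = FALSE)
  cc <- ceac(psa)
  expect_equal(nrow(cc), 51)
  probs <- as.matrix(cc[, strategies()])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(cc)), tolerance = 1e-12)
  expect_error(ceac(psa, numeric(0)))
  expect_error(ceac(psa, -5), ">= 0")

  # hand-built draws: arm a dominates every iteration; b and c exactly tied
  tied <- structure(list(
    n_iterations = 4, seed = 0, arms = c("a", "b", "c"),
    qaly = cbind(a = rep(0.9, 4), b = rep(0.5, 4), c = rep(0.5, 4)),
    cost = cbind(a = rep(100, 4), b = rep(200, 4), c = rep(200, 4))),
    class = "antescreen_psa")
  cc <- ceac(tied, c(0, 20000))
  expect_equal(cc$a, c(1, 1))
  expect_equal(cc$b, c(0, 0))

  no_a <- tied
  no_a$qaly <- no_a$qaly[, c("b", "c")]
  no_a$cost <- no_a$cost[, c("b", "c")]
  no_a$arms <- c("b", "c")
  cc <- ceac(no_a, 20000)
  expect_equal(unlist(cc[1, c("b", "c")]), c(b = 0.5, c = 0.5))
})

test_that("at zero willingness to pay the CEAC counts the cheapest arm", {
  psa <- run_psa(base_params, n_iterations = 400, seed = 9, keep_draws = FALSE)
  cc0 <- ceac(psa, 0)
  cheapest <- table(factor(psa$arms[apply(psa$cost, 1, which.min)],
                           levels = psa$arms)) / psa$n_iterations
  expect_equal(unname(unlist(cc0[1, psa$arms])), unname(c(cheapest)),
               tolerance = 1e-12)
})

test_that("the no-screen acceptability falls as willingness to pay rises", {
  psa <- run_psa(base_params, n_iterations = 5000, seed = 1, keep_draws = FALSE)
  cc <- ceac(psa)
  ns <- cc$no_screen
  # monotone within Monte-Carlo noise: no step up by more than noise, and a
  # clear overall decline
  expect_true(all(diff(ns) < 0.02))
  expect_lt(ns[length(ns)], ns[1])
})

test_that("the CE plane is centred per iteration on the reference arm", {
  psa <- run_psa(base_params, n_iterations = 300, seed = 6, keep_draws = FALSE)
  pl <- ce_plane(psa, "whooley")
  expect_equal(nrow(pl), 3 * psa$n_iterations)
  expect_equal(pl$delta_qaly[pl$strategy == "epds"],
               unname(psa$qaly[, "epds"] - psa$qaly[, "whooley"]))
  expect_error(ce_plane(psa, "nope"), "not among the arms")
})

test_that("the EPDS-vs-Whooley scatter spreads over all four quadrants", {
  psa <- run_psa(base_params, n_iterations = 5000, seed = 1, keep_draws = FALSE)
  pl <- ce_plane(psa, "whooley")
  ep <- pl[pl$strategy == "epds", ]
  shares <- c(mean(ep$delta_qaly > 0 & ep$delta_cost > 0),
              mean(ep$delta_qaly > 0 & ep$delta_cost < 0),
              mean(ep$delta_qaly < 0 & ep$delta_cost > 0),
              mean(ep$delta_qaly < 0 & ep$delta_cost < 0))
  expect_true(all(shares > 0.15 & shares < 0.35))
})

test_that("CEAC drift between the last cumulative blocks is small at 5000 iterations", {
  psa <- run_psa(base_params, n_iterations = 5000, seed = 1, keep_draws = FALSE)
  cv <- convergence_check(psa, lambda = 20000, block_count = 10)
  expect_lt(cv$drift, 0.03)
  expect_equal(nrow(cv$trace), 10)
  cv2 <- convergence_check(psa, lambda = 20000, block_count = 2)
  expect_equal(nrow(cv2$trace), 2)

  degenerate <- structure(list(
    n_iterations = 100, seed = 0, arms = c("a", "b"),
    qaly = cbind(a = rep(0.9, 100), b = rep(0.1, 100)),
    cost = cbind(a = rep(0, 100), b = rep(1000, 100))),
    class = "antescreen_psa")
  expect_equal(convergence_check(degenerate, 20000, 5)$drift, 0)
})
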