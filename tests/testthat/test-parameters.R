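test_that("treatment response probability follows the relative-risk rule", {
  expect_equal(response_probability(0.73, 0.67), 0.5109)
  expect_equal(response_probability(0.48, 0.67), 0.6784)
  expect_equal(response_probability(1.0, 0.67), 0.33)
  expect_error(response_probability(2, 0.67), "exceeds 1")
  expect_error(response_probability(-0.1, 0.5), ">= 0")
})

test_that("later identification rescales linearly with the horizon", {
  expect_equal(later_identification_probability(0.41, 36, 9), 0.1025)
  expect_equal(later_identification_probability(0.41, 36, 36), 0.41)
  expect_equal(later_identification_probability(0, 36, 9), 0)
  expect_error(later_identification_probability(0.9, 9, 36), "exceeds 1")
  expect_error(later_identification_probability(0.5, 0, 9), "> 0")
})

test_that("two-stage screening cost is the stage-1 cost plus weighted stage-2 cost", {
  expect_equal(two_stage_screen_cost(4.53, 9.38, 0.0895), 5.37, tolerance = 0.01 / 5.37)
  expect_equal(two_stage_screen_cost(4.53, 9.38, 0), 4.53)
  expect_equal(two_stage_screen_cost(4.53, 9.38, 1), 13.91)
  expect_error(two_stage_screen_cost(-1, 9.38, 0.1), ">= 0")
  expect_error(two_stage_screen_cost(4.53, 9.38, 1.3), "\\[0, 1\\]")
})

test_that("beta construction from event counts reproduces the mean", {
  expect_equal(beta_from_probability(0.5, 10), c(alpha = 10, beta = 10))
  b <- beta_from_probability(0.0909, 906)
  expect_equal(unname(b["alpha"]), 906)
  expect_equal(unname(b["beta"]), 9061, tolerance = 1e-4)
  for (m in c(0.01, 0.33, 0.77, 0.99)) {
    b <- beta_from_probability(m, 50)
    expect_equal(unname(b["alpha"] / sum(b)), m, tolerance = 1e-9)
  }
  expect_error(beta_from_probability(0, 10), "degenerate")
  expect_error(beta_from_probability(1, 10), "degenerate")
  expect_error(beta_from_probability(0.5, 0), "> 0")
})

test_that("gamma construction matches mean and SE by method of moments", {
  g <- gamma_from_mean_se(759, 227.7)
  expect_equal(unname(g["shape"]), (759 / 227.7)^2, tolerance = 1e-12)
  expect_equal(unname(g["scale"]), 227.7^2 / 759, tolerance = 1e-12)
  # shape depends only on the coefficient of variation
  for (m in c(4.53, 100, 3114)) {
    g <- gamma_from_mean_se(m, 0.3 * m)
    expect_equal(unname(g["shape"]), 1 / 0.09, tolerance = 1e-12)
    expect_equal(unname(prod(g)), m, tolerance = 1e-9)
  }
  expect_equal(gamma_from_mean_se(100, 100), c(shape = 1, scale = 100))
  expect_error(gamma_from_mean_se(0, 10), "> 0")
})

test_that("sampled distributions reproduce their target moments", {
  set.seed(401)
  n <- 1e5
  b <- beta_from_probability(0.0909, 906)
  x <- rbeta(n, b["alpha"], b["beta"])
  expect_lt(abs(mean(x) - 0.0909), 3 * sd(x) / sqrt(n))

  g <- gamma_from_mean_se(759, 227.7)
  y <- rgamma(n, shape = g["shape"], scale = g["scale"])
  expect_lt(abs(mean(y) - 759), 3 * sd(y) / sqrt(n))
  expect_equal(sd(y), 227.7, tolerance = 0.02)

  bs <- beta_from_mean_sd(0.7422, 0.3 * 0.7422)
  z <- rbeta(n, bs["alpha"], bs["beta"])
  expect_lt(abs(mean(z) - 0.7422), 3 * sd(z) / sqrt(n))
})

test_that("effective sample size recovered from a printed CI matches binomial algebra", {
  # mean 0.25 with CI 0.171-0.339 is a ~100-observation binomial
  n_eff <- effective_n_from_ci(0.25, 0.171, 0.339)
  expect_equal(n_eff, 0.25 * 0.75 / ((0.339 - 0.171) / (2 * qnorm(0.975)))^2)
  expect_gt(n_eff, 90)
  expect_lt(n_eff, 115)
})

test_that("default parameters carry the printed base case", {
  p <- base_params
  expect_equal(p$accuracy$whooley$p_positive$mean, 0.0909)
  expect_equal(p$accuracy$epds$p_tp_given_positive$mean, 0.5188)
  expect_equal(p$accuracy$whooley_epds$p_tp_given_both_positive$mean, 0.75)
  expect_equal(p$accuracy$no_screen$p_tn_given_negative$mean, 0.8855)
  expect_equal(p$qalys$nondepressed_to_nondepressed$mean, 0.7422)
  expect_equal(p$qalys$depressed_to_depressed$mean, 0.5991)
  expect_equal(p$costs$c_hipt$mean, 3114)
  expect_equal(p$costs$other_care_nondepressed$mean, 1680)
  expect_equal(p$treatment$p_fsh$mean, 0.7921)
})

test_that("derived parameters round-trip to their printed values", {
  p <- base_params
  expect_equal(p$treatment$p_respond_fsh$mean, 0.5109, tolerance = 1e-4)
  expect_equal(p$treatment$p_respond_hipt$mean, 0.6784, tolerance = 1e-4)
  expect_equal(p$treatment$p_later_id$mean, 0.1025, tolerance = 1e-4)
  # screening costs from minutes at the midwife rate
  rate <- p$costs$midwife_rate_per_min
  for (s in c("whooley", "epds", "no_screen")) {
    expect_equal(p$costs$screen_cost[[s]]$mean,
                 p$costs$screen_minutes[[s]] * rate, tolerance = 0.011)
  }
  expect_equal(p$costs$screen_cost$whooley_epds$mean,
               two_stage_screen_cost(4.53, 9.38, 0.0895), tolerance = 0.01)
})

test_that("other-care costs share a single implied inflation factor", {
  # both 9-month costs derive from the same 18-month source study and
  # inflation index, so their source ratios must agree
  p <- param_means(base_params)
  r_dep <- p$costs$other_care_depressed / (2419 / 2)
  r_nondep <- p$costs$other_care_nondepressed / (2027 / 2)
  expect_lt(abs(r_dep - r_nondep), 0.001)
})

test_that("validation rejects out-of-range and disordered parameters", {
  p <- base_params
  p$accuracy$whooley$p_positive$mean <- 1.3
  expect_error(validate_parameters(p), "accuracy.whooley.p_positive")
  p <- base_params
  p$qalys$depressed_to_depressed$mean <- 0.99
  expect_error(validate_parameters(p), "ordered")
  p <- base_params
  p$utilities$ante_depressed$mean <- 0.95
  expect_error(validate_parameters(p), "depressed utility")
  p <- base_params
  p$treatment$fp_resource_fraction <- -0.1
  expect_error(validate_parameters(p), "fp_resource_fraction")
})

test_that("configuration files overlay the defaults", {
  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_equal(param_means(load_parameters(empty)), param_means(base_params))

  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines("treatment:\n  p_spontaneous: 0", cfg)
  loaded <- load_parameters(cfg)
  expect_equal(param_means(loaded),
               param_means(apply_scenario(base_params, "7a")))

  bad_key <- withr::local_tempfile(fileext = ".yaml")
  writeLines("treatment:\n  p_sponaneous: 0", bad_key)
  expect_error(load_parameters(bad_key), "unknown configuration key")

  bad_val <- withr::local_tempfile(fileext = ".yaml")
  writeLines("accuracy:\n  whooley:\n    p_positive: 1.3", bad_val)
  expect_error(load_parameters(bad_val), "p_positive")
})

test_that("derived parameters recompute from overridden sources unless set directly", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  writeLines("treatment:\n  rr_fsh: 1.0", cfg)
  loaded <- load_parameters(cfg)
  expect_equal(loaded$treatment$p_respond_fsh$mean, 1 - 1.0 * 0.67)
  # explicit override wins over re-derivation
  cfg2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("treatment:\n  p_respond_fsh: 0.6", cfg2)
  expect_equal(load_parameters(cfg2)$treatment$p_respond_fsh$mean, 0.6)
})

test_that("the default configuration dump reloads to the defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  dump_default_config(path)
  expect_equal(param_means(load_parameters(path)), param_means(base_params))
})
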