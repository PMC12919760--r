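test_that("moment matching reproduces the stated mean and SE", {
  set.seed(31)
  n <- 1e5
  g <- param_distribution("u", "gamma", mean = 0.77, se = 0.077)
  x <- draw_distribution(g, n)
  expect_lt(abs(mean(x) - 0.77), 3 * 0.077 / sqrt(n))
  expect_lt(abs(sd(x) - 0.077), 0.005)
  ln <- param_distribution("c", "lognormal", mean = 120, se = 24)
  y <- draw_distribution(ln, n)
  expect_lt(abs(mean(y) - 120), 3 * 24 / sqrt(n))
  expect_true(all(y > 0))
  expect_error(param_distribution("bad", "gamma", mean = -1, se = 0.1),
               "positive")
  expect_error(param_distribution("bad", "gamma", mean = 1, se = -0.1),
               "non-negative")
})

test_that("parameter sampling is degenerate at zero SE and seed-reproducible", {
  spec <- list(param_distribution("utilities.Remission", "gamma", 0.78, 0),
               param_distribution("survival.log_hr", "normal", log(0.54), 0))
  d <- sample_parameters(spec, seed = 4)
  expect_identical(d[["utilities.Remission"]], 0.78)
  expect_identical(d[["survival.log_hr"]], log(0.54))
  spec2 <- list(param_distribution("a", "gamma", 2, 0.5),
                param_distribution("b", "lognormal", 10, 3))
  expect_identical(sample_parameters(spec2, seed = 99),
                   sample_parameters(spec2, seed = 99))
})

test_that("parameter paths update the model inputs", {
  b <- make_base_case_bundle()
  costs <- calibrate_cost_inputs(b)
  upd <- set_model_parameter(b, costs, "utilities.Remission", 0.5)
  expect_equal(upd$bundle$utilities[["Remission"]], 0.5)
  # utilities are capped at 1
  upd <- set_model_parameter(b, costs, "utilities.Remission", 1.3)
  expect_equal(upd$bundle$utilities[["Remission"]], 1)
  # the treatment effect is set on the log scale and exponentiated
  upd <- set_model_parameter(b, costs, "survival.log_hr", log(0.7))
  expect_equal(upd$bundle$survival$hr, 0.7)
  upd <- set_model_parameter(b, costs, "costs.TDM1.monthly.supportive_first_line", 42)
  expect_equal(upd$costs$TDM1$monthly[["supportive_first_line"]], 42)
  upd <- set_model_parameter(b, costs, "settings.weight", 80)
  expect_equal(upd$bundle$settings$weight, 80)
  expect_error(set_model_parameter(b, costs, "nope.x", 1), "unknown")
})

test_that("the acceptability curve matches brute-force enumeration", {
  toy <- structure(list(cloud = data.frame(
    draw = 1:2, delta_cost = c(-10, 10), delta_qalys = c(1, 1),
    dominant = c(TRUE, FALSE))), class = "psa_result")
  cc <- ceac(toy, c(0, 10, 20))
  expect_equal(cc$prob_cost_effective, c(0.5, 0.5, 1))
  # lambda = 0 is the fraction of cost-saving draws by definition
  expect_equal(cc$prob_cost_effective[1], mean(toy$cloud$delta_cost < 0))
  # all-dominant cloud: probability one everywhere
  alldom <- structure(list(cloud = data.frame(
    draw = 1:3, delta_cost = c(-1, -2, -3), delta_qalys = c(1, 2, 3),
    dominant = TRUE)), class = "psa_result")
  expect_equal(ceac(alldom, c(0, 5000, 1e5))$prob_cost_effective, rep(1, 3))
  # monotone non-decreasing in lambda whenever every draw gains QALYs
  set.seed(17)
  for (rep in 1:5) {
    cl <- structure(list(cloud = data.frame(
      draw = 1:200, delta_cost = rnorm(200, 0, 5000),
      delta_qalys = runif(200, 0.01, 2), dominant = NA)),
      class = "psa_result")
    pr <- ceac(cl, seq(0, 2e4, by = 1000))$prob_cost_effective
    expect_true(all(diff(pr) >= 0))
  }
  expect_error(ceac(toy, numeric(0)), "empty")
  expect_error(ceac(toy, -5), "non-negative")
})

test_that("degenerate PSA reproduces the base case and seeds are bit-exact", {
  b <- make_base_case_bundle()
  costs <- calibrate_cost_inputs(b)
  base <- run_base_case(b, costs = costs)
  degen <- lapply(default_psa_spec(b, costs), function(d) {
    d$se <- 0
    d
  })
  psa <- run_psa(b, spec = degen, n = 3, seed = 1, costs = costs)
  expect_equal(psa$cloud$delta_cost,
               rep(base$comparison$delta_cost, 3), tolerance = 1e-9)
  expect_equal(psa$cloud$delta_qalys,
               rep(base$comparison$delta_qalys, 3), tolerance = 1e-9)
  expect_true(psa$dominance_fraction %in% c(0, 1))
  expect_equal(psa$dominance_fraction == 1,
               base$comparison$label == "Dominant")
  # same seed, same spec: bit-identical cloud
  spec <- default_psa_spec(b, costs)
  p1 <- run_psa(b, spec = spec, n = 6, seed = 42, costs = costs)
  p2 <- run_psa(b, spec = spec, n = 6, seed = 42, costs = costs)
  expect_identical(p1$cloud, p2$cloud)
  expect_identical(p1$dominance_fraction, p2$dominance_fraction)
  expect_equal(p1$n_failed, 0)
})

test_that("a single-draw PSA equals sampling plus one model run", {
  b <- make_base_case_bundle()
  costs <- calibrate_cost_inputs(b)
  spec <- default_psa_spec(b, costs)
  psa <- run_psa(b, spec = spec, n = 1, seed = 11, costs = costs)
  set.seed(11)
  draws <- sample_parameters(spec)
  bb <- b; cc <- costs
  for (p in names(draws)) {
    upd <- set_model_parameter(bb, cc, p, draws[[p]])
    bb <- upd$bundle; cc <- upd$costs
  }
  res <- run_base_case(bb, costs = cc)
  expect_equal(psa$cloud$delta_cost, res$comparison$delta_cost,
               tolerance = 1e-12)
  expect_equal(psa$cloud$delta_qalys, res$comparison$delta_qalys,
               tolerance = 1e-12)
})

test_that("tornado entries behave monotonically and zero-width ranges give zero swing", {
  b <- make_base_case_bundle()
  costs <- calibrate_cost_inputs(b)
  price <- costs$TDM1$price_per_mg
  ranges <- list(
    dsa_range("costs.TDM1.price_per_mg", 0.8 * price, 1.2 * price, price),
    dsa_range("utilities.Remission", 0.78, 0.78, 0.78)  # zero width
  )
  tab <- one_way_dsa(b, ranges = ranges, costs = costs)
  zw <- tab[tab$parameter == "utilities.Remission", ]
  expect_equal(zw$swing, 0)
  expect_equal(tab$parameter[nrow(tab)], "utilities.Remission")
  # NMB is non-increasing in the new drug's acquisition price
  pr <- tab[tab$parameter == "costs.TDM1.price_per_mg", ]
  expect_gt(pr$nmb_low, attr(tab, "nmb_base"))
  expect_lt(pr$nmb_high, attr(tab, "nmb_base"))
  nmb_at <- function(v) {
    upd <- set_model_parameter(b, costs, "costs.TDM1.price_per_mg", v)
    run_base_case(upd$bundle, costs = upd$costs)$comparison$nmb
  }
  nmbs <- vapply(price * c(0.5, 1, 1.5, 2), nmb_at, numeric(1))
  expect_true(all(diff(nmbs) < 0))
  expect_error(dsa_range("x", 2, 1), "exceed")
  expect_error(dsa_range("x", 1, 2, base = 3), "outside")
})
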