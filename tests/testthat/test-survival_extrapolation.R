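test_that("mixture-cure survival has the closed form and its bounds", {
  fit <- list(cure_fraction = 0.3, family = "exponential",
              params = c(rate = 0.1))
  expect_equal(mixture_cure_survival(0, fit), 1)
  expect_equal(mixture_cure_survival(12, fit), 0.3 + 0.7 * exp(-1.2))
  full <- list(cure_fraction = 1, family = "weibull",
               params = c(shape = 1.3, scale = 20))
  expect_equal(mixture_cure_survival(c(0, 5, 500), full), rep(1, 3))
  expect_error(mixture_cure_survival(-1, fit), "negative")
})

test_that("mixture-cure curves are non-increasing and plateau at the cure fraction", {
  set.seed(11)
  t <- seq(0, 600, by = 0.5)
  for (fam in families) {
    for (rep in 1:5) {
      fit <- list(cure_fraction = runif(1), family = fam,
                  params = random_latent_params(fam))
      s <- mixture_cure_survival(t, fit)
      expect_true(all(diff(s) <= 1e-12))
      expect_true(all(s <= 1 & s >= fit$cure_fraction - 1e-12))
      expect_equal(mixture_cure_survival(1e9, fit), fit$cure_fraction,
                   tolerance = 1e-4)
    }
  }
})

test_that("negative log-likelihood matches hand-computed contributions", {
  expect_identical(
    negative_log_likelihood(numeric(0), integer(0), 0.5, "exponential",
                            c(rate = 1)), 0)
  # one censored record under full cure: -log(1) = 0
  expect_equal(
    negative_log_likelihood(10, 0, 1, "exponential", c(rate = 0.2)), 0)
  # one event at t = 5, pi = 0.2, exponential rate 0.1
  expect_equal(
    negative_log_likelihood(5, 1, 0.2, "exponential", c(rate = 0.1)),
    -log(0.8 * 0.1 * exp(-0.5)))
  expect_error(
    negative_log_likelihood(c(5, -1), c(1, 0), 0.2, "exponential",
                            c(rate = 0.1)), "strictly positive")
  # an event under full cure has zero density: error names the record
  expect_error(
    negative_log_likelihood(5, 1, 1, "exponential", c(rate = 0.1)),
    "record")
})

test_that("fitting recovers generator parameters on log-normal truth", {
  ipd <- recovery_ipd(seed = 424)
  ctl <- ipd[ipd$arm == "TRAS", ]
  fit <- fit_mixture_cure(ctl, "lognormal")
  expect_lt(abs(fit$cure_fraction - 0.6), 0.05)
  expect_lt(abs(fit$params[["meanlog"]] - 2.5), 0.15)
  # refit on identical input is bit-identical (deterministic multistart)
  fit2 <- fit_mixture_cure(ctl, "lognormal")
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$cure_fraction, fit2$cure_fraction)
})

test_that("all-censored data gives a flagged boundary solution", {
  allc <- data.frame(time = rep(100, 50), event = 0L)
  fit <- fit_mixture_cure(allc, "exponential")
  expect_gte(fit$cure_fraction, 0.999)
  expect_true(fit$boundary)
  expect_equal(fit$loglik, 0)
})

test_that("AIC/BIC fields are consistent with loglik and parameter count", {
  ipd <- recovery_ipd(seed = 77, n = 400)
  ctl <- ipd[ipd$arm == "TRAS", ]
  fits <- lapply(families, function(f) fit_mixture_cure(ctl, f))
  for (f in fits) {
    expect_equal(f$aic, 2 * f$k - 2 * f$loglik, tolerance = 1e-9)
    expect_equal(f$bic, f$k * log(f$n) - 2 * f$loglik, tolerance = 1e-9)
    expect_equal(f$k, 1 + latent_n_params(f$family))
  }
  # independent re-ranking from the returned logliks matches the ranker
  rk <- rank_by_information_criteria(fits)
  aic_indep <- vapply(fits, function(f) 2 * f$k - 2 * f$loglik, numeric(1))
  expect_equal(rk$selected,
               vapply(fits, `[[`, character(1), "family")[which.min(aic_indep)])
  expect_true(all(diff(rk$table$aic) >= 0))
})

test_that("information-criterion ranking breaks ties by parsimony", {
  mk <- function(family, k, loglik, n = 100) {
    structure(list(family = family, k = k, loglik = loglik,
                   aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik,
                   n = n), class = "mixture_cure_fit")
  }
  single <- rank_by_information_criteria(list(mk("weibull", 3, -50)))
  expect_equal(single$selected, "weibull")
  # equal loglik, k = 2 vs k = 3: the smaller model ranks first
  two <- rank_by_information_criteria(list(mk("lognormal", 3, -50),
                                           mk("exponential", 2, -50)))
  expect_equal(two$selected, "exponential")
  expect_equal(two$selected_bic, "exponential")
  expect_error(
    rank_by_information_criteria(list(mk("weibull", 3, -50, n = 100),
                                      mk("weibull", 3, -50, n = 101))),
    "mixed|same data")
})

test_that("cycle-probability conversion matches closed forms", {
  # constant survival: zero probability
  expect_equal(survival_to_cycle_prob(function(t) rep(0.7, length(t)), 0:10),
               rep(0, 11))
  # exponential: 1 - exp(-r) independent of the cycle (memorylessness)
  r <- 0.07
  fit <- list(cure_fraction = 0, family = "exponential", params = c(rate = r))
  expect_equal(survival_to_cycle_prob(fit, 0:99), rep(1 - exp(-r), 100),
               tolerance = 1e-12)
  # cured plateau: probabilities vanish far in the tail
  mix <- list(cure_fraction = 0.5, family = "lognormal",
              params = c(meanlog = 2, sdlog = 0.5))
  expect_lt(survival_to_cycle_prob(mix, 500), 1e-10)
  expect_error(survival_to_cycle_prob(function(t) as.numeric(t < 1), 3),
               "exhausted")
})

test_that("waning schedule interpolates the hazard ratio as specified", {
  sch <- waning_schedule(84, 120)
  expect_equal(effective_hazard_ratio(0.54, 60, sch), 0.54)
  expect_equal(effective_hazard_ratio(0.54, 84, sch), 0.54)
  expect_equal(effective_hazard_ratio(0.54, 120, sch), 1)
  expect_equal(effective_hazard_ratio(0.54, 150, sch), 1)
  expect_equal(effective_hazard_ratio(0.54, 102, sch), sqrt(0.54))
  # continuity at both knots to 1e-12: the knot values are exact and the
  # one-sided limits converge to them
  expect_equal(effective_hazard_ratio(0.54, 84, sch), 0.54,
               tolerance = 1e-12)
  expect_equal(effective_hazard_ratio(0.54, 120, sch), 1, tolerance = 1e-12)
  eps <- 1e-11
  for (t0 in c(84, 120)) {
    expect_equal(effective_hazard_ratio(0.54, t0 - eps, sch),
                 effective_hazard_ratio(0.54, t0, sch), tolerance = 1e-12)
    expect_equal(effective_hazard_ratio(0.54, t0 + eps, sch),
                 effective_hazard_ratio(0.54, t0, sch), tolerance = 1e-12)
  }
  # monotone toward 1 on the waning window
  tt <- seq(84, 120, by = 0.5)
  expect_true(all(diff(effective_hazard_ratio(0.54, tt, sch)) >= 0))
  lin <- waning_schedule(84, 120, mode = "linear")
  expect_equal(effective_hazard_ratio(0.54, 102, lin), (1 + 0.54) / 2)
  expect_error(effective_hazard_ratio(0, 10, sch), "positive")
  expect_error(waning_schedule(120, 84), "t_full")
})

test_that("background mortality blending follows the competing-risks closed form", {
  lt <- data.frame(age = 0:100, annual_q = rep(0.12, 101))
  # zero disease risk: monthly 1 - 0.88^(1/12)
  expect_equal(blend_background_mortality(rep(0, 12), lt, 52),
               rep(1 - 0.88^(1 / 12), 12))
  # zero background leaves disease probabilities unchanged
  p <- c(0.01, 0.05, 0.2)
  expect_equal(blend_background_mortality(p, zero_life_table(), 52), p)
  expect_equal(blend_background_mortality(0, zero_life_table(), 52), 0)
  # independence combination
  expect_equal(combine_independent_risks(0.1, 0.2), 1 - 0.9 * 0.8)
  # attained age beyond the table is an error
  expect_error(monthly_background_mortality(lt, 52, 0:(49 * 12)), "exceeds")
})

test_that("fit serialization round-trips through structured text", {
  ipd <- recovery_ipd(seed = 5, n = 300)
  fit <- fit_mixture_cure(ipd[ipd$arm == "TRAS", ], "lognormal")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_mixture_cure_fit(fit, path)
  back <- read_mixture_cure_fit(path)
  expect_equal(back$cure_fraction, fit$cure_fraction, tolerance = 1e-12)
  expect_equal(back$params, fit$params, tolerance = 1e-12)
  expect_equal(back$aic, fit$aic, tolerance = 1e-9)
  expect_equal(back$family, fit$family)
})
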