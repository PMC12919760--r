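# Uncertainty analysis: parameter distributions by moment matching,
# probabilistic sensitivity analysis (CE plane, dominance fraction, CEAC),
# and one-way deterministic sensitivity analysis (tornado).

#' Parameter distribution for probabilistic sensitivity analysis
#'
#' Location/scale are derived by moment matching from the mean and standard
#' error: gamma `shape = (m/se)^2, rate = m/se^2`; log-normal
#' `sdlog^2 = log(1 + se^2/m^2)`, `meanlog = log(m) - sdlog^2/2`; normal
#' `(m, se)`. A zero SE gives a degenerate (point-mass) distribution.
#'
#' @param path Parameter path in the model inputs (e.g.
#'   `"utilities.Remission"`, `"survival.log_hr"`,
#'   `"costs.TDM1.monthly.supportive_first_line"`).
#' @param family `"gamma"`, `"lognormal"` or `"normal"` (the normal is the
#'   1-dimensional case of the multivariate normal used for the
#'   log-hazard-ratio treatment effect).
#' @param mean,se Moments on the parameter's natural scale.
#' @param lower,upper Optional truncation bounds applied after sampling
#'   (utilities are capped at 1; truncations are counted).
#' @export
param_distribution <- function(path, family = c("gamma", "lognormal", "normal"),
                               mean, se, lower = -Inf, upper = Inf) {
  family <- match.arg(family)
  if (se < 0) stop("standard error must be non-negative for '", path, "'")
  if (family %in% c("gamma", "lognormal") && mean <= 0 && se > 0) {
    stop("infeasible moment matching for '", path,
         "': positive-support family needs a positive mean")
  }
  structure(list(path = path, family = family, mean = mean, se = se,
                 lower = lower, upper = upper),
            class = "param_distribution")
}

#' Vectorized draws from one parameter distribution
#'
#' @param d A [param_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`, truncated to the bounds.
#' @export
draw_distribution <- function(d, n) {
  if (d$se == 0) return(rep(d$mean, n))
  x <- switch(d$family,
    gamma = {
      shape <- (d$mean / d$se)^2
      stats::rgamma(n, shape = shape, rate = shape / d$mean)
    },
    lognormal = {
      sdlog <- sqrt(log(1 + (d$se / d$mean)^2))
      stats::rlnorm(n, meanlog = log(d$mean) - sdlog^2 / 2, sdlog = sdlog)
    },
    normal = stats::rnorm(n, d$mean, d$se)
  )
  pmin(pmax(x, d$lower), d$upper)
}

#' Sample one parameter bundle draw
#'
#' @param spec List of [param_distribution()] objects.
#' @param seed Optional integer seed (omit inside [run_psa()], which seeds
#'   once).
#' @return Named list of draws keyed by path, with a `truncated` attribute
#'   counting bound hits.
#' @export
sample_parameters <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raw <- lapply(spec, function(d) {
    if (d$se == 0) return(list(v = d$mean, tr = 0L))
    x <- switch(d$family,
      gamma = {
        shape <- (d$mean / d$se)^2
        stats::rgamma(1, shape = shape, rate = shape / d$mean)
      },
      lognormal = {
        sdlog <- sqrt(log(1 + (d$se / d$mean)^2))
        stats::rlnorm(1, meanlog = log(d$mean) - sdlog^2 / 2, sdlog = sdlog)
      },
      normal = stats::rnorm(1, d$mean, d$se)
    )
    xc <- min(max(x, d$lower), d$upper)
    list(v = xc, tr = as.integer(xc != x))
  })
  draws <- stats::setNames(lapply(raw, `[[`, "v"),
                           vapply(spec, `[[`, character(1), "path"))
  attr(draws, "truncated") <- sum(vapply(raw, `[[`, integer(1), "tr"))
  draws
}

#' Set one model input by path
#'
#' @param bundle An `input_bundle`.
#' @param costs Calibrated cost inputs ([calibrate_cost_inputs()]).
#' @param path Parameter path (see [param_distribution()]).
#' @param value New value; `"survival.log_hr"` is exponentiated onto the HR.
#' @return List `(bundle, costs)` with the value applied.
#' @export
set_model_parameter <- function(bundle, costs, path, value) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  head <- parts[1]
  if (head == "utilities") {
    bundle$utilities[[parts[2]]] <- min(value, 1)
  } else if (head == "survival" && parts[2] == "log_hr") {
    bundle$survival$hr <- exp(value)
  } else if (head == "survival") {
    bundle$survival[[parts[2]]] <- value
  } else if (head == "settings") {
    bundle$settings[[parts[2]]] <- value
  } else if (head == "transitions") {
    if (length(parts) == 3) {
      bundle$transitions[[parts[2]]][[parts[3]]] <- value
    } else {
      bundle$transitions[[parts[2]]] <- value
    }
  } else if (head == "costs") {
    arm <- parts[2]
    if (!arm %in% ARMS) stop("unknown arm in path: ", path)
    if (parts[3] == "monthly") {
      costs[[arm]]$monthly[[parts[4]]] <- value
    } else {
      costs[[arm]][[parts[3]]] <- value
    }
  } else {
    stop("unknown parameter path: ", path)
  }
  list(bundle = bundle, costs = costs)
}

#' Default probabilistic sensitivity specification
#'
#' Utilities: gamma, SE = 10% of the mean, capped at 1. Administration,
#' adverse-event, diagnostic and supportive-care monthly costs: log-normal,
#' SE = 20% of the mean. Treatment effect: normal on the log-HR scale with
#' the bundle's `log_hr_se`. The SE fractions are unreported in the source
#' analysis and are bundle-configurable (`bundle$psa`).
#'
#' @param bundle An `input_bundle`.
#' @param costs Calibrated costs.
#' @return List of [param_distribution()] objects.
#' @export
default_psa_spec <- function(bundle, costs) {
  fu <- bundle$psa$utility_se_frac
  fc <- bundle$psa$cost_se_frac
  spec <- list()
  for (nm in setdiff(names(bundle$utilities), "Death")) {
    m <- bundle$utilities[[nm]]
    spec[[length(spec) + 1L]] <- param_distribution(
      paste0("utilities.", nm), "gamma", m, fu * m, lower = 0, upper = 1)
  }
  cost_components <- c("administration", "adverse_events", "diagnostic",
                       "supportive_residual", "supportive_nmr",
                       "supportive_remission", "supportive_first_line",
                       "supportive_later_line")
  for (arm in ARMS) {
    for (comp in cost_components) {
      m <- costs[[arm]]$monthly[[comp]]
      if (m <= 0) next  # degenerate zero-cost component (comparator AE)
      spec[[length(spec) + 1L]] <- param_distribution(
        paste0("costs.", arm, ".monthly.", comp), "lognormal", m, fc * m,
        lower = 0)
    }
  }
  spec[[length(spec) + 1L]] <- param_distribution(
    "survival.log_hr", "normal", log(bundle$survival$hr),
    bundle$survival$log_hr_se)
  spec
}

#' Run the probabilistic sensitivity analysis
#'
#' Re-samples parameters per draw (survival extrapolation uncertainty
#' enters through the log-HR; curves are not refit per draw), reruns the
#' deterministic model, and collects the incremental cloud. Failed draws
#' are caught, counted and excluded, never silently dropped.
#'
#' @param bundle An `input_bundle`.
#' @param spec PSA specification (default [default_psa_spec()]).
#' @param n Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param costs Optional precalibrated costs.
#' @return A `psa_result`: `cloud` (data frame `draw`, `delta_cost`,
#'   `delta_qalys`, `dominant`), per-arm mean costs/QALYs,
#'   `dominance_fraction`, `n`, `n_failed`, `seed`, `truncated`.
#' @export
run_psa <- function(bundle = make_base_case_bundle(), spec = NULL, n = 1000,
                    seed = 1, costs = NULL) {
  if (is.null(costs)) costs <- calibrate_cost_inputs(bundle)
  if (is.null(spec)) spec <- default_psa_spec(bundle, costs)
  set.seed(seed)
  rows <- vector("list", n)
  means <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("cost_TDM1", "cost_TRAS",
                                          "qalys_TDM1", "qalys_TRAS")))
  n_failed <- 0L
  truncated <- 0L
  for (i in seq_len(n)) {
    draws <- sample_parameters(spec)
    truncated <- truncated + attr(draws, "truncated")
    res <- tryCatch({
      b <- bundle; cc <- costs
      for (p in names(draws)) {
        upd <- set_model_parameter(b, cc, p, draws[[p]])
        b <- upd$bundle; cc <- upd$costs
      }
      run_base_case(b, costs = cc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      next
    }
    means[i, ] <- c(res$TDM1$cost, res$TRAS$cost,
                    res$TDM1$qalys, res$TRAS$qalys)
    rows[[i]] <- data.frame(
      draw = i, delta_cost = res$comparison$delta_cost,
      delta_qalys = res$comparison$delta_qalys,
      dominant = res$comparison$delta_cost < 0 &
        res$comparison$delta_qalys > 0)
  }
  cloud <- do.call(rbind, rows)
  structure(list(
    cloud = cloud,
    mean_cost = c(TDM1 = mean(means[, 1], na.rm = TRUE),
                  TRAS = mean(means[, 2], na.rm = TRUE)),
    mean_qalys = c(TDM1 = mean(means[, 3], na.rm = TRUE),
                   TRAS = mean(means[, 4], na.rm = TRUE)),
    dominance_fraction = mean(cloud$dominant),
    n = n, n_failed = n_failed, seed = seed, truncated = truncated
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d, %d failed, %d truncations)\n",
              x$n, x$seed, x$n_failed, x$truncated))
  cat(sprintf("  mean cost  TDM1 %10.1f | TRAS %10.1f\n",
              x$mean_cost[["TDM1"]], x$mean_cost[["TRAS"]]))
  cat(sprintf("  mean QALYs TDM1 %10.3f | TRAS %10.3f\n",
              x$mean_qalys[["TDM1"]], x$mean_qalys[["TRAS"]]))
  cat(sprintf("  dominant in %.1f%% of draws\n", 100 * x$dominance_fraction))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result`.
#' @param lambda Willingness-to-pay grid (non-negative).
#' @return Data frame `lambda`, `prob_cost_effective` (fraction of draws
#'   with positive net monetary benefit).
#' @export
ceac <- function(psa, lambda) {
  if (length(lambda) == 0) stop("empty willingness-to-pay grid")
  if (any(lambda < 0)) stop("willingness-to-pay must be non-negative")
  cl <- psa$cloud
  prob <- vapply(lambda, function(l) {
    mean(cl$delta_qalys * l - cl$delta_cost > 0)
  }, numeric(1))
  data.frame(lambda = lambda, prob_cost_effective = prob)
}

#' One-way deterministic sensitivity range
#'
#' @param path Parameter path (see [param_distribution()]).
#' @param low,high Range bounds; must bracket the base value.
#' @param base Base-case value (checked against the bounds).
#' @export
dsa_range <- function(path, low, high, base = NULL) {
  if (low > high) stop("low must not exceed high for '", path, "'")
  if (!is.null(base) && (low > base || base > high)) {
    stop("base value outside [low, high] for '", path, "'")
  }
  structure(list(path = path, low = low, high = high, base = base),
            class = "dsa_range")
}

#' Default one-way sensitivity ranges
#'
#' Body weight, acquisition prices, transition probabilities and cost
#' components at +/-20% of base; utilities at +/-10% (capped at 1);
#' discount rate 0 to 10%. Ranges are fixture assumptions (the source
#' analysis does not print its bounds).
#'
#' @param bundle An `input_bundle`.
#' @param costs Calibrated costs.
#' @return List of [dsa_range()] objects.
#' @export
default_dsa_ranges <- function(bundle, costs) {
  pm20 <- function(path, base) dsa_range(path, 0.8 * base, 1.2 * base, base)
  ranges <- list(
    pm20("settings.weight", bundle$settings$weight),
    pm20("transitions.p_remission_to_1l",
         bundle$transitions$p_remission_to_1l),
    pm20("costs.TDM1.price_per_mg", costs$TDM1$price_per_mg),
    pm20("costs.TRAS.price_per_mg", costs$TRAS$price_per_mg),
    pm20("costs.TDM1.monthly.supportive_first_line",
         costs$TDM1$monthly[["supportive_first_line"]]),
    pm20("costs.TRAS.monthly.supportive_first_line",
         costs$TRAS$monthly[["supportive_first_line"]]),
    dsa_range("settings.discount", 0, 0.10, bundle$settings$discount),
    dsa_range("utilities.ResidualOff",
              0.9 * bundle$utilities[["ResidualOff"]],
              min(1, 1.1 * bundle$utilities[["ResidualOff"]]),
              bundle$utilities[["ResidualOff"]]),
    dsa_range("utilities.LaterLineMet",
              0.9 * bundle$utilities[["LaterLineMet"]],
              min(1, 1.1 * bundle$utilities[["LaterLineMet"]]),
              bundle$utilities[["LaterLineMet"]])
  )
  ranges
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter is set to its low and high bound with all others at base;
#' the net monetary benefit of T-DM1 vs trastuzumab is recomputed; entries
#' are sorted by swing `|NMB(high) - NMB(low)|` descending.
#'
#' @param bundle An `input_bundle`.
#' @param ranges List of [dsa_range()] (default [default_dsa_ranges()]).
#' @param costs Optional precalibrated costs.
#' @return Data frame `parameter`, `nmb_low`, `nmb_high`, `swing`, plus the
#'   base NMB as an attribute.
#' @export
one_way_dsa <- function(bundle = make_base_case_bundle(), ranges = NULL,
                        costs = NULL) {
  if (is.null(costs)) costs <- calibrate_cost_inputs(bundle)
  if (is.null(ranges)) ranges <- default_dsa_ranges(bundle, costs)
  base_res <- run_base_case(bundle, costs = costs)
  nmb_at <- function(path, value) {
    upd <- set_model_parameter(bundle, costs, path, value)
    run_base_case(upd$bundle, costs = upd$costs)$comparison$nmb
  }
  rows <- lapply(ranges, function(r) {
    data.frame(parameter = r$path,
               nmb_low = nmb_at(r$path, r$low),
               nmb_high = nmb_at(r$path, r$high),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$swing <- abs(tab$nmb_high - tab$nmb_low)
  tab <- tab[order(-tab$swing), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "nmb_base") <- base_res$comparison$nmb
  tab
}
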