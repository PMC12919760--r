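# Mixture-cure parametric survival: fitting, information-criterion ranking,
# cycle-probability conversion, treatment-effect waning, background mortality.

LATENT_FAMILIES <- c("exponential", "weibull", "lognormal", "loglogistic")

latent_n_params <- function(family) {
  switch(family,
    exponential = 1L, weibull = 2L, lognormal = 2L, loglogistic = 2L,
    stop("unknown latent family: ", family)
  )
}

#' Latent (uncured) survival function
#'
#' Survival function of the latent event-time distribution for the uncured
#' fraction. Parameterizations follow base R (`weibull`, `lnorm`) and
#' \pkg{flexsurv} (`llogis`).
#'
#' @param t Time in months, non-negative.
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`.
#' @param params Named or positional numeric vector: `rate`; `shape, scale`;
#'   `meanlog, sdlog`; `shape, scale` respectively.
#' @return Survival probabilities, same length as `t`.
#' @export
latent_survival <- function(t, family, params) {
  params <- unname(params)
  switch(family,
    exponential = stats::pexp(t, rate = params[1], lower.tail = FALSE),
    weibull = stats::pweibull(t, shape = params[1], scale = params[2],
                              lower.tail = FALSE),
    lognormal = stats::plnorm(t, meanlog = params[1], sdlog = params[2],
                              lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = params[1], scale = params[2],
                                    lower.tail = FALSE),
    stop("unknown latent family: ", family)
  )
}

#' @rdname latent_survival
#' @export
latent_density <- function(t, family, params) {
  params <- unname(params)
  switch(family,
    exponential = stats::dexp(t, rate = params[1]),
    weibull = stats::dweibull(t, shape = params[1], scale = params[2]),
    lognormal = stats::dlnorm(t, meanlog = params[1], sdlog = params[2]),
    loglogistic = flexsurv::dllogis(t, shape = params[1], scale = params[2]),
    stop("unknown latent family: ", family)
  )
}

latent_quantile <- function(p, family, params) {
  params <- unname(params)
  switch(family,
    exponential = stats::qexp(p, rate = params[1]),
    weibull = stats::qweibull(p, shape = params[1], scale = params[2]),
    lognormal = stats::qlnorm(p, meanlog = params[1], sdlog = params[2]),
    loglogistic = flexsurv::qllogis(p, shape = params[1], scale = params[2]),
    stop("unknown latent family: ", family)
  )
}

#' Mixture-cure survival function
#'
#' `S(t) = pi + (1 - pi) * S_latent(t)`: a fraction `pi` of the cohort is
#' cured (never experiences the event); the remainder follows the latent
#' parametric distribution. The curve plateaus at `pi` as `t` grows.
#'
#' @param t Time in months, non-negative.
#' @param fit A `mixture_cure_fit`, or any list with elements
#'   `cure_fraction`, `family` and `params`.
#' @return Survival probabilities in `[pi, 1]`.
#' @export
mixture_cure_survival <- function(t, fit) {
  if (any(t < 0)) stop("negative time not allowed in mixture_cure_survival()")
  pi <- fit$cure_fraction
  stopifnot(pi >= 0, pi <= 1)
  pi + (1 - pi) * latent_survival(t, fit$family, fit$params)
}

#' Negative log-likelihood of a mixture-cure model
#'
#' Events contribute `-log((1-pi) f(t))`; censored records contribute
#' `-log(pi + (1-pi) S(t))`.
#'
#' @param time Positive event/censoring times (months).
#' @param event Binary event indicator (1 = event, 0 = censored).
#' @param cure_fraction Cured fraction in `[0, 1]`.
#' @param family,params Latent distribution, see [latent_survival()].
#' @return The negative log-likelihood (0 for empty data).
#' @export
negative_log_likelihood <- function(time, event, cure_fraction, family, params) {
  if (length(time) == 0) return(0)
  stopifnot(length(time) == length(event))
  if (any(time <= 0)) stop("all times must be strictly positive")
  pi <- cure_fraction
  ll <- numeric(length(time))
  ev <- event == 1
  if (any(ev)) {
    dens <- (1 - pi) * latent_density(time[ev], family, params)
    bad <- !is.finite(dens) | dens <= 0
    if (any(bad)) {
      stop("non-finite likelihood contribution at event record(s) ",
           paste(which(ev)[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
    }
    ll[ev] <- log(dens)
  }
  if (any(!ev)) {
    sv <- pi + (1 - pi) * latent_survival(time[!ev], family, params)
    bad <- !is.finite(sv) | sv <= 0
    if (any(bad)) {
      stop("non-finite likelihood contribution at censored record(s) ",
           paste(which(!ev)[bad][seq_len(min(5, sum(bad)))], collapse = ", "))
    }
    ll[!ev] <- log(sv)
  }
  -sum(ll)
}

# parameter transforms: optimize on an unconstrained scale
.latent_to_unconstrained <- function(family, params) {
  switch(family,
    exponential = log(params),
    lognormal = c(params[1], log(params[2])),
    c(log(params[1]), log(params[2]))  # weibull / loglogistic
  )
}

.latent_from_unconstrained <- function(family, theta) {
  switch(family,
    exponential = exp(theta),
    lognormal = c(theta[1], exp(theta[2])),
    c(exp(theta[1]), exp(theta[2]))
  )
}

# deterministic latent starting values from observed event times
.latent_start <- function(family, time, event) {
  te <- time[event == 1]
  if (length(te) < 2) te <- c(time, time * 1.5)
  switch(family,
    exponential = max(sum(event), 0.5) / sum(time),
    weibull = c(1.2, stats::median(te)),
    lognormal = c(mean(log(te)), max(stats::sd(log(te)), 0.1)),
    loglogistic = c(1.5, stats::median(te))
  )
}

#' Fit a mixture-cure parametric survival model by maximum likelihood
#'
#' Deterministic bounded multistart: the cure fraction is started on a fixed
#' grid (`pi_starts`), latent parameters from moment-style starts computed
#' from the event times; the best converged solution is returned. Refitting
#' identical data reproduces identical estimates.
#'
#' @param data Data frame with columns `time` (months, > 0) and `event`
#'   (0/1); an optional `arm` column is ignored here (fit per arm upstream).
#' @param family Latent family, see [latent_survival()].
#' @param pi_starts Cure-fraction starting grid.
#' @param control Passed to [stats::nlminb()]; defaults to objective
#'   tolerance `1e-8`.
#' @return A `mixture_cure_fit`: `cure_fraction`, `family`, `params`,
#'   `loglik`, `aic`, `bic`, `n`, `n_events`, `boundary` flag, `convergence`.
#' @export
fit_mixture_cure <- function(data, family,
                             pi_starts = c(0.1, 0.5, 0.9),
                             control = list(rel.tol = 1e-10, abs.tol = 0,
                                            iter.max = 500, eval.max = 800)) {
  family <- match.arg(family, LATENT_FAMILIES)
  stopifnot(all(c("time", "event") %in% names(data)))
  time <- as.numeric(data$time); event <- as.integer(data$event)
  if (any(time <= 0)) stop("all times must be strictly positive")
  n <- length(time)
  if (n < 2) stop("need at least 2 records to fit")
  np <- latent_n_params(family)
  if (length(unique(time[event == 1])) < np && any(event == 1)) {
    warning("fewer distinct event times than latent parameters; ",
            "fit may be unidentified")
  }

  lat0 <- .latent_start(family, time, event)
  if (sum(event) == 0) {
    # no events: likelihood is maximized on the boundary pi = 1 (loglik 0);
    # latent parameters are unidentified and reported at their starts
    k <- 1 + np
    names(lat0) <- switch(family,
      exponential = "rate", weibull = c("shape", "scale"),
      lognormal = c("meanlog", "sdlog"), loglogistic = c("shape", "scale"))
    return(structure(list(
      cure_fraction = 1, family = family, params = lat0,
      loglik = 0, aic = 2 * k, bic = k * log(n),
      k = k, n = n, n_events = 0L, boundary = TRUE,
      convergence = 0L,
      message = "no events observed; cure fraction at upper bound"
    ), class = "mixture_cure_fit"))
  }
  obj <- function(theta) {
    pi <- stats::plogis(theta[1])
    params <- .latent_from_unconstrained(family, theta[-1])
    out <- tryCatch(
      negative_log_likelihood(time, event, pi, family, params),
      error = function(e) Inf
    )
    if (!is.finite(out)) 1e10 else out
  }

  best <- NULL
  diagnostics <- character(0)
  for (p0 in pi_starts) {
    theta0 <- c(stats::qlogis(p0), .latent_to_unconstrained(family, lat0))
    res <- tryCatch(stats::nlminb(theta0, obj, control = control),
                    error = function(e) NULL)
    if (is.null(res)) { diagnostics <- c(diagnostics, "start failed"); next }
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best) || !is.finite(best$objective)) {
    stop("mixture-cure optimizer failed to converge for family '", family,
         "': ", paste(diagnostics, collapse = "; "))
  }
  pi_hat <- stats::plogis(best$par[1])
  params <- .latent_from_unconstrained(family, best$par[-1])
  names(params) <- switch(family,
    exponential = "rate", weibull = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"), loglogistic = c("shape", "scale"))
  loglik <- -best$objective
  k <- 1 + np
  fit <- structure(list(
    cure_fraction = pi_hat, family = family, params = params,
    loglik = loglik, aic = 2 * k - 2 * loglik, bic = k * log(n) - 2 * loglik,
    k = k, n = n, n_events = sum(event),
    boundary = pi_hat > 1 - 1e-3 || pi_hat < 1e-3,
    convergence = best$convergence, message = best$message
  ), class = "mixture_cure_fit")
  fit
}

#' @export
print.mixture_cure_fit <- function(x, ...) {
  cat("Mixture-cure fit (", x$family, " latent), n = ", x$n,
      " (", x$n_events, " events)\n", sep = "")
  cat(sprintf("  cure fraction: %.4f%s\n", x$cure_fraction,
              if (x$boundary) "  [boundary]" else ""))
  cat("  latent params:",
      paste(names(x$params), signif(x$params, 5), sep = " = ",
            collapse = ", "), "\n")
  cat(sprintf("  loglik %.3f | AIC %.2f | BIC %.2f\n", x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Rank mixture-cure fits by information criteria
#'
#' Sorts ascending by AIC (BIC ranking reported alongside). Ties broken by
#' fewer parameters, then by fixed family order
#' exponential < weibull < lognormal < loglogistic.
#'
#' @param fits List of `mixture_cure_fit` objects on the same data.
#' @return List with `table` (data frame of family, k, loglik, aic, bic and
#'   both ranks, sorted by AIC), `selected` (family name, best AIC) and
#'   `selected_bic`.
#' @export
rank_by_information_criteria <- function(fits) {
  stopifnot(length(fits) >= 1)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1) {
    stop("all fits must be computed on the same data (mixed n)")
  }
  fam <- vapply(fits, function(f) f$family, character(1))
  tab <- data.frame(
    family = fam,
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    stringsAsFactors = FALSE
  )
  fam_order <- match(tab$family, LATENT_FAMILIES)
  o_aic <- order(tab$aic, tab$k, fam_order)
  o_bic <- order(tab$bic, tab$k, fam_order)
  tab$aic_rank <- match(seq_len(nrow(tab)), o_aic)
  tab$bic_rank <- match(seq_len(nrow(tab)), o_bic)
  tab <- tab[o_aic, , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, selected = tab$family[1],
       selected_bic = tab$family[tab$bic_rank == 1][1])
}

#' Convert a survival curve to per-cycle transition probabilities
#'
#' `p_k = 1 - S((k+1)*delta) / S(k*delta)`, the conditional probability of
#' the event during cycle `k` given event-free at its start.
#'
#' @param surv Either a function of time (months) or a `mixture_cure_fit`.
#' @param cycles Integer cycle indices (0-based); may be a vector.
#' @param delta Cycle length in months (default 1).
#' @return Per-cycle probabilities in `[0, 1]`.
#' @export
survival_to_cycle_prob <- function(surv, cycles, delta = 1) {
  sfun <- if (is.function(surv)) surv else function(t) mixture_cure_survival(t, surv)
  s0 <- sfun(cycles * delta)
  s1 <- sfun((cycles + 1) * delta)
  if (any(s0 <= 0)) stop("cohort exhausted: S(k*delta) = 0 at cycle ",
                         cycles[which(s0 <= 0)[1]])
  p <- 1 - s1 / s0
  pmin(pmax(p, 0), 1)
}

#' Treatment-effect waning schedule
#'
#' Full effect until `t_full`, no effect from `t_none`, interpolated between.
#' Interpolation is log-linear in the hazard ratio by default (`"loglinear"`),
#' optionally linear in the HR (`"linear"`).
#'
#' @param t_full Months of full effect (default 84).
#' @param t_none Months beyond which there is no effect (default 120).
#' @param mode `"loglinear"` or `"linear"`.
#' @export
waning_schedule <- function(t_full = 84, t_none = 120,
                            mode = c("loglinear", "linear")) {
  mode <- match.arg(mode)
  if (!(t_full < t_none)) stop("t_full must be < t_none")
  structure(list(t_full = t_full, t_none = t_none, mode = mode),
            class = "waning_schedule")
}

#' Effective hazard ratio under waning
#'
#' @param hr Fitted arm contrast (hazard ratio), > 0.
#' @param t Time in months; vectorized.
#' @param schedule A [waning_schedule()].
#' @return Effective HR: `hr` for `t <= t_full`, 1 for `t >= t_none`,
#'   interpolated (continuously, monotone toward 1) in between.
#' @export
effective_hazard_ratio <- function(hr, t, schedule = waning_schedule()) {
  if (hr <= 0) stop("hazard ratio must be strictly positive")
  w <- (schedule$t_none - t) / (schedule$t_none - schedule$t_full)
  w <- pmin(pmax(w, 0), 1)
  if (schedule$mode == "loglinear") exp(w * log(hr)) else 1 + w * (hr - 1)
}

#' Monthly background mortality from an annual life table
#'
#' @param life_table Data frame with columns `age` (years) and `annual_q`
#'   (annual all-cause death probability).
#' @param baseline_age Age in years at cycle 0.
#' @param cycles 0-based cycle indices (months).
#' @return Monthly death probabilities `1 - (1 - q)^(1/12)` at the attained
#'   (completed) age `floor(baseline_age + k/12)`.
#' @export
monthly_background_mortality <- function(life_table, baseline_age, cycles) {
  stopifnot(all(c("age", "annual_q") %in% names(life_table)))
  age <- floor(baseline_age + cycles / 12)
  if (any(age > max(life_table$age))) {
    stop("attained age ", max(age), " exceeds life table (max ",
         max(life_table$age), ")")
  }
  q <- life_table$annual_q[match(age, life_table$age)]
  if (any(is.na(q))) stop("life table missing ages: ",
                          paste(unique(age[is.na(q)]), collapse = ", "))
  1 - (1 - q)^(1 / 12)
}

#' Combine independent competing risks
#'
#' @param p_a,p_b Per-cycle probabilities of two independent risks.
#' @return `1 - (1 - p_a) * (1 - p_b)`.
#' @export
combine_independent_risks <- function(p_a, p_b) 1 - (1 - p_a) * (1 - p_b)

#' Blend disease-specific event probabilities with background mortality
#'
#' @param p_disease Per-cycle disease event/death probabilities (cycle 0
#'   first).
#' @param life_table See [monthly_background_mortality()].
#' @param baseline_age Age at cycle 0 (years).
#' @return All-cause per-cycle probabilities, at least the background level.
#' @export
blend_background_mortality <- function(p_disease, life_table,
                                       baseline_age = 52) {
  cycles <- seq_along(p_disease) - 1
  q_m <- monthly_background_mortality(life_table, baseline_age, cycles)
  combine_independent_risks(p_disease, q_m)
}

#' Serialize / read a mixture-cure fit as structured text
#'
#' @param fit A `mixture_cure_fit`.
#' @param path File path (YAML).
#' @export
write_mixture_cure_fit <- function(fit, path) {
  yaml::write_yaml(list(
    family = fit$family, cure_fraction = fit$cure_fraction,
    params = as.list(fit$params), loglik = fit$loglik, aic = fit$aic,
    bic = fit$bic, n = fit$n, n_events = fit$n_events
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_mixture_cure_fit
#' @export
read_mixture_cure_fit <- function(path) {
  x <- yaml::read_yaml(path)
  np <- latent_n_params(x$family)
  k <- 1 + np
  structure(list(
    cure_fraction = x$cure_fraction, family = x$family,
    params = unlist(x$params), loglik = x$loglik, aic = x$aic, bic = x$bic,
    k = k, n = x$n, n_events = x$n_events,
    boundary = x$cure_fraction > 1 - 1e-5 || x$cure_fraction < 1e-5,
    convergence = 0L, message = "read from file"
  ), class = "mixture_cure_fit")
}
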