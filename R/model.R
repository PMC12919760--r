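# Model assembly: arm-specific survival curves with waning, cost
# calibration against the published per-arm component means, full base-case
# run, and event-reduction summaries.

#' Arm survival curves implied by the base-case bundle
#'
#' The control (trastuzumab) curve is a mixture-cure model whose cure
#' fraction is calibrated so survival at the anchor month matches the
#' published control disease-free survival. The treated (T-DM1) curve uses
#' the same latent distribution with its hazard scaled by the treatment HR
#' and its own anchor-calibrated cure fraction.
#'
#' @param bundle An `input_bundle`.
#' @return List of functions `TDM1(t)`, `TRAS(t)` plus the cure fractions.
#' @export
arm_survival_curves <- function(bundle) {
  sv <- bundle$survival
  lat <- sv$latent
  pi_c <- calibrate_cure_fraction(sv$anchor_surv[["TRAS"]], sv$anchor_time,
                                  lat, 1)
  pi_t <- calibrate_cure_fraction(sv$anchor_surv[["TDM1"]], sv$anchor_time,
                                  lat, sv$hr)
  hr <- sv$hr
  list(
    TRAS = function(t) pi_c + (1 - pi_c) * latent_survival(t, lat$family,
                                                           lat$params),
    TDM1 = function(t) pi_t + (1 - pi_t) *
      latent_survival(t, lat$family, lat$params)^hr,
    cure_fractions = c(TDM1 = pi_t, TRAS = pi_c)
  )
}

#' Per-cycle disease-free exit probabilities with treatment-effect waning
#'
#' Control probabilities come from the control curve. The treated arm uses
#' its own fitted curve while the effect is full, the control hazard once
#' the effect has waned completely, and a log-linear hazard blend in
#' between: `h_w(t) = h_trt(t)^w * h_ctl(t)^(1-w)` with the waning weight
#' `w` falling from 1 at `t_full` to 0 at `t_none`. The blend is continuous
#' and the arms' hazards are equal for all cycles at or beyond `t_none`.
#'
#' @param bundle An `input_bundle`.
#' @param H Number of cycles.
#' @return List with numeric vectors `TDM1` and `TRAS` of length `H`.
#' @export
arm_exit_probabilities <- function(bundle, H = bundle$settings$cycles) {
  curves <- arm_survival_curves(bundle)
  k <- seq_len(H) - 1L
  p_ctl <- survival_to_cycle_prob(curves$TRAS, k)
  p_trt_fit <- survival_to_cycle_prob(curves$TDM1, k)
  wn <- bundle$survival$waning
  w <- pmin(pmax((wn$t_none - k) / (wn$t_none - wn$t_full), 0), 1)
  h_ctl <- -log(1 - p_ctl)
  h_trt <- -log(1 - p_trt_fit)
  h_w <- exp(w * log(h_trt) + (1 - w) * log(h_ctl))
  list(TDM1 = 1 - exp(-h_w), TRAS = p_ctl)
}

#' Assemble the per-arm Markov inputs
#'
#' @param bundle An `input_bundle`.
#' @param arm `"TDM1"` or `"TRAS"`.
#' @param H Number of cycles.
#' @return List consumed by [build_matrix_sequence()].
#' @export
build_arm_inputs <- function(bundle, arm, H = bundle$settings$cycles) {
  arm <- match.arg(arm, ARMS)
  p_exit <- arm_exit_probabilities(bundle, H)[[arm]]
  q_bg <- monthly_background_mortality(bundle$life_table,
                                       bundle$settings$baseline_age,
                                       seq_len(H) - 1L)
  tr <- bundle$transitions
  list(p_exit = p_exit, q_bg = q_bg, shares = tr$df_exit_shares,
       p_rem_1l = tr$p_remission_to_1l,
       p_1l_2l = tr$p_1l_to_2l[[arm]],
       p_2l_death = tr$p_2l_progression[[arm]],
       treat_cycles = bundle$treat_cycles)
}

#' Run one arm's cohort trace
#'
#' @inheritParams build_arm_inputs
#' @return A `cohort_trace` with the arm inputs attached as an attribute.
#' @export
run_arm_trace <- function(bundle, arm, H = bundle$settings$cycles) {
  inputs <- build_arm_inputs(bundle, arm, H)
  matrices <- build_matrix_sequence(inputs, H)
  states <- state_space()
  init <- as.numeric(states == "ResidualOn")
  trace <- run_cohort(init, matrices, H)
  attr(trace, "arm_inputs") <- inputs
  trace
}

# discounted effective occupancy aggregates used by the calibration
.occupancy_denominators <- function(trace, settings, treat_cycles) {
  occ <- half_cycle_effective_occupancy(trace, settings$half_cycle)
  df <- discount_factor(seq_len(nrow(occ)) - 1L, settings$discount)
  states <- state_space()
  tun <- attr(states, "tunnel")
  w <- occ * df
  resid_cols <- match(c("ResidualOn", "ResidualOff"), states)
  list(
    resid_treat = sum(w[seq_len(treat_cycles), match("ResidualOn", states)]),
    resid_all = sum(w[, resid_cols]),
    nmr = sum(w[, tun]),
    remission = sum(w[, match("Remission", states)]),
    first_line = sum(w[, match("FirstLineMet", states)]),
    later_line = sum(w[, match("LaterLineMet", states)])
  )
}

#' Back-solve per-cycle costs from the published per-arm component means
#'
#' The published analysis prints discounted per-patient mean costs per
#' health state and component but not the monthly unit costs behind them.
#' This calibration divides each arm's component target by that arm's
#' discounted effective occupancy on the relevant basis (treatment-phase
#' residual occupancy for acquisition/administration/adverse events;
#' all-cycle residual occupancy for diagnostics and residual supportive
#' care; state occupancy for the recurrence, remission and metastatic
#' supportive-care components). Calibrated monthly costs are arm-specific
#' because the metastatic-line regimens (and hence drug-inclusive
#' supportive costs) differ by prior adjuvant exposure. Derived quantities:
#' the drug price per mg (from the acquisition component and the dosing
#' regimen at the reference weight) and the unit cost of the additional
#' complete blood count (adverse-event component over 14 administrations).
#'
#' @param bundle An `input_bundle`.
#' @param traces Optional named list of precomputed arm traces.
#' @return Named list per arm: `monthly` (named vector of per-cycle costs),
#'   `price_per_mg`, `ae_unit_cost`.
#' @export
calibrate_cost_inputs <- function(bundle, traces = NULL) {
  settings <- bundle$settings
  out <- list()
  for (arm in ARMS) {
    trace <- if (!is.null(traces)) traces[[arm]] else run_arm_trace(bundle, arm)
    D <- .occupancy_denominators(trace, settings, bundle$treat_cycles)
    tg <- bundle$cost_targets[[arm]]
    monthly <- c(
      acquisition = tg$residual[["acquisition"]] / D$resid_treat,
      administration = tg$residual[["administration"]] / D$resid_treat,
      adverse_events = tg$residual[["adverse_events"]] / D$resid_treat,
      diagnostic = tg$residual[["diagnostic"]] / D$resid_all,
      supportive_residual = tg$residual[["supportive"]] / D$resid_all,
      supportive_nmr = tg$nmr_supportive / D$nmr,
      supportive_remission = tg$remission_supportive / D$remission,
      supportive_first_line = tg$first_line_supportive / D$first_line,
      supportive_later_line = tg$later_line_supportive / D$later_line
    )
    regimen <- bundle$regimens[[arm]]
    total_mg <- sum(administration_mg(regimen, settings$weight))
    out[[arm]] <- list(
      monthly = monthly,
      price_per_mg = monthly[["acquisition"]] * bundle$treat_cycles / total_mg,
      ae_unit_cost = monthly[["adverse_events"]] * bundle$treat_cycles /
        regimen$n_cycles
    )
  }
  out
}

#' Build per-component cost matrices for one arm
#'
#' Treatment-phase components (acquisition, administration, adverse events)
#' are spread evenly over the first `treat_cycles` cycles of the
#' on-treatment residual state and are zero afterwards; diagnostics and
#' residual supportive care run over both residual states for the whole
#' horizon; state supportive-care costs are constant monthly amounts.
#' Acquisition is recomputed from the dosing regimen, the price per mg and
#' the body weight so that weight and price changes propagate.
#'
#' @param bundle An `input_bundle`.
#' @param costs Output of [calibrate_cost_inputs()].
#' @param arm `"TDM1"` or `"TRAS"`.
#' @param H Number of cycles.
#' @return Named list of `H x S` matrices, one per cost component.
#' @export
build_cost_matrices <- function(bundle, costs, arm,
                                H = bundle$settings$cycles) {
  arm <- match.arg(arm, ARMS)
  states <- state_space()
  S <- length(states)
  tun <- attr(states, "tunnel")
  tc <- bundle$treat_cycles
  cm <- costs[[arm]]$monthly
  zero <- function() matrix(0, H, S, dimnames = list(NULL, states))
  i <- function(nm) match(nm, states)

  regimen <- bundle$regimens[[arm]]
  regimen$price_per_mg <- costs[[arm]]$price_per_mg
  acq_total <- sum(per_cycle_drug_cost(regimen, bundle$settings$weight))
  acquisition <- zero()
  acquisition[seq_len(tc), i("ResidualOn")] <- acq_total / tc

  administration <- zero()
  administration[seq_len(tc), i("ResidualOn")] <- cm[["administration"]]

  adverse <- zero()
  adverse[seq_len(tc), i("ResidualOn")] <-
    adverse_event_cost(arm, costs[[arm]]$ae_unit_cost,
                       regimen$n_cycles) / tc

  diagnostic <- zero()
  diagnostic[, c(i("ResidualOn"), i("ResidualOff"))] <- cm[["diagnostic"]]

  supportive <- zero()
  supportive[, c(i("ResidualOn"), i("ResidualOff"))] <-
    cm[["supportive_residual"]]
  supportive[, tun] <- cm[["supportive_nmr"]]
  supportive[, i("Remission")] <- cm[["supportive_remission"]]
  supportive[, i("FirstLineMet")] <- cm[["supportive_first_line"]]
  supportive[, i("LaterLineMet")] <- cm[["supportive_later_line"]]

  list(acquisition = acquisition, diagnostic = diagnostic,
       administration = administration, adverse_events = adverse,
       supportive = supportive)
}

# utility vector over the expanded state space
.expand_utilities <- function(utilities) {
  states <- state_space()
  u <- numeric(length(states))
  names(u) <- states
  u["ResidualOn"] <- utilities[["ResidualOn"]]
  u["ResidualOff"] <- utilities[["ResidualOff"]]
  u[attr(states, "tunnel")] <- utilities[["NMR"]]
  u["Remission"] <- utilities[["Remission"]]
  u["FirstLineMet"] <- utilities[["FirstLineMet"]]
  u["LaterLineMet"] <- utilities[["LaterLineMet"]]
  u["Death"] <- utilities[["Death"]]
  u
}

#' Run the full base-case cost-effectiveness model
#'
#' Builds both arms' traces, calibrates per-cycle costs (unless supplied),
#' accumulates discounted costs, life-years and QALYs, and returns the
#' incremental comparison of T-DM1 vs trastuzumab.
#'
#' @param bundle An `input_bundle` (default [make_base_case_bundle()]).
#' @param costs Optional calibrated costs (see [calibrate_cost_inputs()]);
#'   calibrated on the fly when `NULL`.
#' @return A `ce_result`: per-arm lists (`cost`, `qalys`, `life_years`,
#'   `cost_detail`, `trace`), `comparison` (a `ce_comparison`), `costs`,
#'   and the bundle.
#' @export
run_base_case <- function(bundle = make_base_case_bundle(), costs = NULL) {
  validate_bundle(bundle)
  settings <- bundle$settings
  traces <- lapply(stats::setNames(ARMS, ARMS),
                   function(a) run_arm_trace(bundle, a))
  if (is.null(costs)) costs <- calibrate_cost_inputs(bundle, traces)
  u <- .expand_utilities(bundle$utilities)
  arms <- list()
  for (arm in ARMS) {
    cmats <- build_cost_matrices(bundle, costs, arm)
    cost <- accumulate_costs(traces[[arm]], cmats, settings)
    eff <- accumulate_qalys(traces[[arm]], u, settings)
    arms[[arm]] <- list(cost = cost$total, cost_detail = cost,
                        qalys = eff$qalys, life_years = eff$life_years,
                        trace = traces[[arm]])
  }
  comparison <- incremental_summary(arms$TDM1, arms$TRAS, settings$wtp)
  structure(list(TDM1 = arms$TDM1, TRAS = arms$TRAS,
                 comparison = comparison, costs = costs, bundle = bundle),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-effectiveness, T-DM1 vs trastuzumab\n")
  for (arm in ARMS) {
    cat(sprintf("  %-5s cost %10.1f | QALYs %6.3f | LY %6.3f\n", arm,
                x[[arm]]$cost, x[[arm]]$qalys, x[[arm]]$life_years))
  }
  print(x$comparison)
  invisible(x)
}

#' Per-state cost-component table (published-layout report)
#'
#' @param result A `ce_result`.
#' @return Data frame: state group, component, per-arm discounted mean
#'   cost, and the T-DM1-minus-trastuzumab increment.
#' @export
ce_component_table <- function(result) {
  states <- state_space()
  tun <- attr(states, "tunnel")
  group_of <- function(cs) {
    resid <- match(c("ResidualOn", "ResidualOff"), states)
    c(residual = sum(cs[resid]), nmr = sum(cs[tun]),
      remission = unname(cs[match("Remission", states)]),
      first_line = unname(cs[match("FirstLineMet", states)]),
      later_line = unname(cs[match("LaterLineMet", states)]))
  }
  rows <- list()
  for (comp in COST_COMPONENTS) {
    g_t <- group_of(result$TDM1$cost_detail$component_state[comp, ])
    g_c <- group_of(result$TRAS$cost_detail$component_state[comp, ])
    for (g in names(g_t)) {
      rows[[length(rows) + 1L]] <- data.frame(
        state = g, component = comp, TDM1 = unname(g_t[g]),
        TRAS = unname(g_c[g]), incremental = unname(g_t[g] - g_c[g]),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab[tab$TDM1 != 0 | tab$TRAS != 0, , drop = FALSE]
}

#' Cumulative clinical events by month
#'
#' Cumulative incidence of locoregional (non-metastatic) recurrences,
#' metastatic events (from the disease-free and remission states), and
#' deaths, per modeled patient.
#'
#' @param trace A `cohort_trace` from [run_arm_trace()].
#' @param month Months since model entry.
#' @return Named vector `locoregional`, `metastatic`, `death`.
#' @export
cumulative_events <- function(trace, month) {
  inputs <- attr(trace, "arm_inputs")
  if (is.null(inputs)) stop("trace lacks arm inputs; use run_arm_trace()")
  states <- state_space()
  K <- min(month, nrow(trace) - 1L)
  k <- seq_len(K)  # transitions into cycles 1..K
  occ_df <- rowSums(trace[k, match(c("ResidualOn", "ResidualOff"), states),
                          drop = FALSE])
  occ_rem <- trace[k, match("Remission", states)]
  p <- inputs$p_exit[k]
  q <- inputs$q_bg[k]
  loco <- sum(occ_df * (1 - q) * p * inputs$shares[["locoregional"]])
  met <- sum(occ_df * (1 - q) * p * inputs$shares[["metastatic"]]) +
    sum(occ_rem * (1 - q) * inputs$p_rem_1l)
  death <- unname(trace[K + 1L, match("Death", states)])
  c(locoregional = loco, metastatic = met, death = death)
}

#' Relative event reductions, T-DM1 vs trastuzumab
#'
#' @param result A `ce_result`.
#' @param month Evaluation month (default 36).
#' @return Named vector of proportional reductions (1 - T-DM1/trastuzumab).
#' @export
event_reductions <- function(result, month = 36) {
  e_t <- cumulative_events(result$TDM1$trace, month)
  e_c <- cumulative_events(result$TRAS$trace, month)
  1 - e_t / e_c
}
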