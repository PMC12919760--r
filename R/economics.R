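# Micro-costing, utility/QALY accumulation, and incremental summaries
# (ICER / dominance / net monetary benefit). All costs in 2024 US$.

COST_COMPONENTS <- c("acquisition", "diagnostic", "administration",
                     "adverse_events", "supportive")

#' Dosing regimen
#'
#' @param drug Drug name.
#' @param dose_per_kg Maintenance dose in mg/kg.
#' @param loading_dose_per_kg Optional first-administration dose in mg/kg.
#' @param interval_days Days between administrations.
#' @param n_cycles Number of administrations.
#' @param price_per_mg Price per mg (2024 US$); may be `NA` until calibrated.
#' @export
dose_regimen <- function(drug, dose_per_kg, loading_dose_per_kg = NULL,
                         interval_days = 21, n_cycles = 14,
                         price_per_mg = NA_real_) {
  stopifnot(dose_per_kg > 0, n_cycles >= 1)
  if (!is.null(loading_dose_per_kg)) stopifnot(loading_dose_per_kg > 0)
  structure(list(drug = drug, dose_per_kg = dose_per_kg,
                 loading_dose_per_kg = loading_dose_per_kg,
                 interval_days = interval_days, n_cycles = n_cycles,
                 price_per_mg = price_per_mg),
            class = "dose_regimen")
}

#' Milligrams per administration for a regimen
#'
#' @param regimen A [dose_regimen()].
#' @param weight Body weight in kg.
#' @return Vector of length `n_cycles`: mg at each administration (loading
#'   dose first where defined).
#' @export
administration_mg <- function(regimen, weight) {
  if (weight <= 0) stop("weight must be positive")
  mg <- rep(regimen$dose_per_kg * weight, regimen$n_cycles)
  if (!is.null(regimen$loading_dose_per_kg)) {
    mg[1] <- regimen$loading_dose_per_kg * weight
  }
  mg
}

#' Drug cost per administration
#'
#' Linear in mg at the price per minimum concentration unit (no vial
#' wastage); the loading dose applies to the first administration only.
#'
#' @inheritParams administration_mg
#' @return Vector of per-administration costs.
#' @export
per_cycle_drug_cost <- function(regimen, weight) {
  if (is.na(regimen$price_per_mg)) {
    stop("missing price per mg for drug '", regimen$drug, "'")
  }
  administration_mg(regimen, weight) * regimen$price_per_mg
}

#' Share-weighted average price across presentations
#'
#' @param prices Price per mg of each presentation.
#' @param shares Market shares (renormalized to sum 1).
#' @export
weighted_average_price <- function(prices, shares) {
  if (length(prices) == 0) stop("empty presentation list")
  stopifnot(length(prices) == length(shares), all(shares >= 0))
  if (sum(shares) <= 0) stop("market shares must sum to a positive value")
  sum(prices * shares / sum(shares))
}

#' Per-patient adverse-event cost
#'
#' Only the additional complete blood count in the T-DM1-treated population
#' enters the model; the comparator arm carries no adverse-event cost.
#'
#' @param arm `"TDM1"` or `"TRAS"`.
#' @param unit_cost Cost of one complete blood count.
#' @param n_administrations Number of treatment administrations.
#' @return Total adverse-event cost for the arm.
#' @export
adverse_event_cost <- function(arm, unit_cost, n_administrations = 14) {
  if (unit_cost < 0) stop("unit cost must be non-negative")
  if (arm == "TDM1") unit_cost * n_administrations else 0
}

#' Accumulate discounted costs over a cohort trace
#'
#' Component totals are `sum_k occ_eff(k, s) * C[component](k, s) * df(k)`;
#' the grand total equals the sum of components (checked to 1e-9).
#'
#' @param trace A `cohort_trace`.
#' @param cost_matrices Named list (one per component) of `H x S` per-cycle,
#'   per-state cost matrices, or length-`S` vectors recycled over cycles.
#' @param settings A [model_settings()].
#' @return List with `total`, `by_component`, `by_state`, and the full
#'   `component_state` matrix.
#' @export
accumulate_costs <- function(trace, cost_matrices, settings) {
  occ <- half_cycle_effective_occupancy(trace, settings$half_cycle)
  H <- nrow(occ); S <- ncol(occ)
  df <- discount_factor(seq_len(H) - 1L, settings$discount)
  comp_state <- matrix(0, length(cost_matrices), S,
                       dimnames = list(names(cost_matrices), colnames(trace)))
  for (nm in names(cost_matrices)) {
    C <- cost_matrices[[nm]]
    if (is.null(dim(C))) {
      if (length(C) != S) stop("cost vector length does not match state space")
      C <- matrix(C, H, S, byrow = TRUE)
    }
    if (!all(dim(C) == c(H, S))) {
      stop("cost matrix '", nm, "' does not match trace dimensions")
    }
    comp_state[nm, ] <- colSums(occ * C * df)
  }
  by_component <- rowSums(comp_state)
  by_state <- colSums(comp_state)
  total <- sum(comp_state)
  stopifnot(abs(total - sum(by_component)) < 1e-9)
  list(total = total, by_component = by_component, by_state = by_state,
       component_state = comp_state)
}

#' Accumulate discounted QALYs and life-years
#'
#' `QALY = sum_k sum_s occ_eff(k, s) * u(s) * df(k) / 12`; life-years use
#' utility 1 for every alive state, so `QALY <= LY`.
#'
#' @param trace A `cohort_trace`.
#' @param utilities Named utility vector over states (values in `[0, 1]`,
#'   death 0).
#' @param settings A [model_settings()].
#' @return List with `qalys` and `life_years`.
#' @export
accumulate_qalys <- function(trace, utilities, settings) {
  states <- colnames(trace)
  if (!all(states %in% names(utilities))) {
    stop("utilities missing for states: ",
         paste(setdiff(states, names(utilities)), collapse = ", "))
  }
  u <- utilities[states]
  if (any(u < 0 | u > 1)) stop("utilities must lie in [0, 1]")
  occ <- half_cycle_effective_occupancy(trace, settings$half_cycle)
  df <- discount_factor(seq_len(nrow(occ)) - 1L, settings$discount)
  alive <- as.numeric(states != "Death")
  list(
    qalys = sum((occ %*% u) * df) / 12,
    life_years = sum((occ %*% alive) * df) / 12
  )
}

#' Incremental cost-effectiveness summary
#'
#' Differences are new-minus-comparator. The ICER is reported only when
#' `dE != 0` and the signs do not indicate dominance; `NMB = dE * wtp - dC`.
#'
#' @param result_new,result_comparator Lists with `cost` and `qalys`.
#' @param wtp Willingness-to-pay per QALY (default US$6831).
#' @return A `ce_comparison`: `delta_cost`, `delta_qalys`, `icer`, `label`
#'   (`"Dominant"`, `"Dominated"`, `"equivalent"`, `"ICER"`), `nmb`,
#'   `cost_effective`.
#' @export
incremental_summary <- function(result_new, result_comparator, wtp = 6831) {
  dC <- result_new$cost - result_comparator$cost
  dE <- result_new$qalys - result_comparator$qalys
  nmb <- dE * wtp - dC
  if (dC < 0 && dE > 0) {
    label <- "Dominant"; icer <- NA_real_; ce <- TRUE
  } else if (dC > 0 && dE < 0) {
    label <- "Dominated"; icer <- NA_real_; ce <- FALSE
  } else if (dE == 0 && dC == 0) {
    label <- "equivalent"; icer <- NA_real_; ce <- NA
  } else if (dE == 0) {
    label <- if (dC < 0) "Dominant" else "Dominated"
    icer <- NA_real_; ce <- dC < 0
  } else {
    icer <- dC / dE
    label <- "ICER"
    ce <- if (dE > 0) icer <= wtp else icer > wtp
  }
  structure(list(delta_cost = dC, delta_qalys = dE, icer = icer,
                 label = label, nmb = nmb, wtp = wtp, cost_effective = ce),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("Incremental cost: %.2f | Incremental QALYs: %.4f\n",
              x$delta_cost, x$delta_qalys))
  if (x$label == "ICER") {
    cat(sprintf("ICER: %.1f per QALY (WTP %.0f)\n", x$icer, x$wtp))
  } else {
    cat(x$label, "\n")
  }
  cat(sprintf("NMB at WTP %.0f: %.2f\n", x$wtp, x$nmb))
  invisible(x)
}
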