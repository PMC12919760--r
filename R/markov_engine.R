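# Monthly-cycle cohort Markov engine: expanded state space with a 12-month
# non-metastatic recurrence tunnel, time-dependent matrices, half-cycle
# correction, and a micro-simulation oracle used in validation.

TUNNEL_MONTHS <- 12L

#' Model state space
#'
#' Base states: residual invasive disease on/off adjuvant treatment, a
#' 12-compartment non-metastatic recurrence tunnel (fixed 12-month sojourn
#' before remission), remission, first-line metastatic (1L mBC), later-line
#' metastatic (2L+ mBC), and absorbing death. No direct transition from the
#' recurrence tunnel to first-line metastatic disease is modeled.
#'
#' @return Character vector of state names with attributes `tunnel`
#'   (indices of tunnel compartments), `disease_free`, and `alive`.
#' @export
state_space <- function() {
  states <- c("ResidualOn", "ResidualOff",
              paste0("NMR", seq_len(TUNNEL_MONTHS)),
              "Remission", "FirstLineMet", "LaterLineMet", "Death")
  attr(states, "tunnel") <- 2L + seq_len(TUNNEL_MONTHS)
  attr(states, "disease_free") <- 1:2
  attr(states, "alive") <- seq_len(length(states) - 1L)
  states
}

#' Build the transition matrix for one cycle
#'
#' Row-stochastic matrix over [state_space()] for 0-based cycle `k`.
#' Disease-free exits (probability `p_exit`) split into locoregional
#' recurrence, metastatic disease and death by `shares`; background
#' mortality `q_bg` is combined independently with every disease risk.
#' Tunnel compartments advance monthly (remission after 12 months if alive)
#' and carry background mortality only. The structural zero
#' NonMetRecurrence -> FirstLineMet holds every cycle.
#'
#' @param k 0-based cycle index.
#' @param p_exit Disease-free exit probability for this cycle.
#' @param q_bg Monthly background mortality for this cycle.
#' @param shares Named vector `c(locoregional=, metastatic=, death=)`
#'   summing to 1.
#' @param p_rem_1l Monthly remission -> 1L mBC probability.
#' @param p_1l_2l Monthly 1L -> 2L+ progression probability.
#' @param p_2l_death Monthly 2L+ disease-specific death probability.
#' @param treat_cycles Number of initial cycles on adjuvant treatment;
#'   residual-state occupants switch to the off-treatment profile after.
#' @return `S x S` row-stochastic matrix.
#' @export
build_transition_matrix <- function(k, p_exit, q_bg, shares, p_rem_1l,
                                    p_1l_2l, p_2l_death,
                                    treat_cycles = 10L) {
  states <- state_space()
  S <- length(states)
  probs <- c(p_exit, q_bg, shares, p_rem_1l, p_1l_2l, p_2l_death)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(shares) - 1) > 1e-9) stop("destination shares must sum to 1")
  M <- matrix(0, S, S, dimnames = list(states, states))
  i <- function(nm) match(nm, states)

  # disease-free rows: background death first, survivors face the disease exit
  df_stay <- (1 - q_bg) * (1 - p_exit)
  df_nmr <- (1 - q_bg) * p_exit * shares[["locoregional"]]
  df_1l <- (1 - q_bg) * p_exit * shares[["metastatic"]]
  df_death <- q_bg + (1 - q_bg) * p_exit * shares[["death"]]
  on_target <- if (k >= treat_cycles - 1L) "ResidualOff" else "ResidualOn"
  M[i("ResidualOn"), i(on_target)] <- df_stay
  M[i("ResidualOn"), i("NMR1")] <- df_nmr
  M[i("ResidualOn"), i("FirstLineMet")] <- df_1l
  M[i("ResidualOn"), i("Death")] <- df_death
  M[i("ResidualOff"), i("ResidualOff")] <- df_stay
  M[i("ResidualOff"), i("NMR1")] <- df_nmr
  M[i("ResidualOff"), i("FirstLineMet")] <- df_1l
  M[i("ResidualOff"), i("Death")] <- df_death

  # recurrence tunnel: advance if alive; background mortality only
  for (j in seq_len(TUNNEL_MONTHS)) {
    from <- i(paste0("NMR", j))
    to <- if (j < TUNNEL_MONTHS) i(paste0("NMR", j + 1L)) else i("Remission")
    M[from, to] <- 1 - q_bg
    M[from, i("Death")] <- q_bg
  }

  M[i("Remission"), i("FirstLineMet")] <- (1 - q_bg) * p_rem_1l
  M[i("Remission"), i("Death")] <- q_bg
  M[i("Remission"), i("Remission")] <- (1 - q_bg) * (1 - p_rem_1l)

  M[i("FirstLineMet"), i("LaterLineMet")] <- (1 - q_bg) * p_1l_2l
  M[i("FirstLineMet"), i("Death")] <- q_bg
  M[i("FirstLineMet"), i("FirstLineMet")] <- (1 - q_bg) * (1 - p_1l_2l)

  d2 <- combine_independent_risks(p_2l_death, q_bg)
  M[i("LaterLineMet"), i("Death")] <- d2
  M[i("LaterLineMet"), i("LaterLineMet")] <- 1 - d2

  M[i("Death"), i("Death")] <- 1
  validate_transition_matrix(M)
}

#' Validate (and minimally renormalize) a transition matrix
#'
#' Rows must sum to 1; an excess of at most `1e-9` is renormalized, anything
#' larger is an error naming the offending state.
#' @param M Square matrix with state dimnames.
#' @return The validated matrix.
#' @export
validate_transition_matrix <- function(M) {
  if (any(M < -1e-15 | M > 1 + 1e-12)) stop("matrix entries outside [0, 1]")
  rs <- rowSums(M)
  off <- abs(rs - 1)
  if (any(off > 1e-9)) {
    bad <- rownames(M)[which.max(off)]
    stop("competing risks in state '", bad, "' sum to ", rs[which.max(off)])
  }
  if (any(off > 0)) M <- M / rs
  M
}

#' Build the per-cycle transition matrix sequence for one arm
#'
#' @param arm_inputs List with vectors `p_exit` (length H) and `q_bg`
#'   (length H), scalars `p_rem_1l`, `p_1l_2l`, `p_2l_death`,
#'   `treat_cycles`, and `shares`.
#' @param H Number of cycles.
#' @return List of `H` matrices (cycle 0 first).
#' @export
build_matrix_sequence <- function(arm_inputs, H = length(arm_inputs$p_exit)) {
  stopifnot(length(arm_inputs$p_exit) >= H, length(arm_inputs$q_bg) >= H)
  lapply(seq_len(H) - 1L, function(k) {
    build_transition_matrix(
      k, arm_inputs$p_exit[k + 1L], arm_inputs$q_bg[k + 1L],
      arm_inputs$shares, arm_inputs$p_rem_1l, arm_inputs$p_1l_2l,
      arm_inputs$p_2l_death, arm_inputs$treat_cycles
    )
  })
}

#' Propagate a cohort through a matrix sequence
#'
#' @param init Initial distribution over states (sums to 1); the base-case
#'   cohort starts fully in `ResidualOn`.
#' @param matrices List of per-cycle transition matrices.
#' @param H Number of cycles to run (default all).
#' @return A `cohort_trace`: `(H+1) x S` occupancy matrix, cycle 0 first.
#' @export
run_cohort <- function(init, matrices, H = length(matrices)) {
  S <- length(init)
  if (abs(sum(init) - 1) > 1e-12) stop("initial distribution must sum to 1")
  if (any(vapply(matrices[seq_len(H)], function(M) !all(dim(M) == S),
                 logical(1)))) {
    stop("dimension mismatch between init and matrices")
  }
  trace <- matrix(0, H + 1L, S)
  colnames(trace) <- colnames(matrices[[1]])
  trace[1, ] <- init
  row <- init
  for (k in seq_len(H)) {
    row <- as.numeric(row %*% matrices[[k]])
    trace[k + 1L, ] <- row
  }
  structure(trace, class = c("cohort_trace", "matrix", "array"))
}

#' Half-cycle-corrected effective occupancy
#'
#' Trapezoidal convention: effective occupancy for cycle `k` is the average
#' of the start- and end-of-cycle rows. With the correction off, start-of-
#' cycle occupancy is used.
#'
#' @param trace A `cohort_trace` (`H+1` rows).
#' @param half_cycle Logical flag.
#' @return `H x S` matrix of effective occupancy (rows still sum to 1).
#' @export
half_cycle_effective_occupancy <- function(trace, half_cycle = TRUE) {
  H <- nrow(trace) - 1L
  if (H < 1L) stop("trace must have at least 2 rows")
  if (half_cycle) {
    (trace[seq_len(H), , drop = FALSE] +
       trace[seq_len(H) + 1L, , drop = FALSE]) / 2
  } else {
    trace[seq_len(H), , drop = FALSE]
  }
}

#' Per-cycle discount factors
#'
#' @param cycles 0-based cycle indices (months).
#' @param annual_rate Annual discount rate, `>= 0`.
#' @return `(1 + r)^(-k/12)`.
#' @export
discount_factor <- function(cycles, annual_rate) {
  if (annual_rate < 0) stop("discount rate must be non-negative")
  (1 + annual_rate)^(-cycles / 12)
}

#' Individual-level micro-simulation oracle
#'
#' Simulates `n` independent individuals through the same matrices and
#' returns the empirical occupancy trace. Used only for validating
#' [run_cohort()] on small instances.
#'
#' @param init Initial distribution.
#' @param matrices Per-cycle transition matrices.
#' @param n Number of individuals.
#' @param seed Integer seed (bit-identical reruns).
#' @return `(H+1) x S` matrix of empirical occupancy proportions.
#' @export
microsim_cohort <- function(init, matrices, n, seed) {
  set.seed(seed)
  S <- length(init)
  H <- length(matrices)
  counts <- as.integer(stats::rmultinom(1, n, init))
  trace <- matrix(0, H + 1L, S)
  colnames(trace) <- colnames(matrices[[1]])
  trace[1, ] <- counts / n
  for (k in seq_len(H)) {
    M <- matrices[[k]]
    newc <- integer(S)
    for (s in which(counts > 0)) {
      newc <- newc + as.integer(stats::rmultinom(1, counts[s], M[s, ]))
    }
    counts <- newc
    trace[k + 1L, ] <- counts / n
  }
  trace
}
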