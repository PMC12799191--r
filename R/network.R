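#' GABA-to-motoneuron pairing by index rule
#'
#' GABAergic interneurons gate excitatory synapses of the TA motoneuron
#' pool through a deterministic spatial index rule: GABA neuron `i` and
#' motoneuron `j` are paired when `|i - j| < window` (indices 1-based on the
#' R side). Under the injury condition the pair count is increased 1.6-fold
#' by widening the window and, if needed, topping up with pairs at the next
#' index distance (sampled deterministically from `seed`) so spatial
#' locality is preserved.
#'
#' @param n_gaba,n_mn population sizes (defaults 196 and 169).
#' @param sci logical; apply the 1.6-fold injury scaling?
#' @param window index window of the baseline rule (default 4).
#' @param seed integer seed for the top-up sampling under `sci`.
#' @return Tibble `(gaba, mn)` of paired indices.
#' @export
#' @examples
#' nrow(gaba_mn_pairs())            # 1177 baseline pairs
#' nrow(gaba_mn_pairs(sci = TRUE))  # round(1.6 * 1177)
gaba_mn_pairs <- function(n_gaba = 196L, n_mn = 169L, sci = FALSE,
                          window = 4L, seed = 1L) {
  pairs_for <- function(w) {
    g <- rep(seq_len(n_gaba), each = n_mn)
    m <- rep(seq_len(n_mn), times = n_gaba)
    keep <- abs(g - m) < w
    tibble(gaba = g[keep], mn = m[keep])
  }
  base <- pairs_for(window)
  if (!sci) return(base)
  target <- round(1.6 * nrow(base))
  w <- window
  while (nrow(pairs_for(w + 1L)) <= target) w <- w + 1L
  wide <- pairs_for(w)
  deficit <- target - nrow(wide)
  if (deficit > 0) {
    ring <- dplyr::anti_join(pairs_for(w + 1L), wide, by = c("gaba", "mn"))
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    wide <- dplyr::bind_rows(wide, ring[sample.int(nrow(ring), deficit), ])
  }
  dplyr::arrange(wide, .data$gaba, .data$mn)
}

# connection plan for the reflex loop (probabilistic groups); II-fibre
# weights carry the 0.33 small-axon scaling
connection_plan <- function() {
  tibble::tribble(
    ~src,      ~tgt,       ~p,   ~g,          ~kind,  ~axonal, ~gated,
    "Ia_TA",   "IaIN_TA",  0.3,  7,           "exc",  TRUE,    FALSE,
    "II_TA",   "IaIN_TA",  0.3,  7 * 0.33,    "exc",  TRUE,    FALSE,
    "Ia_GM",   "IaIN_GM",  0.3,  7,           "exc",  TRUE,    FALSE,
    "II_GM",   "IaIN_GM",  0.3,  7 * 0.33,    "exc",  TRUE,    FALSE,
    "Ia_GM",   "GABA",     0.4,  12,          "exc",  TRUE,    FALSE,
    "Ia_TA",   "V2a",      0.6,  1,           "exc",  TRUE,    FALSE,
    "II_TA",   "V2a",      0.6,  1 * 0.33,    "exc",  TRUE,    FALSE,
    "IaIN_TA", "IaIN_GM",  0.1,  3,           "inh",  FALSE,   FALSE,
    "IaIN_GM", "IaIN_TA",  0.1,  3,           "inh",  FALSE,   FALSE,
    "Ia_TA",   "MN",       0.3,  30,          "exc",  TRUE,    TRUE,
    "V2a",     "MN",       0.3,  30,          "exc",  FALSE,   TRUE,
    "IaIN_GM", "MN",       0.3,  10,          "inh",  FALSE,   FALSE
  )
}

#' Build the synaptic wiring of the reflex loop
#'
#' Samples every probabilistic synapse group (Bernoulli `p_syn` per
#' source-target pair, per the connection-probability table), attaches the
#' deterministic GABA-to-motoneuron index-rule pairs as presynaptic-gate
#' connections, and draws axonal conduction delays (Normal(2, 0.3) ms,
#' truncated at 0.1 ms). The result is reproducible given `seed`.
#'
#' @param specs population table from [population_specs()].
#' @param sci logical; scale GABA-to-MN pairing 1.6-fold (injury state)?
#' @param seed integer seed for Bernoulli sampling and delay draws.
#' @param gaba_quantum GABA-spillover concentration quantum deposited per
#'   gate spike (dimensionless; see the presynaptic-gate model).
#' @return A tibble of connections: `src_pop`, `src_idx`, `tgt_pop`,
#'   `tgt_idx`, `kind` (`exc`/`inh`/`gate`), `g_nS`, `delay_ms`, `gated`.
#' @export
#' @examples
#' w <- wire_network(seed = 1)
#' dplyr::count(w, src_pop, tgt_pop)
wire_network <- function(specs = population_specs(), sci = FALSE, seed = 1L,
                         gaba_quantum = 0.195) {
  sizes <- setNames(specs$N, specs$name)
  plan <- connection_plan()
  if (!all(c(plan$src, plan$tgt, "GABA", "MN") %in% names(sizes))) {
    abort("unknown population label in the connection plan")
  }
  streams <- seed_streams(seed, n = nrow(plan) + 2L)
  groups <- vector("list", nrow(plan) + 1L)
  for (i in seq_len(nrow(plan))) {
    pl <- plan[i, ]
    ns <- sizes[[pl$src]]; nt <- sizes[[pl$tgt]]
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(streams[i])
    keep <- runif(ns * nt) < pl$p
    src_idx <- rep(seq_len(ns), times = nt)[keep]
    tgt_idx <- rep(seq_len(nt), each = ns)[keep]
    m <- length(src_idx)
    delay <- if (pl$axonal) pmax(0.1, rnorm(m, 2, 0.3)) else rep(DT_MS, m)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    groups[[i]] <- tibble(
      src_pop = pl$src, src_idx = src_idx, tgt_pop = pl$tgt,
      tgt_idx = tgt_idx, kind = pl$kind, g_nS = pl$g, delay_ms = delay,
      gated = pl$gated
    )
  }
  gp <- gaba_mn_pairs(sizes[["GABA"]], sizes[["MN"]], sci = sci,
                      seed = streams[nrow(plan) + 1L])
  groups[[nrow(plan) + 1L]] <- tibble(
    src_pop = "GABA", src_idx = gp$gaba, tgt_pop = "MN", tgt_idx = gp$mn,
    kind = "gate", g_nS = gaba_quantum, delay_ms = DT_MS, gated = FALSE
  )
  out <- dplyr::bind_rows(groups)
  attr(out, "sci") <- sci
  attr(out, "seed") <- seed
  class(out) <- c("network_wiring", class(out))
  out
}

# map a wiring tibble onto global ids for the compiled core
edges_to_gids <- function(wiring, params) {
  base <- params %>% group_by(.data$population) %>%
    summarise(gid0 = min(.data$gid), .groups = "drop")
  b <- setNames(base$gid0, base$population)
  kind_code <- c(exc = 0L, inh = 1L, gate = 2L)
  tibble(
    src_gid = b[wiring$src_pop] + wiring$src_idx - 1L,
    tgt_gid = b[wiring$tgt_pop] + wiring$tgt_idx - 1L,
    w = wiring$g_nS,
    kind = kind_code[wiring$kind],
    delay_steps = ms_delay_steps(wiring$delay_ms),
    gated = as.integer(wiring$gated)
  )
}

#' Closed-form steady state of the presynaptic release factor
#'
#' The release factor relaxes toward `clamp(1 - lambda * C_GABA, 0, 1)`
#' with time constant `tau_gamma`; under a sustained spillover
#' concentration the steady state is that clamped target.
#'
#' @param C_GABA sustained local GABA concentration (unitless).
#' @param lambda inhibition strength (default 0.4).
#' @return Steady-state release factor in \[0, 1\].
#' @export
#' @examples
#' gate_steady_state(1)    # 0.6
#' gate_steady_state(2.5)  # fully suppressed
gate_steady_state <- function(C_GABA, lambda = 0.4) {
  pmin(pmax(1 - lambda * C_GABA, 0), 1)
}

#' Integrate the presynaptic gate against a GABA spike train
#'
#' Reference integrator for the spillover gate: each incoming spike adds
#' `quantum` to the local concentration `C_GABA`, which decays with
#' `tau_gamma`; the release factor `gamma` relaxes toward
#' `clamp(1 - lambda * C_GABA, 0, 1)` with the same time constant.
#'
#' @param spike_times incoming gate spike times (s).
#' @param T total duration (s).
#' @param quantum concentration added per spike.
#' @param lambda inhibition strength.
#' @param tau_gamma gate time constant (ms).
#' @param dt_ms integration step (ms).
#' @return Tibble `(t, C_GABA, gamma)` sampled at `dt_ms`.
#' @export
update_gate <- function(spike_times, T, quantum = 0.03, lambda = 0.4,
                        tau_gamma = 20, dt_ms = DT_MS) {
  nst <- as.integer(round(T * 1e3 / dt_ms))
  Cg <- numeric(nst); gam <- numeric(nst)
  cg <- 0; g <- 1
  dec <- exp(-dt_ms / tau_gamma)
  sp_steps <- floor(spike_times * 1e3 / dt_ms) + 1
  adds <- tabulate(sp_steps[sp_steps >= 1 & sp_steps <= nst], nbins = nst)
  for (k in seq_len(nst)) {
    cg <- cg + adds[k] * quantum
    g <- g + dt_ms / tau_gamma * (gate_steady_state(cg, lambda) - g)
    cg <- cg * dec
    Cg[k] <- cg; gam[k] <- g
  }
  tibble(t = seq_len(nst) * dt_ms * 1e-3, C_GABA = Cg, gamma = gam)
}
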