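# Internal bridge between tidy network tables and the compiled integrator.

# synapse kinetics shared across the network (ms, mV)
SYN_PAR <- list(tau_exc = 0.25, tau_inh_rise = 2, tau_inh_decay = 4.5,
                E_exc = 0, E_inh = -75)

empty_edges <- function() {
  tibble(src_gid = integer(), tgt_gid = integer(), w = numeric(),
         kind = integer(), delay_steps = integer(), gated = integer())
}

# edges: tibble with 0-based src_gid/tgt_gid, w (nS or spillover quantum),
# kind (0 exc / 1 inh / 2 gate), delay_steps (>= 1), gated (0/1)
run_core <- function(params, edges, T_ms, dt_ms = DT_MS,
                     drive = NULL, es = NULL, inj = NULL,
                     gate = list(lambda = the_gate$lambda, tau_gamma = 20),
                     record_v = integer(), record_gamma = integer(),
                     record_every_ms = 0, seeds = c(1L, 2L, 3L),
                     no_spike = NULL) {
  n <- nrow(params)
  nospk <- integer(n)
  if (!is.null(no_spike)) nospk[no_spike + 1L] <- 1L

  neurons <- list(
    kind = as.integer(params$kind), C = params$C, gL = params$gL,
    EL = params$EL, Vth = params$Vth, Vreset = params$Vreset,
    DeltaV = params$DeltaV, a = params$a, tauw = params$tauw, b = params$b,
    tref = params$tref, Vcut = params$Vcut, noise_sd = params$noise_sd,
    no_spike = nospk,
    tau_exc = SYN_PAR$tau_exc, tau_inh_rise = SYN_PAR$tau_inh_rise,
    tau_inh_decay = SYN_PAR$tau_inh_decay,
    E_exc = SYN_PAR$E_exc, E_inh = SYN_PAR$E_inh
  )

  ord <- order(edges$src_gid)
  edges <- edges[ord, , drop = FALSE]
  eptr <- c(0L, cumsum(tabulate(edges$src_gid + 1L, nbins = n)))
  edge_list <- list(eptr = as.integer(eptr), tgt = as.integer(edges$tgt_gid),
                    w = as.numeric(edges$w), kind = as.integer(edges$kind),
                    delay_steps = as.integer(edges$delay_steps),
                    gated = as.integer(edges$gated))

  if (is.null(drive)) {
    drive <- list(gids = integer(), rates = matrix(0, 1, 0), fs = GAIT_FS,
                  g = numeric())
  }
  drive$gids <- as.integer(drive$gids)
  if (is.null(es)) {
    es <- list(gids = integer(), src = integer(), n_src = 0L, freq = 0,
               I_amp = numeric(), pw_steps = 0L)
  }
  es$gids <- as.integer(es$gids); es$src <- as.integer(es$src)
  es$n_src <- as.integer(es$n_src); es$pw_steps <- as.integer(es$pw_steps)

  if (is.null(inj)) inj <- matrix(0, 0, 4)
  inj <- as.matrix(inj)

  every <- if (record_every_ms > 0) as.integer(round(record_every_ms / dt_ms)) else 0L
  rec <- list(v_gids = as.integer(record_v), g_gids = as.integer(record_gamma),
              every = every)

  cpp_simulate(neurons, edge_list, drive, es, inj, gate, rec,
               T_ms, dt_ms,
               as.integer(seeds[1]), as.integer(seeds[2]), as.integer(seeds[3]))
}

# convert a core result to a tidy spike raster keyed by population/neuron
core_raster <- function(res, params) {
  gid <- res$spike_gid
  out <- tibble(
    population = params$population[gid + 1L],
    neuron = params$neuron[gid + 1L],
    t = res$spike_t * 1e-3
  )
  counts <- params %>% dplyr::count(.data$population, name = "N")
  attr(out, "pop_sizes") <- setNames(counts$N, counts$population)
  class(out) <- c("spike_raster", class(out))
  out
}

ms_delay_steps <- function(delay_ms, dt_ms = DT_MS) {
  pmax(1L, as.integer(round(delay_ms / dt_ms)))
}
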