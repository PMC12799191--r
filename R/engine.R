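#' Condition configuration for a locomotor simulation
#'
#' The seven named study conditions toggle four mechanisms on top of the
#' common reflex-loop network:
#' \describe{
#'   \item{sci}{spinal cord injury: GABA-to-MN gate pairing scaled 1.6-fold.}
#'   \item{bws}{body-weight support: afferent EMG-envelope gains
#'     `K_GM = -0.6`, `K_TA = -0.122` (all `BWS_*` conditions also carry the
#'     injury wiring; support is modelled on the injured cord).}
#'   \item{es}{epidural-style electrical stimulation: Poisson pulse sources
#'     (40 Hz, 10 mV, 0.2 ms) on all afferent fibres.}
#'   \item{serotonin}{5-HT agonism surrogate: MN and V2a leak conductance
#'     reduced by 40% (SCI conditions) or 15% (BWS conditions).}
#' }
#'
#' @param name one of `"Baseline"`, `"SCI"`, `"SCI_5HT"`, `"SCI_5HT_ES"`,
#'   `"BWS_ES"`, `"BWS_5HT"`, `"BWS_5HT_ES"`, or `"custom"` to set flags
#'   directly.
#' @param sci,bws,es condition flags (used when `name = "custom"`).
#' @param serotonin leak-conductance reduction fraction in `[0, 1)`.
#' @param n_steps number of analysed gait cycles (default 8).
#' @param settle_steps gait cycles simulated and discarded before the
#'   analysed window (default 1). The network starts from rest with the
#'   release factor at 1, so the first cycle carries an
#'   initialisation transient; one settling cycle lets the spillover gate
#'   and adaptation currents reach their condition-specific regime.
#' @param cycle_duration gait-cycle duration (s).
#' @param stance_fraction stance/swing split (default 0.65).
#' @param es_protocol an [es_protocol()] list.
#' @param gaba_quantum spillover quantum per gate spike.
#' @param stretch_amp named vector `c(TA = , GM = )` of peak spindle
#'   stretches for the synthetic gait (`NULL` for the muscle defaults).
#' @return A `condition_config` list.
#' @export
#' @examples
#' condition_config("SCI")
condition_config <- function(name = "Baseline", sci = FALSE, bws = FALSE,
                             es = FALSE, serotonin = 0, n_steps = 8L,
                             settle_steps = 1L,
                             cycle_duration = 0.7, stance_fraction = 0.65,
                             es_protocol = NULL, gaba_quantum = 0.195,
                             stretch_amp = NULL) {
  presets <- list(
    Baseline    = list(sci = FALSE, bws = FALSE, es = FALSE, serotonin = 0),
    SCI         = list(sci = TRUE,  bws = FALSE, es = FALSE, serotonin = 0),
    SCI_5HT     = list(sci = TRUE,  bws = FALSE, es = FALSE, serotonin = 0.40),
    SCI_5HT_ES  = list(sci = TRUE,  bws = FALSE, es = TRUE,  serotonin = 0.40),
    BWS_ES      = list(sci = TRUE,  bws = TRUE,  es = TRUE,  serotonin = 0),
    BWS_5HT     = list(sci = TRUE,  bws = TRUE,  es = FALSE, serotonin = 0.15),
    BWS_5HT_ES  = list(sci = TRUE,  bws = TRUE,  es = TRUE,  serotonin = 0.15)
  )
  if (name != "custom") {
    if (!name %in% names(presets)) {
      abort(sprintf("unknown condition `%s`", name))
    }
    p <- presets[[name]]
    sci <- p$sci; bws <- p$bws; es <- p$es; serotonin <- p$serotonin
  }
  if (serotonin < 0 || serotonin >= 1) abort("`serotonin` must lie in [0, 1)")
  if (serotonin == 0.40 && (!sci || bws)) {
    abort("a 40% serotonin reduction is defined only for SCI (non-BWS) conditions")
  }
  if (serotonin == 0.15 && !bws) {
    abort("a 15% serotonin reduction is defined only for BWS conditions")
  }
  stopifnot_scalar(n_steps, "n_steps")
  stopifnot_scalar(cycle_duration, "cycle_duration")
  if (is.null(stretch_amp)) stretch_amp <- c(TA = 9, GM = 0.5)
  if (is.null(names(stretch_amp))) {
    stretch_amp <- setNames(rep_len(stretch_amp, 2), c("TA", "GM"))
  }
  cfg <- list(name = name, sci = sci, bws = bws, es = es,
              serotonin = serotonin, n_steps = as.integer(n_steps),
              settle_steps = as.integer(settle_steps),
              cycle_duration = cycle_duration,
              stance_fraction = stance_fraction,
              es_protocol = es_protocol %||% es_protocol(),
              gaba_quantum = gaba_quantum, stretch_amp = stretch_amp,
              dt_ms = DT_MS)
  class(cfg) <- "condition_config"
  cfg
}

#' @export
print.condition_config <- function(x, ...) {
  cat("<condition_config>", x$name, "\n",
      sprintf(" sci=%s bws=%s es=%s serotonin=%.2f | %d steps x %.2f s\n",
              x$sci, x$bws, x$es, x$serotonin, x$n_steps, x$cycle_duration))
  invisible(x)
}

#' Run one full locomotor simulation
#'
#' Builds the synthetic gait profiles for both muscles, converts them to
#' Ia/II afferent rates (with body-weight-support scaling when configured),
#' wires the network (with injury scaling when configured), applies
#' serotonergic and electrical-stimulation modulation, and integrates the
#' whole loop with forward Euler at 50 us. Wiring, membrane noise, afferent
#' Poisson streams and stimulation streams draw from disjoint substreams of
#' `seed`, so every component is independently reproducible.
#'
#' @param cfg a [condition_config()].
#' @param seed master integer seed.
#' @param record_gamma logical; record the motoneuron release factor
#'   (1 kHz decimation)?
#' @param record_v optional character vector of population names whose mean
#'   membrane potential trace should be recorded (1 kHz decimation).
#' @return An `snn_run` list: `raster` (spike raster tibble), `cfg`, `seed`,
#'   `profiles`, and optional traces.
#' @export
#' @examples
#' \donttest{
#' run <- run_condition(condition_config("Baseline", n_steps = 1), seed = 1)
#' dplyr::count(run$raster, population)
#' }
run_condition <- function(cfg, seed, record_gamma = FALSE, record_v = NULL) {
  stopifnot(inherits(cfg, "condition_config"))
  streams <- seed_streams(seed, n = 8L)
  # gait + afferent rates -------------------------------------------------
  K <- apply_bws(cfg$bws)
  n_sim <- cfg$n_steps + cfg$settle_steps
  prof <- list(
    TA = make_synthetic_gait("TA", n_sim, cfg$cycle_duration,
                             seed = streams[1], stance_fraction = cfg$stance_fraction,
                             stretch_amp = cfg$stretch_amp[["TA"]]),
    GM = make_synthetic_gait("GM", n_sim, cfg$cycle_duration,
                             seed = streams[2], stance_fraction = cfg$stance_fraction,
                             stretch_amp = cfg$stretch_amp[["GM"]])
  )
  rates <- list(
    Ia_TA = ia_rate(prof$TA, K$K_TA), II_TA = ii_rate(prof$TA, K$K_TA),
    Ia_GM = ia_rate(prof$GM, K$K_GM), II_GM = ii_rate(prof$GM, K$K_GM)
  )
  # populations + neuromodulation -----------------------------------------
  specs <- population_specs()
  if (cfg$serotonin > 0) {
    specs <- apply_serotonin(specs, serotonin_config(cfg$serotonin))
  }
  params <- expand_neurons(specs, seed = streams[3])
  wiring <- wire_network(specs, sci = cfg$sci, seed = streams[4],
                         gaba_quantum = cfg$gaba_quantum)
  edges <- edges_to_gids(wiring, params)
  # afferent drive ---------------------------------------------------------
  ax_pops <- c("Ia_TA", "II_TA", "Ia_GM", "II_GM")
  dr <- params %>% filter(.data$population %in% ax_pops)
  rmat <- do.call(cbind, lapply(seq_len(nrow(dr)), function(i) {
    rates[[dr$population[i]]]$rate
  }))
  drive <- list(gids = dr$gid, rates = rmat, fs = GAIT_FS,
                g = rep(500, nrow(dr)))
  # electrical stimulation --------------------------------------------------
  es <- NULL
  if (cfg$es) es <- build_es(cfg$es_protocol, params)
  # record ------------------------------------------------------------------
  rec_g <- integer(); rec_vg <- integer()
  if (record_gamma) rec_g <- params$gid[params$population == "MN"]
  if (!is.null(record_v)) rec_vg <- params$gid[params$population %in% record_v]
  every <- if (record_gamma || !is.null(record_v)) 1 else 0
  T_ms <- n_sim * cfg$cycle_duration * 1e3
  res <- run_core(params, edges, T_ms = T_ms, drive = drive, es = es,
                  record_v = rec_vg, record_gamma = rec_g,
                  record_every_ms = every,
                  seeds = streams[5:7])
  t_drop <- cfg$settle_steps * cfg$cycle_duration
  raster <- core_raster(res, params)
  sizes <- attr(raster, "pop_sizes")
  raster <- raster[raster$t >= t_drop, , drop = FALSE]
  # clamp float overhang at the window edges
  raster$t <- pmin(pmax(raster$t - t_drop, 0),
                   cfg$n_steps * cfg$cycle_duration)
  attr(raster, "pop_sizes") <- sizes
  class(raster) <- c("spike_raster", class(raster))
  prof <- lapply(prof, function(p) {
    at <- attributes(p)
    p <- p[p$t >= t_drop, , drop = FALSE]
    p$t <- p$t - t_drop
    for (a in c("muscle", "cycle_duration", "stance_fraction", "fs")) {
      attr(p, a) <- at[[a]]
    }
    class(p) <- c("gait_profile", class(p))
    p
  })
  out <- list(raster = raster, cfg = cfg, seed = seed,
              profiles = prof, wiring_seed = streams[4])
  if (record_gamma) {
    keep <- res$t_rec * 1e-3 >= t_drop
    out$gamma <- tibble(t = res$t_rec[keep] * 1e-3 - t_drop,
                        gamma = rowMeans(res$gamma[keep, , drop = FALSE]))
  }
  if (!is.null(record_v)) {
    keep <- res$t_rec * 1e-3 >= t_drop
    out$v_trace <- tibble(t = res$t_rec[keep] * 1e-3 - t_drop,
                          V = rowMeans(res$V[keep, , drop = FALSE]))
  }
  class(out) <- "snn_run"
  out
}

#' @export
print.snn_run <- function(x, ...) {
  cat("<snn_run>", x$cfg$name, "seed", x$seed, "-",
      nrow(x$raster), "spikes\n")
  invisible(x)
}

#' Run a bank of independent seeds for one condition
#'
#' @param cfg a [condition_config()].
#' @param seeds distinct integer seeds (the study protocol uses 32).
#' @return List of `snn_run` results, one per seed.
#' @export
run_seed_bank <- function(cfg, seeds) {
  if (anyDuplicated(seeds)) abort("`seeds` must be distinct")
  lapply(seeds, function(s) run_condition(cfg, s))
}

#' Mean population firing rate of a run
#'
#' Seed-level summary used throughout the analyses: spikes per neuron per
#' second over the whole run (or per gait phase).
#'
#' @param run an `snn_run`.
#' @param population population name (default `"MN"`).
#' @return Mean rate (Hz).
#' @export
mean_rate <- function(run, population = "MN") {
  N <- attr(run$raster, "pop_sizes")[[population]]
  T <- run$cfg$n_steps * run$cfg$cycle_duration
  sum(run$raster$population == population) / (N * T)
}
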