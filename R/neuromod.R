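#' Epidural-style electrical stimulation protocol
#'
#' Subthreshold stimulation is modelled as independent Poisson pulse
#' sources, each driving three non-overlapping afferent fibres, applied
#' across all flexor and extensor afferents. Each event delivers a
#' rectangular depolarising pulse of the stated width whose current
#' amplitude is calibrated per axon to produce the stated membrane
#' deflection (`I = C_eff * amplitude / pulse_width`, so a 10 mV pulse
#' depolarises the fibre by ~10 mV; with the axon's 30 ms membrane time
#' constant leak losses over 0.2 ms are negligible).
#'
#' @param frequency pulse rate per source (Hz; default 40).
#' @param amplitude_mV membrane deflection per pulse (default 10).
#' @param pulse_width_ms pulse width (default 0.2).
#' @param fanout fibres per source (default 3, non-overlapping).
#' @return An `es_protocol` list.
#' @export
#' @examples
#' es_protocol(frequency = 40)
es_protocol <- function(frequency = 40, amplitude_mV = 10,
                        pulse_width_ms = 0.2, fanout = 3L) {
  stopifnot_scalar(frequency, "frequency", positive = FALSE)
  if (frequency < 0) abort("`frequency` must be >= 0")
  stopifnot_scalar(amplitude_mV, "amplitude_mV")
  stopifnot_scalar(pulse_width_ms, "pulse_width_ms")
  structure(list(frequency = frequency, amplitude_mV = amplitude_mV,
                 pulse_width_ms = pulse_width_ms, fanout = as.integer(fanout)),
            class = "es_protocol")
}

# assign ES sources (exact partition into groups of `fanout`) and per-axon
# pulse currents for the compiled core
build_es <- function(protocol, params) {
  ax <- params %>%
    filter(.data$population %in% c("Ia_TA", "II_TA", "Ia_GM", "II_GM"))
  n <- nrow(ax)
  src <- (seq_len(n) - 1L) %/% protocol$fanout
  I_amp <- ax$C * protocol$amplitude_mV / protocol$pulse_width_ms  # pA
  list(gids = ax$gid, src = src, n_src = max(src) + 1L,
       freq = protocol$frequency, I_amp = I_amp,
       pw_steps = max(1L, as.integer(round(protocol$pulse_width_ms / DT_MS))))
}

#' Serotonergic modulation configuration
#'
#' The net excitability increase produced by 5-HT agonists is modelled as a
#' single-parameter surrogate: a fractional reduction of the leak
#' conductance of motoneurons and V2a interneurons (0.40 under SCI
#' conditions, 0.15 under body-weight-support conditions).
#'
#' @param reduction fraction in `[0, 1)`.
#' @return A `serotonin_config` list.
#' @export
serotonin_config <- function(reduction) {
  if (!is.numeric(reduction) || length(reduction) != 1L ||
      reduction < 0 || reduction >= 1) {
    abort("`reduction` must lie in [0, 1)")
  }
  structure(list(gL_reduction_MN_V2a = reduction), class = "serotonin_config")
}

#' Apply the serotonergic leak-conductance surrogate
#'
#' Multiplies the MN and V2a leak conductances by `1 - reduction`; all
#' other parameters are untouched. Applying a zero reduction returns the
#' specs unchanged.
#'
#' @param specs population table from [population_specs()].
#' @param cfg a [serotonin_config()].
#' @return The modified population table.
#' @export
#' @examples
#' sp <- apply_serotonin(population_specs(), serotonin_config(0.4))
#' sp$gL[sp$name == "V2a"]  # 0.72 nS
apply_serotonin <- function(specs, cfg) {
  stopifnot(inherits(cfg, "serotonin_config"))
  if (isTRUE(attr(specs, "serotonin_applied"))) {
    abort("serotonin modulation has already been applied to these specs")
  }
  idx <- specs$name %in% c("MN", "V2a")
  specs$gL[idx] <- specs$gL[idx] * (1 - cfg$gL_reduction_MN_V2a)
  if (cfg$gL_reduction_MN_V2a > 0) attr(specs, "serotonin_applied") <- TRUE
  specs
}

#' Photostimulation protocol for the presynaptic-inhibition validation
#'
#' Conditioning of the motoneuron EPSP by GABA interneuron activation:
#' a train of threshold current pulses is injected into the GABA population
#' (pulse width 1 ms, 50 Hz, 15 pulses), beginning `lead_delay_ms` before a
#' single afferent test volley at 1.1x the afferent threshold.
#'
#' @param n_pulses,pulse_width_ms,frequency,lead_delay_ms train parameters.
#' @param test_rel_amplitude afferent test amplitude relative to threshold.
#' @return A `photostim_protocol` list.
#' @export
photostim_protocol <- function(n_pulses = 15L, pulse_width_ms = 1,
                               frequency = 50, lead_delay_ms = 45,
                               test_rel_amplitude = 1.1) {
  structure(list(n_pulses = as.integer(n_pulses),
                 pulse_width_ms = pulse_width_ms, frequency = frequency,
                 lead_delay_ms = lead_delay_ms,
                 test_rel_amplitude = test_rel_amplitude),
            class = "photostim_protocol")
}

# static network for evoked-potential protocols: full wiring, no gait
# drive, MN spiking disabled so EPSP peaks are measurable
photostim_once <- function(protocol, seed, gaba_quantum = 0.195,
                           conditioned = TRUE, gaba_pulse_scale = 1.05,
                           sci = FALSE) {
  streams <- seed_streams(seed, 6L)
  specs <- population_specs()
  params <- expand_neurons(specs, seed = streams[1])
  wiring <- wire_network(specs, sci = sci, seed = streams[2],
                         gaba_quantum = gaba_quantum)
  edges <- edges_to_gids(wiring, params)
  mn <- params$gid[params$population == "MN"]
  gaba <- params$gid[params$population == "GABA"]
  ia_ta <- params$gid[params$population == "Ia_TA"]

  gaba_spec <- specs[specs$name == "GABA", ]
  I_gaba <- gaba_pulse_scale * rheobase(gaba_spec, pulse_ms = 1, tol = 5)

  # afferent test volley: brief pulse to all TA Ia axons at rel * threshold;
  # the axon threshold for a 1 ms pulse is found per axon class by bisection
  ax_spec <- tibble(name = "Ia_ax", kind = "cond_LIF", N = 1L,
                    C = axon_geometry()$C_Ia, gL = axon_geometry()$gL_Ia,
                    EL = -80, Vth = -60, Vreset = -70, DeltaV = NA,
                    a = NA, tauw = NA, b = 0, tref = 1.6, noise_sd = 0)
  I_thr <- rheobase(ax_spec, pulse_ms = 1, tol = 2, hi = 3e4)
  I_test <- protocol$test_rel_amplitude * I_thr

  t_train0 <- 20
  t_test <- t_train0 + protocol$lead_delay_ms
  T_ms <- t_test + 60

  inj <- matrix(numeric(0), ncol = 4)
  if (conditioned) {
    onsets <- t_train0 + (seq_len(protocol$n_pulses) - 1) * 1e3 / protocol$frequency
    onsets <- onsets[onsets < T_ms]
    inj <- rbind(inj, cbind(rep(gaba, each = length(onsets)),
                            rep(onsets, length(gaba)),
                            rep(onsets + protocol$pulse_width_ms, length(gaba)),
                            I_gaba))
  }
  inj <- rbind(inj, cbind(ia_ta, t_test, t_test + 1, I_test))

  res <- run_core(params, edges, T_ms = T_ms, inj = inj, record_v = mn,
                  record_every_ms = 0.1, seeds = streams[3:5],
                  no_spike = mn)
  v <- rowMeans(res$V)
  tt <- res$t_rec
  rest <- v[max(which(tt < t_test))]
  win <- tt >= t_test & tt <= t_test + 25
  max(v[win]) - rest
}

#' Conditioned/control EPSP peak ratio under GABA photostimulation
#'
#' Runs the photostimulation protocol twice per seed - an afferent test
#' volley alone (control) and the same volley preceded by the GABA
#' conditioning train - with motoneuron spiking disabled, and returns the
#' mean over seeds of peak-EPSP(conditioned) / peak-EPSP(control). Ratios
#' below 1 quantify presynaptic inhibition of the afferent-to-motoneuron
#' synapse.
#'
#' @param protocol a [photostim_protocol()].
#' @param seeds integer seeds (>= 8 recommended).
#' @param gaba_quantum spillover quantum per gate spike.
#' @param lambda gate inhibition strength (0 disables the gate).
#' @return List with `ratio` (mean), `per_seed` tibble, and the protocol.
#' @export
photostim_epsp_ratio <- function(protocol = photostim_protocol(),
                                 seeds = 1:8, gaba_quantum = 0.195,
                                 lambda = 0.4) {
  per <- purrr::map_dfr(seeds, function(s) {
    ctl <- with_gate_lambda(lambda, photostim_once(protocol, s, gaba_quantum,
                                                   conditioned = FALSE))
    cnd <- with_gate_lambda(lambda, photostim_once(protocol, s, gaba_quantum,
                                                   conditioned = TRUE))
    if (ctl <= 0) abort("zero control EPSP: threshold calibration failed")
    tibble(seed = s, control = ctl, conditioned = cnd, ratio = cnd / ctl)
  })
  list(ratio = mean(per$ratio), per_seed = per, protocol = protocol)
}

# gate lambda is a package-level option threaded into run_core via this
# helper (the compiled core takes it as a parameter)
the_gate <- new.env(parent = emptyenv())
the_gate$lambda <- 0.4

with_gate_lambda <- function(lambda, expr) {
  old <- the_gate$lambda
  the_gate$lambda <- lambda
  on.exit(the_gate$lambda <- old)
  force(expr)
}

#' Synthetic recruitment thresholds for the evoked-response protocol
#'
#' Monotone logistic threshold distributions per fibre class standing in
#' for finite-element recruitment data (synthetic by construction): Ia
#' fibres are recruited at the lowest stimulus amplitudes, II fibres next,
#' and motoneurons (direct efferent recruitment) last.
#'
#' @param seed integer seed.
#' @param amplitudes stimulus amplitudes of the sweep (uA).
#' @return Tibble `(population, neuron, threshold_uA)`.
#' @export
recruitment_thresholds <- function(seed = 1L,
                                   amplitudes = seq(20, 600, by = 20)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  specs <- population_specs()
  qlogis_thr <- function(n, centre, scale) {
    q <- stats::qlogis(stats::ppoints(n))
    sample(pmin(pmax(centre + scale * q, 30), 650))
  }
  dplyr::bind_rows(
    tibble(population = "Ia_TA", neuron = 1:60,
           threshold_uA = qlogis_thr(60, 120, 30)),
    tibble(population = "Ia_GM", neuron = 1:60,
           threshold_uA = qlogis_thr(60, 120, 30)),
    tibble(population = "II_TA", neuron = 1:60,
           threshold_uA = qlogis_thr(60, 220, 40)),
    tibble(population = "II_GM", neuron = 1:60,
           threshold_uA = qlogis_thr(60, 220, 40)),
    tibble(population = "MN", neuron = 1:169,
           threshold_uA = qlogis_thr(169, 420, 60))
  )
}

#' Motor-evoked-potential recruitment sweep
#'
#' For each stimulus amplitude, all fibres (and directly recruited
#' motoneurons) whose recruitment threshold does not exceed the amplitude
#' receive a synchronous volley; the evoked network response is simulated
#' and converted to a synthetic EMG trace, segmented into early (ER),
#' middle (MR) and late (LR) response windows at 1, 4 and 7 ms latency.
#'
#' @param thresholds recruitment table from [recruitment_thresholds()].
#' @param amplitudes stimulus amplitudes (uA), ascending.
#' @param seed integer seed.
#' @param window_ms response-window width (ms).
#' @return List with `traces` (tibble: amplitude_uA, t_ms, emg) and
#'   `windows` (tibble: amplitude_uA, er, mr, lr peak amplitudes).
#' @export
recruitment_sweep <- function(thresholds = recruitment_thresholds(),
                              amplitudes = seq(20, 600, by = 40),
                              seed = 1L, window_ms = 3) {
  if (length(amplitudes) == 0) abort("`amplitudes` must be non-empty")
  amplitudes <- sort(amplitudes)
  streams <- seed_streams(seed, 4L)
  specs <- population_specs()
  params <- expand_neurons(specs, seed = streams[1])
  wiring <- wire_network(specs, sci = FALSE, seed = streams[2])
  edges <- edges_to_gids(wiring, params)
  key <- paste(params$population, params$neuron)
  thr <- setNames(thresholds$threshold_uA,
                  paste(thresholds$population, thresholds$neuron))
  thr_full <- thr[key]

  out_tr <- list(); out_w <- list()
  for (Aix in seq_along(amplitudes)) {
    A <- amplitudes[Aix]
    recruited <- params$gid[!is.na(thr_full) & thr_full <= A]
    T_ms <- 30
    inj <- if (length(recruited)) {
      cbind(recruited, 1, 1.5, 3e4)  # strong 0.5 ms volley at t = 1 ms
    } else matrix(numeric(0), ncol = 4)
    res <- run_core(params, edges, T_ms = T_ms, inj = inj,
                    seeds = c(streams[3], streams[4], streams[1]))
    mn_mask <- res$spike_gid %in% params$gid[params$population == "MN"]
    mn_raster <- tibble(population = "MN",
                        neuron = res$spike_gid[mn_mask],
                        t = res$spike_t[mn_mask] * 1e-3)
    class(mn_raster) <- c("spike_raster", class(mn_raster))
    attr(mn_raster, "pop_sizes") <- c(MN = sum(params$population == "MN"))
    emg <- synth_emg(mn_raster, seed = streams[1] + Aix, T = T_ms * 1e-3)
    emg$t_ms <- emg$t * 1e3 - 1  # latency relative to the volley
    win_peak <- function(lat) {
      w <- emg$t_ms >= lat & emg$t_ms < lat + window_ms
      if (!any(w)) 0 else max(abs(emg$emg[w]))
    }
    out_tr[[Aix]] <- tibble(amplitude_uA = A, t_ms = emg$t_ms, emg = emg$emg)
    out_w[[Aix]] <- tibble(amplitude_uA = A, er = win_peak(1),
                           mr = win_peak(4), lr = win_peak(7),
                           n_recruited = length(recruited))
  }
  list(traces = dplyr::bind_rows(out_tr), windows = dplyr::bind_rows(out_w))
}
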