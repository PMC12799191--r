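#' Synthetic gait profile for one muscle
#'
#' Generates a periodic kinematic/EMG profile emulating treadmill locomotion
#' for the tibialis anterior (TA, ankle flexor) or gastrocnemius medialis
#' (GM, ankle extensor), sampled at 200 Hz. The cycle is split into stance
#' (first `stance_fraction` of the cycle) and swing. The EMG envelope is a
#' plateau-clipped raised-cosine burst placed in the muscle's active phase
#' (GM in stance, TA in swing) and min-max normalised to \[0, 1\]; spindle
#' stretch is a smooth raised-cosine bump, on an optional tonic offset, in
#' anti-phase with the muscle's own envelope (a muscle is stretched while
#' its antagonist is active). Stretch velocity is the analytic derivative
#' of the stretch waveform. Small cycle-to-cycle amplitude variability is
#' drawn deterministically from `seed`.
#'
#' @param muscle `"TA"` or `"GM"`.
#' @param n_steps number of gait cycles (>= 1).
#' @param cycle_duration cycle duration in seconds (0.5-0.9 s is the
#'   physiological band for rodent treadmill stepping; default 0.7 s).
#' @param seed integer seed controlling cycle-to-cycle variability.
#' @param stance_fraction stance/swing split as a fraction of the cycle.
#' @param stretch_amp peak spindle stretch (dimensionless, the unit consumed
#'   by the afferent rate equations). `NULL` selects the muscle default
#'   (TA 9, GM 0.5): the flexor spindle modulates more deeply than the
#'   extensor so the flexor-side reciprocal-inhibition pathway dominates
#'   during its active phase, which keeps Baseline motoneuron bursting in
#'   the physiological band.
#' @param stretch_base tonic stretch offset (dimensionless; default TA 4,
#'   GM 0). The flexor spindle rides on a tonic stretch so its group-II
#'   drive keeps the flexor-side inhibitory interneurons active through the
#'   shortening-phase velocity dip.
#' @param emg_jitter SD of the per-cycle multiplicative envelope jitter.
#' @return A `gait_profile` tibble with columns `t` (s), `stretch`,
#'   `stretch_velocity` (1/s), `emg_env`, and attributes `muscle`,
#'   `cycle_duration`, `stance_fraction`, `fs`.
#' @export
#' @examples
#' gm <- make_synthetic_gait("GM", n_steps = 2, cycle_duration = 0.7, seed = 1)
#' range(gm$emg_env)
make_synthetic_gait <- function(muscle = c("TA", "GM"), n_steps = 8L,
                                cycle_duration = 0.7, seed = 1L,
                                stance_fraction = 0.65,
                                stretch_amp = NULL, stretch_base = NULL,
                                emg_jitter = 0.03) {
  muscle <- match.arg(muscle)
  if (is.null(stretch_amp)) stretch_amp <- if (muscle == "TA") 9 else 0.5
  if (is.null(stretch_base)) stretch_base <- if (muscle == "TA") 4 else 0
  stopifnot_scalar(n_steps, "n_steps")
  stopifnot_scalar(cycle_duration, "cycle_duration")
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    abort("`stance_fraction` must lie in (0, 1)")
  }
  n_steps <- as.integer(n_steps)
  fs <- GAIT_FS
  n_per <- round(cycle_duration * fs)
  n <- n_per * n_steps
  t <- (seq_len(n) - 1L) / fs
  phase <- (t %% cycle_duration) / cycle_duration
  cyc <- pmin(floor(t / cycle_duration) + 1L, n_steps)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  amp_jit <- pmax(0.5, rnorm(n_steps, 1, emg_jitter))

  # envelope: raised-cosine burst centred in the active phase
  if (muscle == "GM") {
    centre <- stance_fraction / 2
    width <- stance_fraction
  } else {
    centre <- stance_fraction + (1 - stance_fraction) / 2
    width <- 1 - stance_fraction
  }
  u <- (phase - centre) / width
  # plateau-clipped raised cosine: EMG envelopes saturate mid-burst
  env <- pmin(1, 1.5 * ifelse(abs(u) < 0.5, cos(pi * u)^2, 0))
  env <- env * amp_jit[cyc]
  env <- env / max(env)  # min-max normalised to [0, 1]

  # stretch: compact raised-cosine bump in anti-phase with the muscle's own
  # envelope (the muscle is stretched while its antagonist is active); the
  # bump returns exactly to zero outside its support so the afferent rate
  # rests at its background value through the muscle's active phase
  sc <- (centre + 0.5) %% 1
  sw <- 1 - width
  du <- (phase - sc + 0.5) %% 1 - 0.5
  us <- du / sw
  on_sup <- abs(us) < 0.5
  stretch <- stretch_base + ifelse(on_sup, stretch_amp * cos(pi * us)^2, 0)
  stretch_velocity <- ifelse(
    on_sup,
    -stretch_amp * pi * sin(2 * pi * us) / (sw * cycle_duration), 0)

  out <- tibble(t = t, stretch = stretch,
                stretch_velocity = stretch_velocity, emg_env = env)
  attr(out, "muscle") <- muscle
  attr(out, "cycle_duration") <- cycle_duration
  attr(out, "stance_fraction") <- stance_fraction
  attr(out, "fs") <- fs
  class(out) <- c("gait_profile", class(out))
  out
}

check_gait_profile <- function(profile) {
  need <- c("t", "stretch", "stretch_velocity", "emg_env")
  if (!all(need %in% names(profile))) {
    abort("`profile` must have columns t, stretch, stretch_velocity, emg_env")
  }
  if (any(profile$emg_env < -1e-9) || any(profile$emg_env > 1 + 1e-9)) {
    abort("`emg_env` must lie in [0, 1]")
  }
  invisible(profile)
}

#' Ia afferent firing rate from a gait profile
#'
#' Muscle-spindle primary (Ia) afferent encoding of stretch, stretch
#' velocity, and (under body-weight support) the EMG envelope:
#' `rate = 50 + 2 * stretch + 4.3 * sign(v) * |v|^0.6 + K * 50 * emg_env`,
#' clipped at zero. At rest (zero stretch, velocity and envelope) the rate
#' is exactly 50 Hz.
#'
#' @param profile a `gait_profile` (or any data frame with the same columns).
#' @param K EMG-envelope scaling gain; 0 for full weight bearing, negative
#'   under body-weight support (see [apply_bws()]).
#' @return A tibble `(t, rate)` with attributes `fibre_class`, `muscle`, `K`.
#' @export
#' @examples
#' p <- make_synthetic_gait("TA", 1, 0.7, seed = 1)
#' head(ia_rate(p, K = 0))
ia_rate <- function(profile, K = 0) {
  check_gait_profile(profile)
  stopifnot_scalar(K, "K", positive = FALSE)
  v <- profile$stretch_velocity
  r <- 50 + 2 * profile$stretch + 4.3 * sign(v) * abs(v)^0.6 +
    K * 50 * profile$emg_env
  afferent_series(profile, pmax(r, 0), "Ia", K)
}

#' II afferent firing rate from a gait profile
#'
#' Muscle-spindle secondary (II) afferent encoding of stretch and (under
#' body-weight support) the EMG envelope:
#' `rate = 80 + 13.5 * stretch + K * 20 * emg_env`, clipped at zero. At rest
#' the rate is exactly 80 Hz.
#'
#' @inheritParams ia_rate
#' @return A tibble `(t, rate)` with attributes `fibre_class`, `muscle`, `K`.
#' @export
ii_rate <- function(profile, K = 0) {
  check_gait_profile(profile)
  stopifnot_scalar(K, "K", positive = FALSE)
  r <- 80 + 13.5 * profile$stretch + K * 20 * profile$emg_env
  afferent_series(profile, pmax(r, 0), "II", K)
}

afferent_series <- function(profile, rate, fibre_class, K) {
  out <- tibble(t = profile$t, rate = rate)
  attr(out, "fibre_class") <- fibre_class
  attr(out, "muscle") <- attr(profile, "muscle")
  attr(out, "K") <- K
  attr(out, "fs") <- attr(profile, "fs") %||% GAIT_FS
  class(out) <- c("afferent_rate_series", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Body-weight-support afferent scaling gains
#'
#' Under 60% effective body-weight support the EMG-envelope contribution to
#' the afferent rate equations is scaled by muscle-specific gains measured
#' in treadmill experiments: `K_GM = -0.6` (extensor unloading) and
#' `K_TA = -0.122`. Without support both gains are 0.
#'
#' @param bws logical; is body-weight support active?
#' @return Named list with `K_GM` and `K_TA`.
#' @export
#' @examples
#' apply_bws(TRUE)
apply_bws <- function(bws) {
  if (!is.logical(bws) || length(bws) != 1L || is.na(bws)) {
    abort("`bws` must be TRUE or FALSE")
  }
  if (bws) list(K_GM = -0.6, K_TA = -0.122) else list(K_GM = 0, K_TA = 0)
}

#' Encode afferent rate series as Poisson drive onto LIF axons
#'
#' Each axon of the population receives an independent inhomogeneous
#' Poisson event train whose intensity follows the commanded rate series
#' (sampled at 200 Hz); events are delivered through the excitatory
#' exponential synapse onto the axon membrane with a drive weight tuned so
#' that the axon relays the commanded rate (each event is suprathreshold,
#' so the axon reproduces the input train up to refractoriness). Gaussian
#' current noise (SD 0.3 pA) is added to every axon.
#'
#' @param rates an `afferent_rate_series` from [ia_rate()]/[ii_rate()], or a
#'   data frame with columns `t`, `rate` sampled at 200 Hz.
#' @param n_axons number of axons.
#' @param seed integer seed (Poisson streams and membrane noise).
#' @param g_drive synaptic weight of the drive events (nS).
#' @return A `spike_raster` tibble `(population, neuron, t)`; attribute
#'   `command_rate` holds the commanded series for tuning checks.
#' @export
#' @examples
#' p <- make_synthetic_gait("TA", 1, 0.7, seed = 1)
#' r <- ia_rate(p, K = 0)
#' raster <- encode_poisson_drive(r, n_axons = 10, seed = 1)
#' nrow(raster) > 0
encode_poisson_drive <- function(rates, n_axons = 60L, seed = 1L,
                                 g_drive = 500) {
  if (!all(c("t", "rate") %in% names(rates))) {
    abort("`rates` must have columns t and rate")
  }
  if (nrow(rates) > 1) {
    dt <- diff(rates$t)
    if (max(abs(dt - 1 / GAIT_FS)) > 1e-6) {
      abort("`rates` must be sampled at 200 Hz")
    }
  }
  fib <- attr(rates, "fibre_class") %||% "Ia"
  ax <- axon_population_spec(fib, n_axons, seed = seed)
  lif <- attr(ax, "lif")
  params <- tibble(
    population = paste0(fib, "_drive"), neuron = seq_len(n_axons), kind = 0L,
    C = ax$C_pF, gL = ax$gL_nS, EL = lif$EL, Vth = lif$Vth,
    Vreset = lif$Vreset, DeltaV = 1, a = 0, tauw = 1, b = 0,
    tref = lif$tref, Vcut = lif$Vth, noise_sd = lif$noise_sd,
    gid = seq_len(n_axons) - 1L
  )
  rmat <- matrix(rates$rate, nrow = nrow(rates), ncol = n_axons)
  streams <- seed_streams(seed, 3L)
  T_ms <- (max(rates$t) + 1 / GAIT_FS) * 1e3
  res <- run_core(params, empty_edges(), T_ms = T_ms,
                  drive = list(gids = params$gid, rates = rmat,
                               fs = GAIT_FS, g = rep(g_drive, n_axons)),
                  seeds = streams)
  out <- core_raster(res, params)
  attr(out, "command_rate") <- rates
  out
}
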