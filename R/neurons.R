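#' Reference Euler step for a conductance-based LIF neuron
#'
#' One forward-Euler update of `dV/dt = (gL (EL - V) + I) / C` with hard
#' threshold/reset. This scalar R implementation mirrors the compiled
#' network core and is intended for small protocols and cross-checks.
#'
#' @param state list with `V` (mV) and `refractory_until` (ms).
#' @param spec one-row population tibble (see [population_specs()]).
#' @param I_syn input current (pA).
#' @param t current time (ms).
#' @param dt_ms step (ms).
#' @return Updated state with a logical `spike` flag.
#' @export
step_cond_lif <- function(state, spec, I_syn, t, dt_ms = DT_MS) {
  if (!is.finite(state$V)) abort("non-finite membrane potential")
  if (t < state$refractory_until) {
    state$V <- spec$Vreset; state$spike <- FALSE
    return(state)
  }
  V <- state$V + dt_ms * (spec$gL * (spec$EL - state$V) + I_syn) / spec$C
  spike <- V >= spec$Vth
  if (spike) {
    V <- spec$Vreset
    # release boundary placed mid-step so the comparison never lands on an
    # exact floating-point step time
    state$refractory_until <- t + dt_ms / 2 + spec$tref
  }
  state$V <- V; state$spike <- spike
  state
}

#' Reference Euler step for an AdEx / exponential LIF neuron
#'
#' One forward-Euler update of the adaptive exponential model
#' `dV/dt = (gL (EL - V) + gL DeltaV exp((V - Vth)/DeltaV) + I - w) / C`,
#' `dw/dt = (a (V - EL) - w) / tauw`, with numerical spike detection at
#' `V_cut = Vth + 5 DeltaV`. For an exponential LIF (motoneuron) the
#' adaptation current `w` is frozen at zero.
#'
#' @inheritParams step_cond_lif
#' @param exp_lif logical; freeze `w` at 0.
#' @export
step_adex <- function(state, spec, I_syn, t, dt_ms = DT_MS, exp_lif = FALSE) {
  if (!is.finite(state$V)) abort("non-finite membrane potential")
  w <- if (is.null(state$w)) 0 else state$w
  if (!exp_lif) {
    w <- w + dt_ms * (spec$a * (state$V - spec$EL) - w) / spec$tauw
  } else {
    w <- 0
  }
  state$w <- w
  if (t < state$refractory_until) {
    state$V <- spec$Vreset; state$spike <- FALSE
    return(state)
  }
  arg <- min((state$V - spec$Vth) / spec$DeltaV, 30)
  ex <- spec$gL * spec$DeltaV * exp(arg)
  V <- state$V + dt_ms *
    (spec$gL * (spec$EL - state$V) + ex + I_syn - w) / spec$C
  Vcut <- spec$Vth + 5 * spec$DeltaV
  spike <- V >= Vcut
  if (spike) {
    V <- spec$Vreset
    state$refractory_until <- t + dt_ms / 2 + spec$tref
    state$w <- w + spec$b
  }
  state$V <- V; state$spike <- spike
  state
}

# single-population current-injection protocol on the compiled core
simulate_pulse <- function(spec, I_pA, pulse_ms = 200, pad_ms = 20,
                           dt_ms = DT_MS) {
  params <- expand_neurons(spec[rep(1, 1), ] %>% mutate(N = 1L), seed = 1L)
  params$noise_sd <- 0
  inj <- matrix(c(0, pad_ms, pad_ms + pulse_ms, I_pA), nrow = 1)
  res <- run_core(params, empty_edges(), T_ms = pad_ms + pulse_ms + pad_ms,
                  dt_ms = dt_ms, inj = inj, seeds = c(1L, 1L, 1L))
  tin <- res$spike_t[res$spike_t >= pad_ms & res$spike_t < pad_ms + pulse_ms]
  list(n_spikes = length(tin), rate = length(tin) / (pulse_ms * 1e-3),
       spike_t = res$spike_t)
}

#' Frequency-current (F-I) characterisation of a population model
#'
#' Applies 200 ms current pulses across a stimulus range (default
#' 10-3160 pA, log-spaced as in standard electrophysiological protocols)
#' to a single model neuron and reports the firing rate during each pulse.
#' The protocol is noise-free and therefore deterministic.
#'
#' @param spec one-row population tibble (a row of [population_specs()]).
#' @param currents injected currents (pA).
#' @param pulse_ms pulse width (ms).
#' @return Tibble `(current_pA, rate_Hz)`.
#' @export
#' @examples
#' iain <- dplyr::filter(population_specs(), name == "IaIN_TA")
#' \donttest{fi_curve(iain, currents = c(100, 300, 1000))}
fi_curve <- function(spec, currents = 10^seq(1, 3.5, length.out = 12),
                     pulse_ms = 200) {
  if (length(currents) == 0) abort("`currents` must be non-empty")
  rates <- vapply(currents, function(I) simulate_pulse(spec, I, pulse_ms)$rate,
                  numeric(1))
  tibble(current_pA = currents, rate_Hz = rates)
}

#' Rheobase of a population model by bisection
#'
#' Minimal 200 ms pulse current eliciting at least one spike, found by
#' bisection to the requested resolution.
#'
#' @inheritParams fi_curve
#' @param lo,hi initial bracket (pA).
#' @param tol bisection resolution (pA).
#' @return Rheobase current (pA).
#' @export
rheobase <- function(spec, lo = 0, hi = 4000, tol = 1, pulse_ms = 200) {
  spikes_at <- function(I) simulate_pulse(spec, I, pulse_ms)$n_spikes > 0
  if (!spikes_at(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  hi
}
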