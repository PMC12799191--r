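#' Electrophysiological specification of the network populations
#'
#' Returns the parameter table for the five interneuron/motoneuron
#' populations and the four afferent axon populations of the ankle-flexor
#' reflex loop. Interneuron and motoneuron parameters follow published
#' rodent electrophysiology; afferent axons are leaky integrate-and-fire
#' (LIF) cables whose effective capacitance follows from the axon geometry
#' (specific capacitance 1 uF/cm^2, length 1 mm, radius drawn per axon).
#'
#' Model kinds: `cond_LIF` (conductance-based LIF), `AdEx` (adaptive
#' exponential LIF with subthreshold adaptation `w`), `exp_LIF` (exponential
#' LIF, i.e. AdEx with `w` frozen at 0). The numerical spike cutoff for
#' exponential models is `V_cut = V_th + 5 * Delta_V`.
#'
#' @param refractory_ms refractory period applied to interneurons and
#'   motoneurons (the axonal value of 1.6 ms is always used for axons).
#' @return A tibble with one row per population: counts, capacitance (pF),
#'   leak conductance (nS), reversal/threshold/reset potentials (mV), AdEx
#'   parameters, refractory period (ms) and current-noise SD (pA).
#' @export
#' @examples
#' population_specs()
population_specs <- function(refractory_ms = 1.6) {
  stopifnot_scalar(refractory_ms, "refractory_ms")
  ax <- axon_geometry()
  tibble::tribble(
    ~name,      ~kind,      ~N,   ~C,    ~gL,  ~EL,  ~Vth, ~Vreset, ~DeltaV, ~a, ~tauw, ~b, ~tref, ~noise_sd,
    "Ia_TA",    "cond_LIF", 60L,  ax$C_Ia, ax$gL_Ia, -80, -60, -70, NA,  NA, NA, 0, 1.6, 0.3,
    "II_TA",    "cond_LIF", 60L,  ax$C_II, ax$gL_II, -80, -60, -70, NA,  NA, NA, 0, 1.6, 0.3,
    "Ia_GM",    "cond_LIF", 60L,  ax$C_Ia, ax$gL_Ia, -80, -60, -70, NA,  NA, NA, 0, 1.6, 0.3,
    "II_GM",    "cond_LIF", 60L,  ax$C_II, ax$gL_II, -80, -60, -70, NA,  NA, NA, 0, 1.6, 0.3,
    "IaIN_TA",  "cond_LIF", 196L, 31.1,  5,    -70,  -50,  -65,     NA,  NA, NA, 0, refractory_ms, 0,
    "IaIN_GM",  "cond_LIF", 196L, 31.1,  5,    -70,  -50,  -65,     NA,  NA, NA, 0, refractory_ms, 0,
    "GABA",     "AdEx",     196L, 100,   1.2,  -70,  -50,  -62.3,   2,   2,  20, 0, refractory_ms, 0,
    "V2a",      "AdEx",     196L, 45,    1.2,  -53,  -42,  -47,     0.5, 2,  55, 0, refractory_ms, 0,
    "MN",       "exp_LIF",  169L, 162,   27,   -75,  -50,  -65,     0.05, NA, NA, 0, refractory_ms, 0
  )
}

# nominal axon capacitance/leak from mean radius; per-axon values are
# re-sampled at network-build time from radius mean +/- SD
axon_geometry <- function() {
  cap <- function(r_um) {
    # 1 uF/cm^2 * pi * r * l, r in um, l = 1 mm -> pF
    1e-6 * pi * (r_um * 1e-4) * 0.1 * 1e12
  }
  list(r_Ia = 9, r_Ia_sd = 0.2, r_II = 4.4, r_II_sd = 0.5,
       C_Ia = cap(9), C_II = cap(4.4),
       gL_Ia = cap(9) / 30, gL_II = cap(4.4) / 30,
       tau_mem = 30, cap = cap)
}

#' Afferent axon population specification
#'
#' LIF axon parameters for one fibre class. Membrane dynamics follow
#' `dV/dt = (E_l - V)/tau + I / C_eff` with `C_eff = C_m * pi * r_axon * l`;
#' the per-axon radius is drawn once at construction (truncated positive).
#'
#' @param fibre_class `"Ia"` or `"II"`.
#' @param n number of axons (default 60).
#' @param seed integer seed for the per-axon radius draw.
#' @return A tibble with one row per axon: radius (um), effective
#'   capacitance (pF) and leak conductance (nS), plus the shared LIF
#'   parameters as attributes.
#' @export
#' @examples
#' ax <- axon_population_spec("Ia", seed = 1)
#' range(ax$r_um)
axon_population_spec <- function(fibre_class = c("Ia", "II"), n = 60L, seed = 1L) {
  fibre_class <- match.arg(fibre_class)
  stopifnot_scalar(n, "n")
  g <- axon_geometry()
  mu <- if (fibre_class == "Ia") g$r_Ia else g$r_II
  sdv <- if (fibre_class == "Ia") g$r_Ia_sd else g$r_II_sd
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  r <- rnorm(n, mu, sdv)
  while (any(r <= 0)) r[r <= 0] <- rnorm(sum(r <= 0), mu, sdv)
  out <- tibble(
    fibre_class = fibre_class, axon = seq_len(n), r_um = r,
    C_pF = g$cap(r), gL_nS = g$cap(r) / g$tau_mem
  )
  attr(out, "lif") <- list(tau_mem = 30, tref = 1.6, EL = -80, Vth = -60,
                           Vreset = -70, noise_sd = 0.3)
  class(out) <- c("axon_population_spec", class(out))
  out
}

# expand the population table (+ sampled axon radii) into flat per-neuron
# parameter vectors for the compiled core; returns list(pops, params) where
# pops maps population name -> global 0-based id range
expand_neurons <- function(specs, seed) {
  g <- axon_geometry()
  streams <- seed_streams(seed, n = 4L)
  kind_code <- c(cond_LIF = 0L, AdEx = 1L, exp_LIF = 2L)
  rows <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    N <- s$N
    C <- rep(s$C, N); gL <- rep(s$gL, N)
    if (s$name %in% c("Ia_TA", "II_TA", "Ia_GM", "II_GM")) {
      fib <- if (startsWith(s$name, "Ia")) "Ia" else "II"
      ax <- axon_population_spec(fib, N, seed = streams[1] + i)
      C <- ax$C_pF; gL <- ax$gL_nS
    }
    rows[[i]] <- tibble(
      population = s$name, neuron = seq_len(N),
      kind = kind_code[[s$kind]], C = C, gL = gL, EL = s$EL, Vth = s$Vth,
      Vreset = s$Vreset,
      DeltaV = ifelse(is.na(s$DeltaV), 1, s$DeltaV),
      a = ifelse(is.na(s$a), 0, s$a), tauw = ifelse(is.na(s$tauw), 1, s$tauw),
      b = s$b, tref = s$tref,
      Vcut = if (s$kind == "cond_LIF") s$Vth else s$Vth + 5 * s$DeltaV,
      noise_sd = s$noise_sd
    )
  }
  params <- dplyr::bind_rows(rows)
  params$gid <- seq_len(nrow(params)) - 1L
  params
}
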