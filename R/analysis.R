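#' Smoothed population firing rate from a spike raster
#'
#' Bins population spike counts at the stated window width, converts to a
#' per-neuron rate in Hz, and smooths with a Gaussian kernel whose SD
#' equals one window. The kernel is normalised so smoothing preserves total
#' spike mass. The 25 ms window is the default for condition analyses; a
#' 4 ms window matches the rodent burst-validation protocol.
#'
#' @param raster a `spike_raster` tibble (or data frame with columns
#'   `population`, `t` in seconds).
#' @param N number of neurons in the population (taken from the raster
#'   attribute when present).
#' @param window_ms bin width, also the Gaussian SD (ms).
#' @param population population to analyse (default `"MN"`).
#' @param T total duration (s); defaults to the last bin covering the data.
#' @return A `rate_series` tibble `(t, rate)`; attributes `window_ms`, `N`.
#' @export
#' @examples
#' r <- tibble::tibble(population = "MN", neuron = 1, t = c(0.1, 0.12, 0.5))
#' population_rate(r, N = 1, window_ms = 25, T = 1)
population_rate <- function(raster, N = NULL, window_ms = 25,
                            population = "MN", T = NULL) {
  stopifnot_scalar(window_ms, "window_ms")
  if (is.null(N)) {
    sizes <- attr(raster, "pop_sizes")
    if (is.null(sizes) || !population %in% names(sizes)) {
      abort("`N` must be supplied when the raster carries no population sizes")
    }
    N <- sizes[[population]]
  }
  tt <- raster$t[raster$population == population]
  if (is.null(T)) T <- if (length(tt)) max(tt) else 1
  wd <- window_ms * 1e-3
  nb <- max(1L, ceiling(T / wd))
  counts <- tabulate(pmin(pmax(floor(tt / wd), 0) + 1L, nb), nbins = nb)
  rate <- counts / (N * wd)
  rate <- gauss_smooth(rate, sigma_bins = 1)
  out <- tibble(t = (seq_len(nb) - 0.5) * wd, rate = rate)
  attr(out, "window_ms") <- window_ms
  attr(out, "N") <- N
  class(out) <- c("rate_series", class(out))
  out
}

# mass-preserving discrete Gaussian smoothing (kernel renormalised at edges)
gauss_smooth <- function(x, sigma_bins = 1) {
  if (sigma_bins <= 0 || length(x) < 3) return(x)
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- dnorm(-half:half, sd = sigma_bins)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  sm <- stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
  # edge renormalisation: divide by the kernel mass that fell inside
  mass <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k,
                        sides = 2)[(half + 1):(half + n)]
  as.numeric(sm / mass)
}

#' Burst detection on a smoothed rate series
#'
#' Threshold-crossing detection with hysteresis: a burst opens when the
#' rate exceeds `on_frac` of the series' 95th-percentile rate for at least
#' `min_dur_ms`, and closes when it stays below `off_frac` of that
#' reference for `min_dur_ms`; bursts separated by less than `merge_ms`
#' are merged. Returns onset/offset times, mean in-burst firing rates, and
#' onset-to-onset burst periods.
#'
#' @param rate a `rate_series` from [population_rate()].
#' @param on_frac,off_frac onset/offset thresholds as fractions of the
#'   95th-percentile rate.
#' @param min_dur_ms minimum supra/sub-threshold duration (ms).
#' @param merge_ms merge bursts separated by less than this gap (ms).
#' @return A `burst_stats` list: `bursts` tibble (onset, offset,
#'   burst_rate), `periods` (s), `threshold_on`, `threshold_off`.
#' @export
#' @examples
#' t <- seq(0.002, 2.8, by = 0.004)
#' r <- tibble::tibble(t = t, rate = ifelse(t %% 0.7 < 0.25, 200, 0))
#' detect_bursts(r)$periods
detect_bursts <- function(rate, on_frac = 0.2, off_frac = 0.1,
                          min_dur_ms = 20, merge_ms = 50) {
  ref <- quantile(rate$rate, 0.95, names = FALSE)
  thr_on <- on_frac * ref
  thr_off <- off_frac * ref
  dt <- if (nrow(rate) > 1) diff(rate$t[1:2]) else 1e-3
  min_bins <- max(1L, round(min_dur_ms * 1e-3 / dt))

  above <- rate$rate > thr_on
  below <- rate$rate < thr_off
  n <- nrow(rate)
  bursts <- list(); in_burst <- FALSE; onset <- NA_real_
  run_above <- 0L; run_below <- 0L
  for (i in seq_len(n)) {
    if (!in_burst) {
      run_above <- if (above[i]) run_above + 1L else 0L
      if (run_above >= min_bins) {
        in_burst <- TRUE
        onset <- rate$t[i - min_bins + 1L]
        run_below <- 0L
      }
    } else {
      run_below <- if (below[i]) run_below + 1L else 0L
      if (run_below >= min_bins) {
        bursts[[length(bursts) + 1L]] <- c(onset, rate$t[i - min_bins])
        in_burst <- FALSE; run_above <- 0L
      }
    }
  }
  if (in_burst) bursts[[length(bursts) + 1L]] <- c(onset, rate$t[n])
  if (length(bursts) == 0) {
    return(structure(list(bursts = tibble(onset = numeric(), offset = numeric(),
                                          burst_rate = numeric()),
                          periods = numeric(), threshold_on = thr_on,
                          threshold_off = thr_off), class = "burst_stats"))
  }
  b <- do.call(rbind, bursts)
  # merge close bursts
  merged <- list(b[1, ])
  if (nrow(b) > 1) {
    for (i in 2:nrow(b)) {
      last <- merged[[length(merged)]]
      if (b[i, 1] - last[2] < merge_ms * 1e-3) {
        merged[[length(merged)]] <- c(last[1], b[i, 2])
      } else merged[[length(merged) + 1L]] <- b[i, ]
    }
  }
  b <- do.call(rbind, merged)
  brate <- vapply(seq_len(nrow(b)), function(i) {
    w <- rate$t >= b[i, 1] & rate$t <= b[i, 2]
    mean(rate$rate[w])
  }, numeric(1))
  structure(list(
    bursts = tibble(onset = b[, 1], offset = b[, 2], burst_rate = brate),
    periods = if (nrow(b) > 1) diff(b[, 1]) else numeric(),
    threshold_on = thr_on, threshold_off = thr_off
  ), class = "burst_stats")
}

#' Synthetic EMG from a motoneuron spike raster
#'
#' Convolves each motor unit's binary spike train with a representative
#' motor-unit action potential wavelet (first-derivative Gaussian, 6 ms
#' support, 10% per-unit amplitude jitter), sums across units, and
#' normalises the summed trace to unit peak amplitude. The per-unit
#' construction is linear before normalisation.
#'
#' @param raster a `spike_raster` with an `"MN"` population (or any raster;
#'   the `population` argument selects the pool).
#' @param seed integer seed for per-unit amplitude jitter.
#' @param T total duration (s).
#' @param fs output sampling rate (Hz).
#' @param population population name.
#' @param normalise logical; normalise the summed trace to unit peak.
#' @return Tibble `(t, emg)`.
#' @export
synth_emg <- function(raster, seed = 1L, T = NULL, fs = 2000,
                      population = "MN", normalise = TRUE) {
  tt <- raster$t[raster$population == population]
  id <- raster$neuron[raster$population == population]
  if (is.null(T)) T <- if (length(tt)) max(tt) + 0.01 else 1
  n <- ceiling(T * fs)
  out <- numeric(n)
  # MUAP: first-derivative Gaussian, 6 ms support
  tw <- seq(-3e-3, 3e-3, by = 1 / fs)
  sig <- 1e-3
  wav <- -tw / sig^2 * exp(-tw^2 / (2 * sig^2))
  wav <- wav / max(abs(wav))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  units <- sort(unique(id))
  # amplitudes are drawn for every unit index up to the largest present so
  # the same unit keeps its amplitude across sub-rasters
  amp_all <- pmax(0, rnorm(max(c(units, 1)), 1, 0.1))
  amp <- setNames(amp_all[units], units)
  half <- (length(wav) - 1L) / 2
  for (u in units) {
    idx <- round(tt[id == u] * fs)
    train <- numeric(n)
    keep <- idx >= 1 & idx <= n
    train[idx[keep]] <- 1
    conv <- stats::filter(c(numeric(half), train, numeric(half)), rev(wav),
                          sides = 2)[(half + 1):(half + n)]
    out <- out + amp[[as.character(u)]] * as.numeric(conv)
  }
  out[is.na(out)] <- 0
  if (normalise && max(abs(out)) > 0) out <- out / max(abs(out))
  tibble(t = (seq_len(n) - 0.5) / fs, emg = out)
}

#' Per-step phase summaries of a rate series
#'
#' Splits each gait cycle at the stance fraction and reports, per step:
#' stance and swing mean rates, their difference (`delta_phase`, stance
#' positive and swing negative), trapezoidal area under the rate curve, and
#' the Fano factor of windowed spike counts (windows are the rate bins
#' downsampled by a factor of 10). Steps with no spikes have an undefined
#' Fano factor and are excluded from Fano summaries (their count is
#' reported). Outlying step values (|z| > 3 within each metric) are
#' removed.
#'
#' @param rate a `rate_series` from [population_rate()].
#' @param raster the spike raster (for the Fano counts).
#' @param cfg a [condition_config()] (cycle duration, stance split, steps).
#' @param population population name.
#' @param z_thresh outlier threshold in SD units.
#' @return A `phase_summary` tibble with one row per step: `step`,
#'   `stance_mean`, `swing_mean`, `delta_phase`, `auc`, `fano`.
#' @export
phase_summaries <- function(rate, raster, cfg, population = "MN",
                            z_thresh = 3) {
  cd <- cfg$cycle_duration
  sf <- cfg$stance_fraction
  n_steps <- cfg$n_steps
  N <- attr(rate, "N") %||% attr(raster, "pop_sizes")[[population]]
  wd <- (attr(rate, "window_ms") %||% 25) * 1e-3
  tt <- raster$t[raster$population == population]

  rows <- lapply(seq_len(n_steps), function(s) {
    t0 <- (s - 1) * cd; t1 <- s * cd
    inw <- rate$t >= t0 & rate$t < t1
    ph <- (rate$t[inw] - t0) / cd
    stance <- mean(rate$rate[inw][ph < sf])
    swing <- mean(rate$rate[inw][ph >= sf])
    auc <- trapz(rate$t[inw], rate$rate[inw])
    # Fano: spike counts in rate bins downsampled x10 within the step
    win <- wd * 10
    nb <- max(1L, floor((t1 - t0) / win))
    cts <- tabulate(floor((tt[tt >= t0 & tt < t1] - t0) / win) + 1L,
                    nbins = nb)
    fano <- if (sum(cts) == 0) NA_real_ else var(cts) / mean(cts)
    tibble(step = s, stance_mean = stance, swing_mean = swing,
           delta_phase = stance - swing, auc = auc, fano = fano)
  })
  out <- dplyr::bind_rows(rows)
  for (col in c("stance_mean", "swing_mean", "delta_phase", "auc", "fano")) {
    out[[col]] <- drop_outliers(out[[col]], z_thresh)
  }
  attr(out, "n_fano_defined") <- sum(!is.na(out$fano))
  class(out) <- c("phase_summary", class(out))
  out
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# z-score outlier removal (values |z| > thresh replaced by NA)
drop_outliers <- function(x, thresh = 3) {
  ok <- !is.na(x)
  if (sum(ok) < 2) return(x)
  z <- (x - mean(x[ok])) / sd(x[ok])
  x[ok & !is.na(z) & abs(z) > thresh] <- NA
  x
}
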