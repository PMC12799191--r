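test_that("population rate handles empty rasters and preserves spike mass", {
  empty <- tibble::tibble(population = character(), neuron = integer(),
                          t = numeric())
  r0 <- population_rate(empty, N = 10, T = 1)
  expect_true(all(r0$rate == 0))
  # mass preservation: integral of the smoothed rate equals count/N
  set.seed(4)
  tt <- runif(500, 0.2, 1.8)  # interior spikes: no kernel mass leaves [0, T]
  ras <- tibble::tibble(population = "MN", neuron = sample(1:20, 500, TRUE),
                        t = tt)
  r <- population_rate(ras, N = 20, window_ms = 25, T = 2)
  wd <- 25e-3
  mass <- sum(r$rate) * wd * 20
  expect_equal(mass, 500, tolerance = 1e-3)
})

test_that("a homogeneous Poisson population is recovered at its rate", {
  set.seed(7)
  rate_true <- 100; N <- 30; T <- 20
  events <- lapply(1:N, function(i) {
    n <- stats::rpois(1, rate_true * T)
    tibble::tibble(population = "MN", neuron = i, t = sort(runif(n, 0, T)))
  })
  ras <- dplyr::bind_rows(events)
  r <- population_rate(ras, N = N, window_ms = 25, T = T)
  se <- sqrt(rate_true / (N * T))
  expect_lt(abs(mean(r$rate) - rate_true), 3 * se)
})

test_that("burst detector recovers a constructed square wave exactly", {
  t <- seq(0.002, 5.6, by = 0.004)
  rate <- tibble::tibble(t = t, rate = ifelse(t %% 0.7 < 0.25, 200, 0))
  bs <- detect_bursts(rate)
  expect_equal(nrow(bs$bursts), 8)
  expect_equal(mean(bs$periods), 0.7, tolerance = 0.01)
  expect_equal(mean(bs$bursts$burst_rate), 200, tolerance = 0.01)
  expect_equal(mean(bs$bursts$offset - bs$bursts$onset), 0.25,
               tolerance = 0.05)
  # constant rate: the whole series is one supra-threshold segment
  const <- tibble::tibble(t = t, rate = rep(100, length(t)))
  bc <- detect_bursts(const)
  expect_lte(nrow(bc$bursts), 1)
  expect_equal(length(bc$periods), 0)
})

test_that("bursts separated by less than the merge gap are merged", {
  t <- seq(0.002, 1.2, by = 0.004)
  r <- ifelse(t < 0.3 | (t > 0.33 & t < 0.6), 200, 0)  # 30 ms gap
  bs <- detect_bursts(tibble::tibble(t = t, rate = r))
  expect_equal(nrow(bs$bursts), 1)
})

test_that("synthetic EMG behaves linearly and peaks at spike times", {
  flat <- synth_emg(tibble::tibble(population = "MN", neuron = integer(),
                                   t = numeric()), T = 0.5)
  expect_true(all(flat$emg == 0))
  one <- tibble::tibble(population = "MN", neuron = 1, t = 0.25)
  e1 <- synth_emg(one, seed = 1, T = 0.5)
  expect_lt(abs(e1$t[which.max(abs(e1$emg))] - 0.25), 0.002)
  # superposition before normalisation
  a <- tibble::tibble(population = "MN", neuron = 1, t = c(0.1, 0.2))
  b <- tibble::tibble(population = "MN", neuron = 2, t = c(0.3))
  eab <- synth_emg(dplyr::bind_rows(a, b), seed = 2, T = 0.5,
                   normalise = FALSE)
  ea <- synth_emg(a, seed = 2, T = 0.5, normalise = FALSE)
  eb <- synth_emg(b, seed = 2, T = 0.5, normalise = FALSE)
  # per-unit amplitudes are drawn by unit id, so the sum decomposes
  expect_equal(eab$emg, ea$emg + eb$emg, tolerance = 1e-8)
})

test_that("phase summaries reduce a constant rate to the obvious values", {
  cfg <- condition_config("Baseline", n_steps = 4, cycle_duration = 1)
  t <- seq(0.0125, 4, by = 0.025)
  rate <- tibble::tibble(t = t, rate = rep(10, length(t)))
  attr(rate, "window_ms") <- 25
  attr(rate, "N") <- 5
  ras <- tibble::tibble(population = "MN", neuron = 1,
                        t = seq(0.05, 3.95, by = 0.1))
  ps <- phase_summaries(rate, ras, cfg)
  expect_equal(nrow(ps), 4)
  expect_equal(ps$stance_mean, rep(10, 4))
  expect_equal(ps$swing_mean, rep(10, 4))
  expect_equal(ps$delta_phase, rep(0, 4))
  expect_equal(ps$auc, rep(10, 4), tolerance = 0.05)
})

test_that("windowed Poisson counts have unit Fano factor", {
  set.seed(11)
  cfg <- condition_config("Baseline", n_steps = 8, cycle_duration = 1)
  n <- stats::rpois(1, 8000)
  ras <- tibble::tibble(population = "MN", neuron = 1,
                        t = sort(runif(n, 0, 8)))
  rate <- population_rate(ras, N = 1, window_ms = 25, T = 8)
  ps <- phase_summaries(rate, ras, cfg)
  fano <- mean(ps$fano, na.rm = TRUE)
  # 95% band for a Poisson Fano estimate at ~32 windows per step, 8 steps
  expect_gt(fano, 0.75)
  expect_lt(fano, 1.25)
})

test_that("z-score outlier removal keeps small-sample extremes", {
  # at n = 4 the most extreme value cannot exceed |z| = 1.5
  x <- c(0, 0, 0, 100)
  expect_equal(spinalsnn:::drop_outliers(x, 3), x)
  y <- c(rep(10, 30), 1e4)
  expect_true(is.na(spinalsnn:::drop_outliers(y, 3)[31]))
})

test_that("steps without spikes report an undefined Fano factor", {
  cfg <- condition_config("Baseline", n_steps = 3, cycle_duration = 1)
  ras <- tibble::tibble(population = "MN", neuron = 1,
                        t = c(runif(50, 0, 1), runif(50, 2, 3)))
  rate <- population_rate(ras, N = 1, window_ms = 25, T = 3)
  ps <- phase_summaries(rate, ras, cfg)
  expect_true(is.na(ps$fano[2]))
  expect_equal(attr(ps, "n_fano_defined"), 2)
})
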