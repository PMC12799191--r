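rest_profile <- tibble::tibble(t = 0, stretch = 0, stretch_velocity = 0,
                               emg_env = 0)

test_that("afferent rate equations give exact background rates at rest", {
  for (K in c(0, -0.6, -0.122, 1)) {
    expect_identical(ia_rate(rest_profile, K)$rate, 50)
    expect_identical(ii_rate(rest_profile, K)$rate, 80)
  }
})

test_that("afferent rate equations match hand-evaluated cases", {
  p <- function(x, v, e) tibble::tibble(t = 0, stretch = x,
                                        stretch_velocity = v, emg_env = e)
  # scalar oracle evaluated independently of the vectorised implementation
  ia_ref <- function(x, v, e, K) {
    max(0, 50 + 2 * x + 4.3 * sign(v) * abs(v)^0.6 + K * 50 * e)
  }
  expect_equal(ia_rate(p(1, 0, 0), 0)$rate, 52)
  expect_equal(ia_rate(p(0, 1, 1), -0.6)$rate, 24.3)
  expect_equal(ia_rate(p(0, 1, 1), -0.6)$rate, ia_ref(0, 1, 1, -0.6))
  expect_equal(ii_rate(p(2, 0, 0), 0)$rate, 107)
  expect_equal(ii_rate(p(0, 0, 1), -0.122)$rate, 80 - 2.44)
  # clipping keeps rates nonnegative under strong unloading
  expect_gte(ia_rate(p(0, -100, 1), -2)$rate, 0)
  # negative-velocity branch agrees with the scalar oracle
  for (v in c(-20, -3, 2.5)) {
    expect_equal(ia_rate(p(1.2, v, 0.4), -0.6)$rate,
                 ia_ref(1.2, v, 0.4, -0.6))
  }
})

test_that("ia_rate is monotone in stretch and in nonnegative velocity", {
  xs <- seq(0, 10, length.out = 25)
  rx <- vapply(xs, function(x)
    ia_rate(tibble::tibble(t = 0, stretch = x, stretch_velocity = 0,
                           emg_env = 0), 0)$rate, numeric(1))
  expect_true(all(diff(rx) >= 0))
  vs <- seq(0, 40, length.out = 25)
  rv <- vapply(vs, function(v)
    ia_rate(tibble::tibble(t = 0, stretch = 1, stretch_velocity = v,
                           emg_env = 0), 0)$rate, numeric(1))
  expect_true(all(diff(rv) >= 0))
})

test_that("body-weight support lowers rates only where the envelope is active", {
  prof <- make_synthetic_gait("GM", n_steps = 2, cycle_duration = 0.7,
                              seed = 3)
  K <- apply_bws(TRUE)
  expect_equal(K$K_GM, -0.6)
  expect_equal(K$K_TA, -0.122)
  expect_equal(apply_bws(FALSE), list(K_GM = 0, K_TA = 0))
  on_rate <- ia_rate(prof, K$K_GM)$rate
  off_rate <- ia_rate(prof, 0)$rate
  active <- prof$emg_env > 0
  expect_true(all(on_rate[active] < off_rate[active]))
  expect_equal(on_rate[!active], off_rate[!active])
  expect_true(all(ii_rate(prof, K$K_GM)$rate[active] <
                    ii_rate(prof, 0)$rate[active]))
})

test_that("synthetic gait respects phasing, sampling and determinism", {
  gm <- make_synthetic_gait("GM", n_steps = 8, cycle_duration = 1, seed = 1)
  ta <- make_synthetic_gait("TA", n_steps = 8, cycle_duration = 1, seed = 1)
  for (s in 0:7) {
    w <- gm$t >= s & gm$t < s + 1
    ph_gm <- gm$t[w][which.max(gm$emg_env[w])] - s
    ph_ta <- ta$t[w][which.max(ta$emg_env[w])] - s
    expect_lt(ph_gm, 0.65)   # extensor envelope peaks in stance
    expect_gte(ph_ta, 0.65)  # flexor envelope peaks in swing
  }
  expect_true(all(gm$emg_env >= 0 & gm$emg_env <= 1))
  one <- make_synthetic_gait("TA", n_steps = 1, cycle_duration = 0.7,
                             seed = 2)
  expect_equal(nrow(one), 140)            # 0.7 s at 200 Hz
  expect_equal(diff(one$t)[1], 1 / 200)
  again <- make_synthetic_gait("TA", n_steps = 1, cycle_duration = 0.7,
                               seed = 2)
  expect_identical(one, again)
  expect_error(make_synthetic_gait("TA", n_steps = 0), "positive")
})

test_that("stretch velocity is consistent with the numerical derivative", {
  p <- make_synthetic_gait("TA", n_steps = 2, cycle_duration = 0.7, seed = 1)
  # central differences away from the support edges
  v_num <- (dplyr::lead(p$stretch) - dplyr::lag(p$stretch)) * 200 / 2
  interior <- !is.na(v_num) & abs(p$stretch_velocity) > 1
  relerr <- abs(p$stretch_velocity[interior] - v_num[interior]) /
    max(abs(p$stretch_velocity))
  expect_lt(max(relerr), 0.05)
})

test_that("Poisson drive encoding is deterministic and silent at zero rate", {
  rates <- tibble::tibble(t = seq(0, 0.995, by = 1 / 200), rate = 0)
  r0 <- encode_poisson_drive(rates, n_axons = 5, seed = 1)
  expect_equal(nrow(r0), 0)
  rates$rate <- 80
  r1 <- encode_poisson_drive(rates, n_axons = 10, seed = 7)
  r2 <- encode_poisson_drive(rates, n_axons = 10, seed = 7)
  expect_identical(r1$t, r2$t)
  expect_identical(r1$neuron, r2$neuron)
  r3 <- encode_poisson_drive(rates, n_axons = 10, seed = 8)
  expect_false(identical(r1$t, r3$t))
  expect_error(encode_poisson_drive(tibble::tibble(t = c(0, 0.1), rate = 1)),
               "200 Hz")
})

test_that("axons relay a constant command at the dead-time-corrected rate", {
  # Monte-Carlo oracle: a Poisson train thinned by an absolute dead time
  # tref relays at r / (1 + r * tref); simulated here directly in R
  cmd <- 100; tref <- 1.6e-3; T <- 10
  set.seed(42)
  ref_rates <- replicate(200, {
    ev <- cumsum(stats::rexp(2000, cmd))
    ev <- ev[ev < T]
    kept <- 0; last <- -Inf
    for (tt in ev) if (tt - last >= tref) { kept <- kept + 1; last <- tt }
    kept / T
  })
  expected <- mean(ref_rates)
  se <- stats::sd(ref_rates) / sqrt(length(ref_rates))
  rates <- tibble::tibble(t = seq(0, T - 1 / 200, by = 1 / 200), rate = cmd)
  ras <- encode_poisson_drive(rates, n_axons = 60, seed = 3)
  per_axon <- tabulate(ras$neuron, nbins = 60) / T
  expect_lt(abs(mean(per_axon) - expected),
            3 * (stats::sd(per_axon) / sqrt(60) + se))
  # the relayed rate tracks the command far better than chance
  expect_gt(mean(per_axon), 0.7 * cmd)
})

test_that("gait profiles round-trip through CSV", {
  p <- make_synthetic_gait("GM", n_steps = 1, cycle_duration = 0.7, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_gait_csv(p, f)
  q <- read_gait_csv(f)
  expect_equal(q$stretch, p$stretch, tolerance = 1e-6)
  expect_equal(attr(q, "muscle"), "GM")
  expect_equal(attr(q, "cycle_duration"), 0.7)
  unlink(f)
})

test_that("spike rasters round-trip through CSV with population sizes", {
  ras <- tibble::tibble(population = c("MN", "MN", "V2a"),
                        neuron = c(1L, 2L, 5L), t = c(0.1, 0.2, 0.15))
  attr(ras, "pop_sizes") <- c(MN = 169L, V2a = 196L)
  class(ras) <- c("spike_raster", class(ras))
  f <- tempfile(fileext = ".csv")
  write_raster_csv(ras, f)
  back <- read_raster_csv(f)
  expect_equal(back$t, ras$t)
  expect_equal(attr(back, "pop_sizes"), c(MN = 169L, V2a = 196L))
  unlink(f)
})
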