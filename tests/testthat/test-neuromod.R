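test_that("serotonin surrogate scales exactly the stated conductances", {
  specs <- population_specs()
  sci <- apply_serotonin(specs, serotonin_config(0.40))
  expect_equal(sci$gL[sci$name == "V2a"], 0.72)
  expect_equal(sci$gL[sci$name == "MN"], 27 * 0.6)
  bws <- apply_serotonin(specs, serotonin_config(0.15))
  expect_equal(bws$gL[bws$name == "MN"], 22.95)
  # all other parameters untouched
  expect_identical(sci$gL[!sci$name %in% c("MN", "V2a")],
                   specs$gL[!specs$name %in% c("MN", "V2a")])
  expect_identical(sci$C, specs$C)
  # zero reduction is the identity
  expect_equal(apply_serotonin(specs, serotonin_config(0))$gL, specs$gL)
  # guard against double application within one run
  expect_error(apply_serotonin(sci, serotonin_config(0.40)), "already")
  expect_error(serotonin_config(1.2), "0, 1")
})

test_that("ES fanout is an exact non-overlapping partition", {
  params <- spinalsnn:::expand_neurons(population_specs(), seed = 1)
  es <- spinalsnn:::build_es(es_protocol(), params)
  expect_equal(length(es$gids), 240)          # all afferent fibres
  expect_equal(anyDuplicated(es$gids), 0)
  per_src <- table(es$src)
  expect_true(all(per_src <= 3))
  expect_equal(es$n_src, 80)
  expect_equal(sort(unique(es$src)), 0:79)
})

test_that("ES event statistics follow the Poisson source rate", {
  # one axon driven by a suprathreshold pulse source: each event fires it
  ax <- axon_population_spec("Ia", 1, seed = 1)
  lif <- attr(ax, "lif")
  params <- tibble::tibble(population = "ax", neuron = 1L, kind = 0L,
                           C = ax$C_pF, gL = ax$gL_nS, EL = lif$EL,
                           Vth = lif$Vth, Vreset = lif$Vreset, DeltaV = 1,
                           a = 0, tauw = 1, b = 0, tref = lif$tref,
                           Vcut = lif$Vth, noise_sd = 0, gid = 0L)
  es <- list(gids = 0L, src = 0L, n_src = 1L, freq = 40,
             I_amp = ax$C_pF * 30 / 0.2, pw_steps = 4L)  # 30 mV: suprathreshold
  res <- spinalsnn:::run_core(params, spinalsnn:::empty_edges(), T_ms = 1e4,
                              es = es, seeds = c(1, 2, 3))
  n <- length(res$spike_t)
  expect_lt(abs(n - 400), 3 * sqrt(400) + 3)
  # frequency 0 produces no events at all
  es0 <- es; es0$freq <- 0
  res0 <- spinalsnn:::run_core(params, spinalsnn:::empty_edges(), T_ms = 1e3,
                               es = es0, seeds = c(1, 2, 3))
  expect_equal(length(res0$spike_t), 0)
})

test_that("photostimulation conditioning depresses the EPSP as designed", {
  ps <- fixture("photostim4", function() photostim_epsp_ratio(seeds = 1:4))
  expect_true(all(ps$per_seed$control > 0))
  expect_true(all(ps$per_seed$ratio < 1))
  # gate disabled -> no conditioning effect
  ps0 <- photostim_epsp_ratio(seeds = 1, lambda = 0)
  expect_equal(ps0$ratio, 1, tolerance = 1e-6)
  # stronger spillover -> stronger depression
  ps_hi <- photostim_epsp_ratio(seeds = 1, gaba_quantum = 0.4)
  expect_lt(ps_hi$per_seed$ratio[1], ps$per_seed$ratio[1])
})

test_that("recruitment thresholds order fibre classes and nest recruitment", {
  thr <- recruitment_thresholds(seed = 1)
  med <- thr %>% dplyr::group_by(population) %>%
    dplyr::summarise(m = stats::median(threshold_uA))
  expect_lt(med$m[med$population == "Ia_TA"], med$m[med$population == "II_TA"])
  expect_lt(med$m[med$population == "II_TA"], med$m[med$population == "MN"])
  # nested recruitment: the recruited set grows with amplitude
  amps <- c(50, 150, 300, 600)
  sets <- lapply(amps, function(a)
    which(thr$threshold_uA <= a))
  for (i in 2:4) expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("recruitment sweep produces evoked responses that grow then saturate", {
  rs <- fixture("recruit", function()
    recruitment_sweep(amplitudes = c(20, 150, 300, 600), seed = 1))
  w <- rs$windows
  expect_equal(nrow(w), 4)
  # amplitude below every threshold: flat trace
  expect_equal(w$er[1], 0)
  expect_equal(w$n_recruited[1], 0)
  # full recruitment yields the maximal early response of the sweep
  expect_equal(w$er[4], max(w$er))
  expect_gt(w$n_recruited[4], w$n_recruited[2])
})
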