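# Shared simulation fixtures, computed once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

baseline_run_8step <- function() {
  fixture("baseline8", function() {
    run_condition(condition_config("Baseline"), seed = 101)
  })
}

paired_bank <- function(seeds = 1:8) {
  fixture("bank", function() {
    list(
      base = lapply(seeds, function(s)
        run_condition(condition_config("Baseline"), seed = s)),
      sci = lapply(seeds, function(s)
        run_condition(condition_config("SCI"), seed = s))
    )
  })
}

# reference Euler relaxation of the release factor under a held spillover
# concentration (independent of the network core)
gate_relax <- function(C, T_s, lambda = 0.4, tau_ms = 20, dt_ms = 0.05) {
  g <- 1
  target <- min(max(1 - lambda * C, 0), 1)
  n <- round(T_s * 1e3 / dt_ms)
  for (i in seq_len(n)) g <- g + dt_ms / tau_ms * (target - g)
  g
}

# synthetic LMM recovery dataset: known condition trajectory with seed-level
# intercept effects of a chosen SD; the trajectory lives on the scale the
# weakly informative priors express
lmm_dataset <- function(sd_seed, n_seed = 8, sigma = 1, seed = 9,
                        condition = "Baseline") {
  set.seed(seed)
  d <- tidyr::expand_grid(condition = condition, seed = seq_len(n_seed),
                          step = 1:8)
  a_s <- rnorm(n_seed, 0, sd_seed)
  d$y <- 8 + 4 * sin(2 * pi * (d$step - 1) / 7) + a_s[d$seed] +
    rnorm(nrow(d), 0, sigma)
  d
}
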