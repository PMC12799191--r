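test_that("the B-spline design is a partition of unity with 8 columns", {
  d <- tidyr::expand_grid(condition = "A", seed = 1:3, step = 1:8)
  set.seed(1); d$y <- rnorm(nrow(d))
  bd <- build_design(d)
  expect_equal(ncol(bd$B), 8)          # 4 interior knots + degree 3 + 1
  expect_equal(rowSums(bd$B), rep(1, nrow(bd$B)), tolerance = 1e-12)
  expect_true(all(bd$t >= 0 & bd$t <= 1))
  # too few distinct time points for the basis dimension
  d4 <- tidyr::expand_grid(condition = "A", seed = 1:3, step = 1:4)
  d4$y <- rnorm(nrow(d4))
  expect_error(build_design(d4), "fewer distinct")
  # a single seed per condition is flagged as degenerate
  d1 <- tidyr::expand_grid(condition = "A", seed = 1, step = 1:8)
  d1$y <- rnorm(8)
  expect_true(build_design(d1)$degenerate_seed_block)
})

test_that("aggregation modes give the documented sample sizes", {
  d <- tidyr::expand_grid(condition = c("X", "Y"), seed = 1:6, step = 1:8)
  set.seed(2); d$y <- rnorm(nrow(d), 50, 5)
  m1 <- aggregate_for_stats(d, "across_seed_mean")
  expect_equal(nrow(m1), 2 * 8)
  m2 <- aggregate_for_stats(d, "per_seed_interstep")
  expect_equal(nrow(m2), 2 * 6)
  # constant input has zero inter-step differences
  dc <- d; dc$y <- 7
  expect_true(all(aggregate_for_stats(dc, "per_seed_interstep")$y == 0))
  # the across-seed mean averages exactly
  one <- d[d$condition == "X" & d$step == 1, ]
  expect_equal(m1$y[m1$condition == "X" & m1$step == 1], mean(one$y))
  dmiss <- d[!(d$condition == "X" & d$seed == 3), ]
  expect_error(aggregate_for_stats(dmiss), "full seed bank")
})

test_that("both likelihood formulations match numerical gradients", {
  d <- lmm_dataset(2, n_seed = 4, seed = 5)
  bd <- build_design(d)
  pr <- list(a = 10, beta = 2, sigma = 2, tau = 1, sigma_fixed = NULL)
  for (nm in c("latent", "marginal")) {
    lg <- if (nm == "latent") spinalsnn:::lmm_lp_grad(bd, pr) else
      spinalsnn:::lmm_marginal_lp_grad(bd, pr)
    idx <- if (nm == "latent") spinalsnn:::lmm_index(bd) else
      spinalsnn:::lmm_marginal_index(bd)
    set.seed(3)
    th <- rnorm(idx$dim, 0, 0.4)
    g <- lg(th)$grad
    gn <- vapply(seq_len(idx$dim), function(j) {
      e <- rep(0, idx$dim); e[j] <- 1e-5
      (lg(th + e)$lp - lg(th - e)$lp) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(g - gn)), 1e-4)
  }
})

test_that("the sampler recovers a known Gaussian target", {
  lg <- function(th) list(lp = -0.5 * sum(th^2 / c(4, 1, 0.25)),
                          grad = -th / c(4, 1, 0.25))
  fit <- nuts_sample(lg, rep(0, 3), n_warmup = 400, n_sample = 800,
                     chains = 2, seed = 2)
  sds <- apply(fit$draws, 3, sd)
  expect_equal(sds, c(2, 1, 0.5), tolerance = 0.1)
  expect_true(all(fit$divergences == 0))
  expect_lt(rhat(fit$draws[, , 1]), 1.05)
})

test_that("marginal and latent formulations agree on a small instance", {
  d <- lmm_dataset(2, n_seed = 4, seed = 5)
  fm <- fit_seed_equivalence(d, chains = 2, n_warmup = 400, n_sample = 600,
                             seed = 1, method = "marginal")
  fl <- fit_seed_equivalence(d, chains = 2, n_warmup = 400, n_sample = 600,
                             seed = 1, method = "latent")
  rm_ <- tidy(fm); rl <- tidy(fl)
  expect_equal(rm_$tau_a, rl$tau_a, tolerance = 0.25)
  expect_equal(rm_$p_tau_a, rl$p_tau_a, tolerance = 0.12)
  expect_equal(rm_$equivalent, rl$equivalent)
})

test_that("with an uninformative likelihood the scale posterior matches its prior", {
  d <- lmm_dataset(0, n_seed = 4, seed = 7)
  fit <- fit_seed_equivalence(d, chains = 2, n_warmup = 400, n_sample = 800,
                              seed = 3, priors = list(sigma_fixed = 1e6))
  tau <- abs(fit$draws[, fit$index$eta_a])
  # HalfNormal(1) prior mass below 1 is 2*pnorm(1) - 1
  expect_equal(mean(tau < 1), 2 * pnorm(1) - 1, tolerance = 0.08)
})

test_that("ROPE probabilities are invariant to chain relabelling", {
  d <- lmm_dataset(0, n_seed = 4, seed = 11)
  fit <- fit_seed_equivalence(d, chains = 2, n_warmup = 300, n_sample = 500,
                              seed = 5)
  dr <- fit$sampler$draws
  p12 <- mean(abs(c(dr[, 1, fit$index$eta_a], dr[, 2, fit$index$eta_a])) < 5)
  p21 <- mean(abs(c(dr[, 2, fit$index$eta_a], dr[, 1, fit$index$eta_a])) < 5)
  expect_identical(p12, p21)
})

test_that("seed_bank_rates summarises runs per seed and step", {
  cfg <- condition_config("Baseline", n_steps = 2)
  runs <- run_seed_bank(cfg, seeds = c(11, 12))
  sb <- seed_bank_rates(runs)
  expect_equal(nrow(sb), 4)
  expect_setequal(unique(sb$seed), c(11, 12))
  expect_true(all(sb$y >= 0))
})
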