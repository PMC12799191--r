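# No-U-Turn sampler (dynamic Hamiltonian Monte Carlo) with dual-averaging
# step-size adaptation and diagonal or dense mass-matrix estimation during
# warmup. Tree doubling uses multinomial sampling of the trajectory (leaves
# weighted by the joint density, new subtrees sampled with the biased
# progressive rule); a transition is flagged divergent when the joint log
# density falls 1000 below its initial value.

#' Sample from a log density with the No-U-Turn sampler
#'
#' Generic dynamic-HMC sampler used by the seed-equivalence model. The
#' target is supplied as a function returning the unnormalised log density
#' and its gradient on the unconstrained scale.
#'
#' @param lp_grad function `(theta) -> list(lp, grad)`.
#' @param init numeric initial position.
#' @param n_warmup,n_sample warmup and retained iterations per chain.
#' @param chains number of chains.
#' @param seed integer seed.
#' @param target_accept dual-averaging acceptance target.
#' @param max_treedepth maximum tree doublings per iteration.
#' @param dense_metric estimate a dense inverse mass matrix during warmup
#'   (suited to low-dimensional, correlated posteriors).
#' @return List with `draws` (n_sample x chains x dim), `energy`
#'   (n_sample x chains), `divergences` (per chain, sampling phase only),
#'   `step_size`, `accept_rate`.
#' @export
nuts_sample <- function(lp_grad, init, n_warmup = 1000, n_sample = 1000,
                        chains = 4, seed = 1L, target_accept = 0.9,
                        max_treedepth = 10, dense_metric = FALSE) {
  d <- length(init)
  draws <- array(NA_real_, c(n_sample, chains, d))
  energy <- matrix(NA_real_, n_sample, chains)
  div <- integer(chains)
  eps_out <- numeric(chains)
  acc_out <- numeric(chains)
  chain_seeds <- seed_streams(seed, chains)

  for (ch in seq_len(chains)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(chain_seeds[ch])
    res <- nuts_chain(lp_grad, init + rnorm(d, 0, 0.1), n_warmup, n_sample,
                      target_accept, max_treedepth, dense_metric)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    draws[, ch, ] <- res$draws
    energy[, ch] <- res$energy
    div[ch] <- res$divergences
    eps_out[ch] <- res$eps
    acc_out[ch] <- res$accept_rate
  }
  list(draws = draws, energy = energy, divergences = div,
       step_size = eps_out, accept_rate = acc_out)
}

nuts_chain <- function(lp_grad, theta, n_warmup, n_sample, target_accept,
                       max_treedepth, dense_metric = FALSE) {
  d <- length(theta)
  minv <- rep(1, d)               # inverse metric (posterior variances)
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) abort("non-finite log density at the initial point")

  eps <- find_epsilon(lp_grad, theta, cur, minv)
  mu <- log(10 * eps)
  log_eps_bar <- log(eps); H_bar <- 0; m_da <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75

  # warmup phases: step size | metric window | step size
  w1 <- max(25L, round(0.15 * n_warmup))
  w3 <- max(25L, round(0.10 * n_warmup))
  w2 <- seq.int(w1 + 1L, max(w1 + 2L, n_warmup - w3))
  acc_sum <- 0; acc_n <- 0
  win_sum <- numeric(d); win_sq <- numeric(d); win_n <- 0
  win_cross <- matrix(0, d, d)

  draws <- matrix(NA_real_, n_sample, d)
  energy <- numeric(n_sample)
  divergences <- 0L

  total <- n_warmup + n_sample
  for (it in seq_len(total)) {
    # jitter the step size to break trajectory-length resonances
    eps_it <- eps * runif(1, 0.9, 1.1)
    p0 <- draw_p(d, minv)
    joint0 <- cur$lp - kin_of(p0, minv)

    th_minus <- theta; th_plus <- theta
    p_minus <- p0; p_plus <- p0
    g_minus <- cur$grad; g_plus <- cur$grad
    lp_prop <- cur$lp; grad_prop <- cur$grad; theta_prop <- theta
    j <- 0L; lw_tree <- 0; s <- TRUE
    alpha_sum <- 0; n_alpha <- 0; diverged <- FALSE

    while (s && j < max_treedepth) {
      dir <- if (runif(1) < 0.5) -1 else 1
      if (dir == -1) {
        bt <- build_tree(lp_grad, th_minus, p_minus, g_minus, dir, j,
                         eps_it, joint0, minv)
        th_minus <- bt$th_minus; p_minus <- bt$p_minus; g_minus <- bt$g_minus
      } else {
        bt <- build_tree(lp_grad, th_plus, p_plus, g_plus, dir, j,
                         eps_it, joint0, minv)
        th_plus <- bt$th_plus; p_plus <- bt$p_plus; g_plus <- bt$g_plus
      }
      # biased progressive sampling: favour the new subtree
      if (bt$s && runif(1) < exp(bt$lw - lw_tree)) {
        theta_prop <- bt$theta_prop; lp_prop <- bt$lp_prop
        grad_prop <- bt$grad_prop
      }
      lw_tree <- log_add(lw_tree, bt$lw)
      alpha_sum <- alpha_sum + bt$alpha; n_alpha <- n_alpha + bt$n_alpha
      if (bt$diverged) diverged <- TRUE
      dth <- th_plus - th_minus
      s <- bt$s && sum(dth * vel_of(p_minus, minv)) >= 0 &&
        sum(dth * vel_of(p_plus, minv)) >= 0
      j <- j + 1L
    }
    theta <- theta_prop
    cur <- list(lp = lp_prop, grad = grad_prop)
    alpha_mean <- if (n_alpha > 0) alpha_sum / n_alpha else 0

    if (it <= n_warmup) {
      m_da <- m_da + 1
      H_bar <- (1 - 1 / (m_da + t0)) * H_bar +
        (target_accept - alpha_mean) / (m_da + t0)
      log_eps <- mu - sqrt(m_da) / gamma * H_bar
      w <- m_da^(-kappa)
      log_eps_bar <- w * log_eps + (1 - w) * log_eps_bar
      eps <- exp(log_eps)
      if (it %in% w2) {
        win_sum <- win_sum + theta; win_sq <- win_sq + theta^2
        if (dense_metric) win_cross <- win_cross + tcrossprod(theta)
        win_n <- win_n + 1
        if (it == max(w2) && win_n > 10) {
          v <- win_sq / win_n - (win_sum / win_n)^2
          if (dense_metric && win_n > d) {
            S <- (win_cross - tcrossprod(win_sum) / win_n) / (win_n - 1)
            # shrink towards the diagonal for stability
            S <- 0.9 * S + 0.1 * diag(pmax(v, 1e-8), d)
            M <- tryCatch(solve(S), error = function(e) NULL)
            if (!is.null(M)) {
              minv <- list(mat = S, chol_m = t(chol(M)))
            } else minv <- pmax(v, 1e-8)
          } else {
            minv <- pmax(v, 1e-8)
          }
          eps <- find_epsilon(lp_grad, theta, cur, minv)
          mu <- log(10 * eps); H_bar <- 0
          log_eps_bar <- log(eps); m_da <- 0
        }
      }
      if (it == n_warmup) eps <- exp(log_eps_bar)
    } else {
      k <- it - n_warmup
      draws[k, ] <- theta
      energy[k] <- -joint0
      if (diverged) divergences <- divergences + 1L
      acc_sum <- acc_sum + alpha_mean; acc_n <- acc_n + 1
    }
  }
  list(draws = draws, energy = energy, divergences = divergences,
       eps = eps, accept_rate = if (acc_n) acc_sum / acc_n else NA_real_)
}


# metric helpers: `minv` is either a vector (diagonal inverse metric) or a
# list(mat = inverse metric, chol_m = chol of the metric) for a dense one
vel_of <- function(p, minv) {
  if (is.list(minv)) as.numeric(minv$mat %*% p) else p * minv
}
kin_of <- function(p, minv) {
  0.5 * sum(p * vel_of(p, minv))
}
draw_p <- function(d, minv) {
  z <- rnorm(d)
  if (is.list(minv)) as.numeric(minv$chol_m %*% z) else z / sqrt(minv)
}

log_add <- function(a, b) {
  if (a == -Inf) return(b)
  if (b == -Inf) return(a)
  m <- max(a, b)
  m + log1p(exp(min(a, b) - m))
}

build_tree <- function(lp_grad, th, p, g, dir, j, eps, joint0, minv) {
  if (j == 0L) {
    lf <- leapfrog(lp_grad, th, p, g, dir * eps, minv)
    joint <- lf$lp - kin_of(lf$p, minv)
    lw <- joint - joint0                 # multinomial leaf weight
    diverged <- !is.finite(joint) || lw < -1000
    if (!is.finite(lw)) lw <- -Inf
    alpha <- min(1, exp(lw))
    if (!is.finite(alpha)) alpha <- 0
    return(list(th_minus = lf$th, p_minus = lf$p, g_minus = lf$grad,
                th_plus = lf$th, p_plus = lf$p, g_plus = lf$grad,
                theta_prop = lf$th, lp_prop = lf$lp, grad_prop = lf$grad,
                lw = lw, s = !diverged, alpha = alpha, n_alpha = 1L,
                diverged = diverged))
  }
  b1 <- build_tree(lp_grad, th, p, g, dir, j - 1L, eps, joint0, minv)
  if (!b1$s) return(b1)
  if (dir == -1) {
    b2 <- build_tree(lp_grad, b1$th_minus, b1$p_minus, b1$g_minus, dir,
                     j - 1L, eps, joint0, minv)
    b1$th_minus <- b2$th_minus; b1$p_minus <- b2$p_minus
    b1$g_minus <- b2$g_minus
  } else {
    b2 <- build_tree(lp_grad, b1$th_plus, b1$p_plus, b1$g_plus, dir,
                     j - 1L, eps, joint0, minv)
    b1$th_plus <- b2$th_plus; b1$p_plus <- b2$p_plus; b1$g_plus <- b2$g_plus
  }
  lw12 <- log_add(b1$lw, b2$lw)
  # uniform multinomial sampling within the combined subtree
  if (b2$s && lw12 > -Inf && runif(1) < exp(b2$lw - lw12)) {
    b1$theta_prop <- b2$theta_prop; b1$lp_prop <- b2$lp_prop
    b1$grad_prop <- b2$grad_prop
  }
  dth <- b1$th_plus - b1$th_minus
  b1$s <- b2$s && sum(dth * vel_of(b1$p_minus, minv)) >= 0 &&
    sum(dth * vel_of(b1$p_plus, minv)) >= 0
  b1$lw <- lw12
  b1$alpha <- b1$alpha + b2$alpha
  b1$n_alpha <- b1$n_alpha + b2$n_alpha
  b1$diverged <- b1$diverged || b2$diverged
  b1
}

leapfrog <- function(lp_grad, th, p, g, eps, minv) {
  p <- p + 0.5 * eps * g
  th <- th + eps * vel_of(p, minv)
  new <- lp_grad(th)
  if (!is.finite(new$lp)) {
    new$lp <- -Inf
    new$grad <- numeric(length(th))
  }
  p <- p + 0.5 * eps * new$grad
  list(th = th, p = p, lp = new$lp, grad = new$grad)
}

find_epsilon <- function(lp_grad, theta, cur, minv) {
  eps <- 0.1
  p <- draw_p(length(theta), minv)
  joint0 <- cur$lp - kin_of(p, minv)
  lf <- leapfrog(lp_grad, theta, p, cur$grad, eps, minv)
  joint <- lf$lp - kin_of(lf$p, minv)
  a <- if (is.finite(joint) && joint - joint0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^a
    lf <- leapfrog(lp_grad, theta, p, cur$grad, eps, minv)
    joint <- lf$lp - kin_of(lf$p, minv)
    ok <- is.finite(joint) && a * (joint - joint0) > a * log(0.5)
    if (!ok) break
  }
  max(eps, 1e-6)
}

#' Split-chain Gelman-Rubin statistic
#'
#' @param x draws matrix (iterations x chains) for one parameter.
#' @return Potential scale reduction factor.
#' @export
rhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  B <- nn * var(mu)
  W <- mean(apply(sp, 2, var))
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# Bayesian fraction of missing information, per chain
bfmi <- function(energy) {
  apply(energy, 2, function(e) {
    v <- var(e)
    if (v == 0) return(NA_real_)
    sum(diff(e)^2) / (length(e) - 1) / v
  })
}
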