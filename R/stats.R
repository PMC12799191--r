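#' Two one-sided tests (TOST) for practical equivalence
#'
#' Paired-difference equivalence test at level `alpha` against symmetric
#' bounds (default +/- 15 Hz, half the minimal rodent TA burst rate at
#' rest). Equivalence is concluded when both one-sided tests reject, i.e.
#' the larger of the two p-values falls below `alpha`. An optional log
#' transform (log1p) is applied to both samples before differencing.
#'
#' @param x,y paired samples (same length and ordering).
#' @param bounds equivalence bounds (same units as the data).
#' @param alpha test level.
#' @param log_transform apply `log1p` before differencing (bounds then act
#'   on the log scale).
#' @return Tibble with `p_lower`, `p_upper`, `p_tost`, `equivalent`,
#'   `mean_diff`.
#' @export
#' @examples
#' tost_equivalence(rnorm(20, 50, 2), rnorm(20, 51, 2))
tost_equivalence <- function(x, y, bounds = 15, alpha = 0.05,
                             log_transform = FALSE) {
  if (length(x) != length(y)) abort("paired samples must have equal length")
  if (log_transform) { x <- log1p(x); y <- log1p(y) }
  d <- x - y
  n <- length(d)
  se <- sd(d) / sqrt(n)
  if (se == 0) {
    eq <- abs(mean(d)) < bounds
    return(tibble(p_lower = as.numeric(!eq), p_upper = as.numeric(!eq),
                  p_tost = as.numeric(!eq), equivalent = eq,
                  mean_diff = mean(d)))
  }
  t_lower <- (mean(d) + bounds) / se   # H0: diff <= -bounds
  t_upper <- (mean(d) - bounds) / se   # H0: diff >= +bounds
  p_lower <- stats::pt(t_lower, n - 1, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, n - 1)
  p <- max(p_lower, p_upper)
  tibble(p_lower = p_lower, p_upper = p_upper, p_tost = p,
         equivalent = p < alpha, mean_diff = mean(d))
}

#' Paired difference test with a normality gate
#'
#' Shapiro-Wilk on the paired differences decides the test: paired t-test
#' when normality is not rejected (p > 0.05), Wilcoxon signed-rank
#' otherwise.
#'
#' @param x,y paired samples.
#' @return Tibble with `shapiro_p`, `test`, `p_value`, `mean_diff`.
#' @export
paired_difference_test <- function(x, y) {
  if (length(x) != length(y)) abort("paired samples must have equal length")
  d <- x - y
  if (all(d == d[1])) {
    return(tibble(shapiro_p = NA_real_, test = "degenerate",
                  p_value = if (d[1] == 0) 1 else 0, mean_diff = mean(d)))
  }
  sw <- shapiro.test(d)$p.value
  if (sw > 0.05) {
    ht <- t.test(x, y, paired = TRUE)
    tibble(shapiro_p = sw, test = "paired t",
           p_value = ht$p.value, mean_diff = mean(d))
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE))
    tibble(shapiro_p = sw, test = "wilcoxon",
           p_value = ht$p.value, mean_diff = mean(d))
  }
}

#' Within-timestep permutation test between two conditions
#'
#' At each timestep, the paired condition labels are permuted within each
#' seed (sign flips of the paired differences) and the observed mean
#' difference is compared with the permutation distribution (2000
#' repetitions by default). Returns a two-sided permutation p-value per
#' timestep.
#'
#' @param a,b matrices (seeds x timesteps) of paired observations.
#' @param n_perm permutation repetitions.
#' @param seed integer seed.
#' @return Tibble `(timestep, observed, p_value)`.
#' @export
permutation_timestep_test <- function(a, b, n_perm = 2000, seed = 1L) {
  if (!all(dim(a) == dim(b))) abort("`a` and `b` must have matching dimensions")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  d <- a - b
  ns <- nrow(d); nt <- ncol(d)
  obs <- colMeans(d)
  signs <- matrix(sample(c(-1, 1), ns * n_perm, replace = TRUE), ns, n_perm)
  p <- vapply(seq_len(nt), function(j) {
    perm <- crossprod(signs, d[, j]) / ns
    (sum(abs(perm) >= abs(obs[j])) + 1) / (n_perm + 1)
  }, numeric(1))
  tibble(timestep = seq_len(nt), observed = obs, p_value = p)
}

#' Frequentist comparison report for two conditions
#'
#' Runs the full battery used for condition contrasts on matched phase
#' summaries: Shapiro-gated paired test, TOST equivalence at +/- 15 Hz,
#' and (when timestep matrices are supplied) within-timestep permutation
#' tests with 2000 repetitions.
#'
#' @param x,y matched numeric vectors (e.g. per-step phase means).
#' @param bounds TOST equivalence bounds (Hz).
#' @param log_transform pass `TRUE` to TOST on log1p scale.
#' @return Tibble combining the paired test and TOST columns.
#' @export
frequentist_tests <- function(x, y, bounds = 15, log_transform = FALSE) {
  dplyr::bind_cols(
    paired_difference_test(x, y),
    tost_equivalence(x, y, bounds = bounds, log_transform = log_transform) %>%
      dplyr::rename_with(~ paste0("tost_", .x))
  )
}
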