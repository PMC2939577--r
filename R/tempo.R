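#' The gamma statistic of Pybus and Harvey
#'
#' Summarises whether the internal nodes of an ultrametric tree cluster
#' toward the root (gamma < 0, an apparent slowdown in cladogenesis) or
#' toward the tips (gamma > 0) relative to the constant-rate pure-birth
#' expectation. With cumulative lineage-times
#' \eqn{T_i = \sum_{k=2}^{i} k\, g_k} and total \eqn{T = T_n},
#' \deqn{\gamma = \frac{\frac{1}{n-2}\sum_{i=2}^{n-1} T_i - T/2}
#'   {T \sqrt{1 / (12 (n-2))}}.}
#' On completely sampled pure-birth trees gamma is asymptotically standard
#' normal; it is exactly invariant to rescaling all branch lengths.
#'
#' @param x a chronogram, a `"branching_times"` object, or a numeric vector
#'   of node ages (n >= 3 tips required).
#' @return an object of class `"gamma_result"`: list with `gamma`, `n`, and
#'   `p_one_tailed` (standard normal lower-tail probability).
#' @examples
#' gamma_stat(branching_times(c(3, 2, 1)))$gamma  # -0.5443
#' @references Pybus, O.G. & Harvey, P.H. (2000) Proc. R. Soc. B 267:2267-2272.
#' @export
gamma_stat <- function(x) {
  bt <- as_branching_times(x)
  n <- bt$n
  if (n < 3L) stop("gamma requires at least 3 tips")
  Tn <- bt$total_time
  if (Tn <= 0) stop("degenerate tree: total lineage-time is zero")
  Tcum <- cumsum((2:n) * bt$g)          # T_i for i = 2..n
  num <- mean(Tcum[seq_len(n - 2L)]) - Tn / 2
  gam <- num / (Tn * sqrt(1 / (12 * (n - 2))))
  structure(list(gamma = gam, n = n, p_one_tailed = stats::pnorm(gam)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma = %.4f (n = %d), one-tailed P(N(0,1) <= gamma) = %.4f\n",
              x$gamma, x$n, x$p_one_tailed))
  invisible(x)
}

#' Constant-rates (CR) test
#'
#' Compares an observed gamma statistic with the standard normal null of the
#' completely sampled constant-rate (pure-birth) process. The default
#' orientation tests for a *decrease* in diversification rate through time
#' (lower tail; reject when gamma < -1.645 at alpha = 0.05); an upper-tail
#' orientation for rate increases and a two-tailed version are available.
#' The tail used is recorded in the result.
#'
#' @param g a `"gamma_result"`, or a numeric gamma value.
#' @param tail `"decrease"` (lower tail, default), `"increase"`, or `"two"`.
#' @param alpha significance level.
#' @return an object of class `"cr_test"`: list with `gamma`, `tail`, `p`,
#'   `critical` (the gamma cutoff at `alpha` for one-tailed orientations) and
#'   `reject`.
#' @examples
#' cr_test(gamma_stat(simulate_yule(50, seed = 1)))
#' cr_test(-1.645)$p  # 0.05 boundary
#' @export
cr_test <- function(g, tail = c("decrease", "increase", "two"), alpha = 0.05) {
  tail <- match.arg(tail)
  gam <- if (inherits(g, "gamma_result")) g$gamma else as.numeric(g)
  p <- switch(tail,
              decrease = stats::pnorm(gam),
              increase = stats::pnorm(gam, lower.tail = FALSE),
              two = 2 * stats::pnorm(-abs(gam)))
  crit <- switch(tail,
                 decrease = stats::qnorm(alpha),
                 increase = stats::qnorm(1 - alpha),
                 two = NA_real_)
  structure(list(gamma = gam, tail = tail, alpha = alpha, p = p,
                 critical = crit, reject = p < alpha),
            class = "cr_test")
}

#' @export
print.cr_test <- function(x, ...) {
  cat(sprintf("CR test (%s): gamma = %.4f, p = %.4f -> %s at alpha = %g\n",
              x$tail, x$gamma, x$p,
              if (x$reject) "reject constant rates" else "no rejection",
              x$alpha))
  invisible(x)
}

#' Monte Carlo constant-rates (MCCR) test for incompletely sampled trees
#'
#' Random incomplete taxon sampling shifts the null distribution of gamma
#' negative (subsampling makes deep nodes look over-represented), inflating
#' the type I error of the CR test. The MCCR test rebuilds the null: `reps`
#' pure-birth trees of the clade's true richness `N_total` are simulated,
#' each is randomly subsampled to the observed tip count `m`, and gamma is
#' computed on each subsampled tree. Because gamma is invariant to time
#' rescaling, the null trees are simulated at unit speciation rate. The
#' default orientation tests for a rate decrease (lower tail).
#'
#' Two p-values are reported: the add-one permutation-style estimator
#' \eqn{p = (1 + \#\{\gamma_{null} \le \gamma_{obs}\})/(reps + 1)} (never
#' exactly 0) and the plain proportion.
#'
#' @param gamma_obs observed gamma (numeric or `"gamma_result"`).
#' @param N_total true extant richness of the clade (>= m).
#' @param m number of sampled tips the observed gamma was computed from.
#' @param reps number of null simulations (>= 100).
#' @param seed optional integer seed (null is reproducible bit-for-bit).
#' @param alpha significance level.
#' @return an object of class `"mccr_result"`: list with `gamma_obs`,
#'   `N_total`, `m`, `reps`, `seed`, `null` (the simulated gamma sample),
#'   `critical` (5th percentile of the null at `alpha = 0.05`), `p` (add-one),
#'   `p_plain`, and `reject`.
#' @examples
#' \donttest{
#' g <- gamma_stat(subsample_tips(simulate_yule(500, seed = 1), 50, seed = 2))
#' mccr_test(g, N_total = 500, m = 50, reps = 200, seed = 3)
#' }
#' @export
mccr_test <- function(gamma_obs, N_total, m, reps = 1000L, seed = NULL,
                      alpha = 0.05) {
  gam <- if (inherits(gamma_obs, "gamma_result")) gamma_obs$gamma
         else as.numeric(gamma_obs)
  N_total <- as.integer(N_total)
  m <- as.integer(m)
  reps <- as.integer(reps)
  if (m < 3L || m > N_total) stop("need 3 <= m <= N_total")
  if (reps < 100L) stop("'reps' must be at least 100")
  if (N_total > 1e6) warning("N_total > 1e6: null simulation will be slow")
  null <- with_seed(seed, vapply(seq_len(reps), function(i)
    gamma_stat(branching_times(.yule_subsampled_x(N_total, m)))$gamma,
    numeric(1)))
  crit <- unname(stats::quantile(null, alpha))
  p <- (1 + sum(null <= gam)) / (reps + 1)
  structure(list(gamma_obs = gam, N_total = N_total, m = m, reps = reps,
                 seed = seed, null = null, critical = crit,
                 p = p, p_plain = mean(null <= gam), alpha = alpha,
                 reject = gam < crit),
            class = "mccr_result")
}

#' @export
print.mccr_result <- function(x, ...) {
  cat(sprintf(
    paste0("MCCR test: gamma_obs = %.4f, N_total = %d sampled to m = %d, ",
           "%d reps\n  null 5th percentile = %.3f; p = %.4f (add-one), ",
           "%.4f (plain) -> %s\n"),
    x$gamma_obs, x$N_total, x$m, x$reps, x$critical, x$p, x$p_plain,
    if (x$reject) "reject constant rates" else "no rejection"))
  invisible(x)
}

#' Lineages-through-time curve
#'
#' The step function of the reconstructed lineage count against time before
#' present: 2 lineages at the crown, increasing by 1 at every branching
#' event (tied events appear as simultaneous steps), reaching the tip count
#' at the present.
#'
#' @param x a chronogram, `"branching_times"` object, or vector of node ages.
#' @return a data frame of class `"ltt"` with columns `time_My` (descending,
#'   ending at 0) and `lineages`.
#' @examples
#' ltt(branching_times(c(3, 2, 1)))
#' @export
ltt <- function(x) {
  bt <- as_branching_times(x)
  out <- data.frame(time_My = c(bt$x, 0),
                    lineages = c(2:bt$n, bt$n))
  class(out) <- c("ltt", "data.frame")
  out
}

# lineage count of an LTT at arbitrary times-before-present: the count at
# time t is 1 + #{branching ages >= t} (so exactly 2 at the crown, n at 0)
.ltt_at <- function(xdesc, times) {
  xasc <- rev(xdesc)
  1L + length(xasc) - findInterval(times, xasc, left.open = TRUE)
}

#' Simulation envelope for lineages-through-time curves
#'
#' Simulates `reps` pure-birth trees of `n_total` tips, randomly subsamples
#' each to `m` tips, and summarises the lineage-count step functions on a
#' common relative-time grid (0 = crown, 1 = present, `grid_points` points):
#' the pointwise mean and the 2.5% / 97.5% envelope. Relative time is used so
#' that trees with different crown ages can be averaged; with `m = n_total`
#' the mean curve is the straight semilog line of the constant-rate process,
#' while subsampling bends the mean curve downward toward the present.
#'
#' @param n_total tips of the full simulated trees.
#' @param m tips retained after random subsampling (default: no subsampling).
#' @param reps number of simulated trees.
#' @param lam speciation rate of the simulated trees (the envelope *shape*
#'   in relative time does not depend on it).
#' @param seed optional integer seed.
#' @param grid_points number of relative-time grid points.
#' @param empirical optional chronogram (or branching times) overlaid on the
#'   same relative grid and returned as column `empirical`.
#' @return a data frame of class `"ltt_envelope"` with columns `rel_time`,
#'   `time_My` (mean crown age scale), `mean`, `lo`, `hi` and optionally
#'   `empirical`; simulation settings are in attributes.
#' @examples
#' \donttest{
#' env <- ltt_envelope(200, m = 50, reps = 100, seed = 1)
#' head(env)
#' }
#' @export
ltt_envelope <- function(n_total, m = n_total, reps = 1000L, lam = 1,
                         seed = NULL, grid_points = 256L, empirical = NULL) {
  n_total <- as.integer(n_total)
  m <- as.integer(m)
  stopifnot(n_total >= 3, m >= 3, m <= n_total, reps >= 2)
  grid <- seq(0, 1, length.out = grid_points)
  counts <- matrix(0, nrow = reps, ncol = grid_points)
  crowns <- numeric(reps)
  with_seed(seed, {
    for (i in seq_len(reps)) {
      xs <- .yule_subsampled_x(n_total, m, lam = lam)
      crowns[i] <- xs[1]
      counts[i, ] <- .ltt_at(xs, (1 - grid) * xs[1])
    }
  })
  out <- data.frame(rel_time = grid,
                    time_My = (1 - grid) * mean(crowns),
                    mean = colMeans(counts),
                    lo = apply(counts, 2, stats::quantile, 0.025),
                    hi = apply(counts, 2, stats::quantile, 0.975))
  if (!is.null(empirical)) {
    bt <- as_branching_times(empirical)
    out$empirical <- .ltt_at(bt$x, (1 - grid) * bt$x[1])
  }
  attr(out, "spec") <- list(n_total = n_total, m = m, reps = reps,
                            lam = lam, seed = seed)
  class(out) <- c("ltt_envelope", "data.frame")
  out
}
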