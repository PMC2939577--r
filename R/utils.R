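# Internal numeric and RNG helpers shared across modules.

# Run expr with a locally seeded RNG when `seed` is non-NULL, restoring the
# caller's RNG state afterwards so simulators compose predictably.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# log(1 + exp(v)) without overflow
log1pexp <- function(v) {
  out <- v
  lo <- v <= 35
  out[lo] <- log1p(exp(v[lo]))
  out
}

# 15-point Gauss-Legendre nodes/weights on [-1, 1]
.gl15 <- local({
  gj <- function(n) {
    # Golub-Welsch: eigen decomposition of the Jacobi matrix
    i <- seq_len(n - 1)
    b <- i / sqrt(4 * i^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- b
    J[cbind(i + 1, i)] <- b
    e <- eigen(J, symmetric = TRUE)
    idx <- order(e$values)
    list(x = e$values[idx], w = 2 * e$vectors[1, idx]^2)
  }
  gj(15L)
})

# Cumulative integrals of exp(logf(u)) between consecutive knots, in log space.
# Returns the log of I(knots[j]) = int_{knots[1]}^{knots[j]} exp(logf(u)) du for
# every knot. Integrand must be continuous; knots ascending. Each panel is
# integrated by 15-point Gauss-Legendre and bisected until successive estimates
# agree to `rel_tol` (adaptive composite scheme; log-space accumulation).
cum_log_quad <- function(logf, knots, rel_tol = 1e-9, max_depth = 40L) {
  stopifnot(length(knots) >= 1, !is.unsorted(knots))
  nk <- length(knots)
  panel <- function(a, b) {
    # returns log integral over [a, b]
    if (b <= a) return(-Inf)
    half <- (b - a) / 2
    mid <- (a + b) / 2
    v <- logf(mid + half * .gl15$x)
    m <- max(v)
    if (!is.finite(m)) return(-Inf)
    m + log(sum(.gl15$w * exp(v - m)) * half)
  }
  refine <- function(a, b, whole, depth) {
    mid <- (a + b) / 2
    l <- panel(a, mid); r <- panel(mid, b)
    comb <- logsum2(l, r)
    if (depth >= max_depth ||
        (is.infinite(comb) && is.infinite(whole)) ||
        abs(exp(min(comb, whole) - max(comb, whole)) - 1) < rel_tol)
      return(comb)
    logsum2(refine(a, mid, l, depth + 1L), refine(mid, b, r, depth + 1L))
  }
  out <- numeric(nk)
  out[1] <- -Inf
  acc <- -Inf
  for (j in seq_len(nk - 1L)) {
    a <- knots[j]; b <- knots[j + 1L]
    w <- panel(a, b)
    w <- refine(a, b, w, 1L)
    acc <- logsum2(acc, w)
    out[j + 1L] <- acc
  }
  out
}

# log(exp(a) + exp(b)) for scalars, tolerating -Inf
logsum2 <- function(a, b) {
  m <- max(a, b)
  if (!is.finite(m)) return(-Inf)
  m + log1p(exp(min(a, b) - m))
}
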