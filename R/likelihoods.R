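# Reconstructed-process log-likelihoods for branching times.
#
# All six models share one crown-conditioned convention: the process starts
# with 2 lineages at the crown age x_2, both of which must leave surviving
# descendants, and the model-independent combinatorial constant
# sum_{k=2}^{n-1} log k (= log (n-1)!) is retained in every likelihood so
# that log-likelihoods and AICs are directly comparable across models.
# Conditioning identity used throughout: T = 2*x_2 + sum_{i>=3} x_i.

#' Pure-birth (Yule) log-likelihood
#'
#' Crown-conditioned reconstructed pure-birth log-likelihood
#' \deqn{\ln L = \sum_{k=2}^{n-1} \ln(k\lambda) - \lambda T,}
#' with \eqn{T} the total lineage-time. The maximum-likelihood estimate is
#' closed-form: \eqn{\hat\lambda = (n-2)/T}.
#'
#' @param x branching times (chronogram, `"branching_times"`, or age vector).
#' @param lam speciation rate (> 0), per My.
#' @return the log-likelihood (natural log).
#' @examples
#' loglik_pure_birth(branching_times(c(3, 2, 1)), 1)  # log 2 + log 3 - 9
#' @export
loglik_pure_birth <- function(x, lam) {
  bt <- as_branching_times(x)
  if (!isTRUE(lam > 0)) stop("'lam' must be > 0")
  lgamma(bt$n) + (bt$n - 2) * log(lam) - lam * bt$total_time
}

#' Constant-rate birth-death log-likelihood
#'
#' Nee-May-Harvey reconstructed-process log-likelihood for constant
#' speciation \eqn{\lambda} and extinction \eqn{\mu}, parameterised by the
#' net rate \eqn{r = \lambda - \mu} and extinction fraction
#' \eqn{a = \mu/\lambda}:
#' \deqn{\ln L = \sum_{k=2}^{n-1}\ln k + (n-2)\ln r + r \sum_{i\ge3} x_i +
#'   n \ln(1-a) - 2 \sum_{i=2}^{n} \ln(e^{r x_i} - a),}
#' with the same crown conditioning as [loglik_pure_birth()]; at `a = 0` the
#' two are identical.
#'
#' @param x branching times.
#' @param r_net net diversification rate (> 0), per My.
#' @param a extinction fraction in `[0, 1)`.
#' @return the log-likelihood.
#' @examples
#' bt <- branching_times(c(3, 2, 1))
#' loglik_bd(bt, 1, 0) == loglik_pure_birth(bt, 1)
#' @export
loglik_bd <- function(x, r_net, a = 0) {
  bt <- as_branching_times(x)
  if (!isTRUE(r_net > 0)) stop("'r_net' must be > 0")
  if (!isTRUE(a >= 0 && a < 1)) stop("'a' must be in [0, 1)")
  n <- bt$n
  xs <- bt$x
  # log(e^{r x} - a) computed stably as r x + log1p(-a e^{-r x})
  lgamma(n) + (n - 2) * log(r_net) + r_net * sum(xs[-1]) + n * log1p(-a) -
    2 * sum(r_net * xs + log1p(-a * exp(-r_net * xs)))
}

# General time-varying reconstructed-process log-likelihood, crown
# conditioned on the survival of both crown lineages. Rates are functions of
# BACKWARD time u (My before present); rho_bw(u) = int_0^u (lambda - mu) and
# log_mu_bw(u) = log mu(u) must be supplied (closed forms per model). With
# E(u) the extinction probability of a lineage alive at u,
#   1 - E(u) = 1 / (1 + e^{-rho(u)} I(u)),  I(u) = int_0^u mu(s) e^{rho(s)} ds,
# the log-likelihood is
#   log (n-1)! + sum_{i>=3} log lambda(x_i) + 2 sum_{i>=2} log(1 - E(x_i))
#     - 2 rho(x_2) - sum_{i>=3} rho(x_i).
# For constant rates this reduces analytically to loglik_bd.
.loglik_timevar <- function(bt, log_lam_bw, rho_bw, log_mu_bw = NULL,
                            rel_tol = 1e-9) {
  n <- bt$n
  xs <- bt$x                              # descending, xs[1] = crown
  rho_x <- rho_bw(xs)
  if (is.null(log_mu_bw)) {
    log_one_minus_E <- numeric(n - 1L)
  } else {
    knots <- sort(unique(c(0, xs)))
    logI_knots <- cum_log_quad(function(u) log_mu_bw(u) + rho_bw(u),
                               knots, rel_tol = rel_tol)
    logI_x <- logI_knots[match(xs, knots)]
    log_one_minus_E <- -log1pexp(logI_x - rho_x)
  }
  lgamma(n) + sum(log_lam_bw(xs[-1])) + 2 * sum(log_one_minus_E) -
    2 * rho_x[1] - sum(rho_x[-1])
}

#' Declining-speciation (SPVAR) log-likelihood
#'
#' Time-varying reconstructed-process likelihood with exponentially decaying
#' speciation and constant extinction:
#' \eqn{\lambda(t) = \lambda_0 e^{-k t}} with \eqn{t} measured forward from
#' the crown, and \eqn{\mu(t) = \mu_0}. At `kdecay = 0` this is the constant
#' birth-death model; with `mu0 = 0` as well, the pure-birth model. The
#' extinction-survival integral has no elementary form and is evaluated by
#' adaptive composite Gauss-Legendre quadrature with panels anchored at the
#' branching times.
#'
#' @param x branching times.
#' @param lam0 initial speciation rate at the crown (> 0).
#' @param kdecay exponential decay rate of speciation (>= 0), per My.
#' @param mu0 constant extinction rate (>= 0).
#' @return the log-likelihood.
#' @export
loglik_spvar <- function(x, lam0, kdecay, mu0 = 0) {
  bt <- as_branching_times(x)
  if (!isTRUE(lam0 > 0) || !isTRUE(kdecay >= 0) || !isTRUE(mu0 >= 0))
    stop("need lam0 > 0, kdecay >= 0, mu0 >= 0")
  x2 <- bt$x[1]
  # backward time u: lambda(u) = lam0 * exp(-kdecay * (x2 - u))
  log_lam_bw <- function(u) log(lam0) - kdecay * (x2 - u)
  Lam <- if (kdecay > 0)
    function(u) (lam0 / kdecay) * (exp(kdecay * (u - x2)) - exp(-kdecay * x2))
  else function(u) lam0 * u
  rho_bw <- function(u) Lam(u) - mu0 * u
  log_mu_bw <- if (mu0 > 0) function(u) rep(log(mu0), length(u)) else NULL
  .loglik_timevar(bt, log_lam_bw, rho_bw, log_mu_bw)
}

#' Rising-extinction (EXVAR) log-likelihood
#'
#' Time-varying reconstructed-process likelihood with constant speciation
#' \eqn{\lambda_0} and extinction rising toward the present:
#' \eqn{\mu(t) = \mu_0 (1 - e^{-z t})} with \eqn{t} forward from the crown.
#' Limits: `mu0 = 0` recovers the pure-birth model; `z` large recovers the
#' constant birth-death model with extinction `mu0`.
#'
#' @param x branching times.
#' @param lam0 speciation rate (> 0).
#' @param mu0 asymptotic extinction rate (>= 0).
#' @param z onset rate of extinction (>= 0), per My.
#' @return the log-likelihood.
#' @export
loglik_exvar <- function(x, lam0, mu0 = 0, z = 0) {
  bt <- as_branching_times(x)
  if (!isTRUE(lam0 > 0) || !isTRUE(mu0 >= 0) || !isTRUE(z >= 0))
    stop("need lam0 > 0, mu0 >= 0, z >= 0")
  x2 <- bt$x[1]
  # backward time u: mu(u) = mu0 * (1 - exp(-z * (x2 - u)))
  log_lam_bw <- function(u) rep(log(lam0), length(u))
  M <- if (z > 0)
    function(u) mu0 * u - (mu0 / z) * (exp(z * (u - x2)) - exp(-z * x2))
  else function(u) 0 * u
  rho_bw <- function(u) lam0 * u - M(u)
  log_mu_bw <- if (mu0 > 0 && z > 0)
    function(u) log(mu0) + log1p(-exp(z * (u - x2))) else NULL
  .loglik_timevar(bt, log_lam_bw, rho_bw, log_mu_bw)
}

# rate index per age for piecewise models: an event exactly at a shift
# boundary belongs to the OLDER segment; rates/shifts oldest first
.piecewise_segment <- function(age, shifts) {
  1L + vapply(age, function(a) sum(shifts > a), integer(1))
}

# cumulative lineage-time A(s) = int_0^s k(tau) dtau for a vector of s,
# where k(tau) = 1 + #{branching ages >= tau} (2 just below the crown)
.lineage_time_below <- function(bt, s) {
  xa <- c(0, rev(bt$x))                   # ascending, starts at the present
  n <- bt$n
  kcnt <- n:2                              # count on (xa[i], xa[i+1])
  widths <- diff(xa)
  cumA <- c(0, cumsum(kcnt * widths))      # A at each knot
  i <- findInterval(s, xa, rightmost.closed = FALSE)
  i <- pmin(i, length(xa) - 1L)
  above <- s >= xa[length(xa)]
  out <- cumA[i] + kcnt[i] * (s - xa[i])
  out[above] <- cumA[length(cumA)]         # beyond the crown: total T
  out
}

#' Piecewise-constant pure-birth (yule2rate / yule3rate) log-likelihood
#'
#' Pure-birth likelihood whose speciation rate is constant within segments
#' of time before present delimited by `shifts` (oldest first; an event
#' falling exactly on a boundary belongs to the older segment):
#' \deqn{\ln L = \sum_{events} \ln(k_e\, \lambda(a_e)) -
#'   \sum_j \lambda_j L_j,}
#' where \eqn{k_e} is the lineage count at each branching event and
#' \eqn{L_j} the lineage-time accumulated within segment j. Given the
#' shifts, the per-segment maximum-likelihood rates are closed form:
#' \eqn{\hat\lambda_j = B_j / L_j} with \eqn{B_j} the number of branching
#' events in the segment (see [fit_model()]).
#'
#' @param x branching times.
#' @param rates positive rates, one per segment (oldest first);
#'   `length(rates) == length(shifts) + 1`.
#' @param shifts strictly decreasing shift times within `(0, crown age)`.
#' @return the log-likelihood.
#' @examples
#' bt <- branching_times(c(3, 2, 1))
#' loglik_piecewise_yule(bt, c(1, 1), 1.5) == loglik_pure_birth(bt, 1)
#' @export
loglik_piecewise_yule <- function(x, rates, shifts = numeric()) {
  bt <- as_branching_times(x)
  if (length(rates) != length(shifts) + 1L)
    stop("length(rates) must equal length(shifts) + 1")
  if (any(rates <= 0)) stop("rates must be > 0")
  if (length(shifts)) {
    if (any(shifts <= 0) || any(shifts >= bt$x[1]))
      stop("shifts must lie strictly inside (0, crown age)")
    if (length(shifts) > 1 && any(diff(shifts) >= 0))
      stop("'shifts' must be strictly decreasing")
  }
  ev <- bt$x[-1]                           # branching events (crown excluded)
  seg_ev <- .piecewise_segment(ev, shifts)
  B <- tabulate(seg_ev, nbins = length(rates))
  bounds <- c(Inf, shifts, 0)
  A <- .lineage_time_below(bt, pmin(bounds, bt$x[1]))
  L <- A[-length(A)] - A[-1]               # lineage-time per segment
  lgamma(bt$n) + sum(B * log(rates)) - sum(rates * L)
}
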