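#' Akaike information criterion from a log-likelihood
#'
#' `AIC = -2 lnL + 2 k`, with `k` the number of free parameters. The
#' parameter counts used by [fit_model()] are 1 (pure birth), 2 (birth
#' death), 3 (SPVAR), 3 (EXVAR), 3 (yule2rate: two rates and a shift time)
#' and 5 (yule3rate: three rates and two shift times).
#'
#' @param loglik log-likelihood (natural log).
#' @param k_free number of free parameters.
#' @return the AIC value.
#' @examples
#' aic(6.30, 5)    # -2.60
#' aic(-26.21, 1)  # 54.42
#' @export
aic <- function(loglik, k_free) -2 * loglik + 2 * k_free

.div_models <- c("pure_birth", "birth_death", "spvar", "exvar",
                 "yule2rate", "yule3rate")
.k_free <- c(pure_birth = 1L, birth_death = 2L, spvar = 3L, exvar = 3L,
             yule2rate = 3L, yule3rate = 5L)

# bounded multi-start maximisation; starts is a list of numeric vectors
.ml_optim <- function(negfn, starts, lower, upper) {
  safe <- function(p) {
    v <- tryCatch(negfn(p), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  fails <- 0L
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch(
      stats::optim(p0, safe, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500L)),
      error = function(e) NULL)
    if (is.null(res)) { fails <- fails + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("optimizer failed from all ", length(starts), " starts")
  best$n_fail <- fails
  best
}

# shift-time candidates: 1-My-style grid union observed branching times,
# all strictly inside (0, crown age)
.shift_candidates <- function(bt, grid_step) {
  x2 <- bt$x[1]
  cand <- c(seq(grid_step, x2, by = grid_step), bt$x[-1])
  sort(unique(cand[cand > 0 & cand < x2]))
}

# closed-form piecewise-Yule profile fit over candidate single shifts
.fit_yule2 <- function(bt, cand) {
  n <- bt$n
  ev <- bt$x[-1]
  Bge <- vapply(cand, function(s) sum(ev >= s), numeric(1))
  A <- .lineage_time_below(bt, cand)
  Ttot <- bt$total_time
  B1 <- Bge; B2 <- (n - 2) - Bge
  L1 <- Ttot - A; L2 <- A
  ok <- B1 > 0 & B2 > 0 & L1 > 0 & L2 > 0
  ll <- rep(-Inf, length(cand))
  ll[ok] <- lgamma(n) + B1[ok] * (log(B1[ok] / L1[ok]) - 1) +
    B2[ok] * (log(B2[ok] / L2[ok]) - 1)
  if (!any(is.finite(ll))) stop("yule2rate: no admissible shift candidate")
  # ties broken toward the older shift
  i <- which(ll >= max(ll) - 0)
  i <- i[which.max(cand[i])]
  list(params = c(lam1 = B1[i] / L1[i], lam2 = B2[i] / L2[i],
                  st1 = cand[i]),
       loglik = ll[i])
}

.fit_yule3 <- function(bt, cand) {
  n <- bt$n
  ev <- bt$x[-1]
  Bge <- vapply(cand, function(s) sum(ev >= s), numeric(1))
  A <- .lineage_time_below(bt, cand)
  Ttot <- bt$total_time
  nc <- length(cand)
  if (nc < 2L) stop("yule3rate: need at least two shift candidates")
  # matrices over (i = older shift s1, j = younger shift s2), s1 > s2
  B1 <- matrix(Bge, nc, nc)                            # events >= s1
  B2 <- outer(rep(1, nc), Bge) - matrix(Bge, nc, nc)   # s2 <= . < s1
  B3 <- (n - 2) - outer(rep(1, nc), Bge)
  L1 <- Ttot - matrix(A, nc, nc)
  L2 <- matrix(A, nc, nc) - outer(rep(1, nc), A)
  L3 <- outer(rep(1, nc), A)
  valid <- outer(cand, cand, ">") & B1 > 0 & B2 > 0 & B3 > 0 &
    L1 > 0 & L2 > 0 & L3 > 0
  term <- function(B, L) ifelse(valid, B * (log(B / L) - 1), -Inf)
  ll <- lgamma(n) + term(B1, L1) + term(B2, L2) + term(B3, L3)
  ll[!valid] <- -Inf
  if (!any(is.finite(ll))) stop("yule3rate: no admissible shift pair")
  mx <- max(ll)
  idx <- which(ll == mx, arr.ind = TRUE)
  # ties: older first shift, then older second shift
  ord <- order(cand[idx[, 1]], cand[idx[, 2]], decreasing = TRUE)
  i <- idx[ord[1], 1]; j <- idx[ord[1], 2]
  list(params = c(lam1 = B1[i, j] / L1[i, j], lam2 = B2[i, j] / L2[i, j],
                  lam3 = B3[i, j] / L3[i, j],
                  st1 = cand[i], st2 = cand[j]),
       loglik = mx)
}

#' Fit one diversification model to branching times by maximum likelihood
#'
#' Models: `"pure_birth"` (closed-form \eqn{\hat\lambda = (n-2)/T}),
#' `"birth_death"` (bounded optimisation over the net rate and extinction
#' fraction; the pure-birth boundary `a = 0` is reachable), `"spvar"` and
#' `"exvar"` (bounded 5-start optimisation), and the piecewise pure-birth
#' models `"yule2rate"` / `"yule3rate"`, fitted by exhaustive search over
#' candidate shift times (the union of a `grid_step`-spaced grid and the
#' observed branching times) with closed-form per-segment rates
#' \eqn{\hat\lambda_j = B_j / L_j}; candidates leaving a segment with no
#' branching event are rejected rather than fitted with a zero rate. Ties in
#' the profile likelihood are broken toward the older shift.
#'
#' For the birth-death fit the implied speciation and extinction rates
#' \eqn{\hat\lambda = \hat r/(1-\hat a)}, \eqn{\hat\mu = \hat\lambda \hat a}
#' are reported alongside the fitted parameters.
#'
#' @param x branching times (chronogram, `"branching_times"`, or ages).
#' @param model one of `"pure_birth"`, `"birth_death"`, `"spvar"`,
#'   `"exvar"`, `"yule2rate"`, `"yule3rate"`.
#' @param grid_step spacing (My) of the shift-time grid for the piecewise
#'   models (default 1 My).
#' @return an object of class `"model_fit"`: list with `model`, `params`
#'   (named vector), `loglik`, `k_free`, `aic`, and optimizer details.
#' @examples
#' fit_model(simulate_yule(50, lam = 0.2, seed = 1), "pure_birth")
#' @export
fit_model <- function(x, model = .div_models, grid_step = 1) {
  model <- match.arg(model)
  bt <- as_branching_times(x)
  if (bt$n < 4L) stop("model fitting needs at least 4 tips")
  if (!isTRUE(grid_step > 0)) stop("'grid_step' must be > 0")
  n <- bt$n
  r0 <- (n - 2) / bt$total_time
  details <- NULL
  if (model == "pure_birth") {
    params <- c(lam = r0)
    ll <- loglik_pure_birth(bt, r0)
  } else if (model == "birth_death") {
    starts <- list(c(r0, 0), c(r0, 0.3), c(0.5 * r0, 0.6), c(2 * r0, 0.9),
                   c(r0, 0.95))
    opt <- .ml_optim(function(p) -loglik_bd(bt, p[1], p[2]), starts,
                     lower = c(1e-8, 0), upper = c(10, 1 - 1e-6))
    lam <- opt$par[1] / (1 - opt$par[2])
    params <- c(r_net = opt$par[1], a = opt$par[2],
                lam = lam, mu = lam * opt$par[2])
    ll <- -opt$value
    details <- opt[c("convergence", "n_fail")]
  } else if (model == "spvar") {
    starts <- list(c(r0, 1e-4, 1e-4), c(r0, 0.02, 0.1 * r0),
                   c(2 * r0, 0.05, 0.5 * r0), c(4 * r0, 0.1, r0),
                   c(0.5 * r0, 0.01, 0.01))
    opt <- .ml_optim(function(p) -loglik_spvar(bt, p[1], p[2], p[3]), starts,
                     lower = c(1e-8, 0, 0), upper = c(10, 10, 10))
    params <- c(lam0 = opt$par[1], kdecay = opt$par[2], mu0 = opt$par[3])
    ll <- -opt$value
    details <- opt[c("convergence", "n_fail")]
  } else if (model == "exvar") {
    starts <- list(c(r0, 1e-4, 1), c(r0, 0.1 * r0, 0.1),
                   c(1.5 * r0, 0.5 * r0, 1), c(2 * r0, r0, 10),
                   c(r0, 0.3 * r0, 0.01))
    opt <- .ml_optim(function(p) -loglik_exvar(bt, p[1], p[2], p[3]), starts,
                     lower = c(1e-8, 0, 0), upper = c(10, 10, 1e3))
    params <- c(lam0 = opt$par[1], mu0 = opt$par[2], z = opt$par[3])
    ll <- -opt$value
    details <- opt[c("convergence", "n_fail")]
  } else {
    cand <- .shift_candidates(bt, grid_step)
    fitfn <- if (model == "yule2rate") .fit_yule2 else .fit_yule3
    res <- fitfn(bt, cand)
    params <- res$params
    ll <- res$loglik
    details <- list(n_candidates = length(cand), grid_step = grid_step)
  }
  structure(list(model = model, params = params, loglik = ll,
                 k_free = .k_free[[model]], aic = aic(ll, .k_free[[model]]),
                 n = n, details = details),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d): lnL = %.4f, k = %d, AIC = %.4f\n",
              x$model, x$n, x$loglik, x$k_free, x$aic))
  print(round(x$params, 6))
  invisible(x)
}

#' Fit and rank all six diversification models
#'
#' Fits the pure-birth, birth-death, SPVAR, EXVAR, yule2rate and yule3rate
#' models (see [fit_model()]), ranks them by AIC, and reports likelihood
#' ratio tests for the nested pairs (pure birth in birth death, pure birth
#' in yule2rate, yule2rate in yule3rate, birth death in SPVAR, birth death
#' in EXVAR) with chi-squared reference distributions on the difference in
#' parameter count. A model whose fit fails contributes an NA row rather
#' than aborting the table.
#'
#' Note these likelihoods take the sampled chronogram at face value: no
#' correction for incomplete taxon sampling is applied, so on subsampled
#' trees the fitted slowdowns partly reflect the sampling artifact.
#'
#' @param x branching times (chronogram, `"branching_times"`, or ages).
#' @param grid_step shift-grid spacing (My) for the piecewise models.
#' @return a data frame of class `"model_fit_table"` with one row per model
#'   (`model`, `lnL`, `k_free`, `AIC`, `dAIC`, `best`); the individual
#'   `"model_fit"` objects are in `attr(, "fits")` and the LRT table in
#'   `attr(, "lrt")`.
#' @examples
#' \donttest{
#' fit_all(simulate_yule(60, lam = 0.2, seed = 1))
#' }
#' @export
fit_all <- function(x, grid_step = 1) {
  bt <- as_branching_times(x)
  fits <- lapply(.div_models, function(mod)
    tryCatch(fit_model(bt, mod, grid_step = grid_step),
             error = function(e) {
               warning(sprintf("fit of %s failed: %s", mod,
                               conditionMessage(e)))
               NULL
             }))
  names(fits) <- .div_models
  ll <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$loglik,
               numeric(1))
  aics <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aic,
                 numeric(1))
  out <- data.frame(model = .div_models, lnL = ll,
                    k_free = unname(.k_free[.div_models]), AIC = aics,
                    dAIC = aics - min(aics, na.rm = TRUE),
                    best = aics == min(aics, na.rm = TRUE))
  rownames(out) <- NULL
  nested <- list(c("pure_birth", "birth_death"),
                 c("pure_birth", "yule2rate"),
                 c("yule2rate", "yule3rate"),
                 c("birth_death", "spvar"),
                 c("birth_death", "exvar"))
  lrt <- do.call(rbind, lapply(nested, function(pr) {
    l0 <- ll[pr[1]]; l1 <- ll[pr[2]]
    df <- .k_free[[pr[2]]] - .k_free[[pr[1]]]
    stat <- max(0, 2 * (l1 - l0))
    data.frame(null = pr[1], alternative = pr[2], df = df, stat = stat,
               p = stats::pchisq(stat, df, lower.tail = FALSE))
  }))
  attr(out, "fits") <- fits
  attr(out, "lrt") <- lrt
  class(out) <- c("model_fit_table", "data.frame")
  out
}

#' @export
print.model_fit_table <- function(x, digits = 4, ...) {
  cat("Diversification model comparison (AIC-ranked)\n")
  df <- as.data.frame(x)
  df$lnL <- round(df$lnL, digits); df$AIC <- round(df$AIC, digits)
  df$dAIC <- round(df$dAIC, digits)
  print(df[order(df$AIC), ], row.names = FALSE)
  cat("\nLikelihood ratio tests (nested pairs):\n")
  lrt <- attr(x, "lrt")
  lrt$stat <- round(lrt$stat, digits); lrt$p <- signif(lrt$p, 3)
  print(lrt, row.names = FALSE)
  invisible(x)
}
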