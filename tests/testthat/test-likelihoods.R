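test_that("pure-birth likelihood matches hand evaluation and its MLE is exact", {
  bt <- branching_times(c(3, 2, 1))
  expect_equal(loglik_pure_birth(bt, 1), log(2) + log(3) - 9,
               tolerance = 1e-12)
  set.seed(61)
  for (i in 1:10) {
    bt <- random_bt(sample(6:100, 1))
    opt <- stats::optimize(function(l) loglik_pure_birth(bt, l),
                           c(1e-6, 10), maximum = TRUE, tol = 1e-10)
    expect_equal(opt$maximum, (bt$n - 2) / bt$total_time, tolerance = 1e-5)
  }
})

test_that("pure-birth rate is recovered from simulated trees", {
  set.seed(63)
  lam <- replicate(60, fit_model(simulate_yule(200, 0.1),
                                 "pure_birth")$params[["lam"]])
  expect_equal(median(lam), 0.1, tolerance = 0.1 * 0.1)
})

test_that("birth-death likelihood reduces to pure birth at a = 0", {
  set.seed(65)
  for (i in 1:6) {
    bt <- random_bt(sample(6:80, 1))
    lam <- runif(1, 0.05, 1)
    expect_equal(loglik_bd(bt, lam, 0), loglik_pure_birth(bt, lam),
                 tolerance = 1e-9)
  }
})

test_that("birth-death MLEs agree with an independent implementation", {
  for (seed in c(71, 72, 73)) {
    tr <- simulate_bd(120, 0.25, 0.12, seed = seed)
    f <- fit_model(tr, "birth_death")
    ref <- ape::birthdeath(tr)
    expect_equal(unname(f$params["r_net"]), unname(ref$para["b-d"]),
                 tolerance = 1e-3)
    expect_equal(unname(f$params["a"]), unname(ref$para["d/b"]),
                 tolerance = 1e-2)
  }
})

test_that("birth-death rates are recovered from simulated trees", {
  set.seed(67)
  est <- t(replicate(40, {
    f <- fit_model(simulate_bd(150, 0.2, 0.1), "birth_death")
    f$params[c("lam", "mu")]
  }))
  # medians within 25% / 35% of the generating rates
  expect_gt(median(est[, 1]), 0.15)
  expect_lt(median(est[, 1]), 0.25)
  expect_gt(median(est[, 2]), 0.065)
  expect_lt(median(est[, 2]), 0.135)
})

test_that("on pure-birth data the birth-death fit can reach the a = 0 boundary", {
  set.seed(69)
  res <- t(replicate(12, {
    tr <- simulate_yule(150, 0.15)
    pb <- fit_model(tr, "pure_birth")
    bd <- fit_model(tr, "birth_death")
    c(gain = bd$loglik - pb$loglik, a = bd$params[["a"]])
  }))
  # BD nests PB, so it can never fit worse ...
  expect_true(all(res[, "gain"] >= -1e-6))
  # ... and on extinction-free data the extinction fraction collapses to the
  # boundary in a substantial share of realisations, with equal likelihoods
  at_boundary <- res[, "a"] < 1e-3
  expect_gte(sum(at_boundary), 3L)
  expect_true(all(abs(res[at_boundary, "gain"]) < 1e-6))
  expect_lt(median(res[, "a"]), 0.3)
})

test_that("time-varying likelihoods collapse to their constant-rate limits", {
  set.seed(75)
  for (i in 1:5) {
    bt <- random_bt(sample(8:60, 1))
    lam <- runif(1, 0.1, 0.6)
    a <- runif(1, 0.1, 0.7)
    r <- lam * (1 - a)
    mu <- lam * a
    expect_equal(loglik_spvar(bt, lam, 0, mu), loglik_bd(bt, r, a),
                 tolerance = 1e-6)
    expect_equal(loglik_spvar(bt, lam, 0, 0), loglik_pure_birth(bt, lam),
                 tolerance = 1e-9)
    expect_equal(loglik_exvar(bt, lam, 0, 3), loglik_pure_birth(bt, lam),
                 tolerance = 1e-9)
    expect_equal(loglik_exvar(bt, lam, mu, 1e6), loglik_bd(bt, r, a),
                 tolerance = 1e-4)
  }
})

test_that("the quadrature scheme matches stats::integrate", {
  bt <- random_bt(40)
  x2 <- bt$x[1]
  lam0 <- 0.4; k <- 0.06; mu0 <- 0.08
  Lam <- function(u) (lam0 / k) * (exp(k * (u - x2)) - exp(-k * x2))
  rho <- function(u) Lam(u) - mu0 * u
  knots <- sort(unique(c(0, bt$x)))
  logI <- divtempo:::cum_log_quad(function(u) log(mu0) + rho(u), knots)
  ref <- stats::integrate(function(u) mu0 * exp(rho(u)), 0, x2,
                          rel.tol = 1e-12, abs.tol = 1e-12)$value
  expect_equal(exp(logI[length(logI)]), ref, tolerance = 1e-8)
})

test_that("likelihood surfaces respond sanely to extinction", {
  set.seed(77)
  bt <- random_bt(50, 0.3)
  lam <- 0.35
  # near mu0 = lambda, more extinction steadily lowers the Yule-tree fit
  lls <- vapply(c(0.7, 0.85, 0.99) * lam,
                function(m) loglik_exvar(bt, lam, m, 0.5), numeric(1))
  expect_true(all(diff(lls) < 0))
  expect_true(all(is.finite(lls)))
  expect_true(is.finite(loglik_spvar(bt, 0.5, 0.1, 0.2)))
})

test_that("piecewise-Yule likelihood collapses and profiles correctly", {
  bt <- branching_times(c(3, 2, 1))
  expect_equal(loglik_piecewise_yule(bt, c(1, 1), 1.5),
               loglik_pure_birth(bt, 1), tolerance = 1e-12)
  expect_equal(loglik_piecewise_yule(bt, 0.7, numeric()),
               loglik_pure_birth(bt, 0.7), tolerance = 1e-12)
  set.seed(79)
  for (i in 1:8) {
    btr <- random_bt(sample(10:80, 1))
    s <- unname(stats::quantile(btr$x, runif(1, 0.2, 0.8)))
    if (s >= btr$x[1] || s <= 0) next
    prof <- divtempo:::.fit_yule2(btr, s)
    opt <- stats::optim(c(0.2, 0.2), function(p)
      -loglik_piecewise_yule(btr, p, s), method = "L-BFGS-B",
      lower = 1e-8, upper = 20)
    expect_equal(prof$loglik, -opt$value,
                 tolerance = 1e-5 * max(1, abs(prof$loglik)))
  }
})

test_that("declining-speciation decay is recovered from simulated trees", {
  set.seed(81)
  kh <- replicate(10, {
    tr <- simulate_time_varying(100, function(t) 0.3 * exp(-0.05 * t),
                                function(t) rep(0.05, length(t)),
                                t_max = 500)
    fit_model(tr, "spvar")$params[["kdecay"]]
  })
  expect_gt(median(kh), 0)
  expect_gte(mean(kh > 1e-6), 0.7)
})
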