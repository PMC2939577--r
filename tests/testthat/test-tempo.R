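test_that("gamma matches hand evaluation and an independent implementation", {
  g <- gamma_stat(branching_times(c(3, 2, 1)))
  # T = 9, T2 = 2, T3 = 5 -> (3.5 - 4.5) / (9 sqrt(1/24))
  expect_equal(g$gamma, (3.5 - 4.5) / (9 * sqrt(1 / 24)), tolerance = 1e-12)
  expect_equal(round(g$gamma, 4), -0.5443)
  for (seed in 1:6) {
    tr <- simulate_bd(35, 0.4, 0.15, seed = seed)
    expect_equal(gamma_stat(tr)$gamma, ape::gammaStat(tr), tolerance = 1e-9)
  }
  expect_error(gamma_stat(branching_times(5)), "at least 3")
})

test_that("gamma is exactly scale invariant", {
  bt <- branching_times(c(3, 2, 1))
  expect_equal(gamma_stat(branching_times(c(3, 2, 1) * 7))$gamma,
               gamma_stat(bt)$gamma, tolerance = 1e-12)
})

test_that("CR test orientation and boundary behave as documented", {
  b <- cr_test(-1.645)
  expect_gte(b$p, 0.0498)
  expect_lte(b$p, 0.0502)
  expect_equal(cr_test(0)$p, 0.5)
  # a positive gamma is non-significant for a decrease; its upper tail is 0.27
  expect_equal(round(cr_test(0.611, tail = "increase")$p, 2), 0.27)
  expect_false(cr_test(0.611)$reject)
  expect_true(cr_test(-2.5)$reject)
  expect_equal(cr_test(1.2, tail = "two")$p, 2 * pnorm(-1.2))
})

test_that("MCCR null collapses to the complete-tree null when m = N", {
  m <- mccr_test(0, N_total = 100, m = 100, reps = 2000, seed = 101)
  expect_equal(m$critical, qnorm(0.05), tolerance = 0.15)
  expect_equal(length(m$null), 2000L)
})

test_that("MCCR results are reproducible and p-values consistent", {
  m1 <- mccr_test(-3, 500, 40, reps = 200, seed = 5)
  m2 <- mccr_test(-3, 500, 40, reps = 200, seed = 5)
  expect_identical(m1$null, m2$null)
  expect_equal(m1$p, (1 + sum(m1$null <= -3)) / 201)
  expect_equal(m1$p_plain, mean(m1$null <= -3))
  expect_error(mccr_test(0, 100, 2), "3 <= m")
  expect_error(mccr_test(0, 100, 50, reps = 50), "at least 100")
})

test_that("the MCCR null is unaffected by the simulation rate", {
  set.seed(43)
  a <- replicate(400, gamma_stat(branching_times(
    divtempo:::.yule_subsampled_x(300, 40, lam = 1)))$gamma)
  b <- replicate(400, gamma_stat(branching_times(
    divtempo:::.yule_subsampled_x(300, 40, lam = 0.3)))$gamma)
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
})

test_that("LTT curves step once per branching event", {
  lt <- ltt(branching_times(c(3, 2, 1)))
  expect_equal(lt$time_My, c(3, 2, 1, 0))
  expect_equal(lt$lineages, c(2, 3, 4, 4))
  for (seed in 1:4) {
    tr <- simulate_yule(30, seed = seed)
    lt <- ltt(tr)
    expect_equal(lt$lineages[nrow(lt)], 30L)
    expect_true(all(diff(lt$lineages[-nrow(lt)]) == 1))
  }
})

test_that("complete-tree LTT envelopes are straight in semilog space", {
  env <- ltt_envelope(100, reps = 200, seed = 51)
  i <- 2:255
  r2 <- summary(stats::lm(log(env$mean[i]) ~ env$rel_time[i]))$r.squared
  expect_gt(r2, 0.99)
  expect_identical(env$mean, ltt_envelope(100, reps = 200, seed = 51)$mean)
})

test_that("subsampling flattens the envelope near the present", {
  envc <- ltt_envelope(100, reps = 150, seed = 53)
  envs <- ltt_envelope(2000, m = 100, reps = 150, seed = 54)
  late_slope <- function(e) {
    i <- e$rel_time >= 0.9
    stats::coef(stats::lm(log(e$mean[i]) ~ e$rel_time[i]))[[2]]
  }
  expect_lt(late_slope(envs), 0.5 * late_slope(envc))
  expect_true(all(envs$lo <= envs$mean + 1e-9 & envs$mean <= envs$hi + 1e-9))
})

test_that("empirical overlays share the envelope grid", {
  tr <- simulate_yule(40, seed = 55)
  env <- ltt_envelope(60, m = 40, reps = 100, seed = 56, empirical = tr)
  expect_equal(env$empirical[length(env$empirical)], 40L)
  expect_equal(env$empirical[1], 2L)
})
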