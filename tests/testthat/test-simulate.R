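test_that("simulators are reproducible under a fixed seed", {
  expect_identical(write_newick(simulate_yule(30, 0.5, seed = 7)),
                   write_newick(simulate_yule(30, 0.5, seed = 7)))
  expect_identical(
    write_newick(simulate_piecewise_yule(30, c(0.1, 0.02), 20, seed = 7)),
    write_newick(simulate_piecewise_yule(30, c(0.1, 0.02), 20, seed = 7)))
  expect_identical(write_newick(simulate_bd(20, 0.3, 0.1, seed = 7)),
                   write_newick(simulate_bd(20, 0.3, 0.1, seed = 7)))
  tr <- simulate_yule(30, seed = 1)
  expect_identical(subsample_tips(tr, 10, seed = 3)$tip.label,
                   subsample_tips(tr, 10, seed = 3)$tip.label)
})

test_that("all simulators emit valid chronograms with the requested size", {
  trees <- list(simulate_yule(17, 0.2, seed = 2),
                simulate_piecewise_yule(17, c(0.2, 0.05), 5, seed = 2),
                simulate_bd(17, 0.3, 0.15, seed = 2),
                simulate_time_varying(17, function(t) 0.3 * exp(-0.04 * t),
                                      function(t) rep(0.02, length(t)),
                                      t_max = 400, seed = 2))
  for (tr in trees) {
    expect_s3_class(tr, "chronogram")
    expect_equal(length(tr$tip.label), 17L)
    expect_lt(attr(tr, "chronogram_info")$max_ultrametric_dev, 1e-8)
  }
})

test_that("2-tip pure-birth crown age matches the waiting-time construction", {
  set.seed(41)
  crowns <- replicate(3000, branching_times(simulate_yule(2, lam = 1))$x[1])
  # construction: single Exp(2*lam) interval, mean 1/2
  expect_equal(mean(crowns), 0.5, tolerance = 0.03)
})

test_that("constant-rate limits coincide across simulators", {
  set.seed(11)
  a <- replicate(800, branching_times(simulate_yule(25, 0.3))$x[1])
  b <- replicate(800, branching_times(simulate_bd(25, 0.3, 0))$x[1])
  expect_gt(suppressWarnings(stats::ks.test(a, b)$p.value), 0.01)
  d <- replicate(800, branching_times(
    simulate_piecewise_yule(25, 0.3, numeric()))$x[1])
  expect_gt(suppressWarnings(stats::ks.test(a, d)$p.value), 0.01)
  e <- replicate(400, branching_times(simulate_time_varying(
    25, function(t) rep(0.3, length(t)), function(t) rep(0, length(t)),
    t_max = 200))$x[1])
  expect_gt(suppressWarnings(stats::ks.test(a, e)$p.value), 0.01)
})

test_that("a piecewise rate drop slows late lineage accumulation", {
  set.seed(13)
  ratio <- replicate(100, {
    bt <- branching_times(simulate_piecewise_yule(120, c(0.08, 0.02), 41))
    lt <- ltt(bt)
    old <- lt$time_My > 41
    young <- lt$time_My <= 41 & lt$time_My > 0
    slope <- function(sel) {
      if (sum(sel) < 3) return(NA_real_)
      -stats::coef(stats::lm(log(lt$lineages[sel]) ~ lt$time_My[sel]))[[2]]
    }
    slope(young) / slope(old)
  })
  expect_lt(mean(ratio, na.rm = TRUE), 1)
})

test_that("declining speciation pushes gamma negative", {
  set.seed(17)
  g <- replicate(60, gamma_stat(simulate_time_varying(
    100, function(t) 0.3 * exp(-0.05 * t),
    function(t) rep(0.02, length(t)), t_max = 500))$gamma)
  expect_lt(mean(g), -1)
})

test_that("random subsampling induces an apparent slowdown", {
  set.seed(19)
  g <- replicate(200, gamma_stat(branching_times(
    divtempo:::.yule_subsampled_x(1000, 50)))$gamma)
  expect_lt(mean(g), -0.5)
})

test_that("subsample_tips checks its arguments and supports identity", {
  tr <- simulate_yule(20, seed = 5)
  expect_equal(length(subsample_tips(tr, 20)$tip.label), 20L)
  expect_error(subsample_tips(tr, 1), "between 2")
  expect_error(subsample_tips(tr, 21), "between 2")
  sub <- subsample_tips(tr, 8, seed = 1, depth_bias = 1)
  expect_equal(length(sub$tip.label), 8L)
})

test_that("gamma is invariant to rescaling simulated trees", {
  for (seed in 1:6) {
    tr <- simulate_yule(40, 0.2, seed = seed)
    g1 <- gamma_stat(tr)$gamma
    tr$edge.length <- tr$edge.length * 7
    expect_equal(gamma_stat(as_chronogram(tr, quiet = TRUE))$gamma, g1,
                 tolerance = 1e-9)
  }
})

test_that("the packaged fixture is deterministic and matches its design", {
  fx <- harpaline_fixture()
  expect_equal(length(fx$harpaline$tip.label), 193L)
  expect_equal(length(fx$brachinine$tip.label), 10L)
  expect_equal(unname(fx$richness),
               c(19811L, 655L, 100L))
  fx2 <- harpaline_fixture()
  expect_identical(write_newick(fx$harpaline), write_newick(fx2$harpaline))
  expect_identical(write_newick(fx$brachinine), write_newick(fx2$brachinine))
})
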