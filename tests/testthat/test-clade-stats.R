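test_that("Slowinski-Guyer probabilities match ERM split enumeration", {
  expect_equal(slowinski_guyer(5, 2)$p, 1 / 3, tolerance = 1e-12)
  expect_equal(slowinski_guyer(1, 1)$p, 1)
  expect_equal(slowinski_guyer(1, 1, tail = "two")$p, 1)
  for (r in c(1, 3, 7, 12, 19)) {
    for (s in seq_len(min(r, 20 - r))) {
      expect_equal(slowinski_guyer(r, s)$p, erm_split_p(r, s),
                   tolerance = 1e-12)
    }
  }
  expect_error(slowinski_guyer(2, 5), "r >= s")
  expect_error(slowinski_guyer(5, 0), "r >= s")
})

test_that("two-tailed Slowinski-Guyer doubles the one-tailed value, capped", {
  for (i in 1:20) {
    r <- sample(1:500, 1)
    s <- sample(1:r, 1)
    p1 <- slowinski_guyer(r, s)$p
    expect_equal(slowinski_guyer(r, s, "two")$p, min(1, 2 * p1))
  }
})

test_that("Magallon-Sanderson estimators satisfy their closed-form limits", {
  expect_equal(ms_rate(2, 10, 0)$r_hat, 0, tolerance = 1e-12)
  expect_equal(ms_rate(100, 10, 0)$r_hat, (log(100) - log(2)) / 10,
               tolerance = 1e-12)
  expect_equal(ms_rate(100, 10, 0, mode = "stem")$r_hat, log(100) / 10,
               tolerance = 1e-12)
  # higher extinction fraction lowers the crown estimate
  expect_lt(ms_rate(500, 20, 0.5)$r_hat, ms_rate(500, 20, 0)$r_hat)
  expect_lt(ms_rate(500, 20, 0.9)$r_hat, ms_rate(500, 20, 0.5)$r_hat)
  expect_error(ms_rate(10, -1), "must be > 0")
  expect_error(ms_rate(10, 5, 1), "\\[0, 1\\)")
})

test_that("r_hat scales as 1/t at fixed richness and extinction fraction", {
  for (i in 1:10) {
    n <- sample(3:5000, 1)
    e <- runif(1, 0, 0.9)
    t1 <- runif(1, 1, 50)
    t2 <- runif(1, 1, 50)
    for (mode in c("crown", "stem")) {
      expect_equal(ms_rate(n, t1, e, mode)$r_hat * t1,
                   ms_rate(n, t2, e, mode)$r_hat * t2, tolerance = 1e-9)
    }
  }
})

test_that("relative cladogenesis p-values reduce to Slowinski-Guyer at k = 2", {
  tr <- comb4()
  rc <- rc_test(tr)
  expect_equal(attr(rc, "n_tests"), nrow(rc))
  # crown-origin branches have k = 2; the 3-descendant branch gives 1/3
  crown_rows <- rc[rc$k == 2, ]
  expect_true(all(abs(crown_rows$p_raw -
                        (4 - crown_rows$r_desc) / 3) < 1e-12))
  expect_equal(rc$p_raw[rc$k == 2 & rc$r_desc == 3], 1 / 3,
               tolerance = 1e-12)
  for (seed in 1:4) {
    big <- simulate_yule(30, seed = seed)
    rcb <- rc_test(big)
    k2 <- rcb[rcb$k == 2 & rcb$r_desc < 30, ]
    # a k = 2 branch with r descendants: p = (n - r)/(n - 1), i.e. the
    # one-tailed sister-clade probability of a clade of size s = n - r
    expect_equal(k2$p_raw, (30 - k2$r_desc) / 29, tolerance = 1e-12)
    maj <- k2[k2$r_desc >= 15, ]
    expect_equal(maj$p_raw,
                 vapply(maj$r_desc, function(r)
                   slowinski_guyer(r, 30 - r)$p, numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("broken-stick p-values equal brute-force composition enumeration", {
  set.seed(23)
  for (n in c(5, 7, 9, 12)) {
    for (rep in 1:2) {
      tr <- simulate_yule(n)
      rc <- rc_test(tr)
      oracle <- mapply(composition_tail_p, n = rc$n, k = rc$k, r = rc$r_desc)
      expect_equal(rc$p_raw, unname(oracle), tolerance = 1e-12)
    }
  }
})

test_that("Bonferroni-corrected test is conservative on constant-rate trees", {
  set.seed(29)
  hits <- replicate(300, any(rc_test(simulate_yule(64, 0.2))$significant))
  expect_lte(mean(hits), 0.10)
})

test_that("the test flags a daughter clade diversifying five times faster", {
  set.seed(31)
  # the slow sister radiates over a long span, so at time slices where the
  # fast clade is still a stem lineage there is a sizeable cohort of
  # contemporaries against which its descendant count is extreme
  found <- replicate(100, {
    slow <- simulate_yule(40, 0.1)
    fast <- simulate_yule(200, 0.5)
    tr <- join_clades(slow, fast, root_age = 2 +
                        max(attr(slow, "chronogram_info")$height,
                            attr(fast, "chronogram_info")$height))
    rc <- rc_test(tr)
    fast_tips <- grep("^b", tr$tip.label)
    sig <- rc[rc$significant, , drop = FALSE]
    if (!nrow(sig)) return(FALSE)
    desc <- lapply(sig$branch, function(v) {
      if (v <= length(tr$tip.label)) v
      else match(ape::extract.clade(tr, v)$tip.label, tr$tip.label)
    })
    any(vapply(desc, function(d) all(d %in% fast_tips), logical(1)))
  })
  expect_gte(mean(found), 0.5)
})

test_that("significant ancestors of significant branches are marked", {
  set.seed(33)
  # strongly imbalanced tree: trickle-down marks at least one ancestor
  slow <- simulate_yule(5, 0.05)
  fast <- simulate_yule(120, 0.8)
  tr <- join_clades(slow, fast, root_age = 1 +
                      max(attr(slow, "chronogram_info")$height,
                          attr(fast, "chronogram_info")$height))
  rc <- rc_test(tr)
  sig <- rc[rc$significant, ]
  if (nrow(sig) >= 2) expect_true(any(sig$sig_descendant))
  expect_true(all(rc$p_bonferroni >= rc$p_raw - 1e-15))
  expect_true(all(rc$p_bonferroni <= 1 + 1e-15))
})
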