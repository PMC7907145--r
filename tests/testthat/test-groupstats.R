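# Welch t maps, FDR / Bonferroni corrections, Pearson helper.

test_that("t_map: null identity, Welch closed form, antisymmetry", {
  set.seed(1)
  a <- matrix(rnorm(40), 8, 5)
  sm0 <- t_map(a, a)
  expect_equal(sm0$t, rep(0, 5))
  expect_equal(sm0$p, rep(1, 5))
  b <- matrix(rnorm(60, 1, 2), 12, 5)
  sm <- t_map(a, b)
  for (ch in 1:5) {
    ref <- welch_oracle(a[, ch], b[, ch])
    expect_equal(sm$t[ch], ref$t, tolerance = 1e-9)
    expect_equal(sm$p[ch], ref$p, tolerance = 1e-9)
    # and against R's own Welch test
    tt <- t.test(a[, ch], b[, ch])
    expect_equal(sm$t[ch], unname(tt$statistic), tolerance = 1e-9)
  }
  sw <- t_map(b, a)
  expect_equal(sw$t, -sm$t)
  expect_equal(sw$p, sm$p)
  expect_error(t_map(a[1, , drop = FALSE], b), "2 subjects")
  expect_error(t_map(a, b[, 1:3]), "differ")
})

test_that("BH step-up: worked example, monotonicity, null FDR control", {
  expect_equal(correct_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(correct_fdr(c(0.9, 0.95), 0.05), c(FALSE, FALSE))
  expect_equal(correct_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05),
               p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH") <= 0.05)
  expect_error(correct_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  # BH flags match p.adjust on random inputs; lowering q never adds discoveries
  for (i in 1:10) {
    p <- runif(50)^sample(1:3, 1)
    expect_equal(correct_fdr(p, 0.1), p.adjust(p, "BH") <= 0.1)
    expect_true(all(correct_fdr(p, 0.01) <= correct_fdr(p, 0.1)))
  }
  # null simulation: observed false-discovery proportion within tolerance
  set.seed(3)
  fdp <- replicate(200, {
    p <- runif(1000)
    mean(correct_fdr(p, 0.05))
  })
  expect_lte(mean(fdp), 0.05)
})

test_that("Bonferroni: worked examples and dominance under BH", {
  expect_true(correct_bonferroni(0.01, 0.05))
  expect_equal(correct_bonferroni(rep(0.01, 10), 0.05), rep(FALSE, 10))
  expect_error(correct_bonferroni(numeric(0)), "empty")
  set.seed(4)
  for (i in 1:10) {
    p <- runif(30)^2
    bonf <- correct_bonferroni(p, 0.05)
    bh <- correct_fdr(p, 0.05)
    expect_true(all(bh[bonf]))   # Bonferroni flags are a subset of BH flags
  }
})

test_that("stat_map flags keep the Bonferroni-within-FDR invariant on data", {
  set.seed(5)
  a <- matrix(rnorm(200), 20, 10)
  b <- matrix(rnorm(200, mean = rep(c(1, 0), each = 5)[col(matrix(0, 20, 10))]),
              20, 10)
  b <- matrix(rnorm(200), 20, 10)
  b[, 1:4] <- b[, 1:4] + 1.2
  sm <- t_map(a, b)
  expect_true(all(sm$sig_fdr[sm$sig_bonferroni]))
})

test_that("pearson_r matches cor.test", {
  set.seed(6)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  got <- pearson_r(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_error(pearson_r(1:2, 1:2), "n >= 3")
})

test_that("injected frontal effects localise to frontal channels", {
  # synthetic cohort with a frontal complexity effect; subject-level channel
  # means; channels flagged by FDR should be predominantly frontal
  cfg <- synth_config(6, trials_per_subject = 2, complexity_effect = 1.2,
                      seed = 31)
  cohort <- generate_cohort(cfg)
  pcfg <- pipeline_config(feature = "fuzzyen", max_trials = 2, seed = 31)
  feats <- extract_cohort_features(cohort, pcfg)
  scm <- eegtopoclass:::subject_channel_means(feats$frames, feats$labels,
                                              feats$subjects)
  sm <- t_map(scm$matrix[scm$labels == 1, ], scm$matrix[scm$labels == 0, ],
              channel_labels = feats$channel_labels)
  flagged <- feats$channel_labels[sm$sig_fdr]
  expect_gt(length(flagged), 0)
  expect_gt(mean(grepl("^(Fp|AF|F)", flagged)), 0.5)
})
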