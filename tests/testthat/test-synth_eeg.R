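# Synthetic cohort generator: determinism, balance, and the injected
# class effects.

small_cfg <- function(...) {
  synth_config(n_subjects_per_class = 2, trials_per_subject = 2, seed = 42, ...)
}

test_that("generation is a pure function of (config, subject, label)", {
  cfg <- small_cfg()
  a <- generate_recording(cfg, "s1", 1)
  b <- generate_recording(cfg, "s1", 1)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, generate_recording(cfg, "s2", 1)$data))
  expect_false(identical(a$data, generate_recording(cfg, "s1", 0)$data))
  expect_true(all(is.finite(a$data)))
  expect_equal(dim(a$data), c(60, 2 * 700))
})

test_that("cohorts are balanced, deterministic, and labelled 0/1", {
  cfg <- synth_config(n_subjects_per_class = 5, trials_per_subject = 1, seed = 7)
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 10)
  labs <- vapply(cohort, `[[`, 0L, "label")
  expect_equal(sort(unique(labs)), c(0L, 1L))
  expect_equal(sum(labs == 0), 5)
  cohort2 <- generate_cohort(cfg)
  expect_identical(lapply(cohort, `[[`, "data"), lapply(cohort2, `[[`, "data"))
})

test_that("invalid configurations and labels are rejected", {
  expect_error(synth_config(0), "positive count")
  expect_error(synth_config(2, trial_duration = 1.333, sampling_rate = 100),
               "integer")
  expect_error(synth_config(2, complexity_effect = -1), ">= 0")
  expect_error(generate_recording(small_cfg(), "s", 2), "label")
})

test_that("zero effects make the classes exchangeable; complexity raises frontal FuzzyEn", {
  # null: mean broadband fuzzy entropy difference ~ 0 over 10 + 10 subjects
  null_cfg <- synth_config(10, trials_per_subject = 1, complexity_effect = 0,
                           theta_power_effect = 1, seed = 3)
  fe_of <- function(rec) {
    # broadband FuzzyEn of the first trial, frontal channels only
    frontal <- grepl("^(Fp|AF|F)", rec$channel_labels)
    x <- rec$data[frontal, 1:700, drop = FALSE]
    mean(apply(x, 1, function(ch) fuzzy_entropy(ch[1:200])))
  }
  cohort <- generate_cohort(null_cfg)
  labs <- vapply(cohort, `[[`, 0L, "label")
  fe <- vapply(cohort, fe_of, 0)
  p_null <- t.test(fe[labs == 1], fe[labs == 0])$p.value
  expect_gt(p_null, 0.01)

  # effect: class-1 frontal FuzzyEn larger in >= 95% of seed replicates
  wins <- 0L
  for (s in 1:10) {
    cfg <- synth_config(2, trials_per_subject = 1, complexity_effect = 0.8,
                        seed = 100 + s)
    cohort <- generate_cohort(cfg)
    labs <- vapply(cohort, `[[`, 0L, "label")
    fe <- vapply(cohort, fe_of, 0)
    if (mean(fe[labs == 1]) > mean(fe[labs == 0])) wins <- wins + 1L
  }
  expect_gte(wins, 10 * 0.95)
})

test_that("cohort round-trips through the on-disk format", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(small_cfg())
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_length(back, length(cohort))
  expect_equal(back[[1]]$data, cohort[[1]]$data, tolerance = 1e-8)
  expect_equal(vapply(back, `[[`, 0L, "label"),
               vapply(cohort, `[[`, 0L, "label"))
})
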