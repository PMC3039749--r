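test_that("generate_burst_train respects rate bounds, spacing, and determinism", {
  expect_equal(n_bursts(generate_burst_train(0, seed = 1)), 0)
  expect_error(generate_burst_train(40), "30")
  a <- generate_burst_train(12, seed = 99)
  b <- generate_burst_train(12, seed = 99)
  expect_identical(a, b)
  for (s in 1:10) {
    tr <- generate_burst_train(25, seed = s)
    if (n_bursts(tr) > 1) expect_true(all(diff(tr$onset) >= 1))
    expect_true(all(tr$amplitude >= 0.1 & tr$amplitude <= 1))
  }
})

test_that("thinned Poisson counts match an independent Monte-Carlo expectation", {
  # oracle: re-simulate the thinning rule directly, many replicates
  thin_oracle <- function(rate, duration, reps = 4000) {
    mean(replicate(reps, {
      n <- rpois(1, rate * duration / 60)
      if (n == 0) return(0)
      on <- sort(runif(n, 0, duration))
      kept <- 1
      last <- on[1]
      for (x in on[-1]) if (x - last >= 1) { kept <- kept + 1; last <- x }
      kept
    }))
  }
  set.seed(123)
  expected <- thin_oracle(10, 600)
  counts <- vapply(1:200, function(s) {
    n_bursts(generate_burst_train(10, duration = 600, seed = 5000 + s))
  }, 0)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.5)
})

test_that("generate_epoch adds calibrated noise and respects the baseline convention", {
  p <- tkernel
  tr <- burst_train(c(10, 40), c(0.5, 0.8))
  clean <- generate_epoch(tr, p, noise_sd = 0, drift_amp = 0, seed = 1)
  ref <- sf_simulate(p, tr, 60, 10)$samples
  expect_equal(clean$series$samples, ref - min(ref), tolerance = 1e-12)

  noisy <- generate_epoch(burst_train(), p, noise_sd = 0.02, drift_amp = 0,
                          seed = 2)
  expect_lt(abs(sd(noisy$series$samples) - 0.02) / 0.02, 0.1)

  for (s in 1:5) {
    e <- generate_epoch(tr, p, seed = s)
    expect_equal(min(e$series$samples), 0)
  }
})

test_that("generate_study is deterministic and separates conditions by rate", {
  p <- tkernel
  d <- study_design(n_subjects = 6, epochs_per_subject = 4, seed = 11)
  s1 <- generate_study(d, p)
  s2 <- generate_study(d, p)
  expect_identical(s1$epochs[[5]]$series$samples,
                   s2$epochs[[5]]$series$samples)
  expect_identical(s1$truth, s2$truth)
  expect_equal(sum(s1$labels$label == "baseline"), 12)  # 2 per subject

  # doubled anticipation rate yields a positive true-count difference for
  # nearly all subjects
  pos <- 0; tot <- 0
  for (seed in 1:10) {
    st <- generate_study(study_design(n_subjects = 6, seed = seed), p)
    for (sub in unique(st$labels$subject)) {
      idx <- which(st$labels$subject == sub)
      bl <- idx[st$labels$label[idx] == "baseline"]
      an <- idx[st$labels$label[idx] == "anticipation"]
      diffc <- mean(vapply(an, function(i) n_bursts(st$truth[[i]]), 0)) -
        mean(vapply(bl, function(i) n_bursts(st$truth[[i]]), 0))
      pos <- pos + (diffc > 0); tot <- tot + 1
    }
  }
  expect_gte(pos / tot, 0.9)
})

test_that("equal condition rates produce no label-count association", {
  p <- tkernel
  rs <- vapply(1:20, function(seed) {
    st <- generate_study(study_design(n_subjects = 20, epochs_per_subject = 4,
                                      anticipation_rate = 6, seed = seed), p)
    truec <- vapply(st$truth, n_bursts, 0L)
    state <- as.integer(st$labels$label == "anticipation")
    suppressWarnings(cor(truec, state))
  }, 0)
  expect_lt(mean(abs(rs), na.rm = TRUE), 0.15)
})

test_that("between-subject designs assign condition rates by group", {
  p <- tkernel
  st <- generate_study(study_design(n_subjects = 4, epochs_per_subject = 3,
                                    design = "between",
                                    anticipation_rate = 30,
                                    baseline_rate = 2, seed = 3), p)
  lab <- st$labels
  expect_equal(sum(lab$label == "baseline"), 4)  # one per subject
  trt <- lab$group == "treatment" & lab$label == "anticipation"
  ctl <- lab$group == "control" & lab$label == "anticipation"
  n_trt <- mean(vapply(st$truth[trt], n_bursts, 0L))
  n_ctl <- mean(vapply(st$truth[ctl], n_bursts, 0L))
  expect_gt(n_trt, n_ctl)
})

test_that("match_bursts pairs nearest onsets greedily and reports errors", {
  truth <- burst_train(c(10, 30), c(0.5, 0.8))
  est <- burst_train(c(10.2, 29.9, 45), c(0.45, 0.9, 0.05))
  mm <- match_bursts(truth, est)
  expect_true(all(mm$matched))
  expect_equal(mm$onset_err, c(0.2, 0.1), tolerance = 1e-9)
  expect_equal(mm$amp_err, c(0.05, 0.1), tolerance = 1e-9)
  # sub-threshold estimates are invisible to matching
  mm2 <- match_bursts(burst_train(45, 0.5), est, threshold = 0.1)
  expect_false(any(mm2$matched))
})
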