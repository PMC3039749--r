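fake_result <- function(amplitudes, onsets = seq_along(amplitudes) * 2) {
  structure(list(bursts = burst_train(onsets, amplitudes)),
            class = "sf_inversion")
}

test_that("count_bursts applies an inclusive threshold and is monotone in it", {
  r <- fake_result(c(0.05, 0.12, 0.30))
  expect_equal(count_bursts(r, 0.1), 2)
  expect_equal(count_bursts(fake_result(numeric(0))), 0)
  expect_equal(count_bursts(r, 0), 3)
  expect_equal(count_bursts(fake_result(c(0.1, 0.2)), 0.1), 2)  # inclusive
  expect_error(count_bursts(r, -1), "non-negative")
  set.seed(2)
  for (i in 1:5) {
    amps <- runif(10, 0, 0.5)
    counts <- vapply(seq(0, 0.5, by = 0.05), function(th) {
      count_bursts(fake_result(amps), th)
    }, 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("count_sf_conventional detects simulated fluctuations by trough-to-peak rise", {
  p <- tkernel
  flat <- sf_epoch(conductance_series(numeric(600), 10))
  expect_equal(count_sf_conventional(flat), 0)
  two <- sf_epoch(baseline_subtract(
    sf_simulate(p, burst_train(c(15, 40), c(0.5, 0.5)), 60, 10)))
  expect_equal(count_sf_conventional(two, threshold = 0.25), 2)
  small <- sf_epoch(baseline_subtract(
    sf_simulate(p, burst_train(30, 0.2), 60, 10)))
  expect_equal(count_sf_conventional(small, threshold = 0.25), 0)
  expect_equal(count_sf_conventional(small, threshold = 0.1), 1)
})

test_that("pearson_r matches the closed-form sums and flags degenerate input", {
  expect_equal(pearson_r(1:5, 1:5), 1.0)
  expect_equal(pearson_r(1:5, -(1:5)), -1.0)
  x <- c(0, 1, 2, 3); y <- c(1, 1, 2, 4)
  n <- 4
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(pearson_r(x, y), r_hand, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("roc_curve equals the Mann-Whitney pairwise oracle and behaves at the extremes", {
  # perfectly separated counts
  expect_equal(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_curve(c(9, 9, 1, 1), c(1, 1, 0, 0))$auc, 1.0)
  # 50 random instances vs the brute-force pairwise construction
  set.seed(31)
  for (i in 1:50) {
    n <- sample(8:30, 1)
    counts <- rpois(n, 4)
    state <- c(0, 1, rbinom(n - 2, 1, 0.5))
    roc <- roc_curve(counts, state)
    expect_equal(roc$auc, mw_auc_oracle(counts, state), tolerance = 1e-10)
    # sorted ROC points are monotone in both coordinates
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$sens) >= 0))
    expect_true(roc$auc >= 0 && roc$auc <= 1)
  }
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both label classes")
})

test_that("coin-flip labels give chance-level AUC on average", {
  set.seed(77)
  aucs <- replicate(2000, {
    counts <- rpois(24, 5)
    state <- c(0, 1, rbinom(22, 1, 0.5))
    roc_curve(counts, state)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("nested_f_test matches the extra-sum-of-squares oracle and degenerates to F = 0", {
  set.seed(13)
  n <- 8
  state <- rnorm(n); base <- rnorm(n); add <- rnorm(n)
  got <- nested_f_test(state, base, add)
  # independent matrix-algebra oracle
  X1 <- cbind(1, base); X2 <- cbind(1, base, add)
  r1 <- state - X1 %*% normal_eq_ls(X1, state)
  r2 <- state - X2 %*% normal_eq_ls(X2, state)
  f_or <- (sum(r1^2) - sum(r2^2)) / (sum(r2^2) / (n - 3))
  expect_equal(got$F, f_or, tolerance = 1e-6)
  expect_equal(got$df1, 1L)
  expect_equal(got$df2, n - 3L)
  expect_equal(got$p, pf(f_or, 1, n - 3, lower.tail = FALSE), tolerance = 1e-9)

  # a perfect added predictor drives the full-model residual to ~0
  perfect <- nested_f_test(state, base, state)
  expect_gt(perfect$F, 1e6)

  expect_warning(out <- nested_f_test(state, base, 2 * base + 1),
                 "collinear")
  expect_equal(out$F, 0)
  # identical predictor is collinear too
  expect_warning(out2 <- nested_f_test(state, base, base), "collinear")
  expect_equal(out2$F, 0)
})

test_that("threshold_sweep reports the contracted correlations", {
  results <- lapply(1:12, function(i) {
    fake_result(c(runif(3, 0.2, 0.9), 0.05))
  })
  counts_same <- vapply(results, count_bursts, 0L, threshold = 0)
  labels <- rep(c("baseline", "anticipation"), 6)
  # identical counts in both arms: r_methods == 1 wherever defined
  sw <- threshold_sweep(results, counts_same, labels,
                        thresholds = c(0, 0.01))
  expect_true(all(sw$r_methods == 1))

  # permuted labels are uninformative on average
  set.seed(21)
  results2 <- lapply(1:16, function(i) fake_result(runif(6, 0, 0.6)))
  conv2 <- vapply(results2, count_bursts, 0L, threshold = 0.3)
  rs <- replicate(100, {
    lab <- sample(rep(0:1, 8))
    threshold_sweep(results2, conv2, lab, thresholds = 0.1)$r_validity_dcm
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(threshold_sweep(results2, conv2, rep(1, 16), 0.1),
               "both label classes")
})

test_that("arousal_scores computes anticipation-minus-baseline per subject", {
  counts <- c(2, 5, 7, 1, 2, 3)
  labels <- rep(c("baseline", "anticipation", "anticipation"), 2)
  subjects <- rep(c("a", "b"), each = 3)
  sc <- arousal_scores(counts, labels, subjects)
  expect_equal(sc$score[sc$subject == "a"], 6 - 2)
  expect_equal(sc$score[sc$subject == "b"], 2.5 - 1)
})

test_that("validity_report bundles counts, correlations, ROC and the nested test", {
  set.seed(3)
  p <- tkernel
  results <- list(); epochs <- list(); labels <- character(0)
  for (i in 1:8) {
    rate_bpm <- if (i %% 2) 4 else 12
    tr <- generate_burst_train(rate_bpm, 0.3, 1, seed = 600 + i)
    epochs[[i]] <- generate_epoch(tr, p, noise_sd = 0.02, drift_amp = 0,
                                  seed = 700 + i)
    results[[i]] <- invert_epoch(epochs[[i]], p)
    labels[i] <- if (i %% 2) "baseline" else "anticipation"
  }
  rep_ <- validity_report(results, epochs, labels)
  expect_s3_class(rep_, "validity_report")
  expect_length(rep_$counts_dcm, 8)
  expect_true(abs(rep_$r_methods) <= 1)
  expect_true(rep_$roc_dcm$auc >= 0 && rep_$roc_dcm$auc <= 1)
  expect_equal(rep_$f_df, c(1L, 5L))
  # doubled burst rate in the anticipation condition is detectable
  expect_gt(rep_$r_validity_dcm, 0)
})
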