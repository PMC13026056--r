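test_that("correct/wrong entropy split means match the partition oracle", {
  # singleton means
  hist <- entropy_history(matrix(c(0.3, 0.9), 2, 1),
                          matrix(c(TRUE, FALSE), 2, 1))
  s <- entropy_split_means(hist, 1)
  expect_equal(s$H_corr, 0.3)
  expect_equal(s$H_err, 0.9)
  # empty subsets are undefined markers, never zero
  all_ok <- entropy_history(matrix(c(0.2, 0.4), 2, 1),
                            matrix(TRUE, 2, 1))
  s2 <- entropy_split_means(all_ok, 1)
  expect_equal(s2$H_corr, 0.3)
  expect_true(is.na(s2$H_err))
  # random history vs explicit loop
  hist <- random_history(50, 10, seed = 41)
  for (e in c(1, 5, 10)) {
    sc <- 0; nc <- 0; se <- 0; ne <- 0
    for (i in 1:50) {
      if (hist$correct[i, e]) { sc <- sc + hist$H[i, e]; nc <- nc + 1 }
      else { se <- se + hist$H[i, e]; ne <- ne + 1 }
    }
    s <- entropy_split_means(hist, e)
    expect_equal(s$H_corr, sc / nc, tolerance = 1e-12)
    expect_equal(s$H_err, se / ne, tolerance = 1e-12)
  }
  expect_error(entropy_split_means(hist, 11), "outside")
})

test_that("sliding-window entropy variance matches the explicit-loop oracle", {
  # constant trajectories have zero fluctuation at every epoch
  const <- entropy_history(matrix(rep(c(0.2, 0.7, 1.0), 20), 3, 20,
                                  byrow = FALSE),
                           matrix(TRUE, 3, 20))
  expect_equal(sliding_window_entropy_variance(const, 5), rep(0, 20))

  hist <- random_history(30, 60, seed = 42)
  v <- sliding_window_entropy_variance(hist, 20)
  for (e in c(1, 2, 7, 20, 21, 45, 60)) {
    idx <- max(1, e - 20 + 1):e
    acc <- 0
    for (i in 1:30) acc <- acc + oracle_pop_var(hist$H[i, idx])
    expect_equal(v[e], acc / 30, tolerance = 1e-12)
  }
  # truncated early windows: epoch 1 uses the single-epoch window
  expect_equal(v[1], 0)

  # invariance to a per-sample constant offset across all epochs
  shifted <- entropy_history(hist$H + matrix(runif(30), 30, 60), hist$correct)
  expect_equal(sliding_window_entropy_variance(shifted, 20), v,
               tolerance = 1e-10)

  # the sample mean commutes with the per-sample window statistic:
  # accumulating window moments epoch-block-wise gives the same score
  for (e in c(3, 30)) {
    idx <- max(1, e - 20 + 1):e
    m1 <- rep(0, 30); m2 <- rep(0, 30)
    for (i in idx) {
      m1 <- m1 + hist$H[, i] / length(idx)
      m2 <- m2 + hist$H[, i]^2 / length(idx)
    }
    expect_equal(mean(m2 - m1^2), v[e], tolerance = 1e-12)
  }
  expect_error(sliding_window_entropy_variance(hist, 1), "W must be")
})

test_that("subject-wise delta correlations match the textbook Pearson formula", {
  mk <- function(subject, method, acc, h, v) {
    data.frame(subject = subject, method = method, acc = acc,
               h_mean = h, var_mean = v)
  }
  # perfect linearity in both directions
  accs <- c(0.6, 0.7, 0.8, 0.9)
  sm <- rbind(
    mk(1:4, "ours", accs, 0.5 - 2 * accs, 0.1 + accs),
    mk(1:4, "A2", accs - accs, 0.5, 0.1))
  # dH = 2*acc, dAcc = acc -> r = 1; dVar = -acc -> r = -1
  r <- delta_correlation(sm, "A2")
  expect_equal(r$r_entropy, 1, tolerance = 1e-12)
  expect_equal(r$r_variance, -1, tolerance = 1e-12)
  expect_equal(r$n_subjects, 4)

  set.seed(43)
  sm2 <- rbind(
    mk(1:9, "ours", runif(9, 0.5, 0.9), runif(9, 0.2, 0.8), runif(9, 0, 0.1)),
    mk(1:9, "A3", runif(9, 0.4, 0.8), runif(9, 0.2, 0.8), runif(9, 0, 0.1)))
  r2 <- delta_correlation(sm2, "A3")
  ours <- sm2[sm2$method == "ours", ]; base <- sm2[sm2$method == "A3", ]
  expect_equal(r2$r_entropy,
               oracle_pearson(ours$acc - base$acc, base$h_mean - ours$h_mean),
               tolerance = 1e-12)
  expect_equal(r2$r_variance,
               oracle_pearson(ours$acc - base$acc,
                              base$var_mean - ours$var_mean),
               tolerance = 1e-12)

  # zero-variance deltas are undefined
  sm3 <- rbind(mk(1:3, "ours", 0.7, 0.5, 0.1), mk(1:3, "A2", 0.6, 0.6, 0.2))
  r3 <- delta_correlation(sm3, "A2")
  expect_true(is.na(r3$r_entropy) && is.na(r3$r_variance))
  expect_error(delta_correlation(sm3[c(1, 4), ], "A2"), ">= 3 subjects")
})

test_that("run histories convert to entropy histories and subject summaries", {
  d <- tiny_data(n_train = 24, n_test = 12, n_samples = 32, seed = 9)
  cfg <- distill_config(C = 3, K = 2, N = 2, E_T = 1, batch_size = 12,
                        seed = 35)
  bank <- train_teacher_bank(d$train, cfg)
  h <- train_student(d$train, d$test, bank, cfg)
  eh <- as_entropy_history(h)
  expect_equal(dim(eh$H), c(12, 6))
  ss <- subject_summary(h, subject = 1, method = "ours", W = 4)
  expect_equal(ss$acc, h$epochs$test_acc[6])
  expect_equal(ss$h_mean, mean(eh$H[, 6]))
  expect_true(ss$var_mean >= 0)
  h_nosnap <- train_student(d$train, d$test, bank, cfg,
                            snapshot_entropy = FALSE)
  expect_error(as_entropy_history(h_nosnap), "without entropy snapshots")
})
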