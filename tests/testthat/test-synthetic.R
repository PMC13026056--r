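test_that("generation is deterministic and label-balanced with disjoint splits", {
  spec <- synth_spec(seed = 5)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$train$trials, d2$train$trials)
  expect_identical(d1$test$labels, d2$test$labels)
  tb <- table(d1$train$labels)
  expect_equal(length(tb), 3L)
  expect_lte(diff(range(tb)), 1)
  expect_lte(diff(range(table(d1$test$labels))), 1)
  # a different seed draws different data
  expect_false(identical(generate_dataset(synth_spec(seed = 6))$train$trials,
                         d1$train$trials))
  expect_error(synth_spec(n_train = 2, C = 3), "n_train")
  expect_error(synth_spec(snr = 0), "snr")
  expect_error(synth_spec(class_freqs = c(10, 10, 12)), "distinct")
})

test_that("measured per-trial SNR tracks the requested level within 10%", {
  for (snr in c(0.5, 1, 2)) {
    spec <- synth_spec(n_train = 100, n_test = 3, snr = snr, seed = 17)
    d <- generate_dataset(spec, return_components = TRUE)
    sig <- d$components$train_signal
    noi <- d$components$train_noise
    # electrode-level: power per active-channel sample over noise power there
    ratios <- sapply(seq_len(100), function(i) {
      act <- spec$active_channels[[d$train$labels[i]]]
      sum(sig[i, act, ]^2) / sum(noi[i, act, ]^2)
    })
    expect_lt(abs(mean(ratios) - snr) / snr, 0.10)
  }
})

test_that("class-conditional spectra peak at the class frequency on active channels", {
  spec <- synth_spec(snr = 5, freq_jitter = 0, seed = 18)
  d <- generate_dataset(spec)
  fs <- spec$fs; n <- spec$n_samples
  freqs_hz <- (seq_len(n / 2) - 1) * fs / n
  for (c in 1:3) {
    ch <- spec$active_channels[[c]][1]
    trials <- which(d$train$labels == c)
    pw <- rep(0, n / 2)
    for (i in trials) {
      f <- stats::fft(d$train$trials[i, ch, ])
      pw <- pw + Mod(f[seq_len(n / 2)])^2
    }
    peak_hz <- freqs_hz[which.max(pw[-1]) + 1]  # skip DC
    expect_lt(abs(peak_hz - spec$class_freqs[c]), fs / n + 1e-9)
  }
  # with per-trial frequency jitter the averaged peak stays near the centre
  spec_j <- synth_spec(snr = 5, seed = 18)
  dj <- generate_dataset(spec_j)
  for (c in 1:3) {
    ch <- spec_j$active_channels[[c]][1]
    pw <- rep(0, n / 2)
    for (i in which(dj$train$labels == c)) {
      pw <- pw + Mod(stats::fft(dj$train$trials[i, ch, ])[seq_len(n / 2)])^2
    }
    peak_hz <- freqs_hz[which.max(pw[-1]) + 1]
    expect_lt(abs(peak_hz - spec_j$class_freqs[c]), 2 * spec_j$freq_jitter)
  }
})

test_that("high SNR makes classes separable by band power; zero SNR is chance", {
  # near-noiseless, distinct single active channel per class, no frequency
  # jitter: a per-channel band-power rule classifies perfectly
  spec <- synth_spec(snr = 1e4, n_train = 30, n_test = 60, seed = 19,
                     freq_jitter = 0, amp_jitter = 0,
                     active_channels = list(1L, 2L, 3L))
  d <- generate_dataset(spec)
  n <- spec$n_samples
  bin_of <- function(f_hz) round(f_hz * n / spec$fs) + 1
  pred <- sapply(seq_len(d$test$n), function(i) {
    scores <- sapply(1:3, function(c) {
      ch <- spec$active_channels[[c]][1]
      Mod(stats::fft(d$test$trials[i, ch, ])[bin_of(spec$class_freqs[c])])^2
    })
    which.max(scores)
  })
  expect_equal(mean(pred == d$test$labels), 1)

  # vanishing SNR: a trained model cannot beat chance beyond binomial noise
  spec0 <- synth_spec(snr = 1e-6, n_train = 90, n_test = 150,
                      n_samples = 64, seed = 20)
  d0 <- generate_dataset(spec0)
  net <- build_backbone("tinycnn", 4, 64, 3, seed = 3)
  fit <- .train_ce(net$arch, net$params, d0$train$trials, d0$train$labels,
                   epochs = 15, lr = 1e-3, weight_decay = 0.009,
                   batch_size = 32, seed = 3)
  acc <- evaluate_model(net$arch, fit$params, d0$test)$accuracy
  expect_lt(abs(acc - 1 / 3), 0.13)  # ~3.4 binomial sd at n = 150
})

test_that("logit fixtures cover the declared regimes", {
  for (C in 2:4) {
    fx <- generate_logit_fixtures(C, n = 30, seed = 2)
    regimes <- vapply(fx, `[[`, "", "regime")
    expect_true(all(c("confident", "uniformish", "adversarial", "zeros",
                      "identical", "tie") %in% regimes))
    zeros <- fx[[which(regimes == "zeros")[1]]]
    expect_identical(zeros$teacher, numeric(C))
    ident <- fx[[which(regimes == "identical")[1]]]
    expect_equal(kd_loss(temp_softmax(ident$teacher, 4), ident$student, 4), 0,
                 tolerance = 1e-12)
    # entropy recomputation separates the confident and uniformish regimes
    h_of <- function(z) predictive_entropy(temp_softmax(z, 1))
    h_conf <- mean(sapply(fx[regimes == "confident"],
                          function(f) h_of(f$teacher)))
    h_unif <- mean(sapply(fx[regimes == "uniformish"],
                          function(f) h_of(f$teacher)))
    expect_lt(h_conf, h_unif)
    # adversarial pairs: teacher and student argmax disagree
    for (f in fx[regimes == "adversarial"]) {
      expect_false(which.max(f$teacher) == which.max(f$student))
    }
  }
})
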