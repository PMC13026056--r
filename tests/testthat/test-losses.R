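test_that("temperature-scaled softmax matches direct evaluation, is shift-invariant, and has the right temperature limits", {
  expect_equal(temp_softmax(c(0, 0, 0, 0), tau = 4), rep(0.25, 4))
  expect_equal(temp_softmax(c(2, 0, -2), tau = 4),
               oracle_softmax(c(2, 0, -2), 4), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:50) {
    C <- sample(2:6, 1)
    z <- rnorm(C, 0, 3)
    tau <- runif(1, 0.2, 8)
    expect_equal(temp_softmax(z, tau), oracle_softmax(z, tau), tolerance = 1e-10)
    expect_equal(temp_softmax(z, tau), temp_softmax(z + rnorm(1, 0, 10), tau),
                 tolerance = 1e-12)
  }

  gapped <- c(3, 1, -1, -4)
  expect_equal(temp_softmax(gapped, 1e3), rep(0.25, 4), tolerance = 1e-2)
  expect_equal(temp_softmax(gapped, 1e-3), c(1, 0, 0, 0), tolerance = 1e-6)

  expect_error(temp_softmax(c(0, 1), tau = 0), "tau")
  expect_error(temp_softmax(c(0, 1), tau = -1), "tau")
  expect_error(temp_softmax(c(0, NA), tau = 1), "finite")
  expect_error(temp_softmax(c(0, Inf), tau = 1), "finite")
})

test_that("cross-entropy equals -log of the softmax entry and handles limits", {
  expect_equal(cross_entropy(rep(0, 5), 3), log(5))
  expect_lt(cross_entropy(c(30, 0, 0), 1), 1e-10)
  set.seed(12)
  for (i in 1:50) {
    C <- sample(2:6, 1)
    z <- rnorm(C, 0, 3)
    y <- sample.int(C, 1)
    expect_equal(cross_entropy(z, y), -log(oracle_softmax(z, 1)[y]),
                 tolerance = 1e-10)
    expect_gte(cross_entropy(z, y), 0)
  }
  expect_error(cross_entropy(c(0, 0), 3), "class index")
  expect_error(cross_entropy(c(0, 0), 0), "class index")
})

test_that("KD loss is tau^2-scaled KL, zero iff distributions coincide", {
  # identical distributions
  set.seed(13)
  z <- rnorm(4)
  expect_equal(kd_loss(temp_softmax(z, 4), z, 4), 0, tolerance = 1e-9)
  # closed form: tau=1, one-hot teacher vs uniform student
  expect_equal(kd_loss(c(1, 0), c(0, 0), 1), log(2), tolerance = 1e-12)
  # zero-probability teacher entries contribute nothing
  expect_equal(kd_loss(c(0.5, 0.5, 0), c(1, 0, -40), 2),
               oracle_kd(c(0.5, 0.5, 0), c(1, 0, -40), 2), tolerance = 1e-9)
  for (i in 1:100) {
    C <- sample(2:6, 1)
    q <- random_prob(C)
    z <- rnorm(C, 0, 3)
    tau <- sample(c(1, 2, 4), 1)
    expect_equal(kd_loss(q, z, tau), oracle_kd(q, z, tau), tolerance = 1e-8)
    expect_gte(kd_loss(q, z, tau), -1e-12)
  }
  expect_error(kd_loss(c(0.7, 0.6), c(0, 0), 1), "sum to 1")
})

test_that("predictive and normalised entropy match the summation oracle and bounds", {
  expect_equal(predictive_entropy(c(1, 0, 0)), 0)
  expect_equal(predictive_entropy(rep(0.25, 4)), log(4))
  expect_equal(predictive_entropy(c(0.5, 0.25, 0.25)),
               oracle_entropy(c(0.5, 0.25, 0.25)), tolerance = 1e-12)
  expect_equal(normalized_entropy(rep(1 / 3, 3)), 1)
  expect_equal(normalized_entropy(c(1, 0, 0, 0)), 0)
  set.seed(14)
  for (i in 1:100) {
    C <- sample(2:7, 1)
    p <- random_prob(C)
    h <- predictive_entropy(p)
    expect_equal(h, oracle_entropy(p), tolerance = 1e-10)
    expect_true(h >= 0 && h <= log(C) + 1e-12)
    expect_equal(normalized_entropy(p), oracle_entropy(p) / log(C),
                 tolerance = 1e-10)
  }
  expect_error(normalized_entropy(1), "C >= 2")
})

test_that("entropy gate hits its knots exactly, is monotone and clip-idempotent", {
  gp <- list(h_low = 0.6, h_high = 0.9)
  expect_identical(entropy_gate(0.6, gp), 0)
  expect_identical(entropy_gate(0.9, gp), 1)
  expect_equal(entropy_gate(0.75, gp), 0.5)
  expect_identical(entropy_gate(0, gp), 0)
  expect_identical(entropy_gate(1, gp), 1)
  hs <- seq(0, 1, by = 0.01)
  w <- entropy_gate(hs, gp)
  expect_true(all(diff(w) >= 0))          # monotone non-decreasing
  expect_true(all(w >= 0 & w <= 1))
  # idempotent under clipping: gating the clamped pre-image changes nothing
  pre <- pmin(pmax(hs, gp$h_low), gp$h_high)
  expect_equal(entropy_gate(pre, gp), w)
  expect_error(entropy_gate(0.5, list(h_low = 0.9, h_high = 0.6)), "h_low")
  expect_error(entropy_gate(1.5, gp), "\\[0, 1\\]")
})

test_that("total loss decomposes into independently recomputed components", {
  cfg <- distill_config(C = 4, tau = 4, lambda_ens = 0.5, lambda_ema = 0.4)
  gp <- list(h_low = cfg$h_low, h_high = cfg$h_high)
  set.seed(15)
  n_checked <- 0
  for (i in 1:1000) {
    C <- 4
    z_s <- rnorm(C, 0, 3)
    y <- sample.int(C, 1)
    q_ens <- random_prob(C)
    q_ema <- random_prob(C)
    phase2 <- (i %% 2 == 0)
    lb <- total_loss(z_s, y, q_ens, if (phase2) q_ema else NULL, cfg,
                     phase2_active = phase2)
    l_ce <- -log(oracle_softmax(z_s, 1)[y])
    l_ens <- oracle_kd(q_ens, z_s, cfg$tau)
    expected <- l_ce + cfg$lambda_ens * l_ens
    if (phase2) {
      l_ema <- oracle_kd(q_ema, z_s, cfg$tau)
      h <- oracle_entropy(q_ema) / log(C)
      w <- min(max((h - gp$h_low) / (gp$h_high - gp$h_low), 0), 1)
      expected <- expected + cfg$lambda_ema * w * l_ema
      expect_equal(lb$gate_w, w, tolerance = 1e-9)
    } else {
      expect_identical(lb$l_kd_ema, 0)
      expect_identical(lb$lambda_ema_e, 0)
    }
    expect_equal(lb$total, expected, tolerance = 1e-6)
    expect_equal(lb$total,
                 lb$l_ce + cfg$lambda_ens * lb$l_kd_ens +
                   lb$lambda_ema_e * lb$gate_w * lb$l_kd_ema,
                 tolerance = 1e-6)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 1000)

  # degenerate config: no ensemble weight -> plain supervised loss
  cfg0 <- distill_config(C = 3, lambda_ens = 0)
  lb <- total_loss(c(1, 0, -1), 2, NULL, NULL, cfg0, phase2_active = FALSE)
  expect_equal(lb$total, cross_entropy(c(1, 0, -1), 2))

  # missing EMA target in phase 2 is an input error
  expect_error(total_loss(c(1, 0, -1), 1, random_prob(3), NULL,
                          distill_config(C = 3), phase2_active = TRUE),
               "q_ema")
})

test_that("loss gradient flows only through the student logits", {
  cfg <- distill_config(C = 4)
  set.seed(16)
  for (i in 1:20) {
    z_s <- rnorm(4, 0, 2)
    y <- sample.int(4, 1)
    q_ens <- random_prob(4)
    q_ema <- random_prob(4)
    phase2 <- (i %% 2 == 0)
    g <- total_loss_grad(z_s, y, q_ens, if (phase2) q_ema else NULL, cfg,
                         phase2_active = phase2)
    # analytic gradient vs central finite differences with teachers frozen
    eps <- 1e-6
    for (c in 1:4) {
      zp <- z_s; zp[c] <- zp[c] + eps
      zm <- z_s; zm[c] <- zm[c] - eps
      num <- (total_loss(zp, y, q_ens, if (phase2) q_ema else NULL, cfg,
                         phase2)$total -
              total_loss(zm, y, q_ens, if (phase2) q_ema else NULL, cfg,
                         phase2)$total) / (2 * eps)
      expect_equal(g[c], num, tolerance = 1e-5)
    }
    if (phase2) {
      # the gate weight itself is a constant w.r.t. gradients: replacing the
      # EMA distribution by one with the same gate and softened distance
      # direction changes the gradient only through (ptau - q_ema)
      g2 <- total_loss_grad(z_s, y, q_ens, q_ema, cfg, TRUE)
      expect_identical(g, g2)  # pure function of its inputs
    }
  }
})
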