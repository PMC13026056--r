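# Online student training with dual-teacher distillation.
#
# Per epoch e in 1..3N: the learning rate comes from the two-stage cosine
# schedule (or a fixed 0.001 under the A3 ablation, which leaves all phase
# bookkeeping untouched); at e = N + 1 the EMA teacher is initialised from
# the student (skipped under A2). Per batch: student forward, batch-mean
# gradient of
#   L = L_ce + lambda_ens * L_kd_ens + lambda_ema(e) * w(x) * L_kd_ema,
# AdamW step, then the EMA update. Ensemble logits are precomputed once per
# training trial before the loop (the teachers are fixed, so caching changes
# nothing numerically). The deployed parameters are always those of the last
# epoch: no early stopping and no validation split.
#
# RNG contract (what makes runs bitwise replayable from cfg$seed):
#   * initialisation uses derive_seed(cfg$seed, "student-init"),
#   * the epoch-e shuffle uses derive_seed(cfg$seed, "student-shuffle", e),
#   * nothing else consumes randomness.

#' Train the distilled student
#'
#' @param train,test [labeled_dataset()]s; the test set is only monitored
#'   (accuracy and per-sample entropy snapshots), never used for selection.
#' @param bank a [train_teacher_bank()] result; may be `NULL` when the
#'   ensemble KD term is disabled (`A1` ablation or `lambda_ens = 0`).
#' @param cfg a [distill_config()]; `cfg$ablation` selects the training
#'   variant (see [distill_config()]).
#' @param backbone registered backbone name.
#' @param width backbone width multiplier.
#' @param snapshot_entropy store the per-test-sample temperature-1 entropy
#'   and correctness matrices (needed for the entropy diagnostics; the extra
#'   cost is one test forward per epoch, which is also what accuracy
#'   monitoring uses).
#' @return object of class `run_history`: per-epoch data frame `epochs`
#'   (eta, phase, mean loss components, mean gate weight, train/test
#'   accuracy), entropy matrix `H` and correctness matrix `correct`
#'   (test samples x epochs) when snapshots are on, `final_params` (and
#'   `final_ema_params` when the EMA teacher ran), `arch`,
#'   `cfg`, and `ema_init_logit_gap` (max |EMA - student| logit difference
#'   on the first Phase-II batch immediately after initialisation; exactly 0
#'   by the copy-semantics contract).
#' @export
train_student <- function(train, test, bank = NULL, cfg,
                          backbone = "tinycnn", width = 1L,
                          snapshot_entropy = TRUE) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(test, "labeled_dataset"))
  abl <- cfg$ablation
  use_ens <- !("A1" %in% abl) && cfg$lambda_ens > 0
  use_ema <- !("A2" %in% abl)
  use_cos <- !("A3" %in% abl)
  use_gate <- !("A4" %in% abl)
  if (train$n_classes > cfg$C) {
    stop_input("training set has %d classes but config C = %d",
               train$n_classes, cfg$C)
  }
  if (use_ens) {
    if (is.null(bank)) stop_input("ensemble KD is enabled but bank is NULL")
    if (bank$C != cfg$C) {
      stop_input("class-count mismatch: bank has %d classes, config C = %d",
                 bank$C, cfg$C)
    }
  }
  net <- build_backbone(backbone, train$n_channels, train$n_samples, cfg$C,
                        seed = derive_seed(cfg$seed, "student-init"),
                        width = width)
  arch <- net$arch; params <- net$params
  opt <- adamw_init(params)
  gate <- list(h_low = cfg$h_low, h_high = cfg$h_high)
  E <- 3L * cfg$N
  n_tr <- train$n

  q_ens_all <- NULL
  if (use_ens) {
    z_ens <- ensemble_logits(bank, train$trials)
    q_ens_all <- .softmax_rows(z_ens, cfg$tau)
  }

  ep <- data.frame(epoch = seq_len(E), phase = "", t = NA_real_,
                   eta = NA_real_, loss_ce = NA_real_, loss_kd_ens = NA_real_,
                   loss_kd_ema = NA_real_, gate_w = NA_real_,
                   train_acc = NA_real_, test_acc = NA_real_,
                   stringsAsFactors = FALSE)
  H <- if (snapshot_entropy) matrix(NA_real_, test$n, E) else NULL
  corr <- if (snapshot_entropy) matrix(NA, test$n, E) else NULL
  ema <- NULL
  ema_gap <- NA_real_

  for (e in seq_len(E)) {
    st <- stage_of_epoch(e, cfg$N, cfg$eta_max, cfg$eta_min)
    eta <- if (use_cos) st$eta else 1e-3
    if (e == cfg$N + 1L && use_ema) {
      ema <- ema_init(params, arch, epoch = e, prev = ema)
    }
    phase2 <- (e > cfg$N) && use_ema

    set.seed(derive_seed(cfg$seed, "student-shuffle", e))
    ord <- sample.int(n_tr)
    starts <- seq.int(1, n_tr, by = cfg$batch_size)
    sums <- c(ce = 0, ens = 0, ema = 0, w = 0)
    first_batch <- TRUE
    for (s in starts) {
      b <- ord[s:min(s + cfg$batch_size - 1, n_tr)]
      nb <- length(b)
      xb <- aperm(train$trials[b, , , drop = FALSE], c(2, 3, 1))
      fw <- backbone_forward(arch, params, xb, keep_cache = TRUE)
      Z <- fw$logits
      P1 <- .softmax_rows(Z, 1)
      idx <- cbind(seq_len(nb), train$labels[b])
      G <- P1
      G[idx] <- G[idx] - 1
      sums["ce"] <- sums["ce"] + sum(-log(pmax(P1[idx], .LOG_EPS)))
      if (use_ens || phase2) Ptau <- .softmax_rows(Z, cfg$tau)
      if (use_ens) {
        Q <- q_ens_all[b, , drop = FALSE]
        G <- G + cfg$lambda_ens * cfg$tau * (Ptau - Q)
        sums["ens"] <- sums["ens"] + sum(.kd_rows(Q, Ptau, cfg$tau))
      }
      if (phase2) {
        Zema <- backbone_forward(arch, ema$params, xb)$logits
        if (first_batch && e == cfg$N + 1L) {
          ema_gap <- max(abs(Zema - Z))
        }
        Qema <- .softmax_rows(Zema, cfg$tau)
        w <- if (use_gate) {
          entropy_gate(.entropy_rows(Qema) / log(cfg$C), gate)
        } else rep(1, nb)
        G <- G + cfg$lambda_ema * w * cfg$tau * (Ptau - Qema)
        sums["ema"] <- sums["ema"] + sum(.kd_rows(Qema, Ptau, cfg$tau))
        sums["w"] <- sums["w"] + sum(w)
      }
      G <- G / nb
      grads <- backbone_backward(arch, params, fw$cache, G)
      stp <- adamw_step(opt, params, grads, eta, cfg$weight_decay)
      params <- stp$params; opt <- stp$opt
      if (phase2) ema <- ema_update(ema, params, cfg$alpha)
      first_batch <- FALSE
    }

    ev_tr <- evaluate_model(arch, params, train)
    ev_te <- evaluate_model(arch, params, test)
    ep$phase[e] <- st$phase; ep$t[e] <- st$t; ep$eta[e] <- eta
    ep$loss_ce[e] <- sums["ce"] / n_tr
    ep$loss_kd_ens[e] <- sums["ens"] / n_tr
    ep$loss_kd_ema[e] <- if (phase2) sums["ema"] / n_tr else 0
    ep$gate_w[e] <- if (phase2) sums["w"] / n_tr else 0
    ep$train_acc[e] <- ev_tr$accuracy
    ep$test_acc[e] <- ev_te$accuracy
    if (snapshot_entropy) {
      H[, e] <- .entropy_rows(ev_te$prob)
      corr[, e] <- ev_te$predicted == test$labels
    }
  }

  structure(list(epochs = ep, H = H, correct = corr,
                 final_params = params,
                 final_ema_params = if (!is.null(ema)) ema$params,
                 arch = arch, cfg = cfg,
                 backbone = backbone,
                 ema_activation_epoch = if (use_ema) cfg$N + 1L else NA_integer_,
                 ema_init_logit_gap = ema_gap),
            class = "run_history")
}

# row-wise tau^2-scaled KL between a teacher probability matrix and the
# already-softened student probability matrix
.kd_rows <- function(Q, Ptau, tau) {
  Tm <- Q * (log(pmax(Q, .LOG_EPS)) - log(pmax(Ptau, .LOG_EPS)))
  Tm[Q == 0] <- 0
  tau^2 * rowSums(Tm)
}

#' Evaluate a parameter set on a dataset
#'
#' Deterministic inference pass; accuracy is the fraction of argmax-correct
#' predictions, with argmax ties broken toward the lowest class index.
#'
#' @param arch backbone architecture.
#' @param params parameter list.
#' @param ds a [labeled_dataset()].
#' @return list with `accuracy`, `prob` (n x C temperature-1 probability
#'   matrix) and `predicted` (1-based class indices).
#' @export
evaluate_model <- function(arch, params, ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (ds$n == 0) stop_input("cannot evaluate on an empty dataset")
  Z <- .forward_trials(arch, params, ds$trials)
  P <- .softmax_rows(Z, 1)
  pred <- max.col(P, ties.method = "first")
  list(accuracy = mean(pred == ds$labels), prob = P, predicted = pred)
}

#' @export
print.run_history <- function(x, ...) {
  E <- nrow(x$epochs)
  cat(sprintf(
    "<run_history> %d epochs ('%s', ablation %s): final train acc %.3f, test acc %.3f\n",
    E, x$backbone, paste(x$cfg$ablation, collapse = "+"),
    x$epochs$train_acc[E], x$epochs$test_acc[E]))
  invisible(x)
}
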