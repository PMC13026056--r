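# Offline K-fold bagging ensemble teacher.
#
# The training set is split into K disjoint, size-balanced folds; member k
# is trained with plain cross-entropy on all trials outside fold k (leave-
# one-fold-out bagging encourages member diversity, helped further by a
# distinct derived seed per member). Members are trained with AdamW at a
# fixed learning rate (no annealing). At student-training time the ensemble
# serves the arithmetic mean of member logits -- averaging happens in logit
# space, not probability space -- which is then temperature-softened into
# the ensemble soft target. Ensemble outputs are constants with respect to
# the student's gradients.

#' Deterministic balanced K-fold partition
#'
#' @param n_trials number of trials (>= K).
#' @param K number of folds (>= 2).
#' @param seed partition seed.
#' @return object of class `fold_assignment`: list with `fold_of_trial`
#'   (integer vector in 1..K) and `K`. Folds are disjoint, cover all trials
#'   and differ in size by at most one.
#' @export
kfold_partition <- function(n_trials, K, seed = 1L) {
  if (K < 2) stop_input("K must be >= 2")
  if (K > n_trials) stop_input("K (%d) exceeds n_trials (%d)", K, n_trials)
  set.seed(derive_seed(seed, "folds", n_trials, K))
  ord <- sample.int(n_trials)
  sizes <- rep(n_trials %/% K, K)
  if (n_trials %% K > 0) sizes[seq_len(n_trials %% K)] <- sizes[seq_len(n_trials %% K)] + 1L
  fold <- integer(n_trials)
  fold[ord] <- rep.int(seq_len(K), times = sizes)
  structure(list(fold_of_trial = fold, K = as.integer(K)),
            class = "fold_assignment")
}

# one plain cross-entropy fit (used for teachers and the CE reference arm)
.train_ce <- function(arch, params, trials, labels, epochs, lr, weight_decay,
                      batch_size, seed, log_batches = FALSE) {
  n <- dim(trials)[1]
  opt <- adamw_init(params)
  loss_log <- numeric(epochs)
  batch_log <- if (log_batches) vector("list", epochs) else NULL
  for (e in seq_len(epochs)) {
    set.seed(derive_seed(seed, "shuffle", e))
    ord <- sample.int(n)
    starts <- seq.int(1, n, by = batch_size)
    if (log_batches) batch_log[[e]] <- list()
    tot <- 0
    for (s in starts) {
      b <- ord[s:min(s + batch_size - 1, n)]
      if (log_batches) batch_log[[e]][[length(batch_log[[e]]) + 1]] <- b
      xb <- aperm(trials[b, , , drop = FALSE], c(2, 3, 1))
      fw <- backbone_forward(arch, params, xb, keep_cache = TRUE)
      P <- .softmax_rows(fw$logits, 1)
      idx <- cbind(seq_along(b), labels[b])
      tot <- tot + sum(-log(pmax(P[idx], .LOG_EPS)))
      G <- P
      G[idx] <- G[idx] - 1
      G <- G / length(b)
      grads <- backbone_backward(arch, params, fw$cache, G)
      st <- adamw_step(opt, params, grads, lr, weight_decay)
      params <- st$params; opt <- st$opt
    }
    loss_log[e] <- tot / n
  }
  list(params = params, loss_log = loss_log, batch_log = batch_log)
}

#' Train the K-fold ensemble teacher bank
#'
#' Trains `cfg$K` copies of the backbone, member k on the trials outside
#' fold k, each for `cfg$E_T` epochs of cross-entropy with AdamW at the
#' fixed learning rate `cfg$eta_T`. Per-member initialisation and shuffle
#' seeds are derived from `cfg$seed` so members differ even on identical
#' data.
#'
#' @param ds training [labeled_dataset()].
#' @param cfg a [distill_config()] (uses `K`, `E_T`, `eta_T`, `batch_size`,
#'   `weight_decay`, `seed`, `C`).
#' @param backbone registered backbone name.
#' @param width backbone width multiplier.
#' @param log_batches record the trial indices of every batch (small runs
#'   only; used to audit the leave-one-fold-out contract).
#' @return object of class `teacher_bank`.
#' @export
train_teacher_bank <- function(ds, cfg, backbone = "tinycnn", width = 1L,
                               log_batches = FALSE) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (ds$n_classes > cfg$C) {
    stop_input("dataset has %d classes but config C = %d", ds$n_classes, cfg$C)
  }
  folds <- kfold_partition(ds$n, cfg$K, seed = cfg$seed)
  members <- vector("list", cfg$K)
  seeds <- integer(cfg$K)
  train_log <- vector("list", cfg$K)
  batch_logs <- vector("list", cfg$K)
  arch <- NULL
  for (k in seq_len(cfg$K)) {
    seeds[k] <- derive_seed(cfg$seed, "teacher", k)
    net <- build_backbone(backbone, ds$n_channels, ds$n_samples, cfg$C,
                          seed = derive_seed(seeds[k], "init"), width = width)
    arch <- net$arch
    keep <- which(folds$fold_of_trial != k)
    fit <- .train_ce(net$arch, net$params,
                     ds$trials[keep, , , drop = FALSE], ds$labels[keep],
                     epochs = cfg$E_T, lr = cfg$eta_T,
                     weight_decay = cfg$weight_decay,
                     batch_size = cfg$batch_size, seed = seeds[k],
                     log_batches = log_batches)
    members[[k]] <- fit$params
    train_log[[k]] <- fit$loss_log
    if (log_batches) {
      # map batch-local indices back to original trial ids
      batch_logs[[k]] <- lapply(fit$batch_log, function(ep)
        lapply(ep, function(b) keep[b]))
    }
  }
  structure(list(members = members, arch = arch, backbone = backbone,
                 folds = folds, K = cfg$K, C = cfg$C, E_T = cfg$E_T,
                 eta_T = cfg$eta_T, seeds = seeds, train_log = train_log,
                 batch_log = if (log_batches) batch_logs else NULL),
            class = "teacher_bank")
}

#' @export
print.teacher_bank <- function(x, ...) {
  cat(sprintf("<teacher_bank> %d x '%s' (%d classes), E_T = %d @ lr %g\n",
              x$K, x$backbone, x$C, x$E_T, x$eta_T))
  invisible(x)
}

#' Averaged ensemble logits
#'
#' `z_ens(x) = (1/K) * sum_k z^(k)(x)`, every member evaluated in inference
#' mode. The result is a constant target for the student (no gradient path).
#'
#' @param bank a [train_teacher_bank()] result.
#' @param x a single (channels, time) trial, a (channels, time, batch)
#'   array, or an (n, channels, time) trial array / [labeled_dataset()].
#' @return n x C logit matrix.
#' @export
ensemble_logits <- function(bank, x) {
  if (!inherits(bank, "teacher_bank") ||
      length(bank$members) != bank$K ||
      any(vapply(bank$members, is.null, TRUE))) {
    stop_input("incomplete teacher bank")
  }
  if (inherits(x, "labeled_dataset")) x <- x$trials
  if (length(dim(x)) == 2) {
    x <- array(x, c(1, dim(x)))
  } else if (length(dim(x)) == 3 && dim(x)[1] == bank$arch$n_channels &&
             dim(x)[2] == bank$arch$n_samples) {
    x <- aperm(x, c(3, 1, 2))  # (channels, time, batch) -> trial-major
  }
  acc <- NULL
  for (k in seq_len(bank$K)) {
    zk <- .forward_trials(bank$arch, bank$members[[k]], x)
    acc <- if (is.null(acc)) zk else acc + zk
  }
  acc / bank$K
}

#' Save a teacher bank to a directory archive
#'
#' One parameter checkpoint per member plus a JSON manifest (backbone name,
#' geometry, K, fold assignment, per-member seeds, E_T, eta_T).
#'
#' @param bank a `teacher_bank`; @param dir target directory.
#' @export
save_teacher_bank <- function(bank, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(backbone = bank$backbone, K = bank$K, C = bank$C,
                   n_channels = bank$arch$n_channels,
                   n_samples = bank$arch$n_samples,
                   width = bank$arch$width,
                   E_T = bank$E_T, eta_T = bank$eta_T, seeds = bank$seeds,
                   fold_of_trial = bank$folds$fold_of_trial,
                   train_log = bank$train_log)
  jsonlite::write_json(manifest, file.path(dir, "bank.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_len(bank$K)) {
    saveRDS(bank$members[[k]], file.path(dir, sprintf("member_%02d.rds", k)))
  }
  invisible(dir)
}

#' Load a teacher bank archive
#' @param dir directory written by [save_teacher_bank()].
#' @return a `teacher_bank`.
#' @export
load_teacher_bank <- function(dir) {
  mf_path <- file.path(dir, "bank.json")
  if (!file.exists(mf_path)) stop_input("no teacher bank manifest at %s", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  net <- build_backbone(mf$backbone, mf$n_channels, mf$n_samples, mf$C,
                        seed = 1L, width = mf$width %||% 1L)
  members <- lapply(seq_len(mf$K), function(k)
    readRDS(file.path(dir, sprintf("member_%02d.rds", k))))
  structure(list(members = members, arch = net$arch, backbone = mf$backbone,
                 folds = structure(list(fold_of_trial = mf$fold_of_trial,
                                        K = mf$K), class = "fold_assignment"),
                 K = mf$K, C = mf$C, E_T = mf$E_T, eta_T = mf$eta_T,
                 seeds = mf$seeds, train_log = mf$train_log,
                 batch_log = NULL),
            class = "teacher_bank")
}
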