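# Desk-scale synthetic benchmark: the full pipeline (teacher bank,
# distilled student and its ablation arms) on the synthetic MI dataset,
# repeated over seeds. This is the package's stand-in for the multi-subject
# study protocol: one seed plays the role of one subject (its own data draw,
# teacher bank and student runs).

#' Run the desk-scale distillation benchmark
#'
#' For each seed: generate a fresh synthetic dataset, train a K-fold teacher
#' bank, then train the requested arms with shared data and bank:
#' `full` (dual-teacher), `A2` (ensemble-only KD), `A3` (fixed learning
#' rate), `ce` (plain cross-entropy, i.e. A1 + A2). Records final test
#' accuracy, the last-`tail_epochs` mean test entropy, the last-`tail_epochs`
#' mean windowed entropy-fluctuation score, and the ensemble teacher's own
#' test accuracy.
#'
#' @param seeds integer vector of benchmark seeds (one "subject" per seed).
#' @param spec a [synth_spec()]; defaults to the desk conditions.
#' @param cfg a [distill_config()]; defaults to [desk_config()]. The per-seed
#'   config/seed and data seed are derived from each element of `seeds`.
#' @param arms subset of `c("full", "A2", "A3", "ce")`.
#' @param tail_epochs number of final epochs over which late-stage entropy
#'   and fluctuation are averaged.
#' @param W fluctuation window.
#' @param backbone backbone name.
#' @return object of class `desk_benchmark`: list with `per_seed` (tidy data
#'   frame: seed, arm, test_acc, tail_entropy, tail_var, ensemble_acc) and
#'   `histories` (nested list of `run_history` objects).
#' @export
run_desk_benchmark <- function(seeds = 1:5, spec = synth_spec(),
                               cfg = desk_config(),
                               arms = c("full", "A2", "A3", "ce"),
                               tail_epochs = 10L, W = 20L,
                               backbone = "tinycnn") {
  arms <- match.arg(arms, c("full", "A2", "A3", "ce"), several.ok = TRUE)
  abl_of <- list(full = "full", A2 = "A2", A3 = "A3", ce = c("A1", "A2"))
  rows <- list(); histories <- list()
  E <- 3L * cfg$N
  tail_idx <- (E - tail_epochs + 1L):E
  for (sd in seeds) {
    spec_i <- spec; spec_i$seed <- derive_seed(sd, "bench-data")
    data <- generate_dataset(spec_i)
    cfg_i <- cfg; cfg_i$seed <- derive_seed(sd, "bench-run")
    need_bank <- any(arms %in% c("full", "A2", "A3"))
    bank <- if (need_bank) {
      train_teacher_bank(data$train, cfg_i, backbone = backbone)
    } else NULL
    ens_acc <- if (need_bank) {
      z <- ensemble_logits(bank, data$test)
      mean(max.col(z, ties.method = "first") == data$test$labels)
    } else NA_real_
    histories[[as.character(sd)]] <- list()
    for (arm in arms) {
      cfg_a <- cfg_i; cfg_a$ablation <- abl_of[[arm]]
      h <- train_student(data$train, data$test,
                         bank = if (arm == "ce") NULL else bank,
                         cfg = cfg_a, backbone = backbone,
                         snapshot_entropy = TRUE)
      hist <- as_entropy_history(h)
      v <- sliding_window_entropy_variance(hist, W)
      rows[[length(rows) + 1]] <- data.frame(
        seed = sd, arm = arm,
        test_acc = h$epochs$test_acc[E],
        tail_entropy = mean(colMeans(hist$H[, tail_idx, drop = FALSE])),
        tail_var = mean(v[tail_idx]),
        ensemble_acc = ens_acc,
        stringsAsFactors = FALSE)
      histories[[as.character(sd)]][[arm]] <- h
    }
  }
  structure(list(per_seed = do.call(rbind, rows), histories = histories,
                 seeds = seeds, cfg = cfg, spec = spec, arms = arms,
                 tail_epochs = tail_epochs, W = W),
            class = "desk_benchmark")
}

#' Aggregate a desk benchmark into headline numbers
#'
#' @param bench a [run_desk_benchmark()] result.
#' @return list of summary quantities: per-arm mean accuracies, the mean
#'   late-stage entropy decrease of the full method vs. the ensemble-only
#'   arm (and the fraction of seeds where it is positive), and the mean
#'   late-stage fluctuation excess of the fixed-lr arm over the cosine arms
#'   (and its seed win fraction).
#' @export
summarize_desk_benchmark <- function(bench) {
  ps <- bench$per_seed
  arm_mean <- function(arm, col) {
    x <- ps[ps$arm == arm, col]
    if (length(x)) mean(x) else NA_real_
  }
  out <- list(
    n_seeds = length(bench$seeds),
    student_accuracy_full = arm_mean("full", "test_acc"),
    student_accuracy_ensemble_only = arm_mean("A2", "test_acc"),
    student_accuracy_fixed_lr = arm_mean("A3", "test_acc"),
    student_accuracy_ce_only = arm_mean("ce", "test_acc"),
    ensemble_teacher_accuracy = mean(ps$ensemble_acc[ps$arm == ps$arm[1]],
                                     na.rm = TRUE)
  )
  if (all(c("full", "A2") %in% bench$arms)) {
    wide_h <- ps[ps$arm == "A2", "tail_entropy"] -
      ps[ps$arm == "full", "tail_entropy"]
    out$entropy_decrease_full_vs_ensemble_only <- mean(wide_h)
    out$entropy_decrease_win_fraction <- mean(wide_h > 0)
  }
  if (all(c("full", "A2", "A3") %in% bench$arms)) {
    cosine <- (ps[ps$arm == "full", "tail_var"] +
                 ps[ps$arm == "A2", "tail_var"]) / 2
    excess <- ps[ps$arm == "A3", "tail_var"] - cosine
    out$variance_increase_fixed_lr_vs_cosine <- mean(excess)
    out$variance_increase_win_fraction <- mean(excess > 0)
  }
  out
}

#' @export
print.desk_benchmark <- function(x, ...) {
  s <- summarize_desk_benchmark(x)
  cat(sprintf("<desk_benchmark> %d seeds, arms: %s\n", s$n_seeds,
              paste(x$arms, collapse = ", ")))
  cat(sprintf("  mean test accuracy: full %.3f | ensemble-only %.3f | fixed-lr %.3f | CE %.3f | teacher %.3f\n",
              s$student_accuracy_full, s$student_accuracy_ensemble_only,
              s$student_accuracy_fixed_lr, s$student_accuracy_ce_only,
              s$ensemble_teacher_accuracy))
  if (!is.null(s$entropy_decrease_full_vs_ensemble_only)) {
    cat(sprintf("  late entropy decrease (full vs ensemble-only): %.4f (wins %d/%d seeds)\n",
                s$entropy_decrease_full_vs_ensemble_only,
                round(s$entropy_decrease_win_fraction * s$n_seeds), s$n_seeds))
  }
  if (!is.null(s$variance_increase_fixed_lr_vs_cosine)) {
    cat(sprintf("  late fluctuation excess (fixed-lr vs cosine): %.5f (wins %d/%d seeds)\n",
                s$variance_increase_fixed_lr_vs_cosine,
                round(s$variance_increase_win_fraction * s$n_seeds), s$n_seeds))
  }
  invisible(x)
}
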