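# Epoch-wise predictive-entropy diagnostics.
#
# Three analyses link training stability to the predictive distribution:
# (1) mean entropy trajectories split by correct vs. misclassified test
# samples; (2) a per-sample sliding-window variance of entropy across epochs
# (window 20, truncated at the start of training), averaged over samples, as
# a fluctuation score; (3) subject-wise Pearson correlations between the
# accuracy gain of the full method over a baseline arm and that arm's
# entropy (or entropy-variance) excess. Variances are population variances
# (divide by the window count, no Bessel correction); entropies are
# temperature-1 student entropies in nats.

#' Assemble an entropy history from a training run
#'
#' @param history a [train_student()] result with snapshots enabled.
#' @return object of class `entropy_history`: matrices `H` (entropies) and
#'   `correct`, both samples x epochs.
#' @export
as_entropy_history <- function(history) {
  if (inherits(history, "entropy_history")) return(history)
  stopifnot(inherits(history, "run_history"))
  if (is.null(history$H)) {
    stop_input("run was trained without entropy snapshots")
  }
  entropy_history(history$H, history$correct)
}

#' Construct an entropy history from matrices
#' @param H samples x epochs matrix of predictive entropies (>= 0).
#' @param correct samples x epochs logical matrix of per-epoch correctness.
#' @return an `entropy_history`.
#' @export
entropy_history <- function(H, correct) {
  if (!identical(dim(H), dim(correct))) {
    stop_input("H and correct must have identical samples x epochs shape")
  }
  if (any(H < -1e-9)) stop_input("entropies must be non-negative")
  structure(list(H = H, correct = correct), class = "entropy_history")
}

#' Mean entropy of correct vs. misclassified samples at one epoch
#'
#' An empty subset yields `NA` (undefined), never 0.
#'
#' @param hist an [entropy_history()].
#' @param e 1-based epoch index.
#' @return list with `H_corr` and `H_err`.
#' @export
entropy_split_means <- function(hist, e) {
  stopifnot(inherits(hist, "entropy_history"))
  if (e < 1 || e > ncol(hist$H)) {
    stop_input("epoch %d outside 1..%d", e, ncol(hist$H))
  }
  ok <- hist$correct[, e]
  list(H_corr = if (any(ok)) mean(hist$H[ok, e]) else NA_real_,
       H_err = if (any(!ok)) mean(hist$H[!ok, e]) else NA_real_)
}

#' Sliding-window entropy-fluctuation score per epoch
#'
#' For each epoch e, the population variance of each sample's entropy over
#' epochs `max(1, e - W + 1) .. e` (early epochs use the truncated window),
#' averaged over samples. A window of size one has variance 0 by convention.
#'
#' @param hist an [entropy_history()].
#' @param W window length in epochs (>= 2); default 20.
#' @return numeric vector with one fluctuation score per epoch.
#' @export
sliding_window_entropy_variance <- function(hist, W = 20L) {
  stopifnot(inherits(hist, "entropy_history"))
  if (W < 2) stop_input("window W must be >= 2")
  E <- ncol(hist$H)
  out <- numeric(E)
  for (e in seq_len(E)) {
    idx <- max(1L, e - W + 1L):e
    Hw <- hist$H[, idx, drop = FALSE]
    m <- rowMeans(Hw)
    v <- rowMeans(Hw * Hw) - m * m   # population variance per sample
    out[e] <- mean(pmax(v, 0))
  }
  out
}

#' Subject summary of one run
#'
#' End-of-training quantities used by the correlation analysis: final test
#' accuracy, mean test entropy at the final epoch, and the windowed entropy
#' fluctuation score at the final epoch.
#'
#' @param history a [train_student()] result with snapshots.
#' @param subject subject identifier.
#' @param method method label (e.g. `"ours"`, `"A2"`, `"A3"`).
#' @param W fluctuation window.
#' @return one-row data frame (subject, method, acc, h_mean, var_mean).
#' @export
subject_summary <- function(history, subject, method, W = 20L) {
  hist <- as_entropy_history(history)
  E <- ncol(hist$H)
  v <- sliding_window_entropy_variance(hist, W)
  data.frame(subject = subject, method = method,
             acc = history$epochs$test_acc[E],
             h_mean = mean(hist$H[, E]),
             var_mean = v[E],
             stringsAsFactors = FALSE)
}

#' Subject-wise delta correlations
#'
#' For each subject s with both the full method (`"ours"`) and a baseline
#' arm b: `dAcc_s = Acc_s^ours - Acc_s^b`, `dH_s = H_s^b - H_s^ours`,
#' `dVar_s = Var_s^b - Var_s^ours`. Returns the Pearson correlations
#' `r(dAcc, dH)` and `r(dAcc, dVar)`; a zero-variance delta vector yields
#' `NA` (undefined).
#'
#' @param summaries data frame of [subject_summary()] rows.
#' @param baseline baseline method label (e.g. `"A2"` or `"A3"`).
#' @return list with `r_entropy`, `r_variance`, `n_subjects` and the per-
#'   subject `deltas` data frame.
#' @export
delta_correlation <- function(summaries, baseline) {
  ours <- summaries[summaries$method == "ours", ]
  base <- summaries[summaries$method == baseline, ]
  common <- intersect(ours$subject, base$subject)
  if (length(common) < 3) {
    stop_input("need >= 3 subjects with both methods, have %d", length(common))
  }
  ours <- ours[match(common, ours$subject), ]
  base <- base[match(common, base$subject), ]
  d <- data.frame(subject = common,
                  d_acc = ours$acc - base$acc,
                  d_h = base$h_mean - ours$h_mean,
                  d_var = base$var_mean - ours$var_mean)
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b, method = "pearson")
  }
  list(r_entropy = safe_cor(d$d_acc, d$d_h),
       r_variance = safe_cor(d$d_acc, d$d_var),
       n_subjects = length(common), deltas = d)
}
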