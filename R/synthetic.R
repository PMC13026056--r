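# Synthetic motor-imagery-like EEG generator.
#
# Real MI decoding operates on few, noisy trials: class-dependent band-limited
# oscillations (mu/beta-band power changes over sensorimotor electrodes)
# buried in broadband noise, with strong single-trial variability. The
# generator emulates that structure: each trial of class c carries a
# Hann-enveloped sinusoid whose frequency is drawn around the class's centre
# frequency (Gaussian per-trial jitter) and whose amplitude fluctuates
# trial-to-trial (lognormal jitter, unit mean power), placed on the class's
# active channels and scaled to a target electrode-level linear SNR (signal
# power per active-channel sample over the unit noise power) before adding
# independent standard Gaussian noise on every channel. By default all
# classes share the same active channels and neighbouring class frequencies
# are 3 Hz apart, so single-trial class evidence is genuinely ambiguous --
# the defaults are calibrated so that a competent convolutional decoder
# lands in the accuracy regime typical of subject-dependent MI benchmarks
# (roughly 0.7-0.85) rather than saturating. The generator deliberately does
# not model volume conduction, 1/f background spectra, artifacts or
# event-related desynchronisation dynamics.

#' Labeled EEG trial dataset
#'
#' @param trials numeric array (n, channels, time).
#' @param labels integer class labels in 1..C.
#' @param fs sampling rate in Hz.
#' @return object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(trials, labels, fs) {
  d <- dim(trials)
  if (length(d) != 3) stop_input("trials must be an (n, channels, time) array")
  if (d[1] != length(labels)) {
    stop_input("number of trials (%d) != number of labels (%d)",
               d[1], length(labels))
  }
  if (any(!is.finite(trials))) stop_input("trials contain non-finite values")
  labels <- as.integer(labels)
  if (any(labels < 1)) stop_input("labels must be positive 1-based integers")
  structure(list(trials = trials, labels = labels, fs = fs,
                 n = d[1], n_channels = d[2], n_samples = d[3],
                 n_classes = max(labels)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d trials, %d ch x %d samples @ %g Hz, %d classes\n",
              x$n, x$n_channels, x$n_samples, x$fs, x$n_classes))
  invisible(x)
}

#' Specification of a synthetic MI-like dataset
#'
#' Defaults are the desk-scale benchmark conditions: 3 classes, 4 channels,
#' 256 samples at 128 Hz, 300 training and 150 test trials at linear SNR 1.
#' Class oscillation frequencies default to an even spread over 8-24 Hz
#' (mu/beta range); each class is active on one channel, cycling through the
#' montage, which makes the classes analytically separable by band power at
#' high SNR.
#'
#' @param C classes; @param n_channels channels; @param n_samples time points.
#' @param fs sampling rate (Hz).
#' @param n_train,n_test trial counts.
#' @param snr electrode-level linear signal-to-noise power ratio (> 0):
#'   expected signal power per active-channel sample divided by the unit
#'   noise power.
#' @param class_freqs length-C vector of distinct centre frequencies (Hz);
#'   default spaces classes 3 Hz apart starting at 10 Hz (mu/beta range).
#' @param active_channels list of length C with the channel indices carrying
#'   each class's oscillation; by default all classes share the first
#'   `min(2, n_channels)` channels, so class identity is carried by spectral
#'   content alone.
#' @param freq_jitter per-trial Gaussian jitter (Hz, sd) of the oscillation
#'   frequency around the class centre; the source of class overlap.
#' @param amp_jitter per-trial lognormal amplitude variability (sigma of the
#'   log-amplitude); scaled to unit mean power so the average SNR is `snr`.
#' @param subject_jitter scale of per-dataset random gain and frequency
#'   perturbation (emulates inter-subject variability; 0 disables).
#' @param seed generator seed.
#' @return object of class `synth_spec`.
#' @export
synth_spec <- function(C = 3L, n_channels = 4L, n_samples = 256L, fs = 128,
                       n_train = 300L, n_test = 150L, snr = 1.0,
                       class_freqs = NULL, active_channels = NULL,
                       freq_jitter = 1.5, amp_jitter = 0.5,
                       subject_jitter = 0, seed = 1L) {
  if (C < 2) stop_input("need C >= 2 classes")
  if (snr <= 0 || !is.finite(snr)) stop_input("snr must be finite and > 0")
  if (n_train < C) stop_input("n_train (%d) must be >= C (%d)", n_train, C)
  if (is.null(class_freqs)) {
    class_freqs <- 10 + 3 * (seq_len(C) - 1)
  }
  if (length(class_freqs) != C || anyDuplicated(class_freqs)) {
    stop_input("class_freqs must be %d distinct frequencies", C)
  }
  if (any(class_freqs >= fs / 2)) {
    stop_input("class_freqs must lie below the Nyquist frequency %g", fs / 2)
  }
  if (is.null(active_channels)) {
    shared <- seq_len(min(2L, n_channels))
    active_channels <- rep(list(shared), C)
  }
  if (length(active_channels) != C ||
      any(vapply(active_channels, length, 1L) == 0)) {
    stop_input("active_channels must be a nonempty channel set per class")
  }
  structure(list(C = as.integer(C), n_channels = as.integer(n_channels),
                 n_samples = as.integer(n_samples), fs = fs,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 snr = snr, class_freqs = class_freqs,
                 active_channels = active_channels,
                 freq_jitter = freq_jitter, amp_jitter = amp_jitter,
                 subject_jitter = subject_jitter, seed = as.integer(seed)),
            class = "synth_spec")
}

.synth_trials <- function(spec, labels, gain, freqs) {
  n <- length(labels)
  trials <- array(stats::rnorm(n * spec$n_channels * spec$n_samples),
                  c(n, spec$n_channels, spec$n_samples))
  signal <- array(0, dim(trials))
  tt <- seq_len(spec$n_samples) - 1
  env <- 0.5 * (1 - cos(2 * pi * tt / (spec$n_samples - 1)))  # Hann envelope
  for (i in seq_len(n)) {
    c <- labels[i]
    phase <- stats::runif(1, 0, 2 * pi)
    f_i <- freqs[c] + spec$freq_jitter * stats::rnorm(1)
    # unit-mean-power lognormal amplitude fluctuation: E[a^2] = 1
    a_i <- exp(spec$amp_jitter * stats::rnorm(1) - spec$amp_jitter^2)
    s <- env * sin(2 * pi * f_i * tt / spec$fs + phase)
    act <- spec$active_channels[[c]]
    S <- matrix(0, spec$n_channels, spec$n_samples)
    S[act, ] <- rep(s, each = length(act))
    p0 <- sum(S^2) / (length(act) * spec$n_samples)
    signal[i, , ] <- S * a_i * sqrt(gain * spec$snr / p0)
  }
  list(trials = trials + signal, signal = signal, noise = trials)
}

#' Generate a synthetic train/test dataset pair
#'
#' Each trial of class c is an amplitude-modulated (Hann-enveloped) sinusoid
#' near `class_freqs[c]` (per-trial frequency and amplitude jitter, random
#' phase) on `active_channels[[c]]`, scaled so that the expected signal
#' power per active-channel sample divided by the unit noise power equals
#' `snr`, plus independent standard Gaussian noise on every channel. Labels
#' are balanced to within one trial per class in each split;
#' train and test are disjoint by construction and the whole draw is
#' deterministic given `spec$seed`.
#'
#' @param spec a [synth_spec()].
#' @param return_components also return the noise-free signal and the noise
#'   arrays (used by SNR diagnostics).
#' @return list with `train` and `test` ([labeled_dataset()]s), the `spec`,
#'   and optionally `components`.
#' @export
generate_dataset <- function(spec, return_components = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(derive_seed(spec$seed, "synth"))
  gain <- 1; freqs <- spec$class_freqs
  if (spec$subject_jitter > 0) {
    gain <- max(0.1, 1 + spec$subject_jitter * stats::rnorm(1))
    freqs <- freqs * (1 + spec$subject_jitter * 0.1 * stats::rnorm(spec$C))
  }
  lab_tr <- sample(rep_len(seq_len(spec$C), spec$n_train))
  lab_te <- sample(rep_len(seq_len(spec$C), spec$n_test))
  tr <- .synth_trials(spec, lab_tr, gain, freqs)
  te <- .synth_trials(spec, lab_te, gain, freqs)
  out <- list(train = labeled_dataset(tr$trials, lab_tr, spec$fs),
              test = labeled_dataset(te$trials, lab_te, spec$fs),
              spec = spec)
  if (return_components) {
    out$components <- list(train_signal = tr$signal, train_noise = tr$noise)
  }
  out
}

#' Random logit fixtures for loss unit tests
#'
#' Reproducible (teacher logits, student logits, label) triples spanning
#' confident, near-uniform and adversarial (teacher and student disagreeing)
#' regimes, plus deterministic special cases: the all-zeros logit vector, an
#' identical teacher/student pair (KD loss must be exactly 0) and an exact
#' two-way argmax tie.
#'
#' @param C number of classes (>= 2).
#' @param n number of random fixtures (the special cases are appended).
#' @param seed RNG seed.
#' @return list of lists with fields `teacher`, `student`, `y`, `regime`.
#' @export
generate_logit_fixtures <- function(C, n = 30, seed = 1L) {
  if (C < 2) stop_input("need C >= 2 classes")
  set.seed(derive_seed(seed, "fixtures", C))
  out <- list()
  regimes <- rep_len(c("confident", "uniformish", "adversarial"), n)
  for (i in seq_len(n)) {
    y <- sample.int(C, 1)
    reg <- regimes[i]
    if (reg == "confident") {
      z_t <- stats::rnorm(C, 0, 0.3); z_t[y] <- z_t[y] + 6
      z_s <- stats::rnorm(C, 0, 0.3); z_s[y] <- z_s[y] + 5
    } else if (reg == "uniformish") {
      z_t <- stats::rnorm(C, 0, 0.1)
      z_s <- stats::rnorm(C, 0, 0.1)
    } else {
      other <- if (C == 2) 3 - y else sample(setdiff(seq_len(C), y), 1)
      z_t <- stats::rnorm(C, 0, 0.3); z_t[y] <- z_t[y] + 4
      z_s <- stats::rnorm(C, 0, 0.3); z_s[other] <- z_s[other] + 4
    }
    out[[length(out) + 1]] <- list(teacher = z_t, student = z_s, y = y,
                                   regime = reg)
  }
  out[[length(out) + 1]] <- list(teacher = numeric(C), student = numeric(C),
                                 y = 1L, regime = "zeros")
  z <- stats::rnorm(C)
  out[[length(out) + 1]] <- list(teacher = z, student = z, y = 1L,
                                 regime = "identical")
  z_tie <- numeric(C); z_tie[1:2] <- 3
  out[[length(out) + 1]] <- list(teacher = z_tie, student = z_tie, y = 2L,
                                 regime = "tie")
  out
}
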