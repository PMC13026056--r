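# Adapter for the public BCI Competition IV-2a/2b trial layout.
#
# The public per-subject recordings are continuous multi-channel signals with
# cue-onset event markers, organised as one file pair per session. This
# adapter consumes a plain-text export of that layout (one signal TSV with a
# channel-name header, samples x channels, plus one events TSV with 0-based
# `cue_sample` and `label` columns per session) and applies the evaluation
# protocol: trials are cropped to [cue - 0.5 s, cue + 4 s) -- at the native
# 250 Hz that is samples [cue - 125, cue + 1000), T = 1125 -- with no other
# preprocessing; all channels present are passed through. For dataset 2a the
# first (training) session forms the train split and the second the test
# split; for 2b sessions 1-3 are train and 4-5 are test. Obtaining the files
# is the user's responsibility (a one-off conversion of the public .mat
# mirror); nothing in the package or tests requires them.

.bnci_session_file <- function(dir, subject, session, what) {
  file.path(dir, sprintf("%s_session%d_%s.tsv", subject, session, what))
}

#' Write one session in the plain-text BNCI-style layout
#'
#' Companion to [load_bnci_trials()], used for conversion and for round-trip
#' testing.
#'
#' @param dir target directory.
#' @param subject subject id (e.g. `"A01"`).
#' @param session 1-based session number.
#' @param signal samples x channels numeric matrix (column names = channels).
#' @param events data frame with 0-based `cue_sample` and integer `label`.
#' @export
write_bnci_session <- function(dir, subject, session, signal, events) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(signal, .bnci_session_file(dir, subject, session, "signal"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(events, .bnci_session_file(dir, subject, session, "events"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Load BNCI-layout trials for one subject and split
#'
#' @param path directory holding the per-session TSV pairs.
#' @param subject subject id matching the file names.
#' @param split `"train"` or `"test"`.
#' @param dataset `"2a"` (session 1 train / session 2 test) or `"2b"`
#'   (sessions 1-3 train / 4-5 test).
#' @param fs sampling rate in Hz (250 for the original recordings). The
#'   crop covers `round(0.5 * fs)` pre-cue and `round(4 * fs)` post-cue
#'   samples (1125 in total at 250 Hz).
#' @return a [labeled_dataset()] of cropped trials.
#' @export
load_bnci_trials <- function(path, subject, split = c("train", "test"),
                             dataset = c("2a", "2b"), fs = 250) {
  split <- match.arg(split)
  dataset <- match.arg(dataset)
  if (!dir.exists(path)) stop_input("BNCI directory not found: %s", path)
  sessions <- if (dataset == "2a") {
    if (split == "train") 1L else 2L
  } else {
    if (split == "train") 1:3 else 4:5
  }
  pre <- round(0.5 * fs)
  post <- round(4 * fs)
  len <- pre + post
  trial_list <- list(); labels <- integer(0)
  for (se in sessions) {
    sf <- .bnci_session_file(path, subject, se, "signal")
    ef <- .bnci_session_file(path, subject, se, "events")
    if (!file.exists(sf) || !file.exists(ef)) {
      stop_input("missing BNCI session files for subject '%s' session %d under %s",
                 subject, se, path)
    }
    sig <- as.matrix(utils::read.table(sf, header = TRUE, sep = "\t"))
    ev <- utils::read.table(ef, header = TRUE, sep = "\t")
    if (!all(c("cue_sample", "label") %in% names(ev))) {
      stop_input("malformed events file %s: need cue_sample and label columns", ef)
    }
    for (i in seq_len(nrow(ev))) {
      cue <- ev$cue_sample[i]  # 0-based sample index of the cue onset
      i0 <- cue - pre          # 0-based, inclusive; half-open [i0, i0 + len)
      if (i0 < 0 || i0 + len > nrow(sig)) {
        stop_input("trial %d of %s session %d out of recording bounds", i, subject, se)
      }
      trial_list[[length(trial_list) + 1]] <-
        t(sig[(i0 + 1):(i0 + len), , drop = FALSE])  # channels x time
      labels <- c(labels, as.integer(ev$label[i]))
    }
  }
  if (length(trial_list) == 0) {
    stop_input("no trials found for subject '%s' split '%s'", subject, split)
  }
  nch <- nrow(trial_list[[1]])
  trials <- array(NA_real_, c(length(trial_list), nch, len))
  for (i in seq_along(trial_list)) trials[i, , ] <- trial_list[[i]]
  labeled_dataset(trials, labels, fs)
}
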