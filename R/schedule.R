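# Two-stage cosine-annealed learning-rate schedule with a single warm
# restart. Phase I covers epochs 1..N (stage length N); Phase II covers
# epochs N+1..3N (stage length 2N), restarting at eta_max. The schedule is
# epoch-granular: one learning rate per epoch, set before the batch loop.

#' Cosine-annealed learning rate within one stage
#'
#' `eta(t) = eta_min + (eta_max - eta_min) * (1 + cos(pi t / Ts)) / 2`,
#' monotone non-increasing on `t` in `[0, Ts]`.
#'
#' @param t local step within the stage (0-based, epochs).
#' @param Ts stage length in epochs.
#' @param eta_max,eta_min learning-rate bounds, `eta_min <= eta_max`.
#' @return learning rate.
#' @export
cosine_lr <- function(t, Ts, eta_max, eta_min) {
  if (Ts < 1) stop_input("Ts must be a positive stage length")
  if (eta_min > eta_max) stop_input("eta_min must not exceed eta_max")
  if (t < 0 || t > Ts) stop_input("t = %g outside [0, Ts = %g]", t, Ts)
  eta_min + 0.5 * (eta_max - eta_min) * (1 + cos(pi * t / Ts))
}

#' Map a 1-based epoch to its stage, local step and learning rate
#'
#' Epochs `e <= N` belong to Phase I with `t = e - 1`, `Ts = N`; epochs
#' `e > N` belong to Phase II with `t = e - 1 - N`, `Ts = 2N`. The learning
#' rate therefore restarts to `eta_max` exactly at `e = N + 1`, the epoch at
#' which the EMA teacher is also initialised.
#'
#' @param e 1-based epoch in `[1, 3N]`.
#' @param N Phase-I length in epochs (total run = 3N epochs).
#' @param eta_max,eta_min learning-rate bounds.
#' @return list with `phase` (`"I"`/`"II"`), `t`, `Ts`, `eta`.
#' @export
stage_of_epoch <- function(e, N, eta_max = 1e-3, eta_min = 1e-5) {
  if (N < 1) stop_input("N must be >= 1")
  if (e < 1 || e > 3 * N || e != round(e)) {
    stop_input("epoch e = %g outside [1, 3N = %d]", e, 3 * N)
  }
  if (e <= N) {
    t <- e - 1; Ts <- N; phase <- "I"
  } else {
    t <- e - 1 - N; Ts <- 2 * N; phase <- "II"
  }
  list(phase = phase, t = t, Ts = Ts,
       eta = cosine_lr(t, Ts, eta_max, eta_min))
}
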