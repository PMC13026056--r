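# Exponential-moving-average (EMA) teacher: a shadow copy of the student's
# parameters updated after every optimiser step as
#   theta_ema <- alpha * theta_ema + (1 - alpha) * theta,
# i.e. a first-order low-pass filter on the optimisation trajectory. The EMA
# teacher is initialised from the student at the first Phase-II epoch
# (e = N + 1) and serves temporally smoothed logits as distillation targets.
# Since the backbones carry no dropout or normalisation statistics, the
# student parameter list is the complete state theta and the EMA forward is
# automatically in inference mode (deterministic).

#' Initialise the EMA teacher from the student
#'
#' Takes a value copy (not an alias) of the current student parameters;
#' immediately after initialisation the EMA teacher's logits equal the
#' student's on any input.
#'
#' @param student_params nested parameter list of the student.
#' @param arch the student's architecture (`$arch` of a backbone).
#' @param epoch 1-based epoch at which activation happens (N + 1).
#' @param prev existing EMA state, if any; initialising twice is an error.
#' @return object of class `ema_state`.
#' @export
ema_init <- function(student_params, arch, epoch = 1L, prev = NULL) {
  if (!is.null(prev) && isTRUE(prev$active)) {
    stop_input("EMA teacher already initialised (at epoch %d)",
               prev$activation_epoch)
  }
  structure(list(params = param_map(identity, student_params),
                 arch = arch, active = TRUE,
                 activation_epoch = as.integer(epoch),
                 n_updates = 0L),
            class = "ema_state")
}

#' One EMA update
#'
#' Elementwise `theta_ema' = alpha * theta_ema + (1 - alpha) * theta`,
#' applied once per batch after the student optimiser step.
#'
#' @param state an active [ema_init()] state.
#' @param student_params current student parameters (shapes must match).
#' @param alpha smoothing coefficient in `[0, 1)`; `alpha = 0` copies the
#'   student, values near 1 freeze the teacher.
#' @return updated `ema_state`.
#' @export
ema_update <- function(state, student_params, alpha) {
  if (!inherits(state, "ema_state") || !isTRUE(state$active)) {
    stop_input("ema_update called on an inactive EMA state")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop_input("alpha must lie in [0, 1)")
  }
  if (!param_shapes_match(state$params, student_params)) {
    stop_input("student parameter shapes do not match the EMA state")
  }
  state$params <- param_map2(function(e, s) alpha * e + (1 - alpha) * s,
                             state$params, student_params)
  state$n_updates <- state$n_updates + 1L
  state
}

#' Logits of the EMA teacher
#'
#' Pure inference forward under the EMA parameters; never touches student
#' parameters or optimiser state.
#'
#' @param state an active `ema_state`.
#' @param x array (channels, time, batch) or a single (channels, time) trial.
#' @return batch x classes logit matrix.
#' @export
ema_forward <- function(state, x) {
  if (!inherits(state, "ema_state") || !isTRUE(state$active)) {
    stop_input("ema_forward called on an inactive EMA state")
  }
  backbone_forward(state$arch, state$params, x)$logits
}

#' @export
print.ema_state <- function(x, ...) {
  cat(sprintf("<ema_state> active, initialised at epoch %d, %d updates\n",
              x$activation_epoch, x$n_updates))
  invisible(x)
}
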