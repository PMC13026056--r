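# Scalar loss and gating mathematics of the dual-teacher objective.
#
# Conventions, fixed package-wide:
#   * natural logarithm everywhere (cross-entropy, KL, entropy); the entropy
#     normalisation H / log C is base-independent, and natural log is the KL
#     convention,
#   * a numerical floor eps = 1e-12 inside every log so that 0 * log 0 = 0
#     holds and no NaN can arise, without altering values at double precision,
#   * teacher distributions and the gate are constants with respect to
#     gradients: only the student logits carry gradient.

.LOG_EPS <- 1e-12

.check_prob <- function(p, name = "p") {
  if (!is.numeric(p) || length(p) < 2) {
    stop_input("%s must be a numeric probability vector of length >= 2", name)
  }
  if (any(!is.finite(p)) || any(p < -1e-9)) {
    stop_input("%s has negative or non-finite entries", name)
  }
  if (abs(sum(p) - 1) > 1e-6) {
    stop_input("%s does not sum to 1 (sum = %.8f)", name, sum(p))
  }
  invisible(TRUE)
}

#' Temperature-scaled softmax
#'
#' `softmax(z / tau)`. Shift-invariant in `z` (a constant added to every
#' logit leaves the output unchanged) and numerically stabilised by
#' max-subtraction.
#'
#' @param z numeric logit vector (length C >= 2, finite).
#' @param tau temperature, > 0. `tau = 1` gives the ordinary softmax.
#' @return probability vector of length C.
#' @examples
#' temp_softmax(c(2, 0, -2), tau = 4)
#' @export
temp_softmax <- function(z, tau = 1) {
  if (!is.numeric(tau) || length(tau) != 1 || !is.finite(tau) || tau <= 0) {
    stop_input("tau must be a positive finite scalar")
  }
  if (!is.numeric(z) || length(z) < 2) {
    stop_input("z must be a numeric logit vector of length >= 2")
  }
  if (any(!is.finite(z))) stop_input("z has non-finite entries")
  s <- z / tau
  s <- s - max(s)
  e <- exp(s)
  e / sum(e)
}

# row-wise softened softmax for a batch logit matrix (n x C)
.softmax_rows <- function(Z, tau = 1) {
  S <- Z / tau
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

#' Supervised cross-entropy loss
#'
#' `-log p_S[y]` with `p_S = softmax(z_s)` (temperature 1).
#'
#' @param z_s student logit vector.
#' @param y 1-based class index.
#' @return non-negative scalar.
#' @export
cross_entropy <- function(z_s, y) {
  C <- length(z_s)
  if (!is.numeric(y) || length(y) != 1 || y != round(y) || y < 1 || y > C) {
    stop_input("y must be a class index in 1..%d", C)
  }
  p <- temp_softmax(z_s, 1)
  -log(max(p[y], .LOG_EPS))
}

#' Temperature-scaled KL distillation loss
#'
#' `tau^2 * KL(q_teacher || softmax(z_s / tau))` with
#' `KL(a || b) = sum_c a_c log(a_c / b_c)`; zero-probability teacher entries
#' contribute 0. The teacher distribution is a constant: gradients flow only
#' through `z_s` (see [total_loss_grad()]).
#'
#' @param q_teacher teacher probability vector.
#' @param z_s student logit vector of the same length.
#' @param tau temperature, > 0.
#' @return non-negative scalar, 0 iff the softened student equals the teacher.
#' @export
kd_loss <- function(q_teacher, z_s, tau) {
  .check_prob(q_teacher, "q_teacher")
  if (length(z_s) != length(q_teacher)) {
    stop_input("q_teacher and z_s differ in length (%d vs %d)",
               length(q_teacher), length(z_s))
  }
  s <- temp_softmax(z_s, tau)
  terms <- q_teacher * (log(pmax(q_teacher, .LOG_EPS)) - log(pmax(s, .LOG_EPS)))
  terms[q_teacher == 0] <- 0
  tau^2 * sum(terms)
}

#' Predictive (Shannon) entropy of a probability vector
#'
#' `-sum p_c log p_c` in nats, with `0 log 0 = 0`; lies in `[0, log C]`.
#'
#' @param p probability vector.
#' @return non-negative scalar.
#' @export
predictive_entropy <- function(p) {
  .check_prob(p)
  terms <- p * log(pmax(p, .LOG_EPS))
  terms[p == 0] <- 0
  max(-sum(terms), 0)
}

# row-wise entropies of a probability matrix (n x C)
.entropy_rows <- function(P) {
  Tm <- P * log(pmax(P, .LOG_EPS))
  Tm[P == 0] <- 0
  pmax(-rowSums(Tm), 0)
}

#' Normalised predictive entropy
#'
#' `predictive_entropy(p) / log(C)`, mapping entropy to `[0, 1]` regardless
#' of the class count (base-independent).
#'
#' @param p probability vector over C >= 2 classes.
#' @return scalar in `[0, 1]`.
#' @export
normalized_entropy <- function(p) {
  if (length(p) < 2) stop_input("normalized entropy needs C >= 2 classes")
  predictive_entropy(p) / log(length(p))
}

#' Per-sample entropy gate
#'
#' Linear, clipped mapping `clip((h - h_low) / (h_high - h_low), 0, 1)`:
#' exactly 0 for `h <= h_low`, exactly 1 for `h >= h_high`, linear between.
#' The gate modulates the EMA distillation term, concentrating the smoothing
#' effect on uncertain (high-entropy) samples; it is treated as a constant
#' with respect to gradients.
#'
#' @param h normalised entropy in `[0, 1]` (vectorised).
#' @param gate list with `h_low` and `h_high`, `0 <= h_low < h_high <= 1`.
#' @return gate weight(s) in `[0, 1]`.
#' @examples
#' entropy_gate(c(0.6, 0.75, 0.9), list(h_low = 0.6, h_high = 0.9))
#' @export
entropy_gate <- function(h, gate) {
  .check_gate(gate)
  if (any(h < -1e-9 | h > 1 + 1e-9)) {
    stop_input("h must lie in [0, 1]")
  }
  pmin(pmax((h - gate$h_low) / (gate$h_high - gate$h_low), 0), 1)
}

.check_gate <- function(gate) {
  if (is.null(gate$h_low) || is.null(gate$h_high)) {
    stop_input("gate must have fields h_low and h_high")
  }
  if (!(gate$h_low >= 0 && gate$h_low < gate$h_high && gate$h_high <= 1)) {
    stop_input("gate invariant violated: need 0 <= h_low < h_high <= 1 (h_low = %g, h_high = %g)",
               gate$h_low, gate$h_high)
  }
  invisible(TRUE)
}

#' Total dual-teacher training objective for one sample
#'
#' `L = L_ce + lambda_ens * L_kd_ens + lambda_ema(e) * w(x) * L_kd_ema`,
#' where `lambda_ema(e)` is 0 in Phase I and `cfg$lambda_ema` in Phase II,
#' and `w(x)` is the entropy gate evaluated on the normalised entropy of the
#' EMA teacher's temperature-softened distribution `q_ema` (identically 1
#' under the `A4` ablation, which removes the gate).
#'
#' @param z_s student logit vector.
#' @param y 1-based true class index.
#' @param q_ens ensemble soft target (temperature-softened); may be `NULL`
#'   when `cfg$lambda_ens == 0` or under the `A1` ablation.
#' @param q_ema EMA soft target; required iff `phase2_active`.
#' @param cfg a [distill_config()].
#' @param phase2_active logical: is the EMA teacher active (epoch > N)?
#' @return list of class `loss_breakdown` with fields `l_ce`, `l_kd_ens`,
#'   `l_kd_ema`, `gate_w`, `total`.
#' @export
total_loss <- function(z_s, y, q_ens, q_ema = NULL, cfg, phase2_active = FALSE) {
  abl <- cfg$ablation
  use_ens <- !("A1" %in% abl) && cfg$lambda_ens > 0
  use_ema <- !("A2" %in% abl)
  use_gate <- !("A4" %in% abl)
  if (phase2_active && use_ema && is.null(q_ema)) {
    stop_input("q_ema is required when phase 2 is active")
  }
  l_ce <- cross_entropy(z_s, y)
  l_kd_ens <- 0
  if (use_ens) {
    if (is.null(q_ens)) stop_input("q_ens is required when lambda_ens > 0")
    l_kd_ens <- kd_loss(q_ens, z_s, cfg$tau)
  }
  l_kd_ema <- 0; gate_w <- 0; lambda_ema_e <- 0
  if (phase2_active && use_ema) {
    lambda_ema_e <- cfg$lambda_ema
    l_kd_ema <- kd_loss(q_ema, z_s, cfg$tau)
    gate_w <- if (use_gate) {
      entropy_gate(normalized_entropy(q_ema),
                   list(h_low = cfg$h_low, h_high = cfg$h_high))
    } else 1
  }
  total <- l_ce + cfg$lambda_ens * (if (use_ens) l_kd_ens else 0) +
    lambda_ema_e * gate_w * l_kd_ema
  structure(list(l_ce = l_ce, l_kd_ens = l_kd_ens, l_kd_ema = l_kd_ema,
                 gate_w = gate_w, lambda_ema_e = lambda_ema_e, total = total),
            class = "loss_breakdown")
}

#' Gradient of the total objective with respect to the student logits
#'
#' Analytic gradient of [total_loss()]. Both teacher distributions and the
#' gate weight are held constant: the only gradient path is through `z_s`
#' (cross-entropy term `p_s - onehot(y)`, each KD term
#' `tau * (softmax(z_s / tau) - q_teacher)`).
#'
#' @inheritParams total_loss
#' @return numeric gradient vector, same length as `z_s`.
#' @export
total_loss_grad <- function(z_s, y, q_ens, q_ema = NULL, cfg,
                            phase2_active = FALSE) {
  abl <- cfg$ablation
  use_ens <- !("A1" %in% abl) && cfg$lambda_ens > 0
  use_ema <- !("A2" %in% abl)
  use_gate <- !("A4" %in% abl)
  p1 <- temp_softmax(z_s, 1)
  g <- p1
  g[y] <- g[y] - 1
  if (use_ens) {
    if (is.null(q_ens)) stop_input("q_ens is required when lambda_ens > 0")
    ptau <- temp_softmax(z_s, cfg$tau)
    g <- g + cfg$lambda_ens * cfg$tau * (ptau - q_ens)
  }
  if (phase2_active && use_ema) {
    if (is.null(q_ema)) stop_input("q_ema is required when phase 2 is active")
    ptau <- temp_softmax(z_s, cfg$tau)
    w <- if (use_gate) {
      entropy_gate(normalized_entropy(q_ema),
                   list(h_low = cfg$h_low, h_high = cfg$h_high))
    } else 1
    g <- g + cfg$lambda_ema * w * cfg$tau * (ptau - q_ema)
  }
  g
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss: total = %.6f (ce = %.6f, kd_ens = %.6f, kd_ema = %.6f, gate = %.3f)\n",
    x$total, x$l_ce, x$l_kd_ens, x$l_kd_ema, x$gate_w))
  invisible(x)
}
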