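# Distillation configuration: every hyperparameter of the training pipeline
# in one validated object, YAML round-trippable. Defaults are the full-scale
# settings (temperature 4, lambda_ens 0.5, lambda_ema 0.4, gate knots
# 0.6/0.9, EMA alpha 0.995, K = 5 teachers for 750 epochs at lr 1e-3,
# AdamW weight decay 0.009, batch 64, Phase-I length N = 500 so 1500 student
# epochs in total). desk_config() scales the run down for laptop-scale
# synthetic benchmarks without touching any loss constant.

.CONFIG_DEFAULTS <- list(
  C = 4L,             # class count
  K = 5L,             # ensemble members / folds
  N = 500L,           # Phase-I length; total student epochs = 3N
  tau = 4,            # distillation temperature
  lambda_ens = 0.5,   # ensemble KD weight
  lambda_ema = 0.4,   # EMA KD weight (Phase II only)
  h_low = 0.6,        # gate lower knot (normalised entropy)
  h_high = 0.9,       # gate upper knot
  alpha = 0.995,      # EMA smoothing coefficient
  eta_max = 1e-3,     # student lr upper bound
  eta_min = 1e-5,     # student lr lower bound
  eta_T = 1e-3,       # teacher lr (fixed, no annealing)
  E_T = 750L,         # teacher epochs
  batch_size = 64L,
  weight_decay = 0.009,
  seed = 1L,
  ablation = "full"   # "full" or subset of c("A1","A2","A3","A4")
)

#' Create a validated distillation configuration
#'
#' Any unset field takes the full-scale default. Ablation flags: `A1` removes
#' the ensemble KD term, `A2` removes the EMA KD branch entirely, `A3`
#' replaces the cosine schedule by a fixed learning rate of 0.001 (phase
#' bookkeeping, including EMA activation at epoch N + 1, is unchanged), `A4`
#' removes the entropy gate (EMA KD weight identically 1 in Phase II).
#'
#' @param ... named fields overriding the defaults (see
#'   [`.CONFIG_DEFAULTS`][distill_config] source for the full list).
#' @return object of class `distill_config`.
#' @examples
#' cfg <- distill_config(C = 3, K = 3, N = 20, E_T = 40)
#' @export
distill_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    stop_input("unknown config field(s): %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  cfg <- validate_config(cfg)
  structure(cfg, class = "distill_config")
}

#' Validate a configuration, naming the offending field
#' @param cfg list of config fields.
#' @return the validated config (with integer fields coerced).
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop_input("invalid config field '%s': %s", field, msg)
  }
  for (f in c("C", "K", "N", "E_T", "batch_size", "seed")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
          cfg[[f]] == round(cfg[[f]]), f, "must be a single integer")
    cfg[[f]] <- as.integer(cfg[[f]])
  }
  chk(cfg$C >= 2, "C", "need at least 2 classes")
  chk(cfg$K >= 2, "K", "need at least 2 ensemble folds")
  chk(cfg$N >= 1, "N", "phase length must be >= 1")
  chk(cfg$E_T >= 1, "E_T", "teacher epochs must be >= 1")
  chk(cfg$batch_size >= 1, "batch_size", "must be >= 1")
  chk(cfg$tau > 0, "tau", "temperature must be > 0")
  chk(cfg$lambda_ens >= 0, "lambda_ens", "must be >= 0")
  chk(cfg$lambda_ema >= 0, "lambda_ema", "must be >= 0")
  chk(cfg$h_low >= 0 && cfg$h_low < 1, "h_low", "must lie in [0, 1)")
  chk(cfg$h_high > 0 && cfg$h_high <= 1, "h_high", "must lie in (0, 1]")
  chk(cfg$h_low < cfg$h_high, "h_low",
      sprintf("h_low (%g) must be < h_high (%g)", cfg$h_low, cfg$h_high))
  chk(cfg$alpha >= 0 && cfg$alpha < 1, "alpha", "must lie in [0, 1)")
  chk(cfg$eta_max > 0, "eta_max", "must be > 0")
  chk(cfg$eta_min >= 0 && cfg$eta_min <= cfg$eta_max, "eta_min",
      "must lie in [0, eta_max]")
  chk(cfg$eta_T > 0, "eta_T", "must be > 0")
  chk(cfg$weight_decay >= 0, "weight_decay", "must be >= 0")
  abl <- cfg$ablation
  ok_abl <- identical(abl, "full") ||
    (length(abl) >= 1 && all(abl %in% c("A1", "A2", "A3", "A4")))
  chk(ok_abl, "ablation", "must be 'full' or a subset of A1..A4")
  cfg
}

#' Load a configuration from YAML
#'
#' Unset fields take the full-scale defaults; all invariants are validated
#' on load with errors naming the offending field.
#'
#' @param path YAML file path.
#' @return a `distill_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(distill_config, vals)
}

#' Save a configuration to YAML
#' @param cfg a `distill_config`.
#' @param path output YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Desk-scale benchmark configuration
#'
#' The scaled-down study conditions used by the synthetic benchmark and the
#' test suite: 3 classes, K = 3 teachers trained 40 epochs, Phase-I length
#' N = 20 (60 student epochs). All loss constants (tau, lambdas, gate knots,
#' alpha, weight decay) keep their full-scale values.
#'
#' @param ... overrides passed on to [distill_config()].
#' @return a `distill_config`.
#' @export
desk_config <- function(...) {
  base <- list(C = 3L, K = 3L, N = 20L, E_T = 40L)
  over <- list(...)
  do.call(distill_config, utils::modifyList(base, over))
}

#' @export
print.distill_config <- function(x, ...) {
  cat(sprintf(
    paste0("<distill_config> C=%d K=%d N=%d (3N=%d epochs) tau=%g ",
           "lambda_ens=%g lambda_ema=%g gate=[%g,%g] alpha=%g\n",
           "  eta=[%g,%g] eta_T=%g E_T=%d batch=%d wd=%g seed=%d ablation=%s\n"),
    x$C, x$K, x$N, 3L * x$N, x$tau, x$lambda_ens, x$lambda_ema,
    x$h_low, x$h_high, x$alpha, x$eta_min, x$eta_max, x$eta_T, x$E_T,
    x$batch_size, x$weight_decay, x$seed, paste(x$ablation, collapse = "+")))
  invisible(x)
}
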