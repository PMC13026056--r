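# Reference backbones mapping (channels x time) EEG trials to class logits.
#
# Three compact, norm-free convolutional decoders are registered:
#   tinycnn              - two conv blocks + global pooling; default for tests
#   eegnet_like          - shared temporal filters, 1x1 spatial mixing, two
#                          pooled stages (in the spirit of EEGNet)
#   shallowconvnet_like  - temporal + spatial filtering, square / log band
#                          power features (in the spirit of ShallowConvNet)
# All are dropout- and normalisation-free so that training-mode and
# inference-mode forwards coincide and every forward is deterministic; the
# only stochastic element of a fit is parameter initialisation and batch
# order. Regularisation comes from AdamW weight decay.

.backbone_registry <- new.env(parent = emptyenv())

#' Register a backbone constructor
#'
#' The registry makes the trainer architecture-agnostic: any constructor
#' taking `(n_channels, n_samples, n_classes, width)` and returning a layer
#' list can be plugged in (e.g. an externally implemented attention-TCN).
#'
#' @param name backbone name used in configs.
#' @param constructor function(n_channels, n_samples, n_classes, width)
#'   returning a list of layers.
#' @export
register_backbone <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  assign(name, constructor, envir = .backbone_registry)
  invisible(name)
}

#' List registered backbone names
#' @return character vector.
#' @export
list_backbones <- function() sort(ls(.backbone_registry))

.tinycnn_layers <- function(n_channels, n_samples, n_classes, width = 1) {
  f1 <- 8 * width; f2 <- 16 * width
  t1 <- n_samples - 8           # conv k=9
  t2 <- t1 %/% 4                # pool 4
  if (n_samples < 9 || t2 < 5) {
    stop_input("tinycnn needs n_samples >= 28, got %d", n_samples)
  }
  list(
    nn_conv(n_channels, f1, 9), nn_act("relu"), nn_pool(4),
    nn_conv(f1, f2, 5), nn_act("relu"), nn_gpool(),
    nn_dense(f2, n_classes)
  )
}

.eegnet_like_layers <- function(n_channels, n_samples, n_classes, width = 1) {
  f1 <- 8 * width; f2 <- 16 * width
  kt <- 33
  t1 <- n_samples - kt + 1
  t2 <- t1 %/% 8
  if (n_samples < kt || t2 < 20) {  # conv k=17 then pool 4 need >= 20
    stop_input("eegnet_like needs n_samples >= %d, got %d",
               kt - 1 + 8 * 20, n_samples)
  }
  list(
    nn_tconv(n_channels, f1, kt),        # shared temporal filters
    nn_conv(f1 * n_channels, f2, 1),     # spatial (across-channel) mixing
    nn_act("elu"), nn_pool(8),
    nn_conv(f2, f2, 17), nn_act("elu"), nn_pool(4),
    nn_gpool(),
    nn_dense(f2, n_classes)
  )
}

.shallowconvnet_like_layers <- function(n_channels, n_samples, n_classes,
                                        width = 1) {
  f1 <- 12 * width; f2 <- 24 * width
  kt <- 13; p <- 14
  t1 <- n_samples - kt + 1
  t2 <- t1 %/% p
  if (n_samples < kt || t2 < 1) {
    stop_input("shallowconvnet_like needs n_samples >= %d, got %d",
               kt - 1 + p, n_samples)
  }
  list(
    nn_tconv(n_channels, f1, kt),
    nn_conv(f1 * n_channels, f2, 1),
    nn_act("square"), nn_pool(p), nn_act("safelog"),
    nn_flatten(),
    nn_dense(f2 * t2, n_classes)
  )
}

register_backbone("tinycnn", .tinycnn_layers)
register_backbone("eegnet_like", .eegnet_like_layers)
register_backbone("shallowconvnet_like", .shallowconvnet_like_layers)

#' Build a backbone network
#'
#' Constructs the architecture and deterministically initialises its
#' parameters from `seed`.
#'
#' @param name registered backbone name; see [list_backbones()].
#' @param n_channels,n_samples input trial geometry (channels x time points).
#' @param n_classes number of output logits.
#' @param seed initialisation seed.
#' @param width integer width multiplier for the filter counts.
#' @return object of class `backbone`: list with `arch` (layer list plus
#'   geometry) and `params` (nested numeric list).
#' @examples
#' net <- build_backbone("tinycnn", 4, 256, 3, seed = 1)
#' x <- array(rnorm(4 * 256 * 2), c(4, 256, 2))
#' dim(backbone_forward(net$arch, net$params, x)$logits)  # 2 x 3
#' @export
build_backbone <- function(name, n_channels, n_samples, n_classes,
                           seed = 1L, width = 1L) {
  if (!exists(name, envir = .backbone_registry)) {
    stop_input("unknown backbone '%s'; registered: %s", name,
               paste(list_backbones(), collapse = ", "))
  }
  if (n_classes < 2) stop_input("n_classes must be >= 2, got %d", n_classes)
  ctor <- get(name, envir = .backbone_registry)
  layers <- ctor(n_channels, n_samples, n_classes, width)
  arch <- list(name = name, n_channels = n_channels, n_samples = n_samples,
               n_classes = n_classes, width = width, layers = layers)
  params <- .nn_init(arch, seed)
  structure(list(arch = arch, params = params), class = "backbone")
}

#' @export
print.backbone <- function(x, ...) {
  cat(sprintf("<backbone '%s'> %d ch x %d samples -> %d classes, %d parameters\n",
              x$arch$name, x$arch$n_channels, x$arch$n_samples,
              x$arch$n_classes, param_count(x$params)))
  invisible(x)
}

#' Forward pass through a backbone
#'
#' Evaluates the network on a batch. The forward is pure: it mutates no
#' parameter or optimiser state, and repeated calls on the same input give
#' identical logits.
#'
#' @param arch architecture list (`$arch` of a [build_backbone()] object).
#' @param params nested parameter list.
#' @param x array of shape (channels, time, batch).
#' @param keep_cache keep intermediate activations for [backbone_backward()].
#' @return list with `logits` (batch x classes matrix) and, if requested,
#'   `cache`.
#' @export
backbone_forward <- function(arch, params, x, keep_cache = FALSE) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  d <- dim(x)
  if (d[1] != arch$n_channels || d[2] != arch$n_samples) {
    stop_input("input is %d x %d but backbone expects %d x %d",
               d[1], d[2], arch$n_channels, arch$n_samples)
  }
  if (!all(is.finite(x))) stop_input("non-finite values in input batch")
  .nn_forward(arch, params, x, keep_cache = keep_cache)
}

#' Backward pass through a backbone
#'
#' @param arch architecture list.
#' @param params nested parameter list.
#' @param cache cache from `backbone_forward(..., keep_cache = TRUE)`.
#' @param dlogits batch x classes matrix of loss gradients w.r.t. logits.
#' @return gradients with the same structure as `params`.
#' @export
backbone_backward <- function(arch, params, cache, dlogits) {
  .nn_backward(arch, params, cache, dlogits)
}

# forward over an (n, channels, time) trial array in memory-bounded chunks
.forward_trials <- function(arch, params, trials, chunk = 256L) {
  n <- dim(trials)[1]
  out <- matrix(NA_real_, n, arch$n_classes)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    xb <- aperm(trials[i:j, , , drop = FALSE], c(2, 3, 1))
    out[i:j, ] <- backbone_forward(arch, params, xb)$logits
    i <- j + 1L
  }
  out
}
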