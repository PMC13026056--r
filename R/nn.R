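# Minimal 1-D convolutional network engine.
#
# All layers operate on arrays of shape (channels, time, batch), column-major,
# so a temporal convolution reduces to one im2col + one matrix product.
# Backward passes are exact analytic gradients (checked against finite
# differences in the test suite). Parameters live in a plain nested list
# (one entry per parameterised layer, each a list of numeric arrays), which
# makes EMA averaging, AdamW, serialization and hashing trivial.

# ---- layer constructors (architecture description only, no state) ----------

nn_conv <- function(c_in, c_out, k) {
  list(type = "conv", c_in = c_in, c_out = c_out, k = k)
}

# temporal convolution with f kernels shared across input channels: each of
# the c_in channels is filtered by each kernel independently, giving
# c_in * f output channels (EEGNet-style "temporal then spatial" front end).
nn_tconv <- function(c_in, f, k) {
  list(type = "tconv", c_in = c_in, f = f, k = k, c_out = c_in * f)
}

nn_act <- function(fun) list(type = "act", fun = fun)
nn_pool <- function(p) list(type = "pool", p = p)
nn_gpool <- function() list(type = "gpool")
nn_flatten <- function() list(type = "flatten")
nn_dense <- function(d_in, d_out) list(type = "dense", d_in = d_in, d_out = d_out)

# ---- im2col convolution core ------------------------------------------------

# flat-index gather/scatter tables, cached per input shape (the same few
# shapes recur on every batch, so the tables are built once per run)
.conv_idx_cache <- new.env(parent = emptyenv())

.conv_idx <- function(ci, tt, b, k) {
  key <- paste(ci, tt, b, k, sep = "x")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  to <- tt - k + 1
  # flat index of X[c, t, bb] is c + (t-1)*ci + (bb-1)*ci*tt; the im2col
  # entry at row (j-1)*ci + c, column (bb-1)*to + t gathers X[c, t+j-1, bb]
  ci <- as.integer(ci); tt <- as.integer(tt); b <- as.integer(b)
  base <- rep(seq_len(ci), times = to) +
    rep((seq_len(to) - 1L) * ci, each = ci)                # j = 1 block, one batch
  base <- rep(base, times = b) +
    rep((seq_len(b) - 1L) * ci * tt, each = ci * to)       # all batch items
  gather <- matrix(0L, ci * k, to * b)
  for (j in seq_len(k)) {
    gather[((j - 1L) * ci + 1L):(j * ci), ] <- base + (j - 1L) * ci
  }
  out <- list(base = base, gather = gather, to = to)
  .conv_idx_cache[[key]] <- out
  out
}

.im2col <- function(X, k) {
  d <- dim(X)
  ix <- .conv_idx(d[1], d[2], d[3], k)
  matrix(X[ix$gather], nrow(ix$gather), ncol(ix$gather))
}

.conv_fw <- function(W, b, X, k) {
  d <- dim(X); ci <- d[1]; tt <- d[2]; bb <- d[3]
  to <- tt - k + 1
  M <- .im2col(X, k)
  Y <- W %*% M + b
  list(Y = array(Y, c(nrow(W), to, bb)), M = M)
}

.conv_bw <- function(W, dY, M, x_dim, k) {
  ci <- x_dim[1]; tt <- x_dim[2]; bb <- x_dim[3]
  to <- tt - k + 1
  dYm <- matrix(dY, nrow(W), to * bb)
  dW <- tcrossprod(dYm, M)
  db <- rowSums(dYm)
  dM <- crossprod(W, dYm)
  ix <- .conv_idx(ci, tt, bb, k)
  dX <- numeric(ci * tt * bb)
  for (j in seq_len(k)) {
    idx <- ix$base + (j - 1L) * ci
    dX[idx] <- dX[idx] + dM[((j - 1) * ci + 1):(j * ci), ]
  }
  list(dX = array(dX, x_dim), dW = dW, db = db)
}

# ---- activations ------------------------------------------------------------

.act_fw <- function(fun, X) {
  switch(fun,
    relu = pmax(X, 0),
    elu = { Y <- X; neg <- X < 0; Y[neg] <- exp(X[neg]) - 1; Y },
    square = X * X,
    # applied to non-negative pooled power features; offset keeps log finite
    safelog = log(X + 1e-6),
    stop_input("unknown activation '%s'", fun)
  )
}

.act_bw <- function(fun, X, dY) {
  switch(fun,
    relu = dY * (X > 0),
    elu = { G <- array(1, dim(X)); neg <- X < 0; G[neg] <- exp(X[neg]); dY * G },
    square = dY * 2 * X,
    safelog = dY / (X + 1e-6)
  )
}

# ---- forward / backward over a whole architecture ---------------------------

#' @keywords internal
.nn_forward <- function(arch, params, X, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(arch$layers)) else NULL
  cur <- X
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    pn <- paste0("L", i)
    if (ly$type == "conv") {
      fw <- .conv_fw(params[[pn]]$W, params[[pn]]$b, cur, ly$k)
      if (keep_cache) cache[[i]] <- list(x_dim = dim(cur), M = fw$M)
      cur <- fw$Y
    } else if (ly$type == "tconv") {
      d <- dim(cur); ci <- d[1]; tt <- d[2]; bb <- d[3]
      Xp <- array(aperm(cur, c(2, 1, 3)), c(1, tt, ci * bb))
      fw <- .conv_fw(params[[pn]]$W, params[[pn]]$b, Xp, ly$k)
      to <- tt - ly$k + 1
      Y4 <- array(fw$Y, c(ly$f, to, ci, bb))
      cur2 <- array(aperm(Y4, c(1, 3, 2, 4)), c(ly$f * ci, to, bb))
      if (keep_cache) cache[[i]] <- list(x_dim = d, xp_dim = dim(Xp), M = fw$M)
      cur <- cur2
    } else if (ly$type == "act") {
      if (keep_cache) cache[[i]] <- list(X = cur)
      cur <- .act_fw(ly$fun, cur)
    } else if (ly$type == "pool") {
      d <- dim(cur); to <- d[2] %/% ly$p
      Y <- cur[, seq.int(1, by = ly$p, length.out = to), , drop = FALSE]
      if (ly$p > 1) {
        for (off in 1:(ly$p - 1)) {
          Y <- Y + cur[, seq.int(1 + off, by = ly$p, length.out = to), , drop = FALSE]
        }
      }
      if (keep_cache) cache[[i]] <- list(x_dim = d)
      cur <- Y / ly$p
    } else if (ly$type == "gpool") {
      d <- dim(cur)
      if (keep_cache) cache[[i]] <- list(x_dim = d)
      cur <- matrix(rowSums(matrix(aperm(cur, c(1, 3, 2)), d[1] * d[3], d[2])),
                    d[1], d[3]) / d[2]
    } else if (ly$type == "flatten") {
      d <- dim(cur)
      if (keep_cache) cache[[i]] <- list(x_dim = d)
      cur <- matrix(cur, d[1] * d[2], d[3])
    } else if (ly$type == "dense") {
      if (keep_cache) cache[[i]] <- list(X = cur)
      cur <- params[[pn]]$W %*% cur + params[[pn]]$b
    } else {
      stop_input("unknown layer type '%s'", ly$type)
    }
  }
  list(logits = t(cur), cache = cache)  # logits: batch x classes
}

#' @keywords internal
.nn_backward <- function(arch, params, cache, dlogits) {
  # dlogits: batch x classes; propagate as (classes, batch)
  cur <- t(dlogits)
  grads <- list()
  for (i in rev(seq_along(arch$layers))) {
    ly <- arch$layers[[i]]
    pn <- paste0("L", i)
    cc <- cache[[i]]
    if (ly$type == "conv") {
      bw <- .conv_bw(params[[pn]]$W, cur, cc$M, cc$x_dim, ly$k)
      grads[[pn]] <- list(W = bw$dW, b = bw$db)
      cur <- bw$dX
    } else if (ly$type == "tconv") {
      d <- cc$x_dim; ci <- d[1]; tt <- d[2]; bb <- d[3]
      to <- tt - ly$k + 1
      dY4 <- array(cur, c(ly$f, ci, to, bb))
      dY2 <- array(aperm(dY4, c(1, 3, 2, 4)), c(ly$f, to, ci * bb))
      bw <- .conv_bw(params[[pn]]$W, dY2, cc$M, cc$xp_dim, ly$k)
      grads[[pn]] <- list(W = bw$dW, b = bw$db)
      cur <- aperm(array(bw$dX, c(tt, ci, bb)), c(2, 1, 3))
    } else if (ly$type == "act") {
      cur <- .act_bw(ly$fun, cc$X, cur)
    } else if (ly$type == "pool") {
      d <- cc$x_dim; to <- d[2] %/% ly$p
      dX <- array(0, d)
      for (off in 0:(ly$p - 1)) {
        dX[, seq.int(1 + off, by = ly$p, length.out = to), ] <- cur / ly$p
      }
      cur <- dX
    } else if (ly$type == "gpool") {
      d <- cc$x_dim
      cur <- aperm(array(cur / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))
    } else if (ly$type == "flatten") {
      cur <- array(cur, cc$x_dim)
    } else if (ly$type == "dense") {
      grads[[pn]] <- list(W = cur %*% t(cc$X), b = rowSums(cur))
      cur <- crossprod(params[[pn]]$W, cur)
    }
  }
  grads[paste0("L", seq_along(arch$layers))[
    paste0("L", seq_along(arch$layers)) %in% names(grads)]]
}

# ---- parameter initialisation ----------------------------------------------

.nn_init <- function(arch, seed) {
  set.seed(seed)
  params <- list()
  for (i in seq_along(arch$layers)) {
    ly <- arch$layers[[i]]
    pn <- paste0("L", i)
    if (ly$type == "conv") {
      sd <- sqrt(2 / (ly$c_in * ly$k))
      params[[pn]] <- list(
        W = matrix(stats::rnorm(ly$c_out * ly$c_in * ly$k, 0, sd),
                   ly$c_out, ly$c_in * ly$k),
        b = numeric(ly$c_out))
    } else if (ly$type == "tconv") {
      sd <- sqrt(2 / ly$k)
      params[[pn]] <- list(
        W = matrix(stats::rnorm(ly$f * ly$k, 0, sd), ly$f, ly$k),
        b = numeric(ly$f))
    } else if (ly$type == "dense") {
      sd <- sqrt(2 / ly$d_in)
      params[[pn]] <- list(
        W = matrix(stats::rnorm(ly$d_out * ly$d_in, 0, sd), ly$d_out, ly$d_in),
        b = numeric(ly$d_out))
    }
  }
  params
}

# ---- AdamW optimiser --------------------------------------------------------

#' Initialise AdamW optimiser state
#'
#' Decoupled-weight-decay Adam; the optimiser used for every teacher and
#' student fit in the package.
#'
#' @param params nested parameter list (as returned by [build_backbone()]).
#' @return optimiser state object.
#' @export
adamw_init <- function(params) {
  list(m = param_map(function(x) x * 0, params),
       v = param_map(function(x) x * 0, params),
       t = 0L)
}

#' One AdamW step
#'
#' @param opt optimiser state from [adamw_init()].
#' @param params current parameters.
#' @param grads gradients with the same structure as `params`.
#' @param lr learning rate for this step.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param beta1,beta2,eps Adam moment/stability constants.
#' @return list with updated `params` and `opt`.
#' @export
adamw_step <- function(opt, params, grads, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- param_map2(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- param_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- param_map2(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                    opt$m, opt$v)
  params <- param_map2(function(p, u) p - lr * u, params, upd)
  if (weight_decay > 0) {
    params <- param_map(function(p) p - lr * weight_decay * p, params)
  }
  list(params = params, opt = opt)
}
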