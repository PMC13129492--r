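#' Configuration of the CNN-extensible LSTM classifier
#'
#' The model is a 1-D temporal convolution front-end (optional) feeding a
#' single-layer LSTM, whose final hidden state passes through an optional
#' ReLU dense layer into a single sigmoid logit. The sigmoid head is the
#' two-class softmax in disguise: with logits `(0, u)` the softmax class-1
#' probability equals `sigmoid(u)` exactly, so a binary cross-entropy loss
#' on the sigmoid output and a softmax head agree. The shipped default
#' (16 conv channels, kernel 3, LSTM hidden 256, dense 64) serializes to
#' about 1.1 MiB at 32-bit precision — the payload one federated round
#' actually ships per client.
#'
#' @param n_features number of input features per time step.
#' @param window_len window length in samples.
#' @param cnn_enabled use the temporal-convolution front-end?
#' @param cnn_channels number of convolution output channels.
#' @param cnn_kernel convolution kernel length in samples
#'   (<= `window_len`).
#' @param lstm_hidden LSTM hidden/cell width.
#' @param dense_hidden width of the ReLU dense layer between the LSTM and
#'   the head; 0 places the head directly on the final hidden state.
#' @param init_scale half-width of the uniform weight initialization.
#' @param seed initialization seed.
#' @param max_size_bytes serialized-size budget for the configuration at
#'   32-bit precision (default 2 MiB).
#' @return an object of class `model_config`.
#' @export
model_config <- function(n_features = 8,
                         window_len = 8,
                         cnn_enabled = TRUE,
                         cnn_channels = 16,
                         cnn_kernel = 3,
                         lstm_hidden = 256,
                         dense_hidden = 64,
                         init_scale = 0.3,
                         seed = 1,
                         max_size_bytes = 2 * 2^20) {
  cfg <- list(
    n_features = check_count(n_features, "n_features"),
    window_len = check_count(window_len, "window_len"),
    cnn_enabled = isTRUE(cnn_enabled),
    cnn_channels = check_count(cnn_channels, "cnn_channels"),
    cnn_kernel = check_count(cnn_kernel, "cnn_kernel"),
    lstm_hidden = check_count(lstm_hidden, "lstm_hidden"),
    dense_hidden = check_count(dense_hidden, "dense_hidden", min = 0),
    init_scale = check_positive(init_scale, "init_scale"),
    seed = as.integer(seed),
    max_size_bytes = max_size_bytes
  )
  if (cfg$cnn_enabled && cfg$cnn_kernel > cfg$window_len) {
    stop_config("cnn_kernel (%d) exceeds window_len (%d)",
                cfg$cnn_kernel, cfg$window_len)
  }
  class(cfg) <- "model_config"
  cfg
}

param_shapes <- function(cfg) {
  lstm_in <- if (cfg$cnn_enabled) cfg$cnn_channels else cfg$n_features
  h <- cfg$lstm_hidden
  shapes <- list()
  if (cfg$cnn_enabled) {
    shapes$conv_w <- c(cfg$cnn_kernel, cfg$n_features, cfg$cnn_channels)
    shapes$conv_b <- cfg$cnn_channels
  }
  for (g in c("i", "f", "o", "c")) {
    shapes[[paste0("W_", g)]] <- c(h + lstm_in, h)
    shapes[[paste0("b_", g)]] <- h
  }
  head_in <- h
  if (cfg$dense_hidden > 0) {
    shapes$W_dense <- c(h, cfg$dense_hidden)
    shapes$b_dense <- cfg$dense_hidden
    head_in <- cfg$dense_hidden
  }
  shapes$W_head <- c(head_in, 1)
  shapes$b_head <- 1
  shapes
}

#' Number of trainable parameters implied by a model configuration
#' @param cfg a [model_config()].
#' @export
param_count <- function(cfg) {
  sum(vapply(param_shapes(cfg), prod, numeric(1)))
}

#' Initialize model parameters
#'
#' Weight matrices and convolution kernels are drawn iid uniform on
#' `(-init_scale, +init_scale)` under the configuration seed; all biases
#' start at zero. The same `(cfg, seed)` always yields an identical
#' parameter vector. The configuration is rejected if its serialized
#' 32-bit size would exceed the configured budget.
#'
#' @param cfg a [model_config()].
#' @return an object of class `param_vector`: a named list of numeric
#'   arrays.
#' @export
init_params <- function(cfg) {
  size <- 4 * param_count(cfg) + PARAM_HEADER_BYTES
  if (size > cfg$max_size_bytes) {
    stop_config("configuration serializes to %d bytes, over the %d budget",
                size, cfg$max_size_bytes)
  }
  shapes <- param_shapes(cfg)
  params <- with_seed(cfg$seed, {
    lapply(shapes, function(s) {
      n <- prod(s)
      is_bias <- length(s) == 1
      v <- if (is_bias) rep(0, n) else
        stats::runif(n, -cfg$init_scale, cfg$init_scale)
      if (length(s) > 1) array(v, s) else v
    })
  })
  structure(params, class = "param_vector")
}

#' @export
print.param_vector <- function(x, ...) {
  n <- sum(vapply(x, length, numeric(1)))
  cat(sprintf("<param_vector> %d arrays, %d parameters (%.2f MiB at 32-bit)\n",
              length(x), n, param_size_bytes(x) / 2^20))
  invisible(x)
}

# Fixed, documented header size of the 32-bit deployment payload: a 64-byte
# preamble (magic, version, array count, checksum) precedes the raw values.
PARAM_HEADER_BYTES <- 64

#' Serialized size of a parameter vector in bytes
#'
#' Accounts the deployment wire format used by the communication ledger:
#' every parameter as a 32-bit float (4 bytes) plus a fixed 64-byte header.
#'
#' @param params a `param_vector`.
#' @return byte count.
#' @export
param_size_bytes <- function(params) {
  4 * sum(vapply(params, length, numeric(1))) + PARAM_HEADER_BYTES
}

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Batched forward pass. X is an array [batch, T, F]. Returns probabilities;
# with cache = TRUE also every intermediate needed for backpropagation.
nn_forward <- function(params, X, cfg, cache = FALSE) {
  if (!all(is.finite(X))) stop_data("non-finite values in model input")
  B <- dim(X)[1]
  T_in <- dim(X)[2]
  if (T_in != cfg$window_len || dim(X)[3] != cfg$n_features) {
    stop_data("input window is %d x %d but the model expects %d x %d",
              T_in, dim(X)[3], cfg$window_len, cfg$n_features)
  }
  h <- cfg$lstm_hidden

  # temporal convolution front-end
  if (cfg$cnn_enabled) {
    K <- cfg$cnn_kernel
    T_seq <- T_in - K + 1
    Wc <- matrix(params$conv_w, K * cfg$n_features, cfg$cnn_channels)
    conv_pre <- vector("list", T_seq)
    seq_x <- vector("list", T_seq)
    for (t in seq_len(T_seq)) {
      patch <- X[, t:(t + K - 1), , drop = FALSE]
      dim(patch) <- c(B, K * cfg$n_features)
      pre <- add_bias(patch %*% Wc, params$conv_b)
      conv_pre[[t]] <- pre
      seq_x[[t]] <- pre * (pre > 0)  # ReLU
    }
  } else {
    T_seq <- T_in
    seq_x <- lapply(seq_len(T_seq), function(t) {
      m <- X[, t, , drop = FALSE]
      dim(m) <- c(B, cfg$n_features)
      m
    })
    conv_pre <- NULL
  }

  H <- matrix(0, B, h)
  C <- matrix(0, B, h)
  steps <- if (cache) vector("list", T_seq) else NULL
  for (t in seq_len(T_seq)) {
    A <- cbind(H, seq_x[[t]])
    I <- sigmoid(add_bias(A %*% params$W_i, params$b_i))
    Fg <- sigmoid(add_bias(A %*% params$W_f, params$b_f))
    O <- sigmoid(add_bias(A %*% params$W_o, params$b_o))
    G <- tanh(add_bias(A %*% params$W_c, params$b_c))
    C_new <- Fg * C + I * G
    tC <- tanh(C_new)
    H_new <- O * tC
    if (cache) {
      steps[[t]] <- list(A = A, I = I, Fg = Fg, O = O, G = G,
                         C_prev = C, tC = tC)
    }
    H <- H_new
    C <- C_new
  }

  if (cfg$dense_hidden > 0) {
    preD <- add_bias(H %*% params$W_dense, params$b_dense)
    D <- preD * (preD > 0)
  } else {
    preD <- NULL
    D <- H
  }
  u <- as.vector(D %*% params$W_head) + params$b_head
  p <- sigmoid(u)
  if (!cache) return(p)
  list(p = p, u = u, D = D, preD = preD, H_T = H, steps = steps,
       seq_x = seq_x, conv_pre = conv_pre, B = B, T_seq = T_seq)
}

# Backpropagation through the head, the LSTM (through time) and the
# convolution front-end. `gu` is dLoss/dlogit per sample (already averaged).
nn_backward <- function(params, X, cfg, fw, gu) {
  B <- fw$B
  h <- cfg$lstm_hidden
  grads <- lapply(params, function(a) {
    z <- a; z[] <- 0; z
  })
  gu <- matrix(gu, ncol = 1)

  grads$W_head <- crossprod(fw$D, gu)
  grads$b_head <- sum(gu)
  gD <- gu %*% t(params$W_head)
  if (cfg$dense_hidden > 0) {
    gPreD <- gD * (fw$preD > 0)
    grads$W_dense <- crossprod(fw$H_T, gPreD)
    grads$b_dense <- colSums(gPreD)
    dH <- gPreD %*% t(params$W_dense)
  } else {
    dH <- gD
  }

  dC <- matrix(0, B, h)
  dX_seq <- vector("list", fw$T_seq)
  for (t in rev(seq_len(fw$T_seq))) {
    st <- fw$steps[[t]]
    dO <- dH * st$tC
    dC <- dC + dH * st$O * (1 - st$tC^2)
    dFg <- dC * st$C_prev
    dI <- dC * st$G
    dG <- dC * st$I
    dC_prev <- dC * st$Fg

    da_i <- dI * st$I * (1 - st$I)
    da_f <- dFg * st$Fg * (1 - st$Fg)
    da_o <- dO * st$O * (1 - st$O)
    da_g <- dG * (1 - st$G^2)

    grads$W_i <- grads$W_i + crossprod(st$A, da_i)
    grads$W_f <- grads$W_f + crossprod(st$A, da_f)
    grads$W_o <- grads$W_o + crossprod(st$A, da_o)
    grads$W_c <- grads$W_c + crossprod(st$A, da_g)
    grads$b_i <- grads$b_i + colSums(da_i)
    grads$b_f <- grads$b_f + colSums(da_f)
    grads$b_o <- grads$b_o + colSums(da_o)
    grads$b_c <- grads$b_c + colSums(da_g)

    dA <- da_i %*% t(params$W_i) + da_f %*% t(params$W_f) +
      da_o %*% t(params$W_o) + da_g %*% t(params$W_c)
    dH <- dA[, seq_len(h), drop = FALSE]
    dX_seq[[t]] <- dA[, (h + 1):ncol(dA), drop = FALSE]
    dC <- dC_prev
  }

  if (cfg$cnn_enabled) {
    K <- cfg$cnn_kernel
    Wc_grad <- matrix(0, K * cfg$n_features, cfg$cnn_channels)
    for (t in seq_len(fw$T_seq)) {
      gPre <- dX_seq[[t]] * (fw$conv_pre[[t]] > 0)
      patch <- X[, t:(t + K - 1), , drop = FALSE]
      dim(patch) <- c(B, K * cfg$n_features)
      Wc_grad <- Wc_grad + crossprod(patch, gPre)
      grads$conv_b <- grads$conv_b + colSums(gPre)
    }
    grads$conv_w <- array(Wc_grad, dim(params$conv_w))
  }
  structure(grads, class = "param_vector")
}

BCE_CLIP <- 1e-7

clip_prob <- function(p) pmin(pmax(p, BCE_CLIP), 1 - BCE_CLIP)

bce <- function(p, y) {
  pc <- clip_prob(p)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

#' Mean binary cross-entropy of a model on a windowed dataset
#'
#' The local training objective: the average over the device's samples of
#' `-(z log p + (1 - z) log(1 - p))`, with predicted probabilities clipped
#' to `[1e-7, 1 - 1e-7]` for numerical safety.
#'
#' @param params a `param_vector`.
#' @param data a non-empty `windowed_dataset`.
#' @param cfg the [model_config()] the parameters were built from.
#' @return scalar loss.
#' @export
local_loss <- function(params, data, cfg) {
  if (n_windows(data) == 0) stop_data("dataset is empty")
  bce(nn_forward(params, data$x, cfg), data$y)
}

# Loss plus gradients on one batch; the unit of work for SGD/Adam.
loss_and_grad <- function(params, X, y, cfg) {
  fw <- nn_forward(params, X, cfg, cache = TRUE)
  pc <- clip_prob(fw$p)
  loss <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  # gradient of the clipped loss: zero where the probability is clipped
  gu <- (fw$p - y) / length(y)
  gu[fw$p < BCE_CLIP | fw$p > 1 - BCE_CLIP] <- 0
  list(loss = loss, grads = nn_backward(params, X, cfg, fw, gu))
}

#' One LSTM cell update
#'
#' Applies the gate recursion to a single time step: input, forget and
#' output gates are sigmoids of affine maps of the concatenation
#' `[h_prev, x_t]`, the candidate is the tanh of its own affine map, the
#' cell state is `f * C_prev + i * candidate`, and the hidden state is
#' `o * tanh(C)` (hence bounded in (-1, 1)).
#'
#' @param x_t numeric input vector for this step (length = LSTM input
#'   width).
#' @param state list with `h` and `c`, each of length `lstm_hidden`; use
#'   zeros to start a sequence.
#' @param params a `param_vector`.
#' @return list with updated `h` and `c`.
#' @export
lstm_step <- function(x_t, state, params) {
  h <- length(state$h)
  if (length(state$c) != h || length(x_t) + h != nrow(params$W_i)) {
    stop_data("lstm_step: shapes of x_t/state do not match the parameters")
  }
  A <- matrix(c(state$h, x_t), 1)
  I <- sigmoid(A %*% params$W_i + params$b_i)
  Fg <- sigmoid(A %*% params$W_f + params$b_f)
  O <- sigmoid(A %*% params$W_o + params$b_o)
  G <- tanh(A %*% params$W_c + params$b_c)
  C_new <- Fg * state$c + I * G
  list(h = as.vector(O * tanh(C_new)), c = as.vector(C_new))
}

#' Temporal convolution feature extraction on one window
#'
#' Valid (no padding) 1-D cross-correlation along time, one output channel
#' per kernel, plus bias, then ReLU: `y = ReLU(w * z + b)`. Output length
#' is `window_len - cnn_kernel + 1`.
#'
#' @param window a `window_len x n_features` matrix.
#' @param params a `param_vector` with `conv_w`/`conv_b`.
#' @param cfg the [model_config()].
#' @return a `(window_len - cnn_kernel + 1) x cnn_channels` matrix.
#' @export
cnn_extract <- function(window, params, cfg) {
  if (!cfg$cnn_enabled) stop_config("cnn_enabled is FALSE in this config")
  if (cfg$cnn_kernel > nrow(window)) {
    stop_config("kernel (%d) longer than window (%d)",
                cfg$cnn_kernel, nrow(window))
  }
  K <- cfg$cnn_kernel
  T_seq <- nrow(window) - K + 1
  Wc <- matrix(params$conv_w, K * ncol(window), cfg$cnn_channels)
  out <- matrix(NA_real_, T_seq, cfg$cnn_channels)
  for (t in seq_len(T_seq)) {
    patch <- window[t:(t + K - 1), , drop = FALSE]
    out[t, ] <- as.vector(matrix(as.vector(patch), 1) %*% Wc) + params$conv_b
  }
  out * (out > 0)
}

#' Predicted stress probability for one window
#'
#' Full forward pass — optional convolution front-end, LSTM over the
#' sequence, dense layer, sigmoid head — on a single normalized window.
#'
#' @param window a `window_len x n_features` matrix of normalized features.
#' @param params a `param_vector`.
#' @param cfg the [model_config()].
#' @return probability of stress in (0, 1).
#' @export
forward_prob <- function(window, params, cfg) {
  X <- array(window, c(1, nrow(window), ncol(window)))
  as.vector(nn_forward(params, X, cfg))
}

# Ablation used to demonstrate order sensitivity: convolution front-end,
# global mean pool over time, then the head. With kernel length 1 the pool
# makes the map permutation-invariant in time.
cnn_pool_logit <- function(window, params, cfg) {
  feats <- cnn_extract(window, params, cfg)
  pooled <- colMeans(feats)
  w <- params$W_head[seq_along(pooled), 1]
  sum(pooled * w) + params$b_head
}

# Two-class softmax class-1 probability for logits (0, u); identical to
# sigmoid(u) — kept as an explicit cross-check of the head equivalence.
softmax2_prob <- function(u) {
  e <- exp(c(0, u) - max(0, u))
  e[2] / sum(e)
}

# ---- parameter arithmetic ----------------------------------------------

check_same_shapes <- function(a, b) {
  if (!identical(names(a), names(b)) ||
      !all(mapply(function(x, y) identical(dim(x), dim(y)) &&
                    length(x) == length(y), a, b))) {
    stop_data("parameter vectors have incompatible shapes")
  }
}

#' @export
`+.param_vector` <- function(e1, e2) {
  check_same_shapes(e1, e2)
  structure(mapply(`+`, e1, e2, SIMPLIFY = FALSE), class = "param_vector")
}

#' @export
`*.param_vector` <- function(e1, e2) {
  if (is.numeric(e1)) { s <- e1; p <- e2 } else { s <- e2; p <- e1 }
  structure(lapply(p, function(a) a * s), class = "param_vector")
}

#' Flatten a parameter vector to one named numeric vector
#' @param params a `param_vector`.
#' @export
flatten_params <- function(params) {
  unlist(lapply(params, as.vector))
}

unflatten_params <- function(v, template) {
  out <- template
  at <- 1L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    a <- template[[nm]]
    a[] <- v[at:(at + n - 1L)]
    out[[nm]] <- a
    at <- at + n
  }
  out
}

# ---- serialization ------------------------------------------------------

#' Serialize / restore model parameters
#'
#' Single binary container: a length-prefixed JSON manifest (array names,
#' shapes, dtype, optional configuration echo) followed by the raw values
#' as little-endian float64, in manifest order. Round-trips bit-exactly.
#' The 32-bit deployment size reported by [param_size_bytes()] refers to
#' the wire format a client would ship, not to this container.
#'
#' @param params a `param_vector`.
#' @param path file path.
#' @param cfg optional [model_config()] echoed into the manifest.
#' @return `write_params` returns `path` invisibly; `read_params` returns
#'   the `param_vector`.
#' @export
write_params <- function(params, path, cfg = NULL) {
  manifest <- list(
    format = "fedherd-params",
    version = 1L,
    dtype = "float64",
    arrays = lapply(params, function(a) as.integer(dim(a) %||% length(a))),
    config = if (!is.null(cfg)) unclass(cfg)[setdiff(names(cfg),
                                                     "start_time")]
  )
  mjson <- charToRaw(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                      digits = NA, null = "null"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(length(mjson), con, size = 4, endian = "little")
  writeBin(mjson, con)
  for (a in params) {
    writeBin(as.vector(a), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  mlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  manifest <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", mlen)),
                                 simplifyVector = FALSE)
  if (!identical(manifest$format, "fedherd-params")) {
    stop_data("'%s' is not a fedherd parameter container", path)
  }
  params <- list()
  for (nm in names(manifest$arrays)) {
    shape <- unlist(manifest$arrays[[nm]])
    v <- readBin(con, "double", prod(shape), size = 8, endian = "little")
    params[[nm]] <- if (length(shape) > 1) array(v, shape) else v
  }
  structure(params, class = "param_vector")
}
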