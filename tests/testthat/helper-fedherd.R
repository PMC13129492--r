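# Independent oracles and small fixtures shared across the suite. The
# oracles deliberately re-derive each quantity with straight-line scalar
# code (loops, no shared helpers) so they stay independent of the package's
# vectorized implementations.

# -- scalar LSTM cell: direct transcription of the gate recursion ---------
ref_lstm_step <- function(x, h, c, params) {
  hid <- length(h)
  inp <- length(x)
  a <- c(h, x)
  out_h <- numeric(hid)
  out_c <- numeric(hid)
  sig <- function(z) 1 / (1 + exp(-z))
  for (j in seq_len(hid)) {
    zi <- zf <- zo <- zg <- 0
    for (k in seq_len(hid + inp)) {
      zi <- zi + params$W_i[k, j] * a[k]
      zf <- zf + params$W_f[k, j] * a[k]
      zo <- zo + params$W_o[k, j] * a[k]
      zg <- zg + params$W_c[k, j] * a[k]
    }
    i_g <- sig(zi + params$b_i[j])
    f_g <- sig(zf + params$b_f[j])
    o_g <- sig(zo + params$b_o[j])
    cand <- tanh(zg + params$b_c[j])
    out_c[j] <- f_g * c[j] + i_g * cand
    out_h[j] <- o_g * tanh(out_c[j])
  }
  list(h = out_h, c = out_c)
}

# -- hand 1-D valid cross-correlation + ReLU ------------------------------
ref_cnn_extract <- function(window, conv_w, conv_b) {
  K <- dim(conv_w)[1]
  n_ch <- dim(conv_w)[3]
  T_out <- nrow(window) - K + 1
  out <- matrix(0, T_out, n_ch)
  for (ch in seq_len(n_ch)) {
    for (t in seq_len(T_out)) {
      acc <- conv_b[ch]
      for (k in seq_len(K)) {
        for (f in seq_len(ncol(window))) {
          acc <- acc + conv_w[k, f, ch] * window[t + k - 1, f]
        }
      }
      out[t, ch] <- max(acc, 0)
    }
  }
  out
}

# -- straight-line single-window forward pass -----------------------------
ref_forward <- function(window, params, cfg) {
  seq_in <- if (cfg$cnn_enabled) {
    ref_cnn_extract(window, params$conv_w, params$conv_b)
  } else {
    window
  }
  h <- rep(0, cfg$lstm_hidden)
  c <- rep(0, cfg$lstm_hidden)
  for (t in seq_len(nrow(seq_in))) {
    st <- ref_lstm_step(seq_in[t, ], h, c, params)
    h <- st$h
    c <- st$c
  }
  d <- h
  if (cfg$dense_hidden > 0) {
    d <- numeric(cfg$dense_hidden)
    for (j in seq_len(cfg$dense_hidden)) {
      d[j] <- max(sum(h * params$W_dense[, j]) + params$b_dense[j], 0)
    }
  }
  u <- sum(d * params$W_head[, 1]) + params$b_head
  1 / (1 + exp(-u))
}

# -- brute-force sample-size-weighted mean of flat client vectors ---------
ref_weighted_mean <- function(mats, ns) {
  total <- sum(ns)
  acc <- 0 * mats[[1]]
  for (j in seq_along(mats)) {
    acc <- acc + (ns[j] / total) * mats[[j]]
  }
  acc
}

# -- first Adam step on one scalar coordinate -----------------------------
ref_adam_first_step <- function(g, lr, beta1 = 0.9, beta2 = 0.999,
                                eps = 1e-8) {
  m_hat <- (beta1 * 0 + (1 - beta1) * g) / (1 - beta1)
  v_hat <- (beta2 * 0 + (1 - beta2) * g^2) / (1 - beta2)
  -lr * m_hat / (sqrt(v_hat) + eps)
}

# -- brute-force confusion tabulation -------------------------------------
ref_confusion <- function(p, y, threshold = 0.5) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(p)) {
    pred <- p[i] > threshold
    if (pred && y[i] == 1) tp <- tp + 1
    if (pred && y[i] == 0) fp <- fp + 1
    if (!pred && y[i] == 1) fn <- fn + 1
    if (!pred && y[i] == 0) tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# -- central finite-difference gradient of the clipped BCE loss -----------
numerical_gradient <- function(params, X, y, cfg, eps = 1e-5) {
  v <- flatten_params(params)
  f <- function(w) {
    p <- fedherd:::unflatten_params(w, params)
    fedherd:::bce(fedherd:::nn_forward(p, X, cfg), y)
  }
  vapply(seq_along(v), function(i) {
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    (f(vp) - f(vm)) / (2 * eps)
  }, numeric(1))
}

# -- fixtures -------------------------------------------------------------

tiny_herd <- function(n_animals = 4, duration_hours = 24, seed = 1, ...) {
  simulate_herd(herd_config(n_animals = n_animals,
                            duration_hours = duration_hours,
                            seed = seed, ...))
}

# A single-animal table with explicit values, for pointwise preprocessing
# checks. `hr`, `temp`, `act` are recycled to `n` rows at 15-min spacing.
manual_table <- function(hr, temp = 38.5, act = 0.2, id = "cow_001",
                         start = as.POSIXct("2024-06-01 00:00:00",
                                            tz = "UTC")) {
  n <- max(length(hr), length(temp), length(act))
  data.frame(
    timestamp = start + (seq_len(n) - 1) * 15 * 60,
    cattle_id = id,
    heart_rate = rep_len(hr, n),
    body_temp = rep_len(temp, n),
    activity_level = rep_len(act, n),
    ambient_temp = 22,
    humidity = 60,
    location_lat = 42,
    location_long = -85,
    is_stressed = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Separable toy windows: constant-in-time windows whose label is a strict
# threshold on feature 1, so a working model can overfit them quickly.
toy_windows <- function(n = 120, window_len = 4, n_features = 2, seed = 1) {
  set.seed(seed)
  v <- runif(n)
  x <- array(0, c(n, window_len, n_features))
  for (i in seq_len(n)) x[i, , 1] <- v[i]
  if (n_features > 1) x[, , 2] <- 0.5
  structure(list(x = x, y = as.integer(v > 0.5),
                 cattle_id = rep("toy", n),
                 end_timestamp = as.POSIXct("2024-06-01", tz = "UTC") +
                   seq_len(n),
                 feature_names = paste0("f", seq_len(n_features)),
                 window_len = window_len, stride = 1),
            class = "windowed_dataset")
}

tiny_model_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_features = 2, window_len = 4, cnn_enabled = FALSE,
         lstm_hidden = 3, dense_hidden = 0, seed = 11),
    list(...)
  )
  do.call(model_config, args)
}

# Random parameters for a config, biases included, seeded.
random_params <- function(cfg, seed = 1, scale = 0.5) {
  p <- init_params(cfg)
  v <- flatten_params(p)
  set.seed(seed)
  fedherd:::unflatten_params(runif(length(v), -scale, scale), p)
}
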