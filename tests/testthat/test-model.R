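test_that("initialization is seeded and counts parameters correctly", {
  cfg <- tiny_model_cfg()
  expect_identical(init_params(cfg), init_params(cfg))
  expect_false(identical(init_params(cfg),
                         init_params(tiny_model_cfg(seed = 12))))

  # 4-gate LSTM + scalar head: 4*(h*(f+h)+h) + (h+1) with h=4, f=10
  cfg245 <- model_config(n_features = 10, window_len = 4,
                         cnn_enabled = FALSE, lstm_hidden = 4,
                         dense_hidden = 0)
  expect_equal(param_count(cfg245), 245)
  expect_equal(param_size_bytes(init_params(cfg245)),
               245 * 4 + fedherd:::PARAM_HEADER_BYTES)

  # biases start at zero, weights inside the init range
  p <- init_params(tiny_model_cfg())
  expect_true(all(p$b_i == 0) && all(p$b_head == 0))
  expect_true(all(abs(p$W_i) <= 0.3))
})

test_that("the shipped default model serializes into the 1-2 MB band", {
  p <- init_params(model_config())
  size <- param_size_bytes(p)
  expect_gte(size, 1 * 2^20)
  expect_lte(size, 2 * 2^20)
  # a configuration over the budget is rejected
  expect_error(init_params(model_config(lstm_hidden = 600)), "budget")
})

test_that("lstm_step matches closed forms and an independent transcription", {
  # zero parameters: gates 0.5, candidate 0, C halves, h = 0.5 tanh(C/2)
  cfg <- tiny_model_cfg(lstm_hidden = 2, n_features = 3)
  p0 <- init_params(tiny_model_cfg(lstm_hidden = 2, n_features = 3,
                                   init_scale = 1e-9))
  p0 <- fedherd:::unflatten_params(0 * flatten_params(p0), p0)
  c_prev <- c(0.8, -0.4)
  st <- lstm_step(c(0.3, 0.9, 0.1), list(h = c(0, 0), c = c_prev), p0)
  expect_equal(st$c, 0.5 * c_prev, tolerance = 1e-15)
  expect_equal(st$h, 0.5 * tanh(0.5 * c_prev), tolerance = 1e-15)

  # zero carry: C_t = i * candidate exactly
  pr <- random_params(cfg, seed = 3)
  st0 <- lstm_step(c(1, 0, 1), list(h = c(0.1, 0.2), c = c(0, 0)), pr)
  a <- matrix(c(0.1, 0.2, 1, 0, 1), 1)
  i_g <- 1 / (1 + exp(-(a %*% pr$W_i + pr$b_i)))
  cand <- tanh(a %*% pr$W_c + pr$b_c)
  expect_equal(st0$c, as.vector(i_g * cand), tolerance = 1e-14)

  # scalar cell, all weights 0.1: matches the scalar reference oracle
  cfg1 <- tiny_model_cfg(lstm_hidden = 1, n_features = 1)
  p1 <- init_params(cfg1)
  for (nm in names(p1)) p1[[nm]][] <- ifelse(grepl("^W", nm), 0.1, 0)
  got <- lstm_step(1, list(h = 0, c = 0), p1)
  ref <- ref_lstm_step(1, 0, 0, p1)
  expect_equal(got$h, ref$h, tolerance = 1e-12)
  expect_equal(got$c, ref$c, tolerance = 1e-12)

  # hidden state is bounded in (-1, 1) after a step
  for (s in 1:20) {
    prs <- random_params(cfg, seed = s, scale = 3)
    sts <- lstm_step(runif(3, -5, 5),
                     list(h = runif(2, -0.9, 0.9), c = rnorm(2, 0, 4)), prs)
    expect_true(all(abs(sts$h) < 1))
  }

  expect_error(lstm_step(c(1, 2), list(h = c(0, 0), c = c(0, 0)), pr),
               "shape")
})

test_that("cnn_extract is a valid cross-correlation with ReLU", {
  cfg <- model_config(n_features = 1, window_len = 4, cnn_enabled = TRUE,
                      cnn_channels = 1, cnn_kernel = 3, lstm_hidden = 2)
  p <- init_params(cfg)
  p$conv_w[] <- c(1, 0, -1)
  p$conv_b[] <- 0
  win <- matrix(c(1, 2, 3, 4), 4, 1)
  # conv gives [-2, -2], ReLU clamps to [0, 0]
  expect_equal(as.vector(cnn_extract(win, p, cfg)), c(0, 0))
  p$conv_w[] <- c(-1, 0, 1)
  expect_equal(as.vector(cnn_extract(win, p, cfg)), c(2, 2))

  # zero input, zero bias -> zero map; huge negative bias -> zeros
  pz <- random_params(cfg, seed = 1)
  pz$conv_b[] <- 0
  expect_equal(as.vector(cnn_extract(matrix(0, 4, 1), pz, cfg)), c(0, 0))
  pz$conv_b[] <- -1e6
  expect_equal(as.vector(cnn_extract(win, pz, cfg)), c(0, 0))

  # multi-channel, multi-feature case against the loop oracle
  cfg2 <- model_config(n_features = 3, window_len = 6, cnn_channels = 4,
                       cnn_kernel = 2, lstm_hidden = 2)
  p2 <- random_params(cfg2, seed = 5)
  set.seed(9)
  win2 <- matrix(runif(18), 6, 3)
  expect_equal(cnn_extract(win2, p2, cfg2),
               ref_cnn_extract(win2, p2$conv_w, p2$conv_b),
               tolerance = 1e-12)

  expect_error(cnn_extract(matrix(0, 1, 1), p, cfg), "kernel")
})

test_that("forward pass matches a straight-line reimplementation", {
  # zero parameters give exactly 0.5; huge head bias saturates
  cfg <- tiny_model_cfg()
  pz <- init_params(cfg)
  pz <- fedherd:::unflatten_params(0 * flatten_params(pz), pz)
  set.seed(2)
  win <- matrix(runif(8), 4, 2)
  expect_identical(forward_prob(win, pz, cfg), 0.5)
  psat <- pz
  psat$b_head[] <- 30
  expect_gt(forward_prob(win, psat, cfg), 0.999999)

  # tiny configs, random weights: match the scalar oracle end to end
  for (s in 1:5) {
    cfgs <- model_config(n_features = 2, window_len = 3, cnn_enabled = TRUE,
                         cnn_channels = 2, cnn_kernel = 2, lstm_hidden = 2,
                         dense_hidden = 2)
    ps <- random_params(cfgs, seed = s)
    set.seed(s + 50)
    w <- matrix(runif(6), 3, 2)
    expect_equal(forward_prob(w, ps, cfgs), ref_forward(w, ps, cfgs),
                 tolerance = 1e-10)
  }
  cfgn <- tiny_model_cfg(lstm_hidden = 4, dense_hidden = 3)
  pn <- random_params(cfgn, seed = 8)
  set.seed(60)
  wn <- matrix(runif(8), 4, 2)
  expect_equal(forward_prob(wn, pn, cfgn), ref_forward(wn, pn, cfgn),
               tolerance = 1e-10)

  expect_error(forward_prob(matrix(c(1, NA, 1, 1, 1, 1, 1, 1), 4, 2),
                            pn, cfgn), "finite")
})

test_that("forward output stays in (0,1) over random windows and params", {
  cfg <- model_config(n_features = 3, window_len = 5, cnn_channels = 2,
                      cnn_kernel = 2, lstm_hidden = 3, dense_hidden = 2)
  for (s in 1:25) {
    p <- random_params(cfg, seed = s, scale = 4)
    set.seed(1000 + s)
    win <- matrix(runif(15, -2, 2), 5, 3)
    pr <- forward_prob(win, p, cfg)
    expect_true(pr > 0 && pr < 1)
  }
})

test_that("sigmoid head equals the 2-class softmax class-1 probability", {
  for (u in c(-30, -5, -0.1, 0, 0.3, 4, 25)) {
    expect_equal(fedherd:::softmax2_prob(u), fedherd:::sigmoid(u),
                 tolerance = 1e-12)
  }
})

test_that("the LSTM is order-aware; a kernel-1 conv + pool ablation is not", {
  cfg <- model_config(n_features = 2, window_len = 6, cnn_enabled = FALSE,
                      lstm_hidden = 4, dense_hidden = 0)
  p <- random_params(cfg, seed = 4)
  set.seed(31)
  win <- matrix(runif(12), 6, 2)
  expect_gt(abs(forward_prob(win, p, cfg) -
                  forward_prob(win[6:1, ], p, cfg)), 1e-8)

  cfg1 <- model_config(n_features = 2, window_len = 6, cnn_enabled = TRUE,
                       cnn_channels = 3, cnn_kernel = 1, lstm_hidden = 3)
  p1 <- random_params(cfg1, seed = 6)
  expect_equal(fedherd:::cnn_pool_logit(win, p1, cfg1),
               fedherd:::cnn_pool_logit(win[sample(6), ], p1, cfg1),
               tolerance = 1e-12)
})

test_that("binary cross-entropy matches analytic values and clipping", {
  cfg <- tiny_model_cfg()
  pz <- init_params(cfg)
  pz <- fedherd:::unflatten_params(0 * flatten_params(pz), pz)
  data <- toy_windows(n = 30, window_len = 4, n_features = 2)
  # all predictions 0.5 -> loss = ln 2 whatever the labels
  expect_equal(local_loss(pz, data, cfg), log(2), tolerance = 1e-12)

  # clipping floor: confident correct predictions cost -log(1 - 1e-7)
  expect_equal(fedherd:::bce(1, 1), -log(1 - 1e-7), tolerance = 1e-12)
  expect_equal(fedherd:::bce(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_equal(-(log(0.9) + log(0.8)) / 2, 0.164252, tolerance = 1e-6)

  expect_error(local_loss(pz, subset_windows(data, integer(0)), cfg),
               "empty")
})

test_that("analytic gradients match central finite differences", {
  check_grad <- function(cfg, n = 6, seed = 1) {
    p <- random_params(cfg, seed = seed, scale = 0.6)
    # shift biases off zero so every path is active
    v <- flatten_params(p) + seq_along(flatten_params(p)) * 1e-3
    p <- fedherd:::unflatten_params(v, p)
    set.seed(seed + 10)
    X <- array(runif(n * cfg$window_len * cfg$n_features),
               c(n, cfg$window_len, cfg$n_features))
    y <- rep_len(c(1, 0), n)
    g <- flatten_params(fedherd:::loss_and_grad(p, X, y, cfg)$grads)
    num <- numerical_gradient(p, X, y, cfg)
    sqrt(sum((g - num)^2)) / (sqrt(sum(g^2)) + sqrt(sum(num^2)))
  }
  # ~50-parameter models, with and without the convolution front-end
  cfg_cnn <- model_config(n_features = 2, window_len = 3, cnn_enabled = TRUE,
                          cnn_channels = 2, cnn_kernel = 2, lstm_hidden = 2,
                          dense_hidden = 0)
  cfg_lstm <- model_config(n_features = 2, window_len = 3,
                           cnn_enabled = FALSE, lstm_hidden = 2,
                           dense_hidden = 2)
  expect_lt(check_grad(cfg_cnn, seed = 1), 1e-4)
  expect_lt(check_grad(cfg_cnn, seed = 2), 1e-4)
  expect_lt(check_grad(cfg_lstm, seed = 3), 1e-4)
})

test_that("parameter containers round-trip bit-exactly", {
  cfg <- tiny_model_cfg(lstm_hidden = 4, dense_hidden = 2, cnn_enabled = TRUE,
                        cnn_channels = 2, cnn_kernel = 2)
  p <- random_params(cfg, seed = 9)
  f <- tempfile(fileext = ".bin")
  write_params(p, f, cfg)
  back <- read_params(f)
  expect_identical(lapply(unclass(back), as.vector),
                   lapply(unclass(p), as.vector))
  expect_identical(lapply(unclass(back), dim), lapply(unclass(p), dim))
  g <- tempfile()
  con <- file(g, "wb")
  writeBin(2L, con, size = 4, endian = "little")
  writeBin(charToRaw("{}"), con)
  close(con)
  expect_error(read_params(g), "container")
})

test_that("parameter arithmetic is element-wise and shape-checked", {
  cfg <- tiny_model_cfg()
  a <- random_params(cfg, seed = 1)
  b <- random_params(cfg, seed = 2)
  s <- a + b
  expect_equal(flatten_params(s), flatten_params(a) + flatten_params(b))
  expect_equal(flatten_params(0.5 * a), 0.5 * flatten_params(a))
  other <- random_params(tiny_model_cfg(lstm_hidden = 5), seed = 1)
  expect_error(a + other, "incompatible")
})
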