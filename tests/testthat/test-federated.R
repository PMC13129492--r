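test_that("fed_config validates its ranges and encodes the defaults", {
  d <- fed_config()
  expect_equal(d$n_clients, 10)
  expect_equal(d$participation, 1.0)
  expect_equal(d$rounds, 50)
  expect_equal(d$local_epochs, 5)
  expect_equal(d$batch_size, 32)
  expect_equal(d$learning_rate, 0.001)
  expect_identical(d$optimizer, "adam")
  expect_error(fed_config(participation = 0), "participation")
  expect_error(fed_config(participation = 1.5), "participation")
  expect_error(fed_config(optimizer = "sgd"), "adam")
})

test_that("local updates: null step, no-op epochs and first Adam step", {
  cfg <- tiny_model_cfg()
  data <- toy_windows(n = 40)
  g0 <- random_params(cfg, seed = 2)

  lr0 <- local_update(g0, data, fed_config(learning_rate = 0), cfg,
                      round_seed = 1)
  expect_identical(flatten_params(lr0$params), flatten_params(g0))

  e0 <- local_update(g0, data, fed_config(local_epochs = 0), cfg,
                     round_seed = 1)
  expect_identical(flatten_params(e0$params), flatten_params(g0))
  expect_equal(e0$n_samples, 40)

  # scalar-logit limit: W_head = 0 makes p = sigmoid(b_head) = 0.5; one
  # full-batch step on a single z = 1 sample has dL/db = p - 1 = -0.5 and
  # Adam's first step moves b by +lr * g/(|g| + eps)
  pz <- fedherd:::unflatten_params(0 * flatten_params(g0), g0)
  one <- subset_windows(data, which(data$y == 1)[1])
  up <- local_update(pz, one, fed_config(local_epochs = 1, batch_size = 1),
                     cfg, round_seed = 3)
  expect_equal(up$params$b_head, ref_adam_first_step(-0.5, 0.001),
               tolerance = 1e-12)
  expect_gt(up$params$b_head, 0)

  expect_error(local_update(g0, subset_windows(data, integer(0)),
                            fed_config(), cfg, round_seed = 1), "empty")
})

test_that("fedavg reproduces hand-computable weighted means", {
  cfg <- tiny_model_cfg(lstm_hidden = 2)
  mk <- function(val, n, id) {
    p <- init_params(cfg)
    p <- fedherd:::unflatten_params(rep(val, length(flatten_params(p))), p)
    structure(list(client_id = id, params = p, n_samples = n,
                   local_loss_trace = numeric(0)), class = "client_update")
  }
  # identical params are a fixed point
  same <- fedavg(list(mk(1.5, 10, 1), mk(1.5, 3, 2)))
  expect_identical(unique(flatten_params(same)), 1.5)
  # equal weights -> plain mean; weights (1, 3) on values (0, 4) -> 3
  expect_equal(unique(flatten_params(fedavg(list(mk(0, 5, 1),
                                                 mk(2, 5, 2))))), 1)
  expect_equal(unique(flatten_params(fedavg(list(mk(0, 1, 1),
                                                 mk(4, 3, 2))))), 3)
  # errors
  expect_error(fedavg(list()), "update")
  expect_error(fedavg(list(mk(0, 0, 1))), "zero")
  bad <- mk(1, 5, 1)
  bad$params <- init_params(tiny_model_cfg(lstm_hidden = 7))
  expect_error(fedavg(list(mk(0, 5, 2), bad)), "incompatible")
})

test_that("fedavg matches the brute-force mean and its invariants", {
  cfg <- tiny_model_cfg(lstm_hidden = 2, n_features = 2)
  template <- init_params(cfg)
  dim_p <- length(flatten_params(template))
  for (s in 1:40) {
    set.seed(s)
    n_cl <- sample(1:8, 1)
    mats <- lapply(seq_len(n_cl), function(i) runif(dim_p, -5, 5))
    ns <- sample(1:500, n_cl, replace = TRUE)
    ups <- lapply(seq_len(n_cl), function(i) {
      structure(list(client_id = i,
                     params = fedherd:::unflatten_params(mats[[i]], template),
                     n_samples = ns[i], local_loss_trace = numeric(0)),
                class = "client_update")
    })
    got <- unname(flatten_params(fedavg(ups)))
    expect_equal(got, ref_weighted_mean(mats, ns), tolerance = 1e-12)
    # convex hull, coordinate-wise
    M <- do.call(rbind, mats)
    expect_true(all(got >= apply(M, 2, min) - 1e-12 &
                      got <= apply(M, 2, max) + 1e-12))
    # aggregation weights sum to one
    expect_equal(sum(ns / sum(ns)), 1, tolerance = 1e-12)
    # permutation invariance, bit for bit
    expect_identical(unname(flatten_params(fedavg(ups[sample(n_cl)]))), got)
  }
})

test_that("a dominant client pins the aggregate to its own update", {
  cfg <- tiny_model_cfg(lstm_hidden = 2)
  template <- init_params(cfg)
  dim_p <- length(flatten_params(template))
  set.seed(7)
  big <- runif(dim_p)
  small <- runif(dim_p, -1, 1)
  ups <- list(
    structure(list(client_id = 1,
                   params = fedherd:::unflatten_params(big, template),
                   n_samples = 999900, local_loss_trace = numeric(0)),
              class = "client_update"),
    structure(list(client_id = 2,
                   params = fedherd:::unflatten_params(small, template),
                   n_samples = 100, local_loss_trace = numeric(0)),
              class = "client_update")
  )
  expect_lt(max(abs(flatten_params(fedavg(ups)) - big)), 1e-3)
})

test_that("one-client federated training equals centralized, bit for bit", {
  cfg <- tiny_model_cfg()
  data <- toy_windows(n = 60)
  fc <- fed_config(n_clients = 1, rounds = 1, local_epochs = 5, seed = 17)
  fed <- run_federated(list(data), fc, cfg)
  cen <- run_centralized(data, fc, cfg, epochs = 5,
                         train_seed = sub_seed(17, "round", 1, "client", 1))
  expect_identical(flatten_params(fed$params), flatten_params(cen$params))

  # and with a single round of one epoch
  fc1 <- fed_config(n_clients = 1, rounds = 1, local_epochs = 1, seed = 4)
  fed1 <- run_federated(list(data), fc1, cfg)
  cen1 <- run_centralized(data, fc1, cfg, epochs = 1,
                          train_seed = sub_seed(4, "round", 1, "client", 1))
  expect_identical(flatten_params(fed1$params), flatten_params(cen1$params))
})

test_that("federated runs are reproducible and keep full ledgers", {
  cfg <- tiny_model_cfg()
  clients <- lapply(1:3, function(s) toy_windows(n = 30, seed = s))
  fc <- fed_config(n_clients = 3, rounds = 4, local_epochs = 1, seed = 5)
  test <- toy_windows(n = 20, seed = 99)
  a <- run_federated(clients, fc, cfg, test_data = test)
  b <- run_federated(clients, fc, cfg, test_data = test)
  expect_identical(a$history, b$history)
  expect_identical(flatten_params(a$params), flatten_params(b$params))

  payload <- param_size_bytes(init_params(cfg))
  expect_equal(nrow(a$ledger), 4)
  expect_true(all(a$ledger$uplink_bytes == 3 * payload))
  expect_true(all(a$ledger$downlink_bytes == 3 * payload))
  expect_equal(nrow(a$history), 4)
  expect_true(all(is.finite(a$history$global_loss)))

  # partial participation shrinks per-round traffic
  fc_half <- fed_config(n_clients = 3, participation = 2 / 3, rounds = 2,
                        local_epochs = 1, seed = 5)
  h <- run_federated(clients, fc_half, cfg)
  expect_true(all(h$ledger$uplink_bytes == 2 * payload))
})

test_that("centralized training descends on a separable toy problem", {
  cfg <- tiny_model_cfg(lstm_hidden = 4, dense_hidden = 3)
  data <- toy_windows(n = 150)
  fit <- run_centralized(data, fed_config(), cfg, epochs = 3, train_seed = 2)
  tr <- fit$history$mean_client_loss
  expect_length(tr, 3)
  expect_true(all(is.finite(tr)))
  expect_true(all(diff(tr) < 0))
  expect_equal(comms_totals(fit$ledger)$uplink_bytes, 0)
  expect_error(run_centralized(subset_windows(data, integer(0)),
                               fed_config(), cfg), "empty")
})

test_that("empty clients are skipped; all-empty runs abort", {
  cfg <- tiny_model_cfg()
  data <- toy_windows(n = 30)
  none <- subset_windows(data, integer(0))
  expect_error(run_federated(list(none, none), fed_config(n_clients = 2),
                             cfg), "empty")
  fc <- fed_config(n_clients = 2, rounds = 2, local_epochs = 1, seed = 1)
  expect_warning(fit <- run_federated(list(data, none), fc, cfg), "empty")
  expect_true(all(fit$ledger$uplink_bytes ==
                    param_size_bytes(init_params(cfg))))
})

test_that("the communication ledger reproduces the analytic totals", {
  # 10 clients x 50 rounds x 1 MB updates = 500 MB uplink (and downlink)
  led <- comms_ledger(50, 10, 2^20)
  tot <- comms_totals(led)
  expect_identical(tot$uplink_mb, 500)
  expect_identical(tot$downlink_mb, 500)
  # 0 rounds -> 0 bytes; 50% participation halves the traffic
  expect_identical(comms_totals(comms_ledger(0, 10, 2^20))$uplink_bytes, 0)
  expect_identical(comms_totals(comms_ledger(50, 5, 2^20))$uplink_mb, 250)
})
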