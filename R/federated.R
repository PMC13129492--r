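#' Federated training configuration
#'
#' Defaults mirror the reference deployment: 10 simulated edge clients,
#' 100% participation, 50 communication rounds of 5 local epochs each,
#' batch size 32, Adam at learning rate 0.001, binary cross-entropy loss,
#' FedAvg aggregation.
#'
#' @param n_clients number of federated clients.
#' @param participation fraction of clients sampled per round, in (0, 1].
#' @param rounds number of communication rounds T.
#' @param local_epochs local epochs E per round.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is implemented.
#' @param loss only `"bce"` (binary cross-entropy) is implemented.
#' @param seed seed controlling client sampling and per-round batching.
#' @return an object of class `fed_config`.
#' @export
fed_config <- function(n_clients = 10,
                       participation = 1.0,
                       rounds = 50,
                       local_epochs = 5,
                       batch_size = 32,
                       learning_rate = 0.001,
                       optimizer = "adam",
                       loss = "bce",
                       seed = 1) {
  if (participation <= 0 || participation > 1) {
    stop_config("'participation' must lie in (0, 1]")
  }
  if (!identical(optimizer, "adam")) {
    stop_config("only the 'adam' optimizer is implemented")
  }
  if (!identical(loss, "bce")) {
    stop_config("only the 'bce' loss is implemented")
  }
  structure(list(
    n_clients = check_count(n_clients, "n_clients"),
    participation = participation,
    rounds = check_count(rounds, "rounds"),
    local_epochs = check_count(local_epochs, "local_epochs", min = 0),
    batch_size = check_count(batch_size, "batch_size"),
    learning_rate = learning_rate,
    optimizer = optimizer,
    loss = loss,
    seed = as.integer(seed)
  ), class = "fed_config")
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(a) { z <- a; z[] <- 0; z })
  list(m = zeros, v = zeros, t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- state$beta1 * state$m[[nm]] +
      (1 - state$beta1) * grads[[nm]]
    state$v[[nm]] <- state$beta2 * state$v[[nm]] +
      (1 - state$beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(params = params, state = state)
}

# Seeded mini-batch Adam on binary cross-entropy: the shared training loop
# behind both a client's local update and the centralized baseline, so the
# single-client limit is bit-identical by construction.
sgd_train <- function(params, data, epochs, batch_size, lr, seed) {
  n <- n_windows(data)
  state <- adam_init(params)
  trace <- numeric(0)
  if (epochs == 0 || n == 0) {
    return(list(params = params, trace = trace))
  }
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        lg <- loss_and_grad(params, data$x[idx, , , drop = FALSE],
                            data$y[idx], attr(data, "model_cfg"))
        st <- adam_step(params, lg$grads, state, lr)
        params <- st$params
        state <- st$state
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      trace <- c(trace, ep_loss / n)
    }
  })
  list(params = params, trace = trace)
}

train_with_cfg <- function(params, data, epochs, fed_cfg, model_cfg, seed) {
  attr(data, "model_cfg") <- model_cfg
  sgd_train(params, data, epochs, fed_cfg$batch_size,
            fed_cfg$learning_rate, seed)
}

#' One client's local training pass
#'
#' Copies the broadcast global parameters, runs `local_epochs` epochs of
#' seeded mini-batch Adam on binary cross-entropy over the client's
#' windows, with a fresh optimizer state each round (clients are
#' stateless between rounds), and returns the trained parameters together
#' with the client's sample count — the FedAvg aggregation weight.
#'
#' @param global_params the broadcast `param_vector`.
#' @param client_data the client's `windowed_dataset` (non-empty).
#' @param fed_cfg a [fed_config()].
#' @param model_cfg the [model_config()].
#' @param round_seed seed for this client's batching this round.
#' @param client_id identifier recorded in the update.
#' @return a `client_update`: list with `client_id`, `params`,
#'   `n_samples`, `local_loss_trace`.
#' @export
local_update <- function(global_params, client_data, fed_cfg, model_cfg,
                         round_seed, client_id = 1L) {
  if (n_windows(client_data) == 0) {
    stop_data("client dataset is empty")
  }
  tr <- train_with_cfg(global_params, client_data, fed_cfg$local_epochs,
                       fed_cfg, model_cfg, round_seed)
  structure(list(client_id = client_id, params = tr$params,
                 n_samples = n_windows(client_data),
                 local_loss_trace = tr$trace),
            class = "client_update")
}

#' Sample-size-weighted federated averaging
#'
#' The aggregation rule of FedAvg: the next global parameter vector is the
#' element-wise weighted mean of the client updates,
#' `k[t+1] = sum_y (|X_y| / sum_j |X_j|) k_y[t]`, weights summing to one.
#' Updates are folded in client-id-sorted order, so the result is
#' bit-identical under any permutation of the input list.
#'
#' @param updates list of `client_update`s (>= 1, shape-compatible).
#' @return the aggregated `param_vector`.
#' @export
fedavg <- function(updates) {
  if (length(updates) == 0) stop_data("no client updates to aggregate")
  ns <- vapply(updates, function(u) as.numeric(u$n_samples), numeric(1))
  if (sum(ns) <= 0) stop_data("total client sample count is zero")
  ord <- order(vapply(updates, function(u) as.character(u$client_id),
                      character(1)))
  updates <- updates[ord]
  ns <- ns[ord]
  w <- ns / sum(ns)
  for (u in updates[-1]) check_same_shapes(updates[[1]]$params, u$params)
  acc <- updates[[1]]$params * w[1]
  for (j in seq_along(updates)[-1]) {
    acc <- acc + updates[[j]]$params * w[j]
  }
  acc
}

# ---- communication ledger ----------------------------------------------

#' Analytic communication ledger for a federated run
#'
#' Per round, the downlink cost is one broadcast of the global parameters
#' to each participating client and the uplink cost is one update of the
#' same size from each; both are `participants x payload_bytes`. All sizes
#' use the 32-bit deployment wire format. 1 MB = 2^20 bytes throughout.
#'
#' @param rounds number of rounds.
#' @param participants participants per round (scalar or length-`rounds`).
#' @param payload_bytes serialized model size in bytes.
#' @return a `comms_ledger`: data frame `round, uplink_bytes,
#'   downlink_bytes`.
#' @export
comms_ledger <- function(rounds, participants, payload_bytes) {
  participants <- rep_len(participants, rounds)
  structure(data.frame(
    round = seq_len(rounds),
    uplink_bytes = participants * payload_bytes,
    downlink_bytes = participants * payload_bytes
  ), class = c("comms_ledger", "data.frame"))
}

#' Total traffic of a communication ledger
#'
#' @param ledger a `comms_ledger`.
#' @return list with totals in bytes and MB (1 MB = 2^20 bytes).
#' @export
comms_totals <- function(ledger) {
  up <- sum(ledger$uplink_bytes)
  down <- sum(ledger$downlink_bytes)
  list(uplink_bytes = up, downlink_bytes = down,
       uplink_mb = up / 2^20, downlink_mb = down / 2^20)
}

# ---- run orchestration --------------------------------------------------

evaluate_round <- function(params, test_data, model_cfg) {
  if (is.null(test_data) || n_windows(test_data) == 0) {
    return(c(loss = NA_real_, accuracy = NA_real_))
  }
  p <- nn_forward(params, test_data$x, model_cfg)
  c(loss = bce(p, test_data$y),
    accuracy = mean((p > 0.5) == (test_data$y == 1)))
}

#' Train the stress classifier by federated averaging
#'
#' Runs the full federated procedure: initialize the global model; then for
#' each communication round, sample the participating clients (without
#' replacement, seeded), broadcast the global parameters, run each
#' client's local update, aggregate by [fedavg()], evaluate on the
#' held-out set and append a communication-ledger entry. Identical
#' configurations and seeds reproduce the run bit-for-bit on one platform.
#'
#' @param clients list of `windowed_dataset`s, one per client; empty
#'   clients are skipped with a warning.
#' @param fed_cfg a [fed_config()] (its `n_clients` must match
#'   `length(clients)`).
#' @param model_cfg a [model_config()].
#' @param test_data optional held-out `windowed_dataset` for per-round
#'   validation.
#' @return an object of class `fedherd_fit`.
#' @export
run_federated <- function(clients, fed_cfg, model_cfg, test_data = NULL) {
  sizes <- vapply(clients, n_windows, numeric(1))
  if (all(sizes == 0)) stop_data("all clients are empty")
  if (any(sizes == 0)) {
    warning(sprintf("%d empty client(s) will never be sampled",
                    sum(sizes == 0)))
  }
  n_clients <- length(clients)
  params <- init_params(model_cfg)
  payload <- param_size_bytes(params)
  n_part <- ceiling(fed_cfg$participation * n_clients)
  history <- vector("list", fed_cfg$rounds)
  ledger_rows <- numeric(fed_cfg$rounds)
  nonempty <- which(sizes > 0)

  for (t in seq_len(fed_cfg$rounds)) {
    part <- with_seed(sub_seed(fed_cfg$seed, "participants", t), {
      pool <- nonempty
      pool[sample.int(length(pool), min(n_part, length(pool)))]
    })
    updates <- lapply(part, function(y) {
      local_update(params, clients[[y]], fed_cfg, model_cfg,
                   round_seed = sub_seed(fed_cfg$seed, "round", t,
                                         "client", y),
                   client_id = y)
    })
    params <- fedavg(updates)
    ev <- evaluate_round(params, test_data, model_cfg)
    history[[t]] <- data.frame(
      round = t,
      global_loss = ev[["loss"]],
      global_accuracy = ev[["accuracy"]],
      mean_client_loss = mean(vapply(updates, function(u) {
        if (length(u$local_loss_trace)) utils::tail(u$local_loss_trace, 1)
        else NA_real_
      }, numeric(1)))
    )
    ledger_rows[t] <- length(part)
  }
  ledger <- comms_ledger(fed_cfg$rounds, ledger_rows, payload)
  structure(list(
    params = params,
    history = do.call(rbind, history),
    ledger = ledger,
    fed_cfg = fed_cfg,
    model_cfg = model_cfg,
    client_sizes = sizes,
    arm = "federated",
    seed = fed_cfg$seed
  ), class = "fedherd_fit")
}

#' Train the centralized baseline on pooled data
#'
#' The comparison arm: the same model and optimizer trained on all windows
#' pooled in one place, by default for `rounds x local_epochs` epochs so
#' the optimization budget matches the federated run. Its communication
#' ledger is empty — no federated traffic.
#'
#' @param pooled a non-empty `windowed_dataset`.
#' @param fed_cfg a [fed_config()] supplying the optimizer settings.
#' @param model_cfg a [model_config()].
#' @param epochs training epochs (default `rounds * local_epochs`).
#' @param train_seed batching seed (default derived from the federated
#'   seed).
#' @param test_data optional held-out set, evaluated once per epoch.
#' @return an object of class `fedherd_fit`.
#' @export
run_centralized <- function(pooled, fed_cfg, model_cfg,
                            epochs = fed_cfg$rounds * fed_cfg$local_epochs,
                            train_seed = sub_seed(fed_cfg$seed,
                                                  "centralized"),
                            test_data = NULL) {
  if (n_windows(pooled) == 0) stop_data("pooled dataset is empty")
  params <- init_params(model_cfg)
  tr <- train_with_cfg(params, pooled, epochs, fed_cfg, model_cfg,
                       train_seed)
  ev <- evaluate_round(tr$params, test_data, model_cfg)
  history <- data.frame(
    round = seq_along(tr$trace),
    global_loss = NA_real_,
    global_accuracy = NA_real_,
    mean_client_loss = tr$trace
  )
  if (nrow(history)) {
    history$global_loss[nrow(history)] <- ev[["loss"]]
    history$global_accuracy[nrow(history)] <- ev[["accuracy"]]
  }
  structure(list(
    params = tr$params,
    history = history,
    ledger = comms_ledger(0, integer(0), 0),
    fed_cfg = fed_cfg,
    model_cfg = model_cfg,
    client_sizes = n_windows(pooled),
    arm = "centralized",
    seed = train_seed
  ), class = "fedherd_fit")
}
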