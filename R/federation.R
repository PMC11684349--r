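# Federated orchestration: client partitioning (IID / Dirichlet label-skew),
# FedAvg aggregation, round loop with one local epoch per round, optional
# DP perturbation of the uploaded update, and a centralized reference trainer
# that shares the same epoch machinery.

#' Federation configuration
#'
#' @param K Number of participating clients per round.
#' @param rounds Number of communication rounds T (the architecture default
#'   elsewhere is 40; experiments here typically use fewer).
#' @param local_epochs Local epochs per round (default 1).
#' @param lr SGD learning rate (default 5e-4).
#' @param mu_prox Proximal coefficient tying local weights to the broadcast
#'   global model (default 0, plain FedAvg).
#' @param batch_size Minibatch size (default 32).
#' @param scheme Client split: `iid` (uniform without replacement) or
#'   `dirichlet` (symmetric Dirichlet label skew over identity labels).
#' @param alpha Dirichlet concentration (> 0); small = more skew.
#' @param D_i Per-client shard size (equal across clients). `NULL` uses
#'   `floor(n / K)`.
#' @param N_total Total enrolled clients N (>= K); when `N_total > K`, K of
#'   them are drawn uniformly each round, giving sampling fraction
#'   `q = K / N_total`.
#' @param val_fraction Fraction of each shard held out locally for
#'   validation / early stopping (default 0.2).
#' @param patience Early-stopping patience in rounds on pooled validation
#'   total loss (default 5); the best-validation model is returned when
#'   finite. `Inf` disables early stopping and returns the final round.
#' @param standardize Z-score features (statistics from the training pool)
#'   before training; the scaler is stored in the returned model.
#' @return An `fl_config` object.
#' @export
fl_config <- function(K = 5L, rounds = 40L, local_epochs = 1L, lr = 5e-4,
                      mu_prox = 0, batch_size = 32L,
                      scheme = c("iid", "dirichlet"), alpha = 0.5,
                      D_i = NULL, N_total = NULL, val_fraction = 0.2,
                      patience = 5L, standardize = TRUE) {
  scheme <- match.arg(scheme)
  if (K < 1) stop_fs("invalid_argument", "K must be >= 1")
  if (alpha <= 0) stop_fs("invalid_argument", "alpha must be > 0")
  if (!is.null(N_total) && N_total < K) {
    stop_fs("invalid_argument", "N_total must be >= K")
  }
  structure(
    list(K = as.integer(K), rounds = as.integer(rounds),
         local_epochs = as.integer(local_epochs), lr = lr, mu_prox = mu_prox,
         batch_size = as.integer(batch_size), scheme = scheme, alpha = alpha,
         D_i = D_i, N_total = if (is.null(N_total)) as.integer(K) else as.integer(N_total),
         val_fraction = val_fraction, patience = patience,
         standardize = standardize),
    class = "fl_config"
  )
}

#' @export
print.fl_config <- function(x, ...) {
  cat(sprintf("<fl_config> K=%d, rounds=%d, lr=%g, scheme=%s\n",
              x$K, x$rounds, x$lr, x$scheme))
  invisible(x)
}

#' Partition a dataset into client shards
#'
#' `iid`: a uniform draw without replacement of `K * D_i` examples split into
#' equal shards. `dirichlet`: each client's identity-label proportions are
#' drawn from a symmetric Dirichlet(`alpha`); examples are then drawn per
#' class without replacement and shards are rebalanced to exactly `D_i`
#' examples each (classes with exhausted pools donate to whatever remains),
#' preserving equal client sizes. Shard index vectors are sorted, and the
#' whole procedure is deterministic in `seed`.
#'
#' @param dataset A `feature_dataset`.
#' @param K Number of clients.
#' @param scheme `iid` or `dirichlet`.
#' @param alpha Dirichlet concentration.
#' @param D_i Shard size; default `floor(n / K)`.
#' @param seed Integer seed.
#' @return List of `client_split`s: `list(client_id, idx, size)` with
#'   pairwise-disjoint sorted `idx` of length `D_i`.
#' @export
partition_clients <- function(dataset, K, scheme = c("iid", "dirichlet"),
                              alpha = 0.5, D_i = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(dataset$x)
  if (is.null(D_i)) D_i <- n %/% K
  D_i <- as.integer(D_i)
  if (K * D_i > n) {
    stop_fs("insufficient_data", "K * D_i = %d exceeds dataset size %d",
            K * D_i, n)
  }
  with_seed(seed, {
    if (scheme == "iid") {
      perm <- sample.int(n)[seq_len(K * D_i)]
      splits <- split(perm, rep(seq_len(K), each = D_i))
    } else {
      y <- dataset$identity
      classes <- sort(unique(y))
      pools <- lapply(classes, function(cl) sample(which(y == cl)))
      names(pools) <- as.character(classes)
      props <- matrix(stats::rgamma(K * length(classes), shape = alpha), K)
      props <- props / rowSums(props)
      splits <- vector("list", K)
      for (u in seq_len(K)) {
        want <- floor(props[u, ] * D_i)
        # distribute the remainder to the largest fractional parts
        rem <- D_i - sum(want)
        if (rem > 0) {
          fr <- props[u, ] * D_i - want
          want[order(fr, decreasing = TRUE)[seq_len(rem)]] <-
            want[order(fr, decreasing = TRUE)[seq_len(rem)]] + 1L
        }
        take <- integer(0)
        deficit <- 0L
        for (ci in seq_along(classes)) {
          avail <- length(pools[[ci]])
          got <- min(want[ci], avail)
          if (got > 0) {
            take <- c(take, pools[[ci]][seq_len(got)])
            pools[[ci]] <- pools[[ci]][-seq_len(got)]
          }
          deficit <- deficit + want[ci] - got
        }
        while (deficit > 0L) {
          sizes <- lengths(pools)
          ci <- which.max(sizes)
          got <- min(deficit, sizes[ci])
          take <- c(take, pools[[ci]][seq_len(got)])
          pools[[ci]] <- pools[[ci]][-seq_len(got)]
          deficit <- deficit - got
        }
        splits[[u]] <- take
      }
    }
    lapply(seq_len(K), function(u) {
      structure(list(client_id = u, idx = sort(splits[[u]]), size = D_i),
                class = "client_split")
    })
  })
}

#' FedAvg weighted aggregation
#'
#' Every parameter of the returned model is the dataset-size-weighted mean
#' `sum_i p_i w_i` with `p_i = D_i / sum(D)` over clients, computed exactly
#' per coordinate.
#'
#' @param client_params List of structurally identical `model_params`.
#' @param client_sizes Positive client dataset sizes (weights).
#' @return Aggregated `model_params` (attributes inherited from the first
#'   client).
#' @export
fedavg_aggregate <- function(client_params, client_sizes) {
  stopifnot(length(client_params) >= 1L,
            length(client_params) == length(client_sizes))
  if (any(client_sizes <= 0)) stop_fs("invalid_argument", "sizes must be > 0")
  ref <- names(client_params[[1]])
  for (cp in client_params) {
    if (!identical(names(cp), ref) ||
        !all(vapply(ref, function(ln) {
          identical(dim(cp[[ln]]$W), dim(client_params[[1]][[ln]]$W)) &&
            length(cp[[ln]]$b) == length(client_params[[1]][[ln]]$b)
        }, logical(1)))) {
      stop_fs("aggregation_error", "client parameter structures differ")
    }
  }
  p <- client_sizes / sum(client_sizes)
  out <- params_scale(client_params[[1]], p[1])
  for (i in seq_along(client_params)[-1]) {
    out <- params_map2(out, client_params[[i]], function(a, b) a + p[i] * b)
  }
  out
}

# standardize features; returns list(x, scaler)
standardize_features <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       scaler = list(center = center, scale = scale))
}

# 80/20-style split of an index vector, deterministic in seed; returns
# list(train, val), both sorted
split_train_val <- function(idx, val_fraction, seed) {
  m <- as.integer(floor(length(idx) * val_fraction))
  if (m == 0L) return(list(train = sort(idx), val = integer(0)))
  perm <- with_seed(seed, sample.int(length(idx)))
  list(train = sort(idx[perm[-seq_len(m)]]), val = sort(idx[perm[seq_len(m)]]))
}

# accuracy + mean losses of a parameter set on rows idx
eval_params <- function(params, x, ys, yi, idx) {
  if (length(idx) == 0L) return(NULL)
  fw <- forward(params, x[idx, , drop = FALSE])
  loss <- multitask_loss(fw$stress, fw$identity, ys[idx], yi[idx])
  list(
    acc_stress = mean(max.col(fw$stress, ties.method = "first") - 1L == ys[idx]),
    acc_identity = mean(max.col(fw$identity, ties.method = "first") - 1L == yi[idx]),
    loss_stress = loss$loss_stress, loss_identity = loss$loss_identity,
    loss_total = loss$total
  )
}

#' Run federated multitask training
#'
#' Executes `rounds` communication rounds: the server broadcasts the global
#' model; each participating client runs `local_epochs` epochs of proximal
#' minibatch SGD on its shard's training part; the client's update (delta to
#' the broadcast model) is optionally clipped and perturbed under the DP
#' configuration; the server applies the dataset-size-weighted FedAvg mean of
#' the updates. Per-round accuracies and losses on the pooled client training
#' and validation sets are logged. All randomness (partition, validation
#' splits, batch order, client sampling, DP noise) derives from `seed`, so a
#' run is bit-reproducible.
#'
#' @param dataset A `feature_dataset`.
#' @param config An [fl_config()].
#' @param dp An optional [dp_config()] (`NULL` or mechanism `none` = no DP).
#' @param seed Integer seed.
#' @return List with `params` (final global `model_params`, carrying the
#'   feature scaler used), `history` (one data frame row per round, task,
#'   split and metric, plus a per-round global parameter checksum),
#'   `partition` (client splits), `val_idx` (pooled held-out indices),
#'   `config`, `dp`, `seed`, and `stopped_round` when early stopping
#'   triggered.
#' @export
run_training <- function(dataset, config = fl_config(), dp = NULL, seed = 1L) {
  n <- nrow(dataset$x)
  K <- config$K
  splits <- partition_clients(dataset, K, config$scheme, config$alpha,
                              config$D_i, seed = derive_seed(seed, 1L))
  x <- dataset$x
  scaler <- NULL
  if (isTRUE(config$standardize)) {
    st <- standardize_features(x)
    x <- st$x
    scaler <- st$scaler
  }
  ys <- dataset$stress
  yi <- dataset$identity

  tv <- lapply(splits, function(sp) {
    split_train_val(sp$idx, config$val_fraction,
                    derive_seed(seed, 2L, sp$client_id))
  })
  train_idx <- lapply(tv, `[[`, "train")
  val_pool <- sort(unlist(lapply(tv, `[[`, "val")))
  train_pool <- sort(unlist(train_idx))
  train_sizes <- lengths(train_idx)
  # per-round train metrics are computed on an evenly spaced subsample so
  # logging stays cheap on large shards
  train_eval_idx <- if (length(train_pool) > 1024L) {
    train_pool[as.integer(seq(1L, length(train_pool), length.out = 1024L))]
  } else train_pool

  global <- build_model(ncol(x), dataset$n_subjects,
                        seed = derive_seed(seed, 0L))
  # gaussian_fixed at sigma = 0 is the null perturbation: skip the delta
  # round-trip entirely so the run is bit-identical to the no-DP path
  use_dp <- !is.null(dp) && dp$mechanism != "none" &&
    !(dp$mechanism == "gaussian_fixed" && dp$sigma == 0)

  hist_list <- list()
  best <- list(loss = Inf, params = global, round = 0L)
  since_best <- 0L
  stopped_round <- NA_integer_

  for (t in seq_len(config$rounds)) {
    active <- seq_len(K)
    if (config$N_total > K) {
      # q = K / N client sampling: which of the N enrolled slots train this
      # round; the K shards stand in for the sampled clients
      active <- with_seed(derive_seed(seed, 3L, t),
                          sort(sample.int(config$N_total, K)))
      active <- ((active - 1L) %% K) + 1L
    }
    client_models <- vector("list", length(active))
    for (j in seq_along(active)) {
      u <- active[j]
      local <- global
      for (e in seq_len(config$local_epochs)) {
        local <- run_local_epoch(
          local, global, x, ys, yi, train_idx[[u]],
          config$batch_size, config$lr, config$mu_prox,
          seed = derive_seed(seed, 100L + t, u * 101L + e))
      }
      if (use_dp) {
        dp_seed <- derive_seed(seed, 200000L + t, u)
        if (dp$noise_target == "weights") {
          # client-level scheme: the scoped layers of the trained local model
          # are norm-clipped and noised before upload
          local <- perturb(local, attr(global, "scopes"), dp,
                           U_i = train_sizes[u], seed = dp_seed)$delta
        } else {
          # update-space scheme: clip and noise the delta to the broadcast
          # model, then reattach it for aggregation
          delta <- params_sub(local, global)
          delta <- perturb(delta, attr(global, "scopes"), dp,
                           U_i = train_sizes[u], seed = dp_seed)$delta
          local <- params_add(global, delta)
        }
      }
      client_models[[j]] <- local
    }
    global <- fedavg_aggregate(client_models, train_sizes[active])

    ev_tr <- eval_params(global, x, ys, yi, train_eval_idx)
    ev_va <- eval_params(global, x, ys, yi, val_pool)
    if (!is.null(ev_tr) && !is.finite(ev_tr$loss_total)) {
      stop_fs("divergence", "non-finite loss at round %d", t)
    }
    hist_list[[t]] <- make_history_rows(t, ev_tr, ev_va, params_checksum(global))

    if (!is.null(ev_va)) {
      if (ev_va$loss_total < best$loss) {
        best <- list(loss = ev_va$loss_total, params = global, round = t)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) { stopped_round <- t; break }
      }
    }
  }

  final <- if (is.finite(config$patience) && best$round > 0L) best$params else global
  attr(final, "meta")$scaler <- scaler
  history <- do.call(rbind, hist_list)
  list(params = final, history = history, partition = splits,
       val_idx = val_pool, config = config, dp = dp, seed = seed,
       stopped_round = stopped_round)
}

make_history_rows <- function(round, ev_tr, ev_va, checksum) {
  row <- function(split, ev) {
    if (is.null(ev)) return(NULL)
    data.frame(round = round,
               task = c("stress", "identity", "stress", "identity", "total"),
               split = split,
               metric = c("accuracy", "accuracy", "loss", "loss", "loss"),
               value = c(ev$acc_stress, ev$acc_identity, ev$loss_stress,
                         ev$loss_identity, ev$loss_total))
  }
  rbind(row("train", ev_tr), row("val", ev_va),
        data.frame(round = round, task = "model", split = "global",
                   metric = "checksum", value = checksum))
}

#' Centralized reference trainer
#'
#' Trains the same multitask model on the pooled dataset with plain minibatch
#' SGD (the `mu_prox = 0` degenerate of the local objective), using the same
#' seed-derivation, validation-split and epoch machinery as the federated
#' path. A federated run with `K = 1`, full participation, no DP and
#' `D_i = n` is bit-identical to this trainer at equal seed.
#'
#' @param dataset A `feature_dataset`.
#' @param config An [fl_config()]; `rounds` is the number of epochs, the
#'   partition fields are ignored.
#' @param seed Integer seed.
#' @return Same shape as [run_training()] (without `partition`).
#' @export
train_centralized <- function(dataset, config = fl_config(), seed = 1L) {
  n <- nrow(dataset$x)
  x <- dataset$x
  scaler <- NULL
  if (isTRUE(config$standardize)) {
    st <- standardize_features(x)
    x <- st$x
    scaler <- st$scaler
  }
  ys <- dataset$stress
  yi <- dataset$identity
  tv <- split_train_val(seq_len(n), config$val_fraction,
                        derive_seed(seed, 2L, 1L))
  train_eval_idx <- if (length(tv$train) > 1024L) {
    tv$train[as.integer(seq(1L, length(tv$train), length.out = 1024L))]
  } else tv$train
  params <- build_model(ncol(x), dataset$n_subjects,
                        seed = derive_seed(seed, 0L))

  hist_list <- list()
  best <- list(loss = Inf, params = params, round = 0L)
  since_best <- 0L
  stopped_round <- NA_integer_
  for (t in seq_len(config$rounds)) {
    params <- run_local_epoch(params, params, x, ys, yi, tv$train,
                              config$batch_size, config$lr, 0,
                              seed = derive_seed(seed, 100L + t, 102L))
    ev_tr <- eval_params(params, x, ys, yi, train_eval_idx)
    ev_va <- eval_params(params, x, ys, yi, tv$val)
    if (!is.finite(ev_tr$loss_total)) {
      stop_fs("divergence", "non-finite loss at epoch %d", t)
    }
    hist_list[[t]] <- make_history_rows(t, ev_tr, ev_va, params_checksum(params))
    if (!is.null(ev_va)) {
      if (ev_va$loss_total < best$loss) {
        best <- list(loss = ev_va$loss_total, params = params, round = t)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) { stopped_round <- t; break }
      }
    }
  }
  final <- if (is.finite(config$patience) && best$round > 0L) best$params else params
  attr(final, "meta")$scaler <- scaler
  list(params = final, history = do.call(rbind, hist_list),
       val_idx = tv$val, config = config, dp = NULL, seed = seed,
       stopped_round = stopped_round)
}

#' Write a round history as JSON lines
#'
#' One JSON object per data-frame row (`round, task, split, metric, value`),
#' with the run's resolved configuration echoed in a leading `config` record
#' for provenance.
#'
#' @param run A result of [run_training()] or [train_centralized()].
#' @param path Output file.
#' @export
write_history_jsonl <- function(run, path) {
  con <- file(path, open = "wb")
  cfg <- list(type = "config", config = unclass(run$config),
              dp = if (!is.null(run$dp)) unclass(run$dp) else NULL,
              seed = run$seed)
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, null = "null")),
             con, sep = "\n")
  for (i in seq_len(nrow(run$history))) {
    writeLines(as.character(jsonlite::toJSON(as.list(run$history[i, ]),
                                             auto_unbox = TRUE, digits = NA)),
               con, sep = "\n")
  }
  close(con)
  invisible(path)
}
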