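# Multitask 1D-CNN: shared convolutional trunk -> binary stress head and
# subject-identity branch. The forward/backward passes are written directly
# in vectorised base R (im2col + BLAS matrix products); the network is small
# enough that this trains in seconds on one core.
#
# Architecture (input = feature vector of width n_features, 1 channel):
#   conv1 1->20, k=8, stride 1, zero padding (length preserved); ReLU; maxpool s=2
#   conv2 20->40, k=8, same; ReLU; maxpool s=2
#   conv3 40->60, k=8, same; ReLU; maxpool s=2
#   flatten -> fc1 -> 100 (ReLU)      [shared; feeds both heads]
#   stress_head: 100 -> 2, linear     [stress-specific]
#   fc2: 100 -> 300 (ReLU)            [identity-specific]
#   identity_head: 300 -> N, linear   [identity-specific]
#
# Layer scopes partition the parameters for selective DP perturbation:
# conv1-3 and fc1 are `shared`, the stress head is `stress_specific`, fc2 and
# the identity head are `identity_specific`.

FS_SCOPES <- c(conv1 = "shared", conv2 = "shared", conv3 = "shared",
               fc1 = "shared", stress_head = "stress_specific",
               fc2 = "identity_specific", identity_head = "identity_specific")

#' Build and initialise the multitask 1D-CNN
#'
#' Convolutions use kernel 8, stride 1 and asymmetric zero padding (3 left,
#' 4 right) so they preserve length; each stride-2 max pool halves it
#' (`floor(L/2)`). After three conv+pool stages an input of width `n`
#' flattens to `60 * floor(floor(floor(n/2)/2)/2)` units (e.g. width 48 ->
#' 360). Weights are He-normal initialised (`sd = sqrt(2 / fan_in)`), biases
#' zero, deterministically from `seed`.
#'
#' @param n_features Input width (>= 8 so one kernel fits and three pooling
#'   stages leave at least one unit).
#' @param n_subjects Number of enrolled subjects N (>= 2); width of the
#'   identity head.
#' @param seed Integer seed for the initialisation.
#' @param channels Conv channel widths (defaults 20, 40, 60).
#' @param kernel Conv kernel size.
#' @param fc1_width,fc2_width Widths of the two fully connected layers.
#' @return A `model_params` object: named list of layers (each `list(W, b)`;
#'   conv weights stored as `(kernel * C_in) x C_out` matrices), with
#'   attributes `scopes` (layer -> scope) and `meta` (dimension bookkeeping).
#' @export
#' @examples
#' p <- build_model(48, n_subjects = 15, seed = 1)
#' attr(p, "meta")$flat_width  # 360
build_model <- function(n_features, n_subjects, seed = 1L,
                        channels = c(20L, 40L, 60L), kernel = 8L,
                        fc1_width = 100L, fc2_width = 300L) {
  n_features <- as.integer(n_features)
  if (n_subjects < 2) stop_fs("invalid_argument", "n_subjects must be >= 2")
  L1 <- n_features %/% 2L; L2 <- L1 %/% 2L; L3 <- L2 %/% 2L
  if (n_features < kernel || L3 < 1L) {
    stop_fs("invalid_architecture",
            "n_features = %d too small for kernel %d and three pooling stages",
            n_features, kernel)
  }
  flat <- channels[3] * L3

  he <- function(fan_in, nrow, ncol) {
    matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
  }
  params <- with_seed(seed, list(
    conv1 = list(W = he(kernel * 1, kernel * 1, channels[1]),
                 b = numeric(channels[1])),
    conv2 = list(W = he(kernel * channels[1], kernel * channels[1], channels[2]),
                 b = numeric(channels[2])),
    conv3 = list(W = he(kernel * channels[2], kernel * channels[2], channels[3]),
                 b = numeric(channels[3])),
    fc1 = list(W = he(flat, flat, fc1_width), b = numeric(fc1_width)),
    stress_head = list(W = he(fc1_width, fc1_width, 2L), b = numeric(2L)),
    fc2 = list(W = he(fc1_width, fc1_width, fc2_width), b = numeric(fc2_width)),
    identity_head = list(W = he(fc2_width, fc2_width, as.integer(n_subjects)),
                         b = numeric(n_subjects))
  ))
  structure(params,
            scopes = FS_SCOPES,
            meta = list(n_features = n_features, n_subjects = as.integer(n_subjects),
                        channels = channels, kernel = as.integer(kernel),
                        pad_left = (kernel - 2L) %/% 2L,
                        pad_right = kernel - 1L - (kernel - 2L) %/% 2L,
                        lengths = c(n_features, L1, L2, L3), flat_width = flat,
                        fc1_width = fc1_width, fc2_width = fc2_width,
                        scaler = NULL),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<model_params> input %d, %d subjects, %d parameters\n",
              meta$n_features, meta$n_subjects, n_params(x)))
  invisible(x)
}

#' Total number of scalar parameters
#' @param params A `model_params`.
#' @return Integer count.
#' @export
n_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

# ---- forward / backward -----------------------------------------------------
#
# Activations flow as (B*L, C) matrices with row index b + B*(t-1); in this
# column-major layout the rows a stride-1 kernel tap touches are one
# contiguous block, which the compiled kernels in src/conv_ops.cpp exploit.
# Reinterpreting (B*L, C) as (B, L*C) is a free `dim<-`, which gives the
# flatten between the conv stack and fc1 (features ordered position-major
# within channel).

#' Forward pass
#'
#' Pure function of `(params, x)`: returns stress logits (2 columns) and
#' identity logits (N columns) for a batch of feature vectors.
#'
#' @param params A `model_params`.
#' @param x Numeric matrix (rows = examples) or a single vector; width must
#'   equal the model's `n_features`.
#' @param cache Keep intermediate activations for a subsequent backward pass.
#' @return List with `stress` and `identity` logit matrices (and `cache` when
#'   requested).
#' @export
forward <- function(params, x, cache = FALSE) {
  meta <- attr(params, "meta")
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != meta$n_features) {
    stop_fs("shape_error", "input width %d != n_features %d",
            ncol(x), meta$n_features)
  }
  B <- nrow(x); k <- meta$kernel
  pl <- meta$pad_left; pr <- meta$pad_right
  cc <- list()

  X <- x
  dim(X) <- c(B * meta$n_features, 1L)
  L <- meta$n_features
  for (i in 1:3) {
    ln <- paste0("conv", i)
    pre <- cpp_conv_fw(X, B, L, params[[ln]]$W, params[[ln]]$b, pl, pr, k)
    Xp <- attr(pre, "Xp")
    attr(pre, "Xp") <- NULL
    R <- pre * (pre > 0)
    mp <- cpp_maxpool_fw(R, B, L)
    if (cache) cc[[ln]] <- list(Xp = Xp, pre = pre,
                                take_first = mp$take_first, L = L)
    X <- mp$out
    L <- L %/% 2L
  }
  flat <- X
  dim(flat) <- c(B, meta$flat_width)

  z1 <- sweep(flat %*% params$fc1$W, 2, params$fc1$b, "+")
  h1 <- z1 * (z1 > 0)
  stress <- sweep(h1 %*% params$stress_head$W, 2, params$stress_head$b, "+")
  z2 <- sweep(h1 %*% params$fc2$W, 2, params$fc2$b, "+")
  h2 <- z2 * (z2 > 0)
  identity <- sweep(h2 %*% params$identity_head$W, 2, params$identity_head$b, "+")

  out <- list(stress = stress, identity = identity)
  if (cache) {
    out$cache <- list(x = x, conv = cc, flat = flat, z1 = z1, h1 = h1,
                      z2 = z2, h2 = h2, B = B)
  }
  out
}

row_max <- function(z) z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]

softmax <- function(z) {
  e <- exp(z - row_max(z))
  e / rowSums(e)
}

# mean softmax cross-entropy and gradient wrt logits (labels 0-based)
ce_loss_grad <- function(logits, labels) {
  n <- nrow(logits)
  if (any(labels < 0 | labels >= ncol(logits))) {
    stop_fs("invalid_label", "label out of range")
  }
  zm <- row_max(logits)
  lse <- zm + log(rowSums(exp(logits - zm)))
  picked <- logits[cbind(seq_len(n), labels + 1L)]
  loss <- mean(lse - picked)
  G <- softmax(logits)
  G[cbind(seq_len(n), labels + 1L)] <- G[cbind(seq_len(n), labels + 1L)] - 1
  list(loss = loss, grad = G / n)
}

#' Multitask loss
#'
#' Mean softmax cross-entropy of each head; the total is their unweighted
#' sum, exactly `loss_stress + loss_identity`.
#'
#' @param stress_logits,identity_logits Logit matrices from [forward()].
#' @param stress_label 0/1 labels; `identity_label` 0-based subject ids.
#' @param identity_label 0-based identity labels.
#' @return List `loss_stress`, `loss_identity`, `total`.
#' @export
multitask_loss <- function(stress_logits, identity_logits,
                           stress_label, identity_label) {
  ls <- ce_loss_grad(stress_logits, stress_label)$loss
  li <- ce_loss_grad(identity_logits, identity_label)$loss
  list(loss_stress = ls, loss_identity = li, total = ls + li)
}

# Full backward pass: returns gradients with the same layer structure as
# params, for the summed multitask loss on the cached batch.
model_gradients <- function(params, fw, stress_label, identity_label) {
  meta <- attr(params, "meta")
  cc <- fw$cache
  gs <- ce_loss_grad(fw$stress, stress_label)
  gi <- ce_loss_grad(fw$identity, identity_label)

  grads <- list()
  # identity branch
  grads$identity_head <- list(W = crossprod(cc$h2, gi$grad), b = colSums(gi$grad))
  dh2 <- gi$grad %*% t(params$identity_head$W)
  dz2 <- dh2 * (cc$z2 > 0)
  grads$fc2 <- list(W = crossprod(cc$h1, dz2), b = colSums(dz2))
  # stress head
  grads$stress_head <- list(W = crossprod(cc$h1, gs$grad), b = colSums(gs$grad))
  # into shared fc1: both heads contribute
  dh1 <- gs$grad %*% t(params$stress_head$W) + dz2 %*% t(params$fc2$W)
  dz1 <- dh1 * (cc$z1 > 0)
  grads$fc1 <- list(W = crossprod(cc$flat, dz1), b = colSums(dz1))
  dflat <- dz1 %*% t(params$fc1$W)

  B <- cc$B; k <- meta$kernel
  L3 <- meta$lengths[4]
  dX <- dflat
  dim(dX) <- c(B * L3, meta$channels[3])
  for (i in 3:1) {
    ln <- paste0("conv", i)
    conv_c <- cc$conv[[ln]]
    dR <- cpp_maxpool_bw(dX, conv_c$take_first, B, conv_c$L)
    dPre <- dR * (conv_c$pre > 0)
    bw <- cpp_conv_bw(dPre, conv_c$Xp, params[[ln]]$W, B, conv_c$L,
                      meta$pad_left, meta$pad_right, k)
    grads[[ln]] <- list(W = bw$dW, b = bw$db)
    dX <- bw$dX
  }
  grads[names(params)]
}

# loss + gradients on one batch, the unit the trainers consume
loss_and_grads <- function(params, x, stress_label, identity_label) {
  fw <- forward(params, x, cache = TRUE)
  loss <- multitask_loss(fw$stress, fw$identity, stress_label, identity_label)
  grads <- model_gradients(params, fw, stress_label, identity_label)
  list(loss = loss, grads = grads)
}

#' One proximal SGD step on a batch
#'
#' Updates every parameter as
#' `w <- w - lr * (grad_w + mu_prox * (w - w_global))`, i.e. one SGD step on
#' the local objective `F(w) + (mu_prox / 2) * ||w - w_global||^2`. With
#' `mu_prox = 0` this is plain SGD and `global_params` is ignored.
#'
#' @param params Current local `model_params`.
#' @param global_params The last broadcast global model (anchor of the
#'   proximal term).
#' @param batch List with `x` (matrix), `stress`, `identity` (labels).
#' @param lr Learning rate (> 0); the architecture default is 5e-4.
#' @param mu_prox Proximal coefficient (>= 0).
#' @return Updated `model_params`.
#' @export
local_train_step <- function(params, global_params, batch, lr = 5e-4,
                             mu_prox = 0) {
  if (lr <= 0) stop_fs("invalid_argument", "lr must be > 0")
  if (mu_prox < 0) stop_fs("invalid_argument", "mu_prox must be >= 0")
  lg <- loss_and_grads(params, batch$x, batch$stress, batch$identity)
  for (ln in names(params)) {
    gW <- lg$grads[[ln]]$W
    gb <- lg$grads[[ln]]$b
    if (!is.finite(sum(gW)) || !is.finite(sum(gb))) {
      stop_fs("numeric_failure", "non-finite gradient in layer %s", ln)
    }
    if (mu_prox > 0) {
      gW <- gW + mu_prox * (params[[ln]]$W - global_params[[ln]]$W)
      gb <- gb + mu_prox * (params[[ln]]$b - global_params[[ln]]$b)
    }
    params[[ln]]$W <- params[[ln]]$W - lr * gW
    params[[ln]]$b <- params[[ln]]$b - lr * gb
  }
  params
}

# One epoch of minibatch proximal SGD over rows idx of (x, ys, yi); the
# shuffle is drawn from `seed` so epochs are reproducible.
run_local_epoch <- function(params, global_params, x, ys, yi, idx,
                            batch_size, lr, mu_prox, seed) {
  ord <- with_seed(seed, sample.int(length(idx)))
  idx <- idx[ord]
  starts <- seq(1L, length(idx), by = batch_size)
  for (s in starts) {
    b <- idx[s:min(s + batch_size - 1L, length(idx))]
    batch <- list(x = x[b, , drop = FALSE], stress = ys[b], identity = yi[b])
    params <- local_train_step(params, global_params, batch, lr, mu_prox)
  }
  params
}

#' Predict class probabilities
#'
#' @param params A `model_params` (its stored feature scaler, if any, is
#'   applied first).
#' @param x Feature matrix.
#' @param task "stress" or "identity".
#' @return Matrix of softmax probabilities.
#' @export
predict_model <- function(params, x, task = c("stress", "identity")) {
  task <- match.arg(task)
  meta <- attr(params, "meta")
  if (!is.null(meta$scaler)) {
    x <- sweep(sweep(x, 2, meta$scaler$center), 2, meta$scaler$scale, "/")
  }
  fw <- forward(params, x)
  softmax(fw[[task]])
}

# ---- parameter arithmetic (used by federation and DP) -----------------------

params_map2 <- function(a, b, f) {
  for (ln in names(a)) {
    a[[ln]]$W <- f(a[[ln]]$W, b[[ln]]$W)
    a[[ln]]$b <- f(a[[ln]]$b, b[[ln]]$b)
  }
  a
}

params_sub <- function(a, b) params_map2(a, b, `-`)
params_add <- function(a, b) params_map2(a, b, `+`)

params_scale <- function(a, s) {
  for (ln in names(a)) {
    a[[ln]]$W <- a[[ln]]$W * s
    a[[ln]]$b <- a[[ln]]$b * s
  }
  a
}

# deterministic scalar fingerprint of a parameter set
params_checksum <- function(params) {
  sum(vapply(params, function(l) sum(l$W) + sum(l$b), numeric(1)))
}

#' Serialise model parameters to a plain-text container
#'
#' One block per layer: a header line `@<layer> scope=<scope> dims=<d1>x<d2>`
#' followed by one \code{\%.17g}-formatted value per line (column-major), then
#' `@bias` and the bias values. Stable layer order makes index-exact
#' aggregation/perturbation of deserialised parameters possible; \code{\%.17g}
#' makes the round trip bit-exact.
#'
#' @param params A `model_params`.
#' @param path Output file.
#' @export
write_params <- function(params, path) {
  meta <- attr(params, "meta")
  scopes <- attr(params, "scopes")
  con <- file(path, open = "wb")
  writeLines(paste0("#fedstress-params v1 meta=",
                    jsonlite::toJSON(meta[c("n_features", "n_subjects", "channels",
                                            "kernel", "fc1_width", "fc2_width")],
                                     auto_unbox = TRUE)), con, sep = "\n")
  for (ln in names(params)) {
    W <- params[[ln]]$W
    writeLines(sprintf("@%s scope=%s dims=%dx%d", ln, scopes[[ln]],
                       nrow(W), ncol(W)), con, sep = "\n")
    writeLines(format_full(as.vector(W)), con, sep = "\n")
    writeLines("@bias", con, sep = "\n")
    writeLines(format_full(params[[ln]]$b), con, sep = "\n")
  }
  close(con)
  invisible(path)
}

#' @rdname write_params
#' @param path File written by `write_params`.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  meta_json <- sub("^#fedstress-params v1 meta=", "", lines[1])
  m <- jsonlite::fromJSON(meta_json)
  params <- build_model(m$n_features, m$n_subjects, seed = 1L,
                        channels = m$channels, kernel = m$kernel,
                        fc1_width = m$fc1_width, fc2_width = m$fc2_width)
  i <- 2L
  while (i <= length(lines)) {
    hdr <- lines[i]
    ln <- sub("^@([a-z0-9_]+) .*$", "\\1", hdr)
    dims <- as.integer(strsplit(sub("^.*dims=", "", hdr), "x")[[1]])
    nW <- dims[1] * dims[2]
    W <- as.numeric(lines[(i + 1L):(i + nW)])
    i <- i + nW + 1L
    stopifnot(lines[i] == "@bias")
    nb <- dims[2]
    b <- as.numeric(lines[(i + 1L):(i + nb)])
    i <- i + nb + 1L
    params[[ln]]$W <- matrix(W, dims[1], dims[2])
    params[[ln]]$b <- b
  }
  params
}
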