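# Multitask 1D-CNN: architecture arithmetic, forward correctness against
# hand computation, loss closed forms, gradients against finite differences,
# the proximal step, overfit sanity and serialization.

test_that("architecture follows the layer table and flatten arithmetic", {
  p <- build_model(48, n_subjects = 15, seed = 1)
  meta <- attr(p, "meta")
  expect_identical(meta$flat_width, 360L)              # 60 x 6 after 3 pools
  expect_identical(dim(p$fc1$W), c(360L, 100L))
  expect_identical(dim(p$stress_head$W), c(100L, 2L))
  expect_identical(dim(p$fc2$W), c(100L, 300L))
  expect_identical(dim(p$identity_head$W), c(300L, 15L))
  expect_identical(dim(p$conv1$W), c(8L, 20L))
  expect_identical(dim(p$conv2$W), c(160L, 40L))
  expect_identical(attr(p, "scopes"),
                   c(conv1 = "shared", conv2 = "shared", conv3 = "shared",
                     fc1 = "shared", stress_head = "stress_specific",
                     fc2 = "identity_specific",
                     identity_head = "identity_specific"))
  expect_identical(build_model(48, 15, seed = 5), build_model(48, 15, seed = 5))
  expect_error(build_model(6, 3, seed = 1), class = "invalid_architecture")
  expect_error(build_model(48, 1, seed = 1), class = "invalid_argument")
})

test_that("forward is pure, shape-checked, and zero params give zero logits", {
  p <- build_model(16, 3, seed = 2)
  x <- matrix(fedstress:::with_seed(3, rnorm(5 * 16)), 5)
  o1 <- forward(p, x); o2 <- forward(p, x)
  expect_identical(o1$stress, o2$stress)
  expect_identical(dim(o1$identity), c(5L, 3L))
  expect_error(forward(p, matrix(0, 2, 15)), class = "shape_error")

  z <- fedstress:::params_scale(p, 0)
  oz <- forward(z, x)
  expect_true(all(oz$stress == 0) && all(oz$identity == 0))
  probs <- predict_model(z, x, "identity")
  expect_equal(unname(probs), matrix(1 / 3, 5, 3), tolerance = 1e-12)
})

test_that("forward matches a hand-traced all-ones network on a tiny input", {
  p <- build_model(16, 2, seed = 1)
  for (ln in names(p)) {
    p[[ln]]$W[] <- 1
    p[[ln]]$b[] <- 0
  }
  x <- c(1:16) / 10
  # independent trace with explicit loops over the documented architecture:
  # zero padding 3|4, window sum (all-ones kernel), ReLU, pairwise max
  conv_ones <- function(v) {
    padded <- c(rep(0, 3), v, rep(0, 4))
    vapply(seq_along(v), function(t) sum(padded[t:(t + 7)]), numeric(1))
  }
  pool2 <- function(v) {
    lo <- length(v) %/% 2
    vapply(seq_len(lo), function(t) max(v[2 * t - 1], v[2 * t]), numeric(1))
  }
  h <- pool2(pmax(conv_ones(x), 0))                       # conv1, 20 equal ch.
  h <- pool2(pmax(20 * conv_ones(h), 0))                  # conv2 sums 20 ch.
  h <- pool2(pmax(40 * conv_ones(h), 0))                  # conv3 sums 40 ch.
  flat_sum <- 60 * sum(h)                                 # 60 identical ch.
  h1 <- max(flat_sum, 0)                                  # every fc1 unit
  stress_expected <- 100 * h1                             # all-ones head
  ident_expected <- 300 * max(100 * h1, 0)                # fc2 then head
  o <- forward(p, x)
  expect_equal(unname(o$stress[1, ]), rep(stress_expected, 2), tolerance = 1e-9)
  expect_equal(unname(o$identity[1, ]), rep(ident_expected, 2), tolerance = 1e-9)
})

test_that("multitask loss has the uniform closed form and is exactly additive", {
  s <- matrix(0, 1, 2); i <- matrix(0, 1, 15)
  l <- multitask_loss(s, i, 0L, 7L)
  expect_equal(l$loss_stress, log(2), tolerance = 1e-12)
  expect_equal(l$loss_identity, log(15), tolerance = 1e-12)
  expect_identical(l$total, l$loss_stress + l$loss_identity)

  big <- multitask_loss(matrix(c(50, -50), 1), matrix(c(50, rep(-50, 14)), 1),
                        0L, 0L)
  expect_lt(big$total, 1e-10)

  set.seed(4)
  sl <- matrix(rnorm(6), 3); il <- matrix(rnorm(12), 3)
  ys <- c(0L, 1L, 0L); yi <- c(2L, 0L, 3L)
  got <- multitask_loss(sl, il, ys, yi)
  direct <- function(z, lab) {
    mean(vapply(seq_len(nrow(z)), function(r) {
      log(sum(exp(z[r, ]))) - z[r, lab[r] + 1]
    }, numeric(1)))
  }
  expect_equal(got$loss_stress, direct(sl, ys), tolerance = 1e-9)
  expect_equal(got$loss_identity, direct(il, yi), tolerance = 1e-9)
  expect_error(multitask_loss(sl, il, c(0L, 2L, 0L), yi), class = "invalid_label")
})

test_that("backpropagated gradients match finite differences", {
  p <- build_model(16, 3, seed = 2)
  x <- matrix(fedstress:::with_seed(5, rnorm(4 * 16)), 4)
  ys <- c(0L, 1L, 0L, 1L); yi <- c(0L, 1L, 2L, 0L)
  lg <- fedstress:::loss_and_grads(p, x, ys, yi)
  h <- 1e-5
  fedstress:::with_seed(6, {
    for (ln in names(p)) {
      for (i in sample(length(p[[ln]]$W), 3)) {
        q <- p
        q[[ln]]$W[i] <- q[[ln]]$W[i] + h
        up <- fedstress:::loss_and_grads(q, x, ys, yi)$loss$total
        q[[ln]]$W[i] <- q[[ln]]$W[i] - 2 * h
        dn <- fedstress:::loss_and_grads(q, x, ys, yi)$loss$total
        num <- (up - dn) / (2 * h)
        expect_equal(lg$grads[[ln]]$W[i], num, tolerance = 1e-4)
      }
      bi <- sample(length(p[[ln]]$b), 1)
      q <- p
      q[[ln]]$b[bi] <- q[[ln]]$b[bi] + h
      up <- fedstress:::loss_and_grads(q, x, ys, yi)$loss$total
      q[[ln]]$b[bi] <- q[[ln]]$b[bi] - 2 * h
      dn <- fedstress:::loss_and_grads(q, x, ys, yi)$loss$total
      expect_equal(lg$grads[[ln]]$b[bi], (up - dn) / (2 * h), tolerance = 1e-4)
    }
  })
})

test_that("the proximal step reduces to SGD and pulls toward the anchor", {
  p <- build_model(16, 3, seed = 7)
  g <- build_model(16, 3, seed = 8)
  batch <- list(x = matrix(fedstress:::with_seed(9, rnorm(6 * 16)), 6),
                stress = rep(0:1, 3), identity = c(0L, 1L, 2L, 0L, 1L, 2L))
  lr <- 0.01; mu <- 0.5
  plain <- local_train_step(p, g, batch, lr = lr, mu_prox = 0)
  sgd_oracle <- fedstress:::params_sub(
    p, fedstress:::params_scale(fedstress:::loss_and_grads(
      p, batch$x, batch$stress, batch$identity)$grads, lr))
  expect_equal(flatten_params(plain), flatten_params(sgd_oracle),
               tolerance = 1e-12)
  # the proximal term adds exactly -lr * mu * (w - w_global)
  prox <- local_train_step(p, g, batch, lr = lr, mu_prox = mu)
  expect_equal(flatten_params(prox),
               flatten_params(plain) -
                 lr * mu * (flatten_params(p) - flatten_params(g)),
               tolerance = 1e-12)
  # anchored at the global model the proximal term vanishes
  at_anchor <- local_train_step(p, p, batch, lr = lr, mu_prox = mu)
  plain_at <- local_train_step(p, p, batch, lr = lr, mu_prox = 0)
  expect_identical(flatten_params(at_anchor), flatten_params(plain_at))
  expect_error(local_train_step(p, g, batch, lr = 0), class = "invalid_argument")
})

test_that("200 steps overfit 32 vectors on both tasks", {
  ds <- toy_dataset(n = 32, n_features = 16, n_subjects = 4, sep = 1.5, seed = 2)
  p <- build_model(16, 4, seed = 3)
  batch <- list(x = scale(ds$x), stress = ds$stress, identity = ds$identity)
  for (i in 1:200) p <- local_train_step(p, p, batch, lr = 0.05, mu_prox = 0)
  fw <- forward(p, batch$x)
  expect_gt(mean(max.col(fw$stress, ties.method = "first") - 1 == ds$stress), 0.95)
  expect_gt(mean(max.col(fw$identity, ties.method = "first") - 1 == ds$identity), 0.95)
})

test_that("parameter serialization round-trips bit-exactly", {
  p <- random_params(11)
  path <- withr::local_tempfile(fileext = ".params")
  write_params(p, path)
  q <- read_params(path)
  expect_identical(flatten_params(q), flatten_params(p))
  expect_identical(attr(q, "scopes"), attr(p, "scopes"))
  expect_match(readLines(path, n = 1), "^#fedstress-params v1")
})
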