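# Shared fixtures, built in code at test time.

# Small labelled feature dataset drawn directly from Gaussian class clusters
# (bypasses the signal generator) for fast model/federation tests.
toy_dataset <- function(n = 300, n_features = 24, n_subjects = 4,
                        sep = 2, seed = 1) {
  fedstress:::with_seed(seed, {
    identity <- sample(0:(n_subjects - 1), n, replace = TRUE)
    stress <- sample(0:1, n, replace = TRUE)
    centers <- matrix(rnorm(n_subjects * n_features), n_subjects)
    shift <- rnorm(n_features)
    x <- sep * centers[identity + 1, , drop = FALSE] +
      sep * outer(stress, shift) +
      matrix(rnorm(n * n_features), n)
    structure(
      list(x = x, stress = stress, identity = identity,
           feature_names = paste0("f", seq_len(n_features)),
           modality = rep("eda", n_features), n_subjects = n_subjects),
      class = "feature_dataset"
    )
  })
}

# Random layer-structured parameter sets for aggregation / DP tests.
random_params <- function(seed, n_features = 16, n_subjects = 3) {
  p <- build_model(n_features, n_subjects, seed = seed)
  fedstress:::with_seed(seed + 1000L, {
    for (ln in names(p)) {
      p[[ln]]$W <- matrix(rnorm(length(p[[ln]]$W)), nrow(p[[ln]]$W))
      p[[ln]]$b <- rnorm(length(p[[ln]]$b))
    }
  })
  p
}

flatten_params <- function(p) unlist(lapply(p, function(l) c(l$W, l$b)),
                                     use.names = FALSE)

# The cohort used by the acceptance experiments: high-separability preset,
# 10 subjects, uniform 4 Hz rates, 79 alternating 700-s blocks (631 windows
# per subject). Built once per test session.
acceptance_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pre <- preset_conditions("high")
      recs <- simulate_cohort(10, pre$identity_strength, pre$stress_effect,
                              n_blocks = 79, block_s = 700,
                              rates = uniform_rates(4), seed = 11)
      cache <<- build_dataset(recs)
    }
    cache
  }
})

last_val_accuracy <- function(run, task) {
  h <- run$history
  a <- h[h$metric == "accuracy" & h$split == "val" & h$task == task, ]
  a$value[a$round == max(a$round)]
}
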