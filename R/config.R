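# Experiment configuration files: one YAML (or JSON) document with sections
# data, model, fl, dp, eval. Every run embeds its resolved configuration and
# seed in its outputs (see write_history_jsonl).

fs_default_config <- function() {
  list(
    data = list(n_subjects = 10L, preset = "high", n_blocks = 79L,
                block_s = 700, rate = 4, noise_ar = 0.6,
                modalities = c("eda", "bvp", "acc_x", "acc_y", "acc_z", "temp"),
                window = 700L, overlap = 0.5, seed = 1L),
    model = list(channels = c(20L, 40L, 60L), kernel = 8L,
                 fc1_width = 100L, fc2_width = 300L),
    fl = list(K = 5L, rounds = 20L, local_epochs = 1L, lr = 5e-4,
              mu_prox = 0, batch_size = 32L, scheme = "iid", alpha = 0.5,
              D_i = 1000L, val_fraction = 0.2, patience = 5L),
    dp = list(mechanism = "none", epsilon = NULL, delta = 1e-5, clip = 1,
              sigma = NULL, scope = "identity_specific", q = 1),
    eval = list(k = 5L, n_seeds = 3L)
  )
}

#' Read an experiment configuration
#'
#' Loads a YAML (or JSON) document with any of the sections `data`, `model`,
#' `fl`, `dp`, `eval` and merges it over the package defaults.
#'
#' @param path Path to the configuration file; `NULL` returns the defaults.
#' @return Nested configuration list.
#' @export
read_experiment_config <- function(path = NULL) {
  cfg <- fs_default_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (sec in names(user)) {
    if (!sec %in% names(cfg)) cfg[[sec]] <- list()
    for (kk in names(user[[sec]])) cfg[[sec]][[kk]] <- user[[sec]][[kk]]
  }
  cfg
}

# build the fl_config / dp_config objects from a config document
fl_config_from <- function(cfg) {
  f <- cfg$fl
  fl_config(K = f$K, rounds = f$rounds, local_epochs = f$local_epochs,
            lr = f$lr, mu_prox = f$mu_prox, batch_size = f$batch_size,
            scheme = f$scheme, alpha = f$alpha, D_i = f$D_i,
            val_fraction = f$val_fraction,
            patience = if (is.null(f$patience)) Inf else f$patience)
}

dp_config_from <- function(cfg) {
  d <- cfg$dp
  if (is.null(d) || identical(d$mechanism, "none")) return(NULL)
  dp_config(mechanism = d$mechanism, epsilon = d$epsilon, delta = d$delta,
            clip = d$clip, sigma = d$sigma, scope = d$scope, q = d$q,
            rounds = cfg$fl$rounds)
}

#' Generate the synthetic dataset described by a configuration
#'
#' Simulates the cohort in the `data` section (separability preset, uniform
#' sampling rate, alternating schedule) and featurises it.
#'
#' @param cfg Configuration list from [read_experiment_config()].
#' @return A `feature_dataset`.
#' @export
dataset_from_config <- function(cfg) {
  d <- cfg$data
  pre <- preset_conditions(d$preset)
  recs <- simulate_cohort(
    n_subjects = d$n_subjects, identity_strength = pre$identity_strength,
    stress_effect = pre$stress_effect, n_blocks = d$n_blocks,
    block_s = d$block_s, rates = uniform_rates(d$rate, d$modalities),
    noise_ar = d$noise_ar, seed = d$seed)
  build_dataset(recs, window = d$window, overlap_fraction = d$overlap)
}
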