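# Evaluation protocol: metrics against oracles, stratified folds, regime
# nesting, ablation identity, sweep plumbing and report reproducibility.

test_that("metrics hit their closed-form and degenerate values", {
  perfect <- compute_metrics(c(0, 1, 1, 0), rbind(c(9, 1), c(1, 9), c(2, 8), c(7, 3)))
  expect_identical(perfect$accuracy, 1)
  expect_identical(perfect$macro_f1, 1)
  expect_identical(perfect$auc, 1)

  const <- compute_metrics(rep(c(0, 1), 10), matrix(0.5, 20, 2))
  expect_identical(const$accuracy, 0.5)
  expect_equal(const$auc, 0.5)

  one_class <- compute_metrics(rep(1L, 5), matrix(rnorm(10), 5))
  expect_true(is.na(one_class$auc))

  expect_error(compute_metrics(c(0, 3), matrix(0, 2, 2)), class = "invalid_label")
})

test_that("macro-F1 matches a hand-computed confusion case", {
  # 10 items, 3 classes; predictions via one-hot score rows
  y <- c(0, 0, 0, 0, 1, 1, 1, 2, 2, 2)
  pred <- c(0, 0, 1, 2, 1, 1, 0, 2, 2, 2)
  scores <- t(vapply(pred, function(p) replace(rep(0, 3), p + 1, 1), numeric(3)))
  m <- compute_metrics(y, scores)
  # class 0: tp=2 fp=1 fn=2 -> F1 = 4/7; class 1: tp=2 fp=1 fn=1 -> 4/6
  # class 2: tp=3 fp=1 fn=0 -> 6/7; macro = mean
  expect_equal(m$macro_f1, mean(c(4 / 7, 4 / 6, 6 / 7)), tolerance = 1e-12)
  expect_identical(m$accuracy, 0.7)
})

test_that("AUC agrees with brute-force pair counting, binary and multiclass", {
  fedstress:::with_seed(31, {
    y <- sample(0:1, 60, replace = TRUE)
    sc <- cbind(rnorm(60), rnorm(60) + y)
    got <- compute_metrics(y, sc)
    expect_equal(got$auc, auc_oracle(y, sc[, 2]), tolerance = 1e-12)

    y3 <- sample(0:2, 90, replace = TRUE)
    sc3 <- matrix(rnorm(270), 90) + outer(y3, 0:2, function(a, b) (a == b) * 1.5)
    got3 <- compute_metrics(y3, sc3)
    want3 <- mean(vapply(0:2, function(cl) {
      auc_oracle(as.integer(y3 == cl), sc3[, cl + 1]) }, numeric(1)))
    expect_equal(got3$auc, want3, tolerance = 1e-12)
  })
})

test_that("stratified folds partition evenly and keep every identity trainable", {
  ds <- toy_dataset(n = 1000, n_subjects = 5, seed = 6)
  fold <- fedstress:::stratified_folds(ds$stress, ds$identity, 5, seed = 2)
  expect_identical(sort(unique(fold)), 1:5)
  expect_true(all(abs(table(fold) - 200) <= 10))
  for (f in 1:5) {
    expect_identical(sort(unique(ds$identity[fold != f])), 0:4)
  }
  # a subject with a single window cannot appear in every training fold
  ds1 <- ds
  keep <- c(which(ds1$identity != 0), which(ds1$identity == 0)[1])
  ds1 <- subset_dataset(ds1, keep)
  expect_error(fedstress:::stratified_folds(ds1$stress, ds1$identity, 5, 1),
               class = "stratification_error")
})

test_that("kfold_evaluate produces a complete, reproducible report", {
  ds <- toy_dataset(n = 250, n_features = 16, n_subjects = 3, sep = 3, seed = 9)
  cfg <- fl_config(K = 2, rounds = 3, D_i = 80, lr = 0.02, patience = Inf)
  rep1 <- kfold_evaluate(ds, "mfl", cfg, k = 3, seed = 5)
  expect_identical(nrow(rep1), 6L)                   # 3 folds x 2 tasks
  expect_true(all(rep1$accuracy >= 0 & rep1$accuracy <= 1))
  expect_true(all(rep1$macro_f1 >= 0 & rep1$macro_f1 <= 1))
  expect_true(all(is.na(rep1$auc) | (rep1$auc >= 0 & rep1$auc <= 1)))
  rep2 <- kfold_evaluate(ds, "mfl", cfg, k = 3, seed = 5)
  expect_identical(summarize_report(rep1), summarize_report(rep2))
  expect_error(kfold_evaluate(ds, "mfl", cfg, k = 1, seed = 1),
               class = "invalid_argument")
})

test_that("label shuffling drives both tasks to chance", {
  ds <- toy_dataset(n = 240, n_features = 16, n_subjects = 4, sep = 3, seed = 10)
  accs <- vapply(1:5, function(s) {
    shuffled <- ds
    shuffled$stress <- fedstress:::with_seed(s, sample(ds$stress))
    shuffled$identity <- fedstress:::with_seed(s + 50, sample(ds$identity))
    cfg <- fl_config(K = 2, rounds = 4, D_i = 96, lr = 0.02, patience = Inf)
    run <- run_training(shuffled, cfg, seed = s)
    test_idx <- setdiff(seq_len(240), sort(unlist(lapply(run$partition, `[[`, "idx"))))
    fw <- predict_model(run$params, shuffled$x[test_idx, ], "stress")
    fi <- predict_model(run$params, shuffled$x[test_idx, ], "identity")
    c(mean(max.col(fw, ties.method = "first") - 1 == shuffled$stress[test_idx]),
      mean(max.col(fi, ties.method = "first") - 1 == shuffled$identity[test_idx]))
  }, numeric(2))
  n_test <- 48 * 5
  expect_lt(abs(mean(accs[1, ]) - 0.5), 2.58 * sqrt(0.25 / n_test) + 0.05)
  expect_lt(abs(mean(accs[2, ]) - 0.25), 2.58 * sqrt(0.25 * 0.75 / n_test) + 0.05)
})

test_that("restricting to all modalities reproduces the unrestricted report", {
  profs <- make_profiles(3, seed = 2, modalities = c("eda", "temp"))
  recs <- lapply(profs, function(p) {
    simulate_recording(p, make_schedule(6, 262.5),
                       rates = c(eda = 4, temp = 4), seed = 40 + p$subject_id)
  })
  ds <- build_dataset(recs)
  cfg <- fl_config(K = 2, rounds = 2, D_i = 12, lr = 0.02, patience = Inf)
  full <- kfold_evaluate(ds, "mfl", cfg, k = 2, seed = 3)
  abl <- modality_ablation(ds, c("eda", "temp"), "mfl", cfg, k = 2, seed = 3)
  expect_identical(full$accuracy, abl$accuracy)
  expect_identical(full$auc, abl$auc)
  expect_identical(unique(abl$modalities), "eda+temp")
  expect_error(modality_ablation(ds, character(0), "mfl", cfg),
               class = "invalid_argument")
})

test_that("modality-targeted effects separate the per-modality reports", {
  # stress response only on EDA; identity signature only on ACC
  profs <- make_profiles(4, identity_strength = 1.2, stress_effect = 1.5,
                         modalities = c("eda", "acc_x"), seed = 8)
  for (i in seq_along(profs)) {
    profs[[i]]$stress_coef["acc_x"] <- 0      # EDA carries the stress signal
    profs[[i]]$baseline["eda"] <- 2           # ACC carries the identity signal
    profs[[i]]$gain["eda"] <- 0.2
  }
  recs <- lapply(profs, function(p) {
    simulate_recording(p, make_schedule(10, 175),
                       rates = c(eda = 4, acc_x = 4), noise_ar = 0.4,
                       seed = 60 + p$subject_id)
  })
  ds <- build_dataset(recs, window = 175, overlap_fraction = 0.5)
  # linear-probe contrast on the feature blocks (fast, classifier-agnostic)
  probe <- function(mods, label) {
    sub <- restrict_modalities(ds, mods)
    xs <- scale(sub$x); y <- if (label == "stress") ds$stress else ds$identity
    cent <- t(vapply(sort(unique(y)), function(cl) {
      colMeans(xs[y == cl, , drop = FALSE]) }, numeric(ncol(xs))))
    d2 <- outer(rowSums(xs^2), rep(1, nrow(cent))) - 2 * xs %*% t(cent) +
      outer(rep(1, nrow(xs)), rowSums(cent^2))
    mean(sort(unique(y))[max.col(-d2, ties.method = "first")] == y)
  }
  expect_gt(probe("eda", "stress"), probe("acc_x", "stress"))
  expect_gt(probe("acc_x", "identity"), probe("eda", "identity"))
})

test_that("a null DP level is bit-identical to the no-DP regime", {
  ds <- toy_dataset(n = 200, n_features = 16, seed = 12)
  cfg <- fl_config(K = 2, rounds = 3, D_i = 80, lr = 0.02, patience = Inf)
  plain <- run_training(ds, cfg, dp = NULL, seed = 6)
  null_dp <- run_training(ds, cfg,
                          dp = dp_config("gaussian_fixed", sigma = 0,
                                         scope = "identity_specific"),
                          seed = 6)
  expect_identical(flatten_params(plain$params), flatten_params(null_dp$params))
  expect_identical(plain$history, null_dp$history)
})

test_that("tradeoff_sweep emits the grid and its level-0 row matches no-DP", {
  ds <- toy_dataset(n = 300, n_features = 16, n_subjects = 3, sep = 3, seed = 13)
  cfg <- fl_config(K = 2, rounds = 2, D_i = 100, lr = 0.02, patience = Inf)
  sw <- tradeoff_sweep(ds, scopes = "identity_specific",
                       mechanisms = "gaussian_fixed", levels = c(0, 0.3),
                       config = cfg, n_seeds = 2, seed = 3)
  expect_identical(nrow(sw), 2L * 2L * 2L)          # levels x seeds x tasks
  expect_setequal(unique(sw$level), c(0, 0.3))
  sw2 <- tradeoff_sweep(ds, scopes = "identity_specific",
                        mechanisms = "gaussian_fixed", levels = c(0, 0.3),
                        config = cfg, n_seeds = 2, seed = 3)
  expect_identical(sw$accuracy, sw2$accuracy)
  md <- format_markdown_table(summarize_report(sw))
  expect_match(md[1], "^\\| .*accuracy")
})

test_that("experiment configs read, merge and drive dataset construction", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("data:", "  n_subjects: 3", "  n_blocks: 4", "  preset: medium",
               "fl:", "  K: 2", "  rounds: 2"), path)
  cfg <- read_experiment_config(path)
  expect_identical(cfg$data$n_subjects, 3L)
  expect_identical(cfg$fl$K, 2L)
  expect_identical(cfg$fl$lr, 5e-4)               # default survives the merge
  expect_identical(cfg$dp$mechanism, "none")
  flc <- fedstress:::fl_config_from(cfg)
  expect_s3_class(flc, "fl_config")
  cfg$data$n_blocks <- 2L
  ds <- dataset_from_config(cfg)
  expect_s3_class(ds, "feature_dataset")
  expect_identical(ds$n_subjects, 3L)
})
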