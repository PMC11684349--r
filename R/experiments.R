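# Evaluation protocol: per-task metrics, stratified k-fold cross-validation
# of the three training regimes (centralized, federated, federated + DP),
# per-modality ablations and privacy-utility sweeps.

#' Accuracy, macro-F1 and AUC from score matrices
#'
#' Accuracy is the argmax match rate. Macro-F1 averages per-class F1 over the
#' classes present in the truth (a class with zero precision+recall
#' contributes 0). AUC is the standard binary AUC against the second column
#' for two-class scores, and the macro one-vs-rest average over truth-present
#' classes otherwise; it is `NA` (undefined, not 0) when the truth holds a
#' single class. AUCs come from `pROC`.
#'
#' @param y_true Integer labels, 0-based.
#' @param scores Matrix of per-class scores (logits or probabilities), one
#'   column per class.
#' @return List `accuracy`, `macro_f1`, `auc`.
#' @export
#' @examples
#' compute_metrics(c(0, 1, 1), rbind(c(5, 0), c(0, 5), c(5, 0)))
compute_metrics <- function(y_true, scores) {
  if (is.vector(scores)) scores <- matrix(scores, ncol = 1)
  n_class <- ncol(scores)
  if (any(y_true < 0 | y_true >= n_class)) {
    stop_fs("invalid_label", "label out of range")
  }
  pred <- max.col(scores, ties.method = "first") - 1L
  accuracy <- mean(pred == y_true)

  present <- sort(unique(y_true))
  f1s <- vapply(present, function(cl) {
    tp <- sum(pred == cl & y_true == cl)
    fp <- sum(pred == cl & y_true != cl)
    fn <- sum(pred != cl & y_true == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  macro_f1 <- mean(f1s)

  auc <- if (length(present) < 2L) {
    NA_real_
  } else if (n_class == 2L) {
    as.numeric(pROC::auc(pROC::roc(
      response = y_true, predictor = scores[, 2],
      levels = c(0, 1), direction = "<", quiet = TRUE)))
  } else {
    mean(vapply(present, function(cl) {
      as.numeric(pROC::auc(pROC::roc(
        response = as.integer(y_true == cl), predictor = scores[, cl + 1L],
        levels = c(0, 1), direction = "<", quiet = TRUE)))
    }, numeric(1)))
  }
  list(accuracy = accuracy, macro_f1 = macro_f1, auc = auc)
}

# Stratified fold assignment on the joint (identity, stress) strata: within
# each stratum, shuffled examples are dealt round-robin across folds. Errors
# if any identity class would be absent from some training fold.
stratified_folds <- function(stress, identity, k, seed) {
  n <- length(stress)
  strata <- interaction(identity, stress, drop = TRUE)
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (s in levels(strata)) {
      rows <- which(strata == s)
      rows <- rows[sample.int(length(rows))]
      fold[rows] <- as.integer(((seq_along(rows) - 1L + offset) %% k) + 1L)
      offset <- offset + length(rows)  # stagger so small strata spread out
    }
  })
  for (f in seq_len(k)) {
    train_ids <- unique(identity[fold != f])
    if (length(setdiff(unique(identity), train_ids)) > 0L) {
      stop_fs("stratification_error",
              "identity class absent from training folds; need more data per subject")
    }
  }
  fold
}

train_regime <- function(train_ds, regime, config, dp, seed) {
  switch(regime,
    centralized = train_centralized(train_ds, config, seed = seed),
    mfl = run_training(train_ds, config, dp = NULL, seed = seed),
    mfl_dp = run_training(train_ds, config, dp = dp, seed = seed)
  )
}

eval_on <- function(params, ds, idx) {
  xs <- ds$x[idx, , drop = FALSE]
  ms <- compute_metrics(ds$stress[idx], predict_model(params, xs, "stress"))
  mi <- compute_metrics(ds$identity[idx], predict_model(params, xs, "identity"))
  rbind(
    data.frame(task = "stress", accuracy = ms$accuracy, macro_f1 = ms$macro_f1,
               auc = ms$auc),
    data.frame(task = "identity", accuracy = mi$accuracy, macro_f1 = mi$macro_f1,
               auc = mi$auc)
  )
}

#' Stratified k-fold evaluation of a training regime
#'
#' Folds are stratified jointly on (identity, stress) so every identity class
#' appears in every training fold; each fold is scored by a model trained
#' under the regime on the remaining `k - 1` folds.
#'
#' @param dataset A `feature_dataset`.
#' @param regime `centralized`, `mfl` (federated, no DP) or `mfl_dp`.
#' @param config An [fl_config()].
#' @param dp A [dp_config()] (used by `mfl_dp`).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed (folds and per-fold training seeds derive from it).
#' @return An `eval_report` data frame: one row per (fold, task) with
#'   `accuracy`, `macro_f1`, `auc`; the resolved configuration is attached as
#'   attribute `config`.
#' @export
kfold_evaluate <- function(dataset, regime = c("mfl", "centralized", "mfl_dp"),
                           config = fl_config(), dp = NULL, k = 5L, seed = 1L) {
  regime <- match.arg(regime)
  if (k < 2) stop_fs("invalid_argument", "k must be >= 2")
  fold <- stratified_folds(dataset$stress, dataset$identity, k,
                           derive_seed(seed, 11L))
  rows <- list()
  for (f in seq_len(k)) {
    train_ds <- subset_dataset(dataset, which(fold != f))
    test_idx <- which(fold == f)
    run <- train_regime(train_ds, regime, config, dp,
                        seed = derive_seed(seed, 20L, f))
    ev <- eval_on(run$params, dataset, test_idx)
    ev$fold <- f
    ev$regime <- regime
    rows[[f]] <- ev
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(fl = config, dp = dp, k = k, seed = seed)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Per-modality ablation
#'
#' Restricts the feature table to the named modalities' feature blocks before
#' running the k-fold evaluation; with all modalities listed this is exactly
#' [kfold_evaluate()].
#'
#' @inheritParams kfold_evaluate
#' @param modalities Non-empty character vector of modalities to keep.
#' @return An `eval_report` with an extra `modalities` column.
#' @export
modality_ablation <- function(dataset, modalities,
                              regime = c("mfl", "centralized", "mfl_dp"),
                              config = fl_config(), dp = NULL, k = 5L,
                              seed = 1L) {
  restricted <- restrict_modalities(dataset, modalities)
  out <- kfold_evaluate(restricted, regime, config, dp, k, seed)
  out$modalities <- paste(sort(modalities), collapse = "+")
  out
}

#' Privacy-utility trade-off sweep
#'
#' Grid of (scope x mechanism x level) runs on a fixed stratified train/test
#' split, each repeated over `n_seeds` training seeds. For the
#' `gaussian_fixed` mechanism the level is the noise sd `sigma` (level 0 is
#' the exact no-DP run); for `laplace`, `gaussian1` and `gaussian2` the level
#' is the privacy budget `epsilon`.
#'
#' @param dataset A `feature_dataset`.
#' @param scopes Character vector of perturbation scopes.
#' @param mechanisms Character vector of mechanisms.
#' @param levels Numeric vector of noise levels (sigma or epsilon).
#' @param config An [fl_config()].
#' @param clip Clipping threshold for the DP configurations.
#' @param delta DP failure probability.
#' @param n_seeds Training seeds per cell (>= 1; default 3).
#' @param holdout_fraction Fraction held out (stratified) for testing.
#' @param seed Master seed.
#' @return Data frame with one row per (scope, mechanism, level, seed, task):
#'   accuracy, macro-F1, AUC on the held-out set.
#' @export
tradeoff_sweep <- function(dataset, scopes = c("identity_specific", "full"),
                           mechanisms = "gaussian_fixed",
                           levels = c(0, 0.1, 0.3, 0.6),
                           config = fl_config(), clip = 1, delta = 1e-5,
                           n_seeds = 3L, holdout_fraction = 0.2, seed = 1L) {
  fold <- stratified_folds(dataset$stress, dataset$identity,
                           k = max(2L, round(1 / holdout_fraction)),
                           seed = derive_seed(seed, 31L))
  test_idx <- which(fold == 1L)
  train_ds <- subset_dataset(dataset, which(fold != 1L))

  rows <- list()
  for (scope in scopes) for (mech in mechanisms) for (lv in levels) {
    dp <- if (lv == 0 || mech == "none") {
      dp_config("gaussian_fixed", sigma = 0, clip = clip, scope = scope)
    } else if (mech == "gaussian_fixed") {
      dp_config("gaussian_fixed", sigma = lv, clip = clip, scope = scope)
    } else {
      dp_config(mech, epsilon = lv, delta = delta, clip = clip, scope = scope,
                rounds = config$rounds)
    }
    for (s in seq_len(n_seeds)) {
      run <- run_training(train_ds, config, dp = dp,
                          seed = derive_seed(seed, 40L + s, 1000L * lv))
      ev <- eval_on(run$params, dataset, test_idx)
      ev$scope <- scope; ev$mechanism <- mech; ev$level <- lv; ev$seed_rep <- s
      rows[[length(rows) + 1L]] <- ev
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(fl = config, clip = clip, delta = delta,
                              seed = seed)
  out
}

#' Summarise an evaluation report
#'
#' Mean and sd of each metric per grouping of the non-metric columns.
#'
#' @param report A data frame from [kfold_evaluate()], [modality_ablation()]
#'   or [tradeoff_sweep()].
#' @return Data frame of group means and sds.
#' @export
summarize_report <- function(report) {
  metrics <- intersect(c("accuracy", "macro_f1", "auc"), names(report))
  groups <- setdiff(names(report), c(metrics, "fold", "seed_rep"))
  agg <- stats::aggregate(report[metrics], by = report[groups],
                          function(v) mean(v, na.rm = TRUE))
  sds <- stats::aggregate(report[metrics], by = report[groups],
                          function(v) stats::sd(v, na.rm = TRUE))
  names(sds)[match(metrics, names(sds))] <- paste0(metrics, "_sd")
  merge(agg, sds, by = groups)
}

#' Format a summary as a markdown table
#'
#' @param df A data frame (typically from [summarize_report()]).
#' @param digits Rounding for numeric columns.
#' @return Character vector of markdown lines.
#' @export
format_markdown_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  cells <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(unlist(lapply(df[i, ], as.character)), collapse = " | "), " |")
  }, character(1))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    cells)
}
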