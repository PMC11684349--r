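# Sliding-window segmentation and per-window feature extraction.
#
# Every modality is segmented at its native rate into fixed-length windows
# (default 700 samples, 50% overlap) and summarised by 12 features per
# window: mean, variance, root-mean-square, skewness, excess kurtosis,
# histogram entropy, mean absolute first difference, mean absolute second
# difference, and 4 log-spaced periodogram band powers.

FS_FEATURES <- c("mean", "variance", "rms", "skewness", "kurtosis", "entropy",
                 "mad1", "mad2", "bp1", "bp2", "bp3", "bp4")

#' Segment a signal into fixed-length overlapping windows
#'
#' Windows start at multiples of `stride = round(window * (1 -
#' overlap_fraction))`; the trailing remainder shorter than one window is
#' dropped, so the window count is `floor((length - window) / stride) + 1`
#' when the signal holds at least one window and 0 otherwise.
#'
#' @param signal Numeric vector of samples.
#' @param window Window length in samples (>= 2; default 700).
#' @param overlap_fraction Fractional overlap in \[0, 1) (default 0.5).
#' @return Numeric matrix, one row per window (0 rows when the signal is
#'   shorter than `window`), with attribute `starts` holding the 1-based
#'   start index of each window.
#' @export
#' @examples
#' nrow(segment(rnorm(2100)))            # 5 windows
#' attr(segment(rnorm(2100)), "starts")  # 1, 351, 701, 1051, 1401
segment <- function(signal, window = 700L, overlap_fraction = 0.5) {
  if (window < 2) stop_fs("invalid_argument", "window must be >= 2")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_fs("invalid_argument", "overlap_fraction must lie in [0, 1)")
  }
  window <- as.integer(window)
  stride <- max(1L, as.integer(round(window * (1 - overlap_fraction))))
  n <- length(signal)
  if (n < window) {
    out <- matrix(numeric(0), nrow = 0, ncol = window)
    attr(out, "starts") <- integer(0)
    return(out)
  }
  k <- (n - window) %/% stride + 1L
  starts <- (seq_len(k) - 1L) * stride + 1L
  idx <- outer(starts, 0:(window - 1L), "+")
  out <- matrix(signal[idx], nrow = k, ncol = window)
  attr(out, "starts") <- starts
  out
}

#' Default frequency bands for band-power features
#'
#' Four log-spaced bands between `nyquist / 100` and the Nyquist frequency
#' `rate / 2`; band powers sum the raw periodogram ordinates with frequency
#' in `(lo, hi]`.
#'
#' @param rate Sampling rate in Hz.
#' @param n_bands Number of bands.
#' @return Matrix with columns `lo`, `hi` (Hz), one row per band.
#' @export
default_bands <- function(rate, n_bands = 4L) {
  nyq <- rate / 2
  edges <- 10^seq(log10(nyq / 100), log10(nyq), length.out = n_bands + 1L)
  cbind(lo = edges[-length(edges)], hi = edges[-1])
}

#' Extract the 12 per-window features
#'
#' Definitions (window `x` of length `n`, sample mean `m`):
#' \itemize{
#'   \item mean; variance: unbiased `sum((x-m)^2)/(n-1)`; rms:
#'     `sqrt(mean(x^2))`;
#'   \item skewness `m3/m2^(3/2)` and excess kurtosis `m4/m2^2 - 3` with
#'     central moments `mk = mean((x-m)^k)`; both defined as 0 for a
#'     zero-variance window;
#'   \item entropy: Shannon entropy (natural log) of a `bins`-bin equal-width
#'     amplitude histogram over `range(x)`, 0 for a constant window;
#'   \item mad1/mad2: mean absolute first/second successive difference;
#'   \item bp1..bp4: raw periodogram `|fft(x - m)|^2 / n` summed over the
#'     frequency bands (DC excluded).
#' }
#'
#' @param window Numeric vector, length >= 3, all finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param bands Band matrix as from [default_bands()]; defaults to
#'   `default_bands(rate)`.
#' @param bins Histogram bin count for the entropy feature.
#' @return Named numeric vector of the 12 features, in the fixed order
#'   `mean, variance, rms, skewness, kurtosis, entropy, mad1, mad2,
#'   bp1..bp4`.
#' @export
#' @examples
#' extract_features(sin(seq(0, 10, length.out = 700)), rate = 4)
extract_features <- function(window, rate, bands = NULL, bins = 16L) {
  if (length(window) < 3) stop_fs("invalid_argument", "window length must be >= 3")
  if (any(!is.finite(window))) stop_fs("invalid_input", "non-finite samples")
  if (rate <= 0) stop_fs("invalid_argument", "rate must be > 0")
  drop(extract_features_mat(matrix(window, nrow = 1), rate, bands, bins))
}

# Vectorised feature extraction: W is (n_windows x window_len). Single code
# path shared with extract_features().
extract_features_mat <- function(W, rate, bands = NULL, bins = 16L) {
  if (is.null(bands)) bands <- default_bands(rate)
  n <- ncol(W)
  k <- nrow(W)
  mu <- rowMeans(W)
  Xc <- W - mu
  m2 <- rowMeans(Xc^2)
  m3 <- rowMeans(Xc^3)
  m4 <- rowMeans(Xc^4)
  variance <- rowSums(Xc^2) / (n - 1)
  rms <- sqrt(rowMeans(W^2))
  skew <- ifelse(m2 > 0, m3 / m2^1.5, 0)
  kurt <- ifelse(m2 > 0, m4 / m2^2 - 3, 0)

  d1 <- abs(W[, -1, drop = FALSE] - W[, -n, drop = FALSE])
  mad1 <- rowMeans(d1)
  D1 <- W[, -1, drop = FALSE] - W[, -n, drop = FALSE]
  d2 <- abs(D1[, -1, drop = FALSE] - D1[, -(n - 1), drop = FALSE])
  mad2 <- rowMeans(d2)

  ent <- vapply(seq_len(k), function(i) {
    x <- W[i, ]
    rg <- range(x)
    if (rg[1] == rg[2]) return(0)
    cuts <- seq(rg[1], rg[2], length.out = bins + 1L)
    cnt <- tabulate(pmin(findInterval(x, cuts, rightmost.closed = TRUE), bins),
                    nbins = bins)
    p <- cnt[cnt > 0] / n
    -sum(p * log(p))
  }, numeric(1))

  # raw periodogram of the demeaned window; frequencies j * rate / n
  Fc <- stats::mvfft(t(Xc))
  P <- (Mod(Fc)^2) / n               # n x k, row j+1 is frequency j*rate/n
  nf <- n %/% 2
  freqs <- (1:nf) * rate / n
  Ph <- P[2:(nf + 1L), , drop = FALSE]
  bp <- sapply(seq_len(nrow(bands)), function(b) {
    sel <- freqs > bands[b, "lo"] & freqs <= bands[b, "hi"]
    if (!any(sel)) return(rep(0, k))
    colSums(Ph[sel, , drop = FALSE])
  })
  if (k == 1L) bp <- matrix(bp, nrow = 1)

  out <- cbind(mu, variance, rms, skew, kurt, ent, mad1, mad2, bp)
  colnames(out) <- FS_FEATURES
  out
}

#' Build a labelled feature dataset from recordings
#'
#' Segments every channel of every recording at its native rate (window
#' measured in samples, so a 700-sample window spans `700 / rate` seconds)
#' and joins the per-modality feature blocks by window ordinal. The number of
#' vectors contributed by a recording is the minimum window count across its
#' modalities. The stress label of a vector is the majority state over the
#' time span of the corresponding window of the slowest-rate modality (ties
#' resolve to stress); the identity label is the recording's `subject_id`.
#'
#' @param recordings List of `multimodal_recording` sharing one modality set.
#' @param window Window length in samples.
#' @param overlap_fraction Fractional window overlap.
#' @param bands Optional band matrix passed to the feature extractor (per
#'   modality, computed from its rate when NULL).
#' @param bins Entropy histogram bin count.
#' @param normalize "none" (default) or "per_subject" (z-score each subject's
#'   feature columns with that subject's own statistics).
#' @return A `feature_dataset`: list with `x` (matrix, one row per window),
#'   `stress` (0/1), `identity` (0-based subject ids), `feature_names`
#'   (`<modality>_<feature>`), `modality` (per column), `n_subjects`.
#' @export
build_dataset <- function(recordings, window = 700L, overlap_fraction = 0.5,
                          bands = NULL, bins = 16L,
                          normalize = c("none", "per_subject")) {
  normalize <- match.arg(normalize)
  stopifnot(length(recordings) >= 1L)
  mods <- names(recordings[[1]]$channels)
  for (rec in recordings) {
    if (!setequal(names(rec$channels), mods)) {
      stop_fs("schema_mismatch", "recordings have inconsistent modality sets")
    }
  }
  mods <- FS_MODALITIES[FS_MODALITIES %in% mods]

  blocks <- list(); stress <- integer(0); identity <- integer(0)
  for (rec in recordings) {
    per_mod <- lapply(mods, function(m) {
      W <- segment(rec$channels[[m]], window, overlap_fraction)
      extract_features_mat(W, rec$rates[[m]], bands, bins)
    })
    n_win <- min(vapply(per_mod, nrow, 1L))
    if (n_win == 0L) next
    feat <- do.call(cbind, lapply(per_mod, function(B) B[seq_len(n_win), , drop = FALSE]))

    # label windows from the slowest modality's time span on the state track
    slow <- mods[which.min(rec$rates[mods])]
    r_slow <- rec$rates[[slow]]
    stride <- max(1L, as.integer(round(window * (1 - overlap_fraction))))
    lab <- vapply(seq_len(n_win), function(kk) {
      s0 <- (kk - 1L) * stride            # 0-based start sample in slow channel
      t0 <- s0 / r_slow
      t1 <- (s0 + window) / r_slow
      i0 <- floor(t0 * rec$ref_rate) + 1L
      i1 <- min(length(rec$states), ceiling(t1 * rec$ref_rate))
      majority_label(rec$states[i0:i1])
    }, integer(1))

    blocks[[length(blocks) + 1L]] <- feat
    stress <- c(stress, lab)
    identity <- c(identity, rep(rec$subject_id, n_win))
  }
  x <- do.call(rbind, blocks)
  feature_names <- as.vector(t(outer(mods, FS_FEATURES, paste, sep = "_")))
  colnames(x) <- feature_names
  modality_of <- rep(mods, each = length(FS_FEATURES))

  if (normalize == "per_subject") {
    for (sid in unique(identity)) {
      rows <- identity == sid
      mu <- colMeans(x[rows, , drop = FALSE])
      sg <- apply(x[rows, , drop = FALSE], 2, stats::sd)
      sg[sg == 0] <- 1
      x[rows, ] <- sweep(sweep(x[rows, , drop = FALSE], 2, mu), 2, sg, "/")
    }
  }

  structure(
    list(x = x, stress = as.integer(stress), identity = as.integer(identity),
         feature_names = feature_names, modality = modality_of,
         n_subjects = length(unique(identity))),
    class = "feature_dataset"
  )
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d windows x %d features, %d subjects, %.1f%% stress\n",
              nrow(x$x), ncol(x$x), x$n_subjects, 100 * mean(x$stress)))
  invisible(x)
}

#' Subset a feature dataset by row index
#' @param dataset A `feature_dataset`.
#' @param idx Integer row indices to keep.
#' @return A `feature_dataset` with the selected rows. Note `n_subjects` is
#'   kept from the parent so identity label space is preserved.
#' @export
subset_dataset <- function(dataset, idx) {
  structure(
    list(x = dataset$x[idx, , drop = FALSE], stress = dataset$stress[idx],
         identity = dataset$identity[idx],
         feature_names = dataset$feature_names, modality = dataset$modality,
         n_subjects = dataset$n_subjects),
    class = "feature_dataset"
  )
}

#' Restrict a feature dataset to a modality subset
#' @param dataset A `feature_dataset`.
#' @param modalities Character vector of modalities to keep.
#' @return A `feature_dataset` with only those modalities' feature columns.
#' @export
restrict_modalities <- function(dataset, modalities) {
  if (length(modalities) == 0L) stop_fs("invalid_argument", "empty modality set")
  missing_m <- setdiff(modalities, unique(dataset$modality))
  if (length(missing_m) > 0L) {
    stop_fs("unknown_modality", "modalities absent from dataset: %s",
            paste(missing_m, collapse = ", "))
  }
  keep <- dataset$modality %in% modalities
  structure(
    list(x = dataset$x[, keep, drop = FALSE], stress = dataset$stress,
         identity = dataset$identity,
         feature_names = dataset$feature_names[keep],
         modality = dataset$modality[keep], n_subjects = dataset$n_subjects),
    class = "feature_dataset"
  )
}

#' Write/read a feature dataset as CSV
#'
#' Header `subject_id,stress,<modality>_<feature>,...`; values printed with
#' \code{\%.17g} so the table round-trips.
#'
#' @param dataset A `feature_dataset`.
#' @param path Output CSV path.
#' @export
write_feature_csv <- function(dataset, path) {
  con <- file(path, open = "wb")
  writeLines(paste(c("subject_id", "stress", dataset$feature_names),
                   collapse = ","), con, sep = "\n")
  rows <- vapply(seq_len(nrow(dataset$x)), function(i) {
    paste(c(dataset$identity[i], dataset$stress[i],
            format_full(dataset$x[i, ])), collapse = ",")
  }, character(1))
  writeLines(rows, con, sep = "\n")
  close(con)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  feature_names <- setdiff(colnames(d), c("subject_id", "stress"))
  x <- as.matrix(d[, feature_names, drop = FALSE])
  modality_of <- sub("_(mean|variance|rms|skewness|kurtosis|entropy|mad1|mad2|bp[0-9]+)$",
                     "", feature_names)
  structure(
    list(x = x, stress = as.integer(d$stress),
         identity = as.integer(d$subject_id), feature_names = feature_names,
         modality = modality_of,
         n_subjects = length(unique(d$subject_id))),
    class = "feature_dataset"
  )
}
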