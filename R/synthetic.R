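# Synthetic multimodal physiological signal generator.
#
# The generator emulates the structure a stress-recognition pipeline needs to
# see in wearable data without claiming physiological realism: per-subject
# baseline offsets and a narrow-band oscillatory "signature" carry identity
# information; a binary stress state modulates level (EDA, skin temperature),
# dominant frequency (BVP, ECG) or variance (acceleration); residual noise is
# AR(1) Gaussian, i.e. temporally smooth.

# Canonical modality order used everywhere (feature blocks, file naming).
FS_MODALITIES <- c("eda", "bvp", "acc_x", "acc_y", "acc_z", "temp", "ecg")

# Per-modality generative constants. Columns:
#   rate      default sampling rate (Hz), mirroring the wrist+chest device mix
#   mu        population baseline level (signal units)
#   bsd       between-subject baseline spread at identity_strength = 1
#   g0        signature oscillation amplitude unit
#   f_lo/f_hi subject signature spectral peak range (Hz)
#   nsd       stationary sd of the AR(1) noise
#   c0        stress response unit; its meaning depends on `effect`
#   effect    which property stress modulates: level shift (c0 in signal
#             units), freq shift (c0 in Hz), or var multiplier (sd scaled by
#             1 + coef during stress)
fs_modality_table <- function() {
  data.frame(
    modality = FS_MODALITIES,
    rate   = c(4, 64, 32, 32, 32, 4, 700),
    mu     = c(2.0, 0.0, 0.0, 0.0, 0.0, 33.0, 0.0),
    bsd    = c(0.8, 0.2, 0.3, 0.3, 0.3, 0.7, 0.1),
    g0     = c(0.3, 1.0, 0.5, 0.5, 0.5, 0.2, 0.8),
    f_lo   = c(0.05, 0.8, 0.5, 0.5, 0.5, 0.01, 0.9),
    f_hi   = c(0.5, 1.5, 3.0, 3.0, 3.0, 0.1, 1.6),
    nsd    = c(0.15, 0.5, 0.25, 0.25, 0.25, 0.1, 0.3),
    c0     = c(1.0, 0.3, 0.8, 0.8, 0.8, -0.5, 0.3),
    effect = c("level", "freq", "var", "var", "var", "level", "freq"),
    stringsAsFactors = FALSE
  )
}

#' Default per-modality sampling rates
#'
#' Mirrors the wrist/chest wearable family: EDA and skin temperature at 4 Hz,
#' acceleration at 32 Hz, blood volume pulse at 64 Hz, ECG at 700 Hz.
#'
#' @param modalities Character vector of modality names (subset of
#'   `eda, bvp, acc_x, acc_y, acc_z, temp, ecg`).
#' @return Named numeric vector of rates in Hz.
#' @export
#' @examples
#' default_rates(c("eda", "bvp"))
default_rates <- function(modalities = FS_MODALITIES) {
  tab <- fs_modality_table()
  check_modalities(modalities)
  stats::setNames(tab$rate[match(modalities, tab$modality)], modalities)
}

#' Uniform sampling rates across modalities
#'
#' All requested channels at one rate. With a single rate the fixed-length
#' window segmentation is time-aligned across modalities, which keeps
#' windowing behaviour independent of any resampling choice.
#'
#' @param rate Sampling rate in Hz applied to every modality.
#' @inheritParams default_rates
#' @return Named numeric vector of rates.
#' @export
uniform_rates <- function(rate = 4, modalities = c("eda", "bvp", "acc_x",
                                                   "acc_y", "acc_z", "temp")) {
  check_modalities(modalities)
  stats::setNames(rep(rate, length(modalities)), modalities)
}

check_modalities <- function(modalities) {
  bad <- setdiff(modalities, FS_MODALITIES)
  if (length(bad) > 0L) {
    stop_fs("unknown_modality", "unknown modality: %s", paste(bad, collapse = ", "))
  }
  invisible(modalities)
}

#' Draw subject profiles for the synthetic generator
#'
#' Each subject gets, per modality (in canonical order `eda, bvp, acc_x,
#' acc_y, acc_z, temp, ecg` restricted to `modalities`), four quantities drawn
#' in this exact sequence from one seeded stream:
#' \enumerate{
#'   \item baseline level: `mu + identity_strength * bsd * rnorm(1)`;
#'   \item signature gain: `identity_strength * g0 * (0.5 + abs(rnorm(1)))`;
#'   \item signature spectral peak: `runif(1, f_lo, f_hi)` Hz;
#'   \item stress coefficient: `stress_effect * c0 * runif(1, 0.8, 1.2)`.
#' }
#' The per-modality constants `mu, bsd, g0, f_lo, f_hi, c0` are fixed
#' generator constants (see `fedstress:::fs_modality_table`). The draw order
#' is part of the contract so the profile statistics can be re-derived
#' independently.
#'
#' `identity_strength = 0` makes all subjects share identical baselines and
#' zero signature gains (no identity signal); `stress_effect = 0` zeroes every
#' stress coefficient (no stress signal).
#'
#' @param n_subjects Number of subjects (>= 1). Subject ids are `0:(n-1)`.
#' @param identity_strength Non-negative scale of between-subject differences.
#' @param stress_effect Non-negative scale of the stress-state response.
#' @param modalities Modalities to parameterise.
#' @param seed Integer seed; fixed seed gives bit-identical profiles.
#' @return List of `subject_profile` objects with fields `subject_id`,
#'   `baseline`, `gain`, `peak_hz`, `stress_coef` (named per modality).
#' @export
#' @examples
#' p <- make_profiles(3, identity_strength = 1, stress_effect = 1, seed = 7)
#' p[[1]]$baseline
make_profiles <- function(n_subjects, identity_strength = 1, stress_effect = 1,
                          modalities = c("eda", "bvp", "acc_x", "acc_y",
                                         "acc_z", "temp"),
                          seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1) {
    stop_fs("invalid_argument", "n_subjects must be >= 1")
  }
  if (identity_strength < 0 || stress_effect < 0) {
    stop_fs("invalid_argument", "strength parameters must be >= 0")
  }
  check_modalities(modalities)
  modalities <- FS_MODALITIES[FS_MODALITIES %in% modalities]
  tab <- fs_modality_table()
  tab <- tab[match(modalities, tab$modality), ]
  n_subjects <- as.integer(n_subjects)

  with_seed(seed, {
    lapply(seq_len(n_subjects) - 1L, function(sid) {
      baseline <- gain <- peak <- coef <- stats::setNames(
        numeric(length(modalities)), modalities)
      for (i in seq_along(modalities)) {
        baseline[i] <- tab$mu[i] + identity_strength * tab$bsd[i] * stats::rnorm(1)
        gain[i] <- identity_strength * tab$g0[i] * (0.5 + abs(stats::rnorm(1)))
        peak[i] <- stats::runif(1, tab$f_lo[i], tab$f_hi[i])
        coef[i] <- stress_effect * tab$c0[i] * stats::runif(1, 0.8, 1.2)
      }
      structure(
        list(subject_id = sid, baseline = baseline, gain = gain,
             peak_hz = peak, stress_coef = coef,
             identity_strength = identity_strength,
             stress_effect = stress_effect),
        class = "subject_profile"
      )
    })
  })
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> id=%d, modalities: %s\n",
              x$subject_id, paste(names(x$baseline), collapse = ", ")))
  invisible(x)
}

#' Alternating stress/non-stress session schedule
#'
#' Convenience builder for a block schedule alternating the two states,
#' starting with non-stress.
#'
#' @param n_blocks Number of blocks.
#' @param block_s Duration of each block in seconds.
#' @return Data frame with columns `state` ("nonstress"/"stress") and
#'   `duration` (seconds), the schedule format taken by
#'   [simulate_recording()].
#' @export
make_schedule <- function(n_blocks = 4, block_s = 700) {
  data.frame(
    state = rep(c("nonstress", "stress"), length.out = n_blocks),
    duration = rep(block_s, n_blocks),
    stringsAsFactors = FALSE
  )
}

#' Simulate one multimodal recording
#'
#' Generates, per channel `m`, samples
#' `x_t = baseline_m + gain_m * sin(2*pi*f_t*t + phase_m) + level_t + e_t`
#' where the stress state at time `t` modulates the channel according to its
#' effect type: level shift (`level_t = stress_coef` during stress; EDA,
#' temperature), dominant-frequency shift (`f_t = peak + stress_coef` during
#' stress; BVP, ECG) or variance shift (AR(1) innovation sd multiplied by
#' `1 + stress_coef` during stress; acceleration). `e_t` is AR(1) noise
#' `e_t = noise_ar * e_{t-1} + sqrt(1 - noise_ar^2) * nsd * z_t` with
#' stationary sd `nsd`. Phases are drawn once per channel from the seed.
#'
#' @param profile A `subject_profile` from [make_profiles()].
#' @param schedule Data frame with columns `state` in
#'   `{"nonstress","stress"}` and `duration` (seconds, > 0).
#' @param rates Named vector of sampling rates (Hz); see [default_rates()] and
#'   [uniform_rates()]. Must be a subset of the profile's modalities.
#' @param noise_ar AR(1) coefficient in \[0, 1).
#' @param seed Integer seed; identical (profile, schedule, seed) give an
#'   identical recording.
#' @return A `multimodal_recording`: list with `channels` (named list of
#'   numeric vectors), `rates`, `states` (0/1 per sample at `ref_rate`),
#'   `ref_rate` (the fastest channel rate), `subject_id`, `duration`.
#' @export
#' @examples
#' pr <- make_profiles(1, seed = 1)[[1]]
#' rec <- simulate_recording(pr, make_schedule(2, 10),
#'                           rates = uniform_rates(4, c("eda", "temp")),
#'                           seed = 3)
#' lengths(rec$channels)
simulate_recording <- function(profile, schedule, rates = NULL,
                               noise_ar = 0.6, seed = 1L) {
  stopifnot(inherits(profile, "subject_profile"))
  if (is.null(rates)) rates <- default_rates(names(profile$baseline))
  if (NROW(schedule) == 0L) stop_fs("invalid_argument", "empty schedule")
  if (any(schedule$duration <= 0)) {
    stop_fs("invalid_argument", "schedule durations must be > 0")
  }
  if (any(rates <= 0)) stop_fs("invalid_argument", "rates must be > 0")
  check_modalities(names(rates))
  missing_m <- setdiff(names(rates), names(profile$baseline))
  if (length(missing_m) > 0L) {
    stop_fs("unknown_modality", "profile lacks modality: %s",
            paste(missing_m, collapse = ", "))
  }
  if (noise_ar < 0 || noise_ar >= 1) {
    stop_fs("invalid_argument", "noise_ar must lie in [0, 1)")
  }

  tab <- fs_modality_table()
  duration <- sum(schedule$duration)
  state01 <- as.integer(schedule$state == "stress")
  ref_rate <- max(rates)

  # state label for sample index i at rate r: state at time (i - 1) / r;
  # block boundaries belong to the following block
  states_at <- function(rate) {
    n <- as.integer(round(duration * rate))
    t_start <- (seq_len(n) - 1L) / rate
    edges <- cumsum(schedule$duration)
    idx <- pmin(findInterval(t_start, edges) + 1L, length(state01))
    state01[idx]
  }

  channels <- vector("list", length(rates))
  names(channels) <- names(rates)
  with_seed(seed, {
    for (m in names(rates)) {
      r <- rates[[m]]
      n <- as.integer(round(duration * r))
      tt <- (seq_len(n) - 1L) / r
      st <- states_at(r)
      row <- tab[tab$modality == m, ]
      phase <- stats::runif(1, 0, 2 * pi)
      coef <- profile$stress_coef[[m]]

      freq <- rep(profile$peak_hz[[m]], n)
      level <- numeric(n)
      sd_mult <- rep(1, n)
      if (row$effect == "level") level <- coef * st
      if (row$effect == "freq")  freq <- freq + coef * st
      if (row$effect == "var")   sd_mult <- 1 + abs(coef) * st

      # integrate instantaneous frequency so frequency shifts are phase-continuous
      ph <- phase + 2 * pi * cumsum(freq) / r
      osc <- profile$gain[[m]] * sin(ph)

      innov <- stats::rnorm(n) * sqrt(1 - noise_ar^2) * row$nsd * sd_mult
      noise <- if (noise_ar > 0) {
        as.numeric(stats::filter(innov, noise_ar, method = "recursive"))
      } else innov

      channels[[m]] <- profile$baseline[[m]] + osc + level + noise
    }
  })

  structure(
    list(channels = channels, rates = rates, states = states_at(ref_rate),
         ref_rate = ref_rate, subject_id = profile$subject_id,
         duration = duration, schedule = schedule, noise_ar = noise_ar),
    class = "multimodal_recording"
  )
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat(sprintf("<multimodal_recording> subject=%d, %ds, channels: %s\n",
              x$subject_id, x$duration,
              paste(sprintf("%s@%gHz", names(x$rates), x$rates), collapse = ", ")))
  invisible(x)
}

#' Separability presets
#'
#' Named generator operating points used by the experiment suite. `high`
#' yields strongly separable identity and stress structure, `medium` a
#' mid-range operating point away from both chance and ceiling, `null` no
#' signal at all (both tasks at chance).
#'
#' @param name One of "high", "medium", "null".
#' @return List with `identity_strength` and `stress_effect`.
#' @export
preset_conditions <- function(name = c("high", "medium", "null")) {
  name <- match.arg(name)
  switch(name,
    high = list(identity_strength = 1.0, stress_effect = 2.0),
    medium = list(identity_strength = 0.5, stress_effect = 1.0),
    null = list(identity_strength = 0, stress_effect = 0)
  )
}

#' Simulate a cohort of recordings
#'
#' One recording per subject under a shared alternating schedule. The
#' default block length (700 s, four window spans at the 4 Hz uniform rate)
#' keeps most windows inside a single state block, mirroring the long
#' condition blocks of laboratory stress protocols.
#'
#' @inheritParams make_profiles
#' @param n_blocks Number of alternating schedule blocks per subject.
#' @param block_s Block duration (seconds).
#' @param rates Named rate vector shared by all subjects.
#' @param noise_ar AR(1) noise coefficient.
#' @param seed Master seed; per-subject recording seeds are derived from it.
#' @return List of `multimodal_recording`.
#' @export
simulate_cohort <- function(n_subjects, identity_strength = 1,
                            stress_effect = 1, n_blocks = 8, block_s = 700,
                            rates = uniform_rates(4), noise_ar = 0.6,
                            seed = 1L) {
  profiles <- make_profiles(n_subjects, identity_strength, stress_effect,
                            modalities = names(rates), seed = seed)
  sched <- make_schedule(n_blocks, block_s)
  lapply(profiles, function(p) {
    simulate_recording(p, sched, rates = rates, noise_ar = noise_ar,
                       seed = derive_seed(seed, 7L, p$subject_id))
  })
}

#' Write/read a recording in the columnar text format
#'
#' One CSV file per (subject, modality): a header comment
#' `# modality=<name> rate=<Hz> subject=<id>` followed by
#' `sample_index,value,state` rows. Values are printed with \code{\%.17g} so
#' doubles round-trip bit-exactly.
#'
#' @param recording A `multimodal_recording`.
#' @param dir Output directory (created if needed).
#' @return `write_recording` invisibly returns the written file paths;
#'   `read_recording` returns a `multimodal_recording` (schedule-free).
#' @export
write_recording <- function(recording, dir) {
  stopifnot(inherits(recording, "multimodal_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in names(recording$channels)) {
    x <- recording$channels[[m]]
    r <- recording$rates[[m]]
    st <- channel_states(recording, m)
    path <- file.path(dir, sprintf("subject%03d_%s.csv", recording$subject_id, m))
    con <- file(path, open = "wb")  # binary mode => LF on every platform
    writeLines(sprintf("# modality=%s rate=%s subject=%d",
                       m, format_full(r), recording$subject_id), con, sep = "\n")
    writeLines("sample_index,value,state", con, sep = "\n")
    writeLines(sprintf("%d,%s,%d", seq_along(x) - 1L, format_full(x), st),
               con, sep = "\n")
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

# Per-sample 0/1 states of one channel, derived from the reference-rate track.
channel_states <- function(recording, modality) {
  r <- recording$rates[[modality]]
  n <- length(recording$channels[[modality]])
  idx <- floor((seq_len(n) - 1L) / r * recording$ref_rate) + 1L
  idx <- pmin(idx, length(recording$states))
  recording$states[idx]
}

#' @rdname write_recording
#' @param paths Character vector of files written by [write_recording()]
#'   (all belonging to one subject).
#' @export
read_recording <- function(paths) {
  channels <- list(); rates <- numeric(0)
  subject <- NA_integer_
  for (path in paths) {
    hdr <- readLines(path, n = 1L)
    kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
    kv <- strsplit(kv, "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    m <- vals[["modality"]]
    r <- as.numeric(vals[["rate"]])
    subject <- as.integer(vals[["subject"]])
    d <- utils::read.csv(path, comment.char = "#")
    channels[[m]] <- d$value
    rates[[m]] <- r
  }
  ref_m <- names(rates)[which.max(rates)]
  d <- utils::read.csv(paths[[which(names(channels) == ref_m)]], comment.char = "#")
  structure(
    list(channels = channels, rates = rates, states = as.integer(d$state),
         ref_rate = max(rates), subject_id = subject,
         duration = length(channels[[ref_m]]) / max(rates), schedule = NULL,
         noise_ar = NA_real_),
    class = "multimodal_recording"
  )
}
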