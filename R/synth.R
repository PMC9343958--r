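#' Configuration for the synthetic gustatory-EEG generator
#'
#' Describes a stated world: two-channel (C3/C4) 512 Hz recordings of 16 s,
#' one per (subject, session, stimulus), in which class identity is encoded
#' purely as band-limited oscillatory power inside the 8--40 Hz analysis band,
#' riding on a 1/f^alpha background. The oscillation is modulated by an
#' onset-rise-then-decay envelope so that taste-evoked activity increases
#' after stimulus onset and decays towards the end of the trial.
#'
#' @param n_subjects number of subjects (default 11).
#' @param n_sessions_per_subject sessions per subject (default 3).
#' @param classes ordered stimulus labels; must be 4 distinct labels
#'   (default water, sucrose, aspartame, sucralose).
#' @param fs sampling rate in Hz (default 512).
#' @param duration_s trial duration in seconds (default 16).
#' @param n_channels channel count (default 2).
#' @param channel_labels channel names (default C3, C4).
#' @param class_profiles named list, one entry per class, each a matrix (or
#'   coercible) with columns `center`, `bw`, `power`: center frequency (Hz,
#'   must lie in \[8, 40\]), full bandwidth (Hz) and relative power of one
#'   band-limited component. Defaults place one component per class at
#'   10, 16, 24 and 32 Hz with 4 Hz bandwidth and unit power.
#' @param effect_size nonnegative scalar multiplying the class-specific
#'   oscillation amplitude; 0 makes all classes statistically identical.
#' @param background_exponent slope alpha of the 1/f^alpha background
#'   (default 1).
#' @param background_sd standard deviation of the background in microvolts
#'   (default 10).
#' @param envelope numeric length-2: onset rise time and decay time constant,
#'   seconds (default c(1, 8)).
#' @param artifact_rate expected high-amplitude artifacts per recording
#'   (default 0: clean recordings; screening tests opt in).
#' @param artifact_amplitude artifact peak amplitude in microvolts
#'   (default 150).
#' @param noise_sd additive broadband (white) noise SD in microvolts
#'   (default 1).
#' @param osc_sd microvolt scale of a unit-power class oscillation component
#'   at effect_size 1 (default 5).
#' @param seed master integer seed; per-recording seeds are hashed from it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 11,
                         n_sessions_per_subject = 3,
                         classes = c("water", "sucrose", "aspartame", "sucralose"),
                         fs = 512,
                         duration_s = 16,
                         n_channels = 2,
                         channel_labels = c("C3", "C4"),
                         class_profiles = NULL,
                         effect_size = 1,
                         background_exponent = 1,
                         background_sd = 10,
                         envelope = c(1, 8),
                         artifact_rate = 0,
                         artifact_amplitude = 150,
                         noise_sd = 1,
                         osc_sd = 5,
                         seed = 1L) {
  if (fs <= 0) input_error("synth_config", "fs must be positive, got %g", fs)
  if (duration_s <= 0)
    input_error("synth_config", "duration_s must be positive, got %g", duration_s)
  if (effect_size < 0)
    input_error("synth_config", "effect_size must be nonnegative, got %g", effect_size)
  classes <- as.character(classes)
  if (length(classes) != 4 || anyDuplicated(classes))
    input_error("synth_config", "classes must be 4 distinct labels")
  if (length(channel_labels) != n_channels)
    input_error("synth_config", "channel_labels length must equal n_channels")
  if (is.null(class_profiles)) {
    centers <- c(10, 16, 24, 32)
    class_profiles <- lapply(seq_along(classes), function(i)
      cbind(center = centers[i], bw = 4, power = 1))
    names(class_profiles) <- classes
  }
  class_profiles <- lapply(class_profiles, function(p) {
    p <- matrix(as.numeric(p), ncol = 3,
                dimnames = list(NULL, c("center", "bw", "power")))
    if (any(p[, "center"] < 8 | p[, "center"] > 40))
      input_error("synth_config", "profile centers must lie within [8, 40] Hz")
    p
  })
  if (!setequal(names(class_profiles), classes))
    input_error("synth_config", "class_profiles must be named by the class labels")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions_per_subject = as.integer(n_sessions_per_subject),
                 classes = classes, fs = fs, duration_s = duration_s,
                 n_channels = as.integer(n_channels),
                 channel_labels = channel_labels,
                 class_profiles = class_profiles,
                 effect_size = effect_size,
                 background_exponent = background_exponent,
                 background_sd = background_sd,
                 envelope = as.numeric(envelope),
                 artifact_rate = artifact_rate,
                 artifact_amplitude = artifact_amplitude,
                 noise_sd = noise_sd, osc_sd = osc_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("<synth_config> %d subjects x %d sessions x %d classes, %g Hz, %g s, effect size %g\n",
              x$n_subjects, x$n_sessions_per_subject, length(x$classes),
              x$fs, x$duration_s, x$effect_size))
  invisible(x)
}

# FFT-shaped coloured noise: white gaussian spectrum scaled by |f|^(-alpha/2),
# returned with unit standard deviation. DC removed.
colored_noise <- function(n, fs, alpha) {
  x <- rnorm(n)
  xf <- fft(x)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n     # two-sided frequency magnitude
  g <- c(0, f[-1]^(-alpha / 2))
  y <- Re(fft(xf * g, inverse = TRUE)) / n
  y / sd(y)
}

# Band-limited gaussian noise with a gaussian spectral bump at `center`
# (full bandwidth `bw`), unit standard deviation.
band_noise <- function(n, fs, center, bw) {
  x <- rnorm(n)
  xf <- fft(x)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n
  g <- exp(-0.5 * ((f - center) / (bw / 2))^2)
  y <- Re(fft(xf * g, inverse = TRUE)) / n
  y / sd(y)
}

# Onset envelope: rises over `rise` seconds, then decays exponentially with
# time constant `decay`.
onset_envelope <- function(t, rise, decay) {
  (1 - exp(-t / rise)) * exp(-pmax(0, t - rise) / decay)
}

#' Generate one synthetic EEG recording
#'
#' The signal per channel is the sum of a 1/f^alpha background, the
#' class-profile band-limited oscillations (scaled by `effect_size` and
#' modulated by the onset envelope) and broadband white noise. Identical
#' `(config, stimulus, ids, seed)` give bit-identical output.
#'
#' @param config a [synth_config()].
#' @param stimulus class label; must be one of `config$classes`.
#' @param subject_id,session_id identifiers recorded in the metadata.
#' @param seed integer seed for this recording; by default hashed from
#'   `config$seed` and the identifiers.
#' @return an object of class `eeg_recording` with fields `samples`
#'   (channels x time matrix, microvolts), `fs`, `channel_labels`,
#'   `stimulus`, `subject_id`, `session_id`, `recording_id`.
#' @export
generate_recording <- function(config, stimulus, subject_id = 1,
                               session_id = 1, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!stimulus %in% config$classes)
    input_error("generate_recording", "unknown stimulus label '%s'", stimulus)
  if (is.null(seed))
    seed <- hash_seed(config$seed, subject_id, session_id, stimulus)
  n <- round(config$fs * config$duration_s)
  t <- (seq_len(n) - 1L) / config$fs
  env <- onset_envelope(t, config$envelope[1], config$envelope[2])
  prof <- config$class_profiles[[stimulus]]
  samples <- with_seed(seed, {
    m <- matrix(0, config$n_channels, n)
    for (ch in seq_len(config$n_channels)) {
      sig <- config$background_sd * colored_noise(n, config$fs, config$background_exponent)
      for (r in seq_len(nrow(prof))) {
        osc <- band_noise(n, config$fs, prof[r, "center"], prof[r, "bw"])
        sig <- sig + config$effect_size * config$osc_sd * prof[r, "power"] * env * osc
      }
      m[ch, ] <- sig + config$noise_sd * rnorm(n)
    }
    m
  })
  rownames(samples) <- config$channel_labels
  rec <- structure(list(samples = samples, fs = config$fs,
                        channel_labels = config$channel_labels,
                        stimulus = stimulus,
                        subject_id = subject_id, session_id = session_id,
                        recording_id = sprintf("S%02d_R%02d_%s",
                                               as.integer(subject_id),
                                               as.integer(session_id), stimulus)),
                   class = "eeg_recording")
  if (config$artifact_rate > 0)
    rec <- inject_artifacts(rec, config$artifact_rate,
                            config$artifact_amplitude,
                            seed = hash_seed(seed, "artifacts"))
  rec
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %d ch x %d samples @ %g Hz, stimulus %s\n",
              x$recording_id, nrow(x$samples), ncol(x$samples), x$fs, x$stimulus))
  invisible(x)
}

#' Generate a full balanced synthetic dataset
#'
#' One recording per (subject, session, class); per-recording seeds are
#' hashed from `config$seed` and the identifiers, so the manifest and every
#' sample array are reproducible, and any single recording can be regenerated
#' alone.
#'
#' @param config a [synth_config()].
#' @return an object of class `recording_set`: list with `recordings` (list of
#'   [generate_recording()] results) and `manifest` (data.frame with columns
#'   recording_id, subject, session, stimulus, path).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  grid <- expand.grid(stimulus = config$classes,
                      session = seq_len(config$n_sessions_per_subject),
                      subject = seq_len(config$n_subjects),
                      stringsAsFactors = FALSE)
  recs <- lapply(seq_len(nrow(grid)), function(i)
    generate_recording(config, grid$stimulus[i], grid$subject[i], grid$session[i]))
  manifest <- data.frame(
    recording_id = vapply(recs, `[[`, character(1), "recording_id"),
    subject = grid$subject, session = grid$session,
    stimulus = grid$stimulus, path = NA_character_,
    stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$recording_id))
    input_error("generate_dataset", "recording ids are not unique")
  structure(list(recordings = recs, manifest = manifest),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set> %d recordings, classes: %s\n",
              length(x$recordings),
              paste(names(table(x$manifest$stimulus)), collapse = ", ")))
  invisible(x)
}

#' Inject transient high-amplitude artifacts into a recording
#'
#' Adds `rpois(1, rate)` gaussian-shaped transients (50 ms width) at uniform
#' random positions on random channels. Each transient's sign matches the
#' underlying sample so the absolute peak is at least `amplitude`. The input
#' recording is not modified.
#'
#' @param recording an `eeg_recording`.
#' @param rate expected artifact count (Poisson mean); must be nonnegative.
#' @param amplitude peak amplitude in microvolts.
#' @param seed integer seed.
#' @return a new `eeg_recording`.
#' @export
inject_artifacts <- function(recording, rate, amplitude = 500, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (rate < 0) input_error("inject_artifacts", "rate must be nonnegative, got %g", rate)
  if (rate == 0) return(recording)
  n <- ncol(recording$samples)
  width <- max(3L, round(0.05 * recording$fs))
  half <- floor(width / 2)
  shape <- exp(-0.5 * ((seq_len(width) - half - 1) / (width / 6))^2)
  with_seed(seed, {
    k <- rpois(1, rate)
    if (k > 0) {
      for (i in seq_len(k)) {
        ch <- sample.int(nrow(recording$samples), 1)
        pos <- sample.int(n - width + 1L, 1)
        idx <- pos:(pos + width - 1L)
        sgn <- sign(recording$samples[ch, pos + half])
        if (sgn == 0) sgn <- 1
        recording$samples[ch, idx] <- recording$samples[ch, idx] +
          sgn * amplitude * shape
      }
    }
  })
  recording
}

#' Write a recording set to disk
#'
#' One plain-text CSV per recording (one column per channel, header row of
#' channel labels) plus `manifest.csv` with columns
#' recording_id,subject,session,stimulus,path.
#'
#' @param rs a `recording_set`.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame with resolved paths, invisibly.
#' @export
write_recording_set <- function(rs, dir) {
  stopifnot(inherits(rs, "recording_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(rs$recordings))
  for (i in seq_along(rs$recordings)) {
    rec <- rs$recordings[[i]]
    paths[i] <- file.path(dir, paste0(rec$recording_id, ".csv"))
    df <- as.data.frame(t(rec$samples))
    names(df) <- rec$channel_labels
    write.csv(df, paths[i], row.names = FALSE)
  }
  manifest <- rs$manifest
  manifest$path <- paths
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a recording set from a manifest
#'
#' Inverse of [write_recording_set()]: reads the manifest CSV and the
#' per-recording tabular files it points to.
#'
#' @param manifest_path path to `manifest.csv`.
#' @param fs sampling rate in Hz of the stored signals (default 512; the
#'   tabular format does not carry it).
#' @return a `recording_set`.
#' @export
read_recording_set <- function(manifest_path, fs = 512) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("recording_id", "subject", "session", "stimulus", "path")
  if (!all(need %in% names(manifest)))
    input_error("read_recording_set", "manifest must have columns %s",
                paste(need, collapse = ","))
  base <- dirname(manifest_path)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    df <- read.csv(p, check.names = FALSE)
    structure(list(samples = t(as.matrix(df)), fs = fs,
                   channel_labels = names(df),
                   stimulus = manifest$stimulus[i],
                   subject_id = manifest$subject[i],
                   session_id = manifest$session[i],
                   recording_id = manifest$recording_id[i]),
              class = "eeg_recording")
  })
  structure(list(recordings = recs, manifest = manifest),
            class = "recording_set")
}
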