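#' Define a prosody profile
#'
#' A prosody profile summarizes the pitch and energy statistics of one
#' emotion/speaker group: mean fundamental frequency, its spread across
#' utterances, a contour shape, an RMS amplitude target and an additive-noise
#' SNR. Profiles drive the synthetic utterance generator, which stands in for
#' recorded emotional speech: happy speech is modeled with a higher, more
#' modulated pitch than sad speech, and male voices sit lower than female.
#'
#' @param label Emotion class: one of `"happy"`, `"sad"`, `"anger"`, `"fear"`.
#' @param gender Speaker group: `"male"` or `"female"`.
#' @param f0_mean Mean fundamental frequency in Hz, inside `[40, 600]` (the
#'   perceivable speech pitch range).
#' @param f0_sd Across-utterance standard deviation of the F0 offset, Hz,
#'   non-negative.
#' @param contour Contour shape over an utterance: `"flat"`, `"rising"`,
#'   `"falling"` or `"modulated"`.
#' @param amplitude RMS target of the voiced region, in `(0, 1]`.
#' @param noise_snr Signal-to-noise ratio of the additive Gaussian noise, dB.
#' @return A one-row tibble of class `prosody_profile`.
#' @export
#' @examples
#' prosody_profile("happy", "female", 240, 15, "modulated")
prosody_profile <- function(label, gender, f0_mean, f0_sd = 15,
                            contour = "flat", amplitude = 0.3,
                            noise_snr = 30) {
  label <- match.arg(label, c("happy", "sad", "anger", "fear"))
  gender <- match.arg(gender, c("male", "female"))
  contour <- match.arg(contour, c("flat", "rising", "falling", "modulated"))
  if (!is.numeric(f0_mean) || f0_mean < 40 || f0_mean > 600) {
    abort("`f0_mean` must lie in [40, 600] Hz.")
  }
  if (!is.numeric(f0_sd) || f0_sd < 0) abort("`f0_sd` must be >= 0.")
  if (!is.numeric(amplitude) || amplitude <= 0 || amplitude > 1) {
    abort("`amplitude` must lie in (0, 1].")
  }
  if (!is.finite(noise_snr)) abort("`noise_snr` must be finite.")
  out <- tibble(
    label = label, gender = gender, f0_mean = f0_mean, f0_sd = f0_sd,
    contour = contour, amplitude = amplitude, noise_snr = noise_snr
  )
  class(out) <- c("prosody_profile", class(out))
  out
}

#' Default happy/sad prosody profiles
#'
#' Four profiles (emotion crossed with gender) whose mean pitches reproduce
#' the ordering observed in emotional-speech corpora: happy above sad within
#' each gender, female above male within each emotion. Happy speech uses a
#' modulated contour (wide pitch excursion), sad speech a gently falling one
#' (narrow excursion), so both the mean and the range of the pitch carry
#' class information.
#'
#' @return A tibble with one row per profile.
#' @export
default_profiles <- function() {
  bind_rows(
    prosody_profile("happy", "female", 240, 15, "modulated"),
    prosody_profile("happy", "male",   180, 15, "modulated"),
    prosody_profile("sad",   "female", 170, 15, "falling"),
    prosody_profile("sad",   "male",   110, 15, "falling")
  )
}

contour_multiplier <- function(contour, t) {
  switch(contour,
    flat      = rep(1, length(t)),
    rising    = seq(0.95, 1.08, length.out = length(t)),
    falling   = seq(1.02, 0.98, length.out = length(t)),
    modulated = 1 + 0.06 * sin(2 * pi * 3 * t)
  )
}

#' Synthesize one emotional utterance
#'
#' Generates a harmonic-source utterance (first 10 harmonics with 1/k
#' amplitude roll-off) whose instantaneous F0 follows the profile's contour
#' around `f0_mean`, with a per-utterance offset drawn from `N(0, f0_sd)`.
#' The voiced region is scaled to the profile's RMS target; Gaussian noise at
#' the profile SNR is added throughout, so the leading/trailing silences
#' contain only noise well below the voiced level. The trailing silence must
#' be at least 2.5 s so the 2-s endpointing rule downstream always closes the
#' utterance.
#'
#' @param profile A [prosody_profile()] (one row).
#' @param duration Voiced duration in seconds, > 0.
#' @param leading_silence,trailing_silence Silence padding in seconds;
#'   `trailing_silence` must be >= 2.5.
#' @param rate Sample rate in Hz (16000).
#' @param seed Optional integer seed; fixed seed gives bit-identical audio.
#' @return An [audio_signal()] with attributes `f0_target` (the utterance's
#'   realized mean F0 in Hz), `f0_hz` (the instantaneous F0 track of the
#'   voiced region, one value per sample) and `voiced_span` (first/last
#'   voiced sample).
#' @export
#' @examples
#' p <- prosody_profile("happy", "female", 240, 0, "flat")
#' sig <- synthesize_utterance(p, duration = 1, seed = 1)
synthesize_utterance <- function(profile, duration = 1.2,
                                 leading_silence = 0.4,
                                 trailing_silence = 2.6,
                                 rate = 16000, seed = NULL) {
  stopifnot(inherits(profile, "prosody_profile"), nrow(profile) == 1)
  if (!is.numeric(duration) || duration <= 0) abort("`duration` must be > 0.")
  if (trailing_silence < 2.5) {
    abort("`trailing_silence` must be >= 2.5 s so endpointing always fires.")
  }
  if (leading_silence < 0) abort("`leading_silence` must be >= 0.")
  n_voiced <- round(duration * rate)
  if (n_voiced < 1) abort("Invalid duration/sample-rate combination: zero samples.")
  if (!is.null(seed)) set.seed(seed)

  t <- seq_len(n_voiced) / rate
  offset <- rnorm(1, 0, profile$f0_sd)
  f0 <- (profile$f0_mean + offset) * contour_multiplier(profile$contour, t)
  f0 <- pmin(pmax(f0, 40), 600)
  phase <- 2 * pi * cumsum(f0) / rate
  voiced <- rowSums(vapply(1:10, function(k) sin(k * phase) / k,
                           numeric(n_voiced)))
  # short raised-cosine ramps avoid onset/offset clicks
  n_ramp <- min(round(0.01 * rate), floor(n_voiced / 2))
  if (n_ramp > 0) {
    ramp <- (1 - cos(pi * seq_len(n_ramp) / n_ramp)) / 2
    voiced[seq_len(n_ramp)] <- voiced[seq_len(n_ramp)] * ramp
    voiced[n_voiced - n_ramp + seq_len(n_ramp)] <-
      voiced[n_voiced - n_ramp + seq_len(n_ramp)] * rev(ramp)
  }
  voiced <- voiced * profile$amplitude / rms(voiced)

  n_lead <- round(leading_silence * rate)
  n_trail <- round(trailing_silence * rate)
  x <- c(numeric(n_lead), voiced, numeric(n_trail))
  sigma <- profile$amplitude * 10^(-profile$noise_snr / 20)
  x <- x + rnorm(length(x), 0, sigma)

  out <- audio_signal(pmin(pmax(x, -1), 1), rate = rate)
  attr(out, "f0_target") <- profile$f0_mean + offset
  attr(out, "f0_hz") <- f0
  attr(out, "voiced_span") <- c(n_lead + 1L, n_lead + n_voiced)
  out
}

#' Generate a labeled synthetic speech dataset
#'
#' Produces `n_per_class` utterances for each prosody profile, with a truth
#' table recording file id, emotion label, gender and the per-utterance seed.
#' Deterministic for a fixed seed; class balance is exact by construction.
#'
#' @param n_per_class Utterances per profile, >= 1.
#' @param profiles Tibble of prosody profiles (default [default_profiles()]).
#' @param seed Integer seed governing per-utterance seeds and durations.
#' @param duration_range Voiced durations are drawn uniformly from this range
#'   (seconds).
#' @return A list with `signals` (named list of [audio_signal()]) and `truth`
#'   (tibble: file, label, gender, seed).
#' @export
make_dataset <- function(n_per_class, profiles = default_profiles(), seed = 1,
                         duration_range = c(1.0, 1.5)) {
  if (n_per_class < 1) abort("`n_per_class` must be >= 1.")
  if (nrow(profiles) == 0) abort("`profiles` must be non-empty.")
  key <- paste(profiles$label, profiles$gender)
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate profile identifiers: %s", key[duplicated(key)][1]))
  }
  set.seed(seed)
  n_total <- nrow(profiles) * n_per_class
  utt_seeds <- sample.int(.Machine$integer.max, n_total)
  durations <- runif(n_total, duration_range[1], duration_range[2])

  signals <- vector("list", n_total)
  rows <- vector("list", n_total)
  idx <- 0L
  for (p in seq_len(nrow(profiles))) {
    prof <- profiles[p, ]
    class(prof) <- c("prosody_profile", class(tibble()))
    for (i in seq_len(n_per_class)) {
      idx <- idx + 1L
      id <- sprintf("%s_%s_%03d", prof$label, substr(prof$gender, 1, 1), i)
      signals[[idx]] <- synthesize_utterance(
        prof, duration = durations[idx], seed = utt_seeds[idx]
      )
      rows[[idx]] <- tibble(file = id, label = prof$label,
                            gender = prof$gender, seed = utt_seeds[idx])
    }
  }
  truth <- bind_rows(rows)
  names(signals) <- truth$file
  list(signals = signals, truth = truth)
}

#' Generate a colored cue-card image
#'
#' A `size` x `size` RGB image that is uniformly the requested primary color,
#' with `noise_fraction` of the pixels replaced by uniformly random colors.
#' The noise fraction is capped below 0.4 so the requested channel always
#' retains the majority of the pixel mass.
#'
#' @param color `"red"` or `"blue"`.
#' @param noise_fraction Fraction of randomized pixels, in `[0, 0.4)`.
#' @param size Image side length in pixels.
#' @param seed Optional integer seed for the noise pattern.
#' @return A numeric `size x size x 3` array with values in 0..255.
#' @export
#' @examples
#' img <- make_card_image("blue", noise_fraction = 0.2, seed = 1)
#' dominant_color(img)
make_card_image <- function(color, noise_fraction = 0, size = 32, seed = NULL) {
  color <- match.arg(color, c("red", "blue"))
  if (!is.numeric(noise_fraction) || noise_fraction < 0 || noise_fraction >= 0.4) {
    abort("`noise_fraction` must lie in [0, 0.4): beyond that the majority color is not guaranteed.")
  }
  if (size < 1) abort("`size` must be >= 1.")
  if (!is.null(seed)) set.seed(seed)
  img <- array(0, dim = c(size, size, 3))
  channel <- if (color == "red") 1 else 3
  img[, , channel] <- 255
  n_noise <- round(noise_fraction * size^2)
  if (n_noise > 0) {
    pix <- sample.int(size^2, n_noise)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[pix] <- sample(0:255, n_noise, replace = TRUE)
      img[, , ch] <- plane
    }
  }
  img
}

#' Write a cue-card image as PNG
#'
#' @param img Array from [make_card_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_card_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Write a dataset to disk as WAV files plus a truth CSV
#'
#' @param dataset Result of [make_dataset()].
#' @param dir Output directory (created if needed).
#' @return The truth-table path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$signals)) {
    write_wav(dataset$signals[[id]], file.path(dir, paste0(id, ".wav")))
  }
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(dataset$truth, truth_path, row.names = FALSE)
  invisible(truth_path)
}
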