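# Shared fixtures built in code.

flat_profile <- function(f0, sd = 0, label = "happy", gender = "female",
                         contour = "flat", amplitude = 0.3, snr = 30) {
  prosody_profile(label, gender, f0, sd, contour, amplitude, snr)
}

# a short utterance with the default silence padding
tone_utterance <- function(f0, duration = 0.8, seed = 1, contour = "flat",
                           sd = 0) {
  synthesize_utterance(flat_profile(f0, sd = sd, contour = contour),
                       duration = duration, leading_silence = 0.4,
                       trailing_silence = 2.6, seed = seed)
}

# small labeled feature table with well-separated classes (no audio needed)
toy_features <- function(n = 20, seed = 1) {
  set.seed(seed)
  happy <- tibble::tibble(
    pitch_mean = rnorm(n, 230, 12), pitch_min = rnorm(n, 205, 10),
    pitch_max = rnorm(n, 260, 10), pitch_range = abs(rnorm(n, 30, 5)),
    energy_mean = abs(rnorm(n, 0.3, 0.03)), label = "happy"
  )
  sad <- tibble::tibble(
    pitch_mean = rnorm(n, 140, 12), pitch_min = rnorm(n, 130, 10),
    pitch_max = rnorm(n, 150, 10), pitch_range = abs(rnorm(n, 6, 2)),
    energy_mean = abs(rnorm(n, 0.25, 0.03)), label = "sad"
  )
  dplyr::bind_rows(happy, sad)
}

# confusion matrix counts as printed in the bundled benchmark tables
human_counts <- matrix(
  c(62, 3, 5, 0,
    5, 62, 1, 2,
    5, 8, 56, 1,
    0, 1, 1, 68),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("Anger", "Fear", "Happy", "Sad"),
                  c("Anger", "Fear", "Happy", "Sad"))
)
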