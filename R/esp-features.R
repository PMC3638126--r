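#' Segment a pitch contour into utterances
#'
#' A window counts as speech when its energy exceeds the dynamic threshold
#' (`voicing_energy_factor` times the noise floor, the 10th percentile of
#' all window energies). Speech windows are accumulated into the current
#' utterance; windows below threshold are discarded. When at least two
#' seconds of consecutive non-speech accumulate (67 windows at the default
#' 481-sample hop and 16 kHz) the utterance is closed. Gaps shorter than two
#' seconds do not split an utterance.
#'
#' @param contour A `pitch_contour` from [estimate_pitch()].
#' @param cfg The [pitch_config()] used (defaults to the contour's own).
#' @return A tibble with one row per retained speech window: `utterance`
#'   (1-based id), `frame`, `start_sample`, `time_s`, `f0`, `energy`,
#'   `voiced`. Zero rows if no speech is present.
#' @export
segment_utterances <- function(contour, cfg = NULL) {
  stopifnot(inherits(contour, "pitch_contour"))
  cfg <- cfg %||% attr(contour, "cfg")
  rate <- attr(contour, "rate")
  hop <- attr(contour, "hop")
  if (nrow(contour) == 0) abort("Contour is empty.")
  gap_windows <- ceiling(2 * rate / hop)

  noise_floor <- quantile(contour$energy, 0.1, names = FALSE)
  speech <- contour$energy > cfg$voicing_energy_factor * noise_floor

  utt_id <- 0L
  open <- FALSE
  silence_run <- 0L
  ids <- rep(NA_integer_, nrow(contour))
  for (i in seq_len(nrow(contour))) {
    if (speech[i]) {
      if (!open) {
        utt_id <- utt_id + 1L
        open <- TRUE
      }
      silence_run <- 0L
      ids[i] <- utt_id
    } else {
      silence_run <- silence_run + 1L
      if (open && silence_run >= gap_windows) open <- FALSE
    }
  }
  keep <- !is.na(ids)
  out <- as_tibble(contour[keep, c("frame", "start_sample", "time_s",
                                   "f0", "energy", "voiced")])
  out <- tibble(utterance = ids[keep], out)
  # an utterance must contain at least one voiced window to be usable
  out
}

#' Extract the five-element prosodic feature vector
#'
#' Computes the mean, minimum, maximum and range of the pitch over the
#' voiced windows of one utterance, plus the mean speech energy (linear RMS)
#' over those windows.
#'
#' @param utt Tibble of one utterance's windows (columns `f0`, `energy`,
#'   `voiced`), e.g. one `utterance` group from [segment_utterances()].
#' @return A one-row tibble: `pitch_mean`, `pitch_min`, `pitch_max`,
#'   `pitch_range`, `energy_mean`, `n_voiced`.
#' @export
extract_features <- function(utt) {
  v <- utt[utt$voiced & !is.na(utt$f0), ]
  if (nrow(v) == 0) abort("Unvoiced utterance: no voiced windows to summarize.")
  tibble(
    pitch_mean = mean(v$f0),
    pitch_min = min(v$f0),
    pitch_max = max(v$f0),
    pitch_range = max(v$f0) - min(v$f0),
    energy_mean = mean(v$energy),
    n_voiced = nrow(v)
  )
}

#' Pitch-track, endpoint and featurize a signal in one call
#'
#' @param signal An [audio_signal()].
#' @param cfg A [pitch_config()].
#' @return A tibble with one row per detected utterance (columns of
#'   [extract_features()] plus `utterance`); zero rows if no voiced
#'   utterance is found.
#' @export
esp_features <- function(signal, cfg = pitch_config()) {
  contour <- estimate_pitch(signal, cfg)
  if (nrow(contour) == 0) return(empty_features())
  segs <- segment_utterances(contour, cfg)
  if (nrow(segs) == 0) return(empty_features())
  ids <- sort(unique(segs$utterance))
  rows <- lapply(ids, function(id) {
    u <- segs[segs$utterance == id, ]
    if (!any(u$voiced)) return(NULL)
    tibble(utterance = id, extract_features(u))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) empty_features() else out
}

empty_features <- function() {
  tibble(utterance = integer(), pitch_mean = numeric(), pitch_min = numeric(),
         pitch_max = numeric(), pitch_range = numeric(),
         energy_mean = numeric(), n_voiced = integer())
}

#' Featurize a whole labeled dataset
#'
#' Runs [esp_features()] over every signal of a [make_dataset()] result and
#' joins the truth table. Signals yielding no utterance are dropped with a
#' warning.
#'
#' @param dataset A list with `signals` and `truth` as from [make_dataset()].
#' @param cfg A [pitch_config()].
#' @return A tibble: `file`, `label`, `gender`, feature columns (first
#'   utterance of each file).
#' @export
dataset_features <- function(dataset, cfg = pitch_config()) {
  rows <- lapply(names(dataset$signals), function(id) {
    ft <- esp_features(dataset$signals[[id]], cfg)
    if (nrow(ft) == 0) {
      warn(sprintf("No utterance detected in '%s'; dropped.", id))
      return(NULL)
    }
    tibble(file = id, ft[1, setdiff(names(ft), "utterance")])
  })
  feats <- bind_rows(rows)
  left_join(feats, dataset$truth, by = "file")
}

esp_feature_cols <- c("pitch_mean", "pitch_min", "pitch_max",
                      "pitch_range", "energy_mean")

#' Fit linear feature scaling on training data
#'
#' Learns per-feature (low, high) bounds from the training vectors and maps
#' them linearly onto `[-1, 1]`. Parameters are frozen from training data
#' only; test vectors outside the training range extrapolate beyond
#' `[-1, 1]` rather than being clipped.
#'
#' @param train Data frame of training feature vectors.
#' @param cols Feature column names (default the five prosodic features).
#' @return An object of class `esp_scaling`: tibble with `feature`, `low`,
#'   `high`.
#' @export
fit_scaling <- function(train, cols = esp_feature_cols) {
  if (nrow(train) < 2) abort("Need at least 2 training vectors to fit scaling.")
  miss <- setdiff(cols, names(train))
  if (length(miss)) abort(sprintf("Missing feature columns: %s",
                                  paste(miss, collapse = ", ")))
  out <- tibble(
    feature = cols,
    low = vapply(cols, function(cl) min(train[[cl]]), numeric(1),
                 USE.NAMES = FALSE),
    high = vapply(cols, function(cl) max(train[[cl]]), numeric(1),
                  USE.NAMES = FALSE)
  )
  if (any(out$low == out$high)) {
    warn(sprintf(
      "Constant training feature(s): %s; mapped to 0.",
      paste(out$feature[out$low == out$high], collapse = ", ")
    ))
  }
  class(out) <- c("esp_scaling", class(out))
  out
}

#' Apply fitted feature scaling
#'
#' @param df Data frame containing the scaled features' columns.
#' @param scaling An `esp_scaling` from [fit_scaling()].
#' @return `df` with the feature columns replaced by their scaled values.
#' @export
apply_scaling <- function(df, scaling) {
  stopifnot(inherits(scaling, "esp_scaling"))
  for (i in seq_len(nrow(scaling))) {
    cl <- scaling$feature[i]
    lo <- scaling$low[i]
    hi <- scaling$high[i]
    df[[cl]] <- if (hi > lo) -1 + 2 * (df[[cl]] - lo) / (hi - lo) else 0
  }
  df
}
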