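#' Pitch tracker configuration
#'
#' Parameters of the two-rate normalized-cross-correlation pitch tracker.
#' The default window of 3361 samples with 2880 samples of overlap (hop 481,
#' about 30 ms at 16 kHz) matches the analysis geometry the speech pipeline
#' was designed around. The search range 40-600 Hz covers perceivable speech
#' pitch.
#'
#' @param window_size Analysis window length in samples.
#' @param overlap Overlap between consecutive windows in samples
#'   (`0 < overlap < window_size`); hop = `window_size - overlap`.
#' @param f0_min,f0_max Pitch search bounds, Hz.
#' @param downsample_factor Integer decimation factor for the coarse
#'   candidate pass (default 8, i.e. a 2 kHz first pass at 16 kHz input).
#' @param n_candidates Maximum voiced candidates kept per window.
#' @param dp_transition_cost Weight of the `|log(f0_t / f0_{t-1})|` frequency
#'   transition cost in the dynamic-programming contour selection.
#' @param voicing_switch_cost Fixed cost of switching between voiced and
#'   unvoiced states between adjacent windows.
#' @param candidate_floor Minimum correlation score for a voiced candidate.
#' @param octave_bias Score penalty per octave of lag above the shortest
#'   searched lag; biases near-equal peaks toward the shorter lag so
#'   subharmonics of strongly periodic frames are not selected.
#' @param voicing_energy_factor A window counts as speech only if its RMS
#'   energy exceeds this multiple of the stream's noise floor (the 10th
#'   percentile of all window energies).
#' @param rate_ref Sample rate the window defaults refer to; windows are
#'   rescaled proportionally for signals at other rates.
#' @return An object of class `pitch_config`.
#' @export
pitch_config <- function(window_size = 3361, overlap = 2880,
                         f0_min = 40, f0_max = 600,
                         downsample_factor = 8, n_candidates = 4,
                         dp_transition_cost = 0.35,
                         voicing_switch_cost = 0.2,
                         candidate_floor = 0.3,
                         octave_bias = 0.02,
                         voicing_energy_factor = 2,
                         rate_ref = 16000) {
  if (!(overlap > 0 && overlap < window_size)) {
    abort("Need 0 < overlap < window_size.")
  }
  if (!(f0_min > 0 && f0_min < f0_max && f0_max < rate_ref / 2)) {
    abort("Need 0 < f0_min < f0_max < rate/2.")
  }
  structure(list(
    window_size = as.integer(window_size), overlap = as.integer(overlap),
    f0_min = f0_min, f0_max = f0_max,
    downsample_factor = as.integer(downsample_factor),
    n_candidates = as.integer(n_candidates),
    dp_transition_cost = dp_transition_cost,
    voicing_switch_cost = voicing_switch_cost,
    candidate_floor = candidate_floor,
    octave_bias = octave_bias,
    voicing_energy_factor = voicing_energy_factor,
    rate_ref = rate_ref
  ), class = "pitch_config")
}

hop_size <- function(cfg) cfg$window_size - cfg$overlap

scale_config <- function(cfg, rate) {
  if (rate == cfg$rate_ref) return(cfg)
  s <- rate / cfg$rate_ref
  cfg$window_size <- max(2L, as.integer(round(cfg$window_size * s)))
  cfg$overlap <- min(cfg$window_size - 1L, as.integer(round(cfg$overlap * s)))
  cfg$rate_ref <- rate
  cfg
}

frame_starts <- function(n, cfg) {
  if (n < cfg$window_size) return(integer())
  seq.int(1L, n - cfg$window_size + 1L, by = hop_size(cfg))
}

#' Slice a signal into overlapping analysis windows
#'
#' Returns one row per complete window (a trailing partial window is
#' discarded), with the window's starting sample, its RMS energy, and the
#' window samples as a list-column.
#'
#' @param signal An [audio_signal()].
#' @param cfg A [pitch_config()].
#' @return A tibble with columns `frame`, `start_sample`, `energy`,
#'   `samples`; zero rows if the signal is shorter than one window.
#' @export
frame_signal <- function(signal, cfg = pitch_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  cfg <- scale_config(cfg, signal$rate)
  x <- signal$samples
  starts <- frame_starts(length(x), cfg)
  if (length(starts) == 0) {
    return(tibble(frame = integer(), start_sample = integer(),
                  energy = numeric(), samples = list()))
  }
  frames <- lapply(starts, function(s) x[s:(s + cfg$window_size - 1L)])
  tibble(
    frame = seq_along(starts),
    start_sample = starts,
    energy = vapply(frames, rms, numeric(1)),
    samples = frames
  )
}

# fast path: plain numeric NCC values for integer lags
nccf_values <- function(frame, lags) {
  n <- length(frame)
  cs <- c(0, cumsum(frame * frame))
  tot <- cs[n + 1]
  vals <- numeric(length(lags))
  for (k in seq_along(lags)) {
    L <- lags[k]
    if (L >= n) next
    e1 <- cs[n - L + 1]
    e2 <- tot - cs[L + 1]
    if (e1 <= .Machine$double.eps || e2 <= .Machine$double.eps) next
    num <- sum(frame[1:(n - L)] * frame[(1 + L):n])
    vals[k] <- min(1, max(-1, num / sqrt(e1 * e2)))
  }
  vals
}

#' Normalized cross-correlation of a frame with its lagged copy
#'
#' For each lag the frame is correlated with its own shifted copy over the
#' overlapping span, normalized by the energies of the two spans, so every
#' value lies in `[-1, 1]`. Lag 0 (trivially 1) is excluded by contract; a
#' zero-energy span yields a correlation of 0 so silent frames are declared
#' unvoiced downstream.
#'
#' @param frame Numeric vector of window samples.
#' @param lags Integer vector of positive lags (samples).
#' @return A tibble with columns `lag` and `ncc`.
#' @export
nccf <- function(frame, lags) {
  lags <- as.integer(lags)
  if (any(lags <= 0)) abort("Lags must be positive; lag 0 is excluded.")
  tibble(lag = lags, ncc = nccf_values(frame, lags))
}

# local maxima indices of v (plateau-tolerant: >= left, > right)
local_maxima <- function(v) {
  n <- length(v)
  if (n == 0) return(integer())
  if (n == 1) return(1L)
  left <- c(TRUE, v[-1] >= v[-n])
  right <- c(v[-n] > v[-1], TRUE)
  which(left & right)
}

# internal candidate representation: list(f0, score, lag, voiced), the last
# entry always the unvoiced candidate (f0 = NA)
new_candidates <- function(f0, score, lag) {
  best <- if (length(score)) max(score) else 0
  list(f0 = c(f0, NA_real_), score = c(score, 1 - best),
       lag = c(lag, NA_real_), voiced = c(rep(TRUE, length(f0)), FALSE))
}

candidates_from_corr <- function(lags, vals, rate, cfg) {
  peaks <- local_maxima(vals)
  peaks <- peaks[vals[peaks] >= cfg$candidate_floor]
  if (length(peaks) == 0) return(new_candidates(numeric(), numeric(), numeric()))
  min_lag <- min(lags)
  score <- vals[peaks] - cfg$octave_bias * log2(lags[peaks] / min_lag)
  ord <- order(score, lags[peaks], decreasing = TRUE)
  peaks <- peaks[ord][seq_len(min(cfg$n_candidates, length(peaks)))]
  lag_star <- vapply(peaks, function(i) {
    L <- lags[i]
    if (i > 1 && i < length(vals) && lags[i - 1] == L - 1 && lags[i + 1] == L + 1) {
      denom <- vals[i - 1] - 2 * vals[i] + vals[i + 1]
      if (abs(denom) > .Machine$double.eps) {
        d <- 0.5 * (vals[i - 1] - vals[i + 1]) / denom
        return(L + max(-0.5, min(0.5, d)))
      }
    }
    as.numeric(L)
  }, numeric(1))
  f0 <- pmin(pmax(rate / lag_star, cfg$f0_min), cfg$f0_max)
  score <- vals[peaks] - cfg$octave_bias * log2(lags[peaks] / min_lag)
  # score ties broken toward the lower frequency
  ord2 <- order(-score, f0)
  new_candidates(f0[ord2], score[ord2], lag_star[ord2])
}

#' Per-frame pitch candidates from a correlation function
#'
#' Picks up to `n_candidates` local maxima above the score floor, converts
#' lag to Hz (with parabolic interpolation of the peak when its neighbours
#' are available), and always appends an explicit unvoiced candidate whose
#' score is `1 - best_peak`: when no strong periodicity is present the
#' unvoiced state is cheap for the contour search, and expensive otherwise.
#' Candidate scores carry a small lag-proportional penalty (`octave_bias`)
#' so near-equal subharmonic peaks lose to the true period; exact score
#' ties break toward the lower frequency.
#'
#' @param corr A tibble from [nccf()] (columns `lag`, `ncc`).
#' @param rate Sample rate of the frame, Hz.
#' @param cfg A [pitch_config()].
#' @return A tibble with columns `f0` (Hz, `NA` for the unvoiced candidate),
#'   `score`, `lag`, `voiced`; the unvoiced candidate is always last.
#' @export
pitch_candidates <- function(corr, rate, cfg = pitch_config()) {
  cc <- candidates_from_corr(corr$lag, corr$ncc, rate, cfg)
  tibble(f0 = cc$f0, score = cc$score, lag = cc$lag, voiced = cc$voiced)
}

# DP on the internal representation; returns list(sel index, total_cost)
dp_core <- function(cands, cfg) {
  n <- length(cands)
  tw <- cfg$dp_transition_cost
  sw <- cfg$voicing_switch_cost
  cost_prev <- 1 - cands[[1]]$score
  back <- vector("list", n)
  for (t in seq_len(n)[-1]) {
    prev <- cands[[t - 1]]
    cur <- cands[[t]]
    m <- length(cur$score)
    p <- length(prev$score)
    ct <- numeric(m)
    bk <- integer(m)
    for (j in seq_len(m)) {
      if (cur$voiced[j]) {
        tc <- ifelse(prev$voiced, tw * abs(log(cur$f0[j] / prev$f0)), sw)
      } else {
        tc <- ifelse(prev$voiced, sw, 0)
      }
      tot <- cost_prev + tc
      bk[j] <- which.min(tot)
      ct[j] <- tot[bk[j]] + (1 - cur$score[j])
    }
    cost_prev <- ct
    back[[t]] <- bk
  }
  sel <- integer(n)
  sel[n] <- which.min(cost_prev)
  if (n > 1) for (t in n:2) sel[t - 1] <- back[[t]][sel[t]]
  list(sel = sel, total_cost = min(cost_prev))
}

#' Select a pitch contour by dynamic programming
#'
#' Minimizes the summed local cost `1 - score` plus transition costs:
#' `dp_transition_cost * |log(f0_t / f0_{t-1})|` between voiced windows and
#' a fixed `voicing_switch_cost` for voiced/unvoiced switches. The result is
#' the exact optimum for this cost, verifiable by exhaustive path search on
#' short inputs.
#'
#' @param candidates A list with one tibble per frame, as produced by
#'   [pitch_candidates()].
#' @param cfg A [pitch_config()].
#' @return A tibble with one row per frame: `frame`, `f0` (`NA` if
#'   unvoiced), `score`, `voiced`, `total_cost` (same value on every row).
#' @export
dp_select <- function(candidates, cfg = pitch_config()) {
  if (length(candidates) == 0) abort("Need at least one frame of candidates.")
  cands <- lapply(candidates, function(cc) {
    list(f0 = cc$f0, score = cc$score, voiced = cc$voiced)
  })
  res <- dp_core(cands, cfg)
  rows <- vapply(seq_along(cands), function(t) {
    j <- res$sel[t]
    c(cands[[t]]$f0[j], cands[[t]]$score[j], cands[[t]]$voiced[j])
  }, numeric(3))
  tibble(
    frame = seq_along(cands),
    f0 = rows[1, ], score = rows[2, ],
    voiced = as.logical(rows[3, ]),
    total_cost = res$total_cost
  )
}

# Candidate generation for one frame: coarse pass on the decimated frame,
# refinement at full rate around each coarse peak.
frame_candidates <- function(frame_full, frame_low, rate, cfg) {
  q <- cfg$downsample_factor
  lag_min <- max(2L, as.integer(floor(rate / cfg$f0_max)))
  lag_max <- as.integer(ceiling(rate / cfg$f0_min))
  lag_min_low <- max(2L, lag_min %/% q)
  lag_max_low <- min(length(frame_low) - 1L, as.integer(ceiling(lag_max / q)))
  if (lag_max_low <= lag_min_low) {
    return(new_candidates(numeric(), numeric(), numeric()))
  }
  lags_low <- lag_min_low:lag_max_low
  vals_low <- nccf_values(frame_low, lags_low)
  peaks <- local_maxima(vals_low)
  peaks <- peaks[vals_low[peaks] >= cfg$candidate_floor]
  if (length(peaks) == 0) {
    return(new_candidates(numeric(), numeric(), numeric()))
  }
  adj <- vals_low[peaks] -
    cfg$octave_bias * log2(lags_low[peaks] / min(lags_low))
  peaks <- peaks[order(adj, decreasing = TRUE)]
  peaks <- peaks[seq_len(min(cfg$n_candidates, length(peaks)))]
  # refine around each coarse peak and around its half-lag: the coarse grid
  # quantizes short periods badly, so the true peak of a high-pitched frame
  # can survive only as its first subharmonic at the low rate
  centers <- unique(unlist(lapply(lags_low[peaks], function(L) {
    c(L * q, max(lag_min, as.integer(round(L * q / 2))))
  })))
  refine_lags <- sort(unique(unlist(lapply(centers, function(ctr) {
    seq.int(max(lag_min, ctr - q %/% 2 - 4L), min(lag_max, ctr + q %/% 2 + 4L))
  }))))
  vals_full <- nccf_values(frame_full, refine_lags)
  candidates_from_corr(refine_lags, vals_full, rate, cfg)
}

#' Estimate a pitch contour
#'
#' Full two-rate tracker: the signal is decimated by `downsample_factor`, a
#' coarse normalized-cross-correlation pass proposes candidate lags per
#' window, the candidates are refined on the full-rate signal in the
#' vicinity of each coarse peak (with parabolic interpolation of the peak
#' for sub-sample resolution), and dynamic programming selects the final
#' contour. A window is reported voiced only if the contour search keeps a
#' voiced state there and its energy clears the dynamic speech threshold
#' (`voicing_energy_factor` times the 10th-percentile noise floor). The
#' threshold presumes the stream contains some silence, as utterances
#' bounded by pauses do.
#'
#' @param signal An [audio_signal()].
#' @param cfg A [pitch_config()].
#' @return A tibble of class `pitch_contour`, one row per window: `frame`,
#'   `start_sample`, `time_s` (window start), `f0` (Hz, `NA` when unvoiced),
#'   `ncc_peak`, `energy`, `voiced`. Attributes: `rate`, `hop`, `cfg`.
#' @export
#' @examples
#' p <- prosody_profile("happy", "female", 200, 0, "flat")
#' sig <- synthesize_utterance(p, duration = 0.6, seed = 1)
#' contour <- estimate_pitch(sig)
#' median(contour$f0[contour$voiced])
estimate_pitch <- function(signal, cfg = pitch_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  cfg <- scale_config(cfg, signal$rate)
  rate <- signal$rate
  hop <- hop_size(cfg)
  x <- signal$samples
  starts <- frame_starts(length(x), cfg)
  if (length(starts) == 0) {
    out <- tibble(frame = integer(), start_sample = integer(),
                  time_s = numeric(), f0 = numeric(), ncc_peak = numeric(),
                  energy = numeric(), voiced = logical())
    return(new_pitch_contour(out, rate, hop, cfg))
  }
  q <- cfg$downsample_factor
  low <- signal::decimate(x, q, ftype = "fir")
  win_low <- cfg$window_size %/% q

  energies <- numeric(length(starts))
  cands <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    s_full <- starts[i]
    frame_full <- x[s_full:(s_full + cfg$window_size - 1L)]
    energies[i] <- rms(frame_full)
    s_low <- min(max(1L, ((s_full - 1L) %/% q) + 1L),
                 max(1L, length(low) - win_low + 1L))
    frame_low <- low[s_low:min(length(low), s_low + win_low - 1L)]
    cands[[i]] <- frame_candidates(frame_full, frame_low, rate, cfg)
  }
  res <- dp_core(cands, cfg)
  sel_f0 <- vapply(seq_along(cands), function(t) cands[[t]]$f0[res$sel[t]],
                   numeric(1))
  sel_score <- vapply(seq_along(cands), function(t) cands[[t]]$score[res$sel[t]],
                      numeric(1))
  sel_voiced <- vapply(seq_along(cands), function(t) cands[[t]]$voiced[res$sel[t]],
                       logical(1))

  noise_floor <- quantile(energies, 0.1, names = FALSE)
  speech <- energies > cfg$voicing_energy_factor * noise_floor
  voiced <- sel_voiced & speech
  out <- tibble(
    frame = seq_along(starts),
    start_sample = starts,
    time_s = (starts - 1) / rate,
    f0 = ifelse(voiced, sel_f0, NA_real_),
    ncc_peak = sel_score,
    energy = energies,
    voiced = voiced
  )
  new_pitch_contour(out, rate, hop, cfg)
}

new_pitch_contour <- function(df, rate, hop, cfg) {
  attr(df, "rate") <- rate
  attr(df, "hop") <- hop
  attr(df, "cfg") <- cfg
  class(df) <- c("pitch_contour", class(df))
  df
}
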