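test_that("framing geometry matches the hop arithmetic", {
  sig <- audio_signal(rep(0.5, 96000))
  fr <- frame_signal(sig)
  expect_equal(nrow(fr), floor((96000 - 3361) / 481) + 1) # 193
  expect_equal(diff(fr$start_sample[1:2]), 481)
  expect_equal(fr$energy, rep(0.5, nrow(fr)))
  zero <- frame_signal(audio_signal(c(rep(0, 5000), 1e-12)))
  expect_true(all(zero$energy < 1e-10))
  short <- frame_signal(audio_signal(rnorm(1000)))
  expect_equal(nrow(short), 0)
})

test_that("NCCF peaks at the period and stays in [-1, 1]", {
  t <- seq_len(3361) / 16000
  frame <- sin(2 * pi * 200 * t)
  corr <- nccf(frame, 27:400)
  expect_true(all(corr$ncc >= -1 & corr$ncc <= 1))
  expect_equal(corr$lag[which.max(corr$ncc)], 80, tolerance = 1)
  expect_error(nccf(frame, 0:10), "lag 0")
  silent <- nccf(rep(0, 3361), 27:400)
  expect_true(all(silent$ncc == 0))
})

test_that("white-noise frames rarely show strong periodicity", {
  set.seed(42)
  peaks <- replicate(100, {
    frame <- rnorm(420)
    max(nccf(frame, 3:50)$ncc)
  })
  expect_lt(mean(peaks >= 0.6), 0.05)
})

test_that("candidate lists find the tone and always carry an unvoiced option", {
  t <- seq_len(3361) / 16000
  corr <- nccf(sin(2 * pi * 200 * t), 27:400)
  cand <- pitch_candidates(corr, 16000, pitch_config())
  v <- cand[cand$voiced, ]
  expect_gte(nrow(v), 1)
  best <- v$f0[which.max(v$score)]
  expect_true(best >= 198 && best <= 202)
  expect_true(any(!cand$voiced))
  # silence: only the unvoiced candidate, and it is attractive
  sil <- pitch_candidates(nccf(rep(0, 3361), 27:400), 16000, pitch_config())
  expect_equal(nrow(sil), 1)
  expect_false(sil$voiced)
  expect_equal(sil$score, 1)
})

test_that("DP equals exhaustive path search on small instances", {
  cfg <- pitch_config()
  exhaustive <- function(cands) {
    idx <- lapply(cands, function(cc) seq_len(nrow(cc)))
    grid <- expand.grid(idx)
    best <- NULL; best_cost <- Inf
    for (r in seq_len(nrow(grid))) {
      cost <- 0
      for (tt in seq_along(cands)) {
        cc <- cands[[tt]][grid[r, tt], ]
        cost <- cost + (1 - cc$score)
        if (tt > 1) {
          pp <- cands[[tt - 1]][grid[r, tt - 1], ]
          cost <- cost + if (pp$voiced && cc$voiced) {
            cfg$dp_transition_cost * abs(log(cc$f0 / pp$f0))
          } else if (pp$voiced != cc$voiced) cfg$voicing_switch_cost else 0
        }
      }
      if (cost < best_cost) { best_cost <- cost; best <- unlist(grid[r, ]) }
    }
    list(path = unname(best), cost = best_cost)
  }
  set.seed(11)
  for (rep in 1:8) {
    n_frames <- sample(2:6, 1)
    cands <- lapply(seq_len(n_frames), function(i) {
      k <- sample(1:3, 1)
      tibble::tibble(
        f0 = runif(k, 80, 400), score = runif(k, 0.3, 0.99),
        lag = NA_real_, voiced = TRUE
      ) |> dplyr::bind_rows(tibble::tibble(
        f0 = NA_real_, score = runif(1, 0, 0.6), lag = NA_real_,
        voiced = FALSE
      ))
    })
    got <- dp_select(cands, cfg)
    oracle <- exhaustive(cands)
    expect_equal(got$total_cost[1], oracle$cost, tolerance = 1e-12)
    sel <- vapply(seq_len(n_frames), function(tt) {
      which(abs(cands[[tt]]$score - got$score[tt]) < 1e-15)[1]
    }, numeric(1))
    expect_equal(unname(sel), oracle$path)
  }
})

test_that("single-candidate frames pass through DP unchanged", {
  cands <- lapply(c(150, 152, 149), function(f) {
    tibble::tibble(f0 = f, score = 0.95, lag = NA_real_, voiced = TRUE)
  })
  out <- dp_select(cands, pitch_config())
  expect_equal(out$f0, c(150, 152, 149))
  expect_true(all(out$voiced))
})

test_that("transition costs suppress octave alternation", {
  # alternating strong 150/300 Hz candidates: an octave-consistent track is
  # cheaper than following the per-frame argmax
  cands <- lapply(1:6, function(i) {
    top <- if (i %% 2 == 0) 300 else 150
    tibble::tibble(
      f0 = c(top, if (top == 300) 150 else 300),
      score = c(0.95, 0.93), lag = NA_real_, voiced = TRUE
    )
  })
  cfg <- pitch_config(dp_transition_cost = 0.5)
  out <- dp_select(cands, cfg)
  expect_true(max(out$f0) / min(out$f0) < 1.5)
})

test_that("the tracker recovers flat tones and glides accurately", {
  sig <- tone_utterance(200, seed = 1)
  contour <- estimate_pitch(sig)
  v <- contour$f0[contour$voiced]
  expect_gt(length(v), 10)
  expect_gte(mean(abs(v - 200) / 200 <= 0.02), 0.95)

  silence <- audio_signal(rnorm(32000, 0, 1e-4))
  expect_equal(sum(estimate_pitch(silence)$voiced), 0)

  glide <- tone_utterance(200, duration = 1, seed = 2, contour = "rising")
  cg <- estimate_pitch(glide)
  vg <- cg$f0[cg$voiced]
  med <- stats::runmed(vg, 5)
  expect_gte(mean(diff(med) >= -1e-9), 0.95)

  # determinism: identical contour for identical input
  expect_identical(estimate_pitch(sig)$f0, contour$f0)
})

test_that("reported pitch respects the configured bounds", {
  cfg <- pitch_config()
  for (f0 in c(90, 250, 380)) {
    contour <- estimate_pitch(tone_utterance(f0, duration = 0.5, seed = f0))
    v <- contour$f0[contour$voiced]
    expect_true(all(v >= cfg$f0_min & v <= cfg$f0_max))
    expect_true(all(contour$ncc_peak >= -1 & contour$ncc_peak <= 1.01))
  }
})
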