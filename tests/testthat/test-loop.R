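test_that("dominant color follows channel mass and rejects ties", {
  expect_equal(dominant_color(make_card_image("red", 0)), "red")
  expect_equal(dominant_color(make_card_image("blue", 0.3, seed = 1)), "blue")
  checker <- array(0, dim = c(2, 2, 3))
  checker[, , 1] <- c(255, 0, 255, 0)
  checker[, , 3] <- c(0, 255, 0, 255)
  expect_error(dominant_color(checker), "Ambiguous")
})

test_that("decisions fire at the first threshold crossing", {
  cfg <- scenario_config(decision_threshold = 3, decision_timeout = 1000)
  log1 <- tibble::tibble(
    time_ms = c(10, 20, 30, 40), neuron = 21:24, group = "PMC1"
  )
  d <- decide(log1, cfg)
  expect_equal(d$side, "left")
  expect_equal(d$time_ms, 30)

  tie <- tibble::tibble(
    time_ms = sort(rep(seq(10, 900, by = 50), 2)),
    neuron = 1,
    group = rep(c("PMC1", "PMC2"), 18)
  )
  expect_equal(decide(tie, cfg)$side, "none")

  # a scan oracle confirms the reported crossing time on a noisy log
  set.seed(4)
  noisy <- tibble::tibble(
    time_ms = sort(runif(400, 0, 1000)),
    neuron = 1,
    group = sample(c("PMC1", "PMC2"), 400, replace = TRUE, prob = c(0.65, 0.35))
  )
  cfg10 <- scenario_config(decision_threshold = 10)
  got <- decide(noisy, cfg10)
  running <- cumsum(ifelse(noisy$group == "PMC1", 1, -1))
  first <- which(abs(running) >= 10)[1]
  expect_equal(got$time_ms, noisy$time_ms[first])
  expect_equal(got$side, if (running[first] > 0) "left" else "right")
})

test_that("spoken rewards classify end to end and silence yields none", {
  feats <- dplyr::bind_rows(
    dplyr::mutate(esp_features(synthesize_utterance(
      default_profiles()[1, ] |> (\(p) { class(p) <- c("prosody_profile", class(tibble::tibble())); p })(),
      duration = 1, seed = 31)), label = "happy"),
    dplyr::mutate(esp_features(synthesize_utterance(
      default_profiles()[3, ] |> (\(p) { class(p) <- c("prosody_profile", class(tibble::tibble())); p })(),
      duration = 1, seed = 32)), label = "sad"),
    dplyr::mutate(esp_features(synthesize_utterance(
      default_profiles()[2, ] |> (\(p) { class(p) <- c("prosody_profile", class(tibble::tibble())); p })(),
      duration = 1, seed = 33)), label = "happy"),
    dplyr::mutate(esp_features(synthesize_utterance(
      default_profiles()[4, ] |> (\(p) { class(p) <- c("prosody_profile", class(tibble::tibble())); p })(),
      duration = 1, seed = 34)), label = "sad")
  )
  m <- esp_train(feats)
  happy_audio <- synthesize_utterance(
    flat_profile(240, sd = 5, contour = "modulated"), duration = 1, seed = 41)
  sad_audio <- synthesize_utterance(
    flat_profile(115, sd = 5, label = "sad", gender = "male",
                 contour = "falling"), duration = 1, seed = 42)
  expect_equal(reward_from_speech(happy_audio, m), "happy")
  expect_equal(reward_from_speech(sad_audio, m), "sad")
  silence <- audio_signal(rnorm(48000, 0, 1e-4))
  expect_warning(lab <- reward_from_speech(silence, m), "No utterance")
  expect_equal(lab, "none")
})

test_that("rewarded trials grow the cued learning projection only", {
  cfg <- scenario_config(correct_map = c(red = "left", blue = "right"))
  set.seed(12)
  st <- build_network(cfg$network)
  # run trials until one red trial is rewarded
  got_reward <- FALSE
  for (k in 1:6) {
    res <- run_trial(st, "red", cfg)
    st <- res$state
    if (res$log$reward_given) { got_reward <- TRUE; break }
  }
  expect_true(got_reward)
  expect_gt(res$log$w_vc1_pmc1_post, res$log$w_vc1_pmc1_pre)
  expect_equal(res$log$w_vc2_pmc2_post, res$log$w_vc2_pmc2_pre)
  expect_equal(res$log$w_vc2_pmc1_post, res$log$w_vc2_pmc1_pre)
})

test_that("trials without feedback leave every weight untouched", {
  cfg <- scenario_config(decision_threshold = 500)  # force decision none
  set.seed(13)
  st <- build_network(cfg$network)
  res <- run_trial(st, "blue", cfg)
  expect_equal(res$log$decision, "none")
  expect_false(res$log$reward_given)
  for (proj in c("vc1_pmc1", "vc2_pmc2", "vc1_pmc2", "vc2_pmc1")) {
    expect_equal(res$log[[paste0("w_", proj, "_post")]],
                 res$log[[paste0("w_", proj, "_pre")]])
  }
})

test_that("sessions are reproducible and log a coherent trial table", {
  cfg <- scenario_config(n_trials = 6)
  s1 <- run_session(cfg, seed = 21)
  s2 <- run_session(cfg, seed = 21)
  expect_identical(s1$trials, s2$trials)
  tr <- s1$trials
  expect_equal(nrow(tr), 6)
  expect_true(all(tr$cue %in% c("red", "blue")))
  # reward implies a decision; correctness matches the map
  expect_true(all(!tr$reward_given | tr$decision != "none"))
  map <- cfg$correct_map
  expect_equal(tr$correct,
               tr$decision != "none" & unname(map[tr$cue]) == tr$decision)
  expect_s3_class(generics::tidy(s1), "tbl_df")
  expect_equal(generics::glance(s1)$n_trials, 6)
})

test_that("criterion detection finds the first sustained-correct trial", {
  expect_equal(criterion_trial(c(F, F, T, T, T, T, T), 5), 3)
  expect_equal(criterion_trial(rep(TRUE, 5), 5), 1)
  expect_true(is.na(criterion_trial(c(T, T, T, F, T, T, T, T), 5)))
  expect_true(is.na(criterion_trial(rep(TRUE, 4), 5)))
})

test_that("label-fed and audio-fed rewards produce identical sequences", {
  feats <- dataset_features(make_dataset(4, seed = 61))
  m <- esp_train(feats)
  # the classifier is error-free on the well-separated default profiles
  expect_equal(mean(esp_classify(m, feats)$.pred == feats$label), 1)
  cfg_lab <- scenario_config(n_trials = 5, reward_source = "labels")
  cfg_aud <- scenario_config(n_trials = 5, reward_source = "audio")
  s_lab <- run_session(cfg_lab, seed = 31)
  s_aud <- run_session(cfg_aud, seed = 31, model = m)
  expect_equal(s_aud$trials$reward_label, s_lab$trials$reward_label)
  expect_equal(s_aud$trials$reward_given, s_lab$trials$reward_given)
})

test_that("swapping the cue statistics swaps which projection grows", {
  cfg <- scenario_config()
  run_cue_block <- function(color, seed) {
    set.seed(seed)
    st <- build_network(network_config(seed = seed))
    for (k in 1:8) {
      res <- run_trial(st, color, cfg)
      st <- res$state
    }
    weights_table(st)
  }
  w_red <- run_cue_block("red", 71)
  w_blue <- run_cue_block("blue", 71)
  pick <- function(wt, proj) wt$mean_weight_uS[wt$projection == proj]
  # red-only sessions move the VC1 pathway, blue-only the VC2 pathway
  expect_gt(pick(w_red, "VC1->PMC1"), pick(w_red, "VC2->PMC2"))
  expect_equal(pick(w_red, "VC2->PMC2"), 0.006)
  expect_gt(pick(w_blue, "VC2->PMC2"), pick(w_blue, "VC1->PMC1"))
  expect_equal(pick(w_blue, "VC1->PMC1"), 0.006)
})
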