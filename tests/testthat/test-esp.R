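test_that("endpointing groups bursts by the two-second rule", {
  mk_contour <- function(pattern) {
    # pattern: character vector of "v" (voiced speech) / "s" (silence) windows
    n <- length(pattern)
    df <- tibble::tibble(
      frame = seq_len(n), start_sample = 1L + (seq_len(n) - 1L) * 481L,
      time_s = (start_sample - 1) / 16000,
      f0 = ifelse(pattern == "v", 150, NA_real_),
      ncc_peak = 0.9,
      energy = ifelse(pattern == "v", 0.3, 0.001),
      voiced = pattern == "v"
    )
    attr(df, "rate") <- 16000; attr(df, "hop") <- 481L
    attr(df, "cfg") <- pitch_config()
    class(df) <- c("pitch_contour", class(df))
    df
  }
  gap <- ceiling(2 * 16000 / 481)  # 67 windows

  one <- segment_utterances(mk_contour(c(rep("s", 10), rep("v", 30), rep("s", 85))))
  expect_equal(unique(one$utterance), 1L)

  # 1 s gap (34 windows) does not split
  gap1s <- c(rep("s", 5), rep("v", 20), rep("s", 34), rep("v", 20), rep("s", 80))
  expect_equal(length(unique(segment_utterances(mk_contour(gap1s))$utterance)), 1)

  # 3 s gap (100 windows) splits
  gap3s <- c(rep("s", 5), rep("v", 20), rep("s", 100), rep("v", 20), rep("s", 80))
  expect_equal(length(unique(segment_utterances(mk_contour(gap3s))$utterance)), 2)
})

test_that("every generated utterance endpoints as exactly one utterance", {
  for (s in 1:4) {
    p <- default_profiles()[s, ]
    class(p) <- c("prosody_profile", class(tibble::tibble()))
    sig <- synthesize_utterance(p, duration = 1, seed = 100 + s)
    segs <- segment_utterances(estimate_pitch(sig))
    expect_equal(length(unique(segs$utterance)), 1)
  }
})

test_that("feature vectors obey their statistics contract", {
  utt <- tibble::tibble(f0 = c(150, 150), energy = c(0.3, 0.3),
                        voiced = TRUE)
  expect_equal(
    unlist(extract_features(utt)[, 1:5]),
    c(pitch_mean = 150, pitch_min = 150, pitch_max = 150,
      pitch_range = 0, energy_mean = 0.3)
  )
  two <- tibble::tibble(f0 = c(100, 200), energy = c(0.2, 0.4), voiced = TRUE)
  ft <- extract_features(two)
  expect_equal(ft$pitch_mean, 150)
  expect_equal(ft$pitch_range, 100)
  expect_error(
    extract_features(tibble::tibble(f0 = NA_real_, energy = 1, voiced = FALSE)),
    "Unvoiced"
  )
  # invariants on tracked audio
  ft2 <- esp_features(tone_utterance(220, seed = 9, contour = "modulated"))
  expect_true(ft2$pitch_min <= ft2$pitch_mean)
  expect_true(ft2$pitch_mean <= ft2$pitch_max)
  expect_equal(ft2$pitch_range, ft2$pitch_max - ft2$pitch_min)
  expect_gt(ft2$energy_mean, 0)
})

test_that("happy profiles yield strictly higher measured mean pitch than sad", {
  happy <- esp_features(synthesize_utterance(
    flat_profile(240, sd = 5, contour = "modulated"), duration = 1, seed = 21))
  sad <- esp_features(synthesize_utterance(
    flat_profile(170, sd = 5, label = "sad", contour = "falling"),
    duration = 1, seed = 22))
  expect_gt(happy$pitch_mean, sad$pitch_mean)
})

test_that("feature scaling maps the training range onto [-1, 1] exactly", {
  train <- tibble::tibble(
    pitch_mean = c(100, 300), pitch_min = c(90, 280),
    pitch_max = c(110, 320), pitch_range = c(20, 40),
    energy_mean = c(0.1, 0.5)
  )
  sc <- fit_scaling(train)
  scaled <- apply_scaling(train, sc)
  expect_true(all(abs(as.matrix(scaled)) <= 1))
  mid <- apply_scaling(
    tibble::tibble(pitch_mean = 200, pitch_min = 185, pitch_max = 215,
                   pitch_range = 30, energy_mean = 0.3), sc)
  expect_equal(mid$pitch_mean, 0)
  # out-of-range test values extrapolate, they are not clipped
  hi <- apply_scaling(
    tibble::tibble(pitch_mean = 350, pitch_min = 90, pitch_max = 110,
                   pitch_range = 20, energy_mean = 0.1), sc)
  expect_equal(hi$pitch_mean, 1.5)
  # constant feature maps to 0 with a warning
  const <- train
  const$energy_mean <- 0.2
  expect_warning(sc2 <- fit_scaling(const), "Constant")
  expect_equal(apply_scaling(const, sc2)$energy_mean, c(0, 0))
})

test_that("scaling is fitted on the training split only", {
  feats <- toy_features(n = 12, seed = 3)
  sp <- esp_split(feats, 0.5, seed = 3)
  train <- sp[sp$split == "train", ]
  sc1 <- fit_scaling(train)
  # perturbing a test sample never changes the fitted parameters
  sp2 <- sp
  sp2$pitch_mean[which(sp2$split == "test")[1]] <- 999
  sc2 <- fit_scaling(sp2[sp2$split == "train", ])
  expect_identical(sc1$low, sc2$low)
  expect_identical(sc1$high, sc2$high)
})

test_that("the classifier separates separable classes and is deterministic", {
  feats <- toy_features(n = 20, seed = 5)
  m <- esp_train(feats)
  pred <- esp_classify(m, feats)
  expect_equal(mean(pred$.pred == feats$label), 1)
  expect_identical(esp_classify(m, feats)$.pred, pred$.pred)
  expect_error(esp_train(feats[feats$label == "happy", ]), "2 classes")
  expect_error(esp_classify(m, feats[, 1:3]), "Feature mismatch")
  # a vector at the happy centroid classifies happy
  centroid <- dplyr::summarise(dplyr::filter(feats, label == "happy"),
                               dplyr::across(1:5, mean))
  expect_equal(esp_classify(m, centroid)$.pred, "happy")
})

test_that("the package's decision rule reproduces the solver's predictions", {
  set.seed(2)
  feats <- toy_features(n = 15, seed = 2)
  # add two extra overlapping classes to exercise one-vs-one voting
  extra <- toy_features(n = 15, seed = 4)
  extra$label <- paste0(extra$label, "2")
  extra$pitch_mean <- extra$pitch_mean + 25
  all4 <- dplyr::bind_rows(feats, extra)
  m <- esp_train(all4)
  sc <- fit_scaling(all4)
  xs <- as.matrix(apply_scaling(all4, sc)[, m$feature_cols])
  ref <- e1071::svm(xs, factor(all4$label), scale = FALSE, kernel = "radial",
                    gamma = m$gamma, cost = m$cost)
  expect_equal(esp_classify(m, all4)$.pred,
               as.character(predict(ref, xs)))
})

test_that("permuted labels drop held-out accuracy to chance", {
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    feats <- toy_features(n = 10, seed = s)
    feats$label <- sample(feats$label)
    sp <- esp_split(feats, 0.5, seed = s)
    m <- esp_train(sp[sp$split == "train", ])
    mean(esp_classify(m, sp[sp$split == "test", ])$.pred ==
           sp$label[sp$split == "test"])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})

test_that("model JSON round trips preserve predictions and the manifest", {
  feats <- toy_features(n = 10, seed = 6)
  m <- esp_train(feats, train_frac = 0.5, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$manifest$train_frac, 0.5)
  set.seed(8)
  probe <- tibble::tibble(
    pitch_mean = runif(100, 80, 320), pitch_min = runif(100, 70, 250),
    pitch_max = runif(100, 120, 400), pitch_range = runif(100, 0, 80),
    energy_mean = runif(100, 0.05, 0.6)
  )
  expect_identical(esp_classify(m2, probe)$.pred,
                   esp_classify(m, probe)$.pred)
  # truncated files are rejected with a schema complaint
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50), trunc)
  expect_error(load_model(trunc), "parse|schema")
  # wrong schema
  empty <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(a = 1), empty, auto_unbox = TRUE)
  expect_error(load_model(empty), "schema")
})

test_that("tidy and glance summarize a fitted model", {
  m <- esp_train(toy_features(n = 8, seed = 7), train_frac = 0.33)
  td <- generics::tidy(m)
  expect_setequal(td$class, c("happy", "sad"))
  gl <- generics::glance(m)
  expect_equal(gl$n_classes, 2)
  expect_equal(gl$train_frac, 0.33)
  expect_equal(gl$n_support, sum(td$n_support))
})
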