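#' Scenario configuration for the closed behavioral loop
#'
#' Parameters of one cue -> decision -> reward session. The defaults
#' (decision threshold 15 spikes, 1 s decision timeout, 500 ms reward
#' window, 2 kHz aggregate cue drive, 3 Hz correlated reward volleys) are
#' the package's own operating point, exposed here and logged with every
#' session.
#'
#' @param decision_threshold Premotor spike-count difference that triggers
#'   a decision, >= 1.
#' @param decision_timeout Maximum decision window, ms.
#' @param reward_duration Reward stimulation window, ms.
#' @param cue_drive Aggregate Poisson rate of the cue stimulus onto the
#'   cued VC column, Hz.
#' @param reward_drive Event rate of the periodic reward volleys, Hz.
#'   During the reward window, regularly spaced volleys from one shared
#'   event stream are delivered to the cued VC column (delay `vc_delay`)
#'   and to the chosen PMC column (`pmc_delay`), emulating the correlated
#'   visual/proprioceptive input that accompanies the rewarded pointing
#'   action; the VC-leading delays make pre-before-post pairings dominate.
#' @param reward_vc_weight,reward_pmc_weight Conductance increment per
#'   reward volley event for the VC and PMC columns, microsiemens. The VC
#'   weight is suprathreshold from rest so every volley elicits one
#'   synchronous spike per VC neuron.
#' @param vc_delay,pmc_delay Length-2 delay ranges (ms) of volley delivery
#'   to the VC and PMC columns.
#' @param n_trials Trials per session.
#' @param correct_map Named character vector mapping cue colors to actions:
#'   red -> left (PMC1), blue -> right (PMC2).
#' @param reward_source `"labels"` (reward labels used directly) or
#'   `"audio"` (a synthetic spoken reward is generated and classified by
#'   the emotion model each trial).
#' @param sad_depresses If `TRUE` (the default), a sad response enables
#'   depression-only plasticity during the feedback window, delivered as
#'   anti-causal volleys that weaken the pathway behind the wrong action.
#'   If `FALSE`, sad feedback simply gives no reward and plasticity stays
#'   off; random wiring asymmetries that favor one premotor column can
#'   then leave the opposite cue unlearnable within a session.
#' @param criterion_run Consecutive correct decisions defining "learned".
#' @param ablate_plasticity If `TRUE`, feedback stimulation is delivered as
#'   usual but plasticity is never enabled -- the no-learning control; the
#'   session should then hover at chance.
#' @param network A [network_config()].
#' @param pitch A [pitch_config()] for the spoken-reward path.
#' @param reward_profiles Prosody profiles used to voice spoken rewards
#'   when `reward_source = "audio"`.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(decision_threshold = 15, decision_timeout = 1000,
                            reward_duration = 500, cue_drive = 2000,
                            reward_drive = 4, reward_vc_weight = 0.05,
                            reward_pmc_weight = 0.03,
                            vc_delay = c(0, 0), pmc_delay = c(2, 6),
                            n_trials = 30,
                            correct_map = c(red = "left", blue = "right"),
                            reward_source = c("labels", "audio"),
                            sad_depresses = TRUE, criterion_run = 5,
                            ablate_plasticity = FALSE,
                            network = network_config(),
                            pitch = pitch_config(),
                            reward_profiles = default_profiles()) {
  reward_source <- match.arg(reward_source)
  if (decision_threshold < 1) abort("decision_threshold must be >= 1.")
  if (decision_timeout <= 0) abort("decision_timeout must be > 0.")
  if (n_trials < 1) abort("n_trials must be >= 1.")
  if (!setequal(names(correct_map), c("red", "blue"))) {
    abort("correct_map must map exactly the cues 'red' and 'blue'.")
  }
  structure(list(
    decision_threshold = decision_threshold,
    decision_timeout = decision_timeout,
    reward_duration = reward_duration,
    cue_drive = cue_drive, reward_drive = reward_drive,
    reward_vc_weight = reward_vc_weight,
    reward_pmc_weight = reward_pmc_weight,
    vc_delay = vc_delay, pmc_delay = pmc_delay,
    n_trials = as.integer(n_trials), correct_map = correct_map,
    reward_source = reward_source, sad_depresses = sad_depresses,
    criterion_run = as.integer(criterion_run),
    ablate_plasticity = ablate_plasticity,
    network = network, pitch = pitch,
    reward_profiles = reward_profiles
  ), class = "scenario_config")
}

cue_vc_group <- function(color) if (color == "red") "VC1" else "VC2"
action_pmc_group <- function(action) if (action == "left") "PMC1" else "PMC2"

#' Dominant primary color of a cue image
#'
#' Compares the summed red and blue channel mass and returns the larger; an
#' exact tie is rejected as an ambiguous cue so the caller can re-present
#' the card.
#'
#' @param image A numeric `h x w x 3` RGB array (e.g. from
#'   [make_card_image()]).
#' @return `"red"` or `"blue"`.
#' @export
dominant_color <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] < 3) {
    abort("`image` must be an RGB array.")
  }
  if (prod(dim(image)) == 0) abort("`image` is empty.")
  red <- sum(image[, , 1])
  blue <- sum(image[, , 3])
  if (red == blue) abort("Ambiguous cue: red and blue mass are equal.")
  if (red > blue) "red" else "blue"
}

#' Decide from premotor activity
#'
#' Scans the spike log from cue onset and accumulates running spike counts
#' for PMC1 and PMC2; the first instant at which the counts differ by at
#' least the decision threshold determines the action (PMC1 -> left,
#' PMC2 -> right). If the threshold is never reached inside the timeout the
#' decision is `"none"`.
#'
#' @param log Spike log tibble (`time_ms`, `neuron`, `group`).
#' @param cfg A [scenario_config()].
#' @param t_start Cue onset time in ms (log times before this are ignored).
#' @return A list with `side` (`"left"`, `"right"` or `"none"`) and
#'   `time_ms` (decision time, `NA` if none).
#' @export
decide <- function(log, cfg, t_start = 0) {
  pmc <- log[log$group %in% c("PMC1", "PMC2") &
               log$time_ms > t_start &
               log$time_ms <= t_start + cfg$decision_timeout, ]
  pmc <- pmc[order(pmc$time_ms), ]
  if (nrow(pmc) > 0) {
    d <- cumsum(ifelse(pmc$group == "PMC1", 1L, -1L))
    hit <- which(abs(d) >= cfg$decision_threshold)
    if (length(hit) > 0) {
      i <- hit[1]
      return(list(side = if (d[i] > 0) "left" else "right",
                  time_ms = pmc$time_ms[i]))
    }
  }
  list(side = "none", time_ms = NA_real_)
}

#' Classify a spoken reward
#'
#' Runs the full speech path (pitch tracking, endpointing, feature
#' extraction, classification) on the first detected utterance.
#'
#' @param audio An [audio_signal()] containing the spoken response.
#' @param model A trained `esp_model`.
#' @param cfg A [pitch_config()].
#' @return `"happy"` or `"sad"`; `"none"` (with a warning) if no utterance
#'   is detected.
#' @export
reward_from_speech <- function(audio, model, cfg = pitch_config()) {
  feats <- esp_features(audio, cfg)
  if (nrow(feats) == 0) {
    warn("No utterance detected in reward audio; treating as no reward.")
    return("none")
  }
  esp_classify(model, feats[1, ])$.pred
}

synth_reward_audio <- function(label, cfg) {
  profs <- cfg$reward_profiles
  cand <- profs[profs$label == label, ]
  if (nrow(cand) == 0) abort(sprintf("No reward profile for label '%s'.", label))
  row <- cand[sample.int(nrow(cand), 1), ]
  class(row) <- c("prosody_profile", class(tibble()))
  synthesize_utterance(row, duration = 1.0,
                       seed = sample.int(.Machine$integer.max, 1))
}

#' Run one cue -> decision -> reward trial
#'
#' Presents the cue (stimulating VC1 for red, VC2 for blue), runs the
#' network through the decision window, reads the decision off the premotor
#' spike counts, and, when the response is happy, enables plasticity and
#' delivers correlated reward volleys to the cued VC column and the chosen
#' PMC column for the reward window before disabling plasticity again. No
#' weight can change outside that window.
#'
#' @param state A `network_state`.
#' @param cue `"red"`/`"blue"`, or an RGB cue-card array whose dominant
#'   color is used.
#' @param cfg A [scenario_config()].
#' @param model Optional `esp_model`, required when
#'   `cfg$reward_source == "audio"`.
#' @return A list with `state` (advanced network) and `log` (one-row trial
#'   tibble).
#' @export
run_trial <- function(state, cue, cfg = scenario_config(), model = NULL) {
  stopifnot(inherits(state, "network_state"))
  color <- if (is.character(cue)) match.arg(cue, c("red", "blue")) else dominant_color(cue)
  vc <- cue_vc_group(color)
  t0 <- state$t
  w_pre <- weights_table(state)

  cue_stim <- stimulus_spec(vc, cfg$cue_drive)
  state <- run_interval(state, cue_stim, cfg$decision_timeout)
  log <- spike_log(state)
  dec <- decide(log, cfg, t_start = t0)
  window <- c(t0, t0 + cfg$decision_timeout)
  pmc1_rate <- group_rate(log, "PMC1", window, state$cfg$n_per_group)
  pmc2_rate <- group_rate(log, "PMC2", window, state$cfg$n_per_group)

  correct <- !identical(dec$side, "none") &&
    identical(unname(cfg$correct_map[color]), dec$side)
  reward_label <- "none"
  reward_given <- FALSE
  if (!identical(dec$side, "none")) {
    intended <- if (correct) "happy" else "sad"
    reward_label <- if (cfg$reward_source == "audio") {
      if (is.null(model)) abort("reward_source = 'audio' requires a trained model.")
      # the spoken-reward path draws from an isolated RNG stream (seeded by
      # the simulation clock) so audio- and label-driven sessions consume
      # identical randomness for the network itself
      rng_state <- get(".Random.seed", envir = globalenv())
      set.seed(as.integer(round(state$t)) %% .Machine$integer.max)
      lab <- reward_from_speech(synth_reward_audio(intended, cfg), model,
                                cfg$pitch)
      assign(".Random.seed", rng_state, envir = globalenv())
      lab
    } else intended
    reward_given <- identical(reward_label, "happy")
    pmc <- action_pmc_group(dec$side)
    if (reward_given) {
      # happy: causal volleys (VC leads, chosen PMC follows) potentiate
      feedback_stim <- bind_rows(
        stimulus_spec(vc, cfg$reward_drive, kind = "volley_periodic",
                      weight = cfg$reward_vc_weight,
                      delay_lo = cfg$vc_delay[1], delay_hi = cfg$vc_delay[2],
                      volley_id = 1L),
        stimulus_spec(pmc, cfg$reward_drive, kind = "volley_periodic",
                      weight = cfg$reward_pmc_weight,
                      delay_lo = cfg$pmc_delay[1], delay_hi = cfg$pmc_delay[2],
                      volley_id = 1L)
      )
      state <- set_plasticity(state, !cfg$ablate_plasticity)
      state <- run_interval(state, feedback_stim, cfg$reward_duration)
      state <- set_plasticity(state, FALSE)
    } else if (cfg$sad_depresses && identical(reward_label, "sad")) {
      # sad: anti-causal volleys (chosen PMC leads, cue VC follows) put
      # every pairing on the depression branch, weakening the pathway that
      # produced the wrong action
      feedback_stim <- bind_rows(
        stimulus_spec(vc, cfg$reward_drive, kind = "volley_periodic",
                      weight = cfg$reward_vc_weight,
                      delay_lo = cfg$pmc_delay[1], delay_hi = cfg$pmc_delay[2],
                      volley_id = 1L),
        stimulus_spec(pmc, cfg$reward_drive, kind = "volley_periodic",
                      weight = cfg$reward_pmc_weight,
                      delay_lo = cfg$vc_delay[1], delay_hi = cfg$vc_delay[2],
                      volley_id = 1L)
      )
      state <- set_plasticity(state, !cfg$ablate_plasticity)
      state <- run_interval(state, feedback_stim, cfg$reward_duration,
                            depression_only = TRUE)
      state <- set_plasticity(state, FALSE)
    }
  }
  w_post <- weights_table(state)

  wide <- function(wt, suffix) {
    vals <- stats::setNames(wt$mean_weight_uS,
                            paste0("w_", gsub("[->]+", "_", tolower(wt$projection)),
                                   "_", suffix))
    as_tibble(as.list(vals))
  }
  log_row <- tibble(
    cue = color, decision = dec$side,
    decision_time_ms = dec$time_ms,
    correct = correct, reward_given = reward_given,
    reward_label = reward_label,
    pmc1_rate_hz = pmc1_rate, pmc2_rate_hz = pmc2_rate
  )
  log_row <- dplyr::bind_cols(log_row, wide(w_pre, "pre"), wide(w_post, "post"))
  list(state = state, log = log_row)
}

probe_rates <- function(state, cfg, duration = 1000) {
  # measure evoked and idle PMC rates on a throwaway copy, plasticity off
  probe_one <- function(color) {
    st <- set_plasticity(state, FALSE)
    t0 <- st$t
    stim <- if (color == "none") NULL else
      stimulus_spec(cue_vc_group(color), cfg$cue_drive)
    st <- run_interval(st, stim, duration)
    log <- spike_log(st)
    tibble(
      cue = color,
      pmc1_rate_hz = group_rate(log, "PMC1", c(t0, t0 + duration),
                                state$cfg$n_per_group),
      pmc2_rate_hz = group_rate(log, "PMC2", c(t0, t0 + duration),
                                state$cfg$n_per_group)
    )
  }
  bind_rows(probe_one("red"), probe_one("blue"), probe_one("none"))
}

#' Run a full learning session
#'
#' Presents a random red/blue cue sequence for `n_trials` trials. Rewards
#' follow the happy-iff-correct policy: a correct decision earns a happy
#' response (enabling reward-gated plasticity), an incorrect one a sad
#' response. Evoked premotor rates are probed (plasticity off, on a state
#' copy) before and after the trial sequence.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed governing the wiring, cue order and all Poisson
#'   drives; the same seed reproduces the session exactly.
#' @param model Optional `esp_model` for `reward_source = "audio"`.
#' @return An object of class `vnr_session`: a list with `trials` (tibble,
#'   one row per trial), `summary` (one-row tibble), `probes` (evoked-rate
#'   probes before/after), `state` (final network), and `config`.
#' @export
#' @examples
#' \donttest{
#' sess <- run_session(scenario_config(n_trials = 10), seed = 1)
#' glance(sess)
#' }
run_session <- function(cfg = scenario_config(), seed = 1, model = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(seed)
  net_cfg <- cfg$network
  net_cfg$seed <- sample.int(.Machine$integer.max, 1)
  cues <- sample(c("red", "blue"), cfg$n_trials, replace = TRUE)
  state <- build_network(net_cfg)

  probes_before <- probe_rates(state, cfg)
  rows <- vector("list", cfg$n_trials)
  for (k in seq_len(cfg$n_trials)) {
    res <- run_trial(state, cues[k], cfg, model)
    state <- res$state
    rows[[k]] <- tibble(trial = k, res$log)
  }
  trials <- bind_rows(rows)
  probes_after <- probe_rates(state, cfg)

  summary <- tibble(
    seed = seed,
    n_trials = cfg$n_trials,
    accuracy = mean(trials$correct),
    n_rewards = sum(trials$reward_given),
    criterion_trial = criterion_trial(trials$correct, cfg$criterion_run),
    w_vc1_pmc1_final = mean_weight(state, "VC1", "PMC1"),
    w_vc2_pmc2_final = mean_weight(state, "VC2", "PMC2"),
    w_vc1_pmc2_final = mean_weight(state, "VC1", "PMC2"),
    w_vc2_pmc1_final = mean_weight(state, "VC2", "PMC1")
  )
  structure(list(
    trials = trials, summary = summary,
    probes = bind_rows(
      tibble(phase = "before", probes_before),
      tibble(phase = "after", probes_after)
    ),
    state = state, config = cfg
  ), class = "vnr_session")
}

#' First trial of sustained correct performance
#'
#' The smallest trial index from which every remaining decision is correct,
#' provided at least `run_length` such trials remain; `NA` if the session
#' never reaches criterion.
#'
#' @param correct Logical vector of per-trial correctness.
#' @param run_length Minimum length of the closing correct run.
#' @return Trial index or `NA`.
#' @export
criterion_trial <- function(correct, run_length = 5) {
  n <- length(correct)
  if (n < run_length) return(NA_integer_)
  for (k in seq_len(n - run_length + 1)) {
    if (all(correct[k:n])) return(k)
  }
  NA_integer_
}

#' @export
print.vnr_session <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<vnr_session: %d trials, accuracy %.2f, criterion trial %s, %d rewards>\n",
    s$n_trials, s$accuracy,
    ifelse(is.na(s$criterion_trial), "not reached", s$criterion_trial),
    s$n_rewards
  ))
  invisible(x)
}

#' @export
tidy.vnr_session <- function(x, ...) x$trials

#' @export
glance.vnr_session <- function(x, ...) x$summary

#' Write session outputs to a directory
#'
#' Emits `trial_log.csv`, `weights.csv` (final per-synapse weights),
#' `spikes.csv` and `summary.json`.
#'
#' @param session A `vnr_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "vnr_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$trials, file.path(dir, "trial_log.csv"),
                   row.names = FALSE)
  utils::write.csv(session$state$synapses, file.path(dir, "weights.csv"),
                   row.names = FALSE)
  utils::write.csv(spike_log(session$state), file.path(dir, "spikes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(session$summary), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
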