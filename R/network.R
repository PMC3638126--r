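#' Leaky integrate-and-fire neuron parameters
#'
#' Conductance-based LIF parameters shared by all neurons of the model.
#' Potentials are in mV, times in ms, conductances in microsiemens; the
#' membrane capacitance is implied by `leak_conductance * membrane_tau`.
#'
#' @param membrane_tau Membrane time constant, ms.
#' @param rest_potential Resting (leak reversal) potential, mV.
#' @param threshold Spike threshold, mV; must exceed the reset potential.
#' @param reset_potential Post-spike reset potential, mV.
#' @param refractory Absolute refractory period, ms.
#' @param excitatory_reversal Excitatory synaptic reversal potential, mV.
#' @param synapse_tau Exponential synaptic conductance decay, ms.
#' @param leak_conductance Leak conductance, microsiemens.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(membrane_tau = 20, rest_potential = -65,
                       threshold = -50, reset_potential = -65,
                       refractory = 2, excitatory_reversal = 0,
                       synapse_tau = 5, leak_conductance = 0.025) {
  if (reset_potential >= threshold) abort("Need reset_potential < threshold.")
  if (membrane_tau <= 0 || synapse_tau <= 0 || refractory <= 0) {
    abort("membrane_tau, synapse_tau and refractory must be positive.")
  }
  if (leak_conductance <= 0) abort("leak_conductance must be positive.")
  structure(list(
    membrane_tau = membrane_tau, rest_potential = rest_potential,
    threshold = threshold, reset_potential = reset_potential,
    refractory = refractory, excitatory_reversal = excitatory_reversal,
    synapse_tau = synapse_tau, leak_conductance = leak_conductance
  ), class = "lif_params")
}

vnr_groups <- c("VC1", "VC2", "PMC1", "PMC2")

vnr_projections <- tibble::tibble(
  projection = c("VC1->PMC1", "VC2->PMC2", "VC1->PMC2", "VC2->PMC1"),
  pre_group = c("VC1", "VC2", "VC1", "VC2"),
  post_group = c("PMC1", "PMC2", "PMC2", "PMC1"),
  potentiating = c(TRUE, TRUE, FALSE, FALSE)
)

#' Network configuration for the four-column model
#'
#' Two visual-cortex columns (VC1, VC2) feed two premotor columns (PMC1,
#' PMC2), ten neurons each. Every VC neuron connects to every PMC neuron of
#' both columns independently with probability 0.5 at an initial weight of
#' 0.006 microsiemens. The matched projections VC1->PMC1 and VC2->PMC2
#' carry the full STDP rule; the crossed projections are depression-only
#' (`a_plus` treated as 0). The premotor columns additionally receive an
#' unspecific background Poisson drive that keeps their idle firing near
#' 4 Hz; the visual columns are driven only by stimuli.
#'
#' @param n_per_group Neurons per column.
#' @param connection_probability Independent VC->PMC connection probability.
#' @param initial_weight Initial synaptic weight, microsiemens.
#' @param w_max Weight upper bound, microsiemens (weights live in
#'   `[0, w_max]`).
#' @param dt Integration step, ms (must be <= 1).
#' @param lif [lif_params()].
#' @param stdp [stdp_rule()].
#' @param pairing `"nearest"` (each spike pairs once with the most recent
#'   partner spike) or `"all"` (all pairs within the windows).
#' @param background_rate Background Poisson rate per neuron, Hz.
#' @param background_groups Groups receiving the background drive. By
#'   default only the premotor columns: visual columns are stimulus-driven
#'   and silent at rest, premotor columns idle near 4 Hz.
#' @param background_weight Conductance increment per background event,
#'   microsiemens.
#' @param stim_weight Conductance increment per stimulus event,
#'   microsiemens.
#' @param seed Integer seed used for the wiring.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_per_group = 10, connection_probability = 0.5,
                           initial_weight = 0.006, w_max = 0.012,
                           dt = 0.1, lif = lif_params(), stdp = stdp_rule(),
                           pairing = c("nearest", "all"),
                           background_rate = 150, background_weight = 0.006,
                           background_groups = c("PMC1", "PMC2"),
                           stim_weight = 0.006, seed = 1) {
  pairing <- match.arg(pairing)
  if (n_per_group < 1) abort("Need at least one neuron per group.")
  if (connection_probability <= 0 || connection_probability > 1) {
    abort("connection_probability must be in (0, 1].")
  }
  if (initial_weight < 0 || initial_weight > w_max) {
    abort("initial_weight must lie within [0, w_max].")
  }
  if (dt <= 0 || dt > 1) abort("dt must be in (0, 1] ms.")
  structure(list(
    n_per_group = as.integer(n_per_group),
    connection_probability = connection_probability,
    initial_weight = initial_weight, w_max = w_max, dt = dt,
    lif = lif, stdp = stdp, pairing = pairing,
    background_rate = background_rate,
    background_weight = background_weight,
    background_groups = background_groups,
    stim_weight = stim_weight, seed = as.integer(seed)
  ), class = "network_config")
}

#' Build the network state
#'
#' Draws the random wiring under `cfg$seed` (each VC/PMC pair connected
#' independently with the configured probability; no recurrent or
#' within-area connections), sets every weight to the initial value, and
#' initializes membranes at rest with plasticity disabled.
#'
#' @param cfg A [network_config()].
#' @return An object of class `network_state`.
#' @export
#' @examples
#' net <- build_network(network_config(seed = 42))
#' mean_weight(net, "VC1", "PMC1")
build_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  m <- cfg$n_per_group
  neurons <- tibble(
    id = seq_len(4L * m),
    group = rep(vnr_groups, each = m)
  )
  group_ids <- function(g) neurons$id[neurons$group == g]

  set.seed(cfg$seed)
  syn <- vector("list", nrow(vnr_projections))
  for (p in seq_len(nrow(vnr_projections))) {
    pre <- group_ids(vnr_projections$pre_group[p])
    post <- group_ids(vnr_projections$post_group[p])
    grid <- expand.grid(pre = pre, post = post)
    keep <- runif(nrow(grid)) < cfg$connection_probability
    syn[[p]] <- tibble(
      pre = grid$pre[keep], post = grid$post[keep],
      projection = vnr_projections$projection[p],
      potentiating = vnr_projections$potentiating[p],
      weight = cfg$initial_weight
    )
  }
  synapses <- bind_rows(syn)

  structure(list(
    cfg = cfg,
    neurons = neurons,
    synapses = synapses,
    V = rep(cfg$lif$rest_potential, nrow(neurons)),
    g = rep(0, nrow(neurons)),
    refrac_until = rep(-Inf, nrow(neurons)),
    t = 0,
    plasticity_enabled = FALSE,
    spike_log = list(),
    hist = rep(list(numeric()), nrow(neurons))
  ), class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "<network_state: %d neurons (4 groups), %d synapses, t = %.1f ms, plasticity %s>\n",
    nrow(x$neurons), nrow(x$synapses), x$t,
    if (x$plasticity_enabled) "on" else "off"
  ))
  invisible(x)
}

#' Enable or disable plasticity
#'
#' While disabled, weights are bit-identical before and after any amount of
#' simulation.
#'
#' @param state A `network_state`.
#' @param enabled Logical.
#' @return The modified state.
#' @export
set_plasticity <- function(state, enabled) {
  stopifnot(inherits(state, "network_state"))
  state$plasticity_enabled <- isTRUE(enabled)
  state
}

#' Describe an external stimulus
#'
#' Three stimulus kinds are supported. `"poisson_drive"` delivers
#' independent Poisson conductance events to each neuron of the group at an
#' aggregate rate shared equally across the group. `"volley_drive"` draws a
#' single shared event stream at `rate` Hz and delivers each event to every
#' neuron of the group with an independent delay drawn uniformly from
#' `[delay_lo, delay_hi]` ms; this produces near-synchronous volleys and is
#' used to model correlated reward input. `"volley_periodic"` is the same
#' with regularly spaced events (period `1000/rate` ms, first event half a
#' period in), as a patterned stimulator would deliver them.
#' `"current_step"` injects a constant current (`rate` read as nA per
#' neuron).
#'
#' @param group Target group name (`"VC1"`, `"VC2"`, `"PMC1"`, `"PMC2"`).
#' @param rate Aggregate Poisson rate (Hz), shared volley rate (Hz), or
#'   current amplitude (nA), depending on `kind`.
#' @param start,stop Active interval in ms, relative to the start of the
#'   `run_interval` call; `stop` must exceed `start`.
#' @param kind `"poisson_drive"`, `"volley_drive"`, `"volley_periodic"` or
#'   `"current_step"`.
#' @param weight Conductance increment per event, microsiemens (defaults to
#'   the network's `stim_weight`).
#' @param delay_lo,delay_hi Per-neuron delivery delay range for
#'   `"volley_drive"`, ms.
#' @param volley_id Volley drives sharing the same positive id draw their
#'   events from one shared stream (the first such drive's rate applies),
#'   so separate groups can receive correlated volleys with different
#'   conduction delays.
#' @return A one-row tibble.
#' @export
stimulus_spec <- function(group, rate, start = 0, stop = Inf,
                          kind = c("poisson_drive", "volley_drive",
                                   "volley_periodic", "current_step"),
                          weight = NA_real_, delay_lo = 0, delay_hi = 0,
                          volley_id = 0L) {
  kind <- match.arg(kind)
  group <- match.arg(group, vnr_groups)
  if (rate < 0) abort("Stimulus rate/amplitude must be >= 0.")
  if (stop <= start) abort("Need stop > start.")
  if (delay_hi < delay_lo || delay_lo < 0) {
    abort("Need 0 <= delay_lo <= delay_hi.")
  }
  tibble(group = group, rate = rate, start = start, stop = stop,
         kind = kind, weight = weight,
         delay_lo = delay_lo, delay_hi = delay_hi,
         volley_id = as.integer(volley_id))
}

run_segment <- function(state, rates, weights, types, delay_lo, delay_hi,
                        volley_ids, i_ext, duration,
                        depression_only = FALSE, record_every = 0) {
  cfg <- state$cfg
  proj_levels <- vnr_projections$projection
  res <- sim_run_cpp(
    state$V, state$g, state$refrac_until,
    as.integer(state$synapses$pre), as.integer(state$synapses$post),
    state$synapses$weight, as.integer(state$synapses$potentiating),
    match(state$synapses$projection, proj_levels),
    unclass(cfg$lif), c(unclass(cfg$stdp), list(w_max = cfg$w_max)),
    rates, weights, as.integer(types), delay_lo, delay_hi,
    as.integer(volley_ids), i_ext,
    state$t, duration, cfg$dt,
    state$plasticity_enabled, cfg$pairing == "all", depression_only,
    state$hist, record_every, length(proj_levels)
  )
  state$V <- res$V
  state$g <- res$g
  state$refrac_until <- res$refrac_until
  state$synapses$weight <- res$syn_w
  state$hist <- res$spike_hist
  if (length(res$spike_t) > 0) {
    state$spike_log[[length(state$spike_log) + 1L]] <- tibble(
      time_ms = res$spike_t,
      neuron = res$spike_n,
      group = state$neurons$group[res$spike_n]
    )
  }
  if (is.matrix(res$weight_trace) && nrow(res$weight_trace) > 0) {
    tr <- as.data.frame(res$weight_trace)
    names(tr) <- c("time_ms", proj_levels)
    attr(state, "last_weight_trace") <- tidyr::pivot_longer(
      as_tibble(tr), -"time_ms",
      names_to = "projection", values_to = "mean_weight_uS"
    )
  }
  state$t <- state$t + duration
  state
}

#' Advance the network
#'
#' Runs the simulation for `duration` ms under the given stimuli, appending
#' to the spike log. Stimuli with start/stop times inside the interval are
#' honored by splitting the interval at their boundaries. Randomness
#' (Poisson drives) is drawn from R's RNG stream, so results are
#' deterministic after `set.seed()`.
#'
#' @param state A `network_state` from [build_network()].
#' @param stimuli `NULL`, or a tibble of [stimulus_spec()] rows.
#' @param duration Interval length in ms, > 0.
#' @param depression_only If `TRUE`, plastic updates use only the
#'   depression branch for this interval (the "sad feedback depresses"
#'   variant).
#' @param record_weights_every If > 0, mean projection weights are sampled
#'   every this many ms and stored as attribute `last_weight_trace`.
#' @return The advanced `network_state`.
#' @export
run_interval <- function(state, stimuli = NULL, duration,
                         depression_only = FALSE,
                         record_weights_every = 0) {
  stopifnot(inherits(state, "network_state"))
  if (duration <= 0) abort("`duration` must be > 0.")
  cfg <- state$cfg
  n <- nrow(state$neurons)

  bounds <- c(0, duration)
  if (!is.null(stimuli) && nrow(stimuli) > 0) {
    bounds <- c(bounds, stimuli$start, pmin(stimuli$stop, duration))
  }
  bounds <- sort(unique(pmax(0, pmin(bounds, duration))))

  for (b in seq_len(length(bounds) - 1)) {
    seg_start <- bounds[b]
    seg_len <- bounds[b + 1] - seg_start
    if (seg_len <= 0) next
    bg_row <- numeric(n)
    bg_row[state$neurons$group %in% cfg$background_groups] <- cfg$background_rate
    rates <- matrix(bg_row, nrow = 1, ncol = n)
    weights <- cfg$background_weight
    types <- 0L
    delay_lo <- 0
    delay_hi <- 0
    volley_ids <- 0L
    i_ext <- numeric(n)
    if (!is.null(stimuli) && nrow(stimuli) > 0) {
      for (s in seq_len(nrow(stimuli))) {
        if (stimuli$start[s] <= seg_start && stimuli$stop[s] > seg_start) {
          members <- state$neurons$group == stimuli$group[s]
          if (stimuli$kind[s] == "current_step") {
            i_ext[members] <- i_ext[members] + stimuli$rate[s]
          } else {
            row <- numeric(n)
            is_volley <- stimuli$kind[s] %in% c("volley_drive",
                                                "volley_periodic")
            row[members] <- if (is_volley) stimuli$rate[s] else
              stimuli$rate[s] / sum(members)
            rates <- rbind(rates, row)
            w <- stimuli$weight[s]
            weights <- c(weights, if (is.na(w)) cfg$stim_weight else w)
            types <- c(types, switch(stimuli$kind[s], poisson_drive = 0L,
                                     volley_drive = 1L, volley_periodic = 2L))
            delay_lo <- c(delay_lo, stimuli$delay_lo[s])
            delay_hi <- c(delay_hi, stimuli$delay_hi[s])
            volley_ids <- c(volley_ids, stimuli$volley_id[s])
          }
        }
      }
    }
    state <- run_segment(state, rates, weights, types, delay_lo, delay_hi,
                         volley_ids, i_ext, seg_len,
                         depression_only, record_weights_every)
  }
  state
}

#' Advance the network by a single step
#'
#' Convenience wrapper over [run_interval()] for one integration step.
#'
#' @inheritParams run_interval
#' @param dt Step length in ms (defaults to the configured step; must be
#'   <= 1 ms).
#' @return The advanced `network_state`.
#' @export
step_network <- function(state, stimuli = NULL, dt = NULL) {
  dt <- dt %||% state$cfg$dt
  if (dt > 1) abort("`dt` must be <= 1 ms.")
  run_interval(state, stimuli, duration = dt)
}

#' Spike log as a tibble
#'
#' @param state A `network_state`.
#' @return Tibble `time_ms`, `neuron`, `group` (possibly empty).
#' @export
spike_log <- function(state) {
  stopifnot(inherits(state, "network_state"))
  if (length(state$spike_log) == 0) {
    return(tibble(time_ms = numeric(), neuron = integer(),
                  group = character()))
  }
  bind_rows(state$spike_log)
}

#' Mean synaptic weight of a projection
#'
#' @param state A `network_state`.
#' @param pre_group,post_group Group names.
#' @return Mean weight in microsiemens.
#' @export
mean_weight <- function(state, pre_group, post_group) {
  stopifnot(inherits(state, "network_state"))
  sel <- state$synapses$pre %in%
    state$neurons$id[state$neurons$group == pre_group] &
    state$synapses$post %in%
      state$neurons$id[state$neurons$group == post_group]
  if (!any(sel)) {
    abort(sprintf(
      "Projection %s->%s has no synapses under this wiring seed; rebuild with another seed.",
      pre_group, post_group
    ))
  }
  mean(state$synapses$weight[sel])
}

#' Mean projection weights as a tibble
#'
#' @param state A `network_state`.
#' @return Tibble `projection`, `n_synapses`, `mean_weight_uS`.
#' @export
weights_table <- function(state) {
  stopifnot(inherits(state, "network_state"))
  state$synapses |>
    group_by(projection = .data$projection) |>
    summarise(n_synapses = n(), mean_weight_uS = mean(.data$weight),
              .groups = "drop")
}

#' Population firing rate of a group
#'
#' Spikes of the group inside the window divided by (number of neurons x
#' window length), in Hz.
#'
#' @param log Spike log tibble (`time_ms`, `neuron`, `group`).
#' @param group Group name.
#' @param window Numeric length-2 vector `c(start, stop)` in ms.
#' @param n_neurons Neurons in the group (default 10).
#' @return Firing rate in Hz.
#' @export
group_rate <- function(log, group, window, n_neurons = 10) {
  if (!group %in% vnr_groups) abort(sprintf("Unknown group: %s", group))
  if (length(window) != 2 || diff(window) <= 0) {
    abort("`window` must be c(start, stop) with stop > start.")
  }
  n_spk <- sum(log$group == group & log$time_ms > window[1] &
                 log$time_ms <= window[2])
  n_spk / (n_neurons * diff(window) * 1e-3)
}
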