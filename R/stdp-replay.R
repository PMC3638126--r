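#' Recompute STDP weight changes from a complete spike log
#'
#' Independent audit of the simulator's incremental pairing bookkeeping:
#' given the full spike log of an interval simulated with plasticity on,
#' this replays every pairing event chronologically from scratch — without
#' any of the simulator's internal state — and returns the final weights.
#' Conventions mirror the simulator's contract: spikes at the same instant
#' pair on the depression branch (`delta_t = 0`); a new spike first pairs
#' as a postsynaptic partner (potentiation, with presynaptic spikes
#' strictly earlier), then as a presynaptic partner (depression, same-time
#' partners included); under nearest-neighbor pairing each new spike pairs
#' once with the most recent partner spike inside the window; each change
#' is `stdp_delta / 100 * w_max`, clamped to `[0, w_max]` immediately.
#'
#' @param log Spike log tibble (`time_ms`, `neuron`) covering the interval.
#' @param synapses Synapse tibble (`pre`, `post`, `potentiating`, `weight`
#'   holding the weights at the start of the interval).
#' @param rule An [stdp_rule()].
#' @param w_max Weight bound, microsiemens.
#' @param pairing `"nearest"` or `"all"`.
#' @param depression_only If `TRUE`, the potentiation branch is disabled
#'   (as during sad-feedback windows).
#' @return Numeric vector of final weights, in the synapse table's order.
#' @export
stdp_replay <- function(log, synapses, rule = stdp_rule(), w_max = 0.012,
                        pairing = c("nearest", "all"),
                        depression_only = FALSE) {
  pairing <- match.arg(pairing)
  nearest <- pairing == "nearest"
  w <- synapses$weight
  scale <- w_max / 100
  n_neuron <- max(c(synapses$pre, synapses$post, log$neuron), 0)
  hist <- rep(list(numeric()), n_neuron)

  in_syn <- split(seq_len(nrow(synapses)), synapses$post)
  out_syn <- split(seq_len(nrow(synapses)), synapses$pre)

  log <- log[order(log$time_ms, log$neuron), ]
  times <- unique(log$time_ms)
  for (t in times) {
    spiking <- sort(log$neuron[log$time_ms == t])
    # potentiation pass: new spikes as postsynaptic partners
    if (!depression_only) {
      for (q in spiking) {
        for (s in in_syn[[as.character(q)]]) {
          if (!synapses$potentiating[s]) next
          hp <- hist[[synapses$pre[s]]]
          hp <- hp[t - hp <= rule$window_plus]
          if (length(hp) == 0) next
          if (nearest) hp <- max(hp)
          for (tp in sort(hp, decreasing = TRUE)) {
            w[s] <- min(w_max, w[s] + scale * rule$a_plus *
                          exp((tp - t) / rule$tau_plus))
          }
        }
      }
    }
    # depression pass: new spikes as presynaptic partners
    for (p in spiking) {
      for (s in out_syn[[as.character(p)]]) {
        q <- synapses$post[s]
        hq <- hist[[q]]
        if (q %in% spiking) hq <- c(hq, t)  # simultaneous spike: delta 0
        hq <- hq[t - hq <= rule$window_minus]
        if (length(hq) == 0) next
        if (nearest) hq <- max(hq)
        for (tq in sort(hq, decreasing = TRUE)) {
          w[s] <- max(0, w[s] - scale * rule$a_minus *
                        exp(-(t - tq) / rule$tau_minus))
        }
      }
    }
    for (i in spiking) hist[[i]] <- c(hist[[i]], t)
  }
  w
}
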