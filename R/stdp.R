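#' Spike-timing-dependent plasticity rule
#'
#' Exponential STDP with asymmetric windows. With `dt = t_pre - t_post`,
#' pre-before-post spiking (`dt < 0`) potentiates by
#' `a_plus * exp(dt / tau_plus)` and post-before-pre (`dt >= 0`, the
#' boundary included) depresses by `a_minus * exp(-dt / tau_minus)`; the
#' change is zero outside the pairing windows (50 ms for potentiation,
#' 100 ms for depression at the defaults, both edges inclusive).
#'
#' The magnitudes `a_plus`/`a_minus` are expressed as percent of the
#' maximum synaptic conductance per pairing event: the network applies
#' `delta_w = stdp_delta(dt) / 100 * w_max` microsiemens.
#'
#' @param a_plus Maximum potentiation magnitude (default 20, percent of
#'   maximum conductance).
#' @param a_minus Maximum depression magnitude (default 10, same units).
#' @param tau_plus,tau_minus Decay constants in ms (default 5 and 5).
#' @param window_plus,window_minus Pairing windows in ms (default 50 and
#'   100); each must be at least its decay constant.
#' @return An object of class `stdp_rule`.
#' @export
#' @examples
#' rule <- stdp_rule()
#' stdp_delta(-5, rule)  # 20 * exp(-1)
stdp_rule <- function(a_plus = 20, a_minus = 10, tau_plus = 5, tau_minus = 5,
                      window_plus = 50, window_minus = 100) {
  vals <- c(a_plus, a_minus, tau_plus, tau_minus, window_plus, window_minus)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All STDP parameters must be positive and finite.")
  }
  if (window_plus < tau_plus || window_minus < tau_minus) {
    abort("Pairing windows must be at least their decay constants.")
  }
  structure(list(
    a_plus = a_plus, a_minus = a_minus,
    tau_plus = tau_plus, tau_minus = tau_minus,
    window_plus = window_plus, window_minus = window_minus
  ), class = "stdp_rule")
}

#' Evaluate the STDP weight-change curve
#'
#' @param delta_t Spike-time differences `t_pre - t_post` in ms (vectorized).
#' @param rule An [stdp_rule()].
#' @return Weight changes in the same units as `a_plus`/`a_minus` (percent
#'   of maximum conductance).
#' @export
stdp_delta <- function(delta_t, rule = stdp_rule()) {
  stopifnot(inherits(rule, "stdp_rule"))
  out <- numeric(length(delta_t))
  pot <- delta_t < 0 & delta_t >= -rule$window_plus
  dep <- delta_t >= 0 & delta_t <= rule$window_minus
  out[pot] <- rule$a_plus * exp(delta_t[pot] / rule$tau_plus)
  out[dep] <- -rule$a_minus * exp(-delta_t[dep] / rule$tau_minus)
  out
}
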