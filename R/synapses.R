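# Graded chemical synapses and electrical coupling: single-step reference
# operations mirrored by the compiled integration loop.

#' One exponential-Euler step of a graded synapse's activation
#'
#' The activation follows the sigmoid steady state
#' \code{s_inf = 1/(1 + exp((V_half - V_pre)/Delta))} with time constant
#' \code{tau_s = (1 - s_inf)/k_minus}, floored at \code{dt} so the update
#' stays well-behaved as \code{s_inf} approaches 1. The result is always
#' in [0, 1].
#'
#' @param syn List with \code{V_half}, \code{Delta} (mV), \code{k_minus}
#'   (ms^-1) — e.g. the params of a graded synapse.
#' @param s Current activation in [0, 1].
#' @param V_pre Presynaptic membrane potential (mV).
#' @param dt Time step (ms), > 0.
#' @return Updated activation.
#' @export
synapse_state_step <- function(syn, s, V_pre, dt) {
  stopifnot(dt > 0)
  s_inf <- 1 / (1 + exp((syn$V_half - V_pre) / syn$Delta))
  tau_s <- max((1 - s_inf) / syn$k_minus, dt)
  s_inf + (s - s_inf) * exp(-dt / tau_s)
}

#' Graded synaptic current into the postsynaptic compartment
#'
#' \code{I = gbar * s * (V_post - E_syn) * 1e-3} (nS x mV scaled to nA);
#' positive is outward from the postsynaptic compartment.
#'
#' @param syn List with \code{gbar} (nS) and \code{E_syn} (mV).
#' @param s Activation in [0, 1].
#' @param V_post Postsynaptic membrane potential (mV).
#' @return Current (nA).
#' @export
synapse_current <- function(syn, s, V_post) {
  syn$gbar * s * (V_post - syn$E_syn) * 1e-3
}

#' Currents through an electrical synapse
#'
#' Ohmic, symmetric coupling: the current into compartment \code{a} is
#' \code{g * (V_b - V_a) * 1e-3} nA and the current into \code{b} is its
#' negative, so the pair conserves charge exactly.
#'
#' @param g Coupling conductance (nS).
#' @param V_a,V_b Membrane potentials (mV).
#' @return Named numeric vector \code{c(I_into_a, I_into_b)} in nA.
#' @export
electrical_current <- function(g, V_a, V_b) {
  i_a <- g * (V_b - V_a) * 1e-3
  c(I_into_a = i_a, I_into_b = -i_a)
}
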