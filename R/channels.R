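# Built-in channel library (classic lobster stomatogastric kinetics) and
# channel-level operations.
#
# Units: V mV, t ms, gbar uS/mm^2, A mm^2, currents nA, Ca uM.
# Sign convention: positive current = outward.

.sigm <- function(V, half, slope) 1 / (1 + exp((half - V) / slope))

.register_builtin_channels <- function() {
  # Fast sodium
  register_channel("NaV", p = 3, q = 1,
    m_inf = function(V) 1 / (1 + exp(-(V + 25.5) / 5.29)),
    h_inf = function(V) 1 / (1 + exp((V + 48.9) / 5.18)),
    tau_m = function(V) 1.32 - 1.26 / (1 + exp(-(V + 120) / 25)),
    tau_h = function(V) (0.67 / (1 + exp(-(V + 62.9) / 10))) *
      (1.5 + 1 / (1 + exp((V + 34.9) / 3.6))),
    default_gbar = 1000, default_E = 50)
  # Transient (low-threshold) calcium
  register_channel("CaT", p = 3, q = 1,
    m_inf = function(V) 1 / (1 + exp(-(V + 27.1) / 7.2)),
    h_inf = function(V) 1 / (1 + exp((V + 32.1) / 5.5)),
    tau_m = function(V) 21.7 - 21.3 / (1 + exp(-(V + 68.1) / 20.5)),
    tau_h = function(V) 105 - 89.8 / (1 + exp(-(V + 55) / 16.9)),
    default_gbar = 25, default_E = 30, is_calcium = TRUE)
  # Slow (persistent) calcium
  register_channel("CaS", p = 3, q = 1,
    m_inf = function(V) 1 / (1 + exp(-(V + 33) / 8.1)),
    h_inf = function(V) 1 / (1 + exp((V + 60) / 6.2)),
    tau_m = function(V) 1.4 + 7 / (exp((V + 27) / 10) + exp(-(V + 70) / 13)),
    tau_h = function(V) 60 + 150 / (exp((V + 55) / 9) + exp(-(V + 65) / 16)),
    default_gbar = 60, default_E = 30, is_calcium = TRUE)
  # Transient potassium (A-type)
  register_channel("ACurrent", p = 3, q = 1,
    m_inf = function(V) 1 / (1 + exp(-(V + 27.2) / 8.7)),
    h_inf = function(V) 1 / (1 + exp((V + 56.9) / 4.9)),
    tau_m = function(V) 11.6 - 10.4 / (1 + exp(-(V + 32.9) / 15.2)),
    tau_h = function(V) 38.6 - 29.2 / (1 + exp(-(V + 38.9) / 26.5)),
    default_gbar = 500, default_E = -80)
  # Calcium-gated potassium; activation carries a Ca/(Ca+3) factor
  register_channel("KCa", p = 4, q = 0,
    m_inf = function(V) 1 / (1 + exp(-(V + 28.3) / 12.6)),
    tau_m = function(V) 90.3 - 75.1 / (1 + exp(-(V + 46) / 22.7)),
    default_gbar = 50, default_E = -80, ca_dep = TRUE, ca_half = 3)
  # Delayed-rectifier potassium
  register_channel("Kd", p = 4, q = 0,
    m_inf = function(V) 1 / (1 + exp(-(V + 12.3) / 11.8)),
    tau_m = function(V) 7.2 - 6.4 / (1 + exp(-(V + 28.3) / 19.2)),
    default_gbar = 1000, default_E = -80)
  # Hyperpolarization-activated inward current
  register_channel("HCurrent", p = 1, q = 0,
    m_inf = function(V) 1 / (1 + exp((V + 70) / 6)),
    tau_m = function(V) 272 + 1499 / (1 + exp(-(V + 42.2) / 8.73)),
    default_gbar = 0.1, default_E = -20)
  # Passive leak
  register_channel("Leak", p = 0, q = 0,
    default_gbar = 1, default_E = -50)
}

.register_builtin_synapses <- function() {
  register_synapse("Glutamatergic", E_syn = -70, V_half = -35, Delta = 5,
                   k_minus = 1 / 40, default_gbar = 0)
  register_synapse("Cholinergic", E_syn = -80, V_half = -35, Delta = 5,
                   k_minus = 1 / 100, default_gbar = 0)
  register_synapse("Electrical", electrical = TRUE, default_gbar = 0)
}

.register_builtin_mechanisms <- function() {
  register_mechanism("CalciumMech",
    params = list(tau_Ca = 200, f = 14.96, Ca_0 = 0.05,
                  Ca_out = 3000, T = 11),
    source = paste(
      "mechanism CalciumMech",
      "dCa/dt = (-f*I_Ca - Ca + Ca_0)/tau_Ca  (exponential Euler, Ca >= 0)",
      "E_Ca = 1000*R*(T+273.15)/(2*F) * log(Ca_out/Ca)", sep = "\n"))
  register_mechanism("IntegralController",
    params = list(tau_m = 5e5, tau_g = 5000, Ca_target = 7, mRNA = 0),
    source = paste(
      "mechanism IntegralController",
      "dmRNA/dt = (Ca_target - Ca)/tau_m",
      "dg/dt = (mRNA - g)/tau_g  (g floored at 0)", sep = "\n"))
}

#' Current through one channel population
#'
#' Ohmic current \code{gbar * m^p * h^q * (V - E) * A} in nA; positive is
#' outward. The current is linear in both \code{gbar} and \code{A}.
#'
#' @param cond A conductance instance (as stored in a model tree), or a
#'   list with fields \code{type}, \code{params$gbar}, \code{params$E},
#'   \code{state$m}, \code{state$h}.
#' @param V Membrane potential (mV).
#' @param A Compartment surface area (mm^2).
#' @return Current in nA.
#' @export
channel_current <- function(cond, V, A) {
  spec <- channel_info(cond$type)
  m <- if (spec$p > 0) cond$state$m else 1
  h <- if (spec$q > 0) cond$state$h else 1
  cond$params$gbar * m^spec$p * h^spec$q * (V - cond$params$E) * A
}

#' Steady-state gating curves of a channel type
#'
#' Evaluates \code{m_inf}, \code{h_inf}, \code{tau_m}, \code{tau_h} on a
#' voltage grid. Non-inactivating channels report \code{h_inf = 1} and
#' \code{tau_h = NA}. For calcium-dependent activation, the saturating
#' calcium factor is applied when \code{Ca} is supplied, otherwise the pure
#' voltage dependence is returned.
#'
#' @param type Channel-type name.
#' @param V Voltage grid (mV); default \eqn{-100..100} at 1 mV.
#' @param Ca Optional intracellular calcium (uM) for calcium-dependent
#'   activation curves.
#' @return A data.frame with columns \code{V, m_inf, h_inf, tau_m, tau_h},
#'   or \code{NULL} (with a message) for an ungated channel.
#' @export
steady_state_curves <- function(type, V = seq(-100, 100, by = 1), Ca = NULL) {
  spec <- channel_info(type)
  if (spec$p == 0 && spec$q == 0) {
    message(type, " has no gating curves (passive)")
    return(invisible(NULL))
  }
  m <- spec$m_inf(V)
  if (spec$ca_dep && !is.null(Ca)) m <- m * Ca / (Ca + spec$ca_half)
  data.frame(
    V = V,
    m_inf = m,
    h_inf = if (spec$q > 0) spec$h_inf(V) else rep(1, length(V)),
    tau_m = spec$tau_m(V),
    tau_h = if (spec$q > 0) spec$tau_h(V) else rep(NA_real_, length(V))
  )
}
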