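# Intracellular mechanisms: calcium influx/buffering with Nernst reversal,
# and calcium-error integral control of conductance densities. These
# single-step functions are the reference forms of what the compiled
# integration loop executes each time step.

.FARADAY <- 96485.33212
.GAS_R <- 8.314462618

#' One exponential-Euler step of calcium buffering
#'
#' Calcium relaxes toward the instantaneous fixed point
#' \code{Ca_inf = Ca_0 - f * I_Ca} with time constant \code{tau_Ca}
#' (inward calcium current is negative, so influx raises \code{Ca_inf}).
#' The result is clipped at 0 from below.
#'
#' @param mech List with \code{tau_Ca} (ms), \code{f} (uM/nA),
#'   \code{Ca_0} (uM) — e.g. the params of a \code{CalciumMech}.
#' @param Ca Current calcium concentration (uM).
#' @param I_Ca_total Total current through calcium channels (nA).
#' @param dt Time step (ms), > 0.
#' @return Updated calcium concentration (uM).
#' @export
calcium_step <- function(mech, Ca, I_Ca_total, dt) {
  stopifnot(dt > 0)
  ca_inf <- mech$Ca_0 - mech$f * I_Ca_total
  ca <- ca_inf + (Ca - ca_inf) * exp(-dt / mech$tau_Ca)
  max(ca, 0)
}

#' Nernst reversal potential for calcium
#'
#' \code{E = 1000 * R * T_K / (2 F) * ln(Ca_out / Ca_in)} in mV, with
#' \code{T_K = T + 273.15}.
#'
#' @param mech List with \code{Ca_out} (uM) and \code{T} (degrees C).
#' @param Ca_in Intracellular calcium (uM), > 0.
#' @return Reversal potential (mV).
#' @export
nernst_reversal <- function(mech, Ca_in) {
  if (any(Ca_in <= 0)) stop("Ca_in must be > 0")
  1000 * .GAS_R * (mech$T + 273.15) / (2 * .FARADAY) *
    log(mech$Ca_out / Ca_in)
}

#' One step of the calcium-error integral controller
#'
#' The mRNA variable integrates the deviation of calcium from its target;
#' the conductance density relaxes toward the mRNA level ("translation").
#' mRNA may go negative; the conductance is floored at 0.
#'
#' @param ctrl List with \code{tau_m} (mRNA timescale, ms), \code{tau_g}
#'   (translation timescale, ms), \code{Ca_target} (uM).
#' @param mRNA Current mRNA level.
#' @param Ca Current calcium (uM).
#' @param g Current maximal conductance density (uS/mm^2).
#' @param dt Time step (ms), > 0.
#' @return List with \code{mRNA} and \code{g} after one step.
#' @export
controller_step <- function(ctrl, mRNA, Ca, g, dt) {
  stopifnot(dt > 0)
  mRNA_new <- mRNA + dt * (ctrl$Ca_target - Ca) / ctrl$tau_m
  g_new <- max(g + dt * (mRNA - g) / ctrl$tau_g, 0)
  list(mRNA = mRNA_new, g = g_new)
}
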