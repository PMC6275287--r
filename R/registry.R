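# Component registries: channel types, synapse types, mechanism types.
# Registered equation sources participate in structural hashing, so the
# stored deparsed text must be deterministic.

.nd_registry <- new.env(parent = emptyenv())

.registry_init <- function() {
  .nd_registry$channels <- list()
  .nd_registry$synapses <- list()
  .nd_registry$mechanisms <- list()
}

.validation_grid <- function() seq(-100, 100, by = 1)

.fun_source <- function(f) {
  if (is.null(f)) return("<none>")
  paste(deparse(f, width.cutoff = 500L), collapse = "\n")
}

#' Register an ion-channel type
#'
#' Adds a Hodgkin-Huxley style channel type to the registry so that it can
#' be attached to compartments. The open probability of the population is
#' \code{m^p * h^q} where each gating variable relaxes toward its
#' voltage-dependent steady state with a voltage-dependent time constant.
#'
#' Gating curves are validated on a standard grid (\eqn{-100..100} mV):
#' steady states must lie in [0, 1] and time constants must be strictly
#' positive there. Exponents must be non-negative integers.
#'
#' @param name Unique channel-type name.
#' @param p,q Integer activation/inactivation exponents (\code{q = 0} for a
#'   non-inactivating channel; then no \code{h} state is allocated).
#' @param m_inf,tau_m,h_inf,tau_h Functions of voltage (mV) returning the
#'   steady-state curves (unitless) and time constants (ms). For a
#'   calcium-dependent activation (see \code{ca_dep}), \code{m_inf} is the
#'   voltage-dependent factor; the full steady state is
#'   \code{Ca/(Ca + ca_half) * m_inf(V)}.
#' @param default_gbar Default maximal conductance density (uS/mm^2).
#' @param default_E Default reversal potential (mV). Ignored dynamically for
#'   calcium channels once a calcium mechanism updates the Nernst reversal.
#' @param is_calcium Flag: current through this channel counts as calcium
#'   influx and its reversal tracks intracellular calcium.
#' @param ca_dep Flag: activation steady state carries the saturating
#'   calcium factor \code{Ca/(Ca + ca_half)}.
#' @param ca_half Half-saturation calcium concentration (uM) for
#'   \code{ca_dep} channels.
#' @param overwrite Replace an existing registration instead of erroring.
#' @return The channel spec, invisibly.
#' @export
register_channel <- function(name, p, q,
                             m_inf = NULL, tau_m = NULL,
                             h_inf = NULL, tau_h = NULL,
                             default_gbar = 0, default_E = -50,
                             is_calcium = FALSE, ca_dep = FALSE,
                             ca_half = 3, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!overwrite && name %in% names(.nd_registry$channels))
    stop("channel type already registered: ", name)
  if (length(p) != 1L || length(q) != 1L || p < 0 || q < 0 ||
      p != round(p) || q != round(q))
    stop("exponents p and q must be non-negative integers")
  p <- as.integer(p); q <- as.integer(q)
  if (p > 0 && (is.null(m_inf) || is.null(tau_m)))
    stop("p > 0 requires m_inf and tau_m")
  if (q > 0 && (is.null(h_inf) || is.null(tau_h)))
    stop("q > 0 requires h_inf and tau_h")
  V <- .validation_grid()
  chk_ss <- function(f, what) {
    y <- f(V)
    if (!all(is.finite(y)) || any(y < -1e-9) || any(y > 1 + 1e-9))
      stop(what, " must lie in [0,1] on [-100,100] mV")
  }
  chk_tau <- function(f, what) {
    y <- f(V)
    if (!all(is.finite(y)) || any(y <= 0))
      stop(what, " must be strictly positive on [-100,100] mV")
  }
  if (p > 0) { chk_ss(m_inf, "m_inf"); chk_tau(tau_m, "tau_m") }
  if (q > 0) { chk_ss(h_inf, "h_inf"); chk_tau(tau_h, "tau_h") }
  spec <- list(
    name = name, p = p, q = q,
    m_inf = m_inf, tau_m = tau_m, h_inf = h_inf, tau_h = tau_h,
    default_gbar = default_gbar, default_E = default_E,
    is_calcium = isTRUE(is_calcium), ca_dep = isTRUE(ca_dep),
    ca_half = ca_half,
    source = paste(
      sprintf("channel %s p=%d q=%d is_calcium=%d ca_dep=%d ca_half=%.17g",
              name, p, q, as.integer(isTRUE(is_calcium)),
              as.integer(isTRUE(ca_dep)), ca_half),
      .fun_source(m_inf), .fun_source(tau_m),
      .fun_source(h_inf), .fun_source(tau_h), sep = "\n")
  )
  class(spec) <- "channel_spec"
  .nd_registry$channels[[name]] <- spec
  invisible(spec)
}

.unregister_channel <- function(name) {
  .nd_registry$channels[[name]] <- NULL
  invisible(NULL)
}

#' Registered channel types
#' @return Character vector of channel-type names.
#' @export
list_channels <- function() sort(names(.nd_registry$channels))

#' Look up a channel spec
#' @param name Channel-type name.
#' @return The registered spec.
#' @export
channel_info <- function(name) {
  spec <- .nd_registry$channels[[name]]
  if (is.null(spec)) stop("unknown channel type: ", name)
  spec
}

#' Register a graded or electrical synapse type
#'
#' Graded synapse types carry default kinetic constants for the sigmoid
#' activation \code{s_inf(V_pre) = 1/(1 + exp((V_half - V_pre)/Delta))} and
#' the closing rate \code{k_minus} (ms^-1); electrical types are ohmic
#' gap junctions.
#'
#' @param name Unique type name.
#' @param E_syn Reversal potential (mV) of the synaptic current.
#' @param V_half,Delta Sigmoid midpoint and slope (mV).
#' @param k_minus Closing rate (ms^-1).
#' @param electrical If TRUE, register an electrical (gap-junction) type;
#'   kinetic arguments are ignored.
#' @param default_gbar Default maximal conductance (nS).
#' @param overwrite Replace an existing registration.
#' @return The synapse spec, invisibly.
#' @export
register_synapse <- function(name, E_syn = -70, V_half = -35, Delta = 5,
                             k_minus = 1 / 40, electrical = FALSE,
                             default_gbar = 0, overwrite = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!overwrite && name %in% names(.nd_registry$synapses))
    stop("synapse type already registered: ", name)
  if (!electrical && Delta <= 0) stop("Delta must be > 0")
  spec <- list(
    name = name, electrical = isTRUE(electrical),
    E_syn = E_syn, V_half = V_half, Delta = Delta, k_minus = k_minus,
    default_gbar = default_gbar,
    source = sprintf(
      "synapse %s electrical=%d E=%.17g V_half=%.17g Delta=%.17g k_minus=%.17g",
      name, as.integer(isTRUE(electrical)), E_syn, V_half, Delta, k_minus)
  )
  class(spec) <- "synapse_spec"
  .nd_registry$synapses[[name]] <- spec
  invisible(spec)
}

#' Registered synapse types
#' @return Character vector of synapse-type names.
#' @export
list_synapses <- function() sort(names(.nd_registry$synapses))

synapse_info <- function(name) {
  spec <- .nd_registry$synapses[[name]]
  if (is.null(spec)) stop("unknown synapse type: ", name)
  spec
}

register_mechanism <- function(name, params, source) {
  .nd_registry$mechanisms[[name]] <-
    list(name = name, params = params, source = source)
  invisible(NULL)
}

mechanism_info <- function(name) {
  spec <- .nd_registry$mechanisms[[name]]
  if (is.null(spec)) stop("unknown mechanism type: ", name)
  spec
}
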