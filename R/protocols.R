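# Experiment layer: spike and burst detection, f-I curves, in-silico
# voltage-clamp characterization with sigmoid^n activation recovery,
# dominant-current labeling, trace-similarity cost, parameter sweeps.

.trace_V <- function(trace, compartment = NULL) {
  if (is.numeric(trace)) return(trace)
  V <- trace$V
  if (is.null(compartment)) V[, 1] else V[, compartment]
}

#' Spike detection and firing rate
#'
#' Spikes are upward crossings of a threshold (default 0 mV) separated by
#' at least a refractory interval. The rate is the spike count divided by
#' the trace duration.
#'
#' @param trace A \code{neuro_trace} or a numeric voltage vector.
#' @param t Time vector (ms); taken from the trace if omitted.
#' @param compartment Compartment label (defaults to the first).
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum separation between detected spikes (ms).
#' @return \code{spike_times}: numeric vector of spike times (ms);
#'   \code{firing_rate}: rate in Hz.
#' @export
spike_times <- function(trace, t = NULL, compartment = NULL,
                        threshold = 0, refractory = 1) {
  V <- .trace_V(trace, compartment)
  if (is.null(t)) t <- trace$t
  stopifnot(length(V) == length(t), all(is.finite(V)))
  n <- length(V)
  if (n < 2L) return(numeric(0))
  up <- which(V[-1] >= threshold & V[-n] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  tt <- t[up]
  keep <- tt[1]
  for (x in tt[-1]) if (x - keep[length(keep)] >= refractory)
    keep <- c(keep, x)
  keep
}

#' @rdname spike_times
#' @export
firing_rate <- function(trace, t = NULL, compartment = NULL,
                        threshold = 0, refractory = 1) {
  if (is.null(t)) t <- trace$t
  spk <- spike_times(trace, t, compartment, threshold, refractory)
  dur <- t[length(t)] - t[1] + (t[2] - t[1])
  1000 * length(spk) / dur
}

#' Group spikes into bursts
#'
#' Spikes closer than \code{max_isi} belong to one burst.
#'
#' @param spk Spike times (ms).
#' @param max_isi Maximum intra-burst inter-spike interval (ms).
#' @return data.frame with \code{onset}, \code{offset}, \code{n_spikes}.
#' @export
detect_bursts <- function(spk, max_isi = 100) {
  if (!length(spk))
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      n_spikes = integer(0)))
  brk <- c(0L, which(diff(spk) > max_isi), length(spk))
  do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    w <- spk[(brk[i] + 1L):brk[i + 1L]]
    data.frame(onset = w[1], offset = w[length(w)], n_spikes = length(w))
  }))
}

#' f-I curve
#'
#' Integrates the model once per current amplitude (always restarting from
#' the same initial state) and reports the firing rate after discarding a
#' transient.
#'
#' @param tree A model tree.
#' @param I_values Injected-current amplitudes (nA), sorted.
#' @param t_end Simulated time per amplitude (ms).
#' @param t_transient Initial interval dropped before counting spikes (ms).
#' @param compartment Compartment to stimulate/record (default first).
#' @param dt Step size (ms).
#' @return data.frame with columns \code{I} (nA) and \code{rate} (Hz).
#' @export
fi_curve <- function(tree, I_values, t_end = 2000, t_transient = 500,
                     compartment = NULL, dt = NULL) {
  stopifnot(inherits(tree, "model_tree"), !is.unsorted(I_values))
  if (is.null(compartment)) compartment <- names(tree$compartments)[1]
  rate <- vapply(I_values, function(I) {
    tr <- tryCatch(
      integrate_model(tree, t_end = t_end, dt = dt,
                      I_ext = stats::setNames(list(I), compartment)),
      error = function(e) stop("integration failed at I = ", I, " nA: ",
                               conditionMessage(e), call. = FALSE))
    keep <- tr$t > t_transient
    firing_rate(tr$V[keep, compartment], tr$t[keep])
  }, numeric(1))
  data.frame(I = I_values, rate = rate)
}

#' Recover a channel's activation curve from simulated voltage clamp
#'
#' Reproduces the classic characterization pipeline: a single-compartment
#' model containing only the channel of interest is clamped to each
#' voltage step; the asymptotic clamp current (mean over the last 10\% of
#' the step) divided by the driving force gives the conductance-voltage
#' curve, which is normalized and fitted with
#' \code{[1/(1 + exp((V_half - V)/k))]^n} by least squares for each
#' candidate exponent. The exponent with the smallest residual sum of
#' squares is selected.
#'
#' @param channel_type Registered channel-type name.
#' @param V_steps Clamp voltages (mV) spanning the activation range.
#' @param E_rev Reversal potential (mV); defaults to the registered value.
#'   Steps at the reversal are dropped (zero driving force) with a warning.
#' @param n_candidates Integer exponents to try.
#' @param t_clamp Clamp-step duration (ms).
#' @param dt Step size (ms).
#' @param gbar,A Conductance density (uS/mm^2) and area (mm^2) of the test
#'   compartment.
#' @return An \code{activation_fit}: list with \code{V}, \code{g},
#'   \code{g_norm}, \code{I_inf}, \code{n_best}, \code{V_half}, \code{k},
#'   and per-exponent \code{residuals}.
#' @export
recover_activation <- function(channel_type, V_steps = seq(-80, 50, by = 5),
                               E_rev = NULL, n_candidates = 1:8,
                               t_clamp = 500, dt = 0.05,
                               gbar = 1000, A = 0.01) {
  spec <- channel_info(channel_type)
  if (is.null(E_rev)) E_rev <- spec$default_E
  tree <- model_tree()
  tree <- add_compartment(tree, "cell", A = A, V = -80)
  tree <- add_conductance(tree, "cell", channel_type, gbar = gbar, E = E_rev)
  drop <- abs(V_steps - E_rev) < 1e-9
  if (any(drop)) {
    warning("dropping clamp step(s) at the reversal potential: ",
            paste(V_steps[drop], collapse = ", "), " mV")
    V_steps <- V_steps[!drop]
  }
  I_inf <- vapply(V_steps, function(vc) {
    tr <- integrate_model(tree, t_end = t_clamp, dt = dt,
                          V_clamp = c(cell = vc))
    tail_n <- max(1L, ceiling(0.1 * length(tr$t)))
    mean(utils::tail(tr$I_clamp[, 1], tail_n))
  }, numeric(1))
  g <- I_inf / (V_steps - E_rev)       # uS (total conductance)
  g_norm <- g / max(g)
  fits <- .fit_sigmoid_n(V_steps, g_norm, n_candidates)
  best <- which.min(fits$rss)
  structure(list(V = V_steps, I_inf = I_inf, g = g, g_norm = g_norm,
                 n_candidates = n_candidates,
                 n_best = n_candidates[best],
                 V_half = fits$V_half[best], k = fits$k[best],
                 residuals = stats::setNames(fits$rss,
                                             paste0("n", n_candidates))),
            class = "activation_fit")
}

# Least-squares sigmoid^n fits with deterministic multi-start. Because the
# data are normalized by their maximum over the tested voltage range, the
# model is normalized the same way (divide by its value at the largest
# step); the true exponent then fits the data exactly.
.fit_sigmoid_n <- function(V, y, n_candidates) {
  starts <- expand.grid(vh = c(-60, -40, -20, 0), k = c(5, 15))
  Vmax <- max(V)
  rss <- vh <- kk <- rep(NA_real_, length(n_candidates))
  for (i in seq_along(n_candidates)) {
    n <- n_candidates[i]
    for (r in seq_len(nrow(starts))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ (1 / (1 + exp((vh - V) / k)))^n /
            (1 / (1 + exp((vh - Vmax) / k)))^n,
          start = list(vh = starts$vh[r], k = starts$k[r]),
          lower = c(vh = -120, k = 0.1), upper = c(vh = 60, k = 60),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      r2 <- sum(residuals(fit)^2)
      if (is.na(rss[i]) || r2 < rss[i] - 1e-12) {
        rss[i] <- r2
        vh[i] <- coef(fit)[["vh"]]
        kk[i] <- coef(fit)[["k"]]
      }
    }
    if (is.na(rss[i]))
      warning("sigmoid^", n, " fit did not converge from any start")
  }
  list(rss = rss, V_half = vh, k = kk)
}

#' @export
print.activation_fit <- function(x, ...) {
  cat("<activation_fit> best exponent n =", x$n_best,
      sprintf("(V_half = %.2f mV, k = %.2f mV)\n", x$V_half, x$k))
  cat("  residual sum of squares by exponent:\n")
  print(signif(x$residuals, 4))
  invisible(x)
}

#' Label each sample with its dominant membrane current
#'
#' While the voltage rises, the dominant current is the strongest inward
#' (most negative) channel current; while it falls, the strongest outward
#' (most positive). Ties go to the first channel in registry order.
#'
#' @param trace A \code{neuro_trace} recorded with
#'   \code{record_currents = TRUE}.
#' @param compartment Compartment label (default first).
#' @return Character vector (one label per sample) of conductance names.
#' @export
dominant_current_labels <- function(trace, compartment = NULL) {
  if (is.null(trace$currents))
    stop("trace lacks channel currents; integrate with record_currents = TRUE")
  if (is.null(compartment)) compartment <- colnames(trace$V)[1]
  sel <- startsWith(colnames(trace$currents), paste0(compartment, "/"))
  if (!any(sel)) stop("no recorded currents for compartment ", compartment)
  cur <- trace$currents[, sel, drop = FALSE]
  chan <- sub("^[^/]*/", "", colnames(cur))
  V <- trace$V[, compartment]
  dV <- c(V[2] - V[1], diff(V))
  idx <- integer(length(V))
  for (i in seq_along(V))
    idx[i] <- if (dV[i] >= 0) which.min(cur[i, ]) else which.max(cur[i, ])
  chan[idx]
}

#' Trajectory-similarity cost between two voltage traces
#'
#' Each trace is embedded as a point cloud in the (V, dV/dt) plane and
#' binned on a shared fixed grid; the cost is the total absolute
#' difference between the two normalized occupancy histograms, bounded in
#' [0, 2] (0 for identical traces, 2 for non-overlapping embeddings).
#'
#' @param trace_a,trace_b \code{neuro_trace} objects or numeric voltage
#'   vectors.
#' @param dt_a,dt_b Sample intervals (ms) when numeric vectors are given.
#' @param bins Number of bins per axis.
#' @param V_range Voltage range (mV) of the grid.
#' @param compartment Compartment label for trace inputs.
#' @return Cost in [0, 2].
#' @export
lemasson_error <- function(trace_a, trace_b, dt_a = NULL, dt_b = NULL,
                           bins = 100, V_range = c(-80, 50),
                           compartment = NULL) {
  if (is.null(dt_b)) dt_b <- dt_a
  get <- function(tr, dt) {
    if (is.numeric(tr)) {
      if (is.null(dt)) stop("dt required for numeric trace input")
      list(V = tr, dt = dt)
    } else list(V = .trace_V(tr, compartment), dt = tr$out_dt)
  }
  a <- get(trace_a, dt_a)
  b <- get(trace_b, dt_b)
  if (length(a$V) < 2L || length(b$V) < 2L) stop("traces too short")
  dva <- diff(a$V) / a$dt
  dvb <- diff(b$V) / b$dt
  M <- max(abs(c(dva, dvb)), 1e-12)
  hist2 <- function(V, dv) {
    V <- V[-length(V)]
    ix <- pmin(pmax(floor((V - V_range[1]) / diff(V_range) * bins) + 1, 1),
               bins)
    iy <- pmin(pmax(floor((dv + M) / (2 * M) * bins) + 1, 1), bins)
    tabulate((iy - 1L) * bins + ix, nbins = bins * bins) / length(V)
  }
  sum(abs(hist2(a$V, dva) - hist2(b$V, dvb)))
}

#' Sweep one parameter through a protocol
#'
#' For each value the parameter is set on a copy of the baseline model and
#' the protocol is run; the baseline is untouched afterwards. The path
#' must resolve to exactly one numeric parameter.
#'
#' @param tree A model tree.
#' @param path Parameter path (e.g. \code{"HH/Kd/gbar"}).
#' @param values Numeric values to sweep.
#' @param protocol Function taking the modified tree (plus \code{...}).
#' @param ... Passed on to \code{protocol}.
#' @return Named list of protocol outputs, one per value.
#' @export
sweep_parameter <- function(tree, path, values, protocol, ...) {
  stopifnot(inherits(tree, "model_tree"), is.function(protocol))
  hits <- grepl(.path_regex(path), .layout_table(tree)$path)
  if (sum(hits) == 0L) stop("path does not resolve: ", path)
  if (sum(hits) > 1L)
    stop("ambiguous sweep path (", sum(hits), " matches): ", path)
  out <- lapply(values, function(v) protocol(set_param(tree, path, v), ...))
  names(out) <- as.character(values)
  out
}
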