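# Model flattening and the user-facing integration entry point.

.TAB_VMIN <- -150
.TAB_VMAX <- 150
.TAB_DV <- 0.05

# Flatten a model tree into the plain arrays the C++ core consumes.
.compile_model <- function(tree) {
  labs <- names(tree$compartments)
  nc <- length(labs)
  if (nc == 0L) stop("model has no compartments")
  A <- Cm <- V0 <- Ca0 <- numeric(nc)
  for (i in seq_len(nc)) {
    cmp <- tree$compartments[[i]]
    A[i] <- cmp$params$A; Cm[i] <- cmp$params$Cm
    V0[i] <- cmp$state$V; Ca0[i] <- cmp$state$Ca
  }

  ch <- list(comp = integer(0), name = character(0), type = character(0),
             gbar = numeric(0), E = numeric(0), p = integer(0),
             q = integer(0), isca = integer(0), cadep = integer(0),
             cahalf = numeric(0), m = numeric(0), h = numeric(0))
  types <- character(0)
  for (i in seq_len(nc)) {
    cmp <- tree$compartments[[i]]
    for (nm in names(cmp$conductances)) {
      cd <- cmp$conductances[[nm]]
      spec <- channel_info(cd$type)
      types <- union(types, cd$type)
      ch$comp <- c(ch$comp, i - 1L)
      ch$name <- c(ch$name, paste(labs[i], nm, sep = "/"))
      ch$type <- c(ch$type, cd$type)
      ch$gbar <- c(ch$gbar, cd$params$gbar)
      ch$E <- c(ch$E, cd$params$E)
      ch$p <- c(ch$p, spec$p); ch$q <- c(ch$q, spec$q)
      ch$isca <- c(ch$isca, as.integer(spec$is_calcium))
      ch$cadep <- c(ch$cadep, as.integer(spec$ca_dep))
      ch$cahalf <- c(ch$cahalf, spec$ca_half)
      ch$m <- c(ch$m, if (spec$p > 0) cd$state$m else 1)
      ch$h <- c(ch$h, if (spec$q > 0) cd$state$h else 1)
    }
  }
  nch <- length(ch$comp)

  # gating lookup tables: 4 rows per type (m_inf, tau_m, h_inf, tau_h)
  vgrid <- seq(.TAB_VMIN, .TAB_VMAX, by = .TAB_DV)
  nv <- length(vgrid)
  tabm <- matrix(1, nrow = max(4 * length(types), 1L), ncol = nv)
  for (k in seq_along(types)) {
    spec <- channel_info(types[k])
    r <- 4 * (k - 1)
    if (spec$p > 0) {
      tabm[r + 1, ] <- spec$m_inf(vgrid)
      tabm[r + 2, ] <- pmax(spec$tau_m(vgrid), 1e-3)
    }
    if (spec$q > 0) {
      tabm[r + 3, ] <- spec$h_inf(vgrid)
      tabm[r + 4, ] <- pmax(spec$tau_h(vgrid), 1e-3)
    }
  }
  ch$tab <- if (nch) match(ch$type, types) - 1L else integer(0)

  sy <- list(pre = integer(0), post = integer(0), g = numeric(0),
             E = numeric(0), vh = numeric(0), dl = numeric(0),
             km = numeric(0), s = numeric(0))
  el <- list(a = integer(0), b = integer(0), g = numeric(0))
  for (syn in tree$synapses) {
    if (syn$electrical) {
      el$a <- c(el$a, match(syn$pre, labs) - 1L)
      el$b <- c(el$b, match(syn$post, labs) - 1L)
      el$g <- c(el$g, syn$params$gbar * 1e-3)  # nS -> uS
    } else {
      sy$pre <- c(sy$pre, match(syn$pre, labs) - 1L)
      sy$post <- c(sy$post, match(syn$post, labs) - 1L)
      sy$g <- c(sy$g, syn$params$gbar * 1e-3)
      sy$E <- c(sy$E, syn$params$E_syn)
      sy$vh <- c(sy$vh, syn$params$V_half)
      sy$dl <- c(sy$dl, syn$params$Delta)
      sy$km <- c(sy$km, syn$params$k_minus)
      sy$s <- c(sy$s, syn$state$s)
    }
  }

  cam <- list(flag = integer(nc), tau = numeric(nc), f = numeric(nc),
              ca0 = numeric(nc), caout = rep(3000, nc), T = rep(11, nc))
  ct <- list(chan = integer(0), comp = integer(0), taum = numeric(0),
             taug = numeric(0), target = numeric(0), mrna = numeric(0),
             name = character(0))
  for (i in seq_len(nc)) {
    cmp <- tree$compartments[[i]]
    for (nm in names(cmp$mechanisms)) {
      mc <- cmp$mechanisms[[nm]]
      if (mc$type == "CalciumMech") {
        cam$flag[i] <- 1L
        cam$tau[i] <- mc$params$tau_Ca
        cam$f[i] <- mc$params$f
        cam$ca0[i] <- mc$params$Ca_0
        cam$caout[i] <- mc$params$Ca_out
        cam$T[i] <- mc$params$T
      } else if (mc$type == "IntegralController") {
        j <- match(paste(labs[i], mc$target, sep = "/"), ch$name)
        ct$chan <- c(ct$chan, j - 1L)
        ct$comp <- c(ct$comp, i - 1L)
        ct$taum <- c(ct$taum, mc$params$tau_m)
        ct$taug <- c(ct$taug, mc$params$tau_g)
        ct$target <- c(ct$target, mc$params$Ca_target)
        ct$mrna <- c(ct$mrna, mc$state$mRNA)
        ct$name <- c(ct$name, paste(labs[i], nm, sep = "/"))
      }
    }
  }

  list(ncomp = nc, labels = labs, A = A, Cm = Cm, V0 = V0, Ca0 = Ca0,
       ch_comp = ch$comp, ch_gbar = ch$gbar, ch_E = ch$E, ch_p = ch$p,
       ch_q = ch$q, ch_isca = ch$isca, ch_cadep = ch$cadep,
       ch_cahalf = ch$cahalf, ch_m = ch$m, ch_h = ch$h, ch_tab = ch$tab,
       ch_name = ch$name,
       tab = tabm, nv = nv, vmin = .TAB_VMIN, dv = .TAB_DV,
       sy_pre = sy$pre, sy_post = sy$post, sy_g = sy$g, sy_E = sy$E,
       sy_vh = sy$vh, sy_dl = sy$dl, sy_km = sy$km, sy_s = sy$s,
       el_a = el$a, el_b = el$b, el_g = el$g,
       cam_flag = cam$flag, cam_tau = cam$tau, cam_f = cam$f,
       cam_ca0 = cam$ca0, cam_caout = cam$caout, cam_T = cam$T,
       ct_chan = ct$chan, ct_comp = ct$comp, ct_taum = ct$taum,
       ct_taug = ct$taug, ct_target = ct$target, ct_mrna = ct$mrna,
       ct_name = ct$name,
       gax = numeric(max(nc - 1L, 0L)))
}

# Axial conductances (uS) between consecutive compartments of a chain from
# cylinder geometry: two half-cylinder resistances in series.
.axial_conductances <- function(tree) {
  labs <- names(tree$compartments)
  nc <- length(labs)
  half_res <- numeric(nc)  # MOhm
  for (i in seq_len(nc)) {
    p <- tree$compartments[[i]]$params
    if (is.null(p$radius) || is.null(p$len) || is.null(p$Ra))
      stop("crank_nicolson requires radius, len and Ra on every compartment ",
           "(or an explicit axial_g)")
    ra_mohm_mm <- p$Ra * 1e-5  # Ohm cm -> MOhm mm
    half_res[i] <- ra_mohm_mm * (p$len / 2) / (pi * p$radius^2)
  }
  if (nc < 2L) return(numeric(0))
  1 / (half_res[-nc] + half_res[-1])
}

# Normalize a per-compartment input (scalar, named vector, or named list of
# scalars/series) into scalar vector + optional full matrix.
.expand_input <- function(x, labs, nsteps, what) {
  nc <- length(labs)
  scalar <- numeric(nc)
  flag <- integer(nc)
  mat <- NULL
  if (is.null(x)) return(list(scalar = scalar, flag = flag, mat = mat))
  if (!is.list(x)) {
    if (is.null(names(x)) && length(x) == 1L && nc == 1L)
      names(x) <- labs
    x <- as.list(x)
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop(what, " must be named by compartment")
  bad <- setdiff(names(x), labs)
  if (length(bad)) stop("unknown compartment in ", what, ": ",
                        paste(bad, collapse = ", "))
  for (nm in names(x)) {
    i <- match(nm, labs)
    v <- x[[nm]]
    flag[i] <- 1L
    if (length(v) == 1L) {
      scalar[i] <- v
    } else {
      if (length(v) != nsteps)
        stop(what, " series for ", nm, " must have length nsteps = ", nsteps)
      if (is.null(mat)) mat <- matrix(0, nrow = nsteps, ncol = nc)
      mat[, i] <- v
      # scalar column stays 0; the matrix supersedes scalars below
    }
  }
  if (!is.null(mat)) {
    for (i in seq_len(nc))
      if (flag[i] == 1L && all(mat[, i] == 0) && scalar[i] != 0)
        mat[, i] <- scalar[i]
  }
  list(scalar = scalar, flag = flag, mat = mat)
}

#' Integrate a model
#'
#' Advances the full model (voltages, gating variables, calcium, synapse
#' activations, homeostatic controllers) with a fixed-step solver and
#' returns a trace sampled every \code{out_dt}. The advanced model (all
#' dynamic variables at the final time) is returned in the trace's
#' \code{$model} element, so runs can be chained and combined with
#' [snapshot()] / [restore_snapshot()].
#'
#' Solvers: \code{"exp_euler"} (default; exponential Euler on gating and
#' voltage, supports networks, clamp and mechanisms), \code{"rk4"}
#' (classical Runge-Kutta on the joint system; single compartment, no
#' synapses), \code{"crank_nicolson"} (implicit tridiagonal voltage solve
#' for an unbranched cable, gating staggered by exponential Euler).
#'
#' @param tree A model tree.
#' @param t_end Total simulated time (ms); defaults to the tree's setting.
#' @param dt Step size (ms).
#' @param out_dt Output sampling step (ms); must be a multiple of dt.
#' @param solver One of \code{"exp_euler"}, \code{"rk4"},
#'   \code{"crank_nicolson"}.
#' @param I_ext Injected current (nA): a single number (one-compartment
#'   models), or a named vector/list by compartment; each entry a scalar or
#'   a series of length \code{t_end/dt}.
#' @param V_clamp Clamp voltage (mV), same shapes as \code{I_ext}. Clamped
#'   compartments have their voltage pinned and the trace's
#'   \code{I_clamp} reports the total membrane current the clamp must
#'   supply.
#' @param record_currents Record per-channel currents (nA).
#' @param record_synapses Record graded-synapse activations.
#' @param record_controllers Record controller mRNA and regulated gbar.
#' @param axial_g Optional explicit axial conductances (uS, length
#'   \code{ncomp - 1}) for the cable solver, overriding geometry.
#' @return A \code{neuro_trace}: list with \code{t}, matrices \code{V},
#'   \code{Ca} (columns = compartments), optional \code{I_clamp},
#'   \code{currents}, \code{synapse_s}, \code{controllers}, the advanced
#'   \code{model}, and provenance metadata (\code{hash}, solver settings).
#' @export
integrate_model <- function(tree, t_end = NULL, dt = NULL, out_dt = NULL,
                            solver = NULL, I_ext = NULL, V_clamp = NULL,
                            record_currents = FALSE,
                            record_synapses = FALSE,
                            record_controllers = FALSE,
                            axial_g = NULL) {
  stopifnot(inherits(tree, "model_tree"))
  if (!length(tree$compartments)) stop("model has no compartments")
  dt <- if (is.null(dt)) tree$sim$dt else dt
  t_end <- if (is.null(t_end)) tree$sim$t_end else t_end
  solver <- if (is.null(solver)) tree$sim$solver else solver
  solver <- match.arg(solver, c("exp_euler", "rk4", "crank_nicolson"))
  out_dt <- if (is.null(out_dt)) dt else out_dt
  if (dt <= 0) stop("dt must be > 0")
  if (t_end < dt) stop("t_end must be >= dt")
  ratio <- out_dt / dt
  if (out_dt < dt || abs(ratio - round(ratio)) > 1e-8)
    stop("out_dt must be a positive multiple of dt")
  out_every <- as.integer(round(ratio))
  nsteps <- as.integer(floor(t_end / dt + 1e-9))

  cm <- .compile_model(tree)
  labs <- cm$labels
  iext <- .expand_input(I_ext, labs, nsteps, "I_ext")
  clmp <- .expand_input(V_clamp, labs, nsteps, "V_clamp")
  conflict <- which(clmp$flag == 1L & iext$flag == 1L)
  if (length(conflict))
    stop("compartment(s) cannot be clamped and current-injected at once: ",
         paste(labs[conflict], collapse = ", "))

  if (solver == "rk4") {
    if (cm$ncomp != 1L || length(tree$synapses))
      stop("rk4 supports only single-compartment models without synapses")
    if (length(cm$ct_chan))
      stop("rk4 does not support integral controllers")
    if (any(clmp$flag == 1L)) stop("voltage clamp requires exp_euler")
  }
  if (solver == "crank_nicolson") {
    if (length(tree$synapses))
      stop("crank_nicolson supports chains without synapses")
    if (any(clmp$flag == 1L)) stop("voltage clamp requires exp_euler")
    cm$gax <- if (!is.null(axial_g)) {
      if (length(axial_g) != cm$ncomp - 1L)
        stop("axial_g must have length ncomp - 1")
      as.numeric(axial_g)
    } else .axial_conductances(tree)
  }

  hash0 <- full_hash(tree)
  sim <- list(dt = dt, nsteps = nsteps, out_every = out_every,
              solver = match(solver,
                             c("exp_euler", "rk4", "crank_nicolson")) - 1L,
              iext_scalar = iext$scalar,
              use_iext_mat = !is.null(iext$mat),
              iext_mat = if (is.null(iext$mat)) matrix(0, 0, 0) else iext$mat,
              clamp_flag = clmp$flag,
              clamp_scalar = clmp$scalar,
              use_clamp_mat = !is.null(clmp$mat),
              clamp_mat = if (is.null(clmp$mat)) matrix(0, 0, 0) else clmp$mat,
              record_currents = record_currents,
              record_synapses = record_synapses,
              record_controllers = record_controllers)

  res <- cpp_integrate(cm, sim)

  colnames(res$V) <- labs
  colnames(res$Ca) <- labs
  tr <- list(t = as.numeric(res$t), V = res$V, Ca = res$Ca,
             dt = dt, out_dt = out_dt, t_end = nsteps * dt, solver = solver,
             hash = hash0)
  if (any(clmp$flag == 1L)) {
    ic <- res$I_clamp
    colnames(ic) <- labs
    tr$I_clamp <- ic[, clmp$flag == 1L, drop = FALSE]
  }
  if (record_currents) {
    colnames(res$currents) <- cm$ch_name
    tr$currents <- res$currents
  }
  if (record_synapses && ncol(res$syn_s)) {
    ids <- .synapse_ids(tree)
    graded <- !vapply(tree$synapses, `[[`, logical(1), "electrical")
    colnames(res$syn_s) <- ids[graded]
    tr$synapse_s <- res$syn_s
  }
  if (record_controllers && length(cm$ct_name)) {
    colnames(res$ctl_mrna) <- cm$ct_name
    colnames(res$ctl_g) <- cm$ct_name
    tr$controllers <- list(mRNA = res$ctl_mrna, gbar = res$ctl_g)
  }

  tr$model <- .writeback_state(tree, cm, res)
  class(tr) <- "neuro_trace"
  tr
}

# Push the final integrated state back into a tree.
.writeback_state <- function(tree, cm, res) {
  labs <- cm$labels
  for (i in seq_along(labs)) {
    tree$compartments[[i]]$state$V <- res$final_V[i]
    tree$compartments[[i]]$state$Ca <- res$final_Ca[i]
  }
  j <- 0L
  for (i in seq_along(labs)) {
    cmp <- tree$compartments[[i]]
    for (nm in names(cmp$conductances)) {
      j <- j + 1L
      spec <- channel_info(cmp$conductances[[nm]]$type)
      if (spec$p > 0) cmp$conductances[[nm]]$state$m <- res$final_m[j]
      if (spec$q > 0) cmp$conductances[[nm]]$state$h <- res$final_h[j]
      cmp$conductances[[nm]]$params$gbar <- res$final_gbar[j]
      cmp$conductances[[nm]]$params$E <- res$final_E[j]
    }
    tree$compartments[[i]] <- cmp
  }
  k <- 0L
  for (si in seq_along(tree$synapses)) {
    if (tree$synapses[[si]]$electrical) next
    k <- k + 1L
    tree$synapses[[si]]$state$s <- res$final_s[k]
  }
  k <- 0L
  for (i in seq_along(labs)) {
    cmp <- tree$compartments[[i]]
    for (nm in names(cmp$mechanisms)) {
      if (cmp$mechanisms[[nm]]$type != "IntegralController") next
      k <- k + 1L
      cmp$mechanisms[[nm]]$state$mRNA <- res$final_mrna[k]
    }
    tree$compartments[[i]] <- cmp
  }
  tree
}

#' @export
print.neuro_trace <- function(x, ...) {
  cat("<neuro_trace>", length(x$t), "samples x", ncol(x$V),
      "compartment(s);", x$solver, "dt =", x$dt, "ms, t_end =", x$t_end,
      "ms\n")
  cat("  model hash:", x$hash, "\n")
  invisible(x)
}
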