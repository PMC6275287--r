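# Hierarchical model container: named compartments holding conductances and
# mechanisms, plus directed synapses. Trees are plain R lists handled
# functionally: every modifier returns the updated tree.
#
# Every parameter and dynamic variable has a slash-separated path
# ("AB/NaV/gbar", "AB/V", "synapses/AB->LP/Glutamatergic/1/s"). Canonical
# (lexicographic, C locale) path order underlies serialization, snapshots
# and hashing, which makes all of them independent of construction order.

.sorted_names <- function(x) {
  nm <- names(x)
  if (is.null(nm)) character(0) else sort(nm, method = "radix")
}

#' Create an empty model tree
#'
#' @param dt,t_end,solver Default simulation settings stored with the tree
#'   and used by [integrate_model()] when not overridden.
#' @return An object of class \code{model_tree}.
#' @export
model_tree <- function(dt = 0.05, t_end = 1000, solver = "exp_euler") {
  structure(list(
    compartments = list(),
    synapses = list(),
    snapshots = list(),
    sim = list(dt = dt, t_end = t_end, solver = solver)
  ), class = "model_tree")
}

#' @export
print.model_tree <- function(x, ...) {
  cat("<model_tree>", length(x$compartments), "compartment(s),",
      length(x$synapses), "synapse(s),",
      state_count(x), "dynamic state variable(s)\n")
  for (lab in names(x$compartments)) {
    cmp <- x$compartments[[lab]]
    cat("  ", lab, ": ", paste(names(cmp$conductances), collapse = ", "),
        if (length(cmp$mechanisms))
          paste0(" | mech: ", paste(names(cmp$mechanisms), collapse = ", "))
        else "", "\n", sep = "")
  }
  invisible(x)
}

#' Add a compartment
#'
#' One isopotential membrane section with surface area \code{A} (mm^2),
#' specific capacitance \code{Cm} (nF/mm^2), membrane potential \code{V}
#' (mV) and intracellular calcium \code{Ca} (uM). Optional cylinder
#' geometry (\code{radius}, \code{len} in mm, axial resistivity \code{Ra}
#' in Ohm cm) enables the Crank-Nicolson cable solver.
#'
#' @param tree A model tree.
#' @param label Unique, non-empty compartment label.
#' @param A,Cm,V,Ca Membrane parameters and initial state.
#' @param radius,len,Ra Optional cable geometry.
#' @return The updated tree.
#' @export
add_compartment <- function(tree, label, A = 0.01, Cm = 10,
                            V = -60, Ca = 0.05,
                            radius = NULL, len = NULL, Ra = NULL) {
  stopifnot(inherits(tree, "model_tree"))
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("compartment label must be a non-empty string")
  if (grepl("/|\\*", label)) stop("label may not contain '/' or '*'")
  if (label %in% names(tree$compartments))
    stop("duplicate compartment label: ", label)
  if (A <= 0 || Cm <= 0 || Ca < 0)
    stop("require A > 0, Cm > 0, Ca >= 0")
  if (!is.null(radius) && is.null(A)) A <- 2 * pi * radius * len
  cmp <- list(label = label,
              params = list(A = A, Cm = Cm),
              state = list(V = V, Ca = Ca),
              conductances = list(),
              mechanisms = list())
  if (!is.null(radius)) cmp$params$radius <- radius
  if (!is.null(len)) cmp$params$len <- len
  if (!is.null(Ra)) cmp$params$Ra <- Ra
  tree$compartments[[label]] <- cmp
  tree
}

.init_gating <- function(spec, V, Ca) {
  st <- list()
  if (spec$p > 0) {
    m <- spec$m_inf(V)
    if (spec$ca_dep) m <- m * Ca / (Ca + spec$ca_half)
    st$m <- m
  }
  if (spec$q > 0) st$h <- spec$h_inf(V)
  st
}

#' Add an ion-channel population to a compartment
#'
#' Gating states are initialized at their steady-state values for the
#' compartment's current voltage (and calcium, for calcium-dependent
#' activation), which removes startup transients.
#'
#' @param tree A model tree.
#' @param compartment Compartment label.
#' @param type Registered channel-type name.
#' @param name Instance name (defaults to the type name); unique within the
#'   compartment.
#' @param gbar Maximal conductance density (uS/mm^2).
#' @param E Reversal potential (mV).
#' @return The updated tree.
#' @export
add_conductance <- function(tree, compartment, type, name = type,
                            gbar = NULL, E = NULL) {
  stopifnot(inherits(tree, "model_tree"))
  cmp <- tree$compartments[[compartment]]
  if (is.null(cmp)) stop("unknown compartment: ", compartment)
  spec <- channel_info(type)
  if (name %in% names(cmp$conductances))
    stop("duplicate conductance name in ", compartment, ": ", name)
  if (name %in% names(cmp$mechanisms))
    stop("name already used by a mechanism: ", name)
  gbar <- if (is.null(gbar)) spec$default_gbar else gbar
  E <- if (is.null(E)) spec$default_E else E
  if (gbar < 0) stop("gbar must be >= 0")
  cond <- list(type = type,
               params = list(gbar = gbar, E = E),
               state = .init_gating(spec, cmp$state$V, cmp$state$Ca))
  cmp$conductances[[name]] <- cond
  tree$compartments[[compartment]] <- cmp
  tree
}

#' Add an intracellular mechanism to a compartment
#'
#' \code{CalciumMech} models calcium influx through calcium channels and
#' first-order buffering back to a baseline, and keeps the calcium reversal
#' potential at its Nernst value. \code{IntegralController} integrates the
#' calcium error into an mRNA variable that drives the maximal conductance
#' of its \code{target} channel.
#'
#' @param tree A model tree.
#' @param compartment Compartment label.
#' @param type Registered mechanism type.
#' @param name Instance name; defaults to the type (calcium mechanism) or
#'   \code{<target>_ctrl} (controller).
#' @param target Conductance name regulated by an integral controller.
#' @param ... Parameter overrides (e.g. \code{tau_Ca}, \code{Ca_target}).
#' @return The updated tree.
#' @export
add_mechanism <- function(tree, compartment, type, name = NULL,
                          target = NULL, ...) {
  stopifnot(inherits(tree, "model_tree"))
  cmp <- tree$compartments[[compartment]]
  if (is.null(cmp)) stop("unknown compartment: ", compartment)
  spec <- mechanism_info(type)
  over <- list(...)
  bad <- setdiff(names(over), names(spec$params))
  if (length(bad)) stop("unknown parameter(s) for ", type, ": ",
                        paste(bad, collapse = ", "))
  params <- utils::modifyList(spec$params, over)
  mech <- list(type = type, params = params, state = list())
  if (type == "IntegralController") {
    if (is.null(target)) stop("IntegralController requires a target")
    if (!target %in% names(cmp$conductances))
      stop("controller target not found in ", compartment, ": ", target)
    mech$target <- target
    mech$state$mRNA <- params$mRNA
    mech$params$mRNA <- NULL
    if (is.null(name)) name <- paste0(target, "_ctrl")
  } else {
    if (type == "CalciumMech" &&
        any(vapply(cmp$mechanisms, function(m) m$type == "CalciumMech",
                   logical(1))))
      stop("compartment already has a CalciumMech: ", compartment)
    if (is.null(name)) name <- type
  }
  if (name %in% names(cmp$mechanisms) || name %in% names(cmp$conductances))
    stop("duplicate component name in ", compartment, ": ", name)
  cmp$mechanisms[[name]] <- mech
  tree$compartments[[compartment]] <- cmp
  tree
}

#' Add a component by kind
#'
#' Generic front end over [add_compartment()], [add_conductance()] and
#' [add_mechanism()]: insert a named component under a parent path with a
#' parameter list. Unspecified parameters take registered defaults.
#'
#' @param tree A model tree.
#' @param parent_path \code{""} (or NULL) for a compartment, otherwise the
#'   label of the parent compartment.
#' @param kind One of \code{"compartment"}, \code{"conductance"},
#'   \code{"mechanism"}.
#' @param name Component name.
#' @param params Named list of parameters. For conductances, \code{type}
#'   names the channel type (defaults to \code{name}); for mechanisms,
#'   \code{type} and optionally \code{target}.
#' @return The updated tree.
#' @export
add_component <- function(tree, parent_path = NULL, kind, name,
                          params = list()) {
  kind <- match.arg(kind, c("compartment", "conductance", "mechanism"))
  if (kind == "compartment") {
    allowed <- c("A", "Cm", "V", "Ca", "radius", "len", "Ra")
    bad <- setdiff(names(params), allowed)
    if (length(bad)) stop("unknown compartment parameter(s): ",
                          paste(bad, collapse = ", "))
    return(do.call(add_compartment, c(list(tree, name), params)))
  }
  if (is.null(parent_path) || !nzchar(parent_path))
    stop(kind, " requires a parent compartment")
  if (!parent_path %in% names(tree$compartments))
    stop("unknown parent: ", parent_path)
  if (kind == "conductance") {
    type <- if (!is.null(params$type)) params$type else name
    params$type <- NULL
    bad <- setdiff(names(params), c("gbar", "E"))
    if (length(bad)) stop("unknown conductance parameter(s): ",
                          paste(bad, collapse = ", "))
    return(do.call(add_conductance,
                   c(list(tree, parent_path, type, name), params)))
  }
  type <- if (!is.null(params$type)) params$type else name
  params$type <- NULL
  target <- params$target
  params$target <- NULL
  do.call(add_mechanism,
          c(list(tree, parent_path, type, name, target), params))
}

#' Connect two compartments with a synapse
#'
#' Appends a directed synapse. Parallel synapses between the same pair are
#' allowed; self-synapses are rejected. Electrical types are symmetric gap
#' junctions.
#'
#' @param tree A model tree.
#' @param pre,post Labels of the pre- and postsynaptic compartments.
#' @param type Registered synapse type.
#' @param gbar Maximal conductance (nS).
#' @param ... Overrides of the type's kinetic constants
#'   (\code{E_syn}, \code{V_half}, \code{Delta}, \code{k_minus}).
#' @return The updated tree.
#' @export
connect <- function(tree, pre, post, type, gbar = NULL, ...) {
  stopifnot(inherits(tree, "model_tree"))
  for (lab in c(pre, post))
    if (!lab %in% names(tree$compartments))
      stop("unknown compartment: ", lab)
  if (identical(pre, post)) stop("self-synapses are not allowed")
  spec <- synapse_info(type)
  gbar <- if (is.null(gbar)) spec$default_gbar else gbar
  if (gbar < 0) stop("gbar must be >= 0")
  over <- list(...)
  if (spec$electrical) {
    if (length(over)) stop("electrical synapses take only gbar")
    syn <- list(type = type, pre = pre, post = post, electrical = TRUE,
                params = list(gbar = gbar), state = list())
  } else {
    allowed <- c("E_syn", "V_half", "Delta", "k_minus")
    bad <- setdiff(names(over), allowed)
    if (length(bad)) stop("unknown synapse parameter(s): ",
                          paste(bad, collapse = ", "))
    params <- utils::modifyList(
      list(gbar = gbar, E_syn = spec$E_syn, V_half = spec$V_half,
           Delta = spec$Delta, k_minus = spec$k_minus),
      over)
    params <- params[c("gbar", "E_syn", "V_half", "Delta", "k_minus")]
    syn <- list(type = type, pre = pre, post = post, electrical = FALSE,
                params = params, state = list(s = 0))
  }
  tree$synapses[[length(tree$synapses) + 1L]] <- syn
  tree
}

#' Replicate a compartment
#'
#' Appends \code{n_copies - 1} deep copies of a compartment, labelled
#' \code{<label>_2 ... <label>_n}. Copies are uncoupled: no synapses are
#' added.
#'
#' @param tree A model tree.
#' @param label Compartment to copy.
#' @param n_copies Total number of copies including the original
#'   (\code{>= 1}).
#' @return The updated tree.
#' @export
replicate_compartment <- function(tree, label, n_copies) {
  stopifnot(inherits(tree, "model_tree"))
  src <- tree$compartments[[label]]
  if (is.null(src)) stop("unknown compartment: ", label)
  if (n_copies < 1) stop("n_copies must be >= 1")
  if (n_copies == 1) return(tree)
  for (k in 2:n_copies) {
    new_lab <- paste0(label, "_", k)
    if (new_lab %in% names(tree$compartments))
      stop("replicate label collision: ", new_lab)
    cpy <- src
    cpy$label <- new_lab
    tree$compartments[[new_lab]] <- cpy
  }
  tree
}

# ---- path enumeration ------------------------------------------------------

# Canonical synapse id: synapses/<pre>-><post>/<type>/<k>, k 1-based among
# synapses sharing the (pre, post, type) triple, in insertion order.
.synapse_ids <- function(tree) {
  if (!length(tree$synapses)) return(character(0))
  key <- vapply(tree$synapses, function(s)
    paste0("synapses/", s$pre, "->", s$post, "/", s$type), character(1))
  idx <- stats::ave(seq_along(key), key, FUN = seq_along)
  paste0(key, "/", idx)
}

# Flat table of every parameter and dynamic variable: path, kind, locator.
.layout_table <- function(tree) {
  rows <- list()
  push <- function(path, kind, comp = NA, sub = NA, field, syn = NA)
    rows[[length(rows) + 1L]] <<- list(path = path, kind = kind, comp = comp,
                                       sub = sub, field = field, syn = syn)
  for (lab in names(tree$compartments)) {
    cmp <- tree$compartments[[lab]]
    for (f in .sorted_names(cmp$params))
      push(paste(lab, f, sep = "/"), "comp_param", lab, field = f)
    for (f in .sorted_names(cmp$state))
      push(paste(lab, f, sep = "/"), "comp_state", lab, field = f)
    for (nm in names(cmp$conductances)) {
      cd <- cmp$conductances[[nm]]
      for (f in .sorted_names(cd$params))
        push(paste(lab, nm, f, sep = "/"), "cond_param", lab, nm, f)
      for (f in .sorted_names(cd$state))
        push(paste(lab, nm, f, sep = "/"), "cond_state", lab, nm, f)
    }
    for (nm in names(cmp$mechanisms)) {
      mc <- cmp$mechanisms[[nm]]
      for (f in .sorted_names(mc$params))
        push(paste(lab, nm, f, sep = "/"), "mech_param", lab, nm, f)
      for (f in .sorted_names(mc$state))
        push(paste(lab, nm, f, sep = "/"), "mech_state", lab, nm, f)
    }
  }
  ids <- .synapse_ids(tree)
  for (i in seq_along(ids)) {
    syn <- tree$synapses[[i]]
    for (f in .sorted_names(syn$params))
      push(paste(ids[i], f, sep = "/"), "syn_param", field = f, syn = i)
    for (f in .sorted_names(syn$state))
      push(paste(ids[i], f, sep = "/"), "syn_state", field = f, syn = i)
  }
  if (!length(rows))
    return(data.frame(path = character(0), kind = character(0),
                      comp = character(0), sub = character(0),
                      field = character(0), syn = integer(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(path = r$path, kind = r$kind, comp = r$comp, sub = r$sub,
               field = r$field, syn = r$syn, stringsAsFactors = FALSE)))
  df[order(df$path, method = "radix"), , drop = FALSE]
}

.layout_get <- function(tree, row) {
  switch(row$kind,
    comp_param = tree$compartments[[row$comp]]$params[[row$field]],
    comp_state = tree$compartments[[row$comp]]$state[[row$field]],
    cond_param = tree$compartments[[row$comp]]$conductances[[row$sub]]$params[[row$field]],
    cond_state = tree$compartments[[row$comp]]$conductances[[row$sub]]$state[[row$field]],
    mech_param = tree$compartments[[row$comp]]$mechanisms[[row$sub]]$params[[row$field]],
    mech_state = tree$compartments[[row$comp]]$mechanisms[[row$sub]]$state[[row$field]],
    syn_param = tree$synapses[[row$syn]]$params[[row$field]],
    syn_state = tree$synapses[[row$syn]]$state[[row$field]])
}

.layout_set <- function(tree, row, value) {
  switch(row$kind,
    comp_param = tree$compartments[[row$comp]]$params[[row$field]] <- value,
    comp_state = tree$compartments[[row$comp]]$state[[row$field]] <- value,
    cond_param = tree$compartments[[row$comp]]$conductances[[row$sub]]$params[[row$field]] <- value,
    cond_state = tree$compartments[[row$comp]]$conductances[[row$sub]]$state[[row$field]] <- value,
    mech_param = tree$compartments[[row$comp]]$mechanisms[[row$sub]]$params[[row$field]] <- value,
    mech_state = tree$compartments[[row$comp]]$mechanisms[[row$sub]]$state[[row$field]] <- value,
    syn_param = tree$synapses[[row$syn]]$params[[row$field]] <- value,
    syn_state = tree$synapses[[row$syn]]$state[[row$field]] <- value)
  tree
}

#' Serialize a model to a flat vector
#'
#' Gathers every parameter and dynamic variable into one numeric vector in
#' canonical order (lexicographic by full path), so two trees with
#' identical content serialize identically regardless of how they were
#' built.
#'
#' @param tree A model tree.
#' @return A list with \code{vector} (numeric) and \code{layout}
#'   (character paths, same length).
#' @export
serialize_model <- function(tree) {
  stopifnot(inherits(tree, "model_tree"))
  tab <- .layout_table(tree)
  vec <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) vec[i] <- .layout_get(tree, tab[i, ])
  list(vector = vec, layout = tab$path)
}

#' Write a serialized vector back into a model
#'
#' Inverse of [serialize_model()]: values are written back in layout
#' order. \code{deserialize_model(tree, serialize_model(tree)$vector)} is
#' the identity.
#'
#' @param tree A model tree.
#' @param vector Numeric vector of length equal to the tree's layout.
#' @return The updated tree.
#' @export
deserialize_model <- function(tree, vector) {
  stopifnot(inherits(tree, "model_tree"))
  tab <- .layout_table(tree)
  if (length(vector) != nrow(tab))
    stop("vector length ", length(vector),
         " does not match layout length ", nrow(tab))
  for (i in seq_len(nrow(tab))) tree <- .layout_set(tree, tab[i, ], vector[i])
  tree
}

# ---- path resolution -------------------------------------------------------

.all_paths <- function(tree) {
  comp_paths <- character(0)
  for (lab in names(tree$compartments)) {
    cmp <- tree$compartments[[lab]]
    comp_paths <- c(comp_paths, lab,
                    if (length(cmp$conductances))
                      paste(lab, names(cmp$conductances), sep = "/"),
                    if (length(cmp$mechanisms))
                      paste(lab, names(cmp$mechanisms), sep = "/"))
  }
  c(comp_paths, .synapse_ids(tree), .layout_table(tree)$path)
}

.path_regex <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("malformed path: must be a non-empty string")
  if (grepl("^/|/$|//", pattern))
    stop("malformed path: empty path component in '", pattern, "'")
  esc <- gsub("([.\\\\+?^$()|{}\\[\\]])", "\\\\\\1", pattern, perl = TRUE)
  paste0("^", gsub("\\*", ".*", esc), "$")
}

#' Resolve a path pattern against a model
#'
#' Paths are slash-separated label sequences down to components or
#' parameters ("AB/NaV/gbar"). \code{*} is a wildcard matching any
#' character run, including separators, so \code{"*\/gbar"} matches every
#' maximal conductance in the tree.
#'
#' @param tree A model tree.
#' @param pattern Path or wildcard pattern.
#' @return Sorted character vector of matching paths (may be empty).
#' @export
resolve_path <- function(tree, pattern) {
  stopifnot(inherits(tree, "model_tree"))
  rx <- .path_regex(pattern)
  paths <- .all_paths(tree)
  sort(unique(paths[grepl(rx, paths)]), method = "radix")
}

#' Read or set one parameter or state by path
#'
#' The path must resolve to exactly one numeric parameter or dynamic
#' variable.
#'
#' @param tree A model tree.
#' @param path Non-wildcard (or uniquely matching) path.
#' @param value Replacement value for \code{set_param}.
#' @return \code{get_param}: the value. \code{set_param}: the updated tree.
#' @export
get_param <- function(tree, path) {
  tab <- .layout_table(tree)
  hit <- grepl(.path_regex(path), tab$path)
  if (sum(hit) == 0L) stop("path does not resolve: ", path)
  if (sum(hit) > 1L) stop("ambiguous path (", sum(hit), " matches): ", path)
  .layout_get(tree, tab[hit, ])
}

#' @rdname get_param
#' @export
set_param <- function(tree, path, value) {
  tab <- .layout_table(tree)
  hit <- grepl(.path_regex(path), tab$path)
  if (sum(hit) == 0L) stop("path does not resolve: ", path)
  if (sum(hit) > 1L) stop("ambiguous path (", sum(hit), " matches): ", path)
  .layout_set(tree, tab[hit, ], value)
}

# ---- snapshots -------------------------------------------------------------

#' Snapshot and restore the full model state
#'
#' \code{snapshot} stores the complete serialized vector (all parameters
#' and dynamic variables) under a case-sensitive name inside the tree;
#' \code{restore_snapshot} writes it back. Because integration is
#' deterministic, re-integrating after a restore reproduces the original
#' continuation bit-exactly.
#'
#' @param tree A model tree.
#' @param name Snapshot name.
#' @return The updated tree.
#' @export
snapshot <- function(tree, name) {
  stopifnot(inherits(tree, "model_tree"), is.character(name), nzchar(name))
  ser <- serialize_model(tree)
  tree$snapshots[[name]] <- ser
  tree
}

#' @rdname snapshot
#' @export
restore_snapshot <- function(tree, name) {
  stopifnot(inherits(tree, "model_tree"))
  snap <- tree$snapshots[[name]]
  if (is.null(snap)) stop("unknown snapshot: ", name)
  cur <- .layout_table(tree)
  if (!identical(cur$path, snap$layout))
    stop("model structure changed since snapshot '", name, "'")
  deserialize_model(tree, snap$vector)
}

# ---- hashing ---------------------------------------------------------------

.structural_string <- function(tree) {
  out <- character(0)
  for (lab in .sorted_names(tree$compartments)) {
    cmp <- tree$compartments[[lab]]
    out <- c(out, paste0("compartment ", lab))
    for (nm in .sorted_names(cmp$conductances)) {
      cd <- cmp$conductances[[nm]]
      out <- c(out, paste0("conductance ", lab, "/", nm, " type=", cd$type),
               channel_info(cd$type)$source)
    }
    for (nm in .sorted_names(cmp$mechanisms)) {
      mc <- cmp$mechanisms[[nm]]
      out <- c(out, paste0("mechanism ", lab, "/", nm, " type=", mc$type,
                           if (!is.null(mc$target))
                             paste0(" target=", mc$target) else ""),
               mechanism_info(mc$type)$source)
    }
  }
  ids <- .synapse_ids(tree)
  for (i in order(ids, method = "radix")) {
    syn <- tree$synapses[[i]]
    out <- c(out, paste0("synapse ", ids[i]), synapse_info(syn$type)$source)
  }
  paste(out, collapse = "\n")
}

#' Model hashes
#'
#' \code{structural_hash} is the MD5 digest of the canonically ordered
#' component types and their registered equation-source text; it is
#' invariant under construction order and parameter values.
#' \code{full_hash} additionally digests the serialized parameter/state
#' vector, so it changes whenever any value changes.
#'
#' @param tree A model tree.
#' @return 32-character lowercase hex string.
#' @export
structural_hash <- function(tree) {
  stopifnot(inherits(tree, "model_tree"))
  digest::digest(.structural_string(tree), algo = "md5", serialize = FALSE)
}

#' @rdname structural_hash
#' @export
full_hash <- function(tree) {
  ser <- serialize_model(tree)
  digest::digest(
    paste(structural_hash(tree),
          paste(sprintf("%.17g", ser$vector), collapse = " ")),
    algo = "md5", serialize = FALSE)
}

#' Number of dynamic state variables
#'
#' Counts every integrated variable: V and Ca per compartment, allocated
#' gating states, graded-synapse activations, and controller mRNA levels.
#'
#' @param tree A model tree.
#' @return Integer count.
#' @export
state_count <- function(tree) {
  stopifnot(inherits(tree, "model_tree"))
  n <- 0L
  for (cmp in tree$compartments) {
    n <- n + 2L  # V, Ca
    for (cd in cmp$conductances) n <- n + length(cd$state)
    for (mc in cmp$mechanisms) n <- n + length(mc$state)
  }
  for (syn in tree$synapses) n <- n + length(syn$state)
  n
}
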