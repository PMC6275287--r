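# Model config (YAML) and trace (CSV) persistence.
#
# The YAML schema is strict: unknown keys are rejected with the path to
# the offending key. save_model() emits a canonical document (sorted
# labels and component names), so save(load(f)) is byte-identical for
# canonical files.

.check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown key(s) at ", where, ": ", paste(bad, collapse = ", "))
}

#' Read a model from a YAML config
#'
#' Top-level keys: \code{compartments}, \code{synapses},
#' \code{simulation}. Every component entry is
#' \code{\{type: <registered name>, params: \{...\}\}}; conductances and
#' compartments may also carry a \code{state} block. Integral controllers
#' can be written either in a compartment's \code{mechanisms} block (with
#' a \code{target}) or nested under their conductance as
#' \code{controller:}; both load to the same model.
#'
#' @param path YAML file path.
#' @return A model tree.
#' @export
load_model <- function(path) {
  doc <- yaml::read_yaml(path)
  .check_keys(doc, c("compartments", "synapses", "simulation"), "top level")
  sim <- doc$simulation
  tree <- model_tree()
  if (!is.null(sim)) {
    .check_keys(sim, c("dt", "t_end", "solver"), "simulation")
    tree$sim <- utils::modifyList(tree$sim, sim)
  }
  for (lab in names(doc$compartments)) {
    cc <- doc$compartments[[lab]]
    .check_keys(cc, c("params", "state", "conductances", "mechanisms"),
                paste0("compartments/", lab))
    args <- c(list(tree, lab), cc$params, cc$state)
    tree <- do.call(add_compartment, args)
    ctrl_queue <- list()
    for (nm in names(cc$conductances)) {
      cd <- cc$conductances[[nm]]
      .check_keys(cd, c("type", "params", "state", "controller"),
                  paste0(lab, "/", nm))
      type <- if (is.null(cd$type)) nm else cd$type
      if (!type %in% names(.nd_registry$channels))
        stop("unknown channel type '", type, "' at ", lab, "/", nm)
      tree <- do.call(add_conductance,
                      c(list(tree, lab, type, nm), cd$params))
      for (f in names(cd$state))
        tree$compartments[[lab]]$conductances[[nm]]$state[[f]] <-
          cd$state[[f]]
      if (!is.null(cd$controller)) {
        ct <- cd$controller
        ct$target <- nm
        ctrl_queue[[length(ctrl_queue) + 1L]] <- ct
      }
    }
    mechs <- cc$mechanisms
    for (ct in ctrl_queue) {
      nm2 <- if (is.null(ct$name)) paste0(ct$target, "_ctrl") else ct$name
      ct$name <- NULL
      mechs[[nm2]] <- ct
    }
    for (nm in names(mechs)) {
      mc <- mechs[[nm]]
      .check_keys(mc, c("type", "target", "params", "state"),
                  paste0(lab, "/", nm))
      type <- if (is.null(mc$type)) nm else mc$type
      if (!type %in% names(.nd_registry$mechanisms))
        stop("unknown mechanism type '", type, "' at ", lab, "/", nm)
      tree <- do.call(add_mechanism,
                      c(list(tree, lab, type, nm, mc$target), mc$params))
      for (f in names(mc$state))
        tree$compartments[[lab]]$mechanisms[[nm]]$state[[f]] <- mc$state[[f]]
    }
  }
  for (i in seq_along(doc$synapses)) {
    sy <- doc$synapses[[i]]
    .check_keys(sy, c("type", "pre", "post", "params", "state"),
                paste0("synapses[", i, "]"))
    if (!sy$type %in% names(.nd_registry$synapses))
      stop("unknown synapse type '", sy$type, "' at synapses[", i, "]")
    tree <- do.call(connect, c(list(tree, sy$pre, sy$post, sy$type),
                               sy$params))
    for (f in names(sy$state))
      tree$synapses[[length(tree$synapses)]]$state[[f]] <- sy$state[[f]]
  }
  tree
}

#' Write a model to a canonical YAML config
#'
#' @param tree A model tree.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(tree, path) {
  stopifnot(inherits(tree, "model_tree"))
  comps <- list()
  for (lab in .sorted_names(tree$compartments)) {
    cmp <- tree$compartments[[lab]]
    entry <- list(params = cmp$params[.sorted_names(cmp$params)],
                  state = cmp$state[.sorted_names(cmp$state)])
    if (length(cmp$conductances)) {
      cds <- list()
      for (nm in .sorted_names(cmp$conductances)) {
        cd <- cmp$conductances[[nm]]
        cds[[nm]] <- list(type = cd$type,
                          params = cd$params[.sorted_names(cd$params)],
                          state = cd$state[.sorted_names(cd$state)])
        if (!length(cd$state)) cds[[nm]]$state <- NULL
      }
      entry$conductances <- cds
    }
    if (length(cmp$mechanisms)) {
      mcs <- list()
      for (nm in .sorted_names(cmp$mechanisms)) {
        mc <- cmp$mechanisms[[nm]]
        e <- list(type = mc$type)
        if (!is.null(mc$target)) e$target <- mc$target
        e$params <- mc$params[.sorted_names(mc$params)]
        if (length(mc$state))
          e$state <- mc$state[.sorted_names(mc$state)]
        mcs[[nm]] <- e
      }
      entry$mechanisms <- mcs
    }
    comps[[lab]] <- entry
  }
  ids <- .synapse_ids(tree)
  syns <- lapply(order(ids, method = "radix"), function(i) {
    sy <- tree$synapses[[i]]
    e <- list(type = sy$type, pre = sy$pre, post = sy$post,
              params = sy$params[.sorted_names(sy$params)])
    if (length(sy$state))
      e$state <- sy$state[.sorted_names(sy$state)]
    e
  })
  doc <- list(compartments = comps)
  if (length(syns)) doc$synapses <- syns
  doc$simulation <- tree$sim[c("dt", "t_end", "solver")]
  # 17 significant digits so every double survives the text round trip
  num_handler <- function(x) {
    if (length(x) == 1L)
      structure(sprintf("%.17g", x), class = "verbatim")
    else x
  }
  writeLines(yaml::as.yaml(doc, handlers = list(numeric = num_handler)),
             path)
  invisible(path)
}

# ---- trace persistence -----------------------------------------------------

.trace_long <- function(trace) {
  rows <- list()
  add <- function(comp, var, val)
    rows[[length(rows) + 1L]] <<-
      data.frame(t = trace$t, compartment = comp, variable = var,
                 value = val, stringsAsFactors = FALSE)
  for (cc in colnames(trace$V)) add(cc, "V", trace$V[, cc])
  for (cc in colnames(trace$Ca)) add(cc, "Ca", trace$Ca[, cc])
  if (!is.null(trace$I_clamp))
    for (cc in colnames(trace$I_clamp)) add(cc, "I_clamp",
                                            trace$I_clamp[, cc])
  if (!is.null(trace$currents))
    for (cc in colnames(trace$currents))
      add(sub("/.*", "", cc), paste0("I:", sub("^[^/]*/", "", cc)),
          trace$currents[, cc])
  if (!is.null(trace$synapse_s))
    for (cc in colnames(trace$synapse_s)) add("synapses", paste0("s:", cc),
                                              trace$synapse_s[, cc])
  if (!is.null(trace$controllers)) {
    for (cc in colnames(trace$controllers$mRNA))
      add(sub("/.*", "", cc), paste0("mRNA:", sub("^[^/]*/", "", cc)),
          trace$controllers$mRNA[, cc])
    for (cc in colnames(trace$controllers$gbar))
      add(sub("/.*", "", cc), paste0("gbar:", sub("^[^/]*/", "", cc)),
          trace$controllers$gbar[, cc])
  }
  do.call(rbind, rows)
}

#' Write / read a trace as tidy CSV
#'
#' Long format (\code{t, compartment, variable, value}) preceded by
#' \code{#}-prefixed header lines carrying the generating model's full
#' hash and the integration settings. Values round-trip losslessly
#' (17 significant digits).
#'
#' @param trace A \code{neuro_trace}.
#' @param path Output / input file path.
#' @return \code{write_trace}: \code{path}, invisibly. \code{read_trace}:
#'   a \code{neuro_trace} (without the model element).
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "neuro_trace"))
  hdr <- c("# neurodyn trace v1",
           paste0("# full_hash: ", trace$hash),
           paste0("# dt: ", sprintf("%.17g", trace$dt)),
           paste0("# out_dt: ", sprintf("%.17g", trace$out_dt)),
           paste0("# t_end: ", sprintf("%.17g", trace$t_end)),
           paste0("# solver: ", trace$solver))
  df <- .trace_long(trace)
  body <- sprintf("%.17g,%s,%s,%.17g",
                  df$t, df$compartment, df$variable, df$value)
  writeLines(c(hdr, "t,compartment,variable,value", body), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# neurodyn trace"))
    stop("not a trace file: ", path)
  hdr <- lines[startsWith(lines, "# ")]
  get_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(ln)) stop("corrupt trace file: missing header ", key)
    sub(paste0("^# ", key, ": *"), "", ln[1])
  }
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]),
                        stringsAsFactors = FALSE)
  if (!identical(names(df), c("t", "compartment", "variable", "value")) ||
      !nrow(df))
    stop("corrupt trace file: ", path)
  tvals <- sort(unique(df$t))
  pick <- function(sub_df) {
    keys <- unique(sub_df$key)
    if (!length(keys)) return(NULL)
    m <- sapply(keys, function(k) sub_df$value[sub_df$key == k])
    m <- matrix(m, ncol = length(keys), dimnames = list(NULL, keys))
    m
  }
  df$key <- df$compartment
  V <- pick(df[df$variable == "V", ])
  Ca <- pick(df[df$variable == "Ca", ])
  tr <- list(t = tvals, V = V, Ca = Ca,
             dt = as.numeric(get_hdr("dt")),
             out_dt = as.numeric(get_hdr("out_dt")),
             t_end = as.numeric(get_hdr("t_end")),
             solver = get_hdr("solver"),
             hash = get_hdr("full_hash"))
  ic <- df[df$variable == "I_clamp", ]
  if (nrow(ic)) tr$I_clamp <- pick(ic)
  cur <- df[startsWith(df$variable, "I:"), ]
  if (nrow(cur)) {
    cur$key <- paste0(cur$compartment, "/", sub("^I:", "", cur$variable))
    tr$currents <- pick(cur)
  }
  ss <- df[startsWith(df$variable, "s:"), ]
  if (nrow(ss)) {
    ss$key <- sub("^s:", "", ss$variable)
    tr$synapse_s <- pick(ss)
  }
  mr <- df[startsWith(df$variable, "mRNA:"), ]
  if (nrow(mr)) {
    mr$key <- paste0(mr$compartment, "/", sub("^mRNA:", "", mr$variable))
    gb <- df[startsWith(df$variable, "gbar:"), ]
    gb$key <- paste0(gb$compartment, "/", sub("^gbar:", "", gb$variable))
    tr$controllers <- list(mRNA = pick(mr), gbar = pick(gb))
  }
  class(tr) <- "neuro_trace"
  tr
}

#' Check a trace against a model
#'
#' Compares the full hash embedded in a trace with the hash of a model,
#' flagging traces generated by a different model or parameterization.
#'
#' @param trace A \code{neuro_trace} (typically from [read_trace()]).
#' @param tree The model to validate against.
#' @return TRUE if the hashes match, FALSE (with a warning) otherwise.
#' @export
validate_trace <- function(trace, tree) {
  ok <- identical(trace$hash, full_hash(tree))
  if (!ok) warning("trace hash ", trace$hash,
                   " does not match model hash ", full_hash(tree))
  ok
}
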