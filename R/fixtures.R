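# Built-in fixture models: deterministic, self-contained reference models
# used throughout the examples and tests.
#
# Conductance densities follow the stomatogastric literature the channel
# kinetics come from, converted to uS/mm^2 (1 mS/cm^2 = 10 uS/mm^2); the
# single-compartment area 0.0628 mm^2 and Cm = 10 nF/mm^2 give the usual
# 0.628 nF cell.

.burster_gbars <- c(NaV = 1000, CaT = 25, CaS = 60, ACurrent = 500,
                    KCa = 50, Kd = 1000, HCurrent = 0.1, Leak = 0.099)

.add_channel_set <- function(tree, lab, gbars, E_leak = -50) {
  for (nm in names(gbars)) {
    tree <- add_conductance(tree, lab, nm, gbar = gbars[[nm]],
                            E = if (nm == "Leak") E_leak else NULL)
  }
  tree
}

#' Build a named fixture model
#'
#' Available fixtures:
#' \describe{
#'   \item{hh_neuron}{Single compartment "HH" with NaV, Kd, Leak —
#'     quiescent at rest, tonically spiking at 0.2 nA.}
#'   \item{bursting_neuron}{Single compartment "AB" with the 8-channel
#'     stomatogastric set plus a calcium mechanism; bursts periodically.
#'     \code{with_calcium_mech = FALSE} removes the mechanism (calcium
#'     then stays constant and the cell spikes tonically).}
#'   \item{homeostatic_neuron}{The 8-channel cell started at small
#'     conductance densities, with an integral controller on every channel
#'     except Leak driving calcium toward \code{Ca_target}.}
#'   \item{pyloric_network}{Three-cell pyloric circuit (AB, LP, PY) with
#'     seven graded synapses of two types; produces the triphasic rhythm.}
#'   \item{passive_cable}{Unbranched chain of leak-only compartments with
#'     cylinder geometry for the Crank-Nicolson solver.}
#' }
#'
#' @param name Fixture name.
#' @param with_calcium_mech (bursting_neuron) include the calcium
#'   mechanism.
#' @param Ca_target (homeostatic_neuron) controller target (uM).
#' @param gbar_init (homeostatic_neuron) initial conductance density
#'   (uS/mm^2) for every controlled channel.
#' @param n_comp (passive_cable) number of compartments.
#' @return A model tree.
#' @export
make_fixture <- function(name = c("hh_neuron", "bursting_neuron",
                                  "homeostatic_neuron", "pyloric_network",
                                  "passive_cable"),
                         with_calcium_mech = TRUE, Ca_target = 65,
                         gbar_init = 10, n_comp = 50) {
  name <- match.arg(name)
  switch(name,
    hh_neuron = {
      tree <- model_tree()
      tree <- add_compartment(tree, "HH", A = 0.01, Cm = 10, V = -60)
      tree <- add_conductance(tree, "HH", "NaV", gbar = 1000, E = 50)
      tree <- add_conductance(tree, "HH", "Kd", gbar = 300, E = -80)
      tree <- add_conductance(tree, "HH", "Leak", gbar = 1, E = -50)
      tree
    },
    bursting_neuron = {
      tree <- model_tree()
      tree <- add_compartment(tree, "AB", A = 0.0628, Cm = 10, V = -60)
      tree <- .add_channel_set(tree, "AB", .burster_gbars)
      if (with_calcium_mech)
        tree <- add_mechanism(tree, "AB", "CalciumMech")
      tree
    },
    homeostatic_neuron = {
      targets <- .burster_gbars[names(.burster_gbars) != "Leak"]
      tree <- model_tree()
      tree <- add_compartment(tree, "AB", A = 0.0628, Cm = 10, V = -60)
      gb <- .burster_gbars
      gb[names(targets)] <- gbar_init
      tree <- .add_channel_set(tree, "AB", gb)
      tree <- add_mechanism(tree, "AB", "CalciumMech")
      # controller mRNA timescales inversely proportional to the intended
      # density ratios: steady-state gbar_i is then proportional to
      # 1/tau_m_i (classic integral-control regulation scheme)
      for (nm in names(targets))
        tree <- add_mechanism(tree, "AB", "IntegralController",
                              target = nm,
                              tau_m = 2e6 / targets[[nm]], tau_g = 5000,
                              Ca_target = Ca_target, mRNA = gbar_init)
      tree
    },
    pyloric_network = {
      gb <- list(
        AB = c(NaV = 1000, CaT = 25, CaS = 60, ACurrent = 500, KCa = 50,
               Kd = 1000, HCurrent = 0.1, Leak = 0),
        LP = c(NaV = 1000, CaS = 40, ACurrent = 200, KCa = 0, Kd = 250,
               HCurrent = 0.5, Leak = 0.3),
        PY = c(NaV = 1000, CaT = 25, CaS = 20, ACurrent = 500, KCa = 0,
               Kd = 1250, HCurrent = 0.5, Leak = 0.1))
      tree <- model_tree()
      for (lab in names(gb)) {
        tree <- add_compartment(tree, lab, A = 0.0628, Cm = 10, V = -60)
        tree <- .add_channel_set(tree, lab, gb[[lab]])
        tree <- add_mechanism(tree, lab, "CalciumMech")
      }
      tree <- connect(tree, "AB", "LP", "Glutamatergic", gbar = 30)
      tree <- connect(tree, "AB", "LP", "Cholinergic", gbar = 30)
      tree <- connect(tree, "AB", "PY", "Glutamatergic", gbar = 10)
      tree <- connect(tree, "AB", "PY", "Cholinergic", gbar = 3)
      tree <- connect(tree, "LP", "AB", "Glutamatergic", gbar = 30)
      tree <- connect(tree, "LP", "PY", "Glutamatergic", gbar = 1)
      tree <- connect(tree, "PY", "LP", "Glutamatergic", gbar = 30)
      tree
    },
    passive_cable = {
      tree <- model_tree()
      for (i in seq_len(n_comp)) {
        lab <- sprintf("cable_%02d", i)
        tree <- add_compartment(tree, lab, A = 2 * pi * 0.01 * 0.1,
                                Cm = 10, V = -50,
                                radius = 0.01, len = 0.1, Ra = 100)
        tree <- add_conductance(tree, lab, "Leak", gbar = 1, E = -50)
      }
      tree
    })
}
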