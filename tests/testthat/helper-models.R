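# Small builders shared across tests.

leak_model <- function(gbar = 1, E = -50, A = 0.01, Cm = 10, V = -60) {
  tree <- model_tree()
  tree <- add_compartment(tree, "c", A = A, Cm = Cm, V = V)
  add_conductance(tree, "c", "Leak", gbar = gbar, E = E)
}

hh_model <- function() make_fixture("hh_neuron")

with_channel <- function(name, ..., code) {
  register_channel(name, ...)
  on.exit(neurodyn:::.unregister_channel(name), add = TRUE)
  force(code)
}
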