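test_that("components are added hierarchically with validation", {
  tree <- add_component(model_tree(), NULL, "compartment", "HH",
                        list(A = 0.01, Cm = 10))
  tree <- add_component(tree, "HH", "conductance", "NaV",
                        list(gbar = 1000, E = 50))
  tree <- add_component(tree, "HH", "conductance", "Kd", list(gbar = 300))
  tree <- add_component(tree, "HH", "conductance", "Leak", list(gbar = 1))
  expect_length(tree$compartments, 1)
  expect_length(tree$compartments$HH$conductances, 3)

  expect_error(add_component(tree, "nope", "conductance", "Kd"),
               "unknown parent")
  expect_error(add_component(tree, "HH", "conductance", "Kd"),
               "duplicate")
  expect_error(add_component(tree, "HH", "conductance", "Kx",
                             list(type = "NotAChannel")),
               "unknown channel type")
  expect_error(add_component(tree, "HH", "conductance", "K2",
                             list(type = "Kd", foo = 1)),
               "unknown conductance parameter")
  expect_error(add_compartment(tree, "HH"), "duplicate compartment")
  expect_error(add_compartment(tree, ""), "non-empty")
})

test_that("path resolution supports exact paths and wildcards", {
  hh <- hh_model()
  expect_identical(resolve_path(hh, "HH/NaV/gbar"), "HH/NaV/gbar")
  expect_length(resolve_path(hh, "*/gbar"), 3)
  expect_length(resolve_path(model_tree(), "AB/*"), 0)
  expect_error(resolve_path(hh, ""), "malformed")
  expect_error(resolve_path(hh, "HH//gbar"), "malformed")
  expect_equal(get_param(hh, "HH/Kd/gbar"), 300)
  expect_error(get_param(hh, "*/gbar"), "ambiguous")
  hh2 <- set_param(hh, "HH/Kd/gbar", 123)
  expect_equal(get_param(hh2, "HH/Kd/gbar"), 123)
  expect_equal(get_param(hh, "HH/Kd/gbar"), 300)  # baseline untouched
})

test_that("connect builds directed synapses with validation", {
  tree <- model_tree()
  tree <- add_compartment(tree, "LP", A = 0.0628)
  tree <- add_compartment(tree, "PY", A = 0.0628)
  tree <- connect(tree, "LP", "PY", "Glutamatergic", gbar = 30)
  expect_length(tree$synapses, 1)
  expect_equal(tree$synapses[[1]]$params$gbar, 30)
  expect_equal(tree$synapses[[1]]$params$E_syn, -70)

  expect_error(connect(tree, "LP", "LP", "Glutamatergic", 5),
               "self-synapses")
  expect_error(connect(tree, "LP", "XX", "Glutamatergic", 5),
               "unknown compartment")
  expect_error(connect(tree, "LP", "PY", "NotASynapse", 5),
               "unknown synapse type")
  # parallel synapses between the same pair are allowed
  tree <- connect(tree, "LP", "PY", "Glutamatergic", gbar = 10)
  expect_length(tree$synapses, 2)
})

test_that("replicate appends uncoupled suffixed deep copies", {
  hh <- hh_model()
  expect_identical(replicate_compartment(hh, "HH", 1), hh)
  hh10 <- replicate_compartment(hh, "HH", 10)
  expect_length(hh10$compartments, 10)
  expect_true("HH_10" %in% names(hh10$compartments))
  expect_length(hh10$synapses, 0)
  # V, Ca, NaV m+h, Kd m = 5 states per copy
  expect_equal(state_count(hh10), 50)
  expect_error(replicate_compartment(hh, "nope", 2), "unknown compartment")
  expect_error(replicate_compartment(hh, "HH", 0), "n_copies")
})

test_that("serialization is canonical and round-trips bit-exactly", {
  hh <- hh_model()
  ser <- serialize_model(hh)
  # enumerate expected slots: compartment A,Cm,V,Ca; NaV gbar,E,m,h;
  # Kd gbar,E,m; Leak gbar,E
  expect_length(ser$vector, 4 + 4 + 3 + 2)
  expect_identical(ser$layout, sort(ser$layout, method = "radix"))

  expect_identical(serialize_model(deserialize_model(hh, ser$vector))$vector,
                   ser$vector)

  # different insertion order, identical content
  tree2 <- model_tree()
  tree2 <- add_compartment(tree2, "HH", A = 0.01, Cm = 10, V = -60)
  tree2 <- add_conductance(tree2, "HH", "Leak", gbar = 1, E = -50)
  tree2 <- add_conductance(tree2, "HH", "Kd", gbar = 300, E = -80)
  tree2 <- add_conductance(tree2, "HH", "NaV", gbar = 1000, E = 50)
  expect_identical(serialize_model(tree2)$vector, ser$vector)

  # one entry changed -> exactly one slot differs
  v <- ser$vector
  v[3] <- v[3] + 1
  changed <- serialize_model(deserialize_model(hh, v))$vector != ser$vector
  expect_equal(sum(changed), 1)

  expect_error(deserialize_model(hh, v[-1]), "length")
})

test_that("snapshots restore the exact model state", {
  hh <- snapshot(hh_model(), "initial")
  pert <- set_param(hh, "HH/Kd/gbar", 50)
  back <- restore_snapshot(pert, "initial")
  expect_identical(serialize_model(back)$vector, serialize_model(hh)$vector)

  # no-op snapshot/restore
  expect_identical(
    serialize_model(restore_snapshot(snapshot(hh, "x"), "x"))$vector,
    serialize_model(hh)$vector)
  expect_error(restore_snapshot(hh, "nope"), "unknown snapshot")
})

test_that("re-integration after a snapshot reset is bit-reproducible", {
  hh <- hh_model()
  tr1 <- integrate_model(hh, t_end = 200, dt = 0.05, I_ext = c(HH = 0.2))
  m <- snapshot(tr1$model, "A")
  cont1 <- integrate_model(m, t_end = 200, dt = 0.05, I_ext = c(HH = 0.2))
  m2 <- restore_snapshot(cont1$model, "A")
  cont2 <- integrate_model(m2, t_end = 200, dt = 0.05, I_ext = c(HH = 0.2))
  expect_identical(cont2$V, cont1$V)
  expect_identical(cont2$Ca, cont1$Ca)
})

test_that("hashes separate structure from parameter values", {
  hh <- hh_model()
  tree2 <- model_tree()
  tree2 <- add_compartment(tree2, "HH", A = 0.01, Cm = 10, V = -60)
  tree2 <- add_conductance(tree2, "HH", "Leak", gbar = 1, E = -50)
  tree2 <- add_conductance(tree2, "HH", "Kd", gbar = 300, E = -80)
  tree2 <- add_conductance(tree2, "HH", "NaV", gbar = 1000, E = 50)
  expect_identical(structural_hash(hh), structural_hash(tree2))
  expect_identical(full_hash(hh), full_hash(tree2))
  expect_match(full_hash(hh), "^[0-9a-f]{32}$")

  pert <- set_param(hh, "HH/Kd/gbar", 299)
  expect_identical(structural_hash(pert), structural_hash(hh))
  expect_false(identical(full_hash(pert), full_hash(hh)))

  # changing a channel's equation source changes the structural hash
  with_channel("Kd2", p = 4, q = 0,
               m_inf = function(V) 1 / (1 + exp(-(V + 15) / 11.8)),
               tau_m = function(V) 7.2 - 6.4 / (1 + exp(-(V + 28.3) / 19.2)),
               default_gbar = 300, default_E = -80, code = {
    alt <- model_tree()
    alt <- add_compartment(alt, "HH", A = 0.01, Cm = 10, V = -60)
    alt <- add_conductance(alt, "HH", "NaV", gbar = 1000, E = 50)
    alt <- add_conductance(alt, "HH", "Kd2", name = "Kd", gbar = 300)
    alt <- add_conductance(alt, "HH", "Leak", gbar = 1, E = -50)
    expect_false(identical(structural_hash(alt), structural_hash(hh)))
  })

  # full hashes distinguish the fixture set
  hashes <- vapply(c("hh_neuron", "bursting_neuron", "homeostatic_neuron",
                     "pyloric_network", "passive_cable"),
                   function(f) full_hash(make_fixture(f)), character(1))
  expect_equal(anyDuplicated(hashes), 0)
})
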