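test_that("spike detection counts upward threshold crossings", {
  t <- seq(0.5, 1000, by = 0.5)
  expect_length(spike_times(rep(-60, length(t)), t), 0)
  # sawtooth crossing 0 mV five times in one second -> 5 Hz
  saw <- 20 * ((t %% 200) / 200) - 10
  expect_length(spike_times(saw, t), 5)
  expect_equal(firing_rate(saw, t), 5)
  # refractory merges double-crossings
  jitter <- saw; jitter[saw > -0.2 & saw < 0.2] <- 0.3
  expect_length(spike_times(jitter, t, refractory = 5), 5)
})

test_that("f-I curve: quiescent at 0, spiking at 0.2 nA, weakly monotone", {
  hh <- hh_model()
  fi <- fi_curve(hh, c(0, 0.1, 0.2, 0.3), t_end = 1500, t_transient = 500)
  expect_equal(fi$rate[fi$I == 0], 0)
  expect_gt(fi$rate[fi$I == 0.2], 0)
  expect_true(all(diff(fi$rate) >= 0))
  expect_true(all(fi$rate >= 0))
  # a single amplitude reduces to the firing rate of one run
  tr <- integrate_model(hh, t_end = 1500, I_ext = c(HH = 0.2))
  keep <- tr$t > 500
  expect_equal(fi_curve(hh, 0.2, t_end = 1500, t_transient = 500)$rate,
               firing_rate(tr$V[keep, 1], tr$t[keep]))
})

test_that("voltage-clamp recovery matches direct gating evaluation", {
  steps <- seq(-60, 40, by = 20)
  fit <- recover_activation("Kd", V_steps = steps, t_clamp = 500)
  sc <- channel_info("Kd")
  direct <- 1000 * sc$m_inf(steps)^4 * (steps - (-80)) * 0.01
  expect_equal(fit$I_inf, direct, tolerance = 0.01)
})

test_that("activation recovery identifies the true exponent", {
  # synthetic first-order sigmoid channel: round-trip within 1%
  with_channel("syn_sig", p = 1, q = 0,
               m_inf = function(V) 1 / (1 + exp((-20 - V) / 8)),
               tau_m = function(V) rep(5, length(V)),
               default_gbar = 100, default_E = -80, code = {
    fit <- recover_activation("syn_sig", V_steps = seq(-70, 40, 5),
                              E_rev = -80)
    expect_equal(fit$n_best, 1)
    expect_equal(fit$V_half, -20, tolerance = 0.01)
    expect_equal(fit$k, 8, tolerance = 0.01)
  })
  # higher true exponents are recovered too
  for (p in c(2, 3)) {
    nm <- paste0("syn_sig", p)
    with_channel(nm, p = p, q = 0,
                 m_inf = function(V) 1 / (1 + exp((-25 - V) / 10)),
                 tau_m = function(V) rep(5, length(V)),
                 default_gbar = 100, default_E = -80, code = {
      fit <- recover_activation(nm, V_steps = seq(-70, 40, 5), E_rev = -80)
      expect_equal(fit$n_best, p)
    })
  }
  # a clamp step at the reversal potential is dropped with a warning
  expect_warning(recover_activation("Kd", V_steps = seq(-80, 50, 10)),
                 "reversal")
})

test_that("dominant-current labels follow the strongest in/outward current", {
  lk <- leak_model()
  tr <- integrate_model(lk, t_end = 50, dt = 0.05, record_currents = TRUE,
                        I_ext = c(c = 0.1))
  expect_true(all(dominant_current_labels(tr) == "Leak"))

  hh <- hh_model()
  trh <- integrate_model(hh, t_end = 300, dt = 0.05, I_ext = c(HH = 0.2),
                         record_currents = TRUE)
  lab <- dominant_current_labels(trh)
  V <- trh$V[, 1]
  dV <- c(V[2] - V[1], diff(V))
  up <- V > -20 & dV > 0.5    # action-potential upstroke
  dn <- V > -20 & dV < -0.5   # repolarization
  expect_gt(sum(up), 10)
  expect_true(all(lab[up] == "NaV"))
  expect_true(all(lab[dn] == "Kd"))

  expect_error(dominant_current_labels(integrate_model(hh, t_end = 10)),
               "record_currents")
})

test_that("dominant-current ties break by registry order", {
  # two identical leak channels: currents tie at every sample
  tree <- model_tree()
  tree <- add_compartment(tree, "c")
  tree <- add_conductance(tree, "c", "Leak", name = "LeakA", gbar = 1)
  tree <- add_conductance(tree, "c", "Leak", name = "LeakB", gbar = 1)
  tr <- integrate_model(tree, t_end = 20, dt = 0.05, record_currents = TRUE)
  expect_true(all(dominant_current_labels(tr) == "LeakA"))
})

test_that("trajectory cost is zero on identity, two on disjoint, symmetric", {
  hh <- hh_model()
  a <- integrate_model(hh, t_end = 500, dt = 0.05, I_ext = c(HH = 0.2))
  expect_equal(lemasson_error(a, a), 0)
  # non-overlapping embeddings: constant traces at different voltages
  expect_equal(lemasson_error(rep(-70, 100), rep(0, 100), dt_a = 1), 2)
  b <- integrate_model(hh, t_end = 500, dt = 0.1, I_ext = c(HH = 0.2))
  expect_equal(lemasson_error(a, b), lemasson_error(b, a))
  expect_gt(lemasson_error(a, b), 0)
})

test_that("parameter sweeps restore the baseline and handle edge cases", {
  hh <- hh_model()
  base <- serialize_model(hh)$vector
  out <- sweep_parameter(hh, "HH/Kd/gbar", c(150, 300, 600),
                         function(tt) get_param(tt, "HH/Kd/gbar"))
  expect_equal(unlist(out, use.names = FALSE), c(150, 300, 600))
  expect_identical(serialize_model(hh)$vector, base)
  expect_length(sweep_parameter(hh, "HH/Kd/gbar", numeric(0), identity), 0)
  expect_error(sweep_parameter(hh, "*/gbar", 1, identity), "ambiguous")

  # sweeping the calcium target of a homeostatic cell changes its endpoint
  ho <- make_fixture("homeostatic_neuron")
  ends <- sweep_parameter(ho, "AB/NaV_ctrl/Ca_target", c(20, 80),
                          function(tt) {
    tr <- integrate_model(tt, t_end = 3000, dt = 0.1)
    get_param(tr$model, "AB/NaV/gbar")
  })
  expect_false(identical(ends[[1]], ends[[2]]))
})
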