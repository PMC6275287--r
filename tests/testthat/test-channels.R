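test_that("channel_current follows gbar * m^p * h^q * (V - E) * A", {
  lk <- leak_model()$compartments$c$conductances$Leak
  # Ohm's law for the passive leak: 1 uS/mm2 * 0.01 mm2 * 10 mV = 0.1 nA
  expect_equal(channel_current(lk, V = -40, A = 0.01), 0.1)
  expect_equal(channel_current(lk, V = -50, A = 0.01), 0)  # at reversal

  hh <- hh_model()$compartments$HH
  nav <- hh$conductances$NaV
  expect_equal(channel_current(nav, V = 50, A = 0.01), 0)  # at reversal
  nav$state$m <- 0
  expect_equal(channel_current(nav, V = 0, A = 0.01), 0)   # closed gate

  # linear in gbar and in A
  set.seed(11)
  for (i in 1:20) {
    V <- runif(1, -90, 40); a <- runif(1, 0.001, 0.1)
    g1 <- runif(1, 1, 500); fac <- runif(1, 0.1, 5)
    kd <- hh$conductances$Kd
    kd$state$m <- runif(1)
    kd$params$gbar <- g1
    i1 <- channel_current(kd, V, a)
    kd$params$gbar <- g1 * fac
    expect_equal(channel_current(kd, V, a), i1 * fac)
    kd$params$gbar <- g1
    expect_equal(channel_current(kd, V, a * fac), i1 * fac)
  }
})

test_that("steady-state curves behave as expected for the builtin library", {
  sc <- steady_state_curves("NaV")
  expect_lt(sc$m_inf[sc$V == -100], 0.01)
  expect_gt(sc$m_inf[sc$V == 50], 0.99)
  expect_true(all(sc$m_inf >= 0 & sc$m_inf <= 1))
  expect_true(all(sc$h_inf >= 0 & sc$h_inf <= 1))
  expect_true(all(sc$tau_m > 0) && all(sc$tau_h > 0))

  # sodium activation much faster than delayed-rectifier activation
  V <- seq(-80, 50, 1)
  nav <- steady_state_curves("NaV", V)
  kd <- steady_state_curves("Kd", V)
  expect_true(all(nav$tau_m < kd$tau_m))
  expect_true(all(is.na(kd$tau_h)))           # non-inactivating
  expect_true(all(kd$h_inf == 1))

  expect_message(out <- steady_state_curves("Leak"), "no gating")
  expect_null(out)

  # calcium-dependent activation carries the saturating factor
  kca0 <- steady_state_curves("KCa", V)
  kca1 <- steady_state_curves("KCa", V, Ca = 3)
  expect_equal(kca1$m_inf, kca0$m_inf * 0.5)
})

test_that("the builtin library covers the fixture channel sets", {
  expect_true(all(c("NaV", "Kd", "Leak") %in% list_channels()))
  expect_true(all(c("NaV", "CaT", "CaS", "ACurrent", "KCa", "Kd",
                    "HCurrent", "Leak") %in% list_channels()))
  expect_true(channel_info("CaT")$is_calcium)
  expect_true(channel_info("CaS")$is_calcium)
  expect_false(channel_info("Kd")$is_calcium)
})

test_that("channel registration validates its spec", {
  expect_error(register_channel("NaV", p = 3, q = 1), "already registered")
  expect_error(
    register_channel("badtau", p = 1, q = 0,
                     m_inf = function(V) 1 / (1 + exp(-V / 10)),
                     tau_m = function(V) V / 100),  # <= 0 on the grid
    "strictly positive")
  expect_error(
    register_channel("badexp", p = 1.5, q = 0,
                     m_inf = function(V) 1 / (1 + exp(-V / 10)),
                     tau_m = function(V) rep(1, length(V))),
    "non-negative integers")
  expect_error(
    register_channel("badss", p = 1, q = 0,
                     m_inf = function(V) V,  # unbounded
                     tau_m = function(V) rep(1, length(V))),
    "lie in \\[0,1\\]")

  # a custom sigmoidal channel is usable in a model
  with_channel("sig1", p = 1, q = 0,
               m_inf = function(V) 1 / (1 + exp((-30 - V) / 10)),
               tau_m = function(V) rep(5, length(V)),
               default_gbar = 10, default_E = -80, code = {
    tree <- model_tree()
    tree <- add_compartment(tree, "c")
    tree <- add_conductance(tree, "c", "sig1")
    tr <- integrate_model(tree, t_end = 50, dt = 0.05)
    expect_true(all(is.finite(tr$V)))
  })
})
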