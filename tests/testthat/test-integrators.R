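test_that("exponential Euler is exact for the passive membrane", {
  lk <- leak_model()
  # tau_V = Cm/g = 10 ms; one 10 ms step from -60 toward -50
  tr <- integrate_model(lk, t_end = 10, dt = 10)
  expect_equal(unname(tr$V[1, 1]), -50 - 10 * exp(-1))
  # with injected current the asymptote is (g E + I/A)/g = -40 mV
  tr2 <- integrate_model(lk, t_end = 500, dt = 0.05, I_ext = c(c = 0.1))
  expect_equal(unname(tr2$V[nrow(tr2$V), 1]), -40, tolerance = 1e-9)
})

test_that("voltage clamp reports the total membrane current", {
  lk <- leak_model()
  tr <- integrate_model(lk, t_end = 100, dt = 0.05, V_clamp = c(c = -40))
  # g*A*(V - E) = 1 * 0.01 * 10 = 0.1 nA
  expect_equal(unname(tr$I_clamp[nrow(tr$I_clamp), 1]), 0.1)
  # clamping at the reversal of the only channel nulls the current
  tr0 <- integrate_model(lk, t_end = 100, dt = 0.05, V_clamp = c(c = -50))
  expect_equal(max(abs(tr0$I_clamp)), 0)

  # Kd-only cell: asymptotic clamp current grows nonlinearly with voltage
  kd <- model_tree()
  kd <- add_compartment(kd, "c", A = 0.01, V = -80)
  kd <- add_conductance(kd, "c", "Kd", gbar = 1000, E = -80)
  iinf <- vapply(c(-40, -10, 20, 50), function(vc) {
    tr <- integrate_model(kd, t_end = 500, dt = 0.05, V_clamp = c(c = vc))
    mean(tail(tr$I_clamp[, 1], 100))
  }, numeric(1))
  expect_true(all(diff(iinf) > 0))
  gap <- diff(iinf)                     # supralinear in this range
  expect_gt(gap[2], gap[1])

  expect_error(
    integrate_model(lk, t_end = 10, dt = 0.05, V_clamp = c(c = -40),
                    I_ext = c(c = 0.1)),
    "clamped and current-injected")
})

test_that("clamping a model at its own resting potential draws no current", {
  hh <- hh_model()
  rest <- integrate_model(hh, t_end = 3000, dt = 0.05)
  v_rest <- unname(rest$V[nrow(rest$V), 1])
  tr <- integrate_model(rest$model, t_end = 200, dt = 0.05,
                        V_clamp = c(HH = v_rest))
  expect_lt(max(abs(tr$I_clamp)), 1e-4)
})

test_that("RK4 reproduces the exact passive exponential to 5th order", {
  lk <- leak_model()
  err <- vapply(c(2, 1), function(dt) {
    tr <- integrate_model(lk, t_end = dt, dt = dt, solver = "rk4")
    abs(tr$V[1, 1] - (-50 - 10 * exp(-dt / 10)))
  }, numeric(1))
  expect_lt(err[1], 1e-4)
  # halving dt shrinks the one-step error ~ 2^5
  expect_gt(err[1] / err[2], 20)
  expect_lt(err[1] / err[2], 45)
})

test_that("RK4 and exponential Euler converge to each other as dt shrinks", {
  hh <- hh_model()
  difs <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    a <- integrate_model(hh, t_end = 100, dt = dt, out_dt = 0.1,
                         I_ext = c(HH = 0.2))
    b <- integrate_model(hh, t_end = 100, dt = dt, out_dt = 0.1,
                         solver = "rk4", I_ext = c(HH = 0.2))
    max(abs(a$V[, 1] - b$V[, 1]))
  }, numeric(1))
  expect_true(all(diff(difs) < 0))
})

test_that("RK4 rejects networks and multi-compartment models", {
  two <- add_compartment(add_compartment(model_tree(), "a"), "b")
  expect_error(integrate_model(two, t_end = 10, solver = "rk4"),
               "single-compartment")
})

test_that("Crank-Nicolson cable matches analytic steady-state attenuation", {
  cab <- make_fixture("passive_cable")
  n <- 50; dx <- 0.1
  tr <- integrate_model(cab, t_end = 2000, dt = 0.05,
                        solver = "crank_nicolson", I_ext = c(cable_01 = 0.05))
  defl <- tr$V[nrow(tr$V), ] + 50
  x <- (seq_len(n) - 0.5) * dx
  # lambda = sqrt(r R_m / (2 R_a)): 0.01 mm * 1 MOhm mm^2 / (2 * 1e-3 MOhm mm)
  lambda <- sqrt(0.01 * 1 / (2 * 100 * 1e-5))
  L <- n * dx
  pred <- cosh((L - x) / lambda) / cosh((L - x[1]) / lambda)
  expect_lt(max(abs(defl / defl[1] - pred) / pred), 0.02)
})

test_that("Crank-Nicolson is second-order accurate in time", {
  cab <- make_fixture("passive_cable", n_comp = 20)
  run <- function(dt) integrate_model(cab, t_end = 50, dt = dt, out_dt = 50,
                                      solver = "crank_nicolson",
                                      I_ext = c(cable_01 = 0.05))$V[1, ]
  ref <- run(0.003125)
  errs <- vapply(c(0.4, 0.2, 0.1), function(dt) max(abs(run(dt) - ref)),
                 numeric(1))
  expect_true(all(diff(errs) < 0))
  # halving dt cuts the error ~4x once in the asymptotic regime
  expect_gt(errs[2] / errs[3], 3)
  expect_lt(errs[2] / errs[3], 5)
})

test_that("zero axial coupling decouples the cable into single compartments", {
  cab <- make_fixture("passive_cable", n_comp = 5)
  tr <- integrate_model(cab, t_end = 100, dt = 0.05,
                        solver = "crank_nicolson", axial_g = rep(0, 4),
                        I_ext = c(cable_01 = 0.05))
  one <- model_tree()
  one <- add_compartment(one, "c", A = 2 * pi * 0.01 * 0.1, Cm = 10, V = -50,
                         radius = 0.01, len = 0.1, Ra = 100)
  one <- add_conductance(one, "c", "Leak", gbar = 1, E = -50)
  ref <- integrate_model(one, t_end = 100, dt = 0.05,
                         solver = "crank_nicolson", I_ext = c(c = 0.05))
  expect_identical(tr$V[, 1], ref$V[, 1])
  expect_true(all(tr$V[, 2:5] == -50))  # unstimulated compartments at rest
})

test_that("integration is deterministic and keeps states in [0,1]", {
  hh <- hh_model()
  a <- integrate_model(hh, t_end = 500, dt = 0.1, I_ext = c(HH = 0.2))
  b <- integrate_model(hh, t_end = 500, dt = 0.1, I_ext = c(HH = 0.2))
  expect_identical(a$V, b$V)

  # gating bounds hold even at coarse dt (exponential Euler property)
  bu <- make_fixture("bursting_neuron")
  for (dt in c(0.5, 0.05)) {
    tr <- integrate_model(bu, t_end = 2000, dt = dt)
    gm <- tr$model
    for (cd in gm$compartments$AB$conductances) {
      if (!is.null(cd$state$m)) expect_true(cd$state$m >= 0 && cd$state$m <= 1)
      if (!is.null(cd$state$h)) expect_true(cd$state$h >= 0 && cd$state$h <= 1)
    }
    expect_true(all(is.finite(tr$V)))
  }
})

test_that("simulation configuration is validated", {
  lk <- leak_model()
  expect_error(integrate_model(lk, t_end = 10, dt = 0.05, out_dt = 0.12),
               "multiple of dt")
  expect_error(integrate_model(lk, t_end = 0.01, dt = 0.05), "t_end")
  expect_error(integrate_model(lk, t_end = 10, dt = -1), "dt")
  expect_error(integrate_model(model_tree(), t_end = 10), "no compartments")
  expect_error(integrate_model(lk, t_end = 10, I_ext = c(zz = 1)),
               "unknown compartment")
  # an injected time series must cover every step
  expect_error(integrate_model(lk, t_end = 10, dt = 0.05,
                               I_ext = list(c = rep(0.1, 10))),
               "length nsteps")
  tr <- integrate_model(lk, t_end = 10, dt = 0.05,
                        I_ext = list(c = rep(0.1, 200)))
  expect_equal(length(tr$t), 200)
})
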