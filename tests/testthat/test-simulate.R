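test_that("basic model trajectories respect monotone fat and logistic bound", {
  tr <- integrate_model("basic", base_params(), diet_init("CD"), c(0, 15))
  expect_true(all(diff(tr$F) <= 1e-12))
  expect_true(all(tr$T <= 2000 * (1 + 1e-6)))
  expect_true(all(unlist(tr[c("T", "E", "F")]) >= -1e-9))

  # tumor-free initial condition: T stays zero, F constant, E relaxes to r*F0/mu
  tr0 <- integrate_model("basic", base_params(), c(T = 0, E = 20, F = 50), c(0, 15))
  expect_true(all(abs(tr0$T) < 1e-10))
  expect_equal(tail(tr0$F, 1), 50, tolerance = 1e-8)
  expect_equal(tail(tr0$E, 1), 20 * 50 / 5.94, tolerance = 1e-6)
})

test_that("compiled solvers agree with the reference right-hand sides", {
  # basic model: integrate_model (compiled) vs deSolve on base_rhs()
  p <- base_params()
  init <- diet_init("HFD")
  tr <- integrate_model("basic", p, init, c(0, 15), grid_dt = 0.5)
  ref <- deSolve::ode(init, tr$time, base_rhs, p, method = "lsoda",
                      rtol = 1e-8, atol = 1e-10)
  for (v in c("T", "E", "F")) {
    expect_lt(max(abs(tr[[v]] - ref[, v])) / max(abs(ref[, v])), 1e-7)
  }
  # extended model under constant control vs ext_rhs()
  pe <- scenario_preset("Ia")$params
  inite <- diet_init("CD", model = "extended")
  tre <- integrate_model("extended", pe, inite, c(0, 20), grid_dt = 0.5,
                         schedule = control_schedule("constant", u_b = 0.9))
  refe <- deSolve::ode(inite, tre$time,
                       function(t, y, pp) ext_rhs(t, y, pp, u = 0.9), pe,
                       method = "lsoda", rtol = 1e-8, atol = 1e-10)
  for (v in c("S", "R", "E", "F")) {
    expect_lt(max(abs(tre[[v]] - refe[, v])) / max(abs(refe[, v]), 1e-6), 1e-6)
  }
})

test_that("extended and basic models agree in the nested limit", {
  pe <- ext_params(c = 0, k2 = 0)
  tre <- integrate_model("extended", pe, c(S = 1, R = 0, E = 170, F = 50), c(0, 15))
  trb <- integrate_model("basic", base_params(), c(T = 1, E = 170, F = 50), c(0, 15))
  expect_lt(max(rel_diff(tre$S, trb$T)), 1e-6)
  expect_lt(max(rel_diff(tre$E, trb$E)), 1e-6)
  expect_lt(max(abs(tre$R)), 1e-10)
})

test_that("untreated tumor approaches the carrying capacity", {
  ps <- scenario_preset("Ia")
  tr <- integrate_model("extended", ps$params,
                        diet_init("CD", model = "extended"), c(0, 60))
  expect_equal(tail(tr$S + tr$R, 1), 2000, tolerance = 0.01)
})

test_that("fat is conserved when consumption and growth are off", {
  pe <- ext_params(alpha = 0, k2 = 0)
  tr <- integrate_model("extended", pe, diet_init("HFD", model = "extended"), c(0, 20))
  expect_lt(max(abs(tr$F - 360)), 1e-6)
})

test_that("grid refinement leaves the terminal state essentially unchanged", {
  ps <- scenario_preset("Ia")
  init <- diet_init("HFD", model = "extended")
  coarse <- integrate_model("extended", ps$params, init, c(0, 25), grid_dt = 0.1)
  fine <- integrate_model("extended", ps$params, init, c(0, 25), grid_dt = 0.05,
                          rtol = 1e-10, atol = 1e-12)
  for (v in c("S", "R", "E", "F")) {
    expect_lt(rel_diff(tail(coarse[[v]], 1), tail(fine[[v]], 1)), 1e-3)
  }
})

test_that("steady-state estrogen reproduces the arm initial conditions", {
  expect_equal(steady_state_estrogen(0, 20, 5.94), 0)
  expect_equal(steady_state_estrogen(50, 20, 5.94), 20 * 50 / 5.94)   # 168.35
  expect_equal(steady_state_estrogen(360, 20, 5.94), 20 * 360 / 5.94) # 1212.1
  expect_equal(round(steady_state_estrogen(50, 20, 5.94), 2), 168.35)
  expect_equal(round(steady_state_estrogen(360, 20, 5.94), 1), 1212.1)
  expect_error(steady_state_estrogen(50, 20, 0), "mu must be")
})

test_that("treatment-start detection interpolates the detection threshold", {
  # trajectory already above threshold: detection at the window start
  ps <- scenario_preset("Ia")
  big <- integrate_model("extended", ps$params,
                         c(S = 800, R = 0, E = 170, F = 50), c(0, 5))
  expect_equal(detect_treatment_start(big), 0)

  # synthetic exponential growth with known crossing time as oracle
  g <- 0.4
  t_star <- log(500) / g
  times <- seq(0, 20, by = 0.5)
  fake <- structure(
    data.frame(time = times, S = exp(g * times), R = 0),
    class = c("trajectory", "data.frame"),
    params = list(m1 = 1 / 2000, eta = 1)
  )
  t_hat <- detect_treatment_start(fake)
  expect_lt(abs(t_hat - t_star), 0.5)          # within one grid step
  expect_lt(abs(t_hat - t_star), 0.5^2 * g * 500 / 500)  # linear-interp error bound

  # refinement consistency on a real run
  un1 <- untreated_run("Ia", "CD")
  un2 <- integrate_model("extended", scenario_preset("Ia")$params,
                         diet_init("CD", model = "extended"), c(0, 25),
                         grid_dt = 0.025)
  expect_lt(abs(detect_treatment_start(un1) - detect_treatment_start(un2)), 0.05)

  # never detectable
  expect_warning(
    t_na <- detect_treatment_start(
      integrate_model("extended", ps$params,
                      c(S = 1, R = 0, E = 170, F = 50), c(0, 2))),
    "not detectable"
  )
  expect_true(is.na(t_na))
})

test_that("alternating schedules switch the control as a square wave", {
  sch <- control_schedule("alternating", u_b = 0.99, phase_on = 1,
                          phase_off = 1, start = 10)
  expect_equal(schedule_value(sch, c(9.5, 10, 10.5, 11, 11.5, 12)),
               c(0, 0.99, 0.99, 0, 0, 0.99))
  ps <- scenario_preset("Ia")
  st <- state_at(untreated_run("Ia", "CD"), 14)
  tr <- integrate_model("extended", ps$params, st, c(14, 20),
                        schedule = control_schedule("alternating", u_b = 0.99,
                                                    start = 14))
  expect_true(all(tr$u %in% c(0, 0.99)))
  # estrogen collapses during on-phases and recovers during off-phases
  expect_lt(min(tr$E), 5)
  expect_gt(max(tr$E[tr$time > 15]), 50)
})

test_that("tabulated controls reproduce an equivalent constant schedule", {
  ps <- scenario_preset("Ia")
  st <- state_at(untreated_run("Ia", "CD"), 14)
  tab <- control_schedule("tabulated",
                          table = data.frame(time = c(14, 25), value = 0.5))
  cst <- control_schedule("constant", u_b = 0.5, start = 14)
  tr1 <- integrate_model("extended", ps$params, st, c(14, 25), schedule = tab)
  tr2 <- integrate_model("extended", ps$params, st, c(14, 25), schedule = cst)
  for (v in c("S", "R", "E", "F")) {
    expect_lt(max(abs(tr1[[v]] - tr2[[v]])) / max(abs(tr2[[v]])), 1e-6)
  }
})

test_that("trajectories write and read back as tidy CSV", {
  tr <- integrate_model("basic", base_params(), diet_init("CD"), c(0, 5),
                        grid_dt = 1)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, path, labels = c(arm = "CD", scenario = "none"))
  long <- read_trajectory(path)
  expect_setequal(unique(long$variable), c("T", "E", "F", "u"))
  expect_equal(long$value[long$variable == "T"], tr$T)
  expect_true(all(long$arm == "CD"))
})
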