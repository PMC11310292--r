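# Internal bridges to the compiled model right-hand sides (src/models.c).
# The exported base_rhs()/ext_rhs()/adjoint_rhs() are the reference
# implementations; the solvers below are what simulation and the
# forward-backward sweep actually call, and the test suite asserts the two
# agree to integration tolerance.

base_par_order <- c("k1", "a1", "m1", "r", "mu", "alpha")
ext_par_order <- c(base_par_order, "eta", "c", "l", "a2", "a3", "k3", "k2", "m2")

check_ode_out <- function(out, times) {
  if (nrow(out) < length(times) || anyNA(out)) {
    stop(sprintf(
      "integration failed near t = %.4g (step-size collapse or non-finite state)",
      out[nrow(out), 1]
    ), call. = FALSE)
  }
  out
}

ode_basic_c <- function(init, times, params, rtol, atol) {
  out <- deSolve::ode(
    y = init, times = times, func = "derivs_basic",
    parms = as.numeric(unlist(params)[base_par_order]),
    dllname = "endoctrl", initfunc = "init_basic",
    method = "lsoda", rtol = rtol, atol = atol
  )
  check_ode_out(out, times)
}

# u_table: two-column (time, value) matrix; linearly interpolated, held
# constant beyond its range
ode_ext_c <- function(init, times, params, u_table, rtol, atol) {
  out <- deSolve::ode(
    y = init, times = times, func = "derivs_ext",
    parms = as.numeric(unlist(params)[ext_par_order]),
    dllname = "endoctrl", initfunc = "init_ext",
    forcings = u_table, initforc = "forc_ext",
    fcontrol = list(method = "linear", rule = 2),
    method = "lsoda", rtol = rtol, atol = atol
  )
  check_ode_out(out, times)
}

# adjoint solve in reversed time tau = t_f - t over the problem grid;
# state and control are supplied as forcing tables against tau
ode_adjoint_c <- function(grid, state, control, params, weights, rtol, atol) {
  t_f <- grid[length(grid)]
  tau <- rev(t_f - grid)
  forc <- lapply(c("S", "R", "E", "F"), function(v) {
    cbind(tau, rev(state[[v]]))
  })
  forc <- c(forc, list(cbind(tau, rev(control))))
  out <- deSolve::ode(
    y = c(lambda1 = 0, lambda2 = 0, lambda3 = 0, lambda4 = 0),
    times = tau, func = "derivs_adj",
    parms = c(as.numeric(unlist(params)[ext_par_order]),
              weights[["omega_S"]], weights[["omega_R"]]),
    dllname = "endoctrl", initfunc = "init_adj",
    forcings = forc, initforc = "forc_adj",
    fcontrol = list(method = "linear", rule = 2),
    method = "lsoda", rtol = rtol, atol = atol
  )
  check_ode_out(out, tau)
  adj <- as.data.frame(out[rev(seq_len(nrow(out))), , drop = FALSE])
  adj$time <- grid
  rownames(adj) <- NULL
  adj[, c("time", "lambda1", "lambda2", "lambda3", "lambda4")]
}
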