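#' Optimal control problem for anti-hormonal treatment
#'
#' Poses the quadratic treatment-scheduling problem: choose a measurable
#' control `u(t)` (fraction of estrogen production suppressed by the
#' aromatase inhibitor) within bounds `[u_a, u_b]` on the treatment window
#' `[t_tr, t_f]` to minimize
#' `J(u) = integral of omega_S*S + omega_R*R + (omega_u/2)*u^2 dt`
#' subject to the extended model dynamics with `dE/dt = (1-u)*r*F - mu*E`.
#' The quadratic control penalty encodes dose-dependent side effects; the
#' cap `u_b < 1` encodes residual local estrogen production that even
#' maximal inhibition cannot remove.
#'
#' @param params an [ext_params()] (its constant multiplier `p` is ignored;
#'   the control replaces it).
#' @param init named `(S, R, E, F)` state at the treatment start.
#' @param window numeric length-2 `(t_tr, t_f)` in days.
#' @param weights numeric length-3 `(omega_S, omega_R, omega_u)`, all
#'   `>= 0` with `omega_u > 0` (the control law divides by it).
#' @param bounds numeric length-2 `(u_a, u_b)` with `0 <= u_a < u_b < 1`.
#' @param grid_dt control discretization step (day).
#' @param rtol,atol solver tolerances for the forward/backward sweeps.
#' @return An object of class `ocp_problem`.
#' @export
ocp_problem <- function(params, init, window, weights = c(1, 1, 1),
                        bounds = c(0, 0.99), grid_dt = 0.05,
                        rtol = 1e-8, atol = 1e-10) {
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("ocp_problem: window must satisfy t_tr < t_f", call. = FALSE)
  }
  weights <- setNames(as.numeric(weights), c("omega_S", "omega_R", "omega_u"))
  if (any(weights < 0) || weights[["omega_u"]] <= 0) {
    stop("ocp_problem: weights must be >= 0 with omega_u > 0", call. = FALSE)
  }
  if (bounds[1] < 0 || bounds[1] >= bounds[2] || bounds[2] >= 1) {
    stop("ocp_problem: control bounds need 0 <= u_a < u_b < 1", call. = FALSE)
  }
  grid <- seq(window[1], window[2], by = grid_dt)
  if (grid[length(grid)] < window[2]) grid <- c(grid, window[2])
  structure(
    list(params = params, init = init, window = window, weights = weights,
         bounds = bounds, grid_dt = grid_dt, grid = grid,
         rtol = rtol, atol = atol),
    class = "ocp_problem"
  )
}

#' Cost functional of the treatment-scheduling problem
#'
#' Composite trapezoidal quadrature of
#' `omega_S*S + omega_R*R + (omega_u/2)*u^2` over the problem window.
#'
#' @param problem an [ocp_problem()].
#' @param state data frame with columns `time`, `S`, `R` on the problem
#'   grid (e.g. from [ocp_forward()]).
#' @param control control values on the same grid.
#' @return Scalar cost.
#' @export
ocp_cost <- function(problem, state, control) {
  if (nrow(state) != length(control)) {
    stop("ocp_cost: state and control must share the grid", call. = FALSE)
  }
  w <- problem$weights
  integrand <- w[["omega_S"]] * state$S + w[["omega_R"]] * state$R +
    w[["omega_u"]] / 2 * control^2
  trapz(state$time, integrand)
}

#' Forward state solve under a tabulated control
#'
#' Integrates the extended model over the problem window with the control
#' interpolated piecewise-linearly between grid nodes.
#'
#' @param problem an [ocp_problem()].
#' @param control control values on `problem$grid`, inside the bounds.
#' @return Data frame `time, S, R, E, F` on the grid.
#' @export
ocp_forward <- function(problem, control) {
  out <- ode_ext_c(problem$init, problem$grid, problem$params,
                   cbind(problem$grid, control), problem$rtol, problem$atol)
  as.data.frame(out)
}

#' Adjoint system of the treatment-scheduling problem
#'
#' Right-hand side of the costate equations obtained from the Pontryagin
#' Hamiltonian of the problem by `dlambda_i/dt = -dH/dx_i`, with terminal
#' condition `lambda_i(t_f) = 0`. `lambda_1 .. lambda_4` pair with
#' `(S, R, E, F)`. The steep Hill-switch derivatives are evaluated through
#' the overflow-safe identity `dh/dE = -(l/E) h (1-h)`.
#'
#' @param t time (day).
#' @param lambda numeric length-4 adjoint vector.
#' @param state named `(S, R, E, F)` state at `t` (interpolated from the
#'   current forward solve).
#' @param u control value at `t`.
#' @param problem an [ocp_problem()].
#' @return Named list whose first element is the adjoint derivative vector.
#' @export
adjoint_rhs <- function(t, lambda, state, u, problem) {
  p <- problem$params
  w <- problem$weights
  s <- pmax(state, 0)
  S <- s[["S"]]; R <- s[["R"]]; E <- s[["E"]]; F <- s[["F"]]
  l1 <- lambda[[1]]; l2 <- lambda[[2]]; l3 <- lambda[[3]]; l4 <- lambda[[4]]

  g <- growth_rate(E, p$k1, p$a1)
  dg <- p$k1 * p$a1 / (p$a1 + E)^2
  h2 <- hill_inhibition(E, p$a2, p$l)
  h3 <- hill_inhibition(E, p$a3, p$l)
  # -dh/dE for each switch; zero in the limit E -> 0 (l >= 1 steep switches)
  mdh2 <- if (E > 0) (p$l / E) * h2 * (1 - h2) else 0
  mdh3 <- if (E > 0) (p$l / E) * h3 * (1 - h3) else 0
  crowd <- 1 - p$m1 * (S + p$eta * R)

  d1 <- -w[["omega_S"]] -
    l1 * (g * (1 - p$m1 * (2 * S + p$eta * R)) - p$c * (h2 + h3)) +
    l2 * (p$m1 * p$k3 * R - p$c * h3) +
    l4 * p$alpha * F
  d2 <- -w[["omega_R"]] +
    l1 * g * S * p$m1 * p$eta -
    l2 * p$k3 * (1 - p$m1 * (S + 2 * p$eta * R)) +
    l4 * p$alpha * F
  d3 <- -l1 * (S * crowd * dg + p$c * S * (mdh2 + mdh3)) +
    l2 * p$c * S * mdh3 +
    l3 * p$mu
  d4 <- -l3 * (1 - u) * p$r -
    l4 * (p$k2 - 2 * p$k2 * p$m2 * F - p$alpha * (S + R))
  list(c(d1, d2, d3, d4))
}

#' Backward adjoint solve
#'
#' Integrates the adjoint system backward from `lambda(t_f) = 0`, with the
#' forward state supplied by dense linear interpolation of `state`.
#'
#' @inheritParams ocp_forward
#' @param state forward solution on the grid (from [ocp_forward()]).
#' @return Data frame `time, lambda1..lambda4` on the grid (ascending time).
#' @export
ocp_backward <- function(problem, state, control) {
  ode_adjoint_c(problem$grid, state, control, problem$params,
                problem$weights, problem$rtol, problem$atol)
}

#' Projected optimal control law
#'
#' Pointwise minimization of the Hamiltonian in `u` gives
#' `u* = min(u_b, max(u_a, r*F*lambda3 / omega_u))`.
#'
#' @param lambda3 adjoint variable paired with the estrogen state.
#' @param F fat volume (mm^3).
#' @param problem an [ocp_problem()].
#' @return Control value(s) clipped to the problem bounds.
#' @export
project_control <- function(lambda3, F, problem) {
  raw <- problem$params$r * F * lambda3 / problem$weights[["omega_u"]]
  pmin(problem$bounds[2], pmax(problem$bounds[1], raw))
}

# L1 relative difference between successive iterates
rel_err <- function(cur, pre, eps = 1e-12) {
  sum(abs(cur - pre)) / max(sum(abs(cur)), eps)
}

#' Forward-backward sweep solver with greedy convex-combination update
#'
#' Iterates (i) a forward state solve under the previous control, (ii) a
#' backward adjoint solve with terminal condition zero, (iii) the pointwise
#' projected control law, and (iv) a greedy line search over the convex
#' combinations `u_s = (1-s)*u_pre + s*u_cand` on a finite grid of
#' `s` values in (0, 1), accepting the `s` with the smallest cost. The sweep
#' stops when the L1 relative differences of control, state and adjoint
#' between successive iterations all fall below `tol`. The small-`s`
#' candidates give a near-no-move fallback, which keeps the accepted cost
#' sequence effectively non-increasing.
#'
#' @param problem an [ocp_problem()].
#' @param u_init starting control on the grid (default: no treatment).
#' @param tol relative-error stopping tolerance.
#' @param max_iter maximal number of sweeps; on hitting it the solution is
#'   returned with `converged = FALSE` and a warning.
#' @param s_grid finite line-search set approximating `s` in (0, 1).
#' @param verbose print per-iteration progress.
#' @return An `ocp_solution`: the best-cost iterate's `control`, `state`,
#'   `adjoint` and `cost`, plus the per-iteration log and a convergence
#'   flag.
#' @export
fbs_solve <- function(problem, u_init = NULL, tol = 1e-5, max_iter = 200,
                      s_grid = c(0.01, 0.05, seq(0.1, 0.9, by = 0.1), 0.95, 0.99),
                      verbose = FALSE) {
  grid <- problem$grid
  u <- if (is.null(u_init)) rep(problem$bounds[1], length(grid)) else u_init
  if (length(u) != length(grid)) stop("fbs_solve: u_init must live on the grid", call. = FALSE)
  u <- pmin(problem$bounds[2], pmax(problem$bounds[1], u))

  x <- ocp_forward(problem, u)
  lam <- ocp_backward(problem, x, u)
  J <- ocp_cost(problem, x, u)
  best <- list(u = u, x = x, lam = lam, J = J)
  log <- vector("list", max_iter)
  converged <- FALSE

  for (it in seq_len(max_iter)) {
    u_cand <- project_control(lam$lambda3, x$F, problem)
    best_s <- NA_real_
    s_J <- Inf
    s_u <- NULL
    s_x <- NULL
    for (s in s_grid) {
      u_s <- (1 - s) * u + s * u_cand
      x_s <- ocp_forward(problem, u_s)
      J_s <- ocp_cost(problem, x_s, u_s)
      if (J_s < s_J) {
        s_J <- J_s; best_s <- s; s_u <- u_s; s_x <- x_s
      }
    }
    lam_new <- ocp_backward(problem, s_x, s_u)
    errs <- c(
      control = rel_err(s_u, u),
      state = rel_err(unlist(s_x[, c("S", "R", "E", "F")]),
                      unlist(x[, c("S", "R", "E", "F")])),
      adjoint = rel_err(unlist(lam_new[, -1]), unlist(lam[, -1]))
    )
    log[[it]] <- data.frame(
      iter = it, s = best_s, cost = s_J,
      err_control = errs[["control"]], err_state = errs[["state"]],
      err_adjoint = errs[["adjoint"]]
    )
    u <- s_u; x <- s_x; lam <- lam_new; J <- s_J
    if (J < best$J) best <- list(u = u, x = x, lam = lam, J = J)
    if (verbose) {
      message(sprintf("FBS iter %3d: s = %.2f, J = %.6g, max err = %.3g",
                      it, best_s, s_J, max(errs)))
    }
    if (all(errs <= tol)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("FBS did not converge within %d iterations", max_iter),
            call. = FALSE)
  }

  structure(
    list(
      control = best$u, state = best$x, adjoint = best$lam, cost = best$J,
      grid = grid, iterations = do.call(rbind, log), converged = converged,
      problem = problem
    ),
    class = "ocp_solution"
  )
}

#' @export
print.ocp_solution <- function(x, ...) {
  n_it <- nrow(x$iterations)
  cat(sprintf(
    "Optimal control solution: cost %.6g after %d sweeps (%sconverged)\n",
    x$cost, n_it, if (x$converged) "" else "NOT "
  ))
  cat(sprintf(
    "  control range [%.4g, %.4g], total dose integral %.4g\n",
    min(x$control), max(x$control), trapz(x$grid, x$control)
  ))
  invisible(x)
}
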