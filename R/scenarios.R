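#' Simulation scenario presets
#'
#' Named presets for the treatment-resistance simulation study. All share
#' the calibrated/assumed core parameters (`k1 = 0.55`, `a1 = 43`,
#' `m1 = 1/2000`, `mu = 5.94`, `r = 20`, `alpha = 1.7e-6`, `eta = 1`,
#' `c = 1`, `l = 10`, `k2 = 0.05`, `m2 = 0.002711`) and differ in the
#' estrogen thresholds for death (`a2`) and adaptation (`a3`), the
#' resistant growth rate `k3` and the preexisting resistant fraction:
#'
#' * `Ia` - adaptive resistance, well-separated thresholds: `a2 = 20`,
#'   `a3 = 1`, `k3 = k1/2`, `R0 = 0`;
#' * `Ib` - as `Ia` but de novo resistance: 25% of the initial tumor is
#'   resistant;
#' * `II` - closer thresholds: `a2 = 10`, `a3 = 1`, `k3 = k1/2`, `R0 = 0`;
#' * `III` - coinciding thresholds and slower resistant growth:
#'   `a2 = a3 = 10`, `k3 = k1/4`, `R0 = 0`.
#'
#' @param name `"Ia"`, `"Ib"`, `"II"` or `"III"`.
#' @return A `scenario_preset`: list with `name`, `params` ([ext_params()]),
#'   `R0_fraction`, `t_f` and control bounds `u_a`, `u_b`.
#' @export
#' @examples
#' scenario_preset("Ia")$params$a2
scenario_preset <- function(name = c("Ia", "Ib", "II", "III")) {
  name <- match.arg(name)
  k1 <- 0.55
  cfg <- switch(name,
    Ia  = list(a2 = 20, a3 = 1, k3 = k1 / 2, R0_fraction = 0),
    Ib  = list(a2 = 20, a3 = 1, k3 = k1 / 2, R0_fraction = 0.25),
    II  = list(a2 = 10, a3 = 1, k3 = k1 / 2, R0_fraction = 0),
    III = list(a2 = 10, a3 = 10, k3 = k1 / 4, R0_fraction = 0)
  )
  structure(
    list(
      name = name,
      params = ext_params(a2 = cfg$a2, a3 = cfg$a3, k3 = cfg$k3),
      R0_fraction = cfg$R0_fraction,
      t_f = 25, u_a = 0, u_b = 0.99
    ),
    class = "scenario_preset"
  )
}

#' @export
print.scenario_preset <- function(x, ...) {
  cat(sprintf(
    "Scenario %s: a2 = %g, a3 = %g pg/g, k3 = %g/day, initial resistant fraction %g\n",
    x$name, x$params$a2, x$params$a3, x$params$k3, x$R0_fraction
  ))
  invisible(x)
}

#' Classify the outcome of a treated trajectory
#'
#' Summarises a full `[0, t_f]` trajectory of the extended model:
#' the final composite tumor volume, the final resistant fraction, the
#' total administered control, and a qualitative class -
#' * `eradicated`: final `S + R` below `eps_erad` (default 1 mm^3, the
#'   initial tumor volume);
#' * `resistant-regrowth`: the tumor is majority-resistant at the end and
#'   still growing;
#' * `contained`: the final tumor is no larger than at treatment start;
#' * `uncontrolled`: anything else.
#'
#' @param traj a `trajectory` of the extended model covering `[0, t_f]`.
#' @param t_tr treatment start day (defaults to the trajectory attribute).
#' @param eps_erad eradication threshold (mm^3).
#' @return One-row data frame with `t_tr`, `final_tumor`,
#'   `final_resistant_fraction`, `total_control` and `classification`.
#' @export
outcome_classify <- function(traj, t_tr = attr(traj, "t_tr"), eps_erad = 1) {
  n <- nrow(traj)
  size <- traj$S + traj$R
  final <- size[n]
  frac_R <- if (final > 0) traj$R[n] / final else 0
  rising <- size[n] > size[n - 1]
  size_at_tr <- if (is.na(t_tr)) NA_real_ else approx(traj$time, size, xout = t_tr)$y
  classification <- if (final < eps_erad) "eradicated"
  else if (frac_R > 0.5 && rising) "resistant-regrowth"
  else if (!is.na(size_at_tr) && final <= size_at_tr) "contained"
  else "uncontrolled"
  data.frame(
    t_tr = if (is.na(t_tr)) NA_real_ else t_tr,
    final_tumor = final,
    final_resistant_fraction = frac_R,
    total_control = trapz(traj$time, traj$u),
    classification = classification
  )
}

#' Run one treatment scenario
#'
#' Simulates the extended model for one scenario preset and diet arm:
#' untreated growth from day 0 until the tumor becomes detectable
#' (`S + eta*R` reaching `1/(4*m1)`, see [detect_treatment_start()]), then
#' the chosen treatment mode on `[t_tr, t_f]`:
#'
#' * `"constant"` - constant multiplier `p` on estrogen production
#'   (control `u = 1 - p`);
#' * `"alternating"` - square wave at `u_b` with equal on/off phases of
#'   `phase` days, starting with an on-phase at `t_tr`;
#' * `"optimal"` - the forward-backward sweep solution of the quadratic
#'   control problem with the given `weights`;
#' * `"none"` - no treatment (baseline).
#'
#' @param preset a [scenario_preset()] or its name.
#' @param diet `"CD"` or `"HFD"`.
#' @param mode treatment mode.
#' @param p constant-treatment multiplier in `(0, 1]`.
#' @param phase on/off phase length in days (alternating).
#' @param weights cost weights `(omega_S, omega_R, omega_u)` (optimal).
#' @param grid_dt output/control grid step (day).
#' @param eps_erad eradication threshold passed to [outcome_classify()].
#' @param ... further arguments passed to [fbs_solve()] (e.g. `tol`,
#'   `max_iter`).
#' @return A list with `trajectory` (full `[0, t_f]` path including the
#'   applied control), `summary` (one-row data frame from
#'   [outcome_classify()] plus run metadata) and, for optimal mode,
#'   `solution` (the `ocp_solution`).
#' @export
#' @examples
#' \donttest{
#' run <- run_scenario("Ia", "CD", mode = "constant", p = 0.0125)
#' run$summary
#' }
run_scenario <- function(preset, diet = c("CD", "HFD"),
                         mode = c("constant", "alternating", "optimal", "none"),
                         p = 0.0125, phase = 1, weights = c(1, 1, 1),
                         grid_dt = 0.05, eps_erad = 1, ...) {
  if (is.character(preset)) preset <- scenario_preset(preset)
  diet <- match.arg(diet)
  mode <- match.arg(mode)
  params <- preset$params
  init <- diet_init(diet, model = "extended", R0_fraction = preset$R0_fraction)
  t_f <- preset$t_f

  untreated <- integrate_model("extended", params, init, c(0, t_f),
                               grid_dt = grid_dt)
  t_tr <- detect_treatment_start(untreated)

  solution <- NULL
  if (mode == "none" || is.na(t_tr)) {
    traj <- untreated
  } else {
    pre <- integrate_model("extended", params, init, c(0, t_tr),
                           grid_dt = grid_dt)
    state_tr <- unlist(pre[nrow(pre), c("S", "R", "E", "F")])
    post <- switch(mode,
      constant = integrate_model("extended", params, state_tr, c(t_tr, t_f),
        schedule = control_schedule("constant", u_b = 1 - p, start = t_tr),
        grid_dt = grid_dt),
      alternating = integrate_model("extended", params, state_tr, c(t_tr, t_f),
        schedule = control_schedule("alternating", u_b = preset$u_b,
                                    phase_on = phase, phase_off = phase,
                                    start = t_tr),
        grid_dt = grid_dt),
      optimal = {
        prob <- ocp_problem(params, state_tr, c(t_tr, t_f),
                            weights = weights,
                            bounds = c(preset$u_a, preset$u_b),
                            grid_dt = grid_dt)
        solution <- fbs_solve(prob, ...)
        out <- solution$state
        out$u <- solution$control
        out
      }
    )
    traj <- rbind(as.data.frame(pre), as.data.frame(post)[-1, ])
    rownames(traj) <- NULL
    traj <- structure(traj, class = c("trajectory", "data.frame"),
                      model = "extended", params = params, t_tr = t_tr)
  }
  attr(traj, "t_tr") <- t_tr

  summary <- outcome_classify(traj, t_tr, eps_erad = eps_erad)
  summary <- cbind(
    data.frame(scenario = preset$name, diet = diet, mode = mode,
               p = if (mode == "constant") p else NA_real_,
               phase = if (mode == "alternating") phase else NA_real_,
               weights = if (mode == "optimal") paste(weights, collapse = ",")
                         else NA_character_),
    summary
  )
  if (!is.null(solution)) summary$ocp_cost <- solution$cost

  out <- list(trajectory = traj, summary = summary)
  if (!is.null(solution)) out$solution <- solution
  out
}

#' Run a matrix of scenarios
#'
#' Cross-product driver over presets, diets and treatment modes, collecting
#' the one-row outcome summaries into a tidy table. Failures of individual
#' cells are recorded (classification `"error"`) and the run continues.
#'
#' @param presets preset names.
#' @param diets diet arms.
#' @param modes list of mode descriptors, each a list with element `mode`
#'   and optional `p`, `phase` or `weights` (see [run_scenario()]).
#' @param ... passed on to [run_scenario()].
#' @return Data frame with one row per (preset, diet, mode).
#' @export
scenario_matrix <- function(presets = c("Ia", "Ib", "II", "III"),
                            diets = c("CD", "HFD"),
                            modes = list(list(mode = "constant", p = 0.0125)),
                            ...) {
  rows <- list()
  for (ps in presets) {
    for (d in diets) {
      for (m in modes) {
        args <- c(list(preset = ps, diet = d), m, list(...))
        res <- tryCatch(do.call(run_scenario, args)$summary,
          error = function(e) {
            data.frame(
              scenario = ps, diet = d, mode = m$mode,
              p = NA_real_, phase = NA_real_, weights = NA_character_,
              t_tr = NA_real_, final_tumor = NA_real_,
              final_resistant_fraction = NA_real_, total_control = NA_real_,
              classification = paste0("error: ", conditionMessage(e))
            )
          }
        )
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$ocp_cost)) r$ocp_cost <- NA_real_
    r
  }))
  rownames(out) <- NULL
  out
}
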