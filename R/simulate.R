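#' Treatment control schedules
#'
#' Describes the estrogen-deprivation control signal `u(t)` applied to the
#' extended model: nothing (`"none"`), a constant level from the treatment
#' start (`"constant"`), an on/off square wave anchored at the treatment
#' start (`"alternating"`: `phase_on` days at `u_b`, then `phase_off` days
#' untreated, beginning with an on-phase), or an arbitrary tabulated curve
#' interpolated piecewise-linearly (`"tabulated"`, used for optimal
#' controls).
#'
#' @param kind one of `"none"`, `"constant"`, `"alternating"`,
#'   `"tabulated"`.
#' @param u_b on-level of the control, in `[0, 1)`. A constant treatment
#'   multiplier `p` corresponds to `u_b = 1 - p`.
#' @param phase_on,phase_off on/off phase lengths in days (alternating).
#' @param start day at which treatment starts; before it `u = 0`.
#' @param table for `"tabulated"`: a two-column object (time, value).
#'
#' @return An object of class `control_schedule`.
#' @export
#' @examples
#' control_schedule("alternating", u_b = 0.99, phase_on = 1, phase_off = 1,
#'                  start = 14)
control_schedule <- function(kind = c("none", "constant", "alternating", "tabulated"),
                             u_b = 0.99, phase_on = 1, phase_off = 1,
                             start = 0, table = NULL) {
  kind <- match.arg(kind)
  if (u_b < 0 || u_b >= 1) stop("control_schedule: u_b must lie in [0, 1)", call. = FALSE)
  if (kind == "alternating" && (phase_on <= 0 || phase_off <= 0)) {
    stop("control_schedule: phase lengths must be > 0", call. = FALSE)
  }
  if (kind == "tabulated") {
    table <- as.data.frame(table)
    if (ncol(table) < 2) stop("control_schedule: table needs (time, value) columns", call. = FALSE)
    names(table)[1:2] <- c("time", "value")
    if (any(table$value < 0 | table$value >= 1)) {
      stop("control_schedule: tabulated values must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, u_b = u_b, phase_on = phase_on, phase_off = phase_off,
         start = start, table = table),
    class = "control_schedule"
  )
}

#' Evaluate a control schedule
#'
#' @param schedule a [control_schedule()] (or `NULL`, treated as no
#'   treatment).
#' @param t time(s) in days.
#' @return Control value(s) `u(t)` in `[0, 1)`. Piecewise-constant schedules
#'   are right-continuous at switch times.
#' @export
schedule_value <- function(schedule, t) {
  if (is.null(schedule) || schedule$kind == "none") return(rep(0, length(t)))
  switch(schedule$kind,
    constant = ifelse(t >= schedule$start, schedule$u_b, 0),
    alternating = {
      period <- schedule$phase_on + schedule$phase_off
      phase <- (t - schedule$start) %% period
      ifelse(t >= schedule$start & phase < schedule$phase_on, schedule$u_b, 0)
    },
    tabulated = {
      f <- approxfun(schedule$table$time, schedule$table$value, rule = 2)
      f(t)
    }
  )
}

# Times in (t0, t1) where a piecewise-constant schedule jumps; integration is
# segmented there so the solver never smooths across a discontinuity.
schedule_switches <- function(schedule, t_span) {
  if (is.null(schedule) || schedule$kind %in% c("none", "tabulated")) return(numeric(0))
  sw <- schedule$start
  if (schedule$kind == "alternating") {
    period <- schedule$phase_on + schedule$phase_off
    if (t_span[2] > schedule$start) {
      k <- ceiling((t_span[2] - schedule$start) / period) + 1
      on_off <- schedule$start + rep(seq_len(k) - 1, each = 2) * period +
        c(0, schedule$phase_on)
      sw <- c(sw, on_off)
    }
  }
  sw <- sort(unique(sw))
  sw[sw > t_span[1] & sw < t_span[2]]
}

#' Integrate the basic or extended model
#'
#' Solves the chosen model over a time window with a stiff-capable solver
#' (`lsoda`, relative tolerance `1e-8`, absolute tolerance `1e-10` by
#' default; the steep Hill switches at `l = 10` make stiffness likely under
#' treatment). Piecewise-constant schedules are handled by segmenting the
#' integration at the switch times; tabulated controls are interpolated
#' piecewise-linearly inside the solver.
#'
#' @param model `"basic"` or `"extended"`.
#' @param params [base_params()] or [ext_params()] matching `model`.
#' @param init named non-negative initial state (`c(T=,E=,F=)` or
#'   `c(S=,R=,E=,F=)`), e.g. from [diet_init()].
#' @param t_span numeric length-2, start and end day.
#' @param schedule a [control_schedule()] applied to the extended model
#'   (`NULL` = untreated; the basic model takes no control).
#' @param grid_dt output grid step (day).
#' @param rtol,atol solver tolerances.
#'
#' @return A `trajectory`: a data frame with columns `time`, the state
#'   variables, and `u` (the applied control), carrying the model, parameters
#'   and (optionally) the treatment start time as attributes.
#' @export
#' @examples
#' tr <- integrate_model("basic", base_params(), diet_init("CD"), c(0, 15))
#' tail(tr, 2)
integrate_model <- function(model = c("basic", "extended"), params, init,
                            t_span, schedule = NULL, grid_dt = 0.05,
                            rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  if (length(t_span) != 2 || t_span[1] >= t_span[2]) {
    stop("integrate_model: t_span must be increasing", call. = FALSE)
  }
  if (any(init < 0)) stop("integrate_model: initial state must be non-negative", call. = FALSE)

  grid <- seq(t_span[1], t_span[2], by = grid_dt)
  if (grid[length(grid)] < t_span[2]) grid <- c(grid, t_span[2])

  if (model == "basic") {
    out <- ode_basic_c(init, grid, params, rtol, atol)
    traj <- as.data.frame(out)
    traj$u <- 0
  } else {
    switches <- schedule_switches(schedule, t_span)
    bounds <- c(t_span[1], switches, t_span[2])
    pieces <- vector("list", length(bounds) - 1)
    state <- init
    for (i in seq_along(pieces)) {
      seg <- c(bounds[i], bounds[i + 1])
      times <- unique(sort(c(seg, grid[grid > seg[1] & grid < seg[2]])))
      if (is.null(schedule) || schedule$kind == "tabulated") {
        u_table <- if (is.null(schedule)) cbind(seg, c(0, 0)) else {
          as.matrix(schedule$table[, c("time", "value")])
        }
        u_out <- schedule_value(schedule, times)
      } else {
        u_seg <- schedule_value(schedule, seg[1] + min(1e-9, diff(seg) / 2))
        u_table <- cbind(seg, c(u_seg, u_seg))
        u_out <- rep(u_seg, length(times))
      }
      out <- ode_ext_c(state, times, params, u_table, rtol, atol)
      piece <- as.data.frame(out)
      piece$u <- u_out
      state <- unlist(piece[nrow(piece), names(init)])
      pieces[[i]] <- if (i > 1) piece[-1, , drop = FALSE] else piece
    }
    traj <- do.call(rbind, pieces)
    rownames(traj) <- NULL
  }

  structure(traj,
    class = c("trajectory", "data.frame"),
    model = model, params = params, schedule = schedule, t_tr = NA_real_
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "Trajectory of the %s model: %d time points on [%g, %g]\n",
    attr(x, "model"), nrow(x), x$time[1], x$time[nrow(x)]
  ))
  t_tr <- attr(x, "t_tr")
  if (!is.na(t_tr)) cat(sprintf("Treatment started at day %.3f\n", t_tr))
  print.data.frame(utils::head(as.data.frame(x), 4), ...)
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  vols <- intersect(c("T", "S", "R"), names(x))
  total <- rowSums(x[, vols, drop = FALSE])
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::matplot(x$time, cbind(total, x$F), type = "l", lty = 1:2,
    col = c("firebrick", "darkorange"),
    xlab = "time (day)", ylab = "volume (mm^3)", ...)
  graphics::par(new = TRUE)
  graphics::plot(x$time, x$E, type = "l", col = "steelblue", axes = FALSE,
    xlab = "", ylab = "")
  graphics::axis(4)
  graphics::mtext("estrogen (pg/g)", side = 4, line = 2.5)
  t_tr <- attr(x, "t_tr")
  if (!is.na(t_tr)) graphics::abline(v = t_tr, lty = 3)
  graphics::legend("topleft", c("tumor", "fat", "estrogen"), lty = c(1, 2, 1),
    col = c("firebrick", "darkorange", "steelblue"), bty = "n")
  invisible(x)
}

#' Detect the treatment start time
#'
#' The treatment start `t_tr` is the first time at which the composite tumor
#' size `S + eta*R` reaches the detectable-size threshold `1/(4*m1)`
#' (500 mm^3 at the default carrying capacity of 2000 mm^3), found by
#' linear interpolation between grid points of an untreated trajectory.
#'
#' The threshold condition is interpreted as the first *upward* crossing
#' (`direction = "reaches"`): a tumor growing from 1 mm^3 is below the
#' threshold from the outset, and treatment begins once it has grown to a
#' detectable size. The literal reading of the strict inequality
#' `S + eta*R < 1/(4*m1)` (`direction = "below"`), under which the condition
#' holds immediately, is selectable for comparison.
#'
#' @param traj untreated `trajectory` of the extended model (a basic-model
#'   trajectory is accepted, with `T` playing the role of `S`).
#' @param eta,m1 competition and inverse-carrying-capacity parameters;
#'   defaults are taken from the trajectory's parameter attribute.
#' @param direction `"reaches"` (default, upward crossing) or `"below"`.
#' @return The crossing day, or `NA` (with a warning) if the tumor never
#'   becomes detectable within the trajectory's window.
#' @export
detect_treatment_start <- function(traj, eta = NULL, m1 = NULL,
                                   direction = c("reaches", "below")) {
  direction <- match.arg(direction)
  p <- attr(traj, "params")
  if (is.null(m1)) m1 <- p$m1
  if (is.null(eta)) eta <- if (!is.null(p$eta)) p$eta else 1
  thr <- 1 / (4 * m1)
  size <- if ("S" %in% names(traj)) traj$S + eta * traj$R else traj$T
  tt <- traj$time
  if (direction == "below") {
    idx <- which(size < thr)
    if (length(idx) == 0) {
      warning("composite tumor size never below threshold", call. = FALSE)
      return(NA_real_)
    }
    return(tt[idx[1]])
  }
  if (size[1] >= thr) return(tt[1])
  above <- which(size >= thr)
  if (length(above) == 0) {
    warning("tumor not detectable within the simulated window", call. = FALSE)
    return(NA_real_)
  }
  i <- above[1]
  # linear interpolation of the upward crossing between grid points
  frac <- (thr - size[i - 1]) / (size[i] - size[i - 1])
  tt[i - 1] + frac * (tt[i] - tt[i - 1])
}

#' Steady-state estrogen concentration
#'
#' At the estrogen steady state `dE/dt = 0` of either model (untreated),
#' `E = r*F/mu`. Used to tie the initial estrogen concentration of each arm
#' to its initial fat volume.
#'
#' @param F fat volume (mm^3).
#' @param r estrogen production rate (pg/g mm^-3 day^-1).
#' @param mu estrogen washout rate (day^-1), `> 0`.
#' @return Estrogen concentration (pg/g).
#' @export
#' @examples
#' steady_state_estrogen(50, 20, 5.94)   # about 168, conventionally rounded to 170
steady_state_estrogen <- function(F, r, mu) {
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop("steady_state_estrogen: mu must be > 0", call. = FALSE)
  }
  r * F / mu
}

#' Write or read a trajectory as tidy CSV
#'
#' Long format with columns `time`, `variable`, `value` plus optional
#' constant label columns (e.g. `arm`, `scenario`, `schedule`).
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @param labels named character vector of constant label columns to attach.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   the long-format data frame.
#' @export
write_trajectory <- function(traj, path, labels = NULL) {
  vars <- setdiff(names(traj), "time")
  long <- do.call(rbind, lapply(vars, function(v) {
    data.frame(time = traj$time, variable = v, value = traj[[v]])
  }))
  for (nm in names(labels)) long[[nm]] <- labels[[nm]]
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) read.csv(path)

# composite trapezoidal quadrature on a (possibly non-uniform) grid
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
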