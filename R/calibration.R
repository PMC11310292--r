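#' Calibration specification for the basic model
#'
#' Declares which parameters of the basic model are fitted and which are
#' fixed, with box bounds applied in log10 space. The defaults mirror the
#' strategy that makes the problem practically identifiable with this
#' experimental design: `m1` (inverse carrying capacity), `mu` (estrogen
#' washout, from the tissue half-life) and `r` (estrogen production) are
#' fixed, while `k1`, `a1` and `alpha` are fitted inside `[1e-7, 1e4]`.
#' Initial estrogen per arm is not fitted either: it is tied to the fixed
#' initial fat volume through the steady state `E0 = r*F0/mu`.
#'
#' @param free character vector of fitted parameter names.
#' @param fixed named list of fixed parameter values.
#' @param bounds length-2 numeric (shared) or named list of per-parameter
#'   `(lower, upper)` bounds, strictly positive.
#' @param T0 initial tumor volume (mm^3), common to both arms.
#' @param F0 named vector of initial fat volumes per arm (mm^3).
#' @param rtol,atol solver tolerances used inside the objective.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(free = c("k1", "a1", "alpha"),
                             fixed = list(m1 = 1 / 2000, mu = 5.94, r = 20),
                             bounds = c(1e-7, 1e4),
                             T0 = 1, F0 = c(CD = 50, HFD = 360),
                             rtol = 1e-6, atol = 1e-8) {
  all_names <- names(formals(base_params))
  if (!all(free %in% all_names)) stop("calibration_spec: unknown free parameter", call. = FALSE)
  if (length(intersect(free, names(fixed))) > 0) {
    stop("calibration_spec: free and fixed parameters overlap", call. = FALSE)
  }
  if (!setequal(c(free, names(fixed)), all_names)) {
    stop("calibration_spec: free + fixed must cover all basic-model parameters",
         call. = FALSE)
  }
  if (is.numeric(bounds) && length(bounds) == 2) {
    bounds <- setNames(rep(list(bounds), length(free)), free)
  }
  for (nm in free) {
    b <- bounds[[nm]]
    if (is.null(b) || b[1] <= 0 || b[1] >= b[2]) {
      stop("calibration_spec: bounds must be positive with lower < upper", call. = FALSE)
    }
  }
  structure(
    list(free = free, fixed = fixed, bounds = bounds, T0 = T0, F0 = F0,
         rtol = rtol, atol = atol),
    class = "calibration_spec"
  )
}

# initial state of one arm under the calibration spec's fixing strategy
spec_init <- function(spec, params, arm) {
  F0 <- spec$F0[[arm]]
  c(T = spec$T0, E = steady_state_estrogen(F0, params$r, params$mu), F = F0)
}

# noiseless model predictions for every record of one arm
arm_predict <- function(params, init, records, rtol, atol) {
  days <- sort(unique(records$day))
  out <- tryCatch(
    suppressWarnings(ode_basic_c(init, c(0, days), params, rtol, atol)),
    error = function(e) NULL
  )
  if (is.null(out)) return(NULL)
  sim <- as.data.frame(out[-1, , drop = FALSE])
  col <- ifelse(records$variable == "fat_volume", "F", "T")
  idx <- match(records$day, days)
  vapply(seq_len(nrow(records)), function(i) sim[[col[i]]][idx[i]], numeric(1))
}

# per-record residual weights: the recorded sd where available and positive,
# otherwise the replicate spread within (arm, variable, day). The floor of
# 1e-3 * |value| keeps noise-free data usable while staying above the
# solver-tolerance mismatch between generator and objective simulations.
resid_weights <- function(data) {
  w <- if ("sd" %in% names(data)) data$sd else rep(NA_real_, nrow(data))
  need <- !is.finite(w) | w <= 0
  if (any(need)) {
    key <- interaction(data$arm, data$variable, data$day, drop = TRUE)
    spread <- tapply(data$value, key, function(v) if (length(v) > 1) sd(v) else NA_real_)
    w[need] <- spread[as.character(key)][need]
  }
  w[!is.finite(w) | w <= 0] <- pmax(abs(data$value[!is.finite(w) | w <= 0]), 1) * 1e-3
  w
}

# weighted residual vector over both arms; a failed simulation returns a
# large finite penalty so optimizers can back out of bad parameter regions
calib_residuals <- function(params, data, spec, weights = resid_weights(data)) {
  res <- numeric(nrow(data))
  for (arm in unique(data$arm)) {
    rows <- which(data$arm == arm)
    pred <- arm_predict(params, spec_init(spec, params, arm), data[rows, ],
                        spec$rtol, spec$atol)
    if (is.null(pred) || any(!is.finite(pred))) return(rep(1e4, nrow(data)))
    res[rows] <- (data$value[rows] - pred) / weights[rows]
  }
  res
}

#' Weighted least-squares calibration objective
#'
#' Simulates each experimental arm of a measurement set from its initial
#' conditions under a full basic-model parameter set (shared across arms)
#' and returns the chi-squared-style weighted residual sum of squares over
#' all tumor- and fat-volume records jointly. Residuals are weighted by the
#' recorded measurement sd, falling back to the replicate spread at each
#' (arm, variable, day) when no sd is recorded. Parameter sets at which the
#' simulation fails score a large finite penalty rather than raising an
#' error, so optimizers can recover.
#'
#' @param params full [base_params()].
#' @param data a `measurement_set` (see [generate_experiment()]).
#' @param spec a [calibration_spec()] providing the fixed initial
#'   conditions and solver tolerances.
#' @return Non-negative scalar.
#' @export
calib_objective <- function(params, data, spec = calibration_spec()) {
  sum(calib_residuals(params, data, spec)^2)
}

params_from_log10 <- function(theta, spec) {
  vals <- as.list(c(setNames(10^theta, spec$free), spec$fixed))
  do.call(base_params, vals[names(formals(base_params))])
}

#' Fit the basic model to measurement data
#'
#' Multistart bounded least-squares calibration. Free parameters are
#' optimized in log10 space (their plausible ranges span several decades)
#' with Levenberg-Marquardt ([minpack.lm::nls.lm]) from Latin-hypercube
#' starting points inside the bounds, plus the bound midpoint; the best
#' converged start wins. Deterministic for a fixed seed.
#'
#' @param data a `measurement_set`.
#' @param spec a [calibration_spec()].
#' @param n_starts number of multistart points.
#' @param seed RNG seed for the Latin hypercube.
#' @param start optional named vector of natural-scale starting values used
#'   as an additional start.
#' @return A `fit_result` with elements `estimates` (natural scale),
#'   `objective` (weighted residual sum of squares), `n_obs`, `converged`,
#'   `params` (full best-fit [base_params()]) and `starts` (the multistart
#'   log).
#' @export
#' @examples
#' ms <- generate_experiment(noise = noise_model(sigma_rel = 0), seed = 1)
#' fit <- fit_model(ms, n_starts = 6, seed = 1)
#' fit$estimates
fit_model <- function(data, spec = calibration_spec(), n_starts = 25,
                      seed = 1L, start = NULL) {
  k <- length(spec$free)
  lo <- log10(vapply(spec$bounds[spec$free], `[`, numeric(1), 1))
  hi <- log10(vapply(spec$bounds[spec$free], `[`, numeric(1), 2))
  if (!is.null(seed)) set.seed(seed)
  starts <- (lo + (hi - lo) * t(lhs::randomLHS(max(n_starts - 1, 1), k)))
  starts <- cbind((lo + hi) / 2, starts)[, seq_len(max(n_starts, 1)), drop = FALSE]
  if (!is.null(start)) starts <- cbind(log10(start[spec$free]), starts)

  weights <- resid_weights(data)
  fn <- function(theta) {
    calib_residuals(params_from_log10(theta, spec), data, spec, weights)
  }
  log <- vector("list", ncol(starts))
  best <- NULL
  for (i in seq_len(ncol(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[, i], lower = lo, upper = hi, fn = fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 200, ftol = 1e-13, ptol = 1e-13
        )
      ),
      error = function(e) NULL
    )
    if (is.null(res)) {
      log[[i]] <- data.frame(start = i, objective = NA_real_, info = -1)
      next
    }
    obj <- res$deviance
    log[[i]] <- data.frame(start = i, objective = obj, info = res$info)
    if (is.null(best) || obj < best$deviance) best <- res
  }
  if (is.null(best)) stop("fit_model: all starts failed", call. = FALSE)

  estimates <- setNames(10^best$par, spec$free)
  structure(
    list(
      estimates = estimates,
      objective = best$deviance,
      n_obs = nrow(data),
      converged = best$info %in% 1:4,
      params = params_from_log10(best$par, spec),
      spec = spec,
      starts = do.call(rbind, log)
    ),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Calibration fit: objective %.4g over %d observations (%sconverged)\n",
    x$objective, x$n_obs, if (x$converged) "" else "NOT "
  ))
  print(x$estimates, ...)
  invisible(x)
}

#' Profile-likelihood identifiability analysis
#'
#' Scans one fitted parameter over a log-spaced grid around its estimate,
#' re-optimizing the remaining free parameters at each grid value (warm
#' started from the neighbouring grid point), and compares the profiled
#' objective against the best objective plus a chi-squared threshold
#' (default 3.84: 95% for one degree of freedom). The parameter is
#' practically identifiable when the profile exceeds the threshold on both
#' sides within the bounds; otherwise the flat side(s) are reported as
#' open. The grid is extended adaptively until the threshold is crossed or
#' a bound is reached.
#'
#' @param data a `measurement_set`.
#' @param spec the [calibration_spec()] used for the fit.
#' @param fit the `fit_result` from [fit_model()].
#' @param param name of the profiled parameter (one of `spec$free`).
#' @param n_grid grid points of the initial scan.
#' @param half_span initial half-width of the scan in decades.
#' @param threshold objective increase defining the confidence region.
#' @param max_extend maximal number of adaptive one-decade extensions per
#'   side.
#' @return A `profile_result` with the grid (natural scale), profiled
#'   objectives, the verdict (`identifiable`, `lower-open`, `upper-open`,
#'   `both-open`) and the threshold-crossing confidence interval `ci`
#'   (open sides fall back to the bound).
#' @export
profile_likelihood <- function(data, spec, fit, param,
                               n_grid = 21, half_span = 1.5,
                               threshold = 3.84, max_extend = 3) {
  if (!param %in% spec$free) stop("profile_likelihood: param is not free", call. = FALSE)
  others <- setdiff(spec$free, param)
  lo_all <- log10(vapply(spec$bounds[spec$free], `[`, numeric(1), 1))
  hi_all <- log10(vapply(spec$bounds[spec$free], `[`, numeric(1), 2))
  weights <- resid_weights(data)

  refit <- function(pval_log, start_others) {
    sub_spec <- spec
    sub_spec$free <- others
    sub_spec$fixed <- c(spec$fixed, setNames(list(10^pval_log), param))
    if (length(others) == 0) {
      return(list(
        obj = sum(calib_residuals(params_from_log10(numeric(0), sub_spec),
                                  data, sub_spec, weights)^2),
        par = numeric(0)
      ))
    }
    fn <- function(theta) {
      calib_residuals(params_from_log10(theta, sub_spec), data, sub_spec, weights)
    }
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = start_others, lower = lo_all[others], upper = hi_all[others],
        fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-11, ptol = 1e-11)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) list(obj = Inf, par = start_others)
    else list(obj = res$deviance, par = res$par)
  }

  center <- log10(fit$estimates[[param]])
  step <- half_span / ((n_grid - 1) / 2)
  cutoff <- fit$objective + threshold

  scan_side <- function(dir) {
    grid <- c(); objs <- c()
    pars <- log10(fit$estimates[others])
    x <- center
    extensions <- 0
    n_side <- (n_grid - 1) / 2
    repeat {
      for (i in seq_len(n_side)) {
        x <- x + dir * step
        if (x < lo_all[param] || x > hi_all[param]) {
          x <- max(min(x, hi_all[param]), lo_all[param])
          r <- refit(x, pars)
          grid <- c(grid, x); objs <- c(objs, r$obj)
          return(list(grid = grid, objs = objs, crossed = r$obj > cutoff,
                      at_bound = TRUE))
        }
        r <- refit(x, pars)
        pars <- r$par
        grid <- c(grid, x); objs <- c(objs, r$obj)
        if (r$obj > cutoff) return(list(grid = grid, objs = objs,
                                        crossed = TRUE, at_bound = FALSE))
      }
      extensions <- extensions + 1
      if (extensions > max_extend) {
        return(list(grid = grid, objs = objs, crossed = FALSE, at_bound = FALSE))
      }
      n_side <- ceiling(1 / step)  # extend by about one decade
    }
  }

  lower <- scan_side(-1)
  upper <- scan_side(+1)
  grid_log <- c(rev(lower$grid), center, upper$grid)
  objs <- c(rev(lower$objs), fit$objective, upper$objs)

  verdict <- if (lower$crossed && upper$crossed) "identifiable"
  else if (!lower$crossed && !upper$crossed) "both-open"
  else if (!lower$crossed) "lower-open"
  else "upper-open"

  # Threshold crossing interpolated on the sqrt(objective rise) scale, where
  # a locally quadratic profile is linear, so coarse grids still give
  # accurate interval edges.
  ci_edge <- function(side, dir) {
    if (!side$crossed) {
      return(unname(10^(if (dir < 0) lo_all[param] else hi_all[param])))
    }
    g <- c(center, side$grid)
    o <- sqrt(pmax(c(fit$objective, side$objs) - fit$objective, 0))
    i <- which(o > sqrt(threshold))[1]
    10^approx(o[(i - 1):i], g[(i - 1):i], xout = sqrt(threshold),
              ties = "ordered")$y
  }

  structure(
    list(
      param = param, grid = 10^grid_log, objective = objs,
      threshold = threshold, best_objective = fit$objective,
      verdict = verdict,
      ci = c(lower = ci_edge(lower, -1), upper = ci_edge(upper, +1))
    ),
    class = "profile_result"
  )
}

#' @export
print.profile_result <- function(x, ...) {
  cat(sprintf(
    "Profile likelihood for %s: %s (95%% interval %.4g - %.4g)\n",
    x$param, x$verdict, x$ci[["lower"]], x$ci[["upper"]]
  ))
  invisible(x)
}

#' Washout rate from a half-life
#'
#' Converts a first-order elimination half-life given in hours to a daily
#' washout rate: `ln(2)/t_half * 24`. The estrogen half-life of 2.8 h in
#' breast tumor tissue gives the default washout rate 5.94 per day.
#'
#' @param t_half half-life in hours, `> 0`.
#' @return Rate in day^-1.
#' @export
#' @examples
#' washout_from_halflife(2.8)  # 5.94
washout_from_halflife <- function(t_half) {
  if (any(!is.finite(t_half)) || any(t_half <= 0)) {
    stop("washout_from_halflife: t_half must be > 0", call. = FALSE)
  }
  log(2) / t_half * 24
}

#' Volume of a spherical tumor
#'
#' `(pi/6) * diameter^3`; a 15 mm diameter tumor (the humane endpoint of the
#' emulated experiment) has a volume of about 1767 mm^3, motivating a tumor
#' carrying capacity of 2000 mm^3.
#'
#' @param diameter sphere diameter (mm), `>= 0`.
#' @return Volume (mm^3).
#' @export
#' @examples
#' sphere_volume(15)
sphere_volume <- function(diameter) {
  if (any(diameter < 0)) stop("sphere_volume: diameter must be >= 0", call. = FALSE)
  pi / 6 * diameter^3
}

#' Admissible range for the estrogen production rate
#'
#' At the estrogen steady state `E = r*F/mu`, requiring the initial estrogen
#' concentration of every arm to fall inside a measured interval
#' `[E_low, E_high]` constrains `r` to `[E_low*mu/F0, E_high*mu/F0]` per
#' initial fat volume; the admissible range is the intersection over arms.
#'
#' @param E_low,E_high bounds of the plausible estrogen concentration
#'   (pg/g), `0 < E_low < E_high`.
#' @param mu estrogen washout rate (day^-1).
#' @param F0_list initial fat volumes (mm^3), all `> 0`.
#' @return A list with `r_low`, `r_high` and `admissible` (`FALSE` with
#'   `NA` bounds when the intersection is empty).
#' @export
#' @examples
#' admissible_r_range(150, 1500, 5.94, c(50, 360))  # 17.82 .. 24.75
admissible_r_range <- function(E_low, E_high, mu, F0_list) {
  if (E_low <= 0 || E_low > E_high) {
    stop("admissible_r_range: need 0 < E_low <= E_high", call. = FALSE)
  }
  if (any(F0_list <= 0)) stop("admissible_r_range: F0 values must be > 0", call. = FALSE)
  lows <- E_low * mu / F0_list
  highs <- E_high * mu / F0_list
  r_low <- max(lows)
  r_high <- min(highs)
  if (r_low > r_high) {
    list(r_low = NA_real_, r_high = NA_real_, admissible = FALSE)
  } else {
    list(r_low = r_low, r_high = r_high, admissible = TRUE)
  }
}
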