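#' Parameters of the basic tumor-estrogen-fat model
#'
#' Constructs and validates the parameter set of the untreated model. The
#' defaults are the calibrated/assumed values for the mouse experiment the
#' package emulates: logistic tumor growth driven by estrogen through
#' Michaelis-Menten kinetics `k1*E/(a1+E)`, estrogen produced by fat at rate
#' `r` and washed out at rate `mu`, and fat consumed by the tumor at rate
#' `alpha`.
#'
#' @param k1 maximum tumor growth rate (day^-1).
#' @param a1 estrogen concentration at half-maximum growth (pg/g).
#' @param m1 inverse tumor carrying capacity (mm^-3).
#' @param r estrogen production rate per unit fat (pg/g mm^-3 day^-1).
#' @param mu estrogen washout rate (day^-1).
#' @param alpha fat consumption rate by tumor cells (day^-1 mm^-3).
#'
#' @return An object of class `base_params` (named list).
#' @export
#' @examples
#' base_params()
base_params <- function(k1 = 0.55, a1 = 43, m1 = 1 / 2000, r = 20,
                        mu = 5.94, alpha = 1.7e-6) {
  p <- list(k1 = k1, a1 = a1, m1 = m1, r = r, mu = mu, alpha = alpha)
  validate_base_params(p)
  structure(p, class = "base_params")
}

validate_base_params <- function(p) {
  vals <- unlist(p[c("k1", "a1", "m1", "r", "mu", "alpha")])
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("base_params: all parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) stop("base_params: all parameters must be >= 0", call. = FALSE)
  if (p$m1 <= 0) stop("base_params: m1 must be > 0", call. = FALSE)
  if (p$mu <= 0) stop("base_params: mu must be > 0", call. = FALSE)
  invisible(p)
}

#' Parameters of the extended sensitive/resistant model
#'
#' Extends [base_params()] with the treatment-resistance compartmental
#' structure: low-estrogen death and adaptation of sensitive cells (Hill
#' switches at thresholds `a2` and `a3` with coefficient `l` and maximum rate
#' `c`), estrogen-independent growth of resistant cells at rate `k3`,
#' logistic fat growth (`k2`, `m2`) and a constant treatment multiplier `p`
#' scaling the estrogen production (`p = 1` means no treatment).
#'
#' @inheritParams base_params
#' @param eta competition intensity of resistant on sensitive cells
#'   (dimensionless).
#' @param c maximum death/adaptation rate of sensitive cells (day^-1).
#' @param l Hill coefficient of the low-estrogen switches (dimensionless,
#'   `>= 1`).
#' @param a2 estrogen threshold below which sensitive cells die (pg/g).
#' @param a3 estrogen threshold below which sensitive cells convert to
#'   resistant (pg/g).
#' @param k3 growth rate of resistant cells (day^-1).
#' @param k2 fat growth rate (day^-1).
#' @param m2 inverse fat carrying capacity (mm^-3).
#' @param p constant treatment multiplier in `(0, 1]`; equivalently the
#'   control value `u = 1 - p`.
#'
#' @return An object of class `ext_params` (named list).
#' @export
#' @examples
#' ext_params(a2 = 20, a3 = 1, k3 = 0.275)
ext_params <- function(k1 = 0.55, a1 = 43, m1 = 1 / 2000, r = 20,
                       mu = 5.94, alpha = 1.7e-6,
                       eta = 1, c = 1, l = 10,
                       a2 = 20, a3 = 1, k3 = k1 / 2,
                       k2 = 0.05, m2 = 0.002711, p = 1) {
  pars <- list(
    k1 = k1, a1 = a1, m1 = m1, r = r, mu = mu, alpha = alpha,
    eta = eta, c = c, l = l, a2 = a2, a3 = a3, k3 = k3,
    k2 = k2, m2 = m2, p = p
  )
  validate_ext_params(pars)
  structure(pars, class = "ext_params")
}

validate_ext_params <- function(pars) {
  vals <- unlist(pars)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("ext_params: all parameters must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) stop("ext_params: all parameters must be >= 0", call. = FALSE)
  if (pars$m1 <= 0) stop("ext_params: m1 must be > 0", call. = FALSE)
  if (pars$mu <= 0) stop("ext_params: mu must be > 0", call. = FALSE)
  if (pars$p <= 0 || pars$p > 1) stop("ext_params: p must satisfy 0 < p <= 1", call. = FALSE)
  if (pars$l < 1) stop("ext_params: Hill coefficient l must be >= 1", call. = FALSE)
  invisible(pars)
}

#' @export
print.base_params <- function(x, ...) {
  cat("Basic tumor-estrogen-fat model parameters:\n")
  print(unlist(x), ...)
  invisible(x)
}

#' @export
print.ext_params <- function(x, ...) {
  cat("Extended sensitive/resistant model parameters:\n")
  print(unlist(x), ...)
  invisible(x)
}

#' Diet-specific initial conditions
#'
#' The two experimental arms differ only in their initial fat volume and,
#' through the estrogen steady state `E0 = r*F0/mu`, their initial estrogen
#' concentration. The control diet (CD) arm starts from 50 mm^3 of fat
#' (estrogen about 170 pg/g); the high-fat diet (HFD) arm from 360 mm^3
#' (about 1200 pg/g). The initial tumor volume is 1 mm^3 for both arms.
#'
#' @param diet `"CD"` or `"HFD"`.
#' @param model `"basic"` for a `(T, E, F)` state, `"extended"` for an
#'   `(S, R, E, F)` state.
#' @param R0_fraction for the extended model, the fraction of the initial
#'   tumor volume that is resistant (de novo resistance); the sensitive
#'   compartment gets the remainder.
#' @param T0 initial tumor volume (mm^3).
#' @param rounded if `TRUE` (default) use the conventional rounded initial
#'   estrogen values (170 / 1200 pg/g); if `FALSE` derive `E0` exactly from
#'   the steady state via [steady_state_estrogen()].
#' @param params parameter set supplying `r` and `mu` when `rounded = FALSE`.
#'
#' @return Named numeric state vector.
#' @export
#' @examples
#' diet_init("CD")
#' diet_init("HFD", model = "extended", R0_fraction = 0.25)
diet_init <- function(diet = c("CD", "HFD"), model = c("basic", "extended"),
                      R0_fraction = 0, T0 = 1, rounded = TRUE,
                      params = base_params()) {
  diet <- match.arg(diet)
  model <- match.arg(model)
  F0 <- if (diet == "CD") 50 else 360
  E0 <- if (rounded) {
    if (diet == "CD") 170 else 1200
  } else {
    steady_state_estrogen(F0, params$r, params$mu)
  }
  if (model == "basic") {
    c(T = T0, E = E0, F = F0)
  } else {
    if (R0_fraction < 0 || R0_fraction > 1) {
      stop("R0_fraction must lie in [0, 1]", call. = FALSE)
    }
    c(S = (1 - R0_fraction) * T0, R = R0_fraction * T0, E = E0, F = F0)
  }
}

#' Read and write parameter sets as YAML or JSON
#'
#' Parameter files use keys matching the model parameter names (`k1`, `a1`,
#' `m1`, `mu`, `r`, `alpha` and, for the extended model, `eta`, `c`, `l`,
#' `a2`, `a3`, `k3`, `k2`, `m2`, `p`). The format is chosen from the file
#' extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @param model `"basic"` or `"extended"`; chooses the validating
#'   constructor.
#' @return `read_params()` returns a `base_params` or `ext_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path, model = c("basic", "extended")) {
  model <- match.arg(model)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  ctor <- if (model == "basic") base_params else ext_params
  do.call(ctor, as.list(vals)[names(vals) %in% names(formals(ctor))])
}

#' @param params a `base_params` or `ext_params` object.
#' @rdname read_params
#' @export
write_params <- function(params, path) {
  vals <- lapply(unclass(params), as.numeric)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
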