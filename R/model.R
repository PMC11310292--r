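#' Hill inhibition switch
#'
#' Decreasing Hill function `a^l / (a^l + E^l)` used for the low-estrogen
#' death and adaptation switches of sensitive tumor cells: close to 1 when
#' the estrogen concentration `E` is well below the threshold `a`, close to 0
#' well above it, and exactly 1/2 at `E = a`.
#'
#' Evaluated as `plogis(-l * (log(E) - log(a)))`, which is algebraically the
#' same quantity but immune to overflow of `E^l` at large Hill coefficients.
#'
#' @param E estrogen concentration (pg/g), `>= 0`. Vectorised.
#' @param a threshold concentration (pg/g), `> 0`.
#' @param l Hill coefficient (dimensionless, `>= 1`).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' hill_inhibition(0, 20, 10)   # 1: full switch at zero estrogen
#' hill_inhibition(20, 20, 10)  # 0.5 at the threshold
hill_inhibition <- function(E, a, l) {
  if (any(!is.finite(a)) || any(a <= 0)) stop("hill_inhibition: a must be > 0", call. = FALSE)
  if (any(!is.finite(l)) || any(l < 1)) stop("hill_inhibition: l must be >= 1", call. = FALSE)
  if (any(!is.finite(E)) || any(E < 0)) stop("hill_inhibition: E must be >= 0", call. = FALSE)
  ifelse(E == 0, 1, plogis(-l * (log(E) - log(a))))
}

# Michaelis-Menten proliferation rate k1*E/(a1+E)
growth_rate <- function(E, k1, a1) k1 * E / (a1 + E)

#' Right-hand side of the basic model
#'
#' Time derivative of the untreated tumor-estrogen-fat system:
#' `dT/dt = k1*E/(a1+E) * T * (1 - m1*T)`, `dE/dt = r*F - mu*E`,
#' `dF/dt = -alpha*T*F`. State components are clipped at zero before
#' evaluation to guard against solver micro-negativity.
#'
#' @param t time (day); unused (the system is autonomous) but kept for the
#'   standard ODE signature.
#' @param state named numeric vector `c(T=, E=, F=)`.
#' @param params a [base_params()] object (or compatible named list).
#' @return Named list whose first element is the derivative vector, as
#'   expected by [deSolve::ode()].
#' @export
#' @examples
#' base_rhs(0, c(T = 1, E = 170, F = 50), base_params())
base_rhs <- function(t, state, params) {
  s <- pmax(state, 0)
  T <- s[["T"]]; E <- s[["E"]]; F <- s[["F"]]
  dT <- growth_rate(E, params$k1, params$a1) * T * (1 - params$m1 * T)
  dE <- params$r * F - params$mu * E
  dF <- -params$alpha * T * F
  list(c(T = dT, E = dE, F = dF))
}

#' Right-hand side of the extended (controlled) model
#'
#' Time derivative of the sensitive/resistant system under an
#' estrogen-deprivation control `u` in `[0, 1)`:
#'
#' * `dS/dt = g(E)*S*(1 - m1*(S + eta*R)) - c*h(E, a2)*S - c*h(E, a3)*S`
#' * `dR/dt = k3*R*(1 - m1*(S + eta*R)) + c*h(E, a3)*S`
#' * `dE/dt = (1 - u)*r*F - mu*E`
#' * `dF/dt = k2*F*(1 - m2*F) - alpha*(S + R)*F`
#'
#' with `g(E) = k1*E/(a1+E)` and `h(E, a) = a^l/(a^l + E^l)`
#' ([hill_inhibition()]). Constant treatment with multiplier `p` is the same
#' mechanism with `u = 1 - p`; `u = 0` is no treatment.
#'
#' @param t time (day).
#' @param state named numeric vector `c(S=, R=, E=, F=)`.
#' @param params an [ext_params()] object (or compatible named list).
#' @param u control value in `[0, 1)` (fraction of estrogen production
#'   suppressed).
#' @return Named list whose first element is the derivative vector.
#' @export
ext_rhs <- function(t, state, params, u = 0) {
  if (!is.finite(u) || u < 0 || u >= 1) {
    stop("ext_rhs: control u must lie in [0, 1)", call. = FALSE)
  }
  s <- pmax(state, 0)
  S <- s[["S"]]; R <- s[["R"]]; E <- s[["E"]]; F <- s[["F"]]
  crowd <- 1 - params$m1 * (S + params$eta * R)
  h2 <- hill_inhibition(E, params$a2, params$l)
  h3 <- hill_inhibition(E, params$a3, params$l)
  dS <- growth_rate(E, params$k1, params$a1) * S * crowd -
    params$c * h2 * S - params$c * h3 * S
  dR <- params$k3 * R * crowd + params$c * h3 * S
  dE <- (1 - u) * params$r * F - params$mu * E
  dF <- params$k2 * F * (1 - params$m2 * F) - params$alpha * (S + R) * F
  list(c(S = dS, R = dR, E = dE, F = dF))
}
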