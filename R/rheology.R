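## Blood rheology: simplified Quemada shear-thinning viscosity. In the
## surrogate's axisymmetric pipe profiles the shear rate reduces to the
## radial gradient of the axial velocity.

#' Quemada viscosity model constants
#'
#' @param mu0 high-shear plateau viscosity, kg/(m s) (default 3.09e-3); the
#'   model is clamped from below at this value.
#' @param mu_inf asymptotic viscosity, kg/(m s) (default 2.65e-3).
#' @param tau0 apparent yield shear stress, Pa (default 4.36e-3).
#' @param lambda shear stress modifier, 1/s (default 2.18e-2).
#' @param form `"sqrt_quemada"` (the standard simplified Quemada closure,
#'   default), `"newtonian"` (constant viscosity `mu0`, for verification
#'   against constant-viscosity closed forms), or `"literal_printed"` (a
#'   non-standard algebraic variant kept for auditability; it never exceeds
#'   `mu0`, so with the clamp it is constant).
#' @return object of class `viscosity_model`.
#' @export
viscosity_model <- function(mu0 = 3.09e-3, mu_inf = 2.65e-3, tau0 = 4.36e-3,
                            lambda = 2.18e-2,
                            form = c("sqrt_quemada", "newtonian",
                                     "literal_printed")) {
  stopifnot(mu0 > 0, mu_inf > 0, tau0 >= 0, lambda > 0)
  structure(list(mu0 = mu0, mu_inf = mu_inf, tau0 = tau0, lambda = lambda,
                 form = match.arg(form)), class = "viscosity_model")
}

#' Quemada apparent blood viscosity
#'
#' Standard simplified Quemada form:
#' `mu = max(mu0, (sqrt(mu_inf) + sqrt(tau0) / (sqrt(lambda) + sqrt(gdot)))^2)`.
#' Viscosity decreases with shear rate and is clamped at the plateau value
#' `mu0` for high shear rates (crossover near 253 1/s with the default
#' constants).
#'
#' @param gdot shear rate(s), 1/s (>= 0); vectorized.
#' @param model a [viscosity_model()].
#' @return viscosity, kg/(m s), same length as `gdot`.
#' @export
quemada_viscosity <- function(gdot, model = viscosity_model()) {
  if (any(gdot < 0)) stop("shear rate must be >= 0")
  mu <- switch(model$form,
    sqrt_quemada = (sqrt(model$mu_inf) +
                      sqrt(model$tau0) / (sqrt(model$lambda) + sqrt(gdot)))^2,
    newtonian = rep(model$mu0, length(gdot)),
    literal_printed = (model$mu_inf + model$tau0 * model$lambda + gdot)^2)
  pmax(model$mu0, mu)
}

#' Shear rate of an axisymmetric pipe profile
#'
#' The second invariant of the rate-of-deformation tensor; for a parallel
#' axial profile `u_z(r)` it reduces to `|du_z/dr|`.
#'
#' @param du_dr radial gradient(s) of the axial velocity, 1/s.
#' @return shear rate(s), 1/s (nonnegative).
#' @export
shear_rate <- function(du_dr) abs(du_dr)
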