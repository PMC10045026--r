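#' Blood-like fluid properties
#'
#' Container for the Newtonian fluid model used throughout the package.
#' Defaults correspond to whole blood treated as a homogeneous Newtonian
#' fluid: density 1060 kg/m^3 and dynamic viscosity 3.71e-3 Pa s. The
#' kinematic viscosity `nu = mu / rho` is derived and stored.
#'
#' @param rho density in kg/m^3 (> 0).
#' @param mu dynamic viscosity in Pa s (> 0).
#' @return an object of class `fluid_properties` with fields `rho`, `mu`,
#'   `nu`.
#' @examples
#' blood <- fluid_properties()
#' blood$nu  # 3.5e-6 m^2/s
#' @export
fluid_properties <- function(rho = 1060, mu = 3.71e-3) {
  check_scalar(rho, "rho", positive = TRUE)
  check_scalar(mu, "mu", positive = TRUE)
  structure(list(rho = rho, mu = mu, nu = mu / rho),
            class = "fluid_properties")
}

#' @export
print.fluid_properties <- function(x, ...) {
  cat(sprintf("Newtonian fluid: rho = %g kg/m^3, mu = %g Pa s, nu = %g m^2/s\n",
              x$rho, x$mu, x$nu))
  invisible(x)
}

#' Reynolds number of the inlet flow
#'
#' `Re = u * rho * D / mu`, evaluated with the inlet section diameter `D`
#' and a representative inlet velocity `u`.
#'
#' @param u velocity magnitude in m/s (>= 0).
#' @param D diameter in m (> 0).
#' @param fluid a [fluid_properties()] object.
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds_number(0.5, 0.035)  # 5000 for the default blood model
#' @export
reynolds_number <- function(u, D, fluid = fluid_properties()) {
  check_scalar(u, "u", nonneg = TRUE)
  check_scalar(D, "D", positive = TRUE)
  u * fluid$rho * D / fluid$mu
}

#' k-epsilon turbulence initialization
#'
#' Initial turbulent state derived from the peak inlet velocity, as used to
#' start a low-Reynolds k-epsilon computation from rest:
#' \deqn{k = \tfrac12 u_{max}^2,\quad
#'       \epsilon = C_\mu^{3/4} k^{3/2} / L,\quad
#'       \nu_t = C_\mu k^2 / \epsilon,}
#' with reference length `L = 0.038 D` and `C_mu = 0.09`.
#'
#' The turbulent viscosity is returned in kinematic form (m^2/s), which is
#' the quantity transported by the closure model; set `dynamic = TRUE` to
#' obtain `mu_t = rho * nu_t` instead.
#'
#' @param u0_max peak inlet velocity magnitude, m/s (> 0).
#' @param D inlet diameter, m (> 0).
#' @param fluid a [fluid_properties()] object.
#' @param c_mu closure constant, default 0.09.
#' @param dynamic if TRUE also report the dynamic turbulent viscosity.
#' @return an object of class `turbulence_init` with fields `k` (m^2/s^2),
#'   `epsilon` (m^2/s^3), `nu_t` (m^2/s), `L` (m), `c_mu`, and `mu_t`
#'   (Pa s) when `dynamic = TRUE`.
#' @examples
#' init_turbulence(0.5, 0.035)
#' @export
init_turbulence <- function(u0_max, D, fluid = fluid_properties(),
                            c_mu = 0.09, dynamic = FALSE) {
  check_scalar(u0_max, "u0_max", positive = TRUE)
  check_scalar(D, "D", positive = TRUE)
  check_scalar(c_mu, "c_mu", positive = TRUE)
  k <- 0.5 * u0_max^2
  L <- 0.038 * D
  epsilon <- c_mu^0.75 * k^1.5 / L
  nu_t <- c_mu * k^2 / epsilon
  out <- list(k = k, epsilon = epsilon, nu_t = nu_t, L = L, c_mu = c_mu)
  if (dynamic) out$mu_t <- fluid$rho * nu_t
  structure(out, class = "turbulence_init")
}

#' @export
print.turbulence_init <- function(x, ...) {
  cat(sprintf("k = %g m^2/s^2, epsilon = %g m^2/s^3, nu_t = %g m^2/s (L = %g m)\n",
              x$k, x$epsilon, x$nu_t, x$L))
  invisible(x)
}
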