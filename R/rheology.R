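#' Carreau-Yasuda rheology parameters
#'
#' Shear-thinning blood viscosity parameters. Defaults are a published set
#' appropriate for flow leading to and within the Circle of Willis:
#' eta_inf = 0.0022 Pa s, eta_0 = 0.022 Pa s, lambda = 0.11 s, a = 0.644,
#' n = 0.392.
#'
#' @param eta_inf infinite-shear viscosity, Pa s.
#' @param eta_0 zero-shear viscosity, Pa s (> eta_inf).
#' @param lambda relaxation time, s.
#' @param a Yasuda transition-width exponent.
#' @param n power-law index (0 < n < 1 for shear thinning).
#' @return an object of class `rheology_params`.
#' @export
rheology_params <- function(eta_inf = 0.0022, eta_0 = 0.022, lambda = 0.11,
                            a = 0.644, n = 0.392) {
  if (!(eta_inf > 0 && eta_0 >= eta_inf))
    stop("need 0 < eta_inf <= eta_0")
  if (lambda <= 0 || a <= 0) stop("lambda and a must be positive")
  if (n <= 0 || n > 1) stop("power index n must lie in (0, 1]")
  structure(list(eta_inf = eta_inf, eta_0 = eta_0, lambda = lambda,
                 a = a, n = n),
            class = "rheology_params")
}

#' Newtonian rheology of constant viscosity
#'
#' Convenience constructor: a degenerate Carreau-Yasuda model with
#' eta_0 = eta_inf = mu, under which the network solver reduces to a linear
#' Poiseuille circuit.
#'
#' @param mu constant dynamic viscosity, Pa s.
#' @return a [rheology_params()].
#' @export
newtonian_params <- function(mu = 0.0035) {
  rheology_params(eta_inf = mu, eta_0 = mu, lambda = 0.11, a = 0.644, n = 1)
}

#' Carreau-Yasuda apparent viscosity
#'
#' \deqn{\mu(\dot\gamma) = \eta_\infty + (\eta_0 - \eta_\infty)
#'   \left[1 + (\lambda\dot\gamma)^a\right]^{(n-1)/a}}
#' Strictly decreasing in shear rate for shear-thinning parameters,
#' interpolating between the zero-shear plateau eta_0 and the infinite-shear
#' plateau eta_inf.
#'
#' @param shear_rate scalar or vector shear rate, 1/s (>= 0).
#' @param params a [rheology_params()].
#' @return apparent viscosity in Pa s (vectorised over `shear_rate`).
#' @export
carreau_yasuda_viscosity <- function(shear_rate, params = rheology_params()) {
  if (any(!is.finite(shear_rate)) || any(shear_rate < 0))
    stop("shear_rate must be finite and non-negative")
  with(params,
       eta_inf + (eta_0 - eta_inf) * (1 + (lambda * shear_rate)^a)^((n - 1) / a))
}

#' Poiseuille wall shear stress
#'
#' \eqn{\tau_w = 32 \mu Q / (\pi D^3)} in SI units; the sign follows the
#' sign of the flow.
#'
#' @param flow_ml_min volumetric flow in mL/min (may be signed).
#' @param diameter_mm lumen diameter in mm (> 0).
#' @param viscosity dynamic viscosity in Pa s (> 0).
#' @return wall shear stress in Pa (vectorised).
#' @export
poiseuille_wss <- function(flow_ml_min, diameter_mm, viscosity) {
  if (any(diameter_mm <= 0)) stop("diameter_mm must be positive")
  if (any(viscosity <= 0)) stop("viscosity must be positive")
  q <- flow_ml_min * 1e-6 / 60
  d <- diameter_mm * 1e-3
  32 * viscosity * q / (pi * d^3)
}

#' Grid convergence index
#'
#' Richardson-extrapolation-based estimate of relative discretisation error
#' from solutions on two grids:
#' \eqn{GCI = F_s |\epsilon| / (r^p - 1)} with
#' \eqn{\epsilon = (f_{coarse} - f_{fine})/f_{fine}}. The mesh is accepted
#' when the GCI falls below the threshold (default 3%).
#'
#' @param f_fine solution quantity on the fine grid (non-zero).
#' @param f_coarse solution quantity on the coarse grid.
#' @param r grid refinement ratio (> 1).
#' @param p_order observed order of convergence (> 0).
#' @param safety_factor Roache safety factor (default 1.25).
#' @param threshold acceptance threshold on the GCI fraction (default 0.03).
#' @return an object of class `gci_result`: list with `gci`, `epsilon`,
#'   `threshold` and logical `pass`.
#' @export
gci <- function(f_fine, f_coarse, r, p_order, safety_factor = 1.25,
                threshold = 0.03) {
  if (!is.finite(f_fine) || f_fine == 0) stop("f_fine must be non-zero")
  if (!is.finite(r) || r <= 1) stop("refinement ratio r must exceed 1")
  if (!is.finite(p_order) || p_order <= 0) stop("p_order must be positive")
  eps <- (f_coarse - f_fine) / f_fine
  g <- safety_factor * abs(eps) / (r^p_order - 1)
  structure(list(gci = g, epsilon = eps, r = r, p_order = p_order,
                 safety_factor = safety_factor, threshold = threshold,
                 pass = g < threshold),
            class = "gci_result")
}

#' @export
print.gci_result <- function(x, ...) {
  cat(sprintf("<gci_result> GCI = %.4f%% (r = %g, p = %g, Fs = %g): %s (threshold %.1f%%)\n",
              100 * x$gci, x$r, x$p_order, x$safety_factor,
              if (x$pass) "PASS" else "FAIL", 100 * x$threshold))
  invisible(x)
}
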