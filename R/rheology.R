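#' Blood rheology parameters
#'
#' Parameter set for the Carreau-Yasuda shear-thinning law and the constant
#' plasma-viscosity alternative. Defaults are the blood-analog fit commonly
#' used for aortic haemodynamics (eta_inf 2.2 mPa.s, eta_0 22 mPa.s, lambda
#' 0.11 s, a 0.644, n 0.392); plasma viscosity defaults to 1.0 mPa.s. All
#' values are overridable and are echoed into every report.
#'
#' @param eta_inf infinite-shear viscosity [Pa.s].
#' @param eta_0 zero-shear viscosity [Pa.s].
#' @param lambda characteristic time [s].
#' @param a transition exponent (dimensionless).
#' @param n power-law exponent, 0 < n < 1.
#' @param mu_plasma constant plasma viscosity [Pa.s].
#' @return an object of class \code{rheology_params}.
#' @export
rheology_params <- function(eta_inf = 2.2e-3, eta_0 = 22e-3, lambda = 0.11,
                            a = 0.644, n = 0.392, mu_plasma = 1.0e-3) {
  stopifnot(eta_0 > eta_inf, eta_inf > 0, lambda > 0, a > 0,
            n > 0, n < 1, mu_plasma > 0)
  structure(list(eta_inf = eta_inf, eta_0 = eta_0, lambda = lambda,
                 a = a, n = n, mu_plasma = mu_plasma),
            class = "rheology_params")
}

#' Carreau-Yasuda viscosity
#'
#' mu(gdot) = eta_inf + (eta_0 - eta_inf) * [1 + (lambda gdot)^a]^((n-1)/a).
#' Strictly decreasing in shear rate, with mu(0) = eta_0 and
#' mu(Inf) = eta_inf.
#'
#' @param shear_rate shear rate [1/s], >= 0 (vectorized).
#' @param params a \code{rheology_params}.
#' @return viscosity [Pa.s].
#' @export
cy_viscosity <- function(shear_rate, params = rheology_params()) {
  if (any(shear_rate < 0)) stop("shear rate must be non-negative")
  with(params,
       eta_inf + (eta_0 - eta_inf) *
         (1 + (lambda * shear_rate)^a)^((n - 1) / a))
}

#' Invert wall shear stress to wall shear rate
#'
#' Solves tau = mu(gdot) * gdot for gdot under the Carreau-Yasuda law. The map
#' gdot -> mu(gdot) gdot is strictly increasing (mu decreases slower than
#' 1/gdot for 0 < n < 1), so the root is unique; bisection on the bracket
#' [0, tau/eta_inf] converges unconditionally.
#'
#' @param tau_mag wall shear stress magnitude [Pa], >= 0 (vectorized).
#' @param params a \code{rheology_params}.
#' @param tol relative residual tolerance.
#' @return shear rate [1/s] with |tau - mu(gdot) gdot| <= tol * max(tau, eps).
#' @export
shear_rate_from_wss <- function(tau_mag, params = rheology_params(),
                                tol = 1e-10) {
  if (any(tau_mag < 0)) stop("shear stress magnitude must be non-negative")
  pos <- tau_mag > 0
  g <- numeric(length(tau_mag))
  if (any(pos)) {
    tau <- tau_mag[pos]
    lo <- numeric(length(tau))
    hi <- tau / params$eta_inf  # mu >= eta_inf so gdot <= tau/eta_inf
    # vectorized bisection; 64 halvings exceed any double tolerance and the
    # residual criterion below certifies convergence
    for (it in 1:64) {
      mid <- 0.5 * (lo + hi)
      up <- cy_viscosity(mid, params) * mid > tau
      hi[up] <- mid[up]
      lo[!up] <- mid[!up]
      if (all(abs(cy_viscosity(mid, params) * mid - tau) <=
                tol * pmax(tau, .Machine$double.eps))) break
    }
    g[pos] <- 0.5 * (lo + hi)
  }
  g
}

#' Wall viscosity map
#'
#' The viscosity entering the single-leaky-junction conductivity, per vertex.
#' \code{plasma} mode returns the constant plasma viscosity everywhere;
#' \code{carreau_yasuda} mode inverts the instantaneous wall shear stress
#' magnitude to a shear rate at each sample and averages mu(gdot(t)) over the
#' cycle (or evaluates mu at the TAWSS-derived shear rate when
#' \code{eval = "at_tawss"}).
#'
#' @param series a \code{wall_field_series}.
#' @param mode \code{"plasma"} or \code{"carreau_yasuda"}.
#' @param params a \code{rheology_params}.
#' @param eval for CY mode: \code{"instantaneous_mean"} (default) averages
#'   mu(gdot(t)) over the cycle; \code{"at_tawss"} evaluates mu once at the
#'   shear rate inverted from TAWSS.
#' @return a \code{scalar_map} of viscosity [Pa.s].
#' @export
wall_viscosity_map <- function(series, mode = c("carreau_yasuda", "plasma"),
                               params = rheology_params(),
                               eval = c("instantaneous_mean", "at_tawss")) {
  mode <- match.arg(mode)
  eval <- match.arg(eval)
  nv <- dim(series$wss)[1L]
  if (mode == "plasma") {
    return(scalar_map(series$mesh, "mu_wall", rep(params$mu_plasma, nv),
                      units = "Pa.s"))
  }
  if (eval == "at_tawss") {
    g <- shear_rate_from_wss(tawss_values(series), params)
    mu <- cy_viscosity(g, params)
  } else {
    mag <- wss_magnitude(series)
    mu_t <- matrix(cy_viscosity(shear_rate_from_wss(as.vector(mag), params),
                                params),
                   nrow = nv)
    mu <- cycle_integral(mu_t, series$times, series$period) / series$period
  }
  scalar_map(series$mesh, "mu_wall", mu, units = "Pa.s")
}
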