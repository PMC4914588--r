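#' Integral of a sampled field over one cardiac cycle
#'
#' Periodic trapezoidal rule: the samples cover [0, T) and the wrap segment
#' from the last sample back to the t = 0 sample (at t = T) closes the cycle.
#' On smooth periodic data this rule is spectrally accurate.
#'
#' @param x numeric vector (one value per time sample) or matrix with one row
#'   per vertex and one column per time sample.
#' @param times sample instants, \code{times[1] == 0}, last < \code{period}.
#' @param period cycle duration T [s].
#' @return the integral over [0, T]; a scalar for vector input, a per-vertex
#'   vector for matrix input.
#' @export
cycle_integral <- function(x, times, period) {
  nt <- length(times)
  if (nt < 3L) stop("need at least 3 time samples")
  if (is.matrix(x)) {
    if (ncol(x) != nt) stop("x must have one column per time sample")
  } else {
    if (length(x) != nt) stop("x must have one value per time sample")
    x <- matrix(x, nrow = 1L)
  }
  # trapezoid weights for the closed periodic grid 0, t2, ..., t_nt, T
  dt <- c(diff(times), period - times[nt])
  w <- numeric(nt)
  w[1L] <- 0.5 * (dt[1L] + dt[nt])  # t=0 sample also closes the wrap segment
  w[2:nt] <- 0.5 * (dt[1:(nt - 1L)] + dt[2:nt])
  out <- drop(x %*% w)
  out
}

wss_magnitude <- function(series) {
  sqrt(series$wss[, , 1L]^2 + series$wss[, , 2L]^2 + series$wss[, , 3L]^2)
}

tawss_values <- function(series) {
  cycle_integral(wss_magnitude(series), series$times, series$period) /
    series$period
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Mean magnitude of the wall shear stress vector over one cycle,
#' (1/T) * integral of ||tau(t)|| dt, per vertex.
#'
#' @param series a \code{wall_field_series}.
#' @return a \code{scalar_map} in Pa.
#' @export
compute_tawss <- function(series) {
  scalar_map(series$mesh, "tawss", tawss_values(series), units = "Pa")
}

#' Oscillatory shear index (OSI)
#'
#' OSI = 0.5 * (1 - ||integral tau dt|| / integral ||tau|| dt). Zero for a
#' shear vector of fixed direction, 0.5 when the cycle-mean vector vanishes.
#' Vertices with zero shear throughout the cycle have indeterminate OSI; they
#' are assigned 0 and flagged (see the \code{flag} component of the result).
#'
#' @param series a \code{wall_field_series}.
#' @return a dimensionless \code{scalar_map} with values in [0, 0.5].
#' @export
compute_osi <- function(series) {
  ix <- cycle_integral(series$wss[, , 1L], series$times, series$period)
  iy <- cycle_integral(series$wss[, , 2L], series$times, series$period)
  iz <- cycle_integral(series$wss[, , 3L], series$times, series$period)
  num <- sqrt(ix^2 + iy^2 + iz^2)
  den <- cycle_integral(wss_magnitude(series), series$times, series$period)
  zero <- den <= 0
  osi <- numeric(length(den))
  osi[!zero] <- 0.5 * (1 - num[!zero] / den[!zero])
  osi <- pmin(pmax(osi, 0), 0.5)  # guard rounding at the endpoints
  scalar_map(series$mesh, "osi", osi, units = "", flag = zero)
}

#' HOLMES index (Highly Oscillatory, Low MagnitudE Shear)
#'
#' HOLMES = TAWSS * (0.5 - OSI): a modified TAWSS that is further reduced
#' where the shear is oscillatory, so the index is small exactly where shear
#' is both weak and directionless. Equals half the reciprocal of the relative
#' residence time.
#'
#' @param tawss TAWSS \code{scalar_map} [Pa].
#' @param osi OSI \code{scalar_map} (dimensionless).
#' @return a \code{scalar_map} in Pa.
#' @export
compute_holmes <- function(tawss, osi) {
  if (!same_mesh_or_null(tawss$mesh, osi$mesh))
    stop("tawss and osi must be on the same mesh")
  scalar_map(tawss$mesh, "holmes", tawss$values * (0.5 - osi$values),
             units = "Pa", flag = osi$flag)
}

#' Relative residence time (RRT)
#'
#' RRT = 1 / ((1 - 2 OSI) * TAWSS); a proxy for near-wall residence of fluid.
#' Where the denominator is at or below machine precision (OSI = 0.5 or zero
#' TAWSS) the value is a NaN sentinel, flagged and excluded from statistics.
#'
#' @param tawss TAWSS \code{scalar_map} [Pa].
#' @param osi OSI \code{scalar_map}.
#' @return a \code{scalar_map} in 1/Pa with a sentinel \code{flag}.
#' @export
compute_rrt <- function(tawss, osi) {
  if (!same_mesh_or_null(tawss$mesh, osi$mesh))
    stop("tawss and osi must be on the same mesh")
  den <- (1 - 2 * osi$values) * tawss$values
  bad <- !(den > .Machine$double.eps)
  rrt <- ifelse(bad, NaN, 1 / den)
  scalar_map(tawss$mesh, "rrt", rrt, units = "1/Pa", flag = bad)
}

#' All shear stress indices at once
#'
#' Convenience wrapper computing TAWSS, OSI, HOLMES and RRT from one series.
#'
#' @param series a \code{wall_field_series}.
#' @return a named list of \code{scalar_map}s
#'   (\code{tawss}, \code{osi}, \code{holmes}, \code{rrt}).
#' @export
shear_indices <- function(series) {
  tawss <- compute_tawss(series)
  osi <- compute_osi(series)
  list(tawss = tawss, osi = osi,
       holmes = compute_holmes(tawss, osi),
       rrt = compute_rrt(tawss, osi))
}
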