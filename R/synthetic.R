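#' Specification of a synthetic pulsatile vessel fixture
#'
#' Declarative description of a cylindrical vessel surface carrying zoned
#' pulsatile wall shear stress and pressure, used to exercise every pipeline
#' stage without external data. Each zone spans an axial fraction of the
#' cylinder and carries an axial shear waveform
#' tau(t) = (A + B sin(2 pi t / T)) e_z (plus optional decaying higher
#' harmonics), so mean magnitude and oscillatory character are set
#' independently per zone and closed-form index values exist. The default
#' three-zone fixture emulates the shear environments of interest: a healthy
#' high-shear zone (A = 4, B = 1 Pa), a low, mildly oscillatory zone
#' (A = 0.05, B = 0.3 Pa) and a reversing zone with moderate mean magnitude
#' but no preferential direction (A = 0, B = 4 Pa) -- the environment that a
#' magnitude-only shear index misclassifies.
#'
#' @param radius cylinder radius [m].
#' @param length cylinder length [m].
#' @param n_circ circumferential resolution (>= 8).
#' @param n_axial axial resolution (>= 8).
#' @param zones list of zones, each a list with \code{frac_lo}, \code{frac_hi}
#'   (axial fraction range, half-open), \code{type} (one of
#'   \code{"healthy_high_shear"}, \code{"low_oscillatory"},
#'   \code{"reversing"}, \code{"rotating"}), \code{A} (mean shear [Pa]),
#'   \code{B} (oscillation amplitude [Pa]) and optional \code{harmonics}
#'   (default 1).
#' @param period cardiac period T [s].
#' @param n_time number of time samples over [0, T).
#' @param p_mean mean pressure [Pa] (default 70 mmHg).
#' @param p_amp pressure pulse amplitude [Pa] (default 20 mmHg).
#' @param noise_sd multiplicative shear-magnitude noise sd (default 0, so
#'   analytic checks are exact).
#' @param seed random seed recorded in the spec and used for any noise.
#' @return an object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(radius = 0.01, length = 0.09,
                           n_circ = 24L, n_axial = 30L,
                           zones = default_zones(),
                           period = 1.0, n_time = 64L,
                           p_mean = 70 * 133.322, p_amp = 20 * 133.322,
                           noise_sd = 0, seed = 1L) {
  stopifnot(n_circ >= 8L, n_axial >= 8L, period > 0, n_time >= 3L,
            noise_sd >= 0)
  fr <- t(vapply(zones, function(z) c(z$frac_lo, z$frac_hi), numeric(2)))
  o <- order(fr[, 1L])
  if (any(fr[o, 1L][-1L] < fr[o, 2L][-nrow(fr)]))
    stop("zones must not overlap")
  if (any(fr[, 1L] >= fr[, 2L])) stop("invalid zone extents")
  structure(list(radius = radius, length = length,
                 n_circ = as.integer(n_circ), n_axial = as.integer(n_axial),
                 zones = zones, period = period, n_time = as.integer(n_time),
                 p_mean = p_mean, p_amp = p_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @rdname synthetic_spec
#' @export
default_zones <- function() {
  list(list(frac_lo = 0,     frac_hi = 1 / 3, type = "healthy_high_shear",
            A = 4,    B = 1),
       list(frac_lo = 1 / 3, frac_hi = 2 / 3, type = "low_oscillatory",
            A = 0.05, B = 0.3),
       list(frac_lo = 2 / 3, frac_hi = 1,     type = "reversing",
            A = 0,    B = 4))
}

zone_of_vertices <- function(spec, mesh) {
  zfrac <- mesh$vertices[, 3L] / spec$length
  id <- rep(NA_integer_, nrow(mesh$vertices))
  for (k in seq_along(spec$zones)) {
    z <- spec$zones[[k]]
    hit <- zfrac >= z$frac_lo &
      (zfrac < z$frac_hi | (z$frac_hi == 1 & zfrac <= 1))
    id[hit] <- k
  }
  if (anyNA(id)) stop("zones do not cover the cylinder axis")
  id
}

zone_waveform <- function(z, phase) {
  h <- if (is.null(z$harmonics)) 1L else as.integer(z$harmonics)
  s <- z$A + z$B * sin(phase)
  if (h > 1L)
    for (k in 2:h) s <- s + (z$B / k^2) * sin(k * phase)
  s
}

#' Generate pulsatile wall fields on a zoned cylinder
#'
#' Builds the cylinder mesh of the spec, labels its vertices by zone
#' (\code{region_id}), and fills in per-vertex shear and pressure time
#' series. Axial-zone shear is directed along the vessel axis with
#' sign-reversing magnitude, spanning the full OSI range with closed-form
#' oracles; a \code{rotating} zone instead carries a constant-magnitude
#' vector rotating in the tangent plane (OSI exactly 0.5). The pressure is
#' spatially uniform, p(t) = p_mean + p_amp sin(2 pi t / T). Generation is
#' deterministic given the spec (including its seed).
#'
#' @param spec a \code{synthetic_spec}.
#' @return a \code{wall_field_series} whose mesh carries the zone labels.
#' @export
make_cylinder_fields <- function(spec) {
  mesh <- mesh_cylinder(spec$radius, spec$length, spec$n_circ, spec$n_axial)
  zid <- zone_of_vertices(spec, mesh)
  mesh$region_id <- zid
  nv <- nrow(mesh$vertices)
  nt <- spec$n_time
  times <- spec$period * (seq_len(nt) - 1L) / nt
  phase <- 2 * pi * times / spec$period
  wss <- array(0, dim = c(nv, nt, 3L))
  theta <- atan2(mesh$vertices[, 2L], mesh$vertices[, 1L])
  for (k in seq_along(spec$zones)) {
    z <- spec$zones[[k]]
    sel <- which(zid == k)
    if (!length(sel)) next
    if (identical(z$type, "rotating")) {
      # constant |tau| = A rotating between axial and circumferential
      for (j in seq_len(nt)) {
        ez <- z$A * sin(phase[j])
        et <- z$A * cos(phase[j])
        wss[sel, j, 1L] <- -sin(theta[sel]) * et
        wss[sel, j, 2L] <-  cos(theta[sel]) * et
        wss[sel, j, 3L] <- ez
      }
    } else {
      s <- zone_waveform(z, phase)
      wss[sel, , 3L] <- matrix(s, nrow = length(sel), ncol = nt,
                               byrow = TRUE)
    }
  }
  if (spec$noise_sd > 0) {
    old <- globalenv()$.Random.seed
    set.seed(spec$seed)
    wss <- wss * (1 + stats::rnorm(length(wss), sd = spec$noise_sd))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  pressure <- matrix(spec$p_mean + spec$p_amp * sin(phase),
                     nrow = nv, ncol = nt, byrow = TRUE)
  wall_field_series(mesh, times, wss, pressure, spec$period)
}

#' Closed-form shear indices for single-harmonic zones
#'
#' For an axial waveform tau(t) = A + B sin(2 pi t/T) the cycle mean of
#' |tau| is A when A >= B, and
#' B (2/pi) (sqrt(1 - c^2) + c asin(c)) with c = A/B otherwise; OSI follows
#' as 0.5 (1 - |A| T / integral |tau| dt) and HOLMES = TAWSS (0.5 - OSI)
#' (= A/2 for A >= 0). Multi-harmonic and rotating zones fall back to a
#' dense 1e5-point trapezoidal quadrature oracle.
#'
#' @param spec a \code{synthetic_spec}.
#' @return data.frame with one row per zone: \code{zone}, \code{type},
#'   \code{tawss}, \code{osi}, \code{holmes}.
#' @export
closed_form_indices <- function(spec) {
  rows <- lapply(seq_along(spec$zones), function(k) {
    z <- spec$zones[[k]]
    if (identical(z$type, "rotating")) {
      tawss <- z$A; osi <- 0.5
    } else if (is.null(z$harmonics) || z$harmonics == 1L) {
      A <- z$A; B <- z$B
      tawss <- if (B == 0 || abs(A) >= B) abs(A) else {
        cc <- abs(A) / B
        B * (2 / pi) * (sqrt(1 - cc^2) + cc * asin(cc))
      }
      osi <- if (tawss > 0) 0.5 * (1 - abs(A) / tawss) else 0
    } else {
      phase <- 2 * pi * seq(0, 1, length.out = 100001L)
      s <- zone_waveform(z, phase)
      m_abs <- quad_mean(phase, abs(s))
      m_sig <- quad_mean(phase, s)
      tawss <- m_abs
      osi <- if (m_abs > 0) 0.5 * (1 - abs(m_sig) / m_abs) else 0
    }
    data.frame(zone = k, type = z$type, tawss = tawss, osi = osi,
               holmes = tawss * (0.5 - osi))
  })
  do.call(rbind, rows)
}

quad_mean <- function(x, y) {
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2) / (x[length(x)] - x[1L])
}

# scalar cascade at one (HOLMES, wall viscosity) point
cascade_lp_at <- function(ssi, mu, params) {
  phi <- leaky_fraction(leaky_cells(mitotic_index(ecsi_from_ssi(ssi))),
                        params$R_cell, params$A_ref)
  lp_leaky(phi, lp_single_lj(params$w, params$l_lj, mu))
}

# dense-quadrature time-average CY wall viscosity of a zone waveform
zone_cy_viscosity <- function(z, rheology) {
  phase <- 2 * pi * seq(0, 1, length.out = 4097L)
  tau <- abs(if (identical(z$type, "rotating")) rep(z$A, length(phase))
             else zone_waveform(z, phase))
  mu <- cy_viscosity(shear_rate_from_wss(tau, rheology), rheology)
  quad_mean(phase, mu)
}

#' Ground-truth atheroprone mask for a synthetic fixture
#'
#' Flags the vertices of the zones that the permeability cascade itself
#' classifies as atheroprone when driven by the zone's analytic HOLMES value
#' and its Carreau-Yasuda wall viscosity: exactly the zones whose analytic
#' HOLMES falls below the level at which Lp,lj crosses the atheroprone
#' threshold. An optional seeded label-flip probability emulates imperfect
#' reference imaging.
#'
#' @param spec a \code{synthetic_spec}.
#' @param params a \code{permeability_params}.
#' @param rheology a \code{rheology_params}.
#' @param flip_prob per-vertex label flip probability (default 0).
#' @param seed seed for the label noise (defaults to the spec seed).
#' @return a \code{wall_mask} with source \code{"reference_explicit"} whose
#'   mesh is the spec's cylinder with zone labels.
#' @export
ground_truth_mask <- function(spec, params = permeability_params(),
                              rheology = rheology_params(),
                              flip_prob = 0, seed = spec$seed) {
  mesh <- mesh_cylinder(spec$radius, spec$length, spec$n_circ, spec$n_axial)
  zid <- zone_of_vertices(spec, mesh)
  mesh$region_id <- zid
  cf <- closed_form_indices(spec)
  prone <- vapply(seq_along(spec$zones), function(k) {
    mu <- zone_cy_viscosity(spec$zones[[k]], rheology)
    cascade_lp_at(cf$holmes[k], mu, params) > params$lp_threshold
  }, logical(1))
  flags <- prone[zid]
  if (flip_prob > 0) {
    old <- globalenv()$.Random.seed
    set.seed(seed)
    flip <- stats::runif(length(flags)) < flip_prob
    flags <- xor(flags, flip)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  wall_mask(mesh, flags, source = "reference_explicit")
}
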