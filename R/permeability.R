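#' Three-pore endothelial permeability parameters
#'
#' Geometry, transport and threshold constants of the endothelial permeability
#' cascade. Leaky-junction geometry defaults to a half-width of 20 nm and a
#' length of 2 um; the external (adventitial-side) pressure defaults to
#' 52.5 mmHg, the diastolic pressure in the descending aorta. The reference
#' unit area for the leaky-cell coverage fraction defaults to 1 mm^2 with an
#' endothelial cell radius of 15 um, which places the healthy-shear
#' leaky-junction conductivity near the normal value of 1.2e-11 m^2 s/kg.
#' Osmotic and normal-junction terms default to zero (pure leaky-junction
#' study mode) so the transmural pressure is the sole driver of volume flux;
#' both are overridable. LDL concentrations are normalized (luminal = 1).
#'
#' @param w leaky-junction half-width [m].
#' @param l_lj leaky-junction length [m].
#' @param R_cell endothelial cell radius [m].
#' @param A_ref reference unit area for the coverage fraction [m^2].
#' @param p_ext external pressure [Pa] (default 52.5 mmHg).
#' @param sigma_d osmotic reflection coefficient (0..1).
#' @param delta_Pi osmotic pressure difference [Pa].
#' @param sigma_f solvent-drag (solute) reflection coefficient (0..1).
#' @param Lp_nj normal-junction hydraulic conductivity [m^2 s/kg].
#' @param P_lj leaky-junction diffusive permeability [m/s].
#' @param c_lum luminal LDL concentration (normalized).
#' @param c_w_end subendothelial LDL concentration (normalized).
#' @param c_ave mean endothelial concentration; carried for completeness of
#'   the solute-flux argument list, unused by the implemented Patlak form.
#' @param vesicle_fraction ratio of vesicular to leaky-junction solute flux.
#' @param lp_threshold atheroprone threshold on Lp,lj [m^2 s/kg].
#' @param jv_normal_range normal transmural volume flux range [m/s].
#' @return an object of class \code{permeability_params}.
#' @export
permeability_params <- function(w = 20e-9, l_lj = 2e-6, R_cell = 15e-6,
                                A_ref = 1e-6, p_ext = 52.5 * 133.322,
                                sigma_d = 0, delta_Pi = 0, sigma_f = 0.44,
                                Lp_nj = 0, P_lj = 2e-9,
                                c_lum = 1, c_w_end = 0.01, c_ave = NA_real_,
                                vesicle_fraction = 0.10,
                                lp_threshold = 1.2e-11,
                                jv_normal_range = c(2e-8, 3e-8)) {
  stopifnot(w > 0, l_lj > 0, R_cell > 0, A_ref > 0, P_lj > 0,
            sigma_d >= 0, sigma_d <= 1, sigma_f >= 0, sigma_f <= 1,
            Lp_nj >= 0, vesicle_fraction >= 0, lp_threshold > 0)
  structure(list(w = w, l_lj = l_lj, R_cell = R_cell, A_ref = A_ref,
                 p_ext = p_ext, sigma_d = sigma_d, delta_Pi = delta_Pi,
                 sigma_f = sigma_f, Lp_nj = Lp_nj, P_lj = P_lj,
                 c_lum = c_lum, c_w_end = c_w_end, c_ave = c_ave,
                 vesicle_fraction = vesicle_fraction,
                 lp_threshold = lp_threshold,
                 jv_normal_range = jv_normal_range),
            class = "permeability_params")
}

#' Endothelial cell shape index from a shear stress index
#'
#' ECSI = 0.380 exp(-0.79 SSI) + 0.225 exp(-0.043 SSI), where the shear
#' stress index SSI is TAWSS or HOLMES [Pa]. ECSI measures endothelial cell
#' roundness (1 = circle, 0 = line); it is 0.605 at zero shear and decays
#' strictly with SSI.
#'
#' @param ssi shear stress index values [Pa], >= 0 (vectorized).
#' @return dimensionless ECSI in (0, 0.605].
#' @export
ecsi_from_ssi <- function(ssi) {
  if (any(ssi < 0)) stop("SSI must be non-negative")
  0.380 * exp(-0.79 * ssi) + 0.225 * exp(-0.043 * ssi)
}

#' Mitotic cell index from cell shape
#'
#' MC = 0.003739 exp(14.75 ECSI): rounder cells (high ECSI) are markedly
#' more often mitotic.
#'
#' @param ecsi cell shape index in [0, 0.605] (vectorized).
#' @return dimensionless mitotic cell index.
#' @export
mitotic_index <- function(ecsi) {
  if (any(ecsi < 0 | ecsi > 0.605 + 1e-9))
    stop("ECSI out of range [0, 0.605]")
  0.003739 * exp(14.75 * ecsi)
}

#' Leaky cell index from the mitotic index
#'
#' LC = 0.307 + 0.805 MC: roughly 80.5 percent of mitotic cells are leaky and
#' these represent about 45.3 percent of all leaky cells, leaving a baseline
#' of non-mitotic leaky cells (the 0.307 intercept).
#'
#' @param mc mitotic cell index, >= 0 (vectorized).
#' @return dimensionless leaky cell index (>= 0.307).
#' @export
leaky_cells <- function(mc) {
  if (any(mc < 0)) stop("MC must be non-negative")
  0.307 + 0.805 * mc
}

#' Fraction of endothelium covered by leaky cells
#'
#' phi = LC * pi * R_cell^2 / A_ref, clipped to [0, 1] with a warning when
#' clipping occurs.
#'
#' @param lc leaky cell index (vectorized).
#' @param R_cell endothelial cell radius [m].
#' @param A_ref reference unit area [m^2].
#' @return coverage fraction in [0, 1].
#' @export
leaky_fraction <- function(lc, R_cell, A_ref) {
  stopifnot(R_cell > 0, A_ref > 0)
  phi <- lc * pi * R_cell^2 / A_ref
  if (any(phi > 1)) {
    warning(sum(phi > 1), " vertex/vertices with leaky coverage > 1; clipped")
    phi <- pmin(phi, 1)
  }
  pmax(phi, 0)
}

#' Hydraulic conductivity of a single leaky junction
#'
#' Lp,slj = w^2 / (3 mu l_lj): Poiseuille slit flow through a junction of
#' half-width w and length l_lj filled with fluid of viscosity mu.
#'
#' @param w half-width [m].
#' @param l_lj junction length [m].
#' @param mu viscosity [Pa.s] (vectorized).
#' @return conductivity [m^2 s/kg].
#' @export
lp_single_lj <- function(w, l_lj, mu) {
  stopifnot(w > 0, l_lj > 0, all(mu > 0))
  w^2 / (3 * mu * l_lj)
}

#' Total leaky-junction hydraulic conductivity
#'
#' Lp,lj = phi * Lp,slj.
#'
#' @param phi leaky coverage fraction (vectorized).
#' @param lp_slj single-junction conductivity [m^2 s/kg] (vectorized).
#' @return conductivity [m^2 s/kg].
#' @export
lp_leaky <- function(phi, lp_slj) {
  if (any(phi < 0) || any(lp_slj < 0)) stop("inputs must be non-negative")
  phi * lp_slj
}

#' Transmural pressure difference across the endothelium
#'
#' dp_end is the luminal driving pressure minus the external pressure. In
#' \code{uniform} mode the luminal pressure is the area-weighted space-and-
#' time mean over the whole surface, applied at every vertex; in
#' \code{local_time_avg} mode it is the per-vertex time average. Non-positive
#' dp_end raises a warning (the inward-flux assumption is violated) but the
#' value is retained.
#'
#' @param series a \code{wall_field_series}.
#' @param mode \code{"uniform"} or \code{"local_time_avg"}.
#' @param p_ext external pressure [Pa].
#' @return a \code{scalar_map} of dp_end [Pa].
#' @export
transmural_pressure <- function(series,
                                mode = c("local_time_avg", "uniform"),
                                p_ext = 52.5 * 133.322) {
  mode <- match.arg(mode)
  ptime <- cycle_integral(series$pressure, series$times, series$period) /
    series$period
  if (mode == "uniform") {
    w <- if (!is.null(series$mesh)) series$mesh$vertex_area
         else rep(1, length(ptime))
    pbar <- sum(w * ptime) / sum(w)
    dp <- rep(pbar, length(ptime)) - p_ext
  } else {
    dp <- ptime - p_ext
  }
  if (any(dp <= 0))
    warning(sum(dp <= 0), " vertex/vertices with dp_end <= 0 ",
            "(inward transmural flux assumption violated); values retained")
  scalar_map(series$mesh, "dp_end", dp, units = "Pa")
}

#' Transmural volume flux (Kedem-Katchalsky)
#'
#' Jv,lj = Lp,lj (dp_end - sigma_d dPi); the normal-junction pathway uses the
#' same driving term with its own conductivity, and Jv = Jv,lj + Jv,nj.
#'
#' @param lp_lj \code{scalar_map} of leaky-junction conductivity.
#' @param dp_end \code{scalar_map} of transmural pressure [Pa].
#' @param params a \code{permeability_params}.
#' @return named list of \code{scalar_map}s \code{jv_lj}, \code{jv_nj},
#'   \code{jv} [m/s].
#' @export
volume_flux <- function(lp_lj, dp_end, params = permeability_params()) {
  if (!same_mesh_or_null(lp_lj$mesh, dp_end$mesh))
    stop("maps must be on the same mesh")
  drive <- dp_end$values - params$sigma_d * params$delta_Pi
  jl <- lp_lj$values * drive
  jn <- params$Lp_nj * drive
  list(jv_lj = scalar_map(lp_lj$mesh, "jv_lj", jl, units = "m/s"),
       jv_nj = scalar_map(lp_lj$mesh, "jv_nj", jn, units = "m/s"),
       jv = scalar_map(lp_lj$mesh, "jv", jl + jn, units = "m/s"))
}

#' Transmural solute (LDL) flux
#'
#' The leaky-junction solute flux follows the Patlak solution of the
#' Kedem-Katchalsky solute equation with modified Peclet number
#' Pe = Jv,lj (1 - sigma_f) / P_lj:
#' Js,lj = Jv,lj (1 - sigma_f) (c_lum - c_w_end e^-Pe) / (1 - e^-Pe).
#' Below |Pe| = 1e-6 the second-order series
#' P_lj (c_lum - c_w_end) + Jv,lj (1 - sigma_f)(c_lum + c_w_end)/2 is used
#' for numerical stability; the two branches agree to O(Pe^2) so the flux is
#' continuous across the switch. The vesicular pathway contributes a fixed
#' fraction of the leaky-junction flux and Js = Js,lj + Js,v.
#'
#' @param jv_lj \code{scalar_map} of leaky-junction volume flux [m/s].
#' @param params a \code{permeability_params} (P_lj must be > 0).
#' @return named list of \code{scalar_map}s \code{js_lj}, \code{js_v},
#'   \code{js} [mol/(m^2 s)] (normalized concentration units).
#' @export
solute_flux <- function(jv_lj, params = permeability_params()) {
  if (params$P_lj <= 0) stop("P_lj must be positive")
  jvp <- jv_lj$values * (1 - params$sigma_f)
  pe <- jvp / params$P_lj
  small <- abs(pe) < 1e-6
  js <- numeric(length(pe))
  cl <- params$c_lum; cw <- params$c_w_end
  js[!small] <- jvp[!small] *
    (cl - cw * exp(-pe[!small])) / (1 - exp(-pe[!small]))
  js[small] <- params$P_lj * (cl - cw) + jvp[small] * (cl + cw) / 2
  jsv <- params$vesicle_fraction * js
  list(js_lj = scalar_map(jv_lj$mesh, "js_lj", js, units = "mol/(m^2.s)"),
       js_v = scalar_map(jv_lj$mesh, "js_v", jsv, units = "mol/(m^2.s)"),
       js = scalar_map(jv_lj$mesh, "js", js + jsv, units = "mol/(m^2.s)"))
}

#' Endothelial permeability cascade
#'
#' The central model of the package: chains the shear stress indices, the
#' wall rheology and the three-pore endothelial transport relations into
#' per-vertex permeability and flux maps. The cascade is
#' SSI -> ECSI -> mitotic cells -> leaky cells -> coverage fraction phi ->
#' Lp,lj = phi w^2/(3 mu l_lj) -> Jv (Kedem-Katchalsky) -> Js (Patlak), with
#' three compared modelling axes: the shear index (TAWSS or HOLMES), the wall
#' viscosity entering Lp,slj (constant plasma or Carreau-Yasuda wall map) and
#' the transmural pressure (uniform or local time average).
#'
#' @param series a \code{wall_field_series}.
#' @param ssi shear stress index driving the cascade: \code{"holmes"} or
#'   \code{"tawss"}.
#' @param viscosity wall viscosity mode: \code{"carreau_yasuda"} or
#'   \code{"plasma"}.
#' @param pressure transmural pressure mode: \code{"local_time_avg"} or
#'   \code{"uniform"}.
#' @param params a \code{permeability_params}.
#' @param rheology a \code{rheology_params}.
#' @return an object of class \code{endoperm}: a list with the option set
#'   (\code{ssi}, \code{viscosity}, \code{pressure}), the shear index maps
#'   (\code{indices}), the wall viscosity map (\code{mu_wall}), every
#'   intermediate map (\code{ecsi}, \code{mc}, \code{lc}, \code{phi},
#'   \code{lp_lj}, \code{dp_end}, \code{jv_lj}, \code{jv_nj}, \code{jv},
#'   \code{js_lj}, \code{js_v}, \code{js}) and the echoed parameter sets.
#' @seealso \code{\link{threshold_mask}}, \code{\link{region_statistics}},
#'   \code{\link{make_cylinder_fields}}
#' @examples
#' spec <- synthetic_spec(n_circ = 12, n_axial = 12)
#' series <- make_cylinder_fields(spec)
#' fit <- endo_permeability(series, ssi = "holmes",
#'                          viscosity = "carreau_yasuda")
#' summary(fit)
#' @export
endo_permeability <- function(series,
                              ssi = c("holmes", "tawss"),
                              viscosity = c("carreau_yasuda", "plasma"),
                              pressure = c("local_time_avg", "uniform"),
                              params = permeability_params(),
                              rheology = rheology_params()) {
  ssi <- match.arg(ssi)
  viscosity <- match.arg(viscosity)
  pressure <- match.arg(pressure)
  idx <- shear_indices(series)
  ssi_map <- idx[[ssi]]
  mu <- wall_viscosity_map(series, mode = viscosity, params = rheology)
  mesh <- series$mesh
  ecsi <- ecsi_from_ssi(ssi_map$values)
  mc <- mitotic_index(ecsi)
  lc <- leaky_cells(mc)
  phi <- leaky_fraction(lc, params$R_cell, params$A_ref)
  lp_slj <- lp_single_lj(params$w, params$l_lj, mu$values)
  lp <- scalar_map(mesh, "lp_lj", lp_leaky(phi, lp_slj),
                   units = "m^2.s/kg")
  dp <- transmural_pressure(series, mode = pressure, p_ext = params$p_ext)
  jv <- volume_flux(lp, dp, params)
  js <- solute_flux(jv$jv_lj, params)
  structure(
    c(list(ssi = ssi, viscosity = viscosity, pressure = pressure,
           mesh = mesh, indices = idx, mu_wall = mu,
           ecsi = scalar_map(mesh, "ecsi", ecsi, units = ""),
           mc = scalar_map(mesh, "mc", mc, units = ""),
           lc = scalar_map(mesh, "lc", lc, units = ""),
           phi = scalar_map(mesh, "phi", phi, units = ""),
           lp_lj = lp, dp_end = dp),
      jv, js,
      list(params = params, rheology = rheology)),
    class = "endoperm")
}

#' @export
print.endoperm <- function(x, ...) {
  cat("Endothelial permeability cascade\n")
  cat("  options: SSI =", x$ssi, "| viscosity =", x$viscosity,
      "| pressure =", x$pressure, "\n")
  cat("  vertices:", length(x$lp_lj$values), "\n")
  cat("  Lp,lj range [m^2.s/kg]:",
      format(range(x$lp_lj$values), digits = 4), "\n")
  frac <- mean(x$lp_lj$values > x$params$lp_threshold)
  cat("  fraction above Lp threshold (", format(x$params$lp_threshold),
      "): ", format(100 * frac, digits = 4), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.endoperm <- function(object, ...) {
  fields <- c("tawss", "osi", "holmes")
  rows <- lapply(fields, function(f) object$indices[[f]]$values)
  names(rows) <- fields
  for (f in c("mu_wall", "ecsi", "phi", "lp_lj", "dp_end", "jv", "js"))
    rows[[f]] <- object[[f]]$values
  tab <- t(vapply(rows, function(v)
    c(min = min(v), median = stats::median(v), mean = mean(v), max = max(v)),
    numeric(4)))
  structure(list(options = c(ssi = object$ssi, viscosity = object$viscosity,
                             pressure = object$pressure),
                 table = tab,
                 pct_above_lp = 100 * mean(object$lp_lj$values >
                                             object$params$lp_threshold),
                 lp_threshold = object$params$lp_threshold),
            class = "summary.endoperm")
}

#' @export
print.summary.endoperm <- function(x, ...) {
  cat("Endothelial permeability cascade summary\n")
  cat("  options:", paste(names(x$options), x$options, sep = " = ",
                          collapse = ", "), "\n\n")
  print(signif(x$table, 4))
  cat("\n  surface fraction with Lp,lj >", format(x$lp_threshold), ":",
      format(x$pct_above_lp, digits = 4), "%\n")
  invisible(x)
}

#' @export
as.data.frame.endoperm <- function(x, ...) {
  df <- data.frame(vertex_id = seq_along(x$lp_lj$values) - 1L)
  for (f in c("tawss", "osi", "holmes", "rrt"))
    df[[f]] <- x$indices[[f]]$values
  for (f in c("mu_wall", "ecsi", "mc", "lc", "phi", "lp_lj", "dp_end",
              "jv_lj", "jv_nj", "jv", "js_lj", "js_v", "js"))
    df[[f]] <- x[[f]]$values
  df
}

#' Plot a permeability cascade field along the vessel axis
#'
#' Scatter of a per-vertex field against the axial (z) coordinate, with the
#' atheroprone Lp threshold drawn when the field is \code{lp_lj}.
#'
#' @param x an \code{endoperm} object with a mesh.
#' @param field name of the field to draw (default \code{"lp_lj"}).
#' @param ... passed to \code{plot}.
#' @export
plot.endoperm <- function(x, field = "lp_lj", ...) {
  if (is.null(x$mesh)) stop("plotting requires a mesh")
  v <- if (field %in% names(x$indices)) x$indices[[field]]$values
       else x[[field]]$values
  z <- x$mesh$vertices[, 3L]
  graphics::plot(z, v, xlab = "axial position z [m]", ylab = field,
                 pch = 16, cex = 0.5, col = "#00000080",
                 log = if (field %in% c("lp_lj", "rrt")) "y" else "", ...)
  if (field == "lp_lj")
    graphics::abline(h = x$params$lp_threshold, col = "red", lty = 2)
  invisible(x)
}
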