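test_that("cell shape index follows the double-exponential shear response", {
  expect_equal(ecsi_from_ssi(0), 0.605)
  expect_equal(ecsi_from_ssi(1),
               0.380 * exp(-0.79) + 0.225 * exp(-0.043))  # ~0.388
  expect_lt(ecsi_from_ssi(100), 1e-2)
  ssi <- seq(0, 10, by = 0.01)
  expect_true(all(diff(ecsi_from_ssi(ssi)) < 0))
  expect_error(ecsi_from_ssi(-0.1), "non-negative")
})

test_that("mitotic and leaky cell relations reproduce worked values", {
  expect_equal(mitotic_index(0), 0.003739)
  expect_equal(mitotic_index(0.605), 0.003739 * exp(14.75 * 0.605))  # ~28.07
  expect_lt(mitotic_index(0.3), mitotic_index(0.4))
  expect_error(mitotic_index(0.7), "range")
  expect_error(mitotic_index(-0.1), "range")
  expect_equal(leaky_cells(0), 0.307)
  expect_equal(leaky_cells(1), 1.112)
  expect_equal(leaky_cells(28.073), 0.307 + 0.805 * 28.073)  # ~22.9
  expect_error(leaky_cells(-1), "non-negative")
})

test_that("leaky coverage fraction is linear below the clip and warns above", {
  phi <- leaky_fraction(0.307, R_cell = 15e-6, A_ref = 1e-6)
  expect_equal(phi, 0.307 * pi * (15e-6)^2 / 1e-6)  # ~2.17e-4
  expect_equal(leaky_fraction(0.614, 15e-6, 1e-6), 2 * phi)
  big_lc <- 1.5 / (pi * (15e-6)^2 / 1e-6)
  expect_warning(phic <- leaky_fraction(big_lc, 15e-6, 1e-6), "clip")
  expect_equal(phic, 1)
})

test_that("single-junction conductivity is the slit-flow expression", {
  lp <- lp_single_lj(w = 20e-9, l_lj = 2e-6, mu = 1e-3)
  expect_equal(lp, (20e-9)^2 / (3 * 1e-3 * 2e-6))  # ~6.67e-8
  expect_equal(lp_single_lj(20e-9, 2e-6, 2e-3), lp / 2)
  expect_equal(lp_single_lj(40e-9, 2e-6, 1e-3), 4 * lp)
  expect_equal(lp_leaky(2.17e-4, lp), 2.17e-4 * lp)
  expect_equal(lp_leaky(0, lp), 0)
})

test_that("transmural pressure modes agree with hand-computed means", {
  mesh <- mesh_cylinder(0.01, 0.05, 8L, 8L)
  nv <- nrow(mesh$vertices)
  nt <- 8L
  times <- (0:(nt - 1)) / nt
  p_ext <- 52.5 * 133.322
  # spatially uniform 70 mmHg: both modes identical, dp = 17.5 mmHg
  p70 <- matrix(70 * 133.322, nv, nt)
  s <- wall_field_series(mesh, times, array(1, c(nv, nt, 3L)), p70, 1)
  dp_u <- transmural_pressure(s, "uniform", p_ext)$values
  dp_l <- transmural_pressure(s, "local_time_avg", p_ext)$values
  expect_equal(dp_u, dp_l)
  expect_equal(dp_u, rep(17.5 * 133.322, nv))  # 2333.135 Pa
  # spatially varying: uniform mode applies the area-weighted mean everywhere
  half <- mesh$vertices[, 3L] < 0.025
  pvar <- matrix(ifelse(half, 60, 80) * 133.322, nv, nt)
  s2 <- wall_field_series(mesh, times, array(1, c(nv, nt, 3L)), pvar, 1)
  pbar <- sum(mesh$vertex_area * pvar[, 1L]) / sum(mesh$vertex_area)
  expect_equal(transmural_pressure(s2, "uniform", p_ext)$values,
               rep(pbar - p_ext, nv))
  expect_equal(transmural_pressure(s2, "local_time_avg", p_ext)$values,
               pvar[, 1L] - p_ext)
  # dp <= 0 warns but retains the value
  s3 <- wall_field_series(mesh, times, array(1, c(nv, nt, 3L)),
                          matrix(1000, nv, nt), 1)
  expect_warning(dp3 <- transmural_pressure(s3, "uniform", p_ext)$values,
                 "dp_end")
  expect_equal(dp3, rep(1000 - p_ext, nv))
})

test_that("volume flux reproduces the normal-range worked example exactly", {
  lp <- scalar_map(NULL, "lp_lj", 1.2e-11, units = "m^2.s/kg")
  dp <- scalar_map(NULL, "dp_end", 17.5 * 133.322, units = "Pa")
  pp <- permeability_params()  # sigma_d dPi = 0, Lp_nj = 0 by default
  jv <- volume_flux(lp, dp, pp)
  expect_equal(jv$jv$values, 1.2e-11 * 17.5 * 133.322)  # ~2.80e-8 m/s
  expect_gte(jv$jv$values, pp$jv_normal_range[1L])
  expect_lte(jv$jv$values, pp$jv_normal_range[2L])
  # osmotic balance nulls the leaky flux
  pp2 <- permeability_params(sigma_d = 1, delta_Pi = 17.5 * 133.322)
  expect_equal(volume_flux(lp, dp, pp2)$jv_lj$values, 0)
  # conservation with a nonzero normal-junction pathway
  pp3 <- permeability_params(Lp_nj = 3e-12)
  jv3 <- volume_flux(lp, dp, pp3)
  expect_identical(jv3$jv$values,
                   jv3$jv_lj$values + jv3$jv_nj$values)
})

test_that("solute flux has the Patlak limits and the 10% vesicle split", {
  pp <- permeability_params()
  mkjv <- function(v) scalar_map(NULL, "jv_lj", v, units = "m/s")
  # pure-diffusion limit
  tiny <- solute_flux(mkjv(1e-18), pp)
  expect_equal(tiny$js_lj$values, pp$P_lj * (pp$c_lum - pp$c_w_end),
               tolerance = 1e-6)
  # convection-dominated limit
  huge <- solute_flux(mkjv(1e-3), pp)
  expect_equal(huge$js_lj$values, 1e-3 * (1 - pp$sigma_f) * pp$c_lum,
               tolerance = 1e-6)
  # vesicular pathway is a fixed fraction of the leaky-junction flux
  jv <- mkjv(10^seq(-10, -6, length.out = 9))
  js <- solute_flux(jv, pp)
  expect_equal(js$js_v$values / js$js_lj$values, rep(0.10, 9))
  expect_identical(js$js$values, js$js_lj$values + js$js_v$values)
  bad <- permeability_params(); bad$P_lj <- 0
  expect_error(solute_flux(jv, bad), "P_lj")
})

test_that("solute flux is continuous across the small-Peclet switch", {
  pp <- permeability_params()
  pe_eps <- 1e-6
  jv_at <- function(pe) pe * pp$P_lj / (1 - pp$sigma_f)
  below <- solute_flux(scalar_map(NULL, "jv", jv_at(pe_eps * (1 - 1e-9)),
                                  units = "m/s"), pp)$js_lj$values
  above <- solute_flux(scalar_map(NULL, "jv", jv_at(pe_eps * (1 + 1e-9)),
                                  units = "m/s"), pp)$js_lj$values
  expect_lt(abs(above - below) / abs(below), 1e-6)
})

test_that("leaky-junction conductivity decreases strictly with the SSI", {
  pp <- permeability_params()
  set.seed(5)
  ssi <- sort(runif(50, 0, 6))
  lp <- vapply(ssi, function(s)
    lp_leaky(leaky_fraction(leaky_cells(mitotic_index(ecsi_from_ssi(s))),
                            pp$R_cell, pp$A_ref),
             lp_single_lj(pp$w, pp$l_lj, 1e-3)),
    numeric(1))
  expect_true(all(diff(lp) < 0))
})

test_that("defaults put healthy and atheroprone shear on opposite sides of the Lp threshold", {
  pp <- permeability_params()
  # healthy SSI ~2.5 Pa with plasma viscosity: within a factor 3 of the
  # normal conductivity 1.2e-11 m^2 s/kg
  lp_healthy <- lp_leaky(
    leaky_fraction(leaky_cells(mitotic_index(ecsi_from_ssi(2.5))),
                   pp$R_cell, pp$A_ref),
    lp_single_lj(pp$w, pp$l_lj, 1e-3))
  expect_gt(lp_healthy, 1.2e-11 / 3)
  expect_lt(lp_healthy, 1.2e-11 * 3)
  # low SSI with CY wall viscosity: above the threshold
  rh <- rheology_params()
  s_low <- single_vertex_series(function(u) rep(0.1, length(u)), nt = 16L)
  mu_low <- wall_viscosity_map(s_low, "carreau_yasuda", rh)$values
  lp_low <- lp_leaky(
    leaky_fraction(leaky_cells(mitotic_index(ecsi_from_ssi(0.1))),
                   pp$R_cell, pp$A_ref),
    lp_single_lj(pp$w, pp$l_lj, mu_low))
  expect_gt(lp_low, pp$lp_threshold)
})

test_that("the assembled cascade honours its cross-variant relations", {
  spec <- synthetic_spec(n_circ = 12L, n_axial = 12L, n_time = 32L)
  series <- make_cylinder_fields(spec)
  fit_h <- endo_permeability(series, ssi = "holmes")
  fit_t <- endo_permeability(series, ssi = "tawss")
  # HOLMES = TAWSS/2 wherever the direction never reverses (OSI = 0)
  sel <- fit_h$indices$osi$values == 0
  expect_true(any(sel))
  expect_equal(fit_h$indices$holmes$values[sel],
               0.5 * fit_t$indices$tawss$values[sel], tolerance = 1e-12)
  # plasma viscosity inflates Lp at low-shear vertices relative to CY
  fit_pl <- endo_permeability(series, ssi = "holmes", viscosity = "plasma")
  low <- fit_h$indices$tawss$values < 0.5
  expect_true(all(fit_pl$lp_lj$values[low] >= fit_h$lp_lj$values[low]))
  # conservation identities hold to machine precision
  expect_identical(fit_h$jv$values,
                   fit_h$jv_lj$values + fit_h$jv_nj$values)
  expect_equal(fit_h$js$values, 1.1 * fit_h$js_lj$values, tolerance = 1e-15)
  # intermediate maps are all retained
  for (f in c("ecsi", "mc", "lc", "phi", "lp_lj", "dp_end", "jv_lj",
              "jv", "js_lj", "js_v", "js"))
    expect_length(fit_h[[f]]$values, nrow(series$mesh$vertices))
})

test_that("the low-oscillatory patch is marked atheroprone by HOLMES+CY only above threshold", {
  spec <- synthetic_spec(n_circ = 12L, n_axial = 12L, n_time = 32L)
  series <- make_cylinder_fields(spec)
  fit <- endo_permeability(series, ssi = "holmes",
                           viscosity = "carreau_yasuda")
  zid <- series$mesh$region_id
  lp <- fit$lp_lj$values
  thr <- fit$params$lp_threshold
  expect_true(all(lp[zid == 1L] < thr))   # healthy high shear stays below
  expect_true(all(lp[zid == 2L] > thr))   # low oscillatory patch above
  expect_true(all(lp[zid == 3L] > thr))   # reversing zone above
})
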