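test_that("threshold masks use strict inequalities and exclude sentinels", {
  hu <- scalar_map(NULL, "hu", c(100, 220, 221, 300), units = "HU")
  m <- threshold_mask(hu, 220, direction = "above", source = "reference_hu")
  expect_identical(m$flags, c(FALSE, FALSE, TRUE, TRUE))
  low <- threshold_mask(scalar_map(NULL, "x", c(1, 2), units = ""), 10,
                        "above")
  expect_false(any(low$flags))
  lp <- scalar_map(NULL, "lp_lj", c(2e-11, 1e-12), units = "m^2.s/kg")
  expect_identical(threshold_mask(lp, 1.2e-11, "above")$flags,
                   c(TRUE, FALSE))
  # sentinel-flagged vertices are excluded and tallied
  sm <- scalar_map(NULL, "rrt", c(5, NaN, 7), units = "1/Pa",
                   flag = c(FALSE, TRUE, FALSE))
  tm <- threshold_mask(sm, 1, "above")
  expect_identical(tm$flags, c(TRUE, FALSE, TRUE))
  expect_identical(tm$n_excluded, 1L)
})

test_that("axial region assignment follows the half-open convention", {
  mesh <- mesh_cylinder(0.01, 3, n_circ = 8L, n_axial = 31L)
  mesh <- assign_regions(mesh, breakpoints = c(0, 1, 2, 3))
  expect_setequal(unique(mesh$region_id), 1:3)
  areas <- vapply(1:3, function(k)
    sum(mesh$vertex_area[mesh$region_id == k]), numeric(1))
  # interior breakpoints land on vertex rings; those rings join the higher
  # region, so region areas differ only by the boundary-ring shares
  expect_equal(max(areas) / min(areas), 1, tolerance = 0.15)
  z <- mesh$vertices[, 3L]
  expect_true(all(mesh$region_id[abs(z - 1) < 1e-12] == 2L))  # at breakpoint
  expect_true(all(mesh$region_id[abs(z - 3) < 1e-12] == 3L))  # far edge kept
  # explicit labels pass through unchanged
  lbl <- rep_len(c(7L, 9L), nrow(mesh$vertices))
  expect_identical(assign_regions(mesh, labels = lbl)$region_id, lbl)
  # out-of-range vertices fall into the overflow region with a warning
  expect_warning(m2 <- assign_regions(mesh, breakpoints = c(1, 2)),
                 "overflow")
  expect_true(any(m2$region_id == 0L))
  expect_error(assign_regions(mesh, breakpoints = c(2, 1)), "increasing")
})

test_that("region statistics reproduce constructed overlap fractions", {
  mesh <- mesh_cylinder(0.01, 1, 8L, 9L)  # 72 vertices, equal areas inside
  nv <- nrow(mesh$vertices)
  ref_flags <- mesh$vertices[, 3L] > 0.5
  ref <- wall_mask(mesh, ref_flags, source = "reference_explicit")
  # identical masks
  same <- wall_mask(mesh, ref_flags, source = "predicted_lp")
  rs <- region_statistics(same, ref, mesh)
  whole <- rs[nrow(rs), ]
  expect_equal(whole$pct_match, 100)
  expect_equal(whole$pct_match_iou, 100)
  expect_equal(whole$pct_area_predicted, whole$pct_area_reference)
  # disjoint masks
  disj <- wall_mask(mesh, !ref_flags, source = "predicted_lp")
  expect_equal(region_statistics(disj, ref, mesh)$pct_match[2L], 0)
  # covering exactly half of the reference area
  zsel <- sort(unique(mesh$vertices[, 3L]))
  upper <- zsel[zsel > 0.5]
  half_flags <- mesh$vertices[, 3L] %in% upper[seq_len(length(upper) / 2)]
  half <- wall_mask(mesh, half_flags, source = "predicted_lp")
  a_ref <- sum(mesh$vertex_area[ref_flags])
  a_half <- sum(mesh$vertex_area[half_flags])
  expect_equal(region_statistics(half, ref, mesh)$pct_match[2L],
               100 * a_half / a_ref)
})

test_that("percent-area is complement-consistent and threshold-monotone", {
  spec <- synthetic_spec(n_circ = 12L, n_axial = 12L, n_time = 16L)
  series <- make_cylinder_fields(spec)
  fit <- endo_permeability(series)
  mesh <- series$mesh
  ref <- ground_truth_mask(spec)
  m <- threshold_mask(fit$lp_lj, fit$params$lp_threshold, "above")
  comp <- wall_mask(mesh, !m$flags, source = "predicted_lp")
  rs_m <- region_statistics(m, ref, mesh)
  rs_c <- region_statistics(comp, ref, mesh)
  expect_equal(rs_m$pct_area_predicted + rs_c$pct_area_predicted,
               rep(100, nrow(rs_m)))
  # raising the threshold never increases the predicted area
  thr <- 10^seq(-12, -10, length.out = 7)
  pa <- vapply(thr, function(t) {
    rs <- region_statistics(threshold_mask(fit$lp_lj, t, "above"), ref, mesh)
    rs$pct_area_predicted[nrow(rs)]
  }, numeric(1))
  expect_true(all(diff(pa) <= 0))
})

test_that("overlap statistics are stable under mesh refinement", {
  pct_match_at <- function(n_circ, n_axial) {
    mesh <- mesh_cylinder(0.01, 1, n_circ, n_axial)
    z <- mesh$vertices[, 3L]
    # thresholds chosen off the vertex rings of both resolutions so the
    # discretized band edges are unambiguous
    pred <- wall_mask(mesh, z > 0.32, source = "predicted_lp")
    ref <- wall_mask(mesh, z > 0.52, source = "reference_explicit")
    rs <- region_statistics(pred, ref, mesh)
    rs$pct_match_iou[nrow(rs)]
  }
  coarse <- pct_match_at(12L, 11L)
  fine <- pct_match_at(24L, 21L)
  analytic <- 100 * 0.48 / 0.68  # band overlap of the fixed pattern
  expect_equal(coarse, analytic, tolerance = 0.1)
  expect_lt(abs(fine - analytic), abs(coarse - analytic) + 1e-9)
})

test_that("reports round-trip through JSON and carry the parameter echo", {
  mesh <- mesh_cylinder(0.01, 1, 8L, 9L)
  flags <- mesh$vertices[, 3L] > 0.5
  pred <- wall_mask(mesh, flags, source = "predicted_lp")
  ref <- wall_mask(mesh, flags, source = "reference_explicit")
  rs <- region_statistics(pred, ref, mesh)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_report(rs, jpath, format = "json",
               params = list(lp_threshold = 1.2e-11),
               config_hash = "deadbeef")
  back <- read_report(jpath)
  expect_equal(back$pct_match, rs$pct_match)
  expect_equal(back$area_total, rs$area_total, tolerance = 1e-12)
  raw <- jsonlite::read_json(jpath)
  expect_equal(raw$params$lp_threshold, 1.2e-11)
  expect_match(raw$provenance, "deadbeef")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_report(rs, cpath, format = "csv", config_hash = "deadbeef")
  lines <- readLines(cpath)
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  expect_equal(nrow(body), nrow(rs))  # regions + whole-surface row
  expect_match(lines[1L], "deadbeef")
})
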