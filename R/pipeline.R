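#' Default pipeline configuration
#'
#' Fully materialized configuration for the synth -> indices -> viscosity ->
#' permeability -> regions pipeline. Every physical parameter carries its
#' unit in the key name or section documentation; unknown keys in a user
#' config are rejected, and the merged (defaults-filled) config is echoed
#' into every report together with its hash, so outputs are self-describing.
#'
#' @return a nested list with sections \code{synth}, \code{indices},
#'   \code{rheology}, \code{permeability} and \code{regions}.
#' @export
default_config <- function() {
  list(
    synth = list(radius_m = 0.01, length_m = 0.09, n_circ = 24L,
                 n_axial = 30L, period_s = 1.0, n_time = 64L,
                 p_mean_pa = 70 * 133.322, p_amp_pa = 20 * 133.322,
                 noise_sd = 0, seed = 1L),
    indices = list(ssi = "holmes"),
    rheology = list(mode = "carreau_yasuda",
                    eta_inf_pas = 2.2e-3, eta_0_pas = 22e-3, lambda_s = 0.11,
                    a = 0.644, n = 0.392, mu_plasma_pas = 1.0e-3,
                    viscosity_eval = "instantaneous_mean"),
    permeability = list(pressure_mode = "local_time_avg",
                        w_m = 20e-9, l_lj_m = 2e-6, R_cell_m = 15e-6,
                        A_ref_m2 = 1e-6, p_ext_pa = 52.5 * 133.322,
                        sigma_d = 0, delta_Pi_pa = 0, sigma_f = 0.44,
                        Lp_nj = 0, P_lj_ms = 2e-9,
                        c_lum = 1, c_w_end = 0.01,
                        vesicle_fraction = 0.10,
                        lp_threshold = 1.2e-11),
    regions = list(breakpoints = NULL, axis = 3L)
  )
}

merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(path, bad, collapse = ", "))
  out <- defaults
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      out[[nm]] <- merge_config(user[[nm]], defaults[[nm]],
                                paste0(path, nm, "."))
    } else out[[nm]] <- user[[nm]]
  }
  out
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML configuration, rejects unknown keys, and fills every missing
#' key from \code{\link{default_config}} so the returned config is fully
#' materialized.
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @return validated config list with attribute \code{"hash"}.
#' @export
read_config <- function(path = NULL) {
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  cfg <- merge_config(user)
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

#' Canonical hash of a configuration
#'
#' 32-bit FNV-1a hash over the canonical deparsed configuration; embedded in
#' every writer's provenance line so outputs can be traced to the exact
#' parameter set.
#'
#' @param cfg a config list.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  canon <- paste(deparse(cfg[order(names(cfg))], control = "exact"),
                 collapse = "")
  bytes <- utf8ToInt(canon)
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256); keeps h a double below 2^32
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime in two 16-bit halves so no
    # intermediate exceeds 2^53
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Translate a config into parameter objects
#'
#' @param cfg a fully materialized config list.
#' @return \code{config_to_params}: list with \code{rheology}
#'   (\code{rheology_params}) and \code{permeability}
#'   (\code{permeability_params}); \code{config_to_spec}: a
#'   \code{synthetic_spec}.
#' @export
config_to_params <- function(cfg) {
  rh <- cfg$rheology; pm <- cfg$permeability
  list(
    rheology = rheology_params(eta_inf = rh$eta_inf_pas,
                               eta_0 = rh$eta_0_pas, lambda = rh$lambda_s,
                               a = rh$a, n = rh$n,
                               mu_plasma = rh$mu_plasma_pas),
    permeability = permeability_params(
      w = pm$w_m, l_lj = pm$l_lj_m, R_cell = pm$R_cell_m,
      A_ref = pm$A_ref_m2, p_ext = pm$p_ext_pa, sigma_d = pm$sigma_d,
      delta_Pi = pm$delta_Pi_pa, sigma_f = pm$sigma_f, Lp_nj = pm$Lp_nj,
      P_lj = pm$P_lj_ms, c_lum = pm$c_lum, c_w_end = pm$c_w_end,
      vesicle_fraction = pm$vesicle_fraction,
      lp_threshold = pm$lp_threshold))
}

#' @rdname config_to_params
#' @export
config_to_spec <- function(cfg) {
  s <- cfg$synth
  synthetic_spec(radius = s$radius_m, length = s$length_m,
                 n_circ = s$n_circ, n_axial = s$n_axial,
                 period = s$period_s, n_time = s$n_time,
                 p_mean = s$p_mean_pa, p_amp = s$p_amp_pa,
                 noise_sd = s$noise_sd, seed = s$seed)
}

#' Run the full pipeline
#'
#' Executes synth (or ingests given fields) -> shear indices -> wall
#' viscosity -> permeability cascade -> atheroprone mask -> region overlap
#' report. Deterministic given (config, seed). When \code{out_dir} is given,
#' intermediate maps, masks and the report are written there with the config
#' hash in every provenance line.
#'
#' @param config a config list from \code{\link{read_config}} /
#'   \code{\link{default_config}}.
#' @param series optional \code{wall_field_series}; when \code{NULL} the
#'   synthetic fixture of the config's \code{synth} section is generated.
#' @param reference optional reference \code{wall_mask}; for synthetic input
#'   the zero-noise ground-truth mask is used by default.
#' @param out_dir optional output directory.
#' @return list with \code{series}, \code{fit} (an \code{endoperm}),
#'   \code{predicted} and \code{reference} masks, \code{report},
#'   \code{config} and \code{config_hash}.
#' @export
run_pipeline <- function(config = default_config(), series = NULL,
                         reference = NULL, out_dir = NULL) {
  config <- merge_config(config)
  hash <- config_hash(config)
  p <- config_to_params(config)
  synthetic <- is.null(series)
  if (synthetic) {
    spec <- config_to_spec(config)
    series <- make_cylinder_fields(spec)
  }
  fit <- endo_permeability(series,
                           ssi = config$indices$ssi,
                           viscosity = config$rheology$mode,
                           pressure = config$permeability$pressure_mode,
                           params = p$permeability, rheology = p$rheology)
  predicted <- threshold_mask(fit$lp_lj, p$permeability$lp_threshold,
                              direction = "above", source = "predicted_lp")
  if (is.null(reference) && synthetic)
    reference <- ground_truth_mask(spec, p$permeability, p$rheology)
  mesh <- series$mesh
  if (!is.null(config$regions$breakpoints))
    mesh <- assign_regions(mesh, breakpoints = config$regions$breakpoints,
                           axis = config$regions$axis)
  report <- if (!is.null(reference))
    region_statistics(predicted, reference, mesh) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_scalar_maps(
      c(fit$indices[c("tawss", "osi", "holmes")],
        list(fit$mu_wall, fit$ecsi, fit$mc, fit$lc, fit$phi, fit$lp_lj,
             fit$dp_end, fit$jv_lj, fit$jv, fit$js_lj, fit$js)),
      file.path(out_dir, "maps.vtk"), format = "vtk-legacy",
      config_hash = hash)
    if (!is.null(report))
      write_report(report, file.path(out_dir, "report.json"),
                   format = "json", params = config, config_hash = hash)
  }
  list(series = series, fit = fit, predicted = predicted,
       reference = reference, report = report, config = config,
       config_hash = hash)
}

#' Compare model variants on one data set
#'
#' Runs the permeability cascade once per variant of
#' \{shear index\} x \{viscosity mode\} x \{pressure mode\} and scores each
#' predicted atheroprone mask against the reference. Variants are ranked by
#' the whole-surface intersection-over-union match (tiebreak: overlap-over-
#' reference match); the overlap-over-reference score saturates at 100 for
#' any variant that over-predicts the whole surface, so IoU is the
#' discriminating column.
#'
#' @param series a \code{wall_field_series}.
#' @param reference a reference \code{wall_mask}.
#' @param variants list of lists with elements \code{ssi},
#'   \code{viscosity}, \code{pressure} (>= 2 after deduplication is not
#'   required, but duplicates are collapsed with a warning). Default: the
#'   full 2 x 2 x 2 matrix.
#' @param params a \code{permeability_params}.
#' @param rheology a \code{rheology_params}.
#' @return data.frame with one row per variant (\code{ssi},
#'   \code{viscosity}, \code{pressure}, \code{pct_area_predicted},
#'   \code{pct_match}, \code{pct_match_iou}, \code{rank}), ordered by rank.
#' @export
compare_variants <- function(series, reference,
                             variants = full_variant_matrix(),
                             params = permeability_params(),
                             rheology = rheology_params()) {
  key <- vapply(variants, function(v)
    paste(v$ssi, v$viscosity, v$pressure, sep = "|"), "")
  if (anyDuplicated(key)) {
    warning("duplicate variant(s) collapsed")
    variants <- variants[!duplicated(key)]
  }
  rows <- lapply(variants, function(v) {
    fit <- endo_permeability(series, ssi = v$ssi, viscosity = v$viscosity,
                             pressure = v$pressure, params = params,
                             rheology = rheology)
    pred <- threshold_mask(fit$lp_lj, params$lp_threshold,
                           direction = "above", source = "predicted_lp")
    rs <- region_statistics(pred, reference, series$mesh)
    whole <- rs[nrow(rs), ]
    data.frame(ssi = v$ssi, viscosity = v$viscosity, pressure = v$pressure,
               pct_area_predicted = whole$pct_area_predicted,
               pct_match = whole$pct_match,
               pct_match_iou = whole$pct_match_iou)
  })
  tab <- do.call(rbind, rows)
  o <- order(-tab$pct_match_iou, -tab$pct_match)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

#' @rdname compare_variants
#' @export
full_variant_matrix <- function() {
  g <- expand.grid(ssi = c("tawss", "holmes"),
                   viscosity = c("plasma", "carreau_yasuda"),
                   pressure = c("uniform", "local_time_avg"),
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
}
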