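#' Per-vertex boolean wall mask
#'
#' @param mesh a \code{surface_mesh} (or \code{NULL}).
#' @param flags logical vector, one flag per vertex.
#' @param source provenance of the mask: \code{"predicted_lp"},
#'   \code{"predicted_jv"}, \code{"reference_hu"} or
#'   \code{"reference_explicit"}.
#' @param n_excluded number of sentinel vertices excluded during
#'   thresholding (forced to \code{FALSE}).
#' @return an object of class \code{wall_mask}.
#' @export
wall_mask <- function(mesh, flags, source = c("predicted_lp", "predicted_jv",
                                              "reference_hu",
                                              "reference_explicit"),
                      n_excluded = 0L) {
  source <- match.arg(source)
  flags <- as.logical(flags)
  if (!is.null(mesh) && length(flags) != nrow(mesh$vertices))
    stop("need one flag per vertex")
  structure(list(mesh = mesh, flags = flags, source = source,
                 n_excluded = as.integer(n_excluded)),
            class = "wall_mask")
}

#' @export
print.wall_mask <- function(x, ...) {
  cat("wall_mask (", x$source, "): ", sum(x$flags), "/", length(x$flags),
      " vertices flagged", sep = "")
  if (x$n_excluded > 0L) cat(" (", x$n_excluded, " excluded)", sep = "")
  cat("\n")
  invisible(x)
}

#' Threshold a scalar map into a wall mask
#'
#' Classifies vertices by comparing map values against a threshold; the
#' atheroprone criteria are strict inequalities (Lp,lj > 1.2e-11 m^2 s/kg,
#' HU > 220). Sentinel-flagged vertices are excluded: their flag is FALSE
#' and they are counted in \code{n_excluded}.
#'
#' @param map a \code{scalar_map}.
#' @param threshold threshold value, in the map's units.
#' @param direction \code{"above"} or \code{"below"}.
#' @param strict use strict inequality (default TRUE).
#' @param source mask provenance label (see \code{\link{wall_mask}}).
#' @return a \code{wall_mask}.
#' @export
threshold_mask <- function(map, threshold, direction = c("above", "below"),
                           strict = TRUE, source = "predicted_lp") {
  direction <- match.arg(direction)
  v <- map$values
  fl <- switch(direction,
               above = if (strict) v > threshold else v >= threshold,
               below = if (strict) v < threshold else v <= threshold)
  excl <- if (is.null(map$flag)) !is.finite(v) else (map$flag | !is.finite(v))
  fl[excl] <- FALSE
  wall_mask(map$mesh, fl, source = source, n_excluded = sum(excl))
}

#' Assign subsection labels to mesh vertices
#'
#' Either cuts the mesh into axial subsections at strictly increasing
#' breakpoints along a coordinate axis (half-open convention [low, high):
#' a vertex exactly at an internal breakpoint joins the higher region), or
#' passes explicit per-vertex labels through. Vertices outside all axial
#' ranges are assigned the overflow region 0 with a warning.
#'
#' @param mesh a \code{surface_mesh}.
#' @param breakpoints strictly increasing axial cut positions (length k+1 for
#'   k regions), or \code{NULL} when \code{labels} is given.
#' @param axis coordinate axis index for breakpoints (1 = x, 2 = y, 3 = z).
#' @param labels explicit per-vertex integer labels, or \code{NULL}.
#' @return the mesh with \code{region_id} set (regions 1..k; 0 = overflow).
#' @export
assign_regions <- function(mesh, breakpoints = NULL, axis = 3L,
                           labels = NULL) {
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(mesh$vertices))
      stop("labels must cover every vertex")
    mesh$region_id <- labels
    return(mesh)
  }
  if (is.null(breakpoints) || any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  x <- mesh$vertices[, axis]
  # half-open [low, high); the final breakpoint is inclusive so the far edge
  # of the last region is not orphaned
  id <- findInterval(x, breakpoints, rightmost.closed = TRUE,
                     left.open = FALSE)
  out <- id < 1L | id > length(breakpoints) - 1L
  if (any(out)) {
    warning(sum(out), " vertex/vertices outside all regions; ",
            "assigned overflow region 0")
    id[out] <- 0L
  }
  mesh$region_id <- as.integer(id)
  mesh
}

#' Region-level overlap statistics of predicted vs reference masks
#'
#' For each subsection of the mesh, computes area-weighted percentages using
#' the per-vertex area weights: the percent of region area flagged by the
#' prediction, the percent flagged by the reference, the percentage match
#' (predicted-and-reference area over reference area; \code{NA} when the
#' region holds no reference area) and the intersection-over-union percentage
#' \code{pct_match_iou}. The overlap-over-reference match saturates at 100
#' for any prediction covering the reference, so the IoU column is the
#' discriminating score when a variant over-predicts. A whole-surface row
#' with \code{region_id = NA} is appended.
#'
#' @param predicted a \code{wall_mask} (model prediction).
#' @param reference a \code{wall_mask} (e.g. thresholded Hounsfield units).
#' @param mesh a \code{surface_mesh} with \code{region_id} set; defaults to
#'   the predicted mask's mesh.
#' @return a \code{region_report}: a data.frame with columns
#'   \code{region_id}, \code{area_total} [m^2], \code{pct_area_predicted},
#'   \code{pct_area_reference}, \code{pct_match}, \code{pct_match_iou}.
#' @export
region_statistics <- function(predicted, reference, mesh = predicted$mesh) {
  if (!same_mesh_or_null(predicted$mesh, reference$mesh))
    stop("masks must be on the same mesh")
  if (is.null(mesh)) stop("a mesh with vertex areas is required")
  if (is.null(mesh$region_id))
    mesh$region_id <- rep(1L, nrow(mesh$vertices))
  va <- mesh$vertex_area
  p <- predicted$flags; r <- reference$flags
  one <- function(sel) {
    at <- sum(va[sel])
    ap <- sum(va[sel & p]); ar <- sum(va[sel & r])
    ai <- sum(va[sel & p & r]); au <- sum(va[sel & (p | r)])
    c(area_total = at,
      pct_area_predicted = 100 * ap / at,
      pct_area_reference = 100 * ar / at,
      pct_match = if (ar > 0) 100 * ai / ar else NA_real_,
      pct_match_iou = if (au > 0) 100 * ai / au else NA_real_)
  }
  ids <- sort(unique(mesh$region_id))
  rows <- t(vapply(ids, function(id) one(mesh$region_id == id), numeric(5)))
  rows <- rbind(rows, one(rep(TRUE, length(va))))
  rep_df <- data.frame(region_id = c(ids, NA_integer_), rows)
  class(rep_df) <- c("region_report", "data.frame")
  rep_df
}

#' @export
print.region_report <- function(x, ...) {
  cat("Region overlap report (last row = whole surface)\n")
  y <- x; class(y) <- "data.frame"
  print(format(y, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Serialize a region report
#'
#' Writes the report with units and the full parameter echo so it is
#' self-describing. CSV output holds one row per region plus the
#' whole-surface summary row; JSON output nests the report rows under
#' \code{report} with the parameter echo under \code{params}.
#'
#' @param report a \code{region_report}.
#' @param path output file.
#' @param format \code{"csv"} or \code{"json"}.
#' @param params optional parameter list echoed into the output.
#' @param config_hash provenance hash to embed.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json"),
                         params = NULL, config_hash = "none") {
  format <- match.arg(format)
  df <- as.data.frame(report)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", provenance_line(config_hash)), con)
    writeLines("# units: area_total=m^2; pct_*=percent", con)
    if (!is.null(params))
      writeLines(paste0("# params: ",
                        jsonlite::toJSON(params, auto_unbox = TRUE,
                                         digits = NA)), con)
    utils::write.csv(df, con, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(provenance = provenance_line(config_hash),
           units = list(area_total = "m^2", percentages = "percent"),
           params = params, report = df),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read back a JSON region report
#' @param path file written by \code{write_report(..., format = "json")}.
#' @return a \code{region_report}.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep_df <- as.data.frame(obj$report)
  class(rep_df) <- c("region_report", "data.frame")
  rep_df
}
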