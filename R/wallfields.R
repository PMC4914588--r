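#' Time-resolved wall fields on a surface mesh
#'
#' Bundles per-vertex wall shear stress vectors and pressures sampled over one
#' cardiac cycle. Samples follow the periodic convention: \code{times[1] == 0},
#' \code{times[length(times)] < period}, and the sample at \code{t = period}
#' is the sample at \code{t = 0}.
#'
#' @param mesh a \code{surface_mesh}, or \code{NULL} for fields-only series
#'   (tabular data without geometry); operations needing area weights require
#'   a mesh.
#' @param times strictly increasing sample instants [s], \code{times[1] == 0}.
#' @param wss numeric array \code{n_vertex x n_time x 3} of wall shear stress
#'   vectors [Pa].
#' @param pressure numeric matrix \code{n_vertex x n_time} [Pa].
#' @param period cycle duration T [s].
#' @return an object of class \code{wall_field_series}.
#' @export
wall_field_series <- function(mesh, times, wss, pressure, period) {
  times <- as.numeric(times)
  nt <- length(times)
  if (nt < 3L) stop("need at least 3 time samples")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (times[1L] != 0) stop("times must start at 0 (periodic convention)")
  if (times[nt] >= period)
    stop("last sample must lie strictly before the period T")
  wss <- as_wss_array(wss, nt)
  nv <- dim(wss)[1L]
  pressure <- as.matrix(pressure)
  if (!all(dim(pressure) == c(nv, nt)))
    stop("pressure must be n_vertex x n_time, matching wss")
  if (!all(is.finite(wss))) stop("non-finite WSS values")
  if (!all(is.finite(pressure))) stop("non-finite pressure values")
  if (!is.null(mesh)) {
    if (!inherits(mesh, "surface_mesh")) stop("mesh must be a surface_mesh")
    if (nrow(mesh$vertices) != nv)
      stop("field arrays have ", nv, " vertices but mesh has ",
           nrow(mesh$vertices))
  }
  structure(list(mesh = mesh, times = times, wss = wss, pressure = pressure,
                 period = as.numeric(period)),
            class = "wall_field_series")
}

as_wss_array <- function(wss, nt) {
  if (is.matrix(wss) && ncol(wss) == 3L) # single vertex convenience
    wss <- array(wss, dim = c(1L, nrow(wss), 3L),
                 dimnames = NULL)[, seq_len(nrow(wss)), , drop = FALSE]
  if (length(dim(wss)) != 3L || dim(wss)[3L] != 3L)
    stop("wss must be an n_vertex x n_time x 3 array")
  if (dim(wss)[2L] != nt) stop("wss time dimension must match times")
  storage.mode(wss) <- "double"
  wss
}

#' @export
print.wall_field_series <- function(x, ...) {
  cat("wall_field_series:", dim(x$wss)[1L], "vertices,",
      length(x$times), "time samples over T =", x$period, "s\n")
  tm <- tawss_values(x)
  cat("  TAWSS range [Pa]:", format(range(tm), digits = 4), "\n")
  invisible(x)
}

#' Per-vertex scalar field on a mesh
#'
#' @param mesh a \code{surface_mesh} (or \code{NULL} for fields-only data).
#' @param name field identifier.
#' @param values one scalar per vertex.
#' @param units unit string (use "" for dimensionless).
#' @param flag optional logical vector marking sentinel vertices to exclude
#'   from statistics (e.g. indeterminate OSI at zero shear).
#' @return an object of class \code{scalar_map}.
#' @export
scalar_map <- function(mesh, name, values, units, flag = NULL) {
  values <- as.numeric(values)
  if (!is.null(mesh) && length(values) != nrow(mesh$vertices))
    stop("need one value per vertex")
  if (missing(units)) stop("units must be declared")
  if (!is.null(flag)) {
    flag <- as.logical(flag)
    if (length(flag) != length(values)) stop("flag length mismatch")
  }
  structure(list(mesh = mesh, name = as.character(name), values = values,
                 units = units, flag = flag),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  ok <- if (is.null(x$flag)) x$values else x$values[!x$flag]
  cat("scalar_map '", x$name, "' [", x$units, "]: ", length(x$values),
      " vertices", sep = "")
  if (!is.null(x$flag) && any(x$flag))
    cat(" (", sum(x$flag), " flagged)", sep = "")
  cat("\n  range:", format(range(ok), digits = 5), "\n")
  invisible(x)
}

MMHG_PA <- 133.322  # Pa per mmHg

provenance_line <- function(config_hash = "none") {
  paste0("endoperm ",
         as.character(utils::packageVersion("endoperm")),
         " config=", config_hash)
}

## ---------------------------------------------------------------- tabular IO

#' Read time-resolved wall fields
#'
#' Two dialects are supported. \code{tabular}: UTF-8 CSV with comment lines
#' (\code{# period: T}, optional \code{# pressure_unit: mmHg}) and columns
#' \code{vertex_id} (0-based), \code{t}, \code{wss_x}, \code{wss_y},
#' \code{wss_z}, \code{pressure}. \code{vtk-legacy}: ASCII POLYDATA with
#' per-timestep POINT_DATA arrays \code{wss_<k>} (vectors) and
#' \code{pressure_<k>} (scalars) plus FIELD metadata \code{times} and
#' \code{period}. Pressures declared in mmHg are converted to Pa on read
#' (133.322 Pa/mmHg); internal storage is always SI.
#'
#' @param path file to read.
#' @param format \code{"vtk-legacy"} or \code{"tabular"}.
#' @param mesh optional \code{surface_mesh} to attach to a tabular series.
#' @return a validated \code{wall_field_series}.
#' @export
read_wall_fields <- function(path, format = c("vtk-legacy", "tabular"),
                             mesh = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tabular") read_wall_fields_tab(path, mesh)
  else read_wall_fields_vtk(path)
}

read_wall_fields_tab <- function(path, mesh) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  period <- header_value(hdr, "period")
  if (is.na(period)) stop("format error: missing '# period:' header key")
  unit <- header_string(hdr, "pressure_unit")
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  need <- c("vertex_id", "t", "wss_x", "wss_y", "wss_z", "pressure")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  times <- sort(unique(dat$t))
  vids <- sort(unique(as.integer(dat$vertex_id)))
  nv <- length(vids); nt <- length(times)
  if (nrow(dat) != nv * nt || !identical(vids, 0:(nv - 1L)))
    stop("consistency error: vertex/time grid is not complete")
  per_t <- table(dat$t)
  if (length(unique(per_t)) != 1L)
    stop("consistency error: non-uniform vertex count across timesteps")
  o <- order(dat$t, dat$vertex_id)
  dat <- dat[o, ]
  wss <- array(0, dim = c(nv, nt, 3L))
  wss[, , 1L] <- matrix(dat$wss_x, nv, nt)
  wss[, , 2L] <- matrix(dat$wss_y, nv, nt)
  wss[, , 3L] <- matrix(dat$wss_z, nv, nt)
  p <- matrix(dat$pressure, nv, nt)
  if (identical(unit, "mmHg")) p <- p * MMHG_PA
  wall_field_series(mesh, times, wss, p, period)
}

header_value <- function(hdr, key) {
  ln <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
  if (!length(ln)) return(NA_real_)
  as.numeric(sub(paste0("^#\\s*", key, "\\s*:\\s*"), "", ln[1L]))
}
header_string <- function(hdr, key) {
  ln <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
  if (!length(ln)) return(NA_character_)
  trimws(sub(paste0("^#\\s*", key, "\\s*:\\s*"), "", ln[1L]))
}

#' Write time-resolved wall fields
#'
#' Inverse of \code{\link{read_wall_fields}}; emits a provenance comment line
#' (tool version, config hash) in both dialects.
#'
#' @param series a \code{wall_field_series}.
#' @param path output file.
#' @param format \code{"vtk-legacy"} or \code{"tabular"}.
#' @param config_hash provenance hash to embed.
#' @return \code{path}, invisibly.
#' @export
write_wall_fields <- function(series, path,
                              format = c("vtk-legacy", "tabular"),
                              config_hash = "none") {
  format <- match.arg(format)
  if (format == "tabular") {
    nv <- dim(series$wss)[1L]; nt <- length(series$times)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# ", provenance_line(config_hash)),
                 "# vertex indexing: 0-based",
                 paste0("# period: ", format(series$period, digits = 17)),
                 "# pressure_unit: Pa",
                 "vertex_id,t,wss_x,wss_y,wss_z,pressure"), con)
    df <- data.frame(
      vertex_id = rep(0:(nv - 1L), times = nt),
      t = rep(series$times, each = nv),
      wss_x = as.vector(series$wss[, , 1L]),
      wss_y = as.vector(series$wss[, , 2L]),
      wss_z = as.vector(series$wss[, , 3L]),
      pressure = as.vector(series$pressure))
    utils::write.table(format(df, digits = 17, scientific = TRUE,
                              trim = TRUE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    if (is.null(series$mesh))
      stop("vtk-legacy output requires a mesh")
    write_vtk(series$mesh, path, config_hash,
              series = series)
  }
  invisible(path)
}

## ------------------------------------------------------------ vtk-legacy IO

fmt_num <- function(x) formatC(x, digits = 12, format = "g")

write_vtk <- function(mesh, path, config_hash = "none", series = NULL,
                      maps = NULL, masks = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w(provenance_line(config_hash))
  w("ASCII")
  if (!is.null(series)) {
    nt <- length(series$times)
    w("FIELD FieldData 2")
    w("times ", nt, " 1 double")
    w(paste(fmt_num(series$times), collapse = " "))
    w("period 1 1 double")
    w(fmt_num(series$period))
  }
  w("DATASET POLYDATA")
  nv <- nrow(mesh$vertices)
  w("POINTS ", nv, " double")
  writeLines(apply(mesh$vertices, 1L,
                   function(r) paste(fmt_num(r), collapse = " ")), con)
  nf <- nrow(mesh$faces)
  w("POLYGONS ", nf, " ", 4L * nf)
  writeLines(paste(3L, mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]),
             con)
  w("POINT_DATA ", nv)
  if (!is.null(series)) {
    for (k in seq_along(series$times)) {
      w("SCALARS pressure_", k - 1L, " double 1")
      w("LOOKUP_TABLE default")
      writeLines(fmt_num(series$pressure[, k]), con)
      w("VECTORS wss_", k - 1L, " double")
      writeLines(apply(series$wss[, k, , drop = FALSE], 1L,
                       function(r) paste(fmt_num(r), collapse = " ")), con)
    }
  }
  for (m in maps) {
    w("SCALARS ", m$name, " double 1")
    w("LOOKUP_TABLE default")
    writeLines(fmt_num(m$values), con)
  }
  for (m in masks) {
    w("SCALARS ", m$name, " int 1")
    w("LOOKUP_TABLE default")
    writeLines(as.character(as.integer(m$values)), con)
  }
  if (!is.null(mesh$region_id)) {
    w("SCALARS region_id int 1")
    w("LOOKUP_TABLE default")
    writeLines(as.character(mesh$region_id), con)
  }
  invisible(path)
}

parse_vtk <- function(path) {
  lines <- readLines(path)
  toks <- function(i) strsplit(trimws(lines[i]), "\\s+")[[1L]]
  i <- 1L; n <- length(lines)
  out <- list(field = list(), scalars = list(), vectors = list())
  read_block <- function(start, count, per_line) {
    vals <- scan(text = paste(lines[start:n], collapse = "\n"),
                 n = count * per_line, quiet = TRUE)
    list(vals = vals,
         consumed = count_lines_for(start, count * per_line))
  }
  count_lines_for <- function(start, nvals) {
    got <- 0L; j <- start
    while (got < nvals) {
      got <- got + length(strsplit(trimws(lines[j]), "\\s+")[[1L]])
      j <- j + 1L
    }
    j - start
  }
  while (i <= n) {
    t <- toks(i)
    if (!length(t)) { i <- i + 1L; next }
    key <- toupper(t[1L])
    if (key == "FIELD") {
      narr <- as.integer(t[3L]); i <- i + 1L
      for (a in seq_len(narr)) {
        ft <- toks(i)
        cnt <- as.integer(ft[2L]) * as.integer(ft[3L])
        b <- read_block(i + 1L, cnt, 1L)
        out$field[[ft[1L]]] <- b$vals
        i <- i + 1L + b$consumed
      }
    } else if (key == "POINTS") {
      np <- as.integer(t[2L])
      b <- read_block(i + 1L, np, 3L)
      out$points <- matrix(b$vals, ncol = 3L, byrow = TRUE)
      i <- i + 1L + b$consumed
    } else if (key == "POLYGONS") {
      nf <- as.integer(t[2L])
      b <- read_block(i + 1L, as.integer(t[3L]), 1L)
      m <- matrix(b$vals, ncol = 4L, byrow = TRUE)
      if (any(m[, 1L] != 3L)) stop("only triangle polygons supported")
      out$faces <- m[, 2:4, drop = FALSE]
      i <- i + 1L + b$consumed
    } else if (key == "SCALARS") {
      nm <- t[2L]
      i <- i + 1L
      if (toupper(toks(i)[1L]) == "LOOKUP_TABLE") i <- i + 1L
      b <- read_block(i, out$npoints, 1L)
      out$scalars[[nm]] <- b$vals
      i <- i + b$consumed
    } else if (key == "VECTORS") {
      nm <- t[2L]
      b <- read_block(i + 1L, out$npoints, 3L)
      out$vectors[[nm]] <- matrix(b$vals, ncol = 3L, byrow = TRUE)
      i <- i + 1L + b$consumed
    } else if (key == "POINT_DATA") {
      out$npoints <- as.integer(t[2L])
      i <- i + 1L
    } else i <- i + 1L
  }
  out$title <- if (n >= 2L) lines[2L] else ""
  out
}

read_wall_fields_vtk <- function(path) {
  p <- parse_vtk(path)
  if (is.null(p$field$times))
    stop("format error: missing FIELD metadata key 'times'")
  if (is.null(p$field$period))
    stop("format error: missing FIELD metadata key 'period'")
  times <- p$field$times
  nt <- length(times)
  nv <- nrow(p$points)
  region <- if (!is.null(p$scalars$region_id))
    as.integer(p$scalars$region_id) else NULL
  mesh <- surface_mesh(p$points, p$faces, region_id = region)
  wss <- array(0, dim = c(nv, nt, 3L))
  press <- matrix(0, nv, nt)
  for (k in seq_len(nt)) {
    wk <- paste0("wss_", k - 1L); pk <- paste0("pressure_", k - 1L)
    if (is.null(p$vectors[[wk]]))
      stop("format error: missing POINT_DATA array '", wk, "'")
    if (is.null(p$scalars[[pk]]))
      stop("format error: missing POINT_DATA array '", pk, "'")
    if (nrow(p$vectors[[wk]]) != nv || length(p$scalars[[pk]]) != nv)
      stop("consistency error: non-uniform vertex count across timesteps")
    wss[, k, ] <- p$vectors[[wk]]
    press[, k] <- p$scalars[[pk]]
  }
  if (grepl("pressure_unit=mmHg", p$title, fixed = TRUE))
    press <- press * MMHG_PA
  wall_field_series(mesh, times, wss, press, p$field$period)
}

## ------------------------------------------------------------ scalar map IO

#' Write scalar maps to disk
#'
#' Writes one named array per map. All maps must share one mesh. The
#' vtk-legacy output carries the mesh and one double POINT_DATA array per
#' map; the csv output holds one column per map keyed by 0-based vertex_id.
#'
#' @param maps a list of \code{scalar_map}s (or a single map).
#' @param path output file.
#' @param format \code{"vtk-legacy"} or \code{"csv"}.
#' @param config_hash provenance hash to embed.
#' @return \code{path}, invisibly.
#' @export
write_scalar_maps <- function(maps, path, format = c("vtk-legacy", "csv"),
                              config_hash = "none") {
  format <- match.arg(format)
  if (inherits(maps, "scalar_map")) maps <- list(maps)
  mesh <- maps[[1L]]$mesh
  for (m in maps)
    if (!same_mesh_or_null(mesh, m$mesh))
      stop("consistency error: maps are on different meshes")
  if (format == "vtk-legacy") {
    if (is.null(mesh)) stop("vtk-legacy output requires maps with a mesh")
    write_vtk(mesh, path, config_hash, maps = maps)
  } else {
    df <- data.frame(vertex_id = seq_along(maps[[1L]]$values) - 1L)
    for (m in maps) df[[m$name]] <- m$values
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# ", provenance_line(config_hash)),
                 paste0("# units: ",
                        paste(vapply(maps, function(m)
                          paste0(m$name, "=", m$units), ""),
                          collapse = "; "))), con)
    utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

same_mesh_or_null <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  same_mesh(a, b)
}

#' Read scalar maps written by \code{write_scalar_maps}
#'
#' @param path file to read.
#' @param format \code{"vtk-legacy"} or \code{"csv"}.
#' @param mesh optional mesh to attach to csv maps.
#' @return a named list of \code{scalar_map}s.
#' @export
read_scalar_maps <- function(path, format = c("vtk-legacy", "csv"),
                             mesh = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    lines <- readLines(path)
    dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
    nms <- setdiff(names(dat), "vertex_id")
    out <- lapply(nms, function(nm)
      scalar_map(mesh, nm, dat[[nm]], units = ""))
  } else {
    p <- parse_vtk(path)
    region <- if (!is.null(p$scalars$region_id))
      as.integer(p$scalars$region_id) else NULL
    msh <- surface_mesh(p$points, p$faces, region_id = region)
    nms <- setdiff(names(p$scalars), "region_id")
    out <- lapply(nms, function(nm)
      scalar_map(msh, nm, p$scalars[[nm]], units = ""))
  }
  names(out) <- vapply(out, function(m) m$name, "")
  out
}
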