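#' Triangulated vessel surface mesh
#'
#' Constructs and validates a triangulated surface mesh, the geometric carrier
#' for all per-vertex wall fields. Vertex indexing is 0-based everywhere
#' (including on-disk tabular files); faces are stored as an integer matrix of
#' 0-based vertex triples.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates [m].
#' @param faces integer m x 3 matrix of 0-based triangle vertex indices.
#' @param region_id optional integer vector, one subsection label per vertex.
#' @return An object of class \code{surface_mesh} with components
#'   \code{vertices}, \code{faces}, \code{vertex_area} [m^2] and
#'   \code{region_id} (or \code{NULL}).
#' @details Per-vertex area weights are computed on construction with the
#'   one-third triangle rule (each triangle's area split equally between its
#'   three corners), so that \code{sum(vertex_area)} equals the total surface
#'   area in the same summation order.
#' @export
surface_mesh <- function(vertices, faces, region_id = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix of vertex triples")
  nv <- nrow(vertices)
  if (any(faces < 0L) || any(faces >= nv))
    stop("face indices out of range [0, ", nv - 1L, "]")
  if (!all((seq_len(nv) - 1L) %in% as.vector(faces)))
    stop("every vertex must be referenced by at least one face")
  if (!is.null(region_id)) {
    region_id <- as.integer(region_id)
    if (length(region_id) != nv) stop("region_id must have one label per vertex")
  }
  mesh <- structure(
    list(vertices = vertices, faces = faces, vertex_area = NULL,
         region_id = region_id),
    class = "surface_mesh")
  mesh$vertex_area <- compute_vertex_areas(mesh)
  mesh
}

#' Per-vertex area weights (one-third triangle rule)
#'
#' Splits each triangle's area equally between its three corner vertices.
#' Degenerate (zero-area) triangles contribute nothing and raise a warning.
#'
#' @param mesh a \code{surface_mesh} (vertex_area may be unset).
#' @return numeric vector of per-vertex areas [m^2]; the sum equals the total
#'   triangle area in the same summation order.
#' @export
compute_vertex_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces + 1L
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cx <- a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L]
  cy <- a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L]
  cz <- a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  tri_area <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  if (any(tri_area == 0))
    warning(sum(tri_area == 0), " degenerate zero-area triangle(s); ",
            "they contribute no vertex area")
  va <- numeric(nrow(v))
  third <- tri_area / 3
  for (k in 1:3) {
    acc <- vapply(split(third, f[, k]), sum, numeric(1))
    idx <- as.integer(names(acc))
    va[idx] <- va[idx] + acc
  }
  va
}

#' Total surface area of a mesh
#' @param mesh a \code{surface_mesh}.
#' @return total area [m^2].
#' @export
mesh_area <- function(mesh) sum(mesh$vertex_area)

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  cat("  total area:", format(mesh_area(x), digits = 6), "m^2\n")
  if (!is.null(x$region_id))
    cat("  regions:", paste(sort(unique(x$region_id)), collapse = ", "), "\n")
  invisible(x)
}

#' Open cylinder shell mesh
#'
#' Builds a triangulated open cylinder of given radius and length along the
#' z axis, the canonical geometry of the synthetic vessel fixtures. The axial
#' coordinate runs over [0, length].
#'
#' @param radius cylinder radius [m].
#' @param length axial length [m].
#' @param n_circ number of circumferential vertices (>= 8).
#' @param n_axial number of axial vertex rings (>= 8).
#' @return a \code{surface_mesh}.
#' @export
mesh_cylinder <- function(radius = 0.01, length = 0.1, n_circ = 24L,
                          n_axial = 30L) {
  n_circ <- as.integer(n_circ); n_axial <- as.integer(n_axial)
  if (n_circ < 8L || n_axial < 8L) stop("resolutions must be >= 8")
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  z <- seq(0, length, length.out = n_axial)
  verts <- cbind(
    x = radius * rep(cos(theta), times = n_axial),
    y = radius * rep(sin(theta), times = n_axial),
    z = rep(z, each = n_circ))
  # quad (i, i+1) x (ring j, j+1), split into two triangles; 0-based indices
  faces <- matrix(0L, nrow = 2L * n_circ * (n_axial - 1L), ncol = 3L)
  r <- 0L
  for (j in 0:(n_axial - 2L)) {
    for (i in 0:(n_circ - 1L)) {
      i2 <- (i + 1L) %% n_circ
      v00 <- j * n_circ + i;        v01 <- j * n_circ + i2
      v10 <- (j + 1L) * n_circ + i; v11 <- (j + 1L) * n_circ + i2
      faces[r + 1L, ] <- c(v00, v01, v11)
      faces[r + 2L, ] <- c(v00, v11, v10)
      r <- r + 2L
    }
  }
  surface_mesh(verts, faces)
}

same_mesh <- function(a, b) {
  isTRUE(all.equal(a$vertices, b$vertices)) && identical(a$faces, b$faces)
}
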