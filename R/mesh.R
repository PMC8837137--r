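#' Triangulated surface mesh in physical millimetres
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer m x 3 matrix of 1-based vertex indices.
#' @param frame coordinate-frame label.
#' @return Object of class `triangle_mesh` with elements `vertices`, `faces`,
#'   `frame`.
#' @details Volumetric operations (Dice, fiducial embedding, voxelization)
#'   additionally require the mesh to be closed, manifold and consistently
#'   outward-wound; see [validate_mesh()].
#' @export
triangle_mesh <- function(vertices, faces, frame = "world") {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  a2 <- face_areas(list(vertices = vertices, faces = faces))
  if (any(a2 <= 1e-12))
    stop(sprintf("%d degenerate (zero-area) faces", sum(a2 <= 1e-12)))
  structure(list(vertices = vertices, faces = faces, frame = frame),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, frame '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$frame))
  invisible(x)
}

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

#' Per-face areas of a mesh (mm^2)
#' @param mesh a [triangle_mesh()] (or a bare vertices/faces list).
#' @return Numeric vector of face areas.
#' @export
face_areas <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  u <- b - a; v <- c - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

face_normals <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  u <- b - a; v <- c - a
  n <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
             u[, 3] * v[, 1] - u[, 1] * v[, 3],
             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# Area-weighted vertex normals (used for normal-direction perturbations).
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh) * face_areas(mesh)
  grp <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  agg <- rowsum(fn[rep(seq_len(nrow(fn)), 3), , drop = FALSE], group = grp)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  vn[as.integer(rownames(agg)), ] <- agg
  vn / pmax(sqrt(rowSums(vn^2)), 1e-300)
}

#' Signed volume enclosed by a mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for a
#' closed, consistently outward-wound surface.
#' @param mesh a [triangle_mesh()].
#' @return Signed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a [triangle_mesh()].
#' @return Surface area.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

edge_key_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Validate mesh topology and orientation
#'
#' @param mesh a [triangle_mesh()].
#' @return List with `closed` (every undirected edge shared by exactly two
#'   faces), `oriented` (each undirected edge traversed once in each
#'   direction), `boundary_edges`, `volume`, `genus0` (Euler characteristic
#'   equals 2).
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  cnt <- edge_key_counts(mesh)
  closed <- all(cnt == 2L)
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  dir_key <- paste(e[, 1], e[, 2])
  oriented <- closed && !anyDuplicated(dir_key)
  n_edges <- length(cnt)
  chi <- nrow(mesh$vertices) - n_edges + nrow(mesh$faces)
  list(closed = closed, oriented = oriented,
       boundary_edges = sum(cnt != 2L),
       volume = mesh_volume(mesh), genus0 = (chi == 2L))
}

require_closed_mesh <- function(mesh, what = "operation") {
  v <- validate_mesh(mesh)
  if (!v$closed)
    stop(sprintf("%s requires a closed mesh (%d boundary/non-manifold edges)",
                 what, v$boundary_edges))
  if (v$volume <= 0)
    stop(sprintf("%s requires an outward-wound mesh (signed volume %.3g <= 0)",
                 what, v$volume))
  invisible(v)
}

#' Apply a rigid transform to a mesh
#' @param transform a [rigid_transform()].
#' @param mesh a [triangle_mesh()].
#' @return The transformed mesh.
#' @export
transform_mesh <- function(transform, mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  frame <- if (!is.null(transform$frame)) transform$frame else mesh$frame
  triangle_mesh(apply_transform(transform, mesh$vertices), mesh$faces, frame)
}

#' Area-weighted uniform samples on a mesh surface
#'
#' Faces are drawn with probability proportional to area and points uniformly
#' by barycentric coordinates within each face; deterministic given `seed`.
#'
#' @param mesh a [triangle_mesh()].
#' @param n number of samples.
#' @param seed integer seed.
#' @param faces optional subset of face indices to restrict sampling to.
#' @return List with `points` (n x 3), `normals` (n x 3 unit outward),
#'   `face` (face index per sample).
#' @export
sample_mesh_surface <- function(mesh, n, seed = 1L, faces = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"), n >= 1)
  idx_pool <- if (is.null(faces)) seq_len(nrow(mesh$faces)) else faces
  ar <- face_areas(mesh)[idx_pool]
  with_seed(seed, {
    fi <- idx_pool[sample.int(length(idx_pool), n, replace = TRUE, prob = ar)]
    r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
    a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
    b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
    c <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
    pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c
    list(points = pts, normals = face_normals(mesh)[fi, , drop = FALSE], face = fi)
  })
}

#' Farthest-point subsample of mesh vertices
#'
#' Greedy farthest-point sampling gives quasi-uniform surface coverage for
#' feeding a mesh to point-set registration. The (seeded) choice of starting
#' vertex is the only randomness; ties go to the lowest vertex index.
#'
#' @param mesh a [triangle_mesh()] or an n x 3 coordinate matrix.
#' @param n number of points to keep; capped at the number of vertices.
#' @param seed integer seed selecting the start vertex.
#' @return n x 3 matrix of sampled coordinates.
#' @export
farthest_point_sample <- function(mesh, n, seed = 1L) {
  pts <- if (inherits(mesh, "triangle_mesh")) mesh$vertices else as.matrix(mesh)
  n <- min(n, nrow(pts))
  start <- with_seed(seed, sample.int(nrow(pts), 1L))
  idx <- cpp_farthest_point_sampling(pts, as.integer(n), as.integer(start))
  pts[idx, , drop = FALSE]
}

#' Are points inside a closed mesh?
#'
#' Ray-parity point-in-polyhedron test with deterministic epsilon jitter when
#' the ray grazes an edge or vertex.
#'
#' @param points n x 3 matrix or [point_set()].
#' @param mesh a closed [triangle_mesh()].
#' @return Logical vector.
#' @export
points_in_mesh <- function(points, mesh) {
  require_closed_mesh(mesh, "points_in_mesh")
  m <- if (inherits(points, "point_set")) ps_coords(points) else as.matrix(points)
  cpp_points_in_mesh(m, mesh$vertices, mesh$faces - 1L)
}
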