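#' Closed or open planar B-spline contour
#'
#' The segmentation representation: a per-slice curve defined by ordered 2D
#' control points, evaluated as a uniform-knot B-spline (periodic when
#' closed). In-plane coordinates are millimetres.
#'
#' @param control_points k x 2 matrix of control coordinates (mm).
#' @param degree spline degree (default cubic).
#' @param closed should the curve close periodically? Default `TRUE`.
#' @return Object of class `bspline_contour`.
#' @export
bspline_contour <- function(control_points, degree = 3L, closed = TRUE) {
  cp <- as.matrix(control_points)
  storage.mode(cp) <- "double"
  if (ncol(cp) != 2L) stop("control_points must be k x 2")
  if (!all(is.finite(cp))) stop("control points must be finite")
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1")
  if (nrow(cp) < degree + 1L)
    stop(sprintf("need at least degree + 1 = %d control points", degree + 1L))
  structure(list(control_points = cp, degree = degree, closed = isTRUE(closed)),
            class = "bspline_contour")
}

#' Evaluate a B-spline contour
#'
#' @param contour a [bspline_contour()].
#' @param t parameter values; closed contours wrap `t` periodically into
#'   `[0, 1)`, open contours require `t` in `[0, 1]`.
#' @return length(t) x 2 matrix of curve points.
#' @export
evaluate_contour <- function(contour, t) {
  stopifnot(inherits(contour, "bspline_contour"))
  t <- as.numeric(t)
  d <- contour$degree
  cp <- contour$control_points
  k <- nrow(cp)
  if (contour$closed) {
    t <- t %% 1
    knots <- seq(-d, k + d) / k
    basis <- splines::splineDesign(knots, t, ord = d + 1L)
    q <- rbind(cp, cp[seq_len(d), , drop = FALSE])
    basis %*% q
  } else {
    if (any(t < 0 | t > 1)) stop("open contours are defined on [0, 1]")
    n_inner <- k - d - 1L
    knots <- c(rep(0, d + 1L), if (n_inner > 0) seq_len(n_inner) / (n_inner + 1L),
               rep(1, d + 1L))
    # splineDesign treats the right endpoint as exclusive; nudge t = 1 inside
    t <- pmin(t, 1 - 1e-12)
    basis <- splines::splineDesign(knots, t, ord = d + 1L)
    basis %*% cp
  }
}

# Dense polyline and cumulative arc length of a contour.
contour_polyline <- function(contour, m = 4096L) {
  if (contour$closed) {
    ts <- seq(0, 1, length.out = m + 1L)
    p <- evaluate_contour(contour, ts[-length(ts)])
    p <- rbind(p, p[1L, , drop = FALSE])
  } else {
    ts <- seq(0, 1, length.out = m + 1L)
    p <- evaluate_contour(contour, ts)
  }
  seg <- sqrt(rowSums(diff(p)^2))
  list(points = p, cum = c(0, cumsum(seg)))
}

#' Contour perimeter (mm)
#' @param contour a [bspline_contour()].
#' @param m dense evaluation count.
#' @return Arc length of the curve.
#' @export
contour_perimeter <- function(contour, m = 4096L) {
  pl <- contour_polyline(contour, m)
  pl$cum[length(pl$cum)]
}

#' Resample a contour to n approximately arc-length-uniform points
#'
#' @param contour a [bspline_contour()].
#' @param n number of points (>= 3).
#' @return n x 2 matrix; orientation of the control polygon is preserved. For
#'   closed contours the n points cover the full period without repeating the
#'   start point.
#' @export
resample_contour <- function(contour, n) {
  stopifnot(inherits(contour, "bspline_contour"))
  if (n < 3) stop("n must be >= 3")
  pl <- contour_polyline(contour, max(4096L, 16L * n))
  total <- pl$cum[length(pl$cum)]
  if (total < 1e-9) stop("degenerate contour: near-zero arc length")
  targets <- if (contour$closed) total * (seq_len(n) - 1) / n else
    total * (seq_len(n) - 1) / (n - 1)
  ix <- findInterval(targets, pl$cum, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), length(pl$cum) - 1L)
  f <- (targets - pl$cum[ix]) / pmax(pl$cum[ix + 1L] - pl$cum[ix], 1e-300)
  pl$points[ix, , drop = FALSE] * (1 - f) +
    pl$points[ix + 1L, , drop = FALSE] * f
}

#' Ordered stack of per-slice contours
#'
#' @param contours list of [bspline_contour()] objects, one per slice.
#' @param slice_positions strictly monotone out-of-plane coordinates (mm).
#' @param plane slicing axis: the out-of-plane coordinate (`"x"`, `"y"` or
#'   `"z"`). In-plane contour axes are the remaining two in right-handed
#'   order (`x -> (y,z)`, `y -> (z,x)`, `z -> (x,y)`).
#' @param frame coordinate frame label.
#' @return Object of class `contour_stack`.
#' @export
contour_stack <- function(contours, slice_positions, plane = "z",
                          frame = "world") {
  if (!is.list(contours) || !all(vapply(contours, inherits, TRUE, "bspline_contour")))
    stop("contours must be a list of bspline_contour objects")
  slice_positions <- as.numeric(slice_positions)
  if (length(contours) != length(slice_positions))
    stop("one slice position per contour required")
  if (length(contours) < 2L) stop("need at least 2 contours to loft")
  dz <- diff(slice_positions)
  if (!(all(dz > 0) || all(dz < 0)))
    stop("slice positions must be strictly monotone")
  if (!plane %in% c("x", "y", "z")) stop("plane must be 'x', 'y' or 'z'")
  structure(list(contours = contours, slice_positions = slice_positions,
                 plane = plane, frame = frame),
            class = "contour_stack")
}

embed_slice <- function(p2, pos, plane) {
  n <- nrow(p2)
  switch(plane,
         z = cbind(p2[, 1], p2[, 2], rep(pos, n)),
         x = cbind(rep(pos, n), p2[, 1], p2[, 2]),
         y = cbind(p2[, 2], rep(pos, n), p2[, 1]))
}

polygon_signed_area <- function(p) {
  q <- rbind(p, p[1L, , drop = FALSE])
  sum(q[-nrow(q), 1] * q[-1, 2] - q[-1, 1] * q[-nrow(q), 2]) / 2
}

# Cyclic offset of ring b minimizing sum of squared distances to ring a.
best_cyclic_offset <- function(a, b) {
  n <- nrow(a)
  best <- 0L; bestv <- Inf
  for (k in 0L:(n - 1L)) {
    idx <- ((seq_len(n) - 1L + k) %% n) + 1L
    v <- sum((a - b[idx, , drop = FALSE])^2)
    if (v < bestv) { bestv <- v; best <- k }
  }
  ((seq_len(n) - 1L + best) %% n) + 1L
}

#' Loft a contour stack into a closed triangulated mesh
#'
#' Each contour is resampled to `samples_per_contour` arc-length-uniform
#' points with consistent winding, adjacent rings are aligned by the cyclic
#' offset minimizing the summed squared inter-ring distance, stitched with an
#' alternating triangle band, and the first and last rings are capped with a
#' fan to their centroid. The result is validated closed, manifold and
#' outward-wound. Stacks with branching anatomy (several contours on one
#' slice) are not representable and are rejected at construction.
#'
#' @param stack a [contour_stack()].
#' @param samples_per_contour points per ring (>= 3).
#' @return A closed [triangle_mesh()] with positive signed volume.
#' @export
loft_contour_stack <- function(stack, samples_per_contour = 96L) {
  stopifnot(inherits(stack, "contour_stack"))
  n <- as.integer(samples_per_contour)
  if (n < 3L) stop("samples_per_contour must be >= 3")
  ns <- length(stack$contours)
  rings2d <- lapply(stack$contours, resample_contour, n = n)
  # consistent in-plane winding (counter-clockwise)
  rings2d <- lapply(rings2d, function(r)
    if (polygon_signed_area(r) < 0) r[rev(seq_len(n)), , drop = FALSE] else r)
  rings <- vector("list", ns)
  rings[[1L]] <- rings2d[[1L]]
  for (i in 2L:ns)
    rings[[i]] <- rings2d[[i]][best_cyclic_offset(rings[[i - 1L]], rings2d[[i]]), ,
                               drop = FALSE]
  verts <- do.call(rbind, lapply(seq_len(ns), function(i)
    embed_slice(rings[[i]], stack$slice_positions[i], stack$plane)))

  faces <- vector("list", ns - 1L)
  jn <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(ns - 1L)) {
    a <- (i - 1L) * n + seq_len(n); a2 <- (i - 1L) * n + jn
    b <- i * n + seq_len(n);        b2 <- i * n + jn
    faces[[i]] <- rbind(cbind(a, a2, b), cbind(a2, b2, b))
  }
  f <- do.call(rbind, faces)

  c1 <- colMeans(rings[[1L]]); cN <- colMeans(rings[[ns]])
  v1 <- embed_slice(rbind(c1), stack$slice_positions[1L], stack$plane)
  vN <- embed_slice(rbind(cN), stack$slice_positions[ns], stack$plane)
  i1 <- nrow(verts) + 1L; iN <- nrow(verts) + 2L
  verts <- rbind(verts, v1, vN)
  cap1 <- cbind(jn, seq_len(n), i1)
  capN <- cbind((ns - 1L) * n + seq_len(n), (ns - 1L) * n + jn, iN)
  f <- rbind(f, cap1, capN)

  mesh <- triangle_mesh(verts, f, frame = stack$frame)
  vol <- mesh_volume(mesh)
  if (vol < 0) {
    mesh <- triangle_mesh(verts, f[, c(1L, 3L, 2L)], frame = stack$frame)
    vol <- -vol
  }
  val <- validate_mesh(mesh)
  if (!val$closed)
    stop(sprintf("lofted mesh not closed (%d bad edges)", val$boundary_edges))
  if (vol <= 0) {
    # locate the offending band by its (negative) volume contribution
    bandvol <- vapply(seq_len(ns - 1L), function(i) {
      m <- triangle_mesh(verts, faces[[i]][, , drop = FALSE], frame = stack$frame)
      mesh_volume(m)
    }, 0)
    worst <- which.min(bandvol)
    stop(sprintf("self-intersecting stitch between slices %d and %d (signed volume <= 0)",
                 worst, worst + 1L))
  }
  mesh
}
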