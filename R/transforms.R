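#' Rigid (similarity) transform in physical millimetres
#'
#' A transform acting on 3D points as `p -> scale * R p + t`
#' (rotate-then-translate). Rotations must be proper (orthonormal with
#' determinant +1); `scale` stays at 1 for strictly rigid motion and is only
#' different from 1 when scaling is explicitly enabled in a registration.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation numeric length-3 translation in mm.
#' @param scale positive scalar, default 1.
#' @param frame optional label of the target coordinate frame.
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90), c(1, 0, 0))
#' apply_transform(t1, rbind(c(1, 0, 0)))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1, frame = NULL) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(is.numeric(rotation), all(dim(rotation) == c(3L, 3L)),
            length(translation) == 3L, length(scale) == 1L)
  if (!all(is.finite(rotation)) || !all(is.finite(translation)) ||
      !is.finite(scale) || scale <= 0)
    stop("rigid_transform: non-finite entries or non-positive scale")
  orth <- max(abs(crossprod(rotation) - diag(3)))
  if (orth > 1e-9)
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.3g)", orth))
  if (det(rotation) < 0)
    stop("rotation has negative determinant (reflection, not a rotation)")
  structure(list(rotation = rotation, translation = translation,
                 scale = scale, frame = frame),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("Rigid transform: rotation %.3f deg, translation %.3f mm%s\n",
              ang, sqrt(sum(x$translation^2)),
              if (x$scale != 1) sprintf(", scale %.5f", x$scale) else ""))
  invisible(x)
}

#' Rotation matrix about an axis
#'
#' @param axis numeric length-3 axis (need not be normalized).
#' @param angle_deg rotation angle in degrees (right-handed).
#' @return A 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be non-zero")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

rotation_angle_deg <- function(R) {
  # atan2 form resolves angles near 0 and pi far better than acos(trace)
  ct <- (sum(diag(R)) - 1) / 2
  st <- sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
               (R[2, 1] - R[1, 2])^2) / 2
  atan2(st, ct) * 180 / pi
}

#' Labeled set of 3D points in a named coordinate frame
#'
#' @param points numeric n x 3 matrix of coordinates in mm.
#' @param frame non-empty frame label.
#' @param labels optional character vector, one label per point.
#' @return Object of class `point_set`: the coordinate matrix with `frame`
#'   and `labels` attributes.
#' @export
point_set <- function(points, frame = "world", labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns")
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop("point coordinates must be finite")
  if (!is.character(frame) || length(frame) != 1L || !nzchar(frame))
    stop("frame must be a non-empty string")
  if (!is.null(labels) && length(labels) != nrow(points))
    stop("labels must have one entry per point")
  structure(points, frame = frame, labels = labels, class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set: %d points in frame '%s'\n", nrow(x), attr(x, "frame")))
  invisible(x)
}

ps_coords <- function(x) {
  m <- unclass(x)
  attr(m, "frame") <- NULL
  attr(m, "labels") <- NULL
  m
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points a [point_set()] or plain n x 3 matrix (mm).
#' @return Points of the same type, mapped by `scale * R p + t`; for a
#'   `point_set` the frame is set to the transform's target frame when one is
#'   recorded.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  is_ps <- inherits(points, "point_set")
  m <- if (is_ps) ps_coords(points) else as.matrix(points)
  if (!all(is.finite(m))) stop("apply_transform: non-finite input coordinates")
  out <- transform$scale * (m %*% t(transform$rotation))
  out <- sweep(out, 2, transform$translation, "+")
  if (is_ps) {
    frame <- if (!is.null(transform$frame)) transform$frame else attr(points, "frame")
    point_set(out, frame = frame, labels = attr(points, "labels"))
  } else out
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  a$scale * (a$rotation %*% b$translation) + a$translation,
                  a$scale * b$scale,
                  frame = a$frame)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return The inverse transform: `compose_transforms(t, invert_transform(t))`
#'   is the identity.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  rigid_transform(t(t$rotation),
                  -as.numeric(t(t$rotation) %*% t$translation) / t$scale,
                  1 / t$scale)
}

#' Rotation and translation discrepancy between two transforms
#'
#' Measures how far two rigid transforms are apart: the rotation angle and
#' the translation norm of the residual transform `a o b^-1`. Used to score a
#' recovered registration against a known ground-truth motion.
#'
#' @param a,b [rigid_transform()] objects with scale 1.
#' @return Named numeric vector `c(rotation_deg =, translation_mm =)`;
#'   rotation in \[0, 180\] degrees.
#' @export
transform_discrepancy <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  if (a$scale != 1 || b$scale != 1)
    stop("transform_discrepancy is defined for scale-1 transforms")
  d <- compose_transforms(a, invert_transform(b))
  c(rotation_deg = rotation_angle_deg(d$rotation),
    translation_mm = sqrt(sum(d$translation^2)))
}

#' Uniformly random rigid transform (for simulation)
#'
#' Axis drawn uniformly on the sphere, angle uniform in
#' `[0, max_rotation_deg]`, translation direction uniform with magnitude
#' uniform in `[0, max_translation_mm]`.
#'
#' @param max_rotation_deg,max_translation_mm motion bounds.
#' @param seed integer seed; the global RNG state is restored on exit.
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_rotation_deg = 15,
                                   max_translation_mm = 20, seed = 1L) {
  with_seed(seed, {
    ax <- stats::rnorm(3)
    ang <- stats::runif(1, 0, max_rotation_deg)
    td <- stats::rnorm(3)
    td <- td / sqrt(sum(td^2))
    tm <- stats::runif(1, 0, max_translation_mm)
    rigid_transform(rotation_about_axis(ax, ang), td * tm)
  })
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic sub-seed derivation; keeps values within 32-bit integer range.
derive_seed <- function(master, index) {
  as.integer((as.double(master) %% 2147483647 * 69069 + as.double(index) * 12347 + 1) %%
               2147483647)
}
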