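smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Control points for a radial cross-section r(theta). The control radius is
# pre-scaled so the cubic B-spline passes through (not inside) the target
# radius: a uniform cubic curve through points on a circle shrinks it by
# (2 + cos(2*pi/K)) / 3.
radial_contour <- function(r_fun, n_control = 24L, degree = 3L) {
  th <- 2 * pi * (seq_len(n_control) - 1) / n_control
  scale <- if (degree == 3L) 3 / (2 + cos(2 * pi / n_control)) else 1
  r <- r_fun(th) * scale
  bspline_contour(cbind(r * cos(th), r * sin(th)), degree = degree,
                  closed = TRUE)
}

detail_settings <- function(detail) {
  switch(match.arg(detail, c("coarse", "medium", "fine")),
         coarse = list(slices = 24L, ring = 48L, control = 20L),
         medium = list(slices = 36L, ring = 72L, control = 24L),
         fine   = list(slices = 56L, ring = 128L, control = 32L))
}

#' Synthetic bone-like closed mesh
#'
#' Parametric stand-in for segmented distal-femur / proximal-tibia models:
#' a stack of radial cross-section contours (shaft, condylar lobes or tibial
#' plateau) lofted into a closed mesh, with a seeded smooth random modulation
#' of the radius for inter-case variety. The `"ellipsoid"` kind is an exact
#' analytic shape used for metric calibration. Shapes are parametric blends,
#' not anatomical atlases.
#'
#' @param kind `"femur"` (tapering shaft flaring into two condylar lobes,
#'   long axis +z pointing distally), `"tibia"` (proximal plateau tapering
#'   into a shaft) or `"ellipsoid"`.
#' @param size_mm characteristic length (mm) for the bones (default 80), or
#'   the three semi-axes for `"ellipsoid"` (default `c(30, 25, 20)`).
#' @param detail `"coarse"`, `"medium"` or `"fine"` tessellation.
#' @param seed integer seed for the random surface modulation.
#' @param modulation_sd relative RMS amplitude of the random radius
#'   modulation (0 disables it; ellipsoids default to 0).
#' @return A closed, outward-wound [triangle_mesh()].
#' @export
make_bone_like_mesh <- function(kind = c("femur", "tibia", "ellipsoid"),
                                size_mm = NULL, detail = "medium", seed = 1L,
                                modulation_sd = 0.02) {
  kind <- match.arg(kind)
  ds <- detail_settings(detail)
  if (kind == "ellipsoid") {
    ax <- if (is.null(size_mm)) c(30, 25, 20) else
      if (length(size_mm) == 1L) rep(size_mm, 3) else as.numeric(size_mm)
    stopifnot(length(ax) == 3L, all(ax > 0))
    phi_min <- pi / (2 * ds$slices)
    phi <- seq(pi - phi_min, phi_min, length.out = ds$slices)  # z ascending
    # radial distance of the ellipse cross-section along direction theta
    contours <- lapply(phi, function(p) {
      s <- sin(p)
      radial_contour(function(th) {
        a <- ax[1] * s; b <- ax[2] * s
        a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
      }, n_control = ds$control)
    })
    stack <- contour_stack(contours, ax[3] * cos(phi), plane = "z")
    return(loft_contour_stack(stack, samples_per_contour = ds$ring))
  }

  L <- if (is.null(size_mm)) 80 else as.numeric(size_mm)[1]
  stopifnot(L > 0)
  mod <- modulation_field(seed, modulation_sd)
  zf <- seq(0, 1, length.out = ds$slices)
  z <- zf * L
  sc <- L / 80  # cross-section radii scale with the overall size
  contours <- lapply(seq_along(zf), function(i) {
    u <- zf[i]
    if (kind == "femur") {
      r0 <- (14 + 9 * smoothstep((u - 0.5) / 0.38)) * sc
      c2 <- 0.22 * smoothstep((u - 0.55) / 0.3)
      c1 <- 0.06 * smoothstep((u - 0.5) / 0.4)
      tip <- sqrt(pmax(1 - ((u - 0.86) / 0.2)^2 * (u > 0.86), 0.2))
    } else {
      r0 <- (22 - 9 * smoothstep((u - 0.12) / 0.3)) * sc
      c2 <- 0.14 * (1 - smoothstep((u - 0.1) / 0.3))
      c1 <- 0.05 * (1 - smoothstep((u - 0.2) / 0.4))
      tip <- sqrt(pmax(1 - ((0.14 - u) / 0.18)^2 * (u < 0.14), 0.25))
    }
    radial_contour(function(th)
      pmax(r0 * tip * (1 + c2 * cos(2 * th) + c1 * cos(th)) *
             (1 + mod(th, u)), 1), n_control = ds$control)
  })
  stack <- contour_stack(contours, z, plane = "z")
  loft_contour_stack(stack, samples_per_contour = ds$ring)
}

# Seeded smooth random field on (theta, zf): low-order Fourier x cosine
# basis, RMS approximately `sd`, used to modulate the cross-section radius.
modulation_field <- function(seed, sd) {
  if (sd <= 0) return(function(th, u) 0)
  co <- with_seed(seed, {
    array(stats::rnorm(3L * 2L * 3L), dim = c(3L, 2L, 3L))
  })
  # basis has RMS ~1.65 over (theta, u, coefficients); rescale to `sd`
  function(th, u) {
    v <- 0
    for (j in 1:3) for (k in 0:2) {
      v <- v + (co[j, 1, k + 1] * cos(j * th) + co[j, 2, k + 1] * sin(j * th)) *
        cos(k * pi * u) / j
    }
    v * sd / 1.65
  }
}

#' Perturb a segmentation with a smooth correlated surface field
#'
#' Emulates interoperator segmentation differences: vertices are displaced
#' along their normals by a spatially correlated Gaussian random field
#' (radial-basis mixture with the stated correlation length) normalized to
#' the requested RMS amplitude. Topology is unchanged and the mesh stays
#' closed.
#'
#' Because both operators trace the same bone in the same image frame, their
#' disagreement carries no net rigid motion: the linearized rigid component
#' (best-fit translation + infinitesimal rotation, area-weighted) is
#' projected out of the displacement field before it is applied, so the
#' perturbed reference is unbiased in pose relative to the original.
#'
#' @param mesh a closed [triangle_mesh()].
#' @param amplitude_mm RMS displacement (mm); 0 returns the mesh unchanged.
#' @param correlation_length_mm spatial scale of the field.
#' @param seed integer seed.
#' @return The perturbed [triangle_mesh()].
#' @export
perturb_segmentation <- function(mesh, amplitude_mm = 0.3,
                                 correlation_length_mm = 10, seed = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (amplitude_mm < 0) stop("amplitude must be >= 0")
  if (amplitude_mm == 0) return(mesh)
  n_ctrl <- 150L
  ctrl <- sample_mesh_surface(mesh, n_ctrl, seed = seed)$points
  wts <- with_seed(derive_seed(seed, 1L), stats::rnorm(n_ctrl))
  V <- mesh$vertices
  d2 <- outer(rowSums(V^2), rowSums(ctrl^2), "+") - 2 * V %*% t(ctrl)
  field <- as.numeric(exp(-pmax(d2, 0) / (2 * correlation_length_mm^2)) %*% wts)
  nrm <- vertex_normals(mesh)
  # remove the rigidly absorbable component: a rigid velocity t + omega x v
  # displaces the surface normally by n . (t + omega x v), so the scalar
  # normal field is orthogonalized (area-weighted) against those 6 functions
  w <- vertex_areas(mesh)
  Vc <- sweep(V, 2, colSums(V * w) / sum(w))
  basis <- cbind(nrm,
                 Vc[, 2] * nrm[, 3] - Vc[, 3] * nrm[, 2],
                 Vc[, 3] * nrm[, 1] - Vc[, 1] * nrm[, 3],
                 Vc[, 1] * nrm[, 2] - Vc[, 2] * nrm[, 1])
  beta <- solve(crossprod(basis * w, basis), crossprod(basis * w, field))
  field <- field - as.numeric(basis %*% beta)
  field_rms <- sqrt(mean(field^2))
  if (field_rms < 1e-12) return(mesh)
  field <- field * amplitude_mm / field_rms
  out <- triangle_mesh(V + field * nrm, mesh$faces, mesh$frame)
  v0 <- mesh_volume(mesh); v1 <- mesh_volume(out)
  if (v1 < 0.8 * v0)
    stop("perturbation amplitude too large: signed volume dropped by > 20%")
  out
}

# Per-vertex area share (one third of adjacent face areas).
vertex_areas <- function(mesh) {
  ar <- face_areas(mesh) / 3
  grp <- c(mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3])
  agg <- rowsum(rep(ar, 3), group = grp)
  out <- numeric(nrow(mesh$vertices))
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Simulated operator model for attraction-point placement
#'
#' @param placement_noise_sd isotropic Gaussian localization error (mm).
#' @param surface_bias_sd standard deviation (mm) of a systematic signed
#'   offset along the surface normal, drawn once per point set; emulates
#'   edge-appearance differences between modalities.
#' @return Object of class `operator_model`.
#' @export
operator_model <- function(placement_noise_sd = 0.3, surface_bias_sd = 0) {
  if (placement_noise_sd < 0 || surface_bias_sd < 0)
    stop("standard deviations must be non-negative")
  structure(list(placement_noise_sd = placement_noise_sd,
                 surface_bias_sd = surface_bias_sd),
            class = "operator_model")
}

#' Simulate operator-placed attraction points on a bone surface
#'
#' Draws `n` area-weighted uniform samples of the surface (emulating an
#' operator asked to distribute points more or less homogeneously, without
#' localizing particular features), then displaces each by the operator
#' model's systematic normal offset plus isotropic localization noise.
#'
#' @param mesh the target-frame bone surface ([triangle_mesh()]).
#' @param n number of points (>= 4).
#' @param operator an [operator_model()].
#' @param region `"all"` or `"partial"`; partial restricts placement to the
#'   `region_fraction` of the surface area at the distal (+z) end, emulating
#'   partially identifiable tissue contours.
#' @param region_fraction surface-area fraction for `region = "partial"`.
#' @param seed integer seed.
#' @return A [point_set()] in the mesh's frame.
#' @export
simulate_operator_points <- function(mesh, n, operator = operator_model(),
                                     region = c("all", "partial"),
                                     region_fraction = 0.4, seed = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"), inherits(operator, "operator_model"))
  region <- match.arg(region)
  if (n < 4L) stop("at least 4 points are required")
  faces <- NULL
  if (region == "partial") {
    if (region_fraction <= 0 || region_fraction > 1)
      stop("region_fraction must be in (0, 1]")
    ar <- face_areas(mesh)
    cz <- (mesh$vertices[mesh$faces[, 1], 3] + mesh$vertices[mesh$faces[, 2], 3] +
             mesh$vertices[mesh$faces[, 3], 3]) / 3
    ord <- order(cz, decreasing = TRUE)
    keep <- cumsum(ar[ord]) <= region_fraction * sum(ar)
    if (!any(keep)) stop("partial region too small to hold any points")
    faces <- ord[keep]
  }
  s <- sample_mesh_surface(mesh, n, seed = seed, faces = faces)
  noise <- with_seed(derive_seed(seed, 2L), {
    bias <- if (operator$surface_bias_sd > 0)
      stats::rnorm(1, 0, operator$surface_bias_sd) else 0
    jitter <- if (operator$placement_noise_sd > 0)
      matrix(stats::rnorm(3 * n, 0, operator$placement_noise_sd), n, 3) else
        matrix(0, n, 3)
    bias * s$normals + jitter
  })
  point_set(s$points + noise, frame = mesh$frame)
}

place_internal_fiducials <- function(mesh, n = 5L, seed = 1L) {
  centroid <- colMeans(mesh$vertices)
  for (trial in 0:24) {
    p <- sample_mesh_surface(mesh, n, seed = derive_seed(seed, 100L + trial))$points
    f <- sweep(0.55 * sweep(p, 2, centroid), 2, centroid, "+")
    inside <- points_in_mesh(f, mesh)
    sv <- svd(sweep(f, 2, colMeans(f)), nu = 0, nv = 0)$d
    if (all(inside %in% TRUE) && sv[2] > 1e-6 * sv[1]) return(f)
  }
  stop("could not place internal fiducials")
}

#' Assemble a synthetic ground-truth registration case
#'
#' Builds the full study geometry with known truth: a source-frame bone
#' model; a rigid repositioning motion drawn uniformly within the stated
#' ranges; a target-frame reference segmentation (the moved model perturbed
#' by a smooth interoperator field); a large pool of simulated operator
#' attraction points on the moved bone edges; and fiducial markers strictly
#' inside the bone, mapped exactly (or with stated noise) by the true
#' motion.
#'
#' @param kind `"femur"` or `"tibia"`.
#' @param seed master seed of the case.
#' @param max_rotation_deg,max_translation_mm repositioning motion bounds.
#' @param operator an [operator_model()] for the attraction-point pool.
#' @param perturbation_amplitude_mm,correlation_length_mm interoperator
#'   segmentation field (see [perturb_segmentation()]).
#' @param n_candidates size of the attraction-point pool.
#' @param n_fiducials embedded fiducial markers per bone.
#' @param fiducial_noise_sd localization noise on target-frame fiducials.
#' @param detail,modulation_sd mesh generation settings
#'   (see [make_bone_like_mesh()]).
#' @return Object of class `ground_truth_case`: list with `model`,
#'   `reference`, `true_transform`, `attraction_candidates`,
#'   `fiducials_source`, `fiducials_target`, `kind`, `seed`.
#' @export
make_ground_truth_case <- function(kind = "femur", seed = 1L,
                                   max_rotation_deg = 15,
                                   max_translation_mm = 20,
                                   operator = operator_model(),
                                   perturbation_amplitude_mm = 0.3,
                                   correlation_length_mm = 10,
                                   n_candidates = 4000L, n_fiducials = 5L,
                                   fiducial_noise_sd = 0, detail = "medium",
                                   modulation_sd = 0.02) {
  model <- make_bone_like_mesh(kind, detail = detail, seed = derive_seed(seed, 1L),
                               modulation_sd = modulation_sd)
  model$frame <- "source"
  true_transform <- random_rigid_transform(max_rotation_deg, max_translation_mm,
                                           seed = derive_seed(seed, 2L))
  true_transform$frame <- "target"
  moved <- transform_mesh(true_transform, model)
  reference <- if (perturbation_amplitude_mm > 0)
    perturb_segmentation(moved, perturbation_amplitude_mm,
                         correlation_length_mm, seed = derive_seed(seed, 3L))
  else moved
  candidates <- simulate_operator_points(moved, n_candidates, operator,
                                         seed = derive_seed(seed, 4L))
  fs <- place_internal_fiducials(model, n_fiducials, seed = derive_seed(seed, 5L))
  ft <- apply_transform(true_transform, fs)
  if (fiducial_noise_sd > 0)
    ft <- ft + with_seed(derive_seed(seed, 6L),
                         matrix(stats::rnorm(length(ft), 0, fiducial_noise_sd),
                                nrow(ft), 3))
  structure(list(model = model, reference = reference,
                 true_transform = true_transform,
                 attraction_candidates = candidates,
                 fiducials_source = point_set(fs, frame = "source"),
                 fiducials_target = point_set(ft, frame = "target"),
                 kind = kind, seed = as.integer(seed)),
            class = "ground_truth_case")
}

#' @export
print.ground_truth_case <- function(x, ...) {
  td <- transform_discrepancy(x$true_transform,
                              rigid_transform(frame = x$true_transform$frame))
  cat(sprintf("ground_truth_case (%s, seed %d): motion %.2f deg / %.2f mm, %d candidate points\n",
              x$kind, x$seed, td["rotation_deg"], td["translation_mm"],
              nrow(x$attraction_candidates)))
  invisible(x)
}
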