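#' Register a bone model onto sparse attraction points
#'
#' The expert-supervised route: the model surface is downsampled to
#' quasi-uniform coverage by seeded farthest-point sampling and positioned
#' onto the manually placed attraction points with rigid CPD. The mesh
#' samples act as the moving Gaussian centroids and the attraction points as
#' the fixed data, so points covering only part of the surface (partial
#' tissues) still register: uncovered surface regions simply receive low
#' responsibility.
#'
#' After the CPD stage, a point-to-surface polish removes the quantization
#' of the sampled centroid cloud: attraction points are iteratively matched
#' to their exact closest points on the triangulated surface and the rigid
#' fit is re-solved in closed form, so noise-free points on the true surface
#' are recovered to numerical precision rather than to the sample spacing.
#'
#' When the points cover only part of the surface (partial tissues), pass
#' `init_translation = FALSE` (the centroid pre-alignment is biased by the
#' uncovered surface) and a `sigma2_init` commensurate with the coarse
#' pre-positioning error, e.g. `25` for alignment known to within ~5 mm;
#' the default full-dispersion initialization over-anneals in that setting
#' and can slide the model along its long axis.
#'
#' @param model a [triangle_mesh()] in the source frame.
#' @param attraction_points [point_set()] or n x 3 matrix in the target
#'   frame; at least 4 points.
#' @param moving_sample_count mesh vertices kept by farthest-point sampling.
#' @param seed seed for the farthest-point start vertex.
#' @param refine run the point-to-surface refinement stage (default `TRUE`).
#' @param ... passed to [cpd_rigid()] (`w`, `tolerance`, ...).
#' @return A `cpd_rigid` fit whose `transform` maps the model frame into the
#'   target (image) frame.
#' @export
register_model_to_points <- function(model, attraction_points,
                                     moving_sample_count = 2000L, seed = 1L,
                                     refine = TRUE, ...) {
  stopifnot(inherits(model, "triangle_mesh"))
  npts <- if (inherits(attraction_points, "point_set"))
    nrow(attraction_points) else nrow(as.matrix(attraction_points))
  if (npts < 4L)
    stop("at least 4 attraction points are required")
  samples <- farthest_point_sample(model, moving_sample_count, seed = seed)
  fit <- cpd_rigid(samples, attraction_points, ...)
  if (refine)
    fit$transform <- refine_to_surface(model, attraction_points, fit$transform)
  fit$method <- "points"
  fit
}

#' Point-to-surface rigid refinement
#'
#' Iterative closest-point polish of a rigid transform: each target-frame
#' point is matched to its exact closest point on the transformed model
#' surface (face interior, edge and vertex cases handled exactly) and the
#' corresponding-point least-squares transform is re-solved in closed form,
#' until the pose change per iteration is negligible. Minimizes the summed
#' squared point-to-surface distance locally; intended as a polish after a
#' CPD alignment, not as a global registration on its own.
#'
#' @param model a [triangle_mesh()].
#' @param points target-frame points ([point_set()] or matrix).
#' @param transform initial [rigid_transform()] (model -> target frame).
#' @param max_iterations iteration cap.
#' @param tolerance stop when rotation change (rad) + relative translation
#'   change per iteration falls below this.
#' @return The refined [rigid_transform()].
#' @export
refine_to_surface <- function(model, points, transform,
                              max_iterations = 2000L, tolerance = 1e-9) {
  stopifnot(inherits(model, "triangle_mesh"))
  X <- if (inherits(points, "point_set")) ps_coords(points) else as.matrix(points)
  if (transform$scale != 1)
    stop("refine_to_surface expects a scale-1 transform")
  scale_ref <- max(1, sqrt(mean(rowSums(sweep(X, 2, colMeans(X))^2))))
  res <- cpp_refine_icp(model$vertices, model$faces - 1L, X,
                        transform$rotation, transform$translation,
                        as.integer(max_iterations), tolerance, scale_ref)
  tr <- rigid_transform(res$rotation, res$translation, 1,
                        frame = transform$frame)
  tr$refine_iterations <- res$iterations
  tr
}

#' Register a bone model onto a full reference model
#'
#' The substitution gold standard: both surfaces are downsampled by
#' farthest-point sampling and aligned with rigid CPD (model samples moving,
#' reference samples fixed). Equivalent to the attraction-point route with an
#' excessive number of points covering the whole surface.
#'
#' The same point-to-surface polish as in [register_model_to_points()] is
#' applied afterwards, with the reference samples in the role of (dense)
#' attraction points.
#'
#' @param model,reference [triangle_mesh()] objects.
#' @param moving_sample_count,fixed_sample_count samples per mesh.
#' @param seed seed for the farthest-point starts.
#' @param refine run the point-to-surface refinement stage (default `TRUE`).
#' @param ... passed to [cpd_rigid()].
#' @return A `cpd_rigid` fit mapping the model frame onto the reference
#'   frame.
#' @export
register_model_to_model <- function(model, reference,
                                    moving_sample_count = 2000L,
                                    fixed_sample_count = 2000L, seed = 1L,
                                    refine = TRUE, ...) {
  stopifnot(inherits(model, "triangle_mesh"), inherits(reference, "triangle_mesh"))
  ys <- farthest_point_sample(model, moving_sample_count, seed = seed)
  xs <- farthest_point_sample(reference, fixed_sample_count,
                              seed = derive_seed(seed, 1L))
  fit <- cpd_rigid(ys, xs, ...)
  if (refine)
    fit$transform <- refine_to_surface(model, xs, fit$transform)
  fit$method <- "model"
  fit
}

#' Corresponding-point least-squares rigid fit (fiducial gold standard)
#'
#' Closed-form Kabsch/Umeyama solution of the rigid transform minimizing
#' `sum ||T(source_i) - target_i||^2` over matched pairs: rotation from the
#' SVD of the cross-covariance with determinant-sign correction (never a
#' reflection), translation from the centroids. This is how fiducial markers
#' embedded in a bone give a gold-standard registration: their coordinates in
#' the two acquisitions are matched by label.
#'
#' @param source,target matched [point_set()] objects or n x 3 matrices
#'   (same count, >= 3, not collinear), paired by order.
#' @return A [rigid_transform()] mapping source onto target.
#' @export
fit_rigid_corresponding <- function(source, target) {
  S <- if (inherits(source, "point_set")) ps_coords(source) else as.matrix(source)
  Tm <- if (inherits(target, "point_set")) ps_coords(target) else as.matrix(target)
  if (nrow(S) != nrow(Tm)) stop("source and target must have equal counts")
  if (nrow(S) < 3L) stop("at least 3 point pairs are required")
  mu_s <- colMeans(S); mu_t <- colMeans(Tm)
  Sh <- sweep(S, 2, mu_s); Th <- sweep(Tm, 2, mu_t)
  H <- crossprod(Th, Sh)  # target' source
  sv <- svd(H)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("point pairs are (near-)collinear; rotation is not identifiable")
  C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R <- sv$u %*% C %*% t(sv$v)
  frame <- if (inherits(target, "point_set")) attr(target, "frame") else NULL
  rigid_transform(R, mu_t - as.numeric(R %*% mu_s), frame = frame)
}

#' Fiducial registration error (FRE)
#'
#' Root-mean-square residual of matched fiducial pairs after applying a
#' transform; the standard diagnostic for a fiducial-based registration.
#'
#' @param source,target matched point sets (equal counts).
#' @param transform a [rigid_transform()] mapping source into the target
#'   frame.
#' @return RMS residual in mm.
#' @export
fiducial_registration_error <- function(source, target, transform) {
  S <- if (inherits(source, "point_set")) ps_coords(source) else as.matrix(source)
  Tm <- if (inherits(target, "point_set")) ps_coords(target) else as.matrix(target)
  if (nrow(S) != nrow(Tm)) stop("source and target must have equal counts")
  r <- apply_transform(transform, S) - Tm
  sqrt(mean(rowSums(r^2)))
}
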