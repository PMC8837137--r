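#' Rigid coherent point drift registration
#'
#' Fits the rigid motion aligning a moving point set onto a fixed point set
#' by coherent point drift (CPD): the moving points are the centroids of an
#' isotropic Gaussian mixture (shared variance `sigma2`) with an added
#' uniform outlier component of weight `w`, and the mixture is rigidly moved
#' to maximize the likelihood of the fixed points via EM. The E-step computes
#' posterior correspondence probabilities; the M-step solves rotation in
#' closed form by SVD of the posterior-weighted cross-covariance (with
#' determinant-sign correction so the solution is never a reflection),
#' translation from weighted centroids, and updates `sigma2`.
#'
#' Because the fixed data may cover only part of the moving surface (sparse
#' attraction points on a bone model), the moving set plays the role of
#' mixture centroids: data points always find nearby centroids, and surface
#' regions without data simply receive low responsibility.
#'
#' @param moving n x 3 matrix or [point_set()]: the Gaussian centroids
#'   (e.g. mesh surface samples) to be moved.
#' @param fixed m x 3 matrix or [point_set()]: the data (e.g. attraction
#'   points).
#' @param w outlier weight in `[0, 1)`. Default 0.1: expert-placed points are
#'   near-clean but edge ambiguity between modalities justifies a floor.
#' @param max_iterations EM iteration cap.
#' @param tolerance relative `sigma2` change declaring convergence.
#' @param allow_scaling estimate a global scale? Default `FALSE` (same
#'   physical bone in both frames).
#' @param init_translation pre-align centroids before iterating? Skippable
#'   when the fixed data covers only part of the moving surface, where the
#'   centroid offset biases the start.
#' @param sigma2_init optional initial variance (mm^2); default is the mean
#'   pairwise dispersion between the sets.
#' @return Object of class `cpd_rigid` with elements `transform`
#'   (a [rigid_transform()] mapping moving -> fixed frame), `sigma2`
#'   (final, mm^2), `sigma2_trace`, `iterations`, `converged`, `loglik`,
#'   plus the inputs' sizes. Non-convergence is reported via
#'   `converged = FALSE`, not an error.
#' @seealso [register_model_to_points()], [register_model_to_model()]
#' @examples
#' y <- matrix(rnorm(60), 20, 3)
#' tr <- rigid_transform(rotation_about_axis(c(1, 1, 0), 10), c(2, 0, 1))
#' fit <- cpd_rigid(y, apply_transform(tr, y), w = 0)
#' transform_discrepancy(fit$transform, tr)
#' @export
cpd_rigid <- function(moving, fixed, w = 0.1, max_iterations = 150L,
                      tolerance = 1e-8, allow_scaling = FALSE,
                      init_translation = TRUE, sigma2_init = NULL) {
  Y <- if (inherits(moving, "point_set")) ps_coords(moving) else as.matrix(moving)
  X <- if (inherits(fixed, "point_set")) ps_coords(fixed) else as.matrix(fixed)
  storage.mode(X) <- "double"; storage.mode(Y) <- "double"
  if (nrow(Y) < 4L || nrow(X) < 4L)
    stop("cpd_rigid requires at least 4 points in each set")
  if (w < 0 || w >= 1) stop("outlier weight w must be in [0, 1)")
  if (tolerance <= 0) stop("tolerance must be positive")
  check_rank2 <- function(m, name) {
    sv <- svd(sweep(m, 2, colMeans(m)), nu = 0, nv = 0)$d
    if (sv[2] < 1e-9 * max(sv[1], 1e-300))
      stop(sprintf("degenerate geometry: %s points are (near-)collinear", name))
  }
  check_rank2(X, "fixed"); check_rank2(Y, "moving")

  N <- nrow(X); M <- nrow(Y)
  R <- diag(3); s <- 1
  tvec <- if (init_translation) colMeans(X) - colMeans(Y) else c(0, 0, 0)
  TY <- sweep(Y, 2, tvec, "+")
  sigma2 <- if (!is.null(sigma2_init)) sigma2_init else {
    (M * sum(rowSums(X^2)) + N * sum(rowSums(TY^2)) -
       2 * sum(colSums(X) * colSums(TY))) / (3 * N * M)
  }
  sigma2 <- max(sigma2, 1e-12)

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  loglik <- NA_real_
  xs2 <- rowSums(X^2)
  collapsed <- FALSE
  while (iter < max_iterations) {
    iter <- iter + 1L
    e <- cpp_cpd_estep(X, TY, sigma2, w, N)
    Np <- sum(e$P1)
    if (Np < 1e-12) {
      # every data point classified as outlier: keep the last valid pose
      if (iter == 1L)
        stop("all data points classified as outliers; registration failed")
      collapsed <- TRUE
      break
    }
    mu_x <- as.numeric(crossprod(X, e$Pt1)) / Np
    mu_y <- as.numeric(crossprod(Y, e$P1)) / Np
    A <- crossprod(e$PX, Y) - Np * tcrossprod(mu_x, mu_y)
    sv <- svd(A)
    if (sv$d[2] < 1e-15 * max(sv$d[1], 1e-300)) {
      # the posterior has collapsed onto (nearly) collinear support; the EM
      # cannot proceed, so report non-convergence with the last valid pose
      if (iter == 1L)
        stop("degenerate geometry: rank-deficient cross-covariance")
      collapsed <- TRUE
      break
    }
    C <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
    R <- sv$u %*% C %*% t(sv$v)
    trAR <- sum(diag(crossprod(A, R)))
    tryy <- sum(e$P1 * rowSums(Y^2)) - Np * sum(mu_y^2)
    s <- if (allow_scaling) trAR / tryy else 1
    tvec <- mu_x - s * as.numeric(R %*% mu_y)
    trxx <- sum(e$Pt1 * xs2) - Np * sum(mu_x^2)
    # at the optimal scale this reduces to (trxx - s*trAR); with s fixed the
    # full quadratic form is required
    sigma2_new <- if (allow_scaling)
      max((trxx - s * trAR) / (3 * Np), 1e-12) else
      max((trxx - 2 * trAR + tryy) / (3 * Np), 1e-12)
    TY <- sweep(s * (Y %*% t(R)), 2, tvec, "+")
    trace <- c(trace, sigma2_new)
    loglik <- e$loglik
    # a vanishing mixture variance means an (essentially) exact fit
    if (abs(sigma2 - sigma2_new) / sigma2 < tolerance || sigma2_new < 1e-10) {
      sigma2 <- sigma2_new
      converged <- TRUE
      break
    }
    sigma2 <- sigma2_new
  }

  out_frame <- if (inherits(fixed, "point_set")) attr(fixed, "frame") else NULL
  structure(list(
    transform = rigid_transform(R, tvec, s, frame = out_frame),
    sigma2 = sigma2, sigma2_trace = trace, iterations = iter,
    converged = converged && !collapsed, collapsed = collapsed,
    loglik = loglik,
    n_moving = M, n_fixed = N, w = w,
    moving = Y, fixed = X, call = match.call()
  ), class = "cpd_rigid")
}

#' CPD E-step posterior matrix
#'
#' The posterior probability that data point `x_n` was generated by centroid
#' `y_m`, under Gaussian kernels of variance `sigma2` and a uniform outlier
#' component of weight `w` (spread over a reference volume of `nrow(fixed)`,
#' the standard convention). Intended for inspection and testing on small
#' instances; the fitting loop accumulates the same quantities in compiled
#' code without materializing the matrix.
#'
#' @param moving m x 3 centroids (already transformed).
#' @param fixed n x 3 data points.
#' @param sigma2 Gaussian variance (mm^2).
#' @param w outlier weight in `[0, 1)`.
#' @return m x n matrix of posteriors; column sums are at most 1, with the
#'   deficit 1 - colSum being the outlier posterior.
#' @export
cpd_posteriors <- function(moving, fixed, sigma2, w = 0) {
  Y <- as.matrix(moving); X <- as.matrix(fixed)
  d2 <- outer(rowSums(Y^2), rowSums(X^2), "+") - 2 * Y %*% t(X)
  num <- exp(-pmax(d2, 0) / (2 * sigma2))
  cc <- if (w > 0)
    (2 * pi * sigma2)^1.5 * (w / (1 - w)) * nrow(Y) / nrow(X) else 0
  sweep(num, 2, colSums(num) + cc, "/")
}

#' @export
print.cpd_rigid <- function(x, ...) {
  cat("Rigid CPD registration\n")
  cat(sprintf("  moving: %d points, fixed: %d points, outlier weight %.3g\n",
              x$n_moving, x$n_fixed, x$w))
  print(x$transform)
  cat(sprintf("  sigma2 %.4g mm^2 after %d iterations (%s)\n", x$sigma2,
              x$iterations, if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
summary.cpd_rigid <- function(object, ...) {
  res <- residuals(object)
  out <- list(
    rotation_deg = rotation_angle_deg(object$transform$rotation),
    translation_mm = sqrt(sum(object$transform$translation^2)),
    scale = object$transform$scale,
    sigma2 = object$sigma2, iterations = object$iterations,
    converged = object$converged, loglik = object$loglik,
    residual_rms_mm = sqrt(mean(res^2)), residual_max_mm = max(res))
  class(out) <- "summary.cpd_rigid"
  out
}

#' @export
print.summary.cpd_rigid <- function(x, ...) {
  cat(sprintf("Rigid CPD fit: rotation %.3f deg, translation %.3f mm, scale %.5f\n",
              x$rotation_deg, x$translation_mm, x$scale))
  cat(sprintf("  sigma2 = %.4g mm^2, loglik = %.4g, %d iterations (%s)\n",
              x$sigma2, x$loglik, x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  data-to-nearest-centroid residuals: rms %.4f mm, max %.4f mm\n",
              x$residual_rms_mm, x$residual_max_mm))
  invisible(x)
}

#' @export
coef.cpd_rigid <- function(object, ...) {
  tr <- object$transform
  c(stats::setNames(as.numeric(t(tr$rotation)),
                    paste0("R", rep(1:3, each = 3), rep(1:3, 3))),
    t1 = tr$translation[1], t2 = tr$translation[2], t3 = tr$translation[3],
    scale = tr$scale)
}

#' Apply a fitted CPD transform to points
#'
#' @param object a fitted `cpd_rigid` object.
#' @param newdata points to map into the fixed frame; defaults to the moving
#'   set used in the fit. A [triangle_mesh()] is transformed whole.
#' @param ... unused.
#' @return Transformed points (or mesh).
#' @export
predict.cpd_rigid <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$moving
  if (inherits(newdata, "triangle_mesh"))
    transform_mesh(object$transform, newdata)
  else apply_transform(object$transform, newdata)
}

#' Distances from each fixed point to its nearest transformed centroid
#'
#' @param object a fitted `cpd_rigid`.
#' @param ... unused.
#' @return Numeric vector (mm), one entry per fixed point.
#' @export
residuals.cpd_rigid <- function(object, ...) {
  TY <- apply_transform(object$transform, object$moving)
  d2 <- outer(rowSums(object$fixed^2), rowSums(TY^2), "+") -
    2 * object$fixed %*% t(TY)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Convergence trace of a CPD fit
#'
#' Plots the Gaussian variance `sigma2` against the EM iteration on a log
#' scale; a flat tail indicates convergence.
#'
#' @param x a fitted `cpd_rigid`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cpd_rigid <- function(x, ...) {
  graphics::plot(seq_along(x$sigma2_trace), x$sigma2_trace, type = "b",
                 log = "y", xlab = "EM iteration",
                 ylab = expression(sigma^2 ~ (mm^2)), ...)
  invisible(x)
}

#' @export
logLik.cpd_rigid <- function(object, ...) {
  structure(object$loglik, df = if (object$transform$scale != 1) 7 else 6,
            class = "logLik")
}
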