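test_that("self-registration of identical sets returns the identity", {
  set.seed(1)
  y <- matrix(rnorm(60) * 10, 20, 3)
  fit <- cpd_rigid(y, y, w = 0)
  d <- transform_discrepancy(fit$transform, rigid_transform())
  expect_lt(d[["rotation_deg"]], 1e-6)
  expect_lt(d[["translation_mm"]], 1e-6)
  expect_true(fit$converged)
})

test_that("E-step posteriors split evenly for a symmetric instance", {
  y <- rbind(c(-1, 0, 0), c(1, 0, 0))
  x <- rbind(c(0, 0.3, 0))
  P <- cpd_posteriors(y, x, sigma2 = 0.5, w = 0)
  expect_equal(as.numeric(P), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("E-step posteriors match brute-force mixture responsibilities", {
  set.seed(7)
  for (i in 1:5) {
    Y <- matrix(rnorm(9), 3, 3)
    X <- matrix(rnorm(12), 4, 3)
    for (w in c(0, 0.1, 0.4)) {
      P <- cpd_posteriors(Y, X, sigma2 = 0.7, w = w)
      expect_lt(max(abs(P - oracle_cpd_posteriors(Y, X, 0.7, w))), 1e-12)
      # compiled sufficient statistics agree with the posterior matrix
      e <- serialreg:::cpp_cpd_estep(X, Y, 0.7, w, nrow(X))
      expect_lt(max(abs(e$P1 - rowSums(P))), 1e-12)
      expect_lt(max(abs(e$Pt1 - colSums(P))), 1e-12)
      expect_lt(max(abs(e$PX - P %*% X)), 1e-12)
    }
  }
})

test_that("a known rigid motion of surface samples is recovered precisely", {
  mesh <- make_bone_like_mesh("femur", detail = "coarse", seed = 2)
  y <- sample_mesh_surface(mesh, 500, seed = 3)$points
  tr <- rigid_transform(rotation_about_axis(c(1, 2, -1), 10), c(5, -4, 5))
  fit <- cpd_rigid(y, apply_transform(tr, y), w = 0.1)
  d <- transform_discrepancy(fit$transform, tr)
  expect_lt(d[["rotation_deg"]], 0.1)
  expect_lt(d[["translation_mm"]], 0.05)
})

test_that("sigma2 is non-increasing after the first iteration", {
  set.seed(21)
  for (i in 1:30) {
    M <- sample(30:80, 1); N <- sample(10:25, 1)
    Y <- matrix(rnorm(3 * M), M) * 10
    tr <- random_rigid_transform(20, 10, seed = i)
    X <- apply_transform(tr, Y[sample(M, N), ]) +
      matrix(rnorm(3 * N, 0, 0.4), N)
    fit <- cpd_rigid(Y, X, w = 0.1)
    s <- fit$sigma2_trace
    # sigma2 is non-increasing up to late-stage convergence wiggle: the EM
    # ascends the likelihood, and sigma2 trades off against the pose at the
    # 1e-4 relative level near the fixed point
    if (length(s) > 2)
      expect_lt(max(diff(s[-1])), 1e-4 * s[1])
  }
})

test_that("estimated rotations are always proper, even near reflections", {
  set.seed(33)
  for (i in 1:20) {
    # nearly planar clouds provoke the reflection ambiguity
    Y <- cbind(matrix(rnorm(80) * 10, 40, 2), rnorm(40, 0, 0.01))
    tr <- random_rigid_transform(170, 5, seed = i)
    X <- apply_transform(tr, Y[sample(40, 20), ]) + matrix(rnorm(60, 0, 0.2), 20)
    fit <- cpd_rigid(Y, X, w = 0.1)
    expect_gt(det(fit$transform$rotation), 0)
    expect_lt(max(abs(crossprod(fit$transform$rotation) - diag(3))), 1e-9)
  }
})

test_that("registration is equivariant under a common rigid motion", {
  set.seed(44)
  mesh <- make_bone_like_mesh("femur", detail = "coarse", seed = 5)
  Y <- sample_mesh_surface(mesh, 200, seed = 6)$points
  tr <- rigid_transform(rotation_about_axis(c(0, 1, 1), 8), c(3, 1, -2))
  X <- apply_transform(tr, sample_mesh_surface(mesh, 60, seed = 7)$points)
  base <- cpd_rigid(Y, X, w = 0.1)
  for (i in 1:20) {
    Q <- random_rigid_transform(90, 30, seed = 100 + i)
    fit <- cpd_rigid(apply_transform(Q, Y), apply_transform(Q, X), w = 0.1)
    conj <- compose_transforms(Q, compose_transforms(base$transform,
                                                     invert_transform(Q)))
    d <- transform_discrepancy(fit$transform, conj)
    expect_lt(d[["rotation_deg"]], 1e-6)
    expect_lt(d[["translation_mm"]], 1e-6)
  }
})

test_that("cpd_rigid validates inputs and flags non-convergence", {
  line <- cbind(1:10, 0, 0)
  good <- matrix(rnorm(30), 10, 3)
  expect_error(cpd_rigid(line, good, w = 0), "collinear")
  expect_error(cpd_rigid(good, line, w = 0), "collinear")
  expect_error(cpd_rigid(good[1:3, ], good, w = 0), "at least 4")
  expect_error(cpd_rigid(good, good, w = 1.2), "\\[0, 1\\)")

  fit <- cpd_rigid(good, good + 50, w = 0, max_iterations = 2)
  expect_false(fit$converged)
  expect_lte(fit$iterations, 2)
})

test_that("cpd_rigid S3 methods behave like a fitted model object", {
  set.seed(10)
  y <- matrix(rnorm(90) * 10, 30, 3)
  tr <- rigid_transform(rotation_about_axis(c(1, 0, 0), 12), c(1, 2, 3))
  fit <- cpd_rigid(y, apply_transform(tr, y), w = 0)
  expect_s3_class(fit, "cpd_rigid")
  expect_named(coef(fit)[10:13], c("t1", "t2", "t3", "scale"))
  pred <- predict(fit)
  expect_lt(max(abs(pred - apply_transform(tr, y))), 1e-4)
  expect_lt(max(residuals(fit)), 1e-4)
  expect_output(print(fit), "Rigid CPD")
  expect_output(print(summary(fit)), "residuals")
  expect_s3_class(logLik(fit), "logLik")
})

test_that("scaling is estimated only when enabled", {
  set.seed(12)
  y <- matrix(rnorm(90) * 10, 30, 3)
  x <- apply_transform(rigid_transform(diag(3), c(1, 1, 1), scale = 1), 1.07 * y)
  fit <- cpd_rigid(y, x, w = 0, allow_scaling = TRUE)
  expect_equal(fit$transform$scale, 1.07, tolerance = 1e-3)
  fit1 <- cpd_rigid(y, x, w = 0)
  expect_identical(fit1$transform$scale, 1)
})
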