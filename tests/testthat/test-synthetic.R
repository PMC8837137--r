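test_that("ellipsoid meshes match the analytic volume", {
  e <- make_bone_like_mesh("ellipsoid", c(30, 25, 20), detail = "fine")
  v_true <- 4 / 3 * pi * 30 * 25 * 20
  expect_lt(abs(mesh_volume(e) - v_true) / v_true, 0.02)
})

test_that("bone-like meshes are closed, outward and genus 0 across seeds", {
  for (seed in 1:4) {
    for (kind in c("femur", "tibia")) {
      m <- make_bone_like_mesh(kind, detail = "coarse", seed = seed)
      v <- validate_mesh(m)
      expect_true(v$closed, label = paste(kind, seed, "closed"))
      expect_true(v$oriented, label = paste(kind, seed, "oriented"))
      expect_true(v$genus0, label = paste(kind, seed, "genus0"))
      expect_gt(v$volume, 0)
    }
  }
})

test_that("different seeds give different surfaces with the same topology", {
  a <- make_bone_like_mesh("femur", detail = "coarse", seed = 1)
  b <- make_bone_like_mesh("femur", detail = "coarse", seed = 2)
  expect_gt(mean_absolute_distance(a, b, 1000), 0)
  expect_true(validate_mesh(b)$genus0)
})

test_that("segmentation perturbation has the stated amplitude and keeps topology", {
  m <- make_bone_like_mesh("femur", detail = "coarse", seed = 3)
  expect_identical(perturb_segmentation(m, 0, seed = 1), m)

  mads <- vapply(1:8, function(s)
    mean_absolute_distance(m, perturb_segmentation(m, 0.3, 10, seed = s), 2000),
    0)
  expect_true(all(mads > 0.15 & mads < 0.45))
  p <- perturb_segmentation(m, 0.3, 10, seed = 1)
  expect_true(validate_mesh(p)$closed)
  expect_error(perturb_segmentation(m, 25, 25, seed = 1), "amplitude")
})

test_that("zero-noise operator points lie exactly on the surface", {
  m <- make_bone_like_mesh("tibia", detail = "coarse", seed = 4)
  ps <- simulate_operator_points(m, 200, operator_model(0, 0), seed = 5)
  expect_lt(max(point_to_surface_distances(ps, m)), 1e-9)
})

test_that("operator noise produces the expected point-to-surface spread", {
  m <- make_bone_like_mesh("femur", detail = "coarse", seed = 6)
  # isotropic sd 0.3: distance to surface is approximately half-normal in
  # the normal component; RMS near 0.3, mean near 0.3 * sqrt(2/pi)
  rmss <- vapply(1:10, function(s) {
    ps <- simulate_operator_points(m, 500, operator_model(0.3, 0), seed = s)
    sqrt(mean(point_to_surface_distances(ps, m)^2))
  }, 0)
  expect_true(all(rmss > 0.25 & rmss < 0.35))
})

test_that("a 4000-point pool covers the surface homogeneously", {
  m <- make_bone_like_mesh("femur", detail = "coarse", seed = 7)
  ps <- simulate_operator_points(m, 4000, operator_model(0, 0), seed = 8)
  co <- unclass(ps)
  nn <- vapply(seq_len(500), function(i) {
    d2 <- rowSums(sweep(co, 2, co[i, ])^2)
    sqrt(min(d2[-i]))
  }, 0)
  expect_lt(stats::sd(nn) / mean(nn), 0.6)
})

test_that("partial placement restricts points to the distal surface", {
  m <- make_bone_like_mesh("femur", detail = "coarse", seed = 9)
  ps <- simulate_operator_points(m, 100, operator_model(0, 0),
                                 region = "partial", region_fraction = 0.4,
                                 seed = 10)
  # distal = +z end for this generator
  expect_gt(min(unclass(ps)[, 3]), stats::quantile(m$vertices[, 3], 0.35))
  expect_error(simulate_operator_points(m, 10, operator_model(0, 0),
                                        region = "partial",
                                        region_fraction = 0), "fraction")
})

test_that("ground-truth cases are internally consistent", {
  cs <- make_ground_truth_case("femur", seed = 11, detail = "coarse")
  # fiducials related exactly by the true transform
  fit <- fit_rigid_corresponding(cs$fiducials_source, cs$fiducials_target)
  expect_lt(max_transform_diff(fit, cs$true_transform), 1e-9)
  # fiducials strictly inside the model
  expect_true(all(points_in_mesh(cs$fiducials_source, cs$model)))
  # reference sits near the moved model at the perturbation amplitude
  moved <- transform_mesh(cs$true_transform, cs$model)
  mad <- mean_absolute_distance(moved, cs$reference, 2000)
  expect_true(mad > 0.1 && mad < 0.5)
  expect_identical(nrow(cs$attraction_candidates), 4000L)
})

test_that("zero-noise cases are solved to the oracle transform", {
  cs <- make_ground_truth_case("tibia", seed = 12, detail = "coarse",
                               operator = operator_model(0, 0),
                               perturbation_amplitude_mm = 0,
                               n_candidates = 300)
  pts <- subsample_points(cs$attraction_candidates, 128, seed = 13)
  fit <- register_model_to_points(cs$model, pts, seed = 14)
  d <- transform_discrepancy(fit$transform, cs$true_transform)
  expect_lt(d[["rotation_deg"]], 0.1)
  expect_lt(d[["translation_mm"]], 0.05)
})

test_that("generated meshes always satisfy the metric-module preconditions", {
  for (seed in 1:6) {
    m <- make_bone_like_mesh(if (seed %% 2) "femur" else "tibia",
                             detail = "coarse", seed = seed)
    expect_silent(serialreg:::require_closed_mesh(m))
  }
})
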