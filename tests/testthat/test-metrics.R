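test_that("point-to-surface distances are exact for closed forms", {
  m <- cube_mesh(10)
  expect_equal(max(point_to_surface_distances(m$vertices, m)), 0)
  # height above a face interior
  expect_equal(point_to_surface_distances(rbind(c(5, 5, 13)), m), 3,
               tolerance = 1e-12)
  # beyond an edge and a corner
  expect_equal(point_to_surface_distances(rbind(c(-3, 5, 14)), m), 5,
               tolerance = 1e-12)
  expect_equal(point_to_surface_distances(rbind(c(-1, -2, 12)), m), 3,
               tolerance = 1e-12)
})

test_that("distances agree with an exhaustive per-triangle oracle", {
  mesh <- make_bone_like_mesh("ellipsoid", c(12, 10, 8), detail = "coarse")
  set.seed(31)
  pts <- matrix(rnorm(60, 0, 12), 20, 3)
  d <- point_to_surface_distances(pts, mesh)
  for (i in seq_len(nrow(pts)))
    expect_equal(d[i], oracle_point_mesh_dist(pts[i, ], mesh),
                 tolerance = 1e-9)
})

test_that("MAD is zero for identical meshes and exact for sphere offsets", {
  mesh <- make_bone_like_mesh("femur", detail = "coarse", seed = 1)
  expect_lt(mean_absolute_distance(mesh, mesh, 1000), 1e-9)

  s1 <- sphere_mesh(10)
  s2 <- sphere_mesh(10.5)
  expect_equal(mean_absolute_distance(s1, s2, 10000), 0.5, tolerance = 0.02)
})

test_that("MAD is exactly symmetric and monotone in translation offset", {
  a <- make_bone_like_mesh("tibia", detail = "coarse", seed = 2)
  b <- perturb_segmentation(a, 0.4, 12, seed = 3)
  expect_identical(mean_absolute_distance(a, b, 2000),
                   mean_absolute_distance(b, a, 2000))

  cube <- cube_mesh(10)
  mads <- vapply(c(0.5, 1, 2, 4), function(dx) {
    moved <- transform_mesh(rigid_transform(translation = c(dx, 0, 0)), cube)
    mean_absolute_distance(cube, moved, 4000)
  }, 0)
  expect_true(all(diff(mads) > 0))
})

test_that("voxelization counts exactly on aligned grids and converges on spheres", {
  cube <- cube_mesh(10)
  g <- image_grid(c(0.5, 0.5, 0.5), c(1, 1, 1), c(10, 10, 10))
  expect_identical(sum(voxelize_closed_mesh(cube, g)), 1000L)

  s <- sphere_mesh(10)
  gs <- serialreg:::grid_covering(list(s), 0.5)
  vol <- sum(voxelize_closed_mesh(s, gs)) * 0.5^3
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)

  # first-order convergence: error roughly halves with the voxel size
  err <- vapply(c(1, 0.5), function(h) {
    gh <- serialreg:::grid_covering(list(s), h)
    abs(sum(voxelize_closed_mesh(s, gh)) * h^3 - 4 / 3 * pi * 1000)
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("open meshes are rejected with the boundary-edge count", {
  cube <- cube_mesh(10)
  open <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  g <- image_grid(c(0, 0, 0), c(1, 1, 1), c(12, 12, 12))
  expect_error(voxelize_closed_mesh(open, g), "closed mesh \\(3")
  expect_error(dice_index(open, cube), "closed")
})

test_that("Dice matches closed-form overlaps and is symmetric", {
  c1 <- cube_mesh(10)
  expect_equal(dice_index(c1, c1, 0.25), 1, tolerance = 1e-12)
  expect_equal(dice_index(c1, cube_mesh(10, c(100, 0, 0)), 0.5), 0)
  d <- dice_index(c1, cube_mesh(10, c(5, 0, 0)), 0.25)
  expect_equal(d, 0.5, tolerance = 0.01 * 0.5)
  # symmetry to numerical identity
  a <- sphere_mesh(10, "medium")
  b <- transform_mesh(rigid_transform(translation = c(2, 1, 0)), a)
  expect_equal(dice_index(a, b, 0.5), dice_index(b, a, 0.5),
               tolerance = 1e-12)
})

test_that("Dice is stable under grid refinement on smooth shapes", {
  a <- sphere_mesh(10, "medium")
  b <- transform_mesh(rigid_transform(translation = c(1, 0.5, 0.25)), a)
  d1 <- dice_index(a, b, 1)
  d2 <- dice_index(a, b, 0.5)
  expect_lt(abs(d1 - d2), 0.005)
})

test_that("compare_models bundles both metrics with their settings", {
  cube <- cube_mesh(10)
  rep0 <- compare_models(cube, cube, 2000, 0.5)
  expect_equal(rep0$mad_mm, 0, tolerance = 1e-9)
  expect_equal(rep0$dice, 1, tolerance = 1e-12)
  expect_identical(rep0$sample_count, 2000L)
  expect_identical(rep0$voxel_size_mm, 0.5)

  # cube shifted by 1 mm along x; per direction: the leading face is
  # uniformly 1 mm away, the trailing face sees min(1, dist to nearest side)
  # with mean int_0^1 (1 - s/5)^2 ds = 0.8133, and the four side faces
  # contribute (1/10) int_0^1 s ds = 0.05 each
  moved <- transform_mesh(rigid_transform(translation = c(1, 0, 0)), cube)
  rep1 <- compare_models(moved, cube, 20000, 0.25)
  mad_true <- (1 + 0.81333 + 4 * 0.05) / 6
  expect_equal(rep1$mad_mm, mad_true, tolerance = 0.02)
  dice_true <- 2 * (9 * 10 * 10) / (1000 + 1000)
  expect_equal(rep1$dice, dice_true, tolerance = 0.01)
  expect_output(print(rep1), "MAD")
})

test_that("image_grid validates its fields", {
  expect_error(image_grid(c(0, 0, 0), c(0.5, -1, 0.5), c(10, 10, 10)),
               "positive")
  expect_error(image_grid(c(0, 0, 0), c(1, 1, 1), c(0, 5, 5)), ">= 1")
})
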