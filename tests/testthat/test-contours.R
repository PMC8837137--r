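circle_contour <- function(r = 10, k = 24, compensate = TRUE) {
  th <- 2 * pi * (seq_len(k) - 1) / k
  s <- if (compensate) 3 / (2 + cos(2 * pi / k)) else 1
  bspline_contour(cbind(r * s * cos(th), r * s * sin(th)))
}

test_that("contour evaluation: linear case, periodicity, circle fidelity", {
  lin <- bspline_contour(rbind(c(0, 0), c(2, 0)), degree = 1, closed = FALSE)
  expect_equal(as.numeric(evaluate_contour(lin, 0.5)), c(1, 0),
               tolerance = 1e-12)

  cc <- circle_contour(10, compensate = FALSE)
  expect_lt(max(abs(evaluate_contour(cc, 0) - evaluate_contour(cc, 1 - 1e-9))),
            1e-6)

  # control points on a circle of radius 10: best-fit circle deviation < 2%
  p <- evaluate_contour(cc, (0:255) / 256)
  r <- sqrt(rowSums(p^2))
  expect_lt(max(abs(r - mean(r))) / mean(r), 0.02)
})

test_that("contour evaluation rejects out-of-domain t for open curves", {
  lin <- bspline_contour(rbind(c(0, 0), c(2, 0)), degree = 1, closed = FALSE)
  expect_error(evaluate_contour(lin, 1.5), "\\[0, 1\\]")
  # closed curves wrap
  cc <- circle_contour()
  expect_equal(evaluate_contour(cc, 1.25), evaluate_contour(cc, 0.25),
               tolerance = 1e-12)
})

test_that("resample_contour is arc-length uniform and perimeter-faithful", {
  cc <- circle_contour(10)
  p4 <- resample_contour(cc, 4)
  ang <- atan2(p4[, 2], p4[, 1])
  gaps <- sort((diff(c(ang, ang[1] + 2 * pi)) %% (2 * pi)))
  expect_true(all(abs(gaps - pi / 2) < 1e-3))

  dense_per <- contour_perimeter(cc)
  for (n in c(64, 128)) {
    pn <- resample_contour(cc, n)
    per <- sum(sqrt(rowSums((pn[c(2:n, 1), ] - pn)^2)))
    expect_lt(abs(per - dense_per) / dense_per, 0.01)
    seg <- sqrt(rowSums((pn[c(2:n, 1), ] - pn)^2))
    expect_true(all(seg[-1] / seg[-n] > 0.9 & seg[-1] / seg[-n] < 1.1))
  }

  degen <- bspline_contour(matrix(0, 4, 2))
  expect_error(resample_contour(degen, 16), "degenerate")
  expect_error(resample_contour(cc, 2), ">= 3")
})

test_that("lofting a circular stack reproduces cylinder volume and area", {
  st <- contour_stack(rep(list(circle_contour(10)), 11), seq(0, 50, 5))
  m <- loft_contour_stack(st, 128)
  expect_lt(abs(mesh_volume(m) - pi * 100 * 50) / (pi * 100 * 50), 0.01)
  a_true <- 2 * pi * 10 * 50 + 2 * pi * 100
  expect_lt(abs(mesh_area(m) - a_true) / a_true, 0.02)
  v <- validate_mesh(m)
  expect_true(v$closed && v$oriented && v$genus0)
})

test_that("two square contours loft into a closed box", {
  sq <- bspline_contour(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
                        degree = 1)
  m <- loft_contour_stack(contour_stack(list(sq, sq), c(0, 5)), 32)
  v <- validate_mesh(m)
  expect_true(v$closed)
  expect_gt(v$volume, 0)
})

test_that("lofted volume converges toward the analytic value as sampling doubles", {
  cyl_err <- function(n) {
    st <- contour_stack(rep(list(circle_contour(10)), 6), seq(0, 50, 10))
    abs(mesh_volume(loft_contour_stack(st, n)) - pi * 100 * 50)
  }
  errs <- vapply(c(16, 32, 64, 128), cyl_err, 0)
  expect_true(all(diff(errs) < 0))

  cone <- lapply(seq(0, 1, length.out = 6), function(u)
    circle_contour(10 * (1 - 0.9 * u)))
  cone_err <- function(n) {
    st <- contour_stack(cone, seq(0, 30, 6))
    v_true <- pi * 30 / 3 * (10^2 + 10 * 1 + 1^2)  # frustum 10 -> 1
    abs(mesh_volume(loft_contour_stack(st, n)) - v_true)
  }
  cerrs <- vapply(c(16, 32, 64, 128), cone_err, 0)
  expect_true(all(diff(cerrs) < 0))
})

test_that("contour stacks validate their invariants", {
  cc <- circle_contour()
  expect_error(contour_stack(list(cc, cc), c(0, 0)), "monotone")
  expect_error(contour_stack(list(cc), 0), "at least 2")
  expect_error(bspline_contour(rbind(c(0, 0), c(1, 1)), degree = 3),
               "control points")
})
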