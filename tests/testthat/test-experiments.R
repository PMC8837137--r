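test_that("subsampling draws distinct pool members deterministically", {
  pool <- point_set(matrix(rnorm(300), 100, 3), "target",
                    labels = sprintf("p%03d", 1:100))
  all_of_it <- subsample_points(pool, 100, seed = 1)
  expect_identical(sort(attr(all_of_it, "labels")), sort(attr(pool, "labels")))

  s32 <- subsample_points(pool, 32, seed = 2)
  expect_identical(nrow(s32), 32L)
  expect_true(all(attr(s32, "labels") %in% attr(pool, "labels")))
  expect_false(anyDuplicated(attr(s32, "labels")) > 0)

  expect_identical(subsample_points(pool, 32, seed = 2), s32)
  expect_false(identical(subsample_points(pool, 32, seed = 3), s32))
  expect_error(subsample_points(pool, 101, seed = 1), "pool")
})

test_that("rank-sum p-values match closed forms and exact enumeration", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(wilcoxon_rank_sum(x, x + 1e-9 * 0), 1, tolerance = 1e-9)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12)), 0.1,
               tolerance = 1e-12)

  set.seed(41)
  for (i in 1:20) {
    m <- sample(2:4, 1); n <- sample(2:4, 1)
    xx <- rnorm(m); yy <- rnorm(n, 0.5)
    expect_equal(wilcoxon_rank_sum(xx, yy), oracle_rank_sum_p(xx, yy),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(1, c(1, 2)), ">= 2")
})

test_that("signed-rank p-values match closed forms and exact enumeration", {
  expect_equal(wilcoxon_signed_rank(c(-2, 2, -1, 1, -3, 3)), 1,
               tolerance = 1e-9)
  expect_equal(wilcoxon_signed_rank(seq(0.5, 5, 0.5)), 2 / 2^10,
               tolerance = 1e-12)

  set.seed(42)
  for (i in 1:20) {
    d <- rnorm(sample(4:10, 1), 0.3)
    expect_equal(wilcoxon_signed_rank(d), oracle_signed_rank_p(d),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_signed_rank(c(0, 0)), "nonzero")
})

test_that("Bonferroni adjustment caps at one and respects the family size", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 5), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.7)), c(0.4, 1))
  expect_identical(bonferroni_adjust(0.123, 1), 0.123)
  expect_error(bonferroni_adjust(1.4, 2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2, 0.3), 2), "family_size")
})

test_that("median and quartiles follow the linear-interpolation convention", {
  expect_equal(unname(summarize_median_iqr(1:5)), c(3, 2, 4))
  expect_equal(unname(summarize_median_iqr(rep(7, 4))), c(7, 7, 7))
  set.seed(43)
  v <- rnorm(37)
  s <- sort(v)
  direct <- function(p) {
    h <- (length(v) - 1) * p
    lo <- floor(h)
    s[lo + 1] * (1 - (h - lo)) + s[pmin(lo + 2, length(v))] * (h - lo)
  }
  expect_equal(unname(summarize_median_iqr(v)),
               c(direct(0.5), direct(0.25), direct(0.75)), tolerance = 1e-12)
  expect_error(summarize_median_iqr(numeric(0)), "empty")
})

small_cfg <- function(seed = 7) {
  study_config(point_counts = c(32L, 64L), repeats_per_count = 2L,
               n_cases = 1L, master_seed = seed, detail = "coarse",
               mad_samples = 1000L, voxel_size_mm = 1.5,
               moving_sample_count = 800L)
}

test_that("the point-count harness produces the full record grid", {
  cfg <- small_cfg()
  cases <- generate_study_cases(cfg)
  res <- run_point_count_study(cases, cfg)
  expect_identical(nrow(res$records),
                   length(cases) * 2L * 2L)
  expect_identical(nrow(res$summary), 2L * 2L)  # kinds x counts
  expect_true(all(res$tests$p_adjusted >= res$tests$p_raw - 1e-12))
  expect_true(all(res$records$mad_mm[!res$records$failed] > 0))
  expect_output(print(res), "study_result")
})

test_that("studies are bit-identical under the same master seed", {
  cfg <- small_cfg(9)
  r1 <- run_point_count_study(generate_study_cases(cfg), cfg)
  r2 <- run_point_count_study(generate_study_cases(cfg), cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$tests, r2$tests)
})

test_that("method comparison solves degenerate zero-noise regimes exactly", {
  cfg <- study_config(n_cases = 1L, master_seed = 3, detail = "coarse",
                      mad_samples = 1000L, voxel_size_mm = 1.5,
                      moving_sample_count = 800L)
  cases <- lapply(c("femur", "tibia"), function(k)
    make_ground_truth_case(k, seed = 50 + nchar(k),
                           operator = operator_model(0, 0),
                           perturbation_amplitude_mm = 0,
                           detail = "coarse", n_candidates = 300L))
  res <- run_method_comparison(cases, point_count = 128L, config = cfg)
  expect_identical(nrow(res$records), 6L)
  expect_true(all(res$records$rotation_err_deg < 0.1))
  expect_true(all(res$records$translation_err_mm < 0.05))
  gold <- res$records[res$records$method == "gold", ]
  expect_true(all(gold$rotation_err_deg < 1e-5))
})

test_that("the gold route is immune to surface noise given clean fiducials", {
  cs <- make_ground_truth_case("femur", seed = 77, detail = "coarse",
                               perturbation_amplitude_mm = 0.4)
  fit <- fit_rigid_corresponding(cs$fiducials_source, cs$fiducials_target)
  expect_lt(max_transform_diff(fit, cs$true_transform), 1e-9)
})

test_that("gold method requires fiducials", {
  cs <- make_ground_truth_case("femur", seed = 78, detail = "coarse")
  cs$fiducials_source <- NULL
  expect_error(run_method_comparison(list(cs), methods = c("expert", "gold"),
                                     config = small_cfg()),
               "fiducials")
})
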