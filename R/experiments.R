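#' Study configuration
#'
#' Defaults mirror the attraction-point-count design: counts 32...1024 in
#' doublings, 10 repeats per count, 10 cases per bone kind. The metric
#' settings are the problem sizes the study harness evaluates each
#' registration with.
#'
#' @param point_counts strictly increasing attraction-point counts.
#' @param repeats_per_count random subsample repeats per count.
#' @param n_cases ground-truth cases (knees) per bone kind.
#' @param kinds bone kinds simulated.
#' @param regime `"intra"` (same-protocol: 0.3 mm placement noise, no normal
#'   bias) or `"inter"` (intermodality: 0.6 mm noise plus 0.2 mm normal
#'   bias).
#' @param master_seed single seed from which every case, subsample and
#'   sampling seed is derived; identical `master_seed` reproduces study
#'   tables bit-identically.
#' @param w,moving_sample_count CPD settings used for every registration.
#' @param mad_samples,voxel_size_mm metric problem sizes used per record.
#' @param detail mesh tessellation for generated cases.
#' @return Object of class `study_config`.
#' @export
study_config <- function(point_counts = c(32L, 64L, 128L, 256L, 512L, 1024L),
                         repeats_per_count = 10L, n_cases = 10L,
                         kinds = c("femur", "tibia"),
                         regime = c("intra", "inter"), master_seed = 1L,
                         w = 0.1, moving_sample_count = 2000L,
                         mad_samples = 2000L, voxel_size_mm = 1.0,
                         detail = "medium") {
  regime <- match.arg(regime)
  point_counts <- as.integer(point_counts)
  if (any(diff(point_counts) <= 0))
    stop("point_counts must be strictly increasing")
  structure(list(point_counts = point_counts,
                 repeats_per_count = as.integer(repeats_per_count),
                 n_cases = as.integer(n_cases), kinds = kinds,
                 regime = regime, master_seed = as.integer(master_seed),
                 w = w, moving_sample_count = as.integer(moving_sample_count),
                 mad_samples = as.integer(mad_samples),
                 voxel_size_mm = voxel_size_mm, detail = detail),
            class = "study_config")
}

regime_operator <- function(regime) {
  if (regime == "inter") operator_model(placement_noise_sd = 0.6,
                                        surface_bias_sd = 0.2)
  else operator_model(placement_noise_sd = 0.3, surface_bias_sd = 0)
}

#' Generate the ground-truth cases of a study
#'
#' @param config a [study_config()].
#' @param ... overrides passed to [make_ground_truth_case()].
#' @return List of `ground_truth_case` objects
#'   (`n_cases * length(kinds)` of them).
#' @export
generate_study_cases <- function(config, ...) {
  stopifnot(inherits(config, "study_config"))
  op <- regime_operator(config$regime)
  cases <- list()
  k <- 0L
  for (kind in config$kinds) for (i in seq_len(config$n_cases)) {
    k <- k + 1L
    cases[[k]] <- make_ground_truth_case(
      kind = kind, seed = derive_seed(config$master_seed, 1000L + k),
      operator = op, detail = config$detail, ...)
  }
  cases
}

#' Random subsample of an attraction-point pool
#'
#' @param pool a [point_set()] (or matrix).
#' @param n points to draw, uniformly without replacement.
#' @param seed integer seed; the draw is deterministic per seed.
#' @return A [point_set()] of n distinct pool members.
#' @export
subsample_points <- function(pool, n, seed = 1L) {
  m <- if (inherits(pool, "point_set")) ps_coords(pool) else as.matrix(pool)
  if (n > nrow(m)) stop("cannot subsample more points than the pool holds")
  idx <- with_seed(seed, sample.int(nrow(m), n))
  frame <- if (inherits(pool, "point_set")) attr(pool, "frame") else "world"
  labels <- attr(pool, "labels")
  point_set(m[idx, , drop = FALSE], frame = frame,
            labels = if (!is.null(labels)) labels[idx])
}

case_metrics <- function(registered_mesh, case, config, seed) {
  rep_ <- compare_models(registered_mesh, case$reference,
                         samples_per_surface = config$mad_samples,
                         voxel_size_mm = config$voxel_size_mm, seed = seed)
  rep_
}

#' Attraction-point-count study
#'
#' For every case, point count and repeat: draw that many attraction points
#' at random from the case's candidate pool, register the model to them,
#' move the model into the target frame and score it against the reference
#' segmentation (MAD, Dice) and against the known motion (rotation /
#' translation discrepancy). At the defaults this produces
#' `n_cases * 6 counts * 10 repeats = 600` records per bone kind. Summaries
#' are median (Q1, Q3); consecutive counts are compared with two-sided
#' Wilcoxon rank-sum tests, Bonferroni-adjusted within each bone-and-metric
#' family.
#'
#' @param cases list of `ground_truth_case` objects
#'   (e.g. [generate_study_cases()]).
#' @param config a [study_config()].
#' @return Object of class `study_result`: list with `records` (long-form
#'   data frame), `summary` (median/Q1/Q3 rows), `tests` (raw and
#'   Bonferroni-adjusted p-values, all repeats pooled),
#'   `tests_per_case_median` (the same comparisons on one median per case,
#'   so repeats of a knee never count as independent observations),
#'   `failed` count, and `quartile_convention`.
#' @export
run_point_count_study <- function(cases, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  rows <- vector("list", length(cases) * length(config$point_counts) *
                   config$repeats_per_count)
  r <- 0L
  task <- 0L
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    if (nrow(case$attraction_candidates) < max(config$point_counts))
      stop("candidate pool smaller than the largest point count")
    fps_seed <- derive_seed(config$master_seed, 500000L + ci)
    samples <- farthest_point_sample(case$model, config$moving_sample_count,
                                     seed = fps_seed)
    for (n_pts in config$point_counts) for (rep_i in seq_len(config$repeats_per_count)) {
      task <- task + 1L
      sseed <- derive_seed(config$master_seed, 2L * task)
      pts <- subsample_points(case$attraction_candidates, n_pts, seed = sseed)
      r <- r + 1L
      row <- data.frame(case = ci, kind = case$kind, n_points = n_pts,
                        repeat_ = rep_i, mad_mm = NA_real_, dice = NA_real_,
                        rotation_err_deg = NA_real_,
                        translation_err_mm = NA_real_, converged = NA,
                        failed = FALSE, stringsAsFactors = FALSE)
      fit <- tryCatch({
        f <- cpd_rigid(samples, pts, w = config$w)
        f$transform <- refine_to_surface(case$model, pts, f$transform)
        f
      }, error = function(e) e)
      if (inherits(fit, "error")) {
        row$failed <- TRUE
        rows[[r]] <- row
        next
      }
      reg_mesh <- transform_mesh(fit$transform, case$model)
      met <- case_metrics(reg_mesh, case, config,
                          seed = derive_seed(config$master_seed, 2L * task + 1L))
      td <- transform_discrepancy(fit$transform, case$true_transform)
      row$mad_mm <- met$mad_mm; row$dice <- met$dice
      row$rotation_err_deg <- td[["rotation_deg"]]
      row$translation_err_mm <- td[["translation_mm"]]
      row$converged <- fit$converged
      rows[[r]] <- row
    }
  }
  records <- do.call(rbind, rows)
  summarize_point_count_study(records, config)
}

summarize_point_count_study <- function(records, config) {
  ok <- records[!records$failed, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(ok, list(ok$kind, ok$n_points), drop = TRUE),
    function(d) {
      m <- summarize_median_iqr(d$mad_mm); dd <- summarize_median_iqr(d$dice)
      data.frame(kind = d$kind[1], n_points = d$n_points[1], n = nrow(d),
                 mad_median = m[1], mad_q1 = m[2], mad_q3 = m[3],
                 dice_median = dd[1], dice_q1 = dd[2], dice_q3 = dd[3],
                 stringsAsFactors = FALSE)
    }))
  summ <- summ[order(summ$kind, summ$n_points), ]
  rownames(summ) <- NULL

  counts <- sort(unique(ok$n_points))
  fam <- length(counts) - 1L
  consecutive_tests <- function(value_of) {
    tests <- list()
    for (kind in unique(ok$kind)) for (metric in c("mad_mm", "dice")) {
      p_raw <- vapply(seq_len(fam), function(i) {
        x <- value_of(kind, metric, counts[i])
        y <- value_of(kind, metric, counts[i + 1L])
        if (length(x) < 2L || length(y) < 2L) NA_real_ else
          wilcoxon_rank_sum(x, y)
      }, 0)
      tests[[length(tests) + 1L]] <- data.frame(
        kind = kind, metric = metric, from = counts[-length(counts)],
        to = counts[-1L], p_raw = p_raw,
        p_adjusted = bonferroni_adjust(p_raw, fam), stringsAsFactors = FALSE)
    }
    do.call(rbind, tests)
  }
  # primary: all repeats pooled (mirrors summaries over cases x repeats);
  # variant: one median per case, so repeats of a knee never count as
  # independent observations
  pooled <- consecutive_tests(function(kind, metric, n)
    ok[ok$kind == kind & ok$n_points == n, metric])
  per_case <- consecutive_tests(function(kind, metric, n) {
    d <- ok[ok$kind == kind & ok$n_points == n, ]
    as.numeric(tapply(d[[metric]], d$case, stats::median))
  })
  structure(list(records = records, summary = summ,
                 tests = pooled, tests_per_case_median = per_case,
                 failed = sum(records$failed),
                 quartile_convention = "linear interpolation (R type 7)",
                 config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d records (%d failed)\n", nrow(x$records), x$failed))
  s <- x$summary
  s$mad <- sprintf("%.2f (%.2f, %.2f)", s$mad_median, s$mad_q1, s$mad_q3)
  if ("dice_median" %in% names(s))
    s$dice <- sprintf("%.3f (%.3f, %.3f)", s$dice_median, s$dice_q1, s$dice_q3)
  keep <- intersect(c("kind", "n_points", "method", "n", "mad", "dice"), names(s))
  print(s[, keep], row.names = FALSE)
  invisible(x)
}

register_by_method <- function(case, method, point_count, config, task_seed) {
  switch(method,
    expert = {
      pts <- subsample_points(case$attraction_candidates, point_count,
                              seed = task_seed)
      fit <- register_model_to_points(case$model, pts,
                                      moving_sample_count = config$moving_sample_count,
                                      seed = derive_seed(task_seed, 1L),
                                      w = config$w)
      fit$transform
    },
    gold = fit_rigid_corresponding(case$fiducials_source, case$fiducials_target),
    substitution = {
      fit <- register_model_to_model(case$model, case$reference,
                                     moving_sample_count = config$moving_sample_count,
                                     fixed_sample_count = config$moving_sample_count,
                                     seed = derive_seed(task_seed, 2L),
                                     w = config$w)
      fit$transform
    },
    stop(sprintf("unknown method '%s'", method)))
}

#' Registration-method comparison study
#'
#' Registers each case with the requested methods — `"expert"` (attraction
#' points at `point_count`, the ideal-count choice of 128 by default),
#' `"gold"` (fiducial-marker Kabsch fit) and `"substitution"` (whole-model
#' CPD) — and scores every registration against the reference segmentation
#' and the known motion. Methods are compared pairwise on MAD and Dice with
#' two-sided Wilcoxon signed-rank tests across cases.
#'
#' @param cases list of `ground_truth_case` objects.
#' @param methods subset of `c("expert", "gold", "substitution")`; `"gold"`
#'   requires fiducials in every case.
#' @param point_count attraction points used by the expert method.
#' @param config a [study_config()].
#' @return A `study_result` with one record per case and method, a
#'   median (Q1, Q3) summary per kind and method, and the signed-rank test
#'   table (every non-reference method against the first method listed).
#' @export
run_method_comparison <- function(cases,
                                  methods = c("expert", "gold", "substitution"),
                                  point_count = 128L,
                                  config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  methods <- match.arg(methods, c("expert", "gold", "substitution"),
                       several.ok = TRUE)
  if ("gold" %in% methods &&
      any(vapply(cases, function(cs) is.null(cs$fiducials_source), TRUE)))
    stop("gold method requested but cases carry no fiducials")
  rows <- list()
  for (ci in seq_along(cases)) {
    case <- cases[[ci]]
    for (method in methods) {
      task_seed <- derive_seed(config$master_seed,
                               700000L + 10L * ci + match(method, methods))
      tr <- tryCatch(register_by_method(case, method, point_count, config,
                                        task_seed),
                     error = function(e) e)
      row <- data.frame(case = ci, kind = case$kind, method = method,
                        mad_mm = NA_real_, dice = NA_real_,
                        rotation_err_deg = NA_real_,
                        translation_err_mm = NA_real_, failed = FALSE,
                        stringsAsFactors = FALSE)
      if (inherits(tr, "error")) {
        row$failed <- TRUE
      } else {
        reg_mesh <- transform_mesh(tr, case$model)
        met <- case_metrics(reg_mesh, case, config,
                            seed = derive_seed(task_seed, 3L))
        td <- transform_discrepancy(tr, case$true_transform)
        row$mad_mm <- met$mad_mm; row$dice <- met$dice
        row$rotation_err_deg <- td[["rotation_deg"]]
        row$translation_err_mm <- td[["translation_mm"]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  records <- do.call(rbind, rows)
  ok <- records[!records$failed, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(ok, list(ok$kind, ok$method), drop = TRUE),
    function(d) {
      m <- summarize_median_iqr(d$mad_mm); dd <- summarize_median_iqr(d$dice)
      data.frame(kind = d$kind[1], method = d$method[1], n = nrow(d),
                 mad_median = m[1], mad_q1 = m[2], mad_q3 = m[3],
                 dice_median = dd[1], dice_q1 = dd[2], dice_q3 = dd[3],
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL

  ref_method <- methods[1L]
  tests <- list()
  if (length(methods) > 1L) {
    for (kind in unique(ok$kind)) for (metric in c("mad_mm", "dice")) {
      for (other in setdiff(methods, ref_method)) {
        a <- ok[ok$kind == kind & ok$method == ref_method, ]
        b <- ok[ok$kind == kind & ok$method == other, ]
        shared <- intersect(a$case, b$case)
        diffs <- a[match(shared, a$case), metric] - b[match(shared, b$case), metric]
        p <- if (sum(diffs != 0) < 2L) NA_real_ else wilcoxon_signed_rank(diffs)
        tests[[length(tests) + 1L]] <- data.frame(
          kind = kind, metric = metric, method_a = ref_method,
          method_b = other, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(records = records, summary = summ,
                 tests = if (length(tests)) do.call(rbind, tests) else NULL,
                 failed = sum(records$failed),
                 quartile_convention = "linear interpolation (R type 7)",
                 config = config),
            class = "study_result")
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; normal approximation (with the tie-corrected variance,
#' without continuity correction) otherwise.
#'
#' @param x,y numeric samples with at least 2 values each.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  exact <- (length(x) + length(y) <= 20L) && !anyDuplicated(c(x, y))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                      correct = FALSE)$p.value)
}

#' Two-sided Wilcoxon signed-rank p-value on paired differences
#'
#' Zero differences are dropped; exact sign enumeration for up to 15 nonzero
#' differences without tied magnitudes, normal approximation (tie-corrected,
#' no continuity correction) beyond.
#'
#' @param paired_diffs numeric vector of paired differences, at least 2 of
#'   them nonzero.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(paired_diffs) {
  d <- paired_diffs[paired_diffs != 0]
  if (length(d) < 2L) stop("need at least 2 nonzero differences")
  exact <- length(d) <= 15L && !anyDuplicated(abs(d))
  suppressWarnings(stats::wilcox.test(d, exact = exact,
                                      correct = FALSE)$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, p * family_size)` elementwise (the standard Bonferroni rule, as in
#' [stats::p.adjust()] with an explicit family size).
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param family_size number of comparisons in the family; defaults to
#'   `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (family_size < length(p_values))
    stop("family_size must be at least the number of p-values")
  stats::p.adjust(p_values, method = "bonferroni", n = family_size)
}

#' Median and quartiles (linear-interpolation convention)
#'
#' @param values numeric sample with at least 1 value.
#' @return Named vector `c(median =, q1 =, q3 =)` computed with the
#'   linear-interpolation quantile convention ([stats::quantile()] type 7).
#' @export
summarize_median_iqr <- function(values) {
  if (length(values) < 1L) stop("empty sample")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
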