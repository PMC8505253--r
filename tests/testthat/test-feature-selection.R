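test_that("group t-statistic reduces to the classical two-sample t", {
  co <- manual_cohort(values = c(0, 1, 2, 2, 3, 4),
    groups = c(rep("control", 3), rep("patient", 3)))
  glm <- fit_voxelwise_glm(co, covariates = character(0))
  row <- glm$table[glm$table$voxel == 1, ]
  expect_equal(row$t, 2.449, tolerance = 1e-3)
  expect_equal(glm$df, 4)
  expect_equal(row$beta, 2)

  # identical groups: t = 0, p = 1
  co0 <- manual_cohort(values = rep(c(1, 2, 3), 2),
    groups = c(rep("control", 3), rep("patient", 3)))
  glm0 <- fit_voxelwise_glm(co0, covariates = character(0))
  row0 <- glm0$table[glm0$table$voxel == 1, ]
  expect_equal(row0$t, 0)
  expect_equal(row0$p, 1)
})

test_that("voxelwise GLM matches the closed-form OLS oracle to 1e-8", {
  set.seed(2024)
  for (rep in 1:20) {
    n <- sample(8:20, 1)
    n_vox <- sample(3:10, 1)
    groups <- sample(c(rep("patient", ceiling(n / 2)),
      rep("control", floor(n / 2))))
    co <- manual_cohort(values = rnorm(n), groups = groups,
      grid = c(4, 4, 4), seed = rep)
    co$phenotype$age <- runif(n, 20, 60)
    co$phenotype$sex <- rbinom(n, 1, 0.5)
    glm <- fit_voxelwise_glm(co)
    X <- cbind(1, as.numeric(groups == "patient"),
      co$phenotype$sex, co$phenotype$age - mean(co$phenotype$age))
    for (v in seq_len(n_vox)) {
      expect_equal(glm$table$t[v], ols_t_oracle(X, co$data[, v], 2),
        tolerance = 1e-8)
    }
  }
})

test_that("statistics are invariant to subject ordering", {
  fx <- planted_fixture()
  co <- fx$cohort
  ids <- co$phenotype$subject_id
  shuffled <- subset_cohort(co, sample(ids))
  g1 <- fit_voxelwise_glm(co)
  g2 <- fit_voxelwise_glm(shuffled)
  expect_equal(g1$table$t, g2$table$t, tolerance = 1e-10)
})

test_that("rank-deficient designs fail loudly naming the aliased column", {
  co <- manual_cohort(values = rnorm(10),
    groups = rep(c("patient", "control"), each = 5))
  co$phenotype$age <- ifelse(co$phenotype$group == "patient", 40, 20)
  co$phenotype$sex <- 0L  # constant: collinear with intercept
  expect_error(fit_voxelwise_glm(co), "rank deficient")
})

test_that("smoothness estimator recovers white-noise and smoothed fields", {
  cfg <- sim_config(n_patients = 20, n_controls = 20,
    grid_shape = c(12, 12, 12), effect_size = 0, shared_effect = 0,
    smoothing_fwhm = 0, seed = 3)
  co <- generate_cohort(cfg)
  fwhm <- estimate_smoothness(fit_voxelwise_glm(co))
  expect_true(all(fwhm >= 1.0 & fwhm <= 1.25))

  cfg3 <- sim_config(n_patients = 20, n_controls = 20,
    grid_shape = c(12, 12, 12), effect_size = 0, shared_effect = 0,
    smoothing_fwhm = 3, seed = 4)
  co3 <- generate_cohort(cfg3)
  fwhm3 <- estimate_smoothness(fit_voxelwise_glm(co3))
  expect_true(all(abs(fwhm3 - 3) / 3 <= 0.2))

  # constant residuals are refused, never silently smoothed
  cod <- manual_cohort(values = rnorm(6),
    groups = rep(c("patient", "control"), each = 3))
  cod$data[] <- 1
  glmd <- fit_voxelwise_glm(cod, covariates = character(0))
  expect_error(estimate_smoothness(glmd), "degenerate")
})

test_that("subthreshold maps give an empty, non-error selection", {
  cfg <- sim_config(n_patients = 10, n_controls = 10,
    grid_shape = c(8, 8, 8), effect_size = 0, shared_effect = 0,
    smoothing_fwhm = 0, seed = 8)
  co <- generate_cohort(cfg)
  glm <- fit_voxelwise_glm(co)
  sel <- cluster_correct(glm, voxel_p = 1e-8)
  expect_s3_class(sel, "selected_voxels")
  expect_equal(nrow(sel$voxels), 0)
  expect_error(extract_feature_matrix(co, sel), "no selected voxels")
})

test_that("a planted compact effect is recovered as one overlapping cluster", {
  # 5x5x5 cube of effect inside a 14^3 grid, 100 subjects per arm
  grid <- c(14, 14, 14)
  mask <- array(TRUE, dim = grid)
  cube_ijk <- as.matrix(expand.grid(i = 5:9, j = 5:9, k = 5:9))
  cube <- sort((cube_ijk[, 1] - 1) + (cube_ijk[, 2] - 1) * grid[1] +
    (cube_ijk[, 3] - 1) * grid[1] * grid[2] + 1)
  n <- 200
  set.seed(123)
  data <- matrix(rnorm(n * prod(grid)), n, prod(grid))
  groups <- rep(c("patient", "control"), each = 100)
  data[groups == "patient", cube] <- data[groups == "patient", cube] + 1
  ids <- sprintf("s%03d", 1:n)
  rownames(data) <- ids
  co <- structure(list(
    phenotype = tibble::tibble(subject_id = ids, group = groups,
      diagnosis = "x", age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
      medicated = NA_integer_),
    data = data, mask = mask, grid = as.integer(grid), affine = diag(4),
    truth = NULL, config = NULL), class = "cohort")
  glm <- fit_voxelwise_glm(co)
  for (method in c("grf", "permutation")) {
    sel <- cluster_correct(glm, method = method, n_perm = 199, seed = 1)
    expect_equal(sum(sel$clusters$kept), 1)
    dice <- 2 * length(intersect(sel$voxels$voxel, cube)) /
      (nrow(sel$voxels) + length(cube))
    expect_gte(dice, 0.7)
  }
})

test_that("stricter voxel thresholds never enlarge the selected set", {
  fx <- planted_fixture()
  sel_loose <- cluster_correct(fx$glm, voxel_p = 0.001)
  sel_strict <- cluster_correct(fx$glm, voxel_p = 0.0001)
  expect_true(all(sel_strict$voxels$voxel %in% sel_loose$voxels$voxel))
})

test_that("feature extraction returns raw voxel values in ascending order", {
  fx <- planted_fixture()
  fm <- fx$features
  pats <- fx$cohort$phenotype$subject_id[
    fx$cohort$phenotype$group == "patient"]
  expect_equal(dim(unclass(fm)), c(length(pats), nrow(fx$selected$voxels)))
  expect_false(is.unsorted(attr(fm, "voxels")$voxel))
  # extraction identity at a handful of entries
  for (s in pats[c(1, 5)]) {
    for (vi in c(1, nrow(fx$selected$voxels))) {
      v <- attr(fm, "voxels")$voxel[vi]
      expect_identical(as.numeric(unclass(fm)[s, vi]),
        as.numeric(fx$cohort$data[s, v]))
    }
  }
  expect_error(extract_feature_matrix(fx$cohort, fx$selected,
    subjects = c(pats[1], "sub-9999")), "sub-9999")
})
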