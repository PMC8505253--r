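test_that("Cohen's d follows the pooled-sd convention", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohens_d(c(2, 3, 4), c(0, 1, 2)), 2)
  x <- rnorm(20, 3); y <- rnorm(20, 1)
  expect_equal(cohens_d(3 * x, 3 * y), cohens_d(x, y), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled variance")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment in factor tests matches the hand step-up procedure", {
  set.seed(33)
  for (m in c(1, 5, 20, 50)) {
    p <- runif(m)^sample(1:3, 1)
    expect_equal(stats::p.adjust(p, "BH") < 0.05, bh_reject(p, 0.05))
  }
  # canonical fixture: [0.01, 0.02, 0.03, 0.5] at q = 0.05
  expect_equal(bh_reject(c(0.01, 0.02, 0.03, 0.5), 0.05),
    c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH") < 0.05,
    c(TRUE, TRUE, TRUE, FALSE))
  # m = 1 reduces to the raw test
  expect_equal(bh_reject(0.04, 0.05), TRUE)
})

test_that("factor tests report Welch statistics, CI, d and FDR flags", {
  set.seed(44)
  n <- 60
  df <- tibble::tibble(
    arm = rep(c("a", "b"), each = n / 2),
    factor_1 = c(rnorm(n / 2, 1), rnorm(n / 2, 0)),   # real difference
    factor_2 = rnorm(n),                              # null
    factor_3 = c(rep(NA_real_, n / 2), rnorm(n / 2))  # untestable
  )
  out <- factor_tests(df, group = "arm")
  expect_equal(nrow(out), 3)
  r1 <- out[out$factor == "factor_1", ]
  tt <- t.test(df$factor_1[df$arm == "a"], df$factor_1[df$arm == "b"])
  expect_equal(r1$p.value, tt$p.value)
  expect_equal(c(r1$conf.low, r1$conf.high), as.numeric(tt$conf.int))
  expect_true(r1$significant)
  expect_true(out$untestable[out$factor == "factor_3"])
  expect_true(all(out$p.adjusted >= out$p.value, na.rm = TRUE))
  # identical distributions across arms yield no rejections
  out0 <- factor_tests(tibble::tibble(
    arm = rep(c("a", "b"), each = 20),
    factor_1 = rep(rep(c(0, 1), 10), 2)), group = "arm")
  expect_false(any(out0$significant))
})

test_that("logistic score association matches an independent ML oracle", {
  # 20-row worked fixture
  y <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
  x <- c(-1.2, -0.8, 0.3, -1.5, 0.2, -0.4, -1.1, 0.6, -0.9, -0.1,
    0.9, 1.4, 0.1, 0.8, 1.9, -0.2, 1.1, 0.7, 1.6, 0.4)
  res <- score_association(y, data.frame(score_1 = x), alpha = 0.004)
  oracle <- logistic_oracle(matrix(x, ncol = 1), y)
  expect_equal(res$table$estimate, oracle$coef[2], tolerance = 1e-4)
  expect_equal(res$table$r2_nagelkerke, oracle$r2_nagelkerke,
    tolerance = 1e-4)
})

test_that("Nagelkerke R2 is null-calibrated, saturates, and is affine-invariant", {
  set.seed(66)
  n <- 500
  y <- rep(0:1, each = n / 2)
  x_null <- rnorm(n)
  res0 <- score_association(y, data.frame(score_1 = x_null))
  expect_lt(res0$table$r2_nagelkerke, 0.02)

  # separation margin of ~2 sd
  x_sep <- c(rnorm(n / 2, -2.2), rnorm(n / 2, 2.2))
  res1 <- score_association(y, data.frame(score_1 = x_sep))
  expect_gte(res1$table$r2_nagelkerke, 0.9)
  expect_lt(res1$table$r2_nagelkerke, 1)

  # affine rescaling of the score leaves R2 unchanged
  res2 <- score_association(y, data.frame(score_1 = 100 * x_null - 7))
  expect_equal(res2$table$r2_nagelkerke, res0$table$r2_nagelkerke,
    tolerance = 1e-8)
  expect_error(score_association(c(rep(1, 5), rep(0, 400)),
    data.frame(s = rnorm(405))), "at least 10")
})

test_that("perfect separation is flagged, not fatal", {
  y <- rep(0:1, each = 15)
  x <- c(rnorm(15, -10), rnorm(15, 10))
  res <- score_association(y, data.frame(score_1 = x))
  expect_true(res$table$separation)
  expect_lt(res$table$r2_nagelkerke, 1)
  expect_gt(res$table$r2_nagelkerke, 0.9)
})

test_that("subtype contrasts reuse the GLM machinery and add d maps", {
  fx <- planted_fixture()
  truth <- fx$cohort$truth
  contrasts <- subtype_contrast_maps(fx$cohort, truth,
    method = "grf")
  expect_named(contrasts, c("subtype_1", "subtype_2"))

  ct <- contrasts$subtype_1
  # internal consistency: identical to fit_voxelwise_glm on the subset
  members <- truth$subject_id[truth$subtype == 1]
  controls <- fx$cohort$phenotype$subject_id[
    fx$cohort$phenotype$group == "control"]
  direct <- fit_voxelwise_glm(fx$cohort, subjects = c(members, controls))
  expect_equal(ct$maps$t, direct$table$t, tolerance = 1e-10)
  # d and t share sign wherever the effect is unambiguous (the d map is
  # unadjusted, so covariate adjustment can flip near-zero voxels)
  nz <- abs(ct$maps$t) > 2
  expect_true(all(sign(ct$maps$d[nz]) == sign(ct$maps$t[nz])))

  expect_error(
    subtype_contrast_maps(fx$cohort,
      tibble::tibble(subject_id = truth$subject_id[1:2],
        subtype = c(1, 1))),
    "refusing")
})

test_that("planted signs are recovered voxelwise in the contrast maps", {
  # pure sign-opposed subtype deviations (no shared patient shift)
  cfg <- sim_config(n_patients = 220, n_controls = 110, effect_size = 1,
    shared_effect = 0, smoothing_fwhm = 0, seed = 17)
  co <- generate_cohort(cfg)
  contrasts <- subtype_contrast_maps(co, co$truth)
  ct1 <- contrasts$subtype_1
  frontal_d <- ct1$maps$d[match(cfg$frontal_region, ct1$maps$voxel)]
  posterior_d <- ct1$maps$d[match(cfg$posterior_region, ct1$maps$voxel)]
  expect_gte(mean(frontal_d > 0), 0.95)
  expect_gte(mean(posterior_d < 0), 0.95)
  # the second subtype shows the converse pattern
  ct2 <- contrasts$subtype_2
  post2 <- ct2$maps$d[match(cfg$posterior_region, ct2$maps$voxel)]
  front2 <- ct2$maps$d[match(cfg$frontal_region, ct2$maps$voxel)]
  expect_gte(mean(post2 > 0), 0.95)
  expect_gte(mean(front2 < 0), 0.95)
})

test_that("a subtype generated like the controls yields no retained clusters", {
  cfg <- sim_config(n_patients = 40, n_controls = 40,
    grid_shape = c(12, 12, 12), n_subtypes = 1, effect_size = 0,
    shared_effect = 0, smoothing_fwhm = 0, seed = 13)
  co <- generate_cohort(cfg)
  contrasts <- subtype_contrast_maps(co, co$truth)
  expect_equal(sum(contrasts$subtype_1$clusters$clusters$kept), 0)
  expect_lt(abs(mean(contrasts$subtype_1$maps$d)), 0.05)
})
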