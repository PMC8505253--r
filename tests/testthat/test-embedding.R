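test_that("layer schedule follows the halving rule", {
  expect_equal(build_layer_schedule(2175, 5),
    c(2175, 2048, 1024, 512, 256, 128, 64, 32, 5))
  expect_equal(build_layer_schedule(2175, 2)[1:8],
    c(2175, 2048, 1024, 512, 256, 128, 64, 32))
  expect_equal(build_layer_schedule(300, 3), c(300, 256, 128, 64, 32, 3))
  expect_equal(build_layer_schedule(40, 2), c(40, 32, 2))
  for (d in 2:10) {
    sched <- build_layer_schedule(294, d)
    expect_true(all(diff(sched) < 0))
    expect_equal(sched[length(sched)], d)
  }
  expect_error(build_layer_schedule(10, 10), "d < input_dim")
  expect_error(build_layer_schedule(10, 12), "d < input_dim")
})

test_that("the reference backward pass matches numerical gradients", {
  set.seed(1)
  X <- matrix(rnorm(5 * 6), 5, 6)
  sched <- c(6L, 4L, 2L)
  dims <- c(sched, rev(sched)[-1])
  acts <- subtypr:::ae_activations(sched, "relu")
  params <- subtypr:::ae_init(dims, acts)
  A <- subtypr:::ae_forward(params, X, acts)
  grads <- subtypr:::ae_backward(params, A, X, acts)
  eps <- 1e-6
  for (l in seq_along(params$W)) {
    for (idx in c(1, length(params$W[[l]]))) {
      pp <- params; pp$W[[l]][idx] <- pp$W[[l]][idx] + eps
      pm <- params; pm$W[[l]][idx] <- pm$W[[l]][idx] - eps
      num <- (subtypr:::ae_mse(pp, X, acts) -
        subtypr:::ae_mse(pm, X, acts)) / (2 * eps)
      expect_equal(grads$W[[l]][idx], num, tolerance = 1e-5)
    }
  }
})

test_that("a linear autoencoder on rank-d data reaches the PCA optimum", {
  set.seed(7)
  n <- 60; p <- 20; d <- 2
  basis <- matrix(rnorm(p * d), p, d)
  X <- matrix(rnorm(n * d), n, d) %*% t(basis)
  rownames(X) <- sprintf("s%02d", 1:n)
  ae <- train_autoencoder(X, d = d, activation = "linear", epochs = 800,
    learning_rate = 5e-3, patience = 0, seed = 3)
  total_var <- mean(scale(X, scale = apply(X, 2, sd))^2)
  expect_lte(ae$final_mse, 0.01 * total_var)
  # PCA oracle: the linear optimum for rank-d data is exactly zero error
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  recon_err <- sum(pc$sdev[-(1:d)]^2) / sum(pc$sdev^2)
  expect_lt(recon_err, 1e-10)
})

test_that("training is bit-reproducible under a fixed seed, in both engines", {
  fx <- planted_fixture()
  fm <- fx$features
  for (eng in c("cpp", "r")) {
    a <- train_autoencoder(fm, d = 3, epochs = 15, seed = 11, engine = eng)
    b <- train_autoencoder(fm, d = 3, epochs = 15, seed = 11, engine = eng)
    expect_identical(a$latent, b$latent)
    expect_identical(a$params, b$params)
  }
  a <- train_autoencoder(fm, d = 3, epochs = 15, seed = 11)
  c <- train_autoencoder(fm, d = 3, epochs = 15, seed = 12)
  expect_false(identical(a$latent, c$latent))
})

test_that("the recorded loss never ends above its starting point", {
  fx <- planted_fixture()
  for (d in c(2, 5)) {
    ae <- train_autoencoder(fx$features, d = d, epochs = 30, seed = d)
    expect_lte(ae$final_mse, ae$initial_mse)
    expect_equal(ae$loss_trace$mse[1], ae$initial_mse)
    expect_equal(min(ae$loss_trace$mse), ae$final_mse, tolerance = 1e-12)
  }
})

test_that("a near-identity schedule can reproduce its input", {
  set.seed(5)
  X <- matrix(rnorm(40 * 8), 40, 8)
  ae <- train_autoencoder(X, d = 8, layer_sizes = c(8L, 8L),
    activation = "linear", epochs = 2000, learning_rate = 1e-2,
    patience = 0, seed = 2)
  expect_lte(ae$final_mse, 0.001 * mean(scale(X)^2))
})

test_that("encode() reproduces training latents and is functional", {
  fx <- planted_fixture()
  fm <- fx$features
  ae <- train_autoencoder(fm, d = 4, epochs = 20, seed = 8)
  expect_equal(encode(ae, fm), ae$latent, tolerance = 1e-5)
  # duplicated subject rows encode identically
  dup <- unclass(fm)[c(1, 1), , drop = FALSE]
  z <- encode(ae, dup)
  expect_identical(z[1, ], z[2, ])
  expect_error(encode(ae, unclass(fm)[, 1:5]), "mismatch")
})

test_that("constant columns are refused or dropped as configured", {
  set.seed(6)
  X <- cbind(matrix(rnorm(30 * 6), 30, 6), 1)
  expect_error(train_autoencoder(X, d = 2, epochs = 5), "constant")
  ae <- train_autoencoder(X, d = 2, epochs = 5, on_constant = "drop")
  expect_equal(ae$n_input, 6)
  z <- encode(ae, X)  # full-width input accepted, dropped column ignored
  expect_equal(ncol(z), 2)
})

test_that("the nine per-dimension embeddings have the right widths", {
  fx <- planted_fixture()
  models <- train_embeddings(fx$features, d_range = 2:10, seed = 1,
    epochs = 8)
  expect_named(models, paste0("d", 2:10))
  for (d in 2:10) {
    expect_equal(ncol(models[[paste0("d", d)]]$latent), d)
    expect_equal(nrow(models[[paste0("d", d)]]$latent),
      nrow(fx$features))
  }
})

test_that("planted subtypes separate in the 2-D embedding", {
  fx <- planted_fixture()
  truth <- fx$cohort$truth
  for (seed in 1:3) {
    ae <- train_autoencoder(fx$features, d = 2, epochs = 40, seed = seed)
    z <- ae$latent[truth$subject_id, , drop = FALSE]
    mu <- rowsum(z, truth$subtype) / as.vector(table(truth$subtype))
    between <- sqrt(sum((mu[1, ] - mu[2, ])^2))
    within <- mean(sqrt(rowSums((z - mu[truth$subtype, ])^2)))
    expect_gt(between, within)
  }
})
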