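# Shared simulated fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Planted two-subtype cohort at reduced size, with its screen and features
planted_fixture <- function() {
  if (is.null(.fixtures$planted)) {
    cfg <- sim_config(n_patients = 80, n_controls = 60, seed = 42)
    cohort <- generate_cohort(cfg)
    glm <- fit_voxelwise_glm(cohort)
    sel <- cluster_correct(glm)
    fm <- extract_feature_matrix(cohort, sel)
    .fixtures$planted <- list(config = cfg, cohort = cohort, glm = glm,
      selected = sel, features = fm)
  }
  .fixtures$planted
}

# Minimal hand-built cohort: one signal voxel with given per-subject values,
# the remaining mask voxels standard-normal noise.
manual_cohort <- function(values, groups, grid = c(6, 6, 6), seed = 99) {
  n <- length(values)
  set.seed(seed)
  mask <- array(TRUE, dim = grid)
  data <- matrix(stats::rnorm(n * prod(grid)), n, prod(grid))
  data[, 1] <- values
  ids <- sprintf("s%02d", seq_len(n))
  rownames(data) <- ids
  structure(
    list(
      phenotype = tibble::tibble(
        subject_id = ids, group = groups,
        diagnosis = ifelse(groups == "patient", "SZ", "HC"),
        age = rep(30, n), sex = rep(0L, n),
        medicated = ifelse(groups == "patient", 1L, NA_integer_)
      ),
      data = data, mask = mask, grid = as.integer(grid), affine = diag(4),
      truth = NULL, config = NULL
    ),
    class = "cohort"
  )
}

# Fabricate a consensus-like partition table (enough for the robustness API)
fake_run <- function(ids, labels) {
  tibble::tibble(subject_id = ids, cluster = as.integer(labels))
}
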