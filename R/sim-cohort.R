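#' Simulation configuration for a synthetic ALFF cohort
#'
#' Describes a two-arm cohort (patients vs controls) of voxelwise ALFF maps on
#' a small 3D grid, with latent patient subtypes planted as sign-opposed mean
#' shifts in designated "frontal" and "posterior" mask regions. Subtype 1
#' carries increased frontal and decreased posterior ALFF, subtype 2 the
#' converse; on top of the subtype deviations all patients share a common
#' positive shift (`shared_effect`) in both regions, emulating the
#' trans-diagnostic case-control alteration that makes the voxelwise screen
#' able to find the affected regions in the first place.
#'
#' All effect sizes are expressed in units of the voxel noise standard
#' deviation, so `effect_size = 1` plants a Cohen's d of 1 per affected voxel.
#'
#' @param n_patients,n_controls arm sizes.
#' @param grid_shape integer 3-vector, voxels per axis.
#' @param mask_fraction fraction of grid voxels inside the brain mask
#'   (ellipsoidal mask, deterministic).
#' @param n_subtypes number of latent patient subtypes (>= 1).
#' @param subtype_proportions simplex vector of length `n_subtypes`.
#' @param effect_size standardized subtype mean shift per affected voxel
#'   (noise-sd units).
#' @param shared_effect standardized patient-vs-control shift shared by all
#'   patients in both regions (noise-sd units).
#' @param frontal_region,posterior_region optional integer vectors of flat
#'   voxel indices; defaults are spheres in the anterior/posterior thirds of
#'   the mask along the first axis.
#' @param age_range numeric length-2, uniform age range in years.
#' @param sex_balance probability of sex == 1.
#' @param age_beta,sex_beta additive covariate effects, uniform over the mask,
#'   in noise-sd units (age effect is per standardized-age unit).
#' @param noise_sd voxel noise standard deviation (ALFF units).
#' @param smoothing_fwhm optional Gaussian smoothing of the noise field, FWHM
#'   in voxels (0 = white noise); smoothed noise is renormalised to `noise_sd`.
#' @param n_factors number of clinical factor scores (patients only).
#' @param factor_effect standardized reduction of factor scores in medicated
#'   subtype-1 patients (emulates a medication-responsive subtype).
#' @param n_scores number of continuous risk-score columns (all subjects).
#' @param score_effect standardized shift of `score_1` in subtype-1 patients
#'   relative to everyone else (emulates a polygenic-score association with a
#'   single subtype).
#' @param seed integer RNG seed; identical configs give bit-identical cohorts.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 200, n_controls = 100,
                       grid_shape = c(16L, 16L, 16L), mask_fraction = 0.5,
                       n_subtypes = 2, subtype_proportions = NULL,
                       effect_size = 1.0, shared_effect = 0.8,
                       frontal_region = NULL, posterior_region = NULL,
                       age_range = c(18, 60), sex_balance = 0.5,
                       age_beta = 0.15, sex_beta = 0.1,
                       noise_sd = 1.0, smoothing_fwhm = 2.0,
                       n_factors = 4, factor_effect = 0.7,
                       n_scores = 5, score_effect = 0.5,
                       seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 4)) {
    abort("grid_shape must be three integers >= 4")
  }
  if (n_patients < 1 || n_controls < 1) abort("arm sizes must be positive")
  if (n_subtypes < 1) abort("n_subtypes must be >= 1")
  if (is.null(subtype_proportions)) {
    subtype_proportions <- rep(1 / n_subtypes, n_subtypes)
  }
  if (length(subtype_proportions) != n_subtypes ||
    any(subtype_proportions < 0) ||
    abs(sum(subtype_proportions) - 1) > 1e-9) {
    abort("subtype_proportions must be a simplex vector of length n_subtypes")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (mask_fraction <= 0 || mask_fraction > 1) {
    abort("mask_fraction must be in (0, 1]")
  }
  mask <- make_ellipsoid_mask(grid_shape, mask_fraction)
  mask_idx <- which(mask)
  if (is.null(frontal_region)) {
    frontal_region <- default_region(grid_shape, mask, anterior = TRUE)
  }
  if (is.null(posterior_region)) {
    posterior_region <- default_region(grid_shape, mask, anterior = FALSE)
  }
  frontal_region <- as.integer(frontal_region)
  posterior_region <- as.integer(posterior_region)
  if (!all(frontal_region %in% mask_idx) ||
    !all(posterior_region %in% mask_idx)) {
    abort("frontal/posterior regions must be subsets of the brain mask")
  }
  if (length(intersect(frontal_region, posterior_region)) > 0) {
    abort("frontal and posterior regions must be disjoint")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
      grid_shape = grid_shape, mask_fraction = mask_fraction, mask = mask,
      n_subtypes = as.integer(n_subtypes),
      subtype_proportions = subtype_proportions,
      effect_size = effect_size, shared_effect = shared_effect,
      frontal_region = frontal_region, posterior_region = posterior_region,
      age_range = age_range, sex_balance = sex_balance,
      age_beta = age_beta, sex_beta = sex_beta,
      noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
      n_factors = as.integer(n_factors), factor_effect = factor_effect,
      n_scores = as.integer(n_scores), score_effect = score_effect,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Deterministic ellipsoidal mask covering ~fraction of the grid
make_ellipsoid_mask <- function(grid_shape, fraction) {
  cx <- lapply(grid_shape, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
  g <- expand.grid(x = cx[[1]], y = cx[[2]], z = cx[[3]])
  r2 <- g$x^2 + g$y^2 + g$z^2
  thr <- stats::quantile(r2, fraction, names = FALSE, type = 1)
  array(r2 <= thr, dim = grid_shape)
}

# Sphere of ~100+ voxels in the anterior (high-i) or posterior (low-i) part
# of the mask along the first axis
default_region <- function(grid_shape, mask, anterior) {
  nx <- grid_shape[1]
  c_ant <- round(0.72 * nx)
  c_post <- round(0.28 * nx)
  center <- c(if (anterior) c_ant else c_post,
    round(grid_shape[2] / 2), round(grid_shape[3] / 2))
  # cap the radius at half the centre separation so the regions stay disjoint
  radius <- min(max(1.2, nx / 5), (c_ant - c_post) / 2 - 0.05)
  idx <- which(mask)
  ijk <- flat_to_ijk(idx, grid_shape)
  d2 <- (ijk[, 1] - center[1])^2 + (ijk[, 2] - center[2])^2 +
    (ijk[, 3] - center[3])^2
  sort(idx[d2 <= radius^2])
}

# frontal/posterior sign per subtype: subtype 1 = (+, -), subtype 2 = (-, +),
# further subtypes cycle through (+, +) and (-, -)
subtype_signs <- function(s) {
  patterns <- list(c(1, -1), c(-1, 1), c(1, 1), c(-1, -1))
  patterns[[((s - 1) %% 4) + 1]]
}

#' Generate a synthetic ALFF cohort with planted subtypes
#'
#' Draws per-subject 3D ALFF volumes and a phenotype table under the
#' generative model described in [sim_config()]. Ground-truth subtype labels
#' are stored in a separate `truth` table so downstream stages cannot consume
#' them accidentally.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `cohort`: list with `phenotype` (tibble),
#'   `data` (subjects x voxels matrix, full grid, flat column-major order),
#'   `mask` (logical array), `grid`, `affine`, `truth` (tibble or NULL) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_p <- config$n_patients
  n_c <- config$n_controls
  n <- n_p + n_c
  grid <- config$grid_shape
  n_vox <- prod(grid)
  mask_idx <- which(config$mask)

  subject_id <- sprintf("sub-%04d", seq_len(n))
  group <- c(rep("patient", n_p), rep("control", n_c))
  diagnosis <- c(rep(c("SZ", "BD", "MDD"), length.out = n_p), rep("HC", n_c))

  # latent subtypes: largest-remainder counts, order shuffled
  counts <- floor(config$subtype_proportions * n_p)
  rem <- n_p - sum(counts)
  if (rem > 0) {
    extra <- order(config$subtype_proportions * n_p - counts,
      decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  subtype <- sample(rep.int(seq_len(config$n_subtypes), counts))

  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  z_age <- (age - mean(config$age_range)) /
    (diff(config$age_range) / sqrt(12))
  sex <- stats::rbinom(n, 1, config$sex_balance)
  medicated <- c(stats::rbinom(n_p, 1, 0.5), rep(NA_integer_, n_c))

  # clinical factor scores: patients only; medicated subtype-1 patients score
  # lower (medication-responsive subtype)
  factors <- matrix(NA_real_, n, config$n_factors)
  if (config$n_factors > 0) {
    for (k in seq_len(config$n_factors)) {
      base <- stats::rnorm(n_p)
      shift <- -config$factor_effect *
        as.numeric(subtype == 1 & medicated[seq_len(n_p)] == 1)
      factors[seq_len(n_p), k] <- base + shift
    }
  }

  # continuous risk scores: all subjects; score_1 elevated in subtype 1 only
  scores <- matrix(NA_real_, n, config$n_scores)
  if (config$n_scores > 0) {
    for (m in seq_len(config$n_scores)) {
      sc <- stats::rnorm(n)
      if (m == 1) {
        sc[seq_len(n_p)][subtype == 1] <-
          sc[seq_len(n_p)][subtype == 1] + config$score_effect
      }
      scores[, m] <- sc
    }
  }

  # per-subject volumes
  s <- config$noise_sd
  signal_base <- numeric(n_vox)
  data <- matrix(0, n, n_vox, dimnames = list(subject_id, NULL))
  for (i in seq_len(n)) {
    vol <- numeric(n_vox)
    vol[mask_idx] <- 1 + s * (config$age_beta * z_age[i] +
      config$sex_beta * sex[i])
    if (group[i] == "patient") {
      sgn <- subtype_signs(subtype[i])
      vol[config$frontal_region] <- vol[config$frontal_region] +
        s * (config$shared_effect + sgn[1] * config$effect_size)
      vol[config$posterior_region] <- vol[config$posterior_region] +
        s * (config$shared_effect + sgn[2] * config$effect_size)
    }
    noise <- array(stats::rnorm(n_vox, sd = s), dim = grid)
    if (config$smoothing_fwhm > 0) {
      noise <- smooth_field(noise, config$smoothing_fwhm)
    }
    vol <- vol + as.vector(noise)
    vol[-mask_idx] <- 0
    data[i, ] <- vol
  }

  phenotype <- tibble(
    subject_id = subject_id, group = group, diagnosis = diagnosis,
    age = age, sex = sex, medicated = medicated
  )
  if (config$n_factors > 0) {
    colnames(factors) <- paste0("factor_", seq_len(config$n_factors))
    phenotype <- dplyr::bind_cols(phenotype, as_tibble(factors))
  }
  if (config$n_scores > 0) {
    colnames(scores) <- paste0("score_", seq_len(config$n_scores))
    phenotype <- dplyr::bind_cols(phenotype, as_tibble(scores))
  }

  structure(
    list(
      phenotype = phenotype,
      data = data,
      mask = config$mask,
      grid = grid,
      affine = diag(4),
      truth = tibble(
        subject_id = subject_id[seq_len(n_p)],
        subtype = as.integer(subtype)
      ),
      config = config
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$phenotype)
  cat(sprintf(
    "<cohort> %d subjects (%d patients, %d controls), grid %s, %d mask voxels%s\n",
    n, sum(x$phenotype$group == "patient"),
    sum(x$phenotype$group == "control"),
    paste(x$grid, collapse = "x"), sum(x$mask),
    if (!is.null(x$truth)) ", simulated (truth available)" else ""
  ))
  invisible(x)
}

#' Subset a cohort by subject id
#'
#' @param cohort a `cohort`.
#' @param ids subject ids to keep (order preserved as given).
#' @return A `cohort` restricted to `ids`.
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "cohort"))
  missing_ids <- setdiff(ids, cohort$phenotype$subject_id)
  if (length(missing_ids) > 0) {
    abort(paste0("unknown subject ids: ", paste(missing_ids, collapse = ", ")))
  }
  out <- cohort
  out$phenotype <- cohort$phenotype[
    match(ids, cohort$phenotype$subject_id), , drop = FALSE]
  out$data <- cohort$data[ids, , drop = FALSE]
  if (!is.null(cohort$truth)) {
    out$truth <- cohort$truth[cohort$truth$subject_id %in% ids, , drop = FALSE]
  }
  out
}

#' Write a cohort to disk as NIfTI volumes plus tables
#'
#' Writes one NIfTI-1 volume per subject, the brain mask, a tab-delimited
#' phenotype table, a JSON ground-truth file (simulated cohorts only) and a
#' JSON manifest listing every file with its MD5 checksum.
#'
#' @param cohort a `cohort`.
#' @param directory output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return The manifest, invisibly (a list).
#' @export
write_cohort <- function(cohort, directory, overwrite = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (dir.exists(directory) && length(dir(directory)) > 0 && !overwrite) {
    abort(paste0("directory ", directory,
      " is non-empty; use overwrite = TRUE"))
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (id in cohort$phenotype$subject_id) {
    vol <- array(cohort$data[id, ], dim = cohort$grid)
    path <- file.path(directory, paste0(id, "_alff.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol), path)
    files <- c(files, path)
  }
  mask_path <- file.path(directory, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(cohort$mask),
    dim = cohort$grid)), mask_path)
  files <- c(files, mask_path)
  pheno_path <- file.path(directory, "phenotype.tsv")
  utils::write.table(cohort$phenotype, pheno_path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, pheno_path)
  if (!is.null(cohort$truth)) {
    truth_path <- file.path(directory, "truth.json")
    jsonlite::write_json(cohort$truth, truth_path, digits = NA)
    files <- c(files, truth_path)
  }
  manifest <- list(
    grid = cohort$grid,
    n_subjects = nrow(cohort$phenotype),
    simulated = !is.null(cohort$truth),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory a directory produced by [write_cohort()].
#' @return A `cohort`.
#' @export
read_cohort <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(paste0("no manifest.json in ", directory))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  phenotype <- as_tibble(utils::read.delim(
    file.path(directory, "phenotype.tsv"), sep = "\t",
    stringsAsFactors = FALSE))
  if (!"group" %in% names(phenotype)) {
    abort("phenotype table lacks a 'group' column")
  }
  mask_img <- RNifti::readNifti(file.path(directory, "mask.nii.gz"))
  grid <- dim(mask_img)
  mask <- array(as.vector(mask_img) > 0.5, dim = grid)
  n <- nrow(phenotype)
  data <- matrix(0, n, prod(grid),
    dimnames = list(phenotype$subject_id, NULL))
  for (id in phenotype$subject_id) {
    img <- RNifti::readNifti(file.path(directory, paste0(id, "_alff.nii.gz")))
    data[id, ] <- as.vector(img)
  }
  truth <- NULL
  truth_path <- file.path(directory, "truth.json")
  if (file.exists(truth_path)) {
    truth <- as_tibble(jsonlite::read_json(truth_path, simplifyVector = TRUE))
    truth$subtype <- as.integer(truth$subtype)
  }
  structure(
    list(phenotype = phenotype, data = data, mask = mask,
      grid = as.integer(grid), affine = diag(4), truth = truth,
      config = NULL),
    class = "cohort"
  )
}
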