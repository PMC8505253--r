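# Mass-univariate screen: voxelwise OLS for the group effect with age and sex
# covariates, smoothness estimation, and cluster-level correction (Gaussian
# random field theory or Freedman-Lane permutation).

# Build the design matrix: intercept, group (0/1), sex (0/1), mean-centered
# age. Age centering leaves the group contrast unchanged but keeps the solve
# well-conditioned.
build_design <- function(phenotype, covariates = c("sex", "age")) {
  if (!"group" %in% names(phenotype)) {
    abort("phenotype lacks a 'group' column")
  }
  g <- as.numeric(phenotype$group == "patient")
  X <- cbind(intercept = 1, group = g)
  if ("sex" %in% covariates && "sex" %in% names(phenotype)) {
    X <- cbind(X, sex = as.numeric(phenotype$sex))
  }
  if ("age" %in% covariates && "age" %in% names(phenotype)) {
    X <- cbind(X, age = phenotype$age - mean(phenotype$age))
  }
  X
}

# OLS group t-statistics for all voxels at once. X fixed, Y is n x V.
glm_group_t <- function(X, Y, group_col = 2L) {
  qrX <- qr(X)
  df <- nrow(X) - qrX$rank
  B <- qr.coef(qrX, Y)
  fitted <- X %*% B
  res <- Y - fitted
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * xtx_inv[group_col, group_col])
  t <- B[group_col, ] / se
  t[se == 0] <- 0
  list(beta = B[group_col, ], se = se, t = t, df = df, res = res,
    fitted = fitted, B = B)
}

#' Voxelwise general linear model for the group effect
#'
#' Fits, at every mask voxel, an ordinary least-squares model of ALFF on
#' group (patient vs control) with sex and mean-centered age as covariates,
#' and returns the group coefficient, t statistic and two-sided p-value per
#' voxel. Results are invariant to subject ordering.
#'
#' @param cohort a `cohort`.
#' @param subjects optional subject ids to restrict the fit to.
#' @param covariates covariate columns to include (subset of `"sex"`,
#'   `"age"`); both by default.
#' @return An object of class `voxel_glm`: per-voxel table (`tidy()` it),
#'   residual matrix, design, degrees of freedom.
#' @export
fit_voxelwise_glm <- function(cohort, subjects = NULL,
                              covariates = c("sex", "age")) {
  stopifnot(inherits(cohort, "cohort"))
  ph <- cohort$phenotype
  if (!is.null(subjects)) {
    missing_ids <- setdiff(subjects, ph$subject_id)
    if (length(missing_ids) > 0) {
      abort(paste0("subject volume missing for: ",
        paste(missing_ids, collapse = ", ")))
    }
    ph <- ph[match(subjects, ph$subject_id), , drop = FALSE]
  }
  tab <- table(ph$group)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("need at least 2 subjects per group")
  }
  X <- build_design(ph, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    abort(paste0("design matrix is rank deficient; aliased columns: ",
      paste(bad, collapse = ", ")))
  }
  mask_idx <- which(cohort$mask)
  Y <- cohort$data[ph$subject_id, mask_idx, drop = FALSE]
  fit <- glm_group_t(X, Y)
  ijk <- flat_to_ijk(mask_idx, cohort$grid)
  table <- tibble(
    voxel = mask_idx, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    beta = unname(fit$beta), se = unname(fit$se), t = unname(fit$t),
    p = 2 * stats::pt(abs(fit$t), fit$df, lower.tail = FALSE)
  )
  structure(
    list(table = table, df = fit$df, residuals = fit$res,
      fitted = fit$fitted, X = X, Y = Y, phenotype = ph,
      mask = cohort$mask, mask_idx = mask_idx, grid = cohort$grid,
      covariates = covariates),
    class = "voxel_glm"
  )
}

#' @export
print.voxel_glm <- function(x, ...) {
  cat(sprintf("<voxel_glm> %d voxels, %d subjects, %d residual df\n",
    nrow(x$table), nrow(x$X), x$df))
  invisible(x)
}

#' Estimate the spatial smoothness (FWHM) of the residual fields
#'
#' Variance-of-gradients estimator: the GLM residual images are normalised to
#' unit norm per voxel, the mean squared difference of adjacent mask voxels is
#' computed per axis, and the FWHM of an equivalent Gaussian autocorrelation
#' follows as `sqrt(4 log 2 / lambda)`. White-noise residuals give roughly
#' 1.1-1.2 voxels per axis; estimates are clamped at 1 voxel.
#'
#' @param glm a `voxel_glm`.
#' @return Numeric 3-vector of per-axis FWHM in voxels.
#' @export
estimate_smoothness <- function(glm) {
  stopifnot(inherits(glm, "voxel_glm"))
  res <- glm$residuals
  if (nrow(res) < 3) abort("need residuals from at least 3 subjects")
  norms <- sqrt(colSums(res^2))
  if (any(norms < 1e-12)) {
    abort(paste0("degenerate (constant) residuals at ",
      sum(norms < 1e-12), " voxels; smoothness is undefined"))
  }
  U <- sweep(res, 2, norms, "/")
  grid <- glm$grid
  inmask <- logical(prod(grid))
  inmask[glm$mask_idx] <- TRUE
  pos <- integer(prod(grid))
  pos[glm$mask_idx] <- seq_along(glm$mask_idx)
  ijk <- flat_to_ijk(glm$mask_idx, grid)
  strides <- c(1L, grid[1], grid[1] * grid[2])
  fwhm <- numeric(3)
  for (a in 1:3) {
    ok <- ijk[, a] < grid[a]
    v <- glm$mask_idx[ok]
    w <- v + strides[a]
    keep <- inmask[w]
    v <- v[keep]; w <- w[keep]
    if (length(v) < 10) {
      fwhm[a] <- 1
      next
    }
    lambda <- mean(colSums((U[, pos[v], drop = FALSE] -
      U[, pos[w], drop = FALSE])^2))
    fwhm[a] <- max(1, sqrt(4 * log(2) / lambda))
  }
  fwhm
}

# Corrected cluster p-value from random-field theory for a two-sided test on
# a Gaussianised t-field. Classic expected-cluster formulation:
#   E[m] = S (2pi)^-2 |Lambda|^1/2 u^2 exp(-u^2/2)   (one tail, D = 3)
#   E[N] = S Phibar(u),  E[n] = E[N] / E[m]
#   P(extent >= k) = exp(-beta k^(2/D)),  beta = (Gamma(D/2+1)/E[n])^(2/D)
#   p_corr = 1 - exp(-2 E[m] P(extent >= k))
grf_cluster_p <- function(extent, n_mask, fwhm, voxel_p) {
  u <- stats::qnorm(1 - voxel_p / 2)
  lambda_half <- (4 * log(2))^(3 / 2) / prod(fwhm)
  Em1 <- n_mask * (2 * pi)^(-2) * lambda_half * u^2 * exp(-u^2 / 2)
  EN1 <- n_mask * stats::pnorm(u, lower.tail = FALSE)
  En <- EN1 / Em1
  beta <- (gamma(3 / 2 + 1) / En)^(2 / 3)
  p_k <- exp(-beta * extent^(2 / 3))
  pmin(1, 1 - exp(-2 * Em1 * p_k))
}

# Connected suprathreshold clusters of |t| at the two-sided critical value
supra_clusters <- function(t, df, mask_idx, grid, voxel_p, connectivity) {
  t_crit <- stats::qt(1 - voxel_p / 2, df)
  sel <- abs(t) > t_crit
  idx <- mask_idx[sel]
  if (length(idx) == 0) {
    return(list(idx = integer(0), comp = integer(0), t_crit = t_crit))
  }
  comp <- connected_components(idx, grid, connectivity)
  list(idx = idx, comp = comp, t_crit = t_crit, t = t[sel])
}

#' Cluster-level correction of a voxelwise GLM
#'
#' Thresholds the |t| map at the two-sided voxel critical value, extracts
#' connected components (26-connectivity by default) and assigns each a
#' corrected cluster p-value, either from Gaussian random field theory using
#' the estimated residual smoothness (`method = "grf"`) or from a
#' Freedman-Lane permutation null of the maximal suprathreshold cluster
#' extent (`method = "permutation"`). Clusters with corrected p below
#' `cluster_p` are retained; their member voxels form the selected set.
#'
#' @param glm a `voxel_glm`.
#' @param voxel_p voxel-level two-sided threshold (default 0.001).
#' @param cluster_p cluster-level corrected threshold (default 0.05).
#' @param method `"grf"` or `"permutation"`.
#' @param connectivity 6, 18 or 26.
#' @param n_perm number of permutations for `method = "permutation"`.
#' @param seed RNG seed for the permutations.
#' @return An object of class `selected_voxels` with a `clusters` tibble
#'   (extent, peak, corrected p, kept flag) and a `voxels` tibble of the
#'   selected voxels; empty (non-error) when nothing survives.
#' @export
cluster_correct <- function(glm, voxel_p = 0.001, cluster_p = 0.05,
                            method = c("grf", "permutation"),
                            connectivity = 26, n_perm = 999, seed = NULL) {
  stopifnot(inherits(glm, "voxel_glm"))
  method <- match.arg(method)
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1)
  sup <- supra_clusters(glm$table$t, glm$df, glm$mask_idx, glm$grid,
    voxel_p, connectivity)
  thresholds <- list(voxel_p = voxel_p, cluster_p = cluster_p,
    method = method, connectivity = connectivity)
  empty <- structure(
    list(
      clusters = tibble(cluster = integer(0), extent = integer(0),
        peak_i = integer(0), peak_j = integer(0), peak_k = integer(0),
        peak_t = numeric(0), p_corrected = numeric(0), kept = logical(0)),
      voxels = tibble(voxel = integer(0), i = integer(0), j = integer(0),
        k = integer(0), cluster = integer(0)),
      thresholds = thresholds, grid = glm$grid, fwhm = NULL
    ),
    class = "selected_voxels"
  )
  if (length(sup$idx) == 0) return(empty)

  comp_ids <- sort(unique(sup$comp))
  extents <- as.integer(table(factor(sup$comp, levels = comp_ids)))
  fwhm <- NULL
  if (method == "grf") {
    fwhm <- tryCatch(estimate_smoothness(glm), error = function(e) {
      abort(paste0("smoothness estimation failed (", conditionMessage(e),
        "); rerun with method = \"permutation\""))
    })
    p_corr <- grf_cluster_p(extents, length(glm$mask_idx), fwhm, voxel_p)
  } else {
    null_max <- permutation_null_max_extent(glm, voxel_p, connectivity,
      n_perm, seed)
    p_corr <- vapply(extents, function(k) {
      (1 + sum(null_max >= k)) / (n_perm + 1)
    }, numeric(1))
  }

  # peak voxel per cluster
  clusters <- purrr::map_dfr(seq_along(comp_ids), function(ci) {
    members <- which(sup$comp == comp_ids[ci])
    peak <- members[which.max(abs(sup$t[members]))]
    ijk <- flat_to_ijk(sup$idx[peak], glm$grid)
    tibble(cluster = ci, extent = extents[ci],
      peak_i = ijk[1, 1], peak_j = ijk[1, 2], peak_k = ijk[1, 3],
      peak_t = sup$t[peak], p_corrected = p_corr[ci],
      kept = p_corr[ci] < cluster_p)
  })
  kept_ids <- clusters$cluster[clusters$kept]
  keep_vox <- sup$comp %in% comp_ids[kept_ids]
  vox_idx <- sup$idx[keep_vox]
  ord <- order(vox_idx)
  ijk <- flat_to_ijk(vox_idx[ord], glm$grid)
  voxels <- tibble(
    voxel = vox_idx[ord], i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    cluster = match(sup$comp[keep_vox], comp_ids)[ord]
  )
  structure(
    list(clusters = clusters, voxels = voxels, thresholds = thresholds,
      grid = glm$grid, fwhm = fwhm),
    class = "selected_voxels"
  )
}

#' @export
print.selected_voxels <- function(x, ...) {
  cat(sprintf(
    "<selected_voxels> %d suprathreshold clusters, %d retained, %d voxels selected (%s, voxel p<%g, cluster p<%g)\n",
    nrow(x$clusters), sum(x$clusters$kept), nrow(x$voxels),
    x$thresholds$method, x$thresholds$voxel_p, x$thresholds$cluster_p))
  invisible(x)
}

# Freedman-Lane permutation null of the maximal suprathreshold cluster
# extent: residuals of the reduced (covariates-only) model are permuted and
# added back to the reduced fit, the full model is refitted, and the largest
# |t|-cluster extent is recorded per permutation.
permutation_null_max_extent <- function(glm, voxel_p, connectivity,
                                        n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- glm$X
  group_col <- match("group", colnames(X))
  X0 <- X[, -group_col, drop = FALSE]
  qr0 <- qr(X0)
  B0 <- qr.coef(qr0, glm$Y)
  fitted0 <- X0 %*% B0
  res0 <- glm$Y - fitted0
  n <- nrow(X)
  t_crit <- stats::qt(1 - voxel_p / 2, glm$df)
  vapply(seq_len(n_perm), function(p) {
    Y_star <- fitted0 + res0[sample.int(n), , drop = FALSE]
    t_star <- glm_group_t(X, Y_star, group_col)$t
    idx <- glm$mask_idx[abs(t_star) > t_crit]
    if (length(idx) == 0) return(0L)
    comp <- connected_components(idx, glm$grid, connectivity)
    max(tabulate(comp))
  }, integer(1))
}

#' Extract the subjects-by-selected-voxels feature matrix
#'
#' Reads the raw ALFF value of every selected voxel for the requested
#' subjects (by default the patients, which is the set that gets clustered).
#' Columns are ordered by ascending flat voxel index.
#'
#' @param cohort a `cohort`.
#' @param selected a `selected_voxels` with at least one retained voxel.
#' @param subjects subject ids; default all patients.
#' @return A numeric matrix of class `feature_matrix` with attributes
#'   `voxels` (coordinate tibble) and row names = subject ids.
#' @export
extract_feature_matrix <- function(cohort, selected, subjects = NULL) {
  stopifnot(inherits(cohort, "cohort"), inherits(selected, "selected_voxels"))
  if (nrow(selected$voxels) == 0) {
    abort("no selected voxels; cannot build a feature matrix")
  }
  if (is.null(subjects)) {
    subjects <- cohort$phenotype$subject_id[cohort$phenotype$group == "patient"]
  }
  missing_ids <- setdiff(subjects, rownames(cohort$data))
  if (length(missing_ids) > 0) {
    abort(paste0("subject volume missing for: ",
      paste(missing_ids, collapse = ", ")))
  }
  M <- cohort$data[subjects, selected$voxels$voxel, drop = FALSE]
  colnames(M) <- paste0("v", selected$voxels$voxel)
  structure(M, voxels = selected$voxels, class = c("feature_matrix", "matrix"))
}
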