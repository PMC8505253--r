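# Subtype validation statistics: voxelwise subtype-vs-control contrast maps
# with effect sizes, FDR-corrected two-sample tests on clinical factor
# scores, and logistic associations of continuous risk scores with
# Nagelkerke pseudo-R2.

#' Cohen's d (pooled standard deviation)
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled`, where the
#' pooled standard deviation weights the two sample variances by their
#' degrees of freedom.
#'
#' @param x,y numeric samples of size >= 2.
#' @return A single number; positive when `x` has the larger mean.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) abort("both samples need at least 2 observations")
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 <= 0) abort("zero pooled variance; Cohen's d is undefined")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' FDR-corrected two-sample tests on factor scores
#'
#' Welch two-sample t-test per factor column between two groups, with
#' Benjamini-Hochberg adjustment across the factors of the comparison
#' family. Rows whose scores are entirely missing in either arm are marked
#' untestable rather than dropped.
#'
#' @param data data frame with the factor columns and a grouping column.
#' @param group name of the grouping column (2 levels; the first sorted level
#'   is arm 1) or a vector of group labels.
#' @param factors character vector of factor-score column names; default all
#'   columns starting with `"factor_"`.
#' @param q FDR threshold for the significance flag (default 0.05).
#' @return A tibble (class `factor_test_table`): one row per factor with
#'   group means, mean difference and 95% CI, Cohen's d, raw and
#'   BH-adjusted p, and a significance flag.
#' @export
factor_tests <- function(data, group, factors = NULL, q = 0.05) {
  g <- if (length(group) == 1 && is.character(group)) data[[group]] else group
  lev <- sort(unique(as.character(g[!is.na(g)])))
  if (length(lev) != 2) abort("grouping must have exactly 2 levels")
  if (is.null(factors)) {
    factors <- grep("^factor_", names(data), value = TRUE)
  }
  if (length(factors) == 0) abort("no factor columns to test")
  rows <- purrr::map_dfr(factors, function(f) {
    x <- data[[f]][g == lev[1] & !is.na(g)]
    y <- data[[f]][g == lev[2] & !is.na(g)]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) {
      return(tibble(factor = f, mean_1 = mean(x, na.rm = TRUE),
        mean_2 = mean(y, na.rm = TRUE), estimate = NA_real_,
        conf.low = NA_real_, conf.high = NA_real_, cohens_d = NA_real_,
        p.value = NA_real_, untestable = TRUE))
    }
    tt <- stats::t.test(x, y)   # Welch
    tibble(
      factor = f, mean_1 = mean(x, na.rm = TRUE), mean_2 = mean(y, na.rm = TRUE),
      estimate = unname(tt$estimate[1] - tt$estimate[2]),
      conf.low = tt$conf.int[1], conf.high = tt$conf.int[2],
      cohens_d = cohens_d(x, y), p.value = tt$p.value,
      untestable = FALSE
    )
  })
  rows$p.adjusted <- stats::p.adjust(rows$p.value, method = "BH")
  rows$significant <- !is.na(rows$p.adjusted) & rows$p.adjusted < q
  attr(rows, "groups") <- lev
  attr(rows, "q") <- q
  class(rows) <- c("factor_test_table", class(rows))
  rows
}

# Nagelkerke pseudo-R2 from a fitted binomial glm
nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(fit$y ~ 1,
    family = stats::binomial())))
  cs <- 1 - exp(2 * (ll0 - ll1) / n)
  cs / (1 - exp(2 * ll0 / n))
}

#' Logistic association of continuous scores with a binary label
#'
#' For each score column, fits a maximum-likelihood logistic regression of
#' the label on the score (plus optional covariates) and reports the score
#' coefficient, its Wald p-value and the Nagelkerke pseudo-R2
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`. Significance is called at `alpha`
#' (default 0.004, a multi-threshold correction level). Perfect separation is
#' reported with a convergence flag, never as an error.
#'
#' @param labels binary vector (0/1 or logical), e.g. subtype-vs-control.
#' @param scores numeric matrix or data frame of score columns.
#' @param covariates optional data frame of covariate columns (off by
#'   default).
#' @param alpha significance threshold (default 0.004).
#' @param top_n how many best-fit columns to list (default 10).
#' @return A `score_association`: per-score tibble (`$table`) sorted as
#'   given, plus `$best` (top `top_n` by R2) and the threshold used.
#' @export
score_association <- function(labels, scores, covariates = NULL,
                              alpha = 0.004, top_n = 10) {
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) abort("labels must be binary (0/1)")
  if (min(table(y)) < 10) {
    abort("need at least 10 subjects per arm")
  }
  scores <- as.data.frame(scores)
  if (!all(vapply(scores, function(s) all(is.finite(s)), logical(1)))) {
    abort("scores must be finite")
  }
  base_df <- if (is.null(covariates)) {
    data.frame(y = y)
  } else {
    cbind(data.frame(y = y), as.data.frame(covariates))
  }
  rows <- purrr::map_dfr(names(scores), function(nm) {
    df <- cbind(base_df, .score = scores[[nm]])
    sep_flag <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
          conditionMessage(w))) {
          sep_flag <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    co <- summary(fit)$coefficients
    tibble(
      score = nm,
      estimate = co[".score", "Estimate"],
      p.value = co[".score", "Pr(>|z|)"],
      r2_nagelkerke = min(nagelkerke_r2(fit), 1 - 1e-12),
      separation = sep_flag
    )
  })
  rows$significant <- rows$p.value < alpha
  best <- rows[order(-rows$r2_nagelkerke), ]
  best <- best[seq_len(min(top_n, nrow(best))), ]
  structure(
    list(table = rows, best = best, alpha = alpha),
    class = "score_association"
  )
}

#' @export
print.score_association <- function(x, ...) {
  cat(sprintf(
    "<score_association> %d scores, %d significant at alpha = %g; best R2 = %.3f (%s)\n",
    nrow(x$table), sum(x$table$significant), x$alpha,
    x$best$r2_nagelkerke[1], x$best$score[1]))
  invisible(x)
}

#' Voxelwise subtype-vs-control contrast maps
#'
#' For each subtype, fits the voxelwise GLM of the subtype's patients against
#' the controls (same design as the feature-selection screen), adds a
#' voxelwise Cohen's d map, and applies cluster-level correction at the given
#' thresholds.
#'
#' @param cohort a `cohort`.
#' @param subtype_labels tibble with `subject_id` and `subtype` (patients).
#' @param voxel_p,cluster_p,method,connectivity passed to [cluster_correct()].
#' @param min_n refuse subtypes smaller than this (default 3).
#' @return Named list of `subtype_contrast` objects, one per subtype, each
#'   with `$maps` (per-voxel t, p, d tibble), `$clusters`, `$glm` and group
#'   sizes.
#' @export
subtype_contrast_maps <- function(cohort, subtype_labels,
                                  voxel_p = 0.001, cluster_p = 0.05,
                                  method = "grf", connectivity = 26,
                                  min_n = 3) {
  stopifnot(inherits(cohort, "cohort"))
  controls <- cohort$phenotype$subject_id[cohort$phenotype$group == "control"]
  if (length(controls) == 0) abort("cohort has no controls")
  subtypes <- sort(unique(subtype_labels$subtype))
  out <- purrr::map(subtypes, function(s) {
    members <- subtype_labels$subject_id[subtype_labels$subtype == s]
    if (length(members) < min_n) {
      abort(sprintf("subtype %s has only %d members (< %d); refusing contrast",
        s, length(members), min_n))
    }
    sub <- subset_cohort(cohort, c(members, controls))
    glm <- fit_voxelwise_glm(sub)
    # voxelwise Cohen's d from the two group means and pooled sd
    is_pat <- sub$phenotype$group == "patient"
    Yp <- glm$Y[is_pat, , drop = FALSE]
    Yc <- glm$Y[!is_pat, , drop = FALSE]
    np <- nrow(Yp); nc <- nrow(Yc)
    sp2 <- ((np - 1) * apply(Yp, 2, stats::var) +
      (nc - 1) * apply(Yc, 2, stats::var)) / (np + nc - 2)
    d <- (colMeans(Yp) - colMeans(Yc)) / sqrt(pmax(sp2, 1e-300))
    selected <- cluster_correct(glm, voxel_p = voxel_p,
      cluster_p = cluster_p, method = method, connectivity = connectivity)
    maps <- glm$table
    maps$d <- unname(d)
    structure(
      list(subtype = s, maps = maps, clusters = selected, glm = glm,
        n_subtype = np, n_control = nc),
      class = "subtype_contrast"
    )
  })
  names(out) <- paste0("subtype_", subtypes)
  out
}

#' @export
print.subtype_contrast <- function(x, ...) {
  cat(sprintf(
    "<subtype_contrast> subtype %s (n=%d) vs controls (n=%d); %d retained clusters\n",
    x$subtype, x$n_subtype, x$n_control, sum(x$clusters$clusters$kept)))
  invisible(x)
}
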