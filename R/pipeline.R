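# End-to-end orchestration: simulate (optional) -> voxelwise screen ->
# per-dimension embeddings -> ensemble consensus (x J runs) -> robustness
# merging -> validation, all driven by one master seed.

pipeline_keys <- c(
  "sim", "cohort_dir", "voxel_p", "cluster_p", "correction", "n_perm",
  "connectivity", "d_range", "epochs", "batch_size", "learning_rate",
  "k", "n_runs", "delta", "validate", "alpha", "seed", "out_dir"
)

#' Pipeline configuration
#'
#' A single object holding every stage's parameters. Exactly one of `sim`
#' (a [sim_config()] for a synthetic cohort) or `cohort_dir` (a directory
#' readable by [read_cohort()]) must be given. The master `seed`
#' deterministically derives all stage seeds (simulation, autoencoder runs,
#' permutations), so a config reruns bit-identically.
#'
#' @param sim a [sim_config()], or NULL.
#' @param cohort_dir path to a cohort directory, or NULL.
#' @param voxel_p,cluster_p feature-selection thresholds.
#' @param correction `"grf"` or `"permutation"`.
#' @param n_perm permutations when `correction = "permutation"`.
#' @param connectivity cluster connectivity (6/18/26).
#' @param d_range embedding dimensions (default `2:10`).
#' @param epochs,batch_size,learning_rate autoencoder training parameters.
#' @param k clusters per run, or `"auto"` (mean-silhouette choice).
#' @param n_runs independent clustering runs for the robustness step.
#' @param delta robustness threshold.
#' @param validate run the validation stage.
#' @param alpha significance threshold for score associations.
#' @param seed master seed.
#' @param out_dir optional output/cache directory.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, cohort_dir = NULL,
                            voxel_p = 0.001, cluster_p = 0.05,
                            correction = c("grf", "permutation"),
                            n_perm = 999, connectivity = 26,
                            d_range = 2:10, epochs = 60, batch_size = 32,
                            learning_rate = 1e-3, k = "auto", n_runs = 6,
                            delta = 0.8, validate = TRUE, alpha = 0.004,
                            seed = 1L, out_dir = NULL) {
  correction <- match.arg(correction)
  if (is.null(sim) == is.null(cohort_dir)) {
    abort("exactly one of `sim` or `cohort_dir` must be given")
  }
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  stopifnot(n_runs >= 2, delta > 0, delta <= 1, length(d_range) >= 1)
  structure(
    list(sim = sim, cohort_dir = cohort_dir, voxel_p = voxel_p,
      cluster_p = cluster_p, correction = correction, n_perm = n_perm,
      connectivity = connectivity, d_range = d_range, epochs = epochs,
      batch_size = batch_size, learning_rate = learning_rate, k = k,
      n_runs = n_runs, delta = delta, validate = validate, alpha = alpha,
      seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected rather than ignored. The `sim` block, if
#' present, is passed to [sim_config()] (which likewise rejects invalid
#' values).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), pipeline_keys)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$sim)) {
    sim_keys <- names(formals(sim_config))
    unknown <- setdiff(names(raw$sim), sim_keys)
    if (length(unknown) > 0) {
      abort(paste0("unknown sim keys: ", paste(unknown, collapse = ", ")))
    }
    raw$sim <- do.call(sim_config, raw$sim)
  }
  do.call(pipeline_config, raw)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ",
      conditionMessage(e)))
  })
}

stage_cache <- function(out_dir, stage, key, compute) {
  if (is.null(out_dir)) return(compute())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_file <- file.path(out_dir, paste0("stage_", stage, ".rds"))
  if (file.exists(cache_file)) {
    cached <- readRDS(cache_file)
    if (identical(cached$key, key)) return(cached$value)
  }
  value <- compute()
  saveRDS(list(key = key, value = value), cache_file)
  value
}

#' Run the full subtyping pipeline
#'
#' Executes simulate (if configured) -> voxelwise GLM screen with
#' cluster-level correction -> per-dimension autoencoder embeddings and
#' ensemble consensus, repeated over `n_runs` independent runs -> robustness
#' merging -> validation statistics. Every stage seed is derived from the
#' master seed and recorded in the run manifest; when `out_dir` is set,
#' stage outputs are cached on disk and reruns with an identical config
#' reuse them.
#'
#' @param config a [pipeline_config()].
#' @return A `subtype_pipeline`: list with the cohort, selection, run set,
#'   robustness report, final labels, validation results, recovery ARI
#'   against planted truth (simulated cohorts) and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 3)
  manifest <- list(seed = config$seed,
    stage_seeds = list(simulate = seeds[1], runs = seeds[2],
      permutation = seeds[3]),
    stages = list())
  timing <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  # --- cohort -------------------------------------------------------------
  t0 <- Sys.time()
  cohort <- with_stage("simulate/load", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- seeds[1]
      stage_cache(config$out_dir, "cohort", rlang::hash(sim),
        function() generate_cohort(sim))
    } else {
      read_cohort(config$cohort_dir)
    }
  })
  if (!all(c("group") %in% names(cohort$phenotype)) ||
    length(unique(cohort$phenotype$group)) < 2) {
    abort("phenotype table must contain a 'group' column with two arms")
  }
  manifest$stages$cohort <- list(
    n_subjects = nrow(cohort$phenotype), wall_time = timing(t0))

  # --- feature selection --------------------------------------------------
  t0 <- Sys.time()
  sel_key <- rlang::hash(list(config$voxel_p, config$cluster_p,
    config$correction, config$n_perm, config$connectivity, seeds,
    dim(cohort$data)))
  selection <- with_stage("select", stage_cache(
    config$out_dir, "selection", sel_key, function() {
      glm <- fit_voxelwise_glm(cohort)
      selected <- cluster_correct(glm,
        voxel_p = config$voxel_p, cluster_p = config$cluster_p,
        method = config$correction, connectivity = config$connectivity,
        n_perm = config$n_perm, seed = seeds[3])
      if (nrow(selected$voxels) == 0) {
        abort("no voxels survived the screen; nothing to cluster")
      }
      list(glm_table = glm$table, df = glm$df, selected = selected)
    }))
  features <- with_stage("select",
    extract_feature_matrix(cohort, selection$selected))
  manifest$stages$select <- list(
    n_clusters = sum(selection$selected$clusters$kept),
    n_voxels = nrow(selection$selected$voxels), wall_time = timing(t0))

  # --- embeddings + ensemble runs ----------------------------------------
  t0 <- Sys.time()
  runs_key <- rlang::hash(list(sel_key, config$d_range, config$epochs,
    config$batch_size, config$learning_rate, config$k, config$n_runs))
  runs <- with_stage("embed/cluster", stage_cache(
    config$out_dir, "runs", runs_key, function() {
      cluster_runs(features,
        n_runs = config$n_runs, d_range = config$d_range, k = config$k,
        seed = seeds[2], epochs = config$epochs,
        batch_size = config$batch_size,
        learning_rate = config$learning_rate)
    }))
  manifest$stages$cluster <- list(k = runs$k, n_runs = config$n_runs,
    wall_time = timing(t0))

  # --- robustness merging -------------------------------------------------
  t0 <- Sys.time()
  report <- with_stage("merge", merge_until_robust(runs, delta = config$delta))
  manifest$stages$merge <- list(
    k0 = report$k0, n_merges = report$n_merges,
    n_subtypes = length(unique(report$final$subtype)),
    wall_time = timing(t0))

  # --- recovery against planted truth ------------------------------------
  recovery_ari <- NULL
  if (!is.null(cohort$truth)) {
    m <- dplyr::inner_join(report$final, cohort$truth, by = "subject_id")
    recovery_ari <- ari(m$subtype.x, m$subtype.y)
    manifest$stages$merge$recovery_ari <- recovery_ari
  }

  # --- validation ---------------------------------------------------------
  validation <- NULL
  if (isTRUE(config$validate)) {
    t0 <- Sys.time()
    validation <- with_stage("validate",
      validate_subtypes(cohort, report$final, alpha = config$alpha))
    manifest$stages$validate <- list(wall_time = timing(t0))
  }

  out <- structure(
    list(config = config, cohort = cohort, selection = selection,
      features_dim = dim(features), runs = runs, report = report,
      final = report$final, validation = validation,
      recovery_ari = recovery_ari, manifest = manifest),
    class = "subtype_pipeline"
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

# Clinical/score validation battery for the final subtypes
validate_subtypes <- function(cohort, final, alpha = 0.004) {
  ph <- cohort$phenotype
  pats <- dplyr::inner_join(ph, final, by = "subject_id")
  subtypes <- sort(unique(final$subtype))
  factor_cols <- grep("^factor_", names(ph), value = TRUE)
  score_cols <- grep("^score_", names(ph), value = TRUE)

  between <- NULL
  if (length(subtypes) >= 2 && length(factor_cols) > 0) {
    two <- pats[pats$subtype %in% subtypes[1:2], ]
    between <- factor_tests(two, group = as.character(two$subtype))
  }
  medication <- purrr::map(subtypes, function(s) {
    d <- pats[pats$subtype == s & !is.na(pats$medicated), ]
    if (length(unique(d$medicated)) < 2 || length(factor_cols) == 0 ||
      min(table(d$medicated)) < 2) {
      return(NULL)
    }
    factor_tests(d, group = ifelse(d$medicated == 1,
      "medicated", "unmedicated"))
  })
  names(medication) <- paste0("subtype_", subtypes)

  controls <- ph[ph$group == "control", ]
  scores <- purrr::map(subtypes, function(s) {
    members <- pats[pats$subtype == s, ]
    if (length(score_cols) == 0) return(NULL)
    df <- dplyr::bind_rows(members[, c("subject_id", score_cols)],
      controls[, c("subject_id", score_cols)])
    labels <- c(rep(1, nrow(members)), rep(0, nrow(controls)))
    if (min(table(labels)) < 10) return(NULL)
    score_association(labels, df[, score_cols, drop = FALSE], alpha = alpha)
  })
  names(scores) <- paste0("subtype_", subtypes)

  list(between_subtypes = between, medication = medication, scores = scores)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$final, file.path(out_dir, "subtypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(
      delta = result$report$delta, k0 = result$report$k0,
      n_merges = result$report$n_merges,
      robustness = result$report$robustness,
      history = result$report$history
    ),
    file.path(out_dir, "robustness.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest,
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' @export
print.subtype_pipeline <- function(x, ...) {
  cat(sprintf(
    "<subtype_pipeline> %d subjects, %d selected voxels, k=%s, %d final subtypes%s\n",
    nrow(x$cohort$phenotype), x$features_dim[2], x$runs$k,
    length(unique(x$final$subtype)),
    if (!is.null(x$recovery_ari)) {
      sprintf(", recovery ARI %.3f", x$recovery_ari)
    } else ""))
  invisible(x)
}
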