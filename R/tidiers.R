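# broom-style tidy()/glance() methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.voxel_glm <- function(x, ...) x$table

#' @export
glance.voxel_glm <- function(x, ...) {
  tibble(n_voxels = nrow(x$table), n_subjects = nrow(x$X), df = x$df,
    n_significant_unc = sum(x$table$p < 0.001))
}

#' @export
tidy.selected_voxels <- function(x, ...) x$clusters

#' @export
glance.selected_voxels <- function(x, ...) {
  tibble(
    n_clusters = nrow(x$clusters), n_kept = sum(x$clusters$kept),
    n_voxels = nrow(x$voxels), method = x$thresholds$method,
    voxel_p = x$thresholds$voxel_p, cluster_p = x$thresholds$cluster_p
  )
}

#' @export
tidy.autoencoder <- function(x, ...) x$loss_trace

#' @export
glance.autoencoder <- function(x, ...) {
  tibble(
    d = x$d, seed = x$seed, schedule = paste(x$schedule, collapse = "-"),
    initial_mse = x$initial_mse, final_mse = x$final_mse,
    epochs = nrow(x$loss_trace) - 1
  )
}

#' @export
tidy.consensus_result <- function(x, ...) {
  as_tibble(unclass(x)[c("subject_id", "cluster", "agreement",
    "low_agreement")])
}

#' @export
glance.consensus_result <- function(x, ...) {
  tibble(
    k = length(unique(x$cluster)), n_subjects = nrow(x),
    mean_agreement = mean(x$agreement),
    n_low_agreement = sum(x$low_agreement)
  )
}

#' @export
tidy.robustness_report <- function(x, ...) x$trajectory

#' @export
glance.robustness_report <- function(x, ...) {
  tibble(
    k0 = x$k0, n_merges = x$n_merges,
    n_subtypes = nrow(x$robustness),
    min_robustness = min(x$robustness$robustness),
    delta = x$delta
  )
}

#' @export
tidy.factor_test_table <- function(x, ...) as_tibble(x)

#' @export
tidy.score_association <- function(x, ...) x$table

#' @export
glance.score_association <- function(x, ...) {
  tibble(
    n_scores = nrow(x$table), n_significant = sum(x$table$significant),
    alpha = x$alpha, best_score = x$best$score[1],
    best_r2 = x$best$r2_nagelkerke[1]
  )
}

#' @export
tidy.subtype_contrast <- function(x, ...) x$maps

#' @export
glance.subtype_contrast <- function(x, ...) {
  tibble(
    subtype = x$subtype, n_subtype = x$n_subtype, n_control = x$n_control,
    n_kept_clusters = sum(x$clusters$clusters$kept),
    max_abs_d = max(abs(x$maps$d))
  )
}
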