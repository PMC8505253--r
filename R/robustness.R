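# Step three of the subtyping method: quantify the stability of every
# consensus cluster across repeated full clustering runs with a Jaccard-style
# robustness index, and iteratively merge the least robust clusters until all
# survive the threshold delta.

#' Repeated full clustering runs on one feature matrix
#'
#' A "run" re-trains all per-dimension autoencoders with fresh seeds,
#' re-clusters every representation and takes the consensus; the feature
#' selection is deterministic given the cohort and is not repeated. The
#' number of clusters is shared across runs (chosen on the first run when
#' `k = "auto"`).
#'
#' @param features subjects x voxels matrix.
#' @param n_runs number of independent runs (default 6).
#' @param d_range embedding dimensions (default `2:10`).
#' @param k clusters per run, or `"auto"`.
#' @param seed master seed; per-run, per-dimension seeds are derived from it.
#' @param ... passed to [train_autoencoder()] (epochs, batch_size, ...).
#' @return A `run_set`: list with `runs` (list of `consensus_result`), `k`,
#'   and the seed table.
#' @export
cluster_runs <- function(features, n_runs = 6, d_range = 2:10, k = "auto",
                         seed = 1L, ...) {
  stopifnot(n_runs >= 2)
  seeds <- matrix(derive_seeds(seed, n_runs * length(d_range)),
    nrow = n_runs)
  runs <- vector("list", n_runs)
  for (j in seq_len(n_runs)) {
    models <- train_embeddings(features, d_range = d_range,
      seeds = seeds[j, ], ...)
    latents <- purrr::map(models, "latent")
    if (identical(k, "auto") && j == 1) k <- choose_k(latents)$k
    runs[[j]] <- cluster_ensemble(latents, k = k)
  }
  structure(list(runs = runs, k = k, seeds = seeds), class = "run_set")
}

#' Match consensus clusters across runs
#'
#' Identifies, for every cluster `i` of the reference run, its counterpart in
#' each run `j` as the run-`j` cluster with maximal Jaccard overlap, assigned
#' one-to-one by exact optimal matching on the Jaccard matrix. Reference
#' clusters with no counterpart in a run get an empty member set there.
#'
#' @param runs a `run_set` (or plain list of `consensus_result`s).
#' @param reference index of the reference run (default 1).
#' @return List over reference clusters; element `i` is a list over runs of
#'   subject-id vectors `C_i^j`. The reference partition is in attribute
#'   `reference`.
#' @export
match_clusters_across_runs <- function(runs, reference = 1) {
  run_list <- if (inherits(runs, "run_set")) runs$runs else runs
  stopifnot(length(run_list) >= 2)
  ref <- run_list[[reference]]
  ids <- ref$subject_id
  ref_sets <- split(ref$subject_id, ref$cluster)
  k_ref <- length(ref_sets)
  member_sets <- purrr::map(seq_len(k_ref), function(i) {
    vector("list", length(run_list))
  })
  for (j in seq_along(run_list)) {
    run <- run_list[[j]]
    if (!setequal(run$subject_id, ids) ||
      length(run$subject_id) != length(ids)) {
      abort("all runs must cover the same subject set")
    }
    run_sets <- split(run$subject_id, run$cluster)
    jac <- matrix(0, k_ref, length(run_sets))
    for (a in seq_len(k_ref)) {
      for (b in seq_along(run_sets)) {
        inter <- length(intersect(ref_sets[[a]], run_sets[[b]]))
        uni <- length(ref_sets[[a]]) + length(run_sets[[b]]) - inter
        jac[a, b] <- inter / uni
      }
    }
    assign <- max_assignment(jac)   # ref cluster -> run cluster (NA if none)
    for (a in seq_len(k_ref)) {
      member_sets[[a]][[j]] <- if (is.na(assign[a])) {
        character(0)
      } else {
        run_sets[[assign[a]]]
      }
    }
  }
  names(member_sets) <- names(ref_sets)
  attr(member_sets, "reference") <- ref
  member_sets
}

#' Robustness index of a cluster across runs
#'
#' The ratio of the intersection to the union of a cluster's member sets
#' over repeated runs: `R = |intersection_j C^j| / |union_j C^j|`. Equal to 1
#' when the membership is identical in every run, 0 when the runs share no
#' member; an empty union is defined as 0.
#'
#' @param member_sets list of subject-id vectors, one per run.
#' @return A number in `[0, 1]`.
#' @export
robustness_index <- function(member_sets) {
  stopifnot(length(member_sets) >= 1)
  uni <- Reduce(union, member_sets)
  if (length(uni) == 0) return(0)
  inter <- Reduce(intersect, member_sets)
  length(inter) / length(uni)
}

#' Merge unstable clusters until all are robust
#'
#' Computes the robustness index of every cluster of the reference run's
#' consensus (with cluster correspondence across runs from
#' [match_clusters_across_runs()]); while the minimum index does not exceed
#' `delta`, the two clusters with the lowest indices are merged - both in the
#' reference and inside every run's matched sets, so the recomputed index
#' reflects the merged entity - and the loop repeats. Ties in the index are
#' broken by the smaller cluster index. The loop performs at most `k0 - 1`
#' merges (stopping when one cluster remains).
#'
#' @param runs a `run_set` (or list of `consensus_result`s), all over the
#'   same subjects.
#' @param delta robustness threshold in `(0, 1]`; clusters must satisfy
#'   `R > delta` (default 0.8).
#' @param reference index of the reference run (default 1).
#' @return A `robustness_report`: final subtype labels (`$final`), the final
#'   per-cluster indices (`$robustness`), the merge history (`$history`) and
#'   the per-iteration index trajectory (`$trajectory`).
#' @export
merge_until_robust <- function(runs, delta = 0.8, reference = 1) {
  stopifnot(delta > 0, delta <= 1)
  run_list <- if (inherits(runs, "run_set")) runs$runs else runs
  if (length(run_list) < 2) {
    abort("robustness requires at least 2 runs")
  }
  member_sets <- match_clusters_across_runs(run_list, reference = reference)
  ref <- attr(member_sets, "reference")
  k0 <- length(member_sets)
  n_runs <- length(run_list)
  # current clusters = groups of original reference cluster indices
  groups <- as.list(seq_len(k0))

  group_sets <- function(g) {
    purrr::map(seq_len(n_runs), function(j) {
      unique(unlist(purrr::map(g, function(i) member_sets[[i]][[j]])))
    })
  }
  group_r <- function() {
    vapply(groups, function(g) robustness_index(group_sets(g)), numeric(1))
  }

  history <- list()
  trajectory <- list()
  iter <- 0L
  repeat {
    r <- group_r()
    trajectory[[iter + 1L]] <- tibble(
      iteration = iter,
      cluster = seq_along(groups),
      members = purrr::map_chr(groups, paste, collapse = "+"),
      robustness = r
    )
    if (length(groups) == 1L || min(r) > delta) break
    ord <- order(r, seq_along(groups))
    a <- min(ord[1:2]); b <- max(ord[1:2])
    history[[iter + 1L]] <- tibble(
      iteration = iter + 1L,
      cluster_a = paste(groups[[a]], collapse = "+"),
      cluster_b = paste(groups[[b]], collapse = "+"),
      r_a = r[a], r_b = r[b]
    )
    groups[[a]] <- sort(c(groups[[a]], groups[[b]]))
    groups[[b]] <- NULL
    iter <- iter + 1L
  }

  # final labels: subjects follow their reference cluster's group (consensus
  # labels need not be contiguous, so map through the sorted levels)
  ref_levels <- sort(unique(ref$cluster))
  ref_to_final <- integer(k0)
  for (g in seq_along(groups)) ref_to_final[groups[[g]]] <- g
  final <- tibble(
    subject_id = ref$subject_id,
    subtype = ref_to_final[match(ref$cluster, ref_levels)]
  )
  structure(
    list(
      final = final,
      robustness = trajectory[[length(trajectory)]],
      history = if (length(history)) dplyr::bind_rows(history) else
        tibble(iteration = integer(0), cluster_a = character(0),
          cluster_b = character(0), r_a = numeric(0), r_b = numeric(0)),
      trajectory = dplyr::bind_rows(trajectory),
      delta = delta, k0 = k0, n_merges = iter,
      reference = reference
    ),
    class = "robustness_report"
  )
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf(
    "<robustness_report> %d initial clusters -> %d subtypes after %d merges (delta = %g)\n",
    x$k0, nrow(x$robustness), x$n_merges, x$delta))
  cat(sprintf("  final robustness: %s\n",
    paste(sprintf("%.3f", x$robustness$robustness), collapse = ", ")))
  invisible(x)
}
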