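# Step two of the subtyping method: complete-linkage hierarchical clustering
# of every low-dimensional representation, label alignment across
# representations, and a per-subject majority (plurality) consensus.

#' Complete-linkage hierarchical clustering of a latent representation
#'
#' Agglomerative clustering with Euclidean point distance and complete
#' linkage, cut to exactly `k` clusters. Deterministic given the input.
#'
#' @param latent subjects x d numeric matrix (rownames = subject ids).
#' @param k number of clusters, `1 <= k <= nrow(latent)`.
#' @return A `partition`: tibble with `subject_id` and integer `cluster`
#'   (labels `1..k`, each non-empty), with attributes `k` and `d`.
#' @export
hier_cluster <- function(latent, k) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  if (k > n || k < 1) abort("k must be between 1 and the number of subjects")
  if (!all(is.finite(latent))) abort("latent matrix must be finite")
  ids <- rownames(latent) %||% as.character(seq_len(n))
  labels <- if (k == n) {
    seq_len(n)
  } else {
    hc <- stats::hclust(stats::dist(latent), method = "complete")
    unname(stats::cutree(hc, k = k))
  }
  new_partition(ids, as.integer(labels), k = k, d = ncol(latent))
}

new_partition <- function(subject_id, cluster, k = max(cluster), d = NA) {
  out <- tibble(subject_id = subject_id, cluster = as.integer(cluster))
  structure(out, k = as.integer(k), d = d,
    class = c("partition", class(out)))
}

partition_labels <- function(p) {
  stats::setNames(p$cluster, p$subject_id)
}

#' Align cluster labels across partitions
#'
#' Independent clusterings name their clusters arbitrarily; before a majority
#' vote the labels must agree. Each partition is relabelled by the
#' maximum-agreement one-to-one matching of its clusters against a reference
#' partition (exact optimal assignment on the contingency table). Clusters
#' that cannot be matched (when a partition has more clusters than the
#' reference) receive fresh labels above the reference's range. Subject
#' memberships are never changed.
#'
#' @param partitions list of `partition` objects over the same subjects.
#' @param reference index of the reference partition (default: the middle
#'   one, i.e. the median embedding dimension).
#' @return List of relabelled `partition` objects (the reference unchanged).
#' @export
align_labels <- function(partitions, reference = ceiling(length(partitions) / 2)) {
  stopifnot(length(partitions) >= 1)
  ref <- partitions[[reference]]
  ref_ids <- ref$subject_id
  purrr::map(partitions, function(p) {
    if (!setequal(p$subject_id, ref_ids) ||
      length(p$subject_id) != length(ref_ids)) {
      abort("all partitions must cover the same subject set")
    }
    p_lab <- partition_labels(p)[ref_ids]
    ref_lab <- partition_labels(ref)[ref_ids]
    k_run <- max(p_lab)
    k_ref <- max(ref_lab)
    cont <- matrix(0L, k_run, k_ref)
    tab <- table(factor(p_lab, levels = seq_len(k_run)),
      factor(ref_lab, levels = seq_len(k_ref)))
    cont[, ] <- as.integer(tab)
    assign <- max_assignment(cont)   # run cluster -> ref cluster (NA if none)
    unmatched <- which(is.na(assign))
    if (length(unmatched) > 0) {
      assign[unmatched] <- k_ref + seq_along(unmatched)
    }
    out <- p
    out$cluster <- as.integer(assign[p$cluster])
    attr(out, "k") <- attr(p, "k")
    out
  })
}

#' Majority consensus over aligned partitions
#'
#' Assigns every subject the plurality label across the aligned partitions;
#' ties are broken deterministically by the smallest label. The per-subject
#' agreement fraction (votes for the winning label over the number of
#' partitions) is recorded, and subjects with agreement below 0.5 are flagged
#' rather than dropped.
#'
#' @param aligned list of label-aligned `partition` objects (see
#'   [align_labels()]).
#' @return A `consensus_result`: tibble with `subject_id`, `cluster`,
#'   `agreement`, `low_agreement`; the aligned partitions are kept in the
#'   `partitions` attribute.
#' @export
consensus <- function(aligned) {
  stopifnot(length(aligned) >= 1)
  ids <- aligned[[1]]$subject_id
  votes <- vapply(aligned, function(p) partition_labels(p)[ids],
    integer(length(ids)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = length(ids))
  n_rep <- ncol(votes)
  max_lab <- max(votes)
  winner <- integer(length(ids))
  agree <- numeric(length(ids))
  for (s in seq_along(ids)) {
    counts <- tabulate(votes[s, ], nbins = max_lab)
    winner[s] <- which.max(counts)          # smallest label wins ties
    agree[s] <- counts[winner[s]] / n_rep
  }
  out <- tibble(
    subject_id = ids, cluster = winner,
    agreement = agree, low_agreement = agree < 0.5
  )
  structure(out,
    k = length(unique(winner)),
    partitions = aligned,
    class = c("consensus_result", class(out))
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf(
    "<consensus_result> %d subjects, %d clusters, mean agreement %.2f (%d low-agreement)\n",
    nrow(x), length(unique(x$cluster)), mean(x$agreement),
    sum(x$low_agreement)))
  NextMethod()
}

#' Choose the number of clusters by mean silhouette width
#'
#' Computes, for each candidate `k`, the mean silhouette width of the
#' complete-linkage partition of every latent representation, and returns the
#' `k` maximising the average across representations (smallest `k` on ties).
#'
#' @param latents list of latent matrices.
#' @param k_range candidate cluster counts (default `2:10`).
#' @return List with `k` (the choice) and `silhouette` (tibble of mean widths
#'   per k).
#' @export
choose_k <- function(latents, k_range = 2:10) {
  k_range <- k_range[k_range < nrow(latents[[1]])]
  sil <- purrr::map_dfr(k_range, function(k) {
    widths <- purrr::map_dbl(latents, function(z) {
      part <- hier_cluster(z, k)
      mean(cluster::silhouette(part$cluster, stats::dist(z))[, "sil_width"])
    })
    tibble(k = k, mean_silhouette = mean(widths))
  })
  list(k = sil$k[which.max(sil$mean_silhouette)], silhouette = sil)
}

#' Ensemble clustering of a family of latent representations
#'
#' Clusters every latent matrix with [hier_cluster()], aligns labels against
#' the reference representation (the median dimension by default) and takes
#' the majority consensus.
#'
#' @param latents named list of latent matrices (one per embedding dimension).
#' @param k number of clusters, or `"auto"` to choose by [choose_k()].
#' @param reference index of the reference representation for alignment.
#' @return A `consensus_result`; the chosen `k` is in attribute `k_used`.
#' @export
cluster_ensemble <- function(latents, k = "auto",
                             reference = ceiling(length(latents) / 2)) {
  if (identical(k, "auto")) k <- choose_k(latents)$k
  parts <- purrr::map(latents, hier_cluster, k = k)
  aligned <- align_labels(parts, reference = reference)
  out <- consensus(aligned)
  attr(out, "k_used") <- k
  out
}
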