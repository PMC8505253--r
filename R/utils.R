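# Internal numerical utilities shared across modules.

#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Exact maximum-weight one-to-one assignment of rows to columns by dynamic
# programming over column bitmasks: O(nr * 2^nc). Cluster counts here are
# small (<= 12), so exhaustive DP is both exact and cheap; no external
# assignment solver is needed.
# Returns an integer vector of length nrow(score): column assigned to each row,
# NA where rows outnumber columns and the row is left unmatched.
max_assignment <- function(score) {
  nr <- nrow(score)
  nc <- ncol(score)
  if (nc > 25) abort("assignment problem too large for bitmask DP")
  if (nr > nc) {
    # pad with dummy columns of score 0 (rows matched to a dummy are unmatched)
    score <- cbind(score, matrix(0, nr, nr - nc))
    res <- max_assignment(score)
    res[res > nc] <- NA_integer_
    return(res)
  }
  n_mask <- bitwShiftL(1L, nc)
  neg <- -Inf
  best <- rep(neg, n_mask)
  best[1L] <- 0
  choice <- matrix(NA_integer_, nr, n_mask)
  popcount <- integer(n_mask)
  for (m in seq_len(n_mask - 1L)) {
    popcount[m + 1L] <- popcount[bitwShiftR(m, 1L) + 1L] + bitwAnd(m, 1L)
  }
  for (m in seq_len(n_mask - 1L)) {
    r <- popcount[m + 1L]           # row index being assigned (1-based)
    if (r > nr) next
    for (j in seq_len(nc)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(m, bit) == 0L) next
      prev <- best[bitwXor(m, bit) + 1L]
      if (!is.finite(prev)) next
      cand <- prev + score[r, j]
      if (cand > best[m + 1L]) {
        best[m + 1L] <- cand
        choice[r, m + 1L] <- j
      }
    }
  }
  # find the best full assignment of all nr rows
  full <- which(popcount == nr) - 1L
  m_best <- full[which.max(best[full + 1L])]
  assign <- integer(nr)
  m <- m_best
  for (r in rev(seq_len(nr))) {
    j <- choice[r, m + 1L]
    assign[r] <- j
    m <- bitwXor(m, bitwShiftL(1L, j - 1L))
  }
  assign
}

# 3D coordinates <-> flat (column-major, 1-based) voxel indices
flat_to_ijk <- function(idx, dim) {
  idx0 <- idx - 1L
  i <- idx0 %% dim[1]
  j <- (idx0 %/% dim[1]) %% dim[2]
  k <- idx0 %/% (dim[1] * dim[2])
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

ijk_to_flat <- function(ijk, dim) {
  as.integer((ijk[, 1] - 1L) + (ijk[, 2] - 1L) * dim[1] +
    (ijk[, 3] - 1L) * dim[1] * dim[2] + 1L)
}

# Neighbour offsets for 6/18/26 connectivity in 3D
connectivity_offsets <- function(connectivity = 26) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
    "6" = ord == 1,
    "18" = ord <= 2,
    "26" = rep(TRUE, nrow(off)),
    abort("connectivity must be 6, 18 or 26")
  )
  off[keep, , drop = FALSE]
}

# Connected components of a set of voxels (flat indices) in a grid.
# Returns an integer component label per input voxel, labels 1..n_comp in
# order of first appearance (ascending flat index of the component seed).
connected_components <- function(flat_idx, dim, connectivity = 26) {
  n <- length(flat_idx)
  if (n == 0L) return(integer(0))
  ord <- order(flat_idx)
  flat_idx <- flat_idx[ord]
  inset <- integer(prod(dim))            # 0 = outside, else position in flat_idx
  inset[flat_idx] <- seq_len(n)
  off <- connectivity_offsets(connectivity)
  coords <- flat_to_ijk(flat_idx, dim)
  labels <- integer(n)
  comp <- 0L
  stack <- integer(n)
  for (s in seq_len(n)) {
    if (labels[s] != 0L) next
    comp <- comp + 1L
    top <- 1L
    stack[1L] <- s
    labels[s] <- comp
    while (top > 0L) {
      cur <- stack[top]
      top <- top - 1L
      cc <- coords[cur, ]
      ni <- cc[1] + off[, 1]; nj <- cc[2] + off[, 2]; nk <- cc[3] + off[, 3]
      ok <- ni >= 1L & ni <= dim[1] & nj >= 1L & nj <= dim[2] &
        nk >= 1L & nk <= dim[3]
      if (!any(ok)) next
      nf <- (ni[ok] - 1L) + (nj[ok] - 1L) * dim[1] +
        (nk[ok] - 1L) * dim[1] * dim[2] + 1L
      pos <- inset[nf]
      pos <- pos[pos > 0L]
      for (p in pos) {
        if (labels[p] == 0L) {
          labels[p] <- comp
          top <- top + 1L
          stack[top] <- p
        }
      }
    }
  }
  out <- integer(n)
  out[ord] <- labels
  out
}

# Separable 3D Gaussian smoothing with circular (wrap-around) boundary and
# exact variance renormalisation, so that smoothed white noise keeps its
# marginal standard deviation while gaining the requested spatial FWHM.
smooth_field <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  sigma <- fwhm / sqrt(8 * log(2))
  h <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-h:h, sd = sigma)
  w <- w / sum(w)
  dims <- dim(x)
  for (axis in 1:3) {
    out <- array(0, dims)
    for (t in seq_along(w)) {
      sh <- (-h:h)[t]
      idx <- ((seq_len(dims[axis]) - 1L + sh) %% dims[axis]) + 1L
      out <- out + w[t] * switch(axis,
        x[idx, , , drop = FALSE],
        x[, idx, , drop = FALSE],
        x[, , idx, drop = FALSE]
      )
    }
    x <- out
  }
  # renormalise: smoothed variance of unit white noise is prod of 1D ||w||^2
  x / sqrt(sum(w^2))^3
}

# Deterministic derivation of per-stage seeds from a master seed.
# Counter-based: the master seed initialises R's RNG once and a block of
# sub-seeds is drawn; every stage's seed is recorded in the run manifest.
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(master_seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Adjusted Rand index between two label vectors (thin wrapper; mclust's
# implementation is the field standard).
#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two cluster label vectors; 1 for
#' identical partitions (up to relabelling), ~0 for independent ones.
#'
#' @param x,y label vectors of equal length.
#' @return A single number in \[-1, 1\].
#' @export
ari <- function(x, y) {
  stopifnot(length(x) == length(y))
  mclust::adjustedRandIndex(x, y)
}
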