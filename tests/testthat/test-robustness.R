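test_that("robustness index equals the stated set-ratio on fixtures", {
  expect_equal(robustness_index(list(1:5, 1:5, 1:5)), 1)
  expect_equal(robustness_index(list(1:3, 4:6)), 0)
  expect_equal(robustness_index(list(c(1, 2, 3, 4), c(1, 2, 3),
    c(1, 2, 3, 5))), 0.6)
  expect_equal(robustness_index(list(character(0), character(0))), 0)
})

test_that("robustness index matches a brute-force oracle on random instances", {
  set.seed(77)
  for (rep in 1:30) {
    n_runs <- sample(2:10, 1)
    universe <- seq_len(sample(5:30, 1))
    sets <- purrr::map(seq_len(n_runs), function(j) {
      sample(universe, sample.int(length(universe), 1))
    })
    expect_equal(robustness_index(sets), brute_robustness(sets))
  }
})

test_that("an additional discordant run can only lower the index", {
  set.seed(41)
  for (rep in 1:20) {
    universe <- 1:25
    sets <- purrr::map(1:4, function(j) sample(universe, sample(5:20, 1)))
    r_before <- robustness_index(sets)
    r_after <- robustness_index(c(sets, list(sample(universe, 10))))
    expect_lte(r_after, r_before + 1e-12)
  }
})

test_that("cluster matching pairs like with like via Jaccard overlap", {
  ids <- sprintf("s%03d", 1:100)
  ref <- fake_run(ids, rep(1:2, each = 50))
  runs <- list(ref, ref, ref)
  ms <- match_clusters_across_runs(runs, reference = 1)
  expect_equal(ms[[1]][[2]], ids[1:50])
  expect_equal(ms[[2]][[3]], ids[51:100])

  # one run swaps the boundary subjects 50 and 51
  swap <- fake_run(ids, c(rep(1, 49), 2, 1, rep(2, 49)))
  ms2 <- match_clusters_across_runs(list(ref, swap), reference = 1)
  expect_equal(sort(ms2[[1]][[2]]), sort(c(ids[1:49], ids[51])))

  # a run with fewer clusters leaves one reference cluster unmatched
  coarse <- fake_run(ids, rep(1, 100))
  ms3 <- match_clusters_across_runs(list(ref, coarse), reference = 1)
  empty <- vapply(ms3, function(m) length(m[[2]]) == 0, logical(1))
  expect_equal(sum(empty), 1)
})

test_that("merge loop is a no-op when every cluster is already robust", {
  ids <- sprintf("s%03d", 1:60)
  ref <- fake_run(ids, rep(1:3, each = 20))
  runs <- list(ref, ref, ref, ref)
  rep_out <- merge_until_robust(runs, delta = 0.8)
  expect_equal(rep_out$n_merges, 0)
  expect_equal(rep_out$final$subtype,
    as.integer(rep(1:3, each = 20)))
  expect_true(all(rep_out$robustness$robustness == 1))
})

test_that("two fragile clusters collapse into one with index 1", {
  set.seed(10)
  ids <- sprintf("s%03d", 1:40)
  a <- fake_run(ids, rep(1:2, each = 20))
  b <- fake_run(ids, sample(rep(1:2, each = 20)))  # memberships scrambled
  rep_out <- merge_until_robust(list(a, b), delta = 0.8)
  expect_equal(length(unique(rep_out$final$subtype)), 1)
  expect_equal(rep_out$robustness$robustness, 1)
  expect_equal(rep_out$n_merges, 1)
})

test_that("only the unstable pair is merged in a 3-cluster fixture", {
  # cluster A (1..30) is stable; B and C exchange ~40% of members across runs
  ids <- sprintf("s%03d", 1:90)
  ref <- fake_run(ids, rep(1:3, each = 30))
  make_run <- function(swap) {
    lab <- rep(1:3, each = 30)
    lab[31:(30 + swap)] <- 3
    lab[61:(60 + swap)] <- 2
    fake_run(ids, lab)
  }
  runs <- list(ref, make_run(12), make_run(12))
  ms <- match_clusters_across_runs(runs, reference = 1)
  r0 <- vapply(ms, robustness_index, numeric(1))
  expect_gt(r0[1], 0.8)
  expect_lt(r0[2], 0.8)
  expect_lt(r0[3], 0.8)

  rep_out <- merge_until_robust(runs, delta = 0.8)
  expect_equal(rep_out$n_merges, 1)
  expect_equal(rep_out$history$cluster_a, "2")
  expect_equal(rep_out$history$cluster_b, "3")
  final <- rep_out$final
  expect_equal(length(unique(final$subtype[31:90])), 1)
  expect_equal(length(unique(final$subtype[1:30])), 1)
  expect_false(final$subtype[1] == final$subtype[31])
  merged_r <- rep_out$robustness$robustness[
    rep_out$robustness$members == "2+3"]
  expect_gte(merged_r, 0.8)
})

test_that("merging terminates and only coarsens the reference partition", {
  set.seed(55)
  ids <- sprintf("s%03d", 1:80)
  k0 <- 4
  ref_lab <- rep(1:k0, each = 20)
  runs <- c(list(fake_run(ids, ref_lab)), purrr::map(2:4, function(j) {
    lab <- ref_lab
    noisy <- sample(80, 25)
    lab[noisy] <- sample(1:k0, 25, replace = TRUE)
    fake_run(ids, lab)
  }))
  rep_out <- merge_until_robust(runs, delta = 0.8)
  expect_lte(rep_out$n_merges, k0 - 1)
  ok <- min(rep_out$robustness$robustness) > 0.8 ||
    nrow(rep_out$robustness) == 1
  expect_true(ok)
  # coarsening: subjects sharing a reference cluster share a final subtype
  for (cl in 1:k0) {
    expect_equal(length(unique(rep_out$final$subtype[ref_lab == cl])), 1)
  }
  expect_error(merge_until_robust(runs[1], delta = 0.8), "at least 2")
})
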