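test_that("UPGMA agglomeration follows average linkage with deterministic ties", {
  # identical sequences join at distance zero
  aln <- small_aln(c("ACGU", "ACGU"))
  tr <- build_upgma(aln)
  expect_equal(tr$height, 0)
  expect_equal(tr$merge, matrix(c(-1L, -2L), 1))

  # two clean clades: (1,2) and (3,4) merge first, root joins them
  aln <- small_aln(c("AAAA", "AAAA", "GGGG", "GGGG"))
  tr <- build_upgma(aln)
  expect_equal(tr$merge[1, ], c(-1L, -2L))
  expect_equal(tr$merge[2, ], c(-3L, -4L))
  expect_equal(tr$merge[3, ], c(1L, 2L))
  expect_equal(tr$height, c(0, 0, 0.5))

  # three equidistant sequences: the tie resolves to the lowest index pair
  aln <- small_aln(c("AAGG", "AGAG", "AGGA"))
  d <- aln_distance(aln)
  expect_true(all(abs(d[upper.tri(d)] - d[1, 2]) < 1e-12))
  expect_equal(build_upgma(aln)$merge[1, ], c(-1L, -2L))
})

test_that("UPGMA heights agree with hclust average linkage", {
  set.seed(42)
  n <- 9
  d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  d[upper.tri(d)] <- runif(sum(upper.tri(d)), 0.1, 1)
  d <- d + t(d)
  ours <- build_upgma(d)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # hclust heights are the joined cluster distance; ours are half of it
  # (ultrametric leaf-to-node convention)
  expect_equal(sort(2 * ours$height), sort(hc$height), tolerance = 1e-12)
  # cophenetic distances must agree pairwise, not just in aggregate
  # (ape::as.phylo.hclust makes tip-to-tip path length equal the hclust
  # merge height, i.e. twice our node height)
  coph_ref <- as.matrix(stats::cophenetic(hc))
  coph_ours <- as.matrix(ape::cophenetic.phylo(as_phylo(ours))) * 2
  expect_equal(coph_ours[rownames(coph_ref), colnames(coph_ref)], coph_ref,
               tolerance = 1e-9)
})

test_that("tree partitions are nested with sizes 1..N-1", {
  fx <- make_fixture(fixture_spec(n_leaves = 8, L = 30, seed = 4))
  tr <- build_upgma(fx$alignment)
  part <- tree_partitions(tr)
  expect_equal(nrow(part), 7)
  for (lvl in seq_len(nrow(part))) {
    expect_equal(length(unique(part[lvl, ])), lvl)
    if (lvl > 1) {
      # each group at this level lies inside one group of the previous level
      for (gr in unique(part[lvl, ])) {
        expect_equal(length(unique(part[lvl - 1, part[lvl, ] == gr])), 1)
      }
    }
  }
})

test_that("integer ET matches the hand-traced values", {
  aln <- small_aln(c("AAAA", "AAAA", "GGGG", "GGGG"))
  tree <- build_upgma(aln)
  col <- small_aln(c("A", "A", "G", "G"))   # clade-fixed column
  expect_equal(integer_et(col, tree)$rank, 2)

  cons <- small_aln(c("C", "C", "C", "C"))  # fully conserved: rank 1
  expect_equal(integer_et(cons, tree)$rank, 1)

  dist4 <- small_aln(c("A", "C", "G", "U")) # all distinct: rank N
  expect_equal(integer_et(dist4, tree)$rank, 4)

  # gap counts as a nucleotide state: A,A,-,- is clade-fixed, rank 2
  gapped <- small_aln(c("A", "A", "-", "-"))
  expect_equal(integer_et(gapped, tree)$rank, 2)

  # integer ranks stay in [1, N]
  fx <- make_fixture(fixture_spec(seed = 12))
  r <- integer_et(fx$alignment, build_upgma(fx$alignment))$rank
  expect_true(all(r == round(r)))
  expect_true(all(r >= 1 & r <= fx$alignment$N))
})

test_that("real-value ET matches the hand-evaluated entropy weighting", {
  aln <- small_aln(c("AAAA", "AAAA", "GGGG", "GGGG"))
  tree <- build_upgma(aln)
  col <- small_aln(c("A", "A", "G", "G"))
  # level 1: whole-alignment entropy ln 2; levels 2 and 3: all groups fixed
  expect_equal(rvet(col, tree)$rank, 1 + log(2), tolerance = 1e-12)

  cons <- small_aln(c("C", "C", "C", "C"))
  expect_identical(rvet(cons, tree)$rank, 1)

  # tree/alignment leaf mismatch is an input error
  bad <- small_aln(c("A", "A", "G", "G"), ids = c("x1", "x2", "x3", "x4"))
  expect_error(rvet(bad, tree), "leaves")
})

test_that("integer and real-value ET agree on the class ordering of fixture columns", {
  fx <- make_fixture(fixture_spec(seed = 21))
  tree <- build_upgma(fx$alignment)
  for (tr in list(integer_et(fx$alignment, tree), rvet(fx$alignment, tree))) {
    mcov <- tapply(tr$coverage, fx$truth, mean)
    expect_lt(mcov[["conserved"]], mcov[["clade_specific"]])
    expect_lt(mcov[["clade_specific"]], mcov[["random"]])
  }
})

test_that("coverage is a tie-sharing percentile", {
  expect_equal(coverage(c(1.0, 1.69, 4.0)), c(1, 2, 3) / 3 * 100)
  expect_equal(coverage(c(2, 2, 2)), c(100, 100, 100))
  expect_equal(coverage(5), 100)
  # ties share the largest position
  expect_equal(coverage(c(1, 1, 3, 2)), c(50, 50, 100, 75))
})

test_that("ranks are invariant under sequence reordering", {
  fx <- make_fixture(fixture_spec(n_leaves = 8, L = 40, seed = 33))
  aln <- fx$alignment
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  aln_p <- rna_alignment(aln$ids[perm], aln$rows[perm], query_id = aln$query_id)
  r1 <- rvet(aln, build_upgma(aln))$rank
  r2 <- rvet(aln_p, build_upgma(aln_p))$rank
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("Shannon conservation scores columns by whole-alignment entropy", {
  aln <- small_aln(c("AAAC", "ACAG", "AGAU", "AUAA"))
  sh <- shannon_conservation(aln)
  expect_equal(sh$rank[[1]], 0)              # conserved
  expect_equal(sh$rank[[2]], log(4))         # A,C,G,U
  expect_equal(sh$rank[[4]], log(4))
  expect_equal(shannon_conservation(small_aln(c("A", "A", "G", "G")))$rank,
               log(2))
  expect_equal(which.min(sh$coverage), 1)    # conserved column ranks best
})

test_that("entropy-weighted ET beats plain conservation on noisy clade signal", {
  better <- 0
  for (s in 1:5) {
    fx <- make_fixture(fixture_spec(noise = 0.15, seed = 40 + s))
    tr <- rvet(fx$alignment, build_upgma(fx$alignment))
    sh <- shannon_conservation(fx$alignment)
    cl <- fx$truth == "clade_specific"
    if (mean(tr$coverage[cl]) < mean(sh$coverage[cl])) better <- better + 1
  }
  expect_gte(better, 4)
})
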