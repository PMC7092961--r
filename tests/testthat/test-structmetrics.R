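toy_structure <- function(coords, bases = NULL) {
  L <- nrow(coords)
  if (is.null(bases)) bases <- rep("A", L)
  structure(list(
    residues = data.frame(chain = "A", resno = seq_len(L), base = bases,
                          res_index = seq_len(L)),
    atoms = data.frame(res_index = seq_len(L),
                       x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    sequence = paste(bases, collapse = "")), class = "rna_structure")
}

test_that("tertiary contacts follow the distance cutoff and neighbor exclusion", {
  # residues 1 and 3 at 3.9 A -> contact; 1 and 4 at 4.1 A -> none;
  # 1 and 2 adjacent in chain -> excluded by default
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(3.9, 0, 0), c(-4.1, 0, 0))
  g <- contact_graph_3d(toy_structure(coords))
  expect_true(g$adj[1, 3])
  expect_false(g$adj[1, 4])
  expect_false(g$adj[1, 2])
  g0 <- contact_graph_3d(toy_structure(coords), exclude_neighbors = 0)
  expect_true(g0$adj[1, 2])

  # multi-atom residues use the minimum inter-atom distance
  fx1 <- make_fixture(fixture_spec(n_leaves = 4, L = 20, seed = 3))
  fx2 <- make_fixture(fixture_spec(n_leaves = 4, L = 20, multi_atom = TRUE, seed = 3))
  g1 <- contact_graph_3d(fx1$structure)
  g2 <- contact_graph_3d(fx2$structure)
  # extra atoms can only add contacts, never remove them
  expect_true(all(g2$adj[g1$adj]))
})

test_that("secondary and primary contact graphs have the defined edge sets", {
  g1 <- contact_graph_1d(4)
  expect_equal(sum(g1$adj) / 2, 3)
  g2 <- contact_graph_2d(parse_wuss("((..))"), 6)
  expect_equal(sum(g2$adj) / 2, 5 + 2)   # backbone plus the two pairs
  expect_true(g2$adj[1, 6] && g2$adj[2, 5])
  expect_equal(sum(contact_graph_1d(1)$adj), 0)
  expect_error(contact_graph_2d(parse_wuss("((..))"), 4), "outside")
})

test_that("selection clustering weight counts internal edges", {
  g <- path_graph(4)
  expect_equal(scw(c(1, 2), g), 1)
  expect_equal(scw(integer(0), g), 0L)
  expect_equal(scw(3, g), 0L)
  expect_equal(scw(1:4, g), 3)
  expect_error(scw(5, g), "outside")
})

test_that("analytic clustering z matches the worked path-graph case", {
  g <- path_graph(4)
  cz <- clustering_z(c(1, 2), g)
  expect_equal(cz$expected_w, 0.5)
  expect_equal(cz$sigma, 0.5)
  expect_equal(cz$z, 1.0)
  # degenerate: complete graph has zero variance at any k
  adj <- matrix(TRUE, 5, 5); diag(adj) <- FALSE
  gK <- rnaet:::new_contact_graph(adj, "tertiary")
  expect_false(clustering_z(c(1, 2, 3), gK)$valid)
  expect_true(is.na(clustering_z(c(1, 2, 3), gK)$z))
})

test_that("analytic SCW moments equal exhaustive enumeration on small graphs", {
  graphs <- list(path_graph(7), contact_graph_2d(parse_wuss("((..))"), 6),
                 random_graph(8, 0.3, 1), random_graph(9, 0.6, 2))
  for (g in graphs) {
    for (k in 2:(g$L - 1)) {
      mo <- rnaet:::scw_null_moments(k, g)
      en <- enum_scw_moments(g, k)
      expect_equal(mo$mean, en$mean, tolerance = 1e-10)
      expect_equal(mo$var, en$var, tolerance = 1e-10)
    }
  }
})

test_that("analytic and permutation z-scores agree within Monte Carlo error", {
  g <- random_graph(20, 0.25, 7)
  sel <- c(1, 4, 5, 9, 13, 17)
  an <- clustering_z(sel, g)
  pe <- clustering_z(sel, g, mode = "permutation", n_perm = 20000, seed = 11)
  # mean of the permutation null within 3 MC standard errors of analytic
  expect_lt(abs(an$expected_w - pe$expected_w), 3 * an$sigma / sqrt(20000) + 1e-9)
  expect_lt(abs(an$z - pe$z), 0.15)
  expect_error(clustering_z(sel, g, mode = "permutation"), "seed")
})

test_that("z-profile bins cumulatively with plateau fill", {
  # all positions tied: the only attained bin is 100%, others inherit it
  tr <- trace_result(rep(1, 6))
  g <- path_graph(6)
  zp <- z_profile(tr, g)
  expect_equal(sum(zp$bins$valid), 1)
  expect_equal(zp$bins$z_filled, rep(0, 6))
  expect_equal(zp$mean_0_35, 0)

  # planted fixture: contiguous top-ranked positions cluster strongly
  fx <- make_fixture(fixture_spec(seed = 7))
  tr <- rvet(fx$alignment, build_upgma(fx$alignment))
  g3 <- contact_graph_3d(fx$structure)
  expect_gte(z_profile(tr, g3)$mean_0_35, 2)

  # selections are cumulative: w is monotone non-decreasing
  expect_true(all(diff(z_profile(tr, g3)$bins$w) >= 0))

  # mismatched lengths are an input error
  expect_error(z_profile(tr, path_graph(10)), "different numbers")
})

test_that("random ranks give unremarkable clustering z on the fixture geometry", {
  fx <- make_fixture(fixture_spec(seed = 1))
  g <- contact_graph_3d(fx$structure)
  ok <- 0; n <- 40
  for (s in seq_len(n)) {
    set.seed(1000 + s)
    tr <- trace_result(sample(seq_len(fx$spec$L)))
    if (abs(z_profile(tr, g)$mean_0_35) <= 2) ok <- ok + 1
  }
  expect_gte(ok / n, 0.9)
})

test_that("smoothness sums squared rank differences over contacts", {
  g <- path_graph(3)
  expect_equal(smoothness(trace_result(c(1, 1, 2)), g, x = "rank"), 1)
  expect_equal(smoothness(trace_result(c(2, 2, 2)), g, x = "rank"), 0)
  # clustered arrangements are smoother than alternating ones
  expect_lt(smoothness(trace_result(c(1, 1, 2)), g, x = "rank"),
            smoothness(trace_result(c(1, 2, 1)), g, x = "rank"))

  # invariance under translation, quadratic scaling under rank scaling
  fx <- make_fixture(fixture_spec(n_leaves = 8, L = 30, seed = 3))
  g3 <- contact_graph_3d(fx$structure)
  r <- rvet(fx$alignment, build_upgma(fx$alignment))$rank
  s0 <- smoothness(trace_result(r), g3, x = "rank")
  # translation changes rank values but not differences
  tr_shift <- trace_result(r + 5)
  expect_equal(smoothness(tr_shift, g3, x = "rank"), s0, tolerance = 1e-9)
  tr_scale <- trace_result(3 * r)
  expect_equal(smoothness(tr_scale, g3, x = "rank"), 9 * s0, tolerance = 1e-9)
})
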