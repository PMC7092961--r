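# Independent oracles used across the suite.  These deliberately use
# brute force / exhaustive enumeration and stay independent of the code
# paths they check.

# AUC by explicit pair counting, ties credited 1/2
pair_count_auc <- function(score, label) {
  pos <- score[label]; neg <- score[!label]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# exact SCW null moments by enumerating every k-subset of positions
enum_scw_moments <- function(g, k) {
  subsets <- utils::combn(g$L, k)
  ws <- apply(subsets, 2, function(s) sum(g$adj[s, s]) / 2)
  list(mean = mean(ws), var = stats::var(ws) * (length(ws) - 1) / length(ws))
}

# exact overlap-count moments by enumerating every n-subset of a universe
# with M marked positions
enum_overlap_moments <- function(N, M, n) {
  subsets <- utils::combn(N, n)
  ks <- apply(subsets, 2, function(s) sum(s <= M))
  list(mean = mean(ks), sd = sqrt(stats::var(ks) * (length(ks) - 1) / length(ks)))
}

# one-sided hypergeometric tail by direct summation over choose()
enum_hyper_tail <- function(k1, n1, k2, n2) {
  K <- k1 + k2; N <- n1 + n2
  kk <- max(0, K - (N - n1)):min(K, n1)
  probs <- choose(K, kk) * choose(N - K, n1 - kk) / choose(N, n1)
  sum(probs[kk >= k1])
}

# Erdos-Renyi style random contact graph (deterministic under seed)
random_graph <- function(L, p, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, L, L)
  for (i in seq_len(L - 1)) for (j in (i + 1):L)
    adj[i, j] <- adj[j, i] <- stats::runif(1) < p
  rnaet:::new_contact_graph(adj, "tertiary")
}

path_graph <- function(L) contact_graph_1d(L)

small_aln <- function(rows, ids = sprintf("s%d", seq_along(rows)), ...) {
  rna_alignment(ids, rows, ...)
}

# append iid uniform random decoy rows to a fixture alignment
contaminate_alignment <- function(aln, frac = 0.3, seed = 1) {
  n_dec <- round(frac * aln$N)
  set.seed(seed)
  dec <- replicate(n_dec, paste(sample(c("A", "C", "G", "U"), aln$L_aln,
                                       replace = TRUE), collapse = ""))
  rna_alignment(c(aln$ids, sprintf("dec%02d", seq_len(n_dec))),
                c(aln$rows, dec), query_id = aln$query_id)
}
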