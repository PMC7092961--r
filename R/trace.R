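#' Pairwise alignment distance matrix
#'
#' Normalized Hamming distance, 1 - (identical columns / alignment width),
#' with the gap character counting as an ordinary fifth symbol.
#'
#' @param aln an `rna_alignment`.
#' @return symmetric N x N numeric matrix.
#' @export
aln_distance <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
    }
  }
  d
}

#' Build a UPGMA tree
#'
#' Average-linkage agglomeration on the normalized Hamming distance.
#' Ties in the minimum inter-cluster distance are broken toward the
#' lexicographically lowest pair of current cluster indices (leaves first,
#' then internal clusters in creation order), so the tree is
#' bit-reproducible.  Merge heights are half the joined cluster distance
#' (ultrametric convention).
#'
#' @param aln an `rna_alignment`, or a symmetric distance matrix with
#'   dimnames.
#' @return Object of class `upgma_tree`: `merge`/`height` in
#'   [stats::hclust()] convention, `labels`, and `leafsets` (leaf index
#'   vector under each internal node).
#' @export
build_upgma <- function(aln) {
  d <- if (inherits(aln, "rna_alignment")) aln_distance(aln) else as.matrix(aln)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  # active clusters keyed by hclust-style id: -leaf or +internal
  active_id <- -seq_len(n)      # cluster ids in creation order of activation
  sizes <- rep(1L, n)
  dd <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  leafsets <- vector("list", n - 1)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1)) {
    k <- length(active_id)
    # minimum distance; tie -> lowest (i, j) position pair in current order
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (dd[i, j] < bestd - 1e-12) {
          bestd <- dd[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[[1]]; j <- best[[2]]
    merge[step, ] <- c(active_id[[i]], active_id[[j]])
    height[[step]] <- bestd / 2
    newmem <- c(members[[i]], members[[j]])
    leafsets[[step]] <- sort(newmem)
    # UPGMA update: size-weighted average of distances
    si <- sizes[[i]]; sj <- sizes[[j]]
    newrow <- (si * dd[i, ] + sj * dd[j, ]) / (si + sj)
    keep <- setdiff(seq_len(k), c(i, j))
    dd <- rbind(cbind(dd[keep, keep, drop = FALSE], newrow[keep]),
                c(newrow[keep], 0))
    active_id <- c(active_id[keep], step)
    sizes <- c(sizes[keep], si + sj)
    members <- c(members[keep], list(newmem))
  }
  structure(list(merge = merge, height = height, labels = labels,
                 leafsets = leafsets, N = n),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("upgma_tree: %d leaves, %d internal nodes, root height %.4f\n",
              x$N, x$N - 1, x$height[[x$N - 1]]))
  invisible(x)
}

#' Convert a UPGMA tree to ape phylo / export Newick
#'
#' @param tree an `upgma_tree`.
#' @return an [ape::as.phylo()] object.
#' @export
as_phylo <- function(tree) {
  hc <- structure(list(merge = tree$merge, height = tree$height,
                       order = seq_len(tree$N), labels = tree$labels,
                       method = "average"),
                  class = "hclust")
  hc$order <- stats::order.dendrogram(stats::as.dendrogram(hc))
  ape::as.phylo(hc)
}

#' @rdname as_phylo
#' @param path output Newick file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(as_phylo(tree), file = path)
  invisible(path)
}

# Internal: order of internal nodes by increasing distance from the root.
# UPGMA heights are monotone non-decreasing in creation order, so the root
# (last created) is first; equal-height nodes keep reverse creation order,
# giving one deterministic split per level (partition sizes 1..N-1).
root_order <- function(tree) {
  order(-tree$height, -seq_along(tree$height))
}

#' Nested leaf partitions by tree level
#'
#' Level n cuts the tree into exactly n groups: the root split is applied
#' first, then the next internal node by root distance, and so on.  The
#' partitions are nested (each refines the previous).
#'
#' @param tree an `upgma_tree`.
#' @return (N-1) x N integer matrix; row n assigns each leaf (column,
#'   ordered as `tree$labels`) to a group 1..n.
#' @export
tree_partitions <- function(tree) {
  n <- tree$N
  ord <- root_order(tree)
  part <- matrix(0L, n - 1, n)
  part[1, ] <- 1L
  if (n == 2) return(part)
  for (lvl in 2:(n - 1)) {
    node <- ord[[lvl - 1]]  # node consumed between level lvl-1 and lvl
    part[lvl, ] <- part[lvl - 1, ]
    # second child's leaves become a new group
    child <- tree$merge[node, 2]
    leaves <- if (child < 0) -child else tree$leafsets[[child]]
    part[lvl, leaves] <- lvl
  }
  # relabel groups to 1..n per row (cosmetic, keeps invariant simple)
  for (lvl in seq_len(n - 1)) {
    part[lvl, ] <- match(part[lvl, ], unique(part[lvl, ]))
  }
  part
}

# Internal: per-node symbol counts, entropies and variation flags.
# Returns for every cluster (leaf or internal) the per-column entropy
# vector and whether the column varies inside the cluster.  Computed
# bottom-up from one-hot leaf counts, so each internal node costs one
# matrix addition.
node_column_stats <- function(aln, tree) {
  m <- aln_matrix(aln)
  n <- tree$N; L <- aln$L_aln
  syms <- RNA_ALPHABET
  leaf_counts <- lapply(seq_len(n), function(i) {
    cm <- matrix(0L, length(syms), L)
    cm[cbind(match(m[i, ], syms), seq_len(L))] <- 1L
    cm
  })
  ent <- vector("list", 2 * n - 1)   # index: leaf i, or n + node
  varies <- vector("list", 2 * n - 1)
  counts <- vector("list", 2 * n - 1)
  for (i in seq_len(n)) {
    counts[[i]] <- leaf_counts[[i]]
    ent[[i]] <- numeric(L)
    varies[[i]] <- rep(FALSE, L)
  }
  for (node in seq_len(n - 1)) {
    ch <- tree$merge[node, ]
    idx <- ifelse(ch < 0, -ch, n + ch)
    cc <- counts[[idx[[1]]]] + counts[[idx[[2]]]]
    counts[[n + node]] <- cc
    size <- sum(cc[, 1])
    p <- cc / size
    pl <- p * log(p)
    pl[!is.finite(pl)] <- 0
    ent[[n + node]] <- -colSums(pl)
    varies[[n + node]] <- colSums(cc > 0) > 1
  }
  list(ent = ent, varies = varies, n = n, L = L)
}

#' Integer Evolutionary Trace ranks
#'
#' The classic trace: the absolute rank of column i is 1 plus the number
#' of tree levels at which the column still varies within at least one
#' group.  A fully conserved column earns rank 1; a column distinct in
#' every sequence earns rank N.  Gaps count as a nucleotide state.
#'
#' @param aln an `rna_alignment`.
#' @param tree matching `upgma_tree` (leaves = alignment ids).
#' @return An `et_trace` object (see [trace_result()]).
#' @export
integer_et <- function(aln, tree) {
  check_tree_matches(aln, tree)
  st <- node_column_stats(aln, tree)
  n <- st$n
  ord <- root_order(tree)
  # V[lvl, col]: number of groups at this level in which the column varies
  V <- st$varies[[n + ord[[1]]]] * 1L
  r <- 1 + (V > 0)
  if (n > 2) {
    for (lvl in 2:(n - 1)) {
      node <- ord[[lvl - 1]]
      ch <- tree$merge[node, ]
      idx <- ifelse(ch < 0, -ch, n + ch)
      V <- V - st$varies[[n + node]] + st$varies[[idx[[1]]]] + st$varies[[idx[[2]]]]
      r <- r + (V > 0)
    }
  }
  trace_result(r, method = "integer")
}

#' Real-value Evolutionary Trace ranks
#'
#' Entropy-weighted trace: each tree level contributes the mean Shannon
#' entropy (natural log) of the column within the level's groups, the
#' level with n groups weighted 1/n.  Fully conserved columns score
#' exactly 1; ranks are real-valued and better resolved than the integer
#' trace.  Gaps and N count as symbols of their own.
#'
#' @inheritParams integer_et
#' @return An `et_trace` object.
#' @export
rvet <- function(aln, tree) {
  check_tree_matches(aln, tree)
  st <- node_column_stats(aln, tree)
  n <- st$n
  ord <- root_order(tree)
  S <- st$ent[[n + ord[[1]]]]
  r <- 1 + S  # level 1, weight 1/1
  if (n > 2) {
    for (lvl in 2:(n - 1)) {
      node <- ord[[lvl - 1]]
      ch <- tree$merge[node, ]
      idx <- ifelse(ch < 0, -ch, n + ch)
      S <- S - st$ent[[n + node]] + st$ent[[idx[[1]]]] + st$ent[[idx[[2]]]]
      r <- r + S / lvl
    }
  }
  trace_result(r, method = "rvET")
}

check_tree_matches <- function(aln, tree) {
  if (!setequal(tree$labels, aln$ids) || tree$N != aln$N)
    stop("tree leaves do not match alignment ids", call. = FALSE)
  if (!identical(tree$labels, aln$ids))
    stop("tree leaf order differs from alignment order; rebuild the tree from this alignment",
         call. = FALSE)
  invisible(TRUE)
}

#' Trace result container
#'
#' @param rank numeric vector of per-column absolute ranks (or entropy
#'   scores for the conservation baseline).
#' @param method one of `"integer"`, `"rvET"`, `"entropy"`.
#' @return `et_trace` object: list with `rank`, `coverage` (percentile in
#'   (0, 100], ties sharing the largest position), `method`, `L`.
#' @export
trace_result <- function(rank, method = "rvET") {
  structure(list(rank = as.numeric(rank), coverage = coverage(rank),
                 method = method, L = length(rank)),
            class = "et_trace")
}

#' @export
print.et_trace <- function(x, ...) {
  cat(sprintf("et_trace (%s): %d columns, rank range [%.4g, %.4g]\n",
              x$method, x$L, min(x$rank), max(x$rank)))
  invisible(x)
}

#' @export
as.data.frame.et_trace <- function(x, ...) {
  data.frame(column = seq_len(x$L), rank = x$rank, coverage = x$coverage)
}

#' Percentile coverage of ranks
#'
#' Columns are sorted by ascending rank; the coverage of a column is 100
#' times the largest sorted position among the columns tied with it,
#' divided by the number of columns.  Coverage is in (0, 100] and tied
#' ranks share identical coverage.
#'
#' @param rank numeric vector.
#' @return numeric vector of the same length.
#' @export
coverage <- function(rank) {
  L <- length(rank)
  if (L < 1) stop("need at least one column", call. = FALSE)
  # largest sorted position among ties = count of values <= r
  sr <- sort(rank)
  pos <- vapply(rank, function(r) sum(sr <= r + 0), numeric(1))
  100 * pos / L
}

#' Shannon-entropy conservation baseline
#'
#' Tree-free per-column Shannon entropy (natural log) over the whole
#' alignment, normalized to the same percentile-coverage scale as the
#' trace methods.  Serves as the conservation comparator for ET.
#'
#' @param aln an `rna_alignment`.
#' @return An `et_trace` with `method = "entropy"`; `rank` holds the raw
#'   entropy values.
#' @export
shannon_conservation <- function(aln) {
  m <- aln_matrix(aln)
  ent <- apply(m, 2, function(col) {
    p <- table(col) / length(col)
    -sum(p * log(p))
  })
  trace_result(unname(ent), method = "entropy")
}
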