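#' Tertiary-structure contact graph
#'
#' Two residues are in contact when their minimum heavy-atom distance is
#' at most `cutoff` Angstrom (4 by default) and they are farther apart
#' along the chain than `exclude_neighbors` (immediate backbone neighbors
#' contact trivially and are excluded by default; set
#' `exclude_neighbors = 0` to keep them).
#'
#' @param struct an `rna_structure`.
#' @param cutoff contact distance cutoff in Angstrom.
#' @param exclude_neighbors chain-separation below or equal to which pairs
#'   are never contacts (default 1 = skip i,i+1).
#' @param atoms `"heavy"` (all heavy atoms) or `"c1"` (C1' only; falls
#'   back to all atoms for residues without a C1', e.g. pseudo-atom toys).
#' @return A `contact_graph`: list with `L`, logical adjacency `adj`,
#'   `context = "tertiary"`, `cutoff`.
#' @export
contact_graph_3d <- function(struct, cutoff = 4.0, exclude_neighbors = 1,
                             atoms = c("heavy", "c1")) {
  atoms <- match.arg(atoms)
  at <- struct$atoms
  L <- nrow(struct$residues)
  if (L < 2) stop("need at least 2 residues", call. = FALSE)
  xyz <- split(as.matrix(at[, c("x", "y", "z")]), at$res_index)
  xyz <- lapply(xyz, function(v) matrix(v, ncol = 3))
  adj <- matrix(FALSE, L, L)
  cut2 <- cutoff^2
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (j - i <= exclude_neighbors) next
      a <- xyz[[i]]; b <- xyz[[j]]
      # squared min distance between the two atom sets
      d2 <- min(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b))
      if (d2 <= cut2) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  new_contact_graph(adj, "tertiary", cutoff = cutoff)
}

#' Secondary-structure contact graph
#'
#' Edges are the base pairs plus the backbone neighbors (i, i+1).
#'
#' @param ss an `rna_ss` (see [parse_wuss()]), pairs in 1..L.
#' @param L number of positions.
#' @return A `contact_graph` with `context = "secondary"`.
#' @export
contact_graph_2d <- function(ss, L) {
  adj <- backbone_adj(L)
  if (nrow(ss$pairs)) {
    if (max(ss$pairs) > L || min(ss$pairs) < 1)
      stop("base-pair index outside 1..L", call. = FALSE)
    adj[ss$pairs] <- TRUE
    adj[ss$pairs[, c(2, 1), drop = FALSE]] <- TRUE
  }
  new_contact_graph(adj, "secondary")
}

#' Primary-sequence contact graph
#'
#' Backbone neighbors (i, i+1) only.
#'
#' @param L number of positions.
#' @return A `contact_graph` with `context = "primary"`.
#' @export
contact_graph_1d <- function(L) {
  new_contact_graph(backbone_adj(L), "primary")
}

backbone_adj <- function(L) {
  adj <- matrix(FALSE, L, L)
  if (L >= 2) {
    idx <- cbind(seq_len(L - 1), seq_len(L - 1) + 1L)
    adj[idx] <- TRUE
    adj[idx[, c(2, 1), drop = FALSE]] <- TRUE
  }
  adj
}

new_contact_graph <- function(adj, context, cutoff = NA_real_) {
  diag(adj) <- FALSE
  stopifnot(isSymmetric(adj))
  structure(list(L = nrow(adj), adj = adj, context = context, cutoff = cutoff),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("contact_graph (%s): %d positions, %d edges\n",
              x$context, x$L, graph_edge_count(x)))
  invisible(x)
}

graph_edge_count <- function(g) sum(g$adj) / 2

# number of unordered 2-paths (distinct triples i-c-j with c adjacent to both)
graph_two_paths <- function(g) {
  deg <- rowSums(g$adj)
  sum(choose(deg, 2))
}

#' Selection Clustering Weight
#'
#' The number of contact-graph edges with both endpoints in the selected
#' position set.
#'
#' @param sel integer vector of selected positions.
#' @param g a `contact_graph`.
#' @return integer edge count.
#' @export
scw <- function(sel, g) {
  sel <- unique(as.integer(sel))
  if (length(sel) && (min(sel) < 1 || max(sel) > g$L))
    stop("selection outside graph positions", call. = FALSE)
  if (length(sel) < 2) return(0L)
  as.integer(sum(g$adj[sel, sel]) / 2)
}

# Analytic mean and variance of SCW under uniform selection of k of L
# positions without replacement.  With E edges and T unordered 2-paths:
#   <w>    = E p2
#   Var(w) = E p2 + 2 T p3 + (E(E-1) - 2T) p4 - (E p2)^2
# where p_m is the probability that m given distinct positions are all
# selected, p_m = k(k-1)...(k-m+1) / (L(L-1)...(L-m+1)).
scw_null_moments <- function(k, g) {
  L <- g$L
  E <- graph_edge_count(g)
  Tp <- graph_two_paths(g)
  pm <- function(m) {
    if (k < m) return(0)
    prod((k - seq_len(m) + 1) / (L - seq_len(m) + 1))
  }
  mu <- E * pm(2)
  v <- E * pm(2) + 2 * Tp * pm(3) + (E * (E - 1) - 2 * Tp) * pm(4) - mu^2
  list(mean = mu, var = max(v, 0))
}

#' Clustering z-score of a selection
#'
#' Standardized excess of the Selection Clustering Weight over its
#' expectation under uniform random selection of the same number of
#' positions.  The analytic mode uses closed-form first and second
#' moments; the permutation mode estimates them by Monte Carlo.
#'
#' @param sel integer vector of selected positions.
#' @param g a `contact_graph`.
#' @param mode `"analytic"` or `"permutation"`.
#' @param n_perm number of random selections in permutation mode.
#' @param seed RNG seed for permutation mode (required there).
#' @return list with `w`, `expected_w`, `sigma`, `z`, `valid`.  When the
#'   null variance is zero the z-score is undefined: `z = NA`,
#'   `valid = FALSE`.
#' @export
clustering_z <- function(sel, g, mode = c("analytic", "permutation"),
                         n_perm = 10000, seed = NULL) {
  mode <- match.arg(mode)
  sel <- unique(as.integer(sel))
  k <- length(sel)
  w <- scw(sel, g)
  if (mode == "analytic") {
    mo <- scw_null_moments(k, g)
    mu <- mo$mean; sg <- sqrt(mo$var)
  } else {
    if (is.null(seed)) stop("permutation mode requires a seed", call. = FALSE)
    ws <- with_seed(seed, vapply(seq_len(n_perm), function(i)
      scw(sample.int(g$L, k), g), numeric(1)))
    mu <- mean(ws); sg <- stats::sd(ws)
  }
  valid <- is.finite(sg) && sg > 1e-12
  list(w = w, expected_w = mu, sigma = sg,
       z = if (valid) (w - mu) / sg else NA_real_, valid = valid)
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Cumulative clustering z-score profile
#'
#' Positions are binned cumulatively by trace rank: bin b (coverage
#' 100 b / L) selects all positions with coverage at most that threshold.
#' A bin is attained when its selection size equals b; bins inside a tied
#' rank plateau are not attained and inherit the z-score of the closest
#' valid bin (ties toward lower coverage).  The profile summary
#' `mean_0_35` averages the (filled) bins with coverage <= `max_cov`.
#'
#' A bin whose null variance is zero but whose observed weight equals its
#' expectation exactly (for example the full selection) is scored z = 0
#' and counts as valid; a zero-variance bin with a non-zero deviation is
#' invalid.
#'
#' @param trace an `et_trace` whose positions correspond to graph
#'   positions (map alignment columns first if needed).
#' @param g a `contact_graph` with `L == trace$L`.
#' @param max_cov upper coverage bound of the summary window (default 35).
#' @return A `z_profile`: list with `bins` data frame (`bin`,
#'   `coverage_bin`, `selection_size`, `w`, `expected_w`, `sigma`, `z`,
#'   `valid`, `z_filled`) and `mean_0_35`.
#' @export
z_profile <- function(trace, g, max_cov = 35) {
  if (trace$L != g$L)
    stop("trace and contact graph cover different numbers of positions", call. = FALSE)
  L <- trace$L
  ord <- order(trace$coverage, seq_len(L))
  scov <- trace$coverage[ord]
  thr <- 100 * seq_len(L) / L
  # cumulative SCW: adding the b-th position contributes its edges into
  # the current selection
  w_inc <- numeric(L)
  insel <- rep(FALSE, L)
  for (b in seq_len(L)) {
    p <- ord[[b]]
    w_inc[[b]] <- sum(g$adj[p, insel])
    insel[[p]] <- TRUE
  }
  w_run <- cumsum(w_inc)
  attained <- scov <= thr + 1e-9 & c(scov[-1] > thr[-L] + 1e-9, TRUE)
  E <- graph_edge_count(g)
  Tp <- graph_two_paths(g)
  b <- seq_len(L)
  p2 <- b * (b - 1) / (L * (L - 1))
  p3 <- if (L > 2) p2 * pmax(b - 2, 0) / (L - 2) else rep(0, L)
  p4 <- if (L > 3) p3 * pmax(b - 3, 0) / (L - 3) else rep(0, L)
  mu <- E * p2
  sg <- sqrt(pmax(E * p2 + 2 * Tp * p3 + (E * (E - 1) - 2 * Tp) * p4 - mu^2, 0))
  z <- ifelse(sg > 1e-12, (w_run - mu) / sg,
              ifelse(abs(w_run - mu) < 1e-9, 0, NA_real_))
  valid <- attained & !is.na(z)
  bins <- data.frame(bin = b, coverage_bin = thr, selection_size = b,
                     w = w_run, expected_w = mu, sigma = sg, z = z,
                     valid = valid)
  finalize_profile(bins, max_cov, kind = "clustering")
}

# shared by clustering and overlap profiles: fill non-valid bins from the
# closest valid bin (ties toward lower coverage) and average over the
# 0..max_cov window
finalize_profile <- function(bins, max_cov, kind) {
  vidx <- which(bins$valid)
  if (!length(vidx))
    stop("no valid bin in the z-score profile", call. = FALSE)
  fill <- vapply(seq_len(nrow(bins)), function(b) {
    if (bins$valid[[b]]) return(bins$z[[b]])
    d <- abs(vidx - b)
    pick <- vidx[d == min(d)]
    bins$z[[min(pick)]]  # tie toward lower coverage
  }, numeric(1))
  bins$z_filled <- fill
  win <- bins$coverage_bin <= max_cov + 1e-9
  if (!any(win))
    stop("no profile bin at or below the coverage window", call. = FALSE)
  structure(list(bins = bins, mean_0_35 = mean(fill[win]), kind = kind,
                 max_cov = max_cov),
            class = "z_profile")
}

#' @export
print.z_profile <- function(x, ...) {
  cat(sprintf("z_profile (%s): %d bins, mean z over 0-%g%% coverage = %.3f\n",
              x$kind, nrow(x$bins), x$max_cov, x$mean_0_35))
  invisible(x)
}

#' Evolutionary Trace smoothness
#'
#' Sum over structurally adjacent position pairs of the squared rank
#' difference.  Lower values mean evolutionary importance varies smoothly
#' over the structure.  Uses percentile coverage by default so values are
#' comparable across molecules; set `x = "rank"` for absolute ranks.
#'
#' @param trace an `et_trace`.
#' @param g a `contact_graph` with matching positions.
#' @param x `"coverage"` or `"rank"`.
#' @return non-negative numeric; 0 iff all adjacent positions share one
#'   rank.
#' @export
smoothness <- function(trace, g, x = c("coverage", "rank")) {
  x <- match.arg(x)
  if (trace$L != g$L)
    stop("trace and contact graph cover different numbers of positions", call. = FALSE)
  v <- if (x == "coverage") trace$coverage else trace$rank
  idx <- which(upper.tri(g$adj) & g$adj, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  sum((v[idx[, 1]] - v[idx[, 2]])^2)
}
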