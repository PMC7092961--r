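#' Hypergeometric overlap z-score
#'
#' Standardized excess of functional-site members recovered by a
#' selection of size `n` from a universe of `N_pos` positions containing
#' `M` site members.  The expected overlap is `m = n M / N_pos`; the
#' standard deviation is the hypergeometric one,
#' `sqrt(n (M/N) (1 - M/N) (N - n) / (N - 1))`.
#'
#' @param n selection size (0 < n < N_pos).
#' @param M site size (0 < M < N_pos).
#' @param N_pos universe size.
#' @param k observed number of site members in the selection.
#' @return list with `k`, `m`, `sigma`, `z`, `valid`; `z = NA` and
#'   `valid = FALSE` when the null variance vanishes.
#' @export
overlap_z <- function(n, M, N_pos, k) {
  if (n <= 0 || n >= N_pos || M <= 0 || M >= N_pos) {
    m <- n * M / N_pos
    return(list(k = k, m = m, sigma = 0, z = NA_real_, valid = FALSE))
  }
  m <- n * M / N_pos
  sigma <- sqrt(n * (M / N_pos) * (1 - M / N_pos) * (N_pos - n) / (N_pos - 1))
  valid <- sigma > 1e-12
  list(k = k, m = m, sigma = sigma,
       z = if (valid) (k - m) / sigma else NA_real_, valid = valid)
}

#' Cumulative overlap z-score profile for a functional site
#'
#' Positions belonging to excluded sites are removed from the universe
#' before binning (they count neither as positives nor negatives), then
#' the remaining positions are cumulatively binned by trace rank exactly
#' as in the clustering profile.  Each attained bin is scored with
#' [overlap_z()]; non-attained or zero-variance bins inherit the closest
#' valid bin.  Also reports the ROC AUC of the ranking against the site.
#'
#' @param trace an `et_trace`; positions index the trace.
#' @param site_positions integer vector: site members, as trace positions
#'   (map structure residues to columns first if needed).
#' @param exclude_positions positions of other known sites to drop from
#'   the universe.
#' @param max_cov coverage window for the summary mean (default 35).
#' @return An `overlap_result`: list with `bins` data frame (`bin`,
#'   `coverage_bin`, `n`, `k`, `m`, `sigma`, `z`, `valid`, `z_filled`),
#'   `mean_0_35`, `auc`, `N_pos`, `M`.
#' @export
overlap_profile <- function(trace, site_positions, exclude_positions = integer(0),
                            max_cov = 35) {
  L <- trace$L
  site_positions <- unique(as.integer(site_positions))
  if (length(site_positions) && (min(site_positions) < 1 || max(site_positions) > L))
    stop("site positions outside trace positions", call. = FALSE)
  universe <- setdiff(seq_len(L), exclude_positions)
  site_u <- intersect(site_positions, universe)
  if (!length(site_u))
    stop("functional site is empty after exclusion", call. = FALSE)
  N_pos <- length(universe)
  M <- length(site_u)
  # re-rank within the shrunken universe
  cov_u <- coverage(trace$rank[universe])
  ord <- order(cov_u, seq_len(N_pos))
  scov <- cov_u[ord]
  is_site <- universe %in% site_u
  b <- seq_len(N_pos)
  thr <- 100 * b / N_pos
  k_run <- cumsum(is_site[ord])
  attained <- scov <= thr + 1e-9 & c(scov[-1] > thr[-N_pos] + 1e-9, TRUE)
  m <- b * M / N_pos
  sg <- ifelse(b < N_pos,
               sqrt(b * (M / N_pos) * (1 - M / N_pos) * (N_pos - b) / (N_pos - 1)),
               0)
  z <- ifelse(sg > 1e-12, (k_run - m) / sg, NA_real_)
  bins <- data.frame(bin = b, coverage_bin = thr, n = b, k = k_run,
                     m = m, sigma = sg, z = z,
                     valid = attained & !is.na(z) & sg > 1e-12)
  prof <- finalize_profile(bins, max_cov, kind = "overlap")
  prof$auc <- roc_auc_scores(-cov_u, is_site)
  prof$N_pos <- N_pos
  prof$M <- M
  class(prof) <- c("overlap_result", class(prof))
  prof
}

#' ROC AUC of a trace against a functional site
#'
#' Area under the ROC curve by pair counting: the fraction of
#' (positive, negative) position pairs in which the site member is ranked
#' better (lower coverage), ties scoring 1/2.
#'
#' @inheritParams overlap_profile
#' @return numeric AUC in `[0, 1]`.
#' @export
roc_auc <- function(trace, site_positions, exclude_positions = integer(0)) {
  L <- trace$L
  universe <- setdiff(seq_len(L), exclude_positions)
  labels <- universe %in% site_positions
  if (!any(labels) || all(labels))
    stop("need at least one positive and one negative position", call. = FALSE)
  roc_auc_scores(-trace$coverage[universe], labels)
}

# Mann-Whitney formulation; identical to explicit pair counting with ties
# credited 1/2 (asserted against the pair-count oracle in the tests)
roc_auc_scores <- function(score, label) {
  np <- sum(label); nn <- sum(!label)
  if (np == 0 || nn == 0)
    stop("need at least one positive and one negative position", call. = FALSE)
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - np * (np + 1) / 2) / (np * nn)
}

#' One-sided hypergeometric 2x2 test
#'
#' Tail probability of observing at least `k1` successes in `n1` draws
#' without replacement from the pooled population of `n1 + n2` elements
#' containing `k1 + k2` successes.  Used e.g. to compare the fraction of
#' backbone-mediated contacts between two sets of inter-subunit bridge
#' contacts.
#'
#' @param k1,n1 successes and draws in the first group.
#' @param k2,n2 successes and draws in the second group.
#' @return one-sided p-value.
#' @export
hypergeom_2x2 <- function(k1, n1, k2, n2) {
  stopifnot(k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
  K <- k1 + k2
  N <- n1 + n2
  stats::phyper(k1 - 1, K, N - K, n1, lower.tail = FALSE)
}
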