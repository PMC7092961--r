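#' Rank Entropy of a trace
#'
#' Shannon entropy (natural log) of the distribution of distinct rank
#' values over columns: zero when every column shares one rank (an
#' entirely conserved alignment), maximal (`ln L`) when every column has
#' a unique rank.  Used to keep alignment optimization from collapsing to
#' a few invariant sequences.
#'
#' @param trace an `et_trace`.
#' @return list with `RE` and the rank-value frequency table `f_r`.
#' @export
rank_entropy <- function(trace) {
  f <- table(trace$rank) / trace$L
  list(RE = -sum(f * log(f)), f_r = f)
}

#' Randomly degrade an alignment
#'
#' Replaces a fraction `shuffle_rate` of the non-gap characters (chosen
#' uniformly at random) with uniform random bases from A, C, G, U; gaps
#' are never touched.  At rate 1 every non-gap character is resampled and
#' the expected per-site identity with the original is 0.25.  The
#' alternative mode permutes characters within their columns instead.
#'
#' @param aln an `rna_alignment`.
#' @param shuffle_rate fraction in `[0, 1]`.
#' @param seed RNG seed (required: degradation is stochastic).
#' @param mode `"resample"` (default) or `"permute"` (within-column
#'   shuffle of the selected characters).
#' @return a degraded `rna_alignment`.
#' @export
degrade_alignment <- function(aln, shuffle_rate, seed,
                              mode = c("resample", "permute")) {
  mode <- match.arg(mode)
  stopifnot(shuffle_rate >= 0, shuffle_rate <= 1)
  if (shuffle_rate == 0) return(aln)
  m <- aln_matrix(aln)
  nongap <- which(m != "-")
  n_pick <- round(shuffle_rate * length(nongap))
  with_seed(seed, {
    pick <- if (n_pick > 0) sample(nongap, n_pick) else integer(0)
    if (mode == "resample") {
      m[pick] <- sample(c("A", "C", "G", "U"), length(pick), replace = TRUE)
    } else {
      cols <- ((pick - 1) %/% nrow(m)) + 1
      for (cc in unique(cols)) {
        idx <- pick[cols == cc]
        m[idx] <- m[sample(idx)]
      }
    }
  })
  rna_alignment(aln$ids, apply(m, 1, paste, collapse = ""),
                query_id = aln$query_id, ss_cons = aln$ss_cons)
}

#' Alignment degradation study
#'
#' Reproduces the alignment-quality experiment: degrade the alignment at
#' a series of shuffle rates, re-trace each replicate, and record the
#' mean overlap z-score, mean clustering z-score and smoothness per rate
#' bin, together with the Pearson correlations of the rate-bin means.
#'
#' @param aln an `rna_alignment`.
#' @param g a `contact_graph` over the trace positions.
#' @param site_positions functional-site members as trace positions.
#' @param rates numeric vector of shuffle rates (at least 3).
#' @param reps replicates per rate.
#' @param seed base RNG seed; replicate r at rate index i uses a seed
#'   derived deterministically from it.
#' @param method trace method, `"rvet"` (default) or `"integer"`.
#' @return list with `table` (`rate`, `z_o`, `z_c`, `smt` means),
#'   `cor_zo_zc`, `cor_zo_smt`.
#' @export
degradation_study <- function(aln, g, site_positions, rates, reps = 3, seed = 1,
                              method = c("rvet", "integer")) {
  method <- match.arg(method)
  if (length(rates) < 3)
    stop("need at least 3 rate bins to report correlations", call. = FALSE)
  rows <- vector("list", length(rates))
  for (i in seq_along(rates)) {
    zo <- zc <- sm <- numeric(reps)
    for (r in seq_len(reps)) {
      dseed <- (seed * 1000L + i * 100L + r) %% .Machine$integer.max
      da <- degrade_alignment(aln, rates[[i]], seed = dseed)
      tree <- build_upgma(da)
      tr <- if (method == "rvet") rvet(da, tree) else integer_et(da, tree)
      zc[[r]] <- z_profile(tr, g)$mean_0_35
      zo[[r]] <- overlap_profile(tr, site_positions)$mean_0_35
      sm[[r]] <- smoothness(tr, g)
    }
    rows[[i]] <- data.frame(rate = rates[[i]], z_o = mean(zo), z_c = mean(zc),
                            smt = mean(sm))
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       cor_zo_zc = stats::cor(tab$z_o, tab$z_c),
       cor_zo_smt = stats::cor(tab$z_o, tab$smt))
}

#' Optimize alignment selection over a random sub-alignment ensemble
#'
#' Generates an ensemble of sub-alignments by removing a uniform-random
#' number of sequences (1 to N - min_keep - 1; the query row is always
#' retained), traces each member, and selects the member maximizing the
#' chosen criterion: `"zc35"` maximizes the mean clustering z-score over
#' the 0-35% coverage window; `"re_smt"` maximizes the product of
#' min-max-normalized Rank Entropy and (1 - min-max-normalized
#' smoothness), both normalized over the current ensemble, so diversity
#' guards against the degenerate few-invariant-sequences optimum that
#' pure smoothness selects.  `"smt"` (pure smoothness, minimized) is
#' provided to expose that failure mode.
#'
#' @param ref_aln reference `rna_alignment` (N > min_keep + 1).
#' @param g a `contact_graph` over the trace positions.
#' @param criterion `"zc35"`, `"re_smt"` or `"smt"`.
#' @param ensemble_size number of ensemble members.
#' @param min_keep minimum number of retained sequences (default 20).
#' @param seed base RNG seed; member i draws from a seed derived from it.
#' @param method trace method.
#' @return list with `best` (the selected `rna_alignment`), `best_id`,
#'   and `records` data frame (`member_id`, `n_removed`, `zc35`, `SMT`,
#'   `RE`, `score`, `seed`).
#' @export
optimize_alignment <- function(ref_aln, g, criterion = c("zc35", "re_smt", "smt"),
                               ensemble_size = 100, min_keep = 20, seed = 1,
                               method = c("rvet", "integer")) {
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  N <- ref_aln$N
  if (N <= min_keep + 1)
    stop("alignment too small: need N > min_keep + 1", call. = FALSE)
  if (ensemble_size < 1) stop("ensemble_size must be >= 1", call. = FALSE)
  removable <- setdiff(ref_aln$ids, ref_aln$query_id)
  members <- vector("list", ensemble_size)
  recs <- vector("list", ensemble_size)
  for (i in seq_len(ensemble_size)) {
    mseed <- (seed * 10000L + i) %% .Machine$integer.max
    sub <- with_seed(mseed, {
      n_rm <- sample.int(N - min_keep - 1L, 1L)
      rm_ids <- sample(removable, min(n_rm, length(removable)))
      keep <- !ref_aln$ids %in% rm_ids
      rna_alignment(ref_aln$ids[keep], ref_aln$rows[keep],
                    query_id = ref_aln$query_id, ss_cons = ref_aln$ss_cons)
    })
    tree <- build_upgma(sub)
    tr <- if (method == "rvet") rvet(sub, tree) else integer_et(sub, tree)
    zc <- tryCatch(z_profile(tr, g)$mean_0_35, error = function(e) NA_real_)
    recs[[i]] <- data.frame(member_id = i, n_removed = N - sub$N,
                            zc35 = zc, SMT = smoothness(tr, g),
                            RE = rank_entropy(tr)$RE, seed = mseed)
    members[[i]] <- sub
  }
  records <- do.call(rbind, recs)
  score <- switch(criterion,
    zc35 = records$zc35,
    smt = -records$SMT,
    re_smt = {
      re_n <- minmax(records$RE)
      smt_n <- minmax(records$SMT)
      re_n * (1 - smt_n)
    })
  records$score <- score
  ok <- which(is.finite(score))
  if (!length(ok)) stop("all ensemble members have invalid scores", call. = FALSE)
  best_id <- ok[[which.max(score[ok])]]  # ties: lowest member_id
  list(best = members[[best_id]], best_id = best_id, records = records)
}

minmax <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) < 1e-12) return(rep(0.5, length(x)))
  (x - rng[[1]]) / diff(rng)
}
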