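#' Synthetic-fixture specification
#'
#' Describes a tree-structured synthetic alignment plus a toy helix
#' structure with a planted functional site, used to exercise and
#' calibrate every pipeline stage without external data.  Leaves form a
#' balanced binary tree; columns come in three classes: conserved
#' (identical in all leaves), clade-specific (fixed within each clade at
#' `clade_depth`, distinct between clades — the signal that separates ET
#' from plain conservation), and random (iid uniform bases).  The
#' conserved and clade-specific columns form one contiguous block, so on
#' the helix structure the planted site is spatially clustered.
#'
#' @param n_leaves number of sequences; a power of 2.
#' @param L number of alignment columns.
#' @param class_fractions fractions (conserved, clade_specific, random);
#'   must sum to 1.
#' @param clade_depth tree depth at which clade-specific columns are
#'   fixed (1 = the two top-level clades).
#' @param rise,twist,radius helix geometry: rise per residue (Angstrom),
#'   twist per residue (degrees), radius (Angstrom).  The defaults put
#'   residues i and i+2 about 3.6 A apart, inside the 4 A contact cutoff,
#'   while i and i+1 (excluded backbone neighbors) are 2.3 A apart.
#' @param site_offset 1-based column at which the important block starts.
#' @param multi_atom if TRUE each residue gets two atoms (exercises the
#'   minimum-distance contact rule).
#' @param noise per-character substitution probability applied to the
#'   conserved and clade-specific columns (default 0: clean class
#'   signal).  Non-zero noise blurs whole-column conservation while the
#'   phylogenetic signal survives within clades, the regime in which the
#'   entropy-weighted trace outperforms plain conservation.
#' @param seed RNG seed for sequence generation.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_leaves = 16, L = 80,
                         class_fractions = c(conserved = 0.2,
                                             clade_specific = 0.2,
                                             random = 0.6),
                         clade_depth = 1, rise = 1.0, twist = 30, radius = 3.0,
                         site_offset = 1, multi_atom = FALSE, noise = 0,
                         seed = 1) {
  if (bitwAnd(n_leaves, n_leaves - 1L) != 0 || n_leaves < 4)
    stop("n_leaves must be a power of 2, at least 4", call. = FALSE)
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class fractions must sum to 1", call. = FALSE)
  if (2^clade_depth > n_leaves) stop("clade_depth too deep for n_leaves", call. = FALSE)
  if (2^clade_depth > 4)
    stop("clade_depth > 2 cannot give each clade a distinct base", call. = FALSE)
  structure(list(n_leaves = n_leaves, L = L,
                 class_fractions = class_fractions, clade_depth = clade_depth,
                 rise = rise, twist = twist, radius = radius,
                 site_offset = site_offset, multi_atom = multi_atom,
                 noise = noise, seed = seed),
            class = "fixture_spec")
}

#' Generate a synthetic fixture
#'
#' @param spec a [fixture_spec()].
#' @return list of class `rna_fixture`: `alignment` (`rna_alignment`),
#'   `structure` (`rna_structure`, pseudo-atom helix, residues in column
#'   order), `site` (`functional_site` over the conserved and
#'   clade-specific columns), `truth` (character vector of per-column
#'   class labels), `spec`.
#' @export
make_fixture <- function(spec) {
  L <- spec$L; n <- spec$n_leaves
  n_cons <- round(spec$class_fractions[[1]] * L)
  n_clade <- round(spec$class_fractions[[2]] * L)
  n_rand <- L - n_cons - n_clade
  n_imp <- n_cons + n_clade
  if (spec$site_offset + n_imp - 1 > L)
    stop("important block does not fit at site_offset", call. = FALSE)
  truth <- rep("random", L)
  block <- seq(spec$site_offset, length.out = n_imp)
  cons_slots <- block[seq_len(n_cons)]
  clade_slots <- setdiff(block, cons_slots)
  truth[cons_slots] <- "conserved"
  truth[clade_slots] <- "clade_specific"
  bases <- c("A", "C", "G", "U")
  n_clades <- 2^spec$clade_depth
  clade_of <- rep(seq_len(n_clades), each = n / n_clades)
  m <- with_seed(spec$seed, {
    mm <- matrix("", n, L)
    for (j in seq_len(L)) {
      mm[, j] <- switch(truth[[j]],
        conserved = rep(sample(bases, 1), n),
        clade_specific = sample(bases, n_clades)[clade_of],
        random = sample(bases, n, replace = TRUE))
    }
    if (spec$noise > 0) {
      imp <- which(truth != "random")
      for (j in imp) {
        hit <- stats::runif(n) < spec$noise
        if (any(hit)) mm[hit, j] <- sample(bases, sum(hit), replace = TRUE)
      }
    }
    mm
  })
  ids <- sprintf("s%02d", seq_len(n))
  aln <- rna_alignment(ids, apply(m, 1, paste, collapse = ""), query_id = ids[[1]])
  struct <- helix_structure(L, rise = spec$rise, twist = spec$twist,
                            radius = spec$radius, multi_atom = spec$multi_atom,
                            bases = m[1, ])
  site <- if (n_imp > 0) functional_site("planted", sort(c(cons_slots, clade_slots))) else NULL
  structure(list(alignment = aln, structure = struct, site = site,
                 truth = truth, spec = spec),
            class = "rna_fixture")
}

# toy helix: one pseudo-atom (or two, slightly offset) per residue
helix_structure <- function(L, rise, twist, radius, multi_atom = FALSE,
                            bases = rep("A", L)) {
  th <- (seq_len(L) - 1) * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), (seq_len(L) - 1) * rise)
  res_index <- seq_len(L)
  if (multi_atom) {
    off <- cbind(0.4 * cos(th + pi / 2), 0.4 * sin(th + pi / 2), 0.2)
    xyz <- rbind(xyz, xyz + off)
    res_index <- c(res_index, res_index)
    ord <- order(res_index)
    xyz <- xyz[ord, , drop = FALSE]
    res_index <- res_index[ord]
  }
  residues <- data.frame(chain = "A", resno = seq_len(L), base = bases,
                         res_index = seq_len(L), stringsAsFactors = FALSE)
  atoms <- data.frame(res_index = res_index,
                      x = round(xyz[, 1], 3), y = round(xyz[, 2], 3),
                      z = round(xyz[, 3], 3))
  structure(list(residues = residues, atoms = atoms,
                 sequence = paste(bases, collapse = "")),
            class = "rna_structure")
}

#' Write a fixture bundle to disk
#'
#' Writes `alignment.sto` (Stockholm), `structure.pdb`, `sites.tsv` and
#' `truth.json` into `dir`.  Deterministic bytes for a fixed-spec, fixed
#' seed fixture.
#'
#' @param fixture an `rna_fixture`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named files.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(alignment = file.path(dir, "alignment.sto"),
             structure = file.path(dir, "structure.pdb"),
             sites = file.path(dir, "sites.tsv"),
             truth = file.path(dir, "truth.json"))
  write_alignment(fixture$alignment, paths[["alignment"]], format = "stockholm")
  write_structure_pdb(fixture$structure, paths[["structure"]])
  if (!is.null(fixture$site)) write_sites(list(fixture$site), paths[["sites"]])
  jsonlite::write_json(list(truth = fixture$truth,
                            site = if (is.null(fixture$site)) integer(0) else fixture$site$members,
                            seed = fixture$spec$seed),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Write an `rna_structure` as a PDB file
#'
#' @param struct an `rna_structure`.
#' @param path output file.
#' @export
write_structure_pdb <- function(struct, path) {
  at <- struct$atoms
  res <- struct$residues
  base <- res$base[at$res_index]
  lines <- sprintf("ATOM  %5d %4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                   seq_len(nrow(at)),
                   ifelse(duplicated(at$res_index), " C2 ", " C1'"),
                   base, "A", res$resno[at$res_index], at$x, at$y, at$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
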