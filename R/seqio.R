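RNA_ALPHABET <- c("A", "C", "G", "U", "N", "-")

normalize_seq <- function(x) {
  x <- toupper(x)
  x <- chartr("T", "U", x)
  x <- gsub("[.~]", "-", x)
  # anything outside the working alphabet becomes the ambiguity code N
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(ch) {
    ch[!ch %in% RNA_ALPHABET] <- "N"
    paste(ch, collapse = "")
  }, character(1))
}

#' RNA multiple sequence alignment
#'
#' Construct a normalized alignment over the alphabet A, C, G, U, N, `-`.
#' Uppercasing, T to U, and mapping of the gap characters `.`, `~`, `-`
#' to `-` are applied; any remaining character becomes N.  Gaps are kept as
#' a first-class fifth symbol throughout the package, so they participate
#' in distance and entropy computations.
#'
#' @param ids character vector of sequence identifiers.
#' @param rows character vector of aligned sequences (equal lengths).
#' @param query_id identifier of the reference sequence (defaults to the
#'   first id); used when mapping alignment columns onto a structure.
#' @param ss_cons optional consensus secondary-structure string (WUSS).
#' @return An object of class `rna_alignment` with fields `ids`, `rows`,
#'   `N`, `L_aln`, `query_id`, `ss_cons`.
#' @export
rna_alignment <- function(ids, rows, query_id = ids[[1]], ss_cons = NULL) {
  ids <- as.character(ids)
  rows <- normalize_seq(as.character(rows))
  if (length(ids) != length(rows)) stop("ids and rows differ in length", call. = FALSE)
  if (length(rows) < 2) stop("alignment needs at least 2 sequences", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) stop("ragged alignment: rows differ in width", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence identifiers", call. = FALSE)
  if (!query_id %in% ids) stop("query_id not present in alignment", call. = FALSE)
  structure(list(ids = ids, rows = rows, N = length(rows), L_aln = widths[[1]],
                 query_id = query_id, ss_cons = ss_cons),
            class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("rna_alignment: %d sequences x %d columns (query: %s)\n",
              x$N, x$L_aln, x$query_id))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param aln an `rna_alignment`.
#' @return N x L character matrix with sequence ids as rownames.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA or Stockholm.  For Stockholm, the `#=GC SS_cons`
#' annotation line is captured verbatim (concatenated across interleaved
#' blocks) and stored on the returned alignment.
#'
#' @param path file path.
#' @param format `"auto"` (sniff first line), `"stockholm"` or `"fasta"`.
#' @param query_id reference sequence id; defaults to the first sequence.
#' @return An [rna_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "stockholm", "fasta"),
                           query_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) < 2) stop("alignment needs at least 2 sequences", call. = FALSE)
    ids <- sub("\\s.*$", "", names(set))
    rows <- as.character(set)
    aln <- rna_alignment(ids, unname(rows),
                         query_id = if (is.null(query_id)) ids[[1]] else query_id)
    return(aln)
  }
  read_stockholm(path, query_id = query_id)
}

# Stockholm reader (interleaved blocks supported); keeps #=GC SS_cons.
# Biostrings parses the sequences of this format but drops the GC
# annotation we need downstream, hence the dedicated reader.
read_stockholm <- function(path, query_id = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[[1]]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header)", call. = FALSE)
  seqs <- list()
  ss <- character(0)
  for (ln in lines[-1]) {
    if (grepl("^\\s*$", ln) || identical(ln, "//")) next
    if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
      ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
      next
    }
    if (grepl("^#", ln)) next
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2)
      stop("malformed Stockholm sequence line: ", ln, call. = FALSE)
    nm <- parts[[1]]
    seqs[[nm]] <- paste0(if (is.null(seqs[[nm]])) "" else seqs[[nm]], parts[[2]])
  }
  if (length(seqs) < 2) stop("alignment needs at least 2 sequences", call. = FALSE)
  ids <- names(seqs)
  rna_alignment(ids, unlist(seqs, use.names = FALSE),
                query_id = if (is.null(query_id)) ids[[1]] else query_id,
                ss_cons = if (length(ss)) paste(ss, collapse = "") else NULL)
}

#' Write an alignment
#'
#' @param aln an `rna_alignment`.
#' @param path output file.
#' @param format `"stockholm"` or `"fasta"`.
#' @export
write_alignment <- function(aln, path, format = c("stockholm", "fasta")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(paste0(">", aln$ids, "\n", aln$rows), path)
    return(invisible(path))
  }
  w <- max(nchar(aln$ids), nchar("#=GC SS_cons"))
  body <- sprintf("%-*s %s", w, aln$ids, aln$rows)
  if (!is.null(aln$ss_cons))
    body <- c(body, sprintf("%-*s %s", w, "#=GC SS_cons", aln$ss_cons))
  writeLines(c("# STOCKHOLM 1.0", body, "//"), path)
  invisible(path)
}

#' Parse WUSS/dot-bracket secondary structure
#'
#' Supports the nested bracket families `()`, `<>`, `[]`, `{}` and the
#' pseudoknot letter families `Aa`..`Zz` (uppercase opens, lowercase
#' closes).  Every other character is unpaired.  Each family is resolved
#' with its own stack, so crossing (pseudoknotted) pairs between families
#' are representable.
#'
#' @param ss_string secondary-structure string.
#' @return An object of class `rna_ss`: list with `pairs` (two-column
#'   integer matrix, i < j, 1-based positions) and `length`.
#' @export
parse_wuss <- function(ss_string) {
  ch <- strsplit(ss_string, "", fixed = TRUE)[[1]]
  openers <- c("(" = ")", "<" = ">", "[" = "]", "{" = "}",
               stats::setNames(letters, LETTERS))
  closers <- stats::setNames(names(openers), openers)
  stacks <- list()
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    c_i <- ch[[i]]
    if (c_i %in% names(openers)) {
      stacks[[c_i]] <- c(stacks[[c_i]], i)
    } else if (c_i %in% names(closers)) {
      fam <- closers[[c_i]]
      st <- stacks[[fam]]
      if (!length(st))
        stop(sprintf("unbalanced secondary structure: unmatched '%s' (family '%s%s') at position %d",
                     c_i, fam, c_i, i), call. = FALSE)
      pairs <- rbind(pairs, c(st[[length(st)]], i))
      stacks[[fam]] <- st[-length(st)]
    }
  }
  left <- vapply(stacks, length, integer(1))
  if (any(left > 0)) {
    fam <- names(stacks)[which(left > 0)[[1]]]
    stop(sprintf("unbalanced secondary structure: %d unmatched '%s' (family '%s%s')",
                 left[[fam]], fam, fam, openers[[fam]]), call. = FALSE)
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  if (anyDuplicated(as.vector(pairs)))
    stop("secondary structure assigns a position to more than one pair", call. = FALSE)
  structure(list(pairs = pairs, length = length(ch)), class = "rna_ss")
}

# render an rna_ss back to dot-bracket (nested pairs only); used in tests
ss_to_string <- function(ss) {
  out <- rep(".", ss$length)
  if (nrow(ss$pairs)) {
    out[ss$pairs[, 1]] <- "("
    out[ss$pairs[, 2]] <- ")"
  }
  paste(out, collapse = "")
}

# residue names accepted as nucleic; covers RNA, DNA and common one-letter
NUCLEIC_RESID <- c(A = "A", C = "C", G = "G", U = "U", T = "U", N = "N", I = "N",
                   DA = "A", DC = "C", DG = "G", DT = "U", DU = "U", DI = "N",
                   RA = "A", RC = "C", RG = "G", RU = "U")

#' Read an RNA chain from a PDB or mmCIF file
#'
#' Keeps heavy atoms only (hydrogens dropped) of the nucleic residues of
#' one chain, in chain order.  For multi-model files only the first model
#' is used (bio3d default).
#'
#' @param path PDB (`.pdb`/`.ent`) or mmCIF (`.cif`) file.
#' @param chain chain identifier; default takes the first chain containing
#'   nucleic residues.
#' @return Object of class `rna_structure`: `residues` data frame (`chain`,
#'   `resno`, `base`, `res_index`), `atoms` data frame (`res_index`, `x`,
#'   `y`, `z`), and `sequence` (one-letter string over the residues).
#' @export
read_structure <- function(path, chain = NULL) {
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  at <- at[at$type == "ATOM" | at$type == "HETATM", , drop = FALSE]
  nucleic <- toupper(trimws(at$resid)) %in% names(NUCLEIC_RESID)
  if (!is.null(chain)) {
    if (!chain %in% unique(at$chain)) stop("chain '", chain, "' not found", call. = FALSE)
    keep_chain <- at$chain == chain
  } else {
    cands <- unique(at$chain[nucleic])
    if (!length(cands)) stop("no nucleic residues in structure", call. = FALSE)
    keep_chain <- at$chain == cands[[1]]
  }
  at <- at[keep_chain & nucleic, , drop = FALSE]
  if (!nrow(at)) stop("no nucleic residues in selected chain", call. = FALSE)
  # drop hydrogens by element symbol when present, else by atom-name prefix
  elem <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy)))) {
    toupper(trimws(at$elesy))
  } else {
    sub("^[0-9]*([A-Za-z]).*$", "\\1", toupper(trimws(at$elety)))
  }
  at <- at[elem != "H" & elem != "D", , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms in selected chain", call. = FALSE)
  key <- paste(at$chain, at$resno, at$insert)
  res_index <- match(key, unique(key))
  first <- !duplicated(key)
  residues <- data.frame(chain = at$chain[first], resno = at$resno[first],
                         base = unname(NUCLEIC_RESID[toupper(trimws(at$resid[first]))]),
                         res_index = res_index[first], stringsAsFactors = FALSE)
  atoms <- data.frame(res_index = res_index, x = at$x, y = at$y, z = at$z)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in structure", call. = FALSE)
  structure(list(residues = residues, atoms = atoms,
                 sequence = paste(residues$base, collapse = "")),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("rna_structure: %d residues, %d heavy atoms\n",
              nrow(x$residues), nrow(x$atoms)))
  invisible(x)
}

#' Map alignment columns onto structure residues
#'
#' Ungaps the query row and matches it against the structure sequence:
#' first by exact substring match (deterministic on clean inputs), else by
#' global pairwise alignment.  Mapped base identities that disagree are
#' flagged; a mismatch fraction above `max_mismatch` is an error.
#'
#' @param aln an `rna_alignment` whose `query_id` row corresponds to the
#'   structure.
#' @param struct an `rna_structure`.
#' @param max_mismatch maximum tolerated fraction of mismatched mapped
#'   bases (default 0.10).
#' @return data frame of class `column_residue_map` with columns `column`
#'   (1-based alignment column), `res_index` (structure residue ordinal)
#'   and `match` (logical base agreement).
#' @export
map_columns <- function(aln, struct, max_mismatch = 0.10) {
  qrow <- aln$rows[[match(aln$query_id, aln$ids)]]
  qchars <- strsplit(qrow, "", fixed = TRUE)[[1]]
  qcols <- which(qchars != "-")
  qseq <- paste(qchars[qcols], collapse = "")
  sseq <- struct$sequence
  if (nchar(qseq) == 0) stop("query row is all gaps", call. = FALSE)
  qpos <- spos <- integer(0)
  hit <- regexpr(sseq, qseq, fixed = TRUE)
  if (hit > 0) {
    spos <- seq_len(nchar(sseq))
    qpos <- as.integer(hit) + spos - 1L
  } else {
    hit2 <- regexpr(qseq, sseq, fixed = TRUE)
    if (hit2 > 0) {
      qpos <- seq_len(nchar(qseq))
      spos <- as.integer(hit2) + qpos - 1L
    } else {
      pa <- Biostrings::pairwiseAlignment(qseq, sseq, type = "global",
                                          gapOpening = 4, gapExtension = 1)
      pq <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      ps <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      iq <- is_ <- 0L
      for (k in seq_along(pq)) {
        if (pq[[k]] != "-") iq <- iq + 1L
        if (ps[[k]] != "-") is_ <- is_ + 1L
        if (pq[[k]] != "-" && ps[[k]] != "-") {
          qpos <- c(qpos, iq); spos <- c(spos, is_)
        }
      }
    }
  }
  if (!length(qpos)) stop("could not map query onto structure", call. = FALSE)
  qb <- strsplit(qseq, "")[[1]][qpos]
  sb <- strsplit(sseq, "")[[1]][spos]
  match_ok <- qb == sb | qb == "N" | sb == "N"
  mm <- mean(!match_ok)
  if (mm > max_mismatch)
    stop(sprintf("column/residue mapping mismatch fraction %.3f exceeds %.3f",
                 mm, max_mismatch), call. = FALSE)
  out <- data.frame(column = qcols[qpos], res_index = spos, match = match_ok)
  class(out) <- c("column_residue_map", class(out))
  attr(out, "mismatch_fraction") <- mm
  out
}

#' Read a functional-site table
#'
#' Two-column TSV (`site_name`, `residue_index`), one residue per line.
#'
#' @param path TSV file; a header line is detected and skipped.
#' @return named list of `functional_site` objects (fields `name`,
#'   `members`, `M`).
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("site_name", "residue_index"),
                          colClasses = c("character", "character"))
  if (nrow(df) && is.na(suppressWarnings(as.integer(df$residue_index[[1]]))))
    df <- df[-1, , drop = FALSE]
  df$residue_index <- as.integer(df$residue_index)
  sites <- lapply(split(df$residue_index, df$site_name), functional_site_members)
  for (nm in names(sites)) sites[[nm]]$name <- nm
  sites
}

functional_site_members <- function(members) {
  members <- sort(unique(as.integer(members)))
  if (!length(members)) stop("functional site must have at least one member", call. = FALSE)
  structure(list(name = "site", members = members, M = length(members)),
            class = "functional_site")
}

#' Define a functional site
#'
#' @param name site label.
#' @param members integer vector of structure residue indices (ordinals).
#' @export
functional_site <- function(name, members) {
  s <- functional_site_members(members)
  s$name <- name
  s
}

#' Write a functional-site table
#'
#' @param sites list of `functional_site` objects.
#' @param path output TSV.
#' @export
write_sites <- function(sites, path) {
  rows <- unlist(lapply(sites, function(s)
    sprintf("%s\t%d", s$name, s$members)))
  writeLines(rows, path)
  invisible(path)
}
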