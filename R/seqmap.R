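#' Global pairwise sequence alignment with affine gaps
#'
#' Needleman-Wunsch-style optimal global alignment of two amino-acid
#' sequences (BLOSUM62, gap open -10, gap extend -0.5 by default),
#' computed with `Biostrings::pairwiseAlignment`.  For closely related
#' sequences such as the human and rat PAH regulatory domains the
#' resulting identity is robust to reasonable parameter choices.
#'
#' @param seq_a,seq_b character strings over the standard amino-acid
#'   alphabet.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend gap penalties as negative scores
#'   (defaults -10, -0.5).
#' @return object of class `pairwise_alignment`: list with equal-length
#'   gapped strings `aligned_a`, `aligned_b`, the alignment `score` and
#'   `identity` (percent over aligned non-gap columns).
#' @export
global_align <- function(seq_a, seq_b, matrix = "BLOSUM62",
                         gap_open = -10, gap_extend = -0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  seq_a <- toupper(gsub("\\s", "", seq_a))
  seq_b <- toupper(gsub("\\s", "", seq_b))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", seq_a) ||
      grepl("[^ACDEFGHIKLMNPQRSTVWY]", seq_b))
    stop("sequences must use the standard 20 amino-acid letters")
  submat <- get(utils::data(list = matrix, package = "Biostrings",
                            envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = submat, gapOpening = -gap_open,
    gapExtension = -gap_extend, type = "global")
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  out <- structure(list(aligned_a = ga, aligned_b = gb,
                        score = Biostrings::score(pa), identity = NA_real_),
                   class = "pairwise_alignment")
  out$identity <- percent_identity(out)
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: %d columns, score %.1f, identity %.1f%%\n",
              nchar(x$aligned_a), x$score, x$identity))
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' `100 * identical aligned pairs / aligned (non-gap) columns`.  The
#' denominator excludes gap columns; this choice matters for reported
#' identity values and is therefore fixed here.
#'
#' @param alignment a `pairwise_alignment` (or a list with `aligned_a`,
#'   `aligned_b`).
#' @return percentage in [0, 100].
#' @export
percent_identity <- function(alignment) {
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  if (length(a) != length(b)) stop("gapped strings differ in length")
  aligned <- a != "-" & b != "-"
  if (!any(aligned)) stop("alignment has zero aligned (non-gap) columns")
  100 * sum(a[aligned] == b[aligned]) / sum(aligned)
}

#' Equivalent-atom map from a sequence alignment
#'
#' Builds ordered pairs of equivalent atom indices (one per non-gap
#' aligned column whose residues both carry the named atom) between two
#' homologous structures — the input that combined essential dynamics
#' needs to pool trajectories of different systems.
#'
#' @param alignment a `pairwise_alignment` whose degapped strings match
#'   the residue sequences of the two structures.
#' @param struct_a,struct_b `md_structure` objects.
#' @param atom_name atom matched per residue (default `"CA"`).
#' @return object of class `atom_map`: two-column integer matrix
#'   (`index_a`, `index_b`) of atom indices.
#' @export
atom_map <- function(alignment, struct_a, struct_b, atom_name = "CA") {
  seq_of <- function(st) {
    at <- st$atoms
    keep <- !duplicated(paste(at$chain, at$resid))
    list(res1 = aa_three_to_one(at$resname[keep]),
         chain = at$chain[keep], resid = at$resid[keep])
  }
  sa <- seq_of(struct_a); sb <- seq_of(struct_b)
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  if (paste(a[a != "-"], collapse = "") != paste(sa$res1, collapse = ""))
    stop("structure A residue sequence does not match the degapped alignment")
  if (paste(b[b != "-"], collapse = "") != paste(sb$res1, collapse = ""))
    stop("structure B residue sequence does not match the degapped alignment")
  ia <- cumsum(a != "-"); ib <- cumsum(b != "-")
  pairs <- matrix(0L, 0L, 2L)
  find_atom <- function(st, s, r) {
    at <- st$atoms
    which(at$chain == s$chain[r] & at$resid == s$resid[r] &
          toupper(at$atom_name) == toupper(atom_name))
  }
  for (col in which(a != "-" & b != "-")) {
    pa <- find_atom(struct_a, sa, ia[col])
    pb <- find_atom(struct_b, sb, ib[col])
    if (length(pa) == 1L && length(pb) == 1L)
      pairs <- rbind(pairs, c(pa, pb))
  }
  colnames(pairs) <- c("index_a", "index_b")
  structure(pairs, class = c("atom_map", class(pairs)))
}

#' One-letter codes for 3-letter residue names
#' @param resname character vector of 3-letter residue names.
#' @return character vector of one-letter codes (`X` for unknown).
#' @export
aa_three_to_one <- function(resname) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- tab[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- names(ss)
  out
}
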