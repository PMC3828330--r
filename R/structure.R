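#' @title Domain containers for structures, trajectories and selections
#' @description
#' `actdyn` represents a molecular structure as an `md_structure`: an atom
#' table (name, element, residue index/name, chain) plus an `n x 3`
#' coordinate matrix in Angstrom and a vector of van der Waals radii.  A
#' trajectory (`md_trajectory`) couples one such topology to an ordered
#' stack of coordinate frames with a strictly increasing time axis in ps.
#' @name actdyn-containers
NULL

# Bondi van der Waals radii (Angstrom) by element; overridable per call.
.bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
.default_radius <- 1.70

#' Van der Waals radii for a vector of element symbols
#'
#' Bondi radii for the common elements (C 1.70, N 1.55, O 1.52, S 1.80,
#' H 1.20 Angstrom); unknown elements fall back to 1.70 Angstrom.
#'
#' @param element character vector of element symbols.
#' @param override named numeric vector of per-element overrides (Angstrom).
#' @return numeric vector of radii, all positive.
#' @export
vdw_radii <- function(element, override = NULL) {
  tab <- .bondi_radii
  if (!is.null(override)) {
    if (is.null(names(override)) || any(!nzchar(names(override))))
      stop("radius overrides must be a named numeric vector")
    tab[toupper(names(override))] <- override
  }
  r <- unname(tab[toupper(element)])
  r[is.na(r)] <- .default_radius
  r
}

#' Construct a structure object
#'
#' @param atom_name character vector of PDB atom names (e.g. "CA", "OG1").
#' @param element character vector of element symbols; inferred from the
#'   atom name when missing.
#' @param resid integer vector of author residue numbers (non-decreasing
#'   within a chain).
#' @param resname character vector of 3-letter residue names.
#' @param chain character vector of chain identifiers.
#' @param xyz n x 3 numeric matrix of coordinates (Angstrom).
#' @param radius optional numeric vector of vdW radii; defaults to Bondi
#'   radii by element.
#' @return an object of class `md_structure` with components `atoms`
#'   (data.frame), `xyz` (matrix) and `radius`.
#' @export
md_structure <- function(atom_name, element = NULL, resid, resname,
                         chain = "A", xyz, radius = NULL) {
  n <- length(atom_name)
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L || nrow(xyz) != n)
    stop("xyz must be an n x 3 numeric matrix matching the atom count")
  if (any(!is.finite(xyz)))
    stop("all coordinates must be finite")
  if (is.null(element)) element <- guess_element(atom_name)
  chain <- rep_len(as.character(chain), n)
  resid <- as.integer(resid)
  for (ch in unique(chain)) {
    ri <- resid[chain == ch]
    if (is.unsorted(ri))
      stop("residue indices must be non-decreasing within chain ", ch)
  }
  if (is.null(radius)) radius <- vdw_radii(element)
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("vdw radii must be positive and finite")
  atoms <- data.frame(atom_name = as.character(atom_name),
                      element = toupper(as.character(element)),
                      resid = resid,
                      resname = as.character(resname),
                      chain = chain,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, xyz = unname(xyz), radius = radius),
            class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat(sprintf("md_structure: %d atoms, %d residues, chains %s\n",
              nrow(x$atoms), n_residues(x),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an `md_structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Number of distinct residues in a structure
#' @param structure an `md_structure`.
#' @return integer residue count.
#' @export
n_residues <- function(structure)
  length(unique(paste(structure$atoms$chain, structure$atoms$resid)))

# Element symbol from a PDB atom name: strip digits/primes, handle the
# leading-digit hydrogen convention ("1HB"), take the first letter(s).
guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  nm <- sub("^[0-9]+", "", nm)
  el <- substr(nm, 1L, 1L)
  two <- substr(nm, 1L, 2L)
  el[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN")] <-
    two[two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "MN")]
  el
}

#' Construct a trajectory object
#'
#' @param structure an `md_structure` providing the topology; its `xyz`
#'   is used as frame 1 if `frames` is missing.
#' @param frames list of n_atoms x 3 coordinate matrices, or a 3-D array
#'   `c(n_atoms, 3, n_frames)`.
#' @param times numeric vector of frame times (ps), strictly increasing;
#'   defaults to 0, 1, 2, ... frame units.
#' @return an object of class `md_trajectory` with components `structure`,
#'   `coords` (3-D array, atoms x 3 x frames) and `times`.
#' @export
md_trajectory <- function(structure, frames = NULL, times = NULL) {
  stopifnot(inherits(structure, "md_structure"))
  na <- n_atoms(structure)
  if (is.null(frames)) frames <- list(structure$xyz)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    coords <- frames
  } else {
    frames <- lapply(frames, as.matrix)
    for (k in seq_along(frames)) {
      f <- frames[[k]]
      if (nrow(f) != na || ncol(f) != 3L)
        stop("frame ", k, " has ", nrow(f), " atoms; topology has ", na)
    }
    coords <- array(unlist(frames, use.names = FALSE), dim = c(na, 3L, length(frames)))
  }
  if (dim(coords)[1] != na)
    stop("frame atom count (", dim(coords)[1], ") does not match topology (", na, ")")
  nf <- dim(coords)[3]
  if (is.null(times)) times <- as.numeric(seq_len(nf) - 1L)
  if (length(times) != nf)
    stop("length(times) must equal the number of frames")
  if (nf > 1L && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (any(!is.finite(coords))) stop("all frame coordinates must be finite")
  structure(list(structure = structure, coords = coords, times = as.numeric(times)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames x %d atoms, t = %g..%g ps\n",
              n_frames(x), dim(x$coords)[1], x$times[1], x$times[n_frames(x)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame of a trajectory as a coordinate matrix
#' @param traj an `md_trajectory`.
#' @param i frame index.
#' @return n_atoms x 3 matrix (Angstrom).
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  traj$coords[, , i, drop = TRUE]
}

.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HA", "H1", "H2", "H3")
.backbone_heavy <- c("N", "CA", "C", "O", "OXT")

#' Select atoms with a small selection grammar
#'
#' The grammar supports the clauses `name <A> <B> ...` (atom-name list),
#' `resid <a>-<b>` or `resid <a> <b> ...` (author residue numbers),
#' `chain <X>`, and the keywords `backbone` (N, CA, C, O, OXT and backbone
#' hydrogens), `sidechain` (side-chain heavy atoms), `heavy`/`noh`
#' (non-hydrogen), `protein` (all atoms of standard residues) and `calpha`
#' (shorthand for `name CA`).  Clauses are combined with `and`.
#'
#' @param structure an `md_structure`.
#' @param spec selection string, e.g. `"name CA and resid 33-111"`.
#' @return ascending integer vector of atom indices (possibly empty),
#'   of class `md_selection`.
#' @examples
#' s <- gen_chain(5, "helix")
#' select_atoms(s, "name CA")
#' @export
select_atoms <- function(structure, spec) {
  stopifnot(inherits(structure, "md_structure"))
  if (!is.character(spec) || length(spec) != 1L || !nzchar(trimws(spec)))
    stop("selection spec must be a single non-empty string")
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  clauses <- strsplit(trimws(spec), "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    key <- tolower(toks[1])
    m <- switch(key,
      name = {
        if (length(toks) < 2L) stop("malformed selection clause: '", cl, "'")
        toupper(at$atom_name) %in% toupper(toks[-1])
      },
      resid = {
        if (length(toks) < 2L) stop("malformed selection clause: '", cl, "'")
        ids <- integer(0)
        for (tk in toks[-1]) {
          if (grepl("^-?[0-9]+--?[0-9]+$", tk)) {
            ab <- regmatches(tk, regexec("^(-?[0-9]+)-(-?[0-9]+)$", tk))[[1]]
            ids <- c(ids, seq(as.integer(ab[2]), as.integer(ab[3])))
          } else if (grepl("^-?[0-9]+$", tk)) {
            ids <- c(ids, as.integer(tk))
          } else stop("malformed residue token '", tk, "' in clause '", cl, "'")
        }
        at$resid %in% ids
      },
      chain = {
        if (length(toks) < 2L) stop("malformed selection clause: '", cl, "'")
        at$chain %in% toks[-1]
      },
      backbone = toupper(at$atom_name) %in% .backbone_names,
      sidechain = !(toupper(at$atom_name) %in% .backbone_names) & at$element != "H",
      heavy = at$element != "H",
      noh = at$element != "H",
      protein = rep(TRUE, nrow(at)),
      calpha = toupper(at$atom_name) == "CA",
      stop("unknown selection keyword '", key, "' in clause '", cl, "'")
    )
    keep <- keep & m
  }
  structure(which(keep), class = "md_selection")
}

#' Built-in residue selections from the PAH regulatory-domain study
#'
#' Named residue sets used throughout the ACT-domain analyses:
#' `"hydrophobic_patch"` is the solvent-exposed hydrophobic surface between
#' helix alpha1 and strand beta2 (Val45-Ala49, Val51, Leu52, Leu54, Phe55,
#' Val60-Thr63, Ile65, Ser67, Tyr77); `"hydrophobic_core"` is the buried
#' core set (Leu37, Phe39, Leu41, Val51, Phe55, Ile65, Phe79, Leu91, Ile94,
#' Leu98); `"L1"`..`"L4"` are the four mobile loop-containing regions
#' (L1 42-45, L2 59-64, L3 70-75, L4 82-90); `"act"` is the ACT domain
#' range 33-111.  All in author (human PAH) numbering.
#'
#' @param set one of `"hydrophobic_patch"`, `"hydrophobic_core"`,
#'   `"L1"`, `"L2"`, `"L3"`, `"L4"`, `"act"`.
#' @return integer vector of residue numbers.
#' @export
named_residue_set <- function(set = c("hydrophobic_patch", "hydrophobic_core",
                                      "L1", "L2", "L3", "L4", "act")) {
  set <- match.arg(set)
  switch(set,
    hydrophobic_patch = c(45:49, 51, 52, 54, 55, 60:63, 65, 67, 77),
    hydrophobic_core = c(37, 39, 41, 51, 55, 65, 79, 91, 94, 98),
    L1 = 42:45, L2 = 59:64, L3 = 70:75, L4 = 82:90,
    act = 33:111)
}

# Internal: validate a selection or coerce an integer vector to one.
as_selection <- function(structure, sel) {
  if (inherits(sel, "md_selection")) sel <- unclass(sel)
  sel <- as.integer(sel)
  if (any(is.na(sel)) || any(sel < 1L) || any(sel > n_atoms(structure)))
    stop("selection indices out of range")
  if (anyDuplicated(sel)) stop("selection indices must be unique")
  if (is.unsorted(sel)) stop("selection indices must be ascending")
  sel
}
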