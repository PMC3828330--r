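#' Read a (multi-model) PDB file as a structure and trajectory
#'
#' Parses fixed-column ATOM/HETATM records.  MODEL/ENDMDL blocks delimit
#' trajectory frames; a file without MODEL records is a single implicit
#' model.  The topology is taken from the first model and every model must
#' present the same atoms in the same order.  Alternate-location indicators
#' other than blank or 'A' are dropped; insertion codes are rejected.
#'
#' @param path path to a PDB file.
#' @param dt optional time step (ps) between models; frame times default
#'   to 0, 1, 2, ... frame units.
#' @param het logical; keep HETATM records (e.g. water oxygens)?
#' @return an `md_trajectory` (its `$structure` holds the first-model
#'   topology and coordinates).
#' @export
read_pdb <- function(path, dt = NULL, het = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep_type <- if (het) c("ATOM  ", "HETATM") else "ATOM  "
  is_atom <- rec %in% keep_type
  is_model <- rec == "MODEL "
  is_endmdl <- rec == "ENDMDL"
  if (!any(is_atom)) stop("no ATOM records found in ", path)

  # assign a model id to every atom line
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_of_atom <- model_id[is_atom]
  if (any(model_of_atom == 0L))
    model_of_atom[model_of_atom == 0L] <- 1L  # atoms before first MODEL
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)

  altloc <- substr(atom_lines, 17, 17)
  ok_alt <- altloc %in% c(" ", "A")
  atom_lines <- atom_lines[ok_alt]
  atom_lineno <- atom_lineno[ok_alt]
  model_of_atom <- model_of_atom[ok_alt]

  icode <- substr(atom_lines, 27, 27)
  if (any(icode != " "))
    stop("insertion codes are not supported (line ",
         atom_lineno[which(icode != " ")[1]], ")")

  parse_num <- function(txt, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & nzchar(trimws(txt)) | !nzchar(trimws(txt)))
    if (length(bad))
      stop("unparseable ", what, " field at line ", atom_lineno[bad[1]])
    v
  }
  x <- parse_num(substr(atom_lines, 31, 38), "x coordinate")
  y <- parse_num(substr(atom_lines, 39, 46), "y coordinate")
  z <- parse_num(substr(atom_lines, 47, 54), "z coordinate")

  models <- sort(unique(model_of_atom))
  first <- model_of_atom == models[1]
  n_per <- tabulate(match(model_of_atom, models))
  if (any(n_per != n_per[1])) {
    bad <- which(n_per != n_per[1])[1]
    stop("model ", bad, " has ", n_per[bad],
         " atoms; model 1 has ", n_per[1])
  }

  name <- trimws(substr(atom_lines[first], 13, 16))
  resname <- trimws(substr(atom_lines[first], 18, 20))
  chain <- substr(atom_lines[first], 22, 22)
  resid <- suppressWarnings(as.integer(trimws(substr(atom_lines[first], 23, 26))))
  if (any(is.na(resid)))
    stop("unparseable residue number at line ",
         atom_lineno[first][which(is.na(resid))[1]])
  elem <- trimws(substr(atom_lines[first], 77, 78))
  elem[!nzchar(elem)] <- guess_element(name[!nzchar(elem)])

  na <- n_per[1]
  nf <- length(models)
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  for (k in seq_len(nf)) {
    idx <- which(model_of_atom == models[k])
    coords[, 1, k] <- x[idx]; coords[, 2, k] <- y[idx]; coords[, 3, k] <- z[idx]
    nm_k <- trimws(substr(atom_lines[idx], 13, 16))
    if (!identical(nm_k, name))
      stop("model ", k, " atom order differs from model 1")
  }

  st <- md_structure(atom_name = name, element = elem, resid = resid,
                     resname = resname, chain = chain, xyz = coords[, , 1])
  times <- if (is.null(dt)) NULL else (seq_len(nf) - 1L) * dt
  md_trajectory(st, frames = coords, times = times)
}

#' Write a structure or trajectory as a (multi-model) PDB file
#'
#' Coordinates are written with 3 decimals (PDB precision); reading the
#' file back reproduces them to 0.001 Angstrom and all atom metadata
#' exactly.  Multi-frame input produces one MODEL/ENDMDL block per frame.
#'
#' @param x an `md_structure` or `md_trajectory`.
#' @param path output file path.
#' @param frames optional list/array of coordinate frames overriding the
#'   frames stored in `x`.
#' @param bfactor optional numeric vector (one value per atom) written in
#'   the B-factor column, e.g. per-atom RMSF or hydration scores.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path, frames = NULL, bfactor = NULL) {
  if (inherits(x, "md_trajectory")) {
    st <- x$structure
    if (is.null(frames)) frames <- x$coords
  } else if (inherits(x, "md_structure")) {
    st <- x
    if (is.null(frames)) frames <- list(st$xyz)
  } else stop("x must be an md_structure or md_trajectory")
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  na <- n_atoms(st)
  if (is.null(bfactor)) bfactor <- rep(0, na)
  if (length(bfactor) != na) stop("bfactor must have one value per atom")
  at <- st$atoms
  # PDB atom-name column convention: names of <4 chars start in column 14
  nm <- ifelse(nchar(at$atom_name) >= 4L, substr(at$atom_name, 1, 4),
               sprintf(" %-3s", at$atom_name))
  con <- file(path, "wt")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (k in seq_along(frames)) {
    xyz <- as.matrix(frames[[k]])
    if (nrow(xyz) != na || ncol(xyz) != 3L)
      stop("frame ", k, " does not match the atom count")
    if (any(abs(xyz) >= 10000))
      stop("coordinate overflows PDB columns (|x| >= 10000) in frame ", k)
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(na) %% 100000L, nm, at$resname, at$chain, at$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, bfactor, at$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a time series as tab-separated text
#'
#' @param times numeric vector (ps or frame units).
#' @param values numeric vector or matrix (one column per series).
#' @param path output path.
#' @param names column names for the value columns.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(times, values, path, names = NULL) {
  values <- as.matrix(values)
  if (is.null(names)) names <- if (ncol(values) == 1L) "value"
    else paste0("v", seq_len(ncol(values)))
  df <- data.frame(time = times, values)
  colnames(df) <- c("time", names)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
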