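#' Water number-density map around a solute
#'
#' Bins water-oxygen positions on a rectangular grid (default spacing
#' 0.5 Angstrom) covering the solute plus a padding margin, averages the
#' per-voxel number density over frames, and normalizes by the bulk
#' density estimated in the 6-8 Angstrom shell around the solute (shell
#' distance measured to the nearest solute heavy atom).  Solute frames
#' must already be superposed on a common reference, with the same
#' transform applied to the waters.
#'
#' @param solute_coords n x 3 matrix of (reference-frame) solute heavy
#'   atom coordinates.
#' @param waters list of per-frame water-oxygen coordinate matrices
#'   (m_t x 3), already in the reference frame.
#' @param spacing grid spacing, Angstrom (default 0.5).
#' @param padding margin beyond the solute bounding box, Angstrom
#'   (default 10, so the 6-8 shell is covered).
#' @param shell numeric length-2, the bulk-normalization shell distances
#'   (default `c(6, 8)`).
#' @return object of class `density_map`: list with `origin`, `spacing`,
#'   `dims`, `values` (3-D array of normalized density g(r)),
#'   `bulk_density` (Angstrom^-3), `raw_mean_counts` (3-D array of mean
#'   per-voxel counts, for closure checks) and `n_frames`.
#' @export
density_map <- function(solute_coords, waters, spacing = 0.5, padding = 10,
                        shell = c(6, 8)) {
  solute_coords <- as.matrix(solute_coords)
  if (!is.list(waters)) waters <- list(as.matrix(waters))
  if (spacing <= 0) stop("spacing must be positive")
  nf <- length(waters)
  lo <- apply(solute_coords, 2, min) - padding
  hi <- apply(solute_coords, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing))
  origin <- lo
  counts <- array(0, dim = dims)
  nvox <- prod(dims)
  for (k in seq_len(nf)) {
    w <- as.matrix(waters[[k]])
    if (nrow(w) == 0L) next
    ix <- floor(sweep(w, 2, origin) / spacing) + 1L
    ok <- ix[, 1] >= 1L & ix[, 1] <= dims[1] &
          ix[, 2] >= 1L & ix[, 2] <= dims[2] &
          ix[, 3] >= 1L & ix[, 3] <= dims[3]
    ix <- ix[ok, , drop = FALSE]
    if (nrow(ix) == 0L) next
    lin <- ix[, 1] + dims[1] * (ix[, 2] - 1L) + dims[1] * dims[2] * (ix[, 3] - 1L)
    tab <- tabulate(lin, nbins = nvox)
    counts <- counts + array(tab, dim = dims)
  }
  mean_counts <- counts / nf
  dens <- mean_counts / spacing^3          # number density, A^-3
  # voxel-center distances to the nearest solute atom, for the bulk shell
  cx <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing
  cy <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing
  cz <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing
  centers <- cbind(rep(cx, times = dims[2] * dims[3]),
                   rep(rep(cy, each = dims[1]), times = dims[3]),
                   rep(cz, each = dims[1] * dims[2]))
  d2min <- rep(Inf, nvox)
  for (a in seq_len(nrow(solute_coords))) {
    d2 <- (centers[, 1] - solute_coords[a, 1])^2 +
          (centers[, 2] - solute_coords[a, 2])^2 +
          (centers[, 3] - solute_coords[a, 3])^2
    d2min <- pmin(d2min, d2)
  }
  dmin <- sqrt(d2min)
  in_shell <- dmin >= shell[1] & dmin <= shell[2]
  if (!any(in_shell)) stop("empty ", shell[1], "-", shell[2],
                           " A bulk shell: cannot normalize the density map")
  bulk <- mean(dens[in_shell])
  if (bulk <= 0) stop("bulk density in the ", shell[1], "-", shell[2],
                      " A shell is zero: cannot normalize")
  structure(list(origin = origin, spacing = spacing, dims = dims,
                 values = dens / bulk, bulk_density = bulk,
                 raw_mean_counts = mean_counts, n_frames = nf,
                 solute_dmin = array(dmin, dim = dims)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density_map: %d x %d x %d voxels @ %.2f A, bulk %.4f A^-3\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$bulk_density))
  invisible(x)
}

#' Voxel-center coordinates of a density map
#' @param map a `density_map`.
#' @param index integer matrix (k x 3) of voxel indices.
#' @return k x 3 matrix of Cartesian centers (Angstrom).
#' @export
voxel_centers <- function(map, index) {
  index <- matrix(as.numeric(index), ncol = 3L)
  sweep((index - 0.5) * map$spacing, 2, map$origin, "+")
}

#' Hydration sites: supra-bulk local maxima of a density map
#'
#' A hydration site is a voxel whose normalized density exceeds 1 and is
#' strictly greater than all of its (up to 26) neighbours; its position
#' is the voxel center.
#'
#' On maps estimated from finitely many snapshots, sampling noise in the
#' bulk produces spurious shallow maxima marginally above 1; rank by `g`
#' (the returned order) or enable `smooth` to suppress them.
#'
#' @param map a `density_map`.
#' @param g_min minimum normalized density (default 1).
#' @param smooth logical; apply a 3x3x3 boxcar average before maximum
#'   detection (default `FALSE`).
#' @return data.frame with `x`, `y`, `z` (Angstrom) and `g`, ordered by
#'   decreasing `g`; zero rows when the map is featureless.
#' @export
hydration_sites <- function(map, g_min = 1, smooth = FALSE) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  if (smooth) {
    d <- dim(v)
    sm <- array(0, d); cnt <- array(0, d)
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      si <- max(1, 1 + di):min(d[1], d[1] + di)
      sj <- max(1, 1 + dj):min(d[2], d[2] + dj)
      sk <- max(1, 1 + dk):min(d[3], d[3] + dk)
      ti <- si - di; tj <- sj - dj; tk <- sk - dk
      sm[ti, tj, tk] <- sm[ti, tj, tk] + v[si, sj, sk]
      cnt[ti, tj, tk] <- cnt[ti, tj, tk] + 1
    }
    v <- sm / cnt
  }
  d <- dim(v)
  cand <- which(v > g_min, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0), g = numeric(0)))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]; k <- cand[r, 3]
    val <- v[i, j, k]
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) next
      if (v[ii, jj, kk] >= val) { ok <- FALSE; break }
    }
    keep[r] <- ok
  }
  cand <- cand[keep, , drop = FALSE]
  pos <- voxel_centers(map, cand)
  out <- data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    g = v[cand])
  out[order(-out$g), , drop = FALSE]
}

#' Per-atom hydration score from hydration sites
#'
#' `S_hyd(i) = sum over sites s within cutoff of g_s * (1 - d_is / cutoff)`:
#' each nearby site contributes its density weighted by a linear taper
#' from 1 at zero distance to 0 at the cutoff.  Atoms surrounded by many
#' sites, or close to few high-density sites, score high; buried atoms
#' with no nearby sites score zero.
#'
#' @param sites data.frame from [hydration_sites()].
#' @param structure an `md_structure` in the same reference frame.
#' @param selection atom indices to score (default: all heavy atoms).
#' @param cutoff site-atom distance cutoff, Angstrom (default 4.0).
#' @return numeric vector of non-negative scores, one per selected atom.
#' @export
hydration_score <- function(sites, structure, selection = NULL, cutoff = 4.0) {
  stopifnot(inherits(structure, "md_structure"))
  if (is.null(selection)) selection <- which(structure$atoms$element != "H")
  selection <- as.integer(unclass(selection))
  xyz <- structure$xyz[selection, , drop = FALSE]
  s <- numeric(nrow(xyz))
  if (nrow(sites) == 0L) return(s)
  sp <- as.matrix(sites[, c("x", "y", "z")])
  for (a in seq_len(nrow(xyz))) {
    d <- sqrt(colSums((t(sp) - xyz[a, ])^2))
    w <- pmax(1 - d / cutoff, 0)
    s[a] <- sum(sites$g * w)
  }
  s
}

#' Write a density map in OpenDX grid format
#'
#' Plain-text OpenDX scalar field readable by common molecular viewers.
#'
#' @param map a `density_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  d <- map$dims
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", map$origin[1] + map$spacing / 2,
            map$origin[2] + map$spacing / 2, map$origin[3] + map$spacing / 2),
    sprintf("delta %.4f 0 0", map$spacing),
    sprintf("delta 0 %.4f 0", map$spacing),
    sprintf("delta 0 0 %.4f", map$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # OpenDX expects z fastest
  v <- aperm(map$values, c(3, 2, 1))
  vals <- as.numeric(v)
  pad <- (-length(vals)) %% 3
  if (pad) vals <- c(vals, rep(NA, pad))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(sprintf("%.6g", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
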