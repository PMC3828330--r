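#' Positional covariance matrix of a fitted trajectory
#'
#' Builds the 3N x 3N covariance matrix of the Cartesian coordinates of
#' the selected atoms, `C = mean_t (x - <x>)(x - <x>)'` with population
#' (1/n) normalization.  The trajectory must be superposed first so that
#' internal motion, not rigid-body motion, dominates.
#'
#' @param fitted_traj an `md_trajectory`, already superposed (see
#'   [fit_trajectory()]); pass `fitted = FALSE` to acknowledge an
#'   unfitted trajectory (a warning is still raised).
#' @param selection atom indices (typically the C-alpha set).
#' @param fitted logical; set `FALSE` to flag that no superposition was
#'   applied (warning).
#' @return list with `matrix` (3N x 3N, Angstrom^2, symmetric PSD) and
#'   `mean` (3N vector of average coordinates, atom-major x,y,z order).
#' @export
covariance_matrix <- function(fitted_traj, selection = NULL, fitted = TRUE) {
  stopifnot(inherits(fitted_traj, "md_trajectory"))
  if (!fitted) warning("trajectory flagged as unfitted; covariance will mix rigid-body motion")
  if (n_frames(fitted_traj) < 2L) stop("covariance needs at least 2 frames")
  m <- traj_matrix(fitted_traj, selection)   # frames x 3N
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  cv <- crossprod(mc) / nrow(mc)
  cv <- (cv + t(cv)) / 2
  list(matrix = cv, mean = mu)
}

# Internal: trajectory as frames x 3N matrix (atom-major x,y,z order).
traj_matrix <- function(traj, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[1])
  selection <- as.integer(unclass(selection))
  x <- traj$coords[selection, , , drop = FALSE]
  na <- dim(x)[1]; nf <- dim(x)[3]
  m <- matrix(aperm(x, c(2, 1, 3)), nrow = 3L * na, ncol = nf)
  t(m)
}

#' Essential dynamics: diagonalize a positional covariance matrix
#'
#' Principal components of the C-alpha fluctuations are the eigenvectors
#' of the covariance matrix; eigenvalues (Angstrom^2) are the variances
#' along each collective mode.  Eigenvector signs are fixed by making the
#' largest-magnitude component positive, so projections are reproducible.
#'
#' @param covariance a symmetric matrix, or the list returned by
#'   [covariance_matrix()].
#' @param mean_coords 3N vector of mean coordinates (taken from the
#'   `covariance_matrix()` list when given).
#' @return an object of class `mode_basis`: list with `mean_coords`,
#'   `vectors` (3N x 3N orthonormal columns), `values` (descending,
#'   non-negative eigenvalues) and `n_atoms`.
#' @export
pca_modes <- function(covariance, mean_coords = NULL) {
  if (is.list(covariance) && !is.null(covariance$matrix)) {
    if (is.null(mean_coords)) mean_coords <- covariance$mean
    covariance <- covariance$matrix
  }
  covariance <- as.matrix(covariance)
  if (nrow(covariance) != ncol(covariance) ||
      max(abs(covariance - t(covariance))) > 1e-8 * max(1, max(abs(covariance))))
    stop("covariance must be a symmetric matrix")
  eg <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  vals <- eg$values
  vals[vals < 0 & vals > -1e-10] <- 0
  vecs <- eg$vectors
  # sign convention: largest-|component| of each eigenvector is positive
  for (k in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, k]))
    if (vecs[i, k] < 0) vecs[, k] <- -vecs[, k]
  }
  if (is.null(mean_coords)) mean_coords <- rep(0, nrow(covariance))
  structure(list(mean_coords = as.numeric(mean_coords), vectors = vecs,
                 values = vals, n_atoms = nrow(covariance) / 3L),
            class = "mode_basis")
}

#' @export
print.mode_basis <- function(x, ...) {
  vf <- if (sum(x$values) > 0) x$values / sum(x$values) else x$values
  cat(sprintf("mode_basis: %d atoms, %d modes; top variance fractions: %s\n",
              x$n_atoms, length(x$values),
              paste(sprintf("%.3f", utils::head(vf, 3)), collapse = " ")))
  invisible(x)
}

#' Fraction of total fluctuation captured by each mode
#' @param basis a `mode_basis`.
#' @return numeric vector `values / sum(values)`.
#' @export
variance_fractions <- function(basis) {
  stopifnot(inherits(basis, "mode_basis"))
  tot <- sum(basis$values)
  if (tot <= 0) stop("mode basis has an all-zero spectrum")
  basis$values / tot
}

#' Project a trajectory onto principal components
#'
#' `p_k(t) = (x(t) - mean_coords) . u_k` for each requested mode.  The
#' trajectory must be superposed on the same reference used to build the
#' basis.
#'
#' @param traj an `md_trajectory` (superposed), or a frames x 3N matrix.
#' @param basis a `mode_basis`.
#' @param k mode indices (default: all).
#' @param selection atom indices reducing the trajectory to the basis
#'   atoms (default: all atoms of `traj`).
#' @return frames x length(k) matrix of projections (Angstrom).
#' @export
project_modes <- function(traj, basis, k = NULL, selection = NULL) {
  stopifnot(inherits(basis, "mode_basis"))
  m <- if (inherits(traj, "md_trajectory")) traj_matrix(traj, selection) else as.matrix(traj)
  if (ncol(m) != length(basis$mean_coords))
    stop("trajectory atom count does not match the mode basis")
  if (is.null(k)) k <- seq_along(basis$values)
  if (any(k < 1L | k > ncol(basis$vectors))) stop("mode index out of range")
  p <- sweep(m, 2, basis$mean_coords) %*% basis$vectors[, k, drop = FALSE]
  colnames(p) <- paste0("PC", k)
  p
}

#' Combined essential dynamics over several trajectories
#'
#' Performs essential dynamics on the pseudo-trajectory obtained by
#' concatenating several trajectories reduced to a common equivalent-atom
#' set (e.g. C-alpha atoms matched across homologous systems by a sequence
#' alignment).  All trajectories are first superposed on one common
#' reference over the mapped atoms; frames are pooled with equal weight,
#' and per-trajectory projections are computed against the pooled mean.
#'
#' @param trajs list of `md_trajectory` objects.
#' @param selections list of atom-index vectors, one per trajectory,
#'   each selecting that system's copy of the common atom set (same
#'   length and order across trajectories).  Built from [atom_map()]
#'   pairs for homologous systems; default: all atoms of each trajectory.
#' @param reference n x 3 matrix of reference coordinates for the common
#'   atom set (default: first frame of the first trajectory, reduced).
#' @param fit logical; superpose every reduced frame on the reference
#'   before pooling (default `TRUE`).  Set `FALSE` for trajectories that
#'   are already in a common frame of reference.
#' @return list with `basis` (a `mode_basis` from the pooled frames) and
#'   `projections` (list of per-trajectory projection matrices on all
#'   modes, computed against the pooled mean).
#' @export
combined_ed <- function(trajs, selections = NULL, reference = NULL,
                        fit = TRUE) {
  stopifnot(is.list(trajs), length(trajs) >= 1L)
  nt <- length(trajs)
  if (is.null(selections))
    selections <- lapply(trajs, function(tr) seq_len(dim(tr$coords)[1]))
  selections <- lapply(selections, function(s) as.integer(unclass(s)))
  ns <- vapply(selections, length, 1L)
  if (length(unique(ns)) != 1L)
    stop("mapped-atom counts differ across trajectories: ",
         paste(ns, collapse = ", "))
  if (is.null(reference))
    reference <- frame_coords(trajs[[1]], 1)[selections[[1]], , drop = FALSE]
  mats <- vector("list", nt)
  for (i in seq_len(nt)) {
    tr <- trajs[[i]]; sel <- selections[[i]]
    nf <- n_frames(tr)
    red <- array(tr$coords[sel, , , drop = FALSE], dim = c(length(sel), 3L, nf))
    if (fit) for (k in seq_len(nf)) {
      f <- kabsch_fit(red[, , k], reference)
      red[, , k] <- apply_fit(red[, , k], f)
    }
    mats[[i]] <- traj_matrix(md_trajectory(
      md_structure(atom_name = trajs[[i]]$structure$atoms$atom_name[sel],
                   element = trajs[[i]]$structure$atoms$element[sel],
                   resid = trajs[[i]]$structure$atoms$resid[sel],
                   resname = trajs[[i]]$structure$atoms$resname[sel],
                   chain = trajs[[i]]$structure$atoms$chain[sel],
                   xyz = red[, , 1]),
      frames = red))
  }
  pooled <- do.call(rbind, mats)
  mu <- colMeans(pooled)
  mc <- sweep(pooled, 2, mu)
  cv <- crossprod(mc) / nrow(mc)
  basis <- pca_modes((cv + t(cv)) / 2, mean_coords = mu)
  projections <- lapply(mats, function(m) {
    p <- sweep(m, 2, mu) %*% basis$vectors
    colnames(p) <- paste0("PC", seq_len(ncol(p)))
    p
  })
  list(basis = basis, projections = projections)
}

#' Porcupine vectors for one principal component
#'
#' Per-atom displacement arrows `scale * sqrt(lambda_k) * u_k,i` anchored
#' at the average atom positions — the data behind "porcupine" renderings
#' of a collective mode (exported as numbers, not rendered).
#'
#' @param basis a `mode_basis`.
#' @param k mode index.
#' @param scale arrow scale factor (default 1).
#' @return data.frame with anchor columns `x, y, z` (mean positions) and
#'   arrow components `vx, vy, vz` (Angstrom).
#' @export
porcupine <- function(basis, k = 1, scale = 1) {
  stopifnot(inherits(basis, "mode_basis"))
  if (k < 1L || k > ncol(basis$vectors)) stop("mode index out of range")
  u <- matrix(basis$vectors[, k], ncol = 3L, byrow = TRUE)
  anchor <- matrix(basis$mean_coords, ncol = 3L, byrow = TRUE)
  v <- scale * sqrt(basis$values[k]) * u
  data.frame(x = anchor[, 1], y = anchor[, 2], z = anchor[, 3],
             vx = v[, 1], vy = v[, 2], vz = v[, 3])
}
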