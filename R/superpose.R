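#' Least-squares rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' the selected atoms of `mobile` and `reference`.  The rotation is
#' obtained from the SVD of the cross-covariance matrix with reflection
#' correction, so `det(rotation) = +1` always.
#'
#' @param mobile n x 3 coordinate matrix (or `md_structure`).
#' @param reference n x 3 coordinate matrix (or `md_structure`).
#' @param selection atom indices used for the fit (default: all atoms).
#' @return a list of class `kabsch_fit` with `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom) over the selection.
#'   Fitted coordinates of any atom set `X` sharing the mobile frame are
#'   `X %*% t(rotation) + translation` (see [apply_fit()]).
#' @export
kabsch_fit <- function(mobile, reference, selection = NULL) {
  mob <- if (inherits(mobile, "md_structure")) mobile$xyz else as.matrix(mobile)
  ref <- if (inherits(reference, "md_structure")) reference$xyz else as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(mob))
  selection <- as.integer(unclass(selection))
  a <- mob[selection, , drop = FALSE]
  b <- ref[selection, , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("selected atom counts differ between mobile and reference")
  if (nrow(a) < 3L) stop("superposition needs at least 3 selected atoms")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  # collinearity check: rank of the centered reference coordinates
  if (qr(b0)$rank < 2L || qr(a0)$rank < 2L)
    stop("selected atoms are collinear; superposition is underdetermined")
  h <- crossprod(a0, b0)              # 3x3 covariance of mobile vs reference
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  corr <- diag(c(1, 1, d))
  rot <- sv$v %*% corr %*% t(sv$u)    # maps centered mobile onto centered ref
  fitted <- a0 %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b0)^2)))
  trans <- as.numeric(cb - rot %*% ca)
  structure(list(rotation = rot, translation = trans, rmsd = rmsd),
            class = "kabsch_fit")
}

#' Apply a rigid-body fit to coordinates
#'
#' @param coords n x 3 matrix in the mobile frame of reference.
#' @param fit a `kabsch_fit`.
#' @return transformed n x 3 matrix.
#' @export
apply_fit <- function(coords, fit) {
  stopifnot(inherits(fit, "kabsch_fit"))
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Root-mean-square deviation between two coordinate sets
#'
#' @param a,b n x 3 matrices.
#' @param selection optional atom indices.
#' @param fit logical; superpose `a` onto `b` first (default `FALSE`)?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = NULL, fit = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(selection)) selection <- seq_len(nrow(a))
  selection <- as.integer(unclass(selection))
  if (fit) return(kabsch_fit(a, b, selection)$rmsd)
  sqrt(mean(rowSums((a[selection, , drop = FALSE] - b[selection, , drop = FALSE])^2)))
}

#' Superpose every trajectory frame onto a reference
#'
#' Each frame is rigid-body fitted (over `selection`) onto the reference
#' coordinates; by default the reference is the starting structure, as in
#' the trajectory analyses this package reproduces.  Optionally the fit
#' can be iterated against the running average structure.
#'
#' @param traj an `md_trajectory`.
#' @param reference n x 3 matrix or `md_structure`; defaults to frame 1.
#' @param selection atom indices used for the fit (default: all atoms).
#' @param iterate_average logical; if `TRUE`, refit to the average of the
#'   fitted frames until the average moves by less than `tol` (off by
#'   default).
#' @param tol convergence tolerance (Angstrom RMSD of the average) for
#'   `iterate_average`.
#' @return an `md_trajectory` of fitted frames, with attribute
#'   `"rmsd"` holding the per-frame RMSD (Angstrom) to the reference over
#'   the fitting selection.
#' @export
fit_trajectory <- function(traj, reference = NULL, selection = NULL,
                           iterate_average = FALSE, tol = 1e-6) {
  stopifnot(inherits(traj, "md_trajectory"))
  ref <- if (is.null(reference)) frame_coords(traj, 1)
         else if (inherits(reference, "md_structure")) reference$xyz
         else as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[1])
  selection <- as.integer(unclass(selection))
  nf <- n_frames(traj)
  fit_all <- function(ref) {
    out <- array(NA_real_, dim = dim(traj$coords))
    rms <- numeric(nf)
    for (k in seq_len(nf)) {
      f <- kabsch_fit(traj$coords[, , k], ref, selection)
      out[, , k] <- apply_fit(traj$coords[, , k], f)
      rms[k] <- f$rmsd
    }
    list(coords = out, rmsd = rms)
  }
  res <- fit_all(ref)
  if (iterate_average && nf > 1L) {
    for (it in 1:50) {
      avg <- apply(res$coords, c(1, 2), mean)
      prev <- avg
      res <- fit_all(avg)
      avg2 <- apply(res$coords, c(1, 2), mean)
      if (rmsd(avg2[selection, ], prev[selection, ]) < tol) break
    }
  }
  out <- md_trajectory(traj$structure, frames = res$coords, times = traj$times)
  attr(out, "rmsd") <- res$rmsd
  out
}

#' Root-mean-square fluctuation about the average position
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` for each selected atom of an
#' already-superposed trajectory.  Exported per-atom values can be written
#' into the PDB B-factor column for "sausage"-style rendering in external
#' viewers (see [write_pdb()]).
#'
#' @param fitted_traj an `md_trajectory`, already superposed.
#' @param selection atom indices (default: all atoms).
#' @return numeric vector of per-atom RMSF (Angstrom), one per selected
#'   atom, all non-negative.
#' @export
rmsf <- function(fitted_traj, selection = NULL) {
  stopifnot(inherits(fitted_traj, "md_trajectory"))
  if (is.null(selection)) selection <- seq_len(dim(fitted_traj$coords)[1])
  selection <- as.integer(unclass(selection))
  x <- fitted_traj$coords[selection, , , drop = FALSE]
  nf <- dim(x)[3]
  if (nf == 1L) {
    warning("single-frame trajectory: RMSF is identically zero")
    return(numeric(dim(x)[1]))
  }
  m <- apply(x, c(1, 2), mean)
  dev2 <- (x - array(m, dim = dim(x)))^2
  sqrt(apply(dev2, 1, sum) / nf)
}
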