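#' Size of the essential subspace
#'
#' Smallest number of leading principal components whose cumulative
#' eigenvalue fraction reaches `fraction` of the total fluctuation
#' (default 90%).
#'
#' @param eigenvalues non-negative eigenvalues in descending order.
#' @param fraction target cumulative fraction in (0, 1].
#' @return integer `n`.
#' @export
essential_space_size <- function(eigenvalues, fraction = 0.90) {
  ev <- as.numeric(eigenvalues)
  if (any(ev < -1e-12)) stop("eigenvalues must be non-negative")
  ev <- pmax(ev, 0)
  if (is.unsorted(rev(ev))) stop("eigenvalues must be in descending order")
  tot <- sum(ev)
  if (tot <= 0) stop("all-zero eigenvalue spectrum")
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  which(cumsum(ev) / tot >= fraction - 1e-12)[1]
}

#' Functional mode analysis: fit the maximally correlated motion
#'
#' Finds the linear combination of principal-component projections whose
#' time series has maximal Pearson correlation with a scalar functional
#' property (e.g. the solvent accessibility of a binding surface).  The
#' optimum over coefficient directions is the ordinary least-squares
#' solution on centered variables; `r_build` is the multiple correlation
#' coefficient on the model-building frames and `r_cv` the correlation of
#' the frozen model on the held-out validation frames.
#'
#' @param projections n_frames x n matrix of PC projections (columns
#'   PC1..PCn, the essential space).
#' @param property numeric vector, one value per frame.
#' @param split last frame index of the building set; frames
#'   `(split+1):n_frames` form the validation set.  Default: 90% of the
#'   frames (the 45 ns / 5 ns convention).
#' @return object of class `mcm_model`: list with unit-norm
#'   `coefficients` (oriented so `r_build >= 0`), `n`, `r_build`, `r_cv`,
#'   `build_variances` (per-PC projection variances on the building set)
#'   and `split`.
#' @export
fit_mcm <- function(projections, property, split = NULL) {
  p <- as.matrix(projections)
  f <- as.numeric(property)
  nf <- nrow(p)
  if (length(f) != nf) stop("property length does not match the projection frames")
  if (is.null(split)) split <- floor(0.9 * nf)
  split <- as.integer(split)
  if (split < 2L || split >= nf)
    stop("split must lie strictly inside the series (2 <= split < n_frames)")
  nb <- seq_len(split); nv <- (split + 1L):nf
  pb <- p[nb, , drop = FALSE]; fb <- f[nb]
  pb_c <- sweep(pb, 2, colMeans(pb)); fb_c <- fb - mean(fb)
  # drop linearly dependent PCs (rank-deficient building block)
  qrp <- qr(pb_c)
  keep <- seq_len(ncol(pb_c))
  if (qrp$rank < ncol(pb_c)) {
    keep <- sort(qrp$pivot[seq_len(qrp$rank)])
    warning("dropping ", ncol(pb_c) - qrp$rank,
            " linearly dependent PC(s) from the MCM fit")
    pb_c <- pb_c[, keep, drop = FALSE]
  }
  a <- qr.solve(crossprod(pb_c), crossprod(pb_c, fb_c))
  coef <- numeric(ncol(p))
  coef[keep] <- a
  nrm <- sqrt(sum(coef^2))
  if (nrm == 0) stop("property is uncorrelated with every PC (zero coefficients)")
  coef <- coef / nrm
  mb <- as.numeric(pb %*% coef)
  r_build <- stats::cor(mb, fb)
  if (is.na(r_build)) r_build <- 0
  if (r_build < 0) { coef <- -coef; r_build <- -r_build; mb <- -mb }
  mv <- as.numeric(p[nv, , drop = FALSE] %*% coef)
  r_cv <- suppressWarnings(stats::cor(mv, f[nv]))
  if (is.na(r_cv)) r_cv <- 0
  structure(list(coefficients = coef, n = ncol(p), r_build = r_build,
                 r_cv = r_cv,
                 build_variances = apply(sweep(pb, 2, colMeans(pb)), 2,
                                         function(z) mean(z^2)),
                 split = split),
            class = "mcm_model")
}

#' @export
print.mcm_model <- function(x, ...) {
  cat(sprintf("mcm_model: %d PCs, r_build = %.3f, r_cv = %.3f\n",
              x$n, x$r_build, x$r_cv))
  invisible(x)
}

#' Per-PC contribution to the variance of the modelled property
#'
#' `%var_k = a_k^2 v_k / sum_j a_j^2 v_j`, where `v_k` is the variance of
#' PC k.  By default `v_k` is the building-set projection variance (the
#' coefficients were fitted there); pass `eigenvalues` to use the
#' full-trajectory mode variances instead.
#'
#' @param model an `mcm_model`.
#' @param eigenvalues optional eigenvalues replacing the building-set
#'   projection variances.
#' @return list with `fractions` (non-negative, summing to 1) and
#'   `argmax` (index of the dominant PC).
#' @export
pc_contributions <- function(model, eigenvalues = NULL) {
  stopifnot(inherits(model, "mcm_model"))
  v <- if (is.null(eigenvalues)) {
    bv <- numeric(model$n)
    bv[seq_along(model$build_variances)] <- model$build_variances
    bv
  } else as.numeric(eigenvalues)[seq_len(model$n)]
  w <- model$coefficients^2 * v
  tot <- sum(w)
  if (tot <= 0) stop("all contributions are zero")
  fr <- w / tot
  list(fractions = fr, argmax = which.max(fr))
}

#' Export an MCM as a pseudo-mode for porcupine rendering
#'
#' Combines the essential-space eigenvectors with the fitted MCM
#' coefficients into a single 3N collective vector, returned as a
#' one-mode `mode_basis` so that [porcupine()] applies directly.
#'
#' @param model an `mcm_model`.
#' @param basis the `mode_basis` whose first `model$n` modes were used.
#' @return a `mode_basis` with a single mode of unit norm; its eigenvalue
#'   is the building-set variance of the MCM projection.
#' @export
mcm_pseudo_mode <- function(model, basis) {
  stopifnot(inherits(model, "mcm_model"), inherits(basis, "mode_basis"))
  u <- basis$vectors[, seq_len(model$n), drop = FALSE] %*% model$coefficients
  u <- u / sqrt(sum(u^2))
  lam <- sum(model$coefficients^2 * model$build_variances)
  structure(list(mean_coords = basis$mean_coords, vectors = u,
                 values = lam, n_atoms = basis$n_atoms),
            class = "mode_basis")
}
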