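#' Dynamic cross-correlation matrix
#'
#' Per-atom normalized covariance of displacement vectors over a fitted
#' trajectory: `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`.
#' Symmetric, unit diagonal, entries in [-1, 1].  Atoms with zero
#' positional variance produce 0 entries with a warning.
#'
#' @param fitted_traj an `md_trajectory`, already superposed.
#' @param selection atom indices (typically C-alpha atoms).
#' @return N x N numeric matrix.
#' @export
dccm <- function(fitted_traj, selection = NULL) {
  stopifnot(inherits(fitted_traj, "md_trajectory"))
  if (n_frames(fitted_traj) < 2L) stop("dccm needs at least 2 frames")
  m <- traj_matrix(fitted_traj, selection)      # frames x 3N
  mc <- sweep(m, 2, colMeans(m))
  cv <- crossprod(mc) / nrow(mc)                # 3N x 3N
  na <- ncol(cv) / 3L
  # trace of each 3x3 block: sum the three coordinate sub-matrices
  ix <- function(c1) seq(c1, by = 3L, length.out = na)
  inner <- cv[ix(1), ix(1)] + cv[ix(2), ix(2)] + cv[ix(3), ix(3)]
  v <- diag(inner)
  zero <- v <= 0
  if (any(zero)) warning(sum(zero), " atom(s) with zero variance; their correlations set to 0")
  denom <- sqrt(outer(pmax(v, 0), pmax(v, 0)))
  cc <- inner / denom
  cc[!is.finite(cc)] <- 0
  cc[zero, ] <- 0; cc[, zero] <- 0
  diag(cc)[!zero] <- 1
  cc <- (cc + t(cc)) / 2
  pmin(pmax(cc, -1), 1)
}

#' Correlation web from a cross-correlation matrix
#'
#' Connects residue pairs whose dynamic correlation exceeds a threshold
#' (strictly greater, per the 0.3 convention), excluding near-sequence
#' neighbours whose correlation is trivial.
#'
#' @param cc N x N correlation matrix (e.g. from [dccm()]).
#' @param threshold edge threshold in (0, 1]; default 0.3.
#' @param neighbor_exclusion exclude pairs with `|i - j| <= ` this value
#'   in sequence positions (default 2).
#' @param absolute logical; use `|C_ij|` instead of signed `C_ij`
#'   (default `FALSE`, matching the signed "higher than 0.3" convention).
#' @param nodes optional residue numbers labelling the matrix rows.
#' @return object of class `correlation_web`: list with `nodes`, `edges`
#'   (data.frame `i`, `j`, `value` with `i < j` in node positions) and
#'   the parameters used.
#' @export
correlation_web <- function(cc, threshold = 0.3, neighbor_exclusion = 2,
                            absolute = FALSE, nodes = NULL) {
  cc <- as.matrix(cc)
  n <- nrow(cc)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  if (is.null(nodes)) nodes <- seq_len(n)
  val <- if (absolute) abs(cc) else cc
  sel <- which(upper.tri(cc) & val > threshold, arr.ind = TRUE)
  if (nrow(sel)) {
    keep <- abs(sel[, 2] - sel[, 1]) > neighbor_exclusion
    sel <- sel[keep, , drop = FALSE]
  }
  edges <- data.frame(i = sel[, 1], j = sel[, 2],
                      value = cc[sel])
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 neighbor_exclusion = neighbor_exclusion,
                 absolute = absolute),
            class = "correlation_web")
}

#' @export
print.correlation_web <- function(x, ...) {
  cat(sprintf("correlation_web: %d nodes, %d edges (threshold %s%.2f, |i-j| > %d)\n",
              length(x$nodes), nrow(x$edges), if (x$absolute) "|C| > " else "C > ",
              x$threshold, x$neighbor_exclusion))
  invisible(x)
}

#' Count web links bridging helix and strand residues
#'
#' The number of correlation-web edges with one endpoint in a helix (H)
#' and the other in a beta-strand (E), a summary of how concertedly the
#' helices move with the sheet.
#'
#' @param web a `correlation_web`.
#' @param ss_labels character vector of per-residue labels (H/E/T/C),
#'   one per web node.
#' @return integer count.
#' @export
count_cross_links <- function(web, ss_labels) {
  stopifnot(inherits(web, "correlation_web"))
  if (length(ss_labels) != length(web$nodes))
    stop("ss_labels length (", length(ss_labels),
         ") does not match node count (", length(web$nodes), ")")
  if (nrow(web$edges) == 0L) return(0L)
  a <- ss_labels[web$edges$i]; b <- ss_labels[web$edges$j]
  sum((a == "H" & b == "E") | (a == "E" & b == "H"))
}

#' Write a correlation web as an edge-list TSV
#' @param web a `correlation_web`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_web_tsv <- function(web, path) {
  stopifnot(inherits(web, "correlation_web"))
  df <- data.frame(res_i = web$nodes[web$edges$i],
                   res_j = web$nodes[web$edges$j],
                   correlation = web$edges$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
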