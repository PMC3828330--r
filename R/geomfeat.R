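#' Shrake-Rupley solvent accessible surface area
#'
#' Classic point-counting SASA: each atom's sphere is expanded by the
#' probe radius and covered with a deterministic golden-spiral point set;
#' the accessible area is the fraction of points not buried inside any
#' neighbouring expanded sphere times `4*pi*(r+probe)^2`.
#'
#' @param structure an `md_structure`.
#' @param selection atoms to report areas for (default: all heavy atoms).
#' @param coords optional n x 3 matrix overriding `structure$xyz` (e.g. a
#'   trajectory frame).
#' @param probe probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points points per sphere (default 960).
#' @param include_h logical; include hydrogens as occluders and targets
#'   (default `FALSE`: heavy atoms only).
#' @return numeric vector of per-atom areas (Angstrom^2) for the
#'   selection, with attribute `"total"` holding the sum.
#' @export
sasa <- function(structure, selection = NULL, coords = NULL, probe = 1.4,
                 n_points = 960, include_h = FALSE) {
  stopifnot(inherits(structure, "md_structure"))
  occl <- if (include_h) seq_len(n_atoms(structure))
          else which(structure$atoms$element != "H")
  if (is.null(selection)) selection <- occl
  selection <- as.integer(unclass(selection))
  if (length(selection) == 0L) stop("empty selection")
  if (!include_h) selection <- selection[structure$atoms$element[selection] != "H"]
  xyz <- if (is.null(coords)) structure$xyz else as.matrix(coords)
  r <- structure$radius
  ox <- xyz[occl, , drop = FALSE]
  orad <- r[occl]
  # identical coordinates make the surface ill-defined
  if (nrow(ox) > 1L) {
    dd <- as.matrix(stats::dist(ox))
    diag(dd) <- Inf
    if (any(dd < 1e-9)) stop("overlapping identical coordinates between atoms")
  }
  sp <- sphere_points(n_points)
  out <- numeric(length(selection))
  for (s in seq_along(selection)) {
    i <- selection[s]
    ri <- r[i] + probe
    pts <- sweep(sp * ri, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    d2i <- colSums((t(ox) - xyz[i, ])^2)
    nb <- which(d2i < (ri + orad + probe)^2 & d2i > 1e-18)
    for (j in nb) {
      rj2 <- (orad[j] + probe)^2
      idx <- which(free)
      if (!length(idx)) break
      d2 <- (pts[idx, 1] - ox[j, 1])^2 + (pts[idx, 2] - ox[j, 2])^2 +
            (pts[idx, 3] - ox[j, 3])^2
      free[idx[d2 < rj2]] <- FALSE
    }
    out[s] <- 4 * pi * ri^2 * sum(free) / n_points
  }
  attr(out, "total") <- sum(out)
  out
}

#' Deterministic golden-spiral points on the unit sphere
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' SASA time series over a trajectory
#'
#' Total solvent accessible surface area of a residue set (backbone and
#' side chains) per sampled frame — e.g. of the hydrophobic surface
#' between helix alpha1 and strand beta2, the functional property used in
#' functional mode analysis.
#'
#' @param traj an `md_trajectory`.
#' @param selection atom indices whose summed area is reported.
#' @param probe probe radius, Angstrom.
#' @param stride sample every `stride`-th frame (default 1).
#' @param n_points points per sphere.
#' @return numeric vector of total areas (Angstrom^2), with attribute
#'   `"times"` holding the sampled frame times.
#' @export
sasa_series <- function(traj, selection = NULL, probe = 1.4, stride = 1,
                        n_points = 960) {
  stopifnot(inherits(traj, "md_trajectory"))
  frames <- seq(1L, n_frames(traj), by = stride)
  vals <- vapply(frames, function(k) {
    attr(sasa(traj$structure, selection, coords = frame_coords(traj, k),
              probe = probe, n_points = n_points), "total")
  }, numeric(1))
  attr(vals, "times") <- traj$times[frames]
  vals
}

# -- hydrogen bonds ----------------------------------------------------------

# Internal: donor table (heavy atom + hydrogen coordinates) for a frame.
# Backbone amide H may be inferred at ideal geometry (bisector of N-CA and
# N-C_prev, 1.01 A); side-chain donors require explicit hydrogens.
hbond_donors <- function(structure, xyz, infer_h = TRUE) {
  at <- structure$atoms
  polar <- which(at$element %in% c("N", "O"))
  hyd <- which(at$element == "H")
  don_heavy <- integer(0); don_h <- list(); don_hidx <- integer(0)
  if (length(hyd)) {
    for (h in hyd) {
      # covalent assignment: nearest polar heavy atom of the same residue
      same <- polar[at$resid[polar] == at$resid[h] & at$chain[polar] == at$chain[h]]
      if (!length(same)) next
      d2 <- colSums((t(xyz[same, , drop = FALSE]) - xyz[h, ])^2)
      j <- which(d2 < 1.25^2)
      if (length(j)) {
        j <- same[j[which.min(d2[j])]]
        don_heavy <- c(don_heavy, j)
        don_h <- c(don_h, list(xyz[h, ]))
        don_hidx <- c(don_hidx, h)
      }
    }
  }
  # backbone amide N without an explicit hydrogen
  bbN <- which(toupper(at$atom_name) == "N")
  bbN <- setdiff(bbN, don_heavy)
  missing_named <- character(0)
  for (i in bbN) {
    if (at$resname[i] == "PRO") next
    prev <- which(at$chain == at$chain[i] & at$resid == at$resid[i] - 1L &
                  toupper(at$atom_name) == "C")
    ca <- which(at$chain == at$chain[i] & at$resid == at$resid[i] &
                toupper(at$atom_name) == "CA")
    if (length(prev) != 1L || length(ca) != 1L) next   # chain terminus
    if (!infer_h) {
      missing_named <- c(missing_named,
                         paste0(at$resname[i], at$resid[i], ":N"))
      next
    }
    u1 <- xyz[i, ] - xyz[prev, ]; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- xyz[i, ] - xyz[ca, ];   u2 <- u2 / sqrt(sum(u2^2))
    b <- u1 + u2
    b <- b / sqrt(sum(b^2))
    don_heavy <- c(don_heavy, i)
    don_h <- c(don_h, list(xyz[i, ] + 1.01 * b))
    don_hidx <- c(don_hidx, NA_integer_)
  }
  if (length(missing_named))
    stop("missing hydrogens for donor(s) ", paste(missing_named, collapse = ", "),
         " and inference is disabled")
  list(heavy = don_heavy,
       h = if (length(don_h)) do.call(rbind, don_h) else matrix(0, 0, 3),
       hidx = don_hidx)
}

#' Geometric hydrogen-bond detection in one frame
#'
#' Enumerates all donor-acceptor pairs with donor-acceptor distance at
#' most `d_cut` (3.5 Angstrom) and acceptor-donor-hydrogen angle at most
#' `ang_cut` (30 degrees).  Donors are N/O atoms carrying a hydrogen
#' (backbone amide hydrogens may be inferred at ideal geometry);
#' acceptors are oxygen atoms and nitrogen atoms with no attached
#' hydrogen.  Donor and acceptor must belong to different residues.
#'
#' @param structure an `md_structure`.
#' @param coords optional frame coordinates overriding `structure$xyz`.
#' @param donors,acceptors optional atom-index vectors restricting the
#'   candidate heavy atoms.
#' @param d_cut acceptor-donor distance cutoff, Angstrom (default 3.5).
#' @param ang_cut acceptor-donor-hydrogen angle cutoff, degrees
#'   (default 30).
#' @param infer_h infer missing backbone amide hydrogens (default
#'   `TRUE`); if `FALSE`, a backbone donor without hydrogen is an error.
#' @return data.frame with columns `donor`, `hydrogen` (atom index, `NA`
#'   when inferred), `acceptor`, `distance` (Angstrom) and `angle`
#'   (degrees).
#' @export
hbonds <- function(structure, coords = NULL, donors = NULL, acceptors = NULL,
                   d_cut = 3.5, ang_cut = 30, infer_h = TRUE) {
  stopifnot(inherits(structure, "md_structure"))
  xyz <- if (is.null(coords)) structure$xyz else as.matrix(coords)
  at <- structure$atoms
  dn <- hbond_donors(structure, xyz, infer_h = infer_h)
  if (!is.null(donors)) {
    keep <- dn$heavy %in% as.integer(unclass(donors))
    dn$heavy <- dn$heavy[keep]; dn$h <- dn$h[keep, , drop = FALSE]
    dn$hidx <- dn$hidx[keep]
  }
  acc <- which(at$element == "O" |
               (at$element == "N" & !(seq_len(nrow(at)) %in% dn$heavy)))
  if (!is.null(acceptors)) acc <- intersect(acc, as.integer(unclass(acceptors)))
  out <- data.frame(donor = integer(0), hydrogen = integer(0),
                    acceptor = integer(0), distance = numeric(0),
                    angle = numeric(0))
  if (!length(dn$heavy) || !length(acc)) return(out)
  for (k in seq_along(dn$heavy)) {
    d <- dn$heavy[k]
    da <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[d, ])^2))
    same_res <- at$resid[acc] == at$resid[d] & at$chain[acc] == at$chain[d]
    cand <- which(da <= d_cut & !same_res & da > 1e-9)
    for (ci in cand) {
      a <- acc[ci]
      v1 <- xyz[a, ] - xyz[d, ]
      v2 <- dn$h[k, ] - xyz[d, ]
      ang <- acos(pmin(pmax(sum(v1 * v2) /
               sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (ang <= ang_cut)
        out <- rbind(out, data.frame(donor = d, hydrogen = dn$hidx[k],
                                     acceptor = a, distance = da[ci],
                                     angle = ang))
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-frame count of hydrogen bonds between two residue groups
#'
#' Counts bonds whose donor lies in one group and acceptor in the other
#' (either direction), per trajectory frame — e.g. contacts forming
#' between two loop regions along a simulation.
#'
#' @param traj an `md_trajectory`.
#' @param group_a,group_b disjoint vectors of residue numbers.
#' @param include_sidechains logical; include side-chain atoms (default
#'   `TRUE`; `FALSE` restricts both groups to backbone atoms).
#' @param d_cut,ang_cut,infer_h as in [hbonds()].
#' @return integer vector of per-frame counts, with attribute `"times"`.
#' @export
hbond_series <- function(traj, group_a, group_b, include_sidechains = TRUE,
                         d_cut = 3.5, ang_cut = 30, infer_h = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (length(intersect(group_a, group_b)))
    stop("residue groups must be disjoint")
  at <- traj$structure$atoms
  pick <- function(grp) {
    idx <- which(at$resid %in% grp)
    if (!include_sidechains)
      idx <- idx[toupper(at$atom_name[idx]) %in% .backbone_names]
    idx
  }
  ia <- pick(group_a); ib <- pick(group_b)
  counts <- integer(n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    hb <- hbonds(traj$structure, coords = frame_coords(traj, k),
                 d_cut = d_cut, ang_cut = ang_cut, infer_h = infer_h)
    if (!nrow(hb)) next
    cross <- (hb$donor %in% ia & hb$acceptor %in% ib) |
             (hb$donor %in% ib & hb$acceptor %in% ia)
    if (!include_sidechains)
      cross <- cross & hb$donor %in% c(ia, ib) & hb$acceptor %in% c(ia, ib)
    counts[k] <- sum(cross)
  }
  attr(counts, "times") <- traj$times
  counts
}

# -- reduced secondary structure --------------------------------------------

#' Reduced secondary-structure assignment (H/E/T/C)
#'
#' A reduced re-implementation of the hydrogen-bond-based classifier:
#' backbone N-H...O=C bonds are scored with the electrostatic energy
#' `E = 0.084 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN) * 332` kcal/mol and
#' accepted when `E < -0.5`.  Two consecutive i -> i+4 bonds define a
#' helix (H, covering 3-10/alpha/pi in one class); ladder-paired residues
#' (parallel or antiparallel bridges) are strand (E); residues inside
#' isolated 3/4/5-turns are turn (T); everything else is coil (C).
#' Amide hydrogens are placed at ideal geometry when absent.  Residues
#' with missing backbone atoms are labelled C with a warning.
#'
#' @param structure an `md_structure` with backbone N, CA, C, O atoms.
#' @param coords optional frame coordinates overriding `structure$xyz`.
#' @return character vector of labels (`"H"`, `"E"`, `"T"`, `"C"`), one
#'   per residue, named by `chain:resid`.
#' @export
assign_ss <- function(structure, coords = NULL) {
  stopifnot(inherits(structure, "md_structure"))
  xyz <- if (is.null(coords)) structure$xyz else as.matrix(coords)
  at <- structure$atoms
  key <- paste(at$chain, at$resid, sep = ":")
  resk <- unique(key)
  nr <- length(resk)
  idx_of <- function(k, nm) {
    i <- which(key == k & toupper(at$atom_name) == nm)
    if (length(i) == 1L) i else NA_integer_
  }
  iN <- vapply(resk, idx_of, 1L, nm = "N")
  iCA <- vapply(resk, idx_of, 1L, nm = "CA")
  iC <- vapply(resk, idx_of, 1L, nm = "C")
  iO <- vapply(resk, idx_of, 1L, nm = "O")
  ok <- !(is.na(iN) | is.na(iCA) | is.na(iC) | is.na(iO))
  if (any(!ok)) warning(sum(!ok), " residue(s) with missing backbone atoms labelled C")
  # ideal amide H: bisector of (N-C_prev) and (N-CA), 1.01 A from N
  H <- matrix(NA_real_, nr, 3)
  if (nr < 3L) { lab <- rep("C", nr); names(lab) <- resk; return(lab) }
  for (r in 2:nr) {
    if (!ok[r] || !ok[r - 1L]) next
    u1 <- xyz[iN[r], ] - xyz[iC[r - 1L], ]; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- xyz[iN[r], ] - xyz[iCA[r], ]; u2 <- u2 / sqrt(sum(u2^2))
    b <- u1 + u2; b <- b / sqrt(sum(b^2))
    H[r, ] <- xyz[iN[r], ] + 1.01 * b
  }
  # hb[d, a]: N-H of residue d donates to C=O of residue a
  hb <- matrix(FALSE, nr, nr)
  for (d in seq_len(nr)) {
    if (!ok[d] || any(is.na(H[d, ]))) next
    for (a in seq_len(nr)) {
      if (!ok[a] || abs(d - a) < 2L) next
      dON <- sqrt(sum((xyz[iO[a], ] - xyz[iN[d], ])^2))
      if (dON > 5.2) next
      dCH <- sqrt(sum((xyz[iC[a], ] - H[d, ])^2))
      dOH <- sqrt(sum((xyz[iO[a], ] - H[d, ])^2))
      dCN <- sqrt(sum((xyz[iC[a], ] - xyz[iN[d], ])^2))
      e <- 0.084 * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN) * 332
      hb[d, a] <- e < -0.5
    }
  }
  lab <- rep("C", nr)
  HB <- function(d, a) d >= 1L && d <= nr && a >= 1L && a <= nr && hb[d, a]
  # helices: two consecutive i -> i+4 turns
  turn4 <- vapply(seq_len(nr), function(i) HB(i + 4L, i), TRUE)
  for (i in seq_len(nr - 1L)) {
    if (turn4[i] && turn4[i + 1L]) lab[(i + 1L):min(i + 4L, nr)] <- "H"
  }
  # bridges (Hbond(x, y): C=O of x accepts from N-H of y)
  HBx <- function(x, y) HB(y, x)
  if (nr >= 3L) for (i in 2:(nr - 1L)) for (j in 2:(nr - 1L)) {
    if (abs(i - j) < 3L) next
    par <- (HBx(i - 1L, j) && HBx(j, i + 1L)) || (HBx(j - 1L, i) && HBx(i, j + 1L))
    anti <- (HBx(i, j) && HBx(j, i)) ||
            (HBx(i - 1L, j + 1L) && HBx(j - 1L, i + 1L))
    if (par || anti) { lab[i] <- "E"; lab[j] <- "E" }
  }
  # isolated turns
  for (k in 3:5) for (i in seq_len(nr)) {
    if (HB(i + k, i)) {
      span <- (i + 1L):(i + k - 1L)
      span <- span[span <= nr]
      lab[span][lab[span] == "C"] <- "T"
    }
  }
  names(lab) <- resk
  lab
}

# -- side-chain distance matrices -------------------------------------------

#' Windowed minimum side-chain distance matrix
#'
#' Entry (a, b) is the mean over the window frames of the minimum
#' distance between any pair of side-chain heavy atoms of residues a and
#' b (glycine contributes its C-alpha).  Symmetric with zero diagonal.
#'
#' @param traj an `md_trajectory`.
#' @param residues vector of residue numbers (e.g. the hydrophobic core).
#' @param window frame indices to average over (default: all frames).
#' @return R x R matrix (Angstrom) with residue numbers as dimnames.
#' @export
distance_matrix <- function(traj, residues, window = NULL) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.null(window)) window <- seq_len(n_frames(traj))
  window <- as.integer(window)
  if (!length(window)) stop("empty frame window")
  if (any(window < 1L | window > n_frames(traj))) stop("window frame out of range")
  at <- traj$structure$atoms
  grp <- lapply(residues, function(r) {
    idx <- which(at$resid == r &
                 !(toupper(at$atom_name) %in% .backbone_names) &
                 at$element != "H")
    if (!length(idx)) idx <- which(at$resid == r & toupper(at$atom_name) == "CA")
    if (!length(idx)) stop("residue ", r, " has no side-chain heavy atoms or CA")
    idx
  })
  nr <- length(residues)
  acc <- matrix(0, nr, nr)
  for (k in window) {
    xyz <- frame_coords(traj, k)
    for (a in seq_len(nr - 1L)) for (b in (a + 1L):nr) {
      pa <- xyz[grp[[a]], , drop = FALSE]
      pb <- xyz[grp[[b]], , drop = FALSE]
      d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
      m <- sqrt(max(min(d2), 0))
      acc[a, b] <- acc[a, b] + m
      acc[b, a] <- acc[b, a] + m
    }
  }
  out <- acc / length(window)
  dimnames(out) <- list(residues, residues)
  out
}
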