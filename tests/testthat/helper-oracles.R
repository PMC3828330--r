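# Independent oracles used to cross-check the package implementations.
# Each is deliberately written along a different algorithmic route than
# the code it checks.

# Horn's quaternion method for optimal superposition RMSD.
horn_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  m <- crossprod(a, b)   # 3x3
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       -sxx - syy + szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(k, symmetric = TRUE)$values)
  e2 <- (sum(a^2) + sum(b^2) - 2 * lam) / nrow(a)
  sqrt(max(e2, 0))
}

# Score-only affine-gap global alignment DP (Gotoh), gap costs positive:
# a gap of length L costs open + L * extend.
gotoh_score <- function(s1, s2, submat, open = 10, extend = 0.5) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  neg <- -1e9
  M <- matrix(neg, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + extend * i)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- submat[a[i], b[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend, X[i, j + 1] - extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend, Y[i + 1, j] - extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force dynamic cross-correlation by explicit summation.
brute_dccm <- function(frames_list) {
  nf <- length(frames_list); na <- nrow(frames_list[[1]])
  mean_xyz <- Reduce(`+`, frames_list) / nf
  cc <- matrix(0, na, na)
  for (i in seq_len(na)) for (j in seq_len(na)) {
    num <- 0; vi <- 0; vj <- 0
    for (t in seq_len(nf)) {
      di <- frames_list[[t]][i, ] - mean_xyz[i, ]
      dj <- frames_list[[t]][j, ] - mean_xyz[j, ]
      num <- num + sum(di * dj)
      vi <- vi + sum(di * di)
      vj <- vj + sum(dj * dj)
    }
    cc[i, j] <- num / sqrt(vi * vj)
  }
  cc
}

# Monte-Carlo SASA: uniform points on each expanded sphere.
mc_sasa <- function(xyz, radii, probe = 1.4, n_total = 1e6, seed = 99) {
  set.seed(seed)
  na <- nrow(xyz)
  n_per <- ceiling(n_total / na)
  total <- 0
  for (i in seq_len(na)) {
    ri <- radii[i] + probe
    p <- matrix(stats::rnorm(3 * n_per), ncol = 3)
    p <- p / sqrt(rowSums(p^2)) * ri
    p <- sweep(p, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_per)
    for (j in seq_len(na)[-i]) {
      rj <- radii[j] + probe
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= rj^2
    }
    total <- total + 4 * pi * ri^2 * mean(free)
  }
  total
}

# Brute-force H-bond enumeration given explicit donor/H/acceptor lists.
brute_hbonds <- function(xyz, donor_idx, h_idx, acceptor_idx, resid,
                         d_cut = 3.5, ang_cut = 30) {
  out <- NULL
  for (k in seq_along(donor_idx)) {
    d <- donor_idx[k]; h <- h_idx[k]
    for (a in acceptor_idx) {
      if (resid[a] == resid[d]) next
      da <- sqrt(sum((xyz[a, ] - xyz[d, ])^2))
      if (da > d_cut || da < 1e-9) next
      v1 <- xyz[a, ] - xyz[d, ]; v2 <- xyz[h, ] - xyz[d, ]
      ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (ang <= ang_cut) out <- rbind(out, c(d, a))
    }
  }
  out
}

# Dense direction search for the maximally correlated linear combination
# (FMA oracle): Fibonacci sphere + deterministic cone refinement.
grid_search_direction <- function(projections, property, n_coarse = 5000) {
  p <- as.matrix(projections); f <- as.numeric(property)
  stopifnot(ncol(p) == 3L)
  fib <- function(n) {
    i <- seq_len(n) - 0.5
    phi <- acos(1 - 2 * i / n)
    th <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  }
  score <- function(dirs) abs(stats::cor(p %*% t(dirs), f))
  dirs <- fib(n_coarse)
  r <- score(dirs)
  best <- dirs[which.max(r), ]
  width <- 0.1
  set.seed(1234)
  for (round in 1:6) {
    pert <- matrix(stats::rnorm(3 * 3000, sd = width), ncol = 3)
    cand <- sweep(pert, 2, best, "+")
    cand <- cand / sqrt(rowSums(cand^2))
    r <- score(cand)
    if (max(r) > abs(stats::cor(p %*% best, f))) best <- cand[which.max(r), ]
    width <- width / 4
  }
  best
}

# Small CA-only chain for mode-planting tests.
ca_chain <- function(n_res, spacing = 3.8, resid_start = 1L) {
  md_structure(atom_name = rep("CA", n_res), element = rep("C", n_res),
               resid = seq(resid_start, length.out = n_res),
               resname = "ALA", chain = "A",
               xyz = cbind(seq_len(n_res) * spacing,
                           sin(seq_len(n_res)), cos(seq_len(n_res))))
}

# Principal angles (degrees) between two orthonormal column spaces.
principal_angles <- function(u, v) {
  s <- svd(crossprod(u, v))$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}
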