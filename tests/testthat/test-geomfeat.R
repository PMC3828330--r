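test_that("SASA reproduces closed forms and shrinks under occlusion", {
  iso <- md_structure("C", element = "C", resid = 1, resname = "UNK",
                      chain = "A", xyz = matrix(0, 1, 3))
  expect_equal(as.numeric(sasa(iso)), 4 * pi * (1.70 + 1.4)^2,
               tolerance = 1e-10)
  # two atoms far apart: both isolated
  two <- md_structure(c("C", "C"), element = c("C", "C"), resid = c(1, 2),
                      resname = "UNK", chain = "A",
                      xyz = rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(as.numeric(sasa(two)), rep(4 * pi * 3.1^2, 2), tolerance = 1e-10)
  # adding a neighbour can only reduce each atom's area
  close3 <- md_structure(c("C", "C", "C"), element = rep("C", 3),
                         resid = 1:3, resname = "UNK", chain = "A",
                         xyz = rbind(c(0, 0, 0), c(2.2, 0, 0), c(0, 2.2, 0)))
  s2 <- sasa(two)
  s3 <- sasa(close3)
  expect_lt(s3[1], s2[1])
  # identical coordinates are rejected
  dup <- md_structure(c("C", "C"), element = c("C", "C"), resid = 1:2,
                      resname = "UNK", chain = "A",
                      xyz = rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(sasa(dup), "overlapping")
})

test_that("SASA agrees with a million-point Monte-Carlo oracle within 2%", {
  set.seed(90)
  xyz <- matrix(rnorm(15, sd = 1.6), 5, 3)
  # keep atoms from exact overlap
  while (min(dist(xyz)) < 1.0) xyz <- matrix(rnorm(15, sd = 1.6), 5, 3)
  st <- md_structure(c("C", "N", "O", "C", "S"),
                     element = c("C", "N", "O", "C", "S"),
                     resid = 1:5, resname = "UNK", chain = "A", xyz = xyz)
  total <- attr(sasa(st), "total")
  oracle <- mc_sasa(xyz, st$radius, n_total = 1e6)
  expect_lt(abs(total - oracle) / oracle, 0.02)
})

test_that("SASA series tracks rigid, strided and two-state trajectories", {
  st <- gen_chain(6, "strand")
  heavy <- select_atoms(st, "heavy")
  rigid <- md_trajectory(st, frames = replicate(5, st$xyz, simplify = FALSE))
  s <- sasa_series(rigid, heavy)
  expect_equal(max(s) - min(s), 0, tolerance = 1e-9)
  expect_length(sasa_series(rigid, heavy, stride = 2), 3L)

  # two-state burial: series means differ by the endpoint SASA difference
  open_st <- gen_chain(6, "hairpin")
  b_atoms <- which(open_st$atoms$chain == "B")
  open_coords <- open_st$xyz
  open_coords[b_atoms, ] <- sweep(open_coords[b_atoms, ], 2, c(0, 25, 0), "+")
  closed_coords <- open_st$xyz
  tr <- gen_two_state_trajectory(open_st, open_coords, closed_coords,
                                 switch_frame = 11, noise = 0, n_frames = 20)
  hv <- select_atoms(open_st, "heavy")
  ss <- sasa_series(tr, hv)
  d_series <- mean(ss[1:10]) - mean(ss[11:20])
  d_endpoint <- attr(sasa(open_st, hv, coords = open_coords), "total") -
    attr(sasa(open_st, hv, coords = closed_coords), "total")
  expect_gt(d_endpoint, 0)
  expect_equal(d_series, d_endpoint, tolerance = 0.02 * abs(d_endpoint))
})

test_that("hydrogen bonds obey both geometric cutoffs", {
  geom <- function(d, ang_deg) {
    a <- ang_deg * pi / 180
    md_structure(c("N", "H", "O"), element = c("N", "H", "O"),
                 resid = c(1, 1, 2), resname = c("GLY", "GLY", "HOH"),
                 chain = "A",
                 xyz = rbind(c(0, 0, 0), c(cos(a), sin(a), 0) * 1.0,
                             c(d, 0, 0)))
  }
  expect_equal(nrow(hbonds(geom(2.9, 10))), 1L)
  expect_equal(nrow(hbonds(geom(3.6, 10))), 0L)   # distance fail
  expect_equal(nrow(hbonds(geom(2.9, 35))), 0L)   # angle fail
  hb <- hbonds(geom(3.5, 30))                     # boundary inclusive
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 3.5, tolerance = 1e-9)
})

test_that("H-bond enumeration equals brute force on a synthetic peptide pair", {
  set.seed(91)
  n_res <- 5
  nm <- character(0); el <- character(0); rid <- integer(0)
  xyz <- NULL
  for (r in 1:n_res) {
    base <- c(3.5 * r, ifelse(r %% 2 == 0, 0.6, 0), 0)
    block <- rbind(base, base + c(-0.8, 0.6, 0), base + c(1.8, -0.5, 0.3),
                   base + c(2.5, 0.2, -0.2))
    # rigid per-residue jitter keeps covalent N-H geometry intact
    xyz <- rbind(xyz, block + matrix(rep(rnorm(3, sd = 0.35), each = 4), 4, 3))
    nm <- c(nm, "N", "H", "C", "O")
    el <- c(el, "N", "H", "C", "O")
    rid <- c(rid, rep(r, 4))
  }
  st <- md_structure(nm, element = el, resid = rid, resname = "GLY",
                     chain = "A", xyz = xyz)
  hb <- hbonds(st, infer_h = FALSE)
  don <- which(el == "N"); hyd <- which(el == "H"); acc <- which(el == "O")
  oracle <- brute_hbonds(xyz, don, hyd, acc, rid)
  got <- if (nrow(hb)) hb[order(hb$donor, hb$acceptor), c("donor", "acceptor")]
         else NULL
  if (is.null(oracle)) {
    expect_equal(nrow(hb), 0L)
  } else {
    oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
    expect_equal(unname(as.matrix(got)), unname(oracle))
  }
  expect_gt(nrow(hb), 0L)   # the fixture is built to contain bonds
})

test_that("missing donor hydrogens error when inference is disabled", {
  st <- gen_chain(4, "helix")   # backbone has no explicit H
  expect_error(hbonds(st, infer_h = FALSE), "missing hydrogens")
  expect_silent(hbonds(st, infer_h = TRUE))
})

test_that("inter-group H-bond series detects planted contact formation", {
  closed <- gen_chain(6, "hairpin")
  b_atoms <- which(closed$atoms$chain == "B")
  open_coords <- closed$xyz
  open_coords[b_atoms, ] <- sweep(open_coords[b_atoms, ], 2, c(0, 30, 0), "+")
  tr <- gen_two_state_trajectory(closed, open_coords, closed$xyz,
                                 switch_frame = 8, noise = 0.02, n_frames = 14,
                                 seed = 92)
  grp_a <- unique(closed$atoms$resid[closed$atoms$chain == "A"])
  grp_b <- unique(closed$atoms$resid[closed$atoms$chain == "B"])
  series <- hbond_series(tr, grp_a, grp_b)
  expect_equal(max(series[1:7]), 0L)
  expect_true(all(series[8:14] >= 1L))
  # symmetric under group swap
  expect_equal(series, hbond_series(tr, grp_b, grp_a), ignore_attr = TRUE)
  expect_error(hbond_series(tr, grp_a, grp_a), "disjoint")
})

test_that("reduced secondary structure labels canonical geometries", {
  helix <- gen_chain(12, "helix")
  ssh <- assign_ss(helix)
  expect_true(all(ssh[3:10] == "H"))
  hairpin <- gen_chain(7, "hairpin")
  ssp <- assign_ss(hairpin)
  # interior residues of both strands are ladder-paired
  expect_gte(sum(ssp == "E"), 8)
  ext <- assign_ss(gen_chain(10, "extended"))
  expect_false(any(ext %in% c("H", "E")))
  coil <- assign_ss(gen_chain(10, "coil"))
  expect_false(any(coil == "H"))
})

test_that("distance matrices equal brute force and are rigid-motion invariant", {
  # rigid two-residue case: single-frame hand minimum
  st <- gen_chain(5, "strand")
  tr <- md_trajectory(st, frames = replicate(3, st$xyz, simplify = FALSE))
  dm <- distance_matrix(tr, c(1, 4))
  at <- st$atoms
  sc <- function(r) which(at$resid == r & at$atom_name == "CB")
  hand <- sqrt(sum((st$xyz[sc(1), ] - st$xyz[sc(4), ])^2))
  expect_equal(dm[1, 2], hand, tolerance = 1e-12)
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), c("1" = 0, "4" = 0))

  # 3-residue, 5-frame fixture vs triple loop
  set.seed(93)
  frames <- lapply(1:5, function(k) st$xyz + matrix(rnorm(length(st$xyz), sd = 0.3),
                                                    ncol = 3))
  trf <- md_trajectory(st, frames = frames)
  res <- c(1, 3, 5)
  dmf <- distance_matrix(trf, res, window = 1:5)
  sidech <- lapply(res, function(r)
    which(at$resid == r & !(at$atom_name %in% c("N", "CA", "C", "O"))))
  for (a in 1:2) for (b in (a + 1):3) {
    vals <- vapply(1:5, function(t) {
      best <- Inf
      for (i in sidech[[a]]) for (j in sidech[[b]])
        best <- min(best, sqrt(sum((frames[[t]][i, ] - frames[[t]][j, ])^2)))
      best
    }, numeric(1))
    expect_equal(dmf[a, b], mean(vals), tolerance = 1e-12)
  }
  # rigid motion leaves it unchanged
  th <- 0.8
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  frames_rot <- lapply(frames, function(f) sweep(f %*% rot, 2, c(3, -1, 2), "+"))
  dmr <- distance_matrix(md_trajectory(st, frames = frames_rot), res, 1:5)
  expect_equal(dmr, dmf, tolerance = 1e-9)
  expect_error(distance_matrix(trf, res, window = integer(0)), "empty")

  # glycine falls back to C-alpha
  gly <- gen_chain(4, "strand", with_cb = FALSE)
  trg <- md_trajectory(gly)
  dmg <- distance_matrix(trg, c(1, 3))
  ca <- function(r) which(gly$atoms$resid == r & gly$atoms$atom_name == "CA")
  expect_equal(dmg[1, 2], sqrt(sum((gly$xyz[ca(1), ] - gly$xyz[ca(3), ])^2)),
               tolerance = 1e-12)
})
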