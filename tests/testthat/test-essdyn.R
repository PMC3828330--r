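test_that("covariance matches hand computation and basic identities", {
  # 2 atoms in 1D-style toy motion: hand-computed covariance
  st <- ca_chain(2)
  d1 <- c(0.0, 1.0, 2.0, 3.0)
  d2 <- c(0.0, -1.0, 0.0, 1.0)
  frames <- lapply(1:4, function(k) {
    z <- st$xyz
    z[1, 1] <- z[1, 1] + d1[k]
    z[2, 1] <- z[2, 1] + d2[k]
    z
  })
  tr <- md_trajectory(st, frames = frames)
  cv <- covariance_matrix(tr)$matrix
  v1 <- mean((d1 - mean(d1))^2)
  v2 <- mean((d2 - mean(d2))^2)
  c12 <- mean((d1 - mean(d1)) * (d2 - mean(d2)))
  expect_equal(cv[1, 1], v1)
  expect_equal(cv[4, 4], v2)
  expect_equal(cv[1, 4], c12)
  expect_equal(cv[2, 2], 0)       # y of atom 1 never moves
  # static trajectory: zero matrix
  trs <- md_trajectory(st, frames = list(st$xyz, st$xyz, st$xyz))
  expect_equal(max(abs(covariance_matrix(trs)$matrix)), 0)
  expect_warning(covariance_matrix(tr, fitted = FALSE), "unfitted")
})

test_that("pca_modes satisfies the mode-basis invariants and axis-aligned cases", {
  d <- diag(c(4, 1, 0, 0, 0, 0))
  b <- pca_modes(d)
  expect_equal(b$values[1:2], c(4, 1))
  expect_equal(abs(b$vectors[1, 1]), 1)
  expect_equal(abs(b$vectors[2, 2]), 1)
  # invariants on a random PSD matrix
  set.seed(8)
  a <- matrix(rnorm(81), 9, 9); cvm <- crossprod(a) / 9
  b2 <- pca_modes(cvm)
  g <- crossprod(b2$vectors)
  expect_lt(max(abs(g - diag(9))), 1e-8)
  expect_true(all(diff(b2$values) <= 1e-12))
  expect_true(all(b2$values >= -1e-10))
  expect_equal(sum(b2$values), sum(diag(cvm)), tolerance = 1e-10)
  recon <- b2$vectors %*% diag(b2$values) %*% t(b2$vectors)
  expect_lt(norm(recon - cvm, "F") / norm(cvm, "F"), 1e-8)
  expect_error(pca_modes(matrix(rnorm(16), 4, 4)), "symmetric")
})

test_that("planted variance fractions and subspaces are recovered within sampling error", {
  st <- ca_chain(20)
  u <- random_modes(st, 3, seed = 21)
  fr <- c(0.7, 0.2, 0.1)
  tot <- 8
  amps <- sqrt(fr * tot)
  nf <- 5000
  tr <- gen_mode_trajectory(st, u, amps, noise_sigma = 0.02, n_frames = nf,
                            seed = 22)
  b <- pca_modes(covariance_matrix(tr))
  vf <- variance_fractions(b)
  noise_tot <- 3 * n_atoms(st) * 0.02^2
  truth <- fr * tot / (tot + noise_tot)
  se <- truth * sqrt(2 / nf)
  expect_true(all(abs(vf[1:3] - truth) < 3 * se + 0.002))
  ang <- principal_angles(u, b$vectors[, 1:3])
  expect_lt(max(ang), 5)
  # subspace overlap
  expect_gt(min(svd(crossprod(u, b$vectors[, 1:3]))$d), 0.99)
})

test_that("projections have the eigenvalue variances and are uncorrelated", {
  st <- ca_chain(12)
  tr <- gen_mode_trajectory(st, random_modes(st, 2, seed = 31), c(1.2, 0.6),
                            noise_sigma = 0.05, n_frames = 800, seed = 32)
  cv <- covariance_matrix(tr)
  b <- pca_modes(cv)
  p <- project_modes(tr, b, 1:5)
  # projecting the mean gives zero
  pm <- project_modes(matrix(b$mean_coords, 1), b, 1:3)
  expect_equal(as.numeric(pm), rep(0, 3), tolerance = 1e-10)
  # population variance of p_k equals lambda_k
  nf <- nrow(p)
  for (k in 1:5)
    expect_equal(mean((p[, k] - mean(p[, k]))^2), b$values[k], tolerance = 1e-8)
  cors <- stats::cor(p)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-6)
  expect_error(project_modes(tr, b, k = 10000), "out of range")
  # recovered PC1 series tracks the planted mode amplitude
  z <- attr(tr, "z")
  expect_gt(abs(stats::cor(p[, 1], z[, 1])), 0.99)
})

test_that("combined ED is duplication-invariant and separates shifted systems", {
  st <- ca_chain(10)
  tr <- gen_mode_trajectory(st, random_modes(st, 2, seed = 41), c(1, 0.4),
                            noise_sigma = 0.05, n_frames = 300, seed = 42)
  single <- pca_modes(covariance_matrix(tr))
  both <- combined_ed(list(tr, tr), fit = FALSE)
  expect_equal(both$basis$values, single$values, tolerance = 1e-10)
  # pooled trace identity: pooled trace = mean of per-trajectory second
  # moments about the pooled mean
  m <- rbind(do.call(rbind, lapply(1:2, function(i) actdyn:::traj_matrix(tr))))
  mu <- colMeans(m)
  expect_equal(sum(both$basis$values),
               mean(rowSums(sweep(m, 2, mu)^2)), tolerance = 1e-8)

  # two systems jittering around means separated along a planted mode
  u <- random_modes(st, 1, seed = 43)
  stB <- st
  stB$xyz <- st$xyz + 3 * matrix(u, ncol = 3, byrow = TRUE)
  trA <- gen_mode_trajectory(st, u, 0.3, noise_sigma = 0.05, n_frames = 200,
                             seed = 44)
  trB <- gen_mode_trajectory(stB, u, 0.3, noise_sigma = 0.05, n_frames = 200,
                             seed = 45)
  ce <- combined_ed(list(trA, trB), reference = st$xyz)
  p1a <- ce$projections[[1]][, 1]
  p1b <- ce$projections[[2]][, 1]
  expect_true(max(p1a) < min(p1b) || max(p1b) < min(p1a))
  expect_equal(nrow(ce$projections[[1]]) + nrow(ce$projections[[2]]), 400L)
  expect_error(combined_ed(list(trA, trB), selections = list(1:10, 1:9)),
               "differ")
})

test_that("porcupine vectors encode per-atom mode amplitude and direction", {
  st <- ca_chain(15)
  u <- random_modes(st, 1, seed = 51)
  tr <- gen_mode_trajectory(st, u, 2, noise_sigma = 0.01, n_frames = 2000,
                            seed = 52)
  b <- pca_modes(covariance_matrix(tr))
  pq <- porcupine(b, 1, scale = 2)
  expect_equal(nrow(pq), 15L)
  v <- as.matrix(pq[, c("vx", "vy", "vz")])
  expect_equal(sqrt(sum(v^2)), 2 * sqrt(b$values[1]), tolerance = 1e-10)
  expect_true(all(porcupine(b, 1, scale = 0)[, 4:6] == 0))
  # parallel to planted displacements for atoms moving above the noise floor
  um <- matrix(u, ncol = 3, byrow = TRUE)
  amp <- sqrt(rowSums(um^2))
  big <- which(amp > 0.1)
  cosines <- abs(rowSums(v[big, ] * um[big, ])) /
    (sqrt(rowSums(v[big, ]^2)) * amp[big])
  expect_true(all(cosines > 0.99))
  expect_error(porcupine(b, 100), "out of range")
})
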