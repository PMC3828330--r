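test_that("generators are bit-reproducible under a fixed seed", {
  st <- ca_chain(10)
  u <- random_modes(st, 2, seed = 7)
  expect_identical(u, random_modes(st, 2, seed = 7))
  t1 <- gen_mode_trajectory(st, u, c(1, 0.5), noise_sigma = 0.1,
                            n_frames = 50, seed = 9)
  t2 <- gen_mode_trajectory(st, u, c(1, 0.5), noise_sigma = 0.1,
                            n_frames = 50, seed = 9)
  expect_identical(t1$coords, t2$coords)
  w1 <- gen_solvated_frames(st, 100, n_frames = 3, seed = 5)
  w2 <- gen_solvated_frames(st, 100, n_frames = 3, seed = 5)
  expect_identical(w1[[3]], w2[[3]])
  p1 <- gen_coupled_property(attr(t1, "z"), 1, beta = 2, noise_sigma = 1, seed = 4)
  p2 <- gen_coupled_property(attr(t1, "z"), 1, beta = 2, noise_sigma = 1, seed = 4)
  expect_identical(p1, p2)
  expect_identical(gen_chain(5, "helix")$xyz, gen_chain(5, "helix")$xyz)
})

test_that("mode trajectories honour their degenerate and error contracts", {
  st <- ca_chain(6)
  u <- random_modes(st, 1, seed = 1)
  static <- gen_mode_trajectory(st, u, 0, noise_sigma = 0, n_frames = 5, seed = 2)
  expect_equal(max(abs(static$coords[, , 1] - static$coords[, , 5])), 0)
  expect_equal(static$coords[, , 1], st$xyz)
  bad <- cbind(u, u)   # not orthonormal
  expect_error(gen_mode_trajectory(st, bad, c(1, 1)), "orthonormal")
  expect_error(gen_mode_trajectory(st, u, c(1, 2)), "one amplitude")
  expect_error(gen_mode_trajectory(st, cbind(c(u, 0, 0, 0)), 1), "3N")
})

test_that("planted statistics converge at the 3-SE level", {
  st <- ca_chain(15)
  u <- random_modes(st, 2, seed = 11)
  nf <- 5000
  tr <- gen_mode_trajectory(st, u, c(3, 1), noise_sigma = 0.1, n_frames = nf,
                            seed = 12)
  b <- pca_modes(covariance_matrix(tr))
  tot <- 9 + 1 + 3 * 15 * 0.01
  truth <- c(9, 1) / tot
  vf <- variance_fractions(b)
  se <- truth * sqrt(2 / nf)
  expect_lt(abs(vf[1] - truth[1]), 3 * se[1] + 0.003)
  expect_lt(abs(vf[2] - truth[2]), 3 * se[2] + 0.003)
})

test_that("coupled properties reach their designed correlation", {
  st <- ca_chain(10)
  u <- random_modes(st, 3, seed = 21)
  nf <- 5000
  tr <- gen_mode_trajectory(st, u, c(2, 1, 0.5), noise_sigma = 0.05,
                            n_frames = nf, seed = 22)
  b <- pca_modes(covariance_matrix(tr))
  p <- project_modes(tr, b, 1:5)
  # sigma = 0: perfect linear target
  f0 <- gen_coupled_property(p, 1, beta = 1.3, noise_sigma = 0)
  m0 <- fit_mcm(p, f0, split = floor(0.9 * nf))
  expect_equal(m0$r_build, 1, tolerance = 1e-10)
  # beta chosen for population r = 0.82
  sigma <- 1.0
  beta <- coupling_for_r(0.82, stats::var(p[, 1]), sigma)
  f <- gen_coupled_property(p, 1, beta = beta, noise_sigma = sigma, seed = 23)
  m <- fit_mcm(p, f, split = floor(0.9 * nf))
  expect_lt(abs(m$r_build - 0.82), 0.03)
})

test_that("solvated frames respect the box and weight contracts", {
  st <- ca_chain(5)
  expect_error(gen_solvated_frames(st, 100,
                                   hotspots = list(list(atom = 1, sigma = 1,
                                                        weight = 1.2))),
               "sum to at most 1")
  expect_error(gen_solvated_frames(st, 100,
                                   box = list(origin = c(0, 0, 0),
                                              lengths = c(5, 5, 5))),
               "8 Angstrom")
  w <- gen_solvated_frames(st, 500, n_frames = 4, seed = 31)
  box <- attr(w, "box")
  all_pts <- do.call(rbind, w)
  expect_true(all(sweep(all_pts, 2, box$origin) >= 0))
  expect_true(all(sweep(all_pts, 2, box$origin + box$lengths) <= 0))
  expect_equal(nrow(w[[1]]), 500L)
})

test_that("two-state trajectories place the switch where planted", {
  st <- ca_chain(6)
  open <- st$xyz
  closed <- st$xyz + 2
  expect_error(gen_two_state_trajectory(st, open, closed, switch_frame = 200,
                                        n_frames = 100), "switch_frame")
  tr <- gen_two_state_trajectory(st, open, closed, switch_frame = 6,
                                 noise = 0, n_frames = 10)
  vals <- apply(tr$coords, 3, function(f) mean(f))
  expect_equal(length(unique(round(vals, 12))), 2L)
  expect_equal(tr$coords[, , 5], open)
  expect_equal(tr$coords[, , 6], closed)
})

test_that("the mixed-geometry chain reproduces its intended fold census", {
  m <- gen_chain(60, "mixed")
  lay <- attr(m, "layout")
  ss <- assign_ss(m)
  expect_equal(length(ss), length(lay))
  expect_gte(mean(ss[lay == "E"] == "E"), 0.7)
  expect_gte(mean(ss[lay == "H"] == "H"), 0.7)
})
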