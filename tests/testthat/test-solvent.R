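solute_1atom <- function() {
  md_structure("CA", element = "C", resid = 1, resname = "ALA", chain = "A",
               xyz = matrix(0, 1, 3))
}

test_that("uniform bulk normalizes to g = 1 with the shell mean exactly 1", {
  st <- solute_1atom()
  w <- gen_solvated_frames(st, 3000, n_frames = 40, seed = 80)
  dm <- density_map(st$xyz, w, spacing = 1.0)
  shell <- dm$solute_dmin >= 6 & dm$solute_dmin <= 8
  expect_equal(mean(dm$values[shell]), 1, tolerance = 1e-12)   # by construction
  expect_equal(mean(dm$values), 1, tolerance = 0.1)
  # closure: all waters land in the grid
  expect_equal(sum(dm$raw_mean_counts), 3000, tolerance = 3000 * 1e-3)
  # doubling the waters doubles the bulk density but leaves g near 1
  w2 <- gen_solvated_frames(st, 6000, n_frames = 40, seed = 81)
  dm2 <- density_map(st$xyz, w2, spacing = 1.0)
  expect_equal(dm2$bulk_density / dm$bulk_density, 2, tolerance = 0.05)
  expect_equal(mean(dm2$values), 1, tolerance = 0.1)
})

test_that("a frozen point source produces the closed-form density spike", {
  st <- solute_1atom()
  n_bulk <- 2000; nf <- 25
  w <- gen_solvated_frames(st, n_bulk, n_frames = nf, seed = 82)
  spike <- c(3.25, 3.25, 3.25)
  w_spiked <- lapply(w, function(f) rbind(f, matrix(spike, 1, 3)))
  dm <- density_map(st$xyz, w_spiked, spacing = 0.5)
  ix <- floor((spike - dm$origin) / dm$spacing) + 1
  g_spike <- dm$values[ix[1], ix[2], ix[3]]
  # one guaranteed count per frame in that voxel, plus bulk background
  expected <- (1 / 0.5^3) / dm$bulk_density
  expect_equal(g_spike, expected, tolerance = 0.15)
  expect_gt(g_spike, 10)
})

test_that("normalization fails cleanly when the bulk shell is empty", {
  st <- solute_1atom()
  w <- list(matrix(runif(30, -2, 2), 10, 3))
  expect_error(density_map(st$xyz, w, spacing = 0.5, padding = 3),
               "bulk shell")
})

test_that("the map is invariant under rigid translation of the whole system", {
  st <- solute_1atom()
  w <- gen_solvated_frames(st, 800, n_frames = 5, seed = 83)
  dm <- density_map(st$xyz, w, spacing = 1.0)
  shift <- c(7.3, -2.1, 4.4)
  w_shift <- lapply(w, function(f) sweep(f, 2, shift, "+"))
  dm_shift <- density_map(sweep(st$xyz, 2, shift, "+"), w_shift, spacing = 1.0)
  expect_equal(dm_shift$values, dm$values, tolerance = 1e-12)
  expect_equal(dm_shift$origin, dm$origin + shift, tolerance = 1e-12)
})

test_that("hydration sites localize planted hotspots and respect the g > 1 rule", {
  # featureless map: no sites
  flat <- structure(list(origin = c(0, 0, 0), spacing = 1, dims = c(5, 5, 5),
                         values = array(1, c(5, 5, 5)), bulk_density = 1),
                    class = "density_map")
  expect_equal(nrow(hydration_sites(flat)), 0L)

  st <- gen_chain(4, "helix")
  hot_atom <- select_atoms(st, "name O and resid 2")[1]
  w <- gen_solvated_frames(st, 2500, n_frames = 30,
                           hotspots = list(list(atom = hot_atom, sigma = 0.5,
                                                weight = 0.05)),
                           seed = 84)
  heavy <- select_atoms(st, "heavy")
  dm <- density_map(st$xyz[heavy, , drop = FALSE], w, spacing = 0.5)
  sites <- hydration_sites(dm)
  expect_true(all(sites$g > 1))
  top <- as.numeric(sites[1, c("x", "y", "z")])
  expect_lt(sqrt(sum((top - st$xyz[hot_atom, ])^2)), sqrt(3) * dm$spacing)

  # two well-separated hotspots: the two top sites find both
  hot2 <- select_atoms(st, "name O and resid 4")[1]
  expect_gt(sqrt(sum((st$xyz[hot_atom, ] - st$xyz[hot2, ])^2)), 1.5)
  w2 <- gen_solvated_frames(st, 2500, n_frames = 30,
                            hotspots = list(
                              list(atom = hot_atom, sigma = 0.5, weight = 0.05),
                              list(atom = hot2, sigma = 0.5, weight = 0.05)),
                            seed = 85)
  dm2 <- density_map(st$xyz[heavy, , drop = FALSE], w2, spacing = 0.5)
  s2 <- hydration_sites(dm2)
  d_to <- function(site, atom) sqrt(sum((as.numeric(site[c("x", "y", "z")]) -
                                         st$xyz[atom, ])^2))
  dd <- cbind(c(d_to(s2[1, ], hot_atom), d_to(s2[2, ], hot_atom)),
              c(d_to(s2[1, ], hot2), d_to(s2[2, ], hot2)))
  expect_lt(max(apply(dd, 2, min)), sqrt(3) * dm2$spacing)

  # doubling a hotspot weight increases its g value
  w3 <- gen_solvated_frames(st, 2500, n_frames = 30,
                            hotspots = list(list(atom = hot_atom, sigma = 0.5,
                                                 weight = 0.10)),
                            seed = 84)
  dm3 <- density_map(st$xyz[heavy, , drop = FALSE], w3, spacing = 0.5)
  expect_gt(hydration_sites(dm3)$g[1], sites$g[1])
})

test_that("hydration scores follow the tapered-sum formula and its monotonicity", {
  st <- solute_1atom()
  # no sites: zero score
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      g = numeric(0))
  expect_equal(hydration_score(empty, st), 0)
  # one site of g = 2 at distance cutoff/2: score = 2 * 0.5
  site <- data.frame(x = 2.0, y = 0, z = 0, g = 2)
  expect_equal(hydration_score(site, st, cutoff = 4), 1.0)
  # monotone in distance and in density
  s_near <- data.frame(x = 1, y = 0, z = 0, g = 2)
  s_far <- data.frame(x = 3, y = 0, z = 0, g = 2)
  expect_gt(hydration_score(s_near, st), hydration_score(s_far, st))
  s_dense <- data.frame(x = 2, y = 0, z = 0, g = 5)
  expect_gt(hydration_score(s_dense, st), hydration_score(site, st))
  # outside the cutoff: zero
  s_out <- data.frame(x = 9, y = 0, z = 0, g = 10)
  expect_equal(hydration_score(s_out, st, cutoff = 4), 0)
})

test_that("hotspots planted at polar atoms raise their scores above apolar atoms", {
  st <- gen_chain(8, "helix")
  at <- st$atoms
  polar <- which(at$element %in% c("N", "O"))
  apolar <- which(at$element == "C")
  hs <- lapply(polar, function(i) list(atom = i, sigma = 0.5, weight = 0.025))
  w <- gen_solvated_frames(st, 4000, n_frames = 25, hotspots = hs, seed = 86)
  heavy <- select_atoms(st, "heavy")
  dm <- density_map(st$xyz[heavy, , drop = FALSE], w, spacing = 0.5)
  sites <- utils::head(hydration_sites(dm), 2 * length(polar))  # strongest sites
  scores <- hydration_score(sites, st, seq_len(n_atoms(st)))
  wt <- stats::wilcox.test(scores[polar], scores[apolar], alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
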