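# RDFs, coordination numbers, residue maps, nonbonded profiles.

make_gas <- function(n_a = 50, n_b = 20000, box = 5, n_frames = 50,
                     seed = 21) {
  top <- topology(name = c(rep("CA", n_a), rep("OW", n_b)),
                  res_id = seq_len(n_a + n_b),
                  res_name = c(rep("ALA", n_a), rep("HOH", n_b)),
                  chain = c(rep("A", n_a), rep("S", n_b)))
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    matrix(runif(3 * (n_a + n_b)) * box, ncol = 3)
  })
  list(top = top, traj = trajectory(frames, rep(box, 3)),
       sel_a = seq_len(n_a), sel_b = n_a + seq_len(n_b))
}

test_that("an ideal gas gives g(r) = 1 and the closed-form CN", {
  gas <- make_gas()
  rr <- rdf(gas$top, gas$traj, gas$sel_a, gas$sel_b, r_max = 2.25,
            bin_width = 0.05)
  win <- rr$r >= 0.3 & rr$r <= 0.45 * 5
  expect_true(all(abs(rr$g[win] - 1) < 0.02))
  cn <- coordination_number(rr, 0.8)
  cn_ideal <- 4 / 3 * pi * 0.8^3 * rr$density
  expect_lt(abs(cn / cn_ideal - 1), 0.01)
  # CN is non-decreasing in the cutoff
  cuts <- seq(0.2, 2.0, by = 0.2)
  cns <- sapply(cuts, coordination_number, rdf = rr)
  expect_true(all(diff(cns) >= 0))
  expect_error(coordination_number(rr, 3), "outside")
  expect_error(rdf(gas$top, gas$traj, gas$sel_a, gas$sel_b, r_max = 2.6),
               "half the smallest box")
})

test_that("CN by RDF integration matches direct pair counting", {
  gas <- make_gas(n_a = 20, n_b = 2000, n_frames = 20, seed = 8)
  rr <- rdf(gas$top, gas$traj, gas$sel_a, gas$sel_b, r_max = 1.5,
            bin_width = 0.01)
  r_cut <- 0.7
  cn <- coordination_number(rr, r_cut)
  # oracle: count neighbours directly on the same configurations
  direct <- mean(sapply(seq_along(gas$traj$frames), function(fi) {
    fr <- gas$traj$frames[[fi]]
    mean(sapply(gas$sel_a, function(a) {
      d <- minimum_image(sweep(fr[gas$sel_b, ], 2, fr[a, ]), rep(5, 3))
      sum(rowSums(d^2) <= r_cut^2)
    }))
  }))
  expect_lt(abs(cn - direct) / direct, 0.01)
})

test_that("a single fixed neighbour lands in its distance bin", {
  top <- topology(c("CA", "OW"), 1:2, c("ALA", "HOH"), c("A", "S"))
  fr <- rbind(c(2, 2, 2), c(2, 2, 2.5))
  tr <- trajectory(fr, c(6, 6, 6))
  rr <- rdf(top, tr, 1, 2, r_max = 1, bin_width = 0.02)
  expect_equal(sum(rr$counts), 1)
  expect_lt(abs(rr$r[which(rr$counts == 1)] - 0.5), 0.02 + 1e-9)
  # doubling the bin width conserves total counts
  rr2 <- rdf(top, tr, 1, 2, r_max = 1, bin_width = 0.04)
  expect_equal(sum(rr2$counts), sum(rr$counts))
})

test_that("first_minimum finds the constructed minimum and rejects flat g", {
  r <- seq(0.005, 1, by = 0.005)
  g <- 1 + exp(-(r - 0.3)^2 / 0.002) - 0.5 * exp(-(r - 0.5)^2 / 0.002)
  fake <- structure(list(r = r, g = g, density = 1, counts = g,
                         bin_width = 0.005), class = "rdf_result")
  expect_lt(abs(first_minimum(fake) - 0.5), 0.005 + 1e-9)
  # smoothing a noiseless curve does not move the minimum
  expect_equal(first_minimum(fake, smooth_window = 3), first_minimum(fake),
               tolerance = 0.005)
  flat <- structure(list(r = r, g = rep(1, length(r)), density = 1,
                         counts = r, bin_width = 0.005),
                    class = "rdf_result")
  expect_error(first_minimum(flat), "monotone|no interior")
})

test_that("hydration and urea maps recover the generator's profiles", {
  targets <- rbind(
    matrix(rep(c(2, 3, 4, 5), each = 1), nrow = 1)[rep(1, 11), ])
  seps <- c(0.9, 1.4, 2.0, 2.7)
  scenes <- lapply(seq_along(seps), function(i) {
    build_dimer_scene(dimer_scene_spec(
      com_separation = seps[i], water_targets = targets[, i],
      urea_targets = rep(i - 1, 11), seed = 300 + i))
  })
  wmap <- scene_series_map(scenes, "water", normalize = "water_max")
  expect_equal(unname(wmap$values),
               matrix(rep(c(0.4, 0.6, 0.8, 1.0), each = 11), nrow = 11))
  umap <- scene_series_map(scenes, "urea", normalize = "own_max")
  expect_true(all(umap$values <= 1 + 1e-12))
  expect_equal(unname(umap$values[, 4]), rep(1, 11))
  raw <- scene_series_map(scenes, "urea", normalize = "none")
  expect_equal(unname(raw$values[1, ]), c(0, 1, 2, 3))
})

test_that("maps are invariant under rotation and chain relabelling", {
  sc <- build_dimer_scene(dimer_scene_spec(
    1.6, water_targets = c(5, 4, 3, 2, 3, 4, 5, 4, 3, 2, 5), seed = 77))
  base <- hydration_map(sc$topology, sc$trajectory, 1.6, normalize = "none")
  box <- sc$trajectory$box[1, ]
  q <- random_rotation(3)
  ctr <- matrix(box / 2, nrow(sc$trajectory$frames[[1]]), 3, byrow = TRUE)
  rot <- (sc$trajectory$frames[[1]] - ctr) %*% q + ctr
  mrot <- hydration_map(sc$topology, trajectory(rot, box), 1.6,
                        normalize = "none")
  expect_equal(mrot$values, base$values)
  # relabel chains A <-> B
  top2 <- sc$topology
  top2$chain[top2$chain == "A"] <- "Z"
  top2$chain[top2$chain == "B"] <- "A"
  top2$chain[top2$chain == "Z"] <- "B"
  class(top2) <- c("topology", "data.frame")
  mswap <- hydration_map(top2, sc$trajectory, 1.6, normalize = "none")
  expect_equal(mswap$values, base$values)
})

test_that("O-N neighbour maps count constructed interchain contacts", {
  n_res <- 8
  coords <- default_backbone_coords(n_res)
  # three contacts incident to residue 5 of each chain, one to residue 6;
  # the cluster sits at y = 7.5, far from every default backbone atom
  coords[["A.5.O"]] <- c(3.0, 7.5, 5.0)
  coords[["B.5.N"]] <- c(3.0, 7.5, 5.30)    # O(A5)-N(B5)
  coords[["B.6.N"]] <- c(3.2, 7.5, 5.25)    # O(A5)-N(B6), d = 0.3202
  coords[["A.5.N"]] <- c(2.6, 7.5, 5.0)
  coords[["B.5.O"]] <- c(2.6, 7.5, 5.30)    # N(A5)-O(B5)
  coords[["A.6.N"]] <- c(2.8, 7.5, 5.55)    # N(A6)-O(B5), d = 0.3202
  fix <- make_backbone_pair(n_res, coords)
  m <- on_neighbor_map(fix$topology, fix$trajectory, xi = 1.0)
  expected <- rep(0, n_res); expected[5] <- 3; expected[6] <- 1
  expect_equal(unname(m$values[, 1]), expected)
  # all distances beyond the cutoff: zero map
  far <- make_backbone_pair(n_res, default_backbone_coords(n_res))
  m0 <- on_neighbor_map(far$topology, far$trajectory, xi = 1.0)
  expect_true(all(m0$values == 0))
  # a pair at exactly 0.35 nm counts (the criterion is r <= 3.5 A)
  cb <- default_backbone_coords(n_res)
  cb[["A.2.O"]] <- c(2.5, 7.5, 5.0)
  cb[["B.2.N"]] <- c(2.5, 7.5, 5.35)
  mb <- on_neighbor_map(make_backbone_pair(n_res, cb)$topology,
                        make_backbone_pair(n_res, cb)$trajectory, xi = 1.0)
  expect_equal(unname(mb$values[2, 1]), 1)
  # single chain errors
  solo <- subset_atoms(far$topology, far$trajectory,
                       select_atoms(far$topology, chain = "A"))
  expect_error(on_neighbor_map(solo$topology, solo$trajectory, xi = 1),
               "two peptide chains")
})

test_that("nonbonded energies match Coulomb and LJ closed forms", {
  expect_equal(lj_coulomb_energy(1.0, qi = 1, qj = -1, eps = 0), -138.935)
  expect_equal(lj_coulomb_energy(0.3, eps = 2, sigma = 0.3), 0)
  expect_equal(lj_coulomb_energy(2^(1 / 6) * 0.3, eps = 2, sigma = 0.3), -2)
  # profile on a two-atom toy dimer
  top <- topology(c("CA", "CA"), c(1, 1), "ALA", c("A", "B"))
  tr <- trajectory(rbind(c(2, 2, 2), c(2, 2, 3)), c(10, 10, 10))
  prof <- nonbonded_energy_profile(top, tr, xi = 1.0,
                                   charges = c(1, -1), lj_eps = c(0, 0),
                                   lj_sigma = c(0.3, 0.3))
  expect_equal(prof$energy, -138.935)
  expect_error(nonbonded_energy_profile(top, tr, 1.0, charges = c(1, NA),
                                        lj_eps = c(0, 0),
                                        lj_sigma = c(0.3, 0.3)),
               "missing nonbonded parameters")
})
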