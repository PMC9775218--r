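# Generators: biased sampling, dimer scenes, Crooks work samples, motifs.

test_that("harmonic-plus-bias sampling matches the closed-form Gaussian", {
  pot <- analytic_potential("harmonic", k = 10)
  n <- 5e4
  x <- sample_biased_window(pot, bias_center = 0.5, bias_k = 100, n = n,
                            seed = 7)
  mu <- 100 * 0.5 / 110
  v <- 1 / 110
  expect_lt(abs(mean(x) - mu), 3 * sqrt(v / n))
  expect_lt(abs(var(x) - v), 3 * v * sqrt(2 / (n - 1)))
  # determinism: same seed, same stream; different seed, different stream
  expect_identical(x, sample_biased_window(pot, 0.5, 100, n, seed = 7))
  expect_false(identical(x, sample_biased_window(pot, 0.5, 100, n, seed = 8)))
})

test_that("zero bias on a flat tabulated potential gives uniform samples", {
  flat <- analytic_potential("tabulated", x = seq(0, 1, 0.1), y = rep(0, 11))
  u <- sample_biased_window(flat, 0.5, 0, 2e4, seed = 3)
  expect_true(all(u >= 0 & u <= 1))
  h <- hist(u, breaks = seq(0, 1, 0.1), plot = FALSE)
  chi2 <- sum((h$counts - 2000)^2 / 2000)
  expect_lt(chi2, qchisq(0.99, df = 9))
})

test_that("Langevin sampling of a double well is stationary and symmetric", {
  pot <- analytic_potential("double_well", a = 2, b = 0.8)
  x <- sample_biased_window(pot, 0, 0, 1e5, seed = 11)
  # symmetric wells: equal occupancy
  expect_lt(abs(mean(x > 0) - 0.5), 0.02)
  # Kolmogorov-Smirnov against the numerically normalised Boltzmann density
  grid <- seq(min(x) - 0.5, max(x) + 0.5, length.out = 8001)
  dens <- exp(-pot$u(grid))
  cdf <- cumsum(dens) / sum(dens)
  ks <- suppressWarnings(
    ks.test(x, approxfun(grid, cdf, yleft = 0, yright = 1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("non-finite potential at the start point is rejected", {
  bad <- analytic_potential("tabulated", x = c(0, 1), y = c(Inf, Inf))
  expect_error(sample_biased_window(bad, 0.5, 10, 10, seed = 1),
               "not finite")
})

test_that("work samples have the prescribed moments and obey Crooks", {
  ws <- generate_work_samples(work_sample_spec(2, 1, 1e4, 1e4, seed = 5))
  # forward mean is dG + sigma^2/2 by construction
  expect_lt(abs(mean(ws$forward) - 2.5), 3 / sqrt(1e4))
  expect_lt(abs(mean(ws$reverse) - (-1.5)), 3 / sqrt(1e4))
  # direct Crooks check: ln P_f(W)/P_r(-W) regressed on W has slope 1,
  # intercept -dG
  br <- seq(-1, 5, by = 0.25)
  hf <- hist(ws$forward[ws$forward > -1 & ws$forward < 5], breaks = br,
             plot = FALSE)
  hr <- hist(-ws$reverse[-ws$reverse > -1 & -ws$reverse < 5], breaks = br,
             plot = FALSE)
  ok <- hf$counts >= 10 & hr$counts >= 10
  y <- log(hf$counts[ok] / hr$counts[ok])
  # per-bin variance of the log count ratio is ~ 1/n_f + 1/n_r
  wts <- 1 / (1 / hf$counts[ok] + 1 / hr$counts[ok])
  fit <- lm(y ~ hf$mids[ok], weights = wts)
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[2] - 1), 3 * se[2])
  expect_lt(abs(coef(fit)[1] - (-2)), 3 * se[1])
})

test_that("vanishing work spread collapses all samples onto zero", {
  ws <- generate_work_samples(work_sample_spec(0, 1e-8, 10, 10, seed = 1))
  expect_lt(max(abs(c(ws$forward, ws$reverse))), 1e-6)
})

test_that("dimer scenes honour COM separation and exact shell counts", {
  targets <- c(5, 4, 3, 2, 3, 4, 5, 4, 3, 2, 5)
  spec <- dimer_scene_spec(com_separation = 2.7, water_targets = targets,
                           urea_targets = rep(1, 11), glycine_residues = 6,
                           seed = 42)
  sc <- build_dimer_scene(spec)
  selA <- select_atoms(sc$topology, chain = "A")
  selB <- select_atoms(sc$topology, chain = "B")
  d <- com_distance(sc$topology, sc$trajectory$frames[[1]], selA, selB,
                    sc$trajectory$box[1, ])
  expect_lt(abs(d - 2.7), 1e-6)
  m <- hydration_map(sc$topology, sc$trajectory, xi = 2.7,
                     normalize = "none")
  expect_equal(unname(m$values[, 1]), targets)
  mu <- hydration_map(sc$topology, sc$trajectory, xi = 2.7, solvent = "urea",
                      normalize = "none")
  expect_equal(unname(mu$values[, 1]), rep(1, 11))
  # determinism and seed sensitivity with invariant counts
  sc2 <- build_dimer_scene(spec)
  expect_identical(sc$trajectory$frames[[1]], sc2$trajectory$frames[[1]])
  spec2 <- spec; spec2$seed <- 43L
  sc3 <- build_dimer_scene(spec2)
  expect_false(identical(sc$trajectory$frames[[1]],
                         sc3$trajectory$frames[[1]]))
  m3 <- hydration_map(sc3$topology, sc3$trajectory, xi = 2.7,
                      normalize = "none")
  expect_equal(m3$values, m$values)
})

test_that("impossible solvent placement raises a capacity error", {
  # nearly coincident chains: every point of one shell lies in another
  spec <- dimer_scene_spec(com_separation = 1e-9, n_residues = 2,
                           water_targets = c(1, 1), seed = 1)
  expect_error(build_dimer_scene(spec), "capacity")
  expect_error(dimer_scene_spec(2.0, box = c(1, 1, 1)), "box too small")
  expect_error(dimer_scene_spec(2.0, water_targets = c(-1)), ">= 0")
})

test_that("motif fixtures realise the requested hydrogen-bond pattern", {
  fb <- generate_secondary_structure_fixture("beta_pair", 6)
  hb <- backbone_hbonds(fb$topology, fb$trajectory$frames[[1]])
  # doubly hydrogen-bonded inter-strand ladder on every residue pair
  inter <- hb[hb$acceptor_chain != hb$donor_chain, ]
  expect_equal(nrow(inter), 12)
  # antiparallel pairing: residue i bonds residue n + 1 - i
  expect_true(all(inter$acceptor_res + inter$donor_res == 7))
  expect_true(all(inter$energy < -0.5))

  fg <- generate_secondary_structure_fixture("helix_310", 6)
  hg <- backbone_hbonds(fg$topology, fg$trajectory$frames[[1]])
  expect_equal(sort(hg$donor_res - hg$acceptor_res), rep(3, 3))
  expect_true(all(hg$energy < -0.5))

  fc <- generate_secondary_structure_fixture("coil", 6)
  hc <- backbone_hbonds(fc$topology, fc$trajectory$frames[[1]])
  expect_equal(nrow(hc), 0)

  expect_error(generate_secondary_structure_fixture("pi_helix", 6))
})
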