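# Radius of gyration and DSSP-lite classification.

test_that("radius of gyration matches closed forms", {
  n <- 12
  top <- topology(rep("CA", n), seq_len(n), "ALA", "A")
  # coincident atoms
  tr0 <- trajectory(matrix(1, n, 3), c(10, 10, 10))
  expect_equal(radius_of_gyration(top, tr0), 0)
  # two equal masses 0.2 nm apart: Rg = 0.1 nm
  top2 <- topology(c("CA", "CA"), 1:2, "ALA", "A")
  tr2 <- trajectory(rbind(c(0, 0, 0), c(0.2, 0, 0)), c(10, 10, 10))
  expect_equal(radius_of_gyration(top2, tr2), 0.1)
  # N equal masses on a ring of radius rho: Rg = rho
  rho <- 0.7
  ang <- 2 * pi * seq_len(n) / n
  ring <- cbind(rho * cos(ang), rho * sin(ang), 0)
  expect_equal(radius_of_gyration(top, trajectory(ring, c(10, 10, 10))), rho)
  expect_error(radius_of_gyration(top, tr0, integer(0)), "empty selection")
})

test_that("Rg is invariant under rigid rotation and translation", {
  sc <- build_dimer_scene(dimer_scene_spec(1.4, seed = 3))
  sel <- select_atoms(sc$topology, chain = "A")
  base <- radius_of_gyration(sc$topology, sc$trajectory, sel)
  for (seed in 1:5) {
    q <- random_rotation(seed)
    fr <- sc$trajectory$frames[[1]] %*% q +
      matrix(runif(3), nrow(sc$trajectory$frames[[1]]), 3, byrow = TRUE)
    tr <- trajectory(fr, sc$trajectory$box[1, ])
    expect_equal(radius_of_gyration(sc$topology, tr, sel), base,
                 tolerance = 1e-10)
  }
})

test_that("Rg distributions are normalised densities", {
  d <- rg_distribution(rep(0.8, 100), bin_width = 0.02)
  expect_equal(sum(d$density > 0), 1)
  expect_equal(max(d$density), 1 / 0.02)
  set.seed(2)
  s <- rnorm(2e4, 0.9, 0.05)
  d2 <- rg_distribution(s, bin_width = 0.005)
  expect_equal(sum(d2$density) * 0.005, 1, tolerance = 1e-9)
  mu <- sum(d2$rg * d2$density) * 0.005
  expect_lt(abs(mu - 0.9), 3 * 0.05 / sqrt(2e4) + 0.005)
})

test_that("Kabsch-Sander energy matches direct arithmetic", {
  # collinear ideal geometry, coordinates in nm
  e <- kabsch_sander_energy(C = c(-0.124, 0, 0), O = c(0, 0, 0),
                            N = c(0.29, 0, 0), H = c(0.19, 0, 0))
  expect_equal(e, 27.888 * (1 / 2.9 + 1 / 3.14 - 1 / 1.9 - 1 / 4.14),
               tolerance = 1e-6)
  expect_equal(e, -2.916, tolerance = 1e-3)
  # brute-force re-evaluation on random geometries
  set.seed(5)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 0.3), 4)
    dd <- function(a, b) sqrt(sum((p[a, ] - p[b, ])^2)) * 10  # nm -> A
    ref <- 27.888 * (1 / dd(2, 3) + 1 / dd(1, 4) - 1 / dd(2, 4) -
                       1 / dd(1, 3))
    expect_equal(kabsch_sander_energy(p[1, ], p[2, ], p[3, ], p[4, ]), ref,
                 tolerance = 1e-9)
  }
  expect_error(kabsch_sander_energy(c(0, 0, 0), c(0.001, 0, 0),
                                    c(0.002, 0, 0), c(0.003, 0, 0)),
               "coincident")
})

test_that("motif fixtures are classified as their motifs", {
  fb <- generate_secondary_structure_fixture("beta_pair", 6)
  sb <- assign_secondary_structure(fb$topology, fb$trajectory$frames[[1]])
  expect_true(all(sb$class == "E"))
  fg <- generate_secondary_structure_fixture("helix_310", 6)
  sg <- assign_secondary_structure(fg$topology, fg$trajectory$frames[[1]])
  expect_equal(ss_string(sg)[["A"]], "CGGGGC")
  fc <- generate_secondary_structure_fixture("coil", 6)
  sc <- assign_secondary_structure(fc$topology, fc$trajectory$frames[[1]])
  expect_true(all(sc$class == "C"))
})

test_that("classification is invariant under chain order", {
  fb <- generate_secondary_structure_fixture("beta_pair", 5)
  n <- nrow(fb$topology)
  ordb <- order(fb$topology$chain != "B")   # chain B first
  top2 <- fb$topology[ordb, ]
  class(top2) <- c("topology", "data.frame")
  fr2 <- fb$trajectory$frames[[1]][ordb, ]
  s1 <- assign_secondary_structure(fb$topology, fb$trajectory$frames[[1]])
  s2 <- assign_secondary_structure(top2, fr2)
  key <- function(s) s$class[order(s$chain, s$res_id)]
  expect_identical(key(s1), key(s2))
})

test_that("missing amide hydrogens are reconstructed from the backbone", {
  fb <- generate_secondary_structure_fixture("beta_pair", 6)
  keep <- which(fb$topology$name != "H")
  sub <- subset_atoms(fb$topology, fb$trajectory, keep)
  s <- assign_secondary_structure(sub$topology, sub$trajectory$frames[[1]])
  # residue 1 of each chain has no preceding C, cannot donate, so it and
  # its antiparallel partner (residue 6 of the other chain) lose their
  # doubly hydrogen-bonded bridge; the interior ladder survives on
  # reconstructed hydrogens alone
  for (ch in c("A", "B")) {
    cls <- s$class[s$chain == ch]
    expect_equal(cls[2:5], rep("E", 4))
    expect_equal(cls[c(1, 6)], c("C", "C"))
  }
})

test_that("secondary-structure fractions partition to one per xi", {
  fb <- generate_secondary_structure_fixture("beta_pair", 6)
  f1 <- fb$trajectory$frames[[1]]
  f2 <- f1
  selB <- select_atoms(fb$topology, chain = "B")
  f2[selB, 3] <- f2[selB, 3] + 3      # pull strands apart: no H-bonds
  tr <- trajectory(list(f1, f2, f2), pmax(fb$trajectory$box[1, ], 8))
  prof <- ss_fraction_profile(fb$topology, tr, xi = c(0.5, 0.5, 2.0))
  expect_equal(rowSums(prof[, c("E", "G", "H", "T", "C")]), c(1, 1))
  # xi = 0.5 pools one beta frame and one coil frame: E fraction 1/2
  expect_equal(prof$E[prof$xi == 0.5], 0.5)
  expect_equal(prof$C[prof$xi == 2.0], 1.0)
})
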