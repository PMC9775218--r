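# WHAM, entropy correction, tail shift, bootstrap, binding depth.

test_that("a single unbiased window reduces to -kT ln(histogram)", {
  set.seed(9)
  xi <- rnorm(1e5, 0, sqrt(1 / 10))        # exp(-U), U = 1/2 * 10 * xi^2
  prof <- wham(umbrella_window(0, 0, xi), bin_width = 0.01)
  h <- hist(xi, breaks = seq(floor(min(xi) / 0.01) * 0.01,
                             ceiling(max(xi) / 0.01) * 0.01 + 0.005,
                             by = 0.01), plot = FALSE)
  ref <- -kT_kJmol(298) * log(h$counts[h$counts > 0])
  dev <- prof$w - ref
  expect_lt(max(abs(dev - mean(dev))), 1e-9)
  # and the histogram estimate recovers the analytic potential
  fit <- pmf_rms_kt(prof, harmonic_reference_kt, min_count = 30)
  expect_lt(fit$rms, 0.1)
})

test_that("WHAM is invariant under window permutation and splitting", {
  pot <- analytic_potential("harmonic", k = 10)
  wins <- lapply(1:7, function(i) {
    sample_umbrella_window(pot, -0.6 + 0.2 * i, 50, 2000, seed = i)
  })
  a <- wham(wins, 0.02)
  b <- wham(rev(wins), 0.02)
  expect_equal(a$xi, b$xi)
  expect_lt(max(abs(a$w - b$w)), 1e-9)
  # split one window's samples into two windows with the same bias
  sp <- wins
  s <- sp[[4]]
  sp[[4]] <- umbrella_window(s$center, s$k, s$samples[1:1000])
  sp[[8]] <- umbrella_window(s$center, s$k, s$samples[1001:2000])
  cc <- wham(sp, 0.02)
  expect_lt(max(abs(a$w - cc$w)), 1e-9)
  # two identical windows get identical offsets
  dup <- wham(list(wins[[3]], wins[[3]]), 0.02)
  expect_lt(abs(diff(dup$f_offsets)), 1e-9)
})

test_that("disconnected windows and non-convergence raise typed errors", {
  w1 <- umbrella_window(0, 5000, rnorm(100, 0, 0.01))
  w2 <- umbrella_window(5, 5000, rnorm(100, 5, 0.01))
  expect_error(wham(list(w1, w2), 0.01), "disconnected")
  pot <- analytic_potential("harmonic", k = 10)
  wins <- lapply(1:3, function(i) {
    sample_umbrella_window(pot, -0.2 + 0.2 * i, 50, 500, seed = i)
  })
  expect_error(wham(wins, 0.02, tol = 1e-12, max_iter = 2), "converge")
  expect_error(wham(list(w1, umbrella_window(0, 5000, 0.01,
                                             temperature = 310))),
               "temperature")
})

test_that("entropy correction adds exactly 2RT ln(xi)", {
  prof <- new_profile_for_test(xi = c(0.5, 1, 2), w = c(0, 0, 0))
  out <- entropy_correct(prof, temperature = 298)
  expect_equal(out$w[2], 0)                                   # ln 1 = 0
  expect_equal(out$w[3], 2 * 0.0083144621 * 298 * log(2))     # 3.435
  expect_equal(out$w[3], 3.435, tolerance = 1e-4)
  expect_lt(out$w[1], 0)
  # monotone in xi
  expect_true(all(diff(out$w - prof$w) > 0))
  bad <- new_profile_for_test(xi = c(-0.1, 0.5), w = c(0, 0))
  expect_error(entropy_correct(bad), "xi > 0")
})

test_that("tail shift zeroes the tail mean, idempotently, affinely", {
  prof <- new_profile_for_test(xi = seq(0.1, 2, by = 0.1),
                               w = rep(4.2, 20))
  s <- shift_to_zero_tail(prof, 0.25)
  expect_equal(s$w, rep(0, 20))
  prof2 <- new_profile_for_test(xi = seq(0.1, 2, by = 0.1),
                                w = sin(1:20) + 4.2)
  s1 <- shift_to_zero_tail(prof2, 0.2)
  s2 <- shift_to_zero_tail(s1, 0.2)
  expect_equal(s1$w, s2$w)
  expect_equal(mean(tail(s1$w, 4)), 0)
  expect_equal(diff(s1$w), diff(prof2$w))
  # last-point variant
  sl <- shift_to_zero_tail(prof2, use_last_point = TRUE)
  expect_equal(tail(sl$w, 1), 0)
})

test_that("bootstrap errors are seed-stable and shrink with sampling", {
  pot <- analytic_potential("harmonic", k = 10)
  mk <- function(n) lapply(1:7, function(i) {
    sample_umbrella_window(pot, -0.6 + 0.2 * i, 50, n, seed = 100 + i)
  })
  small <- mk(300); big <- mk(3000)
  b1 <- bayesian_bootstrap(small, 0.02, n_boot = 30, seed = 4,
                           entropy = FALSE)
  b2 <- bayesian_bootstrap(small, 0.02, n_boot = 30, seed = 4,
                           entropy = FALSE)
  expect_identical(b1$err, b2$err)
  b3 <- bayesian_bootstrap(big, 0.02, n_boot = 30, seed = 4, entropy = FALSE)
  common_small <- b1$xi %in% b3$xi
  common_big <- b3$xi %in% b1$xi
  expect_lt(median(b3$err[common_big]), median(b1$err[common_small]))
})

test_that("binding depth finds the global minimum with the tie rule", {
  p1 <- new_profile_for_test(xi = seq(0.5, 2.5, by = 0.1),
                             w = seq(0.5, 2.5, by = 0.1)^2, shifted = TRUE)
  bd <- binding_depth(p1)
  expect_equal(bd$xi_min, 0.5)
  expect_true(bd$repulsive)
  # exact tie resolves toward smaller xi
  p2 <- new_profile_for_test(xi = c(0.5, 1.0, 1.5, 2.0, 2.5),
                             w = c(1, -2, 1, -2, 0), shifted = TRUE)
  expect_equal(binding_depth(p2)$xi_min, 1.0)
  expect_false(binding_depth(p2)$repulsive)
  expect_warning(binding_depth(new_profile_for_test(c(1, 2), c(0, 1))),
                 "gauge")
})
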