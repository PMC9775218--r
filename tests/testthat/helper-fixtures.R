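# Shared fixtures, memoised so expensive sampling runs once per session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The 21-window harmonic umbrella fixture: U = 1/2 * 10 * xi^2 (kT),
# centres -1..1 nm step 0.1, bias 100 kT/nm^2, exact Gaussian sampling.
harmonic_fixture <- function(n_per = 5000, seed = 1) {
  memo(sprintf("harm_%d_%d", n_per, seed), function() {
    pot <- analytic_potential("harmonic", k = 10)
    centers <- seq(-1, 1, by = 0.1)
    lapply(seq_along(centers), function(i) {
      sample_umbrella_window(pot, centers[i], 100, n_per,
                             seed = seed * 1000 + i)
    })
  })
}

harmonic_reference_kt <- function(xi) 0.5 * 10 * xi^2

# Count-weighted RMS (in kT) between a profile and the analytic reference,
# after removing the arbitrary additive constant; bins below the count
# threshold are estimator-starved and excluded.
pmf_rms_kt <- function(profile, ref_fun, min_count = 10) {
  kT <- kT_kJmol(profile$temperature)
  keep <- profile$n_eff >= min_count
  r <- profile$w[keep] / kT - ref_fun(profile$xi[keep])
  shift <- sum(r * profile$n_eff[keep]) / sum(profile$n_eff[keep])
  list(rms = sqrt(mean((r - shift)^2)), shift = shift, keep = keep)
}

# Hand-built PMF profiles for the correction/shift/depth unit tests.
new_profile_for_test <- function(xi, w, shifted = FALSE) {
  pmfsolv:::new_pmf_profile(xi = xi, w = w, err = rep(NA_real_, length(w)),
                            n_eff = rep(100, length(w)), temperature = 298,
                            shifted = shifted)
}

# Minimal two-chain backbone topology (N, CA, C, O per residue) with
# coordinates supplied by the caller as a list keyed by "chain.res.atom".
make_backbone_pair <- function(n_res, coords, box = c(20, 20, 20)) {
  nm <- c("N", "CA", "C", "O")
  name <- rep(nm, times = 2 * n_res)
  res <- rep(rep(seq_len(n_res), each = length(nm)), times = 2)
  chain <- rep(c("A", "B"), each = n_res * length(nm))
  top <- topology(name = name, res_id = res, res_name = "ALA", chain = chain)
  xyz <- matrix(NA_real_, nrow = nrow(top), ncol = 3)
  for (i in seq_len(nrow(top))) {
    key <- paste(top$chain[i], top$res_id[i], top$name[i], sep = ".")
    xyz[i, ] <- coords[[key]]
  }
  stopifnot(!anyNA(xyz))
  list(topology = top, trajectory = trajectory(xyz, box))
}

# Default backbone coordinates: two straight chains along x (spacing dx nm)
# separated by `gap` nm in z; O and N beads offset slightly so nothing is
# within contact range unless a test moves it.
default_backbone_coords <- function(n_res, dx = 0.8, gap = 1.5) {
  coords <- list()
  for (ch in c("A", "B")) {
    z <- if (ch == "A") 5 else 5 + gap
    for (r in seq_len(n_res)) {
      x <- 2 + (r - 1) * dx
      coords[[paste(ch, r, "N", sep = ".")]] <- c(x - 0.12, 5, z)
      coords[[paste(ch, r, "CA", sep = ".")]] <- c(x, 5, z)
      coords[[paste(ch, r, "C", sep = ".")]] <- c(x + 0.12, 5, z)
      coords[[paste(ch, r, "O", sep = ".")]] <- c(x + 0.12, 5.12, z)
    }
  }
  coords
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
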