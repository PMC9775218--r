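#' Synthetic ground-truth generators
#'
#' Every downstream estimator in this package (WHAM, BAR, solvation maps,
#' secondary structure) is validated against synthetic inputs with known
#' answers: biased samples from an analytic 1-D potential, bead-peptide
#' dimer scenes with exactly controlled first-shell solvent counts, work
#' samples obeying the Crooks fluctuation relation, and idealised backbone
#' motifs carrying a prescribed hydrogen-bond pattern.
#'
#' @name toy_system
NULL

# Run expr with a local RNG stream; global .Random.seed is untouched.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Analytic 1-D free-energy potentials (in kT, coordinate in nm)
#'
#' Forms: `harmonic` U = k/2 (x - center)^2; `double_well`
#' U = a (x^2 - b^2)^2; `tabulated` (cubic-spline interpolation of (x, y)
#' nodes, infinite outside the tabulated range, i.e. reflecting walls for
#' the Langevin sampler).
#'
#' @param form one of "harmonic", "double_well", "tabulated"
#' @param k,center harmonic parameters (kT/nm^2, nm)
#' @param a,b double-well parameters (kT/nm^4, nm)
#' @param x,y tabulated nodes (nm, kT)
#' @return an `analytic_potential` with elements `u(x)`, `du(x)` and
#'   `range` (NULL when unbounded)
#' @export
analytic_potential <- function(form = c("harmonic", "double_well", "tabulated"),
                               k = 1, center = 0, a = 1, b = 1,
                               x = NULL, y = NULL) {
  form <- match.arg(form)
  pot <- switch(form,
    harmonic = {
      stopifnot(k >= 0)
      list(u = function(xi) 0.5 * k * (xi - center)^2,
           du = function(xi) k * (xi - center),
           range = NULL, params = list(k = k, center = center))
    },
    double_well = {
      stopifnot(a > 0, b > 0)
      list(u = function(xi) a * (xi^2 - b^2)^2,
           du = function(xi) 4 * a * xi * (xi^2 - b^2),
           range = NULL, params = list(a = a, b = b))
    },
    tabulated = {
      stopifnot(!is.null(x), !is.null(y), length(x) == length(y),
                length(x) >= 2, !is.unsorted(x))
      sf <- stats::splinefun(x, y, method = "natural")
      rng <- range(x)
      list(u = function(xi) ifelse(xi < rng[1] | xi > rng[2], Inf, sf(xi)),
           du = function(xi) sf(xi, deriv = 1),
           range = rng, params = list(x = x, y = y))
    })
  pot$form <- form
  class(pot) <- "analytic_potential"
  pot
}

biased_u <- function(potential, bias_center, bias_k) {
  function(xi) potential$u(xi) + 0.5 * bias_k * (xi - bias_center)^2
}

# dt such that dt * max|U''| <= 0.01 (probed numerically over the sampled
# range); overdamped Euler-Maruyama with reflecting walls for bounded
# potentials. Burn-in is 10x the local relaxation time; retained samples are
# spaced 3 relaxation times apart across parallel independent walkers, so
# residual autocorrelation is negligible.
langevin_sample <- function(potential, bias_center, bias_k, n, seed) {
  rng <- potential$range
  probe <- if (!is.null(rng)) {
    seq(rng[1], rng[2], length.out = 201)
  } else {
    w <- if (bias_k > 0) 4 / sqrt(bias_k) else 4
    ctr <- if (potential$form == "double_well")
      c(-potential$params$b, potential$params$b) else bias_center
    seq(min(ctr) - w, max(ctr) + w, length.out = 201)
  }
  utot <- biased_u(potential, bias_center, bias_k)
  uvals <- utot(probe)
  if (!any(is.finite(uvals)))
    stop("potential not finite over the sampling range")
  # restrict to the thermally accessible region (within 15 kT of the
  # minimum): the step-size bound only needs to hold where walkers go
  acc <- is.finite(uvals) & uvals <= min(uvals, na.rm = TRUE) + 15
  probe <- seq(min(probe[acc]), max(probe[acc]), length.out = 201)
  h <- diff(probe[1:2])
  uvals <- utot(probe)
  upp <- abs(diff(diff(uvals)) / h^2)
  upp <- upp[is.finite(upp)]
  kmax <- max(c(upp, bias_k, 1))
  dt <- 0.01 / kmax
  # relaxation time (steps) from the curvature at the dominant minimum
  i_min <- which.min(uvals)
  k_well <- if (i_min > 1 && i_min < length(uvals)) {
    abs((uvals[i_min - 1] - 2 * uvals[i_min] + uvals[i_min + 1]) / h^2)
  } else kmax
  kmin <- max(min(k_well, kmax), 0.5)
  tau <- max(1L, ceiling(1 / (dt * kmin)))
  burn <- 10L * tau
  spacing <- 3L * tau

  start <- probe[i_min]
  if (!is.finite(utot(start))) stop("potential not finite at start point")

  with_seed(seed, {
    nw <- min(n, 2048L)
    per <- ceiling(n / nw)
    # overdispersed start: spread walkers over the probe range at finite U
    ok <- probe[is.finite(uvals)]
    x <- sample(ok, nw, replace = TRUE) +
      stats::rnorm(nw, 0, min(0.05, h))
    if (!is.null(rng)) x <- pmin(pmax(x, rng[1]), rng[2])
    sig <- sqrt(2 * dt)
    grad <- function(x) potential$du(x) + bias_k * (x - bias_center)
    out <- matrix(NA_real_, nrow = nw, ncol = per)
    total <- burn + per * spacing
    j <- 0L
    for (s in seq_len(total)) {
      x <- x - grad(x) * dt + sig * stats::rnorm(nw)
      if (!is.null(rng)) {  # reflecting walls
        x <- ifelse(x < rng[1], 2 * rng[1] - x, x)
        x <- ifelse(x > rng[2], 2 * rng[2] - x, x)
        x <- pmin(pmax(x, rng[1]), rng[2])
      }
      if (s > burn && (s - burn) %% spacing == 0L) {
        j <- j + 1L
        out[, j] <- x
      }
    }
    as.numeric(out)[seq_len(n)]
  })
}

#' Draw reaction-coordinate samples from a biased ensemble
#'
#' Emulates umbrella-sampling MD: samples are distributed as
#' exp(-[U(xi) + k_b/2 (xi - xi0)^2]) with all energies in kT. For a
#' harmonic potential the biased density is Gaussian and is sampled
#' exactly; otherwise an overdamped-Langevin (Euler-Maruyama) integrator
#' with automatic time step, burn-in and decorrelating thinning is used.
#'
#' @param potential an [analytic_potential()]
#' @param bias_center restraint centre xi0 (nm)
#' @param bias_k restraint spring constant (kT/nm^2, >= 0)
#' @param n number of samples (>= 1)
#' @param temperature kelvin (recorded; the potential is already in kT)
#' @param seed integer seed; all randomness is local to the call
#' @return numeric vector of n reaction-coordinate samples (nm)
#' @export
sample_biased_window <- function(potential, bias_center, bias_k, n,
                                 temperature = 298, seed = 1) {
  stopifnot(inherits(potential, "analytic_potential"), n >= 1, bias_k >= 0)
  if (potential$form == "harmonic") {
    k <- potential$params$k
    c0 <- potential$params$center
    prec <- k + bias_k
    if (prec <= 0) stop("flat unbounded potential cannot be sampled")
    mu <- (k * c0 + bias_k * bias_center) / prec
    return(with_seed(seed, stats::rnorm(n, mu, sqrt(1 / prec))))
  }
  langevin_sample(potential, bias_center, bias_k, n, seed)
}

#' Sample a whole umbrella window from an analytic potential
#'
#' Convenience wrapper returning an [umbrella_window()]; the spring
#' constant is converted from kT/nm^2 to kJ mol^-1 nm^-2 at the stated
#' temperature, matching the window file convention.
#'
#' @inheritParams sample_biased_window
#' @return an `umbrella_window`
#' @export
sample_umbrella_window <- function(potential, bias_center, bias_k, n,
                                   temperature = 298, seed = 1) {
  xi <- sample_biased_window(potential, bias_center, bias_k, n,
                             temperature, seed)
  umbrella_window(center = bias_center,
                  k = kt_to_kjmol(bias_k, temperature),
                  samples = xi, temperature = temperature)
}

## ----------------------------------------------------------- dimer scenes

#' Specification of a synthetic bead-peptide dimer scene
#'
#' Two identical bead chains (per residue: N, H, CA, C, O and CB, the CB
#' omitted for glycine-like residues) at an exactly controlled
#' centre-of-mass separation, surrounded by single-bead water (residue HOH,
#' atom OW) and urea (residue URE, atom C) with exactly the requested
#' number of solvent beads inside each residue's first shell. Shells are
#' centred on CB (CA for glycine-like residues).
#'
#' @param com_separation COM-COM distance between the chains (nm, > 0)
#' @param water_targets integer first-shell water counts per residue
#'   (recycled across the two chains)
#' @param urea_targets integer first-shell urea counts per residue
#' @param n_residues residues per chain
#' @param shell_radius first-shell radius (nm)
#' @param glycine_residues residue indices built without CB
#' @param bulk_water,bulk_urea extra solvent beads placed outside all shells
#' @param box length-3 box (nm); computed from the geometry when NULL
#' @param seed integer seed
#' @return a `dimer_scene_spec`
#' @export
dimer_scene_spec <- function(com_separation,
                             water_targets = rep(5L, n_residues),
                             urea_targets = rep(0L, n_residues),
                             n_residues = 11L,
                             shell_radius = 0.55,
                             glycine_residues = integer(0),
                             bulk_water = 0L, bulk_urea = 0L,
                             box = NULL, seed = 1L) {
  stopifnot(com_separation > 0, n_residues >= 1, shell_radius > 0)
  water_targets <- rep_len(as.integer(round(water_targets)), n_residues)
  urea_targets <- rep_len(as.integer(round(urea_targets)), n_residues)
  if (any(water_targets < 0) || any(urea_targets < 0))
    stop("solvent targets must be >= 0")
  spacing <- max(1.2, 2 * shell_radius + 0.1)
  if (is.null(box)) {
    box <- c(n_residues * spacing + 2 * shell_radius + 2,
             2 * shell_radius + 3,
             com_separation + 2 * shell_radius + 3)
  }
  if (any(box < c(n_residues * spacing, 1, com_separation) + 2 * shell_radius))
    stop("box too small to contain both chains plus the shell cutoff")
  structure(list(com_separation = com_separation,
                 water_targets = water_targets, urea_targets = urea_targets,
                 n_residues = as.integer(n_residues),
                 shell_radius = shell_radius, spacing = spacing,
                 glycine_residues = as.integer(glycine_residues),
                 bulk_water = as.integer(bulk_water),
                 bulk_urea = as.integer(bulk_urea),
                 box = box, seed = as.integer(seed)),
            class = "dimer_scene_spec")
}

# Bead offsets (nm) of one residue relative to its CA position.
RESIDUE_BEADS <- list(
  N  = c(-0.12, 0.05, 0),
  H  = c(-0.12, 0.15, 0),
  CA = c(0, 0, 0),
  C  = c(0.12, 0.05, 0),
  O  = c(0.12, 0.17, 0),
  CB = c(0, -0.15, 0)
)

build_bead_chain <- function(spec, chain_id, origin) {
  nm <- character(0); rid <- integer(0); rnm <- character(0)
  xyz <- NULL
  for (i in seq_len(spec$n_residues)) {
    gly <- i %in% spec$glycine_residues
    beads <- RESIDUE_BEADS[if (gly) setdiff(names(RESIDUE_BEADS), "CB")
                           else names(RESIDUE_BEADS)]
    base <- origin + c((i - 1) * spec$spacing, 0, 0)
    for (b in names(beads)) {
      nm <- c(nm, b); rid <- c(rid, i)
      rnm <- c(rnm, if (gly) "GLY" else "ALA")
      xyz <- rbind(xyz, base + beads[[b]])
    }
  }
  list(name = nm, res_id = rid, res_name = rnm,
       chain = rep(chain_id, length(nm)), xyz = xyz)
}

#' Build a deterministic dimer scene
#'
#' See [dimer_scene_spec()]. The emitted chain B is chain A translated
#' along z by the requested COM separation, so the (mass-weighted) COM
#' distance equals `com_separation` exactly. Solvent beads are placed by
#' rejection sampling: uniform within the target residue's shell, rejected
#' if inside any other residue's shell, so per-residue shell counts equal
#' the targets exactly rather than in expectation.
#'
#' @param spec a `dimer_scene_spec`
#' @return list with `topology`, `trajectory` (single frame) and the spec
#' @export
build_dimer_scene <- function(spec) {
  stopifnot(inherits(spec, "dimer_scene_spec"))
  box <- spec$box
  mid <- box / 2
  origin_a <- mid - c((spec$n_residues - 1) * spec$spacing / 2, 0,
                      spec$com_separation / 2)
  origin_b <- origin_a + c(0, 0, spec$com_separation)
  cha <- build_bead_chain(spec, "A", origin_a)
  chb <- build_bead_chain(spec, "B", origin_b)

  # shell reference sites: CB, or CA for glycine-like residues
  ref_sites <- NULL
  ref_key <- character(0)
  for (ch in list(cha, chb)) {
    for (i in seq_len(spec$n_residues)) {
      want <- if (i %in% spec$glycine_residues) "CA" else "CB"
      idx <- which(ch$res_id == i & ch$name == want)
      ref_sites <- rbind(ref_sites, ch$xyz[idx, ])
      ref_key <- c(ref_key, paste0(ch$chain[1], i))
    }
  }

  place_in_shell <- function(center, exclude_centers, r) {
    for (attempt in seq_len(20000)) {
      u <- stats::runif(1)^(1 / 3) * r
      v <- stats::rnorm(3)
      p <- center + u * v / sqrt(sum(v^2))
      d <- sweep(exclude_centers, 2, p)
      d <- minimum_image(d, box)
      if (all(rowSums(d^2) > r^2)) return(p %% box)
    }
    stop("capacity error: cannot place solvent bead inside shell without ",
         "entering another residue's shell")
  }
  place_in_bulk <- function(all_centers, r) {
    for (attempt in seq_len(20000)) {
      p <- stats::runif(3) * box
      d <- minimum_image(sweep(all_centers, 2, p), box)
      if (all(rowSums(d^2) > r^2)) return(p)
    }
    stop("capacity error: box too crowded for bulk solvent")
  }

  sol <- with_seed(spec$seed, {
    nmv <- character(0); rnv <- character(0); xyz <- NULL
    nsite <- nrow(ref_sites)
    for (s in seq_len(nsite)) {
      res_i <- ((s - 1) %% spec$n_residues) + 1
      others <- ref_sites[-s, , drop = FALSE]
      for (rep_w in seq_len(spec$water_targets[res_i])) {
        xyz <- rbind(xyz, place_in_shell(ref_sites[s, ], others,
                                         spec$shell_radius))
        nmv <- c(nmv, "OW"); rnv <- c(rnv, "HOH")
      }
      for (rep_u in seq_len(spec$urea_targets[res_i])) {
        xyz <- rbind(xyz, place_in_shell(ref_sites[s, ], others,
                                         spec$shell_radius))
        nmv <- c(nmv, "C"); rnv <- c(rnv, "URE")
      }
    }
    for (rep_b in seq_len(spec$bulk_water)) {
      xyz <- rbind(xyz, place_in_bulk(ref_sites, spec$shell_radius))
      nmv <- c(nmv, "OW"); rnv <- c(rnv, "HOH")
    }
    for (rep_b in seq_len(spec$bulk_urea)) {
      xyz <- rbind(xyz, place_in_bulk(ref_sites, spec$shell_radius))
      nmv <- c(nmv, "C"); rnv <- c(rnv, "URE")
    }
    list(name = nmv, res_name = rnv, xyz = xyz)
  })

  n_sol <- length(sol$name)
  top <- topology(
    name = c(cha$name, chb$name, sol$name),
    res_id = c(cha$res_id, chb$res_id,
               spec$n_residues + seq_len(max(n_sol, 1))[seq_len(n_sol)]),
    res_name = c(cha$res_name, chb$res_name, sol$res_name),
    chain = c(cha$chain, chb$chain, rep("S", n_sol)))
  xyz <- rbind(cha$xyz, chb$xyz, sol$xyz)
  list(topology = top, trajectory = trajectory(xyz, box), spec = spec)
}

## ------------------------------------------------------------ work samples

#' Specification of Crooks-consistent work samples
#'
#' Forward samples ~ Normal(dG + sigma^2/2, sigma^2) and reverse samples
#' ~ Normal(-dG + sigma^2/2, sigma^2), all in kT. This Gaussian pair
#' satisfies the Crooks fluctuation relation
#' ln P_f(W)/P_r(-W) = W - dG exactly, so `delta_g_true` is the analytic
#' free-energy difference recovered by any consistent estimator.
#'
#' @param delta_g_true true free-energy difference (kT)
#' @param sigma work standard deviation (kT, > 0)
#' @param n_forward,n_reverse sample counts (>= 2)
#' @param seed integer seed
#' @return a `work_sample_spec`
#' @export
work_sample_spec <- function(delta_g_true, sigma, n_forward, n_reverse,
                             seed = 1L) {
  stopifnot(is.finite(delta_g_true), sigma > 0,
            n_forward >= 2, n_reverse >= 2)
  structure(list(delta_g_true = delta_g_true, sigma = sigma,
                 n_forward = as.integer(n_forward),
                 n_reverse = as.integer(n_reverse), seed = as.integer(seed)),
            class = "work_sample_spec")
}

#' Generate forward/reverse work samples obeying the Crooks relation
#'
#' @param spec a [work_sample_spec()]
#' @return list with numeric vectors `forward` and `reverse` (kT) and the
#'   spec
#' @export
generate_work_samples <- function(spec) {
  stopifnot(inherits(spec, "work_sample_spec"))
  with_seed(spec$seed, {
    fwd <- stats::rnorm(spec$n_forward, spec$delta_g_true + spec$sigma^2 / 2,
                        spec$sigma)
    rev <- stats::rnorm(spec$n_reverse, -spec$delta_g_true + spec$sigma^2 / 2,
                        spec$sigma)
    list(forward = fwd, reverse = rev, spec = spec)
  })
}

## ------------------------------------------------- secondary-structure kit

ss_fixture_chain <- function(ca, n_fun, h_fun, c_fun, o_fun, cb_fun,
                             chain_id, n) {
  nm <- character(0); rid <- integer(0); xyz <- NULL
  for (i in seq_len(n)) {
    beads <- list(N = n_fun(i), H = h_fun(i), CA = ca(i), C = c_fun(i),
                  O = o_fun(i), CB = cb_fun(i))
    for (b in names(beads)) {
      nm <- c(nm, b); rid <- c(rid, i)
      xyz <- rbind(xyz, beads[[b]])
    }
  }
  list(name = nm, res_id = rid, res_name = rep("ALA", length(nm)),
       chain = rep(chain_id, length(nm)), xyz = xyz)
}

#' Idealised backbone fixtures for the secondary-structure classifier
#'
#' Builds single-frame backbone geometries (bond lengths N-H = 1.0 A,
#' C=O = 1.23 A; schematic strand/helix scaffolds) whose Kabsch-Sander
#' hydrogen-bond pattern realises the requested motif:
#' `beta_pair` gives two strands of `n_residues` each with a doubly
#' hydrogen-bonded inter-strand ladder on every residue pair; `helix_310`
#' gives one chain with i+3 -> i hydrogen bonds; `coil` gives one extended
#' chain with no donor within hydrogen-bonding range.
#'
#' @param motif one of "beta_pair", "helix_310", "coil"
#' @param n_residues residues per chain (>= 4)
#' @return list with `topology` and single-frame `trajectory`
#' @export
generate_secondary_structure_fixture <- function(
    motif = c("beta_pair", "helix_310", "coil"), n_residues = 6L) {
  motif <- match.arg(motif)
  stopifnot(n_residues >= 4)
  n <- as.integer(n_residues)
  A <- 0.1  # Angstrom -> nm
  chains <- switch(motif,
    beta_pair = {
      sp <- 3.8
      a <- ss_fixture_chain(
        ca = function(i) A * c(sp * i, 0, 0),
        n_fun = function(i) A * c(sp * i - 1.3, 0.2, 0),
        h_fun = function(i) A * c(sp * i - 1.3, 1.2, 0),
        c_fun = function(i) A * c(sp * i + 1.3, 0.2, 0),
        o_fun = function(i) A * c(sp * i + 1.3, 1.43, 0),
        cb_fun = function(i) A * c(sp * i, -1.4, 0),
        chain_id = "A", n = n)
      # chain B runs antiparallel (residue order reversed along x), so its
      # C(prev)-N-CA bisector points the reconstructed amide H toward A
      xb <- function(i) sp * (n + 1 - i)
      b <- ss_fixture_chain(
        ca = function(i) A * c(xb(i), 5.0, 0),
        n_fun = function(i) A * c(xb(i) + 1.3, 4.8, 0),
        h_fun = function(i) A * c(xb(i) + 1.3, 3.8, 0),
        c_fun = function(i) A * c(xb(i) - 1.3, 4.8, 0),
        o_fun = function(i) A * c(xb(i) - 1.3, 3.57, 0),
        cb_fun = function(i) A * c(xb(i), 6.4, 0),
        chain_id = "B", n = n)
      list(a, b)
    },
    helix_310 = {
      rho <- 1.9; rise <- 2.0
      th <- function(i) i * 2 * pi / 3
      list(ss_fixture_chain(
        ca = function(i) A * c(2.3 * cos(th(i) + 0.7), 2.3 * sin(th(i) + 0.7),
                               rise * i + 0.6),
        n_fun = function(i) A * c(rho * cos(th(i)), rho * sin(th(i)), rise * i),
        h_fun = function(i) A * c(rho * cos(th(i)), rho * sin(th(i)),
                                  rise * i - 1),
        c_fun = function(i) A * c(rho * cos(th(i)), rho * sin(th(i)),
                                  rise * i + 1.2),
        o_fun = function(i) A * c(rho * cos(th(i)), rho * sin(th(i)),
                                  rise * i + 2.43),
        cb_fun = function(i) A * c(3.2 * cos(th(i) + 0.7),
                                   3.2 * sin(th(i) + 0.7), rise * i + 0.6),
        chain_id = "A", n = n))
    },
    coil = {
      sp <- 3.8
      list(ss_fixture_chain(
        ca = function(i) A * c(sp * i, 0, 0),
        n_fun = function(i) A * c(sp * i - 1.3, -0.2, 0),
        h_fun = function(i) A * c(sp * i - 1.3, -1.2, 0),
        c_fun = function(i) A * c(sp * i + 1.3, 0.2, 0),
        o_fun = function(i) A * c(sp * i + 1.3, 1.43, 0),
        cb_fun = function(i) A * c(sp * i, 1.5, 0),
        chain_id = "A", n = n))
    })
  nm <- unlist(lapply(chains, `[[`, "name"))
  rid <- unlist(lapply(chains, `[[`, "res_id"))
  rnm <- unlist(lapply(chains, `[[`, "res_name"))
  chv <- unlist(lapply(chains, `[[`, "chain"))
  xyz <- do.call(rbind, lapply(chains, `[[`, "xyz"))
  span <- apply(xyz, 2, function(v) diff(range(v)))
  box <- pmax(span + 3, 5)
  top <- topology(name = nm, res_id = rid, res_name = rnm, chain = chv)
  list(topology = top, trajectory = trajectory(xyz, box))
}
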