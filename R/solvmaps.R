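#' RDFs, coordination numbers and per-residue solvation maps
#'
#' Radial distribution functions and coordination numbers
#' CN = rho int_0^rcut g(r) 4 pi r^2 dr; per-residue normalised
#' hydration/co-solvent maps along the reaction coordinate (counts within
#' each residue's first shell around CB, CA for glycine, averaged over the
#' two peptide chains); interpeptide backbone O-N neighbour maps at the
#' 0.35 nm criterion; and toy LJ+Coulomb nonbonded energy profiles.
#'
#' @name solvmaps
NULL

#' Radial distribution function between two selections
#'
#' Minimum-image pair-distance histogram normalised by the ideal-gas shell
#' count at the B-group number density, averaged over frames.
#'
#' @param topology a `topology`
#' @param traj a `trajectory`
#' @param sel_a,sel_b integer atom indices (non-empty)
#' @param r_max histogram range (nm), must be below half the smallest box
#'   length
#' @param bin_width bin width (nm)
#' @return an `rdf_result` with grid `r` (bin centres), `g`, the reference
#'   density (nm^-3) and raw shell counts
#' @export
rdf <- function(topology, traj, sel_a, sel_b, r_max, bin_width = 0.002) {
  stopifnot(length(sel_a) > 0, length(sel_b) > 0, bin_width > 0)
  if (r_max >= min(traj$box) / 2)
    stop("r_max must be smaller than half the smallest box length")
  edges <- seq(0, r_max + bin_width, by = bin_width)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  vol <- prod(traj$box[1, ])
  for (fi in seq_along(traj$frames)) {
    fr <- traj$frames[[fi]]
    box <- traj$box[fi, ]
    for (ai in sel_a) {
      d <- minimum_image(sweep(fr[sel_b, , drop = FALSE], 2, fr[ai, ]), box)
      r <- sqrt(rowSums(d^2))
      r <- r[sel_b != ai & r <= r_max]
      h <- findInterval(r, edges, rightmost.closed = TRUE, all.inside = TRUE)
      counts <- counts + tabulate(h, nbins = nb)
    }
  }
  rho_b <- length(sel_b) / vol
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  norm <- length(traj$frames) * length(sel_a) * rho_b * shell_vol
  structure(list(r = edges[-1] - bin_width / 2, g = counts / norm,
                 density = rho_b, counts = counts, bin_width = bin_width),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("RDF: %d bins to %.3g nm, reference density %.4g nm^-3\n",
              length(x$r), max(x$r) + x$bin_width / 2, x$density))
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  plot(x$r, x$g, type = "l", xlab = "r (nm)", ylab = "g(r)", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Coordination number from an RDF
#'
#' CN = rho int_0^rcut g(r) 4 pi r^2 dr by trapezoidal quadrature; the
#' average neighbour count within r_cut.
#'
#' @param rdf an `rdf_result`
#' @param r_cut integration cutoff (nm), within the RDF grid
#' @return dimensionless coordination number
#' @export
coordination_number <- function(rdf, r_cut) {
  rmax <- max(rdf$r) + rdf$bin_width / 2
  if (r_cut <= 0 || r_cut > rmax + 1e-12)
    stop("r_cut outside the RDF grid (0, ", signif(rmax, 4), "]")
  r <- c(0, rdf$r)
  integrand <- c(0, rdf$g * 4 * pi * rdf$r^2) * rdf$density
  keep <- r <= r_cut
  r_in <- r[keep]; f_in <- integrand[keep]
  if (r_cut > max(r_in)) {  # close the last partial bin by interpolation
    f_cut <- stats::approx(r, integrand, xout = r_cut, rule = 2)$y
    r_in <- c(r_in, r_cut); f_in <- c(f_in, f_cut)
  }
  sum(diff(r_in) * (utils::head(f_in, -1) + utils::tail(f_in, -1)) / 2)
}

#' First minimum of an RDF
#'
#' First local minimum of the moving-average-smoothed g(r) after the first
#' local maximum; ties resolve toward smaller r. A monotone g(r) (e.g. an
#' ideal gas) has no first shell and raises an error prompting an explicit
#' cutoff.
#'
#' @param rdf an `rdf_result`
#' @param smooth_window moving-average window in bins (1 = no smoothing)
#' @return r at the first minimum (nm)
#' @export
first_minimum <- function(rdf, smooth_window = 1) {
  g <- rdf$g
  if (smooth_window > 1) {
    k <- rep(1 / smooth_window, smooth_window)
    g <- as.numeric(stats::filter(g, k, sides = 2))
  }
  ok <- which(!is.na(g))
  gv <- g[ok]
  n <- length(gv)
  if (n < 3) stop("RDF too short to locate a first minimum")
  dmax <- which(diff(gv) < 0)
  first_max <- if (length(dmax) > 0) dmax[1] else NA
  if (is.na(first_max) || first_max >= n - 1)
    stop("no interior maximum: RDF is monotone; supply an explicit cutoff")
  after <- first_max + which(diff(gv[(first_max + 1):n]) > 0)
  if (length(after) == 0)
    stop("no minimum after the first maximum; supply an explicit cutoff")
  rdf$r[ok[after[1]]]
}

## --------------------------------------------------------- residue maps

peptide_chains <- function(topology) {
  sort(unique(topology$chain[topology$role == "bb_CA"]))
}

# Reference site (CB, else CA) atom index per residue per chain.
reference_sites <- function(topology) {
  chains <- peptide_chains(topology)
  if (length(chains) == 0) stop("no peptide chains in topology")
  res_ids <- sort(unique(topology$res_id[topology$chain %in% chains &
                                           topology$role == "bb_CA"]))
  sites <- matrix(NA_integer_, nrow = length(res_ids), ncol = length(chains),
                  dimnames = list(res_ids, chains))
  for (ci in seq_along(chains)) {
    for (ri in seq_along(res_ids)) {
      idx <- which(topology$chain == chains[ci] &
                     topology$res_id == res_ids[ri])
      cb <- idx[topology$role[idx] == "sc_CB"]
      ca <- idx[topology$role[idx] == "bb_CA"]
      sites[ri, ci] <- if (length(cb) > 0) cb[1]
                       else if (length(ca) > 0) ca[1] else NA_integer_
    }
  }
  list(sites = sites, res_ids = res_ids, chains = chains)
}

solvent_indices <- function(topology, solvent = c("water", "urea")) {
  solvent <- match.arg(solvent)
  if (solvent == "water") {
    select_atoms(topology, role = "water_O")
  } else {
    # one designated carbon per urea molecule, so molecules are counted
    idx <- select_atoms(topology, role = "urea_atom")
    idx[topology$element[idx] == "C"]
  }
}

new_residue_map <- function(values, res_ids, xi_keys, normalization,
                            norm_constants = NULL) {
  dimnames(values) <- list(res_ids, signif(xi_keys, 8))
  structure(list(values = values, res_ids = res_ids, xi = xi_keys,
                 normalization = normalization,
                 norm_constants = norm_constants),
            class = "residue_map")
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("residue map: %d residues x %d xi bins (normalization: %s)\n",
              nrow(x$values), ncol(x$values), x$normalization))
  print(signif(x$values, 3))
  invisible(x)
}

#' @export
plot.residue_map <- function(x, ...) {
  graphics::image(x = x$xi, y = x$res_ids, z = t(x$values),
                  xlab = expression(xi ~ "(nm)"), ylab = "residue", ...)
  invisible(x)
}

#' Per-residue solvation (hydration or urea) map along xi
#'
#' For every residue and xi key: the number of solvent particles (water
#' oxygens, or one designated carbon per urea molecule) within the
#' residue's first-shell radius of its reference site (CB; CA for
#' glycine-like residues), averaged over the frames at that xi and over
#' the two peptide chains. Normalisation: `"water_max"` divides each
#' residue's row by the per-residue maximum supplied in `norm_constants`
#' (the maximum hydration number of that residue in water) or, when
#' absent, by the row's own maximum; `"own_max"` always uses the row's own
#' maximum; `"none"` returns raw counts.
#'
#' @param topology a `topology`
#' @param traj a `trajectory`
#' @param xi reaction-coordinate key per frame
#' @param solvent "water" or "urea"
#' @param shell_radius scalar or per-residue first-shell radii (nm)
#' @param normalize "water_max", "own_max" or "none"
#' @param norm_constants optional per-residue normalisation constants
#' @return a `residue_map`
#' @export
hydration_map <- function(topology, traj, xi, solvent = c("water", "urea"),
                          shell_radius = 0.55,
                          normalize = c("water_max", "own_max", "none"),
                          norm_constants = NULL) {
  solvent <- match.arg(solvent)
  normalize <- match.arg(normalize)
  stopifnot(length(xi) == length(traj$frames))
  rs <- reference_sites(topology)
  nres <- length(rs$res_ids)
  radii <- rep_len(shell_radius, nres)
  sol <- solvent_indices(topology, solvent)
  keys <- sort(unique(xi))
  raw <- matrix(NA_real_, nrow = nres, ncol = length(keys))
  if (any(is.na(rs$sites)))
    warning("residues without a CB/CA reference site are flagged NA: ",
            paste(rs$res_ids[rowSums(is.na(rs$sites)) > 0], collapse = ","),
            call. = FALSE)
  for (ki in seq_along(keys)) {
    fr_idx <- which(xi == keys[ki])
    acc <- matrix(0, nrow = nres, ncol = length(rs$chains))
    for (fi in fr_idx) {
      fr <- traj$frames[[fi]]; box <- traj$box[fi, ]
      for (ci in seq_along(rs$chains)) {
        for (ri in seq_len(nres)) {
          site <- rs$sites[ri, ci]
          if (is.na(site)) { acc[ri, ci] <- NA; next }
          if (length(sol) == 0) next
          d <- minimum_image(sweep(fr[sol, , drop = FALSE], 2, fr[site, ]),
                             box)
          acc[ri, ci] <- acc[ri, ci] + sum(rowSums(d^2) <= radii[ri]^2)
        }
      }
    }
    raw[, ki] <- rowMeans(acc) / length(fr_idx)
  }
  consts <- switch(normalize,
    none = rep(1, nres),
    own_max = apply(raw, 1, max, na.rm = TRUE),
    water_max = if (is.null(norm_constants))
      apply(raw, 1, max, na.rm = TRUE) else rep_len(norm_constants, nres))
  consts[consts == 0] <- 1
  vals <- if (normalize == "none") raw else raw / consts
  new_residue_map(vals, rs$res_ids, keys, normalize,
                  if (normalize == "none") NULL else consts)
}

#' Interpeptide backbone O-N neighbour map
#'
#' For every residue and xi key: the number of interchain backbone
#' carbonyl-amino pairs within the cutoff (r <= 0.35 nm by default, the
#' boundary included) involving that residue, counting both
#' O(chain A)-N(chain B) and N(chain A)-O(chain B) pairs, averaged over
#' the two chains. Values are unnormalised counts.
#'
#' @inheritParams hydration_map
#' @param cutoff neighbour criterion (nm); pairs at exactly the cutoff
#'   count
#' @return a `residue_map` of raw counts
#' @export
on_neighbor_map <- function(topology, traj, xi, cutoff = 0.35) {
  stopifnot(length(xi) == length(traj$frames))
  chains <- peptide_chains(topology)
  if (length(chains) != 2)
    stop("O-N neighbour map needs exactly two peptide chains, found ",
         length(chains))
  res_ids <- sort(unique(topology$res_id[topology$chain %in% chains &
                                           topology$role == "bb_CA"]))
  nres <- length(res_ids)
  idx_of <- function(chain, role) {
    i <- select_atoms(topology, chain = chain, role = role)
    i[order(topology$res_id[i])]
  }
  oa <- idx_of(chains[1], "bb_O"); na_ <- idx_of(chains[1], "bb_N")
  ob <- idx_of(chains[2], "bb_O"); nb_ <- idx_of(chains[2], "bb_N")
  keys <- sort(unique(xi))
  vals <- matrix(0, nrow = nres, ncol = length(keys))
  pair_counts <- function(fr, box, set1, set2) {
    # contacts[r1, r2] over residues of set1 x set2
    m <- matrix(0, nres, nres)
    for (i in seq_along(set1)) {
      d <- minimum_image(sweep(fr[set2, , drop = FALSE], 2, fr[set1[i], ]),
                         box)
      hit <- which(rowSums(d^2) <= cutoff^2 + 1e-12)
      ri <- match(topology$res_id[set1[i]], res_ids)
      for (h in hit) {
        rj <- match(topology$res_id[set2[h]], res_ids)
        m[ri, rj] <- m[ri, rj] + 1
      }
    }
    m
  }
  for (ki in seq_along(keys)) {
    fr_idx <- which(xi == keys[ki])
    acc <- 0
    for (fi in fr_idx) {
      fr <- traj$frames[[fi]]; box <- traj$box[fi, ]
      on_ab <- pair_counts(fr, box, oa, nb_)  # O(A) - N(B)
      no_ab <- pair_counts(fr, box, na_, ob)  # N(A) - O(B)
      per_res_a <- rowSums(on_ab) + rowSums(no_ab)
      per_res_b <- colSums(on_ab) + colSums(no_ab)
      acc <- acc + (per_res_a + per_res_b) / 2
    }
    vals[, ki] <- acc / length(fr_idx)
  }
  new_residue_map(vals, res_ids, keys, "none")
}

#' Toy nonbonded LJ + Coulomb energy profile along xi
#'
#' Mean over the frames at each xi of
#' sum_pairs 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6) + f_elec q_i q_j / r
#' with minimum-image distances, Lorentz-Berthelot combining rules and no
#' cutoff. Scope "interchain" sums pairs between the two peptide chains;
#' "intrachain" sums pairs within each chain, excluding pairs inside one
#' residue (treated as bonded).
#'
#' @inheritParams hydration_map
#' @param charges per-atom charges (e), full topology length
#' @param lj_eps,lj_sigma per-atom LJ parameters (kJ/mol, nm)
#' @param scope "interchain" or "intrachain"
#' @return data frame with columns xi and energy (kJ/mol)
#' @export
nonbonded_energy_profile <- function(topology, traj, xi, charges, lj_eps,
                                     lj_sigma,
                                     scope = c("interchain", "intrachain")) {
  scope <- match.arg(scope)
  stopifnot(length(xi) == length(traj$frames))
  chains <- peptide_chains(topology)
  if (length(chains) != 2) stop("energy profile needs two peptide chains")
  sel <- which(topology$chain %in% chains)
  need <- unique(sel)
  bad <- need[is.na(charges[need]) | is.na(lj_eps[need]) |
                is.na(lj_sigma[need])]
  if (length(bad) > 0)
    stop("missing nonbonded parameters for atoms: ",
         paste(utils::head(bad, 10), collapse = ","))
  ia <- which(topology$chain == chains[1])
  ib <- which(topology$chain == chains[2])
  pairs <- if (scope == "interchain") {
    expand.grid(i = ia, j = ib)
  } else {
    same_res <- function(i, j) topology$res_id[i] == topology$res_id[j]
    p <- rbind(t(utils::combn(ia, 2)), t(utils::combn(ib, 2)))
    p <- as.data.frame(p); names(p) <- c("i", "j")
    p[!same_res(p$i, p$j), ]
  }
  eps_ij <- sqrt(lj_eps[pairs$i] * lj_eps[pairs$j])
  sig_ij <- (lj_sigma[pairs$i] + lj_sigma[pairs$j]) / 2
  qq <- charges[pairs$i] * charges[pairs$j]
  keys <- sort(unique(xi))
  energy <- vapply(keys, function(k) {
    fr_idx <- which(xi == k)
    mean(vapply(fr_idx, function(fi) {
      fr <- traj$frames[[fi]]; box <- traj$box[fi, ]
      d <- minimum_image(fr[pairs$i, , drop = FALSE] -
                           fr[pairs$j, , drop = FALSE], box)
      r <- sqrt(rowSums(d^2))
      sr6 <- (sig_ij / r)^6
      sum(4 * eps_ij * (sr6^2 - sr6) + COULOMB_KJ_NM * qq / r)
    }, 1.0))
  }, 1.0)
  data.frame(xi = keys, energy = energy)
}

#' Pairwise LJ + Coulomb energy (toy systems)
#'
#' @param r distance (nm)
#' @param qi,qj charges (e)
#' @param eps,sigma LJ parameters of the pair (kJ/mol, nm)
#' @return energy in kJ/mol
#' @export
lj_coulomb_energy <- function(r, qi = 0, qj = 0, eps = 0, sigma = 0.3) {
  sr6 <- (sigma / r)^6
  4 * eps * (sr6^2 - sr6) + COULOMB_KJ_NM * qi * qj / r
}

#' Write a residue map as a TSV matrix
#'
#' Rows are residues, columns xi bins; values rounded to 6 significant
#' digits.
#'
#' @param map a `residue_map`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_residue_map <- function(map, path) {
  m <- signif(map$values, 6)
  df <- data.frame(residue = map$res_ids, m, check.names = FALSE)
  names(df) <- c("residue", signif(map$xi, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
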