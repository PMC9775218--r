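#' Radius of gyration and DSSP-lite secondary structure
#'
#' Compactness (mass-weighted radius of gyration) and a reduced
#' Kabsch-Sander secondary-structure classification driven by the
#' electrostatic backbone hydrogen-bond energy
#' E = 27.888 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol (distances in
#' Angstrom), with the hydrogen-bond criterion E < -0.5 kcal/mol
#' (-2.09 kJ/mol). Classes: E (beta sheet/bridge, B folded into E),
#' G (3-10 helix), H (alpha helix), T (turn), C (coil).
#'
#' @name structure_analysis
NULL

#' Hydrogen-bond energy threshold
#'
#' The Kabsch-Sander criterion in kcal/mol and its kJ/mol equivalent.
#' @export
HB_THRESHOLD_KCAL <- -0.5

#' @rdname HB_THRESHOLD_KCAL
#' @export
HB_THRESHOLD_KJ <- -2.09  # round(-0.5 * 4.184, 2)

#' Per-frame radius of gyration
#'
#' Rg = sqrt(sum_i m_i |r_i - r_COM|^2 / sum_i m_i), per frame, over a
#' selection assumed whole (no periodic wrapping applied).
#'
#' @param topology a `topology`
#' @param traj a `trajectory`
#' @param selection integer atom indices (default: all atoms)
#' @param mass_weighted use atomic masses (default) or unit weights
#' @return numeric vector, one Rg (nm) per frame
#' @export
radius_of_gyration <- function(topology, traj, selection = NULL,
                               mass_weighted = TRUE) {
  if (is.null(selection)) selection <- seq_len(nrow(topology))
  if (length(selection) == 0) stop("empty selection in radius_of_gyration")
  w <- if (mass_weighted) atom_masses(topology)[selection]
       else rep(1, length(selection))
  vapply(traj$frames, function(fr) {
    r <- fr[selection, , drop = FALSE]
    com <- colSums(r * w) / sum(w)
    sqrt(sum(w * rowSums(sweep(r, 2, com)^2)) / sum(w))
  }, 1.0)
}

#' Normalised radius-of-gyration distribution
#'
#' @param series numeric Rg series (nm), non-empty
#' @param bin_width histogram bin width (nm)
#' @return data frame with columns `rg` (bin centre) and `density`;
#'   the density integrates to 1
#' @export
rg_distribution <- function(series, bin_width = 0.01) {
  stopifnot(length(series) > 0, bin_width > 0)
  lo <- floor(min(series) / bin_width) * bin_width
  hi <- ceiling(max(series) / bin_width) * bin_width
  breaks <- seq(lo - bin_width / 2, hi + bin_width, by = bin_width)
  h <- graphics::hist(series, breaks = breaks, plot = FALSE)
  data.frame(rg = h$mids, density = h$density)
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' E = 27.888 (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol with distances
#' in Angstrom; inputs are nm, the package coordinate unit.
#'
#' @param C,O acceptor carbonyl carbon and oxygen positions (nm)
#' @param N,H donor amide nitrogen and hydrogen positions (nm)
#' @return energy in kcal/mol
#' @export
kabsch_sander_energy <- function(C, O, N, H) {
  stopifnot(all(is.finite(c(C, O, N, H))))
  d <- function(a, b) sqrt(sum((a - b)^2))
  r_on <- d(O, N); r_ch <- d(C, H); r_oh <- d(O, H); r_cn <- d(C, N)
  if (min(r_on, r_ch, r_oh, r_cn) <= 0.01)
    stop("near-coincident atoms in hydrogen-bond energy evaluation")
  27.888 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn) / 10
}

# Per-residue backbone atom table for one frame; reconstructs missing amide
# H at 1.0 A from N along the bisector opposite the C(prev)-N and CA-N
# directions. PRO (and residues without N) cannot donate.
backbone_table <- function(topology, frame) {
  key <- paste(topology$chain, topology$res_id, sep = "\r")
  ukey <- unique(key[topology$role %in%
                       c("bb_N", "bb_H", "bb_CA", "bb_C", "bb_O")])
  res <- do.call(rbind, lapply(ukey, function(k) {
    idx <- which(key == k)
    data.frame(chain = topology$chain[idx[1]],
               res_id = topology$res_id[idx[1]],
               res_name = topology$res_name[idx[1]],
               N = find_role(topology, idx, "bb_N"),
               H = find_role(topology, idx, "bb_H"),
               CA = find_role(topology, idx, "bb_CA"),
               C = find_role(topology, idx, "bb_C"),
               O = find_role(topology, idx, "bb_O"),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$chain, res$res_id), ]
  rownames(res) <- NULL
  n <- nrow(res)
  pos <- array(NA_real_, dim = c(n, 5, 3),
               dimnames = list(NULL, c("N", "H", "CA", "C", "O"), NULL))
  for (a in c("N", "H", "CA", "C", "O")) {
    ok <- !is.na(res[[a]])
    pos[ok, a, ] <- frame[res[[a]][ok], , drop = FALSE]
  }
  # reconstruct H where absent (not for proline, which has no amide H)
  for (i in seq_len(n)) {
    if (!is.na(res$H[i]) || toupper(res$res_name[i]) == "PRO") next
    prev <- which(res$chain == res$chain[i] & res$res_id == res$res_id[i] - 1)
    if (length(prev) != 1 || is.na(res$C[prev]) ||
        any(is.na(pos[i, c("N", "CA"), ]))) next
    Np <- pos[i, "N", ]; CAp <- pos[i, "CA", ]; Cprev <- pos[prev, "C", ]
    u1 <- (Np - Cprev); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- (Np - CAp); u2 <- u2 / sqrt(sum(u2^2))
    dir <- u1 + u2
    nd <- sqrt(sum(dir^2))
    if (nd < 1e-8) next
    pos[i, "H", ] <- Np + 0.1 * dir / nd   # 1.0 Angstrom = 0.1 nm
  }
  list(res = res, pos = pos)
}

find_role <- function(topology, idx, role) {
  hit <- idx[topology$role[idx] == role]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

# Hydrogen-bond matrix: hb[acceptor, donor] TRUE when the CO of the
# acceptor residue binds the NH of the donor residue with E < threshold.
hbond_matrix <- function(bb, threshold = HB_THRESHOLD_KCAL) {
  res <- bb$res; pos <- bb$pos
  n <- nrow(res)
  hb <- matrix(FALSE, n, n)
  energy <- matrix(NA_real_, n, n)
  can_accept <- !is.na(res$C) & !is.na(res$O) & is.finite(pos[, "C", 1])
  can_donate <- !is.na(res$N) & is.finite(pos[, "H", 1]) &
    toupper(res$res_name) != "PRO"
  for (a in which(can_accept)) {
    for (d in which(can_donate)) {
      if (a == d) next
      if (res$chain[a] == res$chain[d] &&
          abs(res$res_id[a] - res$res_id[d]) < 2) next
      e <- kabsch_sander_energy(pos[a, "C", ], pos[a, "O", ],
                                pos[d, "N", ], pos[d, "H", ])
      energy[a, d] <- e
      hb[a, d] <- e < threshold
    }
  }
  list(hb = hb, energy = energy)
}

#' Enumerate backbone hydrogen bonds in one frame
#'
#' @param topology a `topology`
#' @param frame n x 3 coordinates (nm)
#' @param threshold hydrogen-bond energy criterion (kcal/mol)
#' @return data frame with acceptor/donor chain and residue plus energy
#'   (kcal/mol); only bonds below the threshold are listed
#' @export
backbone_hbonds <- function(topology, frame,
                            threshold = HB_THRESHOLD_KCAL) {
  bb <- backbone_table(topology, frame)
  hm <- hbond_matrix(bb, threshold)
  idx <- which(hm$hb, arr.ind = TRUE)
  data.frame(acceptor_chain = bb$res$chain[idx[, 1]],
             acceptor_res = bb$res$res_id[idx[, 1]],
             donor_chain = bb$res$chain[idx[, 2]],
             donor_res = bb$res$res_id[idx[, 2]],
             energy = hm$energy[idx],
             stringsAsFactors = FALSE)
}

#' Assign secondary structure for one frame
#'
#' Reduced Kabsch-Sander assignment from the backbone hydrogen-bond
#' pattern (Hbond(i, j): CO of i accepts the NH of j):
#' two consecutive 4-turns give alpha helix H, two consecutive 3-turns
#' give 3-10 helix G, parallel/antiparallel bridge patterns give E (single
#' bridges are folded into E), a bare i -> i+n turn (n = 3, 4, 5) gives T
#' for the bracketed residues, everything else is coil C. Precedence when
#' patterns overlap: H over G over E over T.
#'
#' @inheritParams backbone_hbonds
#' @return data frame (class `ss_record`) with chain, res_id, class
#' @export
assign_secondary_structure <- function(topology, frame,
                                       threshold = HB_THRESHOLD_KCAL) {
  bb <- backbone_table(topology, frame)
  res <- bb$res
  n <- nrow(res)
  hb <- hbond_matrix(bb, threshold)$hb
  cls <- rep("C", n)

  same_chain_offset <- function(i, k) {
    j <- which(res$chain == res$chain[i] & res$res_id == res$res_id[i] + k)
    if (length(j) == 1) j else NA_integer_
  }
  turn_at <- matrix(FALSE, n, 3)  # columns: 3-, 4-, 5-turns
  for (i in seq_len(n)) {
    for (k in 3:5) {
      j <- same_chain_offset(i, k)
      if (!is.na(j) && hb[i, j]) turn_at[i, k - 2] <- TRUE
    }
  }
  # T: residues bracketed by any bare turn
  for (i in seq_len(n)) {
    for (k in 3:5) {
      if (!turn_at[i, k - 2]) next
      for (m in seq_len(k - 1)) {
        j <- same_chain_offset(i, m)
        if (!is.na(j)) cls[j] <- "T"
      }
    }
  }
  # E: bridge patterns (minimum separation 3 within a chain)
  hbond <- function(i, j) !is.na(i) && !is.na(j) && hb[i, j]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (res$chain[i] == res$chain[j] &&
          abs(res$res_id[i] - res$res_id[j]) < 3) next
      im1 <- same_chain_offset(i, -1); ip1 <- same_chain_offset(i, 1)
      jm1 <- same_chain_offset(j, -1); jp1 <- same_chain_offset(j, 1)
      para <- (hbond(im1, j) && hbond(j, ip1)) ||
              (hbond(jm1, i) && hbond(i, jp1))
      anti <- (hbond(i, j) && hbond(j, i)) ||
              (hbond(im1, jp1) && hbond(jm1, ip1))
      if (para || anti) cls[c(i, j)] <- "E"
    }
  }
  # G then H: two consecutive turns, helices override sheets and turns
  for (i in seq_len(n)) {
    i2 <- same_chain_offset(i, 1)
    if (is.na(i2)) next
    if (turn_at[i, 1] && turn_at[i2, 1]) {
      for (m in 1:3) {
        j <- same_chain_offset(i, m)
        if (!is.na(j)) cls[j] <- "G"
      }
    }
  }
  for (i in seq_len(n)) {
    i2 <- same_chain_offset(i, 1)
    if (is.na(i2)) next
    if (turn_at[i, 2] && turn_at[i2, 2]) {
      for (m in 1:4) {
        j <- same_chain_offset(i, m)
        if (!is.na(j)) cls[j] <- "H"
      }
    }
  }
  out <- data.frame(chain = res$chain, res_id = res$res_id, class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("ss_record", "data.frame")
  out
}

#' Secondary-structure fractions along the reaction coordinate
#'
#' Frames are grouped by their xi key; within each group, class fractions
#' are pooled over residues x frames, so the five classes sum to 1 at
#' every xi.
#'
#' @param topology a `topology`
#' @param traj a `trajectory`
#' @param xi numeric reaction-coordinate key per frame
#' @param threshold hydrogen-bond criterion (kcal/mol)
#' @return data frame with columns xi, E, G, H, T, C
#' @export
ss_fraction_profile <- function(topology, traj, xi,
                                threshold = HB_THRESHOLD_KCAL) {
  stopifnot(length(xi) == length(traj$frames))
  keys <- sort(unique(xi))
  classes <- c("E", "G", "H", "T", "C")
  rows <- lapply(keys, function(k) {
    fr_idx <- which(xi == k)
    cl <- unlist(lapply(fr_idx, function(fi) {
      assign_secondary_structure(topology, traj$frames[[fi]], threshold)$class
    }))
    tab <- table(factor(cl, levels = classes))
    as.numeric(tab) / length(cl)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- classes
  cbind(data.frame(xi = keys), out)
}

#' One-letter secondary-structure string for a frame
#'
#' @param record an `ss_record` from [assign_secondary_structure()]
#' @return named character vector, one string per chain
#' @export
ss_string <- function(record) {
  vapply(split(record$class, record$chain), paste0, "", collapse = "")
}
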