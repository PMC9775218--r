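#' Role-labelled topologies and coordinate trajectories
#'
#' A `topology` is a data frame with one row per atom and columns
#' `name`, `element`, `role`, `res_id`, `res_name`, `chain`. Roles label the
#' atom categories the solvation and secondary-structure analyses need:
#' backbone N/H/CA/C/O, side-chain CB, water oxygen/hydrogen and urea atoms.
#' A `trajectory` holds an ordered list of n_atoms x 3 coordinate matrices in
#' nm plus per-frame orthorhombic box lengths in nm.
#'
#' @name trajio
NULL

ATOM_ROLES <- c("bb_N", "bb_H", "bb_CA", "bb_C", "bb_O",
                "sc_CB", "sc_other", "water_O", "water_H", "urea_atom")

WATER_RESNAMES <- c("HOH", "SOL", "WAT", "TIP4", "W")
UREA_RESNAMES <- c("URE", "URA", "UREA")

#' Infer the analysis role of an atom from its name and residue name
#'
#' Pure mapping table: backbone N/H/CA/C/O and side-chain CB of protein
#' residues map to the corresponding backbone/side-chain roles; atoms of
#' water residues (HOH/SOL/WAT) map to water_O/water_H; atoms of urea
#' residues (URE) map to urea_atom; everything else is sc_other.
#'
#' @param name atom name (e.g. "CA", "OW")
#' @param res_name residue name (e.g. "ALA", "HOH")
#' @param warn warn when falling back to sc_other
#' @return character vector of roles
#' @export
infer_role <- function(name, res_name, warn = FALSE) {
  name <- toupper(trimws(name))
  res_name <- toupper(trimws(res_name))
  n <- max(length(name), length(res_name))
  name <- rep_len(name, n)
  res_name <- rep_len(res_name, n)
  role <- rep("sc_other", n)

  is_water <- res_name %in% WATER_RESNAMES
  role[is_water & name %in% c("OW", "O", "OH2")] <- "water_O"
  role[is_water & grepl("^H", name)] <- "water_H"
  role[res_name %in% UREA_RESNAMES] <- "urea_atom"

  is_pep <- !is_water & !(res_name %in% UREA_RESNAMES)
  role[is_pep & name == "N"] <- "bb_N"
  role[is_pep & name %in% c("H", "HN", "H1")] <- "bb_H"
  role[is_pep & name == "CA"] <- "bb_CA"
  role[is_pep & name == "C"] <- "bb_C"
  role[is_pep & name %in% c("O", "OXT")] <- "bb_O"
  role[is_pep & name == "CB"] <- "sc_CB"

  if (warn && any(role == "sc_other")) {
    unk <- unique(name[role == "sc_other"])
    warning("atoms mapped to role sc_other: ", paste(unk, collapse = ", "),
            call. = FALSE)
  }
  role
}

guess_element <- function(name) {
  nm <- gsub("[0-9'\"]", "", toupper(trimws(name)))
  el <- substr(nm, 1, 1)
  el[nm == ""] <- "C"
  el
}

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  S = 32.06, P = 30.974)

#' Atomic masses for a topology
#' @param topology a `topology`
#' @return numeric vector of masses in g/mol (unknown elements get 12.011)
#' @export
atom_masses <- function(topology) {
  m <- ELEMENT_MASS[topology$element]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Construct a topology
#'
#' @param name,res_id,res_name,chain per-atom vectors
#' @param element per-atom elements; inferred from names if NULL
#' @param role per-atom roles; inferred via [infer_role()] if NULL
#' @return a `topology` (classed data frame)
#' @export
topology <- function(name, res_id, res_name, chain,
                     element = NULL, role = NULL) {
  if (is.null(element)) element <- guess_element(name)
  if (is.null(role)) role <- infer_role(name, res_name)
  stopifnot(all(role %in% ATOM_ROLES))
  top <- data.frame(name = as.character(name), element = as.character(element),
                    role = as.character(role), res_id = as.integer(res_id),
                    res_name = as.character(res_name),
                    chain = as.character(chain), stringsAsFactors = FALSE)
  # residue indices must be non-decreasing within each chain
  for (ch in unique(top$chain)) {
    ri <- top$res_id[top$chain == ch]
    if (is.unsorted(ri)) stop("residue indices decrease within chain ", ch)
  }
  class(top) <- c("topology", "data.frame")
  top
}

#' Construct a trajectory
#'
#' @param frames a single n x 3 matrix or list of them, coordinates in nm
#' @param box length-3 box vector (nm) or matrix with one row per frame
#' @return a `trajectory`
#' @export
trajectory <- function(frames, box) {
  if (is.matrix(frames)) frames <- list(frames)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    stopifnot(ncol(f) == 3, all(is.finite(f)))
    dimnames(f) <- NULL
    f
  })
  na <- unique(vapply(frames, nrow, 1L))
  if (length(na) != 1) stop("atom count differs across frames")
  if (is.null(dim(box))) box <- matrix(box, nrow = length(frames), ncol = 3,
                                       byrow = TRUE)
  box <- as.matrix(box)
  stopifnot(nrow(box) == length(frames), ncol(box) == 3, all(box > 0))
  structure(list(frames = frames, box = box, n_atoms = na),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frame(s), %d atoms, box %s nm\n",
              length(x$frames), x$n_atoms,
              paste(signif(x$box[1, ], 4), collapse = " x ")))
  invisible(x)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, chains %s\n",
              nrow(x), length(unique(paste(x$chain, x$res_id))),
              paste(unique(x$chain), collapse = ",")))
  print(table(x$role))
  invisible(x)
}

#' Select atom indices by attributes
#'
#' @param topology a `topology`
#' @param chain,role,name,res_id optional filters (vectors allowed)
#' @return integer indices into the topology
#' @export
select_atoms <- function(topology, chain = NULL, role = NULL, name = NULL,
                         res_id = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(chain)) keep <- keep & topology$chain %in% chain
  if (!is.null(role)) keep <- keep & topology$role %in% role
  if (!is.null(name)) keep <- keep & topology$name %in% name
  if (!is.null(res_id)) keep <- keep & topology$res_id %in% res_id
  which(keep)
}

#' Subset a topology/trajectory pair to selected atoms
#'
#' @param topology a `topology`
#' @param traj a `trajectory`
#' @param sel integer atom indices to keep
#' @return list with subsetted `topology` and `trajectory`
#' @export
subset_atoms <- function(topology, traj, sel) {
  stopifnot(length(sel) > 0)
  top <- topology[sel, , drop = FALSE]
  rownames(top) <- NULL
  class(top) <- c("topology", "data.frame")
  list(topology = top,
       trajectory = trajectory(lapply(traj$frames,
                                      function(f) f[sel, , drop = FALSE]),
                               traj$box))
}

#' Minimum-image displacement components
#'
#' @param d displacement (vector or matrix with 3 columns), nm
#' @param box length-3 orthorhombic box, nm
#' @return wrapped displacement with each component in (-L/2, L/2]
#' @export
minimum_image <- function(d, box) {
  if (is.matrix(d)) {
    sweep(d, 2, box, function(x, L) x - L * round(x / L))
  } else {
    d - box * round(d / box)
  }
}

#' Centre-of-mass distance between two selections
#'
#' The reaction coordinate of the umbrella-sampling analysis: the
#' minimum-image distance between the (mass-weighted) centroids of two
#' disjoint atom selections. Each selection is assumed whole (not wrapped
#' across the boundary); only the centroid difference is minimum-imaged.
#'
#' @param topology a `topology`
#' @param frame n x 3 coordinate matrix (nm)
#' @param sel_a,sel_b integer atom indices, non-empty and disjoint
#' @param box length-3 box (nm)
#' @param mass_weighted use atomic masses (default) or plain centroids
#' @return distance in nm
#' @export
com_distance <- function(topology, frame, sel_a, sel_b, box,
                         mass_weighted = TRUE) {
  if (length(sel_a) == 0 || length(sel_b) == 0)
    stop("empty selection in com_distance")
  if (length(intersect(sel_a, sel_b)) > 0)
    stop("selections overlap in com_distance")
  w <- if (mass_weighted) atom_masses(topology) else rep(1, nrow(topology))
  com <- function(sel) {
    colSums(frame[sel, , drop = FALSE] * w[sel]) / sum(w[sel])
  }
  d <- minimum_image(com(sel_a) - com(sel_b), box)
  sqrt(sum(d^2))
}

## ---------------------------------------------------------------- formats

parse_cryst1 <- function(line) {
  a <- as.numeric(substr(line, 7, 15))
  b <- as.numeric(substr(line, 16, 24))
  c_ <- as.numeric(substr(line, 25, 33))
  al <- as.numeric(substr(line, 34, 40))
  be <- as.numeric(substr(line, 41, 47))
  ga <- as.numeric(substr(line, 48, 54))
  if (any(abs(c(al, be, ga) - 90) > 1e-3))
    stop("triclinic boxes are not supported (CRYST1 angles != 90)")
  c(a, b, c_) * 0.1  # Angstrom -> nm
}

read_pdb_structure <- function(path) {
  lines <- readLines(path)
  cl <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cl) > 0) parse_cryst1(cl[1]) else {
    warning("no CRYST1 record; assuming a 1000 nm box", call. = FALSE)
    c(1000, 1000, 1000)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  top <- topology(name = at$elety, res_id = at$resno, res_name = at$resid,
                  chain = chain)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE) * 0.1
  })
  list(topology = top, trajectory = trajectory(frames, box))
}

write_pdb_structure <- function(topology, traj, path) {
  box_a <- traj$box[1, ] * 10
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    box_a[1], box_a[2], box_a[3], 90, 90, 90), con)
  n_frames <- length(traj$frames)
  is_het <- topology$role %in% c("water_O", "water_H", "urea_atom")
  rec <- ifelse(is_het, "HETATM", "ATOM  ")
  nm4 <- ifelse(nchar(topology$name) < 4,
                sprintf(" %-3s", topology$name),
                sprintf("%-4s", topology$name))
  for (fi in seq_len(n_frames)) {
    if (n_frames > 1) writeLines(sprintf("MODEL %8d", fi), con)
    xyz <- traj$frames[[fi]] * 10
    writeLines(sprintf(
      "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, seq_len(nrow(topology)) %% 100000, nm4,
      substr(topology$res_name, 1, 3), substr(topology$chain, 1, 1),
      topology$res_id %% 10000, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
      topology$element), con)
    if (n_frames > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

read_gro_structure <- function(path) {
  lines <- readLines(path)
  frames <- list()
  boxes <- list()
  top <- NULL
  i <- 1
  while (i <= length(lines)) {
    if (i + 1 > length(lines)) break
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(nat)) stop("malformed GRO atom count at line ", i + 1)
    if (i + 1 + nat + 1 > length(lines))
      stop("truncated GRO frame starting at line ", i)
    rows <- lines[(i + 2):(i + 1 + nat)]
    resid <- as.integer(substr(rows, 1, 5))
    resnm <- trimws(substr(rows, 6, 10))
    atnm <- trimws(substr(rows, 11, 15))
    x <- as.numeric(substr(rows, 21, 28))
    y <- as.numeric(substr(rows, 29, 36))
    z <- as.numeric(substr(rows, 37, 44))
    if (anyNA(c(x, y, z)))
      stop("malformed GRO coordinate near line ", i + 2)
    bx <- as.numeric(strsplit(trimws(lines[i + 2 + nat]), "\\s+")[[1]])
    if (length(bx) > 3 && any(abs(bx[-(1:3)]) > 1e-9))
      stop("triclinic boxes are not supported (GRO off-diagonal terms)")
    if (is.null(top)) {
      # GRO has no chain field: start a new chain whenever resid restarts
      chain_brk <- cumsum(c(TRUE, diff(resid) < 0))
      top <- topology(name = atnm, res_id = resid, res_name = resnm,
                      chain = LETTERS[pmin(chain_brk, 26)])
    } else if (nat != nrow(top)) {
      stop("atom count changes across GRO frames")
    }
    frames[[length(frames) + 1]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1]] <- bx[1:3]
    i <- i + nat + 3
  }
  if (is.null(top)) stop("no frames found in GRO file")
  list(topology = top,
       trajectory = trajectory(frames, do.call(rbind, boxes)))
}

write_gro_structure <- function(topology, traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(traj$frames)) {
    writeLines(sprintf("pmfsolv frame %d", fi), con)
    writeLines(sprintf("%5d", nrow(topology)), con)
    xyz <- traj$frames[[fi]]
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       topology$res_id %% 100000,
                       substr(topology$res_name, 1, 5),
                       substr(topology$name, 1, 5),
                       seq_len(nrow(topology)) %% 100000,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[fi, 1],
                       traj$box[fi, 2], traj$box[fi, 3]), con)
  }
  invisible(path)
}

read_extxyz_structure <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); top <- NULL
  i <- 1
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed extxyz atom count at line ", i)
    comment <- lines[i + 1]
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]*"', comment))
    if (length(lat) == 0) stop("extxyz comment lacks Lattice at line ", i + 1)
    lv <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
    if (length(lv) != 9) stop("Lattice must have 9 components, line ", i + 1)
    off <- lv[-c(1, 5, 9)]
    if (any(abs(off) > 1e-9))
      stop("triclinic boxes are not supported (extxyz Lattice off-diagonal)")
    box <- lv[c(1, 5, 9)] * 0.1
    rows <- lines[(i + 2):(i + 1 + nat)]
    parts <- strsplit(trimws(rows), "\\s+")
    ncol_row <- length(parts[[1]])
    m <- matrix(unlist(parts), ncol = ncol_row, byrow = TRUE)
    xyz <- matrix(as.numeric(m[, 2:4]), ncol = 3) * 0.1
    if (is.null(top)) {
      if (ncol_row >= 8) {
        top <- topology(name = m[, 5], res_id = as.integer(m[, 7]),
                        res_name = m[, 6], chain = m[, 8], element = m[, 1])
      } else {
        top <- topology(name = m[, 1], res_id = seq_len(nat),
                        res_name = "UNK", chain = "A", element = m[, 1])
      }
    } else if (nat != nrow(top)) {
      stop("atom count changes across extxyz frames")
    }
    frames[[length(frames) + 1]] <- xyz
    boxes[[length(boxes) + 1]] <- box
    i <- i + nat + 2
  }
  list(topology = top,
       trajectory = trajectory(frames, do.call(rbind, boxes)))
}

write_extxyz_structure <- function(topology, traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  props <- paste0("Properties=species:S:1:pos:R:3:name:S:1:resname:S:1:",
                  "resid:I:1:chain:S:1")
  for (fi in seq_along(traj$frames)) {
    b <- traj$box[fi, ] * 10
    writeLines(sprintf("%d", nrow(topology)), con)
    writeLines(sprintf('Lattice="%.6f 0.0 0.0 0.0 %.6f 0.0 0.0 0.0 %.6f" %s',
                       b[1], b[2], b[3], props), con)
    xyz <- traj$frames[[fi]] * 10
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f %-4s %-4s %d %s",
                       topology$element, xyz[, 1], xyz[, 2], xyz[, 3],
                       topology$name, topology$res_name, topology$res_id,
                       topology$chain), con)
  }
  invisible(path)
}

#' Read a structure/trajectory file
#'
#' Supported dialects: PDB (via bio3d, multi-model; box from CRYST1,
#' coordinates converted to nm), GRO (fixed-column, box on the trailing
#' line, possibly multi-frame) and extended-XYZ (Lattice in the comment
#' line; positions in Angstrom). Roles are inferred from atom and residue
#' names by [infer_role()]. Only orthorhombic boxes are supported.
#'
#' @param path input file
#' @param format one of "auto", "pdb", "gro", "extxyz"
#' @return list with elements `topology` and `trajectory`
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro", "extxyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     pdb = "pdb", gro = "gro", xyz = "extxyz",
                     extxyz = "extxyz",
                     stop("cannot infer format from extension of ", path))
  }
  switch(format,
         pdb = read_pdb_structure(path),
         gro = read_gro_structure(path),
         extxyz = read_extxyz_structure(path))
}

#' Write a structure/trajectory file
#'
#' @param topology a `topology`
#' @param traj a `trajectory`
#' @param path output file
#' @param format one of "pdb", "gro", "extxyz"
#' @return `path`, invisibly
#' @export
write_structure <- function(topology, traj, path,
                            format = c("pdb", "gro", "extxyz")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory"), nrow(topology) == traj$n_atoms)
  switch(format,
         pdb = write_pdb_structure(topology, traj, path),
         gro = write_gro_structure(topology, traj, path),
         extxyz = write_extxyz_structure(topology, traj, path))
  invisible(path)
}

## ------------------------------------------------------- umbrella windows

#' Construct an umbrella window
#'
#' @param center bias centre xi0 in nm
#' @param k spring constant in kJ mol^-1 nm^-2 (>= 0)
#' @param samples reaction-coordinate series in nm, non-empty and finite
#' @param temperature kelvin
#' @return an `umbrella_window`
#' @export
umbrella_window <- function(center, k, samples, temperature = 298) {
  stopifnot(is.numeric(center), length(center) == 1, is.finite(center),
            is.numeric(k), k >= 0, temperature > 0)
  samples <- as.numeric(samples)
  if (length(samples) == 0 || !all(is.finite(samples)))
    stop("window samples must be non-empty and finite")
  structure(list(center = center, k = k, samples = samples,
                 temperature = temperature), class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("umbrella window: xi0 = %.4g nm, k = %.4g kJ/mol/nm^2, %d samples, T = %g K\n",
              x$center, x$k, length(x$samples), x$temperature))
  invisible(x)
}

#' Read an umbrella-window sample series
#'
#' Plain-text two-column layout (time, xi in nm); comment lines starting
#' with `#` or `@` are skipped. Header comments must carry the bias centre
#' and spring constant, e.g. `# center 0.50` and `# k 5000`
#' (kJ mol^-1 nm^-2); `# temperature 298` is optional.
#'
#' @param path input file
#' @return an `umbrella_window`
#' @export
read_window_series <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^[#@]", lines)]
  get_meta <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "\\s+[-0-9.eE+]+"), hdr))
    m <- m[lengths(m) > 0 | nchar(m) > 0]
    if (length(m) == 0) return(NA_real_)
    as.numeric(strsplit(m[[1]], "\\s+")[[1]][2])
  }
  center <- get_meta("center")
  k <- get_meta("\\bk")
  temperature <- get_meta("temperature")
  if (is.na(center) || is.na(k))
    stop("window header must carry 'center' and 'k' metadata: ", path)
  if (is.na(temperature)) temperature <- 298
  dat <- lines[!grepl("^[#@]", lines) & nzchar(trimws(lines))]
  if (length(dat) == 0) stop("window file has no data rows: ", path)
  vals <- lapply(strsplit(trimws(dat), "\\s+"), as.numeric)
  xi <- vapply(vals, function(v) v[min(2, length(v))], 1.0)
  umbrella_window(center, k, xi, temperature)
}

#' Write an umbrella-window sample series
#'
#' @param window an `umbrella_window`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_window_series <- function(window, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# center %.10g", window$center),
               sprintf("# k %.10g", window$k),
               sprintf("# temperature %.10g", window$temperature)), con)
  writeLines(sprintf("%d\t%.8g", seq_along(window$samples) - 1L,
                     window$samples), con)
  invisible(path)
}
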