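#' Potential of mean force by the weighted histogram analysis method
#'
#' Umbrella-sampling windows (harmonic restraints at spaced centres along
#' the peptide-peptide COM separation) are combined into one unbiased
#' free-energy profile W(xi) by iterating the WHAM equations to
#' self-consistency. The radial Jacobian of the COM coordinate is removed
#' by adding 2RT ln(xi) (the entropy correction) and the profile is
#' shifted to zero free energy at the longest separations. Errors come
#' from a Bayesian bootstrap that reweights whole windows with
#' Dirichlet(1, ..., 1) weights.
#'
#' @name umbrella_wham
NULL

new_pmf_profile <- function(xi, w, err, n_eff, temperature, f_offsets = NULL,
                            corrected = FALSE, shifted = FALSE,
                            convergence = NULL) {
  stopifnot(!is.unsorted(xi, strictly = TRUE), all(err >= 0 | is.na(err)))
  structure(list(xi = xi, w = w, err = err, n_eff = n_eff,
                 temperature = temperature, f_offsets = f_offsets,
                 corrected = corrected, shifted = shifted,
                 convergence = convergence),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d bins, xi in [%.3g, %.3g] nm, T = %g K\n",
              length(x$xi), min(x$xi), max(x$xi), x$temperature))
  cat(sprintf("  entropy-corrected: %s; tail-shifted: %s\n",
              x$corrected, x$shifted))
  if (!is.null(x$convergence))
    cat(sprintf("  WHAM: %d iterations, residual %.3g kT\n",
                x$convergence$iterations, x$convergence$residual))
  bd <- binding_depth(x, check_prepared = FALSE)
  cat(sprintf("  minimum: W(%.3g nm) = %.4g kJ/mol%s\n", bd$xi_min, bd$w_min,
              if (bd$repulsive) " [repulsive profile]" else ""))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  has_err <- any(is.finite(x$err))
  ylim <- range(c(x$w - ifelse(is.na(x$err), 0, x$err),
                  x$w + ifelse(is.na(x$err), 0, x$err)), finite = TRUE)
  plot(x$xi, x$w, type = "l", xlab = expression(xi ~ "(nm)"),
       ylab = "W (kJ/mol)", ylim = ylim, ...)
  if (has_err) {
    ok <- is.finite(x$err)
    graphics::polygon(c(x$xi[ok], rev(x$xi[ok])),
                      c(x$w[ok] - x$err[ok], rev(x$w[ok] + x$err[ok])),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(x$xi, x$w)
  }
  invisible(x)
}

# Shared histogramming for a window set: common grid, per-window counts.
wham_histogram <- function(windows, bin_width) {
  all_xi <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(all_xi) / bin_width) * bin_width
  hi <- ceiling(max(all_xi) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  centers <- edges[-length(edges)] + bin_width / 2
  counts <- t(vapply(windows, function(w) {
    h <- findInterval(w$samples, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    tabulate(h, nbins = length(centers))
  }, numeric(length(centers))))
  list(edges = edges, centers = centers, counts = counts)
}

check_window_overlap <- function(counts) {
  nw <- nrow(counts)
  if (nw == 1) return(invisible(TRUE))
  occ <- counts > 0
  adj <- (occ %*% t(occ)) > 0
  seen <- rep(FALSE, nw); queue <- 1L; seen[1] <- TRUE
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (!all(seen)) {
    stop("window overlap graph is disconnected; no histogram overlap ",
         "between window groups {", paste(which(seen), collapse = ","),
         "} and {", paste(which(!seen), collapse = ","), "}")
  }
  invisible(TRUE)
}

# Core self-consistent iteration. counts: windows x bins; u: windows x bins
# bias energies in kT; g: window weights (mean 1 for the unweighted case).
wham_core <- function(counts, u, g, tol, max_iter) {
  B <- exp(-u)
  a <- g * rowSums(counts)            # weighted window sample sizes
  cbar <- colSums(counts * g)         # weighted bin counts
  f <- rep(0, nrow(counts))
  for (it in seq_len(max_iter)) {
    denom <- colSums(B * (a * exp(f)))
    p <- ifelse(denom > 0, cbar / denom, 0)
    p <- p / sum(p)
    f_new <- -log(as.numeric(B %*% p))
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tol) {
      return(list(p = p, f = f, iterations = it, residual = resid))
    }
  }
  stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kT)",
               max_iter, resid))
}

#' Solve the WHAM equations for a set of umbrella windows
#'
#' Iterates p_j proportional to sum_i n_ij / sum_i N_i exp(f_i - u_i(xi_j)),
#' f_i = -kT ln sum_j p_j exp(-u_i(xi_j)) (all in kT internally) until the
#' largest change in any window offset f_i falls below `tol` kT. Bins with
#' zero total counts are excluded from the returned profile rather than
#' assigned infinite free energy. The profile is defined up to a constant
#' (see [shift_to_zero_tail()]).
#'
#' @param windows list of [umbrella_window()] objects sharing one
#'   temperature, with a connected histogram-overlap graph
#' @param bin_width histogram bin width in nm
#' @param tol convergence tolerance on the window offsets, in kT
#' @param max_iter iteration cap
#' @param weights optional per-window Bayesian-bootstrap weights (mean 1)
#' @return a `pmf_profile` (uncorrected, unshifted) whose `f_offsets`
#'   element carries the per-window free energies in kJ/mol
#' @export
wham <- function(windows, bin_width = 0.01, tol = 1e-7, max_iter = 1e5,
                 weights = NULL) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, TRUE, "umbrella_window")))
  temps <- vapply(windows, `[[`, 1.0, "temperature")
  if (diff(range(temps)) > 1e-9)
    stop("all windows must share one temperature")
  kT <- kT_kJmol(temps[1])
  if (is.null(weights)) weights <- rep(1, length(windows))
  stopifnot(length(weights) == length(windows), all(weights >= 0))

  hist <- wham_histogram(windows, bin_width)
  check_window_overlap(hist$counts)
  centers <- hist$centers
  kvec <- vapply(windows, `[[`, 1.0, "k") / kT   # kT/nm^2
  cvec <- vapply(windows, `[[`, 1.0, "center")
  # windows x bins bias energies in kT
  u <- 0.5 * kvec * outer(cvec, centers, function(c0, x) (x - c0)^2)

  sol <- wham_core(hist$counts, u, weights, tol, max_iter)
  keep <- colSums(hist$counts) > 0 & sol$p > 0
  w_kt <- -log(sol$p[keep])
  w_kt <- w_kt - min(w_kt)
  new_pmf_profile(xi = centers[keep], w = w_kt * kT,
                  err = rep(NA_real_, sum(keep)),
                  n_eff = colSums(hist$counts)[keep],
                  temperature = temps[1],
                  f_offsets = sol$f * kT,
                  convergence = list(iterations = sol$iterations,
                                     residual = sol$residual))
}

#' Radial Jacobian (entropy) correction of a COM-distance PMF
#'
#' Adds 2RT ln(xi) to the profile, removing the r^2 growth of the sampling
#' volume along a radial COM coordinate. xi is taken in nm with an implicit
#' 1 nm reference length; the additive constant this choice leaves behind
#' is absorbed by the tail shift.
#'
#' @param profile a `pmf_profile` with all xi > 0
#' @param temperature kelvin; defaults to the profile's temperature
#' @return corrected `pmf_profile` (errors unchanged)
#' @export
entropy_correct <- function(profile, temperature = profile$temperature) {
  stopifnot(inherits(profile, "pmf_profile"))
  if (any(profile$xi <= 0))
    stop("entropy correction needs xi > 0 everywhere")
  profile$w <- profile$w + entropy_correction_term(profile$xi, temperature)
  profile$corrected <- TRUE
  profile
}

#' The 2RT ln(xi) correction term itself
#'
#' @param xi COM separation(s) in nm, > 0
#' @param temperature kelvin
#' @return correction in kJ/mol
#' @export
entropy_correction_term <- function(xi, temperature = 298) {
  if (any(xi <= 0)) stop("xi must be > 0")
  2 * GAS_CONSTANT_KJ * temperature * log(xi)
}

#' Shift a PMF to zero free energy at the longest separations
#'
#' Subtracts the mean of W over the last `tail_fraction` of the grid
#' (or the single last point), so the tail mean (or last point) becomes
#' exactly zero. Idempotent; interior differences are preserved.
#'
#' @param profile a `pmf_profile`
#' @param tail_fraction fraction of trailing bins to average over,
#'   in (0, 0.5]
#' @param use_last_point use only the final grid point instead of a tail
#'   average
#' @return shifted `pmf_profile`
#' @export
shift_to_zero_tail <- function(profile, tail_fraction = 0.1,
                               use_last_point = FALSE) {
  stopifnot(inherits(profile, "pmf_profile"),
            tail_fraction > 0, tail_fraction <= 0.5)
  n <- length(profile$w)
  m <- if (use_last_point) 1L else max(1L, ceiling(tail_fraction * n))
  shift <- mean(profile$w[(n - m + 1):n])
  profile$w <- profile$w - shift
  profile$shifted <- TRUE
  profile
}

#' Bayesian-bootstrap errors for a WHAM profile
#'
#' Each replicate draws Dirichlet(1, ..., 1) weights over whole windows
#' (windows, not frames, are the resampling unit because frames within a
#' window are autocorrelated), reruns WHAM and re-applies the entropy
#' correction and tail shift. The per-bin standard deviation across
#' replicates is the error. A replicate whose WHAM fails is dropped with a
#' warning; at least 80% must succeed.
#'
#' @inheritParams wham
#' @param n_boot number of replicates (>= 2)
#' @param seed integer seed (replicates are deterministic given the seed)
#' @param entropy apply [entropy_correct()] per replicate
#' @param tail_fraction,use_last_point passed to [shift_to_zero_tail()]
#' @return list with `err` (per-bin SE, aligned to the base WHAM grid) and
#'   `xi`
#' @export
bayesian_bootstrap <- function(windows, bin_width = 0.01, n_boot = 50,
                               seed = 1, tol = 1e-7, max_iter = 1e5,
                               entropy = TRUE, tail_fraction = 0.1,
                               use_last_point = FALSE) {
  stopifnot(n_boot >= 2)
  nw <- length(windows)
  base <- wham(windows, bin_width, tol, max_iter)
  reps <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      wts <- stats::rgamma(nw, 1)
      wts <- wts / sum(wts) * nw
      tryCatch({
        p <- wham(windows, bin_width, tol, max_iter, weights = wts)
        if (entropy) p <- entropy_correct(p)
        p <- shift_to_zero_tail(p, tail_fraction, use_last_point)
        stats::approx(p$xi, p$w, xout = base$xi, rule = 1)$y
      }, error = function(e) {
        warning("bootstrap replicate ", b, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    })
  })
  ok <- !vapply(reps, is.null, TRUE)
  if (mean(ok) < 0.8)
    stop("more than 20% of bootstrap replicates failed")
  mat <- do.call(rbind, reps[ok])
  err <- apply(mat, 2, stats::sd, na.rm = TRUE)
  list(xi = base$xi, err = err, n_ok = sum(ok))
}

#' Full PMF estimation from umbrella windows
#'
#' Runs [wham()], applies the entropy correction and tail shift, and
#' attaches Bayesian-bootstrap errors.
#'
#' @inheritParams bayesian_bootstrap
#' @param entropy apply the 2RT ln(xi) correction
#' @return a corrected, shifted `pmf_profile` with errors
#' @export
pmf_from_windows <- function(windows, bin_width = 0.01, n_boot = 50,
                             seed = 1, tol = 1e-7, max_iter = 1e5,
                             entropy = TRUE, tail_fraction = 0.1,
                             use_last_point = FALSE) {
  prof <- wham(windows, bin_width, tol, max_iter)
  if (entropy) prof <- entropy_correct(prof)
  prof <- shift_to_zero_tail(prof, tail_fraction, use_last_point)
  bb <- bayesian_bootstrap(windows, bin_width, n_boot, seed, tol, max_iter,
                           entropy, tail_fraction, use_last_point)
  prof$err <- bb$err
  prof
}

#' Location and depth of the binding minimum of a PMF
#'
#' Global minimum over the grid, ties broken toward smaller xi. A profile
#' that is positive everywhere is flagged repulsive (a contact minimum
#' replaced by a repulsive state).
#'
#' @param profile a corrected, shifted `pmf_profile`
#' @param check_prepared insist that the profile has been shifted
#' @return list with `xi_min` (nm), `w_min` (kJ/mol) and logical
#'   `repulsive`
#' @export
binding_depth <- function(profile, check_prepared = TRUE) {
  stopifnot(inherits(profile, "pmf_profile"))
  if (check_prepared && !profile$shifted)
    warning("profile has not been tail-shifted; depth is gauge-dependent")
  i <- which.min(profile$w)   # which.min returns the first (smallest xi) tie
  list(xi_min = profile$xi[i], w_min = profile$w[i],
       repulsive = all(profile$w > 0))
}

#' Write a PMF profile as TSV
#'
#' Columns xi, w, err, n_eff; values rounded to 6 significant digits so
#' outputs are byte-stable across platforms.
#'
#' @param profile a `pmf_profile`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pmf <- function(profile, path) {
  df <- data.frame(xi = signif(profile$xi, 6), w = signif(profile$w, 6),
                   err = signif(profile$err, 6), n_eff = profile$n_eff)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
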