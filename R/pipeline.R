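#' Pipeline orchestration: configuration and the synthetic demo
#'
#' `run_demo()` exercises every analysis stage on synthetic ground truth
#' (harmonic umbrella windows, Crooks work samples, a xi-series of dimer
#' scenes, secondary-structure fixtures, an ideal-gas RDF) and asserts the
#' module-level recovery properties; `validate_config()` checks a flat
#' declarative YAML run configuration fail-closed.
#'
#' @name pipeline
NULL

CONFIG_DEFAULTS <- list(
  temperature = 298, bin_width = 0.01, tol = 1e-7, max_iter = 1e5,
  n_boot = 50, tail_fraction = 0.1, on_cutoff = 0.35, shell_radius = 0.55,
  rdf_bin_width = 0.002, seed = 1, normalization = "water_max",
  windows_dir = NULL, output_dir = NULL)

CONFIG_PATH_KEYS <- c("windows_dir", "output_dir")

#' Validate a run configuration file
#'
#' Flat YAML with keys drawn from: temperature, bin_width, tol, max_iter,
#' n_boot, tail_fraction, on_cutoff, shell_radius, rdf_bin_width, seed,
#' normalization, windows_dir, output_dir. Unknown keys are rejected
#' (fail-closed), referenced paths must exist, temperature must be
#' positive; every violation is reported in one aggregated error,
#' annotated with the line in the file where the key appears.
#'
#' @param path YAML config file
#' @return a `run_config` list with defaults filled in
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  lines <- readLines(path)
  line_of <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\s*:"), lines)
    if (length(hit) > 0) hit[1] else NA_integer_
  }
  errs <- character(0)
  add_err <- function(key, msg) {
    ln <- line_of(key)
    errs <<- c(errs, sprintf("%s%s: %s",
                             if (is.na(ln)) "" else sprintf("line %d, ", ln),
                             key, msg))
  }
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  for (k in unknown) add_err(k, "unknown key (rejected)")
  cfg <- utils::modifyList(CONFIG_DEFAULTS,
                           raw[intersect(names(raw), names(CONFIG_DEFAULTS))])
  if (!is.numeric(cfg$temperature) || cfg$temperature <= 0)
    add_err("temperature", "must be a positive number")
  for (k in c("bin_width", "tol", "tail_fraction", "on_cutoff",
              "shell_radius", "rdf_bin_width")) {
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      add_err(k, "must be a positive number")
  }
  if (cfg$tail_fraction > 0.5) add_err("tail_fraction", "must be <= 0.5")
  if (!cfg$normalization %in% c("water_max", "own_max", "none"))
    add_err("normalization", "must be water_max, own_max or none")
  for (k in CONFIG_PATH_KEYS) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      add_err(k, paste("path does not exist:", cfg[[k]]))
  }
  if (length(errs) > 0)
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

demo_stage <- function(report, name, params, fun) {
  t0 <- proc.time()["elapsed"]
  out <- fun()
  report$stages[[name]] <- list(status = "ok", parameters = params,
                                seconds = signif(proc.time()["elapsed"] - t0,
                                                 4))
  list(report = report, value = out)
}

#' Run the end-to-end synthetic demo
#'
#' Generates the harmonic umbrella fixture, the Crooks work fixture, a
#' xi-series of dimer scenes and the secondary-structure fixtures; runs
#' every analysis stage; asserts each module's recovery property against
#' its analytic ground truth; and writes all per-figure tables (TSV, values
#' rounded to 6 significant digits) plus a JSON run report to `out_dir`.
#' Deterministic for a fixed seed: rerunning yields byte-identical tables.
#'
#' @param seed integer seed driving every stochastic stage
#' @param out_dir output directory (created if needed)
#' @return a `run_report` (invisibly) with per-stage status, parameters,
#'   timings and output checksums
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("pmfsolv_demo_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = seed, stages = list())
  kT <- kT_kJmol(298)

  ## stage 1: umbrella sampling + WHAM on the harmonic fixture
  k_true <- 10; k_bias <- 100; n_win <- 2000
  centers <- seq(-1, 1, by = 0.1)
  pot <- analytic_potential("harmonic", k = k_true)
  st <- demo_stage(report, "pmf",
                   list(k = k_true, bias_k = k_bias, n_per_window = n_win,
                        centers = range(centers)), function() {
    windows <- lapply(seq_along(centers), function(i) {
      sample_umbrella_window(pot, centers[i], k_bias, n_win,
                             seed = seed * 1000 + i)
    })
    prof <- wham(windows, bin_width = 0.01)
    prof <- shift_to_zero_tail(prof, 0.1)
    bb <- bayesian_bootstrap(windows, bin_width = 0.01, n_boot = 20,
                             seed = seed, entropy = FALSE)
    prof$err <- bb$err
    keep <- prof$n_eff >= 10
    w_kt <- prof$w[keep] / kT
    ref <- 0.5 * k_true * prof$xi[keep]^2
    resid <- (w_kt - ref) - mean(w_kt - ref)
    rms <- sqrt(mean(resid^2))
    if (rms >= 0.15)
      stop("demo assertion failed: WHAM RMS vs analytic PMF = ",
           signif(rms, 3), " kT (expected < 0.15)")
    list(profile = prof, rms_kt = rms)
  })
  report <- st$report
  pmf_res <- st$value
  write_pmf(pmf_res$profile, file.path(out_dir, "pmf.tsv"))
  bd <- binding_depth(pmf_res$profile)
  write_json_summary(list(xi_min = bd$xi_min, depth_kjmol = bd$w_min,
                          repulsive = bd$repulsive,
                          rms_vs_analytic_kt = pmf_res$rms_kt,
                          iterations = pmf_res$profile$convergence$iterations),
                     file.path(out_dir, "pmf_summary.json"))

  ## stage 2: BAR on the Crooks fixture
  st <- demo_stage(report, "bar", list(delta_g = 2, sigma = 1, n = 5000),
                   function() {
    ws <- generate_work_samples(work_sample_spec(2, 1, 5000, 5000,
                                                 seed = seed + 17))
    fit <- bar_pair(lambda_pair(ws$forward, ws$reverse))
    if (abs(fit$df - 2) >= 3 * fit$se)
      stop("demo assertion failed: BAR estimate ", signif(fit$df, 4),
           " kT outside 3 SE of the true 2 kT")
    fit
  })
  report <- st$report
  bar_fit_res <- st$value
  write_json_summary(list(dF_kt = bar_fit_res$df, se_kt = bar_fit_res$se,
                          dG_kjmol = kt_to_kjmol(bar_fit_res$df),
                          true_kt = 2),
                     file.path(out_dir, "bar.json"))

  ## stage 3: dimer scenes -> hydration/urea maps, O-N map, Rg
  seps <- c(0.9, 1.4, 2.0, 2.7)
  n_res <- 11
  water_targets <- sapply(seps, function(s) {
    base <- c(4, rep(2, n_res - 2), 4)          # termini stay hydrated
    dehyd <- round(base + 3 * min(s / 2.7, 1))  # contact strips the shell
    dehyd
  })
  urea_targets <- sapply(seps, function(s) {
    round(c(1, rep(0, n_res - 2), 1) + 2 * min(s / 2.7, 1))
  })
  st <- demo_stage(report, "maps",
                   list(separations = seps, shell_radius = 0.55),
                   function() {
    scenes <- lapply(seq_along(seps), function(i) {
      build_dimer_scene(dimer_scene_spec(
        com_separation = seps[i], n_residues = n_res,
        water_targets = water_targets[, i], urea_targets = urea_targets[, i],
        glycine_residues = c(6), seed = seed * 100 + i))
    })
    wmap <- scene_series_map(scenes, solvent = "water",
                             normalize = "water_max")
    umap <- scene_series_map(scenes, solvent = "urea",
                             normalize = "own_max")
    expected_w <- sweep(water_targets, 1,
                        apply(water_targets, 1, max), "/")
    if (max(abs(wmap$values - expected_w)) > 1e-9)
      stop("demo assertion failed: hydration map != generator profile")
    pep <- lapply(scenes, function(sc) {
      sel <- which(sc$topology$chain %in% c("A", "B"))
      subset_atoms(sc$topology, sc$trajectory, sel)
    })
    ptraj <- trajectory(lapply(pep, function(p) p$trajectory$frames[[1]]),
                        do.call(rbind, lapply(pep,
                                              function(p) p$trajectory$box)))
    onmap <- on_neighbor_map(pep[[1]]$topology, ptraj, xi = seps)
    rg <- radius_of_gyration(pep[[1]]$topology, ptraj,
                             select_atoms(pep[[1]]$topology, chain = "A"))
    list(wmap = wmap, umap = umap, onmap = onmap, rg = rg)
  })
  report <- st$report
  maps <- st$value
  write_residue_map(maps$wmap, file.path(out_dir, "hydration_map.tsv"))
  write_residue_map(maps$umap, file.path(out_dir, "urea_map.tsv"))
  write_residue_map(maps$onmap, file.path(out_dir, "on_neighbor_map.tsv"))
  utils::write.table(data.frame(xi = seps, rg = signif(maps$rg, 6)),
                     file.path(out_dir, "rg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## stage 4: secondary structure on the motif fixtures
  st <- demo_stage(report, "secondary_structure", list(n_residues = 6),
                   function() {
    fb <- generate_secondary_structure_fixture("beta_pair", 6)
    fc <- generate_secondary_structure_fixture("coil", 6)
    fg <- generate_secondary_structure_fixture("helix_310", 6)
    sb <- assign_secondary_structure(fb$topology, fb$trajectory$frames[[1]])
    sc <- assign_secondary_structure(fc$topology, fc$trajectory$frames[[1]])
    sg <- assign_secondary_structure(fg$topology, fg$trajectory$frames[[1]])
    if (!all(sb$class == "E"))
      stop("demo assertion failed: beta_pair fixture not classified E")
    if (!all(sc$class == "C"))
      stop("demo assertion failed: coil fixture not classified C")
    if (!all(sg$class[2:5] == "G"))
      stop("demo assertion failed: 3-10 fixture interior not classified G")
    list(beta = sb, coil = sc, helix = sg)
  })
  report <- st$report
  ssr <- st$value
  writeLines(c(paste("beta_pair:", paste(ss_string(ssr$beta),
                                         collapse = " ")),
               paste("helix_310:", paste(ss_string(ssr$helix),
                                         collapse = " ")),
               paste("coil:", paste(ss_string(ssr$coil), collapse = " "))),
             file.path(out_dir, "secondary_structure.txt"))

  ## stage 5: ideal-gas RDF and coordination number
  st <- demo_stage(report, "rdf", list(n_solvent = 2000, n_frames = 50),
                   function() {
    box <- c(6, 6, 6)
    n_sol <- 2000
    top <- topology(name = c("CA", rep("OW", n_sol)),
                    res_id = c(1, 1 + seq_len(n_sol)),
                    res_name = c("ALA", rep("HOH", n_sol)),
                    chain = c("A", rep("S", n_sol)))
    frames <- with_seed(seed + 31, lapply(seq_len(50), function(i) {
      rbind(box / 2, matrix(stats::runif(3 * n_sol) * box[1],
                            ncol = 3, byrow = TRUE))
    }))
    traj <- trajectory(frames, box)
    rr <- rdf(top, traj, sel_a = 1, sel_b = 1 + seq_len(n_sol),
              r_max = 2.5, bin_width = 0.02)
    cn <- coordination_number(rr, 1.0)
    cn_ideal <- 4 / 3 * pi * 1^3 * rr$density
    if (abs(cn / cn_ideal - 1) > 0.02)
      stop("demo assertion failed: ideal-gas CN off by ",
           signif(abs(cn / cn_ideal - 1) * 100, 3), "%")
    list(rdf = rr, cn = cn, cn_ideal = cn_ideal)
  })
  report <- st$report
  rdfr <- st$value
  utils::write.table(data.frame(r = signif(rdfr$rdf$r, 6),
                                g = signif(rdfr$rdf$g, 6)),
                     file.path(out_dir, "rdf.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  outputs <- list.files(out_dir, full.names = TRUE)
  report$checksums <- as.list(tools::md5sum(outputs))
  names(report$checksums) <- basename(outputs)
  write_json_summary(report, file.path(out_dir, "run_report.json"))
  report$output_dir <- out_dir
  class(report) <- "run_report"
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("pmfsolv demo run (seed %d): %d stages in %s\n", x$seed,
              length(x$stages), x$output_dir))
  for (nm in names(x$stages)) {
    cat(sprintf("  %-20s %s (%.3g s)\n", nm, x$stages[[nm]]$status,
                x$stages[[nm]]$seconds))
  }
  invisible(x)
}

#' Solvation map across a series of dimer scenes
#'
#' Scenes built at different xi generally contain different numbers of
#' solvent beads, so they cannot share one trajectory; this helper counts
#' per scene (via [hydration_map()] with `normalize = "none"`) and then
#' assembles and normalises the combined residue x xi map.
#'
#' @param scenes list of [build_dimer_scene()] results, ordered by their
#'   `com_separation`
#' @param solvent "water" or "urea"
#' @param shell_radius first-shell radius (nm); defaults to each scene's
#'   spec value
#' @param normalize,norm_constants as in [hydration_map()]
#' @return a `residue_map`
#' @export
scene_series_map <- function(scenes, solvent = c("water", "urea"),
                             shell_radius = NULL,
                             normalize = c("water_max", "own_max", "none"),
                             norm_constants = NULL) {
  solvent <- match.arg(solvent)
  normalize <- match.arg(normalize)
  cols <- lapply(scenes, function(sc) {
    r <- if (is.null(shell_radius)) sc$spec$shell_radius else shell_radius
    m <- hydration_map(sc$topology, sc$trajectory,
                       xi = sc$spec$com_separation, solvent = solvent,
                       shell_radius = r, normalize = "none")
    m$values[, 1]
  })
  raw <- do.call(cbind, cols)
  xi <- vapply(scenes, function(sc) sc$spec$com_separation, 1.0)
  res_ids <- seq_len(nrow(raw))
  ord <- order(xi)
  raw <- raw[, ord, drop = FALSE]
  xi <- xi[ord]
  consts <- switch(normalize,
    none = rep(1, nrow(raw)),
    own_max = apply(raw, 1, max),
    water_max = if (is.null(norm_constants)) apply(raw, 1, max)
                else rep_len(norm_constants, nrow(raw)))
  consts[consts == 0] <- 1
  vals <- if (normalize == "none") raw else raw / consts
  new_residue_map(vals, res_ids, xi, normalize,
                  if (normalize == "none") NULL else consts)
}
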