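#' Default pipeline configuration
#'
#' All analysis parameters with their standard defaults: correlation-web
#' threshold 0.3, density grid spacing 0.5 Angstrom with the 6-8 Angstrom
#' bulk shell, essential-space fraction 0.90, build/validation split
#' fraction 0.9, H-bond cutoffs 3.5 Angstrom / 30 degrees, SASA probe
#' 1.4 Angstrom.  Unknown keys passed to [run_pipeline()] are rejected
#' before any computation.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    input_pdb = NULL,          # multi-model PDB trajectory; NULL = synthetic demo
    selection = "name CA",     # analysis selection
    web_threshold = 0.3,
    neighbor_exclusion = 2,
    grid_spacing = 0.5,
    bulk_shell = c(6, 8),
    fma_fraction = 0.90,
    split_fraction = 0.9,
    hbond_dcut = 3.5,
    hbond_angcut = 30,
    sasa_probe = 1.4,
    sasa_stride = 1,
    stages = c("fit", "ed", "web", "sasa", "fma", "solvent", "features"),
    demo_n_residues = 20,
    demo_n_frames = 200,
    demo_n_waters = 400,
    seed = 1L,
    output_dir = NULL
  )
}

#' Run the full trajectory-analysis pipeline
#'
#' Executes superposition, essential dynamics, correlation web, SASA
#' series, functional mode analysis, solvent density/hydration scoring
#' and geometric features on a user trajectory (multi-model PDB) or on a
#' built-in synthetic demo system, writing a JSON report, TSV data files
#' and a manifest of outputs.  Deterministic under a fixed `seed`.
#'
#' @param config a list overriding entries of [default_config()], or the
#'   path to a YAML file with such entries.
#' @return the report, invisibly (a nested list); files are written to
#'   `config$output_dir` when set.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  stages <- cfg$stages
  report <- list(config = cfg[setdiff(names(cfg), "output_dir")])
  outdir <- cfg$output_dir
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  emit <- function(name, writer) {
    if (is.null(outdir)) return(invisible(NULL))
    path <- file.path(outdir, name)
    writer(path)
    path
  }
  artifacts <- character(0)

  # input: user trajectory or synthetic demo
  waters <- NULL
  if (!is.null(cfg$input_pdb)) {
    traj <- read_pdb(cfg$input_pdb)
  } else {
    st <- gen_chain(cfg$demo_n_residues, "helix")
    modes <- random_modes(st, 2, seed = cfg$seed)
    traj <- gen_mode_trajectory(st, modes, amplitudes = c(1.5, 0.8),
                                noise_sigma = 0.1,
                                n_frames = cfg$demo_n_frames, seed = cfg$seed)
    waters <- gen_solvated_frames(st, cfg$demo_n_waters, n_frames = 20,
                                  hotspots = list(list(atom = 1L, sigma = 0.8,
                                                       weight = 0.08)),
                                  seed = cfg$seed + 1L)
  }
  sel <- select_atoms(traj$structure, cfg$selection)
  if (!length(sel)) stop("stage fit: empty analysis selection")

  fitted <- traj
  if ("fit" %in% stages) {
    fitted <- fit_trajectory(traj, selection = sel)
    rf <- rmsf(fitted, sel)
    report$fit <- list(rmsd = unname(attr(fitted, "rmsd")), rmsf = unname(rf))
    artifacts <- c(artifacts, emit("rmsf.tsv", function(p)
      write_series_tsv(seq_along(rf), rf, p, names = "rmsf")))
  }

  basis <- NULL
  if ("ed" %in% stages) {
    cv <- covariance_matrix(fitted, sel)
    basis <- pca_modes(cv)
    proj <- project_modes(fitted, basis, k = seq_len(min(5L, length(basis$values))),
                          selection = sel)
    report$ed <- list(variance_fractions = unname(variance_fractions(basis)),
                      projections_head = utils::head(proj))
    artifacts <- c(artifacts, emit("projections.tsv", function(p)
      write_series_tsv(fitted$times, proj, p, names = colnames(proj))))
  }

  if ("web" %in% stages) {
    cc <- dccm(fitted, sel)
    web <- correlation_web(cc, threshold = cfg$web_threshold,
                           neighbor_exclusion = cfg$neighbor_exclusion,
                           nodes = traj$structure$atoms$resid[sel])
    report$web <- list(n_edges = nrow(web$edges))
    artifacts <- c(artifacts, emit("web.tsv", function(p) write_web_tsv(web, p)))
  }

  sasa_vals <- NULL
  if ("sasa" %in% stages) {
    heavy <- select_atoms(traj$structure, "heavy")
    sasa_vals <- sasa_series(fitted, heavy, probe = cfg$sasa_probe,
                             stride = cfg$sasa_stride)
    report$sasa <- list(mean = mean(sasa_vals), sd = stats::sd(sasa_vals))
    artifacts <- c(artifacts, emit("sasa.tsv", function(p)
      write_series_tsv(attr(sasa_vals, "times"), as.numeric(sasa_vals), p,
                       names = "sasa")))
  }

  if ("fma" %in% stages && !is.null(basis) && !is.null(sasa_vals) &&
      cfg$sasa_stride == 1) {
    n_ess <- essential_space_size(basis$values, cfg$fma_fraction)
    proj <- project_modes(fitted, basis, k = seq_len(n_ess), selection = sel)
    model <- fit_mcm(proj, as.numeric(sasa_vals),
                     split = floor(cfg$split_fraction * n_frames(fitted)))
    contrib <- pc_contributions(model)
    report$fma <- list(n = n_ess, r_build = model$r_build, r_cv = model$r_cv,
                       pc_var_fractions = unname(contrib$fractions),
                       argmax_pc = contrib$argmax)
  }

  if ("solvent" %in% stages && !is.null(waters)) {
    heavy <- select_atoms(traj$structure, "heavy")
    dm <- density_map(traj$structure$xyz[heavy, , drop = FALSE], waters,
                      spacing = cfg$grid_spacing, shell = cfg$bulk_shell)
    sites <- hydration_sites(dm)
    scores <- hydration_score(sites, traj$structure, heavy)
    report$solvent <- list(n_sites = nrow(sites),
                           max_g = if (nrow(sites)) max(sites$g) else NA_real_,
                           mean_score = mean(scores))
    artifacts <- c(artifacts, emit("density.dx", function(p) write_dx(dm, p)))
  }

  if ("features" %in% stages) {
    ss <- assign_ss(traj$structure, coords = frame_coords(traj, 1))
    report$features <- list(ss = unname(ss), ss_counts = as.list(table(ss)))
  }

  if (!is.null(outdir)) {
    report_path <- file.path(outdir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    artifacts <- c(artifacts, report_path)
    manifest <- data.frame(
      file = basename(unlist(artifacts)),
      md5 = vapply(unlist(artifacts), function(p) unname(tools::md5sum(p)), ""),
      row.names = NULL)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         pretty = TRUE)
  }
  invisible(report)
}
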