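pipeline_defaults <- function() {
  list(
    seed = 1L,
    temperature = 300,
    out_dir = "bendrc_run",
    separation = list(d = 5L, n_scans = 500L, n_vectors = 2000L,
                      model = "gaussian"),
    fma = list(k_max = 10L, split = "half", tol = 0.005),
    wham = list(bins = 100L, n_boot = 50L, tol = 1e-7),
    basins = list(split = "auto")
  )
}

known_config_keys <- function() {
  list(top = c("seed", "temperature", "out_dir", "ensembles", "separation",
               "fma", "wham", "basins"),
       ensembles = c("fixture_dir", "ens_a", "ens_b", "pdb_a", "pdb_b",
                     "mask_spec", "reference"),
       separation = c("d", "n_scans", "n_vectors", "model"),
       fma = c("k_max", "split", "tol"),
       wham = c("windows_manifest", "bins", "n_boot", "tol",
                "spring_k_unit"),
       basins = c("split"))
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), fills in
#' defaults (500 scans x 2000 vectors for the separation search, 300 K,
#' gaussian density model), checks that every referenced path exists,
#' rejects unknown keys, and converts spring constants given in kT/nm^2 to
#' kJ mol^-1 nm^-2 at the configured temperature.
#'
#' @param config path to a YAML file, or a configuration list.
#' @return the normalized configuration list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_input("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  keys <- known_config_keys()
  problems <- character()
  unknown <- setdiff(names(config), keys$top)
  if (length(unknown))
    problems <- c(problems, paste("unknown top-level keys:",
                                  paste(unknown, collapse = ", ")))
  for (sec in c("ensembles", "separation", "fma", "wham", "basins")) {
    if (!is.null(config[[sec]])) {
      bad <- setdiff(names(config[[sec]]), keys[[sec]])
      if (length(bad))
        problems <- c(problems, paste0("unknown keys in ", sec, ": ",
                                       paste(bad, collapse = ", ")))
    }
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (cfg$separation$n_scans < 1 || cfg$separation$n_vectors < 1)
    problems <- c(problems, "separation scan/vector counts must be >= 1")
  if (cfg$temperature <= 0)
    problems <- c(problems, "temperature must be positive (Kelvin)")
  ens <- cfg$ensembles
  for (key in c("fixture_dir", "ens_a", "ens_b", "windows_manifest")) {
    pth <- ens[[key]] %||% cfg$wham[[key]]
    if (!is.null(pth) && !file.exists(pth))
      problems <- c(problems, paste0("missing path for ", key, ": ", pth))
  }
  if (length(problems))
    stop_input("invalid configuration:\n  ",
               paste(problems, collapse = "\n  "))
  # spring constants supplied in kT/nm^2 are converted once, here
  if (identical(cfg$wham$spring_k_unit, "kT")) {
    cfg$wham$spring_k_factor <- kT_kJmol(cfg$temperature)
    cfg$wham$spring_k_unit <- "kJ/mol"
  } else {
    cfg$wham$spring_k_factor <- 1
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full ensemble-analysis pipeline
#'
#' Executes, in order: ensemble loading (from a fixture bundle written by
#' [write_fixture_set] or from configured flat-ensemble files), PCA of the
#' combined ensemble, projection, the ensemble-separation search, PLS
#' functional mode analysis of the RMSD to a reference conformation, WHAM
#' reconstruction of the umbrella windows with bootstrap errors, and basin
#' analysis. Every stage writes its artifact under `out_dir` and the run
#' ends with a machine-readable `summary.json`.
#'
#' @param config a `pipeline_config` from [validate_config] (or a path /
#'   list, validated on the fly).
#' @return the summary list, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf("[bendrc] %s", sprintf(...)))
  summary <- list(seed = cfg$seed, temperature = cfg$temperature)
  t0 <- Sys.time()

  # --- stage 1: ensembles -------------------------------------------------
  ens <- cfg$ensembles
  if (!is.null(ens$fixture_dir)) {
    fa <- read_flat_ensemble(file.path(ens$fixture_dir, "gauss_ens1.tsv"))
    fb <- read_flat_ensemble(file.path(ens$fixture_dir, "gauss_ens2.tsv"))
    wm <- file.path(ens$fixture_dir, "window_manifest.tsv")
  } else {
    fa <- read_flat_ensemble(ens$ens_a)
    fb <- read_flat_ensemble(ens$ens_b)
    wm <- cfg$wham$windows_manifest
  }
  log_msg("loaded ensembles: %d + %d frames, %d coordinates",
          nrow(fa$X), nrow(fb$X), ncol(fa$X))

  # --- stage 2: PCA -------------------------------------------------------
  combined <- flat_ensemble(rbind(fa$X, fb$X))
  basis <- compute_pca(combined)
  vf <- variance_fractions(basis)
  summary$pca <- list(n_modes = length(basis$eigenvalues),
                      variance_fraction_1 = vf[1])
  proj <- project(combined, basis, seq_len(min(2, length(vf))))
  write_projection(proj, file.path(cfg$out_dir, "pca_projection.tsv"))

  # --- stage 3: separation search ----------------------------------------
  sep_seed <- derive_seed(cfg$seed, 31)
  sep <- search_separation_rc(fa, fb, d = cfg$separation$d,
                              n_scans = cfg$separation$n_scans,
                              n_vectors = cfg$separation$n_vectors,
                              model = cfg$separation$model,
                              seed = sep_seed)
  utils::write.table(data.frame(coord = seq_along(sep$n_hat),
                                n_hat = sep$n_hat),
                     file.path(cfg$out_dir, "separation_vector.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  summary$separation <- list(overlap = sep$overlap_value, d = sep$d_used,
                             seed = sep_seed)
  log_msg("separation search: overlap %.4g at d = %d", sep$overlap_value,
          sep$d_used)

  # 2-D plane: separation RC x largest orthogonal motion
  ortho <- max_variance_orthogonal(combined, sep$n_hat)
  plane <- cbind(sweep(combined$X, 2, combined$mean) %*% sep$n_hat,
                 sweep(combined$X, 2, combined$mean) %*% ortho)
  utils::write.table(data.frame(frame = combined$frame_labels,
                                sep_rc = plane[, 1], ortho_rc = plane[, 2]),
                     file.path(cfg$out_dir, "separation_plane.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- stage 4: FMA -------------------------------------------------------
  reference <- if (!is.null(ens$reference)) {
    as.numeric(utils::read.table(ens$reference, header = TRUE, sep = "\t")[[2]])
  } else fa$X[1, ]
  f <- rmsd_series(combined, reference)
  fma_seed <- derive_seed(cfg$seed, 47)
  fma <- run_fma(combined$X, f, k_max = cfg$fma$k_max, split = cfg$fma$split,
                 tol = cfg$fma$tol, seed = fma_seed)
  summary$fma <- list(k = fma$k, rm = fma$rm, rv = fma$rv, seed = fma_seed)
  utils::write.table(data.frame(k = seq_along(fma$rv_by_k),
                                rm = fma$rm_by_k, rv = fma$rv_by_k),
                     file.path(cfg$out_dir, "fma_rv_curve.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  log_msg("FMA: k = %d, Rm = %.3f, Rv = %.3f", fma$k, fma$rm, fma$rv)

  # --- stage 5: free energy ----------------------------------------------
  if (!is.null(wm) && file.exists(wm)) {
    windows <- read_windows(wm)
    for (i in seq_along(windows))
      windows[[i]]$spring_k <- windows[[i]]$spring_k * cfg$wham$spring_k_factor
    boot_seed <- derive_seed(cfg$seed, 59)
    profile <- bootstrap_profile_error(windows, bins = cfg$wham$bins,
                                       temperature = cfg$temperature,
                                       n_boot = cfg$wham$n_boot,
                                       seed = boot_seed, tol = cfg$wham$tol)
    write_profile(profile, file.path(cfg$out_dir, "free_energy_profile.tsv"))
    ba <- basin_analysis(profile, split = cfg$basins$split)
    summary$free_energy <- list(
      ddg = ba$ddg, dg_basin_1 = ba$dg_basin_1, dg_basin_2 = ba$dg_basin_2,
      p_deeper = ba$p_deeper, barrier_position = ba$barrier_position,
      bootstrap_seed = boot_seed)
    log_msg("basins: ddG = %.2f kT, deeper-basin population %.4f",
            ba$ddg, ba$p_deeper)
  }

  summary$wall_time_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
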