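#' Full-run configuration
#'
#' Combines the cohort configuration with the acquisition, phantom and
#' statistics settings of a complete simulated study.
#'
#' @param cohort a [cohort_config()].
#' @param grid_dim phantom grid size in voxels (scalar).
#' @param voxel_size isotropic voxel edge, mm.
#' @param bvalue diffusion weighting, s/mm^2.
#' @param n_directions number of gradient directions.
#' @param roi_diameter ALPS ROI diameter, mm.
#' @param alpha significance level.
#' @param fwe_m family size for the Bonferroni correction.
#' @param covariates model covariate column names.
#' @param verbose log progress to stderr.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       grid_dim = 64, voxel_size = 1.8,
                       bvalue = 1000, n_directions = 64,
                       roi_diameter = 5.4,
                       alpha = 0.05, fwe_m = 3,
                       covariates = alps_covariates,
                       verbose = TRUE) {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, grid_dim = grid_dim,
                 voxel_size = voxel_size, bvalue = bvalue,
                 n_directions = n_directions, roi_diameter = roi_diameter,
                 alpha = alpha, fwe_m = fwe_m, covariates = covariates,
                 verbose = verbose),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  coh <- raw$cohort
  cohort <- cohort_config(
    group_sizes = unlist(coh$group_sizes),
    alps_mean = unlist(coh$alps_mean), alps_sd = unlist(coh$alps_sd),
    age_mean = unlist(coh$age_mean), age_sd = unlist(coh$age_sd),
    sex_male = unlist(coh$sex_male),
    education_mean = unlist(coh$education_mean),
    education_sd = unlist(coh$education_sd),
    icv_mean = unlist(coh$icv_mean), icv_sd = unlist(coh$icv_sd),
    hypertension = unlist(coh$hypertension),
    hyperlipidemia = unlist(coh$hyperlipidemia),
    fazekas_mean = unlist(coh$fazekas_mean),
    fazekas_sd = unlist(coh$fazekas_sd),
    homair_mean = unlist(coh$homair_mean),
    homair_sd = unlist(coh$homair_sd),
    fpg_mean = unlist(coh$fpg_mean), fpg_sd = unlist(coh$fpg_sd),
    ogtt_mean = unlist(coh$ogtt_mean), ogtt_sd = unlist(coh$ogtt_sd),
    hba1c_mean = unlist(coh$hba1c_mean), hba1c_sd = unlist(coh$hba1c_sd),
    alps_homair_partial_r = coh$alps_homair_partial_r,
    noise_sigma = coh$noise_sigma,
    master_seed = coh$master_seed
  )
  run_config(cohort = cohort, grid_dim = raw$grid_dim,
             voxel_size = raw$voxel_size, bvalue = raw$bvalue,
             n_directions = raw$n_directions,
             roi_diameter = raw$roi_diameter, alpha = raw$alpha,
             fwe_m = raw$fwe_m, covariates = unlist(raw$covariates),
             verbose = isTRUE(raw$verbose))
}

log_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Measure the ALPS index of one simulated subject
#'
#' Runs the per-subject imaging chain in memory: ground-truth tensor
#' field on the phantom, Stejskal-Tanner DWI simulation with Rician
#' noise, voxelwise OLS tensor fit, scalar maps, ROI extraction and the
#' ALPS index.
#'
#' @param diffusivities named vector (or left/right list) of the four
#'   ground-truth ROI diffusivities, mm^2/s (see [build_tensor_field()]).
#' @param geometry a [phantom_geometry()].
#' @param scheme an `alps_scheme`.
#' @param noise_sigma Rician noise level relative to the b = 0 signal.
#' @param seed integer noise seed.
#' @param rois ROI table; defaults to [default_roi_set()] of the
#'   geometry.
#' @return One-row tibble from [measure_alps()].
#' @export
simulate_subject_alps <- function(diffusivities, geometry, scheme,
                                  noise_sigma = 0, seed = 1L,
                                  rois = NULL) {
  rois <- rois %||% default_roi_set(geometry)
  tf <- build_tensor_field(geometry, diffusivities)
  dwi <- simulate_dwi(tf, scheme, noise_sigma = noise_sigma, seed = seed)
  fit <- fit_tensor_ols(dwi, scheme)
  maps <- compute_scalar_maps(fit)
  measure_alps(maps, rois, voxel_size = geometry$voxel_size)
}

#' Measure ALPS for every subject of a generated cohort
#'
#' Applies [simulate_subject_alps()] to each subject's ground truth and
#' returns the cohort table with the measured bilateral ALPS in the
#' `alps` column (the true index is kept as `alps_true`).
#'
#' @param cohort_obj an `alps_cohort` from [generate_cohort()].
#' @param geometry,scheme,rois phantom, acquisition and ROI settings.
#' @param noise_sigma noise level; defaults to the cohort config value.
#' @param verbose log progress.
#' @return List with `cohort` (tibble with measured `alps`) and
#'   `measurements` (per-subject wide ALPS table).
#' @export
measure_cohort_alps <- function(cohort_obj, geometry, scheme,
                                noise_sigma = NULL, rois = NULL,
                                verbose = FALSE) {
  stopifnot(inherits(cohort_obj, "alps_cohort"))
  noise_sigma <- noise_sigma %||% cohort_obj$config$noise_sigma
  rois <- rois %||% default_roi_set(geometry)
  truth <- cohort_obj$truth
  meas <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    log_msg(verbose, "measuring %s (%d/%d)", tr$subject, i, nrow(truth))
    row <- simulate_subject_alps(
      c(dxx_proj = tr$dxx_proj, dxx_assoc = tr$dxx_assoc,
        dyy_proj = tr$dyy_proj, dzz_assoc = tr$dzz_assoc),
      geometry, scheme, noise_sigma = noise_sigma, seed = tr$seed,
      rois = rois
    )
    cbind(tibble(subject = tr$subject), row)
  })
  cohort <- cohort_obj$cohort
  cohort$alps_true <- cohort$alps
  cohort$alps <- meas$alps_bilateral[match(cohort$subject, meas$subject)]
  list(cohort = cohort, measurements = meas)
}

#' Pipeline stages on disk
#'
#' `run_simulate()` writes all generator outputs (cohort TSV, ground
#' truth JSON, FSL bval/bvec, one DWI NIfTI per subject, ROI set JSON,
#' config YAML, and a manifest of MD5 hashes).  `run_fit()` fits
#' tensors and writes the Dxx/Dyy/Dzz/FA maps per subject with a JSON
#' sidecar recording element order and fit settings.  `run_alps()`
#' extracts ROI diffusivities and writes the per-subject ALPS table.
#' `run_stats()` runs the group comparison, partial correlation and
#' screening tests and writes `results.json` plus a markdown report.
#' `run_full()` chains all four.  Each stage reads only files written
#' by earlier stages, so a run is resumable from any intermediate.
#'
#' @param config a [run_config()].
#' @param dir working directory for the run.
#' @return Each stage invisibly returns the paths (or results) it
#'   produced.
#' @export
run_simulate <- function(config, dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(dir, "dwi"), recursive = TRUE, showWarnings = FALSE)
  vb <- config$verbose
  coh <- generate_cohort(config$cohort)
  geometry <- phantom_geometry(config$grid_dim, config$voxel_size)
  scheme <- make_scheme(config$n_directions, config$bvalue)
  log_msg(vb, "simulate: %d subjects, seed %d, noise %.3g",
          nrow(coh$cohort), config$cohort$master_seed,
          config$cohort$noise_sigma)

  files <- character()
  p <- function(...) file.path(dir, ...)
  readr::write_tsv(coh$cohort, p("cohort.tsv"))
  jsonlite::write_json(coh$truth, p("ground_truth.json"), digits = NA,
                       pretty = TRUE)
  write_bval_bvec(scheme, p("scheme.bval"), p("scheme.bvec"))
  write_roi_json(default_roi_set(geometry, config$roi_diameter),
                 p("rois.json"))
  write_run_config(config, p("config.yaml"))
  files <- p(c("cohort.tsv", "ground_truth.json", "scheme.bval",
               "scheme.bvec", "rois.json", "config.yaml"))
  for (i in seq_len(nrow(coh$truth))) {
    tr <- coh$truth[i, ]
    tf <- build_tensor_field(geometry, c(
      dxx_proj = tr$dxx_proj, dxx_assoc = tr$dxx_assoc,
      dyy_proj = tr$dyy_proj, dzz_assoc = tr$dzz_assoc
    ))
    dwi <- simulate_dwi(tf, scheme, noise_sigma = config$cohort$noise_sigma,
                        seed = tr$seed)
    fp <- p("dwi", paste0(tr$subject, "_dwi.nii.gz"))
    write_volume(dwi, fp, config$voxel_size)
    files <- c(files, fp)
    log_msg(vb, "simulate: wrote %s", basename(fp))
  }
  write_manifest(dir, files, config)
  invisible(files)
}

#' @rdname run_simulate
#' @export
run_fit <- function(dir) {
  config <- read_run_config(file.path(dir, "config.yaml"))
  scheme <- read_bval_bvec(file.path(dir, "scheme.bval"),
                           file.path(dir, "scheme.bvec"))
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  dwis <- sort(list.files(file.path(dir, "dwi"), pattern = "_dwi\\.nii",
                          full.names = TRUE))
  if (length(dwis) == 0) abort("stage fit-dti: no DWI volumes found; run simulate first.")
  out <- character()
  total_clamped <- 0L
  for (f in dwis) {
    sub <- sub("_dwi\\.nii(\\.gz)?$", "", basename(f))
    dwi <- read_volume(f)
    fit <- fit_tensor_ols(dwi, scheme)
    maps <- compute_scalar_maps(fit)
    for (nm in c("dxx", "dyy", "dzz", "fa")) {
      fp <- file.path(dir, "maps", sprintf("%s_%s.nii.gz", sub, nm))
      write_volume(maps[[nm]], fp, config$voxel_size)
      out <- c(out, fp)
    }
    total_clamped <- total_clamped + fit$n_clamped
    log_msg(config$verbose, "fit-dti: %s (%d clamped samples)", sub,
            fit$n_clamped)
  }
  jsonlite::write_json(
    list(element_order = c("dxx", "dxy", "dxz", "dyy", "dyz", "dzz"),
         estimator = "ols-log-linear", signal_floor = 1e-6,
         clamped_samples = total_clamped),
    file.path(dir, "maps", "fit.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out)
}

#' @rdname run_simulate
#' @export
run_alps <- function(dir) {
  config <- read_run_config(file.path(dir, "config.yaml"))
  rois <- read_roi_json(file.path(dir, "rois.json"))
  map_files <- list.files(file.path(dir, "maps"), pattern = "_dxx\\.nii")
  if (length(map_files) == 0) abort("stage alps: no scalar maps found; run fit-dti first.")
  subs <- sort(sub("_dxx\\.nii(\\.gz)?$", "", map_files))
  res <- purrr::map_dfr(subs, function(sub) {
    rd <- function(nm) read_volume(file.path(dir, "maps",
                                             sprintf("%s_%s.nii.gz", sub, nm)))
    maps <- structure(list(dxx = rd("dxx"), dyy = rd("dyy"),
                           dzz = rd("dzz"), fa = rd("fa")),
                      class = "scalar_maps")
    maps$mask <- array(TRUE, dim = dim(maps$dxx))
    cbind(tibble(subject = sub),
          measure_alps(maps, rois, voxel_size = config$voxel_size))
  })
  readr::write_tsv(res, file.path(dir, "alps.tsv"))
  log_msg(config$verbose, "alps: wrote %d subject rows", nrow(res))
  invisible(file.path(dir, "alps.tsv"))
}

#' @rdname run_simulate
#' @export
run_stats <- function(dir) {
  config <- read_run_config(file.path(dir, "config.yaml"))
  cohort <- readr::read_tsv(file.path(dir, "cohort.tsv"),
                            show_col_types = FALSE)
  cohort$group <- factor(cohort$group, levels = alps_group_levels)
  cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  alps_tab <- readr::read_tsv(file.path(dir, "alps.tsv"),
                              show_col_types = FALSE)
  cohort$alps_true <- cohort$alps
  cohort$alps <- alps_tab$alps_bilateral[match(cohort$subject,
                                               alps_tab$subject)]
  results <- analyze_cohort(cohort, covariates = config$covariates,
                            fwe_m = config$fwe_m)
  jsonlite::write_json(results_to_json(results),
                       file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(results, alpha = config$alpha),
             file.path(dir, "report.md"))
  log_msg(config$verbose, "stats: wrote results.json and report.md")
  invisible(results)
}

#' @rdname run_simulate
#' @export
run_full <- function(config, dir) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s failed: %s", name, conditionMessage(e)))
    })
  }
  stage("simulate", run_simulate(config, dir))
  stage("fit-dti", run_fit(dir))
  stage("alps", run_alps(dir))
  stage("stats", run_stats(dir))
}

#' Statistical analysis of a measured cohort
#'
#' Runs the study's statistics on a cohort table that carries an `alps`
#' column: covariate-adjusted pairwise group comparisons with
#' family-wise-error correction and Cohen's d, the ALPS/HOMA-IR partial
#' correlation over the merged Pre-DM and T2DM subjects, the VIF
#' multicollinearity screen, and the demographic comparison table.
#' Analyses whose sample sizes are insufficient (tiny test cohorts) are
#' reported as skipped rather than failing the run.
#'
#' @param cohort cohort tibble with `alps`, `group`, `homa_ir` and the
#'   covariate columns.
#' @param covariates model covariates.
#' @param fwe_m family size for the correction.
#' @return List of class `alps_results` with elements
#'   `group_comparison`, `partial_correlation`, `vif`, `demographics`,
#'   `skipped`.
#' @export
analyze_cohort <- function(cohort, covariates = alps_covariates, fwe_m = 3) {
  skipped <- list()
  try_part <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      skipped[[name]] <<- conditionMessage(e)
      NULL
    })
  }
  n_model <- length(covariates) + nlevels(droplevels(cohort$group)) + 1
  cmp <- try_part("group_comparison", {
    if (nrow(cohort) <= n_model) abort("too few subjects for the adjusted model.")
    alps_group_comparison(cohort, "alps", covariates, m_fwe = fwe_m)
  })
  pc <- try_part("partial_correlation", {
    sub <- cohort[cohort$group %in% c("Pre-DM", "T2DM"), ]
    partial_correlation(sub, "alps", "homa_ir", covariates)
  })
  vif <- try_part("vif", compute_vif(cohort, covariates))
  demo <- try_part("demographics", demographic_table(cohort))
  structure(list(group_comparison = cmp, partial_correlation = pc,
                 vif = vif, demographics = demo, skipped = skipped),
            class = "alps_results")
}

results_to_json <- function(results) {
  list(
    group_comparison = if (!is.null(results$group_comparison)) {
      tidy(results$group_comparison)
    },
    partial_correlation = results$partial_correlation,
    vif = results$vif,
    demographics = results$demographics,
    skipped = results$skipped
  )
}

#' @export
print.alps_results <- function(x, ...) {
  cat("<alps_results>\n")
  if (!is.null(x$group_comparison)) {
    print(as.data.frame(tidy(x$group_comparison)), digits = 3)
  }
  if (!is.null(x$partial_correlation)) {
    cat(sprintf("ALPS ~ HOMA-IR partial r = %.3f (p = %.4g, df = %d)\n",
                x$partial_correlation$r, x$partial_correlation$p.value,
                x$partial_correlation$df))
  }
  if (length(x$skipped) > 0) {
    cat("skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  }
  invisible(x)
}
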