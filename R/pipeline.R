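#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. Every source of
#' randomness in the pipeline flows from the single `seed`.
#'
#' @param n_patients Cohort size (default 20).
#' @param seed Integer seed (default 1).
#' @param imaging Simulate + fit a DWI phantom per ROI (`TRUE`) or carry
#'   the cohort's true medians through unchanged (`FALSE`).
#' @param histology Simulate + segment a histology image per ROI (`TRUE`)
#'   or carry the true fractions through (`FALSE`).
#' @param bvalues Acquisition scheme, s/mm^2.
#' @param s0 Phantom unattenuated signal.
#' @param snr Signal-to-noise ratio `s0 / sigma_eff` of the phantoms.
#' @param averages Signal averages in the noise model.
#' @param roi_voxels In-plane ROI half-extent: each ROI becomes a box of
#'   `(2 r + 1)^2` voxels (default r = 2, 25 voxels).
#' @param noise_shape Shape of the simulated noise-only scan used for
#'   noise estimation.
#' @param noise_window,noise_convention Passed to
#'   [estimate_noise_level()].
#' @param histo_shape,histo_mode Histology image size and generation mode.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return A `"dki_pipeline_config"` list.
#' @export
pipeline_config <- function(n_patients = 20, seed = 1,
                            imaging = TRUE, histology = TRUE,
                            bvalues = c(150, 600, 1050, 1500),
                            s0 = 100, snr = 50, averages = 8,
                            roi_voxels = 2, noise_shape = c(48, 48),
                            noise_window = 25,
                            noise_convention = "rician_mean",
                            histo_shape = c(60, 60),
                            histo_mode = "exact_count",
                            out_dir = NULL) {
  structure(as.list(environment()), class = "dki_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path YAML path.
#' @return A `"dki_pipeline_config"` list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' Run the simulate-fit-segment-summarize-analyze study pipeline
#'
#' End-to-end emulation of the study: a cohort of patients with true
#' tissue composition and DKI medians is simulated; for each ROI a
#' noisy diffusion-weighted phantom is generated and fitted voxelwise with
#' noise compensation (noise level estimated from a simulated noise-only
#' scan) to give measured ROI-median `D_app`/`K_app`; a histology image
#' with the ROI's true composition is generated and segmented to give
#' measured fractions; and the full statistical analysis grid is run on
#' the measured cohort table.
#'
#' @param config A [pipeline_config()], a YAML path, or `NULL` for
#'   defaults.
#' @return A `"dki_study"` list: `truth` and `cohort` (measured) tibbles,
#'   `analysis` (22-row results tibble), `noise` (the noise estimate) and
#'   `config`. If `config$out_dir` is set, writes `cohort_truth.csv`,
#'   `cohort_measured.csv`, `analysis.csv` and `report.json` there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config)) config <- pipeline_config()
  set.seed(config$seed)
  truth <- simulate_cohort(n_patients = config$n_patients)
  sigma_eff <- config$s0 / config$snr
  sigma <- sigma_eff * sqrt(config$averages)

  noise_scan <- matrix(
    rician_magnitude(rep(0, prod(config$noise_shape)), sigma_eff),
    config$noise_shape[1L], config$noise_shape[2L]
  )
  noise_est <- estimate_noise_level(noise_scan, window = config$noise_window,
                                    convention = config$noise_convention)

  cohort <- truth
  r <- config$roi_voxels
  side <- 2L * r + 1L
  vol_shape <- c(side + 2L, side + 2L, 1L)
  center <- c((side + 3L) / 2, (side + 3L) / 2, 1)
  for (i in seq_len(nrow(truth))) {
    if (config$imaging) {
      reg <- phantom_region("box", center = center,
                            halfsize = c(r, r, 0.4),
                            s0 = config$s0,
                            d_app = truth$median_d_app[i] * 1e-3,
                            k_app = truth$median_k_app[i])
      ph <- simulate_dwi_phantom(vol_shape, list(reg),
                                 bvalues = config$bvalues,
                                 sigma = sigma, averages = config$averages)
      maps <- fit_dki_volume(ph$series, fit_config(noise = noise_est))
      mask <- ph$truth$region == 1L
      cohort$median_d_app[i] <- as.numeric(roi_median(maps$d_app, mask)) * 1e3
      cohort$median_k_app[i] <- as.numeric(roi_median(maps$k_app, mask))
    }
    if (config$histology) {
      hs <- simulate_histology_image(
        config$histo_shape,
        c(truth$cellularity[i], truth$fsm[i], truth$luminal[i]),
        mode = config$histo_mode
      )
      fr <- compute_tissue_fractions(classify_pixels(hs$image))
      cohort$cellularity[i] <- fr$cellularity
      cohort$fsm[i] <- fr$fsm
      cohort$luminal[i] <- fr$luminal
    }
  }
  analysis <- run_study_analyses(cohort)
  out <- structure(list(truth = truth, cohort = cohort, analysis = analysis,
                        noise = noise_est, config = config),
                   class = "dki_study")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(truth, file.path(config$out_dir, "cohort_truth.csv"))
    write_cohort_csv(cohort, file.path(config$out_dir, "cohort_measured.csv"))
    write_analysis_csv(analysis, file.path(config$out_dir, "analysis.csv"))
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(
      list(config = cfg, seed = config$seed,
           noise = list(n = noise_est$n, convention = noise_est$convention),
           package_version = as.character(utils::packageVersion("dkihisto")),
           n_significant = sum(analysis$p_value < 0.05)),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null",
      force = TRUE
    )
  }
  out
}

#' @export
print.dki_study <- function(x, ...) {
  cat(sprintf("<dki_study> %d patients, %d ROIs (%d tumor / %d normal)\n",
              length(unique(x$cohort$patient_id)), nrow(x$cohort),
              sum(x$cohort$tissue == "tumor"),
              sum(x$cohort$tissue == "normal")))
  writeLines(format_study_report(x$analysis))
  invisible(x)
}

#' Tidy the analysis table of a pipeline run
#'
#' @param x A `"dki_study"` object.
#' @param ... Unused.
#' @return The 22-row analysis tibble.
#' @method tidy dki_study
#' @export
tidy.dki_study <- function(x, ...) x$analysis

#' One-row summary of a pipeline run
#'
#' @param x A `"dki_study"` object.
#' @param ... Unused.
#' @return A tibble summarising cohort size, measured group medians and
#'   the number of significant results.
#' @method glance dki_study
#' @export
glance.dki_study <- function(x, ...) {
  tum <- x$cohort[x$cohort$tissue == "tumor", ]
  nor <- x$cohort[x$cohort$tissue == "normal", ]
  tibble::tibble(
    n_patients = length(unique(x$cohort$patient_id)),
    n_rois = nrow(x$cohort),
    median_d_app_tumor = stats::median(tum$median_d_app),
    median_d_app_normal = stats::median(nor$median_d_app),
    median_k_app_tumor = stats::median(tum$median_k_app),
    median_k_app_normal = stats::median(nor$median_k_app),
    n_significant = sum(x$analysis$p_value < 0.05)
  )
}
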