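# End-to-end orchestration: cohort truth -> per-subject phantoms and
# simulated acquisitions -> image analysis -> summary table -> statistics.

#' Analyse one subject's simulated acquisitions
#'
#' Runs the full per-subject image-analysis chain: dual-echo back-
#' extrapolation with both coils, coil-field estimation, density calibration,
#' SV template matching, vessel-filtered perfusion quantification, and the
#' image-based LCI; returns one summary row plus the maps.
#'
#' @param phantom the subject's `lung_phantom` (supplies masks and scalars).
#' @param acq an `acquisition_bundle` from [simulate_acquisitions()].
#' @param grid SV candidate grid.
#' @param min_corr SV template-correlation threshold.
#' @param vessel_threshold vessel filter fraction of maximum delivered.
#' @param smoothing_scale coil-field smoothing in voxels.
#' @return list with `summary` (one-row data frame), `sv_map`, `q_map`,
#'   `density_map`, `coil_field`, `lci`.
#' @export
analyze_subject <- function(phantom, acq, grid = default_sv_grid(),
                            min_corr = 0.5, vessel_threshold = 0.35,
                            smoothing_scale = 5) {
  support <- phantom$lung_mask | phantom$phantom_roi

  fit_body <- extrapolate_s0(acq$echo_body$echo1, acq$echo_body$echo2,
                             acq$echo_body$te1, acq$echo_body$te2)
  fit_torso <- extrapolate_s0(acq$echo_torso$echo1, acq$echo_torso$echo2,
                              acq$echo_torso$te1, acq$echo_torso$te2)
  dens <- calibrate_density(fit_body, phantom$phantom_roi,
                            phantom$phantom_density)
  coil <- estimate_coil_field(fit_torso$s0, fit_body$s0,
                              smoothing_scale = smoothing_scale,
                              support = support)

  svm <- estimate_sv_map(acq$sv_series, acq$sv_series$schedule,
                         mask = phantom$lung_mask, grid = grid,
                         min_corr = min_corr)
  svs <- sv_summary(svm)
  lci <- suppressWarnings(
    image_lci(svm, frc = phantom$frc, tidal_volume = phantom$tidal_volume))

  qmap <- correct_and_calibrate(subtract_pair(acq$asl), coil,
                                reference = acq$asl$nonselective,
                                phantom_roi = phantom$phantom_roi,
                                lung_mask = phantom$lung_mask,
                                phantom_density = phantom$phantom_density,
                                voxel_volume = phantom$voxel_volume,
                                heart_rate = phantom$heart_rate)
  qmap <- filter_vessels(qmap, vessel_threshold)
  qs <- q_summary(qmap)

  lung <- phantom$lung_mask
  summary <- data.frame(
    mean_sv = unname(svs["mean"]), rd_sv = unname(svs["rd"]),
    lci = lci$lci, lci_mean_sv = lci$lci_mean_sv,
    mean_q = unname(qs["mean"]), rd_q = unname(qs["rd"]),
    mean_density = mean(dens$density[lung], na.rm = TRUE),
    n_valid_sv = svm$qc$n_valid, n_vessel_removed = qmap$n_removed,
    heart_rate = phantom$heart_rate
  )
  list(summary = summary, sv_map = svm, q_map = qmap, density_map = dens,
       coil_field = coil, lci = lci)
}

write_nifti_map <- function(img, path) {
  img[!is.finite(img)] <- 0
  RNifti::writeNifti(RNifti::asNifti(img), path)
  invisible(path)
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a subject-level cohort ([simulate_cohort()]), builds a digital
#' phantom per subject-timepoint parameterised by that subject's true values,
#' simulates all acquisitions, analyses each with the estimation chain, and
#' writes the run directory: per-subject NIfTI maps (optional), the combined
#' summary CSV (estimated alongside true values), the group-comparison
#' report, the correlation screen (BMI against the estimated post-pre change
#' in mean perfusion; pre-exposure RD of SV against the change in RD of Q),
#' a QC JSON and a plain-text log. Per-subject seeds are derived from the
#' master seed by a stable hash so results do not depend on processing
#' order; a failure in one subject is recorded and does not abort the
#' cohort.
#'
#' @param config a `cohort_config` (or partial list).
#' @param out_dir output directory (created if needed); NULL to skip all
#'   file output and return results only.
#' @param seed master seed.
#' @param write_images write per-subject NIfTI maps (summary files are
#'   always written when `out_dir` is given).
#' @return invisibly, a list with `summary` (data frame), `report`,
#'   `correlations`, `qc` and `config`.
#' @export
run_pipeline <- function(config = default_cohort_config(), out_dir = NULL,
                         seed = 1L, write_images = FALSE) {
  config <- validate_config(unclass(config))
  truth <- simulate_cohort(config, seed = seed)
  img <- config$imaging
  grid <- default_sv_grid()
  log_lines <- c(sprintf("lungmap pipeline run, seed %d, config hash %s",
                         as.integer(seed), config_hash(config)),
                 sprintf("subjects: %d control + %d vaper",
                         config$n_control, config$n_vaper))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (write_images)
      dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
  }

  rows <- vector("list", nrow(truth))
  failures <- character(0)
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    subj_seed <- derive_seed(seed, i)
    res <- tryCatch({
      phantom <- make_phantom(
        shape = c(img$shape, img$shape),
        sv_params = list(mean = row$mean_sv, rd = row$rd_sv),
        q_params = list(mean = row$mean_q, rd = row$rd_q),
        vessel_spec = list(n = img$vessel_n, intensity = img$vessel_intensity),
        frc = row$frc, heart_rate = row$heart_rate,
        tidal_volume = row$tidal_volume, seed = subj_seed)
      acq <- simulate_acquisitions(phantom, default_schedule(),
                                   enhancement = img$enhancement,
                                   snr_sv = img$snr_sv, snr_asl = img$snr_asl,
                                   snr_echo = img$snr_echo,
                                   seed = derive_seed(subj_seed, 1))
      ana <- analyze_subject(phantom, acq, grid = grid,
                             min_corr = img$min_corr,
                             vessel_threshold = img$vessel_threshold,
                             smoothing_scale = img$smoothing_scale)
      if (!is.null(out_dir) && write_images) {
        stem <- file.path(out_dir, "maps",
                          paste0(row$subject, "_", row$timepoint))
        write_nifti_map(ana$sv_map$sv, paste0(stem, "_sv.nii.gz"))
        write_nifti_map(ana$q_map$q, paste0(stem, "_q.nii.gz"))
        write_nifti_map(ana$density_map$density,
                        paste0(stem, "_density.nii.gz"))
        write_nifti_map(phantom$sv_true, paste0(stem, "_sv_true.nii.gz"))
        write_nifti_map(phantom$q_true, paste0(stem, "_q_true.nii.gz"))
      }
      ana$summary
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("%s/%s: %s", row$subject, row$timepoint,
                             conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      names(res) <- paste0("est_", names(res))
      rows[[i]] <- cbind(truth[i, ], res, row.names = NULL)
    }
  }
  summary <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(summary) <- NULL

  # statistics layer on the estimated metrics
  est <- summary
  est$mean_sv <- est$est_mean_sv; est$rd_sv <- est$est_rd_sv
  est$lci <- est$est_lci; est$mean_q <- est$est_mean_q
  est$rd_q <- est$est_rd_q
  est$heart_rate <- summary$heart_rate
  report <- build_summary_tables(est)

  pre <- est[est$group == "vaper" & est$timepoint == "pre", ]
  post <- est[est$group == "vaper" & est$timepoint == "post", ]
  post <- post[match(pre$subject, post$subject), ]
  change <- data.frame(subject = pre$subject, bmi = pre$bmi,
                       rd_sv_pre = pre$rd_sv,
                       delta_mean_q = post$mean_q - pre$mean_q,
                       delta_rd_q = post$rd_q - pre$rd_q)
  correlations <- correlation_screen(
    change,
    pairs = list(c("bmi", "delta_mean_q"), c("rd_sv_pre", "delta_rd_q")),
    method = "spearman")

  qc <- list(seed = as.integer(seed), config_hash = config_hash(config),
             n_analysed = nrow(summary) , n_failed = length(failures),
             failures = failures)
  if (!is.null(out_dir)) {
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "group_report.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    writeLines(c(log_lines,
                 sprintf("analysed %d subject-timepoints, %d failures",
                         nrow(summary), length(failures)), failures),
               file.path(out_dir, "run.log"))
  }
  invisible(list(summary = summary, report = report,
                 correlations = correlations, qc = qc, config = config))
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file with any subset of the configuration keys.
#' @return a complete, validated `cohort_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}
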