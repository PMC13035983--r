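#' Measure one labeled labyrinth volume
#'
#' Extracts the five substructure voxel clouds, fits the three canal
#' planes by total least squares, and runs the cochlear and vestibular
#' measurement chains. Returns one row of canonical metric columns.
#'
#' @param vol a [label_volume()] (or path to a NIfTI file).
#' @param ... passed to [measure_cochlea()] / [measure_vestibule()]
#'   (`bin_width_mm`, `ch_mode`, `surface`, `method`, ...).
#' @return one-row data.frame of metrics (see package docs for names).
#' @export
measure_labyrinth <- function(vol, ...) {
  if (is.character(vol)) vol <- read_label_volume(vol)
  stopifnot(inherits(vol, "label_volume"))
  dots <- list(...)
  coch_args <- dots[names(dots) %in%
                      c("bin_width_mm", "ch_mode", "force_basal_positive_x")]
  vest_args <- dots[names(dots) %in% c("surface", "method")]
  canal_fits <- lapply(c(PSC = "PSC", LSC = "LSC", SSC = "SSC"), function(nm)
    fit_plane(extract_voxel_cloud(vol, nm)$points_mm))
  cm <- do.call(measure_cochlea,
                c(list(extract_voxel_cloud(vol, "cochlea"), canal_fits),
                  coch_args))
  vm <- do.call(measure_vestibule,
                c(list(extract_voxel_cloud(vol, "vestibule"), canal_fits),
                  vest_args))
  data.frame(
    CH_mm = cm$CH_mm, coch_volume_mm3 = cm$volume_mm3,
    BLD_mm = cm$BLD_mm, BSD_mm = cm$BSD_mm,
    CDL_mm = cm$CDL_mm, TL2_mm = cm$TL2_mm, BTL_mm = cm$BTL_mm,
    angle_modiolus_LSC_deg = cm$angle_modiolus_LSC_deg,
    angle_modiolus_PSC_deg = cm$angle_modiolus_PSC_deg,
    angle_modiolus_SSC_deg = cm$angle_modiolus_SSC_deg,
    vest_volume_mm3 = vm$volume_mm3,
    length_A_mm = vm$length_A_mm, length_B_mm = vm$length_B_mm,
    length_C_mm = vm$length_C_mm,
    area_AB_mm2 = vm$area_AB_mm2, area_AC_mm2 = vm$area_AC_mm2,
    area_BC_mm2 = vm$area_BC_mm2,
    angle_AB_LSC_deg = vm$angle_AB_LSC_deg,
    angle_AC_LSC_deg = vm$angle_AC_LSC_deg,
    angle_BC_LSC_deg = vm$angle_BC_LSC_deg,
    angle_AB_PSC_deg = vm$angle_AB_PSC_deg,
    angle_AC_PSC_deg = vm$angle_AC_PSC_deg,
    angle_BC_PSC_deg = vm$angle_BC_PSC_deg,
    angle_AB_SSC_deg = vm$angle_AB_SSC_deg,
    angle_AC_SSC_deg = vm$angle_AC_SSC_deg,
    angle_BC_SSC_deg = vm$angle_BC_SSC_deg
  )
}

#' Group-comparison table over many metrics
#'
#' Applies [three_group_comparison()] to each metric and collects the
#' results into one table (per-group mean/sd, F, p, post hoc adjusted p
#' values), mirroring a clinical comparison table.
#'
#' @param records ear-level data.frame.
#' @param metrics metric column names; default: canonical columns present.
#' @param posthoc see [three_group_comparison()].
#' @return data.frame, one row per metric.
#' @export
comparison_table <- function(records, metrics = NULL,
                             posthoc = c("bonferroni", "tukey")) {
  posthoc <- match.arg(posthoc)
  if (is.null(metrics)) metrics <- intersect(metric_columns(), names(records))
  rows <- lapply(metrics, function(m) {
    gc <- three_group_comparison(records, m, posthoc)
    g <- gc$groups
    out <- data.frame(metric = m)
    for (i in seq_len(nrow(g))) {
      out[[paste0(tolower(g$group[i]), "_mean")]] <- g$mean[i]
      out[[paste0(tolower(g$group[i]), "_sd")]] <- g$sd[i]
    }
    out$F_statistic <- gc$F_statistic
    out$p_value <- gc$p_value
    for (i in seq_len(nrow(gc$posthoc)))
      out[[paste0("p_", gsub("-", "_", gc$posthoc$pair[i]))]] <-
        gc$posthoc$p_adj[i]
    out
  })
  do.call(rbind, rows)
}

#' Run the full morphometry-and-statistics pipeline
#'
#' Either simulates a measurement-level cohort (`config$cohort`, a
#' [cohort_spec()]) or measures a directory of labeled NIfTI volumes
#' (`config$volumes_dir` + `config$metadata`, a data.frame or CSV path
#' with an `ear_id` column matching the file names `<ear_id>.nii.gz` plus
#' `group` and optional clinical columns). It then produces the
#' statistical report tables: per-metric three-group comparisons, EH
#' grade correlations, duration-stratified tests and the demographic
#' summary. With `config$out_dir` set, tables are written as CSV along
#' with a JSON run log (seed, package version, config echo).
#'
#' @param config list; see Details above. A ready-made record table can
#'   also be passed directly as `config$records` (data.frame or CSV
#'   path). Optional fields: `posthoc`, `metrics`, `out_dir`, `seed`
#'   (overrides the cohort spec seed).
#' @return list with `records`, `comparisons`, `correlations_cochlear`,
#'   `correlations_vestibular`, `duration_tests`, `summary`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  posthoc <- if (is.null(config$posthoc)) "bonferroni" else config$posthoc
  if (!is.null(config$records)) {
    records <- config$records
    if (is.character(records))
      records <- utils::read.csv(records, stringsAsFactors = FALSE)
    seed <- if (is.null(config$seed)) NA_integer_ else config$seed
  } else if (!is.null(config$cohort)) {
    spec <- config$cohort
    if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
    records <- simulate_cohort(spec)
    seed <- spec$seed
  } else if (!is.null(config$volumes_dir)) {
    md <- config$metadata
    if (is.character(md)) md <- utils::read.csv(md, stringsAsFactors = FALSE)
    if (is.null(md$ear_id)) stop("metadata must have an ear_id column")
    files <- list.files(config$volumes_dir, pattern = "\\.nii(\\.gz)?$",
                        full.names = TRUE)
    ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
    missing_vol <- setdiff(md$ear_id, ids)
    missing_md <- setdiff(ids, md$ear_id)
    if (length(missing_vol) || length(missing_md))
      stop("metadata/volume mismatch; no volume for: [",
           paste(missing_vol, collapse = ", "), "]; no metadata for: [",
           paste(missing_md, collapse = ", "), "]")
    rows <- lapply(md$ear_id, function(id)
      measure_labyrinth(files[match(id, ids)]))
    records <- cbind(md, do.call(rbind, rows))
    seed <- if (is.null(config$seed)) NA_integer_ else config$seed
  } else {
    stop("config needs either a cohort spec or a volumes_dir + metadata")
  }
  metrics <- if (is.null(config$metrics))
    intersect(metric_columns(), names(records)) else config$metrics

  comparisons <- comparison_table(records, metrics, posthoc)
  cor_v <- cor_c <- NULL
  if ("eh_vestibular_grade" %in% names(records) &&
      any(!is.na(records$eh_vestibular_grade)))
    cor_v <- eh_correlations(records, "vestibular", metrics)
  if ("eh_cochlear_grade" %in% names(records) &&
      any(!is.na(records$eh_cochlear_grade)))
    cor_c <- eh_correlations(records, "cochlear", metrics)
  dur <- NULL
  if ("duration_years" %in% names(records) &&
      sum(is.finite(records$duration_years[records$group == "MDAE"])) >= 4L)
    dur <- duration_stratified_tests(records, metrics)
  summ <- summarize_cohort(records)
  log <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("labyrinthometry")),
    n_records = nrow(records),
    metrics = metrics,
    posthoc = posthoc,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  out <- list(records = records, comparisons = comparisons,
              correlations_cochlear = cor_c, correlations_vestibular = cor_v,
              duration_tests = dur, summary = summ, log = log)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(config$out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons,
                     file.path(config$out_dir, "group_comparisons.csv"),
                     row.names = FALSE)
    if (!is.null(cor_v))
      utils::write.csv(cor_v, file.path(config$out_dir,
                                        "correlations_vestibular.csv"),
                       row.names = FALSE)
    if (!is.null(cor_c))
      utils::write.csv(cor_c, file.path(config$out_dir,
                                        "correlations_cochlear.csv"),
                       row.names = FALSE)
    if (!is.null(dur))
      utils::write.csv(dur, file.path(config$out_dir, "duration_tests.csv"),
                       row.names = FALSE)
    utils::write.csv(summ$categorical,
                     file.path(config$out_dir, "summary_categorical.csv"),
                     row.names = FALSE)
    utils::write.csv(summ$continuous,
                     file.path(config$out_dir, "summary_continuous.csv"),
                     row.names = FALSE)
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
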