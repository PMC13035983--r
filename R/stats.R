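#' Pure-tone average
#'
#' Mean of the air-conduction thresholds at 500, 1000, 2000 and 4000 Hz.
#'
#' @param thresholds_db numeric vector of the four thresholds in dB HL,
#'   in frequency order or named `"500"`, `"1000"`, `"2000"`, `"4000"`.
#' @return PTA in dB HL.
#' @export
pta <- function(thresholds_db) {
  freqs <- c("500", "1000", "2000", "4000")
  if (!is.null(names(thresholds_db))) {
    missing <- setdiff(freqs, names(thresholds_db))
    if (length(missing))
      stop("missing threshold at ", paste(missing, collapse = ", "), " Hz")
    thresholds_db <- thresholds_db[freqs]
  }
  if (length(thresholds_db) != 4L || !all(is.finite(thresholds_db)))
    stop("PTA needs four finite thresholds (500/1000/2000/4000 Hz)")
  mean(thresholds_db)
}

#' Three-group comparison of one metric
#'
#' One-way ANOVA of a metric across the MDAE, MDUE and HC groups,
#' followed by post hoc pairwise comparisons (Bonferroni-adjusted
#' pairwise t tests by default, or Tukey's HSD).
#'
#' @param records ear-level data.frame with a `group` column (values in
#'   `MDAE`, `MDUE`, `HC`) and the metric column.
#' @param metric metric column name.
#' @param posthoc `"bonferroni"` (default) or `"tukey"`.
#' @return object of class `group_comparison`: list with `metric`,
#'   `groups` (mean/sd/n per group), `F_statistic`, `p_value` and
#'   `posthoc` (data.frame of pairwise adjusted p values).
#' @export
three_group_comparison <- function(records, metric,
                                   posthoc = c("bonferroni", "tukey")) {
  posthoc <- match.arg(posthoc)
  if (!metric %in% names(records)) stop("no such metric column: ", metric)
  keep <- is.finite(records[[metric]]) & records$group %in% c("MDAE", "MDUE", "HC")
  x <- records[[metric]][keep]
  g <- factor(records$group[keep], levels = c("MDAE", "MDUE", "HC"))
  n <- table(g)
  if (any(n < 2L))
    stop("each group needs at least 2 finite values of ", metric,
         " (got ", paste(n, collapse = "/"), ")")
  if (stats::var(x) == 0)
    stop("metric ", metric, " is constant: F statistic undefined")
  fit <- stats::aov(x ~ g)
  s <- summary(fit)[[1L]]
  groups <- data.frame(
    group = levels(g),
    n = as.integer(n),
    mean = as.numeric(tapply(x, g, mean)),
    sd = as.numeric(tapply(x, g, stats::sd)),
    row.names = NULL
  )
  ph <- if (posthoc == "bonferroni") {
    pt <- stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni")$p.value
    pairs <- data.frame(
      pair = c("MDAE-MDUE", "MDAE-HC", "MDUE-HC"),
      p_adj = c(pt["MDUE", "MDAE"], pt["HC", "MDAE"], pt["HC", "MDUE"]),
      row.names = NULL
    )
    pairs
  } else {
    tk <- stats::TukeyHSD(fit)$g
    data.frame(pair = rownames(tk), p_adj = tk[, "p adj"], row.names = NULL)
  }
  structure(
    list(metric = metric, groups = groups,
         F_statistic = s[["F value"]][1L], p_value = s[["Pr(>F)"]][1L],
         posthoc_method = posthoc, posthoc = ph),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: F = %.3f, p = %.4g (%s post hoc)\n",
              x$metric, x$F_statistic, x$p_value, x$posthoc_method))
  for (i in seq_len(nrow(x$groups)))
    cat(sprintf("  %-4s n=%3d  %.3f +/- %.3f\n", x$groups$group[i],
                x$groups$n[i], x$groups$mean[i], x$groups$sd[i]))
  invisible(x)
}

#' Spearman correlations of metrics with EH grade
#'
#' Spearman rank correlation (average ranks on ties, asymptotic two-sided
#' p values) between each metric and the ordinal endolymphatic-hydrops
#' grade over the MD-affected ears. A constant grade vector is flagged
#' (`NA` with a note), never reported as zero correlation.
#'
#' @param records ear-level data.frame.
#' @param grade_type `"vestibular"` or `"cochlear"`.
#' @param metrics metric column names; default: all canonical metric
#'   columns present.
#' @return data.frame with `metric`, `spearman_r`, `p_value`, `n`, `note`.
#' @export
eh_correlations <- function(records, grade_type = c("vestibular", "cochlear"),
                            metrics = NULL) {
  grade_type <- match.arg(grade_type)
  gcol <- paste0("eh_", grade_type, "_grade")
  if (!gcol %in% names(records)) stop("no grade column ", gcol)
  md <- records[records$group == "MDAE" & !is.na(records[[gcol]]), ]
  if (!nrow(md)) stop("no MDAE records with ", grade_type, " EH grades")
  if (is.null(metrics)) metrics <- intersect(metric_columns(), names(records))
  grade <- md[[gcol]]
  constant <- length(unique(grade)) < 2L
  rows <- lapply(metrics, function(m) {
    if (constant) {
      return(data.frame(metric = m, spearman_r = NA_real_, p_value = NA_real_,
                        n = nrow(md), note = "constant grades"))
    }
    ct <- suppressWarnings(
      stats::cor.test(md[[m]], grade, method = "spearman", exact = FALSE))
    data.frame(metric = m, spearman_r = unname(ct$estimate),
               p_value = ct$p.value, n = nrow(md), note = "")
  })
  if (constant) warning("EH ", grade_type,
                        " grades are constant; correlations undefined")
  do.call(rbind, rows)
}

#' Duration-stratified comparisons of MDAE metrics
#'
#' Splits MD patients into short-to-intermediate and long disease
#' duration at the cutoff (long means strictly greater than the cutoff
#' by default) and compares each metric between strata on the affected
#' ears with independent two-sample t tests (pooled variance by default,
#' matching conventional SPSS output; Welch optional).
#'
#' @param records ear-level data.frame.
#' @param metrics metric column names; default: all canonical metric
#'   columns present.
#' @param cutoff_years duration cutoff (default 5).
#' @param strict if `TRUE` (default) long duration means
#'   `> cutoff_years`; if `FALSE`, `>= cutoff_years`.
#' @param var_equal pooled-variance t test (default) or Welch.
#' @return data.frame with per-stratum mean/sd/n, `t_statistic` and
#'   `p_value` per metric (t is short minus long, so a larger
#'   long-duration mean gives a negative t).
#' @export
duration_stratified_tests <- function(records, metrics = NULL,
                                      cutoff_years = 5, strict = TRUE,
                                      var_equal = TRUE) {
  md <- records[records$group == "MDAE" & is.finite(records$duration_years), ]
  long <- if (strict) md$duration_years > cutoff_years else
    md$duration_years >= cutoff_years
  if (sum(long) < 2L || sum(!long) < 2L)
    stop("both duration strata need at least 2 affected ears")
  if (is.null(metrics)) metrics <- intersect(metric_columns(), names(records))
  rows <- lapply(metrics, function(m) {
    a <- md[[m]][!long]; b <- md[[m]][long]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(metric = m,
               n_short = length(a), mean_short = mean(a), sd_short = stats::sd(a),
               n_long = length(b), mean_long = mean(b), sd_long = stats::sd(b),
               t_statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Demographic and clinical cohort summary
#'
#' Counts with percentages (two decimals) for the categorical fields and
#' mean +/- sd for the continuous fields, in the style of a clinical
#' Table 1. Percentages for MD-patient characteristics are out of the
#' number of patients.
#'
#' @param records ear-level data.frame.
#' @return list with `categorical` (field, level, n, pct) and
#'   `continuous` (field, mean, sd) data.frames.
#' @export
summarize_cohort <- function(records) {
  if (!nrow(records)) stop("empty cohort")
  md <- records[records$group == "MDAE", ]
  npat <- nrow(md)
  cat_row <- function(field, level, n, total) {
    data.frame(field = field, level = level, n = n,
               pct = round(100 * n / total, 2))
  }
  cats <- list()
  if (npat) {
    for (lv in c("F", "M"))
      cats[[length(cats) + 1L]] <- cat_row("sex", lv, sum(md$sex == lv), npat)
    for (lv in c("L", "R"))
      cats[[length(cats) + 1L]] <- cat_row("laterality", lv,
                                           sum(md$ear_side == lv), npat)
    if ("duration_years" %in% names(md)) {
      d <- md$duration_years
      cats[[length(cats) + 1L]] <- cat_row("duration", "<1 year", sum(d < 1), npat)
      cats[[length(cats) + 1L]] <- cat_row("duration", "1-5 years",
                                           sum(d >= 1 & d <= 5), npat)
      cats[[length(cats) + 1L]] <- cat_row("duration", ">5 years", sum(d > 5), npat)
    }
  }
  categorical <- if (length(cats)) do.call(rbind, cats) else
    data.frame(field = character(), level = character(),
               n = integer(), pct = numeric())
  cont <- list()
  if ("age_years" %in% names(md) && npat)
    cont[[length(cont) + 1L]] <- data.frame(field = "age_years",
                                            mean = mean(md$age_years),
                                            sd = stats::sd(md$age_years))
  if ("pta_db" %in% names(records)) {
    for (g in c("MDAE", "MDUE")) {
      x <- records$pta_db[records$group == g]
      if (length(x) > 1L)
        cont[[length(cont) + 1L]] <- data.frame(
          field = paste0("pta_db_", g), mean = mean(x), sd = stats::sd(x))
    }
  }
  continuous <- if (length(cont)) do.call(rbind, cont) else
    data.frame(field = character(), mean = numeric(), sd = numeric())
  list(categorical = categorical, continuous = continuous)
}

# Canonical per-ear metric column names shared by the measurement chain
# and the cohort simulator.
metric_columns <- function() {
  c("CH_mm", "coch_volume_mm3", "BLD_mm", "BSD_mm",
    "CDL_mm", "TL2_mm", "BTL_mm",
    "angle_modiolus_LSC_deg", "angle_modiolus_PSC_deg",
    "angle_modiolus_SSC_deg",
    "vest_volume_mm3", "length_A_mm", "length_B_mm", "length_C_mm",
    "area_AB_mm2", "area_AC_mm2", "area_BC_mm2",
    "angle_AB_LSC_deg", "angle_AC_LSC_deg", "angle_BC_LSC_deg",
    "angle_AB_PSC_deg", "angle_AC_PSC_deg", "angle_BC_PSC_deg",
    "angle_AB_SSC_deg", "angle_AC_SSC_deg", "angle_BC_SSC_deg")
}
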