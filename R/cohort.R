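#' Default generating parameters for simulated cohorts
#'
#' Per-metric group means and standard deviations (MD-affected ears,
#' MD-unaffected ears, healthy controls) used by [simulate_cohort()].
#' Defaults are the published adult inner-ear scale for unilateral
#' Meniere's disease cohorts: slightly greater cochlear height and
#' smaller vestibular-plane-to-LSC angles in MD ears, with diameters and
#' volumes essentially shared across groups. Duct lengths (CDL/2TL/BTL)
#' and section areas are not drawn: they are computed from the drawn BLD
#' and vestibular diameters by the same formulas the measurement chain
#' uses, so simulated records satisfy the package's internal identities.
#'
#' @return data.frame with columns `metric`, `mdae_mean`, `mdae_sd`,
#'   `mdue_mean`, `mdue_sd`, `hc_mean`, `hc_sd`.
#' @export
default_cohort_params <- function() {
  p <- rbind(
    c("CH_mm",                    4.06, 0.22,  4.02, 0.23,  3.98, 0.22),
    c("coch_volume_mm3",         75.01, 7.76, 74.12, 8.36, 73.82, 7.49),
    c("BLD_mm",                   9.08, 0.44,  9.03, 0.65,  8.98, 0.38),
    c("BSD_mm",                   6.55, 0.33,  6.50, 0.41,  6.50, 0.30),
    c("angle_modiolus_LSC_deg",  57.89, 5.59, 59.07, 6.23, 56.02, 5.81),
    c("angle_modiolus_PSC_deg",  73.92, 13.47, 76.01, 11.38, 75.73, 11.43),
    c("angle_modiolus_SSC_deg",  41.52, 13.48, 40.76, 13.68, 41.28, 13.27),
    c("vest_volume_mm3",         54.12, 7.09, 54.03, 7.20, 55.11, 7.20),
    c("length_A_mm",              6.14, 0.52,  6.20, 0.68,  6.21, 0.53),
    c("length_B_mm",              4.59, 0.40,  4.54, 0.39,  4.61, 0.46),
    c("length_C_mm",              2.19, 0.12,  2.19, 0.12,  2.21, 0.11),
    c("angle_AB_LSC_deg",        31.38, 11.91, 30.90, 9.10, 36.60, 12.62),
    c("angle_AC_LSC_deg",        75.60, 13.46, 77.55, 11.00, 71.51, 14.15),
    c("angle_BC_LSC_deg",        65.36, 7.25, 64.28, 7.53, 62.37, 7.69),
    c("angle_AB_PSC_deg",        64.99, 20.85, 67.03, 20.62, 64.65, 19.16),
    c("angle_AC_PSC_deg",        71.34, 10.11, 70.51, 11.46, 72.46, 11.38),
    c("angle_BC_PSC_deg",        36.17, 19.61, 35.40, 17.76, 35.76, 19.98),
    c("angle_AB_SSC_deg",        64.99, 20.85, 67.03, 20.62, 64.65, 19.16),
    c("angle_AC_SSC_deg",        71.34, 10.11, 70.51, 11.46, 72.46, 11.38),
    c("angle_BC_SSC_deg",        36.17, 19.61, 35.40, 17.76, 35.76, 19.98)
  )
  out <- data.frame(metric = p[, 1L], stringsAsFactors = FALSE)
  nm <- c("mdae_mean", "mdae_sd", "mdue_mean", "mdue_sd", "hc_mean", "hc_sd")
  for (i in seq_along(nm)) out[[nm[i]]] <- as.numeric(p[, i + 1L])
  out
}

#' Metrics derived deterministically from drawn metrics
#' @noRd
derived_metric_names <- function() {
  c("CDL_mm", "TL2_mm", "BTL_mm", "area_AB_mm2", "area_AC_mm2", "area_BC_mm2")
}

#' Specification of a simulated measurement-level cohort
#'
#' Defines the design of a three-group ear cohort: paired affected and
#' unaffected ears for each Meniere's-disease patient plus unpaired
#' healthy-control ears, per-ear metric draws with group-specific means,
#' an ordinal endolymphatic-hydrops (EH) grade linked to a driver metric
#' through a thresholded latent Gaussian with a stated target Spearman
#' correlation, and a disease-duration mixture with additive vestibular
#' size shifts for long-duration (> 5 years) patients that preserve the
#' overall group means.
#'
#' @param n_patients number of MD patients (each contributes one MDAE and
#'   one MDUE ear).
#' @param n_hc number of healthy-control ears.
#' @param metric_params data.frame as from [default_cohort_params()].
#' @param duration_mix probabilities of the `<1`, `1-5` and `>5` year
#'   duration strata (must sum to 1).
#' @param duration_effects named numeric vector of additive shifts
#'   applied to long-duration MDAE ears.
#' @param eh_vestibular,eh_cochlear lists with `probs` (grade
#'   distribution over grades `0..length(probs)-1`), `driver` (metric
#'   name or `NULL` for independence) and `target_spearman`.
#' @param pta_affected,pta_unaffected,age mean/sd pairs.
#' @param p_female,p_left probabilities for sex and affected-ear side.
#' @param seed integer RNG seed; identical specs and seeds give
#'   bit-identical cohorts.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 105L,
                        n_hc = 100L,
                        metric_params = default_cohort_params(),
                        duration_mix = c(lt1 = 0.0381, y1to5 = 0.4095,
                                         gt5 = 0.5524),
                        duration_effects = c(vest_volume_mm3 = 2.73,
                                             length_B_mm = 0.19),
                        eh_vestibular = list(
                          probs = c(0.1429, 0.4762, 0.2857, 0.0952),
                          driver = "angle_modiolus_SSC_deg",
                          target_spearman = 0.243),
                        eh_cochlear = list(
                          probs = c(0.0762, 0.4000, 0.3619, 0.1619),
                          driver = NULL,
                          target_spearman = 0),
                        pta_affected = c(65.69, 18.09),
                        pta_unaffected = c(23.64, 14.09),
                        age = c(57.33, 10.62),
                        p_female = 0.5714,
                        p_left = 0.5619,
                        seed = 1L) {
  if (n_patients <= 0 || n_hc <= 0) stop("group sizes must be positive")
  stopifnot(is.data.frame(metric_params),
            all(c("metric", "mdae_mean", "mdae_sd", "mdue_mean", "mdue_sd",
                  "hc_mean", "hc_sd") %in% names(metric_params)))
  duration_mix <- duration_mix / sum(duration_mix)
  for (m in names(duration_effects)) {
    if (!m %in% metric_params$metric)
      stop("duration effect refers to unknown metric: ", m)
  }
  for (g in list(eh_vestibular, eh_cochlear)) {
    if (abs(sum(g$probs) - 1) > 0.01) stop("EH grade probabilities must sum to 1")
    if (!is.null(g$driver) && !g$driver %in% metric_params$metric)
      stop("EH grade driver refers to unknown metric: ", g$driver)
  }
  structure(
    list(n_patients = as.integer(n_patients), n_hc = as.integer(n_hc),
         metric_params = metric_params, duration_mix = duration_mix,
         duration_effects = duration_effects,
         eh_vestibular = eh_vestibular, eh_cochlear = eh_cochlear,
         pta_affected = pta_affected, pta_unaffected = pta_unaffected,
         age = age, p_female = p_female, p_left = p_left,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Population Spearman correlation between a graded latent and a metric
#'
#' For a bivariate-normal pair (metric z-score, latent) with Pearson
#' correlation `r`, where the latent is cut into ordinal grades with the
#' given probabilities, returns the population Spearman correlation
#' (average ranks for the tied grades) between the metric and the grade.
#' Used to calibrate the latent correlation to a target Spearman.
#'
#' @param r latent Pearson correlation in (-1, 1).
#' @param probs grade probabilities.
#' @return population Spearman correlation.
#' @export
spearman_of_latent <- function(r, probs) {
  Fk <- cumsum(probs)
  q <- stats::qnorm(c(0, Fk))             # -Inf .. Inf cut points
  ck <- (c(0, Fk[-length(Fk)]) + Fk) / 2  # fractional mid-ranks
  s <- sqrt(2 - r^2)
  EUh <- 0
  for (k in seq_along(probs)) {
    EUh <- EUh + ck[k] * stats::integrate(
      function(l) stats::dnorm(l) * stats::pnorm(r * l / s),
      q[k], q[k + 1L], rel.tol = 1e-9)$value
  }
  Ec <- sum(ck * probs)
  vc <- sum(ck^2 * probs) - Ec^2
  (EUh - 0.5 * Ec) / (sqrt(1 / 12) * sqrt(vc))
}

#' @rdname spearman_of_latent
#' @param target target Spearman correlation between metric and grade.
#' @export
calibrate_latent_corr <- function(target, probs) {
  if (target == 0) return(0)
  stats::uniroot(function(r) spearman_of_latent(r, probs) - target,
                 c(-0.999, 0.999), tol = 1e-8)$root
}

draw_grades <- function(n, model, z_driver) {
  q <- stats::qnorm(cumsum(model$probs))
  q <- q[-length(q)]                       # internal thresholds
  r <- if (is.null(model$driver) || model$target_spearman == 0) 0 else
    calibrate_latent_corr(model$target_spearman, model$probs)
  latent <- r * z_driver + sqrt(1 - r^2) * stats::rnorm(n)
  findInterval(latent, q)                  # grades 0..K-1
}

#' Simulate a measurement-level cohort
#'
#' Draws one ear-level record table according to a [cohort_spec()]:
#' Gaussian metric draws per group, derived duct lengths and section
#' areas computed from the drawn diameters, paired MDAE/MDUE ears per
#' patient, disease durations from the stratum mixture (long-duration
#' MDAE ears receive the additive vestibular shifts, with stratum means
#' offset so the overall group mean is preserved), EH grades from the
#' calibrated latent link, and pure-tone averages. Fully reproducible
#' given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per ear: identifiers, `group`
#'   (`MDAE`/`MDUE`/`HC`), demographics, `duration_years`,
#'   `eh_cochlear_grade`/`eh_vestibular_grade` (MDAE ears only, `NA`
#'   elsewhere), `pta_db`, and all metric columns.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  st <- local_seed(spec$seed)
  on.exit(restore_seed(st))
  np <- spec$n_patients
  nh <- spec$n_hc
  mp <- spec$metric_params

  # patient-level covariates
  sex <- ifelse(stats::runif(np) < spec$p_female, "F", "M")
  age <- stats::rnorm(np, spec$age[1L], spec$age[2L])
  side <- ifelse(stats::runif(np) < spec$p_left, "L", "R")
  stratum <- sample(c("lt1", "y1to5", "gt5"), np, replace = TRUE,
                    prob = spec$duration_mix)
  duration <- ifelse(stratum == "lt1", stats::runif(np, 0.2, 1),
              ifelse(stratum == "y1to5", stats::runif(np, 1, 5),
                     5 + stats::rexp(np, rate = 1 / 4)))
  hc_sex <- ifelse(stats::runif(nh) < spec$p_female, "F", "M")
  hc_age <- stats::rnorm(nh, spec$age[1L], spec$age[2L])
  hc_side <- sample(c("L", "R"), nh, replace = TRUE)

  group <- c(rep("MDAE", np), rep("MDUE", np), rep("HC", nh))
  rec <- data.frame(
    ear_id = c(sprintf("P%03d_AE", seq_len(np)),
               sprintf("P%03d_UE", seq_len(np)),
               sprintf("C%03d", seq_len(nh))),
    patient_id = c(sprintf("P%03d", seq_len(np)),
                   sprintf("P%03d", seq_len(np)),
                   sprintf("C%03d", seq_len(nh))),
    group = group,
    ear_side = c(side, ifelse(side == "L", "R", "L"), hc_side),
    sex = c(sex, sex, hc_sex),
    age_years = c(age, age, hc_age),
    duration_years = c(duration, duration, rep(NA_real_, nh)),
    stringsAsFactors = FALSE
  )
  p_gt5 <- spec$duration_mix[["gt5"]]
  long_mdae <- rec$group == "MDAE" & rec$duration_years > 5
  n_all <- nrow(rec)
  for (i in seq_len(nrow(mp))) {
    m <- mp$metric[i]
    mu <- ifelse(rec$group == "MDAE", mp$mdae_mean[i],
          ifelse(rec$group == "MDUE", mp$mdue_mean[i], mp$hc_mean[i]))
    sd <- ifelse(rec$group == "MDAE", mp$mdae_sd[i],
          ifelse(rec$group == "MDUE", mp$mdue_sd[i], mp$hc_sd[i]))
    if (m %in% names(spec$duration_effects)) {
      eff <- spec$duration_effects[[m]]
      mdae <- rec$group == "MDAE"
      mu[mdae] <- mu[mdae] - p_gt5 * eff      # short-stratum baseline
      mu[long_mdae] <- mu[long_mdae] + eff
    }
    rec[[m]] <- stats::rnorm(n_all, mu, sd)
  }
  # derived metrics: same formulas as the measurement chain (skipped
  # when a reduced parameter table omits the source metrics)
  if (!is.null(rec$BLD_mm)) {
    dl <- vapply(rec$BLD_mm, derived_lengths, numeric(3L))
    rec$CDL_mm <- dl["CDL_mm", ]
    rec$TL2_mm <- dl["TL2_mm", ]
    rec$BTL_mm <- dl["BTL_mm", ]
  }
  if (!is.null(rec$length_A_mm) && !is.null(rec$length_B_mm) &&
      !is.null(rec$length_C_mm)) {
    rec$area_AB_mm2 <- pi / 4 * rec$length_A_mm * rec$length_B_mm
    rec$area_AC_mm2 <- pi / 4 * rec$length_A_mm * rec$length_C_mm
    rec$area_BC_mm2 <- pi / 4 * rec$length_B_mm * rec$length_C_mm
  }

  # EH grades on affected ears, linked to the driver metric
  mdae_idx <- which(rec$group == "MDAE")
  rec$eh_vestibular_grade <- NA_integer_
  rec$eh_cochlear_grade <- NA_integer_
  z_for <- function(model) {
    if (is.null(model$driver)) return(rep(0, length(mdae_idx)))
    i <- match(model$driver, mp$metric)
    (rec[[model$driver]][mdae_idx] - mp$mdae_mean[i]) / mp$mdae_sd[i]
  }
  rec$eh_vestibular_grade[mdae_idx] <-
    draw_grades(length(mdae_idx), spec$eh_vestibular, z_for(spec$eh_vestibular))
  rec$eh_cochlear_grade[mdae_idx] <-
    draw_grades(length(mdae_idx), spec$eh_cochlear, z_for(spec$eh_cochlear))

  rec$pta_db <- ifelse(
    rec$group == "MDAE",
    stats::rnorm(n_all, spec$pta_affected[1L], spec$pta_affected[2L]),
    stats::rnorm(n_all, spec$pta_unaffected[1L], spec$pta_unaffected[2L]))
  rec
}

#' Measure a cohort of phantoms (phantom-level simulation)
#'
#' The slower, fully mechanistic alternative to [simulate_cohort()]:
#' each ear is a jittered [phantom_spec()] that is voxelized, assembled
#' and pushed through the full measurement chain. Intended for
#' end-to-end validation at small n, not for power studies.
#'
#' @param specs list of [phantom_spec()] objects, one per ear.
#' @param ... passed to [measure_labyrinth()].
#' @return data.frame of measured metric rows (one per spec).
#' @export
measure_phantom_cohort <- function(specs, ...) {
  rows <- lapply(seq_along(specs), function(i) {
    asm <- assemble_labyrinth(specs[[i]])
    row <- measure_labyrinth(asm$volume, ...)
    cbind(data.frame(ear_id = sprintf("phantom_%03d", i)), row)
  })
  do.call(rbind, rows)
}
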