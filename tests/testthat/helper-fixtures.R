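# Shared fixtures, built once per test file.

.fixtures <- new.env(parent = emptyenv())

# Default phantom assembly at study spacing (0.1 mm), cached.
default_assembly <- function() {
  if (is.null(.fixtures$asm)) .fixtures$asm <- assemble_labyrinth(phantom_spec())
  .fixtures$asm
}

# Canal plane fits of the default assembly.
default_canal_fits <- function() {
  if (is.null(.fixtures$fits)) {
    vol <- default_assembly()$volume
    .fixtures$fits <- lapply(c(PSC = "PSC", LSC = "LSC", SSC = "SSC"),
                             function(nm)
                               fit_plane(extract_voxel_cloud(vol, nm)$points_mm))
  }
  .fixtures$fits
}

# Exact surface samples of an axis-aligned ellipsoid (deterministic grid).
ellipsoid_surface_points <- function(a, b, c_, n_theta = 24L, n_phi = 48L) {
  th <- seq(0.1, pi - 0.1, length.out = n_theta)
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-1L]
  g <- expand.grid(th = th, ph = ph)
  cbind(a * sin(g$th) * cos(g$ph),
        b * sin(g$th) * sin(g$ph),
        c_ * cos(g$th))
}

# Dense planar ellipse samples embedded at z = 0 (voxel-lattice style).
ellipse_points_2d <- function(a, b, step = 0.05) {
  xs <- seq(-a, a, by = step)
  ys <- seq(-b, b, by = step)
  g <- expand.grid(x = xs, y = ys)
  g <- g[(g$x / a)^2 + (g$y / b)^2 <= 1, ]
  as.matrix(g)
}

# A reduced cohort parameter table with a single metric and the given
# group means (shared sd), for fast calibration studies.
one_metric_params <- function(metric, mdae, mdue, hc, sd) {
  data.frame(metric = metric,
             mdae_mean = mdae, mdae_sd = sd,
             mdue_mean = mdue, mdue_sd = sd,
             hc_mean = hc, hc_sd = sd,
             stringsAsFactors = FALSE)
}

one_metric_cohort <- function(metric, mdae, mdue, hc, sd, seed,
                              n_patients = 105L, n_hc = 100L) {
  cohort_spec(
    n_patients = n_patients, n_hc = n_hc,
    metric_params = one_metric_params(metric, mdae, mdue, hc, sd),
    duration_effects = NULL,
    eh_vestibular = list(probs = c(0.5, 0.5), driver = NULL,
                         target_spearman = 0),
    eh_cochlear = list(probs = c(0.5, 0.5), driver = NULL,
                       target_spearman = 0),
    seed = seed
  )
}
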