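test_that("pure-tone average", {
  expect_equal(pta(c(60, 65, 70, 65)), 65)
  expect_equal(pta(c(0, 0, 0, 0)), 0)
  expect_equal(pta(c(20, 25, 25, 24.56)), 23.64)
  expect_equal(pta(c(`1000` = 25, `500` = 20, `4000` = 24.56, `2000` = 25)),
               23.64)
  expect_error(pta(c(`500` = 20, `1000` = 25, `2000` = 25)), "4000")
  expect_error(pta(c(20, 25, NA, 30)), "finite")
})

test_that("one-way ANOVA matches the brute-force sum-of-squares oracle", {
  # small three-group example, F computed from first principles
  x <- c(6.1, 5.8, 6.4, 6.0, 5.9,   7.0, 6.8, 7.3, 6.9, 7.1,
         6.5, 6.3, 6.7, 6.4, 6.6)
  g <- rep(c("MDAE", "MDUE", "HC"), each = 5)
  rec <- data.frame(group = g, y = x)
  gc <- three_group_comparison(rec, "y")
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ssb / 2) / (ssw / (length(x) - 3))
  expect_equal(gc$F_statistic, f_oracle, tolerance = 1e-6)
  expect_equal(gc$p_value, pf(f_oracle, 2, 12, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_setequal(gc$posthoc$pair, c("MDAE-MDUE", "MDAE-HC", "MDUE-HC"))
  expect_true(all(gc$posthoc$p_adj >= 0 & gc$posthoc$p_adj <= 1))
  # Tukey variant runs and reports the same pair set
  gt <- three_group_comparison(rec, "y", posthoc = "tukey")
  expect_equal(nrow(gt$posthoc), 3)
})

test_that("ANOVA degenerate inputs are flagged", {
  rec <- data.frame(group = rep(c("MDAE", "MDUE", "HC"), each = 3),
                    y = rep(5, 9))
  expect_error(three_group_comparison(rec, "y"), "constant")
  rec2 <- data.frame(group = rep(c("MDAE", "MDUE"), each = 3), y = rnorm(6))
  expect_error(three_group_comparison(rec2, "y"), "at least 2")
})

test_that("Spearman correlations match hand-ranked oracles", {
  rec <- data.frame(group = "MDAE",
                    eh_vestibular_grade = c(1, 3, 2, 4),
                    m = c(1, 2, 3, 4))
  out <- eh_correlations(rec, "vestibular", metrics = "m")
  expect_equal(out$spearman_r, 0.8)   # hand-ranked: 1 - 6*2/(4*15)
  # strictly increasing metric: perfect rank correlation
  rec2 <- data.frame(group = "MDAE", eh_vestibular_grade = 0:9,
                     m = exp(0:9))
  expect_equal(eh_correlations(rec2, "vestibular", "m")$spearman_r, 1)
  # invariance under strictly monotone transforms
  set.seed(2)
  rec3 <- data.frame(group = "MDAE",
                     eh_vestibular_grade = sample(0:3, 40, TRUE),
                     m = rnorm(40))
  r_raw <- eh_correlations(rec3, "vestibular", "m")$spearman_r
  rec3$m <- exp(rec3$m)
  expect_equal(eh_correlations(rec3, "vestibular", "m")$spearman_r, r_raw)
  # constant grades are flagged, not reported as zero
  rec4 <- data.frame(group = "MDAE", eh_vestibular_grade = rep(2L, 10),
                     m = rnorm(10))
  expect_warning(out4 <- eh_correlations(rec4, "vestibular", "m"), "constant")
  expect_true(is.na(out4$spearman_r))
  expect_equal(out4$note, "constant grades")
})

test_that("a null metric stays uncorrelated with grade across replicates", {
  set.seed(14)
  rs <- replicate(200, {
    rec <- data.frame(group = "MDAE",
                      eh_vestibular_grade = sample(0:3, 105, TRUE,
                                                   prob = c(.14, .48, .28, .10)),
                      m = rnorm(105))
    eh_correlations(rec, "vestibular", "m")$spearman_r
  })
  expect_gte(mean(abs(rs) < 0.2), 0.95)
})

test_that("duration-stratified t tests match the closed form", {
  a <- c(5.1, 4.8, 5.6, 5.0, 4.7)
  b <- c(5.9, 6.1, 5.4, 6.3, 5.8, 6.0)
  rec <- data.frame(group = "MDAE",
                    duration_years = c(rep(2, 5), rep(8, 6)),
                    m = c(a, b))
  out <- duration_stratified_tests(rec, "m")
  sp2 <- ((4 * var(a) + 5 * var(b)) / 9)
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 6))
  expect_equal(out$t_statistic, t_oracle, tolerance = 1e-9)
  expect_equal(out$p_value, 2 * pt(abs(t_oracle), 9, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(out$n_short, 5)
  expect_equal(out$n_long, 6)
  # identical strata: t = 0, p = 1
  rec2 <- data.frame(group = "MDAE",
                     duration_years = c(rep(2, 4), rep(8, 4)),
                     m = c(1, 2, 3, 4, 1, 2, 3, 4))
  out2 <- duration_stratified_tests(rec2, "m")
  expect_equal(out2$t_statistic, 0)
  expect_equal(out2$p_value, 1)
  # cutoff strictness is configurable
  rec3 <- data.frame(group = "MDAE",
                     duration_years = c(2, 3, 5, 5, 8, 9),
                     m = rnorm(6))
  expect_equal(duration_stratified_tests(rec3, "m")$n_long, 2)
  expect_equal(duration_stratified_tests(rec3, "m", strict = FALSE)$n_long, 4)
  expect_error(duration_stratified_tests(
    data.frame(group = "MDAE", duration_years = c(2, 3, 8), m = rnorm(3)), "m"),
    "at least 2")
})

test_that("cohort summary reproduces printed-count percentages", {
  rec <- data.frame(
    group = rep("MDAE", 105),
    sex = c(rep("F", 60), rep("M", 45)),
    ear_side = c(rep("L", 59), rep("R", 46)),
    duration_years = c(rep(0.5, 4), rep(3, 43), rep(7, 58)),
    age_years = rnorm(105, 57, 10)
  )
  s <- summarize_cohort(rec)
  cat_get <- function(field, level)
    s$categorical$pct[s$categorical$field == field &
                        s$categorical$level == level]
  expect_equal(cat_get("sex", "F"), 57.14)
  expect_equal(cat_get("sex", "M"), 42.86)
  expect_equal(cat_get("laterality", "L"), 56.19)
  expect_equal(cat_get("laterality", "R"), 43.81)
  expect_equal(cat_get("duration", "<1 year"), 3.81)
  expect_equal(cat_get("duration", ">5 years"), 55.24)
  # empty category reported as 0 (0.00%)
  rec$sex <- rep("F", 105)
  s2 <- summarize_cohort(rec)
  expect_equal(s2$categorical$n[s2$categorical$level == "M"], 0)
  expect_equal(s2$categorical$pct[s2$categorical$level == "M"], 0)
  # percentages per field sum to ~100
  for (f in unique(s$categorical$field))
    expect_equal(sum(s$categorical$pct[s$categorical$field == f]), 100,
                 tolerance = 0.02)
  expect_error(summarize_cohort(rec[0, ]), "empty")
})

test_that("shuffling group labels destroys an injected effect", {
  rec <- simulate_cohort(one_metric_cohort("CH_mm", 4.2, 4.1, 3.98,
                                           sd = 0.22, seed = 55))
  p_real <- three_group_comparison(rec, "CH_mm")$p_value
  expect_lt(p_real, 0.05)
  set.seed(56)
  p_perm <- replicate(200, {
    rec$group <- sample(rec$group)
    three_group_comparison(rec, "CH_mm")$p_value
  })
  rate <- mean(p_perm < 0.05)
  expect_lt(abs(rate - 0.05), 0.05)
})
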