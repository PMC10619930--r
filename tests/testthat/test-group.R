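test_that("condition-by-age model recovers the native-specific trajectory", {
  co <- generate_cohort(generator_config(seed = 8))
  m <- fit_condition_age_model(co$records)
  tb <- m$table
  expect_setequal(tb$term, c("(Intercept)", "age_c", "cond", "age_c:cond"))
  # native grows, non-native flat; native coded -0.5 makes the
  # age x condition estimate negative
  expect_lt(tb$estimate[tb$term == "age_c:cond"], 0)
  expect_lt(tb$p[tb$term == "age_c:cond"], 0.05)
  sl <- m$slopes
  expect_lt(sl$p[sl$condition == "native"], 0.001)
  expect_gt(sl$p[sl$condition == "nonnative"], 0.05)
  # Satterthwaite df close to the participant-level residual df
  expect_equal(tb$df[tb$term == "age_c:cond"], 64, tolerance = 0.1)
  expect_error(fit_condition_age_model(
    co$records[co$records$participant == "p001", ]), "2 participants")
})

test_that("recoding the condition contrast flips the relevant signs exactly", {
  co <- generate_cohort(generator_config(seed = 9))
  r <- co$records
  m1 <- fit_condition_age_model(r)
  r2 <- r
  r2$condition <- ifelse(r$condition == "native", "nonnative", "native")
  m2 <- fit_condition_age_model(r2)
  g <- function(m, term) m$table$estimate[m$table$term == term]
  expect_equal(g(m1, "cond"), -g(m2, "cond"), tolerance = 1e-6)
  expect_equal(g(m1, "age_c:cond"), -g(m2, "age_c:cond"), tolerance = 1e-6)
  expect_equal(g(m1, "age_c"), g(m2, "age_c"), tolerance = 1e-6)
})

test_that("divergence age is recovered and degenerate inputs behave", {
  # noise-free positive constant difference: earliest grid age
  rec <- data.frame(participant = rep(sprintf("p%02d", 1:20), 2),
                    age_months = rep(seq(3, 54, length.out = 20), 2),
                    condition = rep(c("native", "nonnative"), each = 20),
                    r_observed = rep(c(0.05, 0.01), each = 20),
                    r_baseline = 0)
  da <- divergence_age(rec, "condition")
  expect_equal(as.numeric(da), 3)

  # zero difference + noise: "none" in most replicates
  set.seed(1)
  nones <- sapply(1:30, function(i) {
    co <- generate_cohort(generator_config(
      beta_condition = 0, n_participants = 40L, n_female = 20L,
      seed = 600 + i))
    is.na(divergence_age(co$records, "condition"))
  })
  expect_gte(mean(nones), 0.9)

  # known crossover at 20 months recovered within +/- 6 months
  hits <- sapply(1:30, function(i) {
    co <- generate_cohort(generator_config(
      crossover_condition = 20, n_participants = 40L, n_female = 20L,
      seed = 700 + i))
    da <- divergence_age(co$records, "condition")
    !is.na(da) && abs(da - 20) <= 6
  })
  expect_gte(mean(hits), 0.7)

  # baseline pairing uses observed - baseline in the native condition
  co <- generate_cohort(generator_config(seed = 10))
  dab <- divergence_age(co$records, "baseline")
  expect_false(is.na(dab))
  expect_lt(abs(dab - co$truth$config$crossover_baseline), 8)
})

test_that("feature-timing model finds the duration-rank interaction", {
  co <- generate_cohort(generator_config(seed = 11))
  m <- fit_feature_timing_model(co$feature_records)
  tb <- m$table
  expect_true("age_c:dr" %in% tb$term)
  expect_gt(tb$t[tb$term == "age_c:dr"], 2)
  expect_lt(tb$p[tb$term == "age_c:dr"], 0.05)
  # occurrence rank is controlled for
  expect_true("occurrence_rank" %in% tb$term)
  fr <- co$feature_records
  fr$duration_rank <- 5L
  expect_error(fit_feature_timing_model(fr), "constant")
})

test_that("pitch model dissociates drivers and reports VIF/LRT", {
  co <- generate_cohort(generator_config(rank_link = "pitch",
                                         decouple_ranks = TRUE, seed = 12))
  m <- fit_pitch_similarity_model(co$feature_records)
  tb <- m$table
  expect_lt(tb$p[tb$term == "age_c:pr"], 0.05)
  expect_gt(tb$p[tb$term == "age_c:dr"], 0.05)
  expect_true(is.finite(m$lrt$p))
  expect_lt(m$lrt$p, 0.05)   # pitch term adds real information here
  expect_true(all(is.finite(m$vif)))

  # identical rank columns: no added information, comparison non-significant
  fr <- co$feature_records
  fr$pitch_similarity_rank <- fr$duration_rank
  m2 <- fit_pitch_similarity_model(fr)
  expect_gt(m2$lrt$p, 0.05)
  # and the duplicated interaction columns are flagged as collinear
  expect_gt(max(m2$vif), 3)
})

test_that("mean-centering age does not change interaction t values", {
  co <- generate_cohort(generator_config(seed = 13))
  r <- co$records
  m1 <- fit_condition_age_model(r)
  r2 <- r
  r2$age_months <- r2$age_months + 100  # only shifts the center
  m2 <- fit_condition_age_model(r2)
  expect_equal(m1$table$t[m1$table$term == "age_c:cond"],
               m2$table$t[m2$table$term == "age_c:cond"], tolerance = 1e-6)
})

test_that("sex-balanced bootstrap is reproducible and calibrated under the null", {
  co <- generate_cohort(generator_config(seed = 14))
  b1 <- balanced_bootstrap_ci(co$records, "condition_age", n_boot = 40,
                              seed = 5)
  b2 <- balanced_bootstrap_ci(co$records, "condition_age", n_boot = 40,
                              seed = 5)
  expect_identical(b1, b2)
  expect_true(all(is.finite(b1$ci_lower)) && all(is.finite(b1$ci_upper)))
  expect_true(all(b1$ci_lower < b1$ci_upper))
  # no sex effect in the generator: CIs for sex interactions include 0
  expect_true(all(b1$ci_lower < 0 & b1$ci_upper > 0))
  # timing variant runs too
  bt <- balanced_bootstrap_ci(co$feature_records, "timing", n_boot = 10,
                              seed = 6)
  expect_true(any(grepl("sex_code", bt$term)))
  one_sex <- co$records[co$records$sex == "f", ]
  expect_error(balanced_bootstrap_ci(one_sex, "condition_age", n_boot = 5),
               "both sexes")
})

test_that("age-shape comparison keeps linear and detects quadratic", {
  co <- generate_cohort(generator_config(seed = 15))
  cs <- compare_age_shapes(co$records)
  expect_setequal(cs$term, c("log", "quadratic", "cubic"))
  expect_true(all(cs$p > 0.01))  # generated linear: no shape improves much
  # inject a strong quadratic component
  r <- co$records
  ac <- r$age_months - mean(r$age_months)
  r$r_observed <- r$r_observed + 5e-5 * ac^2
  cs2 <- compare_age_shapes(r)
  expect_lt(cs2$p[cs2$term == "quadratic"], 0.05)
})
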