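test_that("default cohorts reproduce the study design dimensions", {
  cohort <- generate_cohort(cohort_config(seed = 5))
  expect_identical(dim(cohort$table), c(39L, 117L))
  expect_identical(sum(cohort$labels == 1L), 23L)
  expect_identical(sum(cohort$labels == -1L), 16L)
  expect_identical(colnames(cohort$table$values), mrs_schema()$feature_names)
  expect_false(anyNA(cohort$table$values))
})

test_that("generation is a pure function of the config", {
  a <- generate_cohort(cohort_config(seed = 123, missing_rate = 0.05))
  b <- generate_cohort(cohort_config(seed = 123, missing_rate = 0.05))
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$labels, b$labels)
  c <- generate_cohort(cohort_config(seed = 124, missing_rate = 0.05))
  expect_false(identical(a$table$values, c$table$values))
})

test_that("sem-mode sampling moments match the reconstructed group parameters", {
  # large negative group: sample moments of one feature against closed form
  cfg <- cohort_config(n_pos = 2, n_neg = 10000, seed = 31)
  cohort <- generate_cohort(cfg)
  x <- cohort$table$values[cohort$labels == -1L, "RDT.Cho+PCh"]
  target_sd <- 0.245 * sqrt(16)   # dispersion read as SEM at the reference n
  expect_lt(abs(mean(x) - 9.435), 4 * target_sd / sqrt(10000))
  expect_lt(abs(sd(x) - target_sd) / target_sd, 0.05)
})

test_that("sd mode uses the dispersion directly as the sampling SD", {
  cfg <- cohort_config(n_pos = 2, n_neg = 10000, dispersion_mode = "sd",
                       seed = 32)
  x <- generate_cohort(cfg)
  v <- x$table$values[x$labels == -1L, "RDT.Cho+PCh"]
  expect_lt(abs(sd(v) - 0.245) / 0.245, 0.05)
})

test_that("effect_scale collapses or stretches the group separation", {
  null_mom <- blsvm:::cohort_moments(cohort_config(effect_scale = 0))
  expect_equal(null_mom$mean_pos, null_mom$mean_neg)
  wide_mom <- blsvm:::cohort_moments(cohort_config(effect_scale = 2))
  base_mom <- blsvm:::cohort_moments(cohort_config(effect_scale = 1))
  expect_equal(wide_mom$mean_pos - wide_mom$mean_neg,
               2 * (base_mom$mean_pos - base_mom$mean_neg))
})

test_that("screening AUC of the significant set grows with effect_scale", {
  sig <- reference_significant()
  mean_auc <- function(scale) {
    mean(vapply(1:20, function(s) {
      cohort <- generate_cohort(cohort_config(effect_scale = scale,
                                              seed = 7000 + s))
      sc <- screen_features(cohort$table, cohort$labels)
      mean(abs(sc$auc[match(sig, sc$feature)] - 0.5))
    }, 1))
  }
  aucs <- c(mean_auc(0), mean_auc(0.5), mean_auc(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("MCAR injection hits the binomial cell count and spares no-row-left cases", {
  cohort <- generate_cohort(cohort_config(seed = 77))
  expect_identical(inject_missing(cohort$table, 0), cohort$table)

  masked <- inject_missing(cohort$table, 0.1, seed = 8)
  n_cells <- 39 * 117
  expected <- n_cells * 0.1
  slack <- 4 * sqrt(n_cells * 0.1 * 0.9)
  expect_lt(abs(sum(is.na(masked$values)) - expected), slack)
  # pre-mask values retained for oracles
  expect_identical(attr(masked, "shadow"), cohort$table$values)
  expect_equal(masked$values[!is.na(masked$values)],
               cohort$table$values[!is.na(masked$values)])

  # near-total missingness never yields an all-missing subject
  small <- feature_table(matrix(rnorm(40), 8, 5,
                                dimnames = list(NULL, paste0("f", 1:5))))
  for (s in 1:10) {
    hard <- inject_missing(small, 0.95, seed = s)
    expect_true(all(rowSums(!is.na(hard$values)) >= 1))
  }

  expect_error(inject_missing(cohort$table, 1), "missing_rate")
  expect_error(inject_missing(cohort$table, -0.1), "missing_rate")
})
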