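test_that("pearson_abs matches the product-moment formula and its edge cases", {
  x <- c(0.5, 1.7, 2.2, 4.1, 5.0)
  perfect <- pearson_abs(x, 2 * x + 1)
  expect_equal(perfect$abs_rho, 1)

  x4 <- c(1, 2, 3, 4); y4 <- c(1, 3, 2, 4)
  got <- pearson_abs(x4, y4)
  oracle <- abs(sum((x4 - mean(x4)) * (y4 - mean(y4))) /
                  sqrt(sum((x4 - mean(x4))^2) * sum((y4 - mean(y4))^2)))
  expect_equal(got$abs_rho, 0.8)
  expect_equal(got$abs_rho, oracle, tolerance = 1e-12)
  # two-sided t-transform oracle for the p-value
  tstat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(got$p_value, 2 * stats::pt(-tstat, df = 2), tolerance = 1e-12)

  expect_error(pearson_abs(x4, rep(2, 4)), class = "vocalmct_undefined_feature")
  expect_error(pearson_abs(x4, c(1, 2, 3)), "length")
  expect_error(pearson_abs(1:2, 2:1), "at least 3")
})

test_that("abs_rho is invariant under affine maps and sign flips", {
  set.seed(41)
  for (i in 1:25) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    base <- pearson_abs(x, y)$abs_rho
    a <- stats::runif(1, -5, 5); b <- stats::runif(1, 0.1, 4) * sample(c(-1, 1), 1)
    expect_equal(pearson_abs(a + b * x, y)$abs_rho, base, tolerance = 1e-10)
    expect_equal(pearson_abs(x, a + b * y)$abs_rho, base, tolerance = 1e-10)
    expect_equal(pearson_abs(-x, y)$abs_rho, base, tolerance = 1e-10)
  }
})

test_that("p-value decreases with n at fixed abs_rho", {
  x <- c(1, 2, 3, 5); y <- c(2, 1, 5, 7)  # |rho| strictly inside (0, 1)
  ps <- vapply(1:4, function(k) {
    r <- pearson_abs(rep(x, k), rep(y, k))
    r$p_value
  }, numeric(1))
  rhos <- vapply(1:4, function(k) pearson_abs(rep(x, k), rep(y, k))$abs_rho,
                 numeric(1))
  expect_equal(rhos, rep(rhos[1], 4), tolerance = 1e-12)
  expect_true(all(diff(ps) < 0))
})

# A hand-built biomarker table: mu_3 linear in FEV1, the rest noise.
fake_subject_rows <- function(n_steps = 6, seed = 50, constant = character()) {
  set.seed(seed)
  fev <- seq(3.4, 2.5, length.out = n_steps)
  rows <- data.frame(subject_id = "F01", step_index = seq_len(n_steps) - 1L,
                     cumulative_dose_mcg = c(0, 100 * 2^(seq_len(n_steps - 1) - 1)),
                     fev1_l = fev)
  for (b in c(paste0("mu_", 1:40), paste0("sigma_", 1:40)))
    rows[[b]] <- if (b %in% constant) 1 else stats::rnorm(n_steps)
  rows$mu_3 <- 1000 - 200 * fev
  rows
}

test_that("correlate_all screens all 80 biomarkers with pairwise completeness", {
  rows <- fake_subject_rows()
  co <- correlate_all(rows)
  expect_equal(nrow(co), 80L)
  expect_equal(co$abs_rho[co$biomarker == "mu_3"], 1)
  expect_equal(co$biomarker[1], "mu_3")

  flipped <- rows
  flipped$mu_3 <- -flipped$mu_3
  expect_equal(correlate_all(flipped)$abs_rho[1], 1)

  # constant biomarkers are skipped, not reported
  rows_const <- fake_subject_rows(constant = c("sigma_7", "mu_11"))
  co2 <- correlate_all(rows_const)
  expect_equal(nrow(co2), 78L)
  expect_false(any(co2$biomarker %in% c("sigma_7", "mu_11")))

  # a missing step leaves pairwise-complete correlation with reduced n
  rows_na <- fake_subject_rows(n_steps = 6)
  rows_na$mu_5[2] <- NA
  co3 <- correlate_all(rows_na)
  expect_equal(co3$n[co3$biomarker == "mu_5"], 5L)
  expect_equal(co3$n[co3$biomarker == "mu_3"], 6L)

  expect_error(correlate_all(fake_subject_rows(n_steps = 2)), "at least 3")
})

test_that("best biomarker ranking breaks ties mu-first then by lower id", {
  co <- data.frame(biomarker = c("sigma_5", "mu_5", "mu_9"),
                   abs_rho = c(0.9, 0.9, 0.7),
                   p_value = c(0.01, 0.01, 0.2),
                   p_bonferroni = 1, n = 5)
  expect_equal(best_biomarker(co)$parameter, "mu_5")

  co2 <- data.frame(biomarker = c("mu_7", "mu_5"), abs_rho = c(0.8, 0.8),
                    p_value = 0.05, p_bonferroni = 1, n = 5)
  expect_equal(best_biomarker(co2)$parameter, "mu_5")

  single <- data.frame(biomarker = "sigma_31", abs_rho = 0.4, p_value = 0.4,
                       p_bonferroni = 1, n = 4)
  expect_equal(best_biomarker(single)$parameter, "sigma_31")
  expect_error(best_biomarker(single[0, ]), "no defined")
})

test_that("cross-subject feature summary uses the sample SD", {
  cos <- list(
    A = data.frame(biomarker = "mu_40", abs_rho = 0.2),
    B = data.frame(biomarker = "mu_40", abs_rho = 0.8))
  s <- cross_subject_feature_summary(cos, "mu_40")
  expect_equal(s$mean_abs_rho, 0.5)
  expect_equal(s$sd_abs_rho, stats::sd(c(0.2, 0.8)))
  expect_equal(s$n_subjects, 2L)

  allone <- list(A = data.frame(biomarker = "mu_1", abs_rho = 1),
                 B = data.frame(biomarker = "mu_1", abs_rho = 1),
                 C = data.frame(biomarker = "mu_1", abs_rho = 1))
  s1 <- cross_subject_feature_summary(allone, "mu_1")
  expect_equal(c(s1$mean_abs_rho, s1$sd_abs_rho), c(1, 0))

  expect_error(cross_subject_feature_summary(cos, "sigma_2"),
               "fewer than 2")
})

test_that("cohort report has one best-biomarker row per subject", {
  tabs <- lapply(1:4, function(i) {
    r <- fake_subject_rows(seed = 60 + i)
    r$subject_id <- sprintf("F%02d", i)
    # two subjects cross the 20% fall (positive), two stay shallow (negative)
    r$fev1_l <- if (i <= 2) seq(3.4, 2.4, length.out = nrow(r)) else
      seq(3.4, 3.0, length.out = nrow(r))
    r$mu_3 <- 1000 - 200 * r$fev1_l
    r
  })
  table <- do.call(rbind, tabs)
  rep <- build_report(table)
  expect_equal(nrow(rep$subjects), 4L)
  expect_named(rep$subjects, c("subject_id", "parameter", "abs_rho",
                               "p_value", "mct_result"))
  expect_equal(rep$subjects$parameter, rep("mu_3", 4))
  expect_equal(sort(unique(rep$subjects$mct_result)),
               c("negative", "positive"))
  expect_equal(rep$features$parameter[1], "mu_3")

  out <- withr::local_tempdir()
  build_report(table, out_dir = out)
  expect_true(file.exists(file.path(out, "report.csv")))
  expect_true(file.exists(file.path(out, "feature_summary.csv")))

  expect_error(build_report(table[0, ]), "empty")
})
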