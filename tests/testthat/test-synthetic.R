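test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(cohort_config(seed = 9))
  b <- simulate_cohort(cohort_config(seed = 9))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$tables, b$tables)
  c <- simulate_cohort(cohort_config(seed = 10))
  expect_false(identical(a$tables$U, c$tables$U))
})

test_that("the age-PMI copula hits its target correlation", {
  md0 <- simulate_metadata(cohort_config(n_samples = 2000, seed = 7,
                                         age_pmi_correlation = 0))
  expect_lt(abs(cor(md0$age_years, md0$pmi_hours)), 0.05)
  md <- simulate_metadata(cohort_config(n_samples = 2000, seed = 7))
  r <- cor(md$age_years, md$pmi_hours)
  expect_gt(r, 0.30)
  expect_lt(r, 0.40)
  expect_true(all(md$pmi_hours >= 16 & md$pmi_hours <= 170))
  expect_true(all(md$age_years >= 20 & md$age_years <= 87))
})

test_that("metadata generation rejects cohorts too small for cross-validation", {
  expect_error(simulate_metadata(cohort_config(n_samples = 3)), "at least 4")
})

test_that("with noise off the table equals the closed-form latent model", {
  panel <- tibble::tibble(
    name = c("lin", "surge"), baseline = c(10, 5), pmi_slope = c(0.1, 0),
    age_slope = 0, surge_onset = c(NA, 100), surge_slope = c(0, 0.2),
    exogenous = FALSE, u_only = FALSE, role = c("pmi_linked", "surge")
  )
  cfg <- cohort_config(n_samples = 6, panel = panel, noise_cv = 0,
                       bio_cv = 0, sample_scale_cv = 0, seed = 3)
  md <- simulate_metadata(cfg)
  md$pmi_hours <- c(100, 50, 20, 120, 80, 150)
  cc <- simulate_concentrations(md, cfg)
  tbl <- cc$tables$U
  expect_equal(tbl$lin, 10 + 0.1 * md$pmi_hours)
  expect_equal(tbl$lin[1], 20)
  # hinge inactive below onset, active above it
  expect_equal(tbl$surge[2], 5)
  expect_equal(tbl$surge[4], 5 + 0.2 * 20)
  expect_equal(as.matrix(tbl[-1]), attr(cc$truth, "latent"), ignore_attr = TRUE)
  # U and LLE identical without noise
  expect_equal(tbl$lin, cc$tables$LLE$lin)
})

test_that("paired U/LLE tables share their biology", {
  cohort <- simulate_cohort(cohort_config(n_samples = 200, seed = 5))
  shared <- setdiff(intersect(names(cohort$tables$U), names(cohort$tables$LLE)),
                    "sample_id")
  pc <- vapply(shared, function(m) cor(cohort$tables$U[[m]], cohort$tables$LLE[[m]]),
               numeric(1))
  roles <- cohort$truth$role[match(shared, cohort$truth$name)]
  # metabolites carrying latent structure: pairing dominated by shared biology
  expect_gt(min(pc[roles %in% c("pmi_linked", "surge")]), 0.9)
  # structureless fillers still strongly concordant
  expect_gt(median(pc), 0.85)
})

test_that("the stable-metabolite control carries no PMI structure", {
  truth <- simulate_cohort(cohort_config(seed = 1))$truth
  hb <- truth[truth$name == "3-hydroxybutyrate", ]
  expect_equal(hb$pmi_slope, 0)
  expect_true(is.na(hb$surge_onset))
  expect_equal(hb$role, "stable")
  # panel composition: 4 PMI-linked, 4 surge, 1 stable, 2 exogenous, 39 nulls
  expect_equal(unname(table(truth$role)[c("pmi_linked", "surge", "stable",
                                          "exogenous", "null")]),
               c(4L, 4L, 1L, 2L, 39L), ignore_attr = TRUE)
})

test_that("concentrations are non-negative and finite at default noise", {
  cohort <- simulate_cohort(cohort_config(seed = 21))
  for (tbl in cohort$tables) {
    m <- as.matrix(tbl[-1])
    expect_true(all(is.finite(m)))
    expect_true(all(m >= 0))
  }
})
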