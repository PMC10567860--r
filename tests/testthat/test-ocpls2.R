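test_that("with no constraint the fit reduces to textbook NIPALS PLS", {
  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(8:20, 1)
    p <- sample(3:10, 1)
    a_max <- sample(1:3, 1)
    inst <- make_linear_instance(n, p, seed)
    y <- inst$y + rnorm(n)
    sp <- scale_pair(inst$X, y)
    oracle <- reference_pls1(sp$X, sp$y, a_max)
    fit <- ocpls2(sp$X, y, z = NULL, n_predictive = a_max)
    fitted_scaled <- (fit$fitted - mean(y)) / sd(y)
    expect_lt(max(abs(fitted_scaled - c(oracle$fitted))), 1e-6)
    # a zero constraint column must behave identically
    fit0 <- ocpls2(sp$X, y, z = matrix(0, n, 1), n_predictive = a_max)
    expect_equal(fit0$fitted, fit$fitted, tolerance = 1e-8)
  }
})

test_that("predictive scores are exactly orthogonal to the constraint", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 18; p <- 12
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    z <- cbind(rnorm(n), rnorm(n))[, seq_len(sample(1:2, 1)), drop = FALSE]
    no <- sample(0:1, 1)
    fit <- ocpls2(scale(X), y, z = z, n_predictive = 2, n_non_predictive = no)
    expect_lt(max(abs(crossprod(fit$scores, fit$constraint))), 1e-8)
    if (no > 0) {
      expect_lt(max(abs(crossprod(fit$ortho_scores, fit$constraint))), 1e-8)
    }
    # predictive scores mutually orthogonal
    g <- crossprod(fit$scores)
    expect_lt(max(abs(g - diag(diag(g)))), 1e-8)
  }
})

test_that("the constrained model recovers the signal part of y = Xb + Zg", {
  set.seed(99)
  n <- 60; p <- 10
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
  beta <- c(rep(1, 3), rep(0, p - 3))
  z <- resid(lm(rnorm(n) ~ X))  # constraint variation outside the X space
  y <- c(X %*% beta) + 3 * z
  fit <- ocpls2(scale(X), y, z = z, n_predictive = 6)
  X_new <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", 1:p)))
  X_new_s <- sweep(sweep(X_new, 2, fit$x_center), 2, fit$x_scale, "/")
  pred <- predict(fit, X_new_s)
  expect_gt(cor(pred, c(X_new %*% beta)), 0.99)
})

test_that("prediction is consistent with the fit and centring identities", {
  cohort <- simulate_cohort(cohort_config(seed = 6))
  tbl <- exclude_exogenous(cohort$tables$U)
  y <- cohort$metadata$pmi_hours
  sc <- autoscale(tbl)
  fit <- ocpls2(sc, y, z = cohort$metadata$age_years, 1, 0)
  # predicting the training data reproduces the fitted values
  expect_equal(predict(fit, sc), fit$fitted, tolerance = 1e-10, ignore_attr = TRUE)
  # RMSE of the training predictions is SDEC by definition
  perf <- performance_metrics(y, fit$fitted, "calibration")
  expect_equal(perf$error, sqrt(mean((y - fit$fitted)^2)))
  # a sample at the training means predicts the mean PMI
  centre <- matrix(0, 1, length(fit$metabolites),
                   dimnames = list("c", fit$metabolites))
  sc_centre <- structure(list(values = centre), class = "pf_scaled")
  expect_equal(unname(predict(fit, sc_centre)), mean(y))
  # panel mismatch is a clear error
  bad <- tbl[, 1:10]
  expect_error(predict(fit, bad), "panel mismatch")
})

test_that("performance metrics match hand-computed sums of squares", {
  perf <- performance_metrics(c(0, 0, 3, 3), c(1, -1, 4, 2), "calibration")
  expect_equal(perf$error, 1)
  expect_equal(perf$r2, 1 - 4 / 9)
  ideal <- performance_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ideal$error, 0)
  expect_equal(ideal$r2, 1)
  null_pred <- performance_metrics(c(1, 2, 3), rep(2, 3))
  expect_equal(null_pred$r2, 0)
  expect_error(performance_metrics(c(2, 2), c(1, 2)), "constant")
})

test_that("VIP satisfies its normalization and symmetry identities", {
  set.seed(31)
  # orthogonal two-predictor design where only the first carries y
  y <- rnorm(40)
  v <- rnorm(40)
  v <- resid(lm(v ~ y))
  X <- cbind(a = y / sd(y), b = v / sd(v))
  fit <- ocpls2(X, y, n_predictive = 1)
  expect_equal(unname(vip(fit)), c(sqrt(2), 0), tolerance = 1e-8)
  # duplicated informative predictors share identical VIPs
  X3 <- cbind(a = y, a2 = y, b = v)
  colnames(X3) <- c("a", "a2", "b")
  fit3 <- ocpls2(scale(X3), y, n_predictive = 1)
  v3 <- vip(fit3)
  expect_equal(v3[["a"]], v3[["a2"]], tolerance = 1e-10)
  # sum of squared VIPs equals the number of predictors
  cohort <- simulate_cohort(cohort_config(seed = 3))
  fitc <- ocpls2(autoscale(exclude_exogenous(cohort$tables$U)),
                 cohort$metadata$pmi_hours,
                 z = cohort$metadata$age_years, 2, 1)
  expect_lt(abs(sum(vip(fitc)^2) - length(fitc$metabolites)), 1e-8)
})

test_that("the constrained fit is immune to age while the unconstrained is not", {
  # fitted values live in the span of the predictive scores, which are exactly
  # orthogonal to centred age: the constrained model cannot encode age.
  cors_con <- cors_unc <- numeric(25)
  for (s in seq_len(25)) {
    panel <- dplyr::bind_rows(
      default_panel(),
      tibble::tibble(name = "age_marker", baseline = 0.5, pmi_slope = 0,
                     age_slope = 0.04, surge_onset = NA_real_, surge_slope = 0,
                     exogenous = FALSE, u_only = FALSE, role = "age_linked")
    )
    cohort <- simulate_cohort(cohort_config(seed = 400 + s, panel = panel,
                                            pmi_range = c(16, 100)))
    tbl <- exclude_exogenous(cohort$tables$U)
    y <- cohort$metadata$pmi_hours
    age <- cohort$metadata$age_years
    sc <- autoscale(tbl)
    fit_con <- ocpls2(sc, y, z = age, 1, 0)
    fit_unc <- ocpls2(sc, y, z = NULL, 1, 0)
    age_resid <- age - mean(age)
    cors_con[s] <- cor(fit_con$fitted, age_resid)
    cors_unc[s] <- cor(fit_unc$fitted, age_resid)
  }
  expect_lt(max(abs(cors_con)), 1e-8)
  expect_gt(mean(cors_unc), 0.1)
})

test_that("repeated cross-validation is deterministic and separates signal from noise", {
  cohort <- simulate_cohort(cohort_config(seed = 12))
  tbl <- exclude_exogenous(cohort$tables$U)
  y <- cohort$metadata$pmi_hours
  z <- cohort$metadata$age_years
  cv1 <- suppressWarnings(repeated_cv(tbl, y, z, 1, 0, seed = 77))
  cv2 <- suppressWarnings(repeated_cv(tbl, y, z, 1, 0, seed = 77))
  expect_identical(cv1$q2, cv2$q2)
  expect_identical(cv1$sdecv, cv2$sdecv)
  # noise-free linear signal: near-perfect Q2
  inst <- make_linear_instance(40, 6, seed = 13)
  cv_sig <- repeated_cv(inst$X, 100 + inst$y * 10, NULL, 3, 0,
                        repetitions = 5, seed = 1)
  expect_gt(cv_sig$q2, 0.95)
  # pure noise: Q2 near or below zero on average over seeds
  q2s <- vapply(1:30, function(s) {
    set.seed(s)
    Xn <- matrix(rnorm(60 * 8), 60, 8)
    yn <- rnorm(60)
    suppressWarnings(repeated_cv(Xn, yn, NULL, 1, 0, repetitions = 3,
                                 seed = s)$q2)
  }, numeric(1))
  expect_lt(mean(q2s), 0.05)
})

test_that("component selection finds the generating structure", {
  set.seed(55)
  n <- 40
  t1 <- rnorm(n)
  # single exact latent factor: only a (1, 0) model is identifiable
  X <- outer(t1, c(1, 1, 1, 0.5, 0.5))
  colnames(X) <- paste0("m", 1:5)
  y <- 50 + 10 * t1 + rnorm(n, sd = 1)
  sel <- select_components(X, y, max_predictive = 3, max_non_predictive = 1,
                           repetitions = 5, seed = 2)
  expect_equal(sel$n_predictive, 1L)
  expect_equal(sel$n_non_predictive, 0L)
  # a strong y-uncorrelated systematic factor calls for a non-predictive component
  Xn <- X + matrix(rnorm(n * 5, sd = 0.4), n, 5)
  t2 <- rnorm(n)
  X2 <- Xn + outer(t2, c(6, -6, 6, -6, 6))
  sel2 <- select_components(X2, y, max_predictive = 1, max_non_predictive = 2,
                            repetitions = 5, seed = 2)
  expect_gte(sel2$n_non_predictive, 1L)
  # the search space can be capped to a single predictive component
  sel3 <- select_components(Xn, y, max_predictive = 1, max_non_predictive = 0,
                            repetitions = 2, seed = 2)
  expect_equal(c(sel3$n_predictive, sel3$n_non_predictive), c(1L, 0L))
})

test_that("the randomization test hits its boundary p-value on strong signal", {
  inst <- make_linear_instance(24, 5, seed = 3)
  y <- 80 + 20 * scale(inst$y)
  rt <- randomization_test(inst$X, c(y), NULL, 1, 0, n_permutations = 99,
                           repetitions = 2, seed = 4)
  expect_equal(rt$p_r2, 1 / 100)
  expect_equal(rt$p_q2, 1 / 100)
  expect_gte(rt$p_r2, 1 / (1 + rt$n_permutations))
  expect_error(
    randomization_test(inst$X, c(y), NULL, 1, 0, n_permutations = 10),
    "99"
  )
})

test_that("an over-constrained fit fails loudly", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  z <- matrix(rnorm(30), 10, 3)
  expect_error(ocpls2(scale(X), rnorm(10), z = z), "null space")
})
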