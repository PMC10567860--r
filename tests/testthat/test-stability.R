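test_that("BMS subsampling matches its binomial expectation and is deterministic", {
  masks <- bms_subsamples(24, 50, probability = 0.7, count = 200, seed = 1)
  rows <- vapply(masks, function(m) sum(m$rows), numeric(1))
  expect_gt(mean(rows), 15.5)   # E = 16.8
  expect_lt(mean(rows), 18)
  cols <- vapply(masks, function(m) sum(m$cols), numeric(1))
  expect_gt(mean(cols), 31)     # E = 35
  expect_lt(mean(cols), 39)
  expect_identical(masks, bms_subsamples(24, 50, 0.7, 200, seed = 1))
  full <- bms_subsamples(10, 5, probability = 1, count = 3, seed = 1)
  expect_true(all(vapply(full, function(m) all(m$rows) && all(m$cols), logical(1))))
  # masks below the minima are redrawn
  small <- bms_subsamples(10, 2, probability = 0.4, count = 50, seed = 2)
  expect_true(all(vapply(small, function(m) sum(m$cols), numeric(1)) >= 2))
})

test_that("the Poisson-binomial tail matches brute-force enumeration", {
  set.seed(42)
  for (i in 1:10) {
    S <- sample(5:15, 1)
    probs <- runif(S)
    k <- sample(0:S, 1)
    expect_equal(pfpmi:::poisbinom_tail(probs, k),
                 brute_poisbinom_tail(probs, k), tolerance = 1e-12)
  }
  # equal probabilities reduce to the binomial tail
  expect_equal(pfpmi:::poisbinom_tail(rep(0.3, 12), 4),
               sum(dbinom(4:12, 12, 0.3)), tolerance = 1e-12)
})

test_that("relevance_test flags extreme counts and centres on its null", {
  S <- 60
  avail <- matrix(TRUE, S, 2, dimnames = list(NULL, c("hit", "typical")))
  sel <- matrix(FALSE, S, 2, dimnames = list(NULL, c("hit", "typical")))
  sel[, "hit"] <- TRUE
  # subset sizes ~ half the available predictors elsewhere: fake via a third column
  avail3 <- cbind(avail, other = TRUE)
  sel3 <- cbind(sel, other = rep(c(TRUE, FALSE), length.out = S))
  # null prob per subsample is (size/3) <= 2/3; always-selected must be extreme
  rep <- relevance_test(sel3, avail3, alpha = 0.05)
  expect_lt(rep$p_value[rep$metabolite == "hit"], 1e-10)
  expect_true(rep$relevant[rep$metabolite == "hit"])
  # a count at the null expectation gives p near one half
  set.seed(8)
  S2 <- 100
  sizes_sel <- matrix(FALSE, S2, 4, dimnames = list(NULL, letters[1:4]))
  for (s in 1:S2) sizes_sel[s, sample(4, 2)] <- TRUE  # uniform size-2 subsets
  avail2 <- matrix(TRUE, S2, 4, dimnames = list(NULL, letters[1:4]))
  rep2 <- relevance_test(sizes_sel, avail2)
  target <- rep2[which.min(abs(rep2$selection_count - S2 / 2)), ]
  expect_gt(target$p_value, 0.3)
  expect_lt(target$p_value, 0.7)
})

test_that("best_subset retains a strongly informative predictor", {
  found <- logical(50)
  for (s in seq_len(50)) {
    set.seed(600 + s)
    n <- 24
    X <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, c("signal", paste0("noise", 1:19))))
    y <- 60 + 25 * X[, "signal"]
    sub <- best_subset(X, y, NULL, repetitions = 3, seed = 600 + s)
    found[s] <- "signal" %in% sub
  }
  expect_gt(mean(found), 0.95)
})

test_that("best_subset keeps at least one of two duplicated informative columns", {
  set.seed(17)
  n <- 24
  sig <- rnorm(n)
  X <- cbind(dup1 = sig, dup2 = sig, matrix(rnorm(n * 8), n, 8,
                                            dimnames = list(NULL, paste0("n", 1:8))))
  y <- 70 + 20 * sig + rnorm(n, sd = 2)
  sub <- best_subset(X, y, NULL, repetitions = 3, seed = 17)
  expect_true(any(c("dup1", "dup2") %in% sub))
})

test_that("stability selection separates true markers from the stable control", {
  cohort <- simulate_cohort(cohort_config(seed = 300, pmi_range = c(16, 100)))
  tbl <- exclude_exogenous(cohort$tables$U)
  st <- suppressWarnings(
    stability_selection(tbl, cohort$metadata$pmi_hours,
                        z = cohort$metadata$age_years,
                        n_subsamples = 100, seed = 300))
  expect_s3_class(st, "pf_stability")
  expect_true(all(st$selection_frequency >= 0 & st$selection_frequency <= 1))
  expect_true(all(st$relevant == (st$p_value < 0.05)))
  markers <- c("choline", "ethanolamine", "glycine", "hypoxanthine")
  freq <- st$selection_frequency[match(markers, st$metabolite)]
  hb_freq <- st$selection_frequency[st$metabolite == "3-hydroxybutyrate"]
  expect_true(all(freq > hb_freq))
  expect_gte(sum(st$relevant[match(markers, st$metabolite)]), 3)
})

test_that("selection frequency responds monotonically to the true slope", {
  freqs <- vapply(c(0.01, 0.05, 0.1), function(slope) {
    panel <- default_panel()
    panel$pmi_slope[panel$name == "choline"] <- slope
    cohort <- simulate_cohort(cohort_config(seed = 42, panel = panel,
                                            pmi_range = c(16, 100)))
    tbl <- exclude_exogenous(cohort$tables$U)
    st <- suppressWarnings(
      stability_selection(tbl, cohort$metadata$pmi_hours,
                          z = cohort$metadata$age_years,
                          n_subsamples = 60, seed = 42))
    st$selection_frequency[st$metabolite == "choline"]
  }, numeric(1))
  expect_true(all(diff(freqs) >= 0))
})
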