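#' PMI-stratified training/test split
#'
#' Bins PMI into `n_bins` equal-frequency bins and draws the test set within
#' bins proportionally to bin size (largest-remainder rounding), so the test
#' set spans the whole PMI range. The draw is re-attempted (up to
#' `max_attempts`) until the training set matches the cohort's sex proportion
#' to within one sample and its mean age lies within half a cohort SD of the
#' cohort mean, reproducing a split whose training demographics mirror the
#' collected samples.
#'
#' @param metadata Metadata tibble.
#' @param train_size,test_size Sizes; must sum to the cohort size (defaults
#'   18 and 6).
#' @param n_bins Number of equal-frequency PMI bins (default 4).
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap (default 100).
#' @return A list of class `pf_split`: `train_ids`, `test_ids`, `pmi_bins`
#'   (break points), `seed`, `attempts`.
#' @examples
#' split <- stratified_split(load_cohort_fixture(), seed = 1)
#' length(split$train_ids); length(split$test_ids)
#' @export
stratified_split <- function(metadata, train_size = 18, test_size = 6,
                             n_bins = 4, seed = 1, max_attempts = 100) {
  validate_metadata(metadata)
  n <- nrow(metadata)
  if (train_size + test_size != n) {
    stop("train_size + test_size must equal the cohort size (", n, ")", call. = FALSE)
  }
  breaks <- unique(quantile(metadata$pmi_hours, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(metadata$pmi_hours, breaks = breaks, include.lowest = TRUE)
  if (any(table(bin) == 0)) stop("empty PMI bin; reduce n_bins", call. = FALSE)
  # proportional allocation of the test set, largest-remainder rounding
  sizes <- as.integer(table(bin))
  quota <- test_size * sizes / n
  alloc <- floor(quota)
  rem <- test_size - sum(alloc)
  if (rem > 0) {
    extra <- order(quota - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  alloc <- pmin(alloc, sizes)
  male_frac <- mean(metadata$sex == "M")
  age_mean <- mean(metadata$age_years); age_sd <- sd(metadata$age_years)
  withr::with_seed(stream_seed(seed, "split"), {
    for (attempt in seq_len(max_attempts)) {
      test_ids <- unlist(lapply(seq_along(levels(bin)), function(b) {
        ids <- metadata$sample_id[bin == levels(bin)[b]]
        if (alloc[b] == 0) character(0) else sample(ids, alloc[b])
      }))
      train_ids <- setdiff(metadata$sample_id, test_ids)
      tr <- metadata[metadata$sample_id %in% train_ids, ]
      sex_ok <- abs(sum(tr$sex == "M") - male_frac * train_size) <= 1
      age_ok <- abs(mean(tr$age_years) - age_mean) <= 0.5 * age_sd
      if ((sex_ok && age_ok) || test_size == 0) {
        return(structure(list(train_ids = train_ids, test_ids = test_ids,
                              pmi_bins = breaks, seed = seed, attempts = attempt),
                         class = "pf_split"))
      }
    }
  })
  stop("no split satisfying the demographic constraints after ", max_attempts,
       " attempts; try a different seed or bin count", call. = FALSE)
}

#' @export
print.pf_split <- function(x, ...) {
  cat(sprintf("Stratified split: %d training / %d test samples (%d attempt(s))\n",
              length(x$train_ids), length(x$test_ids), x$attempts))
  invisible(x)
}

#' Restrict a cohort to a maximum PMI
#'
#' Keeps the samples with PMI at or below `max_pmi` in the metadata and in
#' every aligned concentration table, the range-restriction strategy used
#' when late-PMI non-linearity (bacterial co-metabolism) degrades a linear
#' model.
#'
#' @param metadata Metadata tibble.
#' @param tables A concentration tibble or a named list of them.
#' @param max_pmi Hours; must exceed the minimum cohort PMI.
#' @return List with filtered `metadata` and `tables` (same shape as input).
#'   Fewer than 10 remaining samples warns; fewer than 6 is an error.
#' @export
restrict_range <- function(metadata, tables, max_pmi) {
  validate_metadata(metadata)
  if (max_pmi <= min(metadata$pmi_hours)) {
    stop("max_pmi is at or below the minimum cohort PMI", call. = FALSE)
  }
  keep <- metadata$pmi_hours <= max_pmi
  if (sum(keep) < 6) stop("fewer than 6 samples remain below max_pmi", call. = FALSE)
  if (sum(keep) < 10) warning("fewer than 10 samples remain below max_pmi", call. = FALSE)
  md <- metadata[keep, ]
  single <- is.data.frame(tables)
  tl <- if (single) list(table = tables) else tables
  tl <- lapply(tl, function(t) t[t$sample_id %in% md$sample_id, ])
  list(metadata = md, tables = if (single) tl[[1]] else tl)
}

#' Run the full PMI-estimation study workflow
#'
#' Orchestrates the complete analysis on one or more protocol tables:
#' exogenous-metabolite exclusion, cohort summary, PMI-stratified
#' training/test split, and then per protocol and per PMI range
#' (full and restricted): training-set autoscaling, component selection by
#' repeated cross-validation, the age-constrained oCPLS2 fit with R2/SDEC,
#' Q2/SDECV, randomization-test p-values, held-out prediction (SDEP),
#' VIP-based stability selection, and age-corrected univariate profiles.
#' The restricted-range analysis reuses the full-range split minus the
#' samples above the cut-off.
#'
#' @param tables Concentration tibble or named list of them (e.g.
#'   `list(U = ..., LLE = ...)`).
#' @param metadata Metadata tibble covering every sample id.
#' @param constraint Metadata column(s) used as the orthogonality constraint
#'   (default `"age_years"`); `NULL` for unconstrained PLS.
#' @param exclusions Exogenous exclusion list (default
#'   [default_exclusions()]).
#' @param ranges Named numeric vector of maximum PMIs per analysis range
#'   (default `c(full = Inf, le_100 = 100)`).
#' @param train_size,test_size,n_bins Split settings (see
#'   [stratified_split()]).
#' @param max_predictive,max_non_predictive Component search bounds.
#' @param cv_k,cv_repetitions Model-level cross-validation settings
#'   (default 5-fold, 20 repetitions).
#' @param n_permutations Randomization-test permutations (default 999); set
#'   `run_permutations = FALSE` to skip.
#' @param run_permutations,run_stability Toggle the expensive stages.
#' @param stability_subsamples,stability_cv_repetitions Stability-selection
#'   settings (default 200 subsamples, 5 within-subsample CV repetitions).
#' @param alpha Significance level used throughout (default 0.05).
#' @param seed Integer seed; every random stage derives its stream from it.
#' @return A list of class `pf_run`: `cohort`, `split`, `performance` (one
#'   row per protocol x range), `stability` and `profiles` tibbles, `config`,
#'   `seed`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' run <- run_study(cohort$tables, cohort$metadata, seed = 1,
#'                  run_permutations = FALSE, stability_subsamples = 25)
#' run$performance
#' }
#' @export
run_study <- function(tables, metadata, constraint = "age_years",
                      exclusions = default_exclusions(),
                      ranges = c(full = Inf, le_100 = 100),
                      train_size = 18, test_size = 6, n_bins = 4,
                      max_predictive = 2, max_non_predictive = 1,
                      cv_k = 5, cv_repetitions = 20,
                      n_permutations = 999, run_permutations = TRUE,
                      run_stability = TRUE,
                      stability_subsamples = 200, stability_cv_repetitions = 5,
                      alpha = 0.05, seed = 1) {
  if (is.data.frame(tables)) tables <- list(U = tables)
  validate_metadata(metadata)
  if (is.null(names(ranges))) names(ranges) <- paste0("range_", seq_along(ranges))
  tables <- lapply(tables, exclude_exogenous, exclusions = exclusions)
  cohort <- cohort_summary(metadata)
  split <- stratified_split(metadata, train_size = train_size,
                            test_size = test_size, n_bins = n_bins, seed = seed)
  perf_rows <- list(); stab_rows <- list(); prof_rows <- list()
  for (prot in names(tables)) {
    tbl <- tables[[prot]]
    md <- metadata[match(tbl$sample_id, metadata$sample_id), ]
    for (rg in names(ranges)) {
      max_pmi <- ranges[[rg]]
      keep <- md$pmi_hours <= max_pmi
      md_r <- md[keep, ]; tbl_r <- tbl[keep, ]
      tr <- tbl_r$sample_id %in% split$train_ids
      te <- tbl_r$sample_id %in% split$test_ids
      y_tr <- md_r$pmi_hours[tr]
      Z_tr <- if (is.null(constraint)) NULL else as.matrix(md_r[tr, constraint])
      X_tr <- tbl_r[tr, ]
      sel <- select_components(X_tr, y_tr, Z_tr,
                               max_predictive = max_predictive,
                               max_non_predictive = max_non_predictive,
                               k = cv_k, repetitions = cv_repetitions, seed = seed)
      sc_tr <- suppressWarnings(autoscale(X_tr))
      fit <- ocpls2(sc_tr, y_tr, z = Z_tr,
                    n_predictive = sel$n_predictive,
                    n_non_predictive = sel$n_non_predictive)
      cal <- performance_metrics(y_tr, fit$fitted, mode = "calibration")
      cv <- suppressWarnings(
        repeated_cv(X_tr, y_tr, Z_tr, sel$n_predictive, sel$n_non_predictive,
                    k = cv_k, repetitions = cv_repetitions, seed = seed))
      p_r2 <- p_q2 <- NA_real_
      if (run_permutations) {
        rt <- randomization_test(X_tr, y_tr, Z_tr, sel$n_predictive,
                                 sel$n_non_predictive,
                                 n_permutations = n_permutations,
                                 k = cv_k, repetitions = cv_repetitions,
                                 seed = seed)
        p_r2 <- rt$p_r2; p_q2 <- rt$p_q2
      }
      sdep <- NA_real_
      if (sum(te) >= 2) {
        pred <- predict(fit, autoscale(tbl_r[te, ], reference = sc_tr))
        sdep <- performance_metrics(md_r$pmi_hours[te], pred,
                                    mode = "prediction")$error
      }
      perf_rows[[paste(prot, rg)]] <- tibble::tibble(
        protocol = prot, range = rg, max_pmi = max_pmi,
        n_train = sum(tr), n_test = sum(te),
        n_predictive = sel$n_predictive,
        n_non_predictive = sel$n_non_predictive,
        r2 = cal$r2, q2 = cv$q2, sdec = cal$error, sdecv = cv$sdecv,
        sdep = sdep, p_r2 = p_r2, p_q2 = p_q2
      )
      if (run_stability) {
        st <- suppressWarnings(
          stability_selection(X_tr, y_tr, Z_tr,
                              n_subsamples = stability_subsamples,
                              alpha = alpha,
                              n_predictive = sel$n_predictive,
                              n_non_predictive = sel$n_non_predictive,
                              repetitions = stability_cv_repetitions,
                              seed = seed))
        stab_rows[[paste(prot, rg)]] <- dplyr::mutate(
          tibble::as_tibble(st), protocol = prot, range = rg, .before = 1)
      }
      prof_rows[[paste(prot, rg)]] <- dplyr::mutate(
        metabolite_profiles(tbl_r, md_r, protocol = prot),
        range = rg, .after = "protocol")
    }
  }
  structure(list(
    cohort = cohort, split = split,
    performance = dplyr::bind_rows(perf_rows),
    stability = if (run_stability) dplyr::bind_rows(stab_rows) else NULL,
    profiles = dplyr::bind_rows(prof_rows),
    config = list(constraint = constraint, exclusions = exclusions,
                  ranges = ranges, train_size = train_size,
                  test_size = test_size, n_bins = n_bins,
                  max_predictive = max_predictive,
                  max_non_predictive = max_non_predictive,
                  cv_k = cv_k, cv_repetitions = cv_repetitions,
                  n_permutations = if (run_permutations) n_permutations else 0,
                  stability_subsamples = if (run_stability) stability_subsamples else 0,
                  alpha = alpha),
    seed = seed,
    version = as.character(utils::packageVersion("pfpmi"))
  ), class = "pf_run")
}

#' @export
print.pf_run <- function(x, ...) {
  cat("PMI estimation study run (seed", x$seed, ")\n")
  cat(sprintf("Cohort: n = %d, PMI %.0f +/- %.0f h, age %.0f +/- %.0f y, r(PMI, age) = %.2f\n",
              x$cohort$n, x$cohort$pmi_mean, x$cohort$pmi_sd,
              x$cohort$age_mean, x$cohort$age_sd, x$cohort$pmi_age_r))
  print(x$performance)
  invisible(x)
}

#' Performance table of a study run
#'
#' @param x A `pf_run` object.
#' @param ... Unused.
#' @return The per-protocol, per-range performance tibble with R2/Q2 to 3
#'   decimals and errors to whole hours (reporting precision).
#' @method tidy pf_run
#' @export
tidy.pf_run <- function(x, ...) {
  dplyr::mutate(
    x$performance,
    dplyr::across(c("r2", "q2"), ~ round(.x, 3)),
    dplyr::across(c("sdec", "sdecv", "sdep"), ~ round(.x, 0))
  )
}
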