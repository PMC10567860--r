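#' Binary Matrix Sampling subsamples
#'
#' Draws `count` random subsamples of a samples-by-predictors table by
#' independent Bernoulli(`probability`) masking of both rows (samples) and
#' columns (predictors). Masks retaining fewer than `min_rows` rows or
#' `min_cols` columns are redrawn (the number of redraws is recorded in
#' `attr(., "redraws")`).
#'
#' @param n_samples,n_predictors Dimensions of the table being subsampled.
#' @param probability Inclusion probability for every row and column
#'   (default 0.7).
#' @param count Number of subsamples (default 200).
#' @param seed Integer seed for the subsampling stream.
#' @param min_rows,min_cols Minimum retained rows/columns (defaults 8 and 2).
#' @return A list of `count` elements, each a list with logical vectors
#'   `rows` and `cols`.
#' @export
bms_subsamples <- function(n_samples, n_predictors, probability = 0.7,
                           count = 200, seed = 1, min_rows = 8, min_cols = 2) {
  stopifnot(probability > 0, probability <= 1, count >= 1)
  redraws <- 0L
  out <- withr::with_seed(stream_seed(seed, "subsamples"), {
    lapply(seq_len(count), function(s) {
      repeat {
        rows <- runif(n_samples) < probability
        cols <- runif(n_predictors) < probability
        if (sum(rows) >= min(min_rows, n_samples) && sum(cols) >= min_cols) {
          return(list(rows = rows, cols = cols))
        }
        redraws <<- redraws + 1L
      }
    })
  })
  attr(out, "redraws") <- redraws
  out
}

#' VIP-guided best predictor subset within one subsample
#'
#' Iterative backward elimination: fit the constrained model on all available
#' predictors, score it by cross-validated Q2, drop every predictor with
#' VIP < 1, refit and rescore; stop when Q2 stops improving or fewer than 2
#' predictors remain. Returns the subset with maximal Q2 along the path.
#'
#' @param x Raw concentration matrix or tibble (the subsample; rescaled
#'   internally, per CV fold).
#' @param y Response vector (hours).
#' @param z Constraint vector/matrix or `NULL`.
#' @param n_predictive,n_non_predictive Component counts.
#' @param k,repetitions Cross-validation settings (defaults 5-fold, 5
#'   repetitions: a lighter CV than final model assessment, applied inside
#'   every subsample).
#' @param seed Integer seed.
#' @return Character vector of selected predictor names; the search path is
#'   in `attr(., "path")`.
#' @export
best_subset <- function(x, y, z = NULL, n_predictive = 1, n_non_predictive = 0,
                        k = 5, repetitions = 5, seed = 1) {
  X <- if (is.data.frame(x)) conc_matrix(x) else as.matrix(x)
  stopifnot(!is.null(colnames(X)))
  current <- colnames(X)
  path <- list()
  q2_prev <- -Inf
  repeat {
    Xc <- X[, current, drop = FALSE]
    q2 <- suppressWarnings(
      repeated_cv(Xc, y, z, n_predictive, n_non_predictive,
                  k = k, repetitions = repetitions, seed = seed)$q2)
    path[[length(path) + 1]] <- list(subset = current, q2 = q2)
    fit <- ocpls2(autoscale_matrix(Xc), y, z = z,
                  n_predictive = n_predictive, n_non_predictive = n_non_predictive)
    v <- vip(fit)
    nxt <- intersect(current, names(v)[v >= 1])
    if (length(nxt) < 2 || length(nxt) == length(current)) break
    if (q2 < q2_prev) break
    q2_prev <- q2
    current <- nxt
  }
  q2s <- vapply(path, `[[`, numeric(1), "q2")
  best <- path[[which.max(q2s)]]$subset
  attr(best, "path") <- tibble::tibble(
    step = seq_along(path),
    size = vapply(path, function(s) length(s$subset), integer(1)),
    q2 = q2s
  )
  best
}

#' Stability selection of relevant metabolites
#'
#' Runs [best_subset()] on each Binary-Matrix-Sampling subsample and compares
#' every metabolite's selection count with the count expected if each
#' subsample's subset had been chosen uniformly at random among its available
#' predictors (size-matched random-choice null, exact Poisson-binomial
#' tail probability). Metabolites with a one-sided p below `alpha` are
#' flagged relevant.
#'
#' @param x Concentration tibble or raw matrix (samples x metabolites).
#' @param y PMI vector (hours).
#' @param z Constraint vector/matrix (age) or `NULL`.
#' @param n_subsamples Number of BMS subsamples (default 200).
#' @param probability BMS inclusion probability (default 0.7).
#' @param alpha Significance level for the relevance flag (default 0.05).
#' @param n_predictive,n_non_predictive Component counts for the subsample
#'   models.
#' @param k,repetitions Within-subsample cross-validation settings.
#' @param seed Integer seed.
#' @return A tibble of class `pf_stability` with one row per metabolite:
#'   `metabolite`, `selection_count`, `n_available`, `selection_frequency`,
#'   `null_frequency`, `p_value`, `relevant`. Settings and the number of
#'   usable subsamples are attached as attributes.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' tbl <- exclude_exogenous(cohort$tables$U)
#' rep <- stability_selection(tbl, cohort$metadata$pmi_hours,
#'                            z = cohort$metadata$age_years,
#'                            n_subsamples = 50, seed = 1)
#' dplyr::filter(rep, relevant)
#' }
#' @export
stability_selection <- function(x, y, z = NULL, n_subsamples = 200,
                                probability = 0.7, alpha = 0.05,
                                n_predictive = 1, n_non_predictive = 0,
                                k = 5, repetitions = 5, seed = 1) {
  X <- if (is.data.frame(x)) conc_matrix(x) else as.matrix(x)
  y <- as.numeric(y)
  Z <- if (is.null(z)) NULL else as.matrix(z)
  mets <- colnames(X)
  masks <- bms_subsamples(nrow(X), ncol(X), probability = probability,
                          count = n_subsamples, seed = seed)
  selected <- availability <- matrix(FALSE, n_subsamples, length(mets),
                                     dimnames = list(NULL, mets))
  usable <- logical(n_subsamples)
  for (s in seq_len(n_subsamples)) {
    m <- masks[[s]]
    Xs <- X[m$rows, m$cols, drop = FALSE]
    # drop columns that are constant within the subsample (unscalable)
    ok_col <- apply(Xs, 2, sd) > .Machine$double.eps^0.5
    Xs <- Xs[, ok_col, drop = FALSE]
    if (ncol(Xs) < 2 || sd(y[m$rows]) < .Machine$double.eps^0.5) {
      warning("subsample ", s, " skipped (degenerate)", call. = FALSE)
      next
    }
    Zs <- if (is.null(Z)) NULL else Z[m$rows, , drop = FALSE]
    sub <- tryCatch(
      best_subset(Xs, y[m$rows], Zs, n_predictive, n_non_predictive,
                  k = k, repetitions = repetitions,
                  seed = stream_seed(seed, "subsamples") + s),
      error = function(e) NULL
    )
    if (is.null(sub)) {
      warning("subsample ", s, " skipped (model not fittable)", call. = FALSE)
      next
    }
    usable[s] <- TRUE
    availability[s, colnames(Xs)] <- TRUE
    selected[s, sub] <- TRUE
  }
  report <- relevance_test(selected[usable, , drop = FALSE],
                           availability[usable, , drop = FALSE], alpha = alpha)
  attr(report, "settings") <- list(
    n_subsamples = n_subsamples, n_usable = sum(usable),
    probability = probability, alpha = alpha,
    n_predictive = n_predictive, n_non_predictive = n_non_predictive,
    cv_k = k, cv_repetitions = repetitions, seed = seed
  )
  class(report) <- c("pf_stability", class(report))
  report
}

#' Random-choice relevance test for selection counts
#'
#' Under the null, the subset chosen in subsample s is a uniform random draw
#' of its observed size among the predictors available in s, so metabolite j
#' is selected there with probability (subset size)/(available predictors).
#' Its total selection count is then Poisson-binomial across subsamples; the
#' one-sided p-value \eqn{P(N \ge count_{obs})} is computed exactly by
#' dynamic-programming convolution.
#'
#' @param selected Logical matrix, subsamples x metabolites: was the
#'   metabolite in the returned subset?
#' @param availability Logical matrix of the same shape: was the metabolite
#'   among the subsample's available predictors?
#' @param alpha Significance level for the `relevant` flag.
#' @return Tibble with `metabolite`, `selection_count`, `n_available`,
#'   `selection_frequency`, `null_frequency`, `p_value`, `relevant`.
#' @export
relevance_test <- function(selected, availability, alpha = 0.05) {
  stopifnot(is.matrix(selected), is.matrix(availability),
            all(dim(selected) == dim(availability)),
            !any(selected & !availability))
  S <- nrow(selected)
  if (S < 1) stop("no usable subsamples", call. = FALSE)
  sizes <- rowSums(selected)
  avail_n <- rowSums(availability)
  mets <- colnames(selected)
  res <- purrr::map_dfr(seq_along(mets), function(j) {
    probs <- ifelse(availability[, j], sizes / pmax(avail_n, 1), 0)
    count <- sum(selected[, j])
    tibble::tibble(
      metabolite = mets[j],
      selection_count = count,
      n_available = sum(availability[, j]),
      selection_frequency = count / S,
      null_frequency = mean(probs),
      p_value = poisbinom_tail(probs, count)
    )
  })
  res$relevant <- res$p_value < alpha
  res
}

# exact P(N >= k) for N = sum of independent Bernoulli(probs), DP convolution
poisbinom_tail <- function(probs, k) {
  if (k <= 0) return(1)
  pmf <- poisbinom_pmf(probs)
  if (k > length(probs)) return(0)
  sum(pmf[(k + 1):length(pmf)])
}

poisbinom_pmf <- function(probs) {
  dp <- c(1, numeric(length(probs)))
  for (p in probs) {
    dp <- dp * (1 - p) + c(0, head(dp, -1)) * p
  }
  dp  # dp[i] = P(N = i - 1)
}

#' @export
print.pf_stability <- function(x, ...) {
  st <- attr(x, "settings")
  cat(sprintf("Stability selection: %d/%d usable subsamples (p = %.2f), alpha = %.2f\n",
              st$n_usable, st$n_subsamples, st$probability, st$alpha))
  cat(sum(x$relevant), "of", nrow(x), "metabolites flagged relevant\n")
  NextMethod()
}

#' Selection-frequency plot for a stability report
#'
#' @param object A `pf_stability` report.
#' @param ... Unused.
#' @return A ggplot: observed vs null selection frequency per metabolite,
#'   relevant ones highlighted.
#' @method autoplot pf_stability
#' @export
autoplot.pf_stability <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$selection_frequency)
  df$metabolite <- factor(df$metabolite, levels = df$metabolite)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$metabolite)) +
    ggplot2::geom_col(ggplot2::aes(x = .data$selection_frequency,
                                   fill = .data$relevant)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$null_frequency), shape = 124, size = 3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey70")) +
    ggplot2::labs(x = "selection frequency (| = random-choice null)",
                  y = NULL, fill = "relevant") +
    ggplot2::theme_minimal()
}
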