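#' Principal component analysis of an autoscaled table
#'
#' Thin SVD-based PCA for exploratory analysis of autoscaled concentration
#' tables. The sign of each component is fixed by making its
#' largest-magnitude loading positive, so scores are reproducible across row
#' orderings.
#'
#' @param scaled A `pf_scaled` object (see [autoscale()]) or a numeric matrix
#'   already centred.
#' @param n_components Number of components to retain; must not exceed
#'   `min(n - 1, p)`.
#' @return An object of class `pf_pca`: `loadings` (p x A, orthonormal
#'   columns), `scores` (n x A), `explained_variance` (eigenvalues,
#'   non-increasing), `explained_fraction`, `all_eigenvalues` (full spectrum,
#'   used by the Q-residual limit), `n_components`, `scaling` and the sample
#'   ids.
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 3))
#' pca <- fit_pca(autoscale(exclude_exogenous(cohort$tables$U)), 2)
#' glance(pca)
#' @export
fit_pca <- function(scaled, n_components = 2) {
  x <- if (inherits(scaled, "pf_scaled")) scaled$values else as.matrix(scaled)
  n <- nrow(x); p <- ncol(x)
  rank_max <- min(n - 1, p)
  if (n_components > rank_max) {
    stop("n_components (", n_components, ") exceeds min(n - 1, p) = ", rank_max, call. = FALSE)
  }
  sv <- svd(x)
  eig <- sv$d^2 / (n - 1)
  if (n_components > sum(sv$d > max(sv$d) * 1e-12)) {
    stop("n_components exceeds the rank of the data", call. = FALSE)
  }
  load <- sv$v[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  load <- sweep(load, 2, flip, "*")
  scores <- x %*% load
  rownames(load) <- colnames(x)
  rownames(scores) <- rownames(x)
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(
    loadings = load, scores = scores,
    explained_variance = eig[seq_len(n_components)],
    explained_fraction = eig[seq_len(n_components)] / sum(eig),
    all_eigenvalues = eig, n_components = n_components,
    scaling = if (inherits(scaled, "pf_scaled")) scaled[c("center", "scale")] else NULL,
    sample_ids = rownames(x), n = n, p = p,
    row_ssq = rowSums(x^2)
  ), class = "pf_pca")
}

#' Choose the number of PCs reaching a cumulative explained-variance target
#'
#' @param scaled A `pf_scaled` object or centred matrix.
#' @param target Cumulative explained-variance fraction (default 0.8).
#' @param cap Maximum number of components (default 5).
#' @return Integer component count.
#' @export
choose_n_components <- function(scaled, target = 0.8, cap = 5) {
  x <- if (inherits(scaled, "pf_scaled")) scaled$values else as.matrix(scaled)
  eig <- svd(x, nu = 0, nv = 0)$d^2
  k <- which(cumsum(eig) / sum(eig) >= target)[1]
  max(1L, min(as.integer(k), cap, nrow(x) - 1L, ncol(x)))
}

#' Hotelling T2 and Q-residual outlier tests
#'
#' Flags samples whose position in the retained score space (Hotelling T2,
#' F-distribution limit) or whose squared residual distance from the PCA
#' model plane (Q statistic, Jackson--Mudholkar limit) exceeds the
#' `1 - alpha` control limit.
#'
#' @param model A `pf_pca` fit.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return A tibble with one row per sample: `sample_id`, `t2`, `t2_limit`,
#'   `t2_flag`, `q`, `q_limit`, `q_flag`. When the model leaves essentially no
#'   residual variance the Q test is skipped with a warning (`q` columns NA).
#' @export
pca_outlier_tests <- function(model, alpha = 0.05) {
  stopifnot(inherits(model, "pf_pca"), alpha > 0, alpha < 1)
  A <- model$n_components
  n <- model$n
  lam <- model$explained_variance
  t2 <- rowSums(sweep(model$scores^2, 2, lam, "/"))
  t2_limit <- A * (n - 1) * (n + 1) / (n * (n - A)) * qf(1 - alpha, A, n - A)
  resid_eig <- model$all_eigenvalues[-seq_len(A)]
  resid_eig <- resid_eig[resid_eig > 1e-12 * sum(model$all_eigenvalues)]
  if (length(resid_eig) == 0) {
    warning("no residual variance beyond the retained components; Q test skipped",
            call. = FALSE)
    q <- q_limit <- NA_real_
    q_flag <- NA
  } else {
    # squared residuals after reconstruction from the retained components
    # scores %*% t(loadings) reconstructs; need original scaled x
    th1 <- sum(resid_eig); th2 <- sum(resid_eig^2); th3 <- sum(resid_eig^3)
    h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
    if (!is.finite(h0) || h0 < 1e-3) h0 <- 1e-3
    ca <- qnorm(1 - alpha)
    q_limit <- th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 +
                        th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
    # residual SSQ per sample: total row SSQ minus retained-score SSQ
    # (orthogonal decomposition: ||x_i||^2 = ||t_i||^2 + Q_i)
    q <- model$row_ssq - rowSums(model$scores^2)
    q <- pmax(q, 0)
    q_flag <- q > q_limit
  }
  tibble::tibble(
    sample_id = model$sample_ids,
    t2 = t2, t2_limit = t2_limit, t2_flag = t2 > t2_limit,
    q = q, q_limit = q_limit, q_flag = q_flag
  )
}

#' @export
print.pf_pca <- function(x, ...) {
  cat("PCA:", x$n_components, "components,",
      sprintf("%.1f%%", 100 * sum(x$explained_fraction)), "of variance\n")
  invisible(x)
}

#' @rdname fit_pca
#' @param x,object A `pf_pca` object.
#' @param ... Unused.
#' @method tidy pf_pca
#' @export
tidy.pf_pca <- function(x, ...) {
  tibble::as_tibble(x$scores) |>
    dplyr::mutate(sample_id = x$sample_ids, .before = 1)
}

#' @rdname fit_pca
#' @method glance pf_pca
#' @export
glance.pf_pca <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    explained_fraction = sum(x$explained_fraction),
    n = x$n, p = x$p
  )
}

#' Score plot of a PCA model
#'
#' @param object A `pf_pca` fit.
#' @param metadata Optional metadata tibble; when given, points are coloured
#'   by PMI (binned into `pmi_bins` equally spaced intervals, the usual way
#'   post-mortem trajectories are displayed) and shaped by protocol if present.
#' @param pmi_bins Number of equally spaced PMI colour intervals (default 9).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pf_pca
#' @export
autoplot.pf_pca <- function(object, metadata = NULL, pmi_bins = 9, ...) {
  df <- tidy.pf_pca(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  if (!is.null(metadata)) {
    df <- dplyr::left_join(df, metadata, by = "sample_id")
    df$pmi_interval <- cut(df$pmi_hours, breaks = pmi_bins)
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                          colour = .data$pmi_interval))
    if ("protocol" %in% names(df) && length(unique(df$protocol)) > 1) {
      p <- p + ggplot2::aes(shape = .data$protocol)
    }
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_fraction[2]),
      colour = "PMI (h)"
    ) +
    ggplot2::theme_minimal()
}
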