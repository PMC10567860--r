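#' Orthogonally constrained PLS2 regression (oCPLS2)
#'
#' Fits a PLS regression of a response (PMI in hours) on an autoscaled
#' predictor matrix under the constraint that every score component is
#' exactly orthogonal to external factor columns (the confounder matrix `z`,
#' age by default in this package). Each predictive weight vector is the
#' covariance direction projected into the null space of
#' \eqn{Z^{\top}X_{current}}, so the scores satisfy \eqn{Z^{\top}t = 0} by
#' construction and the latent space cannot encode the confounder.
#' Non-predictive components are removed first, OPLS-style: systematic
#' X-variation orthogonal to both the response and the constraint is filtered
#' out before the predictive regression.
#'
#' @param x Predictors: a `pf_scaled` object (recommended), a concentration
#'   tibble (autoscaled internally), or a numeric matrix taken as already
#'   scaled.
#' @param y Response vector (hours); centred and scaled internally.
#' @param z Constraint matrix or vector (e.g. age in years), or `NULL` for an
#'   unconstrained PLS fit. Columns are mean-centred internally.
#' @param n_predictive Number of predictive (y-correlated) score components.
#' @param n_non_predictive Number of non-predictive (orthogonal-filter)
#'   components removed before the predictive regression.
#'
#' @return An object of class `ocpls2` with elements `weights` (W, p x A),
#'   `loadings` (P), `y_loadings` (q), `scores` (predictive score matrix T),
#'   `ortho_scores`, `ortho_weights`, `ortho_loadings`, `coefficients`
#'   (scaled space), `fitted` (hours), `constraint` (centred Z),
#'   `x_center`/`x_scale`/`y_center`/`y_scale`/`z_center`, `metabolites`,
#'   `n_predictive`, `n_non_predictive`, `ssy` (response variance captured
#'   per predictive component).
#'
#' @examples
#' cohort <- simulate_cohort(cohort_config(seed = 1))
#' tbl <- exclude_exogenous(cohort$tables$U)
#' fit <- ocpls2(autoscale(tbl), cohort$metadata$pmi_hours,
#'               z = cohort$metadata$age_years)
#' glance(fit)
#' max(abs(crossprod(fit$scores, fit$constraint)))  # ~ 0: the constraint
#' @export
ocpls2 <- function(x, y, z = NULL, n_predictive = 1, n_non_predictive = 0) {
  prep <- prep_xyz(x, y, z)
  fit <- ocpls2_core(prep$X, prep$y_scaled, prep$Z, n_predictive, n_non_predictive)
  fitted_hours <- c(fit$fitted_scaled) * prep$y_scale + prep$y_center
  structure(c(fit, list(
    fitted = fitted_hours, y = y,
    x_center = prep$x_center, x_scale = prep$x_scale,
    y_center = prep$y_center, y_scale = prep$y_scale,
    z_center = prep$z_center, constraint = prep$Z,
    metabolites = prep$metabolites,
    n_predictive = n_predictive, n_non_predictive = n_non_predictive
  )), class = "ocpls2")
}

# normalise inputs: X scaled matrix, y scaled vector, Z centred matrix
prep_xyz <- function(x, y, z) {
  if (inherits(x, "pf_scaled")) {
    X <- x$values; x_center <- x$center; x_scale <- x$scale
  } else if (is.data.frame(x)) {
    sc <- autoscale(x)
    X <- sc$values; x_center <- sc$center; x_scale <- sc$scale
  } else {
    X <- as.matrix(x)
    if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
    x_center <- setNames(rep(0, ncol(X)), colnames(X))
    x_scale <- setNames(rep(1, ncol(X)), colnames(X))
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("x and y have different numbers of samples", call. = FALSE)
  y_center <- mean(y)
  y_sd <- sd(y)
  if (y_sd < .Machine$double.eps^0.5) stop("response is constant", call. = FALSE)
  if (!is.null(z)) {
    Z <- as.matrix(z)
    if (nrow(Z) != nrow(X)) stop("z and x have different numbers of samples", call. = FALSE)
    z_center <- colMeans(Z)
    Z <- sweep(Z, 2, z_center)
    if (all(abs(Z) < 1e-12)) { Z <- NULL; z_center <- NULL }
  } else {
    Z <- NULL; z_center <- NULL
  }
  list(X = X, y_scaled = (y - y_center) / y_sd, Z = Z,
       x_center = x_center, x_scale = x_scale,
       y_center = y_center, y_scale = y_sd, z_center = z_center,
       metabolites = colnames(X))
}

# project w into null(Z^T Xc): t = Xc w then satisfies Z^T t = 0 exactly
constrain_weight <- function(w, Xc, Z) {
  if (is.null(Z)) return(w)
  M <- crossprod(Z, Xc)               # q x p
  MMt <- tcrossprod(M)
  sv <- svd(MMt)
  pos <- sv$d > max(sv$d, 0) * 1e-12
  if (!any(pos)) return(w)            # Z^T X ~ 0: constraint already satisfied
  inv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  w - crossprod(M, inv %*% (M %*% w))
}

ocpls2_core <- function(X, y, Z, n_predictive, n_non_predictive, tol = 1e-12) {
  n <- nrow(X); p <- ncol(X)
  if (n_predictive < 1) stop("n_predictive must be >= 1", call. = FALSE)
  if (!is.null(Z) && ncol(Z) >= p) {
    stop("constraint has as many columns as there are predictors: null space of Z'X is empty",
         call. = FALSE)
  }
  Xf <- X
  To <- Wo <- Po <- NULL
  if (n_non_predictive > 0) {
    To <- matrix(0, n, n_non_predictive)
    Wo <- matrix(0, p, n_non_predictive)
    Po <- matrix(0, p, n_non_predictive)
    for (i in seq_len(n_non_predictive)) {
      w <- constrain_weight(crossprod(Xf, y), Xf, Z)
      nw <- sqrt(sum(w^2))
      if (nw < tol) stop("requested components exceed the available rank", call. = FALSE)
      w <- w / nw
      t_p <- Xf %*% w
      p_load <- crossprod(Xf, t_p) / c(crossprod(t_p))
      w_o <- p_load - c(crossprod(w, p_load)) * w
      w_o <- constrain_weight(w_o, Xf, Z)
      nwo <- sqrt(sum(w_o^2))
      if (nwo < tol) stop("no systematic orthogonal variation left: reduce n_non_predictive",
                          call. = FALSE)
      w_o <- w_o / nwo
      t_o <- Xf %*% w_o
      p_o <- crossprod(Xf, t_o) / c(crossprod(t_o))
      Xf <- Xf - tcrossprod(t_o, p_o)
      To[, i] <- t_o; Wo[, i] <- w_o; Po[, i] <- p_o
    }
  }
  X_filtered <- Xf
  Xa <- Xf; ya <- y
  W <- P <- matrix(0, p, n_predictive)
  Tm <- matrix(0, n, n_predictive)
  qv <- numeric(n_predictive)
  ssy <- numeric(n_predictive)
  for (a in seq_len(n_predictive)) {
    w <- constrain_weight(crossprod(Xa, ya), Xa, Z)
    nw <- sqrt(sum(w^2))
    if (nw < tol) stop("requested components exceed the available rank", call. = FALSE)
    w <- w / nw
    t_a <- Xa %*% w
    tt <- c(crossprod(t_a))
    if (tt < tol) stop("requested components exceed the available rank", call. = FALSE)
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- c(crossprod(ya, t_a)) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    qv[a] <- q_a
    ssy[a] <- q_a^2 * tt
  }
  B <- W %*% solve(crossprod(P, W), qv)
  rownames(W) <- rownames(P) <- rownames(B) <- colnames(X)
  list(weights = W, loadings = P, y_loadings = qv,
       scores = Tm, ortho_scores = To, ortho_weights = Wo, ortho_loadings = Po,
       coefficients = B, fitted_scaled = X_filtered %*% B, ssy = ssy)
}

#' Predict PMI for new samples
#'
#' Applies the training centring/scaling to `newdata`, removes the fitted
#' non-predictive components, and maps through the regression coefficients
#' back to the hours scale.
#'
#' @param object An `ocpls2` fit.
#' @param newdata A concentration tibble, `pf_scaled` object built with the
#'   training reference, or numeric matrix in mM (raw scale) or already
#'   scaled if the model was fitted on a plain matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted PMI in hours.
#' @export
predict.ocpls2 <- function(object, newdata, ...) {
  if (inherits(newdata, "pf_scaled")) {
    Xn <- newdata$values
  } else if (is.data.frame(newdata)) {
    Xn <- conc_matrix(newdata)
  } else {
    Xn <- as.matrix(newdata)
    if (is.null(colnames(Xn))) colnames(Xn) <- object$metabolites
  }
  missing_m <- setdiff(object$metabolites, colnames(Xn))
  extra_m <- setdiff(colnames(Xn), object$metabolites)
  if (length(missing_m) > 0 || length(extra_m) > 0) {
    stop("metabolite panel mismatch; missing: [",
         paste(missing_m, collapse = ", "), "], extra: [",
         paste(extra_m, collapse = ", "), "]", call. = FALSE)
  }
  Xn <- Xn[, object$metabolites, drop = FALSE]
  if (!inherits(newdata, "pf_scaled")) {
    Xn <- sweep(sweep(Xn, 2, object$x_center), 2, object$x_scale, "/")
  }
  if (object$n_non_predictive > 0) {
    for (i in seq_len(object$n_non_predictive)) {
      t_o <- Xn %*% object$ortho_weights[, i]
      Xn <- Xn - tcrossprod(t_o, object$ortho_loadings[, i])
    }
  }
  c(Xn %*% object$coefficients) * object$y_scale + object$y_center
}

#' @export
print.ocpls2 <- function(x, ...) {
  perf <- performance_metrics(x$y, x$fitted, mode = "calibration")
  cat(sprintf("oCPLS2: %d predictive + %d non-predictive component(s), %d predictors\n",
              x$n_predictive, x$n_non_predictive, length(x$metabolites)))
  cat(sprintf("R2 = %.3f, SDEC = %.1f h%s\n", perf$r2, perf$error,
              if (is.null(x$constraint)) " (unconstrained)" else ""))
  invisible(x)
}

#' @rdname ocpls2
#' @param object,... An `ocpls2` fit (for the `tidy`/`glance`/`augment`
#'   methods); further arguments ignored.
#' @method tidy ocpls2
#' @export
tidy.ocpls2 <- function(x, ...) {
  tibble::tibble(
    metabolite = x$metabolites,
    coefficient = c(x$coefficients),
    vip = vip(x)
  ) |> dplyr::arrange(dplyr::desc(.data$vip))
}

#' @rdname ocpls2
#' @method glance ocpls2
#' @export
glance.ocpls2 <- function(x, ...) {
  perf <- performance_metrics(x$y, x$fitted, mode = "calibration")
  tibble::tibble(
    r2 = perf$r2, sdec = perf$error,
    n_predictive = x$n_predictive, n_non_predictive = x$n_non_predictive,
    n = length(x$y), p = length(x$metabolites),
    constrained = !is.null(x$constraint)
  )
}

#' @rdname ocpls2
#' @method augment ocpls2
#' @export
augment.ocpls2 <- function(x, ...) {
  tibble::tibble(
    pmi_hours = x$y,
    .fitted = x$fitted,
    .resid = x$y - x$fitted
  )
}

#' Variable Influence on Projection (VIP)
#'
#' Per-predictor importance over the predictive components:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{SSY_a} is the response variance captured by component a. The
#' squared VIPs average to 1, so VIP > 1 marks above-average influence.
#'
#' @param model An `ocpls2` fit with at least one predictive component.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "ocpls2"))
  W <- model$weights
  p <- nrow(W)
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  ssy <- model$ssy
  v <- sqrt(p * c(wn^2 %*% ssy) / sum(ssy))
  setNames(v, model$metabolites)
}

#' Calibration / prediction error and R2
#'
#' SDEC (calibration) and SDEP (prediction) are the root-mean-square error
#' \eqn{\sqrt{\sum (y - \hat y)^2 / n}} in hours;
#' \eqn{R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2}.
#'
#' @param y_true Observed response (hours).
#' @param y_hat Fitted (calibration) or predicted (prediction) response.
#' @param mode `"calibration"` or `"prediction"`; only labels the error
#'   column.
#' @return A one-row tibble with `error` (named `sdec` or `sdep` in the
#'   `metric` column), `r2`, `n`, `mode`.
#' @export
performance_metrics <- function(y_true, y_hat, mode = c("calibration", "prediction")) {
  mode <- match.arg(mode)
  y_true <- as.numeric(y_true); y_hat <- as.numeric(y_hat)
  if (length(y_true) != length(y_hat)) stop("y_true and y_hat lengths differ", call. = FALSE)
  if (length(y_true) < 2) stop("need at least 2 observations", call. = FALSE)
  tss <- sum((y_true - mean(y_true))^2)
  if (tss < .Machine$double.eps) stop("constant y_true: R2 undefined", call. = FALSE)
  rss <- sum((y_true - y_hat)^2)
  tibble::tibble(
    metric = if (mode == "calibration") "sdec" else "sdep",
    error = sqrt(rss / length(y_true)),
    r2 = 1 - rss / tss,
    n = length(y_true),
    mode = mode
  )
}

#' Repeated k-fold cross-validation (Q2, SDECV)
#'
#' For each repetition a fresh random fold assignment is drawn; within each
#' training fold the autoscaling statistics, the constraint centring and the
#' model are recomputed from scratch and applied to the held-out fold. Per
#' repetition, Q2 = 1 - PRESS/TSS from the pooled held-out residuals and
#' SDECV = sqrt(PRESS/n); both are then averaged over repetitions.
#'
#' @param x Concentration tibble or raw (unscaled) matrix, samples x
#'   metabolites.
#' @param y PMI vector, hours.
#' @param z Constraint vector/matrix (age) or `NULL`.
#' @param n_predictive,n_non_predictive Component counts (see [ocpls2()]).
#' @param k Folds (default 5). `repetitions` repeats (default 20).
#' @param repetitions Number of repeated fold assignments.
#' @param seed Integer seed for the fold stream.
#' @return A list with `q2`, `sdecv`, and `per_repetition` (tibble of
#'   per-repetition Q2 and SDECV).
#' @export
repeated_cv <- function(x, y, z = NULL, n_predictive = 1, n_non_predictive = 0,
                        k = 5, repetitions = 20, seed = 1) {
  X <- if (is.data.frame(x)) conc_matrix(x) else as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < k) stop("need at least k samples", call. = FALSE)
  Z <- if (is.null(z)) NULL else as.matrix(z)
  tss <- sum((y - mean(y))^2)
  q2s <- sdecvs <- rep(NA_real_, repetitions)
  withr::with_seed(stream_seed(seed, "folds"), {
    for (r in seq_len(repetitions)) {
      folds <- sample(rep(seq_len(k), length.out = n))
      press <- 0
      ok <- TRUE
      for (f in seq_len(k)) {
        test <- folds == f
        res <- tryCatch(
          cv_fold_predict(X, y, Z, test, n_predictive, n_non_predictive),
          error = function(e) NULL
        )
        if (is.null(res)) { ok <- FALSE; break }
        press <- press + sum((y[test] - res)^2)
      }
      if (!ok) {
        warning("repetition ", r, " discarded (degenerate fold)", call. = FALSE)
        next
      }
      q2s[r] <- 1 - press / tss
      sdecvs[r] <- sqrt(press / n)
    }
  })
  keep <- !is.na(q2s)
  if (!any(keep)) stop("every cross-validation repetition was degenerate", call. = FALSE)
  list(
    q2 = mean(q2s[keep]), sdecv = mean(sdecvs[keep]),
    per_repetition = tibble::tibble(repetition = which(keep),
                                    q2 = q2s[keep], sdecv = sdecvs[keep])
  )
}

# fit on the training part of one fold, predict the held-out rows (hours)
cv_fold_predict <- function(X, y, Z, test, n_predictive, n_non_predictive) {
  tr <- !test
  if (sd(y[tr]) < .Machine$double.eps^0.5) stop("constant y in training fold")
  Xtr <- X[tr, , drop = FALSE]
  sds <- apply(Xtr, 2, sd)
  keep <- sds > .Machine$double.eps^0.5
  Xtr <- Xtr[, keep, drop = FALSE]
  ctr <- colMeans(Xtr); scl <- apply(Xtr, 2, sd)
  Xtr_s <- sweep(sweep(Xtr, 2, ctr), 2, scl, "/")
  Ztr <- if (is.null(Z)) NULL else Z[tr, , drop = FALSE]
  fit <- ocpls2(Xtr_s, y[tr], z = Ztr,
                n_predictive = n_predictive, n_non_predictive = n_non_predictive)
  Xte <- X[test, keep, drop = FALSE]
  Xte_s <- sweep(sweep(Xte, 2, ctr), 2, scl, "/")
  predict(fit, Xte_s)
}

#' Select the numbers of predictive and non-predictive components
#'
#' Grid search over component configurations, scoring each with the mean Q2
#' of [repeated_cv()] and breaking ties toward fewer components.
#'
#' @inheritParams repeated_cv
#' @param max_predictive,max_non_predictive Upper bounds of the search grid.
#' @return A list with `n_predictive`, `n_non_predictive`, `q2`, and `grid`
#'   (tibble of every configuration scored).
#' @export
select_components <- function(x, y, z = NULL, max_predictive = 3,
                              max_non_predictive = 2, k = 5, repetitions = 20,
                              seed = 1) {
  stopifnot(max_predictive >= 1, max_non_predictive >= 0)
  grid <- expand.grid(n_predictive = seq_len(max_predictive),
                      n_non_predictive = 0:max_non_predictive)
  grid <- grid[order(grid$n_predictive + grid$n_non_predictive,
                     grid$n_non_predictive), ]
  scores <- purrr::pmap_dbl(grid, function(n_predictive, n_non_predictive) {
    res <- tryCatch(
      suppressWarnings(repeated_cv(x, y, z, n_predictive, n_non_predictive,
                                   k = k, repetitions = repetitions, seed = seed)),
      error = function(e) NULL
    )
    if (is.null(res)) -Inf else res$q2
  })
  best <- which.max(scores)  # grid ordered by total components: ties -> fewer
  list(
    n_predictive = grid$n_predictive[best],
    n_non_predictive = grid$n_non_predictive[best],
    q2 = scores[best],
    grid = tibble::as_tibble(cbind(grid, q2 = scores))
  )
}

#' Randomization (permutation) test for R2 and Q2
#'
#' Permutes the response (constraint rows stay aligned with the predictors),
#' re-runs the full fit and cross-validation at the fixed component
#' configuration for every permutation, and reports
#' \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) / (1 + n_{perm})}
#' separately for R2 and Q2. Guards against an over-fitted model: a real
#' signal should beat what permuted responses can achieve.
#'
#' @inheritParams repeated_cv
#' @param n_permutations Number of permutations (at least 99; default 999).
#' @return A one-row tibble: `r2`, `q2` (observed), `p_r2`, `p_q2`,
#'   `n_permutations`; the permuted statistics are in
#'   `attr(., "permuted")`.
#' @export
randomization_test <- function(x, y, z = NULL, n_predictive = 1,
                               n_non_predictive = 0, n_permutations = 999,
                               k = 5, repetitions = 20, seed = 1) {
  if (n_permutations < 99) stop("use at least 99 permutations", call. = FALSE)
  X <- if (is.data.frame(x)) conc_matrix(x) else as.matrix(x)
  y <- as.numeric(y)
  obs_fit <- ocpls2(autoscale_matrix(X), y, z = z,
                    n_predictive = n_predictive, n_non_predictive = n_non_predictive)
  obs_r2 <- performance_metrics(y, obs_fit$fitted)$r2
  obs_q2 <- suppressWarnings(
    repeated_cv(X, y, z, n_predictive, n_non_predictive,
                k = k, repetitions = repetitions, seed = seed)$q2)
  perm_r2 <- perm_q2 <- numeric(n_permutations)
  withr::with_seed(stream_seed(seed, "permutations"), {
    perms <- replicate(n_permutations, sample.int(length(y)))
  })
  for (i in seq_len(n_permutations)) {
    yp <- y[perms[, i]]
    fit_i <- ocpls2(autoscale_matrix(X), yp, z = z,
                    n_predictive = n_predictive, n_non_predictive = n_non_predictive)
    perm_r2[i] <- performance_metrics(yp, fit_i$fitted)$r2
    perm_q2[i] <- suppressWarnings(
      repeated_cv(X, yp, z, n_predictive, n_non_predictive,
                  k = k, repetitions = repetitions,
                  seed = stream_seed(seed, "permutations") + i)$q2)
  }
  out <- tibble::tibble(
    r2 = obs_r2, q2 = obs_q2,
    p_r2 = (1 + sum(perm_r2 >= obs_r2)) / (1 + n_permutations),
    p_q2 = (1 + sum(perm_q2 >= obs_q2)) / (1 + n_permutations),
    n_permutations = n_permutations
  )
  attr(out, "permuted") <- tibble::tibble(r2 = perm_r2, q2 = perm_q2)
  out
}

# autoscale a plain matrix, dropping zero-variance columns silently
autoscale_matrix <- function(X) {
  sds <- apply(X, 2, sd)
  keep <- sds > .Machine$double.eps^0.5
  X <- X[, keep, drop = FALSE]
  scale(X, center = TRUE, scale = apply(X, 2, sd))[, , drop = FALSE]
}
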