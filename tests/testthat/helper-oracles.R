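# Independent reference implementations used as oracles. These are kept
# deliberately naive (textbook algorithms, loops, brute force) and are never
# called by package code.

# Textbook NIPALS PLS1: X (n x p) centred/scaled, y centred/scaled.
# Returns fitted values in the scaled space.
reference_pls1 <- function(X, y, n_components) {
  Xa <- X
  ya <- y
  W <- P <- matrix(0, ncol(X), n_components)
  qv <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- t(Xa) %*% ya
    w <- w / sqrt(sum(w^2))
    t_a <- Xa %*% w
    p_a <- t(Xa) %*% t_a / c(t(t_a) %*% t_a)
    q_a <- c(t(ya) %*% t_a) / c(t(t_a) %*% t_a)
    Xa <- Xa - t_a %*% t(p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    qv[a] <- q_a
  }
  b <- W %*% solve(t(P) %*% W) %*% qv
  list(coefficients = b, fitted = X %*% b)
}

# Brute-force Poisson-binomial tail P(N >= k) by enumerating all 2^S outcomes.
brute_poisbinom_tail <- function(probs, k) {
  S <- length(probs)
  stopifnot(S <= 15)
  total <- 0
  for (mask in 0:(2^S - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(S)]
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1, probs, 1 - probs))
    }
  }
  total
}

# Small random regression instance with an exact linear structure.
make_linear_instance <- function(n, p, seed, beta_scale = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("m", seq_len(p))))
  beta <- rnorm(p) * beta_scale
  list(X = X, beta = beta, y = c(X %*% beta))
}

# Convenience: scaled matrix + scaled response for oracle comparisons.
scale_pair <- function(X, y) {
  Xs <- scale(X)
  ys <- c(scale(y))
  list(X = Xs[, , drop = FALSE], y = ys)
}

# Write a small concentration CSV and return its path.
write_temp_conc <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
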