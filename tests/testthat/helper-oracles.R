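# Independent brute-force oracles: plain-loop implementations of the kernel
# density and mutual-information formulas, kept deliberately naive so they
# share no code with the package internals.

kde1_naive <- function(x, h, query) {
  n <- length(x)
  out <- numeric(length(query))
  for (k in seq_along(query)) {
    s <- 0
    for (i in seq_len(n)) s <- s + exp(-(query[k] - x[i])^2 / (2 * h^2))
    out[k] <- s / (sqrt(2 * pi) * n * h)
  }
  out
}

kde2_naive <- function(x, y, h, qx, qy) {
  n <- length(x)
  out <- numeric(length(qx))
  for (k in seq_along(qx)) {
    s <- 0
    for (i in seq_len(n))
      s <- s + exp(-((qx[k] - x[i])^2 + (qy[k] - y[i])^2) / (2 * h^2))
    out[k] <- s / (2 * pi * n * h^2)
  }
  out
}

mi_naive <- function(x, y, h) {
  n <- length(x)
  total <- 0
  for (j in seq_len(n)) {
    fj <- kde2_naive(x, y, h, x[j], y[j])
    fx <- kde1_naive(x, h, x[j])
    fy <- kde1_naive(y, h, y[j])
    total <- total + log(fj / (fx * fy))
  }
  total / n
}

# UCV objective oracles: integral term by adaptive quadrature of the squared
# density, leave-one-out term by direct looping.
ucv1_naive <- function(x, h) {
  n <- length(x)
  f2 <- function(t) kde1_naive(x, h, t)^2
  term1 <- stats::integrate(Vectorize(f2), min(x) - 10 * h, max(x) + 10 * h,
                            rel.tol = 1e-10, subdivisions = 500L)$value
  term2 <- 0
  for (i in seq_len(n))
    term2 <- term2 + kde1_naive(x[-i], h, x[i])
  term1 - (2 / n) * term2
}

simpson_weights <- function(m) {  # m odd
  w <- rep(c(4, 2), length.out = m - 2)
  c(1, w[-length(w)], 4, 1) / 3
}

# tensor-grid Simpson quadrature of the squared bivariate KDE; the integrand
# is smooth so this converges far below 1e-6 at m = 801
ucv2_naive <- function(x, y, h, m = 801L) {
  n <- length(x)
  gx <- seq(min(x) - 8 * h, max(x) + 8 * h, length.out = m)
  gy <- seq(min(y) - 8 * h, max(y) + 8 * h, length.out = m)
  F <- matrix(0, m, m)
  for (i in seq_len(n))
    F <- F + outer(exp(-(gx - x[i])^2 / (2 * h^2)),
                   exp(-(gy - y[i])^2 / (2 * h^2)))
  F <- F / (2 * pi * n * h^2)
  w <- simpson_weights(m)
  term1 <- diff(gx[1:2]) * diff(gy[1:2]) * drop(t(w) %*% F^2 %*% w)
  term2 <- 0
  for (i in seq_len(n))
    term2 <- term2 + kde2_naive(x[-i], y[-i], h, x[i], y[i])
  term1 - (2 / n) * term2
}

# normal-equations solve, the textbook route the package avoids
coef_normal_equations <- function(X, y) {
  Xs <- scale(X)
  yc <- y - mean(y)
  unname(drop(solve(t(Xs) %*% Xs) %*% t(Xs) %*% yc))
}

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)

# small planted dataset reused by pipeline-level tests
small_planted <- function(seed = 1L, n = 80L) {
  edges <- data.frame(input = c(1, 2, 4), output = c(1, 2, 3),
                      link = c("linear", "linear", "saturating"),
                      effect_size = c(1.2, 1, 1))
  generate_planted(planted_network_spec(
    n_inputs = 5, n_outputs = 3, n_observations = n, edges = edges,
    noise_sd = 0.4, seed = seed))
}
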