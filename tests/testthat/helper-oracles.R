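# Independent numeric oracles used across the suite.

# Log-determinant of the numerically differentiated Jacobian of `f` at `x`.
fd_logdet <- function(f, x, h = 1e-5) {
  d <- length(x)
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    e <- rep(0, d)
    e[j] <- h
    J[, j] <- (f(x + e) - f(x - e)) / (2 * h)
  }
  as.numeric(determinant(J, logarithm = TRUE)$modulus)
}

# Seeded two-moons-style 2-D sample: two interleaved crescents.
two_moons <- function(n, noise = 0.1) {
  t <- stats::runif(n, 0, pi)
  b <- stats::rbinom(n, 1, 0.5)
  x <- ifelse(b == 1, cos(t), 1 - cos(t))
  y <- ifelse(b == 1, sin(t), 0.5 - sin(t))
  cbind(x + stats::rnorm(n, 0, noise), y + stats::rnorm(n, 0, noise))
}

# A MAF layer with constant conditioner outputs mu, log sigma = alpha.
constant_maf_layer <- function(d, mu = rep(0, d), alpha = rep(0, d),
                               hidden = 4L) {
  lay <- new_maf_layer(d, hidden, init = "identity")
  lay$params$b_mu <- mu
  lay$params$b_alpha <- alpha
  lay
}

# Small well-separated Gaussian classification fixture.
gaussian_classes <- function(n_per, d = 20L, k = 3L, sep = 6) {
  x <- do.call(rbind, lapply(seq_len(k), function(c_) {
    mu <- rep(0, d)
    mu[c_] <- sep
    matrix(stats::rnorm(n_per * d), n_per, d) +
      matrix(mu, n_per, d, byrow = TRUE)
  }))
  labeled_dataset(
    count_matrix(x, layer = "lognorm"),
    rep(paste0("class_", seq_len(k)), each = n_per)
  )
}
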