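# Independent oracles used by the REML tests. These deliberately use dense
# linear algebra on the marginal covariance V = sa*A + se*I, a different
# route than the package's sparse mixed-model-equation likelihood.

dense_neg2_reml <- function(y, X, A, sa, se) {
  n <- length(y)
  V <- sa * A + se * diag(n)
  Vi <- solve(V)
  M <- t(X) %*% Vi %*% X
  beta <- solve(M, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(determinant(V)$modulus) + as.numeric(determinant(M)$modulus) +
    as.numeric(t(r) %*% Vi %*% r)
}

# Profile the restricted likelihood over h2 with the total variance
# maximized analytically; grid search plus two refinement passes.
profile_h2_oracle <- function(y, X, A) {
  n <- length(y)
  p <- qr(X)$rank
  prof <- function(h2) {
    V0 <- h2 * A + (1 - h2) * diag(n)
    Vi <- solve(V0)
    M <- t(X) %*% Vi %*% X
    beta <- solve(M, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    yPy <- as.numeric(t(r) %*% Vi %*% r)
    sp2 <- yPy / (n - p)
    (n - p) * log(sp2) + as.numeric(determinant(V0)$modulus) +
      as.numeric(determinant(M)$modulus) + (n - p)
  }
  lo <- 1e-4; hi <- 1 - 1e-4
  for (pass in 1:3) {
    grid <- seq(lo, hi, length.out = 81)
    vals <- vapply(grid, prof, numeric(1))
    k <- which.min(vals)
    step <- grid[2] - grid[1]
    lo <- max(1e-6, grid[k] - step)
    hi <- min(1 - 1e-6, grid[k] + step)
  }
  grid[k]
}

# Closed-form balanced paternal half-sib ANOVA heritability estimator.
halfsib_anova_h2 <- function(y, sire) {
  k <- as.vector(table(sire))
  stopifnot(length(unique(k)) == 1)
  k <- k[1]
  s <- length(unique(sire))
  means <- tapply(y, sire, mean)
  msb <- k * sum((means - mean(y))^2) / (s - 1)
  msw <- sum((y - means[sire])^2) / (s * (k - 1))
  sig_s <- (msb - msw) / k
  4 * sig_s / (sig_s + msw)
}

# Simulate a paternal half-sib design: sires are unrelated founders, each
# with k progeny from unknown dams. Returns pedigree + phenotypes.
sim_halfsib <- function(n_sires, k, h2, mu = 10, vp = 4, seed = 1) {
  set.seed(seed)
  sires <- sprintf("S%03d", seq_len(n_sires))
  prog <- sprintf("P%04d", seq_len(n_sires * k))
  ped <- data.frame(animal = c(sires, prog),
                    sire = c(rep(NA, n_sires), rep(sires, each = k)),
                    dam = NA)
  ped <- read_pedigree(ped)
  sa <- h2 * vp
  bv <- simulate_breeding_values(ped, matrix(sa, 1, 1))
  y <- mu + bv[prog, 1] + rnorm(length(prog), 0, sqrt(vp - sa))
  list(ped = ped, data = data.frame(animal = prog, y = y,
                                    sire = rep(sires, each = k)))
}
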