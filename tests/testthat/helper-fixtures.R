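# Shared fixtures built in code.

kT300 <- flipsampler::kT_of(300)

# small deterministic multivariate-normal sampler on the counter RNG
mvn_samples <- function(n, mu, Sigma, seed, stream = 20) {
  d <- length(mu)
  z <- matrix(flipsampler::counter_normals(seed, 0, stream, n * d), n, d)
  L <- chol(Sigma)
  sweep(z %*% L, 2, mu, "+")
}

# brute-force harmonic-LDA Rayleigh objective over directions in the plane;
# the within-class scatter is the matrix harmonic mean of the two covariances
hlda_rayleigh_scan <- function(mu_a, mu_b, S_a, S_b, n_angles = 1e4) {
  Sh <- solve(solve(S_a) + solve(S_b))
  th <- seq(0, pi, length.out = n_angles)
  J <- vapply(th, function(t) {
    w <- c(cos(t), sin(t))
    sum(w * (mu_a - mu_b))^2 / drop(t(w) %*% Sh %*% w)
  }, numeric(1))
  th[which.max(J)]
}

# independent (naive) re-enumeration of the gromos clustering algorithm on a
# precomputed distance matrix
gromos_enumerate <- function(D, cutoff) {
  n <- nrow(D)
  alive <- rep(TRUE, n)
  assignment <- integer(n)
  k <- 0
  while (any(alive)) {
    idx <- which(alive)
    best <- idx[1]; best_n <- -1L
    for (i in idx) {
      cnt <- sum(D[i, idx] < cutoff) - 1L
      if (cnt > best_n) { best_n <- cnt; best <- i }
    }
    members <- idx[D[best, idx] < cutoff]
    members <- union(best, members)
    k <- k + 1
    assignment[members] <- k
    alive[members] <- FALSE
  }
  assignment
}

# random rigid transform from seeded draws
random_rotation <- function(seed) {
  q <- flipsampler::counter_normals(seed, 0, 21, 4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# a minimal synthetic PDB with the flip CV's contact atoms (fictitious
# coordinates; stands in for a real hairpin structure)
write_premir21_fixture_pdb <- function(path) {
  atoms <- data.frame(
    serial = 1:8,
    name = c("N6", "N1", "H1", "N2", "N3", "O2'", "O5'", "C4'"),
    resname = c("A", "A", "G", "G", "C", "C", "A", "A"),
    resid = c(29, 29, 45, 45, 46, 46, 47, 47),
    chain = "A", stringsAsFactors = FALSE)
  coords <- matrix(c(0.0, 0.0, 0.0,
                     0.1, 0.0, 0.0,
                     0.3, 0.1, 0.0,
                     0.3, -0.1, 0.1,
                     0.4, 0.2, -0.1,
                     0.5, 0.0, 0.2,
                     0.6, 0.1, 0.1,
                     0.7, -0.1, 0.0), ncol = 3, byrow = TRUE)
  flipsampler::write_pdb(atoms, coords, path)
  path
}
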