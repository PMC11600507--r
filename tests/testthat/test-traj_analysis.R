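# Superposition, RMSD/RMSF, gromos clustering, cross-correlation, contacts,
# principal modes.

ref_frame <- function(m = 8, seed = 50) {
  matrix(flipsampler::counter_normals(seed, 0, 70, m * 3), m, 3)
}

test_that("Kabsch superposition recovers rigid transforms exactly", {
  A <- ref_frame()
  self <- kabsch_superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation(9)
  B <- A %*% R + matrix(c(0.3, -1, 2), nrow(A), 3, byrow = TRUE)
  fit <- kabsch_superpose(B, A)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # collinear fit selections are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 0.1), "degenerate")
})

test_that("Kabsch RMSD matches independent numerical minimization", {
  # two noisy 4-point sets; the oracle minimizes RMSD over rotations with
  # multi-start Nelder-Mead on Euler angles
  A <- ref_frame(4, seed = 51)
  B <- A + 0.2 * matrix(counter_normals(52, 0, 71, 12), 4, 3)
  got <- kabsch_superpose(B, A)$rmsd
  rot_of <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rx %*% Ry %*% Rz
  }
  Bc <- sweep(B, 2, colMeans(B)); Ac <- sweep(A, 2, colMeans(A))
  obj <- function(p) sqrt(mean(rowSums((Bc %*% rot_of(p) - Ac)^2)))
  best <- Inf
  for (s in 1:8) {
    p0 <- counter_uniforms(s, 0, 72, 3) * 2 * pi
    o <- optim(p0, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, o$value)
  }
  expect_equal(got, best, tolerance = 1e-6)
})

test_that("rmsd_series matches the chi-distribution moment for Gaussian noise", {
  m <- 20
  ref <- ref_frame(m, seed = 53)
  sig <- 0.01
  nf <- 2000
  noise <- array(sig * counter_normals(54, 0, 73, nf * m * 3), c(nf, m, 3))
  traj <- aperm(array(ref, c(m, 3, nf)), c(3, 1, 2)) + noise
  rs <- rmsd_series(traj, ref)
  # superposition removes 6 degrees of freedom: RMSD ~ (sigma/sqrt(m)) chi_d
  d <- 3 * m - 6
  expected <- sig / sqrt(m) * sqrt(2) * exp(lgamma((d + 1) / 2) - lgamma(d / 2))
  expect_equal(mean(rs$rmsd), expected, tolerance = 0.02)
  # static trajectory against its own first frame: all zeros
  static <- aperm(array(ref, c(m, 3, 5)), c(3, 1, 2))
  expect_lt(max(rmsd_series(static, ref)$rmsd), 1e-12)
})

test_that("rmsf reproduces closed forms and rigid-motion invariance", {
  m <- 6
  ref <- ref_frame(m, seed = 55)
  nf <- 1e4
  sig <- 0.05
  traj <- aperm(array(ref, c(m, 3, nf)), c(3, 1, 2))
  traj[, 1, ] <- traj[, 1, ] + sig * matrix(counter_normals(56, 0, 74, nf * 3),
                                            nf, 3)
  f <- rmsf(traj, superpose = FALSE)
  expect_equal(f[1], sig * sqrt(3), tolerance = 0.03)
  expect_lt(max(f[-1]), 1e-12)
  # global rigid motion of every frame leaves RMSF unchanged (with fit on all)
  R <- random_rotation(10)
  traj2 <- traj
  for (i in seq_len(nf %/% 20)) traj2[i, , ] <- traj2[i, , ] %*% R
  f2 <- rmsf(traj2[seq_len(500), , ], superpose = TRUE)
  f1 <- rmsf(traj[seq_len(500), , ], superpose = TRUE)
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("gromos clustering equals exhaustive enumeration on small fixtures", {
  base <- ref_frame(4, seed = 57)
  mk_traj <- function(shifts) {
    arr <- array(0, c(length(shifts), 4, 3))
    for (i in seq_along(shifts)) {
      arr[i, , ] <- base
      arr[i, 1, 1] <- arr[i, 1, 1] + shifts[i]
    }
    arr
  }
  for (trial in 1:8) {
    shifts <- round(counter_uniforms(trial, 0, 75, 6), 2)
    traj <- mk_traj(shifts)
    cutoff <- 0.12
    got <- gromos_cluster(traj, cutoff)
    D <- matrix(0, 6, 6)
    for (i in 1:5) for (j in (i + 1):6)
      D[i, j] <- D[j, i] <- kabsch_superpose(traj[i, , ], traj[j, , ])$rmsd
    want <- gromos_enumerate(D, cutoff)
    # partitions must be identical up to label names
    expect_equal(length(unique(got$assignment)), length(unique(want)))
    for (k in unique(want))
      expect_equal(length(unique(got$assignment[want == k])), 1L)
    expect_equal(sum(got$sizes), 6L)
    expect_true(all(diff(got$sizes) <= 0))
    # centroid belongs to its cluster
    for (c in seq_along(got$centroids))
      expect_equal(got$assignment[got$centroids[c]], c)
  }
  # degenerate cases
  same <- mk_traj(rep(0, 5))
  expect_equal(length(gromos_cluster(same, 0.1)$sizes), 1L)
  apart <- mk_traj(c(0, 10, 20, 30))
  expect_equal(length(gromos_cluster(apart, 0.1)$sizes), 4L)
})

test_that("cross-correlation reproduces the worked examples exactly", {
  # 4-frame, 2-site example with y = z = 0
  arr <- array(0, c(4, 2, 3))
  arr[, 1, 1] <- c(-.5, .5, -.5, .5)
  arr[, 2, 1] <- c(.5, -.5, .5, -.5)
  C <- cross_correlation(arr, superpose = FALSE)
  expect_equal(C[1, 1], 1, tolerance = 1e-12)
  expect_equal(C[2, 2], 1, tolerance = 1e-12)
  expect_equal(C[1, 2], -1, tolerance = 1e-12)
  # decorrelated pattern
  arr2 <- arr
  arr2[, 1, 1] <- c(-.5, .5, .5, -.5)
  arr2[, 2, 1] <- c(-.5, -.5, .5, .5)
  C2 <- cross_correlation(arr2, superpose = FALSE)
  expect_equal(C2[1, 2], 0, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(C)))
  # zero-variance sites are flagged, not NaN
  arr3 <- arr
  arr3[, 2, ] <- 1
  C3 <- cross_correlation(arr3, superpose = FALSE)
  expect_true(all(is.na(C3[2, ])))
  expect_equal(attr(C3, "flagged"), 2L)
  expect_equal(C3[1, 1], 1)
})

test_that("correlation and clustering are invariant to frame permutation", {
  nf <- 60
  arr <- array(counter_normals(58, 0, 76, nf * 4 * 3), c(nf, 4, 3)) * 0.1 +
    aperm(array(ref_frame(4, 59), c(4, 3, nf)), c(3, 1, 2))
  perm <- order(counter_uniforms(60, 0, 77, nf))
  C1 <- cross_correlation(arr, superpose = FALSE)
  C2 <- cross_correlation(arr[perm, , ], superpose = FALSE)
  expect_equal(unclass(C1), unclass(C2), tolerance = 1e-9)
  g1 <- gromos_cluster(arr, 0.2)
  g2 <- gromos_cluster(arr[perm, , ], 0.2)
  expect_equal(sort(g1$sizes), sort(g2$sizes))
})

test_that("contact frequencies count frames below the cutoff", {
  nf <- 10
  arr <- array(0, c(nf, 2, 3))
  arr[, 2, 1] <- c(rep(0.3, 3), rep(1.0, 7))  # within 0.4 nm in 3 frames
  cf <- contact_frequency(arr, list(A = 1L), list(B = 2L), cutoff = 0.4)
  expect_equal(cf$frequency, 0.3)
  # permanently bonded and never-in-contact pairs
  arr[, 2, 1] <- 0.1
  expect_equal(contact_frequency(arr, list(A = 1L), list(B = 2L))$frequency, 1)
  arr[, 2, 1] <- 5
  expect_equal(contact_frequency(arr, list(A = 1L), list(B = 2L))$frequency, 0)
  expect_error(contact_frequency(arr, list(), list(B = 2L)), "empty")
  expect_error(contact_frequency(arr, list(A = 1L), list(B = 1L)), "disjoint")
})

test_that("principal modes satisfy the trace identity and find 1D motion", {
  nf <- 500
  arr <- aperm(array(ref_frame(5, 61), c(5, 3, nf)), c(3, 1, 2))
  drive <- counter_normals(62, 0, 78, nf)
  arr[, 3, 2] <- arr[, 3, 2] + 0.5 * drive  # one site moves along y only
  pm <- principal_modes(arr, superpose = FALSE)
  expect_equal(pm$values[1], var(0.5 * drive), tolerance = 1e-9)
  expect_lt(max(pm$values[-1]), 1e-12)
  v1 <- abs(pm$vectors[, 1])
  expect_gt(v1[which.max(v1)], 0.999)
  # trace conservation on generic data
  arr2 <- array(counter_normals(63, 0, 79, nf * 5 * 3), c(nf, 5, 3))
  pm2 <- principal_modes(arr2, superpose = FALSE)
  X <- matrix(arr2, nf, 15)
  expect_equal(sum(pm2$values), sum(apply(X, 2, var)), tolerance = 1e-9)
  # isotropic noise: eigenvalue spread stays narrow at large n
  arr3 <- array(counter_normals(64, 0, 80, 1e4 * 3 * 3), c(1e4, 3, 3))
  pm3 <- principal_modes(arr3, superpose = FALSE)
  expect_lt(pm3$values[1] / pm3$values[9], 1.2)
})
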