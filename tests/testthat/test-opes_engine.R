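# OPES-Explore kernel bias and the multithermal expanded ensemble.

test_that("empty and single-kernel bias behave as the closed form dictates", {
  st <- opes_state(barrier = 20, sigma0 = 0.1, grid = c(-5, 5, 2001))
  s <- seq(-4, 4, length.out = 101)
  expect_equal(as.numeric(opes_bias(st, s)), rep(0, 101))
  # one kernel: sup V = 0 at the kernel, inf V = -DeltaE far away
  st1 <- opes_update(st, 0)
  expect_equal(nrow(st1$kernels), 1)
  expect_equal(st1$kernels[1, "center"], c(center = 0))
  expect_equal(st1$kernels[1, "sigma"], c(sigma = 0.1))
  v0 <- as.numeric(opes_bias(st1, 0))
  vf <- as.numeric(opes_bias(st1, 100))
  expect_equal(v0, 0, tolerance = 1e-9)
  expect_equal(v0 - vf, 20, tolerance = 1e-6)  # range capped at DeltaE
})

test_that("two depositions at the same point merge into one doubled kernel", {
  st <- opes_state(barrier = 10, sigma0 = 0.2)
  st <- opes_update(opes_update(st, 0.5), 0.5)
  expect_equal(nrow(st$kernels), 1)
  expect_equal(unname(st$kernels[1, "height"]), 2)
  expect_equal(unname(st$kernels[1, "center"]), 0.5)
})

test_that("bias range never exceeds the barrier for randomized kernel sets", {
  s <- seq(-6, 6, length.out = 601)
  for (k in 1:200) {
    nk <- 1 + (k %% 17)
    st <- opes_state(barrier = 5 + (k %% 4) * 5, sigma0 = 0.1,
                     grid = c(-6, 6, 2001))
    centers <- 4 * (counter_uniforms(k, 0, 41, nk) - 0.5)
    for (c0 in centers) st <- opes_update(st, c0)
    V <- as.numeric(opes_bias(st, s))
    expect_lte(max(V) - min(V), st$barrier + 1e-9)
    expect_lte(max(V), 1e-9)  # sup pinned at zero
  }
})

test_that("zero-barrier limit gives gamma -> 1 and vanishing bias", {
  st <- opes_state(barrier = 1e-6, sigma0 = 0.1)
  st <- opes_update(st, 0)
  expect_lt(max(abs(as.numeric(opes_bias(st, seq(-2, 2, 0.1))))), 1e-5)
})

test_that("the kernel density of many depositions is consistent with its source", {
  # 1e4 depositions from a standard normal: the compressed KDE should match
  # the normal within Kolmogorov distance 0.05
  st <- opes_state(barrier = 50, sigma0 = 0.3, grid = c(-5, 5, 2001))
  x <- counter_normals(13, 0, 42, 1e4)
  for (xi in x) st <- opes_update(st, xi)
  grid <- seq(-5, 5, length.out = 1001)
  k <- st$kernels
  dens <- rowSums(vapply(seq_len(nrow(k)), function(i)
    k[i, 3] * dnorm(grid, k[i, 1], k[i, 2]), numeric(length(grid))))
  dens <- dens / sum(dens * (grid[2] - grid[1]))
  cdf <- cumsum(dens) * (grid[2] - grid[1])
  expect_lt(max(abs(cdf - pnorm(grid))), 0.05)
  # compression keeps the kernel list small
  expect_lt(nrow(k), 200)
})

test_that("multithermal bias is zero on a trivial grid and monotone for heating", {
  st1 <- multithermal_state(300, t0 = 300)
  expect_equal(as.numeric(multithermal_bias(st1, c(-50, 0, 50, 500))),
               rep(0, 4))
  st2 <- multithermal_state(c(300, 340, 380), t0 = 300)
  U <- seq(-20, 120, length.out = 50)
  V <- as.numeric(multithermal_bias(st2, U))
  # all beta_j <= beta0: V non-increasing in U
  expect_true(all(diff(V) <= 1e-9))
})

test_that("shift adaptation recovers the harmonic free-energy difference", {
  # 1D harmonic well at 300 K: dF to a hotter ensemble is (kT0/2) ln(T2/T0)
  kspring <- 100
  x <- sqrt(kT300 / kspring) * counter_normals(21, 0, 43, 2e5)
  U <- 0.5 * kspring * x^2
  st <- multithermal_state(c(300, 400), t0 = 300, stride = 100)
  st <- adapt_shifts(st, U, bias_history = 0)
  target <- -(kT300 / 2) * log(400 / 300)
  expect_equal(st$lambdas[2], target, tolerance = 0.05)
  expect_equal(st$lambdas[1], 0, tolerance = 1e-9)
  # single-beta grid: no-op
  st1 <- adapt_shifts(multithermal_state(300), U, bias_history = 0)
  expect_equal(st1$lambdas, 0)
  # repeated self-consistent calls on a stationary history converge
  st_a <- adapt_shifts(st, U)
  st_b <- adapt_shifts(st_a, U)
  st_c <- adapt_shifts(st_b, U)
  expect_lt(max(abs(st_c$lambdas - st_b$lambdas)),
            max(abs(st_b$lambdas - st_a$lambdas)) + 1e-9)
  expect_lt(max(abs(st_c$lambdas - st_b$lambdas)), 0.1)
})

test_that("an adapted two-temperature ensemble visits both targets", {
  # near-harmonic well (high flip barrier keeps the run in one basin)
  m <- make_flip_model(-2, 40, coupling = 2, ligand_strength = 0)
  lad <- structure(list(
    n_replicas = 1L,
    replicas = list(list(layers = list(), mt = list(
      temperatures = c(300, 400), stride = 500L))),
    temperature = 300, exchange_stride = 10000L, ceilings = 400,
    cv_ids = character(0)), class = "ladder_config")
  run <- run_oneopes(lad, m, 4e5, seed = 2, colvar_stride = 10L)
  cv <- run$replicas[[1]]$colvar
  keep <- -(1:2000)
  U <- cv$ene[keep]
  B <- cv$bias.final[keep]
  # converged shift adaptation visits every grid temperature evenly enough
  vis <- run$replicas[[1]]$mt$visitation
  expect_gt(min(vis) / max(vis), 1 / 10)
  # overlap coefficient of the sampled energy histogram with each target
  # Boltzmann ensemble, obtained by reweighting the run itself
  beta0 <- 1 / kT300
  edges <- seq(min(U) - 1e-9, max(U) + 1e-9, length.out = 41)
  bin <- findInterval(U, edges, rightmost.closed = TRUE)
  hist_of <- function(w) {
    h <- tapply(w, factor(bin, levels = seq_len(40)), sum)
    h[is.na(h)] <- 0
    h / sum(h)
  }
  p_samp <- hist_of(rep(1, length(U)))
  for (Tj in c(300, 400)) {
    lw <- beta0 * B - (1 / kT_of(Tj) - beta0) * U
    p_j <- hist_of(exp(lw - max(lw)))
    expect_gt(sum(pmin(p_samp, p_j)), 0.3)
  }
})
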