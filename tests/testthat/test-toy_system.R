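# The synthetic-data generator: model construction, Langevin dynamics,
# basin sampling.

test_that("flip model reproduces its free-energy targets by quadrature", {
  kT <- kT300
  # symmetric well
  m0 <- make_double_well(0, 12)
  expect_lt(abs(m0$delta_g_truth), 1e-6)
  # the apo gap of the hairpin study: -2.6 kcal/mol
  ma <- make_flip_model(-10.9, 20)
  expect_equal(ma$delta_g_truth, -10.9, tolerance = 0.01 / 10.9)
  # ligand additivity: a 12.6 kJ/mol term on the bulged basin shifts the gap
  mh <- make_flip_model(-10.9, 20, ligand_strength = 12.6)
  expect_equal(mh$delta_g_truth - ma$delta_g_truth, -12.6, tolerance = 0.2 / 12.6)
  # infeasible target rejected with a parameterization error
  expect_error(make_flip_model(-30, 20), "infeasible")
})

test_that("analytic gradient matches central differences", {
  m <- make_flip_model(-10.9, 20, ligand_strength = 5)
  pts <- cbind(seq(-1.6, 1.6, length.out = 9), seq(8, 16, length.out = 9))
  h <- 1e-5
  g <- model_gradient(m, pts)
  for (d in 1:2) {
    xp <- pts; xp[, d] <- xp[, d] + h
    xm <- pts; xm[, d] <- xm[, d] - h
    num <- (model_energy(m, xp) - model_energy(m, xm)) / (2 * h)
    expect_equal(g[, d], num, tolerance = 1e-5)
  }
})

test_that("ligand selector is bounded and monotone along the flip coordinate", {
  m <- make_flip_model(-5, 20, ligand_strength = 10)
  x <- seq(-2, 2, length.out = 201)
  g <- (model_energy(m, cbind(x, m$params$ymid + m$params$yamp * tanh(2 * x))) -
        model_energy(make_flip_model(-5, 20), cbind(x, m$params$ymid +
                       m$params$yamp * tanh(2 * x)))) / m$params$epsL
  expect_true(all(g >= -1e-9 & g <= 1 + 1e-9))
  expect_true(all(diff(g) >= -1e-12))
})

test_that("Langevin integrator is deterministic and T = 0 is quiescent", {
  m <- make_flip_model(-10.9, 20)
  t1 <- run_langevin(m, 5000, seed = 9)
  t2 <- run_langevin(m, 5000, seed = 9)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_langevin(m, 5000, seed = 10)
  expect_false(identical(t1$frames, t3$frames))
  # zero temperature from the basin minimum: stays put
  q <- run_langevin(m, 2000, temperature = 0, seed = 1,
                    x0 = basin_minimum(m, "stacked"))
  drift <- max(abs(sweep(q$frames, 2, basin_minimum(m, "stacked"))))
  expect_lt(drift, 1e-8)
})

test_that("pure-R reference integrator reproduces the compiled path bitwise", {
  m <- make_flip_model(-10.9, 20)
  a <- run_langevin(m, 400, seed = 4, stride = 1)
  b <- run_langevin(m, 400, seed = 4, stride = 1,
                    bias_force = function(x) c(0, 0))
  expect_equal(a$frames, b$frames, tolerance = 1e-14)
})

test_that("equipartition holds on the exactly harmonic hydration coordinate", {
  # with yamp = 0 the y coordinate is a pure harmonic well of stiffness ky
  m <- make_flip_model(-10.9, 20, coupling = 40.1, yamp = 0)
  k <- m$params$ky
  tr <- run_langevin(m, 1e6, seed = 2, stride = 5)
  v <- var(tr$frames[, 2])
  expect_equal(v, kT300 / k, tolerance = 0.05)
})

test_that("zero-friction zero-noise dynamics conserve total energy", {
  m <- make_flip_model(-10.9, 20)
  tr <- run_langevin(m, 1e4, dt = 1e-3, friction = 0, temperature = 0,
                     seed = 1, x0 = basin_minimum(m, "stacked") + c(0.05, 0.1),
                     bias_force = function(x) c(0, 0), stride = 10)
  ke <- rowSums(sweep(tr$velocities^2, 2, m$params$mass / 2, "*"))
  etot <- model_energy(m, tr$frames) + ke
  expect_lt(max(etot) - min(etot), 1e-4)
})

test_that("basin sampling is confined and separates the feature means", {
  m <- make_flip_model(-10.9, 20)
  expect_equal(nrow(sample_basin(m, "stacked", 0)$features), 0)
  sa <- sample_basin(m, "stacked", 3000, seed = 5)
  sb <- sample_basin(m, "bulged", 3000, seed = 6)
  expect_true(all(sa$x < m$separatrix))
  expect_true(all(sb$x >= m$separatrix))
  # construction gap of feature 1 between basins: s_1 * (tanh(2 xb) - tanh(2 xa))
  fm <- m$feature
  gap_obs <- mean(sb$features[, 1]) - mean(sa$features[, 1])
  gap_thr <- fm$s[1] * (mean(tanh(2 * sb$x)) - mean(tanh(2 * sa$x)))
  se <- sqrt(var(sa$features[, 1]) / 3000 + var(sb$features[, 1]) / 3000)
  expect_lt(abs(gap_obs - gap_thr), 3 * se)
})

test_that("long unbiased runs reproduce quadrature populations (detailed balance proxy)", {
  # a low-barrier model so that unbiased dynamics crosses often
  m <- make_flip_model(-2, 5, coupling = 0.05)
  tr <- run_langevin(m, 2e6, seed = 8, stride = 20)
  x <- tr$frames[-(1:1000), 1]
  p_obs <- mean(x < m$separatrix)
  p_quad <- 1 / (1 + exp(m$delta_g_truth / kT300))
  # block bootstrap standard error (20 contiguous blocks)
  blocks <- split(x, cut(seq_along(x), 20, labels = FALSE))
  bs <- vapply(1:200, function(k) {
    u <- ceiling(counter_uniforms(k, 0, 31, 20) * 20)
    mean(unlist(blocks[u]) < m$separatrix)
  }, numeric(1))
  expect_lt(abs(p_obs - p_quad), 3 * sd(bs) + 1e-9)
})
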