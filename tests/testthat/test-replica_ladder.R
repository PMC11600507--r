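# Ladder construction, exchanges and the OneOPES driver.

make_test_cv <- function() toy_cv_hlda(-0.8, 0.35)

test_that("the default ladder reproduces the published arrangement", {
  m <- make_flip_model(-10.9, 20)
  lad <- build_default_ladder(make_test_cv(), toy_aux_cvs(m, 7))
  expect_equal(lad$n_replicas, 8L)
  expect_length(lad$replicas[[1]]$layers, 1)      # replica 0: main CV only
  expect_null(lad$replicas[[1]]$mt)
  expect_length(lad$replicas[[8]]$layers, 8)      # replica 7: all CVs
  expect_equal(max(lad$replicas[[8]]$mt$temperatures), 320)
  expect_equal(lad$ceilings, c(302, 304, 306, 308, 310, 314, 320))
  expect_equal(lad$exchange_stride, 2000L)
  expect_equal(lad$replicas[[1]]$layers[[1]]$barrier, 20)
  expect_equal(lad$replicas[[1]]$layers[[1]]$pace, 20000L)
  expect_equal(lad$replicas[[2]]$layers[[2]]$barrier, 3)
  expect_equal(lad$replicas[[2]]$layers[[2]]$pace, 40000L)
  # single replica: plain OPES-Explore
  l1 <- build_default_ladder(make_test_cv(), list(), n_replicas = 1L)
  expect_length(l1$replicas, 1)
  expect_null(l1$replicas[[1]]$mt)
  # invalid configurations rejected
  expect_error(build_default_ladder(make_test_cv(), exchange_stride = 0),
               "positive")
  expect_error(build_default_ladder(make_test_cv(),
                                    list(toy_cv_coord(2L, id = "hlda"))),
               "duplicate")
  expect_error(build_default_ladder(make_test_cv(), toy_aux_cvs(m, 7),
                                    n_replicas = 4L), "at most")
})

test_that("exchange acceptance follows the Metropolis rule", {
  mk <- function(bias) list(x = 0, bias = bias, temperature = 300)
  # identical bias states: probability exactly 1
  r <- attempt_exchange(mk(function(x) 1.5), mk(function(x) 1.5), u = 0.999)
  expect_equal(r$prob, 1)
  expect_true(r$accepted)
  # mismatched thermostats rejected
  hot <- list(x = 0, bias = function(x) 0, temperature = 310)
  expect_error(attempt_exchange(mk(function(x) 0), hot, u = 0.5), "thermostat")
  # swap applied twice restores the configurations
  ri <- list(x = -1, bias = function(x) 0, temperature = 300)
  rj <- list(x = +1, bias = function(x) 0, temperature = 300)
  s1 <- attempt_exchange(ri, rj, u = 0.5)
  s2 <- attempt_exchange(s1$replica_i, s1$replica_j, u = 0.5)
  expect_equal(s2$replica_i$x, -1)
  expect_equal(s2$replica_j$x, +1)
})

test_that("empirical exchange acceptance matches exp(-delta) at delta = 10 kT", {
  kT <- kT300
  # biases engineered so that the swap costs exactly 10 kT
  ri <- list(x = 0, bias = function(x) if (x == 0) 0 else 10 * kT,
             temperature = 300)
  rj <- list(x = 1, bias = function(x) 0, temperature = 300)
  probe <- attempt_exchange(ri, rj, u = 0.5)
  expect_equal(probe$delta, 10, tolerance = 1e-12)
  n <- 1e5
  u <- counter_uniforms(77, 0, 51, n)
  acc <- sum(u < exp(-probe$delta))
  p_hat <- acc / n
  se <- sqrt(exp(-10) * (1 - exp(-10)) / n)
  expect_lt(abs(p_hat - exp(-10)), 3 * se + 1e-12)
})

test_that("the OneOPES driver is deterministic and keeps its books", {
  m <- make_flip_model(-10.9, 20)
  lad <- build_default_ladder(make_test_cv(), toy_aux_cvs(m, 1),
                              n_replicas = 2L, main_pace = 500L,
                              aux_pace = 1000L, exchange_stride = 1000L)
  r1 <- run_oneopes(lad, m, 2e4, seed = 6, colvar_stride = 100L)
  r2 <- run_oneopes(lad, m, 2e4, seed = 6, colvar_stride = 100L)
  expect_identical(r1$replicas[[1]]$colvar, r2$replicas[[1]]$colvar)
  expect_identical(r1$exchange_log, r2$exchange_log)
  # exchange log: one attempt per stride (2 replicas -> only even parity has a pair)
  expect_equal(nrow(r1$exchange_log), floor(2e4 / 1000 / 2))
  expect_true(all(r1$exchange_log$step %% 1000 == 0))
  # below the first pace: no kernels anywhere, unbiased dynamics
  r0 <- run_oneopes(lad, m, 400, seed = 6, colvar_stride = 100L)
  expect_equal(nrow(r0$replicas[[1]]$kernels[[1]]), 0)
  expect_equal(max(abs(r0$replicas[[1]]$colvar$bias)), 0)
})

test_that("a 2-replica ladder shuttles the symmetric double well", {
  m <- make_double_well(0, 12)
  cvx <- toy_cv_coord(1L, grid = c(-2.2, 2.2, 2001), id = "x")
  lad <- build_default_ladder(cvx, list(), n_replicas = 2L,
                              main_pace = 500L, ceilings = 310)
  run <- run_oneopes(lad, m, 1e6, seed = 3, colvar_stride = 100L)
  x0 <- run$replicas[[1]]$colvar$x
  crossings <- sum(diff(sign(x0 - m$separatrix)) != 0)
  expect_gte(crossings, 10)  # >= 5 round trips
  expect_equal(nrow(run$exchange_log), floor(1e6 / 2000 / 2))
})

test_that("ladder sampling preserves the physical ensemble after reweighting", {
  # the pipeline's core property: reweighted dG from replica 0 agrees with
  # the quadrature truth on the toy model
  kT <- kT300
  m <- make_double_well(2 * kT, 10)
  cvx <- toy_cv_coord(1L, grid = c(-2.2, 2.2, 2001), id = "x")
  lad <- build_default_ladder(cvx, list(), n_replicas = 2L,
                              main_pace = 500L, ceilings = 320)
  run <- run_oneopes(lad, m, 2e6, seed = 4, colvar_stride = 50L)
  cv0 <- run$replicas[[1]]$colvar
  burn <- cv0$time > 0.2 * max(cv0$time)
  w <- reweight_weights(cv0[burn, ], kT)
  dg <- basin_delta_g(cv0$x[burn], w, kT, separatrix = m$separatrix)
  expect_lt(abs(dg$delta_g - m$delta_g_truth), 0.3 * kT)
})

test_that("the ladder finds hidden-coordinate transitions faster than one replica", {
  # strong hydration coupling gates the flip; the multi-replica ladder's
  # hydration layer and heat ramp should shorten the first transition
  m <- make_flip_model(-8, 18, coupling = 1.2)
  cvt <- toy_cv_hlda(-0.8, 0.35)
  first_cross <- function(run) {
    x <- run$replicas[[1]]$colvar$x
    i <- which(x > m$separatrix)[1]
    if (is.na(i)) length(x) + 1 else i
  }
  lad8 <- build_default_ladder(cvt, toy_aux_cvs(m, 3), n_replicas = 4L,
                               main_pace = 500L, aux_pace = 1000L)
  lad1 <- build_default_ladder(cvt, list(), n_replicas = 1L, main_pace = 500L)
  t8 <- t1 <- numeric(6)
  for (k in 1:6) {
    t8[k] <- first_cross(run_oneopes(lad8, m, 3e5, seed = 100 + k,
                                     colvar_stride = 20L))
    t1[k] <- first_cross(run_oneopes(lad1, m, 3e5, seed = 100 + k,
                                     colvar_stride = 20L))
  }
  expect_lt(median(t8), median(t1) + 1)
})
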