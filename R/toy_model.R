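# Synthetic-data generator: analytic flip models, Langevin dynamics, and
# labeled within-basin sampling for CV training.

#' Construct a two-basin flip model with a hidden hydration-like coordinate
#'
#' Builds the 2D model
#' \deqn{U(x, y) = a (x^2-1)^2 + b x + k_y (y - y_0(x))^2 / 2 + \epsilon_L g(x)}
#' where \code{x} is the flip coordinate with basins near -1 ("stacked") and
#' +1 ("bulged"), \code{y} is a slow hydration-like coordinate whose
#' basin-dependent mean is \code{y0(x) = ymid + yamp * tanh(2 x)}, and
#' \code{g(x) = (1 + tanh(gk x)) / 2} is a smooth indicator of the bulged
#' basin. The tilt \code{b} is solved numerically so that the quadrature
#' free-energy gap between the basins equals \code{delta_g_target} when
#' \code{ligand_strength = 0}; the quadrature truth at the actual
#' \code{ligand_strength} is stored in the model.
#'
#' @param delta_g_target target free-energy gap G(stacked) - G(bulged) in
#'   kJ/mol of the apo landscape (negative favors stacked)
#' @param barrier height of the apo double-well barrier \code{a} in kJ/mol;
#'   must exceed \code{|delta_g_target|}
#' @param coupling dimensionless strength of the hydration gate; the stiffness
#'   is \code{ky = coupling * kT(300 K) / nm^2}
#' @param ligand_strength \eqn{\epsilon_L \ge 0} in kJ/mol, added as
#'   \code{ligand_strength * g(x)} (destabilizes the bulged basin, i.e. a
#'   ligand that stabilizes the stacked state)
#' @param temperature temperature in K used for the quadrature truth
#' @param ymid,yamp center and half-span of the hydration mean (stacked ~
#'   \code{ymid - yamp}, bulged ~ \code{ymid + yamp})
#' @param gk steepness of the bulged-basin indicator
#' @param masses per-dimension masses in reduced units; the hydration
#'   coordinate is heavier (slower) by default
#' @param sigma_f additive Gaussian noise (nm) of the contact-like features
#' @param feature_seed seed of the one-off draw of feature-map parameters
#' @return an object of class \code{toy_model}
#' @export
make_flip_model <- function(delta_g_target = -10.9, barrier = 20,
                            coupling = 0.2, ligand_strength = 0,
                            temperature = 300, ymid = 12, yamp = 3, gk = 4,
                            masses = c(1, 5), sigma_f = 0.05,
                            feature_seed = 42) {
  stopifnot(barrier > 0, ligand_strength >= 0)
  if (abs(delta_g_target) >= barrier)
    stop("infeasible target: |delta_g_target| = ", abs(delta_g_target),
         " kJ/mol must be smaller than the barrier (", barrier, " kJ/mol)")
  ky <- coupling * kT_of(300)
  params <- list(dim = 2L, a = barrier, b = 0, ky = ky, ymid = ymid,
                 yamp = yamp, epsL = 0, gk = gk, mass = masses)
  kT <- kT_of(temperature)
  # solve the tilt b so that the apo quadrature gap hits the target
  gap_of_b <- function(b) {
    p <- params; p$b <- b
    .quad_dg_1d(p, kT) - delta_g_target
  }
  b <- tryCatch(
    uniroot(gap_of_b, lower = -0.9 * barrier, upper = 0.9 * barrier,
            tol = 1e-10)$root,
    error = function(e)
      stop("infeasible target: no tilt reproduces delta_g_target = ",
           delta_g_target, " kJ/mol within the bracket (", conditionMessage(e), ")"))
  params$b <- b
  params$epsL <- ligand_strength

  # one-off feature-map parameters: 10 contact-like distances
  u <- counter_uniforms(feature_seed, 0, 7, 30)
  fm <- list(
    m = 0.3 + 0.7 * u[1:10],                        # baseline distances, nm
    s = (0.05 + 0.15 * u[11:20]) * ifelse(u[21:30] < 0.5, -1, 1), # flip response
    sigma_f = sigma_f)

  model <- structure(
    list(dim = 2L, params = params, labels = c("stacked", "bulged"),
         feature = fm, temperature = temperature,
         delta_g_target = delta_g_target, coupling = coupling,
         ligand_strength = ligand_strength),
    class = "toy_model")
  model$separatrix <- separatrix(model)
  model$delta_g_truth <- quadrature_delta_g(model, temperature)
  model
}

#' Construct a 1D double-well model
#'
#' Plain tilted quartic double well \code{U(x) = a (x^2-1)^2 + b x} with the
#' tilt solved so the quadrature free-energy gap between the two basins equals
#' \code{delta_g_target}.
#'
#' @inheritParams make_flip_model
#' @return an object of class \code{toy_model} with \code{dim = 1}
#' @export
make_double_well <- function(delta_g_target = 0, barrier = 12,
                             temperature = 300, mass = 1) {
  stopifnot(barrier > 0)
  if (abs(delta_g_target) >= barrier)
    stop("infeasible target: |delta_g_target| must be below the barrier")
  params <- list(dim = 1L, a = barrier, b = 0, ky = 0, ymid = 0, yamp = 0,
                 epsL = 0, gk = 1, mass = mass)
  kT <- kT_of(temperature)
  b <- uniroot(function(b) { p <- params; p$b <- b; .quad_dg_1d(p, kT) - delta_g_target },
               lower = -0.9 * barrier, upper = 0.9 * barrier, tol = 1e-10)$root
  params$b <- b
  model <- structure(
    list(dim = 1L, params = params, labels = c("stacked", "bulged"),
         feature = NULL, temperature = temperature,
         delta_g_target = delta_g_target, ligand_strength = 0),
    class = "toy_model")
  model$separatrix <- separatrix(model)
  model$delta_g_truth <- quadrature_delta_g(model, temperature)
  model
}

#' @export
print.toy_model <- function(x, ...) {
  cat("toy_model (", x$dim, "D): a =", format(x$params$a), "b =",
      format(x$params$b), "epsL =", format(x$params$epsL), "\n")
  cat("  separatrix x* =", format(x$separatrix), " quadrature dG =",
      format(x$delta_g_truth), "kJ/mol\n")
  invisible(x)
}

# effective 1D potential along the flip coordinate; for the 2D model the
# harmonic y integrates out to an x-independent constant, so this is the exact
# potential of mean force up to a shift.
.pmf_1d <- function(params, x) {
  u <- params$a * (x^2 - 1)^2 + params$b * x
  if (params$epsL != 0) u <- u + params$epsL * 0.5 * (1 + tanh(params$gk * x))
  u
}

# quadrature free-energy gap G(x < x*) - G(x > x*) from the exact 1D PMF;
# trapezoid rule on each side with the separatrix as a shared endpoint
.quad_dg_1d <- function(params, kT, n = 4001L) {
  sep <- .separatrix_of(params)
  ref <- min(.pmf_1d(params, seq(-2.5, 2.5, length.out = 2001)))
  side <- function(lo, hi) {
    xs <- seq(lo, hi, length.out = n)
    w <- exp(-(.pmf_1d(params, xs) - ref) / kT)
    sum((w[-1] + w[-n]) / 2) * (xs[2] - xs[1])
  }
  -kT * log(side(-2.5, sep) / side(sep, 2.5))
}

.separatrix_of <- function(params) {
  optimize(function(x) .pmf_1d(params, x), c(-0.9, 0.9), maximum = TRUE,
           tol = 1e-9)$maximum
}

#' Basin separatrix of a toy model
#'
#' The maximum of the 1D potential of mean force along the flip coordinate
#' between the two minima (the standard convention for the dividing surface).
#'
#' @param model a \code{toy_model}
#' @return the flip-coordinate value of the separatrix
#' @export
separatrix <- function(model) .separatrix_of(model$params)

#' Quadrature free-energy gap of a toy model
#'
#' 2D trapezoid quadrature of \eqn{\exp(-\beta U)} over both basins (1D for a
#' double well); the "truth" that enhanced-sampling estimates are judged
#' against. Sign convention: \code{dG = G(stacked) - G(bulged)}, stacked being
#' the basin at negative flip coordinate.
#'
#' @param model a \code{toy_model}
#' @param temperature temperature in K
#' @param nx,ny quadrature grid sizes
#' @return free-energy gap in kJ/mol
#' @export
quadrature_delta_g <- function(model, temperature = model$temperature,
                               nx = 1201L, ny = 601L) {
  kT <- kT_of(temperature)
  p <- model$params
  if (model$dim == 1L) return(.quad_dg_1d(p, kT))
  xs <- seq(-2.5, 2.5, length.out = nx)
  sy <- sqrt(kT / p$ky)
  ys <- seq(p$ymid - p$yamp - 8 * sy, p$ymid + p$yamp + 8 * sy, length.out = ny)
  grid <- expand.grid(x = xs, y = ys)
  u <- cpp_model_energy(.cpp_model(model), as.matrix(grid))
  w <- exp(-(u - min(u)) / kT)
  sep <- .separatrix_of(p)
  pa <- sum(w[grid$x < sep])
  pb <- sum(w[grid$x >= sep])
  -kT * log(pa / pb)
}

.cpp_model <- function(model) model$params

#' Potential energy of a toy model
#' @param model a \code{toy_model}
#' @param x coordinate matrix (n x dim) or vector of length dim
#' @return energies in kJ/mol
#' @export
model_energy <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  cpp_model_energy(.cpp_model(model), x)
}

#' Analytic gradient of a toy model
#' @inheritParams model_energy
#' @return gradient matrix (n x dim) in kJ/mol/nm
#' @export
model_gradient <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  cpp_model_gradient(.cpp_model(model), x)
}

#' Location of a basin minimum
#' @param model a \code{toy_model}
#' @param basin "stacked" or "bulged"
#' @return coordinate vector of the basin minimum
#' @export
basin_minimum <- function(model, basin = c("stacked", "bulged")) {
  basin <- match.arg(basin, model$labels)
  p <- model$params
  rng <- if (basin == "stacked") c(-1.8, model$separatrix) else c(model$separatrix, 1.8)
  xm <- optimize(function(x) .pmf_1d(p, x), rng)$minimum
  # Newton polish on the analytic PMF derivative (machine-precision minimum)
  g1 <- function(x) {
    g <- 4 * p$a * x * (x^2 - 1) + p$b
    if (p$epsL != 0) g <- g + p$epsL * 0.5 * p$gk * (1 - tanh(p$gk * x)^2)
    g
  }
  for (i in 1:8) {
    h <- 1e-6
    xm <- xm - g1(xm) / ((g1(xm + h) - g1(xm - h)) / (2 * h))
  }
  if (model$dim == 1L) return(xm)
  c(xm, p$ymid + p$yamp * tanh(2 * xm))
}

#' Contact-like feature map of a flip model
#'
#' Maps flip coordinates to 10 contact-like distances
#' \code{d_i(x) = m_i + s_i tanh(2 x) (+ noise)}, with \code{m_i, s_i} drawn
#' once from a seeded configuration so that HLDA has a recoverable
#' discriminant direction.
#'
#' @param model a 2D \code{toy_model}
#' @param x vector of flip-coordinate values
#' @param noise if TRUE add i.i.d. Gaussian noise of sd \code{sigma_f}
#' @param seed seed of the noise stream (counter-based, reproducible)
#' @return matrix length(x) x 10 of feature values in nm
#' @export
feature_map <- function(model, x, noise = TRUE, seed = 0) {
  fm <- model$feature
  if (is.null(fm)) stop("model has no feature map (1D double well)")
  base <- outer(tanh(2 * x), fm$s) + matrix(fm$m, length(x), 10, byrow = TRUE)
  if (noise && fm$sigma_f > 0) {
    eps <- counter_normals(seed, 0, 8, 10 * length(x))
    base <- base + fm$sigma_f * matrix(eps, length(x), 10)
  }
  base
}

#' Run Langevin dynamics on a toy model
#'
#' BAOAB discretization of underdamped Langevin dynamics. With
#' \code{bias_force = NULL} the fast compiled path is used; a user-supplied
#' bias force runs a pure-R reference loop fed by the identical counter-based
#' noise stream, so both paths produce bitwise-identical trajectories for a
#' zero bias.
#'
#' @param model a \code{toy_model}
#' @param n_steps number of integration steps
#' @param dt time step in ps (require \code{dt * friction < 1})
#' @param friction friction in 1/ps
#' @param temperature temperature in K
#' @param seed integer seed; identical seed and inputs give identical output
#' @param bias_force optional function(x) returning a bias force vector in
#'   kJ/mol/nm
#' @param x0 initial coordinates (default: stacked-basin minimum)
#' @param stride record every \code{stride}-th frame
#' @param wall optional reflecting wall \code{c(lo, hi)} on the flip coordinate
#' @return object of class \code{trajectory}: list with \code{frames}
#'   (n_rec x dim matrix, nm), \code{times} (ps), \code{temperature},
#'   \code{seed}
#' @export
run_langevin <- function(model, n_steps, dt = 0.002, friction = 10,
                         temperature = 300, seed = 1, bias_force = NULL,
                         x0 = NULL, stride = 1L, wall = NULL) {
  stopifnot(dt * friction < 1, n_steps >= 1)
  if (is.null(x0)) x0 <- basin_minimum(model, "stacked")
  if (is.null(bias_force)) {
    rep0 <- list(layers = list(), mt = NULL, wall = wall)
    run <- cpp_run_ladder(.cpp_model(model), list(rep0), n_steps, dt, friction,
                          temperature, seed, 0L, as.integer(stride),
                          matrix(x0, nrow = 1))
    cm <- run$replicas[[1]]$colvar
    nr <- run$replicas[[1]]$n_rows
    frames <- cm[seq_len(nr), 1 + seq_len(model$dim), drop = FALSE]
    times <- cm[seq_len(nr), 1]
  } else {
    res <- .r_baoab(model, n_steps, dt, friction, temperature, seed,
                    bias_force, x0, stride, wall)
    frames <- res$frames
    times <- res$times
  }
  out <- list(frames = frames, times = times, temperature = temperature,
              seed = seed, dt = dt, friction = friction)
  if (is.null(bias_force)) out["velocities"] <- list(NULL)
  else out$velocities <- res$velocities
  structure(out, class = "trajectory")
}

# pure-R BAOAB reference loop; mirrors the compiled integrator step for step,
# including the noise-counter layout, so the two agree bitwise when the bias
# force is zero.
.r_baoab <- function(model, n_steps, dt, friction, temperature, seed,
                     bias_force, x0, stride, wall) {
  p <- model$params
  d <- model$dim
  kT <- kT_of(temperature)
  mass <- p$mass[seq_len(d)]
  c1 <- exp(-friction * dt)
  c2 <- sqrt(1 - c1^2)
  x <- as.numeric(x0)
  v <- sqrt(kT / mass) * counter_normals(seed, 0, 1, d)
  force <- function(x) {
    f <- -as.numeric(cpp_model_gradient(p, matrix(x, 1)))
    if (!is.null(bias_force)) f <- f + as.numeric(bias_force(x))
    f
  }
  f <- force(x)
  n_rec <- floor(n_steps / stride) + 1
  frames <- matrix(NA_real_, n_rec, d)
  vels <- matrix(NA_real_, n_rec, d)
  times <- numeric(n_rec)
  frames[1, ] <- x
  vels[1, ] <- v
  irec <- 1
  noise <- if (temperature > 0 && friction > 0)
    matrix(counter_normals(seed, 0, 0, n_steps * d), ncol = d, byrow = TRUE)
  else NULL
  sig <- sqrt(kT / mass)
  for (step in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f / mass
    x <- x + 0.5 * dt * v
    if (!is.null(noise)) {
      v <- c1 * v + c2 * sig * noise[step, ]
    } else if (friction > 0) {
      v <- c1 * v
    }
    x <- x + 0.5 * dt * v
    if (!is.null(wall)) {
      if (x[1] < wall[1]) { x[1] <- 2 * wall[1] - x[1]; v[1] <- -v[1] }
      if (x[1] > wall[2]) { x[1] <- 2 * wall[2] - x[1]; v[1] <- -v[1] }
    }
    f <- force(x)
    if (!all(is.finite(f)))
      stop("non-finite force at step ", step)
    v <- v + 0.5 * dt * f / mass
    if (step %% stride == 0) {
      irec <- irec + 1
      frames[irec, ] <- x
      vels[irec, ] <- v
      times[irec] <- step * dt
    }
  }
  list(frames = frames[seq_len(irec), , drop = FALSE],
       velocities = vels[seq_len(irec), , drop = FALSE],
       times = times[seq_len(irec)])
}

#' Draw labeled within-basin feature samples
#'
#' Runs restrained unbiased dynamics confined to one basin (reflecting wall at
#' the separatrix) and maps the visited flip coordinates through the feature
#' map. These labeled ensembles are the training input for HLDA.
#'
#' @param model a 2D \code{toy_model}
#' @param basin "stacked" or "bulged"
#' @param n number of samples
#' @param seed integer seed
#' @param stride integration steps between retained samples
#' @param n_equil discarded equilibration steps
#' @inheritParams run_langevin
#' @return object of class \code{labeled_samples}: list with \code{features}
#'   (n x 10, nm), \code{label}, \code{source_seed}, \code{x} (flip coords)
#' @export
sample_basin <- function(model, basin = c("stacked", "bulged"), n, seed = 1,
                         stride = 10L, n_equil = 2000L, dt = 0.002,
                         friction = 10, temperature = 300) {
  basin <- match.arg(basin, model$labels)
  if (n == 0)
    return(structure(list(features = matrix(numeric(0), 0, 10), label = basin,
                          source_seed = seed, x = numeric(0)),
                     class = "labeled_samples"))
  sep <- model$separatrix
  wall <- if (basin == "stacked") c(-Inf, sep) else c(sep, Inf)
  if (!any(is.finite(c(basin_minimum(model, basin)))))
    stop("basin interval empty")
  traj <- run_langevin(model, n_equil + n * stride, dt = dt,
                       friction = friction, temperature = temperature,
                       seed = seed, x0 = basin_minimum(model, basin),
                       stride = stride, wall = wall)
  keep <- tail(seq_len(nrow(traj$frames)), n)
  x <- traj$frames[keep, 1]
  structure(list(features = feature_map(model, x, noise = TRUE, seed = seed),
                 label = basin, source_seed = seed, x = x),
            class = "labeled_samples")
}
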