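# OneOPES-style orchestration: the 8-replica ladder, synchronized biased
# dynamics, and neighbor exchanges.

# --- collective variables computable on the toy model -----------------------
# Encoded for the compiled engine as c(type, p1, p2, p3):
#   type 0: s = p1 + p2 * tanh(2 x)       (HLDA evaluated on noiseless features)
#   type 1: s = coordinate p1 (1-based in R, 0-based in C++)
#   type 2: s = sin(p2 * x_{p1} + p3)     (bounded torsion-like CV)

#' Toy HLDA collective variable
#'
#' The HLDA combination evaluated on the noiseless feature map reduces to
#' \code{a + b tanh(2x)}; this is the deterministic form used to bias the
#' dynamics.
#' @param a,b intercept and amplitude
#' @param id CV name
#' @return object of class \code{toy_cv}
#' @export
toy_cv_hlda <- function(a, b, id = "hlda") {
  rng <- sort(c(a - b, a + b))
  pad <- 0.05 * diff(rng) + 1e-6
  structure(list(id = id, spec = c(0, a, b, 0), grid = c(rng[1] - pad, rng[2] + pad, 2001)),
            class = "toy_cv")
}

#' Toy coordinate collective variable (e.g. the hydration coordinate y)
#' @param index coordinate index (1 = flip x, 2 = hydration y)
#' @param grid evaluation range \code{c(min, max, n)}
#' @param id CV name
#' @export
toy_cv_coord <- function(index = 2L, grid = c(-3, 3, 2001), id = "hydration") {
  structure(list(id = id, spec = c(1, index - 1L, 0, 0), grid = grid),
            class = "toy_cv")
}

#' Toy torsion-like collective variable \code{sin(freq * x + phase)}
#' @param index coordinate index
#' @param freq,phase frequency and phase of the periodic proxy
#' @param id CV name
#' @export
toy_cv_torsion <- function(index = 1L, freq = 1, phase = 0, id = "t2") {
  structure(list(id = id, spec = c(2, index - 1L, freq, phase),
                 grid = c(-1.05, 1.05, 2001)), class = "toy_cv")
}

#' Convert a trained HLDA CV into its deterministic toy form
#'
#' On the noiseless feature map \code{d_i = m_i + s_i tanh(2x)} the linear
#' combination collapses to \code{a + b tanh(2x)}.
#' @param cv an \code{hlda_cv}
#' @param model the 2D \code{toy_model} whose feature map defines m and s
#' @return a \code{toy_cv}
#' @export
hlda_as_toy_cv <- function(cv, model) {
  fm <- model$feature
  toy_cv_hlda(a = cv$offset + sum(cv$coefficients * fm$m),
              b = sum(cv$coefficients * fm$s))
}

#' Default auxiliary CVs for the toy flip model
#'
#' The first auxiliary CV is the hidden hydration coordinate; the remaining
#' ones are bounded torsion-like functions of the flip coordinate with
#' distinct frequencies and phases (standing in for per-nucleotide torsions).
#' @param model the \code{toy_model} (sets the hydration grid range)
#' @param n number of auxiliary CVs (<= 7)
#' @return list of \code{toy_cv}
#' @export
toy_aux_cvs <- function(model, n = 7L) {
  stopifnot(n >= 1, n <= 7)
  p <- model$params
  sy <- sqrt(kT_of(model$temperature) / p$ky)
  hyd <- toy_cv_coord(2L, grid = c(p$ymid - p$yamp - 8 * sy,
                                   p$ymid + p$yamp + 8 * sy, 2001),
                      id = "hydration")
  freqs <- c(1, 1, 2, 2, 3, 3)
  phases <- c(0, pi / 2, 0, pi / 2, 0, pi / 2)
  aux <- list(hyd)
  for (k in seq_len(n - 1))
    aux[[k + 1]] <- toy_cv_torsion(1L, freqs[k], phases[k], id = paste0("t", k + 1))
  aux
}

#' Build the default OneOPES replica ladder
#'
#' Replica 0 carries the main OPES-Explore layer only (the
#' convergence-dedicated replica); replica r >= 1 additionally biases the
#' first r auxiliary CVs with low-barrier layers and is progressively heated
#' by a multithermal layer up to its ceiling. Defaults follow the published
#' 8-replica arrangement: ceilings 302, 304, 306, 308, 310, 314, 320 K,
#' exchange stride 2000 steps, main layer barrier 20 kJ/mol at pace 20000,
#' auxiliary layers 3 kJ/mol at pace 40000, thermostat 300 K.
#'
#' @param main_cv a \code{toy_cv} biased on every replica
#' @param aux_cvs ordered list of auxiliary \code{toy_cv}
#'   (length <= n_replicas - 1)
#' @param n_replicas number of replicas
#' @param temperature thermostat temperature in K
#' @param ceilings per-exploratory-replica multithermal ceilings in K;
#'   linearly rescaled from the 8-replica defaults when n_replicas differs
#' @param exchange_stride steps between neighbor exchange attempts
#' @param main_barrier,main_pace main layer barrier (kJ/mol) and pace
#' @param aux_barrier,aux_pace auxiliary layer barrier (kJ/mol) and pace
#' @param mt_points temperatures per multithermal grid
#' @param mt_stride steps between multithermal shift updates
#' @return object of class \code{ladder_config}
#' @export
build_default_ladder <- function(main_cv, aux_cvs = list(), n_replicas = 8L,
                                 temperature = 300, ceilings = NULL,
                                 exchange_stride = 2000L,
                                 main_barrier = 20, main_pace = 20000L,
                                 aux_barrier = 3, aux_pace = 40000L,
                                 mt_points = 5L, mt_stride = 500L) {
  n_replicas <- as.integer(n_replicas)
  stopifnot(n_replicas >= 1)
  if (exchange_stride <= 0) stop("exchange_stride must be positive")
  if (main_pace <= 0 || aux_pace <= 0) stop("paces must be positive")
  if (length(aux_cvs) > n_replicas - 1)
    stop("need at most n_replicas - 1 auxiliary CVs")
  ids <- c(main_cv$id, vapply(aux_cvs, `[[`, "", "id"))
  if (anyDuplicated(ids)) stop("duplicate CV ids: ", paste(ids, collapse = ", "))
  default_ceil <- c(302, 304, 306, 308, 310, 314, 320)
  if (is.null(ceilings)) {
    ceilings <- if (n_replicas == 8L) default_ceil
    else if (n_replicas == 1L) numeric(0)
    else stats::approx(seq(0, 1, length.out = 7), default_ceil,
                       seq(0, 1, length.out = n_replicas - 1))$y
  }
  if (length(ceilings) != max(n_replicas - 1, 0) ||
      is.unsorted(ceilings))
    stop("ceilings must be non-decreasing with one value per exploratory replica")

  layer_cfg <- function(cv, barrier, pace)
    list(cv = cv$spec, cv_id = cv$id, barrier = barrier, pace = as.integer(pace),
         sigma0 = NA_real_, gamma = NA_real_, merge_threshold = 1,
         grid = cv$grid)
  replicas <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    layers <- list(layer_cfg(main_cv, main_barrier, main_pace))
    n_aux <- min(r - 1, length(aux_cvs))
    for (k in seq_len(n_aux))
      layers[[k + 1]] <- layer_cfg(aux_cvs[[k]], aux_barrier, aux_pace)
    mt <- NULL
    if (r > 1)
      mt <- list(temperatures = seq(temperature, ceilings[r - 1],
                                    length.out = mt_points),
                 stride = as.integer(mt_stride))
    replicas[[r]] <- list(layers = layers, mt = mt)
  }
  structure(list(n_replicas = n_replicas, replicas = replicas,
                 temperature = temperature, exchange_stride = as.integer(exchange_stride),
                 ceilings = ceilings, cv_ids = ids),
            class = "ladder_config")
}

#' @export
print.ladder_config <- function(x, ...) {
  cat("ladder_config:", x$n_replicas, "replicas at", x$temperature,
      "K, exchange every", x$exchange_stride, "steps\n")
  for (r in seq_len(x$n_replicas)) {
    rc <- x$replicas[[r]]
    ids <- vapply(rc$layers, `[[`, "", "cv_id")
    cat(sprintf("  replica %d: %s%s\n", r - 1, paste(ids, collapse = " + "),
                if (!is.null(rc$mt)) paste0(" | multiT to ",
                                            max(rc$mt$temperatures), " K") else ""))
  }
  invisible(x)
}

#' Run a OneOPES replica ladder on a toy model
#'
#' Synchronous BAOAB stepping of all replicas with per-layer depositions at
#' each layer's pace and even/odd alternating neighbor exchange attempts.
#' Exchanges swap configurations (positions and velocities), never bias
#' states. Replica 0 is the convergence stream used for reweighting.
#'
#' @param ladder a \code{ladder_config}
#' @param model a \code{toy_model}
#' @param n_steps integration steps
#' @param seed integer seed; the run is fully deterministic per seed
#' @param dt,friction integrator parameters (ps, 1/ps)
#' @param colvar_stride record every so many steps
#' @param x0 initial coordinates (matrix n_replicas x dim, default: all at the
#'   stacked minimum)
#' @return object of class \code{ladder_run}: per-replica COLVAR data frames
#'   (time, coordinates, per-layer CVs, potential energy \code{ene},
#'   instantaneous bias \code{bias} and final-bias column \code{bias.final}),
#'   kernel tables, multithermal summaries, and the exchange log
#' @export
run_oneopes <- function(ladder, model, n_steps, seed = 1, dt = 0.002,
                        friction = 10, colvar_stride = 100L, x0 = NULL) {
  stopifnot(inherits(ladder, "ladder_config"), dt * friction < 1)
  R <- ladder$n_replicas
  if (is.null(x0)) {
    x0 <- matrix(rep(basin_minimum(model, "stacked"), each = R), nrow = R)
  }
  out <- cpp_run_ladder(.cpp_model(model), ladder$replicas, n_steps, dt,
                        friction, ladder$temperature, seed,
                        ladder$exchange_stride, as.integer(colvar_stride), x0)
  dim <- out$dim
  max_layers <- out$max_layers
  coord_names <- c("x", "y")[seq_len(dim)]
  reps <- lapply(seq_len(R), function(r) {
    rr <- out$replicas[[r]]
    nr <- rr$n_rows
    cm <- rr$colvar[seq_len(nr), , drop = FALSE]
    ids <- vapply(ladder$replicas[[r]]$layers, `[[`, "", "cv_id")
    cvn <- if (max_layers > 0)
      paste0("cv.", c(ids, rep("unused", max_layers - length(ids))))
    else character(0)
    colnames(cm) <- c("time", coord_names, cvn, "ene", "bias")
    df <- as.data.frame(cm[, colnames(cm) != "cv.unused", drop = FALSE])
    df$bias.final <- rr$bias_final
    kernels <- rr$kernels
    names(kernels) <- ids
    list(colvar = df, kernels = kernels, sigma0 = rr$sigma0, mt = rr$mt,
         layer_ids = ids)
  })
  ex <- out$exchange_log
  exchange_log <- data.frame(step = ex[, 1], replica_i = as.integer(ex[, 2]),
                             replica_j = as.integer(ex[, 3]), delta = ex[, 4],
                             accepted = ex[, 5] > 0.5)
  structure(list(replicas = reps, exchange_log = exchange_log,
                 ladder = ladder, model = model, seed = seed, dt = dt,
                 friction = friction, n_steps = n_steps,
                 colvar_stride = colvar_stride),
            class = "ladder_run")
}

#' @export
print.ladder_run <- function(x, ...) {
  acc <- if (nrow(x$exchange_log)) mean(x$exchange_log$accepted) else NA
  cat("ladder_run:", x$ladder$n_replicas, "replicas,",
      format(x$n_steps, big.mark = ","), "steps, exchange acceptance",
      if (is.na(acc)) "n/a" else sprintf("%.2f", acc), "\n")
  invisible(x)
}

#' Attempt a Metropolis replica exchange
#'
#' Accepts the configuration swap with probability
#' \deqn{\min\{1, \exp(-\beta [(B_i(x_j) + B_j(x_i)) - (B_i(x_i) + B_j(x_j))])\}}
#' where \eqn{B_r} is replica r's total bias. On acceptance the configurations
#' swap; bias states never do.
#'
#' @param replica_i,replica_j lists with elements \code{x} (configuration),
#'   \code{bias} (function of x returning total bias energy in kJ/mol) and
#'   \code{temperature} (thermostat K, must match)
#' @param u uniform random number in (0,1); drawn from \code{runif} if missing
#' @return list with \code{accepted}, \code{delta} (in kT), \code{prob}, and
#'   the two replicas (configurations swapped if accepted)
#' @export
attempt_exchange <- function(replica_i, replica_j, u = NULL) {
  if (!isTRUE(all.equal(replica_i$temperature, replica_j$temperature)))
    stop("mismatched thermostat temperatures")
  kT <- kT_of(replica_i$temperature)
  delta <- ((replica_i$bias(replica_j$x) + replica_j$bias(replica_i$x)) -
            (replica_i$bias(replica_i$x) + replica_j$bias(replica_j$x))) / kT
  prob <- min(1, exp(-delta))
  if (is.null(u)) u <- runif(1)
  accepted <- u < prob || delta <= 0
  if (accepted) {
    tmp <- replica_i$x
    replica_i$x <- replica_j$x
    replica_j$x <- tmp
  }
  list(accepted = accepted, delta = delta, prob = prob,
       replica_i = replica_i, replica_j = replica_j)
}
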