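# OPES-Explore bias layers and the multithermal expanded ensemble.

#' Create an OPES-Explore bias layer state
#'
#' The layer maintains a compressed list of unit-weight Gaussian kernels
#' estimating the *sampled* distribution (the Explore flavor) and evaluates
#' the bias
#' \deqn{V(s) = (\gamma - 1)\, kT \, \log\big((1-\varepsilon)\,\tilde p(s)/Z
#'   + \varepsilon\big), \qquad Z = \sup_s \tilde p(s),}
#' with \eqn{\varepsilon = \exp(-\beta \Delta E / (\gamma - 1))}. This pins
#' \eqn{\sup V = 0} and caps the bias range at exactly \eqn{\Delta E} for any
#' kernel set. With no kernels the bias is identically zero.
#'
#' @param barrier barrier parameter \eqn{\Delta E} in kJ/mol
#' @param temperature temperature in K
#' @param gamma bias factor; default \eqn{\beta \Delta E}
#' @param pace integration steps between depositions
#' @param sigma0 initial kernel bandwidth; \code{NA} lets the engine estimate
#'   it from the pre-deposition CV fluctuations
#' @param merge_threshold kernels closer than this multiple of an existing
#'   kernel's bandwidth are merged (weighted-moment merge)
#' @param grid evaluation grid \code{c(min, max, n)} used by the compiled
#'   engine's cached linear interpolation
#' @param cv_id name of the collective variable this layer biases
#' @return object of class \code{opes_state}
#' @export
opes_state <- function(barrier, temperature = 300, gamma = NULL, pace = 500L,
                       sigma0 = NA_real_, merge_threshold = 1,
                       grid = c(-3, 3, 2001), cv_id = "cv") {
  stopifnot(barrier > 0, pace >= 1)
  kT <- kT_of(temperature)
  # default beta * DeltaE, clamped above 1 so the zero-barrier limit is V -> 0
  if (is.null(gamma)) gamma <- max(barrier / kT, 1 + 1e-8)
  if (gamma <= 1) stop("bias factor gamma must exceed 1")
  structure(list(
    kernels = matrix(numeric(0), 0, 3,
                     dimnames = list(NULL, c("center", "sigma", "height"))),
    barrier = barrier, gamma = gamma, kT = kT,
    epsilon = exp(-barrier / ((gamma - 1) * kT)),
    pace = as.integer(pace), sigma0 = sigma0,
    merge_threshold = merge_threshold, grid = grid, cv_id = cv_id,
    n_deposited = 0L), class = "opes_state")
}

#' @export
print.opes_state <- function(x, ...) {
  cat("opes_state on '", x$cv_id, "': DeltaE = ", x$barrier,
      " kJ/mol, gamma = ", round(x$gamma, 3), ", ", nrow(x$kernels),
      " kernels (", x$n_deposited, " deposited)\n", sep = "")
  invisible(x)
}

#' Evaluate an OPES bias
#'
#' Exact kernel-sum evaluation (no grid interpolation); the supremum
#' normalization Z is located by a dense scan over the layer's grid range plus
#' the kernel centers.
#'
#' @param state an \code{opes_state}
#' @param s CV value(s)
#' @return bias energy in kJ/mol (vector as \code{s}), with the analytic
#'   derivative attached as attribute \code{"derivative"}
#' @export
opes_bias <- function(state, s) {
  res <- cpp_opes_eval(state$kernels, as.numeric(s), state$barrier,
                       state$gamma, state$kT, state$grid[1], state$grid[2],
                       as.integer(state$grid[3]))
  structure(res$V, derivative = res$dV)
}

#' Deposit an observed CV value into an OPES layer
#'
#' Adds a kernel at \code{s_observed} with bandwidth
#' \eqn{\sigma = \sigma_0 n_{\mathrm{eff}}^{-1/5}} (1D adaptive shrinkage),
#' merging with the nearest existing kernel when closer than
#' \code{merge_threshold} bandwidths (weighted-moment merge).
#'
#' @param state an \code{opes_state}
#' @param s_observed observed CV value at a deposition step
#' @return the updated \code{opes_state}
#' @export
opes_update <- function(state, s_observed) {
  if (!is.finite(s_observed)) stop("non-finite CV value at deposition")
  if (is.na(state$sigma0))
    stop("sigma0 is unset; give sigma0 explicitly for R-level updates")
  n_eff <- state$n_deposited + 1
  sig <- state$sigma0 * n_eff^(-1 / 5)
  state$kernels <- cpp_opes_deposit(state$kernels, s_observed, sig,
                                    state$merge_threshold)
  colnames(state$kernels) <- c("center", "sigma", "height")
  state$n_deposited <- n_eff
  state
}

#' Create a multithermal expanded-ensemble state
#'
#' Expanded ensemble over an inverse-temperature grid spanning the thermostat
#' temperature to a ceiling:
#' \deqn{V(U) = -\frac{1}{\beta_0} \log \frac{1}{J} \sum_j
#'  \exp\big(-(\beta_j - \beta_0) U + \beta_0 \lambda_j\big)}
#' with shifts \eqn{\lambda_j} adapted on the fly toward the free energy of
#' ensemble j, so every grid temperature is visited.
#'
#' @param temperatures grid of temperatures in K (first one is usually the
#'   thermostat temperature)
#' @param t0 thermostat temperature in K
#' @param stride steps between shift updates
#' @return object of class \code{multithermal_state}
#' @export
multithermal_state <- function(temperatures, t0 = 300, stride = 500L) {
  temperatures <- as.numeric(temperatures)
  stopifnot(length(temperatures) >= 1, all(temperatures > 0), stride >= 1)
  if (is.unsorted(temperatures))
    stop("temperature grid must be non-decreasing")
  structure(list(temperatures = temperatures,
                 betas = 1 / (KB_KJ_MOL * temperatures),
                 beta0 = 1 / (KB_KJ_MOL * t0), t0 = t0,
                 lambdas = numeric(length(temperatures)),
                 stride = as.integer(stride)),
            class = "multithermal_state")
}

#' Evaluate the multithermal bias
#' @param state a \code{multithermal_state}
#' @param U potential energy value(s) in kJ/mol
#' @return bias energy in kJ/mol with \code{dV/dU} attached as attribute
#'   \code{"dVdU"}
#' @export
multithermal_bias <- function(state, U) {
  res <- cpp_mt_bias(as.numeric(U), state$betas, state$lambdas, state$beta0)
  structure(res$V, dVdU = res$dVdU)
}

#' Adapt multithermal shifts from an energy history
#'
#' Reweighting estimate of each grid ensemble's free energy:
#' \deqn{\lambda_j = -\frac{1}{\beta_0}\,\log
#'   \frac{\sum_t w_t e^{-(\beta_j-\beta_0) U_t}}{\sum_t w_t}},
#' with weights \eqn{w_t = e^{\beta_0 B_t}} unbiasing the ensemble the history
#' was sampled from. When \code{bias_history} is omitted the history is
#' assumed sampled under the state's own current bias; repeated calls on a
#' fixed stationary history are then a convergent fixed-point iteration, and
#' the update is idempotent at convergence.
#'
#' @param state a \code{multithermal_state}
#' @param U_history potential-energy samples in kJ/mol
#' @param bias_history optional total bias energy at each sample (0 for an
#'   unbiased history)
#' @return the updated \code{multithermal_state}
#' @export
adapt_shifts <- function(state, U_history, bias_history = NULL) {
  if (length(U_history) == 0) return(state)
  if (length(U_history) < state$stride) return(state)
  if (length(state$betas) == 1) return(state)
  B <- if (is.null(bias_history)) as.numeric(multithermal_bias(state, U_history))
       else rep_len(as.numeric(bias_history), length(U_history))
  lw <- state$beta0 * B
  lse <- function(a) { m <- max(a); m + log(sum(exp(a - m))) }
  l0 <- lse(lw)
  state$lambdas <- vapply(seq_along(state$betas), function(j) {
    -(lse(lw - (state$betas[j] - state$beta0) * U_history) - l0) / state$beta0
  }, numeric(1))
  state
}
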