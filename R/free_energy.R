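# Reweighting biased time series into free-energy surfaces, basin free-energy
# differences and convergence diagnostics.

#' Static-final-bias reweighting weights
#'
#' \eqn{w_t \propto \exp(V_\mathrm{final}(s_t)/kT)}: the accumulated bias at
#' the end of the run, evaluated at each frame's CV values, unbiases the
#' sampled ensemble. Weights are normalized to sum to 1.
#'
#' @param colvar a COLVAR data frame carrying a final-bias column (as written
#'   by \code{\link{run_oneopes}}), or a numeric vector of final bias energies
#' @param kT thermal energy in kJ/mol
#' @param bias_col name of the final-bias column
#' @return numeric weights summing to 1
#' @export
reweight_weights <- function(colvar, kT, bias_col = "bias.final") {
  B <- if (is.numeric(colvar)) colvar
  else {
    if (!bias_col %in% names(colvar))
      stop("missing bias column '", bias_col, "'")
    colvar[[bias_col]]
  }
  w <- exp((B - max(B)) / kT)
  w / sum(w)
}

#' One-dimensional free-energy surface from weighted samples
#'
#' \eqn{F(s) = -kT \log(\text{weighted histogram})}, shifted so the minimum is
#' zero; empty cells are infinite.
#'
#' @param s CV samples
#' @param weights per-sample weights (default uniform)
#' @param kT thermal energy in kJ/mol
#' @param edges bin edges; default 200 bins spanning the observed range
#'   padded by 5 percent
#' @param nbins number of bins when \code{edges} is NULL
#' @return object of class \code{fes}: \code{centers}, \code{edges}, \code{F}
#'   (kJ/mol), \code{counts}, \code{kT}
#' @export
fes_1d <- function(s, weights = NULL, kT, edges = NULL, nbins = 200L) {
  if (is.null(weights)) weights <- rep(1 / length(s), length(s))
  stopifnot(length(weights) == length(s))
  if (is.null(edges)) {
    r <- range(s)
    pad <- 0.05 * diff(r) + 1e-12
    edges <- seq(r[1] - pad, r[2] + pad, length.out = nbins + 1)
  }
  idx <- findInterval(s, edges, rightmost.closed = TRUE)
  inside <- idx >= 1 & idx <= length(edges) - 1
  if (!any(inside)) stop("all samples fall outside the grid")
  h <- numeric(length(edges) - 1)
  tab <- tapply(weights[inside], idx[inside], sum)
  h[as.integer(names(tab))] <- tab
  F <- ifelse(h > 0, -kT * log(h), Inf)
  F <- F - min(F)
  cnt <- numeric(length(h))
  tab2 <- table(idx[inside])
  cnt[as.integer(names(tab2))] <- as.numeric(tab2)
  structure(list(centers = (edges[-1] + edges[-length(edges)]) / 2,
                 edges = edges, F = F, counts = cnt, kT = kT),
            class = "fes")
}

#' Two-dimensional free-energy surface from weighted samples
#'
#' @param sx,sy CV samples along the two axes
#' @param weights per-sample weights (default uniform)
#' @param kT thermal energy in kJ/mol
#' @param nbins bins per axis (default 100)
#' @param edges_x,edges_y optional bin edges
#' @param axis_names labels of the two axes
#' @return object of class \code{fes2d} with matrix \code{F} (kJ/mol; rows =
#'   x bins), axis centers and edges
#' @export
fes_2d <- function(sx, sy, weights = NULL, kT, nbins = 100L,
                   edges_x = NULL, edges_y = NULL,
                   axis_names = c("cv1", "cv2")) {
  stopifnot(length(sx) == length(sy))
  if (is.null(weights)) weights <- rep(1 / length(sx), length(sx))
  mk <- function(s) {
    r <- range(s); pad <- 0.05 * diff(r) + 1e-12
    seq(r[1] - pad, r[2] + pad, length.out = nbins + 1)
  }
  if (is.null(edges_x)) edges_x <- mk(sx)
  if (is.null(edges_y)) edges_y <- mk(sy)
  ix <- findInterval(sx, edges_x, rightmost.closed = TRUE)
  iy <- findInterval(sy, edges_y, rightmost.closed = TRUE)
  nx <- length(edges_x) - 1; ny <- length(edges_y) - 1
  inside <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  if (!any(inside)) stop("all samples fall outside the grid")
  h <- matrix(0, nx, ny)
  cell <- (iy[inside] - 1) * nx + ix[inside]
  tab <- tapply(weights[inside], cell, sum)
  h[as.integer(names(tab))] <- tab
  F <- ifelse(h > 0, -kT * log(h), Inf)
  F <- F - min(F)
  structure(list(centers_x = (edges_x[-1] + edges_x[-(nx + 1)]) / 2,
                 centers_y = (edges_y[-1] + edges_y[-(ny + 1)]) / 2,
                 edges_x = edges_x, edges_y = edges_y, F = F, kT = kT,
                 axis_names = axis_names),
            class = "fes2d")
}

#' Locate the separatrix of a bimodal 1D free-energy surface
#'
#' The maximum of F between the two lowest local minima.
#' @param fes a \code{fes}
#' @return the CV value of the dividing point
#' @export
find_separatrix <- function(fes) {
  F <- fes$F; n <- length(F)
  fin <- is.finite(F)
  locmin <- which(fin & F <= c(Inf, F[-n]) & F <= c(F[-1], Inf))
  if (length(locmin) < 2) stop("fewer than two minima on the surface")
  two <- locmin[order(F[locmin])][1:2]
  two <- sort(two)
  between <- seq(two[1], two[2])
  Fb <- F[between]
  Fb[!is.finite(Fb)] <- max(Fb[is.finite(Fb)]) # empty gap cells sit at the top
  fes$centers[between[which.max(Fb)]]
}

#' Basin free-energy difference from weighted samples
#'
#' Population estimator \eqn{\Delta G = -kT \ln(P_A/P_B)} with A the basin
#' below the separatrix ("stacked") and B above it ("bulged"); the minima
#' depth difference \eqn{F(\min_A) - F(\min_B)} is reported alongside. A
#' growing-prefix \eqn{\Delta G(t)} series and a 20-block bootstrap error are
#' attached. One empty side yields an infinite (flagged) estimate rather than
#' an error.
#'
#' @param s CV samples (time ordered)
#' @param weights per-sample weights (default uniform)
#' @param kT thermal energy in kJ/mol
#' @param separatrix dividing CV value; default: the FES maximum between the
#'   two lowest minima
#' @param n_prefix number of growing-prefix evaluation points
#' @param n_blocks blocks of the block bootstrap
#' @param n_boot bootstrap resamples
#' @return object of class \code{delta_g}: \code{delta_g} (kJ/mol),
#'   \code{delta_g_kcal}, \code{depth_difference}, \code{error} (kJ/mol),
#'   \code{series} (data frame fraction/dg), \code{separatrix}
#' @export
basin_delta_g <- function(s, weights = NULL, kT, separatrix = NULL,
                          n_prefix = 50L, n_blocks = 20L, n_boot = 200L) {
  n <- length(s)
  if (is.null(weights)) weights <- rep(1 / n, n)
  fes <- fes_1d(s, weights, kT)
  if (is.null(separatrix)) separatrix <- find_separatrix(fes)
  dg_of <- function(idx) {
    pa <- sum(weights[idx][s[idx] < separatrix])
    pb <- sum(weights[idx][s[idx] >= separatrix])
    if (pa == 0 || pb == 0) return(sign(pb - pa) * Inf)
    -kT * log(pa / pb)
  }
  dg <- dg_of(seq_len(n))
  # minima depth difference on the FES (infinite when a side is unvisited)
  below <- fes$centers < separatrix
  depth <- if (any(below) && any(!below))
    min(fes$F[below]) - min(fes$F[!below])
  else sign(sum(!below) - sum(below)) * Inf
  # growing-prefix series
  fr <- seq(1 / n_prefix, 1, length.out = n_prefix)
  series <- data.frame(fraction = fr,
                       dg = vapply(fr, function(f) dg_of(seq_len(ceiling(f * n))),
                                   numeric(1)))
  # block bootstrap
  err <- NA_real_
  if (is.finite(dg) && n >= n_blocks) {
    blocks <- split(seq_len(n), cut(seq_len(n), n_blocks, labels = FALSE))
    bs <- vapply(seq_len(n_boot), function(k) {
      u <- counter_uniforms(k, 0, 11, n_blocks)
      pick <- unlist(blocks[ceiling(u * n_blocks)], use.names = FALSE)
      dg_of(pick)
    }, numeric(1))
    err <- sd(bs[is.finite(bs)])
  }
  structure(list(delta_g = dg, delta_g_kcal = dg / KCAL_TO_KJ,
                 depth_difference = depth, error = err, series = series,
                 separatrix = separatrix, kT = kT, fes = fes),
            class = "delta_g")
}

#' @export
print.delta_g <- function(x, ...) {
  cat(sprintf("delta_g: %.3f kJ/mol (%.3f kcal/mol), depth difference %.3f kJ/mol, error %.3f\n",
              x$delta_g, x$delta_g_kcal, x$depth_difference, x$error))
  invisible(x)
}

#' Convergence assessment of a free-energy time series
#'
#' The series is split into consecutive windows; it is converged when the last
#' two window means differ by less than the tolerance and the last window's
#' standard error is below it. The onset is the start (series index) of the
#' first window from which the criterion holds through the end.
#'
#' @param series numeric \eqn{\Delta G(t)} values (or a \code{delta_g} object,
#'   whose prefix series is used)
#' @param window window length in series points
#' @param tolerance convergence tolerance in the series' energy units
#' @return list with \code{converged}, \code{onset} (series index or NA),
#'   \code{window_means}
#' @export
convergence_report <- function(series, window, tolerance) {
  x <- if (inherits(series, "delta_g")) series$series$dg else as.numeric(series)
  x <- x[is.finite(x)]
  n_win <- floor(length(x) / window)
  if (n_win < 2) stop("need at least two full windows")
  idx <- seq_len(n_win * window)
  wid <- rep(seq_len(n_win), each = window)
  means <- tapply(x[idx], wid, mean)
  ses <- tapply(x[idx], wid, function(v) sd(v) / sqrt(length(v)))
  # window k agrees when its mean matches the next window's within tolerance
  agree <- abs(diff(means)) < tolerance
  sat <- agree & ses[-n_win] < tolerance
  converged <- isTRUE(agree[n_win - 1]) && ses[n_win] < tolerance
  onset <- NA_integer_
  if (converged && any(sat)) {
    run <- rev(cumprod(rev(sat)))
    k <- which(run > 0)[1]
    if (!is.na(k)) onset <- as.integer((k - 1) * window + 1)
  }
  list(converged = converged, onset = onset,
       window_means = as.numeric(means))
}
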