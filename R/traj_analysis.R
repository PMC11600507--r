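# Structural analytics: superposition/RMSD/RMSF, gromos clustering,
# cross-correlation maps, interface contact frequencies, principal modes.
#
# Trajectories are arrays (n_frames x n_sites x 3) in nm. One representative
# site per residue is the caller's choice (e.g. C4' for nucleotides, CA for
# amino acids); the choice is recorded in output attributes, not guessed.

.as_traj <- function(traj) {
  if (is.array(traj) && length(dim(traj)) == 3) return(traj)
  stop("trajectory must be an n_frames x n_sites x 3 array")
}

#' Kabsch superposition of one frame onto a reference
#'
#' Least-squares optimal proper rotation (determinant +1) and translation of
#' the mobile frame onto the reference, fitted on \code{fit_sel}.
#'
#' @param mobile,reference coordinate matrices (sites x 3), nm
#' @param fit_sel site indices used for the fit (default: all)
#' @param measure_sel site indices on which the reported RMSD is computed
#'   (default: the fit selection)
#' @return list with \code{rotation} (3 x 3), \code{translation},
#'   \code{coords} (transformed mobile frame), \code{rmsd} (nm)
#' @export
kabsch_superpose <- function(mobile, reference, fit_sel = NULL,
                             measure_sel = NULL) {
  if (is.null(fit_sel)) fit_sel <- seq_len(nrow(mobile))
  if (is.null(measure_sel)) measure_sel <- fit_sel
  if (length(fit_sel) < 3) stop("need at least 3 fit sites")
  P <- mobile[fit_sel, , drop = FALSE]
  Q <- reference[fit_sel, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) fit selection")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  coords <- sweep(sweep(mobile, 2, cp) %*% R, 2, cq, "+")
  dev <- coords[measure_sel, , drop = FALSE] - reference[measure_sel, , drop = FALSE]
  list(rotation = R, translation = cq - cp %*% R,
       coords = coords, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Per-frame RMSD of a trajectory against a reference
#'
#' Each frame is superposed on the fit selection and the RMSD is measured on
#' the measure selection; a running average at the given window is attached.
#'
#' @param traj trajectory array (frames x sites x 3)
#' @param reference reference frame (sites x 3)
#' @param fit_sel,measure_sel site index selections
#' @param window running-average window in frames (NULL to skip)
#' @return data frame with \code{frame}, \code{rmsd} and (if requested)
#'   \code{running} columns, nm
#' @export
rmsd_series <- function(traj, reference, fit_sel = NULL, measure_sel = NULL,
                        window = NULL) {
  traj <- .as_traj(traj)
  if (length(fit_sel) == 0 && !is.null(fit_sel)) stop("empty selection")
  r <- vapply(seq_len(dim(traj)[1]), function(i)
    kabsch_superpose(traj[i, , ], reference, fit_sel, measure_sel)$rmsd,
    numeric(1))
  out <- data.frame(frame = seq_along(r), rmsd = r)
  if (!is.null(window)) {
    out$running <- stats::filter(r, rep(1 / window, window), sides = 1)
  }
  out
}

#' Root-mean-square fluctuation per site
#'
#' Every frame is superposed onto the reference on the fit selection; the
#' RMSF of site i is \eqn{\sqrt{\langle \| r_i - \langle r_i\rangle \|^2 \rangle}}.
#'
#' @param traj trajectory array
#' @param sel site indices to report (default: all)
#' @param reference reference frame for superposition (default: first frame)
#' @param fit_sel fit selection (default: all sites)
#' @param superpose set FALSE to skip superposition
#' @return numeric vector of per-site fluctuations (nm)
#' @export
rmsf <- function(traj, sel = NULL, reference = NULL, fit_sel = NULL,
                 superpose = TRUE) {
  traj <- .as_traj(traj)
  nf <- dim(traj)[1]
  if (nf < 2) stop("need at least 2 frames")
  if (is.null(sel)) sel <- seq_len(dim(traj)[2])
  if (is.null(reference)) reference <- traj[1, , ]
  fitted <- if (superpose)
    vapply(seq_len(nf), function(i)
      kabsch_superpose(traj[i, , ], reference, fit_sel)$coords,
      matrix(0, dim(traj)[2], 3))
  else aperm(traj, c(2, 3, 1))
  mean_str <- apply(fitted, c(1, 2), mean)
  dev2 <- apply((fitted - array(mean_str, dim(fitted)))^2, c(1, 3), sum)
  sqrt(rowMeans(dev2))[sel]
}

#' gromos (Daura) clustering of a trajectory
#'
#' Iteratively: compute the pairwise RMSD matrix; the frame with the most
#' neighbors within the cutoff becomes a centroid, it and its neighbors form
#' a cluster and are removed; repeat until no frames remain. Ties are broken
#' by the lowest frame index. Clusters are relabeled by decreasing size.
#'
#' @param traj trajectory array
#' @param cutoff RMSD cutoff in nm (the published choice for the RNA hairpin
#'   is 2.0 Angstrom = 0.2 nm)
#' @param fit_sel,measure_sel selections for pairwise superposition and RMSD
#' @return object of class \code{cluster_result}: \code{assignment} (per-frame
#'   cluster id), \code{centroids} (frame index per cluster), \code{sizes}
#'   (descending), \code{cutoff}
#' @export
gromos_cluster <- function(traj, cutoff, fit_sel = NULL, measure_sel = NULL) {
  stopifnot(cutoff > 0)
  traj <- .as_traj(traj)
  nf <- dim(traj)[1]
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in seq(i + 1, nf)) {
    D[i, j] <- D[j, i] <- kabsch_superpose(traj[i, , ], traj[j, , ],
                                           fit_sel, measure_sel)$rmsd
  }
  alive <- rep(TRUE, nf)
  assignment <- integer(nf)
  centroids <- integer(0)
  k <- 0
  while (any(alive)) {
    idx <- which(alive)
    counts <- vapply(idx, function(i) sum(D[i, idx] < cutoff) - 1L, integer(1))
    center <- idx[which.max(counts)]  # which.max takes the first = lowest index
    members <- idx[D[center, idx] < cutoff]
    members <- union(center, members)
    k <- k + 1
    assignment[members] <- k
    centroids[k] <- center
    alive[members] <- FALSE
  }
  sizes <- as.integer(table(assignment))
  ord <- order(-sizes, centroids)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(assignment = relabel[assignment],
                 centroids = centroids[ord], sizes = sizes[ord],
                 cutoff = cutoff, n_frames = nf),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("gromos clustering:", length(x$sizes), "clusters of", x$n_frames,
      "frames at cutoff", x$cutoff, "nm; sizes:",
      paste(utils::head(x$sizes, 10), collapse = " "), "\n")
  invisible(x)
}

#' Dynamic cross-correlation matrix of per-residue motions
#'
#' Pearson correlation of positional fluctuations,
#' \deqn{C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'  {\sqrt{\langle \Delta r_i^2\rangle \langle \Delta r_j^2\rangle}},\qquad
#'  \Delta r = r - \langle r \rangle,}
#' computed from one representative site per residue after superposing every
#' frame onto the first. Entries range from -1 to 1, with the diagonal exactly
#' 1; zero-variance sites are flagged \code{NA} (recorded in attribute
#' \code{"flagged"}) rather than propagating NaN.
#'
#' @param traj trajectory array (frames x sites x 3), one site per residue
#' @param fit_sel fit selection for the superposition
#' @param superpose set FALSE if frames are already aligned
#' @return matrix of class \code{correlation_matrix}
#' @export
cross_correlation <- function(traj, fit_sel = NULL, superpose = TRUE) {
  traj <- .as_traj(traj)
  nf <- dim(traj)[1]; ns <- dim(traj)[2]
  if (nf < 2) stop("need at least 2 frames")
  if (superpose) {
    ref <- traj[1, , ]
    for (i in seq_len(nf)) traj[i, , ] <- kabsch_superpose(traj[i, , ], ref,
                                                           fit_sel)$coords
  }
  mean_str <- apply(traj, c(2, 3), mean)
  dev <- traj - rep(1, nf) %o% mean_str
  # inner products <dri . drj>
  flat <- matrix(dev, nf, ns * 3)
  ip <- matrix(0, ns, ns)
  for (k in 1:3) {
    comp <- flat[, ((k - 1) * ns + 1):(k * ns), drop = FALSE]
    ip <- ip + crossprod(comp) / nf
  }
  v <- diag(ip)
  flagged <- v < 1e-300
  denom <- sqrt(outer(v, v))
  C <- ip / denom
  C[flagged, ] <- NA_real_
  C[, flagged] <- NA_real_
  di <- diag(C); di[!flagged] <- 1; diag(C) <- di
  structure(C, class = c("correlation_matrix", "matrix"),
            flagged = which(flagged), n_frames = nf)
}

#' Contact frequency between two residue groups
#'
#' A residue pair is in contact in a frame when any inter-site distance is
#' below the cutoff; the frequency is the fraction of frames in contact.
#'
#' @param traj trajectory array
#' @param group_a,group_b named lists mapping residue labels to site indices;
#'   the groups must be disjoint and non-empty
#' @param cutoff contact cutoff in nm (default 0.4 nm = 4.0 Angstrom)
#' @return data frame with \code{res_a}, \code{res_b}, \code{frequency}
#' @export
contact_frequency <- function(traj, group_a, group_b, cutoff = 0.4) {
  traj <- .as_traj(traj)
  if (length(group_a) == 0 || length(group_b) == 0) stop("empty group")
  if (length(intersect(unlist(group_a), unlist(group_b))))
    stop("groups must be disjoint")
  nf <- dim(traj)[1]
  out <- expand.grid(res_a = names(group_a), res_b = names(group_b),
                     stringsAsFactors = FALSE)
  out$frequency <- mapply(function(ra, rb) {
    ia <- group_a[[ra]]; ib <- group_b[[rb]]
    hits <- vapply(seq_len(nf), function(f) {
      A <- traj[f, ia, , drop = FALSE][1, , , drop = TRUE]
      B <- traj[f, ib, , drop = FALSE][1, , , drop = TRUE]
      A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
      dmin <- min(sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") -
                              2 * A %*% t(B), 0)))
      dmin < cutoff
    }, logical(1))
    mean(hits)
  }, out$res_a, out$res_b)
  out
}

#' Principal modes of positional fluctuation
#'
#' Eigendecomposition of the covariance of concatenated site coordinates
#' after superposition; eigenvalues are non-negative and sorted descending.
#'
#' @param traj trajectory array
#' @param sel site selection (default: all)
#' @param fit_sel fit selection for superposition
#' @param superpose set FALSE if frames are already aligned
#' @return list with \code{values} (nm^2), \code{vectors} (3m x k),
#'   \code{mean} (mean structure)
#' @export
principal_modes <- function(traj, sel = NULL, fit_sel = NULL,
                            superpose = TRUE) {
  traj <- .as_traj(traj)
  nf <- dim(traj)[1]
  if (nf < 2) stop("need at least 2 frames")
  if (is.null(sel)) sel <- seq_len(dim(traj)[2])
  if (superpose) {
    ref <- traj[1, , ]
    for (i in seq_len(nf)) traj[i, , ] <- kabsch_superpose(traj[i, , ],
                                                           ref, fit_sel)$coords
  }
  X <- matrix(traj[, sel, ], nf, length(sel) * 3)
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (nf - 1)
  e <- eigen(C, symmetric = TRUE)
  list(values = pmax(e$values, 0), vectors = e$vectors,
       mean = matrix(colMeans(X), length(sel), 3))
}
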