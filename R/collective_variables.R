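# Feature extraction (contacts, coordination, torsions) and harmonic-LDA
# collective variables.

#' Define a set of atom-pair contacts
#'
#' Selectors follow "RESNAME+RESID:ATOMNAME" (e.g. \code{"A29:N6"}), resolved
#' against a structure record; values are computed in nm.
#'
#' @param sel_a,sel_b character vectors of site selectors
#' @param names optional human-readable pair names
#' @return object of class \code{contact_set} (a data.frame)
#' @export
contact_set <- function(sel_a, sel_b, names = NULL) {
  stopifnot(length(sel_a) == length(sel_b))
  if (is.null(names)) names <- paste0(sel_a, "-", sel_b)
  key <- paste(sel_a, sel_b)
  if (anyDuplicated(key)) stop("duplicate contact pairs")
  structure(data.frame(name = names, sel_a = sel_a, sel_b = sel_b,
                       stringsAsFactors = FALSE),
            class = c("contact_set", "data.frame"))
}

#' The ten intra-RNA contacts of the pre-miR21 flip CV
#'
#' The contact pairs around the flipping adenine A29 (its Watson-Crick edge
#' atoms N6/N1 against G45, C46 and A47 sites) together with their published
#' LDA coefficients. Coefficients are dimensionless and apply to distances in
#' nm; this unit convention is recorded in the CV metadata.
#'
#' @return an \code{hlda_cv} carrying the contact set and coefficients
#' @export
premir21_hlda <- function() {
  a <- c(rep("A29:N6", 5), rep("A29:N1", 5))
  b <- rep(c("G45:H1", "G45:N2", "C46:N3", "C46:O2'", "A47:O5'"), 2)
  coef <- c(-11.63, -11.31, -12.32, -10.22, -10.56,
            -10.74, -9.31, -11.83, -11.32, -12.20)
  hlda_cv(coefficients = coef, contacts = contact_set(a, b),
          metadata = list(units = "nm", source = "published flip CV"))
}

#' Construct an HLDA collective variable
#'
#' A weighted linear combination of contact distances:
#' \code{value = offset + sum_i c_i d_i}.
#'
#' @param coefficients numeric coefficients c_i (applied to nm distances)
#' @param contacts optional \code{contact_set} of the same length
#' @param offset scalar offset (default 0)
#' @param metadata free-form training metadata list
#' @return object of class \code{hlda_cv}
#' @export
hlda_cv <- function(coefficients, contacts = NULL, offset = 0,
                    metadata = list()) {
  coefficients <- as.numeric(coefficients)
  if (!all(is.finite(coefficients)) || sqrt(sum(coefficients^2)) == 0)
    stop("coefficients must be finite with non-zero norm")
  if (!is.null(contacts) && nrow(contacts) != length(coefficients))
    stop("contact set and coefficient lengths differ")
  structure(list(coefficients = coefficients, contacts = contacts,
                 offset = offset, metadata = metadata),
            class = "hlda_cv")
}

#' @export
print.hlda_cv <- function(x, ...) {
  cat("hlda_cv with", length(x$coefficients), "features, offset",
      format(x$offset), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Evaluate an HLDA CV on feature values
#'
#' @param cv an \code{hlda_cv}
#' @param features numeric vector (one frame) or matrix (frames x features) of
#'   distances in nm
#' @return scalar or vector of CV values
#' @export
eval_hlda <- function(cv, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(cv$coefficients))
    stop("feature count (", ncol(features), ") does not match coefficient count (",
         length(cv$coefficients), ")")
  drop(cv$offset + features %*% cv$coefficients)
}

#' Train an HLDA CV from two labeled ensembles
#'
#' Harmonic linear discriminant analysis: the discriminant
#' \deqn{w \propto (\Sigma_A^{-1} + \Sigma_B^{-1})(\mu_A - \mu_B)}
#' with each covariance regularized as \eqn{\Sigma + \delta I}, maximizes the
#' Rayleigh objective
#' \eqn{J(w) = [w^T(\mu_A-\mu_B)]^2 / (w^T \Sigma_h w)} whose within-class
#' scatter \eqn{\Sigma_h = (\Sigma_A^{-1} + \Sigma_B^{-1})^{-1}} is the matrix
#' harmonic mean of the class covariances. The result is normalized to
#' unit Euclidean norm with the sign fixed so that the mean CV value over
#' class A is below the mean over class B.
#'
#' @param samples_a,samples_b \code{labeled_samples} (or plain feature
#'   matrices); class A is conventionally the "stacked" ensemble
#' @param ridge covariance regularization \eqn{\delta}; default
#'   \code{1e-6 * trace(Sigma) / dim} per class
#' @return an \code{hlda_cv} with training metadata
#' @export
train_hlda <- function(samples_a, samples_b, ridge = NULL) {
  A <- if (inherits(samples_a, "labeled_samples")) samples_a$features else as.matrix(samples_a)
  B <- if (inherits(samples_b, "labeled_samples")) samples_b$features else as.matrix(samples_b)
  d <- ncol(A)
  stopifnot(ncol(B) == d)
  if (nrow(A) < d + 2 || nrow(B) < d + 2)
    stop("need at least dim + 2 samples per class")
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  dmu <- mu_a - mu_b
  if (sqrt(sum(dmu^2)) < 1e-12)
    stop("degenerate classes: identical means, no discriminant exists")
  reg <- function(S, ridge) {
    r <- if (is.null(ridge)) 1e-6 * sum(diag(S)) / d else ridge
    S + diag(r, d)
  }
  Sa <- reg(cov(A), ridge); Sb <- reg(cov(B), ridge)
  w <- tryCatch(solve(Sa, dmu) + solve(Sb, dmu),
                error = function(e)
                  stop("singular regularized covariance; use a larger ridge (",
                       conditionMessage(e), ")"))
  w <- w / sqrt(sum(w^2))
  if (sum(w * mu_a) > sum(w * mu_b)) w <- -w
  Sh <- solve(solve(Sa) + solve(Sb))
  J <- sum(w * dmu)^2 / drop(t(w) %*% Sh %*% w)
  hlda_cv(w, metadata = list(
    n_a = nrow(A), n_b = nrow(B),
    ridge = if (is.null(ridge)) 1e-6 * mean(c(sum(diag(Sa)), sum(diag(Sb)))) / d else ridge,
    objective = J, units = "nm",
    sign_convention = "mean(class A) < mean(class B)"))
}

#' Distances of a contact set in a coordinate frame
#'
#' Euclidean distances, minimum-image if a periodic box is present.
#'
#' @param frame coordinate matrix (atoms x 3) in nm
#' @param contacts a \code{contact_set}
#' @param structure optional \code{structure_record} used to resolve the
#'   selectors; if omitted the frame's rownames are matched directly
#' @param box optional periodic box lengths (nm)
#' @param switched apply the rational switching function so each contact is a
#'   value in (0, 1] instead of a raw distance (off by default: the flip CV's
#'   coefficients apply to raw distances)
#' @param r0,n,m switching parameters, used when \code{switched = TRUE}
#' @return numeric vector of distances in nm (or switched contact values),
#'   named by pair
#' @export
contact_distances <- function(frame, contacts, structure = NULL, box = NULL,
                              switched = FALSE, r0 = 0.3, n = 6L, m = 12L) {
  ia <- vapply(contacts$sel_a, resolve_selector, 1L,
               structure = structure, frame = frame)
  ib <- vapply(contacts$sel_b, resolve_selector, 1L,
               structure = structure, frame = frame)
  d <- frame[ia, , drop = FALSE] - frame[ib, , drop = FALSE]
  if (!is.null(box)) {
    for (k in seq_len(ncol(d)))
      d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  r <- sqrt(rowSums(d^2))
  if (switched)
    r <- vapply(r, coordination_number, numeric(1), r0 = r0, n = n, m = m)
  stats::setNames(r, contacts$name)
}

#' Resolve a "RESNAME+RESID:ATOMNAME" selector to a site index
#' @param sel selector string, e.g. "A29:N6"
#' @param structure optional \code{structure_record}
#' @param frame coordinate matrix whose rownames are matched when no
#'   structure is given
#' @return integer row index of the unique matching site
#' @export
resolve_selector <- function(sel, structure = NULL, frame = NULL) {
  if (is.null(structure)) {
    idx <- which(rownames(frame) == sel)
  } else {
    m <- regmatches(sel, regexec("^([A-Za-z]+)([0-9]+):(.+)$", sel))[[1]]
    if (length(m) == 0) stop("unparsable selector: ", sel)
    resname <- m[2]; resid <- as.integer(m[3]); atom <- m[4]
    at <- structure$atoms
    idx <- which(at$resid == resid & at$name == atom &
                 substr(at$resname, 1, nchar(resname)) == resname)
  }
  if (length(idx) != 1)
    stop("selector '", sel, "' resolves to ", length(idx), " sites (need exactly 1)")
  as.integer(idx)
}

#' Coordination number with a rational switching function
#'
#' \deqn{n(r) = \sum_j \frac{1 - (r_j/r_0)^n}{1 - (r_j/r_0)^m}}
#' Each neighbor contributes a value in (0, 1]; the function is continuous at
#' \eqn{r_j = r_0} where the limit is \eqn{n/m}. Defaults follow the common
#' water-oxygen choice (r0 = 0.3 nm, n = 6, m = 12).
#'
#' @param r numeric vector of neighbor distances in nm
#' @param r0 switching radius in nm
#' @param n,m even integer exponents, m > n >= 2
#' @return the coordination number (scalar)
#' @export
coordination_number <- function(r, r0 = 0.3, n = 6L, m = 12L) {
  stopifnot(r0 > 0, n >= 2, m > n, n %% 2 == 0, m %% 2 == 0)
  if (length(r) == 0) return(0)
  q <- r / r0
  out <- ifelse(abs(q - 1) < 1e-8, n / m, (1 - q^n) / (1 - q^m))
  sum(out)
}

#' Signed dihedral angle of four sites
#'
#' Standard atan2 convention with the sign fixed by the right-hand rule about
#' the central bond; planar cis is 0, planar trans is \eqn{\pi}.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors
#' @return angle in radians in (-pi, pi]
#' @export
torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    stop("collinear triple: dihedral undefined")
  b2h <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross(n1, n2) * b2h), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}
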