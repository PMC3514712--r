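#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all landmarks from their centroid. Equals the
#' Frobenius norm of the centered configuration; scales linearly with the
#' configuration (units of the input coordinates, typically mm).
#'
#' @param config A k x d coordinate matrix (k >= 2).
#' @return A positive scalar.
#' @export
#' @examples
#' centroid_size(rbind(c(-1, -1, 0), c(1, -1, 0), c(1, 1, 0), c(-1, 1, 0)))
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 2L) stop("need at least 2 landmarks", call. = FALSE)
  if (!all(is.finite(config))) stop("non-finite coordinates", call. = FALSE)
  cs <- sqrt(sum(scale(config, scale = FALSE)^2))
  if (cs == 0)
    stop("degenerate configuration: all landmarks coincide", call. = FALSE)
  cs
}

# Internal: translate a configuration so its centroid is at the origin.
center_config <- function(config) {
  sweep(config, 2L, colMeans(config), "-")
}

#' Optimal rotation between two centered configurations
#'
#' Returns the proper rotation `R` (det +1) minimizing `||B - A %*% R||`
#' (Kabsch/Procrustes solution via SVD of `t(A) %*% B`). Reflections are
#' excluded: when the unconstrained optimum would be a reflection, the
#' singular direction with the smallest singular value is sign-flipped, which
#' is the optimal proper rotation. For rank-deficient cross-products the SVD
#' sign ambiguity is resolved deterministically by making the largest-magnitude
#' entry of each left singular vector positive.
#'
#' @param A,B Centered k x d matrices (same dimensions).
#' @return A d x d rotation matrix.
#' @export
optimal_rotation <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("dimension mismatch", call. = FALSE)
  M <- crossprod(A, B)
  sv <- svd(M)
  U <- sv$u; V <- sv$v
  # deterministic sign convention, relevant only for (near-)degenerate spectra
  for (j in seq_len(ncol(U))) {
    pivot <- which.max(abs(U[, j]))
    if (U[pivot, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  R <- U %*% t(V)
  if (det(R) < 0) {
    j <- which.min(sv$d)
    U[, j] <- -U[, j]
    R <- U %*% t(V)
  }
  R
}

#' Generalized Procrustes Analysis
#'
#' Iterative least-squares superimposition: each configuration is centered,
#' scaled to unit centroid size and rotated to the current consensus; the
#' consensus is then recomputed as the coordinate-wise mean and rescaled to
#' unit centroid size. Iteration stops when the root-sum-square change of the
#' consensus falls below `tol`. The aligned shapes are finally projected
#' orthogonally onto the tangent space at the consensus, which makes ordinary
#' multivariate statistics applicable to the resulting Procrustes shape
#' coordinates. Reflections are never used (landmark sets are biologically
#' homologous), and the superimposition removes translation, scale and
#' orientation only — shape variation is untouched.
#'
#' @param dataset A [landmark_dataset()] with n >= 2 specimens.
#' @param tol Convergence tolerance on the consensus change (default 1e-10,
#'   far below any realistic digitizing noise).
#' @param max_iter Maximum number of iterations (default 100).
#' @return An object of class `gpa_fit`:
#'   \describe{
#'     \item{aligned}{k x d x n array of tangent-space shape coordinates.}
#'     \item{consensus}{k x d mean shape, centered, centroid size 1.}
#'     \item{centroid_sizes, log_centroid_sizes}{per-specimen size (mm) and
#'       its natural logarithm.}
#'     \item{iterations, converged}{convergence diagnostics.}
#'     \item{metadata}{the dataset's metadata, carried through.}
#'   }
#' @export
gpa <- function(dataset, tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  n <- n_specimens(dataset)
  if (n < 2L) stop("GPA requires at least 2 specimens", call. = FALSE)
  k <- n_landmarks(dataset)
  d <- dim(dataset$coords)[2L]
  cs <- numeric(n)
  X <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- center_config(dataset$coords[, , i])
    cs[i] <- sqrt(sum(ci^2))
    if (cs[i] == 0)
      stop("degenerate configuration (all landmarks coincide): specimen ",
           specimen_ids(dataset)[i], call. = FALSE)
    X[[i]] <- ci / cs[i]
  }
  consensus <- X[[1L]]
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) X[[i]] <- X[[i]] %*% optimal_rotation(X[[i]], consensus)
    new_cons <- Reduce(`+`, X) / n
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations", call. = FALSE)
  dimnames(consensus) <- dimnames(dataset$coords)[1:2]
  # orthogonal projection onto the tangent hyperplane {y : <y - c, c> = 0}
  cvec <- flat(consensus)
  aligned <- array(NA_real_, c(k, d, n),
                   dimnames = dimnames(dataset$coords))
  for (i in seq_len(n)) {
    xi <- flat(X[[i]])
    aligned[, , i] <- unflat(xi - (sum(xi * cvec) - 1) * cvec, consensus)
  }
  structure(list(aligned = aligned,
                 consensus = consensus,
                 centroid_sizes = setNames(cs, specimen_ids(dataset)),
                 log_centroid_sizes = setNames(log(cs), specimen_ids(dataset)),
                 iterations = iter,
                 converged = converged,
                 metadata = dataset$metadata),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  dm <- dim(x$aligned)
  cat(sprintf("GPA fit: %d specimens, %d landmarks, %dD; %d iterations (%s)\n",
              dm[3L], dm[1L], dm[2L], x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Procrustes distance between two shapes
#'
#' Euclidean norm of the difference between two sets of Procrustes shape
#' coordinates from the same superimposition — the standard tangent-space
#' approximation to Procrustes distance.
#'
#' @param s1,s2 k x d shape matrices from the same superimposition.
#' @return A nonnegative scalar in Procrustes units.
#' @export
procrustes_distance <- function(s1, s2) {
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  if (!all(dim(s1) == dim(s2)))
    stop("shapes have mismatched dimensions", call. = FALSE)
  sqrt(sum((s1 - s2)^2))
}

#' Interlandmark distance on raw coordinates
#'
#' Euclidean distance between two named landmarks in a configuration's
#' original (pre-superimposition) coordinates, in the input units (mm). Used
#' for linear size predictors such as the hormion-opisthocranion distance
#' proxying chondrocranial length.
#'
#' @param config A k x d matrix with landmark names as row names.
#' @param a,b Landmark names.
#' @return A nonnegative scalar.
#' @export
interlandmark_distance <- function(config, a, b) {
  config <- as.matrix(config)
  nm <- rownames(config)
  for (lmk in c(a, b)) {
    if (!lmk %in% nm)
      stop("unknown landmark '", lmk, "'; available: ",
           paste(nm, collapse = ", "), call. = FALSE)
  }
  sqrt(sum((config[a, ] - config[b, ])^2))
}

#' Mean shape of a set of aligned configurations
#'
#' @param shapes A k x d x n array of aligned shapes, or a list of k x d
#'   matrices.
#' @return The coordinate-wise mean, a k x d matrix.
#' @export
mean_shape <- function(shapes) {
  if (is.list(shapes)) {
    if (!length(shapes)) stop("empty set of shapes", call. = FALSE)
    return(Reduce(`+`, shapes) / length(shapes))
  }
  if (!is.array(shapes) || length(dim(shapes)) != 3L || dim(shapes)[3L] < 1L)
    stop("'shapes' must be a nonempty k x d x n array or list", call. = FALSE)
  out <- apply(shapes, c(1L, 2L), mean)
  dimnames(out) <- dimnames(shapes)[1:2]
  out
}

# Internal: n x (k*d) matrix of flattened aligned shapes from a gpa_fit.
shapes_matrix <- function(fit) {
  dm <- dim(fit$aligned)
  t(apply(fit$aligned, 3L, flat))
}
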