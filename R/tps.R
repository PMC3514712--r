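#' Project a 3D shape onto a plane
#'
#' Orthogonal projection used to render 3D landmark configurations as 2D
#' deformation grids. Named planes keep the corresponding coordinate pair;
#' a numeric 3-vector is interpreted as the plane normal and the projection is
#' expressed in an orthonormal basis of its complement (deterministically
#' chosen via QR).
#'
#' @param shape A k x 3 matrix (k x 2 input is returned unchanged for
#'   `"xy"`).
#' @param plane `"xy"`, `"xz"`, `"yz"`, or a nonzero numeric length-3 normal
#'   vector.
#' @return A k x 2 matrix.
#' @export
project_to_plane <- function(shape, plane = "xy") {
  shape <- as.matrix(shape)
  if (ncol(shape) == 2L) {
    if (identical(plane, "xy")) return(shape)
    stop("2D input can only be projected onto 'xy'", call. = FALSE)
  }
  if (ncol(shape) != 3L) stop("'shape' must be k x 3", call. = FALSE)
  if (is.character(plane)) {
    cols <- switch(plane, xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L),
                   stop("unknown plane '", plane, "'", call. = FALSE))
    out <- shape[, cols, drop = FALSE]
  } else {
    plane <- as.numeric(plane)
    if (length(plane) != 3L) stop("normal must have length 3", call. = FALSE)
    nrm <- sqrt(sum(plane^2))
    if (nrm == 0) stop("zero normal vector", call. = FALSE)
    basis <- qr.Q(qr(cbind(plane / nrm, diag(3))))[, 2:3]
    out <- shape %*% basis
  }
  rownames(out) <- rownames(shape)
  colnames(out) <- NULL
  out
}

# Internal: TPS radial kernel U(r) = r^2 log r, with U(0) = 0.
tps_kernel <- function(r) {
  out <- r^2 * log(r)
  out[r == 0] <- 0
  out
}

# Internal: m x m kernel matrix between two 2D point sets.
tps_kernel_matrix <- function(p, q) {
  dx <- outer(p[, 1L], q[, 1L], "-")
  dy <- outer(p[, 2L], q[, 2L], "-")
  tps_kernel(sqrt(dx^2 + dy^2))
}

#' Fit a thin-plate spline between two 2D point sets
#'
#' Solves the classical bordered system of the interpolating thin-plate
#' spline with kernel `U(r) = r^2 log(r)`: the fitted map sends every source
#' point exactly to its target and minimizes the integral bending energy among
#' all such maps. The kernel weights satisfy the side conditions
#' `sum(w) = 0` and `sum(source * w) = 0` per output dimension, so the map is
#' affine at infinity.
#'
#' @param source,target m x 2 matrices, m >= 3, source points neither
#'   duplicated nor collinear.
#' @return An object of class `tps_model`: `source`, `affine` (3 x 2; rows
#'   intercept, x, y), `weights` (m x 2), and `bending_energy`
#'   (`sum over output dims of w' K w`, zero iff the map is affine).
#' @seealso [tps_apply()], [deformation_grid()]
#' @export
tps_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (ncol(source) != 2L || ncol(target) != 2L)
    stop("thin-plate splines are fitted in 2D; project first", call. = FALSE)
  m <- nrow(source)
  if (m < 3L || nrow(target) != m)
    stop("need m >= 3 matched source/target points", call. = FALSE)
  if (anyDuplicated(round(source, 12L)))
    stop("duplicate source points: singular TPS system", call. = FALSE)
  P <- cbind(1, source)
  if (qr(P)$rank < 3L)
    stop("collinear source points: singular TPS system", call. = FALSE)
  K <- tps_kernel_matrix(source, source)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  sol <- solve(L, rbind(target, matrix(0, 3L, 2L)))
  w <- sol[seq_len(m), , drop = FALSE]
  a <- sol[m + 1:3, , drop = FALSE]
  be <- sum(diag(t(w) %*% K %*% w))
  structure(list(source = source, affine = a, weights = w,
                 bending_energy = max(0, be)),
            class = "tps_model")
}

#' Evaluate a fitted thin-plate spline
#'
#' @param model A [tps_fit()] model.
#' @param points p x 2 matrix of evaluation points.
#' @return p x 2 matrix of mapped points.
#' @export
tps_apply <- function(model, points) {
  stopifnot(inherits(model, "tps_model"))
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("'points' must be p x 2", call. = FALSE)
  U <- tps_kernel_matrix(points, model$source)
  cbind(1, points) %*% model$affine + U %*% model$weights
}

#' Thin-plate spline deformation grid
#'
#' The standard visualization of a shape change: a regular lattice spanning
#' the reference shape's bounding box (padded 10%) is warped by the TPS map
#' from the reference to `reference + magnify * (deformed - reference)`.
#' Magnification is explicit because publication figures typically exaggerate
#' shape changes; record it alongside any figure.
#'
#' @param reference,deformed k x 2 landmark matrices in the same
#'   superimposition (project 3D shapes first with [project_to_plane()]).
#' @param grid_n Number of lattice lines per direction (>= 2).
#' @param magnify Nonnegative exaggeration factor (1 = true change, 0 =
#'   identity grid).
#' @param line_points Sample points per grid line (visual smoothness).
#' @return An object of class `deformation_grid`: `lines` (list of p x 2
#'   polylines), `landmarks_ref`, `landmarks_warped`, `magnify`, `model`.
#' @export
deformation_grid <- function(reference, deformed, grid_n = 20L, magnify = 1,
                             line_points = 50L) {
  reference <- as.matrix(reference); deformed <- as.matrix(deformed)
  if (grid_n < 2L) stop("'grid_n' must be at least 2", call. = FALSE)
  if (magnify < 0) stop("'magnify' must be nonnegative", call. = FALSE)
  target <- reference + magnify * (deformed - reference)
  model <- tps_fit(reference, target)
  rng <- apply(reference, 2L, range)
  pad <- 0.1 * (rng[2L, ] - rng[1L, ])
  xs <- seq(rng[1L, 1L] - pad[1L], rng[2L, 1L] + pad[1L], length.out = grid_n)
  ys <- seq(rng[1L, 2L] - pad[2L], rng[2L, 2L] + pad[2L], length.out = grid_n)
  xf <- seq(min(xs), max(xs), length.out = max(grid_n, line_points))
  yf <- seq(min(ys), max(ys), length.out = max(grid_n, line_points))
  lines <- c(lapply(ys, function(y) tps_apply(model, cbind(xf, y))),
             lapply(xs, function(x) tps_apply(model, cbind(x, yf))))
  structure(list(lines = lines,
                 landmarks_ref = reference,
                 landmarks_warped = tps_apply(model, reference),
                 magnify = magnify,
                 model = model),
            class = "deformation_grid")
}

#' Plot a deformation grid
#'
#' Base-graphics rendering of a [deformation_grid()], optionally overlaying a
#' wireframe connecting named landmark pairs.
#'
#' @param grid A `deformation_grid`.
#' @param edges Optional 2-column matrix (or data.frame) of landmark names or
#'   indices to connect as a wireframe on the warped landmarks.
#' @param main Plot title.
#' @param grid_col,point_col,wire_col Colors.
#' @param ... Passed to [graphics::plot()].
#' @return The grid, invisibly.
#' @export
plot_deformation_grid <- function(grid, edges = NULL, main = "",
                                  grid_col = "grey60", point_col = "black",
                                  wire_col = "steelblue", ...) {
  stopifnot(inherits(grid, "deformation_grid"))
  all_pts <- do.call(rbind, grid$lines)
  plot(all_pts, type = "n", asp = 1, xlab = "", ylab = "", axes = FALSE,
       main = main, ...)
  for (ln in grid$lines) graphics::lines(ln, col = grid_col)
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    lmk <- grid$landmarks_warped
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1L]; j <- edges[e, 2L]
      if (is.character(i) || !is.numeric(edges)) {
        i <- match(edges[e, 1L], rownames(lmk))
        j <- match(edges[e, 2L], rownames(lmk))
        if (anyNA(c(i, j)))
          stop("wireframe edge names not found among landmarks", call. = FALSE)
      }
      graphics::segments(lmk[i, 1L], lmk[i, 2L], lmk[j, 1L], lmk[j, 2L],
                         col = wire_col, lwd = 2)
    }
  }
  graphics::points(grid$landmarks_warped, pch = 19, col = point_col)
  invisible(grid)
}
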