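# Shared fixtures and independent oracles for the test suite.

# Flatten a k x d matrix column-major (mirrors the package convention).
fl <- function(m) as.numeric(m)

# Random proper rotation matrix.
random_rotation <- function(d) {
  R <- qr.Q(qr(matrix(rnorm(d * d), d)))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# Apply a random similarity transform to every specimen of a dataset.
perturb_dataset <- function(dataset) {
  co <- dataset$coords
  d <- dim(co)[2L]
  for (i in seq_len(dim(co)[3L])) {
    R <- random_rotation(d)
    s <- runif(1L, 0.5, 2)
    tr <- rnorm(d, 0, 50)
    co[, , i] <- sweep(s * co[, , i] %*% R, 2L, tr, "+")
  }
  landmark_dataset(co, dataset$metadata)
}

# Small random dataset built directly from raw coordinates (not the
# simulator): base shape + iid noise, under nuisance similarity transforms.
random_small_dataset <- function(n, k, d, noise = 0.05) {
  base <- matrix(rnorm(k * d), k, d)
  co <- array(NA_real_, c(k, d, n),
              dimnames = list(paste0("lm", seq_len(k)), NULL,
                              paste0("s", seq_len(n))))
  for (i in seq_len(n)) {
    cfg <- base + matrix(rnorm(k * d, 0, noise), k, d)
    co[, , i] <- sweep(runif(1, 0.5, 2) * cfg %*% random_rotation(d),
                       2L, rnorm(d, 0, 10), "+")
  }
  landmark_dataset(co)
}

# Independent pooled within-stratum regression oracle assembled
# coordinate-by-coordinate with lm() on stratum-centered data.
oracle_pooled_ols <- function(fit, x, strata = NULL) {
  Y <- t(apply(fit$aligned, 3L, as.numeric))
  n <- nrow(Y)
  strata <- factor(if (is.null(strata)) rep("all", n) else strata)
  Yc <- Y; xc <- x
  for (lev in levels(strata)) {
    id <- strata == lev
    Yc[id, ] <- sweep(Y[id, , drop = FALSE], 2L,
                      colMeans(Y[id, , drop = FALSE]), "-")
    xc[id] <- x[id] - mean(x[id])
  }
  beta <- apply(Yc, 2L, function(y) unname(coef(lm(y ~ xc + 0))))
  fitted <- outer(xc, beta)
  list(beta = beta,
       percent_var = 100 * (1 - sum((Yc - fitted)^2) / sum(Yc^2)),
       scores = as.numeric(
         (Y - matrix(as.numeric(fit$consensus), n, ncol(Y), byrow = TRUE)) %*%
           (beta / sqrt(sum(beta^2)))))
}

# Brute-force optimal-rotation oracle: minimize the residual over an
# angle-axis parametrization from several starts.
oracle_best_rotation_residual <- function(A, B) {
  rot_from <- function(p) {
    theta <- sqrt(sum(p^2))
    if (theta < 1e-12) return(diag(3))
    ax <- p / theta
    Kx <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    diag(3) + sin(theta) * Kx + (1 - cos(theta)) * Kx %*% Kx
  }
  obj <- function(p) sum((B - A %*% rot_from(p))^2)
  best <- Inf
  for (s in seq_len(25)) {
    p0 <- runif(3, -pi, pi)
    res <- optim(p0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, res$value)
  }
  best
}

# Independent TPS route: null-space (constrained least squares) solution of
# the interpolation problem, yielding weights and bending energy without the
# bordered-system solve.
oracle_tps_energy <- function(source, target) {
  m <- nrow(source)
  U <- function(r) { out <- r^2 * log(r); out[r == 0] <- 0; out }
  K <- U(as.matrix(dist(source)))
  P <- cbind(1, source)
  Q <- qr.Q(qr(P), complete = TRUE)
  Q2 <- Q[, 4:m, drop = FALSE]
  energy <- 0
  for (j in 1:2) {
    gamma <- solve(t(Q2) %*% K %*% Q2, t(Q2) %*% target[, j])
    w <- Q2 %*% gamma
    energy <- energy + as.numeric(t(w) %*% K %*% w)
  }
  energy
}

# Rotate a regression vector from its fit's consensus frame into the
# template's frame (shape vectors are only comparable after frame alignment).
to_template_frame <- function(vec, consensus, template) {
  vec %*% optimal_rotation(consensus, template)
}

# A fixed unit tangent effect vector at the built-in template.
fixed_effect_vector <- function(seed = 77) {
  tpl <- cranial_template()
  set.seed(seed)
  shape_tangent_vector(tpl, matrix(rnorm(length(tpl)), nrow(tpl)))
}
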