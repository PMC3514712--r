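#' Pooled within-group multivariate regression of shape on a predictor
#'
#' Fits the linear effect of a scalar size predictor (e.g. cube-root brain
#' volume, chondrocranial length, log centroid size) on Procrustes shape
#' coordinates. To account for sexual dimorphism the regression is pooled
#' within strata: both the tangent-space shape coordinates and the predictor
#' are centered by their stratum means before a single common slope is fitted,
#'
#' \deqn{\beta = \sum_i \tilde x_i \tilde Y_i / \sum_i \tilde x_i^2,}
#'
#' coordinate-wise over all k x d coordinates. The variance explained is
#' `100 * SS_pred / SS_tot` with both sums over all stratum-centered tangent
#' coordinates, and significance is assessed by permuting the predictor within
#' strata (the superimposition is held fixed; it does not depend on the
#' predictor).
#'
#' @param fit A [gpa()] result.
#' @param x Numeric predictor, one value per specimen, on its analysis scale
#'   (cube-root mm for brain volume, mm for interlandmark lengths, natural-log
#'   units for overall size).
#' @param strata Optional factor of pooling strata (typically sex). `NULL`
#'   fits a single stratum. Every stratum must contain at least 2 specimens.
#' @param predictor_name Label stored with the model.
#' @param n_perm Number of random permutations for the significance test
#'   (default 5000). `0` skips the test (`p_value = NA`).
#' @param seed Seed for the permutation stream.
#' @return An object of class `shape_regression` with elements
#'   `predictor_name`, `beta` (k x d, Procrustes units per unit predictor),
#'   `consensus`, `strata`, `x`, `x_mean` (pooled predictor mean),
#'   `percent_var`, `p_value`, `n_perm`, `seed`, and `scores`
#'   (see [regression_scores()]).
#' @seealso [predict_shape()], [predicted_shape_change()],
#'   [permutation_test_regression()]
#' @export
pooled_within_regression <- function(fit, x, strata = NULL,
                                     predictor_name = deparse(substitute(x)),
                                     n_perm = 5000L, seed = 1L) {
  stopifnot(inherits(fit, "gpa_fit"))
  Y <- shapes_matrix(fit)
  n <- nrow(Y)
  if (length(x) != n) stop("'x' must have one value per specimen", call. = FALSE)
  if (!all(is.finite(x))) stop("'x' must be finite", call. = FALSE)
  if (n < 3L) stop("need at least 3 specimens", call. = FALSE)
  strata <- check_strata(strata, n)
  cen <- stratum_center(Y, x, strata)
  ss_x <- sum(cen$x^2)
  if (ss_x <= 0)
    stop("zero pooled predictor variance: no slope is estimable", call. = FALSE)
  beta_vec <- crossprod(cen$Y, cen$x)[, 1L] / ss_x
  ss_tot <- sum(cen$Y^2)
  if (ss_tot <= 0) stop("all shapes identical: zero total variance", call. = FALSE)
  ss_pred <- ss_x * sum(beta_vec^2)
  percent_var <- 100 * ss_pred / ss_tot
  p <- if (n_perm >= 1L)
    permutation_test_regression(fit, x, strata, n_perm = n_perm, seed = seed)
  else NA_real_
  model <- structure(list(predictor_name = predictor_name,
                          beta = unflat(beta_vec, fit$consensus),
                          consensus = fit$consensus,
                          strata = strata,
                          x = x,
                          x_mean = mean(x),
                          percent_var = percent_var,
                          p_value = p,
                          n_perm = as.integer(n_perm),
                          seed = as.integer(seed)),
                     class = "shape_regression")
  model$scores <- if (sum(beta_vec^2) > 0) regression_scores(fit, model) else
    rep(NA_real_, n)
  model
}

#' @export
print.shape_regression <- function(x, ...) {
  cat(sprintf("Shape regression on '%s': %.3f%% of shape variance explained",
              x$predictor_name, x$percent_var))
  if (!is.na(x$p_value))
    cat(sprintf(" (p = %.4g, %d permutations)", x$p_value, x$n_perm))
  cat(sprintf("\n||beta|| = %.5g Procrustes units per unit predictor\n",
              sqrt(sum(x$beta^2))))
  invisible(x)
}

# Internal: validate strata, default single stratum.
check_strata <- function(strata, n) {
  if (is.null(strata)) strata <- rep("all", n)
  if (length(strata) != n)
    stop("'strata' must have one label per specimen", call. = FALSE)
  strata <- factor(strata)
  sizes <- table(strata)
  if (any(sizes < 2L))
    stop("stratum ", paste(names(sizes)[sizes < 2L], collapse = ", "),
         " has fewer than 2 specimens; its deviations are degenerate",
         call. = FALSE)
  strata
}

# Internal: center rows of Y and entries of x by stratum means.
stratum_center <- function(Y, x, strata) {
  for (lev in levels(strata)) {
    idx <- which(strata == lev)
    Y[idx, ] <- sweep(Y[idx, , drop = FALSE], 2L,
                      colMeans(Y[idx, , drop = FALSE]), "-")
    x[idx] <- x[idx] - mean(x[idx])
  }
  list(Y = Y, x = x)
}

#' Projection scores along a regression vector
#'
#' Each specimen's original (stratum-uncentered) deviation from the consensus
#' is projected onto the unit-normalized regression vector, so scores are in
#' Procrustes units and order specimens along the fitted axis of shape change.
#'
#' @param fit A [gpa()] result from the same superimposition the model was
#'   fitted on, or an n x (k*d) matrix of flattened aligned shapes.
#' @param model A [pooled_within_regression()] model.
#' @return A numeric vector of n scores, in specimen order.
#' @export
regression_scores <- function(fit, model) {
  Y <- if (inherits(fit, "gpa_fit")) shapes_matrix(fit) else as.matrix(fit)
  b <- flat(model$beta)
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("regression vector is zero: no axis to project on",
                    call. = FALSE)
  as.numeric((Y - matrix(flat(model$consensus), nrow(Y), length(b),
                         byrow = TRUE)) %*% (b / nb))
}

#' Percent of total shape variance explained by a predictor
#'
#' Convenience wrapper computing only the variance fraction of
#' [pooled_within_regression()] (no permutations).
#'
#' @inheritParams pooled_within_regression
#' @return A scalar in \[0, 100\].
#' @export
percent_variance_explained <- function(fit, x, strata = NULL) {
  pooled_within_regression(fit, x, strata, predictor_name = "x",
                           n_perm = 0L)$percent_var
}

#' Predicted Procrustes-distance change per predictor change
#'
#' The Procrustes distance between the shapes predicted at `x` and at
#' `x + delta_x`: `|delta_x| * ||beta||`. `delta_x` must be on the predictor's
#' analysis scale — for brain volume that is the difference of group means of
#' the *cube-root* volumes, never a raw-volume percentage.
#'
#' @param model A fitted `shape_regression`.
#' @param delta_x Predictor change on the analysis scale.
#' @return A nonnegative scalar in Procrustes units.
#' @export
predicted_shape_change <- function(model, delta_x) {
  stopifnot(inherits(model, "shape_regression"))
  abs(delta_x) * sqrt(sum(model$beta^2))
}

#' Predicted shape at a predictor value
#'
#' `consensus + (x - x_mean) * beta`, with `x_mean` the pooled (grand) mean of
#' the predictor in the fitting sample.
#'
#' @param model A fitted `shape_regression`.
#' @param x Predictor value on the analysis scale.
#' @return A k x d shape matrix.
#' @export
predict_shape <- function(model, x) {
  stopifnot(inherits(model, "shape_regression"))
  model$consensus + (x - model$x_mean) * model$beta
}

#' Permutation test for a shape regression
#'
#' The test statistic is the predicted sum of squares of the pooled
#' within-stratum regression. The predictor is randomly permuted within strata
#' (preserving the dimorphism structure) and the p-value uses the add-one
#' convention `p = (1 + #permuted >= observed) / (n_perm + 1)`, so the
#' smallest attainable p is `1/(n_perm + 1)`. The superimposition is held
#' fixed across permutations.
#'
#' @inheritParams pooled_within_regression
#' @return A p-value in (0, 1\].
#' @export
permutation_test_regression <- function(fit, x, strata = NULL,
                                        n_perm = 5000L, seed = 1L) {
  Y <- if (inherits(fit, "gpa_fit")) shapes_matrix(fit) else as.matrix(fit)
  n <- nrow(Y)
  strata <- check_strata(strata, n)
  if (n_perm < 1L) stop("'n_perm' must be at least 1", call. = FALSE)
  cen <- stratum_center(Y, x, strata)
  pred_ss <- function(xc) {
    ssx <- sum(xc^2)
    if (ssx == 0) return(0)
    sum(crossprod(cen$Y, xc)^2) / ssx
  }
  observed <- pred_ss(cen$x)
  idx_by_stratum <- split(seq_len(n), strata)
  exceed <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_perm)) {
      xp <- cen$x
      for (idx in idx_by_stratum) xp[idx] <- xp[idx][sample.int(length(idx))]
      # within-stratum permutation preserves stratum means, so xp stays centered
      if (pred_ss(xp) >= observed) count <- count + 1L
    }
    count
  })
  (1 + exceed) / (n_perm + 1)
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean; the
#' unit-free variability measure used to compare predictor variability across
#' species with very different absolute sizes.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return A scalar.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero: CV undefined", call. = FALSE)
  sd(values) / m
}
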