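#' Mean-shape contrast between two groups
#'
#' Quantifies the average shape effect of a perturbation (e.g. a mutation) as
#' the difference between two group mean shapes in a *joint* superimposition
#' of all specimens: `effect_vector = mean(alt) - mean(ref)`, with magnitude
#' the Procrustes distance between the two means. Significance is assessed by
#' permuting the group labels of the two groups' specimens while holding the
#' superimposition fixed. The estimated distance is upward-biased by sampling
#' noise (a norm of a noisy vector); no bias correction is applied.
#'
#' @param fit A [gpa()] result from a joint superimposition that includes both
#'   groups (and possibly others, which are ignored).
#' @param groups Group label per specimen (character or factor).
#' @param ref,alt Names of the reference (e.g. wildtype) and alternative
#'   (e.g. mutant) groups.
#' @param n_perm Number of label permutations (default 5000); `0` skips the
#'   test.
#' @param seed Seed for the permutation stream.
#' @param predictor Optional numeric predictor (analysis scale) per specimen;
#'   when given, the difference of its group means is stored as
#'   `predictor_shift`.
#' @param predictor_raw Optional raw-scale measurement (e.g. brain volume in
#'   mm^3) per specimen; when given, `predictor_shift_pct` is the percent
#'   change of its group mean relative to the reference group.
#' @return An object of class `group_contrast` with fields `ref_group`,
#'   `alt_group`, `effect_vector` (k x d), `distance` (Procrustes units),
#'   `p_value`, `n_perm`, `seed`, `consensus`, `n_ref`, `n_alt`,
#'   `predictor_shift`, `predictor_shift_pct`.
#' @export
group_contrast <- function(fit, groups, ref, alt, n_perm = 5000L, seed = 1L,
                           predictor = NULL, predictor_raw = NULL) {
  stopifnot(inherits(fit, "gpa_fit"))
  Y <- shapes_matrix(fit)
  n <- nrow(Y)
  if (length(groups) != n)
    stop("'groups' must have one label per specimen", call. = FALSE)
  groups <- as.character(groups)
  for (g in c(ref, alt)) if (!g %in% groups)
    stop("group '", g, "' has no specimens", call. = FALSE)
  i_ref <- which(groups == ref)
  i_alt <- which(groups == alt)
  mean_of <- function(idx) colMeans(Y[idx, , drop = FALSE])
  eff <- mean_of(i_alt) - mean_of(i_ref)
  dist_obs <- sqrt(sum(eff^2))
  p <- NA_real_
  if (n_perm >= 1L) {
    pool <- c(i_ref, i_alt)
    n_ref <- length(i_ref)
    p <- with_seed(seed, {
      count <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample(pool)
        dperm <- sqrt(sum((mean_of(perm[-seq_len(n_ref)]) -
                           mean_of(perm[seq_len(n_ref)]))^2))
        if (dperm >= dist_obs) count <- count + 1L
      }
      (1 + count) / (n_perm + 1)
    })
  }
  shift <- shift_pct <- NA_real_
  if (!is.null(predictor)) {
    if (length(predictor) != n || anyNA(predictor[c(i_ref, i_alt)]))
      stop("'predictor' must be complete for both groups", call. = FALSE)
    shift <- mean(predictor[i_alt]) - mean(predictor[i_ref])
  }
  if (!is.null(predictor_raw)) {
    if (length(predictor_raw) != n || anyNA(predictor_raw[c(i_ref, i_alt)]))
      stop("'predictor_raw' must be complete for both groups", call. = FALSE)
    shift_pct <- 100 * (mean(predictor_raw[i_alt]) - mean(predictor_raw[i_ref])) /
      mean(predictor_raw[i_ref])
  }
  structure(list(ref_group = ref, alt_group = alt,
                 effect_vector = unflat(eff, fit$consensus),
                 distance = dist_obs,
                 p_value = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 consensus = fit$consensus,
                 n_ref = length(i_ref), n_alt = length(i_alt),
                 predictor_shift = shift,
                 predictor_shift_pct = shift_pct),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("Mean-shape contrast %s (n=%d) vs %s (n=%d): %.5g Procrustes units",
              x$alt_group, x$n_alt, x$ref_group, x$n_ref, x$distance))
  if (!is.na(x$p_value)) cat(sprintf(" (p = %.4g)", x$p_value))
  cat("\n")
  if (!is.na(x$predictor_shift))
    cat(sprintf("predictor shift: %.5g (analysis scale)", x$predictor_shift),
        if (!is.na(x$predictor_shift_pct))
          sprintf(", %.3g%% (raw scale)", x$predictor_shift_pct) else "",
        "\n", sep = "")
  invisible(x)
}

#' Group difference of a predictor
#'
#' On the `analysis` scale the shift is the difference of group means of the
#' (already transformed) predictor column; on the `percent` scale it is the
#' percent change of the group mean of the *raw* measurement relative to the
#' reference group.
#'
#' @param metadata A data.frame with a group column and the predictor column.
#' @param predictor Name of the predictor column to average. Pass the
#'   analysis-scale column (e.g. cube-root volume) with `scale = "analysis"`
#'   and the raw column (e.g. volume) with `scale = "percent"`.
#' @param ref,alt Group names.
#' @param scale `"analysis"` or `"percent"`.
#' @param group_col Name of the grouping column (default `"group"`).
#' @return A scalar.
#' @export
predictor_shift <- function(metadata, predictor, ref, alt,
                            scale = c("analysis", "percent"),
                            group_col = "group") {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(metadata))
  for (cn in c(predictor, group_col)) if (!cn %in% names(metadata))
    stop("column '", cn, "' not found in metadata", call. = FALSE)
  g <- as.character(metadata[[group_col]])
  v <- metadata[[predictor]]
  for (grp in c(ref, alt)) {
    if (!grp %in% g) stop("group '", grp, "' not present", call. = FALSE)
    if (anyNA(v[g == grp]))
      stop("missing '", predictor, "' values in group '", grp, "'",
           call. = FALSE)
  }
  m_ref <- mean(v[g == ref]); m_alt <- mean(v[g == alt])
  if (scale == "analysis") m_alt - m_ref else 100 * (m_alt - m_ref) / m_ref
}

#' Angle between two shape-change vectors
#'
#' Arc-cosine of the cosine between the flattened vectors, clamped to
#' \[-1, 1\], in degrees. Only meaningful for vectors expressed in the same
#' superimposition (or frames explicitly aligned first); cross-species angles
#' are not computed by this package because large mean-shape differences make
#' them uninterpretable.
#'
#' @param v1,v2 Nonzero shape vectors (k x d matrices or flat vectors).
#' @return Angle in degrees, in \[0, 180\].
#' @export
vector_angle <- function(v1, v2) {
  a <- flat(as.matrix(v1)); b <- flat(as.matrix(v2))
  if (length(a) != length(b)) stop("dimension mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero vector has no direction", call. = FALSE)
  a <- a / na; b <- b / nb
  # atan2 form: numerically exact near 0 and 180 degrees, unlike acos
  2 * atan2(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2))) * 180 / pi
}

#' Compare an observed group contrast with a regression prediction
#'
#' The funneling test: if a mutation acts on cranial shape only through the
#' developmental variable the regression models (brain size, chondrocranial
#' length, overall size), the shape change predicted from the
#' normal-population regression for the observed predictor shift should match
#' the observed mutant-wildtype Procrustes distance. A ratio well above 1
#' indicates pathways beyond the modeled variable (or partially cancelling
#' effects in the normal population).
#'
#' The model is typically fitted on a normal-population superimposition and
#' the contrast on a joint wildtype+mutant superimposition, so the two vectors
#' live in different tangent spaces. Before computing the angle they are
#' brought into a common frame: the regression vector is rotated by the
#' optimal rotation between the two consensus shapes (the identity when both
#' come from the same fit), and both vectors are then projected onto the
#' tangent hyperplane at the contrast's consensus. Without the projection the
#' angle would carry a spurious term of half the mean-shape shift, because
#' each vector is orthogonal to its own, slightly tilted, consensus.
#'
#' @param contrast A [group_contrast()] result with a non-`NA`
#'   `predictor_shift`.
#' @param model A [pooled_within_regression()] model for the same landmark
#'   set.
#' @return A list of class `funneling_comparison`: `observed` and `predicted`
#'   Procrustes distances, their `ratio` (observed/predicted), and
#'   `angle_deg` between the effect vector and the regression vector.
#' @export
funneling_comparison <- function(contrast, model) {
  stopifnot(inherits(contrast, "group_contrast"),
            inherits(model, "shape_regression"))
  if (is.na(contrast$predictor_shift))
    stop("contrast carries no predictor shift; refit group_contrast() with ",
         "'predictor'", call. = FALSE)
  if (sum(model$beta^2) == 0)
    stop("regression vector is zero", call. = FALSE)
  if (!all(dim(model$beta) == dim(contrast$effect_vector)))
    stop("model and contrast use different landmark sets", call. = FALSE)
  predicted <- predicted_shape_change(model, contrast$predictor_shift)
  R <- optimal_rotation(model$consensus, contrast$consensus)
  cvec <- flat(contrast$consensus)
  cvec <- cvec / sqrt(sum(cvec^2))
  in_tangent <- function(v) { v <- flat(v); v - sum(v * cvec) * cvec }
  structure(list(observed = contrast$distance,
                 predicted = predicted,
                 ratio = contrast$distance / predicted,
                 angle_deg = vector_angle(in_tangent(model$beta %*% R),
                                          in_tangent(contrast$effect_vector))),
            class = "funneling_comparison")
}

#' @export
print.funneling_comparison <- function(x, ...) {
  cat(sprintf(paste0("Funneling comparison: observed %.5g vs predicted %.5g",
                     " Procrustes units\nratio = %.4g, angle = %.2f deg\n"),
              x$observed, x$predicted, x$ratio, x$angle_deg))
  invisible(x)
}
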