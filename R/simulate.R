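#' Built-in 18-landmark half-cranium template
#'
#' A fixed 3D template of 18 named unilateral (left-side) cranial landmarks,
#' centered and scaled to unit centroid size. The landmark names are standard
#' craniometric points (including hormion and opisthocranion, whose distance
#' proxies chondrocranial length); the coordinates are plausible but arbitrary
#' constants fixed so that simulations are deterministic — they carry no
#' anatomical authority.
#'
#' @return An 18 x 3 matrix with landmark names as row names.
#' @export
cranial_template <- function() {
  m <- rbind(
    nasion         = c( 9.0, 0.0,  5.0),
    glabella       = c( 9.2, 0.0,  6.0),
    bregma         = c( 5.0, 0.0, 10.0),
    lambda         = c(-3.0, 0.0,  8.5),
    opisthocranion = c(-4.5, 0.0,  5.0),
    inion          = c(-4.0, 0.0,  4.0),
    euryon         = c( 0.0, 7.0,  6.0),
    porion         = c( 0.5, 6.0,  1.0),
    asterion       = c(-2.5, 5.0,  3.0),
    basion         = c(-1.0, 0.0,  0.0),
    opisthion      = c(-2.5, 0.0,  0.5),
    hormion        = c( 3.0, 0.0,  1.0),
    staphylion     = c( 4.0, 0.0,  0.5),
    alveolare      = c( 8.5, 0.0,  0.0),
    subspinale     = c( 8.8, 0.0,  1.5),
    zygoorbitale   = c( 7.0, 2.5,  4.0),
    frontomalare   = c( 7.5, 4.0,  5.5),
    zygomaxillare  = c( 6.5, 4.0,  2.0))
  colnames(m) <- c("x", "y", "z")
  m <- center_config(m)
  m / sqrt(sum(m^2))
}

#' Project a vector into the shape tangent space at a template
#'
#' Removes from `v` all components along the similarity-transform directions
#' at `template` — translations (column means), scaling (the template itself)
#' and infinitesimal rotations — and normalizes the remainder to unit norm.
#' Effect vectors used by the simulator must live in this space: variation
#' injected along translation/scale/rotation directions is, by construction,
#' removed again by Procrustes superimposition and could never be recovered by
#' the downstream analysis.
#'
#' @param template Centered k x d template shape (unit centroid size).
#' @param v A k x d matrix (or flat vector) to project.
#' @return A unit-norm k x d matrix in the tangent space.
#' @export
shape_tangent_vector <- function(template, v) {
  template <- as.matrix(template)
  k <- nrow(template); d <- ncol(template)
  v <- if (is.matrix(v)) v else unflat(as.numeric(v), template)
  if (!all(dim(v) == dim(template))) stop("dimension mismatch", call. = FALSE)
  v <- center_config(v)
  # basis of removed directions: uniform scaling + infinitesimal rotations
  gens <- list(flat(template))
  if (d == 2L) {
    A <- matrix(c(0, -1, 1, 0), 2L, 2L)
    gens <- c(gens, list(flat(template %*% A)))
  } else if (d == 3L) {
    skews <- list(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3L, 3L),
                  matrix(c(0, 0, -1, 0, 0, 0, 1, 0, 0), 3L, 3L),
                  matrix(c(0, 0, 0, 0, 0, -1, 0, 1, 0), 3L, 3L))
    gens <- c(gens, lapply(skews, function(A) flat(template %*% A)))
  }
  B <- qr.Q(qr(do.call(cbind, gens)))
  vv <- flat(v)
  vv <- vv - B %*% crossprod(B, vv)
  nv <- sqrt(sum(vv^2))
  if (nv < 1e-12)
    stop("vector lies entirely in the similarity directions", call. = FALSE)
  unflat(as.numeric(vv) / nv, template)
}

# Internal: deterministic pseudo-random unit tangent vector at a template.
default_tangent_vector <- function(template, seed) {
  v <- with_seed(seed, matrix(rnorm(length(template)), nrow(template)))
  shape_tangent_vector(template, v)
}

#' Specify a synthetic landmark population
#'
#' Defines the generative model the analysis assumes: tangent-space shapes
#' `template + sum_e slope_e * (x_e - mean_e) * V_e + sex_offset * I(female) +
#' noise`, with latent size predictors `x_e ~ N(mean_e, sd_e)`, isotropic
#' per-coordinate Gaussian landmark noise, and a per-specimen nuisance
#' similarity transform (rotation, translation, scale) producing the raw
#' coordinates. Effect vectors are projected into the shape tangent space at
#' the template (see [shape_tangent_vector()]) and stored unit-normalized; the
#' slope carries the magnitude.
#'
#' The defaults emulate a wildtype inbred mouse sample: n = 48 specimens, a
#' latent cube-root brain volume with mean 7.7 mm and SD 0.37 mm (coefficient
#' of variation 0.048), slope 0.017 Procrustes units per mm (so the predictor
#' explains a few percent of shape variance over the default noise), a sexual
#' dimorphism offset of 0.01 Procrustes units, per-coordinate noise SD 0.004,
#' and nuisance scale drawn uniformly from 44-56 mm (log-centroid-size CV near
#' 0.017) with free rotation and translation.
#'
#' @param n Number of specimens (>= 2).
#' @param effects List of effects, each a list with `name`, `slope`
#'   (Procrustes units per predictor unit), `mean` and `sd` of the latent
#'   predictor, and optionally `vector` (k x d, projected and normalized;
#'   a deterministic default is derived from the effect's position).
#' @param template k x d mean shape, centered at unit centroid size.
#' @param sex_offset k x d dimorphism vector added to females (`NULL` for
#'   none); projected into the tangent space, magnitude preserved.
#' @param sex_ratio Probability a specimen is female.
#' @param noise_sd Per-coordinate isotropic noise SD (Procrustes units).
#' @param nuisance List with `rotate` (logical), `translate_sd` (mm) and
#'   `scale_range` (length-2, mm) for the per-specimen similarity transform.
#' @param seed Mandatory integer seed; the generator derives one substream per
#'   specimen, so enlarging `n` preserves earlier specimens.
#' @return An object of class `simulation_spec`.
#' @seealso [simulate_population()], [simulate_mutant_pair()]
#' @export
simulation_spec <- function(n = 48L,
                            effects = list(list(name = "brain_size",
                                                slope = 0.017,
                                                mean = 7.7, sd = 0.37)),
                            template = cranial_template(),
                            sex_offset = 0.01 *
                              default_tangent_vector(template, 202L),
                            sex_ratio = 0.5,
                            noise_sd = 0.004,
                            nuisance = list(rotate = TRUE, translate_sd = 10,
                                            scale_range = c(44, 56)),
                            seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  bad <- character(0)
  if (!is.numeric(n) || n < 2L) bad <- c(bad, "n")
  if (!is.numeric(noise_sd) || noise_sd < 0) bad <- c(bad, "noise_sd")
  if (!is.numeric(sex_ratio) || sex_ratio < 0 || sex_ratio > 1)
    bad <- c(bad, "sex_ratio")
  if (!is.list(nuisance) ||
      !all(c("rotate", "translate_sd", "scale_range") %in% names(nuisance)) ||
      length(nuisance$scale_range) != 2L ||
      any(nuisance$scale_range <= 0)) bad <- c(bad, "nuisance")
  if (length(bad))
    stop("invalid simulation spec field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  template <- as.matrix(template)
  for (e in seq_along(effects)) {
    eff <- effects[[e]]
    if (!all(c("name", "slope", "mean", "sd") %in% names(eff)))
      stop("invalid simulation spec field(s): effects[[", e,
           "]] needs name, slope, mean, sd", call. = FALSE)
    if (eff$sd < 0)
      stop("invalid simulation spec field(s): effects[[", e, "]]$sd",
           call. = FALSE)
    if (is.null(eff$vector))
      eff$vector <- default_tangent_vector(template, 100L + e)
    eff$vector <- shape_tangent_vector(template, eff$vector)
    effects[[e]] <- eff
  }
  if (!is.null(sex_offset)) {
    mag <- sqrt(sum(as.matrix(sex_offset)^2))
    sex_offset <- if (mag > 0)
      mag * shape_tangent_vector(template, as.matrix(sex_offset)) else NULL
  }
  structure(list(n = as.integer(n), effects = effects, template = template,
                 sex_offset = sex_offset, sex_ratio = sex_ratio,
                 noise_sd = noise_sd, nuisance = nuisance,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Internal: substream seed for specimen i of block `block`, kept below 2^31.
substream_seed <- function(seed, i, block = 0L) {
  as.integer((as.numeric(seed) + block * 1000003 + i * 7919) %% 2147483629)
}

# Internal: simulate one specimen from its own RNG substream.
simulate_specimen <- function(spec, i, block = 0L, predictor_means = NULL) {
  with_seed(substream_seed(spec$seed, i, block), {
    shape <- spec$template
    xs <- numeric(length(spec$effects))
    for (e in seq_along(spec$effects)) {
      eff <- spec$effects[[e]]
      mu <- if (is.null(predictor_means)) eff$mean else predictor_means[e]
      xs[e] <- rnorm(1L, mu, eff$sd)
      # shape responds to deviations from the *population* mean, so a shifted
      # predictor mean displaces the group mean shape along the effect vector
      shape <- shape + eff$slope * (xs[e] - eff$mean) * eff$vector
    }
    sex <- if (runif(1L) < spec$sex_ratio) "F" else "M"
    if (sex == "F" && !is.null(spec$sex_offset))
      shape <- shape + spec$sex_offset
    if (spec$noise_sd > 0)
      shape <- shape + matrix(rnorm(length(shape), 0, spec$noise_sd),
                              nrow(shape))
    d <- ncol(shape)
    R <- diag(d)
    if (isTRUE(spec$nuisance$rotate)) {
      R <- qr.Q(qr(matrix(rnorm(d * d), d)))
      if (det(R) < 0) R[, 1L] <- -R[, 1L]
    }
    trans <- rnorm(d, 0, spec$nuisance$translate_sd)
    size <- runif(1L, spec$nuisance$scale_range[1L],
                  spec$nuisance$scale_range[2L])
    raw <- sweep(size * (shape %*% R), 2L, trans, "+")
    rownames(raw) <- rownames(spec$template)
    list(raw = raw, predictors = xs, sex = sex)
  })
}

# Internal: assemble specimens into a landmark_dataset.
assemble_dataset <- function(spec, specimens, ids, group_labels) {
  k <- nrow(spec$template); d <- ncol(spec$template)
  coords <- array(NA_real_, c(k, d, length(specimens)),
                  dimnames = list(rownames(spec$template),
                                  c("x", "y", "z")[seq_len(d)], ids))
  for (i in seq_along(specimens)) coords[, , i] <- specimens[[i]]$raw
  md <- data.frame(specimen_id = ids,
                   sex = vapply(specimens, function(s) s$sex, character(1)),
                   group = group_labels,
                   stringsAsFactors = FALSE)
  for (e in seq_along(spec$effects))
    md[[spec$effects[[e]]$name]] <-
      vapply(specimens, function(s) s$predictors[e], numeric(1))
  landmark_dataset(coords, md)
}

#' Simulate a landmark population
#'
#' Draws `spec$n` specimens from the generative model of a
#' [simulation_spec()]. Fully reproducible: the same spec (including seed)
#' yields bit-identical datasets, and increasing `n` appends specimens without
#' changing earlier ones.
#'
#' @param spec A `simulation_spec`.
#' @param group Group label written to the metadata (default `"wildtype"`).
#' @param id_prefix Prefix for generated specimen ids.
#' @return A [landmark_dataset()] whose metadata records sex, group and the
#'   true latent predictor value for every effect.
#' @export
simulate_population <- function(spec, group = "wildtype",
                                id_prefix = "sim") {
  stopifnot(inherits(spec, "simulation_spec"))
  specimens <- lapply(seq_len(spec$n), function(i) simulate_specimen(spec, i))
  ids <- sprintf("%s_%04d", id_prefix, seq_len(spec$n))
  assemble_dataset(spec, specimens, ids, rep(group, spec$n))
}

#' Simulate a wildtype/mutant strain pair
#'
#' The wildtype group is drawn exactly as [simulate_population()] would draw
#' it. The mutant group (an independent RNG substream) is perturbed in exactly
#' one of two ways: `predictor_shift` displaces the latent mean of one
#' effect's predictor, so the mutant mean shape moves along that effect vector
#' by `slope * shift`; or `displacement` adds a fixed k x d mean-shape offset
#' directly (projected into the tangent space, magnitude preserved).
#'
#' @param spec A `simulation_spec` (defines the wildtype).
#' @param predictor_shift Scalar shift of the latent predictor mean, on the
#'   analysis scale.
#' @param effect Name of the shifted effect (default: the spec's first).
#' @param displacement Direct k x d mean-shape displacement.
#' @param n_mutant Mutant sample size (default `spec$n`).
#' @return A [landmark_dataset()] with groups `wildtype` and `mutant`.
#' @export
simulate_mutant_pair <- function(spec, predictor_shift = NULL,
                                 effect = NULL, displacement = NULL,
                                 n_mutant = spec$n) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(predictor_shift) && !is.null(displacement))
    stop("specify either 'predictor_shift' or 'displacement', not both",
         call. = FALSE)
  wt <- lapply(seq_len(spec$n), function(i) simulate_specimen(spec, i))
  mut_spec <- spec
  means <- vapply(spec$effects, function(e) e$mean, numeric(1))
  if (!is.null(predictor_shift)) {
    if (is.null(effect)) effect <- spec$effects[[1L]]$name
    e_idx <- match(effect, vapply(spec$effects, `[[`, character(1), "name"))
    if (is.na(e_idx)) stop("unknown effect '", effect, "'", call. = FALSE)
    means[e_idx] <- means[e_idx] + predictor_shift
  }
  mut <- lapply(seq_len(n_mutant), function(i)
    simulate_specimen(mut_spec, i, block = 1L, predictor_means = means))
  if (!is.null(displacement)) {
    displacement <- as.matrix(displacement)
    mag <- sqrt(sum(displacement^2))
    if (mag > 0) {
      disp <- mag * shape_tangent_vector(spec$template, displacement)
      # re-apply each mutant's own nuisance transform to the displaced shape
      mut <- lapply(seq_len(n_mutant), function(i) {
        s <- mut[[i]]
        base <- simulate_specimen_shape_only(mut_spec, i, 1L, means)
        s$raw <- redo_nuisance(mut_spec, i, 1L, base + disp)
        s
      })
    }
  }
  ids <- c(sprintf("wt_%04d", seq_len(spec$n)),
           sprintf("mut_%04d", seq_len(n_mutant)))
  assemble_dataset(spec, c(wt, mut), ids,
                   c(rep("wildtype", spec$n), rep("mutant", n_mutant)))
}

# Internal: the tangent-space shape of a specimen before the nuisance
# transform (replays the substream draws in the same order).
simulate_specimen_shape_only <- function(spec, i, block, predictor_means) {
  with_seed(substream_seed(spec$seed, i, block), {
    shape <- spec$template
    for (e in seq_along(spec$effects)) {
      eff <- spec$effects[[e]]
      x <- rnorm(1L, predictor_means[e], eff$sd)
      shape <- shape + eff$slope * (x - eff$mean) * eff$vector
    }
    sex <- if (runif(1L) < spec$sex_ratio) "F" else "M"
    if (sex == "F" && !is.null(spec$sex_offset)) shape <- shape + spec$sex_offset
    if (spec$noise_sd > 0)
      shape <- shape + matrix(rnorm(length(shape), 0, spec$noise_sd),
                              nrow(shape))
    shape
  })
}

# Internal: replay a specimen's nuisance similarity transform on a new shape.
redo_nuisance <- function(spec, i, block, shape) {
  with_seed(substream_seed(spec$seed, i, block), {
    for (e in seq_along(spec$effects)) rnorm(1L)
    runif(1L)
    if (spec$noise_sd > 0) rnorm(length(shape))
    d <- ncol(shape)
    R <- diag(d)
    if (isTRUE(spec$nuisance$rotate)) {
      R <- qr.Q(qr(matrix(rnorm(d * d), d)))
      if (det(R) < 0) R[, 1L] <- -R[, 1L]
    }
    trans <- rnorm(d, 0, spec$nuisance$translate_sd)
    size <- runif(1L, spec$nuisance$scale_range[1L],
                  spec$nuisance$scale_range[2L])
    raw <- sweep(size * (shape %*% R), 2L, trans, "+")
    rownames(raw) <- rownames(spec$template)
    raw
  })
}

#' Measure size predictors on a landmark dataset
#'
#' Appends the two landmark-derived size predictors to the metadata:
#' `chondrocranial_length`, the hormion-opisthocranion interlandmark distance
#' measured on the raw (pre-superimposition) coordinates in mm; and
#' `overall_size`, the natural-log centroid size of the raw configuration.
#' Latent predictors recorded by the simulator (e.g. `brain_size`, already on
#' the cube-root scale) pass through untouched.
#'
#' @param dataset A [landmark_dataset()] whose landmarks include `hormion`
#'   and `opisthocranion`.
#' @return The dataset with the two columns appended to its metadata.
#' @export
measure_predictors <- function(dataset) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  nm <- landmark_names(dataset)
  missing_lm <- setdiff(c("hormion", "opisthocranion"), nm)
  if (length(missing_lm))
    stop("landmark(s) not present: ", paste(missing_lm, collapse = ", "),
         call. = FALSE)
  n <- n_specimens(dataset)
  chon <- numeric(n); ovl <- numeric(n)
  for (i in seq_len(n)) {
    cfg <- dataset$coords[, , i]
    chon[i] <- interlandmark_distance(cfg, "hormion", "opisthocranion")
    ovl[i] <- log(centroid_size(cfg))
  }
  dataset$metadata$chondrocranial_length <- chon
  dataset$metadata$overall_size <- ovl
  dataset
}
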