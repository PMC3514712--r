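# Wildtype/mutant pair displaced along a known tangent vector, noiseless,
# with amplitudes small enough that shape-space curvature is negligible.
noiseless_pair <- function(shift = 5e-4, sdx = 1e-4, slope = 0.01,
                           displacement = NULL, seed = 21) {
  V <- fixed_effect_vector()
  spec <- simulation_spec(
    n = 30, seed = seed, noise_sd = 0, sex_offset = NULL,
    effects = list(list(name = "p", slope = slope, mean = 0, sd = sdx,
                        vector = V)))
  pair <- if (is.null(displacement))
    simulate_mutant_pair(spec, predictor_shift = shift, n_mutant = 30)
  else simulate_mutant_pair(spec, displacement = displacement, n_mutant = 30)
  list(spec = spec, pair = pair, fit = gpa(pair), V = V, slope = slope)
}

test_that("a pure mean displacement is recovered as the contrast distance", {
  fx <- noiseless_pair(sdx = 0, displacement = 2e-4 * fixed_effect_vector())
  ct <- group_contrast(fx$fit, fx$pair$metadata$group, "wildtype", "mutant",
                       n_perm = 0)
  expect_lt(abs(ct$distance - 2e-4), 1e-10)
  expect_equal(ct$distance, sqrt(sum(ct$effect_vector^2)), tolerance = 1e-12)
})

test_that("a noiseless predictor shift moves the mean by slope * shift", {
  fx <- noiseless_pair()
  ct <- group_contrast(fx$fit, fx$pair$metadata$group, "wildtype", "mutant",
                       n_perm = 0, predictor = fx$pair$metadata$p)
  # the realized shift (recorded in the metadata) drives the realized means
  expect_equal(ct$distance, fx$slope * abs(ct$predictor_shift),
               tolerance = 1e-8)
})

test_that("swapping reference and alternative negates the effect vector", {
  fx <- noiseless_pair()
  g <- fx$pair$metadata$group
  a <- group_contrast(fx$fit, g, "wildtype", "mutant", n_perm = 0)
  b <- group_contrast(fx$fit, g, "mutant", "wildtype", n_perm = 0)
  expect_equal(a$effect_vector, -b$effect_vector, tolerance = 1e-14)
  expect_equal(a$distance, b$distance, tolerance = 1e-14)
})

test_that("identical duplicated groups give distance 0 and p = 1", {
  set.seed(19)
  ds <- random_small_dataset(n = 4, k = 5, d = 3)
  co <- ds$coords[, , c(1:4, 1:4)]
  dimnames(co)[[3]] <- paste0("s", 1:8)
  fit <- gpa(landmark_dataset(co))
  ct <- group_contrast(fit, rep(c("a", "b"), each = 4), "a", "b",
                       n_perm = 99, seed = 2)
  expect_lt(ct$distance, 1e-12)
  expect_equal(ct$p_value, 1)
  expect_error(group_contrast(fit, rep("a", 8), "a", "zz"), "no specimens")
})

test_that("contrast distance tracks a known mean shift within Monte Carlo error", {
  V <- fixed_effect_vector()
  delta <- 0.03
  spec <- simulation_spec(n = 50, seed = 55, noise_sd = 0.004,
                          sex_offset = NULL,
                          effects = list(list(name = "p", slope = 0.017,
                                              mean = 7.7, sd = 1e-6,
                                              vector = V)))
  dists <- vapply(1:12, function(r) {
    sp <- spec; sp$seed <- 55L + r
    pair <- simulate_mutant_pair(sp, displacement = delta * V, n_mutant = 50)
    group_contrast(gpa(pair), pair$metadata$group, "wildtype", "mutant",
                   n_perm = 0)$distance
  }, numeric(1))
  # norm of a noisy mean difference: upward-biased; bias + 3 MC SE band
  se <- sd(dists) / sqrt(length(dists))
  expect_lt(abs(mean(dists) - delta), 3 * se + (mean(dists^2) - delta^2) / delta)
  expect_gt(mean(dists), delta)  # the documented upward noise bias
})

test_that("contrast statistics ignore specimen order and common rotations", {
  fx <- noiseless_pair()
  g <- fx$pair$metadata$group
  ct <- group_contrast(fx$fit, g, "wildtype", "mutant", n_perm = 0)
  perm <- sample(length(g))
  co <- fx$pair$coords[, , perm]
  ds2 <- landmark_dataset(co, fx$pair$metadata[perm, ])
  ct2 <- group_contrast(gpa(ds2), g[perm], "wildtype", "mutant", n_perm = 0)
  expect_equal(ct2$distance, ct$distance, tolerance = 1e-8)
})

test_that("predictor shifts are group-mean differences on the right scale", {
  md <- data.frame(specimen_id = paste0("s", 1:4),
                   group = c("wt", "wt", "mut", "mut"),
                   volume = c(7.9, 8.1, 9.26, 9.46),
                   volume_cbrt = c(7.9, 8.1, 9.26, 9.46)^(1 / 3))
  expect_equal(predictor_shift(md, "volume", "wt", "mut", scale = "percent"),
               17)
  expect_equal(predictor_shift(md, "volume_cbrt", "wt", "mut"),
               mean(c(9.26, 9.46)^(1 / 3)) - mean(c(7.9, 8.1)^(1 / 3)))
  same <- md; same$group <- "wt"; same$volume <- 8
  same2 <- rbind(md, md); same2$group <- rep(c("wt", "mut"), each = 4)
  same2$volume <- rep(md$volume, 2)
  expect_equal(predictor_shift(same2, "volume", "wt", "mut"), 0)
  expect_equal(predictor_shift(same2, "volume", "wt", "mut", "percent"), 0)
  expect_error(predictor_shift(md, "nope", "wt", "mut"), "nope")
})

test_that("cube-root analysis-scale shift matches direct arithmetic", {
  md <- data.frame(specimen_id = c("a", "b"), group = c("wt", "mut"),
                   cbrt = c(8, 9.36)^(1 / 3))
  expect_equal(predictor_shift(md, "cbrt", "wt", "mut"),
               9.36^(1 / 3) - 8^(1 / 3), tolerance = 1e-12)
  expect_equal(9.36^(1 / 3) - 8^(1 / 3), 0.10746, tolerance = 1e-4)
})

test_that("vector angles hit the canonical values", {
  set.seed(20)
  v <- matrix(rnorm(12), 4, 3)
  expect_equal(vector_angle(v, v), 0)
  expect_equal(vector_angle(v, -v), 180)
  w <- matrix(rnorm(12), 4, 3)
  w <- w - sum(w * v) / sum(v * v) * v
  expect_equal(vector_angle(v, w), 90, tolerance = 1e-8)
  expect_error(vector_angle(v, 0 * v), "zero vector")
})

test_that("funneling ratio and angle are exact under the generative identity", {
  fx <- noiseless_pair()
  wt_idx <- fx$pair$metadata$group == "wildtype"
  wt <- landmark_dataset(fx$pair$coords[, , wt_idx],
                         fx$pair$metadata[wt_idx, ])
  model <- pooled_within_regression(gpa(wt), wt$metadata$p, n_perm = 0)
  ct <- group_contrast(fx$fit, fx$pair$metadata$group, "wildtype", "mutant",
                       n_perm = 0, predictor = fx$pair$metadata$p)
  fun <- funneling_comparison(ct, model)
  expect_equal(fun$ratio, 1, tolerance = 1e-8)
  expect_lt(fun$angle_deg, 1e-6)
  expect_equal(fun$predicted,
               predicted_shape_change(model, ct$predictor_shift))
})

test_that("mutants displaced orthogonally to the axis sit at 90 degrees", {
  V <- fixed_effect_vector()
  set.seed(22)
  W <- shape_tangent_vector(cranial_template(), matrix(rnorm(54), 18))
  W <- shape_tangent_vector(cranial_template(),
                            as.numeric(W) - sum(as.numeric(W) * as.numeric(V)) *
                              as.numeric(V))
  fx <- noiseless_pair(sdx = 0, displacement = 1e-3 * W)
  wt_idx <- fx$pair$metadata$group == "wildtype"
  # model from a population that *does* vary along V
  fx_var <- noiseless_pair()
  wt <- landmark_dataset(fx_var$pair$coords[, , wt_idx],
                         fx_var$pair$metadata[wt_idx, ])
  model <- pooled_within_regression(gpa(wt), wt$metadata$p, n_perm = 0)
  ct <- group_contrast(fx$fit, fx$pair$metadata$group, "wildtype", "mutant",
                       n_perm = 0, predictor = fx$pair$metadata$p)
  expect_equal(funneling_comparison(ct, model)$angle_deg, 90,
               tolerance = 1e-4)
})
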