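# A small noiseless population whose shapes vary linearly along a known
# tangent vector; amplitudes are kept small so shape-space curvature is far
# below the tolerances being asserted.
noiseless_fixture <- function(n = 30, seed = 21, sdx = 1e-4, slope = 0.01) {
  V <- fixed_effect_vector()
  spec <- simulation_spec(
    n = n, seed = seed, noise_sd = 0, sex_offset = NULL,
    effects = list(list(name = "p", slope = slope, mean = 0, sd = sdx,
                        vector = V)))
  ds <- simulate_population(spec)
  list(ds = ds, fit = gpa(ds), x = ds$metadata$p, V = V, slope = slope)
}

test_that("noiseless linear variation is recovered exactly", {
  fx <- noiseless_fixture()
  m <- pooled_within_regression(fx$fit, fx$x, n_perm = 0)
  beta_t <- to_template_frame(m$beta, m$consensus, cranial_template())
  expect_lt(sqrt(sum((beta_t - fx$slope * fx$V)^2)), 1e-8)
  expect_equal(m$percent_var, 100, tolerance = 1e-10)
  expect_equal(cor(m$scores, fx$x, method = "spearman"), 1)
})

test_that("an orthogonalized predictor yields a null regression", {
  set.seed(13)
  ds <- random_small_dataset(n = 10, k = 5, d = 3)
  fit <- gpa(ds)
  Y <- t(apply(fit$aligned, 3, as.numeric))
  Yc <- scale(Y, scale = FALSE)
  x <- rnorm(10)
  x <- x - mean(x)
  x <- x - Yc %*% solve(crossprod(Yc) + 1e-12 * diag(ncol(Yc)),
                        crossprod(Yc, x))  # project x off all coordinates
  x <- as.numeric(x)
  m <- pooled_within_regression(fit, x, n_perm = 0)
  expect_lt(sqrt(sum(m$beta^2)), 1e-8)
  expect_lt(m$percent_var, 1e-8)
})

test_that("beta, variance explained and scores match the per-coordinate
           least-squares oracle", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    ds <- random_small_dataset(n = n, k = sample(4:5, 1), d = sample(2:3, 1))
    fit <- gpa(ds)
    x <- rnorm(n)
    strata <- sample(c("F", "M"), n, replace = TRUE)
    while (min(table(strata)) < 2) strata <- sample(c("F", "M"), n, TRUE)
    m <- pooled_within_regression(fit, x, strata, n_perm = 0)
    orc <- oracle_pooled_ols(fit, x, strata)
    expect_equal(as.numeric(m$beta), orc$beta, tolerance = 1e-10)
    expect_equal(m$percent_var, orc$percent_var, tolerance = 1e-10)
    expect_equal(m$scores, orc$scores, tolerance = 1e-10)
  }
})

test_that("scores are projections: consensus scores 0, orthogonal shifts inert", {
  fx <- noiseless_fixture()
  m <- pooled_within_regression(fx$fit, fx$x, n_perm = 0)
  cons_row <- matrix(as.numeric(m$consensus), 1)
  Y <- t(apply(fx$fit$aligned, 3, as.numeric))
  expect_equal(regression_scores(cons_row, m), 0, tolerance = 1e-12)
  # adding a constant vector orthogonal to beta shifts no score
  b <- as.numeric(m$beta)
  set.seed(15)
  w <- rnorm(length(b))
  w <- w - sum(w * b) / sum(b * b) * b
  expect_lt(max(abs(regression_scores(Y + matrix(w, nrow(Y), length(b),
                                                 byrow = TRUE), m) -
                      regression_scores(Y, m))), 1e-10)
})

test_that("shape prediction is linear and inverts the generative model", {
  fx <- noiseless_fixture()
  m <- pooled_within_regression(fx$fit, fx$x, n_perm = 0)
  expect_equal(predict_shape(m, m$x_mean), m$consensus)
  a <- 0.3; b <- -1.2
  expect_equal(predict_shape(m, a) + predict_shape(m, b),
               2 * predict_shape(m, (a + b) / 2), tolerance = 1e-12)
  # noiseless data: predictions reproduce each specimen's aligned shape
  for (i in c(1, 10, 30))
    expect_lt(procrustes_distance(predict_shape(m, fx$x[i]),
                                  fx$fit$aligned[, , i]), 1e-9)
})

test_that("predicted shape change is |delta| * ||beta|| and self-consistent", {
  fx <- noiseless_fixture()
  m <- pooled_within_regression(fx$fit, fx$x, n_perm = 0)
  nb <- sqrt(sum(m$beta^2))
  expect_equal(predicted_shape_change(m, 0.2), 0.2 * nb)
  expect_identical(predicted_shape_change(m, 0), 0)
  for (x0 in c(-1, 0, 2.5))
    expect_equal(predicted_shape_change(m, 0.37),
                 procrustes_distance(predict_shape(m, x0),
                                     predict_shape(m, x0 + 0.37)),
                 tolerance = 1e-12)
})

test_that("permutation p-values are add-one, bounded, and seed-reproducible", {
  fx <- noiseless_fixture()
  p <- permutation_test_regression(fx$fit, fx$x, n_perm = 199, seed = 9)
  expect_equal(p, 1 / 200)  # perfect signal: observed is the unique maximum
  p2 <- permutation_test_regression(fx$fit, fx$x, n_perm = 199, seed = 9)
  expect_identical(p, p2)
  set.seed(16)
  ds <- random_small_dataset(n = 8, k = 4, d = 2)
  fit <- gpa(ds)
  for (s in 1:3) {
    pv <- permutation_test_regression(fit, rnorm(8), n_perm = 49, seed = s)
    expect_gt(pv, 0)
    expect_lte(pv, 1)
    expect_gte(pv, 1 / 50)
  }
})

test_that("estimated effect direction converges to truth with sample size", {
  V <- fixed_effect_vector()
  tpl <- cranial_template()
  angle_for_n <- function(n, r) {
    spec <- simulation_spec(n = n, seed = 4000 + r)
    ds <- simulate_population(spec)
    m <- pooled_within_regression(gpa(ds), ds$metadata$brain_size,
                                  strata = ds$metadata$sex, n_perm = 0)
    Vd <- spec$effects[[1]]$vector
    vector_angle(to_template_frame(m$beta, m$consensus, tpl), Vd)
  }
  med <- vapply(c(25, 100, 400), function(n)
    median(vapply(1:11, function(r) angle_for_n(n, r), numeric(1))),
    numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("degenerate regression inputs fail fast", {
  set.seed(17)
  ds <- random_small_dataset(n = 6, k = 4, d = 2)
  fit <- gpa(ds)
  expect_error(pooled_within_regression(fit, rep(1, 6), n_perm = 0),
               "zero pooled predictor variance")
  expect_error(pooled_within_regression(fit, rnorm(6),
                                        strata = c("a", rep("b", 5)),
                                        n_perm = 0),
               "fewer than 2")
  expect_error(pooled_within_regression(fit, rnorm(4), n_perm = 0),
               "one value per specimen")
})

test_that("coefficient of variation is sd/mean and scale-free", {
  expect_equal(coefficient_of_variation(c(2, 4)), sqrt(2) / 3)
  expect_identical(coefficient_of_variation(rep(3.7, 5)), 0)
  set.seed(18)
  v <- rexp(20) + 1
  expect_equal(coefficient_of_variation(17.3 * v),
               coefficient_of_variation(v), tolerance = 1e-12)
  expect_error(coefficient_of_variation(c(-1, 1)), "mean is zero")
  expect_error(coefficient_of_variation(3), "at least 2")
})
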