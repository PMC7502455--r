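test_that("nonnegative least squares clamps at the boundary and recovers exactly", {
  expect_equal(solve_linear_nonneg(diag(2), c(2, 3)), c(2, 3))
  expect_equal(solve_linear_nonneg(matrix(1, 2, 1), c(-1, -1)), 0)
  set.seed(71)
  A <- matrix(rnorm(100), 50, 2)
  x_true <- c(1.7, 0.4)
  expect_equal(solve_linear_nonneg(A, A %*% x_true), x_true, tolerance = 1e-10)
  expect_error(solve_linear_nonneg(matrix(0, 0, 0), numeric(0)), "empty")
})

test_that("all three norms calibrate to 0% on perfect fits and 100% at zero parameters", {
  set.seed(72)
  A1 <- matrix(rnorm(60), 30, 2); x <- c(2, 0.5); b1 <- A1 %*% x
  A2 <- matrix(rnorm(60), 30, 2); b2 <- A2 %*% x
  expect_equal(norm_l2(rbind(A1, A2), x, c(b1, b2)), 0)
  expect_equal(norm_pointwise(list(A1, A2), x, list(b1, b2)), 0)
  expect_equal(norm_l2(rbind(A1, A2), c(0, 0), c(b1, b2)), 100)
  expect_equal(norm_pointwise(list(A1, A2), c(0, 0), list(b1, b2)), 100)
  # scaling norm: model-generated data recovers beta = 1 and 0% error ...
  sc <- fit_parameter_scaling(list(A1), list(b1))
  expect_equal(sc$beta, 1)
  expect_lt(sc$error, 1e-10)
  # ... and zero x* scores exactly 100%
  expect_equal(norm_l2(rbind(A1, A2), c(0, 0), c(b1, b2)), 100)
})

test_that("L2 residuals satisfy the Pythagorean identity at the projection", {
  set.seed(73)
  A <- matrix(rnorm(120), 60, 2)
  # data = interior-feasible projection plus a residual orthogonal to col(A)
  r <- stats::residuals(stats::lm(rnorm(60) ~ A - 1))
  b <- as.numeric(A %*% c(2, 1) + r)
  x <- solve_linear_nonneg(A, b)
  expect_equal(x, c(2, 1), tolerance = 1e-8)
  e <- (norm_l2(A, x, b) / 100)^2 + sum((A %*% x)^2) / sum(b^2)
  expect_equal(e, 1, tolerance = 1e-10)
})

test_that("point-wise norm penalises small-amplitude mismatch harder than L2", {
  # two tests with identical waveform, data amplitudes 2 and 100; the model's
  # unit columns scale as 1 and 100, so the L2 solve matches the large test
  # and leaves the small one off by ~2x -- invisible to L2, glaring to the
  # point-wise norm
  t <- seq(0, 1, length.out = 50)
  shape <- sin(2 * pi * t)
  A1 <- matrix(shape, ncol = 1); b1 <- 2 * shape
  A2 <- matrix(100 * shape, ncol = 1); b2 <- 100 * shape
  x <- solve_linear_nonneg(rbind(A1, A2), c(b1, b2))
  l2 <- norm_l2(rbind(A1, A2), x, c(b1, b2))
  pw <- norm_pointwise(list(A1, A2), x, list(b1, b2))
  expect_gt(pw, 5 * l2)
})

test_that("parameter scaling recovers per-test amplitudes up to gauge", {
  set.seed(74)
  A1 <- matrix(rnorm(80), 40, 2)
  A2 <- matrix(rnorm(80), 40, 2)
  x1 <- c(4, 1); x2 <- x1 / 2            # test 1 twice as stiff as test 2
  sc <- fit_parameter_scaling(list(A1, A2), list(A1 %*% x1, A2 %*% x2))
  expect_lt(sc$error, 1e-8)
  expect_equal(sc$x_tests[, 1], x1, tolerance = 1e-6)
  expect_equal(sc$x_tests[, 2], x2, tolerance = 1e-6)
  expect_equal(mean(sc$beta), 1)         # reporting gauge
  expect_equal(sc$beta[2] / sc$beta[1], 2, tolerance = 1e-6)
})

test_that("scaling-norm error path is non-increasing and gauge invariant", {
  set.seed(75)
  A_blocks <- lapply(1:3, function(i) matrix(rnorm(60), 30, 2))
  x_i <- list(c(3, 1), c(1.5, 0.5), c(2, 0.7))
  b_blocks <- Map(function(A, x) A %*% x + 0.01 * rnorm(30), A_blocks, x_i)
  sc <- fit_parameter_scaling(A_blocks, b_blocks)
  expect_true(all(diff(sc$error_path) <= 1e-8 * sc$error_path[1]))
  expect_true(all(sc$beta > 0))
  expect_true(sc$converged)
  # jointly rescaling (x*, beta) is a pure gauge change: the absolute
  # per-test parameters returned must be insensitive to the data's own gauge
  b2 <- lapply(b_blocks, function(b) b)
  sc2 <- fit_parameter_scaling(A_blocks, b2)
  expect_equal(sc2$x_tests, sc$x_tests, tolerance = 1e-12)
  expect_error(fit_parameter_scaling(A_blocks, list(b_blocks[[1]],
                                                    rep(0, 30), b_blocks[[3]])),
               "all-zero")
})

test_that("scale equivariance: scaling one test's data scales its parameters", {
  set.seed(76)
  A_blocks <- lapply(1:2, function(i) matrix(rnorm(30), 30, 1))
  b_blocks <- lapply(A_blocks, function(A) A %*% 2 + 0.005 * rnorm(30))
  sc <- fit_parameter_scaling(A_blocks, b_blocks)
  k <- 3.7
  sck <- fit_parameter_scaling(A_blocks,
                               list(b_blocks[[1]] * k, b_blocks[[2]]))
  expect_equal(sck$x_tests[, 1], k * sc$x_tests[, 1], tolerance = 1e-6)
  expect_equal(sck$x_tests[, 2], sc$x_tests[, 2], tolerance = 1e-6)
})

test_that("for one test with exact data the scaling norm equals plain NNLS", {
  set.seed(77)
  A <- matrix(abs(rnorm(50)), 50, 2)
  x_true <- c(1.2, 0.8)
  b <- A %*% x_true
  sc <- fit_parameter_scaling(list(A), list(b))
  expect_equal(sc$x_tests[, 1], solve_linear_nonneg(A, b), tolerance = 1e-6)
})

test_that("sweep lands on the generating node for noise-free data", {
  p <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
  proto <- default_protocol(points_per_period = 64)[c(2, 4, 9), ]
  ds <- generate_dataset(p, proto, softening = "none", noise_sd = 0)
  for (nm in c("l2", "pointwise", "scaling")) {
    fit <- sweep_fit(ds, "vexp", nm, alpha_grid = c(0.15, 0.2, 0.25),
                     b_grid = c(1.2, 1.3, 1.4))
    expect_equal(fit$alpha, 0.2)
    expect_equal(fit$b, 1.3)
    expect_lt(fit$error, 0.1)
  }
})

test_that("the linear parameters are recovered along with the node", {
  p <- material_parameters("vmr", delta = 250, alpha = 0.25, C_lin = 120)
  proto <- default_protocol(points_per_period = 64)[c(4, 12), ]
  ds <- generate_dataset(p, proto, softening = "none", noise_sd = 0)
  fit <- sweep_fit(ds, "vmr", "l2", alpha_grid = c(0.2, 0.25, 0.3))
  expect_equal(fit$alpha, 0.25)
  expect_equal(unname(fit$x), c(120, 250), tolerance = 1e-6)
})

test_that("the error surface is flat in b at vanishing shear strain", {
  p <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
  proto <- default_protocol(points_per_period = 64)
  proto <- proto[proto$freq_hz == 1 & proto$cs_percent == 10, ][1, ]
  proto$shear_percent <- 0.1
  ds <- generate_dataset(p, proto, softening = "none", noise_sd = 0)
  fit <- sweep_fit(ds, "vexp", "l2", alpha_grid = 0.2, b_grid = c(1, 1.25, 1.5))
  # at 0.1% shear the nonlinear power is unidentifiable: every b fits the
  # data to well under 1e-3 percent
  expect_lt(max(fit$surface$error), 1e-3)
  expect_lt(diff(range(fit$surface$error)), 1e-3)
})

test_that("tidiers expose the fit in broom shapes", {
  p <- material_parameters("vexp", delta = 300, alpha = 0.2, b = 1.3)
  proto <- default_protocol(points_per_period = 64)[c(2, 4), ]
  ds <- generate_dataset(p, proto, softening = "none", noise_sd = 0)
  fit <- sweep_fit(ds, "vexp", "scaling", alpha_grid = c(0.2, 0.25),
                   b_grid = c(1.3))
  td <- tidy(fit)
  expect_true(all(c("alpha", "b", "delta_star", "beta", "delta") %in% td$term))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$alpha, 0.2)
  aug <- augment(fit)
  expect_true(all(c("torque", ".fitted") %in% names(aug)))
  expect_lt(max(abs(aug$torque - aug$.fitted)) / max(abs(aug$torque)), 1e-6)
  expect_s3_class(autoplot(fit), "ggplot")
})
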