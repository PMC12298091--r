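# B-spline basis, KAN layer, grid refinement, pooling, standardization,
# modality fusion.

test_that("B-spline basis is a local partition of unity on random grids", {
  set.seed(1)
  for (k in 1:10) {
    K <- sample(4:20, 1)
    degree <- sample(0:3, 1)
    if (K < degree + 1) K <- degree + 1
    rng <- sort(runif(2, -5, 5)); if (diff(rng) < 0.1) rng[2] <- rng[1] + 1
    x <- runif(100, rng[1], rng[2])
    B <- bspline_basis(x, K, degree, rng)
    expect_true(all(B >= 0))
    expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
    expect_true(all(rowSums(B > 1e-12) <= degree + 1))
  }
})

test_that("degree-0 basis is the cell indicator", {
  B <- bspline_basis(c(0.05, 0.55, 0.95), K = 10, degree = 0,
                     range = c(0, 1))
  expect_equal(B[1, ], c(1, rep(0, 9)))
  expect_equal(B[2, 6], 1)
  expect_equal(rowSums(B), rep(1, 3))
})

test_that("basis values match the splineDesign recursion oracle", {
  set.seed(2)
  K <- 12; degree <- 3; rng <- c(0, 1)
  kn <- iopscreen:::bspline_knots(K, degree, rng)
  x <- c(kn[(degree + 1):(K + 1)], runif(50))   # knots and random points
  x <- pmin(pmax(x, 0), 1)
  B <- bspline_basis(x, K, degree, rng)
  oracle <- splines::splineDesign(kn, x, ord = degree + 1)
  expect_lt(max(abs(B - oracle)), 1e-10)
})

test_that("basis derivative matches finite differences", {
  x <- seq(0.05, 0.95, by = 0.05)
  eps <- 1e-7
  D <- bspline_basis_deriv(x, 16, 3, c(0, 1))
  fd <- (bspline_basis(x + eps, 16, 3, c(0, 1)) -
           bspline_basis(x - eps, 16, 3, c(0, 1))) / (2 * eps)
  expect_lt(max(abs(D - fd)), 1e-5)
})

test_that("KAN output is linear in the outer weights", {
  layer <- kan_layer(3, 2, K = 8, range = c(0, 1), seed = 3)
  X <- matrix(runif(15), 5, 3)
  base <- kan_forward(layer, X)
  scaled <- layer
  scaled$params$lambda <- layer$params$lambda * 2.5
  expect_equal(kan_forward(scaled, X), base * 2.5, tolerance = 1e-12)
})

test_that("spline coefficients fitted to the identity reproduce it", {
  x <- seq(0, 1, length.out = 200)
  alpha <- bspline_fit(x, x, K = 16, degree = 3, range = c(0, 1))
  layer <- kan_layer(1, 1, K = 16, degree = 3, range = c(0, 1))
  layer$params$alpha.1 <- matrix(alpha, ncol = 1)
  layer$params$lambda[] <- 1
  xs <- runif(50)
  expect_equal(as.numeric(kan_forward(layer, matrix(xs, ncol = 1))), xs,
               tolerance = 1e-6)
})

test_that("a trained KAN recovers a smooth univariate function", {
  set.seed(4)
  x <- runif(300)
  y <- 4 * x * (1 - x)
  fit <- kan_fit_univariate(x, y, K = 16, steps = 200, lr = 0.05, seed = 5)
  xg <- seq(0.01, 0.99, length.out = 101)
  pred <- as.numeric(kan_forward(fit$layer, matrix(xg, ncol = 1)))
  rmse <- sqrt(mean((pred - 4 * xg * (1 - xg))^2))
  expect_lt(rmse, 0.05)
})

test_that("knot budgets are conserved and follow image gradients", {
  flat <- matrix(0.5, 32, 32)
  rf <- refine_grid(flat, budget = 64, regions = c(4, 4))
  expect_identical(sum(rf$allocation), 64L)
  expect_true(all(rf$allocation == 4L))   # uniform under zero gradient
  # single vertical step edge: the edge column's regions get the maximum
  step <- cbind(matrix(0, 32, 12), matrix(1, 32, 20))
  rs <- refine_grid(step, budget = 100, regions = c(4, 4))
  expect_identical(sum(rs$allocation), 100L)
  edge_region_col <- ceiling(12 / (32 / 4))   # region column containing the edge
  expect_true(all(rs$allocation[, edge_region_col] ==
                    max(rs$allocation)))
  # monotone in regional gradient
  ord <- order(as.numeric(rs$gradient))
  expect_true(all(diff(as.numeric(rs$allocation)[ord]) >= 0))
  expect_error(refine_grid(flat, budget = 3, regions = c(4, 4)), "budget")
})

test_that("global average pooling is the arithmetic mean and linear", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_identical(gap_pool(m), 2.5)
  expect_identical(gap_pool(matrix(7, 5, 9)), 7)
  a <- matrix(runif(16), 4, 4); b <- matrix(runif(16), 4, 4)
  expect_equal(gap_pool(a + b), gap_pool(a) + gap_pool(b))
  arr <- array(runif(24), dim = c(2, 3, 4))
  expect_equal(gap_pool(arr), apply(arr, 3, mean))
})

test_that("clinical standardization is exact and guarded", {
  coh <- fix_cohort(60)
  std <- clinical_standardizer(coh$table)
  Z <- standardize_clinical(coh$table, std$mu, std$sigma)
  expect_lt(max(abs(colMeans(Z))), 1e-6)
  expect_lt(max(abs(apply(Z, 2, sd) - 1)), 1e-6)
  expect_equal(as.numeric(standardize_clinical(std$mu, std$mu, std$sigma)),
               rep(0, 6))
  bad <- std$sigma; bad["corneal_volume"] <- 0
  expect_error(standardize_clinical(coh$table, std$mu, bad),
               "corneal_volume")
})

test_that("modality fusion is convex and responsive to both weights", {
  v <- matrix(runif(12), 3, 4)
  expect_equal(fuse_modalities(v, matrix(0, 3, 4), c(1, 0)), v)
  expect_equal(fuse_modalities(v, v, c(0.5, 0.5)), v)
  expect_error(fuse_modalities(v, matrix(0, 3, 5), c(0.5, 0.5)), "width")
  # numeric gradient of a loss wrt both raw weights is nonzero
  set.seed(6)
  f <- matrix(runif(12), 3, 4); g <- matrix(runif(12), 3, 4)
  loss_at <- function(raw) {
    fused <- fuse_modalities(f, g, matrix(raw, 1, 2))
    mean((ad_value(fused) - 0.2)^2)
  }
  eps <- 1e-6
  for (k in 1:2) {
    d <- c(0, 0); d[k] <- eps
    grad_k <- (loss_at(c(0.3, -0.1) + d) - loss_at(c(0.3, -0.1) - d)) /
      (2 * eps)
    expect_gt(abs(grad_k), 1e-8)
  }
})

test_that("modality weights stay on the simplex throughout training", {
  set.seed(7)
  n <- 60
  Ximg <- matrix(rnorm(n * 5), n, 5)
  Xcl <- matrix(rnorm(n * 6), n, 6)
  y <- 1L + as.integer(Ximg[, 1] + Xcl[, 2] > 0)
  head <- fusion_head(5, 6, width = 4, K = 8, seed = 8)
  for (ep in 1:5) {
    fit <- train_fusion(head, Ximg, Xcl, y, epochs = 1, seed = 8 + ep)
    head <- fit$head
    w <- modality_weights(head)
    expect_true(all(w >= 0))
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})
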