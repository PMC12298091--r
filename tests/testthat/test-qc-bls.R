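# Broad Learning System quality monitor and geometric integrity screening.

test_that("node mapping follows the sigmoid chain", {
  m <- bls_model(3, m = 2, p = 1, seed = 1)
  # zero weights/biases -> all nodes 0.5
  m0 <- m
  m0$Wf[] <- 0; m0$bf[] <- 0; m0$We[] <- 0; m0$be[] <- 0
  Z <- bls_map_features(m0, matrix(rnorm(6), 2, 3))$Z
  expect_equal(as.numeric(Z), rep(0.5, 6))
  # hand-set weights match a hand-computed chain
  m$Wf <- matrix(c(1, 0, -1, 0.5, 0.5, 0.5), 3, 2)
  m$bf <- c(0.1, -0.2)
  m$We <- matrix(c(1, -1), 2, 1)
  m$be <- 0.3
  x <- c(0.2, -0.4, 0.6)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(as.numeric(x %*% m$Wf) + m$bf)
  e <- sig(sum(h * m$We) + m$be)
  got <- bls_map_features(m, matrix(x, 1, 3))
  expect_equal(as.numeric(got$H), h, tolerance = 1e-12)
  expect_equal(as.numeric(got$E), e, tolerance = 1e-12)
  # bounded in (0, 1)
  Zr <- bls_map_features(m, matrix(rnorm(30), 10, 3))$Z
  expect_true(all(Zr > 0 & Zr < 1))
  expect_error(bls_map_features(m, matrix(0, 2, 5)), "dimension")
})

test_that("ridge solutions match an independent normal-equation oracle", {
  set.seed(2)
  for (k in 1:5) {
    Z <- matrix(rnorm(50 * 30), 50, 30)
    y <- rnorm(50)
    got <- ridge_solve(Z, y, 0.1)
    oracle <- solve(t(Z) %*% Z + 0.1 * diag(30), t(Z) %*% y)
    expect_lt(max(abs(got - oracle)), 1e-8)
  }
})

test_that("lambda = 0 interpolates square systems and huge lambda shrinks", {
  set.seed(3)
  Z <- matrix(rnorm(64), 8, 8) + diag(8)
  y <- rnorm(8)
  b0 <- ridge_solve(Z, y, 0)
  expect_equal(as.numeric(Z %*% b0), y, tolerance = 1e-6)
  bL <- ridge_solve(Z, y, 1e9)
  expect_lt(sqrt(sum(bL^2)), 1e-6 * sqrt(sum(b0^2)))
})

test_that("rank-deficient lambda = 0 designs fall back to the pseudoinverse", {
  Z <- cbind(1:6, (1:6) * 2)   # rank 1
  y <- rnorm(6)
  b <- ridge_solve(Z, y, 0)
  expect_true(all(is.finite(b)))
  # minimum-norm solution reproduces the projection of y
  expect_equal(as.numeric(Z %*% b), as.numeric(Z %*% MASS::ginv(Z) %*% y),
               tolerance = 1e-8)
})

test_that("incremental enhancement nodes equal a full refit", {
  set.seed(4)
  X <- matrix(runif(200 * 40), 200, 40)
  y <- runif(200)
  m <- bls_model(40, m = 30, p = 20, lambda = 1e-2, seed = 5)
  m <- bls_fit(m, X, y)
  mse0 <- mean((bls_map_features(m, X)$Z %*% m$beta - y)^2)
  # delta_p = 0 leaves the model unchanged
  expect_identical(add_enhancement_nodes(m, 0L), m)
  m2 <- add_enhancement_nodes(m, 50L, seed = 6)
  expect_identical(m2$p, 70)
  # oracle: rebuild the widened model from scratch with identical nodes
  full <- m
  full$We <- m2$We; full$be <- m2$be; full$p <- m2$p
  full <- bls_fit(full, X, y)
  expect_lt(max(abs(m2$beta - full$beta)), 1e-6)
  mse2 <- mean((bls_map_features(m2, X)$Z %*% m2$beta - y)^2)
  expect_lte(mse2, mse0 + 1e-10)
})

test_that("quality classification is boundary-inclusive at T", {
  expect_true(classify_quality(0.71, 0.7))
  expect_true(classify_quality(0.70, 0.7))
  expect_false(classify_quality(0.69, 0.7))
  # raising T never converts a rejection into an acceptance
  scores <- runif(100)
  for (T1 in c(0.3, 0.5, 0.7)) {
    lo <- classify_quality(scores, T1)
    hi <- classify_quality(scores, T1 + 0.1)
    expect_true(all(lo | !hi))
  }
})

test_that("quality targets are monotone in corruption and scoring works", {
  qs <- fix_qc_set(n = 80)
  clean_t <- quality_target(qs$references[[1]], qs$references[[1]], 0)
  expect_equal(clean_t, 1)
  t_corr <- quality_target(qs$images[[2]], qs$references[[2]],
                           qs$magnitudes[2])
  expect_lt(t_corr, clean_t)
  model <- bls_quality_fit(qs$images, qs$references, qs$magnitudes,
                           m = 60, p = 30, seed = 3)
  s1 <- bls_score(model, qs$images[1:10], qs$references[1:10])
  s2 <- bls_score(model, qs$images[1:10], qs$references[1:10])
  expect_identical(s1, s2)   # deterministic given fixed model
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_error(bls_score(bls_model(10, m = 2, p = 1), qs$images[1:2],
                         qs$references[1:2]), "not fitted")
})

test_that("a training pair reproduced exactly interpolates its target", {
  set.seed(8)
  imgs <- lapply(1:12, function(i) matrix(runif(64), 8, 8))
  refs <- lapply(1:12, function(i) matrix(runif(64), 8, 8))
  y <- mapply(quality_target, imgs, refs, 0)
  X <- quality_features(imgs, refs, size = 8)
  m <- bls_model(64, m = 40, p = 0, lambda = 0, seed = 9)
  m <- bls_fit(m, X, y)
  pred <- bls_score(m, X)
  expect_equal(pred, pmin(pmax(y, 0), 1), tolerance = 1e-6)
})

test_that("integrity screening flags the published failure modes", {
  ph <- fix_phantom()
  expect_no_flags(ph$image)
  gap <- inject_artifact(ph$image, list(kind = "edge_discontinuity",
                                        magnitude = 0.5), seed = 2)
  expect_true("edge_discontinuity" %in% edge_integrity_check(gap)$flags)
  sat <- inject_artifact(ph$image, list(kind = "bright_region",
                                        magnitude = 0.8), seed = 2)
  expect_true("saturated_region" %in% edge_integrity_check(sat)$flags)
  blank <- matrix(0, 64, 64)
  expect_identical(edge_integrity_check(blank)$flags, "missing_contour")
})
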