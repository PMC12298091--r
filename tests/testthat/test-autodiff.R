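# Reverse-mode core: every operation's gradient is checked against central
# finite differences on random inputs.

fd_check <- function(build_loss, params, tol = 1e-5) {
  leaves <- lapply(params, ad_leaf)
  loss <- build_loss(leaves)
  ad_backward(loss)
  for (nm in names(params)) {
    g <- leaves[[nm]]$grad
    expect_false(is.null(g), info = nm)
    p <- params[[nm]]
    for (i in sample(length(p), min(3L, length(p)))) {
      eps <- 1e-6 * max(1, abs(p[i]))
      pp <- params; pp[[nm]][i] <- p[i] + eps
      lp <- ad_value(build_loss(pp))
      pm <- params; pm[[nm]][i] <- p[i] - eps
      lm <- ad_value(build_loss(pm))
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(g[i] - fd) / max(abs(fd), 1e-6), tol)
    }
  }
}

test_that("gradients of matrix ops match finite differences", {
  set.seed(1)
  params <- list(W = matrix(rnorm(12), 4, 3), b = matrix(rnorm(3), 1, 3),
                 V = matrix(rnorm(9), 3, 3))
  X <- matrix(rnorm(20), 5, 4)
  fd_check(function(P) {
    h <- ad_tanh(ad_add(ad_mm(X, P$W), P$b))
    o <- ad_sigmoid(ad_mm(h, P$V))
    ad_mean(ad_square(ad_sub(o, 0.3)))
  }, params)
})

test_that("gradients of attention-style ops match finite differences", {
  set.seed(2)
  params <- list(Q = matrix(rnorm(24), 8, 3), g = rep(1, 8), b = rep(0, 8))
  X <- matrix(rnorm(64), 8, 8)
  mask <- matrix(0, 8, 8); mask[1:4, 5:8] <- -Inf; mask[5:8, 1:4] <- -Inf
  fd_check(function(P) {
    h <- ad_layernorm(X, P$g, P$b)
    q <- ad_mm(h, P$Q)
    s <- ad_scale(ad_mm(q, ad_transpose(q)), 1 / sqrt(3))
    a <- ad_softmax_rows(s, mask)
    ad_mean(ad_square(ad_mm(a, q)))
  }, params, tol = 1e-4)
})

test_that("gradients of structural ops match finite differences", {
  set.seed(3)
  params <- list(A = matrix(rnorm(12), 6, 2), B = matrix(rnorm(12), 6, 2))
  idx <- c(1L, 3L, 3L, 5L, 6L)
  fd_check(function(P) {
    g1 <- ad_rows(ad_pad_zero_row(P$A), c(idx, 7L))
    g2 <- ad_cbind(list(g1, ad_rows(P$B, c(2L, 2L, 4L, 1L, 6L, 5L))))
    ad_mean(ad_abs(ad_relu(g2)))
  }, params, tol = 1e-4)
})

test_that("cross-entropy and gelu gradients match finite differences", {
  set.seed(4)
  params <- list(W = matrix(rnorm(6), 3, 2))
  X <- matrix(rnorm(12), 4, 3)
  y <- c(1L, 2L, 1L, 2L)
  fd_check(function(P) {
    ad_ce_logits(ad_gelu(ad_mm(X, P$W)), y)
  }, params)
})

test_that("softmax rows are probability distributions", {
  set.seed(5)
  s <- matrix(rnorm(30), 5, 6)
  p <- ad_softmax_rows(s)
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  mask <- matrix(0, 5, 6); mask[, 4:6] <- -Inf
  pm <- ad_softmax_rows(s, mask)
  expect_equal(rowSums(pm), rep(1, 5), tolerance = 1e-12)
  expect_true(all(pm[, 4:6] == 0))
})

test_that("AdamW skips frozen parameters and updates the rest", {
  params <- list(a.W = matrix(1, 2, 2), b.W = matrix(1, 2, 2))
  grads <- list(a.W = matrix(1, 2, 2), b.W = matrix(1, 2, 2))
  st <- adamw_init(params)
  out <- adamw_step(params, grads, st, lr = 0.1, frozen = "a")
  expect_identical(out$params$a.W, params$a.W)
  expect_false(identical(out$params$b.W, params$b.W))
})
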