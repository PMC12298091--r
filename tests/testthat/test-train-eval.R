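# Loss/schedule utilities, splitting, metrics, cross-validation, baselines,
# correlation analysis.

test_that("L1-regularized total loss matches its closed form", {
  expect_identical(total_loss(1.7, c(1, -2, 3), 0), 1.7)
  expect_identical(total_loss(1.7, c(0, 0), 0.5), 1.7)
  expect_identical(total_loss(1.0, c(1, -2, 3), 0.5), 4.0)
})

test_that("dynamic dropout decays hyperbolically", {
  expect_identical(dropout_schedule(0.5, 0.1, 0), 0.5)
  expect_identical(dropout_schedule(0.5, 0.1, 10), 0.25)
  expect_identical(dropout_schedule(0.3, 0, 100), 0.3)
  p <- dropout_schedule(0.5, 0.2, 0:20)
  expect_true(all(diff(p) < 0))
})

test_that("patient-grouped 8:1:1 split reproduces the published arithmetic", {
  labels <- rep(c("normal", "high"), c(680, 100))
  plan <- split_dataset(labels, patient_ids = seq_along(labels), seed = 1)
  expect_length(plan$train, 624L)
  expect_length(plan$validation, 78L)
  expect_length(plan$test, 78L)
  # stratification: per-split high fraction within one sample of 100/780
  for (s in c("train", "validation", "test")) {
    n_high <- sum(labels[plan[[s]]] == "high")
    expect_lt(abs(n_high - length(plan[[s]]) * 100 / 780), 1 + 1e-9)
  }
  # disjoint and exhaustive
  all_idx <- sort(c(plan$train, plan$validation, plan$test))
  expect_identical(all_idx, seq_along(labels))
})

test_that("no patient is split across subsets", {
  set.seed(2)
  n <- 300
  labels <- sample(c("normal", "high"), n, replace = TRUE, prob = c(.85, .15))
  patients <- sample(1:120, n, replace = TRUE)
  plan <- split_dataset(labels, patients, seed = 3)
  member <- rep(NA_character_, n)
  for (s in c("train", "validation", "test")) member[plan[[s]]] <- s
  for (p in unique(patients)) {
    expect_length(unique(member[patients == p]), 1L)
  }
  # determinism
  plan2 <- split_dataset(labels, patients, seed = 3)
  expect_identical(plan[1:3], plan2[1:3])
})

test_that("metric formulas agree with a brute-force counting oracle", {
  brute <- function(yt, yp) {
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (i in seq_along(yt)) {
      if (yt[i] == 2 && yp[i] == 2) tp <- tp + 1
      if (yt[i] == 1 && yp[i] == 1) tn <- tn + 1
      if (yt[i] == 1 && yp[i] == 2) fp <- fp + 1
      if (yt[i] == 2 && yp[i] == 1) fn <- fn + 1
    }
    pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rc <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    sp <- if (tn + fp == 0) 0 else tn / (tn + fp)
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    list(tp, tn, fp, fn, (tp + tn) / length(yt), pr, rc, f1, sp, mcc)
  }
  set.seed(4)
  for (k in 1:200) {
    n <- sample(2:40, 1)
    yt <- sample(1:2, n, replace = TRUE)
    yp <- sample(1:2, n, replace = TRUE)
    m <- compute_metrics(yt, yp, positive = 2)
    o <- brute(yt, yp)
    expect_equal(unname(unlist(m[c("TP", "TN", "FP", "FN", "accuracy",
                                   "precision", "recall", "f1",
                                   "specificity", "mcc")])),
                 unname(unlist(o)), tolerance = 1e-12)
  }
})

test_that("MCC is 1 on perfect predictions and ~0 on independent ones", {
  yt <- rep(1:2, 50)
  expect_identical(compute_metrics(yt, yt, positive = 2)$mcc, 1)
  expect_identical(compute_metrics(rep(c(1, 1, 2, 2), 25),
                                   rep(c(2, 1, 2, 1), 25),
                                   positive = 2)$mcc, 0)
  set.seed(5)
  n <- 10000
  yt <- sample(1:2, n, replace = TRUE)
  yp <- sample(1:2, n, replace = TRUE)
  expect_lt(abs(compute_metrics(yt, yp, positive = 2)$mcc), 0.05)
  expect_error(compute_metrics(integer(0), integer(0)), "empty")
})

test_that("Pearson correlation obeys its contracts", {
  x <- rnorm(20)
  expect_equal(pearson_corr(x, x), 1)
  expect_equal(pearson_corr(x, -x), -1)
  expect_error(pearson_corr(x, rep(1, 20)), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), "at least 3")
})

test_that("stratified folds partition the data deterministically", {
  set.seed(6)
  y <- sample(c("a", "b"), 100, replace = TRUE, prob = c(0.8, 0.2))
  f1 <- stratified_folds(y, k = 5, seed = 7)
  f2 <- stratified_folds(y, k = 5, seed = 7)
  expect_identical(f1, f2)
  expect_identical(sort(unique(f1)), 1:5)
  for (k in 1:5) {
    expect_true(all(c("a", "b") %in% y[f1 == k]))
  }
  expect_error(stratified_folds(rep(c("a", "b"), c(98, 2)), k = 5),
               "fewer samples")
})

test_that("median reporting follows the median definition", {
  accs <- c(0.6, 0.7, 0.8, 0.9, 1.0)
  expect_identical(stats::median(accs), 0.8)
})

test_that("baselines solve separable problems and are null-calibrated", {
  # linearly separable synthetic table
  set.seed(8)
  n <- 120
  tab <- data.frame(
    pupil_center_thickness = c(rnorm(n / 2, 0), rnorm(n / 2, 20)),
    corneal_vertex_thickness = rnorm(n),
    corneal_volume = abs(rnorm(n)) + 1,
    anterior_chamber_depth = rnorm(n),
    anterior_chamber_volume = rnorm(n),
    corneal_diameter = rnorm(n)
  )
  labels <- rep(c("normal", "high"), each = n / 2)
  res <- fit_baselines(tab, labels, seed = 9)
  for (nm in c("svm", "rf", "lr")) {
    expect_gte(res[[nm]]$median["accuracy"], 0.99)
  }
  expect_error(fit_baselines(tab, rep("normal", n)), "both classes")
})

test_that("label-shuffled baselines have near-zero MCC", {
  set.seed(10)
  n <- 2000
  tab <- data.frame(
    pupil_center_thickness = rnorm(n), corneal_vertex_thickness = rnorm(n),
    corneal_volume = abs(rnorm(n)) + 1, anterior_chamber_depth = rnorm(n),
    anterior_chamber_volume = rnorm(n), corneal_diameter = rnorm(n)
  )
  labels <- sample(rep(c("normal", "high"), c(1700, 300)))
  res <- fit_baselines(tab, labels, seed = 11)
  for (nm in c("svm", "rf", "lr")) {
    expect_lt(abs(res[[nm]]$median["mcc"]), 0.1)
  }
})

test_that("early stopping fires only after a flat validation plateau", {
  set.seed(12)
  n <- 80
  Ximg <- matrix(rnorm(n * 4), n, 4)
  y <- 1L + as.integer(Ximg[, 1] > 0)
  head <- fusion_head(4, 0, width = 4, K = 8, seed = 13)
  fit <- train_fusion(head, Ximg, NULL, y,
                      val = list(X_img = Ximg, X_clin = NULL, y = y),
                      epochs = 60, patience = 5, seed = 14)
  # separable task: validation accuracy saturates at 1, then patience stops
  expect_lt(fit$epochs_run, 60L)
  va <- fit$history$val_acc
  best_before_stop <- cummax(va)
  last <- length(va)
  expect_equal(va[last - 0:4], rep(max(va), 5), tolerance = 1e-9)
})
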