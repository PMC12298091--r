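# Grad-CAM heatmaps and quantitative attribution.

test_that("heatmaps are non-negative, max-normalized and image-shaped", {
  cfg <- backbone_config(tiny_preset = TRUE)
  mdl <- build_backbone(cfg, seed = 1)
  img <- fix_phantom()$image
  for (stage in c(2, 3)) {
    hm <- grad_cam(mdl, img, target_class = 2, stage = stage)
    expect_identical(dim(hm$map), dim(img))
    expect_true(all(hm$map >= 0))
    expect_true(max(hm$map) == 1 || all(hm$map == 0))
  }
  auto <- grad_cam(mdl, img)
  expect_equal(auto$stage, 2)   # deepest stage with grid side >= 7
})

test_that("a zero-gradient head yields an all-zero heatmap", {
  cfg <- backbone_config(tiny_preset = TRUE)
  mdl <- build_backbone(cfg, seed = 2)
  mdl$params$head.W[] <- 0   # class score constant -> zero gradients
  hm <- grad_cam(mdl, fix_phantom()$image, target_class = 2, stage = 2)
  expect_true(all(hm$map == 0))
})

test_that("attribution fractions are scale-invariant and bounded", {
  h <- matrix(runif(64 * 64), 64, 64)
  mask <- matrix(FALSE, 64, 64); mask[10:30, ] <- TRUE
  fr <- attribution_report(h, list(band = mask))
  fr2 <- attribution_report(h * 7.3, list(band = mask))
  expect_equal(fr, fr2, tolerance = 1e-12)
  expect_true(fr[1, 1] >= 0 && fr[1, 1] <= 1)
  # whole-image mask captures all mass; zero heatmap yields zero fractions
  full <- attribution_report(h, list(all = matrix(TRUE, 64, 64)))
  expect_equal(unname(full[1, 1]), 1)
  z <- attribution_report(matrix(0, 64, 64), list(all = matrix(TRUE, 64, 64)))
  expect_identical(unname(z[1, 1]), 0)
  expect_error(attribution_report(h, list(bad = matrix(TRUE, 32, 32))),
               "shapes differ")
})

test_that("disjoint region fractions sum to at most one", {
  h <- matrix(runif(64 * 64), 64, 64)
  m1 <- matrix(FALSE, 64, 64); m1[1:20, ] <- TRUE
  m2 <- matrix(FALSE, 64, 64); m2[41:64, ] <- TRUE
  fr <- attribution_report(h, list(top = m1, bottom = m2))
  expect_lte(sum(fr[1, ]), 1)
})

test_that("bilinear upsampling preserves constants and range", {
  up <- iopscreen:::upsample_bilinear(matrix(0.4, 4, 4), 64, 64)
  expect_equal(up, matrix(0.4, 64, 64), tolerance = 1e-12)
  m <- matrix(runif(16), 4, 4)
  u <- iopscreen:::upsample_bilinear(m, 64, 64)
  expect_gte(min(u), min(m) - 1e-12)
  expect_lte(max(u), max(m) + 1e-12)
  # corners are interpolated exactly (align-corners)
  expect_equal(u[1, 1], m[1, 1])
  expect_equal(u[64, 64], m[4, 4])
})
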