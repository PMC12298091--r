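# Windowed-attention encoder: shapes, attention normalization, freezing,
# transfer training.

test_that("patch partition counts and errors follow the divisibility law", {
  img <- matrix(runif(224 * 224), 224, 224)
  tok <- patch_partition(img, 4)
  expect_identical(nrow(tok), 3136L)
  expect_identical(ncol(tok), 16L)
  small <- patch_partition(matrix(1:64, 8, 8), 4)
  expect_identical(nrow(small), 4L)
  expect_error(patch_partition(matrix(0, 10, 10), 4), "divisible")
  # patches reproduce the image content
  expect_equal(sum(tok), sum(img))
})

test_that("stage shape law holds across valid configurations", {
  for (embed in c(8, 16)) {
    for (input in c(32, 64)) {
      cfg <- backbone_config(input_size = input, patch_size = 4,
                             depths = c(1, 1, 1, 1), heads = c(2, 2, 2, 2),
                             window_size = 4, embed_dim = embed,
                             mlp_ratio = 2)
      mdl <- build_backbone(cfg, seed = 1)
      st <- forward_stages(mdl, matrix(runif(input^2), input, input))
      expect_length(st, 4L)
      for (s in 1:4) {
        side <- input / (4 * 2^(s - 1))
        expect_identical(nrow(st[[s]]), as.integer(side^2))
        expect_identical(ncol(st[[s]]), as.integer(embed * 2^(s - 1)))
        expect_true(all(is.finite(st[[s]])))
      }
    }
  }
  expect_error(backbone_config(input_size = 225), "divisible")
  expect_error(backbone_config(heads = c(5, 6, 12, 24)), "heads")
})

test_that("identical inputs give identical features", {
  cfg <- backbone_config(tiny_preset = TRUE)
  mdl <- build_backbone(cfg, seed = 2)
  img <- fix_phantom()$image
  expect_identical(forward_stages(mdl, img), forward_stages(mdl, img))
  expect_error(backbone_forward(mdl, matrix(0, 32, 32)), "64 x 64")
})

test_that("attention rows are normalized, with and without shift", {
  tok <- matrix(rnorm(64 * 8), 64, 8)   # 8x8 grid
  for (shift in c(0, 2)) {
    wa <- window_attention(tok, window_size = 4, heads = 2, shift = shift)
    expect_identical(dim(wa$tokens), dim(tok))
    expect_true(all(is.finite(wa$tokens)))
    for (a in wa$attention) {
      expect_equal(rowSums(a), rep(1, 64), tolerance = 1e-6)
    }
  }
  # oversized window falls back to global attention: all weights positive
  wg <- window_attention(tok, window_size = 16, heads = 2)
  expect_true(all(wg$attention[[1]] > 0))
  # windowed attention masks cross-window pairs
  w0 <- window_attention(tok, window_size = 4, heads = 2, shift = 0)
  wid <- iopscreen:::window_ids(8L, 4L, 0L)
  cross <- outer(wid, wid, "!=")
  expect_true(all(w0$attention[[1]][cross] == 0))
})

test_that("freeze policies are airtight and validated", {
  cfg <- backbone_config(tiny_preset = TRUE)
  mdl <- build_backbone(cfg, seed = 3)
  expect_error(apply_freeze_policy(mdl, "stage9"), "matches no layer")
  coh <- fix_cohort(20)
  imgs <- coh$images[1:8]
  labs <- rep(c(1L, 2L), 4)

  frozen_all <- apply_freeze_policy(mdl, "all")
  out <- pretrain_transfer(frozen_all, imgs, labs, epochs = 1, seed = 4)
  expect_identical(out$model$params, mdl$params)

  part <- apply_freeze_policy(mdl, c("patch", "stage1"))
  out2 <- pretrain_transfer(part, imgs, labs, epochs = 1, seed = 4)
  expect_identical(out2$model$params$patch.W, mdl$params$patch.W)
  expect_identical(out2$model$params[["stage1.block1.qkv.W"]],
                   mdl$params[["stage1.block1.qkv.W"]])
  expect_false(identical(out2$model$params[["stage3.block1.qkv.W"]],
                         mdl$params[["stage3.block1.qkv.W"]]))
  # empty policy leaves everything trainable
  none <- apply_freeze_policy(mdl, "none")
  expect_length(none$frozen, 0L)
})

test_that("transfer training reduces the loss and is reproducible", {
  cfg <- backbone_config(tiny_preset = TRUE)
  mdl <- build_backbone(cfg, seed = 5)
  coh <- fix_cohort(40)
  sel <- c(which(coh$table$label == "normal")[1:10],
           which(coh$table$label == "high"))
  sel <- sel[!is.na(sel)]
  imgs <- coh$images[sel]
  labs <- as.integer(coh$table$label[sel])
  expect_error(pretrain_transfer(mdl, list(), integer(0)), "empty")
  zero <- pretrain_transfer(mdl, imgs, labs, epochs = 0)
  expect_identical(zero$model$params, mdl$params)
  run1 <- pretrain_transfer(mdl, imgs, labs, epochs = 3, seed = 6)
  expect_lt(run1$history[3], run1$history[1])
  run2 <- pretrain_transfer(mdl, imgs, labs, epochs = 3, seed = 6)
  expect_identical(run1$history, run2$history)
})

test_that("checkpoints round-trip through disk", {
  cfg <- backbone_config(tiny_preset = TRUE)
  mdl <- build_backbone(cfg, seed = 7)
  mdl <- apply_freeze_policy(mdl, "patch")
  path <- tempfile(fileext = ".rds")
  save_backbone(mdl, path)
  back <- load_backbone(path)
  expect_identical(back$params, mdl$params)
  expect_identical(back$frozen, mdl$frozen)
  img <- fix_phantom()$image
  expect_identical(backbone_logits(back, img), backbone_logits(mdl, img))
})
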