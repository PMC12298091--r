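# Synthetic cohort generator: calibration, rendering geometry, artifacts.

test_that("empty and repeated sampling behave as contracted", {
  cfg <- fix_config()
  expect_identical(nrow(sample_clinical(cfg, 0, seed = 1)), 0L)
  a <- sample_clinical(cfg, 50, seed = 42)
  b <- sample_clinical(cfg, 50, seed = 42)
  expect_identical(a, b)
})

test_that("labels follow the 21 mmHg rule exactly", {
  tab <- sample_clinical(fix_config(), 500, seed = 9)
  expect_true(all((tab$iop > 21) == (tab$label == "high")))
  expect_true(all(tab$iop > 0))
})

test_that("class-conditional means and the class fraction are calibrated", {
  cfg <- fix_config()
  n <- 6000
  tab <- sample_clinical(cfg, n, seed = 13)
  frac <- mean(tab$label == "high")
  expect_lt(abs(frac - 100 / 780), 0.02)
  for (cls in c("normal", "high")) {
    sel <- tab$label == cls
    for (a in iopscreen:::PHANTOM_ATTRS) {
      se <- cfg$group_sds[[a]] / sqrt(sum(sel))
      expect_lt(abs(mean(tab[[a]][sel]) - cfg$group_means[cls, a]),
                3 * se + 1e-9)
    }
  }
})

test_that("pooled attribute-IOP correlations approach configured targets", {
  tab <- sample_clinical(fix_config(), 10000, seed = 17)
  expect_lt(abs(pearson_corr(tab$pupil_center_thickness, tab$iop) - 0.41),
            0.05)
  expect_lt(abs(pearson_corr(tab$anterior_chamber_depth, tab$iop) + 0.17),
            0.05)
  expect_lt(abs(pearson_corr(tab$anterior_chamber_volume, tab$iop) + 0.14),
            0.05)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(phantom_config(class_prob_high = 0), "class_prob_high")
  expect_error(phantom_config(class_prob_high = 1.2), "class_prob_high")
  expect_error(phantom_config(target_correlations = c(iop = 0.5)), "unknown")
  expect_error(
    phantom_config(target_correlations = c(corneal_volume = 1.2)),
    "magnitude")
  expect_error(phantom_config(image_height = 16))
})

test_that("rendering is a pure function of record, config and seed", {
  ph1 <- fix_phantom()
  ph2 <- fix_phantom()
  rec <- sample_clinical(fix_config(), 1, seed = 7)
  ph3 <- render_phantom(rec, fix_config(), seed = 7)
  expect_identical(ph1$image, ph3$image)
  expect_true(all(ph1$image >= 0 & ph1$image <= 1))
})

test_that("noise-free band thickness matches a column-scan oracle", {
  cfg0 <- phantom_config(noise_sd = 0)
  rec <- sample_clinical(cfg0, 1, seed = 5)
  ph <- render_phantom(rec, cfg0, seed = 5)
  # oracle: count bright pixels per column
  counts <- apply(ph$image > 0.6, 2, sum)
  expect_true(all(counts == ph$truth$band_px))
})

test_that("thicker corneas render strictly more bright-band pixels", {
  cfg0 <- phantom_config(noise_sd = 0)
  rec <- sample_clinical(cfg0, 1, seed = 6)
  rec_thick <- rec
  rec_thick$pupil_center_thickness <- rec$pupil_center_thickness + 40
  a <- render_phantom(rec, cfg0, seed = 3)
  b <- render_phantom(rec_thick, cfg0, seed = 3)
  expect_gt(sum(b$image > 0.6), sum(a$image > 0.6))
})

test_that("deeper anterior chambers render a taller dark wedge", {
  cfg0 <- phantom_config(noise_sd = 0)
  rec <- sample_clinical(cfg0, 1, seed = 8)
  rec_deep <- rec
  rec_deep$anterior_chamber_depth <- rec$anterior_chamber_depth + 3
  a <- render_phantom(rec, cfg0, seed = 3)
  b <- render_phantom(rec_deep, cfg0, seed = 3)
  expect_gt(sum(b$image < 0.1), sum(a$image < 0.1))
})

test_that("artifact injection honours the magnitude-zero identity", {
  ph <- fix_phantom()
  for (kind in c("edge_discontinuity", "bright_region", "texture_noise",
                 "blur")) {
    out <- inject_artifact(ph$image, list(kind = kind, magnitude = 0),
                           seed = 1)
    expect_identical(out, ph$image)
  }
  expect_error(inject_artifact(ph$image, list(kind = "vignette",
                                              magnitude = 0.5)),
               "unknown artifact")
})

test_that("bright-region artifacts saturate and edge gaps break the band", {
  ph <- fix_phantom()
  br <- inject_artifact(ph$image, list(kind = "bright_region",
                                       magnitude = 0.6), seed = 2)
  expect_identical(max(br), 1.0)
  gap <- inject_artifact(ph$image, list(kind = "edge_discontinuity",
                                        magnitude = 0.5), seed = 2)
  # edge-tracing oracle: per-column presence of the bright band
  clean_cols <- apply(ph$image > 0.55, 2, any)
  gap_cols <- apply(gap > 0.55, 2, any)
  expect_true(all(clean_cols))
  expect_false(all(gap_cols))
  # the bright-column trace splits into more runs than the clean image's
  runs <- function(x) sum(rle(x)$values)
  expect_gt(runs(gap_cols), runs(clean_cols))
})

test_that("phantom ground-truth masks cover band and wedge", {
  ph <- fix_phantom()
  m <- phantom_mask(ph$truth, 64, 64)
  expect_identical(dim(m), c(64L, 64L))
  # all very bright and very dark pixels of the noiseless geometry lie inside
  cfg0 <- phantom_config(noise_sd = 0)
  rec <- sample_clinical(cfg0, 1, seed = 7)
  ph0 <- render_phantom(rec, cfg0, seed = 77)
  m0 <- phantom_mask(ph0$truth, 64, 64)
  expect_true(all(m0[ph0$image > 0.6]))
  expect_true(all(m0[ph0$image < 0.1]))
})

test_that("record validation enforces the field invariants", {
  rec <- sample_clinical(fix_config(), 1, seed = 3)
  expect_true(validate_record(rec))
  bad <- rec; bad$corneal_volume <- -1
  expect_error(validate_record(bad), "strictly positive")
  bad2 <- rec; bad2$iop <- NaN
  expect_error(validate_record(bad2), "non-finite")
  expect_error(validate_record(rec[, -1]), "lacks attributes")
})
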