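# Configuration, dataset I/O and the end-to-end pipeline.

#' Default pipeline configuration
#'
#' Nested configuration for every stage, with the desk-scale defaults. All
#' randomness in [run_pipeline()] derives from the single global `seed`.
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "iopscreen_run",
    phantom = list(n = 300L, image_height = 64L, image_width = 64L,
                   noise_sd = 0.02),
    augment = list(mode = "classic", n_per_class = 40L),
    qc = list(enabled = TRUE, m = 200L, p = 100L, lambda = 1e-2,
              threshold = 0.7, n_train = 120L),
    backbone = list(tiny_preset = TRUE, pretrain_epochs = 4L,
                    freeze = "none"),
    fusion = list(epochs = 20L, l1_lambda = 1e-4, p0 = 0.2, beta_drop = 0.1,
                  patience = 10L, width = 8L),
    split = list(train = 0.8, validation = 0.1, test = 0.1),
    explain = list(n_images = 4L)
  )
}

#' Load / save a pipeline configuration
#'
#' JSON or YAML by file extension; unknown keys (at any nesting level)
#' are rejected so typos cannot silently fall back to defaults, and missing
#' keys take their default values.
#'
#' @param path configuration file (`.json`, `.yaml` or `.yml`).
#' @return merged, validated configuration list.
#' @export
load_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: ", ext, call. = FALSE))
  merge_config(default_run_config(), user, prefix = "")
}

#' @rdname load_run_config
#' @param config configuration list to write.
#' @export
save_run_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(config, path, auto_unbox = TRUE,
                                pretty = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(config, path),
    stop("unsupported config format: ", ext, call. = FALSE))
  invisible(path)
}

merge_config <- function(defaults, user, prefix = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     prefix = paste0(prefix, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Read an image + clinical-table dataset from disk
#'
#' The CSV must contain the eight clinical attribute columns plus `label`,
#' `patient_id` and `path` (PNG file relative to `image_dir`). Rows whose
#' image cannot be read are reported and excluded.
#'
#' @param image_dir directory holding the PNG images.
#' @param clinical_csv path to the clinical table.
#' @return list with `table`, `images` (list of matrices) and `failures`
#'   (character vector of unreadable paths).
#' @export
read_image_table <- function(image_dir, clinical_csv) {
  tab <- utils::read.csv(clinical_csv, stringsAsFactors = FALSE)
  required <- c(PHANTOM_ATTRS, "label", "patient_id", "path")
  missing <- setdiff(required, colnames(tab))
  if (length(missing) > 0L) {
    stop("clinical table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  images <- vector("list", nrow(tab))
  ok <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    f <- file.path(image_dir, tab$path[i])
    img <- tryCatch({
      m <- png::readPNG(f)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(img)) next
    images[[i]] <- img
    ok[i] <- TRUE
  }
  failures <- tab$path[!ok]
  if (length(failures) > 0L) {
    warning(length(failures), " image(s) could not be read",
            call. = FALSE)
  }
  tab$label <- factor(tab$label, levels = c("normal", "high"))
  list(table = tab[ok, , drop = FALSE], images = images[ok],
       failures = failures)
}

#' Run the full pipeline
#'
#' Executes, from one seed: phantom synthesis, patient-grouped splitting,
#' augmentation, BLS + integrity quality gating, backbone pretraining on the
#' gated augmented set, fusion-head training on the training split with
#' early stopping on the validation split, evaluation on the test split, and
#' Grad-CAM attribution against the phantom ground-truth masks. All stage
#' outputs are written under `config$out_dir`.
#'
#' @param config nested configuration (see [default_run_config()]).
#' @return invisibly, a list with the evaluation `metrics`, the `ablation`
#'   style artifacts of the trained variant, the `attribution` summary and
#'   output `paths`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  config <- merge_config(default_run_config(), config)
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # synth
  pc <- stage("synth", phantom_config(
    image_height = config$phantom$image_height,
    image_width = config$phantom$image_width,
    noise_sd = config$phantom$noise_sd))
  cohort <- stage("synth", phantom_cohort(pc, config$phantom$n, seed = seed))
  tab <- cohort$table

  # split
  plan <- stage("split", split_dataset(tab$label, tab$patient_id,
                                       ratios = unlist(config$split),
                                       seed = child_seed(seed, 1L)))

  # augment (training-split sources only)
  tr <- plan$train
  src_n <- cohort$images[tr[tab$label[tr] == "normal"]]
  src_h <- cohort$images[tr[tab$label[tr] == "high"]]
  aug <- stage("augment", generate_augmented(
    src_n, src_h, n_per_class = config$augment$n_per_class,
    mode = config$augment$mode, seed = child_seed(seed, 2L)))
  aug_refs <- lapply(seq_along(aug$images), function(k) {
    src <- if (aug$source_domain[k] == "normal") src_n else src_h
    src[[aug$source_id[k]]]
  })

  # quality gate
  if (isTRUE(config$qc$enabled)) {
    qc_train <- stage("qc", build_qc_training_set(
      cohort$images[tr], n = config$qc$n_train,
      seed = child_seed(seed, 3L)))
    qc_model <- stage("qc", bls_quality_fit(
      qc_train$images, qc_train$references, qc_train$magnitudes,
      m = config$qc$m, p = config$qc$p, lambda = config$qc$lambda,
      threshold = config$qc$threshold, seed = child_seed(seed, 4L)))
    verdicts <- stage("qc", qc_gate(qc_model, aug$images, aug_refs))
    keep <- verdicts$is_high_quality
    utils::write.csv(cbind(id = seq_along(aug$images), verdicts),
                     file.path(out_dir, "qc_verdicts.csv"),
                     row.names = FALSE)
  } else {
    keep <- rep(TRUE, length(aug$images))
    verdicts <- NULL
  }
  gated_images <- aug$images[keep]
  gated_labels <- as.integer(aug$domain)[keep]

  # pretrain
  bcfg <- stage("pretrain", backbone_config(
    tiny_preset = isTRUE(config$backbone$tiny_preset)))
  backbone <- stage("pretrain", {
    m <- build_backbone(bcfg, seed = child_seed(seed, 5L))
    m <- apply_freeze_policy(m, config$backbone$freeze)
    pretrain_transfer(m, gated_images, gated_labels,
                      epochs = config$backbone$pretrain_epochs,
                      seed = child_seed(seed, 6L))$model
  })

  # train fusion head
  y <- as.integer(tab$label)
  feats <- stage("train", extract_features(backbone, cohort$images))
  std <- stage("train", clinical_standardizer(tab[plan$train, ]))
  Xc <- standardize_clinical(tab, std$mu, std$sigma)
  head <- fusion_head(d_image = ncol(feats), d_clinical = ncol(Xc),
                      width = config$fusion$width,
                      seed = child_seed(seed, 7L))
  head$standardizer <- std
  fit <- stage("train", train_fusion(
    head, feats[plan$train, ], Xc[plan$train, ], y[plan$train],
    val = list(X_img = feats[plan$validation, ],
               X_clin = Xc[plan$validation, ], y = y[plan$validation]),
    epochs = config$fusion$epochs, l1_lambda = config$fusion$l1_lambda,
    p0 = config$fusion$p0, beta_drop = config$fusion$beta_drop,
    patience = config$fusion$patience, seed = child_seed(seed, 8L)))

  # eval
  pred <- stage("eval", predict_fusion(fit$head, feats[plan$test, ],
                                       Xc[plan$test, ]))
  metrics <- stage("eval", compute_metrics(y[plan$test], pred,
                                           positive = 2L))

  # explain
  n_exp <- min(config$explain$n_images, length(plan$test))
  exp_idx <- plan$test[seq_len(n_exp)]
  attribution <- stage("explain", {
    hms <- lapply(exp_idx, function(i) {
      grad_cam(backbone, cohort$images[[i]])
    })
    masks <- lapply(exp_idx, function(i) {
      list(informative = phantom_mask(cohort$truths[[i]],
                                      pc$image_height, pc$image_width))
    })
    for (k in seq_along(hms)) {
      write_heatmap_png(hms[[k]], cohort$images[[exp_idx[k]]],
                        file.path(out_dir, sprintf("heatmap_%03d.png", k)))
    }
    attribution_report(hms, masks)
  })

  # artifacts
  paths <- list(
    config = file.path(out_dir, "config.json"),
    split = file.path(out_dir, "split.json"),
    metrics = file.path(out_dir, "metrics.json"),
    attribution = file.path(out_dir, "attribution.json"),
    history = file.path(out_dir, "fusion_history.csv"),
    checkpoint = file.path(out_dir, "backbone.rds")
  )
  save_run_config(config, paths$config)
  jsonlite::write_json(lapply(plan[c("train", "validation", "test")],
                              identity),
                       paths$split, auto_unbox = FALSE)
  jsonlite::write_json(unclass(metrics), paths$metrics, auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(list(in_mask_fraction = as.numeric(attribution)),
                       paths$attribution, auto_unbox = FALSE, digits = NA)
  utils::write.csv(fit$history, paths$history, row.names = FALSE)
  save_backbone(backbone, paths$checkpoint)

  invisible(list(metrics = metrics, attribution = attribution,
                 split = plan, qc = verdicts, head = fit$head,
                 backbone = backbone, paths = paths))
}

# corrupted/clean pairs for quality-gate training: even indices get a random
# artifact of random magnitude, paired with their clean original
build_qc_training_set <- function(clean_images, n, seed = 1L) {
  kinds <- c("edge_discontinuity", "bright_region", "texture_noise", "blur")
  n <- min(n, length(clean_images))
  with_seed(seed, {
    pick <- sample(length(clean_images), n)
    images <- clean_images[pick]
    references <- images
    magnitudes <- numeric(n)
    for (k in seq(2L, n, by = 2L)) {
      mag <- stats::runif(1, 0.4, 0.9)
      kind <- sample(kinds, 1L)
      images[[k]] <- inject_artifact(images[[k]],
                                     list(kind = kind, magnitude = mag),
                                     seed = child_seed(seed, k))
      magnitudes[k] <- mag
    }
    list(images = images, references = references, magnitudes = magnitudes)
  })
}
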