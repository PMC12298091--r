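# Training schedule utilities, data splitting, metrics, cross-validation,
# classical baselines, correlation analysis and the ablation harness.

#' Total loss with L1 regularization
#'
#' `L_total = L_task + lambda * sum_i |w_i|`.
#'
#' @param task_loss scalar task loss (e.g. cross-entropy).
#' @param weights numeric vector/matrix of model weights.
#' @param lambda L1 coefficient (>= 0).
#' @return scalar.
#' @export
total_loss <- function(task_loss, weights, lambda) {
  stopifnot(lambda >= 0)
  task_loss + lambda * sum(abs(weights))
}

#' Dynamic dropout schedule
#'
#' `p(t) = p0 / (1 + beta * t)`: starts at `p0` and decays as training
#' progresses, so regularization is strongest early.
#'
#' @param p0 initial dropout probability.
#' @param beta decay rate (>= 0; 0 keeps the rate constant).
#' @param t training step (>= 0).
#' @return dropout probability at step `t`.
#' @export
dropout_schedule <- function(p0, beta, t) {
  stopifnot(all(t >= 0), beta >= 0)
  p0 / (1 + beta * t)
}

## ---- data splitting --------------------------------------------------------

#' Stratified, patient-grouped train/validation/test split
#'
#' Splits samples into train/validation/test at the given ratios such that
#' (1) all samples of a patient land in exactly one subset and (2) each
#' subset's class ratio matches the global one as closely as the grouping
#' allows. Per class, whole patients are assigned greedily (largest patient
#' first, random tie-break from the seed) to the subset with the largest
#' remaining deficit. With one eye per patient the published arithmetic is
#' exact: 780 samples at 8:1:1 give 624/624+78+78.
#'
#' @param labels factor/character class labels.
#' @param patient_ids patient identifier per sample.
#' @param ratios length-3 numeric, must sum to 1.
#' @param seed seed.
#' @return object of class `split_plan`: list of index vectors `train`,
#'   `validation`, `test` plus per-split class counts.
#' @export
split_dataset <- function(labels, patient_ids,
                          ratios = c(train = 0.8, validation = 0.1,
                                     test = 0.1),
                          seed = 1L) {
  stopifnot(length(labels) == length(patient_ids))
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1",
                                        call. = FALSE)
  labels <- as.factor(labels)
  splits <- c("train", "validation", "test")
  ncls <- nlevels(labels)
  # per-class integer split targets by largest remainder
  tgt <- matrix(0, 3L, ncls, dimnames = list(splits, levels(labels)))
  for (cls in levels(labels)) {
    target <- sum(labels == cls) * ratios
    t0 <- floor(target)
    rem <- round(sum(target)) - sum(t0)
    if (rem > 0) {
      add <- order(target - t0, decreasing = TRUE)[seq_len(rem)]
      t0[add] <- t0[add] + 1
    }
    tgt[, cls] <- t0
  }
  assign_split <- rep(NA_character_, length(labels))
  with_seed(seed, {
    # whole patients are assigned as units, so class-mixed patients can
    # never straddle two subsets; largest patients first, seeded tie-break
    pats <- split(seq_along(labels), patient_ids)
    ord <- order(-lengths(pats), stats::runif(length(pats)))
    pats <- pats[ord]
    filled <- tgt * 0
    overflow <- FALSE
    for (pk in seq_along(pats)) {
      cnt <- as.numeric(table(labels[pats[[pk]]]))
      deficit <- pmax(tgt - filled, 0)
      fits <- apply(deficit, 1L, function(d) sum(pmin(d, cnt)))
      if (max(fits) < sum(cnt)) overflow <- TRUE
      # break ties toward the split with the largest remaining deficit
      dest <- splits[order(-fits, -rowSums(deficit))[1L]]
      assign_split[pats[[pk]]] <- dest
      filled[dest, ] <- filled[dest, ] + cnt
    }
    if (overflow) {
      warning("some patients exceed their split's remaining class ",
              "capacity; best-effort split", call. = FALSE)
    }
  })
  plan <- lapply(stats::setNames(splits, splits),
                 function(s) which(assign_split == s))
  counts <- vapply(plan, function(ix) table(labels[ix]),
                   integer(nlevels(labels)))
  structure(list(train = plan$train, validation = plan$validation,
                 test = plan$test, class_counts = counts,
                 ratios = ratios), class = "split_plan")
}

#' Stratified k-fold assignment
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed seed.
#' @return integer fold id per sample (1..k); every class appears in every
#'   fold or an error is raised.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1L) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in levels(labels)) {
      sel <- sample(which(labels == cls))
      if (length(sel) < k) {
        stop("class '", cls, "' has fewer samples than folds", call. = FALSE)
      }
      fold[sel] <- rep_len(seq_len(k), length(sel))
    }
  })
  fold
}

## ---- metrics ---------------------------------------------------------------

#' Confusion-matrix classification metrics
#'
#' Computes TP/TN/FP/FN and the six reported metrics: accuracy, precision
#' `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 `2PR/(P+R)`, specificity
#' `TN/(TN+FP)`, and the Matthews correlation coefficient. Conventions for
#' empty denominators: rate metrics with a zero denominator are 0, and MCC
#' with a zero denominator is defined as 0.
#'
#' @param y_true,y_pred equal-length binary label vectors; the positive class
#'   is `positive` (default `"high"`, or 2 for integer labels).
#' @param positive positive-class value.
#' @return object of class `metrics_report` (a named list).
#' @export
compute_metrics <- function(y_true, y_pred, positive = NULL) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  if (is.null(positive)) {
    positive <- if (is.numeric(y_true)) max(y_true) else "high"
  }
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  specificity <- safe_div(tn, tn + fp)
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 accuracy = (tp + tn) / length(y_true),
                 precision = precision, recall = recall, f1 = f1,
                 specificity = specificity, mcc = mcc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "confusion: TP=%d TN=%d FP=%d FN=%d\naccuracy=%.3f precision=%.3f recall=%.3f f1=%.3f specificity=%.3f mcc=%.3f\n",
    x$TP, x$TN, x$FP, x$FN, x$accuracy, x$precision, x$recall, x$f1,
    x$specificity, x$mcc))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over the standard estimator with the input checks the
#' pipeline relies on (length >= 3, non-degenerate variance).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with at least 3 observations",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

## ---- cross-validation and baselines ----------------------------------------

#' Stratified 5-fold cross-validation
#'
#' Retrains a model from scratch on each fold's training portion and
#' evaluates on the held-out fold; reports per-fold metrics and their
#' medians (median reporting mitigates fold outliers). Fold assignment is
#' deterministic given the seed.
#'
#' @param model_factory `function(X_train, y_train, seed)` returning an
#'   object with a `function(model, X)` predict method supplied as
#'   `predict_fun`.
#' @param predict_fun `function(model, X)` returning class predictions.
#' @param X feature matrix / data.frame.
#' @param y class labels.
#' @param k number of folds.
#' @param seed seed.
#' @return list with `folds` (list of `metrics_report`) and `median`
#'   (named vector of median metrics).
#' @export
crossval_kfold <- function(model_factory, predict_fun, X, y, k = 5,
                           seed = 1L) {
  fold <- stratified_folds(y, k = k, seed = seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    model <- model_factory(X[tr, , drop = FALSE], y[tr],
                           seed = child_seed(seed, f))
    pred <- predict_fun(model, X[!tr, , drop = FALSE])
    reports[[f]] <- compute_metrics(y[!tr], pred)
  }
  metric_names <- c("accuracy", "precision", "recall", "f1", "specificity",
                    "mcc")
  med <- vapply(metric_names, function(mn) {
    stats::median(vapply(reports, function(r) r[[mn]], numeric(1)))
  }, numeric(1))
  list(folds = reports, median = med, fold_id = fold)
}

#' Classical machine-learning baselines on clinical features
#'
#' Trains a support vector machine, a random forest and a logistic
#' regression on the six standardized structural attributes and evaluates
#' all three under the same stratified 5-fold protocol.
#'
#' @param table clinical data.frame containing the six structural columns.
#' @param labels class labels aligned with `table`.
#' @param seed seed.
#' @return named list of cross-validation results (`svm`, `rf`, `lr`).
#' @export
fit_baselines <- function(table, labels, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L) {
    stop("need both classes present", call. = FALSE)
  }
  std <- clinical_standardizer(table)
  X <- standardize_clinical(table, std$mu, std$sigma)

  factories <- list(
    svm = function(Xtr, ytr, seed) {
      with_seed(seed, e1071::svm(Xtr, as.factor(ytr), kernel = "radial"))
    },
    rf = function(Xtr, ytr, seed) {
      with_seed(seed,
                randomForest::randomForest(Xtr, as.factor(ytr), ntree = 200))
    },
    lr = function(Xtr, ytr, seed) {
      df <- as.data.frame(Xtr)
      df$.y <- as.factor(ytr)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = "binomial"))
    }
  )
  predictors <- list(
    svm = function(m, Xte) as.character(stats::predict(m, Xte)),
    rf = function(m, Xte) as.character(stats::predict(m, Xte)),
    lr = function(m, Xte) {
      pr <- stats::predict(m, as.data.frame(Xte), type = "response")
      levels(as.factor(m$model$.y))[1 + (pr > 0.5)]
    }
  )
  out <- list()
  for (nm in names(factories)) {
    out[[nm]] <- crossval_kfold(factories[[nm]], predictors[[nm]], X,
                                as.character(labels), k = 5, seed = seed)
  }
  out
}

## ---- ablation harness ------------------------------------------------------

#' Ablation study over pipeline variants
#'
#' Compares, under identical splits and seeds, the full multimodal model
#' (pretrained backbone features + clinical branch), the image-only model
#' (pretrained backbone features alone) and the no-pretraining model
#' (randomly initialised backbone features alone). For each variant a fusion
#' head is trained on the training split with early stopping on the
#' validation split and evaluated on the test split.
#'
#' @param cohort a [phantom_cohort()].
#' @param variants subset of `c("full", "image_only", "no_pretrain")`.
#' @param backbone_cfg a [backbone_config()]; default tiny preset.
#' @param pretrain_per_class augmented images per domain used for backbone
#'   pretraining.
#' @param pretrain_epochs backbone pretraining epochs.
#' @param head_epochs fusion-head training epochs.
#' @param seed seed.
#' @return list with `table` (one row per variant: the six metrics) and
#'   `reports` (full `metrics_report` objects).
#' @export
run_ablation <- function(cohort,
                         variants = c("full", "image_only", "no_pretrain"),
                         backbone_cfg = NULL, pretrain_per_class = 200,
                         pretrain_epochs = 10, head_epochs = 25, seed = 1L) {
  variants <- match.arg(variants, several.ok = TRUE)
  backbone_cfg <- backbone_cfg %||% backbone_config(tiny_preset = TRUE)
  tab <- cohort$table
  plan <- split_dataset(tab$label, tab$patient_id, seed = seed)
  y <- as.integer(tab$label)    # 1 = normal, 2 = high

  # pretraining set: classic-jittered images from the training split only
  tr_idx <- plan$train
  src_n <- cohort$images[tr_idx[tab$label[tr_idx] == "normal"]]
  src_h <- cohort$images[tr_idx[tab$label[tr_idx] == "high"]]
  aug <- generate_augmented(src_n, src_h, n_per_class = pretrain_per_class,
                            mode = "classic", seed = child_seed(seed, 21L))
  aug_labels <- as.integer(aug$domain)

  # pretraining starts from random init, so every layer trains here; the
  # freeze policy belongs to later fine-tuning stages, not to this phase
  pre <- build_backbone(backbone_cfg, seed = child_seed(seed, 22L))
  pre <- pretrain_transfer(pre, aug$images, aug_labels,
                           epochs = pretrain_epochs, lr = 1.5e-3,
                           batch_size = 8,
                           val_images = cohort$images[plan$validation],
                           val_labels = y[plan$validation],
                           seed = child_seed(seed, 23L))$model
  rnd <- build_backbone(backbone_cfg, seed = child_seed(seed, 22L))

  feats <- list()
  if (any(variants %in% c("full", "image_only"))) {
    feats$pre <- extract_features(pre, cohort$images)
  }
  if ("no_pretrain" %in% variants) {
    feats$rnd <- extract_features(rnd, cohort$images)
  }
  std <- clinical_standardizer(tab[plan$train, ])
  Xc <- standardize_clinical(tab, std$mu, std$sigma)

  eval_variant <- function(Ximg, use_clinical) {
    Xcl <- if (use_clinical) Xc else NULL
    head <- fusion_head(d_image = ncol(Ximg),
                        d_clinical = if (use_clinical) ncol(Xc) else 0L,
                        seed = child_seed(seed, 31L))
    head$standardizer <- std
    fit <- train_fusion(
      head, Ximg[plan$train, , drop = FALSE],
      if (use_clinical) Xcl[plan$train, , drop = FALSE] else NULL,
      y[plan$train],
      val = list(X_img = Ximg[plan$validation, , drop = FALSE],
                 X_clin = if (use_clinical)
                   Xcl[plan$validation, , drop = FALSE] else NULL,
                 y = y[plan$validation]),
      epochs = head_epochs, seed = child_seed(seed, 32L))
    pred <- predict_fusion(fit$head, Ximg[plan$test, , drop = FALSE],
                           if (use_clinical)
                             Xcl[plan$test, , drop = FALSE] else NULL)
    compute_metrics(y[plan$test], pred, positive = 2L)
  }

  reports <- list()
  for (v in variants) {
    reports[[v]] <- switch(v,
      full = eval_variant(feats$pre, TRUE),
      image_only = eval_variant(feats$pre, FALSE),
      no_pretrain = eval_variant(feats$rnd, FALSE))
  }
  metric_names <- c("accuracy", "precision", "recall", "f1", "specificity",
                    "mcc")
  table_out <- do.call(rbind, lapply(names(reports), function(v) {
    data.frame(variant = v,
               as.list(unlist(reports[[v]][metric_names])))
  }))
  list(table = table_out, reports = reports, split = plan,
       backbone_pretrained = pre, backbone_random = rnd,
       standardizer = std)
}

#' Fine-tune a pretrained backbone on labelled cohort images
#'
#' The second training phase of the pipeline: starting from a phantom-
#' pretrained encoder, freeze the lower layers (patch embedding and stage 1
#' by default), and fine-tune the rest on a stratified subsample of the
#' training split with inverse-class-frequency-weighted cross-entropy,
#' checkpointing on validation-split cross-entropy. The returned model is
#' the one the Grad-CAM attribution analysis explains.
#'
#' @param backbone a pretrained [build_backbone()] model.
#' @param cohort a [phantom_cohort()] (or any list with `images` and
#'   `table$label`).
#' @param plan a [split_dataset()] plan on the cohort.
#' @param freeze freeze policy applied before fine-tuning.
#' @param n_train number of training images used (stratified subsample of
#'   the training split).
#' @param epochs,lr,batch_size optimiser settings.
#' @param seed seed.
#' @return list with fine-tuned `model`, `history`, `val_loss`,
#'   `val_accuracy` and `best_epoch`.
#' @export
finetune_backbone <- function(backbone, cohort, plan,
                              freeze = c("patch", "stage1"),
                              n_train = 400, epochs = 3, lr = 5e-4,
                              batch_size = 4, seed = 1L) {
  y <- as.integer(cohort$table$label)
  tr <- plan$train
  if (length(tr) > n_train) {
    tr <- with_seed(child_seed(seed, 1L), {
      keep <- c()
      for (cls in 1:2) {
        sel <- tr[y[tr] == cls]
        take <- max(1L, round(n_train * length(sel) / length(tr)))
        keep <- c(keep, sample(sel, min(take, length(sel))))
      }
      sort(keep)
    })
  }
  model <- apply_freeze_policy(backbone, freeze)
  pretrain_transfer(model, cohort$images[tr], y[tr], epochs = epochs,
                    lr = lr, batch_size = batch_size,
                    class_weights = "balanced",
                    val_images = cohort$images[plan$validation],
                    val_labels = y[plan$validation],
                    seed = child_seed(seed, 2L))
}
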