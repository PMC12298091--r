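# Windowed-attention hierarchical image encoder.
#
# A Swin-style transformer at configurable scale: 4x4 patch embedding, four
# stages of window-based multi-head self-attention blocks with alternating
# shifted windows, patch merging between stages (spatial side halves, channel
# width doubles), layer normalization throughout, and a linear classification
# head on globally averaged final-stage tokens. Window attention is realised
# as masked full attention over the token grid: tokens attend only to tokens
# in the same (possibly shifted) window, which at this token count is the
# simplest exact formulation. When a window does not fit the grid the block
# falls back to global attention.
#
# The reference configuration (224 px, embed 96, depths (2,2,6,2), heads
# (3,6,12,24), window 7) is available; the tiny preset (64 px, embed 24,
# depths (1,1,2,1), window 4) is the test and desk-scale default.

#' Backbone configuration
#'
#' @param input_size input image side in pixels.
#' @param patch_size patch side (input must be divisible by it).
#' @param depths per-stage block counts.
#' @param heads per-stage attention head counts (must divide the stage
#'   channel widths `embed_dim * 2^(s-1)`).
#' @param window_size attention window side in tokens.
#' @param embed_dim channel width after patch embedding.
#' @param mlp_ratio MLP expansion ratio inside each block.
#' @param tiny_preset if `TRUE`, overrides the geometry with the desk-scale
#'   preset (64 px, embed 24, depths (1,1,2,1), window 4, mlp_ratio 2).
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(input_size = 224, patch_size = 4,
                            depths = c(2, 2, 6, 2), heads = c(3, 6, 12, 24),
                            window_size = 7, embed_dim = 96, mlp_ratio = 4,
                            tiny_preset = FALSE) {
  if (tiny_preset) {
    input_size <- 64; embed_dim <- 24; depths <- c(1, 1, 2, 1)
    heads <- c(3, 6, 12, 24); window_size <- 4; mlp_ratio <- 2
  }
  n_stages <- length(depths)
  stopifnot(n_stages == length(heads), n_stages >= 1)
  if (input_size %% patch_size != 0) {
    stop("input_size must be divisible by patch_size", call. = FALSE)
  }
  side0 <- input_size / patch_size
  if (side0 %% 2^(n_stages - 1) != 0) {
    stop("token grid must be divisible by the stage downsampling product",
         call. = FALSE)
  }
  dims <- embed_dim * 2^(seq_len(n_stages) - 1)
  if (any(dims %% heads != 0)) {
    stop("heads must divide the per-stage channel widths", call. = FALSE)
  }
  structure(list(input_size = input_size, patch_size = patch_size,
                 depths = depths, heads = heads, window_size = window_size,
                 embed_dim = embed_dim, mlp_ratio = mlp_ratio,
                 dims = dims,
                 sides = side0 / 2^(seq_len(n_stages) - 1)),
            class = "backbone_config")
}

#' Partition an image into flattened patches
#'
#' Divides an H x W image into non-overlapping `patch_size` square patches,
#' returning one row per patch (row-major over the patch grid). With a
#' projection matrix the rows are linearly embedded, which is the patch
#' embedding of the backbone.
#'
#' @param image numeric matrix.
#' @param patch_size patch side; both image dimensions must divide by it.
#' @param proj optional `(patch_size^2) x C` projection matrix.
#' @return `T x patch_size^2` (or `T x C`) matrix with attributes
#'   `grid = c(rows, cols)`.
#' @export
patch_partition <- function(image, patch_size, proj = NULL) {
  stopifnot_image(image)
  H <- nrow(image); W <- ncol(image)
  if (H %% patch_size != 0 || W %% patch_size != 0) {
    stop("image dimensions must be divisible by patch_size", call. = FALSE)
  }
  gh <- H / patch_size; gw <- W / patch_size
  out <- matrix(0, gh * gw, patch_size^2)
  k <- 0L
  for (dx in seq_len(patch_size)) {
    for (dy in seq_len(patch_size)) {
      k <- k + 1L
      sub <- image[seq(dy, H, by = patch_size), seq(dx, W, by = patch_size)]
      out[, k] <- as.numeric(t(sub))   # row-major token order
    }
  }
  if (!is.null(proj)) out <- out %*% proj
  attr(out, "grid") <- c(gh, gw)
  out
}

# window id per token of a side x side row-major grid; shift in tokens
window_ids <- function(side, window, shift = 0) {
  r <- rep(seq_len(side) - 1L, each = side)
  c <- rep(seq_len(side) - 1L, times = side)
  wr <- ((r + shift) %% side) %/% window
  wc <- ((c + shift) %% side) %/% window
  wr * ceiling(side / window) + wc
}

# additive attention mask (0 within window, -Inf across); NULL = global
window_mask <- function(side, window, shift = 0) {
  if (window >= side) return(NULL)
  wid <- window_ids(side, window, shift)
  same <- outer(wid, wid, "==")
  mask <- matrix(-Inf, length(wid), length(wid))
  mask[same] <- 0
  mask
}

#' Build a windowed-attention backbone
#'
#' @param config a [backbone_config()].
#' @param seed seed for weight initialisation.
#' @return object of class `backbone_model` with a named parameter list; all
#'   parameters are trainable until a freeze policy is applied.
#' @export
build_backbone <- function(config, seed = 1L) {
  stopifnot(inherits(config, "backbone_config"))
  tn <- function(n, m) matrix(stats::rnorm(n * m, sd = 0.02), n, m)
  with_seed(seed, {
    side0 <- config$sides[1]
    P <- list(
      patch.W = tn(config$patch_size^2, config$embed_dim),
      patch.b = matrix(0, 1L, config$embed_dim),
      # learnable absolute positional embedding; without it windowed
      # attention can only form spatial-statistics features
      patch.pos = tn(side0 * side0, config$embed_dim)
    )
    for (s in seq_along(config$depths)) {
      C <- config$dims[s]
      for (b in seq_len(config$depths[s])) {
        pfx <- sprintf("stage%d.block%d", s, b)
        P[[paste0(pfx, ".ln1.g")]] <- rep(1, C)
        P[[paste0(pfx, ".ln1.b")]] <- rep(0, C)
        P[[paste0(pfx, ".qkv.W")]] <- tn(C, 3L * C)
        P[[paste0(pfx, ".qkv.b")]] <- matrix(0, 1L, 3L * C)
        # residual output projections start at zero: every block begins as
        # the identity map, which keeps deep training stable
        P[[paste0(pfx, ".proj.W")]] <- matrix(0, C, C)
        P[[paste0(pfx, ".proj.b")]] <- matrix(0, 1L, C)
        P[[paste0(pfx, ".ln2.g")]] <- rep(1, C)
        P[[paste0(pfx, ".ln2.b")]] <- rep(0, C)
        hidden <- C * config$mlp_ratio
        P[[paste0(pfx, ".mlp.W1")]] <- tn(C, hidden)
        P[[paste0(pfx, ".mlp.b1")]] <- matrix(0, 1L, hidden)
        P[[paste0(pfx, ".mlp.W2")]] <- matrix(0, hidden, C)
        P[[paste0(pfx, ".mlp.b2")]] <- matrix(0, 1L, C)
      }
      if (s < length(config$depths)) {
        pfx <- sprintf("merge%d", s)
        P[[paste0(pfx, ".ln.g")]] <- rep(1, 4L * C)
        P[[paste0(pfx, ".ln.b")]] <- rep(0, 4L * C)
        P[[paste0(pfx, ".W")]] <- tn(4L * C, 2L * C)
      }
    }
    Cl <- config$dims[length(config$dims)]
    P$head.ln.g <- rep(1, Cl)
    P$head.ln.b <- rep(0, Cl)
    P$head.W <- tn(Cl, 2L)
    P$head.b <- matrix(0, 1L, 2L)

    masks <- vector("list", length(config$depths))
    merges <- vector("list", length(config$depths) - 1L)
    for (s in seq_along(config$depths)) {
      side <- config$sides[s]
      masks[[s]] <- list(plain = window_mask(side, config$window_size, 0),
                         shifted = window_mask(side, config$window_size,
                                               config$window_size %/% 2))
      if (s < length(config$depths)) merges[[s]] <- merge_indices(side)
    }
    structure(list(config = config, params = P, frozen = character(),
                   masks = masks, merges = merges),
              class = "backbone_model")
  })
}

# indices of the 2x2 neighbourhoods gathered by patch merging
merge_indices <- function(side) {
  half <- side / 2
  r <- rep(seq_len(half), each = half)
  c <- rep(seq_len(half), times = half)
  at <- function(R, C) (R - 1L) * side + C
  list(i00 = at(2L * r - 1L, 2L * c - 1L), i01 = at(2L * r - 1L, 2L * c),
       i10 = at(2L * r, 2L * c - 1L), i11 = at(2L * r, 2L * c))
}

# fused multi-head self-attention over a packed qkv matrix (T x 3C), with a
# hand-derived backward; one autodiff node instead of ~10 per head
ad_mha <- function(qkv, C, heads, mask) {
  qv <- ad_value(qkv)
  T_ <- nrow(qv)
  hd <- C %/% heads
  scale <- 1 / sqrt(hd)
  qs <- vector("list", heads); ks <- qs; vs <- qs; ps <- qs
  out <- matrix(0, T_, C)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * hd + 1L):(h * hd)
    q <- qv[, cols, drop = FALSE]
    k <- qv[, C + cols, drop = FALSE]
    v <- qv[, 2L * C + cols, drop = FALSE]
    s <- tcrossprod(q, k) * scale
    if (!is.null(mask)) s <- s + mask
    mx <- s[cbind(seq_len(T_), max.col(s, ties.method = "first"))]
    e <- exp(s - mx)
    p <- e / rowSums(e)
    out[, cols] <- p %*% v
    qs[[h]] <- q; ks[[h]] <- k; vs[[h]] <- v; ps[[h]] <- p
  }
  if (!is_ad(qkv)) return(out)
  ad_node(out, list(qkv), function(g) {
    dqkv <- matrix(0, T_, 3L * C)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * hd + 1L):(h * hd)
      dO <- g[, cols, drop = FALSE]
      p <- ps[[h]]
      dV <- crossprod(p, dO)
      dP <- tcrossprod(dO, vs[[h]])
      dS <- p * (dP - rowSums(dP * p))
      dqkv[, cols] <- (dS %*% ks[[h]]) * scale
      dqkv[, C + cols] <- crossprod(dS, qs[[h]]) * scale
      dqkv[, 2L * C + cols] <- dV
    }
    ad_accum(qkv, dqkv)
  })
}

# one transformer block (pre-norm attention + MLP, both residual)
swin_block <- function(x, C, heads, mask, pfx, P) {
  g <- function(nm) P[[paste0(pfx, ".", nm)]]
  h <- ad_layernorm(x, g("ln1.g"), g("ln1.b"))
  qkv <- ad_add(ad_mm(h, g("qkv.W")), g("qkv.b"))
  o <- ad_mha(qkv, C, heads, mask)
  o <- ad_add(ad_mm(o, g("proj.W")), g("proj.b"))
  x <- ad_add(x, o)
  h2 <- ad_layernorm(x, g("ln2.g"), g("ln2.b"))
  m <- ad_gelu(ad_add(ad_mm(h2, g("mlp.W1")), g("mlp.b1")))
  m <- ad_add(ad_mm(m, g("mlp.W2")), g("mlp.b2"))
  ad_add(x, m)
}

# full backbone forward; P may be plain parameters or autodiff leaves
backbone_forward <- function(model, image, P = NULL) {
  P <- P %||% model$params
  cfg <- model$config
  if (nrow(image) != cfg$input_size || ncol(image) != cfg$input_size) {
    stop(sprintf("input must be %d x %d", cfg$input_size, cfg$input_size),
         call. = FALSE)
  }
  tok <- patch_partition(image, cfg$patch_size)
  x <- ad_add(ad_add(ad_mm(tok, P$patch.W), P$patch.b), P$patch.pos)
  stages <- vector("list", length(cfg$depths))
  for (s in seq_along(cfg$depths)) {
    C <- cfg$dims[s]
    for (b in seq_len(cfg$depths[s])) {
      mask <- if (b %% 2L == 1L) model$masks[[s]]$plain
              else model$masks[[s]]$shifted
      x <- swin_block(x, C, cfg$heads[s], mask,
                      sprintf("stage%d.block%d", s, b), P)
    }
    stages[[s]] <- x
    if (s < length(cfg$depths)) {
      mi <- model$merges[[s]]
      cat4 <- ad_cbind(list(ad_rows(x, mi$i00), ad_rows(x, mi$i01),
                            ad_rows(x, mi$i10), ad_rows(x, mi$i11)))
      pfx <- sprintf("merge%d", s)
      cat4 <- ad_layernorm(cat4, P[[paste0(pfx, ".ln.g")]],
                           P[[paste0(pfx, ".ln.b")]])
      x <- ad_mm(cat4, P[[paste0(pfx, ".W")]])
    }
  }
  pooled <- ad_colmeans(ad_layernorm(x, P$head.ln.g, P$head.ln.b))
  logits <- ad_add(ad_mm(pooled, P$head.W), P$head.b)
  list(stages = stages, logits = logits)
}

#' Per-stage feature maps of an image
#'
#' Runs the backbone and returns the four stage token matrices. Stage `s`
#' (1-based) has spatial side `input_size / (patch_size * 2^(s-1))` and
#' channel width `embed_dim * 2^(s-1)`.
#'
#' @param model a [build_backbone()] model.
#' @param image input image matrix.
#' @return list of `stage_tokens` matrices (tokens x channels, with a `side`
#'   attribute).
#' @export
forward_stages <- function(model, image) {
  out <- backbone_forward(model, image)
  lapply(seq_along(out$stages), function(s) {
    m <- ad_value(out$stages[[s]])
    attr(m, "side") <- model$config$sides[s]
    class(m) <- c("stage_tokens", class(m))
    m
  })
}

#' Classification logits of the backbone head
#'
#' @param model a [build_backbone()] model.
#' @param image input image matrix.
#' @return 1 x 2 logits matrix.
#' @export
backbone_logits <- function(model, image) {
  ad_value(backbone_forward(model, image)$logits)
}

#' Standalone windowed multi-head self-attention
#'
#' One attention layer over a square token grid with the given window size
#' and cyclic shift; exposes the per-head attention matrices (each row a
#' probability distribution over the tokens visible in the same window).
#' Windows larger than the grid fall back to global attention.
#'
#' @param tokens `T x C` token matrix (T a perfect square).
#' @param window_size window side in tokens.
#' @param heads number of heads (must divide C).
#' @param shift cyclic window shift in tokens.
#' @param seed seed for the random projection weights.
#' @return list with `tokens` (same shape as input) and `attention` (list of
#'   per-head `T x T` matrices).
#' @export
window_attention <- function(tokens, window_size, heads, shift = 0,
                             seed = 1L) {
  T_ <- nrow(tokens); C <- ncol(tokens)
  side <- sqrt(T_)
  if (side != round(side)) stop("token count must be a perfect square",
                                call. = FALSE)
  if (C %% heads != 0) stop("heads must divide the channel width",
                            call. = FALSE)
  mask <- window_mask(as.integer(side), window_size, shift)
  with_seed(seed, {
    Wqkv <- matrix(stats::rnorm(C * 3 * C, sd = 0.02), C, 3 * C)
    qkv <- tokens %*% Wqkv
    hd <- C %/% heads
    outs <- vector("list", heads)
    attn <- vector("list", heads)
    for (hh in seq_len(heads)) {
      cols <- ((hh - 1L) * hd + 1L):(hh * hd)
      q <- qkv[, cols, drop = FALSE]
      k <- qkv[, C + cols, drop = FALSE]
      v <- qkv[, 2 * C + cols, drop = FALSE]
      s <- q %*% t(k) / sqrt(hd)
      a <- ad_softmax_rows(s, mask)
      attn[[hh]] <- a
      outs[[hh]] <- a %*% v
    }
    list(tokens = do.call(cbind, outs), attention = attn)
  })
}

## ---- transfer learning -----------------------------------------------------

#' Apply a transfer-learning freeze policy
#'
#' Marks parameter groups as frozen; frozen parameters are skipped by the
#' optimiser and remain bit-identical across training. Valid group names are
#' `patch` (the patch-embedding projection), `stage1` ... `stage4` (optionally
#' down to `stageS.blockB`), `merge1` ... `merge3`, `head`, plus the
#' shorthands `all` and `none`. The published policy of freezing the lower
#' feature-extraction layers corresponds to `c("patch", "stage1")` (the patch
#' embedding playing the role of the lower convolutional layers).
#'
#' @param model a [build_backbone()] model.
#' @param policy character vector of group names.
#' @return model with the `frozen` field set.
#' @export
apply_freeze_policy <- function(model, policy) {
  if (length(policy) == 1L && policy == "all") {
    model$frozen <- unique(sub("\\.[^.]+$", "", names(model$params)))
    return(model)
  }
  if (length(policy) == 0L || identical(policy, "none")) {
    model$frozen <- character()
    return(model)
  }
  nms <- names(model$params)
  for (pol in policy) {
    hits <- vapply(nms, function(n) is_frozen(n, pol), logical(1))
    if (!any(hits)) stop("freeze policy matches no layer: ", pol,
                         call. = FALSE)
  }
  model$frozen <- policy
  model
}

#' Pretrain / fine-tune the backbone classifier
#'
#' Supervised training with cross-entropy, AdamW and a cosine learning-rate
#' decay after linear warmup. Frozen parameter groups are not updated.
#' Deterministic given the seed.
#'
#' @param model a [build_backbone()] model (optionally with a freeze policy).
#' @param images list of input image matrices (QC-passed).
#' @param labels integer labels (1 = normal domain, 2 = high domain).
#' @param epochs training epochs (0 returns the model unchanged).
#' @param lr peak learning rate.
#' @param batch_size gradient-accumulation batch size.
#' @param keep_best if `TRUE` (default) the returned model carries the
#'   parameters of the best epoch — lowest validation cross-entropy when a
#'   validation set is given, lowest mean training loss otherwise. Standard
#'   checkpointing; it selects the best-generalising epoch and makes a
#'   late-training instability harmless.
#' @param val_images,val_labels optional held-out set scored once per epoch
#'   for checkpoint selection.
#' @param class_weights optional per-class loss weights (`"balanced"` for
#'   inverse class frequency when fine-tuning on the imbalanced cohort);
#'   `NULL` for plain cross-entropy.
#' @param seed seed.
#' @return list with trained `model`, per-epoch loss `history`, per-epoch
#'   `val_loss` / `val_accuracy` (if applicable), and `best_epoch`.
#' @export
pretrain_transfer <- function(model, images, labels, epochs = 5, lr = 1e-3,
                              batch_size = 8, keep_best = TRUE,
                              val_images = NULL, val_labels = NULL,
                              class_weights = NULL, seed = 1L) {
  if (length(images) == 0L) stop("empty training set", call. = FALSE)
  stopifnot(length(images) == length(labels))
  if (epochs == 0L) return(list(model = model, history = numeric(0),
                                best_epoch = 0L))
  has_val <- !is.null(val_images)
  if (identical(class_weights, "balanced")) {
    freq <- tabulate(labels, nbins = 2L)
    class_weights <- ifelse(freq > 0, length(labels) / (2 * pmax(freq, 1L)),
                            0)
  }
  n <- length(images)
  state <- adamw_init(model$params)
  history <- numeric(epochs)
  val_accuracy <- if (has_val) numeric(epochs) else NULL
  val_loss <- if (has_val) numeric(epochs) else NULL
  total_steps <- epochs * ceiling(n / batch_size)
  warmup <- ceiling(n / batch_size)   # one epoch of linear warmup
  step <- 0L
  best_loss <- Inf
  best_metric <- Inf
  best_params <- model$params
  best_epoch <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      idx <- sample(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        b <- idx[start:min(start + batch_size - 1L, n)]
        step <- step + 1L
        lr_t <- if (step <= warmup) lr * step / warmup
                else lr * 0.5 * (1 + cos(pi * (step - warmup) /
                                           max(1, total_steps - warmup)))
        leaves <- lapply(model$params, ad_leaf)
        bl <- 0
        for (i in b) {
          out <- backbone_forward(model, images[[i]], P = leaves)
          loss <- ad_ce_logits(out$logits, labels[i], class_weights)
          ad_backward(loss)
          bl <- bl + loss$value
        }
        grads <- lapply(ad_grads(leaves), function(g) {
          if (is.null(g)) NULL else g / length(b)
        })
        upd <- adamw_step(model$params, grads, state, lr = lr_t,
                          weight_decay = 1e-4, frozen = model$frozen,
                          clip_norm = 1.0)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bl / length(b)
        nb <- nb + 1L
      }
      history[ep] <- ep_loss / nb
      if (has_val) {
        vl <- 0; va <- 0
        for (k in seq_along(val_images)) {
          lo <- backbone_forward(model, val_images[[k]])$logits
          p <- exp(lo - max(lo)); p <- p / sum(p)
          vl <- vl - log(max(p[val_labels[k]], 1e-12))
          va <- va + (which.max(lo) == val_labels[k])
        }
        val_loss[ep] <- vl / length(val_images)
        val_accuracy[ep] <- va / length(val_images)
        better <- val_loss[ep] < best_metric
      } else {
        better <- history[ep] < best_loss
      }
      if (better) {
        best_loss <- history[ep]
        if (has_val) best_metric <- val_loss[ep]
        best_params <- model$params
        best_epoch <- ep
      }
    }
  })
  if (keep_best) model$params <- best_params
  list(model = model, history = history, val_loss = val_loss,
       val_accuracy = val_accuracy, best_epoch = best_epoch)
}

#' Pooled hierarchical features for fusion
#'
#' Runs the backbone on each image and concatenates the global-average-pooled
#' token features of the selected stages (default: the final two stages).
#'
#' @param model a [build_backbone()] model.
#' @param images list of image matrices.
#' @param stages 1-based stage indices to pool.
#' @return `length(images) x D` feature matrix.
#' @export
extract_features <- function(model, images, stages = NULL) {
  cfg <- model$config
  ns <- length(cfg$depths)
  stages <- stages %||% c(ns - 1L, ns)
  D <- sum(cfg$dims[stages])
  out <- matrix(0, length(images), D)
  for (i in seq_along(images)) {
    st <- forward_stages(model, images[[i]])
    out[i, ] <- unlist(lapply(st[stages], gap_pool))
  }
  out
}

#' Save / load a backbone checkpoint
#'
#' The checkpoint embeds the configuration, parameters and freeze state.
#'
#' @param model a `backbone_model`.
#' @param path file path.
#' @export
save_backbone <- function(model, path) {
  saveRDS(list(config = unclass(model$config), params = model$params,
               frozen = model$frozen), path)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(backbone_config, ck$config[c("input_size", "patch_size",
                                              "depths", "heads",
                                              "window_size", "embed_dim",
                                              "mlp_ratio")])
  model <- build_backbone(cfg, seed = 0L)
  model$params <- ck$params
  model$frozen <- ck$frozen
  model
}
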