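# Grad-CAM region attribution.
#
# Class activation maps for the windowed-attention backbone: the gradient of
# a class logit is backpropagated to a chosen stage's token features, channel
# weights are the spatial mean of those gradients, and the rectified
# weighted channel sum — reshaped to the stage's token grid, bilinearly
# upsampled to the input size and max-normalized — highlights the image
# regions driving the prediction. On phantoms the rendering ground truth
# provides exact region masks, so attribution can be scored quantitatively.

#' Grad-CAM heatmap for a backbone prediction
#'
#' @param model a [build_backbone()] model (with its classification head).
#' @param image input image matrix.
#' @param target_class class index (1 = normal, 2 = high); defaults to the
#'   predicted class.
#' @param stage 1-based stage index, or `"auto"` (deepest stage whose token
#'   grid side is at least 7, so the map retains enough spatial resolution
#'   to localize; at the 224 px reference geometry this is the final stage,
#'   at the 64 px tiny preset stage 2).
#' @return object of class `heatmap`: list with `map` (H x W in `[0,1]`,
#'   all-zero when the class score has zero gradient everywhere), `stage`,
#'   `target_class`.
#' @export
grad_cam <- function(model, image, target_class = NULL, stage = "auto") {
  cfg <- model$config
  if (identical(stage, "auto")) {
    ok <- which(cfg$sides >= 7)
    stage <- if (length(ok) > 0) max(ok) else 1L
  }
  stopifnot(stage >= 1, stage <= length(cfg$sides))
  leaves <- lapply(model$params, ad_leaf)
  out <- backbone_forward(model, image, P = leaves)
  logits <- ad_value(out$logits)
  if (is.null(target_class)) target_class <- which.max(logits)
  score <- ad_cols(out$logits, target_class)
  ad_backward(score)
  node <- out$stages[[stage]]
  A <- ad_value(node)
  G <- node$grad
  side <- cfg$sides[stage]
  map <- if (is.null(G)) {
    matrix(0, side, side)
  } else {
    w <- colMeans(G)
    cam <- pmax(A %*% w, 0)
    matrix(cam, side, side, byrow = TRUE)   # tokens are row-major
  }
  up <- upsample_bilinear(map, nrow(image), ncol(image))
  mx <- max(up)
  if (mx > 0) up <- up / mx
  structure(list(map = up, stage = stage, target_class = target_class),
            class = "heatmap")
}

# bilinear upsampling of a small matrix to H x W (align-corners style)
upsample_bilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == 1L && w == 1L) return(matrix(m[1, 1], H, W))
  ry <- if (h > 1) (seq_len(H) - 1) * (h - 1) / (H - 1) else rep(0, H)
  rx <- if (w > 1) (seq_len(W) - 1) * (w - 1) / (W - 1) else rep(0, W)
  y0 <- pmin(floor(ry), h - 2); x0 <- pmin(floor(rx), w - 2)
  fy <- ry - y0; fx <- rx - x0
  out <- matrix(0, H, W)
  for (j in seq_len(W)) {
    c0 <- m[, x0[j] + 1L]; c1 <- m[, x0[j] + 2L]
    col0 <- c0[y0 + 1L] * (1 - fy) + c0[y0 + 2L] * fy
    col1 <- c1[y0 + 1L] * (1 - fy) + c1[y0 + 2L] * fy
    out[, j] <- col0 * (1 - fx[j]) + col1 * fx[j]
  }
  out
}

#' Per-region heatmap mass fractions
#'
#' For each heatmap, the fraction of total heatmap mass falling inside each
#' named region mask; fractions over disjoint regions sum to at most 1, the
#' remainder being background. An all-zero heatmap yields zero fractions.
#' Fractions are invariant to rescaling the heatmap.
#'
#' @param heatmaps a `heatmap`, or list of them (or plain matrices).
#' @param masks a named list of logical mask matrices (applied to every
#'   heatmap), or a list of such lists, one per heatmap.
#' @return matrix: one row per heatmap, one column per region.
#' @export
attribution_report <- function(heatmaps, masks) {
  if (inherits(heatmaps, "heatmap") || is.matrix(heatmaps)) {
    heatmaps <- list(heatmaps)
  }
  per_image_masks <- is.list(masks) && length(masks) == length(heatmaps) &&
    is.list(masks[[1]]) && !is.matrix(masks[[1]])
  get_masks <- function(i) if (per_image_masks) masks[[i]] else masks
  region_names <- names(get_masks(1L))
  if (is.null(region_names)) stop("masks must be named", call. = FALSE)
  out <- matrix(0, length(heatmaps), length(region_names),
                dimnames = list(NULL, region_names))
  for (i in seq_along(heatmaps)) {
    h <- heatmaps[[i]]
    hm <- if (inherits(h, "heatmap")) h$map else h
    ms <- get_masks(i)
    tot <- sum(hm)
    for (r in region_names) {
      mk <- ms[[r]]
      if (!all(dim(mk) == dim(hm))) {
        stop("mask and heatmap shapes differ", call. = FALSE)
      }
      out[i, r] <- if (tot == 0) 0 else sum(hm[mk]) / tot
    }
  }
  out
}

#' Write heatmap overlays as PNG
#'
#' @param heatmap a `heatmap` object.
#' @param image the underlying image matrix.
#' @param path output PNG path.
#' @param alpha overlay strength in `[0,1]`.
#' @export
write_heatmap_png <- function(heatmap, image, path, alpha = 0.5) {
  h <- heatmap$map
  rgb <- array(0, dim = c(nrow(image), ncol(image), 3L))
  rgb[, , 1] <- clip01(image * (1 - alpha) + h * alpha)
  rgb[, , 2] <- clip01(image * (1 - alpha))
  rgb[, , 3] <- clip01(image * (1 - alpha) + (1 - h) * alpha * 0.3)
  png::writePNG(rgb, path)
  invisible(path)
}
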