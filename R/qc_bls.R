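# Broad Learning System (BLS) quality monitor.
#
# A BLS is a flat network: random sigmoid feature nodes on the input, random
# sigmoid enhancement nodes on the feature nodes, and a ridge-regression
# output layer solved in closed form. Only the output weights are ever fitted;
# the random mappings are fixed at construction, which is what makes the
# incremental addition of enhancement nodes (a block-inverse update of the
# ridge normal equations) possible without retraining. Here the BLS regresses
# an image-quality score in [0,1] used to gate augmented images at a
# threshold T (default 0.7, boundary inclusive).

#' Construct an (unfitted) BLS model
#'
#' @param input_dim dimension of flattened image features.
#' @param m number of feature nodes (>= 1; the reference configuration uses
#'   1000).
#' @param p number of enhancement nodes (>= 0; reference 600).
#' @param lambda ridge penalty (>= 0).
#' @param threshold quality gate threshold T.
#' @param enh_only if `TRUE` the ridge layer sees only the enhancement nodes;
#'   the default regresses on the concatenated feature + enhancement nodes as
#'   in the standard BLS.
#' @param gain scale of the random feature weights (sd = gain / sqrt(d)).
#' @param seed seed for the fixed random mappings.
#' @return object of class `bls_model` (unfitted).
#' @export
bls_model <- function(input_dim, m = 1000, p = 600, lambda = 1e-2,
                      threshold = 0.7, enh_only = FALSE, gain = 4,
                      seed = 1L) {
  stopifnot(m >= 1, p >= 0, lambda >= 0, input_dim >= 1)
  with_seed(seed, {
    structure(list(
      input_dim = input_dim, m = m, p = p,
      lambda = lambda, threshold = threshold, enh_only = enh_only,
      Wf = matrix(stats::rnorm(input_dim * m, sd = gain / sqrt(input_dim)),
                  input_dim, m),
      bf = stats::runif(m, -1, 1),
      We = if (p > 0) matrix(stats::rnorm(m * p, sd = 2 / sqrt(m)), m, p)
           else matrix(0, m, 0),
      be = if (p > 0) stats::runif(p, -1, 1) else numeric(0),
      beta = NULL, Ginv = NULL, train = NULL
    ), class = "bls_model")
  })
}

#' Map samples through the random feature and enhancement nodes
#'
#' `H = sigma(X Wf + bf)`, `E = sigma(H We + be)`; the design matrix is
#' `[H E]` (or `E` alone under `enh_only`). Sigmoid keeps every node output
#' in (0, 1).
#'
#' @param model a [bls_model()].
#' @param X sample matrix, one row per sample.
#' @return list with `H`, `E` and the ridge design matrix `Z`.
#' @export
bls_map_features <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$input_dim) {
    stop(sprintf("input dimension %d does not match model (%d)",
                 ncol(X), model$input_dim), call. = FALSE)
  }
  H <- sigmoid(sweep(X %*% model$Wf, 2L, model$bf, "+"))
  E <- if (model$p > 0) {
    sigmoid(sweep(H %*% model$We, 2L, model$be, "+"))
  } else matrix(0, nrow(X), 0)
  Z <- if (model$enh_only) E else cbind(H, E)
  list(H = H, E = E, Z = Z)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Solve the ridge output weights
#'
#' Solves `(Z'Z + lambda I) beta = Z'y`. With `lambda = 0` and a
#' rank-deficient design the minimum-norm pseudoinverse solution is returned
#' (SVD fallback).
#'
#' @param Z design matrix.
#' @param y regression targets.
#' @param lambda ridge penalty (>= 0).
#' @return coefficient vector.
#' @export
ridge_solve <- function(Z, y, lambda) {
  stopifnot(nrow(Z) == length(y), lambda >= 0)
  if (lambda > 0) {
    G <- crossprod(Z) + diag(lambda, ncol(Z))
    return(drop(solve(G, crossprod(Z, y))))
  }
  out <- tryCatch(drop(solve(crossprod(Z), crossprod(Z, y))),
                  error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd(Z)
  keep <- s$d > max(dim(Z)) * .Machine$double.eps * s$d[1]
  drop(s$v[, keep, drop = FALSE] %*%
         ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep]))
}

#' Fit the BLS output weights on training images/targets
#'
#' @param model a [bls_model()].
#' @param X feature matrix (rows = samples), e.g. from [image_features()].
#' @param y quality targets in `[0,1]` (1 = clean).
#' @return fitted model (caches the training design for incremental updates).
#' @export
bls_fit <- function(model, X, y) {
  maps <- bls_map_features(model, X)
  Z <- maps$Z
  model$beta <- ridge_solve(Z, y, model$lambda)
  model$Ginv <- if (model$lambda > 0) {
    solve(crossprod(Z) + diag(model$lambda, ncol(Z)))
  } else NULL
  model$train <- list(H = maps$H, Z = Z, y = y)
  model
}

#' Incrementally add enhancement nodes
#'
#' Widens the network by `delta_p` new random enhancement nodes and refits the
#' output weights with a block-inverse (Schur complement) update of the ridge
#' normal equations, using the cached training design — the defining BLS
#' operation: no retraining of existing nodes. The result is identical (to
#' numerical precision) to a full refit with the same random nodes, and the
#' training MSE never increases.
#'
#' @param model a fitted [bls_model()].
#' @param delta_p number of nodes to add (>= 0).
#' @param seed seed for the new random mappings.
#' @return updated fitted model.
#' @export
add_enhancement_nodes <- function(model, delta_p, seed = 1L) {
  stopifnot(delta_p >= 0)
  if (is.null(model$beta)) stop("model is not fitted", call. = FALSE)
  if (delta_p == 0L) return(model)
  tr <- model$train
  with_seed(seed, {
    We2 <- matrix(stats::rnorm(model$m * delta_p, sd = 2 / sqrt(model$m)),
                  model$m, delta_p)
    be2 <- stats::runif(delta_p, -1, 1)
    B <- sigmoid(sweep(tr$H %*% We2, 2L, be2, "+"))
    A <- tr$Z
    lambda <- model$lambda
    if (!is.null(model$Ginv)) {
      Ainv <- model$Ginv
      AtB <- crossprod(A, B)
      S <- crossprod(B) + diag(lambda, delta_p) - crossprod(AtB, Ainv %*% AtB)
      Sinv <- solve(S)
      U <- Ainv %*% AtB             # k x delta_p
      TL <- Ainv + U %*% Sinv %*% t(U)
      TR <- -U %*% Sinv
      Ginv_new <- rbind(cbind(TL, TR), cbind(t(TR), Sinv))
      rhs <- c(crossprod(A, tr$y), crossprod(B, tr$y))
      beta <- drop(Ginv_new %*% rhs)
      # the sigmoid design is ill-conditioned; two iterative-refinement
      # steps restore the accuracy lost by the explicit block inverse
      G_new <- rbind(cbind(crossprod(A) + diag(lambda, ncol(A)), AtB),
                     cbind(t(AtB), crossprod(B) + diag(lambda, delta_p)))
      for (it in 1:2) {
        beta <- beta + drop(Ginv_new %*% (rhs - G_new %*% beta))
      }
      model$Ginv <- Ginv_new
    } else {
      Z_new <- cbind(A, B)
      beta <- ridge_solve(Z_new, tr$y, lambda)
    }
    model$We <- cbind(model$We, We2)
    model$be <- c(model$be, be2)
    model$p <- model$p + delta_p
    model$beta <- beta
    model$train$Z <- cbind(A, B)
    model
  })
}

#' Quality score of images under a fitted BLS
#'
#' Computes the paired-difference representation of each (image, reference)
#' pair, pushes it through the fixed random nodes and applies the fitted
#' ridge weights; scores are clipped to `[0,1]` so the 0.7 gate threshold is
#' meaningful. A precomputed feature matrix may be passed as `images` (with
#' `references = NULL`).
#'
#' @param model a fitted [bls_model()].
#' @param images a list of image matrices, or a precomputed feature matrix.
#' @param references list of paired source images (required when `images`
#'   are matrices).
#' @param feature_size side length for image downsampling (default 32).
#' @return numeric score per image.
#' @export
bls_score <- function(model, images, references = NULL, feature_size = 32) {
  if (is.null(model$beta)) stop("model is not fitted", call. = FALSE)
  X <- if (is.matrix(images) && !is.list(images) &&
           ncol(images) == model$input_dim) {
    images
  } else {
    if (is.null(references)) {
      stop("`references` are required to score images", call. = FALSE)
    }
    quality_features(images, references, feature_size)
  }
  Z <- bls_map_features(model, X)$Z
  clip01(drop(Z %*% model$beta))
}

#' Paired-difference quality features
#'
#' Flattened `size x size` downsample of the absolute difference between each
#' generated image and its paired source, the input representation of the
#' quality regression.
#'
#' @param images,references lists of image matrices of equal size.
#' @param size downsampling side length.
#' @return matrix, one row per pair.
#' @export
quality_features <- function(images, references, size = 32) {
  stopifnot(length(images) == length(references))
  diffs <- mapply(function(a, b) abs(a - b), images, references,
                  SIMPLIFY = FALSE)
  image_features(diffs, size)
}

#' Threshold a quality score
#'
#' High quality iff `score >= threshold` (boundary inclusive).
#'
#' @param score numeric score(s).
#' @param threshold gate threshold T (default 0.7).
#' @return logical vector.
#' @export
classify_quality <- function(score, threshold = 0.7) {
  score >= threshold
}

#' Flattened downsampled image features
#'
#' Downsamples each image to `size x size` (block mean when the dimensions
#' divide evenly, bilinear resize otherwise) and flattens, giving the BLS a
#' tractable fixed-width input.
#'
#' @param images list of image matrices (or a single matrix).
#' @param size target side length.
#' @return matrix, one row per image.
#' @export
image_features <- function(images, size = 32) {
  if (is.matrix(images)) images <- list(images)
  t(vapply(images, function(im) {
    as.numeric(downsample_image(im, size))
  }, numeric(size * size)))
}

downsample_image <- function(im, size) {
  H <- nrow(im); W <- ncol(im)
  if (H == size && W == size) return(im)
  if (H %% size == 0 && W %% size == 0) {
    fh <- H / size; fw <- W / size
    rg <- rep(seq_len(size), each = fh)
    cg <- rep(seq_len(size), each = fw)
    out <- rowsum(im, rg)
    out <- t(rowsum(t(out), cg)) / (fh * fw)
    return(out)
  }
  matrix(as.numeric(EBImage::resize(im, w = size, h = size)), size, size)
}

#' Quality training target from a paired reference
#'
#' The published pipeline gates generated images by a similarity score against
#' the paired real image without defining the similarity; here the target is
#' the Pearson (normalized cross-) correlation between image and reference,
#' mapped to `[0,1]`, and scaled down by `1 - magnitude` for samples carrying
#' an injected artifact of known magnitude, making the target monotone in
#' corruption.
#'
#' @param image,reference image matrices of equal size.
#' @param magnitude known artifact magnitude in `[0,1]` (0 for clean).
#' @return scalar target in `[0,1]`.
#' @export
quality_target <- function(image, reference, magnitude = 0) {
  ncc <- suppressWarnings(stats::cor(as.numeric(image), as.numeric(reference)))
  if (!is.finite(ncc)) ncc <- 0
  clip01(((ncc + 1) / 2) * (1 - magnitude))
}

#' Train a BLS quality gate on labelled phantoms
#'
#' @param images list of (possibly corrupted) images.
#' @param references list of paired clean images.
#' @param magnitudes artifact magnitude per image (0 = clean).
#' @param m,p,lambda,threshold,enh_only,gain BLS hyperparameters.
#' @param seed seed for the random mappings.
#' @param feature_size image downsampling side.
#' @return fitted `bls_model`.
#' @export
bls_quality_fit <- function(images, references, magnitudes,
                            m = 1000, p = 600, lambda = 1e-2, threshold = 0.7,
                            enh_only = FALSE, gain = 4, seed = 1L,
                            feature_size = 32) {
  stopifnot(length(images) == length(references),
            length(images) == length(magnitudes))
  y <- mapply(quality_target, images, references, magnitudes)
  X <- quality_features(images, references, feature_size)
  model <- bls_model(ncol(X), m = m, p = p, lambda = lambda,
                     threshold = threshold, enh_only = enh_only, gain = gain,
                     seed = seed)
  bls_fit(model, X, y)
}

## ---- geometric integrity screening ----------------------------------------

#' Canny-style geometric integrity check
#'
#' Screens an anterior-segment image for the structural failure modes of
#' low-quality generated samples: a missing corneal contour, a discontinuous
#' corneal band (an interior run of columns with no bright-band pixel), and
#' saturated regions above an area threshold. Edge pixels are extracted with
#' a Gaussian-smoothed Sobel gradient and thresholded; connected edge
#' components are counted as a diagnostic.
#'
#' @param image H x W matrix in `[0,1]`.
#' @param band_intensity minimum intensity regarded as corneal band.
#' @param saturation_area_frac flag saturated regions above this area
#'   fraction.
#' @return list with `flags` (character vector, possibly empty),
#'   `n_edge_components`, and `bright_column_fraction`.
#' @export
edge_integrity_check <- function(image, band_intensity = 0.55,
                                 saturation_area_frac = 0.005) {
  stopifnot_image(image)
  flags <- character(0)
  if (stats::sd(image) < 1e-6) {
    return(list(flags = "missing_contour", n_edge_components = 0L,
                bright_column_fraction = 0))
  }
  sm <- matrix(as.numeric(EBImage::gblur(image, sigma = 1)),
               nrow(image), ncol(image))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- matrix(as.numeric(EBImage::filter2(sm, kx)), nrow(sm), ncol(sm))
  gy <- matrix(as.numeric(EBImage::filter2(sm, t(kx))), nrow(sm), ncol(sm))
  mag <- sqrt(gx^2 + gy^2)
  edges <- mag > 0.25 * max(mag)
  ncomp <- max(EBImage::bwlabel(edges))

  bright_cols <- apply(image > band_intensity, 2L, any)
  frac <- mean(bright_cols)
  if (!any(bright_cols)) {
    flags <- c(flags, "missing_contour")
  } else {
    runs <- rle(bright_cols)
    interior <- seq_along(runs$values) > 1 &
      seq_along(runs$values) < length(runs$values)
    if (any(!runs$values & runs$lengths >= 2 & interior)) {
      flags <- c(flags, "edge_discontinuity")
    }
  }
  if (mean(image >= 0.98) > saturation_area_frac) {
    flags <- c(flags, "saturated_region")
  }
  list(flags = flags, n_edge_components = as.integer(ncomp),
       bright_column_fraction = frac)
}

#' Gate a set of images through BLS score + integrity screening
#'
#' The full quality gate of the pipeline: an image passes iff its BLS
#' regression score reaches the threshold T *and* the Canny-style integrity
#' screen raises no flag.
#'
#' @param model fitted `bls_model`.
#' @param images list of images.
#' @param references list of paired source images.
#' @param threshold gate threshold (defaults to the model's).
#' @param check_integrity also require an empty integrity-flag set.
#' @return data.frame with `score`, `is_high_quality` and `flags` per image.
#' @export
qc_gate <- function(model, images, references, threshold = NULL,
                    check_integrity = TRUE) {
  threshold <- threshold %||% model$threshold
  scores <- bls_score(model, images, references)
  pass <- classify_quality(scores, threshold)
  flags <- character(length(images))
  if (check_integrity) {
    for (i in seq_along(images)) {
      fl <- edge_integrity_check(images[[i]])$flags
      flags[i] <- paste(fl, collapse = ";")
      if (length(fl) > 0L) pass[i] <- FALSE
    }
  }
  data.frame(score = scores, is_high_quality = pass, flags = flags,
             stringsAsFactors = FALSE)
}
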