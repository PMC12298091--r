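# Kolmogorov-Arnold (KAN) fusion head.
#
# A KAN layer places a learnable univariate function on every edge and sums
# on nodes: out_j(x) = sum_i lambda_ij * phi_ij(x_i), with each phi_ij a
# B-spline expansion sum_k alpha_ijk B_k(x_i) on a fixed knot grid. The
# basis is evaluated by the Cox-de Boor recursion, implemented here together
# with its analytic derivative because backpropagation needs d phi / d x at
# the layer input. The fusion head standardizes six structural clinical
# attributes, projects image and clinical branches to a common width, takes
# a convex (simplex-constrained) modality-weighted sum, and classifies the
# fused vector with a KAN layer.

## ---- B-spline basis --------------------------------------------------------

# clamped uniform knot vector giving exactly K basis functions
bspline_knots <- function(K, degree, range = c(0, 1)) {
  stopifnot(K >= degree + 1, range[2] > range[1])
  interior <- seq(range[1], range[2], length.out = K - degree + 1)
  c(rep(range[1], degree), interior, rep(range[2], degree))
}

#' B-spline basis matrix (Cox-de Boor)
#'
#' Evaluates the `K` clamped B-spline basis functions of the given degree on
#' a uniform knot grid over `range`. Values outside the range are clamped to
#' the boundary. Inside the range the basis is a partition of unity
#' (non-negative, sums to 1) with local support (at most degree + 1 nonzero
#' functions per point).
#'
#' @param x evaluation points.
#' @param K number of basis functions (>= degree + 1).
#' @param degree spline degree (>= 0; default cubic).
#' @param range support interval.
#' @return `length(x) x K` matrix of basis values.
#' @export
bspline_basis <- function(x, K, degree = 3, range = c(0, 1)) {
  knots <- bspline_knots(K, degree, range)
  x <- pmin(pmax(x, range[1]), range[2])
  cox_de_boor(x, knots, degree)
}

cox_de_boor <- function(x, knots, degree) {
  n <- length(x)
  ncell <- length(knots) - 1L
  B <- matrix(0, n, ncell)
  for (j in seq_len(ncell)) {
    if (knots[j] < knots[j + 1]) {
      B[, j] <- as.numeric(x >= knots[j] & x < knots[j + 1])
    }
  }
  b <- knots[length(knots)]
  lastcell <- max(which(knots < b))
  B[x >= b, lastcell] <- 1
  if (degree == 0) return(B)
  for (d in seq_len(degree)) {
    Bn <- matrix(0, n, ncell - d)
    for (j in seq_len(ncell - d)) {
      den1 <- knots[j + d] - knots[j]
      den2 <- knots[j + d + 1] - knots[j + 1]
      t1 <- if (den1 > 0) (x - knots[j]) / den1 * B[, j] else 0
      t2 <- if (den2 > 0) (knots[j + d + 1] - x) / den2 * B[, j + 1] else 0
      Bn[, j] <- t1 + t2
    }
    B <- Bn
  }
  B
}

#' Derivative of the B-spline basis
#'
#' Analytic first derivative of [bspline_basis()] with respect to `x`,
#' using the standard degree-lowering identity.
#'
#' @inheritParams bspline_basis
#' @return `length(x) x K` matrix of derivative values.
#' @export
bspline_basis_deriv <- function(x, K, degree = 3, range = c(0, 1)) {
  if (degree == 0) return(matrix(0, length(x), K))
  knots <- bspline_knots(K, degree, range)
  x <- pmin(pmax(x, range[1]), range[2])
  Blow <- cox_de_boor(x, knots, degree - 1L)  # length(x) x (K + 1)
  D <- matrix(0, length(x), K)
  for (j in seq_len(K)) {
    den1 <- knots[j + degree] - knots[j]
    den2 <- knots[j + degree + 1] - knots[j + 1]
    t1 <- if (den1 > 0) degree / den1 * Blow[, j] else 0
    t2 <- if (den2 > 0) degree / den2 * Blow[, j + 1] else 0
    D[, j] <- t1 - t2
  }
  D
}

# autodiff wrapper: x is an N x 1 node (already clamped into `range`);
# returns the N x K basis with backward through the analytic derivative
ad_bspline <- function(x, K, degree, range) {
  xv <- as.numeric(ad_value(x))
  B <- bspline_basis(xv, K, degree, range)
  if (!is_ad(x)) return(B)
  ad_node(B, list(x), function(g) {
    D <- bspline_basis_deriv(xv, K, degree, range)
    ad_accum(x, matrix(rowSums(g * D), ncol = 1L))
  })
}

# least-squares spline coefficients for a target function sample
#' @export
bspline_fit <- function(x, y, K, degree = 3, range = c(0, 1)) {
  B <- bspline_basis(x, K, degree, range)
  qr.coef(qr(B), y)
}

## ---- KAN layer -------------------------------------------------------------

#' Construct a KAN layer
#'
#' `n_in` inputs, `n_out` additive output nodes; every edge (i, j) carries a
#' learnable spline `phi_ij` with `K` coefficients, plus an outer weight
#' `lambda_ij`. Coefficients start near zero so the initial map is gentle.
#'
#' @param n_in,n_out layer widths.
#' @param K number of spline basis functions per edge.
#' @param degree spline degree.
#' @param range input domain covered by the knot grid; inputs are clamped
#'   into it.
#' @param seed seed for initialisation.
#' @return object of class `kan_layer` with a named parameter list.
#' @export
kan_layer <- function(n_in, n_out = 1L, K = 16, degree = 3,
                      range = c(-3, 3), seed = 1L) {
  stopifnot(K >= degree + 1)
  with_seed(seed, {
    params <- list()
    for (i in seq_len(n_in)) {
      params[[paste0("alpha.", i)]] <-
        matrix(stats::rnorm(K * n_out, sd = 0.1), K, n_out)
    }
    params$lambda <- matrix(1, n_in, n_out)
    structure(list(n_in = n_in, n_out = n_out, K = K, degree = degree,
                   range = range, params = params),
              class = "kan_layer")
  })
}

#' KAN layer forward map
#'
#' `out[, j] = sum_i lambda[i, j] * B(x_i) %*% alpha_i[, j]` — linear in both
#' `alpha` and `lambda`. Accepts plain matrices (inference) or autodiff nodes
#' (training); inputs are clamped into the knot-grid domain.
#'
#' @param layer a [kan_layer()].
#' @param X `N x n_in` input matrix (or `ad_node`).
#' @param params optional named parameter list (e.g. autodiff leaves)
#'   overriding the layer's own.
#' @return `N x n_out` matrix (or node).
#' @export
kan_forward <- function(layer, X, params = NULL) {
  params <- params %||% layer$params
  n_in <- layer$n_in
  out <- NULL
  for (i in seq_len(n_in)) {
    xi <- ad_clamp(ad_cols(X, i), layer$range[1], layer$range[2])
    Bi <- ad_bspline(xi, layer$K, layer$degree, layer$range)
    phi <- ad_mm(Bi, params[[paste0("alpha.", i)]])
    lam_i <- ad_rows_of(params$lambda, i)
    contrib <- ad_rowmul(phi, lam_i)
    out <- if (is.null(out)) contrib else ad_add(out, contrib)
  }
  out
}

# row i of a (possibly node) matrix as a 1 x C row vector
ad_rows_of <- function(m, i) {
  if (is_ad(m)) ad_rows(m, i) else m[i, , drop = FALSE]
}

#' Fit a univariate function with a single-edge KAN
#'
#' Gradient training (Adam, mean-squared error) of the spline coefficients of
#' a 1-input KAN on samples of a univariate target; used to demonstrate
#' function recovery.
#'
#' @param x,y training samples.
#' @param K,degree,range spline configuration.
#' @param steps gradient steps.
#' @param lr learning rate.
#' @param seed seed.
#' @return list with the trained `layer` and the loss `history`.
#' @export
kan_fit_univariate <- function(x, y, K = 16, degree = 3, range = c(0, 1),
                               steps = 200, lr = 0.05, seed = 1L) {
  layer <- kan_layer(1L, 1L, K = K, degree = degree, range = range,
                     seed = seed)
  X <- matrix(x, ncol = 1L)
  Y <- matrix(y, ncol = 1L)
  state <- adamw_init(layer$params)
  history <- numeric(steps)
  for (s in seq_len(steps)) {
    leaves <- lapply(layer$params, ad_leaf)
    pred <- kan_forward(layer, X, params = leaves)
    loss <- ad_mean(ad_square(ad_sub(pred, Y)))
    ad_backward(loss)
    upd <- adamw_step(layer$params, ad_grads(leaves), state, lr = lr)
    layer$params <- upd$params
    state <- upd$state
    history[s] <- loss$value
  }
  list(layer = layer, history = history)
}

## ---- adaptive grid refinement ----------------------------------------------

#' Gradient-driven knot allocation
#'
#' Splits the image into a regular grid of regions, measures the mean
#' gradient magnitude (finite differences) per region and allocates a total
#' knot budget proportionally: regions with larger gradients — edges of the
#' cornea and chamber — receive more knots. Allocation is by proportional
#' floors with the remaining knots going to the highest-gradient regions,
#' which conserves the budget exactly and is monotone in regional gradient.
#' A constant image yields the uniform allocation.
#'
#' @param image H x W matrix.
#' @param budget total number of knots (>= number of regions).
#' @param regions `c(rows, cols)` of the region grid.
#' @return list with `allocation` (matrix, sums to `budget`) and
#'   `gradient` (regional mean gradient magnitudes).
#' @export
refine_grid <- function(image, budget, regions = c(4, 4)) {
  stopifnot_image(image)
  nr <- regions[1]; nc <- regions[2]
  if (budget < nr * nc) {
    stop("budget must be at least the number of regions", call. = FALSE)
  }
  H <- nrow(image); W <- ncol(image)
  gx <- cbind(abs(image[, -1] - image[, -W]), 0)
  gy <- rbind(abs(image[-1, ] - image[-H, ]), 0)
  mag <- sqrt(gx^2 + gy^2)
  ridx <- ceiling(seq_len(H) / (H / nr))
  cidx <- ceiling(seq_len(W) / (W / nc))
  gm <- rowsum(t(rowsum(mag, ridx)), cidx)  # nc x nr of sums
  counts <- rowsum(t(rowsum(matrix(1, H, W), ridx)), cidx)
  g <- t(gm / counts)                        # nr x nc mean gradient
  w <- as.numeric(g)
  if (sum(w) <= 0) w <- rep(1, length(w))
  share <- budget * w / sum(w)
  alloc <- floor(share)
  rem <- budget - sum(alloc)
  if (rem > 0) {
    ord <- order(w, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  list(allocation = matrix(as.integer(alloc), nr, nc),
       gradient = g)
}

## ---- pooling and standardization -------------------------------------------

#' Global average pooling
#'
#' Per-channel spatial mean: a plain H x W matrix pools to a scalar, an
#' H x W x C array to a length-C vector, and a tokens-by-channels matrix of
#' class `stage_tokens` (backbone stage features) to a length-C vector.
#'
#' @param feature_map matrix, 3-d array, or stage-token matrix.
#' @return scalar or numeric vector.
#' @export
gap_pool <- function(feature_map) {
  if (length(feature_map) == 0L) stop("empty feature map", call. = FALSE)
  if (inherits(feature_map, "stage_tokens")) {
    return(colMeans(unclass(feature_map)))
  }
  if (is.array(feature_map) && length(dim(feature_map)) == 3L) {
    return(apply(feature_map, 3L, mean))
  }
  mean(feature_map)
}

#' Names of the six structural clinical attributes used for fusion
#'
#' Pupil-center thickness, corneal-vertex thickness, corneal volume, anterior
#' chamber depth, anterior chamber volume and corneal diameter — age and IOP
#' (the label source) are excluded so the label cannot leak through the
#' clinical branch.
#' @export
clinical_feature_names <- function() {
  c("pupil_center_thickness", "corneal_vertex_thickness", "corneal_volume",
    "anterior_chamber_depth", "anterior_chamber_volume", "corneal_diameter")
}

#' Fit a clinical standardizer on a training table
#'
#' @param table data.frame containing the six structural attributes.
#' @return list with `mu` and `sigma` per attribute.
#' @export
clinical_standardizer <- function(table) {
  nms <- clinical_feature_names()
  missing <- setdiff(nms, colnames(table))
  if (length(missing) > 0L) {
    stop("table lacks clinical columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(table[, nms])
  list(mu = colMeans(X), sigma = apply(X, 2L, stats::sd))
}

#' Standardize the six structural clinical attributes
#'
#' `(x - mu) / sigma` elementwise, with training-set statistics.
#'
#' @param x matrix or data.frame of the six attributes (or a 6-vector).
#' @param mu,sigma standardization statistics (sigma strictly positive).
#' @return standardized matrix.
#' @export
standardize_clinical <- function(x, mu, sigma) {
  if (any(sigma <= 0)) {
    bad <- names(sigma)[sigma <= 0] %||% which(sigma <= 0)
    stop("degenerate (zero-variance) clinical attribute: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.data.frame(x)) x <- as.matrix(x[, clinical_feature_names()])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  sweep(sweep(x, 2L, mu, "-"), 2L, sigma, "/")
}

## ---- fusion head -----------------------------------------------------------

#' Construct the multimodal fusion head
#'
#' Projects the pooled image-feature vector and the standardized clinical
#' vector to a common width, combines them with learnable simplex-constrained
#' modality weights (softmax of two free parameters, so the weights stay
#' nonnegative and sum to one throughout training), and classifies the fused
#' vector with a KAN layer into 2 logits.
#'
#' @param d_image dimension of the pooled image features.
#' @param d_clinical dimension of the clinical vector (0 for image-only).
#' @param width common projection width.
#' @param K,degree,range KAN spline configuration.
#' @param seed seed for initialisation.
#' @return object of class `fusion_head`.
#' @export
fusion_head <- function(d_image, d_clinical = 6L, width = 8L, K = 16,
                        degree = 3, range = c(-3, 3), seed = 1L) {
  with_seed(seed, {
    params <- list(
      proj_img.W = matrix(stats::rnorm(d_image * width,
                                       sd = 1 / sqrt(d_image)),
                          d_image, width),
      proj_img.b = matrix(0, 1L, width)
    )
    if (d_clinical > 0L) {
      params$proj_clin.W <- matrix(stats::rnorm(d_clinical * width,
                                                sd = 1 / sqrt(d_clinical)),
                                   d_clinical, width)
      params$proj_clin.b <- matrix(0, 1L, width)
      params$fuse.raw <- matrix(0, 1L, 2L)
    }
    kan <- kan_layer(width, 2L, K = K, degree = degree, range = range,
                     seed = child_seed(seed, 2L))
    for (nm in names(kan$params)) params[[paste0("kan.", nm)]] <- kan$params[[nm]]
    structure(list(d_image = d_image, d_clinical = d_clinical, width = width,
                   kan = kan, params = params, standardizer = NULL),
              class = "fusion_head")
  })
}

#' Current modality weights of a fusion head
#'
#' Softmax of the two free fusion parameters: nonnegative, sum to one.
#'
#' @param head a [fusion_head()].
#' @return named vector `c(image =, clinical =)`.
#' @export
modality_weights <- function(head) {
  if (head$d_clinical == 0L) return(c(image = 1, clinical = 0))
  r <- as.numeric(head$params$fuse.raw)
  e <- exp(r - max(r))
  w <- e / sum(e)
  c(image = w[1], clinical = w[2])
}

#' Convex fusion of projected modality vectors
#'
#' `w_image * f_image + w_clinical * x_clinical`, with weights on the
#' 2-simplex. Both inputs must share the projection width.
#'
#' @param f_image,x_clinical `N x width` matrices (or nodes).
#' @param weights length-2 vector of nonnegative weights summing to 1, or a
#'   node of the raw fusion parameters (softmaxed internally).
#' @return fused `N x width` matrix (or node).
#' @export
fuse_modalities <- function(f_image, x_clinical, weights) {
  if (ncol(ad_value(f_image)) != ncol(ad_value(x_clinical))) {
    stop("modality widths differ; project to a common width first",
         call. = FALSE)
  }
  if (is_ad(weights) || (is.matrix(ad_value(weights)))) {
    w <- ad_softmax_rows(weights)
    a <- ad_mul(f_image, ad_cols(w, 1L))
    b <- ad_mul(x_clinical, ad_cols(w, 2L))
    return(ad_add(a, b))
  }
  w <- weights / sum(weights)
  ad_add(ad_scale(f_image, w[1]), ad_scale(x_clinical, w[2]))
}

# forward pass of the head; X_img N x d_image, X_clin N x d_clinical (already
# standardized); params may be autodiff leaves; drop_mask optional plain
# matrix for (inverted) dropout on the fused vector
fusion_forward <- function(head, X_img, X_clin, params = NULL,
                           drop_mask = NULL) {
  params <- params %||% head$params
  f <- ad_add(ad_mm(X_img, params$proj_img.W), params$proj_img.b)
  f <- ad_tanh(f)
  if (head$d_clinical > 0L) {
    g <- ad_add(ad_mm(X_clin, params$proj_clin.W), params$proj_clin.b)
    g <- ad_tanh(g)
    fused <- fuse_modalities(f, g, params$fuse.raw)
  } else {
    fused <- f
  }
  if (!is.null(drop_mask)) fused <- ad_mul(fused, drop_mask)
  kan_params <- params[startsWith(names(params), "kan.")]
  names(kan_params) <- sub("^kan\\.", "", names(kan_params))
  kan_forward(head$kan, fused, params = kan_params)
}

#' Train the fusion head
#'
#' Cross-entropy with L1 regularization of the head weights, AdamW, a
#' dynamically decaying dropout rate `p(t) = p0 / (1 + beta t)` on the fused
#' vector, and early stopping when validation accuracy has not improved for
#' `patience` consecutive epochs.
#'
#' @param head a [fusion_head()].
#' @param X_img,X_clin training features (clinical already standardized;
#'   `X_clin` may be `NULL` for an image-only head).
#' @param y integer labels (1 = normal, 2 = high).
#' @param val optional list(X_img, X_clin, y) for early stopping.
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param l1_lambda L1 penalty weight.
#' @param p0,beta_drop dynamic dropout schedule parameters.
#' @param patience early-stopping patience (epochs).
#' @param batch_size minibatch size.
#' @param class_weights `NULL` for plain cross-entropy (the default, matching
#'   the task loss of the published head), `"balanced"` for inverse class
#'   frequency (useful at the 87:13 cohort imbalance if recall on the
#'   minority class matters more than raw accuracy), or an explicit length-2
#'   weight vector.
#' @param seed seed.
#' @return list with trained `head`, per-epoch `history`, and
#'   `epochs_run`.
#' @export
train_fusion <- function(head, X_img, X_clin, y, val = NULL, epochs = 30,
                         lr = 0.02, l1_lambda = 1e-4, p0 = 0.2,
                         beta_drop = 0.1, patience = 10, batch_size = 32,
                         class_weights = NULL, seed = 1L) {
  stopifnot(patience >= 1, p0 >= 0, p0 < 1, beta_drop >= 0, l1_lambda >= 0)
  n <- nrow(X_img)
  if (identical(class_weights, "balanced")) {
    freq <- tabulate(y, nbins = 2L)
    class_weights <- ifelse(freq > 0, n / (2 * pmax(freq, 1L)), 0)
  }
  state <- adamw_init(head$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_acc = numeric(0))
  best_acc <- -Inf
  stall <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      p_drop <- dropout_schedule(p0, beta_drop, ep - 1L)
      idx <- sample(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        b <- idx[start:min(start + batch_size - 1L, n)]
        leaves <- lapply(head$params, ad_leaf)
        mask <- if (p_drop > 0) {
          matrix(stats::rbinom(length(b) * head$width, 1L, 1 - p_drop) /
                   (1 - p_drop), length(b), head$width)
        } else NULL
        logits <- fusion_forward(head, X_img[b, , drop = FALSE],
                                 if (is.null(X_clin)) NULL
                                 else X_clin[b, , drop = FALSE],
                                 params = leaves, drop_mask = mask)
        loss <- ad_ce_logits(logits, y[b], class_weights)
        ad_backward(loss)
        grads <- ad_grads(leaves)
        if (l1_lambda > 0) {
          for (nm in names(grads)) {
            if (is.null(grads[[nm]])) next
            grads[[nm]] <- grads[[nm]] + l1_lambda * sign(head$params[[nm]])
          }
        }
        upd <- adamw_step(head$params, grads, state, lr = lr)
        head$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + total_loss(loss$value, unlist(head$params),
                                        l1_lambda)
        nb <- nb + 1L
      }
      vacc <- NA_real_
      if (!is.null(val)) {
        pred <- predict_fusion(head, val$X_img, val$X_clin)
        vacc <- mean(pred == val$y)
        if (vacc > best_acc + 1e-6) {
          best_acc <- vacc
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / nb,
                                           val_acc = vacc))
      if (!is.null(val) && stall >= patience) break
    }
  })
  list(head = head, history = history, epochs_run = nrow(history))
}

#' Predict classes with a trained fusion head
#'
#' @param head trained [fusion_head()].
#' @param X_img,X_clin feature matrices (clinical standardized; `X_clin`
#'   `NULL` for image-only heads).
#' @return integer class predictions (1 = normal, 2 = high).
#' @export
predict_fusion <- function(head, X_img, X_clin = NULL) {
  logits <- fusion_forward(head, X_img, X_clin)
  max.col(ad_value(logits), ties.method = "first")
}
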