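# Minimal reverse-mode automatic differentiation on base-R matrices.
#
# Every differentiable computation in the package (cycle-consistent
# augmentation, the windowed-attention encoder, the KAN fusion head and
# Grad-CAM) is expressed through the operations below. A node records its
# value, its parents and a closure that scatters an incoming adjoint onto the
# parents; node ids increase with creation time, so descending-id order is a
# valid reverse topological order. When no argument is a node an operation
# returns a plain value, which gives a zero-overhead "no gradient" path for
# inference.

.ad <- new.env(parent = emptyenv())
.ad$count <- 0L

#' Create an autodiff leaf node
#'
#' Wraps a numeric matrix (or scalar) as a differentiable leaf. After a call
#' to [ad_backward()] on a downstream scalar node, the accumulated adjoint is
#' available as `x$grad`.
#'
#' @param value numeric matrix, vector or scalar.
#' @return an `ad_node` environment with fields `value` and (after backward)
#'   `grad`.
#' @export
ad_leaf <- function(value) {
  ad_node(value, list(), NULL)
}

ad_node <- function(value, parents, backward) {
  .ad$count <- .ad$count + 1L
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$id <- .ad$count
  class(n) <- "ad_node"
  n
}

#' @export
is_ad <- function(x) inherits(x, "ad_node")

#' @export
ad_value <- function(x) if (is_ad(x)) x$value else x

ad_accum <- function(n, g) {
  n$grad <- if (is.null(n$grad)) g else n$grad + g
}

any_ad <- function(...) {
  args <- list(...)
  any(vapply(args, is_ad, logical(1)))
}

#' Run reverse-mode backpropagation
#'
#' Seeds the adjoint of `node` (normally a scalar loss) and propagates
#' gradients to every reachable leaf.
#'
#' @param node terminal `ad_node`.
#' @param grad adjoint seed, defaults to 1.
#' @export
ad_backward <- function(node, grad = 1) {
  stopifnot(is_ad(node))
  seen <- new.env(parent = emptyenv())
  stack <- list(node)
  nodes <- list()
  while (length(stack) > 0L) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      nodes[[length(nodes) + 1L]] <- n
      for (p in n$parents) {
        if (is_ad(p)) stack[[length(stack) + 1L]] <- p
      }
    }
  }
  ids <- vapply(nodes, function(n) n$id, numeric(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  node$grad <- grad
  for (n in nodes) {
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n$grad)
  }
  invisible(node)
}

## ---- arithmetic ------------------------------------------------------------

#' @export
ad_mm <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  v <- av %*% bv
  if (!any_ad(a, b)) return(v)
  ad_node(v, list(a, b), function(g) {
    if (is_ad(a)) ad_accum(a, g %*% t(bv))
    if (is_ad(b)) ad_accum(b, crossprod(av, g))
  })
}

#' @export
ad_transpose <- function(a) {
  av <- ad_value(a)
  if (!is_ad(a)) return(t(av))
  ad_node(t(av), list(a), function(g) ad_accum(a, t(g)))
}

# a: N x C; b: same shape, a length-C/1xC row broadcast, or a scalar
#' @export
ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  brow <- is.matrix(av) && nrow(av) > 1L &&
    ((!is.matrix(bv) && length(bv) == ncol(av) && ncol(av) > 1L) ||
       (is.matrix(bv) && nrow(bv) == 1L && ncol(bv) == ncol(av)))
  bscalar <- !brow && length(bv) == 1L && length(av) > 1L
  v <- if (brow) sweep(av, 2L, as.numeric(bv), "+")
  else if (bscalar) av + as.numeric(bv)
  else av + bv
  if (!any_ad(a, b)) return(v)
  ad_node(v, list(a, b), function(g) {
    if (is_ad(a)) ad_accum(a, g)
    if (is_ad(b)) {
      gb <- if (brow) {
        cs <- colSums(g)
        if (is.matrix(bv)) matrix(cs, 1L) else cs
      } else if (bscalar) sum(g) else g
      ad_accum(b, gb)
    }
  })
}

#' @export
ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

# multiply by a plain scalar
#' @export
ad_scale <- function(a, s) {
  av <- ad_value(a)
  v <- av * s
  if (!is_ad(a)) return(v)
  ad_node(v, list(a), function(g) ad_accum(a, g * s))
}

# elementwise product; shapes equal, or one side a scalar (plain or node)
#' @export
ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  v <- if (length(bv) == 1L) av * as.numeric(bv)
  else if (length(av) == 1L) as.numeric(av) * bv
  else av * bv
  if (!any_ad(a, b)) return(v)
  ad_node(v, list(a, b), function(g) {
    if (is_ad(a)) {
      ga <- if (length(av) == 1L) sum(g * bv) else if (length(bv) == 1L) g * as.numeric(bv) else g * bv
      ad_accum(a, ga)
    }
    if (is_ad(b)) {
      gb <- if (length(bv) == 1L) sum(g * av) else if (length(av) == 1L) g * as.numeric(av) else g * av
      ad_accum(b, gb)
    }
  })
}

# multiply each row of a (N x C) by row vector v (1 x C or length C)
#' @export
ad_rowmul <- function(a, v) {
  av <- ad_value(a); vv <- ad_value(v)
  val <- sweep(av, 2L, as.numeric(vv), "*")
  if (!any_ad(a, v)) return(val)
  ad_node(val, list(a, v), function(g) {
    if (is_ad(a)) ad_accum(a, sweep(g, 2L, as.numeric(vv), "*"))
    if (is_ad(v)) {
      gv <- colSums(g * av)
      if (is.matrix(vv)) gv <- matrix(gv, 1L)
      ad_accum(v, gv)
    }
  })
}

## ---- nonlinearities --------------------------------------------------------

#' @export
ad_sigmoid <- function(a) {
  av <- ad_value(a)
  v <- 1 / (1 + exp(-av))
  if (!is_ad(a)) return(v)
  ad_node(v, list(a), function(g) ad_accum(a, g * v * (1 - v)))
}

#' @export
ad_tanh <- function(a) {
  av <- ad_value(a)
  v <- tanh(av)
  if (!is_ad(a)) return(v)
  ad_node(v, list(a), function(g) ad_accum(a, g * (1 - v^2)))
}

#' @export
ad_relu <- function(a) {
  av <- ad_value(a)
  v <- pmax(av, 0)
  if (!is_ad(a)) return(v)
  ad_node(v, list(a), function(g) ad_accum(a, g * (av > 0)))
}

#' @export
ad_gelu <- function(a) {
  av <- ad_value(a)
  v <- av * stats::pnorm(av)
  if (!is_ad(a)) return(v)
  ad_node(v, list(a), function(g) {
    ad_accum(a, g * (stats::pnorm(av) + av * stats::dnorm(av)))
  })
}

#' @export
ad_abs <- function(a) {
  av <- ad_value(a)
  v <- abs(av)
  if (!is_ad(a)) return(v)
  ad_node(v, list(a), function(g) ad_accum(a, g * sign(av)))
}

#' @export
ad_square <- function(a) {
  av <- ad_value(a)
  v <- av^2
  if (!is_ad(a)) return(v)
  ad_node(v, list(a), function(g) ad_accum(a, g * 2 * av))
}

#' @export
ad_clamp <- function(a, lo, hi) {
  av <- ad_value(a)
  v <- pmin(pmax(av, lo), hi)
  if (!is_ad(a)) return(v)
  inside <- (av >= lo) & (av <= hi)
  ad_node(v, list(a), function(g) ad_accum(a, g * inside))
}

## ---- reductions ------------------------------------------------------------

#' @export
ad_mean <- function(a) {
  av <- ad_value(a)
  v <- mean(av)
  if (!is_ad(a)) return(v)
  n <- length(av)
  ad_node(v, list(a), function(g) {
    ad_accum(a, array(as.numeric(g) / n, dim = dim_or_len(av)))
  })
}

#' @export
ad_sum <- function(a) {
  av <- ad_value(a)
  v <- sum(av)
  if (!is_ad(a)) return(v)
  ad_node(v, list(a), function(g) {
    ad_accum(a, array(as.numeric(g), dim = dim_or_len(av)))
  })
}

dim_or_len <- function(x) if (is.matrix(x)) dim(x) else length(x)

# column means of an N x C matrix -> 1 x C
#' @export
ad_colmeans <- function(a) {
  av <- ad_value(a)
  v <- matrix(colMeans(av), 1L)
  if (!is_ad(a)) return(v)
  n <- nrow(av)
  ad_node(v, list(a), function(g) {
    ad_accum(a, matrix(rep(as.numeric(g) / n, each = n), n))
  })
}

## ---- structural ops --------------------------------------------------------

# row gather (window partition, patch merging, im2col); idx may repeat rows
#' @export
ad_rows <- function(a, idx) {
  av <- ad_value(a)
  v <- av[idx, , drop = FALSE]
  if (!is_ad(a)) return(v)
  n <- nrow(av)
  ad_node(v, list(a), function(g) {
    gs <- rowsum(g, group = idx)
    full <- matrix(0, n, ncol(av))
    full[as.integer(rownames(gs)), ] <- gs
    ad_accum(a, full)
  })
}

#' @export
ad_cols <- function(a, idx) {
  av <- ad_value(a)
  v <- av[, idx, drop = FALSE]
  if (!is_ad(a)) return(v)
  ad_node(v, list(a), function(g) {
    full <- matrix(0, nrow(av), ncol(av))
    full[, idx] <- full[, idx] + g
    ad_accum(a, full)
  })
}

# append one all-zero row (padding target for im2col gathers)
#' @export
ad_pad_zero_row <- function(a) {
  av <- ad_value(a)
  v <- rbind(av, 0)
  if (!is_ad(a)) return(v)
  n <- nrow(av)
  ad_node(v, list(a), function(g) ad_accum(a, g[seq_len(n), , drop = FALSE]))
}

#' @export
ad_cbind <- function(parts) {
  vals <- lapply(parts, ad_value)
  v <- do.call(cbind, vals)
  if (!any(vapply(parts, is_ad, logical(1)))) return(v)
  widths <- vapply(vals, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(v, parts, function(g) {
    for (i in seq_along(parts)) {
      if (is_ad(parts[[i]])) {
        ad_accum(parts[[i]], g[, starts[i]:ends[i], drop = FALSE])
      }
    }
  })
}

## ---- normalisation and attention -------------------------------------------

# row-wise softmax with an optional plain additive mask (0 / -Inf)
#' @export
ad_softmax_rows <- function(a, mask = NULL) {
  av <- ad_value(a)
  s <- if (is.null(mask)) av else av + mask
  m <- s[cbind(seq_len(nrow(s)), max.col(s, ties.method = "first"))]
  e <- exp(s - m)
  p <- e / rowSums(e)
  if (!is_ad(a)) return(p)
  ad_node(p, list(a), function(g) {
    dot <- rowSums(g * p)
    ad_accum(a, p * (g - dot))
  })
}

# per-row layer normalisation with learnable gain and bias (length-C vectors)
#' @export
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- ad_value(a)
  gv <- as.numeric(ad_value(gamma)); bv <- as.numeric(ad_value(beta))
  mu <- rowMeans(av)
  xc <- av - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  v <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  if (!any_ad(a, gamma, beta)) return(v)
  ad_node(v, list(a, gamma, beta), function(g) {
    if (is_ad(gamma)) ad_accum(gamma, colSums(g * xhat))
    if (is_ad(beta)) ad_accum(beta, colSums(g))
    if (is_ad(a)) {
      dxhat <- sweep(g, 2L, gv, "*")
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * xhat)
      ad_accum(a, (dxhat - m1 - xhat * m2) * inv)
    }
  })
}

## ---- losses ----------------------------------------------------------------

# mean cross-entropy over rows of logits; y integer class labels in 1..C;
# optional per-class weights (e.g. inverse class frequency) are normalised so
# the weighted loss stays on the same scale as the unweighted one
#' @export
ad_ce_logits <- function(logits, y, class_weights = NULL) {
  lv <- ad_value(logits)
  n <- nrow(lv)
  w <- if (is.null(class_weights)) rep(1, n) else {
    wy <- class_weights[y]
    wy * n / sum(wy)
  }
  m <- lv[cbind(seq_len(n), max.col(lv, ties.method = "first"))]
  e <- exp(lv - m)
  p <- e / rowSums(e)
  picked <- p[cbind(seq_len(n), y)]
  v <- -mean(w * log(pmax(picked, 1e-12)))
  if (!is_ad(logits)) return(v)
  ad_node(v, list(logits), function(g) {
    onehot <- matrix(0, n, ncol(lv))
    onehot[cbind(seq_len(n), y)] <- 1
    ad_accum(logits, as.numeric(g) * w * (p - onehot) / n)
  })
}

## ---- optimiser -------------------------------------------------------------

#' AdamW optimiser state
#'
#' @param params named list of numeric parameter matrices.
#' @return optimiser state passed to [adamw_step()].
#' @export
adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One AdamW update
#'
#' @param params named list of parameter matrices.
#' @param grads named list of gradients (missing / NULL entries are skipped).
#' @param state state from [adamw_init()].
#' @param lr learning rate.
#' @param beta1,beta2,eps Adam moment constants.
#' @param weight_decay decoupled weight decay.
#' @param frozen character vector of parameter-name prefixes excluded from the
#'   update (transfer-learning freeze policy).
#' @return list with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 0,
                       frozen = character(), clip_norm = NULL) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  if (!is.null(clip_norm)) {
    gn <- sqrt(sum(vapply(grads, function(g) {
      if (is.null(g)) 0 else sum(g^2)
    }, numeric(1))))
    if (gn > clip_norm) {
      grads <- lapply(grads, function(g) if (is.null(g)) NULL
                      else g * clip_norm / gn)
    }
  }
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is_frozen(nm, frozen)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    # norms and biases are conventionally exempt from weight decay
    wd <- if (grepl("(^|\\.)(b|b1|b2|g)$|\\.ln", nm)) 0 else weight_decay
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           wd * params[[nm]])
  }
  list(params = params, state = state)
}

is_frozen <- function(name, frozen) {
  if (length(frozen) == 0L) return(FALSE)
  any(vapply(frozen, function(f) {
    name == f || startsWith(name, paste0(f, "."))
  }, logical(1)))
}

# read leaf gradients back into a named list aligned with `leaves`
ad_grads <- function(leaves) {
  lapply(leaves, function(l) if (is.null(l$grad)) NULL else l$grad)
}
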