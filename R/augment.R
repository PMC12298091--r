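# Cycle-consistent image augmentation (toy scale).
#
# Two small convolutional generators translate between the normal-IOP and
# high-IOP image domains; two convolutional discriminators drive a
# least-squares adversarial loss, and an L1 cycle-consistency penalty
# requires that translating to the other domain and back reconstructs the
# input. The published pipeline cites the standard formulation without
# stating architecture or loss weights, so both are configuration here, at
# desk scale (64 px, narrow channels, few epochs). A `classic` fallback mode
# (flip / translate / intensity jitter) produces augmented sets of identical
# shape without adversarial training.
#
# Convolutions are realised as im2col gathers + matrix products on the
# autodiff core; images are flattened column-major to (H*W) x channels.

#' CycleGAN configuration
#'
#' @param image_size square image side.
#' @param generator_width,discriminator_width channel counts.
#' @param cycle_weight weight of the L1 cycle-consistency loss (>= 0).
#' @param epochs training epochs (>= 1).
#' @param learning_rate Adam learning rate.
#' @param seed seed.
#' @export
cyclegan_config <- function(image_size = 64, generator_width = 8,
                            discriminator_width = 8, cycle_weight = 10,
                            epochs = 5, learning_rate = 2e-3, seed = 1L) {
  stopifnot(cycle_weight >= 0, epochs >= 1)
  structure(list(image_size = image_size, generator_width = generator_width,
                 discriminator_width = discriminator_width,
                 cycle_weight = cycle_weight, epochs = epochs,
                 learning_rate = learning_rate, seed = seed),
            class = "cyclegan_config")
}

# 3x3 im2col gather indices with zero padding (pad row = H*W + 1)
conv_indices <- function(H, W) {
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      k <- k + 1L
      ii <- i + di; jj <- j + dj
      ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
      idx[, k] <- ifelse(ok, (jj - 1L) * H + ii, H * W + 1L)
    }
  }
  idx
}

conv3x3 <- function(x, W, b, idx) {
  xp <- ad_pad_zero_row(x)
  parts <- lapply(seq_len(ncol(idx)), function(k) ad_rows(xp, idx[, k]))
  ad_add(ad_mm(ad_cbind(parts), W), b)
}

new_conv_params <- function(cin, cout, gain = 0.5) {
  list(W = matrix(stats::rnorm(9 * cin * cout, sd = gain / sqrt(9 * cin)),
                  9 * cin, cout),
       b = matrix(0, 1L, cout))
}

#' Construct a toy convolutional generator
#'
#' Three 3x3 convolutions (1 -> width -> width -> 1) with ReLU activations
#' and a sigmoid output, so generated values always lie in `[0,1]`.
#'
#' @param image_size square image side.
#' @param width channel count.
#' @param seed seed.
#' @return object of class `cyclegan_generator`.
#' @export
conv_generator <- function(image_size, width = 8, seed = 1L) {
  with_seed(seed, {
    p1 <- new_conv_params(1L, width); p2 <- new_conv_params(width, width)
    p3 <- new_conv_params(width, 1L)
    structure(list(type = "conv", image_size = image_size, width = width,
                   params = list(c1.W = p1$W, c1.b = p1$b, c2.W = p2$W,
                                 c2.b = p2$b, c3.W = p3$W, c3.b = p3$b),
                   idx = conv_indices(image_size, image_size)),
              class = "cyclegan_generator")
  })
}

#' Identity generator
#'
#' A generator whose forward map is the identity; with a pair of these the
#' cycle-consistency loss is exactly zero.
#'
#' @param image_size square image side.
#' @export
identity_generator <- function(image_size) {
  structure(list(type = "identity", image_size = image_size,
                 params = list(), idx = NULL),
            class = "cyclegan_generator")
}

# forward on an (H*W) x 1 (node or plain) column
generator_forward <- function(gen, x, params = NULL) {
  if (gen$type == "identity") return(x)
  P <- params %||% gen$params
  h <- ad_relu(conv3x3(x, P$c1.W, P$c1.b, gen$idx))
  h <- ad_relu(conv3x3(h, P$c2.W, P$c2.b, gen$idx))
  ad_sigmoid(conv3x3(h, P$c3.W, P$c3.b, gen$idx))
}

#' Apply a generator to an image
#'
#' @param gen a `cyclegan_generator`.
#' @param image square image matrix matching the generator's size.
#' @return generated image matrix in `[0,1]`.
#' @export
apply_generator <- function(gen, image) {
  stopifnot(nrow(image) == gen$image_size, ncol(image) == gen$image_size)
  x <- matrix(as.numeric(image), ncol = 1L)
  out <- ad_value(generator_forward(gen, x))
  clip01(matrix(out, gen$image_size, gen$image_size))
}

conv_discriminator <- function(image_size, width = 8, seed = 1L) {
  with_seed(seed, {
    p1 <- new_conv_params(1L, width)
    structure(list(image_size = image_size, width = width,
                   params = list(c1.W = p1$W, c1.b = p1$b,
                                 out.W = matrix(stats::rnorm(width, sd = 0.2),
                                                width, 1L),
                                 out.b = matrix(0, 1L, 1L)),
                   idx = conv_indices(image_size, image_size)),
              class = "cyclegan_discriminator")
  })
}

discriminator_forward <- function(disc, x, params = NULL) {
  P <- params %||% disc$params
  h <- ad_relu(conv3x3(x, P$c1.W, P$c1.b, disc$idx))
  pooled <- ad_colmeans(h)
  ad_add(ad_mm(pooled, P$out.W), P$out.b)
}

#' Cycle-consistency reconstruction error
#'
#' Mean absolute reconstruction error of translating each image to the other
#' domain and back, `mean |F(G(x)) - x|`; finite, non-negative, and exactly
#' zero for identity generators.
#'
#' @param gen_fwd,gen_back the two generators.
#' @param images list of image matrices.
#' @return scalar.
#' @export
cycle_loss <- function(gen_fwd, gen_back, images) {
  errs <- vapply(images, function(im) {
    rec <- apply_generator(gen_back, apply_generator(gen_fwd, im))
    mean(abs(rec - im))
  }, numeric(1))
  mean(errs)
}

#' Train a toy CycleGAN
#'
#' Least-squares adversarial losses for both directions plus the weighted L1
#' cycle loss; generators and discriminators are updated alternately with
#' Adam. Deterministic given `config$seed`.
#'
#' @param images_normal,images_high non-empty lists of same-size images from
#'   the two IOP domains.
#' @param config a [cyclegan_config()].
#' @return list with `generator_n2h`, `generator_h2n` and `history` (one row
#'   per epoch: mean adversarial and cycle losses).
#' @export
train_cyclegan <- function(images_normal, images_high, config) {
  if (length(images_normal) == 0L || length(images_high) == 0L) {
    stop("both image domains must be non-empty", call. = FALSE)
  }
  sz <- config$image_size
  ok <- vapply(c(images_normal, images_high),
               function(im) all(dim(im) == c(sz, sz)), logical(1))
  if (!all(ok)) stop("all images must be image_size x image_size",
                     call. = FALSE)
  G_ab <- conv_generator(sz, config$generator_width,
                         seed = child_seed(config$seed, 1L))
  G_ba <- conv_generator(sz, config$generator_width,
                         seed = child_seed(config$seed, 2L))
  D_a <- conv_discriminator(sz, config$discriminator_width,
                            seed = child_seed(config$seed, 3L))
  D_b <- conv_discriminator(sz, config$discriminator_width,
                            seed = child_seed(config$seed, 4L))
  gp <- c(prefix_names(G_ab$params, "ab."), prefix_names(G_ba$params, "ba."))
  dp <- c(prefix_names(D_a$params, "a."), prefix_names(D_b$params, "b."))
  g_state <- adamw_init(gp)
  d_state <- adamw_init(dp)
  lam <- config$cycle_weight
  history <- data.frame(epoch = integer(0), adv_loss = numeric(0),
                        cycle_loss = numeric(0))

  flat <- function(im) matrix(as.numeric(im), ncol = 1L)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ia <- sample(length(images_normal))
      ib <- sample(length(images_high))
      npair <- min(length(ia), length(ib))
      adv_sum <- 0; cyc_sum <- 0
      for (t in seq_len(npair)) {
        a <- flat(images_normal[[ia[t]]])
        b <- flat(images_high[[ib[t]]])

        # generator update (discriminators fixed)
        leaves <- lapply(gp, ad_leaf)
        Pab <- strip_prefix(leaves, "ab."); Pba <- strip_prefix(leaves, "ba.")
        fake_b <- generator_forward(G_ab, a, Pab)
        fake_a <- generator_forward(G_ba, b, Pba)
        adv <- ad_add(ad_square(ad_add(discriminator_forward(D_b, fake_b), -1)),
                      ad_square(ad_add(discriminator_forward(D_a, fake_a), -1)))
        rec_a <- generator_forward(G_ba, fake_b, Pba)
        rec_b <- generator_forward(G_ab, fake_a, Pab)
        cyc <- ad_add(ad_mean(ad_abs(ad_sub(rec_a, a))),
                      ad_mean(ad_abs(ad_sub(rec_b, b))))
        loss_g <- ad_add(adv, ad_scale(cyc, lam))
        ad_backward(loss_g)
        upd <- adamw_step(gp, ad_grads(leaves), g_state,
                          lr = config$learning_rate)
        gp <- upd$params; g_state <- upd$state
        G_ab$params <- strip_prefix(gp, "ab.")
        G_ba$params <- strip_prefix(gp, "ba.")
        adv_sum <- adv_sum + ad_value(adv) / 2
        cyc_sum <- cyc_sum + ad_value(cyc) / 2

        # discriminator update (generators fixed, fakes detached)
        fb <- ad_value(fake_b); fa <- ad_value(fake_a)
        dleaves <- lapply(dp, ad_leaf)
        Pa <- strip_prefix(dleaves, "a."); Pb <- strip_prefix(dleaves, "b.")
        loss_d <- ad_scale(ad_add(
          ad_add(ad_square(ad_add(discriminator_forward(D_b, b, Pb), -1)),
                 ad_square(discriminator_forward(D_b, fb, Pb))),
          ad_add(ad_square(ad_add(discriminator_forward(D_a, a, Pa), -1)),
                 ad_square(discriminator_forward(D_a, fa, Pa)))), 0.5)
        ad_backward(loss_d)
        dupd <- adamw_step(dp, ad_grads(dleaves), d_state,
                           lr = config$learning_rate)
        dp <- dupd$params; d_state <- dupd$state
        D_a$params <- strip_prefix(dp, "a.")
        D_b$params <- strip_prefix(dp, "b.")
      }
      history <- rbind(history,
                       data.frame(epoch = ep, adv_loss = adv_sum / npair,
                                  cycle_loss = cyc_sum / npair))
    }
  })
  list(generator_n2h = G_ab, generator_h2n = G_ba, history = history)
}

prefix_names <- function(lst, pfx) {
  stats::setNames(lst, paste0(pfx, names(lst)))
}

strip_prefix <- function(lst, pfx) {
  sel <- startsWith(names(lst), pfx)
  stats::setNames(lst[sel], substring(names(lst)[sel], nchar(pfx) + 1L))
}

## ---- classic augmentation --------------------------------------------------

#' Classic geometric/intensity jitter
#'
#' Horizontal flip (50%), integer translation up to 3 px (edge replication),
#' and an affine intensity jitter, clipped to `[0,1]`.
#'
#' @param image image matrix.
#' @param seed integer seed.
#' @return jittered image.
#' @export
classic_augment <- function(image, seed = 1L) {
  stopifnot_image(image)
  H <- nrow(image); W <- ncol(image)
  with_seed(seed, {
    if (stats::runif(1) < 0.5) image <- image[, W:1]
    dx <- sample(-3:3, 1L); dy <- sample(-3:3, 1L)
    ri <- pmin(pmax(seq_len(H) - dy, 1L), H)
    ci <- pmin(pmax(seq_len(W) - dx, 1L), W)
    image <- image[ri, ci]
    gain <- stats::runif(1, 0.9, 1.1)
    off <- stats::runif(1, -0.05, 0.05)
    clip01(image * gain + off)
  })
}

#' Generate an augmented image set
#'
#' Produces exactly `n_per_class` images per IOP domain (2 * n_per_class in
#' total, e.g. 600 + 600 = 1200 at the published scale), each with recorded
#' provenance. In `cyclegan` mode, images of one domain are synthesised by
#' translating source images of the other domain through the corresponding
#' generator; in `classic` mode, same-domain sources are jittered.
#'
#' @param sources_normal,sources_high lists of source images per domain.
#' @param n_per_class images to generate per domain (>= 0).
#' @param mode `"classic"` or `"cyclegan"`.
#' @param generators list with `n2h` and `h2n` generators (cyclegan mode).
#' @param seed seed.
#' @return list of class `augmented_set` with `images`, `domain` (factor),
#'   `source_id` and `source_domain`.
#' @export
generate_augmented <- function(sources_normal, sources_high, n_per_class,
                               mode = c("classic", "cyclegan"),
                               generators = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_per_class >= 0)
  if (length(sources_normal) == 0L || length(sources_high) == 0L) {
    stop("source images required for both domains", call. = FALSE)
  }
  if (mode == "cyclegan" &&
      (is.null(generators$n2h) || is.null(generators$h2n))) {
    stop("cyclegan mode requires `generators$n2h` and `generators$h2n`",
         call. = FALSE)
  }
  images <- vector("list", 2L * n_per_class)
  domain <- character(2L * n_per_class)
  source_id <- integer(2L * n_per_class)
  source_domain <- character(2L * n_per_class)
  if (n_per_class > 0L) {
    with_seed(seed, {
      k <- 0L
      for (dom in c("normal", "high")) {
        for (j in seq_len(n_per_class)) {
          k <- k + 1L
          domain[k] <- dom
          if (mode == "classic") {
            src <- if (dom == "normal") sources_normal else sources_high
            sid <- sample(length(src), 1L)
            images[[k]] <- classic_augment(src[[sid]],
                                           seed = child_seed(seed, k))
            source_id[k] <- sid
            source_domain[k] <- dom
          } else {
            src <- if (dom == "normal") sources_high else sources_normal
            gen <- if (dom == "normal") generators$h2n else generators$n2h
            sid <- sample(length(src), 1L)
            images[[k]] <- apply_generator(gen, src[[sid]])
            source_id[k] <- sid
            source_domain[k] <- if (dom == "normal") "high" else "normal"
          }
        }
      }
    })
  }
  structure(list(images = images,
                 domain = factor(domain, levels = c("normal", "high")),
                 source_id = source_id, source_domain = source_domain),
            class = "augmented_set")
}
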