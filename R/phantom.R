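# Synthetic Scheimpflug-like phantom cohort.
#
# The generator emulates the study cohort this package is built around:
# anterior-segment cross-sections of 780 eyes, 680 with normal intraocular
# pressure (IOP <= 21 mmHg) and 100 with elevated IOP, each carrying eight
# clinical attributes. Class-conditional attribute means follow the published
# baseline table verbatim; the joint attribute/IOP distribution is a per-class
# truncated multivariate normal (Gaussian copula with normal marginals) whose
# within-class correlations are calibrated so that the *pooled* cohort
# reproduces the published attribute-IOP Pearson correlations
# (r = 0.41 for central corneal thickness, -0.17 for anterior chamber depth,
# -0.14 for anterior chamber volume).

PHANTOM_ATTRS <- c("age", "pupil_center_thickness", "corneal_vertex_thickness",
                   "corneal_volume", "anterior_chamber_depth",
                   "anterior_chamber_volume", "corneal_diameter", "iop")

default_group_means <- function() {
  rbind(
    normal = c(age = 67.3, pupil_center_thickness = 530.5,
               corneal_vertex_thickness = 530.9, corneal_volume = 96.1,
               anterior_chamber_depth = 7.9, anterior_chamber_volume = 115.4,
               corneal_diameter = 2.9, iop = 15),
    high = c(age = 69.5, pupil_center_thickness = 570.7,
             corneal_vertex_thickness = 572.4, corneal_volume = 62.5,
             anterior_chamber_depth = 2.5, anterior_chamber_volume = 111.7,
             corneal_diameter = 3.1, iop = 27)
  )
}

#' Phantom generator configuration
#'
#' Builds and calibrates the configuration for the synthetic cohort. The
#' class-conditional means default to the published baseline table (used
#' verbatim, including its physiologically odd anterior-chamber-depth and
#' corneal-diameter rows). Within-class standard deviations default to
#' `sd_frac` (10%) of the pooled attribute mean; for attributes carrying a
#' pooled correlation target the within-class correlation with IOP is solved
#' in closed form from the between-class mean shift, and where no admissible
#' within-class correlation (|rho| <= `rho_max`) can reach the target, that
#' attribute's sd is widened to the smallest feasible value. The calibration
#' is deterministic and happens once, at configuration time.
#'
#' @param image_height,image_width phantom size in pixels (>= 32).
#' @param class_prob_high probability of the high-IOP class
#'   (default 100/780 = 12.8%).
#' @param group_means 2 x 8 matrix (rows `normal`, `high`) of class means.
#' @param group_sds optional 8-vector of within-class sds (shared by the two
#'   classes); `NULL` uses the calibrated defaults.
#' @param target_correlations named vector of pooled attribute-IOP Pearson
#'   targets.
#' @param sd_frac base within-class sd as a fraction of the pooled mean.
#' @param rho_max largest admissible within-class correlation magnitude.
#' @param noise_sd sd of additive speckle noise on rendered images.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 64, image_width = 64,
                           class_prob_high = 100 / 780,
                           group_means = default_group_means(),
                           group_sds = NULL,
                           target_correlations = c(
                             pupil_center_thickness = 0.41,
                             anterior_chamber_depth = -0.17,
                             anterior_chamber_volume = -0.14),
                           sd_frac = 0.10, rho_max = 0.8, noise_sd = 0.02) {
  stopifnot(image_height >= 32, image_width >= 32)
  if (!(class_prob_high > 0 && class_prob_high < 1)) {
    stop("`class_prob_high` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!all(PHANTOM_ATTRS %in% colnames(group_means))) {
    stop("`group_means` must have the eight clinical attribute columns",
         call. = FALSE)
  }
  group_means <- group_means[c("normal", "high"), PHANTOM_ATTRS]
  if (any(abs(target_correlations) >= 1)) {
    stop("target correlations must have magnitude < 1", call. = FALSE)
  }
  unknown <- setdiff(names(target_correlations), setdiff(PHANTOM_ATTRS, "iop"))
  if (length(unknown) > 0L) {
    stop("unknown attribute in `target_correlations`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  p <- class_prob_high
  pooled_mean <- (1 - p) * group_means["normal", ] + p * group_means["high", ]
  sds <- group_sds %||% (sd_frac * abs(pooled_mean))
  sds <- stats::setNames(as.numeric(sds), PHANTOM_ATTRS)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)

  cal <- calibrate_within_class(group_means, sds, p, target_correlations,
                                rho_max)

  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    class_prob_high = p,
    group_means = group_means,
    group_sds = cal$sds,
    target_correlations = target_correlations,
    within_correlations = cal$rho,
    noise_sd = noise_sd,
    sd_frac = sd_frac,
    rho_max = rho_max
  ), class = "phantom_config")
}

# Solve, for each targeted attribute a, the within-class correlation rho with
# IOP such that the pooled Pearson correlation equals the target:
#   pooled cov  = rho * S_a * S_I + p q dA dI
#   pooled vars = S_a^2 + p q dA^2   and   S_I^2 + p q dI^2
# If |rho| exceeds rho_max, widen S_a until rho(S_a) = sign(rho) * rho_max.
calibrate_within_class <- function(means, sds, p, targets, rho_max) {
  q <- 1 - p
  dI <- means["high", "iop"] - means["normal", "iop"]
  SI <- sds[["iop"]]
  VI <- SI^2 + p * q * dI^2
  rho <- stats::setNames(numeric(length(targets)), names(targets))
  for (a in names(targets)) {
    r_star <- targets[[a]]
    dA <- means["high", a] - means["normal", a]
    B <- p * q * dA * dI
    rho_of <- function(S) {
      (r_star * sqrt((S^2 + p * q * dA^2) * VI) - B) / (S * SI)
    }
    S0 <- sds[[a]]
    r0 <- rho_of(S0)
    if (abs(r0) <= rho_max) {
      rho[a] <- r0
      next
    }
    # widening the within-class sd dilutes the between-class component;
    # rho(S) tends to r_star * sqrt(VI) / SI as S grows
    limit <- r_star * sqrt(VI) / SI
    if (abs(limit) >= rho_max) {
      warning(sprintf(
        "pooled correlation target %.2f for '%s' unreachable; clamping",
        r_star, a), call. = FALSE)
      rho[a] <- sign(r0) * rho_max
      next
    }
    f <- function(S) abs(rho_of(S)) - rho_max
    hi <- S0
    while (f(hi) > 0 && hi < S0 * 1e6) hi <- hi * 2
    root <- stats::uniroot(f, lower = S0, upper = hi, tol = 1e-10)
    sds[[a]] <- root$root
    rho[a] <- rho_of(root$root)
  }
  ssq <- sum(rho^2)
  if (ssq >= 0.98) {
    # keep the within-class correlation matrix positive definite
    rho <- rho * sqrt(0.95 / ssq)
    warning("within-class correlations rescaled to keep the copula PSD",
            call. = FALSE)
  }
  list(sds = sds, rho = rho)
}

within_class_covariance <- function(config) {
  k <- length(PHANTOM_ATTRS)
  C <- diag(k)
  dimnames(C) <- list(PHANTOM_ATTRS, PHANTOM_ATTRS)
  for (a in names(config$within_correlations)) {
    C[a, "iop"] <- C["iop", a] <- config$within_correlations[[a]]
  }
  D <- diag(config$group_sds)
  D %*% C %*% D
}

#' Sample clinical records with labels
#'
#' Draws `n` labelled clinical records from the calibrated per-class truncated
#' multivariate normal. Labels follow the 21 mmHg rule exactly: the normal
#' class is conditioned on IOP <= 21 mmHg and the high class on IOP > 21 mmHg
#' (rejection resampling; the truncation point sits several within-class sds
#' from either class mean, so acceptance is near certain).
#'
#' @param config a [phantom_config()].
#' @param n number of records (>= 0).
#' @param seed integer seed.
#' @return data.frame with the eight attribute columns plus a `label` factor
#'   (`normal` / `high`).
#' @export
sample_clinical <- function(config, n, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"), n >= 0)
  cols <- c(PHANTOM_ATTRS, "label")
  if (n == 0L) {
    out <- stats::setNames(
      data.frame(matrix(numeric(0), 0L, length(PHANTOM_ATTRS))),
      PHANTOM_ATTRS)
    out$label <- factor(character(0), levels = c("normal", "high"))
    return(out)
  }
  sigma <- within_class_covariance(config)
  L <- chol(sigma)
  with_seed(seed, {
    lab <- ifelse(stats::runif(n) < config$class_prob_high, "high", "normal")
    X <- matrix(NA_real_, n, length(PHANTOM_ATTRS),
                dimnames = list(NULL, PHANTOM_ATTRS))
    for (cls in c("normal", "high")) {
      idx <- which(lab == cls)
      if (length(idx) == 0L) next
      mu <- config$group_means[cls, ]
      draw <- function(m) {
        Z <- matrix(stats::rnorm(m * length(mu)), m)
        Y <- sweep(Z %*% L, 2L, mu, "+")
        colnames(Y) <- PHANTOM_ATTRS
        Y
      }
      Y <- draw(length(idx))
      bad <- which(!records_admissible(Y, cls))
      tries <- 0L
      while (length(bad) > 0L && tries < 1000L) {
        Y[bad, ] <- draw(length(bad))
        bad <- which(!records_admissible(Y, cls))
        tries <- tries + 1L
      }
      X[idx, ] <- Y
    }
    out <- as.data.frame(X)
    out$label <- factor(lab, levels = c("normal", "high"))
    out
  })
}

# class-consistency of IOP with the 21 mmHg rule plus the record invariants
records_admissible <- function(Y, cls) {
  iop <- Y[, "iop"]
  ok <- if (cls == "high") iop > 21 else iop <= 21
  pos <- c("pupil_center_thickness", "corneal_vertex_thickness",
           "corneal_volume", "anterior_chamber_volume", "corneal_diameter")
  ok & iop > 0 & rowSums(Y[, pos, drop = FALSE] <= 0) == 0 &
    rowSums(!is.finite(Y)) == 0
}

#' Validate a clinical record
#'
#' Checks the record invariants: all fields finite, thickness and volume
#' fields strictly positive, IOP positive.
#'
#' @param record one-row data.frame or named vector with the eight attributes.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_record <- function(record) {
  rec <- as.list(record)
  missing <- setdiff(PHANTOM_ATTRS, names(rec))
  if (length(missing) > 0L) {
    stop("record lacks attributes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- unlist(rec[PHANTOM_ATTRS])
  if (any(!is.finite(vals))) stop("record has non-finite fields", call. = FALSE)
  pos <- c("pupil_center_thickness", "corneal_vertex_thickness",
           "corneal_volume", "anterior_chamber_volume", "corneal_diameter",
           "iop")
  if (any(vals[pos] <= 0)) {
    stop("thickness/volume fields and IOP must be strictly positive",
         call. = FALSE)
  }
  invisible(TRUE)
}

## ---- rendering -------------------------------------------------------------

# affine maps from clinical units to pixels (scaled with image size)
band_thickness_px <- function(pct_um, scale) {
  max(2L, as.integer(round((8 + 0.1 * (pct_um - 530.5)) * scale)))
}

chamber_depth_px <- function(acd_mm, scale, H) {
  d <- as.integer(round((2 + 3 * acd_mm) * scale))
  max(2L, min(d, as.integer(H / 2)))
}

#' Render a stylised Scheimpflug cross-section
#'
#' Draws a bright corneal arc band whose pixel thickness is an affine map of
#' pupil-center thickness and a dark anterior-chamber wedge whose vertical
#' extent is an affine map of anterior chamber depth, over a flat background,
#' with additive Gaussian speckle noise. Arc pose (centre, radius, apex row)
#' is drawn from the seed, so geometry is a pure function of
#' (record, config, seed).
#'
#' @param record one-row data.frame or named vector of clinical attributes.
#' @param config a [phantom_config()].
#' @param seed integer seed.
#' @return list with `image` (H x W matrix in `[0,1]`) and `truth` (rendering
#'   geometry: band thickness and chamber depth in px, arc centre/radius, and
#'   the per-column anterior surface row).
#' @export
render_phantom <- function(record, config, seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$image_height; W <- config$image_width
  if (H < 32 || W < 32) stop("image dimensions must be >= 32", call. = FALSE)
  rec <- as.list(record)
  s <- min(H, W) / 64
  t_px <- band_thickness_px(as.numeric(rec$pupil_center_thickness), s)
  d_px <- chamber_depth_px(as.numeric(rec$anterior_chamber_depth), s, H)

  with_seed(seed, {
    cx <- W / 2 + stats::runif(1, -0.05, 0.05) * W
    R <- (1.2 + stats::runif(1, -0.15, 0.15)) * W
    y0 <- round((0.12 + stats::runif(1, -0.03, 0.03)) * H)
    xs <- seq_len(W)
    ya <- y0 + round((xs - cx)^2 / (2 * R))
    ya <- pmax(1L, pmin(as.integer(ya), H - t_px - d_px - 1L))

    img <- matrix(0.15, H, W)
    for (x in xs) {
      a <- ya[x]
      img[a:(a + t_px - 1L), x] <- 0.85
      img[(a + t_px):(a + t_px + d_px - 1L), x] <- 0.05
      lo <- a + t_px + d_px
      if (lo <= H) img[lo:H, x] <- 0.35
    }
    if (config$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W)
    }
    list(image = clip01(img),
         truth = list(band_px = t_px, chamber_px = d_px,
                      arc_center = c(x = cx, y = y0), arc_radius = R,
                      anterior_row = ya))
  })
}

#' Ground-truth informative-region mask
#'
#' Logical H x W mask covering the corneal band plus anterior-chamber wedge,
#' the only pixels whose geometry carries the class label. Used to score
#' Grad-CAM attribution against known ground truth.
#'
#' @param truth the `truth` element returned by [render_phantom()].
#' @param H,W image dimensions.
#' @return logical matrix.
#' @export
phantom_mask <- function(truth, H, W) {
  m <- matrix(FALSE, H, W)
  for (x in seq_len(W)) {
    a <- truth$anterior_row[x]
    b <- min(H, a + truth$band_px + truth$chamber_px - 1L)
    m[a:b, x] <- TRUE
  }
  m
}

#' Generate a labelled phantom cohort
#'
#' Couples [sample_clinical()] and [render_phantom()] into a complete dataset:
#' clinical table, rendered images and rendering ground truth. Each sample
#' gets its own derived seed, so the whole cohort is reproducible from one
#' integer.
#'
#' @param config a [phantom_config()].
#' @param n cohort size.
#' @param seed integer seed.
#' @param eyes_per_patient average eyes contributed per patient; the default 1
#'   gives one patient per sample.
#' @return list with `table` (attributes + `label` + `patient_id`), `images`
#'   (list of matrices) and `truths` (list of rendering geometry).
#' @export
phantom_cohort <- function(config, n, seed = 1L, eyes_per_patient = 1) {
  tab <- sample_clinical(config, n, seed = seed)
  if (eyes_per_patient <= 1) {
    tab$patient_id <- seq_len(n)
  } else {
    tab$patient_id <- with_seed(child_seed(seed, 7L), {
      ids <- rep(seq_len(ceiling(n / eyes_per_patient)),
                 each = ceiling(eyes_per_patient))[seq_len(n)]
      sample(ids)
    })
  }
  images <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    r <- render_phantom(tab[i, ], config, seed = child_seed(seed, i))
    images[[i]] <- r$image
    truths[[i]] <- r$truth
  }
  list(table = tab, images = images, truths = truths, config = config)
}

## ---- artifact injection ----------------------------------------------------

#' Inject a synthetic acquisition artifact
#'
#' Reproduces the failure modes seen in low-quality generated images: corneal
#' edge discontinuities, abnormally bright (saturated) regions, patches of
#' random texture noise, and blur. `magnitude = 0` returns the input
#' unchanged for every kind.
#'
#' @param image H x W matrix in `[0,1]`.
#' @param spec list with `kind` (one of `edge_discontinuity`, `bright_region`,
#'   `texture_noise`, `blur`), `magnitude` in `[0,1]`, and optional `location`
#'   (`c(x, y)` in pixels, or `"random"`).
#' @param seed integer seed used when `location = "random"` and for noise.
#' @return corrupted image matrix in `[0,1]`.
#' @export
inject_artifact <- function(image, spec, seed = 1L) {
  stopifnot_image(image)
  kinds <- c("edge_discontinuity", "bright_region", "texture_noise", "blur")
  if (!spec$kind %in% kinds) {
    stop("unknown artifact kind: ", spec$kind, call. = FALSE)
  }
  mag <- spec$magnitude
  if (mag < 0 || mag > 1) stop("magnitude must be in [0,1]", call. = FALSE)
  if (mag == 0) return(image)
  H <- nrow(image); W <- ncol(image)
  loc <- spec$location %||% "random"

  with_seed(seed, {
    switch(spec$kind,
      edge_discontinuity = {
        gap <- max(2L, as.integer(round(mag * W / 3)))
        x0 <- if (identical(loc, "random")) {
          sample(seq(max(1L, round(0.15 * W)), max(1L, round(0.85 * W) - gap)), 1L)
        } else as.integer(loc[1])
        cols <- x0:min(W, x0 + gap - 1L)
        sub <- image[, cols, drop = FALSE]
        sub[sub > 0.55] <- 0.15
        image[, cols] <- sub
        image
      },
      bright_region = {
        side <- max(3L, as.integer(round(3 + mag * 10)))
        xy <- artifact_origin(loc, H, W, side)
        image[xy[2]:(xy[2] + side - 1L), xy[1]:(xy[1] + side - 1L)] <- 1.0
        image
      },
      texture_noise = {
        side <- max(4L, as.integer(round(mag * min(H, W) / 1.5)))
        xy <- artifact_origin(loc, H, W, side)
        image[xy[2]:(xy[2] + side - 1L), xy[1]:(xy[1] + side - 1L)] <-
          matrix(stats::runif(side * side), side)
        image
      },
      blur = {
        sigma <- 0.5 + 2.5 * mag
        blurred <- EBImage::gblur(image, sigma = sigma)
        clip01(matrix(as.numeric(blurred), H, W))
      }
    )
  })
}

artifact_origin <- function(loc, H, W, side) {
  if (identical(loc, "random")) {
    c(sample(seq_len(W - side), 1L), sample(seq_len(H - side), 1L))
  } else {
    c(min(as.integer(loc[1]), W - side), min(as.integer(loc[2]), H - side))
  }
}

## ---- disk I/O --------------------------------------------------------------

#' Write a phantom cohort to disk
#'
#' Writes one 8-bit grayscale PNG per sample and a clinical CSV table (eight
#' attributes + label + patient id + relative file path).
#'
#' @param cohort result of [phantom_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the CSV table.
#' @export
write_phantom_dataset <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(cohort$table)
  paths <- sprintf("phantom_%04d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(cohort$images[[i]], file.path(dir, paths[i]))
  }
  tab <- cohort$table
  tab$path <- paths
  csv <- file.path(dir, "clinical.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(csv)
}
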