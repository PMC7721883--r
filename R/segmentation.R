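#' Maximum-intensity projection of a stack
#'
#' @param stack an [shg_stack()].
#' @return an [image2d()] with the per-pixel maximum over z.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "shg_stack"))
  d <- dim(stack$voxels)
  out <- matrix(stack$voxels[, , 1], d[1], d[2])
  for (z in seq_len(d[3])[-1]) {
    out <- pmax(out, matrix(stack$voxels[, , z], d[1], d[2]))
  }
  image2d(out, stack$pixel_size_um)
}

#' Per-pixel probability of the crypt class
#'
#' @param probs numeric matrix with values in `[0, 1]`.
#' @param pixel_size_um physical pixel size (um).
#' @return an object of class `probability_map`.
#' @export
probability_map <- function(probs, pixel_size_um) {
  stopifnot(is.matrix(probs))
  check_pixel_size(pixel_size_um)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(list(probs = probs, pixel_size_um = as.numeric(pixel_size_um)),
            class = "probability_map")
}

#' Read an externally produced probability map from TIFF
#'
#' Escape hatch for users with their own pixel classifier: any TIFF whose
#' values scale to `[0, 1]` can replace [predict_probability()] in the
#' pipeline. Integer images are divided by their bit-depth maximum.
#'
#' @param path TIFF path.
#' @param pixel_size_override pixel size in micrometers.
#' @return a [probability_map()].
#' @export
read_probability_map <- function(path, pixel_size_override = NULL) {
  stack <- read_image(path, pixel_size_override)
  m <- stack$voxels[, , 1]
  if (max(m) > 1) {
    maxv <- if (max(m) <= 255) 255 else 65535
    m <- m / maxv
  }
  probability_map(m, stack$pixel_size_um)
}

#' Pixel feature bank
#'
#' Per scale sigma (in px): Gaussian-smoothed intensity, gradient magnitude
#' of the smoothed image, and local variance (Gaussian-weighted
#' E[x^2] - E[x]^2), plus the raw intensity. Reflective boundary handling
#' throughout; fully deterministic.
#'
#' @param img an [image2d()] or matrix.
#' @param scales positive Gaussian sigmas in pixels.
#' @return 3D array (rows, cols, features) with named feature slices.
#' @export
compute_features <- function(img, scales = c(1, 2, 4)) {
  stopifnot(length(scales) >= 1, all(scales > 0))
  m <- as_matrix2d(img)
  feats <- list(raw = m)
  for (s in scales) {
    sm <- gaussian_filter(m, s)
    g <- gradient_cd(sm)
    v <- gaussian_filter(m^2, s) - sm^2
    feats[[sprintf("smooth_s%g", s)]] <- sm
    feats[[sprintf("grad_s%g", s)]] <- sqrt(g$dr^2 + g$dc^2)
    feats[[sprintf("var_s%g", s)]] <- pmax(v, 0)
  }
  arr <- array(unlist(feats, use.names = FALSE),
               dim = c(dim(m), length(feats)))
  dimnames(arr) <- list(NULL, NULL, names(feats))
  arr
}

#' Train a two-stage logistic pixel classifier
#'
#' A deterministic, dependency-light stand-in for an interactively trained
#' autocontext pixel classifier: stage 1 is a logistic linear model over
#' the [compute_features()] bank, fit on sparsely labeled pixels; stage 2
#' (the autocontext stage) refits with Gaussian-smoothed stage-1 crypt
#' probabilities appended as extra features, letting spatial context
#' correct textured-wall errors.
#'
#' @param images list of [image2d()] (or matrices).
#' @param label_masks list of integer matrices aligned with `images`:
#'   0 = unlabeled, 1 = crypt, 2 = collagen/background.
#' @param n_stages 1 or 2.
#' @param scales feature sigmas in px.
#' @param max_train_px cap on labeled pixels used per fit (deterministic
#'   subsample under `seed`).
#' @param seed RNG seed for the subsample.
#' @return an object of class `pixel_classifier`.
#' @export
train_pixel_classifier <- function(images, label_masks, n_stages = 2,
                                   scales = c(1, 2, 4),
                                   max_train_px = 20000L, seed = 1L) {
  stopifnot(n_stages %in% c(1L, 2L), length(images) == length(label_masks),
            length(images) >= 1L)
  mats <- lapply(images, as_matrix2d)
  masks <- lapply(label_masks, function(m) {
    stopifnot(is.matrix(m), all(m %in% c(0L, 1L, 2L)))
    m
  })
  n_lab <- sum(vapply(masks, function(m) sum(m > 0L), numeric(1)))
  if (n_lab == 0L) {
    stop("label masks are empty")
  }
  classes <- unique(unlist(lapply(masks, function(m) unique(m[m > 0L]))))
  if (length(classes) < 2L) {
    stop("labels of only one class; need both crypt and collagen pixels")
  }

  feat_list <- lapply(mats, compute_features, scales = scales)
  gather <- function(feats) {
    x <- do.call(rbind, lapply(seq_along(feats), function(i) {
      sel <- masks[[i]] > 0L
      apply(feats[[i]], 3L, function(sl) sl[sel])
    }))
    y <- unlist(lapply(masks, function(m) m[m > 0L])) == 1L
    list(x = as.matrix(x), y = y)
  }

  fit_stage <- function(x, y) {
    if (nrow(x) > max_train_px) {
      keep <- withr::with_seed(seed, sample.int(nrow(x), max_train_px))
      x <- x[keep, , drop = FALSE]
      y <- y[keep]
    }
    center <- colMeans(x)
    scale <- apply(x, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, xs), as.numeric(y),
                     family = stats::binomial())
    )
    coef <- fit$coefficients
    coef[!is.finite(coef)] <- 0
    list(center = center, scale = scale, coef = coef)
  }

  d1 <- gather(feat_list)
  stage1 <- fit_stage(d1$x, d1$y)
  stages <- list(stage1)

  if (n_stages == 2L) {
    feat2 <- lapply(seq_along(mats), function(i) {
      p1 <- stage_probability(feat_list[[i]], stage1)
      augment_with_context(feat_list[[i]], p1, scales)
    })
    feat_list2 <- feat2
    d2 <- local({
      x <- do.call(rbind, lapply(seq_along(feat_list2), function(i) {
        sel <- masks[[i]] > 0L
        apply(feat_list2[[i]], 3L, function(sl) sl[sel])
      }))
      y <- unlist(lapply(masks, function(m) m[m > 0L])) == 1L
      list(x = as.matrix(x), y = y)
    })
    stages[[2L]] <- fit_stage(d2$x, d2$y)
  }

  structure(list(scales = scales, n_stages = as.integer(n_stages),
                 stages = stages),
            class = "pixel_classifier")
}

stage_probability <- function(feats, stage) {
  d <- dim(feats)
  x <- matrix(feats, d[1] * d[2], d[3])
  xs <- sweep(sweep(x, 2L, stage$center), 2L, stage$scale, "/")
  eta <- drop(cbind(1, xs) %*% stage$coef)
  matrix(stats::plogis(eta), d[1], d[2])
}

augment_with_context <- function(feats, prob, scales) {
  extra <- lapply(scales, function(s) gaussian_filter(prob, s))
  arr <- array(c(feats, unlist(extra)),
               dim = c(dim(prob), dim(feats)[3] + length(scales)))
  dimnames(arr) <- list(NULL, NULL,
                        c(dimnames(feats)[[3]],
                          sprintf("context_s%g", scales)))
  arr
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d stage(s), scales {%s} px, %d features\n",
              x$n_stages, paste(x$scales, collapse = ", "),
              length(x$stages[[1]]$coef) - 1L))
  invisible(x)
}

#' Predict the crypt-class probability map for an image
#'
#' @param classifier a [train_pixel_classifier()] result.
#' @param img an [image2d()].
#' @return a [probability_map()]; the complementary (collagen) class is
#'   one minus these values.
#' @export
predict_probability <- function(classifier, img) {
  stopifnot(inherits(classifier, "pixel_classifier"),
            inherits(img, "image2d"))
  feats <- compute_features(img, classifier$scales)
  check_stage_dim(classifier$stages[[1]], feats)
  p <- stage_probability(feats, classifier$stages[[1]])
  if (classifier$n_stages == 2L) {
    feats2 <- augment_with_context(feats, p, classifier$scales)
    check_stage_dim(classifier$stages[[2]], feats2)
    p <- stage_probability(feats2, classifier$stages[[2]])
  }
  probability_map(p, img$pixel_size_um)
}

check_stage_dim <- function(stage, feats) {
  if (length(stage$coef) - 1L != dim(feats)[3]) {
    stop(sprintf("feature-dimension mismatch: classifier expects %d, got %d",
                 length(stage$coef) - 1L, dim(feats)[3]))
  }
}

#' Hysteresis thresholding of a probability map
#'
#' A pixel is selected iff its probability strictly exceeds `low` and it is
#' connected, through pixels above `low`, to some pixel strictly above
#' `high`. Strict inequalities are used at both levels so the operation is
#' exactly defined; ties at a float threshold are measure-zero in practice.
#'
#' @param prob_map a [probability_map()] or numeric matrix in `[0, 1]`.
#' @param low,high thresholds with `0 <= low <= high <= 1`.
#' @param connectivity 8 (default) or 4.
#' @return logical matrix mask.
#' @export
hysteresis_segment <- function(prob_map, low = 0.5, high = 0.8,
                               connectivity = 8) {
  probs <- if (inherits(prob_map, "probability_map")) {
    prob_map$probs
  } else {
    as_matrix2d(prob_map)
  }
  stopifnot(low >= 0, low <= high, high <= 1)
  comp <- label_components(probs > low, connectivity = connectivity)
  seeds <- unique(comp[probs > high])
  seeds <- seeds[seeds > 0L]
  matrix(comp %in% seeds, nrow(probs), ncol(probs))
}

#' Post-process a binary crypt mask into a label map
#'
#' Objects are 8-connected components of the mask. Background holes fully
#' enclosed by a single object are filled into it (background connectivity
#' 4), *before* the size filter, so filled area counts toward the minimum;
#' objects smaller than `min_area_um2` are then discarded, labels are
#' renumbered contiguously by descending area, and border flags mark
#' objects touching any image edge. The operation is idempotent.
#'
#' @param mask logical (or 0/1) matrix.
#' @param pixel_size_um physical pixel size (um).
#' @param min_area_um2 minimum object area kept, in um^2 (default 300).
#' @return a [crypt_label_map()].
#' @export
postprocess_labels <- function(mask, pixel_size_um, min_area_um2 = 300) {
  stopifnot(is.matrix(mask))
  check_pixel_size(pixel_size_um)
  lab <- label_components(mask != 0, connectivity = 8)
  lab <- fill_holes_single_owner(lab)
  k <- max(lab, 0L)
  if (k > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = k) * pixel_size_um^2
    drop <- which(areas < min_area_um2)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
    }
    lab <- renumber_by_area(relabel_contiguous(lab))
  }
  crypt_label_map(lab, pixel_size_um)
}

relabel_contiguous <- function(lab) {
  k <- max(lab, 0L)
  if (k == 0L) {
    return(lab)
  }
  present <- sort(unique(lab[lab > 0L]))
  renum <- integer(k)
  renum[present] <- seq_along(present)
  lab[lab > 0L] <- renum[lab[lab > 0L]]
  lab
}

#' Segment crypts from a stack, image, or probability map
#'
#' Convenience composition of the full segmentation path: max projection
#' (for stacks), probability prediction (unless a probability map is given
#' directly), hysteresis thresholding and post-processing.
#'
#' @param x an [shg_stack()], [image2d()], or [probability_map()].
#' @param classifier a [pixel_classifier][train_pixel_classifier()];
#'   required unless `x` is already a probability map.
#' @param config an [analysis_config()].
#' @return a [crypt_label_map()].
#' @export
segment_crypts <- function(x, classifier = NULL,
                           config = analysis_config()) {
  if (inherits(x, "shg_stack")) {
    x <- max_project(x)
  }
  if (inherits(x, "image2d")) {
    if (is.null(classifier)) {
      stop("a classifier is required to segment an intensity image")
    }
    x <- predict_probability(classifier, x)
  }
  stopifnot(inherits(x, "probability_map"))
  mask <- hysteresis_segment(x, config$low_threshold, config$high_threshold)
  postprocess_labels(mask, x$pixel_size_um, config$min_area_um2)
}
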