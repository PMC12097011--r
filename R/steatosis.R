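#' Multi-scale voxel features for steatosis segmentation
#'
#' The steatotic phenotype in Nissl bright-field volumes is a vacuolated,
#' intermediate-bright region textured by interspersed small dark cells; it
#' is separable from parenchyma and lumens by smoothed intensity and local
#' texture.  Features per voxel: Gaussian-smoothed intensity at each scale,
#' local standard deviation at each scale, and the local intensity range
#' (one-voxel neighbourhood), giving `2 * length(scales) + 1` features.
#' Scales are interpreted as FWHM in um (`sigma = scale / 2.355`), so the
#' finest admissible scale stays close to the raw voxel value.
#'
#' @param gray a grayscale `voxel_grid`.
#' @param scales_um smoothing scales in um; each must be >= the voxel
#'   spacing.
#' @return an object of class `feature_stack`: matrix (n_voxels x n_features)
#'   plus the feature specification.
#' @export
extract_features <- function(gray, scales_um = c(2, 4, 8)) {
  stopifnot_voxel_grid(gray, "gray")
  if (length(scales_um) == 0) stop("scales_um must be nonempty")
  if (any(scales_um < max(gray$spacing)))
    stop("every scale must be at least the voxel spacing")
  x <- gray$data
  d <- dim(x)
  nfeat <- 2L * length(scales_um) + 1L
  F <- matrix(0, length(x), nfeat)
  fnames <- character(nfeat)
  col <- 0L
  for (s in scales_um) {
    sig <- s / 2.355 / gray$spacing  # scale is FWHM
    g1 <- cpp_gauss_smooth(as.vector(x), d, sig)
    g2 <- cpp_gauss_smooth(as.vector(x)^2, d, sig)
    col <- col + 1L
    F[, col] <- g1
    fnames[col] <- sprintf("gauss_%g", s)
    col <- col + 1L
    F[, col] <- sqrt(pmax(g2 - g1^2, 0))
    fnames[col] <- sprintf("localsd_%g", s)
  }
  col <- col + 1L
  F[, col] <- cpp_minmax_filter(as.vector(x), d, 1L, TRUE) -
    cpp_minmax_filter(as.vector(x), d, 1L, FALSE)
  fnames[col] <- "range_1vox"
  colnames(F) <- fnames
  structure(list(features = F, names = fnames, scales_um = scales_um,
                 dim = d, spacing = gray$spacing, origin = gray$origin),
            class = "feature_stack")
}

#' Train the steatosis voxel classifier
#'
#' A regularized logistic-regression voxel classifier on the multi-scale
#' feature stack — a desk-scale stand-in for cloud deep-learning semantic
#' segmentation that preserves the measured interfaces: sparse
#' target/background annotation, iterative training, and loss / accuracy /
#' IoU curves on training and held-out validation voxels.  Unlabeled voxels
#' never enter the loss.  Internally the standardized features are augmented
#' with their squares, so classes occupying an intermediate intensity band
#' (the steatotic phenotype sits between dark parenchyma and bright lumens)
#' are separable by the otherwise linear model.  Training is full-batch
#' gradient descent and is exactly reproducible given `seed`.
#'
#' @param features a `feature_stack` from [extract_features()].
#' @param labels a `voxel_grid` with 0 = unlabeled, 1 = target (steatosis),
#'   2 = background; both classes must be present.
#' @param iterations number of gradient steps (>= 1).
#' @param val_fraction fraction of labeled voxels held out for validation,
#'   in (0, 1).
#' @param seed RNG seed for the train/validation split.
#' @param learning_rate gradient step size on standardized features.
#' @param log_every record the training curves every this many iterations.
#' @return list with `classifier` (class `voxel_classifier`) and `curves`
#'   (data.frame of class `training_curves`: iteration, loss, train/val
#'   accuracy, train/val IoU).
#' @export
train_classifier <- function(features, labels, iterations = 300,
                             val_fraction = 0.25, seed = 1,
                             learning_rate = 0.5, log_every = 50) {
  stopifnot(inherits(features, "feature_stack"))
  stopifnot_voxel_grid(labels, "labels")
  if (!identical(dim(labels$data), features$dim))
    stop("labels and features disagree on grid shape")
  if (iterations < 1) stop("iterations must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  lab <- as.vector(labels$data)
  labeled <- which(lab == 1L | lab == 2L)
  if (!any(lab == 1L) || !any(lab == 2L))
    stop("annotation must contain both target and background voxels")
  y <- as.numeric(lab[labeled] == 1L)

  set.seed(seed)
  nval <- max(1L, round(val_fraction * length(labeled)))
  val_sel <- sample(seq_along(labeled), nval)
  tr_sel <- setdiff(seq_along(labeled), val_sel)
  if (length(unique(y[tr_sel])) < 2)
    stop("training split lost one class; annotate more voxels")

  X <- features$features[labeled, , drop = FALSE]
  mu <- colMeans(X[tr_sel, , drop = FALSE])
  sdv <- apply(X[tr_sel, , drop = FALSE], 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xs <- cbind(Xs, Xs^2) # quadratic expansion: intermediate bands

  w <- rep(0, ncol(Xs))
  b <- 0
  lambda <- 1e-4
  curves <- list()
  metrics <- function(sel) {
    p <- stats::plogis(Xs[sel, , drop = FALSE] %*% w + b)
    pred <- p >= 0.5
    yy <- y[sel] == 1
    acc <- mean(pred == yy)
    inter <- sum(pred & yy)
    uni <- sum(pred | yy)
    iou <- if (uni == 0) 1 else inter / uni
    c(acc = acc, iou = iou)
  }
  for (it in seq_len(iterations)) {
    eta <- stats::plogis(Xs[tr_sel, , drop = FALSE] %*% w + b)
    err <- as.vector(eta) - y[tr_sel]
    gw <- crossprod(Xs[tr_sel, , drop = FALSE], err) / length(tr_sel) +
      lambda * w
    gb <- mean(err)
    w <- w - learning_rate * as.vector(gw)
    b <- b - learning_rate * gb
    if (it %% log_every == 0 || it == iterations || it == 1) {
      eta <- stats::plogis(Xs[tr_sel, , drop = FALSE] %*% w + b)
      eps <- 1e-12
      loss <- -mean(y[tr_sel] * log(eta + eps) +
                      (1 - y[tr_sel]) * log(1 - eta + eps))
      mt <- metrics(tr_sel)
      mv <- metrics(val_sel)
      curves[[length(curves) + 1]] <- data.frame(
        iteration = it, loss = loss,
        train_accuracy = mt["acc"], val_accuracy = mv["acc"],
        train_iou = mt["iou"], val_iou = mv["iou"], row.names = NULL)
    }
  }
  curves <- do.call(rbind, curves)
  class(curves) <- c("training_curves", "data.frame")
  clf <- structure(list(weights = as.vector(w), bias = b,
                        feature_names = features$names,
                        scales_um = features$scales_um,
                        standardize = list(mu = mu, sd = sdv),
                        threshold = 0.5, seed = seed),
                   class = "voxel_classifier")
  list(classifier = clf, curves = curves)
}

#' Predict a steatosis mask with morphological post-processing
#'
#' Applies the classifier voxel-wise, thresholds at its decision threshold,
#' then (optionally) closes the mask with a ball of `closing_radius_um` and
#' removes connected components smaller than `min_component_um3`.
#'
#' @param classifier a `voxel_classifier`.
#' @param features a `feature_stack` built with the same specification as at
#'   training time (checked).
#' @param closing_radius_um morphological closing radius, um (0 = off).
#' @param min_component_um3 minimum component volume retained (0 = off).
#' @return a logical `voxel_grid`.
#' @export
predict_steatosis <- function(classifier, features, closing_radius_um = 0,
                              min_component_um3 = 0) {
  stopifnot(inherits(classifier, "voxel_classifier"))
  stopifnot(inherits(features, "feature_stack"))
  if (!identical(classifier$feature_names, features$names))
    stop("feature specification differs from the one used in training")
  Xs <- sweep(sweep(features$features, 2, classifier$standardize$mu), 2,
              classifier$standardize$sd, "/")
  Xs <- cbind(Xs, Xs^2)
  score <- stats::plogis(as.vector(Xs %*% classifier$weights + classifier$bias))
  m <- array(score >= classifier$threshold, features$dim)
  spacing <- features$spacing
  if (closing_radius_um > 0 && any(m)) {
    r <- closing_radius_um
    dil <- array(cpp_edt(as.vector(m), features$dim, spacing) <= r,
                 features$dim)
    m <- array(cpp_edt(as.vector(!dil), features$dim, spacing) > r,
               features$dim)
  }
  if (min_component_um3 > 0 && any(m)) {
    lab <- cpp_label_components(as.vector(m), features$dim, 26L)
    sizes <- tabulate(lab)
    keep <- sizes * prod(spacing) >= min_component_um3
    m <- array(lab > 0 & keep[pmax(lab, 1L)], features$dim)
  }
  voxel_grid(m, spacing, features$origin, "labels")
}

#' Validate a classifier on labeled voxels of an independent volume
#'
#' Applies the classifier to a feature stack and scores it on the labeled
#' voxels (1 = target, 2 = background, 0 = ignored) of an annotation volume —
#' the held-out evaluation used to report final validation accuracy/IoU.
#'
#' @param classifier a `voxel_classifier`.
#' @param features a `feature_stack` (same specification as training).
#' @param labels a 0/1/2 annotation `voxel_grid`.
#' @return list with `accuracy`, `iou` and `n` (labeled voxels scored).
#' @export
validate_classifier <- function(classifier, features, labels) {
  stopifnot(inherits(classifier, "voxel_classifier"))
  if (!identical(classifier$feature_names, features$names))
    stop("feature specification differs from the one used in training")
  lab <- as.vector(labels$data)
  sel <- which(lab == 1L | lab == 2L)
  if (length(sel) == 0) stop("no labeled voxels to validate on")
  Xs <- sweep(sweep(features$features[sel, , drop = FALSE], 2,
                    classifier$standardize$mu), 2,
              classifier$standardize$sd, "/")
  Xs <- cbind(Xs, Xs^2)
  p <- stats::plogis(as.vector(Xs %*% classifier$weights + classifier$bias))
  pred <- p >= classifier$threshold
  y <- lab[sel] == 1L
  inter <- sum(pred & y)
  uni <- sum(pred | y)
  list(accuracy = mean(pred == y),
       iou = if (uni == 0) 1 else inter / uni,
       n = length(sel))
}

#' Overlap metrics between a predicted and a reference mask
#'
#' @param pred,truth `voxel_grid` masks on the same grid.
#' @return list with `accuracy` (voxelwise agreement), `iou`
#'   (intersection-over-union, defined as 1 when both masks are empty) and
#'   `dice`.
#' @export
evaluate_overlap <- function(pred, truth) {
  stopifnot_voxel_grid(pred, "pred")
  stopifnot_voxel_grid(truth, "truth")
  check_same_grid(pred, truth, "pred and truth")
  p <- as_logical_mask(pred)
  t <- as_logical_mask(truth)
  inter <- sum(p & t)
  uni <- sum(p | t)
  list(accuracy = mean(p == t),
       iou = if (uni == 0) 1 else inter / uni,
       dice = if (sum(p) + sum(t) == 0) 1 else 2 * inter / (sum(p) + sum(t)))
}

#' Extract masked grayscale values (label times gray)
#'
#' The standard "multiply the labeled image by the grayscale image" step:
#' grayscale is kept where the mask is set and zeroed elsewhere.
#'
#' @param gray grayscale `voxel_grid`.
#' @param mask `voxel_grid` mask on the same grid.
#' @return a grayscale `voxel_grid`.
#' @export
apply_mask <- function(gray, mask) {
  stopifnot_voxel_grid(gray, "gray")
  stopifnot_voxel_grid(mask, "mask")
  check_same_grid(gray, mask, "gray and mask")
  out <- gray$data * as.numeric(as_logical_mask(mask))
  voxel_grid(array(out, dim(gray$data)), gray$spacing, gray$origin,
             "grayscale")
}
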