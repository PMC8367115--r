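# Surrogate pill classifier: a transparent nearest-class-mean model over
# colour and shape features, evaluated with top-k accuracy per imaging
# condition.  It stands in for a GPU-trained CNN so the accuracy-vs-colour-
# difference analysis is executable at desk scale; the evaluation interface
# accepts any model with a compatible predict method.

# Boundary length from the 8-connected contour chain with the
# Vossepoel-Smeulders step weights (0.948 straight, 1.340 diagonal), a
# low-bias perimeter estimator for digitised smooth shapes.
chain_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask * 1))
  if (!length(oc)) return(0)
  pts <- oc[[which.max(vapply(oc, nrow, 0L))]]
  d <- abs(pts - pts[c(2:nrow(pts), 1), , drop = FALSE])
  steps <- rowSums(pmin(d, 1))
  sum(ifelse(steps == 2, 1.340, 0.948))
}

#' Feature vector of a segmented pill ROI
#'
#' Colour features are the mean L*a*b* of the masked region; shape features
#' are scale-invariant (area fraction of the square crop, aspect ratio and
#' eccentricity from normalised central moments, circularity 4*pi*A/P^2);
#' the imprint score is the coefficient of variation of the grayscale
#' intensity inside the (eroded) mask, which responds to embossed glyphs.
#'
#' @param roi H x W x 3 8-bit RGB crop.
#' @param mask logical pill mask of matching dimensions.
#' @param white reference white for the Lab conversion.
#' @return Named numeric vector with elements `L`, `a`, `b`,
#'   `area_fraction`, `aspect`, `eccentricity`, `circularity`,
#'   `imprint_score`.
#' @export
featurize_roi <- function(roi, mask, white = "anchored") {
  check_rgb_image(roi)
  stopifnot(identical(dim(mask), dim(roi)[1:2]))
  if (!any(mask)) {
    pc_stop("pillchroma_domain_error", "featurize_roi: empty mask")
  }
  lab <- rgb_to_lab(roi_mean_color(roi, mask), white = white)

  idx <- which(mask, arr.ind = TRUE)
  yc <- idx[, 1] - mean(idx[, 1])
  xc <- idx[, 2] - mean(idx[, 2])
  mu20 <- mean(yc^2); mu02 <- mean(xc^2); mu11 <- mean(yc * xc)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  aspect <- sqrt(l1 / l2)
  ecc <- sqrt(max(1 - l2 / l1, 0))

  perim <- chain_perimeter(mask)
  circ <- if (perim > 0) 4 * pi * sum(mask) / perim^2 else NA_real_

  core <- EBImage::erode(mask * 1, EBImage::makeBrush(3, "diamond")) > 0
  if (!any(core)) core <- mask
  gray <- to_grayscale(roi)
  gv <- gray[core]
  imprint <- if (mean(gv) > 0) sd(gv) / mean(gv) else 0
  if (is.na(imprint)) imprint <- 0

  c(L = unname(lab[1]), a = unname(lab[2]), b = unname(lab[3]),
    area_fraction = sum(mask) / length(mask),
    aspect = aspect, eccentricity = ecc, circularity = unname(circ),
    imprint_score = imprint)
}

#' Fit a nearest-class-mean pill classifier
#'
#' Standardises each feature dimension over the training pool (zero mean,
#' unit variance; constant dimensions are left unscaled) and stores the
#' per-class mean in the standardised space.  Prediction ranks classes by
#' Euclidean distance to these means, breaking ties by ascending label.
#' The fit is invariant to the order of the training rows.
#'
#' @param x numeric matrix of feature vectors (one row per training image).
#' @param labels integer class labels, one per row of `x`; every class must
#'   have at least one example.
#' @return An object of class `pill_classifier` with components `means`
#'   (class x feature matrix), `center`, `scale`, `labels`.
#' @seealso [predict.pill_classifier()], [topk_accuracy()]
#' @export
pill_classifier <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), nrow(x) >= 1)
  if (anyNA(x)) {
    pc_stop("pillchroma_training_error", "feature matrix contains missing values")
  }
  labs <- sort(unique(labels))
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  z <- scale(x, center = center, scale = scl)
  means <- t(vapply(labs, function(l) colMeans(z[labels == l, , drop = FALSE]),
                    numeric(ncol(x))))
  rownames(means) <- labs
  structure(list(means = means, center = center, scale = scl, labels = labs),
            class = "pill_classifier")
}

#' Rank class labels for new feature vectors
#'
#' @param object a [pill_classifier()].
#' @param newdata feature vector or matrix (one row per image).
#' @param k number of top-ranked labels to return (1 to the number of
#'   classes).
#' @param ... unused.
#' @return An n x k integer matrix: labels ordered by ascending distance to
#'   the class means, ties broken by ascending label.
#' @export
predict.pill_classifier <- function(object, newdata, k = 1, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, 1)
  newdata <- as.matrix(newdata)
  K <- length(object$labels)
  if (k < 1 || k > K) {
    pc_stop("pillchroma_domain_error", "k must lie in [1, %d]", K)
  }
  z <- scale(newdata, center = object$center, scale = object$scale)
  out <- matrix(NA_integer_, nrow(z), k)
  for (i in seq_len(nrow(z))) {
    d <- sqrt(colSums((t(object$means) - z[i, ])^2))
    ord <- order(d, object$labels)
    out[i, ] <- object$labels[ord[seq_len(k)]]
  }
  out
}

#' @export
print.pill_classifier <- function(x, ...) {
  cat(sprintf("Nearest-class-mean pill classifier: %d classes, %d features\n",
              length(x$labels), ncol(x$means)))
  cat("  features:", paste(colnames(x$means), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.pill_classifier <- function(object, ...) {
  cat(sprintf("Nearest-class-mean classifier over %d classes\n",
              length(object$labels)))
  cat("Standardised class means:\n")
  print(round(object$means, 3))
  invisible(object)
}

#' @export
coef.pill_classifier <- function(object, ...) object$means

#' Top-k accuracy per imaging condition
#'
#' @param model a [pill_classifier()] (or any model whose `predict` returns
#'   an n x k label matrix).
#' @param x feature matrix of the evaluation images.
#' @param labels true labels.
#' @param condition condition name per image.
#' @param k vector of cutoffs (default `c(1, 5)`).
#' @return Data frame `condition`, `k`, `accuracy`, `n`.
#' @export
topk_accuracy <- function(model, x, labels, condition, k = c(1, 5)) {
  x <- as.matrix(x)
  if (nrow(x) == 0) {
    pc_stop("pillchroma_domain_error", "empty evaluation set")
  }
  stopifnot(nrow(x) == length(labels), length(labels) == length(condition))
  kmax <- max(k)
  pred <- predict(model, x, k = kmax)
  res <- list()
  for (cond in unique(condition)) {
    sel <- condition == cond
    for (kk in sort(k)) {
      hit <- vapply(which(sel), function(i) labels[i] %in% pred[i, seq_len(kk)],
                    logical(1))
      res[[length(res) + 1L]] <- data.frame(
        condition = cond, k = kk, accuracy = mean(hit), n = sum(sel),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}

#' Serialise / restore a classifier as JSON
#'
#' @param model a [pill_classifier()].
#' @param path output/input file path.
#' @return `write_classifier` returns `path` invisibly; `read_classifier`
#'   returns the restored `pill_classifier`.
#' @export
write_classifier <- function(model, path) {
  jsonlite::write_json(
    list(means = model$means, center = model$center, scale = model$scale,
         labels = model$labels, feature_names = colnames(model$means)),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- j$means
  colnames(means) <- j$feature_names
  rownames(means) <- j$labels
  structure(list(means = means,
                 center = setNames(j$center, j$feature_names),
                 scale = setNames(j$scale, j$feature_names),
                 labels = j$labels),
            class = "pill_classifier")
}
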