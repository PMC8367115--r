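# Region-of-interest extraction: the nine-step preprocessing chain that
# isolates the pill from a photograph.  Grayscale -> Gaussian blur ->
# threshold, Canny edge tracing -> contour closing and filling, then the
# original image is masked and cropped to a square window around the pill.
#
# Standard image operations (blur, Otsu threshold, morphological closing,
# hole filling, connected components) come from EBImage; the Canny detector
# (Sobel gradients, non-maximum suppression, hysteresis) is implemented here.

#' Segmentation parameters
#'
#' @param blur_radius Gaussian blur sigma in pixels applied before
#'   thresholding and edge detection (default 2).
#' @param canny_low,canny_high hysteresis thresholds on the Sobel gradient
#'   magnitude, 8-bit scale (defaults 50 and 150).
#' @param pad padding in pixels added around the tight bounding box before
#'   squaring (default 2).
#' @param edges_from source image for the Canny stage: `"blur"` feeds the
#'   blurred grayscale, `"threshold"` feeds the binarised mask.
#' @return A named list of class `roi_params`.
#' @export
roi_params <- function(blur_radius = 2, canny_low = 50, canny_high = 150,
                       pad = 2, edges_from = c("blur", "threshold")) {
  stopifnot(blur_radius >= 0, canny_low < canny_high, pad >= 0)
  structure(list(
    blur_radius = blur_radius, canny_low = canny_low,
    canny_high = canny_high, pad = pad,
    edges_from = match.arg(edges_from)
  ), class = "roi_params")
}

#' Convert an RGB image to grayscale
#'
#' Luma combination with ITU-R BT.601 weights (0.299, 0.587, 0.114).
#'
#' @param img H x W x 3 array with 8-bit channel values.
#' @return H x W numeric matrix in `[0, 255]`.
#' @export
to_grayscale <- function(img) {
  check_rgb_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Blur-and-threshold segmentation
#'
#' Gaussian blur followed by a global Otsu threshold.  The foreground is the
#' side of the threshold *not* occupied by the image border (the pill sits
#' in the interior; the border is background), then reduced to its largest
#' connected component with holes filled.
#'
#' @param gray H x W grayscale matrix in `[0, 255]`.
#' @param blur_radius Gaussian sigma in pixels; 0 skips the blur.
#' @return Logical foreground mask of the same dimensions.
#' @export
binarize_mask <- function(gray, blur_radius = 2) {
  stopifnot(is.matrix(gray))
  g <- gray / 255
  if (blur_radius > 0) g <- EBImage::gblur(g, sigma = blur_radius)
  if (diff(range(g)) < 1e-6) {
    pc_stop("pillchroma_threshold_error",
            "image is constant after blurring; no threshold separates foreground from background")
  }
  thr <- EBImage::otsu(EBImage::Image(clip01(g)))
  border <- c(g[1:2, ], g[nrow(g) - 0:1, ], g[, 1:2], g[, ncol(g) - 0:1])
  fg <- if (mean(border) > thr) g < thr else g > thr
  if (!any(fg) || all(fg)) {
    pc_stop("pillchroma_threshold_error",
            "degenerate threshold: foreground is empty or covers the whole image")
  }
  lab <- EBImage::bwlabel(fg)
  best <- which.max(tabulate(lab[lab > 0]))
  EBImage::fillHull(lab == best) > 0
}

shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dy, 1), H)
  ci <- pmin(pmax(seq_len(W) + dx, 1), W)
  m[ri, ci, drop = FALSE]
}

#' Canny edge detection
#'
#' Gaussian blur, Sobel gradients, non-maximum suppression along the
#' quantised gradient direction, and hysteresis: weak edges (magnitude at
#' least `low`) are kept only in connected components containing a strong
#' edge (magnitude at least `high`).
#'
#' @param gray H x W grayscale matrix in `[0, 255]`.
#' @param low,high hysteresis thresholds on the Sobel magnitude (8-bit
#'   scale).
#' @param blur_radius Gaussian sigma applied before differentiation.
#' @return Logical edge map.
#' @export
canny_edges <- function(gray, low = 50, high = 150, blur_radius = 2) {
  stopifnot(is.matrix(gray), low < high)
  g <- gray
  if (blur_radius > 0) g <- EBImage::gblur(g, sigma = blur_radius)
  gx <- (shift_mat(g, -1, 1) + 2 * shift_mat(g, 0, 1) + shift_mat(g, 1, 1)) -
        (shift_mat(g, -1, -1) + 2 * shift_mat(g, 0, -1) + shift_mat(g, 1, -1))
  gy <- (shift_mat(g, 1, -1) + 2 * shift_mat(g, 1, 0) + shift_mat(g, 1, 1)) -
        (shift_mat(g, -1, -1) + 2 * shift_mat(g, -1, 0) + shift_mat(g, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  # non-maximum suppression in one of four quantised directions
  theta <- atan2(gy, gx)
  bin <- (round(theta / (pi / 4)) %% 4)
  n1 <- mag; n2 <- mag
  for (b in 0:3) {
    off <- switch(b + 1L,
      list(c(0, 1), c(0, -1)),    # horizontal gradient -> compare left/right
      list(c(1, 1), c(-1, -1)),   # diagonal
      list(c(1, 0), c(-1, 0)),    # vertical gradient -> compare up/down
      list(c(1, -1), c(-1, 1))    # anti-diagonal
    )
    sel <- bin == b
    n1[sel] <- shift_mat(mag, off[[1]][1], off[[1]][2])[sel]
    n2[sel] <- shift_mat(mag, off[[2]][1], off[[2]][2])[sel]
  }
  nms <- mag >= n1 & mag >= n2
  weak <- nms & mag >= low
  strong <- nms & mag >= high
  if (!any(strong)) return(matrix(FALSE, nrow(gray), ncol(gray)))
  lab <- EBImage::bwlabel(weak)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  lab %in% keep & weak
}

#' Trace the pill outline and fill it
#'
#' Canny edge map, morphological closing to seal small gaps in the outline,
#' hole filling, then the largest connected component is returned as the
#' pill mask.  A thin erosion compensates the closing dilation so the filled
#' area tracks the true object area.  Fails when no filled interior emerges
#' (open contour or blank image).
#'
#' @param gray H x W grayscale matrix in `[0, 255]` (typically the blurred
#'   grayscale or a binarised mask scaled to 0/255).
#' @param canny_low,canny_high hysteresis thresholds.
#' @param blur_radius blur applied inside the Canny stage.
#' @return Logical pill mask.
#' @export
trace_and_fill <- function(gray, canny_low = 50, canny_high = 150,
                           blur_radius = 2) {
  edges <- canny_edges(gray, canny_low, canny_high, blur_radius)
  if (!any(edges)) {
    pc_stop("pillchroma_segmentation_error",
            "trace_and_fill: no edges found by the Canny detector")
  }
  brush <- EBImage::makeBrush(3, "diamond")
  closed <- EBImage::closing(edges * 1, brush) > 0
  filled <- EBImage::fillHull(closed * 1) > 0
  interior <- filled & !closed
  lab <- EBImage::bwlabel(filled)
  best <- which.max(tabulate(lab[lab > 0]))
  region <- lab == best
  if (sum(interior & region) < pmax(32, 0.25 * sum(region))) {
    pc_stop("pillchroma_segmentation_error",
            "trace_and_fill: no closed contour could be filled")
  }
  EBImage::erode(region * 1, brush) > 0
}

#' Mask the image and crop a square window around the pill
#'
#' Sets every pixel outside the mask to black, takes the tight bounding box
#' of the mask, pads it, and expands the shorter side symmetrically to a
#' square.  When the square window would cross the image border it is
#' shifted inward; it shrinks only if the image itself is smaller than the
#' window.
#'
#' @param img H x W x 3 8-bit RGB array.
#' @param mask logical matrix of the same height/width.
#' @param pad padding in pixels around the tight box.
#' @return A list with `roi` (cropped masked image), `roi_mask` (cropped
#'   mask) and `bbox` (`c(row_min, col_min, row_max, col_max)`, half-open,
#'   0-based rows/cols convention: 1-based inclusive start, exclusive end).
#' @export
mask_and_crop <- function(img, mask, pad = 2) {
  check_rgb_image(img)
  stopifnot(identical(dim(mask), dim(img)[1:2]))
  if (!any(mask)) {
    pc_stop("pillchroma_segmentation_error", "mask_and_crop: empty mask")
  }
  H <- nrow(mask); W <- ncol(mask)
  masked <- img
  for (ch in 1:3) {
    pl <- masked[, , ch]
    pl[!mask] <- 0
    masked[, , ch] <- pl
  }
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  side <- max(diff(rr), diff(cc)) + 1 + 2 * pad
  side <- min(side, H, W)
  place <- function(center, side, limit) {
    lo <- round(center - side / 2)
    lo <- min(max(lo, 1), limit - side + 1)
    c(lo, lo + side)  # half-open
  }
  rwin <- place(mean(rr), side, H)
  cwin <- place(mean(cc), side, W)
  list(
    roi = masked[rwin[1]:(rwin[2] - 1), cwin[1]:(cwin[2] - 1), , drop = FALSE],
    roi_mask = mask[rwin[1]:(rwin[2] - 1), cwin[1]:(cwin[2] - 1), drop = FALSE],
    bbox = c(row_min = rwin[1], col_min = cwin[1],
             row_max = rwin[2], col_max = cwin[2])
  )
}

#' Extract the pill region of interest
#'
#' Runs the full preprocessing chain: grayscale conversion, blur/threshold
#' binarisation, Canny contour tracing and filling, masking and square
#' cropping.  When the contour-fill strategy fails (open contour, blank edge
#' map, implausible area) the thresholded mask is used instead and the
#' result is flagged as a fallback; when both strategies fail a
#' segmentation error is raised naming the stages.
#'
#' @param img H x W x 3 8-bit RGB array.
#' @param config a [roi_params()] list.
#' @return A list of class `pill_roi`: `roi` (square cropped masked image),
#'   `mask` (full-size pill mask), `roi_mask`, `bbox`, `fallback` (logical),
#'   `stage` (`"contour_fill"` or `"threshold"`).
#' @export
extract_roi <- function(img, config = roi_params()) {
  gray <- to_grayscale(img)
  bin <- tryCatch(binarize_mask(gray, config$blur_radius), error = identity)
  edges_src <- if (config$edges_from == "blur") {
    gray
  } else if (!inherits(bin, "error")) {
    bin * 255
  } else {
    gray
  }
  tf <- tryCatch(
    trace_and_fill(edges_src, config$canny_low, config$canny_high,
                   config$blur_radius),
    error = identity
  )
  plausible <- function(m) {
    !inherits(m, "error") && {
      f <- sum(m) / length(m)
      f >= 0.01 && f <= 0.95
    }
  }
  if (plausible(tf)) {
    mask <- tf; fallback <- FALSE; stage <- "contour_fill"
  } else if (plausible(bin)) {
    mask <- bin; fallback <- TRUE; stage <- "threshold"
  } else {
    msg_tf <- if (inherits(tf, "error")) conditionMessage(tf) else "implausible mask area"
    msg_bin <- if (inherits(bin, "error")) conditionMessage(bin) else "implausible mask area"
    pc_stop("pillchroma_segmentation_error",
            "segmentation failed at both stages [contour_fill: %s] [threshold: %s]",
            msg_tf, msg_bin)
  }
  crop <- mask_and_crop(img, mask, config$pad)
  structure(
    c(crop["roi"], list(mask = mask), crop[c("roi_mask", "bbox")],
      list(fallback = fallback, stage = stage)),
    class = "pill_roi"
  )
}

#' @export
print.pill_roi <- function(x, ...) {
  cat(sprintf("<pill_roi> %dx%d crop, mask area %d px, stage %s%s\n",
              nrow(x$roi_mask), ncol(x$roi_mask), sum(x$mask), x$stage,
              if (x$fallback) " (fallback)" else ""))
  invisible(x)
}
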