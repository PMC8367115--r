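# CIE colorimetry: RGB -> XYZ -> L*a*b* and the Euclidean colour difference
# Delta E*ab.  The RGB -> XYZ matrix is the one used by the ImageJ RGB
# analysis workflow this chain mirrors; its white point is taken as the
# image of RGB white under that matrix, so L* spans exactly [0, 100] over
# the RGB cube.  RGB channels are normalised to [0, 1].

rgb_xyz_matrix <- matrix(c(
  0.4303, 0.3416, 0.1784,
  0.2219, 0.7068, 0.0713,
  0.0202, 0.1296, 0.9393
), nrow = 3, byrow = TRUE, dimnames = list(c("x", "y", "z"), c("r", "g", "b")))

as_color_matrix <- function(c3, what) {
  m <- if (is.matrix(c3)) c3 else matrix(c3, ncol = 3, byrow = FALSE)
  if (!is.matrix(m) || ncol(m) != 3 || !is.numeric(m)) {
    pc_stop("pillchroma_domain_error", "%s must be a length-3 vector or an n x 3 matrix", what)
  }
  m
}

#' Convert RGB to CIE XYZ
#'
#' Linear map with the fixed 3x3 matrix (rows 0.4303/0.3416/0.1784,
#' 0.2219/0.7068/0.0713, 0.0202/0.1296/0.9393).  Note this is not the sRGB
#' D65 matrix; it is applied verbatim to linear `[0, 1]` channels.
#'
#' @param rgb length-3 vector or n x 3 matrix with channels in `[0, 1]`.
#' @return Matrix (n x 3) of XYZ coordinates; a single colour comes back as
#'   a named length-3 vector.
#' @export
#' @examples
#' rgb_to_xyz(c(1, 0, 0))  # (0.4303, 0.2219, 0.0202)
rgb_to_xyz <- function(rgb) {
  m <- as_color_matrix(rgb, "rgb")
  if (min(m) < 0 || max(m) > 1) {
    pc_stop("pillchroma_domain_error", "RGB channels must lie in [0, 1]")
  }
  out <- m %*% t(rgb_xyz_matrix)
  colnames(out) <- c("x", "y", "z")
  if (nrow(out) == 1L) out[1, ] else out
}

#' The white-anchored reference white
#'
#' The XYZ image of RGB white (1, 1, 1) under the conversion matrix:
#' (0.9503, 1.0000, 1.0891).  Anchoring the white point here makes
#' L*(white) = 100 and a* = b* = 0 exactly.
#'
#' @return Named length-3 vector `(x, y, z)`.
#' @export
anchored_white <- function() {
  rgb_to_xyz(c(1, 1, 1))
}

#' Standard D65 reference white
#'
#' The CIE D65 2-degree observer white point, offered as an alternative to
#' [anchored_white()].
#'
#' @return Named length-3 vector.
#' @export
d65_white <- function() {
  c(x = 0.95047, y = 1.00000, z = 1.08883)
}

resolve_white <- function(white) {
  if (is.character(white)) {
    switch(match.arg(white, c("anchored", "d65")),
           anchored = anchored_white(), d65 = d65_white())
  } else {
    w <- as.numeric(white)
    if (length(w) != 3 || any(w <= 0)) {
      pc_stop("pillchroma_domain_error", "white point must be three positive numbers")
    }
    setNames(w, c("x", "y", "z"))
  }
}

#' The L*a*b* companding function f(q)
#'
#' Piecewise: `q^(1/3)` above the knee at q = 0.008856 and the linear branch
#' `7.787 q + 16/116` at or below it.  The two branches agree at the knee to
#' within 1e-4.
#'
#' @param q nonnegative numeric vector.
#' @return `f(q)`, same length as `q`.
#' @export
lab_f <- function(q) {
  if (any(q < 0)) {
    pc_stop("pillchroma_domain_error", "lab_f is defined for q >= 0")
  }
  ifelse(q > 0.008856, q^(1 / 3), 7.787 * q + 16 / 116)
}

#' Convert CIE XYZ to L*a*b*
#'
#' `L* = 116 f(Y/Yn) - 16`, `a* = 500 (f(X/Xn) - f(Y/Yn))`,
#' `b* = 200 (f(Y/Yn) - f(Z/Zn))`.
#'
#' @param xyz length-3 vector or n x 3 matrix of XYZ coordinates.
#' @param white reference white: `"anchored"` (default), `"d65"`, or a
#'   length-3 numeric vector.
#' @return `(L, a, b)` vector or n x 3 matrix.
#' @export
#' @examples
#' xyz_to_lab(anchored_white())  # (100, 0, 0)
xyz_to_lab <- function(xyz, white = "anchored") {
  m <- as_color_matrix(xyz, "xyz")
  if (min(m) < 0) {
    pc_stop("pillchroma_domain_error", "XYZ components must be nonnegative")
  }
  w <- resolve_white(white)
  fx <- lab_f(m[, 1] / w[1])
  fy <- lab_f(m[, 2] / w[2])
  fz <- lab_f(m[, 3] / w[3])
  out <- cbind(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
  if (nrow(out) == 1L) out[1, ] else out
}

#' Convert RGB directly to L*a*b*
#'
#' @inheritParams rgb_to_xyz
#' @inheritParams xyz_to_lab
#' @return `(L, a, b)` vector or n x 3 matrix.
#' @export
rgb_to_lab <- function(rgb, white = "anchored") {
  xyz <- rgb_to_xyz(rgb)
  xyz_to_lab(if (is.matrix(xyz)) xyz else matrix(xyz, 1), white = white)
}

#' Euclidean colour difference Delta E*ab
#'
#' `sqrt(dL^2 + da^2 + db^2)` between two L*a*b* colours (or rowwise between
#' two n x 3 matrices).
#'
#' @param p,q length-3 Lab vectors or n x 3 matrices.
#' @return Nonnegative numeric vector of colour differences.
#' @export
#' @examples
#' delta_e(c(50, 10, -10), c(40, -2, 6))  # sqrt(500)
delta_e <- function(p, q) {
  pm <- as_color_matrix(p, "p")
  qm <- as_color_matrix(q, "q")
  stopifnot(nrow(pm) == nrow(qm) || nrow(pm) == 1L || nrow(qm) == 1L)
  if (nrow(pm) == 1L) pm <- pm[rep(1, nrow(qm)), , drop = FALSE]
  if (nrow(qm) == 1L) qm <- qm[rep(1, nrow(pm)), , drop = FALSE]
  sqrt(rowSums((pm - qm)^2))
}

#' Mean ROI colour
#'
#' Arithmetic mean of each channel over the foreground pixels, scaled to
#' `[0, 1]`.
#'
#' @param img H x W x 3 8-bit RGB array.
#' @param mask logical foreground mask of matching dimensions.
#' @return Length-3 RGB vector in `[0, 1]`.
#' @export
roi_mean_color <- function(img, mask) {
  check_rgb_image(img)
  stopifnot(identical(dim(mask), dim(img)[1:2]))
  if (!any(mask)) {
    pc_stop("pillchroma_domain_error", "roi_mean_color: empty mask")
  }
  vapply(1:3, function(ch) mean(img[, , ch][mask]), 0) / 255
}

#' Per-pill, per-condition colour differences against the reference
#'
#' Each pill's reference colour is the mean L*a*b* colour over its
#' reference-condition images.  For every (pill, condition) cell the colour
#' difference of each replicate image against that reference colour is
#' computed and averaged.
#'
#' @param reference data frame of reference-condition measurements with
#'   columns `label`, `L`, `a`, `b` (one row per image).
#' @param conditions data frame of real-world measurements with columns
#'   `label`, `condition`, `L`, `a`, `b`.
#' @return Data frame with one row per (pill, condition): `label`,
#'   `condition`, `delta_e`, `n_images`.
#' @export
condition_delta_e <- function(reference, conditions) {
  need <- c("label", "L", "a", "b")
  stopifnot(all(need %in% names(reference)),
            all(c(need, "condition") %in% names(conditions)))
  missing_ref <- setdiff(unique(conditions$label), unique(reference$label))
  if (length(missing_ref)) {
    pc_stop("pillchroma_pairing_error",
            "no reference images for pill label(s): %s",
            paste(missing_ref, collapse = ", "))
  }
  ref_mean <- aggregate(reference[, c("L", "a", "b")],
                        by = list(label = reference$label), FUN = mean)
  i <- match(conditions$label, ref_mean$label)
  de <- delta_e(as.matrix(conditions[, c("L", "a", "b")]),
                as.matrix(ref_mean[i, c("L", "a", "b")]))
  agg <- aggregate(de, by = list(label = conditions$label,
                                 condition = conditions$condition),
                   FUN = mean)
  n <- aggregate(de, by = list(label = conditions$label,
                               condition = conditions$condition),
                 FUN = length)
  out <- data.frame(label = agg$label, condition = agg$condition,
                    delta_e = agg$x, n_images = n$x,
                    stringsAsFactors = FALSE)
  # radix ordering is locale-independent, keeping outputs byte-reproducible
  out[order(out$label, out$condition, method = "radix"), , drop = FALSE]
}
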