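# Synthetic pill photograph renderer.
#
# Imaging model (per pixel, linear radiance in [0,1] before quantisation):
#   radiance = surface * ev_gain * ae_gain * flash_gain + flash_highlight + noise
# then clipped to [0,1] and quantised to 8 bits.
#   - ev_gain = 2^EV (photographic stops),
#   - ae_gain emulates smartphone average metering: a black background makes
#     the camera brighten the scene (1 + ae_coef), a white one darken it
#     (1 - ae_coef),
#   - flash adds a global gain plus a localised specular highlight on the
#     pill,
#   - sensor noise is iid Gaussian per pixel and channel.
# The reference condition is captured in a calibrated photo box with manual
# lighting: no auto-exposure, no flash, EV 0, so it renders the surface
# colour identically (up to noise and quantisation).

#' Rendering parameters
#'
#' Collects the tunable parameters of the synthetic imaging model with their
#' defaults.
#'
#' @param noise_sigma sensor-noise standard deviation in 8-bit counts
#'   (default 2).
#' @param flash_gain global multiplicative gain applied when the flash fires
#'   (default 1.2).
#' @param flash_highlight peak amplitude of the specular highlight, as a
#'   fraction of full scale (default 0.25).
#' @param ae_coef auto-exposure coupling: scene gain is `1 + ae_coef` on a
#'   black background and `1 - ae_coef` on a white one (default 0.45).
#' @param area_fraction length-2 range of the canvas area fraction the pill
#'   occupies (default 0.25--0.45).
#' @param background_black,background_white background reflectance levels on
#'   the [0,1] scale (defaults 0.02 and 0.97).
#' @param imprint_depth multiplicative darkening of imprint pixels relative
#'   to the surface colour (default 0.65).
#' @return A named list of class `render_params`.
#' @export
render_params <- function(noise_sigma = 2, flash_gain = 1.2,
                          flash_highlight = 0.25, ae_coef = 0.45,
                          area_fraction = c(0.25, 0.45),
                          background_black = 0.02, background_white = 0.97,
                          imprint_depth = 0.65) {
  stopifnot(noise_sigma >= 0, length(area_fraction) == 2,
            all(area_fraction > 0), all(area_fraction < 1))
  structure(list(
    noise_sigma = noise_sigma, flash_gain = flash_gain,
    flash_highlight = flash_highlight, ae_coef = ae_coef,
    area_fraction = area_fraction, background_black = background_black,
    background_white = background_white, imprint_depth = imprint_depth
  ), class = "render_params")
}

# Binary mask of a pill shape on an H x W grid.  `area` is the target pixel
# area; `angle` rotates elongated/polygonal shapes.
shape_mask <- function(shape, H, W, cy, cx, area, angle = 0) {
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # rotate coordinates into the shape frame
  u <- cos(angle) * xx + sin(angle) * yy
  v <- -sin(angle) * xx + cos(angle) * yy
  regular_polygon <- function(n) {
    R <- sqrt(2 * area / (n * sin(2 * pi / n)))
    th <- atan2(v, u)
    r <- sqrt(u^2 + v^2)
    sector <- (th %% (2 * pi / n)) - pi / n
    r <= R * cos(pi / n) / cos(sector)
  }
  stadium <- function(aspect) {
    b <- sqrt(area / (4 * (aspect - 1) + pi))
    a <- aspect * b
    du <- pmax(abs(u) - (a - b), 0)
    sqrt(du^2 + v^2) <= b
  }
  switch(shape,
    round = {
      r <- sqrt(area / pi)
      u^2 + v^2 <= r^2
    },
    oval = {
      k <- 1.6
      a <- sqrt(area * k / pi)
      b <- sqrt(area / (pi * k))
      (u / a)^2 + (v / b)^2 <= 1
    },
    oblong = stadium(2.2),
    capsule = stadium(2.8),
    triangle = regular_polygon(3L),
    pentagon = regular_polygon(5L),
    diamond = {
      k <- 1.4
      a <- sqrt(area * k / 2)
      b <- sqrt(area / (2 * k))
      abs(u) / a + abs(v) / b <= 1
    },
    pc_stop("pillchroma_domain_error", "unknown shape '%s'", shape)
  )
}

# Imprint glyph: an embossed annulus plus a central bar, darkened by
# `depth`.  Returns a logical matrix of glyph pixels (subset of the mask).
imprint_glyph <- function(mask, cy, cx, r_eff) {
  H <- nrow(mask); W <- ncol(mask)
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  r <- sqrt(yy^2 + xx^2)
  ring <- abs(r - 0.45 * r_eff) <= pmax(0.06 * r_eff, 1)
  bar <- abs(yy) <= pmax(0.05 * r_eff, 1) & abs(xx) <= 0.22 * r_eff
  (ring | bar) & mask
}

as_condition_row <- function(condition) {
  if (is.character(condition)) return(find_condition(condition))
  stopifnot(is.data.frame(condition), nrow(condition) == 1)
  condition
}

as_pill_row <- function(pill) {
  stopifnot(is.data.frame(pill), nrow(pill) == 1)
  pill
}

#' Render one synthetic pill photograph
#'
#' Draws the pill's shape at a seeded random size, position and orientation,
#' applies the imaging model for the requested condition (exposure gain
#' `2^EV`, auto-exposure coupling to the background, optional flash gain and
#' specular highlight, Gaussian sensor noise) and quantises to 8 bits.  The
#' reference condition bypasses auto-exposure and flash, so with zero noise
#' the mean pill colour reproduces the true surface colour to within
#' quantisation.
#'
#' @param pill one row of a [pill_catalog()].
#' @param condition a condition name (see [all_conditions()]) or a one-row
#'   condition data frame.
#' @param canvas canvas side in pixels (square canvas; must be at least 64).
#' @param seed integer seed; identical inputs give bit-identical images.
#' @param params a [render_params()] list.
#' @return A list of class `pill_render` with elements `image` (H x W x 3
#'   8-bit array), `mask` (logical ground-truth mask), `truth_rgb` (mean
#'   surface colour over the mask, 8-bit scale), `label`, `condition`,
#'   `seed`.
#' @export
#' @examples
#' cat19 <- pill_catalog(seed = 1)
#' rec <- render_pill(cat19[1, ], "REF", canvas = 96, seed = 7)
#' range(rec$image)
render_pill <- function(pill, condition, canvas = 96, seed = 1,
                        params = render_params()) {
  pill <- as_pill_row(pill)
  cond <- as_condition_row(condition)
  if (length(canvas) == 1) canvas <- c(canvas, canvas)
  H <- canvas[1]; W <- canvas[2]
  if (H < 64 || W < 64) {
    pc_stop("pillchroma_sizing_error",
            "canvas %dx%d is too small to hold a pill at the minimum area fraction (need >= 64x64)",
            H, W)
  }
  with_seed(seed, {
    frac <- runif(1, params$area_fraction[1], params$area_fraction[2])
    area <- frac * H * W
    cy <- H / 2 + runif(1, -0.05, 0.05) * H
    cx <- W / 2 + runif(1, -0.05, 0.05) * W
    angle <- runif(1, 0, pi)
    mask <- shape_mask(pill$shape, H, W, cy, cx, area, angle)
    r_eff <- sqrt(sum(mask) / pi)

    # surface colour map (8-bit scale), imprint embossed as a darker glyph
    base <- c(pill$r, pill$g, pill$b)
    surface <- array(rep(base, each = H * W), c(H, W, 3))
    if (isTRUE(pill$has_imprint)) {
      glyph <- imprint_glyph(mask, cy, cx, r_eff)
      for (ch in 1:3) {
        pl <- surface[, , ch]
        pl[glyph] <- pl[glyph] * params$imprint_depth
        surface[, , ch] <- pl
      }
    }
    truth_rgb <- vapply(1:3, function(ch) mean(surface[, , ch][mask]), 0)

    bg_val <- if (cond$background == "black") params$background_black else params$background_white
    scene <- surface / 255
    for (ch in 1:3) {
      pl <- scene[, , ch]
      pl[!mask] <- bg_val
      scene[, , ch] <- pl
    }

    if (!cond$is_reference) {
      gain <- 2^cond$ev *
        (1 + params$ae_coef * if (cond$background == "black") 1 else -1)
      if (cond$flash == "on") gain <- gain * params$flash_gain
      scene <- scene * gain
      if (cond$flash == "on" && params$flash_highlight > 0) {
        hy <- cy - 0.3 * r_eff
        hx <- cx - 0.3 * r_eff
        yy <- matrix(seq_len(H), H, W) - hy
        xx <- matrix(seq_len(W), H, W, byrow = TRUE) - hx
        blob <- params$flash_highlight * exp(-(yy^2 + xx^2) / (2 * (0.5 * r_eff)^2))
        blob[!mask] <- 0  # specular highlight lives on the glossy pill surface
        scene <- scene + array(rep(blob, 3), c(H, W, 3))
      }
    }

    if (params$noise_sigma > 0) {
      scene <- scene + array(rnorm(H * W * 3, 0, params$noise_sigma / 255), c(H, W, 3))
    }
    img <- round(255 * clip01(scene))
    structure(list(
      image = img, mask = mask, truth_rgb = truth_rgb,
      label = pill$label, condition = cond$name, seed = seed
    ), class = "pill_render")
  })
}

#' @export
print.pill_render <- function(x, ...) {
  cat(sprintf("<pill_render> pill %d, condition %s, %dx%d, seed %d\n",
              x$label, x$condition, nrow(x$mask), ncol(x$mask), x$seed))
  cat(sprintf("  truth RGB (%.1f, %.1f, %.1f); mask area %d px\n",
              x$truth_rgb[1], x$truth_rgb[2], x$truth_rgb[3], sum(x$mask)))
  invisible(x)
}

#' Generate a labelled pill-image dataset on disk
#'
#' Renders `n_per_cell` images for every (pill, condition) cell, writes them
#' as 8-bit PNG files with ground-truth mask PNGs alongside, and writes a
#' `manifest.csv` (columns `path,label,condition,seed`) plus a `truth.csv`
#' with mask paths and true surface colours.
#'
#' @param dir output directory (created if needed).
#' @param catalog a [pill_catalog()].
#' @param conditions condition data frame; defaults to [all_conditions()]
#'   (the 12-condition grid plus the reference set).
#' @param n_per_cell replicates per (pill, condition) cell.
#' @param seed master seed; per-image seeds are drawn from it and recorded
#'   in the manifest.
#' @param canvas canvas side in pixels.
#' @param params a [render_params()] list.
#' @return Invisibly, a list with `manifest`, `truth` (data frames) and
#'   `dir`.
#' @export
generate_pill_dataset <- function(dir, catalog = pill_catalog(),
                                  conditions = all_conditions(),
                                  n_per_cell = 1, seed = 1, canvas = 96,
                                  params = render_params()) {
  if (n_per_cell < 1) {
    pc_stop("pillchroma_domain_error", "n_per_cell must be >= 1")
  }
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    pc_stop("pillchroma_io_error", "cannot create output directory '%s'", dir)
  }
  dir.create(file.path(dir, "images"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)

  n_img <- nrow(catalog) * nrow(conditions) * n_per_cell
  img_seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_img))

  rows <- vector("list", n_img)
  truths <- vector("list", n_img)
  i <- 0L
  for (p in seq_len(nrow(catalog))) {
    for (cc in seq_len(nrow(conditions))) {
      for (rep_i in seq_len(n_per_cell)) {
        i <- i + 1L
        rec <- render_pill(catalog[p, ], conditions[cc, ], canvas = canvas,
                           seed = img_seeds[i], params = params)
        stem <- sprintf("pill%02d_%s_rep%d", rec$label, rec$condition, rep_i)
        img_path <- file.path("images", paste0(stem, ".png"))
        mask_path <- file.path("masks", paste0(stem, "_mask.png"))
        png::writePNG(rec$image / 255, file.path(dir, img_path))
        png::writePNG(rec$mask * 1, file.path(dir, mask_path))
        rows[[i]] <- data.frame(
          path = img_path, label = rec$label, condition = rec$condition,
          seed = rec$seed, stringsAsFactors = FALSE
        )
        truths[[i]] <- data.frame(
          path = img_path, mask_path = mask_path,
          truth_r = rec$truth_rgb[1], truth_g = rec$truth_rgb[2],
          truth_b = rec$truth_rgb[3],
          is_reference = conditions$is_reference[cc],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  manifest <- do.call(rbind, rows)
  truth <- do.call(rbind, truths)
  write.csv(manifest, file.path(dir, "manifest.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(truth, file.path(dir, "truth.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, truth = truth, dir = dir))
}

#' Read a dataset image back as an 8-bit RGB array
#'
#' @param path path to a PNG written by [generate_pill_dataset()].
#' @return H x W x 3 array of integers in `[0, 255]`.
#' @export
read_pill_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3))
  round(a[, , 1:3, drop = FALSE] * 255)
}

read_pill_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a > 0.5
}
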