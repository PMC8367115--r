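# The 19-pill reference catalog.  Shape, colour-category and dosage-form
# marginals follow the study's reference set: colours pink 1 / blue 5 /
# white 5 / yellow 4 / green 1 / yellow-green 2 / orange 1; dosage forms
# film-coated 10 / sugar-coated 2 / uncoated 6 / hard capsule 1; shape counts
# 6, 3, 4, 1, 2, 2, 1 mapped onto the seven named shapes below.

pill_shapes <- c("round", "oval", "oblong", "capsule", "triangle", "pentagon", "diamond")
pill_color_categories <- c("pink", "blue", "white", "yellow", "green", "yellow-green", "orange")
pill_dosage_forms <- c("film-coated", "sugar-coated", "uncoated", "hard-capsule")

# Per-category RGB gamuts (8-bit) from which base colours are drawn.  Each row
# gives lo/hi per channel; the dominant channel is enforced by construction.
color_gamuts <- list(
  "pink"         = rbind(r = c(220, 250), g = c(140, 180), b = c(160, 200)),
  "blue"         = rbind(r = c(40, 110),  g = c(80, 160),  b = c(180, 245)),
  "white"        = rbind(r = c(215, 245), g = c(215, 245), b = c(215, 245)),
  "yellow"       = rbind(r = c(210, 250), g = c(185, 230), b = c(40, 110)),
  "green"        = rbind(r = c(60, 120),  g = c(160, 220), b = c(60, 120)),
  "yellow-green" = rbind(r = c(150, 190), g = c(200, 240), b = c(60, 110)),
  "orange"       = rbind(r = c(230, 255), g = c(130, 170), b = c(30, 70))
)

# Fixed label -> attribute assignment.  The single capsule-shaped pill is the
# single hard capsule; everything else is a tablet.
catalog_colors <- c("pink", rep("blue", 5), rep("white", 5), rep("yellow", 4),
                    "green", rep("yellow-green", 2), "orange")
catalog_shapes <- c("round", "round", "oval", "oblong", "triangle", "round",
                    "oval", "oblong", "pentagon", "round", "round", "oval",
                    "oblong", "diamond", "triangle", "round", "oblong",
                    "pentagon", "capsule")
catalog_forms <- c(rep("film-coated", 10), rep("sugar-coated", 2),
                   rep("uncoated", 6), "hard-capsule")

draw_base_rgb <- function(category) {
  gam <- color_gamuts[[category]]
  v <- round(runif(3, gam[, 1], gam[, 2]))
  if (category == "white") {
    # white pills are near-neutral: small chromatic jitter around one level
    base <- round(runif(1, gam[1, 1], gam[1, 2]))
    v <- pmin(255, pmax(0, base + round(runif(3, -6, 6))))
  }
  as.integer(v)
}

#' Build the 19-pill catalog
#'
#' Generates the reference set of 19 pill classes with the study's shape,
#' colour-category and dosage-form distribution.  Base surface colours are
#' drawn within per-category gamuts (e.g. blue pills have a dominant blue
#' channel) and are pairwise distinct; the draw is deterministic given
#' `seed`.
#'
#' @param seed integer seed controlling the colour draw.
#' @param imprint_fraction fraction of pills carrying an embossed imprint
#'   glyph (default 0.5).
#' @return A data frame with 19 rows and columns `label`, `shape`,
#'   `color_category`, `dosage_form`, `r`, `g`, `b` (8-bit base colour) and
#'   `has_imprint`.
#' @export
#' @examples
#' cat19 <- pill_catalog(seed = 1)
#' table(cat19$color_category)
pill_catalog <- function(seed = 1, imprint_fraction = 0.5) {
  with_seed(seed, {
    rgb <- matrix(NA_integer_, 19, 3, dimnames = list(NULL, c("r", "g", "b")))
    for (i in seq_len(19)) {
      repeat {
        v <- draw_base_rgb(catalog_colors[i])
        if (i == 1L || !any(colSums(t(rgb[seq_len(i - 1), , drop = FALSE]) == v) == 3L)) {
          rgb[i, ] <- v
          break
        }
      }
    }
    out <- data.frame(
      label = seq_len(19),
      shape = catalog_shapes,
      color_category = catalog_colors,
      dosage_form = catalog_forms,
      rgb,
      has_imprint = runif(19) < imprint_fraction,
      stringsAsFactors = FALSE
    )
    class(out) <- c("pill_catalog", "data.frame")
    out
  })
}

#' @export
print.pill_catalog <- function(x, ...) {
  cat("Pill catalog:", nrow(x), "classes\n")
  cat("  colours:     ", paste(names(table(x$color_category)),
                               table(x$color_category), collapse = ", "), "\n")
  cat("  dosage forms:", paste(names(table(x$dosage_form)),
                               table(x$dosage_form), collapse = ", "), "\n")
  print.data.frame(x, ...)
  invisible(x)
}
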