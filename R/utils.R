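# Internal helpers shared across modules.

# Classed errors so callers can distinguish failure modes programmatically.
pc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pillchroma_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Validate an 8-bit RGB array (H x W x 3, values in [0, 255]).
check_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    pc_stop("pillchroma_dimension_error", "expected an H x W x 3 RGB array")
  }
  if (dim(img)[1] < 1L || dim(img)[2] < 1L) {
    pc_stop("pillchroma_dimension_error", "image has zero extent")
  }
  if (min(img) < 0 || max(img) > 255) {
    pc_stop("pillchroma_domain_error", "RGB channel values must lie in [0, 255]")
  }
  invisible(img)
}

#' Intersection over union of two binary masks
#'
#' Segmentation quality score between a predicted mask and a ground-truth
#' mask of the same dimensions.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return A number in `[0, 1]`; `NaN` when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(NaN)
  inter / uni
}
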