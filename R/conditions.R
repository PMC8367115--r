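# The study's imaging-condition grid: 2 backgrounds x 2 flash states x 3
# exposure values, plus the controlled reference condition (black background,
# flash off) under which training/reference images are captured.

ev_levels <- c(-2, 0, 2)

format_ev <- function(ev) {
  ifelse(ev == 0, "0", sprintf("%+.1f", ev))
}

#' Name an imaging condition
#'
#' Builds the condition-set name used throughout the package:
#' `{B|W}_{O|X}_EV{-2.0|0|+2.0}` for background black/white, flash on/off and
#' the exposure value.
#'
#' @param background `"black"` or `"white"`.
#' @param flash `"on"` or `"off"`.
#' @param ev exposure value, one of -2, 0, +2.
#' @return Character vector of condition names.
#' @export
#' @examples
#' condition_name("black", "on", -2)  # "B_O_EV-2.0"
condition_name <- function(background, flash, ev) {
  b <- c(black = "B", white = "W")[match.arg(background, c("black", "white"), several.ok = TRUE)]
  f <- c(on = "O", off = "X")[match.arg(flash, c("on", "off"), several.ok = TRUE)]
  paste0(b, "_", f, "_EV", format_ev(ev))
}

#' The 12 real-world imaging conditions
#'
#' Full factorial of background colour (black, white), flash (on, off) and
#' exposure value (-2.0, 0, +2.0).
#'
#' @return A data frame with 12 rows and columns `name`, `background`,
#'   `flash`, `ev`, `is_reference` (all `FALSE`).
#' @seealso [reference_condition()]
#' @export
condition_grid <- function() {
  g <- expand.grid(
    ev = ev_levels,
    flash = c("on", "off"),
    background = c("black", "white"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- g[, c("background", "flash", "ev")]
  data.frame(
    name = condition_name(g$background, g$flash, g$ev),
    g,
    is_reference = FALSE,
    stringsAsFactors = FALSE
  )
}

#' The reference imaging condition
#'
#' The controlled capture setup: black background, flash off, neutral
#' exposure, fixed studio lighting.  Reference images anchor both the colour
#' differences and the classifier's training set.
#'
#' @return A one-row data frame in the same layout as [condition_grid()].
#' @export
reference_condition <- function() {
  data.frame(
    name = "REF", background = "black", flash = "off", ev = 0,
    is_reference = TRUE, stringsAsFactors = FALSE
  )
}

#' All capture conditions
#'
#' @return The reference condition row-bound to the 12-condition grid
#'   (13 rows).
#' @export
all_conditions <- function() {
  rbind(reference_condition(), condition_grid())
}

find_condition <- function(name) {
  conds <- all_conditions()
  i <- match(name, conds$name)
  if (is.na(i)) {
    pc_stop("pillchroma_domain_error", "unknown condition name '%s'", name)
  }
  conds[i, , drop = FALSE]
}
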