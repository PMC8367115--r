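# Geometric fixtures built in code: masks with known analytic areas and the
# flat-colour images that carry them.

disk_mask <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  yy <- matrix(seq_len(n), n, n) - cy
  xx <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
  yy^2 + xx^2 <= r^2
}

ellipse_mask <- function(n, a, b) {
  yy <- matrix(seq_len(n), n, n) - (n + 1) / 2
  xx <- matrix(seq_len(n), n, n, byrow = TRUE) - (n + 1) / 2
  (xx / a)^2 + (yy / b)^2 <= 1
}

capsule_mask <- function(n, half_len, r) {
  yy <- matrix(seq_len(n), n, n) - (n + 1) / 2
  xx <- matrix(seq_len(n), n, n, byrow = TRUE) - (n + 1) / 2
  du <- pmax(abs(xx) - half_len, 0)
  sqrt(du^2 + yy^2) <= r
}

# Flat-colour RGB image from a mask: foreground fg, background bg (scalars
# or length-3).
flat_image <- function(mask, fg = 200, bg = 10) {
  fg <- rep(fg, length.out = 3)
  bg <- rep(bg, length.out = 3)
  a <- array(0, c(nrow(mask), ncol(mask), 3))
  for (ch in 1:3) {
    pl <- matrix(bg[ch], nrow(mask), ncol(mask))
    pl[mask] <- fg[ch]
    a[, , ch] <- pl
  }
  a
}

# Small experiment configuration used by end-to-end tests.
small_config <- function(seed, out_dir = NULL, n_per_cell = 1) {
  experiment_config(seed = seed, n_per_cell = n_per_cell, canvas = 64,
                    out_dir = out_dir)
}
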