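test_that("grayscale conversion uses the documented luma weights", {
  u <- array(137, c(8, 8, 3))
  expect_true(all(to_grayscale(u) == 137))
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 255
  expect_equal(round(to_grayscale(red)[1, 1]), 76)
  rnd <- array(sample(0:255, 48, replace = TRUE), c(4, 4, 3))
  g <- to_grayscale(rnd)
  expect_true(all(g >= min(rnd) - 1e-9 & g <= max(rnd) + 1e-9))
})

test_that("blur/threshold segmentation recovers the disk under either polarity", {
  m <- disk_mask(128, 30)
  bright <- binarize_mask(to_grayscale(flat_image(m, 200, 10)))
  expect_lt(mean(bright != m), 0.02)
  dark <- binarize_mask(to_grayscale(flat_image(m, 10, 200)))
  expect_lt(mean(dark != m), 0.02)
  expect_lt(mean(bright != dark), 0.005)
  expect_error(binarize_mask(matrix(80, 64, 64)),
               class = "pillchroma_threshold_error")
})

test_that("contour tracing fills geometric outlines to their analytic areas", {
  shapes <- list(
    disk = list(mask = disk_mask(128, 30), area = pi * 30^2),
    ellipse = list(mask = ellipse_mask(128, 40, 22), area = pi * 40 * 22),
    capsule = list(mask = capsule_mask(128, 20, 14),
                   area = 4 * 14 * 20 + pi * 14^2)
  )
  for (nm in names(shapes)) {
    filled <- trace_and_fill(to_grayscale(flat_image(shapes[[nm]]$mask)))
    expect_lt(abs(sum(filled) - shapes[[nm]]$area) / shapes[[nm]]$area, 0.05,
              label = sprintf("%s area within 5%% of analytic", nm))
  }
  expect_error(trace_and_fill(matrix(0, 64, 64)),
               class = "pillchroma_segmentation_error")
})

test_that("nested contours fill only the outer outline", {
  outer <- disk_mask(128, 30)
  ring <- disk_mask(128, 14) & !disk_mask(128, 10)
  img <- flat_image(outer, 200, 10)
  for (ch in 1:3) { pl <- img[, , ch]; pl[ring] <- 90; img[, , ch] <- pl }
  filled <- trace_and_fill(to_grayscale(img))
  expect_lt(abs(sum(filled) - pi * 900) / (pi * 900), 0.05)
  expect_true(all(filled[disk_mask(128, 12) & !disk_mask(128, 11)]))
})

test_that("mask_and_crop squares the window and zeroes the outside", {
  r <- 20; pad <- 2
  m <- disk_mask(96, r)
  img <- flat_image(m, c(200, 150, 90), 10)
  out <- mask_and_crop(img, m, pad = pad)
  side <- 2 * r + 2 * pad  # disk centred between pixels: extent 2r
  expect_equal(dim(out$roi)[1:2], c(side, side))
  expect_equal(dim(out$roi)[1], dim(out$roi)[2])
  expect_true(all(out$roi[!array(out$roi_mask, dim(out$roi))] == 0))
  expect_equal(unname(out$bbox["row_max"] - out$bbox["row_min"]), side)

  # full-image mask: crop equals the (squared) original
  full <- matrix(TRUE, 64, 96)
  img2 <- flat_image(full, c(10, 20, 30))
  out2 <- mask_and_crop(img2, full, pad = 0)
  expect_equal(dim(out2$roi)[1:2], c(64, 64))

  # object near the corner: window shifts inward, side preserved
  m3 <- disk_mask(96, 15, cy = 18, cx = 18)
  out3 <- mask_and_crop(flat_image(m3), m3, pad = 6)
  expect_equal(dim(out3$roi)[1], dim(out3$roi)[2])
  expect_gte(out3$bbox["row_min"], 1)
  expect_lte(out3$bbox["row_max"], 97)
  expect_equal(unname(out3$bbox["row_max"] - out3$bbox["row_min"]),
               2 * 15 + 1 + 12)  # integer centre: extent 2r+1
  expect_error(mask_and_crop(img, matrix(FALSE, 96, 96)),
               class = "pillchroma_segmentation_error")
})

test_that("extract_roi recovers synthetic pills against the ground truth", {
  cat19 <- pill_catalog(seed = 1)
  for (i in c(1, 7, 19)) {
    rec <- render_pill(cat19[i, ], "REF", canvas = 96, seed = 30 + i)
    res <- extract_roi(rec$image)
    expect_gte(mask_iou(res$mask, rec$mask), 0.8)
    expect_equal(dim(res$roi)[1], dim(res$roi)[2])
    outside <- !array(res$roi_mask, dim(res$roi))
    expect_true(all(res$roi[outside] == 0))
  }
})

test_that("extract_roi is nearly idempotent on its own output", {
  cat19 <- pill_catalog(seed = 1)
  rec <- render_pill(cat19[2, ], "REF", canvas = 96, seed = 4)
  first <- extract_roi(rec$image)
  second <- extract_roi(first$roi)
  expect_gte(mask_iou(second$mask, first$roi_mask), 0.95)
})

test_that("hopeless images fail with a segmentation error, not silent output", {
  blank <- array(255, c(96, 96, 3))
  expect_error(extract_roi(blank), class = "pillchroma_segmentation_error")
  err <- tryCatch(extract_roi(blank), error = identity)
  expect_match(conditionMessage(err), "contour_fill")
  expect_match(conditionMessage(err), "threshold")
})

test_that("both Canny wirings are available", {
  cat19 <- pill_catalog(seed = 1)
  rec <- render_pill(cat19[5, ], "REF", canvas = 96, seed = 8)
  for (wiring in c("blur", "threshold")) {
    res <- extract_roi(rec$image, roi_params(edges_from = wiring))
    expect_gte(mask_iou(res$mask, rec$mask), 0.8)
  }
})
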