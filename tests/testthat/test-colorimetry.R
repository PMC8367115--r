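test_that("the RGB to XYZ map matches the printed matrix", {
  expect_equal(unname(rgb_to_xyz(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(rgb_to_xyz(c(1, 0, 0))), c(0.4303, 0.2219, 0.0202),
               tolerance = 1e-12)
  expect_equal(unname(rgb_to_xyz(c(0, 1, 0))), c(0.3416, 0.7068, 0.1296),
               tolerance = 1e-12)
  expect_equal(unname(rgb_to_xyz(c(1, 1, 1))), c(0.9503, 1.0000, 1.0891),
               tolerance = 1e-12)
  expect_equal(unname(anchored_white()), c(0.9503, 1.0000, 1.0891),
               tolerance = 1e-12)
  expect_error(rgb_to_xyz(c(1.2, 0, 0)), class = "pillchroma_domain_error")
})

test_that("the companding function has the printed linear branch and a continuous knee", {
  expect_equal(lab_f(0), 16 / 116)
  expect_equal(lab_f(1), 1)
  knee <- 0.008856
  expect_lte(abs((7.787 * knee + 16 / 116) - knee^(1 / 3)), 1e-4)
  expect_lte(abs(lab_f(knee - 1e-12) - lab_f(knee + 1e-12)), 1e-4)
  expect_error(lab_f(-0.1), class = "pillchroma_domain_error")
})

test_that("Lab conversion is white-anchored and neutral on grays", {
  expect_equal(unname(xyz_to_lab(anchored_white())), c(100, 0, 0),
               tolerance = 1e-9)
  expect_equal(unname(xyz_to_lab(c(0, 0, 0))), c(0, 0, 0), tolerance = 1e-9)
  lab_gray <- rgb_to_lab(c(0.5, 0.5, 0.5))
  expect_equal(unname(lab_gray[1]), 76.0693, tolerance = 1e-3)
  expect_equal(unname(lab_gray[2]), 0, tolerance = 1e-9)
  expect_equal(unname(lab_gray[3]), 0, tolerance = 1e-9)
  # any (v, v, v) is exactly neutral
  vs <- seq(0, 1, length.out = 21)
  labs <- rgb_to_lab(cbind(vs, vs, vs))
  expect_true(all(abs(labs[, c("a", "b")]) < 1e-9))
  # L* strictly increasing in Y
  expect_true(all(diff(labs[, "L"]) > 0))
  expect_error(xyz_to_lab(c(0.5, 0.5, 0.5), white = c(-1, 1, 1)),
               class = "pillchroma_domain_error")
})

test_that("delta E is the Euclidean Lab distance", {
  expect_equal(delta_e(c(30, 5, -4), c(30, 5, -4)), 0)
  expect_equal(delta_e(c(0, 0, 0), c(100, 0, 0)), 100)
  expect_equal(delta_e(c(50, 10, -10), c(40, -2, 6)), sqrt(500),
               tolerance = 1e-12)
})

test_that("delta E satisfies the metric axioms on random Lab triples", {
  set.seed(99)
  n <- 2000
  rand_lab <- function() cbind(runif(n, 0, 100), runif(n, -120, 120),
                               runif(n, -120, 120))
  p <- rand_lab(); q <- rand_lab(); r <- rand_lab()
  expect_true(all(delta_e(p, p) == 0))
  expect_true(all(delta_e(p, q) >= 0))
  expect_equal(delta_e(p, q), delta_e(q, p))
  expect_true(all(delta_e(p, r) <= delta_e(p, q) + delta_e(q, r) + 1e-9))
})

test_that("ROI mean colour averages only foreground pixels", {
  m <- matrix(FALSE, 10, 10); m[3:8, 3:8] <- TRUE
  img <- flat_image(m, c(100, 150, 200), 255)
  expect_equal(unname(roi_mean_color(img, m)), c(100, 150, 200) / 255)
  # poisoned background must not leak in
  img2 <- flat_image(m, c(100, 150, 200), 0)
  expect_equal(roi_mean_color(img, m), roi_mean_color(img2, m))
  # half black / half white
  m3 <- matrix(TRUE, 10, 10)
  img3 <- flat_image(m3, 0)
  img3[, 6:10, ] <- 255
  expect_equal(unname(roi_mean_color(img3, m3)), c(0.5, 0.5, 0.5))
  expect_error(roi_mean_color(img, matrix(FALSE, 10, 10)),
               class = "pillchroma_domain_error")
})

test_that("condition-level colour differences pair pills against their reference", {
  labels <- rep(1:19, times = 12)
  conds <- rep(condition_grid()$name, each = 19)
  ref <- data.frame(label = 1:19, L = 50 + 1:19, a = 1:19 / 2, b = -(1:19) / 3)
  same <- data.frame(label = labels, condition = conds,
                     L = (50 + 1:19)[labels], a = (1:19 / 2)[labels],
                     b = (-(1:19) / 3)[labels])
  de <- condition_delta_e(ref, same)
  expect_equal(nrow(de), 228)
  expect_true(all(de$delta_e == 0))
  expect_true(all(de$n_images == 1))

  shifted <- same
  shifted$L <- shifted$L + 7  # pure luminance shift on neutral colours
  de2 <- condition_delta_e(ref, shifted)
  expect_equal(de2$delta_e, rep(7, 228))

  expect_error(condition_delta_e(ref[1:5, ], same),
               class = "pillchroma_pairing_error")
})

test_that("replicates average within a cell", {
  ref <- data.frame(label = 1, L = 50, a = 0, b = 0)
  reps <- data.frame(label = 1, condition = "B_O_EV0",
                     L = c(53, 57), a = 0, b = 0)
  de <- condition_delta_e(ref, reps)
  expect_equal(de$delta_e, 5)
  expect_equal(de$n_images, 2)
})
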