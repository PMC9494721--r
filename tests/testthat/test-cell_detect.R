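# Segmentation chain: blur, thresholds, morphology, contours, sites.

test_that("gaussian_blur is an identity for sigma 0 and preserves constants", {
  img <- random_gray(c(40, 40), 1)
  expect_identical(gaussian_blur(img, 0), img)
  const <- matrix(77, 30, 30)
  expect_identical(gaussian_blur(const, 3), const)
  # impulse response reproduces the kernel within rounding
  imp <- matrix(0, 21, 21); imp[11, 11] <- 255
  out <- gaussian_blur(imp, 1.5)
  k <- nanosense:::gaussian_kernel1d(1.5)
  r <- (length(k) - 1) / 2
  expected <- 255 * outer(k, k)
  got <- out[(11 - r):(11 + r), (11 - r):(11 + r)]
  expect_true(max(abs(got - expected)) <= 0.5 + 1e-9)
})

test_that("otsu_threshold matches the exhaustive oracle", {
  # spec two-level case and assorted random images
  two <- image_from_histogram(c(10, 200), c(50, 50))
  expect_equal(otsu_threshold(two), oracle_otsu(two))
  for (seed in 1:5) {
    img <- random_gray(c(25, 25), seed)
    expect_equal(otsu_threshold(img), oracle_otsu(img))
  }
  # complement symmetry: thresholds mirror within 1 level
  img <- random_gray(c(30, 30), 42, lo = 20, hi = 230)
  t1 <- otsu_threshold(img)
  t2 <- otsu_threshold(255 - img)
  expect_lte(abs(t2 - (255 - t1)), 1)
  expect_error(otsu_threshold(matrix(7, 5, 5)), "degenerate")
})

test_that("histogram_peak returns the smallest-level mode", {
  expect_equal(histogram_peak(matrix(77, 4, 4)), 77)
  expect_equal(histogram_peak(image_from_histogram(c(10, 200), c(30, 70))), 200)
  tie <- image_from_histogram(c(10, 200), c(50, 50))
  expect_equal(histogram_peak(tie), 10)
  expect_equal(histogram_peak(tie), oracle_mode(tie))
})

test_that("triangle_threshold maximizes the point-line distance", {
  # spike at 200 plus a linear ramp from 50 to 199
  lv <- 50:200
  ct <- c(seq_len(150), 400)
  img <- image_from_histogram(lv, ct)
  expect_equal(triangle_threshold(img, "darker_end"),
               oracle_triangle(img, "darker_end"))
  for (seed in 1:5) {
    set.seed(seed)
    lv <- sort(sample(0:255, 30))
    ct <- sample(1:50, 30, replace = TRUE)
    img <- image_from_histogram(lv, ct)
    for (side in c("brighter_end", "darker_end")) {
      peak <- histogram_peak(img)
      endb <- if (side == "brighter_end") max(lv) else min(lv)
      if (abs(endb - peak) < 2) next   # degenerate by construction
      got <- triangle_threshold(img, side)
      expect_equal(got, oracle_triangle(img, side))
      # result strictly between peak and end
      expect_true(got > min(peak, endb) && got < max(peak, endb))
    }
  }
  # peak at the requested end is degenerate
  ramp <- image_from_histogram(100:110, c(50, rep(1, 10)))
  expect_error(triangle_threshold(ramp, "darker_end"), "degenerate")
})

test_that("hybrid_binarize branches purely on T_otsu vs T_peak", {
  sc <- std_scene()
  neg <- render_cell_image(sc, -40)
  pos <- render_cell_image(sc, 40)
  bn <- hybrid_binarize(gaussian_blur(neg, 2))
  bp <- hybrid_binarize(gaussian_blur(pos, 2))
  expect_equal(bn$branch, "triangle")
  expect_true(bn$t_otsu >= bn$t_peak)
  expect_equal(bp$branch, "otsu")
  expect_true(bp$t_otsu < bp$t_peak)
  expect_equal(bp$threshold, bp$t_otsu)
})

test_that("morph_close merges small gaps and is idempotent away from borders", {
  m <- matrix(FALSE, 40, 40)
  m[10:20, 10:14] <- TRUE
  m[10:20, 16:20] <- TRUE    # 1-px vertical gap at col 15
  closed <- morph_close(m, 1)
  expect_equal(oracle_component_count(m), 2)
  expect_equal(oracle_component_count(closed), 1)
  # idempotence on interior blobs
  set.seed(8)
  blob <- matrix(FALSE, 50, 50)
  blob[10:40, 10:40] <- matrix(runif(31^2) < 0.45, 31, 31)
  c1 <- morph_close(blob, 2)
  c2 <- morph_close(c1, 2)
  expect_identical(c1, c2)
  # all-true stays all-true
  allt <- matrix(TRUE, 20, 20)
  expect_identical(morph_close(allt, 2), allt)
})

test_that("label_components agrees with flood-fill on random masks", {
  for (seed in 1:6) {
    set.seed(seed)
    m <- matrix(runif(40 * 40) < 0.35, 40, 40)
    lab <- label_components(m)
    expect_equal(max(lab), oracle_component_count(m))
    # labels partition the foreground
    expect_identical(lab > 0, m)
  }
})

test_that("extract_contours counts, orders and filters components", {
  shape <- c(90, 90)
  m <- disk_mask(shape, 20, 20, 8) | disk_mask(shape, 60, 30, 12) |
       disk_mask(shape, 40, 70, 5)
  cts <- extract_contours(m, min_area = 10)
  expect_length(cts, 3)
  # ordered by decreasing pixel area
  areas <- vapply(cts, function(ct) ct$npix, numeric(1))
  expect_true(all(diff(areas) <= 0))
  # empty foreground
  expect_length(extract_contours(matrix(FALSE, 10, 10)), 0)
  # disk with a hole: outer contour only
  ring <- disk_mask(shape, 45, 45, 20) & !disk_mask(shape, 45, 45, 10)
  expect_length(extract_contours(ring, min_area = 10), 1)
  # border exclusion removes components touching the frame
  edge <- disk_mask(shape, 3, 45, 6)
  expect_length(extract_contours(edge, min_area = 10), 0)
  expect_length(extract_contours(edge, min_area = 10, exclude_border = FALSE), 1)
  # min_area filter
  expect_length(extract_contours(m, min_area = 200), 1)
})

test_that("contour geometry matches the constructed disk", {
  m <- disk_mask(c(60, 60), 30, 30, 12)
  ct <- extract_contours(m, min_area = 10)[[1]]
  expect_equal(ct$npix, sum(m))
  # shoelace area close to pixel count for a convex blob
  expect_lt(abs(ct$area - sum(m)) / sum(m), 0.15)
  expect_gte(nrow(ct$vertices), 3)
})

test_that("penetration_sites returns polygon centroids", {
  sq <- structure(list(vertices = matrix(c(0, 0, 10, 0, 10, 10, 0, 10),
                                         ncol = 2, byrow = TRUE),
                       area = 100, npix = 121, perimeter = 40),
                  class = "contour")
  s <- penetration_sites(list(sq))
  expect_equal(as.numeric(s), c(5, 5))
  # filled-disk centroid within 0.5 px of the disk centre
  m <- disk_mask(c(60, 60), 25, 35, 11)
  ct <- extract_contours(m, min_area = 10)[[1]]
  s2 <- penetration_sites(list(ct))
  expect_lt(max(abs(s2 - c(24, 34))), 0.5)
  # centroid of a convex contour lies inside it
  expect_true(m[round(s2[1]) + 1, round(s2[2]) + 1])
  expect_equal(nrow(penetration_sites(list())), 0)
})

test_that("nocc follows the end-to-end contracts on seeded scenes", {
  expect_equal(nocc(matrix(150, 60, 60)), 0)
  sc <- std_scene(12)
  expect_equal(nocc(render_cell_image(sc, 40)), 12)
  expect_equal(nocc(render_cell_image(sc, -40)), 0)
  # NOCC equals the post-filter component count (oracle) on the
  # intermediate inverted mask
  img <- gaussian_blur(render_cell_image(sc, 40), 2)
  bin <- hybrid_binarize(img)
  inv <- !morph_close(bin$mask, 2)
  lab_ct <- extract_contours(inv, min_area = 30)
  expect_equal(nocc(render_cell_image(sc, 40)), length(lab_ct))
})

test_that("detection is robust across positive defocus and separations", {
  sc <- std_scene(12)
  for (df in c(15, 30, 60, 90)) {
    d <- detect_cells(render_cell_image(sc, df))
    expect_equal(d$nocc, 12)
    expect_equal(nrow(d$sites), 12)
    expect_equal(d$thresholds$branch, "otsu")
  }
})
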