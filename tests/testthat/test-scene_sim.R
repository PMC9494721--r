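# Synthetic-scene generator: thickness fields, defocus rendering,
# z-stacks, tip renders and ground truth.

test_that("thickness_field matches the analytic profiles", {
  ph <- cell_phantom(c(50, 60), c(12, 9), h_max = 4)
  h <- thickness_field(ph, c(120, 120))
  # maximum at the centre
  expect_equal(h[51, 61], 4)
  expect_equal(max(h), 4)
  # compact support: zero outside the ellipse
  expect_equal(h[50 + 1, 60 + 13 + 1], 0)
  expect_equal(h[1, 1], 0)
  # ellipsoid continuous at the boundary: values near edge are small
  edge_vals <- h[51, 60 + 9:12 + 1]
  expect_true(all(diff(edge_vals) < 0))
  expect_error(cell_phantom(c(0, 0), c(-1, 5), 2), "semi-axes")
  expect_error(cell_phantom(c(0, 0), c(5, 5), 0), "h_max")
})

test_that("paraboloid has constant interior discrete Laplacian", {
  R <- 30
  ph <- cell_phantom(c(60, 60), c(R, R), h_max = 5, profile = "paraboloid")
  h <- thickness_field(ph, c(121, 121))
  lap <- nanosense:::laplacian5(h, spacing = 1)
  interior <- disk_mask(c(121, 121), 61, 61, R - 3)
  expected <- -4 * 5 / R^2
  expect_true(all(abs(lap[interior] - expected) < 1e-9))
})

test_that("in-focus render is uniform at I0 and defocus sign flips contrast", {
  sc <- cell_scene(list(cell_phantom(c(40, 40), c(12, 12), 4)),
                   image_shape = c(80, 80), background_intensity = 150,
                   noise_sigma = 0)
  img0 <- render_cell_image(sc, 0)
  expect_true(all(img0 == 150))
  cpos <- nanosense:::contrast_field(sc, 25)
  cneg <- nanosense:::contrast_field(sc, -25)
  expect_equal(cpos, -cneg)
})

test_that("contrast is linear in defocus, delta_n and h_max (pre-clip)", {
  base <- function(df, dn, hm) {
    sc <- cell_scene(list(cell_phantom(c(40, 40), c(12, 12), hm, delta_n = dn)),
                     image_shape = c(80, 80), noise_sigma = 0)
    max(abs(nanosense:::contrast_field(sc, df)))
  }
  c1 <- base(10, 0.03, 4)
  expect_equal(base(20, 0.03, 4) / c1, 2, tolerance = 1e-9)
  expect_equal(base(10, 0.06, 4) / c1, 2, tolerance = 1e-9)
  expect_equal(base(10, 0.03, 8) / c1, 2, tolerance = 1e-9)
})

test_that("paraboloid interior gray level matches the constant-Laplacian form", {
  R <- 40; hm <- 4; dn <- 0.035; I0 <- 150
  sc <- cell_scene(list(cell_phantom(c(60, 60), c(R, R), hm, delta_n = dn,
                                     profile = "paraboloid")),
                   image_shape = c(121, 121), background_intensity = I0,
                   noise_sigma = 0)
  for (df in c(20, 50)) {
    img <- render_cell_image(sc, df)
    expected <- I0 * (1 - 4 * df * dn * hm / R^2)
    interior <- disk_mask(c(121, 121), 61, 61, R / 3)
    expect_true(all(abs(img[interior] - expected) <= 0.01 * expected))
  }
})

test_that("background far from phantoms stays exactly at I0 (noise off)", {
  sc <- cell_scene(list(cell_phantom(c(30, 30), c(10, 10), 4)),
                   image_shape = c(120, 120), noise_sigma = 0)
  img <- render_cell_image(sc, 40)
  # edge softness support is ~3 sigma = 6 px beyond the 10 px ellipse
  expect_true(all(img[60:120, 60:120] == 150))
})

test_that("rendering is deterministic and z-stacks are consistent", {
  sc <- std_scene(5, shape = c(120L, 120L), seed = 11)
  a <- render_cell_image(sc, 30)
  b <- render_cell_image(sc, 30)
  expect_identical(a, b)
  z <- seq(-10, 10, by = 5)
  s1 <- render_zstack(sc, z)
  s2 <- render_zstack(sc, z)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  # single-plane stack differs from direct render only via the plane seed
  one <- render_zstack(sc, 30)
  expect_identical(one[[1]],
                   render_cell_image(sc, 30,
                                     plane_seed = nanosense:::derive_seed(11, 1L)))
  expect_error(render_zstack(sc, c(0, 10, 5)), "monotone")
  expect_error(render_zstack(sc, numeric(0)), "nonempty")
  # 60 planes at 5 um spacing span 295 um
  z60 <- seq(0, by = 5, length.out = 60)
  expect_equal(max(z60) - min(z60), 295)
})

test_that("overlapping phantoms require the explicit flag", {
  p1 <- cell_phantom(c(40, 40), c(12, 12), 4)
  p2 <- cell_phantom(c(45, 45), c(12, 12), 4)
  expect_error(cell_scene(list(p1, p2), image_shape = c(100, 100)), "overlap")
  expect_s3_class(cell_scene(list(p1, p2), image_shape = c(100, 100),
                             allow_overlap = TRUE), "cell_scene")
})

test_that("ground truth mirrors the phantom geometry", {
  sc <- std_scene(3, shape = c(150L, 150L), seed = 5, noise_sigma = 0)
  gt <- make_ground_truth(sc)
  expect_equal(gt$cell_count, 3)
  expect_length(gt$masks, 3)
  for (i in 1:3) {
    expect_equal(gt$masks[[i]],
                 thickness_field(sc$phantoms[[i]], sc$image_shape) > 0)
    ctr <- round(gt$centroids[i, ]) + 1
    expect_true(gt$masks[[i]][ctr[1], ctr[2]])
  }
  empty <- make_ground_truth(cell_scene(image_shape = c(50, 50)))
  expect_equal(empty$cell_count, 0)
  expect_length(empty$masks, 0)
})

test_that("tip renders obey focus, attenuation and apex-location contracts", {
  tip <- std_tip()
  at_focus <- render_tip_image(tip, tip$z_focus, c(240, 240), 180, 0)
  # minimum gray level inside the triangle equals I0 - opacity
  expect_equal(min(at_focus), 180 - tip$opacity)
  # apex: extremal dark pixel along the apex direction within 1 px
  dark <- which(at_focus < 180 - tip$opacity / 2, arr.ind = TRUE)
  apex_px <- dark[which.min(dark[, 1]), ]        # tip points upward (row min)
  expect_lte(max(abs(apex_px - 1 - tip$apex)), 1)
  # far beyond the detectability limit the frame is uniform background
  far <- render_tip_image(tip, tip$detect_limit + 50, c(240, 240), 180, 0)
  expect_true(all(far == 180))
  # determinism with noise
  n1 <- render_tip_image(tip, 30, c(240, 240), 180, 2, seed = 9)
  n2 <- render_tip_image(tip, 30, c(240, 240), 180, 2, seed = 9)
  expect_identical(n1, n2)
})

test_that("random_scene places the requested number of separated phantoms", {
  sc <- random_scene(15, image_shape = c(300L, 300L), seed = 2)
  expect_length(sc$phantoms, 15)
  # supports must not overlap (validated by cell_scene, re-check directly)
  cover <- Reduce(`+`, lapply(sc$phantoms, function(p)
    thickness_field(p, sc$image_shape) > 0))
  expect_lte(max(cover), 1)
})
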