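# Focus measures and curve analytics.

test_that("classical measures vanish on constants and match closed forms", {
  const <- matrix(123, 20, 20)
  expect_equal(tenengrad(const), 0)
  expect_equal(energy(const), 0)
  expect_equal(brenner(const), 0)
  expect_equal(variance_focus(const), 0)
  # Brenner on a column ramp I(x, y) = x: each valid term is 2^2
  W <- 17; H <- 9
  ramp <- matrix(rep(0:(W - 1), each = H), H, W)
  expect_equal(brenner(ramp), 4 * (W - 2) * H)
  # variance of a two-level image {0, 2} in equal halves: sum (I - 1)^2 = n
  n <- 100
  two <- matrix(rep(c(0, 2), each = n / 2), 10, 10)
  expect_equal(variance_focus(two), n)
  expect_error(tenengrad(matrix(1, 2, 2)), "3x3")
})

test_that("gradient measures are invariant to constant offsets", {
  img <- random_gray(c(25, 25), 4, lo = 20, hi = 200)
  for (f in list(tenengrad, energy, brenner, variance_focus)) {
    expect_equal(f(img + 30), f(img), tolerance = 1e-12)
  }
})

test_that("focus_curve evaluates metrics per plane with normalization", {
  sc <- std_scene(6, shape = c(140L, 140L), seed = 9)
  z <- c(-20, 0, 20, 40)
  stack <- render_zstack(sc, z)
  fc <- focus_curve(stack, z, metric = "variance")
  expect_length(fc$values, 4)
  expect_false(fc$normalized)
  nc <- normalize_curve(fc)
  expect_equal(range(nc$values), c(0, 1))
  # plain min-max arithmetic
  raw <- structure(list(z = 1:3, values = c(2, 6, 10), metric = "x",
                        normalized = FALSE), class = "focus_curve")
  expect_equal(normalize_curve(raw)$values, c(0, 0.5, 1))
  expect_error(focus_curve(stack, z, metric = "nope"), "unknown")
  one <- focus_curve(stack[1], z[1], metric = "energy")
  expect_length(one$values, 1)
})

test_that("find_best_defocus is an exhaustive argmax with |z| tie-break", {
  sc <- std_scene(8, shape = c(160L, 160L), seed = 13)
  z <- seq(-30, 50, by = 10)
  stack <- render_zstack(sc, z)
  res <- find_best_defocus(stack, z)
  counts <- vapply(stack, nocc, integer(1))
  expect_equal(res$curve$values, as.numeric(counts))
  best_brute <- which(counts == max(counts))
  expect_true(res$index %in% best_brute)
  expect_equal(abs(res$z_best), min(abs(z[best_brute])))
  expect_equal(res$detection$nocc, max(counts))
  # all-zero curve errors
  flat <- list(matrix(150, 50, 50), matrix(150, 50, 50))
  expect_error(find_best_defocus(flat, c(0, 5)), "no focus")
})

make_curve <- function(values, z = seq_along(values)) {
  structure(list(z = as.numeric(z), values = as.numeric(values),
                 metric = "test", normalized = FALSE), class = "focus_curve")
}

test_that("count_false_maxima counts interior strict maxima minus the global", {
  expect_equal(count_false_maxima(make_curve(c(0, 1, 3, 7, 3, 1, 0))), 0)
  expect_equal(count_false_maxima(make_curve(c(0, 2, 1, 3, 0))), 1)
  expect_equal(count_false_maxima(make_curve(c(1, 2, 3, 4, 5))), 0)
  # plateaus collapse to one candidate
  expect_equal(count_false_maxima(make_curve(c(0, 2, 2, 2, 1, 5, 0))), 1)
  expect_error(count_false_maxima(make_curve(c(1, 2))), "short")
  # brute-force check on random curves
  for (seed in 1:5) {
    set.seed(seed)
    v <- sample(0:9, 15, replace = TRUE)
    r <- rle(v)$values
    n <- length(r)
    brute <- 0L
    if (n >= 3) {
      for (i in 2:(n - 1))
        if (r[i] > r[i - 1] && r[i] > r[i + 1] && i != which.max(r))
          brute <- brute + 1L
    }
    expect_equal(count_false_maxima(make_curve(v)), brute)
  }
})

test_that("curve_range brackets the global extremum", {
  # unimodal: ends count as minima, full span
  uni <- make_curve(c(0, 2, 5, 9, 5, 2, 0), z = seq(0, 295, length.out = 7))
  expect_equal(as.numeric(curve_range(uni, "minima_bracket")), 295)
  # spec example: minima at z = 10 and z = 20 bracket the max at 15
  ex <- make_curve(c(0, 1, 0, 5, 0), z = c(0, 5, 10, 15, 20))
  expect_equal(as.numeric(curve_range(ex, "minima_bracket")), 10)
  # symmetric curve: flanks equidistant from the maximum
  sym <- make_curve(c(5, 1, 8, 1, 5), z = c(0, 5, 10, 15, 20))
  expect_equal(as.numeric(curve_range(sym, "minima_bracket")), 10)
  # maxima_bracket: maxima flanking the focus-plane minimum
  w <- make_curve(c(0, 6, 1, 7, 0), z = c(0, 5, 10, 15, 20))
  expect_equal(as.numeric(curve_range(w, "maxima_bracket")), 10)
  # degenerate (monotone) curve returns full span with a flag
  mono <- make_curve(1:5, z = c(0, 5, 10, 15, 20))
  r <- curve_range(mono, "minima_bracket")
  expect_true(isTRUE(attr(r, "degenerate")))
  expect_equal(as.numeric(r), 20)
})

test_that("noise_level is the sum of squared second differences", {
  expect_equal(noise_level(make_curve(c(3, 5, 7, 9, 11))), 0)
  expect_equal(noise_level(make_curve(c(0, 1, 4, 9))), 8)
  v <- c(2, 7, 1, 8, 3)
  expect_equal(noise_level(make_curve(5 * v)), 25 * noise_level(make_curve(v)))
  expect_error(noise_level(make_curve(c(1, 2))), "short")
})

test_that("NOCC curve on a clean stack is one-sided and unimodal", {
  sc <- std_scene(10, shape = c(200L, 200L), seed = 21, noise_sigma = 1)
  z <- seq(-50, 70, by = 10)
  stack <- render_zstack(sc, z)
  fc <- focus_curve(stack, z, metric = "nocc")
  expect_true(all(fc$values[z < 0] == 0))
  expect_true(any(fc$values[z > 0] > 0))
  expect_equal(count_false_maxima(fc), 0)
})
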