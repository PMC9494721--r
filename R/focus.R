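# Focus measures and focus-curve analysis. Classical sharpness measures
# (Tenengrad, Energy, Brenner, Variance) peak at the true focal plane;
# the NOCC measure instead peaks at the positively defocused plane where
# transparent adherent cells segment best, and is zero by construction on
# the negative-defocus side.

#' Classical focus measures
#'
#' All four are computed in floating point over the valid interior:
#' * Tenengrad: `sum(Sx^2 + Sy^2)` with 3x3 Sobel gradients;
#' * Energy: `sum((I[x+1,y]-I[x,y])^2 + (I[x,y+1]-I[x,y])^2)`;
#' * Brenner: `sum((I[x+2,y]-I[x,y])^2)`;
#' * Variance: `sum((I - mean(I))^2)`.
#'
#' All are invariant to adding a constant gray offset and are zero on a
#' constant image.
#'
#' @param img gray matrix, at least 3x3.
#' @return scalar focus value.
#' @name focus-measures
NULL

check_focus_input <- function(img) {
  assert_gray(img)
  if (nrow(img) < 3L || ncol(img) < 3L)
    stop("image must be at least 3x3 for focus measures", call. = FALSE)
  img
}

#' @rdname focus-measures
#' @export
tenengrad <- function(img) {
  check_focus_input(img)
  nr <- nrow(img); nc <- ncol(img)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  # 3x3 Sobel: gx along columns, gy along rows
  gx <- (img[i - 1, j + 1] + 2 * img[i, j + 1] + img[i + 1, j + 1]) -
        (img[i - 1, j - 1] + 2 * img[i, j - 1] + img[i + 1, j - 1])
  gy <- (img[i + 1, j - 1] + 2 * img[i + 1, j] + img[i + 1, j + 1]) -
        (img[i - 1, j - 1] + 2 * img[i - 1, j] + img[i - 1, j + 1])
  sum(gx^2 + gy^2)
}

#' @rdname focus-measures
#' @export
energy <- function(img) {
  check_focus_input(img)
  dr <- img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE]
  dc <- img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]
  sum(dr^2) + sum(dc^2)
}

#' @rdname focus-measures
#' @export
brenner <- function(img) {
  check_focus_input(img)
  nc <- ncol(img)
  d2 <- img[, 3:nc, drop = FALSE] - img[, seq_len(nc - 2), drop = FALSE]
  sum(d2^2)
}

#' @rdname focus-measures
#' @export
variance_focus <- function(img) {
  check_focus_input(img)
  sum((img - mean(img))^2)
}

focus_metric_fun <- function(metric, ...) {
  params <- list(...)
  switch(metric,
    tenengrad = tenengrad,
    energy = energy,
    brenner = brenner,
    variance = variance_focus,
    nocc = function(img) do.call(nocc, c(list(img), params)),
    stop("unknown focus metric: ", metric, call. = FALSE))
}

#' Build a focus curve over a z-stack
#'
#' @param images list of gray matrices (one per plane, in stack order).
#' @param z numeric stage positions matching `images`.
#' @param metric one of `"nocc"`, `"tenengrad"`, `"energy"`, `"brenner"`,
#'   `"variance"`.
#' @param normalize min-max normalize values to `[0, 1]`.
#' @param ... extra parameters for the NOCC chain (see [detect_cells()]).
#' @return object of class `focus_curve` with fields `z`, `values`,
#'   `metric`, `normalized`.
#' @export
focus_curve <- function(images, z, metric = "nocc", normalize = FALSE, ...) {
  if (length(images) == 0L) stop("empty stack", call. = FALSE)
  if (length(images) != length(z))
    stop("`images` and `z` lengths differ", call. = FALSE)
  f <- focus_metric_fun(metric, ...)
  vals <- vapply(images, f, numeric(1))
  fc <- structure(list(z = as.numeric(z), values = as.numeric(vals),
                       metric = metric, normalized = FALSE),
                  class = "focus_curve")
  if (normalize) fc <- normalize_curve(fc)
  fc
}

#' Min-max normalize a focus curve to [0, 1]
#'
#' An all-equal curve is left unchanged (flagged normalized).
#'
#' @param curve a `focus_curve`.
#' @return normalized `focus_curve`.
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "focus_curve"))
  rng <- range(curve$values)
  if (diff(rng) > 0)
    curve$values <- (curve$values - rng[1]) / diff(rng)
  curve$normalized <- TRUE
  curve
}

#' Find the best defocused plane by maximal NOCC
#'
#' Exhaustive search over the stack; ties resolve to the smallest `|z|`
#' (then the smaller z). Errors when every plane yields zero contours.
#'
#' @param images list of gray matrices.
#' @param z stage positions.
#' @param ... parameters for [detect_cells()].
#' @return list with `z_best`, `index`, `detection` (the
#'   `detection_result` at the winning plane), and `curve`.
#' @export
find_best_defocus <- function(images, z, ...) {
  if (length(images) == 0L) stop("empty stack", call. = FALSE)
  dets <- lapply(images, detect_cells, ...)
  counts <- vapply(dets, function(d) d$nocc, integer(1))
  if (all(counts == 0L))
    stop("no focus found: NOCC is zero on every plane", call. = FALSE)
  best <- which(counts == max(counts))
  best <- best[order(abs(z[best]), z[best])][1]
  list(z_best = z[best], index = best, detection = dets[[best]],
       curve = structure(list(z = as.numeric(z), values = as.numeric(counts),
                              metric = "nocc", normalized = FALSE),
                         class = "focus_curve"))
}

# Collapse runs of equal values to single candidates (value, z at run
# centre, index of run centre).
collapse_plateaus <- function(curve) {
  r <- rle(curve$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- (starts + ends) / 2
  zmid <- (curve$z[starts] + curve$z[ends]) / 2
  list(values = r$values, z = zmid, mid = mid)
}

#' Count false maxima of a focus curve
#'
#' Number of strict interior local maxima, excluding the global maximum.
#' Plateaus are collapsed to a single candidate first.
#'
#' @param curve a `focus_curve` of length >= 3.
#' @return integer count.
#' @export
count_false_maxima <- function(curve) {
  stopifnot(inherits(curve, "focus_curve"))
  if (length(curve$values) < 3L) stop("curve too short", call. = FALSE)
  cp <- collapse_plateaus(curve)
  v <- cp$values
  n <- length(v)
  if (n < 3L) return(0L)
  i <- 2:(n - 1)
  ismax <- v[i] > v[i - 1] & v[i] > v[i + 1]
  cand <- i[ismax]
  g <- which.max(v)
  length(setdiff(cand, g))
}

#' Effective z-range of a focus curve
#'
#' `minima_bracket`: z-distance between the local minima nearest to and
#' flanking the global maximum; curve ends count as minima. This is the
#' classical range of a focus curve, appropriate for measures peaking at
#' focus (and for NOCC, which peaks at the usable defocused plane).
#' `maxima_bracket`: z-distance between the local maxima flanking the
#' curve's global minimum; appropriate for classical measures on
#' transparent cells, whose focal plane sits in a local minimum between
#' two defocus maxima. When the required extrema are missing the full
#' z-span is returned with attribute `degenerate = TRUE`.
#'
#' @param curve a `focus_curve` of length >= 3.
#' @param mode `"minima_bracket"` or `"maxima_bracket"`.
#' @return range in the z units of the curve.
#' @export
curve_range <- function(curve, mode = c("minima_bracket", "maxima_bracket")) {
  mode <- match.arg(mode)
  stopifnot(inherits(curve, "focus_curve"))
  if (length(curve$values) < 3L) stop("curve too short", call. = FALSE)
  cp <- collapse_plateaus(curve)
  v <- cp$values
  n <- length(v)
  full <- abs(curve$z[length(curve$z)] - curve$z[1])
  degenerate <- function() structure(full, degenerate = TRUE)
  if (n < 3L) return(degenerate())
  if (mode == "minima_bracket") {
    g <- which.max(v)
    is_min <- c(TRUE, v[2:(n - 1)] < v[1:(n - 2)] & v[2:(n - 1)] < v[3:n], TRUE)
    left <- which(is_min[seq_len(g - 1)])
    right <- which(is_min) ; right <- right[right > g]
    if (!length(left) || !length(right)) return(degenerate())
    abs(cp$z[min(right)] - cp$z[max(left)])
  } else {
    # focus plane = deepest interior local minimum (ends are not eligible);
    # flanking local maxima, with the curve ends counting as maxima
    i <- 2:(n - 1)
    is_int_min <- v[i] < v[i - 1] & v[i] < v[i + 1]
    cand <- i[is_int_min]
    if (!length(cand)) return(degenerate())
    g <- cand[which.min(v[cand])]
    is_max <- c(TRUE, v[i] > v[i - 1] & v[i] > v[i + 1], TRUE)
    left <- which(is_max[seq_len(g - 1)])
    right <- which(is_max); right <- right[right > g]
    if (!length(left) || !length(right)) return(degenerate())
    abs(cp$z[min(right)] - cp$z[max(left)])
  }
}

#' Noise level of a focus curve
#'
#' Sum of squared second differences of the sample values (unit index
#' step). Zero for any affine-linear curve. Comparisons between metrics
#' should be made on min-max-normalized curves (see [curve_quality()]).
#'
#' @param curve a `focus_curve` of length >= 3.
#' @return scalar noise level.
#' @export
noise_level <- function(curve) {
  stopifnot(inherits(curve, "focus_curve"))
  v <- curve$values
  if (length(v) < 3L) stop("curve too short", call. = FALSE)
  n <- length(v)
  d2 <- v[1:(n - 2)] - 2 * v[2:(n - 1)] + v[3:n]
  sum(d2^2)
}

#' Focus-curve quality summary
#'
#' Computes the comparison metrics on the min-max-normalized curve:
#' range, number of false maxima, noise level and the z of the global
#' maximum.
#'
#' @param curve a `focus_curve`.
#' @param range_mode passed to [curve_range()].
#' @return list with `range_um`, `false_maxima`, `noise_level`, `best_z`.
#' @export
curve_quality <- function(curve, range_mode = "minima_bracket") {
  nc <- normalize_curve(curve)
  list(range_um = as.numeric(curve_range(nc, range_mode)),
       false_maxima = count_false_maxima(nc),
       noise_level = noise_level(nc),
       best_z = nc$z[which.max(nc$values)])
}

#' @export
print.focus_curve <- function(x, ...) {
  cat(sprintf("focus curve (%s%s): %d planes, z in [%g, %g]\n",
              x$metric, if (x$normalized) ", normalized" else "",
              length(x$z), min(x$z), max(x$z)))
  invisible(x)
}
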