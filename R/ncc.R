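# Zero-mean normalised cross-correlation template matching and the
# nonovershoot descent controller. The similarity at offset (x, y) is
#   S = sum(T' * I') / sqrt(sum(T'^2) * sum(I'^2)),
# with T' and I' the mean-subtracted template and image window, so S is
# bounded in [-1, 1] and invariant to affine intensity changes of the
# window (positive gain).

#' Create a matching template
#'
#' @param pixels gray matrix, at least 2x2, not constant-valued.
#' @return object of class `ncc_template`.
#' @export
ncc_template <- function(pixels) {
  assert_gray(pixels, "pixels")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("template must be at least 2x2", call. = FALSE)
  if (max(pixels) == min(pixels))
    stop("template must not be constant-valued", call. = FALSE)
  structure(list(pixels = pixels, h = nrow(pixels), w = ncol(pixels)),
            class = "ncc_template")
}

#' Crop a template around the focused tip apex
#'
#' Convenience: renders the tip phantom at its focal plane and crops a
#' window around the apex, mimicking a precollected template image of
#' the focused tip.
#'
#' @param tip a [tip_phantom()].
#' @param shape frame dimensions used for the render.
#' @param background background gray level.
#' @param half_size half the template side length, pixels.
#' @return an [ncc_template()].
#' @export
template_from_tip <- function(tip, shape = c(240L, 240L), background = 180,
                              half_size = 30L) {
  img <- render_tip_image(tip, tip$z_focus, shape, background, 0)
  r <- round(tip$apex[1]) + 1L
  c_ <- round(tip$apex[2]) + 1L
  rs <- max(1L, r - half_size):min(nrow(img), r + half_size)
  cs <- max(1L, c_ - half_size):min(ncol(img), c_ + half_size)
  ncc_template(img[rs, cs, drop = FALSE])
}

# Windowed sums over all template-sized offsets via integral images.
window_sums <- function(img, h, w) {
  S <- apply(apply(img, 2, cumsum), 1, cumsum)   # transposed integral image
  S <- t(S)
  pad <- matrix(0, nrow(S) + 1L, ncol(S) + 1L)
  pad[-1, -1] <- S
  nr <- nrow(img) - h + 1L
  nc <- ncol(img) - w + 1L
  i <- seq_len(nr); j <- seq_len(nc)
  pad[i + h, j + w, drop = FALSE] - pad[i, j + w, drop = FALSE] -
    pad[i + h, j, drop = FALSE] + pad[i, j, drop = FALSE]
}

#' Zero-mean normalised cross-correlation similarity map
#'
#' Evaluates the similarity for every offset at which the template fits
#' inside the image. Windows with zero variance are assigned similarity 0
#' (a flat window cannot match a structured template).
#'
#' @param img gray matrix.
#' @param template an [ncc_template()] (or a matrix, converted).
#' @return object of class `similarity_map`: `values` (matrix of size
#'   `dim(img) - dim(template) + 1`), `h`, `w`. Offsets are 0-based:
#'   entry `[1, 1]` is offset `(0, 0)` (template aligned at top-left).
#' @export
ncc_similarity <- function(img, template) {
  assert_gray(img)
  if (is.matrix(template)) template <- ncc_template(template)
  stopifnot(inherits(template, "ncc_template"))
  h <- template$h; w <- template$w
  if (h > nrow(img) || w > ncol(img))
    stop("template larger than image", call. = FALSE)
  tz <- template$pixels - mean(template$pixels)
  tnorm2 <- sum(tz^2)
  n <- h * w
  nr <- nrow(img) - h + 1L
  nc <- ncol(img) - w + 1L
  # cross term sum(T * I_window), accumulated one template pixel at a time
  cross <- matrix(0, nr, nc)
  for (a in seq_len(h)) {
    rows <- a:(a + nr - 1L)
    sub <- img[rows, , drop = FALSE]
    for (b in seq_len(w)) {
      tv <- tz[a, b]
      if (tv != 0)
        cross <- cross + tv * sub[, b:(b + nc - 1L), drop = FALSE]
    }
  }
  s1 <- window_sums(img, h, w)        # sum I
  s2 <- window_sums(img^2, h, w)      # sum I^2
  ivar <- s2 - s1^2 / n               # sum I'^2
  # sum(T' * I) equals sum(T' * I') because sum(T') = 0
  denom <- sqrt(tnorm2 * pmax(ivar, 0))
  vals <- matrix(0, nr, nc)
  nzero <- denom > 0
  vals[nzero] <- cross[nzero] / denom[nzero]
  structure(list(values = vals, h = h, w = w), class = "similarity_map")
}

#' Best match in a similarity map
#'
#' @param map a `similarity_map`.
#' @return list with `s_max` and `offset` (0-based `(row, col)` shift);
#'   ties resolve to the smallest row, then column.
#' @export
best_match <- function(map) {
  stopifnot(inherits(map, "similarity_map"))
  v <- map$values
  if (length(v) == 0L) stop("empty similarity map", call. = FALSE)
  m <- max(v)
  idx <- which(v == m, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  list(s_max = m, offset = as.numeric(idx[1, ] - 1L))
}

#' Virtual tip stage for the descent controller
#'
#' Bundles the tip phantom and imaging conditions so that
#' [approach_until_similar()] can render frames at arbitrary stage
#' positions.
#'
#' @param tip a [tip_phantom()].
#' @param z_start initial stage position, micrometers (above focus).
#' @param shape frame dimensions.
#' @param background background gray level.
#' @param noise_sigma camera noise SD, gray levels.
#' @param seed integer seed for per-step noise.
#' @return object of class `tip_stage`.
#' @export
tip_stage <- function(tip, z_start, shape = c(240L, 240L), background = 180,
                      noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(tip, "tip_phantom"))
  structure(list(tip = tip, z_start = as.numeric(z_start),
                 shape = as.integer(shape), background = background,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "tip_stage")
}

#' Descend the tip until template similarity crosses a threshold
#'
#' At each stage position the tip is rendered, the maximal zero-mean NCC
#' similarity against the focused-tip template is computed, and the stage
#' descends by `step` while the similarity stays below `threshold`.
#' Stopping before the focal plane (nonovershoot) is achieved by
#' choosing a threshold below the similarity attained just above focus.
#'
#' @param stage a [tip_stage()].
#' @param template an [ncc_template()].
#' @param threshold similarity threshold in (0, 1).
#' @param step descent step, micrometers.
#' @param z_limit lowest stage position to visit; reaching it without
#'   crossing the threshold is flagged, not an error.
#' @return object of class `approach_log`: `z_sequence`,
#'   `similarity_sequence`, `stop_z`, `stopped_before_focus`,
#'   `threshold_crossed`.
#' @export
approach_until_similar <- function(stage, template, threshold = 0.92,
                                   step = 5, z_limit = NULL) {
  stopifnot(inherits(stage, "tip_stage"))
  if (is.matrix(template)) template <- ncc_template(template)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (is.null(z_limit)) z_limit <- stage$tip$z_focus
  zs <- numeric(0)
  ss <- numeric(0)
  z <- stage$z_start
  crossed <- FALSE
  k <- 0L
  repeat {
    k <- k + 1L
    img <- render_tip_image(stage$tip, z, stage$shape, stage$background,
                            stage$noise_sigma, seed = derive_seed(stage$seed, k))
    s <- best_match(ncc_similarity(img, template))$s_max
    zs <- c(zs, z)
    ss <- c(ss, s)
    if (s >= threshold) { crossed <- TRUE; break }
    if (z - step < z_limit - 1e-9) break
    z <- z - step
  }
  structure(list(z_sequence = zs, similarity_sequence = ss,
                 stop_z = zs[length(zs)],
                 stopped_before_focus = zs[length(zs)] > stage$tip$z_focus,
                 threshold_crossed = crossed),
            class = "approach_log")
}

#' @export
print.approach_log <- function(x, ...) {
  cat(sprintf(
    "tip approach: %d steps, stop z = %g (%s, threshold %scrossed)\n",
    length(x$z_sequence), x$stop_z,
    if (x$stopped_before_focus) "before focus" else "at/past focus",
    if (x$threshold_crossed) "" else "not "))
  invisible(x)
}
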