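# Low-level raster helpers shared by the simulator and the vision modules.
# Images are plain numeric matrices in [0, 255], indexed [row, col],
# 0-based pixel coordinates at pixel centres (origin top-left).

#' Clamp values to the 8-bit range
#'
#' @param x numeric vector or matrix.
#' @return `x` with values clamped to `[0, 255]`.
#' @keywords internal
clip8 <- function(x) pmin(pmax(x, 0), 255)

# Round and clamp to integer gray levels; storage stays double.
quantize8 <- function(x) {
  out <- clip8(round(x))
  storage.mode(out) <- "double"
  out
}

assert_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop(sprintf("`%s` must be a nonempty numeric matrix", arg), call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(sprintf("`%s` must contain gray levels in [0, 255]", arg), call. = FALSE)
  invisible(img)
}

#' Convert an RGB array to 8-bit grayscale
#'
#' Uses the standard luminance weights 0.299 R + 0.587 G + 0.114 B.
#' Matrices pass through unchanged (after validation).
#'
#' @param x a `rows x cols` gray matrix or `rows x cols x 3` RGB array
#'   (values in `[0, 255]` or `[0, 1]`; the latter is rescaled).
#' @return gray matrix with values in `[0, 255]`.
#' @export
as_gray <- function(x) {
  if (is.matrix(x)) {
    if (max(x) <= 1 && min(x) >= 0 && max(x) > 0) x <- x * 255
    assert_gray(x)
    return(x)
  }
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] >= 3L) {
    if (max(x) <= 1) x <- x * 255
    g <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    return(quantize8(g))
  }
  stop("cannot interpret input as a gray or RGB image", call. = FALSE)
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(sr) && length(sc))
    out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

# Symmetric (edge-duplicating) reflection of out-of-range indices into 1..n.
reflect_index <- function(idx, n) {
  # period 2n sawtooth: 1..n then n..1
  j <- (idx - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Banded convolution matrix with symmetric border reflection; rows sum to 1
# when the kernel does, so constant signals are preserved exactly.
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (k in seq_along(kernel)) {
    j <- reflect_index(i + (k - 1L - r), n)
    ij <- cbind(i, j)
    M[ij] <- M[ij] + kernel[k]
  }
  M
}

# Separable convolution of a matrix with a symmetric 1-D kernel (both axes),
# symmetric border handling, computed in floating point.
conv_sep <- function(m, kernel) {
  Kr <- conv_band_matrix(nrow(m), kernel)
  Kc <- conv_band_matrix(ncol(m), kernel)
  Kr %*% m %*% t(Kc)
}

# Floating-point Gaussian smoothing (no quantization); sigma in pixels.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep(m, gaussian_kernel1d(sigma))
}

# 5-point discrete Laplacian, zero outside the domain, scaled by spacing^-2.
laplacian5 <- function(field, spacing = 1) {
  (shift_mat(field, 1, 0) + shift_mat(field, -1, 0) +
     shift_mat(field, 0, 1) + shift_mat(field, 0, -1) - 4 * field) / spacing^2
}

#' Downsample an image by integer block averaging
#'
#' Area-average resampling used to shrink large camera frames before
#' processing (e.g. 4096x2168 to 1024x542 with `factor = 4`). Trailing
#' rows/columns that do not fill a block are dropped.
#'
#' @param img gray matrix.
#' @param factor positive integer block size.
#' @return downsampled gray matrix (quantized to 8-bit levels).
#' @export
downsample <- function(img, factor = 4L) {
  assert_gray(img)
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(img)
  nr <- nrow(img) %/% factor
  nc <- ncol(img) %/% factor
  if (nr < 1L || nc < 1L) stop("image smaller than one block", call. = FALSE)
  x <- img[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  # sum within row-blocks, then gather every factor-th column per block
  s <- colSums(array(x, c(factor, nr, factor * nc)))  # nr x (factor*nc)
  out <- matrix(0, nr, nc)
  for (bc in seq_len(factor)) {
    out <- out + s[, seq(bc, factor * nc, by = factor), drop = FALSE]
  }
  quantize8(out / factor^2)
}

# Evaluate run-state of .Random.seed around expr so library code never
# perturbs (or depends on) the caller's RNG stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed below 2^31 from a base seed and an index.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011 * 33029 + as.numeric(k) * 2063 + 17) %% 2147483629)
}
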