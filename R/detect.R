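# Cell detection: Gaussian blur, hybrid triangle/Otsu binarization,
# morphological closing, inversion, contour extraction and centroid
# (penetration-site) identification. The contour count (NOCC) doubles as
# the focus measure for adherent cells.

#' Gaussian blur of a gray image
#'
#' Separable Gaussian convolution with symmetric (reflective) borders,
#' quantized back to 8-bit gray levels. `sigma = 0` returns the input.
#'
#' @param img gray matrix.
#' @param sigma kernel SD in pixels, `>= 0`.
#' @return blurred gray matrix.
#' @export
gaussian_blur <- function(img, sigma = 2) {
  assert_gray(img)
  if (sigma < 0) stop("`sigma` must be nonnegative", call. = FALSE)
  if (sigma == 0) return(img)
  quantize8(smooth_gaussian(img, sigma))
}

# 256-bin histogram of an 8-bit image; index i holds the count of level i-1.
gray_histogram <- function(img) {
  tabulate(as.integer(round(img)) + 1L, nbins = 256L)
}

#' Otsu threshold
#'
#' Gray level maximizing between-class variance of the 256-bin histogram;
#' pixels `<= T` form the lower class. Ties resolve to the smallest level.
#'
#' @param img gray matrix with at least two distinct levels.
#' @return integer threshold in `[0, 254]`.
#' @export
otsu_threshold <- function(img) {
  assert_gray(img)
  h <- gray_histogram(img)
  if (sum(h > 0) < 2L)
    stop("degenerate histogram: image has fewer than two gray levels",
         call. = FALSE)
  p <- h / sum(h)
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  # between-class variance for threshold t = 0..254 (class split at <= t)
  w <- w0[1:255]
  m <- mu[1:255]
  valid <- w > 0 & w < 1
  sb <- rep(-Inf, 255)
  sb[valid] <- (mu_t * w[valid] - m[valid])^2 / (w[valid] * (1 - w[valid]))
  which.max(sb) - 1L
}

#' Histogram peak (mode) gray level
#'
#' @param img gray matrix.
#' @return most frequent gray level; ties resolve to the smallest level.
#' @export
histogram_peak <- function(img) {
  assert_gray(img)
  which.max(gray_histogram(img)) - 1L
}

#' Triangle threshold
#'
#' Constructs the line from the histogram peak `(T_peak, count)` to the
#' farthest nonzero bin on the requested side and returns the bin with
#' maximal perpendicular distance between the histogram curve and that
#' line, searched strictly between the two anchor bins.
#'
#' @param img gray matrix.
#' @param toward `"brighter_end"` or `"darker_end"`: which histogram tail
#'   anchors the line.
#' @return integer threshold level.
#' @export
triangle_threshold <- function(img, toward = c("brighter_end", "darker_end")) {
  toward <- match.arg(toward)
  assert_gray(img)
  h <- gray_histogram(img)
  if (sum(h > 0) < 2L)
    stop("degenerate histogram: image has fewer than two gray levels",
         call. = FALSE)
  peak <- which.max(h)                        # 1-based bin
  nz <- which(h > 0)
  end <- if (toward == "brighter_end") max(nz) else min(nz)
  if (end == peak)
    stop("degenerate histogram: peak coincides with the ", toward, call. = FALSE)
  bins <- if (end > peak) (peak + 1L):(end - 1L) else (end + 1L):(peak - 1L)
  if (end - peak == 1L || peak - end == 1L)
    stop("degenerate histogram: no bins between peak and ", toward, call. = FALSE)
  # perpendicular distance from (b, h[b]) to the peak--end line
  x1 <- peak; y1 <- h[peak]; x2 <- end; y2 <- h[end]
  d <- abs((y2 - y1) * bins - (x2 - x1) * h[bins] + x2 * y1 - y2 * x1)
  bins[which.max(d)] - 1L
}

#' Hybrid triangle/Otsu binarization
#'
#' Compares the Otsu threshold with the histogram mode: when
#' `T_otsu > T_peak` the scene is taken as negatively defocused (cells
#' brighter than background) and the triangle rule anchored at the
#' brighter tail is used, which leaves a single connected background and
#' hence zero cell contours downstream. When `T_otsu < T_peak` the Otsu
#' threshold is used directly (positive defocus, dark cells). A tie is
#' treated as negative defocus. Foreground (`TRUE`) pixels are those
#' *above* the chosen threshold; the downstream inversion turns dark
#' cells into foreground.
#'
#' @param img gray matrix.
#' @return list with `mask` (logical matrix, `TRUE` above threshold),
#'   `branch` (`"triangle"` or `"otsu"`), `threshold`, `t_otsu`, `t_peak`.
#' @export
hybrid_binarize <- function(img) {
  t_otsu <- otsu_threshold(img)
  t_peak <- histogram_peak(img)
  if (t_otsu >= t_peak) {
    thr <- triangle_threshold(img, "brighter_end")
    branch <- "triangle"
  } else {
    thr <- t_otsu
    branch <- "otsu"
  }
  list(mask = img > thr, branch = branch, threshold = thr,
       t_otsu = t_otsu, t_peak = t_peak)
}

# Disk-shaped structuring element as (dr, dc) offsets.
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

binary_dilate <- function(mask, offsets) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift_mat(mask, offsets$dr[i], offsets$dc[i], fill = FALSE)
  out
}

binary_erode <- function(mask, offsets) {
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift_mat(mask, offsets$dr[i], offsets$dc[i], fill = TRUE)
  out
}

#' Morphological closing with a disk structuring element
#'
#' Dilation followed by erosion; fills gaps up to about `2 * se_radius`
#' pixels and removes small dark specks from the foreground.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @param se_radius disk radius in pixels, `>= 1`.
#' @return closed logical matrix.
#' @export
morph_close <- function(mask, se_radius = 2) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (se_radius < 1) stop("`se_radius` must be >= 1", call. = FALSE)
  off <- disk_offsets(se_radius)
  binary_erode(binary_dilate(mask, off), off)
}

#' Label connected foreground components
#'
#' Run-based two-pass labelling with union-find merging.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix; 0 = background, components numbered from 1 in
#'   raster-scan order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  pad <- if (connectivity == 8L) 1L else 0L
  prev_runs <- NULL  # matrix: start, end, label
  for (r in seq_len(nr)) {
    row <- mask[r, ]
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- rl$values
    runs <- cbind(start = starts[keep], end = ends[keep],
                  label = rep(0L, sum(keep)))
    if (nrow(runs)) {
      for (i in seq_len(nrow(runs))) {
        lab <- 0L
        if (!is.null(prev_runs) && nrow(prev_runs)) {
          ov <- prev_runs[, "start"] <= runs[i, "end"] + pad &
                prev_runs[, "end"] >= runs[i, "start"] - pad
          for (j in which(ov)) {
            pl <- find(prev_runs[j, "label"])
            if (lab == 0L) lab <- pl
            else if (pl != lab) parent[pl] <- find(lab)
          }
        }
        if (lab == 0L) {
          parent[length(parent) + 1L] <- length(parent) + 1L
          lab <- length(parent)
        }
        runs[i, "label"] <- lab
        labels[r, runs[i, "start"]:runs[i, "end"]] <- lab
      }
    }
    prev_runs <- runs
  }
  if (length(parent)) {
    roots <- vapply(seq_along(parent), find, integer(1))
    remap <- integer(length(parent))
    nz <- labels > 0L
    first_seen <- unique(roots[labels[which(nz)]])  # raster order of roots
    remap[first_seen] <- seq_along(first_seen)
    labels[nz] <- remap[roots[labels[nz]]]
  }
  labels
}

# Moore-neighbour boundary trace of one component with backtracking and
# Jacob's stopping criterion. Returns an n x 2 matrix of 0-based
# (row, col) pixel centres, clockwise, starting at the topmost-leftmost
# foreground pixel (whose West neighbour is guaranteed background).
trace_boundary <- function(is_fg, start) {
  # clockwise neighbour order (rows grow downwards): E, SE, S, SW, W, NW, N, NE
  nbr <- matrix(c(0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L, 0L, -1L,
                  -1L, -1L, -1L, 0L, -1L, 1L), ncol = 2, byrow = TRUE)
  nr <- nrow(is_fg); nc <- ncol(is_fg)
  fg <- function(p) p[1] >= 1L && p[1] <= nr && p[2] >= 1L && p[2] <= nc &&
    is_fg[p[1], p[2]]
  dir_of <- function(from, to) {
    d <- to - from
    which(nbr[, 1] == d[1] & nbr[, 2] == d[2]) - 1L
  }
  cur <- start
  back <- start + c(0L, -1L)              # entered from the West
  second <- NULL
  pts <- list(start)
  limit <- 4L * (nr * nc) + 8L
  repeat {
    dcb <- dir_of(cur, back)
    nxt <- NULL
    for (k in 1:8) {
      d <- (dcb + k) %% 8L
      p <- cur + nbr[d + 1L, ]
      if (fg(p)) {
        nxt <- p
        back <- cur + nbr[(d - 1L) %% 8L + 1L, ]  # last background examined
        break
      }
    }
    if (is.null(nxt)) break               # isolated pixel
    # stop when about to repeat the very first move (start -> second)
    if (!is.null(second) && all(cur == start) && all(nxt == second)) break
    if (is.null(second)) second <- nxt
    cur <- nxt
    pts[[length(pts) + 1L]] <- cur
    if (length(pts) > limit) break        # safety net
  }
  # drop the duplicated closing vertex if present
  v <- do.call(rbind, pts)
  if (nrow(v) > 1L && all(v[nrow(v), ] == v[1L, ])) v <- v[-nrow(v), , drop = FALSE]
  v - 1L
}

# Compact per-component statistics from a label matrix.
component_stats <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(data.frame(label = integer(0)))
  idx <- which(labels > 0L)
  lab <- labels[idx]
  r <- (idx - 1L) %% nrow(labels) + 1L
  c_ <- (idx - 1L) %/% nrow(labels) + 1L
  data.frame(
    label = seq_len(n),
    npix = tabulate(lab, n),
    rmin = vapply(split(r, lab), min, 0)[as.character(seq_len(n))],
    rmax = vapply(split(r, lab), max, 0)[as.character(seq_len(n))],
    cmin = vapply(split(c_, lab), min, 0)[as.character(seq_len(n))],
    cmax = vapply(split(c_, lab), max, 0)[as.character(seq_len(n))],
    crow = vapply(split(r, lab), mean, 0)[as.character(seq_len(n))] - 1,
    ccol = vapply(split(c_, lab), mean, 0)[as.character(seq_len(n))] - 1
  )
}

shoelace_area <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  x <- v[, 2]; y <- v[, 1]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polyline_perimeter <- function(v) {
  n <- nrow(v)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt((v[j, 1] - v[, 1])^2 + (v[j, 2] - v[, 2])^2))
}

#' Extract outer contours of foreground components
#'
#' Labels 8-connected components, filters them by pixel area (and
#' optionally discards components touching the image border — the rule
#' that keeps the connected background of a negatively defocused frame
#' out of the cell count), then traces each survivor's outer boundary.
#'
#' @param mask logical matrix (`TRUE` = foreground).
#' @param min_area minimum component pixel count.
#' @param exclude_border drop components touching the frame edge.
#' @return list of `contour` objects (fields `vertices` — n x 2 matrix of
#'   0-based (row, col) pixel centres, `area` — shoelace polygon area,
#'   `npix` — component pixel count, `perimeter`, `centroid` — pixel-mask
#'   centroid), ordered by decreasing pixel area.
#' @export
extract_contours <- function(mask, min_area = 30, exclude_border = TRUE) {
  stopifnot(is.matrix(mask), is.logical(mask))
  labels <- label_components(mask, 8L)
  st <- component_stats(labels)
  if (!nrow(st)) return(list())
  keep <- st$npix >= min_area
  if (exclude_border)
    keep <- keep & st$rmin > 1 & st$cmin > 1 &
      st$rmax < nrow(mask) & st$cmax < ncol(mask)
  st <- st[keep, , drop = FALSE]
  if (!nrow(st)) return(list())
  st <- st[order(-st$npix), , drop = FALSE]
  out <- vector("list", nrow(st))
  ok <- logical(nrow(st))
  for (i in seq_len(nrow(st))) {
    l <- st$label[i]
    sub <- labels == l
    # topmost row of the component, then leftmost pixel in it
    start_row <- st$rmin[i]
    start_col <- which(sub[start_row, ])[1]
    v <- trace_boundary(sub, c(start_row, start_col))
    if (nrow(v) < 3L) next
    ok[i] <- TRUE
    out[[i]] <- structure(list(
      vertices = v,
      area = shoelace_area(v),
      npix = st$npix[i],
      perimeter = polyline_perimeter(v),
      centroid = c(st$crow[i], st$ccol[i])
    ), class = "contour")
  }
  out[ok]
}

#' Centroids of contours (penetration sites)
#'
#' Centroid of the filled polygon from the standard polygon area moments;
#' contours with (near-)zero polygon area fall back to their pixel-mask
#' centroid when available, otherwise they are skipped with a warning.
#'
#' @param contours list of `contour` objects.
#' @return n x 2 matrix of 0-based (row, col) site coordinates.
#' @export
penetration_sites <- function(contours) {
  out <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  for (ct in contours) {
    v <- ct$vertices
    n <- nrow(v)
    j <- c(2:n, 1L)
    x <- v[, 2]; y <- v[, 1]
    cr <- x * y[j] - x[j] * y
    a <- sum(cr) / 2
    if (abs(a) < 1e-9) {
      if (!is.null(ct$centroid)) out <- rbind(out, ct$centroid)
      else warning("zero-area contour skipped")
      next
    }
    cx <- sum((x + x[j]) * cr) / (6 * a)
    cy <- sum((y + y[j]) * cr) / (6 * a)
    out <- rbind(out, c(cy, cx))
  }
  rownames(out) <- NULL
  out
}

#' Detect adherent cells in a defocused frame
#'
#' Full segmentation chain: Gaussian blur, grayscale conversion, hybrid
#' triangle/Otsu binarization, morphological closing, inversion, outer
#' contour extraction and centroid identification. The number of
#' extracted contours is the NOCC focus measure.
#'
#' @param img gray matrix (or RGB array; converted by luminance).
#' @param sigma blur SD in pixels.
#' @param se_radius closing-disk radius in pixels.
#' @param min_area minimum component pixel area.
#' @param exclude_border drop components touching the frame edge.
#' @return object of class `detection_result`: `contours`, `sites`
#'   (n x 2 matrix), `nocc`, `thresholds` (list with `t_otsu`, `t_peak`,
#'   `branch`, `threshold`).
#' @export
detect_cells <- function(img, sigma = 2, se_radius = 2, min_area = 30,
                         exclude_border = TRUE) {
  img <- as_gray(img)
  blurred <- gaussian_blur(img, sigma)
  bin <- tryCatch(hybrid_binarize(blurred), error = function(e) NULL)
  if (is.null(bin)) {
    # degenerate (constant) frame: nothing to segment
    return(structure(list(contours = list(),
                          sites = matrix(numeric(0), 0, 2),
                          nocc = 0L,
                          thresholds = list(t_otsu = NA_integer_,
                                            t_peak = NA_integer_,
                                            branch = "degenerate",
                                            threshold = NA_integer_)),
                     class = "detection_result"))
  }
  closed <- morph_close(bin$mask, se_radius)
  inv <- !closed
  contours <- extract_contours(inv, min_area = min_area,
                               exclude_border = exclude_border)
  structure(list(contours = contours,
                 sites = penetration_sites(contours),
                 nocc = length(contours),
                 thresholds = bin[c("t_otsu", "t_peak", "branch", "threshold")]),
            class = "detection_result")
}

#' Number of cell contours (NOCC) focus measure
#'
#' @inheritParams detect_cells
#' @param ... passed to [detect_cells()].
#' @return integer contour count.
#' @export
nocc <- function(img, ...) {
  detect_cells(img, ...)$nocc
}

#' @export
print.detection_result <- function(x, ...) {
  cat("cell detection: NOCC =", x$nocc,
      "| branch =", x$thresholds$branch, "\n")
  if (x$nocc > 0) {
    cat(sprintf("  thresholds: T_otsu = %s, T_peak = %s, applied = %s\n",
                x$thresholds$t_otsu, x$thresholds$t_peak,
                x$thresholds$threshold))
  }
  invisible(x)
}
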