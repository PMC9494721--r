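# Pipette-tip localisation: gamma enhancement, Otsu binarization,
# closing, inversion, longest-contour extraction, polygon simplification
# and a triangle test. The sharp vertex of the fitted triangle is the tip.

#' Gamma transformation
#'
#' `out = round(255 * (in / 255)^gamma)`. Exponents below 1 brighten the
#' midtones, lifting the faint silhouette of a defocused tip out of the
#' background.
#'
#' @param img gray matrix.
#' @param gamma positive exponent.
#' @return transformed gray matrix.
#' @export
gamma_transform <- function(img, gamma = 0.6) {
  assert_gray(img)
  if (!is.numeric(gamma) || gamma <= 0)
    stop("`gamma` must be positive", call. = FALSE)
  quantize8(255 * (img / 255)^gamma)
}

#' Longest contour
#'
#' @param contours nonempty list of `contour` objects.
#' @return the contour with maximal perimeter; ties resolve to the larger
#'   polygon area.
#' @export
longest_contour <- function(contours) {
  if (length(contours) == 0L) stop("no contours found", call. = FALSE)
  per <- vapply(contours, function(ct) ct$perimeter, numeric(1))
  area <- vapply(contours, function(ct) ct$area, numeric(1))
  best <- which(per == max(per))
  if (length(best) > 1L) best <- best[which.max(area[best])]
  contours[[best]]
}

#' Simplify a closed contour (Ramer-Douglas-Peucker)
#'
#' Closed-curve variant: the two mutually farthest vertices split the
#' ring into two chains, each simplified with tolerance
#' `epsilon_frac * perimeter`. Output vertices are a subset of the input
#' vertices.
#'
#' @param contour a `contour` object (or an n x 2 vertex matrix).
#' @param epsilon_frac tolerance as a fraction of the contour perimeter.
#' @return m x 2 matrix of simplified polygon vertices (closed, first
#'   vertex not repeated).
#' @export
fit_polygon <- function(contour, epsilon_frac = 0.02) {
  if (epsilon_frac <= 0) stop("`epsilon_frac` must be positive", call. = FALSE)
  v <- if (inherits(contour, "contour")) contour$vertices else contour
  v <- matrix(as.numeric(v), nrow(v), 2L)
  n <- nrow(v)
  if (n <= 3L) return(v)
  eps <- epsilon_frac * polyline_perimeter(v)
  # split at the two mutually farthest vertices (O(n^2), contours are short)
  dmat <- as.matrix(stats::dist(v))
  far <- arrayInd(which.max(dmat), dim(dmat))
  i1 <- min(far); i2 <- max(far)
  chain1 <- v[i1:i2, , drop = FALSE]
  chain2 <- v[c(i2:n, 1:i1), , drop = FALSE]
  s1 <- rdp_chain(chain1, eps)
  s2 <- rdp_chain(chain2, eps)
  # merge, dropping the duplicated split vertices
  out <- rbind(s1, s2[-1, , drop = FALSE])
  out[-nrow(out), , drop = FALSE]
}

# iterative RDP on an open chain (explicit stack; avoids deep recursion)
rdp_chain <- function(pts, eps) {
  n <- nrow(pts)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len <- sqrt(sum(ab^2))
    ids <- (i + 1L):(j - 1L)
    if (len == 0) {
      d <- sqrt((pts[ids, 1] - a[1])^2 + (pts[ids, 2] - a[2])^2)
    } else {
      d <- abs((pts[ids, 1] - a[1]) * ab[2] - (pts[ids, 2] - a[2]) * ab[1]) / len
    }
    k <- ids[which.max(d)]
    if (max(d) > eps) {
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  pts[keep, , drop = FALSE]
}

# Interior angles (radians) of a polygon given as n x 2 vertices.
interior_angles <- function(poly) {
  n <- nrow(poly)
  vapply(seq_len(n), function(i) {
    p <- poly[i, ]
    a <- poly[if (i == 1L) n else i - 1L, ]
    b <- poly[if (i == n) 1L else i + 1L, ]
    u <- a - p; w <- b - p
    cosang <- sum(u * w) / (sqrt(sum(u^2)) * sqrt(sum(w^2)))
    acos(pmin(pmax(cosang, -1), 1))
  }, numeric(1))
}

#' Locate the pipette tip in a frame
#'
#' Chain: gamma transform, Otsu binarization, morphological closing,
#' inversion (the tip is darker than the background), outer contours,
#' longest contour, closed-curve polygon simplification. Detection
#' succeeds when the simplified polygon has exactly 3 vertices and covers
#' at least `min_area_ratio` of the traced contour's polygon area (the
#' latter rejects degenerate 3-vertex fits). The apex is the vertex with
#' the smallest interior angle.
#'
#' @param img gray matrix.
#' @param gamma gamma-transform exponent.
#' @param se_radius closing-disk radius, pixels.
#' @param min_area minimum component pixel area.
#' @param epsilon_frac RDP tolerance as a fraction of contour perimeter.
#' @param min_area_ratio minimal fitted-polygon / contour-polygon area
#'   ratio for a valid triangle.
#' @param roi optional `(rmin, rmax, cmin, cmax)` 0-based window to
#'   restrict the search (coordinates in the full frame).
#' @return object of class `tip_detection`: `detected`, `apex`
#'   (0-based row/col, `NA` when not detected), `polygon`,
#'   `contour_length`.
#' @export
locate_tip <- function(img, gamma = 0.6, se_radius = 1, min_area = 30,
                       epsilon_frac = 0.03, min_area_ratio = 0.8,
                       roi = NULL) {
  img <- as_gray(img)
  offset <- c(0, 0)
  if (!is.null(roi)) {
    roi <- round(roi)
    rmin <- max(0, roi[1]); rmax <- min(nrow(img) - 1, roi[2])
    cmin <- max(0, roi[3]); cmax <- min(ncol(img) - 1, roi[4])
    img <- img[(rmin + 1):(rmax + 1), (cmin + 1):(cmax + 1), drop = FALSE]
    offset <- c(rmin, cmin)
  }
  not_found <- structure(list(detected = FALSE, apex = c(NA_real_, NA_real_),
                              polygon = NULL, contour_length = 0),
                         class = "tip_detection")
  g <- gamma_transform(img, gamma)
  thr <- tryCatch(otsu_threshold(g), error = function(e) NULL)
  if (is.null(thr)) return(not_found)
  mask <- g > thr                       # background bright -> TRUE
  closed <- morph_close(mask, se_radius)
  contours <- extract_contours(!closed, min_area = min_area,
                               exclude_border = FALSE)
  if (length(contours) == 0L) return(not_found)
  ct <- longest_contour(contours)
  poly <- fit_polygon(ct, epsilon_frac)
  ok <- nrow(poly) == 3L &&
    ct$area > 0 && shoelace_area(poly) / ct$area >= min_area_ratio
  if (!ok) {
    not_found$contour_length <- ct$perimeter
    return(not_found)
  }
  apex <- poly[which.min(interior_angles(poly)), ] + offset
  structure(list(detected = TRUE, apex = as.numeric(apex),
                 polygon = poly + matrix(offset, nrow(poly), 2, byrow = TRUE),
                 contour_length = ct$perimeter),
            class = "tip_detection")
}

#' @export
print.tip_detection <- function(x, ...) {
  if (x$detected)
    cat(sprintf("tip detected at (row = %.1f, col = %.1f)\n",
                x$apex[1], x$apex[2]))
  else cat("tip not detected\n")
  invisible(x)
}
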