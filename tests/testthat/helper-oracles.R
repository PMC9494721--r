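# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (loops, enumeration) and share no code
# with the implementation paths they check.

# Brute-force Otsu: exhaustive between-class variance over all 256
# candidate thresholds, computed directly from pixel values.
oracle_otsu <- function(img) {
  v <- as.vector(round(img))
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v)
    s <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

# Brute-force histogram mode with smallest-level ties.
oracle_mode <- function(img) {
  v <- as.vector(round(img))
  counts <- sapply(0:255, function(g) sum(v == g))
  (0:255)[which.max(counts)]
}

# Brute-force triangle threshold: perpendicular point-line distance
# evaluated for every interior bin.
oracle_triangle <- function(img, toward) {
  h <- sapply(0:255, function(g) sum(round(img) == g))
  peak <- which.max(h)
  nz <- which(h > 0)
  end <- if (toward == "brighter_end") max(nz) else min(nz)
  rng <- if (end > peak) (peak + 1):(end - 1) else (end + 1):(peak - 1)
  p1 <- c(peak, h[peak]); p2 <- c(end, h[end])
  seg <- p2 - p1
  dist <- sapply(rng, function(b) {
    abs(seg[2] * (b - p1[1]) - seg[1] * (h[b] - p1[2])) / sqrt(sum(seg^2))
  })
  rng[which.max(dist)] - 1L
}

# Flood-fill connected-component count (8-connectivity), queue-based.
oracle_component_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0L
  for (idx in which(mask & !seen)) {
    if (seen[idx]) next
    count <- count + 1L
    queue <- idx
    seen[idx] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      r <- (cur - 1L) %% nr + 1L
      c_ <- (cur - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c_ + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          queue <- c(queue, (cc - 1L) * nr + rr)
        }
      }
    }
  }
  count
}

# Quadruple-loop zero-mean NCC (direct transcription of the definition).
oracle_ncc <- function(img, tmpl) {
  h <- nrow(tmpl); w <- ncol(tmpl)
  nr <- nrow(img) - h + 1L
  nc <- ncol(img) - w + 1L
  out <- matrix(0, nr, nc)
  tbar <- mean(tmpl)
  for (y in seq_len(nr)) {
    for (x in seq_len(nc)) {
      num <- 0; st2 <- 0; si2 <- 0
      win <- img[y:(y + h - 1L), x:(x + w - 1L)]
      ibar <- mean(win)
      for (yy in seq_len(h)) {
        for (xx in seq_len(w)) {
          tv <- tmpl[yy, xx] - tbar
          iv <- win[yy, xx] - ibar
          num <- num + tv * iv
          st2 <- st2 + tv^2
          si2 <- si2 + iv^2
        }
      }
      out[y, x] <- if (st2 > 0 && si2 > 0) num / sqrt(st2 * si2) else 0
    }
  }
  out
}

# --- fixture builders -------------------------------------------------

# Filled-disk mask centred at (r0, c0) (1-based), radius rad.
disk_mask <- function(shape, r0, c0, rad) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= rad^2
}

# Gray image from an explicit histogram specification (levels, counts),
# shaped into a near-square matrix.
image_from_histogram <- function(levels, counts) {
  v <- rep(levels, counts)
  n <- length(v)
  nc <- ceiling(sqrt(n))
  nr <- ceiling(n / nc)
  m <- matrix(v[1], nr, nc)
  m[seq_len(n)] <- v
  m
}

# Deterministic integer-valued random gray image.
random_gray <- function(shape, seed, lo = 0, hi = 255) {
  set.seed(seed)
  matrix(as.numeric(sample(lo:hi, prod(shape), replace = TRUE)),
         shape[1], shape[2])
}

# Standard small cell scene used by several suites.
std_scene <- function(n = 12, shape = c(220L, 220L), seed = 3,
                      noise_sigma = 2, ...) {
  random_scene(n, image_shape = shape, seed = seed,
               noise_sigma = noise_sigma, ...)
}

std_tip <- function() tip_phantom(c(60, 120))
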