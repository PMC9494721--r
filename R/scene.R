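# Synthetic-scene generator: transparent adherent-cell phantoms rendered
# under defocus, opaque pipette-tip renders, and ground-truth bookkeeping.
#
# The optical model is the thin transparent-object contrast law
#   I(p) = I0 * (1 + df * dn * lap(h)(p)),
# with df the signed defocus distance (um), dn the refractive-index
# difference between cell and medium, and h the cell thickness field (um).
# Contrast therefore scales linearly with defocus, index contrast and
# thickness curvature, and vanishes exactly in focus.

#' Create an adherent-cell phantom
#'
#' A phantom is an elliptical thickness profile with compact support.
#' The `ellipsoid` profile is `h_max * sqrt(max(0, 1 - (x/a)^2 - (y/b)^2))`,
#' the `paraboloid` profile `h_max * max(0, 1 - (x/a)^2 - (y/b)^2)`,
#' with (x, y) the pixel offsets from `center` in column/row direction.
#'
#' @param center numeric `(row, col)` pixel coordinates (0-based).
#' @param semi_axes numeric `(a, b)` semi-axes in pixels (`a` along
#'   columns, `b` along rows); both positive.
#' @param h_max peak thickness in micrometers.
#' @param delta_n refractive-index difference between cell and medium.
#' @param profile `"ellipsoid"` (continuous at the support boundary)
#'   or `"paraboloid"` (constant interior Laplacian).
#' @return object of class `cell_phantom`.
#' @export
cell_phantom <- function(center, semi_axes, h_max, delta_n = 0.035,
                         profile = c("ellipsoid", "paraboloid")) {
  profile <- match.arg(profile)
  if (length(center) != 2L || !is.numeric(center))
    stop("`center` must be numeric (row, col)", call. = FALSE)
  if (length(semi_axes) != 2L || any(semi_axes <= 0))
    stop("invalid phantom: semi-axes must be positive", call. = FALSE)
  if (h_max <= 0) stop("invalid phantom: h_max must be positive", call. = FALSE)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 h_max = as.numeric(h_max),
                 delta_n = as.numeric(delta_n),
                 profile = profile),
            class = "cell_phantom")
}

#' Evaluate the thickness field of a phantom on a pixel grid
#'
#' @param phantom a [cell_phantom()].
#' @param shape integer `(rows, cols)` of the target raster.
#' @return numeric matrix of thicknesses in micrometers, zero outside the
#'   support ellipse.
#' @export
thickness_field <- function(phantom, shape) {
  stopifnot(inherits(phantom, "cell_phantom"))
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape <= 0))
    stop("`shape` must be two positive integers", call. = FALSE)
  rows <- seq_len(shape[1]) - 1
  cols <- seq_len(shape[2]) - 1
  dy <- (rows - phantom$center[1]) / phantom$semi_axes[2]
  dx <- (cols - phantom$center[2]) / phantom$semi_axes[1]
  q <- pmax(1 - outer(dy^2, dx^2, `+`), 0)
  if (phantom$profile == "ellipsoid") phantom$h_max * sqrt(q)
  else phantom$h_max * q
}

#' Assemble a renderable scene of cell phantoms
#'
#' @param phantoms list of [cell_phantom()] objects (possibly empty).
#' @param image_shape integer `(rows, cols)` of rendered frames.
#' @param background_intensity background gray level `I0`, strictly
#'   inside `(0, 255)`.
#' @param pixel_size micrometers per pixel.
#' @param noise_sigma additive Gaussian camera-noise SD in gray levels.
#' @param rng_seed integer seed; identical `(scene, defocus)` pairs
#'   render bit-identically.
#' @param edge_softness Gaussian smoothing (in micrometers) applied to the
#'   summed thickness field before differentiation, emulating the feathered
#'   margin of adherent cells. Without it the hard support edge of the
#'   analytic profiles produces an unphysically strong contrast ring.
#' @param allow_overlap if `FALSE` (default), overlapping phantom supports
#'   raise an error.
#' @return object of class `cell_scene`.
#' @export
cell_scene <- function(phantoms = list(), image_shape = c(256L, 256L),
                       background_intensity = 150, pixel_size = 1,
                       noise_sigma = 0, rng_seed = 1L,
                       edge_softness = 2, allow_overlap = FALSE) {
  stopifnot(all(vapply(phantoms, inherits, TRUE, "cell_phantom")))
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape <= 0))
    stop("`image_shape` must be two positive integers", call. = FALSE)
  if (background_intensity <= 0 || background_intensity >= 255)
    stop("`background_intensity` must lie strictly inside (0, 255)", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be positive", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be nonnegative", call. = FALSE)
  sc <- structure(list(phantoms = phantoms,
                       image_shape = image_shape,
                       background_intensity = as.numeric(background_intensity),
                       pixel_size = as.numeric(pixel_size),
                       noise_sigma = as.numeric(noise_sigma),
                       rng_seed = as.integer(rng_seed),
                       edge_softness = as.numeric(edge_softness)),
                  class = "cell_scene")
  if (!allow_overlap && length(phantoms) > 1L) {
    cover <- matrix(0L, image_shape[1], image_shape[2])
    for (ph in phantoms) cover <- cover + (thickness_field(ph, image_shape) > 0)
    if (any(cover > 1L))
      stop("phantom supports overlap; pass allow_overlap = TRUE to permit this",
           call. = FALSE)
  }
  sc
}

# Defocus contrast field C(p) = df * sum_i dn_i * lap(h_i)(p), dimensionless.
# Laplacian spacing is physical (pixel_size), so um inputs cancel exactly.
contrast_field <- function(scene, delta_f) {
  stopifnot(inherits(scene, "cell_scene"))
  shape <- scene$image_shape
  acc <- matrix(0, shape[1], shape[2])
  sig_px <- scene$edge_softness / scene$pixel_size
  for (ph in scene$phantoms) {
    h <- thickness_field(ph, shape)
    if (sig_px > 0) h <- smooth_gaussian(h, sig_px)
    acc <- acc + ph$delta_n * laplacian5(h, spacing = scene$pixel_size)
  }
  delta_f * acc
}

#' Render a defocused scene image
#'
#' Applies the linear defocus-contrast model, adds seeded Gaussian camera
#' noise, then rounds and clips to 8-bit gray levels. Positive defocus is
#' the side on which cell interiors darken relative to the background.
#'
#' @param scene a [cell_scene()].
#' @param delta_f signed defocus distance in micrometers.
#' @param plane_seed optional integer overriding the scene seed for this
#'   plane (used by [render_zstack()]).
#' @return gray matrix, `attr(, "pixel_size")` set from the scene.
#' @export
render_cell_image <- function(scene, delta_f, plane_seed = NULL) {
  stopifnot(inherits(scene, "cell_scene"))
  img <- scene$background_intensity * (1 + contrast_field(scene, delta_f))
  if (scene$noise_sigma > 0) {
    seed <- if (is.null(plane_seed)) scene$rng_seed else plane_seed
    img <- img + with_seed(seed,
      matrix(stats::rnorm(length(img), 0, scene$noise_sigma),
             nrow(img), ncol(img)))
  }
  out <- quantize8(img)
  attr(out, "pixel_size") <- scene$pixel_size
  out
}

#' Render a defocus series (z-stack)
#'
#' One frame per requested defocus, each with an independent noise
#' realisation derived deterministically from the scene seed and the
#' plane index.
#'
#' @param scene a [cell_scene()].
#' @param z_list strictly monotone numeric defocus values (micrometers).
#' @return list of gray matrices, named by `z_list`.
#' @export
render_zstack <- function(scene, z_list) {
  if (length(z_list) == 0L) stop("`z_list` must be nonempty", call. = FALSE)
  d <- diff(z_list)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("`z_list` must be strictly monotone", call. = FALSE)
  out <- lapply(seq_along(z_list), function(i)
    render_cell_image(scene, z_list[i],
                      plane_seed = derive_seed(scene$rng_seed, i)))
  names(out) <- as.character(z_list)
  out
}

#' Extract per-phantom ground truth from a scene
#'
#' The nucleus mask of each phantom is its analytic support
#' (`thickness_field > 0`); the centroid is the phantom centre.
#'
#' @param scene a [cell_scene()].
#' @return object of class `ground_truth` with elements `masks` (list of
#'   logical matrices), `centroids` (n x 2 matrix, 0-based row/col),
#'   `cell_count`, and `labels` (integer raster, 0 = background, later
#'   phantoms win where supports overlap).
#' @export
make_ground_truth <- function(scene) {
  stopifnot(inherits(scene, "cell_scene"))
  shape <- scene$image_shape
  masks <- lapply(scene$phantoms, function(ph)
    thickness_field(ph, shape) > 0)
  labels <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(masks)) labels[masks[[i]]] <- i
  centroids <- if (length(masks))
    do.call(rbind, lapply(scene$phantoms, function(ph) ph$center))
  else matrix(numeric(0), 0, 2)
  colnames(centroids) <- c("row", "col")
  structure(list(masks = masks, centroids = centroids,
                 cell_count = length(masks), labels = labels),
            class = "ground_truth")
}

#' Create a pipette-tip phantom
#'
#' An opaque triangular silhouette: apex at `apex`, body extending along
#' `orientation` with the given half-angle and length. Away from the focal
#' plane the render is Gaussian-blurred and its contrast attenuated so
#' that the tip eventually vanishes into the background, emulating the
#' empirical detectability limit of a defocused pipette (about 110 um).
#'
#' @param apex `(row, col)` apex coordinates in pixels (0-based).
#' @param half_angle tip half-angle in degrees, in (0, 90).
#' @param orientation direction from apex into the body, degrees
#'   (0 = +col, 90 = +row).
#' @param length body length in pixels.
#' @param opacity gray-level depression at focus (0, 255].
#' @param z_focus stage position of best focus, micrometers.
#' @param sigma0 blur SD (pixels) at focus.
#' @param blur_gain blur SD increase per micrometer of defocus.
#' @param detect_limit defocus (micrometers) at which the silhouette
#'   contrast reaches zero (linear attenuation).
#' @return object of class `tip_phantom`.
#' @export
tip_phantom <- function(apex, half_angle = 22, orientation = 90,
                        length = 120, opacity = 120, z_focus = 0,
                        sigma0 = 0.5, blur_gain = 0.04, detect_limit = 110) {
  if (half_angle <= 0 || half_angle >= 90)
    stop("`half_angle` must lie in (0, 90) degrees", call. = FALSE)
  if (length <= 0 || opacity <= 0)
    stop("`length` and `opacity` must be positive", call. = FALSE)
  structure(list(apex = as.numeric(apex), half_angle = as.numeric(half_angle),
                 orientation = as.numeric(orientation),
                 length = as.numeric(length), opacity = as.numeric(opacity),
                 z_focus = as.numeric(z_focus), sigma0 = as.numeric(sigma0),
                 blur_gain = as.numeric(blur_gain),
                 detect_limit = as.numeric(detect_limit)),
            class = "tip_phantom")
}

# Filled-triangle indicator of the tip silhouette on the pixel grid.
tip_mask <- function(tip, shape) {
  th <- tip$orientation * pi / 180
  u <- c(sin(th), cos(th))              # (row, col) body direction
  v <- c(cos(th), -sin(th))             # perpendicular
  a <- tip$apex
  base <- a + tip$length * u
  hw <- tip$length * tan(tip$half_angle * pi / 180)
  p1 <- base + hw * v
  p2 <- base - hw * v
  rows <- seq_len(shape[1]) - 1
  cols <- seq_len(shape[2]) - 1
  R <- matrix(rows, shape[1], shape[2])
  C <- matrix(cols, shape[1], shape[2], byrow = TRUE)
  edge <- function(pa, pb) {
    (C - pa[2]) * (pb[1] - pa[1]) - (R - pa[1]) * (pb[2] - pa[2])
  }
  e1 <- edge(a, p1); e2 <- edge(p1, p2); e3 <- edge(p2, a)
  (e1 >= 0 & e2 >= 0 & e3 >= 0) | (e1 <= 0 & e2 <= 0 & e3 <= 0)
}

#' Render the pipette tip at a stage position
#'
#' @param tip a [tip_phantom()].
#' @param z stage position, micrometers.
#' @param shape `(rows, cols)` of the frame.
#' @param background background gray level `I0`.
#' @param noise_sigma Gaussian noise SD in gray levels.
#' @param seed integer noise seed.
#' @return gray matrix.
#' @export
render_tip_image <- function(tip, z, shape = c(240L, 240L),
                             background = 180, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(tip, "tip_phantom"))
  shape <- as.integer(shape)
  if (any(shape <= 0)) stop("`shape` must be positive", call. = FALSE)
  dz <- abs(z - tip$z_focus)
  atten <- max(0, 1 - dz / tip$detect_limit)
  img <- matrix(background, shape[1], shape[2])
  if (atten > 0) {
    depth <- tip$opacity * atten * tip_mask(tip, shape)
    sigma <- tip$sigma0 + tip$blur_gain * dz
    if (sigma > 0) depth <- smooth_gaussian(depth, sigma)
    img <- img - depth
  }
  if (noise_sigma > 0)
    img <- img + with_seed(seed,
      matrix(stats::rnorm(length(img), 0, noise_sigma), shape[1], shape[2]))
  quantize8(img)
}

#' Generate a random scene of well-separated phantoms
#'
#' Rejection-samples phantom centres so that support ellipses (padded by
#' `margin` pixels) do not overlap and stay inside the frame.
#'
#' @param n_cells number of phantoms.
#' @param image_shape frame dimensions `(rows, cols)`.
#' @param seed integer seed controlling both placement and render noise.
#' @param semi_axis_range range of sampled semi-axes, pixels.
#' @param h_max_range range of sampled peak thicknesses, micrometers.
#' @param delta_n refractive-index difference used for all phantoms.
#' @param profile thickness profile for all phantoms.
#' @param margin minimum support-to-support separation, pixels.
#' @param ... passed to [cell_scene()] (e.g. `noise_sigma`,
#'   `background_intensity`).
#' @return a [cell_scene()].
#' @export
random_scene <- function(n_cells, image_shape = c(256L, 256L), seed = 1L,
                         semi_axis_range = c(10, 16), h_max_range = c(3, 5),
                         delta_n = 0.035, profile = "ellipsoid",
                         margin = 10, ...) {
  image_shape <- as.integer(image_shape)
  phantoms <- with_seed(derive_seed(seed, 0L), {
    placed <- list()
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    tries <- 0L
    while (length(placed) < n_cells && tries < 4000L) {
      tries <- tries + 1L
      ax <- stats::runif(2, semi_axis_range[1], semi_axis_range[2])
      r <- max(ax)
      ctr <- c(stats::runif(1, r + margin, image_shape[1] - 1 - r - margin),
               stats::runif(1, r + margin, image_shape[2] - 1 - r - margin))
      if (nrow(centers)) {
        d <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
        if (any(d < radii + r + margin)) next
      }
      placed[[length(placed) + 1L]] <-
        cell_phantom(ctr, ax, stats::runif(1, h_max_range[1], h_max_range[2]),
                     delta_n = delta_n, profile = profile)
      centers <- rbind(centers, ctr)
      radii <- c(radii, r)
    }
    if (length(placed) < n_cells)
      stop("could not place ", n_cells, " non-overlapping phantoms; ",
           "enlarge the frame or shrink the cells", call. = FALSE)
    placed
  })
  cell_scene(phantoms, image_shape = image_shape, rng_seed = seed, ...)
}
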