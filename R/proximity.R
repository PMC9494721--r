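# Ion-current proximity detection. Near a surface the pipette orifice is
# progressively occluded and the access resistance rises, pulling the
# current below its steady-state value:
#   I(d) = I_inf / (1 + c / d),   c = (3/2) ln(r_o / r_i) r_i r_e / h_p,
# where d is the tip-surface distance. The surface is declared when the
# (smoothed) current drops a set fraction below the far-field baseline.

#' Pipette tip/base geometry
#'
#' @param r_i internal tip radius, meters.
#' @param r_o outer tip radius, meters (`> r_i`).
#' @param r_e internal base radius, meters (`>= r_i`).
#' @param h_p pipette height, meters.
#' @return object of class `pipette_geometry`.
#' @export
pipette_geometry <- function(r_i = 50e-9, r_o = 80e-9, r_e = 0.5e-3,
                             h_p = 5e-3) {
  if (!(r_i > 0 && r_o > r_i)) stop("need 0 < r_i < r_o", call. = FALSE)
  if (r_e < r_i) stop("need r_e >= r_i", call. = FALSE)
  if (h_p <= 0) stop("need h_p > 0", call. = FALSE)
  structure(list(r_i = r_i, r_o = r_o, r_e = r_e, h_p = h_p),
            class = "pipette_geometry")
}

#' Approach-curve model
#'
#' Bundles the geometry with the steady-state current `I_inf` (the
#' current far from any surface, set by the pipette resistance alone;
#' `I_inf = U / R_p` for applied potential `U`, which may be recorded for
#' reference but is not used in the computation). The derived length
#' constant `c` is the distance at which the current halves.
#'
#' @param geometry a [pipette_geometry()].
#' @param I_inf steady-state current, amperes.
#' @param U applied potential, volts (informational).
#' @return object of class `approach_model` with the derived constant `c`.
#' @export
approach_model <- function(geometry = pipette_geometry(), I_inf = 1e-9,
                           U = NULL) {
  stopifnot(inherits(geometry, "pipette_geometry"))
  if (I_inf <= 0) stop("`I_inf` must be positive", call. = FALSE)
  cc <- 1.5 * log(geometry$r_o / geometry$r_i) *
    geometry$r_i * geometry$r_e / geometry$h_p
  structure(list(geometry = geometry, I_inf = I_inf, U = U, c = cc),
            class = "approach_model")
}

#' Distance-dependent ion current
#'
#' @param d tip-surface distance(s), meters, strictly positive.
#' @param model an [approach_model()].
#' @return current(s) in amperes; strictly increasing in `d`, bounded by
#'   `I_inf`.
#' @export
ion_current <- function(d, model) {
  stopifnot(inherits(model, "approach_model"))
  if (any(d <= 0)) stop("`d` must be positive", call. = FALSE)
  model$I_inf / (1 + model$c / d)
}

#' Analytic stop distance for a relative current drop
#'
#' Distance at which `I = (1 - p) * I_inf`: `d* = c (1 - p) / p`.
#'
#' @param model an [approach_model()].
#' @param p drop fraction in (0, 1), e.g. `0.02` for a 2 % reduction.
#' @return stop distance in meters.
#' @export
stop_distance <- function(model, p = 0.02) {
  stopifnot(inherits(model, "approach_model"))
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)", call. = FALSE)
  model$c * (1 - p) / p
}

#' Simulate a noisy approach trace
#'
#' @param model an [approach_model()].
#' @param distances strictly decreasing tip-surface distances, meters.
#' @param noise_sigma additive Gaussian current noise SD, amperes.
#' @param seed integer seed.
#' @return object of class `approach_trace`: `distance`, `current`,
#'   `noise_sigma`, `seed`.
#' @export
simulate_approach <- function(model, distances, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(model, "approach_model"))
  if (length(distances) < 2L || any(diff(distances) >= 0))
    stop("`distances` must be strictly decreasing", call. = FALSE)
  cur <- ion_current(distances, model)
  if (noise_sigma > 0)
    cur <- cur + with_seed(seed, stats::rnorm(length(cur), 0, noise_sigma))
  structure(list(distance = as.numeric(distances), current = as.numeric(cur),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "approach_trace")
}

#' Detect the surface from an approach trace
#'
#' Estimates the far-field baseline as the median of the first
#' `baseline_n` samples, smooths the current with a centred moving median
#' of width `smooth_w` (odd), and declares the surface at the first index
#' where `confirm_m` consecutive smoothed samples fall at or below
#' `(1 - p) * baseline`.
#'
#' @param trace an [approach_trace()] (or a list with `distance` and
#'   `current`).
#' @param p relative current-drop threshold in (0, 1).
#' @param baseline_n samples used for the baseline estimate.
#' @param smooth_w moving-median window (odd, `>= 1`).
#' @param confirm_m consecutive below-threshold samples required.
#' @return list with `detected`, `index`, `position` (distance at the
#'   detection index, `NA` when not detected), `baseline`, `threshold`.
#' @export
detect_surface <- function(trace, p = 0.02, baseline_n = 20L,
                           smooth_w = 5L, confirm_m = 3L) {
  if (p <= 0 || p >= 1) stop("`p` must lie in (0, 1)", call. = FALSE)
  cur <- trace$current
  n <- length(cur)
  if (n <= baseline_n + confirm_m)
    stop("trace too short for baseline + confirmation", call. = FALSE)
  smooth_w <- as.integer(smooth_w)
  if (smooth_w %% 2L == 0L) smooth_w <- smooth_w + 1L
  baseline <- stats::median(cur[seq_len(baseline_n)])
  sm <- if (smooth_w > 1L) stats::runmed(cur, smooth_w, endrule = "median")
        else cur
  thr <- (1 - p) * baseline
  below <- sm <= thr
  # first index starting a run of confirm_m below-threshold samples
  run <- 0L
  hit <- NA_integer_
  for (i in seq_len(n)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= confirm_m) { hit <- i - confirm_m + 1L; break }
  }
  if (is.na(hit))
    return(list(detected = FALSE, index = NA_integer_, position = NA_real_,
                baseline = baseline, threshold = thr))
  list(detected = TRUE, index = hit, position = trace$distance[hit],
       baseline = baseline, threshold = thr)
}
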