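# Experiment orchestration: cell focusing and detection, penetration
# path planning, tip autofocus, per-site approach with ion-current
# feedback, evaluation and report output. Stage order is fixed: focus
# cells -> detect -> plan path -> autofocus tip -> approach each site.

#' Plan the penetration path through detected sites
#'
#' Nearest-neighbour tour from `start`; `nn_2opt` additionally applies
#' 2-opt swaps until no improvement remains. Ties resolve to the lowest
#' site index. Total length includes the leg from `start` to the first
#' site.
#'
#' @param sites n x 2 matrix of (row, col) sites.
#' @param start length-2 starting point.
#' @param method `"nearest_neighbor"` or `"nn_2opt"`.
#' @return object of class `penetration_plan`: `order` (site indices),
#'   `sites` (reordered), `start`, `total_length`, `method`.
#' @export
plan_path <- function(sites, start = c(0, 0),
                      method = c("nearest_neighbor", "nn_2opt")) {
  method <- match.arg(method)
  sites <- matrix(as.numeric(sites), ncol = 2)
  if (nrow(sites) == 0L) stop("`sites` must be nonempty", call. = FALSE)
  n <- nrow(sites)
  remaining <- seq_len(n)
  ord <- integer(0)
  cur <- as.numeric(start)
  while (length(remaining)) {
    d <- sqrt((sites[remaining, 1] - cur[1])^2 +
              (sites[remaining, 2] - cur[2])^2)
    pick <- remaining[which.min(d)]   # which.min takes the first = lowest index
    ord <- c(ord, pick)
    cur <- sites[pick, ]
    remaining <- setdiff(remaining, pick)
  }
  tour_length <- function(ord) {
    pts <- rbind(start, sites[ord, , drop = FALSE])
    sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                        pts[-nrow(pts), , drop = FALSE])^2)))
  }
  if (method == "nn_2opt" && n >= 3L) {
    improved <- TRUE
    best <- tour_length(ord)
    while (improved) {
      improved <- FALSE
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          cand <- ord
          cand[i:j] <- rev(cand[i:j])
          len <- tour_length(cand)
          if (len < best - 1e-12) {
            ord <- cand; best <- len; improved <- TRUE
          }
        }
      }
    }
  }
  structure(list(order = ord, sites = sites[ord, , drop = FALSE],
                 start = as.numeric(start), total_length = tour_length(ord),
                 method = method),
            class = "penetration_plan")
}

#' Default experiment configuration
#'
#' Returns a fully populated nested configuration list; supplied values
#' override defaults element-wise (one level deep per block).
#'
#' @param ... named blocks overriding defaults: `scene`, `zstack`,
#'   `detection`, `tip`, `autofocus`, `proximity`, `planner`, `seed`.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    seed = 1L,
    scene = list(n_cells = 20L, image_shape = c(320L, 320L),
                 background_intensity = 150, noise_sigma = 2,
                 pixel_size = 1, delta_n = 0.035, profile = "ellipsoid",
                 semi_axis_range = c(10, 16), h_max_range = c(3, 5),
                 margin = 10),
    zstack = list(z_min = -60, z_max = 60, step = 20),
    detection = list(sigma = 2, se_radius = 2, min_area = 30),
    tip = list(shape = c(240L, 240L), background = 180, apex = c(60, 120),
               half_angle = 22, orientation = 90, length = 120,
               opacity = 120, z_focus = 0, noise_sigma = 0,
               template_half_size = 30L, z_start = 105),
    autofocus = list(threshold = 0.92, step = 5),
    proximity = list(p = 0.02, baseline_n = 20L, smooth_w = 5L,
                     confirm_m = 3L, noise_frac = 0.002,
                     d_start_factor = 1e4, n_samples = 220L),
    planner = "nearest_neighbor"
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' The file holds any subset of the [experiment_config()] blocks;
#' missing entries take defaults. YAML requires the optional `yaml`
#' package; JSON is always available.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return an `experiment_config`.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML requires the `yaml` package; use JSON instead",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(experiment_config, raw)
}

#' Run the full virtual experiment
#'
#' Executes the automated-sensing sequence on synthetic inputs:
#' 1. render a defocus series of the cell scene and move to the plane of
#'    maximal NOCC;
#' 2. detect cells and their penetration sites there;
#' 3. autofocus the virtual pipette tip by template-matching descent
#'    (nonovershoot stop);
#' 4. plan the penetration path from the detected apex;
#' 5. approach each site with the ion-current model and record the
#'    surface-detection event;
#' 6. score detections against the scene ground truth.
#'
#' All randomness derives from `config$seed`; identical configurations
#' produce identical reports.
#'
#' @param config an [experiment_config()].
#' @return object of class `run_report`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  sc_cfg <- config$scene
  scene <- if (sc_cfg$n_cells > 0)
    random_scene(sc_cfg$n_cells, image_shape = sc_cfg$image_shape,
                 seed = config$seed,
                 semi_axis_range = sc_cfg$semi_axis_range,
                 h_max_range = sc_cfg$h_max_range,
                 delta_n = sc_cfg$delta_n, profile = sc_cfg$profile,
                 margin = sc_cfg$margin,
                 background_intensity = sc_cfg$background_intensity,
                 noise_sigma = sc_cfg$noise_sigma,
                 pixel_size = sc_cfg$pixel_size)
  else
    cell_scene(list(), image_shape = sc_cfg$image_shape,
               background_intensity = sc_cfg$background_intensity,
               noise_sigma = sc_cfg$noise_sigma,
               pixel_size = sc_cfg$pixel_size, rng_seed = config$seed)
  truth <- make_ground_truth(scene)

  z_list <- seq(config$zstack$z_min, config$zstack$z_max,
                by = config$zstack$step)
  stack <- render_zstack(scene, z_list)
  det_par <- config$detection
  focus_res <- tryCatch(
    find_best_defocus(stack, z_list, sigma = det_par$sigma,
                      se_radius = det_par$se_radius,
                      min_area = det_par$min_area),
    error = function(e) NULL)

  detection <- if (is.null(focus_res)) NULL else focus_res$detection
  sites <- if (is.null(detection)) matrix(numeric(0), 0, 2)
           else detection$sites

  # tip autofocus
  tp_cfg <- config$tip
  tip <- tip_phantom(tp_cfg$apex, tp_cfg$half_angle, tp_cfg$orientation,
                     tp_cfg$length, tp_cfg$opacity, tp_cfg$z_focus)
  template <- template_from_tip(tip, tp_cfg$shape, tp_cfg$background,
                                tp_cfg$template_half_size)
  stage <- tip_stage(tip, tp_cfg$z_start, tp_cfg$shape, tp_cfg$background,
                     tp_cfg$noise_sigma, seed = derive_seed(config$seed, 101L))
  autofocus <- approach_until_similar(stage, template,
                                      threshold = config$autofocus$threshold,
                                      step = config$autofocus$step)
  tip_fix <- locate_tip(render_tip_image(tip, autofocus$stop_z, tp_cfg$shape,
                                         tp_cfg$background, 0))

  # path planning from the detected apex (fall back to phantom apex)
  start_pt <- if (tip_fix$detected) tip_fix$apex else tip$apex
  plan <- if (nrow(sites) > 0)
    plan_path(sites, start = start_pt, method = config$planner)
  else NULL

  # per-site approach with ion-current feedback
  px_cfg <- config$proximity
  model <- approach_model()
  dstar <- stop_distance(model, px_cfg$p)
  # log-spaced so sampling stays fine near the surface
  schedule <- model$c * exp(seq(log(px_cfg$d_start_factor), log(0.5),
                                length.out = px_cfg$n_samples))
  approaches <- list()
  if (!is.null(plan)) {
    for (k in seq_len(nrow(plan$sites))) {
      tr <- simulate_approach(model, schedule,
                              noise_sigma = px_cfg$noise_frac * model$I_inf,
                              seed = derive_seed(config$seed, 200L + k))
      det <- detect_surface(tr, p = px_cfg$p, baseline_n = px_cfg$baseline_n,
                            smooth_w = px_cfg$smooth_w,
                            confirm_m = px_cfg$confirm_m)
      approaches[[k]] <- list(site = plan$sites[k, ], surface = det,
                              analytic_stop = dstar,
                              penetrated = isTRUE(det$detected))
    }
  }

  counts <- if (nrow(sites) > 0 || truth$cell_count > 0)
    match_detections(sites, truth) else NULL
  rt <- if (!is.null(counts) && counts$tp + counts$fn > 0) rates(counts)
        else NULL

  structure(list(
    seed = config$seed,
    z_best = if (is.null(focus_res)) NA_real_ else focus_res$z_best,
    focus_curve = if (is.null(focus_res)) NULL else focus_res$curve,
    detection = detection,
    plan = plan,
    autofocus = autofocus,
    tip_detection = tip_fix,
    approaches = approaches,
    counts = counts,
    rates = rt,
    config = config
  ), class = "run_report")
}

# Reduce a report to plain (JSON-serialisable) structures.
report_to_list <- function(report) {
  stopifnot(inherits(report, "run_report"))
  sites <- if (is.null(report$detection)) NULL else report$detection$sites
  list(
    seed = report$seed,
    z_best = report$z_best,
    nocc = if (is.null(report$detection)) 0L else report$detection$nocc,
    branch = if (is.null(report$detection)) NA_character_
             else report$detection$thresholds$branch,
    sites = if (is.null(sites)) list() else unname(apply(sites, 1, as.numeric,
                                                         simplify = FALSE)),
    plan = if (is.null(report$plan)) NULL else list(
      order = report$plan$order,
      total_length = report$plan$total_length,
      method = report$plan$method),
    autofocus = list(stop_z = report$autofocus$stop_z,
                     stopped_before_focus = report$autofocus$stopped_before_focus,
                     threshold_crossed = report$autofocus$threshold_crossed,
                     steps = length(report$autofocus$z_sequence)),
    tip = list(detected = report$tip_detection$detected,
               apex = report$tip_detection$apex),
    approaches = lapply(report$approaches, function(a) list(
      site = as.numeric(a$site),
      detected = a$surface$detected,
      position = a$surface$position,
      analytic_stop = a$analytic_stop,
      penetrated = a$penetrated)),
    evaluation = if (is.null(report$rates)) NULL else list(
      tp = report$counts$tp, fn = report$counts$fn, fp = report$counts$fp,
      tpr = report$rates$tpr, fpr = report$rates$fpr)
  )
}

#' Write a run report as JSON
#'
#' Serialisation is deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report a `run_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat("virtual experiment report\n")
  cat(sprintf("  best defocus plane: z = %g um, NOCC = %s\n", x$z_best,
              if (is.null(x$detection)) 0 else x$detection$nocc))
  cat(sprintf("  tip autofocus: stop z = %g (%s)\n", x$autofocus$stop_z,
              if (x$autofocus$stopped_before_focus) "before focus"
              else "at/past focus"))
  if (!is.null(x$plan))
    cat(sprintf("  path: %d sites, total length %.1f px\n",
                nrow(x$plan$sites), x$plan$total_length))
  if (!is.null(x$rates))
    cat(sprintf("  evaluation: TPR = %.2f%%, FPR = %.2f%%\n",
                x$rates$tpr, x$rates$fpr))
  invisible(x)
}
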