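# File I/O: images (PNG via the optional `png` package, plain-text PGM
# always), CSV tables for sites/curves/traces, JSON ground truth.

#' Write a gray image
#'
#' Format follows the file extension: `.png` (requires the `png`
#' package) or `.pgm` (plain-text P2, always available).
#'
#' @param img gray matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  assert_gray(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the `png` package; use .pgm instead",
           call. = FALSE)
    png::writePNG(img / 255, path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
    write(t(round(img)), con, ncolumns = ncol(img))
  } else stop("unsupported image extension: .", ext, call. = FALSE)
  invisible(path)
}

#' Read a gray image
#'
#' Accepts `.png` (gray or RGB, converted by luminance) and plain-text
#' `.pgm` (P2).
#'
#' @param path input path.
#' @return gray matrix in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the `png` package", call. = FALSE)
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3]
    return(as_gray(if (is.matrix(x)) x * 255 else x))
  }
  if (ext == "pgm") {
    txt <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
    if (txt[1] != "P2") stop("only plain-text (P2) PGM supported", call. = FALSE)
    w <- as.integer(txt[2]); h <- as.integer(txt[3])
    vals <- as.numeric(txt[-(1:4)])
    return(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
  }
  stop("unsupported image extension: .", ext, call. = FALSE)
}

#' Write a z-stack as per-plane images plus an index CSV
#'
#' @param stack named list of gray matrices (names = z positions).
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @param format `"png"` or `"pgm"`.
#' @return data frame of the index (plane, z, file), invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "plane", format = "pgm") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z <- as.numeric(names(stack))
  files <- sprintf("%s_%03d.%s", prefix, seq_along(stack), format)
  for (i in seq_along(stack))
    write_image(stack[[i]], file.path(dir, files[i]))
  idx <- data.frame(plane = seq_along(stack), z_um = z, file = files)
  utils::write.csv(idx, file.path(dir, paste0(prefix, "_index.csv")),
                   row.names = FALSE)
  invisible(idx)
}

#' Write ground truth (centroid JSON and label raster)
#'
#' @param truth a `ground_truth`.
#' @param dir output directory.
#' @param format label-image format (`"pgm"` or `"png"`).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir, format = "pgm") {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(cell_count = truth$cell_count,
         centroids = unname(apply(truth$centroids, 1, as.numeric,
                                  simplify = FALSE))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  # label raster scaled into gray range for inspection
  lab <- truth$labels
  img <- if (max(lab) > 0) quantize8(lab * (255 / max(lab)))
         else matrix(0, nrow(lab), ncol(lab))
  write_image(img, file.path(dir, paste0("labels.", format)))
  invisible(dir)
}

#' Write detected sites as CSV
#'
#' Columns: `site_id`, `row`, `col`, `contour_area`.
#'
#' @param detection a `detection_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sites_csv <- function(detection, path) {
  stopifnot(inherits(detection, "detection_result"))
  s <- detection$sites
  df <- data.frame(site_id = seq_len(nrow(s)),
                   row = s[, 1], col = s[, 2],
                   contour_area = vapply(detection$contours,
                                         function(ct) ct$area, numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a focus curve as CSV
#'
#' Columns: `z_um`, `metric`, `value`.
#'
#' @param curve a `focus_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "focus_curve"))
  utils::write.csv(data.frame(z_um = curve$z, metric = curve$metric,
                              value = curve$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an approach trace as CSV
#'
#' Columns: `distance_m`, `current_A`.
#'
#' @param trace an `approach_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(distance_m = trace$distance,
                              current_A = trace$current),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an approach trace from CSV
#'
#' @param path CSV with columns `distance_m`, `current_A`.
#' @return an `approach_trace` (noise metadata unknown: set to `NA`).
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(distance = df$distance_m, current = df$current_A,
                 noise_sigma = NA_real_, seed = NA_integer_),
            class = "approach_trace")
}
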