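# Detection scoring against nucleus ground truth. Rates follow
#   TPR = TP / (TP + FN),  FPR = FP / (TP + FN),
# expressed in percent; TP + FN equals the number of visible cells.
# Counts may be fractional (replicate averages).

#' Construct evaluation counts
#'
#' @param tp accurately identified cells (may be fractional when counts
#'   are replicate averages).
#' @param fn missed visible cells.
#' @param fp false detections: off-target sites plus duplicate labels.
#' @return object of class `eval_counts`.
#' @export
eval_counts <- function(tp, fn, fp) {
  if (any(c(tp, fn, fp) < 0)) stop("counts must be nonnegative", call. = FALSE)
  structure(list(tp = as.numeric(tp), fn = as.numeric(fn),
                 fp = as.numeric(fp)), class = "eval_counts")
}

#' Match detected sites against ground truth
#'
#' Greedy one-to-one assignment in site order: a site inside an
#' unmatched cell's nucleus mask scores a true positive; further sites
#' inside an already-matched cell are duplicate labels (false
#' positives); sites inside no mask are off-target (false positives);
#' cells left unmatched are false negatives.
#'
#' @param sites n x 2 matrix of 0-based (row, col) detected sites.
#' @param truth a `ground_truth` (see [make_ground_truth()]).
#' @return an [eval_counts()].
#' @export
match_detections <- function(sites, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  n_cells <- truth$cell_count
  matched <- logical(n_cells)
  tp <- 0; fp <- 0
  if (length(sites)) {
    for (k in seq_len(nrow(sites))) {
      r <- round(sites[k, 1]) + 1L
      c_ <- round(sites[k, 2]) + 1L
      hit <- 0L
      for (i in seq_len(n_cells)) {
        m <- truth$masks[[i]]
        if (r >= 1L && r <= nrow(m) && c_ >= 1L && c_ <= ncol(m) &&
            m[r, c_]) { hit <- i; break }
      }
      if (hit == 0L) fp <- fp + 1
      else if (matched[hit]) fp <- fp + 1
      else { matched[hit] <- TRUE; tp <- tp + 1 }
    }
  }
  eval_counts(tp, n_cells - tp, fp)
}

#' True- and false-positive rates (percent)
#'
#' @param counts an [eval_counts()].
#' @return object of class `eval_rates` with `tpr` and `fpr` in percent.
#' @export
rates <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  denom <- counts$tp + counts$fn
  if (denom <= 0) stop("TP + FN must be positive", call. = FALSE)
  structure(list(tpr = 100 * counts$tp / denom,
                 fpr = 100 * counts$fp / denom),
            class = "eval_rates")
}

#' Component-wise mean of evaluation counts
#'
#' Fractional results are expected: replicate-averaged counts are
#' first-class citizens of this bookkeeping.
#'
#' @param counts_list nonempty list of [eval_counts()].
#' @return an [eval_counts()] of the arithmetic means.
#' @export
average_counts <- function(counts_list) {
  if (length(counts_list) == 0L) stop("empty list", call. = FALSE)
  stopifnot(all(vapply(counts_list, inherits, TRUE, "eval_counts")))
  eval_counts(mean(vapply(counts_list, function(x) x$tp, numeric(1))),
              mean(vapply(counts_list, function(x) x$fn, numeric(1))),
              mean(vapply(counts_list, function(x) x$fp, numeric(1))))
}

#' Published benchmark detection counts
#'
#' Replicate-averaged detection counts reported for the HUVEC and
#' NIH/3T3 adherent-cell benchmarks of this detection approach (10
#' evaluation frames, 755 HUVEC and 593 NIH/3T3 cells in total). Used to
#' validate the rate computations; the per-line counts are inputs, the
#' rates are recomputed.
#'
#' @return data frame with columns `cell_line`, `tp`, `fn`, `fp`.
#' @export
benchmark_counts <- function() {
  data.frame(cell_line = c("HUVEC", "NIH-3T3"),
             tp = c(145, 114.6),
             fn = c(3.8, 8),
             fp = c(11, 9.6),
             stringsAsFactors = FALSE)
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("counts: TP = %g, FN = %g, FP = %g\n", x$tp, x$fn, x$fp))
  invisible(x)
}

#' @export
print.eval_rates <- function(x, ...) {
  cat(sprintf("TPR = %.2f%%, FPR = %.2f%%\n", x$tpr, x$fpr))
  invisible(x)
}
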