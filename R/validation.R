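#' Paired random sample of prediction and truth rasters
#'
#' Uniform without-replacement sample over the cells valid in both layers,
#' the sampling design used to validate a continuous loss-probability
#' surface against a binary observed-loss map (truth coded 1 = lost,
#' 0 = retained).
#'
#' @param pred_raster continuous prediction `grid_raster`.
#' @param truth_raster 0/1 truth `grid_raster`.
#' @param n sample size (must not exceed the jointly valid cell count).
#' @param seed integer seed; fixed seed gives the same sample.
#' @return list with numeric `pred` and integer `obs` of length `n`.
#' @export
sample_points <- function(pred_raster, truth_raster, n, seed = 1) {
  check_aligned(pred_raster, truth_raster)
  ok <- !is_nodata_cell(pred_raster) & !is_nodata_cell(truth_raster)
  idx <- which(ok)
  if (n > length(idx))
    stop("n exceeds the number of jointly valid cells (", length(idx), ")")
  sel <- with_seed(seed, sample(idx, n))
  list(pred = as.numeric(pred_raster$values[sel]),
       obs = as.integer(truth_raster$values[sel] > 0))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney probability that a
#' random positive outranks a random negative, ties counted half.
#'
#' @param pred numeric scores.
#' @param obs 0/1 outcomes (both classes must be present).
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  obs <- as.integer(obs > 0)
  n1 <- sum(obs == 1L); n0 <- sum(obs == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(pred)
  (sum(r[obs == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a cut-point
#'
#' Classifies positive iff `pred >= t` and returns the standard 2x2 table
#' metrics plus Cohen's kappa.
#'
#' @param pred numeric scores.
#' @param obs 0/1 outcomes.
#' @param t cut-point in \[0, 1\].
#' @return named list: `sensitivity`, `specificity`, `pcc`, `kappa`, and
#'   the table counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_cutpoint <- function(pred, obs, t) {
  if (!length(pred)) stop("empty input")
  stopifnot(length(pred) == length(obs), t >= 0, t <= 1)
  obs <- as.integer(obs > 0)
  pos <- pred >= t
  tp <- sum(pos & obs == 1L); fp <- sum(pos & obs == 0L)
  fn <- sum(!pos & obs == 1L); tn <- sum(!pos & obs == 0L)
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe >= 1) 0 else (po - pe) / (1 - pe)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       pcc = po, kappa = kappa, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Validation metrics at the kappa-optimal cut-point
#'
#' Scans cut-points over a regular grid, finds the one maximising Cohen's
#' kappa (ties broken toward the smaller cut-point, matching the reported
#' two-decimal metric precision) and reports AUC, sensitivity, specificity
#' and percent correctly classified there.
#'
#' @param pred numeric scores in \[0, 1\].
#' @param obs 0/1 outcomes, both classes present.
#' @param grid_step cut-point grid spacing (default 0.01).
#' @return list of class `validation_result`: `auc`, `sensitivity`,
#'   `specificity`, `pcc`, `kappa`, `cutpoint`, `n_points`.
#' @export
kappa_optimal_cutpoint <- function(pred, obs, grid_step = 0.01) {
  obs <- as.integer(obs > 0)
  if (!sum(obs == 1L) || !sum(obs == 0L)) stop("both classes must be present")
  grid <- seq(0, 1, by = grid_step)
  kap <- vapply(grid, function(t) confusion_at_cutpoint(pred, obs, t)$kappa,
                numeric(1))
  best <- grid[which.max(kap)]  # which.max returns the first (smallest t)
  cm <- confusion_at_cutpoint(pred, obs, best)
  structure(list(auc = rank_auc(pred, obs), sensitivity = cm$sensitivity,
                 specificity = cm$specificity, pcc = cm$pcc,
                 kappa = cm$kappa, cutpoint = best,
                 n_points = length(pred)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(paste0("<validation_result> n = %d\n",
                     "  AUC %.3f | cut-point %.2f (max kappa %.3f)\n",
                     "  sensitivity %.3f, specificity %.3f, PCC %.3f\n"),
              x$n_points, x$auc, x$cutpoint, x$kappa,
              x$sensitivity, x$specificity, x$pcc))
  invisible(x)
}

#' Validate a loss-probability raster against observed loss
#'
#' Convenience wrapper: samples `n` paired points and computes the full
#' metric suite at the kappa-optimal cut-point.
#'
#' @inheritParams sample_points
#' @inheritParams kappa_optimal_cutpoint
#' @return a `validation_result`.
#' @export
validate_risk <- function(pred_raster, truth_raster, n, seed = 1,
                          grid_step = 0.01) {
  pts <- sample_points(pred_raster, truth_raster, n, seed = seed)
  kappa_optimal_cutpoint(pts$pred, pts$obs, grid_step = grid_step)
}
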