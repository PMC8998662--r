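# Metric suite for comparing an original and a synthetic sequence set, plus
# classifier metrics with ROC support. Sequence sets are vectorized into
# feature matrices (per-position base frequencies by default, k-mer
# frequencies optionally) before the numeric comparisons.

#' Vectorize a sequence set into a feature matrix
#'
#' `position_freq` builds a `4 x L` matrix of per-position base frequencies
#' (rows in [DNA_BASES] order; each column sums to 1; `N` bases contribute
#' 0.25 to each row). `kmer_freq` builds a `4^k x 1` matrix of overlapping
#' k-mer frequencies (windows containing `N` are skipped; frequencies sum
#' to 1).
#'
#' @param seqs Character vector of sequences (equal lengths required for
#'   `position_freq`).
#' @param mode `"position_freq"` or `"kmer_freq"`.
#' @param k k-mer length for `kmer_freq` (default 3).
#' @return A numeric matrix of class `feature_matrix` with attribute
#'   `provenance` set to `mode`.
#' @export
build_feature_matrix <- function(seqs, mode = c("position_freq", "kmer_freq"),
                                 k = 3L) {
  mode <- match.arg(mode)
  stopifnot(length(seqs) >= 1L)
  if (mode == "position_freq") {
    if (length(unique(nchar(seqs))) != 1L) {
      stop("position_freq requires equal-length sequences")
    }
    X <- encode_batch(seqs, "uniform")
    M <- matrix(colMeans(X), nrow = 4L,
                dimnames = list(DNA_BASES,
                                sprintf("pos_%d", seq_len(ncol(X) / 4L))))
  } else {
    stopifnot(k >= 1L)
    kmers <- do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                             stringsAsFactors = FALSE)))
    kmers <- sort(kmers)
    counts <- stats::setNames(numeric(length(kmers)), kmers)
    for (s in toupper(seqs)) {
      L <- nchar(s)
      if (L < k) next
      wins <- substring(s, 1:(L - k + 1L), k:L)
      wins <- wins[!grepl("N", wins, fixed = TRUE)]
      if (length(wins)) {
        tb <- table(wins)
        counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
      }
    }
    if (sum(counts) == 0) stop("no scorable k-mer windows")
    M <- matrix(counts / sum(counts), ncol = 1L,
                dimnames = list(kmers, "kmer_freq"))
  }
  structure(M, provenance = mode, class = c("feature_matrix", "matrix", "array"))
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation between two equal-length vectors.
#'
#' @param Or,Sn Numeric vectors of equal length (>= 2) with nonzero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(Or, Sn) {
  stopifnot(length(Or) == length(Sn), length(Or) >= 2L)
  if (stats::sd(Or) == 0 || stats::sd(Sn) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(as.vector(Or), as.vector(Sn))
}

#' Mean absolute error
#'
#' @param Or,Sn Numeric vectors of equal length.
#' @return `mean(|Or - Sn|)`, nonnegative; 0 iff identical.
#' @export
mae <- function(Or, Sn) {
  stopifnot(length(Or) == length(Sn), length(Or) >= 1L)
  mean(abs(Or - Sn))
}

#' Percent root-mean-square difference
#'
#' `100 * sqrt(sum((Or - Sn)^2) / sum(Or^2))`: the residual energy relative
#' to the reference signal, on a percent scale. Asymmetric by construction
#' (normalized by the original).
#'
#' @param Or,Sn Numeric vectors of equal length; `Or` must not be all zero.
#' @return Nonnegative percentage.
#' @export
prd <- function(Or, Sn) {
  stopifnot(length(Or) == length(Sn), length(Or) >= 1L)
  denom <- sum(Or^2)
  if (denom == 0) stop("PRD undefined: reference vector is all zero")
  100 * sqrt(sum((Or - Sn)^2) / denom)
}

#' Root-mean-square error
#'
#' `sqrt(mean((Or - Sn)^2))`, the standard textbook statistic.
#'
#' @param Or,Sn Numeric vectors of equal length.
#' @return Nonnegative; 0 iff identical; equals `|c|` for a constant offset
#'   `c`.
#' @export
rmse <- function(Or, Sn) {
  stopifnot(length(Or) == length(Sn), length(Or) >= 1L)
  sqrt(mean((Or - Sn)^2))
}

#' Mirror column association
#'
#' Mean over columns of the Pearson correlation between the corresponding
#' columns of the original and synthetic feature matrices. Columns with zero
#' variance on either side are skipped; the number skipped is reported in the
#' `n_skipped` attribute.
#'
#' @param OrM,SnM Numeric matrices of identical shape.
#' @return Mean per-column correlation in `[-1, 1]`; errors when no column
#'   has nonzero variance on both sides.
#' @export
mirror_column_association <- function(OrM, SnM) {
  stopifnot(is.matrix(OrM), is.matrix(SnM), all(dim(OrM) == dim(SnM)))
  if (nrow(OrM) < 2L) stop("columns need at least 2 rows to correlate")
  cors <- vapply(seq_len(ncol(OrM)), function(j) {
    if (stats::sd(OrM[, j]) == 0 || stats::sd(SnM[, j]) == 0) NA_real_
    else stats::cor(OrM[, j], SnM[, j])
  }, numeric(1))
  skipped <- sum(is.na(cors))
  if (skipped == ncol(OrM)) stop("no valid columns: all have zero variance")
  structure(mean(cors, na.rm = TRUE), n_skipped = skipped)
}

#' Discrete Fréchet distance between two curves
#'
#' Minimum over all monotone couplings of the two point sequences of the
#' maximum pointwise Euclidean distance (the "dog-leash" distance), computed
#' by dynamic programming in `O(n * m)`.
#'
#' @param O,P Numeric matrices with one point per row (vectors are treated as
#'   one-dimensional curves). Both must be nonempty.
#' @return Nonnegative distance; 0 when the curves coincide.
#' @export
frechet_distance <- function(O, P) {
  if (is.null(dim(O))) O <- matrix(O, ncol = 1L)
  if (is.null(dim(P))) P <- matrix(P, ncol = 1L)
  n <- nrow(O)
  m <- nrow(P)
  if (n == 0L || m == 0L) stop("empty curve")
  stopifnot(ncol(O) == ncol(P))
  D <- matrix(0, n, m)
  for (j in seq_len(m)) {
    diff <- sweep(O, 2L, P[j, ], "-")
    D[, j] <- sqrt(rowSums(diff * diff))
  }
  ca <- matrix(0, n, m)
  ca[1, 1] <- D[1, 1]
  for (i in 2:max(n, 2L)) if (n >= 2L) ca[i, 1] <- max(ca[i - 1, 1], D[i, 1])
  for (j in 2:max(m, 2L)) if (m >= 2L) ca[1, j] <- max(ca[1, j - 1], D[1, j])
  if (n >= 2L && m >= 2L) {
    for (i in 2:n) {
      for (j in 2:m) {
        ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                        D[i, j])
      }
    }
  }
  ca[n, m]
}

#' Confusion counts from binary truth/prediction vectors
#'
#' @param truth,pred Logical vectors (or coercible) of equal length.
#' @return A list of class `confusion_counts` with integer fields `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as.logical(truth)
  pred <- as.logical(pred)
  stopifnot(length(truth) == length(pred), !anyNA(truth), !anyNA(pred))
  structure(list(TP = sum(truth & pred), TN = sum(!truth & !pred),
                 FP = sum(!truth & pred), FN = sum(truth & !pred)),
            class = "confusion_counts")
}

#' Classifier metrics from a confusion table
#'
#' Accuracy, Matthews correlation coefficient, sensitivity and specificity.
#' Accuracy, sensitivity and specificity are reported on the 0-100 percent
#' scale; MCC on `[-1, 1]`. When any factor of the MCC denominator is zero
#' the MCC is defined as 0. Sensitivity/specificity with a zero denominator
#' raise an error.
#'
#' @param counts A [confusion_counts()] object, or a list/vector with
#'   entries `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector `c(Acc, MCC, Sen, Spc)`.
#' @export
classifier_metrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]])
  TN <- as.numeric(counts[["TN"]])
  FP <- as.numeric(counts[["FP"]])
  FN <- as.numeric(counts[["FN"]])
  total <- TP + TN + FP + FN
  if (total <= 0) stop("empty confusion table")
  if (TP + FN == 0) stop("sensitivity undefined: no positive examples")
  if (TN + FP == 0) stop("specificity undefined: no negative examples")
  denom <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  c(Acc = 100 * (TP + TN) / total,
    MCC = mcc,
    Sen = 100 * TP / (TP + FN),
    Spc = 100 * TN / (TN + FP))
}

#' ROC curve and area under it
#'
#' Sweeps a decision threshold over the unique scores and reports the
#' (false-positive rate, true-positive rate) curve with the trapezoid-rule
#' area.
#'
#' @param scores Numeric scores (higher means more positive).
#' @param labels Logical (or coercible) true class labels; both classes must
#'   be present.
#' @return A list with `points` (data frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0L || N == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last_of_tie <- c(sc[-1] != sc[-length(sc)], TRUE)
  pts <- data.frame(fpr = c(0, fp[last_of_tie] / N),
                    tpr = c(0, tp[last_of_tie] / P))
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  list(points = pts, auc = auc)
}

#' Compare an original and a synthetic sequence set
#'
#' Vectorizes both sets with [build_feature_matrix()], flattens the matrices
#' consistently, and computes the full metric suite: Pearson correlation,
#' MAE, PRD, RMSE, mirror column association, and the discrete Fréchet
#' distance between the two matrices' column-profile curves (column index
#' along the curve, each column's feature vector as the point).
#'
#' @param original,synthetic Nonempty character vectors of sequences.
#' @param mode,k Passed to [build_feature_matrix()].
#' @return A list of class `metric_report` with fields `pearson`, `mae`,
#'   `prd`, `rmse`, `mirror_column_association` (`NA` when no column pair
#'   has usable variance), `frechet`, and `mode`.
#' @export
compare_datasets <- function(original, synthetic,
                             mode = c("position_freq", "kmer_freq"), k = 3L) {
  mode <- match.arg(mode)
  stopifnot(length(original) >= 1L, length(synthetic) >= 1L)
  OrM <- build_feature_matrix(original, mode, k)
  SnM <- build_feature_matrix(synthetic, mode, k)
  if (!all(dim(OrM) == dim(SnM))) {
    stop("feature matrices have different shapes; use equal sequence lengths")
  }
  assoc <- tryCatch(as.numeric(mirror_column_association(OrM, SnM)),
                    error = function(e) NA_real_)
  structure(list(
    pearson = pearson(as.vector(OrM), as.vector(SnM)),
    mae = mae(as.vector(OrM), as.vector(SnM)),
    prd = prd(as.vector(OrM), as.vector(SnM)),
    rmse = rmse(as.vector(OrM), as.vector(SnM)),
    mirror_column_association = assoc,
    frechet = frechet_distance(t(unclass(OrM)), t(unclass(SnM))),
    mode = mode
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Original vs synthetic sequence sets (", x$mode, ")\n", sep = "")
  cat(sprintf("  Pearson correlation       %8.4f\n", x$pearson))
  cat(sprintf("  MAE                       %8.4f\n", x$mae))
  cat(sprintf("  PRD (%%)                   %8.2f\n", x$prd))
  cat(sprintf("  RMSE                      %8.4f\n", x$rmse))
  cat(sprintf("  Mirror column association %8.4f\n",
              x$mirror_column_association))
  cat(sprintf("  Frechet distance          %8.4f\n", x$frechet))
  invisible(x)
}
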