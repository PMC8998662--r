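# PWM motif evaluator: slides the motif's probability matrix along a
# sequence, takes the inner product with each window (a one-dimensional
# convolution), max-pools over offsets, and thresholds the resulting score.
# Acts as the second gate of the feedback loop.

# best achievable window score: sum of per-position column maxima
pwm_max_score <- function(p) {
  sum(apply(unclass(p), 1L, max))
}

# reverse-complement a one-hot (L x 4) matrix: reverse positions, swap A<->T
# and C<->G channels (channel order A, T, C, G)
revcomp_onehot <- function(M) {
  M[rev(seq_len(nrow(M))), c(2L, 1L, 4L, 3L), drop = FALSE]
}

score_windows <- function(M, p) {
  Len <- nrow(p)
  L <- nrow(M)
  n_off <- L - Len + 1L
  scores <- numeric(n_off)
  for (j in seq_len(Len)) {
    contrib <- as.vector(M %*% p[j, ])
    scores <- scores + contrib[j:(j + n_off - 1L)]
  }
  scores
}

#' Motif-matching score of a sequence
#'
#' Computes, for every length-`Len` window of the sequence, the inner product
#' between the PWM and the window's one-hot encoding, and max-pools over
#' windows. The raw maximum is normalized by the best achievable window score
#' (the sum of the PWM's per-position column maxima) so scores are comparable
#' across motifs and lie in (0, 1] for hard sequences. Offset ties break
#' toward the smallest offset.
#'
#' @param seq A character DNA sequence or an `L x 4` one-hot matrix (hard or
#'   soft).
#' @param p A [pwm] object; `Len` must not exceed the sequence length.
#' @param scan_revcomp Also scan the reverse complement and keep the better
#'   strand (default `FALSE`: single-strand scan).
#' @return A list of class `motif_score`: `raw_max`, `normalized`,
#'   `best_offset` (0-based) and `strand` (`"+"` or `"-"`).
#' @export
motif_score <- function(seq, p, scan_revcomp = FALSE) {
  stopifnot(inherits(p, "pwm"))
  M <- if (is.character(seq)) one_hot_encode(seq, "uniform") else seq
  stopifnot(is.matrix(M), ncol(M) == 4L)
  if (nrow(M) < nrow(p)) {
    stop("sequence length ", nrow(M), " shorter than motif length ", nrow(p))
  }
  scores <- score_windows(M, p)
  strand <- "+"
  if (scan_revcomp) {
    rscores <- score_windows(revcomp_onehot(M), p)
    if (max(rscores) > max(scores)) {
      scores <- rscores
      strand <- "-"
    }
  }
  best <- which.max(scores)
  structure(list(raw_max = scores[best],
                 normalized = scores[best] / pwm_max_score(p),
                 best_offset = best - 1L,
                 strand = strand),
            class = "motif_score")
}

#' Motif scores for a batch of sequences
#'
#' Vectorized form of [motif_score()] (single-strand scan).
#'
#' @param seqs Character vector of equal-length sequences or an
#'   `onehot_batch` matrix.
#' @param p A [pwm] object.
#' @return Data frame with columns `id`, `raw_max`, `normalized`,
#'   `best_offset` (0-based).
#' @export
motif_score_batch <- function(seqs, p) {
  stopifnot(inherits(p, "pwm"))
  ids <- NULL
  if (is.character(seqs)) {
    ids <- names(seqs) %||% sprintf("seq_%d", seq_along(seqs))
    seqs <- encode_batch(seqs, "uniform")
  }
  X <- seqs
  B <- nrow(X)
  L <- ncol(X) / 4L
  Len <- nrow(p)
  if (L < Len) stop("sequence length ", L, " shorter than motif length ", Len)
  ids <- ids %||% sprintf("seq_%d", seq_len(B))
  n_off <- L - Len + 1L
  S <- matrix(0, B, n_off)
  for (j in seq_len(Len)) {
    PB <- matrix(flat_to_blc(X, 4L) %*% p[j, ], B, L)
    S <- S + PB[, j:(j + n_off - 1L), drop = FALSE]
  }
  best <- max.col(S, ties.method = "first")
  raw <- S[cbind(seq_len(B), best)]
  data.frame(id = ids, raw_max = raw,
             normalized = raw / pwm_max_score(p),
             best_offset = best - 1L)
}

#' Threshold filter on normalized motif scores
#'
#' Passes sequences whose normalized motif score strictly exceeds the
#' threshold. Order and total count are preserved across the two parts.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param p A [pwm] object.
#' @param threshold Normalized-score threshold in (0, 1); default 0.75.
#' @return List with `passed`, `rejected` (character vectors) and `scores`
#'   (the [motif_score_batch()] data frame).
#' @export
filter_by_score <- function(seqs, p, threshold = 0.75) {
  sc <- motif_score_batch(seqs, p)
  keep <- sc$normalized > threshold
  list(passed = seqs[keep], rejected = seqs[!keep], scores = sc)
}

#' Grid search over score thresholds
#'
#' Evaluates each candidate threshold on a labeled synthetic set: how many
#' sequences pass, and how well passing agrees with the known embedding
#' indicator (fraction of sequences where "passes" equals "carries the
#' motif").
#'
#' @param seqs Character vector of sequences.
#' @param embedded Logical vector: does each sequence carry an embedded motif
#'   instance (as reported by [simulate_dataset()]).
#' @param p A [pwm] object.
#' @param grid Candidate thresholds (default 0.65 to 0.90 in steps of 0.05).
#' @return Data frame with columns `threshold`, `n_pass`, `agreement`;
#'   `n_pass` is non-increasing in the threshold.
#' @export
grid_search_threshold <- function(seqs, embedded, p,
                                  grid = seq(0.65, 0.90, by = 0.05)) {
  if (!length(grid)) stop("empty threshold grid")
  stopifnot(length(seqs) == length(embedded))
  sc <- motif_score_batch(seqs, p)
  out <- lapply(sort(grid), function(th) {
    pass <- sc$normalized > th
    data.frame(threshold = th, n_pass = sum(pass),
               agreement = mean(pass == embedded))
  })
  do.call(rbind, out)
}
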