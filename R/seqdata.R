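# Sequence containers, one-hot codec, FASTA / PWM input-output and the
# synthetic dataset simulators used for fixtures and method validation.

#' One-hot channel order
#'
#' Column order of every one-hot encoded sequence and every PWM in the
#' package: A, T, C, G (not alphabetical). A encodes as (1,0,0,0), T as
#' (0,1,0,0), C as (0,0,1,0) and G as (0,0,0,1).
#'
#' @format Character vector of length 4.
#' @export
DNA_BASES <- c("A", "T", "C", "G")

# ---- one-hot codec ----------------------------------------------------------

#' One-hot encode a DNA sequence
#'
#' Converts a character DNA sequence into an L x 4 matrix over the channel
#' order [DNA_BASES] (A, T, C, G). Ambiguous bases (`N`) are either rejected
#' or encoded as the uniform row (0.25, 0.25, 0.25, 0.25).
#'
#' @param seq Character scalar over the alphabet A/C/G/T (optionally N).
#' @param n_policy `"reject"` (default) errors on N; `"uniform"` encodes N as
#'   a uniform distribution over the four bases.
#' @return An L x 4 numeric matrix with `colnames` `DNA_BASES`, every row
#'   summing to 1, and attribute `is_hard` (`TRUE` iff all rows are 0/1
#'   indicator rows, i.e. no N was present).
#' @seealso [one_hot_decode()]
#' @export
one_hot_encode <- function(seq, n_policy = c("reject", "uniform")) {
  n_policy <- match.arg(n_policy)
  stopifnot(is.character(seq), length(seq) == 1L)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(DNA_BASES, "N"))
  if (any(bad)) {
    stop("invalid alphabet: ", paste(unique(chars[bad]), collapse = ", "))
  }
  has_n <- any(chars == "N")
  if (has_n && n_policy == "reject") {
    stop("invalid alphabet: sequence contains N under n_policy = 'reject'")
  }
  M <- matrix(0, length(chars), 4L, dimnames = list(NULL, DNA_BASES))
  for (b in seq_along(DNA_BASES)) {
    M[chars == DNA_BASES[b], b] <- 1
  }
  M[chars == "N", ] <- 0.25
  attr(M, "is_hard") <- !has_n
  M
}

#' Decode a one-hot matrix back to a DNA sequence
#'
#' Takes the per-row argmax of an L x 4 (possibly soft) one-hot matrix and
#' maps it back to bases. Ties are resolved toward the first base in
#' [DNA_BASES] order when `tie_break = "first"`.
#'
#' @param oh L x 4 numeric matrix (hard or soft one-hot; rows need not be
#'   exactly normalized).
#' @param tie_break `"first"` (default) or `"error"`.
#' @return Character scalar of length-L DNA.
#' @export
one_hot_decode <- function(oh, tie_break = c("first", "error")) {
  tie_break <- match.arg(tie_break)
  stopifnot(is.matrix(oh), ncol(oh) == 4L)
  if (tie_break == "error") {
    rmax <- apply(oh, 1L, max)
    if (any(rowSums(oh == rmax) > 1L)) {
      stop("ambiguous row: argmax tie under tie_break = 'error'")
    }
  }
  paste(DNA_BASES[max.col(oh, ties.method = "first")], collapse = "")
}

#' Encode a set of equal-length sequences as a batch matrix
#'
#' Stacks one-hot encodings into the (B, L*4) layout consumed by the
#' generator, critic and predictor: column `(l-1)*4 + c` holds channel `c`
#' (in [DNA_BASES] order) of position `l`.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param n_policy Passed to [one_hot_encode()].
#' @return A numeric matrix of class `onehot_batch` with attributes `L`
#'   (sequence length) and `is_hard`.
#' @export
encode_batch <- function(seqs, n_policy = c("reject", "uniform")) {
  n_policy <- match.arg(n_policy)
  stopifnot(length(seqs) >= 1L)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must all have the same length")
  X <- matrix(0, length(seqs), L * 4L)
  hard <- TRUE
  for (i in seq_along(seqs)) {
    M <- one_hot_encode(seqs[[i]], n_policy)
    hard <- hard && attr(M, "is_hard")
    X[i, ] <- as.vector(t(M))
  }
  structure(X, L = L, is_hard = hard, class = c("onehot_batch", "matrix", "array"))
}

#' Decode a batch matrix back to sequences
#'
#' @param X `(B, L*4)` matrix in the [encode_batch()] layout.
#' @param tie_break Passed to [one_hot_decode()].
#' @return Character vector of B sequences.
#' @export
decode_batch <- function(X, tie_break = c("first", "error")) {
  tie_break <- match.arg(tie_break)
  L <- ncol(X) / 4L
  vapply(seq_len(nrow(X)), function(i) {
    one_hot_decode(matrix(X[i, ], L, 4L, byrow = TRUE,
                          dimnames = list(NULL, DNA_BASES)), tie_break)
  }, character(1))
}

# batch row i -> L x 4 matrix
batch_row_matrix <- function(X, i) {
  L <- ncol(X) / 4L
  matrix(X[i, ], L, 4L, byrow = TRUE, dimnames = list(NULL, DNA_BASES))
}

# ---- FASTA ------------------------------------------------------------------

#' Read sequences from a FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()]; bases are uppercased on read and an
#' empty file yields an empty vector.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector (names become record ids; unnamed
#'   sequences get `seq_<i>` ids).
#' @param path Output path. Lines are wrapped at 60 characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    ids <- paste0("seq_", seq_along(seqs))
    if (!is.null(names(seqs))) ids[nzchar(names(seqs))] <- names(seqs)[nzchar(names(seqs))]
    names(seqs) <- ids
  }
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

# ---- PWM --------------------------------------------------------------------

#' Construct a position weight matrix
#'
#' A PWM summarizes a motif of length `Len` as a `Len x 4` matrix whose rows
#' are probability distributions over [DNA_BASES].
#'
#' @param matrix `Len x 4` nonnegative numeric matrix; each row must sum to 1
#'   within `1e-3` (rows are renormalized to sum exactly to 1).
#' @param name Optional motif name.
#' @return An object of class `pwm`.
#' @export
pwm <- function(matrix, name = "motif") {
  stopifnot(is.matrix(matrix), ncol(matrix) == 4L, nrow(matrix) >= 1L)
  if (any(matrix < 0)) stop("PWM entries must be nonnegative")
  rs <- rowSums(matrix)
  if (any(abs(rs - 1) > 1e-3)) {
    stop("PWM row sums deviate from 1 by more than 1e-3")
  }
  matrix <- matrix / rs
  colnames(matrix) <- DNA_BASES
  structure(matrix, name = name, class = c("pwm", "matrix", "array"))
}

#' Read a PWM from a plain-text matrix file
#'
#' The file holds one whitespace-separated numeric row per line; `#` lines are
#' comments (the first one, if any, names the motif). Two orientations exist
#' in the wild: positions-by-base (`Len x 4`, one motif position per line) and
#' the transposed base-by-positions dialect (`4 x Len`). With
#' `orientation = "auto"` the axis of size 4 decides; a 4 x 4 file is
#' ambiguous and requires an explicit orientation.
#'
#' @param path Path to the matrix file.
#' @param orientation `"auto"`, `"positions_by_base"` or `"base_by_positions"`.
#' @return A [pwm] object. Rows are renormalized if within `1e-3` of summing
#'   to 1, otherwise an error is raised.
#' @export
read_pwm <- function(path,
                     orientation = c("auto", "positions_by_base", "base_by_positions")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  comment <- grepl("^\\s*#", lines)
  name <- "motif"
  if (any(comment)) {
    name <- sub("^\\s*#\\s*", "", lines[comment][1])
    if (!nzchar(name)) name <- "motif"
  }
  lines <- trimws(lines[!comment])
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty PWM file: ", path)
  rows <- lapply(strsplit(lines, "\\s+"), as.numeric)
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop("ragged rows in PWM file: ", path)
  if (any(vapply(rows, function(r) any(is.na(r)), logical(1)))) {
    stop("non-numeric entries in PWM file: ", path)
  }
  M <- do.call(rbind, rows)
  if (orientation == "auto") {
    if (nrow(M) == 4L && ncol(M) == 4L) {
      stop("4 x 4 PWM file is orientation-ambiguous; pass `orientation`")
    }
    if (ncol(M) == 4L) orientation <- "positions_by_base"
    else if (nrow(M) == 4L) orientation <- "base_by_positions"
    else stop("PWM file has no axis of size 4")
  }
  if (orientation == "base_by_positions") M <- t(M)
  if (ncol(M) != 4L) stop("PWM must have 4 base columns, got ", ncol(M))
  pwm(M, name = name)
}

#' Write a PWM to a plain-text matrix file
#'
#' @param x A [pwm] object.
#' @param path Output path (positions-by-base orientation, `# name` header).
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  stopifnot(inherits(x, "pwm"))
  lines <- c(paste("#", attr(x, "name")),
             apply(unclass(x), 1L, function(r) paste(format(r, digits = 10), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Build a sharply peaked PWM from a consensus string
#'
#' Each position gives probability `max_prob` to the consensus base and
#' splits the remainder evenly over the other three. Convenient for toy
#' training data where the motif should be close to deterministic.
#'
#' @param consensus Character scalar over A/C/G/T.
#' @param max_prob Probability of the consensus base per position
#'   (default 0.97).
#' @return A [pwm] object.
#' @export
consensus_pwm <- function(consensus, max_prob = 0.97) {
  stopifnot(max_prob > 0.25, max_prob <= 1)
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  stopifnot(all(chars %in% DNA_BASES))
  M <- matrix((1 - max_prob) / 3, length(chars), 4L)
  M[cbind(seq_along(chars), match(chars, DNA_BASES))] <- max_prob
  pwm(M, name = consensus)
}

#' Consensus sequence of a PWM
#'
#' @param x A [pwm] object.
#' @return Character scalar: per-position argmax base (ties toward
#'   [DNA_BASES] order).
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[max.col(unclass(x), ties.method = "first")], collapse = "")
}

# ---- synthetic datasets -----------------------------------------------------

#' Consensus motifs for the synthetic sigma-promoter task
#'
#' One distinct 12-mer consensus per promoter class, loosely patterned on the
#' -35/-10 (sigma-24, sigma-32) and -24/-12 (sigma-54) box elements of
#' bacterial sigma-factor promoters. They define the learnable signal in the
#' synthetic 4-class classification task.
#'
#' @return Named character vector with entries `sigma24`, `sigma32`,
#'   `sigma54`.
#' @export
sigma_class_motifs <- function() {
  c(sigma24 = "GGAACTTTCTGA",
    sigma32 = "CTTGAAACCCCA",
    sigma54 = "TGGCACGCTTGC")
}

# sample one motif instance from a PWM (per-position categorical draw)
sample_motif_instance <- function(p) {
  Len <- nrow(p)
  idx <- vapply(seq_len(Len), function(j) {
    sample.int(4L, 1L, prob = p[j, ])
  }, integer(1))
  DNA_BASES[idx]
}

mutate_consensus <- function(chars, rate) {
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    for (i in which(hit)) {
      chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    }
  }
  chars
}

#' Simulate a synthetic sequence dataset
#'
#' Generates background DNA with a configurable per-base composition and,
#' optionally, (a) embeds one instance of a PWM motif (sampled per position)
#' at a uniform random offset with probability `motif_embed_prob`, or (b)
#' builds a balanced labeled promoter set in which each non-background class
#' embeds its consensus motif with a per-base mutation rate. Stands in for
#' unreleased training data in all examples and tests.
#'
#' @param n Number of sequences.
#' @param length Sequence length L.
#' @param background Length-4 base composition over [DNA_BASES]; must sum
#'   to 1 within 1e-9. Default uniform.
#' @param motif Optional [pwm] to embed.
#' @param motif_embed_prob Probability that a sequence carries a motif
#'   instance (default 1).
#' @param class_motifs Optional named character vector mapping promoter class
#'   labels to consensus strings, as from [sigma_class_motifs()]. When given,
#'   labels are balanced over `c("none", names(class_motifs))` and `motif` is
#'   ignored.
#' @param mutation_rate Per-base mutation probability applied to embedded
#'   class consensus motifs (default 0.05).
#' @param seed Integer seed; the simulation is bit-reproducible given it.
#' @return A list of class `synthetic_sequences` with elements `sequences`
#'   (named character vector), `labels` (factor, or `NULL` without
#'   `class_motifs`), `embedded` (logical: does the sequence carry a motif),
#'   and `offsets` (0-based embedding offset, `NA` when none).
#' @export
simulate_dataset <- function(n, length, background = rep(0.25, 4),
                             motif = NULL, motif_embed_prob = 1,
                             class_motifs = NULL, mutation_rate = 0.05,
                             seed = 1L) {
  stopifnot(n >= 1L, length >= 1L, length(background) == 4L)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (motif_embed_prob < 0 || motif_embed_prob > 1) {
    stop("motif_embed_prob must lie in [0, 1]")
  }
  with_seed(seed, {
    chars <- matrix(sample(DNA_BASES, n * length, replace = TRUE, prob = background),
                    nrow = n)
    embedded <- rep(FALSE, n)
    offsets <- rep(NA_integer_, n)
    labels <- NULL
    if (!is.null(class_motifs)) {
      classes <- c("none", names(class_motifs))
      labels <- factor(rep_len(classes, n), levels = classes)
      labels <- labels[sample.int(n)]
      for (i in seq_len(n)) {
        lab <- as.character(labels[i])
        if (lab == "none") next
        cons <- strsplit(class_motifs[[lab]], "", fixed = TRUE)[[1]]
        if (length(cons) > length) stop("class motif longer than sequence length")
        inst <- mutate_consensus(cons, mutation_rate)
        off <- sample.int(length - base::length(cons) + 1L, 1L) - 1L
        chars[i, (off + 1L):(off + base::length(cons))] <- inst
        embedded[i] <- TRUE
        offsets[i] <- off
      }
    } else if (!is.null(motif)) {
      Len <- nrow(motif)
      if (Len > length) stop("motif longer than sequence length")
      for (i in seq_len(n)) {
        if (stats::runif(1) < motif_embed_prob) {
          inst <- sample_motif_instance(motif)
          off <- sample.int(length - Len + 1L, 1L) - 1L
          chars[i, (off + 1L):(off + Len)] <- inst
          embedded[i] <- TRUE
          offsets[i] <- off
        }
      }
    }
    sequences <- apply(chars, 1L, paste, collapse = "")
    names(sequences) <- sprintf("sim_%d", seq_len(n))
    structure(
      list(sequences = sequences, labels = labels,
           embedded = embedded, offsets = offsets),
      class = "synthetic_sequences"
    )
  })
}

#' @export
print.synthetic_sequences <- function(x, ...) {
  cat("synthetic_sequences:", length(x$sequences), "sequences of length",
      nchar(x$sequences[[1]]), "\n")
  if (!is.null(x$labels)) {
    cat("labels:\n")
    print(table(x$labels))
  } else {
    cat(sum(x$embedded), "sequences carry an embedded motif\n")
  }
  invisible(x)
}

#' Write a two-column id/label table
#'
#' @param labels Factor or character vector of labels, named by sequence id
#'   (or supply `ids`).
#' @param path Output path (tab-separated, no header).
#' @param ids Optional sequence ids.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path, ids = names(labels)) {
  stopifnot(!is.null(ids), length(ids) == length(labels))
  utils::write.table(data.frame(id = ids, label = as.character(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column id/label table
#'
#' @param path Tab-separated file of `id<TAB>label` rows.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("id", "label"),
                          colClasses = "character")
  stats::setNames(df$label, df$id)
}
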