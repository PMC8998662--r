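# Independent oracles and small fixture builders shared across the suite.
# Oracles are deliberately naive (double loops, explicit recursion) and never
# share code with the implementation paths they check.

# central-difference numerical gradient of a scalar function
num_grad <- function(f, x, h = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# brute-force motif scan: explicit double loop over offsets and positions
brute_motif_score <- function(oh, p) {
  L <- nrow(oh)
  Len <- nrow(p)
  best <- -Inf
  best_off <- NA_integer_
  for (o in 0:(L - Len)) {
    s <- 0
    for (j in seq_len(Len)) {
      s <- s + sum(p[j, ] * oh[o + j, ])
    }
    if (s > best) {
      best <- s
      best_off <- o
    }
  }
  maxach <- 0
  for (j in seq_len(Len)) maxach <- maxach + max(p[j, ])
  list(raw_max = best, normalized = best / maxach, best_offset = best_off)
}

# discrete Frechet distance by the memoized recursive definition
recursive_frechet <- function(O, P) {
  if (is.null(dim(O))) O <- matrix(O, ncol = 1)
  if (is.null(dim(P))) P <- matrix(P, ncol = 1)
  memo <- new.env()
  d <- function(i, j) sqrt(sum((O[i, ] - P[j, ])^2))
  cf <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == 1 && j == 1) {
      d(1, 1)
    } else if (j == 1) {
      max(cf(i - 1, 1), d(i, 1))
    } else if (i == 1) {
      max(cf(1, j - 1), d(1, j))
    } else {
      max(min(cf(i - 1, j), cf(i - 1, j - 1), cf(i, j - 1)), d(i, j))
    }
    memo[[key]] <- v
    v
  }
  cf(nrow(O), nrow(P))
}

# per-item counting oracle for the confusion-derived metrics
counting_metrics <- function(truth, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] && pred[i]) tp <- tp + 1L
    else if (!truth[i] && !pred[i]) tn <- tn + 1L
    else if (!truth[i] && pred[i]) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

random_pwm <- function(len) {
  M <- matrix(stats::rexp(len * 4), len, 4)
  pwm(M / rowSums(M))
}

random_hard_seq <- function(L) {
  paste(sample(c("A", "T", "C", "G"), L, replace = TRUE), collapse = "")
}

# small generator/critic pair for fast structural tests
tiny_gan <- function(L = 12L, latent = 8L, channels = 8L, blocks = 1L,
                     gseed = 1L, cseed = 2L) {
  list(
    gen = build_generator(
      generator_config(latent_dim = latent, seq_len = L, channels = channels,
                       n_res_blocks = blocks, kernel = 3L), seed = gseed),
    critic = build_critic(
      critic_config(seq_len = L, channels = channels, n_res_blocks = blocks,
                    kernel = 3L), seed = cseed)
  )
}
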