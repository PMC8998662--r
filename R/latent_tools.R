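# Latent-space analyses of a trained generator: linear interpolation between
# latent points, gradient-based search for latent preimages of a target
# sequence, and reflection (negation through the origin) with a base-to-base
# complementation tally.

#' Linear interpolation between two latent points
#'
#' Decodes the affine path `(1 - a) * C1 + a * C2`, `a` evenly spaced on
#' `[0, 1]`, through the generator. The endpoints decode to exactly the
#' sequences generated from `C1` and `C2`.
#'
#' @param generator A [build_generator()] object.
#' @param C1,C2 Latent vectors of length `latent_dim`.
#' @param n_steps Number of points along the path (>= 2).
#' @return A list of class `interpolation_path`: `alphas`, `points`
#'   (`n_steps x latent_dim`), `decoded` (soft `onehot_batch`), `sequences`
#'   (hard decodings).
#' @export
interpolate <- function(generator, C1, C2, n_steps = 8L) {
  stopifnot(inherits(generator, "seq_generator"), n_steps >= 2L)
  d <- generator$cfg$latent_dim
  if (length(C1) != d || length(C2) != d) {
    stop("latent vectors must have dimension ", d)
  }
  alphas <- seq(0, 1, length.out = n_steps)
  points <- outer(1 - alphas, C1) + outer(alphas, C2)
  decoded <- generator_forward(generator, points)
  structure(list(alphas = alphas, points = points, decoded = decoded,
                 sequences = decode_batch(decoded)),
            class = "interpolation_path")
}

#' Gradient-based latent search for a target sequence
#'
#' Finds latent vectors whose decodings match a fixed target sequence:
#' starting from independent standard-normal initializations, minimizes the
#' per-position cross-entropy (in nats) between the generator's softmax
#' output and the target's one-hot encoding by Adam gradient descent through
#' the generator. Restarts whose final loss exceeds `tol` are dropped, so
#' the result may be empty.
#'
#' @param generator A [build_generator()] object.
#' @param target Target sequence: character scalar or `L x 4` hard one-hot
#'   matrix.
#' @param n_restarts Number of independent starts (default 5).
#' @param max_iters Gradient iterations per restart (default 200).
#' @param lr Adam learning rate on the latent vector (default 0.05).
#' @param tol Acceptance tolerance on the final loss, nats per position
#'   (default 0.1).
#' @param seed Integer seed.
#' @param init Optional matrix of starting points (`n_restarts x
#'   latent_dim`), overriding the random initialization.
#' @return A list with `latents` (matrix, one accepted vector per row,
#'   possibly zero rows), `losses` (final loss of every restart) and
#'   `accepted` (logical per restart).
#' @export
latent_search <- function(generator, target, n_restarts = 5L,
                          max_iters = 200L, lr = 0.05, tol = 0.1,
                          seed = 1L, init = NULL) {
  stopifnot(inherits(generator, "seq_generator"))
  L <- generator$cfg$seq_len
  d <- generator$cfg$latent_dim
  T_ <- if (is.character(target)) one_hot_encode(target) else target
  stopifnot(is.matrix(T_), nrow(T_) == L, ncol(T_) == 4L)
  Tflat <- matrix(as.vector(t(T_)), 1L)
  net <- generator$net
  params <- generator$params
  losses <- numeric(n_restarts)
  zs <- matrix(0, n_restarts, d)
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      z <- if (is.null(init)) matrix(stats::rnorm(d), 1L) else
        matrix(init[r, ], 1L)
      opt <- adam_init(list(z = z))
      loss <- Inf
      for (it in seq_len(max_iters)) {
        fw <- nn_forward(net, params, z)
        # per-position probability assigned to the target base
        p_true <- pmax(rowSums(matrix(fw$out * Tflat, L, 4L, byrow = TRUE)),
                       1e-12)
        loss <- -mean(log(p_true))
        if (loss < tol / 4) break
        dY <- matrix(-(as.vector(Tflat) / rep(p_true, each = 4L)) / L, 1L)
        dz <- nn_backward(net, params, fw$caches, dY)$dX
        st <- adam_step(list(z = z), list(z = dz), opt, lr, 0.9, 0.999)
        z <- st$params$z
        opt <- st$opt
      }
      losses[r] <- loss
      zs[r, ] <- z
    }
  })
  accepted <- losses <= tol
  list(latents = zs[accepted, , drop = FALSE], losses = losses,
       accepted = accepted)
}

#' Reflect a latent vector through the origin
#'
#' The latent prior is a standard normal, for which negation through the
#' origin is the natural reflection; it is a norm-preserving involution.
#'
#' @param z Latent vector or matrix of latent vectors (rows).
#' @return `-z`.
#' @export
reflect <- function(z) {
  -z
}

#' Base-complementation tally under latent reflection
#'
#' Samples latent vectors `z`, decodes `generator(z)` and `generator(-z)` to
#' hard sequences, and tallies position-wise which base the reflected
#' decoding produces for each base of the original decoding. A generator
#' that has internalized Watson-Crick complementarity shows high mass on
#' A<->T and G<->C.
#'
#' @param generator A [build_generator()] object.
#' @param n_samples Number of latent draws (positive).
#' @param seed Integer seed.
#' @return A 4 x 4 row-normalized matrix of class `complementation_report`
#'   (rows: base generated from `z`; columns: base generated at the same
#'   position from `-z`; rows sum to 1, or are `NA` for bases never
#'   generated). The raw counts are in the `counts` attribute.
#' @export
complementation_report <- function(generator, n_samples = 200L, seed = 1L) {
  stopifnot(inherits(generator, "seq_generator"))
  if (n_samples <= 0L) stop("n_samples must be positive")
  Z <- sample_latent(n_samples, generator$cfg$latent_dim, seed)
  A <- harden_batch(generator_forward(generator, Z))
  B <- harden_batch(generator_forward(generator, reflect(Z)))
  ai <- max.col(flat_to_blc(A, 4L), ties.method = "first")
  bi <- max.col(flat_to_blc(B, 4L), ties.method = "first")
  counts <- matrix(0, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  tb <- table(factor(ai, levels = 1:4), factor(bi, levels = 1:4))
  counts[] <- as.numeric(tb)
  rs <- rowSums(counts)
  M <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(M, counts = counts, n_samples = n_samples,
            class = c("complementation_report", "matrix", "array"))
}

#' Plot an interpolation path as a color raster
#'
#' Renders the decoded path with the conventional channel colors A = green,
#' C = blue, G = yellow, T = red; interpolation runs top to bottom, sequence
#' position left to right.
#'
#' @param x An [interpolate()] result.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the base-index matrix that was drawn.
#' @export
plot.interpolation_path <- function(x, ...) {
  idx <- t(vapply(x$sequences, function(s) {
    match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES)
  }, integer(nchar(x$sequences[[1]]))))
  cols <- c(A = "green3", T = "red3", C = "blue3", G = "gold")
  graphics::image(t(idx[rev(seq_len(nrow(idx))), , drop = FALSE]),
                  col = cols, zlim = c(1, 4), axes = FALSE,
                  xlab = "position", ylab = "interpolation", ...)
  invisible(idx)
}
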