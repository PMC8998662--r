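# Residual WGAN-GP generator and critic for one-hot DNA, with the critic /
# generator losses and the gradient penalty that enforces the critic's
# 1-Lipschitz constraint.
#
# Loss conventions (minimized quantities):
#   critic_loss      = E[D(fake)] - E[D(real)]      (drives real up, fake down)
#   gradient_penalty = lambda * E[(||grad_xhat D(xhat)||_2 - 1)^2]
#   generator_loss   = -E[D(fake)]
# The classical saturating min-max objective of the original GAN
# (min_G max_D E[log D(x)] + E[log(1 - D(G(z)))]) is background only; the
# package trains the Wasserstein form exclusively.

residual_block <- function(channels, kernel, scale) {
  nn_residual(
    list(
      nn_relu(),
      nn_conv1d(channels, channels, kernel, "same"),
      nn_relu(),
      nn_conv1d(channels, channels, kernel, "same")
    ),
    scale
  )
}

#' Generator configuration
#'
#' @param latent_dim Latent dimension (default 100); latent vectors are drawn
#'   from a standard normal.
#' @param seq_len Generated sequence length L.
#' @param channels Convolutional channel count C of the residual trunk.
#' @param n_res_blocks Number of residual blocks.
#' @param kernel Convolution kernel length (odd).
#' @param res_scale Residual scaling factor r in (0, 1]: each block computes
#'   `x + r * F(x)`.
#' @return A `generator_config` list.
#' @export
generator_config <- function(latent_dim = 100L, seq_len = 50L, channels = 64L,
                             n_res_blocks = 5L, kernel = 5L, res_scale = 0.3) {
  stopifnot(latent_dim >= 1L, seq_len >= 1L, channels >= 1L,
            n_res_blocks >= 0L, res_scale > 0, res_scale <= 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 seq_len = as.integer(seq_len),
                 channels = as.integer(channels),
                 n_res_blocks = as.integer(n_res_blocks),
                 kernel = as.integer(kernel), res_scale = res_scale),
            class = "generator_config")
}

#' Critic configuration
#'
#' @param seq_len Input sequence length L.
#' @inheritParams generator_config
#' @return A `critic_config` list.
#' @export
critic_config <- function(seq_len = 50L, channels = 64L, n_res_blocks = 5L,
                          kernel = 5L, res_scale = 0.3) {
  stopifnot(seq_len >= 1L, channels >= 1L, n_res_blocks >= 0L,
            res_scale > 0, res_scale <= 1)
  structure(list(seq_len = as.integer(seq_len),
                 channels = as.integer(channels),
                 n_res_blocks = as.integer(n_res_blocks),
                 kernel = as.integer(kernel), res_scale = res_scale),
            class = "critic_config")
}

#' Build the residual generator
#'
#' Architecture: `Linear(latent_dim -> L*C)` -> reshape to (L, C) ->
#' `n_res_blocks` residual blocks (ReLU -> Conv1d -> ReLU -> Conv1d, output
#' scaled by r and added to the block input) -> `Conv1d(C -> 4)` -> softmax
#' applied to each position separately, so every output row is a probability
#' distribution over [DNA_BASES].
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `seq_generator`.
#' @export
build_generator <- function(cfg = generator_config(), seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  layers <- c(
    list(nn_linear(cfg$latent_dim, cfg$seq_len * cfg$channels),
         nn_reshape(cfg$seq_len, cfg$channels)),
    lapply(seq_len(cfg$n_res_blocks), function(i) {
      residual_block(cfg$channels, cfg$kernel, cfg$res_scale)
    }),
    list(nn_conv1d(cfg$channels, 4L, cfg$kernel, "same"),
         nn_softmax(4L))
  )
  net <- structure(list(layers = layers), class = "nn_net")
  params <- with_seed(seed, nn_init(net))
  structure(list(net = net, params = params, cfg = cfg, seed = seed),
            class = "seq_generator")
}

#' Build the residual critic
#'
#' Architecture: `Conv1d(4 -> C)` -> `n_res_blocks` residual blocks ->
#' flatten -> `Linear(L*C -> 1)`. The output is an unbounded real score per
#' sequence (a Wasserstein critic has no final sigmoid). Both hard 0/1 and
#' soft softmax encodings are accepted; only the `(B, L*4)` shape is checked.
#'
#' @param cfg A [critic_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `seq_critic`.
#' @export
build_critic <- function(cfg = critic_config(), seed = 2L) {
  stopifnot(inherits(cfg, "critic_config"))
  layers <- c(
    list(nn_conv1d(4L, cfg$channels, cfg$kernel, "same")),
    lapply(seq_len(cfg$n_res_blocks), function(i) {
      residual_block(cfg$channels, cfg$kernel, cfg$res_scale)
    }),
    list(nn_flatten(),
         nn_linear(cfg$seq_len * cfg$channels, 1L))
  )
  net <- structure(list(layers = layers), class = "nn_net")
  params <- with_seed(seed, nn_init(net))
  structure(list(net = net, params = params, cfg = cfg, seed = seed),
            class = "seq_critic")
}

#' Sample latent vectors
#'
#' @param n Number of vectors.
#' @param latent_dim Latent dimension.
#' @param seed Optional seed (`NULL` draws from the current stream).
#' @return An `n x latent_dim` matrix of standard-normal draws.
#' @export
sample_latent <- function(n, latent_dim = 100L, seed = NULL) {
  with_seed(seed, matrix(stats::rnorm(n * latent_dim), n, latent_dim))
}

#' Run the generator on a batch of latent vectors
#'
#' @param generator A [build_generator()] object.
#' @param Z Latent matrix `(B, latent_dim)` (a single vector is accepted).
#' @return A soft `onehot_batch` matrix `(B, L*4)`; each position-row sums
#'   to 1.
#' @export
generator_forward <- function(generator, Z) {
  stopifnot(inherits(generator, "seq_generator"))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  if (ncol(Z) != generator$cfg$latent_dim) {
    stop("latent dimension mismatch: expected ", generator$cfg$latent_dim)
  }
  out <- nn_forward(generator$net, generator$params, Z, training = FALSE)$out
  structure(out, L = generator$cfg$seq_len, is_hard = FALSE,
            class = c("onehot_batch", "matrix", "array"))
}

# forward pass keeping caches (for backprop during training)
generator_forward_cached <- function(generator, Z) {
  nn_forward(generator$net, generator$params, Z, training = FALSE)
}

#' Score a batch of sequences with the critic
#'
#' @param critic A [build_critic()] object or a [custom_critic()].
#' @param X `(B, L*4)` one-hot batch (hard or soft).
#' @return Numeric vector of B unbounded real scores.
#' @export
critic_score <- function(critic, X) {
  UseMethod("critic_score")
}

#' @export
critic_score.seq_critic <- function(critic, X) {
  check_critic_input(critic, X)
  as.vector(nn_forward(critic$net, critic$params, X, training = FALSE)$out)
}

#' @export
critic_score.custom_critic <- function(critic, X) {
  as.vector(critic$score(X))
}

check_critic_input <- function(critic, X) {
  if (ncol(X) != critic$cfg$seq_len * 4L) {
    stop("critic expects sequences of length ", critic$cfg$seq_len,
         " (got ", ncol(X) / 4L, ")")
  }
  invisible(TRUE)
}

#' Per-item input gradient of the critic
#'
#' Returns the gradient of each sequence's score with respect to that
#' sequence's `L*4` input entries (scores are per-item, so the batch gradient
#' is block-diagonal and can be reported row-wise).
#'
#' @param critic A [build_critic()] object or a [custom_critic()].
#' @param X `(B, L*4)` batch.
#' @return Matrix of the same shape as `X`.
#' @export
critic_input_grad <- function(critic, X) {
  UseMethod("critic_input_grad")
}

#' @export
critic_input_grad.seq_critic <- function(critic, X) {
  check_critic_input(critic, X)
  fw <- nn_forward(critic$net, critic$params, X, training = FALSE)
  nn_backward(critic$net, critic$params, fw$caches,
              matrix(1, nrow(X), 1L))$dX
}

#' @export
critic_input_grad.custom_critic <- function(critic, X) {
  critic$input_grad(X)
}

#' Wrap arbitrary score/gradient functions as a critic
#'
#' Lets any differentiable scoring function with a known input gradient be
#' used wherever a critic is expected (losses, gradient penalty). Useful for
#' analytic diagnostics, e.g. a linear critic whose penalty has a closed form.
#'
#' @param score Function mapping a `(B, L*4)` matrix to B scores.
#' @param input_grad Function mapping the same matrix to the per-item input
#'   gradients (same shape as the input).
#' @return An object of class `custom_critic`.
#' @export
custom_critic <- function(score, input_grad) {
  stopifnot(is.function(score), is.function(input_grad))
  structure(list(score = score, input_grad = input_grad),
            class = "custom_critic")
}

#' Original critic loss
#'
#' `mean(D(fake)) - mean(D(real))`: minimizing it drives real scores up and
#' fake scores down, the Wasserstein max-over-critics objective written as a
#' minimization.
#'
#' @param critic Critic object.
#' @param real,fake `(B, L*4)` batches.
#' @return Scalar loss.
#' @export
critic_loss <- function(critic, real, fake) {
  if (nrow(real) == 0L || nrow(fake) == 0L) stop("empty batch")
  mean(critic_score(critic, fake)) - mean(critic_score(critic, real))
}

#' Generator loss
#'
#' `-mean(D(fake))`: the generator maximizes the critic's score of its
#' output.
#'
#' @param critic Critic object.
#' @param fake `(B, L*4)` batch of generated sequences.
#' @return Scalar loss.
#' @export
generator_loss <- function(critic, fake) {
  if (nrow(fake) == 0L) stop("empty batch")
  -mean(critic_score(critic, fake))
}

#' Gradient penalty
#'
#' Interpolates `xhat = eps * real + (1 - eps) * fake` with one
#' `eps ~ Uniform(0, 1)` per batch item, and returns
#' `lambda * mean((||grad_xhat D(xhat)||_2 - 1)^2)`, the gradient norm taken
#' over all `L*4` entries of each item. Zero exactly when every interpolate
#' has unit gradient norm.
#'
#' @param critic Critic object.
#' @param real,fake `(B, L*4)` batches of equal shape.
#' @param lambda Penalty weight (default 12).
#' @param seed Optional seed for the eps draws.
#' @return Scalar penalty (nonnegative).
#' @export
gradient_penalty <- function(critic, real, fake, lambda = 12, seed = NULL) {
  stopifnot(all(dim(real) == dim(fake)))
  if (nrow(real) == 0L) stop("empty batch")
  eps <- with_seed(seed, stats::runif(nrow(real)))
  xhat <- eps * real + (1 - eps) * fake
  g <- critic_input_grad(critic, xhat)
  norms <- sqrt(rowSums(g * g))
  lambda * mean((norms - 1)^2)
}

# gradient of the penalty w.r.t. critic parameters.
#
# d/dtheta (||g_i|| - 1)^2 = 2 (||g_i|| - 1) * d/dtheta (ghat_i . grad_x D),
# with ghat_i = g_i / ||g_i|| held fixed. The directional derivative
# ghat_i . grad_x D(xhat_i; theta) is realized as a central difference in
# input space, (D(xhat + h ghat) - D(xhat - h ghat)) / (2h): for a
# ReLU/conv/linear critic D is piecewise linear in x, so this is exact unless
# the segment [xhat - h ghat, xhat + h ghat] crosses an activation kink.
# This turns the second-order penalty gradient into two ordinary backward
# passes.
gradient_penalty_param_grads <- function(critic, real, fake, lambda,
                                         eps, h = 1e-4) {
  B <- nrow(real)
  xhat <- eps * real + (1 - eps) * fake
  g <- critic_input_grad(critic, xhat)
  norms <- sqrt(rowSums(g * g))
  safe <- pmax(norms, 1e-12)
  ghat <- g / safe
  w <- 2 * lambda * (norms - 1) / B
  fw_p <- nn_forward(critic$net, critic$params, xhat + h * ghat)
  gr_p <- nn_backward(critic$net, critic$params, fw_p$caches,
                      matrix(w / (2 * h), B, 1L))$grads
  fw_m <- nn_forward(critic$net, critic$params, xhat - h * ghat)
  gr_m <- nn_backward(critic$net, critic$params, fw_m$caches,
                      matrix(-w / (2 * h), B, 1L))$grads
  list(grads = param_map2(`+`, gr_p, gr_m),
       penalty = lambda * mean((norms - 1)^2))
}

# round soft generator output to hard one-hot (per-position argmax, ties to
# the first base in DNA_BASES order)
harden_batch <- function(X) {
  B <- nrow(X)
  P <- flat_to_blc(X, 4L)
  idx <- max.col(P, ties.method = "first")
  H <- matrix(0, nrow(P), 4L)
  H[cbind(seq_len(nrow(P)), idx)] <- 1
  structure(blc_to_flat(H, B), L = ncol(X) / 4L, is_hard = TRUE,
            class = c("onehot_batch", "matrix", "array"))
}
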