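test_that("generator emits valid position-wise distributions of the right shape", {
  gan <- tiny_gan(L = 12)
  Z <- sample_latent(5, 8, seed = 1)
  F <- generator_forward(gan$gen, Z)
  expect_equal(dim(F), c(5L, 12L * 4L))
  expect_lt(max(abs(rowSums(promogan:::flat_to_blc(F, 4L)) - 1)), 1e-6)
  # deterministic given weights: identical latents give identical outputs
  F2 <- generator_forward(gan$gen, Z)
  expect_identical(F, F2)
  Fdup <- generator_forward(gan$gen, Z[c(1, 1), ])
  expect_identical(Fdup[1, ], Fdup[2, ])
})

test_that("a zero residual scale makes each block the identity map", {
  blk <- promogan:::residual_block(6, 3, scale = 1)
  blk0 <- promogan:::residual_block(6, 3, scale = 1e-12)
  set.seed(4)
  params <- promogan:::nn_init_layer(blk)
  X <- matrix(rnorm(2 * 10 * 6), 2, 60)
  out1 <- promogan:::layer_forward(blk, params, X)$out
  expect_false(isTRUE(all.equal(out1, X)))
  blk0$scale <- 0
  out0 <- promogan:::layer_forward(blk0, params, X)$out
  expect_identical(out0, X)
})

test_that("critic returns one finite unbounded score per sequence", {
  gan <- tiny_gan(L = 12)
  F <- generator_forward(gan$gen, sample_latent(7, 8, seed = 2))
  s <- critic_score(gan$critic, F)
  expect_length(s, 7L)
  expect_true(all(is.finite(s)))
  # per-item independence: permuting the batch permutes the scores
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  expect_equal(critic_score(gan$critic, F[perm, ]), s[perm])
  # hard encodings are accepted too
  expect_length(critic_score(gan$critic, promogan:::harden_batch(F)), 7L)
  expect_error(critic_score(gan$critic, F[, 1:8]), "length")
})

test_that("critic and generator losses obey their algebraic identities", {
  gan <- tiny_gan(L = 12)
  F <- generator_forward(gan$gen, sample_latent(6, 8, seed = 3))
  R <- promogan:::harden_batch(generator_forward(gan$gen, sample_latent(6, 8, seed = 4)))
  expect_equal(critic_loss(gan$critic, F, F), 0)
  const <- custom_critic(function(X) rep(2.5, nrow(X)),
                         function(X) matrix(0, nrow(X), ncol(X)))
  expect_equal(critic_loss(const, R, F), 0)
  expect_equal(generator_loss(const, F), -2.5)
  # generator_loss + mean real score = -critic_loss
  expect_equal(generator_loss(gan$critic, F) + mean(critic_score(gan$critic, R)),
               -critic_loss(gan$critic, R, F))
  # linearity: doubling the critic doubles the generator loss
  dbl <- custom_critic(function(X) 2 * critic_score(gan$critic, X),
                       function(X) 2 * critic_input_grad(gan$critic, X))
  expect_equal(generator_loss(dbl, F), 2 * generator_loss(gan$critic, F))
  expect_error(critic_loss(gan$critic, R[0, , drop = FALSE], F), "empty")
  # hand-computed toy: linear critic w . x on a 1-position alphabet
  w <- c(1, -1, 2, 0)
  lin <- custom_critic(function(X) X %*% w,
                       function(X) matrix(w, nrow(X), 4, byrow = TRUE))
  real1 <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))   # A, T -> scores 1, -1
  fake1 <- rbind(c(0, 0, 1, 0), c(0, 0, 1, 0))   # C, C -> scores 2, 2
  expect_equal(critic_loss(lin, real1, fake1), 2 - 0)
})

test_that("gradient penalty matches closed forms for analytic critics", {
  L <- 1L
  real <- matrix(runif(8 * 4), 8, 4)
  fake <- matrix(runif(8 * 4), 8, 4)
  # sum-of-entries critic: gradient norm sqrt(4L) = 2 everywhere
  cc_sum <- custom_critic(function(X) rowSums(X),
                          function(X) matrix(1, nrow(X), ncol(X)))
  expect_equal(gradient_penalty(cc_sum, real, fake, lambda = 12, seed = 1),
               12 * (sqrt(4 * L) - 1)^2)
  # unit-gradient critic: penalty exactly 0
  cc_unit <- custom_critic(function(X) rowSums(X) / sqrt(4 * L),
                           function(X) matrix(1 / sqrt(4 * L), nrow(X), ncol(X)))
  expect_equal(gradient_penalty(cc_unit, real, fake, lambda = 12, seed = 1), 0)
  # lambda = 0 kills the penalty for any critic
  expect_equal(gradient_penalty(cc_sum, real, fake, lambda = 0, seed = 1), 0)
  # penalty is nonnegative for a real critic
  gan <- tiny_gan(L = 12)
  F <- generator_forward(gan$gen, sample_latent(8, 8, seed = 5))
  H <- promogan:::harden_batch(generator_forward(gan$gen, sample_latent(8, 8, seed = 6)))
  expect_gte(gradient_penalty(gan$critic, H, F, 12, seed = 2), 0)
})

test_that("penalty parameter gradients match numerical differentiation", {
  gan <- tiny_gan(L = 6, channels = 4, blocks = 1)
  critic <- gan$critic
  set.seed(31)
  real <- promogan:::harden_batch(
    generator_forward(gan$gen, sample_latent(4, 8)))
  fake <- generator_forward(gan$gen, sample_latent(4, 8))
  eps <- runif(4)
  res <- promogan:::gradient_penalty_param_grads(critic, real, fake,
                                                 lambda = 12, eps = eps)
  penalty_at <- function(v) {
    pos <- 0L
    p <- promogan:::param_map(function(x) {
      n <- length(x)
      out <- v[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (!is.null(dim(x))) dim(out) <- dim(x)
      out
    }, critic$params)
    c2 <- critic
    c2$params <- p
    xhat <- eps * real + (1 - eps) * fake
    g <- critic_input_grad(c2, xhat)
    12 * mean((sqrt(rowSums(g * g)) - 1)^2)
  }
  v0 <- unlist(critic$params)
  expect_equal(res$penalty, penalty_at(v0), tolerance = 1e-10)
  gnum <- num_grad(penalty_at, v0, h = 1e-5)
  gan_grads <- unlist(res$grads)
  expect_lt(max(abs(gnum - gan_grads)), 1e-4)
})

test_that("a fixed-seed training step is bit-reproducible", {
  gan <- tiny_gan(L = 12)
  sim <- simulate_dataset(40, 12, seed = 8)
  sch <- training_schedule(batch_size = 8, critic_steps_per_gen = 2, seed = 5)
  st1 <- feedback_gan(gan$gen, gan$critic, sim$sequences, schedule = sch)
  st2 <- feedback_gan(gan$gen, gan$critic, sim$sequences, schedule = sch)
  st1 <- wgan_gp_step(st1, seed = 77)
  st2 <- wgan_gp_step(st2, seed = 77)
  expect_identical(st1$generator$params, st2$generator$params)
  expect_identical(st1$critic$params, st2$critic$params)
  expect_identical(st1$log, st2$log)
})

test_that("training shifts single-position base frequencies toward the target", {
  # 1-position toy: real data drawn 0.7/0.1/0.1/0.1 over A/T/C/G. A short run
  # must at least cut the total-variation distance; the full 2000-step run
  # driving TV below 0.1 is exercised in the acceptance suite.
  target <- c(0.7, 0.1, 0.1, 0.1)
  real <- with_seed(11, sample(DNA_BASES, 256, TRUE, prob = target))
  gcfg <- generator_config(latent_dim = 8, seq_len = 1, channels = 8,
                           n_res_blocks = 1, kernel = 5)
  ccfg <- critic_config(seq_len = 1, channels = 8, n_res_blocks = 1, kernel = 5)
  st <- feedback_gan(build_generator(gcfg, 1), build_critic(ccfg, 2), real,
                     schedule = training_schedule(batch_size = 32,
                                                  max_steps = 300,
                                                  stop_patience = 0,
                                                  lr = 1e-3, seed = 7))
  tv <- function(state) {
    gs <- generate_sequences(state, 500, seed = 123)
    freq <- table(factor(gs$sequence, levels = DNA_BASES)) / 500
    0.5 * sum(abs(as.numeric(freq) - target))
  }
  tv0 <- tv(st)
  for (i in seq_len(300)) st <- wgan_gp_step(st)
  expect_lt(tv(st), tv0)
})
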