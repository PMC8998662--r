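# Feedback training loop: the generator's output is hard-decoded and gated by
# the promoter classifier, then by the PWM evaluator; only sequences passing
# both gates (padded by a ranked fallback) reach the critic. Gating decisions
# are made on hard argmax decodings while the critic consumes the
# corresponding soft softmax outputs, keeping the generator update
# differentiable. The predictor and the PWM are frozen during GAN training.

#' Training schedule
#'
#' @param batch_size Sequences per batch (default 32).
#' @param critic_steps_per_gen Critic updates per generator update
#'   (default 5).
#' @param max_steps Maximum number of feedback steps for [train_feedback()].
#' @param fallback_top_k When fewer than `batch_size` generated sequences
#'   pass both gates, the fake batch is padded with up to `fallback_top_k`
#'   rejected sequences ranked by promoter probability times normalized motif
#'   score (recycled if still short). Defaults to `batch_size`.
#' @param stop_patience Window (in steps) of the critic-loss moving average
#'   used for plateau detection; the run stops early when the absolute change
#'   between consecutive window means falls below `1e-3`. `0` disables early
#'   stopping.
#' @param lambda_gp Gradient-penalty weight (default 12).
#' @param lr Adam learning rate for both networks (default 1e-4).
#' @param beta1,beta2 Adam moment coefficients (defaults 0 and 0.9, the
#'   conventional setting for gradient-penalty critics).
#' @param seed Run seed; every stochastic draw of the run derives from it.
#' @return A `training_schedule` list.
#' @export
training_schedule <- function(batch_size = 32L, critic_steps_per_gen = 5L,
                              max_steps = 500L, fallback_top_k = batch_size,
                              stop_patience = 50L, lambda_gp = 12,
                              lr = 1e-4, beta1 = 0, beta2 = 0.9, seed = 1L) {
  stopifnot(batch_size >= 1L, critic_steps_per_gen >= 1L, max_steps >= 0L,
            fallback_top_k >= 1L, fallback_top_k <= batch_size,
            stop_patience >= 0L, lambda_gp >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 critic_steps_per_gen = as.integer(critic_steps_per_gen),
                 max_steps = as.integer(max_steps),
                 fallback_top_k = as.integer(fallback_top_k),
                 stop_patience = as.integer(stop_patience),
                 lambda_gp = lambda_gp, lr = lr,
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed)),
            class = "training_schedule")
}

#' Assemble a feedback GAN training state
#'
#' Bundles the generator, critic, frozen gates and real data into a single
#' state object that [feedback_step()], [wgan_gp_step()] and
#' [train_feedback()] advance. With `predictor = NULL` and `pwm = NULL` the
#' gates are absent and training reduces to plain WGAN-GP.
#'
#' @param generator A [build_generator()] object.
#' @param critic A [build_critic()] object with matching `seq_len`.
#' @param real_seqs Character vector of real training sequences, all of
#'   length `seq_len` (sequences of any other length are rejected, not
#'   padded); must contain at least `batch_size` sequences.
#' @param predictor Optional trained [promoter_predictor][build_predictor]
#'   (first gate).
#' @param pwm Optional [pwm] (second gate).
#' @param threshold Normalized motif-score threshold of the evaluator gate
#'   (default 0.75).
#' @param schedule A [training_schedule()].
#' @return An object of class `feedback_gan`.
#' @export
feedback_gan <- function(generator, critic, real_seqs, predictor = NULL,
                         pwm = NULL, threshold = 0.75,
                         schedule = training_schedule()) {
  stopifnot(inherits(generator, "seq_generator"),
            inherits(critic, "seq_critic"),
            inherits(schedule, "training_schedule"))
  if (!length(real_seqs)) stop("empty real data")
  L <- generator$cfg$seq_len
  if (critic$cfg$seq_len != L) stop("generator/critic sequence length mismatch")
  if (any(nchar(real_seqs) != L)) {
    stop("all real sequences must have length ", L, " (no padding/truncation)")
  }
  if (length(real_seqs) < schedule$batch_size) {
    stop("need at least batch_size = ", schedule$batch_size, " real sequences")
  }
  if (!is.null(predictor)) stopifnot(inherits(predictor, "promoter_predictor"))
  if (!is.null(pwm)) stopifnot(inherits(pwm, "pwm"))
  structure(list(
    generator = generator, critic = critic,
    predictor = predictor, pwm = pwm, threshold = threshold,
    schedule = schedule,
    real = encode_batch(real_seqs),
    opt_g = adam_init(generator$params),
    opt_c = adam_init(critic$params),
    step = 0L,
    log = NULL
  ), class = "feedback_gan")
}

# gate a soft generated batch: hard-decode, apply predictor then evaluator,
# pad with ranked fallback so the critic always receives a full batch.
# Deterministic (consumes no RNG).
gate_select <- function(state, F) {
  B <- nrow(F)
  H <- harden_batch(F)
  if (!is.null(state$predictor)) {
    P <- predictor_probs(state$predictor, H)
    is_prom <- max.col(P, ties.method = "first") != 1L
    prom_prob <- 1 - P[, 1L]
  } else {
    is_prom <- rep(TRUE, B)
    prom_prob <- rep(1, B)
  }
  if (!is.null(state$pwm)) {
    sc <- motif_score_batch(H, state$pwm)$normalized
    pass_eval <- is_prom & (sc > state$threshold)
  } else {
    sc <- rep(NA_real_, B)
    pass_eval <- is_prom
  }
  sel <- which(pass_eval)
  need <- B - length(sel)
  if (need > 0L) {
    cand <- which(!pass_eval)
    rank_score <- prom_prob[cand] * ifelse(is.na(sc[cand]), 1, sc[cand])
    cand <- cand[order(rank_score, decreasing = TRUE)]
    cand <- cand[seq_len(min(state$schedule$fallback_top_k, length(cand)))]
    sel <- c(sel, rep_len(cand, need))
  }
  list(sel = sel,
       n_pass_predictor = sum(is_prom),
       n_pass_evaluator = sum(pass_eval),
       mean_motif_score = if (all(is.na(sc))) NA_real_ else mean(sc))
}

# one critic update; RNG draws in order: real indices, latent batch, eps.
# `gated` switches the feedback gates on/off (off = plain WGAN-GP).
critic_update <- function(state, gated) {
  sch <- state$schedule
  bs <- sch$batch_size
  idx <- sample.int(nrow(state$real), bs)
  real_b <- state$real[idx, , drop = FALSE]
  Z <- matrix(stats::rnorm(bs * state$generator$cfg$latent_dim), bs,
              state$generator$cfg$latent_dim)
  F <- generator_forward(state$generator, Z)
  sel <- if (gated) gate_select(state, F)$sel else seq_len(bs)
  fake <- F[sel, , drop = FALSE]
  eps <- stats::runif(bs)

  cnet <- state$critic$net
  cp <- state$critic$params
  fw_f <- nn_forward(cnet, cp, fake)
  fw_r <- nn_forward(cnet, cp, real_b)
  loss_orig <- mean(fw_f$out) - mean(fw_r$out)
  gr_f <- nn_backward(cnet, cp, fw_f$caches, matrix(1 / bs, bs, 1L))$grads
  gr_r <- nn_backward(cnet, cp, fw_r$caches, matrix(-1 / bs, bs, 1L))$grads
  gp <- gradient_penalty_param_grads(state$critic, real_b, fake,
                                     sch$lambda_gp, eps)
  grads <- param_map2(`+`, param_map2(`+`, gr_f, gr_r), gp$grads)
  st <- adam_step(cp, grads, state$opt_c, sch$lr, sch$beta1, sch$beta2)
  state$critic$params <- st$params
  state$opt_c <- st$opt
  state$last_critic <- list(loss = loss_orig, penalty = gp$penalty)
  state
}

# one generator update; RNG draws: latent batch only
generator_update <- function(state, gated) {
  sch <- state$schedule
  bs <- sch$batch_size
  Z <- matrix(stats::rnorm(bs * state$generator$cfg$latent_dim), bs,
              state$generator$cfg$latent_dim)
  fwg <- generator_forward_cached(state$generator, Z)
  F <- fwg$out
  gate <- if (gated) {
    gate_select(state, F)
  } else {
    list(sel = seq_len(bs), n_pass_predictor = bs, n_pass_evaluator = bs,
         mean_motif_score = NA_real_)
  }
  fake <- F[gate$sel, , drop = FALSE]
  cnet <- state$critic$net
  cp <- state$critic$params
  fw_c <- nn_forward(cnet, cp, fake)
  gloss <- -mean(fw_c$out)
  dfake <- nn_backward(cnet, cp, fw_c$caches, matrix(-1 / bs, bs, 1L))$dX
  dF <- matrix(0, bs, ncol(F))
  acc <- rowsum(dfake, group = gate$sel)
  dF[as.integer(rownames(acc)), ] <- acc
  g_grads <- nn_backward(state$generator$net, state$generator$params,
                         fwg$caches, dF)$grads
  st <- adam_step(state$generator$params, g_grads, state$opt_g,
                  sch$lr, sch$beta1, sch$beta2)
  state$generator$params <- st$params
  state$opt_g <- st$opt
  state$last_gen <- list(loss = gloss, gate = gate)
  state
}

run_step <- function(state, seed, gated) {
  sch <- state$schedule
  if (is.null(seed)) seed <- derive_seed(sch$seed, state$step + 1L)
  with_seed(seed, {
    closs <- numeric(sch$critic_steps_per_gen)
    cpen <- numeric(sch$critic_steps_per_gen)
    for (s in seq_len(sch$critic_steps_per_gen)) {
      state <- critic_update(state, gated)
      closs[s] <- state$last_critic$loss
      cpen[s] <- state$last_critic$penalty
    }
    state <- generator_update(state, gated)
  })
  gate <- state$last_gen$gate
  state$step <- state$step + 1L
  row <- data.frame(step = state$step,
                    critic_loss = mean(closs),
                    gradient_penalty = mean(cpen),
                    generator_loss = state$last_gen$loss,
                    n_pass_predictor = gate$n_pass_predictor,
                    n_pass_evaluator = gate$n_pass_evaluator,
                    mean_motif_score = gate$mean_motif_score)
  state$log <- rbind(state$log, row)
  state
}

#' One feedback training step
#'
#' Performs `critic_steps_per_gen` critic updates followed by one generator
#' update. Each critic update draws a fresh real batch, generates a fresh
#' fake batch, gates it (predictor first, evaluator second, both applied to
#' hard decodings), pads by the fallback rule, and applies the WGAN-GP
#' critic objective. The generator update maximizes the critic's score of
#' its gated soft outputs.
#'
#' @param state A [feedback_gan()] state.
#' @param seed Step seed; defaults to a substream derived from the schedule
#'   seed and the step index. Fixed seed + fixed state gives bit-identical
#'   results.
#' @return The advanced state; `state$log` gains one row (step index, critic
#'   loss, gradient penalty, generator loss, gate pass counts, mean
#'   normalized motif score of the generated batch).
#' @export
feedback_step <- function(state, seed = NULL) {
  stopifnot(inherits(state, "feedback_gan"))
  run_step(state, seed, gated = TRUE)
}

#' One plain WGAN-GP step (no feedback gates)
#'
#' Identical update schedule to [feedback_step()] but every generated
#' sequence reaches the critic. With an accept-everything predictor and a
#' zero evaluator threshold, [feedback_step()] reproduces this step
#' bit-for-bit under the same seed.
#'
#' @inheritParams feedback_step
#' @return The advanced state.
#' @export
wgan_gp_step <- function(state, seed = NULL) {
  stopifnot(inherits(state, "feedback_gan"))
  run_step(state, seed, gated = FALSE)
}

#' Run the feedback training loop
#'
#' Advances the state by up to `max_steps` feedback steps, stopping early
#' when the critic loss plateaus (the operational reading of generator and
#' critic reaching equilibrium): when the absolute change between the means
#' of two consecutive `stop_patience`-step windows of the critic loss falls
#' below `1e-3`.
#'
#' @param state A [feedback_gan()] state.
#' @param max_steps Overrides `schedule$max_steps` when given.
#' @param verbose Print a progress line every 50 steps.
#' @return The trained state (models, optimizer states and the step log).
#' @export
train_feedback <- function(state, max_steps = NULL, verbose = FALSE) {
  stopifnot(inherits(state, "feedback_gan"))
  max_steps <- max_steps %||% state$schedule$max_steps
  pat <- state$schedule$stop_patience
  n_done <- 0L
  while (n_done < max_steps) {
    state <- feedback_step(state)
    n_done <- n_done + 1L
    if (verbose && n_done %% 50L == 0L) {
      message(sprintf("step %5d  critic %8.4f  gen %8.4f  pass %d/%d",
                      state$step, utils::tail(state$log$critic_loss, 1),
                      utils::tail(state$log$generator_loss, 1),
                      utils::tail(state$log$n_pass_evaluator, 1),
                      state$schedule$batch_size))
    }
    if (pat > 0L && nrow(state$log) >= 2L * pat) {
      cl <- state$log$critic_loss
      recent <- mean(cl[(length(cl) - pat + 1L):length(cl)])
      prev <- mean(cl[(length(cl) - 2L * pat + 1L):(length(cl) - pat)])
      if (abs(recent - prev) < 1e-3) break
    }
  }
  state
}

#' Generate sequences from a trained generator
#'
#' Samples latent vectors, decodes the generator's soft output to hard
#' sequences, and optionally annotates each sequence with the gate
#' diagnostics (promoter class and probability, motif score, pass flags).
#'
#' @param x A `feedback_gan` state or a `seq_generator`.
#' @param n Number of sequences (positive).
#' @param seed Integer seed for the latent draws.
#' @param annotate Attach gate annotations when the gates are available
#'   (default `TRUE`; only possible for a `feedback_gan` state).
#' @return A data frame with columns `id`, `sequence` and, when annotated,
#'   `predicted_class`, `promoter_prob`, `motif_raw`, `motif_normalized`,
#'   `pass_predictor`, `pass_evaluator`.
#' @export
generate_sequences <- function(x, n, seed = 1L, annotate = TRUE) {
  if (n <= 0L) stop("n must be positive")
  gen <- if (inherits(x, "feedback_gan")) x$generator else x
  stopifnot(inherits(gen, "seq_generator"))
  Z <- sample_latent(n, gen$cfg$latent_dim, seed)
  F <- generator_forward(gen, Z)
  seqs <- decode_batch(F)
  out <- data.frame(id = sprintf("gen_%d", seq_len(n)), sequence = seqs)
  if (annotate && inherits(x, "feedback_gan") &&
      (!is.null(x$predictor) || !is.null(x$pwm))) {
    H <- harden_batch(F)
    if (!is.null(x$predictor)) {
      P <- predictor_probs(x$predictor, H)
      ci <- max.col(P, ties.method = "first")
      out$predicted_class <- x$predictor$cfg$classes[ci]
      out$promoter_prob <- 1 - P[, 1L]
      out$pass_predictor <- ci != 1L
    }
    if (!is.null(x$pwm)) {
      sc <- motif_score_batch(H, x$pwm)
      out$motif_raw <- sc$raw_max
      out$motif_normalized <- sc$normalized
      out$pass_evaluator <- (out$pass_predictor %||% TRUE) &
        (sc$normalized > x$threshold)
    }
  }
  out
}

#' Save / load a training checkpoint
#'
#' Checkpoints carry the generator and critic (weights and configs), the
#' frozen gates, optimizer states, the schedule (including the run seed) and
#' the step log.
#'
#' @param state A `feedback_gan` state.
#' @param path File path.
#' @return `path` invisibly; `load_checkpoint` returns the state.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "feedback_gan"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  stopifnot(inherits(state, "feedback_gan"))
  state
}
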