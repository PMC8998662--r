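# Layered CNN promoter classifier: decides whether a sequence looks like a
# promoter and, if so, which sigma-factor subtype it belongs to. Acts as the
# first gate of the feedback loop.

#' Predictor configuration
#'
#' The classifier is a fixed two-stage convolutional architecture:
#' `[Conv1d -> ReLU -> MaxPool(pool_window) -> Dropout(dropout_p)] x 2 ->
#' Flatten -> FullyConnected(n_classes) -> softmax`. Pooling is
#' non-overlapping (stride = window).
#'
#' @param seq_len Input sequence length L; must be at least `pool_window^2`
#'   so both pooling stages see a full window. Pooling keeps a short final
#'   window, so no trailing positions are discarded.
#' @param conv_channels Channel counts of the two convolutional layers.
#' @param kernels Kernel lengths of the two convolutional layers (odd).
#' @param pool_window Max-pooling window (default 6).
#' @param dropout_p Dropout probability (default 0.5), active only while
#'   training.
#' @param classes Class labels; the first is the non-promoter class.
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(seq_len, conv_channels = c(32L, 64L),
                             kernels = c(7L, 5L), pool_window = 6L,
                             dropout_p = 0.5,
                             classes = c("none", "sigma24", "sigma32", "sigma54")) {
  stopifnot(length(conv_channels) == 2L, length(kernels) == 2L,
            pool_window >= 1L, dropout_p >= 0, dropout_p < 1,
            length(classes) >= 2L)
  if (seq_len < pool_window^2) {
    stop("seq_len = ", seq_len, " too short for two pooling stages of window ",
         pool_window)
  }
  L1 <- as.integer(ceiling(seq_len / pool_window))
  L2 <- as.integer(ceiling(L1 / pool_window))
  structure(list(seq_len = as.integer(seq_len),
                 conv_channels = as.integer(conv_channels),
                 kernels = as.integer(kernels),
                 pool_window = as.integer(pool_window),
                 dropout_p = dropout_p,
                 classes = classes,
                 n_classes = length(classes),
                 flat_dim = as.integer(L2 * conv_channels[2])),
            class = "predictor_config")
}

#' Build the layered-CNN promoter classifier
#'
#' @param cfg A [predictor_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `promoter_predictor` (untrained).
#' @export
build_predictor <- function(cfg, seed = 3L) {
  stopifnot(inherits(cfg, "predictor_config"))
  layers <- list(
    nn_conv1d(4L, cfg$conv_channels[1], cfg$kernels[1], "same"),
    nn_relu(),
    nn_maxpool(cfg$pool_window, cfg$conv_channels[1]),
    nn_dropout(cfg$dropout_p),
    nn_conv1d(cfg$conv_channels[1], cfg$conv_channels[2], cfg$kernels[2], "same"),
    nn_relu(),
    nn_maxpool(cfg$pool_window, cfg$conv_channels[2]),
    nn_dropout(cfg$dropout_p),
    nn_flatten(),
    nn_linear(cfg$flat_dim, cfg$n_classes),
    nn_softmax(cfg$n_classes)
  )
  net <- structure(list(layers = layers), class = "nn_net")
  params <- with_seed(seed, nn_init(net))
  structure(list(net = net, params = params, cfg = cfg, seed = seed,
                 trained = FALSE, history = NULL),
            class = "promoter_predictor")
}

#' Describe the predictor architecture
#'
#' Introspects a built predictor layer by layer; useful for verifying the
#' structural contract (two convolutions, pooling window, dropout rate).
#'
#' @param predictor A [build_predictor()] object.
#' @return A data frame with columns `layer` (kind) and `detail`.
#' @export
predictor_architecture <- function(predictor) {
  stopifnot(inherits(predictor, "promoter_predictor"))
  rows <- lapply(predictor$net$layers, function(l) {
    detail <- switch(l$kind,
      conv1d = sprintf("%d -> %d channels, kernel %d", l$c_in, l$c_out, l$kernel),
      maxpool = sprintf("window %d", l$window),
      dropout = sprintf("p = %g", l$p),
      linear = sprintf("%d -> %d", l$d_in, l$d_out),
      softmax = sprintf("%d classes", l$channels),
      ""
    )
    data.frame(layer = l$kind, detail = detail)
  })
  do.call(rbind, rows)
}

# class-probability matrix, eval mode (deterministic)
predictor_probs <- function(predictor, X) {
  if (is.character(X)) X <- encode_batch(X)
  if (ncol(X) != predictor$cfg$seq_len * 4L) {
    stop("predictor expects sequences of length ", predictor$cfg$seq_len)
  }
  P <- nn_forward(predictor$net, predictor$params, X, training = FALSE)$out
  colnames(P) <- predictor$cfg$classes
  P
}

#' Predict promoter classes
#'
#' @param object A `promoter_predictor`.
#' @param newdata Character vector of sequences or an `onehot_batch` matrix.
#' @param ... Unused.
#' @return A data frame with one row per sequence: class probabilities,
#'   `predicted_class`, `is_promoter` (predicted class is not the
#'   non-promoter class) and `max_prob`.
#' @export
predict.promoter_predictor <- function(object, newdata, ...) {
  ids <- if (is.character(newdata) && !is.null(names(newdata))) {
    names(newdata)
  } else {
    sprintf("seq_%d", seq_len(if (is.character(newdata)) length(newdata) else nrow(newdata)))
  }
  P <- predictor_probs(object, newdata)
  pred_i <- max.col(P, ties.method = "first")
  out <- data.frame(id = ids, P,
                    predicted_class = factor(object$cfg$classes[pred_i],
                                             levels = object$cfg$classes),
                    is_promoter = pred_i != 1L,
                    max_prob = P[cbind(seq_len(nrow(P)), pred_i)])
  rownames(out) <- NULL
  out
}

#' Train the promoter classifier
#'
#' Minimizes multiclass cross-entropy with Adam over shuffled minibatches.
#' Deterministic given `seed` (which drives shuffling and dropout).
#'
#' @param predictor A [build_predictor()] object.
#' @param seqs Character vector of training sequences (length
#'   `cfg$seq_len`).
#' @param labels Vector of class labels; every label must be one of
#'   `cfg$classes` and at least two classes must be present.
#' @param epochs Number of passes over the data.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss/accuracy.
#' @return The trained predictor, with a `history` data frame (`epoch`,
#'   `loss`, `accuracy`).
#' @export
train_predictor <- function(predictor, seqs, labels, epochs = 20L,
                            batch_size = 64L, lr = 1e-2, seed = 1L,
                            verbose = FALSE) {
  stopifnot(inherits(predictor, "promoter_predictor"),
            length(seqs) == length(labels))
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), predictor$cfg$classes)
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  if (length(unique(labels)) < 2L) stop("training data contains a single class")
  X <- encode_batch(seqs)
  y <- match(labels, predictor$cfg$classes)
  n <- nrow(X)
  K <- predictor$cfg$n_classes
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y)] <- 1
  net <- predictor$net
  params <- predictor$params
  opt <- adam_init(params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        nb <- length(idx)
        fw <- nn_forward(net, params, X[idx, , drop = FALSE], training = TRUE)
        P <- fw$out
        Yb <- Y[idx, , drop = FALSE]
        p_true <- pmax(rowSums(P * Yb), 1e-12)
        ep_loss <- ep_loss - sum(log(p_true))
        ep_correct <- ep_correct +
          sum(max.col(P, ties.method = "first") == y[idx])
        dY <- -(Yb / p_true) / nb
        grads <- nn_backward(net, params, fw$caches, dY)$grads
        st <- adam_step(params, grads, opt, lr, 0.9, 0.999)
        params <- st$params
        opt <- st$opt
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ep_loss / n,
                                  accuracy = ep_correct / n))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f",
                        epoch, ep_loss / n, ep_correct / n))
      }
    }
  })
  predictor$params <- params
  predictor$trained <- TRUE
  predictor$history <- history
  predictor
}

#' Split sequences by predicted promoter status
#'
#' Partitions the input into sequences the classifier calls promoters (any
#' sigma class) and the rest. The partition is exhaustive, disjoint and
#' order-stable within each part.
#'
#' @param predictor A trained `promoter_predictor`.
#' @param seqs Character vector of sequences.
#' @return A list with elements `passed` and `rejected` (character vectors)
#'   and `prediction` (the full prediction data frame).
#' @export
filter_promoters <- function(predictor, seqs) {
  pred <- predict(predictor, seqs)
  list(passed = seqs[pred$is_promoter],
       rejected = seqs[!pred$is_promoter],
       prediction = pred)
}

#' Stratified k-fold cross-validation of the promoter classifier
#'
#' Splits each class into k near-equal folds, trains a fresh predictor on
#' k-1 folds, and evaluates on the held-out fold. One-vs-rest confusion
#' counts are pooled over folds and summarized with [classifier_metrics()]
#' (accuracy, Matthews correlation coefficient, sensitivity, specificity per
#' class).
#'
#' @param cfg A [predictor_config()] describing the model to build per fold.
#' @param seqs Character vector of sequences.
#' @param labels Class labels (each class needs at least `k` members).
#' @param k Number of folds (default 10).
#' @param seed Integer seed (fold assignment and per-fold training).
#' @param epochs,batch_size,lr Passed to [train_predictor()].
#' @return A list with `accuracy` (overall fraction of correct held-out
#'   predictions), `fold_accuracy`, `class_metrics` (per-class one-vs-rest
#'   counts and metrics), and `confusion` (pooled truth x prediction table).
#' @export
cross_validate <- function(cfg, seqs, labels, k = 10L, seed = 1L,
                           epochs = 20L, batch_size = 64L, lr = 1e-2) {
  stopifnot(inherits(cfg, "predictor_config"), length(seqs) == length(labels))
  labels <- factor(as.character(labels), levels = cfg$classes)
  counts <- table(labels)
  if (any(counts[counts > 0] < k)) {
    stop("every class must have at least k = ", k, " members")
  }
  n <- length(seqs)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      if (!length(idx)) next
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  predicted <- factor(rep(NA_character_, n), levels = cfg$classes)
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- which(fold != f)
    pred <- build_predictor(cfg, seed = derive_seed(seed, f))
    pred <- train_predictor(pred, seqs[train], labels[train],
                            epochs = epochs, batch_size = batch_size,
                            lr = lr, seed = derive_seed(seed, 1000L + f))
    p <- predict(pred, seqs[test])
    predicted[test] <- p$predicted_class
    fold_acc[f] <- mean(p$predicted_class == labels[test])
  }
  class_metrics <- do.call(rbind, lapply(cfg$classes, function(cl) {
    cc <- confusion_counts(labels == cl, predicted == cl)
    m <- classifier_metrics(cc)
    data.frame(class = cl, TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
               Acc = m[["Acc"]], MCC = m[["MCC"]],
               Sen = m[["Sen"]], Spc = m[["Spc"]])
  }))
  list(accuracy = mean(predicted == labels),
       fold_accuracy = fold_acc,
       class_metrics = class_metrics,
       confusion = table(truth = labels, predicted = predicted))
}
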