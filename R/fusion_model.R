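# Multimodal fusion classifier: per-pair feature assembly, a multilayer
# perceptron with an optional square projection layer, and the two-stage
# training schedule (Adam from scratch, then fine-tuning with plateau
# learning-rate decay).  The network is
#
#   x -> [P x + bP]        (optional projection, input_dim -> input_dim)
#     -> ReLU -> dropout
#     -> W1 ... + b1       (hidden layer, -> hidden_dim)
#     -> ReLU -> dropout
#     -> W2 ... + b2       (output layer, -> n_classes logits)
#
# trained with softmax cross-entropy.  The projection layer re-weights and
# linearly mixes the concatenated heterogeneous features before
# compression, the model's answer to cross-modal scale mismatch (no input
# standardization is applied by default).

#' Model configuration
#'
#' @param modalities character subset of the feature-store modality names
#'   (conventionally `"ssp"`, `"psp"`, `"emb"`).
#' @param dims named integer vector of per-modality dimensions.  Defaults
#'   to the reference setting: SSP 200, PSP 300, embeddings at their native
#'   768.
#' @param use_projection include the square projection layer (default
#'   `TRUE`).
#' @param hidden_dim hidden layer width (default 512).
#' @param dropout dropout rate in \[0, 1) after projection and hidden
#'   activations (default 0.3).
#' @param learning_rate initial Adam learning rate (default 1e-3).
#' @param n_classes number of interaction classes (default 79).
#' @param seed seed for weight initialization and the training RNG.
#' @param batch_size minibatch size (default 256).
#' @param max_epochs_stage1 epoch cap for from-scratch training (default
#'   300).
#' @param early_stop_from stage-1 early stopping (patience
#'   `patience`) can only trigger from this epoch on (default 200).
#' @param patience early-stopping patience, both stages (default 20).
#' @param max_epochs_stage2 epoch cap for fine-tuning (default 100).
#' @param plateau_factor,plateau_patience,min_lr ReduceLROnPlateau
#'   parameters for stage 2 (defaults 0.1, 5, 1e-6; mode is "max" on
#'   validation accuracy).
#' @param standardize z-score features using training-set statistics
#'   before the network (default `FALSE`; the projection layer handles
#'   scale alignment).
#' @return object of class `ddi_model_config`.
#' @export
model_config <- function(modalities = c("ssp", "emb"),
                         dims = c(ssp = 200, psp = 300, emb = 768),
                         use_projection = TRUE, hidden_dim = 512,
                         dropout = 0.3, learning_rate = 1e-3,
                         n_classes = 79, seed = 1, batch_size = 256,
                         max_epochs_stage1 = 300, early_stop_from = 200,
                         patience = 20, max_epochs_stage2 = 100,
                         plateau_factor = 0.1, plateau_patience = 5,
                         min_lr = 1e-6, standardize = FALSE) {
  stopifnot(length(modalities) >= 1, all(modalities %in% names(dims)),
            dropout >= 0, dropout < 1, n_classes >= 2, learning_rate >= 0)
  if (hidden_dim <= 0) stop("hidden_dim must be positive")
  input_dim <- 2L * sum(as.integer(dims[modalities]))
  structure(list(modalities = modalities, dims = dims[modalities],
                 input_dim = input_dim, use_projection = use_projection,
                 hidden_dim = as.integer(hidden_dim), dropout = dropout,
                 learning_rate = learning_rate,
                 n_classes = as.integer(n_classes), seed = as.integer(seed),
                 batch_size = as.integer(batch_size),
                 max_epochs_stage1 = as.integer(max_epochs_stage1),
                 early_stop_from = as.integer(early_stop_from),
                 patience = as.integer(patience),
                 max_epochs_stage2 = as.integer(max_epochs_stage2),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 min_lr = min_lr, standardize = standardize),
            class = "ddi_model_config")
}

#' Bundle per-modality feature matrices into a store
#'
#' All matrices must cover the same drugs; rows are aligned to a common
#' sorted drug-id index.
#'
#' @param matrices named list of numeric matrices with drug ids as
#'   rownames, one per modality.
#' @return object of class `ddi_feature_store` with fields `matrices`,
#'   `drug_ids`, `dims`.
#' @export
feature_store <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1,
            !is.null(names(matrices)), all(nzchar(names(matrices))))
  ids <- lapply(matrices, rownames)
  if (any(vapply(ids, is.null, logical(1))))
    stop("every feature matrix needs drug ids as rownames")
  common <- unname(sort(ids[[1]]))
  for (nm in names(matrices)) {
    if (!setequal(ids[[nm]], common))
      stop("modality '", nm, "' does not cover the same drugs as '",
           names(matrices)[1], "'")
    matrices[[nm]] <- as.matrix(matrices[[nm]])[common, , drop = FALSE]
  }
  structure(list(matrices = matrices, drug_ids = common,
                 dims = vapply(matrices, ncol, integer(1))),
            class = "ddi_feature_store")
}

#' Assemble per-pair feature vectors
#'
#' Concatenates, for each ordered pair, drug A's features across the
#' requested modalities followed by drug B's — order-sensitive, so
#' (A, B) and (B, A) yield different vectors whenever the drugs differ.
#'
#' @param pairs data.frame of ordered pairs (`drug_a`, `drug_b`).
#' @param store a [feature_store()].
#' @param modalities modalities to concatenate, in order.
#' @return n x (2 * sum of modality dims) numeric matrix.
#' @export
assemble_pair_vectors <- function(pairs, store, modalities) {
  stopifnot(inherits(store, "ddi_feature_store"))
  miss_mod <- setdiff(modalities, names(store$matrices))
  if (length(miss_mod) > 0)
    stop("modality '", miss_mod[1], "' missing from feature store")
  ia <- match(pairs$drug_a, store$drug_ids)
  ib <- match(pairs$drug_b, store$drug_ids)
  if (anyNA(ia) || anyNA(ib)) {
    missing_drug <- c(pairs$drug_a[is.na(ia)], pairs$drug_b[is.na(ib)])[1]
    stop("drug '", missing_drug, "' missing from feature store (modalities ",
         paste(modalities, collapse = ","), ")")
  }
  blocks_a <- lapply(modalities, function(m) store$matrices[[m]][ia, , drop = FALSE])
  blocks_b <- lapply(modalities, function(m) store$matrices[[m]][ib, , drop = FALSE])
  X <- do.call(cbind, c(blocks_a, blocks_b))
  dimnames(X) <- NULL
  X
}

#' Build an (untrained) fusion MLP
#'
#' Weight initialization is seeded He-normal (sd `sqrt(2/fan_in)`), suited
#' to the ReLU activations; biases start at zero.  Two builds with the
#' same config are bit-identical.
#'
#' @param config a [model_config()].
#' @return object of class `ddi_mlp`: list with `params` and `config`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "ddi_model_config"))
  d <- config$input_dim; h <- config$hidden_dim; k <- config$n_classes
  params <- with_preserved_rng(config$seed, {
    p <- list()
    if (config$use_projection) {
      p$P <- matrix(stats::rnorm(d * d, sd = sqrt(2 / d)), d, d)
      p$bP <- numeric(d)
    }
    p$W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)
    p$b1 <- numeric(h)
    p$W2 <- matrix(stats::rnorm(h * k, sd = sqrt(2 / h)), h, k)
    p$b2 <- numeric(k)
    p
  })
  structure(list(params = params, config = config), class = "ddi_mlp")
}

#' Number of learnable parameters
#' @param model a `ddi_mlp` or a parameter list.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  p <- if (inherits(model, "ddi_mlp")) model$params else model
  sum(vapply(p, length, integer(1)))
}

# Forward pass.  In training mode applies inverted dropout with masks
# drawn from the current RNG stream; returns caches for backprop.
mlp_forward <- function(params, X, dropout = 0, training = FALSE) {
  n <- nrow(X)
  cache <- list(X = X)
  H <- X
  if (!is.null(params$P)) {
    A0 <- sweep(H %*% params$P, 2, params$bP, `+`)
    H <- pmax(A0, 0)
    cache$A0 <- A0
    if (training && dropout > 0) {
      M0 <- matrix((stats::runif(length(H)) >= dropout) / (1 - dropout),
                   nrow(H), ncol(H))
      H <- H * M0
      cache$M0 <- M0
    }
    cache$H0 <- H
  }
  A1 <- sweep(H %*% params$W1, 2, params$b1, `+`)
  H1 <- pmax(A1, 0)
  cache$A1 <- A1
  if (training && dropout > 0) {
    M1 <- matrix((stats::runif(length(H1)) >= dropout) / (1 - dropout),
                 nrow(H1), ncol(H1))
    H1 <- H1 * M1
    cache$M1 <- M1
  }
  cache$H1 <- H1
  logits <- sweep(H1 %*% params$W2, 2, params$b2, `+`)
  list(logits = logits, cache = cache)
}

# Numerically stable softmax over rows.
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean cross-entropy and gradients for a batch.  y is 0-based class ids.
mlp_loss_grads <- function(params, fwd, y) {
  logits <- fwd$logits
  n <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(z)))
  idx <- cbind(seq_len(n), y + 1L)
  loss <- mean(lse - z[idx])
  Pmat <- exp(z) / rowSums(exp(z))
  dL <- Pmat
  dL[idx] <- dL[idx] - 1
  dL <- dL / n
  cache <- fwd$cache
  grads <- list()
  grads$W2 <- crossprod(cache$H1, dL)
  grads$b2 <- colSums(dL)
  dH1 <- tcrossprod(dL, params$W2)
  if (!is.null(cache$M1)) dH1 <- dH1 * cache$M1
  dA1 <- dH1 * (cache$A1 > 0)
  Hin <- if (!is.null(params$P)) cache$H0 else cache$X
  grads$W1 <- crossprod(Hin, dA1)
  grads$b1 <- colSums(dA1)
  if (!is.null(params$P)) {
    dH0 <- tcrossprod(dA1, params$W1)
    if (!is.null(cache$M0)) dH0 <- dH0 * cache$M0
    dA0 <- dH0 * (cache$A0 > 0)
    grads$P <- crossprod(cache$X, dA0)
    grads$bP <- colSums(dA0)
  }
  list(loss = loss, grads = grads)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Plateau learning-rate scheduler (mode = max)
#'
#' Multiplies the learning rate by `factor` each time the monitored metric
#' has failed to improve on the best value for `patience` consecutive
#' epochs, never dropping below `min_lr`.  The baseline is the best metric
#' already achieved when the scheduler is created (for fine-tuning, the
#' resumed checkpoint's validation accuracy), so a stage that never
#' improves decays at epochs `patience`, `2*patience`, ...
#'
#' @param init_lr initial learning rate.
#' @param factor multiplicative decay (default 0.1).
#' @param patience stagnant epochs before each decay (default 5).
#' @param min_lr learning-rate floor (default 1e-6).
#' @param baseline best metric value seen so far (default `-Inf`).
#' @return list with `step(metric)` (records one epoch's metric and returns
#'   the learning rate to use next) and `get_lr()`.
#' @export
make_plateau_scheduler <- function(init_lr, factor = 0.1, patience = 5,
                                   min_lr = 1e-6, baseline = -Inf) {
  lr <- init_lr
  best <- baseline
  bad <- 0L
  step <- function(metric) {
    if (metric > best) {
      best <<- metric
      bad <<- 0L
    } else {
      bad <<- bad + 1L
      if (bad >= patience) {
        lr <<- max(lr * factor, min_lr)
        bad <<- 0L
      }
    }
    lr
  }
  list(step = step, get_lr = function() lr)
}

# Shared epoch loop for both training stages.  `data` is list(x, y) with
# 0-based integer labels.  Returns history, best checkpoint, final params.
train_core <- function(params, config, train, val, stage,
                       init_best_acc = -Inf, scheduler = NULL,
                       rng_offset = 0L) {
  n <- nrow(train$x)
  if (n == 0 || nrow(val$x) == 0) stop("empty training or validation partition")
  max_epochs <- if (stage == 1L) config$max_epochs_stage1 else config$max_epochs_stage2
  state <- adam_init(params)
  lr <- config$learning_rate
  best <- list(params = params, epoch = 0L, val_accuracy = init_best_acc)
  hist <- vector("list", max_epochs)
  with_preserved_rng(config$seed + rng_offset, {
    for (epoch in seq_len(max_epochs)) {
      perm <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1, n)]
        fwd <- mlp_forward(params, train$x[idx, , drop = FALSE],
                           dropout = config$dropout, training = TRUE)
        lg <- mlp_loss_grads(params, fwd, train$y[idx])
        if (!is.finite(lg$loss))
          stop("training diverged: non-finite loss at stage ", stage,
               " epoch ", epoch)
        upd <- adam_step(params, lg$grads, state, lr)
        params <- upd$params
        state <- upd$state
        losses <- c(losses, lg$loss * length(idx))
      }
      train_loss <- sum(losses) / n
      val_logits <- mlp_forward(params, val$x)$logits
      val_pred <- max.col(val_logits, ties.method = "first") - 1L
      val_acc <- mean(val_pred == val$y)
      hist[[epoch]] <- data.frame(stage = stage, epoch = epoch,
                                  train_loss = train_loss,
                                  val_accuracy = val_acc, lr = lr)
      if (val_acc > best$val_accuracy)
        best <- list(params = params, epoch = epoch, val_accuracy = val_acc)
      if (!is.null(scheduler)) lr <- scheduler$step(val_acc)
      stop_now <- if (stage == 1L) {
        epoch >= config$early_stop_from &&
          epoch - max(best$epoch, config$early_stop_from) >= config$patience
      } else {
        epoch - max(best$epoch, 0L) >= config$patience
      }
      if (stop_now) break
    }
  })
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  rownames(history) <- NULL
  list(history = history, best = best, params = params)
}

#' Stage 1: train the fusion MLP from scratch
#'
#' Up to `max_epochs_stage1` epochs of minibatch Adam with cross-entropy
#' loss at a fixed learning rate.  Early stopping monitors validation
#' accuracy with the configured patience but cannot trigger before
#' `early_stop_from`.  The best-validation-accuracy checkpoint is kept.
#'
#' @param model a [build_model()] result.
#' @param train,val lists with `x` (feature matrix) and `y` (0-based
#'   integer class labels).
#' @param config optional [model_config()] overriding the model's own.
#' @return object of class `ddi_training_history`: list with per-epoch
#'   `history` (stage, epoch, train_loss, val_accuracy, lr), `best`
#'   checkpoint (`params`, `epoch`, `val_accuracy`), final `params` and
#'   the `config`.
#' @export
train_stage1 <- function(model, train, val, config = NULL) {
  stopifnot(inherits(model, "ddi_mlp"))
  config <- config %||% model$config
  res <- train_core(model$params, config, train, val, stage = 1L,
                    rng_offset = 1L)
  structure(c(res, list(config = config)), class = "ddi_training_history")
}

#' Stage 2: fine-tune from the stage-1 checkpoint
#'
#' Resumes from the best stage-1 parameters for up to `max_epochs_stage2`
#' epochs.  The learning rate is reduced by `plateau_factor` whenever
#' validation accuracy stagnates for `plateau_patience` consecutive epochs
#' (floored at `min_lr`), and early stopping applies with the configured
#' patience.  Test metrics should be computed from this stage's best
#' validation checkpoint.
#'
#' @param checkpoint the `best` element of a stage-1
#'   `ddi_training_history` (or the history itself).
#' @param train,val as in [train_stage1()].
#' @param config a [model_config()].
#' @return a `ddi_training_history`; its `best` checkpoint is the overall
#'   best across the resumed baseline and fine-tuning.
#' @export
fine_tune_stage2 <- function(checkpoint, train, val, config) {
  if (inherits(checkpoint, "ddi_training_history"))
    checkpoint <- checkpoint$best
  if (is.null(checkpoint$params))
    stop("missing stage-1 checkpoint")
  stopifnot(inherits(config, "ddi_model_config"))
  sched <- make_plateau_scheduler(config$learning_rate,
                                  factor = config$plateau_factor,
                                  patience = config$plateau_patience,
                                  min_lr = config$min_lr,
                                  baseline = checkpoint$val_accuracy)
  res <- train_core(checkpoint$params, config, train, val, stage = 2L,
                    init_best_acc = checkpoint$val_accuracy,
                    scheduler = sched, rng_offset = 2L)
  if (res$best$epoch == 0L) res$best$params <- checkpoint$params
  structure(c(res, list(config = config)), class = "ddi_training_history")
}

#' Class probabilities from a trained model
#'
#' Softmax over the network's logits in evaluation mode (no dropout); rows
#' sum to 1.  The predicted class of a row is its argmax, ties resolved in
#' favor of the lowest class id.
#'
#' @param model a `ddi_mlp`, a `ddi_training_history` (its best
#'   checkpoint is used), or a bare parameter list.
#' @param x feature matrix with `input_dim` columns.
#' @param config a [model_config()]; required when `model` is a bare list.
#' @return n x n_classes probability matrix.
#' @export
predict_proba <- function(model, x, config = NULL) {
  if (inherits(model, "ddi_training_history")) {
    config <- config %||% model$config
    params <- model$best$params
  } else if (inherits(model, "ddi_mlp")) {
    config <- config %||% model$config
    params <- model$params
  } else {
    params <- model
    if (is.null(config)) stop("config required for a bare parameter list")
  }
  if (ncol(x) != config$input_dim)
    stop("feature matrix has ", ncol(x), " columns; model expects ",
         config$input_dim)
  softmax_rows(mlp_forward(params, x)$logits)
}
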