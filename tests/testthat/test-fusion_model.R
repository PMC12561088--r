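fake_store <- function(n = 6, d_ssp = 3, d_emb = 5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("D%02d", seq_len(n))
  m <- function(d) matrix(rnorm(n * d), n, d, dimnames = list(ids, NULL))
  feature_store(list(ssp = m(d_ssp), emb = m(d_emb)))
}

toy_problem <- function(n = 200, d = 10, seed = 2) {
  # linearly separable 2-class problem
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * d), n, d) + outer(ifelse(y == 1, 3, -3), rep(1, d))
  list(x = x, y = y)
}

test_that("pair vectors concatenate drug A then drug B across modalities", {
  store <- fake_store()
  pairs <- data.frame(drug_a = c("D01", "D02"), drug_b = c("D02", "D01"))
  X <- assemble_pair_vectors(pairs, store, c("ssp", "emb"))
  expect_equal(dim(X), c(2, 2 * (3 + 5)))
  expect_equal(X[1, 1:3], unname(store$matrices$ssp["D01", ]))
  expect_equal(X[1, 4:8], unname(store$matrices$emb["D01", ]))
  expect_equal(X[1, 9:11], unname(store$matrices$ssp["D02", ]))
  # ordered pairs: (A,B) and (B,A) differ
  expect_false(isTRUE(all.equal(X[1, ], X[2, ])))
  # single-modality width
  expect_equal(ncol(assemble_pair_vectors(pairs, store, "emb")), 2 * 5)
})

test_that("assembly errors name the missing drug or modality", {
  store <- fake_store()
  expect_error(assemble_pair_vectors(
    data.frame(drug_a = "D01", drug_b = "ZZZ"), store, "ssp"), "ZZZ")
  expect_error(assemble_pair_vectors(
    data.frame(drug_a = "D01", drug_b = "D02"), store, "psp"), "psp")
})

test_that("projection layer adds exactly input_dim^2 + input_dim parameters", {
  dims <- c(ssp = 4, emb = 6)
  with_p <- build_model(model_config(c("ssp", "emb"), dims, n_classes = 5,
                                     hidden_dim = 8))
  no_p <- build_model(model_config(c("ssp", "emb"), dims, n_classes = 5,
                                   hidden_dim = 8, use_projection = FALSE))
  d <- 2 * sum(dims)
  expect_equal(n_params(with_p) - n_params(no_p), d^2 + d)
})

test_that("model construction is seeded and forward pass has the right
           shape", {
  cfg <- model_config(c("ssp", "emb"), c(ssp = 3, emb = 5), n_classes = 7,
                      hidden_dim = 16, seed = 42)
  m1 <- build_model(cfg); m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  X <- matrix(rnorm(4 * cfg$input_dim), 4)
  prob <- predict_proba(m1, X)
  expect_equal(dim(prob), c(4, 7))
  expect_equal(rowSums(prob), rep(1, 4), tolerance = 1e-6)
  # identical inputs give identical outputs in eval mode
  X2 <- X[c(1, 1, 2), ]
  p2 <- predict_proba(m1, X2)
  expect_identical(p2[1, ], p2[2, ])
  expect_error(predict_proba(m1, X[, 1:5]), "expects")
})

test_that("softmax of all-zero logits is uniform over classes", {
  cfg <- model_config("emb", c(emb = 4), n_classes = 79, hidden_dim = 3)
  m <- build_model(cfg)
  m$params <- lapply(m$params, function(p) p * 0)
  prob <- predict_proba(m, matrix(rnorm(2 * 8), 2))
  expect_equal(as.numeric(prob), rep(1 / 79, 2 * 79), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config("emb", c(emb = 3), n_classes = 3, hidden_dim = 4,
                      dropout = 0, seed = 3)
  model <- build_model(cfg)
  set.seed(4)
  X <- matrix(rnorm(6 * 6), 6)
  y <- sample(0:2, 6, replace = TRUE)
  fwd <- ddifusion:::mlp_forward(model$params, X)
  lg <- ddifusion:::mlp_loss_grads(model$params, fwd, y)
  loss_at <- function(params) {
    f <- ddifusion:::mlp_forward(params, X)
    z <- f$logits - apply(f$logits, 1, max)
    mean(log(rowSums(exp(z))) - z[cbind(seq_len(6), y + 1)])
  }
  eps <- 1e-6
  for (nm in names(lg$grads)) {
    for (i in sample(length(model$params[[nm]]), min(5, length(model$params[[nm]])))) {
      up <- model$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- model$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("stage-1 training reduces loss on a separable toy problem and is
           bit-reproducible", {
  data <- toy_problem()
  cfg <- model_config("emb", c(emb = 5), n_classes = 2, hidden_dim = 16,
                      seed = 1, max_epochs_stage1 = 10, batch_size = 64)
  model <- build_model(cfg)
  h <- train_stage1(model, data, data, cfg)
  expect_lt(h$history$train_loss[10], h$history$train_loss[1])
  expect_equal(h$best$val_accuracy, max(h$history$val_accuracy))
  h2 <- train_stage1(build_model(cfg), data, data, cfg)
  expect_identical(h$history, h2$history)
  expect_identical(h$best$params, h2$best$params)
})

test_that("stage-1 early stopping cannot trigger before its activation
           epoch", {
  # frozen model (learning rate 0): validation accuracy never improves
  # after epoch 1, so the run stops exactly patience epochs after the
  # activation point
  data <- toy_problem(n = 30, d = 4)
  cfg <- model_config("emb", c(emb = 2), n_classes = 2, hidden_dim = 4,
                      seed = 1, learning_rate = 0, max_epochs_stage1 = 60,
                      early_stop_from = 30, patience = 10, dropout = 0)
  h <- train_stage1(build_model(cfg), data, data, cfg)
  expect_equal(nrow(h$history), 40)
})

test_that("plateau scheduler decays by its factor after each stagnant
           window and respects the floor", {
  sched <- make_plateau_scheduler(1e-3, factor = 0.1, patience = 5,
                                  min_lr = 1e-6, baseline = 0.5)
  lrs <- vapply(1:25, function(i) sched$step(0.4), numeric(1))
  expect_equal(lrs[5], 1e-4)   # after 5 stagnant epochs
  expect_equal(lrs[10], 1e-5)  # after 10
  expect_equal(lrs[12], 1e-5)  # mid-window: unchanged
  expect_true(all(lrs >= 1e-6))
  expect_equal(lrs[25], 1e-6)  # floored
  # an improving metric never triggers decay
  up <- make_plateau_scheduler(1e-3, baseline = 0)
  lrs_up <- vapply(seq(0.1, 0.9, by = 0.1), up$step, numeric(1))
  expect_true(all(lrs_up == 1e-3))
})

test_that("stage-2 fine-tuning resumes from the checkpoint with
           non-increasing learning rate", {
  data <- toy_problem()
  cfg <- model_config("emb", c(emb = 5), n_classes = 2, hidden_dim = 16,
                      seed = 1, max_epochs_stage1 = 5, max_epochs_stage2 = 8,
                      batch_size = 64)
  h1 <- train_stage1(build_model(cfg), data, data, cfg)
  h2 <- fine_tune_stage2(h1, data, data, cfg)
  expect_true(all(diff(h2$history$lr) <= 0))
  expect_gte(h2$best$val_accuracy, h1$best$val_accuracy)
  expect_error(fine_tune_stage2(list(params = NULL), data, data, cfg),
               "checkpoint")
})

test_that("training errors on diverging (non-finite) loss", {
  data <- toy_problem(n = 40, d = 4)
  cfg <- model_config("emb", c(emb = 2), n_classes = 2, hidden_dim = 4,
                      seed = 1, learning_rate = 1e3, max_epochs_stage1 = 50)
  model <- build_model(cfg)
  model$params <- lapply(model$params, function(p) p * 1e150)
  expect_error(train_stage1(model, data, data, cfg), "diverged")
})
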