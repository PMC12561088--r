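one_hot <- function(y, k) {
  m <- matrix(0, length(y), k)
  m[cbind(seq_along(y), y + 1)] <- 1
  m
}

test_that("perfect predictions give perfect metrics", {
  y <- rep(0:3, each = 5)
  m <- compute_metrics(y, one_hot(y, 4))
  expect_equal(m$accuracy, 1)
  expect_equal(m$macro_f1, 1)
  expect_equal(m$macro_auroc, 1)
  expect_equal(m$macro_aupr, 1)
  expect_equal(unname(m$per_class_accuracy), rep(1, 4))
})

test_that("chance-level predictions land at chance accuracy and AUROC 0.5", {
  set.seed(131)
  n <- 10000
  y <- rep(0:3, each = n / 4)
  prob <- matrix(runif(n * 4), n, 4)
  prob <- prob / rowSums(prob)
  m <- compute_metrics(y, prob)
  ci <- 2.576 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(m$accuracy - 0.25), ci)
  expect_lt(abs(m$macro_auroc - 0.5), 0.02)
})

test_that("AUROC on the 4-sample two-class toy equals 0.75", {
  # ranked pairs: 3 concordant, 1 discordant
  y <- c(0, 0, 1, 1)
  s1 <- c(0.1, 0.4, 0.35, 0.8)
  prob <- cbind(1 - s1, s1)
  m <- suppressWarnings(compute_metrics(y, prob))
  expect_equal(ddifusion:::auroc_binary(s1, y == 1), 0.75)
})

test_that("AUROC equals brute-force Mann-Whitney, including ties", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    pos <- runif(n) < 0.3
    if (sum(pos) == 0 || sum(pos) == n) next
    expect_equal(ddifusion:::auroc_binary(scores, pos),
                 auroc_bruteforce(scores, pos))
  }
})

test_that("metrics on one-hot probabilities reproduce a brute-force
           confusion-matrix computation", {
  set.seed(15)
  y <- sample(0:4, 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.7, y, sample(0:4, 300, replace = TRUE))
  m <- compute_metrics(y, one_hot(pred, 5))
  conf <- table(factor(y, levels = 0:4), factor(pred, levels = 0:4))
  expect_equal(m$accuracy, sum(diag(conf)) / sum(conf))
  prec <- diag(conf) / pmax(colSums(conf), 1)
  prec[colSums(conf) == 0] <- 0
  rec <- diag(conf) / rowSums(conf)
  expect_equal(m$macro_precision, mean(prec), tolerance = 1e-12)
  expect_equal(m$macro_recall, mean(rec), tolerance = 1e-12)
})

test_that("classes absent from the test set are excluded with a warning", {
  y <- c(0, 0, 1, 1)
  prob <- one_hot(y, 3)
  expect_warning(m <- compute_metrics(y, prob), "absent")
  expect_equal(m$classes_evaluated, c(0, 1))
  expect_true(is.na(m$per_class_accuracy["2"]))
})

test_that("probability rows must normalize", {
  expect_error(compute_metrics(c(0, 1), matrix(c(1, 1, 1, 1), 2)), "sum to 1")
})

toy_labels <- function() {
  # confusion rows: [[8,2,0],[1,9,0],[0,0,10]]
  y <- rep(0:2, each = 10)
  pred <- c(rep(0, 8), 1, 1, 0, rep(1, 9), rep(2, 10))
  list(y = y, pred = pred)
}

test_that("misclassification table computes counts and normalized ratios", {
  tl <- toy_labels()
  cs <- misclassification_table(tl$y, tl$pred)
  expect_equal(unname(rowSums(cs$confusion)), c(10, 10, 10))
  tab <- cs$table[order(cs$table$class_id), ]
  expect_equal(tab$miscls_count, c(2L, 1L, 0L))
  expect_equal(tab$miscls_ratio_pct, c(200 / 3, 100 / 3, 0), tolerance = 1e-10)
  expect_equal(sum(tab$miscls_ratio_pct), 100)
  expect_equal(sum(tab$test_ratio_pct), 100)
  # ranking: class 0 first (largest error share)
  expect_equal(cs$table$class_id[1:2], c(0, 1))
})

test_that("misclassification table handles the error-free case", {
  y <- rep(0:1, 5)
  expect_message(cs <- misclassification_table(y, y), "no misclassified")
  expect_equal(cs$table$miscls_count, c(0L, 0L))
  expect_equal(cs$table$miscls_ratio_pct, c(0, 0))
})

test_that("error heatmap normalizes by total errors and masks the
           diagonal", {
  tl <- toy_labels()
  cs <- misclassification_table(tl$y, tl$pred)
  H <- error_heatmap(cs, top_k = 2)
  expect_equal(H["0", "1"], 2 / 3)
  expect_equal(H["1", "0"], 1 / 3)
  expect_true(all(is.na(diag(H))))
  expect_lte(sum(H, na.rm = TRUE), 1)
  # a single error concentrates all mass in one cell
  one <- misclassification_table(c(0, 1, 1), c(1, 1, 1))
  H1 <- error_heatmap(one, top_k = 2)
  expect_equal(H1["0", "1"], 1)
  expect_error(error_heatmap(cs, top_k = 10), "top_k")
})
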