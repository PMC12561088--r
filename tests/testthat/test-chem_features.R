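test_that("fingerprinting is deterministic and canonicalization-invariant", {
  a <- fingerprint_from_smiles("CC", radius = 2, n_bits = 2048)
  b <- fingerprint_from_smiles("CC", radius = 2, n_bits = 2048)
  expect_identical(a$on_bits, b$on_bits)
  expect_false(a$empty)
  # aromatic and Kekulé benzene are the same molecule
  arom <- fingerprint_from_smiles("c1ccccc1", 2, 2048)
  kek <- fingerprint_from_smiles("C1=CC=CC=C1", 2, 2048)
  expect_identical(arom$on_bits, kek$on_bits)
})

test_that("unparseable SMILES raise a parse error naming the input", {
  expect_error(fingerprint_from_smiles("not_a_smiles", 2, 2048),
               "not_a_smiles")
  expect_error(fingerprint_from_smiles("", 2, 2048), "empty")
  expect_error(canonical_smiles("]]["), "parse error")
})

test_that("fingerprint parameters are validated", {
  expect_error(fingerprint_from_smiles("CC", radius = 4), "radius")
  expect_error(fingerprint_from_smiles("CC", n_bits = 1000), "power of two")
  expect_error(fingerprint_from_smiles("CC", n_bits = 8192), "4096")
})

test_that("radius 2 ignores structure beyond 2 bonds, radius 3 sees it", {
  # heptane and octane share every radius-<=2 atom environment but differ
  # in radius-3 environments near the chain ends
  h4 <- fingerprint_from_smiles("CCCCCCC", radius = 2)
  o4 <- fingerprint_from_smiles("CCCCCCCC", radius = 2)
  expect_identical(h4$on_bits, o4$on_bits)
  h6 <- fingerprint_from_smiles("CCCCCCC", radius = 3)
  o6 <- fingerprint_from_smiles("CCCCCCCC", radius = 3)
  expect_false(identical(h6$on_bits, o6$on_bits))
})

test_that("tanimoto matches the set formula, including edge cases", {
  f1 <- make_fp(c(1, 2, 3)); f2 <- make_fp(c(2, 3, 4))
  expect_equal(tanimoto(f1, f2), 0.5)  # |{2,3}| / |{1,2,3,4}|
  expect_equal(tanimoto(f1, f1), 1)
  expect_equal(tanimoto(make_fp(1:5), make_fp(10:14)), 0)
  expect_error(tanimoto(make_fp(1, n_bits = 1024), make_fp(1, n_bits = 2048)),
               "mismatched n_bits")
  expect_warning(z <- tanimoto(make_fp(integer(0)), make_fp(integer(0))),
                 "empty")
  expect_equal(z, 0)
})

test_that("tanimoto equals brute force on 1000 random fingerprint pairs", {
  set.seed(42)
  for (i in 1:1000) {
    a <- random_fp("a"); b <- random_fp("b")
    expect_identical(tanimoto(a, b), tanimoto_oracle(a$on_bits, b$on_bits))
  }
})

test_that("build_ssp produces a symmetric unit-diagonal matrix matching a
           pairwise oracle", {
  expect_equal(build_ssp(list(make_fp(1:4, id = "only")))[1, 1], 1)
  set.seed(11)
  fps <- lapply(sprintf("D%02d", 1:10), random_fp)
  S <- build_ssp(fps)
  expect_identical(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 10))
  for (i in 1:10) for (j in 1:10)
    expect_equal(S[i, j], tanimoto_oracle(fps[[i]]$on_bits, fps[[j]]$on_bits))
})

test_that("build_ssp rejects duplicate ids, naming the duplicate", {
  fps <- list(make_fp(1:3, id = "dup"), make_fp(2:5, id = "dup"))
  expect_error(build_ssp(fps), "dup")
})

test_that("reduce_pca recovers low-rank structure exactly", {
  set.seed(3)
  # rows in a 2-dimensional affine subspace of R^6
  basis <- matrix(rnorm(12), 2, 6)
  x <- matrix(rnorm(40), 20, 2) %*% basis + rep(rnorm(6), each = 20)
  rownames(x) <- sprintf("D%02d", 1:20)
  red <- reduce_pca(x, 2)
  expect_gte(red$cumulative_variance, 0.999)
  expect_true(red$variance_ok)
  # cross-check the axis variances against a dense eigendecomposition
  ev <- eigen(cov(x), symmetric = TRUE)$values
  expect_equal(red$explained_variance_ratio, (ev / sum(ev))[1:2],
               tolerance = 1e-8)
})

test_that("reduce_pca keeps full variance at k = n - 1 and errors on
           infeasible k", {
  set.seed(4)
  x <- matrix(rnorm(10 * 40), 10, 40)
  red <- reduce_pca(x, 9)
  expect_equal(red$cumulative_variance, 1, tolerance = 1e-10)
  expect_error(reduce_pca(x, 11), "exceeds")
  expect_error(reduce_pca(x[1, , drop = FALSE], 1), "at least 2 rows")
})

test_that("PCA reconstruction error is monotone in k", {
  set.seed(5)
  x <- matrix(rnorm(30 * 12), 30, 12)
  recon_err <- function(k) {
    r <- reduce_pca(x, k)
    xhat <- r$components[, 1:k, drop = FALSE] %*% t(r$rotation) +
      rep(r$center, each = nrow(x))
    sum((x - xhat)^2)
  }
  errs <- vapply(1:11, recon_err, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})

test_that("PCA projection is row-permutation invariant up to axis sign", {
  set.seed(6)
  x <- matrix(rnorm(25 * 8), 25, 8)
  rownames(x) <- sprintf("D%02d", 1:25)
  perm <- sample(25)
  a <- reduce_pca(x, 3)$components
  b <- reduce_pca(x[perm, ], 3)$components
  expect_equal(abs(a[perm, ]), abs(b), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("empty fingerprints are flagged and scored 0 in the SSP", {
  fps <- list(make_fp(1:5, id = "a"), make_fp(integer(0), id = "b"))
  expect_warning(S <- build_ssp(fps), "empty")
  expect_equal(attr(S, "empty_drugs"), "b")
  expect_equal(unname(S["b", ]), c(0, 0))
})
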