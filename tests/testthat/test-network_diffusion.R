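test_that("load_ppi filters, deduplicates and strips self-loops", {
  df <- data.frame(protein_a = c("A", "B", "A", "B", "C"),
                   protein_b = c("B", "C", "C", "A", "C"),
                   score = c(900, 650, 800, 700, 950))
  net <- load_ppi(df, min_confidence = 700)
  # B-C (650) dropped below threshold, C-C self-loop removed,
  # A-B/B-A collapsed to max 900
  expect_equal(nrow(net$edges), 2)
  ab <- net$edges[net$edges$protein_a == "A" & net$edges$protein_b == "B", ]
  expect_equal(ab$weight, 900)
  expect_equal(net$report$n_below_threshold, 1)
  expect_equal(net$report$n_self_loops, 1)
  expect_equal(net$report$n_duplicates_collapsed, 1)
})

test_that("load_ppi reports malformed rows by line and rejects empty
           networks", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tscore", "A\tB\t900", "A\tC\tnot_a_number"),
             path)
  expect_error(load_ppi(path), "line 3")
  df <- data.frame(protein_a = "A", protein_b = "B", score = 100)
  expect_error(load_ppi(df, min_confidence = 700), "empty network")
})

test_that("transition matrix normalizes columns by incident weight", {
  star <- data.frame(protein_a = c("h", "h", "h"),
                     protein_b = c("a", "b", "c"), score = c(800, 800, 800))
  W <- transition_matrix(load_ppi(star))
  expect_equal(unname(W[c("a", "b", "c"), "h"]), rep(1 / 3, 3))
  path3 <- data.frame(protein_a = c("a", "b"), protein_b = c("b", "c"),
                      score = c(800, 800))
  Wp <- transition_matrix(load_ppi(path3))
  expect_equal(unname(Wp[c("a", "c"), "b"]), c(0.5, 0.5))
  set.seed(8)
  Wr <- transition_matrix(load_ppi(random_connected_ppi(20)))
  expect_equal(unname(Matrix::colSums(Wr)), rep(1, 20), tolerance = 1e-12)
})

test_that("rwr fixed points match hand-computed and closed-form solutions", {
  # single node: the walk never leaves the seed
  one <- Matrix::Matrix(0, 1, 1, sparse = TRUE)
  expect_equal(rwr(one, 1, restart = 0.5)$scores, 1, ignore_attr = TRUE)
  # two nodes, one edge, seed (1,0), restart 1/2 -> (2/3, 1/3)
  W2 <- Matrix::Matrix(c(0, 1, 1, 0), 2, 2, sparse = TRUE)
  p <- rwr(W2, c(1, 0), restart = 0.5, tol = 1e-12)
  expect_equal(unname(p$scores), c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_true(p$converged)
  # random graphs vs the dense linear solve
  set.seed(9)
  for (i in 1:5) {
    W <- transition_matrix(load_ppi(random_connected_ppi(15)))
    seed_vec <- numeric(15); seed_vec[sample.int(15, 2)] <- 0.5
    it <- rwr(W, seed_vec, restart = 0.4, tol = 1e-10)
    expect_lt(max(abs(it$scores - rwr_closed_form(W, seed_vec, 0.4))), 1e-6)
    expect_equal(sum(it$scores), 1, tolerance = 1e-8)
  }
})

test_that("rwr localizes to the seed as restart grows", {
  set.seed(10)
  W <- transition_matrix(load_ppi(random_connected_ppi(12)))
  seed_vec <- numeric(12); seed_vec[1] <- 1
  d <- vapply(c(0.2, 0.5, 0.8, 0.95), function(r)
    sum(abs(rwr(W, seed_vec, restart = r, tol = 1e-10)$scores - seed_vec)),
    numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("rwr validates its seed", {
  W <- Matrix::Matrix(c(0, 1, 1, 0), 2, 2, sparse = TRUE)
  expect_error(rwr(W, c(0, 0)), "sums to 0")
  expect_error(rwr(W, c(0.7, 0.7)), "sum to 1")
  expect_error(rwr(W, c(-0.5, 1.5)), "non-negative")
})

test_that("drug diffusion profiles are deterministic, flag unmapped drugs,
           and respect connected components", {
  # two disconnected triangles
  ppi <- data.frame(
    protein_a = c("A1", "A2", "A3", "B1", "B2", "B3"),
    protein_b = c("A2", "A3", "A1", "B2", "B3", "B1"),
    score = rep(900, 6))
  net <- load_ppi(ppi)
  assoc <- data.frame(drug_id = c("d1", "d2", "d3", "d3"),
                      protein_id = c("A1", "A1", "ZZZ", "A2"))
  expect_warning(
    prof <- drug_diffusion_profiles(assoc, net, drug_ids = c("d1", "d2", "d3", "d4")),
    "no mapped network proteins")
  # identical seed sets give identical profiles
  expect_equal(prof$scores["d1", ], prof$scores["d2", ])
  # mass cannot cross into the disconnected component
  expect_equal(unname(prof$scores["d1", c("B1", "B2", "B3")]), c(0, 0, 0))
  # unmapped drug: zero profile, flagged; out-of-network protein reported
  expect_true(prof$zero_profile["d4"])
  expect_equal(unname(prof$scores["d4", ]), rep(0, 6))
  expect_equal(prof$dropped_proteins$protein_id, "ZZZ")
})

test_that("PSP cosine similarity matches a brute-force oracle", {
  set.seed(12)
  x <- matrix(rexp(10 * 30), 10, 30)
  rownames(x) <- sprintf("D%02d", 1:10)
  red <- build_psp(x, k = 3)
  S <- attr(red, "similarity")
  for (i in 1:10) for (j in 1:10) {
    expected <- if (i == j) 1 else
      sum(x[i, ] * x[j, ]) / sqrt(sum(x[i, ]^2) * sum(x[j, ]^2))
    expect_equal(S[i, j], expected, tolerance = 1e-10)
  }
  expect_identical(S, t(S))
  expect_true(all(S >= 0 & S <= 1 + 1e-12))
})

test_that("PSP similarity handles identical, orthogonal and zero profiles", {
  x <- rbind(a = c(1, 2, 0, 0), b = c(2, 4, 0, 0),  # parallel
             c = c(0, 0, 3, 0),                      # orthogonal support
             z = c(0, 0, 0, 0))                      # zero profile
  S <- attr(build_psp(x, k = 2), "similarity")
  expect_equal(S["a", "b"], 1, tolerance = 1e-12)
  expect_equal(S["a", "c"], 0)
  expect_equal(unname(S["z", c("a", "b", "c")]), c(0, 0, 0))
  expect_equal(S["z", "z"], 1)
})
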