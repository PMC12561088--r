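# Shared fixtures: hand-built fingerprints, toy graphs, and small cached
# synthetic datasets.  Everything is generated in code at test time.

make_fp <- function(bits, n_bits = 2048, id = "x", radius = 2) {
  structure(list(drug_id = id, on_bits = as.integer(sort(unique(bits))),
                 radius = as.integer(radius), n_bits = as.integer(n_bits),
                 empty = length(bits) == 0L),
            class = "ddi_fingerprint")
}

random_fp <- function(id, n_bits = 2048, density = 0.02) {
  k <- max(1L, stats::rbinom(1, n_bits, density))
  make_fp(sample.int(n_bits, k) - 1L, n_bits = n_bits, id = id)
}

# Independent brute-force Tanimoto oracle over explicit bit sets.
tanimoto_oracle <- function(a_bits, b_bits) {
  if (length(a_bits) == 0 && length(b_bits) == 0) return(0)
  length(intersect(a_bits, b_bits)) / length(union(a_bits, b_bits))
}

# Random connected undirected weighted graph as a PPI edge data.frame:
# a ring for connectivity plus random chords.
random_connected_ppi <- function(n_nodes, extra = n_nodes, weighted = TRUE) {
  ids <- sprintf("N%03d", seq_len(n_nodes))
  a <- seq_len(n_nodes)
  b <- c(seq_len(n_nodes)[-1], 1)
  if (extra > 0) {
    ca <- sample.int(n_nodes, extra, replace = TRUE)
    cb <- sample.int(n_nodes, extra, replace = TRUE)
    keep <- ca != cb
    a <- c(a, ca[keep]); b <- c(b, cb[keep])
  }
  w <- if (weighted) sample(700:999, length(a), replace = TRUE)
       else rep(800, length(a))
  data.frame(protein_a = ids[a], protein_b = ids[b], score = w,
             stringsAsFactors = FALSE)
}

# Dense closed-form RWR oracle: r * solve(I - (1-r) W) %*% seed.
rwr_closed_form <- function(W, seed, restart) {
  Wd <- as.matrix(W)
  as.numeric(restart * solve(diag(nrow(Wd)) - (1 - restart) * Wd, seed))
}

# Brute-force one-vs-rest AUROC over all (positive, negative) score pairs,
# ties counting 1/2.
auroc_bruteforce <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Small cached synthetic datasets so several test files can share them.
.fixture_env <- new.env(parent = emptyenv())

tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- synthetic_config(n_drugs = 30, n_proteins = 60, n_clusters = 3,
                            n_classes = 4, pairs_per_class = 30,
                            label_noise = 0, seed = 7)
    .fixture_env$tiny <- generate_synthetic(cfg)
  }
  .fixture_env$tiny
}

# Desk-scale training schedule used throughout the tests; the dataset and
# generator parameters stay at their defaults.
desk_config <- list(max_epochs_stage1 = 40, max_epochs_stage2 = 10)
desk_config_small <- list(max_epochs_stage1 = 30, max_epochs_stage2 = 5)
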