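# Protein similarity profile (PSP): weighted PPI network -> random walk
# with restart from each drug's CTET seed proteins -> cosine similarity of
# diffusion profiles -> PCA-reduced per-drug feature.

#' Load a weighted protein-protein interaction network
#'
#' Reads a STRING-style edge list (`protein_a`, `protein_b`, `score`),
#' drops edges below the confidence threshold, removes self-loops, and
#' collapses duplicate unordered pairs keeping the maximum score.
#'
#' @param x path to a TSV with columns `protein_a`, `protein_b`, `score`,
#'   or an equivalent data.frame.
#' @param min_confidence edges with `score` below this are dropped.
#'   Default 700, STRING's customary high-confidence cutoff.
#' @return object of class `ddi_ppi_network`: list with sorted
#'   `protein_ids`, an `edges` data.frame (one row per unordered pair,
#'   columns `protein_a`, `protein_b`, `weight`), and a `report` counting
#'   input rows, sub-threshold drops, self-loops and collapsed duplicates.
#' @export
load_ppi <- function(x, min_confidence = 700) {
  if (is.character(x)) {
    df <- read_tsv_checked(x, c("protein_a", "protein_b", "score"), "PPI edge")
  } else {
    df <- as.data.frame(x)
    miss <- setdiff(c("protein_a", "protein_b", "score"), names(df))
    if (length(miss) > 0)
      stop("PPI edge table is missing column(s): ", paste(miss, collapse = ", "))
  }
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) | !nzchar(as.character(df$protein_a)) |
                 !nzchar(as.character(df$protein_b)))
  if (length(bad) > 0)
    stop("malformed PPI row at line ", bad[1] + 1L,
         " (counting the header line)")
  if (any(score < 0)) stop("negative edge score")
  n_input <- nrow(df)
  keep <- score >= min_confidence
  n_below <- sum(!keep)
  a <- as.character(df$protein_a)[keep]
  b <- as.character(df$protein_b)[keep]
  w <- score[keep]
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; w <- w[!self]
  # canonical unordered orientation, then keep the max score per pair
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  agg <- tapply(w, key, max)
  n_dup <- length(key) - length(agg)
  if (length(agg) == 0)
    stop("empty network after filtering at min_confidence = ", min_confidence)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  edges <- data.frame(protein_a = vapply(parts, `[`, "", 1),
                      protein_b = vapply(parts, `[`, "", 2),
                      weight = as.numeric(agg),
                      stringsAsFactors = FALSE, row.names = NULL)
  edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(protein_ids = sort(unique(c(edges$protein_a, edges$protein_b))),
                 edges = edges,
                 report = list(n_input = n_input, n_below_threshold = n_below,
                               n_self_loops = n_self, n_duplicates_collapsed = n_dup,
                               min_confidence = min_confidence)),
            class = "ddi_ppi_network")
}

#' @export
print.ddi_ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d proteins, %d edges (dropped %d below %.0f, %d self-loops)\n",
              length(x$protein_ids), nrow(x$edges),
              x$report$n_below_threshold, x$report$min_confidence,
              x$report$n_self_loops))
  invisible(x)
}

#' Column-stochastic transition matrix of a PPI network
#'
#' Entry (i, j) is `weight(i, j) / sum_i weight(i, j)`: the probability of
#' stepping to protein i from protein j, proportional to edge evidence.
#' Columns of isolated (degree-zero) nodes are all zero and their ids are
#' recorded in the `"isolated"` attribute.
#'
#' @param network a `ddi_ppi_network`.
#' @return sparse M x M `dgCMatrix` with protein ids as dimnames.
#' @export
transition_matrix <- function(network) {
  stopifnot(inherits(network, "ddi_ppi_network"))
  ids <- network$protein_ids
  m <- length(ids)
  if (m == 0) stop("empty network")
  i <- match(network$edges$protein_a, ids)
  j <- match(network$edges$protein_b, ids)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(network$edges$weight, 2),
                            dims = c(m, m), dimnames = list(ids, ids))
  cs <- Matrix::colSums(A)
  isolated <- ids[cs == 0]
  inv <- ifelse(cs > 0, 1 / cs, 0)
  W <- A %*% Matrix::Diagonal(m, inv)
  dimnames(W) <- list(ids, ids)
  W <- methods::as(W, "CsparseMatrix")
  attr(W, "isolated") <- isolated
  W
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - restart) * W %*% p + restart * seed` from `p = seed`
#' until the L1 change drops below `tol` or `max_iter` is reached.  For a
#' column-stochastic `W` the iteration converges to the seed-biased
#' stationary distribution `restart * solve(I - (1 - restart) * W) %*% seed`.
#'
#' @param W column-stochastic M x M matrix (dense or sparse).
#' @param seed non-negative length-M vector summing to 1.
#' @param restart restart probability in (0, 1); default 0.5, the customary
#'   setting in network-propagation studies of gene/protein neighborhoods.
#' @param tol L1 convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' Mass that would leak through dangling all-zero columns (isolated nodes)
#' is restarted at the seed, so scores always sum to 1.
#'
#' @return object of class `ddi_diffusion_profile`: list with `scores`
#'   (named when `W` has dimnames), `restart`, `converged`, `iterations`.
#' @export
rwr <- function(W, seed, restart = 0.5, tol = 1e-6, max_iter = 1000) {
  if (!(restart > 0 && restart < 1)) stop("restart must be in (0, 1)")
  if (any(seed < 0)) stop("seed must be non-negative")
  s <- sum(seed)
  if (s == 0) stop("seed sums to 0; handle empty seed sets before calling rwr")
  if (abs(s - 1) > 1e-8) stop("seed must sum to 1")
  if (length(seed) != nrow(W)) stop("seed length does not match W")
  p <- seed
  delta <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    wp <- as.numeric(W %*% p)
    # mass leaving through dangling (all-zero) columns restarts at the
    # seed, so the walk conserves probability on any sub-stochastic W
    dangling <- sum(p) - sum(wp)
    p_new <- (1 - restart) * (wp + dangling * seed) + restart * seed
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
  }
  names(p) <- rownames(W)
  structure(list(scores = p, restart = restart,
                 converged = delta < tol, iterations = it, tol = tol),
            class = "ddi_diffusion_profile")
}

#' Read a drug-to-protein (CTET) association table
#'
#' @param x path to a TSV with columns `drug_id`, `protein_id`, or an
#'   equivalent data.frame.
#' @return data.frame with character columns `drug_id`, `protein_id`.
#' @export
read_associations <- function(x) {
  if (is.character(x)) {
    df <- read_tsv_checked(x, c("drug_id", "protein_id"), "association")
  } else {
    df <- as.data.frame(x)
    miss <- setdiff(c("drug_id", "protein_id"), names(df))
    if (length(miss) > 0)
      stop("association table is missing column(s): ",
           paste(miss, collapse = ", "))
  }
  data.frame(drug_id = as.character(df$drug_id),
             protein_id = as.character(df$protein_id),
             stringsAsFactors = FALSE)
}

#' Diffusion profiles for every drug
#'
#' Seeds a random walk with restart at each drug's mapped proteins (uniform
#' mass over those present in the network) and collects the stationary
#' scores.  Drugs whose mapped proteins all fall outside the network — or
#' that have no mapping at all — get an all-zero profile and are flagged
#' rather than dropped.  Identical seed sets are solved once and shared.
#'
#' @param associations data.frame (`drug_id`, `protein_id`) or path; see
#'   [read_associations()].
#' @param network a `ddi_ppi_network`.
#' @param restart,tol,max_iter passed to [rwr()].
#' @param drug_ids optional vector fixing the set and order of drugs;
#'   defaults to the drugs appearing in `associations`.
#' @return object of class `ddi_diffusion_profiles`: list with `scores`
#'   (N x M matrix, drugs by proteins), `zero_profile` (named flag vector),
#'   `converged`, `iterations`, `restart`, and `dropped_proteins` (the
#'   associations pointing outside the network).
#' @export
drug_diffusion_profiles <- function(associations, network, restart = 0.5,
                                    tol = 1e-6, max_iter = 1000,
                                    drug_ids = NULL) {
  assoc <- read_associations(associations)
  stopifnot(inherits(network, "ddi_ppi_network"))
  ids <- drug_ids %||% sort(unique(assoc$drug_id))
  ids <- as.character(ids)
  prot <- network$protein_ids
  m <- length(prot)
  W <- transition_matrix(network)
  in_net <- assoc$protein_id %in% prot
  dropped <- assoc[!in_net, , drop = FALSE]
  assoc <- assoc[in_net, , drop = FALSE]
  seed_sets <- split(match(assoc$protein_id, prot), assoc$drug_id)

  scores <- matrix(0, length(ids), m, dimnames = list(ids, prot))
  converged <- rep(NA, length(ids)); iterations <- rep(NA_integer_, length(ids))
  zero_profile <- rep(FALSE, length(ids))
  names(converged) <- names(iterations) <- names(zero_profile) <- ids
  cache <- new.env(parent = emptyenv())
  for (d in ids) {
    idx <- sort(unique(seed_sets[[d]]))
    if (length(idx) == 0) {
      zero_profile[d] <- TRUE
      next
    }
    key <- paste(idx, collapse = ",")
    prof <- get0(key, envir = cache)
    if (is.null(prof)) {
      seed <- numeric(m)
      seed[idx] <- 1 / length(idx)
      prof <- rwr(W, seed, restart = restart, tol = tol, max_iter = max_iter)
      assign(key, prof, envir = cache)
    }
    scores[d, ] <- prof$scores
    converged[d] <- prof$converged
    iterations[d] <- prof$iterations
  }
  if (any(zero_profile))
    warning(sum(zero_profile), " drug(s) have no mapped network proteins; ",
            "their diffusion profiles are all-zero and flagged")
  structure(list(scores = scores, zero_profile = zero_profile,
                 converged = converged, iterations = iterations,
                 restart = restart, dropped_proteins = dropped),
            class = "ddi_diffusion_profiles")
}

# Row-wise cosine similarity; all-zero rows get similarity 0 to everything
# and 1 to themselves.
cosine_similarity <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  xn <- x / ifelse(nrm > 0, nrm, 1)
  S <- tcrossprod(xn)
  diag(S) <- 1
  S
}

#' Build the PSP feature from diffusion profiles
#'
#' Mirrors the SSP construction: each drug's profile is its similarity to
#' every drug — here the cosine similarity between diffusion score vectors
#' — and the resulting N x N matrix is PCA-reduced to `k` components.
#' `method = "raw"` instead reduces the diffusion score matrix directly
#' (drugs by proteins), the alternative reading of a diffusion-based
#' profile.
#'
#' @param profiles a `ddi_diffusion_profiles` object (or plain drugs x
#'   proteins score matrix).
#' @param k components to retain; default 300.
#' @param method `"cosine"` (default) or `"raw"`.
#' @param variance_target passed to [reduce_pca()].
#' @return a `ddi_reduced_profile`; for `method = "cosine"` the similarity
#'   matrix is attached as attribute `"similarity"`.
#' @export
build_psp <- function(profiles, k = 300, method = c("cosine", "raw"),
                      variance_target = 0.95) {
  method <- match.arg(method)
  x <- if (inherits(profiles, "ddi_diffusion_profiles")) profiles$scores
       else as.matrix(profiles)
  if (method == "cosine") {
    S <- cosine_similarity(x)
    red <- reduce_pca(S, k, variance_target = variance_target)
    attr(red, "similarity") <- S
  } else {
    red <- reduce_pca(x, k, variance_target = variance_target)
  }
  red
}
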