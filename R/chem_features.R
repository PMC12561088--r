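# Structural similarity profile (SSP): SMILES -> extended-connectivity
# fingerprints -> pairwise Tanimoto matrix -> PCA-reduced per-drug profile.

# Native bit width of the OpenBabel ECFP implementation; requested bit
# spaces are folded down from this by modular OR.
.OB_ECFP_BITS <- 4096L

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to the backend's canonical form, so that chemically
#' identical inputs written differently (e.g. aromatic vs Kekulé benzene)
#' map to identical fingerprints.  Drug tables aggregated from several
#' sources routinely mix such variants.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length.
#' @examples
#' canonical_smiles(c("C1=CC=CC=C1", "c1ccccc1"))
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) stop("empty SMILES string", call. = FALSE)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = s),
                    error = function(e) "")
    out <- sub("[ \t\r\n].*$", "", out)
    if (!nzchar(out))
      stop("SMILES parse error: '", s, "'", call. = FALSE)
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Extended-connectivity fingerprint from a SMILES string
#'
#' Hashes circular substructures of the molecule up to the given radius
#' (radius 2 = ECFP4, radius 3 = ECFP6) and folds the resulting bit set
#' into an `n_bits`-wide binary space.  Deterministic: identical inputs
#' always yield identical bit sets.
#'
#' @param smiles single SMILES string.
#' @param radius neighborhood radius, 2 (ECFP4, default) or 3 (ECFP6).
#' @param n_bits width of the folded bit space; a power of two in
#'   \[1024, 4096\] (the backend's native width).  Default 2048.
#' @param drug_id optional identifier carried on the fingerprint.
#' @param canonicalize canonicalize the SMILES first (default `TRUE`).
#' @return an object of class `ddi_fingerprint`: a list with `drug_id`,
#'   sorted 0-based `on_bits`, `radius`, `n_bits` and an `empty` flag for
#'   degenerate molecules that set no bits.
#' @examples
#' fp <- fingerprint_from_smiles("c1ccccc1CCO", drug_id = "D1")
#' length(fp$on_bits)
#' @export
fingerprint_from_smiles <- function(smiles, radius = 2, n_bits = 2048,
                                    drug_id = NULL, canonicalize = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (is.na(smiles) || !nzchar(smiles)) stop("empty SMILES string")
  if (!radius %in% c(2, 3)) stop("radius must be 2 (ECFP4) or 3 (ECFP6)")
  if (!is_power_of_two(n_bits) || n_bits < 1024)
    stop("n_bits must be a power of two >= 1024")
  if (n_bits > .OB_ECFP_BITS)
    stop("n_bits must not exceed the fingerprint backend's native ",
         .OB_ECFP_BITS, "-bit space")
  smi <- if (canonicalize) canonical_smiles(smiles) else smiles
  mol <- tryCatch(ChemmineOB::forEachMol("SMILES", smi, identity),
                  error = function(e)
                    stop("SMILES parse error: '", smiles, "'", call. = FALSE))
  name <- if (radius == 2) "ECFP4" else "ECFP6"
  bits <- ChemmineOB::fingerprint_OB(mol, name)
  on_native <- which(as.numeric(bits) > 0) - 1L
  on_bits <- sort(unique(on_native %% as.integer(n_bits)))
  structure(list(drug_id = drug_id,
                 on_bits = as.integer(on_bits),
                 radius = as.integer(radius),
                 n_bits = as.integer(n_bits),
                 empty = length(on_bits) == 0L),
            class = "ddi_fingerprint")
}

#' Fingerprint every drug in a drug table
#'
#' @param drugs data.frame with columns `drug_id` and `smiles`.
#' @inheritParams fingerprint_from_smiles
#' @return list of [fingerprint_from_smiles()] objects, one per row.
#' @export
fingerprints_from_table <- function(drugs, radius = 2, n_bits = 2048,
                                    canonicalize = TRUE) {
  stopifnot(is.data.frame(drugs), all(c("drug_id", "smiles") %in% names(drugs)))
  unname(Map(function(s, id) fingerprint_from_smiles(
    s, radius = radius, n_bits = n_bits, drug_id = id,
    canonicalize = canonicalize),
    drugs$smiles, drugs$drug_id))
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|A intersect B| / |A union B|` over the on-bit sets.  When both
#' fingerprints are empty the ratio is 0/0; it is defined here as 0 (with a
#' warning) since empty fingerprints carry no evidence of similarity.
#'
#' @param a,b `ddi_fingerprint` objects with equal `n_bits`.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "ddi_fingerprint"), inherits(b, "ddi_fingerprint"))
  if (a$n_bits != b$n_bits)
    stop("fingerprints have mismatched n_bits: ", a$n_bits, " vs ", b$n_bits)
  na <- length(a$on_bits); nb <- length(b$on_bits)
  if (na == 0L && nb == 0L) {
    warning("both fingerprints are empty; Tanimoto defined as 0")
    return(0)
  }
  inter <- length(intersect(a$on_bits, b$on_bits))
  inter / (na + nb - inter)
}

#' Pairwise Tanimoto similarity matrix (the SSP before reduction)
#'
#' Row i is drug i's structural similarity profile: its Tanimoto similarity
#' to every drug in the collection.  Computed through a sparse drug-by-bit
#' incidence matrix, so it scales to thousands of drugs.
#'
#' @param fingerprints list of `ddi_fingerprint` objects sharing `n_bits`,
#'   each with a unique, non-missing `drug_id`.
#' @return symmetric N x N numeric matrix in \[0, 1\] with drug ids as
#'   dimnames and unit diagonal for non-empty fingerprints.  Ids of empty
#'   fingerprints are recorded in the `"empty_drugs"` attribute.
#' @export
build_ssp <- function(fingerprints) {
  stopifnot(is.list(fingerprints), length(fingerprints) >= 1)
  ids <- unname(vapply(fingerprints, function(f) {
    if (is.null(f$drug_id)) stop("every fingerprint needs a drug_id")
    as.character(f$drug_id)
  }, character(1)))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate drug_id: ", paste(unique(dup), collapse = ", "))
  nb <- unique(vapply(fingerprints, `[[`, integer(1), "n_bits"))
  if (length(nb) != 1) stop("fingerprints have mismatched n_bits")

  n <- length(fingerprints)
  sizes <- vapply(fingerprints, function(f) length(f$on_bits), integer(1))
  X <- Matrix::sparseMatrix(
    i = rep(seq_len(n), sizes),
    j = unlist(lapply(fingerprints, `[[`, "on_bits")) + 1L,
    x = 1, dims = c(n, nb))
  inter <- as.matrix(X %*% Matrix::t(X))
  uni <- outer(sizes, sizes, `+`) - inter
  S <- ifelse(uni == 0, 0, inter / uni)
  diag(S) <- ifelse(sizes > 0, 1, 0)
  dimnames(S) <- list(ids, ids)
  empty <- ids[sizes == 0L]
  if (length(empty) > 0)
    warning("empty fingerprints (similarity 0 to everything): ",
            paste(empty, collapse = ", "))
  attr(S, "empty_drugs") <- empty
  S
}

#' PCA-reduce a per-drug profile matrix
#'
#' Projects the mean-centered rows onto their top-`k` principal axes.  The
#' reduction is expected to preserve at least `variance_target` of the
#' variance; when it does not, the result is flagged (`variance_ok =
#' FALSE`), not rejected.
#'
#' By default the PCA is fit on all rows (transductive, matching how
#' similarity profiles are built over the full drug collection).  Passing
#' `fit_rows` fits the axes on a subset (e.g. training drugs only) and
#' projects everything — the leakage-safe alternative.
#'
#' @param x numeric matrix, rows = drugs (a similarity matrix or any
#'   profile matrix); rownames are carried to the output.
#' @param k number of components to retain, `1 <= k <= min(nrow, ncol)`.
#' @param fit_rows optional row indices (or rownames) to fit the PCA on.
#' @param variance_target cumulative explained-variance threshold used for
#'   the validation flag (default 0.95).
#' @return object of class `ddi_reduced_profile`: list with `components`
#'   (N x k scores), `explained_variance_ratio` (length k, non-increasing),
#'   `cumulative_variance`, `variance_ok`, `k`, and the fitted `rotation`
#'   and `center` for projecting new data.
#' @export
reduce_pca <- function(x, k, fit_rows = NULL, variance_target = 0.95) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("need at least 2 rows for PCA")
  if (k < 1) stop("k must be >= 1")
  if (k > min(n, p))
    stop("k = ", k, " exceeds min(rows, source dimension) = ", min(n, p))
  fit <- if (is.null(fit_rows)) x else x[fit_rows, , drop = FALSE]
  pc <- stats::prcomp(fit, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  kk <- min(k, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(kk), drop = FALSE]
  scores <- scale(x, center = pc$center, scale = FALSE) %*% rot
  evr <- (pc$sdev^2 / total_var)[seq_len(kk)]
  if (kk < k) {    # rank-deficient input: pad with exact-zero components
    scores <- cbind(scores, matrix(0, n, k - kk))
    evr <- c(evr, rep(0, k - kk))
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(x)
  cum_var <- sum(evr)
  structure(list(components = scores,
                 explained_variance_ratio = evr,
                 cumulative_variance = cum_var,
                 variance_ok = cum_var >= variance_target,
                 variance_target = variance_target,
                 k = as.integer(k),
                 rotation = rot,
                 center = pc$center),
            class = "ddi_reduced_profile")
}

#' @export
print.ddi_reduced_profile <- function(x, ...) {
  cat(sprintf("PCA-reduced profile: %d drugs x %d components, %.1f%% variance%s\n",
              nrow(x$components), x$k, 100 * x$cumulative_variance,
              if (x$variance_ok) "" else
                sprintf("  [below %.0f%% target]", 100 * x$variance_target)))
  invisible(x)
}
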