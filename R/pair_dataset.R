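# Labeled ordered drug pairs: readers, the class catalog,
# insufficient-class filtering, and the stratified train/val/test split.

#' Read a drug table
#'
#' @param path TSV with header columns `drug_id`, `name`, `smiles`,
#'   `description` (UTF-8).
#' @return data.frame with character columns.
#' @export
read_drug_table <- function(path) {
  df <- read_tsv_checked(path, c("drug_id", "name", "smiles", "description"),
                         "drug")
  if (anyDuplicated(df$drug_id))
    stop("duplicate drug_id in ", path)
  df
}

#' Read a labeled ordered drug-pair table
#'
#' Pairs are ordered: (A, B) and (B, A) are distinct records, because class
#' sentences are directional ("the concentration of Drug B is increased
#' ...").
#'
#' @param path TSV with columns `drug_a`, `drug_b`, `class_id`
#'   (non-negative integer).
#' @return data.frame with `drug_a`, `drug_b` (character) and `class_id`
#'   (integer).
#' @export
read_pairs <- function(path) {
  df <- read_tsv_checked(path, c("drug_a", "drug_b", "class_id"), "pair")
  cls <- suppressWarnings(as.integer(df$class_id))
  bad <- which(is.na(cls) | cls < 0)
  if (length(bad) > 0)
    stop("invalid class_id at line ", bad[1] + 1L, " of ", path)
  out <- data.frame(drug_a = as.character(df$drug_a),
                    drug_b = as.character(df$drug_b),
                    class_id = cls, stringsAsFactors = FALSE)
  if (any(out$drug_a == out$drug_b))
    stop("self-pair (drug_a == drug_b) in ", path)
  out
}

#' Read a class catalog
#'
#' @param path TSV with columns `class_id`, `description`.
#' @return data.frame with integer `class_id` and character `description`.
#' @export
read_class_catalog <- function(path) {
  df <- read_tsv_checked(path, c("class_id", "description"), "class catalog")
  data.frame(class_id = as.integer(df$class_id),
             description = as.character(df$description),
             stringsAsFactors = FALSE)
}

#' Drop interaction classes with insufficient data
#'
#' Classes with fewer than `min_count` pairs are removed together with
#' their pairs, and the survivors are re-indexed contiguously from 0.  The
#' returned catalog retains the original ids so predictions can be mapped
#' back.
#'
#' @param pairs data.frame of ordered pairs (see [read_pairs()]).
#' @param min_count minimum pairs a class needs to survive; default 5, the
#'   smallest count that lets every class populate all three partitions
#'   under stratification.
#' @param catalog optional class catalog supplying descriptions.
#' @return list with `pairs` (re-indexed), `catalog` (data.frame
#'   `class_id`, `original_class_id`, `description`, `count`) and `removed`
#'   (data.frame of dropped classes with their counts).
#' @export
filter_classes <- function(pairs, min_count = 5, catalog = NULL) {
  stopifnot(min_count >= 1)
  counts <- table(pairs$class_id)
  orig <- as.integer(names(counts))
  keep <- as.integer(counts) >= min_count
  if (!any(keep))
    stop("all classes fall below min_count = ", min_count)
  kept_orig <- sort(orig[keep])
  removed <- data.frame(original_class_id = sort(orig[!keep]),
                        count = as.integer(counts[as.character(sort(orig[!keep]))]),
                        row.names = NULL)
  new_id <- seq_along(kept_orig) - 1L
  map <- stats::setNames(new_id, kept_orig)
  out <- pairs[pairs$class_id %in% kept_orig, , drop = FALSE]
  out$class_id <- unname(map[as.character(out$class_id)])
  rownames(out) <- NULL
  cat_out <- data.frame(class_id = new_id, original_class_id = kept_orig,
                        description = NA_character_,
                        count = as.integer(counts[as.character(kept_orig)]),
                        row.names = NULL)
  if (!is.null(catalog))
    cat_out$description <-
      catalog$description[match(kept_orig, catalog$class_id)]
  list(pairs = out, catalog = cat_out, removed = removed)
}

# Largest-remainder apportionment of n into parts proportional to ratios.
# Ties in the fractional parts are broken by position (earlier part wins).
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- round(n - sum(base))
  if (rem > 0) {
    frac <- exact - base
    ord <- order(-frac, seq_along(ratios))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stratified train/validation/test split of ordered pairs
#'
#' Within every class, the partition sizes are the largest-remainder
#' apportionment of the class size by `ratios`, so per-class proportions
#' match the global ratios as closely as integer counts allow (the test
#' fraction of each class is within 1/class-size of the target).  Which
#' pairs land where is a seeded within-class shuffle: the assignment is
#' fully reproducible given the seed.
#'
#' @param pairs data.frame of ordered pairs with `class_id`.
#' @param ratios length-3 numeric summing to 1; default
#'   `c(train = 0.64, val = 0.16, test = 0.20)`.
#' @param seed integer RNG seed for the within-class shuffles.
#' @return the input data.frame with an added `partition` factor
#'   (`train`/`val`/`test`); attributes `"seed"` and `"ratios"`.
#' @export
stratified_split <- function(pairs,
                             ratios = c(train = 0.64, val = 0.16, test = 0.20),
                             seed = 1) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8, all(ratios > 0))
  parts <- c("train", "val", "test")
  sizes <- table(pairs$class_id)
  if (any(sizes < 3))
    stop("class(es) with fewer than 3 pairs: ",
         paste(names(sizes)[sizes < 3], collapse = ", "),
         "; run filter_classes() first")
  partition <- character(nrow(pairs))
  with_preserved_rng(seed, {
    for (cl in sort(unique(pairs$class_id))) {
      idx <- which(pairs$class_id == cl)
      counts <- largest_remainder(length(idx), ratios)
      idx <- idx[sample.int(length(idx))]
      partition[idx] <- rep(parts, counts)
    }
  })
  pairs$partition <- factor(partition, levels = parts)
  attr(pairs, "seed") <- seed
  attr(pairs, "ratios") <- stats::setNames(as.numeric(ratios), parts)
  pairs
}

#' Symmetric augmentation of ordered pairs
#'
#' Adds the reversed record (B, A) with the same class for every pair whose
#' reverse is not already present.  Off by default throughout the package:
#' interaction sentences are directional, so blanket symmetrization is only
#' sound for classes known to be symmetric.
#'
#' @param pairs data.frame of ordered pairs.
#' @return augmented data.frame.
#' @export
augment_symmetric <- function(pairs) {
  key <- paste(pairs$drug_a, pairs$drug_b, sep = "\r")
  rev <- data.frame(drug_a = pairs$drug_b, drug_b = pairs$drug_a,
                    class_id = pairs$class_id, stringsAsFactors = FALSE)
  rev_key <- paste(rev$drug_a, rev$drug_b, sep = "\r")
  out <- rbind(pairs[, c("drug_a", "drug_b", "class_id")],
               rev[!(rev_key %in% key), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Write a split assignment to TSV
#'
#' @param split output of [stratified_split()].
#' @param path output TSV path.
#' @export
write_split <- function(split, path) {
  utils::write.table(split, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
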