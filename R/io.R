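# Writers for derived per-drug features: dense TSV matrices with a
# drug_id index column plus a JSON sidecar recording provenance settings.

#' Write a reduced profile (SSP/PSP) to TSV with a JSON sidecar
#'
#' @param reduced a `ddi_reduced_profile`.
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param settings named list of provenance settings (radius, n_bits,
#'   restart, thresholds, ...) recorded in the sidecar alongside `k` and
#'   the explained variance.
#' @return named character vector of the two paths, invisibly.
#' @export
write_reduced_profile <- function(reduced, prefix, settings = list()) {
  stopifnot(inherits(reduced, "ddi_reduced_profile"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  df <- data.frame(drug_id = rownames(reduced$components),
                   reduced$components, check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(settings,
      list(k = reduced$k,
           explained_variance_ratio = reduced$explained_variance_ratio,
           cumulative_variance = reduced$cumulative_variance,
           variance_ok = reduced$variance_ok)),
    json, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Write an embedding matrix to TSV with a JSON sidecar
#'
#' @param embeddings matrix from [embed_texts()].
#' @param prefix output path prefix.
#' @return named character vector of the two paths, invisibly.
#' @export
write_embeddings <- function(embeddings, prefix) {
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  df <- data.frame(drug_id = rownames(embeddings), embeddings,
                   check.names = FALSE)
  colnames(df) <- c("drug_id", paste0("V", seq_len(ncol(embeddings))))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  trunc <- attr(embeddings, "truncated")
  jsonlite::write_json(
    list(provider = attr(embeddings, "provider") %||% "unknown",
         dim = ncol(embeddings),
         n_truncated = if (is.null(trunc)) 0L else sum(trunc)),
    json, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Read a per-drug feature matrix written by the writers above
#'
#' @param path TSV with a `drug_id` first column.
#' @return numeric matrix with drug ids as rownames.
#' @export
read_feature_matrix <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (names(df)[1] != "drug_id") stop(path, " has no drug_id index column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$drug_id)
  m
}
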