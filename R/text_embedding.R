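# Drug text preparation and fixed 768-dimensional semantic embeddings via
# a pluggable provider.  The deterministic mock provider is the built-in
# backend; any object of class `ddi_embedding_provider` that produces
# length-768 vectors (e.g. a transformer [CLS]-state extractor) plugs in.

#' Prepare a drug's text for embedding
#'
#' If the drug's name already occurs in its description (case-insensitive,
#' literal match), the description is used as provided; otherwise the name
#' is prepended ("name. description").  An empty description yields the
#' bare name.  Idempotent: preparing an already-prepared text returns it
#' unchanged.
#'
#' @param name drug name, non-empty.
#' @param description free-text description (may be empty or `NA`).
#' @return the prepared text, a single string containing the name.
#' @examples
#' prepare_text("Aspirin", "Aspirin is a salicylate.")
#' prepare_text("Aspirin", "A common salicylate.")
#' @export
prepare_text <- function(name, description) {
  if (is.null(name) || is.na(name) || !nzchar(name))
    stop("drug name must be non-empty")
  if (is.null(description) || is.na(description) || !nzchar(description))
    return(name)
  if (grepl(tolower(name), tolower(description), fixed = TRUE))
    return(description)
  paste0(name, ". ", description)
}

#' Prepare every drug text in a drug table
#'
#' @param drugs data.frame with columns `drug_id`, `name`, `description`.
#' @return the input with an added `prepared` column.
#' @export
prepare_drug_texts <- function(drugs) {
  stopifnot(is.data.frame(drugs))
  miss <- setdiff(c("drug_id", "name", "description"), names(drugs))
  if (length(miss) > 0)
    stop("drug table is missing column(s): ", paste(miss, collapse = ", "))
  drugs$prepared <- mapply(prepare_text, drugs$name, drugs$description,
                           USE.NAMES = FALSE)
  drugs
}

#' Deterministic mock embedding provider
#'
#' A test/benchmark backend standing in for a transformer text encoder.
#' Each text is embedded as `(1 - noise) * e + noise * u`, where `e` is the
#' unit basis direction assigned (via `keyword_map`) to the first keyword
#' found in the text, and `u` is a unit-norm pseudo-random vector seeded by
#' a stable hash of the text and the provider seed.  Texts sharing a
#' keyword therefore embed close together (cosine ~ (1-noise)^2 /
#' (1-2*noise+2*noise^2) > 0.9 at the default noise), while texts with
#' different keywords embed nearly orthogonally.  Texts matching no keyword
#' embed as pure noise.
#'
#' @param seed integer provider seed.
#' @param keyword_map named integer vector mapping keyword (lower-cased
#'   literal substring) to a basis direction index in 1..`dim`.
#' @param noise mixing weight of the pseudo-random component, in \[0, 1);
#'   default 0.1.
#' @param dim embedding dimension; default 768.
#' @param token_limit maximum whitespace-token length accepted before
#'   [embed_texts()] truncates; default 512.
#' @return object of class `ddi_embedding_provider` with fields `name`,
#'   `dim`, `token_limit` and a function `embed_one(text)`.
#' @export
mock_embedding_provider <- function(seed = 1, keyword_map = integer(0),
                                    noise = 0.1, dim = 768,
                                    token_limit = 512) {
  stopifnot(noise >= 0, noise < 1, dim >= 1)
  keyword_map <- unlist(keyword_map)
  if (length(keyword_map) > 0) {
    if (is.null(names(keyword_map)) || any(!nzchar(names(keyword_map))))
      stop("keyword_map must be a named vector (keyword -> direction index)")
    if (any(keyword_map < 1 | keyword_map > dim))
      stop("keyword_map direction indices must lie in 1..dim")
  }
  keywords <- tolower(names(keyword_map))
  embed_one <- function(text) {
    stopifnot(is.character(text), length(text) == 1)
    h <- stable_hash(text)
    u <- with_preserved_rng(as.integer((seed * 1000003 + h) %% 2147483647), {
      v <- stats::rnorm(dim)
      v / sqrt(sum(v^2))
    })
    lt <- tolower(text)
    hit <- which(vapply(keywords, function(k) grepl(k, lt, fixed = TRUE),
                        logical(1)))
    if (length(hit) == 0) return(u)
    e <- numeric(dim)
    e[keyword_map[[hit[1]]]] <- 1
    (1 - noise) * e + noise * u
  }
  structure(list(name = "mock", dim = as.integer(dim),
                 token_limit = as.integer(token_limit),
                 seed = as.integer(seed), noise = noise,
                 embed_one = embed_one),
            class = "ddi_embedding_provider")
}

#' Embed prepared drug texts
#'
#' Produces one fixed-length vector per drug through the given provider.
#' Texts longer than the provider's token limit (whitespace tokens) are
#' truncated to the limit and flagged, preserving the drug rather than
#' dropping it.
#'
#' @param texts data.frame with columns `drug_id` and `prepared` (see
#'   [prepare_drug_texts()]).
#' @param provider a `ddi_embedding_provider`.
#' @return N x `dim` numeric matrix with drug ids as rownames; attributes
#'   `"truncated"` (named logical vector) and `"provider"` (provider name).
#' @export
embed_texts <- function(texts, provider) {
  stopifnot(is.data.frame(texts), inherits(provider, "ddi_embedding_provider"))
  miss <- setdiff(c("drug_id", "prepared"), names(texts))
  if (length(miss) > 0)
    stop("texts need column(s): ", paste(miss, collapse = ", "),
         "; run prepare_drug_texts() first")
  n <- nrow(texts)
  out <- matrix(NA_real_, n, provider$dim,
                dimnames = list(as.character(texts$drug_id), NULL))
  truncated <- logical(n)
  names(truncated) <- rownames(out)
  for (i in seq_len(n)) {
    txt <- texts$prepared[i]
    toks <- strsplit(txt, "[[:space:]]+")[[1]]
    if (length(toks) > provider$token_limit) {
      txt <- paste(toks[seq_len(provider$token_limit)], collapse = " ")
      truncated[i] <- TRUE
    }
    v <- tryCatch(provider$embed_one(txt), error = function(e)
      stop("embedding failed for drug ", texts$drug_id[i], ": ",
           conditionMessage(e), call. = FALSE))
    if (length(v) != provider$dim || any(!is.finite(v)))
      stop("embedding failed for drug ", texts$drug_id[i],
           ": provider returned an invalid vector")
    out[i, ] <- v
  }
  attr(out, "truncated") <- truncated
  attr(out, "provider") <- provider$name
  out
}
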