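`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' @noRd
is_power_of_two <- function(x) {
  x == round(x) && x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

# Deterministic 31-adic string hash modulo 2^31 - 1.  Used to derive
# per-text RNG streams; exact in double arithmetic (31 * 2^31 < 2^53).
stable_hash <- function(text) {
  codes <- utf8ToInt(enc2utf8(text))
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  h
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Read a TSV with required columns, erroring with the file and the missing
# column names.  Returns a plain data.frame.
read_tsv_checked <- function(path, required, what = "table") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = "character",
                                        encoding = "UTF-8"))
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}
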