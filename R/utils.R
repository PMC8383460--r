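# Shared helpers: classed conditions, text normalization, seeded evaluation.

#' @importFrom data.table data.table as.data.table rbindlist setDT setkey :=
#' @importFrom stats runif setNames
#' @importFrom utils head read.delim write.table
NULL

abort <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "phenomine_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a label or free-text string
#'
#' The matching policy used everywhere in the package: lowercase, collapse
#' internal whitespace to single spaces, strip leading/trailing punctuation
#' from every token. No stemming. Internal punctuation (apostrophes, hyphens)
#' is kept so that e.g. "Alzheimer's disease" survives as one term.
#'
#' @param x character vector of labels or text.
#' @return character vector of normalized strings ("" if nothing survives).
#' @export
normalize_label <- function(x) {
  vapply(x, function(s) paste(tokenize_text(s), collapse = " "), "",
         USE.NAMES = FALSE)
}

# Tokenize under the same policy; returns a character vector of tokens.
tokenize_text <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  toks <- strsplit(tolower(s), "[[:space:]]+")[[1]]
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 2654435761 + 97 * seq_len(n)) %% 2147483629
}

pair_key <- function(disease, phenotype) paste(disease, phenotype, sep = "\r")
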