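# Corpus ingestion, mention detection and abstract-level co-occurrence
# counting over two ontologies (disease side and phenotype side).

#' Read an abstract corpus
#'
#' Accepts JSON-lines (objects with `doc_id`, `title`, `body`) or 3-column
#' TSV (doc_id, title, body; no header).
#'
#' @param path corpus file.
#' @param format `"jsonl"` or `"tsv"`; guessed from the extension by default.
#' @return data.frame with columns doc_id, title, body.
#' @export
read_corpus <- function(path, format = NULL) {
  if (!file.exists(path)) abort("phenomine_io", "corpus not found: %s", path)
  format <- format %||%
    (if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv")
  if (format == "jsonl") {
    recs <- lapply(readLines(path, warn = FALSE), jsonlite::fromJSON)
    out <- data.frame(
      doc_id = vapply(recs, function(r) as.character(r$doc_id), ""),
      title = vapply(recs, function(r) as.character(r$title %||% ""), ""),
      body = vapply(recs, function(r) as.character(r$body %||% ""), ""),
      stringsAsFactors = FALSE)
  } else {
    out <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                      quote = "", col.names = c("doc_id", "title", "body"))
    out$doc_id <- as.character(out$doc_id)
  }
  if (anyDuplicated(out$doc_id))
    abort("phenomine_io", "duplicate doc_id in corpus: %s",
          out$doc_id[duplicated(out$doc_id)][1])
  out
}

# Longest-match, non-overlapping scan of a token vector against one lexicon.
# Returns the character vector of matched class ids (deduplicated).
scan_tokens <- function(tokens, lex) {
  n <- length(tokens)
  if (!n || !length(lex$terms)) return(character(0))
  hits <- character(0)
  i <- 1L
  while (i <= n) {
    matched <- 0L
    for (len in seq(min(lex$max_tokens, n - i + 1L), 1L)) {
      key <- paste(tokens[i:(i + len - 1L)], collapse = " ")
      cls <- lex$terms[[key]]
      if (!is.null(cls)) {
        hits <- c(hits, cls)
        matched <- len
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  unique(hits)
}

#' Detect direct class mentions in one document
#'
#' Title and body are concatenated, normalized, and scanned with
#' longest-match non-overlapping matching on token boundaries, separately
#' against the disease and the phenotype lexicon. A term mapping to several
#' classes yields all of them. No hierarchy propagation is applied here.
#'
#' @param doc list or one-row data.frame with `title` and `body`.
#' @param lex_disease,lex_phenotype `term_lexicon` objects.
#' @return data.frame with columns class_id, ontology ("disease"/"phenotype").
#' @export
match_mentions <- function(doc, lex_disease, lex_phenotype) {
  toks <- tokenize_text(paste(doc$title %||% "", doc$body %||% ""))
  d <- scan_tokens(toks, lex_disease)
  p <- scan_tokens(toks, lex_phenotype)
  data.frame(class_id = c(d, p),
             ontology = rep(c("disease", "phenotype"), c(length(d), length(p))),
             stringsAsFactors = FALSE)
}

#' Close a mention set under superclass addition
#'
#' Every mention of a class is also a mention of each of its superclasses
#' within the same ontology.
#'
#' @param hits data.frame as returned by [match_mentions()].
#' @param g_disease,g_phenotype `ontology_graph` objects (either may be
#'   `NULL` to skip that side).
#' @return data.frame of the same shape, closed under ancestor addition.
#' @export
propagate_mentions <- function(hits, g_disease = NULL, g_phenotype = NULL) {
  close_side <- function(ids, g) {
    if (is.null(g) || !length(ids)) return(ids)
    unique(unlist(lapply(ids, function(i) ancestors(g, i, include_self = TRUE)),
                  use.names = FALSE))
  }
  d <- close_side(hits$class_id[hits$ontology == "disease"], g_disease)
  p <- close_side(hits$class_id[hits$ontology == "phenotype"], g_phenotype)
  data.frame(class_id = c(d, p),
             ontology = rep(c("disease", "phenotype"), c(length(d), length(p))),
             stringsAsFactors = FALSE)
}

#' Abstract-level occurrence and co-occurrence counts
#'
#' Computes, over the restricted corpus (abstracts mentioning at least one
#' disease and at least one phenotype class after propagation), the tallies
#' feeding the NPMI score: `n_tot`, per-class abstract counts `n_c` / `n_d`,
#' and per-pair counts `n_cd`. Presence is boolean per abstract.
#'
#' @param corpus data.frame from [read_corpus()].
#' @param lex_disease,lex_phenotype `term_lexicon` objects.
#' @param g_disease,g_phenotype `ontology_graph` objects used for mention
#'   propagation (`propagate_disease = FALSE` turns off the disease side).
#' @param propagate_disease propagate disease mentions up their hierarchy
#'   (mirrors the phenotype side; default `TRUE`).
#' @param propagate_phenotype propagate phenotype mentions (default `TRUE`;
#'   turn off when the lexicon itself already encodes the full Terms(C)
#'   expansion).
#' @return object of class `cooccurrence_counts`: `n_tot` (int), `n_c`,
#'   `n_d` (named integer vectors), `n_cd` (data.frame disease_id,
#'   phenotype_id, n).
#' @export
count_cooccurrence <- function(corpus, lex_disease, lex_phenotype,
                               g_disease, g_phenotype,
                               propagate_disease = TRUE,
                               propagate_phenotype = TRUE) {
  per_doc <- lapply(seq_len(nrow(corpus)), function(i) {
    hits <- match_mentions(corpus[i, ], lex_disease, lex_phenotype)
    hits <- propagate_mentions(hits,
                               if (propagate_disease) g_disease else NULL,
                               if (propagate_phenotype) g_phenotype else NULL)
    d <- hits$class_id[hits$ontology == "disease"]
    p <- hits$class_id[hits$ontology == "phenotype"]
    if (!length(d) || !length(p)) return(NULL)
    list(d = d, p = p)
  })
  per_doc <- per_doc[!vapply(per_doc, is.null, TRUE)]
  if (!length(per_doc))
    abort("phenomine_empty_corpus",
          "no abstract contains both a disease and a phenotype mention")
  n_tot <- length(per_doc)
  n_c <- table(unlist(lapply(per_doc, `[[`, "d"), use.names = FALSE))
  n_d <- table(unlist(lapply(per_doc, `[[`, "p"), use.names = FALSE))
  pairs <- data.table::rbindlist(lapply(per_doc, function(x)
    data.table::CJ(disease_id = x$d, phenotype_id = x$p)))
  n_cd <- pairs[, list(n = .N), by = c("disease_id", "phenotype_id")]
  data.table::setkey(n_cd, disease_id, phenotype_id)
  structure(list(
    n_tot = n_tot,
    n_c = setNames(as.integer(n_c), names(n_c)),
    n_d = setNames(as.integer(n_d), names(n_d)),
    n_cd = as.data.frame(n_cd)
  ), class = "cooccurrence_counts")
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat(sprintf(
    "<cooccurrence_counts> n_tot=%d; %d disease classes, %d phenotype classes, %d co-mention pairs\n",
    x$n_tot, length(x$n_c), length(x$n_d), nrow(x$n_cd)))
  invisible(x)
}

#' Write co-occurrence counts as four TSV files
#'
#' @param counts a `cooccurrence_counts` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the four file paths.
#' @export
write_counts <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("totals.tsv", "disease_counts.tsv",
                            "phenotype_counts.tsv", "pair_counts.tsv"))
  write.table(data.frame(n_tot = counts$n_tot), paths[1],
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(class_id = names(counts$n_c), n = counts$n_c),
              paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(class_id = names(counts$n_d), n = counts$n_d),
              paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(counts$n_cd, paths[4], sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(paths)
}
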