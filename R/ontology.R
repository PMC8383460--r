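# Ontology loading, subclass closure and the term lexicon.
#
# An ontology here is a labeled DAG of classes connected by subclass edges
# (child "is_a" parent). Two on-disk dialects are supported: a minimal
# OBO-like stanza format and a pair of TSV files (edges + labels).

#' Construct an ontology graph from class and edge tables
#'
#' @param classes data.frame with columns `class_id`, `primary_label`, and
#'   optionally `synonyms` / `alt_labels` (list columns or `|`-separated
#'   strings) and a logical `obsolete` column.
#' @param edges data.frame with columns `child`, `parent` (subclass edges).
#' @return an object of class `ontology_graph` with elements `classes`
#'   (named list of per-class records), `edges`, `children`/`parents`
#'   adjacency lists, and `roots`.
#' @export
ontology_graph <- function(classes, edges) {
  classes <- as.data.frame(classes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) edges <- unique(edges[, c("child", "parent")])
  ids <- as.character(classes$class_id)
  if (anyDuplicated(ids))
    abort("phenomine_invalid_ontology", "duplicate class id: %s",
          ids[duplicated(ids)][1])
  split_multi <- function(col) {
    if (is.null(col)) return(rep(list(character(0)), length(ids)))
    if (is.list(col)) return(lapply(col, function(x) as.character(x[nzchar(x)])))
    lapply(strsplit(ifelse(is.na(col), "", col), "|", fixed = TRUE),
           function(x) x[nzchar(x)])
  }
  syns <- split_multi(classes$synonyms)
  alts <- split_multi(classes$alt_labels)
  obs <- if (is.null(classes$obsolete)) rep(FALSE, length(ids)) else
    classes$obsolete %in% c(TRUE, "true", "TRUE")
  recs <- lapply(seq_along(ids), function(i) {
    list(class_id = ids[i],
         primary_label = as.character(classes$primary_label[i]),
         synonyms = syns[[i]], alt_labels = alts[[i]], obsolete = obs[i])
  })
  names(recs) <- ids

  bad <- setdiff(unique(c(edges$child, edges$parent)), ids)
  if (length(bad))
    abort("phenomine_unknown_class", "edge references unknown class: %s",
          bad[1])
  if (nrow(edges)) {
    ig <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                        directed = TRUE, vertices = ids)
    if (!igraph::is_dag(ig))
      abort("phenomine_cyclic_hierarchy",
            "subclass hierarchy contains a cycle")
  } else {
    ig <- igraph::make_empty_graph(n = length(ids), directed = TRUE)
    ig <- igraph::set_vertex_attr(ig, "name", value = ids)
  }
  children <- split(edges$child, factor(edges$parent, levels = ids))
  parents <- split(edges$parent, factor(edges$child, levels = ids))
  roots <- ids[lengths(parents) == 0L]
  structure(list(classes = recs, edges = edges, igraph = ig,
                 children = children, parents = parents, roots = roots),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %d classes, %d subclass edges, %d root(s)\n",
              length(x$classes), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Load an ontology from disk
#'
#' @param path path to the ontology file. For `dialect = "obo_like"` a
#'   stanza-per-class file with `id:`, `name:`, `synonym:`, `alt_id`-free
#'   `is_a:` lines; for `dialect = "tsv_edges"` a headerless
#'   child<TAB>parent edge list, with labels supplied via `labels_path`
#'   (TSV: id, label, type in {primary, synonym, alt}).
#' @param dialect one of `"obo_like"`, `"tsv_edges"`.
#' @param labels_path labels TSV, required for the `tsv_edges` dialect.
#' @return an `ontology_graph`.
#' @export
load_ontology <- function(path, dialect = c("obo_like", "tsv_edges"),
                          labels_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    abort("phenomine_io", "ontology file not found: %s", path)
  if (dialect == "obo_like") parse_obo_like(path)
  else parse_tsv_edges(path, labels_path)
}

parse_obo_like <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- grep("^\\[Term\\]\\s*$", lines)
  if (!length(term_starts))
    abort("phenomine_io", "no [Term] stanzas in %s", path)
  bounds <- c(term_starts, length(lines) + 1L)
  cls <- list(); edge_child <- character(0); edge_parent <- character(0)
  for (i in seq_along(term_starts)) {
    chunk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    grab <- function(key) {
      m <- grep(paste0("^", key, ":"), chunk, value = TRUE)
      trimws(sub(paste0("^", key, ":"), "", m))
    }
    id <- grab("id")[1]
    if (is.na(id) || !nzchar(id))
      abort("phenomine_io", "stanza %d has no id", i)
    name <- grab("name")[1]
    syn_raw <- grab("synonym")
    # synonym: "text" EXACT []   (scope/trailer optional)
    syns <- sub('^"(.*?)".*$', "\\1", syn_raw)
    syns <- syns[nzchar(syns)]
    isa <- sub("\\s*!.*$", "", grab("is_a"))
    isa <- trimws(isa); isa <- isa[nzchar(isa)]
    obsolete <- any(grepl("^true", grab("is_obsolete")))
    cls[[length(cls) + 1L]] <- list(class_id = id,
                                    primary_label = if (is.na(name)) "" else name,
                                    synonyms = syns, obsolete = obsolete)
    edge_child <- c(edge_child, rep(id, length(isa)))
    edge_parent <- c(edge_parent, isa)
  }
  classes <- data.frame(
    class_id = vapply(cls, `[[`, "", "class_id"),
    primary_label = vapply(cls, `[[`, "", "primary_label"),
    obsolete = vapply(cls, `[[`, TRUE, "obsolete"),
    stringsAsFactors = FALSE)
  classes$synonyms <- lapply(cls, `[[`, "synonyms")
  ontology_graph(classes, data.frame(child = edge_child, parent = edge_parent,
                                     stringsAsFactors = FALSE))
}

parse_tsv_edges <- function(path, labels_path) {
  if (is.null(labels_path) || !file.exists(labels_path))
    abort("phenomine_io", "tsv_edges dialect requires an existing labels_path")
  ed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("child", "parent"))
  lb <- read.delim(labels_path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("class_id", "label", "type"))
  ids <- unique(c(lb$class_id, ed$child, ed$parent))
  prim <- lb[lb$type == "primary", ]
  primary <- setNames(prim$label[!duplicated(prim$class_id)],
                      prim$class_id[!duplicated(prim$class_id)])
  classes <- data.frame(class_id = ids,
                        primary_label = unname(primary[ids]),
                        stringsAsFactors = FALSE)
  classes$primary_label[is.na(classes$primary_label)] <- ""
  classes$synonyms <- lapply(ids, function(i)
    lb$label[lb$class_id == i & lb$type == "synonym"])
  classes$alt_labels <- lapply(ids, function(i)
    lb$label[lb$class_id == i & lb$type == "alt"])
  ontology_graph(classes, ed)
}

check_class <- function(g, id) {
  if (!id %in% names(g$classes))
    abort("phenomine_unknown_class", "unknown class: %s", id)
}

reachable <- function(g, id, mode) {
  # mode "in" follows edges child->parent backwards (descendants);
  # mode "out" follows them forwards (ancestors).
  out <- igraph::subcomponent(g$igraph, id, mode = mode)
  setdiff(names(out), id)
}

#' Descendant classes under the subclass relation
#'
#' @param g an `ontology_graph`.
#' @param class_id a class identifier present in `g`.
#' @param include_self include `class_id` itself (reflexive closure).
#' @return character vector of class ids.
#' @export
descendants <- function(g, class_id, include_self = FALSE) {
  check_class(g, class_id)
  d <- reachable(g, class_id, "in")
  if (include_self) c(class_id, d) else d
}

#' Ancestor classes under the subclass relation
#' @inheritParams descendants
#' @export
ancestors <- function(g, class_id, include_self = FALSE) {
  check_class(g, class_id)
  a <- reachable(g, class_id, "out")
  if (include_self) c(class_id, a) else a
}

class_labels <- function(g, id, include = c("primary", "synonym", "alt")) {
  rec <- g$classes[[id]]
  if (isTRUE(rec$obsolete)) return(character(0))
  out <- character(0)
  if ("primary" %in% include) out <- c(out, rec$primary_label)
  if ("synonym" %in% include) out <- c(out, rec$synonyms)
  if ("alt" %in% include) out <- c(out, rec$alt_labels)
  out[nzchar(out)]
}

#' Build the normalized term lexicon for an ontology
#'
#' Maps every normalized label/synonym string to the set of classes it can
#' refer to directly. Obsolete or unlabeled classes contribute nothing:
#' they cannot be mentioned in text.
#'
#' @param g an `ontology_graph`.
#' @param include which label kinds to index.
#' @return an object of class `term_lexicon`: `terms` (named list,
#'   normalized term -> character vector of class ids), `policy`,
#'   `max_tokens` (longest term length in tokens).
#' @export
build_term_lexicon <- function(g, include = c("primary", "synonym", "alt")) {
  rows <- lapply(names(g$classes), function(id) {
    labs <- normalize_label(class_labels(g, id, include))
    labs <- unique(labs[nzchar(labs)])
    if (!length(labs)) return(NULL)
    data.frame(term = labs, class_id = id, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(term = character(0),
                                      class_id = character(0))
  terms <- lapply(split(tab$class_id, tab$term), unique)
  max_tokens <- if (length(terms))
    max(lengths(strsplit(names(terms), " ", fixed = TRUE))) else 0L
  structure(list(terms = terms,
                 policy = "lowercase; collapse whitespace; strip edge punctuation; no stemming",
                 max_tokens = max_tokens),
            class = "term_lexicon")
}

#' @export
print.term_lexicon <- function(x, ...) {
  cat(sprintf("<term_lexicon> %d terms (longest %d tokens); policy: %s\n",
              length(x$terms), x$max_tokens, x$policy))
  invisible(x)
}

#' All terms that can refer to a class
#'
#' Terms(C): the union of normalized labels of C and of every subclass of C.
#' Mentioning any member counts as mentioning C.
#'
#' @param g an `ontology_graph`.
#' @param class_id class identifier.
#' @param include label kinds to use.
#' @return character vector of normalized terms.
#' @export
terms_of_class <- function(g, class_id,
                           include = c("primary", "synonym", "alt")) {
  check_class(g, class_id)
  ids <- descendants(g, class_id, include_self = TRUE)
  labs <- unlist(lapply(ids, function(i) class_labels(g, i, include)),
                 use.names = FALSE)
  unique(normalize_label(labs[nzchar(labs)]))
}
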