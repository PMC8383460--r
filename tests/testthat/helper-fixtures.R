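# Shared builders and independent oracles used across the test files.

# Tiny hand-built ontology: chain A -> B -> C (A is_a B is_a C).
chain_ontology <- function() {
  classes <- data.frame(class_id = c("A", "B", "C"),
                        primary_label = c("alpha state", "beta state",
                                          "gamma state"),
                        stringsAsFactors = FALSE)
  ontology_graph(classes, data.frame(child = c("A", "B"),
                                     parent = c("B", "C")))
}

# ICD-like fixture: G30 with its four dotted children, plus a sibling leaf.
g30_ontology <- function() {
  ids <- c("G30", "G30.0", "G30.1", "G30.8", "G30.9", "G31")
  labs <- c("alzheimer disease", "alzheimer disease with early onset",
            "alzheimer disease with late onset", "other alzheimer disease",
            "alzheimer disease unspecified", "other degenerative disease")
  classes <- data.frame(class_id = ids, primary_label = labs,
                        stringsAsFactors = FALSE)
  ontology_graph(classes,
                 data.frame(child = c("G30.0", "G30.1", "G30.8", "G30.9"),
                            parent = "G30"))
}

# Seeded random DAG over n nodes: a tree plus extra forward edges, so some
# nodes have several parents.
random_dag <- function(n, seed, p_extra = 0.08) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  child <- character(0); parent <- character(0)
  for (i in 2:n) {
    child <- c(child, ids[i])
    parent <- c(parent, ids[sample.int(i - 1, 1)])
  }
  for (i in 3:n) {
    if (runif(1) < p_extra) {
      extra <- ids[sample.int(i - 1, 1)]
      if (!extra %in% parent[child == ids[i]]) {
        child <- c(child, ids[i]); parent <- c(parent, extra)
      }
    }
  }
  classes <- data.frame(class_id = ids,
                        primary_label = paste("node", ids),
                        stringsAsFactors = FALSE)
  ontology_graph(classes, data.frame(child = child, parent = parent,
                                     stringsAsFactors = FALSE))
}

# Brute-force fixed-point closure oracle over raw edges, independent of the
# package's graph machinery.
naive_closure <- function(edges, start, direction = c("down", "up"),
                          include_self = FALSE) {
  direction <- match.arg(direction)
  frontier <- start
  seen <- character(0)
  while (length(frontier)) {
    seen <- union(seen, frontier)
    nxt <- if (direction == "down")
      edges$child[edges$parent %in% frontier]
    else edges$parent[edges$child %in% frontier]
    frontier <- setdiff(unique(nxt), seen)
  }
  if (include_self) seen else setdiff(seen, start)
}

# Exhaustive mention oracle: every lexicon term whose token sequence occurs
# contiguously in the document's tokens (token-boundary substring search).
brute_force_mentions <- function(doc, lex) {
  toks <- phenomine:::tokenize_text(paste(doc$title, doc$body))
  found <- character(0)
  for (term in names(lex$terms)) {
    tt <- strsplit(term, " ", fixed = TRUE)[[1]]
    L <- length(tt)
    if (L > length(toks)) next
    for (s in seq_len(length(toks) - L + 1)) {
      if (all(toks[s:(s + L - 1)] == tt)) {
        found <- c(found, lex$terms[[term]])
        break
      }
    }
  }
  sort(unique(found))
}

# Pair-set helper for readable comparisons.
pair_set <- function(df) sort(paste(df$disease_id, df$phenotype_id))

# Brute-force AUC: fraction of concordant (pos, neg) pairs, ties count 1/2.
concordant_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (if (p > q) 1 else if (p == q) 0.5 else 0)
  tot / (length(pos) * length(neg))
}

# Small standard fixture bundle shared by several files (cheap to build).
small_fixture <- function(seed = 42, n_docs = 200) {
  spec <- fixture_spec(n_docs = n_docs, hierarchy_depth = 2, branching = 4,
                       n_planted_pairs = 5, seed = seed)
  dis <- gen_ontology(spec, "disease")
  phe <- gen_ontology(spec, "phenotype")
  planted <- gen_planted_pairs(spec, dis$graph, phe$graph)
  corp <- gen_corpus(spec, dis$graph, phe$graph, planted)
  list(spec = spec, dis = dis, phe = phe, planted = planted,
       corpus = corp$corpus, background = corp$background)
}
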