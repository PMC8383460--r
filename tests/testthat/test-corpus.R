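# Mention matching, propagation and abstract-level co-occurrence counting.

test_that("longest match wins and unmatched text yields nothing", {
  lex <- structure(list(terms = list(
    "alzheimer's disease" = "Y",
    "alzheimer's disease with early onset" = "X"),
    policy = "test", max_tokens = 6L), class = "term_lexicon")
  empty <- structure(list(terms = list(), policy = "test", max_tokens = 0L),
                     class = "term_lexicon")
  doc <- list(title = "",
              body = "alzheimer's disease with early onset in a cohort")
  hits <- match_mentions(doc, lex, empty)
  expect_equal(hits$class_id, "X")
  none <- match_mentions(list(title = "no", body = "terms here"),
                         lex, empty)
  expect_equal(nrow(none), 0)
})

test_that("a term naming several classes yields all of them", {
  lex <- structure(list(terms = list("shared label" = c("C1", "C2")),
                        policy = "test", max_tokens = 2L),
                   class = "term_lexicon")
  empty <- structure(list(terms = list(), policy = "test", max_tokens = 0L),
                     class = "term_lexicon")
  hits <- match_mentions(list(title = "a shared label", body = ""),
                         lex, empty)
  expect_setequal(hits$class_id, c("C1", "C2"))
})

test_that("mention detection equals the exhaustive term-scan oracle on a synthetic corpus", {
  fx <- small_fixture(seed = 8, n_docs = 20)
  for (i in seq_len(nrow(fx$corpus))) {
    doc <- fx$corpus[i, ]
    got <- match_mentions(doc, fx$dis$lexicon, fx$phe$lexicon)
    expect_equal(sort(got$class_id[got$ontology == "disease"]),
                 brute_force_mentions(doc, fx$dis$lexicon))
    expect_equal(sort(got$class_id[got$ontology == "phenotype"]),
                 brute_force_mentions(doc, fx$phe$lexicon))
  }
})

test_that("mention propagation adds exactly the ancestors", {
  g <- chain_ontology()
  hits <- data.frame(class_id = "A", ontology = "phenotype")
  out <- propagate_mentions(hits, g_phenotype = g)
  expect_setequal(out$class_id, c("A", "B", "C"))
  root_hit <- data.frame(class_id = "C", ontology = "phenotype")
  expect_equal(propagate_mentions(root_hit, g_phenotype = g)$class_id, "C")
  # random DAG: equals the brute-force ancestor closure
  gd <- random_dag(50, 17)
  for (id in sample(names(gd$classes), 6)) {
    out <- propagate_mentions(data.frame(class_id = id,
                                         ontology = "disease"),
                              g_disease = gd)
    expect_setequal(out$class_id,
                    naive_closure(gd$edges, id, "up", include_self = TRUE))
  }
})

test_that("the restricted corpus keeps only co-mention abstracts", {
  g_d <- g30_ontology()
  g_p <- chain_ontology()
  lex_d <- build_term_lexicon(g_d)
  lex_p <- build_term_lexicon(g_p)
  corpus <- data.frame(
    doc_id = c("d1", "d2"),
    title = c("", ""),
    body = c("alzheimer disease and alpha state", "alzheimer disease only"),
    stringsAsFactors = FALSE)
  counts <- count_cooccurrence(corpus, lex_d, lex_p, g_d, g_p)
  expect_equal(counts$n_tot, 1)
  expect_equal(unname(counts$n_c["G30"]), 1)
  expect_equal(unname(counts$n_d["A"]), 1)
  expect_equal(counts$n_cd$n[counts$n_cd$disease_id == "G30" &
                               counts$n_cd$phenotype_id == "A"], 1)
})

test_that("a child mention counts for its parent without the parent appearing literally", {
  g_d <- g30_ontology()
  g_p <- chain_ontology()
  corpus <- data.frame(
    doc_id = "d1", title = "",
    body = "alzheimer disease with early onset presenting alpha state",
    stringsAsFactors = FALSE)
  counts <- count_cooccurrence(corpus, build_term_lexicon(g_d),
                               build_term_lexicon(g_p), g_d, g_p)
  # G30 via its subclass; phenotype ancestors B, C via subclass A
  expect_equal(unname(counts$n_c["G30"]), 1)
  pair <- counts$n_cd[counts$n_cd$disease_id == "G30" &
                        counts$n_cd$phenotype_id == "C", ]
  expect_equal(pair$n, 1)
})

test_that("counts equal a per-document brute-force recount on a planted corpus", {
  fx <- small_fixture(seed = 4, n_docs = 200)
  counts <- count_cooccurrence(fx$corpus, fx$dis$lexicon, fx$phe$lexicon,
                               fx$dis$graph, fx$phe$graph)
  # independent recount: per doc, oracle mentions + oracle ancestor closure
  n_c <- integer(0); n_d <- integer(0); n_cd <- list(); n_tot <- 0L
  for (i in seq_len(nrow(fx$corpus))) {
    doc <- fx$corpus[i, ]
    d <- brute_force_mentions(doc, fx$dis$lexicon)
    p <- brute_force_mentions(doc, fx$phe$lexicon)
    d <- unique(unlist(lapply(d, function(x)
      naive_closure(fx$dis$graph$edges, x, "up", include_self = TRUE))))
    p <- unique(unlist(lapply(p, function(x)
      naive_closure(fx$phe$graph$edges, x, "up", include_self = TRUE))))
    if (!length(d) || !length(p)) next
    n_tot <- n_tot + 1L
    for (x in d) n_c[x] <- (if (is.na(n_c[x])) 0L else n_c[x]) + 1L
    for (x in p) n_d[x] <- (if (is.na(n_d[x])) 0L else n_d[x]) + 1L
    n_cd[[length(n_cd) + 1L]] <- expand.grid(disease_id = d,
                                             phenotype_id = p,
                                             stringsAsFactors = FALSE)
  }
  expect_equal(counts$n_tot, n_tot)
  expect_equal(counts$n_c[sort(names(counts$n_c))],
               n_c[sort(names(n_c))])
  expect_equal(counts$n_d[sort(names(counts$n_d))],
               n_d[sort(names(n_d))])
  oracle_pairs <- do.call(rbind, n_cd)
  oracle_tab <- aggregate(list(n = rep(1L, nrow(oracle_pairs))),
                          oracle_pairs, sum)
  got <- counts$n_cd[order(counts$n_cd$disease_id,
                           counts$n_cd$phenotype_id), ]
  want <- oracle_tab[order(oracle_tab$disease_id,
                           oracle_tab$phenotype_id), ]
  expect_equal(got$n, want$n)
  expect_equal(got$disease_id, want$disease_id)
  expect_equal(got$phenotype_id, want$phenotype_id)
})

test_that("counts are monotone under the hierarchy and deterministic across passes", {
  fx <- small_fixture(seed = 6, n_docs = 150)
  counts <- count_cooccurrence(fx$corpus, fx$dis$lexicon, fx$phe$lexicon,
                               fx$dis$graph, fx$phe$graph)
  g <- fx$phe$graph
  for (e in seq_len(nrow(g$edges))) {
    ch <- g$edges$child[e]; pa <- g$edges$parent[e]
    nch <- counts$n_d[ch]; npa <- counts$n_d[pa]
    if (!is.na(nch))
      expect_gte(unname(if (is.na(npa)) 0L else npa), unname(nch))
  }
  again <- count_cooccurrence(fx$corpus, fx$dis$lexicon, fx$phe$lexicon,
                              fx$dis$graph, fx$phe$graph)
  expect_identical(counts, again)
})

test_that("an empty restricted corpus raises the dedicated error", {
  g_d <- g30_ontology(); g_p <- chain_ontology()
  corpus <- data.frame(doc_id = "d1", title = "t", body = "nothing here",
                       stringsAsFactors = FALSE)
  expect_error(count_cooccurrence(corpus, build_term_lexicon(g_d),
                                  build_term_lexicon(g_p), g_d, g_p),
               class = "phenomine_empty_corpus")
})

test_that("corpus io round-trips jsonl and tsv and rejects duplicate ids", {
  dir <- withr::local_tempdir()
  df <- data.frame(doc_id = c("a", "b"), title = c("t1", "t2"),
                   body = c("b1", "b2"), stringsAsFactors = FALSE)
  jl <- file.path(dir, "c.jsonl")
  writeLines(vapply(seq_len(2), function(i)
    as.character(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE)),
    ""), jl)
  expect_equal(read_corpus(jl), df)
  tsv <- file.path(dir, "c.tsv")
  write.table(df, tsv, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  expect_equal(read_corpus(tsv), df)
  writeLines(c("a\tt\tb", "a\tt\tb"), tsv)
  expect_error(read_corpus(tsv), class = "phenomine_io")
})
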