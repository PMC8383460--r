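# Bridged harvesting, generic filtering, propagation and curation.

mk_records <- function(disease, phenotype, provenance = "wikidata",
                       status = "accepted") {
  n <- length(disease)
  data.frame(disease_id = disease, phenotype_id = phenotype,
             provenance = rep(provenance, length.out = n),
             curation_status = rep(status, length.out = n),
             stringsAsFactors = FALSE)
}

test_that("bridging fans associations out over mapped codes and reports drops", {
  assoc <- data.frame(disease_id = c("MIM:1", "MIM:1", "MIM:2"),
                      phenotype_id = c("HP:a", "HP:b", "HP:c"),
                      stringsAsFactors = FALSE)
  bridge <- data.frame(source_id = c("MIM:1", "MIM:1"),
                       target_id = c("G30", "G31"),
                       resource = "umls", stringsAsFactors = FALSE)
  out <- bridge_associations(assoc, bridge)
  # 2 phenotypes x 2 codes for MIM:1; MIM:2 unmapped
  expect_equal(nrow(out), 4)
  expect_setequal(out$provenance, "hpo_via_umls")
  expect_equal(attr(out, "dropped"), "MIM:2")
  # one code, two phenotypes
  one <- bridge_associations(assoc[1:2, ], bridge[1, , drop = FALSE])
  expect_equal(nrow(one), 2)
})

test_that("bridging equals a nested-loop join oracle on a larger fixture", {
  set.seed(33)
  assoc <- data.frame(
    disease_id = sample(sprintf("MIM:%d", 1:10), 25, replace = TRUE),
    phenotype_id = sprintf("HP:%03d", sample(1:40, 25)),
    stringsAsFactors = FALSE)
  assoc <- unique(assoc)
  bridge <- data.frame(
    source_id = sprintf("MIM:%d", sample(1:10, 12, replace = TRUE)),
    target_id = sprintf("C%02d", sample(1:15, 12, replace = TRUE)),
    resource = sample(c("umls", "wikidata"), 12, replace = TRUE),
    stringsAsFactors = FALSE)
  bridge <- unique(bridge)
  out <- bridge_associations(assoc, bridge)
  oracle <- list()
  for (i in seq_len(nrow(assoc)))
    for (j in seq_len(nrow(bridge)))
      if (assoc$disease_id[i] == bridge$source_id[j])
        oracle[[length(oracle) + 1]] <-
          paste(bridge$target_id[j], assoc$phenotype_id[i])
  expect_setequal(pair_set(out), unique(unlist(oracle)))
})

test_that("the generic-phenotype filter removes exactly the blocked ids", {
  recs <- mk_records(c("G30", "G30", "G31"),
                     c("HP:0000006", "HP:x", "HP:y"))
  out <- filter_generic(recs)
  expect_equal(attr(out, "n_removed"), 1)
  expect_false("HP:0000006" %in% out$phenotype_id)
  expect_equal(nrow(filter_generic(recs, character(0))), 3)
  # 100-record fixture vs set-difference oracle
  set.seed(7)
  big <- mk_records(sprintf("D%02d", sample(1:20, 100, replace = TRUE)),
                    sprintf("HP:%03d", sample(1:30, 100, replace = TRUE)))
  blocked <- sprintf("HP:%03d", 1:8)
  out <- filter_generic(big, blocked)
  expect_setequal(pair_set(out),
                  pair_set(big[!big$phenotype_id %in% blocked, ]))
})

test_that("hierarchy propagation emits one record per proper descendant", {
  g <- g30_ontology()
  recs <- mk_records("G30", "HP:x")
  out <- propagate_icd(recs, g)
  newer <- out[out$provenance == "prop_icd", ]
  expect_equal(nrow(newer), 4)
  expect_setequal(newer$disease_id, c("G30.0", "G30.1", "G30.8", "G30.9"))
  # leaf disease: nothing to add
  leaf <- propagate_icd(mk_records("G30.1", "HP:x"), g)
  expect_equal(sum(leaf$provenance == "prop_icd"), 0)
})

test_that("code-syntax parenting stands in when the hierarchy lacks the code", {
  recs <- mk_records("Q87", "HP:z")
  out <- propagate_icd(recs, g_icd = NULL,
                       universe = c("Q87", "Q87.0", "Q87.4", "Q88.1"))
  newer <- out[out$provenance == "prop_icd", ]
  expect_setequal(newer$disease_id, c("Q87.0", "Q87.4"))
})

test_that("propagation skips pairs already asserted from a curated source", {
  g <- g30_ontology()
  recs <- rbind(mk_records("G30", "HP:x"),
                mk_records("G30.1", "HP:x", provenance = "umls_direct"))
  out <- propagate_icd(recs, g)
  got <- out[out$disease_id == "G30.1" & out$phenotype_id == "HP:x", ]
  expect_equal(got$provenance, "umls_direct")
})

test_that("propagation is idempotent and matches the closure oracle on a random hierarchy", {
  g <- random_dag(40, 23)
  set.seed(24)
  recs <- mk_records(sample(names(g$classes), 8),
                     sprintf("HP:%02d", 1:8))
  once <- propagate_icd(recs, g)
  twice <- propagate_icd(once, g)
  expect_equal(pair_set(once), pair_set(twice))
  expect_equal(nrow(once), nrow(twice))
  oracle <- unique(unlist(lapply(seq_len(nrow(recs)), function(i)
    paste(naive_closure(g$edges, recs$disease_id[i], "down",
                        include_self = TRUE),
          recs$phenotype_id[i]))))
  expect_setequal(pair_set(once), oracle)
})

test_that("generic filtering and propagation commute", {
  g <- g30_ontology()
  recs <- mk_records(c("G30", "G30"), c("HP:0000006", "HP:x"))
  a <- propagate_icd(filter_generic(recs), g)
  b <- filter_generic(propagate_icd(recs, g))
  expect_setequal(pair_set(a), pair_set(b))
  expect_false("HP:0000006" %in% c(a$phenotype_id, b$phenotype_id))
})

test_that("lexical superclass matching links unannotated diseases only", {
  pheno <- ontology_graph(
    data.frame(class_id = c("HP:0032551", "HP:0000001"),
               primary_label = c("Hemorrhoids", "All"),
               stringsAsFactors = FALSE),
    data.frame(child = "HP:0032551", parent = "HP:0000001"))
  lex <- build_term_lexicon(pheno)
  diseases <- data.frame(
    disease_id = c("I84.4", "K00.1"),
    label = c("External hemorrhoids with complications",
              "Something unrelated entirely"),
    stringsAsFactors = FALSE)
  none <- mk_records(character(0), character(0))
  out <- propagate_lexical(diseases, lex, none)
  expect_equal(out$disease_id, "I84.4")
  expect_equal(out$phenotype_id, "HP:0032551")
  expect_equal(out$provenance, "prop_lexical")
  # an already-annotated disease is not eligible
  existing <- mk_records("I84.4", "HP:0032551", provenance = "umls_direct")
  expect_equal(nrow(propagate_lexical(diseases, lex, existing)), 0)
})

test_that("lexical matching picks the longest label and matches an all-pairs scan", {
  pheno <- ontology_graph(
    data.frame(class_id = c("H1", "H2"),
               primary_label = c("anemia", "aplastic anemia"),
               stringsAsFactors = FALSE),
    data.frame(child = character(0), parent = character(0)))
  lex <- build_term_lexicon(pheno)
  diseases <- data.frame(disease_id = "D1",
                         label = "congenital aplastic anemia syndrome",
                         stringsAsFactors = FALSE)
  out <- propagate_lexical(diseases, lex,
                           mk_records(character(0), character(0)))
  expect_equal(out$phenotype_id, "H2")
  # 30-label fixture against a brute-force containment scan (longest wins)
  fx <- small_fixture(seed = 9, n_docs = 5)
  g <- fx$phe$graph
  labs <- vapply(g$classes, function(r) r$primary_label, "")
  set.seed(91)
  dis <- data.frame(
    disease_id = sprintf("Z%02d", 1:30),
    label = paste(sample(c("late", "early", "regional"), 30, replace = TRUE),
                  sample(unname(labs), 30, replace = TRUE)),
    stringsAsFactors = FALSE)
  lex_p <- fx$phe$lexicon
  got <- propagate_lexical(dis, lex_p,
                           mk_records(character(0), character(0)))
  for (i in seq_len(nrow(dis))) {
    dtok <- phenomine:::tokenize_text(dis$label[i])
    cands <- Filter(function(term) {
      tt <- strsplit(term, " ", fixed = TRUE)[[1]]
      L <- length(tt)
      L <= length(dtok) &&
        any(vapply(seq_len(length(dtok) - L + 1), function(s)
          all(dtok[s:(s + L - 1)] == tt), TRUE))
    }, names(lex_p$terms))
    if (!length(cands)) {
      expect_false(dis$disease_id[i] %in% got$disease_id)
    } else {
      best <- cands[order(-lengths(strsplit(cands, " ")), cands)][1]
      expect_setequal(
        got$phenotype_id[got$disease_id == dis$disease_id[i]],
        lex_p$terms[[best]])
    }
  }
})

test_that("common-disease selection is a pure membership filter", {
  recs <- mk_records(c("A1", "A2", "A3"), c("HP:1", "HP:2", "HP:3"))
  expect_equal(nrow(select_common(recs, character(0))), 0)
  expect_equal(select_common(recs, unique(recs$disease_id)), recs)
  set.seed(5)
  keep <- sample(recs$disease_id, 2)
  expect_setequal(pair_set(select_common(recs, keep)),
                  pair_set(recs[recs$disease_id %in% keep, ]))
})

test_that("curation overrides remove, add and account for every change", {
  recs <- mk_records(c("A1", "A2", "A3"), c("HP:1", "HP:2", "HP:3"))
  ov <- data.frame(disease_id = c("A1", "A9"),
                   phenotype_id = c("HP:1", "HP:9"),
                   action = c("remove", "add"), stringsAsFactors = FALSE)
  out <- apply_curation(recs, ov)
  expect_equal(nrow(out), 3)
  expect_equal(sum(out$provenance == "expert"), 1)
  expect_equal(out$curation_status[out$provenance == "expert"], "added_fn")
  removed <- attr(out, "removed")
  expect_equal(removed$curation_status, "removed_fp")
  expect_equal(pair_set(removed), "A1 HP:1")
  # identity on an empty override set
  empty <- ov[0, ]
  expect_equal(apply_curation(recs, empty), recs, ignore_attr = TRUE)
  # a removal aimed at nothing warns
  expect_warning(apply_curation(recs,
                                data.frame(disease_id = "zz",
                                           phenotype_id = "HP:0",
                                           action = "remove")),
                 "absent")
})

test_that("randomized overrides equal a sequential replay oracle", {
  set.seed(44)
  recs <- unique(mk_records(sprintf("D%d", sample(1:6, 30, replace = TRUE)),
                            sprintf("HP:%d", sample(1:10, 30, replace = TRUE))))
  ov <- data.frame(
    disease_id = c(sample(recs$disease_id, 5), "D9", "D9"),
    phenotype_id = c(sample(recs$phenotype_id, 5), "HP:91", "HP:92"),
    action = c(rep("remove", 5), "add", "add"), stringsAsFactors = FALSE)
  # sampled removals may target non-existent pairs; the warning is expected
  out <- suppressWarnings(apply_curation(recs, ov))
  replay <- recs
  for (i in seq_len(nrow(ov))) {
    if (ov$action[i] == "remove") {
      replay <- replay[!(replay$disease_id == ov$disease_id[i] &
                           replay$phenotype_id == ov$phenotype_id[i]), ]
    } else {
      replay <- rbind(replay, mk_records(ov$disease_id[i],
                                         ov$phenotype_id[i],
                                         "expert", "added_fn"))
    }
  }
  expect_setequal(pair_set(out), pair_set(replay))
})

test_that("dedup keeps the most reliable provenance and the summary partitions", {
  recs <- rbind(mk_records("G30", "HP:1", "prop_icd"),
                mk_records("G30", "HP:1", "umls_direct"),
                mk_records("G30", "HP:1", "hpo_via_wikidata"),
                mk_records("G31", "HP:2", "wikidata"))
  dd <- dedup_associations(recs)
  expect_equal(nrow(dd), 2)
  expect_equal(dd$provenance[dd$disease_id == "G30"], "umls_direct")
  s <- provenance_summary(dd)
  expect_equal(s$n[s$provenance == "TOTAL"],
               sum(s$n[s$provenance != "TOTAL"]))
})

test_that("mapping tables parse, dedupe and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source_id\ttarget_id\tresource",
               "MIM:1\tG30\tumls", "MIM:1\tG30\tumls",
               "MIM:2\tG31\twikidata"), path)
  mt <- read_mapping_table(path)
  expect_equal(nrow(mt), 2)
  writeLines("only_one_column", path)
  expect_error(read_mapping_table(path),
               class = "phenomine_mapping_parse")
})
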