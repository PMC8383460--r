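# Seeded synthetic fixtures: toy ontologies with multi-token labels, a
# corpus with planted disease-phenotype co-mention structure, mapping
# bridges with injected wrong links, gold standards and gene-phenotype
# tables. Everything is a pure function of (spec, seed).

FIXTURE_ADJECTIVES <- c(
  "acute", "chronic", "focal", "diffuse", "juvenile", "senile", "benign",
  "malignant", "primary", "secondary", "familial", "sporadic", "distal",
  "proximal", "bilateral", "recurrent", "congenital", "atypical", "severe",
  "transient", "nodular", "cystic", "fibrous", "spastic", "latent")

# Disjoint noun pools per ontology kind so that a synthetic disease label
# can never collide with a synthetic phenotype label.
FIXTURE_NOUNS <- list(
  disease = c("gliosis", "carcinoma", "melanoma", "anemia", "palsy",
              "embolism", "thrombosis", "ischemia", "necrosis", "dystrophy",
              "sclerosis", "dysplasia", "neuropathy"),
  phenotype = c("atrophy", "stenosis", "fibrosis", "edema", "tremor",
                "seizure", "lesion", "ulcer", "cyst", "nodule",
                "hypoplasia", "hypertrophy"))

#' Fixture generation parameters
#'
#' @param n_docs corpus size (default 2000).
#' @param hierarchy_depth ontology depth below the root (default 3).
#' @param branching children per internal node (default 4, giving 64 leaf
#'   classes per side at depth 3 - enough for 20 planted pairs plus
#'   one-per-leaf background pairs).
#' @param p_planted per-document co-mention probability of a planted pair
#'   (default 0.3).
#' @param p_background per-document co-mention probability of any other
#'   leaf pair (default 0.02).
#' @param n_planted_pairs number of planted disease-phenotype pairs
#'   (default 20).
#' @param synonym_rate expected extra synonyms per class (default 0.3).
#' @param p_solo per-document probability that a leaf class is mentioned
#'   on its own, independently of any pair event (default 0.05). Solo
#'   mentions keep marginal counts above joint counts, as in real
#'   abstracts where most class mentions are not co-mentions.
#' @param seed master RNG seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_docs = 2000, hierarchy_depth = 3, branching = 4,
                         p_planted = 0.3, p_background = 0.02,
                         n_planted_pairs = 20, synonym_rate = 0.3,
                         p_solo = 0.05, seed = 1) {
  if (!(p_background >= 0 && p_background < p_planted && p_planted <= 1))
    abort("phenomine_invalid_spec",
          "need 0 <= p_background < p_planted <= 1")
  if (min(n_docs, hierarchy_depth, branching, n_planted_pairs) < 1)
    abort("phenomine_invalid_spec", "counts must be positive")
  structure(list(n_docs = n_docs, hierarchy_depth = hierarchy_depth,
                 branching = branching, p_planted = p_planted,
                 p_background = p_background,
                 n_planted_pairs = n_planted_pairs,
                 synonym_rate = synonym_rate, p_solo = p_solo, seed = seed),
            class = "fixture_spec")
}

gen_label <- function(kind) {
  paste(sample(FIXTURE_ADJECTIVES, 1), sample(FIXTURE_ADJECTIVES, 1),
        sample(FIXTURE_NOUNS[[kind]], 1))
}

#' Generate a seeded random ontology
#'
#' A rooted tree of depth `hierarchy_depth` with `branching` children per
#' internal node, unique two-adjective-one-noun labels and `synonym_rate`
#' extra synonyms. The disease kind issues ICD-style ids: letter codes at
#' intermediate levels and dotted codes (`X##.#`) at the last level, so
#' code-syntax parenting is exercised; the phenotype kind issues
#' `PH:nnnnnnn` CURIEs.
#'
#' @param spec a `fixture_spec`.
#' @param kind "disease" or "phenotype".
#' @return list: `graph` (`ontology_graph`), `lexicon` (`term_lexicon`).
#' @export
gen_ontology <- function(spec, kind = c("disease", "phenotype")) {
  kind <- match.arg(kind)
  seeds <- derive_seeds(spec$seed, 4)
  with_seed(if (kind == "disease") seeds[1] else seeds[2], {
    depth <- spec$hierarchy_depth
    b <- spec$branching
    n_per_level <- b^(0:depth)
    ids <- character(0); labels <- character(0)
    child <- character(0); parent <- character(0)
    level_ids <- list()
    counter <- 0L
    for (lev in 0:depth) {
      lv <- character(n_per_level[lev + 1])
      for (j in seq_len(n_per_level[lev + 1])) {
        counter <- counter + 1L
        lv[j] <- if (kind == "phenotype") {
          sprintf("PH:%07d", counter)
        } else if (lev == 0) {
          "ICD:ROOT"
        } else if (lev < depth) {
          sprintf("%s%02d", LETTERS[(lev %% 26) + 1], counter)
        } else {
          # dotted child of its parent code
          p <- level_ids[[lev]][ceiling(j / b)]
          sprintf("%s.%d", p, (j - 1) %% b)
        }
      }
      level_ids[[lev + 1]] <- lv
      ids <- c(ids, lv)
      if (lev > 0) {
        child <- c(child, lv)
        parent <- c(parent, rep(level_ids[[lev]], each = b))
      }
    }
    labels <- character(length(ids))
    used <- character(0)
    for (i in seq_along(ids)) {
      repeat {
        lab <- gen_label(kind)
        if (!lab %in% used) break
      }
      used <- c(used, lab)
      labels[i] <- lab
    }
    n_syn <- stats::rpois(length(ids), spec$synonym_rate)
    syns <- lapply(seq_along(ids), function(i) {
      if (n_syn[i] == 0) return(character(0))
      out <- character(n_syn[i])
      for (k in seq_len(n_syn[i])) {
        repeat {
          lab <- gen_label(kind)
          if (!lab %in% used) break
        }
        used <<- c(used, lab)
        out[k] <- lab
      }
      out
    })
    classes <- data.frame(class_id = ids, primary_label = labels,
                          stringsAsFactors = FALSE)
    classes$synonyms <- syns
    g <- ontology_graph(classes,
                        data.frame(child = child, parent = parent,
                                   stringsAsFactors = FALSE))
    list(graph = g, lexicon = build_term_lexicon(g))
  })
}

leaf_classes <- function(g) {
  names(g$classes)[lengths(g$children) == 0L]
}

#' Choose the planted disease-phenotype pairs
#'
#' Pairs use distinct leaf classes on both sides (sampling without
#' replacement), so each planted association has its own disease and
#' phenotype.
#'
#' @param spec a `fixture_spec`.
#' @param g_d,g_p disease/phenotype `ontology_graph`s.
#' @return data.frame disease_id, phenotype_id.
#' @export
gen_planted_pairs <- function(spec, g_d, g_p) {
  seeds <- derive_seeds(spec$seed, 4)
  with_seed(seeds[3], {
    ld <- leaf_classes(g_d); lp <- leaf_classes(g_p)
    n <- spec$n_planted_pairs
    if (n > min(length(ld), length(lp)))
      abort("phenomine_invalid_spec",
            "n_planted_pairs exceeds available leaf classes")
    data.frame(disease_id = sample(ld, n), phenotype_id = sample(lp, n),
               stringsAsFactors = FALSE)
  })
}

#' Generate a corpus with planted co-mention structure
#'
#' Each document mentions the two labels of a planted pair with
#' probability `p_planted`, independently per pair. The leaf classes not
#' used by planted pairs are matched one-to-one into background pairs that
#' co-occur with probability `p_background`, so every pair's per-document
#' co-mention probability is exactly its nominal rate (pairs never share a
#' class). Mentions are rendered as primary labels shuffled among filler
#' tokens.
#'
#' @param spec a `fixture_spec`.
#' @param g_d,g_p ontologies from [gen_ontology()].
#' @param planted data.frame from [gen_planted_pairs()].
#' @return list: `corpus` (data.frame doc_id, title, body), `planted`
#'   (echoed), `background` (the background pair table).
#' @export
gen_corpus <- function(spec, g_d, g_p, planted) {
  seeds <- derive_seeds(spec$seed, 4)
  with_seed(seeds[4], {
    ld <- setdiff(leaf_classes(g_d), planted$disease_id)
    lp <- setdiff(leaf_classes(g_p), planted$phenotype_id)
    n_bg <- min(length(ld), length(lp))
    background <- data.frame(disease_id = sample(ld, n_bg),
                             phenotype_id = sample(lp, n_bg),
                             stringsAsFactors = FALSE)
    pairs <- rbind(planted, background)
    prob <- rep(c(spec$p_planted, spec$p_background),
                c(nrow(planted), n_bg))
    label_of <- function(g, id) g$classes[[id]]$primary_label
    d_lab <- vapply(pairs$disease_id, label_of, "", g = g_d)
    p_lab <- vapply(pairs$phenotype_id, label_of, "", g = g_p)
    filler <- c("study", "of", "patients", "with", "reported", "cases",
                "clinical", "findings", "in", "a", "cohort", "analysis")
    all_d <- leaf_classes(g_d); all_p <- leaf_classes(g_p)
    solo_d <- vapply(all_d, label_of, "", g = g_d)
    solo_p <- vapply(all_p, label_of, "", g = g_p)
    docs <- vector("list", spec$n_docs)
    for (i in seq_len(spec$n_docs)) {
      fire <- runif(nrow(pairs)) < prob
      solo <- c(solo_d[runif(length(solo_d)) < spec$p_solo],
                solo_p[runif(length(solo_p)) < spec$p_solo])
      mentions <- unique(c(d_lab[fire], p_lab[fire], solo))
      words <- c(sample(filler, 4, replace = TRUE), mentions,
                 sample(filler, 3, replace = TRUE))
      docs[[i]] <- data.frame(
        doc_id = sprintf("doc%05d", i),
        title = paste(sample(filler, 3, replace = TRUE), collapse = " "),
        body = paste(sample(words), collapse = " "),
        stringsAsFactors = FALSE)
    }
    list(corpus = do.call(rbind, docs), planted = planted,
         background = background)
  })
}

#' Generate gold standard, mapping bridges and gene-phenotype fixtures
#'
#' The gold standard is the planted truth with a fraction of phenotypes
#' lifted to their parent class (exercising strict-vs-soft divergence).
#' The OMIM-style bridge maps synthetic `MIM:` ids onto planted diseases,
#' with `wrong_link_rate` of the links redirected to a different disease
#' (emulating noisy cross-terminology mappings). Genes carry noisy copies
#' of the planted disease profiles.
#'
#' @param spec a `fixture_spec`.
#' @param g_d,g_p ontologies.
#' @param planted data.frame from [gen_planted_pairs()].
#' @param ancestor_rate fraction of gold phenotypes lifted to a parent
#'   (default 0.25).
#' @param wrong_link_rate fraction of bridge links pointing at the wrong
#'   disease (default 0).
#' @param gene_noise fraction of each gene's phenotypes replaced by random
#'   ones (default 0).
#' @return list: `gold` (pair df), `bridge` (mapping df), `omim_assoc`
#'   (pair df keyed by MIM ids), `gene_pheno` (df gene_id, phenotype_id),
#'   `gene_disease` (df gene_id, disease_id truth).
#' @export
gen_gold_and_bridges <- function(spec, g_d, g_p, planted,
                                 ancestor_rate = 0.25, wrong_link_rate = 0,
                                 gene_noise = 0) {
  seeds <- derive_seeds(spec$seed + 13, 3)
  # gold: planted truth with some phenotypes lifted one level up
  gold <- with_seed(seeds[1], {
    g <- planted
    lift <- runif(nrow(g)) < ancestor_rate
    for (i in which(lift)) {
      par <- g_p$parents[[g$phenotype_id[i]]]
      if (length(par)) g$phenotype_id[i] <- par[1]
    }
    unique(g)
  })
  # bridge: MIM:nnn -> planted disease, with injected wrong links
  bridge <- with_seed(seeds[2], {
    mim <- sprintf("MIM:6%05d", seq_len(nrow(planted)))
    target <- planted$disease_id
    wrong <- runif(length(mim)) < wrong_link_rate
    for (i in which(wrong))
      target[i] <- sample(setdiff(planted$disease_id, target[i]), 1)
    data.frame(source_id = mim, target_id = target,
               resource = rep(c("umls", "wikidata"),
                              length.out = length(mim)),
               stringsAsFactors = FALSE)
  })
  # one synthetic MIM id per planted disease, carrying its phenotype
  omim_assoc <- data.frame(
    disease_id = sprintf("MIM:6%05d", seq_len(nrow(planted))),
    phenotype_id = planted$phenotype_id, stringsAsFactors = FALSE)
  # genes: one per planted disease, profile = disease phenotypes +- noise
  gene_tabs <- with_seed(seeds[3], {
    lp <- leaf_classes(g_p)
    by_dis <- split(planted$phenotype_id, planted$disease_id)
    genes <- sprintf("GENE:%03d", seq_along(by_dis))
    gp <- lapply(seq_along(by_dis), function(i) {
      ph <- by_dis[[i]]
      swap <- runif(length(ph)) < gene_noise
      ph[swap] <- sample(setdiff(lp, ph), sum(swap))
      data.frame(gene_id = genes[i], phenotype_id = ph,
                 stringsAsFactors = FALSE)
    })
    list(gene_pheno = do.call(rbind, gp),
         gene_disease = data.frame(gene_id = genes,
                                   disease_id = names(by_dis),
                                   stringsAsFactors = FALSE))
  })
  list(gold = gold, bridge = bridge, omim_assoc = omim_assoc,
       gene_pheno = gene_tabs$gene_pheno,
       gene_disease = gene_tabs$gene_disease)
}

#' Write a full fixture bundle to a directory
#'
#' Emits the TSV/JSONL dialects the main modules read: ontologies (edge +
#' label TSVs), corpus (JSONL), bridge/gold/gene tables (TSV).
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory.
#' @return invisibly, the list of generated objects.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dis <- gen_ontology(spec, "disease")
  phe <- gen_ontology(spec, "phenotype")
  planted <- gen_planted_pairs(spec, dis$graph, phe$graph)
  corp <- gen_corpus(spec, dis$graph, phe$graph, planted)
  aux <- gen_gold_and_bridges(spec, dis$graph, phe$graph, planted)
  write_ontology_tsv <- function(g, stem) {
    write.table(g$edges, file.path(dir, paste0(stem, "_edges.tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    rows <- lapply(g$classes, function(r) {
      data.frame(class_id = r$class_id,
                 label = c(r$primary_label, r$synonyms),
                 type = c("primary", rep("synonym", length(r$synonyms))),
                 stringsAsFactors = FALSE)
    })
    write.table(do.call(rbind, rows),
                file.path(dir, paste0(stem, "_labels.tsv")),
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
  }
  write_ontology_tsv(dis$graph, "disease")
  write_ontology_tsv(phe$graph, "phenotype")
  con <- file(file.path(dir, "corpus.jsonl"), "w")
  for (i in seq_len(nrow(corp$corpus)))
    writeLines(jsonlite::toJSON(as.list(corp$corpus[i, ]),
                                auto_unbox = TRUE), con)
  close(con)
  for (nm in c("gold", "bridge", "omim_assoc", "gene_pheno", "gene_disease"))
    write.table(aux[[nm]], file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                row.names = FALSE, quote = FALSE)
  write.table(planted, file.path(dir, "planted.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(list(disease = dis, phenotype = phe, planted = planted,
                 corpus = corp$corpus, aux = aux))
}
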