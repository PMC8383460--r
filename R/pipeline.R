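# End-to-end orchestration of the two dataset-building pipelines, with a
# JSON run manifest (stage counts + content hashes) per run.

#' Run configuration
#'
#' Flat list of input paths and parameters shared by the pipeline runners.
#' Any entry may be `NULL` to skip the corresponding stage.
#'
#' @param disease_edges,disease_labels,phenotype_edges,phenotype_labels
#'   ontology TSVs (tsv_edges dialect).
#' @param corpus abstract corpus (JSONL or TSV).
#' @param assoc curated association TSV keyed by the bridge's source ids.
#' @param bridge mapping-bridge TSV.
#' @param block_list file with one blocked phenotype id per line (optional;
#'   defaults to the built-in generic list).
#' @param common_ids file with one disease id per line (optional).
#' @param overrides curation override TSV (optional).
#' @param min_npmi strict lower bound on reported scores (default 0).
#' @param top_k optional rank threshold on the text-mining output.
#' @param eval_mode "strict" or "soft".
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(disease_edges = NULL, disease_labels = NULL,
                       phenotype_edges = NULL, phenotype_labels = NULL,
                       corpus = NULL, assoc = NULL, bridge = NULL,
                       block_list = NULL, common_ids = NULL,
                       overrides = NULL, min_npmi = 0, top_k = NULL,
                       eval_mode = "strict", seed = 1, out_dir = ".") {
  cfg <- list(disease_edges = disease_edges, disease_labels = disease_labels,
              phenotype_edges = phenotype_edges,
              phenotype_labels = phenotype_labels, corpus = corpus,
              assoc = assoc, bridge = bridge, block_list = block_list,
              common_ids = common_ids, overrides = overrides,
              min_npmi = min_npmi, top_k = top_k, eval_mode = eval_mode,
              seed = seed, out_dir = out_dir)
  paths <- unlist(cfg[c("disease_edges", "disease_labels", "phenotype_edges",
                        "phenotype_labels", "corpus", "assoc", "bridge",
                        "block_list", "common_ids", "overrides")])
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    abort("phenomine_io", "config path does not exist: %s", missing[1])
  structure(cfg, class = "run_config")
}

write_manifest <- function(out_dir, pipeline, cfg, stages, files) {
  manifest <- list(
    pipeline = pipeline,
    config = cfg[!vapply(cfg, is.null, TRUE)],
    stages = stages,
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  path <- file.path(out_dir, paste0(pipeline, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run the text-mining pipeline end to end
#'
#' load ontologies -> build lexicons -> count co-occurrence -> NPMI score
#' -> optional rank threshold; writes the scored association TSV, the four
#' count TSVs and a JSON manifest with per-stage counts.
#'
#' @param cfg a [run_config()].
#' @return list: `scores` (data.frame), `counts`
#'   (`cooccurrence_counts`), `manifest` (path).
#' @export
run_textmine <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("phenomine_stage_failure", "[%s] %s", name, conditionMessage(e)))
  }
  g_d <- stage("load_disease_ontology",
               load_ontology(cfg$disease_edges, "tsv_edges",
                             cfg$disease_labels))
  g_p <- stage("load_phenotype_ontology",
               load_ontology(cfg$phenotype_edges, "tsv_edges",
                             cfg$phenotype_labels))
  lex_d <- stage("lexicon", build_term_lexicon(g_d))
  lex_p <- stage("lexicon", build_term_lexicon(g_p))
  corpus <- stage("read_corpus", read_corpus(cfg$corpus))
  counts <- stage("count", count_cooccurrence(corpus, lex_d, lex_p, g_d, g_p))
  scores <- stage("score", score_all(counts, min_npmi = cfg$min_npmi))
  if (!is.null(cfg$top_k))
    scores <- scores[scores$rank <= cfg$top_k, , drop = FALSE]
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  score_path <- file.path(cfg$out_dir, "textmine_scores.tsv")
  write_scores(scores, score_path)
  count_paths <- write_counts(counts, file.path(cfg$out_dir, "counts"))
  stages <- list(corpus_docs = nrow(corpus), n_tot = counts$n_tot,
                 scored_pairs = nrow(scores),
                 diseases = length(unique(scores$disease_id)),
                 phenotypes = length(unique(scores$phenotype_id)))
  manifest <- write_manifest(cfg$out_dir, "textmine", cfg, stages,
                             c(score_path, count_paths))
  list(scores = scores, counts = counts, manifest = manifest)
}

#' Run the semi-automatic harvesting pipeline end to end
#'
#' bridge -> dedup -> generic filter -> hierarchy propagation -> lexical
#' propagation -> optional common-disease selection -> optional curation
#' overrides; writes the released association TSV, a per-provenance
#' summary and a JSON manifest.
#'
#' @param cfg a [run_config()].
#' @return list: `records`, `summary` (provenance counts), `manifest`.
#' @export
run_harvest <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("phenomine_stage_failure", "[%s] %s", name, conditionMessage(e)))
  }
  g_d <- stage("load_disease_ontology",
               load_ontology(cfg$disease_edges, "tsv_edges",
                             cfg$disease_labels))
  assoc <- stage("read_assoc", read_associations(cfg$assoc))
  bridge <- stage("read_bridge", read_mapping_table(cfg$bridge))
  records <- stage("bridge", bridge_associations(assoc, bridge))
  records <- stage("dedup", dedup_associations(records))
  blocked <- if (!is.null(cfg$block_list))
    readLines(cfg$block_list, warn = FALSE) else generic_phenotype_blocklist()
  records <- stage("filter_generic", filter_generic(records, blocked))
  records <- stage("propagate_icd", propagate_icd(records, g_d))
  dis_labels <- data.frame(
    disease_id = names(g_d$classes),
    label = vapply(g_d$classes, function(r) r$primary_label, ""),
    stringsAsFactors = FALSE)
  g_p <- if (!is.null(cfg$phenotype_edges))
    stage("load_phenotype_ontology",
          load_ontology(cfg$phenotype_edges, "tsv_edges",
                        cfg$phenotype_labels)) else NULL
  if (!is.null(g_p)) {
    lex_p <- build_term_lexicon(g_p)
    lexical <- stage("propagate_lexical",
                     propagate_lexical(dis_labels, lex_p, records))
    records <- rbind(records, lexical)
  }
  if (!is.null(cfg$common_ids))
    records <- stage("select_common",
                     select_common(records,
                                   readLines(cfg$common_ids, warn = FALSE)))
  if (!is.null(cfg$overrides)) {
    ov <- read.delim(cfg$overrides, stringsAsFactors = FALSE)
    records <- stage("apply_curation", apply_curation(records, ov))
  }
  summary <- provenance_summary(records)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  rec_path <- file.path(cfg$out_dir, "harvest_associations.tsv")
  write_associations(records, rec_path)
  sum_path <- file.path(cfg$out_dir, "harvest_provenance.tsv")
  write.table(summary, sum_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  stages <- as.list(setNames(summary$n, summary$provenance))
  manifest <- write_manifest(cfg$out_dir, "harvest", cfg, stages,
                             c(rec_path, sum_path))
  list(records = records, summary = summary, manifest = manifest)
}
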