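# Semi-automatic harvesting of curated disease-phenotype associations:
# mapping bridges, generic-phenotype filtering, hierarchy and lexical
# propagation, common-disease selection and expert curation overrides.

PROVENANCE_LEVELS <- c("umls_direct", "hpo_via_umls", "hpo_via_wikidata",
                       "wikidata", "expert", "prop_icd", "prop_lexical")

#' Default generic-phenotype block list
#'
#' Clinically uninformative phenotype classes (inheritance modes, clinical
#' modifiers, laterality) removed from harvested association sets. The
#' shipped default contains the five canonical examples; extend it with
#' your own ids for a fuller filter.
#'
#' @return character vector of phenotype class ids.
#' @export
generic_phenotype_blocklist <- function() {
  c("HP:0000005",  # Mode of inheritance
    "HP:0000006",  # Autosomal dominant inheritance
    "HP:0012824",  # Severity
    "HP:0025285",  # Aggravated by
    "HP:0012834")  # Right
}

new_association_records <- function(disease_id, phenotype_id, provenance,
                                    curation_status = "accepted") {
  n <- max(length(disease_id), length(phenotype_id))
  data.frame(disease_id = rep(as.character(disease_id), length.out = n),
             phenotype_id = rep(as.character(phenotype_id), length.out = n),
             provenance = rep(as.character(provenance), length.out = n),
             curation_status = rep(as.character(curation_status),
                                   length.out = n),
             stringsAsFactors = FALSE)
}

#' Read a cross-terminology mapping table
#'
#' TSV with columns source_id, target_id, resource (header optional).
#' Duplicate rows are collapsed; a source may map to several targets.
#'
#' @param path mapping TSV.
#' @return data.frame: source_id, target_id, resource.
#' @export
read_mapping_table <- function(path) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    quote = "")
  if (ncol(raw) < 3)
    abort("phenomine_mapping_parse",
          "mapping table needs 3 columns (source_id, target_id, resource): %s",
          path)
  names(raw)[1:3] <- c("source_id", "target_id", "resource")
  if (tolower(raw$source_id[1]) == "source_id") raw <- raw[-1, , drop = FALSE]
  raw <- raw[, c("source_id", "target_id", "resource")]
  if (any(!nzchar(raw$source_id)) || any(!nzchar(raw$target_id)))
    abort("phenomine_mapping_parse", "empty identifier in mapping table")
  unique(raw)
}

#' Re-key curated associations through a mapping bridge
#'
#' Joins an association table keyed by one identifier space (e.g. OMIM) with
#' a mapping bridge into the disease terminology (e.g. OMIM -> ICD-10).
#' Every (source disease, phenotype) pair yields one record per mapped
#' target code; the record provenance is derived from the bridge row's
#' resource tag. Unmapped diseases are dropped and reported via the
#' `dropped` attribute.
#'
#' @param assoc data.frame with columns disease_id (source space),
#'   phenotype_id.
#' @param bridge data.frame from [read_mapping_table()].
#' @param provenance_map named character vector resource tag -> provenance
#'   label; defaults to the bridged-HPO convention (`umls` ->
#'   `hpo_via_umls`, `wikidata` -> `hpo_via_wikidata`).
#' @return association records (attribute `dropped`: unmapped disease ids).
#' @export
bridge_associations <- function(assoc, bridge,
                                provenance_map = c(umls = "hpo_via_umls",
                                                   wikidata = "hpo_via_wikidata")) {
  merged <- merge(assoc, bridge, by.x = "disease_id", by.y = "source_id")
  prov <- unname(provenance_map[merged$resource])
  prov[is.na(prov)] <- merged$resource[is.na(prov)]
  out <- unique(new_association_records(merged$target_id,
                                        merged$phenotype_id, prov))
  attr(out, "dropped") <- setdiff(unique(assoc$disease_id),
                                  unique(bridge$source_id))
  out
}

#' Remove associations to generic phenotypes
#'
#' @param records association records.
#' @param blocked character vector of phenotype ids to remove
#'   (default [generic_phenotype_blocklist()]).
#' @return surviving records; attribute `n_removed` reports removals.
#' @export
filter_generic <- function(records, blocked = generic_phenotype_blocklist()) {
  drop <- records$phenotype_id %in% blocked
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

# Children of ICD-style codes derived from code syntax: "G30.0" is a child
# of "G30". Used when a harvested id is absent from the loaded hierarchy.
icd_syntax_children <- function(code, universe) {
  universe[startsWith(universe, paste0(code, ".")) & universe != code]
}

#' Propagate annotations down the disease hierarchy
#'
#' For each record on class P, emits one `prop_icd` record per proper
#' descendant of P that does not already carry that phenotype from a
#' non-propagated source. Original records are untouched. Disease ids
#' missing from the hierarchy fall back to code-syntax children
#' (dotted-code extensions of the id) within `universe`; ids with neither
#' are skipped with a warning.
#'
#' @param records association records.
#' @param g_icd disease `ontology_graph` (may be `NULL` to rely on code
#'   syntax only).
#' @param universe disease ids considered to exist (defaults to ids in the
#'   graph plus ids in `records`).
#' @return rbind of the input and the new `prop_icd` records.
#' @export
propagate_icd <- function(records, g_icd = NULL, universe = NULL) {
  known <- if (!is.null(g_icd)) names(g_icd$classes) else character(0)
  universe <- unique(c(universe, known, records$disease_id))
  existing_nonprop <- pair_key(
    records$disease_id[!records$provenance %in% c("prop_icd", "prop_lexical")],
    records$phenotype_id[!records$provenance %in% c("prop_icd", "prop_lexical")])
  base <- records[records$provenance != "prop_icd", , drop = FALSE]
  new_rows <- lapply(seq_len(nrow(base)), function(i) {
    did <- base$disease_id[i]
    kids <- if (did %in% known) descendants(g_icd, did, include_self = FALSE)
            else icd_syntax_children(did, universe)
    if (!length(kids) && !did %in% known &&
        !grepl("^[A-Za-z][0-9]", did)) {
      warning(sprintf("disease id %s not in hierarchy; skipped", did),
              call. = FALSE)
      return(NULL)
    }
    if (!length(kids)) return(NULL)
    new_association_records(kids, base$phenotype_id[i], "prop_icd")
  })
  new_rec <- do.call(rbind, new_rows)
  if (is.null(new_rec))
    new_rec <- new_association_records(character(0), character(0),
                                       character(0))
  new_rec <- unique(new_rec)
  new_rec <- new_rec[!pair_key(new_rec$disease_id, new_rec$phenotype_id) %in%
                       existing_nonprop, , drop = FALSE]
  # never re-add a pair already present from an earlier propagation round
  new_rec <- new_rec[!pair_key(new_rec$disease_id, new_rec$phenotype_id) %in%
                       pair_key(records$disease_id, records$phenotype_id), ,
                     drop = FALSE]
  out <- rbind(records, new_rec)
  rownames(out) <- NULL
  out
}

#' Annotate unannotated diseases by lexical superclass match
#'
#' A disease with no association from any other provenance is linked to a
#' phenotype class whose normalized label occurs as a token-boundary
#' substring of the normalized disease label; the longest matching
#' phenotype label wins (a term naming several classes yields all of them).
#'
#' @param diseases data.frame with columns disease_id, label.
#' @param pheno_lex `term_lexicon` built from the phenotype ontology.
#' @param existing association records already gathered.
#' @return new `prop_lexical` records (possibly zero rows).
#' @export
propagate_lexical <- function(diseases, pheno_lex, existing) {
  annotated <- unique(existing$disease_id)
  cand <- diseases[!diseases$disease_id %in% annotated, , drop = FALSE]
  if (!nrow(cand) || !length(pheno_lex$terms))
    return(new_association_records(character(0), character(0), character(0)))
  term_names <- names(pheno_lex$terms)
  term_tok <- strsplit(term_names, " ", fixed = TRUE)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    dtok <- tokenize_text(cand$label[i])
    if (!length(dtok)) return(NULL)
    hit <- 0L
    for (j in order(-lengths(term_tok), term_names)) {
      tt <- term_tok[[j]]
      L <- length(tt)
      if (L > length(dtok)) next
      ok <- FALSE
      for (s in 1:(length(dtok) - L + 1L))
        if (all(dtok[s:(s + L - 1L)] == tt)) { ok <- TRUE; break }
      if (ok) { hit <- j; break }
    }
    if (!hit) return(NULL)
    new_association_records(cand$disease_id[i],
                            pheno_lex$terms[[hit]], "prop_lexical")
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- new_association_records(character(0), character(0), character(0))
  rownames(out) <- NULL
  out
}

#' Restrict records to a common-disease list
#'
#' The list (e.g. codes with at least 100 biobank patients) is always an
#' input file, never computed here.
#'
#' @param records association records.
#' @param common_ids character vector of disease ids to keep.
#' @return the restricted records.
#' @export
select_common <- function(records, common_ids) {
  out <- records[records$disease_id %in% common_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply expert curation overrides
#'
#' Removals drop the pair from the released set (returned via the
#' `removed` attribute with curation_status `removed_fp`); additions enter
#' with provenance `expert` and curation_status `added_fn`. A removal
#' targeting an absent pair warns.
#'
#' @param records association records.
#' @param overrides data.frame with columns disease_id, phenotype_id,
#'   action ("remove" or "add").
#' @return released records (attribute `removed`: the dropped records).
#' @export
apply_curation <- function(records, overrides) {
  removed <- records[0, , drop = FALSE]
  out <- records
  if (nrow(overrides)) {
    bad <- setdiff(unique(overrides$action), c("remove", "add"))
    if (length(bad))
      abort("phenomine_invalid_override", "unknown override action: %s",
            bad[1])
    rem <- overrides[overrides$action == "remove", , drop = FALSE]
    if (nrow(rem)) {
      keys <- pair_key(out$disease_id, out$phenotype_id)
      rkeys <- pair_key(rem$disease_id, rem$phenotype_id)
      missing <- rkeys[!rkeys %in% keys]
      if (length(missing))
        warning(sprintf("%d removal(s) target absent records",
                        length(missing)), call. = FALSE)
      removed <- out[keys %in% rkeys, , drop = FALSE]
      if (nrow(removed)) removed$curation_status <- "removed_fp"
      out <- out[!keys %in% rkeys, , drop = FALSE]
    }
    add <- overrides[overrides$action == "add", , drop = FALSE]
    if (nrow(add))
      out <- rbind(out, new_association_records(add$disease_id,
                                                add$phenotype_id,
                                                "expert", "added_fn"))
  }
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Deduplicate records keeping one provenance per pair
#'
#' When the same (disease, phenotype) pair arrives from several sources,
#' the most reliable provenance is kept, in the order
#' umls_direct > hpo_via_umls > hpo_via_wikidata > wikidata > expert >
#' prop_icd > prop_lexical.
#'
#' @param records association records.
#' @return deduplicated records.
#' @export
dedup_associations <- function(records) {
  pr <- match(records$provenance, PROVENANCE_LEVELS)
  pr[is.na(pr)] <- length(PROVENANCE_LEVELS) + 1L
  ord <- order(records$disease_id, records$phenotype_id, pr)
  out <- records[ord, , drop = FALSE]
  out <- out[!duplicated(pair_key(out$disease_id, out$phenotype_id)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-provenance association counts
#'
#' One row per provenance plus a TOTAL row; the provenance counts always
#' sum exactly to the total (partition discipline).
#'
#' @param records association records.
#' @return data.frame: provenance, n.
#' @export
provenance_summary <- function(records) {
  lev <- c(PROVENANCE_LEVELS, setdiff(unique(records$provenance),
                                      PROVENANCE_LEVELS))
  tab <- table(factor(records$provenance, levels = lev))
  out <- data.frame(provenance = c(names(tab), "TOTAL"),
                    n = c(as.integer(tab), nrow(records)),
                    stringsAsFactors = FALSE)
  out[out$n > 0 | out$provenance == "TOTAL", , drop = FALSE]
}

#' Read / write association record TSVs
#'
#' TSV columns: disease_id, phenotype_id, provenance, curation_status
#' (header row required on read by [read_associations()]).
#'
#' @param path TSV file.
#' @return data.frame of association records.
#' @export
read_associations <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE, quote = "")
  need <- c("disease_id", "phenotype_id")
  if (!all(need %in% names(out)))
    abort("phenomine_io", "association TSV must have columns %s",
          paste(need, collapse = ", "))
  if (is.null(out$provenance)) out$provenance <- "expert"
  if (is.null(out$curation_status)) out$curation_status <- "accepted"
  out
}

#' @rdname read_associations
#' @param records association records to write.
#' @export
write_associations <- function(records, path) {
  write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
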