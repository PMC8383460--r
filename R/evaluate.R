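# Strict and soft comparison of predicted association sets against a gold
# standard, precision/recall/F computation, rank sweeps and coverage
# arithmetic.

as_pair_df <- function(x) {
  if (is.data.frame(x)) {
    df <- data.frame(disease_id = as.character(x$disease_id),
                     phenotype_id = as.character(x$phenotype_id),
                     stringsAsFactors = FALSE)
  } else if (is.list(x)) {  # named list: disease -> phenotype ids
    df <- data.frame(
      disease_id = rep(names(x), lengths(x)),
      phenotype_id = unlist(x, use.names = FALSE),
      stringsAsFactors = FALSE)
  } else {
    abort("phenomine_io", "expected a pair data.frame or named list")
  }
  unique(df)
}

#' Confusion counts helper
#' @param tp,fp,fn non-negative integers.
#' @return object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0))
    abort("phenomine_invalid_counts", "confusion counts must be non-negative")
  structure(list(tp = as.numeric(tp), fp = as.numeric(fp),
                 fn = as.numeric(fn)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%g fp=%g fn=%g (predicted %g, gold %g)\n",
              x$tp, x$fp, x$fn, x$tp + x$fp, x$tp + x$fn))
  invisible(x)
}

#' Strict comparison of predicted vs gold association pairs
#'
#' Exact class matching: the phenotype hierarchy is ignored entirely.
#'
#' @param pred,gold pair data.frames (disease_id, phenotype_id) or named
#'   lists disease -> phenotype ids.
#' @return `confusion_counts` with tp = |pred n gold|, fp = |pred \\ gold|,
#'   fn = |gold \\ pred|.
#' @export
compare_strict <- function(pred, gold) {
  p <- as_pair_df(pred); g <- as_pair_df(gold)
  pk <- pair_key(p$disease_id, p$phenotype_id)
  gk <- pair_key(g$disease_id, g$phenotype_id)
  confusion_counts(tp = length(intersect(pk, gk)),
                   fp = length(setdiff(pk, gk)),
                   fn = length(setdiff(gk, pk)))
}

# Close a pair set under phenotype-ancestor addition (per disease).
close_pairs <- function(pairs, g_pheno) {
  df <- as_pair_df(pairs)
  bad <- setdiff(unique(df$phenotype_id), names(g_pheno$classes))
  if (length(bad))
    abort("phenomine_unknown_class", "phenotype not in ontology: %s", bad[1])
  anc <- lapply(unique(df$phenotype_id), ancestors, g = g_pheno,
                include_self = TRUE)
  names(anc) <- unique(df$phenotype_id)
  expanded <- anc[df$phenotype_id]
  unique(data.frame(
    disease_id = rep(df$disease_id, lengths(expanded)),
    phenotype_id = unlist(expanded, use.names = FALSE),
    stringsAsFactors = FALSE))
}

#' Soft (hierarchy-aware) comparison
#'
#' Both sets are first closed under phenotype-ancestor addition per
#' disease, then compared exactly as in [compare_strict()]. The disease
#' side is never closed.
#'
#' @inheritParams compare_strict
#' @param g_pheno phenotype `ontology_graph`.
#' @return `confusion_counts` on the closed sets.
#' @export
compare_soft <- function(pred, gold, g_pheno) {
  compare_strict(close_pairs(pred, g_pheno), close_pairs(gold, g_pheno))
}

#' Precision, recall and F-score from confusion counts
#'
#' precision = tp/(tp+fp), recall = tp/(tp+fn), F = 2PR/(P+R). Values are
#' kept at full precision; round only at report time.
#'
#' @param counts a `confusion_counts` object (or list with tp/fp/fn).
#' @return named numeric vector: precision, recall, f_score.
#' @export
prf <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp == 0 || tp + fn == 0)
    abort("phenomine_undefined_metric",
          "empty prediction or gold set: P/R undefined")
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f_score = f)
}

#' Evaluation report (counts + metrics + mode)
#'
#' @param pred,gold pair sets.
#' @param mode "strict" or "soft".
#' @param g_pheno phenotype ontology (soft mode only).
#' @return object of class `evaluation_report`: mode, counts, metrics.
#' @export
evaluate_associations <- function(pred, gold, mode = c("strict", "soft"),
                                  g_pheno = NULL) {
  mode <- match.arg(mode)
  counts <- if (mode == "strict") compare_strict(pred, gold)
            else compare_soft(pred, gold, g_pheno)
  structure(list(mode = mode, counts = counts, metrics = prf(counts)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<evaluation_report> mode=%s tp=%g fp=%g fn=%g  P=%.2f R=%.2f F=%.2f\n",
              x$mode, x$counts$tp, x$counts$fp, x$counts$fn,
              m["precision"], m["recall"], m["f_score"]))
  invisible(x)
}

#' Corrected metrics after manual re-labeling of false positives
#'
#' Re-labels a caller-supplied number of false positives as true positives
#' (e.g. predictions found correct on manual review but absent from the
#' gold standard) and recomputes P/R/F. The residual false-positive count
#' may be given explicitly when the review left some calls unresolved.
#'
#' @param counts a `confusion_counts` object.
#' @param n_relabelled number of fp re-labeled as tp.
#' @param residual_fp remaining fp count (default `fp - n_relabelled`).
#' @return `evaluation_report` with mode `"corrected"`.
#' @export
corrected_report <- function(counts, n_relabelled,
                             residual_fp = counts$fp - n_relabelled) {
  if (n_relabelled > counts$fp)
    abort("phenomine_invalid_counts",
          "cannot relabel more fp than available")
  cc <- confusion_counts(tp = counts$tp + n_relabelled, fp = residual_fp,
                         fn = counts$fn)
  structure(list(mode = "corrected", counts = cc, metrics = prf(cc)),
            class = "evaluation_report")
}

#' Evaluate rank-thresholded profiles over a grid of cutoffs
#'
#' For each k in `k_grid`: threshold the scored associations at rank k,
#' compare against the gold standard in the requested mode, and report
#' P/R/F. Also reports the k with maximal F.
#'
#' @param scores data.frame from [score_all()].
#' @param gold gold-standard pair set.
#' @param mode "strict" or "soft".
#' @param k_grid increasing integer vector of rank cutoffs.
#' @param g_pheno phenotype ontology (soft mode only).
#' @return object of class `rank_sweep`: `table` (k, tp, fp, fn, precision,
#'   recall, f_score), `best_k`.
#' @export
rank_sweep <- function(scores, gold, mode = c("strict", "soft"), k_grid,
                       g_pheno = NULL) {
  mode <- match.arg(mode)
  if (!length(k_grid)) abort("phenomine_invalid_threshold", "empty k_grid")
  if (is.unsorted(k_grid, strictly = TRUE))
    abort("phenomine_invalid_threshold", "k_grid must be strictly increasing")
  rows <- lapply(k_grid, function(k) {
    pred <- threshold_profile(scores, k)
    rep_k <- evaluate_associations(pred, gold, mode, g_pheno)
    data.frame(k = k, tp = rep_k$counts$tp, fp = rep_k$counts$fp,
               fn = rep_k$counts$fn,
               precision = rep_k$metrics["precision"],
               recall = rep_k$metrics["recall"],
               f_score = rep_k$metrics["f_score"],
               row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, mode = mode,
                 best_k = tab$k[which.max(tab$f_score)]),
            class = "rank_sweep")
}

#' @export
print.rank_sweep <- function(x, ...) {
  cat(sprintf("<rank_sweep> mode=%s, %d cutoffs; best k=%s (F=%.3f)\n",
              x$mode, nrow(x$table), x$best_k,
              max(x$table$f_score)))
  invisible(x)
}

#' Coverage and overlap accounting over named disease-id sets
#'
#' Works either from explicit id sets or from printed sizes via the
#' inclusion-exclusion shortcut (two sets only).
#'
#' @param sets named list of character vectors of disease ids; or `NULL`
#'   when using `sizes`.
#' @param universe_size total number of disease ids in the terminology.
#' @param sizes optional named numeric vector `c(a = , b = , overlap = )`
#'   giving |A|, |B| and |A n B| directly.
#' @return list: per-set sizes, pairwise intersections, union size, and
#'   union percentage of the universe (rounded to a whole percent).
#' @export
coverage_stats <- function(sets = NULL, universe_size, sizes = NULL) {
  if (!is.null(sizes)) {
    union_size <- unname(sizes["a"] + sizes["b"] - sizes["overlap"])
    set_sizes <- c(a = unname(sizes["a"]), b = unname(sizes["b"]))
    inter <- c("a&b" = unname(sizes["overlap"]))
  } else {
    set_sizes <- vapply(sets, function(s) length(unique(s)), 0)
    nm <- names(sets)
    inter <- c()
    if (length(sets) > 1) {
      cmb <- utils::combn(seq_along(sets), 2)
      inter <- apply(cmb, 2, function(ij)
        length(intersect(sets[[ij[1]]], sets[[ij[2]]])))
      names(inter) <- apply(cmb, 2, function(ij)
        paste(nm[ij[1]], nm[ij[2]], sep = "&"))
    }
    union_size <- length(unique(unlist(sets)))
  }
  if (universe_size < union_size)
    abort("phenomine_invalid_counts",
          "universe smaller than the union of the sets")
  list(set_sizes = set_sizes, intersections = inter,
       union_size = unname(union_size),
       union_pct = round(100 * union_size / universe_size),
       uncovered = unname(universe_size - union_size))
}
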