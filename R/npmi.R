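# Normalized pointwise mutual information over ontology classes, plus
# per-disease ranking and rank-threshold profiles.

# Vectorized core; all arguments numeric vectors of equal length.
npmi_value <- function(n_cd, n_c, n_d, n_tot) {
  out <- numeric(length(n_cd))
  zero <- n_cd == 0
  full <- n_cd == n_tot
  mid <- !zero & !full
  out[zero] <- -1
  out[full] <- 1
  if (any(mid)) {
    num <- log(n_cd[mid] * n_tot / (n_c[mid] * n_d[mid]))
    den <- -log(n_cd[mid] / n_tot)
    out[mid] <- num / den
  }
  out
}

#' NPMI between a disease and a phenotype class
#'
#' npmi(C,D) = log(n_CD * n_tot / (n_C * n_D)) / (-log(n_CD / n_tot)),
#' computed from abstract-level class counts. The value lies in \[-1, 1\]:
#' -1 for never co-mentioned (by convention), 0 at independence, +1 for
#' perfect co-occurrence (including the degenerate n_CD = n_tot case).
#'
#' @param counts a `cooccurrence_counts` object.
#' @param disease_id,phenotype_id class identifiers.
#' @return a single numeric value in \[-1, 1\].
#' @export
npmi <- function(counts, disease_id, phenotype_id) {
  if (counts$n_tot <= 0)
    abort("phenomine_inconsistent_counts", "n_tot must be positive")
  nc <- unname(counts$n_c[disease_id]); nc <- if (is.na(nc)) 0L else nc
  nd <- unname(counts$n_d[phenotype_id]); nd <- if (is.na(nd)) 0L else nd
  row <- counts$n_cd[counts$n_cd$disease_id == disease_id &
                       counts$n_cd$phenotype_id == phenotype_id, ]
  ncd <- if (nrow(row)) row$n[1] else 0L
  if (ncd > 0 && (nc == 0 || nd == 0))
    abort("phenomine_inconsistent_counts",
          "joint count %d with a zero marginal for (%s, %s)",
          ncd, disease_id, phenotype_id)
  if (nc == 0 || nd == 0)
    abort("phenomine_inconsistent_counts",
          "zero marginal count for (%s, %s)", disease_id, phenotype_id)
  if (ncd > min(nc, nd) || max(nc, nd) > counts$n_tot)
    abort("phenomine_inconsistent_counts",
          "counts violate n_cd <= min(n_c, n_d) <= n_tot")
  npmi_value(ncd, nc, nd, counts$n_tot)
}

#' Score every co-mentioned disease-phenotype pair
#'
#' Scores all pairs with n_CD >= 1 and assigns per-disease ranks by
#' descending NPMI (ties broken by phenotype id, for determinism).
#'
#' @param counts a `cooccurrence_counts` object.
#' @param positive_only keep only strictly positive scores (default `TRUE`,
#'   the usual association-dataset setting).
#' @param min_npmi alternative lower bound (strict inequality), overriding
#'   `positive_only` when supplied.
#' @return data.frame: disease_id, phenotype_id, npmi, rank.
#' @export
score_all <- function(counts, positive_only = TRUE, min_npmi = NULL) {
  tab <- counts$n_cd
  if (!nrow(tab))
    return(data.frame(disease_id = character(0), phenotype_id = character(0),
                      npmi = numeric(0), rank = integer(0)))
  score <- npmi_value(tab$n,
                      counts$n_c[tab$disease_id],
                      counts$n_d[tab$phenotype_id],
                      counts$n_tot)
  out <- data.frame(disease_id = tab$disease_id,
                    phenotype_id = tab$phenotype_id,
                    npmi = score, stringsAsFactors = FALSE)
  thr <- min_npmi %||% (if (positive_only) 0 else -Inf)
  out <- out[out$npmi > thr, , drop = FALSE]
  out <- out[order(out$disease_id, -out$npmi, out$phenotype_id), ,
             drop = FALSE]
  out$rank <- stats::ave(out$npmi, out$disease_id,
                         FUN = function(v) seq_along(v))
  out$rank <- as.integer(out$rank)
  rownames(out) <- NULL
  out
}

#' Rank-thresholded phenotype profile per disease
#'
#' @param scores data.frame from [score_all()] (must carry `rank`).
#' @param k keep phenotypes with rank <= k; diseases with fewer than `k`
#'   scored phenotypes keep all of them.
#' @return named list: disease_id -> character vector of phenotype ids.
#' @export
threshold_profile <- function(scores, k) {
  if (!is.numeric(k) || length(k) != 1 || k < 1)
    abort("phenomine_invalid_threshold", "rank threshold k must be >= 1")
  kept <- scores[scores$rank <= k, , drop = FALSE]
  split(kept$phenotype_id, kept$disease_id)
}

#' Write association scores to TSV
#' @param scores data.frame from [score_all()].
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
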