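# Phenotype-profile embeddings: annotation graph construction, seeded
# random walks, skip-gram training (negative sampling, single worker) and
# cosine-similarity / ROC utilities.

#' Build the walkable annotation graph
#'
#' Undirected graph whose nodes are phenotype classes plus entities
#' (diseases or genes) and whose edges are the ontology's subclass edges
#' plus one annotation edge per (entity, phenotype) pair.
#'
#' @param g_pheno phenotype `ontology_graph`.
#' @param profiles data.frame with columns entity_id, phenotype_id and
#'   optionally entity_kind ("disease"/"gene").
#' @return igraph object with vertex attribute `kind` (class/entity) and
#'   edge attribute `type` (subclass/annotation).
#' @export
build_annotation_graph <- function(g_pheno, profiles) {
  bad <- setdiff(unique(profiles$phenotype_id), names(g_pheno$classes))
  if (length(bad))
    abort("phenomine_unknown_class",
          "profile phenotype not in ontology: %s", bad[1])
  classes <- names(g_pheno$classes)
  entities <- unique(profiles$entity_id)
  if (length(intersect(entities, classes)))
    abort("phenomine_invalid_profile",
          "entity ids collide with class ids: %s",
          intersect(entities, classes)[1])
  verts <- data.frame(name = c(classes, entities),
                      kind = rep(c("class", "entity"),
                                 c(length(classes), length(entities))),
                      stringsAsFactors = FALSE)
  edges <- rbind(
    if (nrow(g_pheno$edges))
      data.frame(from = g_pheno$edges$child, to = g_pheno$edges$parent,
                 type = "subclass", stringsAsFactors = FALSE),
    data.frame(from = profiles$entity_id, to = profiles$phenotype_id,
               type = "annotation", stringsAsFactors = FALSE))
  edges <- unique(edges)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Generate a random-walk corpus over the annotation graph
#'
#' Uniform random neighbor steps, `walks_per_node` walks started at every
#' node, each of at most `walk_depth` steps (so sequences have length
#' `walk_depth + 1`). Fully reproducible from `seed`. Isolated nodes yield
#' single-node walks.
#'
#' @param g igraph from [build_annotation_graph()].
#' @param walk_depth number of steps per walk (default 3).
#' @param walks_per_node walks started per node (default 10).
#' @param seed integer RNG seed.
#' @return list of character vectors of node ids.
#' @export
random_walk_corpus <- function(g, walk_depth = 3, walks_per_node = 10, seed) {
  if (walk_depth < 1) abort("phenomine_invalid_threshold",
                            "walk_depth must be >= 1")
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)
  with_seed(seed, {
    walks <- vector("list", length(nodes) * walks_per_node)
    k <- 0L
    for (v in nodes) {
      for (w in seq_len(walks_per_node)) {
        k <- k + 1L
        walks[[k]] <- if (deg[[v]] == 0L) v else
          names(igraph::random_walk(g, start = v, steps = walk_depth,
                                    stuck = "return"))
      }
    }
    walks
  })
}

#' Write / read a walk corpus (one walk per line, space-separated ids)
#' @param walks list of character vectors.
#' @param path plain-text file.
#' @export
write_walks <- function(walks, path) {
  writeLines(vapply(walks, paste, "", collapse = " "), path)
  invisible(path)
}

#' @rdname write_walks
#' @export
read_walks <- function(path) {
  strsplit(readLines(path, warn = FALSE), " ", fixed = TRUE)
}

#' Train node embeddings from a walk corpus
#'
#' Skip-gram with negative sampling over the walk corpus, single worker,
#' deterministic for a fixed seed. Defaults follow the usual
#' graph-embedding settings: dimension 100, window 5, min_count 1.
#'
#' @param walks list of character vectors (node-id sequences).
#' @param dim embedding dimension.
#' @param window context window size.
#' @param min_count minimum corpus frequency for a node to get a vector.
#' @param epochs training epochs.
#' @param negative negative samples per positive pair.
#' @param learning_rate initial SGD step size (linearly decayed).
#' @param seed integer seed controlling init and negative sampling.
#' @return object of class `embedding_space`: `vectors` (matrix, one row
#'   per node), `meta` (hyperparameters).
#' @export
train_embeddings <- function(walks, dim = 100, window = 5, min_count = 1,
                             epochs = 5, negative = 5, learning_rate = 0.025,
                             seed = 1) {
  tokens <- unlist(walks, use.names = FALSE)
  if (!length(tokens))
    abort("phenomine_empty_corpus", "walk corpus is empty")
  freq <- table(tokens)
  vocab <- names(freq)[freq >= min_count]
  if (!length(vocab))
    abort("phenomine_empty_corpus", "no node meets min_count")
  vocab <- sort(vocab)
  counts <- as.numeric(freq[vocab])
  # (center, context) pairs within the fixed window, vocabulary-filtered
  acc_c <- vector("list", length(walks)); acc_x <- acc_c
  for (k in seq_along(walks)) {
    idx <- match(walks[[k]], vocab)
    idx <- idx[!is.na(idx)]
    n <- length(idx)
    if (n < 2) next
    cc <- vector("list", n); xx <- cc
    for (i in seq_len(n)) {
      lo <- max(1L, i - window); hi <- min(n, i + window)
      ctx <- idx[setdiff(lo:hi, i)]
      cc[[i]] <- rep(idx[i], length(ctx)); xx[[i]] <- ctx
    }
    acc_c[[k]] <- unlist(cc); acc_x[[k]] <- unlist(xx)
  }
  centers <- unlist(acc_c); contexts <- unlist(acc_x)
  if (!length(centers))
    abort("phenomine_empty_corpus", "no training pairs in walk corpus")
  init <- with_seed(seed, {
    (runif(length(vocab) * dim) - 0.5) / dim
  })
  emb <- sgns_train(centers - 1L, contexts - 1L, length(vocab),
                    as.integer(dim), as.numeric(counts),
                    as.integer(epochs), as.integer(negative),
                    as.numeric(learning_rate), as.integer(seed %% 2147483647),
                    as.numeric(init))
  rownames(emb) <- vocab
  structure(list(vectors = emb,
                 meta = list(dim = dim, window = window,
                             min_count = min_count, epochs = epochs,
                             negative = negative, seed = seed)),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space> %d nodes x %d dims (window %d, seed %s)\n",
              nrow(x$vectors), x$meta$dim, x$meta$window,
              format(x$meta$seed)))
  invisible(x)
}

#' Write embeddings as TSV (node_id + dim floats)
#' @param space an `embedding_space`.
#' @param path output TSV.
#' @export
write_embeddings <- function(space, path) {
  df <- data.frame(node_id = rownames(space$vectors), space$vectors,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cosine similarity between two vectors
#'
#' sim(v1, v2) = (v1 . v2) / (||v1|| ||v2||), in \[-1, 1\].
#'
#' @param v1,v2 numeric vectors of equal length.
#' @return a single numeric value.
#' @export
cosine <- function(v1, v2) {
  if (length(v1) != length(v2))
    abort("phenomine_dimension_mismatch",
          "vectors differ in dimension (%d vs %d)", length(v1), length(v2))
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    abort("phenomine_zero_norm", "cosine undefined for a zero vector")
  sum(v1 * v2) / (n1 * n2)
}

#' Area under the ROC curve from scored positives and negatives
#'
#' Rank (Mann-Whitney) formulation; tied scores contribute 1/2.
#'
#' @param scores numeric similarity scores.
#' @param labels logical or "pos"/"neg" labels, parallel to `scores`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "pos"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    abort("phenomine_undefined_auc",
          "AUC needs both positive and negative examples")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points (threshold, TPR, FPR)
#'
#' @inheritParams roc_auc
#' @return data.frame threshold, tpr, fpr, plus attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "pos"
  thr <- sort(unique(scores), decreasing = TRUE)
  out <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), 0),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), 0))
  attr(out, "auc") <- roc_auc(scores, labels)
  out
}
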