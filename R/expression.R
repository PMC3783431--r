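## Replicate-median probe summarization, cross-species gene consolidation,
## differential-expression calls, sum-squared ranking, and heat-map matrix
## construction.

#' Summarize replicate spots to probe-level log2 ratios
#'
#' One value per probe: the median of its unflagged replicate M values
#' (the median of the 46 replicates on the default platform). Probes with
#' no usable replicate get NA with a reason.
#'
#' @param ma_features Feature table carrying `probe_id`, `M`, `flag`.
#' @param exclusions Optional character vector of probe ids to suppress
#'   entirely.
#' @return data.frame `probe_id`, `m` (median log2 ratio), `n_rep`
#'   (replicates used); attribute `missing_reason` names probes without a
#'   value.
#' @export
summarize_probes <- function(ma_features, exclusions = NULL) {
  probes <- sort(unique(ma_features$probe_id))
  use <- ma_features$flag == "ok" & !is.na(ma_features$M)
  if (!is.null(exclusions)) use <- use & !(ma_features$probe_id %in% exclusions)
  x <- ma_features[use, ]
  f <- factor(x$probe_id, levels = probes)
  m <- tapply(x$M, f, stats::median)
  n <- tapply(x$M, f, length)
  n[is.na(n)] <- 0L
  res <- data.frame(probe_id = probes, m = as.numeric(m),
                    n_rep = as.integer(n), stringsAsFactors = FALSE)
  miss <- res$probe_id[res$n_rep == 0]
  attr(res, "missing_reason") <- if (length(miss))
    stats::setNames(rep("no unflagged replicates", length(miss)), miss)
  else stats::setNames(character(), character())
  res
}

#' Build a probe-level log2 ratio matrix across fish
#'
#' Convenience wrapper applying [summarize_probes()] to each fish's MA
#' feature table.
#'
#' @param ma_tables Named list of MA feature tables (one per fish).
#' @param exclusions Optional probe ids to suppress.
#' @return Numeric matrix, probes x fish.
#' @export
probe_matrix <- function(ma_tables, exclusions = NULL) {
  summaries <- lapply(ma_tables, summarize_probes, exclusions = exclusions)
  probes <- summaries[[1]]$probe_id
  mat <- sapply(summaries, function(s) s$m[match(probes, s$probe_id)])
  rownames(mat) <- probes
  colnames(mat) <- names(ma_tables)
  mat
}

#' Consolidate species probes into gene-level values
#'
#' The gene-level log2 ratio per fish is the arithmetic mean of that
#' gene's probe values (all species, all gene regions). Genes whose probes
#' are all missing for a fish are NA for that fish.
#'
#' @param pmat Probe matrix (probes x fish), as from [probe_matrix()].
#' @param design Design table mapping `probe_id` to `gene_id`.
#' @return Gene matrix (genes x fish); attribute `provenance` lists the
#'   probes contributing to each gene row.
#' @export
consolidate_genes <- function(pmat, design) {
  map <- unique(design[, c("probe_id", "gene_id")])
  gene <- map$gene_id[match(rownames(pmat), map$probe_id)]
  if (anyNA(gene))
    stop2("probes without a gene mapping: %s",
          paste(utils::head(rownames(pmat)[is.na(gene)], 3), collapse = ", "))
  genes <- sort(unique(gene))
  gmat <- do.call(rbind, lapply(genes, function(g) {
    colMeans(pmat[gene == g, , drop = FALSE], na.rm = TRUE)
  }))
  gmat[is.nan(gmat)] <- NA_real_
  rownames(gmat) <- genes
  attr(gmat, "provenance") <- split(rownames(pmat), gene)[genes]
  gmat
}

#' Call differential expression at a fixed log2 threshold
#'
#' @param values Numeric vector of log2 ratios.
#' @param tau Threshold (default 2, i.e. 4-fold): `up` if value > tau,
#'   `down` if value < -tau, else `unchanged`. Missing values are
#'   `unchanged` and recorded in attribute `missing`.
#' @return Character vector of calls.
#' @export
call_de <- function(values, tau = 2) {
  call <- rep("unchanged", length(values))
  call[!is.na(values) & values > tau] <- "up"
  call[!is.na(values) & values < -tau] <- "down"
  attr(call, "missing") <- which(is.na(values))
  call
}

#' Rank features by the sum-squared statistic
#'
#' score(row) = sum over fish of the squared log2 ratio; missing entries
#' contribute zero. The statistic measures total modulation across any and
#' all fish, so a transcript altered in a single fish still ranks.
#'
#' @param mat Numeric matrix, features x fish (>= 1 column).
#' @return data.frame `id`, `score`, `rank` sorted by descending score,
#'   ties broken lexicographically by id.
#' @export
sum_squared_rank <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1,
                                       dimnames = list(names(mat), NULL))
  if (ncol(mat) < 1) stop2("need >= 1 fish column")
  m2 <- mat^2
  m2[is.na(m2)] <- 0
  score <- rowSums(m2)
  o <- order(-score, rownames(mat))
  data.frame(id = rownames(mat)[o], score = as.numeric(score[o]),
             rank = seq_along(o), stringsAsFactors = FALSE)
}

#' Consolidate the top-ranked probes into gene strips
#'
#' Takes the top `k` probes of a sum-squared ranking and groups them by
#' gene, merging species variants of the same gene into one strip;
#' strip order follows each gene's first appearance in the ranking.
#'
#' @param ranked Output of [sum_squared_rank()] on a probe matrix.
#' @param design Design table mapping `probe_id` to `gene_id`.
#' @param k Number of top probes to keep (default 100).
#' @return data.frame `gene_id`, `n_probes`, `probe_ids`
#'   (comma-separated), `best_rank`, in first-appearance order.
#' @export
top_k_consolidate <- function(ranked, design, k = 100L) {
  if (k > nrow(ranked)) {
    warn2("k = %d exceeds list length %d; using the full list",
          k, nrow(ranked))
    k <- nrow(ranked)
  }
  top <- ranked[seq_len(k), ]
  map <- unique(design[, c("probe_id", "gene_id")])
  top$gene_id <- map$gene_id[match(top$id, map$probe_id)]
  if (anyNA(top$gene_id))
    stop2("ranked probes missing from design: %s",
          paste(utils::head(top$id[is.na(top$gene_id)], 3), collapse = ", "))
  genes <- unique(top$gene_id)   # first-appearance order
  out <- do.call(rbind, lapply(genes, function(g) {
    sub <- top[top$gene_id == g, ]
    data.frame(gene_id = g, n_probes = nrow(sub),
               probe_ids = paste(sub$id, collapse = ","),
               best_rank = min(sub$rank), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Heat-map matrix with fold-change clipping and Ward row ordering
#'
#' Clips log2 ratios to +/- log2(clip_fold) (default 8-fold, i.e. +/- 3
#' log2 units) and orders rows by agglomerative Ward clustering on the
#' Euclidean distance of the clipped rows. The ordering consolidates
#' visually similar genes; it is display-only, not an inference step.
#'
#' @param gmat Gene matrix (genes x fish).
#' @param clip_fold Linear fold beyond which values are truncated
#'   (default 8).
#' @return List: `matrix` (clipped, rows in cluster order), `order`
#'   (row permutation), `hclust` (the dendrogram object), `dropped`
#'   (all-missing rows removed, with a warning).
#' @export
heatmap_matrix <- function(gmat, clip_fold = 8) {
  clip <- log2(clip_fold)
  all_na <- apply(gmat, 1, function(r) all(is.na(r)))
  if (any(all_na))
    warn2("dropping %d all-missing row(s): %s", sum(all_na),
          paste(utils::head(rownames(gmat)[all_na], 3), collapse = ", "))
  g <- gmat[!all_na, , drop = FALSE]
  g[g > clip] <- clip
  g[g < -clip] <- -clip
  if (nrow(g) >= 3) {
    g0 <- g
    g0[is.na(g0)] <- 0
    hc <- stats::hclust(stats::dist(g0), method = "ward.D2")
    ord <- hc$order
  } else {
    hc <- NULL
    ord <- seq_len(nrow(g))
  }
  list(matrix = g[ord, , drop = FALSE], order = ord, hclust = hc,
       dropped = rownames(gmat)[all_na])
}
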