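## Conserved-window multi-species probe selection.
##
## Probes for an unsequenced target species are designed from multiple
## alignments of the corresponding gene in sequenced relatives: windows in
## which all aligned species agree closely are likely to hybridize with the
## (unknown) homolog of the target.  Scoring is deliberately conservative:
## a window's score is the MINIMUM pairwise identity over all species pairs.

VALID_BASES <- c("A", "C", "G", "T")

#' Construct a multiple alignment object
#'
#' A light container for a gapped nucleotide multiple alignment of one gene
#' across several species. Sequences are uppercased on ingest; characters
#' outside `A`, `C`, `G`, `T`, `-` (including ambiguity codes such as `N`)
#' are rejected.
#'
#' @param gene_id Gene identifier.
#' @param species Character vector of species identifiers (one per row).
#' @param sequences Character vector of aligned sequences, equal lengths,
#'   alphabet `ACGT-`.
#' @return An object of class `multi_alignment`.
#' @examples
#' aln <- multi_alignment("vtg1", c("fugu", "tilapia"),
#'                        c("ACGTACGT", "ACGTACGA"))
#' @export
multi_alignment <- function(gene_id, species, sequences) {
  if (length(species) != length(sequences))
    stop2("species and sequences must have equal length")
  if (length(sequences) < 2)
    stop2("a multiple alignment needs at least 2 rows")
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1)
    stop2("aligned sequences must all have the same length")
  bad <- grepl(sprintf("[^%s-]", paste(VALID_BASES, collapse = "")), sequences)
  if (any(bad))
    stop2("sequence for species '%s' contains characters outside ACGT-",
          species[which(bad)[1]])
  if (anyDuplicated(species))
    stop2("duplicated species identifiers in alignment")
  structure(list(gene_id = gene_id, species = species,
                 sequences = sequences, width = widths[1]),
            class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat(sprintf("multi_alignment '%s': %d species x %d columns\n",
              x$gene_id, length(x$species), x$width))
  invisible(x)
}

#' Ungapped pairwise nucleotide identity
#'
#' Fraction of positions at which two equal-length, gap-free sequences carry
#' the same base. On a 60-mer, 9 mismatches give 51/60 = 0.85, the usual
#' cross-species hybridization cut-off.
#'
#' @param a,b Equal-length gap-free nucleotide sequences.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 0.75
#' @export
pairwise_identity <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b))
    stop2("pairwise_identity: sequences differ in length (%d vs %d)",
          nchar(a), nchar(b))
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
    stop2("pairwise_identity: sequences must be gap-free")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca == cb)
}

#' Scan a multiple alignment for conserved probe windows
#'
#' Slides a fixed-length window over the alignment columns. Windows touching
#' a gap in any row are excluded. For each remaining window position one
#' candidate is emitted per source row (the row whose bases become the probe
#' sequence); the window's conservation score is the minimum pairwise
#' identity among all row pairs within the window.
#'
#' @param alignment A [multi_alignment()].
#' @param window Window length in alignment columns (default 60, the probe
#'   length of ink-jet 60-mer platforms).
#' @return A data.frame with columns `gene_id`, `species`, `start` (0-based
#'   alignment column), `sequence`, `min_pairwise_identity`, sorted by score
#'   descending, then start ascending, then species. Empty (with a warning)
#'   when no gap-free window exists.
#' @export
find_conserved_windows <- function(alignment, window = 60L) {
  stopifnot(inherits(alignment, "multi_alignment"))
  window <- as.integer(window)
  if (alignment$width < window)
    stop2("alignment has %d columns; window of %d requested",
          alignment$width, window)
  n <- length(alignment$species)
  chars <- do.call(rbind, strsplit(alignment$sequences, "", fixed = TRUE))
  ncol_aln <- ncol(chars)
  nstart <- ncol_aln - window + 1L

  ## windows containing a gap in any row are excluded
  gap_col <- colSums(chars == "-") > 0
  cg <- cumsum(gap_col)
  gaps_in_window <- cg[window:ncol_aln] - c(0, cg)[1:nstart]
  ok <- gaps_in_window == 0
  if (!any(ok)) {
    warn2("alignment '%s': no gap-free window of length %d",
          alignment$gene_id, window)
    return(data.frame(gene_id = character(), species = character(),
                      start = integer(), sequence = character(),
                      min_pairwise_identity = numeric()))
  }

  ## min pairwise identity per window via rolling sums of per-column matches
  pairs <- utils::combn(n, 2)
  min_ident <- rep(Inf, nstart)
  for (k in seq_len(ncol(pairs))) {
    m <- as.numeric(chars[pairs[1, k], ] == chars[pairs[2, k], ])
    cm <- cumsum(m)
    wsum <- cm[window:ncol_aln] - c(0, cm)[1:nstart]
    min_ident <- pmin(min_ident, wsum / window)
  }

  starts0 <- which(ok) - 1L     # 0-based
  res <- expand.grid(species = alignment$species, start = starts0,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$gene_id <- alignment$gene_id
  res$min_pairwise_identity <- min_ident[res$start + 1L]
  res$sequence <- vapply(seq_len(nrow(res)), function(i) {
    row <- match(res$species[i], alignment$species)
    paste(chars[row, (res$start[i] + 1L):(res$start[i] + window)],
          collapse = "")
  }, character(1))
  res <- res[order(-res$min_pairwise_identity, res$start, res$species), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("gene_id", "species", "start", "sequence",
          "min_pairwise_identity")]
}

#' Screen a probe against a cross-species homolog
#'
#' Ungapped sliding-offset identity of a probe against every window of a
#' homologous target sequence; the probe passes when its best identity
#' reaches the threshold (default 0.85, i.e. at least 51/60 matching bases
#' for a 60-mer).
#'
#' @param probe Gap-free probe sequence.
#' @param target Homolog sequence, at least as long as the probe.
#' @param threshold Identity required to pass (default 0.85).
#' @return A list with `best_offset` (0-based, leftmost on ties),
#'   `best_identity`, and logical `pass`.
#' @export
screen_cross_species <- function(probe, target, threshold = 0.85) {
  probe <- toupper(probe); target <- toupper(target)
  np <- nchar(probe); nt <- nchar(target)
  if (nt < np)
    stop2("target (%d nt) shorter than probe (%d nt)", nt, np)
  pc <- strsplit(probe, "", fixed = TRUE)[[1]]
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  noff <- nt - np + 1L
  ident <- vapply(seq_len(noff), function(o) {
    mean(pc == tc[o:(o + np - 1L)])
  }, numeric(1))
  best <- which.max(ident)   # leftmost maximum
  list(best_offset = best - 1L, best_identity = ident[best],
       pass = ident[best] >= threshold)
}

#' Select a multi-species probe set from gene alignments
#'
#' For each gene, scans its alignment for conserved gap-free windows, keeps
#' each source species' best-scoring window whose minimum pairwise identity
#' reaches `min_identity`, and emits at most `per_gene_limit` probes per
#' gene (highest-scoring first). Genes with no qualifying window are never
#' silently dropped: they appear in the `rejected` attribute with their best
#' attainable score.
#'
#' @param alignments List of [multi_alignment()] objects.
#' @param window Probe length (default 60).
#' @param min_identity Minimum interspecies identity for a window to
#'   qualify (default 0.80; use 0.90 for the strict preset).
#' @param per_gene_limit Maximum probes emitted per gene (default 5).
#' @return data.frame with columns `probe_id`, `gene_id`, `species`,
#'   `sequence`, `start`, `min_pairwise_identity`; attribute `rejected` is a
#'   data.frame of genes without a qualifying window.
#' @export
design_probe_set <- function(alignments, window = 60L, min_identity = 0.80,
                             per_gene_limit = 5L) {
  picked <- list()
  rejected <- list()
  for (aln in alignments) {
    cand <- find_conserved_windows(aln, window = window)
    best_score <- if (nrow(cand)) max(cand$min_pairwise_identity) else NA_real_
    cand <- cand[cand$min_pairwise_identity >= min_identity, , drop = FALSE]
    if (!nrow(cand)) {
      rejected[[length(rejected) + 1L]] <-
        data.frame(gene_id = aln$gene_id, best_score = best_score)
      next
    }
    ## best window per source species (cand is already sorted)
    cand <- cand[!duplicated(cand$species), , drop = FALSE]
    cand <- utils::head(cand, per_gene_limit)
    picked[[length(picked) + 1L]] <- cand
  }
  out <- if (length(picked)) do.call(rbind, picked) else
    data.frame(gene_id = character(), species = character(),
               start = integer(), sequence = character(),
               min_pairwise_identity = numeric())
  if (nrow(out))
    out <- cbind(probe_id = sprintf("%s_%s", out$gene_id, out$species), out)
  else
    out <- cbind(probe_id = character(), out)
  rownames(out) <- NULL
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(gene_id = character(), best_score = numeric())
  out
}
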