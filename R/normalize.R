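## MA transformation, pooled-reference construction, and simultaneous
## multiple-loess normalization.

#' MA transformation of two matched log2 intensity vectors
#'
#' M = sample - reference measures differential expression; A = (sample +
#' reference)/2 measures signal intensity. The transform is invertible:
#' sample = A + M/2, reference = A - M/2.
#'
#' @param sample_log2,reference_log2 Equal-length numeric vectors in
#'   matched feature order.
#' @return data.frame with columns `M` and `A`.
#' @export
compute_ma <- function(sample_log2, reference_log2) {
  if (length(sample_log2) != length(reference_log2))
    stop2("compute_ma: length mismatch (%d vs %d)",
          length(sample_log2), length(reference_log2))
  data.frame(M = sample_log2 - reference_log2,
             A = (sample_log2 + reference_log2) / 2)
}

#' Pool control hybridizations into a reference
#'
#' Emulates equimolar pooling of labeled cRNA from several control fish:
#' per feature, the pooled log2 signal is the log2 of the arithmetic mean
#' of the linear-scale intensities.
#'
#' @param control_tables List of >= 2 feature tables sharing the same
#'   feature set (same rows in the same (row, col, probe_id) order).
#' @return A feature table with the pooled `log2_signal`.
#' @export
pool_reference <- function(control_tables) {
  if (length(control_tables) < 2)
    stop2("pool_reference needs at least 2 control tables")
  key <- function(t) paste(t$row, t$col, t$probe_id)
  k0 <- key(control_tables[[1]])
  for (i in seq_along(control_tables)[-1]) {
    if (!identical(key(control_tables[[i]]), k0))
      stop2("control table %d has a different feature set/order", i)
  }
  lin <- sapply(control_tables, function(t) 2^t$log2_signal)
  pooled <- control_tables[[1]]
  pooled$log2_signal <- log2(rowMeans(lin))
  pooled
}

#' Simultaneous multiple-loess normalization
#'
#' Removes smooth intensity-dependent bias from all samples at once by
#' iterating: (1) form the consensus intensity (per-feature mean across
#' samples); (2) for each sample, fit a local-linear tricube smoother of
#' (sample - consensus) against the consensus and subtract the fitted
#' curve. Iteration stops when the largest absolute correction falls below
#' `tol` or `max_iter` is reached; non-convergence is reported, not thrown.
#'
#' @param mat Numeric matrix, features x samples (log2 scale), >= 50
#'   features and >= 2 samples.
#' @details Corrections are centered across samples at each feature, so
#' the consensus itself is invariant: only relative (between-sample) bias
#' is removable without an external reference. Predictions are held
#' constant beyond the 1st/99th percentile of the consensus to avoid
#' boundary extrapolation noise. Note the attainable tolerance is bounded
#' below by the smoother's own noise floor (roughly the local-fit standard
#' error); on noisy data a very small `tol` ends at `max_iter` with
#' `converged = FALSE`, which is reported, not thrown.
#'
#' @param span Loess span in (0, 1] (default 0.3).
#' @param max_iter Maximum iterations (default 10).
#' @param tol Convergence tolerance on the largest correction (default 1e-3).
#' @return List of class `multiloess_result`: `normalized` (matrix of the
#'   input shape), `curves` (per-sample data.frames of the last fitted
#'   correction vs consensus A), `iterations`, `converged`.
#' @export
multiloess_normalize <- function(mat, span = 0.3, max_iter = 10L,
                                 tol = 1e-3) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop2("multiloess_normalize needs >= 2 samples")
  if (nrow(mat) < 50) stop2("multiloess_normalize needs >= 50 features")
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop2("span must lie in (0, 1]")
  out <- mat
  curves <- vector("list", ncol(mat))
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    consensus <- rowMeans(out)
    qr <- stats::quantile(consensus, c(0.01, 0.99), names = FALSE)
    xc <- pmin(pmax(consensus, qr[1]), qr[2])
    corr <- matrix(0, nrow(out), ncol(out))
    for (j in seq_len(ncol(out))) {
      m <- out[, j] - consensus
      if (max(abs(m)) < tol) {
        curves[[j]] <- data.frame(A = consensus, correction = 0)
        next
      }
      fit <- stats::loess(m ~ consensus, span = span, degree = 1,
                          family = "symmetric")
      corr[, j] <- stats::predict(fit, xc)
      curves[[j]] <- data.frame(A = consensus, correction = corr[, j])
    }
    corr <- corr - rowMeans(corr)   # consensus-preserving
    out <- out - corr
    if (max(abs(corr)) < tol) { converged <- TRUE; break }
  }
  names(curves) <- colnames(mat)
  structure(list(normalized = out, curves = curves, iterations = iter,
                 converged = converged),
            class = "multiloess_result")
}

#' @export
print.multiloess_result <- function(x, ...) {
  cat(sprintf("multiloess_normalize: %d features x %d samples, %d iteration(s), %s\n",
              nrow(x$normalized), ncol(x$normalized), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
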