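## Spearman correlation with significance, phenotype-expression screening,
## fold-change power planning, and qPCR relative quantification.

## all permutations of 1..n as an integer matrix (rows = permutations)
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- perm_matrix(n - 1L)
  m <- nrow(sub)
  out <- matrix(0L, nrow = n * m, ncol = n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * m + 1L):(i * m)
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow = m)
  }
  out
}

#' Spearman rank correlation with significance
#'
#' rho is the Pearson correlation of average-ranked values (tied values
#' share average ranks). The two-sided p-value uses the t approximation
#' with n - 2 degrees of freedom for n > 9 and exact enumeration over all
#' n! rank permutations for n <= 9.
#'
#' @param x,y Equal-length numeric vectors; pairs with a missing value are
#'   dropped. At least 3 complete pairs required.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact permutation
#'   null; default `NULL` switches at n <= 9.
#' @return List: `rho`, `p`, `n`, `method` ("exact" or "t-approximation").
#' @export
spearman_cor <- function(x, y, exact = NULL) {
  if (length(x) != length(y))
    stop2("spearman_cor: length mismatch (%d vs %d)", length(x), length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop2("spearman_cor: need >= 3 complete pairs, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop2("spearman_cor: correlation undefined for a constant vector")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  use_exact <- if (is.null(exact)) n <= 9 else exact
  if (use_exact) {
    if (n > 9) stop2("exact permutation null limited to n <= 9")
    pm <- perm_matrix(n)
    ry_perm <- matrix(ry[pm], nrow = nrow(pm))
    s <- as.numeric(ry_perm %*% rx)
    ## rho is an affine function of s for fixed marginals
    denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rho_perm <- (s - n * mean(rx) * mean(ry)) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Screen all gene-by-endpoint Spearman correlations
#'
#' Tests every pairing of a gene-expression row with a phenotype endpoint
#' (gene-by-gene pairs can be screened the same way by passing a second
#' gene matrix as `phenotypes`). Constant rows are excluded with a
#' warning, not an error.
#'
#' @param gmat Gene matrix, genes x fish (fish ids as column names).
#' @param phenotypes data.frame with a `fish_id` column and numeric
#'   endpoint columns, e.g. from [load_packaged_phenotypes()] or
#'   [simulate_phenotypes()].
#' @param alpha Significance level for the flag (default 0.05).
#' @param endpoints Endpoint columns to use; default all numeric columns.
#' @return data.frame `gene`, `endpoint`, `rho`, `p`, `n`, `significant`.
#' @export
phenotype_correlations <- function(gmat, phenotypes, alpha = 0.05,
                                   endpoints = NULL) {
  shared <- intersect(colnames(gmat), phenotypes$fish_id)
  if (length(shared) < 3)
    stop2("only %d fish shared between matrices; need >= 3", length(shared))
  ph <- phenotypes[match(shared, phenotypes$fish_id), , drop = FALSE]
  if (is.null(endpoints)) {
    num <- vapply(ph, is.numeric, logical(1))
    endpoints <- setdiff(names(ph)[num], c("fish_id", "sample"))
  }
  const <- apply(gmat[, shared, drop = FALSE], 1,
                 function(r) stats::sd(r, na.rm = TRUE) == 0 ||
                   all(is.na(r)))
  if (any(const))
    warn2("excluding %d constant gene row(s): %s", sum(const),
          paste(utils::head(rownames(gmat)[const], 3), collapse = ", "))
  genes <- rownames(gmat)[!const]
  res <- list()
  for (g in genes) {
    for (ep in endpoints) {
      r <- spearman_cor(gmat[g, shared], ph[[ep]])
      res[[length(res) + 1L]] <-
        data.frame(gene = g, endpoint = ep, rho = r$rho, p = r$p, n = r$n,
                   significant = r$p <= alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Power to detect a fold change with a normal test
#'
#' Effect size d = log2(fold_change) / sigma. Two-sided power is
#' pnorm(d sqrt(n) - z_{1-alpha/2}) + pnorm(-d sqrt(n) - z_{1-alpha/2});
#' the one-sided version drops the second term and uses z_{1-alpha}.
#' At fold_change = 1 the two-sided power equals alpha exactly.
#'
#' @param fold_change Linear fold change to detect (> 0).
#' @param sigma Per-measurement SD of the log2 ratio (> 0). See
#'   [calibrate_power_sigma()] for fixing sigma from a known operating
#'   point.
#' @param n Number of biological replicates (>= 1).
#' @param alpha Significance level in (0, 1).
#' @param two_sided Two-sided test (default) or one-sided.
#' @return Power in `[0, 1]`.
#' @export
power_fold_change <- function(fold_change, sigma, n, alpha = 0.05,
                              two_sided = TRUE) {
  if (any(fold_change <= 0)) stop2("fold_change must be positive")
  if (sigma <= 0) stop2("sigma must be positive")
  if (n < 1) stop2("n must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop2("alpha must lie in (0, 1)")
  d <- log2(fold_change) / sigma
  if (two_sided) {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(d * sqrt(n) - z) + stats::pnorm(-d * sqrt(n) - z)
  } else {
    z <- stats::qnorm(1 - alpha)
    stats::pnorm(d * sqrt(n) - z)
  }
}

#' Calibrate the log2-ratio SD from a known power operating point
#'
#' Solves for the sigma at which detecting `fold_change` with `n`
#' replicates at level `alpha` has exactly the given power — e.g. a
#' platform on which a 1.5-fold change at n = 3 has power 0.70 implies
#' sigma of about 0.41 log2 units.
#'
#' @param fold_change,n,alpha,two_sided As in [power_fold_change()].
#' @param power Target power in (alpha, 1).
#' @return sigma, log2 units.
#' @export
calibrate_power_sigma <- function(fold_change, n, power, alpha = 0.05,
                                  two_sided = TRUE) {
  if (power <= alpha || power >= 1)
    stop2("power must lie in (alpha, 1)")
  stats::uniroot(function(s)
    power_fold_change(fold_change, s, n, alpha, two_sided) - power,
    interval = c(1e-6, 1e3), tol = 1e-12)$root
}

#' Smallest replicate number reaching a target power
#'
#' Incremental search over n; errors if the target is unreachable within
#' n <= 1e6 (e.g. fold_change = 1, where power is capped at alpha).
#'
#' @param fold_change,sigma,alpha,two_sided As in [power_fold_change()].
#' @param target_power Required power in (alpha, 1).
#' @return Smallest integer n with power >= target_power.
#' @export
min_replicates <- function(fold_change, sigma, target_power,
                           alpha = 0.05, two_sided = TRUE) {
  if (target_power <= alpha || target_power >= 1)
    stop2("target_power must lie in (alpha, 1)")
  n <- 1L
  while (n <= 1e6) {
    if (power_fold_change(fold_change, sigma, n, alpha, two_sided) >=
        target_power)
      return(n)
    n <- n + 1L
  }
  stop2("target power %.3f unreachable within n <= 1e6 (fold_change %.3g)",
        target_power, fold_change)
}

#' qPCR relative quantification (2^dCT) and fold changes vs reference fish
#'
#' Per sample, dCT is the difference between the mean triplicate cycle
#' threshold of the reference transcript (e.g. GAPDH) and that of the
#' target, so higher target expression gives a larger relative quantity
#' 2^dCT. Each sample's fold change is the mean log2 ratio of its relative
#' quantity against each reference fish, reported on the log2 scale.
#'
#' @param records data.frame with columns `sample`, `gene`, `ct1`, `ct2`,
#'   `ct3` (one row per sample per gene).
#' @param target_gene Target transcript name.
#' @param reference_gene Normalizer transcript name (default "GAPDH").
#' @param reference_fish Character vector (>= 1) of sample ids serving as
#'   the reference fish.
#' @return data.frame `sample`, `dct`, `relative_quantity`, `log2_fold`,
#'   `flagged` (incomplete triplicates are flagged and excluded from fold
#'   changes).
#' @export
qpcr_relative <- function(records, target_gene, reference_gene = "GAPDH",
                          reference_fish) {
  need <- c("sample", "gene", "ct1", "ct2", "ct3")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop2("records lack column(s): %s",
                          paste(miss, collapse = ", "))
  cts <- as.matrix(records[, c("ct1", "ct2", "ct3")])
  if (any(cts[!is.na(cts)] <= 0)) stop2("cycle values must be positive")
  samples <- unique(records$sample)
  get_mean <- function(s, g) {
    row <- which(records$sample == s & records$gene == g)
    if (length(row) != 1) return(NA_real_)
    v <- cts[row, ]
    if (anyNA(v)) return(NA_real_)   # incomplete triplicate
    mean(v)
  }
  dct <- vapply(samples, function(s)
    get_mean(s, reference_gene) - get_mean(s, target_gene), numeric(1))
  rq <- 2^dct
  flagged <- is.na(dct)
  if (!all(reference_fish %in% samples))
    stop2("reference fish absent from records: %s",
          paste(setdiff(reference_fish, samples), collapse = ", "))
  ref_rq <- rq[match(reference_fish, samples)]
  if (anyNA(ref_rq))
    stop2("reference fish with incomplete triplicates: %s",
          paste(reference_fish[is.na(ref_rq)], collapse = ", "))
  log2_fold <- vapply(seq_along(samples), function(i) {
    if (flagged[i]) return(NA_real_)
    mean(log2(rq[i]) - log2(ref_rq))
  }, numeric(1))
  data.frame(sample = samples, dct = as.numeric(dct),
             relative_quantity = as.numeric(rq),
             log2_fold = log2_fold, flagged = flagged,
             stringsAsFactors = FALSE)
}
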