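## Platform-comparison metrics, box-plot summaries, and spatial
## hybridization artifact detection.

#' Per-probe replicate dispersion
#'
#' Mean and sample SD of the replicate spots of each probe, for assessing
#' whether probe variance depends on signal strength (on a well-behaved
#' platform it does not).
#'
#' @param features Feature table with `probe_id`, `log2_signal`, `flag`.
#' @return data.frame `probe_id`, `mean`, `sd`, `n`; probes with fewer
#'   than 2 unflagged spots are excluded and listed in attribute
#'   `excluded`.
#' @export
replicate_dispersion <- function(features) {
  ok <- features$flag == "ok"
  n_all <- table(features$probe_id)
  x <- features[ok, ]
  n <- tapply(x$log2_signal, x$probe_id, length)
  keep <- names(n)[n >= 2]
  excluded <- setdiff(names(n_all), keep)
  x <- x[x$probe_id %in% keep, ]
  res <- data.frame(
    probe_id = keep,
    mean = as.numeric(tapply(x$log2_signal, factor(x$probe_id, keep), mean)),
    sd = as.numeric(tapply(x$log2_signal, factor(x$probe_id, keep),
                           stats::sd)),
    n = as.integer(n[keep]),
    stringsAsFactors = FALSE)
  res <- res[order(res$probe_id), ]
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  res
}

#' Cross-platform signal concordance
#'
#' Joins per-probe median signals measured on two platforms, reports their
#' Spearman rank correlation, and the fraction of probes whose +/- 1 SD
#' crosshair box (replicate SD on each axis) intersects the monotone
#' (isotonic) fit of platform B on platform A.
#'
#' @param medians_a,medians_b Named numeric vectors of per-probe signals.
#' @param sd_a,sd_b Named numeric vectors of per-probe replicate SDs.
#' @return List: `table` (joined per-probe data), `rho` (Spearman),
#'   `crosshair_fraction`.
#' @export
platform_concordance <- function(medians_a, medians_b, sd_a = NULL,
                                 sd_b = NULL) {
  shared <- intersect(names(medians_a), names(medians_b))
  if (length(shared) < 10)
    stop2("only %d shared probes; need at least 10", length(shared))
  a <- medians_a[shared]; b <- medians_b[shared]
  rho <- spearman_cor(a, b)$rho
  o <- order(a)
  iso <- stats::isoreg(a[o], b[o])
  fit_at <- function(x) stats::approx(a[o], iso$yf, xout = x, rule = 2)$y
  if (is.null(sd_a)) sd_a <- stats::setNames(rep(0, length(shared)), shared)
  if (is.null(sd_b)) sd_b <- stats::setNames(rep(0, length(shared)), shared)
  lo <- fit_at(a - sd_a[shared]); hi <- fit_at(a + sd_a[shared])
  inter <- pmin(lo, hi) <= b + sd_b[shared] &
           pmax(lo, hi) >= b - sd_b[shared]
  list(table = data.frame(probe_id = shared, a = as.numeric(a),
                          b = as.numeric(b), sd_a = as.numeric(sd_a[shared]),
                          sd_b = as.numeric(sd_b[shared]),
                          stringsAsFactors = FALSE),
       rho = rho, crosshair_fraction = mean(inter))
}

#' Sign-agreement quadrant analysis of two platforms' log2 ratios
#'
#' Among probes exceeding the fold-change threshold on both platforms,
#' counts sign-concordant (quadrants I/III) and sign-discordant (II/IV)
#' probes.
#'
#' @param ratios_a,ratios_b Named numeric vectors of log2 ratios.
#' @param threshold Absolute log2 ratio both platforms must exceed.
#' @return List with `concordant`, `discordant`, `n_considered`, `table`.
#' @export
quadrant_analysis <- function(ratios_a, ratios_b, threshold = 1) {
  shared <- intersect(names(ratios_a), names(ratios_b))
  a <- ratios_a[shared]; b <- ratios_b[shared]
  sel <- abs(a) >= threshold & abs(b) >= threshold
  conc <- sum(sel & sign(a) == sign(b))
  disc <- sum(sel & sign(a) != sign(b))
  list(concordant = conc, discordant = disc, n_considered = sum(sel),
       table = data.frame(probe_id = shared, a = as.numeric(a),
                          b = as.numeric(b), considered = as.logical(sel),
                          stringsAsFactors = FALSE))
}

#' Intensity distribution summary
#'
#' Histogram of spot log2 intensities with sample skewness and the share
#' of total linear-scale signal carried by spots above the 90th intensity
#' percentile (a long right tail concentrates signal there).
#'
#' @param features Feature table (>= 100 spots) or numeric vector.
#' @param breaks Histogram break specification (passed to [hist()]).
#' @return List: `histogram`, `skewness`, `tail_mass`.
#' @export
intensity_distribution <- function(features, breaks = 50) {
  x <- if (is.data.frame(features)) features$log2_signal else features
  if (length(x) < 100) stop2("need >= 100 spots, got %d", length(x))
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / s2^1.5
  q90 <- stats::quantile(x, 0.9, names = FALSE)
  lin <- 2^x
  list(histogram = h, skewness = skew,
       tail_mass = sum(lin[x > q90]) / sum(lin))
}

#' Detect a linear spatial hybridization artifact
#'
#' Selects the spots in the negative tail of the M distribution, computes
#' the principal axes of their (row, col) coordinates, and flags an
#' artifact when the tail is both populous and collinear: collinearity is
#' 1 - lambda2/lambda1 of the coordinate covariance eigenvalues, so points
#' concentrated along a line score near 1 and scattered points near 0.
#'
#' @param features Feature table carrying an `M` column (log2 ratio versus
#'   a reference) plus `row`, `col`, `probe_id`.
#' @param tail_threshold Spots with `M` below this enter the tail
#'   (default -1.5).
#' @param min_tail Minimum tail size to flag (default 20).
#' @param collinearity_cutoff Minimum collinearity to flag (default 0.95).
#' @return List of class `artifact_report`: `tail_threshold`, `n_tail`,
#'   `center`, `direction` (unit vector in (row, col) space),
#'   `angle_deg` (vs the column axis, i.e. 0 means "along a row"),
#'   `collinearity`, `flagged`, `probe_ids`, `spots`.
#' @export
detect_spatial_artifact <- function(features, tail_threshold = -1.5,
                                    min_tail = 20L,
                                    collinearity_cutoff = 0.95) {
  if (!"M" %in% names(features))
    stop2("features must carry an M column (log2 ratio vs reference)")
  tail <- features[!is.na(features$M) & features$M < tail_threshold, ,
                   drop = FALSE]
  n_tail <- nrow(tail)
  if (n_tail < 2) {
    return(structure(list(tail_threshold = tail_threshold, n_tail = n_tail,
                          center = c(NA_real_, NA_real_),
                          direction = c(NA_real_, NA_real_),
                          angle_deg = NA_real_, collinearity = NA_real_,
                          flagged = FALSE,
                          probe_ids = unique(tail$probe_id), spots = tail),
                     class = "artifact_report"))
  }
  xy <- cbind(tail$row, tail$col)
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  ev <- eigen(cv, symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  collin <- if (lambda[1] == 0) 0 else 1 - lambda[2] / lambda[1]
  dir <- ev$vectors[, 1]
  ## angle vs the column axis: 0 deg = constant row (line along a row)
  angle <- atan2(abs(dir[1]), abs(dir[2])) * 180 / pi
  flagged <- n_tail >= min_tail && collin >= collinearity_cutoff
  structure(list(tail_threshold = tail_threshold, n_tail = n_tail,
                 center = ctr, direction = dir, angle_deg = angle,
                 collinearity = collin, flagged = flagged,
                 probe_ids = unique(tail$probe_id), spots = tail),
            class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("artifact_report: %d tail spots (M < %.2f), collinearity %.3f, %s\n",
              x$n_tail, x$tail_threshold,
              ifelse(is.na(x$collinearity), NA, x$collinearity),
              if (x$flagged) "FLAGGED" else "not flagged"))
  invisible(x)
}

#' Propagate an artifact exclusion into a feature table
#'
#' Marks the offending spots `suppressed` rather than deleting them, so
#' downstream summaries can skip them while the record of the exclusion
#' is preserved.
#'
#' @param features Feature table.
#' @param report An `artifact_report`.
#' @return The feature table with flags updated.
#' @export
apply_artifact_exclusion <- function(features, report) {
  if (!report$flagged) return(features)
  key <- paste(features$row, features$col)
  bad <- key %in% paste(report$spots$row, report$spots$col)
  features$flag[bad] <- "suppressed"
  features
}

#' Five-number summary with Tukey whiskers
#'
#' Quartiles by linear interpolation (type 7); whiskers extend to the most
#' extreme observations within 1.5 IQR of the quartiles; points beyond are
#' outliers.
#'
#' @param values Numeric vector, length >= 5.
#' @return List: `min`, `q1`, `median`, `q3`, `max`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5) stop2("need >= 5 values, got %d", length(values))
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(min = min(values), q1 = q[1], median = q[2], q3 = q[3],
       max = max(values),
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}
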