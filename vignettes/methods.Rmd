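---
title: "Methods: cross-species microarray analysis and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species microarray analysis and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msarray)
```

`msarray` implements the analysis pathway of a cross-species 60-mer
microarray used to monitor endocrine disruption in an unsequenced flatfish,
together with a ground-truth simulator that makes every stage testable.
This vignette explains the models, the defaults and their units, the
numerical choices, and the limits of what the synthetic data can show.

## Probe design from conserved windows

For a gene with homologs in several sequenced fish, candidate probes are
60-column gap-free windows of the multiple alignment. A window's
conservation score is the **minimum** pairwise identity over all species
pairs within the window — a deliberately conservative aggregation (the
mean would let one divergent species hide behind the others). Windows are
emitted once per source row, sorted by score, ties broken by start
position and species so output order is deterministic.

Two identity thresholds matter:

* `min_interspecies_identity` (default **0.80**) gates which windows may
  become probes. The platform's design language ("80% and 90% identity")
  is ambiguous between a range, two alternatives, and pair-specific
  thresholds; we implement a single lower bound with 0.90 available as a
  strict preset, and record rejected genes rather than dropping them.
* Cross-species screening passes a probe when its best **ungapped**
  sliding-offset identity against a homolog reaches **0.85** (51/60
  bases — the classic hybridization tolerance for a 60-mer). Ungapped
  scanning rather than local alignment is intentional: probe/target
  hybridization is positional, and it keeps an exact brute-force oracle
  feasible, which the test suite exercises.

Ambiguity codes (`N` etc.) are rejected at ingest and sequences
uppercased; the tested contract is simpler than one that silently guesses.

## The synthetic study

The generator emulates the monitoring design itself, not an abstract
array. Defaults are the study conditions:

| Quantity | Default | Why |
|---|---|---|
| unique probes | 326 | platform content |
| replicate locations/probe | 46 | platform content |
| print grid | 100 x 150 | 15,000 cells >= 14,996 spots; physical pitch is unknown, the grid is the smallest round layout that fits |
| wild fish | LA 3, PV 2, OC 7, DP 7, SD 3 (22) | field roster |
| control fish | 3, pooled into the reference | pooled-reference design |
| spot noise SD | 0.3 log2 | second-generation platform quality |
| between-fish SD | 0.4 log2 (controls 0.1) | wild populations are heterogeneous; lab-acclimated controls much less so |
| species affinity SD | 0.25 log2 | imperfect cross-species hybridization |

Spot log2 intensity is additive:
`mu_p + a(p, s) + x(f, g) + bias(A) + eps`, with probe baselines `mu_p`
drawn from a right-skewed mixture (85% N(7, 0.7), 15% N(10, 1)) so the
intensity distribution has the long right tail real arrays show, species
affinities `a` fixed per probe, fish effects `x(f, g)` drawn once per
fish and gene from `Normal(mean_log2fc, between_fish_sd)` of that fish's
site, and `eps` independent spot noise. `bias` is an optional smooth
function of intensity used to exercise normalization.

The truth table assigns the 21 endocrine-responsive genes of the
diagnostic signature signed effects matching the field observations
(vitellogenins, *ZP3*, *CYP1A* and heat-shock proteins induced; *ERb*,
*CYP3A*, hepcidin, *GSTa*, *MT*, *PPARa/g* and several receptors
repressed), with magnitudes in {1, 2, 3} log2 units so the +/- 8-fold
clipping and the 4-fold DE threshold paths are both exercised, scaled per
site by {0.75, 1, 1.25} to emulate unequal exposure. All other genes, and
every gene at the control site, have mean zero.

Genes are unevenly represented across species (the 21 signal genes carry
100 probes in total, between 3 and 5 source species each; 44 null
multi-species genes carry 5 each; 6 housekeeping genes one each). This
matters downstream: probes of one gene share the same fish effects, so
their sum-squared scores travel together, and gene representation — not a
per-probe coin flip — determines what a top-k probe cut can return.

What the simulator does **not** model: dye chemistry, scanner saturation,
background subtraction, amplification efficiency, and any within-gene
probe response differences (all probes of a gene respond with slope 1).
Passing tests therefore show the analysis chain is correct under the
stated model; they do not certify performance on hybridization chemistry
the model omits.

### Phenotype coupling

Phenotype endpoints are generated by a Gaussian copula: the endpoint's
latent normal score correlates with the normal score of one gene's
expression at Pearson level `2 sin(pi rho_s / 6)`, the exact
Spearman-to-Pearson conversion for bivariate normal ranks, so observed
Spearman correlations converge to the requested target as the number of
fish grows (the suite checks +/- 0.1 at n = 500). Marginals are
log-normal, scaled per endpoint to the ranges of the packaged wild-fish
table; they are continuous (no age rounding) because ties would attenuate
the copula's rank correlation.

## Normalization

The reference is pooled on the **linear** intensity scale — the log2 of
the mean of linear intensities — mirroring physical cRNA pooling (the mean
of logs would be the geometric mean, a different experiment). MA
coordinates are `M = sample - reference`, `A = (sample + reference)/2`,
exactly invertible.

`multiloess_normalize()` removes smooth intensity-dependent bias from all
samples *simultaneously*: iterate (1) consensus = per-feature mean across
samples, (2) per sample, fit a local-linear tricube smoother (span 0.3,
robust `family = "symmetric"`) of sample-minus-consensus against the
consensus and subtract it. Two numerical choices stabilize the iteration:

* corrections are **centered across samples** at each feature, so the
  consensus is invariant. Only between-sample bias is identifiable
  without an external standard, and without centering the iteration
  slowly diverges (local-linear smoothers have boundary eigenvalues
  slightly outside [0, 1]);
* predictions are **clamped** beyond the 1st/99th percentile of the
  consensus, where extrapolation chases single points.

Convergence is declared when the largest absolute correction falls below
`tol`. The attainable tolerance is bounded below by the smoother's noise
floor — roughly the local-fit standard error, about 4e-3 at 2,000
features and span 0.3 — so a `tol` below that ends at `max_iter` with
`converged = FALSE`, reported rather than thrown. At `tol = 0.01` (1% in
intensity, well below any biological effect of interest) the procedure
converges in a few iterations and is idempotent: rerunning changes no
value by more than `tol`. The test suite checks bias removal to
|per-A-decile median M| < 0.05 and idempotence at that tolerance.

## Artifact detection

A hybridization defect shows up as a heavy negative tail in a self-vs-pool
MA plot whose spots, plotted by (row, col), concentrate along a line.
`detect_spatial_artifact()` makes that visual judgment reproducible:
select spots with `M < -1.5`, compute the principal axes of their
coordinates, and define **collinearity = 1 - lambda2/lambda1** of the
coordinate covariance eigenvalues (a total-least-squares line fit): points
on a line score near 1, scattered points near 0. An artifact is flagged
when the tail has at least `min_tail = 20` spots **and** collinearity
reaches 0.95. Both cutoffs are exposed; the defaults give >= 95%
sensitivity to full-row -2 log2 shifts and <= 5% false flags on
artifact-free arrays in the suite's 200-run checks. Flagged spots are
marked `suppressed`, never deleted — downstream medians skip them while
the exclusion record survives. An alternative policy (discarding all 46
replicates of any affected probe) would also be defensible; we suppress
only the affected spots because the replicate median is already robust to
the survivors.

## Ranking and consolidation

Probe-level values are medians of the 46 replicate log2 ratios (robust to
a corrupted spot: one +10 outlier among 46 Gaussian replicates moves the
median by < 0.1). Gene values are arithmetic means over all of a gene's
probes — all species, all regions. Genes are ranked by the sum-squared
statistic, the sum of squared log2 ratios across all fish: a transcript
altered in a single fish at one site still ranks, which is the point of a
multi-site field screen. Missing entries contribute zero (absent evidence
is not evidence of change), and ties break lexicographically so output is
deterministic. The top 100 probes are consolidated into per-gene strips in
first-appearance order. Heat-map matrices clip to +/- 3 log2 units
(8-fold) and order rows by Ward clustering (`ward.D2` on Euclidean
distance of the clipped rows; the metric is a display choice — clustering
consolidates visually similar genes and is not an inference step).

The DE threshold is `|M| > 2`, i.e. 4-fold, taken literally from the
platform's stated rule and exposed as `tau`; a 2-fold reading (`tau = 1`)
is one parameter away.

## Power and qPCR

The power model is a two-sided normal test on the mean log2 ratio:
`d = log2(FC)/sigma`, `power = Phi(d sqrt(n) - z_{1-a/2}) +
Phi(-d sqrt(n) - z_{1-a/2})`. The per-measurement SD sigma is not a
platform constant anyone states; it is *calibrated* from an operating
point with `calibrate_power_sigma()`. The two published operating points
are mutually consistent under this model: fixing "1.5-fold at n = 3 has
power 0.70" gives sigma = 0.408 log2 units, under which a 2-fold change
has power 0.99 — and calibrating from the 2-fold point recovers 0.70 for
1.5-fold. The suite verifies both directions plus a 50,000-replicate
Monte Carlo agreement within 3 standard errors.

Spearman p-values use the t approximation with n - 2 degrees of freedom
for n > 9 and full enumeration over all n! rank permutations for n <= 9
(9! = 362,880 is enumerable; both nulls are available via the `exact`
argument since the field tables were computed with unspecified software).
Constant vectors are an error for a single correlation but only a warning
(with exclusion) in the screening path, where one flat gene should not
abort a 160-pair scan.

qPCR relative quantities follow `2^dCT` with
`dCT = mean Ct(reference transcript) - mean Ct(target)` over triplicates —
the sign convention chosen so higher target expression gives a larger
quantity. Fold changes are mean log2 ratios against each reference fish,
reported on the log2 scale. The construction is invariant to any global
Ct shift, and incomplete triplicates are flagged and excluded rather than
imputed.

## Problem sizes used by the test suite

The oracle-equivalence and property tests run at the platform's native
sizes (326 probes x 46 replicates x 22 fish); the repeated-run checks use
200 artifact simulations, 100 end-to-end recovery runs, 200 null
phenotype screens and a 50,000-replicate power Monte Carlo — sizes at
which the binomial uncertainty of each estimated rate is comfortably
below the margin being asserted.

## Known limitations

* The multiple-loess variant here (consensus iteration, local-linear
  tricube, span 0.3) is one member of a family; the procedure it emulates
  is cited only by reference in the platform literature, so equivalence
  to any specific prior implementation is not claimed.
* The artifact detector is tuned for *linear* defects; a blob-shaped
  defect with low collinearity will not flag (by design — the decision
  rule encodes the line geometry).
* Cross-species probes respond with unit slope in the simulator; real
  cross-species hybridization attenuates fold changes, so real-data
  recovery will be conservative relative to the simulated benchmark.
* No multiple-testing correction is applied in the phenotype screen (the
  field analysis reports raw p-values); users screening many genes should
  apply `p.adjust` to the returned column as appropriate.
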