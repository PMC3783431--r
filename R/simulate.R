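## Synthetic single-color array data with known ground truth.
##
## The generator emulates the monitoring study design: a 60-mer platform
## with 326 unique probes each printed at 46 spatial locations, genes
## represented by probes from several fish species, 22 wild fish from five
## coastal sites plus three laboratory control fish whose hybridizations
## are pooled into the reference, and an optional hybridization artifact
## concentrated along a line on the grid.

IMPACTED_SITES <- c("LA", "PV", "OC", "DP", "SD")
CONTROL_SITE <- "REF"

## The 21 endocrine-responsive genes of the diagnostic heat map, with the
## qualitative direction of their response at impacted sites (+ induced,
## - repressed), a per-gene effect magnitude in {1, 2, 3} log2 units so
## that clipping and threshold paths are all exercised, and the number of
## source-species probes representing each gene on the array (genes are
## unevenly represented across species; the 21 genes together carry 100
## probes).
SIGNAL_GENES <- data.frame(
  gene_id = c("Vtg1", "Vtg2", "CYP1A", "ZP3", "ZP2", "HSP70",
              "ERb", "CYP3A", "HEPC1", "GSTa", "MT", "PPARa", "PPARg",
              "TRa", "AR", "RXR", "SHBG", "HSP90A", "HSP90B", "ERa",
              "IGFBP1"),
  direction = c(+1, +1, +1, +1, +1, +1,
                -1, -1, -1, -1, -1, -1, -1,
                -1, -1, -1, -1, +1, +1, -1,
                -1),
  magnitude = c(3, 3, 2, 2, 1, 1,
                2, 2, 3, 1, 1, 2, 2,
                1, 1, 2, 1, 1, 1, 2,
                2),
  n_species = c(5, 5, 5, 5, 5, 5,
                4, 5, 5, 5, 5, 5, 5,
                4, 5, 5, 4, 5, 5, 3,
                5),
  stringsAsFactors = FALSE
)

## per-site scaling of the common effect (wild sites differ in exposure)
SITE_SCALE <- c(LA = 1.25, PV = 1.0, OC = 0.75, DP = 1.0, SD = 0.75)

#' Platform specification
#'
#' Describes one emulated array platform. The default is the second
#' generation ink-jet platform: 60-mer probes, each replicated at 46
#' distinct spatial locations, with low spot noise. `prototype = TRUE`
#' gives the earlier spotted platform (65-mers, 4 replicates, noisier,
#' higher overall signal).
#'
#' @param name Platform label.
#' @param probe_length Probe length in nucleotides.
#' @param replicates_per_probe Spatial replicate spots per probe.
#' @param noise_sd Spot-level noise SD, log2 units.
#' @param baseline_offset Additive log2 offset on all spots.
#' @param prototype Convenience switch for the spotted prototype.
#' @return A `platform_spec` list.
#' @export
platform_spec <- function(name = "inkjet60", probe_length = 60L,
                          replicates_per_probe = 46L, noise_sd = 0.3,
                          baseline_offset = 0, prototype = FALSE) {
  if (prototype) {
    name <- "spotted65"; probe_length <- 65L
    replicates_per_probe <- 4L; noise_sd <- 0.8; baseline_offset <- 1.5
  }
  if (replicates_per_probe < 1L) stop2("replicates_per_probe must be >= 1")
  if (probe_length <= 0L) stop2("probe_length must be positive")
  if (noise_sd < 0) stop2("noise_sd must be non-negative")
  structure(list(name = name, probe_length = as.integer(probe_length),
                 replicates_per_probe = as.integer(replicates_per_probe),
                 noise_sd = noise_sd, baseline_offset = baseline_offset),
            class = "platform_spec")
}

#' Simulation configuration
#'
#' Defaults reproduce the study layout: 65 multi-species genes (the 21
#' endocrine-responsive genes carry 100 probes via their uneven species
#' representation; 44 null genes carry 5 species probes each) plus 6
#' single-probe housekeeping genes, 326 probes in total; a 100 x 150
#' print grid, 3 laboratory control fish, and the published per-site
#' roster (LA 3, PV 2, OC 7, DP 7, SD 3 = 22 wild fish).
#'
#' @param n_genes Number of multi-species genes.
#' @param species_per_gene Probes (source species) per multi-species gene.
#' @param n_housekeeping Single-probe housekeeping genes appended.
#' @param n_control_fish Laboratory control fish pooled into the reference.
#' @param fish_per_site Named integer vector, wild fish per site.
#' @param grid_rows,grid_cols Print grid dimensions.
#' @param between_fish_sd Between-fish spread of gene effects at impacted
#'   sites, log2 units.
#' @param control_sd Between-fish spread for control fish (laboratory
#'   acclimated, hence small).
#' @param seed Integer seed; fixed seed gives byte-identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 65L, species_per_gene = 5L,
                       n_housekeeping = 6L, n_control_fish = 3L,
                       fish_per_site = c(LA = 3L, PV = 2L, OC = 7L,
                                         DP = 7L, SD = 3L),
                       grid_rows = 100L, grid_cols = 150L,
                       between_fish_sd = 0.4, control_sd = 0.1,
                       seed = 1L) {
  cfg <- structure(list(n_genes = as.integer(n_genes),
                        species_per_gene = as.integer(species_per_gene),
                        n_housekeeping = as.integer(n_housekeeping),
                        n_control_fish = as.integer(n_control_fish),
                        fish_per_site = fish_per_site,
                        grid_rows = as.integer(grid_rows),
                        grid_cols = as.integer(grid_cols),
                        between_fish_sd = between_fish_sd,
                        control_sd = control_sd,
                        seed = as.integer(seed)),
                   class = "sim_config")
  if (cfg$between_fish_sd < 0 || cfg$control_sd < 0)
    stop2("spread parameters must be non-negative")
  cfg
}

#' Signal model for spot intensities
#'
#' Spot log2 intensity is mu_p + a(p,s) + x(f,g) + bias(A) + eps, where
#' mu_p is the probe baseline, a the probe/species hybridization affinity,
#' x the fish-by-gene expression effect, bias a smooth intensity-dependent
#' distortion, and eps spot noise. With all effects and noise at zero every
#' spot equals its probe baseline.
#'
#' @param affinity_sd SD of the probe/species affinity, log2 units.
#' @param intensity_bias Function of the baseline intensity added to each
#'   spot (`NULL` for none); used to emulate intensity-dependent dye/
#'   labeling bias.
#' @param noise_sd Spot noise SD override; `NULL` takes the platform value.
#' @return A `signal_model` list.
#' @export
signal_model <- function(affinity_sd = 0.25, intensity_bias = NULL,
                         noise_sd = NULL) {
  if (affinity_sd < 0) stop2("affinity_sd must be non-negative")
  if (!is.null(noise_sd) && noise_sd < 0) stop2("noise_sd must be non-negative")
  if (!is.null(intensity_bias) && !is.function(intensity_bias))
    stop2("intensity_bias must be a function or NULL")
  structure(list(affinity_sd = affinity_sd, intensity_bias = intensity_bias,
                 noise_sd = noise_sd), class = "signal_model")
}

#' Ground-truth per-site expression effects
#'
#' Builds the truth table the generator samples from: for each gene and
#' site, the mean log2 fold change relative to laboratory controls and the
#' between-fish spread. The 21 named endocrine-responsive genes carry
#' signed effects matching the field observations (Vtg1/Vtg2/CYP1A/ZP3 and
#' the heat-shock proteins induced; ERb, CYP3A, HEPC1, GSTa, MT, PPARa/g
#' and other receptors repressed); all other genes, and every gene at the
#' control site, have mean zero.
#'
#' @param config A [sim_config()].
#' @param min_abs_effect Optional floor on the absolute effect of the named
#'   signal genes at impacted sites (e.g. 2 to plant only strong signals);
#'   `NULL` keeps the default {1,2,3} magnitudes.
#' @return data.frame `gene_id`, `site_id`, `mean_log2fc`,
#'   `between_fish_sd`; attribute `signal_genes` lists the perturbed genes.
#' @export
build_default_truth <- function(config = sim_config(),
                                min_abs_effect = NULL) {
  genes <- gene_roster(config)
  sites <- c(IMPACTED_SITES, CONTROL_SITE)
  truth <- expand.grid(gene_id = genes$gene_id, site_id = sites,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$mean_log2fc <- 0
  truth$between_fish_sd <- ifelse(truth$site_id == CONTROL_SITE,
                                  config$control_sd, config$between_fish_sd)
  idx <- match(truth$gene_id, SIGNAL_GENES$gene_id)
  hit <- !is.na(idx) & truth$site_id != CONTROL_SITE
  mag <- SIGNAL_GENES$magnitude[idx[hit]]
  if (!is.null(min_abs_effect)) mag <- pmax(mag, min_abs_effect)
  truth$mean_log2fc[hit] <- SIGNAL_GENES$direction[idx[hit]] * mag *
    SITE_SCALE[truth$site_id[hit]]
  attr(truth, "signal_genes") <- intersect(genes$gene_id,
                                           SIGNAL_GENES$gene_id)
  truth
}

## gene/species roster implied by a config: signal genes first (with their
## catalog species representation, capped at species_per_gene), then null
## multi-species genes, then housekeeping singletons
gene_roster <- function(config) {
  n_ms <- config$n_genes
  n_named <- min(nrow(SIGNAL_GENES), n_ms)
  named <- SIGNAL_GENES$gene_id[seq_len(n_named)]
  named_k <- pmin(SIGNAL_GENES$n_species[seq_len(n_named)],
                  config$species_per_gene)
  n_null <- n_ms - n_named
  nulls <- if (n_null > 0) sprintf("gene%03d", seq_len(n_null)) else character()
  hk <- if (config$n_housekeeping > 0)
    sprintf("HK%02d", seq_len(config$n_housekeeping)) else character()
  data.frame(
    gene_id = c(named, nulls, hk),
    n_species = c(named_k, rep(config$species_per_gene, n_null),
                  rep(1L, config$n_housekeeping)),
    stringsAsFactors = FALSE)
}

#' Generate an array design
#'
#' Lays out the probe set on the print grid: each probe receives
#' `replicates_per_probe` distinct (row, col) locations drawn from a seeded
#' permutation of the grid; no location is reused. The default
#' configuration yields exactly 326 unique probes, each at 46 locations.
#'
#' @param config A [sim_config()].
#' @param platform A [platform_spec()].
#' @return data.frame `probe_id`, `gene_id`, `species`, `row`, `col`
#'   (0-based grid coordinates), one record per spot.
#' @export
generate_design <- function(config = sim_config(),
                            platform = platform_spec()) {
  roster <- gene_roster(config)
  probes <- data.frame(
    gene_id = rep(roster$gene_id, roster$n_species),
    species = unlist(lapply(roster$n_species, function(k)
      sprintf("sp%d", seq_len(k)))),
    stringsAsFactors = FALSE)
  probes$probe_id <- sprintf("%s_%s", probes$gene_id, probes$species)
  n_spots <- nrow(probes) * platform$replicates_per_probe
  n_cells <- config$grid_rows * config$grid_cols
  if (n_cells < n_spots)
    stop2("grid %dx%d has %d cells; %d spots requested",
          config$grid_rows, config$grid_cols, n_cells, n_spots)
  loc <- with_seed(config$seed, sample.int(n_cells, n_spots))
  design <- probes[rep(seq_len(nrow(probes)),
                       each = platform$replicates_per_probe), ]
  design$row <- (loc - 1L) %/% config$grid_cols
  design$col <- (loc - 1L) %% config$grid_cols
  rownames(design) <- NULL
  design[, c("probe_id", "gene_id", "species", "row", "col")]
}

#' Simulate single-color hybridizations
#'
#' Produces one feature table per wild fish and per control fish under the
#' additive signal model. Probe baselines are drawn once per design from a
#' right-skewed mixture (most probes weak, a minority strongly expressed,
#' matching the long right tail of real intensity distributions); species
#' affinities once per probe; fish-by-gene effects once per fish and gene
#' from Normal(mean_log2fc, between_fish_sd) of that fish's site.
#'
#' @param design Output of [generate_design()].
#' @param truth Output of [build_default_truth()] (or same schema).
#' @param model A [signal_model()].
#' @param config A [sim_config()].
#' @param platform A [platform_spec()].
#' @return A list with `samples` (named list of feature tables, wild fish),
#'   `controls` (feature tables of control fish), `fish` (roster
#'   data.frame), and `truth_x` (matrix fish x gene of realized effects).
#' @export
simulate_arrays <- function(design, truth, model = signal_model(),
                            config = sim_config(),
                            platform = platform_spec()) {
  genes <- unique(design$gene_id)
  missing_genes <- setdiff(genes, truth$gene_id)
  if (length(missing_genes))
    stop2("genes missing from truth: %s",
          paste(utils::head(missing_genes, 5), collapse = ", "))
  probes <- unique(design[, c("probe_id", "gene_id", "species")])
  noise_sd <- if (is.null(model$noise_sd)) platform$noise_sd else
    model$noise_sd

  fish <- data.frame(
    fish_id = c(unlist(lapply(names(config$fish_per_site), function(s)
      sprintf("%s_%d", s, seq_len(config$fish_per_site[[s]])))),
      sprintf("CTRL_%s", LETTERS[seq_len(config$n_control_fish)])),
    site_id = c(rep(names(config$fish_per_site), config$fish_per_site),
                rep(CONTROL_SITE, config$n_control_fish)),
    stringsAsFactors = FALSE)

  with_seed(config$seed + 1L, {
    mix <- stats::runif(nrow(probes)) < 0.15
    mu <- ifelse(mix, stats::rnorm(nrow(probes), 10, 1.0),
                 stats::rnorm(nrow(probes), 7, 0.7)) +
      platform$baseline_offset
    names(mu) <- probes$probe_id
    affinity <- stats::rnorm(nrow(probes), 0, model$affinity_sd)
    names(affinity) <- probes$probe_id

    ## realized fish-by-gene effects
    key <- paste(truth$gene_id, truth$site_id)
    truth_mean <- truth$mean_log2fc[match(paste(rep(genes, nrow(fish)),
      rep(fish$site_id, each = length(genes))), key)]
    truth_sd <- truth$between_fish_sd[match(paste(rep(genes, nrow(fish)),
      rep(fish$site_id, each = length(genes))), key)]
    x <- matrix(stats::rnorm(length(genes) * nrow(fish),
                             mean = truth_mean, sd = truth_sd),
                nrow = nrow(fish), ncol = length(genes), byrow = TRUE,
                dimnames = list(fish$fish_id, genes))

    base_spot <- mu[design$probe_id] + affinity[design$probe_id]
    if (!is.null(model$intensity_bias))
      bias <- model$intensity_bias(base_spot)
    else
      bias <- 0
    gene_idx <- match(design$gene_id, genes)

    tables <- lapply(seq_len(nrow(fish)), function(f) {
      sig <- base_spot + x[f, gene_idx] + bias +
        stats::rnorm(nrow(design), 0, noise_sd)
      data.frame(row = design$row, col = design$col,
                 probe_id = design$probe_id,
                 log2_signal = as.numeric(sig),
                 flag = "ok", stringsAsFactors = FALSE)
    })
    names(tables) <- fish$fish_id
    is_ctrl <- fish$site_id == CONTROL_SITE
    list(samples = tables[!is_ctrl], controls = tables[is_ctrl],
         fish = fish, truth_x = x)
  })
}

#' Inject a linear spatial artifact
#'
#' Adds `shift` log2 units to every spot whose perpendicular distance to
#' the line through `point` with direction `direction` is at most `width`,
#' emulating a hybridization defect concentrated along a line.
#'
#' @param features A feature table (`row`, `col`, ... `log2_signal`).
#' @param point Numeric length-2 (row, col) on the line.
#' @param direction Numeric length-2 direction vector of the line.
#' @param width Half-width in spot units.
#' @param shift Log2 shift applied inside the band.
#' @return The modified feature table; attribute `n_modified` counts the
#'   affected spots, attribute `modified` gives their indices.
#' @export
inject_spatial_artifact <- function(features, point, direction,
                                    width = 0.5, shift = -2) {
  d <- direction / sqrt(sum(direction^2))
  normal <- c(-d[2], d[1])
  dist <- abs((features$row - point[1]) * normal[1] +
              (features$col - point[2]) * normal[2])
  hit <- dist <= width
  features$log2_signal[hit] <- features$log2_signal[hit] + shift
  attr(features, "n_modified") <- sum(hit)
  attr(features, "modified") <- which(hit)
  features
}

PHENO_ENDPOINTS <- c("VTG", "E2", "Cort", "T4", "T", "IGF_I",
                     "calc_age", "SL")

#' Simulate phenotype endpoints coupled to gene expression
#'
#' Generates the eight plasma/morphometric endpoints per fish by a Gaussian
#' copula: each endpoint's latent normal score is correlated with the
#' normal score of one gene's expression at Pearson level
#' 2*sin(pi*rho_s/6), so that the observed Spearman correlation converges
#' to the requested target as the number of fish grows. Marginals are
#' log-normal, scaled per endpoint to the ranges seen in wild male turbot.
#'
#' @param expression Numeric matrix genes x fish (realized expression
#'   effects, e.g. `truth_x` transposed or a consolidated gene matrix).
#' @param coupling data.frame with columns `endpoint`, `gene`, `rho`
#'   (target Spearman, in `[-1, 1]`); endpoints not listed are independent.
#' @param seed Integer seed.
#' @return data.frame with `fish_id` and the eight endpoint columns.
#' @export
simulate_phenotypes <- function(expression, coupling = NULL, seed = 1L) {
  if (is.null(colnames(expression)))
    stop2("expression matrix needs fish ids as column names")
  if (!is.null(coupling)) {
    if (!all(c("endpoint", "gene", "rho") %in% names(coupling)))
      stop2("coupling needs columns endpoint, gene, rho")
    if (any(abs(coupling$rho) > 1))
      stop2("coupling rho outside [-1, 1]")
    bad <- setdiff(coupling$endpoint, PHENO_ENDPOINTS)
    if (length(bad)) stop2("unknown endpoint: %s", bad[1])
  }
  n <- ncol(expression)
  ## marginal scales chosen to match wild male turbot plasma chemistry
  meanlog <- c(VTG = log(0.07), E2 = log(450), Cort = log(35),
               T4 = log(33), T = log(1.5), IGF_I = log(24),
               calc_age = log(7), SL = log(15))
  sdlog <- c(VTG = 0.8, E2 = 0.7, Cort = 1.0, T4 = 0.45, T = 0.45,
             IGF_I = 0.3, calc_age = 0.15, SL = 0.1)
  with_seed(seed, {
    out <- data.frame(fish_id = colnames(expression),
                      stringsAsFactors = FALSE)
    for (ep in PHENO_ENDPOINTS) {
      row <- if (!is.null(coupling)) match(ep, coupling$endpoint) else NA
      if (!is.na(row) && coupling$rho[row] != 0) {
        g <- coupling$gene[row]
        if (!g %in% rownames(expression))
          stop2("coupled gene '%s' absent from expression matrix", g)
        ## normal scores of the gene's values across fish
        r <- rank(expression[g, ], ties.method = "average")
        z_g <- stats::qnorm(r / (n + 1))
        z_g <- z_g / stats::sd(z_g)
        rho_p <- 2 * sin(pi * coupling$rho[row] / 6)
        z <- rho_p * z_g + sqrt(1 - rho_p^2) * stats::rnorm(n)
      } else {
        z <- stats::rnorm(n)
      }
      out[[ep]] <- exp(meanlog[[ep]] + sdlog[[ep]] * z)
    }
    out
  })
}
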