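## Reproducible multi-stage runs. The exported run_analysis() ties the
## simulation, normalization, QC, ranking and correlation stages into a
## single seeded run with a manifest; inst/cli/msarray-cli.R is a thin
## shell front-end over it.

KNOWN_CONFIG_KEYS <- c(
  "seed", "out_dir", "span", "tau", "tail_threshold", "k", "alpha",
  "min_tail", "collinearity_cutoff", "features_dir", "alignment_files",
  "qpcr_file", "qpcr_target", "qpcr_reference_gene", "qpcr_reference_fish",
  "fold_changes", "sigma", "n_replicates", "min_abs_effect", "verbose")

default_run_config <- function() {
  list(seed = 1L, out_dir = "msarray_run", span = 0.3, tau = 2,
       tail_threshold = -1.5, k = 100L, alpha = 0.05, min_tail = 20L,
       collinearity_cutoff = 0.95, fold_changes = c(1.5, 2),
       sigma = NULL, n_replicates = 3L, min_abs_effect = NULL,
       verbose = FALSE)
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop2("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop2("config must be a list or a YAML file path")
  unknown <- setdiff(names(config), KNOWN_CONFIG_KEYS)
  if (length(unknown))
    stop2("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(default_run_config(), config)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- format_num(df[[j]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out))
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")),
               con, sep = "\n")
  invisible(path)
}

write_manifest <- function(cfg, subcommand, inputs, outputs, out_dir) {
  manifest <- list(
    package = "msarray",
    version = as.character(utils::packageVersion("msarray")),
    subcommand = subcommand,
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("out_dir", "verbose"))],
    input_md5 = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

#' Run an analysis stage end to end
#'
#' Subcommands: `simulate` writes a seeded default design, ground truth
#' and per-fish feature tables; `design-probes` designs a probe set from
#' aligned FASTA files; `rank` and `full` run the analysis chain
#' (simulate, pool the reference, MA-transform, detect and suppress
#' spatial artifacts, summarize probe medians, sum-squared rank, top-k
#' gene consolidation, phenotype correlation); `power` writes a power
#' table; `qpcr` performs 2^dCT relative quantification on a qPCR TSV.
#' Every run writes `manifest.json` recording the package version,
#' parameters, seed, and input digests, so any artifact is reproducible
#' from its manifest alone.
#'
#' @param subcommand One of `"simulate"`, `"design-probes"`,
#'   `"normalize"`, `"qc"`, `"rank"`, `"correlate"`, `"power"`, `"qpcr"`,
#'   `"full"`. `normalize` and `qc` operate on a directory of feature
#'   tables (as written by `simulate`), control arrays identified by the
#'   `CTRL_` prefix.
#' @param config Named list or path to a YAML file; unknown keys are
#'   rejected. Keys include `seed`, `out_dir`, `span`, `tau`,
#'   `tail_threshold`, `k`, `alpha`, `alignment_files`, `qpcr_file`,
#'   `fold_changes`, `sigma`, `n_replicates`.
#' @param ... Individual config overrides (flags win over the file).
#' @return Invisibly, a list of the stage's main results.
#' @export
run_analysis <- function(subcommand = c("simulate", "design-probes",
                                        "normalize", "qc", "rank",
                                        "correlate", "power", "qpcr",
                                        "full"),
                         config = list(), ...) {
  subcommand <- match.arg(subcommand)
  cfg <- read_run_config(config)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), KNOWN_CONFIG_KEYS)
  if (length(unknown))
    stop2("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, overrides)

  ## validate referenced inputs BEFORE creating any output
  inputs <- character()
  if (subcommand == "design-probes") {
    if (is.null(cfg$alignment_files))
      stop2("design-probes requires config key 'alignment_files'")
    missing <- cfg$alignment_files[!file.exists(cfg$alignment_files)]
    if (length(missing)) stop2("input not found: %s", missing[1])
    inputs <- cfg$alignment_files
  }
  if (subcommand == "qpcr") {
    if (is.null(cfg$qpcr_file)) stop2("qpcr requires config key 'qpcr_file'")
    if (!file.exists(cfg$qpcr_file))
      stop2("input not found: %s", cfg$qpcr_file)
    inputs <- cfg$qpcr_file
  }
  if (subcommand %in% c("normalize", "qc")) {
    if (is.null(cfg$features_dir))
      stop2("%s requires config key 'features_dir'", subcommand)
    if (!dir.exists(cfg$features_dir))
      stop2("input not found: %s", cfg$features_dir)
    feature_files <- list.files(cfg$features_dir, pattern = "\\.tsv$",
                                full.names = TRUE)
    if (!length(feature_files))
      stop2("no feature tables (*.tsv) in %s", cfg$features_dir)
    inputs <- feature_files
  }
  if (subcommand == "correlate") {
    if (is.null(cfg$features_dir))
      stop2("correlate requires config key 'features_dir' (a prior run directory containing gene_matrix.tsv)")
    gm_path <- file.path(cfg$features_dir, "gene_matrix.tsv")
    if (!file.exists(gm_path)) stop2("input not found: %s", gm_path)
    inputs <- gm_path
  }

  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  results <- list()

  if (subcommand %in% c("simulate", "rank", "full")) {
    simcfg <- sim_config(seed = cfg$seed)
    platform <- platform_spec()
    truth <- build_default_truth(simcfg, min_abs_effect = cfg$min_abs_effect)
    design <- generate_design(simcfg, platform)
    sim <- simulate_arrays(design, truth, signal_model(), simcfg, platform)
    write_design(design, file.path(out_dir, "design.tsv"))
    write_tsv(truth, file.path(out_dir, "truth.tsv"))
    outputs <- c(outputs, "design.tsv", "truth.tsv")
    if (subcommand == "simulate") {
      feat_dir <- file.path(out_dir, "features")
      dir.create(feat_dir, showWarnings = FALSE)
      for (id in names(c(sim$samples, sim$controls))) {
        tabs <- c(sim$samples, sim$controls)
        write_feature_table(tabs[[id]],
                            file.path(feat_dir, paste0(id, ".tsv")))
      }
      outputs <- c(outputs, "features/")
      results <- list(design = design, truth = truth, sim = sim)
    } else {
      ## analysis chain on the simulated run
      pooled <- pool_reference(sim$controls)
      ma_tables <- lapply(sim$samples, function(tab) {
        ma <- compute_ma(tab$log2_signal, pooled$log2_signal)
        cbind(tab, ma)
      })
      for (id in names(ma_tables)) {
        rep_art <- detect_spatial_artifact(
          ma_tables[[id]], tail_threshold = cfg$tail_threshold,
          min_tail = cfg$min_tail,
          collinearity_cutoff = cfg$collinearity_cutoff)
        if (rep_art$flagged)
          ma_tables[[id]] <- apply_artifact_exclusion(ma_tables[[id]],
                                                      rep_art)
      }
      pmat <- probe_matrix(ma_tables)
      ranked <- sum_squared_rank(pmat)
      strips <- top_k_consolidate(ranked, design, k = cfg$k)
      gmat <- consolidate_genes(pmat, design)
      calls <- call_de(gmat, tau = cfg$tau)
      write_tsv(ranked, file.path(out_dir, "ranked_probes.tsv"))
      write_tsv(strips, file.path(out_dir, "top_gene_strips.tsv"))
      gm <- data.frame(gene_id = rownames(gmat), gmat, check.names = FALSE)
      write_tsv(gm, file.path(out_dir, "gene_matrix.tsv"))
      outputs <- c(outputs, "ranked_probes.tsv", "top_gene_strips.tsv",
                   "gene_matrix.tsv")
      results <- list(design = design, truth = truth, ranked = ranked,
                      strips = strips, gene_matrix = gmat, calls = calls)
      if (subcommand == "full") {
        pheno <- simulate_phenotypes(
          t(sim$truth_x[colnames(gmat), , drop = FALSE]),
          coupling = data.frame(endpoint = "SL", gene = "Vtg1", rho = 0.5),
          seed = cfg$seed + 2L)
        corr <- phenotype_correlations(gmat, pheno, alpha = cfg$alpha)
        write_tsv(pheno, file.path(out_dir, "phenotypes.tsv"))
        write_tsv(corr, file.path(out_dir, "phenotype_correlations.tsv"))
        outputs <- c(outputs, "phenotypes.tsv",
                     "phenotype_correlations.tsv")
        results$phenotypes <- pheno
        results$correlations <- corr
      }
    }
  } else if (subcommand == "design-probes") {
    alignments <- lapply(cfg$alignment_files, function(f) {
      seqs <- read_fasta(f)
      gene <- sub("\\.[^.]*$", "", basename(f))
      multi_alignment(gene, names(seqs), unname(seqs))
    })
    probes <- design_probe_set(alignments)
    write_tsv(probes, file.path(out_dir, "probes.tsv"))
    write_tsv(attr(probes, "rejected"),
              file.path(out_dir, "rejected_genes.tsv"))
    write_fasta(stats::setNames(probes$sequence, probes$probe_id),
                file.path(out_dir, "probes.fasta"))
    outputs <- c("probes.tsv", "rejected_genes.tsv", "probes.fasta")
    results <- list(probes = probes)
  } else if (subcommand %in% c("normalize", "qc")) {
    tables <- lapply(feature_files, read_feature_table)
    names(tables) <- sub("\\.tsv$", "", basename(feature_files))
    key <- function(t) paste(t$row, t$col, t$probe_id)
    k0 <- key(tables[[1]])
    for (i in seq_along(tables)[-1])
      if (!identical(key(tables[[i]]), k0))
        stop2("feature table '%s' has a different feature set/order",
              names(tables)[i])
    if (subcommand == "normalize") {
      mat <- sapply(tables, function(t) t$log2_signal)
      res <- multiloess_normalize(mat, span = cfg$span)
      norm_dir <- file.path(out_dir, "normalized")
      dir.create(norm_dir, showWarnings = FALSE)
      for (id in names(tables)) {
        tab <- tables[[id]]
        tab$log2_signal <- res$normalized[, id]
        write_feature_table(tab, file.path(norm_dir, paste0(id, ".tsv")))
      }
      outputs <- "normalized/"
      results <- list(normalization = res)
    } else {
      is_ctrl <- startsWith(names(tables), "CTRL")
      if (sum(is_ctrl) < 2)
        stop2("qc needs >= 2 control tables (CTRL_* files) to pool")
      pooled <- pool_reference(tables[is_ctrl])
      art <- list(); box <- list()
      for (id in names(tables)) {
        tab <- tables[[id]]
        tab$M <- tab$log2_signal - pooled$log2_signal
        rep <- detect_spatial_artifact(
          tab, tail_threshold = cfg$tail_threshold,
          min_tail = cfg$min_tail,
          collinearity_cutoff = cfg$collinearity_cutoff)
        art[[id]] <- data.frame(sample = id, n_tail = rep$n_tail,
                                collinearity = rep$collinearity,
                                flagged = rep$flagged)
        b <- boxplot_summary(tab$M)
        box[[id]] <- data.frame(sample = id, min = b$min, q1 = b$q1,
                                median = b$median, q3 = b$q3, max = b$max,
                                n_outliers = length(b$outliers))
      }
      art <- do.call(rbind, art); box <- do.call(rbind, box)
      write_tsv(art, file.path(out_dir, "qc_artifacts.tsv"))
      write_tsv(box, file.path(out_dir, "qc_boxplots.tsv"))
      outputs <- c("qc_artifacts.tsv", "qc_boxplots.tsv")
      results <- list(artifacts = art, boxplots = box)
    }
  } else if (subcommand == "power") {
    sigma <- if (is.null(cfg$sigma))
      calibrate_power_sigma(1.5, 3, 0.70) else cfg$sigma
    tab <- data.frame(fold_change = cfg$fold_changes,
                      sigma = sigma, n = cfg$n_replicates,
                      alpha = cfg$alpha)
    tab$power <- power_fold_change(tab$fold_change, sigma,
                                   cfg$n_replicates, cfg$alpha)
    write_tsv(tab, file.path(out_dir, "power_table.tsv"))
    outputs <- "power_table.tsv"
    results <- list(power_table = tab)
  } else if (subcommand == "qpcr") {
    records <- utils::read.delim(cfg$qpcr_file, stringsAsFactors = FALSE)
    res <- qpcr_relative(records, target_gene = cfg$qpcr_target,
                         reference_gene = cfg$qpcr_reference_gene %||%
                           "GAPDH",
                         reference_fish = cfg$qpcr_reference_fish)
    write_tsv(res, file.path(out_dir, "qpcr_relative.tsv"))
    outputs <- "qpcr_relative.tsv"
    results <- list(qpcr = res)
  } else if (subcommand == "correlate") {
    gm_path <- file.path(cfg$features_dir, "gene_matrix.tsv")
    gm <- utils::read.delim(gm_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    gmat <- as.matrix(gm[, -1, drop = FALSE])
    rownames(gmat) <- gm[[1]]
    pheno_path <- file.path(cfg$features_dir, "phenotypes.tsv")
    pheno <- if (file.exists(pheno_path))
      utils::read.delim(pheno_path, stringsAsFactors = FALSE)
    else load_packaged_phenotypes()
    corr <- phenotype_correlations(gmat, pheno, alpha = cfg$alpha)
    write_tsv(corr, file.path(out_dir, "phenotype_correlations.tsv"))
    outputs <- "phenotype_correlations.tsv"
    results <- list(correlations = corr)
  }

  write_manifest(cfg, subcommand, inputs, outputs, out_dir)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
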