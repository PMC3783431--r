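# Shared fixture builders for the test suite. Everything is generated in
# code; seeds are fixed per call site.

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else with_fixed_seed(seed, draw())
}

with_fixed_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

mutate_seq <- function(s, positions, to = NULL) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[p])
    ch[p] <- if (is.null(to)) alt[1] else to
  }
  paste(ch, collapse = "")
}

# Small simulated run shared by several tests: default-shape design on a
# reduced gene set for speed.
small_sim <- function(seed = 11, noise_sd = 0.3, n_genes = 10,
                      species_per_gene = 2, reps = 8,
                      min_abs_effect = NULL) {
  # grid sized to hold the spots at ~80% occupancy
  side <- ceiling(sqrt(n_genes * species_per_gene * reps / 0.8)) + 2
  cfg <- sim_config(n_genes = n_genes, species_per_gene = species_per_gene,
                    n_housekeeping = 2, grid_rows = side, grid_cols = side,
                    seed = seed)
  platform <- platform_spec(replicates_per_probe = reps, noise_sd = noise_sd)
  truth <- build_default_truth(cfg, min_abs_effect = min_abs_effect)
  design <- generate_design(cfg, platform)
  sim <- simulate_arrays(design, truth, signal_model(), cfg, platform)
  list(cfg = cfg, platform = platform, truth = truth, design = design,
       sim = sim)
}

# Brute-force Ward (Lance-Williams, ward.D2 update on Euclidean
# distances); returns the merge sets in order, for comparison with hclust.
ward_oracle_merges <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  merges <- list()
  dm <- d2
  diag(dm) <- Inf
  for (step in seq_len(n - 1)) {
    # find minimal pair among active clusters
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (dm[i, j] < bestd) { bestd <- dm[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merges[[step]] <- sort(c(members[[i]], members[[j]]))
    # Lance-Williams ward.D2 update on squared distances
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      dm[i, k] <- dm[k, i] <-
        ((ni + nk) * dm[i, k] + (nj + nk) * dm[j, k] - nk * dm[i, j]) /
        (ni + nj + nk)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  merges
}

# merge sets from an hclust object, in merge order
hclust_merges <- function(hc) {
  n <- nrow(hc$merge) + 1
  sets <- vector("list", n - 1)
  for (s in seq_len(n - 1)) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  sets
}
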