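# Synthetic data generator: truth table, design layout, signal model,
# spatial artifacts, phenotype copula.

test_that("default truth carries the published effect directions", {
  tr <- build_default_truth()
  q <- function(gene, site) tr$mean_log2fc[tr$gene_id == gene &
                                             tr$site_id == site]
  expect_gt(q("Vtg1", "LA"), 0)
  expect_gt(q("Vtg2", "SD"), 0)
  expect_gt(q("CYP1A", "OC"), 0)
  expect_gt(q("ZP3", "DP"), 0)
  for (s in c("LA", "PV", "OC", "DP", "SD")) {
    expect_lt(q("HEPC1", s), 0)
    expect_lt(q("ERb", s), 0)
    expect_lt(q("CYP3A", s), 0)
    expect_lt(q("GSTa", s), 0)
    expect_lt(q("MT", s), 0)
    expect_lt(q("PPARa", s), 0)
    expect_lt(q("PPARg", s), 0)
  }
  # control site all zeros; spreads non-negative; >= 21 perturbed genes
  expect_true(all(tr$mean_log2fc[tr$site_id == "REF"] == 0))
  expect_true(all(tr$between_fish_sd >= 0))
  expect_gte(length(attr(tr, "signal_genes")), 21)
})

test_that("design layout assigns distinct locations and respects the grid", {
  cfg <- sim_config(n_genes = 2, species_per_gene = 1, n_housekeeping = 0,
                    grid_rows = 4, grid_cols = 4, seed = 5)
  d <- generate_design(cfg, platform_spec(replicates_per_probe = 2))
  expect_equal(length(unique(d$probe_id)), 2)
  expect_equal(nrow(d), 4)
  expect_equal(anyDuplicated(d[, c("row", "col")]), 0)
  expect_true(all(d$row >= 0 & d$row < 4 & d$col >= 0 & d$col < 4))
  # too-small grid errors
  expect_error(generate_design(
    sim_config(n_genes = 2, species_per_gene = 1, n_housekeeping = 0,
               grid_rows = 1, grid_cols = 3),
    platform_spec(replicates_per_probe = 2)), "grid")
})

test_that("identical seeds give identical designs, signals and phenotypes", {
  a <- small_sim(seed = 33)
  b <- small_sim(seed = 33)
  expect_identical(a$design, b$design)
  expect_identical(a$sim$samples, b$sim$samples)
  expect_identical(a$sim$truth_x, b$sim$truth_x)
  pa <- simulate_phenotypes(t(a$sim$truth_x), seed = 4)
  pb <- simulate_phenotypes(t(b$sim$truth_x), seed = 4)
  expect_identical(pa, pb)
  c <- small_sim(seed = 34)
  expect_false(identical(a$sim$samples, c$sim$samples))
})

test_that("with zero noise and zero effects every spot equals its baseline", {
  cfg <- sim_config(n_genes = 4, species_per_gene = 2, n_housekeeping = 0,
                    grid_rows = 10, grid_cols = 10,
                    between_fish_sd = 0, control_sd = 0, seed = 2)
  tr <- build_default_truth(cfg)
  tr$mean_log2fc <- 0    # all effects off
  pl <- platform_spec(replicates_per_probe = 3, noise_sd = 0)
  d <- generate_design(cfg, pl)
  sim <- simulate_arrays(d, tr, signal_model(affinity_sd = 0), cfg, pl)
  # every array identical to every other, spot for spot
  ref <- sim$controls[[1]]$log2_signal
  for (tab in c(sim$samples, sim$controls))
    expect_equal(tab$log2_signal, ref)
  # replicate spots of one probe all equal (pure baseline)
  t1 <- sim$samples[[1]]
  expect_true(all(tapply(t1$log2_signal, t1$probe_id, sd) == 0))
})

test_that("a forced +2 gene effect appears as M = +2 on every replicate", {
  cfg <- sim_config(n_genes = 3, species_per_gene = 2, n_housekeeping = 0,
                    grid_rows = 10, grid_cols = 10,
                    between_fish_sd = 0, control_sd = 0, seed = 3)
  tr <- build_default_truth(cfg)
  tr$mean_log2fc <- ifelse(tr$gene_id == "Vtg1" & tr$site_id != "REF", 2, 0)
  pl <- platform_spec(replicates_per_probe = 4, noise_sd = 0)
  d <- generate_design(cfg, pl)
  sim <- simulate_arrays(d, tr, signal_model(), cfg, pl)
  pooled <- pool_reference(sim$controls)
  ma <- compute_ma(sim$samples[[1]]$log2_signal, pooled$log2_signal)
  vtg_spots <- d$gene_id == "Vtg1"
  expect_equal(ma$M[vtg_spots], rep(2, sum(vtg_spots)))
  expect_equal(ma$M[!vtg_spots], rep(0, sum(!vtg_spots)))
})

test_that("fish-by-gene draws follow Normal(mean_log2fc, between_fish_sd)", {
  # Monte Carlo: many fish at one site, one gene, check the empirical mean
  cfg <- sim_config(n_genes = 1, species_per_gene = 1, n_housekeeping = 0,
                    fish_per_site = c(LA = 500L), grid_rows = 3,
                    grid_cols = 3, between_fish_sd = 0.3, seed = 8)
  tr <- build_default_truth(cfg)   # Vtg1 at LA: 3 * 1.25 = 3.75
  pl <- platform_spec(replicates_per_probe = 1, noise_sd = 0)
  d <- generate_design(cfg, pl)
  sim <- simulate_arrays(d, tr, signal_model(), cfg, pl)
  x <- sim$truth_x[grepl("^LA", rownames(sim$truth_x)), "Vtg1"]
  expect_length(x, 500)
  target <- tr$mean_log2fc[tr$gene_id == "Vtg1" & tr$site_id == "LA"]
  se <- 0.3 / sqrt(500)
  expect_lt(abs(mean(x) - target), 3 * se)
  expect_lt(abs(sd(x) - 0.3), 0.06)
})

test_that("spatial artifact injection modifies exactly the band and nothing else", {
  s <- small_sim(seed = 41)
  tab <- s$sim$samples[[1]]
  # zero shift is the identity
  out0 <- inject_spatial_artifact(tab, point = c(5, 0),
                                  direction = c(0, 1), width = 0.5,
                                  shift = 0)
  expect_equal(out0$log2_signal, tab$log2_signal)
  # -2 along row 5: exactly the row-5 spots change, by exactly -2
  out <- inject_spatial_artifact(tab, point = c(5, 0), direction = c(0, 1),
                                 width = 0.5, shift = -2)
  hit <- tab$row == 5
  expect_equal(attr(out, "n_modified"), sum(hit))
  expect_equal(out$log2_signal[hit], tab$log2_signal[hit] - 2)
  expect_equal(out$log2_signal[!hit], tab$log2_signal[!hit])
})

test_that("an artifact in one control makes its self-vs-pool tail heavy", {
  s <- small_sim(seed = 51, n_genes = 20, species_per_gene = 3, reps = 12)
  ctrl <- s$sim$controls
  ctrl[["CTRL_A"]] <- inject_spatial_artifact(
    ctrl[["CTRL_A"]], point = c(10, 0), direction = c(0, 1),
    width = 1.5, shift = -2.5)
  pooled <- pool_reference(ctrl)
  tails <- vapply(ctrl, function(tab)
    sum(compute_ma(tab$log2_signal, pooled$log2_signal)$M < -1.5),
    numeric(1))
  expect_gt(tails[["CTRL_A"]], 20)
  expect_equal(unname(tails[c("CTRL_B", "CTRL_C")]), c(0, 0))
})

test_that("phenotype copula hits its Spearman coupling targets", {
  # uncoupled: all endpoint-gene correlations stay small at n = 200
  set.seed(9)
  expr <- matrix(rnorm(3 * 200), nrow = 3,
                 dimnames = list(c("Vtg1", "ERb", "MT"),
                                 sprintf("f%03d", 1:200)))
  ph0 <- simulate_phenotypes(expr, coupling = NULL, seed = 10)
  for (g in rownames(expr)) for (ep in c("VTG", "E2", "SL")) {
    expect_lt(abs(spearman_cor(expr[g, ], ph0[[ep]])$rho), 0.2)
  }
  # coupled at rho 0.5, n = 500: observed within +/- 0.1
  expr2 <- matrix(rnorm(500), nrow = 1,
                  dimnames = list("Vtg1", sprintf("f%03d", 1:500)))
  ph <- simulate_phenotypes(
    expr2, coupling = data.frame(endpoint = "SL", gene = "Vtg1",
                                 rho = 0.5), seed = 11)
  rho <- spearman_cor(expr2["Vtg1", ], ph$SL)$rho
  expect_lt(abs(rho - 0.5), 0.1)
  # schema: the eight endpoints of the field table
  expect_true(all(c("VTG", "E2", "Cort", "T4", "T", "IGF_I",
                    "calc_age", "SL") %in% names(ph)))
  expect_error(simulate_phenotypes(
    expr2, coupling = data.frame(endpoint = "SL", gene = "Vtg1",
                                 rho = 1.5)), "rho")
})

test_that("noise-free pipeline recovers fish-by-gene effects exactly", {
  cfg <- sim_config(n_genes = 6, species_per_gene = 2, n_housekeeping = 0,
                    grid_rows = 15, grid_cols = 15, control_sd = 0,
                    seed = 12)
  tr <- build_default_truth(cfg)
  pl <- platform_spec(replicates_per_probe = 5, noise_sd = 0)
  d <- generate_design(cfg, pl)
  sim <- simulate_arrays(d, tr, signal_model(), cfg, pl)
  pooled <- pool_reference(sim$controls)
  ma <- lapply(sim$samples, function(tab)
    cbind(tab, compute_ma(tab$log2_signal, pooled$log2_signal)))
  pm <- probe_matrix(ma)
  gm <- consolidate_genes(pm, d)
  for (f in colnames(gm)) for (g in rownames(gm)) {
    expect_equal(gm[g, f], unname(sim$truth_x[f, g]), tolerance = 1e-10)
  }
})
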