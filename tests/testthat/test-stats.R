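# Spearman correlation, phenotype screening, power planning, qPCR.

test_that("Spearman rho handles monotone transforms and matches an oracle", {
  x <- c(2, 5, 1, 9, 7, 4, 8)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  # invariance under strictly monotone transforms of either input
  y <- c(3, 1, 4, 1.5, 9, 2.6, 5)
  r0 <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(x^3, y)$rho, r0)
  expect_equal(spearman_cor(x, log(y))$rho, r0)
  # rank-and-Pearson oracle on the printed field table (age vs length)
  ph <- load_packaged_phenotypes()
  got <- spearman_cor(ph$calc_age, ph$SL)
  rx <- rank(ph$calc_age); ry <- rank(ph$SL)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  expect_equal(got$n, 22)
  # cross-check against the standard implementation
  expect_equal(got$rho,
               suppressWarnings(cor.test(ph$calc_age, ph$SL,
                                         method = "spearman"))$estimate,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("exact permutation p equals full enumeration and the t path is sane", {
  set.seed(101)
  for (n in c(4, 5, 6)) {
    x <- rnorm(n); y <- rnorm(n)
    got <- spearman_cor(x, y)
    expect_equal(got$method, "exact")
    # independent enumeration oracle over all n! permutations of y
    rx <- rank(x); ry <- rank(y)
    rho_obs <- cor(rx, ry)
    perms <- NULL
    permute <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    rhos <- vapply(permute(seq_len(n)),
                   function(p) cor(rx, ry[p]), numeric(1))
    expect_equal(got$p, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
  }
  # large-n path: t approximation agrees with cor.test's asymptotics
  set.seed(102)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- spearman_cor(x, y)
  expect_equal(got$method, "t-approximation")
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = FALSE))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("phenotype screening recovers planted couplings and excludes constants", {
  set.seed(103)
  hits <- vapply(1:30, function(i) {
    expr <- matrix(rnorm(100), nrow = 1,
                   dimnames = list("Vtg1", sprintf("f%03d", 1:100)))
    ph <- simulate_phenotypes(expr,
      coupling = data.frame(endpoint = "SL", gene = "Vtg1", rho = 0.6),
      seed = 1000 + i)
    ph$fish_id <- colnames(expr)
    res <- phenotype_correlations(expr, ph)
    row <- res[res$gene == "Vtg1" & res$endpoint == "SL", ]
    row$significant && row$rho > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # constant gene rows excluded with a warning
  gm <- rbind(Vtg1 = rnorm(10), flatgene = rep(1, 10))
  colnames(gm) <- sprintf("f%02d", 1:10)
  ph <- data.frame(fish_id = colnames(gm), SL = rnorm(10))
  expect_warning(res <- phenotype_correlations(gm, ph), "constant")
  expect_false("flatgene" %in% res$gene)
})

test_that("null phenotype screening flags at about the alpha rate", {
  set.seed(104)
  rates <- vapply(1:40, function(i) {
    gm <- matrix(rnorm(20 * 50), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("f%03d", 1:50)))
    ph <- simulate_phenotypes(gm, coupling = NULL, seed = 2000 + i)
    ph$fish_id <- colnames(gm)
    mean(phenotype_correlations(gm, ph)$significant)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("fold-change power matches its closed form and boundary cases", {
  # null case: no fold change leaves only the type-I rate
  expect_equal(power_fold_change(1, sigma = 0.4, n = 3), 0.05,
               tolerance = 1e-12)
  # monotone in n and fold change, decreasing in sigma
  p_n <- vapply(1:8, function(n) power_fold_change(2, 0.4, n), numeric(1))
  expect_true(all(diff(p_n) > 0))
  p_fc <- vapply(c(1.2, 1.5, 2, 3), function(fc)
    power_fold_change(fc, 0.4, 3), numeric(1))
  expect_true(all(diff(p_fc) > 0))
  p_s <- vapply(c(0.2, 0.4, 0.8), function(s)
    power_fold_change(2, s, 3), numeric(1))
  expect_true(all(diff(p_s) < 0))
})

test_that("Monte Carlo z-test rejection rates match the closed form", {
  set.seed(105)
  nrep <- 20000
  pts <- list(c(fc = 1.5, sigma = 0.41, n = 3),
              c(fc = 2, sigma = 0.41, n = 3),
              c(fc = 1.2, sigma = 0.3, n = 5),
              c(fc = 1, sigma = 0.4, n = 3),
              c(fc = 3, sigma = 0.8, n = 2))
  for (p in pts) {
    d <- log2(p[["fc"]])
    means <- d + rnorm(nrep, 0, p[["sigma"]] / sqrt(p[["n"]]))
    z <- means / (p[["sigma"]] / sqrt(p[["n"]]))
    rej <- mean(abs(z) > qnorm(0.975))
    theo <- power_fold_change(p[["fc"]], p[["sigma"]], p[["n"]])
    se <- sqrt(theo * (1 - theo) / nrep)
    expect_lt(abs(rej - theo), 3 * max(se, 1e-4))
  }
})

test_that("replicate planning enumerates the smallest sufficient n", {
  sigma <- calibrate_power_sigma(1.5, 3, 0.70)
  # enumeration oracle
  oracle <- function(fc, target) {
    for (n in 1:50)
      if (power_fold_change(fc, sigma, n) >= target) return(n)
    NA
  }
  for (fc in c(1.5, 2, 3)) for (tp in c(0.7, 0.9, 0.95)) {
    expect_equal(min_replicates(fc, sigma, tp), oracle(fc, tp))
  }
  expect_equal(min_replicates(2, sigma, 0.95), 3)
  # never decreases as the target rises
  ns <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.99), function(tp)
    min_replicates(1.5, sigma, tp), numeric(1))
  expect_true(all(diff(ns) >= 0))
  # a unit fold change can never reach power above alpha
  expect_error(min_replicates(1, sigma, 0.8), "unreachable")
})

test_that("qPCR relative quantities follow 2^dCT and the fold-change oracle", {
  recs <- data.frame(
    sample = rep(c("fishA", "fishB", "refX", "refY"), each = 2),
    gene = rep(c("Vtg1", "GAPDH"), 4),
    ct1 = c(20, 26, 22, 26, 24, 26, 24.5, 26),
    ct2 = c(20.2, 26.1, 22.1, 25.9, 24.1, 26.1, 24.4, 26.2),
    ct3 = c(19.8, 25.9, 21.9, 26.1, 23.9, 25.9, 24.6, 25.8))
  res <- qpcr_relative(recs, "Vtg1", "GAPDH",
                       reference_fish = c("refX", "refY"))
  # dCT = mean(ct reference gene) - mean(ct target); RQ = 2^dCT
  a <- res[res$sample == "fishA", ]
  expect_equal(a$dct, 26 - 20)
  expect_equal(a$relative_quantity, 2^6)
  # hand-computed mean log2 ratio against the two reference fish
  rq <- function(s) {
    sub <- recs[recs$sample == s, ]
    2^(mean(unlist(sub[sub$gene == "GAPDH", 3:5])) -
       mean(unlist(sub[sub$gene == "Vtg1", 3:5])))
  }
  oracle <- mean(c(log2(rq("fishA") / rq("refX")),
                   log2(rq("fishA") / rq("refY"))))
  expect_equal(a$log2_fold, oracle, tolerance = 1e-12)
  # dCT of 0 and 1 map to quantities 1 and 2
  flat <- data.frame(sample = rep(c("s1", "r1"), each = 2),
                     gene = rep(c("tgt", "GAPDH"), 2),
                     ct1 = c(25, 25, 25, 26), ct2 = c(25, 25, 25, 26),
                     ct3 = c(25, 25, 25, 26))
  fr <- qpcr_relative(flat, "tgt", "GAPDH", reference_fish = "r1")
  expect_equal(fr$relative_quantity[fr$sample == "s1"], 1)
  expect_equal(fr$relative_quantity[fr$sample == "r1"], 2)
})

test_that("qPCR quantities are invariant to a global Ct shift and flag gaps", {
  recs <- data.frame(
    sample = rep(c("s1", "r1"), each = 2),
    gene = rep(c("tgt", "GAPDH"), 2),
    ct1 = c(21, 26, 23, 26), ct2 = c(21.1, 26, 23.2, 26),
    ct3 = c(20.9, 26, 22.8, 26))
  base <- qpcr_relative(recs, "tgt", "GAPDH", reference_fish = "r1")
  shifted <- recs
  shifted[, c("ct1", "ct2", "ct3")] <-
    shifted[, c("ct1", "ct2", "ct3")] + 3
  res <- qpcr_relative(shifted, "tgt", "GAPDH", reference_fish = "r1")
  expect_equal(res$relative_quantity, base$relative_quantity)
  expect_equal(res$log2_fold, base$log2_fold)
  # incomplete triplicate: flagged, excluded from fold changes
  broken <- recs
  broken$ct2[1] <- NA
  res2 <- qpcr_relative(broken, "tgt", "GAPDH", reference_fish = "r1")
  expect_true(res2$flagged[res2$sample == "s1"])
  expect_true(is.na(res2$log2_fold[res2$sample == "s1"]))
})
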