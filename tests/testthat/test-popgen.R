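test_that("QC applies strict MAF and missingness thresholds", {
  # 20 hybrids: MAF 0.04 (below), 0.05 (boundary kept), 25% and 20% missing
  n <- 50
  c1 <- c(rep(1, 4), rep(0, n - 4))           # maf 0.04
  c2 <- c(rep(1, 5), rep(0, n - 5))           # maf 0.05, kept (strict <)
  c3 <- c(rep(NA, 13), rep(1, 17), rep(0, 20))  # 26% missing, removed
  c4 <- c(rep(NA, 10), rep(1, 20), rep(0, 20))  # 20% missing, kept
  G <- toy_geno(cbind(c1, c2, c3, c4))
  out <- qc_and_impute(G)
  expect_equal(colnames(out$geno), c("m2", "m4"))
  expect_false(anyNA(out$geno))
  # modal imputation: m4 is mostly 0/1 with 1 as joint mode? counts 20 each,
  # tie broken towards the smaller genotype
  expect_true(all(out$geno[1:10, "m4"] == 0))
  tallies <- attr(out, "qc")
  expect_equal(unname(tallies["retained"]), 2L)
})

test_that("QC is idempotent and keeps complete common-frequency data intact", {
  set.seed(2)
  G <- toy_geno(matrix(rbinom(200, 2, 0.5), 20, 10))
  out1 <- qc_and_impute(G)
  out2 <- qc_and_impute(out1)
  expect_equal(out1$geno, out2$geno)
  expect_error(qc_and_impute(toy_geno(matrix(0L, 10, 3))), "all SNPs removed")
})

test_that("GRM matches the hand-computed VanRaden values", {
  cnt <- rbind(c(0, 2), c(2, 0), c(1, 1))
  G <- toy_geno(cnt)
  K <- grm(G)
  # by hand: p = (0.5, 0.5); W = counts - 1; denom = 2 * 0.25 * 2 = 1
  W <- cnt - 1
  expect_equal(unname(K), W %*% t(W) / 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(K, "method"), "vanraden")
})

test_that("GRM duplication, PSD and permutation equivariance hold", {
  set.seed(7)
  cnt <- matrix(rbinom(400, 2, runif(20, 0.2, 0.8)), 20, 20, byrow = TRUE)
  cnt[2, ] <- cnt[1, ]
  K <- grm(toy_geno(cnt))
  expect_equal(K[1, ], K[2, ])
  expect_equal(K[1, 1], K[2, 2])
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  perm <- sample(20)
  Kp <- grm(toy_geno(cnt[perm, ]))
  expect_equal(unname(Kp), unname(K[perm, perm]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("IBS equals the manual allele-sharing tabulation", {
  cnt <- rbind(a = c(0, 1, 2), b = c(2, 1, 0), c = c(0, 0, 2))
  K <- ibs_matrix(toy_geno(cnt))
  # manual: ab shares (0,2,0)/2 -> mean 1/3; ac: (1, .5, 1) -> 5/6; bc (0,.5,0)->1/6
  expect_equal(K["a", "b"], 1 / 3)
  expect_equal(K["a", "c"], 5 / 6)
  expect_equal(K["b", "c"], 1 / 6)
  expect_equal(diag(K), c(a = 1, b = 1, c = 1))
  ident <- toy_geno(rbind(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(ibs_matrix(ident)[1, 2], 1)
  opp <- toy_geno(rbind(c(0, 0), c(2, 2)))
  expect_equal(ibs_matrix(opp)[1, 2], 0)
  expect_error(ibs_matrix(toy_geno(rbind(c(NA, 1), c(0, 1)))), "complete")
})

test_that("Nei diversity is zero when fixed and ~0.5 at p = 0.5", {
  fixed <- toy_geno(matrix(2L, 30, 5))
  expect_equal(unname(nei_diversity(fixed, rep("g", 30))), 0)
  set.seed(3)
  half <- toy_geno(matrix(rbinom(5000 * 40, 2, 0.5), 40, 5000))
  he <- nei_diversity(half, rep("g", 40))
  expect_equal(unname(he), 0.5, tolerance = 0.01)
})

test_that("diversity is stable across eras in a stationary panel", {
  cfg <- sim_config(n_hybrids = 150, n_snps = 4000, n_selected_loci = 0,
                    structure_mix = c(intercept = 0, slope = 0, sd = 0.8),
                    missing_rate = 0, seed = 31)
  panel <- simulate_panel(cfg)
  he <- nei_diversity(panel$geno, panel$meta$group)
  expect_lt(max(he) - min(he), 0.01)
})

test_that("PCA separates year cohorts and respects the sign convention", {
  # two cohorts with disjoint fixed alleles
  cnt <- rbind(matrix(c(2L, 0L), 10, 40, byrow = TRUE)[, rep(1:2, 20)],
               matrix(c(0L, 2L), 10, 40, byrow = TRUE)[, rep(1:2, 20)])
  set.seed(8)
  cnt <- cnt + matrix(rbinom(800, 1, 0.05), 20, 40)
  cnt[cnt > 2] <- 2L
  years <- c(rep(1950, 10), rep(2010, 10))
  res <- pca_year(toy_geno(cnt), years)
  expect_gt(res$r2_year, 0.9)
  expect_gte(cor(res$scores[, 1], years), 0)
  expect_equal(sum(res$explained), 1)
  # duplicated hybrids get identical scores
  cnt2 <- rbind(cnt, cnt[1, , drop = FALSE])
  res2 <- pca_year(toy_geno(cnt2), c(years, 1950))
  expect_equal(res2$scores[21, ], res2$scores[1, ], tolerance = 1e-8)
})

test_that("PC1-year R2 is null-calibrated for year-independent structure", {
  cfg <- sim_config(n_hybrids = 80, n_snps = 2000, n_selected_loci = 0,
                    structure_mix = c(intercept = 0, slope = 0, sd = 1),
                    missing_rate = 0, seed = 17)
  panel <- simulate_panel(cfg)
  G <- panel$geno
  res <- pca_year(G, panel$meta$year)
  set.seed(99)
  null_r2 <- replicate(99, {
    pca_year(G, sample(panel$meta$year))$r2_year
  })
  expect_lt(res$r2_year, quantile(null_r2, 0.95))
})

test_that("LD pruning removes duplicates and leaves independent SNPs", {
  set.seed(5)
  base <- matrix(rbinom(50 * 30, 2, 0.5), 50, 30)
  base[, 7] <- base[, 6]                 # exact duplicate in one window
  G <- toy_geno(base)
  kept <- ld_prune(G, window_snps = 10, step = 2, r2_max = 0.2)
  expect_equal(sum(c(6, 7) %in% kept), 1L)
  # mutually independent SNPs: all retained
  ind <- toy_geno(matrix(rbinom(200 * 20, 2, 0.5), 200, 20))
  expect_equal(ld_prune(ind), seq_len(20))
  # post-hoc: no retained pair within a window exceeds the r2 cap
  for (s in seq(1, length(kept) - 1, by = 2)) {
    win <- kept[s:min(s + 9, length(kept))]
    if (length(win) < 2) next
    cc <- suppressWarnings(cor(base[, win]))^2
    diag(cc) <- 0
    expect_lte(max(cc, na.rm = TRUE), 0.2 + 1e-12)
  }
})
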