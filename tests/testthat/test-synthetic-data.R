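test_that("invalid configurations are rejected", {
  expect_error(sim_config(year_range = c(2000, 2000)), "degenerate year")
  expect_error(sim_config(n_snps = 10, n_selected_loci = 11),
               "n_selected_loci")
  expect_error(sim_config(n_experiments_per_scenario = 0), "no experiments")
  expect_error(sim_config(missing_rate = 1.2), "missing_rate")
})

test_that("a fixed seed makes every simulator bit-identical", {
  cfg <- sim_config(n_hybrids = 20, n_snps = 300, seed = 5)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$geno$geno, p2$geno$geno)
  expect_identical(p1$truth$selected, p2$truth$selected)
  e1 <- simulate_environments(cfg)
  e2 <- simulate_environments(cfg)
  expect_identical(e1$envs, e2$envs)
  t1 <- simulate_trial(cfg, p1, e1)
  t2 <- simulate_trial(cfg, p2, e2)
  expect_identical(t1$trial$gn, t2$trial$gn)
  cfg2 <- sim_config(n_hybrids = 20, n_snps = 300, seed = 6)
  p3 <- simulate_panel(cfg2)
  expect_false(identical(p1$geno$geno, p3$geno$geno))
})

test_that("zero missing rate yields a complete matrix", {
  cfg <- sim_config(n_hybrids = 15, n_snps = 200, missing_rate = 0, seed = 3)
  expect_false(anyNA(simulate_panel(cfg)$geno$geno))
})

test_that("a trend-free unstructured panel has uniform association p-values", {
  cfg <- sim_config(n_hybrids = 120, n_snps = 3000, n_selected_loci = 0,
                    structure_mix = c(intercept = 0, slope = 0, sd = 0.8),
                    missing_rate = 0, seed = 29)
  panel <- simulate_panel(cfg)
  y <- panel$meta$year
  yc <- y - mean(y)
  gc <- scale(panel$geno$geno, center = TRUE, scale = FALSE)
  # per-SNP OLS p-values, vectorised
  n <- length(y)
  sxx <- colSums(gc^2)
  b <- colSums(gc * yc) / sxx
  rss <- sum(yc^2) - b^2 * sxx
  tv <- b / sqrt(rss / (n - 2) / sxx)
  pv <- 2 * pt(-abs(tv), n - 2)
  pv <- pv[is.finite(pv)]
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
  # and the mean per-SNP slope is centred at zero
  bf <- b[is.finite(b)]
  expect_lt(abs(mean(bf)), 3 * sd(bf) / sqrt(length(bf)))
})

test_that("selected loci drift apart between era quartiles, neutral do not", {
  cfg <- sim_config(n_hybrids = 200, n_snps = 3000, n_selected_loci = 50,
                    trend_slope = 0.05, missing_rate = 0, seed = 37)
  panel <- simulate_panel(cfg)
  yrs <- panel$meta$year
  qt <- quantile(yrs, c(0.25, 0.75))
  oldest <- which(yrs <= qt[1]); newest <- which(yrs >= qt[2])
  dp <- abs(colMeans(panel$geno$geno[newest, ]) -
              colMeans(panel$geno$geno[oldest, ])) / 2
  sel <- panel$geno$map$id %in% panel$truth$selected
  expect_gt(mean(dp[sel]), mean(dp[!sel]))
  expect_gt(mean(dp[sel]), 2 * mean(dp[!sel]))
})

test_that("water-deficit environments sit below the -0.1 MPa threshold", {
  cfg <- sim_config(seed = 43)
  env <- simulate_environments(cfg)
  wd <- env$truth$water_class == "WD"
  expect_true(all(env$envs$psi[wd] < -0.1))
  expect_true(all(env$envs$psi[!wd] > -0.1))
})

test_that("zero dispersion collapses every scenario to one covariate point", {
  cfg <- sim_config(env_dispersion = 0, seed = 47)
  env <- simulate_environments(cfg)
  sp <- split(env$envs$tmax_flo, env$truth$scenario)
  for (v in sp) expect_equal(max(v) - min(v), 0)
})

test_that("k-medoids recovers the planted temperature classes at defaults", {
  cfg <- sim_config(seed = 53)
  env <- simulate_environments(cfg)
  cl <- cluster_temperature(env$envs)
  expect_gt(rand_index(cl$labels, env$truth$temp_class), 0.9)
})

test_that("a fully degenerate trial is exactly the intercept", {
  cfg <- sim_config(n_hybrids = 10, n_snps = 100, gain_per_year = 0,
                    n_qtls_stable = 0, n_qtls_adaptive = 0,
                    var_components = c(genetic = 0, environment = 0,
                                       gxe = 0, residual = 0),
                    missing_rate = 0, seed = 59)
  panel <- simulate_panel(cfg)
  env <- simulate_environments(cfg)
  tr <- simulate_trial(cfg, panel, env)
  expect_equal(max(tr$trial$yield) - min(tr$trial$yield), 0)
  expect_equal(tr$trial$yield[1], 9)
})

test_that("ANOVA on a large trial recovers the planted variance components", {
  cfg <- sim_config(n_hybrids = 250, n_snps = 100, n_qtls_stable = 0,
                    n_qtls_adaptive = 0, missing_rate = 0, seed = 61)
  panel <- simulate_panel(cfg)
  env <- simulate_environments(cfg)
  trial <- simulate_trial(cfg, panel, env)$trial
  n_h <- length(unique(trial$hybrid))
  n_e <- length(unique(trial$experiment))
  ms <- anova(lm(yield ~ hybrid + experiment, data = trial))
  ms_g <- ms["hybrid", "Mean Sq"]
  ms_e <- ms["experiment", "Mean Sq"]
  ms_r <- ms["Residuals", "Mean Sq"]
  vg <- (ms_g - ms_r) / n_e
  ve <- (ms_e - ms_r) / n_h
  vc <- cfg$var_components
  expect_equal(vg, unname(vc["genetic"]), tolerance = 0.1)
  expect_equal(ve, unname(vc["environment"]), tolerance = 0.1)
  # one record per cell: interaction and residual are estimated jointly
  expect_equal(ms_r, unname(vc["gxe"] + vc["residual"]), tolerance = 0.1)
})

test_that("trial rejects mismatched genotype and metadata tables", {
  cfg <- sim_config(n_hybrids = 10, n_snps = 50, n_selected_loci = 5,
                    seed = 67)
  panel <- simulate_panel(cfg)
  env <- simulate_environments(cfg)
  panel$meta <- panel$meta[-1, ]
  expect_error(simulate_trial(cfg, panel, env), "mismatch")
})

test_that("a full simulation writes all artefacts to disk", {
  cfg <- sim_config(n_hybrids = 8, n_snps = 60, seed = 71,
                    n_experiments_per_scenario = 1)
  panel <- simulate_panel(cfg)
  env <- simulate_environments(cfg)
  tr <- suppressWarnings(simulate_trial(cfg, panel, env))
  dir <- withr::local_tempdir()
  write_simulation(panel, env, tr, dir)
  files <- list.files(dir)
  expect_true(all(c("genotypes.vcf", "genotypes.tsv", "metadata.csv",
                    "environments.csv", "true_scenarios.csv", "trial.csv",
                    "true_selected_loci.csv", "true_dag.csv",
                    "effect_table.csv") %in% files))
  G <- read_genotypes(file.path(dir, "genotypes.vcf"))
  expect_equal(unname(G$geno), unname(panel$geno$geno))
})
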