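balanced_trial <- function(n_h = 6, n_e = 4, seed = 1, sd = 0.5) {
  set.seed(seed)
  g <- rnorm(n_h, 10, 2)
  e <- rnorm(n_e, 0, 1)
  d <- expand.grid(hybrid = sprintf("h%d", 1:n_h),
                   experiment = sprintf("e%d", 1:n_e),
                   stringsAsFactors = FALSE)
  d$gn <- g[match(d$hybrid, sprintf("h%d", 1:n_h))] +
    e[match(d$experiment, sprintf("e%d", 1:n_e))] + rnorm(nrow(d), 0, sd)
  d$scenario <- "all"
  d
}

test_that("BLUEs equal simple means on a balanced complete design", {
  d <- balanced_trial()
  m <- genotype_means(d, group_by = "none")
  simple <- tapply(d$gn, d$hybrid, mean)
  expect_equal(m[names(simple), "all"], c(simple), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("BLUEs approach arithmetic means when experiments are identical", {
  d <- balanced_trial()
  d$gn <- d$gn - ave(d$gn, d$experiment) + mean(d$gn)  # remove exp effects
  m <- genotype_means(d, group_by = "none")
  simple <- tapply(d$gn, d$hybrid, mean)
  expect_equal(m[names(simple), "all"], c(simple), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("unbalanced BLUEs agree with an independent mixed-model fit", {
  skip_if_not_installed("lme4")
  set.seed(12)
  d <- balanced_trial(n_h = 5, n_e = 4, sd = 1)
  d <- d[-sample(nrow(d), 6), ]               # unbalance
  m <- genotype_means(d, group_by = "none")
  fit <- lme4::lmer(gn ~ 0 + hybrid + (1 | experiment), data = d,
                    REML = TRUE)
  ours <- m[, "all"]
  theirs <- lme4::fixef(fit)
  names(theirs) <- sub("^hybrid", "", names(theirs))
  expect_equal(ours[names(theirs)], theirs, tolerance = 1e-4)
})

test_that("hybrids absent from a group get NA, few experiments fall back", {
  d <- balanced_trial(n_h = 4, n_e = 4)
  d$scenario <- ifelse(d$experiment %in% c("e1", "e2"), "A", "B")
  d <- d[!(d$hybrid == "h1" & d$scenario == "B"), ]
  m <- genotype_means(d, group_by = "scenario")
  expect_false(is.na(m["h1", "A"]))
  expect_true(is.na(m["h1", "B"]))
  one <- balanced_trial(n_h = 3, n_e = 1)
  expect_warning(m1 <- genotype_means(one, group_by = "none"),
                 "arithmetic")
  expect_equal(m1[, "all"],
               c(tapply(one$gn, one$hybrid, mean))[rownames(m1)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("genetic gain handles constant, exact and noisy trends", {
  years <- seq(1950, 2015, length.out = 30)
  gg0 <- suppressWarnings(genetic_gain(rep(5, 30), years))
  expect_equal(gg0$slope, 0)
  expect_equal(gg0$p_value, 1)
  gg2 <- suppressWarnings(genetic_gain(2 * years, years))
  expect_equal(gg2$slope, 2, tolerance = 1e-10)
  expect_equal(gg2$r2, 1)
  set.seed(3)
  ggn <- genetic_gain(0.1 * years + rnorm(30, 0, 1), years)
  expect_true(ggn$ci[1] < 0.1 && 0.1 < ggn$ci[2])
})

test_that("sequential SS on an orthogonal design match hand computation", {
  years <- c(-3, -1, 1, 3)
  g_res <- c(1, -1, -1, 1)                   # orthogonal to years
  s_eff <- c(A = 2, B = -2)
  e_dev <- c(e1 = 1, e2 = -1, e3 = 1, e4 = -1)
  scen_of <- c(e1 = "A", e2 = "A", e3 = "B", e4 = "B")
  d <- expand.grid(hybrid = sprintf("h%d", 1:4),
                   experiment = names(scen_of), stringsAsFactors = FALSE)
  d$scenario <- scen_of[d$experiment]
  d$year <- 2000 + years[match(d$hybrid, sprintf("h%d", 1:4))]
  d$gn <- 10 + 0.5 * years[match(d$hybrid, sprintf("h%d", 1:4))] +
    g_res[match(d$hybrid, sprintf("h%d", 1:4))] +
    s_eff[d$scenario] + e_dev[d$experiment]
  vp <- suppressWarnings(partition_variance(d))
  ss <- setNames(vp$ss, vp$term)
  # hand: each hybrid appears in 4 experiments, each experiment has 4 hybrids
  expect_equal(unname(ss["G_year"]), 4 * 0.25 * sum(years^2))
  expect_equal(unname(ss["G_res"]), 4 * sum(g_res^2))
  expect_equal(unname(ss["Scen"]), 4 * sum((s_eff[scen_of] - 0)^2))
  expect_equal(unname(ss["E_res"]), 4 * sum(e_dev^2))
  expect_lt(unname(ss["residual"]), 1e-10)
  expect_equal(sum(vp$proportion), 1, tolerance = 1e-8)
})

test_that("partition proportions are affine-invariant and detect pure signal", {
  cfg <- sim_config(n_hybrids = 30, n_snps = 200, n_experiments_per_scenario = 2,
                    seed = 41)
  env <- simulate_environments(cfg)
  panel <- simulate_panel(cfg)
  trial <- simulate_trial(cfg, panel, env)$trial
  vp1 <- partition_variance(trial)
  trial2 <- trial
  trial2$gn <- 3 + 7 * trial2$gn
  vp2 <- partition_variance(trial2)
  expect_equal(vp2$proportion, vp1$proportion, tolerance = 1e-8)
  # pure year trend and nothing else
  d <- balanced_trial(n_h = 10, n_e = 4, sd = 0)
  d$year <- rep(seq(1950, 2013, length.out = 10), 4)
  d$gn <- 5 + 0.1 * d$year
  d$scenario <- rep(c("A", "B"), each = 20)
  vp3 <- suppressWarnings(partition_variance(d))
  expect_gt(vp3$proportion[vp3$term == "G_year"], 0.98)
})

test_that("pure-noise responses put almost everything in the residual", {
  set.seed(51)
  n_h <- 100; n_e <- 50
  d <- expand.grid(hybrid = sprintf("h%03d", 1:n_h),
                   experiment = sprintf("e%02d", 1:n_e),
                   stringsAsFactors = FALSE)
  d$year <- rep(seq(1950, 2015, length.out = n_h), n_e)
  d$scenario <- rep(rep(c("s1", "s2", "s3"), length.out = n_e), each = n_h)
  d$gn <- rnorm(nrow(d))
  vp <- partition_variance(d)
  nonres <- vp$proportion[vp$term != "residual"]
  expect_true(all(nonres < 0.02))
})

test_that("forward-backward selection drops inert terms", {
  set.seed(61)
  n_h <- 40; n_e <- 12
  d <- expand.grid(hybrid = sprintf("h%02d", 1:n_h),
                   experiment = sprintf("e%02d", 1:n_e),
                   stringsAsFactors = FALSE)
  d$year <- rep(seq(1950, 2015, length.out = n_h), n_e)
  d$scenario <- rep(rep(c("s1", "s2"), each = n_e / 2), each = n_h)
  d$gn <- 0.15 * d$year + rnorm(nrow(d), 0, 1)   # only a year trend
  vp <- partition_variance(d, selection = "forward-backward")
  expect_gt(vp$proportion[vp$term == "G_year"], 0.5)
  expect_equal(vp$proportion[vp$term == "G_year_x_Scen"], 0)
})

test_that("factorial regression recovers planted water-potential sensitivities", {
  set.seed(71)
  n_h <- 40; n_e <- 16
  psi <- rep(c(-0.05, -0.3), each = n_e / 2) + rnorm(n_e, 0, 0.03)
  rint <- rnorm(n_e, 350, 20)
  beta1 <- c(rep(-50, n_h / 2), rep(0, n_h / 2))   # GN per MPa
  d <- expand.grid(hybrid = sprintf("h%02d", 1:n_h),
                   experiment = sprintf("e%02d", 1:n_e),
                   stringsAsFactors = FALSE)
  hi <- match(d$hybrid, sprintf("h%02d", 1:n_h))
  ei <- match(d$experiment, sprintf("e%02d", 1:n_e))
  d$gn <- 3000 + 10 * hi + 30 * (ei %% 3) +
    beta1[hi] * (psi[ei] - mean(psi)) + rnorm(nrow(d), 0, 3)
  d$psi <- psi[ei]
  d$r_int <- rint[ei]
  sens <- factorial_regression(d)
  expect_true("psi" %in% attr(sens, "admitted"))
  grp <- rep(c("sensitive", "flat"), each = n_h / 2)
  m <- tapply(sens$beta1, grp, mean)
  se_grp <- sqrt(tapply(sens$beta1, grp, var) / (n_h / 2))
  sep <- abs(m["sensitive"] - m["flat"]) / sqrt(sum(se_grp^2))
  expect_gt(sep, 3)
})

test_that("environment-invariant genotypes show null sensitivities", {
  set.seed(81)
  n_h <- 30; n_e <- 20
  psi <- rnorm(n_e, -0.2, 0.1)
  d <- expand.grid(hybrid = sprintf("h%02d", 1:n_h),
                   experiment = sprintf("e%02d", 1:n_e),
                   stringsAsFactors = FALSE)
  hi <- match(d$hybrid, sprintf("h%02d", 1:n_h))
  ei <- match(d$experiment, sprintf("e%02d", 1:n_e))
  d$gn <- 3000 + 5 * hi + 20 * ei + rnorm(nrow(d), 0, 5)
  d$psi <- psi[ei]
  d$r_int <- rnorm(n_e, 350, 20)[ei]
  sens <- factorial_regression(d)
  if (length(attr(sens, "admitted"))) {
    expect_gte(mean(abs(sens$t1) < 2, na.rm = TRUE), 0.9)
  } else {
    expect_true(all(is.na(sens$beta1)))
  }
})

test_that("a constant environmental index is never admitted", {
  d <- balanced_trial(n_h = 10, n_e = 6)
  d$psi <- -0.2
  d$r_int <- rnorm(6, 350, 30)[match(d$experiment, sprintf("e%d", 1:6))]
  sens <- factorial_regression(d)
  expect_false("psi" %in% attr(sens, "admitted"))
  expect_true(all(is.na(sens$beta1)))
})
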