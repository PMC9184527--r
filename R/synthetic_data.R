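## Synthetic era panels, environments, and multi-environment trials with
## known ground truth, emulating a 1950-2015 European maize genetic
## progress panel.

## B73-like chromosome lengths (bp), 10 chromosomes
.default_chrom_lengths <- c(3.01e8, 2.37e8, 2.32e8, 2.42e8, 2.17e8,
                            1.69e8, 1.76e8, 1.75e8, 1.57e8, 1.49e8)

#' Default ground-truth QTL effect table
#'
#' Six QTLs mirroring the structure of published maize yield QTLs: three
#' constitutive loci (flowering time / architecture) with stable positive
#' effects of 0.10-0.24 t/ha across all scenarios (mean about +0.18), and
#' three adaptive loci (ABA synthesis, stomatal conductance, temperature
#' response) whose effects flip sign between well-watered and
#' water-deficit (or cool and hot) scenarios, spanning about -0.16 to
#' +0.17 t/ha. Marker ids are placeholders filled in by
#' [simulate_panel()].
#'
#' @return An [effect_table()].
#' @export
default_effect_table <- function() {
  eff <- rbind(
    # qtl      cool_WW warm_WW hot_WW cool_WD warm_WD hot_WD
    c1 = c(0.12, 0.11, 0.10, 0.13, 0.12, 0.11),
    c2 = c(0.24, 0.23, 0.22, 0.24, 0.23, 0.22),
    c3 = c(0.18, 0.17, 0.16, 0.19, 0.18, 0.17),
    a1 = c(0.10, 0.08, 0.05, -0.12, -0.14, -0.16),
    a2 = c(0.12, 0.10, 0.06, -0.10, -0.13, -0.15),
    a3 = c(0.17, 0.02, -0.14, 0.10, -0.02, -0.12))
  colnames(eff) <- .scenario_levels[c(1, 2, 3, 4, 5, 6)]
  effect_table(qtl = rownames(eff),
               marker = paste0("pending_", rownames(eff)),
               class = c(rep("constitutive", 3), rep("adaptive", 3)),
               favorable_allele = rep("?", 6),
               effects = eff)
}

#' Simulation configuration
#'
#' Defines the study conditions of a synthetic era panel: a two-ancestry
#' structured population whose mixture proportion drifts with year of
#' release (emulating the documented Iodent shift, and hence a leading
#' PCA axis correlated with year), a minority of loci with logit-linear
#' year trends in allele frequency, six environmental scenarios
#' (cool/warm/hot x WW/WD), and a grain-yield trend of about
#' 101 kg/ha/yr carried by mediating traits (vegetative duration, silk
#' number, canopy leaf-area distribution).
#'
#' @param n_hybrids number of hybrids (default 60, the genotyped panel
#'   size).
#' @param year_range first and last year of release (default 1950-2015).
#' @param n_snps number of SNPs (default 10000).
#' @param chrom_lengths bp per chromosome (default: 10 maize-like
#'   chromosomes).
#' @param n_selected_loci number of loci with a year trend (default 50).
#' @param trend_slope per-year logit-scale change in selected-allele
#'   frequency (default 0.05).
#' @param structure_mix list/vector with elements `intercept`, `slope`
#'   (logit admixture per year), `sd` (hybrid-level logit noise).
#' @param ancestry_fst differentiation between the two ancestral pools
#'   (Balding-Nichols F, default 0.15).
#' @param n_qtls_stable,n_qtls_adaptive counts of constitutive/adaptive
#'   QTLs (defaults 3 and 3; must match `scenario_effects`).
#' @param scenario_effects ground-truth [effect_table()] (default
#'   [default_effect_table()]).
#' @param n_experiments_per_scenario experiments per scenario (default 4,
#'   i.e. 24 fields).
#' @param gain_per_year yield trend in kg/ha/yr (default 101).
#' @param var_components named variances (t/ha squared):
#'   `genetic` (total genotypic main effect, including the year trend),
#'   `environment`, `gxe`, `residual`.
#' @param env_dispersion multiplier on within-scenario covariate SDs
#'   (default 1; the source study does not report this dispersion, so it
#'   is a free parameter).
#' @param missing_rate missing-genotype fraction (default 0.02).
#' @param seed integer seed fixing all outputs bit-identically.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_hybrids = 60, year_range = c(1950, 2015),
                       n_snps = 10000,
                       chrom_lengths = .default_chrom_lengths,
                       n_selected_loci = 50, trend_slope = 0.05,
                       structure_mix = c(intercept = 0, slope = 0.06,
                                         sd = 0.8),
                       ancestry_fst = 0.15,
                       n_qtls_stable = 3, n_qtls_adaptive = 3,
                       scenario_effects = default_effect_table(),
                       n_experiments_per_scenario = 4,
                       gain_per_year = 101,
                       var_components = c(genetic = 5, environment = 2.25,
                                          gxe = 0.25, residual = 0.25),
                       env_dispersion = 1, missing_rate = 0.02, seed = 1) {
  cfg <- list(n_hybrids = n_hybrids, year_range = year_range,
              n_snps = n_snps, chrom_lengths = chrom_lengths,
              n_selected_loci = n_selected_loci, trend_slope = trend_slope,
              structure_mix = structure_mix, ancestry_fst = ancestry_fst,
              n_qtls_stable = n_qtls_stable,
              n_qtls_adaptive = n_qtls_adaptive,
              scenario_effects = scenario_effects,
              n_experiments_per_scenario = n_experiments_per_scenario,
              gain_per_year = gain_per_year,
              var_components = var_components,
              env_dispersion = env_dispersion,
              missing_rate = missing_rate, seed = seed)
  .assert(n_hybrids > 0 && n_snps > 0, "counts must be > 0")
  .assert(length(year_range) == 2 && year_range[2] > year_range[1],
          "invalid config: degenerate year range")
  .assert(all(chrom_lengths > 0), "chromosome lengths must be positive")
  .assert(n_selected_loci >= 0 && n_selected_loci <= n_snps,
          "invalid config: n_selected_loci exceeds n_snps")
  .assert(ancestry_fst > 0 && ancestry_fst < 1, "ancestry_fst in (0,1)")
  .assert(all(var_components >= 0), "variances must be >= 0")
  .assert(missing_rate >= 0 && missing_rate < 1, "missing_rate in [0,1)")
  .assert(n_qtls_stable >= 0 && n_qtls_adaptive >= 0, "negative QTL count")
  .assert(sum(n_experiments_per_scenario) > 0,
          "invalid config: no experiments")
  .assert(n_qtls_stable + n_qtls_adaptive <=
            nrow(scenario_effects),
          "effect table smaller than requested QTL counts")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an era panel: genotypes and release-year metadata
#'
#' Hybrid years of release span the year range uniformly. Neutral SNP
#' frequencies follow a two-ancestry Balding-Nichols model whose mixture
#' proportion is a logistic function of year plus hybrid-level noise
#' (`structure_mix`), producing a leading PCA axis correlated with year.
#' Selected loci add a logit-linear frequency trend of `trend_slope` per
#' year. Genotypes are binomial(2, p) draws, missing entries are
#' missing-completely-at-random, and marker positions are uniform within
#' chromosomes (chromosome picked proportional to length).
#'
#' @param config a [sim_config()].
#' @return List: `geno` ([genotype_matrix()]), `meta` (data frame
#'   `hybrid`, `year`, `group` in old/intermediate/recent year terciles),
#'   `truth` (selected-locus ids, QTL marker assignments + effect table
#'   with alleles resolved, admixture proportions).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_panel_impl(config))
}

.simulate_panel_impl <- function(cfg) {
  n <- cfg$n_hybrids
  m <- cfg$n_snps
  years <- round(seq(cfg$year_range[1], cfg$year_range[2], length.out = n))
  yc <- years - mean(range(years))
  hyb <- sprintf("hyb%03d", seq_len(n))

  # marker map
  nchr <- length(cfg$chrom_lengths)
  chr_of <- sample.int(nchr, m, replace = TRUE,
                       prob = cfg$chrom_lengths / sum(cfg$chrom_lengths))
  pos <- floor(stats::runif(m) * cfg$chrom_lengths[chr_of])
  ord <- order(chr_of, pos)
  chr_of <- chr_of[ord]; pos <- pos[ord]
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), "")
  map <- data.frame(id = sprintf("snp%05d", seq_len(m)),
                    chrom = sprintf("chr%d", chr_of), pos = pos,
                    ref = ref, alt = alt, stringsAsFactors = FALSE)

  # two-ancestry Balding-Nichols frequencies
  Fst <- cfg$ancestry_fst
  p0 <- stats::runif(m, 0.05, 0.95)
  shp <- p0 * (1 - Fst) / Fst
  shq <- (1 - p0) * (1 - Fst) / Fst
  pA <- stats::rbeta(m, shp, shq)
  pB <- stats::rbeta(m, shp, shq)
  sm <- cfg$structure_mix
  w <- stats::plogis(sm[["intercept"]] + sm[["slope"]] * yc +
                       stats::rnorm(n, 0, sm[["sd"]]))
  P <- outer(w, pA) + outer(1 - w, pB)            # n x m expected freqs

  # selected loci: logit-linear trend in year replaces the neutral drift
  sel <- if (cfg$n_selected_loci > 0) {
    sort(sample.int(m, cfg$n_selected_loci))
  } else integer(0)
  if (length(sel)) {
    base <- stats::runif(length(sel), 0.3, 0.7)
    P[, sel] <- stats::plogis(
      matrix(stats::qlogis(base), n, length(sel), byrow = TRUE) +
        outer(yc, rep(cfg$trend_slope, length(sel))))
  }
  P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
  geno <- matrix(stats::rbinom(n * m, 2, P), n, m)
  if (cfg$missing_rate > 0) {
    drop <- stats::runif(n * m) < cfg$missing_rate
    geno[drop] <- NA_integer_
  }
  rownames(geno) <- hyb
  G <- genotype_matrix(geno, map)

  tert <- stats::quantile(years, c(1 / 3, 2 / 3))
  meta <- data.frame(hybrid = hyb, year = years,
                     group = cut(years, c(-Inf, tert, Inf),
                                 labels = c("old", "intermediate",
                                            "recent")),
                     stringsAsFactors = FALSE)

  # assign QTL peak markers: constitutive QTLs on selected (trending)
  # loci, adaptive QTLs on neutral loci -- matching the observed contrast
  # of rising favorable-allele frequencies at stable-effect QTLs only
  eff <- cfg$scenario_effects
  n_c <- cfg$n_qtls_stable; n_a <- cfg$n_qtls_adaptive
  eff <- eff[order(match(eff$class, c("constitutive", "adaptive"))), ]
  eff <- rbind(utils::head(eff[eff$class == "constitutive", ], n_c),
               utils::head(eff[eff$class == "adaptive", ], n_a))
  neutral <- setdiff(seq_len(m), sel)
  .assert(length(neutral) >= n_a,
          "too few neutral loci to place %d adaptive QTLs", n_a)
  cand_c <- if (n_c > 0) sel[seq_len(min(n_c, length(sel)))] else integer(0)
  if (length(cand_c) < n_c) {
    cand_c <- c(cand_c, sample(neutral, n_c - length(cand_c)))
  }
  cand_a <- if (n_a > 0) sample(neutral, n_a) else integer(0)
  qtl_cols <- c(cand_c, cand_a)
  if (nrow(eff)) {
    eff$marker <- map$id[qtl_cols]
    # favorable allele = alt allele (whose count the trend increases)
    eff$favorable_allele <- map$alt[qtl_cols]
  }
  list(geno = G, meta = meta,
       truth = list(selected = map$id[sel], admixture = w,
                    qtl_cols = qtl_cols, effects = eff))
}

#' Simulate field-experiment environments for the six scenarios
#'
#' Each experiment draws phase-wise covariates from scenario-specific
#' normal distributions centred near the reported scenario means
#' (flowering-phase Tmin 15/17/18 degC and Tmax 25/28/30 degC for
#' cool/warm/hot), and a mean soil water potential above (WW, centred at
#' -0.05 MPa) or below (WD, centred at -0.4 MPa) the -0.1 MPa threshold.
#' Planted scenario labels are stored for recovery tests.
#'
#' @param config a [sim_config()].
#' @return List: `envs` ([env_records()]), `truth` (data frame
#'   `experiment`, `temp_class`, `water_class`, `scenario`).
#' @export
simulate_environments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1, .simulate_env_impl(config))
}

.simulate_env_impl <- function(cfg) {
  temp_means <- data.frame(temp = c("cool", "warm", "hot"),
                           tmin_flo = c(15, 17, 18),
                           tmax_flo = c(25, 28, 30))
  n_per <- rep(cfg$n_experiments_per_scenario, length.out = 6)
  disp <- cfg$env_dispersion
  rows <- list()
  k <- 0
  for (ti in 1:3) for (wi in 1:2) {
    sidx <- (wi - 1) * 3 + ti
    nexp <- n_per[sidx]
    if (nexp == 0) next
    temp <- temp_means$temp[ti]
    water <- c("WW", "WD")[wi]
    for (r in seq_len(nexp)) {
      k <- k + 1
      tmin_f <- stats::rnorm(1, temp_means$tmin_flo[ti], 0.35 * disp)
      tmax_f <- stats::rnorm(1, temp_means$tmax_flo[ti], 0.5 * disp)
      tmax_f <- max(tmax_f, tmin_f + 4)
      psi <- if (water == "WW") {
        min(stats::rnorm(1, -0.05, 0.015 * disp), -0.001)
      } else {
        stats::rnorm(1, -0.4, 0.08 * disp)
      }
      psi <- if (water == "WW") max(psi, -0.099) else min(psi, -0.101)
      light_base <- c(cool = 315, warm = 350, hot = 385)[[temp]]
      rows[[k]] <- data.frame(
        experiment = sprintf("exp%02d", k),
        light_veg = max(stats::rnorm(1, light_base, 12 * disp), 1),
        light_flo = max(stats::rnorm(1, 150 + 10 * (ti - 2), 6 * disp), 1),
        light_gf = max(stats::rnorm(1, 450 + 25 * (ti - 2), 15 * disp), 1),
        tmin_veg = tmin_f - 1.5 + stats::rnorm(1, 0, 0.3 * disp),
        tmin_flo = tmin_f,
        tmin_gf = tmin_f + 0.5 + stats::rnorm(1, 0, 0.3 * disp),
        tmax_veg = tmax_f - 1 + stats::rnorm(1, 0, 0.4 * disp),
        tmax_flo = tmax_f,
        tmax_gf = tmax_f + 0.5 + stats::rnorm(1, 0, 0.4 * disp),
        psi = psi,
        temp_class = temp, water_class = water,
        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, rows)
  all$tmin_veg <- pmin(all$tmin_veg, all$tmax_veg - 0.5)
  all$tmin_gf <- pmin(all$tmin_gf, all$tmax_gf - 0.5)
  envs <- env_records(all$experiment, all$light_veg, all$light_flo,
                      all$light_gf, all$tmin_veg, all$tmin_flo,
                      all$tmin_gf, all$tmax_veg, all$tmax_flo,
                      all$tmax_gf, all$psi)
  truth <- data.frame(experiment = all$experiment,
                      temp_class = all$temp_class,
                      water_class = all$water_class,
                      scenario = paste(all$temp_class, all$water_class,
                                       sep = "_"),
                      stringsAsFactors = FALSE)
  list(envs = envs, truth = truth)
}

## grams per grain used to convert yield (t/ha) to grain number per m2
.grain_weight_g <- 0.30

#' Simulate a multi-environment trial with known mediation structure
#'
#' Grain yield per (hybrid, experiment) is built from: a year-of-release
#' trend of `gain_per_year` flowing through mediating traits (vegetative
#' duration, silk number, and leaf-area distribution -> ear-layer light)
#' plus a direct residual year effect; QTL allelic effects looked up by
#' the experiment's scenario; a scenario main effect plus
#' experiment-within-scenario deviations (scaled to the `environment`
#' variance, 76% of it between scenarios); a G x E term; and residual
#' noise. The mediating traits follow the known DAG
#' year -> {veg, silk, rh_pad}, rh_pad -> ear_light,
#' {veg, silk, ear_light} -> gn, whose true arc set is returned for
#' recovery tests. Grain number is yield divided by a fixed grain weight.
#'
#' @param config a [sim_config()].
#' @param panel result of [simulate_panel()].
#' @param envs result of [simulate_environments()].
#' @return List: `trial` (trial table, one record per hybrid x
#'   experiment), `truth` (true DAG arcs, trait effect sizes, variance
#'   parts).
#' @export
simulate_trial <- function(config, panel, envs) {
  stopifnot(inherits(config, "sim_config"))
  .assert(identical(panel$meta$hybrid, rownames(panel$geno$geno)),
          "genotype/metadata hybrid mismatch")
  with_seed(config$seed + 2, .simulate_trial_impl(config, panel, envs))
}

.simulate_trial_impl <- function(cfg, panel, envs) {
  meta <- panel$meta
  n <- nrow(meta)
  yc <- meta$year - mean(meta$year)
  gain <- cfg$gain_per_year / 1000          # t/ha per year
  vc <- cfg$var_components

  # mediating traits (genotypic values); slopes give the year trend
  veg <- 55 + 0.154 * yc + stats::rnorm(n, 0, 1.5)      # d20
  silk <- 30 + 0.100 * yc + stats::rnorm(n, 0, 2.0)     # silk count
  rh_pad <- 0.50 + 0.0012 * yc + stats::rnorm(n, 0, 0.01)
  rh_pad <- pmin(pmax(rh_pad, 0.01), 0.99)
  ear_light <- 0.20 + 0.50 * (rh_pad - 0.50) + stats::rnorm(n, 0, 0.003)

  env <- envs$envs
  scen <- envs$truth$scenario
  ne <- nrow(env)

  # QTL contributions, centred allele counts, scenario-conditional effects
  eff <- panel$truth$effects
  qtl_term <- matrix(0, n, ne)
  if (!is.null(eff) && nrow(eff)) {
    cnt <- panel$geno$geno[, panel$truth$qtl_cols, drop = FALSE]
    cnt[is.na(cnt)] <- 1L
    cnt <- sweep(cnt, 2, colMeans(cnt))
    for (qi in seq_len(nrow(eff))) {
      e_scen <- unlist(eff[qi, .scenario_levels])[scen]
      qtl_term <- qtl_term + outer(cnt[, qi], as.numeric(e_scen))
    }
  }
  # year trend already carried by the QTLs (their frequencies drift with
  # era); the trait-mediated trend is reduced accordingly so that the
  # total expected genotypic trend equals gain_per_year
  q_h <- rowMeans(qtl_term)
  slope_q <- stats::cov(q_h, yc) / stats::var(yc)

  # trait -> yield coefficients: mediated year slope shares 20/20/48%,
  # direct residual year effect 12% of the total gain
  b_veg <- 0.20 * gain / 0.154
  b_silk <- 0.20 * gain / 0.100
  b_light <- 0.48 * gain / (0.50 * 0.0012)
  b_direct <- 0.12 * gain - slope_q
  g_med <- b_veg * (veg - mean(veg)) + b_silk * (silk - mean(silk)) +
    b_light * (ear_light - mean(ear_light)) + b_direct * yc
  v_med <- stats::var(g_med + q_h)
  v_res <- max(vc[["genetic"]] - v_med, 0)
  if (vc[["genetic"]] > 0 && v_res == 0) {
    warning("year-mediated genetic variance exceeds the genetic target; ",
            "G_res set to zero")
  }
  g_res <- stats::rnorm(n, 0, sqrt(v_res))
  g_res <- g_res - mean(g_res)
  g_tot <- g_med + g_res

  # environment main effect: 76% of variance between scenarios
  scen_lev <- unique(scen)
  scen_base <- c(cool_WW = 0.9, warm_WW = 0.5, hot_WW = -0.1,
                 cool_WD = -0.1, warm_WD = -0.4, hot_WD = -0.8)
  scen_eff <- scen_base[scen]
  exp_dev <- stats::rnorm(ne, 0, 1)
  exp_dev <- exp_dev - stats::ave(exp_dev, scen)       # centre in scenario
  rescale <- function(x, v) {
    if (stats::var(x) < 1e-12 || v <= 0) return(x * 0)
    x * sqrt(v / stats::var(x))
  }
  scen_eff <- rescale(scen_eff - mean(scen_eff), 0.76 * vc[["environment"]])
  exp_dev <- rescale(exp_dev, 0.24 * vc[["environment"]])
  e_tot <- scen_eff + exp_dev

  # year x scenario slope heterogeneity (GEI_year, ~1% of variance at the
  # default gain); proportional to the gain so a no-trend panel has none.
  # Its realised variance is carved out of the G x E budget so the total
  # interaction variance stays at var_components["gxe"].
  slope_dev <- stats::rnorm(length(scen_lev), 0, 0.15 * gain)
  names(slope_dev) <- scen_lev
  # centre across experiments: interaction deviations, not a mean slope
  slope_dev <- slope_dev - mean(slope_dev[scen])
  gei_year <- outer(yc, slope_dev[scen])
  v_gei <- stats::var(as.numeric(gei_year))
  v_gxe <- vc[["gxe"]] - v_gei
  if (v_gxe < 0) {
    warning("year x scenario heterogeneity exceeds the gxe budget")
    v_gxe <- 0
  }
  gxe <- matrix(stats::rnorm(n * ne, 0, sqrt(v_gxe)), n, ne)
  resid <- matrix(stats::rnorm(n * ne, 0, sqrt(vc[["residual"]])), n, ne)

  yield <- 9 + outer(g_tot, e_tot, "+") + qtl_term + gei_year + gxe + resid
  yield <- pmax(yield, 0.1)
  gn <- yield * 100 / .grain_weight_g              # grains per m2

  trial <- data.frame(
    hybrid = rep(meta$hybrid, ne),
    experiment = rep(env$experiment, each = n),
    scenario = rep(scen, each = n),
    temp_class = rep(envs$truth$temp_class, each = n),
    water_class = rep(envs$truth$water_class, each = n),
    year = rep(meta$year, ne),
    yield = as.numeric(yield),
    gn = as.numeric(gn),
    veg = rep(veg, ne),
    silk = rep(silk, ne),
    rh_pad = rep(rh_pad, ne),
    ear_light = rep(ear_light, ne),
    psi = rep(env$psi, each = n),
    r_int = rep(env$light_veg, each = n),
    stringsAsFactors = FALSE)
  true_dag <- rbind(c("year", "veg"), c("year", "silk"),
                    c("year", "rh_pad"), c("rh_pad", "ear_light"),
                    c("veg", "gn"), c("silk", "gn"), c("ear_light", "gn"),
                    c("year", "gn"))
  colnames(true_dag) <- c("from", "to")
  list(trial = trial,
       truth = list(dag = true_dag,
                    coef = c(veg = b_veg, silk = b_silk,
                             ear_light = b_light, year_direct = b_direct),
                    scen_eff = scen_eff, exp_dev = exp_dev,
                    g_total = g_tot, slope_dev = slope_dev))
}

#' Write a full simulation to disk
#'
#' Genotypes as VCF and additive matrix, metadata / environments / trial
#' as CSV, and the ground-truth files (selected loci, true DAG, true
#' scenario labels, resolved effect table) as CSV for test harnesses.
#'
#' @param panel,envs,trial results of the three simulators.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(panel, envs, trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(panel$geno, file.path(dir, "genotypes.vcf"), "vcf")
  write_genotypes(panel$geno, file.path(dir, "genotypes.tsv"), "matrix")
  utils::write.csv(panel$meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(envs$envs, file.path(dir, "environments.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(envs$truth, file.path(dir, "true_scenarios.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(trial$trial, file.path(dir, "trial.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(id = panel$truth$selected),
                   file.path(dir, "true_selected_loci.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(trial$truth$dag),
                   file.path(dir, "true_dag.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(panel$truth$effects) && nrow(panel$truth$effects)) {
    write_effect_table(panel$truth$effects,
                       file.path(dir, "effect_table.csv"))
  }
  invisible(dir)
}
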