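## Multi-environment trial models: genotype means (BLUEs), genetic gain,
## variance partition of grain number, factorial regression on
## environmental indices.

.check_trial <- function(trial, response) {
  .assert(is.data.frame(trial), "trial must be a data frame")
  .assert(all(c("hybrid", "experiment") %in% names(trial)),
          "trial needs 'hybrid' and 'experiment' columns")
  .assert(response %in% names(trial), "response column '%s' missing", response)
  .assert(!anyDuplicated(trial[, c("hybrid", "experiment")]),
          "duplicate (hybrid, experiment) records")
  invisible(TRUE)
}

## One-random-factor REML by golden-section search on the profiled
## variance ratio gamma = var(experiment) / var(error). The marginal
## covariance I + gamma Z Z' is block diagonal by experiment, so all
## quadratic forms reduce to per-experiment sums.
.reml_blue <- function(y, hybrid, experiment, tol = 1e-8) {
  hybrid <- factor(hybrid)
  experiment <- factor(experiment)
  p <- nlevels(hybrid)
  n <- length(y)
  Tmat <- table(hybrid, experiment)              # p x q incidence counts
  nj <- colSums(Tmat)                            # records per experiment
  nh <- rowSums(Tmat)                            # records per hybrid
  sj <- as.numeric(tapply(y, experiment, sum))
  Xty <- as.numeric(tapply(y, hybrid, sum))
  yty <- sum(y^2)
  Tm <- unclass(Tmat)

  crit <- function(log10g) {
    g <- 10^log10g
    cj <- g / (1 + g * nj)
    A <- diag(nh, p) - Tm %*% (cj * t(Tm))
    b <- Xty - Tm %*% (cj * sj)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(val = Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), as.numeric(b)))
    yVy <- yty - sum(cj * sj^2)
    rss <- max(yVy - sum(b * beta), 1e-300)
    sigma2 <- rss / (n - p)
    val <- (n - p) * log(sigma2) + sum(log1p(g * nj)) +
      2 * sum(log(diag(ch)))
    list(val = val, beta = beta, sigma2 = sigma2, A = A, chol = ch)
  }

  # golden-section minimisation of the REML criterion over log10(gamma)
  gr <- (sqrt(5) - 1) / 2
  lo <- -8; hi <- 8
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- crit(x1)$val; f2 <- crit(x2)$val
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- crit(x1)$val
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- crit(x2)$val
    }
  }
  opt <- (lo + hi) / 2
  # compare against the gamma -> 0 boundary (ordinary least squares limit)
  if (crit(-12)$val < crit(opt)$val) opt <- -12
  fit <- crit(opt)
  Ainv_diag <- diag(chol2inv(fit$chol))
  est <- as.numeric(fit$beta)
  names(est) <- levels(hybrid)
  list(estimate = est,
       se = sqrt(fit$sigma2 * Ainv_diag),
       gamma = 10^opt, sigma_e2 = fit$sigma2,
       sigma_exp2 = 10^opt * fit$sigma2)
}

#' Genotype means per group from a one-random-factor mixed model
#'
#' Best linear unbiased estimates of hybrid means: fixed hybrid effects,
#' random experiment effects, fitted by REML via golden-section search on
#' the profiled variance ratio (tolerance 1e-8). Groups with fewer than
#' two experiments fall back to arithmetic means with a warning. Hybrids
#' absent from a group get `NA`.
#'
#' @param trial trial table with columns `hybrid`, `experiment`, the
#'   response, and the grouping column if used.
#' @param response response column name (default `"gn"`).
#' @param group_by `"scenario"`, any other column name, or `"none"` for a
#'   single group.
#' @return Matrix hybrids x groups of estimates; attribute `details` holds
#'   per-group variance components and standard errors.
#' @export
genotype_means <- function(trial, response = "gn", group_by = "scenario") {
  .check_trial(trial, response)
  if (identical(group_by, "none")) {
    groups <- rep("all", nrow(trial))
  } else {
    .assert(group_by %in% names(trial), "grouping column '%s' missing",
            group_by)
    groups <- as.character(trial[[group_by]])
  }
  hybrids <- sort(unique(as.character(trial$hybrid)))
  glev <- unique(groups)
  out <- matrix(NA_real_, length(hybrids), length(glev),
                dimnames = list(hybrids, glev))
  details <- list()
  for (g in glev) {
    sub <- trial[groups == g, , drop = FALSE]
    y <- sub[[response]]
    if (length(unique(sub$experiment)) < 2) {
      warning(sprintf(
        "group '%s' has < 2 experiments; using arithmetic means", g))
      m <- tapply(y, as.character(sub$hybrid), mean)
      out[names(m), g] <- m
      details[[g]] <- list(method = "arithmetic")
    } else {
      fit <- .reml_blue(y, sub$hybrid, sub$experiment)
      out[names(fit$estimate), g] <- fit$estimate
      details[[g]] <- c(fit[c("gamma", "sigma_e2", "sigma_exp2")],
                        list(se = fit$se, method = "reml"))
    }
  }
  attr(out, "details") <- details
  out
}

#' Genetic gain: regression of a trait on year of release
#'
#' @param means named numeric vector of per-hybrid trait values (e.g. one
#'   column of [genotype_means()]).
#' @param years year of release, aligned with `means`.
#' @return List with `slope`, `se`, `p_value`, `r2`, `ci` (95%), `n`.
#' @export
genetic_gain <- function(means, years) {
  .assert(length(means) == length(years), "means and years must align")
  ok <- is.finite(means) & is.finite(years)
  fit <- stats::lm(means[ok] ~ years[ok])
  sm <- summary(fit)
  co <- sm$coefficients
  slope <- co[2, 1]; se <- co[2, 2]; pv <- co[2, 4]
  scale_y <- stats::sd(means[ok]) + abs(mean(means[ok])) + 1
  if (!is.finite(pv) || sm$sigma < 1e-10 * scale_y) {
    # numerically exact fit: a constant trait has no trend (p = 1),
    # an exact non-constant line is a sure trend (p = 0)
    exact_zero <- abs(slope) * stats::sd(years[ok]) < 1e-10 * scale_y
    pv <- if (exact_zero) 1 else 0
    if (exact_zero) slope <- 0
  }
  ci <- slope + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se
  list(slope = slope, se = se, p_value = pv,
       r2 = sm$r.squared, ci = ci, n = sum(ok), fit = fit)
}

.pv_term_labels <- c(year = "G_year", hybrid = "G_res", scenario = "Scen",
                     experiment = "E_res", `year:scenario` = "G_year_x_Scen")

#' Variance partition of grain number across eras and scenarios
#'
#' Fits the linear model with terms, in order: optional trait covariates,
#' year of release (`G_year`), residual hybrid effect (`G_res`),
#' environmental scenario (`Scen`), experiment-within-scenario (`E_res`),
#' and the year x scenario interaction, then converts sequential (type-I)
#' sums of squares to proportions of the total. With
#' `selection = "forward-backward"`, terms enter and leave by F tests at
#' `alpha`; excluded terms report proportion 0.
#'
#' @param trial trial table with `hybrid`, `experiment`, `scenario`,
#'   `year`, the response, and any covariate columns.
#' @param response response column (default `"gn"`).
#' @param covariates character vector of trait covariate columns placed
#'   before the year term (e.g. `c("veg", "silk", "rh_pad")`).
#' @param selection `"none"` or `"forward-backward"`.
#' @param type `"I"` (sequential, default) or `"III"` (drop1 SS; these
#'   proportions need not sum to 1 and are reported for comparison only).
#' @param alpha F-test threshold for selection (default 0.05).
#' @return Data frame of class `variance_partition` with columns `term`,
#'   `df`, `ss`, `proportion`.
#' @export
partition_variance <- function(trial, response = "gn",
                               covariates = character(),
                               selection = c("none", "forward-backward"),
                               type = c("I", "III"), alpha = 0.05) {
  selection <- match.arg(selection)
  type <- match.arg(type)
  .check_trial(trial, response)
  .assert(all(c("year", "scenario") %in% names(trial)),
          "trial needs 'year' and 'scenario' columns")
  .assert(all(covariates %in% names(trial)), "missing covariate column(s)")
  d <- data.frame(y = trial[[response]],
                  year = as.numeric(trial$year),
                  hybrid = factor(trial$hybrid),
                  scenario = factor(trial$scenario),
                  experiment = factor(trial$experiment))
  for (cv in covariates) d[[cv]] <- trial[[cv]]
  terms_all <- c(covariates, "year", "hybrid", "scenario", "experiment",
                 "year:scenario")
  keep <- terms_all
  if (selection == "forward-backward") {
    keep <- .fb_select(d, terms_all, alpha)
  }
  form <- stats::reformulate(keep, response = "y")
  fit <- stats::lm(form, data = d)
  an <- stats::anova(fit)
  .assert(stats::df.residual(fit) > 0, "saturated model: no residual df")
  zero_df <- rownames(an)[an$Df == 0]
  .assert(length(zero_df) == 0, "aliased term(s): %s",
          paste(zero_df, collapse = ", "))
  if (type == "III") {
    d1 <- stats::drop1(fit, scope = form, test = "F")
    ss <- d1$`Sum of Sq`[-1]
    names(ss) <- rownames(d1)[-1]
    ss <- c(ss, residual = stats::deviance(fit))
    df <- c(d1$Df[-1], stats::df.residual(fit))
  } else {
    ss <- an$`Sum Sq`
    names(ss) <- rownames(an)
    names(ss)[names(ss) == "Residuals"] <- "residual"
    df <- an$Df
  }
  total <- sum(an$`Sum Sq`)
  relabel <- function(x) ifelse(x %in% names(.pv_term_labels),
                                .pv_term_labels[x], x)
  excluded <- setdiff(terms_all, keep)
  out <- data.frame(term = relabel(names(ss)), df = df, ss = as.numeric(ss),
                    proportion = as.numeric(ss) / total,
                    stringsAsFactors = FALSE)
  if (length(excluded)) {
    out <- rbind(out, data.frame(term = relabel(excluded), df = 0, ss = 0,
                                 proportion = 0, stringsAsFactors = FALSE))
  }
  attr(out, "type") <- type
  attr(out, "selected") <- keep
  attr(out, "total_ss") <- total
  class(out) <- c("variance_partition", class(out))
  out
}

## ANOVA-based forward selection then backward elimination over the
## ordered term list; hierarchy: the year:scenario interaction needs both
## main terms present.
.fb_select <- function(d, terms_all, alpha) {
  current <- character()
  repeat {
    added <- FALSE
    for (tm in setdiff(terms_all, current)) {
      if (tm == "year:scenario" &&
          !all(c("year", "scenario") %in% current)) next
      f0 <- if (length(current)) stats::reformulate(current, "y") else y ~ 1
      f1 <- stats::reformulate(c(current, tm), "y")
      a <- stats::anova(stats::lm(f0, d), stats::lm(f1, d))
      pv <- a$`Pr(>F)`[2]
      if (is.finite(pv) && pv < alpha) {
        current <- c(current, tm); added <- TRUE
      }
    }
    if (!added) break
  }
  current <- terms_all[terms_all %in% current]
  repeat {
    dropped <- FALSE
    for (tm in rev(current)) {
      if (tm %in% c("year", "scenario") && "year:scenario" %in% current) next
      f1 <- stats::reformulate(current, "y")
      rest <- setdiff(current, tm)
      f0 <- if (length(rest)) stats::reformulate(rest, "y") else y ~ 1
      a <- stats::anova(stats::lm(f0, d), stats::lm(f1, d))
      pv <- a$`Pr(>F)`[2]
      if (!is.finite(pv) || pv >= alpha) {
        current <- rest; dropped <- TRUE; break
      }
    }
    if (!dropped) break
  }
  terms_all[terms_all %in% current]
}

#' Factorial regression: genotypic sensitivities to environmental indices
#'
#' Classical two-stage factorial regression of the genotype x environment
#' interaction: the response is double-centred (hybrid and experiment
#' means removed) and, per genotype, the interaction residuals are
#' regressed on the centred mean soil water potential at flowering
#' (`psi`, MPa) and the centred intercepted radiation during the
#' vegetative phase (`rint`, MJ m-2). Indices are admitted sequentially by
#' a pooled F test at `alpha`; a constant index is never admitted and its
#' sensitivities are `NA`. Estimated sensitivities are deviations from
#' the panel-mean sensitivity (which is absorbed by the experiment main
#' effect).
#'
#' @param trial trial table (`hybrid`, `experiment`, response).
#' @param response response column (default `"gn"`).
#' @param psi,rint per-experiment indices: either a column name in
#'   `trial` (constant within experiment) or a named vector indexed by
#'   experiment id. Defaults to columns `"psi"` / `"r_int"` when present.
#' @param alpha admission threshold for the pooled F tests.
#' @return Data frame of class `sensitivities` (`hybrid`, `beta1`, `se1`,
#'   `t1`, `beta2`, `se2`, `t2`); attributes `admitted`, `p_admit`,
#'   `gxe_residual_prop` (share of interaction SS left unexplained).
#' @export
factorial_regression <- function(trial, response = "gn", psi = NULL,
                                 rint = NULL, alpha = 0.05) {
  .check_trial(trial, response)
  get_index <- function(x, default_col) {
    if (is.null(x)) {
      .assert(default_col %in% names(trial),
              "index column '%s' missing", default_col)
      v <- tapply(trial[[default_col]], as.character(trial$experiment),
                  function(z) z[1])
    } else if (is.character(x) && length(x) == 1L) {
      v <- tapply(trial[[x]], as.character(trial$experiment),
                  function(z) z[1])
    } else {
      v <- x[as.character(unique(trial$experiment))]
    }
    v
  }
  psi_e <- get_index(psi, "psi")
  rint_e <- get_index(rint, "r_int")
  hyb <- as.character(trial$hybrid)
  exp_id <- as.character(trial$experiment)
  y <- trial[[response]]
  gm <- mean(y)
  mh <- tapply(y, hyb, mean)
  me <- tapply(y, exp_id, mean)
  r <- y - mh[hyb] - me[exp_id] + gm
  ss0 <- sum(r^2)
  hybrids <- sort(unique(hyb))
  n_h <- length(hybrids)
  n_e <- length(unique(exp_id))
  df_base <- length(y) - n_h - n_e + 1

  fit_index <- function(resid, idx_e) {
    # per-hybrid slope of interaction residuals on the centred index
    x <- idx_e[exp_id] - mean(idx_e)
    beta <- se <- rep(NA_real_, n_h)
    names(beta) <- names(se) <- hybrids
    newres <- resid
    for (h in hybrids) {
      sel <- hyb == h
      xx <- x[sel]; yy <- resid[sel]
      sxx <- sum((xx - mean(xx))^2)
      if (sxx < 1e-12) next
      b <- sum((xx - mean(xx)) * yy) / sxx
      beta[h] <- b
      newres[sel] <- yy - b * (xx - mean(xx))
      df_h <- sum(sel) - 2
      if (df_h > 0) se[h] <- sqrt(sum(newres[sel]^2) / df_h / sxx)
    }
    list(beta = beta, se = se, resid = newres)
  }

  admitted <- character()
  p_admit <- c(psi = NA_real_, rint = NA_real_)
  resid <- r
  df_res <- df_base
  res_list <- list()
  for (nm in c("psi", "rint")) {
    idx_e <- if (nm == "psi") psi_e else rint_e
    if (stats::sd(idx_e) < 1e-12) next   # degenerate index: never admitted
    cand <- fit_index(resid, idx_e)
    ss_before <- sum(resid^2)
    ss_after <- sum(cand$resid^2)
    df1 <- sum(!is.na(cand$beta))
    df2 <- df_res - df1
    Fv <- ((ss_before - ss_after) / df1) / (ss_after / df2)
    pv <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    p_admit[nm] <- pv
    if (is.finite(pv) && pv < alpha) {
      admitted <- c(admitted, nm)
      resid <- cand$resid
      df_res <- df2
      res_list[[nm]] <- cand
    }
  }
  na_col <- rep(NA_real_, n_h)
  b1 <- if ("psi" %in% admitted) res_list$psi$beta else na_col
  s1 <- if ("psi" %in% admitted) res_list$psi$se else na_col
  b2 <- if ("rint" %in% admitted) res_list$rint$beta else na_col
  s2 <- if ("rint" %in% admitted) res_list$rint$se else na_col
  out <- data.frame(hybrid = hybrids, beta1 = as.numeric(b1),
                    se1 = as.numeric(s1), t1 = as.numeric(b1 / s1),
                    beta2 = as.numeric(b2), se2 = as.numeric(s2),
                    t2 = as.numeric(b2 / s2), stringsAsFactors = FALSE)
  attr(out, "admitted") <- admitted
  attr(out, "p_admit") <- p_admit
  attr(out, "gxe_residual_prop") <- sum(resid^2) / ss0
  class(out) <- c("sensitivities", class(out))
  out
}
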