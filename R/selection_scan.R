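## Genome scans for regions under selection: (i) kinship-controlled
## regression of allele counts on year of release, (ii) covariance-
## standardised old-vs-recent allele-frequency differentiation.

#' Kinship-controlled temporal genome scan
#'
#' Fits the null mixed model `year = mu + u + e`, `u ~ N(0, sigma_g^2 K)`,
#' once by REML through the eigendecomposition of `K` (single-ratio
#' profile likelihood), then tests every SNP by generalised least squares
#' with the null variance ratio held fixed (EMMAX-style approximation;
#' `exact = TRUE` re-estimates the ratio per SNP). Two-sided Wald p-values
#' on `n - 2` degrees of freedom; SNPs with `-log10 p > threshold` are
#' flagged.
#'
#' @param G a complete [genotype_matrix()].
#' @param years numeric year of release per hybrid (the model response).
#' @param K kinship matrix from [grm()] (same hybrids, same order);
#'   `NULL` for an identity matrix, which reduces the scan to ordinary
#'   per-SNP regression.
#' @param threshold flagging threshold on -log10 p (default 3.5).
#' @param exact per-SNP REML instead of the fixed-ratio approximation.
#' @return Data frame of class `scan_result`: `id`, `chrom`, `pos`,
#'   `beta`, `se`, `neglog10p`, `flag_mlm`, `uninformative`. Attributes:
#'   `lambda` (ratio sigma_e^2/sigma_g^2), `sigma_g2`, `sigma_e2`,
#'   `threshold`.
#' @export
temporal_mlm_scan <- function(G, years, K = NULL, threshold = 3.5,
                              exact = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  .assert(!anyNA(G$geno), "scan requires a complete matrix")
  n <- nrow(G$geno)
  .assert(n >= 20, "need at least 20 hybrids")
  .assert(length(years) == n, "one year per hybrid")
  .assert(stats::sd(years) > 0, "constant years: degenerate response")
  if (is.null(K)) K <- diag(n)
  .assert(all(dim(K) == n), "kinship dimension mismatch")
  Kr <- K + diag(1e-8, n)
  # project out the intercept (the EMMA restricted transformation):
  # REML and all per-SNP tests act on the n-1 dimensional complement,
  # which also removes the exact null vector a VanRaden GRM carries there
  ones <- rep(1, n)
  PK <- Kr - outer(ones, colMeans(Kr)) - outer(rowMeans(Kr), ones) +
    mean(Kr)
  eig <- eigen(PK, symmetric = TRUE)
  .assert(min(eig$values) > -1e-6,
          "kinship matrix not positive semidefinite after ridge")
  r <- n - 1
  d <- pmax(eig$values[seq_len(r)], 1e-9)
  U <- eig$vectors[, seq_len(r), drop = FALSE]
  yt <- crossprod(U, years - mean(years))[, 1]

  reml_null <- function(log10l) {
    lam <- 10^log10l
    w <- 1 / (d + lam)
    s2 <- sum(w * yt^2) / r
    r * log(s2) + sum(log(d + lam))
  }
  opt <- stats::optimize(reml_null, c(-6, 6), tol = 1e-8)
  lam <- 10^opt$minimum
  w <- 1 / (d + lam)
  sigma_g2 <- sum(w * yt^2) / r
  sigma_e2 <- lam * sigma_g2

  Gc <- scale(G$geno, center = TRUE, scale = FALSE)
  Gt <- crossprod(U, Gc)                          # (n-1) x m rotated SNPs
  if (exact) {
    m <- ncol(Gt)
    beta <- se <- pval <- rep(NA_real_, m)
    for (s in seq_len(m)) {
      g <- Gt[, s]
      if (sum(g^2) < 1e-10) next
      reml_s <- function(log10l) {
        lams <- 10^log10l
        ws <- 1 / (d + lams)
        sxx <- sum(ws * g^2)
        b <- sum(ws * g * yt) / sxx
        rss <- max(sum(ws * yt^2) - b^2 * sxx, 1e-300)
        (r - 1) * log(rss / (r - 1)) + sum(log(d + lams)) + log(sxx)
      }
      lam_s <- 10^stats::optimize(reml_s, c(-6, 6), tol = 1e-8)$minimum
      ws <- 1 / (d + lam_s)
      sxx <- sum(ws * g^2)
      b <- sum(ws * g * yt) / sxx
      rss <- max(sum(ws * yt^2) - b^2 * sxx, 0)
      s2 <- rss / (r - 1)
      beta[s] <- b
      se[s] <- sqrt(s2 / sxx)
      pval[s] <- 2 * stats::pt(-abs(b / se[s]), df = r - 1)
    }
  } else {
    # fixed-ratio GLS, fully vectorised over SNPs
    sxx <- colSums(w * Gt^2)
    sxy <- colSums(w * Gt * yt)
    yy <- sum(w * yt^2)
    ok <- sxx > 1e-10
    beta <- sxy / sxx
    rss <- pmax(yy - beta^2 * sxx, 0)
    s2 <- rss / (r - 1)
    se <- sqrt(s2 / sxx)
    tstat <- beta / se
    pval <- 2 * stats::pt(-abs(tstat), df = r - 1)
    beta[!ok] <- NA; se[!ok] <- NA; pval[!ok] <- NA
  }
  nlp <- -log10(pmax(pval, .Machine$double.xmin))
  out <- data.frame(id = G$map$id, chrom = G$map$chrom, pos = G$map$pos,
                    beta = beta, se = se, neglog10p = nlp,
                    flag_mlm = !is.na(nlp) & nlp > threshold,
                    uninformative = is.na(pval),
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- lam
  attr(out, "sigma_g2") <- sigma_g2
  attr(out, "sigma_e2") <- sigma_e2
  attr(out, "threshold") <- threshold
  class(out) <- c("scan_result", class(out))
  out
}

#' Covariance-standardised old-vs-recent differentiation scan
#'
#' Moment-based analogue of the Bayesian XtX statistic: per group g the
#' standardised frequency deviation is
#' \eqn{z_g = (\hat p_g - \hat\pi)/\sqrt{\hat\pi(1-\hat\pi)}} with
#' \eqn{\hat\pi} the pooled frequency; the 2x2 covariance \eqn{\Omega} of
#' `(z_old, z_recent)` is estimated on an LD-pruned SNP subset, and
#' \eqn{XtX = z' \Omega^{-1} z} per SNP. SNPs above the empirical
#' `quantile` of the XtX distribution are flagged as candidate regions
#' under selection.
#'
#' @param G a complete [genotype_matrix()].
#' @param old_group,recent_group disjoint row indices (or hybrid ids) of
#'   the oldest / most recent hybrids (the study design uses 22 + 22).
#' @param pruned_snps SNP column indices (from [ld_prune()]) used to
#'   estimate the among-group covariance; defaults to all SNPs.
#' @param quantile empirical flagging quantile (default 0.9995).
#' @return Data frame of class `scan_result`: `id`, `chrom`, `pos`,
#'   `xtx`, `flag_xtx`, `uninformative`; attributes `omega`, `xtx_threshold`.
#' @export
xtx_scan <- function(G, old_group, recent_group, pruned_snps = NULL,
                     quantile = 0.9995) {
  stopifnot(inherits(G, "genotype_matrix"))
  .assert(!anyNA(G$geno), "scan requires a complete matrix")
  resolve <- function(x) {
    if (is.character(x)) match(x, rownames(G$geno)) else as.integer(x)
  }
  oi <- resolve(old_group); ri <- resolve(recent_group)
  .assert(!anyNA(oi) && !anyNA(ri), "unknown hybrid in group definition")
  .assert(length(intersect(oi, ri)) == 0, "groups must be disjoint")
  p_old <- colMeans(G$geno[oi, , drop = FALSE]) / 2
  p_rec <- colMeans(G$geno[ri, , drop = FALSE]) / 2
  pool <- (colSums(G$geno[oi, , drop = FALSE]) +
             colSums(G$geno[ri, , drop = FALSE])) /
    (2 * (length(oi) + length(ri)))
  informative <- pool > 0 & pool < 1
  sdp <- sqrt(pool * (1 - pool))
  z_old <- ifelse(informative, (p_old - pool) / sdp, 0)
  z_rec <- ifelse(informative, (p_rec - pool) / sdp, 0)
  if (is.null(pruned_snps)) pruned_snps <- seq_len(ncol(G$geno))
  est <- pruned_snps[informative[pruned_snps]]
  .assert(length(est) >= 10, "too few informative pruned SNPs for Omega")
  Z <- cbind(z_old[est], z_rec[est])
  omega <- stats::cov(Z)
  if (abs(det(omega)) < 1e-12) {
    warning("singular among-group covariance; adding ridge 1e-6")
    omega <- omega + diag(1e-6, 2)
  }
  oi_inv <- solve(omega)
  xtx <- oi_inv[1, 1] * z_old^2 + 2 * oi_inv[1, 2] * z_old * z_rec +
    oi_inv[2, 2] * z_rec^2
  xtx[!informative] <- 0
  thr <- stats::quantile(xtx, probs = quantile, names = FALSE)
  out <- data.frame(id = G$map$id, chrom = G$map$chrom, pos = G$map$pos,
                    xtx = xtx, flag_xtx = xtx > thr,
                    uninformative = !informative,
                    stringsAsFactors = FALSE)
  attr(out, "omega") <- omega
  attr(out, "xtx_threshold") <- thr
  class(out) <- c("scan_result", class(out))
  out
}

#' Call regions under selection from flagged SNPs
#'
#' Combines the flag columns of one or more scan results (union or
#' intersection over methods per SNP), expands flagged SNPs to 1-bp point
#' intervals, and merges flagged positions within `merge_window` bp on
#' the same chromosome into a single region. Region names record the
#' contributing methods.
#'
#' @param scans a `scan_result` or a list of them sharing `id`, `chrom`,
#'   `pos` (flag columns are matched by the `flag_` prefix).
#' @param merge_window merge distance in bp (default 5e5).
#' @param combine `"union"` or `"intersection"` over methods.
#' @return A [region_set()]; empty when nothing is flagged.
#' @export
call_rus <- function(scans, merge_window = 5e5,
                     combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  if (inherits(scans, "scan_result")) scans <- list(scans)
  base <- scans[[1]][, c("id", "chrom", "pos")]
  flags <- list()
  for (sc in scans) {
    .assert(identical(sc$id, base$id), "scan results must share markers")
    for (cl in grep("^flag_", names(sc), value = TRUE)) {
      flags[[cl]] <- sc[[cl]]
    }
  }
  .assert(length(flags) > 0, "no flag columns found")
  fm <- do.call(cbind, flags)
  hit <- if (combine == "union") rowSums(fm) > 0 else rowSums(fm) == ncol(fm)
  methods <- vapply(seq_len(nrow(fm)), function(i) {
    paste(sub("^flag_", "", colnames(fm))[fm[i, ]], collapse = "+")
  }, character(1))
  if (!any(hit)) return(region_set(character(), numeric(), numeric()))
  df <- data.frame(chrom = base$chrom[hit], pos = base$pos[hit],
                   method = methods[hit], stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), ]
  new_cluster <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                     diff(df$pos) > merge_window)
  cl <- cumsum(new_cluster)
  chrom <- tapply(df$chrom, cl, `[`, 1)
  start <- tapply(df$pos, cl, min)
  end <- tapply(df$pos, cl, max) + 1
  meth <- tapply(df$method, cl, function(m) {
    paste(sort(unique(unlist(strsplit(m, "+", fixed = TRUE)))),
          collapse = "+")
  })
  region_set(as.character(chrom), as.numeric(start), as.numeric(end),
             name = sprintf("rus_%d_%s", seq_along(chrom), meth))
}

#' Write per-SNP scan statistics as a tab-separated table
#'
#' @param scan a `scan_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
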