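#' SNP quality control and modal imputation
#'
#' Removes SNPs with minor allele frequency strictly below `maf_min`
#' (computed over non-missing calls) and/or a missing fraction strictly
#' above `max_missing`, then replaces remaining missing calls by the
#' per-SNP modal genotype (ties broken towards the smaller count for
#' determinism). The operation is idempotent.
#'
#' @param G a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency retained (default 0.05).
#' @param max_missing maximum tolerated missing fraction (default 0.20).
#' @return A complete [genotype_matrix()]; attribute `qc` holds the
#'   retained/removed tallies.
#' @export
qc_and_impute <- function(G, maf_min = 0.05, max_missing = 0.20) {
  stopifnot(inherits(G, "genotype_matrix"))
  .assert(ncol(G$geno) > 0 && nrow(G$geno) > 0, "empty genotype matrix")
  miss <- colMeans(is.na(G$geno))
  p <- colMeans(G$geno, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  drop_maf <- !is.na(maf) & maf < maf_min
  drop_all_na <- is.na(maf)
  drop_miss <- miss > max_missing
  keep <- !(drop_maf | drop_miss | drop_all_na)
  tallies <- c(retained = sum(keep),
               removed_maf = sum(drop_maf & !drop_miss),
               removed_missing = sum(drop_miss),
               removed_all_missing = sum(drop_all_na & !drop_miss))
  if (!any(keep)) {
    stop(sprintf(
      "all SNPs removed by QC (maf: %d, missing: %d, all-missing: %d)",
      tallies["removed_maf"], tallies["removed_missing"],
      tallies["removed_all_missing"]), call. = FALSE)
  }
  geno <- G$geno[, keep, drop = FALSE]
  na_cols <- which(colSums(is.na(geno)) > 0)
  for (j in na_cols) {
    x <- geno[, j]
    tab <- tabulate(x + 1L, nbins = 3L)   # counts of genotypes 0,1,2
    mode <- which.max(tab) - 1L           # which.max takes first tie -> smaller
    x[is.na(x)] <- mode
    geno[, j] <- x
  }
  out <- genotype_matrix(geno, G$map[keep, , drop = FALSE])
  attr(out, "qc") <- tallies
  out
}

#' VanRaden method-1 genomic relationship matrix
#'
#' Columns are centred by twice the observed allele frequency and the
#' cross-product is scaled by \eqn{\sum_s 2 p_s (1 - p_s)} over polymorphic
#' SNPs. Monomorphic SNPs contribute nothing to the numerator and are
#' excluded from the denominator (with a warning).
#'
#' @param G a complete (no missing) [genotype_matrix()].
#' @return A symmetric hybrids x hybrids matrix with attribute
#'   `method = "vanraden"`.
#' @export
grm <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  .assert(!anyNA(G$geno), "grm requires a complete matrix; run qc_and_impute")
  p <- colMeans(G$geno) / 2
  poly <- p > 0 & p < 1
  if (any(!poly)) {
    warning(sprintf("%d monomorphic SNP(s) excluded from GRM denominator",
                    sum(!poly)))
  }
  .assert(any(poly), "no polymorphic SNPs")
  W <- sweep(G$geno, 2, 2 * p)
  denom <- sum(2 * p[poly] * (1 - p[poly]))
  K <- tcrossprod(W) / denom
  dimnames(K) <- list(rownames(G$geno), rownames(G$geno))
  attr(K, "method") <- "vanraden"
  K
}

#' Pairwise identity-by-state matrix
#'
#' IBS between hybrids i and j is the mean over SNPs of
#' \eqn{(2 - |c_i - c_j|) / 2}; entries lie in \[0, 1\] with unit diagonal.
#'
#' @param G a complete [genotype_matrix()].
#' @return A symmetric hybrids x hybrids matrix, attribute `method = "ibs"`.
#' @export
ibs_matrix <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  .assert(!anyNA(G$geno), "ibs_matrix requires a complete matrix")
  D <- as.matrix(stats::dist(G$geno, method = "manhattan")) / ncol(G$geno)
  K <- 1 - D / 2
  dimnames(K) <- list(rownames(G$geno), rownames(G$geno))
  attr(K, "method") <- "ibs"
  K
}

#' Nei's gene diversity per group
#'
#' Expected heterozygosity within each group of hybrids: the mean over
#' SNPs of \eqn{2 \hat p (1 - \hat p)} with the small-sample correction
#' \eqn{2n / (2n - 1)}, allele frequencies computed from non-missing calls
#' within the group.
#'
#' @param G a [genotype_matrix()].
#' @param groups factor/character vector of group labels, one per hybrid.
#' @return Named numeric vector of He per group.
#' @export
nei_diversity <- function(G, groups) {
  stopifnot(inherits(G, "genotype_matrix"))
  .assert(length(groups) == nrow(G$geno), "one group label per hybrid")
  groups <- as.character(groups)
  vapply(split(seq_len(nrow(G$geno)), groups), function(idx) {
    g <- G$geno[idx, , drop = FALSE]
    n <- colSums(!is.na(g))
    ok <- n > 0
    p <- colMeans(g[, ok, drop = FALSE], na.rm = TRUE) / 2
    he <- 2 * p * (1 - p) * (2 * n[ok]) / (2 * n[ok] - 1)
    mean(he)
  }, numeric(1))
}

#' Genotype PCA and its relationship with year of release
#'
#' Centres allele counts (optionally scales by \eqn{\sqrt{2 p (1-p)}}),
#' extracts principal components by singular value decomposition, and
#' regresses PC1 scores on year of release. PC1 is sign-flipped so that it
#' correlates positively with year.
#'
#' @param G a complete [genotype_matrix()].
#' @param years numeric year of release, one per hybrid.
#' @param scale logical; scale markers to unit expected variance
#'   (default `FALSE`, centred counts only).
#' @return List with `scores` (hybrids x PCs), `explained` (variance
#'   proportions), `r2_year` (R-squared of PC1 on year), and `lm_year`.
#' @export
pca_year <- function(G, years, scale = FALSE) {
  stopifnot(inherits(G, "genotype_matrix"))
  .assert(!anyNA(G$geno), "pca_year requires a complete matrix")
  .assert(nrow(G$geno) >= 3, "need at least 3 hybrids for a PCA")
  .assert(length(years) == nrow(G$geno), "one year per hybrid")
  X <- scale(G$geno, center = TRUE, scale = FALSE)
  if (scale) {
    p <- colMeans(G$geno) / 2
    sd_exp <- sqrt(2 * p * (1 - p))
    keep <- sd_exp > 0
    X <- sweep(X[, keep, drop = FALSE], 2, sd_exp[keep], "/")
  }
  sv <- svd(X)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- rownames(G$geno)
  colnames(scores) <- sprintf("PC%d", seq_len(ncol(scores)))
  if (stats::cor(scores[, 1], years) < 0) {
    scores[, 1] <- -scores[, 1]
  }
  fit <- stats::lm(scores[, 1] ~ years)
  list(scores = scores,
       explained = sv$d^2 / sum(sv$d^2),
       r2_year = summary(fit)$r.squared,
       lm_year = fit)
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window_snps` markers (advancing by `step`) along
#' each chromosome in map order; within a window, the later member of any
#' pair with squared Pearson correlation above `r2_max` is dropped.
#'
#' @param G a complete [genotype_matrix()].
#' @param window_snps window size in SNPs (default 50).
#' @param step window increment in SNPs (default 5).
#' @param r2_max maximum tolerated squared correlation (default 0.2).
#' @param target_n optional; return a seeded uniform subsample of this size
#'   from the pruned set.
#' @param seed RNG seed for the subsample.
#' @return Integer vector of retained SNP column indices.
#' @export
ld_prune <- function(G, window_snps = 50, step = 5, r2_max = 0.2,
                     target_n = NULL, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  .assert(!anyNA(G$geno), "ld_prune requires a complete matrix")
  ord <- order(G$map$chrom, G$map$pos)
  keep <- rep(TRUE, ncol(G$geno))
  for (chr in unique(G$map$chrom)) {
    idx <- ord[G$map$chrom[ord] == chr]
    m <- length(idx)
    starts <- unique(c(seq(1L, max(1L, m - 1L), by = step)))
    for (s in starts) {
      win <- idx[s:min(s + window_snps - 1L, m)]
      win <- win[keep[win]]
      if (length(win) < 2L) next
      cc <- suppressWarnings(stats::cor(G$geno[, win, drop = FALSE]))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      for (a in seq_len(length(win) - 1L)) {
        if (!keep[win[a]]) next
        hits <- which(r2[a, ] > r2_max)
        hits <- hits[hits > a & keep[win[hits]]]
        keep[win[hits]] <- FALSE
      }
    }
  }
  retained <- which(keep)
  if (!is.null(target_n) && target_n < length(retained)) {
    retained <- sort(with_seed(seed, sample(retained, target_n)))
  }
  retained
}
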