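## Permutation enrichment of RUS-QTL colocalization with number- and
## length-matched random regions, and the allele-frequency-shift contrast
## inside vs outside QTL space.

## Merge a region set into per-chromosome sorted non-overlapping
## intervals; used as the fixed side of fast overlap queries.
.merge_regions <- function(regions) {
  out <- list()
  for (chr in unique(regions$chrom)) {
    r <- regions[regions$chrom == chr, , drop = FALSE]
    ord <- order(r$start, r$end)
    s <- r$start[ord]; e <- r$end[ord]
    ms <- s[1]; me <- e[1]
    starts <- ends <- numeric(0)
    if (length(s) > 1) {
      for (i in 2:length(s)) {
        if (s[i] <= me) {
          me <- max(me, e[i])
        } else {
          starts <- c(starts, ms); ends <- c(ends, me)
          ms <- s[i]; me <- e[i]
        }
      }
    }
    out[[chr]] <- list(start = c(starts, ms), end = c(ends, me))
  }
  out
}

## Vectorised half-open overlap query against merged intervals:
## (s, e) overlaps iff some interval has start < e and end > s.
.overlaps_merged <- function(merged, chrom, s, e) {
  hit <- logical(length(s))
  for (chr in unique(chrom)) {
    mi <- merged[[chr]]
    sel <- chrom == chr
    if (is.null(mi)) next
    idx <- findInterval(s[sel], mi$start)          # last start <= s
    left <- idx >= 1 & idx <= length(mi$end)
    left[left] <- mi$end[idx[left]] > s[sel][left]
    nxt <- idx + 1
    right <- nxt <= length(mi$start)
    right[right] <- mi$start[nxt[right]] < e[sel][right]
    hit[sel] <- left | right
  }
  hit
}

#' Count query regions overlapping a fixed region set
#'
#' Number of `query` regions intersecting at least one `fixed` region
#' under 0-based half-open semantics (abutting regions do not overlap);
#' each query region is counted at most once.
#'
#' @param fixed,query [region_set()]s.
#' @return Integer count.
#' @export
overlap_count <- function(fixed, query) {
  stopifnot(inherits(fixed, "region_set"), inherits(query, "region_set"))
  if (nrow(fixed) == 0 || nrow(query) == 0) return(0L)
  merged <- .merge_regions(fixed)
  sum(.overlaps_merged(merged, query$chrom, query$start, query$end))
}

#' Length-matched random region placement
#'
#' One random region per template region, preserving its length exactly:
#' the chromosome is chosen with probability proportional to the number
#' of valid start positions (`length - region length + 1`) and the start
#' uniformly among them. Sampled regions may overlap one another and the
#' template's original positions.
#'
#' @param template a [region_set()] whose lengths are matched.
#' @param genome a [genome_spec()].
#' @param seed RNG seed.
#' @return A [region_set()] with the template's names.
#' @export
sample_random_regions <- function(template, genome, seed = NULL) {
  stopifnot(inherits(template, "region_set"), inherits(genome, "genome_spec"))
  len <- template$end - template$start
  placed <- with_seed(seed, .place_batch(len, genome, 1L))
  region_set(placed$chrom, placed$start, placed$start + len,
             name = template$name)
}

## Sample `reps` placements for each template length; returns vectors of
## length reps * length(len), iteration-major blocks of the template.
.place_batch <- function(len, genome, reps) {
  q <- length(len)
  total <- q * reps
  chrom <- character(total)
  start <- numeric(total)
  for (j in seq_len(q)) {
    valid <- pmax(genome$length - len[j] + 1, 0)
    .assert(any(valid > 0),
            "template length %g exceeds every chromosome", len[j])
    ci <- sample.int(nrow(genome), reps, replace = TRUE, prob = valid)
    pos <- floor(stats::runif(reps) * valid[ci])
    sel <- seq(j, total, by = q)
    chrom[sel] <- genome$chrom[ci]
    start[sel] <- pos
  }
  list(chrom = chrom, start = start, len = rep(len, reps))
}

#' Permutation test of RUS-QTL colocalization enrichment
#'
#' Observed statistic: the number of QTL regions overlapping at least one
#' RUS. Null: `m` draws of number- and length-matched random regions
#' (RUS positions fixed), each counted the same way. The permutation
#' p-value uses the add-one correction `p = (b + 1) / (m + 1)` with `b`
#' the number of null counts at least as extreme as the observed one
#' (one-sided enrichment by default; `alternative = "less"` tests
#' depletion). A chi-square statistic comparing the observed count with
#' the null-mean expectation is reported alongside; the permutation p is
#' primary.
#'
#' @param rus,qtls [region_set()]s (RUS fixed, QTLs randomised).
#' @param genome a [genome_spec()].
#' @param m number of permutations (default 1e5; < 100 warns).
#' @param seed RNG seed; fixes the null draw.
#' @param alternative `"greater"` (enrichment) or `"less"`.
#' @return List of class `enrichment_result`: `observed`, `null_mean`,
#'   `null_sd`, `null` (all m counts), `p_perm`, `chi2`, `p_chi2`, `m`,
#'   `seed`, `flag`.
#' @export
enrichment_test <- function(rus, qtls, genome, m = 1e5, seed = 1,
                            alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(rus, "region_set"), inherits(qtls, "region_set"))
  if (m < 100) warning("m < 100 gives poor p-value resolution")
  if (nrow(rus) == 0 || nrow(qtls) == 0) {
    return(structure(list(observed = 0L, null_mean = NA, null_sd = NA,
                          null = integer(0), p_perm = 1, chi2 = NA,
                          p_chi2 = NA, m = m, seed = seed,
                          flag = "degenerate"),
                     class = "enrichment_result"))
  }
  observed <- overlap_count(rus, qtls)
  merged <- .merge_regions(rus)
  len <- qtls$end - qtls$start
  q <- length(len)
  null <- integer(m)
  with_seed(seed, {
    chunk <- max(1L, min(m, floor(2e6 / q)))
    done <- 0L
    while (done < m) {
      reps <- min(chunk, m - done)
      b <- .place_batch(len, genome, reps)
      hits <- .overlaps_merged(merged, b$chrom, b$start, b$start + b$len)
      null[done + seq_len(reps)] <-
        colSums(matrix(hits, nrow = q))
      done <- done + reps
    }
  })
  bcount <- if (alternative == "greater") sum(null >= observed) else
    sum(null <= observed)
  p_perm <- (bcount + 1) / (m + 1)
  expct <- mean(null)
  chi2 <- p_chi2 <- NA_real_
  if (expct > 0 && expct < q) {
    chi2 <- (observed - expct)^2 / expct +
      ((q - observed) - (q - expct))^2 / (q - expct)
    p_chi2 <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(observed = observed, null_mean = expct,
                 null_sd = stats::sd(null), null = null, p_perm = p_perm,
                 chi2 = chi2, p_chi2 = p_chi2, m = m, seed = seed,
                 flag = "ok"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: observed %s overlaps, null %.2f +/- %.2f (m = %d), p = %.3g\n",
    x$observed, x$null_mean, x$null_sd, x$m, x$p_perm))
  invisible(x)
}

#' Allele-frequency-shift contrast inside vs outside QTL space
#'
#' Statistic: the mean absolute old-vs-recent allele-frequency difference
#' over SNPs falling inside the QTL intervals. Null: the same statistic
#' for `m` draws of length-matched random regions. Permutation p-value
#' with the `(b + 1)/(m + 1)` correction (one-sided: null >= observed).
#'
#' @param G a complete [genotype_matrix()].
#' @param old_group,recent_group row indices or hybrid ids of the two era
#'   groups.
#' @param qtls a [region_set()].
#' @param genome a [genome_spec()].
#' @param m permutations (default 1e4).
#' @param seed RNG seed.
#' @return List of class `freq_shift_result`: `statistic` (mean |dp| in
#'   QTL space), `n_snps`, `null_quantile` (0.95), `p`, `null`.
#' @export
freq_shift_contrast <- function(G, old_group, recent_group, qtls, genome,
                                m = 1e4, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(qtls, "region_set"))
  .assert(!anyNA(G$geno), "requires a complete matrix")
  resolve <- function(x) {
    if (is.character(x)) match(x, rownames(G$geno)) else as.integer(x)
  }
  oi <- resolve(old_group); ri <- resolve(recent_group)
  .assert(length(intersect(oi, ri)) == 0, "groups must be disjoint")
  dp <- abs(colMeans(G$geno[ri, , drop = FALSE]) -
              colMeans(G$geno[oi, , drop = FALSE])) / 2
  # per-chromosome sorted positions with cumulative |dp| for O(log) sums
  idx <- split(seq_len(ncol(G$geno)), G$map$chrom)
  snp <- lapply(idx, function(ii) {
    ord <- ii[order(G$map$pos[ii])]
    list(pos = G$map$pos[ord], cum = cumsum(dp[ord]))
  })
  region_stat <- function(chrom, s, e) {
    # mean |dp| over SNPs with s <= pos < e, summed across regions
    tot <- 0; cnt <- 0
    for (chr in unique(chrom)) {
      sc <- snp[[chr]]
      if (is.null(sc)) next
      sel <- chrom == chr
      hi <- findInterval(e[sel] - 1, sc$pos)
      lo <- findInterval(s[sel] - 1, sc$pos)
      cnt <- cnt + sum(hi - lo)
      cum0 <- c(0, sc$cum)
      tot <- tot + sum(cum0[hi + 1] - cum0[lo + 1])
    }
    if (cnt == 0) return(NA_real_)
    tot / cnt
  }
  observed <- region_stat(qtls$chrom, qtls$start, qtls$end)
  n_in <- {
    cnt <- 0
    for (chr in unique(qtls$chrom)) {
      sc <- snp[[chr]]
      if (is.null(sc)) next
      sel <- qtls$chrom == chr
      cnt <- cnt + sum(findInterval(qtls$end[sel] - 1, sc$pos) -
                         findInterval(qtls$start[sel] - 1, sc$pos))
    }
    cnt
  }
  len <- qtls$end - qtls$start
  q <- length(len)
  null <- rep(NA_real_, m)
  with_seed(seed, {
    chunk <- max(1L, min(m, floor(2e6 / q)))
    done <- 0L
    while (done < m) {
      reps <- min(chunk, m - done)
      b <- .place_batch(len, genome, reps)
      for (r in seq_len(reps)) {
        sel <- (r - 1) * q + seq_len(q)
        null[done + r] <- region_stat(b$chrom[sel], b$start[sel],
                                      b$start[sel] + len)
      }
      done <- done + reps
    }
  })
  ok <- !is.na(null)
  bcount <- sum(null[ok] >= observed)
  p <- (bcount + 1) / (sum(ok) + 1)
  structure(list(statistic = observed, n_snps = n_in,
                 null_quantile = stats::quantile(null[ok], 0.95,
                                                 names = FALSE),
                 p = p, null = null, m = m, seed = seed),
            class = "freq_shift_result")
}

#' Write an enrichment result as JSON (plus optional null histogram CSV)
#'
#' @param x an `enrichment_result`.
#' @param path JSON output path.
#' @param null_csv optional path for a CSV histogram of the null counts.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path, null_csv = NULL) {
  stopifnot(inherits(x, "enrichment_result"))
  obj <- x[c("observed", "null_mean", "null_sd", "p_perm", "chi2",
             "p_chi2", "m", "seed", "flag")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(null_csv) && length(x$null)) {
    tb <- as.data.frame(table(overlaps = x$null), stringsAsFactors = FALSE)
    utils::write.csv(tb, null_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
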