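#' Additive genotype matrix with marker map
#'
#' Container for a hybrids x SNPs matrix of additive allele counts
#' (0/1/2, `NA` for missing; counts are of the alternative allele relative
#' to the reference) plus a marker map. Internal coordinates are 0-based.
#'
#' @param geno integer-valued matrix, rows = hybrids (rownames = ids),
#'   columns = SNPs.
#' @param map data frame with one row per SNP and columns `id`, `chrom`,
#'   `pos` (0-based bp), `ref`, `alt`.
#' @return An object of class `genotype_matrix` with elements `geno` and
#'   `map`.
#' @export
genotype_matrix <- function(geno, map) {
  .assert(is.matrix(geno), "geno must be a matrix")
  .assert(is.data.frame(map), "map must be a data frame")
  .assert(all(c("id", "chrom", "pos", "ref", "alt") %in% names(map)),
          "map needs columns id, chrom, pos, ref, alt")
  .assert(nrow(map) == ncol(geno), "map rows must match geno columns")
  vals <- geno[!is.na(geno)]
  .assert(all(vals %in% c(0, 1, 2)), "allele counts must be 0, 1, 2 or NA")
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("hyb%03d", seq_len(nrow(geno)))
  }
  map$id <- as.character(map$id)
  map$chrom <- as.character(map$chrom)
  .assert(!anyDuplicated(map$id), "marker ids must be unique")
  colnames(geno) <- map$id
  structure(list(geno = geno, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$geno))
  cat(sprintf("genotype_matrix: %d hybrids x %d SNPs (%.2f%% missing), %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), 100 * miss,
              length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

.gt_to_count <- function(gt) {
  # "0/1", "0|1", "./." etc -> additive alt count; any missing allele -> NA
  gt <- sub(":.*", "", gt)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

#' Read genotypes from VCF or an additive text matrix
#'
#' VCF input is parsed with \pkg{vcfR}; only biallelic SNP records are
#' retained (the number skipped is reported via the `n_skipped` attribute
#' and a message). VCF positions (1-based) are converted to the internal
#' 0-based convention. The additive-matrix format is tab-separated with
#' header columns `id, chrom, pos, ref, alt` followed by one column per
#' hybrid holding 0/1/2/NA.
#'
#' @param path input file.
#' @param format `"vcf"` or `"matrix"`.
#' @return A [genotype_matrix()]; attribute `n_skipped` counts dropped
#'   multiallelic records.
#' @export
read_genotypes <- function(path, format = c("vcf", "matrix")) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: %s", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    keep <- vcfR::is.biallelic(v)
    n_skipped <- sum(!keep)
    if (n_skipped > 0) {
      message(sprintf("read_genotypes: skipped %d multiallelic record(s)",
                      n_skipped))
      v <- v[keep, ]
    }
    .assert(nrow(v@fix) > 0, "no biallelic markers retained from %s", path)
    gt <- vcfR::extract.gt(v, element = "GT")
    counts <- apply(gt, 2, .gt_to_count)
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
    geno <- t(counts)
    rownames(geno) <- colnames(gt)
    fix <- v@fix
    map <- data.frame(
      id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                  sprintf("snp_%d", seq_len(nrow(fix))), fix[, "ID"]),
      chrom = fix[, "CHROM"],
      pos = as.numeric(fix[, "POS"]) - 1,  # VCF is 1-based
      ref = fix[, "REF"], alt = fix[, "ALT"],
      stringsAsFactors = FALSE)
    out <- genotype_matrix(geno, map)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("id", "chrom", "pos", "ref", "alt")
    .assert(all(need %in% names(tab)),
            "malformed header: expected columns %s", paste(need, collapse = ", "))
    hyb_cols <- setdiff(names(tab), need)
    .assert(length(hyb_cols) > 0, "no hybrid columns in %s", path)
    geno <- t(as.matrix(tab[, hyb_cols, drop = FALSE]))
    storage.mode(geno) <- "integer"
    rownames(geno) <- hyb_cols
    out <- genotype_matrix(geno, tab[, need])
    n_skipped <- 0L
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write genotypes as VCF or an additive text matrix
#'
#' VCF output is minimal v4.2 with unphased GT genotypes; the internal
#' 0-based positions are written 1-based.
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @param format `"vcf"` or `"matrix"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path, format = c("vcf", "matrix")) {
  stopifnot(inherits(G, "genotype_matrix"))
  format <- match.arg(format)
  if (format == "vcf") {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=gainscan",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(G$geno)), collapse = "\t"))
    code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    gt <- matrix("./.", nrow = ncol(G$geno), ncol = nrow(G$geno))
    ok <- !is.na(t(G$geno))
    gt[ok] <- code[as.character(t(G$geno)[ok])]
    body <- paste(G$map$chrom,
                  format(G$map$pos + 1, scientific = FALSE, trim = TRUE),
                  G$map$id, G$map$ref, G$map$alt, ".", ".", ".", "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(c(hdr, body), path)
  } else {
    tab <- cbind(G$map[, c("id", "chrom", "pos", "ref", "alt")],
                 as.data.frame(t(G$geno)))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
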