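#' Genomic region sets (0-based half-open intervals)
#'
#' A `region_set` is a data frame with columns `chrom`, `start`, `end`,
#' `name` holding genomic intervals in 0-based half-open coordinates
#' (BED convention): a region covers positions `start .. end - 1`.
#' Region-under-selection (RUS) calls and QTL intervals are both carried
#' in this container.
#'
#' @param chrom character vector of chromosome identifiers.
#' @param start,end integer-valued interval bounds, `0 <= start < end`.
#' @param name optional unique region names; auto-generated when missing.
#' @param genome optional [genome_spec()]; when supplied, `end` must not
#'   exceed the chromosome length.
#' @return A data frame of class `region_set`.
#' @export
region_set <- function(chrom, start, end, name = NULL, genome = NULL) {
  n <- length(start)
  if (length(chrom) == 1L && n > 1L) chrom <- rep(chrom, n)
  .assert(length(chrom) == n && length(end) == n,
          "chrom, start, end must have equal length")
  if (n == 0L) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), name = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("region_set", class(out))
    return(out)
  }
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  .assert(all(is.finite(start)) && all(is.finite(end)), "non-finite bounds")
  .assert(all(start >= 0), "start must be >= 0")
  bad <- which(start >= end)
  .assert(length(bad) == 0L, "start >= end for region(s) %s",
          paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(name)) name <- sprintf("region_%d", seq_len(n))
  name <- as.character(name)
  .assert(!anyDuplicated(name), "region names must be unique")
  if (!is.null(genome)) {
    len <- stats::setNames(genome$length, genome$chrom)
    .assert(all(chrom %in% genome$chrom), "chromosome absent from genome spec")
    .assert(all(end <= len[chrom]), "region end exceeds chromosome length")
  }
  out <- data.frame(chrom = chrom, start = start, end = end, name = name,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_set", class(out))
  out
}

#' Ordered chromosome sizes
#'
#' @param chrom chromosome identifiers (unique).
#' @param length chromosome lengths in bp (positive).
#' @return A data frame of class `genome_spec`.
#' @export
genome_spec <- function(chrom, length) {
  .assert(length(chrom) == base::length(length), "unequal lengths")
  chrom <- as.character(chrom)
  .assert(!anyDuplicated(chrom), "duplicated chromosome ids")
  length <- as.numeric(length)
  .assert(all(is.finite(length)) && all(length > 0), "lengths must be > 0")
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_spec", class(out))
  out
}

#' Read a BED3/BED4 file into a region set
#'
#' Intervals are kept verbatim in the file's 0-based half-open convention.
#' Lines with `start >= end` raise an error naming the offending line.
#'
#' @param path path to a tab-separated BED3+ text file.
#' @param genome optional [genome_spec()] used for bounds validation.
#' @return A [region_set()].
#' @export
read_regions <- function(path, genome = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(region_set(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  .assert(all(nf >= 3L), "line %d has fewer than 3 columns",
          which(nf < 3L)[1])
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  .assert(!anyNA(start) && !anyNA(end), "non-numeric coordinate on line %d",
          which(is.na(start) | is.na(end))[1])
  bad <- which(start >= end)
  .assert(length(bad) == 0L, "start >= end on line %d", bad[1])
  name <- if (all(nf >= 4L)) vapply(fields, `[[`, "", 4L) else NULL
  region_set(chrom, start, end, name = name, genome = genome)
}

#' Write a region set as BED
#'
#' Output is sorted by chromosome then start, tab-separated, BED4.
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  ord <- order(regions$chrom, regions$start, regions$end)
  r <- regions[ord, , drop = FALSE]
  lines <- sprintf("%s\t%s\t%s\t%s", r$chrom,
                   format(r$start, scientific = FALSE, trim = TRUE),
                   format(r$end, scientific = FALSE, trim = TRUE), r$name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column chrom-sizes file
#'
#' @param path text file with columns chromosome id and length (bp).
#' @return A [genome_spec()].
#' @export
read_genome <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  .assert(ncol(tab) >= 2L, "chrom-sizes file needs two columns")
  genome_spec(tab[[1]], tab[[2]])
}

#' Write a genome spec as a chrom-sizes file
#' @param genome a [genome_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "genome_spec"))
  writeLines(sprintf("%s\t%s", genome$chrom,
                     format(genome$length, scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}
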