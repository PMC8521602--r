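#' Genomic regions (1-based, inclusive)
#'
#' All coordinates inside the package are 1-based and inclusive on both ends,
#' the convention shared by PLINK MAP files and VCF. Conversion to BED's
#' 0-based half-open coordinates happens only in [write_bed()].
#'
#' @param chrom character vector of chromosome ids.
#' @param start,end numeric vectors of 1-based inclusive bounds, `start <= end`.
#' @return A data frame with columns `chrom`, `start`, `end`.
#' @examples
#' genomic_region("chr1", 67943666, 89271008)
#' @export
genomic_region <- function(chrom, start, end) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(chrom)
  if (length(start) != n || length(end) != n) {
    stop("chrom, start and end must have equal length")
  }
  if (n > 0) {
    if (anyNA(chrom) || anyNA(start) || anyNA(end)) {
      stop("regions must not contain missing values")
    }
    if (any(start < 1)) stop("region start must be >= 1")
    if (any(end < start)) stop("region end must not precede start")
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Region length in megabases
#'
#' Length of a 1-based inclusive region, `(end - start + 1) / 1e6`. The value
#' is returned unrounded; round to one decimal for reporting.
#'
#' @param regions a region data frame from [genomic_region()].
#' @return Numeric vector of lengths in Mb.
#' @examples
#' region_length_mb(genomic_region("chr1", 67943666, 89271008)) # ~21.33
#' @export
region_length_mb <- function(regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  (regions$end - regions$start + 1) / 1e6
}

#' Write regions as BED3
#'
#' Converts 1-based inclusive regions to BED's 0-based half-open convention
#' (`start - 1`, `end`) and writes tab-separated BED3 lines in input order.
#'
#' @param regions a region data frame from [genomic_region()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  regions <- genomic_region(regions$chrom, regions$start, regions$end)
  lines <- sprintf("%s\t%s\t%s", regions$chrom,
                   format(regions$start - 1, scientific = FALSE, trim = TRUE),
                   format(regions$end, scientific = FALSE, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file as 1-based inclusive regions
#'
#' @param path a BED file.
#' @return A region data frame (see [genomic_region()]).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  genomic_region(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Jaccard overlap of two regions
#'
#' Intersection length over union length (in bp, 1-based inclusive); 0 when
#' the regions are on different chromosomes.
#'
#' @param a,b single-row region data frames (see [genomic_region()]).
#' @return Overlap fraction in `[0, 1]`.
#' @export
jaccard_overlap <- function(a, b) {
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (a$chrom != b$chrom) return(0)
  inter <- min(a$end, b$end) - max(a$start, b$start) + 1
  if (inter <= 0) return(0)
  uni <- max(a$end, b$end) - min(a$start, b$start) + 1
  inter / uni
}

## region data frame -> GRanges (internal)
.regions_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start, regions$end))
}
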