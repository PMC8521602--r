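#' Marker map: the coordinate backbone of the analysis
#'
#' An ordered table of array markers. Positions must be strictly increasing
#' within each chromosome and marker names unique; chromosome ids are opaque
#' ordered labels (only autosomes are expected - the X is not handled
#' specially and should be excluded upstream for a recessive autosomal trait).
#'
#' @param chrom character vector of chromosome ids, grouped and in order.
#' @param marker character vector of unique marker names.
#' @param pos numeric vector of 1-based bp positions.
#' @return A data frame with columns `chrom`, `marker`, `pos`.
#' @export
marker_map <- function(chrom, marker, pos) {
  chrom <- as.character(chrom)
  marker <- as.character(marker)
  pos <- as.numeric(pos)
  n <- length(chrom)
  if (length(marker) != n || length(pos) != n) {
    stop("chrom, marker and pos must have equal length")
  }
  if (n == 0) stop("marker map is empty")
  if (anyNA(pos) || any(pos < 1)) stop("marker positions must be >= 1")
  if (anyDuplicated(marker)) stop("marker names must be unique")
  ## chromosomes must form contiguous blocks
  r <- rle(chrom)
  if (anyDuplicated(r$values)) {
    stop("markers of one chromosome must be contiguous in the map")
  }
  bad <- unlist(lapply(split(pos, factor(chrom, levels = r$values)),
                       function(p) any(diff(p) <= 0)))
  if (any(bad)) {
    stop("positions must be strictly increasing within chromosome: ",
         paste(names(bad)[bad], collapse = ", "))
  }
  data.frame(chrom = chrom, marker = marker, pos = pos,
             stringsAsFactors = FALSE)
}

## total marker-spanned extent: sum over chromosomes of (last - first + 1) bp
.map_extent <- function(map) {
  sum(vapply(split(map$pos, map$chrom),
             function(p) max(p) - min(p) + 1, numeric(1)))
}

## indices of markers inside a single region (1-based inclusive)
.markers_in_region <- function(map, region) {
  which(map$chrom == region$chrom &
          map$pos >= region$start & map$pos <= region$end)
}
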