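#' Gene model for consequence classification
#'
#' A flat exon/CDS table: one row per feature interval, grouped by transcript.
#' UTR is implied (exon outside CDS), introns are the gaps between a
#' transcript's exons.
#'
#' @param transcript character vector of transcript ids.
#' @param chrom,strand,type,start,end feature columns; `type` is `"exon"` or
#'   `"CDS"`, coordinates 1-based inclusive.
#' @return A data frame of class `gene_model`.
#' @export
gene_model <- function(transcript, chrom, strand, type, start, end) {
  gmod <- data.frame(transcript = as.character(transcript),
                     chrom = as.character(chrom),
                     strand = as.character(strand),
                     type = as.character(type),
                     start = as.numeric(start), end = as.numeric(end),
                     stringsAsFactors = FALSE)
  if (nrow(gmod) == 0) stop("gene model is empty")
  if (!all(gmod$type %in% c("exon", "CDS"))) {
    stop("malformed gene model: feature types must be 'exon' or 'CDS'")
  }
  if (anyNA(gmod$start) || anyNA(gmod$end) || any(gmod$end < gmod$start)) {
    stop("malformed gene model: invalid feature coordinates")
  }
  if (!all(gmod$strand %in% c("+", "-"))) {
    stop("malformed gene model: strand must be '+' or '-'")
  }
  class(gmod) <- c("gene_model", "data.frame")
  gmod
}

#' Read a gene model from GFF3
#'
#' Imports `exon` and `CDS` features (via \pkg{rtracklayer}) and groups them
#' by their `Parent` transcript.
#'
#' @param path a GFF3 file.
#' @return A [gene_model()] data frame.
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("exon", "CDS")
  gr <- gr[keep]
  if (length(gr) == 0) stop("malformed gene model: no exon/CDS features")
  parent <- vapply(as.list(gr$Parent), function(p) {
    if (length(p) == 0) NA_character_ else sub("^transcript:", "", p[[1]])
  }, character(1))
  if (anyNA(parent)) stop("malformed gene model: exon/CDS without Parent")
  gene_model(parent, as.character(GenomicRanges::seqnames(gr)),
             as.character(GenomicRanges::strand(gr)),
             as.character(gr$type),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Write a gene model as GFF3
#'
#' Emits one `mRNA` line per transcript plus its `exon` and `CDS` features.
#'
#' @param gmod a [gene_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(gmod, path) {
  lines <- "##gff-version 3"
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  for (tx in unique(gmod$transcript)) {
    f <- gmod[gmod$transcript == tx, ]
    lines <- c(lines,
               paste(f$chrom[1], "rohmap", "mRNA", fmt(min(f$start)),
                     fmt(max(f$end)), ".", f$strand[1], ".",
                     paste0("ID=", tx), sep = "\t"),
               paste(f$chrom, "rohmap", f$type, fmt(f$start), fmt(f$end),
                     ".", f$strand, ifelse(f$type == "CDS", "0", "."),
                     paste0("Parent=", tx), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
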