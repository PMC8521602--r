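#' Variant filter configuration
#'
#' Settings of the inheritance-model filter. In `"snv"` mode every case must
#' be homozygous for the alternate allele (autosomal recessive model); in
#' `"sv"` mode heterozygous or homozygous case calls are accepted, to allow
#' for the lower genotyping accuracy of SV/MEI callers. The control panel
#' tolerates up to `max_het_controls` heterozygous and `max_hom_controls`
#' homozygous-alt calls; missing control genotypes never count against the
#' allowances, while a missing case genotype fails the case requirement.
#'
#' @param cases sample ids required to carry the variant.
#' @param controls control-panel sample ids (disjoint from `cases`).
#' @param max_het_controls tolerated heterozygous control calls (default 2).
#' @param max_hom_controls tolerated homozygous-alt control calls (default 0).
#' @param mode `"snv"` or `"sv"`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(cases, controls, max_het_controls = 2,
                          max_hom_controls = 0, mode = c("snv", "sv")) {
  mode <- match.arg(mode)
  if (length(intersect(cases, controls))) {
    stop("case and control sets must be disjoint")
  }
  if (!length(cases)) stop("at least one case is required")
  stopifnot(max_het_controls >= 0, max_hom_controls >= 0)
  structure(list(cases = cases, controls = controls,
                 max_het_controls = max_het_controls,
                 max_hom_controls = max_hom_controls, mode = mode),
            class = "filter_config")
}

#' Recessive-model / private-variant filter
#'
#' Keeps the records compatible with an autosomal recessive model: every
#' case homozygous-alt (`"snv"` mode) or het-or-hom-alt (`"sv"` mode), and at
#' most `max_het_controls` heterozygous plus `max_hom_controls`
#' homozygous-alt calls in the control panel. Record order is preserved.
#'
#' @param vt a [variant_table()].
#' @param cfg a [filter_config()].
#' @return The filtered [variant_table()] (a subset of the input).
#' @export
recessive_filter <- function(vt, cfg) {
  unknown <- setdiff(c(cfg$cases, cfg$controls), colnames(vt$geno))
  if (length(unknown)) {
    stop("sample(s) not in variant table: ", paste(unknown, collapse = ", "))
  }
  if (nrow(vt$variants) == 0) return(vt)
  gc <- vt$geno[, cfg$cases, drop = FALSE]
  case_ok <- if (cfg$mode == "snv") {
    rowSums(gc == 2L, na.rm = TRUE) == length(cfg$cases)
  } else {
    rowSums(gc >= 1L, na.rm = TRUE) == length(cfg$cases)
  }
  gk <- vt$geno[, cfg$controls, drop = FALSE]
  ctrl_ok <- rowSums(gk == 1L, na.rm = TRUE) <= cfg$max_het_controls &
    rowSums(gk == 2L, na.rm = TRUE) <= cfg$max_hom_controls
  keep <- which(case_ok & ctrl_ok)
  variant_table(vt$variants[keep, , drop = FALSE],
                vt$geno[keep, , drop = FALSE])
}

#' Restrict a variant table to candidate regions
#'
#' Keeps records whose position (SNV/indel) or `[pos, END]` span (SV/MEI;
#' any overlap counts) intersects one of the regions. Bounds are inclusive.
#'
#' @param vt a [variant_table()].
#' @param regions a region data frame (disjoint, sorted).
#' @return The restricted [variant_table()].
#' @export
intersect_regions <- function(vt, regions) {
  if (nrow(vt$variants) == 0 || nrow(regions) == 0) {
    keep <- integer(0)
  } else {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(.regions_gr(.variant_span(vt)),
                                        .regions_gr(regions)))
    keep <- sort(unique(S4Vectors::queryHits(hits)))
  }
  variant_table(vt$variants[keep, , drop = FALSE],
                vt$geno[keep, , drop = FALSE])
}

## severity order used throughout
.consequence_levels <- c("splicing", "exonic", "UTR", "intronic", "other")

## classify one span (chrom, s, e) against one transcript's features
.classify_one_tx <- function(chrom, s, e, tx) {
  if (tx$chrom[1] != chrom) return(NA_character_)
  exons <- tx[tx$type == "exon", , drop = FALSE]
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- tx[tx$type == "CDS", , drop = FALSE]
  tx_start <- min(exons$start)
  tx_end <- max(exons$end)
  if (e < tx_start || s > tx_end) return(NA_character_)
  overlaps <- function(fs, fe) any(s <= fe & e >= fs)  # any-overlap, vectorized
  ## canonical splice region: first/last 2 bp of each intron
  if (nrow(exons) > 1) {
    don <- exons$end[-nrow(exons)]     # intron starts at don + 1
    acc <- exons$start[-1]             # intron ends at acc - 1
    if (overlaps(don + 1, don + 2) || overlaps(acc - 2, acc - 1)) {
      return("splicing")
    }
  }
  if (nrow(cds) && overlaps(cds$start, cds$end)) return("exonic")
  if (overlaps(exons$start, exons$end)) return("UTR")
  "intronic"
}

#' Classify variant consequences against a gene model
#'
#' Assigns each record one of `splicing`, `exonic`, `UTR`, `intronic` or
#' `other` with precedence splicing > exonic > UTR > intronic > other:
#' splicing is any overlap with the first or last 2 bp of an intron
#' (canonical splice sites), exonic any overlap with CDS, UTR any overlap
#' with an exon outside CDS, intronic inside a transcript span, other
#' intergenic. A variant touching several transcripts takes the most severe
#' class.
#'
#' @param vt a [variant_table()].
#' @param gmod a [gene_model()].
#' @return The [variant_table()] with its `consequence` column filled.
#' @export
classify_consequence <- function(vt, gmod) {
  if (!inherits(gmod, "gene_model")) {
    gmod <- gene_model(gmod$transcript, gmod$chrom, gmod$strand, gmod$type,
                       gmod$start, gmod$end)
  }
  span <- .variant_span(vt)
  txs <- split(gmod, gmod$transcript)
  cons <- character(nrow(vt$variants))
  for (i in seq_len(nrow(vt$variants))) {
    cls <- vapply(txs, function(tx)
      .classify_one_tx(span$chrom[i], span$start[i], span$end[i], tx),
      character(1))
    cls <- cls[!is.na(cls)]
    cons[i] <- if (length(cls)) {
      .consequence_levels[min(match(cls, .consequence_levels))]
    } else "other"
  }
  vt$variants$consequence <- cons
  vt
}

#' Summary of filtered variants by class, consequence and ROH status
#'
#' Tabulates a classified variant table as consequence categories (rows:
#' Total, Exonic, Intronic, Splicing, UTR, Other) against variant classes,
#' each with an "all survivors" and an "in candidate ROH" column.
#'
#' @param vt a classified [variant_table()] of filter survivors.
#' @param regions candidate regions (for the in-ROH columns).
#' @return An integer matrix; `Total` row equals the column sums of the
#'   category rows.
#' @export
tabulate_filter_summary <- function(vt, regions) {
  if (nrow(vt$variants) && anyNA(vt$variants$consequence)) {
    stop("run classify_consequence() before tabulating")
  }
  groups <- c(snv_indel = "snv_indel", SV = "sv", MEI = "mei")
  grp <- ifelse(vt$variants$class %in% c("SNV", "indel"), "snv_indel",
                vt$variants$class)
  in_roh <- rep(FALSE, nrow(vt$variants))
  if (nrow(vt$variants) && nrow(regions)) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(.regions_gr(.variant_span(vt)),
                                        .regions_gr(regions)))
    in_roh[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  cats <- c("Exonic", "Intronic", "Splicing", "UTR", "Other")
  cons_cat <- c(splicing = "Splicing", exonic = "Exonic", UTR = "UTR",
                intronic = "Intronic", other = "Other")[vt$variants$consequence]
  out <- matrix(0L, length(cats) + 1, 2 * length(groups),
                dimnames = list(
                  c("Total", cats),
                  paste0(rep(groups, each = 2), c("_all", "_roh"))))
  for (gi in seq_along(groups)) {
    sel <- grp == names(groups)[gi]
    for (ri in seq_along(cats)) {
      rsel <- sel & cons_cat == cats[ri]
      out[cats[ri], 2 * gi - 1] <- sum(rsel)
      out[cats[ri], 2 * gi] <- sum(rsel & in_roh)
    }
    out["Total", 2 * gi - 1] <- sum(sel)
    out["Total", 2 * gi] <- sum(sel & in_roh)
  }
  out
}
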