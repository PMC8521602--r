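#' Variant table
#'
#' Multi-sample variant records (SNVs, indels, SVs, MEIs) with per-sample
#' genotype classes. Records are biallelic: multi-allelic VCF rows are
#' decomposed per alternate allele on reading, because the genotype-class
#' logic of the filters is per allele. Genotype classes are `0` hom-ref, `1`
#' het, `2` hom-alt, `NA` missing.
#'
#' @param variants data frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `class` (`"SNV"`, `"indel"`, `"SV"` or `"MEI"`), `svtype`
#'   (`NA` for small variants), `end` (SV/MEI end; `NA` otherwise) and
#'   `consequence` (filled by [classify_consequence()], `NA` until then).
#' @param geno integer matrix of genotype classes, records in rows, samples
#'   in columns (column names are sample ids).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(variants, geno) {
  need <- c("chrom", "pos", "id", "ref", "alt", "class", "svtype", "end",
            "consequence")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants lacks columns: ", paste(miss, collapse = ", "))
  if (!all(variants$class %in% c("SNV", "indel", "SV", "MEI"))) {
    stop("variant class must be SNV, indel, SV or MEI")
  }
  if (nrow(variants) > 0 && any(variants$pos < 1)) stop("positions must be >= 1")
  if (!is.matrix(geno) || nrow(geno) != nrow(variants)) {
    stop("geno must be a matrix with one row per variant record")
  }
  storage.mode(geno) <- "integer"
  if (is.null(colnames(geno))) stop("geno needs sample ids as column names")
  rownames(geno) <- NULL
  rownames(variants) <- NULL
  structure(list(variants = variants, geno = geno), class = "variant_table")
}

#' @exportS3Method base::print
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d records x %d samples\n",
              nrow(x$variants), ncol(x$geno)))
  if (nrow(x$variants)) print(table(x$variants$class))
  invisible(x)
}

## effective span of each record: point for SNV/indel, [pos, END] for SV/MEI
.variant_span <- function(vt) {
  v <- vt$variants
  end <- ifelse(v$class %in% c("SV", "MEI") & !is.na(v$end), v$end, v$pos)
  genomic_region(v$chrom, v$pos, pmax(end, v$pos))
}

#' Read a VCF into a variant table
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}), keeps symbolic alternate alleles
#' (`<DEL>`, `<INS:ME:...>`, ...) with their `SVTYPE`/`END`, decomposes
#' multi-allelic rows per alternate allele, and converts GT fields to
#' genotype classes.
#'
#' @param path a VCF file.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0) {
    samples <- colnames(vcf@gt)[-1]
    if (is.null(samples)) samples <- character(0)
    return(variant_table(
      data.frame(chrom = character(), pos = numeric(), id = character(),
                 ref = character(), alt = character(), class = character(),
                 svtype = character(), end = numeric(),
                 consequence = character(), stringsAsFactors = FALSE),
      matrix(integer(), 0, length(samples),
             dimnames = list(NULL, samples))))
  }
  if (ncol(vcf@gt) < 2 || !all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"]))) {
    stop("VCF must carry a GT FORMAT field for every record")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  info_get <- function(key) {
    x <- vcfR::extract.info(vcf, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  svtype <- info_get("SVTYPE")
  endv <- suppressWarnings(as.numeric(info_get("END")))

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  rows <- list()
  genos <- list()
  k <- 0L
  for (i in seq_len(nrow(fix))) {
    parsed <- strsplit(gt[i, ], "[/|]")
    for (a in seq_along(alts[[i]])) {
      alt <- alts[[i]][a]
      g <- vapply(parsed, function(al) {
        if (length(al) == 0 || any(al == ".") || anyNA(al)) return(NA_integer_)
        sum(al == as.character(a))
      }, integer(1))
      cls <- if (grepl("^<INS:ME", alt) ||
                 (!is.na(svtype[i]) && svtype[i] %in% c("MEI", "INS:ME"))) {
        "MEI"
      } else if (grepl("^<", alt) || !is.na(svtype[i])) {
        "SV"
      } else if (nchar(fix[i, "REF"]) == 1 && nchar(alt) == 1) {
        "SNV"
      } else "indel"
      k <- k + 1L
      rows[[k]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.numeric(fix[i, "POS"]),
        id = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".")
          sprintf("var%05d", k) else
            if (length(alts[[i]]) > 1)
              paste0(fix[i, "ID"], "_", a) else fix[i, "ID"],
        ref = fix[i, "REF"], alt = alt, class = cls,
        svtype = svtype[i], end = endv[i],
        consequence = NA_character_, stringsAsFactors = FALSE)
      genos[[k]] <- g
    }
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(rbind, genos)
  colnames(geno) <- samples
  variant_table(variants, geno)
}

#' Write a variant table as VCF 4.2
#'
#' Plain-text writer; symbolic alleles keep `SVTYPE`/`END` in INFO. Genotype
#' classes map to `0/0`, `0/1`, `1/1` and `./.`.
#'
#' @param vt a [variant_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  v <- vt$variants
  samples <- colnames(vt$geno)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    info <- "."
    if (v$class[i] %in% c("SV", "MEI")) {
      parts <- c(
        if (!is.na(v$svtype[i])) paste0("SVTYPE=", v$svtype[i]),
        if (!is.na(v$end[i]))
          paste0("END=", format(v$end[i], scientific = FALSE)))
      if (length(parts)) info <- paste(parts, collapse = ";")
    }
    g <- vt$geno[i, ]
    gts <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    body[i] <- paste(c(v$chrom[i],
                       format(v$pos[i], scientific = FALSE, trim = TRUE),
                       v$id[i], v$ref[i], v$alt[i], ".", "PASS", info, "GT",
                       gts), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
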