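# small in-code fixtures shared across test files

# genotype matrix from integer class codes; alleles derived from one ref/alt
# letter pair so allelic identity is well defined (0 -> ref/ref, 2 -> alt/alt)
toy_gm <- function(codes, phenotype = NULL, ref = "A", alt = "G") {
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1)
  storage.mode(codes) <- "integer"
  if (is.null(rownames(codes))) {
    rownames(codes) <- paste0("s", seq_len(nrow(codes)))
  }
  if (is.null(colnames(codes))) {
    colnames(codes) <- paste0("m", seq_len(ncol(codes)))
  }
  pair <- c(paste0(ref, "/", ref),
            paste0(min(ref, alt), "/", max(ref, alt)),
            paste0(alt, "/", alt))
  al <- matrix(pair[codes + 1L], nrow(codes), ncol(codes),
               dimnames = dimnames(codes))
  genotype_matrix(codes, al, phenotype)
}

toy_map <- function(m, chrom = "chr1", spacing = 30000, start = 1) {
  marker_map(rep(chrom, m), paste0(chrom, "_", seq_len(m)),
             seq(start, by = spacing, length.out = m))
}

# variant table from compact arguments: geno is records x samples
toy_vt <- function(geno, chrom = "chr1", pos = NULL, class = "SNV",
                   end = NA_real_, ids = NULL) {
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = 1)
  storage.mode(geno) <- "integer"
  nr <- nrow(geno)
  if (is.null(colnames(geno))) {
    colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  }
  if (is.null(pos)) pos <- seq(1e6, by = 1e5, length.out = nr)
  chrom <- rep_len(chrom, nr)
  class <- rep_len(class, nr)
  end <- rep_len(end, nr)
  if (is.null(ids)) ids <- paste0("v", seq_len(nr))
  variant_table(data.frame(
    chrom = chrom, pos = pos, id = ids, ref = "A",
    alt = ifelse(class %in% c("SV", "MEI"), "<DEL>",
                 ifelse(class == "indel", "AT", "G")),
    class = class,
    svtype = ifelse(class %in% c("SV", "MEI"), "DEL", NA_character_),
    end = end, consequence = NA_character_, stringsAsFactors = FALSE),
    geno)
}
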