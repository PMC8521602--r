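#' Genotype matrix over a marker map
#'
#' Diploid genotype calls for a cohort, stored as classes: `0` homozygous for
#' the (lexicographically) first allele, `1` heterozygous, `2` homozygous for
#' the other allele, `NA` missing. ROH detection only needs these classes;
#' allelic matching additionally needs allele identity, so the unordered
#' two-allele code from the PED file is kept alongside as strings like
#' `"A/G"` (alleles sorted within the pair).
#'
#' @param geno integer matrix, samples in rows, markers in columns; values in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names marker names.
#' @param alleles character matrix of the same shape with sorted allele pairs
#'   (`"A/G"`), or `NULL` when allele identity is unavailable.
#' @param phenotype character vector, one of `"case"`, `"control"`,
#'   `"unknown"` per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, alleles = NULL, phenotype = NULL) {
  if (!is.matrix(geno)) stop("geno must be a matrix")
  storage.mode(geno) <- "integer"
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("genotype codes must be 0 (hom), 1 (het), 2 (hom) or NA")
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("sample", seq_len(nrow(geno)))
  }
  if (is.null(phenotype)) phenotype <- rep("unknown", nrow(geno))
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nrow(geno)) {
    stop("one phenotype per sample is required")
  }
  if (!all(phenotype %in% c("case", "control", "unknown"))) {
    stop("phenotypes must be 'case', 'control' or 'unknown'")
  }
  names(phenotype) <- rownames(geno)
  if (!is.null(alleles)) {
    if (!is.matrix(alleles) || !all(dim(alleles) == dim(geno))) {
      stop("alleles must be a matrix with the dimensions of geno")
    }
    dimnames(alleles) <- dimnames(geno)
    if (!identical(is.na(alleles), is.na(geno))) {
      stop("alleles and geno must share the same missingness pattern")
    }
  }
  structure(list(geno = geno, alleles = alleles, phenotype = phenotype),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d cases, %d controls)\n",
              nrow(x$geno), ncol(x$geno),
              sum(x$phenotype == "case"), sum(x$phenotype == "control")))
  cat(sprintf("  missing rate %.4f; allele codes %s\n",
              mean(is.na(x$geno)),
              if (is.null(x$alleles)) "absent" else "present"))
  invisible(x)
}

#' Sample ids of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(gm) rownames(gm$geno)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids or indices to keep (default all).
#' @param markers marker names or indices to keep (default all).
#' @return A [genotype_matrix()] restricted to the selection.
#' @export
subset_genotypes <- function(gm, samples = NULL, markers = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(gm$geno))
  if (is.null(markers)) markers <- seq_len(ncol(gm$geno))
  geno <- gm$geno[samples, markers, drop = FALSE]
  alleles <- if (is.null(gm$alleles)) NULL else
    gm$alleles[samples, markers, drop = FALSE]
  genotype_matrix(geno, alleles, gm$phenotype[samples])
}

## Canonical genotype classes from a sorted allele-pair matrix. Code 0 is
## "homozygous for the lexicographically smallest observed allele", so that a
## PED round trip reproduces classes bit-exactly regardless of which allele a
## simulator called reference.
.recode_from_alleles <- function(alleles) {
  a1 <- substr(alleles, 1, 1)
  a2 <- substr(alleles, 3, 3)
  het <- a1 != a2
  geno <- matrix(NA_integer_, nrow(alleles), ncol(alleles),
                 dimnames = dimnames(alleles))
  for (j in seq_len(ncol(alleles))) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[!is.na(obs)]
    if (!length(obs)) next
    first <- min(obs)
    gj <- ifelse(het[, j], 1L, ifelse(a1[, j] == first, 0L, 2L))
    geno[, j] <- gj
  }
  geno
}
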