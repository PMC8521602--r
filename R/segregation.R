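#' Genotype-by-phenotype counts for a candidate variant
#'
#' Counts used for the segregation check and the allele/carrier frequency
#' arithmetic. Either supply per-sample genotype classes and phenotypes, or
#' the counts directly. Samples in `exclude` (typically the affected family)
#' are removed before counting, matching a frequency estimate "excluding the
#' affected family".
#'
#' @param genotype named integer vector of genotype classes at the candidate
#'   variant (0 wild-type, 1 het, 2 hom-alt, NA missing).
#' @param phenotype named character vector (`"case"` = affected).
#' @param exclude sample ids to drop before counting.
#' @return A list of class `cohort_counts` with `n_affected`,
#'   `n_hom_alt_affected`, `n_hom_alt_unaffected`, `n_het`, `n_wt`,
#'   `n_included` and `excluded`.
#' @export
cohort_counts <- function(genotype, phenotype, exclude = character(0)) {
  ids <- intersect(names(genotype), names(phenotype))
  if (!length(ids)) stop("genotype and phenotype share no sample id")
  ids <- setdiff(ids, exclude)
  g <- genotype[ids]
  affected <- phenotype[ids] == "case"
  called <- !is.na(g)
  structure(list(
    n_affected = sum(affected & called),
    n_hom_alt_affected = sum(g == 2L & affected, na.rm = TRUE),
    n_hom_alt_unaffected = sum(g == 2L & !affected, na.rm = TRUE),
    n_het = sum(g == 1L, na.rm = TRUE),
    n_wt = sum(g == 0L, na.rm = TRUE),
    n_included = sum(called),
    excluded = exclude), class = "cohort_counts")
}

#' Check complete segregation of a recessive variant
#'
#' A recessive candidate segregates completely when every affected individual
#' is homozygous for the alternate allele and no unaffected individual is.
#' With zero affected individuals the check is undefined.
#'
#' @param counts a [cohort_counts()].
#' @return A list with `segregates` (`TRUE`/`FALSE`, `NA` when undefined)
#'   and a human-readable `report`.
#' @export
check_segregation <- function(counts) {
  if (counts$n_affected == 0) {
    warning("no affected individual: segregation cannot be assessed")
    return(list(segregates = NA,
                report = "undefined: no affected individual"))
  }
  ok <- counts$n_hom_alt_affected == counts$n_affected &&
    counts$n_hom_alt_unaffected == 0
  list(segregates = ok,
       report = sprintf(
         "%d/%d affected hom-alt; %d unaffected hom-alt; %d het; %d wild-type",
         counts$n_hom_alt_affected, counts$n_affected,
         counts$n_hom_alt_unaffected, counts$n_het, counts$n_wt))
}

#' Allele and carrier frequency
#'
#' Allele frequency = (2 x hom-alt + het) / (2 x n); carrier frequency =
#' het / n, both over the included samples (exclusions, e.g. the affected
#' family, must already be reflected in `counts` and `n_total_included`).
#' Returned as fractions; multiply by 100 for percent reporting.
#'
#' @param counts a [cohort_counts()].
#' @param n_total_included number of included samples (defaults to the count
#'   recorded in `counts`).
#' @return A list with `allele_frequency` and `carrier_frequency`.
#' @export
frequencies <- function(counts, n_total_included = counts$n_included) {
  if (is.null(n_total_included) || n_total_included == 0) {
    stop("n_total_included must be positive")
  }
  hom_alt <- counts$n_hom_alt_affected + counts$n_hom_alt_unaffected
  list(allele_frequency = (2 * hom_alt + counts$n_het) /
         (2 * n_total_included),
       carrier_frequency = counts$n_het / n_total_included)
}
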