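#' Read PLINK text PED/MAP files
#'
#' Parses a PLINK text fileset into a marker map and a genotype matrix.
#' Genotypes are recoded to classes (see [genotype_matrix()]); `0 0` is
#' missing. Phenotype column 6 follows PLINK coding: `2` = case, `1` =
#' control, anything else = unknown.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (4 columns: chrom, marker, cM, bp).
#' @return A list with elements `map` (see [marker_map()]) and `gm`
#'   (a [genotype_matrix()]).
#' @export
read_pedmap <- function(ped_path, map_path) {
  mp <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric",
                                  "numeric"))
  if (ncol(mp) != 4) stop("MAP file must have 4 columns")
  map <- tryCatch(marker_map(mp[[1]], mp[[2]], mp[[4]]),
                  error = function(e) stop("unsorted or invalid MAP: ",
                                           conditionMessage(e), call. = FALSE))
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("PED file has no samples")
  fields <- strsplit(trimws(lines), "[ \t]+")
  ids <- vapply(fields, function(f) if (length(f) >= 2) f[2] else "?",
                character(1))
  nf <- lengths(fields)
  bad <- nf != 6 + 2 * m
  if (any(bad)) {
    stop(sprintf("PED sample '%s' has %d genotype fields, expected %d (MAP has %d markers)",
                 ids[which(bad)[1]], nf[which(bad)[1]] - 6L, 2L * m, m))
  }
  if (anyDuplicated(ids)) stop("duplicate sample ids in PED")

  gt <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  pheno <- c("1" = "control", "2" = "case")[gt[, 6]]
  pheno[is.na(pheno)] <- "unknown"
  a1 <- gt[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- gt[, 6 + 2 * seq_len(m), drop = FALSE]
  half <- xor(a1 == "0", a2 == "0")
  if (any(half)) {
    warning("half-missing genotypes ('0 X') treated as missing")
  }
  miss <- a1 == "0" | a2 == "0"
  alleles <- matrix(paste0(pmin(a1, a2), "/", pmax(a1, a2)),
                    nrow(gt), m)
  alleles[miss] <- NA_character_
  dimnames(alleles) <- list(ids, map$marker)
  gm <- genotype_matrix(.recode_from_alleles(alleles), alleles, unname(pheno))
  list(map = map, gm = gm)
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_pedmap()]. Requires allele codes in `gm`; missing
#' genotypes are written as `0 0`, phenotypes as 2/1/0 for
#' case/control/unknown.
#'
#' @param gm a [genotype_matrix()] with allele codes.
#' @param map the matching [marker_map()].
#' @param ped_path,map_path output file paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_pedmap <- function(gm, map, ped_path, map_path) {
  if (is.null(gm$alleles)) stop("writing PED requires allele codes")
  if (ncol(gm$geno) != nrow(map)) stop("genotypes and map disagree in size")
  write.table(data.frame(map$chrom, map$marker, 0,
                         format(map$pos, scientific = FALSE, trim = TRUE)),
              map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  a1 <- substr(gm$alleles, 1, 1)
  a2 <- substr(gm$alleles, 3, 3)
  a1[is.na(a1)] <- "0"
  a2[is.na(a2)] <- "0"
  n <- nrow(gm$geno)
  m <- ncol(gm$geno)
  inter <- matrix(NA_character_, n, 2 * m)
  inter[, 2 * seq_len(m) - 1] <- a1
  inter[, 2 * seq_len(m)] <- a2
  pheno_code <- c(case = "2", control = "1", unknown = "0")[gm$phenotype]
  rows <- paste(rownames(gm$geno), rownames(gm$geno), "0", "0", "0",
                pheno_code,
                apply(inter, 1, paste, collapse = " "))
  writeLines(rows, ped_path)
  invisible(c(ped_path, map_path))
}
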