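#' QC configuration
#'
#' Thresholds for pre-analytical genotype QC: samples below the sample
#' call-rate minimum are dropped first, then markers below the marker
#' call-rate minimum or violating Hardy-Weinberg equilibrium. Minor-allele
#' frequency and LD pruning are deliberately not performed: they remove
#' exactly the homozygous stretches a ROH scan is looking for.
#'
#' @param min_sample_call minimum fraction of called genotypes per sample.
#' @param min_marker_call minimum fraction of called genotypes per marker.
#' @param hwe_p markers with an exact HWE p-value below this are dropped.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_sample_call = 0.95, min_marker_call = 0.95,
                      hwe_p = 1e-8) {
  stopifnot(min_sample_call >= 0, min_sample_call <= 1,
            min_marker_call >= 0, min_marker_call <= 1,
            hwe_p >= 0, hwe_p <= 1)
  structure(list(min_sample_call = min_sample_call,
                 min_marker_call = min_marker_call, hwe_p = hwe_p),
            class = "qc_config")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact p-value for departure from Hardy-Weinberg proportions:
#' conditional on the observed allele counts, the probabilities of all
#' heterozygote counts no more likely than the observed one are summed
#' (plain, non-mid p). Computed by the standard recurrence over the
#' conditional distribution, started at its mode.
#'
#' @param n_hom1,n_het,n_hom2 genotype counts (homozygote / heterozygote /
#'   other homozygote).
#' @return p-value in (0, 1].
#' @examples
#' hwe_exact_p(25, 50, 25) # modal heterozygote count at p = q: 1
#' hwe_exact_p(0, 60, 0)   # extreme heterozygote excess: << 1e-8
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  if (anyNA(c(n_hom1, n_het, n_hom2)) ||
      n_hom1 < 0 || n_het < 0 || n_hom2 < 0) {
    stop("genotype counts must be non-negative")
  }
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("at least one called genotype is required")
  nr <- 2 * min(n_hom1, n_hom2) + n_het   # rare allele count
  if (nr == 0) return(1)
  h_vals <- seq.int(nr %% 2, nr, by = 2)
  nh <- length(h_vals)
  ## mode of the conditional distribution
  mid <- floor(nr * (2 * n - nr) / (2 * n))
  if (mid %% 2 != nr %% 2) mid <- mid + 1L
  imid <- (mid - h_vals[1]) / 2 + 1
  probs <- numeric(nh)
  probs[imid] <- 1
  if (imid < nh) {
    for (i in imid:(nh - 1)) {
      h <- h_vals[i]
      hr <- (nr - h) / 2          # rare homozygotes
      hc <- n - h - hr            # common homozygotes
      probs[i + 1] <- probs[i] * 4 * hr * hc / ((h + 2) * (h + 1))
    }
  }
  if (imid > 1) {
    for (i in imid:2) {
      h <- h_vals[i]
      hr <- (nr - h) / 2
      hc <- n - h - hr
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  probs <- probs / sum(probs)
  iobs <- (n_het - h_vals[1]) / 2 + 1
  if (iobs < 1 || iobs > nh || h_vals[iobs] != n_het) {
    stop("heterozygote count inconsistent with allele counts")
  }
  min(1, sum(probs[probs <= probs[iobs] * (1 + 1e-9)]))
}

#' Apply call-rate and HWE QC
#'
#' Samples below the sample call-rate threshold are removed first; marker
#' call rates and HWE are then computed on the retained samples, and failing
#' markers removed. The operation is idempotent. Every removal is listed in
#' the report with its reason and the offending value.
#'
#' @param gm a [genotype_matrix()].
#' @param map the matching [marker_map()].
#' @param cfg a [qc_config()].
#' @return A list with the pruned `gm` and `map` plus a `report` data frame
#'   (columns `entity`, `id`, `reason`, `value`).
#' @export
apply_qc <- function(gm, map, cfg = qc_config()) {
  if (ncol(gm$geno) != nrow(map)) stop("genotypes and map disagree in size")
  report <- data.frame(entity = character(), id = character(),
                       reason = character(), value = numeric(),
                       stringsAsFactors = FALSE)

  sample_cr <- rowMeans(!is.na(gm$geno))
  drop_s <- sample_cr < cfg$min_sample_call
  if (all(drop_s)) stop("QC removed every sample (sample call rate)")
  if (any(drop_s)) {
    report <- rbind(report, data.frame(
      entity = "sample", id = rownames(gm$geno)[drop_s],
      reason = "sample_call_rate", value = sample_cr[drop_s],
      stringsAsFactors = FALSE))
    gm <- subset_genotypes(gm, samples = which(!drop_s))
  }

  g <- gm$geno
  marker_cr <- colMeans(!is.na(g))
  drop_cr <- marker_cr < cfg$min_marker_call

  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  called <- n0 + n1 + n2
  hwe <- rep(NA_real_, ncol(g))
  if (any(called == 0)) {
    warning(sum(called == 0),
            " marker(s) with no called genotypes: HWE undefined, skipped")
  }
  for (j in which(called > 0)) hwe[j] <- hwe_exact_p(n0[j], n1[j], n2[j])
  drop_hwe <- !is.na(hwe) & hwe < cfg$hwe_p

  if (any(drop_cr)) {
    report <- rbind(report, data.frame(
      entity = "marker", id = map$marker[drop_cr],
      reason = "marker_call_rate", value = marker_cr[drop_cr],
      stringsAsFactors = FALSE))
  }
  hwe_only <- drop_hwe & !drop_cr
  if (any(hwe_only)) {
    report <- rbind(report, data.frame(
      entity = "marker", id = map$marker[hwe_only],
      reason = "hwe", value = hwe[hwe_only], stringsAsFactors = FALSE))
  }
  keep <- !(drop_cr | drop_hwe)
  list(gm = subset_genotypes(gm, markers = which(keep)),
       map = map[keep, , drop = FALSE], report = report)
}
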