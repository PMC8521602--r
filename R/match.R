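#' Allelic-matching configuration
#'
#' @param min_match minimum fraction of identical unordered allele pairs for
#'   two samples to count as carrying the same haplotype over a region
#'   (PLINK `--homozyg-match` default, 0.95).
#' @param require_all_cases every case must contribute a segment to a pool
#'   for it to remain a candidate.
#' @param exclude_shared_controls a control allelically matching any case
#'   over the consensus removes the pool.
#' @return A list of class `match_config`.
#' @export
match_config <- function(min_match = 0.95, require_all_cases = TRUE,
                         exclude_shared_controls = TRUE) {
  stopifnot(min_match > 0, min_match <= 1)
  structure(list(min_match = min_match,
                 require_all_cases = require_all_cases,
                 exclude_shared_controls = exclude_shared_controls),
            class = "match_config")
}

#' Pool overlapping ROH segments across individuals
#'
#' Transitive single-linkage pooling of bp-overlapping segments on the same
#' chromosome (the grouping behind PLINK's `--homozyg-group`): two segments
#' share a pool when they overlap, directly or through a chain of overlaps.
#' Each pool records the union of its members and the member-wise consensus
#' (intersection), which is empty (`NA`) when members do not all mutually
#' overlap.
#'
#' @param segments a segment data frame from [call_roh()].
#' @return A list of class `roh_pools`: `pools` (one row per pool with union
#'   and consensus bounds) and `members` (the input segments with a `pool`
#'   column).
#' @export
pool_segments <- function(segments) {
  if (nrow(segments) == 0) {
    pools <- data.frame(pool = integer(), chrom = character(),
                        union_start = numeric(), union_end = numeric(),
                        consensus_start = numeric(), consensus_end = numeric(),
                        n_members = integer(), stringsAsFactors = FALSE)
    return(structure(list(pools = pools, members = segments),
                     class = "roh_pools"))
  }
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(segments$start, segments$end))
  ## min.gapwidth = 0: merge genuinely overlapping ranges only, not adjacent
  pool_gr <- GenomicRanges::reduce(seg_gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(seg_gr, pool_gr)
  pool_of <- rep(NA_integer_, nrow(segments))
  pool_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  members <- segments
  members$pool <- pool_of
  cons <- vapply(seq_along(pool_gr), function(p) {
    s <- segments[pool_of == p, ]
    c(max(s$start), min(s$end))
  }, numeric(2))
  empty <- cons[1, ] > cons[2, ]
  pools <- data.frame(
    pool = seq_along(pool_gr),
    chrom = as.character(GenomicRanges::seqnames(pool_gr)),
    union_start = GenomicRanges::start(pool_gr),
    union_end = GenomicRanges::end(pool_gr),
    consensus_start = ifelse(empty, NA_real_, cons[1, ]),
    consensus_end = ifelse(empty, NA_real_, cons[2, ]),
    n_members = as.integer(table(factor(pool_of, seq_along(pool_gr)))),
    stringsAsFactors = FALSE)
  structure(list(pools = pools, members = members), class = "roh_pools")
}

#' Allelic match fraction of two samples over a region
#'
#' Over the markers of the region at which both samples are called: the
#' fraction with identical unordered allele pairs. Symmetric in the two
#' samples.
#'
#' @param gm a [genotype_matrix()] with allele codes.
#' @param sample_a,sample_b sample ids.
#' @param region a single-row region data frame (see [genomic_region()]).
#' @param map the matching [marker_map()].
#' @return A list with `fraction` (`NA` if no jointly called marker, with a
#'   warning) and `n_informative`.
#' @export
allelic_match_fraction <- function(gm, sample_a, sample_b, region, map) {
  if (is.null(gm$alleles)) stop("allelic matching requires allele codes")
  if (nrow(region) != 1) stop("one region at a time")
  idx <- .markers_in_region(map, region)
  if (!length(idx)) stop("region contains no marker")
  a <- gm$alleles[sample_a, idx]
  b <- gm$alleles[sample_b, idx]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) {
    warning("no jointly called marker in region: match fraction undefined")
    return(list(fraction = NA_real_, n_informative = 0L))
  }
  list(fraction = mean(a[ok] == b[ok]), n_informative = sum(ok))
}

#' Case-specific candidate regions from pooled ROH
#'
#' A pool's consensus region (intersection of the case members' segments) is
#' reported iff (a) every case contributes a member segment, (b) all case
#' pairs are allelically matched over that consensus at `min_match` or above,
#' and (c) every control either contributes no segment overlapping the
#' consensus or matches below `min_match` against every case there
#' ("allelically different or absent in the controls"). Output regions are
#' sorted and pairwise disjoint.
#'
#' @param pools an [pool_segments()] result.
#' @param gm the [genotype_matrix()] (phenotypes define cases and controls).
#' @param map the matching [marker_map()].
#' @param cfg a [match_config()].
#' @return A region data frame of candidate regions, with a `pool` column.
#' @export
case_specific_regions <- function(pools, gm, map, cfg = match_config()) {
  cases <- names(gm$phenotype)[gm$phenotype == "case"]
  controls <- names(gm$phenotype)[gm$phenotype == "control"]
  if (!length(cases)) stop("cohort contains no case")
  res <- list()
  for (p in pools$pools$pool) {
    mem <- pools$members[pools$members$pool == p, ]
    case_mem <- mem[mem$sample %in% cases, ]
    if (cfg$require_all_cases && !all(cases %in% case_mem$sample)) next
    if (nrow(case_mem) == 0) next
    ## consensus over cases only: cases define the candidate interval. A case
    ## may contribute several segments to one pool (its run can be split by a
    ## local cluster of missing calls), so each case counts with the full
    ## interval its segments span; allelic matching over the consensus still
    ## verifies haplotype identity marker by marker.
    span_start <- tapply(case_mem$start, case_mem$sample, min)
    span_end <- tapply(case_mem$end, case_mem$sample, max)
    cs <- max(span_start)
    ce <- min(span_end)
    if (cs > ce) next
    consensus <- genomic_region(mem$chrom[1], cs, ce)
    if (!length(.markers_in_region(map, consensus))) next
    match_to_cases <- function(s) vapply(cases[cases != s], function(cc)
      allelic_match_fraction(gm, s, cc, consensus, map)$fraction, numeric(1))
    pair_ok <- TRUE
    for (i in seq_along(cases)[-1]) {
      for (jj in seq_len(i - 1)) {
        f <- allelic_match_fraction(gm, cases[i], cases[jj], consensus,
                                    map)$fraction
        if (is.na(f) || f < cfg$min_match) pair_ok <- FALSE
      }
    }
    if (!pair_ok) next
    if (cfg$exclude_shared_controls) {
      ctrl_mem <- mem[mem$sample %in% controls &
                        mem$start <= ce & mem$end >= cs, ]
      shared <- FALSE
      for (s in unique(ctrl_mem$sample)) {
        f <- suppressWarnings(match_to_cases(s))
        if (any(!is.na(f) & f >= cfg$min_match)) shared <- TRUE
      }
      if (shared) next
    }
    consensus$pool <- p
    res[[length(res) + 1]] <- consensus
  }
  if (!length(res)) {
    out <- genomic_region(character(), numeric(), numeric())
    out$pool <- integer()
    return(out)
  }
  out <- do.call(rbind, res)
  out <- out[order(match(out$chrom, unique(map$chrom)), out$start), ]
  rownames(out) <- NULL
  out
}
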