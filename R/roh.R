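#' ROH detection parameters
#'
#' Parameters of the sliding-window ROH scan, named after the PLINK 1.9
#' `--homozyg` options they mirror. Two presets reflect the two analysis
#' rounds of the workflow: `"optimization"` (strict windows used while
#' calibrating density/gap on a simulated fully homozygous individual, with
#' permissive unvaried density/gap) and `"detection"` (the shared-ROH scan
#' with the calibrated density/gap).
#'
#' @param preset `"detection"` (default) or `"optimization"`.
#' @param window_snp markers per sliding window (`--homozyg-window-snp`).
#' @param window_missing max missing calls tolerated per window
#'   (`--homozyg-window-missing`).
#' @param window_het max heterozygous calls tolerated per window
#'   (`--homozyg-window-het`).
#' @param window_threshold minimum fraction of passing windows for a marker
#'   to be ROH-eligible (`--homozyg-window-threshold`).
#' @param min_snp minimum markers per reported segment (`--homozyg-snp`);
#'   calibrate with [min_snp_count()].
#' @param min_kb minimum segment length in kb (`--homozyg-kb`).
#' @param max_gap maximum inter-marker gap in kb before a run is split
#'   (`--homozyg-gap`).
#' @param max_density maximum segment kb per SNP (`--homozyg-density`).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(preset = c("detection", "optimization"),
                       window_snp = NULL, window_missing = NULL,
                       window_het = NULL, window_threshold = NULL,
                       min_snp = NULL, min_kb = NULL, max_gap = NULL,
                       max_density = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
    detection = list(window_snp = 50, window_missing = 1, window_het = 1,
                     window_threshold = 0.05, min_snp = 70, min_kb = 1000,
                     max_gap = 200, max_density = 30),
    optimization = list(window_snp = 20, window_missing = 1, window_het = 0,
                        window_threshold = 0.05, min_snp = 70, min_kb = 1000,
                        max_gap = 2000, max_density = 200))
  override <- list(window_snp = window_snp, window_missing = window_missing,
                   window_het = window_het,
                   window_threshold = window_threshold, min_snp = min_snp,
                   min_kb = min_kb, max_gap = max_gap,
                   max_density = max_density)
  for (k in names(override)) if (!is.null(override[[k]])) p[[k]] <- override[[k]]
  stopifnot(p$window_snp >= 1, p$window_missing >= 0, p$window_het >= 0,
            p$window_threshold > 0, p$window_threshold <= 1,
            p$min_snp >= 1, p$min_kb > 0, p$max_gap > 0, p$max_density > 0)
  structure(p, class = "roh_params")
}

#' Per-marker fraction of passing sliding windows
#'
#' For one sample on one chromosome: every placement of a window of
#' `window_snp` consecutive markers that lies fully inside the chromosome's
#' marker list is scored as passing when it holds at most `window_het`
#' heterozygous and at most `window_missing` missing calls. Each marker's hit
#' fraction is the share of passing windows among the windows containing it
#' (edge markers belong to fewer windows). Chromosomes with fewer markers
#' than `window_snp` get fraction 0 everywhere. Missing genotypes count
#' toward neither homozygous nor heterozygous calls; they only consume the
#' missing allowance.
#'
#' @param geno integer genotype-class vector of one sample's markers on one
#'   chromosome, in map order.
#' @param params a [roh_params()].
#' @return Numeric vector of hit fractions, one per marker.
#' @export
window_hit_fraction <- function(geno, params) {
  m <- length(geno)
  w <- params$window_snp
  if (m < w) return(numeric(m))
  het <- !is.na(geno) & geno == 1L
  mis <- is.na(geno)
  csh <- c(0, cumsum(het))
  csm <- c(0, cumsum(mis))
  nw <- m - w + 1
  i <- seq_len(nw)
  pass <- (csh[i + w] - csh[i]) <= params$window_het &
    (csm[i + w] - csm[i]) <= params$window_missing
  cp <- c(0, cumsum(pass))
  j <- seq_len(m)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nw)
  (cp[hi + 1] - cp[lo]) / (hi - lo + 1)
}

#' Call runs of homozygosity
#'
#' Sliding-window ROH detection with PLINK 1.9 semantics. Per sample and
#' chromosome, markers whose window hit fraction (see
#' [window_hit_fraction()]) is at least `window_threshold` are ROH-eligible;
#' maximal runs of consecutive eligible markers are split wherever the bp
#' distance between neighbouring markers exceeds `max_gap` kb, and surviving
#' runs are reported iff they hold at least `min_snp` markers, span at least
#' `min_kb` kb and have a density of at most `max_density` kb per SNP.
#' Segment bounds are the bp positions of the run's first and last markers
#' (1-based inclusive); length in kb is `(end - start + 1) / 1000`. No
#' segment-level heterozygote cap is applied beyond the window allowance.
#'
#' @param gm a [genotype_matrix()] (QC'd).
#' @param map the matching [marker_map()].
#' @param params a [roh_params()].
#' @return Data frame of segments, sorted by sample, chromosome and start:
#'   columns `sample`, `chrom`, `start`, `end`, `kb`, `n_snps`, `n_het`,
#'   `n_missing`.
#' @export
call_roh <- function(gm, map, params = roh_params()) {
  if (ncol(gm$geno) != nrow(map)) stop("genotypes and map disagree in size")
  chroms <- unique(map$chrom)
  out <- vector("list", 64)
  k <- 0L
  for (s in rownames(gm$geno)) {
    for (ch in chroms) {
      idx <- which(map$chrom == ch)
      g <- gm$geno[s, idx]
      pos <- map$pos[idx]
      frac <- window_hit_fraction(g, params)
      elig <- frac >= params$window_threshold - 1e-12
      if (!any(elig)) next
      r <- rle(elig)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (ri in which(r$values)) {
        a <- starts[ri]
        b <- ends[ri]
        ## split at inter-marker gaps wider than max_gap kb
        cuts <- if (b > a) which(diff(pos[a:b]) > params$max_gap * 1000) else
          integer(0)
        sub_start <- c(a, a + cuts)
        sub_end <- c(a + cuts - 1, b)
        for (q in seq_along(sub_start)) {
          i1 <- sub_start[q]
          i2 <- sub_end[q]
          n_snps <- i2 - i1 + 1
          kb <- (pos[i2] - pos[i1] + 1) / 1000
          if (n_snps < params$min_snp || kb < params$min_kb ||
              kb / n_snps > params$max_density + 1e-12) next
          gg <- g[i1:i2]
          k <- k + 1L
          if (k > length(out)) out <- c(out, vector("list", length(out)))
          out[[k]] <- data.frame(
            sample = s, chrom = ch, start = pos[i1], end = pos[i2], kb = kb,
            n_snps = n_snps, n_het = sum(gg == 1L, na.rm = TRUE),
            n_missing = sum(is.na(gg)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0L) {
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), kb = numeric(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), stringsAsFactors = FALSE))
  }
  segs <- do.call(rbind, out[seq_len(k)])
  segs <- segs[order(match(segs$sample, rownames(gm$geno)),
                     match(segs$chrom, chroms), segs$start), ]
  rownames(segs) <- NULL
  segs
}

#' Genome coverage of ROH segments
#'
#' Total segment length divided by the marker-spanned extent of the map (sum
#' over chromosomes of last minus first marker position plus one). Intended
#' for the segments of a single individual; segments of one sample must not
#' overlap.
#'
#' @param segments a segment data frame from [call_roh()].
#' @param map the [marker_map()] the segments were called on.
#' @return Coverage fraction in `[0, 1]` for one fully homozygous individual
#'   (sums across samples if several are present).
#' @export
roh_coverage <- function(segments, map) {
  if (nrow(segments) == 0) return(0)
  for (key in split(seq_len(nrow(segments)),
                    paste(segments$sample, segments$chrom))) {
    s <- segments[key, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("overlapping ROH segments for one sample")
    }
  }
  sum(segments$end - segments$start + 1) / .map_extent(map)
}
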