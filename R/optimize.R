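#' Population-calibrated minimum ROH marker count
#'
#' Minimum number of consecutive homozygous markers for a run to be unlikely
#' to arise by chance, following the standard false-positive argument for ROH
#' scans: the expected number of chance runs across `n_snps` markers in
#' `n_individuals` individuals is capped at `alpha`, giving
#' `ln(alpha / (n_snps * n_individuals)) / ln(1 - mean_het)`, rounded down
#' (never below 1).
#'
#' @param alpha tolerated expected number of false-positive runs (0-1).
#' @param n_snps markers retained after QC.
#' @param n_individuals genotyped individuals entering the scan.
#' @param mean_het mean per-marker SNP heterozygosity of the population
#'   (fraction; see [mean_heterozygosity()]).
#' @return Integer minimum marker count.
#' @examples
#' min_snp_count(0.05, 154235, 6, 0.21) # 70
#' @export
min_snp_count <- function(alpha, n_snps, n_individuals, mean_het) {
  stopifnot(alpha > 0, alpha < 1, n_snps >= 1, n_individuals >= 1,
            mean_het >= 0, mean_het < 1)
  if (mean_het == 0) stop("mean_het must be positive (formula undefined at 0)")
  val <- log(alpha / (n_snps * n_individuals)) / log(1 - mean_het)
  max(1L, as.integer(floor(val)))
}

#' Mean SNP heterozygosity
#'
#' Mean over markers of the fraction of heterozygous calls among non-missing
#' calls. Markers with no called genotype are excluded.
#'
#' @param gm a [genotype_matrix()].
#' @return Heterozygosity fraction in `[0, 1]`.
#' @export
mean_heterozygosity <- function(gm) {
  g <- gm$geno
  het <- colSums(g == 1L, na.rm = TRUE)
  called <- colSums(!is.na(g))
  ok <- called > 0
  if (!any(ok)) stop("no marker has a called genotype")
  mean(het[ok] / called[ok])
}

#' Configuration for the density/gap grid search
#'
#' @param density_grid increasing grid of `max_density` values (kb/SNP).
#' @param gap_grid increasing grid of `max_gap` values (kb).
#' @param base_params [roh_params()] holding every unvaried value; defaults
#'   to the `"optimization"` preset (strict 20-SNP/0-het windows, gap 2000 kb
#'   and density 200 kb/SNP when unvaried).
#' @param plateau_tol absolute coverage gain below which the gap curve is
#'   considered flat ("increased only negligibly").
#' @return A list of class `optimization_config`.
#' @export
optimization_config <- function(density_grid = seq(10, 125, by = 5),
                                gap_grid = seq(20, 1000, by = 20),
                                base_params = roh_params("optimization"),
                                plateau_tol = 0.001) {
  stopifnot(length(density_grid) > 0, length(gap_grid) > 0,
            !is.unsorted(density_grid, strictly = TRUE),
            !is.unsorted(gap_grid, strictly = TRUE),
            plateau_tol >= 0)
  structure(list(density_grid = density_grid, gap_grid = gap_grid,
                 base_params = base_params, plateau_tol = plateau_tol),
            class = "optimization_config")
}

#' Calibrate ROH density and gap on a simulated homozygote
#'
#' Simulates a fully homozygous individual over the map (see
#' [simulate_homozygous_individual()]) and sweeps each grid one-dimensionally
#' with the other parameter held at its unvaried base value, recording the
#' ROH genome coverage of each setting. The chosen density is the smallest
#' grid value whose coverage reaches the maximum attained over the density
#' grid; the chosen gap is the smallest grid value beyond which no later grid
#' value gains more than `plateau_tol` coverage.
#'
#' @param map a [marker_map()] (typically post-QC).
#' @param cfg an [optimization_config()].
#' @return A list with `density`, `gap` and the full `table` of
#'   (parameter, value, coverage) rows.
#' @export
optimize_density_gap <- function(map, cfg = optimization_config()) {
  if (nrow(map) == 0) stop("marker map is empty")
  hom <- simulate_homozygous_individual(map)
  cov_at <- function(density, gap) {
    p <- cfg$base_params
    p$max_density <- density
    p$max_gap <- gap
    roh_coverage(call_roh(hom, map, p), map)
  }
  dens_cov <- vapply(cfg$density_grid, cov_at, numeric(1),
                     gap = cfg$base_params$max_gap)
  gap_cov <- vapply(cfg$gap_grid, function(g)
    cov_at(cfg$base_params$max_density, g), numeric(1))

  chosen_density <- cfg$density_grid[
    which(dens_cov >= max(dens_cov) - 1e-12)[1]]
  remaining_max <- rev(cummax(rev(gap_cov)))
  flat <- remaining_max - gap_cov < cfg$plateau_tol
  chosen_gap <- cfg$gap_grid[which(flat)[1]]

  list(density = chosen_density, gap = chosen_gap,
       table = data.frame(
         parameter = c(rep("density", length(cfg$density_grid)),
                       rep("gap", length(cfg$gap_grid))),
         value = c(cfg$density_grid, cfg$gap_grid),
         coverage = c(dens_cov, gap_cov), stringsAsFactors = FALSE))
}
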