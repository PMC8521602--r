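#' Simulation configuration
#'
#' Defines a desk-scale synthetic cohort with the statistical structure the
#' mapping assumes: a multi-chromosome SNP array, a litter of affected
#' siblings homozygous for one founder haplotype across a planted autozygous
#' segment, carrier/non-carrier relatives, unrelated controls, and a variant
#' call set holding the causal variant plus decoys that exercise every filter
#' branch.
#'
#' Defaults: 3 autosomes of 60 Mb with 3,000 markers each (~20 kb mean
#' spacing, emulating a dense genotyping array), mean SNP heterozygosity
#' 0.21, 1% per-genotype missingness, 4 affected littermates, 6 relatives
#' (2 carrier parents, 4 unaffected littermates), 20 unrelated controls, and
#' a 4.3 Mb planted segment carrying the causal variant.
#'
#' @param chr_lengths named numeric vector of chromosome lengths (bp).
#' @param markers_per_chrom markers simulated per chromosome (>= 70).
#' @param mean_het target mean per-marker heterozygosity (fraction).
#' @param miss_rate per-genotype missing probability.
#' @param n_cases,n_relatives,n_controls cohort sizes (`n_relatives >= 2`:
#'   the first two relatives are the carrier parents).
#' @param planted_region single-row region data frame: the autozygous
#'   segment shared homozygously by all cases.
#' @param causal_pos bp position of the causal variant (inside the planted
#'   region).
#' @param n_background_variants random SNV/indel records added to the call
#'   set besides the causal variant and the decoys.
#' @param seed integer random seed (`NULL`: use the current RNG state).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chr_lengths = c(chr1 = 60e6, chr2 = 60e6,
                                       chr3 = 60e6),
                       markers_per_chrom = 3000,
                       mean_het = 0.21,
                       miss_rate = 0.01,
                       n_cases = 4, n_relatives = 6, n_controls = 20,
                       planted_region = genomic_region("chr2", 30000001,
                                                       34300000),
                       causal_pos = 32150000,
                       n_background_variants = 40,
                       seed = NULL) {
  stopifnot(length(chr_lengths) >= 1, all(chr_lengths > 0),
            markers_per_chrom >= 70,
            mean_het > 0, mean_het < 0.5,
            miss_rate >= 0, miss_rate <= 1,
            n_cases >= 1, n_relatives >= 2, n_controls >= 0,
            nrow(planted_region) == 1)
  if (is.null(names(chr_lengths))) {
    names(chr_lengths) <- paste0("chr", seq_along(chr_lengths))
  }
  if (!planted_region$chrom %in% names(chr_lengths) ||
      planted_region$end > chr_lengths[[planted_region$chrom]]) {
    stop("planted region must lie on a simulated chromosome")
  }
  if (causal_pos < planted_region$start || causal_pos > planted_region$end) {
    stop("causal variant must lie inside the planted region")
  }
  structure(list(chr_lengths = chr_lengths,
                 markers_per_chrom = markers_per_chrom, mean_het = mean_het,
                 miss_rate = miss_rate, n_cases = n_cases,
                 n_relatives = n_relatives, n_controls = n_controls,
                 planted_region = planted_region, causal_pos = causal_pos,
                 n_background_variants = n_background_variants, seed = seed),
            class = "sim_config")
}

#' Simulate a genotyped cohort with a planted autozygous segment
#'
#' Marker positions are drawn uniformly per chromosome. Per-marker allele
#' frequencies come from a symmetric Beta whose single shape parameter is
#' tuned so that the expected heterozygosity `E[2p(1-p)]` equals the target
#' (shape `h / (1 - 2h)`); founder haplotypes and cohort genotypes are then
#' drawn under Hardy-Weinberg proportions. All cases are made homozygous for
#' one founder haplotype across the planted region; the first two relatives
#' (the parents) and a random half of the remaining relatives carry one copy.
#' Missingness is injected uniformly at random after planting. The variant
#' call set holds the causal variant (hom-alt in every case, het in the
#' carriers and in two unrelated controls), recessive-filter decoys, private
#' SV/MEI records with their decoys, and random background variants; a small
#' gene model makes the causal variant exonic.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_population`: `map`, `gm`, `pedigree`,
#'   `variants` (a [variant_table()]), `genes` (a [gene_model()]) and
#'   `truth` (planted region, ids of causal/decoy records, sample roles).
#' @export
simulate_population <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  reg <- config$planted_region

  ## --- marker map ---------------------------------------------------------
  chroms <- names(config$chr_lengths)
  pos_list <- lapply(chroms, function(ch)
    sort(sample.int(config$chr_lengths[[ch]], config$markers_per_chrom)))
  map <- marker_map(
    rep(chroms, each = config$markers_per_chrom),
    paste0(rep(chroms, each = config$markers_per_chrom), "_",
           rep(seq_len(config$markers_per_chrom), length(chroms))),
    unlist(pos_list))
  m <- nrow(map)
  reg_idx <- .markers_in_region(map, reg)
  if (!length(reg_idx)) stop("infeasible config: planted region has no marker")

  ## --- samples ------------------------------------------------------------
  case_ids <- paste0("case", seq_len(config$n_cases))
  rel_ids <- paste0("rel", seq_len(config$n_relatives))
  ctrl_ids <- if (config$n_controls > 0)
    paste0("ctrl", seq_len(config$n_controls)) else character(0)
  ids <- c(case_ids, rel_ids, ctrl_ids)
  n <- length(ids)

  ## --- array genotypes ----------------------------------------------------
  shape <- config$mean_het / (1 - 2 * config$mean_het)
  p_alt <- rbeta(m, shape, shape)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    ra <- sample(c("A", "C", "G", "T"), 2)
    ref[j] <- ra[1]
    alt[j] <- ra[2]
  }
  h1 <- matrix(rbinom(n * m, 1, rep(p_alt, each = n)), n, m)  # alt indicator
  h2 <- matrix(rbinom(n * m, 1, rep(p_alt, each = n)), n, m)

  planted_hap <- rbinom(length(reg_idx), 1, p_alt[reg_idx])
  extra_carriers <- if (config$n_relatives > 2)
    rel_ids[-(1:2)][rbinom(config$n_relatives - 2, 1, 0.5) == 1] else
      character(0)
  carrier_ids <- c(rel_ids[1:2], extra_carriers)
  for (s in case_ids) {
    i <- match(s, ids)
    h1[i, reg_idx] <- planted_hap
    h2[i, reg_idx] <- planted_hap
  }
  for (s in carrier_ids) h1[match(s, ids), reg_idx] <- planted_hap

  base <- matrix(rep(ref, each = n), n, m)
  altm <- matrix(rep(alt, each = n), n, m)
  a1 <- ifelse(h1 == 1, altm, base)
  a2 <- ifelse(h2 == 1, altm, base)
  alleles <- matrix(paste0(pmin(a1, a2), "/", pmax(a1, a2)), n, m,
                    dimnames = list(ids, map$marker))
  if (config$miss_rate > 0) {
    alleles[runif(n * m) < config$miss_rate] <- NA_character_
  }
  phenotype <- c(rep("case", config$n_cases),
                 rep("control", n - config$n_cases))
  gm <- genotype_matrix(.recode_from_alleles(alleles), alleles, phenotype)

  ## --- pedigree -----------------------------------------------------------
  litter <- c(case_ids, if (config$n_relatives > 2) rel_ids[-(1:2)])
  pedigree <- data.frame(
    id = ids,
    sire = ifelse(ids %in% litter, rel_ids[1], NA_character_),
    dam = ifelse(ids %in% litter, rel_ids[2], NA_character_),
    phenotype = phenotype,
    planted_copies = ifelse(ids %in% case_ids, 2L,
                            ifelse(ids %in% carrier_ids, 1L, 0L)),
    stringsAsFactors = FALSE)

  ## --- variant call set ---------------------------------------------------
  geno_of <- function(hom_alt = character(0), het = character(0)) {
    g <- rep(0L, n)
    g[match(hom_alt, ids)] <- 2L
    g[match(het, ids)] <- 1L
    g
  }
  causal_ctrl_het <- if (length(ctrl_ids) >= 2) ctrl_ids[1:2] else ctrl_ids
  rpos <- function(lo, hi, k = 1) sort(round(runif(k, lo, hi)))
  in_start <- reg$start
  in_end <- reg$end
  vrec <- function(chrom, pos, id, ref = "G", alt = "C", class = "SNV",
                   svtype = NA_character_, end = NA_real_) {
    data.frame(chrom = chrom, pos = pos, id = id, ref = ref, alt = alt,
               class = class, svtype = svtype, end = end,
               consequence = NA_character_, stringsAsFactors = FALSE)
  }
  recs <- list(
    list(vrec(reg$chrom, config$causal_pos, "causal"),
         geno_of(hom_alt = case_ids,
                 het = c(carrier_ids, causal_ctrl_het))),
    ## recessive-filter decoys
    list(vrec(reg$chrom, rpos(in_start, config$causal_pos - 10),
              "decoy_het_case"),
         geno_of(hom_alt = case_ids[-1], het = case_ids[1])),
    list(vrec(chroms[1], rpos(5e6, 6e6), "decoy_out_roh", ref = "T",
              alt = "TA", class = "indel"),
         geno_of(hom_alt = case_ids)),
    list(vrec(reg$chrom, rpos(config$causal_pos + 10, in_end),
              "decoy_ctrl_het3"),
         geno_of(hom_alt = case_ids,
                 het = ctrl_ids[seq_len(min(3, length(ctrl_ids)))])),
    list(vrec(reg$chrom, rpos(config$causal_pos + 10, in_end),
              "decoy_ctrl_homalt"),
         geno_of(hom_alt = c(case_ids, ctrl_ids[min(4, length(ctrl_ids))]))),
    ## SV/MEI records (private-variant mode uses the first case only)
    local({
      p <- rpos(in_start, in_end - 10)
      list(vrec(reg$chrom, p, "mei_roh", ref = "N",
                alt = "<INS:ME:LINE1>", class = "MEI", svtype = "INS:ME",
                end = p + 6),
           geno_of(het = case_ids[1]))
    }),
    list(vrec(chroms[1], 12e6, "sv_out_roh", ref = "N", alt = "<DEL>",
              class = "SV", svtype = "DEL", end = 12e6 + 5e4),
         geno_of(het = case_ids[1])),
    local({
      p <- rpos(in_start, in_end - 3e4)
      list(vrec(reg$chrom, p, "sv_decoy_shared",
                ref = "N", alt = "<DEL>", class = "SV", svtype = "DEL",
                end = p + 2e4),
           geno_of(het = c(case_ids[1],
                           ctrl_ids[seq_len(min(5, length(ctrl_ids)))])))
    }))
  ## random background SNVs: Hardy-Weinberg at a random frequency
  if (config$n_background_variants > 0) {
    for (b in seq_len(config$n_background_variants)) {
      ch <- sample(chroms, 1)
      q <- runif(1, 0.05, 0.5)
      g <- rbinom(n, 2, q)
      recs[[length(recs) + 1]] <- list(
        vrec(ch, rpos(1, config$chr_lengths[[ch]]),
             sprintf("bg%03d", b), ref = "A", alt = "G"), g)
    }
  }
  variants <- do.call(rbind, lapply(recs, `[[`, 1))
  vgeno <- do.call(rbind, lapply(recs, function(r) as.integer(r[[2]])))
  colnames(vgeno) <- ids
  ord <- order(match(variants$chrom, chroms), variants$pos)
  vt <- variant_table(variants[ord, ], vgeno[ord, , drop = FALSE])

  ## --- gene model ---------------------------------------------------------
  cp <- config$causal_pos
  genes <- gene_model(
    transcript = c(rep("TX1", 6), rep("TX2", 4)),
    chrom = c(rep(reg$chrom, 6), rep(chroms[1], 4)),
    strand = c(rep("+", 6), rep("-", 4)),
    type = c("exon", "exon", "exon", "CDS", "CDS", "CDS",
             "exon", "exon", "CDS", "CDS"),
    start = c(cp - 10000, cp - 400, cp + 4200,
              cp - 9800, cp - 400, cp + 4200,
              5.0e6, 5.9e6, 5.05e6, 5.90e6),
    end = c(cp - 9500, cp + 300, cp + 5200,
            cp - 9500, cp + 300, cp + 4800,
            5.2e6, 6.0e6, 5.20e6, 5.95e6))

  truth <- list(planted_region = reg, causal_id = "causal",
                causal_pos = config$causal_pos,
                case_ids = case_ids, relative_ids = rel_ids,
                control_ids = ctrl_ids, carrier_ids = carrier_ids,
                decoy_ids = c("decoy_het_case", "decoy_out_roh",
                              "decoy_ctrl_het3", "decoy_ctrl_homalt",
                              "sv_out_roh", "sv_decoy_shared"),
                sv_causal_id = "mei_roh")
  structure(list(map = map, gm = gm, pedigree = pedigree, variants = vt,
                 genes = genes, truth = truth, config = config),
            class = "sim_population")
}

#' Simulate a fully homozygous individual over a map
#'
#' One sample homozygous at every marker with no missing call - the input of
#' the density/gap calibration: on such an individual any failure to cover
#' the genome with ROH is attributable to the map's marker spacing alone.
#'
#' @param map a [marker_map()].
#' @return A [genotype_matrix()] with a single sample `SIM_HOM`.
#' @export
simulate_homozygous_individual <- function(map) {
  if (nrow(map) == 0) stop("marker map is empty")
  geno <- matrix(0L, 1, nrow(map), dimnames = list("SIM_HOM", map$marker))
  alleles <- matrix("A/A", 1, nrow(map),
                    dimnames = list("SIM_HOM", map$marker))
  genotype_matrix(geno, alleles, "unknown")
}

#' Write a simulated population to disk
#'
#' Emits the PED/MAP fileset, the VCF, the gene model GFF3, a phenotype
#' table, the truth BED (planted region) and a truth JSON.
#'
#' @param sim a [simulate_population()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_pedmap(sim$gm, sim$map, fp("cohort.ped"), fp("cohort.map"))
  write_vcf(sim$variants, fp("cohort.vcf"))
  write_gene_model(sim$genes, fp("genes.gff3"))
  write_bed(sim$truth$planted_region, fp("truth.bed"))
  write.table(data.frame(id = names(sim$gm$phenotype),
                         phenotype = sim$gm$phenotype),
              fp("pheno.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
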