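#' Pipeline configuration
#'
#' One configuration object driving the whole mapping run:
#' simulate (or load) -> QC -> parameter calibration -> ROH detection ->
#' pooling and allelic matching -> variant filtering -> consequence
#' classification -> segregation arithmetic. Parameter flow mirrors the
#' mapping workflow: the false-positive formula feeds `min_snp`, the
#' simulated-homozygote grid search feeds `max_density`/`max_gap`, and the
#' detection-preset window parameters do the shared-ROH scan.
#'
#' @param sim a [sim_config()] (used when `input` is `NULL`).
#' @param input optional list of paths for a file-based run: `ped`, `map`,
#'   `vcf`, `genes`, plus `control_panel` (ids of the variant-filter control
#'   panel) and optionally `family` (ids excluded from population
#'   frequencies).
#' @param qc a [qc_config()].
#' @param alpha false-positive allowance of [min_snp_count()].
#' @param density_grid,gap_grid,plateau_tol grid-search settings (see
#'   [optimization_config()]).
#' @param roh named list of [roh_params()] overrides for the detection scan.
#' @param match a [match_config()].
#' @param max_het_controls,max_hom_controls control allowances of the
#'   SNV/indel recessive filter; the SV/MEI private-variant filter always
#'   uses 0/0.
#' @param seed integer seed for the simulated run (overrides `sim$seed`).
#' @param out_dir if non-`NULL`, stage outputs are written here.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input = NULL,
                            qc = qc_config(), alpha = 0.05,
                            density_grid = seq(10, 125, by = 5),
                            gap_grid = seq(20, 1000, by = 20),
                            plateau_tol = 0.001,
                            roh = list(), match = match_config(),
                            max_het_controls = 2, max_hom_controls = 0,
                            seed = NULL, out_dir = NULL) {
  structure(list(sim = sim, input = input, qc = qc, alpha = alpha,
                 density_grid = density_grid, gap_grid = gap_grid,
                 plateau_tol = plateau_tol, roh = roh, match = match,
                 max_het_controls = max_het_controls,
                 max_hom_controls = max_hom_controls, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `sim`, `qc`,
#' `match` and `roh` are nested maps passed to the respective constructors
#' (the `sim` key `planted_region` is given as `chrom`/`start`/`end`).
#'
#' @param path a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) {
    s <- y$sim
    if (!is.null(s$planted_region)) {
      s$planted_region <- genomic_region(s$planted_region$chrom,
                                         s$planted_region$start,
                                         s$planted_region$end)
    }
    if (!is.null(s$chr_lengths)) s$chr_lengths <- unlist(s$chr_lengths)
    do.call(sim_config, s)
  } else sim_config()
  args <- list(sim = sim)
  if (!is.null(y$qc)) args$qc <- do.call(qc_config, y$qc)
  if (!is.null(y$match)) args$match <- do.call(match_config, y$match)
  for (k in c("input", "alpha", "density_grid", "gap_grid", "plateau_tol",
              "roh", "max_het_controls", "max_hom_controls", "seed",
              "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

.vt_subset <- function(vt, idx) {
  variant_table(vt$variants[idx, , drop = FALSE],
                vt$geno[idx, , drop = FALSE])
}

.vt_rbind <- function(a, b) {
  variant_table(rbind(a$variants, b$variants), rbind(a$geno, b$geno))
}

#' Run the full homozygosity-mapping pipeline
#'
#' Executes every stage in order and returns a run report; see
#' [pipeline_config()] for the stage wiring. Deterministic given the seed.
#'
#' @param cfg a [pipeline_config()].
#' @return A list of class `roh_report` with per-stage results: QC report,
#'   mean heterozygosity, calibrated parameters, ROH segments, candidate
#'   regions, surviving variants with consequence classes, the summary
#'   matrix, and segregation/frequency arithmetic for the top candidate.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stage <- "input"
  fail <- function(e) stop(sprintf("pipeline stage '%s' failed: %s", stage,
                                   conditionMessage(e)), call. = FALSE)
  tryCatch({
    if (is.null(cfg$input)) {
      if (!is.null(cfg$seed)) cfg$sim$seed <- cfg$seed
      sim <- simulate_population(cfg$sim)
      map <- sim$map
      gm <- sim$gm
      vt <- sim$variants
      genes <- sim$genes
      panel <- sim$truth$control_ids
      family <- c(sim$truth$case_ids, sim$truth$relative_ids)
      truth <- sim$truth
    } else {
      pm <- read_pedmap(cfg$input$ped, cfg$input$map)
      map <- pm$map
      gm <- pm$gm
      vt <- read_vcf(cfg$input$vcf)
      genes <- read_gene_model(cfg$input$genes)
      panel <- cfg$input$control_panel
      family <- if (!is.null(cfg$input$family)) cfg$input$family else
        character(0)
      truth <- NULL
    }
    cases <- names(gm$phenotype)[gm$phenotype == "case"]

    stage <- "qc"
    qc <- apply_qc(gm, map, cfg$qc)

    stage <- "calibration"
    het <- mean_heterozygosity(qc$gm)
    min_snp <- min_snp_count(cfg$alpha, nrow(qc$map), nrow(qc$gm$geno), het)
    opt <- optimize_density_gap(qc$map, optimization_config(
      cfg$density_grid, cfg$gap_grid,
      roh_params("optimization", min_snp = min_snp), cfg$plateau_tol))

    stage <- "roh_detection"
    det <- do.call(roh_params, c(list(preset = "detection",
                                      min_snp = min_snp,
                                      max_density = opt$density,
                                      max_gap = opt$gap), cfg$roh))
    segs <- call_roh(qc$gm, qc$map, det)

    stage <- "roh_matching"
    pools <- pool_segments(segs)
    regions <- case_specific_regions(pools, qc$gm, qc$map, cfg$match)

    stage <- "variant_filtering"
    is_small <- vt$variants$class %in% c("SNV", "indel")
    snv_kept <- recessive_filter(
      .vt_subset(vt, which(is_small)),
      filter_config(cases, panel, cfg$max_het_controls,
                    cfg$max_hom_controls, "snv"))
    sv_kept <- if (any(!is_small)) {
      recessive_filter(.vt_subset(vt, which(!is_small)),
                       filter_config(cases[1], panel, 0, 0, "sv"))
    } else .vt_subset(vt, integer(0))
    survivors <- classify_consequence(.vt_rbind(snv_kept, sv_kept), genes)
    summary_mat <- tabulate_filter_summary(survivors, regions)
    in_roh <- intersect_regions(survivors, regions)

    stage <- "segregation"
    seg_res <- NULL
    if (nrow(in_roh$variants)) {
      exonic <- which(in_roh$variants$consequence == "exonic")
      cand <- if (length(exonic)) exonic[1] else 1L
      cand_id <- in_roh$variants$id[cand]
      g <- in_roh$geno[cand, ]
      counts_all <- cohort_counts(g, gm$phenotype)
      counts_pop <- cohort_counts(g, gm$phenotype, exclude = family)
      freqs <- if (counts_pop$n_included > 0) frequencies(counts_pop) else
        list(allele_frequency = NA_real_, carrier_frequency = NA_real_)
      seg_res <- c(list(candidate = cand_id),
                   check_segregation(counts_all), freqs)
    }

    report <- structure(list(
      n_samples = nrow(gm$geno), n_markers = nrow(map),
      qc = list(n_samples_removed = sum(qc$report$entity == "sample"),
                n_markers_removed = sum(qc$report$entity == "marker"),
                report = qc$report),
      mean_heterozygosity = het, min_snp = min_snp,
      density = opt$density, gap = opt$gap, optimization_table = opt$table,
      detection_params = unclass(det),
      segments = segs, pools = pools$pools,
      candidate_regions = regions,
      survivors = cbind(survivors$variants,
                        in_roh = survivors$variants$id %in%
                          in_roh$variants$id),
      summary = summary_mat,
      segregation = seg_res), class = "roh_report")
    if (!is.null(truth)) {
      jac <- if (nrow(regions)) max(vapply(seq_len(nrow(regions)),
        function(i) jaccard_overlap(regions[i, c("chrom", "start", "end")],
                                    truth$planted_region), numeric(1))) else 0
      report$truth_eval <- list(
        planted_jaccard = jac,
        causal_retained = truth$causal_id %in% in_roh$variants$id,
        decoys_removed = !any(truth$decoy_ids %in% in_roh$variants$id))
    }

    if (!is.null(cfg$out_dir)) {
      stage <- "output"
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      fp <- function(x) file.path(cfg$out_dir, x)
      wt <- function(x, f) write.table(x, fp(f), sep = "\t", quote = FALSE,
                                       row.names = FALSE)
      wt(qc$report, "qc.tsv")
      wt(opt$table, "opt.tsv")
      wt(segs, "roh.tsv")
      if (nrow(segs)) {
        write_bed(genomic_region(segs$chrom, segs$start, segs$end),
                  fp("roh.bed"))
      }
      if (nrow(regions)) {
        write_bed(regions[, c("chrom", "start", "end")], fp("regions.bed"))
      }
      write_vcf(survivors, fp("kept.vcf"))
      write.table(report$summary, fp("summary.tsv"), sep = "\t",
                  quote = FALSE, col.names = NA)
      jsonlite::write_json(
        report[setdiff(names(report), c("optimization_table", "pools"))],
        fp("report.json"), auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    report
  }, error = fail)
}

#' @exportS3Method base::print
print.roh_report <- function(x, ...) {
  cat("homozygosity-mapping run\n")
  cat(sprintf("  cohort: %d samples, %d markers (%d samples / %d markers removed by QC)\n",
              x$n_samples, x$n_markers, x$qc$n_samples_removed,
              x$qc$n_markers_removed))
  cat(sprintf("  mean heterozygosity %.3f -> min ROH markers %d; density %g kb/SNP, gap %g kb\n",
              x$mean_heterozygosity, x$min_snp, x$density, x$gap))
  cat(sprintf("  %d ROH segments -> %d case-specific region(s)\n",
              nrow(x$segments), nrow(x$candidate_regions)))
  for (i in seq_len(nrow(x$candidate_regions))) {
    r <- x$candidate_regions[i, ]
    cat(sprintf("    %s:%s-%s (%.1f Mb)\n", r$chrom,
                format(r$start, big.mark = ","),
                format(r$end, big.mark = ","),
                region_length_mb(r)))
  }
  cat(sprintf("  %d variant(s) survive filtering, %d in candidate regions\n",
              nrow(x$survivors), sum(x$survivors$in_roh)))
  if (!is.null(x$segregation)) {
    cat(sprintf("  candidate %s: %s; allele freq %.1f%%, carrier freq %.1f%%\n",
                x$segregation$candidate, x$segregation$report,
                100 * x$segregation$allele_frequency,
                100 * x$segregation$carrier_frequency))
  }
  invisible(x)
}
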