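test_that("recessive filter honors the case requirement and control allowances", {
  samples <- c("caseA", "caseB", paste0("k", 1:10))
  geno <- rbind(
    at_boundary = c(2L, 2L, 1L, 1L, rep(0L, 8)),   # 2 het controls: kept
    het_case    = c(1L, 2L, rep(0L, 10)),          # het case: dropped
    over_budget = c(2L, 2L, 1L, 1L, 1L, rep(0L, 7)),  # 3 het controls
    hom_control = c(2L, 2L, 2L, rep(0L, 9)),       # hom-alt control
    miss_case   = c(NA, 2L, rep(0L, 10)),          # missing case fails
    miss_ctrl   = c(2L, 2L, NA, NA, rep(0L, 8)))   # missing controls ignored
  colnames(geno) <- samples
  vt <- toy_vt(geno)
  cfg <- filter_config(c("caseA", "caseB"), paste0("k", 1:10))
  kept <- recessive_filter(vt, cfg)
  expect_equal(kept$variants$id,
               vt$variants$id[rownames(geno) %in%
                                c("at_boundary", "miss_ctrl")])
  ## SV mode accepts het-or-hom cases
  sv_cfg <- filter_config("caseA", paste0("k", 1:10), 0, 0, mode = "sv")
  sv <- toy_vt(matrix(c(1L, 0L, rep(0L, 10)), 1,
                      dimnames = list(NULL, samples)), class = "SV",
               end = 2e6)
  expect_equal(nrow(recessive_filter(sv, sv_cfg)$variants), 1)
  expect_error(recessive_filter(vt, filter_config("nope", "k1")), "nope")
  expect_error(filter_config("a", c("a", "b")), "disjoint")
})

test_that("recessive filter equals exhaustive rule evaluation on random tables", {
  set.seed(101)
  samples <- c(paste0("case", 1:3), paste0("k", 1:8))
  for (rep in 1:60) {
    geno <- matrix(sample(c(0L, 1L, 2L, NA), 12 * 11, TRUE,
                          prob = c(0.5, 0.25, 0.15, 0.1)), 12, 11,
                   dimnames = list(NULL, samples))
    cfg <- filter_config(paste0("case", 1:3), paste0("k", 1:8),
                         max_het_controls = sample(0:3, 1),
                         max_hom_controls = sample(0:1, 1),
                         mode = sample(c("snv", "sv"), 1))
    vt <- toy_vt(geno)
    kept <- recessive_filter(vt, cfg)
    expect_equal(kept$variants$id,
                 vt$variants$id[oracle_recessive_keep(vt, cfg)])
  }
})

test_that("filters are monotone in the control panel and commute with intersection", {
  set.seed(102)
  samples <- c("case1", paste0("k", 1:6))
  geno <- matrix(sample(c(0L, 1L, 2L, NA), 20 * 7, TRUE), 20, 7,
                 dimnames = list(NULL, samples))
  vt <- toy_vt(geno, pos = seq(1e6, by = 2e5, length.out = 20))
  small <- filter_config("case1", paste0("k", 1:4))
  large <- filter_config("case1", paste0("k", 1:6))
  expect_true(all(recessive_filter(vt, large)$variants$id %in%
                    recessive_filter(vt, small)$variants$id))

  regions <- genomic_region("chr1", 2e6, 3.5e6)
  a <- intersect_regions(recessive_filter(vt, small), regions)
  b <- recessive_filter(intersect_regions(vt, regions), small)
  expect_identical(a$variants, b$variants)
  expect_identical(a$geno, b$geno)
})

test_that("region intersection uses inclusive bounds and any-overlap for spans", {
  regions <- genomic_region(c("chr1", "chr2"), c(1e6, 5e6), c(2e6, 6e6))
  geno <- matrix(0L, 4, 1, dimnames = list(NULL, "s"))
  vt <- toy_vt(geno, chrom = c("chr1", "chr1", "chr1", "chr2"),
               pos = c(1e6, 999999, 990000, 5.9e6),
               class = c("SNV", "SNV", "SV", "SV"),
               end = c(NA, NA, 1.05e6, 7e6))
  kept <- intersect_regions(vt, regions)
  ## exact start bp kept; 1 bp before dropped; straddling SVs kept
  expect_equal(kept$variants$id, c("v1", "v3", "v4"))
})

test_that("region intersection equals a linear interval scan", {
  set.seed(103)
  regions <- genomic_region(c("chr1", "chr1"), c(1e6, 8e6), c(3e6, 9e6))
  for (rep in 1:20) {
    cls <- sample(c("SNV", "indel", "SV", "MEI"), 10, TRUE)
    pos <- sort(sample.int(10e6, 10))
    vt <- toy_vt(matrix(0L, 10, 1, dimnames = list(NULL, "s")),
                 chrom = sample(c("chr1", "chr2"), 10, TRUE), pos = pos,
                 class = cls,
                 end = ifelse(cls %in% c("SV", "MEI"),
                              pos + sample.int(5e5, 10), NA))
    expect_equal(intersect_regions(vt, regions)$variants$id,
                 vt$variants$id[oracle_in_regions(vt, regions)])
  }
})

probe_model <- function() {
  ## T1 (+): exons 1000-1999 / 3000-3999 / 5000-5999, CDS 1500-1999 & 3000-3499
  ## T2 (+): single exon 8000-8999, CDS 8200-8799
  ## T3 (-): exons 12000-12999 / 14000-14999, no CDS annotated
  gene_model(
    transcript = c("T1", "T1", "T1", "T1", "T1", "T2", "T2", "T3", "T3"),
    chrom = "chr1",
    strand = c(rep("+", 7), "-", "-"),
    type = c("exon", "exon", "exon", "CDS", "CDS", "exon", "CDS",
             "exon", "exon"),
    start = c(1000, 3000, 5000, 1500, 3000, 8000, 8200, 12000, 14000),
    end = c(1999, 3999, 5999, 1999, 3499, 8999, 8799, 12999, 14999))
}

test_that("consequence classes follow the precedence rules", {
  probes <- c(cds = 1600, utr5 = 1100, splice_don = 2001, cds_edge = 1999,
              intron = 2500, splice_acc = 2999, cds2 = 3200, utr3 = 3600,
              t2_utr = 8100, t2_cds = 8500, t3_exon = 12500, intergenic = 50000)
  expected <- c("exonic", "UTR", "splicing", "exonic", "intronic", "splicing",
                "exonic", "UTR", "UTR", "exonic", "UTR", "other")
  vt <- toy_vt(matrix(0L, length(probes), 1, dimnames = list(NULL, "s")),
               pos = unname(probes))
  got <- classify_consequence(vt, probe_model())
  expect_equal(got$variants$consequence, expected)

  ## a span overlapping CDS and a splice site takes the severest class
  sv <- toy_vt(matrix(0L, 1, 1, dimnames = list(NULL, "s")), pos = 1900,
               class = "SV", end = 2100)
  expect_equal(classify_consequence(sv, probe_model())$variants$consequence,
               "splicing")
  expect_error(classify_consequence(sv, data.frame()), "column|empty|model")
})

test_that("filter summaries conserve record counts", {
  empty <- toy_vt(matrix(0L, 1, 1, dimnames = list(NULL, "s")))
  empty <- intersect_regions(empty, genomic_region("chrX", 1, 2))
  tab0 <- tabulate_filter_summary(empty, genomic_region("chr1", 1, 100))
  expect_true(all(tab0 == 0))

  set.seed(104)
  cls <- sample(c("SNV", "indel", "SV", "MEI"), 30, TRUE)
  pos <- sort(sample.int(50000, 30))
  vt <- toy_vt(matrix(0L, 30, 1, dimnames = list(NULL, "s")), pos = pos,
               class = cls, end = ifelse(cls %in% c("SV", "MEI"),
                                         pos + 100, NA))
  vt <- classify_consequence(vt, probe_model())
  regions <- genomic_region("chr1", 1, 10000)
  tab <- tabulate_filter_summary(vt, regions)
  for (col in colnames(tab)) {
    expect_equal(tab["Total", col], sum(tab[-1, col]))
  }
  expect_equal(sum(tab["Total", c("snv_indel_all", "sv_all", "mei_all")]),
               30)
  expect_error(tabulate_filter_summary(toy_vt(matrix(0L, 1, 1,
                                                     dimnames = list(NULL, "s"))),
                                       regions), "classify")
})
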