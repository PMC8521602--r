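test_that("PED/MAP genotypes are recoded to the four-class alphabet", {
  map_path <- withr::local_tempfile(fileext = ".map")
  ped_path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("chr1\tm1\t0\t1000", "chr1\tm2\t0\t2000"), map_path)
  writeLines("FAM\tdog1\t0\t0\t0\t2\tA A\tA G", ped_path)
  res <- read_pedmap(ped_path, map_path)
  expect_equal(unname(res$gm$geno["dog1", ]), c(0L, 1L))
  expect_equal(unname(res$gm$phenotype), "case")
  expect_equal(res$map$pos, c(1000, 2000))
})

test_that("'0 0' PED genotypes become missing", {
  map_path <- withr::local_tempfile(fileext = ".map")
  ped_path <- withr::local_tempfile(fileext = ".ped")
  writeLines("chr1\tm1\t0\t1000", map_path)
  writeLines("FAM\tdog1\t0\t0\t0\t1\t0 0", ped_path)
  res <- read_pedmap(ped_path, map_path)
  expect_true(is.na(res$gm$geno["dog1", "m1"]))
})

test_that("PED/MAP round trip reproduces the genotype matrix bit-exactly", {
  sim <- simulate_population(sim_config(
    chr_lengths = c(chr1 = 10e6), markers_per_chrom = 150,
    planted_region = genomic_region("chr1", 2e6, 6e6), causal_pos = 4e6,
    n_background_variants = 0, seed = 3))
  ped <- withr::local_tempfile(fileext = ".ped")
  mp <- withr::local_tempfile(fileext = ".map")
  write_pedmap(sim$gm, sim$map, ped, mp)
  back <- read_pedmap(ped, mp)
  expect_identical(back$gm$geno, sim$gm$geno)
  expect_identical(back$gm$alleles, sim$gm$alleles)
  expect_identical(back$gm$phenotype, sim$gm$phenotype)
  expect_equal(back$map, sim$map)
})

test_that("malformed PED/MAP input fails loudly", {
  map_path <- withr::local_tempfile(fileext = ".map")
  ped_path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("chr1\tm1\t0\t1000", "chr1\tm2\t0\t2000"), map_path)
  writeLines(c("F\tdogA\t0\t0\t0\t1\tA A\tG G",
               "F\tdogB\t0\t0\t0\t1\tA A"), ped_path)
  expect_error(read_pedmap(ped_path, map_path), "dogB")
  writeLines(c("chr1\tm1\t0\t2000", "chr1\tm2\t0\t1000"), map_path)
  writeLines("F\tdogA\t0\t0\t0\t1\tA A\tG G", ped_path)
  expect_error(read_pedmap(ped_path, map_path), "unsorted|increasing")
})

test_that("VCF genotype fields map to genotype classes", {
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta\tb",
    "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t1/1\t./.",
    "chr1\t200\tv2\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0|1",
    "chr2\t500\tv3\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=60000\tGT\t0/1\t0/0"),
    vcf_path)
  vt <- read_vcf(vcf_path)
  expect_equal(nrow(vt$variants), 4) # multi-allelic row decomposed
  expect_equal(unname(vt$geno[vt$variants$id == "v1", ]), c(2L, NA))
  expect_equal(unname(vt$geno[vt$variants$id == "v2_1", ]), c(1L, 1L))
  expect_equal(unname(vt$geno[vt$variants$id == "v2_2", ]), c(1L, 0L))
  sv <- vt$variants[vt$variants$id == "v3", ]
  expect_equal(sv$class, "SV")
  expect_equal(sv$end, 60000)
})

test_that("VCF without GT is rejected and round trips preserve classes", {
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ta",
    "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tDP\t10"), vcf_path)
  expect_error(read_vcf(vcf_path), "GT")

  vt <- toy_vt(matrix(c(0L, 1L, 2L, NA, 1L, 0L), 3, 2),
               class = c("SNV", "indel", "MEI"),
               end = c(NA, NA, 2e6))
  vt$variants$alt[3] <- "<INS:ME:LINE1>"
  vt$variants$svtype[3] <- "INS:ME"
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vt, out)
  back <- read_vcf(out)
  expect_identical(back$geno, vt$geno)
  expect_equal(back$variants$class, vt$variants$class)
  expect_equal(back$variants$end, vt$variants$end)
  expect_equal(back$variants$alt, vt$variants$alt)
})

test_that("BED output is 0-based half-open and round trips losslessly", {
  regions <- genomic_region(c("chr1", "c"), c(67943666, 5), c(89271008, 5))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(regions, path)
  expect_equal(readLines(path),
               c("chr1\t67943665\t89271008", "c\t4\t5"))
  back <- read_bed(path)
  expect_equal(back$start, regions$start)
  expect_equal(back$end, regions$end)
  ## sorted input stays sorted
  many <- genomic_region(rep("chr2", 5), seq(100, 500, 100),
                         seq(150, 550, 100))
  write_bed(many, path)
  expect_false(is.unsorted(read_bed(path)$start))
})

test_that("gene models survive a GFF3 round trip", {
  gmod <- gene_model(
    transcript = c("T1", "T1", "T1", "T2"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "+", "+", "-"),
    type = c("exon", "exon", "CDS", "exon"),
    start = c(100, 500, 150, 1000), end = c(200, 700, 200, 2000))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_model(gmod, path)
  back <- read_gene_model(path)
  back <- back[order(back$transcript, back$type, back$start), ]
  ref <- gmod[order(gmod$transcript, gmod$type, gmod$start), ]
  rownames(back) <- rownames(ref) <- NULL
  expect_equal(as.data.frame(back), as.data.frame(ref))
})
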