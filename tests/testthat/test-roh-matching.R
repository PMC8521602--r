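seg_row <- function(sample, start, end, chrom = "chr1") {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             kb = (end - start + 1) / 1000, n_snps = 10L, n_het = 0L,
             n_missing = 0L, stringsAsFactors = FALSE)
}

test_that("pooling is transitive single linkage with union and consensus", {
  segs <- rbind(seg_row("a", 100000, 200000), seg_row("b", 150000, 300000))
  pools <- pool_segments(segs)
  expect_equal(nrow(pools$pools), 1)
  expect_equal(pools$pools$union_start, 100000)
  expect_equal(pools$pools$union_end, 300000)
  expect_equal(pools$pools$consensus_start, 150000)
  expect_equal(pools$pools$consensus_end, 200000)

  ## disjoint segments form separate pools; adjacency is not overlap
  segs2 <- rbind(seg_row("a", 1000, 2000), seg_row("b", 2001, 3000))
  expect_equal(nrow(pool_segments(segs2)$pools), 2)

  ## chain: a-b overlap, b-c overlap, a-c do not -> one pool, empty consensus
  segs3 <- rbind(seg_row("a", 100, 500), seg_row("b", 400, 900),
                 seg_row("c", 800, 1200))
  pools3 <- pool_segments(segs3)
  expect_equal(nrow(pools3$pools), 1)
  expect_equal(pools3$pools$n_members, 3L)
  expect_true(is.na(pools3$pools$consensus_start))
})

test_that("allelic match fraction counts identical pairs among joint calls", {
  codes <- matrix(0L, 2, 10, dimnames = list(c("x", "y"), NULL))
  map <- toy_map(10, spacing = 1000)
  region <- genomic_region("chr1", 1, 10000)
  gm <- toy_gm(codes)
  expect_equal(allelic_match_fraction(gm, "x", "y", region, map)$fraction, 1)

  opp <- codes
  opp["y", ] <- 2L
  expect_equal(allelic_match_fraction(toy_gm(opp), "x", "y", region,
                                      map)$fraction, 0)

  ## 10 markers: 2 discordant, 1 jointly missing -> 7/9
  mixed <- codes
  mixed["y", 1:2] <- 2L
  gm2 <- toy_gm(mixed)
  gm2$geno["x", 3] <- NA_integer_
  gm2$alleles["x", 3] <- NA_character_
  res <- allelic_match_fraction(gm2, "x", "y", region, map)
  expect_equal(res$fraction, 7 / 9)
  expect_equal(res$n_informative, 9L)
  ## symmetry
  expect_equal(allelic_match_fraction(gm2, "y", "x", region, map)$fraction,
               7 / 9)
  ## no joint calls -> flagged NA
  gm2$geno["x", ] <- NA_integer_
  gm2$alleles["x", ] <- NA_character_
  expect_warning(res2 <- allelic_match_fraction(gm2, "x", "y", region, map),
                 "undefined")
  expect_true(is.na(res2$fraction))
})

match_fixture <- function(control_codes = NULL) {
  ## 3 cases sharing a homozygous haplotype over markers 50..150
  m <- 200
  set.seed(91)
  codes <- matrix(sample(c(0L, 1L, 2L), 4 * m, TRUE), 4, m,
                  dimnames = list(c("c1", "c2", "c3", "k1"), NULL))
  codes[1:3, 50:150] <- 0L
  if (!is.null(control_codes)) codes[4, 50:150] <- control_codes
  gm <- toy_gm(codes, phenotype = c("case", "case", "case", "control"))
  map <- toy_map(m, spacing = 30000)
  segs <- rbind(seg_row("c1", map$pos[50], map$pos[150]),
                seg_row("c2", map$pos[48], map$pos[152]),
                seg_row("c3", map$pos[50], map$pos[151]))
  list(gm = gm, map = map, segs = segs)
}

test_that("pools shared by all matching cases become candidate regions", {
  fx <- match_fixture()
  regions <- case_specific_regions(pool_segments(fx$segs), fx$gm, fx$map)
  expect_equal(nrow(regions), 1)
  expect_equal(regions$start, fx$map$pos[50])
  expect_equal(regions$end, fx$map$pos[150])
})

test_that("a control sharing the case haplotype removes the pool", {
  fx <- match_fixture(control_codes = 0L)  # identical hom haplotype
  segs <- rbind(fx$segs, seg_row("k1", fx$map$pos[49], fx$map$pos[151]))
  regions <- case_specific_regions(pool_segments(segs), fx$gm, fx$map)
  expect_equal(nrow(regions), 0)

  ## allelically different control ROH does not
  fx2 <- match_fixture(control_codes = 2L)  # opposite homozygote
  segs2 <- rbind(fx2$segs, seg_row("k1", fx2$map$pos[49], fx2$map$pos[151]))
  regions2 <- case_specific_regions(pool_segments(segs2), fx2$gm, fx2$map)
  expect_equal(nrow(regions2), 1)
})

test_that("a case failing allelic identity removes the pool", {
  fx <- match_fixture()
  fx$gm$geno["c3", 50:150] <- 2L
  fx$gm$alleles["c3", 50:150] <- "G/G"
  regions <- case_specific_regions(pool_segments(fx$segs), fx$gm, fx$map)
  expect_equal(nrow(regions), 0)
})

test_that("controls without ROH never change the result; no cases errors", {
  fx <- match_fixture()
  base <- case_specific_regions(pool_segments(fx$segs), fx$gm, fx$map)
  withr::with_seed(92, {
    extra <- matrix(sample(c(0L, 1L, 2L), 200, TRUE), 1, 200,
                    dimnames = list("k2", NULL))
  })
  gm2 <- toy_gm(rbind(fx$gm$geno, extra),
                phenotype = c(unname(fx$gm$phenotype), "control"))
  expect_equal(case_specific_regions(pool_segments(fx$segs), gm2, fx$map),
               base)

  gm3 <- fx$gm
  gm3$phenotype[] <- "control"
  expect_error(case_specific_regions(pool_segments(fx$segs), gm3, fx$map),
               "no case")
})

test_that("missing a case segment disqualifies a pool", {
  fx <- match_fixture()
  segs <- fx$segs[fx$segs$sample != "c2", ]
  expect_equal(nrow(case_specific_regions(pool_segments(segs), fx$gm,
                                          fx$map)), 0)
})
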