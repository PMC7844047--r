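write_mini_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

eh_header <- function(samples) c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=chr1,length=100000>",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
  "##FORMAT=<ID=REPCN,Number=1,Type=String,Description=\"Repeat units\">",
  "##FORMAT=<ID=ADSP,Number=1,Type=String,Description=\"Spanning\">",
  "##FORMAT=<ID=ADIR,Number=1,Type=String,Description=\"In-repeat\">",
  "##FORMAT=<ID=ADFL,Number=1,Type=String,Description=\"Flanking\">",
  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", samples), collapse = "\t"))

test_that("read_str_vcf parses the ExpansionHunter REPCN dialect", {
  p <- write_mini_vcf(c(
    eh_header(c("S1", "S2")),
    paste(c("chr1", "101", "chr1_101", "C", "<STR>", ".", "PASS", ".",
            "GT:REPCN:ADSP:ADIR:ADFL",
            "1/1:12/15:10/9:0/0:3/3", "1/1:7/7:8/8:1/0:2/2"),
          collapse = "\t"),
    paste(c("chr1", "501", "chr1_501", "G", "<STR>", ".", "PASS", ".",
            "GT:REPCN:ADSP:ADIR:ADFL",
            ".:.:0/0:0/0:0/0", "1/1:9/4:7/7:0/0:1/1"), collapse = "\t"),
    paste(c("chr1", "901", "chr1_901", "G", "<STR>", ".", "PASS", ".",
            "GT:REPCN:ADSP:ADIR:ADFL",
            "1:11:5/5:0/0:1/1", "1/1:5/5:6/6:0/0:2/2"), collapse = "\t")))
  cs <- read_str_vcf(p)
  expect_s3_class(cs, "cgg_callset")
  expect_equal(nrow(cs), 6L)  # 2 samples x 3 loci, fully keyed
  g <- function(s, l) cs[cs$sample == s & cs$locus_id == l, ]
  expect_equal(unlist(g("S1", "chr1_101")[, c("a1", "a2")],
                      use.names = FALSE), c(12L, 15L))
  expect_true(is.na(g("S1", "chr1_501")$a1))       # "." is a missing call
  expect_equal(g("S2", "chr1_501")$a1, 4L)         # normalised ascending
  expect_equal(g("S2", "chr1_501")$a2, 9L)
  expect_equal(unlist(g("S1", "chr1_901")[, c("a1", "a2")],
                      use.names = FALSE), c(11L, 11L))  # haploid duplicated
  expect_equal(g("S1", "chr1_101")$spanning, 19L)  # summed across alleles
  expect_equal(g("S2", "chr1_101")$inrepeat, 1L)
  # sample filter
  expect_equal(unique(read_str_vcf(p, "S2")$sample), "S2")
  expect_error(read_str_vcf("/no/such.vcf"), "cannot read")
})

test_that("read_str_vcf handles the GangSTR dialect and malformed REPCN", {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=REPCN,Number=2,Type=Integer,Description=\"Repeat units\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"))
  p <- write_mini_vcf(c(hdr,
    "chr1\t101\tL1\tC\t<STR>\t.\tPASS\t.\tGT:REPCN\t1/1:12,15",
    "chr1\t501\tL2\tC\t<STR>\t.\tPASS\t.\tGT:REPCN\t.:."))
  cs <- read_str_vcf(p)
  expect_equal(cs$a1[cs$locus_id == "L1"], 12L)
  expect_equal(cs$a2[cs$locus_id == "L1"], 15L)
  expect_true(is.na(cs$a1[cs$locus_id == "L2"]))
  expect_true(all(is.na(cs$spanning)))  # no evidence fields -> unknown

  p2 <- write_mini_vcf(c(eh_header("S1"),
    "chr1\t101\tL1\tC\t<STR>\t.\tPASS\t.\tGT:REPCN\t1/1:x/y"))
  expect_warning(cs2 <- read_str_vcf(p2), "malformed")
  expect_true(is.na(cs2$a1))
})

test_that("emit_vcf -> read_str_vcf round-trips the allele table", {
  set.seed(5)
  pl <- plant_loci(6L, 20000L)
  cfg <- simulation_config(seed = 5, genome_length = 20000L,
                           planted_loci = pl, n_samples = 12L,
                           censor_cap = NA, missing_rate = 0)
  gen <- generate_genome(cfg)
  pop <- simulate_population(gen$truth, cfg)
  vcf <- tempfile(fileext = ".vcf")
  emit_vcf(pop, gen$truth, cfg, vcf)
  cs <- read_str_vcf(vcf)
  expect_equal(allele_call_rate(cs), 1.0)
  m <- merge(pop, as.data.frame(cs), by = c("sample", "locus_id"))
  expect_equal(nrow(m), nrow(pop))
  expect_identical(m$a1.x, m$a1.y)
  expect_identical(m$a2.x, m$a2.y)
})

test_that("exclude_uncovered_loci applies both exclusion rules", {
  # per-locus evidence patterns: locus1 covered, locus2 all-zero,
  # locus3 flanking-only
  cs <- toy_callset(matrix(replicate(15, c(5L, 5L), simplify = FALSE), 5, 3),
                    spanning = rep(c(3L, 0L, 0L), 5),
                    inrepeat = rep(0L, 15),
                    flanking = rep(c(1L, 0L, 2L), 5))
  res <- exclude_uncovered_loci(cs)
  expect_setequal(res$excluded$locus_id, c("chr1_200", "chr1_300"))
  expect_equal(res$excluded$reason[res$excluded$locus_id == "chr1_200"],
               "no_coverage")
  expect_equal(res$excluded$reason[res$excluded$locus_id == "chr1_300"],
               "flanking_only")
  expect_equal(res$kept_loci, "chr1_100")
  # excluded and kept partition the input loci
  expect_setequal(c(res$kept_loci, res$excluded$locus_id),
                  unique(cs$locus_id))
  # unknown evidence -> keep everything
  cs_na <- toy_callset(matrix(replicate(4, c(5L, 5L), simplify = FALSE), 2, 2))
  expect_equal(nrow(exclude_uncovered_loci(cs_na)$excluded), 0L)
})

test_that("allele_call_rate counts missing alleles", {
  al <- matrix(replicate(100, c(7L, 8L), simplify = FALSE), 10, 10)
  al[3, 4] <- list(NULL)  # one missing diploid call
  expect_equal(allele_call_rate(toy_callset(al)), 0.99)
  full <- toy_callset(matrix(replicate(4, c(1L, 2L), simplify = FALSE), 2, 2))
  expect_equal(allele_call_rate(full), 1.0)
  none <- matrix(list(NULL), 2, 2)
  expect_equal(allele_call_rate(toy_callset(none)), 0.0)
})

test_that("callset validates its invariants", {
  df <- data.frame(sample = "S1", locus_id = "L1", a1 = 9L, a2 = 4L)
  cs <- callset(df)
  expect_equal(c(cs$a1, cs$a2), c(4L, 9L))  # sorted ascending
  expect_error(callset(rbind(df, df)), "duplicate")
  expect_error(callset(data.frame(sample = "S1", locus_id = "L1",
                                  a1 = 5L, a2 = NA_integer_)),
               "all-or-nothing")
  expect_error(callset(data.frame(sample = "S1", locus_id = "L1",
                                  a1 = -1L, a2 = 3L)), "negative")
  tsv <- tempfile(fileext = ".tsv")
  write_calls_tsv(cs, tsv)
  expect_equal(read_calls_tsv(tsv)$a2, 9L)
})
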