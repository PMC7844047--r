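test_that("canonical_motif_frames enumerates rotations on both strands", {
  cases <- list(
    CGG = c("CGG", "GGC", "GCG", "CCG", "CGC", "GCC"),
    CAG = c("CAG", "AGC", "GCA", "CTG", "TGC", "GCT"),
    AAA = c("AAA", "TTT"))
  for (m in names(cases)) {
    mc <- canonical_motif_frames(m)
    expect_setequal(mc$frames, cases[[m]])
    expect_true(m %in% mc$frames)
    expect_true(all(nchar(mc$frames) == nchar(m)))
  }
  expect_error(canonical_motif_frames("CGN"), "invalid motif")
  expect_error(canonical_motif_frames(""), "non-empty")
})

test_that("scan_candidates finds and merges frame runs", {
  mc <- canonical_motif_frames("CGG")
  one <- scan_candidates(paste0("ATATAT", strrep("CGG", 5), "TATATA"), mc)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(6L, 21L))

  expect_equal(nrow(scan_candidates("AAAAAAAAAA", mc)), 0L)
  expect_equal(nrow(scan_candidates("", mc)), 0L)

  two <- scan_candidates(paste0(strrep("AT", 10), strrep("CGG", 4),
                                strrep("TA", 100), strrep("GCC", 6),
                                strrep("AT", 10)), mc)
  expect_equal(nrow(two), 2L)
  expect_equal(two$frame, c("CGG", "GCC"))

  # an interrupted run keeps its outermost single copies in one candidate
  intr <- scan_candidates(paste0("TTTTTT", "CGG", "ATT", strrep("CGG", 4),
                                 "TAG", "CGG", "TTTTTT"), mc)
  expect_equal(nrow(intr), 1L)
  expect_equal(c(intr$start, intr$end), c(6L, 30L))
})

test_that("scan truncates candidates at max_length", {
  p <- detection_params(max_length = 30L)
  long <- scan_candidates(strrep("CGG", 50), "CGG", p)
  expect_equal(long$end - long$start, 30L)
})

test_that("wraparound scoring matches hand-computed values", {
  p <- detection_params()
  expect_equal(score_repeat_alignment(strrep("CGG", 12), "CGG", p)$score, 72L)
  expect_equal(score_repeat_alignment(strrep("CGG", 4), "CGG", p)$score, 24L)
  s <- strrep("CGG", 8); substr(s, 10, 10) <- "T"
  r <- score_repeat_alignment(s, "CGG", p)
  expect_equal(r$score, 41L)
  expect_equal(r[c("matches", "mismatches", "indels")],
               list(matches = 23L, mismatches = 1L, indels = 0L))
  # candidate shorter than the motif aligns partially
  expect_equal(score_repeat_alignment("CG", "CGG", p)$score, 4L)
  # N never matches
  expect_equal(score_repeat_alignment("CGGNGG", "CGG", p)$score, 5L)
  expect_error(score_repeat_alignment("CGG", strrep("A", 25), p),
               "max_period")
})

test_that("wraparound scoring equals the independent oracle (spot check)", {
  set.seed(42)
  p <- detection_params()
  for (i in 1:100) {
    n <- sample(3:60, 1)
    s <- if (runif(1) < 0.5) random_dna(n) else cgg_like_seq(n, sample(0:3, 1))
    expect_identical(score_repeat_alignment(s, "CGG", p)$score,
                     wrap_score_oracle(s, "CGG"))
  }
})

test_that("refine_locus trims to the best local span with tie-breaks", {
  pure <- refine_locus(strrep("CGG", 6), "CGG")
  expect_equal(pure[c("start", "end", "units", "interruptions")],
               list(start = 0L, end = 18L, units = 6, interruptions = 0L))

  joined <- refine_locus(paste0(strrep("CGG", 4), "TGG", strrep("CGG", 5)),
                         "CGG")
  expect_equal(joined[c("start", "end", "units", "interruptions")],
               list(start = 0L, end = 30L, units = 10, interruptions = 1L))

  # flanking junk is trimmed; rotations of the frame are reachable
  shifted <- refine_locus(paste0("ATTATT", "GCGGCGGCG", "TATTAT"), "CGG")
  expect_equal(c(shifted$start, shifted$end), c(6L, 15L))

  expect_error(refine_locus("ACGTACGT", "CGG"), class = "cgg_refine_failed")
})

test_that("build_catalog recovers planted loci exactly on a clean genome", {
  bg <- strrep("AT", 2500)
  s <- paste0(substr(bg, 1, 1000), strrep("CGG", 7),
              substr(bg, 1, 2000), strrep("GCC", 5),
              substr(bg, 1, 1500), strrep("CGC", 12), substr(bg, 1, 500))
  g <- Biostrings::DNAStringSet(c(chrA = s))
  cat <- build_catalog(g)
  expect_s3_class(cat, "cgg_catalog")
  expect_equal(nrow(cat), 3L)
  expect_equal(cat$start, c(1000L, 3021L, 4536L))
  expect_equal(cat$end - cat$start, c(21L, 15L, 36L))
  expect_equal(cat$units, c(7, 5, 12))
  expect_equal(cat$motif, c("CGG", "GCC", "CGC"))
  expect_true(all(cat$interruptions == 0L))

  # wrong motif class yields nothing
  expect_equal(nrow(build_catalog(
    Biostrings::DNAStringSet(c(x = paste0("TTTTTT", strrep("CAG", 10),
                                          "TTTTTT"))))), 0L)
  # 3 units is below min_units
  expect_equal(nrow(build_catalog(
    Biostrings::DNAStringSet(c(x = paste0("TTTTTT", strrep("CGG", 3),
                                          "TTTTTT"))))), 0L)
})

test_that("build_catalog is sound, deduplicated, sorted and deterministic", {
  set.seed(7)
  chunks <- c(replicate(12, random_dna(150)),
              replicate(6, strrep(sample(canonical_motif_frames("CGG")$frames,
                                         1), sample(2:12, 1))))
  s <- paste(sample(chunks), collapse = "")
  g <- Biostrings::DNAStringSet(c(c1 = s, c2 = substr(s, 200, 1500)))
  p <- detection_params()
  cat1 <- build_catalog(g, params = p)
  cat2 <- build_catalog(g, params = p)
  expect_identical(cat1, cat2)
  expect_true(all(cat1$score >= p$min_score))
  expect_true(all(floor(cat1$units) >= p$min_units))
  for (ch in unique(cat1$chrom)) {
    d <- cat1[cat1$chrom == ch, ]
    expect_true(all(diff(d$start) > 0))
    if (nrow(d) > 1) expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
  expect_error(build_catalog(Biostrings::DNAStringSet(
    setNames(c("ACGT", "ACGT"), c("a", "a")))), "duplicate")
  expect_error(build_catalog("/nonexistent.fa"), "cannot read")
})

test_that("build_catalog is strand-symmetric", {
  set.seed(13)
  pl <- plant_loci(10L, 20000L)
  cfg <- simulation_config(seed = 13, genome_length = 20000L,
                           planted_loci = pl)
  gen <- generate_genome(cfg)
  fwd <- build_catalog(gen$genome)
  rc <- Biostrings::reverseComplement(gen$genome)
  rev <- build_catalog(rc)
  expect_equal(nrow(rev), nrow(fwd))
  n <- Biostrings::width(gen$genome)[1]
  expect_equal(sort(n - rev$end), sort(fwd$start))
  expect_equal(sort(n - rev$start), sort(fwd$end))
})

test_that("catalog BED and JSON writers round-trip/format correctly", {
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(strrep("TA", 40),
                                                strrep("CGG", 6),
                                                strrep("AT", 40))))
  cat <- build_catalog(g)
  bed <- tempfile(fileext = ".bed")
  write_catalog_bed(cat, bed)
  back <- read_catalog_bed(bed)
  expect_equal(back$start, cat$start)
  expect_equal(back$units, cat$units)
  js <- tempfile(fileext = ".json")
  write_catalog_json(cat, js)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(j$LocusId, cat$locus_id)
  expect_equal(j$VariantType, "Repeat")
  expect_equal(j$ReferenceRegion,
               paste0("chr1:", cat$start + 1L, "-", cat$end))
  expect_equal(j$LocusStructure, "(CGG)*")
})
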