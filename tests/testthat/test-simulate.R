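test_that("generate_genome is seed-deterministic and plants exact truth", {
  cfg <- simulation_config(seed = 9, genome_length = 15000L, n_loci = 4L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth, g2$truth)
  # planted repeats are recovered verbatim from the sequence
  s <- as.character(g1$genome[[1]])
  pure <- g1$truth[g1$truth$interruptions == 0, ]
  for (i in seq_len(nrow(pure)))
    expect_equal(substr(s, pure$start[i] + 1, pure$end[i]),
                 strrep(pure$motif[i], pure$units[i]))
  # background is scrubbed: the only catalogued loci are the planted ones
  cat <- build_catalog(g1$genome)
  expect_equal(cat$start, g1$truth$start)
  expect_equal(cat$end, g1$truth$end)
  expect_equal(cat$units, as.numeric(g1$truth$units))
})

test_that("a zero-loci configuration yields an empty catalogue", {
  cfg <- simulation_config(seed = 2, genome_length = 5000L, n_loci = 0L,
                           planted_loci = data.frame(
                             chrom = character(0), start = integer(0),
                             frame = character(0), units = integer(0),
                             interruptions = integer(0)))
  gen <- generate_genome(cfg)
  expect_equal(nrow(gen$truth), 0L)
  expect_equal(nrow(build_catalog(gen$genome)), 0L)
})

test_that("plant_loci respects spacing, score floor and packing limits", {
  set.seed(4)
  pl <- plant_loci(30L, 50000L)
  expect_true(all(diff(pl$start) >= 0))
  ends <- pl$start + pl$units * 3L
  expect_true(all(pl$start[-1] - ends[-nrow(pl)] >= 50L))
  # interrupted loci always clear the default MinScore of 24
  expect_true(all(6L * pl$units - 7L * pl$interruptions >= 24L))
  expect_error(plant_loci(100L, 2000L), "infeasible packing")
})

test_that("simulate_population follows the instability model", {
  truth <- data.frame(locus_id = c("L1", "L2"), units = c(5L, 40L),
                      p_mut = c(0, 0))
  cfg <- simulation_config(seed = 1, n_samples = 30L)
  # zero mutation probability: every allele equals its central value
  pop <- simulate_population(truth, cfg)
  expect_true(all(pop$a1 == rep(c(5L, 40L), 30)))
  expect_true(all(pop$a2 == rep(c(5L, 40L), 30)))
  # mutation probability 1: every allele differs from the central value
  truth$p_mut <- c(1, 1)
  pop2 <- simulate_population(truth, cfg)
  expect_true(all(pop2$a1 != rep(c(5L, 40L), 30) |
                    pop2$a2 != rep(c(5L, 40L), 30)))
  expect_true(all(pop2$a1 >= 1L))  # truncation at one unit
  # polymorphic fraction rises with central length under a positive slope
  set.seed(99)
  truth3 <- data.frame(locus_id = sprintf("L%03d", 1:60),
                       units = rep(c(5L, 50L), 30))
  truth3$p_mut <- pmin(1, 5e-4 + 3e-4 * truth3$units)
  cfg3 <- simulation_config(seed = 99, n_samples = 200L)
  s3 <- summarize_loci(callset(simulate_population(truth3, cfg3)))
  m <- merge(s3, truth3, by = "locus_id")
  short <- mean(m$polymorphic[m$units == 5])
  long <- mean(m$polymorphic[m$units == 50])
  expect_gt(long, short)
})

test_that("emit_vcf applies the censoring and missingness models", {
  truth <- data.frame(chrom = "chr1", start = c(100L, 400L),
                      end = c(130L, 430L), motif = "CGG",
                      units = c(10L, 10L),
                      locus_id = c("chr1_101", "chr1_401"))
  true_units <- c(40L, 50L, 51L, 70L, 149L, 150L, 200L, 10L)
  at <- data.frame(sample = sprintf("S%03d", rep(1:4, each = 2)),
                   locus_id = rep(c("chr1_101", "chr1_401"), 4),
                   a1 = true_units, a2 = true_units)
  cfg <- simulation_config(seed = 8, missing_rate = 0)
  v <- tempfile(fileext = ".vcf")
  emit_vcf(at, truth, cfg, v)
  cs <- read_str_vcf(v)
  got <- cs$a1[match(paste(at$sample, at$locus_id),
                     paste(cs$sample, cs$locus_id))]
  expect_equal(got, c(40L, 50L, 50L, 50L, 50L, 150L, 200L, 10L))
  # cap disabled: reported equals true everywhere
  cfg_nc <- simulation_config(seed = 8, censor_cap = NA, missing_rate = 0)
  emit_vcf(at, truth, cfg_nc, v)
  expect_equal(sort(read_str_vcf(v)$a1), sort(true_units))
})

test_that("configured uncovered / flanking-only loci are excludable", {
  set.seed(21)
  pl <- plant_loci(5L, 20000L)
  ids <- paste0("chr1_", pl$start + 1L)
  cfg <- simulation_config(seed = 21, genome_length = 20000L,
                           planted_loci = pl, n_samples = 10L,
                           uncovered_loci = ids[2],
                           flanking_only_loci = ids[4])
  gen <- generate_genome(cfg)
  pop <- simulate_population(gen$truth, cfg)
  v <- tempfile(fileext = ".vcf")
  emit_vcf(pop, gen$truth, cfg, v)
  res <- exclude_uncovered_loci(read_str_vcf(v))
  expect_setequal(res$excluded$locus_id, ids[c(2, 4)])
  expect_equal(res$excluded$reason[match(ids[c(2, 4)],
                                         res$excluded$locus_id)],
               c("no_coverage", "flanking_only"))
  expect_setequal(res$kept_loci, ids[c(1, 3, 5)])
})

test_that("gene-model generator realises all labels and panel enrichment", {
  cfg <- simulation_config(seed = 3, genome_length = 60000L, n_loci = 8L,
                           spacing = 3000L)
  gen <- generate_genome(cfg)
  gm <- generate_gene_models(gen$truth, cfg, odds_ratio = 8, panel_size = 25L)
  ann <- assign_region(gen$truth, gm$models)
  expect_setequal(ann$region,
                  c("upstream", "five_utr", "exonic", "intronic",
                    "three_utr", "downstream", "ncRNA", "intergenic"))
  expect_identical(ann$region, unname(gm$roles))
  # GFF3 round trip preserves the annotation
  gff <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(gm$models, gff)
  expect_identical(assign_region(gen$truth, read_gene_models(gff)), ann)
  # an enriched panel overlaps the associated genes more than a null panel
  set.seed(50)
  n_hit <- function(or) {
    p <- simulate_panel(gm$universe, gm$repeat_genes, 25L, or)
    length(intersect(p, gm$repeat_genes))
  }
  enriched <- mean(replicate(40, n_hit(8)))
  null <- mean(replicate(40, n_hit(1)))
  expect_gt(enriched, null)
})

test_that("full simulate -> catalog -> vcf -> popstats round trip", {
  set.seed(77)
  pl <- plant_loci(20L, 60000L)
  cfg <- simulation_config(seed = 77, genome_length = 60000L,
                           planted_loci = pl, n_samples = 50L)
  gen <- generate_genome(cfg)
  cat <- build_catalog(gen$genome)
  expect_equal(cat$locus_id, gen$truth$locus_id)
  pop <- simulate_population(gen$truth, cfg)
  v <- tempfile(fileext = ".vcf")
  emit_vcf(pop, gen$truth, cfg, v)
  s <- summarize_loci(read_str_vcf(v))
  m <- merge(s, gen$truth, by = "locus_id")
  # planted central alleles are recovered as medians at >= 99% of loci
  expect_gte(mean(m$median_units == pmin(m$units, cfg$censor_cap)), 0.99)
})
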