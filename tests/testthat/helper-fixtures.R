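# Shared fixtures and independent oracles for the test suite.

# Independent oracle for the wraparound repeat score: global-local alignment
# of the candidate against an explicit periodic extension of the motif with
# linear gap costs (Biostrings pairwiseAlignment, a code path entirely
# separate from the package's DP).
wrap_score_oracle <- function(seq, motif, match = 2, mismatch = 5,
                              indel = 17) {
  bases <- c("A", "C", "G", "T")
  sub <- matrix(-mismatch, 4, 4, dimnames = list(bases, bases))
  diag(sub) <- match
  subj <- strrep(motif, ceiling(nchar(seq) / nchar(motif)) + 2L)
  as.integer(Biostrings::pairwiseAlignment(
    seq, subj, type = "global-local", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = indel, scoreOnly = TRUE))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# repeat-like sequence: truncated pure CGG run with k random substitutions
cgg_like_seq <- function(n, k = 0L) {
  x <- strsplit(strrep("CGG", ceiling(n / 3)), "")[[1]][seq_len(n)]
  if (k > 0L) x[sample(n, k)] <- sample(c("A", "C", "G", "T"), k,
                                        replace = TRUE)
  paste(x, collapse = "")
}

# minimal diploid call-set builder: alleles is a samples x loci list matrix
# of c(a1, a2) pairs or NULL for a missing call
toy_callset <- function(alleles, samples = NULL, loci = NULL, ...) {
  S <- nrow(alleles); L <- ncol(alleles)
  if (is.null(samples)) samples <- sprintf("S%02d", seq_len(S))
  if (is.null(loci)) loci <- sprintf("chr1_%d", 100L * seq_len(L))
  rows <- do.call(rbind, lapply(seq_len(S), function(i)
    do.call(rbind, lapply(seq_len(L), function(j) {
      al <- alleles[[i, j]]
      data.frame(sample = samples[i], locus_id = loci[j],
                 a1 = if (is.null(al)) NA_integer_ else al[1],
                 a2 = if (is.null(al)) NA_integer_ else al[2],
                 stringsAsFactors = FALSE)
    }))))
  extras <- list(...)
  if (length(extras)) rows <- cbind(rows, data.frame(extras))
  callset(rows)
}

# ARID1B-style fixture: one gene carrying 13 repeat loci (3 upstream,
# 1 five_utr, 8 exonic, 1 intronic)
arid1b_fixture <- function() {
  genes <- data.frame(
    gene = "GENE_A", chrom = "chr6", strand = "+",
    tx_start = 10000L, tx_end = 20000L, cds_start = 11000L,
    cds_end = 19000L, biotype = "coding", stringsAsFactors = FALSE)
  exons <- data.frame(gene = "GENE_A",
                      start = c(10000L, 15000L), end = c(12000L, 20000L))
  starts <- c(9100L, 9400L, 9700L,          # upstream (within 1 kb)
              10200L,                       # five_utr
              11100L + 100L * (0:5), 15100L, 15400L,  # exonic (CDS)
              13500L)                       # intronic
  loci <- data.frame(chrom = "chr6", start = starts, end = starts + 30L,
                     stringsAsFactors = FALSE)
  list(models = gene_models(genes, exons), loci = loci)
}

# Memoised "acceptance world": the 1-Mb genome with 200 planted CGG-class
# repeats (units 4-60, <= 2 interruptions) shared by several acceptance
# criteria.  Built once per test run.
.acceptance_env <- new.env(parent = emptyenv())
acceptance_world <- function() {
  if (is.null(.acceptance_env$world)) {
    set.seed(20210128)
    planted <- plant_loci(200L, 1e6L)
    cfg <- simulation_config(seed = 20210128, genome_length = 1e6L,
                             planted_loci = planted, n_samples = 100L)
    gen <- generate_genome(cfg)
    .acceptance_env$world <- list(cfg = cfg, genome = gen$genome,
                                  truth = gen$truth)
  }
  .acceptance_env$world
}
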