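# Seeded synthetic-data generators: genomes with planted CGG-class repeats,
# diploid cohorts whose allele variability grows with the locus's central
# repeat length, genotyper-style VCF output with read-length censoring, and
# toy gene models realising every region label.  These are explicit
# stand-ins for hg19 and cohort WGS: distributions are chosen for testability
# and for the qualitative structure of real CGG data, not claimed biological.

#' Simulation configuration
#'
#' Defaults encode the cohort this package's tests emulate: 150-bp reads
#' giving a genotyper soft-limit of `floor(150 / 3) = 50` units, a 0.1%
#' per-allele missing rate (about 99.8% of alleles genotyped), and a
#' per-allele mutation probability linear in the central repeat length
#' (`min(1, floor + slope * units)`). The floor/slope defaults (5e-4, 3e-4
#' per unit) are fitted once to the anchor points of a 544-genome cohort in
#' which ~85% of 4-unit-median loci and ~96% of 8-unit-median loci are
#' polymorphic. Mutated alleles move by a geometric step
#' (`Delta ~ Geom(step_geom_p) + 1`) in either direction, truncated below at
#' one unit.
#'
#' @param seed Integer RNG seed; all generators are deterministic given it.
#' @param genome_length Background genome length in bp.
#' @param gc_content Background GC fraction.
#' @param planted_loci Optional data.frame from [plant_loci()]; when NULL,
#'   `n_loci` loci are planted automatically by [generate_genome()].
#' @param n_loci Number of loci to plant when `planted_loci` is NULL.
#' @param n_samples Cohort size (diploid individuals).
#' @param instability_floor Baseline per-allele mutation probability.
#' @param instability_slope Added mutation probability per central unit.
#' @param step_geom_p Geometric parameter of the mutation step size (in
#'   (0, 1]; smaller = heavier tail).
#' @param read_length Read length in bp; sets the default censor cap.
#' @param censor_cap Reported-length soft limit in units; NA disables
#'   censoring. Default `floor(read_length / 3)`.
#' @param missing_rate Per-allele probability of a missing call.
#' @param uncovered_loci,flanking_only_loci Locus ids written to the VCF with
#'   zero spanning/in-repeat evidence (and flanking evidence for the latter),
#'   to exercise locus exclusion.
#' @param chrom Sequence name of the synthetic chromosome.
#' @param min_units Detection threshold used when scrubbing the background.
#' @param spacing Minimum bp between planted repeats (>= 50).
#' @return A list of class `cgg_sim_config`.
#' @export
simulation_config <- function(seed = 1L, genome_length = 100000L,
                              gc_content = 0.41, planted_loci = NULL,
                              n_loci = 20L, n_samples = 100L,
                              instability_floor = 5e-4,
                              instability_slope = 3e-4,
                              step_geom_p = 0.5, read_length = 150L,
                              censor_cap = NULL, missing_rate = 0.001,
                              uncovered_loci = character(0),
                              flanking_only_loci = character(0),
                              chrom = "chr1", min_units = 4L,
                              spacing = 50L) {
  if (is.null(censor_cap)) censor_cap <- as.integer(read_length %/% 3L)
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              gc_content = gc_content, planted_loci = planted_loci,
              n_loci = as.integer(n_loci), n_samples = as.integer(n_samples),
              instability_floor = instability_floor,
              instability_slope = instability_slope,
              step_geom_p = step_geom_p,
              read_length = as.integer(read_length),
              censor_cap = censor_cap, missing_rate = missing_rate,
              uncovered_loci = uncovered_loci,
              flanking_only_loci = flanking_only_loci,
              chrom = chrom, min_units = as.integer(min_units),
              spacing = as.integer(spacing))
  stopifnot(cfg$gc_content > 0, cfg$gc_content < 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$instability_floor >= 0, cfg$instability_slope >= 0,
            cfg$step_geom_p > 0, cfg$step_geom_p <= 1,
            cfg$n_samples > 0, cfg$spacing >= 50L)
  structure(cfg, class = "cgg_sim_config")
}

#' Draw a random set of plantable repeat loci
#'
#' Units are uniform over `units_range`; interruption counts are drawn up to
#' `max_interruptions` but capped at `floor((6u - 24) / 7)`, the largest
#' count for which a u-unit repeat still clears the default MinScore of 24
#' (an interrupted repeat below that is undetectable by construction under
#' the stated scoring, so planting one would be planting an unrecoverable
#' truth). Interruptions are placed in interior units at least 3 units
#' apart, so an exact two-copy seed always survives.
#'
#' @param n Number of loci.
#' @param genome_length Genome length the loci must fit into.
#' @param units_range Integer range of planted repeat units.
#' @param max_interruptions Maximum interruptions per locus (0-2 typical).
#' @param spacing Minimum bp between loci (and from the genome edges).
#' @param frames Frame set to sample motifs from.
#' @param chrom Sequence name.
#' @return data.frame with `chrom`, `start` (0-based), `frame`, `units`,
#'   `interruptions`.
#' @export
plant_loci <- function(n, genome_length, units_range = c(4L, 60L),
                       max_interruptions = 2L, spacing = 50L,
                       frames = canonical_motif_frames("CGG")$frames,
                       chrom = "chr1") {
  units <- sample(units_range[1]:units_range[2], n, replace = TRUE)
  kmax <- pmin(max_interruptions, pmax(0L, (6L * units - 24L) %/% 7L))
  ints <- vapply(kmax, function(k) sample(0:k, 1L), integer(1))
  lens <- units * 3L
  starts <- integer(n)
  lo <- spacing
  hi <- genome_length - spacing
  placed_s <- integer(0); placed_e <- integer(0)
  for (i in order(-lens)) {
    ok <- FALSE
    for (try in seq_len(10000L)) {
      s <- sample(lo:(hi - lens[i]), 1L)
      e <- s + lens[i]
      if (!any(s - spacing < placed_e & e + spacing > placed_s)) {
        starts[i] <- s; placed_s <- c(placed_s, s); placed_e <- c(placed_e, e)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("infeasible packing: cannot place ", n, " loci in ",
                  genome_length, " bp with spacing ", spacing)
  }
  out <- data.frame(chrom = chrom, start = starts,
                    frame = sample(frames, n, replace = TRUE),
                    units = units, interruptions = ints,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

# replace C/G with A/T in [from, to] (1-based, clipped) so no frame can form
.at_scrub <- function(chars, from, to) {
  idx <- max(1L, from):min(length(chars), to)
  idx <- idx[chars[idx] %in% c("C", "G")]
  if (length(idx)) chars[idx] <- sample(c("A", "T"), length(idx),
                                        replace = TRUE)
  chars
}

#' Generate a synthetic genome with planted repeats
#'
#' Background bases are i.i.d. at `gc_content`, then scrubbed so no
#' background window holds 3 or more tandem copies of any frame of the class
#' (stronger than the detection threshold, so chance background hits can
#' never reach it). Planted repeats are inserted verbatim with their
#' interruptions (single-base A/T substitutions in interior units) and
#' separated from the background by 12-bp A/T guard flanks, which keeps
#' local-alignment refinement from extending a planted locus into adjacent
#' chance matches: planted coordinates are exactly recoverable. Deterministic
#' given `config$seed`.
#'
#' @param config A [simulation_config()]; uses `planted_loci` or plants
#'   `n_loci` at random.
#' @param frames Frame set of the motif class.
#' @return list with `genome` (named `DNAStringSet`) and `truth` (data.frame
#'   with coordinates, motif, units, interruptions, `locus_id`, per-allele
#'   mutation probability `p_mut` and `expected_rate`).
#' @export
generate_genome <- function(config,
                            frames = canonical_motif_frames("CGG")$frames) {
  set.seed(config$seed)
  gc <- config$gc_content
  chars <- sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  planted <- config$planted_loci
  if (is.null(planted))
    planted <- plant_loci(config$n_loci, config$genome_length,
                          spacing = config$spacing, frames = frames,
                          chrom = config$chrom)
  if (any(planted$interruptions > 0 & planted$units < 6L))
    stop("planted interruptions in repeats under 6 units are undetectable")
  # scrub background tandem runs of >= 3 copies of any frame
  runs <- .frame_runs(paste(chars, collapse = ""), frames)
  runs <- runs[runs$copies >= 3L, , drop = FALSE]
  L <- nchar(frames[[1L]])
  for (k in seq_len(nrow(runs)))
    chars <- .at_scrub(chars, runs$start[k], runs$start[k] +
                         runs$copies[k] * L - 1L)
  # plant repeats with guard flanks
  truth_int <- integer(nrow(planted))
  for (k in seq_len(nrow(planted))) {
    u <- planted$units[k]
    f <- planted$frame[k]
    rseq <- strsplit(strrep(f, u), "")[[1]]
    ki <- planted$interruptions[k]
    if (ki > 0L) {
      cand <- 2:(u - 1L)
      pos_units <- integer(0)
      while (length(pos_units) < ki) {
        p <- sample(cand, 1L)
        if (!length(pos_units) || all(abs(pos_units - p) >= 3L))
          pos_units <- c(pos_units, p)
      }
      for (p in pos_units) {
        off <- sample(seq_len(L), 1L)
        rseq[(p - 1L) * L + off] <- sample(c("A", "T"), 1L)
      }
    }
    truth_int[k] <- ki
    s0 <- planted$start[k]  # 0-based
    chars[(s0 + 1L):(s0 + length(rseq))] <- rseq
    chars <- .at_scrub(chars, s0 - 11L, s0)
    chars <- .at_scrub(chars, s0 + length(rseq) + 1L,
                       s0 + length(rseq) + 12L)
  }
  seqs <- Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""),
                                            config$chrom))
  p_mut <- pmin(1, config$instability_floor +
                  config$instability_slope * planted$units)
  truth <- data.frame(
    chrom = planted$chrom, start = planted$start,
    end = planted$start + planted$units * L,
    motif = planted$frame, units = planted$units,
    interruptions = truth_int,
    locus_id = if (nrow(planted))
      paste0(planted$chrom, "_", planted$start + 1L) else character(0),
    p_mut = p_mut, expected_rate = p_mut, stringsAsFactors = FALSE)
  list(genome = seqs, truth = truth)
}

#' Simulate diploid cohort alleles at the planted loci
#'
#' Each allele independently mutates away from the planted central length
#' with probability `min(1, floor + slope * units)`; a mutated allele moves
#' `Delta ~ Geom(step_geom_p) + 1` units up or down (equiprobable), truncated
#' below at 1 unit. Since every mutated allele differs from the central
#' value, the expected per-locus polymorphism rate equals the per-allele
#' mutation probability.
#'
#' @param truth Truth table from [generate_genome()].
#' @param config The [simulation_config()].
#' @return A [callset()]-compatible data.frame of true (uncensored) alleles
#'   with `sample`, `locus_id`, `a1`, `a2`.
#' @export
simulate_population <- function(truth, config) {
  set.seed(config$seed + 1L)
  S <- config$n_samples
  nl <- nrow(truth)
  N <- 2L * S * nl
  central <- rep(truth$units, times = S)     # locus fastest, sample slowest
  p <- rep(truth$p_mut, times = S)
  draw <- function() {
    mut <- rbinom(S * nl, 1L, p) == 1L
    step <- (rgeom(S * nl, config$step_geom_p) + 1L) *
      sample(c(-1L, 1L), S * nl, replace = TRUE)
    ifelse(mut, pmax(1L, central + step), central)
  }
  a1 <- draw(); a2 <- draw()
  data.frame(sample = rep(sprintf("S%03d", seq_len(S)), each = nl),
             locus_id = rep(truth$locus_id, times = S),
             a1 = pmin(a1, a2), a2 = pmax(a1, a2),
             stringsAsFactors = FALSE)
}

.censor_units <- function(units, cap) {
  if (is.na(cap)) return(units)
  # reads only resolve lengths up to the cap; well beyond (3x) the cap,
  # fully in-read repeats reappear and the true length is reported again
  ifelse(units > cap & units < 3L * cap, cap, units)
}

#' Write simulated genotypes as an ExpansionHunter-style VCF
#'
#' Applies the read-length censoring model (reported units =
#' `min(true, censor_cap)` for true lengths in `(cap, 3*cap)`, the true
#' length elsewhere), per-allele missingness collapsed to call-level missing
#' calls, and emits `REPCN` plus `ADSP`/`ADIR`/`ADFL` evidence counts.
#' Loci listed in `config$uncovered_loci` are written with zero evidence and
#' no calls; `config$flanking_only_loci` get flanking reads only.
#'
#' @param allele_table Output of [simulate_population()] (true alleles).
#' @param truth Truth table from [generate_genome()].
#' @param config The [simulation_config()].
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
emit_vcf <- function(allele_table, truth, config, path) {
  set.seed(config$seed + 2L)
  samples <- unique(allele_table$sample)
  S <- length(samples)
  nl <- nrow(truth)
  key <- match(paste(allele_table$sample, allele_table$locus_id),
               paste(rep(samples, each = nl), rep(truth$locus_id, S)))
  ord <- order(key)
  at <- allele_table[ord, , drop = FALSE]  # locus-major within sample blocks
  cap <- config$censor_cap
  r1 <- .censor_units(at$a1, cap); r2 <- .censor_units(at$a2, cap)
  miss <- (rbinom(nrow(at), 1L, config$missing_rate) |
             rbinom(nrow(at), 1L, config$missing_rate)) == 1L
  sp <- rpois(nrow(at), 20L) + 5L
  ir <- rpois(nrow(at), 2L)
  fl <- rpois(nrow(at), 5L)
  lidx <- rep(seq_len(nl), times = S)
  unc <- truth$locus_id[lidx] %in% config$uncovered_loci
  flo <- truth$locus_id[lidx] %in% config$flanking_only_loci
  sp[unc | flo] <- 0L; ir[unc | flo] <- 0L
  fl[unc] <- 0L; fl[flo] <- rpois(sum(flo), 4L) + 1L
  miss <- miss | unc | flo
  gt <- ifelse(miss, ".", "1/1")
  repcn <- ifelse(miss, ".", paste0(r1, "/", r2))
  adsp <- paste0(sp, "/", sp); adir <- paste0(ir, "/", ir)
  adfl <- paste0(fl, "/", fl)
  cells <- matrix(paste(gt, repcn, adsp, adir, adfl, sep = ":"),
                  nrow = nl, ncol = S)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", config$chrom, ",length=",
           config$genome_length, ">"),
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##INFO=<ID=RU,Number=1,Type=String,Description=\"Repeat unit\">",
    "##INFO=<ID=RL,Number=1,Type=Integer,Description=\"Reference units\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=REPCN,Number=1,Type=String,",
           "Description=\"Number of repeat units spanned by the alleles\">"),
    paste0("##FORMAT=<ID=ADSP,Number=1,Type=String,",
           "Description=\"Number of spanning reads per allele\">"),
    paste0("##FORMAT=<ID=ADIR,Number=1,Type=String,",
           "Description=\"Number of in-repeat reads per allele\">"),
    paste0("##FORMAT=<ID=ADFL,Number=1,Type=String,",
           "Description=\"Number of flanking reads per allele\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nl), function(i) {
    paste(c(truth$chrom[i], truth$start[i] + 1L, truth$locus_id[i],
            substr(truth$motif[i], 1L, 1L), "<STR>", ".", "PASS",
            paste0("END=", truth$end[i], ";RU=", truth$motif[i],
                   ";RL=", truth$units[i]),
            "GT:REPCN:ADSP:ADIR:ADFL", cells[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate toy gene models realising every region label
#'
#' Places small genes around the first eight planted loci so that the
#' labels upstream, five_utr, exonic, intronic, three_utr, downstream,
#' ncRNA and intergenic are each realised by at least one planted locus
#' (the "downstream" gene is on the minus strand to exercise strand
#' awareness). Requires the eight role loci to be at least 2.5 kb apart.
#' Also writes GFF3 and builds a gene universe with `n_bg` repeat-free
#' background genes plus a panel enriched for repeat-associated genes at a
#' configurable odds ratio.
#'
#' @param truth Truth table from [generate_genome()] (>= 8 loci).
#' @param config The [simulation_config()].
#' @param gff3_path Where to write the GFF3 (NULL = don't write).
#' @param n_bg Number of repeat-free background gene names in the universe.
#' @param panel_size Panel size drawn from the universe.
#' @param odds_ratio Panel enrichment odds for repeat-associated genes.
#' @return list with `models` ([gene_models()]), `gff3` (path or NULL),
#'   `universe`, `repeat_genes`, `panel` (character vectors), and `roles`
#'   (locus_id -> intended label).
#' @export
generate_gene_models <- function(truth, config, gff3_path = NULL,
                                 n_bg = 92L, panel_size = 25L,
                                 odds_ratio = 1) {
  if (nrow(truth) < 8L) stop("need at least 8 planted loci for all labels")
  t8 <- truth[seq_len(8L), , drop = FALSE]
  if (any(diff(t8$start) < 2500L))
    stop("role loci must be >= 2.5 kb apart for clean labels")
  roles <- c("upstream", "five_utr", "exonic", "intronic", "three_utr",
             "downstream", "ncRNA", "intergenic")
  G <- list(); E <- list()
  add <- function(gene, chrom, strand, txs, txe, cs, ce, bt, exons) {
    G[[gene]] <<- data.frame(gene = gene, chrom = chrom, strand = strand,
                             tx_start = txs, tx_end = txe, cds_start = cs,
                             cds_end = ce, biotype = bt,
                             stringsAsFactors = FALSE)
    E[[gene]] <<- data.frame(gene = gene, start = exons[, 1],
                             end = exons[, 2], stringsAsFactors = FALSE)
  }
  for (i in seq_len(8L)) {
    s <- t8$start[i]; e <- t8$end[i]; ch <- t8$chrom[i]
    gn <- sprintf("GENE_%s", toupper(roles[i]))
    switch(roles[i],
      upstream = add(gn, ch, "+", e + 200L, e + 600L, e + 250L, e + 550L,
                     "coding", cbind(e + 200L, e + 600L)),
      five_utr = add(gn, ch, "+", s - 50L, e + 330L, e + 30L, e + 300L,
                     "coding", cbind(s - 50L, e + 330L)),
      exonic = add(gn, ch, "+", s - 100L, e + 100L, s - 50L, e + 50L,
                   "coding", cbind(s - 100L, e + 100L)),
      intronic = add(gn, ch, "+", s - 200L, e + 200L, s - 190L, e + 190L,
                     "coding", rbind(c(s - 200L, s - 150L),
                                     c(e + 150L, e + 200L))),
      three_utr = add(gn, ch, "+", s - 330L, e + 50L, s - 300L, s - 30L,
                      "coding", cbind(s - 330L, e + 50L)),
      downstream = add(gn, ch, "-", e + 200L, e + 600L, e + 250L, e + 550L,
                       "coding", cbind(e + 200L, e + 600L)),
      ncRNA = add(gn, ch, "+", s - 100L, e + 100L, NA_integer_, NA_integer_,
                  "ncRNA", cbind(s - 100L, e + 100L)),
      intergenic = NULL)
  }
  models <- gene_models(do.call(rbind, unname(G)), do.call(rbind, unname(E)))
  rownames(models$genes) <- NULL
  if (!is.null(gff3_path)) write_gene_models_gff3(models, gff3_path)
  set.seed(config$seed + 3L)
  repeat_genes <- models$genes$gene  # all placed genes touch a repeat
  universe <- c(repeat_genes, sprintf("BG_%03d", seq_len(n_bg)))
  panel <- simulate_panel(universe, repeat_genes, panel_size, odds_ratio)
  list(models = models, gff3 = gff3_path, universe = universe,
       repeat_genes = repeat_genes, panel = panel,
       roles = setNames(roles, t8$locus_id))
}

#' Draw a gene panel from a universe with configurable enrichment
#'
#' Weighted sampling without replacement: genes in `associated` get weight
#' `odds_ratio`, others weight 1. `odds_ratio = 1` draws a uniform panel
#' (the null for the enrichment test).
#'
#' @param universe Character vector of gene names.
#' @param associated Subset of `universe` considered repeat-associated.
#' @param n_panel Panel size.
#' @param odds_ratio Relative sampling odds for associated genes.
#' @return Character vector of panel genes.
#' @export
simulate_panel <- function(universe, associated, n_panel, odds_ratio = 1) {
  if (n_panel > length(universe)) stop("panel larger than universe")
  w <- ifelse(universe %in% associated, odds_ratio, 1)
  sample(universe, n_panel, prob = w)
}

#' Write gene models as GFF3
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  g <- models$genes; e <- models$exons
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    gid <- paste0("gene:", g$gene[i]); tid <- paste0("tx:", g$gene[i])
    bt <- if (g$biotype[i] == "coding") "protein_coding" else "ncRNA"
    lines <- c(lines,
      paste(g$chrom[i], "cggcat", "gene", g$tx_start[i] + 1L, g$tx_end[i],
            ".", g$strand[i], ".",
            paste0("ID=", gid, ";Name=", g$gene[i], ";biotype=", bt),
            sep = "\t"),
      paste(g$chrom[i], "cggcat",
            if (g$biotype[i] == "coding") "mRNA" else "ncRNA",
            g$tx_start[i] + 1L, g$tx_end[i], ".", g$strand[i], ".",
            paste0("ID=", tid, ";Parent=", gid), sep = "\t"))
    ei <- e[e$gene == g$gene[i], , drop = FALSE]
    for (k in seq_len(nrow(ei)))
      lines <- c(lines, paste(g$chrom[i], "cggcat", "exon",
                              ei$start[k] + 1L, ei$end[k], ".", g$strand[i],
                              ".", paste0("Parent=", tid), sep = "\t"))
    if (!is.na(g$cds_start[i]))
      lines <- c(lines, paste(g$chrom[i], "cggcat", "CDS",
                              g$cds_start[i] + 1L, g$cds_end[i], ".",
                              g$strand[i], "0", paste0("Parent=", tid),
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
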