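# Gene-region annotation of repeat loci and the panel enrichment test.
# Region labels mirror the usual refGene-style categories: a locus gets
# exactly one label by fixed precedence
#   exonic (CDS) > five_utr > three_utr > ncRNA > intronic >
#   upstream > downstream > intergenic
# with upstream/downstream measured strand-aware within a 1-kb window of the
# transcript ends; a locus over 1 kb from every gene is intergenic.

#' Construct a gene-model set
#'
#' @param genes data.frame with `gene`, `chrom`, `strand` ("+"/"-"),
#'   `tx_start`, `tx_end` (0-based half-open), `cds_start`, `cds_end` (NA for
#'   non-coding), `biotype` ("coding" or "ncRNA").
#' @param exons data.frame with `gene`, `start`, `end` (0-based half-open);
#'   exons must lie within their gene's transcript bounds.
#' @return A list of class `cgg_gene_models`.
#' @export
gene_models <- function(genes, exons) {
  need_g <- c("gene", "chrom", "strand", "tx_start", "tx_end",
              "cds_start", "cds_end", "biotype")
  if (!all(need_g %in% names(genes)))
    stop("genes needs columns ", paste(need_g, collapse = ", "))
  if (!all(c("gene", "start", "end") %in% names(exons)))
    stop("exons needs columns gene, start, end")
  if (anyDuplicated(genes$gene)) stop("duplicate gene names")
  gi <- match(exons$gene, genes$gene)
  if (anyNA(gi)) stop("exon for unknown gene")
  if (any(exons$start < genes$tx_start[gi] | exons$end > genes$tx_end[gi]))
    stop("exon outside transcript bounds")
  structure(list(genes = genes, exons = exons), class = "cgg_gene_models")
}

#' @export
print.cgg_gene_models <- function(x, ...) {
  cat("Gene models:", nrow(x$genes), "genes (",
      sum(x$genes$biotype == "coding"), "coding ),",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features (with `Name` or `ID`, optional `biotype`
#' attribute), transcript-level features (`mRNA`, `transcript`, or `ncRNA`)
#' with `Parent` pointing at the gene, and `exon`/`CDS` features with
#' `Parent` pointing at the transcript (or directly at the gene). A gene
#' without CDS features is non-coding.
#'
#' @param path GFF3 path.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  get1 <- function(x) vapply(x, function(v)
    if (length(v)) as.character(v[[1]]) else NA_character_, character(1))
  md$Parent1 <- if (is.null(md$Parent)) NA_character_ else get1(md$Parent)
  gidx <- md$type == "gene"
  gid <- md$ID[gidx]
  gname <- ifelse(is.na(md$Name[gidx]) | md$Name[gidx] == "",
                  gid, md$Name[gidx])
  id2gene <- setNames(gname, gid)
  tx <- md$type %in% c("mRNA", "transcript", "ncRNA")
  tx2gene <- setNames(id2gene[md$Parent1[tx]], md$ID[tx])
  parent_gene <- function(p) {
    out <- id2gene[p]
    miss <- is.na(out)
    out[miss] <- tx2gene[p[miss]]
    unname(out)
  }
  cds <- md[md$type == "CDS", , drop = FALSE]
  cds$gene <- parent_gene(cds$Parent1)
  cds_rng <- if (nrow(cds))
    do.call(rbind, lapply(split(cds, cds$gene), function(d)
      data.frame(gene = d$gene[1], cds_start = min(d$start) - 1L,
                 cds_end = max(d$end))))
  else data.frame(gene = character(0), cds_start = integer(0),
                  cds_end = integer(0))
  bt <- if (!is.null(md$biotype)) md$biotype[gidx] else NA_character_
  genes <- data.frame(
    gene = gname, chrom = as.character(md$seqnames[gidx]),
    strand = as.character(md$strand[gidx]),
    tx_start = md$start[gidx] - 1L, tx_end = md$end[gidx],
    stringsAsFactors = FALSE)
  genes$cds_start <- cds_rng$cds_start[match(genes$gene, cds_rng$gene)]
  genes$cds_end <- cds_rng$cds_end[match(genes$gene, cds_rng$gene)]
  genes$biotype <- ifelse(!is.na(bt) & bt %in% c("ncRNA", "noncoding"),
                          "ncRNA",
                          ifelse(is.na(genes$cds_start), "ncRNA", "coding"))
  ex <- md[md$type == "exon", , drop = FALSE]
  exons <- if (nrow(ex))
    data.frame(gene = parent_gene(ex$Parent1), start = ex$start - 1L,
               end = ex$end, stringsAsFactors = FALSE)
  else data.frame(gene = character(0), start = integer(0), end = integer(0))
  # genes without explicit exons are single-exon over the full transcript
  noex <- setdiff(genes$gene, exons$gene)
  if (length(noex)) {
    gi <- match(noex, genes$gene)
    exons <- rbind(exons, data.frame(gene = noex, start = genes$tx_start[gi],
                                     end = genes$tx_end[gi]))
  }
  gene_models(genes, exons)
}

# Feature intervals per label, as GRanges with a `gene` column.
.region_features <- function(models, flank = 1000L) {
  g <- models$genes
  e <- models$exons
  gi <- match(e$gene, g$gene)
  mk <- function(chrom, start, end, gene) {
    keep <- end > start
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(start[keep] + 1L, end[keep]),
                           gene = gene[keep])
  }
  coding <- g$biotype == "coding" & !is.na(g$cds_start)
  ec <- coding[gi]
  cds_ex <- mk(g$chrom[gi][ec],
               pmax(e$start[ec], g$cds_start[gi][ec]),
               pmin(e$end[ec], g$cds_end[gi][ec]), e$gene[ec])
  plus <- g$strand[gi] == "+"
  utr5 <- mk(g$chrom[gi][ec],
             pmax(e$start[ec], ifelse(plus[ec], g$tx_start[gi][ec],
                                      g$cds_end[gi][ec])),
             pmin(e$end[ec], ifelse(plus[ec], g$cds_start[gi][ec],
                                    g$tx_end[gi][ec])), e$gene[ec])
  utr3 <- mk(g$chrom[gi][ec],
             pmax(e$start[ec], ifelse(plus[ec], g$cds_end[gi][ec],
                                      g$tx_start[gi][ec])),
             pmin(e$end[ec], ifelse(plus[ec], g$tx_end[gi][ec],
                                    g$cds_start[gi][ec])), e$gene[ec])
  nc <- g$biotype != "coding" | is.na(g$cds_start)
  ncrna <- mk(g$chrom[nc], g$tx_start[nc], g$tx_end[nc], g$gene[nc])
  # introns: coding gene body minus its exons
  intr <- list()
  for (gn in g$gene[coding]) {
    i <- match(gn, g$gene)
    exi <- e[e$gene == gn, , drop = FALSE]
    gaps <- IRanges::gaps(IRanges::reduce(IRanges::IRanges(exi$start + 1L,
                                                           exi$end)),
                          start = g$tx_start[i] + 1L, end = g$tx_end[i])
    if (length(gaps))
      intr[[gn]] <- GenomicRanges::GRanges(g$chrom[i], gaps, gene = gn)
  }
  intronic <- if (length(intr)) do.call(c, unname(intr)) else
    mk(character(0), integer(0), integer(0), character(0))
  gplus <- g$strand == "+"
  up <- mk(g$chrom, ifelse(gplus, g$tx_start - flank, g$tx_end),
           ifelse(gplus, g$tx_start, g$tx_end + flank), g$gene)
  down <- mk(g$chrom, ifelse(gplus, g$tx_end, g$tx_start - flank),
             ifelse(gplus, g$tx_end + flank, g$tx_start), g$gene)
  body <- mk(g$chrom, g$tx_start, g$tx_end, g$gene)
  list(exonic = cds_ex, five_utr = utr5, three_utr = utr3, ncRNA = ncrna,
       intronic = intronic, upstream = up, downstream = down, body = body)
}

#' Assign each repeat locus a gene-region label
#'
#' Precedence across all overlapping genes:
#' exonic (CDS) > five_utr > three_utr > ncRNA > intronic > upstream >
#' downstream > intergenic. Upstream/downstream are strand-aware windows of
#' `flank` bp off the transcript ends; a locus overlapping any gene body is
#' never labelled upstream/downstream. Loci on chromosomes absent from the
#' gene models are intergenic (with a warning).
#'
#' @param loci A `cgg_catalog` or data.frame with `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `locus_id`.
#' @param models A [gene_models()] object.
#' @param flank Window size in bp for upstream/downstream (default 1000).
#' @return data.frame with `locus_id`, `region`, `genes` (comma-joined,
#'   empty for intergenic).
#' @export
assign_region <- function(loci, models, flank = 1000L) {
  loci <- as.data.frame(loci)
  if (is.null(loci$locus_id))
    loci$locus_id <- paste0(loci$chrom, "_", loci$start + 1L)
  if (!all(loci$chrom %in% models$genes$chrom) && nrow(models$genes))
    warning("loci on chromosome(s) absent from gene models: intergenic")
  lgr <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start + 1L, loci$end))
  feats <- .region_features(models, flank)
  region <- rep("intergenic", nrow(loci))
  genes <- rep("", nrow(loci))
  assigned <- logical(nrow(loci))
  # disjoint seqlevels are legitimate here (warned about above)
  ovl <- function(a, b) suppressWarnings(GenomicRanges::findOverlaps(a, b))
  body_hit <- suppressWarnings(
    GenomicRanges::countOverlaps(lgr, feats$body)) > 0
  for (lab in c("exonic", "five_utr", "three_utr", "ncRNA", "intronic",
                "upstream", "downstream")) {
    f <- feats[[lab]]
    if (!length(f)) next
    hits <- ovl(lgr, f)
    q <- S4Vectors::queryHits(hits)
    ok <- !assigned[q]
    if (lab %in% c("upstream", "downstream"))
      ok <- ok & !body_hit[q]  # gene-body overlap beats flanking windows
    if (!any(ok)) next
    gl <- tapply(f$gene[S4Vectors::subjectHits(hits)[ok]], q[ok],
                 function(x) paste(sort(unique(x)), collapse = ","))
    sel <- as.integer(names(gl))
    region[sel] <- lab
    genes[sel] <- as.character(gl)
    assigned[sel] <- TRUE
  }
  data.frame(locus_id = loci$locus_id, region = region, genes = genes,
             stringsAsFactors = FALSE)
}

#' Per-gene repeat association counts
#'
#' For each gene: the number of loci inside its transcript body
#' (intragenic), the number within `flank` bp of either end but outside the
#' body (flanking), and whether any repeat is associated at all. Counts are
#' per gene, so a locus inside two overlapping genes counts for both.
#'
#' @param loci A `cgg_catalog` or data.frame with `chrom`, `start`, `end`.
#' @param models A [gene_models()] object.
#' @param flank Flanking window in bp (default 1000).
#' @return data.frame with `gene`, `n_intragenic`, `n_flanking_1kb`,
#'   `any_repeat`.
#' @export
gene_association_table <- function(loci, models, flank = 1000L) {
  loci <- as.data.frame(loci)
  lgr <- GenomicRanges::GRanges(loci$chrom,
                                IRanges::IRanges(loci$start + 1L, loci$end))
  g <- models$genes
  out <- data.frame(gene = g$gene, n_intragenic = 0L, n_flanking_1kb = 0L,
                    any_repeat = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    body <- GenomicRanges::GRanges(g$chrom[i],
                                   IRanges::IRanges(g$tx_start[i] + 1L,
                                                    g$tx_end[i]))
    win <- GenomicRanges::GRanges(g$chrom[i],
                                  IRanges::IRanges(g$tx_start[i] + 1L - flank,
                                                   g$tx_end[i] + flank))
    inside <- GenomicRanges::countOverlaps(lgr, body) > 0
    near <- GenomicRanges::countOverlaps(lgr, win) > 0 & !inside
    out$n_intragenic[i] <- sum(inside)
    out$n_flanking_1kb[i] <- sum(near)
  }
  out$any_repeat <- out$n_intragenic + out$n_flanking_1kb > 0L
  out
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Closed-form `n (ad - bc)^2 / (r1 r2 c1 c2)` without continuity correction
#' (optionally with Yates correction), p-value from the chi-squared
#' distribution with 1 df.
#'
#' @param tab 2x2 integer matrix.
#' @param yates Apply Yates continuity correction (default FALSE).
#' @return list with `chi2` and `p_value`.
#' @examples
#' chi2_2x2(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
#' @export
chi2_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("need a 2x2 table")
  if (any(tab < 0)) stop("negative cell counts")
  n <- sum(tab)
  r <- rowSums(tab); cc <- colSums(tab)
  if (n == 0 || any(r == 0) || any(cc == 0))
    stop("degenerate margin: expected counts must be positive")
  det <- tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1]
  num <- if (yates) max(0, abs(det) - n / 2)^2 else det^2
  chi2 <- n * num / prod(c(r, cc))
  list(chi2 = chi2, p_value = pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Gene-panel enrichment among repeat-associated genes
#'
#' 2x2 chi-squared test of panel membership against repeat association over
#' a gene universe.
#'
#' @param repeat_genes Character vector of repeat-associated genes.
#' @param panel_genes Character vector of panel genes (e.g. a diagnostic
#'   screening list).
#' @param universe Character vector of all genes under consideration; both
#'   sets must be subsets of it.
#' @param yates Apply Yates continuity correction (default FALSE).
#' @return list with `table` (2x2: panel membership x repeat association),
#'   `chi2`, `p_value`, `n_overlap`.
#' @export
enrichment_chi2 <- function(repeat_genes, panel_genes, universe,
                            yates = FALSE) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  repeat_genes <- unique(repeat_genes); panel_genes <- unique(panel_genes)
  if (!all(repeat_genes %in% universe)) stop("repeat_genes not in universe")
  if (!all(panel_genes %in% universe)) stop("panel_genes not in universe")
  inp <- universe %in% panel_genes
  inr <- universe %in% repeat_genes
  tab <- matrix(c(sum(inp & inr), sum(inp & !inr),
                  sum(!inp & inr), sum(!inp & !inr)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(panel = c("in_panel", "not_panel"),
                                repeat_assoc = c("assoc", "not_assoc")))
  res <- chi2_2x2(tab, yates = yates)
  list(table = tab, chi2 = res$chi2, p_value = res$p_value,
       n_overlap = tab[1, 1])
}

#' Join haploinsufficiency / pLI scores onto genes
#'
#' Flags use strict inequalities (`HI < hi_cutoff`, `pLI > pli_cutoff`);
#' genes absent from the score table get NA flags, not FALSE.
#'
#' @param genes Character vector of gene names.
#' @param score_table data.frame with columns `gene`, `HI`, `pLI`
#'   (case-insensitive names accepted).
#' @param hi_cutoff HI percentage threshold (default 40).
#' @param pli_cutoff pLI threshold (default 0.75).
#' @return data.frame with `gene`, `HI`, `pLI`, `hi_low`, `pli_high`.
#' @export
join_gene_scores <- function(genes, score_table, hi_cutoff = 40,
                             pli_cutoff = 0.75) {
  nm <- tolower(names(score_table))
  gcol <- which(nm %in% c("gene", "gene_name", "symbol"))[1]
  hcol <- which(nm == "hi")[1]
  pcol <- which(nm %in% c("pli", "p_li"))[1]
  if (is.na(gcol) || is.na(hcol) || is.na(pcol))
    stop("score_table needs gene, HI and pLI columns")
  i <- match(genes, score_table[[gcol]])
  hi <- as.numeric(score_table[[hcol]])[i]
  pli <- as.numeric(score_table[[pcol]])[i]
  data.frame(gene = genes, HI = hi, pLI = pli,
             hi_low = hi < hi_cutoff, pli_high = pli > pli_cutoff,
             stringsAsFactors = FALSE)
}
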