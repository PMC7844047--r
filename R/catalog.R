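#' Build the repeat locus catalogue for a genome
#'
#' Full detection pipeline for one motif class:
#' [scan_candidates()] per sequence, wraparound scoring with
#' [score_repeat_alignment()] (candidates below `min_score` dropped),
#' boundary refinement with [refine_locus()], re-scoring of the refined span,
#' the `min_units` filter (on whole units, `floor(span / period)`), the PM/PI
#' purity filter (percent matches >= `pm`, percent indels <= `pi` over the
#' refined span), and finally overlap deduplication (higher score wins, ties
#' to the longer then leftmost locus). Output is sorted by (chrom, start);
#' retained loci are distinct and non-overlapping.
#'
#' @param genome A `Biostrings::DNAStringSet` or path to a (optionally
#'   gzipped) FASTA file. Duplicate sequence names are an error.
#' @param motif_class A [canonical_motif_frames()] object or motif string.
#' @param params [detection_params()].
#' @param align [align_params()].
#' @param seed_units,max_seed_gap Passed to [scan_candidates()].
#' @return A `cgg_catalog` data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `motif` (frame as it occurs at the locus), `units`
#'   (one decimal), `interruptions`, `score`, `locus_id`
#'   (`"<chrom>_<1-based start>"`).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = paste0(
#'   strrep("AT", 30), strrep("CGG", 7), strrep("TA", 30))))
#' build_catalog(g)
#' @export
build_catalog <- function(genome, motif_class = canonical_motif_frames("CGG"),
                          params = detection_params(), align = align_params(),
                          seed_units = 2L, max_seed_gap = 7L) {
  if (is.character(genome)) {
    if (!file.exists(genome)) stop("cannot read FASTA: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or FASTA path")
  if (anyDuplicated(names(genome)))
    stop("duplicate sequence names in genome")
  mc <- .as_motif_class(motif_class)
  L <- nchar(mc$frames[[1L]])
  rows <- list()
  for (ci in seq_along(genome)) {
    chrom <- names(genome)[ci]
    s <- toupper(as.character(genome[[ci]]))
    cands <- scan_candidates(s, mc, params, seed_units, max_seed_gap)
    if (!nrow(cands)) next
    for (k in seq_len(nrow(cands))) {
      cstart <- cands$start[k]
      cseq <- substr(s, cstart + 1L, cands$end[k])
      frame <- cands$frame[k]
      sc <- score_repeat_alignment(cseq, frame, params)
      if (sc$score < params$min_score) next
      ref <- tryCatch(refine_locus(cseq, frame, align),
                      cgg_refine_failed = function(e) {
                        message("locus dropped (", chrom, ":", cstart, "): ",
                                conditionMessage(e))
                        NULL
                      })
      if (is.null(ref)) next
      start0 <- cstart + ref$start
      end0 <- cstart + ref$end
      span <- substr(s, start0 + 1L, end0)
      sc2 <- score_repeat_alignment(span, frame, params)
      if (sc2$score < params$min_score) next
      units <- round(nchar(span) / L, 1L)
      if (floor(units) < params$min_units) next
      aligned <- sc2$matches + sc2$mismatches + sc2$indels
      if (aligned == 0L) next
      if (100 * sc2$matches / aligned < params$pm) next
      if (100 * sc2$indels / aligned > params$pi) next
      at <- substr(s, start0 + 1L, start0 + L)
      motif_here <- if (at %in% mc$frames) at else frame
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = start0, end = end0, motif = motif_here,
        units = units, interruptions = ref$interruptions,
        score = sc2$score, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               motif = character(0), units = numeric(0),
               interruptions = integer(0), score = integer(0),
               stringsAsFactors = FALSE)
  out <- .dedupe_catalog(out)
  out <- out[order(match(out$chrom, names(genome)), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$locus_id <- if (nrow(out)) paste0(out$chrom, "_", out$start + 1L)
    else character(0)
  class(out) <- c("cgg_catalog", "data.frame")
  out
}

# Overlapping refined intervals collapse to the single best locus:
# higher score, then longer, then leftmost.
.dedupe_catalog <- function(df) {
  if (nrow(df) < 2L) return(df)
  keep <- logical(nrow(df))
  for (chrom in unique(df$chrom)) {
    idx <- which(df$chrom == chrom)
    ord <- idx[order(-df$score[idx], -(df$end[idx] - df$start[idx]),
                     df$start[idx])]
    taken_s <- integer(0); taken_e <- integer(0)
    for (i in ord) {
      if (!any(df$start[i] < taken_e & df$end[i] > taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, df$start[i])
        taken_e <- c(taken_e, df$end[i])
      }
    }
  }
  df[keep, , drop = FALSE]
}

#' @export
print.cgg_catalog <- function(x, ...) {
  cat("CGG repeat catalogue:", nrow(x), "loci on",
      length(unique(x$chrom)), "sequence(s)\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more loci\n")
  invisible(x)
}

#' Write a catalogue as BED4+
#'
#' Columns: chrom, start, end (0-based half-open), motif, units,
#' interruptions, score.
#'
#' @param catalog A `cgg_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_bed <- function(catalog, path) {
  df <- as.data.frame(catalog)[, c("chrom", "start", "end", "motif",
                                   "units", "interruptions", "score")]
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4+ catalogue written by [write_catalog_bed()]
#' @param path BED path.
#' @return A `cgg_catalog` data.frame.
#' @export
read_catalog_bed <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "motif", "units",
                                 "interruptions", "score"))
  df$locus_id <- paste0(df$chrom, "_", df$start + 1L)
  class(df) <- c("cgg_catalog", "data.frame")
  df
}

#' Write a catalogue as an ExpansionHunter-style variant catalog JSON
#'
#' An array of objects with `LocusId` (`"<chrom>_<1-based start>"`),
#' `LocusStructure` (`"(CGG)*"` for the base motif), `ReferenceRegion`
#' (1-based inclusive `"chrom:start-end"`), `VariantType` (`"Repeat"`).
#'
#' @param catalog A `cgg_catalog`.
#' @param path Output path.
#' @param base_motif Motif used in `LocusStructure`.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(catalog, path, base_motif = "CGG") {
  df <- as.data.frame(catalog)
  entries <- data.frame(
    LocusId = paste0(df$chrom, "_", df$start + 1L),
    LocusStructure = paste0("(", base_motif, ")*"),
    ReferenceRegion = paste0(df$chrom, ":", df$start + 1L, "-", df$end),
    VariantType = "Repeat", stringsAsFactors = FALSE)
  jsonlite::write_json(entries, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
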