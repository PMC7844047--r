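# Seed-and-extend detection of one motif class, replacing a general-purpose
# tandem repeat finder for the single period-3 class consumed downstream.

# Exact frame occurrences chained into tandem runs. Returns one row per
# maximal run of consecutive copies of a single frame (1-based start).
.frame_runs <- function(sequence, frames) {
  n <- nchar(sequence)
  L <- nchar(frames[[1L]])
  empty <- data.frame(start = integer(0), copies = integer(0),
                      frame = character(0), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  r <- as.integer(charToRaw(sequence))
  key <- numeric(n - L + 1L)
  for (o in seq_len(L) - 1L) key <- key * 256 + r[(1L + o):(n - L + 1L + o)]
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[[fi]]
    fk <- sum(as.integer(charToRaw(f)) * 256^((L - 1L):0L))
    pos <- which(key == fk)
    if (!length(pos)) next
    prev <- match(pos - L, pos)   # occurrence exactly one period earlier
    run_id <- integer(length(pos))
    for (k in seq_along(pos)) {
      run_id[k] <- if (is.na(prev[k])) k else run_id[prev[k]]
    }
    uid <- unique(run_id)
    out[[fi]] <- data.frame(start = pos[match(uid, run_id)],
                            copies = tabulate(match(run_id, uid)),
                            frame = f, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Scan a sequence for candidate repeat regions of one motif class
#'
#' Seeds on runs of at least `seed_units` exact consecutive copies of any
#' frame of the class, then merges overlapping, adjacent, or near-adjacent
#' seeds (gap <= `max_seed_gap` bp) into candidate intervals, so interrupted
#' repeats whose pure sub-runs are short still yield a single candidate.
#' Candidates are truncated at `params$max_length`. Sub-threshold candidates
#' are cheap: they are discarded later by the `min_score` filter.
#'
#' @param sequence Uppercase DNA string; `N` bases never match.
#' @param motif_class A [canonical_motif_frames()] object (or a motif string).
#' @param params [detection_params()].
#' @param seed_units Minimum exact consecutive copies for a seed (must not
#'   exceed `params$min_units`).
#' @param max_seed_gap Maximum gap in bp bridged when merging seeds.
#' @return data.frame with 0-based half-open `start`, `end`, and the dominant
#'   `frame` (frame of the longest exact run inside the candidate).
#' @examples
#' scan_candidates(paste0("ATATAT", strrep("CGG", 5), "TATATA"),
#'                 canonical_motif_frames("CGG"), detection_params())
#' @export
scan_candidates <- function(sequence, motif_class, params = detection_params(),
                            seed_units = 2L, max_seed_gap = 7L) {
  mc <- .as_motif_class(motif_class)
  empty <- data.frame(start = integer(0), end = integer(0),
                      frame = character(0), stringsAsFactors = FALSE)
  if (!nzchar(sequence)) return(empty)
  if (seed_units > params$min_units)
    stop("seed_units must not exceed min_units")
  sequence <- toupper(sequence)
  L <- nchar(mc$frames[[1L]])
  runs <- .frame_runs(sequence, mc$frames)
  if (!nrow(runs)) return(empty)
  # all copies (even single ones) chain into candidates, so an interrupted
  # repeat keeps its outermost units; a candidate must contain at least one
  # anchor run of >= seed_units exact copies
  run_ir <- IRanges::IRanges(start = runs$start, width = runs$copies * L)
  anchor <- runs$copies >= seed_units
  if (!any(anchor)) return(empty)
  merged <- IRanges::reduce(run_ir, min.gapwidth = max_seed_gap + 1L)
  anchored <- IRanges::countOverlaps(merged, run_ir[anchor]) > 0L
  merged <- merged[anchored]
  if (!length(merged)) return(empty)
  a_ir <- run_ir[anchor]
  a_runs <- runs[anchor, , drop = FALSE]
  hit <- IRanges::findOverlaps(a_ir, merged)
  # dominant frame per merged interval: most copies, ties by frame then start
  ord <- order(S4Vectors::subjectHits(hit),
               -a_runs$copies[S4Vectors::queryHits(hit)],
               a_runs$frame[S4Vectors::queryHits(hit)],
               a_runs$start[S4Vectors::queryHits(hit)])
  first <- !duplicated(S4Vectors::subjectHits(hit)[ord])
  dom <- a_runs$frame[S4Vectors::queryHits(hit)[ord][first]]
  start0 <- IRanges::start(merged) - 1L
  end0 <- IRanges::end(merged)
  too_long <- (end0 - start0) > params$max_length
  end0[too_long] <- start0[too_long] + params$max_length
  data.frame(start = start0, end = end0, frame = dom,
             stringsAsFactors = FALSE)
}

#' Score a candidate against a periodic motif by wraparound alignment
#'
#' Optimal alignment of the full candidate against an unbounded periodic
#' extension of the motif (free motif phase at both ends), scored as
#' `match_score * matches - mismatch_penalty * mismatches -
#' indel_penalty * indels`. Deterministic; ties prefer aligned bases over
#' gaps.
#'
#' @param candidate_seq DNA string (uppercase; `N` scores as a mismatch).
#' @param motif Motif string; its length must not exceed `params$max_period`.
#' @param params [detection_params()].
#' @return list with integer `score`, `matches`, `mismatches`, `indels`.
#' @examples
#' score_repeat_alignment(strrep("CGG", 4), "CGG", detection_params())$score  # 24
#' @export
score_repeat_alignment <- function(candidate_seq, motif,
                                   params = detection_params()) {
  if (nchar(motif) > params$max_period)
    stop("motif longer than max_period")
  if (nchar(motif) < 1L) stop("empty motif")
  res <- wrap_align_cpp(toupper(candidate_seq), toupper(motif),
                        params$match_score, params$mismatch_penalty,
                        params$indel_penalty)
  lapply(res, as.integer)
}

#' Refine a candidate region by local alignment against a pure repeat
#'
#' Smith-Waterman local alignment of the region against a pure periodic motif
#' sequence longer than the region, under [align_params()]. Returns the
#' highest-scoring span; ties are broken towards more units, then fewer
#' interruptions, then the leftmost start. Interruptions count mismatched and
#' inserted region positions inside the span.
#'
#' @param region_seq DNA string containing at least one copy of some frame of
#'   the motif's rotation family.
#' @param motif Frame to refine against (its rotations are covered implicitly
#'   by the periodic extension).
#' @param align [align_params()].
#' @return list with 0-based half-open `start`, `end` offsets into
#'   `region_seq`, `units` (span / motif length, one decimal),
#'   `interruptions`, and the local alignment `score`.
#' @export
refine_locus <- function(region_seq, motif, align = align_params()) {
  region_seq <- toupper(region_seq)
  motif <- toupper(motif)
  L <- nchar(motif)
  fam <- .rotations(motif)
  if (!any(vapply(fam, grepl, logical(1), x = region_seq, fixed = TRUE)))
    stop(structure(class = c("cgg_refine_failed", "error", "condition"),
                   list(message = "refinement failed: no motif copy in region",
                        call = sys.call())))
  res <- local_align_cpp(region_seq, motif,
                         align$align_match, align$align_mismatch,
                         align$gap_open, align$gap_extend)
  if (isTRUE(res$failed))
    stop(structure(class = c("cgg_refine_failed", "error", "condition"),
                   list(message = "refinement failed: no positive-scoring span",
                        call = sys.call())))
  list(start = as.integer(res$start), end = as.integer(res$end),
       units = round((res$end - res$start) / L, 1L),
       interruptions = as.integer(res$interruptions),
       score = as.integer(res$score))
}
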