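#' Detection parameters for the repeat catalogue
#'
#' Container for the Tandem-Repeats-Finder-style scoring and filtering
#' parameters that drive [build_catalog()]. Scores are rewards, penalties are
#' positive numbers subtracted from the score: a pure k-unit trinucleotide
#' repeat scores `3 * k * match_score`, so with the defaults a 4-unit pure
#' repeat scores exactly `min_score = 24` and is the smallest retained pure
#' repeat.
#'
#' @param match_score Reward per matched base (> 0).
#' @param mismatch_penalty Penalty per mismatched base (>= 0).
#' @param indel_penalty Penalty per inserted/deleted base (>= 0).
#' @param max_period Maximum motif length in bp accepted for scoring.
#' @param min_score Minimum wraparound alignment score for a retained locus.
#' @param max_length Maximum candidate length in bp; longer candidates are
#'   truncated.
#' @param pm Minimum percent matching bases within the refined span (purity
#'   filter, 0-100).
#' @param pi Maximum percent indel bases within the refined span (0-100).
#' @param min_units Minimum whole repeat units for a retained locus.
#' @return A list of class `cgg_detection_params`.
#' @examples
#' detection_params()
#' @export
detection_params <- function(match_score = 2L, mismatch_penalty = 5L,
                             indel_penalty = 17L, max_period = 20L,
                             min_score = 24L, max_length = 1000L,
                             pm = 80, pi = 10, min_units = 4L) {
  p <- list(match_score = as.integer(match_score),
            mismatch_penalty = as.integer(mismatch_penalty),
            indel_penalty = as.integer(indel_penalty),
            max_period = as.integer(max_period),
            min_score = as.integer(min_score),
            max_length = as.integer(max_length),
            pm = as.numeric(pm), pi = as.numeric(pi),
            min_units = as.integer(min_units))
  if (p$match_score <= 0L) stop("match_score must be > 0")
  if (p$mismatch_penalty < 0L || p$indel_penalty < 0L)
    stop("penalties must be >= 0")
  if (p$min_units < 1L) stop("min_units must be >= 1")
  if (p$max_period < 1L) stop("max_period must be >= 1")
  if (p$pm < 0 || p$pm > 100 || p$pi < 0 || p$pi > 100)
    stop("pm and pi are percentages in [0, 100]")
  structure(p, class = "cgg_detection_params")
}

#' Local-alignment parameters for locus refinement
#'
#' Parameters for the Smith-Waterman refinement step in [refine_locus()].
#' The first base of a gap costs `gap_open`, each further base `gap_extend`.
#'
#' @param align_match Reward per matched base (> 0).
#' @param align_mismatch Penalty per mismatched base (>= 0).
#' @param gap_open Penalty for the first base of a gap (>= 0).
#' @param gap_extend Penalty per additional gap base (>= 0).
#' @return A list of class `cgg_align_params`.
#' @export
align_params <- function(align_match = 2L, align_mismatch = 2L,
                         gap_open = 5L, gap_extend = 1L) {
  p <- list(align_match = as.integer(align_match),
            align_mismatch = as.integer(align_mismatch),
            gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend))
  if (p$align_match <= 0L) stop("align_match must be > 0")
  if (any(unlist(p[-1]) < 0L)) stop("penalties must be >= 0")
  structure(p, class = "cgg_align_params")
}

.revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.rotations <- function(x) {
  n <- nchar(x)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(x, k + 1L, n), substr(x, 1L, k))
  }, character(1))
}

#' All reading-frame variants of a repeat motif
#'
#' A tandem repeat can be read in any rotation of its motif and on either
#' strand; for CGG the class is CGG, GGC, GCG plus the complementary-strand
#' frames CCG, GCC, CGC. All six denote the same repeat locus, so detection
#' and filtering operate on the full frame set.
#'
#' @param base_motif Uppercase DNA motif (ACGT only), e.g. `"CGG"`.
#' @return A list of class `cgg_motif_class` with elements `base_motif` and
#'   `frames` (deduplicated rotations of the motif and of its reverse
#'   complement; the base motif is always included).
#' @examples
#' canonical_motif_frames("CGG")$frames
#' @export
canonical_motif_frames <- function(base_motif) {
  if (!is.character(base_motif) || length(base_motif) != 1L ||
      nchar(base_motif) < 1L)
    stop("base_motif must be a single non-empty string")
  if (grepl("[^ACGT]", base_motif))
    stop("invalid motif: characters other than ACGT in '", base_motif, "'")
  frames <- unique(c(.rotations(base_motif), .rotations(.revcomp(base_motif))))
  # keep the base motif first, remaining frames sorted for determinism
  frames <- c(base_motif, sort(setdiff(frames, base_motif)))
  structure(list(base_motif = base_motif, frames = frames),
            class = "cgg_motif_class")
}

#' @export
print.cgg_motif_class <- function(x, ...) {
  cat("Motif class", x$base_motif, "with", length(x$frames), "frames:",
      paste(x$frames, collapse = " "), "\n")
  invisible(x)
}

.as_motif_class <- function(x) {
  if (is(x, "cgg_motif_class")) return(x)
  canonical_motif_frames(x)
}
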