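# Taxonomy for comparing two STR genotypers' call sets at shared loci.
# Alleles are paired by ascending sort within each genotype; categories are
# purely sign/magnitude/missingness based. The field interpretation of each
# category (for an ExpansionHunter-vs-GangSTR comparison, A = ExpansionHunter):
#   identical   - same unit count from both tools
#   off_by_one  - differ by one unit (handling of incomplete trailing units)
#   a_larger    - A >= 2 units larger (e.g. interruption-aware genotyping)
#   b_larger    - B >= 2 units larger (e.g. read compounding)
#   b_no_call   - B failed to genotype where A called
# Causes are not inferable from genotypes alone; they are documentation only.

.concordance_levels <- c("identical", "off_by_one", "a_larger", "b_larger",
                         "b_no_call", "a_no_call", "both_no_call")

#' Categorise a pair of allele calls from two genotypers
#'
#' @param units_a,units_b Integer repeat units (NA = no call). Vectorised.
#' @return factor with levels identical, off_by_one, a_larger, b_larger,
#'   b_no_call, a_no_call, both_no_call.
#' @examples
#' categorize_allele_pair(c(12, 13, 20, 12), c(12, 12, 15, NA))
#' @export
categorize_allele_pair <- function(units_a, units_b) {
  if (any(units_a < 0, na.rm = TRUE) || any(units_b < 0, na.rm = TRUE))
    stop("negative repeat-unit counts")
  n <- max(length(units_a), length(units_b))
  units_a <- rep_len(units_a, n); units_b <- rep_len(units_b, n)
  out <- character(n)
  out[is.na(units_a) & is.na(units_b)] <- "both_no_call"
  out[is.na(units_a) & !is.na(units_b)] <- "a_no_call"
  out[!is.na(units_a) & is.na(units_b)] <- "b_no_call"
  both <- !is.na(units_a) & !is.na(units_b)
  d <- units_a - units_b
  out[both & d == 0] <- "identical"
  out[both & abs(d) == 1] <- "off_by_one"
  out[both & d >= 2] <- "a_larger"
  out[both & d <= -2] <- "b_larger"
  factor(out, levels = .concordance_levels)
}

#' Compare two call sets allele by allele
#'
#' Joins the two call sets on their shared sample x locus grid (inner join;
#' the join size is reported), pairs alleles by ascending sort within each
#' genotype, categorises every pair, and summarises category counts and
#' fractions. The denominator is the set of allele pairs where A is called,
#' so `b_no_call` is itself a categorised outcome; fractions over that
#' denominator sum to 1. Consistency is the identical plus off-by-one
#' fraction.
#'
#' @param callset_a,callset_b Two [callset()] objects (A is the reference
#'   genotyper for the denominator).
#' @return list with `records` (per-allele data.frame), `counts`,
#'   `fractions` (named by category), `consistency`, `n_pairs`
#'   (A-called denominator), `n_shared_loci`, `n_shared_samples`.
#' @export
concordance_summary <- function(callset_a, callset_b) {
  a <- .as_callset(callset_a); b <- .as_callset(callset_b)
  m <- merge(as.data.frame(a)[, c("sample", "locus_id", "a1", "a2")],
             as.data.frame(b)[, c("sample", "locus_id", "a1", "a2")],
             by = c("sample", "locus_id"), suffixes = c("_a", "_b"))
  if (!nrow(m)) stop("no shared loci between the two call sets")
  m <- m[order(m$sample, m$locus_id), , drop = FALSE]
  records <- data.frame(
    sample = rep(m$sample, 2L), locus_id = rep(m$locus_id, 2L),
    allele_index = rep(1:2, each = nrow(m)),
    units_a = c(m$a1_a, m$a2_a), units_b = c(m$a1_b, m$a2_b),
    stringsAsFactors = FALSE)
  records$category <- categorize_allele_pair(records$units_a, records$units_b)
  called_a <- !is.na(records$units_a)
  counts <- table(records$category[called_a])
  fractions <- if (sum(counts)) as.numeric(counts) / sum(counts) else
    rep(NA_real_, length(counts))
  names(fractions) <- names(counts)
  consistency <- unname(fractions["identical"] + fractions["off_by_one"])
  list(records = records,
       counts = as.integer(counts) |> setNames(names(counts)),
       fractions = fractions,
       consistency = consistency,
       n_pairs = sum(called_a),
       n_shared_loci = length(unique(m$locus_id)),
       n_shared_samples = length(unique(m$sample)))
}
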