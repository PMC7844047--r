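# Locus- and sample-level polymorphism statistics.  The reference point at
# every locus is the population median repeat length (lower median, always an
# element of the allele multiset); a locus is polymorphic as soon as one
# called allele differs from it, and its polymorphism rate is the fraction of
# called alleles that differ.

#' Population median repeat length at a locus
#'
#' Lower median of the allele multiset: the element at position
#' `ceiling(n / 2)` of the sorted alleles, hence always an observed integer
#' allele. An interpolated median would declare every allele polymorphic at
#' even-split loci.
#'
#' @param alleles Integer vector of called allele unit counts (NAs dropped).
#' @return Integer median.
#' @examples
#' locus_median(c(5, 5, 7, 9))  # 5
#' @export
locus_median <- function(alleles) {
  x <- sort(alleles[!is.na(alleles)])
  if (!length(x)) stop("no called alleles: cannot compute a locus median")
  as.integer(x[ceiling(length(x) / 2)])
}

#' Summarise one locus from its called alleles
#'
#' @param alleles Integer vector of called allele unit counts (NAs allowed).
#' @param n_samples Number of samples genotyped at the locus (for the call
#'   rate); defaults to `length(alleles) / 2`.
#' @return list with `median_units`, `min_units`, `max_units`, `polymorphic`,
#'   `polymorphism_rate`, `call_rate`, `n_alleles`.
#' @examples
#' summarize_locus(c(7, 7, 7, 9))
#' @export
summarize_locus <- function(alleles, n_samples = length(alleles) / 2) {
  x <- alleles[!is.na(alleles)]
  if (!length(x)) stop("all-missing locus: no data to summarise")
  med <- locus_median(x)
  rate <- mean(x != med)
  list(median_units = med, min_units = min(x), max_units = max(x),
       polymorphic = rate > 0, polymorphism_rate = rate,
       call_rate = length(x) / (2 * n_samples), n_alleles = length(x))
}

#' Locus summary table for a call set
#'
#' One row per locus ([summarize_locus()] applied locus-wise). All-missing
#' loci are flagged `no_data` with NA statistics instead of being dropped.
#'
#' @param cs A [callset()].
#' @return data.frame with one row per locus.
#' @export
summarize_loci <- function(cs) {
  cs <- .as_callset(cs)
  n_samples <- length(unique(cs$sample))
  loci <- unique(cs$locus_id)
  idx <- split(seq_len(nrow(cs)), factor(cs$locus_id, levels = loci))
  rows <- lapply(loci, function(l) {
    al <- c(cs$a1[idx[[l]]], cs$a2[idx[[l]]])
    if (all(is.na(al)))
      return(data.frame(locus_id = l, median_units = NA_integer_,
                        min_units = NA_integer_, max_units = NA_integer_,
                        polymorphic = NA, polymorphism_rate = NA_real_,
                        call_rate = 0, n_alleles = 0L, no_data = TRUE))
    s <- summarize_locus(al, n_samples)
    data.frame(locus_id = l, median_units = s$median_units,
               min_units = s$min_units, max_units = s$max_units,
               polymorphic = s$polymorphic,
               polymorphism_rate = s$polymorphism_rate,
               call_rate = s$call_rate, n_alleles = s$n_alleles,
               no_data = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-sample polymorphism summary
#'
#' For each sample: the fraction of its called loci where it carries at least
#' one allele differing from that locus's population median, and its largest
#' observed allele.
#'
#' @param cs A [callset()].
#' @param locus_summaries Output of [summarize_loci()] on the same call set.
#' @return data.frame with `sample`, `fraction_polymorphic_loci`,
#'   `largest_allele`.
#' @export
summarize_samples <- function(cs, locus_summaries = summarize_loci(cs)) {
  cs <- .as_callset(cs)
  med <- locus_summaries$median_units[match(cs$locus_id,
                                            locus_summaries$locus_id)]
  called <- !is.na(cs$a1)
  differs <- called & (cs$a1 != med | cs$a2 != med)
  samples <- unique(cs$sample)
  rows <- lapply(samples, function(s) {
    i <- cs$sample == s
    n_called <- sum(called[i])
    data.frame(sample = s,
               fraction_polymorphic_loci =
                 if (n_called) sum(differs[i]) / n_called else NA_real_,
               largest_allele =
                 if (n_called) max(cs$a2[i], na.rm = TRUE) else NA_integer_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Allele deviations from the locus median at polymorphic loci
#'
#' One row per called allele at each polymorphic locus;
#' `deviation = allele - median`. Uniform loci contribute no rows.
#'
#' @param cs A [callset()].
#' @param locus_summaries Output of [summarize_loci()].
#' @return data.frame with `locus_id`, `median_units`, `allele_units`,
#'   `deviation`.
#' @export
deviation_table <- function(cs, locus_summaries = summarize_loci(cs)) {
  cs <- .as_callset(cs)
  poly <- locus_summaries[!is.na(locus_summaries$polymorphic) &
                            locus_summaries$polymorphic, , drop = FALSE]
  sub <- cs[cs$locus_id %in% poly$locus_id, , drop = FALSE]
  long <- data.frame(
    locus_id = rep(sub$locus_id, 2L),
    allele_units = c(sub$a1, sub$a2), stringsAsFactors = FALSE)
  long <- long[!is.na(long$allele_units), , drop = FALSE]
  long$median_units <- poly$median_units[match(long$locus_id, poly$locus_id)]
  long$deviation <- long$allele_units - long$median_units
  rownames(long) <- NULL
  long[, c("locus_id", "median_units", "allele_units", "deviation")]
}

#' Fraction of polymorphic loci by median repeat length
#'
#' Groups loci by their median repeat length (per value, or binned when
#' `breaks` is given) and reports the fraction flagged polymorphic in each
#' group.
#'
#' @param locus_summaries Output of [summarize_loci()].
#' @param breaks Optional numeric cut points passed to [cut()]; when NULL,
#'   one group per observed median value.
#' @return data.frame with `median_units` (value or bin label), `n_loci`,
#'   `fraction_polymorphic`.
#' @export
polymorphic_fraction_by_median <- function(locus_summaries, breaks = NULL) {
  s <- locus_summaries[!is.na(locus_summaries$median_units), , drop = FALSE]
  grp <- if (is.null(breaks)) factor(s$median_units) else
    cut(s$median_units, breaks = breaks)
  n <- tapply(s$polymorphic, grp, length)
  f <- tapply(s$polymorphic, grp, mean)
  out <- data.frame(median_units = names(n), n_loci = as.integer(n),
                    fraction_polymorphic = as.numeric(f),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$n_loci), , drop = FALSE]
  rownames(out) <- NULL
  out
}
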