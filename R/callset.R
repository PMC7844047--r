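# Diploid per-sample, per-locus repeat-unit genotypes ("call set").
# Stored long: one row per sample x locus, alleles sorted ascending,
# missing calls as NA/NA (missingness is all-or-nothing per call).

#' Construct a call set
#'
#' @param df data.frame with columns `sample`, `locus_id`, `a1`, `a2`
#'   (non-negative integer repeat units or NA) and optionally `spanning`,
#'   `inrepeat`, `flanking` read-evidence counts (NA when unknown).
#' @return A `cgg_callset` data.frame (alleles normalised ascending).
#' @export
callset <- function(df) {
  need <- c("sample", "locus_id", "a1", "a2")
  if (!all(need %in% names(df)))
    stop("callset needs columns ", paste(need, collapse = ", "))
  for (col in c("spanning", "inrepeat", "flanking"))
    if (is.null(df[[col]])) df[[col]] <- NA_integer_
  if (anyDuplicated(paste(df$sample, df$locus_id, sep = "\r")))
    stop("duplicate (sample, locus) pairs in call set")
  if (!nrow(df)) stop("empty call set")
  bad <- xor(is.na(df$a1), is.na(df$a2))
  if (any(bad))
    stop("half-missing genotypes: missingness is all-or-nothing per call")
  if (any(df$a1 < 0 | df$a2 < 0, na.rm = TRUE))
    stop("negative repeat-unit counts")
  lo <- pmin(df$a1, df$a2); hi <- pmax(df$a1, df$a2)
  df$a1 <- as.integer(lo); df$a2 <- as.integer(hi)
  df <- df[, c(need, "spanning", "inrepeat", "flanking")]
  rownames(df) <- NULL
  class(df) <- c("cgg_callset", "data.frame")
  df
}

#' @export
print.cgg_callset <- function(x, ...) {
  cat("Call set:", length(unique(x$sample)), "samples x",
      length(unique(x$locus_id)), "loci;",
      sum(is.na(x$a1)), "missing calls\n")
  invisible(x)
}

# "12/15" (ExpansionHunter), "12,15" (GangSTR) or "12" (haploid, duplicated
# to a homozygous pair) -> integer pair; anything else -> NA pair + warning.
.parse_repcn <- function(x) {
  out <- matrix(NA_integer_, nrow = length(x), ncol = 2L)
  ok <- !is.na(x) & x != "." & x != ""
  parts <- strsplit(x[ok], "[/|,]")
  vals <- lapply(parts, function(p) suppressWarnings(as.integer(p)))
  good <- vapply(vals, function(v)
    length(v) %in% 1:2 && !anyNA(v) && all(v >= 0), logical(1))
  if (any(!good))
    warning(sum(!good), " malformed REPCN value(s) treated as missing calls")
  idx <- which(ok)[good]
  v <- vals[good]
  out[idx, 1L] <- vapply(v, `[`, integer(1), 1L)
  out[idx, 2L] <- vapply(v, function(p) p[min(2L, length(p))], integer(1))
  out
}

# evidence fields come as per-allele strings ("10/12"); total per call
.parse_evidence <- function(x) {
  if (is.null(x)) return(NULL)
  vapply(as.character(x), function(v) {
    if (is.na(v) || v == "." || v == "") return(NA_integer_)
    p <- suppressWarnings(as.integer(strsplit(v, "[/|,]")[[1]]))
    if (anyNA(p)) NA_integer_ else sum(p)
  }, integer(1), USE.NAMES = FALSE)
}

#' Read an STR genotype VCF into a call set
#'
#' Parses per-sample repeat-unit genotypes from the `REPCN` FORMAT field
#' (ExpansionHunter `"a/b"` or GangSTR `"a,b"` dialect; `.` or absent means a
#' missing call; haploid records are duplicated to a homozygous pair).
#' Read-class evidence is taken from `ADSP`/`ADIR`/`ADFL` when present
#' (summed across alleles) and left NA (unknown) otherwise.
#'
#' @param vcf_path Path to a VCF 4.x file.
#' @param sample_filter Optional character vector restricting samples.
#' @return A [callset()].
#' @export
read_str_vcf <- function(vcf_path, sample_filter = NULL) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  v <- VariantAnnotation::readVcf(vcf_path)
  g <- VariantAnnotation::geno(v)
  if (!"REPCN" %in% names(g))
    stop("VCF has no REPCN FORMAT field: not an STR genotype VCF")
  repcn <- g$REPCN
  if (length(dim(repcn)) == 3L) {  # Number=2 integer dialect -> 3-d array
    repcn <- matrix(ifelse(is.na(repcn[, , 1L]), NA_character_,
                           paste(repcn[, , 1L], repcn[, , 2L], sep = ",")),
                    nrow = dim(repcn)[1L],
                    dimnames = dimnames(repcn)[1:2])
  } else if (is.list(repcn)) {     # ragged Number=. dialect
    repcn <- matrix(vapply(repcn, function(p)
      if (all(is.na(p))) NA_character_ else paste(p, collapse = ","),
      character(1)), nrow = nrow(repcn), dimnames = dimnames(repcn))
  }
  samples <- colnames(repcn)
  if (!is.null(sample_filter)) {
    samples <- intersect(samples, sample_filter)
    if (!length(samples)) stop("no samples left after sample_filter")
  }
  loci <- rownames(repcn)
  alleles <- .parse_repcn(as.character(repcn[, samples, drop = FALSE]))
  ev <- lapply(c(spanning = "ADSP", inrepeat = "ADIR", flanking = "ADFL"),
               function(f) if (f %in% names(g))
                 .parse_evidence(g[[f]][, samples, drop = FALSE])
               else NA_integer_)
  callset(data.frame(
    sample = rep(samples, each = length(loci)),
    locus_id = rep(loci, times = length(samples)),
    a1 = alleles[, 1L], a2 = alleles[, 2L],
    spanning = ev$spanning, inrepeat = ev$inrepeat, flanking = ev$flanking,
    stringsAsFactors = FALSE))
}

#' Apply the read-evidence locus exclusion rules
#'
#' A locus is excluded with reason `"no_coverage"` when no sample has any
#' spanning, in-repeat, or flanking reads; with reason `"flanking_only"` when
#' no sample has spanning or in-repeat reads but flanking reads exist. Loci
#' whose evidence is entirely unknown (NA) are kept.
#'
#' @param cs A [callset()].
#' @return list with `kept` (filtered callset, or NULL if nothing remains),
#'   `kept_loci` (character), and `excluded` (data.frame locus_id, reason).
#' @export
exclude_uncovered_loci <- function(cs) {
  cs <- .as_callset(cs)
  zero_or_na <- function(x) all(is.na(x) | x == 0L)
  any_known <- function(x) any(!is.na(x))
  per <- split(seq_len(nrow(cs)), cs$locus_id)
  reasons <- vapply(per, function(i) {
    sp <- cs$spanning[i]; ir <- cs$inrepeat[i]; fl <- cs$flanking[i]
    if (!any_known(sp) && !any_known(ir) && !any_known(fl)) return(NA_character_)
    if (zero_or_na(sp) && zero_or_na(ir)) {
      if (any(fl > 0L, na.rm = TRUE)) "flanking_only" else "no_coverage"
    } else NA_character_
  }, character(1))
  excluded <- data.frame(locus_id = names(reasons)[!is.na(reasons)],
                         reason = reasons[!is.na(reasons)],
                         stringsAsFactors = FALSE, row.names = NULL)
  kept_loci <- setdiff(unique(cs$locus_id), excluded$locus_id)
  kept <- if (length(kept_loci))
    callset(as.data.frame(cs)[cs$locus_id %in% kept_loci, , drop = FALSE])
  else NULL
  list(kept = kept, kept_loci = kept_loci, excluded = excluded)
}

#' Fraction of alleles genotyped
#'
#' Non-missing alleles over `2 * samples * loci`.
#'
#' @param cs A [callset()].
#' @return A fraction in `[0, 1]`.
#' @export
allele_call_rate <- function(cs) {
  cs <- .as_callset(cs)
  denom <- 2L * length(unique(cs$sample)) * length(unique(cs$locus_id))
  (sum(!is.na(cs$a1)) + sum(!is.na(cs$a2))) / denom
}

#' Export a call set as TSV (sample, locus, a1, a2 + evidence)
#' @param cs A [callset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(cs, path) {
  write.table(as.data.frame(.as_callset(cs)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a call-set TSV written by [write_calls_tsv()]
#' @param path TSV path.
#' @return A [callset()].
#' @export
read_calls_tsv <- function(path) {
  callset(read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                     stringsAsFactors = FALSE))
}

.as_callset <- function(x) {
  if (is(x, "cgg_callset")) return(x)
  callset(as.data.frame(x))
}
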