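# Pooled variant calling and allele-frequency filtering.
#
# Filters mirror pooled-continuous frequency-based discovery: a site is
# called when total depth >= min_coverage and some non-reference base
# reaches min_alt_reads reads and min_alt_frac of the depth. Only
# single-nucleotide variants are modelled (no MNPs or complex events).

#' Construct a variant call set
#'
#' Builds a `variant_callset` from plain columns; used by [call_variants()]
#' and for assembling call sets from external data.
#'
#' @param pos0 0-based positions (unique within the set).
#' @param ref,alt Single reference/alternate bases, `alt != ref`.
#' @param depth,alt_count Read counts; `af` is `alt_count / depth`.
#' @param library_id,cells,callable_bases,genome_length Metadata attributes;
#'   `callable_bases` is the number of sites meeting the calling depth
#'   threshold and is the denominator of per-megabase densities.
#' @return A `variant_callset` data frame (columns `pos0`, `ref`, `alt`,
#'   `depth`, `alt_count`, `af`).
#' @export
variant_callset <- function(pos0, ref, alt, depth, alt_count,
                            library_id = NA_character_, cells = NA_integer_,
                            callable_bases = NA_real_,
                            genome_length = NA_integer_) {
  n <- length(pos0)
  stopifnot(length(ref) == n, length(alt) == n, length(depth) == n,
            length(alt_count) == n)
  if (anyDuplicated(pos0)) stop("positions must be unique within a call set")
  if (n && any(alt == ref)) stop("`alt` must differ from `ref`")
  if (n && any(alt_count > depth)) stop("`alt_count` cannot exceed `depth`")
  out <- data.frame(pos0 = as.integer(pos0), ref = ref, alt = alt,
                    depth = as.integer(depth),
                    alt_count = as.integer(alt_count),
                    af = ifelse(depth > 0, alt_count / depth, NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "library_id") <- library_id
  attr(out, "cells") <- cells
  attr(out, "callable_bases") <- callable_bases
  attr(out, "genome_length") <- genome_length
  class(out) <- c("variant_callset", "data.frame")
  out
}

#' Call variants from a library pileup
#'
#' Emits one single-nucleotide call per site where total depth is at least
#' `min_coverage` and the best-supported non-reference base has at least
#' `min_alt_reads` reads and at least `min_alt_frac` of the depth.
#'
#' @param pileup A `library_pileup`.
#' @param reference The `genome_model` the pileup was simulated from (same
#'   length).
#' @param min_coverage Minimum total depth at a callable site (default 5).
#' @param min_alt_frac Minimum alternate allele fraction (default 0.01).
#' @param min_alt_reads Minimum alternate read count (default 2).
#' @return A [variant_callset()]; its `callable_bases` attribute counts the
#'   sites with depth >= `min_coverage`.
#' @export
call_variants <- function(pileup, reference, min_coverage = 5L,
                          min_alt_frac = 0.01, min_alt_reads = 2L) {
  stopifnot(inherits(pileup, "library_pileup"),
            inherits(reference, "genome_model"))
  if (pileup$genome_length != reference$length)
    stop("pileup and reference have different lengths")
  cnt <- pileup$counts
  L <- ncol(cnt)
  depth <- colSums(cnt)
  m <- t(cnt)                                   # L x 4
  m[cbind(seq_len(L), reference$codes)] <- 0L   # mask the reference base
  best <- max.col(m, ties.method = "first")
  alt_count <- m[cbind(seq_len(L), best)]
  ok <- depth >= min_coverage &
    alt_count >= min_alt_reads &
    alt_count >= min_alt_frac * depth
  pos <- which(ok)
  variant_callset(pos0 = pos - 1L,
                  ref = DNA_BASES[reference$codes[pos]],
                  alt = DNA_BASES[best[pos]],
                  depth = depth[pos], alt_count = alt_count[pos],
                  library_id = pileup$library_id, cells = pileup$cells,
                  callable_bases = sum(depth >= min_coverage),
                  genome_length = L)
}

subset_callset <- function(calls, keep) {
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("library_id", "cells", "callable_bases", "genome_length"))
    attr(out, a) <- attr(calls, a)
  class(out) <- class(calls)
  out
}

#' Partition calls into heterozygous, fixed and discarded
#'
#' Heterozygous calls have allele frequency strictly between `het_lower`
#' and `het_upper` (the lower bound is strict: a call at exactly 25% is
#' discarded); fixed calls -- complete disagreement with the reference --
#' have `af >= fixed_min`. Everything else is discarded. The three parts
#' always partition the input.
#'
#' @param calls A `variant_callset`.
#' @param het_lower,het_upper Open heterozygous band (defaults 0.25, 0.95).
#' @param fixed_min Minimum allele frequency of a fixed difference
#'   (default 0.99).
#' @return List with elements `het`, `fixed`, `discarded`, each a
#'   `variant_callset`.
#' @export
partition_calls <- function(calls, het_lower = 0.25, het_upper = 0.95,
                            fixed_min = 0.99) {
  stopifnot(inherits(calls, "variant_callset"))
  if (!(het_lower > 0 && het_lower < het_upper && het_upper <= fixed_min &&
        fixed_min <= 1))
    stop("thresholds must satisfy 0 < het_lower < het_upper <= fixed_min <= 1")
  het <- calls$af > het_lower & calls$af < het_upper
  fixed <- calls$af >= fixed_min
  list(het = subset_callset(calls, het),
       fixed = subset_callset(calls, fixed),
       discarded = subset_callset(calls, !het & !fixed))
}

#' Heterozygous SNP density per callable megabase
#'
#' @param het_calls A `variant_callset` of heterozygous calls.
#' @param callable_bases Number of callable sites; defaults to the call
#'   set's own attribute.
#' @return Heterozygous SNPs per callable Mb.
#' @export
het_density <- function(het_calls, callable_bases = NULL) {
  cb <- callable_bases %||% attr(het_calls, "callable_bases")
  if (is.null(cb) || is.na(cb) || cb <= 0)
    stop("callable_bases unknown; supply it explicitly")
  nrow(het_calls) / (cb / 1e6)
}
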