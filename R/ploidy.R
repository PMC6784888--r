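# Ploidy classification and SNP sharing across libraries.
#
# Single-cell libraries separate within-cell heterozygosity from
# cell-to-cell population variation: a heterozygous SNP of a non-haploid
# individual recurs in every independent library of that individual, while
# amplification/sequencing artefacts do not.

#' Classify ploidy from allele-frequency evidence
#'
#' Decision rules: haploid when heterozygous density is below
#' `haploid_max_density` and the spectrum shows no interior peak; diploid
#' when the *dominant* (highest) peak lies within `peak_tol` of 1/2;
#' triploid when peaks fall within `peak_tol` of both 1/3 and 2/3 (a
#' minor residual peak elsewhere does not veto the pattern); otherwise
#' unknown. When the diploid and triploid patterns hold simultaneously
#' the label is unknown, never a guess. A k-mer spectrum, when supplied,
#' is reported as corroborating evidence (a heterozygous mode near half
#' the homozygous-mode multiplicity), but allele-frequency evidence
#' decides.
#'
#' Peaks are only trusted when the spectrum holds at least
#' `min_het_for_peaks` calls: below that, the histogram of a haploid's
#' few error-derived calls is all spikes and carries no mode
#' information.
#'
#' @param spectrum An [af_spectrum()] of heterozygous calls.
#' @param density Heterozygous SNPs per callable megabase (see
#'   [het_density()]).
#' @param kmer_spec Optional [kmer_spectrum()] used for corroboration.
#' @param haploid_max_density Haploid ceiling on heterozygous density per
#'   callable Mb (default 50).
#' @param peak_tol Tolerance around 1/2, 1/3, 2/3 (default 0.05, the
#'   binomial allele-fraction noise scale at depth around 30).
#' @param bandwidth,min_prominence_frac Passed to [detect_peaks()]; the
#'   defaults (smoothing half-width 3 bins of the default 0.02 spectrum,
#'   prominence 0.15) balance valley preservation between the 1/3 and
#'   2/3 modes against the allele-fraction dispersion that
#'   amplification-gain variability adds on top of binomial sampling.
#' @param min_het_for_peaks Minimum heterozygous calls before spectrum
#'   peaks count as evidence (default 25).
#' @param support Allele-frequency band the spectrum was restricted to;
#'   passed to [detect_peaks()] so modes near a band edge are located
#'   without truncation bias.
#' @return A `ploidy_call`: list with `label` (haploid/diploid/triploid/
#'   unknown), `het_density`, `peak_positions`, `shared_het_count` (NA
#'   here; filled by sharing analyses) and `evidence` text.
#' @export
classify_ploidy <- function(spectrum, density, kmer_spec = NULL,
                            haploid_max_density = 50, peak_tol = 0.05,
                            bandwidth = 3L, min_prominence_frac = 0.15,
                            min_het_for_peaks = 25L,
                            support = c(0.25, 0.95)) {
  stopifnot(inherits(spectrum, "af_spectrum"))
  peaks <- if (spectrum$n >= min_het_for_peaks)
    detect_peaks(spectrum$counts, spectrum$mids, bandwidth = bandwidth,
                 min_prominence_frac = min_prominence_frac, refine = TRUE,
                 support = support)
  else numeric(0)
  near <- function(v) any(abs(peaks - v) <= peak_tol)
  dominant <- if (length(peaks)) {
    hts <- smoothed_height_at(spectrum$counts, spectrum$mids, peaks,
                              bandwidth)
    peaks[which.max(hts)]
  } else NA_real_
  diploid_pattern <- length(peaks) > 0 && abs(dominant - 0.5) <= peak_tol
  triploid_pattern <- length(peaks) > 0 && near(1 / 3) && near(2 / 3)
  label <-
    if (spectrum$n == 0 ||
        (density < haploid_max_density && length(peaks) == 0)) "haploid"
    else if (triploid_pattern && !diploid_pattern) "triploid"
    else if (diploid_pattern && !triploid_pattern) "diploid"
    else "unknown"
  ev <- sprintf("het density %.1f/Mb; AF peaks at {%s}",
                density, paste(sprintf("%.3f", peaks), collapse = ", "))
  if (!is.null(kmer_spec)) {
    stopifnot(inherits(kmer_spec, "kmer_spectrum"))
    h <- kmer_spec$histogram
    kp <- detect_peaks(h$n_kmers, h$multiplicity, bandwidth = bandwidth,
                       min_prominence_frac = min_prominence_frac)
    ev <- paste0(ev, sprintf("; k-mer modes at {%s}",
                             paste(round(kp, 1), collapse = ", ")))
    if (length(kp) >= 2 && abs(kp[1] / kp[length(kp)] - 0.5) <= 0.15)
      ev <- paste0(ev, " (half-depth heterozygous mode present)")
  }
  structure(list(label = label, het_density = density,
                 peak_positions = peaks, shared_het_count = NA_integer_,
                 evidence = ev),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("<ploidy_call> %s (%s)\n", x$label, x$evidence))
  invisible(x)
}

#' One-step ploidy call from a pileup
#'
#' Convenience wrapper: calls variants, partitions them, builds the
#' heterozygous allele-frequency spectrum and classifies ploidy.
#'
#' @param pileup A `library_pileup`.
#' @param reference Matching `genome_model`.
#' @param ... Passed on to [classify_ploidy()].
#' @inheritParams call_variants
#' @inheritParams partition_calls
#' @param bin_width Spectrum bin width.
#' @return A `ploidy_call` with the heterozygous call set attached as
#'   attribute `het_calls`.
#' @export
ploidy_from_pileup <- function(pileup, reference, min_coverage = 5L,
                               min_alt_frac = 0.01, min_alt_reads = 2L,
                               het_lower = 0.25, het_upper = 0.95,
                               fixed_min = 0.99, bin_width = 0.02, ...) {
  calls <- call_variants(pileup, reference, min_coverage = min_coverage,
                         min_alt_frac = min_alt_frac,
                         min_alt_reads = min_alt_reads)
  parts <- partition_calls(calls, het_lower = het_lower,
                           het_upper = het_upper, fixed_min = fixed_min)
  spec <- af_spectrum(parts$het, bin_width = bin_width)
  dens <- het_density(parts$het)
  out <- classify_ploidy(spec, dens, support = c(het_lower, het_upper), ...)
  attr(out, "het_calls") <- parts$het
  out
}

call_keys <- function(calls) {
  if (!nrow(calls)) character(0) else paste(calls$pos0, calls$alt, sep = ":")
}

#' Shared heterozygous SNPs across libraries
#'
#' For every pair of call sets, counts heterozygous calls matching on
#' (position, alternate allele), and counts calls present in at least two
#' libraries. Recurrence across independent libraries separates true
#' within-individual heterozygosity from artefacts: non-haploid taxa carry
#' thousands of shared SNPs genome-wide where haploids carry few. The
#' non-haploid flag uses a per-callable-megabase threshold
#' (`min_shared_per_mb`, default 250/Mb; with the matching haploid ceiling
#' 50/Mb these scale the genome-wide bounds of roughly 10,000 vs 2,000
#' shared SNPs to a 40-Mb genome).
#'
#' @param callsets List of >= 2 `variant_callset`s from the same reference.
#' @param het_lower,het_upper,fixed_min Heterozygous band applied to each
#'   set (see [partition_calls()]).
#' @param min_shared_per_mb Threshold on multi-library shared calls per
#'   callable Mb above which the organism is flagged non-haploid.
#' @return A `shared_het_report`: list with `pairwise` (matrix of pairwise
#'   shared counts), `multi_library_count`, `callable_mb` (mean across
#'   libraries), `shared_per_mb`, `non_haploid_by_sharing`.
#' @export
shared_het_analysis <- function(callsets, het_lower = 0.25, het_upper = 0.95,
                                fixed_min = 0.99, min_shared_per_mb = 250) {
  if (!is.list(callsets) || length(callsets) < 2)
    stop("need at least two call sets")
  hets <- lapply(callsets, function(cs)
    partition_calls(cs, het_lower, het_upper, fixed_min)$het)
  keys <- lapply(hets, call_keys)
  ids <- names(callsets) %||% rep(NA_character_, length(callsets))
  if (any(is.na(ids) | ids == ""))
    ids <- vapply(seq_along(callsets), function(i) {
      lid <- attr(callsets[[i]], "library_id")
      if (is.null(lid) || is.na(lid)) paste0("lib", i) else lid
    }, character(1))
  n <- length(keys)
  pw <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n))
    pw[i, j] <- length(intersect(keys[[i]], keys[[j]]))
  tab <- table(unlist(lapply(keys, unique)))
  multi <- sum(tab >= 2)
  cb <- vapply(callsets, function(cs) {
    v <- attr(cs, "callable_bases")
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  callable_mb <- mean(cb, na.rm = TRUE) / 1e6
  spm <- if (is.finite(callable_mb) && callable_mb > 0)
    multi / callable_mb else NA_real_
  structure(list(pairwise = pw, multi_library_count = multi,
                 callable_mb = callable_mb, shared_per_mb = spm,
                 non_haploid_by_sharing = isTRUE(spm > min_shared_per_mb),
                 min_shared_per_mb = min_shared_per_mb),
            class = "shared_het_report")
}

#' @export
print.shared_het_report <- function(x, ...) {
  cat(sprintf("<shared_het_report> %d SNPs in >=2 libraries (%.1f/Mb); non-haploid: %s\n",
              x$multi_library_count, x$shared_per_mb,
              x$non_haploid_by_sharing))
  print(x$pairwise)
  invisible(x)
}

#' Fraction of isolate SNPs recovered by a single-cell library
#'
#' @param isolate_calls Non-empty `variant_callset` from isolate (bulk)
#'   sequencing.
#' @param library_calls `variant_callset` from a single- or multi-cell
#'   library.
#' @return `|isolate intersect library| / |isolate|` on (position, alt)
#'   identity.
#' @export
isolate_recovery <- function(isolate_calls, library_calls) {
  ki <- call_keys(isolate_calls)
  if (!length(ki)) stop("isolate call set is empty")
  length(intersect(ki, call_keys(library_calls))) / length(ki)
}

#' Fixed-difference sharing across libraries (UpSet decomposition)
#'
#' Restricts to genes covered above `coverage_min` in every library, keeps
#' fixed calls (af >= `fixed_min`, complete disagreement with the
#' reference) falling inside those genes, and reports the exclusive
#' intersection size of every library subset: how many SNPs are carried by
#' exactly that set of libraries.
#'
#' @param callsets Named list of `variant_callset`s.
#' @param genes Data frame with columns `gene`, `start`, `end` (0-based
#'   half-open).
#' @param coverage Numeric matrix libraries x genes of per-gene covered
#'   fractions; dimnames must name every library and gene.
#' @param coverage_min Genes must exceed this coverage in all libraries
#'   (default 0.9, strict).
#' @param fixed_min Fixed-call allele frequency floor (default 0.99).
#' @return Data frame with `libraries` (subset label, `+`-joined),
#'   `degree` and `n_snps`, sorted by decreasing size; attribute
#'   `genes_kept` lists the genes that passed the coverage gate.
#' @export
fixed_difference_sharing <- function(callsets, genes, coverage,
                                     coverage_min = 0.9, fixed_min = 0.99) {
  stopifnot(is.list(callsets), length(callsets) >= 1,
            all(c("gene", "start", "end") %in% names(genes)))
  ids <- names(callsets)
  if (is.null(ids) || any(ids == ""))
    stop("`callsets` must be a named list")
  if (is.null(rownames(coverage)) || is.null(colnames(coverage)) ||
      !all(ids %in% rownames(coverage)) ||
      !all(genes$gene %in% colnames(coverage)))
    stop("coverage matrix must cover all libraries x genes")
  if (anyNA(coverage[ids, as.character(genes$gene)]))
    stop("coverage matrix has missing entries")
  cov <- coverage[ids, as.character(genes$gene), drop = FALSE]
  keep <- genes$gene[apply(cov > coverage_min, 2L, all)]
  gk <- genes[genes$gene %in% keep, , drop = FALSE]
  in_kept_gene <- function(p0) {
    if (!nrow(gk)) return(rep(FALSE, length(p0)))
    Reduce(`|`, lapply(seq_len(nrow(gk)),
                       function(i) p0 >= gk$start[i] & p0 < gk$end[i]))
  }
  keysets <- lapply(callsets, function(cs) {
    fx <- cs[cs$af >= fixed_min, , drop = FALSE]
    fx <- fx[in_kept_gene(fx$pos0), , drop = FALSE]
    if (!nrow(fx)) character(0) else paste(fx$pos0, fx$alt, sep = ":")
  })
  all_keys <- unique(unlist(keysets))
  if (!length(all_keys)) {
    out <- data.frame(libraries = character(0), degree = integer(0),
                      n_snps = integer(0))
  } else {
    member <- vapply(keysets, function(k) all_keys %in% k,
                     logical(length(all_keys)))
    member <- matrix(member, nrow = length(all_keys),
                     dimnames = list(NULL, ids))
    pattern <- apply(member, 1L, function(r) paste(ids[r], collapse = "+"))
    tab <- table(pattern)
    out <- data.frame(libraries = names(tab),
                      degree = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                      n_snps = as.integer(tab))
    out <- out[order(-out$n_snps, out$libraries), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "genes_kept") <- as.character(keep)
  out
}

# Smoothed histogram height at given positions (same moving average as
# detect_peaks), used to rank peaks by dominance.
smoothed_height_at <- function(counts, mids, at, bandwidth) {
  w <- as.integer(bandwidth)
  ys <- if (w > 0) {
    pad <- c(rep(0, w), counts, rep(0, w))
    sm <- stats::filter(pad, rep(1 / (2 * w + 1), 2 * w + 1), sides = 2)
    as.numeric(sm[(w + 1):(w + length(counts))])
  } else as.numeric(counts)
  ys[vapply(at, function(p) which.min(abs(mids - p)), integer(1))]
}
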