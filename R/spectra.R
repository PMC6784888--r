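# Allele frequency spectra, k-mer spectra and peak detection.

#' Allele frequency spectrum of heterozygous calls
#'
#' Histogram of per-call allele fractions on (0, 1]. Bins are left-closed
#' (`[a, b)`), the last bin closing at 1. Interior modes at 1/2 (diploid)
#' or at 1/3 and 2/3 (triploid) are the ploidy signal.
#'
#' @param calls A `variant_callset` (typically the `het` part of
#'   [partition_calls()]).
#' @param bin_width Bin width; must divide 1 evenly (default 0.02).
#' @return An `af_spectrum`: list with `breaks`, `mids`, `counts`
#'   (`sum(counts) == n`) and `n`.
#' @export
af_spectrum <- function(calls, bin_width = 0.02) {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("`bin_width` must divide 1 evenly")
  nb <- as.integer(round(nb))
  breaks <- seq_len(nb + 1L) - 1L
  breaks <- breaks / nb
  af <- calls$af
  if (length(af) && (any(af <= 0) || any(af > 1)))
    stop("allele frequencies must lie in (0, 1]")
  bin <- pmin(nb, floor(af * nb) + 1L)  # af == 1 lands in the last bin
  counts <- tabulate(bin, nbins = nb)
  structure(list(breaks = breaks, mids = (breaks[-1L] + breaks[-(nb + 1L)]) / 2,
                 counts = counts, n = length(af)),
            class = "af_spectrum")
}

#' @export
print.af_spectrum <- function(x, ...) {
  cat(sprintf("<af_spectrum> %d variants in %d bins of width %.3g\n",
              x$n, length(x$counts), diff(x$breaks[1:2])))
  invisible(x)
}

#' Exact k-mer multiplicity spectrum
#'
#' Counts every k-mer of every input sequence and histograms how many
#' distinct k-mers occur at each multiplicity. Heterozygous genome copies
#' split k-mer coverage into a half-depth mode, so spectrum modes
#' corroborate allele-frequency evidence of ploidy. K-mers containing
#' characters outside ACGT are skipped.
#'
#' @param sequences Character vector of sequences (or anything coercible
#'   with `as.character`, e.g. a `DNAStringSet`).
#' @param k K-mer size (>= 1, no larger than the longest sequence).
#' @param canonical If `TRUE` (default) a k-mer and its reverse complement
#'   are counted as one, keyed by the lexicographically smaller string.
#' @return A `kmer_spectrum`: list with `k`, `canonical`, `histogram`
#'   (data frame `multiplicity`, `n_kmers`) and `total_kmers`, where
#'   `sum(multiplicity * n_kmers) == total_kmers`.
#' @export
kmer_spectrum <- function(sequences, k, canonical = TRUE) {
  sequences <- as.character(sequences)
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("`k` must be >= 1")
  k <- as.integer(k)
  if (!length(sequences) || all(nchar(sequences) < k))
    stop("`k` exceeds the length of every sequence")
  kmers <- unlist(lapply(toupper(sequences), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (canonical && length(kmers)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(kmers)))
    kmers <- ifelse(kmers <= rc, kmers, rc)
  }
  mult <- table(kmers)
  h <- table(as.integer(mult))
  histogram <- data.frame(multiplicity = as.integer(names(h)),
                          n_kmers = as.integer(h))
  structure(list(k = k, canonical = canonical, histogram = histogram,
                 total_kmers = length(kmers)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> k=%d%s, %d k-mers, %d distinct\n", x$k,
              if (x$canonical) " (canonical)" else "", x$total_kmers,
              sum(x$histogram$n_kmers)))
  invisible(x)
}

#' Detect peaks in a histogram
#'
#' Smooths the histogram with a centred moving average of half-width
#' `bandwidth` bins and returns the positions of local maxima of the
#' smoothed histogram whose topographic prominence -- height above the
#' higher of the two saddles separating the maximum from strictly higher
#' terrain; the full height when no higher terrain exists -- is at least
#' `min_prominence_frac` of the global smoothed maximum. Prominence (not
#' raw height) is what separates genuine modes from shoulder lobes and
#' valley bumps of a broad noisy mode. Plateaus of equal smoothed height
#' count as one peak at their midpoint. With `refine = TRUE` each
#' detected maximum is
#' polished by flat-kernel mean shift (iterated count-weighted centroid
#' over a window of half-width `2 * bandwidth` bins), peaks converging to
#' within half a shift window of each other are merged (local maxima of
#' one broad noisy mode collapse to one peak), and the surviving modes
#' are polished
#' once more as cluster means: every bin is assigned to its nearest mode,
#' each mode moves to its cluster's centroid, and modes whose cluster
#' carries less than `min_prominence_frac` of the largest cluster's mass
#' are dropped. Cluster means average over all the histogram's mass, so
#' they are far less variable than raw argmax positions on sparse, noisy
#' histograms.
#'
#' When the histogram's support is truncated (e.g. an allele-frequency
#' band open at 0.25), a mode near the edge has one flank cut off and its
#' cluster mean is biased away from the edge. Supplying `support` makes
#' the centroid of a mode lying within 0.15 of a support edge use only
#' the part of its cluster symmetric about the mode within the support,
#' which removes that bias; modes further from the edges, where the bias
#' is negligible but symmetric clipping would be destabilised by
#' distributional skew, keep the plain cluster mean.
#'
#' @param counts Numeric histogram heights (non-empty).
#' @param positions Bin positions (defaults to bin index).
#' @param bandwidth Half-width of the smoothing window in bins; 0 disables
#'   smoothing.
#' @param min_prominence_frac Prominence threshold relative to the
#'   global smoothed maximum.
#' @param refine Apply centroid refinement (see above).
#' @param support Optional `c(lo, hi)` support bounds for the
#'   symmetric-window polish (only used with `refine = TRUE`).
#' @return Numeric vector of peak positions in increasing order.
#' @export
detect_peaks <- function(counts, positions = seq_along(counts),
                         bandwidth = 2L, min_prominence_frac = 0.25,
                         refine = FALSE, support = NULL) {
  if (!length(counts)) stop("empty histogram")
  stopifnot(length(positions) == length(counts), bandwidth >= 0)
  n <- length(counts)
  if (all(counts == 0)) return(numeric(0))
  w <- as.integer(bandwidth)
  ys <- if (w > 0) {
    pad <- c(rep(0, w), counts, rep(0, w))
    sm <- stats::filter(pad, rep(1 / (2 * w + 1), 2 * w + 1), sides = 2)
    as.numeric(sm[(w + 1):(w + n)])
  } else as.numeric(counts)
  r <- rle(ys)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  prev <- c(-Inf, r$values[-nr])
  nxt <- c(r$values[-1L], -Inf)
  is_peak <- r$values > prev & r$values > nxt & r$values > 0
  if (!any(is_peak)) return(numeric(0))
  cand <- floor((starts[is_peak] + ends[is_peak]) / 2)
  # topographic prominence: height above the higher of the two saddles
  # on the paths to strictly higher terrain (full height if none)
  prom <- vapply(cand, function(i) {
    h <- ys[i]
    hi <- which(ys > h)
    L <- hi[hi < i]
    sl <- if (length(L)) min(ys[max(L):i]) else -Inf
    R <- hi[hi > i]
    sr <- if (length(R)) min(ys[i:min(R)]) else -Inf
    s <- max(sl, sr)
    if (is.finite(s)) h - s else h
  }, numeric(1))
  keep <- prom >= min_prominence_frac * max(ys)
  if (!any(keep)) return(numeric(0))
  centre <- cand[keep]
  if (refine) {
    spacing <- if (n > 1) (positions[n] - positions[1]) / (n - 1) else 1
    hw <- max(1L, 2L * w) * spacing
    pos <- vapply(positions[centre], function(p) {
      for (it in 1:25) {
        win <- which(positions >= p - hw & positions <= p + hw)
        tot <- sum(counts[win])
        if (tot == 0) break
        p_new <- sum(positions[win] * counts[win]) / tot
        if (abs(p_new - p) < spacing / 20) { p <- p_new; break }
        p <- p_new
      }
      p
    }, numeric(1))
    pos <- sort(unname(pos))
    # merge refinements that converged to the same mode: fixed points of
    # one broad mode land within about half a shift window of each other,
    # while genuinely distinct modes stay a full window apart
    merge_tol <- max(spacing, hw / 2)
    if (length(pos) > 1) {
      grp <- cumsum(c(TRUE, diff(pos) > merge_tol))
      pos <- as.numeric(tapply(pos, grp, mean))
    }
    # cluster-mean polish: assign bins to nearest mode, move each mode to
    # its cluster centroid, drop low-mass clusters, and re-merge. With
    # `support` given, each centroid is taken over the part of the cluster
    # symmetric about the mode within the support, so modes near a support
    # edge are not dragged away from it by their clipped flank.
    for (it in 1:10) {
      if (!length(pos)) break
      nearest <- vapply(positions, function(p) which.min(abs(pos - p)),
                        integer(1))
      cm <- vapply(seq_along(pos), function(j) {
        sel <- nearest == j
        if (!is.null(support)) {
          W <- min(pos[j] - support[1L], support[2L] - pos[j])
          edge_zone <- 0.15 * (support[2L] - support[1L]) / 0.7
          if (W > spacing && W < edge_zone)
            sel <- sel & positions >= pos[j] - W & positions <= pos[j] + W
        }
        tot <- sum(counts[sel])
        if (tot == 0) NA_real_ else sum(positions[sel] * counts[sel]) / tot
      }, numeric(1))
      mass <- vapply(seq_along(pos), function(j) sum(counts[nearest == j]),
                     numeric(1))
      keep <- !is.na(cm) & mass >= min_prominence_frac * max(mass)
      newpos <- sort(cm[keep])
      if (length(newpos) > 1) {
        grp <- cumsum(c(TRUE, diff(newpos) > spacing))
        newpos <- as.numeric(tapply(newpos, grp, mean))
      }
      conv <- length(newpos) == length(pos) &&
        all(abs(newpos - pos) < spacing / 20)
      pos <- newpos
      if (conv) break
    }
  } else {
    pos <- positions[centre]
  }
  sort(unname(pos))
}

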