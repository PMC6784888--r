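# MDA amplification model and pooled library simulation.
#
# MDA (phi29 multiple displacement amplification) produces long tracts of
# amplified or dropped-out genome interleaved along each copy, with large
# gain differences between amplified tracts. The model here is a two-state
# (covered/dropped) Markov chain along positions per genome copy per cell,
# log-normal per-tract gain, Poisson read depth, and uniform base-call
# error. It is an emulation chosen for having a closed-form stationary
# coverage -- the empirical MDA bias itself is not being reproduced.

#' Amplification model for single-cell library simulation
#'
#' @param covered_prob Stationary probability that a genome copy is
#'   amplified (covered) at any given site, in [0, 1].
#' @param mean_tract_bp Mean tract length in bp across covered and dropped
#'   tracts (>= 1). Covered tracts have mean `2 * covered_prob *
#'   mean_tract_bp` and dropped tracts `2 * (1 - covered_prob) *
#'   mean_tract_bp`, which keeps the overall tract mean at `mean_tract_bp`
#'   and the stationary covered probability exactly `covered_prob`.
#' @param gain_sigma Log-scale standard deviation of the per-tract
#'   amplification gain. Gains are log-normal with mean 1, so `mean_depth`
#'   is preserved on average. 0 disables gain variability.
#' @param error_rate Per-base sequencing error probability, in [0, 0.05].
#'   A miscalled read is assigned uniformly to one of the three other bases.
#' @param mean_depth Target mean read depth per covered genome copy.
#' @param independent_sites If `TRUE`, sites are covered i.i.d. with
#'   probability `covered_prob` (no tract structure); used for experiments
#'   whose closed forms require exact per-locus independence.
#' @return An `amplification_model` object.
#' @export
amplification_model <- function(covered_prob = 0.7, mean_tract_bp = 2000,
                                gain_sigma = 0.6, error_rate = 0.005,
                                mean_depth = 30, independent_sites = FALSE) {
  if (covered_prob < 0 || covered_prob > 1)
    stop("`covered_prob` must lie in [0, 1]")
  if (mean_tract_bp < 1) stop("`mean_tract_bp` must be >= 1")
  if (error_rate < 0 || error_rate > 0.05)
    stop("`error_rate` must lie in [0, 0.05]")
  if (gain_sigma < 0) stop("`gain_sigma` must be >= 0")
  if (mean_depth <= 0) stop("`mean_depth` must be positive")
  structure(list(covered_prob = covered_prob, mean_tract_bp = mean_tract_bp,
                 gain_sigma = gain_sigma, error_rate = error_rate,
                 mean_depth = mean_depth,
                 independent_sites = isTRUE(independent_sites)),
            class = "amplification_model")
}

# Sample the covered mask for one genome copy. Returns covered site indices
# and the per-site amplification gain at those sites.
sample_tract_mask <- function(L, amp) {
  p <- amp$covered_prob
  sig <- amp$gain_sigma
  if (p <= 0) return(list(idx = integer(0), gain = numeric(0)))
  if (amp$independent_sites) {
    idx <- which(stats::runif(L) < p)
    gain <- if (sig > 0)
      stats::rlnorm(length(idx), meanlog = -sig^2 / 2, sdlog = sig) else
      rep(1, length(idx))
    return(list(idx = idx, gain = gain))
  }
  t <- amp$mean_tract_bp
  if (p >= 1) {
    # fully covered: tracts only modulate gain
    lens <- integer(0)
    while (sum(lens) < L)
      lens <- c(lens, 1L + stats::rgeom(max(8L, ceiling(L / t)), 1 / max(1, t)))
    k <- which(cumsum(lens) >= L)[1L]
    lens <- lens[seq_len(k)]
    lens[k] <- lens[k] - (sum(lens) - L)
    g <- if (sig > 0)
      stats::rlnorm(k, meanlog = -sig^2 / 2, sdlog = sig) else rep(1, k)
    return(list(idx = seq_len(L), gain = rep.int(g, lens)))
  }
  Lc <- max(1, 2 * p * t)       # mean covered tract
  Ld <- max(1, 2 * (1 - p) * t) # mean dropped tract
  # geometric tract lengths are memoryless, so starting state ~ Bernoulli(p)
  # makes the per-site chain stationary from position 1
  s1 <- stats::runif(1) < p
  lens <- integer(0)
  tot <- 0L
  while (tot < L) {
    nb <- max(8L, ceiling(1.5 * (L - tot) / (Lc + Ld)))
    la <- 1L + stats::rgeom(nb, 1 / (if (s1) Lc else Ld))
    lb <- 1L + stats::rgeom(nb, 1 / (if (s1) Ld else Lc))
    batch <- as.integer(rbind(la, lb)) # alternate a,b,a,b,...
    lens <- c(lens, batch)
    tot <- tot + sum(batch)
  }
  k <- which(cumsum(lens) >= L)[1L]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (sum(as.numeric(lens)) - L)
  states <- rep_len(c(s1, !s1), k)
  keep <- lens > 0L
  lens <- lens[keep]; states <- states[keep]
  covered <- rep.int(states, lens)
  gcov <- states
  ncov <- sum(states)
  g <- numeric(length(states))
  g[states] <- if (sig > 0)
    stats::rlnorm(ncov, meanlog = -sig^2 / 2, sdlog = sig) else rep(1, ncov)
  gain_all <- rep.int(g, lens)
  idx <- which(covered)
  list(idx = idx, gain = gain_all[idx])
}

#' Simulate a pooled single-cell sequencing library
#'
#' For each cell and each of the `ploidy` genome copies, amplified tracts
#' are marked by the two-state Markov chain of the amplification model;
#' covered sites receive Poisson read depth scaled by the tract's
#' log-normal gain; reads report the copy's allele, miscalled with
#' probability `error_rate`. Per-site base counts are summed over all cells
#' and copies. Copies `1..alt_copies` of every cell carry the alternate
#' allele of each planted variant.
#'
#' @param genome A `genome_model`.
#' @param variants A `phased_variants` table from [plant_variants()] (its
#'   `ploidy` attribute sets the copy number per cell).
#' @param cells Number of pooled cells (>= 1), mirroring sorted wells of 1,
#'   10, 30, 50 or 100 cells.
#' @param amp An [amplification_model()].
#' @param seed Integer seed.
#' @param library_id Optional library label.
#' @return A `library_pileup`: list with `counts` (4 x L integer matrix of
#'   per-site read counts in A,C,G,T row order), `cells`, `amp`,
#'   `genome_length`, `library_id`, `seed`.
#' @export
simulate_library <- function(genome, variants, cells, amp, seed,
                             library_id = NULL) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(variants, "phased_variants"),
            inherits(amp, "amplification_model"))
  if (cells < 1) stop("`cells` must be >= 1")
  if (missing(seed)) stop("`seed` is required")
  if (attr(variants, "genome_length") != genome$length)
    stop("variants were planted on a genome of different length")
  set.seed(seed)
  L <- genome$length
  ploidy <- attr(variants, "ploidy")
  vpos <- variants$pos0 + 1L
  valt <- match(variants$alt, DNA_BASES)
  # phase bit mask says which copies carry the alternate; fall back to
  # copies 1..alt_copies for externally built tables without phases
  vphase <- if (!is.null(variants$phase)) variants$phase
            else bitwShiftL(1L, variants$alt_copies) - 1L
  allele_by_copy <- lapply(seq_len(ploidy), function(j) {
    a <- genome$codes
    sel <- bitwAnd(vphase, bitwShiftL(1L, j - 1L)) > 0L
    a[vpos[sel]] <- valt[sel]
    a
  })
  counts <- matrix(0L, nrow = 4L, ncol = L)
  for (cell in seq_len(cells)) {
    for (j in seq_len(ploidy)) {
      mk <- sample_tract_mask(L, amp)
      if (!length(mk$idx)) next
      d <- stats::rpois(length(mk$idx), amp$mean_depth * mk$gain)
      keep <- d > 0L
      idx <- mk$idx[keep]
      d <- d[keep]
      if (!length(idx)) next
      a <- allele_by_copy[[j]][idx]
      if (amp$error_rate > 0) {
        e <- stats::rbinom(length(d), d, amp$error_rate)
        counts[cbind(a, idx)] <- counts[cbind(a, idx)] + (d - e)
        tot <- sum(e)
        if (tot > 0) {
          site <- rep.int(idx, e)
          from <- rep.int(a, e)
          b <- from + sample.int(3L, tot, replace = TRUE)
          b <- ((b - 1L) %% 4L) + 1L
          # counts is 4 x L column-major: linear bin = (site-1)*4 + base
          counts <- counts + tabulate((site - 1L) * 4L + b, nbins = 4L * L)
        }
      } else {
        counts[cbind(a, idx)] <- counts[cbind(a, idx)] + d
      }
    }
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- DNA_BASES
  structure(list(counts = counts, cells = as.integer(cells), amp = amp,
                 genome_length = L,
                 library_id = library_id %||%
                   sprintf("lib_%dcell_s%d", as.integer(cells), as.integer(seed)),
                 seed = as.integer(seed)),
            class = "library_pileup")
}

#' Per-site total read depth of a pileup
#' @param pileup A `library_pileup`.
#' @return Integer vector of length `genome_length`.
#' @export
pileup_depth <- function(pileup) {
  stopifnot(inherits(pileup, "library_pileup"))
  colSums(pileup$counts)
}

#' @export
print.library_pileup <- function(x, ...) {
  d <- pileup_depth(x)
  cat(sprintf("<library_pileup> %s: %d cells, %d bp, mean depth %.1f, %.1f%% sites covered\n",
              x$library_id, x$cells, x$genome_length, mean(d),
              100 * mean(d > 0)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
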