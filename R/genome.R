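# Reference genome and phased variant simulation.
#
# All genomic positions in this package are 0-based half-open internally;
# they become 1-based only in VCF output.

DNA_BASES <- c("A", "C", "G", "T")

#' Simulate a reference genome
#'
#' Draws an i.i.d. nucleotide sequence with a given GC content. The result
#' stands in for the assembled draft genome that single-cell libraries are
#' aligned against.
#'
#' @param length Genome length in base pairs (> 0).
#' @param gc Target GC fraction, strictly between 0 and 1. Each base is G or
#'   C with total probability `gc`, split evenly, and likewise for A/T.
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return A `genome_model` object: a list with `sequence` (single
#'   character string over ACGT), `codes` (integer codes 1--4 in A,C,G,T
#'   order, kept alongside for fast arithmetic), `length`, `gc` and `seed`.
#' @examples
#' g <- simulate_genome(1000, gc = 0.4, seed = 1)
#' substr(g$sequence, 1, 10)
#' @export
simulate_genome <- function(length, gc = 0.5, seed) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) || length < 1)
    stop("`length` must be a single positive integer")
  if (!is.numeric(gc) || length(gc) != 1L || gc <= 0 || gc >= 1)
    stop("`gc` must lie strictly between 0 and 1")
  if (missing(seed)) stop("`seed` is required for reproducible simulation")
  length <- as.integer(length)
  set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- sample.int(4L, length, replace = TRUE, prob = probs)
  genome_from_codes(codes, gc = gc, seed = as.integer(seed))
}

genome_from_codes <- function(codes, gc = NA_real_, seed = NA_integer_) {
  structure(
    list(sequence = paste(DNA_BASES[codes], collapse = ""),
         codes = codes, length = length(codes), gc = gc, seed = seed),
    class = "genome_model")
}

#' Wrap an existing nucleotide sequence as a genome model
#'
#' @param sequence Single character string over A/C/G/T (case-insensitive).
#' @return A `genome_model` (see [simulate_genome()]).
#' @export
genome_from_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) < 1L)
    stop("`sequence` must be a single non-empty string")
  codes <- match(strsplit(toupper(sequence), "")[[1]], DNA_BASES)
  if (anyNA(codes)) stop("sequence contains characters outside ACGT")
  genome_from_codes(codes)
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d bp, GC %s, seed %s\n", x$length,
              ifelse(is.na(x$gc), "?", format(x$gc)),
              ifelse(is.na(x$seed), "?", x$seed)))
  invisible(x)
}

#' Ploidy configuration for variant planting
#'
#' Describes the latent genotype model: the number of genome copies per cell
#' and the per-base rates of heterozygous and fixed (homozygous-difference)
#' sites. Ploidy is capped at 3, matching the haploid-to-triploid range
#' observed in early-diverging fungal single-cell genomes.
#'
#' @param ploidy Integer in 1..3.
#' @param het_rate Heterozygous sites per base pair, in [0, 0.05]. Must be 0
#'   for haploids, which carry no within-cell heterozygosity.
#' @param fixed_rate Homozygous-difference sites per base pair (alternate
#'   allele on every copy), >= 0.
#' @return A `ploidy_config` object.
#' @export
ploidy_config <- function(ploidy, het_rate = 0, fixed_rate = 0) {
  if (!ploidy %in% 1:3) stop("`ploidy` must be 1, 2 or 3")
  if (het_rate < 0 || het_rate > 0.05)
    stop("`het_rate` must lie in [0, 0.05]")
  if (fixed_rate < 0 || het_rate + fixed_rate > 1)
    stop("invalid `fixed_rate`")
  if (ploidy == 1L && het_rate > 0)
    stop("haploid genomes cannot carry heterozygous sites (het_rate must be 0)")
  structure(list(ploidy = as.integer(ploidy), het_rate = het_rate,
                 fixed_rate = fixed_rate),
            class = "ploidy_config")
}

#' Plant phased variants on a genome
#'
#' Each position is independently heterozygous with probability `het_rate`
#' or fixed with probability `fixed_rate`. A heterozygous site carries the
#' alternate allele on `alt_copies` < ploidy genome copies: 1 of 2 for
#' diploids (expected allele fraction 1/2), and uniformly 1 or 2 of 3 for
#' triploids (expected allele fractions 1/3 and 2/3). Fixed sites carry the
#' alternate on every copy.
#'
#' The phase of each variant -- which genome copies carry the alternate --
#' is drawn uniformly among the subsets of size `alt_copies` and is a
#' property of the genotype: every cell of the individual shares it.
#' Unlinked heterozygous variants therefore sit on random haplotypes, as
#' in a real non-haploid genome.
#'
#' @param genome A `genome_model`.
#' @param config A [ploidy_config()].
#' @param seed Integer seed.
#' @return A `phased_variants` data frame with columns `pos0` (0-based,
#'   strictly increasing), `ref`, `alt` (single bases, `alt != ref`),
#'   `alt_copies` and `phase` (bit mask over genome copies, with
#'   `alt_copies` bits set); attributes `ploidy`, `genome_length`, `seed`.
#' @export
plant_variants <- function(genome, config, seed) {
  stopifnot(inherits(genome, "genome_model"), inherits(config, "ploidy_config"))
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  L <- genome$length
  u <- stats::runif(L)
  is_het <- u < config$het_rate
  is_var <- u < config$het_rate + config$fixed_rate
  pos <- which(is_var)
  het <- is_het[pos]
  n <- length(pos)
  ref_code <- genome$codes[pos]
  # alternate base uniform over the three non-reference bases
  alt_code <- ref_code + sample.int(3L, n, replace = TRUE)
  alt_code <- ((alt_code - 1L) %% 4L) + 1L
  alt_copies <- integer(n)
  alt_copies[!het] <- config$ploidy
  if (any(het)) {
    alt_copies[het] <- if (config$ploidy == 3L)
      sample(1:2, sum(het), replace = TRUE) else 1L
  }
  phase <- integer(n)
  phase[!het] <- bitwShiftL(1L, config$ploidy) - 1L  # all copies
  if (any(het)) {
    if (config$ploidy == 2L) {
      phase[het] <- sample(c(1L, 2L), sum(het), replace = TRUE)
    } else { # ploidy 3: one-copy masks {1,2,4}, two-copy masks {3,5,6}
      h1 <- het & alt_copies == 1L
      h2 <- het & alt_copies == 2L
      phase[h1] <- sample(c(1L, 2L, 4L), sum(h1), replace = TRUE)
      phase[h2] <- sample(c(3L, 5L, 6L), sum(h2), replace = TRUE)
    }
  }
  out <- data.frame(pos0 = pos - 1L,
                    ref = DNA_BASES[ref_code],
                    alt = DNA_BASES[alt_code],
                    alt_copies = alt_copies,
                    phase = phase,
                    stringsAsFactors = FALSE)
  attr(out, "ploidy") <- config$ploidy
  attr(out, "genome_length") <- L
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("phased_variants", "data.frame")
  out
}
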