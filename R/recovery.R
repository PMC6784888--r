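# Genome recovery, co-assembly union and marker completeness.
#
# Co-assembly of pooled libraries is modelled as the union of each
# library's covered territory; completeness is proxied by recovery of
# marker intervals (a stand-in for core-eukaryotic-gene completeness on
# real assemblies) and assembly size by the covered base count.

#' Coverage mask from a pileup
#'
#' @param pileup A `library_pileup`.
#' @param min_depth Minimum total depth for a site to count as covered
#'   (inclusive; default 1).
#' @return A `coverage_mask`: list with `covered` (logical over genome
#'   positions), `min_depth`, `library_id`.
#' @export
mask_from_pileup <- function(pileup, min_depth = 1L) {
  stopifnot(inherits(pileup, "library_pileup"))
  coverage_mask(pileup_depth(pileup) >= min_depth,
                min_depth = min_depth, library_id = pileup$library_id)
}

#' @rdname mask_from_pileup
#' @param covered Logical vector over genome positions.
#' @param library_id Library label.
#' @export
coverage_mask <- function(covered, min_depth = 1L, library_id = NA_character_) {
  stopifnot(is.logical(covered), length(covered) > 0)
  structure(list(covered = covered, min_depth = as.integer(min_depth),
                 library_id = library_id),
            class = "coverage_mask")
}

#' Union of coverage masks
#'
#' Positionwise OR of the masks: the co-assembly's recoverable territory.
#'
#' @param masks List of `coverage_mask`s of equal length.
#' @return A `coverage_mask` labelled `"union"`.
#' @export
union_mask <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1,
            all(vapply(masks, inherits, logical(1), "coverage_mask")))
  lens <- vapply(masks, function(m) length(m$covered), integer(1))
  if (length(unique(lens)) != 1L) stop("masks have different lengths")
  coverage_mask(Reduce(`|`, lapply(masks, `[[`, "covered")),
                min_depth = masks[[1]]$min_depth, library_id = "union")
}

#' Covered fraction of a mask
#' @param mask A `coverage_mask`.
#' @export
covered_fraction <- function(mask) mean(mask$covered)

#' Marker interval set
#'
#' Non-overlapping genomic intervals standing in for core marker genes.
#' A marker counts as recovered when at least `recover_frac` of its length
#' is covered (inclusive threshold).
#'
#' @param intervals Data frame with `start`, `end` (0-based half-open).
#' @param recover_frac Covered-length fraction required (default 0.70).
#' @return A `marker_set`.
#' @export
marker_set <- function(intervals, recover_frac = 0.70) {
  stopifnot(all(c("start", "end") %in% names(intervals)))
  if (recover_frac <= 0 || recover_frac > 1)
    stop("`recover_frac` must lie in (0, 1]")
  iv <- intervals[order(intervals$start), , drop = FALSE]
  if (any(iv$end <= iv$start)) stop("empty or inverted marker interval")
  if (nrow(iv) > 1 && any(iv$start[-1] < iv$end[-nrow(iv)]))
    stop("marker intervals overlap")
  rownames(iv) <- NULL
  structure(list(intervals = iv, recover_frac = recover_frac),
            class = "marker_set")
}

#' Randomly placed non-overlapping markers
#'
#' Places `n_markers` intervals of length `marker_len` on a slot grid of
#' spacing `2 * marker_len`, guaranteeing non-overlap.
#'
#' @param genome_length Genome length in bp.
#' @param n_markers Number of markers.
#' @param marker_len Marker length in bp.
#' @param seed Integer seed.
#' @inheritParams marker_set
#' @return A [marker_set()].
#' @export
simulate_markers <- function(genome_length, n_markers = 50, marker_len = 500,
                             recover_frac = 0.70, seed) {
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  n_slots <- floor(genome_length / (2 * marker_len))
  if (n_markers > n_slots)
    stop("genome too short for that many non-overlapping markers")
  slots <- sort(sample.int(n_slots, n_markers))
  start <- (slots - 1L) * 2L * marker_len
  marker_set(data.frame(start = start, end = start + marker_len),
             recover_frac = recover_frac)
}

#' Marker-based completeness of a coverage mask
#'
#' @param mask A `coverage_mask`.
#' @param markers A [marker_set()] whose intervals lie within the genome.
#' @return Percentage (0--100) of markers whose covered length is at least
#'   `recover_frac` of their length.
#' @export
marker_completeness <- function(mask, markers) {
  stopifnot(inherits(mask, "coverage_mask"), inherits(markers, "marker_set"))
  iv <- markers$intervals
  if (!nrow(iv)) stop("empty marker set")
  if (any(iv$end > length(mask$covered)))
    stop("marker intervals extend beyond the genome")
  rec <- vapply(seq_len(nrow(iv)), function(i) {
    len <- iv$end[i] - iv$start[i]
    cov <- sum(mask$covered[(iv$start[i] + 1L):iv$end[i]])
    cov >= markers$recover_frac * len
  }, logical(1))
  100 * mean(rec)
}

#' Simulated genome-recovery experiment
#'
#' Simulates one library per entry of `cell_counts`, computes per-library
#' coverage masks, marker completeness and covered-base counts (the
#' assembly-size proxy), the co-assembly union of all libraries, and the
#' fraction of each library's reads lying in the union mask.
#'
#' @param genome A `genome_model`.
#' @param variants `phased_variants` for the individual being sequenced.
#' @param amp An [amplification_model()].
#' @param cell_counts Integer vector of cells per library, e.g.
#'   `c(1, 10, 30, 50, 100)`.
#' @param markers A [marker_set()].
#' @param seed Integer seed; library i uses `seed + i`.
#' @param min_depth Coverage-mask depth threshold.
#' @return A `recovery_report`: list with `libraries` (data frame of
#'   per-library metrics), `union` (one-row data frame for the
#'   co-assembly), and `points` (the completeness-vs-size scatter table
#'   including the union).
#' @export
recovery_experiment <- function(genome, variants, amp, cell_counts, markers,
                                seed, min_depth = 1L) {
  if (!length(cell_counts)) stop("empty library design")
  if (missing(seed)) stop("`seed` is required")
  libs <- vector("list", length(cell_counts))
  masks <- vector("list", length(cell_counts))
  for (i in seq_along(cell_counts)) {
    libs[[i]] <- simulate_library(genome, variants, cells = cell_counts[i],
                                  amp = amp, seed = seed + i,
                                  library_id = sprintf("L%d_%dcell", i,
                                                       cell_counts[i]))
    masks[[i]] <- mask_from_pileup(libs[[i]], min_depth = min_depth)
  }
  um <- union_mask(masks)
  per <- data.frame(
    library_id = vapply(libs, `[[`, character(1), "library_id"),
    cells = as.integer(cell_counts),
    covered_bases = vapply(masks, function(m) sum(m$covered), numeric(1)),
    covered_fraction = vapply(masks, covered_fraction, numeric(1)),
    completeness_pct = vapply(masks, marker_completeness, numeric(1),
                              markers = markers),
    incorporated_read_frac = vapply(seq_along(libs), function(i) {
      d <- pileup_depth(libs[[i]])
      tot <- sum(d)
      if (tot == 0) return(NA_real_)
      sum(d[um$covered]) / tot
    }, numeric(1)),
    stringsAsFactors = FALSE)
  un <- data.frame(library_id = "union", cells = sum(cell_counts),
                   covered_bases = sum(um$covered),
                   covered_fraction = covered_fraction(um),
                   completeness_pct = marker_completeness(um, markers),
                   incorporated_read_frac = 1,
                   stringsAsFactors = FALSE)
  structure(list(libraries = per, union = un,
                 points = rbind(per, un)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$points[, c("library_id", "cells", "covered_bases",
                     "completeness_pct")], row.names = FALSE)
  invisible(x)
}

#' Pearson correlation of completeness with assembly size
#'
#' @param points Data frame with `completeness_pct` and `covered_bases`
#'   (>= 3 rows), e.g. the `points` table of [recovery_experiment()].
#' @return Pearson correlation coefficient.
#' @export
completeness_size_correlation <- function(points) {
  stopifnot(all(c("completeness_pct", "covered_bases") %in% names(points)))
  if (nrow(points) < 3) stop("need at least 3 points")
  if (stats::sd(points$completeness_pct) == 0 ||
      stats::sd(points$covered_bases) == 0)
    stop("degenerate variance: correlation undefined")
  stats::cor(points$completeness_pct, points$covered_bases)
}
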