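# Orthogroup cluster selection and supermatrix statistics.

#' Orthology cluster set
#'
#' Holds per-cluster gene copy counts across a genome panel, as produced
#' by upstream all-vs-all clustering (consumed, not computed, here).
#'
#' @param counts Integer matrix clusters x genomes of gene copy counts
#'   (>= 0), with complete dimnames.
#' @param lengths Optional per-cluster alignment lengths (> 0), for
#'   supermatrix statistics.
#' @return An `ortho_clusters` object.
#' @export
ortho_clusters <- function(counts, lengths = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` needs cluster rownames and genome colnames")
  if (any(counts < 0)) stop("copy counts must be >= 0")
  if (!is.null(lengths)) {
    stopifnot(length(lengths) == nrow(counts))
    if (any(lengths <= 0)) stop("alignment lengths must be positive")
  }
  structure(list(counts = counts, lengths = lengths,
                 panel = colnames(counts)),
            class = "ortho_clusters")
}

#' @export
print.ortho_clusters <- function(x, ...) {
  cat(sprintf("<ortho_clusters> %d clusters x %d genomes%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$lengths)) "" else " (with lengths)"))
  invisible(x)
}

#' Generate synthetic orthology clusters with known structure
#'
#' Every cluster starts single-copy in every genome; genomes are then
#' knocked out (missing) and duplicated (extra copies) under the chosen
#' model. The planted per-cluster missing counts and multi-copy flags are
#' kept as ground truth for oracle tests of the selection rule.
#'
#' @param n_genomes,n_clusters Panel and cluster counts (> 0).
#' @param p_extra_copy Probability a present genome carries a second copy.
#' @param p_missing Per-genome missing probability (ignored when
#'   `exact_missing` is given).
#' @param exact_missing If set, exactly this many genomes are missing from
#'   every cluster.
#' @param mean_length Mean of Poisson-distributed alignment lengths.
#' @param seed Integer seed; regeneration is byte-identical.
#' @return An [ortho_clusters()] with extra fields `planted_missing` and
#'   `planted_multi`.
#' @export
make_ortho_clusters <- function(n_genomes, n_clusters, p_extra_copy = 0.1,
                                p_missing = 0.15, exact_missing = NULL,
                                mean_length = 300, seed) {
  if (n_genomes < 1 || n_clusters < 1) stop("counts must be positive")
  if (!is.null(exact_missing) && exact_missing >= n_genomes)
    stop("`exact_missing` must be < n_genomes")
  if (missing(seed)) stop("`seed` is required")
  set.seed(seed)
  genomes <- sprintf("g%02d", seq_len(n_genomes))
  cl <- sprintf("cluster%04d", seq_len(n_clusters))
  counts <- matrix(1L, n_clusters, n_genomes, dimnames = list(cl, genomes))
  for (i in seq_len(n_clusters)) {
    if (!is.null(exact_missing)) {
      if (exact_missing > 0)
        counts[i, sample.int(n_genomes, exact_missing)] <- 0L
    } else {
      counts[i, stats::runif(n_genomes) < p_missing] <- 0L
    }
    pres <- which(counts[i, ] > 0)
    dup <- pres[stats::runif(length(pres)) < p_extra_copy]
    counts[i, dup] <- counts[i, dup] + 1L
  }
  out <- ortho_clusters(counts,
                        lengths = pmax(1L, stats::rpois(n_clusters,
                                                        mean_length)))
  out$planted_missing <- rowSums(counts == 0L)
  out$planted_multi <- rowSums(counts > 1L) > 0L
  out
}

#' Select single-copy orthogroups for a supermatrix
#'
#' A cluster is selected when every genome present in it has exactly one
#' gene copy, at most `max_missing` panel genomes are absent, and at least
#' `min_taxa` genomes are present.
#'
#' @param clusters An [ortho_clusters()].
#' @param max_missing Maximum missing taxa per cluster (default 8; must be
#'   smaller than the panel size).
#' @param min_taxa Minimum taxa per orthogroup (default 3).
#' @return Character vector of selected cluster ids.
#' @export
select_single_copy_clusters <- function(clusters, max_missing = 8L,
                                        min_taxa = 3L) {
  stopifnot(inherits(clusters, "ortho_clusters"))
  panel_size <- ncol(clusters$counts)
  if (max_missing >= panel_size)
    stop("`max_missing` must be smaller than the panel size")
  cc <- clusters$counts
  n_present <- rowSums(cc > 0L)
  has_multi <- rowSums(cc > 1L) > 0L
  sel <- !has_multi & (panel_size - n_present) <= max_missing &
    n_present >= min_taxa
  rownames(cc)[sel]
}

#' Supermatrix missing-data statistics
#'
#' For the concatenated alignment of the selected clusters, a taxon's
#' missing fraction is the summed length of clusters lacking it over the
#' total length. Group medians (e.g. target vs other genomes) quantify
#' how much more gappy partial single-cell genomes are.
#'
#' @param clusters An [ortho_clusters()] carrying `lengths`.
#' @param selected Cluster ids to concatenate (default: all).
#' @param groups Optional character vector named by genome giving group
#'   labels for the medians.
#' @return List with `per_taxon` (data frame `taxon`, `missing_frac`) and
#'   `group_medians` (named numeric, or NULL).
#' @export
supermatrix_stats <- function(clusters, selected = NULL, groups = NULL) {
  stopifnot(inherits(clusters, "ortho_clusters"))
  if (is.null(clusters$lengths))
    stop("cluster alignment lengths are required")
  sel <- selected %||% rownames(clusters$counts)
  if (!length(sel)) stop("no selected clusters")
  if (!all(sel %in% rownames(clusters$counts)))
    stop("unknown cluster ids in `selected`")
  idx <- match(sel, rownames(clusters$counts))
  len <- clusters$lengths[idx]
  present <- clusters$counts[idx, , drop = FALSE] > 0L
  total <- sum(len)
  missing_frac <- colSums(len * (!present)) / total
  per_taxon <- data.frame(taxon = colnames(clusters$counts),
                          missing_frac = unname(missing_frac),
                          stringsAsFactors = FALSE)
  gm <- NULL
  if (!is.null(groups)) {
    if (!all(per_taxon$taxon %in% names(groups)))
      stop("every taxon needs a group label")
    g <- groups[per_taxon$taxon]
    gm <- tapply(per_taxon$missing_frac, g, stats::median)
    gm <- stats::setNames(as.numeric(gm), names(gm))
  }
  list(per_taxon = per_taxon, group_medians = gm, total_length = total)
}
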