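# Run configuration: one flat record of every tunable, with key=value
# text serialization.

#' Default run configuration
#'
#' Collects every tunable of the pipeline with its default. Thresholds
#' with an established value keep it here: calling depth 5, alternate
#' fraction 0.01 with 2 supporting reads, heterozygous band open above
#' 0.25, fixed-difference gene coverage gate 0.9, scaffold floor 2000 bp,
#' core fraction 0.75 with 5 absent targets, orthogroup selection with at
#' most 8 missing taxa and at least 3 present, marker recovery fraction
#' 0.70.
#'
#' @param ... Overrides of any default, by name.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome_length = 30000L,
    gc = 0.45,
    het_rate = 0.005,
    fixed_rate = 0.001,
    covered_prob = 0.7,
    mean_tract_bp = 2000,
    gain_sigma = 0.6,
    error_rate = 0.005,
    mean_depth = 30,
    cell_counts = c(1L, 10L),
    min_coverage = 5L,
    min_alt_frac = 0.01,
    min_alt_reads = 2L,
    het_lower = 0.25,
    het_upper = 0.95,
    fixed_min = 0.99,
    bin_width = 0.02,
    haploid_max_density = 50,
    peak_tol = 0.05,
    min_shared_per_mb = 250,
    gene_coverage_min = 0.9,
    scaffold_min_len = 2000L,
    min_depth_mask = 1L,
    recover_frac = 0.70,
    n_markers = 30L,
    marker_len = 400L,
    core_frac = 0.75,
    min_absent_targets = 5L,
    max_missing = 8L,
    min_taxa = 3L,
    kmer_k = 21L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(structure(cfg, class = "run_config"))
}

validate_run_config <- function(cfg) {
  with(cfg, {
    stopifnot(genome_length > 0, gc > 0, gc < 1,
              het_rate >= 0, het_rate <= 0.05,
              covered_prob >= 0, covered_prob <= 1,
              mean_tract_bp >= 1, error_rate >= 0, error_rate <= 0.05,
              all(cell_counts >= 1),
              min_coverage >= 1, min_alt_reads >= 0,
              het_lower > 0, het_lower < het_upper,
              het_upper <= fixed_min, fixed_min <= 1,
              gene_coverage_min > 0, gene_coverage_min <= 1,
              scaffold_min_len >= 0,
              recover_frac > 0, recover_frac <= 1,
              core_frac > 0, core_frac <= 1,
              max_missing >= 0, min_taxa >= 1, kmer_k >= 1)
  })
  cfg
}

#' Write / read a run configuration as key=value text
#'
#' Serialization is lossless: numeric values use full precision and
#' vectors are comma-joined; [read_run_config()] restores the types of
#' the defaults.
#'
#' @param cfg A [run_config()].
#' @param path Text file.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s=%s", k, paste(format(v, digits = 17), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @return `read_run_config`: the restored `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1))
  defaults <- run_config()
  bad <- setdiff(keys, names(defaults))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (i in seq_along(keys)) {
    proto <- defaults[[keys[i]]]
    parts <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    cfg[[keys[i]]] <- if (is.integer(proto)) as.integer(parts)
                      else if (is.numeric(proto)) as.numeric(parts)
                      else trimws(parts)
  }
  validate_run_config(structure(cfg, class = "run_config"))
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x))
    cat(sprintf("  %s = %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}
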