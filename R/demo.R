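# End-to-end demonstration pipeline: exercises every stage on one
# configuration and writes all reports to a directory.

#' Run the end-to-end demonstration pipeline
#'
#' For each ploidy 1..3: simulates a genome and phased variants, a 1-cell
#' and a pooled library, calls and partitions variants, writes VCFs,
#' classifies ploidy from the allele frequency spectrum and runs the
#' shared-heterozygous-SNP analysis across the libraries. Then runs the
#' genome-recovery experiment on the haploid genome, the metabolic
#' deficiency screen on the packaged eight-target fixture, orthogroup
#' selection with supermatrix statistics on a generated cluster set, and
#' an ancestral gain/loss plus tree-congruence example. All reports are
#' written as TSV/VCF/BED/Newick under `out_dir`; re-running with the
#' same configuration reproduces identical report bytes.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-ploidy `ploidy_call`s, the
#'   sharing reports, the `recovery_report`, the `deficiency_report` and
#'   the selected cluster ids. An error is raised if any internal
#'   invariant fails.
#' @export
run_demo <- function(config = run_config(), out_dir = tempfile("sagkit_demo")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  amp <- amplification_model(covered_prob = config$covered_prob,
                             mean_tract_bp = config$mean_tract_bp,
                             gain_sigma = config$gain_sigma,
                             error_rate = config$error_rate,
                             mean_depth = config$mean_depth)
  ploidy_calls <- list()
  sharing <- list()
  summary_rows <- list()
  for (p in 1:3) {
    seed_p <- config$seed * 101L + p
    g <- simulate_genome(config$genome_length, config$gc, seed = seed_p)
    pc <- ploidy_config(p, het_rate = if (p == 1L) 0 else config$het_rate,
                        fixed_rate = config$fixed_rate)
    vars <- plant_variants(g, pc, seed = seed_p + 10L)
    libs <- lapply(seq_along(config$cell_counts), function(i)
      simulate_library(g, vars, cells = config$cell_counts[i], amp = amp,
                       seed = seed_p + 20L + i))
    callsets <- lapply(libs, call_variants, reference = g,
                       min_coverage = config$min_coverage,
                       min_alt_frac = config$min_alt_frac,
                       min_alt_reads = config$min_alt_reads)
    names(callsets) <- vapply(libs, `[[`, character(1), "library_id")
    for (i in seq_along(callsets))
      write_vcf(callsets[[i]],
                file.path(out_dir, sprintf("ploidy%d_%s.vcf", p,
                                           names(callsets)[i])))
    # classify from the deepest (last, most cells) library
    deep <- callsets[[length(callsets)]]
    parts <- partition_calls(deep, config$het_lower, config$het_upper,
                             config$fixed_min)
    spec <- af_spectrum(parts$het, config$bin_width)
    pcall <- classify_ploidy(spec, het_density(parts$het),
                             haploid_max_density = config$haploid_max_density,
                             peak_tol = config$peak_tol)
    ploidy_calls[[p]] <- pcall
    utils::write.table(
      data.frame(af_mid = spec$mids, count = spec$counts),
      file.path(out_dir, sprintf("ploidy%d_afs.tsv", p)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    sh <- shared_het_analysis(callsets, config$het_lower, config$het_upper,
                              config$fixed_min, config$min_shared_per_mb)
    sharing[[p]] <- sh
    summary_rows[[p]] <- data.frame(
      true_ploidy = p, label = pcall$label,
      het_per_mb = round(pcall$het_density, 2),
      peaks = paste(sprintf("%.3f", pcall$peak_positions), collapse = ";"),
      shared_multi = sh$multi_library_count,
      non_haploid_by_sharing = sh$non_haploid_by_sharing)
    if (p >= 2 && pcall$label == "haploid")
      stop("internal invariant failed: non-haploid simulation labelled haploid")
  }
  summary <- do.call(rbind, summary_rows)
  utils::write.table(summary, file.path(out_dir, "ploidy_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # recovery on a haploid genome
  g <- simulate_genome(config$genome_length, config$gc,
                       seed = config$seed * 101L + 7L)
  vars <- plant_variants(g, ploidy_config(1L, 0, config$fixed_rate),
                         seed = config$seed * 101L + 8L)
  n_mk <- min(config$n_markers,
              floor(config$genome_length / (2 * config$marker_len)))
  markers <- simulate_markers(config$genome_length, n_mk,
                              config$marker_len, config$recover_frac,
                              seed = config$seed * 101L + 9L)
  rec <- recovery_experiment(g, vars, amp, config$cell_counts, markers,
                             seed = config$seed * 101L + 30L,
                             min_depth = config$min_depth_mask)
  if (rec$union$completeness_pct <
      max(rec$libraries$completeness_pct) - 1e-9)
    stop("internal invariant failed: union completeness below a library")
  utils::write.table(rec$points, file.path(out_dir, "recovery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(g, file.path(out_dir, "genome.fasta"))

  # comparative screens
  screen <- deficiency_screen(fig_deficiency_fixture(),
                              core_frac = config$core_frac,
                              min_absent_targets = config$min_absent_targets)
  utils::write.table(screen, file.path(out_dir, "deficiency_screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  oc <- make_ortho_clusters(n_genomes = 12, n_clusters = 200,
                            seed = config$seed * 101L + 40L)
  sel <- select_single_copy_clusters(oc, max_missing = config$max_missing,
                                     min_taxa = config$min_taxa)
  roles <- stats::setNames(
    ifelse(seq_len(12) <= 4, "target", "other"), colnames(oc$counts))
  sm <- supermatrix_stats(oc, sel, roles)
  utils::write.table(sm$per_taxon, file.path(out_dir, "supermatrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tr <- ape::read.tree(text = "((((Ra,Mb),(Cp,Bh)),(Dc,(Pc,(Ts,Sp)))),(FL1,FL2));")
  pam <- fig_deficiency_fixture()
  sts <- pam$mat[c("Ra", "Mb", "Cp", "Bh", "Dc", "Pc", "Ts", "Sp"), ,
                 drop = FALSE]
  sts <- rbind(sts, FL1 = 1L, FL2 = 1L)
  anc <- fitch_ancestral(tr, sts)
  utils::write.table(anc$summary, file.path(out_dir, "ancestral.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(tr, file.path(out_dir, "demo_tree.nwk"))
  rfc <- rf_congruence(tr, tr, focal_taxon = "Ra")
  if (rfc$rf_distance != 0 || !rfc$congruent)
    stop("internal invariant failed: self-congruence")

  write_run_config(config, file.path(out_dir, "run_config.txt"))
  invisible(list(ploidy_calls = ploidy_calls, sharing = sharing,
                 recovery = rec, screen = screen, selected_clusters = sel,
                 ancestral = anc, out_dir = out_dir))
}
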