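# Ploidy classification and cross-library SNP sharing.

test_that("zero heterozygous calls classify as haploid", {
  s <- af_spectrum(callset_from_af(numeric(0)))
  pc <- classify_ploidy(s, density = 0)
  expect_equal(pc$label, "haploid")
})

test_that("simulated libraries classify to their true ploidy", {
  # desk-scale check (the full 20-replicate experiment runs in the
  # acceptance suite)
  amp <- amplification_model()
  labs <- character(0)
  for (p in 1:3) for (r in 1:3) {
    seed <- 400 + 10 * p + r
    g <- simulate_genome(1e5, 0.45, seed = seed)
    cfg <- ploidy_config(p, het_rate = if (p == 1) 0 else 0.005,
                         fixed_rate = 0.001)
    v <- plant_variants(g, cfg, seed = seed + 1)
    lib <- simulate_library(g, v, cells = 10, amp = amp, seed = seed + 2)
    pc <- ploidy_from_pileup(lib, g)
    labs <- c(labs, pc$label)
  }
  expect_equal(labs, rep(c("haploid", "diploid", "triploid"), each = 3))
})

test_that("triploid spectra yield peaks at 1/3 and 2/3, diploid at 1/2", {
  amp <- amplification_model()
  g <- simulate_genome(1e5, 0.45, seed = 500)
  v3 <- plant_variants(g, ploidy_config(3, 0.005, 0.001), seed = 501)
  lib3 <- simulate_library(g, v3, cells = 10, amp = amp, seed = 502)
  pk3 <- ploidy_from_pileup(lib3, g)$peak_positions
  expect_true(any(abs(pk3 - 1 / 3) <= 0.05))
  expect_true(any(abs(pk3 - 2 / 3) <= 0.05))

  v2 <- plant_variants(g, ploidy_config(2, 0.005, 0.001), seed = 503)
  lib2 <- simulate_library(g, v2, cells = 10, amp = amp, seed = 504)
  pk2 <- ploidy_from_pileup(lib2, g)$peak_positions
  expect_true(any(abs(pk2 - 0.5) <= 0.05))
})

test_that("conflicting AF patterns resolve to unknown, not a guess", {
  # synthetic spectrum with strong modes at 1/3, 1/2 and 2/3, the 1/2
  # mode dominant
  set.seed(5)
  af <- c(rnorm(300, 1 / 3, 0.02), rnorm(500, 0.5, 0.02),
          rnorm(300, 2 / 3, 0.02))
  af <- pmin(0.94, pmax(0.26, af))
  s <- af_spectrum(callset_from_af(af, pos0 = seq_along(af)))
  pc <- classify_ploidy(s, density = 1000)
  expect_equal(pc$label, "unknown")
})

test_that("pairwise shared heterozygous SNPs count (position, alt) matches", {
  a <- callset_from_af(rep(0.5, 2), pos0 = c(100L, 200L),
                       alt = c("C", "T"), callable_bases = 1e6)
  b <- callset_from_af(rep(0.5, 2), pos0 = c(200L, 300L),
                       alt = c("T", "G"), callable_bases = 1e6)
  rep_ <- shared_het_analysis(list(A = a, B = b))
  expect_equal(rep_$pairwise["A", "B"], 1L)
  expect_equal(rep_$multi_library_count, 1L)

  # identical sets of n calls share all n
  rep2 <- shared_het_analysis(list(A = a, B = a))
  expect_equal(rep2$pairwise["A", "B"], 2L)

  expect_error(shared_het_analysis(list(a)), "two call sets")
})

test_that("adding a call to both libraries never decreases shared counts", {
  set.seed(6)
  pos_pool <- sample.int(5000, 300)
  a_pos <- sort(sample(pos_pool, 100))
  b_pos <- sort(sample(pos_pool, 100))
  mk <- function(p) callset_from_af(rep(0.5, length(p)), pos0 = p,
                                    callable_bases = 1e6)
  base_rep <- shared_het_analysis(list(A = mk(a_pos), B = mk(b_pos)))
  newpos <- setdiff(pos_pool, union(a_pos, b_pos))[1]
  grown <- shared_het_analysis(list(A = mk(sort(c(a_pos, newpos))),
                                    B = mk(sort(c(b_pos, newpos)))))
  expect_true(all(grown$pairwise >= base_rep$pairwise))
  expect_gte(grown$multi_library_count, base_rep$multi_library_count)
})

test_that("two 1-cell libraries from one diploid individual share their het sites", {
  g <- simulate_genome(1e5, 0.45, seed = 600)
  v <- plant_variants(g, ploidy_config(2, het_rate = 0.005), seed = 601)
  amp <- amp_clean(mean_depth = 30)
  libs <- lapply(1:2, function(i)
    simulate_library(g, v, cells = 1, amp = amp, seed = 601 + i))
  hets <- lapply(libs, function(l)
    partition_calls(call_variants(l, g))$het)
  keys <- lapply(hets, function(h) paste(h$pos0, h$alt))
  # truth het sites with calling depth in BOTH libraries
  depths <- lapply(libs, pileup_depth)
  callable <- v$pos0[depths[[1]][v$pos0 + 1L] >= 5 &
                       depths[[2]][v$pos0 + 1L] >= 5]
  truth_keys <- paste(v$pos0, v$alt)[v$pos0 %in% callable]
  shared <- intersect(intersect(keys[[1]], keys[[2]]), truth_keys)
  expect_gte(length(shared) / length(truth_keys), 0.9)
})

test_that("isolate SNP recovery is the contained fraction", {
  iso <- callset_from_af(rep(0.5, 10), pos0 = (1:10) * 50L)
  lib_all <- iso
  expect_equal(isolate_recovery(iso, lib_all), 1.0)
  lib4 <- callset_from_af(rep(0.5, 4), pos0 = (1:4) * 50L)
  expect_equal(isolate_recovery(iso, lib4), 0.4)
  disj <- callset_from_af(rep(0.5, 3), pos0 = (1:3) * 7L)
  expect_equal(isolate_recovery(iso, disj), 0.0)
  expect_error(isolate_recovery(callset_from_af(numeric(0)), iso), "empty")
})

test_that("fixed-difference sharing gates genes on coverage and decomposes exclusively", {
  genes <- data.frame(gene = c("g1", "g2"), start = c(0L, 1000L),
                      end = c(500L, 1500L))
  # six fixed SNPs in g1 shared by L1 and L2; one unique to L3 in g2
  s16 <- (1:6) * 10L
  mk <- function(p) callset_from_af(rep(1, length(p)), pos0 = p)
  cov <- matrix(0.95, 3, 2, dimnames = list(c("L1", "L2", "L3"),
                                            c("g1", "g2")))
  out <- fixed_difference_sharing(
    list(L1 = mk(s16), L2 = mk(s16), L3 = mk(1100L)), genes, cov)
  expect_equal(out$n_snps[out$libraries == "L1+L2"], 6L)
  expect_equal(out$n_snps[out$libraries == "L3"], 1L)
  expect_equal(nrow(out), 2L)

  # a gene below 90% coverage in one library is excluded entirely
  cov2 <- cov; cov2["L2", "g1"] <- 0.85
  out2 <- fixed_difference_sharing(
    list(L1 = mk(s16), L2 = mk(s16), L3 = mk(1100L)), genes, cov2)
  expect_false("g1" %in% attr(out2, "genes_kept"))
  expect_equal(sum(out2$n_snps), 1L)

  # no fixed calls: empty table
  out3 <- fixed_difference_sharing(
    list(L1 = callset_from_af(0.5, pos0 = 10L)), genes,
    cov[1, , drop = FALSE])
  expect_equal(nrow(out3), 0L)

  expect_error(fixed_difference_sharing(list(L9 = mk(s16)), genes, cov),
               "coverage matrix")
})
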