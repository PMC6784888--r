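# Genome, variant and library generators: determinism, planted structure,
# and the sampling laws the downstream analyses rely on.

test_that("simulate_genome is deterministic, GC-targeted, and validates input", {
  g1 <- simulate_genome(8, gc = 0.5, seed = 1)
  g2 <- simulate_genome(8, gc = 0.5, seed = 1)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(nchar(g1$sequence), 8L)
  expect_true(grepl("^[ACGT]+$", g1$sequence))

  # binomial oracle: observed GC within 3 standard errors of the target
  g <- simulate_genome(1e5, gc = 0.25, seed = 7)
  obs_gc <- mean(g$codes %in% 2:3)
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_lt(abs(obs_gc - 0.25), 3 * se)

  expect_error(simulate_genome(0, gc = 0.5, seed = 1), "positive")
  expect_error(simulate_genome(100, gc = 1.2, seed = 1), "between 0 and 1")
  expect_error(simulate_genome(100, gc = 0, seed = 1), "between 0 and 1")
})

test_that("plant_variants respects ploidy structure and binomial site counts", {
  g <- simulate_genome(1e5, seed = 2)

  # haploid: no heterozygosity allowed, fixed sites carry every copy
  expect_error(ploidy_config(1, het_rate = 0.01), "haploid")
  v1 <- plant_variants(g, ploidy_config(1, 0, 0.001), seed = 3)
  expect_true(all(v1$alt_copies == 1L))

  # diploid: every heterozygous record has alt_copies 1 (expected AF 1/2)
  v2 <- plant_variants(g, ploidy_config(2, het_rate = 0.005), seed = 3)
  expect_true(all(v2$alt_copies == 1L))

  # triploid: het count ~ Binomial(L, rate); copies split near 50/50
  v3 <- plant_variants(g, ploidy_config(3, het_rate = 0.005,
                                        fixed_rate = 0.001), seed = 4)
  het <- v3[v3$alt_copies < 3L, ]
  se <- sqrt(1e5 * 0.005 * 0.995)
  expect_lt(abs(nrow(het) - 500), 3 * se)
  expect_true(all(het$alt_copies %in% 1:2))
  frac1 <- mean(het$alt_copies == 1L)
  expect_lt(abs(frac1 - 0.5), 3 * sqrt(0.25 / nrow(het)))
  expect_true(all(v3[v3$alt_copies == 3L, "alt_copies"] == 3L))

  # structural invariants
  expect_false(is.unsorted(v3$pos0, strictly = TRUE))
  expect_true(all(v3$ref != v3$alt))
  # phase mask carries exactly alt_copies bits
  bits <- vapply(v3$phase, function(p) sum(bitwAnd(p, c(1L, 2L, 4L)) > 0),
                 numeric(1))
  expect_equal(bits, as.numeric(v3$alt_copies))

  # determinism
  v3b <- plant_variants(g, ploidy_config(3, het_rate = 0.005,
                                         fixed_rate = 0.001), seed = 4)
  expect_identical(v3, v3b)
})

test_that("library simulation without dropout or error reproduces the genotype", {
  g <- simulate_genome(5000, seed = 5)
  v <- plant_variants(g, ploidy_config(2, het_rate = 0.01), seed = 6)
  lib <- simulate_library(g, v, cells = 2, amp = amp_clean(), seed = 7)
  d <- pileup_depth(lib)
  expect_true(all(d > 0))
  # only genotype-consistent alleles observed at every site
  vpos <- v$pos0 + 1L
  valt <- match(v$alt, c("A", "C", "G", "T"))
  for (i in seq_len(ncol(lib$counts))) {
    allowed <- g$codes[i]
    j <- match(i, vpos)
    if (!is.na(j)) allowed <- c(allowed, valt[j])
    expect_true(all(which(lib$counts[, i] > 0) %in% allowed))
  }
})

test_that("single-cell covered fraction matches the chain's stationary probability", {
  g <- simulate_genome(1e5, seed = 8)
  v <- plant_variants(g, ploidy_config(1), seed = 9)
  amp <- amplification_model(covered_prob = 0.7, mean_tract_bp = 500,
                             gain_sigma = 0, error_rate = 0)
  lib <- simulate_library(g, v, cells = 1, amp = amp, seed = 10)
  frac <- mean(pileup_depth(lib) > 0)
  # variance oracle for the mean of a stationary two-state Markov chain:
  # Var = pq/L * (1+lambda)/(1-lambda), lambda = 1 - 1/Lc - 1/Ld
  p <- 0.7; t <- 500
  Lc <- 2 * p * t; Ld <- 2 * (1 - p) * t
  lambda <- 1 - 1 / Lc - 1 / Ld
  se <- sqrt(p * (1 - p) / 1e5 * (1 + lambda) / (1 - lambda))
  expect_lt(abs(frac - p), 3 * se)
})

test_that("multi-cell union coverage follows the independence closed form", {
  g <- simulate_genome(1e5, seed = 11)
  v <- plant_variants(g, ploidy_config(1), seed = 12)
  amp <- amplification_model(covered_prob = 0.7, gain_sigma = 0,
                             error_rate = 0, independent_sites = TRUE)
  lib <- simulate_library(g, v, cells = 10, amp = amp, seed = 13)
  frac <- mean(pileup_depth(lib) > 0)
  expected <- 1 - 0.3^10
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("observed allele fractions concentrate at alt_copies/ploidy", {
  g <- simulate_genome(1e5, seed = 14)
  v <- plant_variants(g, ploidy_config(3, het_rate = 0.006), seed = 15)
  amp <- amplification_model(covered_prob = 1, error_rate = 0,
                             mean_depth = 30)
  lib <- simulate_library(g, v, cells = 10, amp = amp, seed = 16)
  het <- v[v$alt_copies < 3L, ]
  expect_gte(nrow(het), 500)
  d <- lib$counts[, het$pos0 + 1L, drop = FALSE]
  depth <- colSums(d)
  expect_true(all(depth >= 30))
  altc <- d[cbind(match(het$alt, c("A", "C", "G", "T")), seq_len(ncol(d)))]
  af <- altc / depth
  for (k in 1:2)
    expect_lt(abs(mean(af[het$alt_copies == k]) - k / 3), 0.02)
})

test_that("library simulation is reproducible and validates its inputs", {
  g <- simulate_genome(2000, seed = 17)
  v <- plant_variants(g, ploidy_config(2, het_rate = 0.01), seed = 18)
  amp <- amplification_model()
  l1 <- simulate_library(g, v, cells = 3, amp = amp, seed = 19)
  l2 <- simulate_library(g, v, cells = 3, amp = amp, seed = 19)
  expect_identical(l1$counts, l2$counts)
  expect_error(simulate_library(g, v, cells = 0, amp = amp, seed = 1),
               "cells")
  expect_error(amplification_model(covered_prob = 1.4), "covered_prob")
  expect_error(amplification_model(error_rate = 0.2), "error_rate")
})

test_that("ortho cluster generator honours copy and missing models", {
  # single-copy everywhere: every cluster passes the selection rule
  oc <- make_ortho_clusters(10, 50, p_extra_copy = 0, p_missing = 0,
                            seed = 20)
  expect_identical(select_single_copy_clusters(oc, max_missing = 0),
                   rownames(oc$counts))

  # exactly m missing per cluster: selection at max_missing = m-1 is empty
  oc2 <- make_ortho_clusters(10, 50, p_extra_copy = 0, exact_missing = 3,
                             seed = 21)
  expect_length(select_single_copy_clusters(oc2, max_missing = 2), 0)
  expect_identical(select_single_copy_clusters(oc2, max_missing = 3),
                   rownames(oc2$counts))

  # determinism
  oc3 <- make_ortho_clusters(10, 50, p_extra_copy = 0, exact_missing = 3,
                             seed = 21)
  expect_identical(oc2$counts, oc3$counts)
})

test_that("synthetic EC matrices apply the deficiency plan exactly", {
  spec <- ec_matrix_spec(n_free_living = 8, n_target = 8,
                         n_core_enzymes = 3, n_noncore = 2,
                         deficiency_plan = list(
                           core1 = sprintf("tg%02d", 1:5),
                           core2 = sprintf("tg%02d", c(2, 4))),
                         seed = 22)
  pam <- make_ec_matrix(spec)
  tg <- sprintf("tg%02d", 1:8)
  expect_equal(sum(pam$mat[tg, "core1"]), 3)    # 5 of 8 targets absent
  expect_equal(sum(pam$mat[tg, "core2"]), 6)
  expect_equal(sum(pam$mat[tg, "core3"]), 8)    # unplanned: all present
  expect_true(all(pam$mat[sprintf("fl%02d", 1:8), c("core1", "core2",
                                                    "core3")] == 1))
  # regeneration is byte-identical
  expect_identical(make_ec_matrix(spec)$mat, pam$mat)
  # invalid plan rejected
  expect_error(ec_matrix_spec(4, 2, 1,
                              deficiency_plan = list(core1 = "tg09"),
                              seed = 1), "undeclared")
})
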