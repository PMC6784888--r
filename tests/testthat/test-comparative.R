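# Deficiency screen, ratio regression, orthogroup selection and
# supermatrix statistics.

test_that("the packaged deficiency fixture matches the per-enzyme statements", {
  pam <- fig_deficiency_fixture()
  tg <- names(pam$roles)[pam$roles == "target"]
  expect_length(tg, 8)
  expect_equal(sum(pam$roles == "free_living"), 24)

  present <- function(ec) tg[pam$mat[tg, ec] == 1]
  expect_equal(sum(pam$mat[tg, "EC 2.3.3.1"]), 8)           # all targets
  expect_setequal(present("EC 2.5.1.3"), "Bh")
  expect_setequal(present("EC 2.7.1.50"), "Bh")
  expect_setequal(present("EC 6.3.4.15"), c("Mb", "Ra", "Sp"))
  expect_setequal(present("EC 2.7.7.4"), c("Ra", "Mb"))
  expect_setequal(present("EC 1.8.4.8"), "Mb")
  expect_setequal(present("EC 2.8.1.6"), c("Mb", "Bh"))
  expect_setequal(present("EC 2.3.3.8"), c("Cp", "Bh"))
})

test_that("deficiency screen applies the core and absence rules", {
  scr <- deficiency_screen(fig_deficiency_fixture())
  expect_equal(attr(scr, "core_threshold"), 18)  # ceil(0.75 * 24)
  expect_true(all(scr$core))
  expect_false(scr$deficiency[scr$fun == "EC 2.3.3.1"])
  expect_true(scr$deficiency[scr$fun == "EC 2.5.1.3"])
  expect_equal(sum(scr$deficiency), 9)

  # toy: 4 free-living (core needs >= 3), 3 targets, min_absent 2
  mat <- matrix(1L, 7, 2, dimnames = list(
    c(paste0("f", 1:4), paste0("t", 1:3)), c("e_core", "e_rare")))
  mat["f4", "e_core"] <- 0L
  mat[c("t1", "t2"), "e_core"] <- 0L
  mat[c("f2", "f3", "f4"), "e_rare"] <- 0L
  mat[c("t1", "t2", "t3"), "e_rare"] <- 0L
  roles <- setNames(c(rep("free_living", 4), rep("target", 3)),
                    rownames(mat))
  scr2 <- deficiency_screen(presence_absence_matrix(mat, roles),
                            min_absent_targets = 2)
  expect_true(scr2$deficiency[scr2$fun == "e_core"])   # 3 FL, 2 absent
  expect_false(scr2$core[scr2$fun == "e_rare"])        # 1 FL < 3
  expect_false(scr2$deficiency[scr2$fun == "e_rare"])
})

test_that("deficiency screen equals an independent double-loop filter on random matrices", {
  set.seed(9)
  for (rep_i in 1:25) {
    n_fl <- sample(4:10, 1); n_tg <- sample(3:8, 1); n_e <- sample(2:8, 1)
    mat <- matrix(rbinom(n_e * (n_fl + n_tg), 1, 0.6), n_fl + n_tg, n_e,
                  dimnames = list(c(sprintf("f%d", 1:n_fl),
                                    sprintf("t%d", 1:n_tg)),
                                  sprintf("e%d", 1:n_e)))
    roles <- setNames(c(rep("free_living", n_fl), rep("target", n_tg)),
                      rownames(mat))
    cf <- runif(1, 0.5, 0.9); ma <- sample(1:3, 1)
    scr <- deficiency_screen(presence_absence_matrix(mat, roles),
                             core_frac = cf, min_absent_targets = ma)
    for (e in colnames(mat)) {
      n_pres <- 0; n_abs <- 0
      for (sp in rownames(mat)) {
        if (roles[sp] == "free_living" && mat[sp, e] == 1) n_pres <- n_pres + 1
        if (roles[sp] == "target" && mat[sp, e] == 0) n_abs <- n_abs + 1
      }
      core_o <- n_pres >= ceiling(cf * n_fl)
      expect_equal(scr$core[scr$fun == e], core_o)
      expect_equal(scr$deficiency[scr$fun == e], core_o && n_abs >= ma)
    }
  }
})

test_that("ratio regression matches hand OLS and applies exclusion rules", {
  d <- data.frame(species = paste0("s", 1:3),
                  proteases = c(10, 20, 30), cazymes = c(20, 40, 60),
                  lifestyle = "mycoparasite")
  # exact collinear toy data: summary.lm warns about the perfect fit
  rr <- suppressWarnings(ratio_regression(d))
  expect_equal(rr$slope, 2.0, tolerance = 1e-12)
  expect_equal(rr$intercept, 0.0, tolerance = 1e-10)
  expect_equal(rr$r_squared, 1.0, tolerance = 1e-12)
  expect_true(rr$included)

  # lifestyle with 2 species is excluded by count
  d2 <- rbind(d, data.frame(species = c("m1", "m2"),
                            proteases = c(5, 9), cazymes = c(7, 11),
                            lifestyle = "mycorrhizal"))
  rr2 <- suppressWarnings(ratio_regression(d2))
  expect_false(rr2$included[rr2$lifestyle == "mycorrhizal"])
  expect_true(is.na(rr2$slope[rr2$lifestyle == "mycorrhizal"]))

  # noisy points with low r-squared are excluded by fit quality
  set.seed(10)
  d3 <- data.frame(species = paste0("x", 1:12),
                   proteases = 1:12, cazymes = rnorm(12, 50, 20),
                   lifestyle = "saprotroph")
  rr3 <- ratio_regression(d3, min_r2 = 0.3)
  expect_lt(rr3$r_squared, 0.3)
  expect_false(rr3$included)

  expect_error(ratio_regression(
    data.frame(species = paste0("z", 1:3), proteases = c(4, 4, 4),
               cazymes = 1:3, lifestyle = "l")), "zero-variance")
})

test_that("OLS coefficients agree with the normal equations to 1e-9", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(4:30, 1)
    x <- rpois(n, 40); y <- 2.5 * x + rnorm(n, 0, 10)
    if (sd(x) == 0) next
    d <- data.frame(species = paste0("s", 1:n), proteases = x,
                    cazymes = y, lifestyle = "L")
    rr <- ratio_regression(d, min_r2 = 0)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(rr$intercept, beta[1], tolerance = 1e-9)
    expect_equal(rr$slope, beta[2], tolerance = 1e-9)
    res <- y - X %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    expect_equal(rr$r_squared, r2, tolerance = 1e-9)
  }
})

test_that("single-copy cluster selection follows the three rules", {
  counts <- rbind(cluster1 = c(A = 1, B = 1, C = 1, D = 0),
                  cluster2 = c(A = 2, B = 1, C = 1, D = 1),
                  cluster3 = c(A = 1, B = 1, C = 1, D = 1),
                  cluster4 = c(A = 1, B = 1, C = 0, D = 0))
  oc <- ortho_clusters(counts)
  expect_equal(select_single_copy_clusters(oc, max_missing = 1),
               c("cluster1", "cluster3"))
  # multi-copy genome disqualifies; full single-copy always selected
  expect_equal(select_single_copy_clusters(oc, max_missing = 0), "cluster3")
  # min_taxa floor
  expect_false("cluster4" %in%
                 select_single_copy_clusters(oc, max_missing = 2,
                                             min_taxa = 3))
  expect_error(select_single_copy_clusters(oc, max_missing = 4),
               "panel size")
})

test_that("cluster selection equals brute force on a 1,000-cluster instance", {
  oc <- make_ortho_clusters(n_genomes = 14, n_clusters = 1000,
                            p_extra_copy = 0.15, p_missing = 0.3,
                            seed = 60)
  sel <- select_single_copy_clusters(oc, max_missing = 8, min_taxa = 3)
  brute <- character(0)
  for (cl in rownames(oc$counts)) {
    row <- oc$counts[cl, ]
    ok <- TRUE
    n_present <- 0
    for (v in row) {
      if (v > 1) ok <- FALSE
      if (v > 0) n_present <- n_present + 1
    }
    if (ok && (14 - n_present) <= 8 && n_present >= 3)
      brute <- c(brute, cl)
  }
  expect_identical(sel, brute)
})

test_that("supermatrix missing fractions are length-weighted", {
  counts <- rbind(c1 = c(X = 1, Y = 1, Z = 1), c2 = c(X = 0, Y = 1, Z = 1))
  oc <- ortho_clusters(counts, lengths = c(100, 50))
  sm <- supermatrix_stats(oc, groups = c(X = "target", Y = "other",
                                         Z = "other"))
  expect_equal(sm$per_taxon$missing_frac[sm$per_taxon$taxon == "X"],
               50 / 150)
  expect_equal(sm$per_taxon$missing_frac[sm$per_taxon$taxon == "Y"], 0)
  expect_equal(unname(sm$group_medians["target"]), 1 / 3)
  expect_equal(unname(sm$group_medians["other"]), 0)

  # taxon in no selected cluster is fully missing
  counts2 <- rbind(c1 = c(X = 0, Y = 1), c2 = c(X = 0, Y = 1))
  sm2 <- supermatrix_stats(ortho_clusters(counts2, lengths = c(10, 20)))
  expect_equal(sm2$per_taxon$missing_frac, c(1, 0))

  expect_error(supermatrix_stats(ortho_clusters(counts)), "lengths")
})
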