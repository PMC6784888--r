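# Synthetic enzyme presence/absence matrices and the transcribed
# eight-target metabolic deficiency fixture.

#' Specification for a synthetic presence/absence matrix
#'
#' @param n_free_living,n_target Panel sizes (>= 0).
#' @param n_core_enzymes Enzymes present in (almost) all free-living
#'   species.
#' @param n_noncore Enzymes present in fewer free-living species than the
#'   core threshold.
#' @param deficiency_plan Named list: per core enzyme, the character
#'   vector of target species lacking it. Names must be a subset of the
#'   core enzyme labels (`core1..coreN`), values subsets of the target
#'   labels (`tg01..`).
#' @param core_dropout Number of free-living species a core enzyme is
#'   randomly absent from (default 0; kept below the 25% slack of the
#'   default core rule).
#' @param noncore_presence Fraction of free-living species carrying a
#'   non-core enzyme (default 0.25).
#' @param seed Integer seed.
#' @return An `ec_matrix_spec`.
#' @export
ec_matrix_spec <- function(n_free_living, n_target, n_core_enzymes,
                           n_noncore = 0L, deficiency_plan = list(),
                           core_dropout = 0L, noncore_presence = 0.25,
                           seed) {
  if (missing(seed)) stop("`seed` is required")
  stopifnot(n_free_living >= 0, n_target >= 0, n_core_enzymes >= 0,
            n_noncore >= 0, core_dropout >= 0)
  targets <- sprintf("tg%02d", seq_len(n_target))
  core <- sprintf("core%d", seq_len(n_core_enzymes))
  if (length(deficiency_plan)) {
    if (!all(names(deficiency_plan) %in% core))
      stop("deficiency_plan names must be core enzyme labels")
    if (!all(unlist(deficiency_plan) %in% targets))
      stop("deficiency_plan references undeclared target species")
  }
  structure(list(n_free_living = as.integer(n_free_living),
                 n_target = as.integer(n_target),
                 n_core_enzymes = as.integer(n_core_enzymes),
                 n_noncore = as.integer(n_noncore),
                 deficiency_plan = deficiency_plan,
                 core_dropout = as.integer(core_dropout),
                 noncore_presence = noncore_presence,
                 seed = as.integer(seed)),
            class = "ec_matrix_spec")
}

#' Build a presence/absence matrix from a specification
#'
#' Core enzymes are present in all free-living species except a random
#' `core_dropout`; the deficiency plan is applied exactly to target
#' species (unplanned targets keep the enzyme); non-core enzymes are
#' present in `noncore_presence` of free-living species and in all
#' targets. Byte-identical under the same spec.
#'
#' @param spec An [ec_matrix_spec()].
#' @return A [presence_absence_matrix()].
#' @export
make_ec_matrix <- function(spec) {
  stopifnot(inherits(spec, "ec_matrix_spec"))
  set.seed(spec$seed)
  fl <- sprintf("fl%02d", seq_len(spec$n_free_living))
  tg <- sprintf("tg%02d", seq_len(spec$n_target))
  core <- sprintf("core%d", seq_len(spec$n_core_enzymes))
  noncore <- sprintf("noncore%d", seq_len(spec$n_noncore))
  species <- c(fl, tg)
  funs <- c(core, noncore)
  mat <- matrix(1L, length(species), max(1L, length(funs)),
                dimnames = list(species, if (length(funs)) funs else "none"))
  if (!length(funs)) mat <- mat[, 0, drop = FALSE]
  for (e in core) {
    if (spec$core_dropout > 0 && length(fl))
      mat[sample(fl, min(spec$core_dropout, length(fl))), e] <- 0L
    absent <- spec$deficiency_plan[[e]]
    if (!is.null(absent)) mat[absent, e] <- 0L
  }
  for (e in noncore) {
    if (length(fl)) {
      k <- round(spec$noncore_presence * length(fl))
      mat[fl, e] <- 0L
      if (k > 0) mat[sample(fl, k), e] <- 1L
    }
  }
  roles <- stats::setNames(c(rep("free_living", length(fl)),
                             rep("target", length(tg))), species)
  presence_absence_matrix(mat, roles)
}

#' Eight-target metabolic deficiency fixture
#'
#' The transcribed presence/absence pattern of ten enzyme classifications
#' across the eight uncultured target fungi (Ra *R. allomycis*, Bh
#' *B. helicus*, Cp *C. protostelioides*, Dc *D. cristalligena*, Pc
#' *P. cylindrospora*, Ts *T. sphaerospora*, Sp *S. pseudoplumigaleata*,
#' Mb *M. bicuspidata*), with a 24-species free-living panel in which all
#' ten enzymes are core:
#' sulfate assimilation (EC 2.7.7.4, EC 2.7.1.25 present only in Ra and
#' Mb; EC 1.8.4.8, EC 1.8.1.2 only in Mb), biotin metabolism (EC 2.8.1.6
#' only in Mb and Bh; EC 6.3.4.15 only in Mb, Ra and Sp), thiamine
#' phosphate biosynthesis (EC 2.5.1.3, EC 2.7.1.50 only in Bh), citrate
#' synthase (EC 2.3.3.1, in all eight) and ATP citrate synthase
#' (EC 2.3.3.8, only in the chytrids Cp and Bh).
#'
#' @return A [presence_absence_matrix()] of 32 species x 10 enzymes.
#' @export
fig_deficiency_fixture <- function() {
  targets <- c("Ra", "Bh", "Cp", "Dc", "Pc", "Ts", "Sp", "Mb")
  present <- list(
    "EC 2.7.7.4"  = c("Ra", "Mb"),
    "EC 2.7.1.25" = c("Ra", "Mb"),
    "EC 1.8.4.8"  = "Mb",
    "EC 1.8.1.2"  = "Mb",
    "EC 2.8.1.6"  = c("Mb", "Bh"),
    "EC 6.3.4.15" = c("Mb", "Ra", "Sp"),
    "EC 2.5.1.3"  = "Bh",
    "EC 2.7.1.50" = "Bh",
    "EC 2.3.3.1"  = targets,
    "EC 2.3.3.8"  = c("Cp", "Bh"))
  fl <- sprintf("FL%02d", 1:24)
  species <- c(fl, targets)
  mat <- matrix(0L, length(species), length(present),
                dimnames = list(species, names(present)))
  mat[fl, ] <- 1L  # every enzyme is core in the free-living panel
  for (e in names(present)) mat[present[[e]], e] <- 1L
  roles <- stats::setNames(c(rep("free_living", length(fl)),
                             rep("target", length(targets))), species)
  presence_absence_matrix(mat, roles)
}
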