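# Comparative screens: core-metabolism deficiency filter and
# CAZyme-to-protease ratio regression.

#' Species-by-enzyme presence/absence matrix
#'
#' @param mat Binary matrix, species in rows, functions (EC numbers) in
#'   columns, with complete dimnames.
#' @param roles Character vector named by species with values
#'   `"free_living"` or `"target"`, covering every row of `mat`.
#' @return A `presence_absence_matrix`.
#' @export
presence_absence_matrix <- function(mat, roles) {
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("`mat` needs species rownames and function colnames")
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("species and function labels must be unique")
  if (!all(mat %in% c(0, 1))) stop("`mat` must be strictly binary")
  if (!all(rownames(mat) %in% names(roles)))
    stop("every species needs a role")
  roles <- roles[rownames(mat)]
  if (!all(roles %in% c("free_living", "target")))
    stop("roles must be 'free_living' or 'target'")
  structure(list(mat = matrix(as.integer(mat), nrow = nrow(mat),
                              dimnames = dimnames(mat)),
                 roles = roles),
            class = "presence_absence_matrix")
}

#' @export
print.presence_absence_matrix <- function(x, ...) {
  cat(sprintf("<presence_absence_matrix> %d species (%d free-living, %d target) x %d functions\n",
              nrow(x$mat), sum(x$roles == "free_living"),
              sum(x$roles == "target"), ncol(x$mat)))
  invisible(x)
}

#' Core-metabolism deficiency screen
#'
#' An enzyme is *core* when present in at least `ceiling(core_frac *
#' n_free_living)` free-living species (with the default 0.75 and a
#' 24-species free-living panel the threshold is exactly 18), and a
#' *deficiency* when additionally absent from at least
#' `min_absent_targets` target species. Requiring recurrence of the
#' absence across targets guards against single-genome false negatives
#' from incomplete single-cell assemblies.
#'
#' @param pam A [presence_absence_matrix()] with both roles non-empty.
#' @param core_frac Free-living presence fraction defining core
#'   (default 0.75).
#' @param min_absent_targets Minimum target absences to flag
#'   (default 5).
#' @return A `deficiency_report` data frame: one row per function with
#'   `fl_present`, `target_absent`, `core`, `deficiency`; attribute
#'   `core_threshold`.
#' @export
deficiency_screen <- function(pam, core_frac = 0.75, min_absent_targets = 5L) {
  stopifnot(inherits(pam, "presence_absence_matrix"))
  fl <- names(pam$roles)[pam$roles == "free_living"]
  tg <- names(pam$roles)[pam$roles == "target"]
  if (!length(fl) || !length(tg)) stop("both role classes must be non-empty")
  fl_present <- colSums(pam$mat[fl, , drop = FALSE])
  target_absent <- length(tg) - colSums(pam$mat[tg, , drop = FALSE])
  thr <- ceiling(core_frac * length(fl))
  core <- fl_present >= thr
  deficiency <- core & target_absent >= min_absent_targets
  out <- data.frame(fun = colnames(pam$mat),
                    fl_present = as.integer(fl_present),
                    target_absent = as.integer(target_absent),
                    core = unname(core), deficiency = unname(deficiency),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "core_threshold") <- thr
  attr(out, "n_free_living") <- length(fl)
  attr(out, "n_target") <- length(tg)
  class(out) <- c("deficiency_report", "data.frame")
  out
}

#' CAZyme-to-protease ratio regression per lifestyle
#'
#' Ordinary least squares of total CAZyme counts on total protease counts
#' within each lifestyle (via `stats::lm`). A lifestyle's trend line is
#' excluded when it has fewer than `min_n` species or its fit's r-squared
#' falls below `min_r2`.
#'
#' @param counts Data frame with columns `species`, `cazymes`,
#'   `proteases`, `lifestyle` (counts >= 0).
#' @param min_n Minimum species per included lifestyle (default 3).
#' @param min_r2 Minimum r-squared per included lifestyle (default 0.3).
#' @return A `ratio_regression` data frame: per lifestyle `n`, `slope`,
#'   `intercept`, `r_squared`, `included`.
#' @export
ratio_regression <- function(counts, min_n = 3L, min_r2 = 0.3) {
  stopifnot(all(c("species", "cazymes", "proteases", "lifestyle") %in%
                  names(counts)))
  if (any(counts$cazymes < 0) || any(counts$proteases < 0))
    stop("counts must be non-negative")
  out <- do.call(rbind, lapply(split(counts, counts$lifestyle), function(d) {
    n <- nrow(d)
    if (n < min_n)
      return(data.frame(lifestyle = d$lifestyle[1], n = n,
                        slope = NA_real_, intercept = NA_real_,
                        r_squared = NA_real_, included = FALSE))
    if (stats::sd(d$proteases) == 0)
      stop(sprintf("zero-variance protease counts in lifestyle '%s'",
                   d$lifestyle[1]))
    fit <- stats::lm(cazymes ~ proteases, data = d)
    r2 <- summary(fit)$r.squared
    data.frame(lifestyle = d$lifestyle[1], n = n,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, included = r2 >= min_r2)
  }))
  rownames(out) <- NULL
  class(out) <- c("ratio_regression", "data.frame")
  out
}
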