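# Readers and writers: FASTA, pileup TSV, minimal VCF, BED masks, Newick,
# key-value configuration. Internal coordinates are 0-based half-open;
# VCF positions are written 1-based.

#' Write sequences as FASTA
#'
#' @param x A `genome_model`, a named character vector, or a
#'   `DNAStringSet`.
#' @param path Output file.
#' @param name Sequence name used for a `genome_model` (default
#'   `"genome"`).
#' @export
write_fasta <- function(x, path, name = "genome") {
  if (inherits(x, "genome_model"))
    x <- stats::setNames(x$sequence, name)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x <- Biostrings::DNAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write a pileup as TSV
#'
#' Columns: contig, pos0 (0-based), depth_A, depth_C, depth_G, depth_T.
#'
#' @param pileup A `library_pileup`.
#' @param path Output file.
#' @param contig Contig name.
#' @export
write_pileup <- function(pileup, path, contig = "chr1") {
  stopifnot(inherits(pileup, "library_pileup"))
  df <- data.frame(contig = contig,
                   pos0 = seq_len(pileup$genome_length) - 1L,
                   depth_A = pileup$counts[1L, ],
                   depth_C = pileup$counts[2L, ],
                   depth_G = pileup$counts[3L, ],
                   depth_T = pileup$counts[4L, ])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV
#' @param path TSV written by [write_pileup()].
#' @param cells Cell count metadata (unknown from the file itself).
#' @return A `library_pileup`.
#' @export
read_pileup <- function(path, cells = NA_integer_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("pos0", "depth_A", "depth_C", "depth_G", "depth_T") %in%
                  names(df)))
  df <- df[order(df$pos0), ]
  counts <- t(as.matrix(df[, c("depth_A", "depth_C", "depth_G", "depth_T")]))
  dimnames(counts) <- list(DNA_BASES, NULL)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, cells = cells, amp = NULL,
                 genome_length = ncol(counts),
                 library_id = basename(path), seed = NA_integer_),
            class = "library_pileup")
}

#' Write variant calls as minimal VCF v4.2
#'
#' Pooled-frequency dialect: columns CHROM..INFO only (no genotypes),
#' INFO fields DP (depth), AO (alternate observations), AF (alternate
#' fraction). Internal 0-based positions are written 1-based.
#'
#' @param calls A `variant_callset`.
#' @param path Output file.
#' @param contig Contig name.
#' @export
write_vcf <- function(calls, path, contig = "chr1") {
  stopifnot(inherits(calls, "variant_callset"))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", contig),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate allele observations\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alternate allele frequency\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  rows <- if (nrow(calls))
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AO=%d;AF=%.6g",
            contig, calls$pos0 + 1L, calls$ref, calls$alt, calls$depth,
            calls$alt_count, calls$af)
  else character(0)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a minimal VCF
#'
#' Parses the dialect of [write_vcf()]; AF is recomputed as AO/DP so the
#' round trip is exact.
#'
#' @param path VCF file.
#' @return A `variant_callset` (positions back to 0-based).
#' @export
read_vcf <- function(path) {
  ln <- readLines(path)
  body <- ln[!startsWith(ln, "#")]
  if (!length(body))
    return(variant_callset(integer(0), character(0), character(0),
                           integer(0), integer(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  get_info <- function(info, key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  pos1 <- as.integer(vapply(f, `[[`, character(1), 2L))
  info <- vapply(f, `[[`, character(1), 8L)
  dp <- as.integer(vapply(info, get_info, numeric(1), "DP"))
  ao <- as.integer(vapply(info, get_info, numeric(1), "AO"))
  variant_callset(pos0 = pos1 - 1L,
                  ref = vapply(f, `[[`, character(1), 4L),
                  alt = vapply(f, `[[`, character(1), 5L),
                  depth = dp, alt_count = ao,
                  library_id = basename(path))
}

#' Write a coverage mask as BED
#'
#' Covered runs become 0-based half-open BED intervals.
#'
#' @param mask A `coverage_mask`.
#' @param path Output file.
#' @param contig Contig name.
#' @export
write_mask_bed <- function(mask, path, contig = "chr1") {
  stopifnot(inherits(mask, "coverage_mask"))
  r <- rle(mask$covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  df <- data.frame(contig = contig, start = starts[keep], end = ends[keep])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED coverage mask
#' @param path BED file of covered intervals.
#' @param genome_length Mask length.
#' @param min_depth Metadata only.
#' @return A `coverage_mask`.
#' @export
read_mask_bed <- function(path, genome_length, min_depth = NA_integer_) {
  covered <- rep(FALSE, genome_length)
  if (file.size(path) > 0) {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    for (i in seq_len(nrow(df)))
      covered[(df[i, 2L] + 1L):df[i, 3L]] <- TRUE
  }
  coverage_mask(covered, min_depth = min_depth, library_id = basename(path))
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()] so every
#' tree in the toolkit goes through one code path.
#'
#' @param path Newick file.
#' @return `read_newick`: a `phylo` (or `multiPhylo`) object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Filter scaffolds by minimum length
#'
#' Removes scaffolds shorter than `min_len` (scaffolds of exactly
#' `min_len` are retained), preserving input order. Short single-cell
#' scaffolds are phylogenetically ambiguous and are dropped before
#' comparative analysis.
#'
#' @param records A `DNAStringSet` or character vector of sequences.
#' @param min_len Minimum length in bp (default 2000).
#' @return The retained records, same class as the input.
#' @export
filter_scaffolds <- function(records, min_len = 2000L) {
  if (min_len < 0) stop("`min_len` must be >= 0")
  w <- if (inherits(records, "XStringSet")) Biostrings::width(records)
       else nchar(records)
  records[w >= min_len]
}
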