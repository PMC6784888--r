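# Shared builders for tests. Everything is generated in code; no stored
# fixtures.

# Uniform amplification: full coverage, no gain spread, no error.
amp_clean <- function(mean_depth = 30) {
  amplification_model(covered_prob = 1, gain_sigma = 0, error_rate = 0,
                      mean_depth = mean_depth)
}

# Build a call set directly from allele frequencies at given depth.
callset_from_af <- function(af, depth = 100L, pos0 = seq_along(af) * 10L,
                            alt = "T", ref = "A", ...) {
  variant_callset(pos0 = pos0, ref = rep(ref, length(af)),
                  alt = rep(alt, length.out = length(af)),
                  depth = rep(depth, length(af)),
                  alt_count = as.integer(round(af * depth)), ...)
}

# Build a pileup object from a depth-by-base count matrix (4 x L).
pileup_from_counts <- function(counts, cells = 1L, library_id = "test") {
  rownames(counts) <- c("A", "C", "G", "T")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, cells = cells, amp = NULL,
                 genome_length = ncol(counts), library_id = library_id,
                 seed = NA_integer_),
            class = "library_pileup")
}

# Random rooted binary tree with n tips labelled t1..tn.
random_rooted_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, tip.label = sprintf("t%d", seq_len(n)))
  tr$edge.length <- NULL
  tr
}

# Exhaustive small-parsimony minimum over all internal labellings.
brute_force_parsimony <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  x <- states[tree$tip.label]
  best <- Inf
  for (code in 0:(2^nint - 1)) {
    lab <- c(x, as.integer(intToBits(code))[seq_len(nint)])
    ch <- sum(lab[tree$edge[, 1L]] != lab[tree$edge[, 2L]])
    best <- min(best, ch)
  }
  best
}

# Brute-force nontrivial bipartitions of an unrooted tree as a set of
# canonical strings (side not containing the alphabetically first tip).
brute_force_bipartitions <- function(tree) {
  tu <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  tips <- sort(tu$tip.label)
  ref <- tips[1L]
  ntip <- length(tu$tip.label)
  out <- character(0)
  for (nd in (ntip + 1L):(ntip + tu$Nnode)) {
    below <- tu$tip.label[unlist(lapply(seq_len(ntip), function(i) {
      # walk from tip to root collecting ancestors
      p <- i
      repeat {
        e <- which(tu$edge[, 2L] == p)
        if (!length(e)) return(FALSE)
        p <- tu$edge[e, 1L]
        if (p == nd) return(TRUE)
      }
    }))]
    s <- below
    if (ref %in% s) s <- setdiff(tips, s)
    if (length(s) >= 2L && length(s) <= length(tips) - 2L)
      out <- c(out, paste(sort(s), collapse = "|"))
  }
  unique(out)
}
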