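# Independent brute-force oracles and small fixture builders used across
# the suite. Everything is generated in code; no stored fixtures.

# Brute-force restriction-digest oracle: literally builds the bottom strand
# as its own 5'->3' string, locates recognition occurrences on both strand
# strings, cuts each strand string at the enzyme's offsets, and maps the
# resulting 3' termini back to top-strand coordinates.
#
# Base-pairing diagram used for the cut rules (top coordinates t, site
# start s, pattern length Lp):
#   top strand cut between offsets top_cut and top_cut+1
#     -> the fragment 5' of the cut ends 3' at t = s + top_cut - 1.
#   bottom strand runs antiparallel; its cut lies between top coordinates
#   s + bottom_cut - 1 and s + bottom_cut, and the bottom-strand fragment
#   on the RIGHT of the cut points 3' leftward, terminating at
#   t = s + bottom_cut.
# For occurrences found on the bottom-strand string the same rules apply in
# bottom coordinates b, converted back via t = L - b + 1.
oracle_enzyme_ends <- function(genome_chr, enz) {
  g <- as.character(genome_chr)
  L <- nchar(g)
  bottom <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(g))
  )
  pat <- Biostrings::DNAString(enz$recognition)
  hits_top <- BiocGenerics::start(
    Biostrings::matchPattern(pat, Biostrings::DNAString(g), fixed = FALSE)
  )
  hits_bot <- BiocGenerics::start(
    Biostrings::matchPattern(pat, Biostrings::DNAString(bottom), fixed = FALSE)
  )
  out <- data.frame(pos = integer(), strand = character())
  for (s in hits_top) {
    out <- rbind(out, data.frame(
      pos = c(s + enz$top_cut - 1L, s + enz$bottom_cut),
      strand = c("+", "-")
    ))
  }
  for (b in hits_bot) {
    # termini in bottom coordinates, then mirrored to top coordinates;
    # the strand labels swap with the mirror
    out <- rbind(out, data.frame(
      pos = c(L - (b + enz$top_cut - 1L) + 1L, L - (b + enz$bottom_cut) + 1L),
      strand = c("-", "+")
    ))
  }
  unique(out[order(out$pos, out$strand), , drop = FALSE])
}

# Brute-force deduplication oracle: the retained key SET is the set of
# distinct (rname, pos, strand, umi) tuples.
oracle_dedup_keys <- function(aln, umi) {
  unique(paste(aln$rname, aln$pos, aln$strand, umi, sep = "\r"))
}

# Random alignment-record generator for dedup tests: n_mol molecules, each
# amplified `dup` times (shared UMI/key), shuffled.
random_alignment_records <- function(n_mol, dup = 1L, genome_length = 1e5,
                                     chroms = c("chr1", "chr2"), seed = 1L) {
  set.seed(seed)
  mol <- data.frame(
    rname = sample(chroms, n_mol, replace = TRUE),
    pos = sample.int(genome_length, n_mol, replace = TRUE),
    strand = sample(c("+", "-"), n_mol, replace = TRUE),
    umi = traelr:::random_dna(n_mol, 8L),
    stringsAsFactors = FALSE
  )
  idx <- sample(rep(seq_len(n_mol), each = dup))
  rec <- mol[idx, , drop = FALSE]
  rec$qname <- sprintf("r%06d:%s", seq_len(nrow(rec)), rec$umi)
  rec$width <- 40L
  rec$mapped <- TRUE
  rownames(rec) <- NULL
  rec
}

# Small uniform end set for pipeline tests.
uniform_ends <- function(n, genome_length, seed, margin = 100L) {
  set.seed(seed)
  data.frame(
    chrom = "chr1",
    pos = sample(seq.int(margin, genome_length - margin), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Poisson per-base track on one contig, split between strands.
poisson_track <- function(L, lambda, seed) {
  set.seed(seed)
  track_from_counts(list(chr1 = list(
    F = rpois(L, lambda / 2),
    R = rpois(L, lambda / 2)
  )))
}
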