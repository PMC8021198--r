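#' Plant restriction sites in a random genome
#'
#' Overwrites evenly spaced (jittered) positions of a random genome with a
#' fixed site sequence, leaving room at contig ends for full-length reads.
#'
#' @param genome_length Contig length.
#' @param site Site sequence to plant.
#' @param n_sites Number of copies.
#' @param seed Integer seed.
#' @param margin Minimum distance of a site from either contig end.
#' @return list: `genome` (DNAStringSet), `site_starts` (1-based).
#' @export
plant_sites <- function(genome_length, site, n_sites, seed = 1L,
                        margin = 1000L) {
  w <- nchar(site)
  stopifnot(genome_length > 2 * margin + n_sites * (w + 100L))
  base <- floor(seq(margin, genome_length - margin - w,
                    length.out = n_sites))
  gap <- min(diff(base))
  starts <- with_seed(seed, {
    as.integer(base + floor(runif(n_sites, 0, max(1, gap - w - 50L))))
  })
  g <- random_genome(genome_length, seed = seed + 1L)
  x <- as.character(g[[1L]])
  for (s in starts) substr(x, s, s + w - 1L) <- site
  out <- Biostrings::DNAStringSet(x)
  names(out) <- names(g)
  list(genome = out, site_starts = starts)
}

#' Mapping accuracy of simulated SfiI cleavage ends
#'
#' Simulation study of the full read-level pipeline at SfiI sites of a
#' chosen cut-flank category. Sites whose strand-specific cut-flanking
#' bases are both A (`"A|A"`, the hardest case: TdT A-tails merge with
#' genome-encoded A's) or both non-A (`"B|B"`) are planted in a random
#' genome; 3' ends from both strands of each site are sampled, reads are
#' built with TdT tails drawn from `tails`, and the pipeline (UMI removal,
#' capped poly-T trimming, exact full-length mapping, deduplication,
#' single-nucleotide end calling) is replayed. Accuracy is the fraction of
#' mapped reads whose called end falls within 1 nt of (or exactly at) the
#' true cleavage position.
#'
#' With the default uniform 2-4 nt tails and a 3-T trimming cap, A|A ends
#' are called at offsets -1, 0, +1 of truth for tails of 2, 3 and 4 nt
#' respectively (flank absorption), so essentially all mapped reads fall
#' within +/-1 nt; B|B ends are called exactly whenever the read maps
#' (a 4-nt tail leaves an unmatchable residual T, and such reads fail
#' exact alignment).
#'
#' @param category `"A|A"` or `"B|B"` (strand-specific cut-flank class).
#' @param n_ends Number of simulated ends (default 10000).
#' @param genome_length Random genome length (default 1e6).
#' @param n_sites Number of planted sites (default 120).
#' @param seed Integer seed.
#' @param tails A [tail_model()] (default uniform 2-4 nt).
#' @param read_len Raw read length (default 50).
#' @return list: `category`, `n_reads`, `n_mapped`, `pct_within_1nt`,
#'   `pct_exact` (percentages among mapped reads), `offset_by_tail`
#'   (table of called-minus-true offset by tail length).
#' @export
sfi_mapping_accuracy <- function(category = c("A|A", "B|B"),
                                 n_ends = 10000L, genome_length = 1e6,
                                 n_sites = 120L, seed = 1L,
                                 tails = tail_model(), read_len = 50L) {
  category <- match.arg(category)
  # offsets 5-9 of GGCCNNNNNGGCC chosen so both strand-specific ends of
  # every planted site share the requested category
  site <- if (category == "A|A") "GGCCTTGAAGGCC" else "GGCCCGGCGGGCC"
  planted <- plant_sites(genome_length, site, n_sites, seed = seed)
  layout <- trael_layout()

  ends <- enzyme_ends(planted$genome, trael_enzymes()$SfiI)
  ends <- ends[ends$site_start %in% planted$site_starts, , drop = FALSE]
  cls <- classify_sfi_end(planted$genome, ends$chrom, ends$site_start,
                          ends$strand)
  stopifnot(all(cls$category == category))

  idx <- with_seed(seed + 10L, sample.int(nrow(ends), n_ends, replace = TRUE))
  truth <- ends[idx, c("chrom", "pos", "strand")]
  sim <- make_reads(truth, planted$genome, layout = layout, tails = tails,
                    read_len = read_len, seed = seed + 20L)

  pp <- preprocess_fastq(sim$reads, layout)
  aln <- exact_map(pp$reads$all, planted$genome)
  aln <- aln[aln$mapped, , drop = FALSE]
  dd <- dedup_alignments(aln, umi_delim = layout$umi_delim)
  ep <- alignments_to_endpoints(dd)

  sim_id <- sub(paste0("\\", layout$umi_delim, "[ACGTN]+$"), "",
                dd$alignments$qname)
  ti <- match(sim_id, sim$truth$id)
  offset <- ep$pos - sim$truth$pos[ti]
  strand_ok <- (sim$truth$strand[ti] == "+" & ep$read_strand == "R") |
    (sim$truth$strand[ti] == "-" & ep$read_strand == "F")

  list(
    category = category,
    n_reads = nrow(sim$reads),
    n_mapped = length(offset),
    pct_within_1nt = 100 * mean(abs(offset) <= 1 & strand_ok),
    pct_exact = 100 * mean(offset == 0 & strand_ok),
    offset_by_tail = table(tail = sim$truth$tail_k[ti], offset = offset)
  )
}

#' Origin recovery from a simulated replication profile
#'
#' End-to-end simulation study: a random genome with `n_origins`
#' replication origins emits `n_ends` fork-derived 3' ends at the given
#' polarity strength; reads are built, preprocessed, exactly mapped,
#' deduplicated and windowed, read polarity is computed, and origins are
#' called at negative-to-positive polarity switches. Recovery is assessed
#' against the simulated origin positions, and plateau polarity (windows
#' far from origins and fork-convergence midpoints) against its expected
#' value `2 * polarity_strength - 1`.
#'
#' @param genome_length Genome length (default 1e6).
#' @param n_origins Number of origins (default 10).
#' @param polarity_strength Probability an end's strand matches the fork
#'   direction (default 0.8).
#' @param n_ends Number of simulated replication ends (default 1e5).
#' @param seed Integer seed.
#' @param window,step Window quantitation parameters (default 1000/100).
#' @param smooth_windows,min_swing Origin-calling parameters (defaults 5
#'   and 0.5).
#' @param match_tol Distance (bp) within which a call counts as recovering
#'   an origin (default 2000).
#' @param false_tol Distance (bp) beyond which an origin call counts as
#'   false (default 5000).
#' @return list: `origins` (true positions), `calls` (the call table),
#'   `n_recovered`, `n_false`, `plateau_polarity`, `expected_plateau`,
#'   `n_plateau_windows`.
#' @export
origin_recovery <- function(genome_length = 1e6, n_origins = 10L,
                            polarity_strength = 0.8, n_ends = 1e5,
                            seed = 1L, window = 1000L, step = 100L,
                            smooth_windows = 5L, min_swing = 0.5,
                            match_tol = 2000, false_tol = 5000) {
  g <- random_genome(genome_length, seed = seed)
  span <- c(0.05, 0.95) * genome_length
  base <- seq(span[1], span[2], length.out = n_origins)
  jit <- min(diff(base)) / 4
  origins <- with_seed(seed + 1L, {
    sort(as.integer(base + runif(n_origins, -jit, jit)))
  })
  model <- replication_model(origins, polarity_strength)
  ends <- sample_replication_ends(model, genome_length, n_ends,
                                  seed = seed + 2L)
  layout <- trael_layout()
  sim <- make_reads(ends, g, layout = layout, seed = seed + 3L)
  pp <- preprocess_fastq(sim$reads, layout)
  aln <- exact_map(pp$reads$all, g)
  dd <- dedup_alignments(aln[aln$mapped, , drop = FALSE])
  track <- build_track(alignments_to_endpoints(dd), g)
  pol <- polarity(window_counts(track, window, step))
  calls <- call_origins(pol, smooth_windows = smooth_windows,
                        min_swing = min_swing)
  oc <- calls[calls$type == "origin", , drop = FALSE]

  dmat <- abs(outer(origins, oc$position, "-"))
  n_recovered <- if (nrow(oc)) sum(apply(dmat, 1, min) <= match_tol) else 0L
  n_false <- if (nrow(oc)) sum(apply(dmat, 2, min) > false_tol) else 0L

  # plateau: window centres far from origins and from fork-convergence
  # boundaries (midpoints between adjacent origins, and contig ends)
  bounds <- c(1, (head(origins, -1) + tail(origins, -1)) / 2, genome_length)
  centers <- (pol$start + pol$end) / 2
  d_or <- apply(abs(outer(centers, origins, "-")), 1, min)
  d_bd <- apply(abs(outer(centers, bounds, "-")), 1, min)
  plateau <- d_or > false_tol & d_bd > false_tol & !is.na(pol$polarity)
  dir <- fork_direction(centers[plateau], origins)
  plateau_polarity <- mean(pol$polarity[plateau] * dir)

  list(origins = origins, calls = calls, n_recovered = n_recovered,
       n_false = n_false, plateau_polarity = plateau_polarity,
       expected_plateau = 2 * polarity_strength - 1,
       n_plateau_windows = sum(plateau))
}
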