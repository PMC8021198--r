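test_that("random genomes honour GC content, seed determinism and composition", {
  g0 <- random_genome(2000, gc = 0, seed = 1)
  expect_true(grepl("^[AT]+$", as.character(g0[[1]])))

  g1 <- random_genome(5000, gc = 0.4, seed = 5)
  g2 <- random_genome(5000, gc = 0.4, seed = 5)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- random_genome(5000, gc = 0.4, seed = 6)
  expect_false(identical(as.character(g1), as.character(g3)))

  # base frequencies within 3 SD of binomial expectation at 1 Mb
  gl <- 1e6
  gb <- random_genome(gl, gc = 0.38, seed = 7)
  fr <- Biostrings::alphabetFrequency(gb[[1]])[c("A", "C", "G", "T")]
  p <- c(0.31, 0.19, 0.19, 0.31)
  expect_true(all(abs(fr - gl * p) < 3 * sqrt(gl * p * (1 - p))))

  # multiple contigs
  gm <- random_genome(c(100, 200), seed = 8)
  expect_equal(unname(Biostrings::width(gm)), c(100L, 200L))
})

test_that("built-in enzymes produce the documented cut geometry", {
  enzymes <- trael_enzymes()
  expect_equal(enzymes$SfiI$overhang, 3L)    # 3' extended
  expect_equal(enzymes$NotI$overhang, -4L)   # 5' extended
  expect_equal(enzymes$PmeI$overhang, 0L)    # blunt

  # spec-by-example: site planted at a known offset on a neutral background
  pad <- strrep("C", 30)
  g <- Biostrings::DNAStringSet(c(
    sfi = paste0(pad, "GGCCTCGTAGGCC", pad),
    noti = paste0(pad, "GCGGCCGC", pad),
    pmei = paste0(pad, "GTTTAAAC", pad)
  ))
  s <- 31L  # 1-based site start
  sfi <- enzyme_ends(g["sfi"], enzymes$SfiI)
  expect_equal(sfi$pos[sfi$strand == "+"], s + 7L)
  expect_equal(sfi$pos[sfi$strand == "-"], s + 5L)
  noti <- enzyme_ends(g["noti"], enzymes$NotI)
  expect_equal(noti$pos[noti$strand == "+"], s + 1L)
  expect_equal(noti$pos[noti$strand == "-"], s + 6L)
  pmei <- enzyme_ends(g["pmei"], enzymes$PmeI)
  expect_equal(pmei$pos[pmei$strand == "+"], s + 3L)
  expect_equal(pmei$pos[pmei$strand == "-"], s + 4L)
})

test_that("digest ends agree with the literal both-strand cutting oracle", {
  # 1000 random degenerate SfiI sites across several random genomes
  enz <- trael_enzymes()$SfiI
  total <- 0L
  for (seed in 1:4) {
    set.seed(seed)
    cores <- vapply(1:250, function(i) {
      paste0("GGCC", paste(sample(c("A", "C", "G", "T"), 5, TRUE),
                           collapse = ""), "GGCC")
    }, character(1))
    g <- random_genome(250 * 150 + 2000, seed = seed + 100)
    x <- as.character(g[[1]])
    starts <- seq(1000, by = 150, length.out = 250)
    for (i in seq_along(starts)) {
      substr(x, starts[i], starts[i] + 12L) <- cores[i]
    }
    gg <- Biostrings::DNAStringSet(c(chr1 = x))
    got <- enzyme_ends(gg, enz)
    want <- oracle_enzyme_ends(gg[[1]], enz)
    expect_equal(got[order(got$pos, got$strand), c("pos", "strand")],
                 want[, c("pos", "strand")], ignore_attr = TRUE)
    total <- total + nrow(want) / 2
  }
  expect_gte(total, 1000)

  # a non-palindromic pattern exercises the reverse-complement scan
  asym <- enzyme("Asym", "GGACNNTC", top_cut = 5, bottom_cut = 3)
  pad <- strrep("A", 25)
  gg2 <- Biostrings::DNAStringSet(c(
    chr1 = paste0(pad, "GGACGTTC", pad, "GATTGTCC", pad)
  ))
  got2 <- enzyme_ends(gg2, asym)
  want2 <- oracle_enzyme_ends(gg2[[1]], asym)
  expect_equal(got2[order(got2$pos, got2$strand), c("pos", "strand")],
               want2[, c("pos", "strand")], ignore_attr = TRUE)
  expect_equal(nrow(got2), 4L)   # one forward, one reverse-complement site
})

test_that("SfiI cut-flank classification reads bases in end-strand space", {
  pad <- strrep("C", 20)
  mk <- function(core) {
    Biostrings::DNAStringSet(c(chr1 = paste0(pad, core, pad)))
  }
  s <- 21L

  # no A's at the cut on the forward strand
  g1 <- mk("GGCCTCGCGGGCC")   # offsets 8,9 = C,G
  c1 <- classify_sfi_end(g1, "chr1", s, "+")
  expect_equal(c1$category, "B|B")
  expect_equal(c(c1$flank_5, c1$flank_3), c("C", "G"))

  # A's flanking the forward cut, and 1 terminal A
  g2 <- mk("GGCCTCGAAGGCC")   # offsets 8,9 = A,A
  c2 <- classify_sfi_end(g2, "chr1", s, "+")
  expect_equal(c2$category, "A|A")
  expect_equal(c2$n_terminal_A, 1L)

  # reverse end: offsets 5,6 = T,T complement to A,A in end-strand space
  g3 <- mk("GGCCTTGCGGGCC")
  c3 <- classify_sfi_end(g3, "chr1", s, "-")
  expect_equal(c3$category, "A|A")
  # and the forward end of the same site is B|B (strands classified apart)
  expect_equal(classify_sfi_end(g3, "chr1", s, "+")$category, "B|B")

  # two or more 3'-terminal A's (GGCCNNAA|NGGCC family)
  g4 <- mk("GGCCGCAAGGGCC")   # offsets 7,8 = A,A; offset 9 = G
  c4 <- classify_sfi_end(g4, "chr1", s, "+")
  expect_equal(c4$n_terminal_A, 2L)
  expect_equal(c4$category, "mixed")   # A | G
  # census tallies both conventions without error
  cen <- sfi_site_census(g4)
  expect_equal(sum(cen$by_end), 2L)
  expect_equal(cen$ge2A_ends, 1L)
})

test_that("replication end strands encode deterministic fork direction", {
  # full polarity, single central origin: left of it all ends are
  # reverse-strand, right of it forward-strand
  m1 <- replication_model(data.frame(pos = 5e4), polarity_strength = 1)
  e1 <- sample_replication_ends(m1, 1e5, 4000, seed = 31)
  left <- e1$pos < 5e4
  expect_true(all(e1$strand[left] == "-"))
  expect_true(all(e1$strand[!left] == "+"))

  # polarity strength 0.5: no net strand bias anywhere
  m2 <- replication_model(data.frame(pos = 5e4), polarity_strength = 0.5)
  e2 <- sample_replication_ends(m2, 1e5, 20000, seed = 32)
  pr <- mean(e2$strand == "+")
  expect_lt(abs(pr - 0.5), 0.02)

  # plateau strand bias equals polarity strength on each side
  m3 <- replication_model(data.frame(pos = 5e4), polarity_strength = 0.8)
  e3 <- sample_replication_ends(m3, 1e5, 20000, seed = 33)
  right <- e3$pos >= 5e4
  expect_lt(abs(mean(e3$strand[right] == "+") - 0.8), 0.02)
  expect_lt(abs(mean(e3$strand[!right] == "-") - 0.8), 0.02)

  # two origins: direction flips at the midpoint between them
  m4 <- replication_model(data.frame(pos = c(25000, 75000)),
                          polarity_strength = 1)
  e4 <- sample_replication_ends(m4, 1e5, 4000, seed = 34)
  mid <- e4$pos >= 25000 & e4$pos < 50000
  expect_true(all(e4$strand[mid] == "+"))
  conv <- e4$pos >= 50000 & e4$pos < 75000
  expect_true(all(e4$strand[conv] == "-"))
})

test_that("hotspot end sampling respects centers, weights and dispersion", {
  hs <- data.frame(center = c(10000, 30000), weight = c(9, 1),
                   dispersion = 0)
  e <- sample_hotspot_ends(hs, 20000, seed = 41)
  expect_true(all(e$pos %in% hs$center))
  ratio <- sum(e$pos == 10000) / sum(e$pos == 30000)
  expect_lt(abs(ratio - 9) / 9, 0.15)
  # both strands emitted symmetrically
  expect_lt(abs(mean(e$strand == "+") - 0.5), 0.02)

  # recovered counts correlate with weights across many hotspots
  set.seed(42)
  hs2 <- data.frame(center = seq(5000, 95000, length.out = 100),
                    weight = runif(100, 0.2, 5), dispersion = 50)
  e2 <- sample_hotspot_ends(hs2, 1e5, seed = 43)
  counts <- tabulate(e2$hotspot, nbins = 100)
  expect_gt(cor(counts, hs2$weight), 0.95)

  # dispersion scatters positions around the centre
  expect_gt(sd(e2$pos - hs2$center[e2$hotspot]), 40)
  expect_lt(sd(e2$pos - hs2$center[e2$hotspot]), 60)
})

test_that("reads are the reverse complement of the sequence ending at the 3' end", {
  g <- random_genome(4000, seed = 51)
  gchar <- as.character(g[[1]])
  lay0 <- trael_layout(polyT_cap = 0L)
  truth <- data.frame(chrom = "chr1", pos = c(2000L, 2000L),
                      strand = c("+", "-"))
  sim <- make_reads(truth, g, layout = lay0, tails = tail_model(lengths = 0L),
                    seed = 52)
  W <- 50L - 8L
  # forward-strand end: revcomp of the W bases ending at p; maps reverse
  r1 <- substring(sim$reads$seq[1], 9L)
  expect_equal(r1, traelr:::revcomp_chr(substring(gchar, 2000 - W + 1, 2000)))
  expect_equal(sim$truth$aln_strand[1], "-")
  expect_equal(sim$truth$aln_pos[1] + sim$truth$aln_width[1] - 1L, 2000L)
  # reverse-strand end: the read reads forward from p
  r2 <- substring(sim$reads$seq[2], 9L)
  expect_equal(r2, substring(gchar, 2000, 2000 + W - 1))
  expect_equal(sim$truth$aln_strand[2], "+")
  expect_equal(sim$truth$aln_pos[2], 2000L)
})

test_that("tails become leading T's that trimming removes as expected", {
  # plant a C-rich flank so no genomic T can be absorbed: a 3-nt tail must
  # be trimmed exactly
  pad <- strrep("C", 200)
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(pad, pad)))
  truth <- data.frame(chrom = "chr1", pos = 200L, strand = "+")
  sim <- make_reads(truth, g, tails = tail_model(lengths = 3L), seed = 61)
  expect_match(substring(sim$reads$seq, 9L), "^TTTG")
  pp <- preprocess_fastq(sim$reads, trael_layout())
  expect_equal(pp$reads$all$n_trimmed_T, 3L)
  expect_equal(sim$truth$trim_expected, 3L)
  expect_equal(sim$truth$aln_pos + sim$truth$aln_width - 1L, 200L)
})

test_that("ends too close to a contig boundary are dropped and recorded", {
  g <- random_genome(1000, seed = 71)
  truth <- data.frame(chrom = "chr1", pos = c(10L, 500L, 995L),
                      strand = c("+", "+", "-"))
  sim <- make_reads(truth, g, seed = 72)
  expect_equal(sim$truth$representable, c(FALSE, TRUE, FALSE))
  expect_equal(nrow(sim$reads), 1L)
})

test_that("PCR duplicates share the molecule UMI and collapse in dedup", {
  g <- random_genome(2e4, seed = 81)
  ends <- uniform_ends(500, 2e4, seed = 82)
  sim <- make_reads(ends, g, seed = 83, dup_factor = 3L)
  expect_equal(nrow(sim$truth), 1500L)
  per_mol <- tapply(sim$truth$umi, sim$truth$molecule,
                    function(x) length(unique(x)))
  expect_true(all(per_mol == 1L))
  dd <- dedup_alignments(sim$truth_aln)
  keys <- oracle_dedup_keys(
    data.frame(rname = sim$truth$chrom, pos = sim$truth$aln_pos,
               strand = sim$truth$aln_strand)[sim$truth$aln_mapped, ],
    sim$truth$umi[sim$truth$aln_mapped]
  )
  expect_equal(dd$stats$retained, length(keys))
})

test_that("the exact mapper distinguishes unique, absent and repeated reads", {
  g <- random_genome(5000, seed = 91)
  gchar <- as.character(g[[1]])
  uniq <- substring(gchar, 1000, 1039)
  rc <- traelr:::revcomp_chr(uniq)
  mismatch <- uniq
  substr(mismatch, 20, 20) <- chartr("ACGT", "TGCA", substr(mismatch, 20, 20))
  # a repeated substring: plant a copy elsewhere
  x <- gchar
  substr(x, 3000, 3039) <- uniq
  g2 <- Biostrings::DNAStringSet(c(chr1 = x))

  reads <- data.frame(id = c("u", "r", "m"),
                      seq = c(uniq, rc, mismatch))
  aln <- exact_map(reads, g)
  expect_equal(aln$mapped, c(TRUE, TRUE, FALSE))
  expect_equal(aln$strand[1:2], c("+", "-"))
  expect_equal(aln$pos[1:2], c(1000L, 1000L))
  expect_equal(aln$reason[3], "no_match")

  aln2 <- exact_map(reads[1, , drop = FALSE], g2)
  expect_false(aln2$mapped)
  expect_equal(aln2$reason, "multi_match")
})

test_that("pipeline calls agree with the replayed truth alignments under trimming", {
  # the truth table predicts, for every read, whether the trimmed insert
  # maps and exactly where; the real pipeline must agree record for record
  g <- random_genome(5e4, seed = 101)
  ends <- uniform_ends(800, 5e4, seed = 102)
  lay <- trael_layout()
  sim <- make_reads(ends, g, layout = lay, seed = 103)
  pp <- preprocess_fastq(sim$reads, lay)
  aln <- exact_map(pp$reads$all, g)
  ti <- match(sub(":[ACGT]+$", "", aln$qname), sim$truth$id)
  expect_equal(aln$mapped, sim$truth$aln_mapped[ti])
  m <- aln$mapped
  expect_equal(aln$pos[m], sim$truth$aln_pos[ti][m])
  expect_equal(aln$strand[m], sim$truth$aln_strand[ti][m])
  expect_equal(aln$width[m], sim$truth$aln_width[ti][m])
})

test_that("with no tails the full pipeline reproduces truth ends exactly", {
  g <- random_genome(3e4, seed = 111)
  ends <- uniform_ends(600, 3e4, seed = 112)
  lay0 <- trael_layout(polyT_cap = 0L)
  sim <- make_reads(ends, g, layout = lay0, tails = tail_model(lengths = 0L),
                    seed = 113)
  pl <- trael_pipeline(sim$reads, g, layout = lay0)
  tr <- pl$samples$all$track
  expect_equal(tr$total_mapped, nrow(sim$reads))
  want <- build_track(
    data.frame(chrom = sim$truth$chrom, pos = sim$truth$pos,
               read_strand = ifelse(sim$truth$strand == "+", "R", "F")),
    g
  )
  expect_equal(tr$counts, want$counts)
})
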