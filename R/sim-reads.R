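#' Build TrAEL-seq reads from ground-truth 3' ends
#'
#' A TrAEL-seq read is the reverse complement of the sequence ending at the
#' labelled 3' end: for a forward-strand end at position `p` the genomic
#' part of the read is the reverse complement of the `W` bases ending at
#' `p` (the read maps to the reverse strand with its 5' base at `p`); for a
#' reverse-strand end the genomic part is the forward sequence starting at
#' `p`. The emitted read is `UMI [barcode] T^k genomic`, with `k` drawn
#' from the tail model, so all reads share one raw length `read_len`.
#'
#' Alongside the FASTQ-style read table, the expected *post-trimming*
#' alignment of every read is computed against the genome: capped poly-T
#' trimming is replayed (the leading-T run of `T^k + genomic` trimmed to at
#' most the layout cap), and the trimmed insert is placed at the position
#' where it matches the genome exactly, which may be offset by the
#' over-/under-trimming of genome-encoded A's at the end. This truth
#' alignment lets every downstream stage run without an aligner.
#'
#' @param truth data.frame of ends: `chrom`, `pos`, `strand` (`"+"`
#'   forward-strand end, `"-"` reverse-strand end), optional `barcode`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param layout A [trael_layout()]; if it defines barcodes and `truth` has
#'   no `barcode` column, the first barcode is used for all reads.
#' @param tails A [tail_model()].
#' @param read_len Raw read length (default 50); must exceed the prefix
#'   (UMI + barcode + longest tail) by at least 20.
#' @param seed Integer seed or `NULL`.
#' @param dup_factor PCR duplication factor: each molecule is emitted this
#'   many times, duplicates sharing the molecule's UMI (default 1).
#' @return list of class `trael_sim`:
#'   \describe{
#'     \item{reads}{data.frame `id`, `seq`, `qual` (raw reads).}
#'     \item{truth}{per-read truth: `id`, `molecule`, `chrom`, `pos`,
#'       `strand`, `source`, `tail_k`, `umi`, `barcode`, `representable`,
#'       `trim_expected`, `aln_pos`, `aln_width`, `aln_strand`,
#'       `aln_mapped` (whether the trimmed insert matches the genome
#'       exactly at the expected position).}
#'     \item{truth_aln}{alignment table (`qname`, `rname`, `pos`, `width`,
#'       `strand`, `mapped`) for representable reads, ready for
#'       [write_sam()] or direct use in place of an aligner.}
#'   }
#' @export
make_reads <- function(truth, genome, layout = trael_layout(),
                       tails = tail_model(), read_len = 50L, seed = NULL,
                       dup_factor = 1L) {
  stopifnot(all(c("chrom", "pos", "strand") %in% names(truth)),
            all(truth$strand %in% c("+", "-")))
  dup_factor <- stopifnot_scalar_int(dup_factor, "dup_factor", min = 1L)
  prefix_fixed <- layout$umi_len + layout$barcode_len
  if (read_len <= prefix_fixed + max(tails$lengths) + 20L) {
    stop("read_len must exceed UMI + barcode + longest tail by at least 20")
  }
  n_mol <- nrow(truth)

  with_seed(seed, {
    # per-molecule UMI and tail length, replicated over PCR duplicates
    umi_mol <- random_dna(n_mol, layout$umi_len)
    k_mol <- tails$lengths[sample.int(length(tails$lengths), n_mol,
                                      replace = TRUE, prob = tails$prob)]
    mol_idx <- rep(seq_len(n_mol), each = dup_factor)

    chrom <- truth$chrom[mol_idx]
    pos <- truth$pos[mol_idx]
    strand <- truth$strand[mol_idx]
    source <- if (is.null(truth$source)) rep(NA_character_, n_mol)[mol_idx] else truth$source[mol_idx]
    umi <- umi_mol[mol_idx]
    k <- k_mol[mol_idx]
    barcode <- if (!is.null(truth$barcode)) {
      truth$barcode[mol_idx]
    } else if (layout$barcode_len > 0L) {
      rep(layout$barcodes[[1L]], length(mol_idx))
    } else {
      rep(NA_character_, length(mol_idx))
    }
    n <- length(mol_idx)
    W <- read_len - prefix_fixed - k

    seqlens <- as_seqlengths(genome)
    gchar <- setNames(lapply(names(genome), function(ch) as.character(genome[[ch]])),
                      names(genome))

    representable <- ifelse(strand == "+",
                            pos - W + 1L >= 1L,
                            pos + W - 1L <= seqlens[chrom])

    genomic <- rep(NA_character_, n)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch & representable)
      if (!length(sel)) next
      g <- gchar[[ch]]
      plus <- sel[strand[sel] == "+"]
      if (length(plus)) {
        genomic[plus] <- revcomp_chr(substring(g, pos[plus] - W[plus] + 1L, pos[plus]))
      }
      minus <- sel[strand[sel] == "-"]
      if (length(minus)) {
        genomic[minus] <- substring(g, pos[minus], pos[minus] + W[minus] - 1L)
      }
    }

    tailT <- strrep("T", k)
    bc_part <- ifelse(is.na(barcode), "", barcode)
    seq <- ifelse(representable,
                  paste0(umi, bc_part, tailT, genomic),
                  NA_character_)

    # replay capped trimming against the known genome to get the expected
    # post-trimming alignment (the leading-T run may absorb genomic T's)
    insert <- paste0(tailT, genomic)
    run <- ifelse(representable, leading_t_run(insert), NA_integer_)
    t_exp <- pmin(run, layout$polyT_cap)
    shift <- k - t_exp                     # >0: residual tail Ts; <0: genomic bases lost
    Wp <- read_len - prefix_fixed - t_exp  # trimmed insert width
    aln_pos <- rep(NA_integer_, n)
    aln_mapped <- rep(FALSE, n)
    trimmed <- ifelse(representable, substring(insert, t_exp + 1L), NA_character_)
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch & representable)
      if (!length(sel)) next
      g <- gchar[[ch]]
      L <- seqlens[[ch]]
      plus <- sel[strand[sel] == "+"]
      if (length(plus)) {
        p2 <- pos[plus] + shift[plus]      # 5' base of the aligned read
        lo <- p2 - Wp[plus] + 1L
        okb <- lo >= 1L & p2 <= L
        exp_seq <- rep(NA_character_, length(plus))
        exp_seq[okb] <- revcomp_chr(substring(g, lo[okb], p2[okb]))
        hit <- okb & !is.na(exp_seq) & exp_seq == trimmed[plus]
        aln_mapped[plus] <- hit
        aln_pos[plus][hit] <- lo[hit]      # leftmost reference coordinate
      }
      minus <- sel[strand[sel] == "-"]
      if (length(minus)) {
        p2 <- pos[minus] - shift[minus]
        hi <- p2 + Wp[minus] - 1L
        okb <- p2 >= 1L & hi <= L
        exp_seq <- rep(NA_character_, length(minus))
        exp_seq[okb] <- substring(g, p2[okb], hi[okb])
        hit <- okb & !is.na(exp_seq) & exp_seq == trimmed[minus]
        aln_mapped[minus] <- hit
        aln_pos[minus][hit] <- p2[hit]
      }
    }

    id <- sprintf("sim%07d", seq_len(n))
    truth_out <- data.frame(
      id = id, molecule = mol_idx, chrom = chrom, pos = pos, strand = strand,
      source = source, tail_k = k, umi = umi, barcode = barcode,
      representable = representable, trim_expected = t_exp,
      aln_pos = aln_pos, aln_width = ifelse(representable, Wp, NA_integer_),
      aln_strand = ifelse(strand == "+", "-", "+"),
      aln_mapped = aln_mapped, stringsAsFactors = FALSE
    )
    reads <- data.frame(
      id = id[representable], seq = seq[representable],
      qual = strrep("I", read_len), stringsAsFactors = FALSE
    )
    tm <- truth_out[truth_out$representable & truth_out$aln_mapped, , drop = FALSE]
    truth_aln <- data.frame(
      qname = paste0(tm$id, layout$umi_delim, tm$umi),
      rname = tm$chrom, pos = tm$aln_pos, width = tm$aln_width,
      strand = tm$aln_strand, mapped = TRUE, stringsAsFactors = FALSE
    )
    structure(list(reads = reads, truth = truth_out, truth_aln = truth_aln),
              class = "trael_sim")
  })
}

# n random DNA strings of the given width
random_dna <- function(n, width) {
  if (width == 0L) return(rep("", n))
  m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' @export
print.trael_sim <- function(x, ...) {
  cat(sprintf("TrAEL-seq simulation: %d reads (%d molecules), %d representable\n",
              nrow(x$truth), length(unique(x$truth$molecule)),
              sum(x$truth$representable)))
  cat("  source classes:",
      paste(names(table(x$truth$source)), table(x$truth$source),
            sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Exact full-length read mapper
#'
#' Matches each read exactly (no mismatches or indels) against both strands
#' of a small genome using a preprocessed dictionary. Reads with zero or
#' multiple matches are reported unmapped with a reason. This is the
#' aligner used for simulated data; production libraries should use a real
#' local aligner.
#'
#' @param reads data.frame with columns `id` and `seq` (e.g. a demultiplexed
#'   element of [preprocess_fastq()]'s `reads`), or a FASTQ path.
#' @param genome A [Biostrings::DNAStringSet] (total size up to ~10 Mb).
#' @return Alignment data.frame: `qname`, `rname`, `pos` (1-based leftmost
#'   reference coordinate), `width`, `strand`, `mapped`, `reason`
#'   (`"unique"`, `"no_match"`, `"multi_match"`).
#' @export
exact_map <- function(reads, genome) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  stopifnot(all(c("id", "seq") %in% names(reads)))
  n <- nrow(reads)
  hit_n <- integer(n)
  hit_chrom <- rep(NA_character_, n)
  hit_pos <- rep(NA_integer_, n)
  hit_strand <- rep(NA_character_, n)
  widths <- nchar(reads$seq)

  for (w in unique(widths)) {
    idx <- which(widths == w)
    if (w == 0L) next
    ss <- Biostrings::DNAStringSet(reads$seq[idx])
    pd_f <- Biostrings::PDict(ss)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(ss))
    for (ch in names(genome)) {
      subject <- genome[[ch]]
      for (sm in c("+", "-")) {
        pd <- if (sm == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, subject)
        starts <- Biostrings::startIndex(m)
        nh <- S4Vectors::elementNROWS(m)
        has <- which(nh > 0L)
        for (j in has) {
          i <- idx[j]
          hit_n[i] <- hit_n[i] + nh[j]
          if (hit_n[i] == nh[j] && nh[j] == 1L) {
            hit_chrom[i] <- ch
            hit_pos[i] <- starts[[j]][1L]
            hit_strand[i] <- sm
          }
        }
      }
    }
  }

  mapped <- hit_n == 1L
  data.frame(
    qname = reads$id, rname = ifelse(mapped, hit_chrom, NA_character_),
    pos = ifelse(mapped, hit_pos, NA_integer_),
    width = widths, strand = ifelse(mapped, hit_strand, NA_character_),
    mapped = mapped,
    reason = ifelse(mapped, "unique",
                    ifelse(hit_n == 0L, "no_match", "multi_match")),
    stringsAsFactors = FALSE
  )
}

#' Write an alignment table as SAM
#'
#' Minimal single-end SAM: flag 0/16 for forward/reverse, 4 for unmapped;
#' CIGAR is full-length match.
#'
#' @param aln Alignment data.frame (`qname`, `rname`, `pos`, `width`,
#'   `strand`, `mapped`).
#' @param seqlengths Named contig lengths (or a DNAStringSet).
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, seqlengths, path) {
  seqlengths <- as_seqlengths(seqlengths)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths))
  mapped <- aln$mapped
  flag <- ifelse(!mapped, 4L, ifelse(aln$strand == "-", 16L, 0L))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*",
                 aln$qname, flag,
                 ifelse(mapped, aln$rname, "*"),
                 ifelse(mapped, aln$pos, 0L),
                 ifelse(mapped, 255L, 0L),
                 ifelse(mapped, sprintf("%dM", aln$width), "*"))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read alignments from SAM/BAM into the package's alignment table
#'
#' SAM files are converted to BAM internally; only primary mapped records
#' are returned (secondary/supplementary/unmapped records are excluded by
#' the reader).
#'
#' @param path SAM or BAM path.
#' @return Alignment data.frame: `qname`, `rname`, `pos`, `width`,
#'   `strand`, `mapped` (all `TRUE`).
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else {
    path
  }
  flt <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, use.names = TRUE, param = flt)
  data.frame(
    qname = names(ga),
    rname = as.character(GenomicAlignments::seqnames(ga)),
    pos = BiocGenerics::start(ga),
    width = BiocGenerics::width(ga),
    strand = as.character(BiocGenerics::strand(ga)),
    mapped = TRUE, stringsAsFactors = FALSE
  )
}

#' Write a per-read truth table as TSV
#'
#' @param sim A `trael_sim` from [make_reads()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  write.table(sim$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
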