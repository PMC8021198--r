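#' Generate a random genome
#'
#' Bases are drawn i.i.d. at the stated GC content; deterministic under a
#' fixed seed. Intended as a neutral background for planting restriction
#' sites, origins, stall sites and hotspots.
#'
#' @param length Integer vector of contig lengths (one element per contig).
#' @param gc GC fraction in `[0, 1]` (default 0.38, yeast-like).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param names Contig names (default `chrI`, `chrII`, ...).
#' @return A [Biostrings::DNAStringSet].
#' @examples
#' g <- random_genome(1e4, gc = 0.4, seed = 1)
#' @export
random_genome <- function(length, gc = 0.38, seed = NULL, names = NULL) {
  stopifnot(gc >= 0, gc <= 1, all(length >= 1))
  if (is.null(names)) names <- paste0("chr", seq_along(length))
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, {
    vapply(length, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names
  out
}

#' Restriction enzyme definitions
#'
#' An enzyme is described by its recognition pattern (IUPAC, N allowed) and
#' two cut offsets in top-strand coordinates, 1-based within the site: the
#' top strand is cut between offsets `top_cut` and `top_cut + 1`, the bottom
#' strand between `bottom_cut` and `bottom_cut + 1`. `top_cut - bottom_cut`
#' is the 3' overhang length (negative for 5' overhangs, zero for blunt
#' ends).
#'
#' The cleaved 3' ends follow directly: the forward-strand 3' end is the
#' base at offset `top_cut`, the reverse-strand 3' end is the base at offset
#' `bottom_cut + 1`.
#'
#' @param name Enzyme name.
#' @param recognition IUPAC recognition string.
#' @param top_cut,bottom_cut Cut offsets as described above.
#' @return An object of class `trael_enzyme`.
#' @examples
#' enzyme("SfiI", "GGCCNNNNNGGCC", top_cut = 8, bottom_cut = 5)
#' trael_enzymes()   # built-in NotI / PmeI / SfiI
#' @export
enzyme <- function(name, recognition, top_cut, bottom_cut) {
  L <- nchar(recognition)
  stopifnot(top_cut > 0, top_cut < L, bottom_cut > 0, bottom_cut < L)
  structure(
    list(name = name, recognition = toupper(recognition),
         top_cut = as.integer(top_cut), bottom_cut = as.integer(bottom_cut),
         overhang = as.integer(top_cut - bottom_cut)),
    class = "trael_enzyme"
  )
}

#' @export
print.trael_enzyme <- function(x, ...) {
  kind <- if (x$overhang > 0) {
    sprintf("%d-nt 3' overhang", x$overhang)
  } else if (x$overhang < 0) {
    sprintf("%d-nt 5' overhang", -x$overhang)
  } else {
    "blunt"
  }
  cat(sprintf("%s: %s (top cut %d^%d, bottom cut %d^%d; %s)\n",
              x$name, x$recognition, x$top_cut, x$top_cut + 1L,
              x$bottom_cut, x$bottom_cut + 1L, kind))
  invisible(x)
}

#' @rdname enzyme
#' @export
trael_enzymes <- function() {
  list(
    NotI = enzyme("NotI", "GCGGCCGC", top_cut = 2, bottom_cut = 6),
    PmeI = enzyme("PmeI", "GTTTAAAC", top_cut = 4, bottom_cut = 4),
    SfiI = enzyme("SfiI", "GGCCNNNNNGGCC", top_cut = 8, bottom_cut = 5)
  )
}

#' Read enzyme definitions from a TSV configuration file
#'
#' Columns: `name`, `recognition`, `top_cut`, `bottom_cut`.
#' @param path TSV path.
#' @return Named list of `trael_enzyme` objects.
#' @export
read_enzymes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    enzyme(df$name[i], df$recognition[i], df$top_cut[i], df$bottom_cut[i])
  })
  setNames(out, df$name)
}

# Locate recognition sites of `enz` on the forward strand of one contig,
# plus occurrences of the reverse-complement pattern when it differs.
# Returns a data.frame(start, on_revcomp).
find_sites <- function(subject, enz) {
  pat <- enz$recognition
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                   fixed = FALSE)
  st <- BiocGenerics::start(hits)
  on_rc <- rep(FALSE, length(st))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
  if (!identical(rc, pat)) {
    h2 <- Biostrings::matchPattern(Biostrings::DNAString(rc), subject,
                                   fixed = FALSE)
    st2 <- BiocGenerics::start(h2)
    st2 <- setdiff(st2, st)
    st <- c(st, st2)
    on_rc <- c(on_rc, rep(TRUE, length(st2)))
  }
  o <- order(st)
  data.frame(start = st[o], on_revcomp = on_rc[o])
}

#' Enumerate the strand-specific 3' ends of a restriction digest
#'
#' Scans both strands of the genome for the enzyme's recognition pattern
#' (IUPAC-aware) and reports, per site, the two 3' ends the cut produces:
#' one on the forward strand (at site offset `top_cut`) and one on the
#' reverse strand (at site offset `bottom_cut + 1`). Sites overlapping a
#' contig end are skipped. All coordinates are 1-based.
#'
#' @param genome A [Biostrings::DNAStringSet] (or FASTA path).
#' @param enz A `trael_enzyme` (see [enzyme()]).
#' @return data.frame with one row per 3' end: `chrom`, `site_start`,
#'   `pos` (coordinate of the 3'-terminal base), `strand` (`"+"` forward-
#'   strand end, `"-"` reverse-strand end).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AAAAGGCCTCGTAGGCCAAAA"))
#' enzyme_ends(g, trael_enzymes()$SfiI)
#' @export
enzyme_ends <- function(genome, enz) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  L <- nchar(enz$recognition)
  res <- lapply(names(genome), function(chrom) {
    subject <- genome[[chrom]]
    sites <- find_sites(subject, enz)
    if (nrow(sites) == 0L) return(NULL)
    keep <- sites$start >= 1L & sites$start + L - 1L <= length(subject)
    sites <- sites[keep, , drop = FALSE]
    if (nrow(sites) == 0L) return(NULL)
    # For a site matched as the reverse complement of the pattern, the
    # geometry mirrors: offset i on the pattern corresponds to offset
    # L - i + 1 on the forward strand, and the end strands swap.
    fwd_off <- ifelse(sites$on_revcomp, L - enz$bottom_cut, enz$top_cut)
    rev_off <- ifelse(sites$on_revcomp, L - enz$top_cut + 1L, enz$bottom_cut + 1L)
    data.frame(
      chrom = chrom,
      site_start = rep(sites$start, 2L),
      pos = c(sites$start + fwd_off - 1L, sites$start + rev_off - 1L),
      strand = rep(c("+", "-"), each = nrow(sites)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), site_start = integer(),
                      pos = integer(), strand = character())
  }
  out[order(out$chrom, out$site_start, out$strand), , drop = FALSE]
}

#' Classify the cut-flanking bases of an SfiI 3' end
#'
#' SfiI (GGCCNNNN|NGGCC) leaves a 3-nt 3' overhang; because TdT A-tails are
#' indistinguishable from genome-encoded A's, mapping accuracy at a cleaved
#' end depends on whether the bases flanking the cut, read on the end's own
#' strand, are A. This reports, for the forward- or reverse-strand end of a
#' site, the last base of the end and the first base across the cut (both in
#' the end's strand space), a category (`"B|B"` when neither is A, `"A|A"`
#' when both are, `"mixed"` otherwise), and the number of 3'-terminal A's of
#' the end (the length of the maximal A-run ending at the cut).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param chrom Contig name(s).
#' @param site_start 1-based start coordinate(s) of the 13-bp site.
#' @param strand `"+"` for the forward-strand end, `"-"` for the reverse.
#' @param enz The enzyme (default built-in SfiI).
#' @return data.frame: `chrom`, `site_start`, `strand`, `flank_5` (last base
#'   of the end), `flank_3` (first base across the cut), `category`,
#'   `n_terminal_A`.
#' @export
classify_sfi_end <- function(genome, chrom, site_start, strand,
                             enz = trael_enzymes()$SfiI) {
  n <- max(length(chrom), length(site_start), length(strand))
  chrom <- rep_len(chrom, n)
  site_start <- rep_len(site_start, n)
  strand <- rep_len(strand, n)
  L <- nchar(enz$recognition)

  site_seq <- vapply(seq_len(n), function(i) {
    as.character(Biostrings::subseq(genome[[chrom[i]]], site_start[i],
                                    site_start[i] + L - 1L))
  }, character(1))

  flank_5 <- flank_3 <- character(n)
  n_term_A <- integer(n)
  for (i in seq_len(n)) {
    s <- strsplit(site_seq[i], "")[[1L]]
    if (strand[i] == "+") {
      # forward end: terminal base at top_cut, across the cut at top_cut + 1
      end_bases <- s[seq_len(enz$top_cut)]
      flank_5[i] <- s[enz$top_cut]
      flank_3[i] <- s[enz$top_cut + 1L]
    } else {
      # reverse end: terminal base is the complement of bottom_cut + 1, the
      # base across the cut the complement of bottom_cut; the end's strand
      # reads right-to-left along the top strand.
      comp <- chartr("ACGT", "TGCA", s)
      end_bases <- rev(comp[(enz$bottom_cut + 1L):L])
      flank_5[i] <- comp[enz$bottom_cut + 1L]
      flank_3[i] <- comp[enz$bottom_cut]
    }
    run <- 0L
    for (b in rev(end_bases)) {
      if (b == "A") run <- run + 1L else break
    }
    n_term_A[i] <- run
  }
  category <- ifelse(flank_5 == "A" & flank_3 == "A", "A|A",
                     ifelse(flank_5 != "A" & flank_3 != "A", "B|B", "mixed"))
  data.frame(chrom = chrom, site_start = site_start, strand = strand,
             flank_5 = flank_5, flank_3 = flank_3, category = category,
             n_terminal_A = n_term_A, stringsAsFactors = FALSE)
}

#' Census of SfiI cut-flank categories across a genome
#'
#' Scans both strands for the 13-bp SfiI pattern and classifies every
#' cleaved 3' end with [classify_sfi_end()]. Because published tallies can
#' count either sites or strand-specific ends, both conventions are
#' reported: per-end category counts, and per-site counts where a site is
#' `"A|A"`/`"B|B"` only if both of its ends agree (`"mixed"` otherwise).
#' The `ge2A` tallies count ends (or sites with at least one such end) with
#' two or more 3'-terminal A's.
#'
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return list with elements `ends` (the classified end table), `by_end`
#'   and `by_site` (named count vectors), `ge2A_ends`, `ge2A_sites`.
#' @export
sfi_site_census <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  enz <- trael_enzymes()$SfiI
  ends <- enzyme_ends(genome, enz)
  if (nrow(ends) == 0L) stop("no SfiI sites found")
  cls <- classify_sfi_end(genome, ends$chrom, ends$site_start, ends$strand, enz)
  by_end <- table(factor(cls$category, levels = c("B|B", "A|A", "mixed")))
  key <- paste(cls$chrom, cls$site_start)
  site_cat <- vapply(split(cls$category, key), function(x) {
    if (all(x == "A|A")) "A|A" else if (all(x == "B|B")) "B|B" else "mixed"
  }, character(1))
  by_site <- table(factor(site_cat, levels = c("B|B", "A|A", "mixed")))
  list(
    ends = cls,
    by_end = setNames(as.integer(by_end), names(by_end)),
    by_site = setNames(as.integer(by_site), names(by_site)),
    ge2A_ends = sum(cls$n_terminal_A >= 2L),
    ge2A_sites = length(unique(key[cls$n_terminal_A >= 2L]))
  )
}
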