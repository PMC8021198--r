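#' Convert alignments to single-nucleotide 3'-end points
#'
#' Each primary mapped read is truncated to the single nucleotide at its 5'
#' end, which is the reverse complement of the last nucleotide 5' of the
#' strand break: for a forward-strand alignment this is the leftmost
#' aligned base, for a reverse-strand alignment the rightmost. The labelled
#' genomic 3' end lies on the strand *opposite* to the read strand; tracks
#' are kept in read-strand space (reads are not inverted), matching how
#' polarity is plotted.
#'
#' @param aln Alignment data.frame (`rname`, `pos`, `width`, `strand`) or a
#'   `trael_dedup` object.
#' @return data.frame (`chrom`, `pos`, `read_strand`), `read_strand` in
#'   `{"F", "R"}`.
#' @export
alignments_to_endpoints <- function(aln) {
  if (inherits(aln, "trael_dedup")) aln <- aln$alignments
  stopifnot(all(c("rname", "pos", "strand") %in% names(aln)))
  if (!is.null(aln$mapped)) aln <- aln[aln$mapped, , drop = FALSE]
  fwd <- aln$strand == "+"
  if (any(!fwd) && is.null(aln$width)) {
    stop("alignment width required to locate the 5' base of reverse reads")
  }
  data.frame(
    chrom = aln$rname,
    pos = ifelse(fwd, aln$pos, aln$pos + aln$width - 1L),
    read_strand = ifelse(fwd, "F", "R"),
    stringsAsFactors = FALSE
  )
}

#' Build a strand-specific single-nucleotide 3'-end count track
#'
#' Accumulates end-point counts per (chromosome, position, read strand)
#' into dense per-base vectors.
#'
#' @param endpoints data.frame from [alignments_to_endpoints()].
#' @param seqlengths Named contig lengths (or a DNAStringSet).
#' @return Object of class `trael_track`: per-chromosome list of `F` and
#'   `R` integer count vectors, `seqlengths`, `total_mapped`, and a
#'   `normalized` flag (`"raw"`).
#' @export
build_track <- function(endpoints, seqlengths) {
  seqlengths <- as_seqlengths(seqlengths)
  stopifnot(all(endpoints$chrom %in% names(seqlengths)),
            all(endpoints$read_strand %in% c("F", "R")))
  if (nrow(endpoints) > 0 &&
      (any(endpoints$pos < 1) ||
       any(endpoints$pos > seqlengths[endpoints$chrom]))) {
    stop("endpoint positions outside chromosome bounds")
  }
  counts <- lapply(names(seqlengths), function(ch) {
    L <- seqlengths[[ch]]
    sel <- endpoints$chrom == ch
    list(
      F = tabulate(endpoints$pos[sel & endpoints$read_strand == "F"], nbins = L),
      R = tabulate(endpoints$pos[sel & endpoints$read_strand == "R"], nbins = L)
    )
  })
  names(counts) <- names(seqlengths)
  structure(list(counts = counts, seqlengths = seqlengths,
                 total_mapped = nrow(endpoints), normalized = "raw"),
            class = "trael_track")
}

#' Construct a track directly from per-base count vectors
#'
#' Mainly for simulation and testing: wraps externally generated per-base
#' counts (e.g. a Poisson background) in a `trael_track`.
#'
#' @param counts Named list (per chromosome) of lists with `F` and `R`
#'   numeric vectors.
#' @param normalized Normalisation flag (default `"raw"`).
#' @return A `trael_track`.
#' @export
track_from_counts <- function(counts, normalized = "raw") {
  seqlengths <- vapply(counts, function(x) length(x$F), numeric(1))
  stopifnot(all(vapply(counts, function(x) length(x$F) == length(x$R),
                       logical(1))))
  total <- sum(vapply(counts, function(x) sum(x$F) + sum(x$R), numeric(1)))
  structure(list(counts = counts, seqlengths = seqlengths,
                 total_mapped = total, normalized = normalized),
            class = "trael_track")
}

#' @export
print.trael_track <- function(x, ...) {
  cat(sprintf("TrAEL-seq 3'-end track: %d contig(s), %.0f ends, %s\n",
              length(x$counts), x$total_mapped, x$normalized))
  invisible(x)
}

#' Normalise a track to reads per million mapped
#'
#' Each per-base count is scaled by `1e6 / total_mapped`. Re-normalising an
#' already normalised track is an error.
#'
#' @param track A raw `trael_track`.
#' @param total Total used for scaling; defaults to the track's own
#'   `total_mapped`. Supplying the combined total of two pooled barcoded
#'   libraries gives the shared normalisation used for paired quantitation.
#' @return The normalised track (`normalized = "RPM"`).
#' @export
rpm_normalize <- function(track, total = track$total_mapped) {
  stopifnot(inherits(track, "trael_track"))
  if (track$normalized != "raw") {
    stop("track is already normalised")
  }
  if (total <= 0) stop("cannot normalise an empty track")
  f <- 1e6 / total
  track$counts <- lapply(track$counts, function(x) {
    list(F = x$F * f, R = x$R * f)
  })
  track$normalized <- "RPM"
  track
}

#' Jointly normalise two barcoded samples to their combined total
#'
#' Two samples ligated to different barcoded adaptors, pooled and processed
#' as one library, remain quantitatively comparable; the correct
#' normalisation is to the total reads mapped across both libraries, which
#' preserves the between-sample ratio.
#'
#' @param track_a,track_b Raw `trael_track`s demultiplexed from one pooled
#'   library.
#' @return list of the two tracks, each scaled by
#'   `1e6 / (total_a + total_b)`.
#' @export
paired_normalize <- function(track_a, track_b) {
  tot <- track_a$total_mapped + track_b$total_mapped
  list(rpm_normalize(track_a, total = tot),
       rpm_normalize(track_b, total = tot))
}

#' Sum end counts in sliding windows
#'
#' Windows of `window_size` bp are placed every `step` bp from the start of
#' each chromosome; windows extending past the chromosome end are excluded,
#' as is any window overlapping a masked interval (whole-window removal,
#' matching the filtering of non-single-copy regions).
#'
#' @param track A `trael_track`.
#' @param window_size Window width in bp.
#' @param step Spacing between window starts in bp; must not exceed
#'   `window_size`.
#' @param mask Optional mask of intervals to exclude: a data.frame with
#'   `chrom`, `start`, `end` (1-based, inclusive), a GRanges, or a BED path
#'   (read with [read_mask()]).
#' @return data.frame of class `trael_windows`: `chrom`, `start`, `end`
#'   (1-based, inclusive), `F`, `R`.
#' @export
window_counts <- function(track, window_size, step = window_size, mask = NULL) {
  stopifnot(inherits(track, "trael_track"))
  window_size <- stopifnot_scalar_int(window_size, "window_size", min = 1L)
  step <- stopifnot_scalar_int(step, "step", min = 1L)
  if (step > window_size) {
    stop("step must not exceed window_size (gaps between windows)")
  }
  mask <- normalize_mask(mask)
  res <- lapply(names(track$counts), function(ch) {
    L <- track$seqlengths[[ch]]
    if (L < window_size) return(NULL)
    starts <- seq.int(1L, L - window_size + 1L, by = step)
    ends <- starts + window_size - 1L
    csF <- c(0, cumsum(track$counts[[ch]]$F))
    csR <- c(0, cumsum(track$counts[[ch]]$R))
    df <- data.frame(
      chrom = ch, start = starts, end = ends,
      F = csF[ends + 1L] - csF[starts],
      R = csR[ends + 1L] - csR[starts],
      stringsAsFactors = FALSE
    )
    if (!is.null(mask)) {
      mk <- mask[mask$chrom == ch, , drop = FALSE]
      if (nrow(mk)) {
        ov <- IRanges::overlapsAny(
          IRanges::IRanges(df$start, df$end),
          IRanges::IRanges(mk$start, mk$end)
        )
        df <- df[!ov, , drop = FALSE]
      }
    }
    df
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), F = numeric(), R = numeric())
  }
  rownames(out) <- NULL
  class(out) <- c("trael_windows", "data.frame")
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  attr(out, "normalized") <- track$normalized
  out
}

# Accept a mask as data.frame, GRanges or BED path; return a data.frame
# with 1-based inclusive start/end, or NULL.
normalize_mask <- function(mask) {
  if (is.null(mask)) return(NULL)
  if (is.character(mask) && length(mask) == 1L) mask <- read_mask(mask)
  if (is(mask, "GRanges")) {
    mask <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(mask)),
      start = BiocGenerics::start(mask),
      end = BiocGenerics::end(mask),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(mask)),
            all(mask$end >= mask$start))
  mask
}

#' Read a BED mask of regions to exclude
#'
#' @param path BED path (0-based half-open on disk; returned 1-based
#'   inclusive).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
read_mask <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Export a strand of a track as bedGraph
#'
#' Adjacent equal-value runs are merged; zero runs are omitted. Files are
#' 0-based half-open per the bedGraph standard.
#'
#' @param track A `trael_track`.
#' @param strand `"F"` or `"R"`.
#' @param path Output path.
#' @param keep_zero Include zero-valued runs (default `FALSE`).
#' @return `path`, invisibly.
#' @export
export_bedgraph <- function(track, strand = c("F", "R"), path,
                            keep_zero = FALSE) {
  strand <- match.arg(strand)
  grl <- lapply(names(track$counts), function(ch) {
    v <- track$counts[[ch]][[strand]]
    r <- S4Vectors::Rle(v)
    st <- cumsum(c(1L, S4Vectors::runLength(r)))
    st <- st[-length(st)]
    en <- st + S4Vectors::runLength(r) - 1L
    val <- S4Vectors::runValue(r)
    keep <- if (keep_zero) rep(TRUE, length(val)) else val != 0
    GenomicRanges::GRanges(rep(ch, sum(keep)),
                           IRanges::IRanges(st[keep], en[keep]),
                           score = val[keep])
  })
  gr <- suppressWarnings(do.call(c, grl))
  GenomeInfoDb::seqlengths(gr) <- track$seqlengths[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file back into a strand of a track
#'
#' Inverse of [export_bedgraph()] given the contig lengths.
#'
#' @param path_f,path_r bedGraph paths for the F and R strands (either may
#'   be `NULL` for an all-zero strand).
#' @param seqlengths Named contig lengths.
#' @param normalized Normalisation flag to record (default `"raw"`).
#' @return A `trael_track`.
#' @export
read_bedgraph_track <- function(path_f, path_r, seqlengths,
                                normalized = "raw") {
  seqlengths <- as_seqlengths(seqlengths)
  one <- function(path) {
    out <- lapply(seqlengths, function(L) numeric(L))
    if (!is.null(path)) {
      gr <- rtracklayer::import(path, format = "bedGraph")
      ch <- as.character(GenomicRanges::seqnames(gr))
      st <- BiocGenerics::start(gr)
      en <- BiocGenerics::end(gr)
      sc <- gr$score
      for (i in seq_along(gr)) {
        out[[ch[i]]][st[i]:en[i]] <- sc[i]
      }
    }
    out
  }
  f <- one(path_f)
  r <- one(path_r)
  counts <- setNames(lapply(names(seqlengths), function(ch) {
    list(F = f[[ch]], R = r[[ch]])
  }), names(seqlengths))
  track_from_counts(counts, normalized = normalized)
}
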