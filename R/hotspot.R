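#' Detection parameters for interval and peak calling
#'
#' @param z SD multiplier for interval detection above background
#'   (default 2: an interval is detected when its count is at least the
#'   background mean plus 2 background SDs).
#' @param n_background Number of random background intervals sampled per
#'   distinct query length (default 10000).
#' @param seed Integer seed for background sampling.
#' @param local_flank Span (bp) each side of a candidate base used for the
#'   local background in peak calling (default 2000).
#' @param peak_z SD multiplier for stall-peak calling (default 5).
#' @return list of class `trael_detection_params`.
#' @export
detection_params <- function(z = 2, n_background = 10000L, seed = 1L,
                             local_flank = 2000L, peak_z = 5) {
  stopifnot(z > 0, n_background >= 100, local_flank >= 1, peak_z > 0)
  structure(list(z = z, n_background = as.integer(n_background),
                 seed = as.integer(seed),
                 local_flank = as.integer(local_flank), peak_z = peak_z),
            class = "trael_detection_params")
}

#' Sum track counts over a set of intervals
#'
#' @param track A `trael_track`.
#' @param intervals data.frame `chrom`, `start`, `end` (1-based inclusive),
#'   GRanges, or BED path. Overlapping intervals are counted independently.
#' @param strand_mode `"both"` (F + R), `"F"` or `"R"`.
#' @return The intervals with a `count` column added.
#' @export
quantify_intervals <- function(track, intervals,
                               strand_mode = c("both", "F", "R")) {
  strand_mode <- match.arg(strand_mode)
  intervals <- normalize_mask(intervals)
  stopifnot(all(intervals$chrom %in% names(track$counts)))
  cs <- lapply(track$counts, function(x) {
    v <- switch(strand_mode, both = x$F + x$R, F = x$F, R = x$R)
    c(0, cumsum(v))
  })
  intervals$count <- vapply(seq_len(nrow(intervals)), function(i) {
    ch <- intervals$chrom[i]
    cs[[ch]][intervals$end[i] + 1L] - cs[[ch]][intervals$start[i]]
  }, numeric(1))
  intervals
}

#' Flag intervals enriched over a sampled background (the 2-SD rule)
#'
#' For each distinct query-interval length, `n_background` length-matched
#' intervals are drawn uniformly from the mappable space (with a fixed
#' seed) and quantified on the same track; a query interval is detected
#' when its count is at least the background mean plus `z` background SDs
#' for its length class.
#'
#' @param counts Interval table with a `count` column, as returned by
#'   [quantify_intervals()].
#' @param track The same `trael_track` the counts came from.
#' @param mappable_space data.frame/GRanges/BED of intervals from which
#'   background may be drawn; should exclude the query intervals and any
#'   masked regions. Must span at least 10 times the total query length.
#' @param params A [detection_params()].
#' @param strand_mode As in [quantify_intervals()].
#' @return The interval table with `bg_mean`, `bg_sd` and `detected`
#'   columns; attribute `"background"` holds the per-length background
#'   summaries.
#' @export
detect_above_background <- function(counts, track, mappable_space,
                                    params = detection_params(),
                                    strand_mode = "both") {
  stopifnot("count" %in% names(counts))
  mappable <- normalize_mask(mappable_space)
  widths <- counts$end - counts$start + 1L
  mw <- mappable$end - mappable$start + 1L
  if (sum(mw) < 10 * sum(widths)) {
    stop("mappable space smaller than 10x the total query length")
  }
  bg_summaries <- list()
  bg_mean <- bg_sd <- rep(NA_real_, nrow(counts))
  with_seed(params$seed, {
    for (w in sort(unique(widths))) {
      fit <- mw - w + 1L
      ok <- which(fit > 0L)
      if (!length(ok)) stop(sprintf("no mappable interval fits width %d", w))
      pick <- sample(ok, params$n_background, replace = TRUE,
                     prob = fit[ok])
      off <- floor(runif(params$n_background) * fit[pick])
      bg <- data.frame(
        chrom = mappable$chrom[pick],
        start = mappable$start[pick] + off,
        end = mappable$start[pick] + off + w - 1L
      )
      bgc <- quantify_intervals(track, bg, strand_mode = strand_mode)$count
      m <- mean(bgc)
      s <- sd(bgc)
      sel <- widths == w
      bg_mean[sel] <- m
      bg_sd[sel] <- s
      bg_summaries[[as.character(w)]] <- c(mean = m, sd = s)
    }
  })
  counts$bg_mean <- bg_mean
  counts$bg_sd <- bg_sd
  counts$detected <- counts$count >= bg_mean + params$z * bg_sd
  attr(counts, "background") <- bg_summaries
  counts
}

#' Call strand-specific stall peaks from a per-base track
#'
#' Replication fork barriers and other stall sites appear as sharp
#' single-nucleotide pileups of reads on the strand opposite to the fork
#' direction. A base qualifies as a peak when its raw count is at least the
#' local mean plus `peak_z` local SDs, the local statistics taken over
#' `local_flank` bp each side of the base, excluding the base itself.
#' Adjacent qualifying bases merge into one peak, reported at the position
#' of the maximum count.
#'
#' @param track A raw (unsmoothed) `trael_track`.
#' @param read_strand `"F"` or `"R"`: the read strand scanned. Reads pile
#'   up on the R strand at stalls on rightward-replicated DNA.
#' @param params A [detection_params()] (uses `local_flank`, `peak_z`).
#' @return data.frame: `chrom`, `pos`, `count`, `local_mean`, `local_sd`.
#' @export
call_stall_peaks <- function(track, read_strand = c("R", "F"),
                             params = detection_params()) {
  read_strand <- match.arg(read_strand)
  fl <- params$local_flank
  out <- list()
  for (ch in names(track$counts)) {
    v <- as.numeric(track$counts[[ch]][[read_strand]])
    L <- length(v)
    if (L < 2L) next
    cs <- c(0, cumsum(v))
    cs2 <- c(0, cumsum(v^2))
    lo <- pmax(seq_len(L) - fl, 1L)
    hi <- pmin(seq_len(L) + fl, L)
    nloc <- hi - lo            # window size minus the excluded centre base
    s1 <- cs[hi + 1L] - cs[lo] - v
    s2 <- cs2[hi + 1L] - cs2[lo] - v^2
    m <- s1 / nloc
    va <- pmax(s2 / nloc - m^2, 0)
    sdl <- sqrt(va)
    qual <- (v - m) >= params$peak_z * sdl & v > m
    if (!any(qual)) next
    r <- S4Vectors::Rle(qual)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r)
    for (k in which(keep)) {
      idx <- starts[k]:ends[k]
      top <- idx[which.max(v[idx])]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, pos = top, count = v[top],
        local_mean = m[top], local_sd = sdl[top], stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      count = numeric(), local_mean = numeric(),
                      local_sd = numeric()))
  }
  do.call(rbind, out)
}
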