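#' Read polarity of windowed counts
#'
#' Read polarity is `(R - F) / (R + F)` per window, where `R` and `F` are
#' the reverse- and forward-mapping read counts. It encodes replication
#' fork directionality: in read-strand space polarity switches from
#' negative to positive at active replication origins. The companion value
#' `percent_reverse = 100 * R / (R + F)` is also reported.
#'
#' @param windows A `trael_windows` data.frame from [window_counts()].
#' @param min_reads Minimum `F + R` for a window's polarity to be defined;
#'   below it the value is `NA` (default 1: polarity is computed wherever
#'   reads exist; raise for sparse libraries).
#' @return The input with `polarity` and `percent_reverse` columns added;
#'   class `trael_polarity`.
#' @examples
#' w <- data.frame(chrom = "chr1", start = 1, end = 1000, F = 25, R = 75)
#' polarity(w)$polarity   # 0.5
#' @export
polarity <- function(windows, min_reads = 1L) {
  stopifnot(all(c("F", "R") %in% names(windows)), min_reads >= 1)
  tot <- windows$F + windows$R
  ok <- tot >= min_reads
  windows$polarity <- ifelse(ok, (windows$R - windows$F) / tot, NA_real_)
  windows$percent_reverse <- ifelse(ok, 100 * windows$R / tot, NA_real_)
  class(windows) <- unique(c("trael_polarity", class(windows)))
  windows
}

#' Call replication origins and termination midpoints from a polarity track
#'
#' The polarity profile is smoothed by a centered rolling mean over
#' `smooth_windows` windows; a negative-to-positive sign crossing is called
#' as an origin when the mean of the `smooth_windows` windows to the right
#' minus the mean of those to the left is at least `min_swing`.
#' Positive-to-negative crossings are reported as termination midpoints
#' under the mirrored condition. Runs of `NA` polarity break the track into
#' segments scanned independently.
#'
#' @param pol A `trael_polarity` data.frame; windows must be contiguous and
#'   ordered within each chromosome.
#' @param smooth_windows Width of the smoothing/flank mean, in windows
#'   (default 5).
#' @param min_swing Minimum right-minus-left mean difference (default 0.5).
#' @return data.frame: `chrom`, `position` (midpoint of the two windows
#'   flanking the crossing), `left_polarity`, `right_polarity`, `swing`,
#'   `type` (`"origin"` or `"termination"`).
#' @export
call_origins <- function(pol, smooth_windows = 5L, min_swing = 0.5) {
  stopifnot("polarity" %in% names(pol))
  sw <- stopifnot_scalar_int(smooth_windows, "smooth_windows", min = 1L)
  out <- list()
  for (ch in unique(pol$chrom)) {
    d <- pol[pol$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) < 2L * sw + 1L) {
      warning(sprintf("chromosome %s shorter than the smoothing span; skipped",
                      ch))
      next
    }
    centers <- (d$start + d$end) / 2
    p <- d$polarity
    # segments of consecutive non-NA windows
    na <- is.na(p)
    seg_id <- cumsum(c(TRUE, diff(na) != 0))
    for (seg in split(seq_along(p), seg_id)) {
      if (na[seg[1L]] || length(seg) < 2L * sw + 1L) next
      s <- as.numeric(stats::filter(p[seg], rep(1 / sw, sw), sides = 2))
      nz <- which(!is.na(s) & s != 0)
      if (length(nz) < 2L) next
      sg <- sign(s[nz])
      cross <- which(sg[-1] * sg[-length(sg)] < 0)
      for (ci in cross) {
        i <- nz[ci]        # last window of the left sign (segment-local)
        j <- nz[ci + 1L]   # first window of the right sign
        left_idx <- seg[max(1L, i - sw + 1L):i]
        right_idx <- seg[j:min(length(seg), j + sw - 1L)]
        left_m <- mean(p[left_idx], na.rm = TRUE)
        right_m <- mean(p[right_idx], na.rm = TRUE)
        swing <- right_m - left_m
        type <- if (sg[ci] < 0) "origin" else "termination"
        ok <- if (type == "origin") swing >= min_swing else -swing >= min_swing
        if (!ok) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch,
          position = (centers[seg[i]] + centers[seg[j]]) / 2,
          left_polarity = left_m, right_polarity = right_m,
          swing = abs(swing), type = type, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), position = numeric(),
                      left_polarity = numeric(), right_polarity = numeric(),
                      swing = numeric(), type = character()))
  }
  do.call(rbind, out)
}

#' Compare window polarity between two groups of replicate tracks
#'
#' Per window, polarity means of the two groups are compared by a
#' two-sample t-test (Welch by default), p-values are adjusted by
#' Benjamini-Hochberg across all tested windows, and a window is flagged
#' when the adjusted p-value is below `alpha` *and* the absolute mean
#' difference exceeds `min_delta`. Windows with `NA` polarity in any
#' replicate are excluded from testing.
#'
#' @param group_a,group_b Lists of `trael_polarity` data.frames on an
#'   identical window grid, at least two replicates each.
#' @param alpha Significance level on the BH-adjusted p-value
#'   (default 0.01).
#' @param min_delta Minimum absolute polarity difference (default 0.4).
#' @param var_equal Use the pooled-variance (Student) t-test instead of
#'   Welch (default `FALSE`).
#' @return data.frame: window coordinates, `mean_a`, `mean_b`, `delta`
#'   (`mean_b - mean_a`), `t`, `p`, `padj`, `tested`, `flagged`.
#' @export
compare_groups <- function(group_a, group_b, alpha = 0.01, min_delta = 0.4,
                           var_equal = FALSE) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  grid <- group_a[[1L]][, c("chrom", "start", "end")]
  for (g in c(group_a, group_b)) {
    if (!identical(g[, c("chrom", "start", "end")], grid)) {
      stop("all replicates must share an identical window grid")
    }
  }
  ma <- vapply(group_a, function(g) g$polarity, numeric(nrow(grid)))
  mb <- vapply(group_b, function(g) g$polarity, numeric(nrow(grid)))
  tested <- stats::complete.cases(ma) & stats::complete.cases(mb)

  n <- nrow(grid)
  tstat <- p <- rep(NA_real_, n)
  for (i in which(tested)) {
    ht <- stats::t.test(ma[i, ], mb[i, ], var.equal = var_equal)
    tstat[i] <- unname(ht$statistic)
    p[i] <- ht$p.value
  }
  padj <- rep(NA_real_, n)
  padj[tested] <- stats::p.adjust(p[tested], method = "BH")
  mean_a <- rowMeans(ma)
  mean_b <- rowMeans(mb)
  delta <- mean_b - mean_a
  flagged <- tested & !is.na(padj) & padj < alpha & abs(delta) > min_delta
  data.frame(grid, mean_a = mean_a, mean_b = mean_b, delta = delta,
             t = tstat, p = p, padj = padj, tested = tested,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' MA comparison of windowed counts between two samples
#'
#' Per window and strand: the log2 ratio of library-size-normalised counts
#' (`M`) against the mean log2 normalised count (`A`), with a pseudocount.
#'
#' @param windows_a,windows_b `trael_windows` on the same grid.
#' @param total_a,total_b Library sizes used for normalisation (defaults:
#'   the summed window counts of each sample).
#' @param pseudocount Added before taking logs (default 0.5).
#' @return data.frame: window coordinates, `strand` (`"F"`/`"R"`), `A`, `M`.
#' @export
ma_compare <- function(windows_a, windows_b, total_a = NULL, total_b = NULL,
                       pseudocount = 0.5) {
  grid <- windows_a[, c("chrom", "start", "end")]
  if (!identical(grid, windows_b[, c("chrom", "start", "end")])) {
    stop("windows must share an identical grid")
  }
  if (is.null(total_a)) total_a <- sum(windows_a$F) + sum(windows_a$R)
  if (is.null(total_b)) total_b <- sum(windows_b$F) + sum(windows_b$R)
  scale_a <- 1e6 / total_a
  scale_b <- 1e6 / total_b
  one <- function(strand) {
    a <- windows_a[[strand]] * scale_a + pseudocount
    b <- windows_b[[strand]] * scale_b + pseudocount
    data.frame(grid, strand = strand,
               A = 0.5 * (log2(a) + log2(b)), M = log2(b) - log2(a),
               stringsAsFactors = FALSE)
  }
  rbind(one("F"), one("R"))
}

#' Feature-anchored average profiles
#'
#' Averages per-base track signal across a feature set, in fixed bins
#' around each feature's 5' anchor. Reverse-strand features are
#' coordinate-flipped (and F/R swapped) before averaging, so profiles are
#' in the feature's own orientation; `orientation_mode =
#' "by_replication_direction"` instead orients each feature by the sign of
#' the local polarity from an auxiliary polarity track, and `"none"` keeps
#' genomic orientation for all features.
#'
#' @param track A `trael_track` (typically RPM-normalised).
#' @param features data.frame with `chrom`, `start`, `end`, `strand`, or a
#'   GRanges/BED path.
#' @param flank Half-width of the profiled region around the anchor, bp.
#' @param bin_size Non-overlapping bin width, bp; must divide `2 * flank`.
#' @param orientation_mode `"by_feature_strand"` (default), `"none"` or
#'   `"by_replication_direction"`.
#' @param polarity_track A `trael_polarity` supplying local polarity, used
#'   only for `"by_replication_direction"` (features whose window has `NA`
#'   polarity are dropped).
#' @return data.frame: `bin_start` (bin offset from anchor, bp, left edge),
#'   `F`, `R` (mean signal per bin across features), `n_features`.
#' @export
metaprofile <- function(track, features, flank, bin_size,
                        orientation_mode = c("by_feature_strand", "none",
                                             "by_replication_direction"),
                        polarity_track = NULL) {
  orientation_mode <- match.arg(orientation_mode)
  if (is.character(features) && length(features) == 1L) {
    gr <- rtracklayer::import(features, format = "BED")
    features <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
      strand = as.character(BiocGenerics::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else if (is(features, "GRanges")) {
    features <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(features)),
      start = BiocGenerics::start(features),
      end = BiocGenerics::end(features),
      strand = as.character(BiocGenerics::strand(features)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(features)))
  if ((2 * flank) %% bin_size != 0) {
    stop("bin_size must divide 2 * flank")
  }
  nbins <- 2L * flank %/% bin_size

  flip <- switch(
    orientation_mode,
    none = rep(FALSE, nrow(features)),
    by_feature_strand = features$strand == "-",
    by_replication_direction = {
      if (is.null(polarity_track)) {
        stop("polarity_track required for by_replication_direction")
      }
      local_pol <- feature_polarity(features, polarity_track)
      keep <- !is.na(local_pol)
      features <- features[keep, , drop = FALSE]
      # leftward-replicated loci (negative polarity) are mirrored
      local_pol[keep] < 0
    }
  )

  anchor <- ifelse(features$strand == "-" &
                     orientation_mode == "by_feature_strand",
                   features$end, features$start)
  L <- track$seqlengths[features$chrom]
  keep <- anchor - flank >= 1 & anchor + flank - 1 <= L
  features <- features[keep, , drop = FALSE]
  anchor <- anchor[keep]
  flip <- flip[keep]
  if (!nrow(features)) stop("no features remain after flank filtering")

  accF <- accR <- matrix(0, nrow(features), nbins)
  for (i in seq_len(nrow(features))) {
    ch <- features$chrom[i]
    idx <- (anchor[i] - flank):(anchor[i] + flank - 1L)
    f <- track$counts[[ch]]$F[idx]
    r <- track$counts[[ch]]$R[idx]
    if (flip[i]) {
      tmp <- rev(r); r <- rev(f); f <- tmp   # mirror and swap strands
    }
    bins <- rep(seq_len(nbins), each = bin_size)
    accF[i, ] <- vapply(split(f, bins), sum, numeric(1))
    accR[i, ] <- vapply(split(r, bins), sum, numeric(1))
  }
  data.frame(
    bin_start = seq(-flank, flank - bin_size, by = bin_size),
    F = colMeans(accF), R = colMeans(accR), n_features = nrow(features)
  )
}

# local polarity at each feature's midpoint, from a polarity window table
feature_polarity <- function(features, pol) {
  mid <- (features$start + features$end) / 2
  vapply(seq_len(nrow(features)), function(i) {
    d <- pol[pol$chrom == features$chrom[i] &
               pol$start <= mid[i] & pol$end >= mid[i], , drop = FALSE]
    if (!nrow(d)) return(NA_real_)
    mean(d$polarity, na.rm = TRUE)
  }, numeric(1))
}
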