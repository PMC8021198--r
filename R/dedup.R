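#' Remove PCR duplicates using mapping position, orientation and UMI
#'
#' Alignments sharing an identical key — reference name, leftmost mapping
#' position, read orientation and UMI — are collapsed to a single record
#' (the first encountered in input order). The UMI is recovered from the
#' read identifier, where preprocessing appended it after a delimiter.
#' UMI comparison is exact; no edit-distance clustering is attempted.
#'
#' @param aln Alignment data.frame (`qname`, `rname`, `pos`, `strand`, ...)
#'   or a SAM/BAM path (read with [read_alignments()]; unmapped and
#'   secondary records are excluded by the reader).
#' @param umi_delim Delimiter before the UMI suffix in `qname` (default
#'   `":"`).
#' @param min_mapq Optional MAPQ threshold applied when `aln` has a `mapq`
#'   column (default `NULL`: retain all primary alignments).
#' @return list of class `trael_dedup`: `alignments` (retained records, in
#'   input order, with a `umi` column added) and `stats`
#'   (`input`, `retained`, `duplicates`).
#' @examples
#' aln <- data.frame(qname = c("a:AAAA", "b:AAAA", "c:CCCC"),
#'                   rname = "chr1", pos = 100, strand = "+",
#'                   mapped = TRUE)
#' dedup_alignments(aln)$stats
#' @export
dedup_alignments <- function(aln, umi_delim = ":", min_mapq = NULL) {
  if (is.character(aln) && length(aln) == 1L) aln <- read_alignments(aln)
  stopifnot(all(c("qname", "rname", "pos", "strand") %in% names(aln)))
  if (!is.null(min_mapq) && !is.null(aln$mapq)) {
    aln <- aln[!is.na(aln$mapq) & aln$mapq >= min_mapq, , drop = FALSE]
  }
  n <- nrow(aln)
  pattern <- paste0(".*", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", umi_delim),
                    "([ACGTN]+)$")
  has_umi <- grepl(pattern, aln$qname)
  if (!all(has_umi)) {
    bad <- aln$qname[!has_umi][1L]
    stop(sprintf("read ID lacks a UMI suffix ('%s' delimiter): %s",
                 umi_delim, bad))
  }
  umi <- sub(pattern, "\\1", aln$qname)
  key <- paste(aln$rname, aln$pos, aln$strand, umi, sep = "\r")
  keep <- !duplicated(key)
  out <- aln[keep, , drop = FALSE]
  out$umi <- umi[keep]
  stats <- list(input = n, retained = sum(keep), duplicates = n - sum(keep))
  structure(list(alignments = out, stats = stats), class = "trael_dedup")
}

#' @export
print.trael_dedup <- function(x, ...) {
  s <- x$stats
  cat(sprintf("UMI deduplication: %d in, %d retained, %d duplicates (%.1f%%)\n",
              s$input, s$retained, s$duplicates,
              if (s$input > 0) 100 * s$duplicates / s$input else 0))
  invisible(x)
}
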