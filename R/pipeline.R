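#' Run the TrAEL-seq processing pipeline on raw reads
#'
#' Convenience wrapper chaining the core stages on in-memory data:
#' preprocessing (UMI extraction, optional demultiplexing, capped poly-T
#' trimming), alignment (the exact mapper, or a supplied alignment table
#' such as a simulator truth SAM), UMI deduplication, and conversion to a
#' strand-specific single-nucleotide 3'-end track.
#'
#' @param reads data.frame (`id`, `seq`, `qual`) of raw reads, or a FASTQ
#'   path.
#' @param genome A [Biostrings::DNAStringSet].
#' @param layout A [trael_layout()].
#' @param alignments Optional pre-computed alignment table (`qname` must
#'   carry the UMI suffix); when `NULL`, reads are aligned with
#'   [exact_map()] after preprocessing.
#' @return list of class `trael_pipeline`: per-barcode (or `"all"`) lists
#'   with elements `track` (`trael_track`), `dedup` stats and `alignments`,
#'   plus the preprocessing `summary`.
#' @export
trael_pipeline <- function(reads, genome, layout = trael_layout(),
                           alignments = NULL) {
  pre <- preprocess_fastq(reads, layout)
  samples <- lapply(pre$reads, function(rd) {
    aln <- if (is.null(alignments)) {
      exact_map(rd, genome)
    } else {
      alignments[alignments$qname %in% rd$id, , drop = FALSE]
    }
    aln <- aln[aln$mapped, , drop = FALSE]
    dd <- dedup_alignments(aln, umi_delim = layout$umi_delim)
    ep <- alignments_to_endpoints(dd)
    list(track = build_track(ep, genome), dedup = dd$stats,
         alignments = dd$alignments)
  })
  structure(list(samples = samples, preprocess = pre$summary),
            class = "trael_pipeline")
}

#' @export
print.trael_pipeline <- function(x, ...) {
  cat("TrAEL-seq pipeline run\n")
  for (nm in names(x$samples)) {
    s <- x$samples[[nm]]
    cat(sprintf("  %s: %d alignments in, %d retained, %.0f ends\n",
                nm, s$dedup$input, s$dedup$retained,
                s$track$total_mapped))
  }
  invisible(x)
}
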