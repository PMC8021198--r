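#' Describe the fixed prefix structure of a TrAEL-seq read
#'
#' TrAEL-seq reads start with a fixed-structure prefix:
#' an 8-nt unique molecular identifier (UMI), optionally a 4-nt sample
#' barcode, then the poly-T image of the TdT-added A-tail, then the
#' genome-derived insert. The read structure is
#' `UMI [barcode] (T)n insert`, and trimming removes at most `polyT_cap`
#' leading T bases after the UMI/barcode because the A-tail cannot be
#' distinguished from genome-encoded A's.
#'
#' @param umi_len Number of leading random bases forming the UMI (default 8).
#' @param barcodes Optional character vector of fixed-length sample barcodes
#'   over A/C/G/T (e.g. `c("AGTC", "GACT")` for paired-sample libraries).
#'   `NULL` for unbarcoded libraries.
#' @param polyT_cap Maximum number of leading T bases removed after the
#'   UMI/barcode (default 3).
#' @param umi_delim Delimiter inserted between the original read identifier
#'   and the UMI (default `":"`; survives aligners that truncate read names
#'   at whitespace).
#'
#' @return An object of class `trael_layout`.
#' @examples
#' trael_layout()                                  # standard library
#' trael_layout(barcodes = c("AGTC", "GACT"))      # paired barcoded library
#' @export
trael_layout <- function(umi_len = 8L, barcodes = NULL, polyT_cap = 3L,
                         umi_delim = ":") {
  umi_len <- stopifnot_scalar_int(umi_len, "umi_len", min = 0L)
  polyT_cap <- stopifnot_scalar_int(polyT_cap, "polyT_cap", min = 0L)
  if (!is.null(barcodes)) {
    barcodes <- as.character(barcodes)
    if (length(barcodes) == 0L) barcodes <- NULL
  }
  if (!is.null(barcodes)) {
    if (anyDuplicated(barcodes)) stop("barcodes must be pairwise distinct")
    if (length(unique(nchar(barcodes))) != 1L) {
      stop("all barcodes must have the same length")
    }
    if (any(grepl("[^ACGT]", barcodes))) {
      stop("barcodes must be strings over A/C/G/T")
    }
  }
  structure(
    list(umi_len = umi_len, barcodes = barcodes, polyT_cap = polyT_cap,
         umi_delim = umi_delim,
         barcode_len = if (is.null(barcodes)) 0L else nchar(barcodes[[1L]])),
    class = "trael_layout"
  )
}

#' @export
print.trael_layout <- function(x, ...) {
  cat("TrAEL-seq read layout\n")
  cat("  UMI length :", x$umi_len, "\n")
  cat("  barcodes   :",
      if (is.null(x$barcodes)) "(none)" else paste(x$barcodes, collapse = ", "),
      "\n")
  cat("  poly-T cap :", x$polyT_cap, "\n")
  invisible(x)
}

#' Parse raw reads into UMI, barcode, trimmed poly-T and insert
#'
#' Splits each read according to a [trael_layout()]: the first `umi_len`
#' bases are the UMI, the next `barcode_len` bases are matched exactly
#' against the barcode set (a mismatch or an N gives `"unassigned"`), and
#' then up to `polyT_cap` leading T bases are removed. Qualities are trimmed
#' in lockstep. Reads shorter than the fixed prefix (UMI + barcode) are
#' flagged as dropped, not raised as errors.
#'
#' Only literal `T` counts towards the trimmed run; an `N` terminates it,
#' since an N cannot be confidently assigned to the tail.
#'
#' @param seq Character vector of read sequences (A/C/G/T/N).
#' @param qual Character vector of quality strings, same lengths as `seq`.
#' @param layout A [trael_layout()].
#' @param id Optional character vector of read identifiers; the UMI is
#'   appended to each as `id<delim>UMI`.
#'
#' @return A data.frame with one row per input read: `id`, `umi`, `barcode`
#'   (`NA` for unbarcoded layouts), `n_trimmed_T`, `seq`, `qual`, `dropped`.
#'   Dropped reads have `NA` fields apart from `dropped = TRUE`.
#' @examples
#' lay <- trael_layout()
#' parse_reads("ACGTACGTTTTTTGCGA", "IIIIIIIIIIIIIIIII", lay)
#' @export
parse_reads <- function(seq, qual, layout = trael_layout(), id = NULL) {
  stopifnot(length(seq) == length(qual))
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality strings must have matching lengths")
  }
  n <- length(seq)
  if (is.null(id)) id <- sprintf("read%d", seq_len(n))
  prefix <- layout$umi_len + layout$barcode_len
  dropped <- nchar(seq) <= prefix

  umi <- barcode <- rep(NA_character_, n)
  n_trim <- rep(NA_integer_, n)
  out_seq <- out_qual <- out_id <- rep(NA_character_, n)

  ok <- !dropped
  if (any(ok)) {
    umi[ok] <- substr(seq[ok], 1L, layout$umi_len)
    if (layout$barcode_len > 0L) {
      bc <- substr(seq[ok], layout$umi_len + 1L, prefix)
      barcode[ok] <- ifelse(bc %in% layout$barcodes, bc, "unassigned")
    }
    rest <- substring(seq[ok], prefix + 1L)
    rest_q <- substring(qual[ok], prefix + 1L)
    run <- leading_t_run(rest)
    nt <- pmin(run, layout$polyT_cap)
    n_trim[ok] <- nt
    out_seq[ok] <- substring(rest, nt + 1L)
    out_qual[ok] <- substring(rest_q, nt + 1L)
    out_id[ok] <- if (layout$umi_len > 0L) {
      paste0(id[ok], layout$umi_delim, umi[ok])
    } else {
      id[ok]
    }
  }

  data.frame(
    id = out_id, umi = umi, barcode = barcode, n_trimmed_T = n_trim,
    seq = out_seq, qual = out_qual, dropped = dropped,
    stringsAsFactors = FALSE
  )
}

#' Preprocess a TrAEL-seq FASTQ: UMI extraction, demultiplexing, poly-T trim
#'
#' Applies [parse_reads()] to a whole library and partitions the results by
#' barcode. Every retained record carries its UMI appended to the read
#' identifier so that deduplication can recover it after alignment.
#'
#' @param input Either a path to a FASTQ file (gzip accepted) or a
#'   data.frame with columns `id`, `seq`, `qual`.
#' @param layout A [trael_layout()].
#' @param out_prefix Optional path prefix; if given, one gzipped FASTQ per
#'   barcode (or a single FASTQ for unbarcoded layouts) is written as
#'   `<prefix>_<barcode>.fastq.gz` / `<prefix>.fastq.gz`, plus a TSV summary
#'   `<prefix>_summary.tsv`.
#'
#' @return A list of class `trael_preprocess`:
#' \describe{
#'   \item{reads}{named list of data.frames (`id`, `seq`, `qual`,
#'     `n_trimmed_T`, `umi`), one per barcode or `"all"`.}
#'   \item{summary}{counts: `reads_in`, `reads_out`, `reads_dropped`,
#'     `reads_unassigned`, and the trimmed-T histogram.}
#'   \item{files}{paths written, if `out_prefix` was given.}
#' }
#' @export
preprocess_fastq <- function(input, layout = trael_layout(), out_prefix = NULL) {
  if (is.character(input) && length(input) == 1L) {
    input <- read_fastq(input)
  }
  stopifnot(is.data.frame(input), all(c("id", "seq", "qual") %in% names(input)))

  parsed <- parse_reads(input$seq, input$qual, layout, id = input$id)
  n_in <- nrow(parsed)
  dropped <- sum(parsed$dropped)

  kept <- parsed[!parsed$dropped, , drop = FALSE]
  unassigned <- 0L
  if (layout$barcode_len > 0L) {
    unassigned <- sum(kept$barcode == "unassigned")
    kept <- kept[kept$barcode != "unassigned", , drop = FALSE]
    groups <- split(kept, factor(kept$barcode, levels = layout$barcodes))
  } else {
    groups <- list(all = kept)
  }
  groups <- lapply(groups, function(g) {
    g[, c("id", "seq", "qual", "n_trimmed_T", "umi"), drop = FALSE]
  })

  hist_t <- table(factor(kept$n_trimmed_T, levels = 0:layout$polyT_cap))
  summary <- list(
    reads_in = n_in,
    reads_out = nrow(kept),
    reads_dropped = dropped,
    reads_unassigned = unassigned,
    trimmed_T_histogram = setNames(as.integer(hist_t), names(hist_t))
  )
  stopifnot(summary$reads_out + summary$reads_dropped +
              summary$reads_unassigned == summary$reads_in)

  files <- NULL
  if (!is.null(out_prefix)) {
    files <- character(0)
    for (nm in names(groups)) {
      path <- if (identical(nm, "all")) {
        paste0(out_prefix, ".fastq.gz")
      } else {
        paste0(out_prefix, "_", nm, ".fastq.gz")
      }
      write_fastq(groups[[nm]], path)
      files <- c(files, path)
    }
    sm <- paste0(out_prefix, "_summary.tsv")
    df <- data.frame(
      metric = c("reads_in", "reads_out", "reads_dropped", "reads_unassigned",
                 paste0("trimmed_T_", names(summary$trimmed_T_histogram))),
      value = c(n_in, summary$reads_out, dropped, unassigned,
                unname(summary$trimmed_T_histogram))
    )
    write.table(df, sm, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, sm)
  }

  structure(list(reads = groups, summary = summary, files = files),
            class = "trael_preprocess")
}

#' @export
print.trael_preprocess <- function(x, ...) {
  s <- x$summary
  cat("TrAEL-seq preprocessing summary\n")
  cat(sprintf("  reads in        : %d\n", s$reads_in))
  cat(sprintf("  reads retained  : %d\n", s$reads_out))
  cat(sprintf("  reads dropped   : %d\n", s$reads_dropped))
  cat(sprintf("  unassigned      : %d\n", s$reads_unassigned))
  cat("  trimmed-T histogram:",
      paste(sprintf("%s:%d", names(s$trimmed_T_histogram),
                    s$trimmed_T_histogram), collapse = "  "), "\n")
  invisible(x)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path (gzip accepted).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
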