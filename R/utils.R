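#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rpois sd complete.cases
#'   p.adjust pt t.test
#' @importFrom utils head tail write.table read.table
#' @importFrom methods is
#' @importFrom stats setNames
NULL

# Reverse-complement a character vector of DNA sequences (delegates to
# Biostrings; empty strings pass through).
revcomp_chr <- function(x) {
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Length of the leading run of literal 'T' in each string; an 'N' (or any
# non-T base) terminates the run.
leading_t_run <- function(x) {
  m <- regexpr("^T*", x)
  attr(m, "match.length")
}

stopifnot_scalar_int <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# seqlengths argument normalisation: named numeric vector of contig lengths.
as_seqlengths <- function(x) {
  if (is(x, "DNAStringSet")) {
    setNames(Biostrings::width(x), names(x))
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("'seqlengths' must be a named numeric vector or a DNAStringSet")
  }
}
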