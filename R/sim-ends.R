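#' Describe a replication model for end simulation
#'
#' TrAEL-seq replication signal comes predominantly from the leading-strand
#' 3' end of the fork, so the strand of a sampled end encodes fork
#' direction: a rightward-moving fork exposes a forward-strand 3' end
#' (sequenced as a reverse-mapping read), a leftward fork the opposite.
#' Fork direction at a position is deterministic: away from the nearest
#' origin, with the boundary at the midpoint between adjacent origins.
#' `polarity_strength` is the probability that a sampled end's strand
#' matches that deterministic assignment; windowed read polarity then
#' plateaus at `2 * polarity_strength - 1`. The default 0.8 reflects
#' libraries in which up to ~90% of reads derive from the leading strand.
#'
#' Stall sites are point masses: `weight` is the expected share of reads
#' relative to the uniform background (which has total weight 1), and their
#' strand is fixed (a fork stalled moving rightward accumulates
#' forward-strand 3' ends, i.e. reverse-mapping reads).
#'
#' @param origins data.frame with columns `pos` and optionally `weight`
#'   (firing weight, recorded but not used by the deterministic midpoint
#'   rule), or a numeric vector of positions.
#' @param polarity_strength Probability in `[0, 1]` (default 0.8).
#' @param stall_sites Optional data.frame with columns `pos`, `strand`,
#'   `weight`.
#' @return An object of class `trael_replication_model`.
#' @export
replication_model <- function(origins, polarity_strength = 0.8,
                              stall_sites = NULL) {
  if (is.numeric(origins)) origins <- data.frame(pos = origins)
  stopifnot(is.data.frame(origins), "pos" %in% names(origins))
  if (is.null(origins$weight)) origins$weight <- 1
  origins <- origins[order(origins$pos), , drop = FALSE]
  stopifnot(polarity_strength >= 0, polarity_strength <= 1)
  if (!is.null(stall_sites)) {
    stopifnot(all(c("pos", "strand", "weight") %in% names(stall_sites)),
              all(stall_sites$weight >= 0),
              all(stall_sites$strand %in% c("+", "-")))
  }
  structure(list(origins = origins, polarity_strength = polarity_strength,
                 stall_sites = stall_sites),
            class = "trael_replication_model")
}

# Deterministic fork direction at positions `pos`: +1 for rightward
# (replicated by the origin to the left, or the nearest origin), -1 for
# leftward. Boundaries at midpoints between adjacent origins; left of the
# first origin forks move leftward, right of the last rightward.
fork_direction <- function(pos, origin_pos) {
  origin_pos <- sort(origin_pos)
  d <- vapply(pos, function(p) {
    i <- which.min(abs(origin_pos - p))
    if (p >= origin_pos[i]) 1 else -1
  }, numeric(1))
  d
}

#' Sample replication-derived 3' ends
#'
#' Positions are drawn uniformly along the contig (plus stall-site point
#' masses by weight); each position's end strand follows the model's
#' deterministic fork direction with probability `polarity_strength` and is
#' flipped otherwise. Stall ends always sit at the stall position with the
#' stated strand.
#'
#' @param model A [replication_model()].
#' @param genome_length Length of the (single) contig simulated.
#' @param n Number of ends.
#' @param seed Integer seed or `NULL`.
#' @param chrom Contig name (default `"chr1"`).
#' @return data.frame (`chrom`, `pos`, `strand`, `source`): strand `"+"`
#'   is a forward-strand 3' end (rightward fork), `"-"` a reverse-strand
#'   end; `source` is `"replication"` or `"stall"`.
#' @export
sample_replication_ends <- function(model, genome_length, n, seed = NULL,
                                    chrom = "chr1") {
  stopifnot(inherits(model, "trael_replication_model"), n >= 1)
  with_seed(seed, {
    w_stall <- if (is.null(model$stall_sites)) numeric(0) else model$stall_sites$weight
    probs <- c(1, w_stall)
    comp <- sample.int(length(probs), n, replace = TRUE, prob = probs)
    is_stall <- comp > 1L

    pos <- integer(n)
    strand <- character(n)
    n_rep <- sum(!is_stall)
    if (n_rep > 0L) {
      p <- sample.int(genome_length, n_rep, replace = TRUE)
      dir <- fork_direction(p, model$origins$pos)
      match_dir <- rbinom(n_rep, 1L, model$polarity_strength) == 1L
      eff <- ifelse(match_dir, dir, -dir)
      pos[!is_stall] <- p
      strand[!is_stall] <- ifelse(eff > 0, "+", "-")
    }
    if (any(is_stall)) {
      idx <- comp[is_stall] - 1L
      pos[is_stall] <- model$stall_sites$pos[idx]
      strand[is_stall] <- model$stall_sites$strand[idx]
    }
    data.frame(chrom = chrom, pos = pos, strand = strand,
               source = ifelse(is_stall, "stall", "replication"),
               stringsAsFactors = FALSE)
  })
}

#' Sample 3' ends around double-strand-break hotspots
#'
#' A DSB cuts both strands, and after resection TrAEL-seq still maps the 3'
#' ends at the original break site, so both end strands are emitted
#' symmetrically. Positions scatter around each hotspot centre by a rounded
#' normal with the hotspot's dispersion; hotspots are chosen proportional
#' to their weights.
#'
#' @param hotspots data.frame with columns `center`, `weight`, `dispersion`
#'   (bp SD; 0 for point hotspots).
#' @param n Number of ends.
#' @param seed Integer seed or `NULL`.
#' @param genome_length Optional contig length for clipping positions.
#' @param chrom Contig name (default `"chr1"`).
#' @return data.frame (`chrom`, `pos`, `strand`, `source`, `hotspot`), where
#'   `hotspot` is the row index of the generating hotspot.
#' @export
sample_hotspot_ends <- function(hotspots, n, seed = NULL,
                                genome_length = NULL, chrom = "chr1") {
  stopifnot(all(c("center", "weight", "dispersion") %in% names(hotspots)),
            n >= 1)
  with_seed(seed, {
    idx <- sample.int(nrow(hotspots), n, replace = TRUE,
                      prob = hotspots$weight)
    pos <- hotspots$center[idx] +
      as.integer(round(rnorm(n, 0, hotspots$dispersion[idx])))
    if (!is.null(genome_length)) {
      pos <- pmin(pmax(pos, 1L), genome_length)
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    data.frame(chrom = chrom, pos = pos, strand = strand,
               source = "hotspot", hotspot = idx, stringsAsFactors = FALSE)
  })
}

#' TdT tail-length model
#'
#' Terminal transferase adds short A-tails to 3' ends before adaptor
#' ligation. The default distribution is uniform over 2-4 nt (the average
#' tail observed in libraries); `preset = "short"` gives uniform over
#' 1-3 nt as measured on an in vitro substrate.
#'
#' @param lengths Integer support of the tail-length distribution.
#' @param prob Probabilities (default uniform).
#' @param preset `"default"` (uniform 2:4) or `"short"` (uniform 1:3);
#'   ignored when `lengths` is given.
#' @return An object of class `trael_tail_model`.
#' @export
tail_model <- function(lengths = NULL, prob = NULL, preset = "default") {
  if (is.null(lengths)) {
    lengths <- switch(preset, default = 2:4, short = 1:3,
                      stop("unknown preset"))
  }
  stopifnot(all(lengths >= 0))
  if (is.null(prob)) prob <- rep(1 / length(lengths), length(lengths))
  stopifnot(length(prob) == length(lengths), abs(sum(prob) - 1) < 1e-8)
  structure(list(lengths = as.integer(lengths), prob = prob),
            class = "trael_tail_model")
}
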