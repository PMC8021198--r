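test_that("read polarity follows (R - F) / (R + F) with NA below min_reads", {
  w <- data.frame(chrom = "chr1", start = c(1, 1001, 2001, 3001),
                  end = c(1000, 2000, 3000, 4000),
                  F = c(25, 50, 0, 2), R = c(75, 50, 0, 1))
  p <- polarity(w)
  expect_equal(p$polarity, c(0.5, 0, NA, -1 / 3))
  expect_equal(p$percent_reverse, c(75, 50, NA, 100 / 3))
  # percent-reverse consistency: p == 2 * pr / 100 - 1 wherever defined
  ok <- !is.na(p$polarity)
  expect_equal(p$polarity[ok], 2 * p$percent_reverse[ok] / 100 - 1)
  # min_reads raises the definedness threshold
  p4 <- polarity(w, min_reads = 4)
  expect_equal(is.na(p4$polarity), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("origins are called at negative-to-positive polarity switches", {
  # synthetic step track: -0.7 plateau then +0.7 plateau, switch at 50 kb
  mkstep <- function(noise = 0) {
    n <- 100
    start <- seq(1, by = 1000, length.out = n)
    pol <- c(rep(-0.7, 50), rep(0.7, 50)) + noise * rnorm(n, 0, 0.02)
    data.frame(chrom = "chr1", start = start, end = start + 999,
               F = 100 * (1 - pol) / 2, R = 100 * (1 + pol) / 2)
  }
  p <- polarity(mkstep())
  calls <- call_origins(p)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "origin")
  # the step lies between windows 50 and 51 (centres 49500.5 / 50500.5)
  expect_lt(abs(calls$position - 50000), 1000)

  # constant track: no calls
  flat <- mkstep()
  flat$R <- 60; flat$F <- 40
  expect_equal(nrow(call_origins(polarity(flat))), 0L)

  # a track shorter than the smoothing span warns and returns nothing
  short <- polarity(mkstep())[1:5, ]
  expect_warning(out <- call_origins(short, smooth_windows = 5), "smoothing")
  expect_equal(nrow(out), 0L)
})

test_that("negating a polarity track swaps origin and termination calls", {
  set.seed(61)
  for (i in 1:5) {
    n <- 200
    start <- seq(1, by = 1000, length.out = n)
    # random piecewise profile with several sign changes
    breaks <- sort(sample(20:180, 4))
    lev <- runif(5, -0.8, 0.8)
    pol <- rep(lev, times = diff(c(0, breaks, n)))
    pol <- pol + rnorm(n, 0, 0.03)
    w <- data.frame(chrom = "chr1", start = start, end = start + 999,
                    F = 100 * (1 - pol) / 2, R = 100 * (1 + pol) / 2)
    p1 <- polarity(w)
    w2 <- w; w2$F <- w$R; w2$R <- w$F    # negated polarity
    p2 <- polarity(w2)
    c1 <- call_origins(p1, min_swing = 0.3)
    c2 <- call_origins(p2, min_swing = 0.3)
    expect_equal(c1$position[c1$type == "origin"],
                 c2$position[c2$type == "termination"])
    expect_equal(c1$position[c1$type == "termination"],
                 c2$position[c2$type == "origin"])
  }
})

test_that("NA runs break the track into independently scanned segments", {
  n <- 60
  start <- seq(1, by = 1000, length.out = n)
  pol <- c(rep(-0.7, 20), rep(NA, 5), rep(0.7, 35))
  w <- data.frame(chrom = "chr1", start = start, end = start + 999,
                  F = ifelse(is.na(pol), 0, 100 * (1 - pol) / 2),
                  R = ifelse(is.na(pol), 0, 100 * (1 + pol) / 2))
  # the sign change happens across the NA gap, so no crossing is observable
  expect_equal(nrow(call_origins(polarity(w))), 0L)
})

test_that("group comparison flags only large, significant polarity changes", {
  mkrep <- function(pol, reads = 200, seed) {
    set.seed(seed)
    n <- length(pol)
    R <- rbinom(n, reads, (1 + pol) / 2)
    w <- data.frame(chrom = "chr1",
                    start = seq(1, by = 1000, length.out = n),
                    end = seq(1000, by = 1000, length.out = n),
                    F = reads - R, R = R)
    polarity(w)
  }
  base <- rep(0, 300)

  # identical groups: nothing flagged
  ga <- lapply(1:4, function(s) mkrep(base, seed = s))
  gb <- lapply(5:8, function(s) mkrep(base, seed = s))
  cmp0 <- compare_groups(ga, gb)
  expect_false(any(cmp0$flagged))

  # a true shift of 0.6 in 5% of windows is recovered
  alt <- base
  altered <- seq(10, 300, by = 20)
  alt[altered] <- 0.6
  gb2 <- lapply(9:12, function(s) mkrep(alt, seed = s))
  cmp1 <- compare_groups(ga, gb2)
  hit <- which(cmp1$flagged)
  expect_gte(sum(altered %in% hit), 0.9 * length(altered))
  expect_lte(sum(!(hit %in% altered)), 3)

  # a significant but small difference (0.3) fails the min_delta filter;
  # high-coverage replicates keep the estimated delta well below 0.4
  ga3 <- lapply(21:24, function(s) mkrep(base, reads = 2000, seed = s))
  gb3 <- lapply(13:16, function(s) mkrep(base + 0.3, reads = 2000, seed = s))
  cmp3 <- compare_groups(ga3, gb3)
  expect_true(any(cmp3$padj < 0.01, na.rm = TRUE))
  expect_false(any(cmp3$flagged))

  # windows NA in any replicate are excluded from testing
  ga_na <- ga
  ga_na[[1]]$polarity[5] <- NA
  cmpna <- compare_groups(ga_na, gb)
  expect_false(cmpna$tested[5])
  expect_true(is.na(cmpna$padj[5]))
})

test_that("type-I error of group comparison on null data stays below alpha", {
  mkrep <- function(seed, n = 150, reads = 100) {
    set.seed(seed)
    R <- rbinom(n, reads, 0.5)
    polarity(data.frame(chrom = "chr1",
                        start = seq(1, by = 1000, length.out = n),
                        end = seq(1000, by = 1000, length.out = n),
                        F = reads - R, R = R))
  }
  flagged <- 0L
  total <- 0L
  for (run in 1:20) {
    ga <- lapply(run * 100 + 1:4, mkrep)
    gb <- lapply(run * 100 + 5:8, mkrep)
    cmp <- compare_groups(ga, gb)
    flagged <- flagged + sum(cmp$flagged)
    total <- total + sum(cmp$tested)
  }
  expect_lte(flagged / total, 0.01)
})

test_that("MA comparison reports log ratios of normalised window counts", {
  set.seed(71)
  w <- data.frame(chrom = "chr1", start = seq(1, by = 100, length.out = 50),
                  end = seq(100, by = 100, length.out = 50),
                  F = rpois(50, 50), R = rpois(50, 50))
  # identical samples: all ratios zero
  ma0 <- ma_compare(w, w)
  expect_true(all(ma0$M == 0))
  # doubling all counts at equal library size: ratio 1 everywhere
  w2 <- w; w2$F <- 2 * w$F; w2$R <- 2 * w$R
  tot <- sum(w$F) + sum(w$R)
  ma2 <- ma_compare(w, w2, total_a = tot, total_b = tot)
  expect_true(all(abs(ma2$M - 1) < 0.1))
  # with per-sample library normalisation a global doubling cancels out
  ma2n <- ma_compare(w, w2)
  expect_true(all(abs(ma2n$M) < 1e-10))
  # a 10x spiked window ranks first by ratio
  w3 <- w; w3$F[25] <- w$F[25] * 10
  ma3 <- ma_compare(w, w3, total_a = tot, total_b = tot)
  f <- ma3[ma3$strand == "F", ]
  expect_equal(which.max(f$M), 25L)
})

test_that("metaprofiles are feature-anchored and mirror reverse-strand features", {
  L <- 10000
  counts <- list(chr1 = list(F = numeric(L), R = numeric(L)))
  counts$chr1$F[4800] <- 5      # 200 bp upstream of a + feature at 5000
  counts$chr1$R[5100] <- 2
  tr <- track_from_counts(counts)

  feat <- data.frame(chrom = "chr1", start = 5000, end = 5400, strand = "+")
  mp <- metaprofile(tr, feat, flank = 1000, bin_size = 100)
  expect_equal(nrow(mp), 20L)
  # single feature: the profile is its own signal
  expect_equal(mp$F[mp$bin_start == -200], 5)
  expect_equal(mp$R[mp$bin_start == 100], 2)

  # mirror symmetry: a reverse-strand feature whose window holds the
  # strand-swapped, coordinate-reversed signal yields the same profile
  idx <- 4000:5999
  counts2 <- list(chr1 = list(F = numeric(L), R = numeric(L)))
  counts2$chr1$F[idx] <- rev(counts$chr1$R[idx])
  counts2$chr1$R[idx] <- rev(counts$chr1$F[idx])
  tr2 <- track_from_counts(counts2)
  feat2 <- data.frame(chrom = "chr1", start = 4600, end = 5000, strand = "-")
  mp2 <- metaprofile(tr2, feat2, flank = 1000, bin_size = 100)
  expect_equal(mp2$F, mp$F)
  expect_equal(mp2$R, mp$R)

  # features too close to a contig end are dropped
  feat3 <- rbind(feat, data.frame(chrom = "chr1", start = 500, end = 900,
                                  strand = "+"))
  mp3 <- metaprofile(tr, feat3, flank = 1000, bin_size = 100)
  expect_equal(mp3$n_features[1], 1L)

  # orientation by replication direction flips leftward-replicated loci
  pol <- polarity(data.frame(chrom = "chr1",
                             start = seq(1, 9001, by = 1000),
                             end = seq(1000, 10000, by = 1000),
                             F = 90, R = 10))    # polarity < 0 everywhere
  mp4 <- metaprofile(tr, feat, flank = 1000, bin_size = 100,
                     orientation_mode = "by_replication_direction",
                     polarity_track = pol)
  expect_equal(mp4$R[mp4$bin_start == 100], 5)   # mirrored and swapped
})
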