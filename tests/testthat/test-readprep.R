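mk_reads <- function(bases, quals) {
  tibble::tibble(id = paste0("r", seq_along(bases)), desc = "",
                 bases = bases,
                 qual = vapply(quals, phred_string, ""),
                 mate = NA_integer_)
}

test_that("quality trimming removes low-quality flanks and drops short reads", {
  r <- mk_reads("ACGT", list(c(40, 40, 10, 5)))
  out <- quality_trim(r, trim_config(35, window = 1, min_len = 1))
  expect_equal(out$bases, "AC")
  expect_equal(phred_scores(out$qual)[[1]], c(40L, 40L))

  high <- mk_reads("ACGTACGT", list(rep(40, 8)))
  expect_equal(quality_trim(high, trim_config(35, 4, 1))$bases, "ACGTACGT")

  low <- mk_reads("ACGT", list(rep(10, 4)))
  out2 <- quality_trim(low, trim_config(35, 1, 1))
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "n_dropped"), 1L)
})

test_that("the sliding window cuts at the first failing window", {
  # leading/trailing pass, interior quality collapse triggers the window cut
  q <- c(40, 40, 40, 40, 10, 10, 10, 10, 40)
  r <- mk_reads(strrep("A", 9), list(q))
  out <- quality_trim(r, trim_config(30, window = 4, min_len = 1))
  # first failing window starts at base 3 (mean of 40,40,10,10 = 25)
  expect_equal(nchar(out$bases), 2L)
})

test_that("trimming never lengthens reads and threshold 0 is the identity", {
  set.seed(51)
  reads <- mk_reads(vapply(rep(50, 30), random_nt, ""),
                    lapply(1:30, function(i) sample(0:41, 50, TRUE)))
  out <- quality_trim(reads, trim_config(20, 4, 1))
  expect_true(all(nchar(out$bases) <= 50))
  expect_equal(nchar(out$bases), nchar(out$qual))
  id <- quality_trim(reads, trim_config(0, 4, 1))
  expect_equal(id$bases, reads$bases)
})

test_that("canonical kmer counting is strand-aware and skips N", {
  expect_equal(count_kmers("AAAA", k = 3), c(AAA = 2L))
  expect_equal(count_kmers("ACGT", k = 4), c(ACGT = 1L))
  expect_equal(length(count_kmers("AANA", k = 3)), 0L)
  # a read and its reverse complement give identical tables
  set.seed(52)
  s <- random_nt(60)
  expect_equal(count_kmers(s, 25), count_kmers(revcomp(s), 25))
})

test_that("per-read kmer statistics use lower median and sample stdev", {
  reads <- c("AAAAA")
  # engineer a table by hand: kmers AAAA (x2)
  tab <- count_kmers(reads, 4)
  st <- read_kmer_stats(reads, tab, 4)
  expect_equal(st$coverages[[1]], c(2L, 2L))
  expect_equal(st$pct_stdev, 0)

  # [10, 10, 40]: mean 20, sample sd sqrt(300), pct ~ 86.6
  fake <- setNames(c(10L, 10L, 40L), c("AAAA", "AAAC", "AACC"))
  st2 <- read_kmer_stats("AAAACC", fake, 4)
  expect_equal(st2$coverages[[1]], c(10L, 10L, 40L))
  expect_equal(st2$median, 10)
  expect_equal(st2$mean, 20)
  expect_equal(st2$stdev, sqrt(300), tolerance = 1e-9)
  expect_equal(st2$pct_stdev, 100 * sqrt(300) / 20, tolerance = 1e-9)

  # read shorter than k
  st3 <- read_kmer_stats("ACG", fake, 4)
  expect_equal(st3$coverages[[1]], integer())
  expect_equal(unlist(st3[1, c("median", "mean", "stdev", "pct_stdev")],
                      use.names = FALSE), rep(0, 4))
})

test_that("normalization keeps unique reads, filters aberrant profiles", {
  set.seed(53)
  uniq <- mk_reads(vapply(rep(40, 20), random_nt, ""),
                   lapply(1:20, function(i) rep(40, 40)))
  out <- normalize_reads(uniq, norm_config(k = 25, target_cov = 50,
                                           max_pct_stdev = 1e4, seed = 9))
  expect_equal(out$id, uniq$id)   # all medians ~1 <= target: no downsampling

  # the worked example read: pct_stdev 86.6 passes 100, fails 50
  fake <- setNames(c(10L, 10L, 40L), c("AAAA", "AAAC", "AACC"))
  one <- mk_reads("AAAACC", list(rep(40, 6)))
  kept <- normalize_reads(one, norm_config(k = 4, target_cov = 50,
                                           max_pct_stdev = 100, seed = 1),
                          table = fake)
  expect_equal(nrow(kept), 1L)
  gone <- normalize_reads(one, norm_config(k = 4, target_cov = 50,
                                           max_pct_stdev = 50, seed = 1),
                          table = fake)
  expect_equal(nrow(gone), 0L)
  expect_equal(attr(gone, "decisions")$decision, "aberrant")
})

test_that("normalization is seed-deterministic and threshold-monotone", {
  set.seed(54)
  tpl <- random_nt(300)
  starts <- sample(1:240, 400, TRUE)
  bases <- substring(tpl, starts, starts + 59)
  # give a third of the reads one central substitution: the error kmers
  # (most of the read) drop to singleton coverage while flanking kmers stay
  # high, which is exactly an aberrant coverage profile
  bad <- seq_len(130)
  bases[bad] <- vapply(bases[bad], function(b) {
    substr(b, 30, 30) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(b, 30, 30)), 1)
    b
  }, "")
  reads <- mk_reads(bases, lapply(1:400, function(i) rep(40, 60)))
  cfg <- function(mps) norm_config(k = 25, target_cov = 5,
                                   max_pct_stdev = mps, seed = 77)
  k1 <- normalize_reads(reads, cfg(100))
  k2 <- normalize_reads(reads, cfg(100))
  expect_equal(k1$id, k2$id)     # same seed, same outcome
  d100 <- attr(k1, "decisions")
  d1e4 <- attr(normalize_reads(reads, cfg(1e4)), "decisions")
  elim100 <- d100$id[d100$decision == "aberrant"]
  elim1e4 <- d1e4$id[d1e4$decision == "aberrant"]
  expect_true(all(elim1e4 %in% elim100))
  expect_gt(length(elim100), 0L)
  # kept sets are subsets of the input, in input order
  expect_true(all(k1$id %in% reads$id))
  expect_false(is.unsorted(match(k1$id, reads$id)))
})

test_that("paired normalization decides mates jointly", {
  set.seed(55)
  r1 <- mk_reads(vapply(rep(40, 10), random_nt, ""),
                 lapply(1:10, function(i) rep(40, 40)))
  r2 <- mk_reads(vapply(rep(40, 10), random_nt, ""),
                 lapply(1:10, function(i) rep(40, 40)))
  out <- normalize_reads(r1, norm_config(k = 25, max_pct_stdev = 1e4,
                                         seed = 3), mates = r2)
  expect_equal(nrow(out), nrow(attr(out, "mates")))
  expect_equal(match(out$id, r1$id), match(attr(out, "mates")$id, r2$id))
})
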