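# Read pre-processing: Trimmomatic-style quality trimming and kmer-coverage
# normalization with the aberrant-read (max_pct_stdev) filter. These are the
# two read-processing factors whose settings drive downstream database
# quality in this workflow.

#' Trimming configuration
#'
#' @param phred_threshold Quality threshold (strict trimming uses 35, relaxed
#'   trimming uses 5).
#' @param window Sliding-window width in bases (default 4, the common
#'   Trimmomatic setting).
#' @param min_len Minimum read length after trimming; shorter reads are
#'   dropped (default 36).
#' @return A `trim_config` list.
#' @export
trim_config <- function(phred_threshold = 35L, window = 4L, min_len = 36L) {
  stopifnot(phred_threshold >= 0L, phred_threshold <= 93L, window >= 1L,
            min_len >= 1L)
  structure(list(phred_threshold = phred_threshold, window = window,
                 min_len = min_len), class = "trim_config")
}

#' Normalization configuration
#'
#' @param k Kmer size (default 25).
#' @param target_cov Target kmer coverage; reads whose median kmer coverage
#'   exceeds it are downsampled (default 50).
#' @param max_pct_stdev Aberrant-profile threshold: reads whose kmer-coverage
#'   percent standard deviation (100 x sample stdev / mean) exceeds this are
#'   eliminated. 100 removes aberrant reads; 10000 effectively retains them.
#' @param seed Seed for the downsampling stream.
#' @return A `norm_config` list.
#' @export
norm_config <- function(k = 25L, target_cov = 50L, max_pct_stdev = 100,
                        seed = 1L) {
  stopifnot(k >= 1L, target_cov >= 1L, max_pct_stdev > 0)
  structure(list(k = as.integer(k), target_cov = target_cov,
                 max_pct_stdev = max_pct_stdev, seed = as.integer(seed)),
            class = "norm_config")
}

#' Quality-trim reads
#'
#' Per read: (i) leading, then trailing bases with phred below the threshold
#' are removed; (ii) a sliding window of `cfg$window` bases scans from the 5'
#' end and the read is cut at the first window whose mean phred falls below
#' the threshold; (iii) reads shorter than `cfg$min_len` are dropped. Bases
#' and qualities stay aligned throughout.
#'
#' @param reads Read tibble (`id`, `bases`, `qual`) as from [read_fastq()].
#' @param cfg A [trim_config()].
#' @return The trimmed read tibble (dropped reads removed); the number
#'   dropped is attached as attribute `"n_dropped"`.
#' @export
quality_trim <- function(reads, cfg = trim_config()) {
  thr <- cfg$phred_threshold
  w <- cfg$window
  trim_one <- function(q) {
    n <- length(q)
    lo <- 1L
    while (lo <= n && q[lo] < thr) lo <- lo + 1L
    hi <- n
    while (hi >= lo && q[hi] < thr) hi <- hi - 1L
    if (lo > hi) return(c(0L, 0L))
    q <- q[lo:hi]
    n <- length(q)
    if (n >= w) {
      means <- (cumsum(q)[w:n] - c(0, cumsum(q))[1:(n - w + 1L)]) / w
      bad <- which(means < thr)
      if (length(bad)) {
        cut <- bad[1] - 1L           # keep bases before the failing window
        if (cut == 0L) return(c(0L, 0L))
        return(c(lo, lo + cut - 1L))
      }
    }
    c(lo, hi)
  }
  quals <- phred_scores(reads$qual)
  spans <- vapply(quals, trim_one, integer(2))
  keep_len <- spans[2, ] - spans[1, ] + 1L
  keep_len[spans[1, ] == 0L] <- 0L
  kept <- keep_len >= cfg$min_len
  out <- reads[kept, ]
  out$bases <- substring(out$bases, spans[1, kept], spans[2, kept])
  out$qual <- substring(out$qual, spans[1, kept], spans[2, kept])
  attr(out, "n_dropped") <- sum(!kept)
  out
}

#' Count canonical kmers over a read set
#'
#' Kmers are canonicalized as the lexicographic minimum of the kmer and its
#' reverse complement (strand-agnostic coverage, as assembler normalizers
#' count them); kmers containing non-ACGT characters are skipped.
#'
#' @param reads Read tibble, or a character vector of base strings.
#' @param k Kmer size.
#' @return A named integer vector of canonical kmer counts.
#' @export
count_kmers <- function(reads, k = 25L) {
  bases <- if (is.data.frame(reads)) reads$bases else reads
  km <- extract_kmers(bases, k)
  if (!length(km)) return(setNames(integer(), character()))
  canon <- pmin(km, revcomp(km))
  canon <- canon[!grepl("[^ACGT]", canon)]
  tab <- table(canon)
  setNames(as.integer(tab), names(tab))
}

extract_kmers <- function(bases, k) {
  n <- nchar(bases)
  cnt <- pmax(n - k + 1L, 0L)
  if (!sum(cnt)) return(character())
  starts <- sequence(cnt)
  substring(rep(bases, cnt), starts, starts + k - 1L)
}

#' Per-read kmer coverage statistics
#'
#' For each read, looks its canonical kmers up in `table` and reports the
#' coverage profile and its summary statistics: median (lower of the two
#' middle values for even counts), mean, sample standard deviation (n-1
#' denominator; 0 for a single kmer) and `pct_stdev = 100 * stdev / mean`
#' (0 when the mean is 0). Reads shorter than `k` get all statistics 0.
#'
#' @param reads Read tibble or character vector of base strings.
#' @param table Kmer count table from [count_kmers()] built over the read set
#'   containing these reads.
#' @param k Kmer size used to build `table`.
#' @return A tibble with one row per read: `id`, `coverages` (list column),
#'   `median`, `mean`, `stdev`, `pct_stdev`.
#' @export
read_kmer_stats <- function(reads, table, k = 25L) {
  bases <- if (is.data.frame(reads)) reads$bases else reads
  ids <- if (is.data.frame(reads) && "id" %in% names(reads)) reads$id else
    paste0("read", seq_along(bases))
  n <- nchar(bases)
  cnt <- pmax(n - k + 1L, 0L)
  km <- extract_kmers(bases, k)
  cov_all <- integer(length(km))
  if (length(km)) {
    canon <- pmin(km, revcomp(km))
    hit <- match(canon, names(table))
    cov_all <- ifelse(is.na(hit), 0L, as.integer(table)[hit])
    cov_all[grepl("[^ACGT]", canon)] <- 0L
  }
  covs <- split(cov_all, rep(seq_along(bases), cnt))
  coverages <- rep(list(integer()), length(bases))
  coverages[as.integer(names(covs))] <- covs
  stats <- vapply(coverages, function(x) {
    if (!length(x)) return(c(0, 0, 0, 0))
    med <- sort(x)[ceiling(length(x) / 2)]   # lower-middle median
    mu <- mean(x)
    sdev <- if (length(x) == 1L) 0 else sd(x)
    pct <- if (mu == 0) 0 else 100 * sdev / mu
    c(med, mu, sdev, pct)
  }, numeric(4))
  tibble(id = ids, coverages = coverages, median = stats[1, ],
         mean = stats[2, ], stdev = stats[3, ], pct_stdev = stats[4, ])
}

#' Kmer-coverage normalization with an aberrant-read filter
#'
#' For each read (or read pair), the read is eliminated outright when its
#' kmer-coverage percent standard deviation exceeds `cfg$max_pct_stdev`
#' (aberrant profile, typically caused by sequencing errors); otherwise it is
#' kept with probability `min(1, target_cov / median)` using a seeded uniform
#' stream in input order, so reads at or below the coverage target are always
#' kept. Pairs are decided jointly using the mean of the two mates' medians
#' and the max of their pct_stdevs. One uniform draw is consumed per read
#' (pair) in input order regardless of the aberrant-filter outcome, so kept
#' sets at different `max_pct_stdev` values are directly comparable at the
#' same seed.
#'
#' @param reads Read tibble (mate 1 when `mates` is supplied).
#' @param cfg A [norm_config()].
#' @param mates Optional read tibble of mate-2 reads, row-aligned with
#'   `reads`.
#' @param table Optional precomputed [count_kmers()] table over all input
#'   reads (both mates); computed if omitted.
#' @return The kept rows of `reads` (and of `mates`, as attribute `"mates"`,
#'   when paired). Attribute `"decisions"` records per input read (pair) the
#'   outcome: `"kept"`, `"downsampled"` or `"aberrant"`.
#' @export
normalize_reads <- function(reads, cfg = norm_config(), mates = NULL,
                            table = NULL) {
  if (is.null(table)) {
    all_bases <- c(reads$bases, if (!is.null(mates)) mates$bases)
    table <- count_kmers(all_bases, cfg$k)
  }
  s1 <- read_kmer_stats(reads, table, cfg$k)
  if (!is.null(mates)) {
    stopifnot(nrow(mates) == nrow(reads))
    s2 <- read_kmer_stats(mates, table, cfg$k)
    med <- (s1$median + s2$median) / 2
    pct <- pmax(s1$pct_stdev, s2$pct_stdev)
  } else {
    med <- s1$median
    pct <- s1$pct_stdev
  }
  u <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(cfg$seed)
    runif(nrow(reads))
  })
  prob <- pmin(1, cfg$target_cov / pmax(med, 1e-9))
  prob[med <= cfg$target_cov] <- 1
  aberrant <- pct > cfg$max_pct_stdev
  kept <- !aberrant & u <= prob
  decision <- dplyr::case_when(aberrant ~ "aberrant",
                               !kept ~ "downsampled",
                               TRUE ~ "kept")
  out <- reads[kept, ]
  attr(out, "decisions") <- tibble(id = reads$id, median = med,
                                   pct_stdev = pct, decision = decision)
  if (!is.null(mates)) attr(out, "mates") <- mates[kept, ]
  out
}
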