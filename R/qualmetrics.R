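# Assembly quality metrics: N50, totals, and reference-protein contiguity
# coverage (fraction of reference proteins covered along >= 90% of their
# length by a single transcript at 100% identity).

#' N50 of a set of contig/transcript lengths
#'
#' The length L such that contigs of length >= L contain at least half of all
#' assembled bases; computed by sorting descending and returning the length
#' at which the cumulative sum first reaches half the total.
#'
#' @param lengths Positive integer vector of sequence lengths.
#' @return The N50 length.
#' @examples
#' n50(c(8, 5, 5, 3, 3, 2, 2, 2))  # 5
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list", call. = FALSE)
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Contiguity coverage of reference proteins by transcripts
#'
#' For each reference protein, the best single-transcript coverage is the
#' longest exact common substring between the protein and any six-frame
#' translation segment of any one transcript, divided by the protein length.
#' A protein counts as covered when its best coverage reaches `min_fraction`
#' (default 0.9) -- exact identity is required within the matched substring.
#'
#' @param reference A `protein_db` (or coercible tibble) of reference
#'   proteins.
#' @param transcripts Sequence tibble (`id`, `seq`) or character vector of
#'   transcript nucleotide sequences.
#' @param min_fraction Coverage fraction required to count a protein as
#'   covered (default 0.9).
#' @return A list: `covered` (count), `total`, `per_protein` (tibble
#'   `protein_id`, `best_coverage`, `best_transcript`, `covered`).
#' @export
contiguity_coverage <- function(reference, transcripts, min_fraction = 0.9) {
  reference <- as_protein_db(reference)
  stopifnot(nrow(reference) > 0L)
  transcripts <- as_seq_tbl(transcripts)
  segs <- six_frame_translate(transcripts, min_len = 1L)
  seg_by_tx <- split(segs$aa_seq, segs$source_id)
  best_len <- integer(nrow(reference))
  best_tx <- rep(NA_character_, nrow(reference))
  for (p in seq_len(nrow(reference))) {
    prot <- reference$seq[p]
    for (tx in names(seg_by_tx)) {
      lcs <- longest_common_substring_len(prot, seg_by_tx[[tx]],
                                          lower = best_len[p])
      if (lcs > best_len[p]) {
        best_len[p] <- lcs
        best_tx[p] <- tx
      }
    }
  }
  best_cov <- best_len / nchar(reference$seq)
  per_protein <- tibble(protein_id = reference$id, best_coverage = best_cov,
                        best_transcript = best_tx,
                        covered = best_cov >= min_fraction)
  list(covered = sum(per_protein$covered), total = nrow(reference),
       per_protein = per_protein)
}

# Length of the longest substring of `prot` occurring in any of `segs`.
# Binary search on the length: a common substring of length l exists iff one
# of prot's l-substrings occurs in the segment set. `lower` lets callers skip
# lengths that cannot improve a running best.
longest_common_substring_len <- function(prot, segs, lower = 0L) {
  n <- nchar(prot)
  big <- paste(segs, collapse = "#")   # '#' is outside the aa alphabet
  has_common <- function(l) {
    if (l == 0L) return(TRUE)
    if (l > n) return(FALSE)
    starts <- seq_len(n - l + 1L)
    subs <- unique(substring(prot, starts, starts + l - 1L))
    any(stringi::stri_detect_fixed(big, subs))
  }
  lo <- lower                      # known feasible (or 0)
  hi <- n
  if (!has_common(lo + 1L)) return(lo)
  lo <- lo + 1L
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (has_common(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

#' Assembly metrics for a transcript set
#'
#' @param transcripts Sequence tibble or character vector of transcript
#'   nucleotide sequences.
#' @param reference Optional reference `protein_db` for contiguity coverage.
#' @param min_fraction Coverage threshold passed to [contiguity_coverage()].
#' @return A tibble with one row: `n_transcripts`, `total_bases`, `n50`, and
#'   (when a reference is given) `contiguity_covered`, `contiguity_total`.
#' @export
assembly_metrics <- function(transcripts, reference = NULL,
                             min_fraction = 0.9) {
  transcripts <- as_seq_tbl(transcripts)
  lens <- nchar(transcripts$seq)
  out <- tibble(n_transcripts = nrow(transcripts), total_bases = sum(lens),
                n50 = if (length(lens)) n50(lens) else NA_integer_)
  if (!is.null(reference)) {
    cc <- contiguity_coverage(reference, transcripts, min_fraction)
    out$contiguity_covered <- cc$covered
    out$contiguity_total <- cc$total
  }
  out
}
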