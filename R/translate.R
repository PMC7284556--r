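# Six-frame translation, genome chunking and ORF extraction. These are the
# native replacements for the external 6FT/ORF tooling a proteogenomics
# pipeline would otherwise shell out to, so they are implemented here rather
# than wrapped.

# Standard genetic code (NCBI table 1), third base fastest, TCAG base order.
GENETIC_CODE_STRING <-
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

# 64-slot lookup indexed by base-4 codon code with A,C,G,T = 0..3
AA64 <- local({
  tcag <- c("T", "C", "A", "G")
  g <- expand.grid(b3 = tcag, b2 = tcag, b1 = tcag, stringsAsFactors = FALSE)
  codons <- paste0(g$b1, g$b2, g$b3)  # b1 slowest, b3 fastest: TTT, TTC, ...
  code <- strsplit(GENETIC_CODE_STRING, "")[[1]]
  base_val <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  m <- do.call(rbind, strsplit(codons, ""))
  idx <- 16L * base_val[m[, 1]] + 4L * base_val[m[, 2]] + base_val[m[, 3]]
  out <- character(64)
  out[idx + 1L] <- code
  out
})

BASE_CODE <- local({
  v <- rep(NA_integer_, 128L)
  v[utf8ToInt("A")] <- 0L
  v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L
  v[utf8ToInt("T")] <- 3L
  v
})

#' Reverse complement of nucleotide sequences
#'
#' Vectorized; IUPAC ambiguity codes are complemented to their IUPAC
#' complements (`N` maps to `N`, `R` to `Y`, etc.).
#'
#' @param nt Character vector of nucleotide sequences (uppercase).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ATGC")
#' @export
revcomp <- function(nt) {
  stringi::stri_reverse(chartr("ACGTUMRWSYKVHDBN", "TGCAAKYWSRMBDHVN", nt))
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Frames `+1..+3` translate the forward strand starting at 0-based offset
#' k-1; frames `-1..-3` translate the reverse complement likewise. Successive
#' complete codons are translated (trailing 1-2 nt dropped); stop codons emit
#' `*`; any codon containing a non-ACGT character emits `X`.
#'
#' @param nt A single nucleotide sequence (uppercase, `U` already normalized
#'   to `T` as [read_fasta()] does).
#' @param frame Integer in `-3..-1, 1..3`, or a string such as `"+2"`.
#' @return The amino-acid string for that frame.
#' @examples
#' translate_frame("ATGAAATAG", 1)   # "MK*"
#' translate_frame("ATGAAATAG", -1)  # "LFH"
#' @export
translate_frame <- function(nt, frame) {
  f <- normalize_frame(frame)
  s <- if (f < 0L) revcomp(nt) else nt
  off <- abs(f) - 1L
  n <- nchar(s)
  n_codon <- (n - off) %/% 3L
  if (is.na(n_codon) || n_codon <= 0L) return("")
  x <- BASE_CODE[utf8ToInt(s)]
  i1 <- off + 3L * seq_len(n_codon) - 2L
  idx <- 16L * x[i1] + 4L * x[i1 + 1L] + x[i1 + 2L]
  aa <- AA64[idx + 1L]
  aa[is.na(idx)] <- "X"
  paste(aa, collapse = "")
}

normalize_frame <- function(frame) {
  if (is.character(frame)) frame <- as.integer(sub("^\\+", "", frame))
  frame <- as.integer(frame)
  if (is.na(frame) || frame == 0L || abs(frame) > 3L) {
    stop("frame must be one of +1,+2,+3,-1,-2,-3", call. = FALSE)
  }
  frame
}

format_frame <- function(f) {
  ifelse(f > 0L, paste0("+", f), as.character(f))
}

# Shared engine: stop-free segments of every frame of one sequence.
# require_start trims each segment to its first M (segments without M drop).
frame_segments <- function(seq, source_id, min_len, require_start = FALSE) {
  L <- nchar(seq)
  out <- vector("list", 6L)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  for (k in seq_along(frames)) {
    f <- frames[k]
    aa <- translate_frame(seq, f)
    if (!nzchar(aa)) next
    m <- gregexpr("[^*]+", aa)[[1]]
    if (m[1] == -1L) next
    a0 <- as.integer(m) - 1L              # 0-based aa offset in frame
    len <- attr(m, "match.length")
    aa_seq <- substring(aa, a0 + 1L, a0 + len)
    n_codon <- nchar(aa)
    has_stop <- (a0 + len) < n_codon
    if (require_start) {
      mpos <- as.integer(regexpr("M", aa_seq, fixed = TRUE))
      keep <- mpos > 0L
      a0 <- a0[keep] + (mpos[keep] - 1L)
      len <- len[keep] - (mpos[keep] - 1L)
      has_stop <- has_stop[keep]
      aa_seq <- substring(aa_seq[keep], mpos[keep])
    }
    keep <- len >= min_len
    if (!any(keep)) next
    a0 <- a0[keep]; len <- len[keep]
    has_stop <- has_stop[keep]; aa_seq <- aa_seq[keep]
    off <- abs(f) - 1L
    if (f > 0L) {
      nt_start <- off + 3L * a0
      nt_end <- off + 3L * (a0 + len) + 3L * has_stop
    } else {
      rstart <- off + 3L * a0
      rend <- off + 3L * (a0 + len) + 3L * has_stop
      nt_start <- L - rend
      nt_end <- L - rstart
    }
    out[[k]] <- tibble(
      source_id = source_id,
      frame = format_frame(f),
      aa_seq = aa_seq,
      nt_start = nt_start,
      nt_end = nt_end,
      has_start_codon = startsWith(aa_seq, "M"),
      has_stop_codon = has_stop
    )
  }
  dplyr::bind_rows(out)
}

#' Six-frame translation into stop-free segments
#'
#' Translates each input sequence in all six reading frames, splits every
#' frame translation at stop codons (`*`) -- and only at stops; `X` runs from
#' ambiguous codons stay inside segments -- and returns every maximal
#' stop-free segment of at least `min_len` residues, with forward-strand
#' coordinates. This is the database-construction analogue of the six-frame
#' translation a search engine performs internally on a genome.
#'
#' @param seqs A tibble with columns `id`, `seq` (as from [read_fasta()]), or
#'   a character vector of sequences (named or not).
#' @param min_len Minimum segment length in amino acids (default 7, about the
#'   shortest useful tryptic peptide).
#' @return A tibble with one row per segment: `id`
#'   (`"<source>|<frame>|<nt_start>"`), `source_id`, `frame`, `aa_seq`,
#'   `nt_start`/`nt_end` (0-based half-open on the forward strand, including
#'   the terminating stop codon when `has_stop_codon`), `has_start_codon`,
#'   `has_stop_codon`.
#' @examples
#' six_frame_translate(tibble::tibble(id = "x", seq = "ATGAAATAG"), min_len = 2)
#' @export
six_frame_translate <- function(seqs, min_len = 7L) {
  stopifnot(min_len >= 1L)
  seqs <- as_seq_tbl(seqs)
  res <- purrr::map2(seqs$seq, seqs$id, frame_segments, min_len = min_len)
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    out <- tibble(source_id = character(), frame = character(),
                  aa_seq = character(), nt_start = integer(),
                  nt_end = integer(), has_start_codon = logical(),
                  has_stop_codon = logical())
  }
  dplyr::mutate(out,
                id = paste(.data$source_id, .data$frame, .data$nt_start,
                           sep = "|"),
                .before = 1L)
}

#' Split a genome sequence into overlapping chunks
#'
#' Chunks of `chunk_size` stepping by `chunk_size - overlap`; the last chunk
#' may be shorter. Any window of at most `overlap + 1` nt lies wholly inside
#' at least one chunk, so with the default 120 nt overlap no peptide of up to
#' 40 residues is lost at a chunk boundary during six-frame translation.
#'
#' @inheritParams six_frame_translate
#' @param chunk_size Chunk length in nt (default 100000).
#' @param overlap Overlap between consecutive chunks in nt (default 120).
#' @return A tibble of chunk records: `id` (`"<source>|<offset>"`), `desc`,
#'   `seq`, `source_id`, `offset` (0-based start on the source).
#' @export
split_genome_chunks <- function(seqs, chunk_size = 100000L, overlap = 120L) {
  if (overlap < 0L || chunk_size <= overlap) {
    stop("chunk_size must exceed overlap and overlap must be >= 0",
         call. = FALSE)
  }
  seqs <- as_seq_tbl(seqs)
  one <- function(seq, id, desc) {
    L <- nchar(seq)
    step <- chunk_size - overlap
    starts <- 0L
    while (tail(starts, 1L) + chunk_size < L) {
      starts <- c(starts, tail(starts, 1L) + step)
    }
    tibble(
      id = paste(id, starts, sep = "|"),
      desc = desc,
      seq = substring(seq, starts + 1L, pmin(starts + chunk_size, L)),
      source_id = id,
      offset = starts
    )
  }
  desc <- if ("desc" %in% names(seqs)) seqs$desc else ""
  dplyr::bind_rows(purrr::pmap(list(seqs$seq, seqs$id, desc), one))
}

#' Extract open reading frames from transcripts
#'
#' Reports maximal ORFs in all six reading frames of each transcript. With
#' `require_start = TRUE` an ORF runs from the first ATG after the previous
#' stop to the next stop; with `require_start = FALSE` it runs from the
#' segment start (open 5' end, modeling truncated transcripts) to the stop.
#' ORFs shorter than `min_aa` are discarded.
#'
#' @inheritParams six_frame_translate
#' @param min_aa Minimum ORF length in amino acids (default 100, the common
#'   default of Transdecoder-style ORF finders).
#' @param require_start Require an initiating methionine (default `TRUE`).
#' @return A tibble with the same columns as [six_frame_translate()].
#' @export
extract_orfs <- function(seqs, min_aa = 100L, require_start = TRUE) {
  stopifnot(min_aa >= 1L)
  seqs <- as_seq_tbl(seqs)
  res <- purrr::map2(seqs$seq, seqs$id, frame_segments, min_len = min_aa,
                     require_start = require_start)
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    out <- tibble(source_id = character(), frame = character(),
                  aa_seq = character(), nt_start = integer(),
                  nt_end = integer(), has_start_codon = logical(),
                  has_stop_codon = logical())
  }
  dplyr::mutate(out,
                id = paste(.data$source_id, .data$frame, .data$nt_start,
                           sep = "|"),
                .before = 1L)
}

# Coerce character vectors / data frames to a minimal sequence tibble
as_seq_tbl <- function(x) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    return(tibble(id = ids, seq = unname(x)))
  }
  stopifnot(is.data.frame(x), all(c("id", "seq") %in% names(x)))
  as_tibble(x)
}
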