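# Sequence and read I/O: strict FASTA/FASTQ parsing with record-level
# validation. Records are plain tibbles so everything downstream composes
# with dplyr.

NT_ALPHABET <- "ACGTUMRWSYKVHDBN"
AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYX*"

#' Parse FASTA text into a sequence tibble
#'
#' Reads multi-line FASTA into one row per record. The record id is the first
#' whitespace-delimited word of the header; the description is the remainder
#' (possibly empty). Residues are uppercased and validated against the
#' declared alphabet; for nucleotide input, `U` is normalized to `T` so that
#' downstream translation can assume DNA.
#'
#' @param x Path to a FASTA file, or a character vector of FASTA lines (a
#'   single string containing newlines is also accepted).
#' @param alphabet `"nt"` (ACGTU + IUPAC ambiguity codes) or `"aa"`
#'   (20 amino acids plus `X` and `*`).
#' @return A tibble with columns `id`, `desc`, `seq`. Empty-sequence records
#'   are kept but flagged with a warning.
#' @examples
#' read_fasta(c(">a desc", "ACg", "T"), alphabet = "nt")
#' @export
read_fasta <- function(x, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  lines <- slurp_lines(x)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first)) {
    return(tibble(id = character(), desc = character(), seq = character()))
  }
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA: expected '>' at line ", first, call. = FALSE)
  }
  hdr <- startsWith(lines, ">")
  # interior non-header, non-sequence garbage is impossible to distinguish
  # from sequence; alphabet validation catches it per record
  grp <- cumsum(hdr)
  heads <- lines[hdr]
  ids <- sub("^>(\\S*).*$", "\\1", heads)
  desc <- sub("^>\\S*\\s*", "", heads)
  bad <- which(!nzchar(ids))
  if (length(bad)) {
    stop("malformed FASTA: empty header id at line ", which(hdr)[bad[1]],
         call. = FALSE)
  }
  seq_lines <- ifelse(hdr, "", gsub("\\s+", "", lines))
  seqs <- vapply(split(seq_lines, grp), paste, collapse = "", FUN.VALUE = "")
  seqs <- toupper(unname(seqs))
  if (any(!nzchar(seqs))) {
    warning(sum(!nzchar(seqs)), " empty-sequence record(s): ",
            paste(head(ids[!nzchar(seqs)], 5L), collapse = ", "),
            call. = FALSE)
  }
  validate_residues(seqs, ids, alphabet)
  if (alphabet == "nt") seqs <- stringr::str_replace_all(seqs, "U", "T")
  tibble(id = ids, desc = desc, seq = seqs)
}

#' Parse FASTQ text into a read tibble
#'
#' Strict 4-line FASTQ with phred+33 quality encoding. Base and quality
#' strings must have equal length; `@`/`+` framing is validated.
#'
#' @inheritParams read_fasta
#' @return A tibble with columns `id`, `desc`, `bases`, `qual` (the raw
#'   phred+33 string) and `mate` (integer 1/2 parsed from a trailing `/1`,
#'   `/2` or Casava-style ` 1:`/` 2:` tag, `NA` otherwise). Use
#'   [phred_scores()] to decode `qual` to integers.
#' @export
read_fastq <- function(x) {
  lines <- slurp_lines(x)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  if (!length(lines)) {
    return(tibble(id = character(), desc = character(), bases = character(),
                  qual = character(), mate = integer()))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: ", length(lines), " lines is not a multiple of 4",
         call. = FALSE)
  }
  at <- lines[c(TRUE, FALSE, FALSE, FALSE)]
  bases <- toupper(lines[c(FALSE, TRUE, FALSE, FALSE)])
  plus <- lines[c(FALSE, FALSE, TRUE, FALSE)]
  qual <- lines[c(FALSE, FALSE, FALSE, TRUE)]
  if (any(!startsWith(at, "@"))) {
    stop("malformed FASTQ: missing '@' at record ",
         which(!startsWith(at, "@"))[1], call. = FALSE)
  }
  if (any(!startsWith(plus, "+"))) {
    stop("malformed FASTQ: missing '+' at record ",
         which(!startsWith(plus, "+"))[1], call. = FALSE)
  }
  ids <- sub("^@(\\S*).*$", "\\1", at)
  desc <- sub("^@\\S*\\s*", "", at)
  mism <- nchar(bases) != nchar(qual)
  if (any(mism)) {
    stop("quality length mismatch for read '", ids[mism][1], "'",
         call. = FALSE)
  }
  q <- unlist(lapply(qual, utf8ToInt), use.names = FALSE) - 33L
  if (length(q) && (min(q) < 0L || max(q) > 93L)) {
    stop("phred score outside [0, 93] in quality strings", call. = FALSE)
  }
  mate <- rep(NA_integer_, length(ids))
  mate[grepl("/1$", ids) | grepl("^1[:.]", desc)] <- 1L
  mate[grepl("/2$", ids) | grepl("^2[:.]", desc)] <- 2L
  tibble(id = ids, desc = desc, bases = bases, qual = qual, mate = mate)
}

#' Decode phred+33 quality strings to integer scores
#'
#' @param qual Character vector of phred+33 encoded quality strings.
#' @return A list of integer vectors, one per input string.
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' Encode integer phred scores as a phred+33 string
#'
#' @param scores Integer vector of phred scores in \[0, 93\].
#' @return A single character string.
#' @export
phred_string <- function(scores) {
  stopifnot(all(scores >= 0L), all(scores <= 93L))
  if (!length(scores)) return("")
  intToUtf8(as.integer(scores) + 33L)
}

#' Write sequence records as FASTA
#'
#' @param records Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @param line_width Wrap sequence lines at this many residues (default 60).
#' @return The FASTA lines, invisibly.
#' @export
write_fasta <- function(records, path = NULL, line_width = 60L) {
  stopifnot(line_width >= 1L)
  desc <- if ("desc" %in% names(records)) records$desc else ""
  hdr <- ifelse(nzchar(desc), paste0(">", records$id, " ", desc),
                paste0(">", records$id))
  body <- lapply(records$seq, function(s) {
    n <- nchar(s)
    if (n == 0L) return(character())
    starts <- seq.int(1L, n, by = line_width)
    substring(s, starts, pmin(starts + line_width - 1L, n))
  })
  lines <- unlist(Map(c, hdr, body), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write read records as FASTQ
#'
#' @param reads Tibble with columns `id`, `bases`, `qual` (phred+33 strings).
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return The FASTQ lines, invisibly.
#' @export
write_fastq <- function(reads, path = NULL) {
  if (!"qual" %in% names(reads) || anyNA(reads$qual)) {
    stop("FASTQ output requires quality strings for every read", call. = FALSE)
  }
  if (any(nchar(reads$bases) != nchar(reads$qual))) {
    stop("quality length mismatch", call. = FALSE)
  }
  lines <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+",
                           reads$qual))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# --- internals ---------------------------------------------------------------

slurp_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

validate_residues <- function(seqs, ids, alphabet) {
  allowed <- if (alphabet == "nt") NT_ALPHABET else AA_ALPHABET
  pat <- paste0("[^", gsub("*", "\\*", allowed, fixed = TRUE), "]")
  hit <- stringr::str_extract(seqs, pat)
  bad <- which(!is.na(hit))
  if (length(bad)) {
    stop("illegal ", if (alphabet == "nt") "nucleotide" else "amino acid",
         " character '", hit[bad[1]], "' in record '", ids[bad[1]], "'",
         call. = FALSE)
  }
  invisible(NULL)
}
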