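# Assembly of searchable protein databases: validated containers, exact
# deduplication, concatenation with contaminants, and residue-equalized
# sizing so databases of different provenance can be compared without a
# database-size bias in probability-based scoring.

#' Construct a protein database
#'
#' A protein database is a tibble of protein records (`id`, `desc`, `seq`,
#' `src`) with unique ids and no empty sequences. `*` characters are stripped
#' from ingested sequences with a warning (annotation pipelines sometimes
#' emit trailing stops). The `src` provenance tag (`"subject"`, `"filler"`,
#' `"contaminant"`) travels with every record so that downstream peptide
#' accounting can be restricted to subject proteins.
#'
#' @param records Tibble with columns `id`, `seq` and optionally `desc`,
#'   `src` (as from [read_fasta()]).
#' @param src Default provenance for records lacking a `src` column.
#' @return A `protein_db` tibble with columns `id`, `desc`, `seq`, `src`.
#' @export
protein_db <- function(records, src = "subject") {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  db <- as_tibble(records)
  if (!"desc" %in% names(db)) db$desc <- ""
  if (!"src" %in% names(db)) db$src <- src
  db <- db[, c("id", "desc", "seq", "src")]
  if (any(grepl("*", db$seq, fixed = TRUE))) {
    warning("stripping '*' characters from ",
            sum(grepl("*", db$seq, fixed = TRUE)), " sequence(s)",
            call. = FALSE)
    db$seq <- gsub("*", "", db$seq, fixed = TRUE)
  }
  if (any(!nzchar(db$seq))) {
    stop("empty protein sequence(s): ",
         paste(head(db$id[!nzchar(db$seq)], 5L), collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(db$id)
  if (any(dup)) {
    stop("duplicate protein id(s): ",
         paste(unique(head(db$id[dup], 5L)), collapse = ", "), call. = FALSE)
  }
  class(db) <- c("protein_db", class(db))
  db
}

as_protein_db <- function(x, src = "subject") {
  if (inherits(x, "protein_db")) x else protein_db(x, src = src)
}

#' Remove exact duplicate sequences
#'
#' Among records with byte-identical residue strings only the first in input
#' order is kept; order is otherwise preserved. The removed-to-kept id
#' mapping is attached as the `"removed"` attribute (a tibble with columns
#' `removed_id`, `kept_id`).
#'
#' @param db A `protein_db` (or coercible tibble).
#' @return The deduplicated `protein_db`.
#' @export
dedup_exact <- function(db) {
  db <- as_protein_db(db)
  first <- match(db$seq, db$seq)
  dup <- first != seq_len(nrow(db))
  out <- db[!dup, ]
  attr(out, "removed") <- tibble(removed_id = db$id[dup],
                                 kept_id = db$id[first[dup]])
  out
}

#' Concatenate protein databases
#'
#' Records are concatenated in argument order; residue counts are additive.
#' Id collisions are an error by default, or resolved by suffixing `_2`,
#' `_3`, ... to later occurrences with `id_collision = "suffix"`.
#'
#' @param dbs A list of `protein_db` objects (or coercible tibbles).
#' @param id_collision `"error"` or `"suffix"`.
#' @return The combined `protein_db`.
#' @export
concat_databases <- function(dbs, id_collision = c("error", "suffix")) {
  id_collision <- match.arg(id_collision)
  stopifnot(length(dbs) >= 1L)
  dbs <- lapply(dbs, as_protein_db)
  out <- dplyr::bind_rows(lapply(dbs, function(d) {
    class(d) <- setdiff(class(d), "protein_db"); d
  }))
  dup <- duplicated(out$id)
  if (any(dup)) {
    if (id_collision == "error") {
      stop("id collision: ", paste(unique(head(out$id[dup], 5L)),
                                   collapse = ", "), call. = FALSE)
    }
    counts <- stats::ave(seq_along(out$id), out$id, FUN = seq_along)
    out$id[dup] <- paste0(out$id[dup], "_", counts[dup])
  }
  protein_db(out)
}

#' Pad a database to an exact residue target with filler sequences
#'
#' Appends filler records in filler order until the next whole record would
#' overshoot `target_residues`, then appends a prefix of the next filler
#' record (id suffixed `_trunc`) so the total residue count equals the target
#' exactly. Padded records carry `src = "filler"` so peptide-comparison
#' accounting can exclude them. This reproduces the residue-equalized sizing
#' used to remove database-size bias when comparing searches across databases
#' of different provenance.
#'
#' @param db Subject `protein_db`.
#' @param filler `protein_db` of filler (e.g. bacterial) proteins.
#' @param target_residues Total residue count to reach; must be at least the
#'   current residue count (sizing only grows databases).
#' @return The padded `protein_db`, with exactly `target_residues` residues.
#' @export
pad_to_target <- function(db, filler, target_residues) {
  db <- as_protein_db(db)
  filler <- as_protein_db(filler, src = "filler")
  filler$src <- "filler"
  cur <- sum(nchar(db$seq))
  deficit <- target_residues - cur
  if (deficit < 0) {
    stop("target_residues (", target_residues, ") < current residue count (",
         cur, ")", call. = FALSE)
  }
  if (deficit == 0) return(db)
  lens <- nchar(filler$seq)
  if (sum(lens) < deficit) {
    stop("insufficient filler: need ", deficit, " residues, have ",
         sum(lens), call. = FALSE)
  }
  cum <- cumsum(lens)
  n_whole <- sum(cum <= deficit)
  pad <- filler[seq_len(n_whole), ]
  rest <- deficit - if (n_whole) cum[n_whole] else 0L
  if (rest > 0) {
    part <- filler[n_whole + 1L, ]
    part$seq <- substr(part$seq, 1L, rest)
    part$id <- paste0(part$id, "_trunc")
    pad <- dplyr::bind_rows(pad, part)
  }
  concat_databases(list(db, pad), id_collision = "suffix")
}

#' Database summary statistics
#'
#' @param db A `protein_db` (or coercible tibble).
#' @param bin_width Bin width (residues) for the sequence-length histogram.
#' @return A list with `n_sequences`, `n_residues`, and `length_histogram`
#'   (tibble of `bin_start`, `bin_end`, `n`).
#' @export
db_stats <- function(db, bin_width = 50L) {
  if (is.data.frame(db) && nrow(db) == 0L) {
    return(list(n_sequences = 0L, n_residues = 0L,
                length_histogram = tibble(bin_start = integer(),
                                          bin_end = integer(),
                                          n = integer())))
  }
  db <- as_protein_db(db)
  lens <- nchar(db$seq)
  bins <- (lens - 1L) %/% bin_width
  h <- dplyr::count(tibble(bin = bins), .data$bin)
  list(
    n_sequences = nrow(db),
    n_residues = sum(lens),
    length_histogram = tibble(bin_start = h$bin * bin_width + 1L,
                              bin_end = (h$bin + 1L) * bin_width,
                              n = h$n)
  )
}

#' Histogram of database sequence lengths
#'
#' @param object A `protein_db`.
#' @param bin_width Histogram bin width in residues.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protein_db <- function(object, bin_width = 50L, ...) {
  d <- tibble(length = nchar(object$seq), src = object$src)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, fill = .data$src)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0) +
    ggplot2::labs(x = "sequence length (aa)", y = "sequences",
                  fill = "provenance") +
    ggplot2::theme_minimal()
}
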