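# In-silico tryptic digestion with missed cleavages, tryptic-status
# classification, and monoisotopic peptide masses under the
# carbamidomethyl-C (fixed) / oxidation-M (variable) modification set.

# Monoisotopic residue masses (Da)
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565
MASS_CARBAMIDOMETHYL <- 57.02146
MASS_OXIDATION <- 15.99491

#' Digestion configuration
#'
#' Trypsin cleaves C-terminal of K and R; cleavage is suppressed before
#' proline by default (Mascot-style trypsin). Searches in this workflow allow
#' up to two missed cleavages, mirroring common search-engine settings.
#'
#' @param max_missed Maximum missed cleavages per peptide (default 2).
#' @param suppress_proline Suppress cleavage when the next residue is P
#'   (default `TRUE`).
#' @param min_len,max_len Peptide length bounds in residues (defaults 6 and
#'   60; set to `1` and `Inf` to disable).
#' @return A `digest_config` list.
#' @export
digest_config <- function(max_missed = 2L, suppress_proline = TRUE,
                          min_len = 6L, max_len = 60L) {
  stopifnot(max_missed >= 0L, min_len >= 1L, min_len <= max_len)
  structure(list(max_missed = as.integer(max_missed),
                 suppress_proline = isTRUE(suppress_proline),
                 min_len = min_len, max_len = max_len),
            class = "digest_config")
}

#' Tryptic cleavage sites of a protein
#'
#' Returns 1-based positions p such that the enzyme cuts between residues p
#' and p+1 (i.e. after each K/R, excluding K/R followed by P when
#' `suppress_proline`). A terminal K/R is included (the cut coincides with
#' the protein C-terminus).
#'
#' @param protein A single protein sequence.
#' @param cfg A [digest_config()].
#' @return Integer vector of cut positions.
#' @examples
#' cleavage_sites("MKRTEAGEMRLK", digest_config())  # 2 3 10 12
#' @export
cleavage_sites <- function(protein, cfg = digest_config()) {
  stopifnot(nzchar(protein))
  ch <- strsplit(protein, "")[[1]]
  kr <- which(ch %in% c("K", "R"))
  if (cfg$suppress_proline) {
    nxt <- ch[pmin(kr + 1L, length(ch))]
    kr <- kr[kr == length(ch) | nxt != "P"]
  }
  kr
}

#' Fully tryptic peptides of one protein
#'
#' Enumerates all fully tryptic peptides with 0..`max_missed` missed
#' cleavages within the configured length bounds. Peptides containing `X` or
#' `*` are excluded (they cannot be matched exactly).
#'
#' @param protein A single protein sequence, or a one-row tibble with `id`
#'   and `seq`.
#' @param cfg A [digest_config()].
#' @param protein_id Id recorded in the output (default `"protein"` when a
#'   bare string is given).
#' @return A tibble: `peptide`, `protein_id`, `start`, `end` (0-based
#'   half-open), `missed`.
#' @examples
#' tryptic_digest("MKRTEAGEMRLK", digest_config(max_missed = 0, min_len = 1))
#' @export
tryptic_digest <- function(protein, cfg = digest_config(),
                           protein_id = "protein") {
  if (is.data.frame(protein)) {
    stopifnot(nrow(protein) == 1L)
    protein_id <- protein$id
    protein <- protein$seq
  }
  n <- nchar(protein)
  cuts <- cleavage_sites(protein, cfg)
  bounds <- unique(c(0L, cuts, n))      # 0-based segment boundaries
  m <- length(bounds) - 1L              # number of base segments
  if (m < 1L) {
    return(tibble(peptide = character(), protein_id = character(),
                  start = integer(), end = integer(), missed = integer()))
  }
  i <- rep(seq_len(m), times = pmin(cfg$max_missed + 1L, m - seq_len(m) + 1L))
  j <- sequence(pmin(cfg$max_missed + 1L, m - seq_len(m) + 1L)) + i - 1L
  start <- bounds[i]
  end <- bounds[j + 1L]
  len <- end - start
  keep <- len >= cfg$min_len & len <= cfg$max_len
  start <- start[keep]; end <- end[keep]; missed <- (j - i)[keep]
  if (!length(start)) {
    return(tibble(peptide = character(), protein_id = protein_id,
                  start = integer(), end = integer(), missed = integer())[0, ])
  }
  pep <- substring(protein, start + 1L, end)
  ok <- !grepl("[X*]", pep)
  tibble(peptide = pep[ok], protein_id = protein_id,
         start = start[ok], end = end[ok], missed = missed[ok])
}

#' Digest every protein of a database into a peptide-protein index
#'
#' @param db A `protein_db` (or coercible tibble of `id`, `seq`).
#' @param cfg A [digest_config()].
#' @return A tibble `peptide`, `protein_id`, `src` with one row per distinct
#'   (peptide, protein) pair; the substrate for presence checks and parsimony
#'   inference.
#' @export
digest_database <- function(db, cfg = digest_config()) {
  if (is.data.frame(db) && nrow(db) == 0L) {
    return(tibble(peptide = character(), protein_id = character(),
                  src = character()))
  }
  db <- as_protein_db(db)
  res <- purrr::map2(db$seq, db$id,
                     function(s, i) tryptic_digest(s, cfg, protein_id = i))
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) {
    return(tibble(peptide = character(), protein_id = character(),
                  src = character()))
  }
  out <- dplyr::distinct(out, .data$peptide, .data$protein_id)
  dplyr::left_join(out, tibble(protein_id = db$id, src = db$src),
                   by = "protein_id")
}

#' Classify a peptide occurrence as fully, semi- or non-tryptic
#'
#' A terminus is enzymatic if it coincides with a protein terminus or with a
#' tryptic cleavage site (preceding residue K/R, respecting the KP rule; last
#' residue K/R, respecting the KP rule). Peptides at the end of a truncated
#' transcript's translation therefore classify as fully tryptic by the
#' terminus convention even without a terminal K/R.
#'
#' @param peptide_seq Peptide sequence.
#' @param protein Protein sequence containing it.
#' @param position 0-based start of the occurrence in `protein`.
#' @param cfg A [digest_config()].
#' @return `"full"`, `"semi"` or `"non"`.
#' @export
classify_tryptic <- function(peptide_seq, protein, position,
                             cfg = digest_config()) {
  n <- nchar(protein)
  len <- nchar(peptide_seq)
  if (substr(protein, position + 1L, position + len) != peptide_seq) {
    stop("peptide not found at position ", position, call. = FALSE)
  }
  n_ok <- position == 0L || {
    prev <- substr(protein, position, position)
    first <- substr(peptide_seq, 1L, 1L)
    prev %in% c("K", "R") && !(cfg$suppress_proline && first == "P")
  }
  end <- position + len
  c_ok <- end == n || {
    last <- substr(peptide_seq, len, len)
    nxt <- substr(protein, end + 1L, end + 1L)
    last %in% c("K", "R") && !(cfg$suppress_proline && nxt == "P")
  }
  if (n_ok && c_ok) "full" else if (n_ok || c_ok) "semi" else "non"
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, with carbamidomethyl
#' (+57.02146 Da) applied to every cysteine as a fixed modification and
#' oxidation (+15.99491 Da) applied to `n_oxidations` methionines.
#'
#' @param seq Peptide sequence(s); vectorized.
#' @param n_oxidations Number of oxidized methionines per peptide (recycled).
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("G")  # 75.03203
#' @export
peptide_mass <- function(seq, n_oxidations = 0L) {
  n_ox <- rep_len(as.integer(n_oxidations), length(seq))
  vapply(seq_along(seq), function(k) {
    ch <- strsplit(seq[k], "")[[1]]
    m <- RESIDUE_MASS[ch]
    if (anyNA(m)) {
      stop("unknown residue '", ch[which(is.na(m))[1]], "' in peptide '",
           seq[k], "'", call. = FALSE)
    }
    n_met <- sum(ch == "M")
    if (n_ox[k] > n_met) {
      stop("n_oxidations exceeds methionine count in '", seq[k], "'",
           call. = FALSE)
    }
    sum(m) + MASS_WATER + MASS_CARBAMIDOMETHYL * sum(ch == "C") +
      MASS_OXIDATION * n_ox[k]
  }, numeric(1))
}
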