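# Evaluation core: identification filtering (spectral-count and
# supporting-peptide rules), parsimony protein inference, peptide-set
# comparison across databases, and classification of database-unique
# peptides (SAV-containing, cleavage-site SAV, terminal fragments).

#' Read a peptide identification TSV
#'
#' Expects at least columns `peptide` and `spectral_count` (a search engine's
#' pooled export for one database). Counts for duplicated peptide sequences
#' are summed, mirroring pooling of multiple raw files at the experiment
#' level.
#'
#' @param path TSV file path.
#' @param label Database label attached to the observations.
#' @return A tibble `peptide`, `spectral_count`, `label`.
#' @export
read_identifications <- function(path, label = basename(path)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide", "spectral_count") %in% names(d)))
  pool_observations(tibble(peptide = d$peptide,
                           spectral_count = as.integer(d$spectral_count),
                           label = label))
}

pool_observations <- function(obs) {
  dplyr::summarise(dplyr::group_by(obs, .data$peptide, .data$label),
                   spectral_count = sum(.data$spectral_count),
                   .groups = "drop")[, c("peptide", "spectral_count", "label")]
}

#' Filter an identification set
#'
#' Applies the two experiment-level filters once, in order: (1) observations
#' with fewer than `min_count` spectral counts are removed; (2) the
#' parsimonious protein set over the remaining matched peptides is computed,
#' and peptides all of whose parsimony-assigned proteins have fewer than
#' `min_support` supporting peptides are removed. The steps are not iterated
#' to a fixpoint; set `iterate = TRUE` to repeat both steps until stable.
#'
#' @param obs Observation tibble (`peptide`, `spectral_count`, optionally
#'   `label`).
#' @param index Peptide-protein index for the searched database, as from
#'   [digest_database()] (`peptide`, `protein_id`).
#' @param min_count Minimum spectral count (default 2).
#' @param min_support Minimum supporting peptides per protein (default 2).
#' @param iterate Repeat the two steps until no further removal (default
#'   `FALSE`).
#' @return The filtered observation tibble. Attribute `"removed"` is a tibble
#'   (`peptide`, `reason`) of removed observations; attribute `"parsimony"`
#'   holds the final [parsimony_proteins()] result.
#' @export
filter_identifications <- function(obs, index, min_count = 2L,
                                   min_support = 2L, iterate = FALSE) {
  obs <- as_tibble(obs)
  removed <- tibble(peptide = character(), reason = character())
  low <- obs$spectral_count < min_count
  removed <- dplyr::bind_rows(removed,
                              tibble(peptide = obs$peptide[low],
                                     reason = "spectral_count"))
  obs <- obs[!low, ]
  pars <- NULL
  repeat {
    pars <- parsimony_proteins(obs$peptide, index)
    assign_tbl <- pars$assignment
    support <- dplyr::count(assign_tbl, .data$protein_id,
                            name = "n_peptides")
    ok_prot <- support$protein_id[support$n_peptides >= min_support]
    pep_ok <- unique(assign_tbl$peptide[assign_tbl$protein_id %in% ok_prot])
    drop <- obs$peptide %in% assign_tbl$peptide & !(obs$peptide %in% pep_ok)
    removed <- dplyr::bind_rows(removed,
                                tibble(peptide = obs$peptide[drop],
                                       reason = "protein_support"))
    obs <- obs[!drop, ]
    if (!iterate || !any(drop)) break
  }
  attr(obs, "removed") <- removed
  attr(obs, "parsimony") <- parsimony_proteins(obs$peptide, index)
  obs
}

#' Parsimony protein inference (minimal set cover)
#'
#' Finds a minimal set of proteins explaining all matched peptides. The
#' default greedy cover repeatedly picks the protein covering the most
#' uncovered peptides, breaking ties by more total matched peptides, then
#' lexicographically smaller id. `method = "exact"` enumerates protein
#' subsets in increasing size (feasible for small instances; used as an
#' oracle in tests) and returns a certified minimum cover.
#'
#' @param peptides Character vector of peptide sequences.
#' @param index Peptide-protein index tibble (`peptide`, `protein_id`).
#' @param method `"greedy"` (default) or `"exact"`.
#' @return A `parsimony` object: list with `proteins` (retained ids, in
#'   selection order for greedy), `assignment` (tibble `peptide`,
#'   `protein_id`: every retained protein containing each peptide), and
#'   `orphans` (peptides absent from the index).
#' @export
parsimony_proteins <- function(peptides, index,
                               method = c("greedy", "exact")) {
  method <- match.arg(method)
  peptides <- unique(peptides)
  idx <- index[index$peptide %in% peptides, c("peptide", "protein_id")]
  orphans <- setdiff(peptides, idx$peptide)
  covered_pep <- unique(idx$peptide)
  sets <- split(idx$peptide, idx$protein_id)
  chosen <- character()
  if (length(sets)) {
    if (method == "greedy") {
      isets <- lapply(sets, function(s) match(unique(s), covered_pep))
      total <- lengths(isets)
      ids <- names(isets)
      ord <- order(-total, ids)            # tie-break order, fixed up front
      isets <- isets[ord]; ids <- ids[ord]
      uncovered <- rep(TRUE, length(covered_pep))
      while (any(uncovered)) {
        gain <- vapply(isets, function(s) sum(uncovered[s]), integer(1))
        best <- which.max(gain)            # first max respects tie-break
        chosen <- c(chosen, ids[best])
        uncovered[isets[[best]]] <- FALSE
        isets[best] <- NULL
        ids <- ids[-best]
      }
    } else {
      chosen <- exact_cover(sets, covered_pep)
    }
  }
  assignment <- idx[idx$protein_id %in% chosen, ]
  assignment <- dplyr::arrange(dplyr::distinct(assignment), .data$peptide,
                               .data$protein_id)
  structure(list(proteins = chosen, assignment = assignment,
                 orphans = orphans),
            class = "parsimony")
}

# Smallest protein subset covering all peptides; subsets enumerated in
# increasing size, lexicographic order within a size (deterministic).
exact_cover <- function(sets, universe) {
  ids <- sort(names(sets))
  sets <- sets[ids]
  n <- length(ids)
  for (size in seq_len(n)) {
    combos <- utils::combn(n, size)
    for (j in seq_len(ncol(combos))) {
      pick <- combos[, j]
      if (all(universe %in% unlist(sets[pick], use.names = FALSE))) {
        return(ids[pick])
      }
    }
  }
  character()
}

#' @export
tidy.parsimony <- function(x, ...) x$assignment

#' @export
glance.parsimony <- function(x, ...) {
  tibble(n_proteins = length(x$proteins),
         n_peptides = length(unique(x$assignment$peptide)),
         n_orphans = length(x$orphans))
}

#' @export
print.parsimony <- function(x, ...) {
  cat("Parsimony protein inference: ", length(x$proteins), " protein(s) cover ",
      length(unique(x$assignment$peptide)), " peptide(s); ",
      length(x$orphans), " orphan peptide(s)\n", sep = "")
  invisible(x)
}

#' Compare peptide sets across database searches
#'
#' Exact set-algebra partition of the union of identified peptides of 2 or 3
#' searches into Venn regions. Region labels are `+`/`-` membership patterns
#' over the input labels (e.g. `"A+B-C+"`).
#'
#' @param idsets Named list of filtered observation tibbles (or bare
#'   character vectors of peptides), 2 or 3 of them.
#' @return A `peptide_comparison` object: tibble `region`, `n` with the
#'   per-region peptide lists as attribute `"peptides"`; region counts sum to
#'   the size of the union.
#' @export
compare_peptide_sets <- function(idsets) {
  stopifnot(length(idsets) %in% c(2L, 3L))
  labels <- names(idsets) %||% LETTERS[seq_along(idsets)]
  sets <- lapply(idsets, function(x) {
    unique(if (is.data.frame(x)) x$peptide else as.character(x))
  })
  union_pep <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) union_pep %in% s,
                   logical(length(union_pep)))
  member <- matrix(member, nrow = length(union_pep))
  region_label <- function(r) paste0(labels, ifelse(r, "+", "-"),
                                     collapse = "")
  key <- if (length(union_pep)) apply(member, 1L, region_label) else
    character()
  combos <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), length(labels))))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  regions <- apply(combos, 1L, region_label)
  counts <- table(factor(key, levels = regions))
  out <- tibble(region = names(counts), n = as.integer(counts))
  res <- structure(out, class = c("peptide_comparison", class(out)))
  attr(res, "peptides") <- split(union_pep, key)
  attr(res, "labels") <- labels
  res
}

#' Bar chart of peptide-overlap regions
#'
#' @param x A `peptide_comparison` from [compare_peptide_sets()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_peptide_overlap <- function(x, ...) {
  d <- tibble(region = x$region, n = x$n)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$region, -.data$n),
                                  y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "membership region", y = "peptides") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Is a peptide present in a database?
#'
#' `mode = "substring"` reports any exact occurrence; `mode = "tryptic"`
#' reports only occurrences that are fully tryptic peptides of the database
#' protein under `cfg` with at most `cfg$max_missed` missed cleavages.
#'
#' @param peptide A single peptide sequence.
#' @param db A `protein_db` (or coercible tibble).
#' @param cfg A [digest_config()].
#' @param mode `"substring"` or `"tryptic"`.
#' @return A tibble of occurrences: `protein_id`, `start` (0-based), `end`,
#'   `tryptic_status`, `missed`. Zero rows means absent.
#' @export
peptide_presence <- function(peptide, db, cfg = digest_config(),
                             mode = c("substring", "tryptic")) {
  mode <- match.arg(mode)
  db <- as_protein_db(db)
  hits <- stringr::str_locate_all(db$seq, stringr::fixed(peptide))
  n_hit <- vapply(hits, nrow, integer(1))
  if (!sum(n_hit)) {
    return(tibble(protein_id = character(), start = integer(),
                  end = integer(), tryptic_status = character(),
                  missed = integer()))
  }
  prot_i <- rep(seq_len(nrow(db)), n_hit)
  starts <- unlist(lapply(hits, function(m) m[, 1]), use.names = FALSE) - 1L
  status <- character(length(starts))
  missed <- integer(length(starts))
  for (k in seq_along(starts)) {
    prot <- db$seq[prot_i[k]]
    status[k] <- classify_tryptic(peptide, prot, starts[k], cfg)
    sites <- cleavage_sites(prot, cfg)
    missed[k] <- sum(sites > starts[k] & sites < starts[k] + nchar(peptide))
  }
  out <- tibble(protein_id = db$id[prot_i], start = starts,
                end = starts + nchar(peptide), tryptic_status = status,
                missed = missed)
  if (mode == "tryptic") {
    out <- out[out$tryptic_status == "full" & out$missed <= cfg$max_missed, ]
  }
  out
}

#' Classify a peptide against a reference database (SAV detection)
#'
#' Classification, in precedence order: `exact` if the peptide is present
#' fully tryptically in the reference; `internal_sav` if some same-length
#' reference tryptic peptide (within the missed-cleavage allowance) differs
#' at exactly one position (a single amino acid variant inside the peptide);
#' `flanking_cleavage_sav` if the peptide occurs as an exact substring of a
#' reference protein but fails the tryptic boundary test (the variant sits in
#' the adjacent cleavage site); otherwise `absent`.
#'
#' @param peptide A single peptide sequence.
#' @param reference_db Reference `protein_db`.
#' @param cfg A [digest_config()].
#' @param ref_index Optional precomputed [digest_database()] of
#'   `reference_db` (pass it when classifying many peptides).
#' @return A one-row tibble: `peptide`, `class`, `reference_protein_id`,
#'   `reference_peptide`, `variant_position` (1-based within the peptide for
#'   `internal_sav`, `NA` otherwise).
#' @export
detect_sav <- function(peptide, reference_db, cfg = digest_config(),
                       ref_index = NULL) {
  reference_db <- as_protein_db(reference_db)
  if (is.null(ref_index)) ref_index <- digest_database(reference_db, cfg)
  sav_call <- function(class, prot = NA_character_, ref = NA_character_,
                       pos = NA_integer_) {
    tibble(peptide = peptide, class = class, reference_protein_id = prot,
           reference_peptide = ref, variant_position = pos)
  }
  exact <- ref_index[ref_index$peptide == peptide, ]
  if (nrow(exact)) {
    return(sav_call("exact", exact$protein_id[1], peptide))
  }
  same_len <- ref_index[nchar(ref_index$peptide) == nchar(peptide), ]
  if (nrow(same_len)) {
    cand <- unique(same_len$peptide)
    d <- hamming1(peptide, cand)
    hit <- which(d$dist == 1L)
    if (length(hit)) {
      ref_pep <- cand[hit[1]]
      prot <- same_len$protein_id[same_len$peptide == ref_pep][1]
      return(sav_call("internal_sav", prot, ref_pep, d$pos[hit[1]]))
    }
  }
  sub <- peptide_presence(peptide, reference_db, cfg, mode = "substring")
  if (nrow(sub)) {
    return(sav_call("flanking_cleavage_sav", sub$protein_id[1],
                    substr(reference_db$seq[match(sub$protein_id[1],
                                                  reference_db$id)],
                           sub$start[1] + 1L, sub$end[1])))
  }
  sav_call("absent")
}

# Hamming distance of `x` to each same-length string in `cand`, capped at 2,
# plus the position of the single mismatch when dist == 1
hamming1 <- function(x, cand) {
  xs <- utf8ToInt(x)
  dist <- integer(length(cand))
  pos <- rep(NA_integer_, length(cand))
  for (k in seq_along(cand)) {
    mism <- which(utf8ToInt(cand[k]) != xs)
    dist[k] <- length(mism)
    if (length(mism) == 1L) pos[k] <- mism
  }
  list(dist = dist, pos = pos)
}

#' Does a peptide sit at a terminus of its source protein?
#'
#' Terminal location of a peptide in a translated transcript is the signature
#' of a fragmented or incorrectly assembled transcript.
#'
#' @param peptide A single peptide sequence.
#' @param source_protein The protein (translated transcript) sequence.
#' @return A list: `at_terminus` (logical) and `end` (`"N"`, `"C"`, `"both"`
#'   or `NA`). C-terminal occurrences take precedence in the report when a
#'   peptide occurs at both an internal position and a terminus.
#' @export
terminal_fragment_check <- function(peptide, source_protein) {
  m <- stringr::str_locate_all(source_protein, stringr::fixed(peptide))[[1]]
  if (!nrow(m)) stop("peptide not found in source protein", call. = FALSE)
  at_n <- any(m[, 1] == 1L)
  at_c <- any(m[, 2] == nchar(source_protein))
  list(at_terminus = at_n || at_c,
       end = if (at_n && at_c) "both" else if (at_c) "C" else if (at_n) "N"
             else NA_character_)
}
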