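# Shared fixture builders and independent oracles used across the suite.

random_nt <- function(n, n_frac = 0) {
  pool <- c("A", "C", "G", "T")
  s <- sample(pool, n, replace = TRUE)
  if (n_frac > 0) {
    k <- rbinom(1, n, n_frac)
    if (k > 0) s[sample.int(n, k)] <- "N"
  }
  paste(s, collapse = "")
}

random_protein <- function(n, kr_frac = 0.12) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P", "Q",
          "S", "T", "V", "W", "Y")
  s <- sample(aa, n, replace = TRUE)
  k <- rbinom(1, n, kr_frac)
  if (k > 0) s[sample.int(n, k)] <- sample(c("K", "R"), k, replace = TRUE)
  paste(s, collapse = "")
}

# one fixed codon per amino acid, for hand-building transcripts in tests
CODON1 <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
            G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
            M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
            S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

encode_cds <- function(aa_seq, stop_codon = "TAA") {
  paste0(paste(CODON1[strsplit(aa_seq, "")[[1]]], collapse = ""), stop_codon)
}

# Independent per-offset/per-strand translator built on Biostrings; splits
# frame translations at stops. Oracle for six_frame_translate.
oracle_frame_translate <- function(s, f) {
  x <- if (f < 0) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  } else {
    s
  }
  off <- abs(f) - 1L
  n <- (nchar(x) - off) %/% 3L
  if (n <= 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, off + 1L, off + 3L * n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

# Vectorized variant of the brute-force translator for large batches
oracle_sixframe_segments_set <- function(seqs, min_len) {
  sets <- rep(list(character()), length(seqs))
  dna <- Biostrings::DNAStringSet(seqs)
  for (f in c(1, 2, 3, -1, -2, -3)) {
    x <- if (f < 0) Biostrings::reverseComplement(dna) else dna
    off <- abs(f) - 1L
    w <- pmax((Biostrings::width(x) - off) %/% 3L, 0L) * 3L
    keep <- w > 0L
    aa <- rep("", length(seqs))
    if (any(keep)) {
      sub <- Biostrings::subseq(x[keep], start = off + 1L, width = w[keep])
      aa[keep] <- as.character(Biostrings::translate(
        sub, if.fuzzy.codon = "X", no.init.codon = TRUE))
    }
    parts <- strsplit(aa, "*", fixed = TRUE)
    for (i in seq_along(seqs)) {
      p <- parts[[i]]
      sets[[i]] <- c(sets[[i]], p[nchar(p) >= min_len])
    }
  }
  sets
}

oracle_sixframe_segments <- function(s, min_len) {
  segs <- character()
  for (f in c(1, 2, 3, -1, -2, -3)) {
    aa <- oracle_frame_translate(s, f)
    parts <- strsplit(aa, "*", fixed = TRUE)[[1]]
    segs <- c(segs, parts[nchar(parts) >= min_len])
  }
  segs
}

# Brute-force tryptic digest: scan cut sites with an explicit loop, then
# enumerate peptides by a double loop over boundary pairs.
oracle_digest <- function(protein, max_missed, suppress_proline = TRUE) {
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  cuts <- integer()
  for (i in seq_len(n)) {
    if (ch[i] %in% c("K", "R")) {
      if (i == n || !(suppress_proline && ch[i + 1] == "P")) {
        cuts <- c(cuts, i)
      }
    }
  }
  bounds <- unique(c(0L, cuts, n))
  out <- list()
  for (a in seq_len(length(bounds) - 1L)) {
    for (b in a:min(a + max_missed, length(bounds) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(protein, bounds[a] + 1L, bounds[b + 1L]),
        start = bounds[a], end = bounds[b + 1L], missed = b - a
      )
    }
  }
  do.call(rbind, out)
}

# Quadratic dynamic-programming longest-common-substring oracle
oracle_lcs <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    for (j in seq_along(y)) {
      if (x[i] == y[j]) {
        cur[j] <- if (j > 1L) prev[j - 1L] + 1L else 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# Definitional N50: try every candidate length
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# random set-cover instance: returns list(peptides, index) with every
# peptide covered by at least one protein
random_cover_instance <- function(max_prot = 12, max_pep = 20) {
  n_prot <- sample(2:max_prot, 1)
  n_pep <- sample(2:max_pep, 1)
  peps <- sprintf("PEP%02d", seq_len(n_pep))
  prots <- sprintf("P%02d", seq_len(n_prot))
  rows <- list()
  for (p in prots) {
    k <- sample.int(n_pep, 1)
    rows[[p]] <- data.frame(peptide = sample(peps, k), protein_id = p)
  }
  idx <- do.call(rbind, rows)
  uncov <- setdiff(peps, idx$peptide)
  if (length(uncov)) {
    idx <- rbind(idx, data.frame(peptide = uncov,
                                 protein_id = sample(prots, length(uncov),
                                                     replace = TRUE)))
  }
  list(peptides = peps, index = tibble::as_tibble(idx))
}
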