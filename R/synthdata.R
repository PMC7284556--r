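# Seeded synthetic-data generators for desk-scale end-to-end experiments.
# They emulate the statistical structure of a nut-seed proteogenomics study:
# a proteome dominated by a few highly abundant seed-storage-like protein
# families, transcript sets bearing truncations and single amino acid
# variants (fragmented or error-bearing assemblies), and Illumina-like
# paired-end reads with ~0.1% substitution errors.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Background amino-acid frequencies; K + R together 12% so tryptic peptides
# of useful length are abundant
AA_FREQ <- c(A = 0.08, C = 0.02, D = 0.05, E = 0.06, F = 0.04, G = 0.07,
             H = 0.02, I = 0.05, K = 0.06, L = 0.09, M = 0.02, N = 0.04,
             P = 0.05, Q = 0.04, R = 0.06, S = 0.07, T = 0.05, V = 0.07,
             W = 0.01, Y = 0.03)[AA20]

# codon choices per amino acid, derived from the standard code; built lazily
# so it does not depend on file collation order
.synth_cache <- new.env(parent = emptyenv())
codons_by_aa <- function() {
  if (is.null(.synth_cache$cba)) {
    acgt <- c("A", "C", "G", "T")
    g <- expand.grid(b3 = acgt, b2 = acgt, b1 = acgt,
                     stringsAsFactors = FALSE)
    codons <- paste0(g$b1, g$b2, g$b3)
    idx <- vapply(codons, function(cd) {
      v <- BASE_CODE[utf8ToInt(cd)]
      16L * v[1] + 4L * v[2] + v[3] + 1L
    }, integer(1))
    .synth_cache$cba <- split(codons, AA64[idx])
  }
  .synth_cache$cba
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions this generator emulates: 85 bp
#' paired-end reads, a 0.1% per-base substitution error rate (typical of
#' Illumina data), a two-tier abundance model with a few storage-protein-like
#' high-abundance families, and moderate transcript fragmentation.
#'
#' @param seed Integer seed; every generator is deterministic given it.
#' @param n_proteins Number of proteins in the synthetic proteome.
#' @param length_meanlog,length_sdlog Log-normal protein length parameters
#'   (aa); defaults give a median around 300 aa.
#' @param n_storage_families Number of high-abundance storage-protein-like
#'   records (drawn 1.5x longer, abundance weight 10x).
#' @param sav_rate Per-residue probability that a transcript codon carries an
#'   amino-acid-changing single-nucleotide variant.
#' @param fragmentation_rate Probability that a transcript is truncated; the
#'   truncated fraction is uniform on (0.2, 0.8), removed from a random end.
#' @param read_length Read length in bp (default 85).
#' @param error_rate Per-base substitution error probability (default 0.001).
#' @param coverage Mean read depth over the transcript set.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_proteins = 300L, length_meanlog = 5.7,
                       length_sdlog = 0.35, n_storage_families = 3L,
                       sav_rate = 0.002, fragmentation_rate = 0.2,
                       read_length = 85L, error_rate = 0.001,
                       coverage = 50) {
  stopifnot(n_proteins >= 1L, sav_rate >= 0, sav_rate <= 1,
            fragmentation_rate >= 0, fragmentation_rate <= 1,
            read_length >= 1L, error_rate >= 0, error_rate <= 1,
            coverage > 0)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 n_storage_families = as.integer(n_storage_families),
                 sav_rate = sav_rate, fragmentation_rate = fragmentation_rate,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, coverage = coverage),
            class = "sim_config")
}

#' Simulate a proteome with high-abundance storage-like families
#'
#' Proteins are random sequences over the 20 amino acids (initial M, K+R
#' frequency 12% so tryptic peptides exist). The first
#' `cfg$n_storage_families` records model seed-storage proteins: drawn 1.5x
#' longer and given abundance weight 10, versus 1 for the rest.
#'
#' @param cfg A [sim_config()].
#' @return A list: `db` (a `protein_db`), `abundance` (tibble `protein_id`,
#'   `abundance`).
#' @export
simulate_proteome <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    n <- cfg$n_proteins
    ns <- min(cfg$n_storage_families, n)
    lens <- pmax(30L, as.integer(round(rlnorm(n, cfg$length_meanlog,
                                              cfg$length_sdlog))))
    if (ns) lens[seq_len(ns)] <- as.integer(round(lens[seq_len(ns)] * 1.5))
    ids <- sprintf("prot%04d", seq_len(n))
    if (ns) ids[seq_len(ns)] <- sprintf("storage%02d", seq_len(ns))
    seqs <- vapply(lens, function(L) {
      paste0("M", paste(sample(AA20, L - 1L, replace = TRUE, prob = AA_FREQ),
                        collapse = ""))
    }, character(1))
    db <- protein_db(tibble(id = ids, desc = ifelse(seq_len(n) <= ns,
                                                    "storage family", ""),
                            seq = seqs))
    abundance <- tibble(protein_id = ids,
                        abundance = ifelse(seq_len(n) <= ns, 10, 1))
    list(db = db, abundance = abundance)
  })
}

# Uniform synonymous back-translation of amino-acid sequences (vectorized by
# residue class)
back_translate <- function(aa_seq) {
  ch <- strsplit(aa_seq, "")[[1]]
  codons <- character(length(ch))
  cba <- codons_by_aa()
  for (a in unique(ch)) {
    pos <- which(ch == a)
    choice <- cba[[a]]
    codons[pos] <- choice[sample.int(length(choice), length(pos),
                                     replace = TRUE)]
  }
  codons
}

#' Simulate a genome encoding a proteome
#'
#' Each protein is back-translated (uniform synonymous codons) to a CDS
#' terminated by a stop codon; introns (GT..AG-bounded random sequence) are
#' inserted between codons at `intron_rate` per junction; genes are
#' concatenated with random intergenic spacers into a single contig. The
#' returned truth table gives forward-strand exon coordinates, against which
#' one can verify that peptides spanning exon-exon junctions are absent from
#' the genome's six-frame translation.
#'
#' @param proteome A `protein_db`.
#' @param intron_rate Per-junction intron probability (default 0).
#' @param intron_length_range Min/max intron length in nt.
#' @param spacer_range Min/max intergenic spacer length in nt.
#' @param seed Integer seed.
#' @return A list: `genome` (tibble `id`, `desc`, `seq` with one contig) and
#'   `exons` (tibble `protein_id`, `exon`, `start`, `end`, 0-based half-open
#'   contig coordinates).
#' @export
simulate_genome <- function(proteome, intron_rate = 0,
                            intron_length_range = c(60L, 200L),
                            spacer_range = c(50L, 150L), seed = 1L) {
  proteome <- as_protein_db(proteome)
  with_seed(seed, {
    acgt <- c("A", "C", "G", "T")
    rand_nt <- function(n) paste(sample(acgt, n, replace = TRUE),
                                 collapse = "")
    pieces <- character()
    exons <- list()
    pos <- 0L
    for (p in seq_len(nrow(proteome))) {
      spacer <- rand_nt(sample(spacer_range[1]:spacer_range[2], 1L))
      pieces <- c(pieces, spacer)
      pos <- pos + nchar(spacer)
      codons <- c(back_translate(proteome$seq[p]),
                  sample(c("TAA", "TAG", "TGA"), 1L))
      junction_intron <- runif(length(codons) - 1L) < intron_rate
      ex_start <- pos
      gene_exons <- list()
      exon_i <- 1L
      for (ci in seq_along(codons)) {
        pieces <- c(pieces, codons[ci])
        pos <- pos + 3L
        if (ci < length(codons) && junction_intron[ci]) {
          gene_exons[[exon_i]] <- c(ex_start, pos)
          intron <- paste0("GT",
                           rand_nt(sample(intron_length_range[1]:
                                            intron_length_range[2], 1L) - 4L),
                           "AG")
          pieces <- c(pieces, intron)
          pos <- pos + nchar(intron)
          ex_start <- pos
          exon_i <- exon_i + 1L
        }
      }
      gene_exons[[exon_i]] <- c(ex_start, pos)
      ex <- do.call(rbind, gene_exons)
      exons[[p]] <- tibble(protein_id = proteome$id[p],
                           exon = seq_len(nrow(ex)),
                           start = ex[, 1], end = ex[, 2])
    }
    list(genome = tibble(id = "contig1", desc = "synthetic contig",
                         seq = paste(pieces, collapse = "")),
         exons = dplyr::bind_rows(exons))
  })
}

#' Simulate a transcriptome with truncation and SAVs
#'
#' One CDS-derived transcript per protein (back-translated with fresh codon
#' choices, terminated by a stop codon). Each residue independently carries
#' an amino-acid-changing single-nucleotide variant with probability
#' `cfg$sav_rate`; each transcript is truncated with probability
#' `cfg$fragmentation_rate` (a uniform(0.2, 0.8) fraction of its length
#' removed from a random end, at nucleotide resolution). This stands in for
#' assembler output of controllable quality.
#'
#' @param proteome A `protein_db`.
#' @param cfg A [sim_config()]; uses `seed`, `sav_rate`,
#'   `fragmentation_rate`.
#' @return A list: `transcripts` (tibble `id`, `desc`, `seq`) and `truth`
#'   (tibble `transcript_id`, `protein_id`, `truncated`, `kept_start`,
#'   `kept_end` (0-based half-open on the full CDS+stop), `sav_positions`
#'   (list column of 1-based residue positions)).
#' @export
simulate_transcriptome <- function(proteome, cfg = sim_config()) {
  proteome <- as_protein_db(proteome)
  with_seed(cfg$seed + 1L, {
    n <- nrow(proteome)
    tx <- character(n)
    truth <- vector("list", n)
    for (p in seq_len(n)) {
      aa <- proteome$seq[p]
      L <- nchar(aa)
      codons <- c(back_translate(aa), sample(c("TAA", "TAG", "TGA"), 1L))
      n_sav <- rbinom(1L, L, cfg$sav_rate)
      sav_pos <- sort(sample.int(L, n_sav))
      for (sp in sav_pos) {
        codons[sp] <- mutate_codon_aa(codons[sp])
      }
      cds <- paste(codons, collapse = "")
      kept <- c(0L, nchar(cds))
      truncated <- runif(1L) < cfg$fragmentation_rate
      if (truncated) {
        cut <- runif(1L, 0.2, 0.8)
        n_cut <- as.integer(round(cut * nchar(cds)))
        if (runif(1L) < 0.5) kept <- c(n_cut, nchar(cds)) else
          kept <- c(0L, nchar(cds) - n_cut)
      }
      tx[p] <- substr(cds, kept[1] + 1L, kept[2])
      truth[[p]] <- tibble(transcript_id = paste0("tx_", proteome$id[p]),
                           protein_id = proteome$id[p],
                           truncated = truncated,
                           kept_start = kept[1], kept_end = kept[2],
                           sav_positions = list(sav_pos))
    }
    truth <- dplyr::bind_rows(truth)
    keep <- nzchar(tx)
    list(transcripts = tibble(id = truth$transcript_id,
                              desc = paste0("from ", truth$protein_id),
                              seq = tx)[keep, ],
         truth = truth[keep, ])
  })
}

# Replace one nucleotide of a codon so the encoded amino acid changes to a
# different non-stop amino acid
mutate_codon_aa <- function(codon) {
  acgt <- c("A", "C", "G", "T")
  old_aa <- translate_frame(codon, 1L)
  cand <- character()
  for (i in 1:3) {
    for (b in setdiff(acgt, substr(codon, i, i))) {
      new <- codon
      substr(new, i, i) <- b
      aa <- translate_frame(new, 1L)
      if (aa != old_aa && aa != "*") cand <- c(cand, new)
    }
  }
  cand[sample.int(length(cand), 1L)]
}

#' Simulate Illumina-like paired-end reads from transcripts
#'
#' Fragments are sampled proportional to transcript length times abundance;
#' each yields an 85 bp (by default) forward read from the fragment 5' end
#' and a reverse-complemented read from its 3' end. Substitution errors occur
#' independently at `cfg$error_rate` per base; erroneous bases receive low
#' phred scores (uniform 2-20) and correct bases high ones (uniform 30-40),
#' so phred-based trimming discriminates them.
#'
#' @param transcripts Sequence tibble (`id`, `seq`) or character vector.
#' @param cfg A [sim_config()]; uses `seed`, `read_length`, `error_rate`,
#'   `coverage`.
#' @param abundance Optional tibble (`transcript_id` or `protein_id` ignored;
#'   matched by position) or numeric vector of per-transcript abundance
#'   weights (default all 1).
#' @return A list: `reads1`, `reads2` (read tibbles with truth columns
#'   `n_errors` and `source`), row-aligned pairs.
#' @export
simulate_reads <- function(transcripts, cfg = sim_config(),
                           abundance = NULL) {
  transcripts <- as_seq_tbl(transcripts)
  rl <- cfg$read_length
  long_enough <- nchar(transcripts$seq) >= 2L * rl
  if (!all(long_enough)) {
    warning(sum(!long_enough), " transcript(s) shorter than twice the read",
            " length skipped", call. = FALSE)
    transcripts <- transcripts[long_enough, ]
  }
  stopifnot(nrow(transcripts) > 0L)
  ab <- if (is.null(abundance)) rep(1, nrow(transcripts)) else
    rep_len(as.numeric(abundance), nrow(transcripts))
  with_seed(cfg$seed + 2L, {
    lens <- nchar(transcripts$seq)
    w <- lens * ab
    n_pairs <- max(1L, as.integer(round(cfg$coverage * sum(lens) /
                                          (2 * rl))))
    tx_i <- sample.int(nrow(transcripts), n_pairs, replace = TRUE,
                       prob = w / sum(w))
    frag_len <- pmin(pmax(as.integer(round(rnorm(n_pairs, 300, 30))),
                          2L * rl), lens[tx_i])
    frag_start <- 1L + floor(runif(n_pairs) *
                               (lens[tx_i] - frag_len + 1L))
    fwd <- substring(transcripts$seq[tx_i], frag_start,
                     frag_start + rl - 1L)
    rev_ <- revcomp(substring(transcripts$seq[tx_i],
                              frag_start + frag_len - rl,
                              frag_start + frag_len - 1L))
    inject <- function(bases) {
      n_err <- rbinom(length(bases), rl, cfg$error_rate)
      qual <- character(length(bases))
      acgt <- c("A", "C", "G", "T")
      for (r in seq_along(bases)) {
        q <- sample(30:40, rl, replace = TRUE)
        if (n_err[r] > 0L) {
          pos <- sample.int(rl, n_err[r])
          for (p in pos) {
            substr(bases[r], p, p) <- sample(setdiff(acgt,
                                                     substr(bases[r], p, p)),
                                             1L)
          }
          q[pos] <- sample(2:20, n_err[r], replace = TRUE)
        }
        qual[r] <- intToUtf8(q + 33L)
      }
      list(bases = bases, qual = qual, n_errors = n_err)
    }
    r1 <- inject(fwd)
    r2 <- inject(rev_)
    ids <- sprintf("pair%06d", seq_len(n_pairs))
    src <- transcripts$id[tx_i]
    list(
      reads1 = tibble(id = paste0(ids, "/1"), desc = "", bases = r1$bases,
                      qual = r1$qual, mate = 1L, n_errors = r1$n_errors,
                      source = src),
      reads2 = tibble(id = paste0(ids, "/2"), desc = "", bases = r2$bases,
                      qual = r2$qual, mate = 2L, n_errors = r2$n_errors,
                      source = src)
    )
  })
}

#' Simulate peptide identification exports against candidate databases
#'
#' Samples observed peptides from the tryptic digest of the (true) proteome
#' with probability increasing in protein abundance
#' (`1 - exp(-depth * abundance)`), assigns spectral counts
#' `1 + Poisson(depth * abundance)`, and intersects the observed set with
#' each candidate database's fully tryptic peptide index: a peptide is
#' identifiable against a database only when present fully tryptically. This
#' emulates per-database search results without a scoring engine.
#'
#' @param proteome The true `protein_db` generating the sample.
#' @param abundance Abundance tibble from [simulate_proteome()].
#' @param databases Named list of candidate `protein_db` objects.
#' @param cfg A [digest_config()].
#' @param depth Sampling depth scalar (default 1).
#' @param seed Integer seed.
#' @return A list: `observations` (named list of tibbles `peptide`,
#'   `spectral_count`, `label`, one per database) and `truth` (tibble of all
#'   observed peptides with their source proteins and counts).
#' @export
simulate_observations <- function(proteome, abundance, databases,
                                  cfg = digest_config(), depth = 1,
                                  seed = 1L) {
  proteome <- as_protein_db(proteome)
  peps <- digest_database(proteome, cfg)
  peps <- dplyr::left_join(peps, abundance,
                           by = c(protein_id = "protein_id"))
  by_pep <- dplyr::summarise(dplyr::group_by(peps, .data$peptide),
                             abundance = max(.data$abundance),
                             protein_ids = paste(sort(.data$protein_id),
                                                 collapse = ";"),
                             .groups = "drop")
  with_seed(seed + 3L, {
    p_obs <- 1 - exp(-depth * by_pep$abundance)
    observed <- runif(nrow(by_pep)) < p_obs
    truth <- by_pep[observed, ]
    truth$spectral_count <- 1L + rpois(nrow(truth),
                                       depth * truth$abundance)
    obs <- lapply(names(databases), function(lab) {
      idx <- digest_database(databases[[lab]], cfg)
      hit <- truth$peptide %in% idx$peptide
      tibble(peptide = truth$peptide[hit],
             spectral_count = truth$spectral_count[hit],
             label = lab)
    })
    names(obs) <- names(databases)
    list(observations = obs, truth = truth)
  })
}
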