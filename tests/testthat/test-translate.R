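test_that("reverse complement handles IUPAC codes and empty input", {
  expect_equal(revcomp("ATGC"), "GCAT")
  expect_equal(revcomp(""), "")
  expect_equal(revcomp("ATN"), "NAT")
  expect_equal(revcomp(c("AC", "RY")), c("GT", "RY"))
  # involution on random sequences
  set.seed(21)
  s <- vapply(rep(80, 20), random_nt, "", n_frac = 0.05)
  expect_equal(revcomp(revcomp(s)), s)
})

test_that("single-frame translation follows the standard code", {
  expect_equal(translate_frame("ATGAAATAG", 1), "MK*")
  expect_equal(translate_frame("ATGAAATAG", 3), "EI")
  expect_equal(translate_frame("ATGAAATAG", -1), "LFH")
  # ambiguity codes give X; trailing bases dropped
  expect_equal(translate_frame("ATNAAA", 1), "XK")
  expect_equal(translate_frame("AT", 1), "")
  expect_equal(translate_frame("ATGA", "+2"), "*")
})

test_that("translation agrees with the Biostrings translator frame by frame", {
  set.seed(22)
  for (i in 1:25) {
    s <- random_nt(sample(10:400, 1), n_frac = 0.02)
    for (f in c(1, 2, 3, -1, -2, -3)) {
      expect_equal(translate_frame(s, f), oracle_frame_translate(s, f),
                   info = paste("frame", f))
    }
  }
})

test_that("six-frame segments match hand enumeration", {
  segs <- six_frame_translate(tibble::tibble(id = "x", seq = "ATGAAATAG"),
                              min_len = 2)
  expect_equal(segs$aa_seq, c("MK", "EI", "LFH", "YF", "IS"))
  expect_equal(segs$frame, c("+1", "+3", "-1", "-2", "-3"))

  segs2 <- six_frame_translate("AAAAAA", min_len = 1)
  expect_equal(segs2$aa_seq, c("KK", "K", "K", "FF", "F", "F"))
})

test_that("segment lengths plus stops conserve each frame translation", {
  set.seed(23)
  for (i in 1:10) {
    s <- random_nt(sample(60:300, 1))
    segs <- six_frame_translate(s, min_len = 1)
    for (f in c("+1", "+2", "+3", "-1", "-2", "-3")) {
      aa <- translate_frame(s, f)
      in_frame <- segs[segs$frame == f, ]
      n_stops <- sum(strsplit(aa, "")[[1]] == "*")
      expect_equal(sum(nchar(in_frame$aa_seq)) + n_stops, nchar(aa))
    }
  }
})

test_that("segment coordinates re-translate to their amino acid sequence", {
  set.seed(24)
  for (i in 1:10) {
    s <- random_nt(sample(60:300, 1))
    segs <- six_frame_translate(s, min_len = 1)
    for (k in seq_len(nrow(segs))) {
      sub <- substr(s, segs$nt_start[k] + 1, segs$nt_end[k])
      f <- if (startsWith(segs$frame[k], "-")) -1 else 1
      expected <- paste0(segs$aa_seq[k], if (segs$has_stop_codon[k]) "*")
      expect_equal(translate_frame(sub, f), expected)
    }
  }
})

test_that("six-frame translation is reverse-complement invariant", {
  set.seed(25)
  for (i in 1:10) {
    s <- random_nt(sample(60:250, 1))
    a <- six_frame_translate(s, min_len = 1)
    b <- six_frame_translate(revcomp(s), min_len = 1)
    expect_equal(sort(a$aa_seq), sort(b$aa_seq))
    # coordinates reflect: forward-strand intervals of one equal L - reversed
    L <- nchar(s)
    expect_setequal(paste(a$aa_seq, a$nt_start, a$nt_end),
                    paste(b$aa_seq, L - b$nt_end, L - b$nt_start))
  }
})

test_that("genome chunking steps, covers, and validates parameters", {
  ch <- split_genome_chunks(tibble::tibble(id = "g", seq = strrep("A", 10)),
                            chunk_size = 4, overlap = 2)
  expect_equal(ch$offset, c(0, 2, 4, 6))
  expect_equal(nchar(ch$seq), rep(4L, 4))

  one <- split_genome_chunks("ACG", chunk_size = 10, overlap = 0)
  expect_equal(one$seq, "ACG")

  expect_error(split_genome_chunks("ACGT", chunk_size = 2, overlap = 2),
               "overlap")

  # union of chunks covers the source
  set.seed(26)
  s <- random_nt(1037)
  ch <- split_genome_chunks(s, chunk_size = 200, overlap = 50)
  covered <- rep(FALSE, 1037)
  for (k in seq_len(nrow(ch))) {
    covered[(ch$offset[k] + 1):(ch$offset[k] + nchar(ch$seq[k]))] <- TRUE
  }
  expect_true(all(covered))
  expect_equal(ch$seq, substring(s, ch$offset + 1,
                                 ch$offset + nchar(ch$seq)))
})

test_that("ORF extraction finds start-anchored and 5'-open ORFs", {
  orf <- extract_orfs(tibble::tibble(id = "t", seq = "AAATGGCCTGAAA"),
                      min_aa = 2, require_start = TRUE)
  expect_equal(orf$aa_seq, "MA")
  expect_equal(orf$frame, "+3")
  expect_equal(c(orf$nt_start, orf$nt_end), c(2L, 11L))

  open <- extract_orfs("GCCGCCGCC", min_aa = 2, require_start = FALSE)
  expect_true("AAA" %in% open$aa_seq[open$frame == "+1"])

  # exact CDS inverts translation
  prot <- "MKTAYEELWHNPR"
  cds <- encode_cds(prot)
  rec <- extract_orfs(cds, min_aa = nchar(prot), require_start = TRUE)
  expect_true(prot %in% rec$aa_seq)
})

test_that("ORFs without start requirement are segments of the 6FT", {
  set.seed(27)
  for (i in 1:10) {
    s <- random_nt(sample(90:300, 1))
    orfs <- extract_orfs(s, min_aa = 5, require_start = FALSE)
    segs <- six_frame_translate(s, min_len = 5)
    expect_true(all(orfs$aa_seq %in% segs$aa_seq))
  }
})
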