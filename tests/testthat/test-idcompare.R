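idx2 <- function(...) {
  pairs <- list(...)
  tibble::tibble(peptide = vapply(pairs, `[[`, "", 1),
                 protein_id = vapply(pairs, `[[`, "", 2))
}

obs_tbl <- function(peptides, counts) {
  tibble::tibble(peptide = peptides, spectral_count = counts, label = "db")
}

test_that("identification filters apply spectral-count then protein support", {
  idx <- idx2(c("a", "X"), c("b", "X"))
  kept <- filter_identifications(obs_tbl(c("a", "b"), c(3L, 2L)), idx)
  expect_setequal(kept$peptide, c("a", "b"))

  # the cascade: b fails step 1, then a is sole support of X
  gone <- filter_identifications(obs_tbl(c("a", "b"), c(3L, 1L)), idx)
  expect_equal(nrow(gone), 0L)
  expect_equal(attr(gone, "removed")$reason,
               c("spectral_count", "protein_support"))

  idx3 <- idx2(c("a", "X"), c("b", "X"), c("c", "Y"))
  part <- filter_identifications(obs_tbl(c("a", "b", "c"), c(2L, 2L, 5L)),
                                 idx3)
  expect_setequal(part$peptide, c("a", "b"))
  expect_equal(attr(part, "removed"),
               tibble::tibble(peptide = "c", reason = "protein_support"))
})

test_that("filters apply once by default but can iterate to a fixpoint", {
  # removing d (count 1) leaves X with 2 peptides; removing e at step 2
  # drops Y below support, which only an iterated pass acts on
  idx <- idx2(c("a", "X"), c("b", "X"), c("e", "Y"), c("f", "Y"))
  obs <- obs_tbl(c("a", "b", "e", "f"), c(2L, 2L, 2L, 1L))
  once <- filter_identifications(obs, idx)
  expect_setequal(once$peptide, c("a", "b"))
  iter <- filter_identifications(obs, idx, iterate = TRUE)
  expect_setequal(iter$peptide, c("a", "b"))
  # rerunning the single pass on its own output changes nothing here
  again <- filter_identifications(once, idx)
  expect_equal(again$peptide, once$peptide)
})

test_that("greedy parsimony covers peptides with documented tie-breaks", {
  idx <- idx2(c("p1", "A"), c("p2", "A"), c("p3", "B"), c("p1", "C"))
  res <- parsimony_proteins(c("p1", "p2", "p3"), idx)
  expect_setequal(res$proteins, c("A", "B"))
  expect_equal(res$assignment$protein_id[res$assignment$peptide == "p1"],
               "A")

  tie <- parsimony_proteins("p", idx2(c("p", "B"), c("p", "A")))
  expect_equal(tie$proteins, "A")

  none <- parsimony_proteins(character(), idx)
  expect_equal(none$proteins, character())

  orphan <- parsimony_proteins(c("p1", "zz"), idx)
  expect_equal(orphan$orphans, "zz")

  expect_equal(glance(res)$n_proteins, 2L)
  expect_equal(nrow(tidy(res)), 3L)   # p1 maps to C too, but C is not kept
})

test_that("exact cover certifies minimum covers on crafted instances", {
  # greedy picks the big set first and needs 3; the optimum is 2
  idx <- idx2(c("1", "A"), c("2", "A"), c("3", "A"), c("4", "A"),
              c("1", "B"), c("2", "B"), c("5", "B"),
              c("3", "C"), c("4", "C"), c("6", "C"))
  peps <- as.character(1:6)
  greedy <- parsimony_proteins(peps, idx)
  exact <- parsimony_proteins(peps, idx, method = "exact")
  expect_equal(length(greedy$proteins), 3L)
  expect_equal(length(exact$proteins), 2L)
  expect_setequal(exact$proteins, c("B", "C"))
})

test_that("peptide set comparison partitions the union exactly", {
  two <- compare_peptide_sets(list(X = c("a", "b", "c"),
                                   Y = c("b", "c", "d")))
  expect_equal(sum(two$n), 4L)
  expect_equal(two$n[two$region == "X+Y-"], 1L)
  expect_equal(two$n[two$region == "X-Y+"], 1L)
  expect_equal(two$n[two$region == "X+Y+"], 2L)

  same <- compare_peptide_sets(list(A = c("x", "y"), B = c("x", "y"),
                                    C = c("x", "y")))
  expect_equal(same$n[same$region == "A+B+C+"], 2L)
  expect_equal(sum(same$n), 2L)
})

test_that("three-way region counts match a membership truth table", {
  set.seed(61)
  for (i in 1:20) {
    pool <- sprintf("pep%03d", 1:40)
    sets <- lapply(1:3, function(j) sample(pool, sample(5:30, 1)))
    names(sets) <- c("A", "B", "C")
    got <- compare_peptide_sets(sets)
    union_pep <- unique(unlist(sets))
    key <- vapply(union_pep, function(p) {
      paste0(c("A", "B", "C"),
             ifelse(vapply(sets, function(s) p %in% s, TRUE), "+", "-"),
             collapse = "")
    }, "")
    want <- table(key)
    for (r in got$region) {
      expect_equal(got$n[got$region == r],
                   if (r %in% names(want)) as.integer(want[[r]]) else 0L)
    }
    expect_equal(sum(got$n), length(union_pep))
  }
})

test_that("presence checks distinguish substring from tryptic occurrence", {
  db <- protein_db(tibble::tibble(id = c("A", "B"),
                                  seq = c("MKRTEAGEMRLK", "MATEAGEMRLL")))
  sub <- peptide_presence("TEAGEMR", db, mode = "substring")
  expect_setequal(sub$protein_id, c("A", "B"))
  tryp <- peptide_presence("TEAGEMR", db, mode = "tryptic")
  expect_equal(tryp$protein_id, "A")
  expect_equal(nrow(peptide_presence("WWWW", db, mode = "substring")), 0L)
})

test_that("SAV detection classifies exact, internal and flanking variants", {
  ref <- protein_db(tibble::tibble(
    id = c("legB", "vic"),
    seq = c("MKLYDTSNQSNQLDENARLK", "MATEAGEMRLL")
  ))
  cfg <- digest_config(min_len = 6, max_len = 60)
  sav <- detect_sav("LYDTSNQANQLDENAR", ref, cfg)
  expect_equal(sav$class, "internal_sav")
  expect_equal(sav$reference_peptide, "LYDTSNQSNQLDENAR")
  expect_equal(sav$variant_position, 8L)
  expect_equal(sav$reference_protein_id, "legB")

  flank <- detect_sav("TEAGEMR", ref, cfg)
  expect_equal(flank$class, "flanking_cleavage_sav")
  expect_equal(flank$reference_protein_id, "vic")

  ref2 <- protein_db(tibble::tibble(id = "A", seq = "MKRTEAGEMRLK"))
  expect_equal(detect_sav("TEAGEMR", ref2, cfg)$class, "exact")
  expect_equal(detect_sav("WWWWWWWW", ref, cfg)$class, "absent")
})

test_that("terminal fragment check reports which end is hit", {
  prot <- "MKTEAGEVVLDDK"
  expect_equal(terminal_fragment_check("MKTEAGEV", prot),
               list(at_terminus = TRUE, end = "N"))
  expect_equal(terminal_fragment_check("TEAGEV", prot)$at_terminus, FALSE)
  both <- terminal_fragment_check("DK", "AADKAADK")  # internal and C-terminal
  expect_true(both$at_terminus)
  expect_equal(both$end, "C")
  expect_error(terminal_fragment_check("WW", prot), "not found")
})
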