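test_that("model generation is seed-deterministic", {
  a <- donkey_csn1s2_model("I", seed = 7)
  b <- donkey_csn1s2_model("I", seed = 7)
  expect_identical(a$contig_seq, b$contig_seq)
  expect_identical(a$exons, b$exons)
  c <- donkey_csn1s2_model("I", seed = 8)
  expect_false(identical(a$contig_seq, c$contig_seq))
})

test_that("pseudo-CSN1S2 I honors every printed structural constraint", {
  m <- test_model("I")
  len <- function(l) nchar(exon_seq(m, l))
  expect_equal(sum(!m$exons$extra), 19L)
  expect_equal(len("4"), 24L)
  expect_equal(len("8"), 24L)
  expect_equal(len("15"), 24L)
  expect_equal(len("12"), 129L)
  expect_equal(len("17"), 129L)
  expect_gt(len("19"), 100L)
  expect_equal(m$signal_peptide, "MKFFIFTCLLAVALA")
  # duplications: exons 8/10 and the exon-12/17 openings
  expect_equal(exon_seq(m, "8"), exon_seq(m, "10"))
  expect_equal(substr(exon_seq(m, "12"), 1, 15),
               substr(exon_seq(m, "17"), 1, 15))
  # stop codon at exon-18 nt 10-12
  expect_equal(substr(exon_seq(m, "18"), 10, 12), "TAA")
  # extra exon 12': 105 nt with TAA at nt 28-30
  expect_equal(len("12'"), 105L)
  expect_equal(substr(exon_seq(m, "12'"), 28, 30), "TAA")
  # annotated cryptic sites
  e17 <- m$exons[m$exons$label == "17", ]
  expect_equal(e17$acceptor_offsets[[1]], 15L)
  expect_equal(e17$donor_trims[[1]], 35L)
  # independent re-verification: translation and mature length
  expect_true(all(validate_gene_model(m)$pass))
  expect_equal(translate_isoform(m, "FL")$mature_len, 221L)
  # the XbaI site exists only at the engineered exon-17 acceptor
  hits <- gregexpr("TCTAGA", m$contig_seq, fixed = TRUE)[[1]]
  expect_length(hits, 1L)
  expect_equal(hits[1], m$exons$start[m$exons$label == "17"] - 4L)
})

test_that("pseudo-CSN1S2 II honors every printed structural constraint", {
  m <- test_model("II")
  len <- function(l) nchar(exon_seq(m, l))
  expect_equal(sum(!m$exons$extra), 16L)
  expect_equal(len("7"), 24L)
  expect_equal(len("9"), 24L)
  expect_equal(len("11"), 24L)
  expect_gt(len("16"), 200L)
  expect_equal(m$signal_peptide, "MKFFIITCLLAVALA")
  expect_equal(substr(exon_seq(m, "13"), 1, 33),
               "GTGAAAATCAACCCAAAGTTCCCCTCTCCCCAG")
  expect_equal(len("15"), 105L)
  expect_equal(len("7'"), 45L)
  expect_equal(substr(exon_seq(m, "14"), 10, 12), "TAA")
  expect_true(all(validate_gene_model(m)$pass))
  ref <- translate_isoform(m, "FL")
  expect_equal(ref$mature_len, 142L)
  # printed exon peptides land at their printed mature positions
  expect_equal(substr(ref$mature_seq, 3, 11), "EIKHVSSSE")
  expect_equal(substr(ref$mature_seq, 100, 110), "VKINPKFPSPQ")
  # 7' insertion is flanked by mature Asp50 / Glu51
  expect_equal(substr(ref$mature_seq, 50, 51), "DE")
})

test_that("clone libraries honor class sequences, size and error statistics", {
  m <- test_model("II")
  lib <- simulate_clone_library(m, n_clones = 80, error_rate = 0, seed = 5)
  expect_length(lib$clones, 80L)
  expect_equal(nrow(lib$truth), 80L)
  isoforms <- purrr::map(csn1s2_isoform_classes("II"),
                         ~ apply_events(m, .x))
  names(isoforms) <- purrr::map_chr(isoforms, "pattern_key")
  for (k in seq_len(20)) {
    expect_identical(unname(lib$clones[k]),
                     isoforms[[lib$truth$pattern_key[k]]]$mrna)
  }
  # reproducibility
  lib2 <- simulate_clone_library(m, n_clones = 80, error_rate = 0, seed = 5)
  expect_identical(lib$clones, lib2$clones)

  # substitution errors: mean per-clone mismatch within 3 sigma of binomial
  rate <- 0.002
  libe <- simulate_clone_library(m, classes = "FL", n_clones = 60,
                                 error_rate = rate, seed = 6)
  ref <- spliced_sequence(m)
  d <- vapply(libe$clones, hamming, 0, b = ref)
  L <- nchar(ref)
  expect_lt(abs(mean(d) - L * rate),
            3 * sqrt(L * rate * (1 - rate) / 60))
})

test_that("genotype panels are seeded multinomial draws from HWE", {
  p0 <- simulate_genotype_panel(50, q_alt = 0, seed = 1)
  expect_equal(p0$hom_ref, 50L)
  expect_equal(p0$het + p0$hom_alt, 0L)
  a <- simulate_genotype_panel(119, q_alt = 0.2437, seed = 9)
  b <- simulate_genotype_panel(119, q_alt = 0.2437, seed = 9)
  expect_identical(a, b)
  expect_equal(a$n, 119L)
  big <- simulate_genotype_panel(10000, q_alt = 0.2437, seed = 2)
  q_hat <- allele_frequencies(big)$q_alt
  expect_lt(abs(q_hat - 0.2437), 3 * sqrt(0.2437 * 0.7563 / 20000))
  expect_error(simulate_genotype_panel(10, q_alt = 1.5), "invalid")
})

test_that("generators leave the session RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_genotype_panel(100, 0.3, seed = 55))
  invisible(simulate_clone_library(test_model("I"), classes = "FL",
                                   n_clones = 2, seed = 55))
  expect_identical(.Random.seed, before)
})
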