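test_that("SNV annotation places the exon-12 I>T transition correctly", {
  m <- test_model("I")
  # by construction exon 12 nt 118-120 is an ATT (Ile) codon; its middle base
  # sits at CDS nt 437, precursor codon 146, mature codon 131
  expect_equal(substr(exon_seq(m, "12"), 118, 120), "ATT")
  snv <- annotate_snv(m, "12", 119, "T", "C")
  expect_equal(snv$cdna_pos, 437L)
  expect_equal(snv$codon_number, 131L)
  expect_equal(snv$ref_aa, "I")
  expect_equal(snv$alt_aa, "T")
  expect_false(snv$synonymous)
  expect_equal(snv$label, "p.I131>T")
  prec <- annotate_snv(m, "12", 119, "T", "C", numbering = "precursor")
  expect_equal(prec$codon_number, 146L)
  expect_equal(prec$label, "p.I146>T")
})

test_that("wobble-position substitutions are flagged synonymous", {
  m <- test_model("I")
  # exon 14 codon 4 is GGG by construction; nt 12 is its wobble base
  expect_equal(substr(exon_seq(m, "14"), 10, 12), "GGG")
  snv <- annotate_snv(m, "14", 12, "G", "A")
  expect_true(snv$synonymous)
  expect_equal(snv$ref_aa, "G")
  expect_equal(snv$alt_aa, "G")
  expect_match(snv$label, "=$")
})

test_that("degenerate annotation requests error distinctly", {
  m <- test_model("I")
  expect_error(annotate_snv(m, "12", 119, "T", "T"), "identical")
  expect_error(annotate_snv(m, "1", 5,
                            substr(exon_seq(m, "1"), 5, 5),
                            setdiff(c("A", "C", "G", "T"),
                                    substr(exon_seq(m, "1"), 5, 5))[1]),
               "non-coding")
  expect_error(annotate_snv(m, "12", 119, "A", "C"), "mismatch")
})

test_that("clone-supported substitutions aggregate into SNVs with thresholds", {
  m <- test_model("II")
  snv_spec <- tibble::tibble(exon_label = "12", offset = 30L, alt = "A",
                             carrier_fraction = 0.4)
  ref_base <- substr(exon_seq(m, "12"), 30, 30)
  if (ref_base == "A") snv_spec$alt <- "G"
  lib <- simulate_clone_library(m, classes = c("FL"), n_clones = 10,
                                error_rate = 0, snvs = snv_spec, seed = 8)
  n_carriers <- sum(lib$truth$n_planted)
  expect_gt(n_carriers, 1)  # deterministic under the fixed seed
  calls <- call_clones(m, lib$clones)
  snvs <- aggregate_snvs(calls, m, min_clone_support = 2)
  found <- snvs[snvs$status == "snv", ]
  expect_equal(nrow(found), 1L)
  expect_equal(found$exon_label, "12")
  expect_equal(found$offset_in_exon, 30L)
  expect_equal(found$n_support, n_carriers)
  expect_false(is.na(found$label))

  clean <- aggregate_snvs(call_clones(
    m, simulate_clone_library(m, classes = "FL", n_clones = 5,
                              error_rate = 0, seed = 1)$clones), m)
  expect_equal(nrow(clean), 0L)
})

test_that("seven planted SNVs are all recovered at support threshold 1", {
  m <- test_model("I")
  sites <- tibble::tibble(
    exon_label = c("8", "10", "12", "12", "12", "14", "17"),
    offset = c(5L, 11L, 20L, 60L, 119L, 12L, 100L))
  sites$ref <- purrr::map2_chr(sites$exon_label, sites$offset,
                               ~ substr(exon_seq(m, .x), .y, .y))
  sites$alt <- purrr::map_chr(sites$ref,
                              ~ setdiff(c("A", "C", "G", "T"), .x)[1])
  spec <- tibble::tibble(exon_label = sites$exon_label,
                         offset = sites$offset, alt = sites$alt,
                         carrier_fraction = 0.5)
  lib <- simulate_clone_library(m, classes = "FL", n_clones = 20,
                                error_rate = 0, snvs = spec, seed = 4)
  snvs <- aggregate_snvs(call_clones(m, lib$clones), m,
                         min_clone_support = 1)
  expect_equal(nrow(snvs), 7L)
  expect_setequal(paste(snvs$exon_label, snvs$offset_in_exon),
                  paste(sites$exon_label, sites$offset))
})

test_that("conflicting reference bases at one site raise a model error", {
  mk <- function(ref) tibble::tibble(exon_label = "5", offset_in_exon = 3L,
                                     ref_base = ref, clone_base = "T")
  calls <- tibble::tibble(
    clone_id = c("a", "b"), status = "called", pattern_key = "FL",
    n_events = 0L, n_mismatches = 1L, mismatches = list(mk("A"), mk("G")))
  expect_error(aggregate_snvs(calls), "conflicting reference")
})

test_that("the acceptor G>A transition predicts the 15-nt partial skip", {
  m <- test_model("I")
  pred <- classify_splice_variant(m, "17", ref = "G", alt = "A", offset = -1)
  expect_true(all(pred$disrupts_canonical))
  expect_true(all(pred$kind == "skip_5prime_partial"))
  hit <- pred[pred$length_nt == 15L, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$annotated)
  # every candidate is frame-preserving
  expect_true(all(pred$length_nt %% 3L == 0L))
})

test_that("the predicted allele-specific isoform drops one internal pentapeptide", {
  m <- test_model("I")
  ref <- translate_isoform(m, "FL")
  alt <- translate_isoform(m, "skip5:17:15")
  expect_equal(alt$mature_len, ref$mature_len - 5L)
  expect_equal(substr(ref$mature_seq, 176, 180), "NKINQ")
  expect_equal(alt$mature_seq,
               paste0(substr(ref$mature_seq, 1, 175),
                      substr(ref$mature_seq, 181, nchar(ref$mature_seq))))
})

test_that("acceptor disruption without a cryptic AG predicts whole-exon skipping", {
  m <- gene_model(
    "noag", "c", paste0("ATGAAA", "GTCCAG", "TTTTTT", "GTCCAG", "TAATAA"),
    tibble::tibble(label = c("1", "2", "3"),
                   start = c(0, 12, 24), end = c(6, 18, 30),
                   coding = TRUE, extra = FALSE),
    cds_start_exon = "1", cds_start_offset = 0, signal_peptide_len = 0,
    validate = FALSE)
  pred <- classify_splice_variant(m, "2", ref = "G", alt = "A", offset = -1)
  expect_true(pred$disrupts_canonical)
  expect_equal(pred$kind, "skip_exon")
})

test_that("variants that leave the canonical dinucleotide intact predict nothing", {
  m <- test_model("I")
  e17 <- exon_row <- m$exons[m$exons$label == "17", ]
  base3 <- substr(m$contig_seq, e17$start - 2, e17$start - 2)  # intron -3
  alt <- setdiff(c("A", "C", "G", "T"), base3)[1]
  pred <- classify_splice_variant(m, "17", ref = base3, alt = alt,
                                  offset = -3)
  expect_false(pred$disrupts_canonical)
  expect_true(is.na(pred$kind))
})
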