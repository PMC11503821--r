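test_that("average masses match hand values and the seqinr oracle", {
  expect_equal(round(average_mass(""), 2), 18.02)
  expect_equal(round(average_mass("G"), 2), 75.07)  # 57.0519 + 18.0153
  expect_error(average_mass("GZX"), "unknown residue")
  skip_if_not_installed("seqinr")
  set.seed(5)
  aas <- names(amino_acid_masses()$residue)
  aas <- amino_acid_masses()$residue
  for (i in 1:10) {
    pep <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    expect_equal(average_mass(pep), seqinr::pmw(seqinr::s2c(pep)),
                 tolerance = 0.01)
  }
})

test_that("mass is additive over chain concatenation minus one water", {
  set.seed(9)
  aas <- amino_acid_masses()$residue
  water <- attr(amino_acid_masses(), "water_mass")
  for (i in 1:15) {
    a <- paste(sample(aas, sample(0:20, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:20, 1), replace = TRUE), collapse = "")
    expect_equal(average_mass(paste0(a, b)),
                 average_mass(a) + average_mass(b) - water,
                 tolerance = 1e-9)
  }
})

test_that("the NMD junction rule uses a strict 50-nt threshold", {
  junctions <- c(100L, 300L, 500L)
  expect_true(flag_nmd(449L, junctions))    # 51 nt upstream
  expect_false(flag_nmd(450L, junctions))   # exactly at threshold
  expect_false(flag_nmd(480L, junctions))
  expect_false(flag_nmd(600L, integer(0)))  # single-exon transcript
})

test_that("reference isoforms translate to the annotated proteins", {
  for (gene in c("I", "II")) {
    m <- test_model(gene)
    tr <- translate_isoform(m, "FL")
    expect_equal(tr$status, "ok")
    expect_equal(tr$signal_peptide, m$signal_peptide)
    expect_equal(tr$precursor_seq, paste0(tr$signal_peptide, tr$mature_seq))
    expect_equal(tr$mature_len, if (gene == "I") 221L else 142L)
    expect_false(tr$frameshifted)
    expect_false(tr$ptc)
    expect_false(tr$nmd_candidate)
    expect_equal(tr$novel_cterm, "")
  }
})

test_that("the exon-12' insertion creates a PTC/NMD transcript ending EGIEIIIFM", {
  m <- test_model("I")
  tr <- translate_isoform(m, "insert:12'")
  expect_true(tr$ptc)
  expect_true(tr$nmd_candidate)
  expect_false(tr$frameshifted)  # 105 nt is a triplet insertion
  expect_equal(tr$mature_len, 143L)
  expect_equal(tr$novel_cterm, "EGIEIIIFM")
  expect_true(endsWith(tr$mature_seq, "EGIEIIIFM"))
})

test_that("the 35-nt exon-17 trim frameshifts into exon 18", {
  m <- test_model("I")
  ref <- translate_isoform(m, "FL")
  tr <- translate_isoform(m, "skip3:17:35")
  expect_true(tr$frameshifted)
  expect_false(tr$ptc)  # relocated stop is downstream of the canonical one
  expect_false(tr$nmd_candidate)
  expect_equal(tr$mature_len, 214L)
  expect_equal(nchar(tr$novel_cterm), 8L)
  # mRNA is 35 nt shorter and the stop moves 14 nt downstream within exon 18
  expect_equal(tr$stop_cdna_pos, ref$stop_cdna_pos - 35L + 14L)
  # the first 206 mature residues are reference-identical
  expect_equal(substr(tr$mature_seq, 1, 206), substr(ref$mature_seq, 1, 206))
})

test_that("in-frame events never frameshift and shift length by nt/3", {
  for (gene in c("I", "II")) {
    m <- test_model(gene)
    ref <- translate_isoform(m, "FL")
    cm <- cds_map(m)
    for (cls in csn1s2_isoform_classes(gene)) {
      iso <- apply_events(m, cls)
      tr <- translate_isoform(m, iso)
      if (tr$frameshifted || tr$ptc) next
      coding_nt <- function(lbl, removed_from, removed_to) {
        r <- cm$exons[cm$exons$label == lbl, ]
        if (nrow(r) == 0 || is.na(r$coding_from)) return(0L)
        max(0L, min(removed_to, r$coding_to) -
              max(removed_from, r$coding_from) + 1L)
      }
      delta <- 0L
      for (j in seq_len(nrow(iso$events))) {
        ev <- iso$events[j, ]
        len <- nchar(exon_seq(m, ev$exon_label))
        delta <- delta + switch(
          ev$kind,
          skip_exon = -coding_nt(ev$exon_label, 1L, len),
          skip_5prime_partial = -coding_nt(ev$exon_label, 1L, ev$length_nt),
          skip_3prime_partial = -coding_nt(ev$exon_label,
                                           len - ev$length_nt + 1L, len),
          include_extra_exon = len)
      }
      expect_equal(delta %% 3L, 0L)
      expect_equal(tr$mature_len, ref$mature_len + delta %/% 3L,
                   info = paste(gene, cls))
    }
    # spot anchors: one whole-exon skip and the extra-exon insertion
    if (gene == "II") {
      expect_equal(translate_isoform(m, "skip:9")$mature_len, 134L)
      expect_equal(translate_isoform(m, "insert:7'")$mature_len, 157L)
    }
  }
})

test_that("transcripts without an in-frame stop are reported as run-off", {
  m <- gene_model("nostop", "c1", "ATGAAAGAAGAAGAA",
                  tibble::tibble(label = "1", start = 0, end = 15,
                                 coding = TRUE, extra = FALSE),
                  cds_start_exon = "1", cds_start_offset = 0,
                  signal_peptide_len = 0, validate = FALSE)
  tr <- translate_isoform(m, "FL")
  expect_equal(tr$status, "run_off")
  expect_equal(tr$mature_seq, "")
  expect_false(tr$ptc)
})

test_that("glance returns a one-row table compatible with isoform reports", {
  tr <- translate_isoform(test_model("II"), "skip:10")
  g <- glance(tr)
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1L)
  expect_equal(g$mature_len, 133L)
  expect_named(g, c("gene_id", "pattern_key", "mature_len", "avg_mass_da",
                    "frameshifted", "ptc", "nmd_candidate", "novel_cterm",
                    "stop_cdna_pos", "status"))
})
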