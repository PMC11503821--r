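test_that("a clone equal to the reference mRNA is called FL with no mismatches", {
  m <- test_model("I")
  call <- call_clone(m, spliced_sequence(m))
  expect_equal(call$status, "called")
  expect_equal(call$pattern_key, "FL")
  expect_equal(call$n_events, 0L)
  expect_equal(call$n_mismatches, 0L)
})

test_that("whole-exon skips and annotated truncations are recovered", {
  m <- test_model("II")
  d9 <- call_clone(m, apply_events(m, "skip:9")$mrna)
  expect_equal(d9$pattern_key, "skip:9")
  expect_equal(d9$status, "called")

  combo <- call_clone(m, apply_events(m, "skip:11,skip:12,skip5:13:33")$mrna)
  expect_equal(combo$pattern_key, "skip:11,skip:12,skip5:13:33")
})

test_that("planted substitutions are located in full-exon coordinates", {
  m <- test_model("I")
  iso <- apply_events(m, "skip5:17:15")
  mut <- iso$mrna
  p <- mrna_position(m, iso$segments, "14", 12L)
  ref_base <- substr(mut, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  substr(mut, p, p) <- alt
  call <- call_clone(m, mut)
  expect_equal(call$status, "called")
  expect_equal(call$pattern_key, "skip5:17:15")
  mm <- call$mismatches[[1]]
  expect_equal(nrow(mm), 1L)
  expect_equal(mm$exon_label, "14")
  expect_equal(mm$offset_in_exon, 12L)
  expect_equal(mm$ref_base, ref_base)
  expect_equal(mm$clone_base, alt)
})

test_that("zero-error simulated libraries are recovered class-for-class", {
  for (gene in c("I", "II")) {
    m <- test_model(gene)
    for (seed in 1:2) {
      lib <- simulate_clone_library(m, n_clones = 30, error_rate = 0,
                                    seed = seed)
      calls <- call_clones(m, lib$clones)
      expect_true(all(calls$status == "called"))
      expect_equal(calls$pattern_key, lib$truth$pattern_key)
      expect_true(all(calls$n_mismatches == 0L))
    }
  }
})

test_that("a clone that deletes one of two identical exons is ambiguous", {
  codon <- function(s) paste(rep(s, 3), collapse = "")
  e <- c("ATGGCTAAA", "GAAGAAGAA", "GAAGAAGAA", "TTCTAATGA")
  pieces <- character(0); rows <- list(); pos <- 0L
  for (i in seq_along(e)) {
    rows[[i]] <- tibble::tibble(label = as.character(i), start = pos,
                                end = pos + 9L, coding = TRUE, extra = FALSE,
                                acceptor_offsets = list(integer()),
                                donor_trims = list(integer()))
    pieces <- c(pieces, e[i], if (i < length(e)) "GTTTAG")
    pos <- pos + 9L + (if (i < length(e)) 6L else 0L)
  }
  m <- gene_model("dup", "c", paste(pieces, collapse = ""),
                  dplyr::bind_rows(rows), cds_start_exon = "1",
                  cds_start_offset = 0, signal_peptide_len = 0,
                  validate = FALSE)
  clone <- paste0(e[1], e[2], e[4])  # exon 2 or exon 3 skipped?
  call <- call_clone(m, clone)
  expect_equal(call$status, "ambiguous")
  expect_equal(call$pattern_key, "skip:2")  # lexicographically smallest
})

test_that("partial amplicons are unalignable, not partially matched", {
  m <- test_model("I")
  ref <- spliced_sequence(m)
  call <- call_clone(m, substr(ref, 100, nchar(ref)))
  expect_equal(call$status, "unalignable")
})

test_that("raising the mismatch cap never loses a called clone", {
  m <- test_model("II")
  clone <- mutate_seq(apply_events(m, "skip:10")$mrna, 2, seed = 21)
  lo <- call_clone(m, clone, max_mismatch_per_exon = 2)
  hi <- call_clone(m, clone, max_mismatch_per_exon = 5)
  expect_equal(lo$status, "called")
  expect_equal(hi$status, "called")
  expect_equal(lo$pattern_key, hi$pattern_key)
})

test_that("the dynamic program equals brute-force enumeration on small models", {
  for (seed in 1:6) {
    m <- toy_caller_model(seed, n_exons = 4)
    set.seed(seed * 100)
    for (rep in 1:5) {
      # draw a random true configuration and corrupt it
      ev <- list()
      if (runif(1) < 0.4) ev <- c(ev, list(skip_exon(sample(2:3, 1))))
      if (runif(1) < 0.4) ev <- c(ev, list(include_exon("x")))
      if (runif(1) < 0.3) ev <- c(ev, list(skip_3prime("1", 3)))
      iso <- apply_events(m, dplyr::bind_rows(ev))
      clone <- mutate_seq(iso$mrna, sample(0:2, 1), seed = seed * 100 + rep)
      got <- call_clone(m, clone)
      oracle <- brute_force_call(m, clone)
      expect_false(is.null(oracle))
      expect_equal(got$n_events, oracle$ev)
      expect_equal(got$n_mismatches, oracle$mm)
      expect_equal(got$pattern_key, sort(oracle$keys)[1])
      expect_equal(got$status == "ambiguous", length(oracle$keys) > 1)
    }
  }
})

test_that("library summaries count patterns over cleanly called clones", {
  m <- test_model("II")
  lib <- simulate_clone_library(m, n_clones = 40, error_rate = 0, seed = 3)
  calls <- call_clones(m, lib$clones)
  s <- summarize_library(calls)
  expect_equal(sum(s$patterns$n_clones), 40L)
  expect_equal(sum(s$patterns$frequency), 1)
  expect_equal(s$n_ambiguous, 0L)
  expect_equal(s$n_unalignable, 0L)
  expect_setequal(s$patterns$pattern_key, unique(lib$truth$pattern_key))

  one <- summarize_library(call_clones(m, spliced_sequence(m)))
  expect_equal(one$patterns$frequency, 1)

  # truncated clones are reported but excluded from pattern counts
  mixed <- call_clones(m, c(ok = spliced_sequence(m),
                            bad = substr(spliced_sequence(m), 50, 500)))
  s2 <- summarize_library(mixed)
  expect_equal(s2$n_called, 1L)
  expect_equal(s2$n_unalignable, 1L)
})
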