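# evaluate code under a fixed seed without disturbing the session RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

random_codons <- function(n) {
  paste(sample(.SENSE_CODONS, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministic codon choice for constrained peptides
.PEP_CODON <- c(
  A = "GCC", R = "CGT", N = "AAC", D = "GAC", C = "TGC", E = "GAA",
  Q = "CAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAA",
  M = "ATG", F = "TTC", P = "CCG", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC"
)
encode_peptide <- function(pep) {
  paste(.PEP_CODON[strsplit(pep, "")[[1]]], collapse = "")
}

.ACCEPTOR_15MER <- "AACAAAATCAACCAG"                    # encodes NKINQ
.ACCEPTOR_33MER <- "GTGAAAATCAACCCAAAGTTCCCCTCTCCCCAG"  # encodes VKINPKFPSPQ
.SIGNAL_I <- "MKFFIFTCLLAVALA"
.SIGNAL_II <- "MKFFIITCLLAVALA"

# one intron: canonical GT...AG; acceptor_tail replaces the last bases
make_intron <- function(len = 60L, acceptor_tail = "AG") {
  paste0("GT", random_dna(len - 2L - nchar(acceptor_tail)), acceptor_tail)
}

build_model_from_parts <- function(gene_id, contig_id, parts, exon_meta,
                                   cds_start_exon, cds_start_offset,
                                   signal_peptide, flank5, flank3) {
  pieces <- c(flank5, unlist(purrr::map(parts, "seq")), flank3)
  contig <- paste(pieces, collapse = "")
  pos <- 0L
  rows <- list()
  pos <- nchar(flank5)
  for (p in parts) {
    len <- nchar(p$seq)
    if (!is.null(p$label)) {
      m <- exon_meta[[p$label]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = p$label, start = pos, end = pos + len,
        coding = m$coding, extra = m$extra,
        acceptor_offsets = list(m$acceptor_offsets %||% integer()),
        donor_trims = list(m$donor_trims %||% integer())
      )
    }
    pos <- pos + len
  }
  gene_model(
    gene_id = gene_id, contig_id = contig_id, contig_seq = contig,
    exons = dplyr::bind_rows(rows),
    cds_start_exon = cds_start_exon, cds_start_offset = cds_start_offset,
    signal_peptide_len = nchar(signal_peptide),
    signal_peptide = signal_peptide
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_pseudo_i <- function() {
  ex8 <- random_codons(8)   # exons 8 and 10 are perfect duplicates
  # exon 12: opens with the same 15-mer as exon 17 (NKINQ duplication),
  # 129 nt, with an ATT codon at nt 118-120 available for an I>T transition
  e12 <- paste0(.ACCEPTOR_15MER, random_codons(34), "ATT", random_codons(3))
  # exon 17: 129 nt, opens with the cryptic-acceptor 15-mer; the first base
  # of its exon-codon 32 (nt 94, last base kept after the 35-nt 3' trim)
  # must not be T, or the shifted-frame junction codon would read TAA
  c17 <- sample(.SENSE_CODONS, 38, replace = TRUE)
  if (substr(c17[27], 1, 1) == "T") c17[27] <- "GAA"
  e17 <- paste0(.ACCEPTOR_15MER, paste(c17, collapse = ""))
  # exon 18: canonical TAA at nt 10-12; after the 35-nt exon-17 trim the
  # shifted frame reads 8 codons then TAA at nt 24-26
  e18 <- paste0("AAAGTTCTC", "TAA", "GCTTCGCATTG", "TAA", random_dna(19))
  # extra exon 12': 105 nt, EGIEIIIFM then TAA at nt 28-30
  e12p <- paste0(encode_peptide("EGIEIIIFM"), "TAA", random_codons(25))

  seqs <- list(
    "1" = random_dna(30),
    "2" = paste0(random_dna(11), encode_peptide(.SIGNAL_I), "AAG"),
    "3" = random_codons(9), "4" = random_codons(8), "5" = random_codons(12),
    "6" = random_codons(11), "7" = random_codons(10), "8" = ex8,
    "9" = random_codons(9), "10" = ex8, "11" = random_codons(15),
    "12" = e12, "12'" = e12p, "13" = random_codons(11),
    "14" = paste0(random_codons(3), "GGG", random_codons(6)),
    "15" = random_codons(8), "16" = random_codons(12),
    "17" = e17, "18" = e18, "19" = random_dna(120)
  )
  meta <- purrr::map(seqs, ~ list(coding = TRUE, extra = FALSE))
  meta[["1"]]$coding <- FALSE
  meta[["19"]]$coding <- FALSE
  meta[["12'"]]$extra <- TRUE
  meta[["17"]]$acceptor_offsets <- 15L
  meta[["17"]]$donor_trims <- 35L

  parts <- list()
  labels <- names(seqs)
  for (i in seq_along(labels)) {
    l <- labels[i]
    parts[[length(parts) + 1L]] <- list(label = l, seq = seqs[[l]])
    if (i < length(labels)) {
      # the intron preceding exon 17 ends TCTAG, so the acceptor context
      # TCTAG|A... carries an XbaI site destroyed by the -1 G>A transition
      tail <- if (labels[i + 1L] == "17") "TCTAG" else "AG"
      parts[[length(parts) + 1L]] <- list(label = NULL,
                                          seq = make_intron(60L, tail))
    }
  }
  build_model_from_parts(
    gene_id = "pseudo-CSN1S2-I", contig_id = "synthetic_contig_I",
    parts = parts, exon_meta = meta,
    cds_start_exon = "2", cds_start_offset = 11L,
    signal_peptide = .SIGNAL_I,
    flank5 = random_dna(30), flank3 = random_dna(40)
  )
}

build_pseudo_ii <- function() {
  seqs <- list(
    "1" = random_dna(25),
    "2" = paste0(random_dna(12), encode_peptide(.SIGNAL_II),
                 random_codons(2)),
    "3" = encode_peptide("EIKHVSSSE"),
    "4" = random_codons(10), "5" = random_codons(11), "6" = random_codons(10),
    # exon 7 ends with Asp and exon 8 begins with Glu, so the in-frame 7'
    # insertion falls between mature Asp50 and Glu51
    "7" = paste0(random_codons(7), "GAC"),
    "7'" = encode_peptide("KIELTKEEKLYLKQL"),
    "8" = paste0("GAA", random_codons(8)),
    "9" = random_codons(8),
    "10" = encode_peptide("KTSKKTVDM"),
    "11" = random_codons(8),
    "12" = encode_peptide("EIELSDEEKNYLKQL"),
    "13" = paste0(.ACCEPTOR_33MER, random_codons(29)),
    "14" = paste0(random_codons(3), "TAA", random_dna(33)),
    "15" = random_dna(105),
    "16" = random_dna(210)
  )
  meta <- purrr::map(seqs, ~ list(coding = TRUE, extra = FALSE))
  meta[["1"]]$coding <- FALSE
  meta[["15"]]$coding <- FALSE  # non-coding 3' UTR exon, skippable
  meta[["16"]]$coding <- FALSE
  meta[["7'"]]$extra <- TRUE
  meta[["13"]]$acceptor_offsets <- 33L

  parts <- list()
  labels <- names(seqs)
  for (i in seq_along(labels)) {
    parts[[length(parts) + 1L]] <- list(label = labels[i],
                                        seq = seqs[[labels[i]]])
    if (i < length(labels)) {
      parts[[length(parts) + 1L]] <- list(label = NULL,
                                          seq = make_intron(60L))
    }
  }
  build_model_from_parts(
    gene_id = "pseudo-CSN1S2-II", contig_id = "synthetic_contig_II",
    parts = parts, exon_meta = meta,
    cds_start_exon = "2", cds_start_offset = 12L,
    signal_peptide = .SIGNAL_II,
    flank5 = random_dna(30), flank3 = random_dna(40)
  )
}

#' Synthetic donkey alpha-s2-casein gene models
#'
#' Seed-deterministic gene models emulating the two donkey CSN1S2 paralogs,
#' honoring the published structural constraints:
#'
#' * Pseudo-CSN1S2 I: 19 exons (24-bp exons 4, 8 and 15; >100-bp exon 19;
#'   129-bp exons 12 and 17), signal peptide `MKFFIFTCLLAVALA` at exon-2 nt
#'   12-56, a 221-aa mature protein with the TAA stop at exon-18 nt 10-12,
#'   exons 12 and 17 both opening with the 15-mer `AACAAAATCAACCAG` (NKINQ;
#'   cryptic acceptor at exon-17 offset 15), a 35-nt cryptic-donor trim of
#'   exon 17 whose frameshift reads 8 novel residues into exon 18 before a
#'   relocated TAA at nt 24-26, identical 24-bp exons 8 and 10, and the
#'   optional 105-nt extra exon 12' carrying EGIEIIIFM then TAA at nt 28-30.
#'   The intron before exon 17 ends `TCTAG`, so the acceptor context carries
#'   an XbaI site (T^CTAGA) destroyed by the -1 G>A transition; the site
#'   occurs nowhere else on the contig.
#' * Pseudo-CSN1S2 II: 16 exons (24-bp exons 7, 9 and 11; >200-bp exon 16),
#'   signal peptide `MKFFIITCLLAVALA` at exon-2 nt 13-57, a 142-aa mature
#'   protein with the TAA stop at exon-14 nt 10-12, printed exon peptides
#'   (exon 3 EIKHVSSSE, exon 10 KTSKKTVDM, exon 12 EIELSDEEKNYLKQL), exon 13
#'   opening with the 33-mer `GTGAAAATCAACCCAAAGTTCCCCTCTCCCCAG` (cryptic
#'   acceptor at offset 33), the non-coding 105-nt exon 15, and the optional
#'   in-frame 45-nt extra exon 7' (KIELTKEEKLYLKQL between mature Asp50 and
#'   Glu51).
#'
#' Filler sequence is random but fully determined by `seed`; every generated
#' model passes [validate_gene_model()].
#'
#' @param gene `"I"` or `"II"`.
#' @param seed Integer seed.
#' @return A `csn_gene_model`.
#' @export
donkey_csn1s2_model <- function(gene = c("I", "II"), seed = 1L) {
  gene <- match.arg(gene)
  base <- as.integer(seed) %% 100000L
  for (attempt in 0:49) {
    model <- with_seed(base * 1000L + attempt, {
      if (gene == "I") build_pseudo_i() else build_pseudo_ii()
    })
    rep <- validate_gene_model(model)
    ok <- all(rep$pass)
    if (ok && gene == "I") {
      # the XbaI site must be unique (PCR-RFLP assay design relies on it)
      hits <- gregexpr("TCTAGA", model$contig_seq, fixed = TRUE)[[1]]
      ok <- length(hits) == 1L && hits[1] > 0
    }
    if (ok) return(model)
  }
  stop("could not satisfy model constraints in 50 attempts", call. = FALSE)
}

#' mRNA position of an exon-local site on an isoform
#'
#' @param model A `csn_gene_model`.
#' @param segments Segment tibble of the isoform.
#' @param exon_label,offset Exon and 1-based offset within the full exon.
#' @return 1-based mRNA position, or `NA` if the site is spliced out.
#' @export
mrna_position <- function(model, segments, exon_label, offset) {
  pos <- 0L
  for (i in seq_len(nrow(segments))) {
    e <- exon_row(model, segments$label[i])
    len <- (e$end - e$start) - segments$trim5[i] - segments$trim3[i]
    if (segments$label[i] == exon_label) {
      if (offset <= segments$trim5[i] ||
          offset > (e$end - e$start) - segments$trim3[i]) {
        return(NA_integer_)
      }
      return(pos + (as.integer(offset) - segments$trim5[i]))
    }
    pos <- pos + len
  }
  NA_integer_
}

#' Simulate a cDNA clone library
#'
#' Draws clones from a set of isoform classes, optionally plants SNVs in a
#' fraction of clones, and applies i.i.d. substitution errors per base
#' (substitutions only; indels arise exclusively from splice events, matching
#' the caller's contract). Fully determined by `seed`.
#'
#' @param model A `csn_gene_model`.
#' @param classes Character vector of event-token strings (default: the
#'   published class set for the model's gene via
#'   [csn1s2_isoform_classes()]).
#' @param n_clones Number of clones (default 80, the sequencing scale of one
#'   clone-screening campaign).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param weights Class weights (default uniform; the real libraries' class
#'   weights are unreported).
#' @param snvs Optional planted variants: data frame with columns
#'   `exon_label`, `offset`, `alt`, `carrier_fraction`.
#' @param seed Integer seed.
#' @return A list: `clones` (named character vector), `truth` (tibble
#'   `clone_id`, `pattern_key`, `n_errors`, `n_planted`).
#' @export
simulate_clone_library <- function(model, classes = NULL, n_clones = 80L,
                                   error_rate = 0, weights = NULL,
                                   snvs = NULL, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1)
  if (is.null(classes)) {
    classes <- csn1s2_isoform_classes(
      if (grepl("II", model$gene_id)) "II" else "I")
  }
  isoforms <- purrr::map(classes, ~ apply_events(model, .x))
  if (is.null(weights)) weights <- rep(1, length(classes))
  stopifnot(length(weights) == length(classes), all(weights >= 0))
  weights <- weights / sum(weights)
  if (!is.null(snvs)) snvs <- tibble::as_tibble(snvs)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    idx <- sample.int(length(classes), n_clones, replace = TRUE,
                      prob = weights)
    out <- purrr::map(seq_len(n_clones), function(k) {
      iso <- isoforms[[idx[k]]]
      seqv <- strsplit(iso$mrna, "")[[1]]
      n_planted <- 0L
      if (!is.null(snvs) && nrow(snvs) > 0) {
        for (j in seq_len(nrow(snvs))) {
          if (stats::runif(1) < snvs$carrier_fraction[j]) {
            p <- mrna_position(model, iso$segments, snvs$exon_label[j],
                               snvs$offset[j])
            if (!is.na(p)) {
              seqv[p] <- toupper(snvs$alt[j])
              n_planted <- n_planted + 1L
            }
          }
        }
      }
      n_err <- 0L
      if (error_rate > 0) {
        hit <- which(stats::runif(length(seqv)) < error_rate)
        for (p in hit) {
          seqv[p] <- sample(setdiff(bases, seqv[p]), 1)
        }
        n_err <- length(hit)
      }
      list(seq = paste(seqv, collapse = ""),
           truth = tibble::tibble(
             clone_id = sprintf("clone_%03d", k),
             pattern_key = iso$pattern_key,
             n_errors = n_err, n_planted = n_planted))
    })
    clones <- stats::setNames(purrr::map_chr(out, "seq"),
                              sprintf("clone_%03d", seq_len(n_clones)))
    list(clones = clones,
         truth = dplyr::bind_rows(purrr::map(out, "truth")))
  })
}

#' Write clone sequences as FASTA
#'
#' @param clones Named character vector of DNA sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(clones, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(clones), path)
  invisible(path)
}

#' Simulate a biallelic genotype panel
#'
#' Genotypes are drawn multinomially from Hardy-Weinberg proportions
#' `(p^2, 2pq, q^2)` at the given alternate-allele frequency, or from a
#' user-supplied genotype distribution.
#'
#' @param n Number of individuals.
#' @param q_alt Alternate-allele frequency in `[0, 1]`.
#' @param seed Integer seed.
#' @param hwe Draw under Hardy-Weinberg proportions (default `TRUE`).
#' @param genotype_probs Length-3 probabilities `(hom_ref, het, hom_alt)`
#'   used when `hwe = FALSE`.
#' @param stratum Stratum label for the panel.
#' @return A `csn_panel` (see [genotype_panel()]).
#' @export
simulate_genotype_panel <- function(n, q_alt, seed = 1L, hwe = TRUE,
                                    genotype_probs = NULL, stratum = "all") {
  if (q_alt < 0 || q_alt > 1) stop("invalid allele frequency", call. = FALSE)
  p <- 1 - q_alt
  probs <- if (hwe) c(p^2, 2 * p * q_alt, q_alt^2) else {
    stopifnot(length(genotype_probs) == 3)
    genotype_probs / sum(genotype_probs)
  }
  counts <- with_seed(seed, stats::rmultinom(1, n, probs)[, 1])
  genotype_panel(counts[1], counts[2], counts[3], stratum = stratum)
}
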