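#' Load a restriction-enzyme table
#'
#' The packaged table is a small curated subset of common commercial
#' enzymes (mostly 6-cutters, including XbaI T^CTAGA) with IUPAC recognition
#' sites and top-strand cut offsets; users may supply a full REBASE-derived
#' TSV with columns `name`, `site`, `cut_offset`.
#'
#' @param path Optional TSV path; default is the packaged table.
#' @return A tibble with columns `name`, `site`, `cut_offset`.
#' @export
load_enzymes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "enzymes.tsv", package = "caseinsplice")
  }
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(name = "c", site = "c",
                                          cut_offset = "i"))
}

iupac_ok <- function(site) grepl("^[ACGTRYSWKMBDHVN]+$", toupper(site))

# top-strand cut positions (cut after base k, 1-based; 0 < k < len only)
cut_positions <- function(seq, site, cut_offset) {
  site <- toupper(site)
  if (!iupac_ok(site)) stop("site is not an IUPAC DNA string", call. = FALSE)
  if (cut_offset < 0 || cut_offset > nchar(site)) {
    stop("cut_offset outside the recognition site", call. = FALSE)
  }
  subj <- Biostrings::DNAString(seq)
  slen <- nchar(site)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(site), subj, fixed = FALSE))
  cuts <- fwd + cut_offset - 1L
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(site)))
  if (rc != site) {
    rev <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(rc), subj, fixed = FALSE))
    cuts <- c(cuts, rev + (slen - cut_offset) - 1L)
  }
  cuts <- sort(unique(cuts))
  cuts[cuts > 0 & cuts < nchar(seq)]
}

#' In-silico restriction digest
#'
#' Scans the given strand for every IUPAC match of the recognition site (as
#' written and as its reverse complement; palindromic sites match once per
#' locus) and cuts the top strand after `cut_offset` bases into the site. All
#' overlapping occurrences are cut; n sites yield n+1 fragments whose lengths
#' sum to the sequence length.
#'
#' @param seq DNA string over A/C/G/T.
#' @param enzyme A one-row data frame (or list) with `site` and `cut_offset`,
#'   e.g. one row of [load_enzymes()]; alternatively give `site` /
#'   `cut_offset` directly.
#' @param site,cut_offset Used when `enzyme` is `NULL`.
#' @return Sorted integer vector of fragment lengths (bp).
#' @export
digest <- function(seq, enzyme = NULL, site = NULL, cut_offset = NULL) {
  if (!is.null(enzyme)) {
    site <- enzyme$site
    cut_offset <- enzyme$cut_offset
  }
  cuts <- cut_positions(seq, site, cut_offset)
  sort(as.integer(diff(c(0L, cuts, nchar(seq)))))
}

#' Design allele-discriminating PCR-RFLP assays
#'
#' Digests a reference and an alternate amplicon with every enzyme in the
#' table and reports each enzyme whose fragment pattern differs between
#' alleles, with per-allele and per-genotype band sets (heterozygote = union
#' of the homozygote patterns). Enzymes with degenerate sites that cut both
#' alleles identically are excluded.
#'
#' @param amplicon_ref,amplicon_alt The two allelic amplicon sequences (equal
#'   length, differing at >= 1 position).
#' @param enzymes An enzyme tibble (default: packaged table).
#' @param alleles Length-2 character vector naming the alleles, e.g.
#'   `c("G", "A")`.
#' @return A tibble of class `csn_rflp_assay` with one row per discriminating
#'   enzyme: `enzyme`, `site`, `cut_offset`, `amplicon_len`, list columns
#'   `fragments_ref` / `fragments_alt`, allele names, and a `genotypes` list
#'   column mapping genotype to its sorted band set.
#' @export
design_assay <- function(amplicon_ref, amplicon_alt,
                         enzymes = load_enzymes(),
                         alleles = c("ref", "alt")) {
  if (identical(toupper(amplicon_ref), toupper(amplicon_alt))) {
    stop("the two amplicons are identical", call. = FALSE)
  }
  rows <- purrr::pmap(
    enzymes[, c("name", "site", "cut_offset")],
    function(name, site, cut_offset) {
      fr <- digest(amplicon_ref, site = site, cut_offset = cut_offset)
      fa <- digest(amplicon_alt, site = site, cut_offset = cut_offset)
      if (identical(fr, fa)) return(NULL)
      gt <- list(sort(fr), sort(fa), sort(unique(c(fr, fa))))
      names(gt) <- c(paste0(alleles[1], alleles[1]),
                     paste0(alleles[2], alleles[2]),
                     paste0(alleles[1], alleles[2]))
      tibble::tibble(
        enzyme = name, site = site, cut_offset = cut_offset,
        amplicon_len = nchar(amplicon_ref),
        allele_ref = alleles[1], allele_alt = alleles[2],
        fragments_ref = list(fr), fragments_alt = list(fa),
        genotypes = list(gt))
    })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble::tibble(enzyme = character(), site = character(),
                          cut_offset = integer(), amplicon_len = integer(),
                          allele_ref = character(), allele_alt = character(),
                          fragments_ref = list(), fragments_alt = list(),
                          genotypes = list())
  }
  class(out) <- c("csn_rflp_assay", class(out))
  out
}

#' Call a genotype from observed fragment sizes
#'
#' Matches an observed band set against the expected per-genotype patterns of
#' an assay, allowing a per-band size tolerance (gel resolution; default 5 bp,
#' appropriate for 3% agarose). A pattern matches when observed and expected
#' band lists have equal length and agree pairwise within the tolerance.
#'
#' @param observed Numeric vector of observed band sizes (bp).
#' @param assay One row of a [design_assay()] result.
#' @param tolerance_bp Per-band tolerance (default 5).
#' @return The matching genotype name, or `"unresolved"` when zero or several
#'   genotypes match.
#' @export
genotype_from_fragments <- function(observed, assay, tolerance_bp = 5L) {
  stopifnot(length(observed) > 0)
  if (nrow(assay) != 1) stop("give exactly one assay row", call. = FALSE)
  obs <- sort(as.numeric(observed))
  gt <- assay$genotypes[[1]]
  hits <- names(gt)[purrr::map_lgl(gt, function(exp) {
    length(exp) == length(obs) && all(abs(sort(exp) - obs) <= tolerance_bp)
  })]
  if (length(hits) == 1) hits else "unresolved"
}

#' Export an assay as JSON
#'
#' @param assay A [design_assay()] tibble.
#' @param path Output path.
#' @return `assay`, invisibly.
#' @export
write_assay_json <- function(assay, path) {
  obj <- purrr::pmap(
    assay[, c("enzyme", "site", "cut_offset", "amplicon_len",
              "fragments_ref", "fragments_alt", "genotypes")],
    function(enzyme, site, cut_offset, amplicon_len,
             fragments_ref, fragments_alt, genotypes) {
      list(enzyme = enzyme, site = site, cut_offset = cut_offset,
           amplicon_len = amplicon_len,
           fragments_by_allele = list(ref = fragments_ref,
                                      alt = fragments_alt),
           fragments_by_genotype = genotypes)
    })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(assay)
}

#' Extract the allelic amplicons around a splice-acceptor variant
#'
#' Cuts a genotyping amplicon out of the model contig around an exon's
#' acceptor site and returns the reference amplicon together with the variant
#' amplicon carrying a substitution at an acceptor-relative position
#' (default -1, the last intron base). Amplicon bounds are explicit inputs:
#' `upstream` intronic/exonic bases precede the exon start.
#'
#' @param model A `csn_gene_model`.
#' @param exon_label Exon whose acceptor the amplicon spans.
#' @param upstream Bases of genomic sequence before the exon start.
#' @param width Total amplicon length (bp).
#' @param alt_base Alternate base at `acceptor_offset`.
#' @param acceptor_offset Position of the variant relative to the exon start
#'   (negative = intronic).
#' @return A list with `ref`, `alt` (amplicon strings), `variant_pos`
#'   (1-based position of the variant within the amplicon) and `ref_base`.
#' @export
acceptor_amplicon <- function(model, exon_label, upstream = 191L,
                              width = 558L, alt_base = "A",
                              acceptor_offset = -1L) {
  e <- exon_row(model, exon_label)
  a0 <- e$start - upstream  # 0-based amplicon start
  if (a0 < 0 || a0 + width > nchar(model$contig_seq)) {
    stop("amplicon extends outside the contig", call. = FALSE)
  }
  amp <- substr(model$contig_seq, a0 + 1L, a0 + width)
  vpos <- upstream + acceptor_offset + 1L  # 1-based within amplicon
  ref_base <- substr(amp, vpos, vpos)
  if (toupper(alt_base) == ref_base) {
    stop("alt_base equals the reference base", call. = FALSE)
  }
  alt <- amp
  substr(alt, vpos, vpos) <- toupper(alt_base)
  list(ref = amp, alt = alt, variant_pos = vpos, ref_base = ref_base)
}
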