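#' Run the transcript-analysis stage end to end
#'
#' Calls every clone against the gene model, summarizes the library,
#' translates each observed isoform class, and aggregates clone mismatches
#' into SNVs. Reports are returned as tibbles and, when `out_dir` is given,
#' written as TSVs (`clone_calls.tsv`, `library_summary.tsv`,
#' `isoform_translations.tsv`, `snvs.tsv`). Identical inputs and thresholds
#' yield byte-identical reports.
#'
#' @param model A `csn_gene_model`, or a length-2 character vector
#'   `c(exon_table, fasta)` passed to [read_gene_model()].
#' @param clones Clone sequences as accepted by [call_clones()] (named
#'   vector, `DNAStringSet`, or FASTA path). An empty library yields empty
#'   reports with a warning.
#' @param out_dir Optional output directory (created if missing).
#' @param max_mismatch_per_exon Caller threshold (default 2).
#' @param min_clone_support SNV support threshold (default 2).
#' @param nmd_threshold NMD junction rule distance (default 50 nt).
#' @param config Optional path to a YAML file whose keys override the
#'   threshold arguments (`max_mismatch_per_exon`, `min_clone_support`,
#'   `nmd_threshold`, `out_dir`).
#' @return A list of tibbles: `calls`, `summary` (a `csn_library_summary`),
#'   `translations`, `snvs`, invisibly when `out_dir` is given.
#' @export
run_transcript_analysis <- function(model, clones, out_dir = NULL,
                                    max_mismatch_per_exon = 2L,
                                    min_clone_support = 2L,
                                    nmd_threshold = 50L, config = NULL) {
  if (!is.null(config)) {
    cfg <- yaml::read_yaml(config)
    max_mismatch_per_exon <- cfg$max_mismatch_per_exon %||% max_mismatch_per_exon
    min_clone_support <- cfg$min_clone_support %||% min_clone_support
    nmd_threshold <- cfg$nmd_threshold %||% nmd_threshold
    out_dir <- cfg$out_dir %||% out_dir
  }
  if (is.character(model)) {
    model <- read_gene_model(model[1], model[2])
  }
  if (is.character(clones) && length(clones) == 1L && file.exists(clones)) {
    clones <- Biostrings::readDNAStringSet(clones)
  }
  if (length(clones) == 0) {
    warning("empty clone library: reports will be empty", call. = FALSE)
    calls <- tibble::tibble(clone_id = character(), status = character(),
                            pattern_key = character(), n_events = integer(),
                            n_mismatches = integer(), mismatches = list())
  } else {
    calls <- call_clones(model, clones, max_mismatch_per_exon)
  }
  summ <- summarize_library(calls)
  translations <- if (nrow(summ$patterns) > 0) {
    translate_catalog(model, summ$patterns$pattern_key, nmd_threshold)
  } else {
    tibble::tibble(gene_id = character(), pattern_key = character(),
                   mature_len = integer(), avg_mass_da = double(),
                   frameshifted = logical(), ptc = logical(),
                   nmd_candidate = logical(), novel_cterm = character(),
                   stop_cdna_pos = integer(), status = character())
  }
  snvs <- aggregate_snvs(calls, model, min_clone_support)
  out <- list(calls = calls, summary = summ, translations = translations,
              snvs = snvs)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat_calls <- dplyr::mutate(
      calls,
      mismatches = purrr::map_chr(.data$mismatches, function(m) {
        paste(sprintf("%s:%d:%s>%s", m$exon_label, m$offset_in_exon,
                      m$ref_base, m$clone_base), collapse = ";")
      }))
    readr::write_tsv(flat_calls, file.path(out_dir, "clone_calls.tsv"))
    readr::write_tsv(summ$patterns, file.path(out_dir, "library_summary.tsv"))
    readr::write_tsv(translations,
                     file.path(out_dir, "isoform_translations.tsv"))
    readr::write_tsv(snvs, file.path(out_dir, "snvs.tsv"))
    return(invisible(out))
  }
  out
}

#' Run the genotyping-statistics stage
#'
#' Computes genotype counts, allele frequencies and the Hardy-Weinberg
#' chi-square report for a genotype panel, per stratum and pooled.
#'
#' @param panel A `csn_panel`, or a path to a long-format genotype TSV (see
#'   [read_genotype_tsv()]; requires `ref_allele` / `alt_allele`).
#' @param out_dir Optional output directory for `genotype_stats.tsv`.
#' @param ref_allele,alt_allele Allele characters, used when `panel` is a
#'   file path.
#' @param correct Yates continuity correction for [hwe_test()].
#' @return A list: `frequencies`, `hwe` tibbles.
#' @export
run_genotyping <- function(panel, out_dir = NULL,
                           ref_allele = "G", alt_allele = "A",
                           correct = FALSE) {
  if (is.character(panel)) {
    panel <- read_genotype_tsv(panel, ref_allele, alt_allele)
  }
  freqs <- allele_frequencies(panel)
  hwe <- hwe_test(panel, correct = correct)
  out <- list(frequencies = freqs, hwe = hwe)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tibble::as_tibble(hwe),
                     file.path(out_dir, "genotype_stats.tsv"))
    return(invisible(out))
  }
  out
}
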