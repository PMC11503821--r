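#' Annotate a single-nucleotide variant on the reference isoform
#'
#' Places an exonic substitution on the reference transcript, derives its cDNA
#' position counted from the initiator ATG (+1 = A), the affected codon, and
#' the protein-level consequence in `p.<ref><pos>><alt>` style. Residue
#' numbering follows the mature-protein convention by default (position 1 is
#' the first residue after signal-peptide cleavage); `numbering = "precursor"`
#' counts from the initiator methionine instead.
#'
#' @param model A `csn_gene_model`.
#' @param exon_label Exon carrying the variant.
#' @param offset 1-based nt position within the exon.
#' @param ref,alt Reference and alternate bases (must differ; `ref` must match
#'   the model contig).
#' @param numbering `"mature"` (default) or `"precursor"`.
#' @return A one-row tibble: `gene_id`, `exon_label`, `offset_in_exon`,
#'   `ref_base`, `alt_base`, `cdna_pos`, `codon_number`, `ref_aa`, `alt_aa`,
#'   `synonymous`, `label`.
#' @export
annotate_snv <- function(model, exon_label, offset, ref, alt,
                         numbering = c("mature", "precursor")) {
  numbering <- match.arg(numbering)
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref and alt base are identical", call. = FALSE)
  e <- exon_row(model, exon_label)
  len <- e$end - e$start
  if (offset < 1 || offset > len) {
    stop("offset outside exon '", exon_label, "'", call. = FALSE)
  }
  obs <- substr(model$contig_seq, e$start + offset, e$start + offset)
  if (obs != ref) {
    stop("reference base mismatch at exon ", exon_label, " nt ", offset,
         ": model has ", obs, ", variant says ", ref, call. = FALSE)
  }
  cm <- cds_map(model)
  r <- cm$exons[cm$exons$label == exon_label, ]
  if (nrow(r) == 0) stop("exon '", exon_label, "' is not a reference exon",
                         call. = FALSE)
  if (is.na(r$coding_from) || offset < r$coding_from || offset > r$coding_to) {
    stop("position lies in a non-coding exon or UTR", call. = FALSE)
  }
  cdna_pos <- r$cds_from + (offset - r$coding_from)
  codon_precursor <- (cdna_pos - 1L) %/% 3L + 1L
  phase <- (cdna_pos - 1L) %% 3L  # 0,1,2 within the codon
  cds <- substr(cm$mrna, cm$atg_mrna, cm$atg_mrna + cm$cds_len - 1L)
  codon <- substr(cds, 3L * codon_precursor - 2L, 3L * codon_precursor)
  alt_codon <- codon
  substr(alt_codon, phase + 1L, phase + 1L) <- alt
  ref_aa <- translate_dna(codon)
  alt_aa <- translate_dna(alt_codon)
  codon_number <- if (numbering == "mature") {
    codon_precursor - model$signal_peptide_len
  } else codon_precursor
  synonymous <- ref_aa == alt_aa
  label <- if (synonymous) {
    paste0("p.", ref_aa, codon_number, "=")
  } else {
    paste0("p.", ref_aa, codon_number, ">", alt_aa)
  }
  tibble::tibble(
    gene_id = model$gene_id, exon_label = exon_label,
    offset_in_exon = as.integer(offset), ref_base = ref, alt_base = alt,
    cdna_pos = as.integer(cdna_pos), codon_number = as.integer(codon_number),
    ref_aa = ref_aa, alt_aa = alt_aa, synonymous = synonymous, label = label
  )
}

#' Aggregate clone mismatches into SNVs
#'
#' Pools the per-clone mismatch lists of a library: substitutions observed at
#' the same exon position with the same alternate base in at least
#' `min_clone_support` clones are reported as SNVs; singletons below the
#' threshold are retained as putative RT/PCR/sequencing artifacts rather than
#' silently dropped. Conflicting reference bases at one site indicate a model
#' inconsistency and raise an error.
#'
#' @param calls A calls tibble from [call_clones()] (one gene's library).
#' @param model Optional `csn_gene_model`; when supplied, coding-region SNVs
#'   are annotated via [annotate_snv()] (`cdna_pos`, `codon_number`, `label`,
#'   ...; NA for non-coding positions).
#' @param min_clone_support Minimum clone count for SNV status (default 2).
#' @param numbering Passed to [annotate_snv()].
#' @return A tibble with one row per distinct substitution: `exon_label`,
#'   `offset_in_exon`, `ref_base`, `alt_base`, `n_support`, `status`
#'   (`"snv"` or `"putative_artifact"`) plus annotation columns when `model`
#'   is given.
#' @export
aggregate_snvs <- function(calls, model = NULL, min_clone_support = 2L,
                           numbering = "mature") {
  mm <- dplyr::bind_rows(calls$mismatches[calls$status == "called"])
  if (nrow(mm) > 0) mm <- dplyr::rename(mm, alt_base = "clone_base")
  if (nrow(mm) == 0) {
    out <- tibble::tibble(exon_label = character(),
                          offset_in_exon = integer(), ref_base = character(),
                          alt_base = character(), n_support = integer(),
                          status = character())
    return(out)
  }
  refs <- dplyr::distinct(mm, .data$exon_label, .data$offset_in_exon,
                          .data$ref_base)
  dup <- dplyr::count(refs, .data$exon_label, .data$offset_in_exon)
  if (any(dup$n > 1)) {
    stop("conflicting reference bases at ",
         paste0("exon ", dup$exon_label[dup$n > 1], " nt ",
                dup$offset_in_exon[dup$n > 1], collapse = "; "),
         " (model inconsistency)", call. = FALSE)
  }
  out <- dplyr::count(mm, .data$exon_label, .data$offset_in_exon,
                      .data$ref_base, .data$alt_base, name = "n_support")
  out$status <- ifelse(out$n_support >= min_clone_support,
                       "snv", "putative_artifact")
  out <- dplyr::arrange(out, .data$exon_label, .data$offset_in_exon)
  if (!is.null(model)) {
    ann <- purrr::pmap(
      out[, c("exon_label", "offset_in_exon", "ref_base", "alt_base")],
      function(exon_label, offset_in_exon, ref_base, alt_base) {
        tryCatch(
          annotate_snv(model, exon_label, offset_in_exon, ref_base, alt_base,
                       numbering = numbering)[
            , c("cdna_pos", "codon_number", "ref_aa", "alt_aa",
                "synonymous", "label")],
          error = function(e) tibble::tibble(
            cdna_pos = NA_integer_, codon_number = NA_integer_,
            ref_aa = NA_character_, alt_aa = NA_character_,
            synonymous = NA, label = NA_character_)
        )
      })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(ann))
  }
  out
}

#' Interpret a DNA variant at a splice site
#'
#' For an acceptor-site variant (intronic offsets are negative; -1 is the last
#' intron base), checks whether the substitution destroys the canonical AG
#' dinucleotide. If it does, the downstream exon is scanned with
#' [find_cryptic_acceptors()] for in-frame rescue sites and one predicted
#' `skip_5prime_partial` event is returned per candidate, with the
#' model-annotated (observed) site marked; if no candidate exists, whole-exon
#' skipping is predicted. Donor-side variants (+offsets after the exon;
#' canonical GT) are checked for disruption and predicted as whole-exon
#' skipping. Non-disrupting variants yield no predicted event.
#'
#' @param model A `csn_gene_model`.
#' @param exon_label Exon whose splice site carries the variant.
#' @param ref,alt Reference and alternate bases; `ref` must match the contig.
#' @param offset Position relative to the exon boundary: negative values are
#'   intronic bases upstream of the exon (acceptor side), positive values are
#'   intronic bases downstream (donor side).
#' @param side `"acceptor"` or `"donor"`.
#' @return A tibble with columns `exon_label`, `side`, `offset`, `ref_base`,
#'   `alt_base`, `disrupts_canonical`, `kind`, `length_nt`, `annotated`. One
#'   row per predicted event; a single row with `kind = NA` when the canonical
#'   dinucleotide is intact.
#' @export
classify_splice_variant <- function(model, exon_label, ref, alt,
                                    offset = -1L,
                                    side = c("acceptor", "donor")) {
  side <- match.arg(side)
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) stop("ref and alt base are identical", call. = FALSE)
  e <- exon_row(model, exon_label)
  if (side == "acceptor" && offset >= 0 || side == "donor" && offset <= 0) {
    stop("offset must be negative for acceptor-side and positive for ",
         "donor-side variants", call. = FALSE)
  }
  g <- if (offset < 0) e$start + offset + 1L else e$end + offset  # 1-based
  if (g < 1 || g > nchar(model$contig_seq)) {
    stop("variant position outside contig", call. = FALSE)
  }
  obs <- substr(model$contig_seq, g, g)
  if (obs != ref) {
    stop("reference base mismatch at ", side, " position ", offset,
         " of exon ", exon_label, ": model has ", obs, call. = FALSE)
  }
  if (side == "acceptor") {
    dinuc_pos <- c(e$start - 1L, e$start)  # 1-based intron -2, -1
  } else {
    dinuc_pos <- c(e$end + 1L, e$end + 2L)  # 1-based intron +1, +2
  }
  dinuc <- substr(model$contig_seq, dinuc_pos[1], dinuc_pos[2])
  canonical <- if (side == "acceptor") "AG" else "GT"
  if (dinuc != canonical) {
    stop("no canonical ", canonical, " ", side, " site flanks exon '",
         exon_label, "'", call. = FALSE)
  }
  mut <- dinuc
  hit <- match(g, dinuc_pos)
  if (!is.na(hit)) substr(mut, hit, hit) <- alt
  disrupts <- mut != canonical
  base <- tibble::tibble(exon_label = exon_label, side = side,
                         offset = as.integer(offset), ref_base = ref,
                         alt_base = alt, disrupts_canonical = disrupts)
  if (!disrupts) {
    return(dplyr::mutate(base, kind = NA_character_,
                         length_nt = NA_integer_, annotated = NA))
  }
  if (side == "donor") {
    return(dplyr::mutate(base, kind = "skip_exon",
                         length_nt = NA_integer_, annotated = NA))
  }
  cm <- cds_map(model)
  r <- cm$exons[cm$exons$label == exon_label, ]
  frame <- if (nrow(r) == 1 && !is.na(r$cds_from)) {
    (3L - (r$cds_from - 1L) %% 3L) %% 3L
  } else 0L
  cand <- find_cryptic_acceptors(exon_seq(model, exon_label),
                                 exon_frame = frame, in_frame_only = TRUE)
  cand <- cand[cand < e$end - e$start]  # a full-length trim is not partial
  if (length(cand) == 0) {
    return(dplyr::mutate(base, kind = "skip_exon",
                         length_nt = NA_integer_, annotated = NA))
  }
  dplyr::bind_cols(
    base[rep(1, length(cand)), ],
    tibble::tibble(kind = "skip_5prime_partial", length_nt = as.integer(cand),
                   annotated = cand %in% e$acceptor_offsets[[1]])
  )
}

#' Write SNVs as a minimal VCF-like TSV
#'
#' Contig coordinates are 1-based; INFO carries the exon, cDNA position,
#' protein label and clone support.
#'
#' @param snvs An annotated SNV tibble from [aggregate_snvs()].
#' @param model The `csn_gene_model` the SNVs were called on.
#' @param path Output TSV path.
#' @return `snvs`, invisibly.
#' @export
write_snv_tsv <- function(snvs, model, path) {
  pos <- purrr::map2_int(snvs$exon_label, snvs$offset_in_exon, function(l, o) {
    exon_row(model, l)$start + o
  })
  tab <- tibble::tibble(
    contig = model$contig_id, pos = pos,
    ref = snvs$ref_base, alt = snvs$alt_base,
    info = sprintf("exon=%s;cdna_pos=%s;p=%s;support=%d;status=%s",
                   snvs$exon_label,
                   if (!is.null(snvs$cdna_pos)) snvs$cdna_pos else NA,
                   if (!is.null(snvs$label)) snvs$label else NA,
                   snvs$n_support, snvs$status)
  )
  readr::write_tsv(tab, path)
  invisible(snvs)
}
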