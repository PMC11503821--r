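# Average (isotope-abundance-weighted) residue masses in daltons, unmodified
# side chains, cysteines reduced. One water per peptide chain.
.AA_AVG_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)
.WATER_MASS <- 18.0153

#' Average residue mass table
#'
#' @return A tibble with columns `residue` and `avg_mass_da`, plus the water
#'   mass as the attribute `water_mass`.
#' @export
amino_acid_masses <- function() {
  structure(
    tibble::tibble(residue = names(.AA_AVG_MASS),
                   avg_mass_da = unname(.AA_AVG_MASS)),
    water_mass = .WATER_MASS
  )
}

#' Theoretical average molecular weight of a peptide
#'
#' Sum of average residue masses plus one water mass; the convention behind
#' theoretical-Mw columns of casein isoform tables (average, not monoisotopic;
#' no post-translational modifications).
#'
#' @param peptide Amino-acid string over the 20 canonical residues; the empty
#'   string returns the water mass.
#' @param masses Optional replacement mass table as returned by
#'   [amino_acid_masses()].
#' @return Mass in daltons (full precision; report rounded to 2 decimals).
#' @export
average_mass <- function(peptide, masses = NULL) {
  tab <- .AA_AVG_MASS
  water <- .WATER_MASS
  if (!is.null(masses)) {
    tab <- stats::setNames(masses$avg_mass_da, masses$residue)
    if (!is.null(attr(masses, "water_mass"))) water <- attr(masses, "water_mass")
  }
  if (nchar(peptide) == 0) return(water)
  aa <- strsplit(toupper(peptide), "")[[1]]
  unknown <- setdiff(aa, names(tab))
  if (length(unknown) > 0) {
    stop("unknown residue letter(s): ", paste(unknown, collapse = ","),
         call. = FALSE)
  }
  sum(tab[aa]) + water
}

#' @noRd
translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) stop("cannot translate codon(s): ",
                      paste(codons[is.na(aa)], collapse = ","), call. = FALSE)
  paste(aa, collapse = "")
}

#' Flag a stop codon as a nonsense-mediated-decay candidate
#'
#' Implements the classic 50-nt rule: a termination codon whose start lies more
#' than `threshold` nucleotides upstream of the last exon-exon junction marks
#' the transcript for degradation. The comparison is strict, so a stop exactly
#' at the threshold distance is not flagged.
#'
#' @param stop_cdna_pos 1-based mRNA position of the stop codon's first base.
#' @param junction_positions Ascending 1-based mRNA positions of the exon-exon
#'   junctions (last base of each non-terminal exon).
#' @param threshold Distance in nt (default 50).
#' @return Logical flag.
#' @export
flag_nmd <- function(stop_cdna_pos, junction_positions, threshold = 50L) {
  if (length(junction_positions) == 0) return(FALSE)
  (max(junction_positions) - stop_cdna_pos) > threshold
}

#' Conceptual translation of a transcript isoform
#'
#' Translates an isoform mRNA from the model's initiator ATG to the first
#' in-frame stop, cleaves the annotated signal peptide, and derives the
#' frame/stop diagnostics of a splice-isoform table: whether any event broke
#' the reading frame, whether the stop is premature (genomically upstream of
#' the reference stop), whether the 50-nt junction rule flags the transcript
#' for nonsense-mediated decay, the theoretical average mass of the mature
#' chain, and the novel C-terminal residues translated where the isoform's
#' codon stream leaves the reference codon stream (frameshifted tails, extra
#' exon read-through); in-frame deletions yield no novel C-terminus.
#'
#' Transcripts with no in-frame stop before the mRNA end are reported with
#' `status = "run_off"`, an empty mature sequence and `ptc = FALSE` rather
#' than as an error.
#'
#' @param model A `csn_gene_model`.
#' @param spec A `csn_isoform` from [apply_events()], or an event tibble /
#'   token string, which is applied first.
#' @param nmd_threshold Distance for [flag_nmd()] (default 50 nt).
#' @return An object of class `csn_translation`; see [glance.csn_translation()]
#'   for the one-row summary.
#' @export
translate_isoform <- function(model, spec, nmd_threshold = 50L) {
  if (!inherits(spec, "csn_isoform")) spec <- apply_events(model, spec)
  cm <- cds_map(model)
  segs <- spec$segments
  # mRNA position of the ATG on this isoform
  i_atg <- match(model$cds_start_exon, segs$label)
  if (is.na(i_atg)) {
    stop("isoform removes the exon containing the initiator ATG", call. = FALSE)
  }
  lens <- vapply(seq_len(nrow(segs)), function(i) {
    e <- exon_row(model, segs$label[i])
    (e$end - e$start) - segs$trim5[i] - segs$trim3[i]
  }, 0L)
  if (segs$trim5[i_atg] > model$cds_start_offset) {
    stop("5' trim removes the initiator ATG", call. = FALSE)
  }
  atg <- sum(lens[seq_len(i_atg - 1L)]) +
    (model$cds_start_offset - segs$trim5[i_atg]) + 1L
  mrna <- spec$mrna
  if (substr(mrna, atg, atg + 2L) != "ATG") {
    stop("no ATG at the declared CDS start of this isoform", call. = FALSE)
  }
  aa_full <- translate_dna(substr(mrna, atg, nchar(mrna)))
  stop_at <- regexpr("\\*", aa_full)[1]
  status <- if (stop_at > 0) "ok" else "run_off"
  sig_len <- model$signal_peptide_len

  pos <- segment_positions(model, segs)
  junctions <- utils::head(cumsum(lens), -1)

  frameshifted <- isoform_frameshifted(model, cm, spec$events)

  if (status == "run_off") {
    res <- list(
      gene_id = model$gene_id, pattern_key = spec$pattern_key, status = status,
      precursor_seq = aa_full, signal_peptide = substr(aa_full, 1, sig_len),
      mature_seq = "", mature_len = 0L, avg_mass_da = NA_real_,
      stop_cdna_pos = NA_integer_, frameshifted = frameshifted,
      ptc = FALSE, nmd_candidate = FALSE, novel_cterm = ""
    )
    return(structure(res, class = "csn_translation"))
  }

  n_codons <- stop_at  # includes the stop
  precursor <- substr(aa_full, 1L, n_codons - 1L)
  stop_cdna_pos <- atg + 3L * (n_codons - 1L)
  mature <- substr(precursor, sig_len + 1L, nchar(precursor))

  # genomic triplet of each translated codon (incl. stop)
  codon_pos <- matrix(pos[seq.int(atg, length.out = 3L * n_codons)], nrow = 3L)
  ref_codons <- cm$codon_starts_genomic
  ref_key <- paste(ref_codons[1, ], ref_codons[2, ], ref_codons[3, ])
  iso_key <- paste(codon_pos[1, ], codon_pos[2, ], codon_pos[3, ])
  # reference stop = last reference codon
  ref_stop_genomic <- ref_codons[1, ncol(ref_codons)]
  stop_genomic <- codon_pos[1, n_codons]
  ptc <- is.na(match(iso_key[n_codons], ref_key[ncol(ref_codons)])) &&
    stop_genomic < ref_stop_genomic
  # NMD candidacy presupposes a premature stop: the normal termination codon
  # is not a decay substrate even when non-terminal exons follow it (as the
  # non-coding exon 15 does in CSN1S2 II)
  nmd <- ptc && flag_nmd(stop_cdna_pos, junctions, nmd_threshold)

  # novel C-terminus: residues downstream of the last codon whose genomic
  # triplet is a reference codon (empty when the C-terminus is
  # reference-identical, as after any in-frame deletion or insertion)
  mature_codon_idx <- seq.int(sig_len + 1L, n_codons - 1L)
  novel <- ""
  if (length(mature_codon_idx) > 0) {
    is_ref <- iso_key[mature_codon_idx] %in% ref_key
    if (!any(is_ref)) {
      novel <- mature
    } else if (max(which(is_ref)) < length(is_ref)) {
      novel <- substr(mature, max(which(is_ref)) + 1L, nchar(mature))
    }
  }

  structure(list(
    gene_id = model$gene_id, pattern_key = spec$pattern_key, status = status,
    precursor_seq = precursor,
    signal_peptide = substr(precursor, 1L, sig_len),
    mature_seq = mature, mature_len = nchar(mature),
    avg_mass_da = average_mass(mature),
    stop_cdna_pos = stop_cdna_pos, frameshifted = frameshifted,
    ptc = ptc, nmd_candidate = nmd, novel_cterm = novel
  ), class = "csn_translation")
}

# an event breaks the frame iff the coding nucleotides it removes/inserts are
# not a multiple of 3; removals are intersected with the reference CDS span of
# the exon, insertions within the CDS count their full length
isoform_frameshifted <- function(model, cm, events) {
  if (nrow(events) == 0) return(FALSE)
  any(purrr::pmap_lgl(
    events[, c("kind", "exon_label", "length_nt")],
    function(kind, exon_label, length_nt) {
      if (kind == "include_extra_exon") {
        e <- exon_row(model, exon_label)
        ref_stop <- cm$codon_starts_genomic[1, ncol(cm$codon_starts_genomic)]
        nt <- if (e$start < ref_stop) e$end - e$start else 0L
        return(nt %% 3L != 0L)
      }
      r <- cm$exons[cm$exons$label == exon_label, ]
      if (nrow(r) == 0 || is.na(r$coding_from)) return(FALSE)
      e <- exon_row(model, exon_label)
      len <- e$end - e$start
      removed <- switch(kind,
        skip_exon = c(1L, len),
        skip_5prime_partial = c(1L, length_nt),
        skip_3prime_partial = c(len - length_nt + 1L, len)
      )
      cut <- max(0L, min(removed[2], r$coding_to) -
                   max(removed[1], r$coding_from) + 1L)
      cut %% 3L != 0L
    }
  ))
}

#' @export
print.csn_translation <- function(x, ...) {
  cat(sprintf(
    "<csn_translation> %s [%s]: mature %d aa, %.2f Da%s%s%s%s\n",
    x$gene_id, x$pattern_key, x$mature_len,
    ifelse(is.na(x$avg_mass_da), NA, x$avg_mass_da),
    if (x$frameshifted) ", frameshifted" else "",
    if (x$ptc) ", PTC" else "",
    if (x$nmd_candidate) ", NMD candidate" else "",
    if (x$status != "ok") paste0(" [", x$status, "]") else ""
  ))
  invisible(x)
}

#' One-row summary of a translation result
#'
#' @param x A `csn_translation`.
#' @param ... Unused.
#' @return A one-row tibble, column-compatible with splice-isoform tables:
#'   `pattern_key`, `mature_len`, `avg_mass_da`, `frameshifted`, `ptc`,
#'   `nmd_candidate`, `novel_cterm`, `stop_cdna_pos`, `status`.
#' @export
glance.csn_translation <- function(x, ...) {
  tibble::tibble(
    gene_id = x$gene_id, pattern_key = x$pattern_key,
    mature_len = x$mature_len, avg_mass_da = x$avg_mass_da,
    frameshifted = x$frameshifted, ptc = x$ptc,
    nmd_candidate = x$nmd_candidate, novel_cterm = x$novel_cterm,
    stop_cdna_pos = x$stop_cdna_pos, status = x$status
  )
}

#' @rdname glance.csn_translation
#' @export
tidy.csn_translation <- function(x, ...) glance.csn_translation(x, ...)

#' Translate every isoform of a catalogue
#'
#' @param model A `csn_gene_model`.
#' @param catalog A catalogue tibble from [catalog_from_table()], a character
#'   vector of event-token strings, or a list of `csn_isoform`s.
#' @param nmd_threshold Passed to [translate_isoform()].
#' @return A tibble with one row per isoform (see
#'   [glance.csn_translation()] for columns).
#' @export
translate_catalog <- function(model, catalog, nmd_threshold = 50L) {
  isoforms <- if (is.data.frame(catalog)) catalog$isoform
              else if (is.character(catalog)) purrr::map(catalog, ~ apply_events(model, .x))
              else catalog
  dplyr::bind_rows(purrr::map(
    isoforms, ~ glance.csn_translation(translate_isoform(model, .x, nmd_threshold))
  ))
}

#' Report on a reference cDNA sequence
#'
#' Given a full-length cDNA (e.g. a GenBank mRNA record saved as FASTA),
#' translates the longest ATG-initiated open reading frame (robust to short
#' upstream ATGs in the 5' UTR), cleaves a signal peptide of the given
#' length, and reports mature length and theoretical average mass. Useful for
#' checking deposited reference accessions against printed isoform tables.
#'
#' @param fasta_path Path to a single-record cDNA FASTA.
#' @param signal_peptide_len Residues to cleave from the precursor N-terminus.
#' @return A one-row tibble: `record`, `cdna_length`, `precursor_len`,
#'   `mature_len`, `avg_mass_da`.
#' @export
reference_protein_report <- function(fasta_path, signal_peptide_len = 15L) {
  fa <- Biostrings::readDNAStringSet(fasta_path)
  cdna <- toupper(as.character(fa[[1]]))
  atgs <- gregexpr("ATG", cdna, fixed = TRUE)[[1]]
  if (atgs[1] < 0) stop("no ATG in cDNA", call. = FALSE)
  orfs <- vapply(atgs, function(atg) {
    aa <- translate_dna(substr(cdna, atg, nchar(cdna)))
    stop_at <- regexpr("*", aa, fixed = TRUE)[1]
    if (stop_at > 0) substr(aa, 1, stop_at - 1L) else aa
  }, "")
  precursor <- orfs[which.max(nchar(orfs))]
  mature <- substr(precursor, signal_peptide_len + 1L, nchar(precursor))
  tibble::tibble(
    record = names(fa)[1], cdna_length = nchar(cdna),
    precursor_len = nchar(precursor), mature_len = nchar(mature),
    avg_mass_da = average_mass(mature)
  )
}
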