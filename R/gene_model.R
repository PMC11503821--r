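#' Construct an exon-level gene model
#'
#' A gene model holds one plus-strand contig sequence together with an ordered
#' exon table and the location of the initiator ATG. Coordinates are 0-based
#' half-open internally (`start`/`end` columns); every human-facing report is
#' 1-based. Reverse-strand genes must be reverse-complemented upstream.
#'
#' @param gene_id Gene identifier, e.g. `"CSN1S2-I"`.
#' @param contig_id Name of the contig `contig_seq` comes from.
#' @param contig_seq Contig DNA as a single string over A/C/G/T/N. N is allowed
#'   in the contig but not inside coding exons of the reference isoform.
#' @param exons A data frame with columns `label` (character, unique; primed
#'   labels such as `"12'"` are plain strings), `start`, `end` (0-based
#'   half-open), `coding` (logical), `extra` (logical; `TRUE` for optionally
#'   included exons absent from the reference transcript), and optionally
#'   `acceptor_offsets` / `donor_trims` (list columns of integer nt offsets:
#'   annotated cryptic acceptor positions within the exon, and nt lengths
#'   removable from the 3' end via a cryptic donor).
#' @param cds_start_exon Label of the exon containing the initiator ATG.
#' @param cds_start_offset 0-based offset of the A of the ATG within that exon.
#' @param signal_peptide_len Residue count of the signal peptide (15 for both
#'   donkey alpha-s2-casein genes).
#' @param signal_peptide Optional expected signal-peptide sequence, used by
#'   [validate_gene_model()].
#' @param validate If `TRUE` (default), stop on any failed invariant.
#'
#' @return An object of class `csn_gene_model`.
#' @export
gene_model <- function(gene_id, contig_id, contig_seq, exons,
                       cds_start_exon, cds_start_offset,
                       signal_peptide_len = 15L, signal_peptide = NULL,
                       validate = TRUE) {
  exons <- tibble::as_tibble(exons)
  stopifnot(all(c("label", "start", "end") %in% names(exons)))
  if (!"coding" %in% names(exons)) exons$coding <- TRUE
  if (!"extra" %in% names(exons)) exons$extra <- FALSE
  if (!"acceptor_offsets" %in% names(exons)) {
    exons$acceptor_offsets <- rep(list(integer()), nrow(exons))
  }
  if (!"donor_trims" %in% names(exons)) {
    exons$donor_trims <- rep(list(integer()), nrow(exons))
  }
  exons <- dplyr::mutate(
    exons,
    label = as.character(.data$label),
    start = as.integer(.data$start), end = as.integer(.data$end),
    coding = as.logical(.data$coding), extra = as.logical(.data$extra),
    acceptor_offsets = purrr::map(.data$acceptor_offsets, as.integer),
    donor_trims = purrr::map(.data$donor_trims, as.integer)
  )
  exons <- dplyr::arrange(exons, .data$start)
  model <- structure(
    list(
      gene_id = gene_id, contig_id = contig_id,
      contig_seq = toupper(contig_seq), exons = exons,
      cds_start_exon = as.character(cds_start_exon),
      cds_start_offset = as.integer(cds_start_offset),
      signal_peptide_len = as.integer(signal_peptide_len),
      signal_peptide = signal_peptide
    ),
    class = "csn_gene_model"
  )
  if (validate) {
    rep <- validate_gene_model(model)
    if (!all(rep$pass)) {
      bad <- rep[!rep$pass, ]
      stop("invalid gene model '", gene_id, "': ",
           paste0(bad$check, " (", bad$detail, ")", collapse = "; "),
           call. = FALSE)
    }
  }
  model
}

#' @export
print.csn_gene_model <- function(x, ...) {
  n_extra <- sum(x$exons$extra)
  cat(sprintf(
    "<csn_gene_model> %s on %s: %d exons (%d extra), contig %d bp, ATG at exon %s nt %d\n",
    x$gene_id, x$contig_id, nrow(x$exons), n_extra,
    nchar(x$contig_seq), x$cds_start_exon, x$cds_start_offset + 1L
  ))
  invisible(x)
}

#' @export
#' @rdname gene_model
#' @param x A `csn_gene_model`.
#' @param ... Unused.
tidy.csn_gene_model <- function(x, ...) {
  dplyr::mutate(x$exons, length = .data$end - .data$start,
                gene_id = x$gene_id, .before = 1)
}

exon_row <- function(model, label) {
  i <- match(label, model$exons$label)
  if (is.na(i)) stop("unknown exon label '", label, "' in ", model$gene_id,
                     call. = FALSE)
  model$exons[i, ]
}

#' Extract the sequence of one exon
#'
#' @inheritParams spliced_sequence
#' @param label Exon label.
#' @return A DNA string.
#' @export
exon_seq <- function(model, label) {
  e <- exon_row(model, label)
  substr(model$contig_seq, e$start + 1L, e$end)
}

#' Reference exon segments of a model
#'
#' The reference isoform includes every non-extra exon, untrimmed.
#'
#' @inheritParams spliced_sequence
#' @return A tibble with columns `label`, `trim5`, `trim3`.
#' @export
reference_segments <- function(model) {
  ex <- model$exons[!model$exons$extra, ]
  tibble::tibble(label = ex$label, trim5 = 0L, trim3 = 0L)
}

#' Splice exon segments into a transcript sequence
#'
#' Concatenates the requested exon segments in genomic order. Segments may be
#' trimmed at their 5' end (`trim5`, cryptic-acceptor usage) or 3' end
#' (`trim3`, cryptic-donor usage).
#'
#' @param model A `csn_gene_model`.
#' @param segments A data frame with columns `label` and optionally `trim5`,
#'   `trim3` (nt counts, default 0). Default: all non-extra exons untrimmed
#'   (the reference mRNA). An empty segment table yields an empty string.
#' @return The spliced DNA string.
#' @export
spliced_sequence <- function(model, segments = reference_segments(model)) {
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) == 0) return("")
  if (!"trim5" %in% names(segments)) segments$trim5 <- 0L
  if (!"trim3" %in% names(segments)) segments$trim3 <- 0L
  pieces <- purrr::pmap_chr(
    segments[, c("label", "trim5", "trim3")],
    function(label, trim5, trim3) {
      e <- exon_row(model, label)
      len <- e$end - e$start
      if (trim5 < 0 || trim3 < 0 || trim5 + trim3 > len) {
        stop("segment outside exon bounds for exon '", label, "'",
             call. = FALSE)
      }
      substr(model$contig_seq, e$start + trim5 + 1L, e$end - trim3)
    }
  )
  # genomic order regardless of input row order
  starts <- vapply(segments$label, function(l) exon_row(model, l)$start, 0L)
  paste0(pieces[order(starts)], collapse = "")
}

#' Genomic positions (1-based) covered by a segment table, in transcript order
#' @noRd
segment_positions <- function(model, segments) {
  if (nrow(segments) == 0) return(integer())
  if (!"trim5" %in% names(segments)) segments$trim5 <- 0L
  if (!"trim3" %in% names(segments)) segments$trim3 <- 0L
  starts <- vapply(segments$label, function(l) exon_row(model, l)$start, 0L)
  segments <- segments[order(starts), ]
  unlist(purrr::pmap(
    segments[, c("label", "trim5", "trim3")],
    function(label, trim5, trim3) {
      e <- exon_row(model, label)
      seq.int(e$start + trim5 + 1L, e$end - trim3)
    }
  ), use.names = FALSE)
}

#' Map the reference coding sequence onto the exon table
#'
#' Locates the initiator ATG on the reference mRNA, translates to the first
#' in-frame stop, and returns the coding span of each reference exon, both in
#' exon-local and CDS coordinates.
#'
#' @inheritParams spliced_sequence
#' @return A list with elements `mrna`, `atg_mrna` (1-based mRNA position of
#'   the A of the ATG), `cds_len` (nt, including the stop codon), `stop_found`,
#'   `exons` (tibble: `label`, `mrna_start`, `cds_from`, `cds_to`,
#'   `coding_from`, `coding_to`, exon-local 1-based coding span, NA when
#'   non-coding) and `codon_starts_genomic` (genomic 1-based positions of each
#'   reference codon's three bases, as a 3-row matrix).
#' @export
cds_map <- function(model) {
  segs <- reference_segments(model)
  mrna <- spliced_sequence(model, segs)
  lens <- vapply(segs$label, function(l) {
    e <- exon_row(model, l); e$end - e$start
  }, 0L)
  mrna_start <- cumsum(c(0L, utils::head(lens, -1))) + 1L
  i_atg <- match(model$cds_start_exon, segs$label)
  if (is.na(i_atg)) stop("cds_start_exon is not a reference exon", call. = FALSE)
  atg <- mrna_start[i_atg] + model$cds_start_offset
  if (substr(mrna, atg, atg + 2L) != "ATG") {
    stop("no ATG at the declared CDS start of ", model$gene_id, call. = FALSE)
  }
  aa <- translate_dna(substr(mrna, atg, nchar(mrna)))
  stop_at <- regexpr("\\*", aa)[1]
  stop_found <- stop_at > 0
  n_codons <- if (stop_found) stop_at else floor(nchar(aa))
  cds_len <- 3L * n_codons
  cds_span <- c(atg, atg + cds_len - 1L)
  ex <- tibble::tibble(
    label = segs$label, mrna_start = mrna_start, length = lens,
    cds_from = pmax(cds_span[1], mrna_start) - atg + 1L,
    cds_to = pmin(cds_span[2], mrna_start + lens - 1L) - atg + 1L
  )
  ex <- dplyr::mutate(
    ex,
    has_cds = .data$cds_from <= .data$cds_to,
    coding_from = ifelse(.data$has_cds,
                         .data$cds_from + atg - .data$mrna_start, NA_integer_),
    coding_to = ifelse(.data$has_cds,
                       .data$cds_to + atg - .data$mrna_start, NA_integer_),
    cds_from = ifelse(.data$has_cds, .data$cds_from, NA_integer_),
    cds_to = ifelse(.data$has_cds, .data$cds_to, NA_integer_)
  )
  pos <- segment_positions(model, segs)
  codon_pos <- pos[seq.int(atg, length.out = cds_len)]
  list(
    mrna = mrna, atg_mrna = atg, cds_len = cds_len, stop_found = stop_found,
    n_codons = n_codons, exons = ex,
    codon_starts_genomic = matrix(codon_pos, nrow = 3L)
  )
}

#' Validate a gene model against its invariants
#'
#' Report-only companion to the constructor: every structural invariant is
#' checked and returned as one row, including the "reference isoform translates
#' open from the declared ATG to a stop codon" check.
#'
#' @inheritParams spliced_sequence
#' @return A tibble with columns `check`, `pass`, `detail`.
#' @export
validate_gene_model <- function(model) {
  ex <- model$exons
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, pass = pass, detail = detail)
  }
  add("labels unique", !anyDuplicated(ex$label),
      paste(ex$label[duplicated(ex$label)], collapse = ","))
  add("positive exon lengths", all(ex$end > ex$start))
  ord <- all(diff(ex$start) > 0)
  add("exons ordered by start", ord)
  add("exons non-overlapping",
      ord && all(utils::head(ex$end, -1) <= utils::tail(ex$start, -1)))
  add("contig covers exons", nchar(model$contig_seq) >= max(ex$end))
  add("contig alphabet", grepl("^[ACGTN]*$", model$contig_seq))
  len <- ex$end - ex$start
  add("acceptor offsets inside exon",
      all(purrr::map2_lgl(ex$acceptor_offsets, len,
                          ~ all(.x > 0 & .x < .y))))
  add("donor trims inside exon",
      all(purrr::map2_lgl(ex$donor_trims, len, ~ all(.x > 0 & .x < .y))))
  ok_so_far <- all(purrr::map_lgl(checks, ~ all(.x$pass)))
  if (ok_so_far) {
    cm <- tryCatch(cds_map(model), error = function(e) e)
    if (inherits(cm, "error")) {
      add("reference isoform translates open", FALSE, conditionMessage(cm))
    } else {
      add("stop codon in reference isoform", isTRUE(cm$stop_found))
      prec <- translate_dna(substr(cm$mrna, cm$atg_mrna,
                                   cm$atg_mrna + cm$cds_len - 4L))
      add("reference isoform translates open", !grepl("\\*", prec))
      if (!is.null(model$signal_peptide)) {
        add("signal peptide matches annotation",
            startsWith(prec, model$signal_peptide),
            substr(prec, 1, model$signal_peptide_len))
      }
      coding_seq <- paste0(purrr::map_chr(
        seq_len(nrow(cm$exons)), function(i) {
          r <- cm$exons[i, ]
          if (is.na(r$coding_from)) return("")
          substr(exon_seq(model, r$label), r$coding_from, r$coding_to)
        }), collapse = "")
      add("no N inside coding exons", !grepl("N", coding_seq))
      # declared coding flags agree with the CDS overlap of reference exons
      flag <- ex$coding[!ex$extra]
      add("coding flags match CDS", all(flag == !is.na(cm$exons$cds_from)))
    }
  }
  dplyr::bind_rows(checks)
}

# ---- IO ----------------------------------------------------------------

fmt_int_list <- function(x) vapply(x, function(v) paste(v, collapse = ","), "")

parse_int_list <- function(x) {
  purrr::map(x, function(v) {
    if (is.na(v) || v == "") integer() else as.integer(strsplit(v, ",")[[1]])
  })
}

#' Write a gene model to an exon TSV and a contig FASTA
#'
#' The TSV carries the exon table (columns `label`, `start`, `end`, `coding`,
#' `extra`, `acceptor_offsets`, `donor_trims`; list columns comma-joined) and
#' the gene-level annotations as `# key=value` header comments, so that
#' [read_gene_model()] round-trips the model field-for-field.
#'
#' @inheritParams spliced_sequence
#' @param exon_path,fasta_path Output file paths.
#' @return `model`, invisibly.
#' @export
write_gene_model <- function(model, exon_path, fasta_path) {
  hdr <- c(
    paste0("# gene_id=", model$gene_id),
    paste0("# contig_id=", model$contig_id),
    paste0("# cds_start_exon=", model$cds_start_exon),
    paste0("# cds_start_offset=", model$cds_start_offset),
    paste0("# signal_peptide_len=", model$signal_peptide_len),
    if (!is.null(model$signal_peptide))
      paste0("# signal_peptide=", model$signal_peptide)
  )
  tab <- dplyr::mutate(
    model$exons,
    acceptor_offsets = fmt_int_list(.data$acceptor_offsets),
    donor_trims = fmt_int_list(.data$donor_trims)
  )
  writeLines(c(hdr, paste(names(tab), collapse = "\t")), exon_path)
  utils::write.table(tab, exon_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  dna <- Biostrings::DNAStringSet(stats::setNames(model$contig_seq,
                                                  model$contig_id))
  Biostrings::writeXStringSet(dna, fasta_path)
  invisible(model)
}

#' Read a gene model from an exon table and a FASTA
#'
#' Accepts the TSV written by [write_gene_model()] (gene-level annotations in
#' `# key=value` comments, overridable through the arguments) or a GFF3 file of
#' exon features carrying a `label` attribute (requires rtracklayer).
#'
#' @param exon_table_path Path to the exon TSV (or `.gff`/`.gff3`).
#' @param fasta_path Path to the contig FASTA; the contig named in the header
#'   must be present.
#' @param gene_id,contig_id,cds_start_exon,cds_start_offset,signal_peptide_len,signal_peptide
#'   Optional overrides for the header annotations.
#' @return A validated `csn_gene_model`.
#' @export
read_gene_model <- function(exon_table_path, fasta_path,
                            gene_id = NULL, contig_id = NULL,
                            cds_start_exon = NULL, cds_start_offset = NULL,
                            signal_peptide_len = NULL, signal_peptide = NULL) {
  meta <- list()
  if (grepl("\\.gff3?$", exon_table_path, ignore.case = TRUE)) {
    exons <- read_exons_gff3(exon_table_path)
  } else {
    lines <- readLines(exon_table_path)
    hdr <- grep("^# ", lines, value = TRUE)
    for (h in hdr) {
      kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
      if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
    }
    exons <- readr::read_tsv(exon_table_path, comment = "#",
                             show_col_types = FALSE,
                             col_types = readr::cols(
                               label = "c", start = "i", end = "i",
                               coding = "l", extra = "l",
                               acceptor_offsets = "c", donor_trims = "c"))
    exons$acceptor_offsets <- parse_int_list(exons$acceptor_offsets)
    exons$donor_trims <- parse_int_list(exons$donor_trims)
  }
  pick <- function(arg, key, cast = identity) {
    if (!is.null(arg)) return(arg)
    if (!is.null(meta[[key]])) return(cast(meta[[key]]))
    stop("gene annotation '", key, "' missing from header and arguments",
         call. = FALSE)
  }
  contig_id <- pick(contig_id, "contig_id")
  fa <- Biostrings::readDNAStringSet(fasta_path)
  names(fa) <- sub("\\s.*$", "", names(fa))
  if (!contig_id %in% names(fa)) {
    stop("contig '", contig_id, "' not found in ", fasta_path, call. = FALSE)
  }
  gene_model(
    gene_id = pick(gene_id, "gene_id"),
    contig_id = contig_id,
    contig_seq = as.character(fa[[contig_id]]),
    exons = exons,
    cds_start_exon = pick(cds_start_exon, "cds_start_exon"),
    cds_start_offset = pick(cds_start_offset, "cds_start_offset", as.integer),
    signal_peptide_len = pick(signal_peptide_len, "signal_peptide_len",
                              as.integer),
    signal_peptide = if (!is.null(signal_peptide)) signal_peptide
                     else meta[["signal_peptide"]]
  )
}

#' @noRd
read_exons_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GFF3 import requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  md <- as.data.frame(gr)
  if (is.null(md$label)) stop("GFF3 exon features need a 'label' attribute",
                              call. = FALSE)
  get_l <- function(col) {
    if (is.null(md[[col]])) rep(list(integer()), nrow(md))
    else parse_int_list(as.character(md[[col]]))
  }
  tibble::tibble(
    label = as.character(md$label),
    start = as.integer(md$start) - 1L,  # GFF3 is 1-based closed
    end = as.integer(md$end),
    coding = if (is.null(md$coding)) TRUE else as.logical(md$coding),
    extra = if (is.null(md$extra)) FALSE else as.logical(md$extra),
    acceptor_offsets = get_l("acceptor_offsets"),
    donor_trims = get_l("donor_trims")
  )
}
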