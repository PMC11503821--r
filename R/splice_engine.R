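#' Declarative splice events
#'
#' Constructors for the four event kinds observed in donkey alpha-s2-casein
#' clone libraries: whole-exon skipping, partial 5' skipping via a cryptic
#' acceptor, partial 3' skipping via a cryptic donor, and inclusion of an
#' optionally recognized ("extra") exon such as 12' or 7'. Each returns a
#' one-row tibble; rows combine with [dplyr::bind_rows()] or `c()`-style
#' vectors of event tokens (see [parse_events()]).
#'
#' @param label Exon label the event applies to.
#' @param nt Number of nucleotides removed (partial kinds only).
#' @return A tibble with columns `kind`, `exon_label`, `length_nt`.
#' @name splice_events
NULL

event_row <- function(kind, label, nt = NA_integer_) {
  tibble::tibble(kind = kind, exon_label = as.character(label),
                 length_nt = as.integer(nt))
}

#' @rdname splice_events
#' @export
skip_exon <- function(label) event_row("skip_exon", label)

#' @rdname splice_events
#' @export
skip_5prime <- function(label, nt) event_row("skip_5prime_partial", label, nt)

#' @rdname splice_events
#' @export
skip_3prime <- function(label, nt) event_row("skip_3prime_partial", label, nt)

#' @rdname splice_events
#' @export
include_exon <- function(label) event_row("include_extra_exon", label)

#' Parse splice-event tokens
#'
#' Accepts the compact catalog vocabulary: `skip:<label>`, `skip5:<label>:<nt>`,
#' `skip3:<label>:<nt>`, `insert:<label>`, comma-separated. The tokens `"FL"`
#' and `""` denote the reference isoform (no events).
#'
#' @param tokens A single string of comma-separated tokens.
#' @return An event tibble (possibly zero rows).
#' @export
parse_events <- function(tokens) {
  tokens <- trimws(tokens)
  if (length(tokens) != 1L || is.na(tokens)) stop("need one token string")
  if (tokens %in% c("", "FL")) return(event_row(character(0), character(0)))
  parts <- strsplit(tokens, ",", fixed = TRUE)[[1]]
  rows <- purrr::map(parts, function(tk) {
    f <- strsplit(trimws(tk), ":", fixed = TRUE)[[1]]
    switch(f[1],
      skip = skip_exon(f[2]),
      skip5 = skip_5prime(f[2], as.integer(f[3])),
      skip3 = skip_3prime(f[2], as.integer(f[3])),
      insert = include_exon(f[2]),
      stop("unparseable splice-event token '", tk, "'", call. = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

event_token <- function(kind, label, nt) {
  switch(kind,
    skip_exon = paste0("skip:", label),
    skip_5prime_partial = paste0("skip5:", label, ":", nt),
    skip_3prime_partial = paste0("skip3:", label, ":", nt),
    include_extra_exon = paste0("insert:", label)
  )
}

canonical_events <- function(model, events) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0) return(events)
  starts <- vapply(events$exon_label,
                   function(l) exon_row(model, l)$start, 0L)
  events[order(starts, events$kind != "skip_exon"), ]
}

#' Canonical pattern key of an event set
#'
#' Events are ordered by exon genomic start (whole-exon events before partial
#' events on ties) and rendered as tokens; the empty set is `"FL"`. The key is
#' injective over valid event sets of a model.
#'
#' @inheritParams apply_events
#' @return A string such as `"skip:4,skip:5,skip:6,skip5:17:15"`.
#' @export
pattern_key <- function(model, events) {
  events <- canonical_events(model, events)
  if (nrow(events) == 0) return("FL")
  paste(purrr::pmap_chr(
    events[, c("kind", "exon_label", "length_nt")],
    function(kind, exon_label, length_nt) event_token(kind, exon_label, length_nt)
  ), collapse = ",")
}

validate_events <- function(model, events) {
  if (nrow(events) == 0) return(invisible(events))
  if (anyDuplicated(events$exon_label)) {
    stop("conflicting events on exon(s) ",
         paste(unique(events$exon_label[duplicated(events$exon_label)]),
               collapse = ","), call. = FALSE)
  }
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    e <- exon_row(model, ev$exon_label)
    len <- e$end - e$start
    partial <- ev$kind %in% c("skip_5prime_partial", "skip_3prime_partial")
    if (partial) {
      if (is.na(ev$length_nt)) stop("partial event needs length_nt")
      if (ev$length_nt <= 0 || ev$length_nt >= len) {
        stop("partial length ", ev$length_nt, " outside exon '",
             ev$exon_label, "' (", len, " nt)", call. = FALSE)
      }
    } else if (!is.na(ev$length_nt)) {
      stop("length_nt only applies to partial events", call. = FALSE)
    }
    if (ev$kind == "include_extra_exon" && !e$extra) {
      stop("exon '", ev$exon_label, "' is not an extra exon", call. = FALSE)
    }
    if (ev$kind != "include_extra_exon" && e$extra) {
      stop("skip events do not apply to extra exon '", ev$exon_label, "'",
           call. = FALSE)
    }
  }
  invisible(events)
}

#' Apply splice events to a gene model
#'
#' Builds the transcript isoform implied by a set of splice events: the
#' reference exon set minus skipped (sub)segments plus any included extra
#' exons, concatenated in genomic order.
#'
#' @param model A `csn_gene_model`.
#' @param events An event tibble (see [splice_events]) or a token string
#'   accepted by [parse_events()]. Zero events yield the reference isoform.
#' @return An object of class `csn_isoform`: list with `gene_id`, `events`
#'   (canonically ordered), `segments`, `mrna`, `pattern_key`.
#' @export
apply_events <- function(model, events) {
  if (is.character(events)) events <- parse_events(events)
  events <- canonical_events(model, tibble::as_tibble(events))
  validate_events(model, events)
  segs <- reference_segments(model)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (ev$kind == "include_extra_exon") {
      segs <- dplyr::bind_rows(segs, tibble::tibble(
        label = ev$exon_label, trim5 = 0L, trim3 = 0L))
    } else if (ev$kind == "skip_exon") {
      segs <- segs[segs$label != ev$exon_label, ]
    } else {
      j <- match(ev$exon_label, segs$label)
      if (is.na(j)) stop("partial event on absent exon '", ev$exon_label, "'")
      if (ev$kind == "skip_5prime_partial") segs$trim5[j] <- ev$length_nt
      else segs$trim3[j] <- ev$length_nt
    }
  }
  starts <- vapply(segs$label, function(l) exon_row(model, l)$start, 0L)
  segs <- segs[order(starts), ]
  structure(
    list(gene_id = model$gene_id, events = events, segments = segs,
         mrna = spliced_sequence(model, segs),
         pattern_key = pattern_key(model, events)),
    class = "csn_isoform"
  )
}

#' @export
print.csn_isoform <- function(x, ...) {
  cat(sprintf("<csn_isoform> %s [%s]: %d nt mRNA, %d event(s)\n",
              x$gene_id, x$pattern_key, nchar(x$mrna), nrow(x$events)))
  invisible(x)
}

#' @export
#' @rdname apply_events
#' @param x A `csn_isoform`.
#' @param ... Unused.
tidy.csn_isoform <- function(x, ...) {
  dplyr::mutate(x$events, gene_id = x$gene_id,
                pattern_key = x$pattern_key, .before = 1)
}

#' Scan an exon for candidate cryptic splice-acceptor sites
#'
#' Returns every offset `o` such that the last two bases of the exon's first
#' `o` nucleotides are the acceptor dinucleotide AG, i.e. splicing onto the
#' exon at `o` would remove its first `o` bases. With `in_frame_only = TRUE`
#' (the biologically interesting case for coding exons) only offsets that
#' preserve codon phase are kept: `(o - exon_frame) %% 3 == 0`, which for
#' exons beginning on a codon boundary (`exon_frame = 0`, as in both printed
#' donkey cases) means multiples of 3. All candidates are returned; choosing
#' among them is evidence-driven, never "first match".
#'
#' @param exon_seq Exon DNA string.
#' @param exon_frame 0, 1 or 2: nt of the exon's start completing the previous
#'   codon.
#' @param in_frame_only Keep only frame-preserving offsets (default `TRUE`).
#' @return An ascending integer vector of offsets (possibly empty).
#' @export
find_cryptic_acceptors <- function(exon_seq, exon_frame = 0L,
                                   in_frame_only = TRUE) {
  stopifnot(nchar(exon_seq) > 0)
  v <- strsplit(toupper(exon_seq), "")[[1]]
  n <- length(v)
  if (n < 2) return(integer())
  o <- which(utils::head(v, -1) == "A" & utils::tail(v, -1) == "G") + 1L
  if (in_frame_only) o <- o[(o - as.integer(exon_frame)) %% 3L == 0L]
  o
}

#' Build an isoform catalogue from event descriptions
#'
#' One isoform per row of `rows`, deduplicated by canonical pattern key.
#'
#' @inheritParams apply_events
#' @param rows Character vector of event-token strings (`"FL"` for the
#'   reference), or a data frame with a `pattern` column.
#' @return A tibble with columns `pattern_key`, `n_events`, `mrna_length` and
#'   a list column `isoform` of `csn_isoform` objects.
#' @export
catalog_from_table <- function(model, rows) {
  if (is.data.frame(rows)) rows <- rows$pattern
  isoforms <- purrr::map(rows, ~ apply_events(model, .x))
  keys <- purrr::map_chr(isoforms, "pattern_key")
  keep <- !duplicated(keys)
  isoforms <- isoforms[keep]
  tibble::tibble(
    pattern_key = keys[keep],
    n_events = purrr::map_int(isoforms, ~ nrow(.x$events)),
    mrna_length = purrr::map_int(isoforms, ~ nchar(.x$mrna)),
    isoform = isoforms
  )
}

#' Published splice-pattern classes of the donkey CSN1S2 genes
#'
#' The distinct isoform classes recovered from Ragusana clone libraries at the
#' two loci, as event-token strings over the synthetic gene models: 8 classes
#' for CSN1S2 I and 9 for CSN1S2 II (counting the presence/absence of the
#' non-coding exon 15 as distinct patterns).
#'
#' @param gene `"I"` or `"II"`.
#' @return A character vector of token strings (first element `"FL"`).
#' @export
csn1s2_isoform_classes <- function(gene = c("I", "II")) {
  gene <- match.arg(gene)
  if (gene == "I") {
    c("FL",
      "skip:11",
      "insert:12'",
      "skip:4,skip:5,skip:6,skip3:17:35",
      "skip3:17:35",
      "skip:4,skip:5,skip:6",
      "skip:4,skip:5,skip:6,skip5:17:15",
      "skip5:17:15")
  } else {
    c("FL",
      "skip:15",
      "insert:7'",
      "skip:9,insert:7'",
      "skip:9",
      "skip:10",
      "skip:11,skip:12,skip5:13:33",
      "skip:11,skip:12,skip5:13:33,skip:15",
      "skip:9,skip:10,skip:15")
  }
}
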