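# Per-exon matching options for the caller: full match, annotated 5'/3'
# truncations, whole-exon skip; extra exons are absent by default and
# included as an event. Substitutions are scored inside exons; indels are
# explained exclusively by splice events (Sanger-clone scale data).
caller_units <- function(model) {
  ex <- model$exons
  purrr::map(seq_len(nrow(ex)), function(i) {
    e <- ex[i, ]
    seqch <- substr(model$contig_seq, e$start + 1L, e$end)
    len <- nchar(seqch)
    opts <- list()
    if (e$extra) {
      opts[[1]] <- list(token = NA_character_, n_events = 0L, trim5 = 0L,
                        seq = "", raw = raw(0))
      opts[[2]] <- list(token = paste0("insert:", e$label), n_events = 1L,
                        trim5 = 0L, seq = seqch, raw = charToRaw(seqch))
    } else {
      opts[[1]] <- list(token = NA_character_, n_events = 0L, trim5 = 0L,
                        seq = seqch, raw = charToRaw(seqch))
      k <- 2L
      for (o in e$acceptor_offsets[[1]]) {
        s <- substr(seqch, o + 1L, len)
        opts[[k]] <- list(token = paste0("skip5:", e$label, ":", o),
                          n_events = 1L, trim5 = as.integer(o),
                          seq = s, raw = charToRaw(s))
        k <- k + 1L
      }
      for (t in e$donor_trims[[1]]) {
        s <- substr(seqch, 1L, len - t)
        opts[[k]] <- list(token = paste0("skip3:", e$label, ":", t),
                          n_events = 1L, trim5 = 0L,
                          seq = s, raw = charToRaw(s))
        k <- k + 1L
      }
      opts[[k]] <- list(token = paste0("skip:", e$label), n_events = 1L,
                        trim5 = 0L, seq = "", raw = raw(0))
    }
    list(label = e$label, opts = opts)
  })
}

#' Classify one cDNA clone sequence against a gene model
#'
#' Dynamic program over (exon index, clone position): at each exon the caller
#' branches on matching the full exon, matching with an annotated 5' or 3'
#' truncation, skipping the exon, or including a following extra exon, scoring
#' base mismatches per exon. The objective minimizes `(n_events,
#' n_mismatches, lexicographic pattern key)`, preferring parsimonious splice
#' explanations over mismatch-heavy ones. A clone is `ambiguous` when two or
#' more distinct optimal patterns tie on events and mismatches (the
#' lexicographically smallest is reported), and `unalignable` when no branch
#' reaches the end of the clone within the per-exon mismatch cap (including
#' partial amplicons, which are out of scope for calling).
#'
#' @param model A `csn_gene_model`.
#' @param clone_seq Clone DNA string in mRNA orientation, spanning the full
#'   transcript.
#' @param clone_id Identifier carried into the result.
#' @param max_mismatch_per_exon Substitution cap per exon segment (default 2,
#'   accommodating the observed SNV density of ≤2 per exon).
#' @return A one-row tibble: `clone_id`, `status` (`called`, `ambiguous`,
#'   `unalignable`), `pattern_key`, `n_events`, `n_mismatches`, and a list
#'   column `mismatches` of tibbles `(exon_label, offset_in_exon, ref_base,
#'   clone_base)` with 1-based offsets in full-exon coordinates.
#' @export
call_clone <- function(model, clone_seq, clone_id = "clone",
                       max_mismatch_per_exon = 2L) {
  units <- caller_units(model)
  call_clone_impl(model, units, clone_seq, clone_id, max_mismatch_per_exon)
}

call_clone_impl <- function(model, units, clone_seq, clone_id,
                            max_mismatch_per_exon) {
  clone_raw <- charToRaw(toupper(clone_seq))
  nc <- length(clone_raw)
  n <- length(units)
  memo <- new.env(parent = emptyenv())

  solve <- function(i, pos) {
    if (i > n) {
      if (pos == nc) return(list(ev = 0L, mm = 0L, keys = ""))
      return(NULL)
    }
    key <- paste0(i, ":", pos)
    if (!is.null(memo[[key]])) {
      return(if (identical(memo[[key]], "fail")) NULL else memo[[key]])
    }
    best <- NULL
    for (opt in units[[i]]$opts) {
      len <- length(opt$raw)
      if (pos + len > nc) next
      mm <- if (len == 0L) 0L
            else sum(clone_raw[(pos + 1L):(pos + len)] != opt$raw)
      if (mm > max_mismatch_per_exon) next
      sub <- solve(i + 1L, pos + len)
      if (is.null(sub)) next
      ev <- opt$n_events + sub$ev
      tot_mm <- mm + sub$mm
      keys <- if (is.na(opt$token)) sub$keys
              else ifelse(sub$keys == "", opt$token,
                          paste0(opt$token, ",", sub$keys))
      if (is.null(best) || ev < best$ev ||
          (ev == best$ev && tot_mm < best$mm)) {
        best <- list(ev = ev, mm = tot_mm, keys = unique(keys))
      } else if (ev == best$ev && tot_mm == best$mm) {
        best$keys <- unique(c(best$keys, keys))
      }
    }
    memo[[key]] <- if (is.null(best)) "fail" else best
    best
  }

  res <- solve(1L, 0L)
  empty_mm <- tibble::tibble(exon_label = character(), offset_in_exon = integer(),
                             ref_base = character(), clone_base = character())
  if (is.null(res)) {
    return(tibble::tibble(
      clone_id = clone_id, status = "unalignable", pattern_key = NA_character_,
      n_events = NA_integer_, n_mismatches = NA_integer_,
      mismatches = list(empty_mm)))
  }
  keys <- sort(res$keys)
  pattern <- if (keys[1] == "") "FL" else keys[1]
  status <- if (length(keys) > 1L) "ambiguous" else "called"

  # the pattern fully determines the option taken at each exon, so mismatches
  # are recovered by replaying the chosen segments against the clone
  chosen <- if (pattern == "FL") character() else strsplit(pattern, ",")[[1]]
  by_label <- stats::setNames(
    chosen, purrr::map_chr(chosen, ~ strsplit(.x, ":", fixed = TRUE)[[1]][2]))
  mms <- list()
  pos <- 0L
  for (u in units) {
    tok <- if (u$label %in% names(by_label)) by_label[[u$label]] else NULL
    opt <- NULL
    for (o in u$opts) {
      if (is.null(tok) && is.na(o$token)) { opt <- o; break }
      if (!is.null(tok) && !is.na(o$token) && o$token == tok) { opt <- o; break }
    }
    len <- length(opt$raw)
    if (len > 0L) {
      seg <- clone_raw[(pos + 1L):(pos + len)]
      d <- which(seg != opt$raw)
      if (length(d) > 0L) {
        mms[[length(mms) + 1L]] <- tibble::tibble(
          exon_label = u$label,
          offset_in_exon = as.integer(opt$trim5 + d),
          ref_base = strsplit(opt$seq, "")[[1]][d],
          clone_base = strsplit(rawToChar(seg), "")[[1]][d])
      }
    }
    pos <- pos + len
  }
  mm_tbl <- if (length(mms) > 0) dplyr::bind_rows(mms) else empty_mm
  tibble::tibble(
    clone_id = clone_id, status = status, pattern_key = pattern,
    n_events = res$ev, n_mismatches = res$mm, mismatches = list(mm_tbl))
}

#' Classify a library of clone sequences
#'
#' @inheritParams call_clone
#' @param clones A named character vector of clone sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a clone FASTA.
#' @return A tibble with one row per clone (see [call_clone()]).
#' @export
call_clones <- function(model, clones, max_mismatch_per_exon = 2L) {
  if (is.character(clones) && length(clones) == 1L && file.exists(clones)) {
    clones <- Biostrings::readDNAStringSet(clones)
  }
  if (inherits(clones, "DNAStringSet")) {
    clones <- stats::setNames(as.character(clones), names(clones))
  }
  if (is.null(names(clones))) {
    names(clones) <- paste0("clone_", seq_along(clones))
  }
  units <- caller_units(model)
  dplyr::bind_rows(purrr::imap(
    clones, ~ call_clone_impl(model, units, .x, .y, max_mismatch_per_exon)))
}

#' Summarize a clone library's isoform composition
#'
#' Distinct splice patterns among cleanly called clones, with counts and
#' frequencies; ambiguous and unalignable clones are excluded from the pattern
#' counts but reported alongside.
#'
#' @param calls A calls tibble from [call_clones()].
#' @return An object of class `csn_library_summary`: list with `patterns`
#'   (tibble `pattern_key`, `n_clones`, `frequency`), `n_called`,
#'   `n_ambiguous`, `n_unalignable`.
#' @export
summarize_library <- function(calls) {
  called <- calls[calls$status == "called", ]
  pat <- dplyr::count(called, .data$pattern_key, name = "n_clones",
                      sort = TRUE)
  pat$frequency <- if (nrow(called) > 0) pat$n_clones / nrow(called)
                   else numeric(0)
  structure(list(
    patterns = pat,
    n_called = nrow(called),
    n_ambiguous = sum(calls$status == "ambiguous"),
    n_unalignable = sum(calls$status == "unalignable")
  ), class = "csn_library_summary")
}

#' @export
print.csn_library_summary <- function(x, ...) {
  cat(sprintf(
    "<csn_library_summary> %d called (%d patterns), %d ambiguous, %d unalignable\n",
    x$n_called, nrow(x$patterns), x$n_ambiguous, x$n_unalignable))
  print(x$patterns)
  invisible(x)
}

#' @export
#' @rdname summarize_library
#' @param x A `csn_library_summary`.
#' @param ... Unused.
tidy.csn_library_summary <- function(x, ...) x$patterns

#' @export
#' @rdname summarize_library
glance.csn_library_summary <- function(x, ...) {
  tibble::tibble(n_patterns = nrow(x$patterns), n_called = x$n_called,
                 n_ambiguous = x$n_ambiguous, n_unalignable = x$n_unalignable)
}
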