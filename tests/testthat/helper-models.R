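# shared fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())

test_model <- function(gene = "I") {
  key <- paste0("model_", gene)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- donkey_csn1s2_model(gene, seed = 42)
  }
  .fixtures[[key]]
}

# small gene model for oracle comparisons: n regular exons (random codon
# content), an optional extra exon, annotated 5' offsets / 3' trims;
# translation validity is irrelevant to the caller, so validation is off
toy_caller_model <- function(seed, n_exons = 5) {
  set.seed(seed)
  codons <- c("GCT", "AAA", "GAA", "TTC", "CAG", "GGT", "ATC", "ACG")
  rnd <- function(n) paste(sample(codons, n, replace = TRUE), collapse = "")
  seqs <- lapply(seq_len(n_exons), function(i) rnd(sample(3:5, 1)))
  extra_after <- if (n_exons >= 3) 2L else NA_integer_
  extra_seq <- rnd(3)
  intron <- function() paste0("GT", rnd(4), "AG")
  pieces <- character(0)
  rows <- list()
  pos <- 0L
  add_exon <- function(label, s, extra = FALSE, acc = integer(),
                       don = integer()) {
    pieces <<- c(pieces, s)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      label = label, start = pos, end = pos + nchar(s),
      coding = TRUE, extra = extra,
      acceptor_offsets = list(acc), donor_trims = list(don))
    pos <<- pos + nchar(s)
  }
  add_intron <- function() {
    s <- intron(); pieces <<- c(pieces, s); pos <<- pos + nchar(s)
  }
  for (i in seq_len(n_exons)) {
    len <- nchar(seqs[[i]])
    acc <- if (i == n_exons) 3L else integer()   # annotated 5' option
    don <- if (i == 1L) 3L else integer()        # annotated 3' option
    add_exon(as.character(i), seqs[[i]], acc = acc, don = don)
    if (!is.na(extra_after) && i == extra_after) {
      add_intron(); add_exon("x", extra_seq, extra = TRUE)
    }
    if (i < n_exons) add_intron()
  }
  gene_model("toy", "toy_contig", paste(pieces, collapse = ""),
             dplyr::bind_rows(rows),
             cds_start_exon = "1", cds_start_offset = 0L,
             signal_peptide_len = 0L, validate = FALSE)
}

# brute-force caller oracle: exhaustive enumeration of all per-exon options
brute_force_call <- function(model, clone, cap = 2L) {
  ex <- model$exons
  opts_per_exon <- lapply(seq_len(nrow(ex)), function(i) {
    e <- ex[i, ]
    s <- substr(model$contig_seq, e$start + 1L, e$end)
    len <- nchar(s)
    if (e$extra) {
      list(list(tok = NA_character_, seq = "", ev = 0L),
           list(tok = paste0("insert:", e$label), seq = s, ev = 1L))
    } else {
      o <- list(list(tok = NA_character_, seq = s, ev = 0L),
                list(tok = paste0("skip:", e$label), seq = "", ev = 1L))
      for (a in e$acceptor_offsets[[1]]) {
        o[[length(o) + 1L]] <- list(
          tok = paste0("skip5:", e$label, ":", a),
          seq = substr(s, a + 1L, len), ev = 1L)
      }
      for (d in e$donor_trims[[1]]) {
        o[[length(o) + 1L]] <- list(
          tok = paste0("skip3:", e$label, ":", d),
          seq = substr(s, 1L, len - d), ev = 1L)
      }
      o
    }
  })
  grid <- expand.grid(lapply(opts_per_exon, seq_along))
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    sel <- lapply(seq_along(opts_per_exon),
                  function(j) opts_per_exon[[j]][[grid[r, j]]])
    full <- paste(vapply(sel, `[[`, "", "seq"), collapse = "")
    if (nchar(full) != nchar(clone)) next
    # per-exon mismatch caps
    posn <- 0L
    ok <- TRUE
    mm <- 0L
    for (s in sel) {
      len <- nchar(s$seq)
      if (len > 0) {
        a <- strsplit(substr(clone, posn + 1L, posn + len), "")[[1]]
        b <- strsplit(s$seq, "")[[1]]
        d <- sum(a != b)
        if (d > cap) { ok <- FALSE; break }
        mm <- mm + d
      }
      posn <- posn + len
    }
    if (!ok) next
    ev <- sum(vapply(sel, `[[`, 0L, "ev"))
    toks <- vapply(sel, `[[`, "", "tok")
    key <- paste(toks[!is.na(toks)], collapse = ",")
    if (key == "") key <- "FL"
    if (is.null(best) || ev < best$ev || (ev == best$ev && mm < best$mm)) {
      best <- list(ev = ev, mm = mm, keys = key)
    } else if (ev == best$ev && mm == best$mm) {
      best$keys <- sort(unique(c(best$keys, key)))
    }
  }
  best
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

mutate_seq <- function(seq, n, seed) {
  set.seed(seed)
  v <- strsplit(seq, "")[[1]]
  idx <- sample(length(v), n)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
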