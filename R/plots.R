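#' Plot an exon-level gene model
#'
#' Exons as boxes along the contig, colored by role (coding, UTR/non-coding,
#' extra), with the intron baseline drawn through.
#'
#' @param object A `csn_gene_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csn_gene_model <- function(object, ...) {
  ex <- dplyr::mutate(
    object$exons,
    role = dplyr::case_when(
      .data$extra ~ "extra exon",
      .data$coding ~ "coding exon",
      TRUE ~ "non-coding exon"
    ),
    mid = (.data$start + .data$end) / 2
  )
  ggplot2::ggplot(ex) +
    ggplot2::geom_segment(
      data = tibble::tibble(x = min(ex$start), xend = max(ex$end)),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0),
      linewidth = 0.3, colour = "grey50") +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.4, ymax = 0.4, fill = .data$role)) +
    ggplot2::geom_text(ggplot2::aes(x = .data$mid, y = 0.75,
                                    label = .data$label), size = 2.8) +
    ggplot2::scale_y_continuous(limits = c(-1, 1), breaks = NULL) +
    ggplot2::labs(title = object$gene_id, x = "contig position (bp)",
                  y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a clone-library isoform summary
#'
#' @param object A `csn_library_summary`.
#' @param ... Unused.
#' @return A ggplot bar chart of clone counts per splice pattern.
#' @export
autoplot.csn_library_summary <- function(object, ...) {
  pat <- object$patterns
  ggplot2::ggplot(pat, ggplot2::aes(
    x = stats::reorder(.data$pattern_key, .data$n_clones),
    y = .data$n_clones)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "splice pattern", y = "clones") +
    ggplot2::theme_minimal()
}

#' Plot an RFLP assay as a schematic gel
#'
#' One lane per genotype, bands at expected fragment sizes (log scale, as on
#' an agarose gel).
#'
#' @param object A one-row [design_assay()] result (or a multi-row one, in
#'   which case the first row is drawn).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csn_rflp_assay <- function(object, ...) {
  row <- object[1, ]
  gt <- row$genotypes[[1]]
  bands <- dplyr::bind_rows(purrr::imap(gt, function(fr, g) {
    tibble::tibble(genotype = g, size = fr)
  }))
  ggplot2::ggplot(bands, ggplot2::aes(x = .data$genotype, y = .data$size)) +
    ggplot2::geom_tile(width = 0.6, height = 0.015 * bands$size,
                       fill = "grey20") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = paste0(row$enzyme, " (", row$site, ") PCR-RFLP"),
                  x = "genotype", y = "fragment size (bp)") +
    ggplot2::theme_minimal()
}
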