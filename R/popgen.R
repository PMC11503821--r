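#' Build a genotype panel from counts
#'
#' A panel holds biallelic genotype counts, optionally stratified (e.g. by
#' breed). Vectors are recycled row-wise; each row is one stratum.
#'
#' @param hom_ref,het,hom_alt Genotype counts (>= 0).
#' @param stratum Optional stratum labels.
#' @return A tibble of class `csn_panel` with columns `stratum`, `hom_ref`,
#'   `het`, `hom_alt`, `n`.
#' @export
genotype_panel <- function(hom_ref, het, hom_alt, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep("all", length(hom_ref))
  out <- tibble::tibble(
    stratum = as.character(stratum),
    hom_ref = as.integer(hom_ref), het = as.integer(het),
    hom_alt = as.integer(hom_alt)
  )
  if (any(c(out$hom_ref, out$het, out$hom_alt) < 0)) {
    stop("genotype counts must be non-negative", call. = FALSE)
  }
  out$n <- out$hom_ref + out$het + out$hom_alt
  class(out) <- c("csn_panel", class(out))
  out
}

#' Read a long-format genotype TSV into a panel
#'
#' Expects columns `individual_id`, `stratum`, `genotype`, with genotypes
#' written as two allele characters in either order (e.g. `GG`, `GA`, `AG`,
#' `AA`).
#'
#' @param path TSV path.
#' @param ref_allele,alt_allele The two allele characters.
#' @return A `csn_panel`.
#' @export
read_genotype_tsv <- function(path, ref_allele, alt_allele) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  gt <- toupper(tab$genotype)
  rr <- strrep(toupper(ref_allele), 2)
  aa <- strrep(toupper(alt_allele), 2)
  ra <- c(paste0(toupper(ref_allele), toupper(alt_allele)),
          paste0(toupper(alt_allele), toupper(ref_allele)))
  bad <- setdiff(unique(gt), c(rr, aa, ra))
  if (length(bad) > 0) {
    stop("unrecognized genotype(s): ", paste(bad, collapse = ","),
         call. = FALSE)
  }
  strat <- if ("stratum" %in% names(tab)) tab$stratum else "all"
  agg <- dplyr::count(tibble::tibble(stratum = strat, gt = gt),
                      .data$stratum, .data$gt)
  wide <- tidyr::pivot_wider(agg, names_from = "gt", values_from = "n",
                             values_fill = 0L)
  for (col in c(rr, aa, ra[1])) if (!col %in% names(wide)) wide[[col]] <- 0L
  het <- wide[[ra[1]]] + if (ra[2] %in% names(wide)) wide[[ra[2]]] else 0L
  genotype_panel(wide[[rr]], het, wide[[aa]], stratum = wide$stratum)
}

panel_with_pooled <- function(panel) {
  if (nrow(panel) > 1) {
    pooled <- genotype_panel(sum(panel$hom_ref), sum(panel$het),
                             sum(panel$hom_alt), stratum = "pooled")
    panel <- dplyr::bind_rows(panel, pooled)
  }
  panel
}

#' Allele frequencies by simple allele counting
#'
#' `p_ref = (2 * hom_ref + het) / (2n)`. Multi-stratum panels get per-stratum
#' rows plus a pooled row.
#'
#' @param panel A `csn_panel` (or compatible data frame).
#' @return A tibble: `stratum`, `n`, `p_ref`, `q_alt`.
#' @export
allele_frequencies <- function(panel) {
  panel <- panel_with_pooled(tibble::as_tibble(panel))
  if (any(panel$n == 0)) stop("empty panel", call. = FALSE)
  dplyr::transmute(
    panel,
    stratum = .data$stratum, n = .data$n,
    p_ref = (2 * .data$hom_ref + .data$het) / (2 * .data$n),
    q_alt = 1 - .data$p_ref
  )
}

#' Pearson chi-square test for Hardy-Weinberg equilibrium
#'
#' Compares observed genotype counts to the expectations `n * (p^2, 2pq,
#' q^2)` with allele frequencies estimated by counting; 3 classes minus 1
#' minus 1 estimated frequency leaves 1 degree of freedom. The plain Pearson
#' statistic is the default; Yates' continuity correction is available behind
#' a flag. Monomorphic strata are flagged (`valid = FALSE`, statistic `NA`)
#' since the test is undefined there. Multi-stratum panels are tested per
#' stratum and pooled.
#'
#' @param panel A `csn_panel`.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return A tibble of class `csn_hwe`: `stratum`, `n`, `p_ref`, `q_alt`,
#'   `exp_hom_ref`, `exp_het`, `exp_hom_alt`, `chi2`, `df`, `p_value`,
#'   `valid`.
#' @export
hwe_test <- function(panel, correct = FALSE) {
  panel <- panel_with_pooled(tibble::as_tibble(panel))
  if (any(panel$n == 0)) stop("empty panel", call. = FALSE)
  res <- purrr::pmap(
    panel[, c("stratum", "hom_ref", "het", "hom_alt", "n")],
    function(stratum, hom_ref, het, hom_alt, n) {
      p <- (2 * hom_ref + het) / (2 * n)
      q <- 1 - p
      e <- n * c(p^2, 2 * p * q, q^2)
      valid <- p > 0 && q > 0
      if (valid) {
        o <- c(hom_ref, het, hom_alt)
        dev <- abs(o - e)
        if (correct) dev <- pmax(dev - 0.5, 0)
        chi2 <- sum(dev^2 / e)
        pv <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
      } else {
        chi2 <- NA_real_; pv <- NA_real_
      }
      tibble::tibble(stratum = stratum, n = n, p_ref = p, q_alt = q,
                     exp_hom_ref = e[1], exp_het = e[2], exp_hom_alt = e[3],
                     chi2 = chi2, df = 1L, p_value = pv, valid = valid)
    })
  out <- dplyr::bind_rows(res)
  class(out) <- c("csn_hwe", class(out))
  out
}

#' @export
#' @rdname hwe_test
#' @param x A `csn_hwe` result.
#' @param ... Unused.
glance.csn_hwe <- function(x, ...) {
  r <- x[nrow(x), ]
  tibble::tibble(stratum = r$stratum, n = r$n, p_ref = r$p_ref,
                 q_alt = r$q_alt, chi2 = r$chi2, df = r$df,
                 p_value = r$p_value)
}

#' @export
#' @rdname hwe_test
tidy.csn_hwe <- function(x, ...) tibble::as_tibble(x)
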