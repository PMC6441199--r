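#' False discovery number
#'
#' Number of truly non-DE genes called DE: `#{p < cutoff & !de_mask}` with a
#' strict `<` at the cutoff. Monotonically non-decreasing in `cutoff`.
#'
#' @param pvalues Numeric vector of per-gene p-values.
#' @param de_mask Logical truth labels of equal length (`TRUE` = truly DE).
#' @param cutoff p-value cutoff in (0, 1).
#' @return Integer count.
#' @export
false_discovery_number <- function(pvalues, de_mask, cutoff) {
  if (length(pvalues) != length(de_mask)) {
    abort("pvalues and de_mask must have equal length",
          class = "crossnorm_domain_error")
  }
  if (cutoff <= 0 || cutoff >= 1) {
    abort("cutoff must lie in (0, 1)", class = "crossnorm_domain_error")
  }
  sum(pvalues < cutoff & !de_mask)
}

#' Precision, sensitivity and F-score of a DE call set
#'
#' Rejections are `p < cutoff` (strict). Precision is the fraction of true
#' positives among predicted positives; with zero predicted positives it is
#' recorded as `NA` (missing), never as 0, so that empty call sets do not
#' silently drag averages down. Sensitivity is the fraction of true positives
#' among real positives, and the F-score their harmonic mean (`NA` when
#' precision + sensitivity is 0 or undefined).
#'
#' @inheritParams false_discovery_number
#' @return One-row tibble with `cutoff`, `tp`, `fp`, `fn`, `fd_number`,
#'   `precision`, `sensitivity`, `fscore`.
#' @export
prf_metrics <- function(pvalues, de_mask, cutoff) {
  if (length(pvalues) != length(de_mask)) {
    abort("pvalues and de_mask must have equal length",
          class = "crossnorm_domain_error")
  }
  if (!any(de_mask)) {
    abort("at least one truly DE gene is required",
          class = "crossnorm_domain_error")
  }
  rej <- pvalues < cutoff
  tp <- sum(rej & de_mask)
  fp <- sum(rej & !de_mask)
  fn <- sum(!rej & de_mask)
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  sensitivity <- tp / (tp + fn)
  fscore <- if (is.na(precision) || precision + sensitivity == 0) {
    NA_real_
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  tibble(cutoff = cutoff, tp = tp, fp = fp, fn = fn, fd_number = fp,
         precision = precision, sensitivity = sensitivity, fscore = fscore)
}

#' FDR against an assumed-null conserved set
#'
#' Real-data analogue of the false discovery rate when no truth labels exist:
#' assuming the most conserved orthologs are non-DE, the FDR of a call set is
#' the fraction of all DE calls that fall inside the conserved set.
#'
#' @param pvalues Per-gene p-values aligned with the rows of `tab`.
#' @param conserved Character vector of conserved gene identifiers.
#' @param tab The orthologous table the p-values refer to.
#' @param cutoff p-value cutoff (strict `<`).
#' @return Scalar in \[0, 1\]; errors when there are no DE calls at all.
#' @export
assumed_null_fdr <- function(pvalues, conserved, tab, cutoff) {
  if (length(pvalues) != nrow(tab)) {
    abort("pvalues must have one entry per table row",
          class = "crossnorm_domain_error")
  }
  conserved <- conserved_set(conserved, tab)
  rej <- pvalues < cutoff
  total <- sum(rej)
  if (total == 0L) {
    abort("no DE calls at this cutoff: FDR undefined",
          class = "crossnorm_domain_error")
  }
  sum(rej & tab$gene_id %in% conserved) / total
}

#' Adjusted M and A values
#'
#' Per-gene log2 ratio and mean log2 abundance of the length- and
#' depth-adjusted expressions `x_t / (L_t * N_t)`:
#' `M = log2(e1 / e2)`, `A = log2(e1 * e2) / 2`. For non-DE genes `M` centers
#' on `log2(c)`, so a fitted scaling factor can be judged against the non-DE
#' cloud. Genes with a zero count in either species are excluded; the number
#' of exclusions is recorded in the `n_excluded` attribute.
#'
#' @param tab Orthologous table (depths are taken over all its rows).
#' @param c Scaling factor whose reference line `M = log2(c)` is recorded in
#'   the `m_line` attribute.
#' @return Tibble with `gene_id`, `A`, `M`.
#' @export
ma_values <- function(tab, c) {
  tab <- validate_ortholog_table(tab)
  depths <- ortholog_depths(tab)
  pos <- tab$x1 > 0L & tab$x2 > 0L
  sub <- tab[pos, , drop = FALSE]
  e1 <- sub$x1 / (as.numeric(sub$L1) * depths[["N1"]])
  e2 <- sub$x2 / (as.numeric(sub$L2) * depths[["N2"]])
  out <- tibble(gene_id = sub$gene_id,
                A = 0.5 * log2(e1 * e2),
                M = log2(e1 / e2))
  attr(out, "n_excluded") <- sum(!pos)
  attr(out, "m_line") <- log2(c)
  out
}
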