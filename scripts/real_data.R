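#!/usr/bin/env Rscript
# Human-mouse ortholog analysis pipeline.
#
# Requires the two supplementary inputs of the original human-mouse study
# (not redistributable with this package):
#   * an ortholog table: one row per orthologous transcript pair with columns
#     mappable to gene_id, x1, L1, x2, L2 (human = species 1, mouse = 2);
#   * the list of the 143 most conserved orthologous transcripts.
# Optionally, a longer conservation-ranked identifier list whose top 500/1000
# entries serve as the assumed-null sets for FDR assessment.
#
# Usage:
#   Rscript scripts/real_data.R --counts <table> --conserved <list> \
#       [--ranked <ranked-list>] [--cutoff 1e-6] [--out results/real_data]
#
# Reports: retained transcript count after filtering, mean cross-species
# length difference, both scaling factors, DE counts (total / higher in
# human / higher in mouse) per method, and the assumed-null FDR against the
# top-500 and top-1000 conserved sets when a ranked list is given.

suppressPackageStartupMessages(library(crossnorm))

args <- commandArgs(trailingOnly = TRUE)
arg_value <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1L && i < length(args)) args[[i + 1L]] else default
}
counts_path <- arg_value("--counts")
conserved_path <- arg_value("--conserved")
ranked_path <- arg_value("--ranked")
cutoff <- as.numeric(arg_value("--cutoff", "1e-6"))
out_prefix <- arg_value("--out", "results/real_data")
if (is.null(counts_path) || is.null(conserved_path)) {
  stop("--counts and --conserved are required; see the header of this script")
}
dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)

tab <- read_ortholog_table(counts_path)
message(sprintf("read %d ortholog pairs", nrow(tab)))
tab <- filter_transcripts(tab)
message(sprintf("retained %d transcripts after filtering", nrow(tab)))
message(sprintf("mean |L1 - L2| = %.0f, max = %d",
                mean(abs(tab$L1 - tab$L2)), max(abs(tab$L1 - tab$L2))))

conserved <- read_conserved_list(conserved_path, tab)
message(sprintf("conserved anchor set: %d transcripts", length(conserved)))

fits <- list(scbn = scbn_factor(tab, conserved, keep_grid = FALSE),
             median = median_factor(tab, conserved))

call_summary <- function(res, cutoff) {
  called <- res$p_value < cutoff
  higher_human <- called & res$M > log2(attr(res, "c_used"))
  c(total = sum(called), human = sum(higher_human),
    mouse = sum(called & !higher_human))
}

for (method in names(fits)) {
  fit <- fits[[method]]
  res <- test_all(tab, fit$c_opt)
  ma <- ma_values(tab, fit$c_opt)
  res$M <- ma$M[match(res$gene_id, ma$gene_id)]
  res$M[is.na(res$M)] <- ifelse(res$x1[is.na(res$M)] > 0, Inf, -Inf)
  cs <- call_summary(res, cutoff)
  message(sprintf(
    "%s: c = %.4g; DE at p < %g: %d total, %d higher in human, %d higher in mouse",
    method, fit$c_opt, cutoff, cs[["total"]], cs[["human"]], cs[["mouse"]]))
  write_test_result(res, sprintf("%s_%s_pvalues.tsv", out_prefix, method))
  if (!is.null(ranked_path)) {
    ranked <- suppressWarnings(read_conserved_list(ranked_path, tab))
    for (k in c(500L, 1000L)) {
      top <- utils::head(ranked, k)
      fdr <- assumed_null_fdr(res$p_value, top, tab, cutoff)
      in_top <- sum(res$p_value[tab$gene_id %in% top] < cutoff)
      message(sprintf(
        "  top-%d assumed-null set: %d called DE, FDR = %.3f", k, in_top, fdr))
    }
  }
}
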