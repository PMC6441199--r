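#' Deviation between empirical and nominal type-I error
#'
#' Given p-values of the conserved (assumed-null) genes, computes
#' `| #{p < alpha} / m - alpha |` with a strict `<` at the threshold. This is
#' the objective the SCBN scaling-factor search minimizes: at the true scaling
#' factor the conserved p-values are (approximately) uniform, so the empirical
#' rejection rate should sit near the nominal level.
#'
#' @param pvalues Non-empty numeric vector of p-values in \[0, 1\].
#' @param alpha Nominal level in (0, 1).
#' @return Non-negative scalar deviation.
#' @export
#' @examples
#' empirical_type1_deviation(c(0.01, 0.2, 0.3, 0.4), alpha = 0.05)  # 0.20
empirical_type1_deviation <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0L || anyNA(pvalues)) {
    abort("pvalues must be non-empty and free of NA",
          class = "crossnorm_domain_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)", class = "crossnorm_domain_error")
  }
  abs(mean(pvalues < alpha) - alpha)
}

# Objective of the scaling-factor search, vectorized over a grid of c values.
# Recomputes all conserved-gene p-values at each c; processed in chunks so the
# expanded (gene x grid) vectors stay modest.
scbn_objective <- function(c_grid, x1, x2, L1, L2, N1, N2, alpha,
                           chunk = 2e6) {
  m <- length(x1)
  per <- max(1L, floor(chunk / m))
  out <- numeric(length(c_grid))
  L1N1 <- as.numeric(L1) * N1
  L2N2 <- as.numeric(L2) * N2
  for (start in seq(1L, length(c_grid), by = per)) {
    idx <- start:min(start + per - 1L, length(c_grid))
    cc <- rep(c_grid[idx], each = m)
    a <- cc * rep(L1N1, length(idx))
    p0 <- a / (rep(L2N2, length(idx)) + a)
    pv <- exact_pvalue(rep(x1, length(idx)), rep(x2, length(idx)), p0)
    rej <- colMeans(matrix(pv < alpha, nrow = m))
    out[idx] <- abs(rej - alpha)
  }
  out
}

# Widest run of grid points attaining the minimum objective (within tol).
# Ties in width: midpoint (geometric) closest to ref_c, then the smaller c.
choose_plateau <- function(cs, obj, ref_c = NA_real_, tol = 1e-12) {
  hit <- obj <= min(obj) + tol
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     len = r$lengths[r$values])
  runs$mid <- sqrt(cs[runs$start] * cs[runs$end])
  best <- runs[runs$len == max(runs$len), , drop = FALSE]
  if (nrow(best) > 1L && is.finite(ref_c)) {
    best <- best[order(abs(log(best$mid / ref_c)), best$mid), , drop = FALSE]
  } else {
    best <- best[order(best$mid), , drop = FALSE]
  }
  list(start = best$start[[1]], end = best$end[[1]], mid = best$mid[[1]])
}

new_scaling_result <- function(method, c_opt, objective_value, alpha, plateau,
                               m, grid = NULL, details = list()) {
  structure(
    c(list(method = method, c_opt = c_opt, objective_value = objective_value,
           alpha = alpha, plateau = plateau, m = m, grid = grid), details),
    class = "scaling_result")
}

#' SCBN estimate of the cross-species scaling factor
#'
#' Estimates `c = S2/S1` by a two-stage grid search minimizing the deviation
#' between the empirical and nominal type-I error of the exact test over the
#' conserved gene set (see [empirical_type1_deviation()]). The objective is a
#' step function of `c` (a conserved gene's p-value changes only at finitely
#' many `c`), so the minimizer is a union of plateaus rather than a point.
#'
#' The coarse pass evaluates `coarse_n` log-spaced points on `c_range`
#' (log-spacing respects the species-swap symmetry `c <-> 1/c`); the
#' refinement pass evaluates `refine_n` linearly spaced points spanning the
#' chosen coarse plateau extended by one coarse step on either side. The
#' reported `c_opt` is the geometric midpoint of the widest refined plateau;
#' plateau ties are broken toward the [median_factor()] estimate when that is
#' computable, then toward the smaller `c`.
#'
#' @param tab Filtered orthologous table. Depths `N1, N2` are taken over the
#'   whole table (all orthologous reads), not the conserved subset.
#' @param conserved Character vector of conserved gene identifiers (see
#'   [conserved_set()]).
#' @param alpha Nominal type-I error level of the objective; default 0.05.
#' @param c_range Positive bounds of the coarse search grid.
#' @param coarse_n,refine_n Number of coarse (log-spaced) and refinement
#'   (linear) grid points.
#' @param keep_grid Keep the evaluated grids in the result (for plotting).
#' @return A `scaling_result` object; see [tidy.scaling_result()],
#'   [autoplot.scaling_result()].
#' @export
scbn_factor <- function(tab, conserved, alpha = 0.05,
                        c_range = c(1e-3, 1e3),
                        coarse_n = 601L, refine_n = 401L,
                        keep_grid = TRUE) {
  tab <- validate_ortholog_table(tab)
  conserved <- conserved_set(conserved, tab)
  sub <- tab[tab$gene_id %in% conserved, , drop = FALSE]
  if (all(sub$x1 + sub$x2 == 0L)) {
    abort("all conserved genes have zero counts: objective uninformative",
          class = "crossnorm_domain_error")
  }
  depths <- ortholog_depths(tab)
  if (any(depths < 1)) {
    abort("zero sequencing depth", class = "crossnorm_domain_error")
  }
  ref_c <- tryCatch(
    median_factor(tab, conserved)$c_opt,
    error = function(e) NA_real_)

  coarse <- 10^seq(log10(c_range[[1]]), log10(c_range[[2]]),
                   length.out = coarse_n)
  obj_c <- scbn_objective(coarse, sub$x1, sub$x2, sub$L1, sub$L2,
                          depths[["N1"]], depths[["N2"]], alpha)
  pc <- choose_plateau(coarse, obj_c, ref_c)

  lo <- coarse[max(pc$start - 1L, 1L)]
  hi <- coarse[min(pc$end + 1L, length(coarse))]
  fine <- seq(lo, hi, length.out = refine_n)
  obj_f <- scbn_objective(fine, sub$x1, sub$x2, sub$L1, sub$L2,
                          depths[["N1"]], depths[["N2"]], alpha)
  pf <- choose_plateau(fine, obj_f, ref_c)

  grid <- NULL
  if (keep_grid) {
    grid <- tibble(stage = rep(c("coarse", "refine"),
                               c(length(coarse), length(fine))),
                   c = c(coarse, fine),
                   objective = c(obj_c, obj_f))
  }
  new_scaling_result(
    method = "scbn",
    c_opt = pf$mid,
    objective_value = min(obj_f),
    alpha = alpha,
    plateau = c(fine[pf$start], fine[pf$end]),
    m = length(conserved),
    grid = grid,
    details = list(coarse_plateau = c(coarse[pc$start], coarse[pc$end]),
                   median_reference = ref_c))
}

#' Median-ratio baseline estimate of the scaling factor
#'
#' Reconstruction of the conserved-gene median normalizer: for each conserved
#' gene the depth- and length-adjusted cross-species ratio
#' `r_g = (x1 * L2 * N2) / (x2 * L1 * N1)` estimates `c` when the gene is
#' truly non-DE. Genes are restricted to those whose per-species adjusted
#' expression `x_t / (L_t * N_t)` lies within that species' interquartile
#' range over the conserved set (in both species), and the estimate is the
#' median of `r_g` over the retained genes. The result is on the same scale as
#' the `c` of [test_all()], so the two normalizers are directly comparable.
#'
#' @inheritParams scbn_factor
#' @param alpha Level at which the reported diagnostic objective (the
#'   type-I-error deviation at the estimate, over the conserved set) is
#'   evaluated.
#' @return A `scaling_result` object with `method = "median"`.
#' @export
median_factor <- function(tab, conserved, alpha = 0.05) {
  tab <- validate_ortholog_table(tab)
  conserved <- conserved_set(conserved, tab)
  sub <- tab[tab$gene_id %in% conserved, , drop = FALSE]
  depths <- ortholog_depths(tab)
  if (any(depths < 1)) {
    abort("zero sequencing depth", class = "crossnorm_domain_error")
  }
  pos <- sub$x1 > 0L & sub$x2 > 0L
  if (!any(pos)) {
    abort("no conserved genes expressed in both species",
          class = "crossnorm_domain_error")
  }
  sub <- sub[pos, , drop = FALSE]
  e1 <- sub$x1 / (as.numeric(sub$L1) * depths[["N1"]])
  e2 <- sub$x2 / (as.numeric(sub$L2) * depths[["N2"]])
  q1 <- quantile(e1, c(0.25, 0.75), names = FALSE)
  q2 <- quantile(e2, c(0.25, 0.75), names = FALSE)
  keep <- e1 >= q1[[1]] & e1 <= q1[[2]] & e2 >= q2[[1]] & e2 <= q2[[2]]
  if (!any(keep)) {
    abort("no conserved genes within both interquartile ranges",
          class = "crossnorm_domain_error")
  }
  r <- (e1 / e2)[keep]
  c_med <- median(r)
  pv <- test_all(tab, c_med, alpha = alpha)
  obj <- empirical_type1_deviation(
    pv$p_value[pv$gene_id %in% conserved], alpha)
  new_scaling_result(
    method = "median",
    c_opt = c_med,
    objective_value = obj,
    alpha = alpha,
    plateau = c(c_med, c_med),
    m = length(conserved),
    details = list(n_iqr_retained = sum(keep)))
}
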