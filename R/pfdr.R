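#' Positive false discovery rate from empirical rejection rates
#'
#' Plug-in estimate of the positive false discovery rate at level `alpha`:
#' \deqn{\widehat{pFDR} = \frac{P(H_0)\,\hat P(R \mid H_0)}
#'   {P(H_0)\,\hat P(R \mid H_0) + P(H_1)\,\hat P(R \mid H_1)},}
#' where the conditional rejection rates are the empirical fractions of
#' p-values below `alpha` among the truly non-DE genes (the set `V0`) and the
#' truly DE genes (`V1`). The pFDR conditions on at least one rejection, so a
#' zero denominator is an explicit error, not 0.
#'
#' @param pvalues Numeric vector of per-gene p-values.
#' @param de_mask Logical vector of the same length; `TRUE` marks a truly DE
#'   gene (`V1`), `FALSE` a truly non-DE gene (`V0`). Both sets must be
#'   non-empty.
#' @param alpha Rejection level in (0, 1); rejection is `p < alpha` (strict).
#' @param prior_h0 Prior probability of the null, a number in \[0, 1\] or
#'   `"empirical"` (default) for `n0 / (n0 + n1)`.
#' @return A list of class `pfdr_estimate` with `value`, `alpha`, `prior_h0`
#'   and the pair of empirical `rejection_rates`.
#' @export
#' @examples
#' p <- c(0.001, 0.2, 0.8, 0.004, 0.6)
#' pfdr_estimate(p, de_mask = c(TRUE, TRUE, FALSE, FALSE, FALSE), alpha = 0.05)
pfdr_estimate <- function(pvalues, de_mask, alpha = 0.05,
                          prior_h0 = "empirical") {
  if (length(pvalues) != length(de_mask)) {
    abort("pvalues and de_mask must have equal length",
          class = "crossnorm_domain_error")
  }
  de_mask <- as.logical(de_mask)
  n0 <- sum(!de_mask)
  n1 <- sum(de_mask)
  if (n0 < 1L || n1 < 1L) {
    abort("both V0 (non-DE) and V1 (DE) must be non-empty",
          class = "crossnorm_domain_error")
  }
  r0 <- mean(pvalues[!de_mask] < alpha)
  r1 <- mean(pvalues[de_mask] < alpha)
  if (identical(prior_h0, "empirical")) {
    p_h0 <- n0 / (n0 + n1)
  } else {
    p_h0 <- as.numeric(prior_h0)
    if (is.na(p_h0) || p_h0 < 0 || p_h0 > 1) {
      abort("prior_h0 must be in [0, 1] or \"empirical\"",
            class = "crossnorm_domain_error")
    }
  }
  denom <- p_h0 * r0 + (1 - p_h0) * r1
  if (denom == 0) {
    abort("undefined pFDR: no rejections in either set",
          class = "crossnorm_undefined_pfdr")
  }
  structure(
    list(value = p_h0 * r0 / denom,
         alpha = alpha,
         prior_h0 = p_h0,
         rejection_rates = c(h0 = r0, h1 = r1)),
    class = "pfdr_estimate")
}

#' @export
print.pfdr_estimate <- function(x, ...) {
  cat(sprintf(
    "pFDR estimate: %.4g  (alpha = %g, P(H0) = %.4g, P(R|H0) = %.4g, P(R|H1) = %.4g)\n",
    x$value, x$alpha, x$prior_h0,
    x$rejection_rates[["h0"]], x$rejection_rates[["h1"]]))
  invisible(x)
}
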