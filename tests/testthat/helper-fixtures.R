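# Small deterministic fixtures built in code.

toy_table <- function() {
  tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    x1 = c(5L, 2L, 0L, 3L),
    L1 = c(100L, 250L, 300L, 400L),
    x2 = c(0L, 2L, 7L, 3L),
    L2 = c(120L, 240L, 310L, 400L))
}

write_toy_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene_id\tx1\tL1\tx2\tL2",
               "a\t5\t100\t0\t120",
               "b\t2\t250\t2\t240",
               "c\t0\t300\t7\t310"), path)
  path
}

# Down-scaled null simulation for fast property tests; the study-scale runs
# live in test-acceptance.R.
small_null_config <- function(seed, n_orth = 2000L, m = 400L,
                              depth = c(2e5, 4e5), c_target = 2) {
  sim_config(n_orth = n_orth, prop_de = 0, n_unique = c(0L, 0L),
             n_unmapped = c(0L, 0L), m_conserved = m, depth = depth,
             c_target = c_target, seed = seed)
}

# Independent brute-force oracle for the two-sided deviation p-value with an
# exact-rational qualifying-set comparison: p0 = num/den, and
# |k - n p0| >= |x1 - n p0|  <=>  |k*den - n*num| >= |x1*den - n*num|.
oracle_pvalue <- function(x1, n, num, den) {
  k <- 0:n
  keep <- abs(k * den - n * num) >= abs(x1 * den - n * num)
  sum(dbinom(k[keep], n, num / den))
}
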