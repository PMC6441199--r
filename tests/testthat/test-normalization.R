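test_that("type-I-error deviation uses a strict threshold", {
  expect_equal(empirical_type1_deviation(c(1, 1, 1, 1), 0.05), 0.05)
  expect_equal(empirical_type1_deviation(c(0.01, 0.2, 0.3, 0.4), 0.05), 0.20)
  # p = 0.05 itself is not a rejection under strict '<'
  expect_equal(empirical_type1_deviation(seq(0.05, 1, by = 0.05), 0.05), 0.05)
  expect_error(empirical_type1_deviation(numeric(), 0.05),
               class = "crossnorm_domain_error")
  expect_error(empirical_type1_deviation(c(0.1, NA), 0.05),
               class = "crossnorm_domain_error")
  expect_error(empirical_type1_deviation(0.2, 1), class = "crossnorm_domain_error")
})

test_that("median factor recovers exact ratios and the symmetric case", {
  # all conserved genes share the same count ratio rho with equal lengths, so
  # r_g = rho * N2 / N1 exactly, for every gene: the median equals it too
  tab <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    x1 = c(17L, 34L, 51L, 68L, 85L, 102L),
    L1 = rep(100L, 6),
    x2 = c(10L, 20L, 30L, 40L, 50L, 60L),
    L2 = rep(100L, 6))
  N <- ortholog_depths(tab)
  want <- 1.7 * N[["N2"]] / N[["N1"]]
  fit <- median_factor(tab, tab$gene_id)
  expect_equal(fit$c_opt, want, tolerance = 1e-12)

  sym <- tibble::tibble(gene_id = sprintf("s%d", 1:5),
                        x1 = c(5L, 9L, 14L, 20L, 30L),
                        L1 = c(100L, 150L, 200L, 250L, 300L),
                        x2 = c(5L, 9L, 14L, 20L, 30L),
                        L2 = c(100L, 150L, 200L, 250L, 300L))
  expect_equal(median_factor(sym, sym$gene_id)$c_opt, 1, tolerance = 1e-12)
})

test_that("median factor needs conserved genes expressed in both species", {
  tab <- toy_table()
  expect_error(median_factor(tab, c("a", "c")),  # each zero in one species
               class = "crossnorm_domain_error")
})

test_that("pFDR follows the plug-in formula and its edge conventions", {
  # P(R|H0) = 0.05, P(R|H1) = 1.0, prior 0.5 -> 0.05/1.05
  p <- c(rep(0.01, 1), rep(0.99, 19),   # V0: 1 of 20 rejected
         rep(0.001, 20))                # V1: all rejected
  de <- rep(c(FALSE, TRUE), each = 20)
  est <- pfdr_estimate(p, de, alpha = 0.05, prior_h0 = 0.5)
  expect_equal(est$value, 0.05 / 1.05, tolerance = 1e-12)
  expect_equal(unname(est$rejection_rates), c(0.05, 1))

  # all rejections are null -> pFDR 1
  p2 <- c(0.01, 0.8, 0.9, 0.7)
  expect_equal(pfdr_estimate(p2, c(FALSE, FALSE, TRUE, TRUE))$value, 1)

  # no rejections anywhere -> explicit undefined error
  expect_error(pfdr_estimate(c(0.5, 0.6), c(FALSE, TRUE)),
               class = "crossnorm_undefined_pfdr")

  # equal rejection rates -> estimate equals the prior
  p3 <- c(0.01, 0.9, 0.01, 0.9)
  est3 <- pfdr_estimate(p3, c(FALSE, FALSE, TRUE, TRUE), prior_h0 = 0.3)
  expect_equal(est3$value, 0.3, tolerance = 1e-12)

  expect_error(pfdr_estimate(c(0.1), c(TRUE)), class = "crossnorm_domain_error")
})

test_that("scbn recovers the true scaling factor on simulated null data", {
  ds <- simulate_dataset(small_null_config(seed = 21L))
  fit <- scbn_factor(ds$table, ds$conserved)
  expect_lt(abs(fit$c_opt / ds$c_true - 1), 0.10)
  # the reported c_opt lies inside the reported plateau, and the objective is
  # bounded by its theoretical maximum
  expect_gte(fit$c_opt, fit$plateau[[1]])
  expect_lte(fit$c_opt, fit$plateau[[2]])
  expect_lte(fit$objective_value, max(fit$alpha, 1 - fit$alpha))
  # median baseline recovers it too on clean data
  med <- median_factor(ds$table, ds$conserved)
  expect_lt(abs(med$c_opt / ds$c_true - 1), 0.10)
})

test_that("swapping the two species inverts the estimated factor", {
  ds <- simulate_dataset(small_null_config(seed = 22L))
  swapped <- dplyr::select(ds$table, gene_id,
                           x1 = x2, L1 = L2, x2 = x1, L2 = L1)
  a <- scbn_factor(ds$table, ds$conserved, keep_grid = FALSE)$c_opt
  b <- scbn_factor(swapped, ds$conserved, keep_grid = FALSE)$c_opt
  expect_lt(abs(log(a * b)), log(1.05))  # b ~ 1/a within grid resolution
})

test_that("degenerate conserved sets are rejected", {
  tab <- tibble::tibble(gene_id = c("a", "b"),
                        x1 = c(0L, 10L), L1 = c(100L, 100L),
                        x2 = c(0L, 10L), L2 = c(100L, 100L))
  expect_error(scbn_factor(tab, "a"), class = "crossnorm_domain_error")
})

test_that("the objective is a step function with a genuine plateau", {
  ds <- simulate_dataset(small_null_config(seed = 23L, n_orth = 500L, m = 100L,
                                           depth = c(5e4, 1e5)))
  fit <- scbn_factor(ds$table, ds$conserved)
  fine <- fit$grid[fit$grid$stage == "refine", ]
  on_plateau <- fine$c >= fit$plateau[[1]] & fine$c <= fit$plateau[[2]]
  expect_true(all(abs(fine$objective[on_plateau] - fit$objective_value) < 1e-12))
  # neighbours just outside the plateau are strictly worse
  left <- which(fine$c < fit$plateau[[1]])
  right <- which(fine$c > fit$plateau[[2]])
  if (length(left)) expect_gt(fine$objective[max(left)], fit$objective_value)
  if (length(right)) expect_gt(fine$objective[min(right)], fit$objective_value)
})
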