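test_that("fixing the seed fixes the dataset bit-exactly", {
  cfg <- sim_config(n_orth = 500L, n_unique = c(50L, 80L),
                    n_unmapped = c(60L, 90L), m_conserved = 100L,
                    depth = c(5e4, 1e5), seed = 77L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$conserved, b$conserved)
  expect_identical(a$truth, b$truth)
  expect_identical(a$unmapped, b$unmapped)
})

test_that("counts are integral and expected depths are met", {
  ds <- simulate_dataset(small_null_config(seed = 8L))
  expect_true(is.integer(ds$table$x1) && is.integer(ds$table$x2))
  expect_true(all(ds$table$x1 >= 0L & ds$table$x2 >= 0L))
  expect_true(all(ds$table$L1 >= 1L & ds$table$L2 >= 1L))
  depth <- ds$config$depth
  N <- ortholog_depths(ds$table)
  expect_lt(abs(N[["N1"]] - depth[[1]]), 3 * sqrt(depth[[1]]))
  expect_lt(abs(N[["N2"]] - depth[[2]]), 3 * sqrt(depth[[2]]))
})

test_that("the true scaling factor is recomputable and near the target", {
  ds <- simulate_dataset(small_null_config(seed = 9L))
  expect_equal(true_scaling_factor(ds), ds$c_true, tolerance = 1e-12)
  expect_lt(abs(ds$c_true / 2 - 1), 0.01)  # length rounding only
})

test_that("DE structure matches the configuration", {
  cfg <- sim_config(n_orth = 4000L, prop_de = 0.2, fold = 2,
                    prop_up_sp2 = 0.7, n_unique = c(100L, 200L),
                    n_unmapped = c(0L, 0L), m_conserved = 500L,
                    noise_rate = 0.2, depth = c(2e5, 4e5), seed = 10L)
  ds <- simulate_dataset(cfg)
  core <- !ds$truth$unique_gene
  n_de_core <- sum(ds$truth$de & core)
  expect_equal(n_de_core, 800L)
  # direction balance within binomial sampling error
  up <- sum(ds$truth$direction[ds$truth$de & core] == 1L)
  expect_lt(abs(up / n_de_core - 0.7), 3 * sqrt(0.7 * 0.3 / n_de_core))
  # unique genes are truly DE, in the stated numbers and directions
  expect_equal(sum(ds$truth$unique_gene), 300L)
  expect_true(all(ds$truth$de[ds$truth$unique_gene]))
  expect_equal(sum(ds$table$x2[ds$truth$direction == -1L & ds$truth$unique_gene]), 0L)
  # conserved contamination: exactly round(noise_rate * m) DE genes, none unique
  cons <- ds$truth[ds$truth$conserved, ]
  expect_equal(nrow(cons), 500L)
  expect_equal(sum(cons$de), 100L)
  expect_false(any(cons$unique_gene))
})

test_that("fold-1 and zero-DE configurations are null", {
  ds0 <- simulate_dataset(sim_config(n_orth = 300L, prop_de = 0,
                                     n_unique = c(0L, 0L), n_unmapped = c(0L, 0L),
                                     m_conserved = 50L, depth = c(1e4, 2e4),
                                     seed = 11L))
  expect_false(any(ds0$truth$de))
  ds1 <- simulate_dataset(sim_config(n_orth = 300L, prop_de = 0.1, fold = 1,
                                     n_unique = c(0L, 0L), n_unmapped = c(0L, 0L),
                                     m_conserved = 50L, depth = c(1e4, 2e4),
                                     seed = 12L))
  expect_false(any(ds1$truth$de))  # fold 1 means equal means
})

test_that("infeasible configurations error out", {
  expect_error(
    sim_config(n_orth = 1000L, prop_de = 0.01, m_conserved = 1000L,
               noise_rate = 0.5),
    class = "crossnorm_config_error")  # more noise genes than DE genes
  expect_error(sim_config(noise_rate = 0.7), class = "crossnorm_config_error")
  expect_error(sim_config(fold = 0.5), class = "crossnorm_config_error")
})

test_that("unmapped genes stay outside the table and its depths", {
  cfg <- sim_config(n_orth = 300L, prop_de = 0, n_unique = c(0L, 0L),
                    n_unmapped = c(40L, 70L), m_conserved = 50L,
                    depth = c(1e4, 2e4), seed = 13L)
  ds <- simulate_dataset(cfg)
  expect_equal(nrow(ds$table), 300L)
  expect_equal(table(ds$unmapped$species)[["1"]], 40L)
  expect_equal(table(ds$unmapped$species)[["2"]], 70L)
  expect_false(any(ds$unmapped$gene_id %in% ds$table$gene_id))
})

test_that("study configurations carry the published parameterizations", {
  cfgs <- study_configs()
  expect_setequal(names(cfgs), paste0("study", 1:7))
  s3 <- cfgs$study3$config
  expect_equal(s3$prop_de, 0.2)
  expect_equal(s3$fold, 8)
  expect_equal(s3$prop_up_sp2, 0.7)
  expect_equal(cfgs$study3$sweep$values, c(0, 0.4))
  s2 <- cfgs$study2$config
  expect_equal(s2$fold, 1.5)
  expect_equal(s2$m_conserved, 1000L)
  expect_equal(cfgs$study2$sweep$values, seq(0, 0.6, by = 0.1))
  expect_equal(cfgs$study1$config$fold, 1.2)
  expect_equal(cfgs$study1$config$prop_de, 0.1)
  expect_equal(cfgs$study1$config$n_unique, c(1000L, 2000L))
  expect_equal(cfgs$study1$config$n_unmapped, c(2000L, 4000L))
  expect_equal(range(cfgs$study1$sweep$values), c(50, 1000))
  expect_equal(cfgs$study4$config$prop_de, 0.4)
  expect_equal(range(cfgs$study4$sweep$values), c(1e-4, 0.6))
  expect_equal(cfgs$study6$cutoff, 0.01)
  s7 <- cfgs$study7
  expect_equal(s7$config$noise_rate, 0.2)
  expect_equal(s7$config$fold, 1.5)
  expect_equal(s7$sweep$values, seq(0.1, 0.6, by = 0.1))
})

test_that("a dataset round-trips through the text sidecar files", {
  ds <- simulate_dataset(sim_config(n_orth = 200L, prop_de = 0.1, fold = 2,
                                    n_unique = c(10L, 20L), n_unmapped = c(0L, 0L),
                                    m_conserved = 40L, depth = c(1e4, 2e4),
                                    seed = 14L))
  prefix <- tempfile()
  paths <- write_sim_dataset(ds, prefix)
  back <- read_ortholog_table(paths[["table"]])
  expect_identical(as.data.frame(back), as.data.frame(ds$table))
  expect_identical(read_conserved_list(paths[["conserved"]], back), ds$conserved)
  expect_match(readLines(paths[["config"]])[1], "\\{")
})
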