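#' Configuration for the two-species count simulator
#'
#' Bundles the generator parameters with validation. The defaults reproduce
#' the baseline simulation design used throughout the package's replication
#' studies: 10000 orthologous genes, 10% differentially expressed at 1.2-fold
#' with 90% up-regulated in species 2, 1000/2000 unique genes, 2000/4000
#' unmapped genes, an anchor set of 1000 conserved genes with no
#' contamination, and expected orthologous depths of one and two million
#' reads. Relative expression rates are log-normal (a stand-in for an
#' empirical distribution of real counts; supply `rate_values` to use one),
#' and per-species lengths are log-uniform on \[200, 20000\] bases, reflecting
#' the large cross-species length differences seen in real ortholog tables.
#'
#' @param n_orth Number of orthologous genes expressed in both species.
#' @param prop_de Fraction of the `n_orth` genes that are DE, in \[0, 1).
#' @param fold Fold change of DE genes, >= 1.
#' @param prop_up_sp2 Fraction of DE genes up-regulated in species 2; the
#'   direction is drawn per gene as an independent Bernoulli.
#' @param n_unique Length-2 integer vector: number of unique genes (orthologs
#'   expressed only in species 1, only in species 2). They are part of the
#'   ortholog table and of the depths.
#' @param n_unmapped Length-2 integer vector: genes present in only one
#'   species' genome. They are simulated for library-size realism but excluded
#'   from the ortholog table and from the orthologous depths `N_t`.
#' @param m_conserved Size of the conserved anchor set, drawn from the
#'   non-DE orthologs except for the contaminated fraction.
#' @param noise_rate Fraction of the conserved set replaced by DE genes, in
#'   \[0, 0.6\].
#' @param depth Length-2 vector of expected total orthologous read counts.
#' @param c_target Target true scaling factor `S2/S1`, imposed by rescaling
#'   the species-2 length column (see [simulate_dataset()]); `NULL` leaves the
#'   drawn value. Default 2, giving clearly distinct expression scales.
#' @param length_range Positive bounds of the log-uniform length model (bases).
#' @param rate_meanlog,rate_sdlog Log-normal parameters of the relative
#'   expression-rate model.
#' @param rate_values Optional numeric vector of empirical rates sampled (with
#'   replacement) instead of the log-normal model.
#' @param seed Optional integer seed; fixing it fixes the dataset bit-exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_orth = 10000L, prop_de = 0.1, fold = 1.2,
                       prop_up_sp2 = 0.9, n_unique = c(1000L, 2000L),
                       n_unmapped = c(2000L, 4000L), m_conserved = 1000L,
                       noise_rate = 0, depth = c(1e6, 2e6), c_target = 2,
                       length_range = c(200, 20000),
                       rate_meanlog = 0, rate_sdlog = 1.5,
                       rate_values = NULL, seed = NULL) {
  cfg <- list(n_orth = as.integer(n_orth), prop_de = prop_de, fold = fold,
              prop_up_sp2 = prop_up_sp2, n_unique = as.integer(n_unique),
              n_unmapped = as.integer(n_unmapped),
              m_conserved = as.integer(m_conserved), noise_rate = noise_rate,
              depth = depth, c_target = c_target,
              length_range = length_range, rate_meanlog = rate_meanlog,
              rate_sdlog = rate_sdlog, rate_values = rate_values, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_orth >= 1L,
            length(cfg$n_unique) == 2L, all(cfg$n_unique >= 0L),
            length(cfg$n_unmapped) == 2L, all(cfg$n_unmapped >= 0L),
            length(cfg$depth) == 2L, all(cfg$depth > 0),
            length(cfg$length_range) == 2L, all(cfg$length_range >= 1),
            cfg$length_range[[1]] <= cfg$length_range[[2]])
  if (cfg$prop_de < 0 || cfg$prop_de >= 1) {
    abort("prop_de must lie in [0, 1)", class = "crossnorm_config_error")
  }
  if (cfg$fold < 1) {
    abort("fold must be >= 1", class = "crossnorm_config_error")
  }
  if (cfg$prop_up_sp2 < 0 || cfg$prop_up_sp2 > 1) {
    abort("prop_up_sp2 must lie in [0, 1]", class = "crossnorm_config_error")
  }
  if (cfg$noise_rate < 0 || cfg$noise_rate > 0.6) {
    abort("noise_rate must lie in [0, 0.6]", class = "crossnorm_config_error")
  }
  if (cfg$m_conserved < 1L || cfg$m_conserved > cfg$n_orth) {
    abort("m_conserved must lie in [1, n_orth]",
          class = "crossnorm_config_error")
  }
  n_de <- round(cfg$prop_de * cfg$n_orth)
  n_noise <- round(cfg$noise_rate * cfg$m_conserved)
  if (n_noise > n_de) {
    abort("infeasible config: more conserved noise genes than DE genes",
          class = "crossnorm_config_error")
  }
  if (cfg$m_conserved - n_noise > cfg$n_orth - n_de) {
    abort("infeasible config: conserved set larger than the non-DE pool",
          class = "crossnorm_config_error")
  }
  if (!is.null(cfg$c_target) && cfg$c_target <= 0) {
    abort("c_target must be positive", class = "crossnorm_config_error")
  }
  invisible(cfg)
}

#' Simulate a two-species orthologous RNA-seq dataset with known truth
#'
#' Generates Poisson read counts under the mean model
#' `E(X_gt) = mu_gt * L_gt / S_t * depth_t` with
#' `S_t = sum(mu_gt * L_gt)` over the orthologous set. Per-gene relative rates
#' `mu_g1` come from the rate model and lengths from the per-species length
#' model; non-DE genes have `mu_g2 = mu_g1`, DE genes `mu_g2 = fold * mu_g1`
#' (up in species 2) or `mu_g1 / fold`, and unique genes have `mu = 0` in one
#' species. Unmapped genes are generated per species but live outside the
#' ortholog table and do not enter the depths.
#'
#' When `c_target` is set, the species-2 lengths are rescaled by
#' `c_target * S1 / S2` (and rounded back to whole bases) so that the true
#' scaling factor `c_true = S2/S1` lands on the target; rescaling the rate
#' vector instead would leave the counts untouched and is therefore not a
#' usable control. `c_true` is recomputed exactly from the stored integer
#' lengths.
#'
#' The conserved set contains `m_conserved` genes, of which
#' `round(noise_rate * m_conserved)` are drawn from the DE genes and the rest
#' from the non-DE orthologs.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `table` (the ortholog
#'   tibble), `conserved` (identifiers), `truth` (tibble: `gene_id`, `de`,
#'   `direction` in -1/0/1 with +1 up-regulated in species 2, `unique_gene`,
#'   `conserved`, `mu1`, `mu2`), `unmapped` (per-species side table),
#'   `c_true`, and `config`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  run <- function() simulate_dataset_impl(config)
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed, run())
  } else {
    run()
  }
}

simulate_dataset_impl <- function(cfg) {
  n_core <- cfg$n_orth
  nu <- cfg$n_unique
  n_rows <- n_core + nu[[1]] + nu[[2]]

  draw_rate <- function(n) {
    if (!is.null(cfg$rate_values)) {
      sample(cfg$rate_values, n, replace = TRUE)
    } else {
      rlnorm(n, cfg$rate_meanlog, cfg$rate_sdlog)
    }
  }
  draw_len <- function(n) {
    pmax(1, round(10^runif(n, log10(cfg$length_range[[1]]),
                           log10(cfg$length_range[[2]]))))
  }

  mu1 <- draw_rate(n_rows)
  L1 <- draw_len(n_rows)
  L2 <- draw_len(n_rows)

  n_de <- round(cfg$prop_de * n_core)
  de_idx <- if (n_de > 0) sample.int(n_core, n_de) else integer()
  up2 <- rbinom(n_de, 1L, cfg$prop_up_sp2) == 1L
  mu2 <- mu1
  mu2[de_idx] <- ifelse(up2, mu1[de_idx] * cfg$fold, mu1[de_idx] / cfg$fold)
  direction <- integer(n_rows)
  direction[de_idx] <- ifelse(up2, 1L, -1L)

  unique_gene <- rep(FALSE, n_rows)
  if (nu[[1]] > 0) {
    i1 <- n_core + seq_len(nu[[1]])
    mu2[i1] <- 0
    direction[i1] <- -1L
    unique_gene[i1] <- TRUE
  }
  if (nu[[2]] > 0) {
    i2 <- n_core + nu[[1]] + seq_len(nu[[2]])
    mu1[i2] <- 0
    mu2[i2] <- draw_rate(nu[[2]])
    direction[i2] <- 1L
    unique_gene[i2] <- TRUE
  }

  S1 <- sum(mu1 * L1)
  S2 <- sum(mu2 * L2)
  if (!is.null(cfg$c_target)) {
    L2 <- pmax(1, round(L2 * cfg$c_target * S1 / S2))
    S2 <- sum(mu2 * L2)
  }
  c_true <- S2 / S1

  x1 <- rpois(n_rows, mu1 * L1 / S1 * cfg$depth[[1]])
  x2 <- rpois(n_rows, mu2 * L2 / S2 * cfg$depth[[2]])
  gene_id <- sprintf("g%06d", seq_len(n_rows))

  tab <- tibble(gene_id = gene_id, x1 = as.integer(x1), L1 = as.integer(L1),
                x2 = as.integer(x2), L2 = as.integer(L2))

  de <- mu1 != mu2
  n_noise <- round(cfg$noise_rate * cfg$m_conserved)
  pool_null <- setdiff(seq_len(n_core), de_idx)
  cons_idx <- c(
    if (n_noise > 0) sample(de_idx, n_noise) else integer(),
    sample(pool_null, cfg$m_conserved - n_noise))
  conserved <- gene_id[sort(cons_idx)]

  truth <- tibble(gene_id = gene_id, de = de,
                  direction = as.integer(direction) * as.integer(de),
                  unique_gene = unique_gene,
                  conserved = gene_id %in% conserved,
                  mu1 = mu1, mu2 = mu2)

  unmapped <- simulate_unmapped(cfg, S1, S2, draw_rate, draw_len)

  structure(list(table = tab, conserved = conserved, truth = truth,
                 unmapped = unmapped, c_true = c_true, config = cfg),
            class = "sim_dataset")
}

# Side table of genes without an ortholog; for library-size realism only.
simulate_unmapped <- function(cfg, S1, S2, draw_rate, draw_len) {
  one <- function(species, n, S, depth) {
    if (n == 0L) {
      return(tibble(species = integer(), gene_id = character(),
                    length = integer(), mu = numeric(), count = integer()))
    }
    mu <- draw_rate(n)
    L <- draw_len(n)
    tibble(species = rep(species, n),
           gene_id = sprintf("um%d_%05d", species, seq_len(n)),
           length = as.integer(L), mu = mu,
           count = as.integer(rpois(n, mu * L / S * depth)))
  }
  bind_rows(one(1L, cfg$n_unmapped[[1]], S1, cfg$depth[[1]]),
            one(2L, cfg$n_unmapped[[2]], S2, cfg$depth[[2]]))
}

#' Recompute the true scaling factor from stored simulation parameters
#'
#' @param ds A `sim_dataset`.
#' @return `S2/S1` recomputed from the truth tibble's rates and the table's
#'   lengths; equals `ds$c_true` to machine precision.
#' @export
true_scaling_factor <- function(ds) {
  sum(ds$truth$mu2 * as.numeric(ds$table$L2)) /
    sum(ds$truth$mu1 * as.numeric(ds$table$L1))
}

#' Write a simulated dataset to delimited text files
#'
#' Emits the ortholog table, the conserved list, a truth sidecar and a JSON
#' provenance file (full configuration including the seed) under a common
#' path prefix.
#'
#' @param ds A `sim_dataset`.
#' @param prefix Output path prefix; files are `<prefix>_table.tsv`,
#'   `<prefix>_conserved.txt`, `<prefix>_truth.tsv`, `<prefix>_config.json`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim_dataset <- function(ds, prefix) {
  paths <- c(table = paste0(prefix, "_table.tsv"),
             conserved = paste0(prefix, "_conserved.txt"),
             truth = paste0(prefix, "_truth.tsv"),
             config = paste0(prefix, "_config.json"))
  write_ortholog_table(ds$table, paths[["table"]],
                       comments = sprintf("c_true = %.12g", ds$c_true))
  writeLines(ds$conserved, paths[["conserved"]])
  readr::write_tsv(ds$truth, paths[["truth"]], progress = FALSE)
  cfg <- ds$config
  cfg$rate_values <- NULL
  writeLines(to_json(cfg), paths[["config"]])
  invisible(paths)
}

# Minimal JSON serializer for flat config lists (numbers, strings, vectors).
to_json <- function(x) {
  enc <- function(v) {
    if (is.null(v)) return("null")
    if (is.character(v)) s <- paste0("\"", v, "\"") else s <- format(v, digits = 15)
    if (length(v) == 1L) s else paste0("[", paste(s, collapse = ", "), "]")
  }
  body <- vapply(names(x), function(nm) {
    paste0("  \"", nm, "\": ", enc(x[[nm]]))
  }, character(1))
  paste0("{\n", paste(body, collapse = ",\n"), "\n}")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated two-species dataset: %d ortholog pairs (%d DE, %d unique), %d conserved, c_true = %.4f\n",
    nrow(x$table), sum(x$truth$de), sum(x$truth$unique_gene),
    length(x$conserved), x$c_true))
  invisible(x)
}
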