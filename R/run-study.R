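#' Run a replicated simulation study
#'
#' For each value of the study's swept parameter and each replicate: simulate
#' a dataset, estimate the scaling factor with each requested method, test all
#' orthologs at the estimate, and compute the evaluation metrics against the
#' ground truth. Deterministic under `seed` (per-replicate seeds are drawn up
#' front from the given one).
#'
#' @param study A study name from [study_configs()] (e.g. `"study6"`), or a
#'   study definition list of the same shape, or a bare [sim_config()] (run
#'   with no sweep).
#' @param methods Subset of `c("scbn", "median")`.
#' @param reps Number of replicates per swept value. The full benchmark used
#'   100; smaller values trade Monte-Carlo error for speed.
#' @param cutoff p-value cutoff for DE calls; `NULL` takes the study default.
#'   Ignored (per value) when the swept parameter is the cutoff itself.
#' @param alpha Nominal level for the SCBN objective.
#' @param seed Integer seed making the whole run reproducible.
#' @param sweep_values Optional subset/override of the study's swept values.
#' @return A tibble of class `study_result`: one row per
#'   (sweep value, replicate, method) with the swept parameter, `c_true`, the
#'   estimate `c_est`, its objective value and the metrics of [prf_metrics()].
#' @seealso [study_summary()] for per-method means.
#' @export
run_study <- function(study, methods = c("scbn", "median"), reps = 100L,
                      cutoff = NULL, alpha = 0.05, seed = NULL,
                      sweep_values = NULL) {
  methods <- match.arg(methods, c("scbn", "median"), several.ok = TRUE)
  if (is.character(study)) {
    cfgs <- study_configs()
    if (!study %in% names(cfgs)) {
      abort(paste0("unknown study: ", study), class = "crossnorm_config_error")
    }
    study_name <- study
    study <- cfgs[[study]]
  } else if (inherits(study, "sim_config")) {
    study_name <- "custom"
    study <- list(config = study, sweep = NULL, cutoff = 0.01)
  } else {
    study_name <- "custom"
  }
  param <- study$sweep$param
  values <- sweep_values %||% study$sweep$values %||% NA
  cutoff <- cutoff %||% study$cutoff %||% 0.01

  if (!is.null(seed)) set.seed(seed)
  n_runs <- length(values) * reps
  seeds <- sample.int(.Machine$integer.max - 1L, n_runs)

  run <- 0L
  rows <- purrr::map(seq_along(values), function(vi) {
    v <- values[[vi]]
    cfg <- study$config
    cut_v <- cutoff
    if (!is.null(param)) {
      if (identical(param, "cutoff")) {
        cut_v <- v
      } else {
        cfg[[param]] <- v
        validate_sim_config(cfg)
      }
    }
    purrr::map(seq_len(reps), function(rep_i) {
      run <<- run + 1L
      cfg$seed <- seeds[[run]]
      ds <- simulate_dataset(cfg)
      purrr::map(methods, function(method) {
        fit <- switch(method,
                      scbn = scbn_factor(ds$table, ds$conserved, alpha = alpha,
                                         keep_grid = FALSE),
                      median = median_factor(ds$table, ds$conserved,
                                             alpha = alpha))
        res <- test_all(ds$table, fit$c_opt, alpha = alpha)
        met <- prf_metrics(res$p_value, ds$truth$de, cut_v)
        dplyr::bind_cols(
          tibble(study = study_name,
                 sweep_param = param %||% NA_character_,
                 sweep_value = if (is.null(param)) NA_real_ else as.numeric(v),
                 replicate = rep_i, method = method,
                 c_true = ds$c_true, c_est = fit$c_opt,
                 objective_value = fit$objective_value),
          met)
      }) |> bind_rows()
    }) |> bind_rows()
  }) |> bind_rows()

  class(rows) <- c("study_result", class(rows))
  attr(rows, "alpha") <- alpha
  rows
}

#' Per-method means of a study result
#'
#' Averages the metric rows over replicates within each (method, sweep value)
#' cell. Missing precisions (replicates with no rejections) are excluded from
#' the means rather than counted as zero.
#'
#' @param rows A `study_result` tibble from [run_study()].
#' @return Tibble with one row per method and swept value holding the mean
#'   `fd_number`, `precision`, `sensitivity`, `fscore`, `c_est` and `c_true`.
#' @export
study_summary <- function(rows) {
  rows |>
    group_by(.data$study, .data$method, .data$sweep_param,
             .data$sweep_value, .data$cutoff) |>
    summarise(reps = dplyr::n(),
              fd_number = mean(.data$fd_number),
              precision = mean(.data$precision, na.rm = TRUE),
              sensitivity = mean(.data$sensitivity, na.rm = TRUE),
              fscore = mean(.data$fscore, na.rm = TRUE),
              c_est = mean(.data$c_est),
              c_true = mean(.data$c_true),
              .groups = "drop")
}
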