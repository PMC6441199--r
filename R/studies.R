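#' The seven replication-study parameterizations
#'
#' Named collection of simulation study designs used to benchmark the SCBN
#' estimator against the median baseline. Each entry holds a base
#' [sim_config()], the swept parameter with its values (`sweep`), the default
#' p-value `cutoff` for calling DE, and the metrics of interest.
#'
#' * `study1` -- 10% DE at 1.2-fold, 90% up in species 2, unique genes
#'   1000/2000, unmapped 2000/4000; sweeps the conserved-set size from 50 to
#'   1000; false-discovery number.
#' * `study2` -- as study 1 but 1.5-fold and 1000 conserved genes; sweeps the
#'   conserved-set noise rate 0 to 0.6 in steps of 0.1.
#' * `study3` -- 20% DE at 8-fold, 70% up in species 2; noise 0 and 0.4;
#'   adjusted M-versus-A diagnostics of the two scaling factors.
#' * `study4` -- as study 1 but 40% DE; sweeps the p-value cutoff from 0.0001
#'   to 0.6 (stability of the estimate under the cutoff choice).
#' * `study5` -- as study 2; noise 0 to 0.5; false-discovery number.
#' * `study6` -- as study 2; noise 0 to 0.6; precision, sensitivity and
#'   F-score at cutoff 0.01.
#' * `study7` -- 1.5-fold, conserved noise 0.2; sweeps the DE fraction from
#'   0.1 to 0.6.
#'
#' @return Named list of study definitions consumable by [run_study()].
#' @export
study_configs <- function() {
  base1 <- sim_config(prop_de = 0.1, fold = 1.2, prop_up_sp2 = 0.9,
                      n_unique = c(1000L, 2000L), n_unmapped = c(2000L, 4000L),
                      m_conserved = 1000L, noise_rate = 0)
  base2 <- sim_config(prop_de = 0.1, fold = 1.5, prop_up_sp2 = 0.9,
                      n_unique = c(1000L, 2000L), n_unmapped = c(2000L, 4000L),
                      m_conserved = 1000L, noise_rate = 0)
  list(
    study1 = list(config = base1,
                  sweep = list(param = "m_conserved",
                               values = c(50L, 100L, 200L, 400L, 600L, 800L, 1000L)),
                  cutoff = 0.01, metrics = "fd_number"),
    study2 = list(config = base2,
                  sweep = list(param = "noise_rate",
                               values = seq(0, 0.6, by = 0.1)),
                  cutoff = 0.01, metrics = "fd_number"),
    study3 = list(config = sim_config(prop_de = 0.2, fold = 8,
                                      prop_up_sp2 = 0.7,
                                      n_unique = c(1000L, 2000L),
                                      n_unmapped = c(2000L, 4000L),
                                      m_conserved = 1000L),
                  sweep = list(param = "noise_rate", values = c(0, 0.4)),
                  cutoff = 0.01, metrics = "ma"),
    study4 = list(config = sim_config(prop_de = 0.4, fold = 1.2,
                                      prop_up_sp2 = 0.9,
                                      n_unique = c(1000L, 2000L),
                                      n_unmapped = c(2000L, 4000L),
                                      m_conserved = 1000L),
                  sweep = list(param = "cutoff",
                               values = c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.2,
                                          0.4, 0.6)),
                  cutoff = 0.01, metrics = "fd_number"),
    study5 = list(config = base2,
                  sweep = list(param = "noise_rate",
                               values = seq(0, 0.5, by = 0.1)),
                  cutoff = 0.01, metrics = "fd_number"),
    study6 = list(config = base2,
                  sweep = list(param = "noise_rate",
                               values = seq(0, 0.6, by = 0.1)),
                  cutoff = 0.01, metrics = c("precision", "sensitivity", "fscore")),
    study7 = list(config = sim_config(prop_de = 0.1, fold = 1.5,
                                      prop_up_sp2 = 0.9,
                                      n_unique = c(1000L, 2000L),
                                      n_unmapped = c(2000L, 4000L),
                                      m_conserved = 1000L, noise_rate = 0.2),
                  sweep = list(param = "prop_de",
                               values = seq(0.1, 0.6, by = 0.1)),
                  cutoff = 0.01, metrics = "fd_number")
  )
}
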