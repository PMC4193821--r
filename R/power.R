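#' Simulation-based power and type-I error estimation
#'
#' Repeatedly simulates ascertained case-parent trios under a
#' [sim_config()], runs the named test on the focal SNP of each replicate,
#' and reports the fraction of replicates with p below `alpha`. Under a null
#' configuration (all effects zero) this estimates the type-I error of the
#' test. Replicates in which the test is not estimable (no informative sets,
#' non-convergence, separation) count as non-rejections and are reported
#' separately.
#'
#' Tests: `"gtdt"` is the 1-df Wald test of the G-only model; `"lrt"` is the
#' (1+k)-df likelihood-ratio test of the joint G + G-by-E model against the
#' empty null; `"stratum"` is the 1-df Wald test of the one-copy log odds
#' ratio in the exposure stratum `stratum_combo` under the full joint model.
#' `mode = "subgroup"` instead simulates only trios from `stratum_combo` (its
#' per-stratum OR becomes the per-allele OR of that subgroup) and applies the
#' G-only Wald test to them; both modes answer a "power for this stratum"
#' question and neither is canonical.
#'
#' @param config a [sim_config()] object describing the alternative (or null).
#' @param test one of `"gtdt"`, `"lrt"`, `"stratum"`.
#' @param alpha significance level in (0, 1).
#' @param n_reps number of simulation replicates (>= 100).
#' @param seed integer seed for the whole experiment.
#' @param exposures exposures entering the joint model; defaults to the
#'   config's exposures.
#' @param stratum_combo named 0/1 vector naming the stratum for
#'   `test = "stratum"`; default all-unexposed.
#' @param mode `"full"` (default) or `"subgroup"`, see Details.
#' @return Object of class `power_result`: list with `power`, `mc_se`
#'   (`sqrt(power (1 - power) / n_reps)`), `n_reps`, `alpha`, `test_label`,
#'   `n_nonestimable`, `n_trios`.
#' @export
estimate_power <- function(config, test = c("gtdt", "lrt", "stratum"),
                           alpha = 0.05, n_reps = 1000L, seed = 1L,
                           exposures = NULL, stratum_combo = NULL,
                           mode = c("full", "subgroup")) {
  test <- match.arg(test)
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1, n_reps >= 100)
  if (is.null(exposures)) exposures <- config$exposure_names
  if (test == "stratum" && is.null(stratum_combo))
    stratum_combo <- stats::setNames(rep(0L, length(exposures)), exposures)
  if (mode == "subgroup") {
    if (is.null(stratum_combo))
      stop("subgroup mode needs a stratum_combo")
    # collapse the design to the one stratum: its OR is the per-allele OR
    w <- config$beta_g + sum(config$beta_gxe[names(stratum_combo)] * stratum_combo)
    config <- sim_config(n_trios = config$n_trios, maf = config$maf,
                         exposures = NULL, beta_g = w,
                         missing_rate = config$missing_rate,
                         mendel_error_rate = config$mendel_error_rate)
    test <- "gtdt"
    exposures <- character(0)
  }
  set.seed(seed)
  reject <- 0L; nonest <- 0L
  for (r in seq_len(n_reps)) {
    dat <- simulate_trios(config, seed = NULL)
    p <- tryCatch({
      if (test == "gtdt") {
        fit <- trio_clogit(dat, "snp1")
        if (!fit$converged) NA_real_ else wald_test(fit, 1L)$p
      } else if (test == "lrt") {
        fit <- trio_clogit(dat, "snp1", exposures)
        if (!fit$converged) NA_real_ else lrt(fit)$p
      } else {
        fit <- trio_clogit(dat, "snp1", exposures)
        if (!fit$converged) NA_real_
        else stratum_or(fit, stratum_combo, copies = 1L)$wald_p
      }
    }, error = function(e) NA_real_)
    if (is.na(p)) nonest <- nonest + 1L
    else if (p < alpha) reject <- reject + 1L
  }
  power <- reject / n_reps
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / n_reps),
                 n_reps = as.integer(n_reps), alpha = alpha,
                 test_label = if (mode == "subgroup")
                   paste0(test, " (subgroup)") else test,
                 n_nonestimable = nonest,
                 n_trios = config$n_trios),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Simulated power (%s): %.4f (MC SE %.4f)\n",
              x$test_label, x$power, x$mc_se))
  cat(sprintf("  alpha = %g, %d replicates of %d trios", x$alpha,
              x$n_reps, x$n_trios))
  if (x$n_nonestimable > 0)
    cat(sprintf("; %d non-estimable replicates counted as non-rejections",
                x$n_nonestimable))
  cat("\n")
  invisible(x)
}
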