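#' Simulation configuration for synthetic case-parent trios
#'
#' The generative model mirrors the assumptions of the matched-set analysis:
#' parental genotypes are drawn under Hardy-Weinberg equilibrium at the given
#' MAF, the child receives one uniformly chosen allele from each parent, the
#' maternal exposure combination is drawn from a joint distribution, and the
#' trio is ascertained as a case-trio by rejection sampling with probability
#' `exp(eta - eta_max)` where `eta = beta_g G_child + sum_i beta_gxe_i
#' G_child E_i` (the rare-disease multiplicative model under which the
#' conditional-logistic odds ratios equal the simulated relative risks).
#'
#' Effects can be given directly as coefficients (`beta_g`, `beta_gxe`) or as
#' per-stratum one-copy odds ratios (`stratum_or`: the all-unexposed
#' reference stratum OR named `"ref"` plus one OR per single-exposure
#' stratum), converted as `beta_g = log(OR_ref)`,
#' `beta_gxe_i = log(OR_i / OR_ref)`.
#'
#' Defaults are the conditions of the Asian ETS+VIT analysis that motivates
#' the package: 746 trios, MAF 0.20, maternal exposure rates ETS 38.2% and
#' VIT 15.0% (independent), and per-stratum one-copy odds ratios 0.58
#' (neither exposure), 0.95 (ETS only) and 0.69 (VIT only).
#'
#' @param n_trios number of case-parent trios to ascertain.
#' @param maf minor allele frequency in (0, 0.5].
#' @param exposures named vector of marginal exposure probabilities (combos
#'   drawn independently), or `NULL` for no exposures.
#' @param combo_probs optional explicit joint distribution: data.frame with
#'   one 0/1 column per exposure plus a `prob` column summing to 1; overrides
#'   independence.
#' @param beta_g per-allele log odds ratio for the reference (all-unexposed)
#'   stratum.
#' @param beta_gxe named vector of interaction log odds ratios (one per
#'   exposure; missing names default to 0).
#' @param stratum_or alternative effect spec: named vector with element
#'   `"ref"` and one element per exposure, on the one-copy OR scale.
#' @param missing_rate per member-genotype missingness probability.
#' @param mendel_error_rate per trio-SNP probability that the child dosage is
#'   replaced by a uniformly drawn different dosage.
#' @param n_null_snps extra unlinked null markers simulated alongside the
#'   focal SNP (no ascertainment effect).
#' @param seed optional integer seed stored in the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 746L, maf = 0.20,
                       exposures = c(ETS = 0.382, VIT = 0.150),
                       combo_probs = NULL,
                       beta_g = NULL, beta_gxe = NULL, stratum_or = NULL,
                       missing_rate = 0, mendel_error_rate = 0,
                       n_null_snps = 0L, seed = NULL) {
  stopifnot(n_trios >= 1, maf > 0, maf <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            mendel_error_rate >= 0, mendel_error_rate < 1)
  expo_names <- names(exposures)
  if (length(exposures) && is.null(expo_names))
    stop("exposures must be a named vector of rates")
  if (!is.null(stratum_or)) {
    if (!is.null(beta_g) || !is.null(beta_gxe))
      stop("give either stratum_or or beta_g/beta_gxe, not both")
    if (!"ref" %in% names(stratum_or))
      stop("stratum_or must include the all-unexposed stratum as 'ref'")
    beta_g <- log(stratum_or[["ref"]])
    others <- setdiff(names(stratum_or), "ref")
    if (!all(others %in% expo_names))
      stop("stratum_or names must match exposure names")
    beta_gxe <- log(stratum_or[others] / stratum_or[["ref"]])
    names(beta_gxe) <- others
  }
  if (is.null(beta_g) && is.null(beta_gxe) && is.null(stratum_or) &&
      identical(expo_names, c("ETS", "VIT"))) {
    # default effects: the per-stratum one-copy ORs of the motivating analysis
    beta_g <- log(0.58)
    beta_gxe <- log(c(ETS = 0.95, VIT = 0.69) / 0.58)
  }
  if (is.null(beta_g)) beta_g <- 0
  bgxe <- stats::setNames(rep(0, length(expo_names)), expo_names)
  if (!is.null(beta_gxe)) {
    unknown <- setdiff(names(beta_gxe), expo_names)
    if (length(unknown))
      stop("beta_gxe names not among exposures: ", paste(unknown, collapse = ", "))
    bgxe[names(beta_gxe)] <- beta_gxe
  }
  if (!all(is.finite(c(beta_g, bgxe))))
    stop("effect coefficients must be finite")
  if (!is.null(combo_probs)) {
    stopifnot(is.data.frame(combo_probs), "prob" %in% names(combo_probs),
              all(expo_names %in% names(combo_probs)))
    if (abs(sum(combo_probs$prob) - 1) > 1e-8)
      stop("combo probabilities must sum to 1")
  } else if (length(expo_names)) {
    stopifnot(all(exposures >= 0 & exposures <= 1))
    combo_probs <- expand.grid(rep(list(0:1), length(expo_names)))
    names(combo_probs) <- expo_names
    combo_probs$prob <- apply(combo_probs, 1, function(e)
      prod(ifelse(e == 1, exposures, 1 - exposures)))
  } else {
    combo_probs <- data.frame(prob = 1)
  }
  structure(list(n_trios = as.integer(n_trios), maf = maf,
                 exposure_names = expo_names, combo_probs = combo_probs,
                 beta_g = beta_g, beta_gxe = bgxe,
                 missing_rate = missing_rate,
                 mendel_error_rate = mendel_error_rate,
                 n_null_snps = as.integer(n_null_snps), seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Trio simulation config: n = ", x$n_trios, ", MAF = ", x$maf, "\n", sep = "")
  cat("  beta_g = ", signif(x$beta_g, 4), sep = "")
  if (length(x$beta_gxe))
    cat("; beta_gxe: ",
        paste(names(x$beta_gxe), signif(x$beta_gxe, 4), sep = "=", collapse = ", "),
        sep = "")
  cat("\n")
  if (x$missing_rate > 0 || x$mendel_error_rate > 0)
    cat("  missing rate ", x$missing_rate, ", mendel error rate ",
        x$mendel_error_rate, "\n", sep = "")
  invisible(x)
}

# one Mendelian transmission per parent, vectorised
.transmit <- function(g) (g == 2L) + (g == 1L) * (stats::runif(length(g)) < 0.5)

#' Simulate ascertained case-parent trios
#'
#' Draws trios under the model described in [sim_config()] until `n_trios`
#' case-trios are accepted. Deterministic given the seed. The focal SNP is
#' `snp1`; any `n_null_snps` extra markers are simulated independently under
#' the null (pure Mendelian transmission, no ascertainment distortion).
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; defaults to `config$seed`. Pass `NULL` (with no
#'   seed in the config) to consume the current RNG stream.
#' @return A [trio_data] object with the exposure table attached.
#' @export
simulate_trios <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trios
  k <- length(config$exposure_names)
  cp <- config$combo_probs
  Ecombo <- as.matrix(cp[, config$exposure_names, drop = FALSE])
  w_combo <- config$beta_g + if (k) drop(Ecombo %*% config$beta_gxe) else 0
  eta_max <- 2 * max(0, w_combo)

  fa <- mo <- ch <- integer(0)
  combo_idx <- integer(0)
  while (length(fa) < n) {
    B <- max(1000L, 2L * (n - length(fa)))
    f <- stats::rbinom(B, 2L, config$maf)
    m <- stats::rbinom(B, 2L, config$maf)
    c_ <- .transmit(f) + .transmit(m)
    ci <- sample.int(nrow(cp), B, replace = TRUE, prob = cp$prob)
    eta <- c_ * w_combo[ci]
    acc <- stats::runif(B) < exp(eta - eta_max)
    fa <- c(fa, f[acc]); mo <- c(mo, m[acc]); ch <- c(ch, c_[acc])
    combo_idx <- c(combo_idx, ci[acc])
  }
  fa <- fa[seq_len(n)]; mo <- mo[seq_len(n)]; ch <- ch[seq_len(n)]
  combo_idx <- combo_idx[seq_len(n)]

  m_snps <- 1L + config$n_null_snps
  F <- M <- C <- matrix(NA_integer_, n, m_snps)
  F[, 1] <- fa; M[, 1] <- mo; C[, 1] <- ch
  if (config$n_null_snps > 0) for (j in 2:m_snps) {
    F[, j] <- stats::rbinom(n, 2L, config$maf)
    M[, j] <- stats::rbinom(n, 2L, config$maf)
    C[, j] <- .transmit(F[, j]) + .transmit(M[, j])
  }
  fam <- sprintf("F%05d", seq_len(n))
  markers <- data.frame(snp_id = paste0("snp", seq_len(m_snps)),
                        chrom = "14",
                        pos_bp = 54055337L + 1000L * (seq_len(m_snps) - 1L),
                        allele_minor = "A", allele_major = "G",
                        stringsAsFactors = FALSE)
  expo <- data.frame(family_id = fam, stringsAsFactors = FALSE)
  for (nm in config$exposure_names)
    expo[[nm]] <- as.integer(Ecombo[combo_idx, nm])
  out <- trio_data(markers, fam, F, M, C, expo)
  if (config$missing_rate > 0)
    out <- inject_missing(out, config$missing_rate)
  if (config$mendel_error_rate > 0)
    out <- inject_mendel_errors(out, config$mendel_error_rate)
  out
}

#' Blank genotypes at random
#'
#' Each member-genotype (father, mother or child at each marker) is set to
#' missing independently with probability `rate`; exercises the call-rate QC.
#'
#' @param trios a [trio_data] object.
#' @param rate missingness probability in \[0, 1).
#' @param seed optional seed; `NULL` consumes the current RNG stream.
#' @return The modified [trio_data] object.
#' @export
inject_missing <- function(trios, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(trios)
  for (role in names(trios$geno)) {
    g <- trios$geno[[role]]
    g[stats::runif(length(g)) < rate] <- NA_integer_
    trios$geno[[role]] <- g
  }
  trio_data(trios$markers, trios$family_id, trios$geno$father,
            trios$geno$mother, trios$geno$child, trios$exposures)
}

#' Corrupt child genotypes to create Mendelian errors
#'
#' With probability `rate` per trio-marker, the child dosage is replaced by a
#' uniform draw from the two other dosage values (never the original);
#' exercises the Mendelian-error QC.
#'
#' @inheritParams inject_missing
#' @return The modified [trio_data] object.
#' @export
inject_mendel_errors <- function(trios, rate, seed = NULL) {
  stopifnot(rate >= 0, rate < 1)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(trios)
  ch <- trios$geno$child
  hit <- !is.na(ch) & stats::runif(length(ch)) < rate
  if (any(hit)) {
    shift <- sample(1:2, sum(hit), replace = TRUE)
    ch[hit] <- (ch[hit] + shift) %% 3L  # uniform over the two other dosages
  }
  trio_data(trios$markers, trios$family_id, trios$geno$father,
            trios$geno$mother, ch, trios$exposures)
}
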