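#' Genotypic TDT for one SNP
#'
#' Fits the G-only conditional logistic model over all constructible 1:3
#' matched sets and reports the per-allele odds ratio `exp(beta_g)` with its
#' Wald 95% CI and 1-df Wald p-value.
#'
#' @param trios a [trio_data] object.
#' @param snp marker identifier.
#' @param m_bonferroni number of tests for Bonferroni correction of the Wald
#'   p (`NULL` leaves the column `NA`).
#' @return data.frame in the standard result layout (see [write_results()]),
#'   with the fitted [trio_clogit] object as attribute `"fit"`.
#' @export
gtdt <- function(trios, snp, m_bonferroni = NULL) {
  fit <- trio_clogit(trios, snp)
  se <- sqrt(fit$cov[1, 1])
  w <- wald_test(fit, 1L)
  row <- result_row(snp_id = snp, model = "gTDT", term = "G",
                    beta = fit$beta[[1]], se = se, wald_p = w$p,
                    bonferroni_p = if (!is.null(m_bonferroni))
                      bonferroni(w$p, m_bonferroni) else NA_real_,
                    or = exp(fit$beta[[1]]),
                    ci_lo = exp(fit$beta[[1]] - 1.96 * se),
                    ci_hi = exp(fit$beta[[1]] + 1.96 * se),
                    n_sets = fit$n_sets_informative)
  attr(row, "fit") <- fit
  row
}

#' Joint test of genotype and gene-environment interaction
#'
#' Fits `logit P(case) = beta_g G + sum_i beta_gxe_i G E_i` over matched sets
#' from trios with complete genotypes and complete values for every named
#' exposure, and tests the full model against the empty null by a
#' likelihood-ratio test on `1 + k` df (2 df for one interaction, 3 for two,
#' 5 for four). Each term also gets a 1-df Wald test; the `G` row's odds
#' ratio `exp(beta_g)` is the per-allele OR for trios unexposed to every
#' modelled factor.
#'
#' @param trios a [trio_data] object.
#' @param snp marker identifier.
#' @param exposure_names exposures entering interaction terms.
#' @param m_bonferroni number of tests for Bonferroni correction of the LRT
#'   and Wald p-values.
#' @return data.frame with one row per coefficient (standard result layout);
#'   the LRT statistic/df/p are repeated on every row. The [trio_clogit]
#'   object is attached as attribute `"fit"`.
#' @export
joint_test <- function(trios, snp, exposure_names, m_bonferroni = NULL) {
  fit <- trio_clogit(trios, snp, exposure_names)
  lr <- lrt(fit)
  rows <- lapply(seq_along(fit$beta), function(i) {
    se <- sqrt(fit$cov[i, i])
    w <- wald_test(fit, i)
    result_row(snp_id = snp,
               model = paste0("G", if (length(exposure_names))
                 paste0("+Gx", paste(exposure_names, collapse = "+Gx"))),
               term = names(fit$beta)[i],
               beta = fit$beta[[i]], se = se, wald_p = w$p,
               lrt_stat = lr$stat, lrt_df = lr$df, lrt_p = lr$p,
               bonferroni_p = if (!is.null(m_bonferroni))
                 bonferroni(w$p, m_bonferroni) else NA_real_,
               or = exp(fit$beta[[i]]),
               ci_lo = exp(fit$beta[[i]] - 1.96 * se),
               ci_hi = exp(fit$beta[[i]] + 1.96 * se),
               n_sets = fit$n_sets_informative)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}

#' Stratum-specific odds ratio for carriers
#'
#' For an exposure combination the one-copy odds ratio is
#' `exp(beta_g + sum_i beta_gxe_i E_i)` and the two-copy odds ratio its
#' square, `exp(2 (beta_g + sum_i beta_gxe_i E_i))`; the delta-method
#' variance is `c' Sigma c` with contrast `c = copies * (1, E_1, ..., E_k)`.
#'
#' @param fit a converged [trio_clogit] fit with interaction terms.
#' @param exposure_combo named 0/1 vector over (a subset of) the fit's
#'   exposures; omitted exposures count as unexposed.
#' @param copies 1 or 2 copies of the minor allele.
#' @return list with `exposure_combo`, `copies`, `or_value`, `ci_lo`,
#'   `ci_hi`, `wald_p`.
#' @export
stratum_or <- function(fit, exposure_combo = NULL, copies = 1L) {
  stopifnot(copies %in% c(1L, 2L))
  k <- length(fit$exposures)
  ev <- stats::setNames(rep(0, k), fit$exposures)
  if (length(exposure_combo)) {
    unknown <- setdiff(names(exposure_combo), fit$exposures)
    if (length(unknown))
      stop("exposures not in model: ", paste(unknown, collapse = ", "))
    ev[names(exposure_combo)] <- exposure_combo
  }
  cvec <- copies * c(1, ev)
  w <- wald_test(fit, cvec)
  list(exposure_combo = ev, copies = as.integer(copies),
       or_value = exp(w$estimate),
       ci_lo = exp(w$estimate - 1.96 * w$se),
       ci_hi = exp(w$estimate + 1.96 * w$se),
       wald_p = w$p)
}

#' Allelic transmission disequilibrium test
#'
#' McNemar-type count of minor-allele transmissions (`b`) versus
#' non-transmissions (`c`) from heterozygous parents to the affected child,
#' over Mendelian-consistent trios with complete genotypes;
#' `chi2 = (b - c)^2 / (b + c)` on 1 df. A double-heterozygous mating with a
#' heterozygous child contributes one transmission and one non-transmission.
#'
#' @param trios a [trio_data] object.
#' @param snp marker identifier.
#' @return list with `b`, `c`, `chi2`, `p` (`NA` when `b + c = 0`).
#' @export
allelic_tdt <- function(trios, snp) {
  j <- marker_index(trios, snp)
  fa <- trios$geno$father[, j]; mo <- trios$geno$mother[, j]
  ch <- trios$geno$child[, j]
  ok <- mendel_check_vec(fa, mo, ch) == "CONSISTENT"
  b <- 0L; cc <- 0L
  for (i in which(ok)) {
    if (fa[i] == 1L && mo[i] == 1L) {
      if (ch[i] == 2L) b <- b + 2L
      else if (ch[i] == 0L) cc <- cc + 2L
      else { b <- b + 1L; cc <- cc + 1L }
    } else if (fa[i] == 1L || mo[i] == 1L) {
      other <- if (fa[i] == 1L) mo[i] else fa[i]
      t <- ch[i] - other %/% 2L       # allele transmitted by the het parent
      if (t == 1L) b <- b + 1L else cc <- cc + 1L
    }
  }
  if (b + cc == 0L)
    return(list(b = b, c = cc, chi2 = NA_real_, p = NA_real_))
  chi2 <- (b - cc)^2 / (b + cc)
  list(b = b, c = cc, chi2 = chi2,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Bonferroni correction
#'
#' `min(1, m * p)`, vectorised over `p`.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param m number of tests (>= 1).
#' @return Corrected p-value(s) in (0, 1].
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  pmin(1, m * p)
}

#' Per-stratum odds-ratio table for a joint G-by-E model
#'
#' One row per exposure combination observed among the analysed trios, with
#' the number of trios, the stratum MAF (computed from the parents of the
#' trios in that stratum), and the one-copy odds ratio, CI and Wald p from
#' [stratum_or()]. Empty strata are omitted; row counts sum to the number of
#' analysed trios.
#'
#' @param trios a [trio_data] object.
#' @param snp marker identifier.
#' @param exposure_names exposures of the joint model.
#' @param fit optional prefitted [trio_clogit]; refitted when `NULL`.
#' @return data.frame with one exposure column per modelled exposure plus
#'   `n_trios`, `stratum_maf`, `or`, `ci_lo`, `ci_hi`, `wald_p`.
#' @export
stratum_table <- function(trios, snp, exposure_names, fit = NULL) {
  if (is.null(fit)) fit <- trio_clogit(trios, snp, exposure_names)
  if (!fit$converged) stop("joint fit did not converge")
  sets <- fit$sets
  j <- marker_index(trios, snp)
  combos <- unique(as.data.frame(sets$E))
  combos <- combos[do.call(order, as.list(combos)), , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    combo <- as.integer(combos[r, ])
    names(combo) <- exposure_names
    in_str <- apply(sets$E, 1, function(e) all(e == combo))
    fams <- sets$family_id[in_str]
    idx <- match(fams, trios$family_id)
    par <- c(trios$geno$father[idx, j], trios$geno$mother[idx, j])
    par <- par[!is.na(par)]
    so <- stratum_or(fit, combo, copies = 1L)
    cbind(as.data.frame(as.list(combo)),
          data.frame(n_trios = length(fams),
                     stratum_maf = if (length(par)) sum(par) / (2 * length(par))
                                   else NA_real_,
                     or = so$or_value, ci_lo = so$ci_lo, ci_hi = so$ci_hi,
                     wald_p = so$wald_p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
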