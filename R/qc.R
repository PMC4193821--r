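#' Minor allele frequency from parental dosages
#'
#' MAF is computed on founders only (the parents), as allele count over twice
#' the number of non-missing parental genotypes. If the frequency of the
#' allele the dosages are coded against exceeds 0.5 the allele labels are
#' swapped and the dosages re-coded; a tie at exactly 0.5 is broken to the
#' lexicographically smaller allele label, for determinism.
#'
#' @param parental_dosages integer vector of parental dosages (0/1/2/`NA`)
#'   counting copies of `alleles[1]`.
#' @param alleles length-2 character vector: the allele the dosages count,
#'   then the other allele.
#' @return list with `maf`, `allele_minor`, `allele_major`, `swapped`
#'   (logical) and `dosages` re-coded against the minor allele. All-missing
#'   input gives `maf = NA`.
#' @export
compute_maf <- function(parental_dosages, alleles = c("a", "b")) {
  stopifnot(length(alleles) == 2L)
  d <- parental_dosages[!is.na(parental_dosages)]
  if (!length(d))
    return(list(maf = NA_real_, allele_minor = alleles[1],
                allele_major = alleles[2], swapped = FALSE,
                dosages = parental_dosages))
  freq <- sum(d) / (2 * length(d))
  swap <- freq > 0.5 ||
    (freq == 0.5 && alleles[2] < alleles[1])  # tie: smaller label is minor
  if (swap) {
    list(maf = 1 - freq, allele_minor = alleles[2], allele_major = alleles[1],
         swapped = TRUE, dosages = 2L - parental_dosages)
  } else {
    list(maf = freq, allele_minor = alleles[1], allele_major = alleles[2],
         swapped = FALSE, dosages = parental_dosages)
  }
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the genotype total and the minor allele
#' count, the p-value is the sum of probabilities of all heterozygote counts
#' (same parity as the minor allele count) whose conditional probability does
#' not exceed that of the observed count. Probabilities are computed by the
#' standard ratio recurrence between adjacent heterozygote counts, so the
#' test is stable for thousands of genotypes. One-sided cumulative
#' "probability <= observed" definition; no mid-p correction.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts (non-negative, total
#'   positive).
#' @return p-value in (0, 1].
#' @export
hwe_exact <- function(n_hom_major, n_het, n_hom_minor) {
  stopifnot(n_hom_major >= 0, n_het >= 0, n_hom_minor >= 0)
  n <- n_hom_major + n_het + n_hom_minor
  if (n <= 0) stop("no genotypes")
  n_minor <- 2L * n_hom_minor + n_het
  n_major <- 2L * n_hom_major + n_het
  rare <- min(n_minor, n_major)
  if (rare == 0L) return(1)
  hs <- seq.int(rare %% 2L, rare, by = 2L)
  prob <- numeric(length(hs))
  i0 <- which.max(hs)  # start at the largest feasible het count
  prob[i0] <- 1
  # downward recurrence: P(h-2)/P(h) = h(h-1) / (4 (a+1)(c+1))
  # with a, c the hom counts implied by h
  for (i in rev(seq_len(i0 - 1L))) {
    h <- hs[i + 1L]
    a <- (n_major - h) / 2  # hom major at het count h
    c <- (n_minor - h) / 2
    prob[i] <- prob[i + 1L] * h * (h - 1) / (4 * (a + 1) * (c + 1))
  }
  prob <- prob / sum(prob)
  p_obs <- prob[hs == n_het]
  if (!length(p_obs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}

# allowed child dosages for each (father, mother) dosage pair
.mendel_allowed <- local({
  tab <- vector("list", 9L)
  poss <- function(g) if (g == 0L) 0L else if (g == 2L) 1L else c(0L, 1L)
  for (f in 0:2) for (m in 0:2)
    tab[[3L * f + m + 1L]] <- sort(unique(as.vector(outer(poss(f), poss(m), "+"))))
  tab
})

#' Check one trio genotype for Mendelian consistency
#'
#' @param father,mother,child dosages at one SNP (0/1/2/`NA`).
#' @return `"CONSISTENT"`, `"INCONSISTENT"`, or `"UNKNOWN"` when any member
#'   is missing.
#' @export
mendel_check <- function(father, mother, child) {
  if (is.na(father) || is.na(mother) || is.na(child)) return("UNKNOWN")
  if (child %in% .mendel_allowed[[3L * father + mother + 1L]])
    "CONSISTENT" else "INCONSISTENT"
}

# vectorised over trios at one SNP; returns factor-free character vector
mendel_check_vec <- function(father, mother, child) {
  out <- rep("UNKNOWN", length(father))
  ok <- !is.na(father) & !is.na(mother) & !is.na(child)
  if (any(ok)) {
    allowed <- mapply(function(f, m, c)
      c %in% .mendel_allowed[[3L * f + m + 1L]],
      father[ok], mother[ok], child[ok])
    out[ok] <- ifelse(allowed, "CONSISTENT", "INCONSISTENT")
  }
  out
}

#' Pairwise linkage disequilibrium r-squared from unphased dosages
#'
#' Haplotype frequencies are estimated by EM on pairwise-complete parental
#' dosages (the double-heterozygote phase is the only latent state);
#' r2 = D^2 / (pA (1-pA) pB (1-pB)). A monomorphic input has undefined r2,
#' returned as 0.
#'
#' @param dosages_snp1,dosages_snp2 parental dosage vectors (0/1/2/`NA`).
#' @param max_iter,tol EM controls.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosages_snp1, dosages_snp2, max_iter = 100L, tol = 1e-12) {
  ok <- !is.na(dosages_snp1) & !is.na(dosages_snp2)
  g1 <- dosages_snp1[ok]; g2 <- dosages_snp2[ok]
  n <- length(g1)
  if (n == 0L) return(0)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(0)
  # 3x3 genotype-pair table; every cell except the double heterozygote has
  # known phase. Haplotypes ordered (11, 10, 01, 00), allele 1 = minor.
  tab <- table(factor(g1, levels = 0:2), factor(g2, levels = 0:2))
  cnt <- function(i, j) tab[i + 1L, j + 1L]
  base <- c(cnt(1, 2) + cnt(2, 1) + 2 * cnt(2, 2),          # 11
            cnt(1, 0) + 2 * cnt(2, 0) + cnt(2, 1),          # 10
            cnt(0, 1) + 2 * cnt(0, 2) + cnt(1, 2),          # 01
            2 * cnt(0, 0) + cnt(0, 1) + cnt(1, 0))          # 00
  n_dh <- cnt(1, 1)
  p <- rep(0.25, 4)
  for (it in seq_len(max_iter)) {
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5
    cnt <- base + n_dh * c(w, 1 - w, 1 - w, w)
    p_new <- cnt / (2 * n)
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  D <- p[1] - (p[1] + p[2]) * (p[1] + p[3])
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  min(max(r2, 0), 1)
}

#' Per-marker quality control for trio panels
#'
#' Computes, for every marker: MAF (parents only, with allele swap when the
#' raw frequency exceeds 0.5), call rate (over all three members of every
#' trio), Mendelian error rate (inconsistent over checkable trios), and the
#' exact Hardy-Weinberg p-value on parental genotype counts. Flags:
#' `LOW_MAF` (maf < maf_min), `LOW_CALL` (call rate < call_rate_min, or no
#' parental genotype at all), `HIGH_MENDEL` (error rate > mendel_max),
#' `HWE_FAIL` (p < hwe_alpha), and `LD_DUPLICATE` for any marker in perfect
#' LD (r2 = 1) with an earlier otherwise-passing marker in map order.
#' Mendelian-inconsistent trio genotypes are set to missing in the returned
#' dataset (and counted in the error rate) before downstream analysis.
#'
#' @param trios a [trio_data] object.
#' @param maf_min,call_rate_min,mendel_max QC thresholds; defaults 0.01,
#'   0.95, 0.05.
#' @param hwe_alpha HWE significance threshold; `NULL` (default) uses the
#'   Bonferroni-style 0.05 / (number of markers in the panel).
#' @return list of class `trio_qc` with elements `qc` (per-marker table:
#'   snp_id, maf, call_rate, mendel_error_rate, hwe_p, flags, ld_partner),
#'   `passing` (character vector of unflagged markers), and `trios` (the
#'   dataset with swapped dosages and Mendelian inconsistencies blanked).
#' @export
apply_qc <- function(trios, maf_min = 0.01, call_rate_min = 0.95,
                     mendel_max = 0.05, hwe_alpha = NULL) {
  m <- nrow(trios$markers)
  if (is.null(hwe_alpha)) hwe_alpha <- 0.05 / m
  fa <- trios$geno$father; mo <- trios$geno$mother; ch <- trios$geno$child
  mk <- trios$markers
  maf <- call_rate <- mendel_rate <- hwe_p <- rep(NA_real_, m)
  flags <- vector("list", m)
  ld_partner <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    fl <- character(0)
    call_rate[j] <- mean(!is.na(c(fa[, j], mo[, j], ch[, j])))
    res <- compute_maf(c(fa[, j], mo[, j]),
                       alleles = c(mk$allele_minor[j], mk$allele_major[j]))
    if (res$swapped) {
      mk$allele_minor[j] <- res$allele_minor
      mk$allele_major[j] <- res$allele_major
      fa[, j] <- 2L - fa[, j]; mo[, j] <- 2L - mo[, j]; ch[, j] <- 2L - ch[, j]
    }
    maf[j] <- res$maf
    if (is.na(res$maf)) {
      fl <- c(fl, "LOW_CALL")
    } else {
      if (res$maf < maf_min) fl <- c(fl, "LOW_MAF")
      if (call_rate[j] < call_rate_min) fl <- c(fl, "LOW_CALL")
      par <- c(fa[, j], mo[, j]); par <- par[!is.na(par)]
      hwe_p[j] <- hwe_exact(sum(par == 0L), sum(par == 1L), sum(par == 2L))
      if (hwe_p[j] < hwe_alpha) fl <- c(fl, "HWE_FAIL")
    }
    status <- mendel_check_vec(fa[, j], mo[, j], ch[, j])
    n_inc <- sum(status == "INCONSISTENT")
    n_chk <- n_inc + sum(status == "CONSISTENT")
    mendel_rate[j] <- if (n_chk > 0) n_inc / n_chk else NA_real_
    if (!is.na(mendel_rate[j]) && mendel_rate[j] > mendel_max)
      fl <- c(fl, "HIGH_MENDEL")
    if (n_inc > 0) {  # blank inconsistent trio genotypes for downstream use
      bad <- status == "INCONSISTENT"
      fa[bad, j] <- NA_integer_; mo[bad, j] <- NA_integer_; ch[bad, j] <- NA_integer_
    }
    flags[[j]] <- fl
  }
  # r^2 = 1 de-duplication among markers passing all other flags, in map order
  cand <- which(lengths(flags) == 0L)
  if (length(cand) > 1L) {
    kept <- cand[1]
    for (j in cand[-1]) {
      for (k in kept) {
        r2 <- ld_r2(c(fa[, k], mo[, k]), c(fa[, j], mo[, j]))
        if (r2 >= 1 - 1e-9) {
          flags[[j]] <- "LD_DUPLICATE"
          ld_partner[j] <- mk$snp_id[k]
          break
        }
      }
      if (!length(flags[[j]])) kept <- c(kept, j)
    }
  }
  qc <- data.frame(snp_id = mk$snp_id, maf = maf, call_rate = call_rate,
                   mendel_error_rate = mendel_rate, hwe_p = hwe_p,
                   flags = vapply(flags, paste, "", collapse = ","),
                   ld_partner = ld_partner, stringsAsFactors = FALSE)
  cleaned <- trio_data(mk, trios$family_id, fa, mo, ch, trios$exposures)
  structure(list(qc = qc, passing = mk$snp_id[lengths(flags) == 0L],
                 trios = cleaned,
                 thresholds = list(maf_min = maf_min,
                                   call_rate_min = call_rate_min,
                                   mendel_max = mendel_max,
                                   hwe_alpha = hwe_alpha)),
            class = "trio_qc")
}

#' @export
print.trio_qc <- function(x, ...) {
  cat("Marker QC: ", nrow(x$qc), " markers, ", length(x$passing),
      " passing\n", sep = "")
  th <- x$thresholds
  cat(sprintf("  thresholds: maf >= %g, call rate >= %g, mendel <= %g, hwe alpha %g\n",
              th$maf_min, th$call_rate_min, th$mendel_max, th$hwe_alpha))
  flagged <- x$qc[nzchar(x$qc$flags), c("snp_id", "flags")]
  if (nrow(flagged)) {
    cat("  flagged:\n")
    for (i in seq_len(min(nrow(flagged), 20)))
      cat("    ", flagged$snp_id[i], ": ", flagged$flags[i], "\n", sep = "")
    if (nrow(flagged) > 20) cat("    ...\n")
  }
  invisible(x)
}
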