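# Fixture builders and independent oracles shared across the suite.

# single-SNP trio_data from dosage vectors
make_trios <- function(father, mother, child, exposures = NULL,
                       snp_id = "s1", allele_minor = "A", allele_major = "G") {
  n <- length(father)
  fam <- sprintf("F%03d", seq_len(n))
  mk <- data.frame(snp_id = snp_id, chrom = "1", pos_bp = 100L,
                   allele_minor = allele_minor, allele_major = allele_major,
                   stringsAsFactors = FALSE)
  expo <- if (is.null(exposures)) NULL else {
    df <- as.data.frame(exposures)
    df$family_id <- fam
    df
  }
  trio_data(mk, fam, cbind(as.integer(father)), cbind(as.integer(mother)),
            cbind(as.integer(child)), expo)
}

# multi-SNP trio_data from dosage matrices
make_trios_multi <- function(F, M, C, exposures = NULL) {
  n <- nrow(F); m <- ncol(F)
  fam <- sprintf("F%03d", seq_len(n))
  mk <- data.frame(snp_id = paste0("s", seq_len(m)), chrom = "1",
                   pos_bp = 100L * seq_len(m),
                   allele_minor = "A", allele_major = "G",
                   stringsAsFactors = FALSE)
  expo <- if (is.null(exposures)) NULL else {
    df <- as.data.frame(exposures); df$family_id <- fam; df
  }
  trio_data(mk, fam, F, M, C, expo)
}

# Independent HWE oracle: direct log-multinomial enumeration over all
# heterozygote counts compatible with the allele margins, probability-ordering
# p-value with the same 1e-10 relative tie tolerance as the implementation.
hwe_oracle <- function(n_hom_major, n_het, n_hom_minor) {
  n <- n_hom_major + n_het + n_hom_minor
  n_minor <- 2 * n_hom_minor + n_het
  n_major <- 2 * n - n_minor
  rare <- min(n_minor, n_major)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hs, function(h) {
    c_ <- (n_minor - h) / 2
    a_ <- (n_major - h) / 2
    lgamma(n + 1) - lgamma(a_ + 1) - lgamma(h + 1) - lgamma(c_ + 1) +
      h * log(2) +
      lgamma(n_minor + 1) + lgamma(n_major + 1) - lgamma(2 * n + 1)
  }, 0)
  prob <- exp(logp)
  p_obs <- prob[hs == n_het]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-10)]))
}

# Independent conditional-likelihood evaluator + 1-D grid-search maximiser
# for the G-only model on a matrix of matched-set genotypes (case in col 1).
cond_loglik_1d <- function(beta, G) {
  sum(beta * G[, 1] - log(rowSums(exp(beta * G))))
}
clogit_grid_oracle <- function(G, lo = -10, hi = 10) {
  for (pass in 1:8) {
    grid <- seq(lo, hi, length.out = 201)
    ll <- vapply(grid, cond_loglik_1d, 0, G = G)
    i <- which.max(ll)
    lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  }
  (lo + hi) / 2
}

# expand matched sets to the long format survival::clogit expects
sets_to_long <- function(sets) {
  n <- nrow(sets$G)
  k <- ncol(sets$E)
  long <- data.frame(set = rep(seq_len(n), each = 4),
                     case = rep(c(1, 0, 0, 0), n),
                     G = as.vector(t(sets$G)))
  if (k) for (q in seq_len(k))
    long[[paste0("GxE", q)]] <- long$G * rep(sets$E[, q], each = 4)
  long
}
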