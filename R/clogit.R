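#' Covariate row for one member of a matched set
#'
#' Under additive coding the design for a member with genotype dosage G and
#' maternal exposures E is `[G, G*E_1, ..., G*E_k]`. Exposure main effects do
#' not appear: they are constant within a matched set (the case and its three
#' pseudo-controls share the mother) and hence inestimable in a conditional
#' likelihood.
#'
#' @param member_genotype dosage (0/1/2).
#' @param exposures named 0/1 vector containing every model exposure.
#' @param exposure_names ordered exposures entering interaction terms.
#' @return numeric vector of length `1 + length(exposure_names)`.
#' @export
design_row <- function(member_genotype, exposures = NULL,
                       exposure_names = character(0)) {
  if (length(exposure_names)) {
    ev <- unlist(exposures)[exposure_names]
    if (anyNA(ev)) stop("exposures must contain every model exposure")
    unname(c(member_genotype, member_genotype * ev))
  } else {
    member_genotype
  }
}

# Newton-Raphson maximiser of the conditional logistic likelihood over 1:3
# matched sets. X is an n x 4 x p array of member design rows, case in slot 1.
# Uninformative sets (all four rows identical) are excluded from both the
# fitted and null log-likelihoods; the null (empty) model has log-likelihood
# n_informative * log(1/4).
clogit_fit_array <- function(X, tol = 1e-8, max_iter = 100L, beta_max = 15) {
  stopifnot(length(dim(X)) == 3L, dim(X)[2] == 4L)
  p <- dim(X)[3]
  # informative = design varies within the set
  rng <- apply(X, c(1, 3), function(v) max(v) - min(v))
  rng <- matrix(rng, ncol = p)
  informative <- rowSums(rng > 0) > 0
  n_inf <- sum(informative)
  if (n_inf == 0L) stop("no information: every matched set is uninformative")
  X <- X[informative, , , drop = FALSE]
  Xf <- matrix(X, nrow = n_inf * 4L, ncol = p)  # member-major flattening

  eta_of <- function(beta) matrix(Xf %*% beta, n_inf, 4L)
  loglik_of <- function(beta) {
    eta <- eta_of(beta)
    mx <- apply(eta, 1, max)
    sum(eta[, 1] - mx - log(rowSums(exp(eta - mx))))
  }

  beta <- rep(0, p)
  ll <- loglik_of(beta)
  converged <- FALSE
  separation <- FALSE
  info <- NULL
  for (it in seq_len(max_iter)) {
    eta <- eta_of(beta)
    mx <- apply(eta, 1, max)
    w <- exp(eta - mx)
    prob <- w / rowSums(w)                     # n x 4 conditional probabilities
    pf <- as.vector(prob)                      # aligned with Xf rows
    xbar <- matrix(0, n_inf, p)                # within-set expected design
    for (k in seq_len(p))
      xbar[, k] <- rowSums(matrix(Xf[, k] * pf, n_inf, 4L))
    score <- colSums(matrix(X[, 1, ], n_inf, p) - xbar)
    info <- crossprod(Xf * sqrt(pf)) - crossprod(xbar)
    if (it == 1L && (p > 0 && rcond(info) < 1e-10))
      stop("inestimable term: singular information (set-constant or all-zero column)")
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    step <- solve(info, score)
    # step-halving keeps the concave log-likelihood increasing monotonically
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      ll_new <- loglik_of(beta_new)
      if (ll_new >= ll - 1e-12 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    beta <- beta_new; ll <- ll_new
    if (max(abs(beta)) > beta_max) { separation <- TRUE; break }
  }
  ll <- loglik_of(beta)
  cov <- if (converged && !separation) solve(info) else
    matrix(NA_real_, p, p)
  list(beta = beta, cov = cov, loglik = ll,
       loglik_null = -n_inf * log(4), n_sets_informative = n_inf,
       informative = informative,
       converged = converged && !separation, separation_flag = separation,
       n_iter = it)
}

# assemble the n x 4 x p design array for a genotype matrix G (n x 4) and
# exposure matrix E (n x k): X[s, j, ] = G[s, j] * c(1, E[s, ])
design_array <- function(G, E) {
  n <- nrow(G); k <- ncol(E)
  X <- array(0, dim = c(n, 4L, 1L + k))
  X[, , 1] <- G
  if (k > 0) for (q in seq_len(k)) X[, , 1L + q] <- G * E[, q]
  X
}

#' Fit the genotypic TDT conditional logistic model
#'
#' Maximises the conditional logistic likelihood of the observed case against
#' its three Mendelian pseudo-controls over all constructible matched sets at
#' one SNP, for the model
#' \deqn{\mathrm{logit}\,P(\mathrm{case}) = \beta_g G + \sum_i \beta_{g \times e_i} G E_i,}
#' with G the minor-allele dosage (additive coding) and each E_i a binary
#' maternal exposure. With no exposures this is the genotypic TDT;
#' `exp(beta_g)` is the per-allele odds ratio. Trios with a missing member
#' genotype, a Mendelian inconsistency, or any missing model exposure are
#' skipped for this SNP (per-SNP complete case). Newton-Raphson from zero
#' with step-halving; convergence when the gradient max-norm drops below
#' `tol`. Fits with any |beta| exceeding 15 are flagged as separated and
#' reported non-estimable (infinite standard errors).
#'
#' @param trios a [trio_data] object.
#' @param snp marker identifier.
#' @param exposures character vector of maternal exposures entering G-by-E
#'   interaction terms (may be empty).
#' @param tol,max_iter optimiser controls.
#' @return An object of class `trio_clogit` with components `beta` (named:
#'   `G`, then `G:<exposure>`), `cov`, `loglik`, `loglik_null`
#'   (`n_sets_informative * log(1/4)`), `n_sets_informative`, `n_sets_used`,
#'   `converged`, `separation_flag`, `skipped`, `sets`.
#' @seealso [gtdt()], [joint_test()], [lrt()], [wald_test()]
#' @export
trio_clogit <- function(trios, snp, exposures = character(0),
                        tol = 1e-8, max_iter = 100L) {
  if (anyDuplicated(exposures)) stop("exposure names must be unique")
  sets <- build_matched_sets(trios, snp, exposures)
  fit_matched_sets(sets, tol = tol, max_iter = max_iter,
                   call = match.call())
}

# fit from a prebuilt matched-set bundle (used by trio_clogit and the tests)
fit_matched_sets <- function(sets, tol = 1e-8, max_iter = 100L, call = NULL) {
  if (nrow(sets$G) == 0L)
    stop("no information: no constructible matched sets")
  X <- design_array(sets$G, sets$E)
  eng <- clogit_fit_array(X, tol = tol, max_iter = max_iter)
  nm <- c("G", if (length(sets$exposure_names))
    paste0("G:", sets$exposure_names))
  names(eng$beta) <- nm
  dimnames(eng$cov) <- list(nm, nm)
  structure(list(beta = eng$beta, cov = eng$cov,
                 loglik = eng$loglik, loglik_null = eng$loglik_null,
                 n_sets_informative = eng$n_sets_informative,
                 n_sets_used = nrow(sets$G),
                 informative_families = sets$family_id[eng$informative],
                 converged = eng$converged,
                 separation_flag = eng$separation_flag,
                 n_iter = eng$n_iter,
                 snp_id = sets$snp_id, exposures = sets$exposure_names,
                 skipped = sets$skipped, sets = sets, call = call),
            class = "trio_clogit")
}

#' @export
print.trio_clogit <- function(x, digits = 4, ...) {
  cat("Conditional logistic fit (1 case : 3 pseudo-controls)",
      if (!is.null(x$snp_id)) paste0(" for ", x$snp_id), "\n", sep = "")
  cat("  ", x$n_sets_used, " matched sets (", x$n_sets_informative,
      " informative)\n", sep = "")
  if (x$separation_flag)
    cat("  WARNING: separation detected; estimates are not reliable\n")
  se <- sqrt(diag(x$cov))
  tab <- cbind(beta = x$beta, se = se, OR = exp(x$beta))
  print(round(tab, digits))
  invisible(x)
}

#' @export
coef.trio_clogit <- function(object, ...) object$beta

#' @export
vcov.trio_clogit <- function(object, ...) object$cov

#' @export
logLik.trio_clogit <- function(object, ...) {
  structure(object$loglik, df = length(object$beta),
            nobs = object$n_sets_informative, class = "logLik")
}

#' @export
nobs.trio_clogit <- function(object, ...) object$n_sets_informative

#' @export
confint.trio_clogit <- function(object, parm = NULL, level = 0.95, ...) {
  se <- sqrt(diag(object$cov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$beta - z * se, object$beta + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  rownames(ci) <- names(object$beta)
  if (!is.null(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.trio_clogit <- function(object, ...) {
  se <- sqrt(diag(object$cov))
  z <- object$beta / se
  chi2 <- z^2
  wald_p <- stats::pchisq(chi2, 1, lower.tail = FALSE)
  coefs <- data.frame(beta = object$beta, se = se,
                      or = exp(object$beta),
                      ci_lo = exp(object$beta - 1.96 * se),
                      ci_hi = exp(object$beta + 1.96 * se),
                      wald_chi2 = chi2, wald_p = wald_p)
  lr <- lrt(object)
  structure(list(coefficients = coefs, lrt = lr, fit = object),
            class = "summary.trio_clogit")
}

#' @export
print.summary.trio_clogit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-term Wald tests and odds ratios:\n")
  print(round(as.matrix(x$coefficients), digits))
  cat(sprintf("\nLRT vs empty null: chi2 = %.4g on %d df, p = %.4g\n",
              x$lrt$stat, x$lrt$df, x$lrt$p))
  invisible(x)
}

#' Wald test of a coefficient or contrast
#'
#' `chi2 = (c'beta)^2 / (c' Sigma c)` referred to a 1-df chi-squared.
#'
#' @param fit a converged [trio_clogit] fit.
#' @param contrast coefficient index, coefficient name, or numeric contrast
#'   vector of the coefficient length.
#' @return list with `estimate` (`c'beta`), `se`, `z`, `chi2`, `p`.
#' @export
wald_test <- function(fit, contrast = 1L) {
  if (!fit$converged) stop("Wald test requires a converged fit")
  p <- length(fit$beta)
  if (is.character(contrast)) {
    contrast <- match(contrast, names(fit$beta))
    if (anyNA(contrast)) stop("unknown coefficient name")
  }
  if (length(contrast) == 1L) {
    cvec <- rep(0, p); cvec[as.integer(contrast)] <- 1
  } else {
    stopifnot(length(contrast) == p)
    cvec <- as.numeric(contrast)
  }
  est <- sum(cvec * fit$beta)
  v <- drop(t(cvec) %*% fit$cov %*% cvec)
  if (!is.finite(v) || v <= 0) stop("zero or undefined contrast variance")
  z <- est / sqrt(v)
  list(estimate = est, se = sqrt(v), z = z, chi2 = z^2,
       p = stats::pchisq(z^2, 1, lower.tail = FALSE))
}

#' Likelihood-ratio test between nested matched-set fits
#'
#' With `fit_null = NULL` the comparison is against the empty model, whose
#' log-likelihood over the informative sets is `n * log(1/4)`; the df is then
#' the number of fitted parameters (1 + number of interactions). Both fits
#' must use the same matched sets.
#'
#' @param fit_full,fit_null [trio_clogit] fits, null nested in full.
#' @return list with `stat`, `df`, `p`.
#' @export
lrt <- function(fit_full, fit_null = NULL) {
  if (is.null(fit_null)) {
    stat <- 2 * (fit_full$loglik - fit_full$loglik_null)
    df <- length(fit_full$beta)
  } else {
    if (fit_full$n_sets_informative != fit_null$n_sets_informative ||
        !identical(fit_full$informative_families, fit_null$informative_families))
      stop("set mismatch: the two fits use different matched sets")
    if (length(fit_null$beta) >= length(fit_full$beta))
      stop("null model must be nested in (smaller than) the full model")
    stat <- 2 * (fit_full$loglik - fit_null$loglik)
    df <- length(fit_full$beta) - length(fit_null$beta)
  }
  stat <- max(stat, 0)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}
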