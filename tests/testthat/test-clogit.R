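test_that("design rows are [G, G*E_1, ..., G*E_k]", {
  expect_equal(design_row(2), 2)
  expect_equal(design_row(1, c(ETS = 1, VIT = 0), c("ETS", "VIT")), c(1, 1, 0))
  expect_equal(design_row(0, c(ETS = 1, VIT = 1), c("ETS", "VIT")), c(0, 0, 0))
})

test_that("single-heterozygous-parent matings give the closed form exp(beta) = T/U", {
  td <- make_trios(rep(1, 12), rep(0, 12), c(rep(1, 9), rep(0, 3)))
  fit <- trio_clogit(td, "s1")
  expect_true(fit$converged)
  expect_equal(unname(fit$beta), log(3), tolerance = 1e-8)
  expect_equal(exp(fit$beta[[1]]), 3.0, tolerance = 1e-7)
  # independent 1-D grid-search oracle over the conditional likelihood
  sets <- triogxe:::build_matched_sets(td, "s1")
  expect_equal(unname(fit$beta), clogit_grid_oracle(sets$G), tolerance = 1e-6)
  # null loglik bookkeeping: only informative sets contribute
  expect_equal(fit$loglik_null, fit$n_sets_informative * log(1 / 4))
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("heterozygous cases from Aa x Aa matings give beta = 0 by symmetry", {
  td <- make_trios(rep(1, 8), rep(1, 8), rep(1, 8))
  fit <- trio_clogit(td, "s1")
  expect_equal(unname(fit$beta), 0, tolerance = 1e-8)
  expect_equal(wald_test(fit, 1L)$p, 1, tolerance = 1e-6)
})

test_that("conditional probabilities sum to 1 within each set at any beta", {
  set.seed(3)
  td <- simulate_trios(sim_config(n_trios = 50, maf = 0.25,
                                  exposures = c(ETS = 0.4),
                                  beta_g = log(0.7), beta_gxe = c(ETS = 0.3)),
                       seed = 4)
  sets <- triogxe:::build_matched_sets(td, "snp1", "ETS")
  X <- triogxe:::design_array(sets$G, sets$E)
  for (beta in list(c(0, 0), c(0.5, -1), c(-2, 3))) {
    eta <- apply(X, 2, function(x) x %*% beta)
    prob <- exp(eta) / rowSums(exp(eta))
    expect_equal(rowSums(prob), rep(1, nrow(prob)))
  }
})

test_that("estimates are invariant to pseudo-control ordering", {
  td <- make_trios(c(1, 1, 2, 1, 1, 0), c(1, 0, 1, 1, 0, 1),
                   c(2, 1, 2, 1, 0, 1))
  sets <- triogxe:::build_matched_sets(td, "s1")
  fit1 <- triogxe:::fit_matched_sets(sets)
  perm <- sets
  set.seed(9)
  for (i in seq_len(nrow(perm$G)))
    perm$G[i, 2:4] <- sample(perm$G[i, 2:4])
  fit2 <- triogxe:::fit_matched_sets(perm)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-10)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-10)
})

test_that("set-constant and all-zero columns are inestimable, not absorbed", {
  td <- make_trios(c(1, 1, 2, 1), c(1, 0, 1, 1), c(2, 1, 2, 1),
                   exposures = data.frame(ETS = c(1L, 0L, 1L, 0L),
                                          ZERO = c(0L, 0L, 0L, 0L)))
  # interaction with an identically-zero exposure: all-zero column
  expect_error(trio_clogit(td, "s1", "ZERO"), "inestimable term")
  # exposure main effect: constant within every matched set
  sets <- triogxe:::build_matched_sets(td, "s1", "ETS")
  n <- nrow(sets$G)
  X <- array(0, dim = c(n, 4, 2))
  X[, , 1] <- sets$G
  X[, , 2] <- matrix(sets$E[, 1], n, 4)  # E main effect, set-constant
  expect_error(triogxe:::clogit_fit_array(X), "inestimable term")
})

test_that("no-information and missing-parent corners raise errors", {
  td <- make_trios(c(0, 2), c(0, 2), c(0, 2))  # all parents homozygous
  expect_error(trio_clogit(td, "s1"), "no information")
  expect_error(wald_test(structure(list(converged = FALSE),
                                   class = "trio_clogit")), "converged")
})

test_that("Wald machinery matches the normal quantile anchors", {
  fit <- structure(list(beta = c(G = 0.5), cov = matrix((0.5 / 1.96)^2, 1, 1,
                                                        dimnames = list("G", "G")),
                        converged = TRUE),
                   class = "trio_clogit")
  w <- wald_test(fit, 1L)
  expect_equal(w$z, 1.96)
  expect_equal(w$p, 0.05, tolerance = 1e-3)
  fit$beta <- c(G = 0)
  expect_equal(wald_test(fit, 1L)$p, 1)
})

test_that("fit agrees with survival::clogit on a shared fixture to 1e-6", {
  skip_if_not_installed("survival")
  library(survival)
  set.seed(17)
  td <- simulate_trios(sim_config(n_trios = 400, maf = 0.25,
                                  exposures = c(ETS = 0.4),
                                  beta_g = log(0.7),
                                  beta_gxe = c(ETS = log(1.5))),
                       seed = 18)
  fit <- trio_clogit(td, "snp1", "ETS")
  sets <- fit$sets
  long <- sets_to_long(sets)
  ref <- survival::clogit(case ~ G + GxE1 + strata(set), data = long)
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$cov))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  # Wald p agreement
  z_ref <- coef(ref) / sqrt(diag(vcov(ref)))
  p_ref <- pchisq(z_ref^2, 1, lower.tail = FALSE)
  expect_equal(wald_test(fit, 1L)$p, unname(p_ref[1]), tolerance = 1e-6)
  expect_equal(wald_test(fit, 2L)$p, unname(p_ref[2]), tolerance = 1e-6)
})

test_that("LRT degrees of freedom follow the parameter-count rule", {
  set.seed(23)
  td <- simulate_trios(sim_config(n_trios = 300, maf = 0.3,
                                  exposures = c(ETS = 0.4, VIT = 0.3),
                                  beta_g = 0, beta_gxe = c(ETS = 0, VIT = 0)),
                       seed = 24)
  td$exposures$VIT[1:20] <- NA  # VIT models lose trios; per-model complete case
  fit_g <- trio_clogit(td, "snp1")
  fit_2 <- trio_clogit(td, "snp1", "ETS")
  fit_3 <- trio_clogit(td, "snp1", c("ETS", "VIT"))
  expect_equal(lrt(fit_g)$df, 1)
  expect_equal(lrt(fit_2)$df, 2)
  expect_equal(lrt(fit_3)$df, 3)
  # fit vs itself: zero statistic, p = 1
  self <- lrt(fit_3)
  expect_equal(2 * (fit_3$loglik - fit_3$loglik), 0)
  expect_equal(stats::pchisq(0, 3, lower.tail = FALSE), 1)
  expect_gte(self$stat, 0)
  # nested comparison needs identical matched sets
  expect_error(lrt(fit_3, fit_g), "set mismatch")
  sets3 <- fit_3$sets
  g_only <- sets3; g_only$E <- sets3$E[, 0, drop = FALSE]
  g_only$exposure_names <- character(0)
  fit_g_same <- triogxe:::fit_matched_sets(g_only)
  nested <- lrt(fit_3, fit_g_same)
  expect_equal(nested$df, 2)
  expect_gte(nested$stat, 0)
})

test_that("separation is flagged instead of reporting huge finite estimates", {
  # every informative case carries the maximum genotype: likelihood increases
  # in beta without bound
  td <- make_trios(rep(1, 10), rep(1, 10), rep(2, 10))
  fit <- trio_clogit(td, "s1")
  expect_true(fit$separation_flag)
  expect_false(fit$converged)
})
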