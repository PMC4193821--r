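test_that("gTDT reports the closed-form OR with CI bracketing it", {
  td <- make_trios(rep(1, 12), rep(0, 12), c(rep(1, 9), rep(0, 3)))
  row <- gtdt(td, "s1", m_bonferroni = 117)
  expect_equal(row$or, 3.0, tolerance = 1e-6)
  expect_lte(row$ci_lo, row$or)
  expect_gte(row$ci_hi, row$or)
  expect_equal(row$bonferroni_p, min(1, 117 * row$wald_p))
  # balanced transmissions: OR 1, p 1
  bal <- make_trios(rep(1, 8), rep(0, 8), rep(c(1, 0), 4))
  row_b <- gtdt(bal, "s1")
  expect_equal(row_b$or, 1, tolerance = 1e-7)
  expect_equal(row_b$wald_p, 1, tolerance = 1e-6)
})

test_that("joint model with no interactions reduces exactly to the gTDT", {
  set.seed(41)
  td <- simulate_trios(sim_config(n_trios = 200, maf = 0.25,
                                  exposures = c(ETS = 0.4),
                                  beta_g = log(0.8), beta_gxe = c(ETS = 0.2)),
                       seed = 42)
  fit_g <- attr(gtdt(td, "snp1"), "fit")
  fit_j <- attr(joint_test(td, "snp1", character(0)), "fit")
  expect_equal(fit_g$beta[["G"]], fit_j$beta[["G"]], tolerance = 1e-12)
  expect_equal(fit_g$loglik, fit_j$loglik, tolerance = 1e-12)
})

test_that("joint test carries the (1+k)-df LRT and per-term Wald tests", {
  set.seed(43)
  td <- simulate_trios(sim_config(n_trios = 400, maf = 0.25), seed = 44)
  res <- joint_test(td, "snp1", c("ETS", "VIT"), m_bonferroni = 117)
  expect_equal(nrow(res), 3)
  expect_equal(res$term, c("G", "G:ETS", "G:VIT"))
  expect_equal(unique(res$lrt_df), 3L)
  fit <- attr(res, "fit")
  expect_equal(res$lrt_stat[1], 2 * (fit$loglik - fit$loglik_null),
               tolerance = 1e-10)
  expect_equal(res$bonferroni_p, pmin(1, 117 * res$wald_p))
  # exposure identically zero makes its interaction inestimable
  td0 <- td
  td0$exposures$ETS <- 0L
  expect_error(joint_test(td0, "snp1", "ETS"), "inestimable term")
})

test_that("stratum ORs follow the contrast exp(copies * (beta_g + sum beta_gxe E))", {
  set.seed(45)
  td <- simulate_trios(sim_config(n_trios = 600, maf = 0.25), seed = 46)
  fit <- trio_clogit(td, "snp1", c("ETS", "VIT"))
  b <- fit$beta
  ref <- stratum_or(fit, NULL, copies = 1)
  expect_equal(ref$or_value, exp(b[["G"]]))
  both <- stratum_or(fit, c(ETS = 1, VIT = 1), copies = 1)
  expect_equal(both$or_value, exp(b[["G"]] + b[["G:ETS"]] + b[["G:VIT"]]))
  two <- stratum_or(fit, NULL, copies = 2)
  expect_equal(two$or_value, ref$or_value^2, tolerance = 1e-10)
  expect_lte(ref$ci_lo, ref$or_value); expect_gte(ref$ci_hi, ref$or_value)
})

test_that("stratum OR delta-method variance matches a parametric bootstrap to 5%", {
  set.seed(47)
  cfg <- sim_config(n_trios = 800, maf = 0.25)
  td <- simulate_trios(cfg, seed = 48)
  fit <- trio_clogit(td, "snp1", c("ETS", "VIT"))
  combo <- c(ETS = 1, VIT = 1)
  cvec <- c(1, 1, 1)
  se_delta <- sqrt(drop(t(cvec) %*% fit$cov %*% cvec))
  boot <- replicate(500, {
    d <- simulate_trios(cfg, seed = NULL)
    f <- trio_clogit(d, "snp1", c("ETS", "VIT"))
    sum(cvec * f$beta)
  })
  expect_equal(se_delta, sd(boot), tolerance = 0.10)
})

test_that("allelic TDT counts transmissions from heterozygous parents", {
  # 15 transmissions vs 5: chi2 = (15-5)^2/20 = 5
  td <- make_trios(rep(1, 20), rep(0, 20), c(rep(1, 15), rep(0, 5)))
  res <- allelic_tdt(td, "s1")
  expect_equal(res$b, 15L); expect_equal(res$c, 5L)
  expect_equal(res$chi2, 5.0)
  bal <- make_trios(rep(1, 20), rep(0, 20), rep(c(1, 0), 10))
  res_b <- allelic_tdt(bal, "s1")
  expect_equal(res_b$chi2, 0); expect_equal(res_b$p, 1)
  # double-het matings with het child add one to each arm
  dh <- make_trios(c(1, 1), c(1, 1), c(1, 2))
  res_dh <- allelic_tdt(dh, "s1")
  expect_equal(res_dh$b, 3L); expect_equal(res_dh$c, 1L)
  hom <- make_trios(c(0, 2), c(0, 2), c(0, 2))
  expect_true(is.na(allelic_tdt(hom, "s1")$chi2))
})

test_that("gTDT Wald approaches the allelic TDT on single-het-parent data", {
  td <- make_trios(rep(1, 200), rep(0, 200), c(rep(1, 120), rep(0, 80)))
  g <- gtdt(td, "s1")
  a <- allelic_tdt(td, "s1")
  expect_equal(g$or, 120 / 80, tolerance = 1e-6)
  expect_equal(g$wald_p, a$p, tolerance = 0.05)
})

test_that("Bonferroni correction reproduces printed pairs and is monotone", {
  expect_equal(signif(bonferroni(4.39e-5, 117), 2), 0.0051)
  expect_equal(signif(bonferroni(7.18e-3, 120), 2), 0.86)
  expect_equal(bonferroni(0.5, 3), 1)
  p <- c(1e-6, 1e-4, 0.01, 0.5, 1)
  expect_true(all(diff(bonferroni(p, 10)) >= 0))         # monotone in p
  expect_true(all(bonferroni(0.01, 1:200) ==
                  pmin(1, 0.01 * 1:200)))                # monotone in m, capped
})

test_that("the stratum table covers observed combos and sums to the analysed trios", {
  set.seed(49)
  td <- simulate_trios(sim_config(n_trios = 500, maf = 0.25), seed = 50)
  fit <- trio_clogit(td, "snp1", c("ETS", "VIT"))
  tab <- stratum_table(td, "snp1", c("ETS", "VIT"), fit = fit)
  expect_lte(nrow(tab), 4)
  expect_equal(sum(tab$n_trios), fit$n_sets_used)
  expect_true(all(tab$ci_lo <= tab$or & tab$or <= tab$ci_hi))
  expect_true(all(tab$stratum_maf >= 0 & tab$stratum_maf <= 0.5 + 1e-9))
})

test_that("per-stratum ORs are recovered from data simulated at Table-like effects", {
  set.seed(51)
  ors <- c(ref = 0.58, ETS = 0.95, VIT = 0.69)
  cfg <- sim_config(n_trios = 5000, maf = 0.2,
                    exposures = c(ETS = 0.382, VIT = 0.150),
                    stratum_or = ors)
  td <- simulate_trios(cfg, seed = 52)
  fit <- trio_clogit(td, "snp1", c("ETS", "VIT"))
  se <- sqrt(diag(fit$cov))
  expect_lt(abs(fit$beta[["G"]] - log(0.58)), 3 * se[1])
  expect_lt(abs(fit$beta[["G:ETS"]] - log(0.95 / 0.58)), 3 * se[2])
  expect_lt(abs(fit$beta[["G:VIT"]] - log(0.69 / 0.58)), 3 * se[3])
})
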