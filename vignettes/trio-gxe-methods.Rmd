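---
title: "Methods: genotypic TDT and gene-environment interaction in case-parent trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotypic TDT and gene-environment interaction in case-parent trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(triogxe)
```

## The design and the likelihood

A case-parent trio consists of an affected child and both biological parents.
Given the parental genotypes at a biallelic marker, Mendelian inheritance
admits exactly four child genotypes (each parent transmits each of its two
alleles once); the three not received by the child are its pseudo-controls.
`enumerate_transmissions()` builds this multiset and `build_matched_set()`
removes one instance of the observed case genotype to obtain the 1:3 matched
set. A set in which all four genotypes coincide (both parents homozygous)
carries no information about genotype effects and is excluded from both the
fitted and the null likelihood.

`trio_clogit()` maximises the conditional logistic likelihood

$$\ell(\beta) = \sum_{\text{sets } s}\Big[\eta_{s,\text{case}} -
  \log \sum_{j=1}^{4} e^{\eta_{s,j}}\Big], \qquad
  \eta_{s,j} = \beta_g G_{s,j} + \sum_i \beta_{g\times e_i}\, G_{s,j} E_{s,i},$$

with $G$ the minor-allele dosage (0/1/2, additive coding) and $E_i$ binary
maternal exposures. The exposure vector is a property of the mother and is
therefore identical for the case and all three pseudo-controls; exposure main
effects cancel from the conditional likelihood and are reported as
*inestimable* if forced into the design — only genotype effects and their
modification by exposure are identified. Under this model $e^{\beta_g}$ is
the one-copy odds ratio for trios unexposed to every modelled factor,
$e^{\beta_g + \sum_i \beta_{g\times e_i} E_i}$ the one-copy OR in stratum
$E$, and the two-copy OR is its square (`stratum_or()`, delta-method CIs).

Inference: 1-df Wald tests per term or contrast (`wald_test()`), and the
likelihood-ratio test of the full model against the *empty* null
(`lrt()`), whose log-likelihood over $n$ informative sets is $n\log(1/4)$,
on $1+k$ df for $k$ interactions (2 df for one exposure, 3 for two, 5 for
four). The allelic TDT (`allelic_tdt()`) is provided for comparison:
transmissions versus non-transmissions of the minor allele from heterozygous
parents, $\chi^2 = (b-c)^2/(b+c)$, with a double-heterozygous mating and a
heterozygous child contributing one count to each arm. Multiplicity is
handled by Bonferroni correction, $\min(1, m\,p)$, with $m$ the number of
markers passing QC in the analysis subset (configurable, defaulting to the
number of markers actually tested in the run).

## Numerical choices

* **Optimiser.** Newton-Raphson from $\beta = 0$ with step-halving (the
  conditional log-likelihood is concave, so halving guarantees monotone
  ascent); convergence when the gradient max-norm drops below `1e-8`;
  at most 100 iterations. The covariance is the inverse observed information
  at the optimum.
* **Separation.** If any $|\beta|$ exceeds 15 during iteration (e.g. the
  minor allele is carried by every informative case), the fit is flagged,
  standard errors are reported as infinite and the marker is treated as
  non-estimable rather than returning a huge finite estimate.
* **Inestimability.** A singular information matrix at the starting point
  (all-zero interaction column, set-constant column such as an exposure main
  effect) raises an explicit error instead of dropping or aliasing the term.
* **Exact HWE test.** Conditional on the allele counts, heterozygote-count
  probabilities are computed by the standard adjacent-count ratio recurrence
  (stable for thousands of genotypes); the p-value sums all configurations
  whose probability does not exceed the observed one, with a relative tie
  tolerance of `1e-10`, no mid-p. This probability-ordering definition keeps
  the test valid (uniform or super-uniform under the null), which the suite
  checks by simulation.
* **MAF.** Computed on parents (founders) only; if the coded allele's
  frequency exceeds 0.5 the labels are swapped and all dosages re-coded; a
  tie at exactly 0.5 is broken to the lexicographically smaller allele label
  for determinism.
* **LD de-duplication.** $r^2$ is computed from EM-estimated haplotype
  frequencies on pairwise-complete parents (the double heterozygote is the
  only latent phase). Markers in perfect LD ($r^2 \ge 1 - 10^{-9}$) with an
  earlier otherwise-passing marker in map order are flagged; the first
  marker of each group is kept. Which member of a perfect-LD pair to keep is
  not identified by the data, so map order is adopted as a deterministic
  rule.
* **Missing data.** Per-SNP, per-model complete case: a trio enters the
  analysis of a SNP only with all three genotypes present, Mendelian
  consistency, and (for joint models) all modelled exposures observed, so
  the contributing $n$ varies across SNPs and models. Mendelian-inconsistent
  trio-SNP genotypes are additionally blanked before analysis and counted in
  the per-marker error rate — standard trio hygiene.
* **QC flags.** Defaults: MAF $\ge$ 1%, call rate $\ge$ 95% over all
  $3n$ members, Mendelian error rate $\le$ 5%, and HWE exact $p \ge
  0.05/m$ for an $m$-marker panel (0.05/122 $= 0.00041$ for a 122-SNV
  genotyped panel). A marker *fails* HWE QC when $p$ is *below* the
  threshold — the direction any QC screen requires.

## The synthetic-trio generator

`sim_config()`/`simulate_trios()` generate data with exactly the structure
the estimator assumes: parents drawn Binomial(2, MAF) (Hardy-Weinberg,
independent mates), one uniformly chosen allele transmitted per parent, the
maternal exposure combination drawn from a joint distribution (independent
marginals by default, or an explicit combination table), and case
ascertainment by rejection sampling with probability
$\exp(\eta - \eta_{\max})$, $\eta = \beta_g G_{\text{child}} + \sum_i
\beta_{g\times e_i} G_{\text{child}} E_i$. This embodies the rare-disease
multiplicative risk model — the conditional-logistic odds ratios equal the
simulated relative risks — without committing to a baseline penetrance.
Per-stratum OR input (`stratum_or =` reference stratum plus single-exposure
strata) is converted to $\beta_g = \log \mathrm{OR}_{\text{ref}}$,
$\beta_{g\times e_i} = \log(\mathrm{OR}_i/\mathrm{OR}_{\text{ref}})$; with
two or more exposures the double-exposed stratum is implied by the model
(no exposure-by-exposure interaction term), so only the reference and
single-exposure strata can be matched exactly.

Defaults are fixed at the conditions of the motivating consortium analysis:
746 trios, MAF 0.20, maternal ETS 38.2% and multivitamin use 15.0% drawn
independently, and one-copy stratum ORs 0.58 (neither), 0.95 (ETS only),
0.69 (VIT only). `inject_missing()` (per member-genotype) and
`inject_mendel_errors()` (child dosage replaced by a uniformly drawn
*different* dosage) exercise the QC path.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: linkage disequilibrium between simulated markers,
population structure and assortative mating, genotyping-error modes that are
correlated within families or plates, exposure misclassification, parental
imprinting or maternal-genotype effects, and X-linked transmission. Results
on real panels additionally depend on QC decisions that the simulated data
never trigger.

## Power estimation

`estimate_power()` replaces analytic power formulas with simulation: for
each replicate it draws an ascertained dataset from a `sim_config()`, runs
the requested test (gTDT Wald, the $(1+k)$-df joint LRT — with
`exposures = character(0)` this is the 1-df gTDT LRT — or a stratum Wald
contrast) and reports the rejection fraction with its binomial Monte-Carlo
standard error. Non-estimable replicates count as non-rejections and are
reported separately. For stratum power two modes are provided, because an
analytic tool's exact conditioning is not identified: `"full"` simulates the
whole design and tests the stratum contrast under the joint model;
`"subgroup"` simulates only trios from that stratum (its OR becomes the
per-allele OR) and applies the gTDT. Neither is asserted as canonical.

For small-n, small-alpha settings the Wald and LRT versions of the gTDT
differ noticeably (the Wald test is conservative there); analytic power
calculators built on the likelihood-ratio non-centrality correspond to the
LRT mode, which is what the acceptance script uses for its power anchor
(10,000 replicates of 89 trios at MAF 0.188, per-allele OR 0.72,
$\alpha = 0.05/117$).

## Problem sizes used by the test suite

The suite's simulation-based checks use: 2,000 replicates of 500 trios for
the null calibration of the gTDT Wald and 2-/3-df LRTs (size within 3
Monte-Carlo SEs of 0.05); 300 replicates of 2,000 trios for 95% CI coverage
of $(\beta_g, \beta_{g\times \mathrm{ETS}}) = (\log 0.58, \log 1.6)$ at
exposure rate 0.4; 10,000 replicates for the power anchor; 5,000 trios for
stratum-OR recovery; and 50,000 trios for the closed-form transmission
fraction $0.58/1.58$ under $\beta_g = \log 0.58$. Exact components (HWE
enumeration up to 20 genotypes, the $T/U$ closed form, Bonferroni
arithmetic) are checked against independent oracles at tolerances of
$10^{-12}$ and $10^{-6}$.

## Known limitations

Autosomal biallelic markers and exact trios only (no larger pedigrees, no
phased haplotypes, no VCF input); additive genotype coding only; Wald-type
confidence intervals (no profile or exact conditional inference); binary
exposures only; Bonferroni (not FDR) multiplicity control. The per-stratum
MAF in `stratum_table()` is computed from the parents of the trios in the
stratum — a reporting convention, since founders are the natural frequency
reference in this design.
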