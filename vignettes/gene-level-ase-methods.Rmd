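---
title: "Detecting static and condition-dependent allele-specific expression in genes"
author: "geneAse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting static and condition-dependent allele-specific expression in genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneAse)
```

## The problem

Allele-specific expression (ASE) is an imbalance in transcript abundance
between the two alleles of a heterozygous locus within one individual.
Because both alleles share a cellular environment and trans-acting
factors, allelic imbalance is a sensitive readout of cis-regulatory
variation. Two flavours are distinguished here:

* **static ASE** — imbalance observed in a single sample under one
  condition; the per-variant data are a 2×1 table of reference and
  alternative read counts.
* **individual condition-dependent ASE (icd-ASE)** — a *change* in the
  imbalance between two conditions (e.g. an inflammatory stimulus
  versus untreated) within the same individual; the data are a 2×2
  table of counts per condition.

RNA-seq read counts at heterozygous SNVs carry this signal, but three
obstacles complicate gene-level inference: haplotype phase is usually
unknown, so per-variant effects cannot simply be summed with sign;
counts are overdispersed relative to a binomial because of technical
variability and mapping bias; and genes carry variable numbers of
variants at variable depths, so p-values must come from a null model
that respects the observed design.

## The model

### Variant null model

Allele counts at a heterozygous site are modelled as beta-binomial,
\deqn{alt \sim BB(n, p^0, \rho^0),}
parameterized by the mean allele fraction \eqn{p^0} and the intraclass
correlation \eqn{\rho^0} (shapes \eqn{\alpha = p^0(1-\rho)/\rho},
\eqn{\beta = (1-p^0)(1-\rho)/\rho}); \eqn{\rho = 0} is an ordinary
binomial. The null parameters are estimated by maximum likelihood from
DNA (genomic) allele counts at heterozygous sites, where a 50:50 ratio
is expected and any residual spread is technical
(`fitBetaBinomNull()`). The likelihood is maximised on the
\eqn{(\mathrm{logit}\,p^0, \mathrm{logit}\,\rho^0)} scale from a
method-of-moments start, which keeps both parameters in range without
explicit constraints; the \eqn{\rho = 0} boundary (pooled binomial
MLE) is checked and returned when it dominates, so degenerate inputs
(e.g. perfectly balanced counts) land exactly on the binomial rather
than on a numerically tiny \eqn{\rho}. One global null is fitted for
the dataset; per-sample nulls can be obtained by subsetting the DNA
input.

### Per-variant statistics

Tables containing a zero first receive a pseudo-count of 1 *in every
cell*, keeping odds finite while leaving zero-free tables untouched.
The per-variant statistic is |effect| / se:

* static: effect = \eqn{\ln(alt/ref)}, the log-odds of the allele
  fraction. The standard error derives from the Wilson score interval:
  the 95% interval for the fraction is computed, both endpoints are
  mapped to the log-odds scale, and the se is half the resulting width
  divided by \eqn{z_{0.975}}. Unlike the delta-method
  \eqn{\sqrt{1/alt + 1/ref}} (available via `seMethod = "delta"`), the
  Wilson construction stays finite and well-behaved at extreme
  fractions even before pseudo-counts.
* icd: effect = \eqn{\ln} odds-ratio of the 2×2 table (the log
  stabilises the variance), with Woolf's se
  \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}.

The absolute value makes the statistic phase-free: a gene with two
variants leaning opposite ways (which may be genuine anti-phased
regulation or just unknown phase) accumulates evidence rather than
cancelling. Effects are reported to users on the log2 scale
(`staticEffectSize()` is the allelic-fraction deviation \eqn{|p-0.5|};
`icdEffectSize()` the log2 odds-ratio); the internal statistic uses
natural logs, where |effect|/se is base-invariant as long as effect
and se share a scale.

### Gene statistic and resampled null

The k per-variant statistics of a gene are combined by Stouffer's
method, \eqn{G = \sum_j t_j / \sqrt{k}}. Because the null distribution
of \eqn{G} depends on k and on the read depths, it is obtained by
resampling: each of N replicates draws k pseudo-variants with depths
sampled from the pooled empirical depth distribution of all analysed
variants (per condition for icd), counts from the fitted null,
pseudo-counts and statistics exactly as for observed data, and
Stouffer-combines them. One null distribution per distinct k is built
and shared across genes and samples — O(k) distributions instead of
O(genes) — with genes beyond `kCap` (default 100) sharing a single
aggregated null whose k is resampled from the observed over-cap
counts.

**The icd null couples the two conditions.** A variant's baseline
imbalance — static ASE, reference-mapping bias, local technical
effects — is a property of the variant, present in both conditions;
the icd null hypothesis is that the imbalance does not *change*.
Accordingly a null 2×2 replicate draws one latent allele fraction
\eqn{\theta \sim Beta(\alpha, \beta)} from the fitted null and then an
independent binomial count per condition around that shared
\eqn{\theta}. (Marginally each condition is exactly beta-binomial; at
\eqn{\rho^0 = 0} this coincides with drawing the conditions
independently.) Had the two conditions been resampled independently,
the latent fraction would contribute twice to the null log-odds-ratio
spread and, at the DNA-estimated noise level, the test would have
essentially no power at any odds-ratio — inconsistent both with the
method's robustness to mapping bias (which rests on the within-variant
comparison) and with the observation that noise matters mostly for
small odds-ratios. The condition-dependent simulator applies the same
logic, multiplying the latent odds by \eqn{OR^s}.

### Empirical p-values

With observed and resampled statistics exchangeable under the null,
the add-one empirical p-value \eqn{(1 + \#\{null \ge obs\})/(N+1)} is
valid but conservative wherever the statistic has atoms (fixed depths,
small k make ties common). The default is therefore the randomized
variant
\deqn{p = \frac{\#\{null > obs\} + U\,(1 + \#\{null = obs\})}{N + 1},
\quad U \sim U(0,1),}
which is *exactly* uniform under the null — the test is neither
optimistic nor conservative — and reproducible under `set.seed()`.
The deterministic conservative rule remains available
(`ties = "conservative"`); it guarantees \eqn{p \ge 1/(N+1)} and may
be preferred when bitwise-stable p-values across reruns with
different seeds matter more than exact calibration. N defaults to
\eqn{10^5}; the examples and tests here use \eqn{10^3}–\eqn{10^4} to
keep runtimes short, at the cost of a coarser attainable minimum
p-value.

### Filters, gating, multiple testing

* variants need depth ≥ 10 in a sample (icd: in each condition), and
  an optional summed-conditions filter (≥ 100 by convention) focuses
  the variant-level icd test where it has power;
* genes need ≥ 2 dbSNP variants by default (`minVariants = 1` tests
  single-variant genes);
* for condition-dependent analysis, genes may be gated on weak static
  evidence — nominal static gene p ≤ 0.2 in either condition
  (`cdGate()`) — so static ASE informs without being required;
* BH adjustment is applied within each sample (static) or individual
  (icd), matching per-individual reporting.

### Meta-analysis

Evidence for a gene across individuals (whose genotypes, and hence
testable genes, differ) is combined by Fisher's method over the
samples where the gene was testable: \eqn{\chi^2 = -2\sum \ln p_i}
against \eqn{\chi^2_{2m}}. The degrees of freedom are 2m, not a fixed
2: with m = 1 this reduces to the identity \eqn{p_{meta} = p}, which a
fixed-df variant would violate. The reported significant set is the
union of meta-significant genes and genes significant in any single
sample, flagged by provenance.

## The simulator and what it does (not) emulate

`simScenario()`/`simulateAseData()` generate allele counts at the
count level:

* DNA sites: depth from a pool, alt count beta-binomial — the input
  for null fitting;
* static genes: one random sign s per gene (phase is unknown but
  consistent within a gene), alt counts \eqn{BB(d, 0.5 + s e, \rho)}
  with effect \eqn{e \in [0, 0.5)};
* icd genes: latent \eqn{\theta_U} per variant from the
  \eqn{\rho}-noise Beta, \eqn{odds(\theta_T) = OR^s\,odds(\theta_U)},
  binomial counts per condition.

Default study conditions follow the evaluation design: 2000 genes per
calibration cell; power experiments with 500 alternative + 500 null
genes, k = 2 (matching the ≥ 2-variant pre-filter), per-condition
per-variant depths of 10/50/100, odds-ratios up to 16, overdispersion
0.22 (the DNA-estimated noise level), BH FDR 5%; effect grids 0.05–0.3
(static) and 1.1–16 (icd); variants per gene uniform on {1,…,5} where
not fixed. The mapping-bias robustness experiment perturbs counts by
`ref' = round(1.1·ref)`, `alt' = round(0.9·alt)` (fraction 0.1 by
default).

The simulator works at the level of counts. It does **not** emulate
read-level artefacts: reads spanning multiple variants, remapping
losses, alignment-induced reference bias beyond the supplied
per-variant null ratio, feature-overlap ambiguity, or library-level
correlation between variants. Count-level FDR estimates
(`runSnvFdr()`) are therefore optimistic relative to read-level
simulations, and passing calibration here demonstrates correctness of
the statistical machinery, not immunity to upstream alignment
artefacts on real data.

## Numerical and design notes

* Two-sided exact tests (variant-level binomial and Fisher) use the
  minimum-likelihood rule, as in `binom.test()`/`fisher.test()`, which
  back the implementation; the suite verifies both against exhaustive
  enumeration.
* The sustained-effect threshold percentile uses type-7 linear
  interpolation (R's default), configurable through the `percentile`
  argument.
* The within-gene SNR uses the sample (n−1) standard deviation and
  returns `Inf` for zero spread with positive mean.
* Result tables are written deterministically (fixed column order,
  6 significant digits, sorted by adjusted p then gene id).
* All randomness flows through R's global RNG; a single `set.seed()`
  call makes a whole pipeline run reproducible.

## Limitations

Gene-level detection does not identify *which* haplo-isoform drives
the signal (phasing would be required), and transcript-level analysis
is supported only implicitly by supplying transcript ids in the
`gene_id` column. The per-variant mapping-bias null ratio is consumed
as input, not generated. The ≥ 2-variant default trades coverage for
specificity; single-variant genes are testable but rest entirely on
one site's counts.

## A short worked run

```{r worked, eval = FALSE}
counts <- readAseCounts(system.file("extdata/synthetic_icd_counts.tsv",
                                    package = "geneAse"), mode = "icd")
dna <- readDnaCounts(system.file("extdata/synthetic_dna_counts.tsv",
                                 package = "geneAse"))
null <- fitBetaBinomNull(dna[!dna$excluded, ], minDepth = 0)
set.seed(1)
res <- runGeneAse(counts, null, nSamples = 1e4)
head(geneResults(res))
```

The shipped data are synthetic (four genes carry a planted odds-ratio-8
condition effect, named `ASEG1`–`ASEG4`); the README shows the exact
output of this run.
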