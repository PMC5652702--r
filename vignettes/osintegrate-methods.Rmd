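---
title: "Methods: multi-omics integration for extreme-phenotype osteosarcomas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics integration for extreme-phenotype osteosarcomas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osintegrate)
```

# The problem

Osteosarcoma cohorts large enough for conventional discovery statistics do
not exist: the disease is rare, and the clinically interesting contrast --
tumors that kill through refractory metastasis ("aggressive") versus tumors
cured by standard therapy ("curable") -- restricts analysis to a handful of
phenotypic extreme outliers per species. `osintegrate` implements, as a
reusable and fully tested pipeline, the integration strategy appropriate to
that regime: per-cohort differential expression with a deliberately
conservative decision rule, gene-level somatic mutation evidence, in vitro
drug-screen evidence (IC50s, synergy, kinase target deconvolution), and a
final hypergeometric pathway over-representation step that only retains
pathways containing the target of a drug shown to work in vitro.

Every stage has a synthetic-data generator counterpart with complete ground
truth, so each statistical claim the package makes is backed by a test that
knows the right answer.

# Differential expression

## Model

Counts for gene $g$ in sample $j$ are modeled as negative binomial with
mean $\mu_{gj}$ and dispersion $\phi$, using the RNA-seq convention
$\mathrm{Var} = \mu + \phi\mu^2$ ($\phi = 0$ is the Poisson limit).

**Normalization.** Median-of-ratios size factors are computed against the
geometric-mean pseudo-reference (genes observed in every sample), rescaled
to geometric mean 1. Effective library sizes put these factors back on the
depth scale by multiplying by the geometric mean of the column sums. Note
that multiplying depth-inclusive median-of-ratios factors by each sample's
*own* column sum would count depth twice; the implementation avoids that
while still satisfying the usual sanity cases (identical columns give
factors of 1; a doubled column doubles its factor).

**Quantile adjustment.** The exact test and the conditional dispersion
likelihood require equal library sizes. Counts are scaled to the common
(geometric-mean) effective size and rounded ("pseudo-counts"). This is an
approximation to full quantile adjustment; the recovery tolerances in the
test suite absorb it.

**Dispersion.** The common dispersion maximizes the conditional NB
log-likelihood given per-group totals, summed over genes; groups with fewer
than two replicates carry no information (a design with no replicated group
at all raises an error instructing the user to supply a fixed value -- the
situation that arises when the comparator is a single pooled normal-bone
library). Tagwise dispersions maximize the per-gene conditional likelihood
plus `shrinkage_weight` (default 10, invented and configurable) pseudo-genes
of the cohort-average likelihood; an infinite weight returns the common
value exactly. Optimization is on a log grid with quadratic interpolation;
estimates below $2\times10^{-6}$ are truncated to 0.

**Exact test.** The sum of $s$ i.i.d. NB$(\mu, \phi)$ variables is
NB$(s\mu, \phi/s)$, so conditional on a gene's total the split between the
two groups is free of $\mu$ (negative hypergeometric; binomial at
$\phi = 0$). Two-sided p-values sum the probabilities of all splits no more
likely than the one observed (minimum-likelihood method, with a $10^{-10}$
relative tolerance for ties), capped at 1. A gene with zero total has
$p = 1$ and log2FC 0. Fold changes are aggressive over comparator on
normalized group means with a 0.5 pseudo-count per group.

**Decision rule.** Both the common-dispersion and tagwise-dispersion
p-vectors are BH-adjusted; a gene is significant when *both* FDRs are below
$\alpha = 0.05$. If that yields zero genes the entire run -- never
individual genes -- switches to the fallback rule, both unadjusted p-values
below $\alpha$, and records `mode_used = "unadjusted_fallback"`. This
all-or-nothing semantics mirrors how small extreme-outlier cohorts are
analyzed in practice: the conservative rule is preferred, and the fallback
is an explicitly labeled concession to tiny n.

## What the tests establish

The exact test is verified against a brute-force enumeration oracle (all
splits of totals up to 50, dispersions 0, 0.1, 0.5) that computes
probabilities from `dnbinom` products at an arbitrary mean -- an independent
route. Calibration is property-tested: on null cohorts ($\phi = 0.2$,
5 vs 5, 2000 genes, 20 seeds) the pooled rejection rate at $p < 0.05$ must
lie in the 99% binomial band around 0.05 (measured: 0.0495), and with a
4-fold effect in 5% of genes the dual-FDR rule recovers $\ge 80\%$ of true
positives at observed FDR $\le 0.10$ (measured: 95% sensitivity, 4% FDR).

# Mutation evidence

Variants arrive already impact-annotated (high, moderate, low, modifier --
the SnpEff vocabulary); the package never predicts impact. Aggregation
keeps per-impact multiplicity (a gene may carry several variants of
different impacts) and defines `max_impact` under the explicit severity
ordering high > moderate > low > modifier -- the ordering is asserted in
code because upstream annotation tools imply but do not state it.

Set algebra across specimens filters to `max_impact >=` a configurable
threshold (default: all classes, since modifier clusters are biologically
reportable) and computes every Venn region plus phenotype-level sets. The
default membership mode requires a gene to be mutated in *every* specimen
of a phenotype ("all"), matching how "mutated in both aggressive tumors but
not the curable one" statements are made; an "any" mode is available.
Family clustering strips a trailing numeric suffix (optionally followed by
one letter) from symbols, so NBPF10 and NBPF1 collapse to NBPF; an explicit
map overrides the heuristic, and unmapped genes form singleton families.

# Drug screen

**4PL fits.** Viability against log10 dose is fit by least squares to
$v(c) = b + (t - b) / (1 + 10^{h(\log_{10} c - \log_{10} \mathrm{IC}_{50})})$
with a deterministic multi-start grid (Hill slope in $\pm\{0.5, 1, 2\}$,
midpoint at the tested-dose quartiles; the four best starts are polished by
Nelder-Mead and then BFGS). Fits are normalized so top $\ge$ bottom. The
IC50 is the curve midpoint (relative EC50). It is reported *censored*
("greater than the top tested dose", mirroring screen-table convention)
when the fitted midpoint exceeds the highest tested concentration, the
curve does not decrease, or the fitted dynamic range is below 0.05
viability units (flat data, where the midpoint is unidentifiable). With
noise, censoring is necessarily a property of the *fitted* midpoint: a true
IC50 just above the top dose can legitimately fit below it.

**Efficacy.** A compound is effective against a culture when the fit
converged, the IC50 is uncensored and below 1000 nM (1 uM), and the curve
$R^2$ exceeds 0.6 -- both thresholds configurable, both taken from standard
screen-reporting practice. The recorded reason names the first failing
condition.

**Uncertainty.** `ic50_bootstrap_ci()` uses a parametric residual bootstrap
(refit from the original solution on curve + Gaussian residual noise). Case
resampling was measured to under-cover (0.80 at nominal 0.95) with only
three replicates per dose; the parametric variant covers at 0.94.

**Median effect and combination index.** The median-effect model
$f_a/f_u = (D/D_m)^m$ is fit by linear regression of
$\log_{10}(f_a/(1-f_a))$ on $\log_{10} D$ ($f_a = 1 -$ viability; points at
$f_a \in \{0, 1\}$ are dropped with a warning, a zero slope is an error).
The combination index for doses $(d_1, d_2)$ at combined effect $f_a$ is
$\mathrm{CI} = d_1/D_{x1} + d_2/D_{x2}$ with
$D_{xi} = D_{m,i}(f_a/(1-f_a))^{1/m_i}$; synergy is called at
$\mathrm{CI} \le 0.7$ (the screen's reporting threshold, configurable).
Fixed-ratio designs only; self-combination at any ratio gives
$\mathrm{CI} = 1$ to numerical tolerance, which the suite asserts.

**Target deconvolution.** A compound hits a kinase when its panel
inhibition score reaches 50 (invented, configurable; panel units are left
to the data). Each kinase's count of effective compounds hitting it is
scored by the hypergeometric upper tail against drawing the effective set
at random from the panel; ordering is count desc, p asc, name asc. A
kinase hit by the whole panel correctly scores $p = 1$ (uninformative
recurrence).

# Pathway integration

The evidence set for a specimen is the **union** (default; intersection by
flag) of significant-DE genes and genes mutated at impact $\ge$ moderate.
"Aberrant" genes (fold change above 2 but not significant) never enter the
test -- they exist for node annotation only, as does modifier-impact
mutation multiplicity. Each pathway is scored by the hypergeometric upper
tail of its overlap with the evidence against the background universe.

The universe is the single most consequential unstated choice in this kind
of analysis; the default is the union of the count-matrix genes and all
pathway genes, and it is prominently configurable. Evidence genes outside
the universe are dropped and reported.

Prioritization keeps pathways with unadjusted $p < 0.05$ (strict; a
BH column is emitted for transparency but never filters) **and** at least
one gene that is the target of an effective compound -- the druggability
filter. Ranking is dense in the deterministic order (p, pathway size, id).
Node annotation categorizes each pathway gene with precedence
drug_target > mutated > de_under/de_over > aberrant > none, and attaches
copy-number direction when a CNV table is supplied (computing CNV calls is
out of scope).

# The synthetic cohort

The generator states one world and the tests live in it:

* 2000 genes, 5 aggressive vs 5 curable samples, baseline mean 100,
  NB dispersion 0.2; 5% of genes truly DE at $|\log_2 \mathrm{FC}| = 2$
  (half up, half down); library-size factors uniform on [0.5, 1.5] so
  normalization is always exercised.
* Background somatic variants: Poisson(50) per specimen, placed uniformly
  (so multiplicity arises naturally), impact prior
  (0.02, 0.18, 0.30, 0.50) over high/moderate/low/modifier. The
  literature gives no burden rates for this setting; these are invented
  once, documented, configurable, and not revisited.
* 50 decoy pathways (sizes 10-40) plus one spiked driver pathway of 20
  genes: one slot for the driver kinase, 80% of the rest true-DE or
  driver-mutated genes.
* 50 compounds against 30 kinases (kinases are genes of the universe);
  10% of compounds effective with IC50 log-uniform in 10-500 nM, the rest
  10-100 uM; every effective compound strongly inhibits the driver kinase.
  Four 10-fold-spaced concentrations (1, 10, 100, 1000 nM) in triplicate
  -- the standard screen design; the sources state four concentrations but
  not their values. Viability noise is multiplicative Gaussian at 5% CV.
* One master seed fans out deterministically to per-stage child seeds, so
  any stage can be regenerated alone, and fixed seeds give bit-identical
  outputs.

What the generator does **not** emulate: gene-level mean heterogeneity and
gene-gene correlation, batch effects, impact-dependent mutation hotspots,
plate/edge effects in screens, and pathway overlap structure beyond random
decoys. A green end-to-end test therefore establishes that the machinery
recovers a planted signal under the stated noise model -- not that the
thresholds are optimal for any particular real cohort.

# Numerical choices

* Dispersion optimization domain $\phi \in [10^{-6}, 10]$ on the log scale;
  31-point tagwise grid with quadratic interpolation.
* Exact-test tie tolerance $10^{-10}$ relative; BH ties are handled by the
  standard step-up procedure (original order preserved on output).
* 4PL multi-start is fully deterministic; best residual sum of squares
  wins. $R^2$ is clamped to [0, 1] and set to 0 for zero-variance data.
* Degenerate inputs raise errors early: all-zero count matrices,
  single-replicate-everywhere designs, fewer than two distinct
  concentrations, zero median-effect slopes, combination fractions outside
  (0, 1), pathway sizes exceeding the universe.

# Known limitations

* Two-group designs only; no covariates, batch correction, or multi-factor
  GLMs -- the conditional exact test is the point, and it does not extend.
* The tagwise shrinkage weight is a fixed pseudo-gene count, not estimated
  from the data.
* Non-constant-ratio combination designs and Bliss/Loewe alternatives are
  out of scope.
* Gene identifiers are harmonized strings; no ortholog mapping across
  species is attempted.
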