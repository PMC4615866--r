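---
title: "Sex-methylation association analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-methylation association analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smapipe)
```

# The scientific problem

Autosomal DNA methylation differs systematically between men and women, and
ignoring that difference confounds epigenome-wide association studies
(EWAS). `smapipe` implements a complete discovery–replication workflow for
quantifying these differences from Illumina 450k-style beta-value arrays:
probe quality control against sex-chromosome cross-hybridization,
covariate-adjusted association testing, random-effects meta-analysis across
replication cohorts, genomic-context and gene-set enrichment, and a cis
methylation–expression linkage model. Because cohort-scale human methylation
data cannot be redistributed, the package ships a synthetic-data generator
that reproduces the statistical structure the analysis assumes, with a
ground-truth table, so every stage is testable end to end.

# The association model

The sex–methylation association (SMA) at a CpG is the Pearson correlation
between sex and the covariate-residualized methylation beta-value. With
$y_{pj}$ the beta-value of probe $p$ in sample $j$ and $X$ a covariate
design (age, BMI, smoking, alcohol, lipids, leukocyte composition, plate
dummies, clinical covariates — everything except sex),

$$e_{p} = y_{p} - X\hat\gamma_p, \qquad
  r_p = \mathrm{cor}(e_p, \mathrm{sex}), \qquad
  t_p = r_p\sqrt{\tfrac{n-2}{1-r_p^2}},$$

with a two-sided p-value from the $t_{n-2}$ reference. Sex is coded 0 =
female, 1 = male, so $r_p > 0$ means hypermethylated in males; this
convention is stated in all outputs. Sex itself is deliberately *not*
residualized: the design matrix excludes it, so $r_p$ equals the partial
correlation scaled by $\mathrm{sd}(e_{\mathrm{sex}})/\mathrm{sd}(\mathrm{sex})$
— a conservative (attenuating) choice. Missing betas are handled by
per-probe case-wise deletion with the per-probe $n$ recorded, because that
$n$ sets the meta-analysis variance downstream.

Family-wise error is controlled by Bonferroni: the discovery threshold is
$\alpha/m$ with $m$ the number of probes actually analyzed (degenerate
probes excluded), never a pre-rounded constant.

# Cross-hybridization screen

Probes whose 50-mer sequence aligns well to the sex chromosomes measure a
mixture of autosomal and allosomal methylation, and the allosomal part
differs between sexes — a classic source of false sex associations. The
cross-hybridization value $h$ of a probe is the number of matching bases of
its best alignment to the allosome references. The default scorer is an
exhaustive ungapped offset scan over both probe orientations — exact,
deterministic and oracle-checkable; a gapped Smith–Waterman match count is
available behind a flag for users who prefer a more permissive notion of
"best alignment" (the literature does not pin down one choice, so both are
exposed rather than guessed). Probes with $h > 40$ are excluded — strictly
greater, so $h = 40$ survives. After filtering, the association between
$|r_p|$ and $h_p$ is tested by a one-sided permutation test (Spearman
statistic on $|r|$, robust to the sign convention; Pearson optional) with
the add-one empirical estimator $p = (1 + \#\{\text{perm} \ge
\text{obs}\})/(B+1)$ over $B = 3000$ permutations, so $p$ can never be
exactly zero.

# Replication meta-analysis

Per-cohort correlations are pooled on the Fisher-z scale with
DerSimonian–Laird random effects — the default of the classical `metacor`
routine: $z_i = \mathrm{atanh}(r_i)$, $v_i = 1/(n_i-3)$,
$Q = \sum w_i (z_i - \bar z_{FE})^2$,
$\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w - \sum w^2/\sum w)\}$,
random-effects weights $1/(v_i + \hat\tau^2)$, with a two-sided normal
p-value on the z scale and the pooled correlation
$\hat\theta = \tanh(\bar z)$. Probes missing from any replication cohort
are excluded and counted, so the replication Bonferroni denominator is the
number of probes analyzed in *all* replication cohorts. Two consistency
checks accompany replication: a one-sided exact binomial test of effect
directions agreeing between discovery and replication (computed in log
space; even 700/700 consistent does not underflow), and the Pearson
correlation of per-cohort effect estimates over the probes taken to
replication.

# Enrichment machinery

**CGI context.** Because neighbouring CpGs are correlated, the probe set is
first thinned by independent Bernoulli selection with probability 0.2. The
shore test is framed as a 2x2 Pearson chi-square without continuity
correction — significant vs not, CGI shore (north + south) vs all other
regions — matching the scientific question of shore *over*representation;
a shores-excluded 2x3 contingency test asks whether any signal remains in
island/shelf/open-sea, and a full 2x4 omnibus is available via a flag.
On published per-region counts the 2x2 framing gives $\chi^2 \approx 41.2$,
$p \approx 10^{-10}$; printed values smaller than that are not reproducible
under any standard framing we implemented, so the package reports what the
formula gives.

**Imprinted genes.** The probe-level table is reduced to the best
(minimum-p) CpG per gene, ties broken lexicographically by probe id. The
per-gene $-\log_{10} p$ is Spearman-correlated (midranks) with a binary
imprinted flag; positive rho means imprinted genes carry more significant
associations. The p-value uses the $t$ approximation, two-sided by default
(sidedness is an argument). A hypergeometric tail on significant genes
complements the rank test.

**Probe-count bias (PWF + Wallenius).** Genes covered by more probes get
more chances to contain a significant CpG. The probability weighting
function (PWF) estimates P(gene significant | probe count) by isotonic
regression on equal-count bins, rescaled so the mean weight equals the
observed significant fraction — deterministic and monotone by construction,
unlike a spline. Category enrichment then uses the Wallenius noncentral
hypergeometric upper tail with odds equal to the ratio of mean-weight odds
inside vs outside the category. The Wallenius distribution is computed by
an exact dynamic program over the sequential urn draws (every intermediate
value is a probability, so no overflow at any size); the classical integral
representation is used only as an independent test oracle. A sampling
alternative draws significant-gene sets without replacement with urn
weights $w/(1-w)$ — the odds implied by the PWF — and must agree with the
analytic tail within Monte-Carlo error; with a constant PWF both reduce to
the central hypergeometric test.

# Expression linkage

Replicated CpGs are paired with genes on the same chromosome within 1 Mb
(inclusive; distance 0 inside the gene body, otherwise the smaller distance
to either gene end, strand ignored), and each pair is fit by OLS:

$$\text{expression} = b_0 + b_1\,\text{sex} + b_2\,\text{methylation}
  + \text{covariates} + e.$$

The Bonferroni denominator is the total pair count. A pair is reported
significant when **both** $b_1$ and $b_2$ pass (the default, since the
scientific claim is association with both sex and methylation); rules
`methylation_only` and `either` are available because published reports of
this analysis are ambiguous about which coefficient gated significance.

# The synthetic-data generator

`generate_cohorts()` emulates the structure the analysis assumes, never raw
array chemistry:

* **Betas** are inverse-logits of probe baseline + covariate effects + sex
  effect x sex + block-correlated Gaussian noise, hence strictly in (0,1).
  Baselines come from a bimodal mixture (modes ±1.8 on the logit scale,
  plus a 10% intermediate fraction), the typical hypo/hyper-methylated
  shape of array data.
* **Effect sizes** are specified as target correlations $|r| \sim
  U(0.2, 0.5)$ and converted to logit shifts by the delta method
  $d = \frac{r}{\sqrt{1-r^2}}\,\frac{\sigma}{s}$ ($s = 0.5$ for balanced
  sexes, $\sigma$ = 0.5 the logit noise sd), with a second-order curvature
  correction $d \cdot \sqrt{1 + (1-2p_0)^2\,\mathrm{var}(\mathrm{logit})/2}$
  that compensates the attenuation of the inverse-logit at extreme
  baselines $p_0$. Without the correction realized correlations fall ~5%
  short of target; with it the residual bias is below 0.02.
* **Placement bias**: planted effects choose probes with 3-fold odds in CGI
  shores and in the 50 imprinted genes, giving the enrichment tests a
  known signal. Genes are contiguous probe segments of Poisson-distributed
  size, producing the probe-count-per-gene bias the PWF corrects.
* **Contamination**: 100 probes mix an allosomal component
  $(1-\lambda)\,\beta_{\mathrm{auto}} + \lambda\,\beta_{\mathrm{allo}}$
  with $\lambda = 0.7$ and a between-sex logit shift of 3; their sequences
  are copied from the decoy allosome FASTA with 5 substitutions, so
  $h \ge 45$ and the screen can find them. (With 10 or more substitutions
  $h$ would reach the strictly-greater boundary at 40 and survive — the
  boundary semantics are deliberate.)
* **Cohorts**: three cohorts of 300 samples; per-cohort multiplicative
  effect jitter (sd 0.15) gives the meta-analysis a nonzero-$\tau^2$ regime
  to estimate. Covariates mimic an adult European population cohort (age
  ~ N(60, 9), BMI ~ N(28, 4.8), smoking 15%, lipids, leukocyte fractions
  with deconvolution-style noise, 96-well plate factors).
* **Expression**: 50 of 500 genes are cis-linked to planted CpGs
  ($b_1 = -0.5$, $b_2 = -0.8$, noise sd 0.5 — expression higher with female
  sex and lower methylation under male = 1 coding); decoy genes sit just
  beyond the 1 Mb window to exercise the boundary.

What the generator does **not** emulate: Infinium type I/II chemistry and
its distribution shift, batch intensity effects, detection p-values,
genuine linkage disequilibrium of methylation, age- or cell-type-specific
effect heterogeneity. Passing recovery tests therefore demonstrates that
the statistical machinery is correct under its stated assumptions, not that
those assumptions hold in any particular real cohort.

# Numerical choices and degenerate inputs

* Correlations at machine |r| = 1 produce the smallest positive double
  rather than p = 0; constant probes are flagged degenerate and excluded
  from multiplicity counts.
* Rank-deficient designs fail loudly, naming the collinear columns.
* The DL estimator truncates $\hat\tau^2$ at 0; a single study pools to
  itself exactly (atanh/tanh round trip to 1e-12).
* Hypergeometric tails go through `phyper`'s log-gamma machinery; both
  P(X >= k) and P(X > k) conventions are exposed because published overlap
  p-values do not disambiguate them.
* Ties in best-CpG-per-gene break lexicographically by probe id — stable
  across platforms.
* The empirical permutation p uses the add-one estimator; `n_perm = 0` is
  an error, constant inputs return p = 1 with a degenerate flag.

# Problem sizes used in the shipped tests

The test suite and acceptance script exercise the pipeline at 20,000 probes
x 3 cohorts x 300 samples (recovery), 10,000 probes x 200 samples (null
calibration), and 1,500–2,500 probes for end-to-end pipeline runs. These
sizes give the calibration and recovery checks binomial/Monte-Carlo error
well inside their acceptance bands while a full run of everything stays in
the minutes range on a single core; they are study-shaped, not
chip-sized — a real 450k analysis at 450k probes uses the identical code
paths, only larger inputs.

# Known limitations

* The cross-hybridization scan scores decoy-scale references exactly; for
  real chrX/chrY one would precompute $h$ once with a genome aligner and
  feed the values in — the filtering, permutation and accounting logic is
  unchanged.
* The PWF's isotonic-on-bins fit is coarser than a spline for very uneven
  probe-count distributions; bins are equal-count to keep each estimate
  stable.
* The weighted category test conditions on the observed number of
  significant genes; it does not propagate ontology graph structure
  (parent-term inheritance is out of scope).
* Cell-type deconvolution is consumed as covariates, never estimated;
  normalization (BMIQ-style) is assumed done upstream.

# A minimal run

```{r, eval = FALSE}
res <- simulate_and_run(seed = 7, out_dir = "run1")
res$manifest$counts              # probe accounting at every filter
res$manifest$replication         # meta-analysis summary
res$manifest$enrichment$shore    # shore 2x2 chi-square
```
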