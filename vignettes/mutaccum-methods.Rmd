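---
title: "Mutation-accumulation rate models in mutaccum: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-accumulation rate models in mutaccum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`mutaccum` analyses mutation-accumulation (MA) experiments in haploid
filamentous fungi. The pipeline has five analysis stages — genome and
chromatin annotation, Poisson rate models, single-nucleotide mutation
(SNM) spectra, indel/repeat models, and population diversity — plus a
synthetic-data generator that makes every stage testable without any
external download. This vignette explains the models, the defaults and why
they are what they are, what the generator does and does not emulate, and
the numerical choices underneath.

## The core rate model

Mutation counts per MA line are modelled as

$$y_i \sim \text{Poisson}(\lambda_i), \qquad
  \log \lambda_i = \alpha + \log E_i, \qquad \alpha \sim N(0, 10),$$

where the exposure $E_i$ carries whatever the rate is "per": callable
base pairs, homopolymer loci, or nothing (per-genome). Rates convert as
$\mu = e^{\alpha} / (N\,t\,m)$ with $N$ callable bases, $t$ transfers and
$m$ mitoses per transfer; for per-genome rates $N$ is dropped. Because a
filamentous fungus has no germline, per-mitosis is the natural unit, and
$m$ is itself an estimate: `estimate_mitoses()` models replicate nuclei
counts per transfer phase as lognormal around the phase's true doubling
number, sums per-phase doublings (prior $N(10,10)$ truncated positive,
shared half-normal noise scale), and the posterior draws of $m$ are
resampled against the $\alpha$ draws in `to_rate()` so mitosis uncertainty
propagates into every rate.

Differences between rates are judged by the posterior of their draw-wise
ratio: two rates are called different when 1 falls outside the ratio's 95%
highest-posterior-density interval (HPDI). All intervals in the package
are HPDIs — the shortest interval holding the target mass — computed by a
sliding window over the sorted draws.

### Windowed rate variation

`fit_domain_gc_model()` aggregates mutation counts into fixed-width
windows (200 bp by default, matching the diversity windows; the fitting
granularity is otherwise a free choice) and regresses them on standardised
GC-content, H3K9me3 / H3K27me3 / centromere indicators and a
GC-by-H3K9me3 interaction, with offset
$\log(\text{callable bp} \times \text{lines} \times t \times m)$ so that
$e^{X\beta}$ is a rate in mutations/bp/mitosis. Centromeres are an overlay
on H3K9me3, never a fourth label, because in this genome centromeres
always sit inside H3K9me3 domains and their effect is additive on top of
it. H3K36me2 is deliberately not a predictor (it is close to the mirror
image of H3K9me3 and adds no information), and ancestral-duplication
tracks are dropped for the same collinearity reason.

Two numerical points. First, identical covariate rows are aggregated
before sampling — exact for a Poisson likelihood — and the aggregation key
is always the full covariate set regardless of which predictors a
particular model uses, so that competing models see identical data rows
and WAIC-based pseudo-BMA weights (`model_weights()`) are comparable.
Second, $m$ enters the window offsets as its posterior median rather than
draw-wise; its coefficient of variation is well under 2%, and full
propagation is retained where it matters, in `to_rate()`.

## Spectra

SNMs collapse to six base-pair substitution classes because the mutated
strand is unknown. Relative rates are per-class Poisson posteriors with
the source base-pair census as exposure, renormalised draw-wise to sum to
one, so "all classes equally mutable per source pair" sits at 1/6 (and at
1/32 for trinucleotide classes). Whether such plots are normalised to sum
or to mean is a convention; the output records the choice.

Trinucleotide contexts collapse with their reverse complements into 32
classes. The class representative is the strand whose focal base is A or
C, displayed as `REP:REVCOMP` (e.g. `TCT:AGA`, `GAT:ATC`); this makes the
focal-pair indicator of the flanking regression read directly off the
label. `trinuc_model()` fits 32 class effects plus additive H3K9me3,
centromere and H3K27me3 effects with census offsets and no
class-by-domain interactions.

Domain-versus-domain spectrum ratios are frequency-corrected two ways.
The nucleotide correction uses each domain's source base-pair census as
the class exposure. The trinucleotide correction replaces that census with
the domain's trinucleotide census of matching focal pair, weighted by
genome-wide per-class mutability; the exact correction the original
analyses used is not specified anywhere we could consult, so this
implementation fixes the property that matters: switching the correction
changes ratios only through the census/exposure terms.

`flanking_effects()` regresses log relative rate per trinucleotide class
on focal-pair and flanking-base indicators with each class's posterior sd
as a known measurement sd and no extra residual term. With Gaussian
likelihood and known sds the coefficient posterior is multivariate normal
in closed form, and is reported from exact draws rather than MCMC.
Degenerate (zero) measurement sds are floored at $10^{-3}$ and logged.

## Indels and repeats

Indels get exactly one repeat category. A deletion is homopolymer-class
when its affected interval lies within a catalog run (maximal single-base
runs of at least 5 bp); an insertion additionally must insert the run's
own base. Microsatellites are tandem 2–6 bp motifs with at least 3 copies
found by a maximal regex scan — the original repeat annotation criteria
being unspecified, this simple definition is stated rather than hidden.
`homopolymer_model()` fits per-locus counts with a type indicator (A:T vs
C:G) and one shared length slope (no interaction), offset by locus census;
lengths above 15 bp are pooled to avoid empty strata. Marginal per-type
per-locus rates are census-weighted over length strata.

## Population diversity

Watterson's $\theta_W$ is computed per window with each site's own called
sample size: a segregating site with $n_i$ called alleles contributes
$1/a_{n_i}$, $a_n = \sum_{k=1}^{n-1} 1/k$, divided by the window's
callable length. Sites with fewer than two calls are skipped; any site
with more than one distinct called allele counts as segregating
(multiallelic handling is a convention; this is the inclusive one).
Windows need at least 50% callable bases (configurable) and $\theta$ is
per callable bp, not per window span, so missingness does not deflate it.
Strains are haploid, one allele each.

`diversity_regression()` is a conjugate Bayesian linear regression of
$\theta_W$ on $\log_{10}$ predicted mutation rate, sampled exactly;
Bayesian $R^2$ is explained variance over explained-plus-residual variance
per draw. A two-part (hurdle) variant — logistic regression for
$\theta > 0$, linear model on the positive windows — is available for
robustness to zero-heavy windows; it is one reasonable two-part family,
and is labelled as such.

## The synthetic-data generator

`sim_config()` defines the study conditions once:

* **Genome**: 2 Mb over 4 contigs, a desk-scale stand-in for a ~41 Mb
  genome. Each contig has a central H3K9me3 block (15%) with a centromeric
  core (25% of the block) and an H3K27me3 block (10%); GC targets are
  bimodal (euchromatin 0.54, H3K9me3 0.38) so the domain GC distributions
  barely overlap. Homopolymer tracts are planted on top of naturally
  occurring runs (500 A:T and 300 C:G per Mb, so A:T loci are roughly
  1.7-fold more common).
* **Rates**: expressed exactly as the windowed model parameterises them —
  euchromatic base rate 2.46e-10 /bp/mitosis at the reference GC, 10x
  H3K9me3, 1.4x H3K27me3, a further 1.3x centromeric, GC slope −5 per GC
  unit with +3 inside H3K9me3 — multiplied by `rate_scale = 20` (the
  genome-size ratio) so the expected yield is ~30 mutations per line, the
  regime in which the posteriors have realistic widths.
* **Spectra**: 6-class weights per stratum chosen once to give a
  euchromatic Ts/Tv of 1.5 and a H3K9me3 Ts/Tv of ~0.92 with C:G→G:C
  enrichment in heterochromatin; expected class counts are weights times
  source-pair census, which makes the weights exactly the quantity the
  frequency-corrected estimator recovers.
* **Indels**: per-locus slippage rates 1.79e-8 (A:T) and 8.15e-9 (C:G)
  per mitosis with shared length slope 0.25/bp; non-repeat deletion and
  insertion rates at a 3:1 ratio with long-tailed deletion lengths
  (lognormal, mean ~1 kb) and short insertions (geometric, mean 27 bp), so
  net mutation pressure removes DNA. Complex events and translocations at
  per-genome rates matching a real experiment's yield.
* **Population**: 57 strains; segregating sites are placed so that
  expected $\theta_W$ equals $0.0096 \cdot \log_{10}\mu + c$, anchored so
  a euchromatic window at the base rate has $\theta = 0.015$; mutant
  counts follow the neutral site-frequency spectrum (so subsampling under
  i.i.d. missingness leaves the estimator unbiased), with 20% missing
  calls.

What the generator does **not** emulate: sequencing error and genotyping
filters, mapping bias in repeats, selection during propagation, linkage
and demography in the population sample (sites are independent), RIP
hypermutation, and structural-variant breakpoint signals. Tests passing on
synthetic data therefore validate the estimators and their calibration
under the stated generative model — not the upstream variant-calling
pipeline on real reads.

## MCMC backend and numerical choices

All Poisson-family posteriors are sampled with a compact MCMC backend
written for the small GLMs this package needs: chains start at the
penalised MLE, proposals are preconditioned with the Fisher information,
step scales adapt only during warmup (toward 0.234 joint / 0.44
coordinate-wise acceptance), and convergence is monitored with split-Rhat
(warning above 1.01). For up to 8 coefficients a joint random-walk
proposal is used; larger models (the 35-parameter trinucleotide model) use
component-wise updates plus one joint preconditioned move per sweep to
traverse correlated directions. Defaults are 4 chains of 1000 warmup and
3000 retained iterations. The intercept-only posterior is validated in the
test suite against an independent 1-D grid-integration oracle to within 2%
on the rate scale; the Gaussian measurement-error regression and the
diversity regression are conjugate and sampled exactly, with no MCMC
error at all.

Degenerate inputs are handled explicitly: all-zero counts give a
prior-dominated posterior with a warning (not an error); windows with no
callable bases are dropped with a message; structurally empty
trinucleotide classes are dropped with a warning; zero-census classes with
nonzero counts are an error.

Coordinates are 1-based closed internally, delegated to
IRanges/GenomicRanges; BED input is converted on read and BED-style output
written back 0-based half-open. Window domain labels use majority base
overlap with ties resolved toward the rarer label (H3K9me3 over H3K27me3
over euchromatin).

## Problem sizes in the test suite

Unit tests run on kilobase-scale fixtures with shortened chains where only
correctness of the machinery is at stake. Calibration claims use the
study conditions themselves: the master recovery suite runs 20 synthetic
replicates of the full 2 Mb default configuration with the default MCMC
settings and checks that each generating parameter (domain folds including
the 10x H3K9me3 effect, GC slope and interaction, the six euchromatic
spectrum weights, the homopolymer type ratio and length slope, and the
diversity-rate slope) falls inside its 95% HPDI at least 16 times in 20 —
the sharpest one-sided binomial test of "coverage at least 90%" at that
replicate count. The diversity-slope coverage is assessed against the
generator's true per-window rates; regressing on model-predicted rates
instead adds predictor noise (attenuation), which is a property of the
two-stage design, not of the regression.

## Known limitations

* The Poisson models ignore per-line rate heterogeneity; a hypermutator
  line would violate them (flagged by the per-line count distribution, not
  modelled).
* The trinucleotide model's additive class+domain structure is, by
  construction, mildly misspecified when per-domain 6-class spectra
  differ, since class opportunity and domain composition couple; its
  domain folds are then composition-weighted averages.
* The measurement-error regression conditions on posterior summaries
  (mean, sd) of the relative rates rather than propagating their full
  joint posterior.
* Pseudo-BMA weights use WAIC on the aggregated rows; weights from
  leave-one-window-out cross-validation could differ.
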