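---
title: "Models and methods behind plasfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plasfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

plasfit analyses the classic experimental-evolution design for measuring the
fitness cost a conjugative plasmid imposes on its bacterial host: a
plasmid-bearing and a plasmid-free strain are mixed, grown in batch culture,
and serially transferred (here 1:100 every 24 h) while the composition of the
mixture is tracked by plating and colony screening. The package covers the
five quantitative strands of such a study — competition fitness, plasmid copy
number from sequencing coverage, colony morphology, fold-change
differential expression, and COG category enrichment — plus a synthetic-data
module that generates each input stream with known ground truth. This
vignette explains the models, the tunable parameters, and the design
decisions; the README shows a worked example.

## Relative fitness from competition assays

The fitness index is the ratio of natural-log fold-changes of the two
competitors over the assay interval,

$$W \;=\; \frac{\ln\!\big(N_{t,\mathrm{bearing}}/N_{0,\mathrm{bearing}}\big)}
               {\ln\!\big(N_{t,\mathrm{free}}/N_{0,\mathrm{free}}\big)},$$

with $N$ the CFU counts of each class. $W=1$ is neutrality, $W<1$ a cost of
carriage. The class-specific counts come from a total plate count partitioned
by a screened-colony subsample (`strain_cfus()`); screening is treated as
binomial subsampling of the plate, with no finite-plate hypergeometric
correction, because a plate holds vastly more colonies than the few hundred
screened.

`fitness_trajectory()` computes $W$ per replicate per timepoint and
summarises with the arithmetic mean and the sample ($n-1$) standard
deviation, matching how triplicate error bars are conventionally reported.
Three degenerate situations get explicit treatment rather than silent
propagation:

* **Zero plasmid-bearing colonies among the screened at $t>0$.** $\ln 0$ is
  $-\infty$, but a zero among ~200 screened colonies is a plating-resolution
  event, not proof of extinction. The replicate is flagged `"extinct"` at
  that timepoint (W = `NA`) and excluded from the mean.
* **A free competitor that declined.** The denominator log is negative and
  the signed ratio, while returned, inverts its usual reading; a classed
  warning is attached so pipelines can catch it.
* **A single usable replicate.** `sd_w` is reported as 0 with a classed
  warning and a `single_replicate` flag, keeping output shapes stable.

### Cumulative versus per-interval baselines

Published trajectories are usually "calculated every 24 h" against the
initial mixture, which we read as cumulative-from-$t_0$; both modes are
implemented (`baseline = "initial"` or `"previous"`) and cumulative is the
default. One subtlety matters for cumulative $W$ under serial transfer: the
1:100 dilution at each transfer divides *both* classes equally, so raw
pre-transfer CFU logs each carry a shared $-c\ln D$ term that cancels only
in the per-interval mode. The simulator therefore emits a `cum_dilution`
column (the product of dilution factors applied before each observation) and
`fitness_trajectory()` multiplies counts by it, reconstructing cumulative
fold-changes. With that correction, deterministic exponential growth
satisfies the closed form $W = m_\mathrm{bearing}/m_\mathrm{free}$ exactly
(the test suite demands agreement to $10^{-9}$; the integrator delivers
$\sim 10^{-12}$). Real data without the column are used as printed.

The band-intensity readout (`band_relative_ratio()`) is the PCR-gel analogue
of the same idea: a strain-specific amplicon intensity over a shared
single-copy reference amplicon, normalised to the initial timepoint, so the
series starts at 1 by construction and needs no absolute calibration.

## The serial-transfer batch model

`simulate_competition()` integrates, within each cycle, shared-capacity
logistic growth for three genotypes (plasmid-bearing ancestor $A$,
plasmid-bearing compensated mutant $C$, plasmid-free $F$) plus a
transconjugant pool $T$:

$$\frac{dN_i}{dt} = m_i N_i \left(1 - \frac{\sum_j N_j}{K}\right) + \text{(conversion terms)},$$

with mass-action conjugation $\gamma N_\mathrm{bearing} N_F$ moving free
cells into $T$, segregational loss diverting a fraction $\lambda$ of
bearing divisions into $F$, and compensation converting $A$ to $C$ at a
constant per-cell rate. A single shared capacity reflects one limiting
resource, as in succinate minimal medium. At each transfer every state is
divided by the dilution factor; observations (total CFU/ml plus a binomial
colony screen that cannot distinguish the bearing genotypes) are taken at
the end of each cycle, before dilution.

Default parameters, chosen once as a realistic rendering of the study
conditions:

| parameter | default | why |
|---|---|---|
| $m_F$ | 0.7 h$^{-1}$ | minimal-medium growth rate of a healthy pseudomonad |
| $m_A$ | 0.63 h$^{-1}$ | a 10% plasmid cost, the magnitude implied by $W \approx 0.64$ after one cycle |
| $m_C$ | 0.735 h$^{-1}$ | compensated mutants grow slightly (5%) faster than plasmid-free cells |
| $K$ | $10^9$ ml$^{-1}$ | saturated minimal-medium culture density |
| dilution, period | 100, 24 h | the transfer regime |
| initial density | $10^7$ ml$^{-1}$ | 100-fold dilution of a saturated culture |
| initial bearing fraction | 0.5 | OD-matched equal mixing |
| $\gamma$ | $10^{-15}$ ml cell$^{-1}$ h$^{-1}$ | keeps transconjugants per donor near $10^{-5}$ per cycle, far below the 0.012% at which conjugation is observed to be negligible |
| $\lambda$ | 0 | the plasmid is fully stable in pure culture |
| compensation rate | $10^{-6}$ cell$^{-1}$ h$^{-1}$ | an effective appearance rate for compensated lineages |
| cycles, screen | 6, 200 | the 144-h assay; 200 colonies hybridised |

With compensation off and a cost present, the bearing fraction declines
monotonically; with compensation on, the trajectory is U-shaped — the
ancestor is outcompeted while the compensated genotype rises from rare — and
cumulative $W$ eventually exceeds 1. With the deliberately conservative 5%
compensated advantage this recovery takes tens of cycles rather than the
six of a typical wet assay, in which stronger effective advantages (or
earlier-arising mutants) drive recovery within 144 h; the qualitative-shape
checks therefore run the model for 60 cycles. Deterministic mode suppresses
all sampling and reports exact expected screen counts (fractional), so
closed-form regimes can be verified to integrator precision; stochastic mode
adds binomial screen noise only — total CFU counts are taken as exact, since
plate-count noise is small relative to screening noise at $n \approx 200$.

## Plasmid copy number from coverage

The estimator is the ratio of mean plasmid depth to mean chromosome depth
(`copy_number()`): both depths scale identically with library size, so the
ratio directly estimates plasmid copies per chromosome. It is defined on
depths rather than read counts because per-replicon read counts depend on
the effective read length, which can differ between sequencing batches; in
the bundled 13-strain reference table the depth ratio reproduces every
reported copy number exactly, while read-count ratios do not for two
strains. Reported values are rounded to one decimal, half away from zero.
`simulate_wgs_reads()` inverts the model — reads are allocated binomially
with probability proportional to length × copies — and at $10^5$ reads the
estimator recovers a planted copy number of 3 within ±0.15 in ≥95% of
seeds. At $10^4$ reads the binomial sampling error alone (sd ≈ 0.18 at copy
number 3) exceeds that band, which is why the recovery checks use $10^5$.

## Differential expression by replicate-consistent fold-change

Expression is quantified as RPKM. For a two-condition, two-replicate
design, `call_de()` computes, per ORF, all four cross-condition ratios
$t_i/c_j$ and calls an ORF up only if **all four** exceed the threshold
(strictly greater than 2 by default), down only if all four fall below its
reciprocal. This is deliberately a plain filter, not a distributional test:
requiring every cross-replicate comparison to agree is what substitutes for
a variance model. Within-condition ratios play no role. Values below a
floor (default 0.1 RPKM) are raised to it before ratios, so silent ORFs
never generate infinite fold-changes; the floor, not a pseudocount, keeps
ratios of well-expressed ORFs untouched. The rule is symmetric (swapping
conditions maps up↔down exactly), scale-free, and monotone in the
threshold. Replicate quality is checked by Pearson correlation of the
replicate vectors (`replicate_correlation()`), with 0.97 the conventional
bar for duplicate RNA-Seq of a clonal culture.

## COG enrichment

`enrich_table()` tests each assigned COG category for over-representation
in the DE set with the one-sided hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, summed directly on
the log scale with `lgamma`-based log-factorials. One-sided is the natural
reading of "significantly larger", and it is the variant that reproduces
the O/L/U significance pattern of the bundled reference tables; a
two-sided Fisher option exists behind a flag. No multiple-testing
correction is applied by default (each raw p-value is compared with
$\alpha$), again matching the per-category convention of this literature;
Bonferroni is available. Unassigned ORFs ("–") count toward $n$ and $N$ but
are never themselves tested. The implementation agrees with exhaustive
enumeration of the hypergeometric mass to $10^{-12}$ for all populations
$N \le 60$, and with `stats::phyper` to $\sim 10^{-11}$ at genome scale
(where `lgamma`'s argument magnitude bounds the attainable precision).

## What the generators do and do not emulate

Each generator reproduces the statistical structure the corresponding
analysis assumes: binomial colony screens over deterministic batch
dynamics; binomial read allocation; lognormal baseline expression with
multiplicative replicate noise and planted fold-changes; zero-truncated
normal colony diameters; band intensities with multiplicative noise around
a decaying true ratio. They do **not** emulate plate-count (total CFU)
noise, GC or mappability bias in coverage, overdispersed or
length-dependent count noise, batch effects, or gel-quantification
saturation. Passing the recovery tests therefore shows the estimators are
correct under their own assumptions and calibrated sampling noise — not
that real data meet those assumptions.

## Numerical choices and problem sizes

Integration uses `deSolve::ode` (lsoda) at `rtol = 1e-12`, so closed-form
checks at $10^{-9}$ have two orders of headroom. An infinite carrying
capacity is an accepted special case (the logistic term vanishes exactly).
Copy numbers round half away from zero; histogram bins are left-closed
right-open from 0; threshold fractions use strict inequalities, so
boundary colonies count in neither fraction. Test and acceptance runs use
desk-scale sizes chosen to make the stochastic bounds sharp but cheap: 100
seeds × 200 colonies, 100 seeds × $10^5$ reads, 20 seeds × 2000 ORFs, and
the 60-cycle compensation sweep; the full suite runs in well under two
minutes.

## Known limitations

* The competition model is deterministic between observations; drift at
  the transfer bottleneck ($\sim 10^7$ cells survive a 1:100 dilution) is
  negligible at these densities and is not simulated.
* Compensated mutants are a single genotype with one fixed advantage;
  real sweeps may involve multiple lineages.
* The DE caller has no error model, by design: its false-positive
  behaviour is characterised empirically via the generator, not
  analytically.
* Enrichment p-values are exact but conditional on the annotation; ORFs
  with multiple COG letters must be reduced to one before input.
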