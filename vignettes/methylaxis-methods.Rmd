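---
title: "Models and methods behind methylaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylaxis)
library(dplyr)
```

methylaxis compares whole-genome bisulfite (MethylC-Seq) and Tet-assisted
bisulfite (TAB-Seq) methylomes between two tissue subregions — the
motivating system is the dorsal versus ventral dentate gyrus of mice
reared in enriched versus standard housing — together with the matched
RNA-Seq contrasts. This vignette explains the statistical models, the
tunable parameters and their defaults, the synthetic-data generator used
for validation, and the design choices made where more than one
reasonable construction existed.

## Assay error models and spike-in calibration

Bisulfite sequencing reads both 5-methylcytosine (mC) and
5-hydroxymethylcytosine (hmC) as "methylated"; unmethylated cytosines
fail to convert at the non-conversion rate (NCR), estimated by pooling
calls over a fully unmethylated lambda-like spike-in contig. Given `m`
methylated of `c` total calls, the corrected total methylation level is
the maximum-likelihood estimate

$$p_{mC} = g\!\left[\frac{m/c - \mathrm{NCR}}{1 - \mathrm{NCR}}\right],
\qquad g[x] = \max(x, 0),$$

applied by `correct_mc()`. We additionally cap the estimate at 1: the
published clamp only floors at zero, but sampling noise can push `m/c`
above the model ceiling, and levels must remain probabilities. Clamp
events are rare at realistic coverage and are purely a numerical guard.

TAB-Seq protects hmC with a glucosyl group, Tet-oxidises the remaining
mC, and converts everything else, so only hmC should survive as cytosine.
Three error rates describe the assay: non-conversion $r$, non-oxidation
$s$ and non-protection $t$. With $q$ the observed unconverted fraction
and $p_{mC}$ the matched corrected mC+hmC level at the same site,

$$p_{hmC} = g\!\left[\frac{q - s\,p_{mC} - r\,(1 - p_{mC})}{1 - t}\right],$$

implemented in `correct_hmc()` and clamped to $[0, p_{mC}]$. The matched
$p_{mC}$ comes from the same biological sample's bisulfite table; where
that site has coverage below a configurable minimum (default 3), the hmC
level is withheld rather than computed from a noisy denominator.

Rates are estimated by `estimate_ncr()` and `estimate_tab_rates()` as
pooled ratios of sums across each control contig — the
maximum-likelihood estimate, which weights sites by coverage — with
Clopper–Pearson 95% intervals. Three contigs drive the system: a fully
unmethylated contig (NCR and $r$), a fully CG-methylated contig ($s$,
from CG sites), and a hydroxymethylated contig ($t$). Real 5hmC spike-ins
are not 100% hydroxymethylated, so the hmC contig's true abundance $a$ is
first measured from a matched ordinary-bisulfite run of the same batch
(where incomplete hydroxymethylation leaves unmodified, convertible
cytosines), and $t$ is obtained by inverting the assay model on that
contig:

$$q_C = (1 - t)\,a + s\,a + r\,(1 - a)
\;\Longrightarrow\;
t = 1 - \frac{q_C - s\,a - r\,(1 - a)}{a}.$$

The $s\,a$ term matters: dropping it biases $t$ by roughly $s$ (about
0.02 at the defaults), larger than the estimate's standard error at
typical spike-in depths. When $a \le r$ the system is unidentifiable and
the estimator stops with a diagnostic rather than returning a number.
The confidence interval for $t$ propagates all four binomial components
(delta method); intervals for the directly observed rates remain
Clopper–Pearson.

Whether the NCR correction should be applied per site or only to
aggregated levels is not uniquely determined; both paths exist
(`correct_table()` site-wise, the `ncr` argument of `global_level()` for
aggregates) and agree in expectation because the correction is affine in
`m/c`.

## Methylation levels, bins and profiles

All levels are weighted methylation levels — ratios of summed methylated
calls to summed total calls — which weight sites by coverage and compose
exactly across partitions; an unweighted per-site mean is available
behind the `weighted = FALSE` flag since either convention appears in
practice. The CH level pools the CA, CC and CT classes by their counts.
`binned_levels()` partitions each chromosome into fixed 0-based
half-open bins (default 1 kb) whose numerators and denominators sum
exactly to the global values; `stratify_bin_diffs()` reproduces the
stratified view in which bins are grouped by their regional methylation
difference and the median condition effect is reported per stratum (the
stratum edges are configurable because no canonical edge set exists; the
default is 10-percentage-point strata over ±60%).

`profile_at_features()` anchors at feature midpoints — the natural
anchor for DMR- and binding-site-centred profiles — negates offsets for
minus-strand features, and reports the pooled level per offset bin,
masking bins with fewer than `min_sites` (default 3) site–feature pairs.

## The DMR caller

The caller is a fully specified substitute for smoothing-based
beta-binomial callers, fixed at the field's standard thresholds: at
least a 15% methylation difference at p < 0.05. It is validated by
recovery of implanted truth, not by concordance with any particular
external implementation.

1. **Site test.** Replicate counts are pooled per group. Sites with
   total coverage below 200 get a two-sided Fisher exact test on the
   pooled 2×2 table (an exact enumeration identical to
   `stats::fisher.test`, vectorised for speed and tested against it);
   deeper sites use the normal approximation on the difference of pooled
   proportions.
2. **Over-dispersion guard.** A site is excluded from candidacy when the
   between-replicate range of methylation fractions within either group
   exceeds the absolute between-group difference *and* the replicate
   counts are significantly over-dispersed relative to binomial sampling
   (chi-square upper p < 0.01). The second condition is essential at
   ~15× coverage, where the range of five binomial fractions is ~0.26 in
   expectation — sampling noise alone would otherwise masquerade as
   replicate inconsistency and remove half of all genuinely
   differential sites. The guard stands in for a beta-binomial
   dispersion fit while remaining closed-form and oracle-testable.
3. **Candidates and merging.** Candidate sites (|difference| ≥
   `min_diff`, p < `alpha`, consistent sign, unflagged) merge when
   separated by at most `max_gap_bp` (250) *and* at most
   `max_intervening` (2) covered non-candidate sites. The density
   condition prevents a lone coincidental candidate near a true region
   from dragging the region span across null sites.
4. **Region statistics.** The pooled difference and a signed
   Stouffer-combined p-value are computed over *every* covered site in
   the region span, not only the candidates: candidate-only pooling is
   selection-biased (each seed site was chosen for a large, significant
   difference) and admits short runs of coincidental noise sites.
   Regions are reported when they hold ≥ `min_sites` (3) candidates,
   span difference ≥ `min_diff`, and span p < `alpha`.

`max_gap_bp = 250` and `min_sites = 3` approximate the reported scale of
neuronal CG-DMRs (mean length ~190 bp). CH-context DMRs are out of
scope: differential mCH is analysed through global and binned levels,
and DMRs are defined at CG dinucleotides. CpG dyads are kept as two
strand-specific sites (no dyad merging). The two-group comparison is
unpaired; a paired design for condition contrasts would be future work.

## DMR–gene enrichment and colocalization

`enrichment_curve()` scores DMR density per gene per megabase as a
function of signed, strand-oriented TSS distance (upstream negative).
Every gene within the ±1 Mb window of a DMR contributes a pair — not
only the nearest gene — which is the convention consistent with the
per-gene density normalisation; bins default to 100 kb because no
canonical edges exist. The matched control band stratifies all genes
into deciles of mean expression and repeatedly draws control sets
matching the target's per-decile composition, excluding target genes;
the band is the per-bin 2.5th/97.5th percentile of control curves, using
order-statistic (type 1) quantiles because the per-bin scores are scaled
counts and interpolated quantiles under-cover on discrete distributions.
Deciles are a concrete reading of "control genes with equivalent mean
expression"; a decile short of control genes borrows from its
neighbours with a warning. Because control sets exclude the targets,
the band is slightly anti-correlated with the target curve when the
target set is a large fraction of the universe; calibration checks
therefore use target sets of ~2% of genes, the regime the method is
meant for (tens to hundreds of DE genes against a ~10⁴-gene
transcriptome).

`dmr_gene_hypergeom()` uses the urn: population = all genes, successes =
genes with ≥1 DMR within the gene body ± 10 kb (configurable), sample =
the target set, upper-tail p. `peak_dmr_colocalization()` counts a peak
as colocalized when its midpoint lies within `max_dist` (500 bp, closed)
of a DMR edge; since no canonical urn exists for peak–window overlap
statistics, the population is the set of fixed-width windows tiling the
genome with successes defined by the same midpoint rule. The resulting
p-value depends on that universe choice, which is why printed
colocalization p-values from other universes are not directly
comparable.

## Expression filtering, QC and contrasts

Genes are retained when counts exceed 10 in at least two samples
(default) or when TPM > 1 in at least three samples (alternative;
effective length = exonic length). Sample QC flags aberrant expression
of a female-specific marker (Xist by default) at median + 5·MAD of
marker CPM — the rule that catches a mis-sexed animal — and exclusion is
always reported, never silent.

The differential expression test is a deliberately simple, fully
specified substitute for a negative-binomial GLM: median-of-ratios size
factors, log2(normalised count + 0.5), and Welch t statistics on the
contrast's linear combination of group means. The three contrasts mirror
the study design: (1) the region contrast tests
Dorsal·SH − Ventral·SH = Dorsal·EE − Ventral·EE, a
difference-of-differences whose variance sums over all four design cells
with Welch–Satterthwaite degrees of freedom — note that a regional
effect identical in both conditions satisfies this null, so the
generator's recovery checks implant effects in a single condition cell;
(2) and (3) test the housing-condition effect within dorsal and ventral
respectively. BH adjustment runs across the retained genes of each
contrast, and a DE call requires q < 0.05 together with at least a 20%
fold change (|fold| ≥ 1.2) on the linear scale, applied to the
estimated group-mean contrast.

## The synthetic-data generator

`simulate_study()` and its components generate a genome (i.i.d. bases at
GC fraction 0.42), a strand-resolved cytosine catalogue, gene
annotations, implanted DMRs, per-site true methylation states, assay
count tables, spike-ins and an RNA-Seq count matrix, all deterministic
given one master seed (per-operation substreams derive from it, so
stages are reproducible independently).

Key structural choices:

- **Shared site baselines.** Site-level beta noise (concentration 30) is
  drawn once per site and shared between regions; the only true regional
  differences are the implanted DMRs and the global mCH scaling
  (ventral = dorsal × ratio). Biological site effects are common to both
  subregions of one tissue, and this is what makes a no-implant run
  genuinely null — with independent per-region draws, ~17% of sites
  would carry true differences above the 15% threshold and no caller
  could (or should) report zero DMRs.
- **Study-scale defaults.** mCG baseline 0.75; mCH 0.02 dorsal / 0.04
  ventral (the ~2× regional asymmetry); hmCG 0.15 at CG sites only (CH
  hydroxymethylation exists only behind a negative-control flag);
  coverage truncated-Poisson with mean 15 (matching ~14.8× genome
  coverage; truncation at 1 exercises the low-coverage edge cases);
  5 replicates per group; 100 DMRs per 2 Mb with per-DMR true
  differences ~ Normal(0.26, 0.045) floored at 0.05 (the reported
  26% ± 4.5% scale) and log-normal lengths around 200 bp (the reported
  ~190 bp mean); error rates ncr 0.005, r 0.003, s 0.02, t 0.08; hmC
  spike-in purity 0.9 to exercise the impurity-correction path.
  Spike-in coverage (default 50×) is an independent knob because no
  mass-to-coverage relationship is available to derive it from.
- **Expression.** Log-normal baseline means (meanlog 4, sdlog 1.5),
  negative-binomial counts (dispersion 0.05 by default), fold changes
  applied to a designated design cell. True DE genes are drawn from
  genes with baseline mean ≥ 10 counts: a differential-expression
  hypothesis only exists for expressed genes, and the retained-gene
  universe of the study design has this property by construction.
- **Clipping.** A DMR whose difference would push the hypomethylated
  region below 0.02 is clipped and flagged in the truth set.

What the generator does *not* emulate: read-level artefacts (PCR
duplicates, GC bias, mapping error), correlated CpG dyads, distance
decay of methylation autocorrelation, batch effects, and biological
replicate over-dispersion (replicates are binomial around the shared
truth unless you construct otherwise). Passing recovery tests therefore
demonstrates correctness of the estimators under the stated forward
model, not robustness to every artefact of real libraries — which is
exactly what a validation harness with known truth can and should show.

## Problem sizes and numerical choices

Validation runs use a 2 Mb genome (~176,000 CG sites both strands,
5 vs 5 replicates at 15×) for DMR recovery, ~10⁵ CH sites for the mCH
asymmetry, ≥10⁴ calls per spike-in contig for rate recovery, a
2000-gene universe with 40-gene target sets and 300 resamples for
enrichment calibration, and 2000 genes × 20 samples (200 true DE genes,
dispersion 0.01 — the near-Poisson "low dispersion" regime) for the DE
recovery. The enrichment calibration scales the TSS window with the toy
genome (±200 kb on 1 Mb chromosomes, in the proportion that ±1 Mb bears
to a mammalian genome): with a window comparable to the chromosome
itself, the extreme distance bins are dominated by chromosome-edge
truncation — a positional effect no expression-matched control can
balance — rather than by the signal the band is meant to calibrate.
Three independent target sets are evaluated per simulated DMR
configuration to tighten the Monte Carlo estimate of the band-coverage
fraction. These sizes keep every stage's sampling error far below the
effect sizes being recovered. Ties in the Fisher enumeration use the
standard relative tolerance (1 + 10⁻⁷) on the observed table's
probability; Stouffer z-scores floor p at 10⁻³⁰⁰ to avoid infinite
quantiles; clamped levels count as estimates, not errors.

## Known limitations

- The caller reports unpaired two-group DMRs only.
- hmC levels require the matched bisulfite sample; there is no
  single-assay hmC path.
- The colocalization p-value is universe-dependent (see above).
- The Welch-on-log substitute is less powerful than a well-specified
  count GLM at very low counts; genes near the filter boundary are
  detected less often than a dispersion-sharing model would manage.
- The enrichment band's control draws exclude target genes, so with
  target sets that are a large fraction of all genes the band narrows
  relative to the target's sampling distribution.
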