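---
title: "Cross-population selection scans: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-population selection scans: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The problem

Commercial breeding programs keep a small number of reproductively
isolated purebred lines under sustained directional selection, each with
its own emphasis (growth rate, meat yield, feed efficiency, reproduction).
After a few dozen generations, the alleles favored in a line have risen in
frequency and dragged their haplotype backgrounds with them.  Two
complications make detecting those footprints hard: effective sizes of a
few hundred mean genetic drift alone produces large frequency shifts and
local fixation; and SNP-array data offer only ~1 marker per 20 kb, all
ascertained to be common.  sweepscan addresses this with two
complementary cross-population statistics computed for every ordered pair
of lines, a cross-method and cross-line consensus step that discards
signals drift can mimic in a single line, and a forward simulator that
reproduces the whole design so every stage can be validated against known
truth.

# Statistics

## XP-EHH

Site EHH at distance $x$ from a core SNP is the probability that two
haplotypes sampled without replacement are identical at every marker from
the core out to $x$ (inclusive); at $x = 0$ this is the core-site
homozygosity.  All haplotypes of a population enter one partition (the
"site" construction): the cross-population statistic compares populations,
not allele classes.  iHH integrates the EHH decay curve over genetic
distance by the trapezoid rule, left and right of the core, and

$$\mathrm{XP\text{-}EHH} = \ln\left(\frac{iHH_A}{iHH_B}\right)$$

is standardized genome-wide within each ordered comparison (population
standard deviation, denominator $n$).  Standardized scores are treated as
standard normal and tested one-sided in the upper tail, since a large
positive value indicates extended haplotypes — recent selection — in the
focal population; two-sided P-values are available via `two_sided = TRUE`.
Significant SNPs (P < 0.05) closer than 200 kb are clustered into
candidate regions; a lone significant SNP yields a zero-length region.

Two numerical choices matter and are tested explicitly:

* **Shared truncation.** Both populations are integrated to the *same*
  boundary per direction: the first marker at which the EHH of the
  *combined* two-population sample drops below `ehh_floor` (default 0.05);
  the trapezoid segment reaching that marker is included.  A shared
  boundary keeps the numerator and denominator of the ratio comparable;
  truncating each population at its own boundary would bias the ratio
  toward whichever panel is more diverse.
* **Unusable cores.** A core with $iHH = 0$ on either side of the ratio
  (no integration support) is excluded from standardization and counted,
  not silently dropped.

## XP-CLR-style composite likelihood

The scan places grid points every 2 kb and scores the SNPs within 0.25 cM
of each point.  The model is this package's own, fully documented
drift-vs-sweep mixture (outputs carry the "XP-CLR-style" label to make the
provenance unambiguous):

* **Null**: the focal-line frequency $p_A$ of a SNP with reference
  frequency $p_B$ follows a normal with mean $p_B$ and variance
  $(\omega + 1/n_A)\,p_B(1-p_B)$, renormalized to $[0,1]$.  $\omega$ is a
  genome-wide drift scale estimated by method of moments:
  $\hat\omega = \max\!\big(0,\ \overline{(p_A-p_B)^2/(p_B(1-p_B))} -
  \overline{1/n_A}\big)$ over SNPs with $p_B \in (0,1)$.
* **Sweep of scale $s$** (cM): a SNP at genetic distance $d$ from the grid
  point escapes the sweep with probability $c = 1 - e^{-d/s}$; with
  probability $1-c$ it is drawn from the fixation mixture
  $p_B\,g_1(p_A) + (1-p_B)\,g_0(p_A)$, where $g_1, g_0$ are truncated
  normals at 1 and 0 with width $\varepsilon = 0.02$ — the hitchhiking
  allele is the one the reference carries, with the reference frequency as
  its prior weight.
* **Statistic**: twice the LD-weighted sum of per-SNP log-likelihood
  ratios, maximized over 12 log-spaced scales from 0.01 to 5 cM *plus the
  no-sweep model*, so the score is never negative and is exactly 0 when
  focal and reference frequencies coincide.

SNP weights are $1/k_i$ with $k_i$ the number of window SNPs (including
$i$) whose haplotype correlation with $i$ reaches $|r| \ge 0.9$ in the
*reference* line — the non-focal line, so sweep-distorted focal LD cannot
drive its own weighting.  Monomorphic SNPs have undefined $r$, are treated
as uncorrelated, and SNPs fixed in the reference cannot be scored at all
(the null variance degenerates); they are excluded per window and counted.
Windows with no scorable SNP are flagged and take no part in thresholding.

Per comparison, windows at or above the empirical 99.5 % quantile of
scores (midpoint interpolation; cutoff ties all kept) are retained and
clustered wherever consecutive kept windows are closer than 1 cM; the
region spans the kept grid points.

Model diagnostics worth knowing: with strong drift the truncated normal
null puts too little mass at the frequency boundaries, so absolute scores
are inflated genome-wide and grow with the number of scorable SNPs in a
window; the *ranking* across windows, which the quantile threshold uses,
is what carries the signal.  This is the main reason the thresholding is
quantile-based rather than an absolute cutoff.

## ZHp

For one line, each SNP's called alleles are split into major/minor counts;
a sliding window (5 SNPs, step 1, autosomes only) sums them and

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}
             {(\Sigma n_{MAJ}+\Sigma n_{MIN})^2} \in [0, 0.5]$$

is Z-transformed genome-wide per line.  $H_p = 0$ exactly when all window
SNPs are fixed, which is why strongly negative ZHp marks fixation-level
sweeps — and also why ZHp floors: every fully fixed window ties at the
same minimal value, and "the minimum window" is only defined up to that
tie set.  Validation therefore asks whether the windows overlapping a
known swept locus *attain* the genome-wide minimum, not whether an
index-ordered argmin lands there.  No default significance cutoff is
imposed; the Z scores are reported and the threshold is the analyst's.

## Consensus

Per line and method, regions from the line's four comparisons are unioned
(a region flagged against any reference line is evidence for selection in
the focal line), coalescing intervals separated by at most 1 bp.  The two
methods are then intersected: each XP-CLR region overlapping (≥ 1 bp) an
XP-EHH region of the same line is kept *with the XP-CLR span*, which is
the narrower and better-localized of the two; one wide XP-EHH region may
support several XP-CLR regions.  Finally, the genome is cut at every
candidate boundary and elementary segments covered by ≥ 2 lines are kept,
merging adjacent segments with identical supporting line sets — each
consensus interval is the trimmed common overlap and is contained in every
supporter's own candidate set.  Intervals are 1-based inclusive
internally; BED output converts to 0-based half-open.

# The simulator

`simulate_study()` emulates the study design the scans target: a base
population, K lines drifting in isolation, an ascertained array.

* **Base population.** Ancestral frequencies are drawn from a
  neutral-like spectrum with density $\propto 1/p$ on
  $[\mathrm{maf\_floor}, 1-\mathrm{maf\_floor}]$; founder haplotypes are
  drawn per-SNP independently, and the base panel is built as founder
  mosaics with Poisson crossovers (`founder_depth` = 50 expected
  crossovers per Morgan, standing in for the recombination accumulated
  while the base population mixed) so that nearby SNPs carry LD that
  decays with genetic distance.  Markers sit on a jittered regular grid —
  arrays are designed for even genome coverage, and uniform-random
  placement would let Poisson density clumps, not biology, dominate
  window statistics.  Array-style ascertainment then drops SNPs whose
  pooled minor-allele frequency in the generation-0 panel is below
  `maf_floor` (candidates are oversampled ~1.4× and a random subset of
  survivors is kept, preserving even density).
* **Line evolution.** Each line starts from a random sample of the base
  panel and reproduces by Wright–Fisher mating: each offspring draws two
  parents (with replacement), each contributing one gamete recombined with
  Poisson crossovers per Morgan.  Selection is haploid-multiplicative:
  a parent's sampling weight is $(1+s)$ per copy of the favored allele.
  A favored allele lost to drift is recorded in the truth table, not an
  error.
* **Hard-sweep seeding.** The favored allele arose once, so all carriers
  (frequency `start_freq` in the base panel) share a single origin
  background around the locus.  Each carrier copies the origin over an
  exponential segment per side with mean $100/\mathrm{founder\_depth}$ cM
  — the shared-segment decay a single-origin standing variant actually
  has.  Both alternatives fail basic physics: independent carrier
  backgrounds make a *soft* sweep with no extended-haplotype signal, and
  copying the whole chromosome removes the escape gradient, so the
  frequency-differentiation statistic cannot localize the sweep within
  the swept chromosome.
* **Export.** The configured diploids per line are sampled and emitted
  twice: a phased, complete copy (the scan substrate) and a raw copy with
  genotype-wise missingness, written with `/` separators.  Optional trios
  (sampled parents plus a simulated child, with forced Mendel-error
  injection where the parents' genotypes permit a detectable violation)
  support the pedigree QC filter.  All randomness flows from the single
  configuration seed.

Default scale: 3 chromosomes × 20 Mb at 1 cM/Mb, 3,000 SNPs, 5 lines
(ML1/ML2/ML3/FL1/FL2), Ne = 250, 40 generations, 24–60 diploids sampled
per line.  These sizes mirror the genotyped-line design the package
targets, scaled to a 60 Mb genome so a full five-line study simulates and
scans in well under a minute; the vignette and test suite use them
throughout.

What the simulator deliberately does *not* model: new mutations (the
marker panel is fixed in advance, as on an array), sex chromosomes,
overlapping generations, unequal sex numbers, or admixture events such as
a historical cross between lines.  Consequences for interpreting green
tests: recovery rates measured here speak to drift, LD and ascertainment
of the modeled kind, not to phasing errors (input is perfectly phased),
ascertainment biased toward a discovery breed, or soft/polygenic
selection.

# Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `call_rate_min` | 0.90 | fraction | QC: minimum genotype call rate (pooled over samples) |
| `mendel_max` | 0.001 | rate | QC: maximum Mendelian-error rate per SNP |
| `ehh_floor` | 0.05 | EHH | shared truncation of iHH integration |
| `xpehh_p` | 0.05 | P | XP-EHH significance cutoff (one-sided) |
| `xpehh_gap` | 200,000 | bp | significant-SNP clustering distance |
| `xpclr_spacing` | 2,000 | bp | grid spacing |
| `xpclr_window_cm` | 0.5 | cM | window width |
| `r_cutoff` | 0.9 | \|r\| | LD down-weighting threshold |
| `top_fraction` | 0.005 | fraction | kept upper quantile of window scores |
| `cluster_gap_cm` | 1.0 | cM | kept-window clustering distance |
| `eps` | 0.02 | frequency | width of the fixation components |
| `zhp_window`, `zhp_step` | 5, 1 | SNPs | pooled-heterozygosity windows |
| `min_lines` | 2 | lines | consensus support requirement |
| `flank` | 100,000 | bp | gene search around gene deserts |
| `min_region_snps` | 5 | SNPs | informative SNPs required for haplotype profiling |

The QC call-rate threshold is applied over all samples pooled (one global
threshold); per-line application would interact with unequal line sizes
and is intentionally not the default.  The Mendelian-error denominator is
the number of *check units* — one trio check when both parents are
genotyped at a SNP, one duo check when exactly one is — so a trio with an
impossible child genotype contributes rate 1, not 0.5.

# Degenerate inputs and tie-breaks

* Markers before the first or after the last map anchor are extrapolated
  at the terminal interval's local rate and floored at 0 cM; equal-cM
  anchor plateaus (recombination deserts) interpolate to a constant.
* QC categories are disjoint in a fixed order (excluded chromosome →
  Mendelian → ungenotyped → monomorphic → call rate), so the report's
  counts always sum to the input total and a second pass removes nothing.
* Joint monomorphism is judged on the pooled sample: a SNP fixed in four
  lines but segregating in one is kept.
* The major haplotype of a region breaks frequency ties
  lexicographically, so permuting samples never changes the table.
* The XP-CLR quantile threshold uses midpoint interpolation and keeps all
  cutoff ties; with 1,000 distinct scores and `top_fraction = 0.005`,
  exactly 5 windows survive.
* `naive_impute()` draws each missing allele from the within-line
  frequency (pooled fallback when a line has no call), is deterministic
  given its seed, and never invents phase: the dataset's phase flag
  reflects the GT separators of the source, and haplotype extraction
  separately requires completeness.

# Known limitations

* The composite likelihood is a deliberate simplification: no proper
  drift transition density (no boundary atoms), no two-locus terms, no
  selection coefficients in natural units.  Absolute CLR values are not
  comparable across datasets; ranks within a comparison are what the
  pipeline uses.
* With ~20 kb marker spacing, XP-EHH significance at P < 0.05 marks ~5 %
  of SNPs under the null by construction; the 200 kb clustering then
  yields many zero-length regions, and the cross-method intersection —
  not the XP-EHH call alone — is what controls false positives.
* Lines drifting from one shared base population have positively
  correlated false-positive regions (shared low-diversity segments), so
  cross-line consensus under the null is rarer than single-line calls but
  more common than an independence (product-of-coverages) argument
  suggests.  On a 60 Mb validation genome the per-line null candidate
  coverage averages ~3.5 % with a heavy right tail (maxima near 8–10 %
  across lines and replicates), and null consensus coverage (0.4–3 %) can
  exceed the smallest single line's coverage.  A larger genome averages
  this variance down; the tail behaviour is worth remembering when
  interpreting any single line's coverage on real data.
* ZHp region calling is exposed without a default threshold; the Z scale
  is comparable across lines but the choice of cutoff is study-specific.

# Validation design

Every operation with a closed-form or enumerable answer is tested against
an independent oracle computed in the test itself: exhaustive
pair-counting for EHH, a re-implemented trapezoid for iHH, explicit
segment search for map interpolation, per-position sweeps for every
interval operation, brute-force pairwise correlation for LD weights, and
the deterministic recursion $p' = p(1+s)/(1+sp)$ for the selected-allele
trajectory.  Stochastic end-to-end properties (sweep recovery by the
consensus, ZHp localization, drift-scale recovery, null coverage) are
measured over seeded replicates at the default simulation scale; the
acceptance script reruns them from scratch and reports the measured
rates.
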