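---
title: "Models and methods behind methylaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methylaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylaging)
```

# Overview

`methylaging` characterises aging-related DNA methylation change in
whole-genome bisulfite sequencing (WGBS) cohorts. A molecular marker
can relate to age in more than one way — drift linearly across the
lifespan, change transiently around a particular age, or differ in
level between young and old — so the package implements three
complementary analyses over the same per-CpG count data:

1. **aDMP regression** — per-CpG ordinary least squares of percent
   methylation on age, adjusted for covariates; CpGs with `p < alpha`
   are aging-associated differentially methylated positions.
2. **Sliding-window analysis (SWAN)** — a 10-year window moved along
   the cohort's age axis, testing each feature between adjacent age
   windows; the per-center count of significant features localises
   *when* methylation changes.
3. **aDMR calling** — local-regression smoothing of each sample's
   methylation profile along the genome, a young-baseline t-statistic
   between young and old groups, and grouping of extreme loci into
   regions.

An annotation layer links positions and regions to genes and CpG-island
context, intersects the three result sets, and tests gene lists for
over-representation against arbitrary GMT gene-set collections.

# Input model and conventions

The pipeline consumes Bismark-style cytosine reports: one row per
cytosine with chromosome, 1-based position, strand, methylated and
unmethylated read counts, and sequence context. Internally every
coordinate is 1-based inclusive; BED input/output (0-based half-open)
is converted only at the I/O boundary, so well-formed BED records
round-trip exactly.

A CpG is palindromic, so the two strands report the same methylation
state. By default `read_cytosine_report()` collapses the minus-strand
cytosine at position `p` into its plus-strand partner at `p - 1` by
summing counts; collapsing never changes genome-wide count totals, and
it is exposed as a flag because some pipelines pre-collapse. Datasets
are assembled over the union of loci across samples with `N = 0`
marking absence, which lets the coverage filters implement the literal
"covered at least k-fold in *all* samples" policy (10x for the
position-level analyses, 2x for the region analysis; a
fraction-of-samples relaxation exists behind `min_fraction`). The 10x
filter is applied after strand collapse, where the collapsed counts
are the ones being modelled.

# aDMP regression

For locus $j$ and subject $s$, with $y_{js}$ the percent methylation
$100\,M_{js}/N_{js}$:

$$y_{js} = \beta_{0j} + \beta_{aj}\,\mathrm{age}_s +
  \gamma_j^\top z_s + \varepsilon_{js}$$

where $z_s$ holds the covariates (sex, race and BMI by default;
the myosin-derived muscle fiber ratio
$\mathrm{my7}/(\mathrm{my1}+\mathrm{my2}+\mathrm{my4})$ can be added
as a plain covariate). The age coefficient is reported in percentage
points per year with a two-sided t-test on $n_{used} - k - 1$ degrees
of freedom. Zero-coverage entries are dropped listwise per locus;
loci with fewer than $k + 2$ observations, zero variance, or a
rank-deficient design are flagged and excluded from the BH
multiplicity count.

With one observation per subject no random-effect grouping is
identifiable, so the default fit is OLS; a random-intercept mode
(fitted via lmerTest) is available for genuinely repeated designs.
Significance is called on the per-CpG p-value (`alpha = 0.05`), with
BH q-values reported alongside for FDR-based selection.

# Sliding-window analysis

Centers are integer-spaced ages $c$ with both windows inside the
observed range ($c - w \ge \min(\mathrm{age})$ and
$c \le \max(\mathrm{age}) - w$, $w = 10$ years) and at least 5
subjects per window — boundary centers would compare against windows
with little or no data and report artifactual hits, so they are
excluded. At each center the default comparison is the *adjacent*
one: subjects in $[c-w, c)$ versus $[c, c+w)$, tested per feature by a
linear model on an intercept and a window indicator. Without
covariates this is algebraically the pooled equal-variance two-sample
t-test and is computed in closed form for all features at once; the
test suite checks the equivalence to $10^{-10}$. BH correction is
applied across features within each center, and the per-center count
of features with $q < 0.05$ forms the profile.

A second mode, `mode = "outside"`, compares subjects inside
$[c - w/2, c + w/2]$ against all others. The two modes answer
different questions: a transient, episode-like shift that is active on
an age interval produces *zero* adjacent-window difference at its own
center (both windows are equally affected) and peaks instead at its
onset and offset, whereas the inside-vs-outside comparison peaks at
the episode's center. The adjacent mode is the default as the more
literal sliding-window reading; recovery of a planted episode's center
age is validated in the outside mode, and the test suite asserts the
onset/offset behaviour of the adjacent mode on the same data.

# aDMR calling

Each sample's methylation profile is smoothed along the genome with a
local weighted quadratic: for each locus, the smallest symmetric locus
window holding at least `min_loci = 70` loci and spanning at least
`min_width = 1000` bp (truncated at cluster boundaries; clusters break
at gaps above `cluster_maxgap = 1e8` bp and at chromosome ends) is fit
by weighted least squares with tricube kernel weights in scaled
distance, multiplied by read coverage. Degree-2 polynomials are
reproduced exactly, constants are preserved, and loci with no coverage
receive the fitted value — imputation from neighbours, which is the
point of smoothing at ~10x depth. Clusters with fewer than 3 covered
loci fall back to the coverage-weighted cluster mean and are flagged.
Positions are rescaled per window before solving, and the windowed
normal equations are solved in compiled code with a pseudoinverse
fallback for degenerate geometry.

Subjects are split at a threshold age (inclusive `age >= t` or
exclusive `age > t`; both conventions occur in practice and both are
supported). The per-locus statistic is

$$t_j = \frac{\bar{x}_{old,j} - \bar{x}_{young,j}}
  {\max(s_j, s_{floor})}, \qquad
  s_j = \mathrm{sd}_{young,j}\sqrt{1/n_y + 1/n_o}$$

Methylation variability increases with age, so the *young* group
supplies the baseline variance. Two numerical guards are deliberate
choices where the statistic alone is under-determined: the denominator
is floored at the 0.75 quantile of all per-locus $s_j$ (without a
floor, near-zero-variance loci produce unbounded t), and the
young-group sd is scaled by $\sqrt{1/n_y + 1/n_o}$ so t is
unit-consistent with a two-sample statistic; both are configurable. A
running local mean over ±50 loci within each cluster (shrunk at edges)
is subtracted from the t track, removing large-scale regional drift so
that the extreme-value cutoff picks out local change; ±50 loci is of
the order of half a smoothing window, large enough to estimate the
regional baseline and small enough not to erase region-scale signal.

Regions are maximal runs of consecutive loci with $|t| \ge 4.6$,
constant sign, and inter-locus gaps of at most 300 bp, within one
cluster. Each run is reported with its member-CpG count, direction
(hyper/hypomethylated in old), mean smoothed difference, and area
statistic (sum of corrected t). No minimum CpG count is imposed by
default (`min_cpgs_per_dmr = 1`); region length is left to emerge
from the data, with a filter available.

# Annotation and enrichment

Features link to genes in two ways: overlap with a transcript span
(*intragenic*, distance 0) or a strand-aware TSS within 200 bp on
either side (*tss-proximal*, signed distance negative upstream). A
feature may link to several genes; summary counting prioritises
intragenic, which is how intragenic fractions are reported (rounded to
the nearest percent, halves away from zero). CpG-island context is
`island` (overlap), `shore` (within 2000 bp, boundary inclusive),
`shelf` (2001–4000 bp, following common usage), else `open_sea`. The
three analyses are compared as sets of loci — aDMPs, the union of
SWAN-significant features, and all filtered CpGs inside called aDMRs —
via the seven-region Venn decomposition. Over-representation of a
gene list against a GMT collection uses the upper-tail hypergeometric
probability (equivalent to one-sided Fisher; checked to $10^{-10}$),
BH-corrected across sets.

# The synthetic-data generator

WGBS data of this design are rarely publicly depositable, so the
package ships a generator that emulates the study conditions and
carries a ground-truth ledger for every locus. Defaults: 40 subjects,
ages uniform on 22–83 (real cohorts are described as evenly
distributed; exact ages are supplied verbatim when known), Poisson
coverage with mean 10, CpGs clustered into islands (dense,
low-methylated baselines 0.05–0.25) against a sparse open sea
(baselines 0.70–0.95), and an optional unmethylated lambda spike-in
contig (true methylated fraction 0.005, i.e. ~99.5% bisulfite
conversion) for the conversion-efficiency QC.

The generative model is logit-additive with binomial sampling:

$$p_{sj} = \mathrm{logit}^{-1}\!\big(a_j + b_j(\mathrm{age}_s - \bar a)
 + \mathrm{wave}_j(\mathrm{age}_s) + \mathrm{step}_j(\mathrm{age}_s)
 + \epsilon_{sj}\big),\quad
 N_{sj} \sim \mathrm{Pois}(\lambda),\;
 M_{sj} \sim \mathrm{Bin}(N_{sj}, p_{sj})$$

The subject-level logit noise $\epsilon_{sj} \sim N(0, 0.5)$ induces
beta-binomial-like overdispersion typical of between-subject WGBS
variation. Three planted effect classes mirror the three analyses:
linear slopes (percentage points per year, converted to a logit slope
by the logistic derivative at the baseline,
$b = (\mathrm{slope}/100)/(p_0(1-p_0))$), age-window "waves" (a delta
active while $|\mathrm{age} - c| \le h$; default half-width 5 years, a
10-year episode matching the SWAN window), and regional steps (a delta
for subjects at/above a threshold age, applied to every CpG in an
interval — typically a whole island, which is also how short real
aDMRs survive wide smoothing: the 300-bp grouping rule bounds the
called region at the dense cluster). Step and wave deltas are
converted exactly at the baseline,
$\Delta = \mathrm{logit}(p_0 + \delta/100) - \mathrm{logit}(p_0)$,
clamped with a warning when a delta would push a fraction outside
(0, 1) — note that large negative deltas saturate in low-methylated
islands. Coverage truncation keeps $N = 0$ entries so the
missing-data path is always exercised.

What the generator does *not* emulate: read-level artifacts (m-bias,
conversion errors within reads), spatial correlation of methylation
beyond the planted structure, batch structure beyond an optional
per-(locus, batch) offset, and non-uniform age sampling. Passing tests
therefore demonstrate correctness and calibration of the statistics
under a clean generative model, not robustness to alignment-level
artifacts, which are out of scope upstream of cytosine reports.

# Validation scale and calibration checks

The validation suite runs at desk scale, chosen so each check is
informative yet quick: all-null calibration cohorts use 5,000 CpGs and
40 subjects (type-I error of the aDMP test within 0.05 ± 0.01);
region-recovery genomes use 1,000 CpGs over 2 Mb with a planted
10-CpG island region (delta +30 points, 20+20 subjects, 30x coverage);
specificity uses 20 replicate null genomes (zero called regions in at
least 95%); SWAN recovery plants 200 episode CpGs centered at age 52.
Calibration cohorts for the position-level tests are simulated at 30x
and filtered at the stage's policy, except the type-I check, which is
run at the 10x design depth with a 2x filter — under a Poisson(10)
depth, demanding 10x in all 40 samples retains essentially no loci,
which is a property of the homogeneous simulation rather than of real
libraries whose depth varies by sample. `scripts/acceptance.R`
recomputes all of these quantities from scratch under a caller-chosen
seed.

Two reporting notes. First, region recovery is scored by interval
Jaccard against the planted truth; the called run occasionally drops
an edge CpG whose corrected t falls just below the cutoff, or sweeps
in a neighbour within 300 bp, so the statistic fluctuates with the
seed even when the region is plainly found. Second, smoothing spreads
a strong planted signal into sparse flanking loci, which can surface
as isolated single-CpG calls near a true region ("echoes"); the local
mean correction suppresses most but not all of them. Both behaviours
are inherent to the smoothing-based statistic, not implementation
artifacts.

# Known limitations

- The smoother is the tricube/degree-2 local quadratic only; other
  kernels or degrees are recorded in `smooth_params` for provenance
  but not implemented.
- The t-statistic has no permutation-based significance; the ±4.6
  cutoff is a fixed operating point, and downstream interpretation of
  calls is the user's.
- `ora_hypergeometric` treats gene sets as flat lists; no topology or
  tissue-specific background beyond the supplied universe.
- The pipeline holds all counts in memory; genome-scale WGBS (tens of
  millions of CpGs) would need chunking by chromosome, which the
  per-chromosome clustering already anticipates but the orchestration
  does not implement.
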