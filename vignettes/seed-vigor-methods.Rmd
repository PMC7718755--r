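---
title: "Methods: pouch-image seed-vigor phenotyping and iterative mixed-model GWAS"
author: "oatvigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pouch-image seed-vigor phenotyping and iterative mixed-model GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The phenotyping model

Germination pouches photograph seedlings against gray germination paper:
roots and shoots image as bright (white to light gray) curvilinear or
upright structures on a darker, roughly uniform background. Segmentation
is therefore a global threshold problem, and the threshold is anchored to
the image itself: `threshold = k x median(gray)`, with `k = 1.7` on the
blue channel for roots (the blue channel separates roots from the paper
best) and `k = 1.4` on the luminance conversion for shoots. The median is
a robust estimate of the background level because background pixels
dominate the frame; multiplying it by `k > 1` puts the cut between
background and structure.

Foreground is *strictly above* the threshold. This choice makes a
constant image segment to an empty foreground for any `k > 1`, which is
the right degenerate behavior. Thresholds are clipped to the 8-bit range.
The per-batch manual tweaking a human operator would do is exposed as an
optional multiplier (`batchK`) rather than automated; automating it would
hide a judgment the operator should own.

Connected components are labeled under 8-connectivity by default
(ImageJ-like; thin diagonal roots stay connected), 4-connectivity being
available. Labeling is deterministic: particles are numbered by their
first pixel in row-major order, so reruns and downstream logs are
byte-stable. Particles of **at most 300 px are removed as noise**; shoots
are the particles **strictly above 300 px**. The published rule gives
"between 0 and 300 pixels" for noise and "300 to infinity" for shoots; we
resolve the shared boundary as complementary intervals (<= 300 out,
> 300 in) so no particle is both noise and shoot. Large artifacts that a
human would erase by hand are handled by an optional exclusion-region
mask instead of manual edits.

Root surface area is the summed pixel count times the calibration's area
scale; with `p` px per mm, one pixel is `1/p^2` mm^2. The two built-in
calibrations are the study sites' grids: 450 px = 30 mm (15 px/mm) and
222 px = 25.4 mm. Shoot length is the Feret diameter — the maximum
pairwise distance between pixel centers — computed on the convex hull
(which contains the extremal pair) and checked in tests against a
quadratic-time all-pairs oracle. Pixel coordinates are 0-based and
row-major; boundary points are pixel centers, so a 1x100 px bar has Feret
diameter 99 px. Root and germinated-seed counts are operator-supplied
metadata: the study counted them visually, and we do not pretend to
automate that.

## Traits and cleaning

Per line and day: root surface area RSA_i (mm^2) and mean shoot length
SL_i (mm), i in {3, 4, 5}; RN = total roots / germinated seeds; AVRSA =
RSA_5 / RN; growth rates RG_i = RSA_i − RSA_(i−1) and SG_i = SL_i −
SL_(i−1); relative rates RRGR_i = RG_i / RSA_(i−1) and SRGR_i = SG_i /
SL_(i−1). The SRGR definition deserves a note: the published trait table
prints the formula SG_i / SG_(i−1) but describes "growth rate divided by
the shoot length at the earlier time point" (units day^-1, paralleling
RRGR). We implement the description — it is the unit-consistent reading —
and keep the literal formula behind `srgrLiteral = TRUE`. Missing inputs
propagate; divisions by zero become `NA` with a logged reason, never an
error.

Cleaning rules are location-keyed with the published values as defaults:
root records are dropped when RG_5 < 7 (Taipei) / < 4 (Aberdeen)
mm^2 day^-1 — strictly below, so a line at exactly the cutoff is kept —
or the image quality category exceeds 2, or fewer than 5 seeds
germinated; shoot records when SG_5 < 12 / < 4 mm day^-1 or the emergence
rule fires. The published emergence wording ("discarded if more than one
shoot or three shoots were emerged") is ambiguous; since its stated
motivation is bias of *average* shoot length under variable emergence, we
default to a minimum-emergence reading (require more than 1 emerged shoot
in Taipei, more than 3 in Aberdeen) and provide the literal maximum
reading as an option. The filter is idempotent, partitions records, and
on violation-free synthetic data removes nothing — all tested.

## Augmented design, batch adjustment, heritability

Test lines are unreplicated within a location; six check varieties repeat
in every batch. The batch effect is the marginal mean of the checks in
that batch, centered on the grand mean of the per-batch check means, so
the adjustment is mean-zero over batches and leaves the trait scale
intact (the published text fixes the marginal-mean estimator but not the
reference point; centering is our choice). Adjusted value = raw − batch
effect, checks adjusted identically. After adjustment the between-batch
variance of check means is zero by construction, which the tests verify
numerically.

The replicated checks also carry the variance analysis: a two-way
fixed-effects ANOVA (genotype + batch) on the check subset — balanced
when every check appears in every batch, so the sequential sums of
squares are the classical decomposition — and broad-sense heritability
from its mean squares, σ²g = (MS_G − MS_E)/r clipped at zero, H² =
σ²g/(σ²g + σ²e). The exact published H²-from-SS formula is not printed;
this mean-squares estimator is declared as ours. When a check is missing
from a batch the estimate is reported `NA` rather than computed from an
unbalanced table. Two properties are worth knowing: the σ²g estimator is
unbiased, but H² is a ratio and carries a small-df Jensen bias — with six
genotypes (5 df) the downward bias at true H² = 0.8 is about 0.05, with
twelve genotypes about 0.02. The recovery simulations therefore use
twelve replicated genotypes; with the six-check design, reported H²
values should be read as mildly conservative.

Genotype-by-location interaction is tested by an ML likelihood-ratio
test (lme4): random genotype (reduced) vs. random genotype +
genotype-by-location (full), χ² with 1 df, AIC/BIC reported. ML rather
than REML because the models are also compared by information criteria.
The 1-df reference ignores that the interaction variance sits on its
boundary, matching the published test; a halved-mixture p-value is one
flag away. Locations are analyzed separately downstream, as in the study.

## Marker QC and the association model

Marker filters are missing rate < 0.2, heterozygosity < 0.1, MAF >= 0.05,
with the boundary semantics exactly as printed (strict, strict,
inclusive) and tested at the boundaries. Missing-call handling for the
design matrix is not specified by the study; we mean-impute per marker,
which preserves allele frequency and adds no association signal.
Heterozygous calls stay 1.0 in the additive coding.

The association procedure is the fixed/random-effect iteration. The FEM
is ordinary least squares of the phenotype on intercept, 0–5 genotype
PCs, the current pseudo-QTN columns, and the tested marker; the marker's
t-test gives the p-value. Implementation: all markers are residualized
against the fixed design in one matrix operation, so a scan is O(nm);
markers collinear with the design (including constants) are flagged with
p = 1; pseudo-QTN columns collinear with earlier ones are dropped and
logged; a pseudo-QTN is re-tested with itself excluded from the
covariates, otherwise its own test is degenerate and a true hit would
report p = 1.

Candidates are markers with p < α/m (α = 0.1). The published account
does not describe de-clustering; we keep, within each linkage group, only
the most significant marker in any window narrower than `minSepCM`
(default 1 cM — the panel's LD decays at about this scale) — a
deliberate simplification of the original method's multi-bin search.
Unmapped markers are tested but exempt from distance de-clustering.

The REM is y = Xb + u + e with Var(u) = 2Kσ²a, K built *only from the
pseudo-QTN columns*: centered, cross-multiplied, scaled to mean diagonal
1 — PSD by construction and of rank at most the pseudo-QTN count t. The
variance-ratio profile (REML) is maximized in one dimension on a log grid
refined by `optimize()`; because 2K = Z₂Z₂' with Z₂ of width t, the
inverse and determinant of I + δ·2K reduce to t-dimensional quantities
and a fit costs O(nt²) rather than O(n³). Degenerate cases fall to the
boundary δ = 0 (no genetic variance) rather than erroring. The pseudo-QTN
set itself is chosen by evaluating nested prefixes of the
significance-ordered candidate list (empty set included, capped at 20)
and keeping the prefix with the highest restricted likelihood — a
tractable, monotone-in-evidence alternative to all-subsets search. FEM
and REM alternate until the pseudo-QTN set repeats any earlier state
(cycle-safe) or `maxIter = 10`; the last FEM scan is the report. The
whole procedure is deterministic given its inputs.

PCs enter both FEM and REM (the published account is silent on the REM;
including them keeps the two models' fixed parts identical). The PC count
is chosen by genomic inflation: λ = median(χ²₁(p)) / 0.4549 per candidate
count, picking the smallest count whose |λ − 1| is within twice the
sampling standard error of a median-based λ at the scanned marker count —
differences indistinguishable from noise should not buy covariates. QQ
data tables are emitted for the human look the published workflow used.

Thresholds: Bonferroni α/m with α = 0.1 and configurable divisor — the
published threshold 4.3e-6 against 0.1/22,767 = 4.39e-6 suggests their
divisor was a post-QC count that is not printed, so the divisor is a
parameter, defaulting to the scanned marker count. The post hoc FDR rule
is Benjamini–Hochberg at q = 0.1 on the final scan, per trait and
location, via `stats::p.adjust` and tested against an enumeration oracle.

## Post-GWAS summaries

A unique locus is a unique (linkage group, cM) position at the 0.1 cM
resolution positions are reported at; several SNPs at one position are
one locus, a SNP associated with several traits counts once, and every
unmapped SNP is its own locus (this convention is what makes the packaged
association-table transcriptions reproduce their published 41/34 and
16/16 SNP/locus counts). A co-location tolerance is available but
defaults to 0. Homeologous regions are user-supplied intervals grouped
into sets; loci map by closed-interval containment, a set is reported
when at least two of its member regions carry loci, overlaps resolve to
the nearest midpoint with a log entry, and the packaged region map is
synthetic (the real consensus-map regions are external data). Allele
contrasts summarize a marker's classes (heterozygotes separate) over the
panel, over subgroups, and over the union of the top and bottom trait
fractions (default 10%), the view in which a weak panel-wide effect can
show its worth in specific germplasm.

## The synthetic-data generator

The generator's defaults are the study conditions: 650 test lines + 6
checks, 22,767 markers on 21 linkage groups, MAF floor 0.05, residual
heterozygosity 2% (inbred lines; safely under the 0.1 filter), a weak
two-subpopulation structure (20% southern-like, allele-frequency
divergence 0.1), 8 batches, batch-effect sd 1 on a unit-residual trait
scale — values the study states or, where it does not (map length 150 cM,
divergence, the sd scales), a single choice of what a practitioner would
call realistic, made once and not revisited. Phenotypes follow the FEM's
own generative form: additive planted QTN + subpopulation shift + batch
effect + Gaussian residual; when a target signal fraction `h2` is set,
the residual sd is solved from the realized genetic variance. One global
seed fans out to per-component streams, so the genotype draw does not
shift when the image count changes.

Images are rendered without anti-aliasing — a pixel is in a stroke or it
is not — precisely so the truth mask is exact and the segmentation
contract can be tested to zero tolerance; specks are placed with a
one-pixel clearance so they never 8-connect to a structure, keeping the
after-denoising area exact too. What the renderer deliberately does not
emulate: anti-aliased edges, illumination gradients, root overlap with
shoots, shriveling, humidity artifacts. Passing segmentation tests
therefore certify the *algorithmic* contract (threshold, labeling, size
filter, measurement), not robustness to photographic degradation — on
real images the empirical threshold and the quality-category QC do that
work. Likewise the genotype simulator draws markers independently (no
LD), so de-clustering and locus deduplication are exercised by
construction, not by realistic haplotype structure.

## Numerical choices and test scale

Collinearity in the scan is declared at residual sum of squares below
1e-10·n; the REM grid spans δ in [1e-6, 1e6]; kinships are PSD by
construction and user kinships can be eigen-clipped. Monte-Carlo
assertions in the suite carry binomial/standard-error margins (e.g.
family-wise error over 50 null panels is compared to 0.1 + 2·SE), which
is sampling slack, not tolerance widening. Problem sizes in the default
test run are the package's own choices: 100 rendered pouches for exact
segmentation, 50 null panels of 200 lines x 1,000 markers for calibration,
50 panels of 600 lines x 3,000 markers with three planted QTN (effect
0.4 sd, MAF >= 0.2) for recovery, 200 replicates for heritability — small
enough to run routinely, large enough that the stated tolerances bind.

## Known limitations

No SNP calling, no LD pruning, no BLAST searches (context sequences are
exported as FASTA for external tools), no circular ideograms (the
homeolog tables carry the information). The published SNP lists and the
study's Table-level numeric values are not reproducible without the real
panel's raw data; what the package reproduces exactly are the printed
headline counts, ranges and arithmetic, and what it demonstrates
statistically it demonstrates on synthetic data with known truth.
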