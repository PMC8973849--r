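---
title: "Methods: graded NMD target discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded NMD target discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradedecay)
```

This vignette is the package's account of its models and the choices made
where the design was genuinely open. The pipeline nominates candidate NMD
target genes in a WT / Smg5 KO / Smg6 KO / Smg7 KO embryonic stem cell
panel by requiring two independent lines of evidence per gene — slower
mRNA decay in the knockouts and up-regulation that follows the phenotype
gradient — and provides the satellite analyses such a study uses (GO
over-representation, exon conservation, RIP-seq enrichment, interaction
proteomics).

## Half-life estimation from SLAM-seq

**Model.** During a uridine chase after 4SU labeling, the probability
that a sequenced T position of a labeled transcript reads as C decays
exponentially at the transcript's degradation rate. With labeling rate
$r_0$ (conversion probability at chase time 0), background rate $b$
(spurious T>C calls in unlabeled RNA) and half-life $t_{1/2}$:

$$ r(t) = b + (r_0 - b)\,2^{-t/t_{1/2}}. $$

The estimator subtracts the measured background (a matched no-4SU
sample), then regresses $\ln(r(t) - b)$ on $t$ by ordinary least squares
with a free intercept; $k = -\text{slope}$ and $t_{1/2} = \ln 2 / k$.

**Why OLS on logs with a free intercept.** The single-exponential model
is linear after the log transform, so the fit is closed-form, seed-free
and has no convergence failures; a grid-search nonlinear least-squares fit
on the log scale returns the same optimum (the tests assert agreement to
1e-6), so nothing is lost. The intercept is left free rather than anchored
at $\ln r_0$ because the realized conversion rate at $t = 0$ is itself an
estimate; anchoring it would propagate its sampling error into the slope.

**Degenerate inputs.** Background-subtracted rates $\le 0$ become
missing rather than being clamped to a small positive number: a clamped
value would enter the regression as an arbitrarily low leverage point and
bias the slope. Fits require three usable timepoints; flat or rising
profiles return `nonpositive_k`, insufficient data `nonpositive_rate`,
and transcripts failing the CPM filter `low_cpm`. Half-lives exist only
for `ok` fits.

**Tunable parameters.** CPM threshold 2 (counts per million of the
conversion table's per-sample totals — the table itself defines the
library, since no external library size is available at this stage);
chase times 0/180/360 min; the half-life set requires a strict
$>10\%$ increase in all four KO-vs-WT comparisons (2i and N0–N6, Smg5
and Smg6 KO). Strictness at exactly $+10\%$ is a convention; the
anti-monotonicity of the set in the threshold is asserted in tests.

## The synthetic SLAM-seq generator

`sim_slam()` draws per-transcript, per-condition baseline half-lives
uniformly from 30–600 min and multiplies them by per-genotype effects
(default 1.3 for Smg5/Smg6 KO) in a configurable fraction of transcripts
(default 0.4 — NMD regulates a subset of the transcriptome). Defaults
`labeling_rate = 0.08` and `background_rate = 0.001` are typical
SLAM-seq scales; no published rates exist for the emulated experiment, so
they are package choices. Binomial mode draws Poisson coverages and
binomial conversions; exact mode emits rounded expectations so recovery
tests can be equality tests.

**What exact mode shows and does not show.** Exact-mode recovery tests
use deep coverage (`t_coverage = 1e6`): at moderate coverage a transcript
with a 30-min half-life decays below the 0.001 background by the 6-h
point after count rounding, and its third timepoint is correctly flagged
unusable. That is a detectability property of any pulse-chase design, not
an estimator property, so the noiseless-limit tests remove it while the
stochastic recovery test (500 transcripts, coverage 5000, binomial noise,
median relative error < 10%) keeps it. Passing these tests shows the
estimator inverts its own forward model; real SLAM-seq adds mapping
biases, SNP contamination and isoform mixing that the generator does not
emulate.

## Graded differential expression

**Test.** Each KO is compared with WT per timepoint on
$\log_2\text{CPM}$ (pseudocount 0.5) with a fold-change-threshold test of
the interval null $|\beta| \le \tau$, $\tau = \log_2 1.5$, using the
pooled two-sample variance with $n_a + n_b - 2$ degrees of freedom:

$$ p = P\!\left(T > \frac{|\hat\beta| - \tau}{se}\right)
     + P\!\left(T > \frac{|\hat\beta| + \tau}{se}\right). $$

With $\tau = 0$ this is exactly the two-sided pooled t-test (asserted to
1e-12). The original analysis used limma's moderated framework; the
unmoderated closed form is the default here because it is dependency-free
and exactly testable, and `moderate = TRUE` enables an empirical-Bayes
variance squeeze (method-of-moments inverse-chi-squared prior across
genes) whose results track `limma::treat` closely (correlation of log
p-values > 0.97 in the cross-check test). Zero-variance genes resolve by
the threshold alone: $p = 1$ if $|\hat\beta| \le \tau$, else $p = 0$.

**Multiple testing.** BH is applied within each KO-vs-WT contrast per
timepoint. The adjustment universe is not recorded in the emulated
analysis; per-contrast adjustment is the common default and keeps
contrasts exchangeable.

**Classification.** Genes with padj ≤ 0.01 in at least one KO are
classified by fold-change sign agreement across the three KOs; among
`up_all` genes the graded set requires the strict point-estimate ordering
$\beta_{Smg5} > \beta_{Smg6} > \beta_{Smg7} > 0$ with no significance
requirement on the pairwise orderings and no tie tolerance. Hierarchical
cluster numbering of heatmaps is deliberately replaced by this
deterministic sign-pattern logic. The nesting graded ⊆ up_all ⊆
significant is asserted on every run.

**Generator design.** `sim_counts()` plants a graded-up class (default
log2 effects 2 / 1.5 / 1 for Smg5 / Smg6 / Smg7 KO — strictly ordered,
all clearly above $\tau$) and an equally down-regulated class on a
gamma-distributed baseline, renormalized so every sample's expected
library is the configured size. Defaults of four replicates per group
(two independent KO clones sequenced in duplicate is the natural design
for clonal ESC lines) and NB dispersion 0.02 describe a well-powered
clonal-line experiment: with three replicates the TREAT test's df = 4
tails are too heavy for true four-fold effects to survive BH at
padj ≤ 0.01, which is a fact about such designs worth knowing before
running one. In exact mode replicates are identical and recovery of the
planted sets is exact; in binomial mode the tests require sensitivity
> 0.9 and specificity > 0.95 for graded detection.

## Candidate integration

Candidates per timepoint are the intersection of the gene-level
half-life set with that timepoint's graded set; the core set intersects
both timepoints. Transcript-level half-life calls collapse to genes by
the any-transcript rule (a gene qualifies if any of its transcripts
does), since per-transcript resolution is not preserved downstream. All
set invariants are asserted at construction, and tightening any upstream
threshold can only shrink the core (tested). Reports are ordered
lexicographically so repeated runs are byte-identical.

## GO over-representation with term clustering

Terms are restricted to the background universe before anything else;
the 5–500 size filter applies to the restricted size by default (the
alternative reading — filter on raw annotation size — is a toggle). The
enrichment p-value is the hypergeometric upper tail $P(X \ge k)$
(one-sided; enrichment is what is reported; a two-sided switch exists).
Terms differing by at most five genes are clustered by complete-linkage
hierarchical clustering on the L1 distance between binary membership
vectors, cut at height 5: complete linkage is chosen precisely so the
"differ in at most five genes" property holds for every within-cluster
pair, which single or average linkage would not guarantee. Each cluster
is represented by its smallest term (fewest annotated genes; lexicographic
tie-break), and BH runs over representative p-values only —
non-representatives inherit no adjusted value and are reported through
their representative.

## Exon conservation

Per-base classification with precedence CDS > UTR > intron across all
protein-coding transcripts of a gene (a transcript is protein-coding if
it has a CDS; UTRs of non-coding transcripts are ignored); intron is the
remainder of the gene body, so per-gene class lengths always sum to the
gene-body length (asserted). Coordinates are 0-based half-open
internally; GFF3 is read 1-based inclusive and converted; MAF blocks
follow the MAF convention (0-based starts, minus-strand starts counted on
the reverse strand).

Identity is $\text{matches} \times 100 / \text{length}$ with length the
region's reference-genome length: unaligned or gapped reference bases
contribute zero matches but full length. This denominator choice is what
makes percentile statements meaningful — a poorly alignable region scores
low rather than dropping out. Soft-masked columns count as eligible
matches by default (toggle available). The percentile of a focal region
is the percent of the population with strictly higher identity, with the
focal region excluded.

The toy-genome generator realizes target identities exactly by
substituting a computed number of bases per region (targets implying
non-integer mismatch counts are rejected), writing GFF3 and a gap-free
pairwise MAF; round-trip equality through `classify_regions()` and
`region_identity()` is the oracle. Real whole-genome alignments add
gaps, inversions and unalignable regions the toy construction does not
represent; the scorer handles gapped and minus-strand blocks but the
package does not construct alignments.

## RIP-seq enrichment

The universe is transcripts with CPM ≥ 1 in every input sample. "Bound"
requires IP > empty-vector IP (pooled t on log2 CPM, $\tau = 0$,
BH ≤ 0.05, positive fold change). The high-confidence subset additionally
requires mean IP CPM ≥ 30 and an absolute log2 fold change ≥ 1 in the
IP/input or IP/EV contrast at padj ≤ 0.05. The published description of
the latter filter leaves the ratio orientation ambiguous, so the required
direction is a parameter (`either` by default) rather than a guess. An
abundance-outlier flag is deliberately not implemented: the corresponding
published claim names no method, and an invented one would carry its
authority.

## Label-free proteomics

Filtering removes reverse hits, contaminants, modified-site-only
identifications, groups with fewer than two razor peptides, and groups
lacking three quantified values in at least one experimental group — the
permissive reading of an ambiguous phrase; the strict every-group reading
is a toggle. Renormalization subtracts each sample's median over a
user-specified background protein subset and anchors at the grand median
so the absolute scale is preserved; it is idempotent and equalizes
background medians to machine precision. Imputation models the whole
observed matrix (not per sample): missing cells draw from
$\mathcal N(m - 1.8\,s,\ (0.3\,s)^2)$ with $m, s$ the observed mean and
SD — the standard down-shifted normal for left-censored label-free data.
Only missing cells are touched and the draw is seed-stable. Group testing
is the $\tau = 0$ pooled t at 5% BH FDR (moderation optional, as in the
DE module), and isoform-specific interactor sets partition the union of
the two baits' bound sets.

The proteomics generator defaults to intensity-dependent missingness
(lower-intensity cells more likely missing, calibrated to the configured
overall fraction) because left-censoring is the phenomenon the
down-shifted imputation exists for; MCAR remains available and is what
the imputation-recovery experiments use, since it makes the observed
moments unbiased reference points.

## Problem sizes and numerical conventions

The test suite and acceptance checks run at desk scale by design:
500–2000 features per cohort, 50-repeat null simulations for FDR
calibration, exhaustive hypergeometric verification for margins up to 30.
These sizes give the statistical assertions 3-SE headroom while keeping
the full suite in minutes. Log base 2 throughout; pseudocount 0.5 for
log-CPM; all seeds are explicit and generators restore the caller's RNG
state; reported sets are sorted so outputs are deterministic.

## Known limitations

Upstream read processing (mapping, conversion counting, peptide
quantification) is out of scope — the pipeline starts from count and
intensity tables. Single-exponential decay ignores multi-phase decay and
isoform mixtures. CPM is the only normalization (no TMM/RLE). The
unmoderated default test gives away a little power at very small
replicate numbers compared with moderated frameworks. GO analysis does
not propagate the ontology DAG; the catalog is taken as given. The
conservation module scores pairwise MAF alignments as provided and the
published cross-species percentile values require whole-genome alignments
that are inputs, not products, of this package.
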