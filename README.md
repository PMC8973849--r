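# gradedecay

Identification of phenotypically relevant nonsense-mediated mRNA decay
(NMD) targets in mouse embryonic stem cells, as a tested, reusable R
pipeline. The package is aimed at transcriptomics analysts working with
Smg-factor knockout (KO) panels: it combines SLAM-seq mRNA half-life
estimation with graded cross-genotype differential expression to nominate
candidate NMD target genes, and adds the satellite analyses such a study
needs — GO over-representation with redundancy clustering, exon
conservation scoring from pairwise alignments, RIP-seq enrichment calling,
and label-free proteomics interactor calling. Every stage ships with a
synthetic-data generator with known ground truth, so the whole pipeline is
testable offline without any deposited data.

## The model

**Half-lives from SLAM-seq.** After a 4SU pulse and uridine chase, the
background-subtracted T>C conversion rate of a transcript decays as

    r(t) = r0 · 2^(−t / t½),  k = ln 2 / t½,

so ordinary least squares of ln r(t) on chase time t (free intercept)
gives the decay constant k and half-life t½ = ln 2 / k. Transcripts need
CPM ≥ 2 in every sample of the fitted condition and three usable
timepoints (0, 3 h, 6 h). A transcript enters the *half-life set* when t½
rises by strictly more than 10% in all four direct comparisons (2i and
early differentiation, Smg5 KO and Smg6 KO vs WT).

**Graded differential expression.** Each KO is tested against WT with a
fold-change-threshold (TREAT-style) test of the interval null
H₀: |log₂FC| ≤ τ with τ = log₂ 1.5,

    p = P(T_df > (|β̂| − τ)/se) + P(T_df > (|β̂| + τ)/se),

BH-adjusted per contrast. Genes significant (padj ≤ 0.01) in at least one
KO are classified by fold-change sign pattern (`up_all`, `down_all`,
`mixed`); among `up_all` genes, the *graded* set follows the phenotype
gradient with strict point-estimate ordering β(Smg5) > β(Smg6) > β(Smg7) > 0.

**Candidate targets** are the intersection of the half-life set with the
graded set per timepoint; the core set intersects both timepoints.

The GO stage uses the one-sided Fisher exact (hypergeometric tail) test on
5–500-gene terms, clusters terms differing by at most five genes (complete
linkage on the L1 distance of binary membership vectors), keeps the
smallest term of each cluster as representative, and applies BH over
representatives only. Conservation is percent identity
(matches × 100 / region length) of CDS/UTR/intron regions classified by
per-base precedence CDS > UTR > intron across transcripts. Proteomics
follows the standard label-free route: MaxQuant-style filtering,
background-median renormalization, imputation from a normal distribution
down-shifted 1.8 SD at 0.3 SD width, pooled t-tests at 5% BH FDR, and
isoform-specific interactor set logic.

## Worked example

```r
library(gradedecay)

# simulate a SLAM-seq experiment and estimate half-lives
slam <- sim_slam(slam_sim_config(n_transcripts = 400, seed = 11))
fit  <- fit_halflives(slam$conversions)
glance(fit)
#> # A tibble: 1 × 4
#>   n_fits  n_ok median_halflife cpm_threshold
#> 1   2400  2366            337.             2

# simulate the KO panel RNA-seq and run graded DE
expr <- sim_counts(expr_sim_config(n_genes = 400, seed = 12))
de   <- de_analysis(expr$counts, expr$meta)
glance(de)
#> # A tibble: 2 × 6
#>   timepoint n_genes significant up_all down_all graded
#> 1 2i            400          40     20       20     20
#> 2 N24           400          34     20       14     20

# integrate half-life and graded evidence into candidates
hl  <- consistent_hl_set(fit)
map <- setNames(expr$truth$gene_id, unique(slam$truth$transcript_id))
cs  <- candidate_sets(sort(unname(map[hl])),
                      graded_genes(de, "2i"), graded_genes(de, "N24"))
report_candidates(cs)
#> 4 candidate genes in 2i, 4 at N24, 4 in both
```

2400 fits are attempted (400 transcripts × 3 genotypes × 2 conditions);
2366 succeed — the rest are fast-decaying transcripts whose 6-h signal
falls into the no-4SU background. Of 400 genes, 40 are significantly
deregulated in 2i at padj ≤ 0.01 against the |FC| < 1.5 null, 20 up in
all three KOs, and 20 of those follow the strict Smg5 > Smg6 > Smg7
gradient. Intersecting with the 92 genes showing a consistent >10%
half-life increase leaves 4 candidates supported by both timepoints —
here the simulation planted independent half-life and expression effects,
so the overlap is their chance intersection.

`autoplot()` methods produce the standard views (half-life violins,
graded fold-change profiles, GO dot plots, proteomics volcanoes), and
`tidy()`/`glance()` return tibbles for downstream work.

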