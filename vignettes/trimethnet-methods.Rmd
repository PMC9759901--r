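---
title: "Methods: three-layer methylation-miRNA-mRNA network integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-layer methylation-miRNA-mRNA network integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trimethnet)
```

## The analytical problem

Promoter methylation of a miRNA gene can silence or release that miRNA,
and the miRNA in turn represses its target mRNAs.  In a two-group
case-control design (for instance coronary artery disease patients
against healthy controls, profiled with bisulfite, small-RNA and mRNA
sequencing at n = 5 per group), this cascade shows up as a *regulatory
triplet*: a differentially methylated region (DMR) overlapping a miRNA
promoter, a differentially expressed miRNA, and a differentially
expressed target mRNA, with correlated per-sample levels along the
chain.  The canonical pattern is a hypomethylated promoter with an
upregulated miRNA and downregulated targets (and the mirror pattern for
hypermethylation).

`trimethnet` implements that integration as a chain of small, testable
stages, and ships a synthetic cohort generator with planted triplets so
every stage — and the whole chain — can be validated without any
external data.

## Stage models

### Site calling

At a cytosine with `m` methylated and `u` unmethylated reads, the
methylation level is `m / (m + u)`.  Whether a site is methylated at all
is decided against the null that methylated calls arise purely from
bisulfite non-conversion and sequencing error at rate `p0`:
the p-value is the exact binomial upper tail `P(X >= m | n = m + u, p0)`
and a site is called when coverage reaches `depth_min` (default 5) and
`p <= 0.05`.  `p0` defaults to 0.005, a typical non-conversion rate for
modern bisulfite kits; it is a parameter because it is
protocol-dependent and the screening rule is only as meaningful as this
null.  The "two distribution tests" phrasing that circulates for this
screen is implemented here as the single exact binomial test; nothing in
the procedure requires a second distribution.

### DMR detection

Published DMR callers (the swDMR family among them) do not document a
single canonical algorithm, so the engine here is fixed and fully
parameterized: windows of `window_bp = 1000` advanced by
`step_bp = 100`; a window is testable when it contains at least
`min_cpgs = 3` sites passing the coverage rule in both groups; the
window statistic is Fisher's exact test on the group-pooled (m, u)
counts.  Pooling across the 5 replicates within a group is the default
because per-sample levels at 30-50x coverage are too noisy for a
powered per-window t-test at n = 5; the per-sample Welch alternative is
available as `test = "level_t"`.  Benjamini-Hochberg correction runs
across all testable windows; windows passing `p <= 0.05`, `q <= 0.05`
and an absolute pooled level difference of at least `min_mean_diff =
0.1` are merged when they overlap, keeping the minimum window p.  The
merged region's CpG count and level difference are recomputed over its
full span, and the output contract — sorted, pairwise disjoint regions
that each satisfy every threshold — is enforced after merging, so a
merged span whose recomputed effect dilutes below `min_mean_diff` is
dropped rather than reported in violation of its own screen.  Direction
is `hyper` when cases exceed controls and `hypo` otherwise; an exact
zero difference is unclassifiable and dropped with a warning.

Coordinates are 0-based half-open everywhere inside the package;
1-based formats are converted at the reader/writer boundary.

### Expression screening

miRNA counts are depth-normalized to reads per million (RPM); mRNA
counts are depth- and length-normalized to reads per kilobase per
million (RPKM) using the annotated exon length.  The differential
screen computes `log2FC = log2((mean_case + c) / (mean_control + c))`
with pseudocount `c = 1`, a two-sided Welch t-test on
`log2(value + c)`, and BH Q values.  Welch-on-logs was chosen over a
count GLM for determinism, robustness at n = 5, and because the
screening thresholds — miRNA: `|log2FC| >= 1`, `p < 0.05`,
`q <= 0.05`; mRNA: `p < 0.05`, `q <= 0.05` — are the published style of
criteria this pipeline reproduces, not shrinkage estimates.  The miRNA
preset includes the Q criterion as applied at network construction; a
`mirna_loose` preset without it matches the first-stage screen.
Features that are all-zero in both groups are excluded before testing
(they carry no information and inflate the BH burden); features with
zero variance in both groups get `p = 1` by convention and are logged.

### Promoter assignment and target pairing

The promoter of a miRNA is the strand-aware window `upstream_bp = 2000`
bp upstream of its TSS (`[tss - 2000, tss)` on the plus strand, the
mirrored forward-axis window on the minus strand), clipped at
chromosome bounds; 2 kb is a conventional promoter proxy and the value
is configurable because no single window is authoritative.  DMRs are
matched to promoters of differentially expressed miRNAs by >= 1 bp
half-open interval overlap.  miRNA-mRNA candidates come either from an
external pair table (MiRanda-style exports) or from built-in seed
matching: the default `7mer-m8` site is the exact reverse complement of
miRNA positions 2-8 found anywhere in the 3'UTR, with `8mer` and
`7mer-A1` variants behind a flag.  Full alignment/energy scoring of the
MiRanda kind is deliberately out of scope; exact seed matching is the
reproducible in-repo stand-in.

### Network retention

Candidate edges are scored by Pearson correlation (Spearman available)
on per-sample values: the DMR's coverage-weighted mean methylation
level against miRNA RPM, and miRNA RPM against mRNA RPKM.  The
coverage-weighted region summary was chosen over an unweighted mean of
site levels because per-site depth is uneven and low-coverage sites
carry more noise.  An edge is retained when `p <= 0.05` and
`|r| >= r_min = 0.7`; strict mode (default) additionally requires
anticorrelation (`r < 0`) on both edge kinds plus sign-consistent
endpoints (hypo-up, hyper-down; miRNA and target opposite), the pattern
of a methylation-silenced, target-repressing chain.  Permissive mode
drops the sign constraints and reproduces mixed-direction networks.
The r and p cutoffs are package defaults, not published values; they
sit where a |r| at n = 10 is both nominally significant and practically
large.  When one miRNA promoter overlaps several DMRs all pairs are
kept — there is no best-edge selection.  Triplets are chains whose two
edges share a retained miRNA; network nodes are features with at least
one retained edge.

### Clinical layer

`ttest_from_summary` recomputes two-sided t-tests from printed group
means/SDs/sizes (pooled by default, Welch optional) so published cohort
tables can be checked without subject-level data.
`trait_correlations` correlates feature columns (promoter methylation,
miRNA expression) against clinical traits with pairwise-complete
observations, skipping constant traits with a warning.  `ddct`
implements the qRT-PCR `2^-ddCt` relative-expression transform.

## The synthetic cohort generator

`synth_config()` / `generate_cohort()` draw a complete seeded cohort:

* **Methylation**: CpGs sit at fixed offsets inside each miRNA
  promoter; per-sample coverage is Poisson (`coverage_mean`, default
  30); methylated counts are beta-binomial with mean `meth_base = 0.5`
  and overdispersion `bb_overdispersion = 0.05`.  Beta-binomial rather
  than pure binomial is deliberate: replicate-level biological
  variation is what makes DMR detection nontrivial, and a pure binomial
  generator would make recovery artificially easy.  At planted
  promoters the case mean is shifted by `meth_delta` (default 0.4) in
  the planted direction.
* **Expression**: baseline abundances are log-normal, rescaled to a
  counts-per-million scale so `library_size_mean` (default 1e6) is the
  expected sequencing depth; library sizes are log-normal (sdlog 0.2);
  counts are negative binomial with dispersion `nb_dispersion = 0.05`,
  the standard count-noise model at this depth.  Planted miRNAs are
  shifted by `2^expr_log2fc` in cases (default 4-fold) and their target
  mRNAs by the opposite sign.
* **Sequences**: miRNAs are random 22-mers; 3'UTRs are uniform-random
  ACGT of `utr_length_bp = 500` with one exact 7mer-m8 site planted per
  true pair.  The generator guarantees the planted seed relationships
  are *exhaustive* for planted miRNAs: chance occurrences of a planted
  miRNA's site in any non-target UTR are removed by point mutation.
  Without this, a chance 7-mer (probability ~3% per 500 bp UTR) linking
  a planted miRNA to another triplet's mRNA creates a chain that is
  group-driven at both ends and therefore indistinguishable from truth
  by any correlation filter — a confound of the truth table used for
  scoring, not a property of the method under test.  Decoy miRNAs get
  no planted sites.
* **Clinical traits**: per-group normals with moments resembling a
  small angiography cohort (age, blood pressure, glucose, lipids).  The
  Gensini severity score is generated with a configurable correlation
  (`gensini_r`) to an anchor from the first planted triplet — the
  miRNA's log2 RPM by default, or the planted promoter's methylation
  level — enabling trait-correlation checks at a chosen effect size
  without claiming biological realism.  Gensini itself is consumed as a
  numeric trait, never computed from angiograms.

What the generator does *not* emulate: read-level artifacts (mapping
bias, duplicates, conversion failure beyond the scalar `p0`), genomic
CpG density structure, correlated co-regulation among decoys, isoform
complexity, batch effects, and confounded clinical covariates.  Passing
recovery tests therefore demonstrates the chain's statistical logic
under its stated noise models, not performance on real sequencing data.

## Numerical and degenerate-input choices

* The exact binomial tail is `pbinom(m - 1, n, p0, lower.tail = FALSE)`;
  zero methylated reads give p = 1.
* Zero-coverage sites have undefined level (`NA` in region summaries; an
  error in the scalar `methylation_level`).
* Zero-variance vectors yield an undefined correlation; such candidate
  edges are skipped and counted in `n_skipped`, never silently retained.
* `|r| = 1` maps to p = 0 (the t transform diverges).
* Fisher windows with an exact-zero pooled difference cannot pass
  `min_mean_diff > 0`; with `min_mean_diff = 0` a zero-difference merged
  region is dropped with a warning rather than assigned a direction.
* BH is the FDR procedure everywhere Q values appear.
* Determinism: `generate_cohort` runs on a private RNG stream seeded
  from the config and restores the caller's RNG state, so identical
  configs give bit-identical bundles regardless of ambient RNG use.

## Calibration: what "5%" means for these tests

Two of the package's tests are exact and discrete, and one is a
small-sample approximation, so their null rejection rates sit *at or
below* nominal rather than exactly at it:

* The binomial site test at integer coverage c can only attain sizes
  `P(X >= k)` for integer k, so its exact size at `p_max = 0.05` is the
  largest attainable value below 0.05 — about 0.035 at coverage 30 and
  0.043 at coverage 200 under `p0 = 0.3`.  The calibration suite
  therefore checks the empirical rate two ways: against the nominal 5%
  within two binomial standard errors over 2,000 sites (the
  deep-coverage regime where the discrete gap is small), and against
  the *exact attained size* — computed from the binomial null at each
  realized coverage — over 10,000 sites, which is the rigorous
  statement and holds tightly.
* Welch's t at n = 5 per group is mildly conservative even on ideal
  normal data (size ~0.045) because the Satterthwaite df estimate sits
  below the pooled df.  The null differential screen is checked against
  nominal within two standard errors over 2,000 features, which
  accommodates this known finite-sample deficit.

Neither test is anticonservative anywhere in the tested regimes.

## Problem sizes used by the validation suite

The triplet-recovery experiment runs the full chain at the design it is
meant to stress: 10 planted triplets among 200 decoy miRNAs and 1,000
decoy mRNAs, coverage 50, n = 5 per group, `meth_delta = 0.4`,
`expr_log2fc = 2`, strict mode at `r_min = 0.7`, median over 25 seeded
replicates (about 3.5 minutes on one CPU).  Monte-Carlo checks of
generator moments (planted level difference, planted log2FC, the
Gensini anchor correlation at n = 10) use 40-60 replicate cohorts of
6-50 features, enough to pin the means well inside their stated
tolerances.  Unit oracles (binomial tails to n = 50, hypergeometric
enumeration, per-base interval scans, naive seed scans) run in seconds.

## Known limitations

* Pooled-count Fisher windows treat reads within a group as
  exchangeable; true replicate overdispersion beyond the pooled table
  inflates its optimism, which is why the BH screen is followed by the
  effect-size floor and, downstream, by correlation retention.
* Welch-on-logs has no shrinkage; at n = 5 its power profile differs
  from moderated count models, and low-abundance features near the BH
  boundary are the main source of missed planted mRNAs in recovery
  runs.
* Seed matching ignores pairing thermodynamics, conservation and site
  accessibility; external pair tables are the intended route when a
  real prediction database is available.
* The recovery experiment's precision/recall quantify performance under
  the generator's models only; no claim transfers to real cohorts
  without external validation.
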