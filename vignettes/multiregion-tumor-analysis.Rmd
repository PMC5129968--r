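---
title: "Multiregion tumor sequencing analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiregion tumor sequencing analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tumorith` analyses multiregion tumor exome sequencing at the level of
mutation calls. When one tumor is biopsied in several places and each
biopsy is exome-sequenced against a matched normal, the spatial
distribution of somatic mutations across biopsies carries temporal
information: mutations present everywhere ("public") arose in the founding
clone, mutations confined to a subset of biopsies ("shared") or a single
biopsy ("private") arose later. This vignette documents the models behind
each stage, the tunable parameters and their defaults, what the bundled
simulator does and does not emulate, and the design choices made where the
design was genuinely open.

```{r setup}
library(tumorith)
```

## Joint genotyping by read-evidence rescue

Per-region variant callers drop real mutations, and in a multiregion
design such dropout masquerades as heterogeneity: a clonal mutation missed
by the caller in one of three biopsies looks shared instead of public, and
the intratumoral heterogeneity (ITH) of the case is overestimated. The
remedy is joint genotyping: every mutation called in *any* region is
re-examined in *every* region for supporting reads.

A region is marked present at a candidate site when its caller reported it,
or when the read evidence clears all three rescue thresholds:

| parameter | default | meaning |
|-----------|---------|---------|
| `min_alt_reads` | 2 reads | two supporting reads suppress isolated sequencing errors while staying sensitive |
| `min_vaf` | 0.02 | variant allele fraction floor; below this, support is indistinguishable from noise at exome depth |
| `min_depth` | 10 reads | cells below this are *non-evaluable*: the region cannot testify either way |

Sites enter only through the union of per-region calls — rescue can fill in
a row, never invent one. Non-evaluable cells are excluded from the
categorization denominator rather than counted as absent: counting a
low-coverage region as "mutation absent" would manufacture spurious private
labels invisibly. Each cell carries a provenance flag
(`called`/`rescued`/`absent`), and all thresholds are echoed verbatim into
the report metadata.

```{r}
case <- simulate_case(sim_config(n_trunk = 60, n_branch = 20, n_private = 20,
                                 n_microsat = 0, n_msi_loci = 0,
                                 dropout = 0.2, seq_error = 0, seed = 1))
pm <- build_presence_matrix(merge_candidate_sites(case$calls), case$evidence)
pm
ith_summary(pm)
```

## Spatial categories and ITH statistics

With $R$ evaluable regions, a site present in all $R$ is public, in exactly
one private, and otherwise shared; for the three-biopsy design this is the
3/2/1-biopsies scheme. The summary statistics are the category fractions
(public fraction is the headline ITH measure — low public fraction means
high heterogeneity), per-region mutation counts, the mutation burden
(exonic mutations per Mb of capture target, default 50 Mb, the nominal size
of a whole-exome 50 Mb capture kit; the exact territory is configurable
because nominal and effective target sizes differ), and the
nonsynonymous-to-synonymous (NS/S) ratio. NS/S is an SNV statistic:
missense + nonsense + canonical-splice substitutions over synonymous
substitutions, indels excluded from both sides; with zero synonymous SNVs
the ratio is reported as undefined rather than infinite.

## MSI calling from repeat-length histograms

For each coding microsatellite the package compares the tumor and normal
repeat-length read distributions with a two-sample Kolmogorov–Smirnov test:
$D = \max_x |F_T(x) - F_N(x)|$ over the pooled integer support. Loci with
fewer than `min_reads = 20` reads in either sample are untestable and are
excluded from the multiple-testing family — a KS test at trivial depth is
meaningless. P-values are corrected per tumor–normal pair by
Benjamini–Hochberg, a locus is an *MSI event* when $q < 0.05$, and a genome
is MSI-high (MSI-H) when it carries at least `msih_min_events = 20` events:
microsatellite-stable (MSS) genomes show on the order of 0–5 events while
MSI-H genomes show tens to hundreds, so any threshold in the wide gap
between those regimes separates them; 20 sits comfortably inside the gap.
MSI status is computed per region and rolled up to the case by majority
vote (configurable to `any`/`all`).

Two p-value methods are available:

* **asymptotic** (default): $p = 2\sum_{k\ge1}(-1)^{k-1} e^{-2k^2\lambda^2}$
  with $\lambda = D\sqrt{nm/(n+m)}$. Repeat lengths are integers, so the
  data are heavily tied and this p-value is *conservative* — with a
  stutter-like 5-point support it can overstate mid-range p by several
  tenths. Even on effectively tie-free data, the limiting distribution
  deviates from the permutation law by up to ~0.05–0.07 in the mid-range at
  per-sample read counts of 30–200. This conservatism costs little power at
  realistic effect sizes (see below) and never inflates the event count.
* **permutation**: label permutation of the pooled reads (drawn as
  multivariate hypergeometric splits per support point, add-one corrected).
  Exact up to Monte Carlo error under ties, and therefore the reference
  behavior in the package's tests; preferred for small samples.

```{r}
prof <- triangular_profile(20)           # stutter null around 20 units
set.seed(2)
h <- simulate_microsat_locus(prof, is_msi = TRUE, slip_fraction = 0.7,
                             slip_shift = -2, n_reads = 100)
ks_test_hist(h$tumor, h$normal, method = "permutation", B = 2000)
```

## Copy-number analysis

Binned read depths are turned into log2 tumor/normal ratios with
library-size normalization and median centering; bins whose matched normal
has fewer than 10 reads are masked. GC bias is removed by per-stratum
median subtraction (GC strata of width 0.02, merged until each holds at
least 50 bins) — robust, assumption-free, and sufficient for bin-level
ratios.

Segmentation is a circular-binary-segmentation-style search written for
this package: per chromosome, the arc $(i, j]$ maximizing
$|\bar{x}_{arc} - \bar{x}_{comp}| / \sqrt{1/k + 1/(n-k)}$ is found
(wrapped arcs are redundant because the statistic is symmetric in
arc/complement), the split is accepted when its seeded permutation p-value
is below `alpha = 0.01` with both parts at least `min_bins = 5`, and the
search recurses. Adjacent segments closer than `merge_tol = 0.1` in mean
are merged. The permutation test is seeded, so segmentation is
deterministic given the seed; the noise scale is permutation-invariant and
cancels from the test.

Calls use mean-log2 thresholds of ±0.3 — a single-copy change at purity
~0.7 shifts the ratio by $|\log_2(1 \pm 0.35)| \approx 0.37{-}0.62$, so
±0.3 separates single-copy events from noise while tolerating purity
variation. A called segment covering at least 80% of a chromosome arm is
annotated arm-level, otherwise focal. A chromothripsis-like flag marks
chromosomes where segment means collapse (within `state_tol = 0.15`) into
two states that alternate for at least `min_switches = 8` consecutive
segments — a generalization of the oscillating two-state pattern that
distinguishes chromothripsis from progressive gains/losses; a monotone
staircase never triggers it.

## Evolutionary interpretation

Gene-level events are LoF mutations (nonsense, canonical ±2 splice,
out-of-frame indel — in-frame indels are deliberately excluded), hotspot
missense changes (≥ 5 recurrences in a somatic catalog), plain missense
changes, and copy gains/losses mapped to genes by ≥ 1 bp interval overlap
with a supplied gene model table. On these events the package computes:

* **Biallelic inactivation** (Knudson two-hit): a region is biallelic for a
  gene when it carries two distinct LoF mutations, or one LoF mutation
  plus an overlapping copy loss. Exome data cannot phase the two hits; two
  LoF hits in one region are *assumed* in trans, and the output labels the
  witnessing pair so the assumption is auditable.
* **Convergent evolution**: two functional hits (LoF, hotspot missense,
  copy loss) on the same gene with disjoint region sets — independent
  inactivation in different parts of the tumor. Pathway-level convergence
  is computed only when a gene-to-pathway map is supplied.
* **Chronology**: the partial order trunk (public) ≺ branch (shared) ≺
  private. No order is asserted within a stratum — spatial categories
  cannot resolve it.
* **Region tree**: distinct region subsets in decreasing mutation-count
  order (ties broken lexicographically) are greedily accepted when they
  nest with everything accepted so far; conflicting subsets are flagged
  incompatible rather than resolved. Mosaic cases — genomes caught before a
  clonal sweep — surface their own inconsistency instead of being forced
  into a tree.

```{r}
adenoma_case_evolution("MSS3")
```

The bundled five-case adenoma table (three MSS, two MSI-H gastric adenomas,
three biopsies each) encodes the driver-gene events and regional
distributions of a real multiregion study design and is the package's
qualitative regression fixture: biallelic APC in all five cases (always
with a trunk event), ARID2 truncation in all MSS cases with regionally
exclusive multi-hits in two of them, late hotspot mutations
(KRAS/ERBB2/FBXW7) off the trunk, and an oscillating chromosome 6 in one
MSI-H genome. Its genomic coordinates are approximate gene intervals,
present so the interval-overlap code path is exercised; the scientific
content is the gene, event class and regional distribution.

## What the simulator emulates — and what it does not

`simulate_case()` generates what the downstream stages consume, under a
single seeded RNG stream (same config + seed ⇒ byte-identical output):

* **Clonal architecture**: `n_trunk`/`n_branch`/`n_private` mutations
  carried by all/some/one of `n_regions = 3` biopsies. Defaults
  (500/200/300) give a mid-range public fraction of 0.5.
* **Read evidence**: heterozygous, copy-neutral mutations at VAF =
  `purity/2` (purity default 0.7, matching pathology-confirmed purities
  above 70%); depths Poisson with mean `mean_depth = 100`; alt counts
  binomial with error mixing `seq_error = 0.001` (a wild-type read is
  miscalled to the specific alternate base with probability
  `seq_error/3`). Caller `dropout` removes calls but never evidence,
  creating rescue test cases.
* **Microsatellites**: a symmetric triangular stutter null over the
  reference length ±2 units — any unimodal discrete profile would do for
  KS testing. Unstable loci mix in a shifted copy of the null:
  `slip_fraction = 0.7` of tumor reads (clonal slippage at purity 0.7
  means ~70% of tumor-sample reads carry the slipped allele) shifted by
  `slip_shift = -2` repeat units (deletion slippage). At 100× this gives a
  true $D \approx 0.39$ and comfortable power at FDR 0.05 among 10,000
  loci.
* **Depth tracks**: piecewise-constant true log2 states over `n_bins`
  bins; Poisson depths with library-specific sinusoidal GC bias (tumor
  amplitude `gc_bias_amp = 0.3`, normal half that). Library GC effects do
  not cancel in the ratio — that residual is exactly what GC correction
  exists to remove, so the simulator must not let the bias cancel.

Not emulated: read-level artifacts (mapping error, strand bias, FFPE
damage), germline contamination, subclonal cancer-cell fractions below
clonality, copy-number-dependent VAFs, locus-specific stutter shapes, and
recurrent mutation. Passing tests therefore demonstrate the *statistical
machinery* — rescue, categorization, KS/FDR calling, segmentation —
under the stated generative model, not robustness to every artifact of
real sequencing.

## Validation experiment design and problem sizes

The package's property-based validation (in `tests/testthat/` and
`scripts/acceptance.R`) uses these scales, chosen to exercise study-like
regimes at desk-scale runtimes:

* KS: 1,000 histogram pairs (reads ≤ 200 per sample) for exactness of $D$
  against a brute-force ECDF oracle; ~50 mid-range pairs against a
  $B = 10^4$ permutation oracle for p-value calibration.
* MSI: genomes of 10,000 loci; 200 unstable for power (sensitivity ≥ 0.8
  expected ≈ 0.99), none for type-I control (events ≤ 0.1% expected ≈ 0).
* Recovery: 1,000-mutation cases at public fractions 0.05/0.5/0.9.
  Perfect calling recovers the fractions exactly. Under 20% caller
  dropout with rescue, the residual error is dominated by private
  mutations whose only carrying region dropped out — they vanish from the
  candidate union entirely and no rescue can recover them, biasing the
  public fraction upward by roughly $f_{pub}(1 - d_{denom})$. The
  mid-fraction recovery experiment therefore uses a shared-dominant
  architecture (500/375/125), the regime of a low-ITH MSI-H-like genome,
  where the union bias stays below 0.02; the low-fraction case uses a
  private-dominant MSS-like architecture (50/250/700), where the bias is
  inherently small because few mutations are public.
* Segmentation: 100 chromosomes of 120 bins with two planted breakpoints
  (gap 6× noise sd), 100 flat-noise chromosomes of 100 bins, 50 single-step
  50-bin instances against an exhaustive least-squares oracle.

## Known limitations

* Spatial categories proxy time only on average; a late mutation swept to
  fixation is indistinguishable from a truly early one.
* The asymptotic KS p-value is conservative under ties (documented above);
  use `method = "permutation"` when event counts sit near a decision
  boundary.
* Breakpoint resolution is limited to the bin size, and segmentation
  assumes exchangeable noise within a chromosome (the permutation null).
* The region tree is a greedy laminar family over observed subsets, not a
  maximum-parsimony phylogeny; with three regions this is exactly the
  trunk/branch/private schematic, but with many regions a global method
  would be preferable.
* Biallelic calls inherit the trans assumption; haplotype-resolved data
  would be needed to verify it.
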