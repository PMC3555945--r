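---
title: "Designing and evaluating a high-density SNP array with panelforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating a high-density SNP array with panelforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
```

panelforge implements the design procedure behind fixed-content Infinium-style
SNP genotyping arrays for inbred crop species, together with the
post-genotyping analyses used to evaluate such arrays: minor-allele-frequency
profiles, pairwise genetic distances, and windowed F~st~ scans for signatures
of selection. This vignette explains the models and algorithms, the
parameters that matter, and the design decisions taken where the procedure
left room for choice.

## The design problem

A bead-array assay has a fixed budget of probes (tens of thousands), while a
resequencing experiment discovers far more candidate SNPs than that, very
unevenly distributed: variant density is high where diversity panels differ,
and adjacent candidates often sit a few dozen bases apart. Three objectives
compete: (i) every probe should work (assay chemistry and probe uniqueness
constraints, plus an empirical prior on call success), (ii) markers should
be evenly spaced so that association and linkage studies have uniform
coverage, and (iii) markers should segregate (high minor allele frequency).
The pipeline addresses these in stages.

## Candidate filtering

`apply_filter_cascade()` removes, in a fixed order:

1. **Assay-incompatible types** — A/T and G/C SNPs share a colour channel in
   single-bead two-colour chemistry and cannot be scored; indels are not
   assayable either.
2. **Ambiguous flanks** — any N or IUPAC ambiguity within 60 nt of the
   variant, the window a probe designer needs. Flanks shorter than 60 nt
   (chromosome ends) count as ambiguous: the probe window is incomplete.
3. **Clustered candidates** — a second variant within 25 bp would sit under
   the probe; both members of a close pair are removed (the symmetric
   reading of "within 25 bases of another SNP").
4. **Non-unique flanks** — the 25-mers immediately left and right of the
   variant must each occur exactly once in the genome, counting
   reverse-complement hits; repeated flanks indicate paralogy or repeats.
   Matching is exact: no mismatch tolerance is applied, as none is defined
   for the probe-uniqueness requirement.
5. **Paralog and pool consistency** — a genotype showing *both* alleles of
   an inbred line indicates collapsed paralogous sequence; an observed
   allele absent from the IUPAC code called on the mixed DNA pool indicates
   a calling artefact.

The order is fixed so that per-rule removal counts are reproducible; each
candidate is attributed to the first rule that fires. The retained set is
order-independent for the per-candidate rules (verified by property tests);
only the clustering rule depends on the joint configuration, and it is
symmetric under relabelling.

## Priority groups, validation rates and the selection index

Candidates are graded A–D by the strength of their discovery evidence
(`assign_priority_groups()`): A — allele pair confirmed by the mixed-DNA
pool (or a previously assayed marker); B — the alternate allele seen in at
least two genotypes; C — one genotype but read depth above 3; D — one
genotype at low depth with pool support. The classes overlap; rules are
applied in listed order, so a candidate with both pool support and two
genotypes is an A. A single-genotype candidate at depth exactly 3 is covered
by neither the "greater than 3" nor the "less than 3" clause; it is assigned
to D when pool-supported and is otherwise unassignable, and both cases are
counted separately.

Each class's **priority score** R is estimated from a Sanger resequencing
experiment (`estimate_priority_scores()`): loci with no usable amplicon are
set aside, and R is the validated fraction of the rest. With the shipped
767-locus verification counts this gives R = 1.00, 0.83, 0.77, 0.67 for A–D.
R is kept at full precision internally; whole-percent values appear only in
display.

The **selection index** of candidate *i* is I~i~ = R~i~ × D~i~, where D~i~
∈ [0,1] is the vendor design score predicting assay success. Candidates
with D < 0.4 are dropped outright (the vendor-recommended floor). I is
monotone in both factors and lives in [0,1].

## Chromatin partitioning from the Marey map

Recombination in many plant genomes is suppressed across large
pericentromeric regions. On a Marey map — cumulative genetic position (cM)
against physical position (bp) — these regions appear as a long, nearly
flat middle segment between two steep arms. The procedure defines the
heterochromatic interval as the region between the two inflection points of
that curve.

`fit_partition()` operationalizes this as a continuous three-segment
piecewise-linear least-squares fit. Both breakpoints are searched over the
grid of observed marker positions (so reported boundaries snap to map
points), each candidate fit is a 4-parameter hinge regression, and the
middle slope must be *strictly* the smallest; if no breakpoint pair
satisfies that, the chromosome has no detectable suppressed-recombination
region and an error says so (a uniform-slope map is the canonical case).
One central heterochromatic block per chromosome is assumed, matching how
the partition is used downstream. The fit is invariant to uniform rescaling
of cM and translation of bp. On simulated maps with 200 markers and marker
noise of 0.5 cM, both breakpoints are recovered within 1 Mb in well over
95% of runs (the acceptance suite measures this).

## Quota allocation and iterative thinning

The totals W₁ (euchromatic) and W₂ (heterochromatic) are fixed by the array
budget, in roughly a 5:1 density ratio reflecting the recombination ratio
between the region classes. Region *j* of chromosome *i* receives the raw
quota L~ij~/T~j~ × W~j~ (L = region length, T = class total length).
Raw quotas are integerized by largest remainder so each class total is met
exactly; ties go to the longer region. Published per-chromosome tables of
this arithmetic are not exactly reproducible under any single rounding rule,
so exact-total integerization was chosen as the defensible variant; the one
arithmetically robust published row (a 26.3-Mb euchromatic region at 111.3
SNPs/Mb giving 2,929) is reproduced by `expected_count_at_density()`.

`thin_by_iteration()` then removes one SNP at a time from each
chromosome-region candidate set until its quota remains:

1. find the smallest gap between adjacent retained SNPs;
2. of the two SNPs flanking it, remove the one with the smaller selection
   index;
3. if their indices are equal, remove the one whose *other* adjacent gap is
   smaller (a terminal SNP's other gap is treated as unbounded);
4. if several gaps tie for smallest, consider all SNPs flanking those gaps
   and remove the smallest-index one;
5. any residual tie is broken by the smaller position, for determinism.

Gaps are defined between adjacent SNPs only — there are no gaps to region
boundaries, and the two euchromatic arms of a chromosome never share a gap.
The implementation keeps a binary min-heap of gaps with lazy invalidation
over doubly-linked neighbour arrays (O(n log n) in total) and is tested for
exact equality against a naive re-scan-per-iteration oracle on hundreds of
fixtures with engineered ties. Two properties follow: the removed SNP never
has a higher index than its gap partner (by construction), and relative to
removing the same number of SNPs at random the thinned set has a smaller
spacing standard deviation (checked statistically, not guaranteed per
instance — a low-index SNP in a sparse stretch can still be removed).

Unanchored scaffolds get a separate small budget: scaffolds are ranked by
length and the budget is spent round-robin, best remaining index first.
This concrete rule is this package's own; the motivating design states only
the outcome (a fixed number of scaffold SNPs), not the rule.

## Post-genotyping evaluation

* `call_rate_by_bins()` bins assay outcomes by index or design score
  (lower edge closed, matching "≥a & <b" table conventions) and reports the
  Pearson correlation of bin midpoints with bin success rates. The original
  report of this correlation does not state its basis; bin midpoints are
  used here, and a per-SNP point-biserial correlation is reported alongside.
* `maf_profile()` computes allele frequencies from called samples only and
  folds to MAF = min(p, 1−p); bins are left-closed with the final bin
  closed at 0.5.
* `genetic_distance()` between two samples is the fraction of co-called
  loci with differing genotype calls. A heterozygote differs from either
  homozygote — with fully inbred material the question does not arise, and
  this is the conservative general choice. `distance_distribution()`
  reports all-pairs summaries plus an empirical 2.5–97.5 percentile
  interval of per-pair polymorphic counts; a parametric interval was
  deliberately not used because the published construction of such
  intervals is not recoverable.

## F_st scans for selection signatures

`fst_per_locus()` implements the Weir & Cockerham (1984) two-population
estimator from genotype counts (sample-size and heterozygosity corrected).
Negative estimates — expected under no differentiation — are clamped to 0
so values lie in [0,1]; loci monomorphic in both populations report 0, and
loci with fewer than 2 called samples in either population are excluded
with a count. `fst_multilocus()` combines loci the standard way, as the
ratio of summed variance components.

The distinction matters for interpretation: under Balding–Nichols drift at
parameter F, many loci fix for the *same* allele in both populations and
estimate 0, so the mean of per-locus estimates sits well below F while the
ratio-of-sums recovers F (within 0.01 at F = 0.05/0.2/0.6 in the acceptance
simulations, 100 samples per population, 2,000 loci). Windowed scans
(`window_average()`, unweighted mean per fixed 100-kb grid window) inherit
the per-locus attenuation, which is why scan thresholds should be chosen
relative to the observed genome-wide distribution rather than read as the
underlying differentiation parameter.

Significance is assessed by permuting individuals across the two population
labels (`fst_permutation_test()`), with the add-one correction
p = (1 + #{perm ≥ obs})/(n_perm + 1), so p-values are valid, deterministic
under a fixed seed and floored at 1/(n_perm+1).

`flag_regions()` flags windows with mean F~st~ at or above a threshold
(default 0.6) and merges flagged windows separated by at most `merge_gap`
unflagged windows (default 1, i.e. one 100-kb hole is tolerated inside a
region — the published "100 kb interval to the adjacent regions" phrasing
does not define merging formally, so it is a parameter). Both the
flagged-window count and the merged-region count are returned, since
published per-chromosome counts may use either convention.

## The synthetic-data generators

Every stage can run without external data. The generators are pure
functions of (seed, parameters) — identical calls give byte-identical
files — and each returns a truth record sufficient to compute the expected
output of the stage it feeds.

* `generate_reference()` — random nucleotide chromosomes with declared
  heterochromatic intervals, optional scaffolds, and an optional planted
  duplicated 2-kb block to exercise flank uniqueness. Random sequence makes
  25-mers unique with overwhelming probability, so uniqueness truth is
  controlled by the planted block.
* `generate_candidates()` — Poisson placement at a 5:1
  euchromatic:heterochromatic density ratio; clean candidates are spaced
  more than 25 bp apart and carry evidence consistent with an intended
  priority class (class mix 16/34/40/10% for A/B/C/D, the composition of a
  realistic discovery set); stated fractions of planted violators per
  filter rule. Design scores are Beta(5, 1.5) — right-skewed with a small
  mass below the 0.4 floor, as vendor scores look in practice.
* `generate_linkage_map()` — three-segment polyline with slopes 3/0.2/3
  cM/Mb by default (typical arm vs pericentromere recombination rates),
  additive Gaussian marker noise (0.5 cM default), then a running maximum,
  since cumulative maps cannot decrease.
* `generate_populations()` — ancestral frequencies uniform on
  [0.05, 0.95]; population frequencies Beta-distributed around them with
  variance F·p(1−p) (Balding–Nichols), which makes the expected pairwise
  Weir–Cockerham differentiation between two populations equal F. The
  default is fully inbred individuals (no heterozygotes), matching
  self-pollinating crops; `inbreeding` is configurable. A per-locus F
  vector plants selection signatures.
* `generate_validation_outcomes()` — per-class Bernoulli validation with an
  amplicon-failure rate; defaults mirror a 767-locus verification
  experiment (class sizes 89/233/390/55, rates 1.00/0.83/0.77/0.67, 18%
  failed amplicons).

What the generators do *not* emulate: linkage disequilibrium and physical
clustering of diversity, ascertainment bias of the discovery panel,
genotype-calling error structure, and real repeat landscapes (uniqueness
violations are planted, not emergent). Passing tests therefore demonstrate
algorithmic correctness and estimator calibration under the stated models,
not performance on any particular real genome.

## Numerical choices and scale

Positions are 1-based inclusive in memory; BED output is 0-based half-open.
Gap and index ties are compared exactly (positions are integers; engineered
index ties are exact). The partition fit requires the middle slope to be
smaller than both arm slopes beyond a relative tolerance of 1e−9 so that an
exactly-linear map cleanly fails. Simulation sizes in the test and
acceptance suites (chromosomes of 0.1–0.5 Mb for pipeline runs, 60-Mb
chromosomes with 200 markers for partition recovery, 2,000 loci × 100
samples per population × 10 seeds for F~st~ recovery, 200 thinning fixtures
up to n = 200) were chosen to make stochastic checks stable at desk scale;
all scale linearly if increased.

## Known limitations

* The thinning heuristic is greedy; it does not claim a globally optimal
  even spacing, and no multi-objective solver is provided.
* Exactly one central heterochromatic block per chromosome is fitted;
  acrocentric or multi-block architectures are out of scope.
* The flank-uniqueness rule is exact-match; near-duplicate flanks with
  mismatches are not detected.
* Genotype calls are inputs; nothing here processes raw intensities or
  cluster plots.
* The F~st~ machinery is two-population; multi-way comparisons are made
  pairwise.
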