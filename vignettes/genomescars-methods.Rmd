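---
title: "Models and design choices in genomescars"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in genomescars}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomescars)
```

# Scope

`genomescars` implements the downstream statistical machinery used to
dissect karyotypically complex tumour genomes — undifferentiated
sarcomas being the motivating case — from three inputs that upstream
callers provide: allele-specific copy-number segments, somatic
rearrangement breakpoint pairs, and somatic SNVs with allele fractions.
It does not align reads or call variants. Every method operates on a
user-supplied `genome_build()` coordinate frame; sex chromosomes are
kept but flagged, and the genome-wide LOH fraction is computed over
autosomes only.

All analyses are exercised end-to-end on synthetic cohorts from
`sim_config()` and its simulators, because the motivating cohort data
sit behind controlled access. The generator's defaults are the study
conditions the package is tested under, and they are fixed once: 70x
sequencing depth, purity 0.7, age 60, 1,000 expected per-copy mutations
for timing; gamma(shape 2, scale 50) rearrangement counts; 65%
same-chromosome breakpoint partners with a 5 Mb mean partner distance.

# Copy-number categories and signatures

Each segment is classified along three axes into one of 40 mutually
exclusive categories:

* **zygosity** — homozygous deletion (total copy number 0), LOH (minor
  allele 0, total ≥ 1), heterozygous (minor ≥ 1);
* **total copy number** — deleted (0–1), neutral (2), duplicated (3–4),
  amplified (> 4); heterozygosity excludes the deleted class, and a
  homozygous deletion is always "deleted", which is why the enumeration
  is 20 LOH + 15 heterozygous + 5 homozygous-deletion categories;
* **size** — 0–0.01, 0.01–0.1, 0.1–1, 1–10, > 10 Mb.

Two conventions are deliberately pinned down because touching bin edges
are conventionally quoted without one: segment length is `end − start + 1` under
1-based inclusive coordinates, and size bins are half-open on the right,
`(lower, upper]`, so a segment of exactly 10,000 bp falls in the
smallest bin. Rearrangement categories follow the same pattern
(clustered status × {deletion, tandem duplication, inversion} × five
size bins, plus clustered/unclustered translocations without a size
bin, 32 in total). "Insertion" appears in some callers' vocabularies;
the canonical set has no insertion class, so insertions are rejected
unless the user explicitly folds them into tandem duplications
(`map_insertion = TRUE`) — the discrepancy is surfaced, not hidden.
Events below 1 kb are kept in the smallest bin and logged rather than
dropped.

# Clustered rearrangements

A rearrangement is *clustered* when it falls in a region where
breakpoints are much closer together than is typical for the cohort.
Per sample and chromosome, sorted breakpoint positions yield
inter-breakpoint distances; a penalized piecewise-constant fit
(exact dynamic programming on log10 distances, penalty γ = 25, at least
2 distances per segment) partitions them, and a rearrangement is
flagged when either of its breakpoints is adjacent to a fitted segment
whose mean distance is below 0.1× the mean inter-breakpoint distance of
the whole data set. Using the data-set-wide mean — not the per-sample
mean — is essential: a sample whose rearrangements nearly all arise
from one shattering event would otherwise have a high per-sample mean
and none of its rearrangements called clustered. The coupling this
introduces (flags depend on the cohort through one scalar) is
intentional and documented. A rearrangement with one clustered and one
unclustered breakpoint is clustered.

# Consensus NMF and rank selection

Count matrices (categories × samples) are factorized by
multiplicative-update NMF under the Frobenius objective, with many
random restarts per candidate rank (2–12 by default, 1,000 restarts at
full scale; the test profile uses 50 and states so below). Restart
seeds come from a counter-based stream, so results are reproducible and
runs independent. Run-to-run stability is summarized by consensus
clustering: mean silhouette width, cophenetic correlation and
dispersion of the consensus matrix.

Selecting the rank that "maximizes" these criteria needs care, because
all three are generically maximal at rank 2: when the data hold k > 2
well-separated processes, the choice of which processes merge at rank 2
is determined by the data, not the initialization, so every restart
agrees and stability is perfect. We observed exactly this on synthetic
3-signature data (silhouette 0.94/0.88/0.66 at ranks 2/3/4). The
package therefore uses the row-permuted control — run for precisely
this purpose — as an overfitting guard: a rank k is *admissible* once
moving to k + 1 improves the reconstruction error by no more than the
same step does on permuted data (beyond that point additional
signatures fit noise). Among admissible ranks, the smallest one within
5% of every stability criterion's maximum is selected; if none
qualifies, the admissible rank with the best average standardized
stability. Without a randomized control the stability-only shortlist
rule applies. Exact rank-1 data (reconstruction error ≈ 0 at the
smallest candidate rank) is flagged `degenerate`.

Exposures are re-estimated against fixed, column-normalized signatures
by non-negative least squares with iterative pruning: signatures whose
normalized exposure falls below 0.06 (configurable; the referenced
refitting tool's default) are removed one at a time, weakest first,
with a refit after each removal. Per-sample signature diversity is
Shannon's index, `H = −Σ p_i ln p_i`, over active signatures with
exposures normalized to 1.

# Chromothripsis detection

Chromosomes carrying more than 30 breakpoints are scanned in 3 Mb
windows stepped by 100 kb (end windows truncated, not dropped). Three
randomness tests are combined, and a window is flagged when at least
two indicate chromothripsis:

1. **Spacing** — a one-sample Kolmogorov–Smirnov test of
   whole-chromosome inter-breakpoint distances against the exponential
   with the observed mean; p < 0.05 (strong departure, i.e.
   clustering) is indicative. The verdict is chromosome-level and
   shared by all windows on that chromosome.
2. **Join types** — chi-square goodness of fit of the window's
   {HH, HT, TH, TT} join counts against uniform; randomness is
   *accepted* when p > 0.8. Windows without joins fail.
3. **Fragment order** — breakpoints in the window are indexed by
   position (ties by input order); 1,000 uniform draws of two distinct
   indices give the proportion whose separation exceeds the observed
   mean separation of the window's pairs; p > 0.8 is indicative.

Joins and order pairs count rearrangements with *both* breakpoints in
the window (a single fixed convention; counting either-end joins mixes
in junctions whose partner context is invisible to the window). The
observed mean separation is per-window; a data-set-wide variant was
considered and not implemented, since the per-window reading keeps the
test local. Overlapping flagged windows merge into one call that
carries its strongest window's three p-values for review. Copy-number
oscillation criteria are deliberately not applied — they would exclude
shattering on a doubled genome, which is prevalent in this tumour type.
Cohort recurrence is reported by 100 kb bins as the number of samples
with an overlapping call.

# Monte Carlo recurrence of rearranged regions

The genome is split into 1 Mb bins and, per bin, the observed statistic
is the number of samples with more than one breakpoint in it. The null
model is fitted empirically: `p`, the same-chromosome partner fraction;
`μ_c`, the mean distance between partner breakpoints of
intra-chromosomal events on chromosome c; and per-sample event counts
as a maximum-likelihood gamma (`MASS::fitdistr`), falling back to a
fixed count with a warning if all counts are identical. Simulated
cohorts draw chromosomes length-weighted, inter-chromosomal breakpoints
uniformly, intra-chromosomal partners an Exp(μ_c) apart (bounded
redraws when the distance exceeds the chromosome, then skip-and-log),
and gamma counts rounded to integers.

Bin p-values are `(m + 1)/(M + 1)` with `m` the simulations whose count
*strictly* exceeds the observation. Strict exceedance matters: bin
counts are small integers, simulations tie with the observation
constantly, and the strict form is measurably anti-conservative under
ties (type-I ≈ 0.076 at α = 0.05 on exchangeable null draws in our
calibration), while counting ties (`ties = "conservative"`) gives
≈ 0.020 and the randomized tie-broken p-value is exact (≈ 0.049). The
strict form is retained as the default because it is the method's
defining formula; the conservative variant and the `p_randomized`
column exist because calibration of a discrete Monte Carlo test should
be judged on the randomized p-value, and significance calls in
practice should prefer the conservative variant. Q-values follow the
step-down form `q_i = min_{j ≥ i} (M_p π₀ P_j / j)` with
`π₀ = min(1, (2/M_p) Σ P_i)`, where `M_p` is the number of tested bins
(the number of tests is the only reading under which the formula is a
multiple-testing correction). Bins with q < 0.2 are significant.

# Driver triage and burden classes

Somatic SNVs pass through six ordered rules (hotspot databases;
blacklist/unidirectional/germline-read contamination at the 1.5%
threshold; silent variants retained under their own label rather than
assigned a confidence the rules never state; population-database
membership; patient recurrence; CADD/impact/clinical-significance
re-tiering). Boundary semantics are literal: CADD < 20 demotes,
CADD > 20 promotes, CADD = 20 changes nothing; the burden boundaries
are inclusive (≥ 15,000 SNVs is mutation-high, ≥ 100 rearrangements is
rearrangement-high among mutation-low samples; targeted panels use
> 10 mutations/Mb). Every verdict carries the ordered list of triggered
rules so a tier can be audited by replay. Database memberships are
consumed as user-supplied annotation columns and gene lists, never
fetched. Copy-number driver calls use the gene-level rules
(amplification when the minimum total copy number over an oncogene
exceeds `2^1.3 ×` ploidy ≈ 2.46× ploidy; homozygous deletion at {0,0}
in a tumour suppressor; LOH at minor 0 with a copy remaining), and the
cohort LOH scan slides 1 Mb windows by 100 kb, calling a window LOH for
a sample only when *every* overlapping covered base is minor-allele 0 —
a conservative reading, since partial-window handling is otherwise
undefined; uncovered samples leave the denominator.

# Whole-genome duplication timing

The multiplicity of an SNV — how many tumour copies carry it — is
inferred from its VAF `f`, purity ρ and local copy number: the expected
VAF at multiplicity μ is `ρμ / (ρ n_tot + 2(1 − ρ))`, and μ is the
integer in `[0, n_major]` with the nearest expected VAF (midpoint ties
round down, conservatively toward later timing). An alternative form
of this estimator minimizes a *relative* criterion `|f ⋅ (ρμ)^{-1}
(ρ n_tot + 2(1 − ρ)) − 1|`, whose decision boundaries sit at
`2μ(μ+1)/(2μ+1)` (4/3 between 1 and 2) rather than at VAF midpoints;
both are available (`method = "ratio"`), but the VAF-space reading is
the default because it matches the cited multiplicity method and keeps
misclassification symmetric at realistic depth.

WGD count comes from the length-weighted mode of the major allele
(mode 1 → 0 duplications, 2 → 1, > 2 → 2; ties resolve to the larger
mode with a warning). With one WGD, SNVs in 2+0/2+2 regions time it at
`t = N2 / (N1/2 + N2)`; with two, SNVs in 4+0/4+4 regions give
`t1 = N4/Δ`, `t2 = (N4 + N2/2)/Δ`, `Δ = N4 + N2/2 + N1/4`. Eligible
regions are taken exactly — segments one copy away are never co-opted,
because the closed forms are only valid at those genotypes. Confidence
intervals are percentile bootstrap over 1,000 resamples of the
multiplicity set. Chronological estimates scale by age at diagnosis
(`rt = a·t`, `tbd = a − rt`) under a constant mutation rate with no
acceleration, so they are late bounds. All SNVs are used by default
(not only CpG transitions) to keep counts workable; timing uses
autosomal-style eligible regions only. Driver mutations in eligible
regions are placed pre-/between-/post-WGD from their multiplicity;
anything else is reported not-timeable.

# What the synthetic cohorts do and do not emulate

The generator reproduces the statistical structure each method
consumes: multinomial category counts from known signature mixtures
(materialized as placeable, non-overlapping segments so classification
inverts the generator exactly), gamma-count breakpoint catalogs with
the same partner geometry as the recurrence null, optional shattering
windows with uniform joins and random pairing, and Poisson mutation
accrual at constant per-copy rate with binomial read sampling at depth
70. It does not model biological segment ordering, replication timing,
mutation context, subclonality, or mapping artifacts. Passing tests
therefore demonstrate correctness of the inference under the model's
own assumptions — parameter recovery, calibration, detection — not
robustness to real-data artifacts those assumptions exclude.

Problem sizes used by the test suite and acceptance script, chosen as
desk-scale analyses: 100 single-sample timing replicates at λ = 1000
with 1,000 bootstrap resamples; recurrence calibration with M = 1,000
simulations against 150 null cohorts of 25 samples on a 300 Mb
three-chromosome frame; 200 null chromosomes for the chromothripsis
false-positive rate; NMF on 30 samples × 1,000 segments with 50
restarts per rank over ranks 2–12.

# Known limitations

* The recurrence test's default p-value is anti-conservative under
  ties (see above); use `ties = "conservative"` for significance calls.
* Consensus-stability metrics alone cannot identify the rank; the
  randomized control is required for a meaningful selection.
* Subclonal WGD is invisible to the timing model; bootstrap intervals
  reflect multiplicity resampling only, not VAF misclassification, so
  coverage runs a little below nominal at moderate purity.
* The LOH window rule is strict (all covered bases), so fragmented
  coverage biases windows away from LOH calls.
* `pcf_segments()` is exact dynamic programming, quadratic in the
  number of breakpoints per chromosome — fine for per-sample catalogs,
  not for pooled cohorts on one chromosome.
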