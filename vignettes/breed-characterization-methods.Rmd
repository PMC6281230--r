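---
title: "Methods: genomic characterization of breed diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genomic characterization of breed diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the choices made where the
design was genuinely open, and what the synthetic-data tests do and do
not demonstrate about real data.

## The analysis graph

A breed-characterization run proceeds: genotype input → marker/sample QC
→ (pedigree relationships, when a pedigree exists) → genomic
relationship and IBS distance matrices → ROH and F_ROH → LD decay → Ne
trajectory → MDS / NJ tree / admixture. Every stage is an exported
function; `run_pipeline()` wires them together and writes TSV artifacts
with a checksum manifest.

## Data model and conventions

Genotypes live in a samples × markers dosage matrix counting copies of
`allele2` (0/1/2, `NA` missing), with a marker map (integer chromosome
codes, 1-based bp positions). Chromosome codes 1–38 are canine
autosomes; everything else is non-autosomal for QC purposes. ROH
intervals are closed `[start_bp, end_bp]` at the first/last SNP of the
run — no extrapolation beyond flanking markers.

Orientation: dosages count `allele2` as listed in the map. For PLINK
text input, where the .map carries no alleles, `allele2` is the
alphabetically later allele observed at the marker — a deterministic,
sample-order-independent rule under which write→read round trips are
exact for polymorphic markers (a first-encounter rule cannot be: the
first sample read can never decode as homozygous-allele2). Orientation
of a monomorphic marker is unrecoverable from a .ped file; `recode_minor()`
re-orients to minor-allele dosages when a fixed convention is wanted.
All downstream formulas are symmetric in p vs 1−p, so orientation never
changes a result.

## Quality control

Filters apply in a fixed order — unmapped, non-autosomal, call rate,
MAF, then sample missingness — with strict inequalities exactly as
conventionally quoted ("call rate < 95%", "MAF < 1%", "> 10% missing"
all exclusive). MAF is `min(p, 1−p)` over non-missing calls and is not
recomputed after sample removal (single pass). Defaults: call rate 0.95,
MAF 0.01 (0.05 for within-breed analyses), sample missingness 0.10.

## Pedigree relationships

`additive_relationship_matrix()` is the tabular method in topological
order: founders `a_ii = 1`; `a_ij = (a_{j,s} + a_{j,d})/2` with missing
parents contributing zero; `a_ii = 1 + a_{s,d}/2`. `F_i = a_ii − 1`.
Parents referenced but never listed become founders. Generation numbers
use the maximum-generations-traced convention (founders 0, child =
1 + max of parent generations) — the most common registry convention —
with "complete generations" behind a flag; the mean depth is reported
over a focal subset (by default everyone, typically the genotyped
animals).

## Genomic relationships and IBS distances

The GRM scales each locus by its own heterozygosity `2p_k(1−p_k)`
(per-locus scaling, in contrast to the constant-factor scaling of the
VanRaden estimator, which is out of scope here). Allele frequencies come
from the analyzed sample itself — no external reference panel is
assumed. Missing genotypes are handled pairwise-complete (per-pair locus
sets), not mean-imputed; the per-pair locus counts are the divisor.
Monomorphic loci are excluded (they carry no information and the scaling
is undefined). The IBS distance is the complement of the shared-allele
proportion: per locus 2 (identical genotypes), 0 (opposite homozygotes),
1 (otherwise), divided by `2 ×` shared loci.

`matrix_correlation()` reports the G-vs-A Pearson correlation over
off-diagonals by default; whether published figures of this kind include
the diagonal is usually unstated, so both modes are computed.

## Runs of homozygosity

Window mechanics: 50-SNP windows, step 1, pass when ≤ 2 heterozygous and
≤ 2 missing calls; per SNP the hit rate is passing windows ÷ windows
containing that SNP (edge SNPs sit in fewer windows), eligibility is
hit rate strictly > 0.05 (ties fail — the natural reading of a
threshold "of 0.05"). Candidate runs of eligible SNPs are then trimmed
so they start and end on homozygous non-missing SNPs, split at inter-SNP
gaps > 100 kb, and must satisfy ≥ 50 SNPs, ≥ 100 kb, and ≥ 1 SNP per
50 kb. There is no run-level heterozygote cap beyond the window
mechanics: interior hets whose windows pass do not break a run — that
tolerance is the point of the windowed method, and it is what lets
recall of planted segments survive a 0.5% heterozygote-error rate.

The end trimming deserves a word: without it, a run would extend up to
two heterozygous background SNPs beyond a truly homozygous stretch
(windows overhanging the boundary still pass with ≤ 2 hets), so runs
would systematically terminate on heterozygotes. Trimming restores the
natural invariant that a reported ROH begins and ends homozygous.

`detect_roh_oracle()` is the reference detector: maximal runs of
strictly homozygous non-missing genotypes, same run-level filters. On
clean fixtures with heterozygous flanks the two agree segment for
segment; on data with interior hets the oracle splits what the windowed
detector bridges. On a Hardy-Weinberg background the comparison is not
well-posed at the boundary — chance homozygous background SNPs adjacent
to a segment extend both detectors' runs, by different amounts — which
is why the equivalence fixtures use a heterozygous background and the
error-recall fixtures use the Hardy-Weinberg one.

Default run-level parameters assume a ~170K-array marker density
(inter-SNP spacing well under 50 kb). On sparser maps the gap and
density limits must scale with the spacing or every run is rejected;
the analysis scripts and the F_ROH recovery checks set
`max_gap_bp`/`min_density_bp_per_snp` to small multiples of the median
spacing for exactly this reason.

`F_ROH` divides total ROH length by the autosomal genome length — by
default the SNP-covered span of the analyzed map (published analyses
rarely say whether they used the covered span or a fixed genome size;
a constant can be supplied).

## LD decay and Ne

r² is the squared Pearson correlation of dosage vectors
(genotypic/composite LD) over pairwise-complete samples — the data are
unphased and EM haplotype-frequency estimation is deliberately out of
scope. r² is invariant to allele relabeling. Pairs are syntenic only,
under a distance cap; decay is the per-bin mean with bin midpoints as
the representative distance (bins are narrow; the mean pair distance
would change results in the third decimal).

The Sved relation maps each bin to `Ne = (1/(4c)) (1/r²_adj − α)` at
`t = 1/(2c)` generations, with `c` = midpoint × 1 cM/Mb (a genome
average; configurable, as no recombination map is assumed), sample
correction `r²_adj = r² − 1/(βn)` with β = 1 for genotypic correlations
(β = 2 would suit phased haplotypes), and α = 2 by default (the
mutation-adjusted variant; α = 1 available). Bins with non-positive
`r²_adj` or Ne are dropped and counted. Two caveats are inherent to the
method and documented rather than patched: point estimates of Ne are
sensitive to binning and sample size (trajectory shapes are robust,
levels are not), and the drift approximation `E[r²] ≈ 1/(α + 4Nc)`
holds at mid-range `4Nc`; very short distances exceed it in simulation
even at equilibrium, which is why calibration checks use bins with
`4Nc` roughly 6–18.

## Population structure

MDS is classical Torgerson scaling — double-center the squared distance
matrix, embed on the top eigenvectors scaled by √eigenvalue — which is
exactly `stats::cmdscale`; negative eigenvalues (non-Euclidean input)
are excluded and reported. NJ is Saitou–Nei agglomeration via
`ape::nj`; on additive matrices the recovered path metric equals the
input exactly, and negative branch lengths (non-additive input) are
clamped to zero with the deficit recorded. Breed-level trees use mean
between-sample IBS distances per breed pair; "shared-allele-index"
trees in the literature are interpreted as standard NJ on the 1−IBS
matrix.

The admixture model is the binomial likelihood
`ℓ = Σ_il [x_il ln π_il + (2−x_il) ln(1−π_il)]`, `π_il = Σ_k q_ik f_kl`,
maximized by plain EM (frappe-style multiplicative updates) — the same
likelihood ADMIXTURE accelerates with quasi-Newton block relaxation;
plain EM is slower per unit of convergence but monotone, simple, and
adequate at the problem sizes here (a fidelity trade-off made
deliberately). Missing genotypes drop out of all sums; π is clipped to
`[1e−10, 1−1e−10]`; K = 1 is the closed-form single-population MLE.
Three seeded restarts keep the best log-likelihood, ties broken by the
lowest restart index. Iterate feasibility (Q rows on the simplex, P in
[0,1]) and monotone ℓ are asserted in tests at every step.

Cross-validation masks random folds of the non-missing genotype
*entries* (not samples), refits per K on identical masks, and scores
masked entries by squared error `(x − 2π̂)²`; the selected K minimizes
the mean. A deviance-based error would be the main alternative; squared
error was chosen as the simpler metric with the same argmin in every
simulation we ran. Markers losing all observations in a fold are
excluded from that fold's error.

One recovery bound worth knowing: with K = 2, Fst = 0.1, n = 100,
m = 1000 and Dirichlet(0.5) ancestries, the per-individual information
floor (fitting Q with the true P known) is already RMSE ≈ 0.042–0.048,
and the joint fit converges to ≈ 0.052–0.057. Q-recovery accuracy at
these sizes is information-limited, not optimizer-limited.

## Synthetic data: what it emulates, and what it does not

* `sim_founders()`: flat or Beta MAF spectra, founders unrelated and in
  linkage equilibrium, evenly spaced markers.
* `gene_drop()`: Haldane (no-interference) recombination at 1 cM/Mb;
  founder-allele labels tracked, so realized autozygosity and IBD
  segments are known *at marker resolution* (with ≥ 20k markers the
  discretization error is far below every tolerance used).
* `sim_wright_fisher()`: discrete generations, random mating, no
  mutation (array SNPs are pre-ascertained standing variation);
  per-interval phase switches are Bernoulli `(1 − e^{−2d})/2`, which is
  the Haldane crossover process observed at marker resolution. The
  returned haplotypes can seed `gene_drop()` founders, giving pedigreed
  populations realistic background LD. Burn-in 4N generations is the
  usual equilibrium rule of thumb.
* `sim_admixture()` / `sim_breed_panel()`: Balding-Nichols population
  frequencies around uniform(0.05, 0.95) ancestral frequencies,
  Dirichlet ancestries (or pure breed membership), binomial dosages.
* `plant_roh()`: forced-homozygous segments over a Hardy-Weinberg (or
  all-heterozygous) background with optional per-SNP heterozygote
  errors.

Not modeled, hence not demonstrated by passing tests: array
ascertainment bias and non-uniform marker spacing, genotype-calling
artifacts beyond symmetric heterozygote flips, mutation, selection,
sex chromosomes, phasing, and overlapping generations. Results on real
array data inherit all of those.

## Problem sizes and numerical choices

Simulation-recovery checks run at sizes chosen to make Monte-Carlo
error small relative to the tolerance while staying desk-scale: 50
gene-dropping replicates for F_ROH recovery (tolerance ±0.05 on a mean
near 0.25), a 20-chromosome × 1000-SNP Wright-Fisher population of
N = 100 with 4N burn-in for Ne recovery (factor-2 tolerance), 100
random pedigrees for positive semidefiniteness (eigenvalue floor
−1e−8), 50 planted-ROH fixtures for detector equivalence. EM stops on a
log-likelihood gain below tol (1e−4 routine, 1e−6 for recovery
studies) or an iteration cap; cross-validation fits use a looser cap
since prediction error, not parameter accuracy, is scored.

## Known limitations

Pedigree depth reconstruction ("mean depth") depends on the generation
convention chosen; pairwise-complete GRMs are not guaranteed positive
semidefinite under heavy missingness; the Ne trajectory's time axis
(t = 1/(2c)) is a coarse mapping and neighboring bins overlap in the
history they reflect; EM admixture at large K converges slowly and the
cross-validation cost grows as folds × K values × restarts; NJ on
non-additive matrices is a heuristic (clamped branch lengths are
reported, not hidden).
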