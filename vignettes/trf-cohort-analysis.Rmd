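---
title: "Methods: tRNA-fragment classification and cohort analysis in tRFtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tRNA-fragment classification and cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and procedures implemented in
tRFtools, the assumptions behind them, the parameters that matter, and
the design choices made where the field leaves the design open. It
states no empirical result that the package's tests and acceptance
script do not themselves compute.

## The mature-tRNA coordinate system

Fragments are classified against three sequence spaces per tRNA gene,
all with 1-based inclusive coordinates:

* **Mature space.** The gene sequence (coding strand, 5′→3′) with
  annotated introns excised, the post-transcriptional `CCA` appended,
  and — for histidine tRNAs — the post-transcriptional G−1 prepended as
  *mature position 1*. Eukaryotic tRNA genes do not encode the CCA, so
  it is appended unconditionally (`appendCCA = TRUE`, configurable for
  unusual references; no deduplication check is attempted when a gene
  happens to end in CCA). Under this convention a 72-nt intron-less
  histidine gene yields a 76-nt mature tRNA whose 3′-terminal fragment
  spans end at position 76 — which is what makes the conventional
  `tDR-<start>:76-His-GTG-…` identifiers terminate at the CCA 3′ end.
  A mature→gene coordinate map is kept; post-transcriptional bases map
  to `NA`.
* **Leader space.** The 50 nt of primary transcript immediately
  upstream of gene position 1, in transcription orientation. No
  consensus leader length exists in the literature; 50 nt is a generous
  default and is configurable (`leaderWindow`).
* **Trailer space.** The 35 nt immediately downstream of the gene 3′
  end (`trailerWindow = 35`), matching the usual extent of
  RNA-polymerase-III trailers before the terminator.

Flanks come either from explicit `leader_seq` / `trailer_seq` metadata
columns (already in transcription orientation) or from a genome FASTA,
strand-aware. Flanks shorter than the window (contig edges) are
truncated with a warning, never padded. Minus-strand genes are stored
as coding-strand sequence on load, so all downstream coordinates are
transcript-relative.

## Fragment classification

Classification is by **exhaustive exact matching**: every occurrence of
the candidate sequence in every region string of every gene is
enumerated (overlapping occurrences included). No mismatches or indels
are tolerated — the pipeline is deterministic by construction, and
modification-tolerant alignment is out of scope. Admissible fragment
lengths are 16–35 nt (`minLength`, `maxLength`), the canonical tRF
size range; shorter or longer queries are returned `unclassified` with
no placements.

Per-placement class rules:

| region  | rule                                   | class     |
|---------|----------------------------------------|-----------|
| mature  | end = mature length (CCA-inclusive)    | `3p_trf`  |
| mature  | start ≤ tolerance, end < mature length | `5p_trf`  |
| mature  | otherwise                              | `i_trf`   |
| trailer | start = 1                              | `trf1`    |
| leader  | end = leader length                    | `5pU_trf` |

The 5′ start tolerance is 1, but **2 for histidine genes**: the G−1 is
post-transcriptional, so a genomically templated 5′ fragment of a His
tRNA begins at mature position 2 and would otherwise be misclassified
as internal. Trailer placements that do not begin at position 1 and
leader placements that do not abut the mature start carry no class
(canonical tRF-1s start immediately after the mature 3′ end; 5′U-tRFs
end immediately before the mature start).

When placements span several classes, the class of highest precedence
is retained and conflicting placements are dropped (counted in
`n_dropped_placements`): mature-space identity is biologically primary,
and within it a CCA-terminal placement is the strongest signal, so the
order is `3p > 5p > i > trf1 > 5pU`. A fragment ending exactly at the
mature 3′ terminus is therefore always a 3′-tRF regardless of where it
starts.

**5′ halves.** tRNA halves arise from anticodon-loop cleavage. When the
metadata provides `anticodon_position`, a 5′ fragment is flagged as a
half if its mature end lies within \[anticodon start − 2, anticodon
start + 4\]. Without that annotation a length heuristic (≥ 30 nt,
`halfMinLength`) stands in.

**Multimapping and naming.** The multimap count is the number of
*distinct mature sequences* containing the fragment (distinct genes for
trailer/leader classes) — isodecoders with identical mature sequence
count once. tDR identifiers take their span from the lexicographically
smallest (gene, start) mature placement and append `-M<k>` when k ≥ 2.
Leader/trailer fragments keep their input ids; a mature-span name would
be meaningless for them, so `nameFragment()` refuses. Catalog ids for
databases of record (e.g. `tRFdb-…` accessions) are treated as opaque
input identifiers, never derived.

## Quantification

A read supports a signature iff the read sequence equals the signature
sequence **exactly and full-length** (case-insensitive, U unified to
T). Prefix/suffix matching would make assignment ambiguous whenever one
signature is a terminal substring of another — exactly the situation of
nested 3′ fragments such as the 17-mer/22-mer pair ending at position
76 — so it is deliberately excluded. Reads matching nothing count only
toward the library size.

Abundance is log2(reads-per-million + 1). The per-million denominator
defaults to the total library size (the convention of miRNA-seq-style
quantification); `denominator = "assigned"` normalises over
catalog-assigned reads instead, in which case per-million values sum to
10^6 per sample before the +1/log transform. "Detected" is defined as
count > 0 in at least half the samples (`minDetectFraction = 0.5`,
configurable) — the filter reports the class and chromosome composition
of the kept set.

## Cohort statistics

**Differential expression.** Per signature, the tumor-minus-normal
contrast on the log2 scale. With complete 1:1 pairing the contrast is
the mean per-pair difference (df = n−1); incomplete pairing degrades to
the unpaired pooled-variance contrast with a warning (cohorts with
unequal group sizes cannot be fully paired). Residual variances are
shrunk by empirical Bayes: the scaled-inverse-chi-square prior
(d₀, s₀²) is fitted by moment matching on log s² via trigamma
inversion, the posterior variance is
s̃² = (d₀s₀² + d·s²)/(d₀ + d), and the moderated t has d₀ + d df. This
is the standard limma-style shrinkage re-implemented; exact numerical
parity with limma is not claimed (the test suite cross-checks the two
on shared data). A Welch-t fallback (`method = "welch"`) exists for
cross-validation; under it zero-variance signatures get `NA` p-values,
while shrinkage handles them natively. Significance is the strict gate
|log2FC| > 1 **and** p < 0.05 on the raw p-value; BH q-values are
reported alongside but do not enter the gate, matching the practice of
gating small-cohort fragment screens on raw p. Results carry signed
log2FC so the direction of every call is explicit.

**Median split and survival.** Tumor samples are split at the median
expression; ties at the median go to "low" (a convention that must be
fixed somewhere — it is stated here and in the function contract). A
constant expression vector is a degenerate split and errors. The KM
estimator is the standard product-limit form with right censoring; the
two-group log-rank test accumulates hypergeometric observed-minus-
expected and variance terms at each distinct event time, with χ² = U²/V
on 1 df.

**Cox regression.** The Breslow partial likelihood is maximised by
Newton–Raphson with analytic gradient and Hessian, tolerance 10⁻⁸ on
the score norm, at most 50 iterations. Breslow's approximation is the
simplest correct tie handling and the default here (ties are common
with day-resolution survival times). Categorical covariates are
dummy-encoded against a stated reference level (first level by
default). Monotone likelihood (perfect separation; detected as
non-convergence or |β| > 20) is flagged and no estimates are returned
for that model. Both a univariate sweep (one model per covariate, as in
forest plots) and a joint multivariate model are provided; Wald tests
and exp(β ± 1.96·SE) intervals are reported.

**Association and correlation.** Pathology categories are tested with
the Pearson chi-square (no continuity correction); any zero expected
cell aborts with advice to merge categories. Spearman's rho is the
Pearson correlation of average-ranked data with the t approximation for
p; genes with zero variance are skipped. The top-k table (default
k = 500) is ordered by |rho|, then rho, then gene id, making the
ranking fully deterministic.

## Enrichment

Gene-set content is always user-supplied as GMT; no ontology or pathway
database is fetched, and term names are data. ORA uses the
hypergeometric upper tail P\[X ≥ k\] with the expression-matrix genes as
the default universe; query genes outside the universe are dropped with
a warning; BH q-values are computed across sets.

GSEA walks the score-ranked list with hit increments ∝ |score|^weight
(normalised over the set) and miss decrements 1/(N−K); the enrichment
score is the running-sum extremum by absolute value, and the walk ends
at 0 by construction. The null is **gene-label permutation** — the
module receives a ranked list, not sample-level expression, so
phenotype permutation is not available; this is a documented deviation
from the phenotype-permuting original. NES divides ES by the mean |ES|
of same-sign permutations; the p-value is the same-sign exceedance
fraction with a +1 pseudo-count (so it is never exactly zero and is
reproducible under a fixed seed). The default ranking metric in the
pipeline is the Spearman rho of each mRNA against the biomarker
fragment. Defaults weight = 1 and 1000 permutations follow common
practice; neither is prescribed by the underlying study design, so both
are configurable.

## Target scanning

The scanner is a deliberately simplified, self-contained stand-in for
external hybridization pipelines, so that the target-prediction stage
exists and is testable. It makes no thermodynamic (ΔG) claims.

Seed sites use the standard miRNA taxonomy with the seed at fragment
positions 2–8: `6mer` (UTR reverse complement of 2–7), `7mer-m8` (RC of
2–8), `7mer-A1` (6mer plus an `A` opposite position 1 — an adenine
anchor on the UTR, regardless of the fragment's first base), `8mer`
(both). All overlapping sites are reported, each once at its best type.
Coordinates are 1-based inclusive on the UTR plus strand, UTRs given
5′→3′.

The duplex score is a local antiparallel complementarity alignment by
affine-gap dynamic programming: Watson–Crick +1.0, G:U wobble +0.5,
mismatch −1.0, gap open/extend −2.0/−1.0, floored at 0. Ties between a
fresh local start and a zero-scoring extension resolve to the fresh
start, which keeps tracebacks finite. One property worth stating: the
score is exactly symmetric under exchanging the two strands, but
reverse-complementing *both* inputs preserves the score only for
Watson–Crick pairings — a G:U pair maps to C:A under that transform, so
with a non-trivial wobble bonus the invariance is approximate by
construction (the test suite checks the exact invariance with the
wobble bonus disabled). A prediction passes when it has at least one
seed site and its best duplex score over a ±30-nt window around a site
(window capped at the scorer's 60-nt limit) reaches the threshold,
default half the fragment length — a scale-free default chosen so that
a fragment must pair over at least about half its length.

## What the synthetic-data module emulates

The generators produce every input format the pipeline consumes, under
one mandatory seed (all outputs are bit-reproducible). Default
parameters are fixed once, at values typical for the kind of study the
pipeline addresses, and are not tuned per analysis:

* **Cohort scale:** 16 tumors vs 9 normals with incomplete pairing
  (9 pairs) — the scale of a small paired tumor/control fragment
  screen, which is exactly the regime where the moderated-t shrinkage
  and the auto-degrading paired contrast matter.
* **Reference:** 8 random tRNA-like genes (70–90 nt), including one
  His-GTG family with 2 isodecoders that share their 3′ 22-mer but
  differ upstream — guaranteeing that 3′-fragment naming exercises the
  `-M2` multimap suffix; a chromosome mix weighted toward chr1/chr6
  mirrors the skewed genomic origin typical of fragment catalogs.
* **Counts:** negative binomial with dispersion 0.3 (typical smallRNA
  overdispersion; no count model is prescribed by the analyses
  themselves) around log-normal baselines (median ≈ 200 reads), with
  planted log2 fold changes (defaults: biomarker −2, one signature +2).
* **Survival:** exponential event times with hazard
  λ₀·exp(β·z), λ₀ = 0.002/day, z the standardized log2 expression of
  the biomarker and β = −log 2 (low expression carries the excess
  risk), censored by an independent Uniform(0, 2000 d) time.
* **Pathology:** a lymphovascular-invasion column associated with the
  biomarker median split (65% vs 25% prevalence), plus independent
  stage/N/M/age columns.
* **mRNA:** 300 genes, the first 50 given Spearman ρ = 0.8 with the
  biomarker through a Gaussian copula (latent Pearson r = 2·sin(πρ/6));
  |ρ| > 0.99 is rejected as infeasible.
* **Reads:** per-sample FASTQs with exact signature copies (optional
  per-base substitution rate ε), plus background 16–35-mers rejected
  against the signature set so they can never increment a count;
  background fills 30% of each library. At ε = 0 counting inverts the
  simulation exactly.
* **UTRs:** 200-nt sequences with exactly one planted 7mer-m8 or 8mer
  site each, with rejection sampling against accidental extra cores or
  type upgrades, so site recall and coordinates are checkable exactly.

What it does **not** emulate: RNA modification- and
structure-driven artefacts (misincorporation, premature termination),
sequencing quality profiles, adapter contamination, batch effects, GC
bias, and real tRNA secondary structure. Passing tests on these
simulations therefore validate the *statistical machinery and its
calibration* (type-I error, parameter recovery, exact inversion at zero
noise), not robustness to the measurement artefacts of real small-RNA
libraries.

## Validation problem sizes

The test suite and the acceptance script validate at sizes chosen to
make the checks statistically meaningful while staying desk-scale:
classifier agreement with a naive all-offsets substring oracle on 1000
mixed fragments; DE null calibration on 2000 signatures at the 16-vs-9
group sizes (variances drawn from the model's own
scaled-inverse-chi-square so raw p-values are exactly calibrated) and
planted-effect detection (log2FC = 2, σ = 0.3) over 200 replicates; Cox
recovery of β = 1 at n = 500 over 50 seeds with ~20% uniform censoring
(median estimate and 95% CI coverage); GSEA permutation-p uniformity
over 200 random sets; planted seed-site recall on 100 UTRs; duplex DP
against an exhaustive recursive oracle on ≤ 20-nt pairs. Cross-checks
against independent implementations (limma's shrinkage, survival's KM /
log-rank / Breslow Cox) run in the test suite only — the package never
calls them.

## Known limitations

* Exact matching means fragments from heavily modified positions
  (which cross-map with mismatches in real data) are invisible; that is
  a scope decision, not an accident.
* The trailer/leader windows are fixed-length proxies for the real
  primary transcript; a tRF-1 longer than 35 nt or a leader fragment
  deeper than 50 nt will not be found at the defaults.
* The duplex scorer is not a thermodynamic model; scores rank
  complementarity, nothing more.
* Survival simulation uses a constant baseline hazard; the Cox
  machinery itself is, of course, baseline-free.
* The pipeline analyses one biomarker fragment at a time in the
  survival/correlation stages; genome-wide screens loop over
  signatures.
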