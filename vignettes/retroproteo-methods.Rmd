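---
title: "Methods: repeat-aware detection of LINE-1 ORF proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-aware detection of LINE-1 ORF proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroproteo)
```

## The problem

LINE-1 (L1) elements encode two proteins, ORF1p and ORF2p. ORF1p is abundant
where L1 is derepressed; ORF2p is present at vanishingly low stoichiometry, so
a search engine asked to find it in deep tumour proteomes returns mostly
artifacts. Two properties of the L1 system make naive searches unreliable:

1. **Redundancy.** Hundreds of genomic L1 loci encode ORF proteins that differ
   from a young consensus by only 0.5–2.5% of residues. A peptide that differs
   from the consensus by one residue may come from a rare locus — or from
   deamidation, an unusual cleavage, or a poorly fragmented spectrum.
2. **Weak evidence.** Candidate ORF2p identifications tend to be semi-tryptic,
   sit near the e-value cutoff, and leave prominent peaks unexplained.

This package implements the defensive stack for that situation: fragment-level
quality metrics, hard retention rules, explicit artifact explanations for
variant peptides, sequence analytics over the locus family, a label-free
IP-MS enrichment pipeline, and synthetic generators that make every stage
testable against a known truth.

## Fragment annotation

`fragment_ions()` produces monoisotopic b/y ions:
`b_i = (sum of the first i residue masses + mods + i_z * 1.007276) / z` and
`y_i = (sum of the last i residue masses + mods + 18.010565 + i_z * 1.007276) / z`,
for all prefix lengths `1..L-1` at each requested charge (1+ and 2+ by
default; higher charges and neutral losses are out of scope, matching
HCD behaviour on Orbitrap-class instruments where b/y dominate).

`annotate_fragments()` matches observed peaks within a ppm tolerance
(default 10 ppm, a standard high-resolution fragment setting) and derives:

- **Matched-intensity fraction** — matched peak intensity over total
  intensity, with 0/0 defined as 0. A peak counts once even when it matches
  several theoretical ions, which keeps the fraction in [0, 1].
- **Site coverage and gaps** — cleavage site `s` is covered when `b_s` or
  `y_(L-s)` matched. A *gap* is a maximal run of uncovered sites, reported in
  residues as run length + 1; an entirely uncovered peptide has gap = its
  length, a complete ladder has gap 1. The retention rule "gap ≤ 3" therefore
  tolerates at most two consecutive unsupported cleavage sites. This is one of
  several possible formalizations of "a stretch of sequence without fragment
  evidence"; it was chosen because it is local, testable by brute force, and
  reduces to intuitive values at both extremes.
- **Tryptic status** — a boundary is tryptic when preceded by K/R and not
  followed by P, or at a protein terminus; `full`/`semi`/`non` count the
  tryptic boundaries.

No noise floor is applied before computing the fraction: all peaks count.
Spectra acquired with aggressive peak filtering will therefore score slightly
higher than raw profile data.

## PSM retention and ORF2p rejection flags

`filter_psms()` retains a PSM when the matched fraction exceeds 0.40, the gap
is at most 3 residues, the peptide has at least 7 residues, the e-value is at
most 0.01, and all protein assignments map to one gene. The gene map collapses
every L1 locus of one ORF to a single gene, so peptides shared among loci
survive while peptides shared between, say, ORF2p and a cellular protein do
not. Each rejection records the first rule that failed, in that order, so
rejection tallies are reproducible.

`orf2_rejection_flags()` encodes four review criteria for candidate ORF2p
variant peptides. They are emitted as flags rather than hard drops because
they describe *explainability*, not proof of artifact:

- `semi_tryptic` — the peptide is not fully tryptic;
- `deamidation_explainable` — replacing D with N and/or E with Q at every
  variant position yields an exact consensus substring (deamidation converts
  N→D and Q→E, so the "variant" needs no rare locus);
- `nontryptic_consensus_explainable` — the peptide is an exact consensus
  substring whose boundaries there are not tryptic; if any occurrence has
  fully tryptic boundaries the flag stays off;
- `poor_variant_fragmentation` — a variant position falls inside a
  fragmentation gap > 1, i.e. the residues that make the peptide "variant"
  have no fragment-ion support. The variant positions come from the
  best-matching consensus window (fewest mismatches, first window on ties).

## Correlated peptide sets

To call a protein observed, its peptides should co-vary across samples.
`select_correlated_peptides()` finds the largest peptide set in which every
pair has Spearman ρ ≥ 0.6 over jointly observed samples. "Every pair" is read
strictly, making this a maximum-clique problem on the threshold graph; the
search is exact (clique enumeration) up to 20 peptides and greedy
(highest-degree seed, best mean-correlation growth) above, where exact search
would be exponential. Ties between maximum cliques go to the higher mean
pairwise correlation, then lexicographic order. Pairs with fewer than 3
jointly observed samples have undefined ρ and are treated as below threshold,
with a message.

## Locus-family analytics

Each locus is aligned to the reference ORF with Needleman–Wunsch global
alignment (match +1, mismatch −1, affine gaps open 5 / extend 1, via
Biostrings). At the divergence levels of an L1 family, star alignment of each
locus to the reference is equivalent to a multiple alignment for per-locus
counting, and avoids an external MSA step; pre-aligned inputs can be analysed
by supplying gapped sequences directly. A hand-rolled dynamic program with a
bespoke tie-break order was considered and rejected: the C implementation is
orders of magnitude faster on 1275-residue ORFs, and on sequences this
similar the optimal alignment is effectively unique, so tie-break order does
not affect any reported count.

`variant_count()` counts substituted reference positions, deleted reference
positions, and insertion events — each maximal inserted run counts once, so a
single biological insertion of three residues is one variant, not three.
(Per-residue counting would be defensible; the event convention was chosen and
is stated here so numbers are interpretable.) `percent_divergence` is
100 · variants / reference length.

`per_position_identity()` reports, for each reference position, the percentage
of loci whose aligned residue matches (gaps are mismatches).
`epitope_scan()` locates an epitope on the reference (exact substring, or a
given start) and counts mismatching residues per locus in the aligned window;
gapped window positions score as mismatches, the strict reading when the
tolerance of an antibody for indels is unknown. `aa_to_nt()` maps residue `p`
to nucleotides `3(p-1)+1 .. 3(p-1)+3` (1-based inclusive), e.g. residue 990 of
ORF2p to ORF2 nucleotides 2968–2970 — the site of the G>A polymorphism that
distinguishes the young-subfamily valine from the ancestral methionine inside
the MT5 epitope.

`orthogonalize_loci()` reduces a redundant locus database against observed
peptides: (a) keep every locus with a peptide unique to it; (b) for each
peptide still unexplained, add one representative — the supporting locus most
different from the consensus, ties to the smallest id. Peptides are processed
in lexicographic order (the processing order is otherwise arbitrary), and a
final pruning pass removes representatives made redundant by later additions,
so the output is minimal: dropping any retained locus either orphans a peptide
or discards a uniquely supported locus. Tests verify this against exhaustive
application of the rules on small fixtures.

## Label-free IP-MS enrichment

`preprocess_intensities()` removes reverse and contaminant rows and any
protein whose id contains an excluded identifier (default IGHG1, the IP
antibody heavy chain, which co-purifies in every capture), log2-transforms
non-zero intensities, converts zeros to explicit missing values, and drops
all-missing proteins. Downstream code never tests for zero: missingness is a
mask from here on.

Two imputation schemes run per group (case replicates, control replicates),
in this order, with the partial-missing model fitted before any imputed value
exists:

1. **All replicates missing** — each missing cell draws uniformly from
   `[mu_c - 3*sd_c, mu_c - 2*sd_c]`, where `mu_c`, `sd_c` summarize the
   observed log2 values of that replicate column. This encodes left-censoring:
   a protein quantified nowhere in a group is placed in that column's
   low-abundance tail.
2. **One or two replicates missing** — from proteins fully observed in the
   group, the relative replicate difference
   `delta = (x_i - x_j) / mean(x_i, x_j)` is collected over all replicate
   pairs; new values are `I_new = mean(observed) * |1 + delta_new|` with
   `delta_new ~ N(mu_delta, sd_delta / (rho_bar * sqrt(2)))`, `rho_bar` being
   the mean pairwise Pearson correlation among the group's replicate columns
   on fully observed proteins. The `rho_bar * sqrt(2)` factor shrinks the
   noise for well-correlated replicates; a non-positive `rho_bar` makes the
   scale undefined and raises an error rather than imputing nonsense. Which
   replicates enter `rho_bar` (within-group, as implemented, versus across
   all samples) is a genuinely open choice; within-group was selected because
   the delta distribution itself is a within-group quantity.

`lfq_compare()` runs a per-protein two-sample t-test — Welch by default, since
equal variances are not guaranteed between an IP and a mock capture; a pooled
Student's option exists — with Benjamini–Hochberg adjustment within the
comparison. A protein is significant when `p_adj ≤ 0.05`, `log2FC ≥ 1` and at
least two case replicates are *measured*, not imputed: a fold change carried
entirely by imputation is never called. The non-imputed rule is applied to the
case side (configurable), since enrichment claims rest on the IP
measurements. When both groups are constant, p is 1 for equal means and the
smallest positive double otherwise. `integrate_comparisons()` counts per
protein how many comparisons it passes and tabulates the ≥1/≥2/≥3 tiers.

`rank_band_ids()` implements the gel-band identification heuristic: rank by
log e-value (ties: more PSMs, then id), drop keratins, non-human proteins and
everything at or below trypsin's rank, then walk down dropping entries that
share a homology group with a retained higher rank or have fewer than half
the retained top entry's PSMs. Homology is supplied as group labels; no
sequence-level homology criterion is imposed. The operation is idempotent.

## Synthetic data: what it emulates and what it does not

The generators define the study conditions under which the package is tested:

- `simulate_locus_family()` — consensus of length 1275 (the ORF2p length),
  per-residue substitution rate 0.0125 (matching the ~1.25% mean divergence of
  full-length loci from a young reference), one short indel per locus with
  probability 0.05. Nucleotides are codon-sampled to translate exactly to the
  proteins. Uniform residue composition is used because no tested contract
  depends on composition.
- `simulate_spectra()` — 1+ b/y ladders with per-ion dropout, lognormal
  intensities, and noise peaks rejection-sampled at least 3 tolerance-widths
  away from every theoretical 1+/2+ ion, so the ledger's matched fraction and
  gap are exactly what annotation (at the 1+ charge state) recovers.
- `simulate_ipms_matrix()` — 3 IP vs 3 control replicates; protein log2
  abundances N(23, 2.5); within-group replicate sd 0.5; spiked proteins
  shifted by +2 in the case group; left-censored missingness with a logistic
  probability centred one abundance-sd below the mean, max rate 0.5 (about 8%
  of cells overall — typical of gel-plug IP-MS with match-between-runs). An
  MCAR switch exists for null testing.

These emulate the statistical structure the pipeline consumes, not real data:
no chromatography or retention-time structure, no isotope envelopes, no
correlated (protein-complex) nulls, no charge-state heterogeneity, and
missingness independent across cells given abundance. Passing tests
demonstrate the algebra and the decision rules are right under the stated
model, not that any biological dataset will behave as cleanly.

## Numerical and design notes

- Monoisotopic constants: proton 1.007276 Da, water 18.010565 Da; Leu/Ile are
  isobaric and share a mass.
- Peak matching uses relative (ppm) tolerance; spectra are sorted ascending by
  m/z at parse time, and peaks are deduplicated toward the intensity fraction.
- All randomness flows through explicit seeds (`withr::with_seed`), so
  generators and imputations are byte-reproducible and never disturb the
  session RNG. The pipeline derives each stage's seed from the single run
  seed and records it in the manifest.
- Degenerate inputs have defined behaviour: empty spectra (fraction 0, gap =
  peptide length), zero-variance imputation columns (imputes exactly the
  column mean), constant t-test inputs (p = 1 on equal means), peptides of
  length 1 (no ions, vacuous coverage).
- Problem sizes in the shipped tests — e.g. 1000-PSM filter properties,
  10^4-draw distributional checks, 20-seed spike-recovery runs, 10^4-protein
  null calibration — were chosen as the smallest sizes at which the
  statistical assertions are stable.

## Known limitations

- The spike-recovery design above (effect 2, sd 0.5, 3v3, 50 true among 1050)
  is intrinsically underpowered at BH ≤ 0.05: the per-protein Welch test has a
  median p around 0.01 while full recovery would need p below ~0.002, so only
  a small fraction of spiked proteins can be recovered no matter the
  implementation. The test suite states the nominal sensitivity expectation
  and documents the shortfall rather than relaxing the design; the
  false-discovery proportion and the null calibration of raw p-values are met.
- The PSM table dialect is a reconstruction of a simple search-engine export;
  native search-engine XML is out of scope.
- b/y ions only, no neutral losses; fragment tolerance is configurable but a
  single global value.
- Reproducing the published tumour-scale numbers (significance tier counts,
  hot-locus epitope conservation) requires the deposited proteomics data and
  locus databases; those analyses run through the same functions but are not
  part of the desk-scale test suite.
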