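---
title: "zfx methods: finger grammar, structural classification and stress statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{zfx methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfx)
```

## The finger model

A C2H2 zinc finger coordinates a zinc ion through two cysteines and two
terminal residues that are histidines in the canonical form and may be a
cysteine in degenerate variants. `zfx` models a finger purely by spacing:

```
C X(a) C X(b) T1 X(c) T2
```

with `a` the gap between the cysteines, `b` the gap to the first terminal
residue (the stretch between the second cysteine and `T1` is called the
*helix* here, since it holds the recognition helix), and `c` the gap
between the terminals (the *H-gap*). The default grammar admits
`a` ∈ 1–4, `b` ∈ 12–20, `c` ∈ 3–7 and `T1, T2` ∈ {H, C} with at least one
histidine. These bounds are the union of the plant consensus
Cys-X2-4-Cys-X12-His-X3-5-His and the degenerate four-finger signature
rows of the A1 subsets (which include CX4CX20HX4H, CX2CX13HX3C,
CX1CX12HX3C and CX1CX12HX7H); a narrow H/H-only grammar would miss the
H…C-terminated third and fourth A1 fingers. All bounds are arguments of
`finger_grammar()`, so a narrower or wider grammar is one call away.

**Scanning policy.** Matches are taken left to right and never overlap.
When a window admits several parses, the canonical (H/H) parse wins, then
the shortest, then the smallest cysteine and inner gaps. This order is a
determinism device, not a biological claim: it favours the consensus form
and makes the scan a pure function of the sequence. The test suite checks
the scanner against an independent brute-force enumeration of all
grammar-compatible substrings followed by the same selection policy.

**Linkers and arrays.** The linker between consecutive fingers is counted
strictly between the last coordinating residue of the left finger and the
first cysteine of the right one — the coordinating residues delimit the
finger, and the domain envelope is not otherwise defined by a spacing
grammar. Linkers of at most `tandem_threshold = 10` residues merge
fingers transitively into a tandem array; longer spacers leave them
dispersed. The threshold is the published short-linker rule and is
configurable.

## Structural classification

Classification is hierarchical and purely architectural:

* **Set B** (TF3A-like) requires at least 6 fingers in at least 2 tandem
  arrays. A pure finger-count rule would misclassify large tandem-array
  proteins of set A, so the trigger couples count with the multi-array
  layout of the nine-finger TFIIIA architecture ({1}, {2–4}, {5–9}).
* **Set A** requires at least one tandem array of two or more fingers.
* **Set C** is everything else with at least one finger. A protein with
  no finger is reported `unclassified`, never forced into a set.

Within set C the H-gap decides the subgroup: 3 → C1, 4 → C2, 5 → C3.
Pure-C1 proteins get subset `C1-k` with `k` the finger count; proteins
mixing H-gaps 3 and 4 form the `C1C2mixed` subset and are counted inside
C1, following the published convention. H-gaps outside 3–5 are legal under
the grammar but atypical for the taxonomy; they are excluded from the vote
with a warning and, if nothing typical remains, clamped to the nearest
class — a majority rule keeps a single odd finger from orphaning a protein
out of the partition.

Within set A, the A1 subgroup is recognized by the four-finger template
(finger 1 exactly CX2CX12HX3H, finger 2 with a cysteine gap of 4). Subsets
are decided in order: PCYCC motif → A1d; SATALL block → A1a; the A1c
spacing row (finger 2 inner gap 20 and finger 3 CX2CX13HX3C) → A1c;
otherwise A1b. The order matters only where motifs could co-occur, and
places the rarer, more specific PCYCC first. Non-A1 members split into A2
(three or more fingers spanning more than one arrangement component) and
A4 (a single tandem array). This A2/A4 boundary is a documented heuristic:
the source taxonomy lists members rather than a rule, so the split is kept
in `classify_config()` where it can be tuned.

Motif evidence is positional: QALGGH counts only inside finger helices
(the Q-type marker is a helix feature and is descriptive metadata, not a
classification key), SATALL is matched as the lead of the conserved
C-terminal SATALLQKAAQMGS block in the region after the last finger, and
PCYCC anywhere.

## Physicochemical profiling

`molecular_weight()`, `isoelectric_point()`, `instability_index()` and
`gravy()` implement the ExPASy ProtParam conventions: average residue
masses plus one water; the Bjellqvist pKa set (side chains D/E/C/Y/H/K/R
plus termini, with residue-specific terminal pKa values) solved by
bisection on pH 0–14 to |ΔpH| < 0.005, which is well inside the 2-decimal
reporting convention; the Guruprasad dipeptide-weight sum (10/L × Σ DIWV);
and the Kyte–Doolittle mean hydropathy. The constants are embedded and
were cross-checked against an independent implementation of the same
model; frozen reference values guard them in the tests. `X` residues are
tolerated on input but excluded from all sums with a per-protein warning —
silently assigning a mass or hydropathy to an unknown residue would
corrupt the profile.

## Genomic stages

Gene models come from GFF3 via `rtracklayer`; when a gene carries several
mRNAs, the transcript with the largest summed exon length provides the
exon set. The collapsing rule is this package's choice — annotation-based
family studies rarely state one — and is the only interpretation step in
the reader. Names are assigned by natural chromosome order (numeric
suffix; unplaced scaffolds after all chromosomes, alphabetically) and
ascending start, with ties broken by end then gene id under a warning.

Tandem duplicates are pairs of family genes on one chromosome separated by
at most one other family gene whose proteins share ≥ 70 % identity under
global Needleman–Wunsch alignment (BLOSUM62, gap open 10, gap extend 0.5,
identity = matches / alignment length). Both thresholds follow common
gene-family practice and are exposed; the alignment scoring is pinned so
the pair list is deterministic.

## Expression and stress statistics

Expression filtering keeps genes whose maximum FPKM across conditions is
strictly above 1; the transform is log2(FPKM + 1), defined at zero and
order-preserving. Profile grouping z-scores each gene, computes
correlation distance (1 − r) and cuts an average-linkage tree into k = 7
groups, mirroring the seven developmental and stress profile groups of the
motivating study; the method triple (distance, linkage, z-scoring) is
recorded in the result object because the original analysis names no
algorithm — the choice here is pinned configuration, not a claim about the
original work. Group labels are ordered by centroid peak position so they
are invariant to row order. Constant rows cannot enter a correlation
distance and are assigned to the nearest centroid afterwards, with a
warning.

qPCR fold changes use 2^−ΔΔCt with ΔCt = Ct_target − Ct_reference;
replicate-level fold changes are averaged and their sd reported, since
triplicates without an aggregation rule are the common reporting
convention.

Enzyme panels are summarized as mean ± sample sd. Percent change is
100 × (treated − control)/control against the CK control. Letter groups
come from one-way ANOVA followed by Tukey HSD at α = 0.05; the compact
letter display is built by the standard insert-and-absorb construction
over the Tukey p-values, with letters assigned in descending mean order
starting at "a", so treatments sharing no letter differ significantly.
Correlation of expression with physiology uses Pearson r with the
two-sided t test, per replicate when replicate-level expression exists and
per treatment mean otherwise (then n = 4, flagged by a low-n warning);
p-values are unadjusted at α = 0.05 by default, matching the 0.05-level
significance maps such analyses publish, with `adjust = "BH"` available.

## The synthetic study

The generator exists so that every stage has an exact round trip. Its
defaults are the study conditions of the motivating analysis:

* a 77-protein proteome whose planted composition is the published family
  layout (A1a–A1d 13/1/3/7, A2 2, A4 3, B 2, C1-1…C1-5 19/11/1/2/1,
  C1C2mixed 2, C2 9, C3 1 — 29/2/46 across sets A/B/C, 31 tandem-array
  proteins);
* an FPKM matrix of 77 genes over the four water-stress treatments with
  34 genes kept below the expression threshold, leaving the 43-gene
  expressed set, and seven planted profile archetypes (Gaussian bumps
  sliding across the conditions) with configurable linear-scale noise
  (truncated at zero to keep FPKM non-negative);
* an enzyme panel drawn Normal(mean, sd) from the published per-treatment
  means and sds at n = 3 replicates;
* toy gene models over 12 chromosomes (10 genes on the second, one on the
  eleventh) with one planted adjacent duplicate pair on the fourth.

Background residues exclude C and H, so planted fingers are provably the
only grammar matches and zero-noise classification recovery is exactly
100 %; a `hostile = TRUE` mode re-admits them to stress-test the scanner.
QALGGH is inserted at the start of a helix so its histidine sits at an
inner offset no parse can use; PCYCC is flanked by guard background so its
cysteines cannot complete a window.

What the generator does **not** emulate: real sequence composition
(backgrounds are i.i.d. over 18 residues), homology between family
members, fingers that violate the grammar, annotation noise in gene
models, and count-based noise models for expression. Passing round trips
therefore demonstrate correctness of the detection/classification logic
under the stated grammar, not robustness to every form of real-data
degeneracy; the oracle-equivalence property on random C/H-enriched
sequences covers the scanner's behaviour outside the planted regime.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale: the scanner
oracle comparison uses 1,000 random sequences of up to 200 residues,
planted-label recovery uses a 231-protein zero-noise proteome, the null
calibration of the correlation flag uses 1,000 simulations at n = 12, and
the letter-pattern power check uses 100 seeds at n = 3. These sizes give
binomial standard errors comfortably inside the tolerances being checked
while keeping a full run around a minute. Every source of randomness is
seeded; the pipeline writes a resolved config and manifest beside its
reports, and two runs on the same inputs are byte-identical.

## Known limitations

* The grammar is spacing-only: it cannot separate a true finger from a
  chance C/H arrangement with compatible spacing, and it does not model
  the rare CCHC or CCCC finger chemistries.
* The A2/A4 boundary is heuristic, and the set-B trigger is tuned to the
  TFIIIA architecture; families with ten-finger clusters would need a
  different trigger.
* Subset `C1-k` labels follow finger multiplicity; `k` > 5 yields labels
  beyond the published range rather than an error.
* The pI model ignores cysteine oxidation state and post-translational
  modification, as all ProtParam-style calculators do.
* Treatment-mean correlation (n = 4) has very low power and wide r
  uncertainty; the low-n warning is deliberate.
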