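---
title: "Interphase chromosome profiling: model, simulator and caller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interphase chromosome profiling: model, simulator and caller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icprofiler)
```

## The problem

Products-of-conception specimens are karyotyped to explain a pregnancy loss,
but conventional cytogenetics depends on cell culture (which fails often and
is slow) and targeted FISH panels cover only a handful of chromosomes.
Interphase chromosome profiling (ICP) sidesteps culture: every chromosome is
probed in its own multi-color FISH hybridization of interphase nuclei, and a
whole-genome molecular karyotype is assembled from the per-chromosome signal
patterns. `icprofiler` implements that analysis chain as testable software:
a probe-panel model, a nucleus-level spot simulator, a signal-pattern
extractor, a rule-based per-chromosome caller, and a genome-wide assembler
that emits (and parses) the `icp.` nomenclature dialect.

## Probe panels

The **Standard Resolution** panel runs 23 hybridizations: one per autosome
plus a joint X/Y hybridization. A typical chromosome carries a GREEN
p-subtelomere probe, a YELLOW pericentromeric probe and a RED q-subtelomere
probe; acrocentric chromosomes (13, 14, 15, 21, 22) have no short-arm probe;
the Y short arm is AQUA so X and Y are separable in their shared
hybridization. The **Acrocentric** panel is a single five-color
pericentromeric mix (13 YELLOW, 14 GREEN, 15 RED, 21 AQUA, 22 FARRED) whose
only purpose is Robertsonian translocation detection: a derivative fuses two
pericentromeric regions, so its two colors appear consistently juxtaposed.

The X-chromosome subtelomere colors are not stated explicitly by the design
figures, which show "a typical metacentric chromosome"; we assign GREEN/RED
as for autosomes. That single assumption is what lets XX/XY/XXY complements
be resolved from the GREEN (X count) and AQUA (Y count) primaries, with the
shared YELLOW total serving as an X+Y consistency check.

## The karyotype mini-language

One grammar serves simulator input and the packaged validation fixtures.
It accepts plain cytogenetic strings (`47,XX,+16`), `icp.`-prefixed strings
with an optional `[cpN]` composite suffix, `/`-joined mosaic populations,
`"XX or XY"` sex alternatives, and the descriptive shorthand used by the
early validation cohorts (`Trisomy 16`, `Monosomy X,del(17q)`,
`+21,der t(14;21)`). Band labels inside parentheses — including `?` — are
carried as opaque text and never interpreted genomically; terminal-deletion
arms are read from the first `p`/`q` character of the band text, so
`del(4)(pter)` and `del(4)(p?)` denote the same event class. A `+N`
following a Robertsonian `der` involving chromosome N is folded into the
event as its translocation trisomy. Rendering orders events by the lowest
chromosome involved, structural events before plain gains/losses, which
reproduces every printed fixture string; `same_karyotype_class()` compares
two strings on ploidy, sex compatibility, gains/losses and event classes
while ignoring chromosome counts and band text (one printed fixture string
carries a count inconsistent with its own events).

## The simulator

The nucleus is a two-dimensional unit disk — a microscopy projection; a
third dimension would add nothing to rule-based count logic. For each cell:

* every chromosome copy (or derivative, or displaced terminal fragment)
  is a **territory** whose center is uniform in the disk;
* each of its signals is placed at the center plus isotropic Gaussian noise
  with standard deviation `territory_sd` (default 0.06 nucleus radii),
  truncated to the disk;
* signals of a true fusion group (a Robertsonian derivative's two
  pericentromeric targets) are placed within `0.9 × fusion_distance` of
  each other (`fusion_distance` default 0.05 radii, also the extraction
  radius);
* each true signal is dropped with probability `1 − p_detect`, duplicated
  within the fusion distance with probability `p_split` (so splits re-merge
  at extraction), and each color receives Poisson(`background_rate`)
  uniform spurious spots.

Defaults are noise-free (`p_detect = 1`, `p_split = 0`,
`background_rate = 0`, 20 cells per hybridization, matching the 20-nucleus
scoring minimum); noise is opt-in because no quantitative detection-noise or
satellite-association rates are published — the noisy settings exercised in
the tests are regression guards, not reproductions of measured error rates.

Two placement details are deliberate design choices:

* **Finite resolution.** In the default territory mode, spots belonging to
  *different* signal clusters are kept at least `2 × fusion_distance`
  apart (rejection sampling). Distinct loci that a scorer can resolve are,
  by definition, farther apart than the juxtaposition distance; without
  this constraint a noise-free simulation would sporadically produce
  chance juxtapositions and same-color merges, and noise-free extraction
  could not be exact in every cell. Chance colocalization is still fully
  available for study: setting `territory_sd = Inf` places every signal
  i.i.d. uniformly with no separation constraint (the calibration mode
  checked against an independent Monte-Carlo oracle), and background spots
  colocalize freely.
* **Displacement.** A translocated terminal segment rides on a partner
  chromosome that is invisible in the segment's own hybridization, so the
  displaced signal gets an independent uniform territory of its own — away
  from its chromosome's pericentromeric signal. This is the generative
  mechanism behind the "displaced signal" images; the mechanism is our
  choice, since the source material shows displacement only as images.

Determinism: every hybridization derives its own seed from the master seed
and the hybridization id via a fixed polynomial hash (`derive_seed()`), so
results are reproducible and independent of iteration order; identical
inputs give byte-identical spot tables.

## Extraction and per-chromosome calling

Spots of one cell are clustered by **single linkage** at the fusion radius:
clusters are connected components of the graph joining spots at distance
`≤ r` (closed ball, so ties at exactly `r` join — deterministic on
exact-coordinate fixtures). Single linkage is chosen over centroid linkage
so chains merge. Same-color spots in one cluster count as one signal, which
is what makes split signals harmless; a cluster with two or more colors is
one fusion event. The implementation is `stats::hclust`/`cutree`; the test
suite checks it against an independent brute-force all-pairs component
oracle on hundreds of random instances.

Calling rules, with defaults:

* **Copy number** (`call_copy_number`): the primary is the modal per-cell
  count; ties break toward 2 (the diploid expectation, minimizing false
  aberration calls), then toward the smaller count. A secondary population
  is mosaic only if it has ≥ 4 cells **and** ≥ 20% of cells — at n = 20
  these coincide with the four-of-20 rule; for other n both are required,
  a conservative generalization.
* **Juxtaposition** (`call_fusion`): abnormal strictly above the 20%
  normal cut-off, so 4/20 fused nuclei is still normal and 5/20 abnormal
  — we follow the `>` symbol of the published rule. Each laboratory is
  expected to set its own cut-off; `estimate_cutoff()` returns the larger
  of the maximum observed control fraction and the one-sided exact
  binomial (Clopper–Pearson) upper bound on the pooled control rate.
* **Displacement** (`displacement_evidence`): a terminal-color cluster
  farther than `displaced_threshold` (default 0.35 radii) from every
  pericentromeric cluster. With `territory_sd = 0.06`, the distance from
  a signal to its own territory's pericentromeric signal is Rayleigh with
  scale ≈ 0.085, so a normal signal exceeds 0.35 with probability
  ≈ 2×10⁻⁴, while a uniformly displaced signal does so in roughly three
  quarters of cells — both sides clear the 20% cut-off by wide margins.
* **Interpretation** (`interpret_chromosome`): uniform counts above/below
  baseline are GAIN/LOSS; a terminal count below the pericentromeric
  count is a terminal deletion of that arm; above it (or displaced with
  normal counts) is displaced-terminal evidence; an abnormal fusion is
  FUSION; several event types together give MIXED with all evidence kept.
* **Breakpoint refinement** (`refine_breakpoint`): for any ordered-band
  panel, the breakpoint lies between the last present band and the first
  absent band of the terminal absent run; all-present means no breakpoint,
  all-absent puts it proximal to the first band; interstitial absences
  are reported but never explained by a terminal breakpoint.

## Genome assembly

The baseline copy number is the modal autosomal pericentromeric primary
(2/3/4 → diploid/triploid/tetraploid), and per-chromosome events are
re-expressed against it, so triploids do not surface as 22 gains. Sex is
read from the X/Y hybridization (GREEN = X, AQUA = Y). Robertsonian events
come from the acrocentric mix: each clean abnormal pairwise fusion becomes
`der(a;b)(q10;q10)`, unbalanced with `+c` when exactly one participant
exceeds baseline; a color fused to two partners is flagged, never
auto-resolved, and the matching whole-chromosome gain is consumed by the
derivative so the same evidence is never emitted twice. Terminal
gain/loss/displacement evidence is paired mechanically — terminal loss +
extra terminal → `der(B)t(A;B)` with `?` breakpoints; two displaced
terminals → balanced `t(A;B)`; leftovers stay `del` or are flagged — using
greedy ascending-chromosome order, with multi-pairing ambiguity reported
as a flag. This mechanizes what a cytogeneticist resolves by judgment;
the fewest-event pairing is the only defensible automatic rule.

Mosaics: a second copy-number level supported by at least half the
autosomes (in either primary/secondary orientation) is one genome-wide
ploidy population, not 22 aneuploidies. Within the X/Y hybridization the
two ploidy populations are then separated **per cell** by total X+Y signal
count before taking per-population modes — at 20 cells the minority
population can win the mode in one hybridization by sampling accident, and
the joint per-cell total is immune to that. A male/female split
(AQUA-positive vs negative classes each satisfying the mosaic rule) is
reported as two populations without designating which is fetal: maternal
cell contamination and true sex-discordant mosaicism are a pre-analytic
distinction no caller can make. Chromosome counts are recomputed from
ploidy, sex and events (a Robertsonian derivative subtracts one), and the
final string is `icp.` + count + sex + ordered events + populations +
`[cpN]`, with N the minimum cells analyzed across hybridizations.

## Problem sizes and numerical choices

The packaged validation fixtures transcribe the four published cohorts (43,
40, 41 and 250 specimens; the 250 are printed as 31 result classes and
expanded female-first per the printed sex counts). The end-to-end suite
re-simulates all 41 stage-2 laboratory-1 specimens and one case per
laboratory-2 class, noise-free at 20 cells per hybridization — about 1500
simulated nuclei per case over 24 hybridizations, a few seconds per case.
Monte-Carlo calibration checks use 2000–3000 uniform-mode cells against a
(2–3)×10⁴-replicate oracle and compare within three combined standard
errors. The noisy regression guard runs 100 replicates of a trisomy at
`p_detect = 0.95`, `background_rate = 0.1`.

## Limitations

The simulator emulates signal multiplicity, true fusion geometry,
territory scatter, displacement, detection dropout, splitting and uniform
background. It does **not** emulate pixel-level images, optics or
point-spread functions, intensity variation (a "dim" signal is modeled as
absent), satellite association rates of acrocentric p-arms,
hybridization-efficiency chemistry, 3-D nuclear structure, or spatially
correlated noise. Passing its tests therefore shows the *rules* are
implemented faithfully, not that real microscope data would be called with
these error rates. Interstitial deletions between a subtelomere and the
centromere are invisible to the Standard panel by design; X p-arm
deletions alias into the X count in the joint X/Y hybridization; and
q-terminal events are attributed to X only in the absence of Y, otherwise
flagged ambiguous.
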