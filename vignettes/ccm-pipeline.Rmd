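---
title: "Methods: classifying cotransin sensitivity and screening signal anchors for the conformational consensus motif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cotransin sensitivity and the conformational consensus motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccmscan)
```

## Scientific setting

Cotransin inhibits the Sec61 protein-conducting channel in a
signal-sequence-dependent manner: some secretory and membrane proteins
stop being synthesised into the ER under treatment while others are
untouched. Quantitatively this is measured by SILAC label-swap
proteomics — cells treated with cotransin versus DMSO vehicle, with the
isotope labels exchanged between the two replicate experiments — and the
question of *which sequence feature* makes a signal sequence sensitive
is then a sequence-analysis problem. `ccmscan` packages that analysis:
ratio-based sensitivity classification, fuzzy motif scanning of signal
anchor sequences, enrichment testing, property profiling, helical
projection, motif design and dose–response modelling.

This vignette records the models, the defaults and why they were chosen,
and what the tests do and do not establish.

## Sensitivity classification

A protein with DMSO/cotransin expression ratio $r_f$ (forward,
heavy/light) and $r_r$ (reverse, light/heavy) is called

* **sensitive** iff $r_f > t$ **and** $r_r > t$,
* **up-regulated** iff $r_f < 1/t$ and $r_r < 1/t$,
* **resistant** otherwise, and **incomplete** when a ratio is missing,

with $t = 1.65$ by default. The inequality is strict ("higher than"), so
a tie at the threshold is resistant. Requiring both experiments makes the
filter strictly more conservative than either single experiment — the
sensitive set is provably a subset of each single-experiment set, which a
property test asserts. The reciprocal up-regulation rule is this
package's extension: the screen design is symmetric under label exchange,
so the natural mirror of "both above $t$" is "both below $1/t$"; only a
single up-regulated protein is expected in a cotransin screen and the
rule is not used by any downstream stage.

Proteins quantified in only one experiment are marked `incomplete` and
kept out of the sensitive/resistant strata rather than silently dropped.

## The conformational consensus motif

The motif is defined over residue *classes*, not letters:

* **small** (cavity-forming): G, A, S, T, C;
* **bulky** (separator): by default the complement of the small class
  over the 20 standard residues. The motif's source data never
  enumerate the separator class beyond calling it "more bulky", so the
  complement is the least-committal reading; a hydrophobic-only
  alternative (`L, I, V, F, M, W, Y, P`) can be supplied when a stricter
  transmembrane interpretation is wanted. Whether proline belongs in a
  helical separator is genuinely open; the complement default includes
  it, the hydrophobic set makes it optional.
* **flank**: large charged (D, E, K, R, H — histidine counted as
  charged), large polar (N, Q) and aromatic (F, W, Y) residues.

The motif core is: first patch of **2** small residues, separator of
**2–3** bulky residues, second patch of **1–2** small residues, with a
flank residue **immediately adjacent** to the first and/or last patch
position ("one or both sides" is read as *at least one*,
`either_required`). Adjacency is taken literally because the defining
alignment shows contiguous flank positions. Expanding separator length
(2) × second-patch length (2) × flank placement (3) gives 12 concrete
variants, which `ccm_pattern_family()` enumerates explicitly.

Non-standard letters (B, Z, U, X) stay in sequences but belong to no
class, so they can never satisfy a motif position — conservative
matching.

### Scanning semantics

`scan_sequence()` scans N→C. At each candidate first-patch start, all
valid parses are computed and collapsed to a single reported match:
the **shortest separator** is preferred, then the **longer second
patch**; both flank positions are reported whenever present. The
collapse keeps downstream counting unambiguous (one match per cavity
pair); `all_parses = TRUE` exposes the alternatives. A residue is never
reused within one match — element spans are disjoint by construction.

Cohort screening (`screen_cohort()`) restricts scanning to the annotated
signal span widened by `margin = 2` residues, so a flank lying just
outside the annotated transmembrane segment still counts; matches must
lie entirely inside the widened window. Records without usable
boundaries are flagged skipped and counted separately, never treated as
motif-free. The single known extracellular-N-tail signal anchor raises
the question of orientation; the scanner always reads N→C and keeps
topology as metadata only.

The scanner is verified against an independent brute-force matcher
(PCRE lookahead regexes over all 12 variants, collapsed by the same
documented rule) — exhaustively for all sequences up to length 5 over a
reduced alphabet and on thousands of seeded random sequences up to
length 12. Exhausting length 10 (4^10 sequences) would cost minutes in R
for no additional structural coverage, so the longer lengths are sampled
under a fixed seed.

## Enrichment and property statistics

`fisher_exact()` computes the two-sided p-value by hypergeometric
enumeration with the *probability-mass rule* (sum over tables with
probability ≤ the observed table's), stated explicitly because two-sided
conventions differ. It is checked against a `choose()`-arithmetic
enumeration oracle for **every** 2×2 table with total ≤ 40, and against
`stats::fisher.test` on random tables. The reported odds ratio is the
sample odds ratio $ad/bc$ (infinite on an empty off-diagonal cell), not
the conditional MLE. For the motif screen's table — motif in 12 of 12
sensitive versus 5 of 143 non-sensitive signal anchors — the two-sided p
is $2.39 \times 10^{-14}$.

One caveat made explicit: on discrete tables an exact test is
*conservative*, so null p-values are stochastically **larger** than
uniform. The calibration test therefore checks one-sided closeness (the
empirical cdf of null p never exceeds the uniform cdf beyond one-sided
Kolmogorov–Smirnov fluctuation) rather than two-sided uniformity, which
discreteness would fail by construction.

GRAVY is the mean Kyte–Doolittle hydropathy of a sequence, with
unknown residues excluded from numerator and denominator. Frequency
profiles use half-open bins $[e, e+w)$ in steps of 4 and report percent
of cohort; the source description of the hydrophobicity axis ("0–100 …
in a scale of 0–25") is internally inconsistent, so the rescaling is an
explicit, configurable linear map defaulting to
$[-4.5, 4.5] \to [0, 100]$ (the full Kyte–Doolittle range onto the
plotting axis). Out-of-range values are counted in boundary bins and
flagged, never dropped silently. No curve fitting is attempted for
display profiles — the original figure's fitted curves are undefined.

## Helical cavity projection

The helix model is an ideal wheel: residue $i$ sits at azimuth
$(i-1) \cdot 100°\bmod 360$ (3.6 residues/turn). No 3D coordinates or
solvent-accessible surface are computed — the published surface
renderings are display, not measurement, and any numeric cavity
descriptor here is a package-defined convenience. Cavity membership is
copied verbatim from the match's patch positions; centroid azimuths use
the circular mean (angles near 0/360 wrap), and the angular separation
between centroids is reported in $[0°, 180°]$.

## Motif design

`propose_motif_insertion()` finds a minimum-cardinality substitution set
creating a motif match inside a window. The search is exact without
enumeration of subsets: every concrete variant is laid at every offset,
and the positions whose residues fail the required class are exactly the
mutations that placement needs — so the global minimum is the minimum
over placements. Replacement residues default to one representative per
class (G small, L bulky, K flank), a minimal-perturbation choice that
cannot change the minimal cardinality. Ties break by fewest mutations,
then leftmost match, then lexicographic substitution strings. Budgets
above 5 substitutions are refused rather than approximated. A structural
consequence worth noting: any motif instance needs at least three small
residues (2 + ≥1), so a sequence with none — e.g. poly-leucine — needs
at least three substitutions, plus a fourth if no flank residue exists
and flank creation is permitted; the exhaustive oracle in the test suite
confirms both minima. Verification mode (`verify_motif_insertion()`)
checks a user-supplied set such as the four-substitution
`F25G, F26G, G27L, Q33K` design pattern.

## Dose–response model

Flow-cytometry biosynthesis readouts are normalised as
$100\,(T - B - (C - B))/(D - B - (C - B))$ where $T, D, C, B$ are the
treated, DMSO, cycloheximide and untransfected-background signals —
cycloheximide subtraction removes protein already present when treatment
began. The curve model is the four-parameter logistic
$y = \text{bottom} + (\text{top} - \text{bottom})/(1 + (c/\text{IC}_{50})^h)$,
fitted by least squares with `nls` (port), parameterised in
$\log \text{IC}_{50}$ for stability. The top is fixed at 100 % (data are
DMSO-normalised) and the bottom is free in $[0, \text{top})$ because
cotransin usually does not inhibit completely; the Hill slope is free
with default start 1. Degenerate inputs (no decreasing trend, constant
response) return a flagged failure object instead of erroring. Simulated
assays use eight log-spaced concentrations over 1–50 µM, the assay's
stated range; recovery tests show exact recovery (≤ 1e-6) without noise,
< 15 % error at 10 % CV, and < 5 % bias over 500 simulations.

## The synthetic world

The generators state a world once and the tests live in it:

* **Cohort shape**: 217 proteins, 53 secretory (all SP) and 164
  membrane, the membrane split SAS:SP:unspecified = 105:56:3 — the
  screen's structure. Per-stratum sensitive fractions mirror the same
  screen (50/53, 11/105, 9/56, 1/3).
* **Effects and noise**: sensitive proteins draw a true DMSO/cotransin
  ratio uniformly from 2–10 (the screen reports only threshold
  exceedance, so the range is a package choice: clearly above 1.65 yet
  spanning weak to strong inhibition); resistant proteins have true
  ratio 1. Observed ratios are the truth times independent lognormal
  noise (CV 10 % default), the standard multiplicative error model for
  MS ratio data. Channel intensities consistent with the ratios are
  emitted so that median-normalisation invariance can be tested.
* **Signal anchors**: a hydrophobic core of 18–25 residues between
  polar/charged tails. Core residues are drawn from the bulky class
  *only*, so every small-residue cavity present is a planted one — this
  is what makes planted-motif recall a zero-false-negative test. It is
  also the generator's main departure from reality: genuine TM1 helices
  do contain small residues, so real screens face background matches
  that the synthetic cohort lacks. A green recall test therefore
  establishes scanner correctness, not real-data specificity.
  N-tail topology is drawn 10:1:1 cytoplasmic:extracellular:unspecified.
* **Signal peptides**: tripartite n (1–5, positively charged), h (7–15,
  bulky class), c (3–7, polar non-small, ending in an Ala-X-Ala
  cleavage context). By construction no adjacent small-residue pair can
  arise, so synthetic SPs are motif-free — matching the observation
  that the motif is a signal-anchor feature — and the SP screen doubles
  as a scanner-vs-oracle agreement check rather than a statistical
  false-positive-rate estimate.
* **The screen-table stand-in**: the real protein-level supplementary
  table exists only as a PDF, so `simulate_s1_table()` builds a
  *deterministic, synthetic* stand-in with the same strata and
  classification outcome (50/21/143 of 217), with ratio values spaced
  deterministically on the correct side of the criterion and one
  reciprocal-ratio (up-regulated) secretory protein. No random numbers:
  the count-reproduction test is exact and cannot be tuned by seeds.
* All generators are pure functions of (config, seed): repeated calls
  are byte-identical, and planted truth is always returned explicitly.

## Numerical choices

* Fisher p uses a $1 + 10^{-7}$ relative tolerance when comparing table
  probabilities, guarding probability-mass ties against floating-point
  noise (the same guard `fisher.test` uses).
* Coordinates are 1-based inclusive everywhere, matching protein
  numbering like F25G; files are converted at I/O boundaries only, and
  coordinate violations are errors — never clamped.
* Ratio tables are written with 17 significant digits so decimal text
  round-trips bit-for-bit.
* Report provenance carries the thresholds, scheme, version and input
  hashes; the timestamp is deliberately `NA` so reports are
  byte-reproducible.

## Limitations

* No probabilistic motif models (PWM/HMM) and no de novo motif
  discovery — the consensus is given, and discovery was manual in the
  original analysis.
* No live database retrieval; real signal-sequence boundaries are input
  data. Consequently the real-data screen counts (5 motif hits among
  143 resistant signal anchors) and the TNF-α T45/T46 cavity position
  are not reproduced here; the synthetic-cohort properties stand in for
  them.
* The helix module is a wheel projection, not structure prediction.
* The designer optimises motif presence only; it knows nothing about
  topology, stability or expression of the mutant.
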