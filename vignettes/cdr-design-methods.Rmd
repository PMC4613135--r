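---
title: "Non-combinatorial CDR design and library QC: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-combinatorial CDR design and library QC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrforge)
```

## The problem

Synthetic antibody libraries graft artificial CDR diversity onto a small
number of stable human frameworks. When that diversity comes from random
combinatorial synthesis, many clones carry sequences never seen in natural
antibodies, and liability motifs — N-glycosylation sequons, deamidation- and
isomerization-prone dipeptides, cleavage sites, oxidizable residues — slip
into the binding loops. `cdrforge` implements the opposite strategy: a
*pre-designed, non-combinatorial* repertoire in which every CDR sequence is
simulated from the statistics of natural antibody repertoires and screened
for liabilities before any DNA is synthesized. Diversity per region is
deliberately low (roughly 10^3 unique sequences); the library's size comes
from combining six independently designed CDRs.

## The germline-usage / hypermutation model

For CDR1 and CDR2 (heavy, kappa, lambda) the generative model has two
estimated ingredients:

* **Usage** `u(g)`: the frequency with which germline `g` is the closest
  ancestor of a natural CDR. Ancestry is operationalised as the
  minimal-Hamming-distance germline *of equal length* (`assign_germline()`);
  sequences with no equal-length germline are excluded from estimation but
  counted, since a length-changed CDR has no positionwise comparison.
  Ties are broken lexicographically by germline name, the convention that
  makes estimation and simulation deterministic.
* **Substitution spectrum** `s(g, p, a)`: conditioned on ancestor `g`, the
  frequency with which position `p` carries residue `a` different from the
  germline residue. Column sums of `s(g, p, ·)` are the positional mutation
  rates.

Simulation inverts estimation exactly: draw `g ~ u`, then independently per
position mutate with the positional rate and draw the replacement from the
normalised spectrum. Independence across positions is an explicit modelling
assumption; it reproduces the positional mutation frequencies (the quantity
that is estimated) but not positional covariation, which the profiler does
not measure. A consequence worth knowing: the expected mutation load of a
simulated repertoire equals the usage-weighted sum of positional rates
(`expected_mutations()`), which is what makes "designed ≈ natural" mutation
statistics hold by construction — the test suite verifies this on synthetic
profiles.

Whether spectra should be conditioned per germline or pooled across
germlines is ambiguous; this package conditions per germline (the more
faithful inversion of the estimator) and exposes `pooled = TRUE` in
`build_shm_profile()` for the coarser variant.

## CDR-H3 and light-chain CDR3

V(D)J junctional diversity makes germline assignment for heavy CDR3
impractical, so CDR-H3 is modelled positionally per length over a 9–20
residue range: independent per-position amino-acid frequencies for the
first `L − 3` positions, and the last three residues — Kabat 100–102, the
J-segment-derived tail with its Phe/Met–Asp–Tyr/Val/Leu/Ile consensus —
drawn as intact three-residue units from their pooled natural frequencies.
Pooling the terminal units across lengths (rather than stratifying by
length) is a deliberate simplification: the tail is encoded by the J
segment regardless of loop length.

Light-chain CDR3 is a hybrid: the first six-to-eight residues are simulated
with the germline model above, and the last two or three residues
(approximately the N-terminal part of the J segment) per position from
their natural frequencies. The head/tail split is two residues for CDRs of
length ≤ 9 and three otherwise (`l3_split_rule()`, configurable): the
biology fixes the range of the tail but not an exact rule, so the package
pins a monotone default and lets callers override it.

## PTM policy

The rejection filter (`ptm_policy()`) bans:

| motif | chemistry | span |
|---|---|---|
| N-X-S/T, X ≠ P | N-glycosylation | 3 |
| DG | aspartate isomerization | 2 |
| NG | asparagine deamidation | 2 |
| DP | acid-labile backbone cleavage | 2 |
| C, M | side-chain oxidation | 1 |

Two methionines are exempt because they are common or predominant in
natural antibodies: Kabat H34 (the fourth residue of the five-residue
CDR-H1) and Kabat H100 (the first residue of the CDR-H3 terminal unit,
i.e. third from the end). The mapping of Kabat positions to local
coordinates is fixed by those two anchors.

Scanning appends `junction_flank = 2` framework residues on each side of
the CDR before matching, so motifs straddling the CDR–framework junction
are rejected too; hits entirely inside the flank are ignored (the framework
is fixed and not up for rejection). Two residues cover every banned
dipeptide and every frame of the three-residue sequon that can overlap the
junction; the window width is configurable.

Germline CDRs themselves often carry DG/NG (heavy CDR2 especially);
`sanitize_germline()` substitutes them with SG — repeatedly, left to right,
until none remain — *before* simulation. Profiles are estimated against the
unsanitized germlines (the spectra describe nature), and the designer
sanitizes only the germline sequences it simulates from; this is the reason
`design_repertoire()` takes `sanitize = TRUE` rather than expecting
pre-cleaned inputs.

Rejection is by *resampling to the target count*, not by filtering a fixed
draw: per-region totals (CDR-H3 7,836 = 2 × 3,918-oligo pools; K2/L2 1,000;
others 1,500 — `design_config()`) are exact, and unique counts are
emergent. A region whose profile cannot produce clean sequences (e.g. an
invariant Cys) fails loudly after a configurable attempt budget rather than
looping forever.

## Oligo pools and scFv assembly

Designed repertoires are split in draw order into pools of at most 3,918
sequences — the per-pool capacity of the array-synthesis platform the
design targets — so CDR-H3 fills exactly two pools and the remaining
11,000 CDRs three more. Each oligo is the reverse-translated CDR flanked by
18 nt of its upstream and downstream framework (the overlap-extension PCR
handles). Reverse translation uses one fixed preferred codon per residue
(`preferred_codons()`, E. coli-biased): deterministic and trivially
round-trip-safe; codon optimisation is out of scope. `assemble_scfv()`
interleaves FRs and CDRs (heavy — (G₄S)₃ linker — light).

## Read annotation

Merged reads are translated in all three frames; the terminal five-residue
windows of the framework regions (end of FR1; both ends of FR2 and FR3;
start of FR4) are searched left-to-right with at most one amino-acid
mismatch per window (configurable), so point errors from synthesis or PCR
do not lose the read. Indels shift the frame mid-read, so each anchor may
be found in a different frame; the greedy search enforces ordering (an
anchor must start after the previous anchor ends), prefers exact matches
over mismatched ones, and — because kappa and lambda frameworks are nearly
identical — assigns each read to the scaffold with the most anchors and,
on ties, the fewest total anchor mismatches.

The segment between the end-anchor of FR*k* and the start-anchor of
FR*k*+1 is the CDR. It is **in frame** when its nucleotide span is a
multiple of three and translates without a stop codon; it has the
**designed length** when its translated length occurs in the designed
repertoire; it is a **designed sequence** when the translation is a
designed sequence — a strict implication chain that the test suite asserts
as an invariant. A read with fewer than two anchors on every scaffold is
reported with chain `unknown` and all flags false, not as an error. A
**functional domain** has all three CDRs in frame and no stop codon; the
scFv functional fraction is estimated both read-level (from domain
annotations) and by the product of per-region in-frame fractions, because
those two routes need not agree exactly and published reports are ambiguous
about which was used. Framework mutation rates are counted over compared
framework residues: full FR2/FR3 when both their anchors land consistently,
plus the FR1/FR4 terminal windows.

Coordinates are 1-based inclusive throughout, the R/Bioconductor
convention.

## The synthetic-data generator

Everything the pipeline consumes can be generated with known parameters:

* `demo_germline_set()` — hand-written per-region germline sets (3–4
  entries, realistic lengths: H1 = 5, K2/L2 = 7, H2 = 16–17, ...). The
  sequences are plausible human-like *synthetic* fixtures, not database
  entries; several deliberately contain DG/NG (heavy CDR2) or an H34 Met so
  the sanitizer and exemptions are exercised.
* `demo_scaffolds()` — human-framework-like FR protein sequences with
  typical lengths (heavy 25/14/32/11), reverse-translated with the
  preferred-codon table. They are synthetic stand-ins for the real heavy
  and light frameworks a production library would use, which are not
  distributed with the package.
* `demo_repertoire_spec()` — fixed truth parameters: geometric germline
  usage, deterministic positional substitution rates between 3% and 10%
  (mass split 0.6/0.3/0.1 over three target residues), an antibody-like
  CDR-H3 positional truth with mode length 12–13 and a J-like terminal-unit
  table, and concentrated light-CDR3 tail frequencies ending mostly in Thr.
  Default repertoire sizes are 8,846 heavy, 3,110 kappa and 2,440 lambda
  sequences per region — the natural-repertoire scale the design analysis
  is calibrated for.
* `generate_library_reads()` — per-clone domain reads (one heavy, one
  light) with independent per-nucleotide substitution (0.002), deletion
  (0.002) and insertion (0.001) defaults chosen to emulate array-synthesis
  plus PCR error at the rates that reproduce realistic pre-proofreading
  in-frame fractions; a per-read premature-stop injection (0.01); and a
  `proofread` flag that keeps only reads whose segments all conserve length
  modulo 3 and whose translation is stop-free — the *selective outcome* of
  panning single-CDR libraries against an anti-tag antibody, not a model of
  the panning itself. Because longer CDRs accumulate more indels, their
  preferential dropout under proofreading emerges without being coded.
  `cdr_only = TRUE` restricts errors to CDR segments; it exists for
  calibration experiments where the analytical expectation must be exact.

What passing tests on these fixtures shows — and does not show. The closed
loops (generator → profiler recovers the truth within three binomial
standard errors at n = 10,000; generator → annotator recovers 100% of
error-free reads and tracks injected deletion rates) validate the
estimators and the annotator against the stated models. They do not
validate the models against real repertoires: real SHM is not
position-independent, real NGS errors are not uniform, and real germline
sets are larger and more redundant than the fixtures.

## Numerical and operational choices

* Frequencies are plain maximum-likelihood proportions; no pseudocounts.
  Profile columns therefore sum to 1 up to floating error (asserted at
  1e-9), and a residue never observed at a position has simulation
  probability exactly 0.
* All stochastic operations accept integer seeds and are reproducible
  bit-for-bit (`withr::with_seed`); batching inside the rejection sampler
  only consumes RNG in draw order, so the accepted prefix is
  seed-determined.
* The designer's attempt budget defaults to `max(10 × target, 10,000)`
  candidate draws before declaring an infeasible policy, and a hard stop at
  ~1,000 × target guards against pathologically low acceptance.
* Degenerate inputs fail early with named errors: empty repertoires, stop
  codons in protein inputs, FR lengths not divisible by three, missing
  codon-table residues, tail tables missing a germline length.
* Fidelity *r²* is the squared Pearson correlation of designed vs observed
  relative frequencies on the linear scale, computed only over designed
  sequences observed in the data, and reported as `NA` below three shared
  sequences or when either margin is constant (CDR-H3 repertoires, where
  nearly every designed sequence is unique, routinely hit this).
* Suite and acceptance problem sizes (design targets of a few hundred for
  unit tests, read depths of 400–5,000, full 7,836-sequence CDR-H3 design
  in the acceptance path) were chosen so the whole fixture pipeline runs in
  minutes on a single core while keeping binomial standard errors tight
  enough for three-sigma checks.

## Known limitations

* Amino-acid-level SHM only: no nucleotide hotspot motifs, no transition
  bias, no VDJ junction reconstruction.
* The annotator assumes domain-level reads covering FR1 through FR4; it
  does not merge read pairs (use FLASH or similar upstream), trim
  qualities, or detect chimeras.
* PTM exemptions are positional, not structural; a Met at H34 is tolerated
  wholesale rather than assessed for solvent exposure.
* The natural-antibody PTM-free fraction computed by naive independence
  from per-region burdens over-estimates published natural-source values;
  the estimator is provided for the library case it was derived for, and
  the natural case is reported without being asserted.
* Proofreading is modelled only as its selective outcome; display-level
  biases (expression, folding, anti-tag epitope accessibility) are out of
  scope.
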