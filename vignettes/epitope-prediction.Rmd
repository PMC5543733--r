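---
title: "Classical linear B-cell epitope prediction with epitopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classical linear B-cell epitope prediction with epitopr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epitopr)
```

## The problem

Anti-peptide antibodies are raised against a short synthetic segment of a
protein, so everything depends on choosing a segment that behaves like an
epitope: exposed on the surface, hydrophilic, conformationally flexible,
and free of rigid helix or sheet structure. A motivating use case is the
gamma-type phospholipase A2 inhibitor (PLIγ) of snake serum — a natural
antivenom candidate for which antibody reagents have to be made from a
predicted peptide, and for which the chosen peptide should additionally be
conserved across snake species (so one antibody detects many homologs) and
avoid the protein's active segment (so the antibody does not neutralize the
function it is meant to report on).

epitopr implements the classical propensity-scale toolkit for this
decision as a deterministic, fully parameterized pipeline: five
per-residue predictor tracks, a composite antigenic index, explicit
segment selection rules with reportable rejection reasons, and
alignment-based conservation scoring. Every number the pipeline consumes —
scale tables, windows, bins, weights, thresholds — lives in plain-text
configuration shipped with the package and echoed into every run manifest.

## Predictor tracks

**Hydrophilicity.** The Hopp–Woods scale averaged over a sliding window of
7 residues (the window length the scale's authors recommended for epitope
work). The window value is anchored at the central residue; the first and
last three positions have no full window and are masked by default. A
`shrink` edge policy (average over the in-bounds part) exists for
full-length display. Kyte–Doolittle hydropathy is selectable instead;
it is negated on load so that *high always means hydrophilic* regardless
of the active scale.

**Surface probability.** The Emini construction: for each hexapeptide
window the product of the six fractional surface probabilities divided by
the random expectation,

$$S_i \;=\; \prod_{k=0}^{5} \frac{f(r_{i+k})}{0.37},$$

so \(S > 1\) means above-random expected surface exposure. A 6-residue
window has no central residue; the value is anchored to the window's first
residue by default, with a center-left alternative in the configuration —
the convention used by the legacy desktop implementations is undocumented,
so it is explicit here rather than silent.

**Flexibility.** Karplus–Schulz normalized B-factor indices averaged over
a 7-residue window with center-peaked weights
\((0.25, 0.4375, 0.625, 1, 0.625, 0.4375, 0.25)\), renormalized to sum 1.
With equal weights this reduces exactly to the plain windowed mean, which
is one of the test suite's checks.

**Chou–Fasman secondary structure.** The published nucleation–extension
rules: a helix nucleates where at least 4 of 6 consecutive residues have
\(P_\alpha\) above the former cutoff (1.03) and extends while the running
tetrapeptide mean stays at or above 1.00; strands nucleate at 3 of 5 above
1.05 and extend the same way. A beta-turn is called at position *i* when
the bend probability \(f_1(i)f_2(i{+}1)f_3(i{+}2)f_4(i{+}3)\) exceeds
\(7.5\times10^{-5}\) and the tetrapeptide's mean turn propensity exceeds
1.00 as well as its mean helix and strand propensities; the four positions
become T, overriding helix/strand. Helix–strand overlaps are resolved per
overlapping run by the larger regional mean propensity. Everything else is
coil. All cutoffs are configuration, not code.

**GOR-style structure.** The directional-information predictor: each
state's score at a position is the sum of information contributed by the
neighboring residues at offsets −8..+8, minus a per-state decision
constant (default 0); the argmax wins. The *algorithm* is implemented
exactly and verified against a brute-force double loop. The packaged
parameter table, however, is a constructed stand-in (clearly labelled
`gor_info_synthetic.tsv`): the original published information tables were
not available for transcription, so the table is derived from the
Chou–Fasman propensities with a triangular distance-decay kernel, the
coil row balancing the other three. Any table in the same four-column
format can be substituted through the `table` argument.

**Consensus.** Where the two structure methods disagree, the consensus
takes the *softer* state in the fixed order T > C > E > H. The selection
stage only penalizes rigid fractions, so this bias means a residue is only
counted rigid when both methods call it rigid, and ties resolve
reproducibly. The same order is the argmax tie-break inside the GOR-style
predictor.

## The composite antigenic index

Each component is first discretized onto the bounded score set
\(\{-0.6, -0.3, -0.1, 0, 0.1, 0.3, 0.6\}\) by per-component thresholds
(structure tracks map states directly: T = 0.6, C = 0.3, E = −0.3,
H = −0.6), then combined as a convex combination

$$AI_i \;=\; 0.30\,H_i + 0.15\,S_i + 0.15\,F_i + 0.20\,CF_i + 0.20\,GR_i ,$$

the classical weighting (hydrophilicity heaviest). Because the weights are
nonnegative and sum to 1, the index is bounded by the extreme score levels
and monotone in every component — both tested properties. A position is
masked wherever any component is masked, so the defined range of the index
is the intersection of the component ranges.

The exact bins used by the historical desktop implementation are
unpublished; the package's bins are declared defaults in the
configuration, and no claim of numeric identity with that program's output
is made.

## Segment selection

Candidates are maximal runs of positions with \(AI \ge\) `ai_threshold`
and hydrophilicity \(\ge\) `hydrophilicity_min`; runs separated by at most
`gap_merge` positions are merged. Each candidate is then tested in a
fixed, reportable order — forbidden-region overlap, minimum length (8
residues), rigid-structure fraction, mean surface probability, mean
hydrophilicity, mean flexibility — and the first failure names the single
`rejection_reason`; the full per-criterion flag vector is kept alongside.
The three characteristic failure narratives (too short to be an effective
epitope; hydrophilic but buried; rigid alpha-helix) map onto the
enumerated reasons `too_short`, `low_surface`, `rigid_structure`.

Passed candidates are ranked by a weighted sum of z-scored criterion
means (equal weights by default), with exact ties broken toward the longer
candidate and then the smaller start. Forbidden active-site regions (for
PLIγ, the active decapeptide at positions 87–96 is the motivating example)
are off by default and enabled through configuration: avoiding the active
segment is a design consideration, not an always-on algorithmic step.

Finally, each candidate is annotated for carrier-conjugation readiness:
maleimide coupling to KLH/BSA needs a free thiol, so a peptide already
starting or ending in cysteine is flagged conjugation-ready. The
annotation never changes pass/fail.

### Where the numeric defaults come from

The published selection criteria are qualitative ("good hydrophilicity,
high accessibility, high flexibility, strong antigenicity"). The package
therefore fixes numeric defaults by calibration against its own synthetic
benchmark (below): with `ai_threshold = 0.15`, `hydrophilicity_min =
0.25`, `surface_min = 1.0` (the random-expectation line of the Emini
ratio), `flexibility_min = 1.0` (the average-flexibility line),
`max_rigid_fraction = 0.3` and `gap_merge = 2`, the rank-1 candidate
overlaps a planted epitope-like segment at Jaccard ≥ 0.5 in at least 90%
of 200 seeded replicates — the recovery property the test suite asserts.
The calibration was a coarse grid over these thresholds under the fixed
generator conditions; the residual misses are replicates whose uniform
background happens to contain a charged run that is genuinely
epitope-like by every track, which no threshold setting distinguishes
from the plant.

## Conservation analysis

Given a pre-aligned multi-FASTA, per-column identity is the count of the
modal non-gap residue over a denominator set by the gap policy: non-gap
residues (`exclude`, default, recorded in the report) or all rows
(`count-as-mismatch`). Modal ties break alphabetically so reports are
deterministic. Columns below the variable-identity threshold (default
1.0, i.e. any substitution) are listed as variable, and with declared
sequence groups (venomous vs non-venomous species being the motivating
contrast) each column gets per-group modal residues; a column whose group
modals differ is *discordant* — the signature of a group-diagnostic
substitution. Epitope coordinates stated on the ungapped protein are
projected onto alignment columns through the record's gaps, and back.

The package deliberately does not align: multiple alignment is glue best
left to dedicated tools, and the statistics consume their output. A
single-pair global aligner (match 1, mismatch −1, gap −2, configurable;
backed by the Biostrings dynamic-programming implementation) is bundled
only for projecting an epitope onto one unaligned homolog.

## The synthetic benchmark

`generate_protein()` draws background residues i.i.d. (uniform over the
20 residues by default, so tests do not silently depend on an external
composition table; a Swiss-Prot-like table is available), then overwrites
planted segments: epitope-like segments from the hydrophilic/turn-forming
vocabulary {R,K,D,E,N,Q,S,T,G,P}, buried-helix segments from the
hydrophobic/helix-forming vocabulary {A,L,I,V,F,M,W}. Defaults — length
200 with one epitope-like 20-mer and one buried-helix 15-mer at random
non-overlapping positions — emulate the size of a PLIγ-family mature
protein with one genuine epitope and one buried decoy.
`generate_alignment()` mutates copies of a root sequence i.i.d. per
column and plants fixed, distinct per-group residues at declared
discordant columns; its mean pairwise identity has the closed form
\((1-r)^2 + (1-(1-r)^2)/20\) per column, which the acceptance checks
compare against simulation. Both generators are pure functions of
(specification, seed).

What the benchmark does *not* emulate: real residue autocorrelation,
family-specific composition, actual PLIγ phylogeny, gaps arising from
indel evolution, or glycosylation. Passing the recovery property
therefore shows that the pipeline's tracks and rules separate the
constructions they were designed to separate — it is a correctness and
calibration harness, not evidence about sensitivity on natural proteins.
The one published worked example (six candidate segments on the
*S. annularis* PLIγ, winner 151–172) cannot be regression-tested because
the full protein sequence is not public; the pipeline's rejection
vocabulary and the conserved-epitope analysis mirror that narrative
structurally instead.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere (a 151–172 span is 22
  residues); any BED export would convert at the boundary only.
* Ambiguous residues (B, Z, X, U) are rejected at parse time rather than
  imputed — every scale lookup needs a canonical residue, and failing
  early beats silently guessing.
* Masked positions propagate: the index is undefined wherever any
  component is, and segment extraction only runs over defined positions.
* An empty candidate table is a valid result; file outputs are still
  written and the run exits cleanly.
* All tie-breaks (argmax states, consensus softening, modal residues,
  ranking) are fixed and documented, so identical inputs and
  configuration yield byte-identical reports; the manifest (configuration
  echo + parameter-file checksums + seed) is sufficient to reproduce any
  run.
* Test problem sizes: oracle comparisons run sequences up to 500 residues
  and alignments up to 20 × 300 columns; the end-to-end recovery property
  uses 200 replicates of the default generator. These sizes exercise every
  code path while keeping the default test run fast.

## Known limitations

The propensity methods here are the classical 1970s–80s toolkit: they are
transparent and reproducible, but modern machine-learned predictors are
more accurate on benchmark data and deliberately out of scope. Output
cannot be expected to match the proprietary desktop implementation
curve-for-curve (undocumented variants, bins and constants; and this
package's GOR-style parameter table is an explicitly synthetic stand-in).
Conformational (discontinuous) epitopes, MHC binding, solvent
accessibility from 3D structure, PCR simulation and primer design are all
out of scope; degenerate-primer support is expansion and exact matching
only.
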