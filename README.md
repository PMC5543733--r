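# epitopr

Linear B-cell epitope prediction with the classical propensity-scale
toolkit, plus epitope conservation analysis across homologous sequences.

Anti-peptide antibodies are raised against a short synthetic segment of a
target protein, and the segment has to be chosen well: surface-exposed,
hydrophilic, flexible, not locked into rigid helix or sheet, long enough
to be antigenic, conserved across the homologs you want to detect, and
clear of the protein's active site. The motivating application is the
gamma-type phospholipase A2 inhibitor (PLIγ) of snake serum, where a
single well-chosen peptide yields monoclonal antibodies that detect PLIγ
across many snake species — but the pipeline applies to any protein for
which these classical criteria are the decision basis.

## What it computes

Five per-residue predictor tracks over a protein sequence:

* **Hydrophilicity** — Hopp–Woods scale, 7-residue sliding-window mean
  (Kyte–Doolittle selectable, sign-inverted so high = hydrophilic);
* **Surface probability** — Emini hexapeptide ratio
  S = Π f(rᵢ)/0.37 over each 6-mer window (S > 1 ⇒ above-random exposure);
* **Flexibility** — Karplus–Schulz indices, center-weighted 7-window;
* **Secondary structure** — Chou–Fasman nucleation/extension and a
  GOR-style directional-information predictor (offsets −8..+8, argmax),
  plus their epitope-permissive consensus (T > C > E > H on disagreement);

and combines them into a **composite antigenic index**: each component is
discretized onto the bounded levels {−0.6 … 0.6} and summed with weights
0.30 (hydrophilicity), 0.15 (surface), 0.15 (flexibility), 0.20 + 0.20
(the two structure tracks). Maximal high-index hydrophilic runs become
candidates; each is tested in a fixed order (forbidden region → length ≥ 8
→ rigid fraction → surface → hydrophilicity → flexibility) with the first
failure recorded as its rejection reason; survivors are ranked by z-scored
criterion means and annotated for terminal-cysteine conjugation readiness.

Around the core: FASTA I/O, per-column alignment conservation with
group contrasts (e.g. venomous vs non-venomous species) and
ungapped-to-column coordinate mapping, IUPAC degenerate-primer expansion
and matching, and a seeded synthetic-data generator (planted epitope-like
and buried-helix segments; alignments with planted group-diagnostic
columns) so the whole pipeline is testable without external data.

## Worked example

```r
library(epitopr)
library(dplyr)

# a synthetic 200-residue protein with one planted epitope-like 20-mer
# and one planted buried-helix 15-mer
sim <- generate_protein(synth_spec(), seed = 42)
sim$truth
#> # A tibble: 2 × 4
#>   kind         start   end length
#> 1 epitope-like   152   171     20
#> 2 buried-helix    81    95     15

scan <- predict_epitopes(sim$seq)
scan
#> <epitope_scan> 1 sequence(s), 9 candidate(s), 1 passed
#> rank 1: 151-169 SKGKKPGQNPRRNDPRNDQ

tidy(scan) |> filter(passed) |>
  select(start, end, length, mean_ai, mean_surface, rigid_fraction, rank, cys_note)
#>   start   end length mean_ai mean_surface rigid_fraction  rank cys_note
#> 1   151   169     19   0.486         91.4              0     1 requires added terminal Cys
```

The rank-1 candidate (positions 151–169) recovers the planted epitope
(152–171): mean antigenic index 0.486 on the [−0.6, 0.6] scale, mean
surface ratio 91 (far above the random-expectation value 1), no rigid
consensus structure, and a note that this peptide would need a terminal
cysteine added before maleimide carrier coupling. The eight other
extracted runs were all rejected as `too_short` (under eight residues).
`autoplot(scan)` draws the stacked track panels; `track_table(scan)`
exports them.

Conservation of an epitope window across homologs, with a group contrast:

```r
x <- generate_alignment(n_seqs = 9, ncols = 80, mutation_rate = 0.02,
                        discordant_columns = c(25, 34), seed = 7)
rep <- region_conservation(x$aln, c(21, 42), groups = x$groups)
rep
#> <conservation_report> columns 21-42 (gap policy: exclude)
#> mean identity 0.9495; 4 variable column(s)
rep$variable_positions
#>   column modal_residue identity modal_A modal_B discordant
#> 1     25 Q                0.556 Q       M       TRUE
#> 2     34 Y                0.556 Y       I       TRUE
#> 3     36 K                0.889 K       K       FALSE
#> 4     38 N                0.889 N       N       FALSE
```

The two planted group-diagnostic columns (25 and 34) come back discordant
— each group fixed on its own residue — while the other two variable
columns are ordinary mutational noise shared by both groups.

Degenerate primers expand to their concrete set:

```r
expand_primer("CRCTCATGTAMWTTTGTCACAA")   # R=A/G, M=A/C, W=A/T
#> 8 concrete primers, "CACTCATGTAAATTTGTCACAA" ... "CGCTCATGTACTTTTGTCACAA"
```

A thin command-line wrapper with `predict`, `conserve`, `simulate` and
`expand-primer` subcommands is installed at `inst/scripts/epitopr`.

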