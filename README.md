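# stitchmap

Super-scaffolding of draft genome assemblies with optical genome maps.

Draft assemblies break at repeats and low-complexity regions longer than
their reads. Optical maps — ordered nicking-enzyme label positions along
single DNA molecules hundreds of kb long — span those breaks. `stitchmap`
implements the full toolchain around a consensus-map assembler:

* **Formats** — bit-faithful readers/writers for BNX (single-molecule
  maps), CMAP (consensus and in silico maps), XMAP (map alignments),
  plus FASTA and AGP 2.0 output.
* **In silico digestion** — `digest_fasta()` converts scaffolds to label
  maps by motif search (defaults: nt.BspQI `GCTCTTC` + nt.BbvCI
  `CCTCAGC`; inclusion rules: longer than 20 kb, more than 5 labels) and
  `label_density()` reports labels per 100 kb against the ideal 10–15
  band.
* **Molecule preparation** — `prep_molecules()` splits BNX files by
  scan, estimates each scan's stretch (bases per pixel, nominal 500)
  from alignments to the in silico maps as the length-weighted span
  ratio, rescales, QCs and merges.
* **Assembly sweep** — `compute_thresholds()` derives the assembler's
  p-value threshold triple from the estimated genome length
  (`default = 1e-6 / Mb`, `strict = default/10`, `relaxed = default*10`;
  200 Mb → 5e-09, 5e-10, 5e-08), `plan_sweep()` stages the 3 + 2 run
  plan over thresholds and minimum molecule lengths (150 kb default,
  100/180 kb variants), and `rank_assemblies()` scores candidates by
  genome-length similarity and alignment redundancy.
* **Stitching** — `stitch_once()` inverts consensus-vs-in-silico
  alignments, filters them by confidence and percent-aligned (PAT; dual
  filter sets 13/30 and 8/90 by default, an alignment passes either),
  keeps one alignment per in silico map (longest span, then highest
  confidence, then a deterministic tie-break), infers signed gaps from
  projected spans, and emits FASTA + AGP: positive gaps as `N` runs of
  the estimated length, negative gaps as fixed 100 bp `U` spacers.
  Partial alignments (PAT < 60 %) and extreme negative gaps (< −20 kb)
  are flagged for curation.
* **Iteration** — `run_iterations()` repeats digest → align → stitch
  until no new joins appear, flattening nested super scaffolds so the
  final AGP references only original scaffolds.
* **Simulation** — `make_genome()`, `fragment_genome()`,
  `simulate_consensus_maps()`, `simulate_molecules()`, `truth_xmap()`
  and the naive stand-in aligner `naive_overlap_align()` generate fully
  ground-truthed data so every stage runs without proprietary tools.

A thin CLI over these functions lives at `inst/scripts/stitchmap.R`
(subcommands `digest`, `prep`, `bnx-stats`, `cmap-stats`, `xmap-stats`,
`sweep-plan`, `stitch`, `simulate`).

## Worked example

Simulate a fragmented genome, stitch it back together with the naive
aligner, and check the result against the simulator's ground truth:

```r
library(stitchmap)

g   <- make_genome(2e6, gc = 0.5, seed = 1)
fr  <- fragment_genome(g, 16, seed = 2)          # shuffled, re-oriented
dig <- digest_fasta(fr$scaffolds)
cm  <- simulate_consensus_maps(g, fr$layout, n_maps = 2, seed = 3)

cfg <- stitch_config(filter_sets = list(c(8, 30), c(4, 90)))  # proxy scale
out <- run_iterations(fr$scaffolds, cm$maps, naive_aligner(),
                      stitch_cfg = cfg, max_iter = 5)
out$report
adjacency_recovery(out$agp, fr$layout)
compute_thresholds(sweep_config(200))
```

This prints:

```
  iteration n_new_joins n_records     n50
1         1          14         2 1122116
2         2           1         1 2000000
3         3           0         1 2000000
recovered 15 of 15 true adjacencies (100%)
<threshold_triple relaxed=5e-08 default=5e-09 strict=5e-10>
```

Iteration 1 joins the 14 adjacencies interior to the two consensus maps
(16 scaffolds → 2 super scaffolds); the scaffold straddling both maps can
serve only one of them per pass, so the final join appears at iteration 2;
iteration 3 finds nothing new and the loop stops at its fixpoint. All 15
true adjacencies are recovered with correct orientations, and N50 grows
from the scaffold scale to the genome length. The threshold triple is the
assembler parameter set the sweep module would emit for a 200 Mb genome.
The filter sets here are on the simulator's matched-label-count confidence
scale; with a real aligner's −log10 p-values you would keep the defaults
(13/30 and 8/90).

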