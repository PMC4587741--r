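---
title: "Super-scaffolding draft genomes with optical maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Super-scaffolding draft genomes with optical maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stitchmap)
```

## The problem

Draft genome assemblies are fragmented at repeats, polymorphic regions and
low-complexity sequence that exceed the span of the underlying reads.
Optical genome maps — ordered lists of nicking-enzyme label positions along
single DNA molecules hundreds of kilobases long — span many such breaks.
`stitchmap` implements the analysis chain that turns a draft FASTA plus a
set of consensus genome maps into super scaffolds: ordered, oriented
concatenations of sequence scaffolds with estimated gap lengths, serialized
as FASTA plus AGP 2.0, with potential mis-assemblies flagged rather than
silently resolved.

The chain has four stages, each usable on its own:

1. **In silico digestion** (`digest_fasta()`): scaffolds become label maps
   by motif search, so sequence and maps live in one coordinate currency.
2. **Molecule preparation** (`prep_molecules()`): per-scan stretch (bases
   per pixel) is estimated from alignments to the in silico maps and
   rescaled to the nominal 500 bpp.
3. **Assembly sweep planning** (`compute_thresholds()`, `plan_sweep()`,
   `rank_assemblies()`): p-value thresholds and minimum-length variants
   for the external consensus-map assembler, and scoring of the candidate
   assemblies it returns.
4. **Stitching** (`stitch_once()`, `run_iterations()`): consensus-map
   alignments select, order and orient scaffolds; gaps are inferred; the
   loop repeats until no new joins appear.

The external map assembler and aligner are proprietary and are consumed
through their XMAP output only; a naive stand-in aligner
(`naive_overlap_align()`) makes the whole chain testable at desk scale.

## Data model and coordinate conventions

BNX (one block per imaged molecule), CMAP (consensus or in silico maps)
and XMAP (pairwise map alignments) are parsed bit-faithfully. Positions
stay in the native 1-based floating bp; the writers print one decimal, as
the formats do in the wild. Two normalizations happen at the parser
boundary and are undone on write:

* negative-strand XMAP records store `QryStartPos > QryEndPos` on disk; in
  memory every span is ascending with the strand kept in `orientation`,
  so interval logic has a single code path;
* the channel-0 CMAP end-marker row is stripped on read and re-appended on
  write (its absence is tolerated with a warning, since truncated files
  occur).

Interval-union arithmetic (alignment breadth) treats spans as half-open so
that spans sharing an endpoint merge without double counting. AGP output
is 1-based inclusive, as the format requires, and is validated to tile
each object contiguously; `agp_to_fasta()` is the reconstruction oracle
used by the tests to prove FASTA/AGP consistency byte for byte.

## Digestion

`find_label_sites()` reports each motif occurrence on either strand as the
1-based coordinate of the leftmost matched base. The nick offset within
the recognition site is not modelled: label-interval geometry is invariant
under a constant shift, and published pipelines do not state the offset
convention. A motif equal to its own reverse complement is counted once
per occurrence. Scaffolds qualify for a map when strictly longer than
20 kb with strictly more than 5 labels (both rules are deliberately strict
inequalities); everything else lands in the `excluded` table with the rule
it failed, so the partition of inputs is total and auditable. The default
motifs are the two nicking enzymes used for genomes whose single-enzyme
label density falls below the ideal band of 10–15 labels per 100 kb
(`label_density()` reports the band as a closed interval).

## Molecule stretch

Imaging nominally yields 500 bases per pixel, but true stretch drifts
scan to scan. The estimator is deliberately the ratio of summed aligned
spans, `sum(ref) / sum(qry)` — a length-weighted mean — rather than a
per-molecule average: short noisy alignments then contribute
proportionally to their evidence. Published descriptions say only
"empirical average"; the length-weighted form is the package's choice.
Rescaling multiplies positions and length by the estimated scale, after
which re-estimation on consistently rescaled alignments returns scale 1
to within 1e-9 (a fixpoint property the tests assert). Scans without
alignments are flagged and passed through unscaled. The QC band defaults
to 475–525 bpp (±5 %), a configurable choice; published QC plots show no
numeric band.

## Threshold arithmetic and the sweep

The assembler's default p-value threshold scales inversely with genome
size: `default = numerator / genome length (Mb)`, with
`strict = default / 10` and `relaxed = default * 10`. The printed formula
in the source literature (numerator 1e-5) contradicts its own worked
triple for a ~200 Mb genome (5e-08, 5e-09, 5e-10, which requires 1e-6);
the worked values are treated as authoritative, so the package defaults
the numerator to 1e-6 per Mb and exposes it in `sweep_config()`. The
first round plans three assemblies (relaxed/default/strict threshold) at
the 150 kb default minimum molecule length; if none satisfies, a second
round runs the best threshold at 100 kb and 180 kb, for at most nine
distinct configurations. Candidate assemblies are scored on closeness of
cumulative length to the estimated genome size and on alignment
redundancy (total aligned minus non-redundant breadth against a common in
silico map set). The two criteria have no published precedence, so
`rank_assemblies()` offers both lexicographic orders and always returns
the full table — selection is assistive, not automatic.

## Stitching

Alignments arrive with the in silico maps as reference and are inverted
(`invert_xmap()`) so the consensus map becomes the ordering coordinate
system. Filtering then uses two alignment-quality axes:

* **confidence**, the external aligner's −log10 false-positive p-value,
  consumed as-is (the simulator's matched-label-count proxy is explicitly
  not on this scale);
* **PAT**, the percent of the *total possible* alignment length that is
  aligned. The total possible length extends the aligned reference span
  by the smaller of the two maps' unaligned overhangs on each side (query
  overhangs taken in alignment orientation). End overlaps and containments
  score 100; interior local hits score low. PAT is computed on the
  consensus-map span; the source tool does not state whether it uses the
  reference span, query span or a mix, so this is a documented choice.

An alignment passes if it satisfies *either* of two filter sets (default
confidence ≥ 13 with PAT ≥ 30, or confidence ≥ 8 with PAT ≥ 90 — the
second catches long overlaps in label-poor regions); all boundaries are
inclusive. Consensus maps attracting fewer than two distinct in silico
maps are dropped from consideration, then each in silico map keeps one
alignment: longest consensus-map span, ties to highest confidence, then
smallest consensus map id and entry id — a deterministic stand-in for the
published "chosen arbitrarily".

Components are ordered by their projected spans: the aligned span
extended by the scaffold's unaligned overhangs, i.e. where the whole
scaffold would sit on the consensus map (this assumes 1 bp of scaffold ≙
1 bp of consensus map, valid after stretch normalization). Gaps are the
signed distances between consecutive projections. Positive gaps are
written into the sequence as runs of `N` of the rounded length with AGP
`N` lines; non-positive gaps get the fixed 100 bp spacer and an AGP `U`
(unknown) line — the overlap may be real or may be a mis-assembly, so the
join is recorded but its size is declared unknown. Passing alignments
with PAT below 60 % are flagged as partial; gaps below −20 kb are flagged
as extreme. Both flags are reports, not vetoes, matching the behaviour of
the tool version used for published results; the optional
`min_negative_gap_exclusion` reproduces the later version's behaviour of
excluding both flanking maps from joining in that pass.

## Iteration

`run_iterations()` loops digest → align → invert → stitch until a pass
creates no joins (or `max_iter`, default 5, matching published practice).
Iteration earns its keep where a scaffold straddles two consensus maps:
in pass one it can serve only one of them (one alignment per in silico
map per pass), but once merged into a super scaffold, the merged map
reaches into the second consensus map and recruits the scaffolds there.
A consequence of the one-alignment-per-map rule worth knowing: a long
chain of consensus maps merges from its *ends* inward, roughly one join
per map end per pass, because interior super scaffolds always prefer
their own map. Full recovery in few passes therefore requires consensus
maps that are deep (covering many scaffolds each) rather than many and
shallow — which is also the regime where real consensus maps are useful.
Nested AGP objects are flattened after every pass so the final AGP
references only original input scaffolds, with placements composed
(`-` of `-` is `+`); reconstruction from the flattened AGP is tested to
reproduce the emitted FASTA exactly. Across passes the tests assert the
record count never increases, N50 never decreases, and non-N bases are
conserved.

## The simulator

`make_genome()` / `fragment_genome()` / `simulate_consensus_maps()` /
`simulate_molecules()` generate a fully known study system: an i.i.d.
random genome, scaffolds that tile it minus true gaps (shuffled and
randomly reverse-complemented so stitching must recover order *and*
orientation), consensus maps as genome windows whose labels are the true
digestion perturbed by multiplicative interval sizing error, binomial
label dropout and Poisson false labels, and molecules carrying per-scan
stretch. `truth_xmap()` emits the alignments implied by provenance, with
the matched-label count as a documented confidence proxy.

Window boundaries are placed inside scaffolds, at a label-count quantile
of the boundary scaffold (default 60 % of its sites left of the cut), and
boundary scaffolds are chosen among those with at least 20 sites. This
guarantees the geometry the generator promises: every true adjacency is
interior to one window, and the straddling scaffold is alignable on both
sides, so the only join that *requires* a second pass is the one across
the cut. The default pipeline conditions used by the tests and the
acceptance script are a 2 Mb genome at GC 0.5 (≈24 labels per 100 kb
with the default dual-enzyme digest — deliberately label-rich so every
scaffold portion is alignable) in 16 scaffolds with two consensus maps for the
noise-free iterative run, and a 5 Mb genome in 40 scaffolds with 2 %
sizing sd, 10 % dropout and 1 false label per 100 kb for the noisy
single-pass run; these sizes keep a full run in seconds while leaving
every selection and iteration mechanism exercised.

What the simulator does not emulate: chimeric scaffolds, fragile-site
breakage, coverage-dependent consensus errors, reference bias in the
aligner, and realistic confidence scores. Passing tests therefore show
the *algorithms* are correct under the stated noise model, not that any
particular real genome will reach the same recovery rates.

## The naive stand-in aligner

`naive_overlap_align()` exists so the pipeline can run without the
proprietary aligner; it is suitable for tests and demonstrations only.
Candidate offsets between two label lists are voted by binning all
pairwise position differences (bin width twice the pairing tolerance);
each candidate is evaluated by greedy two-pointer pairing within the
tolerance, in both orientations, and the maximal-match alignment is
reported with the matched count as its confidence proxy. Two numerical
choices matter:

* the tolerance (default 50 bp) must be far below the typical label
  spacing, because a random offset pairs roughly `2·tol/spacing` of the
  labels — at 4 kb spacing and 1.5 kb tolerance chance chains outnumber
  genuine short overlaps;
* a minimum matched *density* (default 0.5 of the labels spanned on
  either map) rejects sparse chance chains outright, since a genuine
  overlap pairs nearly all spanned labels while chance chains pair a few
  percent. Candidates are screened by an index-based density bound before
  the greedy pass, keeping the search fast on large maps.

## Degenerate inputs and small decisions

* `n50()` errors on empty input; batch reports print 0 with a warning
  instead, so one empty stratum cannot abort a table.
* Scans with no alignments: flagged, scale 1, `bpp` absent.
* Identical projected starts during ordering: resolved by projected end,
  with a message.
* Tie-breaks everywhere are deterministic so repeated runs are identical.
* Super-scaffold names (`Super_scaffold_<k>`) use one global counter
  across iterations so names are never reused.
* Simulated positions are rounded to 0.1 bp, the precision the text
  formats print, which keeps write→read round trips exact.

## Limitations

Joins are only as good as the input alignments: the package consumes
confidence scores, it cannot recompute them. Negative-gap regions are
joined with spacers, not locally assembled. Chimeric scaffolds are
flagged (partial alignments, extreme negative gaps) but never broken —
that remains a curation step. The sweep module plans and ranks assembler
runs; it cannot run the proprietary assembler, and its noise parameters
are passed through untouched.
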