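---
title: "Discovering hidden functional centers: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering hidden functional centers: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centerscan)
```

## The model

centerscan operationalizes a minimalistic view of protein function: in a
complex multi-domain protein, only the residues that directly perform a
molecular function — coordinate a substrate, bind a heme iron, contact a
hormone — are under strong purifying selection, while everything around
them drifts. A functional center is therefore modeled as a short pattern of
anchored key residues separated by length-constrained stretches of
arbitrary sequence:

```
[KS] x [CGS] x(10) [KR]        # guanylate cyclase catalytic center, 14 aa
H x(12) P x(14,16) Y x S x R   # H-NOX heme/gas-sensing center, 33-35 aa
```

The assumptions this rests on, and their consequences:

* **Key residues are conserved across non-orthologs.** The motif is built
  from an alignment of *annotated centers*, not whole proteins, drawn from
  distantly related species. If a key residue is not conserved in the
  training set, it will not be anchored, and the motif loses specificity.
* **Spacing is constrained but not fixed.** Gaps carry only a `(min,max)`
  length range. Any residue content inside a gap is accepted; the model has
  no position-specific scoring inside gaps (this is a pattern, not a
  profile/HMM — a deliberate scope decision, matching the search tools this
  emulates).
* **Composition around the center is informative.** Even non-conserved
  residues at a working center tend to preserve bulk physicochemistry, so a
  hit whose molecular weight, isoelectric point and hydrophobicity sit near
  the means of validated centers is more credible than one far away. This
  is the basis of the 0–1 ranking stage.

## Pattern semantics and matching

Patterns use the PROSITE dialect: fixed residues (`H`), classes (`[KS]`),
exclusions (`{P}`), wildcards `x`, `x(N)`, `x(N,M)` and optional terminal
anchors `<`/`>`. One syntactic point deserves emphasis: some informal motif
notations write gap ranges with curly braces, `{N,M}`. In PROSITE, curly
braces mean *exclusion*. The parser here follows PROSITE strictly — ranged
gaps are accepted only as `x(N,M)`, and `{ABC}` always excludes residues
A, B and C — so patterns written here paste into other PROSITE-dialect
tools without silent reinterpretation.

`find_matches` reports **every** distinct `(start, end)` span, including
several end points per start when ranged gaps permit different lengths, and
overlapping spans. Discovery is the goal, and a missed alternative span
could be the biologically relevant one; `shortest_per_start` mode exists
for compact reports. Coordinates are 1-based with inclusive ends in every
output.

The matcher sweeps a position-set through the element list (a boolean
reachability matrix over candidate starts x positions), which stays
polynomial even for wide gaps like `x(20,40)`. Its behavioral contract is
defined by an independently written brute-force enumerator,
`brute_force_matches`: the test suite asserts exact span-set equality on
hundreds of randomized pattern/sequence instances per run, and the
acceptance script repeats that check on 500 instances.

**Ambiguity codes.** `X`, `B`, `Z`, `J`, `U`, `O` in a *sequence* satisfy
only wildcard elements — never fixed residues, classes, or exclusions. This
is the conservative choice: an unknown residue should not certify a key
position, and `{P}` asserting "not proline" cannot be verified for an
unknown residue either. `*` truncates a sequence and `-` is dropped, each
with a warning. Consequently false negatives are possible in heavily
degenerate database entries, which we accept to keep false positives down.

**Relaxation.** When a search retrieves too few candidates, `expand_class`
adds chemically similar residues to an anchor (`[IL]` → `[VIL]`) and
`widen_gap` loosens a gap range. Both operations are constructively
monotone — widening only — so every previously matched span remains
matched; the suite verifies this superset property on randomized instances.
Tightening is done by re-parsing an edited pattern, never through these
operations, so an accidental narrowing cannot masquerade as relaxation.

## Consensus construction

`build_motif` turns a center alignment into a pattern with these rules:

* A column is an **anchor** when the most frequent residue *or residue
  group* reaches `conservation_threshold` (default 0.9) among non-gap rows
  **and** the column's gap fraction is at most `max_gap_fraction` (default
  0.2). The threshold is inclusive (ties anchor) for determinism. The
  defaults encode "keep key amino acids only": 0.9 requires near-unanimity,
  and the gap cap stops a column that most species do not even possess from
  anchoring. Neither value has a canonical published setting, so both are
  exposed as parameters (and CLI flags).
* The default grouping pools basic `{K,R}`, acidic `{D,E}`, aliphatic
  `{I,L,V,M}`, aromatic `{F,Y,W}` and hydroxyl `{S,T}` residues — the
  similarity classes that recur in published center motifs (`[RK]`, `[DE]`,
  `[VIL]`).
* An anchor element contains the residues **observed** at that column, in
  order of first appearance. Completing a class with unobserved group
  members (`group_complete = TRUE`) is opt-in: it is a recommendation for
  inclusive searching, not a property of the data.
* `force_positions` marks columns that anchor regardless of conservation —
  for residues whose function is experimentally proven — and
  `forced_only = TRUE` restricts anchoring to those columns. This also
  covers anchor classes such as `[KS]` that straddle the grouping scheme
  (K is basic, S is hydroxyl) and would otherwise never reach a group
  threshold.
* A maximal run of non-anchor columns becomes one wildcard with
  `(min,max)` equal to the fewest/most non-gap residues any row spans
  there; a run whose minimum is 0 renders as `x(0,M)`. Leading and trailing
  non-anchor runs are trimmed — a motif cannot begin or end in a gap.

These rules make the builder *self-consistent by construction*: every
ungapped training row matches the built motif, for any threshold, because
its anchor residues are in the anchor classes and its run lengths are
within the wildcard bounds. The suite asserts this 100% training recall on
randomized alignments, and that raising the threshold never adds anchors.

Consensus length outside 12–50 aa draws a warning, never an error: short
motifs inflate false positives and long ones suppress recall, but both can
be legitimate when conserved residues are unusually dense or sparse.

## Physicochemical ranking

`compute_features` evaluates, per matched subsequence:

* **Molecular weight** (Da): sum of average residue masses plus one water
  (shipped table, `inst/extdata/tables/residue_masses.tsv`).
* **Isoelectric point** (pH units): the root of the Henderson–Hasselbalch
  net-charge curve over the EMBOSS pKa set (N/C termini plus K, R, H, D, E,
  C, Y side chains), found by bisection on (0, 14) to 1e-7 — the charge
  curve is strictly decreasing in pH, so the root is unique. Published pKa
  sets differ; the table is a versioned data file, and tests cross-check
  the root against an independent grid scan of the same table.
* **Mean hydrophobicity** (dimensionless): the Kyte–Doolittle GRAVY score,
  the arithmetic mean of residue hydropathies.
* **Net charge at pH 7** — reported as an auxiliary column, not scored.

`reference_stats` summarizes a pool of validated center sequences into
per-feature means and standard deviations (sd floored at
`1e-6·|mean| + 1e-9` so single-sequence or degenerate pools still score).
No reference pool ships as ground truth — validated centers live behind
database accessions — so users supply their own FASTA, or generate a
synthetic pool with `sample_motif_instance` for testing.

The per-feature score is `max(0, 1 − |x − μ|/(cσ))` with spread multiplier
`c = 3`. The published description of this screening stage specifies only
the anchor ("1 is closest to the mean"), a 0–1 range, and a green/red
confidence coloring; the linear decay is this package's choice because it
is monotone in the deviation, hits both anchors exactly (1 at μ, 0 at cσ),
and has one interpretable parameter. The green/amber/red cutoffs 0.6/0.3
are likewise documented conventions, configurable per run and recorded in
output headers. The selection rule is applied verbatim: overall mean green,
at least two green features, zero red features. The downstream-acidic
(cation-binding) flag is surfaced as a boolean column but never folded into
the numeric score — no principled weighting exists for it.

The downstream-acidic window defaults to offsets 1–3 past the hit's last
residue. Descriptions of the rule vary between "0–3" and "1, 2, or 3"
positions downstream; offset 0 falls on the motif's own final position, so
1–3 is the default and `window = c(0, 3)` is selectable.

## The synthetic-data module

`random_proteome` draws i.i.d. residues (uniform 1/20 by default — the
simplest analytic null, making single-residue hit counts exactly binomial —
or an empirical Swiss-Prot-frequency preset). `plant_instances` overwrites
non-overlapping regions with strings sampled uniformly from a motif's
language, records exact coordinates as ground truth, verifies each planted
string against its motif at generation time, and can append the
cation-binding D/E at offset 1–3. `toy_center_alignment` builds alignments
with prescribed anchor/gap structure — the first two rows realize each
gap's min and max so both bounds are always observed, anchor-class members
are cycled so every member appears, and filler columns are resampled
(seeded, bounded retries) if they accidentally reach the conservation
threshold — which makes builder round-trips deterministic: the generated
alignment provably rebuilds into the prescribed pattern text.

What this emulates: motif occurrences embedded in unconstrained background,
at controlled density, with known truth. What it does **not** emulate: real
domain architecture, compositional bias, low-complexity regions, repeats,
or evolutionary correlation between sites. Passing the planted-recovery
tests therefore demonstrates correctness of the machinery, not real-proteome
precision: on real proteomes the background-hit rate depends on composition
(a 14-residue pattern already yields chance hits in 50 × 300 aa of random
sequence, as the README example shows), and triaging those is precisely
the ranking stage's job.

Determinism: every generator takes an integer seed, restores the caller's
RNG state, and yields byte-identical output for identical inputs.

## Problem sizes and numerical choices

The shipped test and acceptance runs use: 500 random pattern/sequence
instances (patterns ≤ 6 elements, sequences ≤ 40 aa) for oracle
equivalence; 100 randomized alignments (4–10 rows) for builder
self-consistency; a 100 × 300-aa proteome with 7 planted instances per
curated motif for recovery; 150 randomized instances for relaxation
monotonicity; 10–15-sequence reference pools for ranking. These sizes give
the properties room to fail while keeping a full run around a minute on
one core; all scale linearly if users want heavier assurance.

Degenerate inputs are handled explicitly: empty sequences and empty
proteomes yield empty results (not errors); a hit flush with the sequence
end simply cannot carry a downstream flag; `x(3,3)` renders as `x(3)`;
single-row alignments pass through as literal patterns; a scan that finds
nothing still exits 0 from the CLI.

## Known limitations

* Patterns are hard-constraint; there is no mismatch tolerance or
  position-specific scoring. A center missing one anchor residue is
  invisible regardless of how well everything else fits.
* The ranking emulates the *qualitative* published screen. The exact
  algorithms of the web servers it stands in for are not published in the
  source describing this workflow, so no numeric equivalence is claimed —
  the scoring formula, thresholds and tables are all documented package
  choices.
* Feature scores treat MW, pI and GRAVY as independent; for short
  fragments they are correlated through composition.
* Structural assessment (homology modeling, docking) is out of scope; the
  handoff is the padded candidate FASTA from `export_candidates`.
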