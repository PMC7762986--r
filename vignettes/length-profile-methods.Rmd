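---
title: "Length-profile species identification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-profile species identification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindelr)
```

## The model

`spindelr` identifies species from length variation, not sequence variation.
The underlying picture of a non-coding organellar marker (an intergenic
spacer or intron) is a mosaic: short blocks under strong constraint — the
*conserved anchors*, effectively identical and gap-free across the taxon
group — alternate with *hypervariable regions* where insertions and
deletions accumulate freely. In a multiple alignment the anchors line up as
clean column runs while hypervariable segments are riddled with gaps.

Each specimen is reduced to its **numeric profile**: the ordered vector of
ungapped fragment lengths, one per hypervariable region, over a panel that
may span several markers. Two assumptions make this useful:

* **Indels carry the signal.** Within a closely related group, substitutions
  in these regions are common but phylogenetically noisy, whereas indel
  haplotypes are fewer, longer-lived and less prone to recurrent mutation. A
  profile ignores substitutions entirely — 'N' and every IUPAC ambiguity
  code count as one residue, because ambiguity does not change the physical
  fragment length.
* **Anchors are boundaries, not data.** Lengths are measured strictly
  between anchors; the anchors themselves (being near-constant) contribute
  no discriminating information, only coordinates.

All statistics are functions of the profile table alone (accession ×
region lengths plus species labels), so they apply identically to
single-marker and concatenated panels.

### Statistics

For a table of `m` accessions over `n` regions:

* Identical length vectors are grouped into **distinct profiles** (`N`). A
  profile is **species-specific** when its carriers belong to exactly one
  species (`Nsp` such profiles); a profile carried by three accessions of
  one species is still specific.
* **`f_sp`**, the frequency of species-specific profiles, is by default
  *accession-weighted*: the fraction of accessions with complete profiles
  whose profile is species-specific. This is the only reading consistent
  with published per-region values such as 0.91 on 35 accessions
  (0.91 ≈ 32/35; no k/13 over species comes close), and it is the
  definition the bundled summary table reproduces. A species-level variant
  (fraction of species whose accessions all carry specific profiles) is
  available via `definition = "species"`.
* The **mismatch distribution** counts, for each of the C(m,2) unordered
  accession pairs, the number of panel positions at which both lengths are
  present and unequal. Its mean is the average number of pairwise
  differences `p`; dividing by `n` gives a per-region rate. (Published
  per-region columns are not always `p/n` at the printed precision — e.g. a
  one-region marker printed with `p` = 0.07 but per-region 0.02 — and the
  original normalization is undocumented; this package reports `p/n` and
  leaves the discrepancy visible rather than reverse-engineering it.)
* The **minimum discriminating subset** search enumerates subsets of a
  region pool in increasing cardinality and returns the smallest size at
  which some subset makes every species' set of restricted profiles
  disjoint from every other species' set, together with *all* witness
  subsets of that size in lexicographic order. The pool is an explicit
  argument because published per-marker minima sometimes exceed the
  marker's own region count, implying an unstated larger pool; an explicit
  pool keeps the semantics unambiguous. Search cost is exponential by
  design — study panels have at most ~10 regions — and `f_sp`-based greedy
  selection (`greedy_combination()`, labeled approximate) covers larger
  panels.
* **Combination analysis** scores every nonempty subset of the panel
  (`2^n − 1` of them, guarded at `n ≤ 20`) with `f_sp`, distinct-profile
  count and mean pairwise differences. Because adding a region refines the
  profile partition, `f_sp` is monotone non-decreasing along subset
  inclusion — a property the tests check on random tables. The
  region-by-region matrix reports, for groups i and j (markers by default),
  the mean pairwise differences over the union of their regions divided by
  the union's size; the diagonal carries the single-group values, so both
  the "individual" and the "pairwise" readings of a region-by-region
  analysis come from one symmetric artifact.

### Missing data

A missing length (sequence absent for that marker) is explicit (`NA`), never
imputed. Grouping treats `NA` as a distinct token; `N`, `Nsp` and `f_sp` are
computed over complete profiles only (all-incomplete input is an error, not
a silent 0). Pairwise comparisons are pairwise-complete: positions missing in
either profile are skipped, and pairs with no comparable position are
excluded from the distribution and reported separately
(`n_incomparable_pairs`). This keeps every usable observation without
inventing data.

## Anchor detection

The original workflow relied on externally curated anchor coordinates; this
package accepts such coordinate tables (`read_regions()`, which always
override detection) and also detects anchors itself. A column qualifies when
its gap fraction is at most `max_gap_fraction` **and** the modal-residue
frequency among non-gap characters is at least `min_identity`; maximal runs
of qualifying columns at least `min_width` long become anchors.

Defaults are the strictest settings that recover simulated truth exactly:
`min_identity = 1.0`, `max_gap_fraction = 0.0`, `min_width = 15` columns
(a primer-anchor-like block), `window = 1`. With `window > 1` the two
per-column statistics are smoothed by a centered sliding mean before
thresholding, which tolerates isolated noisy columns inside long blocks;
smoothing preserves the monotonicity of the qualifying predicate in both
thresholds. Consensus ties are broken alphabetically so outputs are
deterministic. Coordinates are 0-based half-open alignment columns in every
file and API.

Degenerate inputs: an alignment with no qualifying run yields an empty
region table (not an error); `window` larger than the alignment, identity
thresholds outside (0, 1], inverted or overlapping intervals, and `'.'`-style
gaps are errors with named offenders. Residues outside `{A,C,G,T,N,-}` are
accepted and listed in a validation report, since chromatogram-derived data
legitimately contain ambiguity codes.

## The simulator and what a green test establishes

`simulate_spindel()` generates the world the analysis assumes, with full
ground truth. Per marker: one random anchor sequence per conserved block,
shared by all sequences; per hypervariable region a base length drawn
uniformly from `hv_base_length_range`, plus a per-species offset from
`species_length_effect_range`, plus — with probability
`intraspecific_indel_prob` — one private insertion-or-deletion per accession
(size uniform on `intraspecific_indel_size_range`, sign by fair coin,
lengths clamped at zero). Segments are realized as uniform-random
nucleotides, left-aligned and gap-padded to the region maximum.

Defaults state the study design being emulated, and were fixed before any
acceptance measurement:

| parameter | default | rationale |
|---|---|---|
| `n_species`, accessions | 13 species, 35 accessions (9×3 + 4×2) | the study's sampling design |
| markers | 4 cp-like + 6 mt-like | the study's marker panel |
| anchor blocks per marker | 6,5,4,4 / 4,4,5,4,3,5 | the study's per-marker anchor counts |
| `conserved_block_length` | 20 bp | primer-anchor scale |
| `hv_base_length_range` | 80–300 bp | organellar spacer segment lengths |
| `species_length_effect_range` | ±10 bp | multi-bp indel haplotype differences |
| `intraspecific_indel_prob` | 0.1 | modest within-species variation |
| `intraspecific_indel_size_range` | 1–5 bp | the indel size class reported for these spacers |
| `missing_prob` | 0 | the study had complete marker coverage |

Two deliberate simplifications: species effects are drawn *without
replacement* whenever the effect range holds at least `n_species` integers,
so "all species effects distinct" holds by construction and the q = 0
parameter-recovery property (`f_sp = 1`, anchors recovered exactly) is a
meaningful end-to-end check rather than a coin flip; and each accession
carries at most one indel event per region, because every statistic depends
only on the resulting lengths, not on the event history.

What the simulator does **not** emulate: substitution patterns (composition
is uniform and irrelevant to lengths), rate heterogeneity among regions,
alignment error (gap placement is canonical left-alignment; tests depend
only on non-gap counts), heteroplasmy, and homoplasy of indel lengths across
species beyond what random effect collisions produce. A green test
establishes that the machinery is correct on data satisfying the model's
assumptions — not that real organellar alignments satisfy them.

## Concatenation protocol

Multi-marker panels are built by profiling each marker separately and
merging (`merge_panels()`), never by physically concatenating alignments.
Peripheral hypervariable spans — outside a marker's first or last anchor —
are excluded by default (`include_peripheral = FALSE` in
`derive_hypervariable_regions()`): adjacent markers are not adjacent in the
genome, so the flanks are not bounded by anchors on both sides and their
"lengths" are truncation artifacts of the amplicon, not biology. A flag
restores them for single-marker exploration.

Duplicate sequences for one accession within a marker are collapsed when
their profiles agree and are an error otherwise, since profiles are reported
per accession. Discrimination is evaluated at species level by default, with
`level = "subspecies"` in `build_profiles()` to treat subspecies as terminal
taxa.

## Known limitations

* Detection uses modal-frequency conservation only; no entropy or
  phylogenetic footprinting scores.
* `f_sp` carries no uncertainty quantification (none is defined for the
  original statistic).
* Exhaustive subset machinery is exponential; beyond ~20 regions only the
  approximate greedy path is offered.
* Reproducing the original study's concatenated statistics requires its
  GenBank sequences and unpublished anchor coordinates; the pipeline can
  run that analysis when given those inputs, but nothing here asserts its
  values.
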