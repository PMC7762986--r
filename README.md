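# spindelr

Species identification from indel length profiles in non-coding organellar
DNA.

Closely related plant taxa — the motivating case is the rye genus *Secale*,
whose 13 commonly distinguished species and subspecies resist discrimination
by substitution-based markers — often differ reliably in the *lengths* of
indel-rich, non-coding chloroplast and mitochondrial regions. `spindelr`
implements the length-profile approach to exploiting that signal:

1. In a multiple sequence alignment of one marker (an intergenic spacer or
   intron), find the **conserved anchor blocks**: gap-free, (near-)identical
   column runs.
2. The segments between consecutive anchors are the **hypervariable
   regions**. Each specimen is summarized by its **numeric profile**: the
   vector of ungapped fragment lengths, one per region. Indels change these
   lengths; substitutions do not, so the profile is robust to the noise that
   confounds tree-based barcoding of such regions.
3. Across a panel of `n` regions (possibly concatenated over markers), taxa
   are compared through their profiles:
   * `N` — number of distinct profiles; `Nsp` — profiles carried by exactly
     one species ("species-specific"); `N = Nsp + ` shared profiles.
   * `f_sp` — frequency of species-specific profiles, computed as the
     fraction of accessions (with complete profiles) whose profile is
     species-specific; a species-level variant is available.
   * the **mismatch distribution** — over all C(m,2) accession pairs, the
     distribution of the number of regions at which two profiles differ, and
     its mean `p` (average pairwise differences).
   * the **minimum discriminating subset** — the smallest set of regions that
     makes every species' profile set disjoint from every other's
     (exhaustive search, all minimal witnesses reported).
   * exhaustive **combination analysis** over all `2^n − 1` region subsets
     and a region-by-region (marker-pair) discriminatory potential matrix.

A ground-truthed simulator generates study-shaped data — identical anchors
flanking hypervariable segments whose lengths carry a per-species effect plus
intraspecific indel noise — so every stage can be tested against known truth.

## Worked example

Simulate a chloroplast-like study design (13 species, 35 accessions, 4
markers with 6/5/4/4 anchor blocks), detect anchors, profile, summarize:

```r
library(spindelr)

cfg <- spindel_sim_config(n_markers = 4, marker_names = paste0("cp", 1:4),
                          conserved_blocks_per_marker = c(6, 5, 4, 4), seed = 42)
sim <- simulate_spindel(cfg)

aln     <- sim$alignments$cp3
regions <- detect_conserved_regions(aln)   # strict defaults recover the anchors
hv      <- derive_hypervariable_regions(regions, aln$width)
tab     <- build_profiles(aln, hv, sim$metadata)
head(as.data.frame(tab), 4)
#>   accession    species cp3:hv0 cp3:hv1 cp3:hv2
#> 1   acc_001 species_01     154     221     244
#> 2   acc_002 species_01     154     221     244
#> 3   acc_003 species_01     150     221     244
#> 4   acc_004 species_02     146     209     249

region_stats(tab, conserved_count = nrow(regions))
#> <region_stats>
#>   conserved blocks:         4
#>   hypervariable regions n:  3
#>   distinct profiles N:      19
#>   species-specific Nsp:     19
#>   species sharing profiles: 0
#>   f_sp:                     1
#>   avg pairwise diffs p:    2.84 (595 pairs)
#>   min regions to separate:  2
```

Every distinct profile here is carried by a single species (`Nsp = N = 19`,
`f_sp = 1`): at this simulation's noise level (intraspecific indel
probability 0.1) the marker identifies all 13 species, and two of its three
regions already suffice (`min regions to separate: 2`). Accessions of the
same species differ only where a private indel hit (e.g. `acc_003` lost 4 bp
in `cp3:hv0`).

Concatenating all four markers and comparing all accession pairs:

```r
tabs <- lapply(sim$alignments, function(a) {
  r <- detect_conserved_regions(a)
  build_profiles(a, derive_hypervariable_regions(r, a$width), sim$metadata)
})
merged <- merge_panels(unname(tabs))
pw <- concatenated_mismatch(merged)
sum(pw$distribution); round(pw$mean, 2)
#> [1] 595      # = C(35,2) pairs
#> [1] 14.26    # mean number of regions differing between two profiles

head(enumerate_combinations(tabs[[3]])[, c("label", "size", "f_sp")], 3)
#>             label size f_sp
#> 1 cp3:hv0,cp3:hv1    2    1
#> 2 cp3:hv0,cp3:hv2    2    1
#> 3 cp3:hv1,cp3:hv2    2    1
```

A published per-region summary for the *Secale* study design (4 cpDNA + 6
mtDNA regions) ships as
`system.file("extdata", "secale_region_summary.tsv", package = "spindelr")`;
`aggregate_region_stats(df, by = "genome")` reproduces its genome-level means
(cpDNA: mean `Nsp` 2.5, mean `f_sp` 0.83; mtDNA: 2.67 and 0.73).

## Command line

`inst/exec/spindel` exposes the pipeline as subcommands:

```sh
spindel simulate  --config sim.yaml --seed 9 --out simdir/
spindel conserved --alignment simdir/m01.fasta --marker m01 --out m01.regions.tsv
spindel profile   --alignment simdir/m01.fasta --marker m01 \
                  --regions m01.regions.tsv --metadata simdir/metadata.tsv \
                  --out m01.profiles.tsv
spindel stats     --profiles m01.profiles.tsv --out m01.stats.json
spindel concat    --profiles m01.profiles.tsv,m02.profiles.tsv --out concat.json
```

Exit codes: 0 success, 1 data/validation error, 2 usage error. All
randomness flows from `--seed`; identical inputs give byte-identical outputs.

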