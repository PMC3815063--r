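# linkpeak

Builds chromosome-scale pseudomolecules from an unordered scaffold
assembly by combining genetic-map anchoring, *in silico* anchoring from
related maps, and windowed mate-pair **link-peak** scoring.

Draft plant genomes typically arrive as thousands of unplaced, unoriented
scaffolds. To turn them into chromosome sequences you need to (i) tie
scaffolds to positions on a genetic map through sequence-tagged-site (STS)
markers, (ii) borrow anchoring evidence from related genotypes or species
where the reference map is thin, (iii) order and orient the scaffolds,
(iv) find and split chimeric scaffolds (false joins between chromosomes),
and (v) emit the result as a standard AGP layout with fixed gaps.
`linkpeak` implements that whole workflow for R users working with
tabular alignment and mapping evidence (no raw reads required), plus the
genetic-map QC and Marey-map recombination profiling that go with it.

## The core statistic

For a *source* scaffold, a window of width *w* slides along its length.
Within a window, every **unsatisfied mate pair** — one end in the window,
the other end reliably mapped to a different, non-adjoining scaffold — is
grouped by its target scaffold, and each group is scored

&nbsp;&nbsp;&nbsp;&nbsp;S(target) = Σ<sub>pairs in group</sub> v(library),

where v is a per-library weight (larger for the reference genotype's
libraries and for longer, more reliably aligned inserts). The
**link-peak score** of the window is max<sub>t</sub> S(t); the **noise
score** is Σ<sub>t≠peak</sub> S(t), which exposes repeat-driven spurious
links. A reciprocally high link-peak between the facing ends of two
scaffolds is called as a scaffolding link; the end pairing (R–L vs. R–R)
gives their relative orientation, propagated over the link graph. Where
link evidence is absent, orientation falls back to the sign of the
Theil–Sen slope of anchor cM against bp within the scaffold.

Supporting machinery includes the marker filter cascade (repeat-depth
filter → indel-tolerant hit grouping → read-pair consistency → unique
placement), clone-end / WGP-tag / synteny proxy anchoring with monotone
map projection and inversion handling, chimera breakpoint detection from
conflicting anchor runs, Kosambi map-function conversion, segregation
distortion scans, and Marey-profile pericentromere calling. A seeded
synthetic-data generator produces genomes, scaffolds (with planted
chimeras), mate-pair libraries, markers, genotypes and maps with known
truth, so every stage is testable end to end.

## Worked example

```r
library(linkpeak)

sim <- simulate_assembly(sim_config(seed = 42))   # ~30 Mb, 56 scaffolds
qc  <- filter_genotype_matrix(sim$markers$genotypes)
cs  <- collapse_cosegregating(qc$geno)
res <- anchor_markers(sim$markers$alignments, sim$markers$map,
                      sim$markers$metadata, cs$groups)
res$report
#> # A tibble: 8 × 2
#>   stage            markers
#>   <chr>              <int>
#> 1 input                244
#> 2 depth_filter         194
#> 3 hit_grouping         194
#> 4 pair_filter          194
#> 5 unique_placement     188
#> 6 map_join             188
#> 7 a_priori              40
#> 8 anchored             228

asm <- assemble_pseudomolecules(res$anchors, sim$pairs, sim$libraries,
                                sim$scaffold_lengths)
asm
#> <pm_assembly> 3 chromosome(s), 51 segments anchored (27.9 Mb),
#>               100.0% oriented, 1 chimera breakpoint(s)

glance(asm)
#> # A tibble: 1 × 7
#>   n_chromosomes anchored_n anchored_Mb oriented_pct mean_N50_Mb n_links ...
#> 1             3         51        27.9          100       0.718      52

tidy(asm, "chimeras")[, 1:4]
#> # A tibble: 1 × 4
#>   scaffold_id breakpoint_bp left_chrom right_chrom
#> 1 S048               335408 3          1
```

The report table counts markers surviving each filter stage (244 in, 50
lost to repeat-like alignments, ambiguity or pairing, 40 placed a
priori). The assembly orders 51 chimera-split segments onto 3
chromosomes, orients all of them (links first, map slope as fallback) and
flags one false join whose two sides carry enough reference-map anchors;
passing projected foreign-map anchors via `anchors_rh =` / `anchors_tom =`
catches misjoins in marker-poor regions too. `write_agp(asm$agp, ...)`
and `build_pm_sequence(asm$agp, seqs)` emit the layout and the
N-gapped chromosome sequences; `profiles_to_wiggle(asm$profiles)` exports
the evidence tracks for a genome browser.

Single formulas work directly on published map summaries:

```r
kosambi_cM(0.25)                      # 27.46531 cM
map_interval_spacing(936.2, 1751, 12) # 0.54 cM/interval
```

A thin command-line front end (`exec/linkpeak`, installed with the
package) exposes `simulate`, `anchor`, `linkscore`, `build-pm`, `stats`
and `marey` subcommands over the same functions.

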