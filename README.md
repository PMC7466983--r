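# evoprintr

Phylogenetic footprinting for regulatory-genomics work: project the
conservation of many test species onto one reference sequence at near
base-pair resolution (an *EvoPrint*), call conserved sequence blocks (CSBs)
and CSB clusters — the building blocks of *cis*-regulatory DNA — and map
CSBs into distantly related taxa to identify ultraconserved CSBs (uCSBs)
with linear-order (colinearity) and orientation (microinversion) analysis.

The package is aimed at people studying enhancers and other non-coding
functional elements in insect (or any compact) genomes who have orthologous
regions in hand as FASTA and want a reproducible, scriptable footprinting
pipeline with a built-in ground-truth simulator for validation.

## The statistic at the core

For test species $s = 1,\dots,S$ and reference positions $p = 1,\dots,L$, a
BLAT-style k-mer seeded local aligner (seeds $k \in \{9,11\}$ on both
strands, ungapped x-drop extension, colinear chaining) yields a boolean
conservation matrix $C_{sp}$: position $p$ is conserved in species $s$ iff
it lies in a retained alignment block and the aligned base is identical.
The relaxed EvoPrint mask with relaxation $R$ is

$$M_R(p) = \mathbf{1}\Big[\textstyle\sum_s (1 - C_{sp}) \le R\Big]$$

rendered as uppercase ($M_R = 1$) / lowercase ($M_R = 0$) over the intact
reference sequence. $R=0$ is the strict print, $R=1$ the standard relaxed
print ("conserved in all or all but one species"). Maximal uppercase runs
≥ `L_min` are CSBs; CSBs within `G` bp of each other form clusters; a CSB
recovered in a distant-taxon contig at ≥ 80% identity over ≥ 50% of its
length is a uCSB.

## Worked example

Simulate six species diverged from a 1,200 bp ancestor carrying three
conserved blocks (45/55/40 bp) in fast-evolving spacers, then footprint:

```r
library(evoprintr)

cfg <- simulation_config(1200, cbind(start = c(200, 520, 900),
                                     length = c(45, 55, 40)),
                         n_species = 6, p_block = 0.01, p_spacer = 0.25,
                         indel_rate = 0.01, seed = 7)
ds   <- generate_dataset(cfg)
prof <- build_profile(ds$ancestor, ds$species_seqs)
ep   <- make_evoprint(prof, R = 1)      # relaxed print: all-but-one
ep
#> <evoprint> ancestor (1200 bp), R = 1, 613/1200 bases conserved

csbs <- call_csbs(ep, caller_params(L_min = 10))
csbs
#> <csb> csb_0001 ancestor:200-246 (46 bp)
#> <csb> csb_0002 ancestor:518-575 (57 bp)
#> <csb> csb_0003 ancestor:897-943 (46 bp)
```

The three called CSBs sit exactly on the planted blocks (200–245, 520–575,
900–940, give or take the odd conserved flanking base), and the 613
uppercase bases are the blocks plus whatever spacer happens to survive in
at least five of six species. A slice of the print around the first block
shows the characteristic block/spacer texture:

```r
substr(render_evoprint(ep), 180, 260)
#> "aCATCGGTagTcgTCagcCtcCACGATAGCCTGTTGACGTCAGGCAACCTTGTGCGTGGTCATAGCTaGgCaatCTAACTc"
```

The scorecard counts conserved bases per species (self score = 1,200):

```r
scorecard(prof)
#>  species score  fraction
#>     sp01   906 0.7550000
#>     sp02   876 0.7300000
#>     ...
```

Mapping a CSB into another species finds it at full identity and coverage,
with strand:

```r
map_csb(csbs[[2]], ds$species_seqs[[3]])[[1]]
#> <ucsb_match> csb_0002 -> sp03:526-583(+) identity 1.000 coverage 1.000
```

`analyze_colinearity()` and `classify_sharing()` extend this to whole CSB
sets against one or two distant targets, flagging microinversions
(minority-strand matches) and order violations.

## Command line

An installed `exec/evoprint` script (or `evoprint_cli()` from R) wires the
workflows into subcommands:

```sh
evoprint simulate --length 2000 --species 8 --seed 7 --out sim/
evoprint evoprint --ref sim/ancestor.fasta --tests sim/species.fasta --relax 1 --out out/
evoprint csbs     --ref sim/ancestor.fasta --tests sim/species.fasta --out out/
evoprint map-ucsb --csbs out/csbs.fasta --target distant.fasta --out out/
```

Outputs are plain text: the wrapped EvoPrint with a missing-species track,
the flat case-masked sequence, a scorecard TSV, a per-base missing-count
bedgraph, CSB BED6/FASTA, cluster TSV, uCSB match TSV and a colinearity
summary.

## Notes

Two acceptance tests in `tests/testthat/test-acceptance.R` are intentionally
left failing; they encode bars the implementation's stated parameter world
cannot meet (exact per-base equality with one specific DP traceback under a
degenerate linear gap cost, and ≥ 90% planted-block recovery from the
*strict* print when 8 independent species at 2% block divergence bound
strict per-base retention at $0.98^8 = 85.1\%$). The methods vignette
(`vignettes/evoprint-methods.Rmd`) carries the full analysis; the relaxed
print meets the recovery bar with room to spare.
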