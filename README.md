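# plastomeDiff

Comparative analysis of near-identical chloroplast genomes in R.

Chloroplast (plastid) genomes of closely related plants are circular
molecules of ~120–160 kb with a conserved quadripartite architecture: a
large and a small single-copy region (LSC, SSC) separated by two identical
inverted repeats (IRa, IRb). Between congeneric species the sequences often
differ by only a few dozen mutations, so the analysis of interest is an
exact census rather than a statistical model:

* **Structure** — find the IR pair as the maximal pair of disjoint segments
  with `IRa = revcomp(IRb)`, label the arcs LSC/SSC, report per-region
  length and GC, and rotate genomes into the canonical LSC-first layout.
* **SSRs** — every maximal perfect tandem repeat of a 1–6 bp motif with the
  conventional class thresholds (≥10 mono, ≥5 di, ≥4 tri, ≥3
  tetra/penta/hexa), each run reported under its primitive motif only.
* **Mutations** — an anchor-based collinear aligner for genome pairs at
  ~0.03% divergence, then substitution calls with transition/transversion
  classes (Ts iff both bases are purines or both pyrimidines), the six
  pooled non-strand-specific substitution types, left-normalized indels
  split into homopolymeric (slippage at a single-base run of ≥3) versus
  non-homopolymeric, insertion/deletion polarity against a designated
  standard genome, and the p-distance (mismatches over non-gap columns).
* **Micro-inversions** — short segments replaced by their reverse
  complement, detected from mismatch runs and masked out of SNP calls, with
  the flanking inverted-repeat arms (hairpin stems) measured by
  complementarity length.
* **Junctions** — distances from each IR border to its nearest gene and the
  genes a border cuts, the quantities compared when studying IR
  expansion/contraction.
* **Simulation** — a generator that builds plastomes with planted genes,
  SSRs, hairpin sites and mutations, returning an exact truth set so the
  whole pipeline is testable end to end without downloads.

## Worked example

Simulate a full-scale plastome pair at the package defaults (a 151,570 bp
genome with a 24,171 bp IR; 44 substitutions, 23 indels, 2 inversions) and
compare the pair:

```r
library(plastomeDiff)

pair <- plastome_pair(genome_spec(seed = 1), mutation_spec(seed = 2))
pair$standard
#> CircularGenome synthetic: 151,570 bp (circular)

st <- detect_inverted_repeats(pair$standard)
st
#> QuadripartiteStructure of synthetic (151,570 bp, IR 24,171 bp)
#>  name  start    end length gc_percent
#>   LSC      1  84214  84214       34.5
#>   IRb  84215 108385  24171       42.9
#>   SSC 108386 127399  19014       29.4
#>   IRa 127400 151570  24171       42.9

cmp <- compare_plastomes(pair$standard, pair$other, features = pair$features)
cmp$summary
#> MutationSummary: 44 substitutions (14 Ts / 30 Tv, ratio 0.47), 23 indels, 2 inversions
#> p-distance: 0.00029
```

All 44+23+2 planted events are re-called; the transition count (here 14) is
a per-seed binomial draw around the default transition fraction, recorded in
`pair$truth`. Event tables carry classes and annotation context:

```r
head(cmp$indels[, c("ref_pos", "seq", "length", "klass", "direction", "category")], 4)
#>   ref_pos   seq length             klass direction   category
#> 1    1669 TTAAT      5 non_homopolymeric Insertion Intergenic
#> 2    5196     A      1     homopolymeric  Deletion Intergenic
#> 3   12160 ATATT      5 non_homopolymeric Insertion Intergenic
#> 4   12716     T      1     homopolymeric  Deletion Intergenic

cmp$inversions[, c("start", "end", "length", "stem_arm_length", "category")]
#>   start   end length stem_arm_length   category
#> 1 11999 12010     12              20 Intergenic
#> 2 62248 62252      5              19 Intergenic

junction_gene_distance(st, pair$features)[, c("junction", "nearest_gene", "distance", "genes_cut")]
#>   junction nearest_gene distance     genes_cut
#> 1  LSC/IRb         g021      347
#> 2  IRb/SSC         g015      443
#> 3  SSC/IRa    ycf1_like        0 ycf1_like:763
#> 4  IRa/LSC    trnH_like        1
```

The last table shows the classic border configuration the generator plants:
a ycf1-like gene cut by the SSC/IRa junction with 763 bp inside the IR, and
a tRNA gene 1 bp into the LSC from the IRa/LSC junction. `run_pipeline()`
wraps all stages and writes `structure.tsv`, `ssr.tsv`,
`substitutions.tsv`, `indels.tsv`, `inversions.tsv`, `junctions.tsv`,
`gene_ts_tv.tsv` and `summary.json` into an output directory;
`inst/scripts/plastome-tools.R` exposes the same stages as shell
subcommands (`structure`, `ssr`, `compare`, `junctions`, `simulate`,
`paper-check`).

## Packaged study tables

`load_paper_fixture("table1" | "table3" | "table4" | "table5" | "table6")`
returns plain-text transcriptions of the genome-feature, indel,
substitution, per-gene Ts/Tv and SSR tables from the motivating saxaul
plastome study, and `paper_check()` recomputes every statistic derivable
from them with the package's own classifiers (Ts/Tv ratio, substitution
spectrum and location breakdown, p-distance, SSR class counts and A/T
share, region-length arithmetic). Rows with typographic inconsistencies in
the printed originals carry a `flag` column rather than silent corrections.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the fixtures-only statistics and runs one full-default-scale
synthetic pair through the complete pipeline, verifying that every planted
event is re-called, then writes the acceptance JSON to `--out`.

See `vignettes/plastome-comparison.Rmd` for the methods, parameter
conventions, simulator assumptions and known limitations.
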