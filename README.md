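# synmapr

Comparative alignment of genetic and genomic maps, conserved-synteny
discovery from gene-homology tables, and publication-quality vertical map
rendering to SVG — as a scriptable R library and command-line tool.

## Who this is for

Geneticists and genome-assembly groups working on species whose maps live
in heterogeneous coordinate systems: genetic linkage maps in centimorgans
(cM), physical/assembly maps in base pairs (bp), radiation-hybrid or ad hoc
marker lists in arbitrary units.  `synmapr` treats every map as a
self-contained one-dimensional coordinate system holding markers (genes,
variants, microsatellites, sequence hits), and integrates them three ways:

* **identity** — markers on different maps sharing a stable database
  accession (strong evidence they are the same object);
* **synonymy** — markers sharing only a name (weaker evidence: sharing a
  name does not guarantee two markers are the same);
* **homology** — asserted orthology/paralogy between genes, consumed from a
  Compara-style table with percent amino-acid identity/similarity scores
  (never computed from sequence here).

On top of these the package discovers **regions of conserved synteny** (the
target chromosome regions where a query region's genes have their
homologues), quantifies gene-order **inversions** via the crossing count of
link pairs, builds **ePCR bridge maps** by locating primer-pair amplicons
in genome FASTA (joining linkage maps to assemblies), and renders
everything as vertically aligned, scaled axes with colour-coded
relationship lines (Okabe–Ito colour-universal-design palette).

## The core statistics and rules

* A homology link between maps `a` and `b` exists for every table record
  whose two gene accessions occur on `a` and `b`; reporting stringency is
  raised with thresholds: keep a link iff `perc_identity >= min_identity`
  and `perc_similarity >= min_similarity` (scoreless links fail active
  thresholds; identity/synonymy links are never score-filtered).
* A conserved region for target chromosome `c` spans
  `[min, max]` of the located target homologues and is ranked by the number
  of distinct contributing source genes.  No minimum block size is imposed;
  callers threshold on the count.
* The crossing count of `k` links is the number of unordered pairs with
  discordant endpoint order (`sign(a_i - a_j) != sign(b_i - b_j)`, interval
  midpoints).  Collinear blocks give 0; a full inversion gives `k(k-1)/2`.
* An ePCR hit is an exact match of the forward primer with the reverse
  primer's reverse-complement strictly downstream on the same strand and a
  product length within the pair's bounds (both orientations tried).  Only
  pairs with exactly one hit genome-wide, on a placed sequence, become
  markers; others are discarded with a reason (`no_hit`, `multiple_hits`,
  `unplaced`).
* On the drawing canvas, maps whose horizontal extents overlap (closed
  intervals, transitively) share a *virtual column*; relationship lines are
  drawn only between maps in **adjacent** columns, which is how a layout
  controls what is visible.

## Worked example

Simulate a cow/human genome pair with one collinear block of 25 genes on
human chr1 and one inverted block of 10 genes on chr2, then search the
whole source chromosome for conserved synteny:

```r
library(synmapr)

sim <- simulate_genome_pair(sim_spec(seed = 1))
sim$source
#> <genome_map> source_chr1  (cow chr1, bp)
#>   extent [1, 2400000] assembly srcAsm1; 40 markers

res <- find_conserved_regions(
  sim$source,
  map_region(sim$source$map_id, sim$source$extent_min, sim$source$extent_max),
  sim$table, "human", sim$targets)
res
#> <conserved_region_set> 2 region(s), 0 unlocatable target gene(s)
#>   human chr1 [150158, 1442787]  25 source gene(s), 25 target gene(s)
#>   human chr2 [49068, 581658]  10 source gene(s), 10 target gene(s)
```

Both implanted blocks are recovered, ranked by how many source genes
support them, with spans covering every located target homologue.  The
chr2 block was implanted in reversed gene order, and the crossing count of
its 10 one-to-one orthology links is the complete-inversion value
`10*9/2 = 45` — the numerical signature of the X-shaped line pattern an
inversion produces between two aligned maps:

```r
r2 <- res$regions[[2]]
o2o <- r2$links[r2$links$link_type == "ortholog_one2one", ]
crossing_count(o2o, sim$source, sim$targets[[2]])
#> [1] 45
```

Draw the bundled six-map integration recipe (private QTL linkage map,
published linkage map, two sequence-hit bridge maps, two gene-annotated
assemblies in four virtual columns):

```sh
Rscript exec/synmapr draw inst/extdata/demo/layout.json \
    inst/extdata/demo/map*.txt --out fig.svg
```

Identity links (shared accessions) appear purple, synonymy links (shared
names) sky-blue; lines only join maps in adjacent columns.  Other
subcommands: `convert` (text/XML/GFF3/BED), `link`, `synteny`, `epcr`,
`simulate` — run `Rscript exec/synmapr` for usage.

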