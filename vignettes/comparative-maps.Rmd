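---
title: "Aligning genetic and genomic maps: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning genetic and genomic maps: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmapr)
```

# The problem

Interpreting mapping data for a poorly characterised species usually means
borrowing structure from a well-annotated one: a QTL interval on a salmon
linkage map becomes useful once its markers can be traced — through shared
identifiers, shared names, sequence hits, and asserted gene homologies —
to an annotated assembly of a model species, where candidate genes can be
read off.  The obstacle is that the maps involved live in incompatible
coordinate systems: linkage maps in centimorgans (recombination distance),
assemblies in base pairs, other analyses in arbitrary units.

`synmapr`'s model deliberately refuses to unify these coordinates.  Every
`genome_map` is a self-contained axis for one chromosome or linkage group
of one species — id, species, chromosome, units (`bp`, `cM`,
`arbitrary`), an optional assembly tag, an extent `[min, max]`, and a
table of markers.  Maps relate to each other only through *typed links
between markers*, never through coordinate conversion.  This mirrors how
the integration is actually reasoned about at the bench: marker X here is
the same object as marker X there; everything else is a drawing problem.

## Markers and their invariants

A marker is a named feature at a point (`start == end`) or range on one
map, optionally carrying a stable accession, a strand and a kind (`gene`,
`variant`, `microsatellite`, `sequence`, `assembly_exception`,
`generic`).  Coordinates are real-valued so one model serves integer bp
and decimal cM; bp maps use the 1-based, both-ends-inclusive convention of
the major genome databases.  Marker order within a map is canonicalised by
`(start, end, name)` on construction, so writers are deterministic and
output files diff cleanly.

One invariant needs explaining: `validate_map()` requires every marker to
*intersect* the map extent, not to be contained in it.  Zooming
(`subregion()`) keeps markers that straddle the region boundary at their
original coordinates — clipping them would falsify data on export, and the
renderer clips visually anyway — so a zoomed map can legitimately hold a
marker whose range overhangs the extent.  Requiring containment would have
made zoom outputs invalid; requiring intersection keeps every operation's
output valid without data loss.  A related edge: constructing a map from a
single point marker with no explicit extent would give a zero-width
extent, so the constructor widens `extent_max` by one unit.

`reorient()` reflects markers about the extent midpoint and swaps
`forward`/`reverse` strands; it is an involution, and zoom commutes with
it (zooming the reflected interval after reorienting retains the same
marker set at the same extent-relative positions).

# File dialects

Three map formats are supported, plus two one-way annotation imports.

**Plain text** — maps are, at their simplest, lists of mappable objects on
an arbitrary axis, and the text dialect says no more than that:

```
#map chr26 salmon cM
#id my_map
#extent 0 60
mk1  0.0
geneX  100  250  -  gene  ENSG0001  an optional description
```

Columns are `name start [end] [strand] [kind] [accession]
[description...]`; `end` is recognised by being numeric, so a missing end
makes a point marker; `.` in the accession column means absent.  Names and
accessions must be whitespace-free.

**Interchange XML** — a nested `mapset → species → map → marker` document
for multi-map files.  The historic genomic-mapping-data schema this role
was modelled on is not publicly printable, so the dialect here is a
minimal compatible one ("GMD-like", not claimed identical), documented by
the reader/writer in `R/formats-xml.R`.  Both dialects round-trip exactly
(`read(write(x)) == x`), which the suite checks on random fixtures.

**GFF3 / BED** — one-way imports via `rtracklayer`, which owns the
grammar and coordinate conventions (BED's 0-based half-open intervals
arrive 1-based inclusive).  `read_gff3_genes()` takes features of type
`gene` on one landmark; marker name is the `Name` attribute falling back
to `ID`, accession is `ID`; the extent comes from the `##sequence-region`
pragma when present.

**Homology tables** are TSVs with the seven fixed columns `gene_a,
species_a, gene_b, species_b, homology_type, perc_identity,
perc_similarity`, mirroring Compara-style homology exports.  Records are
unordered pairs; `lookup_gene()` finds a record whichever column holds the
queried accession.  The six homology types are the standard
orthology-pipeline vocabulary (`ortholog_one2one`,
`apparent_ortholog_one2one`, `ortholog_one2many`, `ortholog_many2many`,
`possible_ortholog`, `paralog`).  Rows with `perc_similarity <
perc_identity` are rejected at read time.

# Relationships

Link discovery is all-pairs and case-sensitive.  Case-sensitivity is a
deliberate conservatism: accessions are case-significant in the source
databases, and silently case-folding names would manufacture false
synonymy — sharing a name is already the weakest evidence class.  When a
marker pair shares both accession and name, only the identity link is
reported: it is the stronger statement, and drawing both would paint two
coincident lines.

Score thresholds (`filter_links()`) apply to homology links only — they
exist to raise the stringency of homology *reporting*, whereas identity
and synonymy carry no scores to threshold.  A homology link lacking a
score fails any active threshold; the alternative (letting scoreless links
through) would make raising a threshold ADD links relative to intent.
Absent thresholds pass everything unchanged, and link counts are monotone
non-increasing in each threshold — both properties are tested.

Colours come from the Okabe–Ito colour-universal-design palette so all
eight link types stay distinguishable for colour-blind readers: identity
purple `#CC79A7`, synonymy sky-blue `#56B4E9`, one-to-one orthology black,
apparent one-to-one vermilion, one-to-many orange, many-to-many
blue-green, possible orthology blue, paralogy yellow.  The guideline
source names the colours but no hex values; the standard Okabe–Ito codes
are used.  User palettes may override per type.

# Conserved synteny and inversions

`find_conserved_regions()` walks the gene markers of a source region,
collects their homology records towards a target species, locates the
matched target genes on the supplied target maps, and groups hits by
target chromosome.  Each hit chromosome yields one region spanning
`[min, max]` of its located genes, carrying one link per homology record
used and the count of distinct contributing source genes; regions are
ranked by that count (chromosome label breaks ties).  Two consequences of
the design:

* **No block rules.**  No minimum gene count or collinearity requirement
  defines a "block of conserved synteny" — the relationships displayed
  derive from analyses conducted elsewhere, and a single-gene hit is still
  reported (ranked last).  Callers threshold on `source_gene_count`.
* **One region per chromosome.**  If two separate clusters of homologues
  sat on one target chromosome they would merge into one wide span.  At
  the region sizes this tool is used at (and in its fixtures) that has not
  mattered; splitting multi-modal spans is future work.

Target genes asserted in the table but absent from every target map go to
a skipped-genes report instead of failing the search — the table routinely
knows more genes than the loaded maps.

The **crossing count** makes "the lines cross" assertable: for links
`i, j` with endpoint midpoints `a, b` on the two maps, the pair crosses
iff `sign(a_i - a_j) != sign(b_i - b_j)`.  Ties (equal midpoints) count as
discordant by this literal rule, which is why the linkage-map simulator
avoids manufacturing ties (below).  Preserved gene order gives 0; complete
inversion of `k` links gives `k(k-1)/2`.

`transfer_markers()` copies markers between maps that share units *and*
assembly tag — the guard exists because copying coordinates between
different assemblies or unit systems is exactly the error the per-map
coordinate model is designed to prevent.

# ePCR bridge maps

Primer pairs from historic genotyping panels can be located on a modern
assembly to bridge a linkage map onto it.  A hit requires the forward
primer to match exactly, the reverse primer's reverse-complement to match
*strictly downstream* on the same strand (primer sites must not overlap),
and the 1-based inclusive span from the first base of the forward match to
the last base of the reverse-complement match to lie within the pair's
product bounds; both pair orientations are tried.  Matching is exact — the
historic maps were built with exact-search tooling plus unique-hit
curation, and exactness keeps the independent test oracle a transparent
position scan.  Mismatch tolerance is a non-goal.

Curation mirrors the historic filter: hits are counted genome-wide; pairs
with zero hits (`no_hit`) or two or more (`multiple_hits`) are discarded,
and a pair whose single hit falls on a sequence whose name matches the
unplaced pattern (default `scaffold|contig|random|Un`; the rule was never
defined programmatically in the original, so it is a configurable regex)
is discarded as `unplaced`.  Survivors become range markers (kind
`sequence`, accession = pair name) on a per-sequence bp map.  Sequence
matching is delegated to `Biostrings::matchPattern`; the hit *rule* is
package code, verified against a pure-R scan of every position.

# Layout and rendering

Placements give each map a box (`x, y, width, height`), a view window in
map units, a flip flag and a label mode.  *Virtual columns* are the
connected components of horizontal overlap between visible placements —
closed intervals, so boxes that merely touch share a column (deterministic
under exact arithmetic on file-specified layouts), transitively since a
column may contain several stacked maps.  Components are ordered by
minimum x (centroid ordering was the other candidate; minimum x is stable
under resizing a map's lower edge).  Links are drawn only between maps in
*adjacent* columns — the layout, not the link set, controls what is
visible — and a link anywhere else is a contract violation, not a silent
drop; the only silent drops are links to hidden maps or to markers outside
the view window, which are clips.

The map→canvas transform is linear interpolation of the view window onto
the vertical box span (reversed when flipped); the inverse round-trips to
within 1e-9 relative tolerance over random windows spanning micro-units to
megabases, and the window endpoints map exactly to the axis ends.  Marker
labels are horizontal; a greedy top-down sweep nudges each label just
below the previous box when they would overlap, dropping (and counting)
labels pushed past the axis bottom — greedy rather than optimal because it
is deterministic, linear, and matches the stacked-label look of the
original displays.  `linked_only` mode labels only markers carrying at
least one link, the standard trick for decluttering a large annotated
assembly aligned to a sparse query map.

Rendering is split into `build_scene()` (model → flat primitive tables,
every primitive carrying its source identifiers) and `render_svg()`
(primitives → SVG 1.1 with fixed element order and a fixed three-decimal
coordinate format).  Identical scenes therefore produce byte-identical
files — the property that makes graphics testable — and `svg_tally()`
parses a document back into primitive counts for comparison against the
model.  Axis ticks use the largest step of the form 1/2/5 × 10^k giving
4–10 ticks in view (no tick rule was inherited, so the conventional one is
used).  Orientation glyphs are up/down triangles for forward/reverse
features; glyph geometry is cosmetic and fixed in `R/render.R`.  Straight
link lines (not ribbons) match the original displays; PDF/PNG export would
be SVG conversions and are out of scope here.

# The synthetic world

All fixtures are generated, seeded and pure: `simulate_genome_pair()`
emulates the structure the comparative workflows assume — consecutive runs
of source genes forming collinear or inverted orthologous blocks on named
target chromosomes, one2one records scored with identity ~ Uniform(60, 95)
percent and similarity = identity + Uniform(0, 5) (typical of
within-vertebrate orthologue pairs; values are a stated choice, not
fitted), plus a 10% fraction of extra `paralog` records as noise.  Gene
lengths are drawn 1–50 kb and placed without overlap by rejection.
`simulate_linkage_map()` maps physical midpoints to cM at 1 cM/Mb (the
classical vertebrate average) plus Gaussian jitter (default 0.5 cM),
clamped monotone non-decreasing *along the physical midpoint order* —
recombination distance cannot run backwards, and clamping in any other
order would manufacture spurious crossings.  `simulate_genome_fasta()`
implants primer amplicons into uniform-random ACGT background; with
20-mers the chance background hit rate is negligible, and the released
seeds are additionally verified hit-free once and pinned.

What the generators do **not** emulate: sequence evolution, gene gain and
loss, translocation mosaic, scored homology ambiguity (one2many tangles),
or assembly error.  A green synteny-recovery test therefore establishes
that the search correctly inverts the generator's planted structure — not
that real orthology tables are this clean.  The bundled six-map demo
(`inst/extdata/demo`, seed 42, regenerable byte-identically by
`write_demo_recipe()`) exercises the four-column integration topology:
private linkage map, published linkage map, two bridge maps sharing names
with it, and two assemblies sharing accessions with the bridges.

# Numerical and degenerate-input choices

* Coordinates serialise as plain decimals with up to 15 significant
  digits; fixture coordinates carry at most 6 decimals, so text and XML
  round-trips are exact.
* Canvas geometry serialises at fixed 3 decimals for byte stability.
* Ties in crossing counts are discordant (literal sign rule).
* Empty link sets, empty maps (explicit extent required), zero-marker
  zoom results, and header-only homology tables are all legal values, not
  errors; the errors that remain (range, schema, validation, usage) carry
  typed condition classes.
* The CLI maps usage errors to exit status 2 and runtime failures to 1;
  data goes only to files, logs to standard error.

# Known limitations

Multi-chromosome containers, live database connectivity, variation-map
download, fuzzy name matching, mismatch-tolerant ePCR, ribbon rendering
and interactive manipulation are explicit non-goals; the layout JSON file
replaces direct manipulation.  Homology is consumed, never predicted.
Overlapping target spans from distinct source sub-regions merge into one
region per chromosome, as discussed above.
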