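---
title: "Discovering and quantifying satellite DNA from low-coverage shotgun reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and quantifying satellite DNA from low-coverage shotgun reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satkit)
library(dplyr)
```

## The problem

Satellite DNAs are long arrays of tandemly repeated, head-to-tail monomers,
usually parked in pericentromeric heterochromatin. Because a satellite family
can occupy anywhere from a hundredth of a percent to ten percent of a plant
genome, even very shallow genome skimming (a few percent coverage of
single-end reads) samples each abundant family thousands of times. satkit
implements the classic graph-based route from such a read set to a
characterised satellite:

1. **Cluster** reads by sequence similarity: reads are vertices, and an edge
   joins two reads whose best local alignment (either strand) reaches an
   identity threshold over a minimum fraction of the shorter read. Connected
   components of this graph are repeat clusters; a cluster's share of all
   quality-filtered reads estimates its family's genome proportion.
2. **Detect** satellites among the large clusters. Reads from a tandem array
   wrap around the repeat's circular coordinate system, so (a) a greedy
   k-mer walk over the cluster's k-mer spectrum closes into a circle, and
   (b) nearly all cluster reads align back to that circular consensus. Both
   conditions together make the satellite call; cluster graph density is
   reported as supporting evidence but is not decisive.
3. **Reconstruct** the consensus monomer by k-mer frequency: starting from
   the most frequent k-mer, repeatedly append the base whose successor k-mer
   is most frequent; a closed walk of length L is the circular consensus
   monomer. A per-position base-frequency profile (sequence logo) is built
   by re-aligning reads to the doubled consensus.
4. **Annotate** the monomer: GC content, perfect and single-substitution
   telomeric hexamers (TTAGGG) in circular coordinates, CAAAA
   pentanucleotides, A4 tracts, and in-silico restriction ladders for the
   isoschizomer pair BstNI (CCWGG, methylation-insensitive) and ScrFI
   (CCNGG, blocked by internal cytosine methylation). Tandem arrays digest
   to a monomer-length band and its multiples; comparing the two enzymes'
   ladders is a computational methylation assay.
5. **Quantify**: genome proportion p (%), copies per 1C genome N, monomer
   length L (bp), and 1C genome size G (pg) are linked by
   `p = 100 * N * L / (G * 978e6)`, with 978 Mbp/pg the standard C-value
   conversion. The same module calibrates slot-blot signal tables (standard
   dilution series fitted through the origin) and compares hybridisation-
   and read-count-based estimates, flagging the satellite
   under-representation that low-coverage 454 libraries are known to show.
6. **Compare** monomer variants: ends-free pairwise identities,
   within/between-group ranges, and distance-matrix export (PHYLIP, NEXUS)
   for external split-network software.

## A worked run on simulated data

```{r pipeline}
fams <- list(satellite_family("sat", monomer = synthetic_monomer(),
                              copies_per_1C = 200, locus_count = 2,
                              divergence = 0.02))
disp <- list(dispersed_family("disp", element_length = 3000, copies = 6))
g <- build_genome(genome_spec(250000, fams, disp, seed = 101))
reads <- shear_reads(g, coverage_fraction = 0.3, read_length_mean = 350,
                     read_length_sd = 50, substitution_error = 0.005,
                     seed = 102)
run <- run_pipeline(reads, pipeline_config(), genome_pg = 6.27)
run$clusters |> select(cluster_id, size, proportion_pct, classification,
                       monomer_length)
```

```{r annotate}
sat_id <- run$clusters$cluster_id[run$clusters$classification == "satellite"][1]
mono <- run$monomers[[sat_id]]
glance(scan_motifs(mono))
```

## The synthetic-data generator

The generator is first-class, tested code, and its defaults encode the study
conditions the pipeline targets: single-end 454-style reads of mean 350 bp
(SD 50 bp, truncated at 50 bp), uniform start positions on a random strand,
~2.2% genome coverage by default, and genomes assembled from (i) tandem
satellite arrays of a ~249 bp monomer at 44% GC with per-copy divergence,
(ii) dispersed element families, and (iii) single-copy background. Per-copy
divergence of 2% reproduces the mid-90s% pairwise copy identities typical of
a homogenised satellite family. Slot-blot tables follow a linear signal
model with multiplicative log-normal noise of configurable CV; the detector
gain is unobservable and cancels in calibration.

What the generator does **not** emulate: 454 homopolymer error spectra are
reduced to an optional per-homopolymer ±1 event (off by default); there is
no chromosome geography (FISH-scale structure), no library-preparation bias
against satellites (so NGS and slot-blot estimates agree on simulated data
and the under-representation flag stays quiet), and no higher-order
chromatin effects on digestion. Passing tests therefore demonstrate
correctness of the algorithms under the stated read model, not robustness to
every 454 artefact.

Because the deposited monomer clones cannot be bundled, the package ships a
**synthetic** 249-bp monomer (`synthetic_monomer()`) engineered to carry the
reported feature profile -- 44% GC, seven perfect telomeric hexamers (one
dimer), exactly five single-substitution telomeric variants, three CAAAA,
four A4 tracts, a single BstNI/ScrFI site, and a degenerate two-sub-repeat
backbone -- plus a synthetic 66-clone set (`synthetic_clone_set()`) with 51
full-length clones and the reported short/long length spectrum. These are
labelled synthetic throughout; results computed on them characterise the
pipeline, not the natural sequences.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `k` | 25 bp | consensus walk k-mer length; toy problems use 11-17 |
| `min_identity_pct` | 90 | edge threshold over the aligned region |
| `min_overlap_fraction` | 0.55 | of the shorter read |
| `min_cluster_proportion_pct` | 0.01 | reporting cut, strict (">") |
| `satellite_mapping_fraction` | 0.80 | read-mapping threshold for the satellite call |
| `mbp_per_pg` | 978 | C-value conversion |
| `seed_k` | 12 bp | shared-k-mer candidate seeding |

The edge thresholds are exposed decisions, not published constants: 90%/55%
follow the parameterisation customary for 454-read repeat clustering.
`seed_k = 12` is deliberately much shorter than the consensus `k`: two reads
overlapping at the 90% identity threshold share a 12-mer with overwhelming
probability, so seeding does not lose edges relative to exhaustive all-pairs
alignment (asserted against that oracle in the tests), while unrelated reads
rarely collide.

## Numerical and design choices

- **Tie-breaking**: successor-count ties in the k-mer walk append the
  alphabetically first base; together with fixed seeds this makes every
  output byte-reproducible (each table carries a config hash).
- **Count floor**: a walk extends only while the best successor count is at
  least `max(2, 1%)` of the starting k-mer's count; otherwise it ends open.
  Open walks are never called satellites.
- **Canonical form**: closed monomers are reported as the lexicographically
  smallest rotation over both strands, so any rotation or strand of the same
  circular sequence yields the identical consensus.
- **Secondary monomers**: after a closed walk its k-mers are removed and the
  walk restarts if the next most frequent k-mer retains at least 10% of the
  first start count, surfacing co-clustered satellites.
- **Identity convention**: monomer comparisons use ends-free global
  alignment (match +1, mismatch -1, gap -2 per base) with identity over the
  aligned columns excluding terminal overhangs, so truncated clones compare
  sensibly against full monomers; sequences are rotation/strand-normalised
  against a reference monomer first, because origin offsets in a circular
  repeat would otherwise masquerade as divergence.
- **Counting conventions**: motif occurrences are sliding-window counts with
  overlap allowed and circular wrap counted once; an "imperfect" telomeric
  repeat is a hexamer at Hamming distance exactly 1 from TTAGGG (the
  original visual criterion is unstated, so this is a documented definition,
  and both-strand counts are reported alongside top-strand counts);
  "proportion exceeding the cut" is strict.
- **Digestion**: cuts fall after position 2 of the recognition site
  (CC^WGG); only the relative ladder structure matters, and fragment lengths
  always sum to the array length.
- **Denominator convention**: genome proportions divide by the
  quality-filtered read count. The filter itself (length >= 100 bp,
  N-fraction <= 2%) is a configurable default, since published filtered
  counts rarely state their criteria.
- **Periodicity**: the support of lag d is the fraction of window offsets
  whose d-shifted window matches at the given stringency; the primary period
  is the smallest lag reaching the support floor (0.5) at the high
  stringency (85% over 15 bp windows), which for a tandem array equals the
  monomer length; sub-repeat structure is read from the low-stringency pass
  (60%). Dot-plot stringencies are decisions -- the original figures print
  none.

## Problem sizes

The bundled tests and the acceptance script run simulations sized to finish
comfortably on one CPU: pipeline runs use a 250 kb genome with a 200-copy
array (~20% satellite) at 30% read coverage (~200 reads), classifier
calibration uses 16 planted satellite and 16 dispersed clusters at >= 50x
monomer coverage, noiseless-recovery checks span 100 random monomers of
20-1000 bp, and Monte-Carlo checks use 500-1000 replicates. These sizes are
the package's own choices; all scale linearly if larger studies are needed.

## Known limitations

- Clusters are connected components; two families bridged by a chimeric
  read merge (optional modularity splitting is not implemented).
- One consensus per cluster is primary; subfamily structure within a cluster
  is out of scope beyond secondary-walk reporting.
- The read-count proportion slightly overweights reads straddling array
  boundaries; this vanishes when arrays are long relative to reads, as real
  satellite arrays are.
- Identity matrices are quadratic in clone count; fine for tens of clones,
  not thousands.
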