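---
title: "Building and mining disease knowledge networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and mining disease knowledge networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dknet)
```

## The model

`dknet` represents heterogeneous disease biology as a typed property graph
built from a protein-centric perspective. Seven node labels — `Protein`,
`Disease`, `Pathway`, `Tissue`, `Drug`, `GEOStudy` and `GEOComparison` — are
joined by sixteen relationship types (see `EDGE_SCHEMA`): curated
protein–disease associations (`BIOMARKER`, `GENETIC_VARIATION`,
`THERAPEUTIC`, `KANEKO_ASSOCIATED`), pathway membership (`IN_PATHWAY`),
protein–protein relations (`PPI_ASSOCIATION`, `PPI_COLOCALIZATION`,
`PPI_GENETIC_INTERACTION`, `SEQ_SIM`), tissue-enhanced expression
(`TISSUE_ENHANCED`), drug relations (`DRUG_TARGET`, `DRUG_ENZYME`,
`DRUG_TRANSPORTER`, `DRUG_CARRIER`) and transcriptomics provenance
(`DEG_RELATED_TO`, `PART_OF`).

Every node is unique per (label, natural key): proteins are keyed by UniProt
accession (uppercased and whitespace-stripped on ingest), diseases, tissues,
studies and drugs by name/identifier, pathways by stable identifier with the
name kept as a property. A `GEOComparison` is keyed `"study::groupA-groupB"`:
comparison labels such as `NC-SA` recur across series, so scoping the key by
study realizes a protein/comparison/study *triple* deduplication rule for
differential-expression edges inside an ordinary pairwise edge store.

Edges deduplicate on (type, endpoint pair); the four protein–protein types
are undirected and canonicalize `(A,B)` and `(B,A)` to a single stored edge.
All other types are stored with their biological direction, but every
traversal operation ignores direction — biologically meaningful paths mix
orientations (protein→disease next to protein–protein hops).

Repeated upserts merge rather than duplicate: new property names are added,
set-valued properties (`methods`, `ensembl_ids`) take the sorted union,
`confidence` keeps its maximum, and conflicting scalar values keep the first
value seen with a warning. The sort-on-union rule is what makes imports
order-independent: permuting upserts yields an identical store. These
policies are a deliberate design choice; the only hard requirement we take
as given is that duplicates must never accumulate, and keep-first plus an
explicit warning makes conflicting source values visible instead of silently
last-writer-wins.

## The sequence-similarity layer

`derive_seqsim()` turns an all-vs-all BLAST hit table into undirected,
scored `SEQ_SIM` edges. An unordered pair (A, B) survives iff

* hits exist in **both** directions (reciprocal hits),
* each directional e-value satisfies `e <= evalue_max` (default `1e-5`), and
* each direction passes the coverage filter
  `r = L / min(len_query, len_subject) > ratio_min` (default `0.60`,
  strict).

The edge score is `s = -log10((e_ab + e_ba) / 2)`. Numerical choices:
e-values reported as exactly `0` are clamped to `1e-180` before averaging
(so a doubly-exact-zero pair scores 180 rather than `Inf`); when several
HSPs exist for one direction, the smallest e-value among those passing the
filters is used; at the default thresholds every surviving score is at least
`-log10(1e-5) = 5`. We apply the coverage ratio **per direction** (both
directions must pass individually) and read "above 0.60" as a strict
inequality — the symmetric, conservative reading; a pair at exactly
`r = 0.60` is excluded.

## Importers

Each importer parses one source layout, applies its filtering rules, and
populates the graph exclusively through the upsert layer, so re-running any
import is a no-op on `kg_stats()`. Each returns an `import_report` with
`records_read = records_kept + records_skipped` and per-reason skip counts
(unmapped identifier, failed filter, unknown category, malformed row) —
silent data loss is never acceptable in knowledgebase construction.

Identifier handling: `load_id_mapping()` builds a case-insensitive multimap
(gene symbol or ENSEMBL id to one *or several* accessions; a symbol mapping
to two accessions fans out to two edges). When an importer is given no
mapping, gene identifiers are taken to be accessions as-is. PSI-MITAB rows
route on the interaction-type term by case-insensitive substring — "genetic
inter*" before "colocalization" before "association" (which also catches
"physical association") — and rows with any other term are skipped with a
counted reason rather than mis-typed.

The differential-expression importer keeps genes with `adj_p < adjp_max`
(default 0.05, strict, configurable — a conventional significance cut for
limma-style adjusted p-values); values outside [0, 1] are counted as
malformed, not silently clamped.

The curated respiratory gene list maps its four categories (BA, COPD, TB,
E-HTN) onto the same `Disease` nodes used by the DisGeNET-style import via
`KANEKO_CATEGORY_MAP`. Sharing disease nodes while keeping a distinct edge
type lets the two sources be compared side by side with the same query,
selected purely by `edge_types`.

## Query patterns

* `shared_disease_proteins()` — proteins carrying an allowed association to
  both diseases; symmetric, sorted output.
* `deg_disease_pathway_context()` — the conjunction: differentially
  expressed in *every* listed comparison, member of at least one pathway
  whose name contains a substring (case-insensitive; `"signal"` selects
  signalling pathways — configurable because exact pathway nomenclature
  varies between releases), and associated with at least one listed disease.
  Returns the witnessing subgraph only.
* `drugs_via_seqsim()` — the repurposing pattern drug → target — similarity
  — biomarker → disease, with an optional score floor and a flag (or
  filter) for drugs that also target the biomarker directly.
* `bounded_all_shortest_paths()` — per source, *all* simple shortest paths
  to the target if the shortest length is within `max_len`, else nothing.
  "Paths of length < 4" is realized as `max_len = 3` with length counted in
  edges. A source equal to the target yields one zero-length path.
  `shortest_paths_between_sets()` unions per-pair results and counts a path
  and its reverse once.

Traversal defaults to `TRAVERSAL_EDGE_TYPES` (curated membership plus the
protein–protein relations) — the relation classes along which a
protein-to-disease chain remains interpretable — and is fully configurable.

Implementation notes. Shortest paths are enumerated by a breadth-first
distance labelling from the target followed by a strictly
distance-decreasing depth-first walk, which guarantees simplicity and
minimality by construction; results are ordered lexicographically by
node-key sequence for determinism. A path is identified by its node
sequence; when several allowed edge types join the same consecutive node
pair, the edge with the lexicographically smallest type is recorded as the
hop's witness rather than multiplying the path per parallel relationship
(a graph-database `allShortestPaths` would return one path per
relationship combination; we found the node-sequence view the more useful
unit for biological reading, and the parallel types remain queryable via
`kg_neighbors()`).

## Synthetic data and the demo network

Because the original external snapshots (UniProt, IntAct, DisGeNET,
DrugBank, HPA, GEO) are neither redistributable nor reproducible at desk
scale, testing rests on two legs.

First, deterministic generators: `make_random_kg()` draws background graphs
at configured per-type densities and plants ground-truth motifs on dedicated
nodes the background never touches — shared-protein pairs, drug/similarity
triples, and chains whose minimality is re-verified by an independent BFS
before the manifest is returned. `make_blast_table()` emits reciprocal,
one-directional, ratio-failing and boundary hit classes (e-value exactly at
threshold, exactly zero, coverage exactly at the cut-off) with an
independently re-evaluated survivor manifest. `make_deg_tables()` emulates
limma-style adjusted-p summaries with a planted cross-study overlap. All
generators are pure functions of (seed, configuration); synthetic accessions
(`SYN*`) avoid implying real biology.

Second, `demo_asthma_kg()`: a small literature-anchored asthma network built
through the package's own importers. It carries the published cross-disease
membership sets verbatim; the full curated gene list itself is not
redistributable, so `kaneko_synthetic_table()` pads those real memberships
with synthetic accessions to the published category sizes (104/58/35/54,
219 distinct genes, 251 memberships — including one synthetic COPD/TB
overlap that balances the distinct-gene count exactly). The circadian-clock
neighbourhood encodes the published three-step path families around the
Asthma node; where the literature names only path endpoints, intermediate
hops are typed `PPI_ASSOCIATION`, and where it names no intermediate at all
(the PER1 and REV-ErbA-alpha bridges) synthetic `SYNP*` proteins are used.
The drug layer is the Tenecteplase→KRT8(P05787)~KRT19(P08727)→Asthma motif
plus a non-matching distractor.

What passing tests on these fixtures shows — and what it does not: the
generators exercise every filter boundary and the planted-recovery logic,
but their degree distributions are homogeneous, identifiers are synthetic,
and no fixture approaches the size or the annotation noise of real 2015-era
database snapshots. Absolute occurrence counts of such snapshots are
therefore out of scope; correctness is argued through exact worked examples
plus property-based equivalence with independent oracles (pairwise filter
enumeration; exhaustive simple-path search; igraph distances).

## Problem sizes and budgets

The test suite checks the similarity derivation against its brute-force
oracle on tables of up to a few hundred accessions and ~10^3–10^4
directional hits, and the traversal against exhaustive enumeration on 100
seeded random graphs of at most 50 nodes with `max_len = 3` — sizes chosen
so that the exhaustive oracles themselves remain exact and fast while still
covering every boundary class. The acceptance script repeats both
equivalence studies from scratch at the same scale.

## Known limitations

* The store is in-memory and single-writer; there are no transactions and
  no query language — the query patterns are R functions.
* MITAB parsing covers the 2.5 tab layout needed here (identifier columns,
  detection method, interaction type, confidence), not the full PSI-MI XML
  model.
* DrugBank ingestion expects the flat CSV layout (drug, accession,
  category); XML is out of scope.
* Traversal treats all edges as unit length; there is no weighted variant.
* `kg_validate()` is a full-rescan invariant check intended for tests and
  post-build assertions, not a cheap runtime guard on every operation.
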