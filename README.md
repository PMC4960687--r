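# dknet — disease knowledge networks as typed property graphs

Systems-medicine questions rarely live in one database: a candidate gene's
interpretation depends on the diseases it is curated for, the pathways and
tissues it acts in, the drugs that target it or its sequence-similar
relatives, and whether it turns up differentially expressed in relevant
cohorts. `dknet` is an R toolkit for assembling exactly this kind of
heterogeneous evidence into a single typed property graph and mining it with
the query patterns used in disease-network studies. It is aimed at
bioinformaticians who want a graph-database-style workflow — schema, natural
keys, duplicate-free ingestion, traversal queries — as plain, testable,
offline R, with Neo4j-compatible exports when a database server is wanted.

## The model in brief

Nodes carry one of seven labels (`Protein`, `Disease`, `Pathway`, `Tissue`,
`Drug`, `GEOStudy`, `GEOComparison`) and are unique per (label, natural
key) — UniProt accessions for proteins, `"study::groupA-groupB"` keys for
expression comparisons. Sixteen relationship types connect them (curated
disease associations, pathway and tissue membership, drug relations,
protein–protein interaction and sequence similarity, expression provenance);
the protein–protein types are undirected and stored once per unordered
pair. All ingestion goes through deduplicating upserts, so any import run
twice is a no-op.

The sequence-similarity layer is derived from all-vs-all BLAST output: an
unordered pair (A, B) becomes a `SEQ_SIM` edge iff hits exist in both
directions, both e-values pass `e ≤ 10⁻⁵`, and both directions satisfy the
coverage filter `r = L / min(len_A, len_B) > 0.60`; the edge score is

```
s = −log10((e_AB + e_BA) / 2)
```

with exact-zero e-values clamped to 10⁻¹⁸⁰.

Four query patterns operate on the graph, ignoring edge direction:

* `shared_disease_proteins()` — proteins associated with two diseases;
* `deg_disease_pathway_context()` — genes differentially expressed in every
  listed comparison, restricted to matching pathways and diseases;
* `drugs_via_seqsim()` — drug → target —similarity— biomarker → disease
  repurposing leads;
* `bounded_all_shortest_paths()` / `shortest_paths_between_sets()` — all
  simple shortest paths within a length bound (length counted in edges).

## Worked example

The package ships a small literature-anchored asthma network,
`demo_asthma_kg()`, built entirely through its own importers (curated
respiratory-disease gene memberships, gene–disease associations, a
circadian-clock neighbourhood, a drug-similarity motif, and three GEO
asthma series with three comparisons each).

```r
library(dknet)
g <- demo_asthma_kg()
g
#> <knowledge_graph: 261 nodes, 306 edges>

# proteins curated for both asthma and essential hypertension
shared_disease_proteins(g, "Asthma", "Hypertension, Essential",
                        edge_types = "KANEKO_ASSOCIATED")
#> [1] "P04040" "P07550" "P12821" "P29474" "P30711"

# shortest paths (at most 3 edges) from clock genes to the Asthma node
paths <- bounded_all_shortest_paths(g, c("Q99743", "O15534"), "Asthma",
                                    max_len = 3)
paths[["Q99743"]][[1]]
#> <path> Q99743 -[PPI_ASSOCIATION]- P67870 -[PPI_ASSOCIATION]- Q9UIL8 -[KANEKO_ASSOCIATED]- Asthma
length(paths[["O15534"]])   # PER1 does not lie within 3 steps
#> [1] 0

# drugs whose target is sequence-similar to an asthma biomarker
drugs_via_seqsim(g, "Asthma")
#>           drug target biomarker seqsim_score direct_target_of_biomarker
#> 1 Tenecteplase P05787    P08727          100                      FALSE
```

The five accessions are the NOS3, catalase, ACE, ADRB2 and
glutathione-S-transferase proteins shared by the two curated disease lists; the path output reads as NPAS2
reaching the Asthma node through two interaction hops and one curated
association; and the single drug lead is the indirect
Tenecteplase–KRT8–KRT19–asthma link (the drug's known target P05787 is
sequence-similar to the asthma biomarker P08727, which it does not target
directly).

Graphs are built from files with a declarative config (`run_build()`),
dumped and reloaded losslessly as JSON-lines (`kg_write_jsonl()` /
`kg_read_jsonl()`), and exported to GraphML, Neo4j bulk-import CSVs or a
Cypher MERGE script (`export_graph()`). A thin command-line wrapper lives at
`inst/cli/dknet.R`:

```sh
Rscript inst/cli/dknet.R query graph.jsonl shared-proteins \
    --disease-a Asthma --disease-b "Hypertension, Essential" \
    --edge-types KANEKO_ASSOCIATED
```

See `vignettes/disease-knowledge-graphs.Rmd` for the full account of the
schema, merge policies, filter semantics and the synthetic-data design.

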