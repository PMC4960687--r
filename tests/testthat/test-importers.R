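test_that("sequence-similarity derivation applies the reciprocal-hit rules", {
  base <- function(q, s, e, aln, ql, sl)
    data.frame(query_id = q, subject_id = s, evalue = e, aln_len = aln,
               query_len = ql, subject_len = sl, stringsAsFactors = FALSE)

  # one-directional hit yields no edge
  expect_equal(nrow(derive_seqsim(base("A", "B", 1e-6, 90, 100, 100))), 0L)

  # clean reciprocal pair: score is -log10 of the e-value mean
  h <- rbind(base("A", "B", 1e-10, 90, 100, 100),
             base("B", "A", 1e-10, 90, 100, 100))
  out <- derive_seqsim(h)
  expect_equal(out$score, 10.0)

  # asymmetric e-values, direct arithmetic: -log10((1e-6 + 1e-8) / 2)
  h <- rbind(base("A", "B", 1e-6, 90, 100, 100),
             base("B", "A", 1e-8, 90, 100, 100))
  expect_equal(derive_seqsim(h)$score, -log10(5.05e-7), tolerance = 1e-12)

  # exact-zero e-values clamp to 1e-180
  h <- rbind(base("A", "B", 0, 90, 100, 100),
             base("B", "A", 0, 90, 100, 100))
  expect_equal(derive_seqsim(h)$score, 180)

  # boundary: e exactly at the threshold is kept (score 5), ratio exactly
  # at the cut-off is excluded (strict >)
  h <- rbind(base("A", "B", 1e-5, 61, 100, 150),
             base("B", "A", 1e-5, 61, 150, 100))
  expect_equal(derive_seqsim(h)$score, 5.0)
  h <- rbind(base("A", "B", 1e-20, 60, 100, 200),
             base("B", "A", 1e-20, 60, 200, 100))
  expect_equal(nrow(derive_seqsim(h)), 0L)

  # the ratio must pass in BOTH directions
  h <- rbind(base("A", "B", 1e-20, 90, 100, 100),
             base("B", "A", 1e-20, 50, 100, 100))
  expect_equal(nrow(derive_seqsim(h)), 0L)

  # self-hits are discarded
  expect_equal(nrow(derive_seqsim(base("A", "A", 0, 100, 100, 100))), 0L)

  # unknown sequence length is a named validation error
  h <- base("A", "B", 1e-10, 90, NA, 100)
  expect_error(derive_seqsim(h), "A")
  expect_error(
    derive_seqsim(data.frame(query_id = "A", subject_id = "B",
                             evalue = 1e-10, aln_len = 90),
                  lengths = c(A = 100)),
    "B")
})

test_that("derivation agrees with the pairwise oracle on random tables", {
  for (seed in 1:8) {
    hits <- random_hits(seed, n_acc = 10L, n_hits = 120L)
    got <- derive_seqsim(hits)
    want <- oracle_seqsim(hits)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("derivation is invariant to hit order and direction relabelling", {
  hits <- random_hits(99, n_acc = 10L, n_hits = 100L)
  ref <- derive_seqsim(hits)
  set.seed(1)
  shuffled <- hits[sample(nrow(hits)), ]
  expect_equal(derive_seqsim(shuffled), ref, tolerance = 1e-12)
  swapped <- hits
  swapped$query_id <- hits$subject_id
  swapped$subject_id <- hits$query_id
  swapped$query_len <- hits$subject_len
  swapped$subject_len <- hits$query_len
  expect_equal(derive_seqsim(swapped), ref, tolerance = 1e-12)
})

test_that("surviving scores sit above the threshold floor", {
  for (seed in c(3, 14)) {
    out <- derive_seqsim(random_hits(seed))
    if (nrow(out)) expect_true(all(out$score >= 5 - 1e-12))
  }
})

test_that("MITAB import routes interaction types and accumulates evidence", {
  g <- kg_new()
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "#ID(s) interactor A\tID(s) interactor B\t...",
    mitab_row("P05067", "P49768"),
    mitab_row("P49768", "P05067",
              method = "psi-mi:\"MI:0007\"(anti tag coimmunoprecipitation)",
              conf = "intact-miscore:0.82"),
    mitab_row("P05067", "Q06124",
              type = "psi-mi:\"MI:0403\"(colocalization)"),
    mitab_row("P05067", "O00327",
              type = "psi-mi:\"MI:0208\"(genetic interaction)"),
    mitab_row("P05067", "P05067"),
    paste(c("chebi:CHEBI:15377", "uniprotkb:P05067", rep("-", 13)),
          collapse = "\t"),
    mitab_row("P05067", "Q06124",
              type = "psi-mi:\"MI:0407\"(direct interaction)")), path)
  rep <- import_mitab(g, path)
  expect_equal(rep$records_read, 7L)
  expect_equal(rep$records_kept, 4L)
  expect_equal(rep$records_read, rep$records_kept + rep$records_skipped)
  expect_equal(unname(rep$skip_reasons[["unmapped id"]]), 1L)
  expect_equal(unname(rep$skip_reasons[["unrouted interaction type"]]), 1L)
  # duplicated pair collapsed into one edge with both methods, max confidence
  e <- kg_neighbors(g, "Protein", "P05067", "PPI_ASSOCIATION")[[1L]]$edge
  expect_equal(e$properties$methods,
               c("anti tag coimmunoprecipitation", "two hybrid"))
  expect_equal(e$properties$confidence, 0.82)
  st <- kg_stats(g)$edge_counts
  expect_equal(st$n[st$type == "PPI_COLOCALIZATION"], 1L)
  expect_equal(st$n[st$type == "PPI_GENETIC_INTERACTION"], 1L)
  # malformed row: wrong column count reported with its line number
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("uniprotkb:A\tuniprotkb:B\tonly-three-columns", bad)
  expect_error(import_mitab(kg_new(), bad), "line 1")
})

test_that("curated gene-disease import maps symbols and association types", {
  mapping <- load_id_mapping(data.frame(
    id = c("NOS2", "DUAL", "DUAL"),
    acc = c("P35228", "Q00001", "Q00002")))
  g <- kg_new()
  tab <- data.frame(
    gene_symbol = c("NOS2", "NOS2", "DUAL", "UNKNOWN", "NOS2"),
    disease_name = c("Hypertension, Essential", "Hypertension, Essential",
                     "Asthma", "Asthma", "Asthma"),
    association_type = c("Biomarker", "Biomarker", "GeneticVariation",
                         "Biomarker", "SomethingElse"),
    stringsAsFactors = FALSE)
  rep <- import_disgenet(g, tab, mapping)
  expect_equal(rep$records_read, 5L)
  expect_equal(rep$records_kept, 3L)
  expect_equal(unname(rep$skip_reasons[["unmapped id"]]), 1L)
  expect_equal(unname(rep$skip_reasons[["unknown association type"]]), 1L)
  # duplicate row collapsed; two-accession symbol fans out to two edges
  st <- kg_stats(g)$edge_counts
  expect_equal(st$n[st$type == "BIOMARKER"], 1L)
  expect_equal(st$n[st$type == "GENETIC_VARIATION"], 2L)
  nb <- kg_neighbors(g, "Disease", "Hypertension, Essential", "BIOMARKER")
  expect_equal(nb[[1L]]$node$key, "P35228")
})

test_that("curated multi-disease list import handles overlapping categories", {
  g <- kg_new()
  tab <- data.frame(gene = c("P29474", "P29474"), category = c("BA", "E-HTN"),
                    stringsAsFactors = FALSE)
  rep <- import_kaneko(g, tab)
  expect_equal(rep$records_kept, 2L)
  expect_equal(kg_stats(g)$node_counts[["Protein"]], 1L)
  expect_equal(sum(kg_stats(g)$edge_counts$n), 2L)
  expect_error(import_kaneko(kg_new(),
                             data.frame(gene = "X", category = "ILD")),
               "unknown category")
  empty <- import_kaneko(kg_new(),
                         data.frame(gene = character(0),
                                    category = character(0)))
  expect_equal(empty$records_read, 0L)
})

test_that("drug import types edges by relation category", {
  g <- kg_new()
  tab <- data.frame(
    drug = c("Tenecteplase", "Tenecteplase", "DrugX", "DrugX", "DrugX",
             "DrugX", "DrugX"),
    accession = c("P05787", "P05787", "Q00001", "Q00002", "Q00003",
                  "Q00004", "Q00005"),
    category = c("target", "target", "target", "enzyme", "carrier",
                 "transporter", "cofactor"),
    stringsAsFactors = FALSE)
  rep <- import_drugbank(g, tab)
  expect_equal(rep$records_kept, 6L)
  expect_equal(unname(rep$skip_reasons[["unknown relation category"]]), 1L)
  st <- kg_stats(g)$edge_counts
  expect_setequal(st$type[st$src_label == "Protein" & st$dst_label == "Drug"],
                  c("DRUG_TARGET", "DRUG_ENZYME", "DRUG_CARRIER",
                    "DRUG_TRANSPORTER"))
  expect_equal(st$n[st$type == "DRUG_TARGET"], 2L)  # duplicate row collapsed
})

test_that("tissue-enhanced import records FPKM and the ENSEMBL property", {
  mapping <- load_id_mapping(data.frame(id = "ENSG00000171345",
                                        acc = "P08727"))
  g <- kg_new()
  tab <- data.frame(
    ensembl = c("ENSG00000171345", "ENSG00000171345", "ENSG00000000000",
                "ENSG00000171345"),
    tissue = c("esophagus", "skin", "esophagus", "lung"),
    rna_ts_fpkm = c("88.2", "12.5", "3.3", "not-a-number"),
    stringsAsFactors = FALSE)
  rep <- import_hpa(g, tab, mapping)
  expect_equal(rep$records_kept, 2L)
  expect_equal(unname(rep$skip_reasons[["unmapped id"]]), 1L)
  expect_equal(unname(rep$skip_reasons[["malformed row"]]), 1L)
  expect_equal(kg_stats(g)$node_counts[["Tissue"]], 2L)
  e <- kg_neighbors(g, "Tissue", "esophagus", "TISSUE_ENHANCED")[[1L]]$edge
  expect_equal(e$properties$rna_ts_fpkm, 88.2)
  expect_equal(kg_node(g, "Protein", "P08727")$properties$ensembl_ids,
               "ENSG00000171345")
})

test_that("pathway import keys by identifier and keeps the first name", {
  g <- kg_new()
  tab <- data.frame(
    accession = c("P35228", "P35228", "P35228", "P01375"),
    pathway_id = c("R-HSA-1", "R-HSA-2", "R-HSA-3", "R-HSA-1"),
    pathway_name = c("Interleukin signalling", "Innate immunity",
                     "Nitric oxide", "interleukin SIGNALLING"),
    stringsAsFactors = FALSE)
  expect_warning(import_reactome(g, tab), "conflict")
  expect_equal(kg_stats(g)$node_counts[["Pathway"]], 3L)
  expect_length(kg_neighbors(g, "Protein", "P35228", "IN_PATHWAY"), 3L)
  expect_equal(kg_node(g, "Pathway", "R-HSA-1")$properties$name,
               "Interleukin signalling")
})

test_that("differential-expression import builds provenance and filters", {
  g <- kg_new()
  studies <- c("GSE27876", "GSE43696", "GSE63142")
  comps <- list(c("NC", "MiA"), c("NC", "SA"), c("MiA", "SA"))
  tab <- data.frame(gene = c("P35228", "P01375", "Q00001", "Q00002"),
                    adj_p = c(0.003, 0.2, 1.5, "bad"),
                    stringsAsFactors = FALSE)
  for (s in studies)
    for (cp in comps) {
      rep <- import_geo_deg(g, s, cp[1L], cp[2L], tab)
      expect_equal(rep$records_read, 4L)
      expect_equal(rep$records_kept, 1L)
      expect_equal(unname(rep$skip_reasons[["failed filter"]]), 1L)
      expect_equal(unname(rep$skip_reasons[["invalid adjusted p-value"]]), 2L)
    }
  st <- kg_stats(g)
  expect_equal(st$node_counts[["GEOStudy"]], 3L)
  expect_equal(st$node_counts[["GEOComparison"]], 9L)
  expect_equal(st$edge_counts$n[st$edge_counts$type == "PART_OF"], 9L)
  # same gene, same comparison label, different study: distinct edges
  expect_equal(st$edge_counts$n[st$edge_counts$type == "DEG_RELATED_TO"], 9L)
  e <- kg_neighbors(g, "Protein", "P35228", "DEG_RELATED_TO")[[1L]]$edge
  expect_equal(e$properties$adj_p, 0.003)
  cmp <- kg_node(g, "GEOComparison", "GSE43696::NC-SA")
  expect_equal(cmp$properties$group_a, "NC")
})

test_that("id mapping lookups are case-insensitive multimaps", {
  m <- load_id_mapping(data.frame(id = c("KRT8", "krt8", "TWO", "TWO"),
                                  acc = c("P05787", "P05787", "A1", "B2")))
  expect_equal(id_lookup(m, "KrT8"), "P05787")
  expect_equal(id_lookup(m, "two"), c("A1", "B2"))
  expect_identical(id_lookup(m, "absent"), character(0))
  empty <- load_id_mapping(data.frame(id = character(0), acc = character(0)))
  expect_identical(id_lookup(empty, "krt8"), character(0))
})

test_that("every importer accounts for all records and is idempotent", {
  mapping <- load_id_mapping(data.frame(id = c("NOS2", "ENSG1"),
                                        acc = c("P35228", "P08727")))
  bl <- make_blast_table(seed = 5, n_random = 20L)
  runs <- list(
    function(g) import_seqsim(g, bl$hits),
    function(g) import_kaneko(g, kaneko_synthetic_table()),
    function(g) import_disgenet(g, data.frame(
      gene_symbol = c("NOS2", "NOS2", "XX"),
      disease_name = "Asthma",
      association_type = c("Biomarker", "Therapeutic", "Biomarker")),
      mapping),
    function(g) import_drugbank(g, data.frame(
      drug = "D1", accession = c("A1", "A2"),
      category = c("target", "enzyme"))),
    function(g) import_hpa(g, data.frame(
      ensembl = c("ENSG1", "ENSG2"), tissue = "lung",
      rna_ts_fpkm = c(10, 20)), mapping),
    function(g) import_reactome(g, data.frame(
      accession = "P35228", pathway_id = "R-HSA-1",
      pathway_name = "Interleukin signalling")),
    function(g) import_geo_deg(g, "GSE43696", "NC", "SA", data.frame(
      gene = c("P35228", "Q1"), adj_p = c(0.01, 0.9))))
  g <- kg_new()
  for (run in runs) {
    r1 <- run(g)
    expect_equal(r1$records_read, r1$records_kept + r1$records_skipped)
    before <- kg_stats(g)
    r2 <- run(g)   # re-running the importer adds nothing
    expect_identical(kg_stats(g), before)
    expect_equal(r2$records_read, r1$records_read)
  }
  expect_true(kg_validate(g))
})
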