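# Deterministic generators for synthetic source files and the shipped demo
# network, so every importer and query is exercisable without any download.
# Every generator is a pure function of (seed, configuration): identical
# inputs give byte-identical outputs, and planted ground truth is re-verified
# independently before it is returned as a manifest.

#' Configuration for the random knowledge-graph generator
#'
#' @param seed Integer seed; the generator is a pure function of
#'   (seed, configuration).
#' @param n_proteins,n_diseases,n_pathways,n_drugs,n_tissues Node counts for
#'   the random background. Synthetic accessions (`SYN00001`, ...) are used
#'   throughout so no real biology is implied.
#' @param edge_density Named numeric vector of per-edge-type densities in
#'   \[0, 1\] (fraction of legal endpoint pairs receiving an edge); names must
#'   be schema edge types other than the GEO provenance types.
#' @param planted_shared_pairs Number of proteins planted as shared between
#'   two dedicated planted diseases.
#' @param planted_drug_motifs Number of planted drug/target/biomarker
#'   similarity motifs.
#' @param planted_path_lengths Integer vector; for each entry a chain of that
#'   many edges is planted between dedicated endpoint nodes.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_proteins = 30L, n_diseases = 4L,
                         n_pathways = 4L, n_drugs = 4L, n_tissues = 3L,
                         edge_density = c(PPI_ASSOCIATION = 0.05,
                                          SEQ_SIM = 0.05,
                                          BIOMARKER = 0.05),
                         planted_shared_pairs = 0L,
                         planted_drug_motifs = 0L,
                         planted_path_lengths = integer(0)) {
  counts <- c(n_proteins, n_diseases, n_pathways, n_drugs, n_tissues,
              planted_shared_pairs, planted_drug_motifs)
  stopifnot(all(counts >= 0L), all(edge_density >= 0), all(edge_density <= 1))
  bad <- setdiff(names(edge_density),
                 setdiff(EDGE_SCHEMA$type, c("PART_OF", "DEG_RELATED_TO")))
  if (length(bad))
    stop("unsupported edge types in density map: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(seed = as.integer(seed), n_proteins = n_proteins,
                 n_diseases = n_diseases, n_pathways = n_pathways,
                 n_drugs = n_drugs, n_tissues = n_tissues,
                 edge_density = edge_density,
                 planted_shared_pairs = planted_shared_pairs,
                 planted_drug_motifs = planted_drug_motifs,
                 planted_path_lengths = as.integer(planted_path_lengths)),
            class = "synth_config")
}

syn_ids <- function(prefix, n) {
  if (n) sprintf("%s%05d", prefix, seq_len(n)) else character(0)
}

#' Generate a random knowledge graph with planted motifs
#'
#' Draws a background graph with the configured node cardinalities and
#' per-type edge densities, then plants recoverable ground-truth motifs on
#' dedicated nodes that the random background never touches: shared-protein
#' pairs between two planted diseases, drug/target/biomarker similarity
#' triples, and chains of specified lengths whose minimality is re-verified
#' by an independent breadth-first search before the manifest is returned.
#'
#' @param config A [synth_config()].
#' @return List with elements `graph` (a `knowledge_graph`) and `manifest`
#'   (ground truth: `shared`, `drug_motifs`, `paths`).
#' @export
make_random_kg <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (any(config$planted_path_lengths < 1L) ||
      any(config$planted_path_lengths > 50L))
    stop("planted path lengths must be between 1 and 50 edges",
         call. = FALSE)
  set.seed(config$seed)
  g <- kg_new()
  prot <- syn_ids("SYN", config$n_proteins)
  dis <- syn_ids("DIS", config$n_diseases)
  pw <- syn_ids("PW", config$n_pathways)
  drug <- syn_ids("DRUG", config$n_drugs)
  tis <- syn_ids("TIS", config$n_tissues)
  for (p in prot) kg_upsert_node(g, "Protein", p)
  for (d in dis) kg_upsert_node(g, "Disease", d)
  for (w in pw) kg_upsert_node(g, "Pathway", w,
                               list(name = paste("Synthetic pathway", w)))
  for (dr in drug) kg_upsert_node(g, "Drug", dr)
  for (t in tis) kg_upsert_node(g, "Tissue", t)

  pool <- list(Protein = prot, Disease = dis, Pathway = pw,
               Drug = drug, Tissue = tis)
  for (type in names(config$edge_density)) {
    dens <- config$edge_density[[type]]
    if (dens <= 0) next
    row <- EDGE_SCHEMA[EDGE_SCHEMA$type == type, ]
    if (row$src_label == row$dst_label) {
      n <- length(pool$Protein)
      if (n < 2L) next
      idx <- utils::combn(n, 2L)
      take <- stats::runif(ncol(idx)) < dens
      for (j in which(take)) {
        props <- if (type == "SEQ_SIM")
          list(score = round(stats::runif(1, 5, 150), 3)) else list()
        kg_upsert_edge(g, type, prot[idx[1L, j]], prot[idx[2L, j]], props)
      }
    } else {
      src <- pool[[row$src_label]]
      dst <- pool[[row$dst_label]]
      if (!length(src) || !length(dst)) next
      grid <- expand.grid(s = src, d = dst, stringsAsFactors = FALSE)
      take <- stats::runif(nrow(grid)) < dens
      for (j in which(take)) {
        props <- switch(type,
                        TISSUE_ENHANCED =
                          list(rna_ts_fpkm = round(stats::runif(1, 1, 500), 1)),
                        list())
        kg_upsert_edge(g, type, grid$s[j], grid$d[j], props)
      }
    }
  }

  manifest <- list()
  if (config$planted_shared_pairs > 0L) {
    da <- "PLANTED DISEASE A"; db <- "PLANTED DISEASE B"
    kg_upsert_node(g, "Disease", da)
    kg_upsert_node(g, "Disease", db)
    shared <- syn_ids("PLSH", config$planted_shared_pairs)
    for (p in shared) {
      kg_upsert_node(g, "Protein", p)
      kg_upsert_edge(g, "KANEKO_ASSOCIATED", p, da)
      kg_upsert_edge(g, "KANEKO_ASSOCIATED", p, db)
    }
    manifest$shared <- list(disease_a = da, disease_b = db,
                            proteins = sort(shared))
  }
  if (config$planted_drug_motifs > 0L) {
    dd <- "PLANTED DISEASE DRUG"
    kg_upsert_node(g, "Disease", dd)
    rows <- lapply(seq_len(config$planted_drug_motifs), function(i) {
      drg <- sprintf("PLDRUG%05d", i)
      tgt <- sprintf("PLTGT%05d", i)
      bio <- sprintf("PLBIO%05d", i)
      score <- round(stats::runif(1, 10, 120), 3)
      kg_upsert_node(g, "Drug", drg)
      kg_upsert_node(g, "Protein", tgt)
      kg_upsert_node(g, "Protein", bio)
      kg_upsert_edge(g, "DRUG_TARGET", tgt, drg)
      kg_upsert_edge(g, "SEQ_SIM", tgt, bio, list(score = score))
      kg_upsert_edge(g, "BIOMARKER", bio, dd)
      data.frame(drug = drg, target = tgt, biomarker = bio,
                 seqsim_score = score, stringsAsFactors = FALSE)
    })
    manifest$drug_motifs <- list(disease = dd, leads = do.call(rbind, rows))
  }
  if (length(config$planted_path_lengths)) {
    rows <- lapply(seq_along(config$planted_path_lengths), function(i) {
      len <- config$planted_path_lengths[i]
      chain <- sprintf("PLPATH%02dN%02d", i, 0:len)
      for (p in chain) kg_upsert_node(g, "Protein", p)
      for (j in seq_len(len))
        kg_upsert_edge(g, "PPI_ASSOCIATION", chain[j], chain[j + 1L])
      data.frame(source = chain[1L], target = chain[len + 1L], length = len,
                 stringsAsFactors = FALSE)
    })
    paths <- do.call(rbind, rows)
    # independent minimality check: the planted chain must be a shortest path
    for (i in seq_len(nrow(paths))) {
      d <- bfs_distances(g, node_id("Protein", paths$source[i]))
      got <- d[[node_id("Protein", paths$target[i])]]
      if (is.null(got) || got != paths$length[i])
        stop("planted path verification failed", call. = FALSE)
    }
    manifest$paths <- paths
  }
  kg_validate(g)
  list(graph = g, manifest = manifest)
}

#' Generate an all-vs-all BLAST hit table with known surviving pairs
#'
#' Emits a controlled mixture of hit classes: reciprocal pairs passing every
#' filter, one-directional hits, pairs failing the coverage ratio in one
#' direction, pairs failing the e-value threshold, and the boundary cases
#' (e-value exactly at the threshold, e-value exactly zero, coverage ratio
#' exactly at the cut-off). The manifest of pairs expected to survive
#' [derive_seqsim()] is recomputed by an independent re-evaluation of the
#' three filter rules before the table is returned.
#'
#' @param seed Integer seed.
#' @param n_random Number of additional random reciprocal pairs (split
#'   between passing and failing classes).
#' @param evalue_max,ratio_min Thresholds the manifest is computed against.
#' @return List with `hits` (directional hit data frame in extended tabular
#'   layout), `lengths` (named vector) and `manifest` (data frame
#'   `protein_a`, `protein_b`, `score` of expected survivors).
#' @export
make_blast_table <- function(seed = 1L, n_random = 40L,
                             evalue_max = 1e-5, ratio_min = 0.60) {
  set.seed(seed)
  rows <- list()
  lens <- list()
  add_hit <- function(q, s, e, aln) {
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = q, subject_id = s, pident = 90, aln_len = aln,
      mismatch = 5L, gapopen = 0L, qstart = 1L, qend = aln, sstart = 1L,
      send = aln, evalue = e, bitscore = 200,
      query_len = lens[[q]], subject_len = lens[[s]],
      stringsAsFactors = FALSE)
  }
  new_pair <- function(tag, i) {
    a <- sprintf("SB%s%04dA", tag, i); b <- sprintf("SB%s%04dB", tag, i)
    la <- sample(200:800, 1L); lb <- sample(200:800, 1L)
    lens[[a]] <<- la; lens[[b]] <<- lb
    c(a, b)
  }
  # random reciprocal pairs: half clean passes, the rest assorted failures
  for (i in seq_len(n_random)) {
    p <- new_pair("R", i)
    mn <- min(lens[[p[1L]]], lens[[p[2L]]])
    cls <- i %% 4L
    if (cls <= 1L) {                      # both directions pass
      add_hit(p[1L], p[2L], 10^stats::runif(1, -40, -6), ceiling(0.8 * mn))
      add_hit(p[2L], p[1L], 10^stats::runif(1, -40, -6), ceiling(0.9 * mn))
    } else if (cls == 2L) {               # reverse direction missing
      add_hit(p[1L], p[2L], 1e-10, ceiling(0.8 * mn))
    } else {                              # one direction fails a filter
      add_hit(p[1L], p[2L], 1e-12, ceiling(0.9 * mn))
      if (i %% 2L) add_hit(p[2L], p[1L], 1e-3, ceiling(0.9 * mn))
      else add_hit(p[2L], p[1L], 1e-12, floor(0.5 * mn))
    }
  }
  # deterministic boundary pairs
  bp <- new_pair("E", 1L)  # e exactly at threshold, ratio just above
  lens[[bp[1L]]] <- 100; lens[[bp[2L]]] <- 150
  add_hit(bp[1L], bp[2L], evalue_max, 61L)
  add_hit(bp[2L], bp[1L], evalue_max, 61L)
  zp <- new_pair("Z", 1L)  # e-value reported as exactly zero
  add_hit(zp[1L], zp[2L], 0, ceiling(0.9 * min(lens[[zp[1L]]], lens[[zp[2L]]])))
  add_hit(zp[2L], zp[1L], 0, ceiling(0.9 * min(lens[[zp[1L]]], lens[[zp[2L]]])))
  rp <- new_pair("B", 1L)  # ratio exactly at the cut-off: must be excluded
  lens[[rp[1L]]] <- 100; lens[[rp[2L]]] <- 200
  add_hit(rp[1L], rp[2L], 1e-20, 60L)
  add_hit(rp[2L], rp[1L], 1e-20, 60L)
  sp <- "SBSELF0001"       # self-hit: discarded before derivation
  lens[[sp]] <- 300
  add_hit(sp, sp, 0, 300L)
  hits <- do.call(rbind, rows)

  # independent re-evaluation of the filter rules, pair by pair
  manifest <- local({
    h <- hits[hits$query_id != hits$subject_id, ]
    ok <- h$evalue <= evalue_max &
      h$aln_len / pmin(h$query_len, h$subject_len) > ratio_min
    h <- h[ok, ]
    if (!nrow(h))
      return(data.frame(protein_a = character(0), protein_b = character(0),
                        score = numeric(0)))
    out <- list()
    pairs <- unique(t(apply(cbind(h$query_id, h$subject_id), 1L, sort)))
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1L]; b <- pairs[k, 2L]
      e_ab <- h$evalue[h$query_id == a & h$subject_id == b]
      e_ba <- h$evalue[h$query_id == b & h$subject_id == a]
      if (!length(e_ab) || !length(e_ba)) next
      e <- pmax(c(min(e_ab), min(e_ba)), 1e-180)
      out[[length(out) + 1L]] <- data.frame(
        protein_a = a, protein_b = b, score = -log10(mean(e)),
        stringsAsFactors = FALSE)
    }
    if (!length(out))
      return(data.frame(protein_a = character(0), protein_b = character(0),
                        score = numeric(0)))
    m <- do.call(rbind, out)
    m <- m[order(m$protein_a, m$protein_b), , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  list(hits = hits, lengths = unlist(lens), manifest = manifest)
}

#' @rdname make_blast_table
#' @param table The `hits` data frame from `make_blast_table()`.
#' @param path Output file for the 14-column extended tabular layout
#'   (no header).
#' @export
write_blast_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Generate limma-style differential-expression tables
#'
#' Emulates the adjusted-p-value summaries of two studies' comparisons of the
#' same sample groups, with a configured fraction of significant genes and a
#' configured overlap of significant genes between the two studies.
#'
#' @param seed Integer seed.
#' @param n_genes Genes per table.
#' @param n_common Genes planted as significant in both studies.
#' @param n_specific Genes significant in exactly one study.
#' @param studies Two study identifiers.
#' @param group_a,group_b Compared sample groups.
#' @param adjp_max The threshold the planted significances respect.
#' @return List with `tables` (named by study: data frames `gene`, `adj_p`)
#'   and `manifest` (`common`: the planted common significant genes;
#'   `comparisons`: the study-scoped comparison keys).
#' @export
make_deg_tables <- function(seed = 1L, n_genes = 60L, n_common = 5L,
                            n_specific = 5L,
                            studies = c("GSE43696", "GSE63142"),
                            group_a = "NC", group_b = "SA",
                            adjp_max = 0.05) {
  stopifnot(length(studies) == 2L,
            n_common + 2L * n_specific <= n_genes)
  set.seed(seed)
  genes <- syn_ids("SYNG", n_genes)
  common <- genes[seq_len(n_common)]
  spec1 <- genes[n_common + seq_len(n_specific)]
  spec2 <- genes[n_common + n_specific + seq_len(n_specific)]
  make_one <- function(sig) {
    p <- stats::runif(n_genes, adjp_max, 1)
    p[genes %in% sig] <- stats::runif(sum(genes %in% sig), 0, adjp_max * 0.9)
    data.frame(gene = genes, adj_p = round(p, 6), stringsAsFactors = FALSE)
  }
  tables <- list(make_one(c(common, spec1)), make_one(c(common, spec2)))
  names(tables) <- studies
  # verify the manifest claim independently against the emitted tables
  for (gn in common)
    for (tb in tables)
      stopifnot(tb$adj_p[tb$gene == gn] < adjp_max)
  list(tables = tables,
       manifest = list(common = sort(common),
                       comparisons = paste0(studies, "::",
                                            group_a, "-", group_b)))
}

# Curated multi-disease memberships printed in the source review's comparison
# tables: every protein below is asthma-associated and additionally belongs
# to the listed control-disease categories.
.KANEKO_CORE <- list(
  "E-HTN" = c("P29474", "P04040", "P12821", "P07550", "P30711"),
  "COPD" = c("P01375", "O00206", "P01137", "P35225", "P01584", "P29474",
             "Q9BZ11", "P07550", "P12821", "P09211", "Q96QV1", "P09488",
             "P16410", "P05305"),
  "TB" = c("P01579", "P01920", "P01911", "P01584", "P22301", "P29460",
           "P05112", "P13501", "P11473", "P01375", "O60603", "Q9NR96"))

# Additional asthma-only anchors carried by the demo network's shortest-path
# neighbourhood (asthma-associated proteins adjacent to the Disease node).
.KANEKO_BA_ANCHORS <- c("Q9UIL8", "P84022", "P01374", "P13569")

#' Synthetic stand-in for the curated respiratory-disease gene list
#'
#' The full supplementary gene list behind the curated respiratory review is
#' not redistributable here, so this constructs a stand-in with the published
#' category sizes (104 BA, 58 COPD, 35 TB, 54 E-HTN; 219 distinct genes, 251
#' memberships): the real cross-disease memberships printed in the published
#' comparison tables are kept verbatim, and the remainder is padded with
#' clearly synthetic accessions (`SYNK...`), including one synthetic COPD/TB
#' overlap so the distinct-gene count matches exactly.
#'
#' @return Data frame with columns `gene`, `category`, one row per
#'   membership, suitable for [import_kaneko()].
#' @export
kaneko_synthetic_table <- function() {
  ba <- sort(unique(c(unlist(.KANEKO_CORE), .KANEKO_BA_ANCHORS)))
  pad <- function(prefix, n) sprintf("SYNK%s%03d", prefix, seq_len(n))
  rows <- rbind(
    data.frame(gene = c(ba, pad("B", 104L - length(ba))), category = "BA",
               stringsAsFactors = FALSE),
    data.frame(gene = c(.KANEKO_CORE$COPD, pad("C", 43L), "SYNKCT001"),
               category = "COPD", stringsAsFactors = FALSE),
    data.frame(gene = c(.KANEKO_CORE$TB, pad("T", 22L), "SYNKCT001"),
               category = "TB", stringsAsFactors = FALSE),
    data.frame(gene = c(.KANEKO_CORE$`E-HTN`, pad("E", 49L)),
               category = "E-HTN", stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}

# Gene-symbol to accession mapping used by the demo network's curated
# disease-association and expression layers.
.DEMO_SYMBOL_MAP <- data.frame(
  id = c("NOS2", "HMOX1", "TGFB1", "MMP9", "TNF", "CCL2", "KRT19", "KRT8"),
  accession = c("P35228", "P09601", "P01137", "P14780", "P01375", "P13500",
                "P08727", "P05787"),
  stringsAsFactors = FALSE)

#' Build the demo asthma knowledge graph
#'
#' Constructs, through the package's own importers and upserts, the small
#' literature-anchored network used in the examples and tests: the curated
#' respiratory-disease gene memberships ([kaneko_synthetic_table()]), curated
#' gene-disease associations for the asthma/COPD/TB/hypertension comparison,
#' the circadian core-clock proteins with the published three-step
#' shortest-path neighbourhood around the Asthma node, the
#' Tenecteplase/KRT8/KRT19 drug-repurposing similarity motif, three GEO
#' asthma studies with three comparisons each, and a small pathway layer.
#' Bridge proteins that the literature leaves unnamed carry synthetic
#' accessions (`SYNP...`).
#'
#' @return A `knowledge_graph`.
#' @export
#' @examples
#' g <- demo_asthma_kg()
#' kg_stats(g)
demo_asthma_kg <- function() {
  g <- kg_new()
  import_kaneko(g, kaneko_synthetic_table())

  mapping <- load_id_mapping(.DEMO_SYMBOL_MAP)
  copd <- "Pulmonary Disease, Chronic Obstructive"
  tb <- "Tuberculosis, Pulmonary"
  ehtn <- "Hypertension, Essential"
  disgenet <- data.frame(
    gene_symbol = c("NOS2", "HMOX1", "TGFB1", "MMP9", "TNF", "CCL2", "KRT19",
                    "NOS2",
                    "NOS2", "HMOX1", "TGFB1", "MMP9", "TNF",
                    "CCL2"),
    disease_name = c(rep("Asthma", 7L), ehtn, rep(copd, 5L), tb),
    association_type = "Biomarker",
    stringsAsFactors = FALSE)
  import_disgenet(g, disgenet, mapping)

  import_drugbank(g, data.frame(
    drug = c("Tenecteplase", "Salbutamol"),
    accession = c("P05787", "P07550"),
    category = "target", stringsAsFactors = FALSE))

  # circadian core-clock proteins and the published path neighbourhood
  clock <- c("O15516", "O00327", "Q16526", "Q49AN0", "Q99743", "O15534",
             "O15055")
  bridges <- c("P67870", "Q99814", "Q92956", "Q12933", "P28799",
               "SYNP0001", "SYNP0002", "P20393", "P05787")
  for (p in c(clock, bridges)) kg_upsert_node(g, "Protein", p)
  ppi <- list(
    c("Q9UIL8", "P67870"), c("P67870", "Q99743"),          # to NPAS2
    c("P84022", "Q99814"), c("Q99814", "O00327"),          # to ARNTL/BMAL1
    c("P01374", "Q92956"), c("Q92956", "O15055"),          # to PER2
    c("P09211", "Q12933"), c("P09211", "P28799"),          # to CRY1 (layer 1)
    c("P01375", "Q12933"), c("P01375", "P28799"),
    c("P13569", "Q12933"), c("P13569", "P28799"),
    c("Q12933", "Q16526"), c("P28799", "Q16526"),          # to CRY1 (layer 2)
    c("O15516", "O00327"),                                 # CLOCK - BMAL1
    c("O15534", "SYNP0001"),                               # PER1 bridge
    c("SYNP0001", "O15055"), c("SYNP0001", "Q16526"),
    c("SYNP0001", "Q49AN0"),
    c("P20393", "SYNP0002"), c("SYNP0002", "O15516"))      # REV-ErbA-alpha
  for (e in ppi) kg_upsert_edge(g, "PPI_ASSOCIATION", e[1L], e[2L])
  seqsim <- list(list("O15516", "Q99743", 52.5),           # CLOCK ~ NPAS2
                 list("Q16526", "Q49AN0", 61.0),           # CRY1 ~ CRY2
                 list("P05787", "P08727", 100.0))          # KRT8 ~ KRT19
  for (e in seqsim)
    kg_upsert_edge(g, "SEQ_SIM", e[[1L]], e[[2L]], list(score = e[[3L]]))

  # three GEO asthma series, three comparisons each
  geo <- list(
    GSE27876 = list(c("NC", "MiA"), c("NC", "SA"), c("MiA", "SA")),
    GSE43696 = list(c("NC", "MMA"), c("NC", "SA"), c("MMA", "SA")),
    GSE63142 = list(c("NC", "MMA"), c("NC", "SA"), c("MMA", "SA")))
  degs <- list(
    "GSE43696::NC-SA" = data.frame(gene = c("P35228", "P01375"),
                                   adj_p = c(0.003, 0.021)),
    "GSE63142::NC-SA" = data.frame(gene = "P35228", adj_p = 0.008))
  for (study in names(geo)) {
    for (grp in geo[[study]]) {
      key <- paste0(study, "::", grp[1L], "-", grp[2L])
      tab <- degs[[key]] %||% data.frame(gene = character(0),
                                         adj_p = numeric(0))
      import_geo_deg(g, study, grp[1L], grp[2L], tab)
    }
  }

  import_reactome(g, data.frame(
    accession = c("P35228", "P01375", "P01375"),
    pathway_id = c("R-HSA-6785807", "R-HSA-75893", "R-HSA-109581"),
    pathway_name = c("Interleukin-4 and Interleukin-13 signaling",
                     "TNF signaling", "Apoptosis"),
    stringsAsFactors = FALSE))

  kg_validate(g)
  g
}
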