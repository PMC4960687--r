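# Source-format importers. Each importer parses one source layout, applies its
# filtering/derivation rules, populates the graph through the upsert layer
# (which guarantees deduplication), and returns an import_report accounting
# for every input record: read = kept + skipped.

`%||%` <- function(a, b) if (is.null(a)) b else a

new_report_env <- function() {
  e <- new.env(parent = emptyenv())
  e$read <- 0L
  e$kept <- 0L
  e$skips <- integer(0)
  e
}

note_skip <- function(re, reason, n = 1L) {
  re$skips[reason] <- (if (reason %in% names(re$skips)) re$skips[[reason]] else 0L) + n
  invisible(NULL)
}

finish_report <- function(re) {
  skips <- re$skips
  if (length(skips)) skips <- skips[order(names(skips))]
  structure(list(records_read = re$read,
                 records_kept = re$kept,
                 records_skipped = sum(skips),
                 skip_reasons = skips),
            class = "import_report")
}

#' @export
print.import_report <- function(x, ...) {
  cat(sprintf("import report: %d read, %d kept, %d skipped\n",
              x$records_read, x$records_kept, x$records_skipped))
  if (length(x$skip_reasons))
    for (r in names(x$skip_reasons))
      cat(sprintf("  - %s: %d\n", r, x$skip_reasons[[r]]))
  invisible(x)
}

# Accept either a data frame or a delimited file path.
as_table <- function(x, sep = "\t", header = TRUE) {
  if (is.data.frame(x)) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (!file.exists(x)) stop("input file not found: ", x, call. = FALSE)
  utils::read.table(x, sep = sep, header = header, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE)
}

#' Load a source-id to UniProt mapping table
#'
#' Reads a two-column table (source identifier, UniProt accession), the layout
#' produced by UniProt's Retrieve/ID mapping tool, into a multimap. Lookups
#' are case-insensitive on the source identifier; duplicate pairs collapse;
#' one identifier may map to several accessions.
#'
#' @param x Path to a headerless two-column TSV, or a data frame whose first
#'   two columns are (source id, accession).
#' @return An object of class `id_mapping`.
#' @export
#' @examples
#' m <- load_id_mapping(data.frame(id = "KRT8", acc = "P05787"))
#' id_lookup(m, "krt8")
load_id_mapping <- function(x) {
  tab <- if (is.data.frame(x)) x else as_table(x, header = FALSE)
  env <- new.env(parent = emptyenv())
  if (nrow(tab)) {
    src <- tolower(trimws(as.character(tab[[1L]])))
    acc <- toupper(trimws(as.character(tab[[2L]])))
    keep <- nzchar(src) & nzchar(acc)
    by_src <- split(acc[keep], src[keep])
    for (nm in names(by_src)) assign(nm, sort(unique(by_src[[nm]])), envir = env)
  }
  structure(list(map = env), class = "id_mapping")
}

#' @rdname load_id_mapping
#' @param mapping An `id_mapping`.
#' @param id A single source identifier (gene symbol or ENSEMBL id).
#' @return `id_lookup()` returns the mapped accessions, `character(0)` when
#'   the identifier is unmapped.
#' @export
id_lookup <- function(mapping, id) {
  stopifnot(inherits(mapping, "id_mapping"), length(id) == 1L)
  mapping$map[[tolower(trimws(id))]] %||% character(0)
}

# Resolve one gene identifier: through the mapping when given, otherwise the
# identifier is taken to be a UniProt accession itself.
resolve_gene <- function(id, id_mapping) {
  if (is.null(id_mapping)) toupper(trimws(id)) else id_lookup(id_mapping, id)
}

#' Read an all-vs-all BLAST tabular hit file
#'
#' Reads extended tabular output (outfmt 6 plus `qlen`/`slen`); the default
#' column order is `qaccver saccver pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore qlen slen`. Only the query/subject ids,
#' e-value, alignment length and sequence lengths are used downstream.
#'
#' @param path Tab-separated hit file without header.
#' @param columns Character vector naming the file's columns; must include
#'   `query_id`, `subject_id`, `evalue`, `aln_len` and (unless a separate
#'   length table is supplied to [derive_seqsim()]) `query_len`, `subject_len`.
#' @return A data frame of directional hits.
#' @export
read_blast_table <- function(path,
                             columns = c("query_id", "subject_id", "pident",
                                         "aln_len", "mismatch", "gapopen",
                                         "qstart", "qend", "sstart", "send",
                                         "evalue", "bitscore",
                                         "query_len", "subject_len")) {
  tab <- as_table(path, header = FALSE)
  if (ncol(tab) < length(columns))
    stop(sprintf("BLAST table has %d columns, expected %d",
                 ncol(tab), length(columns)), call. = FALSE)
  tab <- tab[, seq_along(columns), drop = FALSE]
  names(tab) <- columns
  for (nm in intersect(c("evalue", "aln_len", "query_len", "subject_len"),
                       columns))
    tab[[nm]] <- as.numeric(tab[[nm]])
  tab
}

#' Derive sequence-similarity edges from reciprocal BLAST hits
#'
#' Implements the reciprocal-hit derivation: an unordered protein pair (A, B)
#' yields one similarity edge iff hits exist in both directions (A to B and
#' B to A), both directional e-values pass `e <= evalue_max`, and both hits
#' satisfy the alignment-coverage filter `r = L / min(query_len, subject_len)
#' > ratio_min` (strict). The edge score is
#' `-log10((e_ab + e_ba) / 2)`, with e-values of exactly zero clamped to
#' 1e-180 before averaging. Self-hits are discarded; when several hits exist
#' for one direction, the one with the smallest e-value among those passing
#' the filters is used.
#'
#' @param hits Data frame of directional hits with columns `query_id`,
#'   `subject_id`, `evalue`, `aln_len` and, unless `lengths` is given,
#'   `query_len` and `subject_len`.
#' @param lengths Optional named numeric vector of sequence lengths, used
#'   when the hit table lacks length columns. A hit referencing an accession
#'   with no known length is an error.
#' @param evalue_max Significance threshold on each directional e-value
#'   (inclusive). Default 1e-5.
#' @param ratio_min Alignment-length/shortest-sequence ratio threshold
#'   (exclusive). Default 0.60.
#' @return Data frame with columns `protein_a`, `protein_b` (the unordered
#'   pair, `protein_a < protein_b`) and `score`, sorted by pair.
#' @export
#' @examples
#' hits <- data.frame(query_id = c("A", "B"), subject_id = c("B", "A"),
#'                    evalue = c(1e-10, 1e-10), aln_len = c(90, 90),
#'                    query_len = c(100, 100), subject_len = c(100, 100))
#' derive_seqsim(hits)  # score 10
derive_seqsim <- function(hits, lengths = NULL,
                          evalue_max = 1e-5, ratio_min = 0.60) {
  req <- c("query_id", "subject_id", "evalue", "aln_len")
  if (!all(req %in% names(hits)))
    stop("hit table must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  hits$query_id <- toupper(trimws(as.character(hits$query_id)))
  hits$subject_id <- toupper(trimws(as.character(hits$subject_id)))
  if (!all(c("query_len", "subject_len") %in% names(hits))) {
    if (is.null(lengths))
      stop("hit table lacks query_len/subject_len and no length table given",
           call. = FALSE)
    names(lengths) <- toupper(trimws(names(lengths)))
    unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)),
                       names(lengths))
    if (length(unknown))
      stop("no sequence length known for accession(s): ",
           paste(sort(unknown), collapse = ", "), call. = FALSE)
    hits$query_len <- unname(lengths[hits$query_id])
    hits$subject_len <- unname(lengths[hits$subject_id])
  }
  bad_len <- !is.finite(hits$query_len) | !is.finite(hits$subject_len)
  if (any(bad_len))
    stop("no sequence length known for accession(s): ",
         paste(sort(unique(c(hits$query_id[bad_len],
                             hits$subject_id[bad_len]))), collapse = ", "),
         call. = FALSE)
  empty <- data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  ratio <- hits$aln_len / pmin(hits$query_len, hits$subject_len)
  hits <- hits[hits$evalue <= evalue_max & ratio > ratio_min, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  okey <- paste(hits$query_id, hits$subject_id, sep = .SEP)
  emin <- tapply(hits$evalue, okey, min)
  parts <- strsplit(names(emin), .SEP, fixed = TRUE)
  q <- vapply(parts, `[`, "", 1L)
  s <- vapply(parts, `[`, "", 2L)
  a <- pmin(q, s)
  b <- pmax(q, s)
  pair <- paste(a, b, sep = .SEP)
  both <- names(which(table(pair) == 2L))
  if (!length(both)) return(empty)
  e <- pmax(as.numeric(emin), 1e-180)  # clamp exact-zero e-values
  mean_e <- tapply(e[pair %in% both], pair[pair %in% both], mean)
  pp <- strsplit(names(mean_e), .SEP, fixed = TRUE)
  out <- data.frame(protein_a = vapply(pp, `[`, "", 1L),
                    protein_b = vapply(pp, `[`, "", 2L),
                    score = -log10(as.numeric(mean_e)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Import sequence-similarity edges
#'
#' Applies [derive_seqsim()] to a hit table (or takes pre-derived pair specs)
#' and upserts the corresponding `Protein` nodes and scored, undirected
#' `SEQ_SIM` edges.
#'
#' @param graph Knowledge graph.
#' @param hits Directional hit data frame or BLAST tabular file path
#'   (read with [read_blast_table()]).
#' @param lengths,evalue_max,ratio_min Passed to [derive_seqsim()].
#' @return An `import_report`; `records_read` counts directional hits,
#'   `records_kept` the derived pairs.
#' @export
import_seqsim <- function(graph, hits, lengths = NULL,
                          evalue_max = 1e-5, ratio_min = 0.60) {
  if (is.character(hits)) hits <- read_blast_table(hits)
  re <- new_report_env()
  re$read <- nrow(hits)
  specs <- derive_seqsim(hits, lengths, evalue_max, ratio_min)
  for (i in seq_len(nrow(specs))) {
    kg_upsert_node(graph, "Protein", specs$protein_a[i])
    kg_upsert_node(graph, "Protein", specs$protein_b[i])
    kg_upsert_edge(graph, "SEQ_SIM", specs$protein_a[i], specs$protein_b[i],
                   list(score = specs$score[i]))
    re$kept <- re$kept + 1L
  }
  note_skip(re, "failed filter", re$read - re$kept)
  if (re$read == re$kept) re$skips <- integer(0)
  finish_report(re)
}

# Pull the human-readable label out of a PSI-MI term like
# 'psi-mi:"MI:0915"(physical association)'; fall back to the raw field.
mitab_term_label <- function(field) {
  m <- regmatches(field, gregexpr("\\(([^()]*)\\)", field))[[1L]]
  if (length(m)) sub("^\\(", "", sub("\\)$", "", m[length(m)])) else field
}

mitab_uniprot_id <- function(field, id_mapping) {
  entries <- strsplit(field, "|", fixed = TRUE)[[1L]]
  up <- grep("^uniprotkb:", entries, value = TRUE)
  if (length(up)) {
    acc <- sub("^uniprotkb:", "", up[1L])
    return(toupper(sub("-[0-9]+$", "", acc)))  # collapse isoform suffixes
  }
  if (!is.null(id_mapping) && length(entries)) {
    val <- sub("^[^:]*:", "", entries[1L])
    hit <- id_lookup(id_mapping, val)
    if (length(hit)) return(hit[1L])
  }
  NA_character_
}

route_interaction_type <- function(label) {
  label <- tolower(label)
  if (grepl("genetic inter", label)) "PPI_GENETIC_INTERACTION"
  else if (grepl("colocalization", label)) "PPI_COLOCALIZATION"
  else if (grepl("association", label)) "PPI_ASSOCIATION"
  else NA_character_
}

#' Import protein-protein interactions from a PSI-MITAB 2.5 file
#'
#' Each row routes to one of the three undirected interaction edge types by
#' its interaction-type term: genetic interaction, colocalization, or
#' (physical) association. Edges accumulate the union of detection-method
#' labels in a `methods` property and the maximum `intact-miscore` seen in a
#' `confidence` property. Rows whose interactors cannot be resolved to
#' UniProt accessions are skipped and counted.
#'
#' @param graph Knowledge graph.
#' @param path MITAB 2.5 file (15 tab-separated columns or a superset; lines
#'   starting with `#` are treated as headers).
#' @param id_mapping Optional [load_id_mapping()] object used for non-UniProt
#'   interactor identifiers.
#' @return An `import_report`.
#' @export
import_mitab <- function(graph, path, id_mapping = NULL) {
  lines <- readLines(path, warn = FALSE)
  re <- new_report_env()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 15L)
      stop(sprintf("line %d: MITAB row has %d columns, expected >= 15",
                   i, length(f)), call. = FALSE)
    re$read <- re$read + 1L
    a <- mitab_uniprot_id(f[1L], id_mapping)
    b <- mitab_uniprot_id(f[2L], id_mapping)
    if (is.na(a) || is.na(b)) { note_skip(re, "unmapped id"); next }
    if (a == b) { note_skip(re, "self interaction"); next }
    type <- route_interaction_type(mitab_term_label(f[12L]))
    if (is.na(type)) { note_skip(re, "unrouted interaction type"); next }
    methods <- vapply(strsplit(f[7L], "|", fixed = TRUE)[[1L]],
                      mitab_term_label, "")
    methods <- methods[nzchar(methods) & methods != "-"]
    props <- list(methods = unname(methods))
    sc <- regmatches(f[15L],
                     regexpr("intact-miscore:[0-9eE.+-]+", f[15L]))
    if (length(sc))
      props$confidence <- as.numeric(sub("intact-miscore:", "", sc))
    kg_upsert_node(graph, "Protein", a)
    kg_upsert_node(graph, "Protein", b)
    kg_upsert_edge(graph, type, a, b, props)
    re$kept <- re$kept + 1L
  }
  finish_report(re)
}

DISGENET_TYPE_MAP <- c(biomarker = "BIOMARKER",
                       geneticvariation = "GENETIC_VARIATION",
                       therapeutic = "THERAPEUTIC")

#' Import curated gene-disease associations (DisGeNET-style layout)
#'
#' Upserts `Disease` nodes keyed by disease name and connects them to the
#' proteins mapped from each gene symbol with an edge typed by the curated
#' association class (`Biomarker`, `GeneticVariation`, `Therapeutic`). A
#' symbol mapping to several accessions yields one edge per accession.
#'
#' @param graph Knowledge graph.
#' @param x TSV path (with header) or data frame.
#' @param id_mapping [load_id_mapping()] object resolving gene symbols.
#' @param columns Named character vector locating the `gene`, `disease` and
#'   `type` columns in the input.
#' @return An `import_report`.
#' @export
import_disgenet <- function(graph, x, id_mapping,
                            columns = c(gene = "gene_symbol",
                                        disease = "disease_name",
                                        type = "association_type")) {
  tab <- as_table(x)
  missing_cols <- setdiff(unname(columns), names(tab))
  if (length(missing_cols))
    stop("input lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  re <- new_report_env()
  for (i in seq_len(nrow(tab))) {
    re$read <- re$read + 1L
    raw_type <- gsub("[^a-z]", "", tolower(tab[i, columns[["type"]]]))
    if (!raw_type %in% names(DISGENET_TYPE_MAP)) {
      note_skip(re, "unknown association type"); next
    }
    accs <- resolve_gene(tab[i, columns[["gene"]]], id_mapping)
    if (!length(accs)) { note_skip(re, "unmapped id"); next }
    disease <- trimws(tab[i, columns[["disease"]]])
    kg_upsert_node(graph, "Disease", disease)
    for (acc in accs) {
      kg_upsert_node(graph, "Protein", acc)
      kg_upsert_edge(graph, DISGENET_TYPE_MAP[[raw_type]], acc, disease)
    }
    re$kept <- re$kept + 1L
  }
  finish_report(re)
}

#' Default mapping from curated respiratory-review categories to diseases
#'
#' The curated gene list categorizes genes into bronchial asthma (BA),
#' chronic obstructive pulmonary disease (COPD), tuberculosis (TB) and
#' essential hypertension (E-HTN); this maps each category to the disease
#' node name used by the curated DisGeNET-style import, so both sources
#' attach to the same `Disease` nodes while staying distinguishable by edge
#' type.
#'
#' @export
KANEKO_CATEGORY_MAP <- c(
  "BA" = "Asthma",
  "COPD" = "Pulmonary Disease, Chronic Obstructive",
  "TB" = "Tuberculosis, Pulmonary",
  "E-HTN" = "Hypertension, Essential")

#' Import the curated multi-disease gene memberships (Kaneko-style list)
#'
#' One row per (gene, category) membership; categories may overlap, so one
#' gene can produce several `KANEKO_ASSOCIATED` edges. Category labels are
#' resolved to disease-node names through `category_map`; an unknown category
#' is a validation error.
#'
#' @param graph Knowledge graph.
#' @param x TSV path (with header) or data frame with columns `gene`,
#'   `category`.
#' @param id_mapping Optional mapping; when `NULL`, gene identifiers are taken
#'   to be UniProt accessions.
#' @param category_map Named character vector, category to disease-node name.
#' @return An `import_report`.
#' @export
import_kaneko <- function(graph, x, id_mapping = NULL,
                          category_map = KANEKO_CATEGORY_MAP) {
  tab <- as_table(x)
  if (!nrow(tab)) return(finish_report(new_report_env()))
  if (!all(c("gene", "category") %in% names(tab)))
    stop("input needs columns 'gene' and 'category'", call. = FALSE)
  bad <- setdiff(unique(tab$category), names(category_map))
  if (length(bad))
    stop("unknown category value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  re <- new_report_env()
  for (i in seq_len(nrow(tab))) {
    re$read <- re$read + 1L
    accs <- resolve_gene(tab$gene[i], id_mapping)
    if (!length(accs)) { note_skip(re, "unmapped id"); next }
    disease <- category_map[[tab$category[i]]]
    kg_upsert_node(graph, "Disease", disease)
    for (acc in accs) {
      kg_upsert_node(graph, "Protein", acc)
      kg_upsert_edge(graph, "KANEKO_ASSOCIATED", acc, disease)
    }
    re$kept <- re$kept + 1L
  }
  finish_report(re)
}

DRUG_CATEGORY_MAP <- c(target = "DRUG_TARGET", enzyme = "DRUG_ENZYME",
                       transporter = "DRUG_TRANSPORTER",
                       carrier = "DRUG_CARRIER")

#' Import drug-protein relations (DrugBank CSV layout)
#'
#' @param graph Knowledge graph.
#' @param x CSV path (with header) or data frame with columns `drug`,
#'   `accession`, `category` (one of target/enzyme/carrier/transporter).
#' @return An `import_report`; rows with unknown categories are skipped with
#'   a reason.
#' @export
import_drugbank <- function(graph, x) {
  tab <- if (is.data.frame(x)) x else as_table(x, sep = ",")
  if (!nrow(tab)) return(finish_report(new_report_env()))
  if (!all(c("drug", "accession", "category") %in% names(tab)))
    stop("input needs columns 'drug', 'accession', 'category'", call. = FALSE)
  re <- new_report_env()
  for (i in seq_len(nrow(tab))) {
    re$read <- re$read + 1L
    cat_ <- tolower(trimws(tab$category[i]))
    if (!cat_ %in% names(DRUG_CATEGORY_MAP)) {
      note_skip(re, "unknown relation category"); next
    }
    kg_upsert_node(graph, "Drug", tab$drug[i])
    kg_upsert_node(graph, "Protein", tab$accession[i])
    kg_upsert_edge(graph, DRUG_CATEGORY_MAP[[cat_]],
                   tab$accession[i], tab$drug[i])
    re$kept <- re$kept + 1L
  }
  finish_report(re)
}

#' Import tissue-enhanced expression (Human Protein Atlas layout)
#'
#' Tissues become nodes; a gene flagged as tissue-enhanced links its mapped
#' protein(s) to the tissue with a `TISSUE_ENHANCED` edge carrying the
#' RNA-TS-FPKM value, and the ENSEMBL id is recorded on the protein node's
#' `ensembl_ids` property.
#'
#' @param graph Knowledge graph.
#' @param x TSV path (with header) or data frame with columns `ensembl`,
#'   `tissue`, `rna_ts_fpkm`.
#' @param id_mapping Mapping from ENSEMBL ids to accessions.
#' @return An `import_report`.
#' @export
import_hpa <- function(graph, x, id_mapping) {
  tab <- as_table(x)
  if (!nrow(tab)) return(finish_report(new_report_env()))
  if (!all(c("ensembl", "tissue", "rna_ts_fpkm") %in% names(tab)))
    stop("input needs columns 'ensembl', 'tissue', 'rna_ts_fpkm'",
         call. = FALSE)
  re <- new_report_env()
  for (i in seq_len(nrow(tab))) {
    re$read <- re$read + 1L
    fpkm <- suppressWarnings(as.numeric(tab$rna_ts_fpkm[i]))
    if (!is.finite(fpkm)) { note_skip(re, "malformed row"); next }
    accs <- id_lookup(id_mapping, tab$ensembl[i])
    if (!length(accs)) { note_skip(re, "unmapped id"); next }
    tissue <- trimws(tab$tissue[i])
    kg_upsert_node(graph, "Tissue", tissue)
    for (acc in accs) {
      kg_upsert_node(graph, "Protein", acc,
                     list(ensembl_ids = tab$ensembl[i]))
      kg_upsert_edge(graph, "TISSUE_ENHANCED", acc, tissue,
                     list(rna_ts_fpkm = fpkm))
    }
    re$kept <- re$kept + 1L
  }
  finish_report(re)
}

#' Import protein-pathway membership (Reactome layout)
#'
#' @param graph Knowledge graph.
#' @param x TSV path (with header) or data frame with columns `accession`,
#'   `pathway_id`, `pathway_name`. Pathway nodes are keyed by identifier and
#'   carry the name as a property.
#' @param id_mapping Unused placeholder for interface symmetry (pathway files
#'   already carry accessions); kept for forward compatibility.
#' @return An `import_report`.
#' @export
import_reactome <- function(graph, x, id_mapping = NULL) {
  tab <- as_table(x)
  if (!nrow(tab)) return(finish_report(new_report_env()))
  if (!all(c("accession", "pathway_id", "pathway_name") %in% names(tab)))
    stop("input needs columns 'accession', 'pathway_id', 'pathway_name'",
         call. = FALSE)
  re <- new_report_env()
  for (i in seq_len(nrow(tab))) {
    re$read <- re$read + 1L
    kg_upsert_node(graph, "Pathway", tab$pathway_id[i],
                   list(name = tab$pathway_name[i]))
    kg_upsert_node(graph, "Protein", tab$accession[i])
    kg_upsert_edge(graph, "IN_PATHWAY", tab$accession[i], tab$pathway_id[i])
    re$kept <- re$kept + 1L
  }
  finish_report(re)
}

#' Import one differential-expression comparison from a GEO study
#'
#' Models the transcriptomics provenance chain: a `GEOStudy` node for the
#' series, a `GEOComparison` node for the two compared sample groups (keyed
#' `"study::groupA-groupB"`, so equally named comparisons from different
#' studies stay distinct — the protein/comparison/study triple rule), one
#' `PART_OF` edge, and a `DEG_RELATED_TO` edge carrying the adjusted p-value
#' for every gene passing `adj_p < adjp_max`.
#'
#' @param graph Knowledge graph.
#' @param study_id GEO series identifier (e.g. `"GSE43696"`).
#' @param group_a,group_b Compared sample group labels (e.g. `"NC"`, `"SA"`).
#' @param table TSV path (with header) or data frame with columns `gene`,
#'   `adj_p` — the shape of a limma topTable summary.
#' @param id_mapping Optional mapping; when `NULL`, gene identifiers are taken
#'   to be accessions.
#' @param adjp_max Strict inclusion threshold on the adjusted p-value.
#' @return An `import_report`.
#' @export
import_geo_deg <- function(graph, study_id, group_a, group_b, table,
                           id_mapping = NULL, adjp_max = 0.05) {
  tab <- as_table(table)
  comparison <- paste0(group_a, "-", group_b)
  comp_key <- paste0(study_id, "::", comparison)
  kg_upsert_node(graph, "GEOStudy", study_id)
  kg_upsert_node(graph, "GEOComparison", comp_key,
                 list(group_a = group_a, group_b = group_b))
  kg_upsert_edge(graph, "PART_OF", comp_key, study_id)
  re <- new_report_env()
  if (nrow(tab) && !all(c("gene", "adj_p") %in% names(tab)))
    stop("input needs columns 'gene' and 'adj_p'", call. = FALSE)
  for (i in seq_len(nrow(tab))) {
    re$read <- re$read + 1L
    p <- suppressWarnings(as.numeric(tab$adj_p[i]))
    if (!is.finite(p) || p < 0 || p > 1) {
      note_skip(re, "invalid adjusted p-value"); next
    }
    if (p >= adjp_max) { note_skip(re, "failed filter"); next }
    accs <- resolve_gene(tab$gene[i], id_mapping)
    if (!length(accs)) { note_skip(re, "unmapped id"); next }
    for (acc in accs) {
      kg_upsert_node(graph, "Protein", acc)
      kg_upsert_edge(graph, "DEG_RELATED_TO", acc, comp_key,
                     list(adj_p = p))
    }
    re$kept <- re$kept + 1L
  }
  finish_report(re)
}
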