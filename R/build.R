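# Reproducible offline knowledgebase builds: a declarative config names the
# source files and per-source parameters, the build imports them in order
# through the importer layer, and the result is dumped with an inventory
# report. A thin command-line wrapper over these functions ships in
# inst/cli/dknet.R.

KNOWN_FORMATS <- c("blast", "mitab", "disgenet", "kaneko", "drugbank",
                   "hpa", "reactome", "geo_deg")

#' Read a declarative build configuration
#'
#' YAML (or JSON) with an optional `output` dump path, an optional
#' `id_mapping` TSV path, and a `sources` list; each source entry names a
#' `path` and a `format` (one of
#' `r paste0('\x60', KNOWN_FORMATS, '\x60', collapse = ", ")`) plus
#' per-format parameters (`evalue_max`/`ratio_min` for `blast`, `adjp_max`
#' and `study`/`group_a`/`group_b` for `geo_deg`, `columns` for `disgenet`,
#' `category_map` for `kaneko`).
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return The configuration as a list.
#' @export
read_build_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path)) jsonlite::fromJSON(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
}

validate_build_config <- function(config, base_dir = ".") {
  if (is.null(config$sources) || !length(config$sources))
    stop("config error: no sources declared", call. = FALSE)
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base_dir, p)
  for (src in config$sources) {
    if (is.null(src$format) || !src$format %in% KNOWN_FORMATS)
      stop(sprintf("config error: unknown format '%s'",
                   src$format %||% "<missing>"), call. = FALSE)
    if (is.null(src$path) || !file.exists(resolve(src$path)))
      stop(sprintf("config error: missing source file '%s'",
                   src$path %||% "<missing>"), call. = FALSE)
    if (src$format == "geo_deg" &&
        (is.null(src$study) || is.null(src$group_a) || is.null(src$group_b)))
      stop("config error: geo_deg sources need 'study', 'group_a', 'group_b'",
           call. = FALSE)
  }
  if (!is.null(config$id_mapping) && !file.exists(resolve(config$id_mapping)))
    stop("config error: missing id_mapping file ", config$id_mapping,
         call. = FALSE)
  invisible(TRUE)
}

#' Build a knowledge graph from a declarative configuration
#'
#' Validates the whole configuration up front (unknown formats and missing
#' files are rejected before any import runs), then imports every source in
#' declared order into one graph. Because all population goes through the
#' deduplicating upsert layer, running the same build twice into the same
#' store leaves [kg_stats()] unchanged.
#'
#' @param config A configuration list or a path accepted by
#'   [read_build_config()].
#' @param graph Graph to populate (a fresh one by default).
#' @param base_dir Directory that relative source paths resolve against;
#'   defaults to the config file's directory when `config` is a path.
#' @return List of class `kg_build` with elements `graph`, `reports` (one
#'   `import_report` per source, named by path) and `stats`.
#' @export
run_build <- function(config, graph = kg_new(), base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- read_build_config(config)
  }
  base_dir <- base_dir %||% "."
  validate_build_config(config, base_dir)
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base_dir, p)
  global_mapping <- if (!is.null(config$id_mapping))
    load_id_mapping(resolve(config$id_mapping)) else NULL
  reports <- list()
  for (src in config$sources) {
    p <- resolve(src$path)
    # a source whose identifiers are already accessions can opt out of the
    # id mapping with `use_id_mapping: false`
    mapping <- if (isFALSE(src$use_id_mapping)) NULL else global_mapping
    rep <- switch(src$format,
      blast = import_seqsim(graph, p,
                            evalue_max = src$evalue_max %||% 1e-5,
                            ratio_min = src$ratio_min %||% 0.60),
      mitab = import_mitab(graph, p, mapping),
      disgenet = import_disgenet(
        graph, p, mapping,
        columns = unlist(src$columns) %||% c(gene = "gene_symbol",
                                             disease = "disease_name",
                                             type = "association_type")),
      kaneko = import_kaneko(
        graph, p, mapping,
        category_map = unlist(src$category_map) %||% KANEKO_CATEGORY_MAP),
      drugbank = import_drugbank(graph, p),
      hpa = import_hpa(graph, p, mapping),
      reactome = import_reactome(graph, p, mapping),
      geo_deg = import_geo_deg(graph, src$study, src$group_a, src$group_b,
                               p, mapping,
                               adjp_max = src$adjp_max %||% 0.05))
    reports[[src$path]] <- rep
  }
  kg_validate(graph)
  structure(list(graph = graph, reports = reports, stats = kg_stats(graph)),
            class = "kg_build")
}

#' @export
print.kg_build <- function(x, ...) {
  cat("knowledgebase build\n")
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %s: %d read, %d kept, %d skipped\n",
                nm, r$records_read, r$records_kept, r$records_skipped))
  }
  print(x$stats)
  invisible(x)
}

# --- command-line surface ---------------------------------------------------

cli_parse_flags <- function(args) {
  flags <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      nm <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        flags[[nm]] <- args[i + 1L]
        i <- i + 2L
      } else {
        flags[[nm]] <- TRUE
        i <- i + 1L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = pos)
}

cli_split <- function(x) if (is.null(x)) NULL else strsplit(x, ",", fixed = TRUE)[[1L]]

cli_write_tsv <- function(df, out) {
  utils::write.table(df, out, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Command-line entry point
#'
#' Dispatches the subcommands of the `inst/cli/dknet.R` script: `build`
#' (config in, JSON-lines dump and inventory out), `stats`, `export`
#' (graphml/neo4j_csv/cypher/jsonl), and `query` with the four query
#' patterns (`shared-proteins`, `deg-context`, `drug-seqsim`,
#' `shortest-paths`). Output is deterministic for fixed inputs and flags.
#' Fatal errors print a single-line reason to standard error and return a
#' nonzero status.
#'
#' @param args Character vector of command-line arguments (after
#'   `commandArgs(trailingOnly = TRUE)`).
#' @param out Connection for result output (default standard output).
#' @return Integer exit status, invisibly.
#' @export
kg_cli_main <- function(args, out = stdout()) {
  status <- tryCatch({
    if (!length(args)) stop("usage: dknet.R <build|stats|export|query> ...",
                            call. = FALSE)
    cmd <- args[1L]
    parsed <- cli_parse_flags(args[-1L])
    fl <- parsed$flags
    pos <- parsed$positional
    if (cmd == "build") {
      if (length(pos) < 1L) stop("build needs a config file", call. = FALSE)
      build <- run_build(pos[1L])
      dump <- fl$out %||% build$graph_output %||% "graph.jsonl"
      kg_write_jsonl(build$graph, dump)
      nc <- build$stats$node_counts
      cli_write_tsv(data.frame(label = names(nc), n = as.integer(nc)), out)
      cli_write_tsv(build$stats$edge_counts, out)
    } else if (cmd == "stats") {
      g <- kg_read_jsonl(pos[1L])
      st <- kg_stats(g)
      cli_write_tsv(data.frame(label = names(st$node_counts),
                               n = as.integer(st$node_counts)), out)
      cli_write_tsv(st$edge_counts, out)
    } else if (cmd == "export") {
      if (length(pos) < 3L)
        stop("usage: dknet.R export <dump.jsonl> <format> <path>",
             call. = FALSE)
      g <- kg_read_jsonl(pos[1L])
      export_graph(g, pos[2L], pos[3L])
    } else if (cmd == "query") {
      if (length(pos) < 2L)
        stop("usage: dknet.R query <dump.jsonl> <subcommand> [flags]",
             call. = FALSE)
      g <- kg_read_jsonl(pos[1L])
      sub <- pos[2L]
      res <- switch(sub,
        "shared-proteins" = {
          accs <- shared_disease_proteins(
            g, fl[["disease-a"]], fl[["disease-b"]],
            edge_types = cli_split(fl[["edge-types"]]) %||% DISEASE_EDGE_TYPES)
          data.frame(accession = accs, stringsAsFactors = FALSE)
        },
        "deg-context" = {
          ctx <- deg_disease_pathway_context(
            g, cli_split(fl[["comparisons"]]), fl[["pathway-contains"]],
            cli_split(fl[["diseases"]]))
          data.frame(protein = ctx$proteins, stringsAsFactors = FALSE)
        },
        "drug-seqsim" = drugs_via_seqsim(
          g, fl[["disease"]],
          disease_relation = fl[["relation"]] %||% "BIOMARKER",
          min_score = if (!is.null(fl[["min-score"]]))
            as.numeric(fl[["min-score"]]),
          exclude_direct = isTRUE(fl[["exclude-direct"]])),
        "shortest-paths" = paths_to_df(bounded_all_shortest_paths(
          g, cli_split(fl[["sources"]]), fl[["target"]],
          max_len = as.integer(fl[["max-len"]] %||% 3L),
          allowed_edge_types =
            cli_split(fl[["edge-types"]]) %||% TRAVERSAL_EDGE_TYPES)),
        stop(sprintf("unknown query subcommand '%s'", sub), call. = FALSE))
      cli_write_tsv(res, fl$out %||% out)
    } else {
      stop(sprintf("unknown command '%s'", cmd), call. = FALSE)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
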