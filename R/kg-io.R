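# Serialization: a canonical JSON-lines dump (round-trips through the store)
# plus interoperable exports — GraphML for network tools, bulk-import CSVs
# and a MERGE-based Cypher script for property-graph databases.

#' Write and read the canonical JSON-lines graph dump
#'
#' One JSON object per line: nodes as
#' `{"kind":"node","label":...,"key":...,"properties":{...}}` and edges as
#' `{"kind":"edge","type":...,"src_label":...,"src_key":...,"dst_label":...,
#' "dst_key":...,"properties":{...}}`. Records are emitted in sorted order,
#' so the dump is a pure function of graph content, and loading a dump
#' reproduces identical [kg_stats()].
#'
#' @param graph Knowledge graph.
#' @param path Output (or input) file.
#' @return `kg_write_jsonl()` returns `path` invisibly; `kg_read_jsonl()`
#'   returns a `knowledge_graph`.
#' @export
kg_write_jsonl <- function(graph, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nid in ls(graph$nodes, sorted = TRUE)) {
    n <- graph$nodes[[nid]]
    writeLines(as.character(jsonlite::toJSON(
      list(kind = "node", label = n$label, key = n$key,
           properties = n$properties),
      auto_unbox = TRUE, digits = NA)), con)
  }
  for (eid in ls(graph$edges, sorted = TRUE)) {
    e <- graph$edges[[eid]]
    s <- graph$nodes[[e$src]]
    d <- graph$nodes[[e$dst]]
    writeLines(as.character(jsonlite::toJSON(
      list(kind = "edge", type = e$type, src_label = s$label,
           src_key = s$key, dst_label = d$label, dst_key = d$key,
           properties = e$properties),
      auto_unbox = TRUE, digits = NA)), con)
  }
  invisible(path)
}

#' @rdname kg_write_jsonl
#' @export
kg_read_jsonl <- function(path) {
  if (!file.exists(path)) stop("dump file not found: ", path, call. = FALSE)
  g <- kg_new()
  for (ln in readLines(path, warn = FALSE)) {
    if (!nzchar(ln)) next
    rec <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    props <- as.list(rec$properties)
    if (identical(rec$kind, "node")) {
      kg_upsert_node(g, rec$label, rec$key, props)
    } else if (identical(rec$kind, "edge")) {
      kg_upsert_edge(g, rec$type, rec$src_key, rec$dst_key, props)
    } else {
      stop("malformed dump record (unknown kind): ", ln, call. = FALSE)
    }
  }
  g
}

# Flatten a property list to display scalars: multi-valued entries join with
# ';' (the bulk-import array convention).
flat_prop <- function(v) paste(unlist(v), collapse = ";")

cypher_quote <- function(x) paste0("'", gsub("'", "\\\\'", x), "'")

cypher_value <- function(v) {
  v <- unlist(v)
  lit <- if (is.numeric(v)) format(v, digits = 15) else cypher_quote(v)
  if (length(lit) > 1L) paste0("[", paste(lit, collapse = ", "), "]") else lit
}

#' Export the graph to interoperable formats
#'
#' Supported formats: `"jsonl"` (the canonical dump, see
#' [kg_write_jsonl()]); `"graphml"` (standard GraphML with `label`, `key` and
#' a JSON `properties` attribute, written through igraph); `"neo4j_csv"`
#' (bulk-import node/relationship CSVs with `:ID`, `:LABEL`, `:START_ID`,
#' `:END_ID`, `:TYPE` header conventions, written into a directory); and
#' `"cypher"` (a UTF-8 script of MERGE statements reproducing the graph).
#'
#' @param graph Knowledge graph.
#' @param format One of `"jsonl"`, `"graphml"`, `"neo4j_csv"`, `"cypher"`.
#' @param path Output file, or output directory for `"neo4j_csv"`.
#' @return Character vector of files written, invisibly.
#' @export
export_graph <- function(graph, format = c("jsonl", "graphml", "neo4j_csv",
                                           "cypher"), path) {
  format <- match.arg(format)
  switch(format,
         jsonl = kg_write_jsonl(graph, path),
         graphml = export_graphml(graph, path),
         neo4j_csv = export_neo4j_csv(graph, path),
         cypher = export_cypher(graph, path))
}

export_graphml <- function(graph, path) {
  nodes <- kg_nodes_df(graph)
  edges <- kg_edges_df(graph)
  uid <- function(label, key) paste(label, key, sep = "|")
  vertices <- data.frame(name = uid(nodes$label, nodes$key),
                         label = nodes$label, key = nodes$key,
                         properties = nodes$properties,
                         stringsAsFactors = FALSE)
  if (nrow(edges)) {
    d <- data.frame(from = uid(edges$src_label, edges$src_key),
                    to = uid(edges$dst_label, edges$dst_key),
                    type = edges$type, properties = edges$properties,
                    stringsAsFactors = FALSE)
  } else {
    d <- data.frame(from = character(0), to = character(0),
                    type = character(0), properties = character(0))
  }
  ig <- igraph::graph_from_data_frame(d, directed = TRUE, vertices = vertices)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

export_neo4j_csv <- function(graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nodes <- kg_nodes_df(graph)
  edges <- kg_edges_df(graph)
  uid <- function(label, key) paste(label, key, sep = "|")
  ndf <- data.frame(id = uid(nodes$label, nodes$key), label = nodes$label,
                    key = nodes$key, properties = nodes$properties,
                    stringsAsFactors = FALSE)
  names(ndf) <- c(":ID", ":LABEL", "key", "properties")
  rdf <- data.frame(start = uid(edges$src_label, edges$src_key),
                    end = uid(edges$dst_label, edges$dst_key),
                    type = edges$type, properties = edges$properties,
                    stringsAsFactors = FALSE)
  names(rdf) <- c(":START_ID", ":END_ID", ":TYPE", "properties")
  nfile <- file.path(dir, "nodes.csv")
  rfile <- file.path(dir, "relationships.csv")
  utils::write.csv(ndf, nfile, row.names = FALSE)
  utils::write.csv(rdf, rfile, row.names = FALSE)
  invisible(c(nfile, rfile))
}

export_cypher <- function(graph, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (nid in ls(graph$nodes, sorted = TRUE)) {
    n <- graph$nodes[[nid]]
    line <- sprintf("MERGE (n:%s {key: %s})", n$label, cypher_quote(n$key))
    if (length(n$properties)) {
      sets <- vapply(names(n$properties), function(nm)
        sprintf("n.%s = %s", gsub("[^A-Za-z0-9_]", "_", nm),
                cypher_value(n$properties[[nm]])), "")
      line <- paste0(line, " SET ", paste(sets, collapse = ", "))
    }
    writeLines(paste0(line, ";"), con)
  }
  for (eid in ls(graph$edges, sorted = TRUE)) {
    e <- graph$edges[[eid]]
    s <- graph$nodes[[e$src]]
    d <- graph$nodes[[e$dst]]
    line <- sprintf(
      "MATCH (a:%s {key: %s}), (b:%s {key: %s}) MERGE (a)-[r:%s]->(b)",
      s$label, cypher_quote(s$key), d$label, cypher_quote(d$key), e$type)
    if (length(e$properties)) {
      sets <- vapply(names(e$properties), function(nm)
        sprintf("r.%s = %s", gsub("[^A-Za-z0-9_]", "_", nm),
                cypher_value(e$properties[[nm]])), "")
      line <- paste0(line, " SET ", paste(sets, collapse = ", "))
    }
    writeLines(paste0(line, ";"), con)
  }
  invisible(path)
}
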