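# Typed property-graph store: nodes carry a label and a natural key, edges a
# relationship type from a fixed schema. All mutation goes through upserts that
# enforce natural-key uniqueness and duplicate-free edge semantics.

#' Node labels of the knowledgebase schema
#' @export
NODE_LABELS <- c("Protein", "Disease", "Pathway", "Tissue", "Drug",
                 "GEOStudy", "GEOComparison")

#' Relationship schema
#'
#' Legal endpoint labels per edge type and whether the type is directional.
#' Undirected types (`SEQ_SIM` and the `PPI_*` family) are stored once per
#' unordered endpoint pair.
#' @export
EDGE_SCHEMA <- data.frame(
  type = c("BIOMARKER", "THERAPEUTIC", "GENETIC_VARIATION", "KANEKO_ASSOCIATED",
           "IN_PATHWAY",
           "PPI_ASSOCIATION", "PPI_COLOCALIZATION", "PPI_GENETIC_INTERACTION",
           "SEQ_SIM",
           "TISSUE_ENHANCED",
           "DRUG_TARGET", "DRUG_ENZYME", "DRUG_TRANSPORTER", "DRUG_CARRIER",
           "PART_OF", "DEG_RELATED_TO"),
  src_label = c(rep("Protein", 14L), "GEOComparison", "Protein"),
  dst_label = c(rep("Disease", 4L), "Pathway", rep("Protein", 4L), "Tissue",
                rep("Drug", 4L), "GEOStudy", "GEOComparison"),
  directed = c(rep(TRUE, 5L), rep(FALSE, 4L), rep(TRUE, 7L)),
  stringsAsFactors = FALSE
)

# Property names always merged as sets, even when a single value is supplied.
SET_VALUED_PROPS <- c("ensembl_ids", "methods")

.SEP <- "\u001f"

node_id <- function(label, key) paste(label, key, sep = .SEP)

#' Create an empty knowledge graph
#'
#' A `knowledge_graph` is an environment-backed store of labelled nodes and
#' typed edges. Nodes are unique per (label, natural key); edges are unique per
#' deduplication key (type plus endpoint pair, canonically unordered for the
#' undirected types). Because the store is an environment, the upsert functions
#' modify it in place and return references invisibly.
#'
#' @return An object of class `knowledge_graph`.
#' @seealso [kg_upsert_node()], [kg_upsert_edge()], [kg_stats()]
#' @export
#' @examples
#' g <- kg_new()
#' kg_upsert_node(g, "Protein", "P08727", list(gene_name = "KRT19"))
#' kg_node_count(g)
kg_new <- function() {
  g <- new.env(parent = emptyenv())
  g$nodes <- new.env(parent = emptyenv())      # node_id -> node record
  g$edges <- new.env(parent = emptyenv())      # edge_id -> edge record
  g$by_label <- new.env(parent = emptyenv())   # label -> character keys
  g$incidence <- new.env(parent = emptyenv())  # node_id -> character edge ids
  for (lab in NODE_LABELS) assign(lab, character(0), envir = g$by_label)
  class(g) <- "knowledge_graph"
  g
}

normalize_key <- function(label, key) {
  key <- trimws(as.character(key))
  if (label == "Protein") key <- toupper(key)
  key
}

# Merge an incoming property map into an existing one.
# Rules: new names are added; set-valued properties (any multi-element value,
# or a name in `set_props`) take the sorted union; names in `numeric_max` keep
# the maximum; other scalar conflicts keep the existing value with a warning.
merge_properties <- function(existing, incoming,
                             set_props = SET_VALUED_PROPS,
                             numeric_max = character(0),
                             context = "") {
  nms <- names(incoming)
  if (length(incoming) && (is.null(nms) || any(!nzchar(nms))))
    stop("property names must be non-empty text", call. = FALSE)
  for (nm in nms) {
    new <- incoming[[nm]]
    old <- existing[[nm]]
    if (is.null(old)) {
      existing[[nm]] <- if (nm %in% set_props) sort(unique(unlist(new))) else new
    } else if (nm %in% set_props || is.list(old) || is.list(new) ||
               length(old) > 1L || length(new) > 1L) {
      existing[[nm]] <- sort(unique(c(unlist(old), unlist(new))))
    } else if (nm %in% numeric_max && is.numeric(old) && is.numeric(new)) {
      existing[[nm]] <- max(old, new)
    } else if (!isTRUE(all.equal(old, new))) {
      warning(sprintf("%sproperty '%s': conflicting scalar values, keeping existing",
                      context, nm), call. = FALSE)
    }
  }
  existing
}

#' Insert or update a node
#'
#' Creates the node if no node with this (label, key) exists, otherwise merges
#' the supplied properties into the stored record: new property names are
#' added, set-valued properties (e.g. `ensembl_ids`) take the union, and
#' conflicting scalar values keep the stored value with a warning. Protein keys
#' are UniProt accessions and are uppercased and whitespace-stripped on ingest.
#'
#' @param graph A [kg_new()] knowledge graph (modified in place).
#' @param label Node label, one of
#'   `r paste0('\x60', NODE_LABELS, '\x60', collapse = ", ")`.
#' @param key Non-empty natural key (accession, disease name, pathway id,
#'   tissue name, GEO series id, or `"study::comparison"` for comparisons).
#' @param properties Named list of scalar or vector property values.
#' @return The internal node id, invisibly.
#' @export
kg_upsert_node <- function(graph, label, key, properties = list()) {
  stopifnot(inherits(graph, "knowledge_graph"))
  if (!label %in% NODE_LABELS)
    stop(sprintf("unknown node label '%s'", label), call. = FALSE)
  key <- normalize_key(label, key)
  if (!length(key) || is.na(key) || !nzchar(key))
    stop("node key must be non-empty", call. = FALSE)
  id <- node_id(label, key)
  rec <- graph$nodes[[id]]
  if (is.null(rec)) {
    rec <- list(label = label, key = key,
                properties = merge_properties(list(), properties))
    assign(label, c(graph$by_label[[label]], key), envir = graph$by_label)
  } else {
    rec$properties <- merge_properties(
      rec$properties, properties,
      context = sprintf("node %s/%s: ", label, key))
  }
  graph$nodes[[id]] <- rec
  invisible(id)
}

edge_dedup_id <- function(type, src_id, dst_id, directed) {
  ends <- if (directed) c(src_id, dst_id) else sort(c(src_id, dst_id))
  paste(type, ends[1L], ends[2L], sep = .SEP)
}

#' Insert or update an edge
#'
#' Looks up the schema row for `type` to find the endpoint labels, then
#' creates the edge if its deduplication key is absent, or merges properties
#' into the stored edge otherwise (`methods` is unioned, `confidence` keeps
#' the maximum, other scalar conflicts keep the stored value with a warning).
#' For the undirected types (`SEQ_SIM` and the three `PPI_*` types) the pairs
#' (A,B) and (B,A) resolve to the same stored edge. Both endpoints must
#' already exist in the graph.
#'
#' @param graph Knowledge graph (modified in place).
#' @param type Edge type; see `dknet::EDGE_SCHEMA` for the legal endpoint
#'   labels per type.
#' @param src_key,dst_key Natural keys of the endpoints (labels implied by the
#'   schema; for `DEG_RELATED_TO` the destination is a study-scoped
#'   comparison key such as `"GSE43696::NC-SA"`, which realizes the
#'   protein/comparison/study triple deduplication rule).
#' @param properties Named list of edge properties (e.g. `score` for
#'   `SEQ_SIM`, `adj_p` for `DEG_RELATED_TO`).
#' @return The internal edge id, invisibly.
#' @export
kg_upsert_edge <- function(graph, type, src_key, dst_key, properties = list()) {
  stopifnot(inherits(graph, "knowledge_graph"))
  row <- EDGE_SCHEMA[EDGE_SCHEMA$type == type, ]
  if (!nrow(row))
    stop(sprintf("unknown edge type '%s'", type), call. = FALSE)
  src_key <- normalize_key(row$src_label, src_key)
  dst_key <- normalize_key(row$dst_label, dst_key)
  src <- node_id(row$src_label, src_key)
  dst <- node_id(row$dst_label, dst_key)
  for (end in c(src, dst)) {
    if (is.null(graph$nodes[[end]]))
      stop(sprintf("edge %s: endpoint '%s' not present in graph",
                   type, sub(.SEP, "/", end, fixed = TRUE)), call. = FALSE)
  }
  if (src == dst)
    stop(sprintf("edge %s: self-loops are not allowed", type), call. = FALSE)
  id <- edge_dedup_id(type, src, dst, row$directed)
  rec <- graph$edges[[id]]
  if (is.null(rec)) {
    ends <- if (row$directed) c(src, dst) else sort(c(src, dst))
    rec <- list(id = id, type = type, src = ends[1L], dst = ends[2L],
                directed = row$directed,
                properties = merge_properties(list(), properties,
                                              numeric_max = "confidence"))
    graph$incidence[[src]] <- c(graph$incidence[[src]], id)
    graph$incidence[[dst]] <- c(graph$incidence[[dst]], id)
  } else {
    rec$properties <- merge_properties(
      rec$properties, properties, numeric_max = "confidence",
      context = sprintf("edge %s(%s,%s): ", type, src_key, dst_key))
  }
  graph$edges[[id]] <- rec
  invisible(id)
}

#' @rdname kg_node
#' @export
kg_has_node <- function(graph, label, key) {
  !is.null(graph$nodes[[node_id(label, normalize_key(label, key))]])
}

#' Retrieve a node record
#'
#' @param graph Knowledge graph.
#' @param label,key Node label and natural key.
#' @return `kg_node()` returns the node record (a list with `label`, `key`,
#'   `properties`) or errors if absent; `kg_has_node()` returns a logical.
#' @export
kg_node <- function(graph, label, key) {
  rec <- graph$nodes[[node_id(label, normalize_key(label, key))]]
  if (is.null(rec))
    stop(sprintf("no %s node with key '%s'", label, key), call. = FALSE)
  rec
}

#' @rdname kg_stats
#' @export
kg_node_count <- function(graph) length(ls(graph$nodes, sorted = FALSE))

#' @rdname kg_stats
#' @export
kg_edge_count <- function(graph) length(ls(graph$edges, sorted = FALSE))

#' Node keys for one label
#'
#' @param graph Knowledge graph.
#' @param label Node label.
#' @return Sorted character vector of natural keys.
#' @export
kg_keys <- function(graph, label) {
  if (!label %in% NODE_LABELS)
    stop(sprintf("unknown node label '%s'", label), call. = FALSE)
  sort(graph$by_label[[label]])
}

# Incident edge records of a node id, optionally restricted by type.
incident_edges <- function(graph, nid, edge_types = NULL) {
  ids <- graph$incidence[[nid]]
  if (is.null(ids)) return(list())
  recs <- lapply(ids, function(i) graph$edges[[i]])
  if (!is.null(edge_types))
    recs <- Filter(function(e) e$type %in% edge_types, recs)
  recs
}

other_endpoint <- function(edge, nid) if (edge$src == nid) edge$dst else edge$src

#' Incident edges and neighbouring nodes
#'
#' Returns every edge of the allowed types incident to the node, together with
#' the node at the far end. Undirected types match in both orientations, and
#' directed types are reported regardless of orientation (traversal in this
#' package ignores direction). Results are deterministically ordered by edge
#' type, then neighbour key.
#'
#' @param graph Knowledge graph.
#' @param label,key The node to query.
#' @param edge_types Optional character vector restricting edge types.
#' @return A list of `list(edge = <edge record>, node = <node record>)`.
#' @export
kg_neighbors <- function(graph, label, key, edge_types = NULL) {
  key <- normalize_key(label, key)
  nid <- node_id(label, key)
  if (is.null(graph$nodes[[nid]]))
    stop(sprintf("no %s node with key '%s'", label, key), call. = FALSE)
  recs <- incident_edges(graph, nid, edge_types)
  out <- lapply(recs, function(e) {
    list(edge = e, node = graph$nodes[[other_endpoint(e, nid)]])
  })
  ord <- order(vapply(out, function(x) x$edge$type, ""),
               vapply(out, function(x) x$node$key, ""))
  out[ord]
}

#' Graph occupancy statistics
#'
#' Counts nodes per label and edges per (source label, type, destination
#' label) triple, the shape of a knowledgebase inventory table. Statistics
#' are a pure function of graph content, so re-importing the same sources
#' leaves them unchanged.
#'
#' @param graph Knowledge graph.
#' @return An object of class `kg_stats`: a list with `node_counts` (named
#'   integer vector over all labels) and `edge_counts` (data frame with
#'   columns `src_label`, `type`, `dst_label`, `n`, sorted).
#' @export
kg_stats <- function(graph) {
  node_counts <- vapply(NODE_LABELS,
                        function(l) length(graph$by_label[[l]]), integer(1))
  eids <- ls(graph$edges, sorted = TRUE)
  if (length(eids)) {
    triples <- vapply(eids, function(i) {
      e <- graph$edges[[i]]
      paste(graph$nodes[[e$src]]$label, e$type,
            graph$nodes[[e$dst]]$label, sep = .SEP)
    }, "")
    tab <- table(triples)
    parts <- strsplit(names(tab), .SEP, fixed = TRUE)
    edge_counts <- data.frame(
      src_label = vapply(parts, `[`, "", 1L),
      type = vapply(parts, `[`, "", 2L),
      dst_label = vapply(parts, `[`, "", 3L),
      n = as.integer(tab),
      stringsAsFactors = FALSE)
    edge_counts <- edge_counts[order(edge_counts$src_label, edge_counts$type,
                                     edge_counts$dst_label), , drop = FALSE]
    rownames(edge_counts) <- NULL
  } else {
    edge_counts <- data.frame(src_label = character(0), type = character(0),
                              dst_label = character(0), n = integer(0),
                              stringsAsFactors = FALSE)
  }
  structure(list(node_counts = node_counts, edge_counts = edge_counts),
            class = "kg_stats")
}

#' @export
print.kg_stats <- function(x, ...) {
  cat("Node occurrences:\n")
  nc <- x$node_counts[x$node_counts > 0]
  if (length(nc)) print(nc) else cat("  (empty graph)\n")
  cat("Edge occurrences:\n")
  if (nrow(x$edge_counts)) print(x$edge_counts, row.names = FALSE)
  else cat("  (no edges)\n")
  invisible(x)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph: %d nodes, %d edges>\n",
              kg_node_count(x), kg_edge_count(x)))
  invisible(x)
}

#' @export
summary.knowledge_graph <- function(object, ...) kg_stats(object)

#' Check store invariants by full rescan
#'
#' Verifies referential integrity (every edge endpoint exists), schema
#' conformance of every stored edge, canonical storage of undirected edges,
#' and agreement of the label and incidence indexes with a full rescan of the
#' store. Intended for tests and post-build sanity checks.
#'
#' @param graph Knowledge graph.
#' @return `TRUE` invisibly; errors on the first violated invariant.
#' @export
kg_validate <- function(graph) {
  for (lab in NODE_LABELS) {
    keys <- graph$by_label[[lab]]
    if (anyDuplicated(keys)) stop("duplicate keys in label index: ", lab)
    for (k in keys)
      if (is.null(graph$nodes[[node_id(lab, k)]]))
        stop("label index lists missing node ", lab, "/", k)
  }
  nids <- ls(graph$nodes, sorted = FALSE)
  if (length(nids) != sum(lengths(as.list(graph$by_label))))
    stop("label index does not cover the node store")
  seen <- new.env(parent = emptyenv())
  for (eid in ls(graph$edges, sorted = FALSE)) {
    e <- graph$edges[[eid]]
    for (end in c(e$src, e$dst))
      if (is.null(graph$nodes[[end]]))
        stop("edge with missing endpoint: ", e$type)
    row <- EDGE_SCHEMA[EDGE_SCHEMA$type == e$type, ]
    labs <- c(graph$nodes[[e$src]]$label, graph$nodes[[e$dst]]$label)
    ok <- if (row$directed) identical(labs, c(row$src_label, row$dst_label))
          else setequal(labs, c(row$src_label, row$dst_label))
    if (!ok) stop("edge violates endpoint schema: ", e$type)
    if (!row$directed && e$src > e$dst)
      stop("undirected edge stored non-canonically: ", e$type)
    can <- edge_dedup_id(e$type, e$src, e$dst, row$directed)
    if (!identical(can, eid)) stop("edge id disagrees with dedup key")
    if (!is.null(seen[[can]])) stop("duplicate edge for dedup key")
    seen[[can]] <- TRUE
    for (end in c(e$src, e$dst))
      if (!eid %in% graph$incidence[[end]])
        stop("incidence index misses edge ", e$type)
  }
  for (nid in ls(graph$incidence, sorted = FALSE)) {
    ids <- graph$incidence[[nid]]
    if (anyDuplicated(ids)) stop("duplicate incidence entry at ", nid)
    for (i in ids) if (is.null(graph$edges[[i]]))
      stop("incidence index lists missing edge at ", nid)
  }
  invisible(TRUE)
}

#' Nodes and edges as data frames
#'
#' Flat views of the store, one row per node or edge, with properties carried
#' as a JSON column. Useful for inspection and TSV export.
#'
#' @param graph Knowledge graph.
#' @return A data frame.
#' @export
kg_nodes_df <- function(graph) {
  ids <- ls(graph$nodes, sorted = TRUE)
  recs <- lapply(ids, function(i) graph$nodes[[i]])
  df <- data.frame(
    label = vapply(recs, `[[`, "", "label"),
    key = vapply(recs, `[[`, "", "key"),
    properties = vapply(recs, function(r)
      as.character(jsonlite::toJSON(r$properties, auto_unbox = TRUE)), ""),
    stringsAsFactors = FALSE)
  df[order(df$label, df$key), , drop = FALSE]
}

#' @rdname kg_nodes_df
#' @export
kg_edges_df <- function(graph) {
  ids <- ls(graph$edges, sorted = TRUE)
  recs <- lapply(ids, function(i) graph$edges[[i]])
  split_id <- function(nid) strsplit(nid, .SEP, fixed = TRUE)[[1L]]
  df <- data.frame(
    type = vapply(recs, `[[`, "", "type"),
    src_label = vapply(recs, function(r) split_id(r$src)[1L], ""),
    src_key = vapply(recs, function(r) split_id(r$src)[2L], ""),
    dst_label = vapply(recs, function(r) split_id(r$dst)[1L], ""),
    dst_key = vapply(recs, function(r) split_id(r$dst)[2L], ""),
    directed = vapply(recs, `[[`, NA, "directed"),
    properties = vapply(recs, function(r)
      as.character(jsonlite::toJSON(r$properties, auto_unbox = TRUE)), ""),
    stringsAsFactors = FALSE)
  df <- df[order(df$type, df$src_key, df$dst_key), , drop = FALSE]
  rownames(df) <- NULL
  df
}
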