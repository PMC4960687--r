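# Disease-context mining queries: native pattern-matching and traversal over
# the knowledge graph, mirroring the graph-query idioms a Cypher user would
# write against the same schema. Traversal ignores edge direction throughout;
# relationship semantics are directional but biological paths mix orientations.

#' Edge types linking proteins to diseases
#' @export
DISEASE_EDGE_TYPES <- c("BIOMARKER", "GENETIC_VARIATION", "THERAPEUTIC",
                        "KANEKO_ASSOCIATED")

#' Default edge types for protein-disease traversal
#'
#' Curated disease membership plus the protein-protein relation types
#' (interaction and sequence similarity); the relation classes along which
#' shortest-path exploration is biologically interpretable.
#' @export
TRAVERSAL_EDGE_TYPES <- c("KANEKO_ASSOCIATED", "PPI_ASSOCIATION",
                          "PPI_COLOCALIZATION", "PPI_GENETIC_INTERACTION",
                          "SEQ_SIM")

# Resolve a bare natural key to a node id, searching across labels; errors
# when absent (with near-miss suggestions) or ambiguous.
resolve_key <- function(graph, key, context = "node") {
  hits <- character(0)
  for (lab in NODE_LABELS) {
    k <- normalize_key(lab, key)
    if (!is.null(graph$nodes[[node_id(lab, k)]]))
      hits <- c(hits, node_id(lab, k))
  }
  if (length(hits) == 1L) return(hits)
  if (length(hits) > 1L)
    stop(sprintf("key '%s' matches several labels; qualify the lookup", key),
         call. = FALSE)
  all_keys <- sort(unlist(lapply(NODE_LABELS,
                                 function(l) graph$by_label[[l]])))
  near <- utils::head(agrep(key, all_keys, value = TRUE,
                            ignore.case = TRUE, max.distance = 0.25), 5L)
  stop(sprintf("unknown %s '%s'%s", context, key,
               if (length(near)) paste0("; near misses: ",
                                        paste(near, collapse = ", ")) else ""),
       call. = FALSE)
}

require_disease <- function(graph, key) {
  key <- trimws(key)
  if (!kg_has_node(graph, "Disease", key)) {
    near <- utils::head(agrep(key, graph$by_label[["Disease"]], value = TRUE,
                              ignore.case = TRUE, max.distance = 0.3), 5L)
    stop(sprintf("unknown disease '%s'%s", key,
                 if (length(near)) paste0("; near misses: ",
                                          paste(near, collapse = "; ")) else ""),
         call. = FALSE)
  }
  key
}

#' Proteins shared between two diseases
#'
#' Finds every protein carrying an edge of an allowed disease-association
#' type to both diseases — the pattern used to compare a disease's curated
#' gene complement against a related condition's. Symmetric in its two
#' disease arguments.
#'
#' @param graph Knowledge graph.
#' @param disease_a,disease_b Disease node keys (names).
#' @param edge_types Disease-association edge types to follow; e.g.
#'   `"KANEKO_ASSOCIATED"` alone for the curated review list, or the three
#'   curated DisGeNET classes.
#' @return Sorted character vector of UniProt accessions.
#' @export
#' @examples
#' g <- demo_asthma_kg()
#' shared_disease_proteins(g, "Asthma", "Hypertension, Essential",
#'                         edge_types = "KANEKO_ASSOCIATED")
shared_disease_proteins <- function(graph, disease_a, disease_b,
                                    edge_types = DISEASE_EDGE_TYPES) {
  disease_a <- require_disease(graph, disease_a)
  disease_b <- require_disease(graph, disease_b)
  prot_of <- function(d) {
    nb <- kg_neighbors(graph, "Disease", d, edge_types)
    unique(vapply(nb, function(x) x$node$key, ""))
  }
  sort(intersect(prot_of(disease_a), prot_of(disease_b)))
}

#' Network neighbourhood of differentially expressed genes
#'
#' Selects the proteins differentially expressed in every listed comparison
#' (conjunction over `DEG_RELATED_TO` edges), that sit in at least one
#' pathway whose name contains a filter substring (case-insensitive), and
#' carry at least one association to one of the listed diseases. Returns the
#' witnessing subgraph: the qualifying proteins together with exactly the
#' edges satisfying each clause, plus the comparisons' `PART_OF` links to
#' their studies.
#'
#' @param graph Knowledge graph.
#' @param comparisons Character vector of study-scoped comparison keys
#'   (e.g. `"GSE43696::NC-SA"`); must be non-empty.
#' @param pathway_name_contains Substring matched case-insensitively against
#'   pathway names (e.g. `"signal"` for signalling pathways).
#' @param disease_names Disease node keys the proteins must associate with.
#' @param disease_edge_types Association types accepted for the disease
#'   clause.
#' @return An object of class `context_subgraph`: node-key sets `proteins`,
#'   `pathways`, `diseases`, `comparisons`, `studies` and the witness `edges`.
#' @export
deg_disease_pathway_context <- function(graph, comparisons,
                                        pathway_name_contains,
                                        disease_names,
                                        disease_edge_types = DISEASE_EDGE_TYPES) {
  if (!length(comparisons))
    stop("at least one comparison key is required", call. = FALSE)
  for (cmp in comparisons)
    if (!kg_has_node(graph, "GEOComparison", cmp))
      stop(sprintf("unknown comparison '%s'", cmp), call. = FALSE)
  disease_names <- trimws(disease_names)
  pathway_match <- function(node) {
    nm <- node$properties$name %||% node$key
    grepl(pathway_name_contains, nm, ignore.case = TRUE, fixed = FALSE)
  }
  # candidates: proteins differentially expressed in the first comparison
  cand <- kg_neighbors(graph, "GEOComparison", comparisons[1L],
                       "DEG_RELATED_TO")
  cand_keys <- sort(unique(vapply(cand, function(x) x$node$key, "")))

  proteins <- character(0); pathways <- character(0); diseases <- character(0)
  edges <- list()
  for (p in cand_keys) {
    nb <- kg_neighbors(graph, "Protein", p)
    deg <- Filter(function(x) x$edge$type == "DEG_RELATED_TO" &&
                    x$node$key %in% comparisons, nb)
    if (length(unique(vapply(deg, function(x) x$node$key, ""))) <
        length(comparisons)) next
    pw <- Filter(function(x) x$edge$type == "IN_PATHWAY" && pathway_match(x$node),
                 nb)
    if (!length(pw)) next
    dis <- Filter(function(x) x$edge$type %in% disease_edge_types &&
                    x$node$key %in% disease_names, nb)
    if (!length(dis)) next
    proteins <- c(proteins, p)
    pathways <- c(pathways, vapply(pw, function(x) x$node$key, ""))
    diseases <- c(diseases, vapply(dis, function(x) x$node$key, ""))
    edges <- c(edges, lapply(c(deg, pw, dis), `[[`, "edge"))
  }
  studies <- character(0)
  for (cmp in comparisons) {
    po <- kg_neighbors(graph, "GEOComparison", cmp, "PART_OF")
    studies <- c(studies, vapply(po, function(x) x$node$key, ""))
    edges <- c(edges, lapply(po, `[[`, "edge"))
  }
  edges <- edges[!duplicated(vapply(edges, `[[`, "", "id"))]
  structure(list(proteins = sort(unique(proteins)),
                 pathways = sort(unique(pathways)),
                 diseases = sort(unique(diseases)),
                 comparisons = sort(unique(comparisons)),
                 studies = sort(unique(studies)),
                 edges = edges),
            class = "context_subgraph")
}

#' @export
print.context_subgraph <- function(x, ...) {
  cat(sprintf(paste0("context subgraph: %d proteins, %d pathways, %d diseases,",
                     " %d comparisons, %d studies, %d edges\n"),
              length(x$proteins), length(x$pathways), length(x$diseases),
              length(x$comparisons), length(x$studies), length(x$edges)))
  if (length(x$proteins))
    cat("proteins:", paste(x$proteins, collapse = ", "), "\n")
  invisible(x)
}

#' Drug leads through sequence similarity to disease biomarkers
#'
#' Enumerates the repurposing pattern drug -- DRUG_TARGET --> target protein
#' -- SEQ_SIM -- biomarker -- association --> disease: drugs whose known
#' target is sequence-similar to a protein associated with the disease,
#' suggesting an indirect drug-disease link even when the drug does not
#' target the biomarker itself.
#'
#' @param graph Knowledge graph.
#' @param disease Disease node key.
#' @param disease_relation Association edge type anchoring the biomarker
#'   (default `"BIOMARKER"`).
#' @param min_score Optional lower bound on the similarity edge's score.
#' @param exclude_direct Drop leads whose drug also targets the biomarker
#'   directly.
#' @return Data frame with one row per (drug, target, biomarker) instance:
#'   columns `drug`, `target`, `biomarker`, `seqsim_score`,
#'   `direct_target_of_biomarker`, ordered by (drug, target, biomarker).
#' @export
drugs_via_seqsim <- function(graph, disease, disease_relation = "BIOMARKER",
                             min_score = NULL, exclude_direct = FALSE) {
  disease <- require_disease(graph, disease)
  out <- list()
  bm <- kg_neighbors(graph, "Disease", disease, disease_relation)
  for (b in bm) {
    biomarker <- b$node$key
    direct_drugs <- vapply(
      kg_neighbors(graph, "Protein", biomarker, "DRUG_TARGET"),
      function(x) x$node$key, "")
    for (ss in kg_neighbors(graph, "Protein", biomarker, "SEQ_SIM")) {
      target <- ss$node$key
      score <- ss$edge$properties$score %||% NA_real_
      if (!is.null(min_score) && (is.na(score) || score < min_score)) next
      for (dt in kg_neighbors(graph, "Protein", target, "DRUG_TARGET")) {
        drug <- dt$node$key
        direct <- drug %in% direct_drugs
        if (exclude_direct && direct) next
        out[[length(out) + 1L]] <- data.frame(
          drug = drug, target = target, biomarker = biomarker,
          seqsim_score = score, direct_target_of_biomarker = direct,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(drug = character(0), target = character(0),
                      biomarker = character(0), seqsim_score = numeric(0),
                      direct_target_of_biomarker = logical(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- unique(df)
  df <- df[order(df$drug, df$target, df$biomarker), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Breadth-first distances from a start node over allowed types, direction
# ignored, stopping after max_depth layers.
bfs_distances <- function(graph, start_id, allowed_types = NULL,
                          max_depth = Inf) {
  dist <- new.env(parent = emptyenv())
  dist[[start_id]] <- 0L
  frontier <- start_id
  d <- 0L
  while (length(frontier) && d < max_depth) {
    nxt <- character(0)
    for (nid in frontier) {
      for (e in incident_edges(graph, nid, allowed_types)) {
        o <- other_endpoint(e, nid)
        if (is.null(dist[[o]])) {
          dist[[o]] <- d + 1L
          nxt <- c(nxt, o)
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  dist
}

new_kg_path <- function(graph, node_ids, edges) {
  nodes <- vapply(node_ids, function(i) graph$nodes[[i]]$key, "",
                  USE.NAMES = FALSE)
  labels <- vapply(node_ids, function(i) graph$nodes[[i]]$label, "",
                   USE.NAMES = FALSE)
  structure(list(nodes = nodes, node_labels = labels, edges = edges,
                 length = length(nodes) - 1L),
            class = "kg_path")
}

#' @export
print.kg_path <- function(x, ...) {
  if (!x$length) {
    cat(sprintf("<path length 0: %s>\n", x$nodes))
    return(invisible(x))
  }
  types <- vapply(x$edges, `[[`, "", "type")
  seq_ <- character(0)
  for (i in seq_len(x$length))
    seq_ <- c(seq_, x$nodes[i], sprintf("-[%s]-", types[i]))
  cat("<path>", paste(c(seq_, x$nodes[x$length + 1L]), collapse = " "), "\n")
  invisible(x)
}

# All shortest simple paths from src to the BFS origin, walking strictly
# decreasing distance layers (which guarantees simplicity and minimality).
# When several allowed edges join one hop, the edge with the smallest type
# is recorded as the witness; paths are identified by their node sequence.
enumerate_shortest <- function(graph, src_id, dist, allowed_types) {
  walk <- function(nid, d) {
    if (d == 0L) return(list(list(ids = nid, edges = list())))
    steps <- list()  # neighbour id -> witness edge
    for (e in incident_edges(graph, nid, allowed_types)) {
      o <- other_endpoint(e, nid)
      dn <- dist[[o]]
      if (is.null(dn) || dn != d - 1L) next
      prev <- steps[[o]]
      if (is.null(prev) || e$type < prev$type) steps[[o]] <- e
    }
    res <- list()
    for (o in names(steps)) {
      for (tail in walk(o, d - 1L)) {
        res[[length(res) + 1L]] <-
          list(ids = c(nid, tail$ids), edges = c(steps[o], tail$edges))
      }
    }
    res
  }
  raw <- walk(src_id, dist[[src_id]])
  paths <- lapply(raw, function(p) new_kg_path(graph, p$ids, unname(p$edges)))
  keys <- vapply(paths, function(p) paste(p$nodes, collapse = .SEP), "")
  paths[order(keys)]
}

#' Bounded all-shortest-paths from sources to a target
#'
#' For each source, finds the shortest-path length `k` to the target over the
#' allowed edge types with direction ignored; if `k <= max_len`, returns
#' every simple path of length exactly `k`, otherwise an empty list. A source
#' equal to the target yields one zero-length path. Path multiplicity is
#' counted over node sequences; see the methods vignette for the witness-edge
#' convention when parallel relation types join one hop.
#'
#' @param graph Knowledge graph.
#' @param sources Character vector of node keys (typically accessions).
#'   Unknown sources yield an empty result with a warning.
#' @param target Node key (protein accession or disease name); must exist.
#' @param max_len Maximum path length in edges (a cap of 3 realizes
#'   "paths of length < 4").
#' @param allowed_edge_types Edge types traversal may use; default
#'   [TRAVERSAL_EDGE_TYPES].
#' @return Named list, one entry per source, each a list of `kg_path`
#'   objects ordered lexicographically by node-key sequence.
#' @export
#' @examples
#' g <- demo_asthma_kg()
#' bounded_all_shortest_paths(g, "Q99743", "Asthma", max_len = 3)
bounded_all_shortest_paths <- function(graph, sources, target, max_len = 3L,
                                       allowed_edge_types = TRAVERSAL_EDGE_TYPES) {
  stopifnot(max_len >= 0L)
  target_id <- resolve_key(graph, target, context = "target")
  dist <- bfs_distances(graph, target_id, allowed_edge_types,
                        max_depth = max_len)
  out <- vector("list", length(sources))
  names(out) <- sources
  for (s in sources) {
    sid <- tryCatch(resolve_key(graph, s, context = "source"),
                    error = function(e) NA_character_)
    if (is.na(sid)) {
      warning(sprintf("unknown source '%s'; returning no paths", s),
              call. = FALSE)
      out[[s]] <- list()
      next
    }
    if (sid == target_id) {
      out[[s]] <- list(new_kg_path(graph, sid, list()))
      next
    }
    d <- dist[[sid]]
    out[[s]] <- if (is.null(d) || d > max_len) list()
                else enumerate_shortest(graph, sid, dist, allowed_edge_types)
  }
  out
}

path_signature <- function(p) paste(p$nodes, collapse = .SEP)

canonical_signature <- function(p) {
  fwd <- paste(p$nodes, collapse = .SEP)
  rev_ <- paste(rev(p$nodes), collapse = .SEP)
  min(fwd, rev_)
}

#' Shortest paths between two node sets
#'
#' Union over the target set of [bounded_all_shortest_paths()] results (each
#' source-target pair contributes its own shortest paths), with a path and
#' its reverse counted once.
#'
#' @inheritParams bounded_all_shortest_paths
#' @param targets Character vector of target node keys.
#' @return List of `kg_path` objects, deduplicated and ordered
#'   lexicographically by node-key sequence.
#' @export
shortest_paths_between_sets <- function(graph, sources, targets, max_len = 3L,
                                        allowed_edge_types = TRAVERSAL_EDGE_TYPES) {
  all_paths <- list()
  for (tg in targets) {
    res <- bounded_all_shortest_paths(graph, sources, tg, max_len,
                                      allowed_edge_types)
    for (ps in res) all_paths <- c(all_paths, ps)
  }
  if (!length(all_paths)) return(list())
  sig <- vapply(all_paths, canonical_signature, "")
  all_paths <- all_paths[!duplicated(sig)]
  all_paths[order(vapply(all_paths, path_signature, ""))]
}

#' Tabulate path results
#'
#' @param paths A list of `kg_path` objects, or the named per-source list
#'   returned by [bounded_all_shortest_paths()].
#' @return Data frame with one row per path: `source`, `target`, `length`,
#'   `nodes` (keys joined by `" - "`), `edge_types`.
#' @export
paths_to_df <- function(paths) {
  if (length(paths) && !inherits(paths[[1L]], "kg_path"))
    paths <- unlist(paths, recursive = FALSE)
  if (!length(paths))
    return(data.frame(source = character(0), target = character(0),
                      length = integer(0), nodes = character(0),
                      edge_types = character(0), stringsAsFactors = FALSE))
  data.frame(
    source = vapply(paths, function(p) p$nodes[1L], ""),
    target = vapply(paths, function(p) p$nodes[length(p$nodes)], ""),
    length = vapply(paths, `[[`, 0L, "length"),
    nodes = vapply(paths, function(p) paste(p$nodes, collapse = " - "), ""),
    edge_types = vapply(paths, function(p)
      paste(vapply(p$edges, `[[`, "", "type"), collapse = ","), ""),
    stringsAsFactors = FALSE)
}
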