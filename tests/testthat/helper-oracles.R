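# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately use a different algorithmic route than the
# implementation: nested-loop pair enumeration for the similarity filters and
# exhaustive depth-first simple-path enumeration for traversal.

# Brute-force reciprocal-hit derivation: enumerate every unordered accession
# pair and re-evaluate the three filter rules per direction.
oracle_seqsim <- function(hits, evalue_max = 1e-5, ratio_min = 0.60) {
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  accs <- sort(unique(c(hits$query_id, hits$subject_id)))
  best_e <- function(q, s) {
    rows <- hits[hits$query_id == q & hits$subject_id == s, , drop = FALSE]
    if (!nrow(rows)) return(NA_real_)
    keep <- rows$evalue <= evalue_max &
      rows$aln_len / pmin(rows$query_len, rows$subject_len) > ratio_min
    if (!any(keep)) return(NA_real_)
    min(rows$evalue[keep])
  }
  out <- list()
  for (i in seq_along(accs)) {
    for (j in seq_len(i - 1L)) {
      a <- accs[j]
      b <- accs[i]
      e1 <- best_e(a, b)
      e2 <- best_e(b, a)
      if (is.na(e1) || is.na(e2)) next
      e <- pmax(c(e1, e2), 1e-180)
      out[[length(out) + 1L]] <- data.frame(
        protein_a = a, protein_b = b, score = -log10(mean(e)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  m <- do.call(rbind, out)
  m <- m[order(m$protein_a, m$protein_b), , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Random directional hit tables with duplicated rows, self-hits and values
# clustered around both thresholds.
random_hits <- function(seed, n_acc = 12L, n_hits = 80L) {
  set.seed(seed)
  accs <- sprintf("RT%03d", seq_len(n_acc))
  lens <- stats::setNames(sample(80:400, n_acc, replace = TRUE), accs)
  q <- sample(accs, n_hits, replace = TRUE)
  s <- sample(accs, n_hits, replace = TRUE)
  e <- 10^stats::runif(n_hits, -12, -2)
  e[sample(n_hits, 3L)] <- 1e-5
  e[sample(n_hits, 2L)] <- 0
  mn <- pmin(lens[q], lens[s])
  aln <- pmax(1L, round(mn * stats::runif(n_hits, 0.4, 1.0)))
  data.frame(query_id = q, subject_id = s, evalue = e, aln_len = aln,
             query_len = unname(lens[q]), subject_len = unname(lens[s]),
             stringsAsFactors = FALSE)
}

# Exhaustive simple-path enumeration up to max_len, then min-length filter;
# returns the sorted node-key sequence signatures of all shortest paths.
oracle_shortest_signatures <- function(graph, source, target, max_len,
                                       types = NULL) {
  src <- dknet:::resolve_key(graph, source)
  tgt <- dknet:::resolve_key(graph, target)
  found <- list()
  recurse <- function(nid, path_ids) {
    if (nid == tgt) {
      found[[length(found) + 1L]] <<- path_ids
      return(invisible(NULL))
    }
    if (length(path_ids) - 1L >= max_len) return(invisible(NULL))
    for (e in dknet:::incident_edges(graph, nid, types)) {
      o <- dknet:::other_endpoint(e, nid)
      if (o %in% path_ids) next
      recurse(o, c(path_ids, o))
    }
  }
  recurse(src, src)
  if (!length(found)) return(character(0))
  lens <- vapply(found, length, 0L) - 1L
  keep <- found[lens == min(lens)]
  sigs <- vapply(keep, function(ids)
    paste(vapply(ids, function(i) graph$nodes[[i]]$key, ""), collapse = "|"),
    "")
  sort(unique(sigs))
}

path_signatures <- function(paths) {
  sort(vapply(paths, function(p) paste(p$nodes, collapse = "|"), ""))
}

# One MITAB 2.5 line with the fields the importer reads populated.
mitab_row <- function(a, b,
                      method = "psi-mi:\"MI:0018\"(two hybrid)",
                      type = "psi-mi:\"MI:0915\"(physical association)",
                      conf = "intact-miscore:0.56") {
  f <- rep("-", 15L)
  f[1L] <- paste0("uniprotkb:", a)
  f[2L] <- paste0("uniprotkb:", b)
  f[7L] <- method
  f[12L] <- type
  f[15L] <- conf
  paste(f, collapse = "\t")
}

# Tiny protein-protein graph from an edge list of key pairs.
ppi_graph <- function(pairs, type = "PPI_ASSOCIATION") {
  g <- kg_new()
  for (p in unique(unlist(pairs))) kg_upsert_node(g, "Protein", p)
  for (e in pairs) kg_upsert_edge(g, type, e[[1L]], e[[2L]])
  g
}
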