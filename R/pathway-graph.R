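# Pathway graphs: GO biological-process terms parsed from OBO into a typed
# directed graph (child -> parent edges of five relation types, rooted at
# GO:0008150), KEGG pathways as an undirected "related" graph, extraction of
# the significant-node subgraph with root-connecting paths, and plain-text
# export.

.go_relations <- c("is_a", "part_of", "regulates",
                   "positively_regulates", "negatively_regulates")

#' Parse a GO OBO file into a typed pathway graph
#'
#' Retains terms of one namespace (default `biological_process`) and the five
#' relation types `is_a`, `part_of`, `regulates`, `positively_regulates`,
#' `negatively_regulates` as directed child -> parent edges. Obsolete terms
#' are dropped; edges to terms outside the namespace are ignored.
#'
#' @param path Path to an OBO 1.2/1.4 file.
#' @param namespace Namespace to keep.
#' @param root Root term id that must be present (default `GO:0008150`).
#' @return Directed `igraph` with vertex attributes `name` (id), `term_name`,
#'   `namespace`; edge attribute `relation`; graph attributes `root`,
#'   `source = "GO"`.
#' @export
parse_obo <- function(path, namespace = "biological_process",
                      root = "GO:0008150") {
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                  obsolete = FALSE, parents = character(0),
                  relations = character(0))
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { # other stanza type ([Typedef], ...)
      terms <- flush(cur, terms)
      cur <- NULL; in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (!grepl("^[a-z_]+:", ln)) {
      warning("skipping malformed OBO line ", i, ": ", ln, call. = FALSE)
      next
    }
    key <- sub(":.*$", "", ln)
    val <- sub("^[a-z_]+:\\s*", "", ln)
    val <- sub("\\s*!.*$", "", val)  # strip trailing comment
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "is_a") {
      cur$parents <- c(cur$parents, val)
      cur$relations <- c(cur$relations, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] %in% .go_relations) {
        cur$parents <- c(cur$parents, parts[2L])
        cur$relations <- c(cur$relations, parts[1L])
      }
    }
  }
  terms <- flush(cur, terms)
  keep <- vapply(terms, function(t)
    !t$obsolete && identical(t$namespace, namespace), logical(1))
  terms <- terms[keep]
  if (!root %in% names(terms)) {
    stop("root term ", root, " not found in namespace '", namespace, "'",
         call. = FALSE)
  }
  ids <- names(terms)
  edges <- data.table::rbindlist(lapply(terms, function(t) {
    ok <- t$parents %in% ids & t$parents != t$id
    if (!any(ok)) return(NULL)
    data.table::data.table(from = t$id, to = t$parents[ok],
                           relation = t$relations[ok])
  }))
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
                            term_name = vapply(terms, `[[`, "", "name"),
                            namespace = namespace)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to),
                           relation = edges$relation)
  }
  g <- igraph::set_graph_attr(g, "root", root)
  igraph::set_graph_attr(g, "source", "GO")
}

#' Parse a KEGG pathway relation edge list
#'
#' Two tab-separated columns of pathway ids (header required); duplicate and
#' reversed edges are collapsed, self-edges dropped. An optional two-column
#' names file supplies display names; edges naming unknown pathways are kept
#' with the id as a placeholder name and a warning.
#'
#' @param path Path to the edge list.
#' @param names_path Optional id -> name table.
#' @return Undirected `igraph`; edge attribute `relation = "related"`; graph
#'   attribute `source = "KEGG"`.
#' @export
parse_kegg_relations <- function(path, names_path = NULL) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("KEGG edge list needs 2 columns", call. = FALSE)
  names_map <- character(0)
  if (!is.null(names_path)) {
    nm <- data.table::fread(names_path, sep = "\t", header = TRUE,
                            colClasses = "character")
    names_map <- stats::setNames(as.character(nm[[2L]]), as.character(nm[[1L]]))
  }
  a <- as.character(tab[[1L]]); b <- as.character(tab[[2L]])
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  ids <- sort(unique(c(a, b, names(names_map))))
  if (length(names_map) && any(!c(a, b) %in% names(names_map))) {
    warning("edge list names pathways absent from the names file; ",
            "ids used as placeholder names", call. = FALSE)
  }
  term_names <- ifelse(ids %in% names(names_map), names_map[ids], ids)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids,
                            term_name = unname(term_names))
  if (length(a)) {
    g <- igraph::add_edges(g, rbind(a, b), relation = "related")
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = "first")
  }
  igraph::set_graph_attr(g, "source", "KEGG")
}

#' Extract the significant-pathway subgraph
#'
#' GO (directed, rooted): the subgraph induced by the significant nodes plus
#' every non-significant node lying on a parent-edge path from a significant
#' node to the root — i.e. the ancestors (breadth-first over child -> parent
#' edges, all five relation types) from which the root is reachable — plus the
#' root itself. Significant nodes missing from the graph are warned about and
#' dropped; significant nodes not connected to the root stay as isolated
#' ancestry components, with a warning. With an empty significant set the
#' subgraph contains the root only.
#'
#' KEGG (undirected, no root): the significant nodes plus their one-hop
#' "related" neighbours, with all edges among the included set.
#'
#' Node attributes set on the result: `significant`, `dscore` (from
#' `records`, `NA` when absent), `n_genes` and `size = log(n_genes)` (from
#' `gene_sets`, when supplied).
#'
#' @param graph Output of [parse_obo()] or [parse_kegg_relations()].
#' @param significant_ids Character vector of significant pathway ids.
#' @param records Optional enrichment record table with `pathway_id`, `dscore`.
#' @param gene_sets Optional named list of member genes (for node sizes).
#' @return An `igraph` subgraph.
#' @export
significant_subgraph <- function(graph, significant_ids, records = NULL,
                                 gene_sets = NULL) {
  ids <- unique(as.character(significant_ids))
  missing <- setdiff(ids, igraph::V(graph)$name)
  if (length(missing)) {
    warning("dropping ", length(missing),
            " significant id(s) absent from the graph: ",
            paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    ids <- setdiff(ids, missing)
  }
  src <- igraph::graph_attr(graph, "source")
  if (igraph::is_directed(graph)) {
    root <- igraph::graph_attr(graph, "root")
    # nodes from which the root is reachable (root's in-component)
    reaches_root <- igraph::subcomponent(graph, root, mode = "in")$name
    include <- root
    for (id in ids) {
      anc <- igraph::subcomponent(graph, id, mode = "out")$name  # BFS ancestors
      on_path <- intersect(anc, reaches_root)
      if (!id %in% on_path) {
        warning("significant node ", id, " is not connected to the root; ",
                "kept as an isolated component", call. = FALSE)
        on_path <- union(on_path, anc)
      }
      include <- union(include, on_path)
    }
  } else {
    include <- ids
    if (length(ids)) {
      nb <- unlist(igraph::adjacent_vertices(graph, ids), use.names = FALSE)
      include <- union(include, igraph::V(graph)$name[nb])
    }
  }
  sub <- igraph::induced_subgraph(graph, include)
  vnames <- igraph::V(sub)$name
  sub <- igraph::set_vertex_attr(sub, "significant", value = vnames %in% ids)
  ds <- rep(NA_real_, length(vnames))
  if (!is.null(records) && nrow(records)) {
    idx <- match(vnames, records$pathway_id)
    ds[!is.na(idx)] <- records$dscore[idx[!is.na(idx)]]
  }
  sub <- igraph::set_vertex_attr(sub, "dscore", value = ds)
  ng <- rep(NA_integer_, length(vnames))
  if (!is.null(gene_sets)) {
    sizes <- lengths(gene_sets)
    idx <- match(vnames, names(sizes))
    ng[!is.na(idx)] <- as.integer(sizes[idx[!is.na(idx)]])
  }
  sub <- igraph::set_vertex_attr(sub, "n_genes", value = ng)
  sub <- igraph::set_vertex_attr(
    sub, "size", value = ifelse(!is.na(ng) & ng >= 1L, log(ng), NA_real_))
  igraph::set_graph_attr(sub, "source", src)
}

#' Export a subgraph as a tab-separated edge list plus a JSON node table
#'
#' Writes `<prefix>_edges.tsv` (`from`, `to`, `relation`; sorted) and
#' `<prefix>_nodes.json` (array of objects with `id`, `name`, `dscore`,
#' `significant`, `n_genes`, `size`; sorted by id) for diffable, Cytoscape
#' style rendering downstream.
#'
#' @param subgraph Output of [significant_subgraph()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the two paths, invisibly.
#' @export
export_subgraph <- function(subgraph, dir, prefix = "subgraph") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  edge_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  node_path <- file.path(dir, paste0(prefix, "_nodes.json"))
  el <- igraph::as_data_frame(subgraph, what = "edges")
  if (!nrow(el)) {
    el <- data.frame(from = character(), to = character(),
                     relation = character())
  }
  el <- el[order(el$from, el$to), c("from", "to", "relation"), drop = FALSE]
  data.table::fwrite(el, edge_path, sep = "\t", quote = FALSE)
  nd <- igraph::as_data_frame(subgraph, what = "vertices")
  nd <- nd[order(nd$name), , drop = FALSE]
  nodes <- data.frame(id = unname(nd$name),
                      name = unname(if ("term_name" %in% names(nd))
                        nd$term_name else nd$name),
                      dscore = unname(nd$dscore),
                      significant = unname(nd$significant),
                      n_genes = unname(nd$n_genes),
                      size = unname(nd$size),
                      stringsAsFactors = FALSE, row.names = NULL)
  meta <- list(source = igraph::graph_attr(subgraph, "source"),
               directed = igraph::is_directed(subgraph),
               nodes = nodes)
  jsonlite::write_json(meta, node_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(edges = edge_path, nodes = node_path))
}

#' Re-import an exported subgraph
#'
#' Round-trip counterpart of [export_subgraph()]; used to verify exports.
#'
#' @param edge_path,node_path The two files written by [export_subgraph()].
#' @return An `igraph` isomorphic to the exported subgraph.
#' @export
import_subgraph <- function(edge_path, node_path) {
  meta <- jsonlite::read_json(node_path, simplifyVector = TRUE)
  nodes <- meta$nodes
  el <- data.table::fread(edge_path, sep = "\t", header = TRUE,
                          colClasses = "character")
  g <- igraph::make_empty_graph(n = 0, directed = isTRUE(meta$directed))
  g <- igraph::add_vertices(g, nrow(nodes), name = nodes$id,
                            term_name = nodes$name,
                            dscore = as.numeric(nodes$dscore),
                            significant = as.logical(nodes$significant),
                            n_genes = suppressWarnings(as.integer(nodes$n_genes)),
                            size = as.numeric(nodes$size))
  if (nrow(el)) {
    g <- igraph::add_edges(g, rbind(el$from, el$to), relation = el$relation)
  }
  igraph::set_graph_attr(g, "source", meta$source)
}
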