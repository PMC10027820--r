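# Directed weighted scanpath networks: construction from scanpaths,
# adjacency views, averaging across readers, and the visualization mask.

#' Construct a scanpath network from a weight matrix
#'
#' The canonical in-memory representation is directed: `weights[i, j]` is the
#' number (or averaged number) of saccades from word `i` to word `j`.
#' Self-loops are forbidden — consecutive refixations of one word contribute
#' no edge, and the adjacency diagonal is structurally empty.
#'
#' @param weights Square numeric matrix with node keys as dimnames,
#'   non-negative entries and a zero diagonal.
#' @param provenance List identifying the source (participant/text ids, or
#'   `"averaged"`).
#' @param mask `NULL`, or the `list(degree_gt, weight_gt)` recorded by
#'   [apply_mask()].
#' @return An object of class `scanpath_network`.
#' @export
scanpath_network <- function(weights, provenance = list(), mask = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (nrow(weights) < 1L) stop("a scanpath network needs at least one node")
  if (is.null(rownames(weights)) ||
      !identical(rownames(weights), colnames(weights))) {
    stop("weights must carry identical row/column node keys")
  }
  if (anyDuplicated(rownames(weights))) stop("duplicate node keys")
  if (any(weights < 0)) stop("edge weights must be non-negative")
  if (any(diag(weights) != 0)) stop("self-loops are not allowed (diagonal must be zero)")
  structure(
    list(nodes = rownames(weights), weights = weights,
         directed = TRUE, provenance = provenance, mask = mask),
    class = "scanpath_network"
  )
}

#' Build a directed weighted network from a scanpath
#'
#' Every fixated word type becomes a node (reoccurring words merge into one
#' node) and every saccade between two different words increments the directed
#' edge weight between them by one. Consecutive refixations of the same word
#' produce no edge. The scanpath \code{could humans live mars day could
#' humans} therefore yields 5 nodes and total edge weight 6, with
#' w(could -> humans) = 2.
#'
#' @param sp A [scanpath()] (or bare character vector of node keys, handy for
#'   examples and tests).
#' @param link_sentences Keep edges between consecutive fixations that span a
#'   sentence boundary (default `TRUE`). With `FALSE`, scanpaths are encoded
#'   sentence by sentence and only merged word nodes connect sentences.
#' @return A [scanpath_network()].
#' @export
build_network <- function(sp, link_sentences = TRUE) {
  if (is.character(sp)) {
    keys <- sp
    sent <- rep(1L, length(keys))
    prov <- list()
  } else {
    stopifnot(inherits(sp, "scanpath"))
    keys <- sp$entries$node_key
    sent <- sp$entries$sentence_index
    prov <- list(participant_id = sp$participant_id, text_id = sp$text_id)
  }
  if (length(keys) == 0L) stop("cannot build a network from an empty scanpath")
  nodes <- unique(keys)
  n <- length(nodes)
  w <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (length(keys) > 1L) {
    from <- keys[-length(keys)]
    to <- keys[-1L]
    ok <- from != to
    if (!link_sentences) ok <- ok & (sent[-length(sent)] == sent[-1L])
    for (k in which(ok)) {
      w[from[k], to[k]] <- w[from[k], to[k]] + 1
    }
  }
  scanpath_network(w, provenance = prov)
}

#' @export
print.scanpath_network <- function(x, ...) {
  cat(sprintf("Scanpath network: %d nodes, %d directed edges, total weight %g\n",
              length(x$nodes), sum(x$weights > 0), sum(x$weights)))
  if (!is.null(x$mask)) {
    cat(sprintf("  masked: degree > %g, weight > %g\n",
                x$mask$degree_gt, x$mask$weight_gt))
  }
  prov <- x$provenance
  if (length(prov) > 0L) {
    cat("  source:", paste(unlist(prov), collapse = " / "), "\n")
  }
  invisible(x)
}

#' @export
summary.scanpath_network <- function(object, ...) {
  s <- node_strengths(object)
  out <- list(n_nodes = length(object$nodes),
              n_edges = sum(object$weights > 0),
              total_weight = sum(object$weights),
              density = if (length(object$nodes) >= 2) net_density(object) else NA_real_,
              strength_range = range(s))
  class(out) <- "summary.scanpath_network"
  out
}

#' @export
print.summary.scanpath_network <- function(x, ...) {
  cat(sprintf("nodes %d | edges %d | total weight %g | density %s | strength [%g, %g]\n",
              x$n_nodes, x$n_edges, x$total_weight,
              formatC(x$density, digits = 4), x$strength_range[1],
              x$strength_range[2]))
  invisible(x)
}

#' Adjacency-matrix view of a network
#'
#' The directed view returns the stored weights w_ij. The undirected view is
#' the presentation used in transition tables ("regardless of direction"):
#' cell (i, j) = cell (j, i) = w_ij + w_ji. Only the directed view is
#' lossless.
#'
#' @param net A [scanpath_network()].
#' @param directed Logical; `FALSE` returns the symmetrized view.
#' @return Numeric matrix with node keys as dimnames.
#' @export
as_adjacency <- function(net, directed = TRUE) {
  stopifnot(inherits(net, "scanpath_network"))
  if (directed) net$weights else net$weights + t(net$weights)
}

#' Rebuild a network from a directed adjacency matrix
#'
#' Inverse of `as_adjacency(net, directed = TRUE)`.
#'
#' @param adj Square named numeric matrix of directed weights, zero diagonal.
#' @param provenance Passed through to [scanpath_network()].
#' @return A [scanpath_network()].
#' @export
from_adjacency <- function(adj, provenance = list()) {
  scanpath_network(adj, provenance = provenance)
}

#' Node degree (strength)
#'
#' The degree of a word node is the sum of weights of all its connected edges
#' in both directions — the total number of saccades that landed on and
#' departed from that word.
#'
#' @param net A [scanpath_network()].
#' @param node Node key.
#' @return Non-negative number.
#' @seealso [node_strengths()] for all nodes at once.
#' @export
node_degree <- function(net, node) {
  stopifnot(inherits(net, "scanpath_network"))
  if (!node %in% net$nodes) stop("unknown node: ", node)
  sum(net$weights[node, ]) + sum(net$weights[, node])
}

#' Strength of every node
#'
#' @param net A [scanpath_network()].
#' @return Named numeric vector of strengths (in/out weight sums).
#' @export
node_strengths <- function(net) {
  stopifnot(inherits(net, "scanpath_network"))
  rowSums(net$weights) + colSums(net$weights)
}

#' Average scanpath networks across readers
#'
#' Aligns the networks on the union of their vocabularies and averages each
#' directed edge weight, counting an edge absent from a reader's network as 0.
#' This is the group-level aggregation used to contrast the top and bottom
#' readers of a cohort before masking and visualization.
#'
#' @param nets Non-empty list of [scanpath_network()]s over the same text.
#' @return A [scanpath_network()] with provenance `"averaged"`.
#' @export
average_networks <- function(nets) {
  stopifnot(is.list(nets), length(nets) >= 1L)
  for (n in nets) stopifnot(inherits(n, "scanpath_network"))
  texts <- unique(unlist(lapply(nets, function(n) n$provenance$text_id)))
  if (length(texts) > 1L) {
    stop("cannot average networks built over different texts: ",
         paste(texts, collapse = ", "))
  }
  vocab <- unique(unlist(lapply(nets, function(n) n$nodes)))
  acc <- matrix(0, length(vocab), length(vocab), dimnames = list(vocab, vocab))
  for (n in nets) acc[n$nodes, n$nodes] <- acc[n$nodes, n$nodes] + n$weights
  scanpath_network(acc / length(nets),
                   provenance = list(source = "averaged",
                                     n_networks = length(nets),
                                     text_id = if (length(texts)) texts else NULL))
}

#' Mask a network for visualization
#'
#' Drops low-representativeness structure: first edges with weight <=
#' `weight_gt`, then (degrees recomputed on the edge-filtered graph) nodes
#' with degree <= `degree_gt`, then edges incident to dropped nodes. Both
#' thresholds are strict "greater than" cuts, so an edge of weight exactly
#' 0.3 is removed under the default.
#'
#' @param net A [scanpath_network()].
#' @param degree_gt Keep nodes with degree strictly above this (default 5).
#' @param weight_gt Keep edges with weight strictly above this (default 0.3).
#' @return A masked [scanpath_network()] (possibly with zero surviving
#'   nodes, signalled by a warning).
#' @export
apply_mask <- function(net, degree_gt = 5, weight_gt = 0.3) {
  stopifnot(inherits(net, "scanpath_network"))
  if (degree_gt < 0 || weight_gt < 0) stop("mask thresholds must be non-negative")
  w <- net$weights
  w[w <= weight_gt] <- 0
  deg <- rowSums(w) + colSums(w)
  keep <- deg > degree_gt
  if (!any(keep)) {
    warning("mask removed every node; returning an empty masked network")
    w2 <- matrix(0, 0, 0, dimnames = list(character(0), character(0)))
  } else {
    w2 <- w[keep, keep, drop = FALSE]
  }
  out <- structure(
    list(nodes = rownames(w2), weights = w2, directed = TRUE,
         provenance = net$provenance,
         mask = list(degree_gt = degree_gt, weight_gt = weight_gt)),
    class = "scanpath_network"
  )
  out
}

#' Convert to an igraph graph
#'
#' @param net A [scanpath_network()].
#' @return A directed weighted [igraph::igraph] object with a `degree` node
#'   attribute holding the strength.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "scanpath_network"))
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$degree <- unname(node_strengths(net))
  g
}

#' Export a network to GraphML
#'
#' @param net A [scanpath_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network to GEXF
#'
#' Writes a minimal GEXF 1.2 document (directed, weighted, with a `degree`
#' node attribute).
#'
#' @param net A [scanpath_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(net, path) {
  stopifnot(inherits(net, "scanpath_network"))
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "degree",
                      type = "double")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  strengths <- node_strengths(net)
  for (i in seq_along(net$nodes)) {
    nd <- xml2::xml_add_child(nodes_el, "node", id = net$nodes[i],
                              label = net$nodes[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = format(strengths[i]))
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  idx <- which(net$weights > 0, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    for (k in seq_len(nrow(idx))) {
      xml2::xml_add_child(edges_el, "edge", id = as.character(k - 1L),
                          source = net$nodes[idx[k, 1]],
                          target = net$nodes[idx[k, 2]],
                          weight = format(net$weights[idx[k, 1], idx[k, 2]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write an adjacency matrix to CSV
#'
#' Header row and first column carry the node keys.
#'
#' @param net A [scanpath_network()].
#' @param path Output path.
#' @param directed Adjacency view, see [as_adjacency()].
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(net, path, directed = TRUE) {
  adj <- as_adjacency(net, directed = directed)
  utils::write.csv(adj, path, row.names = TRUE)
  invisible(path)
}

#' Plot a scanpath network
#'
#' Force-directed layout with node size proportional to degree (strength) and
#' edge width proportional to weight; directed arrows distinguish forward
#' saccades from regressions. The layout is deterministic given `seed`.
#'
#' @param x A [scanpath_network()].
#' @param seed Layout seed.
#' @param node_scale,edge_scale Visual scaling factors.
#' @param ... Passed on to [igraph::plot.igraph()].
#' @return `x`, invisibly.
#' @export
plot.scanpath_network <- function(x, seed = 1L, node_scale = 12,
                                  edge_scale = 2.5, ...) {
  if (length(x$nodes) == 0L) {
    message("empty (fully masked) network; nothing to plot")
    return(invisible(x))
  }
  g <- as_igraph(x)
  s <- node_strengths(x)
  size <- if (max(s) > 0) node_scale * (0.25 + 0.75 * s / max(s)) else node_scale / 2
  ew <- igraph::E(g)$weight
  width <- if (length(ew) && max(ew) > 0) edge_scale * ew / max(ew) + 0.3 else 1
  lay <- with_local_seed(seed, igraph::layout_with_fr(g))
  igraph::plot.igraph(g, layout = lay, vertex.size = size,
                      edge.width = width, edge.arrow.size = 0.3,
                      vertex.label.cex = 0.7, ...)
  invisible(x)
}
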