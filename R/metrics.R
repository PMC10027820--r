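# The five scanpath-network metrics: density, Freeman degree centralization,
# directed weighted transitivity, global efficiency, and small-worldness,
# plus the supporting clustering coefficient, characteristic path length,
# inverse-weight shortest distances, and the random reference ensemble.
#
# All formulas operate on the directed weight matrix W (zero diagonal) and
# its symmetrized form A = W + t(W). Node degree k_i is the strength
# sum_j (w_ij + w_ji).

weight_matrix <- function(net) {
  if (inherits(net, "scanpath_network")) return(net$weights)
  if (is.matrix(net)) return(net)
  stop("expected a scanpath_network or a weight matrix")
}

#' Network density
#'
#' Wiring cost of the network: the sum of directed edge weights divided by the
#' number of possible directed edges,
#' \deqn{D = \sum_{i \ne j} w_{ij} / (N (N - 1)).}
#' For a binary graph this is the usual edge density in \[0, 1\]; with saccade
#' counts as weights it can exceed 1.
#'
#' @param net A [scanpath_network()] (or weight matrix).
#' @return Density `D`.
#' @export
net_density <- function(net) {
  w <- weight_matrix(net)
  n <- nrow(w)
  if (n < 2L) stop("density is undefined for networks with fewer than 2 nodes")
  sum(w) / (n * (n - 1))
}

#' Freeman graph centralization
#'
#' Global dispersion of node degree scores around the most central node,
#' \deqn{C = \sum_i (C_{max} - C_i) / ((N - 1)(N - 2)),}
#' where by default `C_i` is the node strength (sum of incident edge weights,
#' both directions). On unit-weight graphs the score is 0 for degree-regular
#' structures and 1 for a perfect star. `binarize = TRUE` counts distinct
#' neighbors instead of summing weights, which keeps the score inside
#' \[0, 1\] for any weighting.
#'
#' @param net A [scanpath_network()] (or weight matrix).
#' @param binarize Use distinct-neighbor degrees instead of weighted
#'   strengths.
#' @return Centralization `C`.
#' @export
net_centralization <- function(net, binarize = FALSE) {
  w <- weight_matrix(net)
  n <- nrow(w)
  if (n < 3L) stop("centralization is undefined for networks with fewer than 3 nodes")
  k <- if (binarize) {
    rowSums((w + t(w)) > 0)
  } else {
    rowSums(w) + colSums(w)
  }
  sum(max(k) - k) / ((n - 1) * (n - 2))
}

#' Classify network topology from centralization
#'
#' Maps a Freeman centralization score onto the conventional topology bands:
#' \[0, 0.2) "linear", \[0.2, 0.4) "hierarchical", \[0.4, 0.6) "network",
#' \[0.6, 1\] "star". Scores outside \[0, 1\] (possible with weighted
#' strengths) are clamped with a warning.
#'
#' @param C Centralization score(s).
#' @return Factor with levels linear, hierarchical, network, star.
#' @export
classify_topology <- function(C) {
  stopifnot(is.numeric(C))
  if (any(C < 0 | C > 1)) {
    warning("centralization outside [0, 1]; clamping before classification")
    C <- pmin(pmax(C, 0), 1)
  }
  cut(C, breaks = c(-Inf, 0.2, 0.4, 0.6, Inf), right = FALSE,
      labels = c("linear", "hierarchical", "network", "star"))
}

# Directed weighted triangle count around every node:
#   t_i = 1/2 sum_{j,h} (w_ij + w_ji)(w_ih + w_hi)(w_jh + w_hj)
# With A = W + t(W) (zero diagonal) this is diag(A^3) / 2; the j = h terms
# vanish because A_jj = 0.
triangle_counts <- function(w) {
  a <- w + t(w)
  diag(a %*% a %*% a) / 2
}

#' Directed weighted transitivity
#'
#' Graph segregation: the relative number of directed weighted triangles over
#' the number of connected triples,
#' \deqn{T = \sum_i t_i \Big/ \sum_i \left[ k_i (k_i - 1)
#'   - 2 \sum_j w_{ij} w_{ji} \right],}
#' with \eqn{t_i = \frac{1}{2}\sum_{j,h} (w_{ij}+w_{ji})(w_{ih}+w_{hi})
#' (w_{jh}+w_{hj})} and \eqn{k_i} the node strength. Raw weights enter the
#' products directly (no normalization). On binary symmetric graphs this
#' reduces exactly to the classic global clustering coefficient.
#'
#' When the network has no connected triples (denominator not positive) the
#' value is 0 with attribute `undefined = TRUE` rather than an error.
#'
#' @param net A [scanpath_network()] (or weight matrix).
#' @return Transitivity `T`.
#' @export
net_transitivity <- function(net) {
  w <- weight_matrix(net)
  k <- rowSums(w) + colSums(w)
  t_i <- triangle_counts(w)
  denom <- sum(k * (k - 1) - 2 * rowSums(w * t(w)))
  if (denom <= 0) {
    return(structure(0, undefined = TRUE))
  }
  sum(t_i) / denom
}

#' Inverse-weight shortest-path distances
#'
#' All-pairs directed shortest distances where each edge's length is the
#' inverse of its weight (a stronger saccade link means a shorter distance).
#' Unreachable ordered pairs get `Inf`; the diagonal is 0.
#'
#' @param net A [scanpath_network()] (or weight matrix).
#' @return N x N numeric matrix `d_ij` with node-key dimnames.
#' @export
shortest_distances <- function(net) {
  w <- weight_matrix(net)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "directed",
                                           weighted = TRUE, diag = FALSE)
  ew <- igraph::E(g)$weight
  d <- igraph::distances(g, mode = "out",
                         weights = if (length(ew)) 1 / ew else numeric(0))
  d[rownames(w), colnames(w), drop = FALSE]
}

#' Global efficiency
#'
#' Graph integration: the mean inverse shortest-path distance over ordered
#' node pairs,
#' \deqn{E = \frac{1}{N} \sum_i \frac{\sum_{j \ne i} d_{ij}^{-1}}{N - 1},}
#' with distances from [shortest_distances()]. Unreachable pairs contribute 0,
#' so `E` is defined on disconnected networks; it is 1 exactly when every
#' ordered pair is joined by a unit-weight edge and 0 for an edgeless graph.
#'
#' @param net A [scanpath_network()] (or weight matrix).
#' @return Efficiency `E`.
#' @export
net_efficiency <- function(net) {
  w <- weight_matrix(net)
  n <- nrow(w)
  if (n < 2L) stop("global efficiency is undefined for networks with fewer than 2 nodes")
  d <- shortest_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Clustering coefficient
#'
#' Mean local clustering over nodes,
#' \deqn{C = \frac{1}{n} \sum_i \frac{2 t_i}{k_i (k_i - 1)},}
#' with the directed weighted triangle count `t_i` and strength `k_i` as in
#' [net_transitivity()]. Nodes with \eqn{k_i (k_i - 1) \le 0} (leaves and
#' isolates, common in scanpath networks) contribute 0.
#'
#' @param net A [scanpath_network()] (or weight matrix).
#' @return Clustering coefficient.
#' @export
net_clustering <- function(net) {
  w <- weight_matrix(net)
  k <- rowSums(w) + colSums(w)
  t_i <- triangle_counts(w)
  denom <- k * (k - 1)
  term <- ifelse(denom > 0, 2 * t_i / denom, 0)
  mean(term)
}

#' Characteristic path length
#'
#' Two modes. `"mean_distance"` (default) is the standard characteristic path
#' length: the mean of finite inverse-weight shortest distances over reachable
#' ordered pairs. `"as_printed"` evaluates the mean-inverse-distance form
#' \eqn{L = \frac{1}{n}\sum_i \sum_{j\ne i} d_{ij}^{-1}/(n-1)}, which is
#' algebraically identical to [net_efficiency()]; it is kept because some
#' method descriptions state the formula in this form. The mode used is
#' recorded wherever `L` enters a derived quantity.
#'
#' @param net A [scanpath_network()] (or weight matrix).
#' @param mode `"mean_distance"` or `"as_printed"`.
#' @return Path length `L`.
#' @export
net_path_length <- function(net, mode = c("mean_distance", "as_printed")) {
  mode <- match.arg(mode)
  w <- weight_matrix(net)
  if (nrow(w) < 2L) stop("path length is undefined for networks with fewer than 2 nodes")
  if (mode == "as_printed") return(net_efficiency(w))
  d <- shortest_distances(w)
  off <- d[row(d) != col(d)]
  finite <- off[is.finite(off)]
  if (length(finite) == 0L) stop("no reachable node pairs; path length undefined")
  mean(finite)
}

#' Random reference ensemble
#'
#' Null model for small-worldness: each reference network keeps the number of
#' nodes and the number of directed edges of the source, places the edges
#' uniformly at random over ordered node pairs (no duplicates, no
#' self-loops), and permutes the original multiset of edge weights onto them.
#' The ensemble's mean clustering coefficient and characteristic path length
#' are returned alongside the members; everything is reproducible from
#' `seed`.
#'
#' @param net A [scanpath_network()] (or weight matrix) with at least one
#'   edge.
#' @param n_refs Ensemble size (default 20).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param l_mode Path-length mode, see [net_path_length()].
#' @return List of class `random_reference_ensemble` with elements `refs`,
#'   `C_rand`, `L_rand`, `n_refs`, `seed`, `l_mode`.
#' @export
random_reference <- function(net, n_refs = 20L, seed = NULL,
                             l_mode = "mean_distance") {
  w <- weight_matrix(net)
  n <- nrow(w)
  pos <- which(w > 0)
  m <- length(pos)
  if (m < 1L) stop("random reference requires at least one edge")
  if (n_refs < 1L) stop("n_refs must be at least 1")
  wts <- w[pos]
  # ordered off-diagonal cell indices of an n x n matrix
  offdiag <- which(row(w) != col(w))
  refs <- with_local_seed(seed, {
    lapply(seq_len(n_refs), function(r) {
      cells <- sample(offdiag, m)
      wr <- matrix(0, n, n, dimnames = dimnames(w))
      wr[cells] <- sample(wts)
      wr
    })
  })
  C_vals <- vapply(refs, net_clustering, numeric(1))
  L_vals <- vapply(refs, function(x) {
    tryCatch(net_path_length(x, mode = l_mode), error = function(e) NA_real_)
  }, numeric(1))
  structure(
    list(refs = lapply(refs, function(x) scanpath_network(x,
           provenance = list(source = "random_reference"))),
         C_rand = mean(C_vals), L_rand = mean(L_vals, na.rm = TRUE),
         C_values = C_vals, L_values = L_vals,
         n_refs = as.integer(n_refs), seed = seed, l_mode = l_mode),
    class = "random_reference_ensemble"
  )
}

#' Small-worldness
#'
#' Clustering-over-path-length ratio normalized by a size-matched random
#' reference ensemble,
#' \deqn{S = (C / L) / (C_{rand} / L_{rand}),}
#' where `C` is the clustering coefficient and `L` the characteristic path
#' length (same `l_mode` for the network and the references). A value above 1
#' indicates small-world structure: more clustered than random at comparable
#' path length.
#'
#' @param net A [scanpath_network()] (or weight matrix).
#' @param n_refs Random reference ensemble size (default 20).
#' @param seed Integer seed for the ensemble.
#' @param l_mode Path-length mode, see [net_path_length()].
#' @return Small-worldness `S` with attributes `C`, `L`, `C_rand`, `L_rand`.
#' @export
net_small_worldness <- function(net, n_refs = 20L, seed = NULL,
                                l_mode = "mean_distance") {
  w <- weight_matrix(net)
  C <- net_clustering(w)
  L <- net_path_length(w, mode = l_mode)
  ens <- random_reference(w, n_refs = n_refs, seed = seed, l_mode = l_mode)
  if (!is.finite(ens$C_rand) || ens$C_rand <= 0) {
    stop("random reference clustering is zero; raise n_refs or check the network")
  }
  if (!is.finite(ens$L_rand) || ens$L_rand <= 0) {
    stop("random reference path length undefined")
  }
  if (L <= 0) stop("characteristic path length must be positive")
  structure((C / L) / (ens$C_rand / ens$L_rand),
            C = C, L = L, C_rand = ens$C_rand, L_rand = ens$L_rand)
}

#' Compute the full metric set for a network
#'
#' Bundles density, centralization (plus its topology class), transitivity,
#' global efficiency and small-worldness with the provenance needed to
#' reproduce them (seed, ensemble size, path-length mode). Metrics whose
#' preconditions fail on the given network (too few nodes, no edges) are
#' returned as `NA` with the failure recorded in `flags`, never silently
#' dropped. Small-worldness is only attempted on networks with at least 4
#' nodes and one edge.
#'
#' @param net A [scanpath_network()].
#' @param n_refs Random reference ensemble size.
#' @param seed Integer seed for the small-worldness ensemble.
#' @param l_mode Path-length mode, see [net_path_length()].
#' @param binarize Passed to [net_centralization()].
#' @return An object of class `metric_set`.
#' @export
metric_set <- function(net, n_refs = 20L, seed = NULL,
                       l_mode = "mean_distance", binarize = FALSE) {
  stopifnot(inherits(net, "scanpath_network"))
  flags <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      flags <<- c(flags, paste0(name, ": ", conditionMessage(e)))
      NA_real_
    })
  }
  n <- length(net$nodes)
  D <- grab("density", net_density(net))
  C <- grab("centralization", net_centralization(net, binarize = binarize))
  T_ <- grab("transitivity", as.numeric(net_transitivity(net)))
  E <- grab("efficiency", net_efficiency(net))
  S <- if (n >= 4L && sum(net$weights > 0) >= 1L) {
    grab("small_worldness",
         as.numeric(net_small_worldness(net, n_refs = n_refs, seed = seed,
                                        l_mode = l_mode)))
  } else {
    flags <- c(flags, "small_worldness: requires >= 4 nodes and >= 1 edge")
    NA_real_
  }
  topo <- if (is.finite(C) && C >= 0 && C <= 1) {
    as.character(classify_topology(C))
  } else {
    NA_character_
  }
  structure(
    list(density = D, centralization = C, transitivity = T_,
         efficiency = E, small_worldness = S, topology = topo,
         n_nodes = n, n_edges = sum(net$weights > 0),
         total_weight = sum(net$weights),
         n_refs = as.integer(n_refs), seed = seed, l_mode = l_mode,
         binarize = binarize, flags = flags,
         provenance = net$provenance),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  cat("Scanpath network metrics\n")
  cat(sprintf("  nodes %d, edges %d, total weight %g\n",
              x$n_nodes, x$n_edges, x$total_weight))
  fmt <- function(v) if (is.na(v)) "NA" else formatC(v, digits = 4, format = "g")
  cat(sprintf("  density          %s\n", fmt(x$density)))
  cat(sprintf("  centralization   %s%s\n", fmt(x$centralization),
              if (!is.na(x$topology)) paste0(" (", x$topology, ")") else ""))
  cat(sprintf("  transitivity     %s\n", fmt(x$transitivity)))
  cat(sprintf("  efficiency       %s\n", fmt(x$efficiency)))
  cat(sprintf("  small-worldness  %s  (n_refs %d, L mode %s)\n",
              fmt(x$small_worldness), x$n_refs, x$l_mode))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(density = x$density, centralization = x$centralization,
             transitivity = x$transitivity, efficiency = x$efficiency,
             small_worldness = x$small_worldness,
             topology = x$topology %||% NA_character_,
             n_nodes = x$n_nodes, n_edges = x$n_edges,
             n_refs = x$n_refs, l_mode = x$l_mode,
             stringsAsFactors = FALSE)
}

#' Ring lattice generator
#'
#' Watts-Strogatz-style undirected ring lattice on `n` nodes, each linked to
#' its `k` nearest neighbors (`k/2` on each side), with each edge rewired to
#' a uniformly random endpoint with probability `p_rewire`. Stored as
#' reciprocal unit-weight arcs; the classic benchmark substrate for
#' small-world structure.
#'
#' @param n Number of nodes.
#' @param k Even neighborhood size.
#' @param p_rewire Per-edge rewiring probability.
#' @param seed Integer seed.
#' @return A [scanpath_network()].
#' @export
ring_lattice <- function(n, k, p_rewire = 0, seed = NULL) {
  stopifnot(n >= 3L, k >= 2L, k %% 2L == 0L, k < n)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ((i - 1L + seq_len(k / 2L)) %% n) + 1L)
  }))
  with_local_seed(seed, {
    has_edge <- function(el, a, b) {
      any((el[, 1] == a & el[, 2] == b) | (el[, 1] == b & el[, 2] == a))
    }
    if (p_rewire > 0) {
      for (e in seq_len(nrow(edges))) {
        if (stats::runif(1) < p_rewire) {
          a <- edges[e, 1]
          cand <- setdiff(seq_len(n), a)
          el_rest <- edges[-e, , drop = FALSE]
          for (try in seq_len(50L)) {
            b <- sample(cand, 1L)
            if (!has_edge(el_rest, a, b)) {
              edges[e, 2] <- b
              break
            }
          }
        }
      }
    }
    edges
  }) -> edges
  w <- matrix(0, n, n, dimnames = list(paste0("v", seq_len(n)),
                                       paste0("v", seq_len(n))))
  for (e in seq_len(nrow(edges))) {
    w[edges[e, 1], edges[e, 2]] <- 1
    w[edges[e, 2], edges[e, 1]] <- 1
  }
  scanpath_network(w, provenance = list(source = "ring_lattice", n = n, k = k,
                                        p_rewire = p_rewire))
}

#' Uniform random directed network
#'
#' Places `n_arcs` directed unit-weight edges uniformly over ordered node
#' pairs without duplicates or self-loops — the same null model that
#' [random_reference()] uses, exposed as a generator for calibration checks.
#'
#' @param n Number of nodes.
#' @param n_arcs Number of directed edges.
#' @param seed Integer seed.
#' @return A [scanpath_network()].
#' @export
random_network <- function(n, n_arcs, seed = NULL) {
  stopifnot(n >= 2L, n_arcs >= 1L, n_arcs <= n * (n - 1L))
  w <- matrix(0, n, n, dimnames = list(paste0("v", seq_len(n)),
                                       paste0("v", seq_len(n))))
  offdiag <- which(row(w) != col(w))
  cells <- with_local_seed(seed, sample(offdiag, n_arcs))
  w[cells] <- 1
  scanpath_network(w, provenance = list(source = "random_network"))
}
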